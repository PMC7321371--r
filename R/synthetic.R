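#' Specification for a synthetic decoy ensemble
#'
#' The generator emulates the two-level structure of server decoy sets for a
#' CASP-style target: a handful of distinct backbone conformations (classes)
#' plus per-template noise. Class centers are the reference backbone
#' deformed along distinct smooth low-frequency displacement fields —
#' mirroring the observation that discriminant coordinates of real ensembles
#' capture concerted movements of the chain — and templates add isotropic
#' per-atom Gaussian noise around their center.
#'
#' @param residue_count number of residues (>= 10).
#' @param n_classes number of conformational classes, 2..10; default 4.
#' @param templates_per_class templates per class (>= 2); default 25, giving
#'   ensembles in the size range of typical server decoy sets.
#' @param class_shift_scale magnitude, in Angstrom, of the displacement of
#'   each class center from the reference backbone; default 3.
#' @param within_noise per-atom, per-coordinate Gaussian standard deviation
#'   within a class, in Angstrom; default 0.5.
#' @param seed integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(residue_count, n_classes = 4,
                           templates_per_class = 25,
                           class_shift_scale = 3.0, within_noise = 0.5,
                           seed = 1) {
  if (residue_count < 10)
    stop("`residue_count` must be at least 10", call. = FALSE)
  if (n_classes < 2 || n_classes > 10)
    stop("`n_classes` must be between 2 and 10", call. = FALSE)
  if (templates_per_class < 2)
    stop("`templates_per_class` must be at least 2", call. = FALSE)
  structure(
    list(residue_count = as.integer(residue_count),
         n_classes = as.integer(n_classes),
         templates_per_class = as.integer(templates_per_class),
         class_shift_scale = class_shift_scale,
         within_noise = within_noise, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a smooth self-avoiding reference backbone
#'
#' Builds an ideal-helix C-alpha geometry (3.8 Angstrom virtual bonds, 100
#' degrees of twist and 1.5 Angstrom rise per residue) whose local frame
#' drifts by small seeded random rotations, producing a gently curved,
#' self-avoiding chain. Consecutive CA-CA distances are exact 3.8 Angstrom
#' chords by construction; helix geometry keeps non-bonded residues
#' (|i - j| >= 3) beyond contact distance.
#'
#' @param residue_count number of residues (>= 10).
#' @param seed integer seed.
#' @return A [ca_trace] labelled `"reference"`.
#' @export
make_reference_backbone <- function(residue_count, seed = 1) {
  if (residue_count < 10)
    stop("`residue_count` must be at least 10", call. = FALSE)
  set.seed(seed)
  rise <- 1.5
  twist <- 100 * pi / 180
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(twist / 2))
  i <- seq_len(residue_count) - 1
  ideal <- cbind(radius * cos(i * twist), radius * sin(i * twist), rise * i)
  steps <- ideal[-1, , drop = FALSE] - ideal[-residue_count, , drop = FALSE]
  # slowly drifting frame: accumulate small random rotations
  rot <- diag(3)
  coords <- matrix(0, residue_count, 3)
  for (s in seq_len(residue_count - 1)) {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    angle <- stats::rnorm(1, 0, 0.5 * pi / 180)
    rot <- rot %*% rotation_about_axis(axis, angle)
    coords[s + 1, ] <- coords[s, ] + as.vector(rot %*% steps[s, ])
  }
  ca_trace(coords, label = "reference")
}

# Rodrigues rotation matrix for a unit axis and angle
rotation_about_axis <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a template ensemble with planted class structure
#'
#' Each class center is the reference backbone displaced along a distinct
#' constant-magnitude low-frequency mode: residue `i` of class `c` moves by
#' `class_shift_scale * (sin(theta_i) u_c + cos(theta_i) w_c)` with
#' `theta_i = 2 pi f_c i / n + phase_c`, one full period times the class
#' index (`f_c = c`) along the chain, and `u_c`, `w_c` a random orthonormal
#' direction pair. Templates add isotropic Gaussian noise (`within_noise`)
#' around their center. Energies come from the supplied energy model; in
#' test mode a per-class offset is added so that one-dimensional k-means on
#' energy recovers the structural classes exactly.
#'
#' @param spec a [synthetic_spec].
#' @param energy an [energy_model()]; default the surrogate potential.
#' @param class_energy_offset optional numeric: if given, class `c` templates
#'   get `(c - 1) * class_energy_offset` added to their energies (test mode).
#' @return List with `ensemble` (a [template_ensemble]), `reference` (the
#'   planted [ca_trace]) and `truth` (a `class_partition` with the generating
#'   labels).
#' @export
make_template_ensemble <- function(spec, energy = energy_model("surrogate"),
                                   class_energy_offset = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  reference <- make_reference_backbone(spec$residue_count, seed = spec$seed)
  set.seed(spec$seed + 1L)
  n <- spec$residue_count
  k <- spec$n_classes
  m <- spec$templates_per_class
  centers <- vector("list", k)
  for (c in seq_len(k)) {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    u <- q[, 1]; w <- q[, 2]
    phase <- stats::runif(1, 0, 2 * pi)
    theta <- 2 * pi * c * (seq_len(n) - 1) / n + phase
    disp <- spec$class_shift_scale *
      (outer(sin(theta), u) + outer(cos(theta), w))
    centers[[c]] <- reference$coords + disp
  }
  traces <- vector("list", k * m)
  labels <- character(k * m)
  truth <- integer(k * m)
  idx <- 0L
  for (c in seq_len(k)) {
    for (j in seq_len(m)) {
      idx <- idx + 1L
      noise <- matrix(stats::rnorm(3 * n, 0, spec$within_noise), n, 3)
      labels[idx] <- sprintf("class%d_tmpl%02d", c, j)
      traces[[idx]] <- ca_trace(centers[[c]] + noise, label = labels[idx])
      truth[idx] <- c
    }
  }
  energies <- vapply(traces, function(t) evaluate_energy(energy, t),
                     numeric(1))
  if (!is.null(class_energy_offset))
    energies <- energies + (truth - 1) * class_energy_offset
  ens <- template_ensemble(traces, energies, labels)
  truth_part <- structure(
    list(k = k, labels = truth, class_sizes = tabulate(truth, k),
         centroids = vapply(seq_len(k), function(c) mean(energies[truth == c]),
                            numeric(1))),
    class = "class_partition"
  )
  list(ensemble = ens, reference = reference, truth = truth_part)
}

#' Write a synthetic ensemble to disk as a pipeline fixture
#'
#' Writes one PDB file per template, the planted reference as
#' `reference.pdb`, the template energies as `energies.tsv` (label, energy)
#' and the generating truth as `truth.json` — the fixture layout consumed by
#' [run_prediction()] and the command-line `predict` subcommand.
#'
#' @param spec a [synthetic_spec].
#' @param dir output directory (created if needed).
#' @param energy an [energy_model()] used to score the templates.
#' @param class_energy_offset see [make_template_ensemble()].
#' @return Invisibly, the [make_template_ensemble()] result.
#' @export
write_synthetic_ensemble <- function(spec, dir,
                                     energy = energy_model("surrogate"),
                                     class_energy_offset = NULL) {
  gen <- make_template_ensemble(spec, energy, class_energy_offset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ens <- gen$ensemble
  for (i in seq_len(ens$n_templates))
    write_ca_trace(ensemble_trace(ens, i),
                   file.path(dir, paste0(ens$labels[i], ".pdb")))
  write_ca_trace(gen$reference, file.path(dir, "reference.pdb"))
  utils::write.table(
    data.frame(label = ens$labels, energy = ens$energies),
    file.path(dir, "energies.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(labels = gen$truth$labels, reference = "reference.pdb",
         n_classes = gen$truth$k),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(gen)
}
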