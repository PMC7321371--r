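#' Surrogate knowledge-based energy for C-alpha traces
#'
#' A deliberately simple stand-in scoring function with the qualitative shape
#' of a knowledge-based potential (lower is better). It penalises deviation of
#' consecutive CA-CA distances from the ideal 3.8 Angstrom virtual bond,
#' steric clashes between sequence-distant residues, and deviation of the
#' radius of gyration from the globular-protein scaling `2.2 * n^0.38`:
#'
#' \deqn{E = w_{bond} \sum_i (d_{i,i+1} - 3.8)^2 +
#'          w_{rep} \sum_{|i-j| \ge 3,\, d_{ij} < 4} (4 - d_{ij})^2 +
#'          w_{rg} (R_g - R_g^{ref})^2}
#'
#' It is invariant under rigid transforms and deterministic.
#'
#' @param trace a [ca_trace].
#' @param w_bond,w_rep,w_rg term weights.
#' @param rg_ref reference radius of gyration; default `2.2 * n^0.38`.
#' @return Finite numeric energy (arbitrary units).
#' @export
surrogate_energy <- function(trace, w_bond = 1, w_rep = 1, w_rg = 0.1,
                             rg_ref = NULL) {
  stopifnot(is_ca_trace(trace))
  x <- trace$coords
  n <- trace$residue_count
  if (is.null(rg_ref)) rg_ref <- 2.2 * n^0.38
  d_seq <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  e_bond <- sum((d_seq - 3.8)^2)
  dm <- as.matrix(stats::dist(x))
  sep <- abs(row(dm) - col(dm))
  close <- sep >= 3 & dm < 4
  e_rep <- sum((4 - dm[close])^2) / 2      # each pair counted once
  rg <- sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  e_rg <- (rg - rg_ref)^2
  w_bond * e_bond + w_rep * e_rep + w_rg * e_rg
}

#' Go-type energy toward a reference structure
#'
#' A test potential whose global minimum is planted at a known structure:
#' `E = k * rmsd(trace, reference)^2` with the RMSD taken after optimal
#' superposition, so the energy is zero iff the trace is rigid-transform
#' equivalent to the reference and strictly positive otherwise. Used to make
#' parameter-recovery experiments verifiable.
#'
#' @param trace a [ca_trace].
#' @param reference the planted minimum, same residue count.
#' @param k spring constant (energy units per Angstrom^2).
#' @return Non-negative energy.
#' @export
go_energy <- function(trace, reference, k = 1) {
  k * rmsd(trace, reference, superpose_first = TRUE)^2
}

#' Construct an energy model
#'
#' Energy evaluation is pluggable: the concrete statistical potentials used
#' on real decoy sets (e.g. dDFIRE with GB/SA solvation) are external
#' programs, so the pipeline only assumes a deterministic function from a
#' trace to a real number, lower meaning better. Built-in models:
#'
#' * `"surrogate"` — [surrogate_energy()]; parameters `w_bond`, `w_rep`,
#'   `w_rg`, `rg_ref`.
#' * `"go"` — [go_energy()]; parameters `reference` (a [ca_trace], required)
#'   and `k`.
#' * `"table"` — fixed per-template energies looked up by trace label;
#'   parameter `energies`, a named numeric vector (e.g. from
#'   [read_energy_table()]). Supports externally computed scores.
#'
#' @param name one of `"surrogate"`, `"go"`, `"table"`.
#' @param ... model parameters, see above.
#' @return An `energy_model` object; call it on a trace via
#'   [evaluate_energy()].
#' @export
energy_model <- function(name = c("surrogate", "go", "table"), ...) {
  name <- match.arg(name)
  params <- list(...)
  fun <- switch(name,
    surrogate = function(trace)
      do.call(surrogate_energy, c(list(trace), params)),
    go = {
      if (is.null(params$reference))
        stop("go energy model requires a `reference` trace", call. = FALSE)
      function(trace)
        go_energy(trace, params$reference,
                  k = if (is.null(params$k)) 1 else params$k)
    },
    table = {
      if (is.null(params$energies) || is.null(names(params$energies)))
        stop("table energy model requires a named `energies` vector",
             call. = FALSE)
      function(trace) {
        e <- unname(params$energies[match(trace$label, names(params$energies))])
        if (length(e) != 1L || is.na(e))
          stop(sprintf("no tabulated energy for template '%s'", trace$label),
               call. = FALSE)
        e
      }
    })
  structure(list(name = name, parameters = params, fun = fun),
            class = "energy_model")
}

#' Evaluate an energy model on a trace
#' @param model an [energy_model()].
#' @param trace a [ca_trace].
#' @return Numeric energy.
#' @export
evaluate_energy <- function(model, trace) {
  stopifnot(inherits(model, "energy_model"))
  model$fun(trace)
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("energy_model '%s'\n", x$name))
  invisible(x)
}

#' Read a two-column template energy table
#'
#' Whitespace- or tab-separated text with one row per template:
#' `label energy`. Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return Named numeric vector of energies.
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("label", "energy"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$energy, tab$label)
}

#' Select templates by energy percentile
#'
#' Keeps every template whose energy does not exceed the given percentile of
#' the energy distribution (linear interpolation between closest ranks; ties
#' at the cutoff are kept). With the default 30th percentile roughly the
#' best-scoring 30\% of templates survive, which keeps the low-energy
#' neighbourhood of the native while preserving conformational variability.
#'
#' @param energies numeric vector of template energies (lower is better),
#'   length at least 2.
#' @param percentile cutoff percentile in (0, 100); default 30.
#' @return A `selection_result`: list with `kept_indices`, `cutoff_energy`
#'   and `percentile`.
#' @export
select_templates <- function(energies, percentile = 30) {
  if (length(energies) == 0L)
    stop("empty ensemble: no energies to select from", call. = FALSE)
  if (length(energies) < 2L)
    stop("need at least 2 template energies", call. = FALSE)
  if (!is.finite(percentile) || percentile <= 0 || percentile >= 100)
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  cutoff <- unname(stats::quantile(energies, percentile / 100, type = 7))
  kept <- which(energies <= cutoff)
  structure(
    list(kept_indices = kept, cutoff_energy = cutoff, percentile = percentile),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection: %d templates kept at the %.1fth percentile (cutoff %.4g)\n",
              length(x$kept_indices), x$percentile, x$cutoff_energy))
  invisible(x)
}
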