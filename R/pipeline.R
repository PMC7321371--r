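#' Configuration of an end-to-end prediction run
#'
#' Bundles every tunable of the pipeline. The defaults are the standard
#' operating point: 30th-percentile energy cutoff, four energy classes, four
#' discriminant dimensions (plus the high-frequency term, five reduced basis
#' terms in total), a 10\% bound margin, and a 40-particle, 50-iteration
#' swarm for both sampling and refinement. `seed` drives every random draw
#' of the run: the sampling swarm uses `seed` and the refinement swarm
#' `seed + 1`.
#'
#' With `k` classes the between-class scatter has rank at most `k - 1`, so
#' the default `lda_dim = n_classes = 4` includes one direction that exists
#' only through the shrinkage regularization; a warning notes this.
#'
#' @param template_dir directory of template PDB files (ignored when
#'   `templates` is given).
#' @param templates optional list of [ca_trace] templates (in-memory input).
#' @param native_path optional path to the native structure for evaluation.
#' @param native optional [ca_trace] native structure.
#' @param energy an [energy_model()]; default the surrogate potential.
#' @param percentile energy-percentile cutoff for template selection.
#' @param n_classes number of k-means energy classes (2..10).
#' @param lda_dim number of discriminant directions (must not exceed
#'   `n_classes`).
#' @param margin search-bound expansion fraction per side.
#' @param energy_tolerance optional energy threshold: sampled models at or
#'   below it are flagged as members of the low-energy equivalence region in
#'   the report (it never gates the pipeline).
#' @param swarm a [swarm_config] for the reduced-space sampling.
#' @param refine a [refine_config] for the SVD refinement stage.
#' @param seed integer master seed.
#' @param output_dir optional directory for run artifacts (predicted PDB,
#'   JSON report, optimizer trace, config echo).
#' @return A `run_config` list.
#' @export
run_config <- function(template_dir = NULL, templates = NULL,
                       native_path = NULL, native = NULL,
                       energy = energy_model("surrogate"),
                       percentile = 30, n_classes = 4, lda_dim = 4,
                       margin = 0.1, energy_tolerance = NULL,
                       swarm = swarm_config(), refine = refine_config(),
                       seed = 1, output_dir = NULL) {
  if (is.null(template_dir) && is.null(templates))
    stop("either `template_dir` or `templates` must be supplied",
         call. = FALSE)
  if (n_classes > 10)
    stop("class-limit error: `n_classes` must be at most 10", call. = FALSE)
  if (n_classes < 2) stop("`n_classes` must be at least 2", call. = FALSE)
  if (lda_dim > n_classes)
    stop("`lda_dim` must not exceed `n_classes`", call. = FALSE)
  if (lda_dim > n_classes - 1)
    warning(sprintf(
      paste("lda_dim = %d with %d classes: the between-class scatter has rank",
            "at most %d, so the last direction is regularization-dominated"),
      lda_dim, n_classes, n_classes - 1), call. = FALSE)
  swarm$seed <- as.integer(seed)
  refine$swarm$seed <- as.integer(seed) + 1L
  structure(
    list(template_dir = template_dir, templates = templates,
         native_path = native_path, native = native,
         energy = energy, percentile = percentile,
         n_classes = as.integer(n_classes), lda_dim = as.integer(lda_dim),
         margin = margin, energy_tolerance = energy_tolerance,
         swarm = swarm, refine = refine, seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

stage_log <- function(stage, t0, fmt, ...) {
  message(sprintf("[%s] (%.2fs) %s", stage,
                  as.numeric(Sys.time()) - t0, sprintf(fmt, ...)))
}

#' Run the full template-based prediction pipeline
#'
#' Executes the stages in order: template loading, energy evaluation and
#' percentile selection, superposition of the selected templates onto the
#' best (lowest-energy) decoy, k-means energy partitioning, regularized
#' discriminant basis with high-frequency term, projection-derived search
#' bounds, bounded swarm sampling of the reduced coordinates, and SVD
#' refinement. If the swarm's best reconstructed model is worse than the
#' best decoy, the pipeline falls back to the best decoy before refinement,
#' and refinement is accept-if-better, so the final energy never exceeds the
#' best selected template's energy. The run is fully reproducible from its
#' inputs and seed.
#'
#' @param config a [run_config].
#' @return A `prediction_result`: list with `predicted` ([ca_trace]),
#'   `predicted_energy`, `best_template_energy`, `best_template_label`,
#'   `rmsd_to_native` (or NULL), `evaluation` (per-residue profile or NULL),
#'   `selection`, `partition`, `basis`, `search_space`, `optimization`
#'   (`pso_result`), `refine_report`, `n_tolerance_models` (sampled models
#'   within `energy_tolerance`, or NULL) and `config`.
#' @export
run_prediction <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())

  # --- load templates ------------------------------------------------------
  traces <- config$templates
  if (is.null(traces)) {
    paths <- sort(list.files(config$template_dir, pattern = "\\.pdb$",
                             full.names = TRUE))
    paths <- paths[basename(paths) != "reference.pdb"]
    if (length(paths) == 0L)
      stop(sprintf("pipeline stage 'load': no PDB templates in '%s'",
                   config$template_dir), call. = FALSE)
    traces <- lapply(paths, read_ca_trace)
  }
  if (length(traces) < 5L)
    stop("pipeline stage 'load': need at least 5 templates", call. = FALSE)
  rc <- vapply(traces, function(t) t$residue_count, integer(1))
  if (length(unique(rc)) != 1L)
    stop("pipeline stage 'load': templates differ in residue count",
         call. = FALSE)
  stage_log("load", t0, "%d templates, %d residues", length(traces), rc[1])

  # --- energies + selection ------------------------------------------------
  energies <- vapply(traces, function(t) evaluate_energy(config$energy, t),
                     numeric(1))
  selection <- select_templates(energies, config$percentile)
  kept <- selection$kept_indices
  if (length(kept) < config$n_classes)
    stop(sprintf(
      "pipeline stage 'select': only %d templates pass the %.4g cutoff but %d classes requested",
      length(kept), selection$cutoff_energy, config$n_classes), call. = FALSE)
  stage_log("select", t0, "%d/%d templates kept (cutoff %.4g)",
            length(kept), length(traces), selection$cutoff_energy)

  # --- superpose to the best decoy ----------------------------------------
  sel_energies <- energies[kept]
  best_local <- which(sel_energies == min(sel_energies))[1]  # label-order tie-break
  best_trace <- traces[[kept[best_local]]]
  aligned <- lapply(kept, function(i) superpose(traces[[i]], best_trace)$trace)
  ens <- template_ensemble(aligned, sel_energies)
  stage_log("superpose", t0, "superposed to best decoy '%s' (E = %.4g)",
            best_trace$label, min(sel_energies))

  # --- partition + reduced basis ------------------------------------------
  partition <- kmeans_energy_partition(ens$energies, k = config$n_classes)
  scatter <- compute_scatter(ens, partition)
  sb_reg <- shrink_scatter(scatter$SB, scatter$sb_samples, scatter$sb_weights)
  sw_reg <- shrink_scatter(scatter$SW, scatter$sw_samples)
  Vd <- lda_basis(sb_reg, sw_reg, d = config$lda_dim)
  m_best <- ens$X[, best_local]
  basis <- append_hf_term(Vd, scatter$mu, m_best)
  stage_log("reduce", t0,
            "classes %s; lambda_B = %.3g, lambda_W = %.3g; %d basis terms",
            paste(partition$class_sizes, collapse = "/"),
            sb_reg$lambda_d, sw_reg$lambda_d, ncol(basis$V))

  # --- bounds + swarm sampling --------------------------------------------
  space <- search_bounds(basis, ens, margin = config$margin)
  objective <- function(a)
    evaluate_energy(config$energy, unflatten(reconstruct(basis, a)))
  opt <- pso_optimize(objective, space, config$swarm)
  stage_log("sample", t0, "swarm best %.6g%s", opt$best_value,
            if (is.na(opt$collapsed_at)) ""
            else sprintf(", collapsed at iteration %d", opt$collapsed_at))

  best_template_energy <- min(sel_energies)
  if (is.finite(opt$best_value) && opt$best_value < best_template_energy) {
    sampled <- unflatten(reconstruct(basis, opt$best_position),
                         label = "sampled-model")
    sampled_energy <- opt$best_value
  } else {
    sampled <- best_trace
    sampled_energy <- best_template_energy
    stage_log("sample", t0, "falling back to best decoy")
  }

  # --- SVD refinement ------------------------------------------------------
  refined <- refine_svd(sampled, config$energy, config$refine)
  predicted <- refined$trace
  predicted$label <- "predicted"
  predicted_energy <- min(refined$report$refined_energy, sampled_energy)
  stage_log("refine", t0, "energy %.6g -> %.6g (%s)",
            refined$report$input_energy, refined$report$refined_energy,
            if (refined$report$accepted) "accepted" else "kept input")

  # --- evaluation ----------------------------------------------------------
  native <- config$native
  if (is.null(native) && !is.null(config$native_path))
    native <- read_ca_trace(config$native_path)
  evaluation <- NULL
  rmsd_native <- NULL
  if (!is.null(native)) {
    evaluation <- evaluate_vs_native(predicted, native)
    rmsd_native <- evaluation$rmsd
    stage_log("evaluate", t0, "rmsd to native %.4f A", rmsd_native)
  }

  n_tol <- NULL
  if (!is.null(config$energy_tolerance))
    n_tol <- sum(opt$sampled_values <= config$energy_tolerance)

  result <- structure(
    list(predicted = predicted,
         predicted_energy = predicted_energy,
         best_template_energy = best_template_energy,
         best_template_label = best_trace$label,
         rmsd_to_native = rmsd_native,
         evaluation = evaluation,
         selection = selection, partition = partition,
         basis = basis, search_space = space,
         optimization = opt, refine_report = refined$report,
         n_tolerance_models = n_tol,
         config = config),
    class = "prediction_result"
  )
  if (!is.null(config$output_dir)) write_prediction(result, config$output_dir)
  result
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: E = %.6g (best template %.6g)%s\n",
              x$predicted_energy, x$best_template_energy,
              if (is.null(x$rmsd_to_native)) ""
              else sprintf(", rmsd to native %.3f A", x$rmsd_to_native)))
  invisible(x)
}

#' Compare a predicted structure with the native
#'
#' @param predicted,native [ca_trace] objects with equal residue counts.
#' @return List with `rmsd` (superposed C-alpha RMSD, Angstrom) and
#'   `per_residue` (per-residue deviations after superposition).
#' @export
evaluate_vs_native <- function(predicted, native) {
  stopifnot(is_ca_trace(predicted), is_ca_trace(native))
  stopifnot_same_length(predicted, native)
  sup <- superpose(predicted, native)
  dev <- sqrt(rowSums((sup$trace$coords - native$coords)^2))
  list(rmsd = sup$result$rmsd, per_residue = dev)
}

#' Write the artifacts of a prediction run
#'
#' Emits `predicted.pdb`, `report.json`, `trace.tsv` (optimizer history) and
#' `config.json` (provenance echo) into `dir`.
#'
#' @param result a `prediction_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_prediction <- function(result, dir) {
  stopifnot(inherits(result, "prediction_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ca_trace(result$predicted, file.path(dir, "predicted.pdb"))
  write_pso_trace(result$optimization, file.path(dir, "trace.tsv"))
  cfg <- result$config
  report <- list(
    energy_model = cfg$energy$name,
    predicted_energy = result$predicted_energy,
    best_template_energy = result$best_template_energy,
    best_template_label = result$best_template_label,
    rmsd_to_native = result$rmsd_to_native,
    n_templates_kept = length(result$selection$kept_indices),
    cutoff_energy = result$selection$cutoff_energy,
    class_sizes = result$partition$class_sizes,
    basis_terms = ncol(result$basis$V),
    collapsed_at = result$optimization$collapsed_at,
    n_sampled_models = length(result$optimization$sampled_values),
    n_tolerance_models = result$n_tolerance_models,
    refine_accepted = result$refine_report$accepted,
    seed = cfg$seed
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  echo <- list(percentile = cfg$percentile, n_classes = cfg$n_classes,
               lda_dim = cfg$lda_dim, margin = cfg$margin,
               energy_tolerance = cfg$energy_tolerance,
               energy_model = cfg$energy$name,
               swarm = cfg$swarm[c("swarm_size", "iterations", "seed",
                                   "collapse_threshold", "variant")],
               refine_delta = cfg$refine$delta, seed = cfg$seed)
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
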