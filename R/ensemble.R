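#' Build a template ensemble matrix
#'
#' Arranges flattened templates column-wise into the ensemble matrix
#' `X` (3*residue_count rows, one column per template), together with their
#' labels and energies. The pipeline superposes templates to a common
#' reference before building the ensemble so that coordinate differences
#' between columns reflect conformation, not rigid placement.
#'
#' @param traces list of [ca_trace] objects with equal residue counts.
#' @param energies numeric vector, one energy per template (lower is better).
#' @param labels optional character vector of template labels; defaults to
#'   the trace labels.
#' @return A `template_ensemble`: list with `X` (n x l matrix), `labels`,
#'   `energies`, `residue_count` and `n_templates`.
#' @export
template_ensemble <- function(traces, energies, labels = NULL) {
  if (length(traces) < 2L)
    stop("a template ensemble needs at least 2 templates", call. = FALSE)
  stopifnot(all(vapply(traces, is_ca_trace, logical(1))))
  rc <- unique(vapply(traces, function(t) t$residue_count, integer(1)))
  if (length(rc) != 1L)
    stop("all templates must share the same residue count; found: ",
         paste(rc, collapse = ", "), call. = FALSE)
  if (length(energies) != length(traces))
    stop("`energies` must have one value per template", call. = FALSE)
  if (!all(is.finite(energies)))
    stop("all template energies must be finite", call. = FALSE)
  if (is.null(labels))
    labels <- vapply(traces, function(t) t$label, character(1))
  X <- vapply(traces, flatten, numeric(3L * rc))
  structure(
    list(X = X, labels = labels, energies = as.numeric(energies),
         residue_count = rc, n_templates = length(traces)),
    class = "template_ensemble"
  )
}

#' @export
print.template_ensemble <- function(x, ...) {
  cat(sprintf("template_ensemble: %d templates x %d residues (energy range [%.4g, %.4g])\n",
              x$n_templates, x$residue_count,
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Extract one ensemble column as a trace
#' @param ensemble a [template_ensemble].
#' @param i column index.
#' @return A [ca_trace].
#' @export
ensemble_trace <- function(ensemble, i) {
  unflatten(ensemble$X[, i], label = ensemble$labels[i])
}

#' Partition templates by one-dimensional k-means on energy
#'
#' Exact k-means clustering of the energy values. In one dimension the
#' optimal k-means clusters are contiguous intervals of the sorted values,
#' so the globally optimal partition is found by dynamic programming over
#' segment boundaries (O(k l^2) with prefix sums) — deterministic, with no
#' dependence on initialization, and always attaining the minimum
#' within-class sum of squares that iterative (Lloyd-type) k-means can only
#' approach. `seed` is accepted for call-site uniformity but does not
#' influence the outcome. Classes are labelled in increasing-centroid
#' (energy) order, so class 1 is always the lowest-energy class. The class
#' count is capped at 10: with an isotropic box search space the probability
#' of sampling inside the inscribed sphere collapses beyond ~10 dimensions,
#' so more classes would not give a usable reduced basis.
#'
#' @param energies numeric vector of template energies (length l >= k).
#' @param k number of classes, between 2 and 10 (default 4).
#' @param seed ignored; the algorithm is deterministic.
#' @return A `class_partition`: list with `k`, integer `labels` (length l,
#'   values 1..k), `class_sizes` and `centroids` (increasing).
#' @export
kmeans_energy_partition <- function(energies, k = 4, seed = NULL) {
  l <- length(energies)
  if (k > 10)
    stop("class-limit error: classification is limited to at most 10 classes",
         call. = FALSE)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (l < k)
    stop(sprintf("insufficient templates: %d templates for %d classes", l, k),
         call. = FALSE)
  e <- as.numeric(energies)
  ord <- order(e)
  x <- e[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg <- function(i, j) {   # within-ss of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s^2 / (j - i + 1), 0)
  }
  # D[m, j]: optimal cost of the first j sorted points in m clusters
  D <- matrix(Inf, k, l)
  B <- matrix(1L, k, l)     # B[m, j]: first index of the last cluster
  for (j in 1:l) D[1, j] <- seg(1, j)
  for (m in 2:k) {
    for (j in m:l) {
      costs <- vapply(m:j, function(i) D[m - 1, i - 1] + seg(i, j), numeric(1))
      best <- which.min(costs)
      D[m, j] <- costs[best]
      B[m, j] <- (m:j)[best]
    }
  }
  sorted_labels <- integer(l)
  j <- l
  for (m in k:1) {
    i <- if (m == 1) 1L else B[m, j]
    sorted_labels[i:j] <- m
    j <- i - 1L
  }
  labels <- integer(l)
  labels[ord] <- sorted_labels
  centers <- vapply(seq_len(k), function(c) mean(e[labels == c]), numeric(1))
  structure(
    list(k = as.integer(k), labels = labels,
         class_sizes = tabulate(labels, nbins = k), centroids = centers),
    class = "class_partition"
  )
}

#' @export
print.class_partition <- function(x, ...) {
  cat(sprintf("class_partition: k = %d, sizes = %s\n",
              x$k, paste(x$class_sizes, collapse = "/")))
  invisible(x)
}
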