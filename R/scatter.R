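#' Between- and within-class scatter matrices of a template ensemble
#'
#' With class means \eqn{\mu_k} and grand mean \eqn{\mu} over the flattened
#' coordinates,
#' \deqn{S_B = \sum_k n_k (\mu_k - \mu)(\mu_k - \mu)^T, \qquad
#'       S_W = \sum_k \sum_{m_i \in C_k} (m_i - \mu_k)(m_i - \mu_k)^T.}
#' The two sum to the total scatter \eqn{\sum_i (m_i - \mu)(m_i - \mu)^T}.
#' With far fewer templates than coordinates \eqn{S_W} is always singular,
#' which is why the discriminant directions are computed from the shrunk
#' matrices (see [shrink_scatter()]).
#'
#' @param ensemble a [template_ensemble].
#' @param partition a [kmeans_energy_partition()] result covering all columns.
#' @return A `scatter_pair`: list with `SB`, `SW` (n x n symmetric), `mu`
#'   (grand mean), `class_means` (n x k matrix), `class_sizes`, and the
#'   weighted centered samples needed by [shrink_scatter()]
#'   (`sb_samples`/`sb_weights`, `sw_samples`).
#' @export
compute_scatter <- function(ensemble, partition) {
  stopifnot(inherits(ensemble, "template_ensemble"),
            inherits(partition, "class_partition"))
  X <- ensemble$X
  l <- ncol(X)
  if (length(partition$labels) != l)
    stop("partition error: partition does not cover all ensemble columns",
         call. = FALSE)
  if (any(partition$class_sizes == 0L))
    stop("partition error: empty class", call. = FALSE)
  k <- partition$k
  mu <- rowMeans(X)
  class_means <- vapply(seq_len(k),
                        function(j) rowMeans(X[, partition$labels == j, drop = FALSE]),
                        numeric(nrow(X)))
  nk <- partition$class_sizes
  Mc <- class_means - mu                       # n x k, centered class means
  SB <- tcrossprod(sweep(Mc, 2, sqrt(nk), "*"))
  Wc <- X - class_means[, partition$labels]    # each column centered on its class mean
  SW <- tcrossprod(Wc)
  structure(
    list(SB = (SB + t(SB)) / 2, SW = (SW + t(SW)) / 2,
         mu = mu, class_means = class_means, class_sizes = nk,
         sb_samples = Mc, sb_weights = nk, sw_samples = Wc),
    class = "scatter_pair"
  )
}

#' L2 shrinkage regularization of a scatter matrix
#'
#' Replaces a (typically singular) scatter matrix by the convex combination
#' \deqn{S^{reg} = (1 - \lambda) S + \lambda\, s\, I_n}
#' with target scale \eqn{s = \mathrm{tr}(S)/p} and data-driven intensity
#' \deqn{\lambda = \frac{2\sum_{i>j} \widehat{var}(S_{ij})}
#'                     {2\sum_{i>j} S_{ij}^2 + \sum_i (S_{ii}-1)^2},}
#' clamped to \[0, 1\] (a zero denominator is defined as \eqn{\lambda = 0}).
#' \eqn{\widehat{var}(S_{ij})} is the maximum-likelihood (divide-by-N)
#' variance of the estimator of \eqn{S_{ij}} built from the per-sample
#' weighted cross-products \eqn{q_t = w_t\, c_{ti} c_{tj}} whose sum is
#' \eqn{S_{ij}}: \eqn{\widehat{var}(S_{ij}) = \sum_t (q_t - S_{ij}/N)^2}.
#' Any \eqn{\lambda > 0} makes the result strictly positive definite when
#' \eqn{s > 0}.
#'
#' @param S symmetric scatter matrix (a weighted sum of outer products of the
#'   centered samples).
#' @param centered_samples p x N matrix whose weighted outer products sum to
#'   `S` (e.g. `sw_samples` or `sb_samples` from [compute_scatter()]).
#' @param weights per-sample weights (recycled); class sizes for the
#'   between-class matrix, 1 for the within-class matrix.
#' @return A `shrinkage_result`: list with `S_reg`, `lambda_d`, `s_d`.
#' @export
shrink_scatter <- function(S, centered_samples, weights = 1) {
  S <- as.matrix(S)
  p <- nrow(S)
  C <- as.matrix(centered_samples)
  N <- ncol(C)
  w <- rep_len(weights, N)
  s_d <- sum(diag(S)) / p
  # var(S_ij) = sum_t q_t^2 - S_ij^2 / N, vectorized over all (i, j)
  V2 <- C^2
  M2 <- V2 %*% (t(V2) * w^2)
  varS <- M2 - S^2 / N
  off <- !diag(TRUE, p)
  num <- sum(varS[off])
  den <- sum(S[off]^2) + sum((diag(S) - 1)^2)
  lambda <- if (den <= 0) 0 else min(max(num / den, 0), 1)
  S_reg <- (1 - lambda) * S + lambda * s_d * diag(p)
  structure(list(S_reg = S_reg, lambda_d = lambda, s_d = s_d),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("shrinkage: lambda = %.4g, target scale s = %.4g\n",
              x$lambda_d, x$s_d))
  invisible(x)
}
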