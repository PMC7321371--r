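#' Discriminant directions from regularized scatter matrices
#'
#' Solves the generalized eigenproblem \eqn{S_B w = \gamma S_W w} for the
#' top-`d` directions, i.e. the leading eigenvectors of
#' \eqn{S_W^{-1} S_B}. For numerical safety it is solved as a symmetric
#' problem through the Cholesky factor of the regularized within-class
#' matrix rather than by forming the inverse. Columns are scaled to unit
#' norm with the sign fixed so the largest-magnitude entry of each column is
#' positive (deterministic across platforms).
#'
#' Because \eqn{rank(S_B) \le k - 1} for `k` classes, at most `k - 1`
#' eigenvalues carry class-separation signal; with the default `d = 4` and
#' `k = 4` classes the 4th direction exists only through the shrinkage
#' regularization and is dominated by it.
#'
#' @param SB_reg,SW_reg [shrink_scatter()] results (or plain matrices) for
#'   the between- and within-class scatter.
#' @param d number of directions to return (1 <= d <= n); default 4.
#' @return n x d matrix of unit-norm discriminant directions, ordered by
#'   decreasing generalized eigenvalue. The eigenvalues are attached as
#'   attribute `"eigenvalues"`.
#' @export
lda_basis <- function(SB_reg, SW_reg, d = 4) {
  SB <- if (inherits(SB_reg, "shrinkage_result")) SB_reg$S_reg else as.matrix(SB_reg)
  SW <- if (inherits(SW_reg, "shrinkage_result")) SW_reg$S_reg else as.matrix(SW_reg)
  n <- nrow(SW)
  if (d < 1 || d > n) stop("`d` must be between 1 and n", call. = FALSE)
  R <- tryCatch(chol(SW), error = function(e)
    stop("regularization required: within-class scatter is not positive definite",
         call. = FALSE))
  # whiten: M = R^-T SB R^-1, symmetric with the same spectrum as SW^-1 SB
  A <- backsolve(R, SB, transpose = TRUE)       # R^-T SB
  M <- t(backsolve(R, t(A), transpose = TRUE))  # (R^-T A^T)^T = A R^-1
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  W <- backsolve(R, ev$vectors[, seq_len(d), drop = FALSE])
  W <- apply(W, 2, function(w) {
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) -w else w
  })
  W <- matrix(W, nrow = n)
  attr(W, "eigenvalues") <- ev$values[seq_len(d)]
  W
}

#' Append the high-frequency residual term to the discriminant basis
#'
#' The discriminant directions describe concerted, low-frequency differences
#' between template classes; reconstruction in that space alone loses the
#' fine-scale detail of any single structure. The basis is therefore
#' completed with the residual of the lowest-energy template after its
#' least-squares projection onto the `d` discriminant directions:
#' \deqn{v_{d+1} = m_{BEST} - (\mu + V_d a)}
#' The `d + 1` columns are then orthonormalized (QR, preserving span and
#' column order; pre-normalization scales are kept in `column_norms`), so
#' that [project()] and [reconstruct()] form an exact least-squares pair and
#' the best template is reproduced exactly by the basis.
#'
#' If the residual norm is below `1e-10` (the best template already lies in
#' the span), the HF column is a zero sentinel, `hf_zero` is `TRUE`, and the
#' effective dimension is `d`.
#'
#' @param Vd n x d matrix of discriminant directions ([lda_basis()]).
#' @param mu grand mean vector (length n).
#' @param m_best flattened coordinates of the lowest-energy selected template.
#' @return A `reduced_basis`: list with `mu`, `V` (n x (d+1), orthonormal
#'   columns except a possible zero HF column), `d`, `column_norms`
#'   (pre-normalization scales, length d+1) and `hf_zero`.
#' @export
append_hf_term <- function(Vd, mu, m_best) {
  Vd <- as.matrix(Vd)
  n <- nrow(Vd)
  d <- ncol(Vd)
  stopifnot(length(mu) == n, length(m_best) == n)
  r <- m_best - mu
  a <- qr.coef(qr(Vd), r)
  a[is.na(a)] <- 0
  resid <- r - Vd %*% a
  resid_norm <- sqrt(sum(resid^2))
  hf_zero <- resid_norm < 1e-10
  if (hf_zero) {
    qr_d <- qr(Vd)
    Q <- qr.Q(qr_d)
    sgn <- sign(diag(qr.R(qr_d)))
    sgn[sgn == 0] <- 1
    Q <- sweep(Q, 2, sgn, "*")
    V <- cbind(Q, 0)
    column_norms <- c(abs(diag(qr.R(qr_d))), 0)
  } else {
    Vfull <- cbind(Vd, as.vector(resid))
    qr_f <- qr(Vfull)
    Q <- qr.Q(qr_f)
    Rdiag <- diag(qr.R(qr_f))
    sgn <- sign(Rdiag)
    sgn[sgn == 0] <- 1
    V <- sweep(Q, 2, sgn, "*")
    column_norms <- abs(Rdiag)
  }
  structure(
    list(mu = as.numeric(mu), V = V, d = d,
         column_norms = column_norms, hf_zero = hf_zero),
    class = "reduced_basis"
  )
}

#' @export
print.reduced_basis <- function(x, ...) {
  cat(sprintf("reduced_basis: %d discriminant direction(s) + HF term%s (n = %d)\n",
              x$d, if (x$hf_zero) " [zero]" else "", length(x$mu)))
  invisible(x)
}

#' Project a structure onto the reduced basis
#'
#' With orthonormal columns the projection `a = V^T (m - mu)` is the
#' least-squares coefficient vector of `m - mu` on the basis.
#'
#' @param basis a [reduced_basis].
#' @param m flattened structure vector (length n).
#' @return Numeric coefficient vector of length `d + 1`.
#' @export
project <- function(basis, m) {
  stopifnot(inherits(basis, "reduced_basis"))
  as.vector(crossprod(basis$V, m - basis$mu))
}

#' Reconstruct a structure from reduced coordinates
#'
#' Returns the flattened model `m = mu + V a`. Use [unflatten()] to obtain a
#' [ca_trace].
#'
#' @param basis a [reduced_basis].
#' @param a reduced coordinate vector (length d + 1).
#' @return Flattened structure vector of length n.
#' @export
reconstruct <- function(basis, a) {
  stopifnot(inherits(basis, "reduced_basis"))
  if (!all(is.finite(a))) stop("reduced coordinates must be finite", call. = FALSE)
  as.vector(basis$mu + basis$V %*% a)
}

#' Prismatic search bounds from template projections
#'
#' The admissible region for the swarm is the axis-aligned box
#' \eqn{l_j \le a_j \le u_j} spanned by the per-coordinate minimum and
#' maximum of the projections of the selected templates, expanded by
#' `margin` times the range on each side (the box is indicative and may be
#' expanded further). A zero-range coordinate is widened to
#' `center +/- margin * max(1, |center|)`.
#'
#' @param basis a [reduced_basis].
#' @param ensemble a [template_ensemble] of the selected templates.
#' @param margin non-negative expansion fraction per side; default 0.1.
#' @return A `search_space`: list with `lower`, `upper` (length d + 1) and
#'   `margin`.
#' @export
search_bounds <- function(basis, ensemble, margin = 0.1) {
  stopifnot(inherits(basis, "reduced_basis"),
            inherits(ensemble, "template_ensemble"))
  if (margin < 0) stop("`margin` must be non-negative", call. = FALSE)
  A <- crossprod(basis$V, ensemble$X - basis$mu)   # (d+1) x l projections
  lo <- apply(A, 1, min)
  hi <- apply(A, 1, max)
  rng <- hi - lo
  zero <- rng < .Machine$double.eps^0.5
  lower <- ifelse(zero, lo - margin * pmax(1, abs(lo)), lo - margin * rng)
  upper <- ifelse(zero, hi + margin * pmax(1, abs(hi)), hi + margin * rng)
  search_space(lower, upper, margin = margin)
}

#' Construct a prismatic search space
#' @param lower,upper numeric bound vectors with `lower <= upper`
#'   component-wise.
#' @param margin the expansion fraction used to build the box (metadata).
#' @return A `search_space` object.
#' @export
search_space <- function(lower, upper, margin = 0) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("`lower` and `upper` must have the same length", call. = FALSE)
  if (any(lower > upper))
    stop("every lower bound must not exceed its upper bound", call. = FALSE)
  structure(list(lower = lower, upper = upper, margin = margin),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("search_space: %d coordinate(s)\n", length(x$lower)))
  for (j in seq_along(x$lower))
    cat(sprintf("  a%d in [%.4g, %.4g]\n", j, x$lower[j], x$upper[j]))
  invisible(x)
}

#' Serialize a reduced basis to JSON
#' @param basis a [reduced_basis].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_reduced_basis <- function(basis, path) {
  stopifnot(inherits(basis, "reduced_basis"))
  obj <- list(mu = basis$mu, V = basis$V, d = basis$d,
              column_norms = basis$column_norms, hf_zero = basis$hf_zero)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a reduced basis from JSON
#' @param path file written by [write_reduced_basis()].
#' @return A [reduced_basis].
#' @export
read_reduced_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mu = as.numeric(obj$mu), V = as.matrix(obj$V), d = as.integer(obj$d),
         column_norms = as.numeric(obj$column_norms),
         hf_zero = isTRUE(obj$hf_zero)),
    class = "reduced_basis"
  )
}
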