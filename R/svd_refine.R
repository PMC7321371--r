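#' Rank-3 SVD basis of a structure's coordinate matrix
#'
#' Formats the structure as the 3 x natoms matrix whose columns are the
#' centered atom coordinates (the centroid is removed and stored, making the
#' factorization translation invariant) and takes its thin SVD
#' \deqn{m = U \Sigma V^T = \sum_{k=1}^{3} \alpha_k u_k v_k^T.}
#' A C-alpha structure has exactly 3 singular values; planar or collinear
#' point sets simply yield zero trailing values. The sign of each left
#' singular vector is fixed so its largest-magnitude entry is positive.
#'
#' @param trace a [ca_trace].
#' @return An `svd_basis`: list with `U` (3 x 3 orthogonal), `alphas`
#'   (3 singular values, descending), `V` (natoms x 3, orthonormal columns),
#'   `centroid` (length 3) and `natoms`.
#' @export
svd_basis <- function(trace) {
  stopifnot(is_ca_trace(trace))
  M <- t(trace$coords)                     # 3 x natoms
  centroid <- rowMeans(M)
  Mc <- M - centroid
  sv <- svd(Mc, nu = 3, nv = 3)
  U <- sv$u
  V <- sv$v
  for (k in 1:3) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  structure(
    list(U = U, alphas = sv$d[1:3], V = V, centroid = centroid,
         natoms = trace$residue_count),
    class = "svd_basis"
  )
}

#' @export
print.svd_basis <- function(x, ...) {
  cat(sprintf("svd_basis: %d atoms, singular values %s\n", x$natoms,
              paste(sprintf("%.4g", x$alphas), collapse = ", ")))
  invisible(x)
}

#' Rebuild a structure from its three SVD coordinates
#'
#' Computes \eqn{\sum_k \beta_k u_k v_k^T}, restores the centroid, and
#' returns the structure; `betas = alphas` reproduces the input exactly.
#'
#' @param basis an [svd_basis].
#' @param betas numeric vector of 3 reduced coordinates.
#' @param centroid translation to restore; defaults to the basis centroid.
#' @return A [ca_trace].
#' @export
reconstruct_svd <- function(basis, betas, centroid = basis$centroid) {
  stopifnot(inherits(basis, "svd_basis"), length(betas) == 3,
            all(is.finite(betas)))
  M <- basis$U %*% (t(basis$V) * betas) + centroid
  ca_trace(t(M), label = "svd-reconstruction")
}

#' Refinement configuration
#' @param delta relative half-width of the beta search box around the
#'   singular values, in (0, 1); default 0.2.
#' @param swarm a [swarm_config] for the refinement optimizer.
#' @return A `refine_config` list.
#' @export
refine_config <- function(delta = 0.2, swarm = swarm_config()) {
  if (delta <= 0 || delta >= 1)
    stop("`delta` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(delta = delta, swarm = swarm), class = "refine_config")
}

#' Refine a structure over its three SVD coordinates
#'
#' Optimizes the three coordinates \eqn{\beta_k} of the structure's rank-3
#' SVD factorization within the box
#' \eqn{[(1-\delta)\alpha_k, (1+\delta)\alpha_k]} using the swarm optimizer,
#' and accepts the refined structure only if its energy is strictly lower
#' than the input's (so refinement can never degrade a model).
#'
#' @param trace the [ca_trace] to refine.
#' @param energy an [energy_model()].
#' @param config a [refine_config].
#' @return List with `trace` (the refined or original structure) and
#'   `report`: `input_energy`, `refined_energy`, `betas`, `accepted`, and the
#'   optimizer result under `optimization`.
#' @export
refine_svd <- function(trace, energy, config = refine_config()) {
  stopifnot(is_ca_trace(trace), inherits(energy, "energy_model"),
            inherits(config, "refine_config"))
  basis <- svd_basis(trace)
  lower <- (1 - config$delta) * basis$alphas
  upper <- (1 + config$delta) * basis$alphas
  space <- search_space(pmin(lower, upper), pmax(lower, upper),
                        margin = config$delta)
  objective <- function(betas)
    evaluate_energy(energy, reconstruct_svd(basis, betas))
  opt <- pso_optimize(objective, space, config$swarm)
  input_energy <- evaluate_energy(energy, trace)
  accepted <- is.finite(opt$best_value) && opt$best_value < input_energy
  out <- if (accepted) {
    refined <- reconstruct_svd(basis, opt$best_position)
    refined$label <- trace$label
    refined
  } else trace
  list(
    trace = out,
    report = list(
      input_energy = input_energy,
      refined_energy = if (accepted) opt$best_value else input_energy,
      betas = if (accepted) opt$best_position else basis$alphas,
      accepted = accepted,
      optimization = opt
    )
  )
}
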