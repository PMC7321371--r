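#' Rigid-body superposition of two C-alpha traces
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `reference` over the
#' one-to-one residue correspondence by index. Only proper rotations are
#' allowed: when the cross-covariance has negative determinant the axis of
#' the smallest singular value is flipped, which also gives a deterministic
#' result for rank-deficient (collinear or coincident) point sets.
#'
#' @param mobile,reference [ca_trace] objects with equal residue counts.
#' @return A list with components
#'   \describe{
#'     \item{result}{a `superposition_result`: `rotation` (3x3 proper
#'       orthogonal), `translation` (length-3, Angstrom) such that a mobile
#'       coordinate column vector x maps to `rotation \%*\% x + translation`,
#'       and `rmsd` (Angstrom) at the optimum.}
#'     \item{trace}{the transformed mobile trace.}
#'   }
#' @examples
#' a <- ca_trace(matrix(rnorm(30), ncol = 3))
#' s <- superpose(a, a)
#' s$result$rmsd  # 0
#' @export
superpose <- function(mobile, reference) {
  stopifnot(is_ca_trace(mobile), is_ca_trace(reference))
  stopifnot_same_length(mobile, reference)
  M <- mobile$coords
  R0 <- reference$coords
  cm <- colMeans(M)
  cr <- colMeans(R0)
  Mc <- sweep(M, 2, cm)
  Rc <- sweep(R0, 2, cr)
  H <- crossprod(Mc, Rc)                      # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                          # fully degenerate: keep identity branch
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  transformed <- Mc %*% t(rot)
  rmsd_val <- sqrt(mean(rowSums((transformed - Rc)^2)))
  transformed <- sweep(transformed, 2, cr, FUN = "+")
  translation <- as.vector(cr - rot %*% cm)
  res <- structure(
    list(rotation = rot, translation = translation, rmsd = rmsd_val),
    class = "superposition_result"
  )
  list(result = res,
       trace = ca_trace(transformed, label = mobile$label))
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Root-mean-square deviation between two traces
#'
#' @param a,b [ca_trace] objects with equal residue counts.
#' @param superpose_first if `TRUE` (default), the minimum RMSD over all
#'   rigid-body transforms is returned (Kabsch superposition); if `FALSE`,
#'   the RMSD of the coordinates as given.
#' @return Non-negative RMSD in Angstrom.
#' @examples
#' a <- ca_trace(matrix(rnorm(30), ncol = 3))
#' b <- ca_trace(a$coords + rep(c(3, 4, 0), each = 10))
#' rmsd(a, b, superpose_first = FALSE)  # 5
#' rmsd(a, b)                           # ~0
#' @export
rmsd <- function(a, b, superpose_first = TRUE) {
  stopifnot(is_ca_trace(a), is_ca_trace(b))
  stopifnot_same_length(a, b)
  if (superpose_first) {
    superpose(a, b)$result$rmsd
  } else {
    sqrt(mean(rowSums((a$coords - b$coords)^2)))
  }
}
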