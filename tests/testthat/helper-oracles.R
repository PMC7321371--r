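# Shared fixtures and independent oracles used across test files.

random_trace <- function(n, seed = NULL, label = "rnd") {
  if (!is.null(seed)) set.seed(seed)
  ca_trace(matrix(rnorm(3 * n, sd = 5), ncol = 3), label = label)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(trace, rot = random_rotation(),
                            shift = rnorm(3, sd = 10)) {
  ca_trace(sweep(trace$coords %*% t(rot), 2, shift, "+"), label = trace$label)
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# Independent superposition oracle: minimize rmsd over rotations parametrized
# by quaternions, coarse random grid followed by a local polish.
oracle_superposed_rmsd <- function(mobile, reference, n_grid = 4000) {
  A <- sweep(mobile$coords, 2, colMeans(mobile$coords))
  B <- sweep(reference$coords, 2, colMeans(reference$coords))
  f <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((A %*% R - B)^2)))
  }
  set.seed(99)
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, f)
  best <- qs[which.min(vals), ]
  opt <- optim(best, f, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  opt$value
}

# Optimal 1-D k-means cost by dynamic programming (optimal clusters of sorted
# 1-D data are contiguous).
dp_kmeans_cost <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {           # within-ss of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- seg_cost(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n)
    D[m, j] <- min(vapply(m:j, function(i) D[m - 1, i - 1] + seg_cost(i, j),
                          numeric(1)))
  D[k, n]
}

partition_cost <- function(x, part) {
  sum(vapply(seq_len(part$k), function(j) {
    xs <- x[part$labels == j]
    sum((xs - mean(xs))^2)
  }, numeric(1)))
}

# Naive double-loop shrinkage intensity: direct transliteration of the
# regularization formulas, kept independent of the vectorized implementation.
naive_shrinkage <- function(S, C, w = 1) {
  p <- nrow(S)
  N <- ncol(C)
  w <- rep_len(w, N)
  s_d <- sum(diag(S)) / p
  num <- 0
  for (i in 2:p) for (j in 1:(i - 1)) {
    q <- w * C[i, ] * C[j, ]
    num <- num + sum((q - S[i, j] / N)^2)
  }
  den <- 0
  for (i in 2:p) for (j in 1:(i - 1)) den <- den + S[i, j]^2
  den <- 2 * den
  for (i in 1:p) den <- den + (S[i, i] - 1)^2
  lambda <- if (den <= 0) 0 else min(max(2 * num / den, 0), 1)
  list(lambda_d = lambda, s_d = s_d)
}

# Weighted scatter from centered samples, for cross-checks.
outer_sum <- function(C, w = 1) {
  w <- rep_len(w, ncol(C))
  C %*% (t(C) * w)
}

# 3-class Gaussian ensemble in `p` dimensions for discriminant-recovery
# checks: class means `sep` standard deviations apart.
gaussian_classes <- function(p = 30, per_class = 20, k = 3, sep = 5,
                             sd_within = 1, seed = 1) {
  set.seed(seed)
  means <- matrix(rnorm(p * k), p, k)
  means <- sweep(means, 2, sqrt(colSums(means^2)), "/") * sep * sd_within
  X <- matrix(NA_real_, p, per_class * k)
  labels <- integer(per_class * k)
  for (c in seq_len(k)) {
    idx <- (c - 1) * per_class + seq_len(per_class)
    X[, idx] <- means[, c] + matrix(rnorm(p * per_class, 0, sd_within),
                                    p, per_class)
    labels[idx] <- c
  }
  list(X = X, labels = labels)
}

# Discriminant pipeline on a plain matrix + labels; returns the
# nearest-centroid training accuracy in the top-`d_use` discriminant
# coordinates.
lda_centroid_accuracy <- function(X, labels, d = 4, d_use = 2) {
  k <- length(unique(labels))
  part <- structure(
    list(k = k, labels = labels, class_sizes = tabulate(labels, k),
         centroids = seq_len(k)),
    class = "class_partition")
  traces <- NULL
  ens <- structure(
    list(X = X, labels = as.character(seq_len(ncol(X))),
         energies = rep(0, ncol(X)),
         residue_count = nrow(X) / 3, n_templates = ncol(X)),
    class = "template_ensemble")
  sc <- compute_scatter(ens, part)
  sb <- shrink_scatter(sc$SB, sc$sb_samples, sc$sb_weights)
  sw <- shrink_scatter(sc$SW, sc$sw_samples)
  W <- lda_basis(sb, sw, d = min(d, nrow(X)))
  proj <- t(W[, seq_len(d_use), drop = FALSE]) %*% (X - sc$mu)
  cent <- vapply(seq_len(k),
                 function(c) rowMeans(proj[, labels == c, drop = FALSE]),
                 numeric(d_use))
  d2 <- vapply(seq_len(k), function(c) colSums((proj - cent[, c])^2),
               numeric(ncol(X)))
  pred <- max.col(-d2, ties.method = "first")
  mean(pred == labels)
}
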