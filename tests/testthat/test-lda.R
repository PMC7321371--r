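make_ens <- function(X) {
  structure(
    list(X = X, labels = as.character(seq_len(ncol(X))),
         energies = rep(0, ncol(X)), residue_count = nrow(X) / 3,
         n_templates = ncol(X)),
    class = "template_ensemble")
}

make_part <- function(labels) {
  k <- length(unique(labels))
  structure(
    list(k = k, labels = labels, class_sizes = tabulate(labels, k),
         centroids = seq_len(k)),
    class = "class_partition")
}

test_that("two spherical classes along e1 give a first discriminant along e1", {
  p <- 10
  mu1 <- c(5, rep(0, p - 1)); mu2 <- c(-5, rep(0, p - 1))
  # per-class samples at mu +/- e_j: the within-class scatter is exactly
  # isotropic, so the discriminant is exactly the mean-difference axis
  cloud <- function(mu) vapply(seq_len(p), function(j) {
    e <- rep(0, p); e[j] <- 1; mu + e
  }, numeric(p))
  X <- cbind(cloud(mu1), cloud(mu1) - 2 * (cloud(mu1) - mu1),
             cloud(mu2), cloud(mu2) - 2 * (cloud(mu2) - mu2))
  labels <- rep(c(1, 2), each = 2 * p)
  sc <- compute_scatter(make_ens(X), make_part(labels))
  sb <- shrink_scatter(sc$SB, sc$sb_samples, sc$sb_weights)
  sw <- shrink_scatter(sc$SW, sc$sw_samples)
  W <- lda_basis(sb, sw, d = 1)
  angle <- acos(min(abs(sum(W[, 1] * c(1, rep(0, p - 1)))), 1))
  expect_lt(angle, 1e-3)
})

test_that("generalized eigenvalues are returned in decreasing order and the
           spectrum beyond k-1 directions is regularization-dominated", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(3:4, 1)
    g <- gaussian_classes(p = 18, per_class = 8, k = k, seed = rep)
    sc <- compute_scatter(make_ens(g$X), make_part(g$labels))
    sb <- shrink_scatter(sc$SB, sc$sb_samples, sc$sb_weights)
    sw <- shrink_scatter(sc$SW, sc$sw_samples)
    W <- lda_basis(sb, sw, d = k + 2)
    ev <- attr(W, "eigenvalues")
    expect_true(all(diff(ev) <= 1e-8))
    expect_lte(ev[k], ev[k - 1] + 1e-8)
  }
})

test_that("four classes with four requested dimensions return four columns", {
  g <- gaussian_classes(p = 30, per_class = 10, k = 4, seed = 2)
  sc <- compute_scatter(make_ens(g$X), make_part(g$labels))
  sb <- shrink_scatter(sc$SB, sc$sb_samples, sc$sb_weights)
  sw <- shrink_scatter(sc$SW, sc$sw_samples)
  W <- lda_basis(sb, sw, d = 4)
  expect_equal(dim(W), c(30, 4))
  expect_equal(colSums(W^2), rep(1, 4), tolerance = 1e-10)
})

test_that("lda_basis refuses a singular within-class matrix", {
  SW <- matrix(0, 6, 6)
  SB <- diag(6)
  expect_error(lda_basis(SB, SW, d = 2), "regularization required")
})

test_that("well-separated Gaussian classes are classified by the top-2
           discriminant coordinates", {
  accs <- vapply(1:3, function(s) {
    g <- gaussian_classes(p = 30, per_class = 20, k = 3, sep = 5, seed = s)
    lda_centroid_accuracy(g$X, g$labels, d = 4, d_use = 2)
  }, numeric(1))
  expect_true(all(accs >= 0.95))
})

test_that("the HF term completes the basis so the best template is exact", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 30
    Vd <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
    mu <- rnorm(n)
    m_best <- rnorm(n, sd = 4)
    basis <- append_hf_term(Vd, mu, m_best)
    expect_false(basis$hf_zero)
    expect_equal(dim(basis$V), c(n, 5))
    # orthonormal columns
    expect_lt(max(abs(crossprod(basis$V) - diag(5))), 1e-8)
    # HF column orthogonal to the discriminant block and spanning the residual
    rec <- reconstruct(basis, project(basis, m_best))
    expect_lt(sqrt(sum((rec - m_best)^2)) / sqrt(sum(m_best^2)), 1e-6)
  }
})

test_that("a best template already in the span yields a zero HF sentinel", {
  n <- 20
  Vd <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  mu <- rnorm(n)
  b1 <- append_hf_term(Vd, mu, mu)
  expect_true(b1$hf_zero)
  expect_equal(b1$V[, 4], rep(0, n))
  expect_equal(b1$column_norms[4], 0)
  b2 <- append_hf_term(Vd, mu, mu + 2 * Vd[, 1])
  expect_true(b2$hf_zero)
  # discriminant block still orthonormal and projection still exact in-span
  rec <- reconstruct(b2, project(b2, mu + 2 * Vd[, 1]))
  expect_equal(rec, mu + 2 * Vd[, 1], tolerance = 1e-9)
})

test_that("projection and reconstruction are an exact least-squares pair", {
  set.seed(43)
  n <- 24
  basis <- append_hf_term(qr.Q(qr(matrix(rnorm(n * 4), n, 4))),
                          rnorm(n), rnorm(n, sd = 3))
  expect_equal(project(basis, basis$mu), rep(0, 5), tolerance = 1e-12)
  for (rep in 1:10) {
    a <- rnorm(5)
    expect_equal(project(basis, reconstruct(basis, a)), a, tolerance = 1e-9)
    # isometry of the orthonormal basis
    expect_equal(sqrt(sum((reconstruct(basis, a) - basis$mu)^2)),
                 sqrt(sum(a^2)), tolerance = 1e-9)
  }
  # affine linearity
  m1 <- rnorm(n); m2 <- rnorm(n)
  expect_equal(project(basis, (m1 + m2) / 2) ,
               (project(basis, m1) + project(basis, m2)) / 2,
               tolerance = 1e-9)
  # optimality: the projection is the closest point of the affine subspace
  x <- rnorm(n, sd = 2)
  best <- sqrt(sum((x - reconstruct(basis, project(basis, x)))^2))
  for (rep in 1:100) {
    a <- rnorm(5, sd = 2)
    expect_lte(best, sqrt(sum((x - reconstruct(basis, a))^2)) + 1e-12)
  }
})

test_that("search bounds cover the template projections with the set margin", {
  n <- 12
  Vd <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  mu <- rep(0, n)
  basis <- append_hf_term(Vd, mu, rnorm(n))
  # two templates projecting to 0 and 1 on the first coordinate
  X <- cbind(mu, basis$V[, 1])
  ens <- make_ens(X)
  sp0 <- search_bounds(basis, ens, margin = 0)
  expect_equal(sp0$lower[1], 0, tolerance = 1e-12)
  expect_equal(sp0$upper[1], 1, tolerance = 1e-12)
  sp <- search_bounds(basis, ens, margin = 0.1)
  expect_equal(sp$lower[1], -0.1, tolerance = 1e-12)
  expect_equal(sp$upper[1], 1.1, tolerance = 1e-12)
  # containment on random ensembles
  set.seed(47)
  for (rep in 1:5) {
    Xr <- matrix(rnorm(n * 8, sd = 3), n, 8)
    ensr <- make_ens(Xr)
    spr <- search_bounds(basis, ensr, margin = runif(1, 0, 0.3))
    A <- crossprod(basis$V, Xr - basis$mu)
    expect_true(all(A >= spr$lower - 1e-10 & A <= spr$upper + 1e-10))
  }
})

test_that("zero-range coordinates are widened around their center", {
  n <- 12
  basis <- append_hf_term(qr.Q(qr(matrix(rnorm(n * 2), n, 2))),
                          rep(0, n), rnorm(n))
  X <- cbind(2 * basis$V[, 1], 2 * basis$V[, 1])   # identical projections
  sp <- search_bounds(basis, make_ens(X), margin = 0.1)
  expect_equal(sp$lower[1], 2 - 0.1 * 2, tolerance = 1e-9)
  expect_equal(sp$upper[1], 2 + 0.1 * 2, tolerance = 1e-9)
  expect_true(all(sp$lower <= sp$upper))
})

test_that("a reduced basis serializes to JSON and back losslessly", {
  set.seed(53)
  n <- 15
  basis <- append_hf_term(qr.Q(qr(matrix(rnorm(n * 3), n, 3))),
                          rnorm(n), rnorm(n))
  path <- withr::local_tempfile(fileext = ".json")
  write_reduced_basis(basis, path)
  back <- read_reduced_basis(path)
  expect_equal(back$mu, basis$mu)
  expect_equal(back$V, basis$V, ignore_attr = TRUE)
  expect_equal(back$d, basis$d)
  expect_equal(back$column_norms, basis$column_norms)
  expect_equal(back$hf_zero, basis$hf_zero)
})
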