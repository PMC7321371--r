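sphere <- function(x) sum(x^2)

test_that("initial positions and velocities respect the search space", {
  set.seed(61)
  for (rep in 1:20) {
    d <- sample(1:6, 1)
    lo <- rnorm(d, sd = 3)
    sp <- search_space(lo, lo + runif(d, 0.5, 4))
    st <- initialize_swarm(sp, swarm_config(swarm_size = 15, seed = rep))
    expect_true(all(st$positions >= matrix(sp$lower, 15, d, byrow = TRUE)))
    expect_true(all(st$positions <= matrix(sp$upper, 15, d, byrow = TRUE)))
    half <- (sp$upper - sp$lower) / 2
    expect_true(all(abs(st$velocities) <= matrix(half, 15, d, byrow = TRUE)))
  }
  expect_error(initialize_swarm(search_space(c(1, 2), c(1, 2)),
                                swarm_config()), "degenerate")
})

test_that("the same seed reproduces the swarm bit for bit", {
  sp <- search_space(rep(-5, 4), rep(5, 4))
  cfg <- swarm_config(seed = 123)
  expect_identical(initialize_swarm(sp, cfg), initialize_swarm(sp, cfg))
  r1 <- pso_optimize(sphere, sp, cfg)
  r2 <- pso_optimize(sphere, sp, cfg)
  expect_identical(r1, r2)
})

test_that("dispersion is 100% at iteration 1, scales with spread, 0 when collapsed", {
  sp <- search_space(rep(-5, 3), rep(5, 3))
  cfg <- swarm_config(swarm_size = 20, seed = 3)
  st <- initialize_swarm(sp, cfg)
  expect_equal(st$dispersion_pct, 100)
  st1 <- pso_step(st, sphere, sp, cfg)  # first step only evaluates
  expect_equal(st1$dispersion_pct, 100)
  # halving every offset from the centroid halves the dispersion
  centroid <- colMeans(st$positions)
  st_half <- st
  st_half$positions <- sweep(sweep(st$positions, 2, centroid), 1:2, 2, "/")
  st_half$positions <- sweep(st_half$positions, 2, centroid, "+")
  expect_equal(swarm_dispersion(st_half, baseline = st$baseline), 50,
               tolerance = 1e-9)
  # identical particles: zero dispersion
  st_same <- st
  st_same$positions <- matrix(1, 20, 3)
  expect_equal(swarm_dispersion(st_same, baseline = st$baseline), 0)
  # degenerate zero baseline defines dispersion 0
  expect_equal(swarm_dispersion(st_same, baseline = 0), 0)
})

test_that("a constant objective never changes the incumbent", {
  sp <- search_space(rep(0, 3), rep(1, 3))
  cfg <- swarm_config(swarm_size = 10, iterations = 15, seed = 5)
  res <- pso_optimize(function(x) 42, sp, cfg)
  expect_equal(res$best_value, 42)
  expect_true(all(res$history$best_value == 42))
})

test_that("every visited position satisfies the bounds exactly", {
  sp <- search_space(c(-1, 0, 2), c(1, 0.5, 2.1))
  cfg <- swarm_config(swarm_size = 12, iterations = 30, seed = 7)
  st <- initialize_swarm(sp, cfg)
  for (t in 1:30) {
    st <- pso_step(st, sphere, sp, cfg)
    expect_true(all(st$positions >= matrix(sp$lower, 12, 3, byrow = TRUE)))
    expect_true(all(st$positions <= matrix(sp$upper, 12, 3, byrow = TRUE)))
  }
})

test_that("the incumbent best value never increases", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  for (s in 1:20) {
    res <- pso_optimize(sphere, sp, swarm_config(seed = s, iterations = 25))
    expect_true(all(diff(res$history$best_value) <= 0))
    expect_equal(res$best_value, min(res$history$best_value))
    expect_lte(res$best_value, min(res$sampled_values))
  }
})

test_that("non-finite objective values are treated as +Inf", {
  sp <- search_space(rep(-2, 2), rep(2, 2))
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  res <- pso_optimize(spiky, sp, swarm_config(seed = 11, iterations = 20))
  expect_true(is.finite(res$best_value))
  expect_lte(res$best_position[1], 0)
})

test_that("the swarm converges on the bounded sphere benchmark", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  best <- vapply(1:20, function(s)
    pso_optimize(sphere, sp, swarm_config(seed = s))$best_value, numeric(1))
  expect_gte(sum(best <= 1e-2), 19)
})

test_that("a quadratic bowl centered in-bounds is located accurately", {
  center <- c(1, -2, 0.5)
  sp <- search_space(rep(-5, 3), rep(5, 3))
  res <- pso_optimize(function(x) sum((x - center)^2), sp,
                      swarm_config(seed = 13))
  expect_lt(sqrt(sum((res$best_position - center)^2)), 1e-3)
})

test_that("the constriction variant also converges and stays in bounds", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  best <- vapply(1:10, function(s)
    pso_optimize(sphere, sp,
                 swarm_config(seed = s, variant = "constriction"))$best_value,
    numeric(1))
  expect_true(all(best <= 1e-2))
})

test_that("post-collapse iterations contribute one de-duplicated model each", {
  # the constriction variant contracts the swarm, so collapse always occurs
  sp <- search_space(rep(-5, 5), rep(5, 5))
  cfg <- swarm_config(swarm_size = 25, iterations = 60, seed = 17,
                      variant = "constriction")
  res <- pso_optimize(sphere, sp, cfg)
  expect_false(is.na(res$collapsed_at))
  c_at <- res$collapsed_at
  expect_equal(nrow(res$sampled_positions),
               25 * (c_at - 1) + (60 - c_at + 1))
  expect_equal(length(res$sampled_values), nrow(res$sampled_positions))
  # dispersion crossed the threshold exactly at the recorded iteration
  expect_true(all(res$history$dispersion_pct[seq_len(c_at - 1)] >=
                  cfg$collapse_threshold))
  expect_lt(res$history$dispersion_pct[c_at], cfg$collapse_threshold)
})

test_that("an uncollapsed run samples the full swarm at every iteration", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  cfg <- swarm_config(swarm_size = 25, iterations = 20, seed = 17)
  res <- pso_optimize(sphere, sp, cfg)
  if (is.na(res$collapsed_at)) {
    expect_equal(nrow(res$sampled_positions), 25 * 20)
  } else {
    c_at <- res$collapsed_at
    expect_equal(nrow(res$sampled_positions),
                 25 * (c_at - 1) + (20 - c_at + 1))
  }
})

test_that("the optimizer trace log round-trips through the TSV writer", {
  sp <- search_space(rep(-1, 2), rep(1, 2))
  res <- pso_optimize(sphere, sp, swarm_config(seed = 19, iterations = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pso_trace(res, path)
  back <- read.delim(path)
  expect_equal(back$best_value, res$history$best_value)
  expect_equal(nrow(back), 8)
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(swarm_config(swarm_size = 1), "at least 2")
  expect_error(swarm_config(iterations = 0), "at least 1")
  expect_error(swarm_config(collapse_threshold = 0), "between 0 and 100")
})
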