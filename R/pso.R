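#' Swarm optimizer configuration
#'
#' Defaults follow the pipeline's standard sampling budget: 40 particles and
#' 50 iterations, which is sufficient for a deep sampling of the 5-coordinate
#' reduced spaces the pipeline builds. The swarm is considered to have
#' collapsed onto an optimum once the median particle dispersion around the
#' swarm centroid falls below `collapse_threshold` percent of its initial
#' value.
#'
#' Two update rules are available:
#' * `"rr"` (default) — the regressive-regressive member of the PSO family,
#'   obtained by a fully implicit discretization of the damped mass-spring
#'   particle dynamics; its velocity update divides by
#'   `1 + (1 - omega) + phi`, which self-damps large accelerations and gives
#'   the variant its high explorative character. Parameters sit on the
#'   high-exploration line `phi_total = 3 (omega - 3/2)` with `omega = 3`:
#'   each attraction coefficient is drawn uniformly on (0, `phi_total`), so
#'   the mean total attraction equals `phi_total` = 4.5.
#' * `"constriction"` — Clerc-Kennedy constriction PSO
#'   (`chi = 0.7298`, `c1 = c2 = 1.49618`), a widely used fallback.
#'
#' @param swarm_size number of particles (>= 2); default 40.
#' @param iterations number of iterations (>= 1); default 50. Iteration 1
#'   evaluates the initial swarm; each later iteration moves and evaluates
#'   every particle once.
#' @param seed integer seed controlling all random draws of the run.
#' @param collapse_threshold dispersion percentage below which the swarm is
#'   considered collapsed; default 3.
#' @param variant `"rr"` or `"constriction"`.
#' @param omega,phi_total RR variant parameters (inertia-like constant and
#'   total mean attraction); ignored by the constriction variant.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(swarm_size = 40, iterations = 50, seed = 1,
                         collapse_threshold = 3,
                         variant = c("rr", "constriction"),
                         omega = 3, phi_total = 3 * (omega - 1.5)) {
  variant <- match.arg(variant)
  if (swarm_size < 2) stop("`swarm_size` must be at least 2", call. = FALSE)
  if (iterations < 1) stop("`iterations` must be at least 1", call. = FALSE)
  if (collapse_threshold <= 0 || collapse_threshold >= 100)
    stop("`collapse_threshold` must lie strictly between 0 and 100",
         call. = FALSE)
  structure(
    list(swarm_size = as.integer(swarm_size),
         iterations = as.integer(iterations),
         seed = as.integer(seed),
         collapse_threshold = collapse_threshold,
         variant = variant, omega = omega, phi_total = phi_total),
    class = "swarm_config"
  )
}

#' Initialize a particle swarm in a prismatic search space
#'
#' Positions are drawn uniformly inside the bounds and velocities uniformly
#' in +/- half the coordinate range; both are deterministic given the seed.
#' Personal and global bests are unset until the first [pso_step()]
#' evaluates the swarm.
#'
#' @param space a [search_space].
#' @param config a [swarm_config]; its `seed` seeds the run's random stream.
#' @return A `swarm_state` with `positions`, `velocities` (swarm_size x d),
#'   unset bests, `iteration = 0`, and `baseline` (initial median distance to
#'   the swarm centroid, the 100\% dispersion reference).
#' @export
initialize_swarm <- function(space, config) {
  stopifnot(inherits(space, "search_space"), inherits(config, "swarm_config"))
  lo <- space$lower; hi <- space$upper
  d <- length(lo)
  if (all(hi - lo <= 0))
    stop("degenerate search space: all coordinates have zero range",
         call. = FALSE)
  s <- config$swarm_size
  set.seed(config$seed)
  positions <- matrix(stats::runif(s * d, rep(lo, each = s), rep(hi, each = s)),
                      s, d)
  half <- (hi - lo) / 2
  velocities <- matrix(stats::runif(s * d, rep(-half, each = s),
                                    rep(half, each = s)), s, d)
  centroid <- colMeans(positions)
  baseline <- stats::median(sqrt(rowSums(sweep(positions, 2, centroid)^2)))
  structure(
    list(positions = positions, velocities = velocities,
         pbest_positions = positions,
         pbest_values = rep(Inf, s),
         gbest_position = positions[1, ], gbest_value = Inf,
         iteration = 0L, baseline = baseline,
         dispersion_pct = if (baseline > 0) 100 else 0),
    class = "swarm_state"
  )
}

#' Median swarm dispersion relative to its initial value
#'
#' Dispersion is the median Euclidean distance of the particles to the swarm
#' centroid, expressed as a percentage of `baseline` (the same median at
#' iteration 1, so the first iteration is 100\% by construction). A zero
#' baseline (all particles initially identical) defines dispersion 0 and an
#' immediate collapse.
#'
#' @param state a `swarm_state`.
#' @param baseline positive reference distance; defaults to the state's own
#'   initial median distance.
#' @return Dispersion percentage.
#' @export
swarm_dispersion <- function(state, baseline = state$baseline) {
  centroid <- colMeans(state$positions)
  med <- stats::median(sqrt(rowSums(sweep(state$positions, 2, centroid)^2)))
  if (baseline <= 0) return(0)
  100 * med / baseline
}

#' Advance the swarm by one iteration
#'
#' The first step evaluates the initial positions; every later step performs
#' one velocity and position update per particle (using the configured
#' variant), then exactly one objective evaluation per particle. Positions
#' leaving the admissible box are clamped to the violated bound and the
#' corresponding velocity component is zeroed, so every returned position
#' satisfies the bounds exactly. Non-finite objective values are treated as
#' +Inf. Random draws come from the run's single generator stream in fixed
#' particle-index order.
#'
#' @param state a `swarm_state`.
#' @param objective function from a position vector to a scalar energy.
#' @param space the [search_space].
#' @param config the [swarm_config].
#' @return The updated `swarm_state` (with `dispersion_pct` refreshed).
#' @export
pso_step <- function(state, objective, space, config) {
  stopifnot(inherits(state, "swarm_state"))
  s <- nrow(state$positions)
  d <- ncol(state$positions)
  X <- state$positions
  V <- state$velocities
  if (state$iteration >= 1L) {
    P <- state$pbest_positions
    g <- state$gbest_position
    Gd <- matrix(g, s, d, byrow = TRUE)
    if (config$variant == "rr") {
      # each coefficient ~ U(0, phi_total), so the total mean attraction
      # phi1 + phi2 has expectation phi_total
      phi1 <- matrix(stats::runif(s * d, 0, config$phi_total), s, d)
      phi2 <- matrix(stats::runif(s * d, 0, config$phi_total), s, d)
      den <- 1 + (1 - config$omega) + phi1 + phi2
      V <- (V + phi1 * (P - X) + phi2 * (Gd - X)) / den
    } else {
      chi <- 0.7298
      c1 <- matrix(stats::runif(s * d, 0, 1.49618), s, d)
      c2 <- matrix(stats::runif(s * d, 0, 1.49618), s, d)
      V <- chi * (V + c1 * (P - X) + c2 * (Gd - X))
    }
    X <- X + V
    lo <- matrix(space$lower, s, d, byrow = TRUE)
    hi <- matrix(space$upper, s, d, byrow = TRUE)
    out <- X < lo | X > hi
    X <- pmin(pmax(X, lo), hi)
    V[out] <- 0
  }
  values <- apply(X, 1, function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  })
  improved <- values < state$pbest_values
  state$pbest_positions[improved, ] <- X[improved, , drop = FALSE]
  state$pbest_values[improved] <- values[improved]
  if (min(values) < state$gbest_value) {
    i <- which.min(values)
    state$gbest_value <- values[i]
    state$gbest_position <- X[i, ]
  }
  state$positions <- X
  state$velocities <- V
  state$iteration <- state$iteration + 1L
  state$last_values <- values
  state$dispersion_pct <- swarm_dispersion(state)
  state
}

#' Run the swarm optimizer over a search space
#'
#' Runs `config$iterations` iterations from a fresh seeded swarm and tracks
#' the incumbent best, the dispersion history, and the collapse iteration
#' (first iteration whose dispersion drops below the threshold). The sampled
#' model list keeps every particle of every pre-collapse iteration but only
#' the iteration-best particle of each post-collapse iteration: once the
#' swarm has collapsed its particles are near-duplicates and would otherwise
#' be overrepresented in any downstream sampling of the low-energy region.
#'
#' @param objective function from a position vector (length d) to a scalar
#'   energy; lower is better.
#' @param space a [search_space].
#' @param config a [swarm_config].
#' @return A `pso_result`: list with `best_position`, `best_value`, `history`
#'   (data.frame: iteration, best_value, dispersion_pct), `sampled_positions`
#'   (matrix), `sampled_values`, and `collapsed_at` (iteration index or NA).
#' @examples
#' sp <- search_space(rep(-5, 3), rep(5, 3))
#' res <- pso_optimize(function(x) sum(x^2), sp, swarm_config(seed = 7))
#' res$best_value
#' @export
pso_optimize <- function(objective, space, config = swarm_config()) {
  state <- initialize_swarm(space, config)
  iters <- config$iterations
  history <- data.frame(iteration = seq_len(iters),
                        best_value = NA_real_, dispersion_pct = NA_real_)
  collapsed_at <- NA_integer_
  sampled_positions <- vector("list", iters)
  sampled_values <- vector("list", iters)
  for (t in seq_len(iters)) {
    state <- pso_step(state, objective, space, config)
    disp <- state$dispersion_pct
    history$best_value[t] <- state$gbest_value
    history$dispersion_pct[t] <- disp
    if (is.na(collapsed_at) && disp < config$collapse_threshold)
      collapsed_at <- t
    if (is.na(collapsed_at)) {
      sampled_positions[[t]] <- state$positions
      sampled_values[[t]] <- state$last_values
    } else {
      i <- which.min(state$last_values)
      sampled_positions[[t]] <- state$positions[i, , drop = FALSE]
      sampled_values[[t]] <- state$last_values[i]
    }
  }
  structure(
    list(best_position = state$gbest_position,
         best_value = state$gbest_value,
         history = history,
         sampled_positions = do.call(rbind, sampled_positions),
         sampled_values = unlist(sampled_values),
         collapsed_at = collapsed_at),
    class = "pso_result"
  )
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("pso_result: best value %.6g after %d iterations%s\n",
              x$best_value, nrow(x$history),
              if (is.na(x$collapsed_at)) " (no collapse)"
              else sprintf(" (collapsed at iteration %d)", x$collapsed_at)))
  invisible(x)
}

#' Write an optimizer trace as a tab-separated log
#' @param result a `pso_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pso_trace <- function(result, path) {
  utils::write.table(result$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
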