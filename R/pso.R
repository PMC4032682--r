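# Particle swarm optimization with time-varying acceleration coefficients
# (TVAC), specialized to the scalar recognition coefficient xi of the CRA
# classifier. Over the run the cognitive coefficient c1 decays (2.5 -> 0.5)
# while the social coefficient c2 grows (0.5 -> 2.5), shifting the swarm
# from exploration to consensus.

#' Swarm configuration
#'
#' @param population Number of particles `G` (default 20).
#' @param p_max Maximum number of iterations (default 100).
#' @param a1,b1 Cognitive acceleration endpoints: `c1` moves linearly from
#'   `a1` at iteration 0 to `b1` at `p_max` (defaults 2.5 and 0.5).
#' @param a2,b2 Social acceleration endpoints: `c2` moves from `a2` to `b2`
#'   (defaults 0.5 and 2.5).
#' @param omega Inertia weight: either a single constant or a length-2
#'   vector `c(start, end)` decayed linearly over the run (default
#'   `c(0.9, 0.4)`).
#' @param xi_bounds Search interval for the recognition coefficient
#'   (default `c(0.001, 50)`; grades underflow and the fitness goes flat for
#'   much larger `xi`).
#' @param epsilon Convergence threshold on the best fitness (default 0.05):
#'   the run stops early once the global best MSEF drops to `epsilon` or
#'   below.
#' @param velocity_limit Velocity clamp as a fraction of the bound range
#'   (default 0.2).
#' @return Object of class `swarm_config`.
#' @export
swarm_config <- function(population = 20, p_max = 100,
                         a1 = 2.5, b1 = 0.5, a2 = 0.5, b2 = 2.5,
                         omega = c(0.9, 0.4),
                         xi_bounds = c(0.001, 50),
                         epsilon = 0.05,
                         velocity_limit = 0.2) {
  if (!is.numeric(population) || population < 2) {
    stop("`population` must be >= 2", call. = FALSE)
  }
  if (!is.numeric(p_max) || p_max < 1) {
    stop("`p_max` must be >= 1", call. = FALSE)
  }
  if (length(xi_bounds) != 2L || xi_bounds[1] <= 0 ||
    xi_bounds[2] <= xi_bounds[1]) {
    stop("`xi_bounds` must be c(lower, upper) with 0 < lower < upper",
      call. = FALSE
    )
  }
  .check_positive(epsilon, "epsilon")
  if (!length(omega) %in% 1:2 || any(!is.finite(omega))) {
    stop("`omega` must be a constant or c(start, end)", call. = FALSE)
  }
  structure(
    list(
      population = as.integer(population), p_max = as.integer(p_max),
      a1 = a1, b1 = b1, a2 = a2, b2 = b2,
      omega = omega, xi_bounds = xi_bounds, epsilon = epsilon,
      velocity_limit = velocity_limit
    ),
    class = "swarm_config"
  )
}

#' Time-varying acceleration coefficients at iteration p
#'
#' Linear interpolation `c1 = (b1 - a1) * p / p_max + a1` and
#' `c2 = (b2 - a2) * p / p_max + a2`.
#'
#' @param p Iteration number, `0 <= p <= p_max`.
#' @param config A [swarm_config()].
#' @return Named vector `c(c1, c2)`.
#' @export
#' @examples
#' tvac_coefficients(0, swarm_config()) # c1 = 2.5, c2 = 0.5
tvac_coefficients <- function(p, config = swarm_config()) {
  stopifnot(inherits(config, "swarm_config"))
  if (!is.finite(p) || p < 0 || p > config$p_max) {
    stop("`p` must be in [0, p_max]", call. = FALSE)
  }
  c(
    c1 = (config$b1 - config$a1) * p / config$p_max + config$a1,
    c2 = (config$b2 - config$a2) * p / config$p_max + config$a2
  )
}

# Inertia weight at iteration p (constant, or linear decay start -> end).
.inertia_weight <- function(p, config) {
  if (length(config$omega) == 1L) {
    return(config$omega)
  }
  config$omega[1] + (config$omega[2] - config$omega[1]) * p / config$p_max
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly within the bounds, velocities start at
#' zero, and personal/global bests are seeded from the initial fitness
#' evaluations. Uses the current RNG stream.
#'
#' @param fitness Function mapping a position (scalar `xi`) to a finite
#'   fitness value to be minimized.
#' @param config A [swarm_config()].
#' @return A `swarm_state` list.
#' @export
swarm_init <- function(fitness, config = swarm_config()) {
  stopifnot(inherits(config, "swarm_config"))
  positions <- runif(
    config$population, config$xi_bounds[1],
    config$xi_bounds[2]
  )
  fits <- vapply(positions, fitness, numeric(1))
  if (any(!is.finite(fits))) {
    stop("fitness returned a non-finite value during initialization",
      call. = FALSE
    )
  }
  best <- which.min(fits)
  structure(
    list(
      positions = positions,
      velocities = numeric(config$population),
      pbest_pos = positions,
      pbest_fit = fits,
      gbest_pos = positions[best],
      gbest_fit = fits[best],
      iteration = 0L
    ),
    class = "swarm_state"
  )
}

#' Advance the swarm by one iteration
#'
#' Applies the TVAC velocity update
#' `v <- omega * v + c1 * rand1 * (pbest - x) + c2 * rand2 * (gbest - x)`
#' with fresh uniform `rand1`, `rand2` per particle, clamps the velocity,
#' moves and clips the positions to the bounds, re-evaluates the fitness,
#' and updates the personal and global bests only on strict improvement.
#'
#' @param state A `swarm_state` from [swarm_init()] or a previous step.
#' @param fitness Fitness function (minimized).
#' @param config A [swarm_config()].
#' @return The updated `swarm_state` (iteration counter incremented).
#' @export
swarm_step <- function(state, fitness, config = swarm_config()) {
  stopifnot(inherits(state, "swarm_state"), inherits(config, "swarm_config"))
  p <- state$iteration
  cc <- tvac_coefficients(p, config)
  w <- .inertia_weight(p, config)
  g <- length(state$positions)
  rand1 <- runif(g)
  rand2 <- runif(g)
  vel <- w * state$velocities +
    cc[["c1"]] * rand1 * (state$pbest_pos - state$positions) +
    cc[["c2"]] * rand2 * (state$gbest_pos - state$positions)
  vmax <- config$velocity_limit * diff(config$xi_bounds)
  vel <- .clamp(vel, -vmax, vmax)
  pos <- .clamp(
    state$positions + vel, config$xi_bounds[1],
    config$xi_bounds[2]
  )
  fits <- vapply(pos, fitness, numeric(1))
  if (any(!is.finite(fits))) {
    stop("fitness returned a non-finite value", call. = FALSE)
  }
  improved <- fits < state$pbest_fit
  state$pbest_pos[improved] <- pos[improved]
  state$pbest_fit[improved] <- fits[improved]
  best <- which.min(state$pbest_fit)
  if (state$pbest_fit[best] < state$gbest_fit) {
    state$gbest_fit <- state$pbest_fit[best]
    state$gbest_pos <- state$pbest_pos[best]
  }
  state$positions <- pos
  state$velocities <- vel
  state$iteration <- p + 1L
  state
}

#' Minimize a scalar fitness with TVAC particle swarm optimization
#'
#' Runs [swarm_init()] and repeated [swarm_step()]s until the global best
#' fitness reaches `epsilon` or `p_max` iterations have elapsed.
#'
#' @inheritParams swarm_step
#' @param seed Optional integer seed for reproducibility; when given, the
#'   RNG is seeded before initialization.
#' @return List with `xi_best`, `fitness_best`, `converged` (TRUE if the
#'   epsilon stop fired), `iterations`, and `trace`, a data frame with one
#'   row per iteration, starting at the post-initialization state
#'   (`iteration, c1, c2, omega, best_xi, best_msef`; the best-fitness
#'   column is non-increasing).
#' @export
#' @examples
#' fit <- pso_optimize(function(x) (x - 3)^2,
#'   swarm_config(xi_bounds = c(0.001, 10), epsilon = 1e-6),
#'   seed = 1
#' )
#' fit$xi_best
pso_optimize <- function(fitness, config = swarm_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- swarm_init(fitness, config)
  trace <- vector("list", config$p_max + 1L)
  cc0 <- tvac_coefficients(0, config)
  trace[[1L]] <- data.frame(
    iteration = 0L,
    c1 = cc0[["c1"]], c2 = cc0[["c2"]],
    omega = .inertia_weight(0, config),
    best_xi = state$gbest_pos,
    best_msef = state$gbest_fit
  )
  p_done <- 0L
  converged <- state$gbest_fit <= config$epsilon
  while (!converged && p_done < config$p_max) {
    state <- swarm_step(state, fitness, config)
    p_done <- state$iteration
    cc <- tvac_coefficients(p_done, config)
    trace[[p_done + 1L]] <- data.frame(
      iteration = p_done,
      c1 = cc[["c1"]], c2 = cc[["c2"]],
      omega = .inertia_weight(p_done, config),
      best_xi = state$gbest_pos,
      best_msef = state$gbest_fit
    )
    converged <- state$gbest_fit <= config$epsilon
  }
  list(
    xi_best = state$gbest_pos,
    fitness_best = state$gbest_fit,
    converged = converged,
    iterations = p_done,
    trace = do.call(rbind, trace[seq_len(p_done + 1L)])
  )
}

#' Tune the recognition coefficient of the CRA classifier
#'
#' Fitness of a candidate `xi` is the leave-one-out MSEF of the classifier
#' on the training set ([cra_loo_msef()]); the pairwise pattern distances
#' are computed once, so each evaluation only re-derives the grades.
#'
#' @inheritParams cra_model
#' @param config A [swarm_config()].
#' @param seed Optional integer seed.
#' @return List with `xi_best`, `msef_best`, `converged`, `iterations`,
#'   `trace` (see [pso_optimize()]).
#' @export
optimize_recognition_coefficient <- function(features, classes = NULL,
                                             config = swarm_config(),
                                             convention = c(
                                               "class_centered",
                                               "as_printed"
                                             ),
                                             error_mode = c(
                                               "wrapped",
                                               "plain"
                                             ),
                                             rescale_grades = FALSE,
                                             seed = NULL) {
  convention <- match.arg(convention)
  error_mode <- match.arg(error_mode)
  base <- cra_model(features, classes,
    xi = 1, convention = convention,
    error_mode = error_mode, rescale_grades = rescale_grades
  )
  ed <- .pairwise_distances(base$patterns)
  fitness <- function(xi) {
    .loo_msef_from_ed(
      ed, base$classes, xi, convention, error_mode,
      rescale_grades
    )
  }
  fit <- pso_optimize(fitness, config, seed = seed)
  list(
    xi_best = fit$xi_best,
    msef_best = fit$fitness_best,
    converged = fit$converged,
    iterations = fit$iterations,
    trace = fit$trace
  )
}

#' Train a CRA classifier with PSO-tuned recognition coefficient
#'
#' Convenience wrapper: runs [optimize_recognition_coefficient()] on the
#' labelled training set and returns the fitted [cra_model()] with the
#' optimization trace attached as attributes `pso` and `training_msef`.
#'
#' @inheritParams optimize_recognition_coefficient
#' @return A `cra_model` with tuned `xi`.
#' @export
cra_train <- function(features, classes = NULL, config = swarm_config(),
                      convention = c("class_centered", "as_printed"),
                      error_mode = c("wrapped", "plain"),
                      rescale_grades = FALSE, seed = NULL) {
  convention <- match.arg(convention)
  error_mode <- match.arg(error_mode)
  opt <- optimize_recognition_coefficient(
    features, classes,
    config = config,
    convention = convention, error_mode = error_mode,
    rescale_grades = rescale_grades, seed = seed
  )
  model <- cra_model(features, classes,
    xi = opt$xi_best, convention = convention,
    error_mode = error_mode, rescale_grades = rescale_grades
  )
  attr(model, "pso") <- opt
  attr(model, "training_msef") <- opt$msef_best
  model
}
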