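#' Genetic-algorithm settings
#'
#' @param population individuals per generation (default 100).
#' @param crossover_rate fraction of offspring produced by arithmetic
#'   crossover (default 0.8).
#' @param elite_count elites copied unchanged each generation (default 2).
#' @param max_generations generation cap (default 50).
#' @param mutation_sd Gaussian mutation standard deviation as a fraction of
#'   the bound width (default 0.05).
#' @param stall_tol stop when the best fitness has improved by less than
#'   this over `stall_generations` consecutive generations (default 1e-6).
#' @param stall_generations generations of stall tolerated before stopping
#'   (default 5).
#' @param seed integer seed.
#' @return list of class `ga_settings`.
#' @export
ga_settings <- function(population = 100, crossover_rate = 0.8,
                        elite_count = 2, max_generations = 50,
                        mutation_sd = 0.05, stall_tol = 1e-6,
                        stall_generations = 5, seed = 1L) {
  if (elite_count >= population) {
    stop_tremorkin("elite_count must be smaller than the population")
  }
  if (crossover_rate <= 0 || crossover_rate > 1) {
    stop_tremorkin("crossover_rate must lie in (0, 1]")
  }
  structure(list(population = population, crossover_rate = crossover_rate,
                 elite_count = elite_count,
                 max_generations = max_generations,
                 mutation_sd = mutation_sd, stall_tol = stall_tol,
                 stall_generations = stall_generations,
                 seed = as.integer(seed)),
            class = "ga_settings")
}

#' Tune the g-h smoothing parameter by genetic algorithm
#'
#' Minimises, over theta in `bounds`, the summed kinematic tracking error of
#' the real-time g-h tremor estimate against the offline low-pass reference
#' across all supplied trials (per-axis KTE summed over the three joint
#' axes). The search is bounded to \[0.8, 1\] by default: lower thetas would
#' let too much tremor leak into the voluntary estimate. The GA uses uniform
#' initialisation within the bounds, roulette-wheel selection on inverted
#' cost, arithmetic crossover, Gaussian mutation clipped to the bounds, and
#' elitism, so the per-generation best fitness never increases.
#'
#' @param trials list of [trial_recording()]s (synthetic or loaded).
#' @param settings a [ga_settings()].
#' @param bounds search interval for theta (default `c(0.8, 1)`).
#' @param joint joint spec as in [estimate_tremor_from_orientation()].
#' @param upsample_rate filter rate in Hz (default 1000).
#' @param fitness optional replacement objective `function(theta) cost`;
#'   when supplied the trials are ignored (used for calibration checks).
#' @return a list of class `ga_result`: `theta` (best), `fitness` (its
#'   cost), `trace` (tibble `generation`, `best_fitness`, `best_theta`),
#'   `settings`.
#' @seealso [grid_search_theta()] for an exhaustive oracle on the same
#'   objective.
#' @export
optimize_theta <- function(trials = NULL, settings = ga_settings(),
                           bounds = c(0.8, 1), joint = "wrist",
                           upsample_rate = 1000, fitness = NULL) {
  if (bounds[1] >= bounds[2] || bounds[1] < 0 || bounds[2] > 1) {
    stop_tremorkin("bounds must be an increasing pair within [0, 1]")
  }
  if (is.null(fitness)) {
    if (length(trials) == 0) stop_tremorkin("no trials supplied")
    fitness <- make_theta_objective(trials, joint, upsample_rate)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(settings$seed)
  width <- bounds[2] - bounds[1]
  pop <- stats::runif(settings$population, bounds[1], bounds[2])
  cost <- vapply(pop, fitness, numeric(1))
  trace <- vector("list", settings$max_generations)
  best_prev <- Inf
  stalled <- 0L
  for (gen in seq_len(settings$max_generations)) {
    ord <- order(cost)
    best <- cost[ord[1]]
    trace[[gen]] <- tibble::tibble(generation = gen, best_fitness = best,
                                   best_theta = pop[ord[1]])
    stalled <- if (gen > 1 && best_prev - best < settings$stall_tol) {
      stalled + 1L
    } else 0L
    if (stalled >= settings$stall_generations) {
      trace <- trace[seq_len(gen)]
      break
    }
    best_prev <- best
    # roulette selection on inverted cost
    w <- max(cost) - cost + 1e-12 * max(1, abs(max(cost)))
    parents <- sample.int(length(pop), 2 * (settings$population -
                                              settings$elite_count),
                          replace = TRUE, prob = w / sum(w))
    p1 <- pop[parents[seq_len(length(parents) / 2)]]
    p2 <- pop[parents[-seq_len(length(parents) / 2)]]
    u <- stats::runif(length(p1))
    cross <- stats::runif(length(p1)) < settings$crossover_rate
    child <- ifelse(cross, u * p1 + (1 - u) * p2, p1)
    child <- child + stats::rnorm(length(child),
                                  sd = settings$mutation_sd * width)
    child <- pmin(pmax(child, bounds[1]), bounds[2])
    elite <- pop[ord[seq_len(settings$elite_count)]]
    elite_cost <- cost[ord[seq_len(settings$elite_count)]]
    pop <- c(elite, child)
    cost <- c(elite_cost, vapply(child, fitness, numeric(1)))
  }
  trace <- dplyr::bind_rows(trace)
  i <- which.min(cost)
  structure(list(theta = pop[i], fitness = cost[i], trace = trace,
                 settings = settings, bounds = bounds),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result theta* = %.4f, fitness = %.6g, %d generations>\n",
              x$theta, x$fitness, max(x$trace$generation)))
  invisible(x)
}

# objective shared by the GA and the grid-search oracle: precompute the
# joint-velocity series and offline reference tremor once per trial, then
# each theta evaluation only reruns the g-h recursion
make_theta_objective <- function(trials, joint = "wrist",
                                 upsample_rate = 1000) {
  prepared <- lapply(trials, function(trial) {
    pair <- resolve_joint(trial, joint)
    y <- joint_velocity_series(trial, pair, upsample_rate)
    ref <- lapply(c("wx", "wy", "wz"), function(a) {
      offline_reference(y[[a]], upsample_rate)$tremor
    })
    list(y = y, ref = ref)
  })
  dt <- 1 / upsample_rate
  function(theta) {
    gains <- gh_gains(theta)
    sum(vapply(prepared, function(p) {
      sum(vapply(1:3, function(i) {
        yv <- p$y[[c("wx", "wy", "wz")[i]]]
        vol <- .gh_filter_core(yv, gains[["g"]], gains[["h"]], dt, TRUE)
        kte(yv - vol, p$ref[[i]])$kte
      }, numeric(1)))
    }, numeric(1)))
  }
}

#' Grid-search oracle for the g-h parameter
#'
#' Evaluates the same objective as [optimize_theta()] on an evenly spaced
#' grid (201 points by default) and returns the minimising theta — an
#' exhaustive cross-check for the stochastic search.
#'
#' @inheritParams optimize_theta
#' @param n_grid number of grid points (default 201).
#' @return list with `theta`, `fitness`, and the full `grid` tibble.
#' @export
grid_search_theta <- function(trials = NULL, bounds = c(0.8, 1),
                              n_grid = 201, joint = "wrist",
                              upsample_rate = 1000, fitness = NULL) {
  if (is.null(fitness)) {
    if (length(trials) == 0) stop_tremorkin("no trials supplied")
    fitness <- make_theta_objective(trials, joint, upsample_rate)
  }
  thetas <- seq(bounds[1], bounds[2], length.out = n_grid)
  cost <- vapply(thetas, fitness, numeric(1))
  i <- which.min(cost)
  list(theta = thetas[i], fitness = cost[i],
       grid = tibble::tibble(theta = thetas, fitness = cost))
}
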