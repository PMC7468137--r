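#' Search space for the continuous optimizers
#'
#' @param lower,upper Per-dimension bounds. Scalars are recycled to `dim`.
#' @param dim Problem dimension (number of decision variables; for feature
#'   selection this is the number of descriptor columns).
#' @return A `search_space` list with vectors `lower`, `upper` and the
#'   dimension `dim`.
#' @export
search_space <- function(lower = 0, upper = 1, dim = length(lower)) {
  stopifnot(dim >= 1)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower >= upper)) {
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, dim = dim),
    class = "search_space"
  )
}

#' Clamp a position into the box bounds
#'
#' @param x Numeric position vector.
#' @param space A [search_space()].
#' @return `x` clamped component-wise into `[lower, upper]`.
#' @export
clip_to_bounds <- function(x, space) {
  pmin(pmax(x, space$lower), space$upper)
}

#' Escaping energy schedule
#'
#' The prey's escaping energy decays linearly over the run:
#' \eqn{E = 2 E_0 (1 - t/T)}. Exploration is triggered while
#' \eqn{|E| \ge 1}; smaller values select among the besiege operators.
#'
#' @param E0 Initial escape energy in (-1, 1).
#' @param t Current iteration (0 <= t <= T).
#' @param T_max Total iterations (>= 1).
#' @return The scalar energy `E`.
#' @export
escaping_energy <- function(E0, t, T_max) {
  if (T_max < 1) stop("T_max must be >= 1", call. = FALSE)
  stopifnot(t >= 0, t <= T_max)
  2 * E0 * (1 - t / T_max)
}

#' Mean hawk position
#'
#' Arithmetic mean of the population rows — the \eqn{X_m} used by the
#' exploration and hard-dive rules.
#'
#' @param positions Population matrix (rows = hawks) or a single position.
#' @return Numeric vector of column means.
#' @export
mean_position <- function(positions) {
  if (is.null(dim(positions))) {
    return(positions)
  }
  if (nrow(positions) == 0L) stop("empty population", call. = FALSE)
  colMeans(positions)
}

#' Sigma of the Levy-flight step distribution
#'
#' Closed-form scale of the Mantegna algorithm for a stability exponent
#' `beta`:
#' \deqn{\sigma = \left[\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}}
#'
#' @param beta Stability exponent in (0, 2]; default 1.5.
#' @return The positive scale \eqn{\sigma}.
#' @export
levy_sigma <- function(beta = 1.5) {
  stopifnot(beta > 0, beta <= 2)
  (gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

# Raw Levy deviates u*sigma/|v|^(1/beta), one per dimension (no step length).
levy_step <- function(d, beta = 1.5) {
  sigma <- levy_sigma(beta)
  u <- stats::rnorm(d) * sigma
  v <- stats::rnorm(d)
  u / abs(v)^(1 / beta)
}

#' Levy flight step vector
#'
#' Heavy-tailed random step used by the rapid-dive operators:
#' \eqn{0.01 \, u \sigma / |v|^{1/\beta}} per coordinate, with `u`, `v`
#' standard-normal draws and \eqn{\sigma} from [levy_sigma()].
#'
#' @param d Dimension of the step vector.
#' @param beta Stability exponent; default 1.5.
#' @return Numeric vector of length `d`.
#' @export
levy_flight <- function(d, beta = 1.5) {
  0.01 * levy_step(d, beta)
}

#' HHO exploration move
#'
#' With probability `q >= 0.5` a hawk perches relative to a random member of
#' the population: \eqn{X_{rand} - r_1 |X_{rand} - 2 r_2 X|}; otherwise it
#' perches relative to the prey and the population mean:
#' \eqn{(X_{rabbit} - X_m) - r_3 (LB + r_4 (UB - LB))}. The random draws
#' `q`, `r1`–`r4` and the random hawk come from the current RNG stream
#' unless supplied (supplying them makes the operator deterministic for
#' testing).
#'
#' @param x Current hawk position.
#' @param positions Population matrix (rows = hawks).
#' @param x_rabbit Best position found so far.
#' @param space A [search_space()].
#' @param q,r1,r2,r3,r4 Optional fixed values for the random scalars.
#' @param rand_index Optional fixed index of the random hawk.
#' @return The proposed position, clipped to bounds.
#' @export
hho_explore <- function(x, positions, x_rabbit, space,
                        q = NULL, r1 = NULL, r2 = NULL, r3 = NULL, r4 = NULL,
                        rand_index = NULL) {
  if (is.null(q)) q <- stats::runif(1)
  if (q >= 0.5) {
    if (is.null(rand_index)) rand_index <- sample.int(nrow(positions), 1L)
    x_rand <- positions[rand_index, ]
    if (is.null(r1)) r1 <- stats::runif(1)
    if (is.null(r2)) r2 <- stats::runif(1)
    out <- x_rand - r1 * abs(x_rand - 2 * r2 * x)
  } else {
    if (is.null(r3)) r3 <- stats::runif(1)
    if (is.null(r4)) r4 <- stats::runif(1)
    x_m <- mean_position(positions)
    out <- (x_rabbit - x_m) - r3 * (space$lower + r4 * (space$upper - space$lower))
  }
  clip_to_bounds(out, space)
}

#' Soft besiege
#'
#' Applied when the prey retains energy (\eqn{|E| \ge 0.5}) but cannot escape
#' (\eqn{r \ge 0.5}): \eqn{\Delta X - E |J X_{rabbit} - X|} with
#' \eqn{\Delta X = X_{rabbit} - X} and jump strength \eqn{J = 2(1 - r_5)}.
#'
#' @param x Current position.
#' @param x_rabbit Best position.
#' @param E Escaping energy.
#' @param J Jump strength in (0, 2].
#' @return The updated (unclipped) position.
#' @export
hho_soft_besiege <- function(x, x_rabbit, E, J) {
  (x_rabbit - x) - E * abs(J * x_rabbit - x)
}

#' Hard besiege
#'
#' Applied when the prey is exhausted (\eqn{|E| < 0.5}, \eqn{r \ge 0.5}):
#' \eqn{X_{rabbit} - E |\Delta X|}.
#'
#' @inheritParams hho_soft_besiege
#' @return The updated (unclipped) position.
#' @export
hho_hard_besiege <- function(x, x_rabbit, E) {
  x_rabbit - E * abs(x_rabbit - x)
}

#' Greedy dive acceptance
#'
#' The rapid-dive operators propose a besiege point `Y` and a Levy-flight
#' point `Z = Y + S * LF`; the hawk moves to `Y` if it strictly improves on
#' its current fitness, else to `Z` if that improves, else stays put.
#' Returns the chosen position together with its fitness so callers avoid
#' re-evaluation.
#'
#' @param x Current position with fitness `fx`.
#' @param y,z Candidate positions.
#' @param fx Current fitness (minimization).
#' @param objective Objective function (minimized).
#' @return List with `x` (chosen position), `f` (its fitness) and `moved`.
#' @export
dive_accept <- function(x, y, z, fx, objective) {
  fy <- objective(y)
  if (fy < fx) {
    return(list(x = y, f = fy, moved = TRUE))
  }
  fz <- objective(z)
  if (fz < fx) {
    return(list(x = z, f = fz, moved = TRUE))
  }
  list(x = x, f = fx, moved = FALSE)
}

# Soft besiege with progressive rapid dives (|E| >= 0.5, r < 0.5).
hho_soft_dive <- function(x, fx, x_rabbit, E, J, objective, space,
                          beta = 1.5) {
  d <- length(x)
  y <- clip_to_bounds(x_rabbit - E * abs(J * x_rabbit - x), space)
  z <- clip_to_bounds(y + stats::runif(d) * levy_flight(d, beta), space)
  dive_accept(x, y, z, fx, objective)
}

# Hard besiege with progressive rapid dives (|E| < 0.5, r < 0.5); uses the
# population mean in place of the hawk's own position inside Y.
hho_hard_dive <- function(x, fx, x_rabbit, x_m, E, J, objective, space,
                          beta = 1.5) {
  d <- length(x)
  y <- clip_to_bounds(x_rabbit - E * abs(J * x_rabbit - x_m), space)
  z <- clip_to_bounds(y + stats::runif(d) * levy_flight(d, beta), space)
  dive_accept(x, y, z, fx, objective)
}

# Population initialization: coordinates LB + c (UB - LB) with c from either
# the uniform RNG stream or a chaotic sequence (column-major fill).
init_population <- function(space, n_agents, map = NULL) {
  if (n_agents < 2) stop("need at least 2 agents", call. = FALSE)
  d <- space$dim
  cvals <- if (is.null(map)) {
    stats::runif(n_agents * d)
  } else {
    chaos_sequence(map, n_agents * d)
  }
  sweep(
    sweep(matrix(cvals, n_agents, d), 2, space$upper - space$lower, "*"),
    2, space$lower, "+"
  )
}

# Shared engine behind hho_run() and chho_cs_run(). With all three hybrid
# switches off this IS baseline HHO; the hybrid run enables chaotic
# initialization, the chaotic energy schedule and/or per-iteration CS
# refinement. Minimizes `objective`.
hawk_engine <- function(objective, space, n_agents, n_iter,
                        chaotic_init = FALSE, chaotic_energy = FALSE,
                        cs_refine = FALSE, map = NULL, cs = cs_params(),
                        beta = 1.5) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if ((chaotic_init || chaotic_energy) && is.null(map)) {
    stop("a chaotic map is required when chaotic features are enabled",
      call. = FALSE
    )
  }
  d <- space$dim
  positions <- init_population(space, n_agents, if (chaotic_init) map else NULL)
  fitnesses <- apply(positions, 1, objective)
  ibest <- which.min(fitnesses)
  x_rabbit <- positions[ibest, ]
  f_rabbit <- fitnesses[ibest]

  chaos_state <- if (chaotic_energy) chaos_init(map) else NULL
  trace <- numeric(n_iter)

  for (t in seq_len(n_iter)) {
    if (chaotic_energy) {
      chaos_state <- chaos_step(map, chaos_state)
      E0 <- 2 * chaos_state$x - 1
    } else {
      E0 <- stats::runif(1, -1, 1)
    }
    E <- escaping_energy(E0, t, n_iter)

    for (i in seq_len(n_agents)) {
      x <- positions[i, ]
      if (abs(E) >= 1) {
        x_new <- hho_explore(x, positions, x_rabbit, space)
        f_new <- objective(x_new)
        positions[i, ] <- x_new
        fitnesses[i] <- f_new
      } else {
        r <- stats::runif(1)
        J <- 2 * (1 - stats::runif(1))
        if (r >= 0.5 && abs(E) >= 0.5) {
          x_new <- clip_to_bounds(hho_soft_besiege(x, x_rabbit, E, J), space)
          positions[i, ] <- x_new
          fitnesses[i] <- objective(x_new)
        } else if (r >= 0.5) {
          x_new <- clip_to_bounds(hho_hard_besiege(x, x_rabbit, E), space)
          positions[i, ] <- x_new
          fitnesses[i] <- objective(x_new)
        } else if (abs(E) >= 0.5) {
          res <- hho_soft_dive(
            x, fitnesses[i], x_rabbit, E, J, objective, space, beta
          )
          positions[i, ] <- res$x
          fitnesses[i] <- res$f
        } else {
          x_m <- mean_position(positions)
          res <- hho_hard_dive(
            x, fitnesses[i], x_rabbit, x_m, E, J, objective, space, beta
          )
          positions[i, ] <- res$x
          fitnesses[i] <- res$f
        }
      }
      if (fitnesses[i] < f_rabbit) {
        f_rabbit <- fitnesses[i]
        x_rabbit <- positions[i, ]
      }
    }

    if (cs_refine) {
      ref <- cs_generation(positions, fitnesses, cs, objective, space)
      positions <- ref$positions
      fitnesses <- ref$fitnesses
      ib <- which.min(fitnesses)
      if (fitnesses[ib] < f_rabbit) {
        f_rabbit <- fitnesses[ib]
        x_rabbit <- positions[ib, ]
      }
    }

    trace[t] <- f_rabbit
  }

  list(
    best_position = x_rabbit, best_fitness = f_rabbit, trace = trace,
    positions = positions, fitnesses = fitnesses
  )
}

#' Run the baseline Harris hawks optimizer
#'
#' Minimizes `objective` over a box-bounded continuous search space with the
#' standard HHO control flow: a per-iteration escape energy
#' \eqn{E = 2 E_0 (1 - t/T)} with \eqn{E_0 \sim U(-1, 1)} dispatches each
#' hawk to exploration (\eqn{|E| \ge 1}), soft or hard besiege, or the
#' Levy-flight rapid-dive variants; the best-so-far prey is updated
#' elitistically so the convergence trace is monotone non-increasing.
#'
#' @param objective Function of a numeric position vector, minimized.
#' @param space A [search_space()].
#' @param n_agents Swarm size (default 30).
#' @param n_iter Iteration budget.
#' @param seed Optional integer seed for reproducibility.
#' @param beta Levy stability exponent for the dive steps (default 1.5).
#' @return A `hawk_opt` object: `best_position`, `best_fitness`, a tibble
#'   `trace` (iteration, best), the `optimizer` label and the `seed`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- hho_run(sphere, search_space(-5, 5, dim = 2), n_iter = 50, seed = 1)
#' res$best_fitness
#' @export
hho_run <- function(objective, space, n_agents = 30, n_iter = 100,
                    seed = NULL, beta = 1.5) {
  if (!is.null(seed)) set.seed(seed)
  eng <- hawk_engine(objective, space, n_agents, n_iter, beta = beta)
  new_hawk_opt(eng, "hho", n_agents, n_iter, seed)
}

new_hawk_opt <- function(eng, optimizer, n_agents, n_iter, seed) {
  structure(
    list(
      best_position = eng$best_position,
      best_fitness = eng$best_fitness,
      trace = tibble::tibble(
        iteration = seq_along(eng$trace),
        best = eng$trace
      ),
      optimizer = optimizer,
      n_agents = n_agents,
      n_iter = n_iter,
      seed = seed
    ),
    class = "hawk_opt"
  )
}

#' @export
print.hawk_opt <- function(x, ...) {
  cat("<hawk_opt> ", x$optimizer, ": ", x$n_agents, " agents, ",
    x$n_iter, " iterations\n",
    sep = ""
  )
  cat("  best fitness:", format(x$best_fitness), "\n")
  cat("  dimension:   ", length(x$best_position), "\n")
  invisible(x)
}
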