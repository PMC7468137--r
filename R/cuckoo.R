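#' Cuckoo search parameters
#'
#' @param pa Alien-egg discovery (abandonment) probability in \[0, 1\];
#'   default 0.25. Each generation the worst `floor(pa * n)` nests are
#'   rebuilt at fresh uniform-random positions.
#' @param step Levy step length; default 0.01.
#' @param beta Levy stability exponent; default 1.5.
#' @return A `cs_params` list.
#' @export
cs_params <- function(pa = 0.25, step = 0.01, beta = 1.5) {
  stopifnot(pa >= 0, pa <= 1, step > 0, beta > 0, beta <= 2)
  structure(list(pa = pa, step = step, beta = beta), class = "cs_params")
}

#' Propose a cuckoo egg by Levy flight
#'
#' Canonical cuckoo-search proposal: the nest takes a Levy-flight step scaled
#' by its distance from the best nest,
#' \eqn{x' = x + \alpha \, L \odot (x - x_{best})} with step length
#' \eqn{\alpha} and `L` a vector of Levy deviates. When the nest *is* the
#' best (the difference vanishes) a pure Levy perturbation
#' \eqn{x + \alpha L} is used instead so the best nest still explores.
#'
#' @param nest Current nest position.
#' @param best Best nest position.
#' @param params A [cs_params()].
#' @param space A [search_space()].
#' @return The proposed position, clipped to bounds.
#' @export
propose_cuckoo <- function(nest, best, params, space) {
  d <- length(nest)
  L <- levy_step(d, params$beta)
  diff <- nest - best
  step <- if (all(diff == 0)) params$step * L else params$step * L * diff
  clip_to_bounds(nest + step, space)
}

#' Replace a random nest if the candidate egg is better
#'
#' The cuckoo dumps its egg in a randomly selected nest; the egg survives
#' only if it strictly improves that nest's fitness (ties keep the
#' incumbent).
#'
#' @param positions Nest position matrix.
#' @param fitnesses Nest fitness vector (minimization).
#' @param j Index of the randomly selected host nest.
#' @param candidate Proposed position.
#' @param objective Objective function (minimized).
#' @return List with updated `positions` and `fitnesses`.
#' @export
greedy_replace <- function(positions, fitnesses, j, candidate, objective) {
  stopifnot(j >= 1, j <= nrow(positions))
  f_cand <- objective(candidate)
  if (f_cand < fitnesses[j]) {
    positions[j, ] <- candidate
    fitnesses[j] <- f_cand
  }
  list(positions = positions, fitnesses = fitnesses)
}

#' Abandon the worst nests
#'
#' A fraction `pa` of the nests is discovered and abandoned each generation:
#' the `floor(pa * n)` worst nests (never the best) are replaced with fresh
#' uniform-random positions and re-evaluated.
#'
#' @inheritParams greedy_replace
#' @param params A [cs_params()].
#' @param space A [search_space()].
#' @return List with updated `positions` and `fitnesses`.
#' @export
abandon_nests <- function(positions, fitnesses, params, objective, space) {
  n <- nrow(positions)
  k <- min(floor(params$pa * n), n - 1L)
  if (k < 1) {
    return(list(positions = positions, fitnesses = fitnesses))
  }
  worst <- order(fitnesses, decreasing = TRUE)[seq_len(k)]
  d <- space$dim
  for (j in worst) {
    fresh <- space$lower + stats::runif(d) * (space$upper - space$lower)
    positions[j, ] <- fresh
    fitnesses[j] <- objective(fresh)
  }
  list(positions = positions, fitnesses = fitnesses)
}

#' One cuckoo-search generation
#'
#' For each nest in turn, proposes a Levy-flight egg against the current best
#' nest and dumps it into a uniformly random host nest (strict-improvement
#' replacement), then abandons the worst `floor(pa * n)` nests. The best
#' nest's fitness never worsens.
#'
#' @inheritParams abandon_nests
#' @return List with updated `positions` and `fitnesses`.
#' @export
cs_generation <- function(positions, fitnesses, params, objective, space) {
  n <- nrow(positions)
  for (i in seq_len(n)) {
    best <- positions[which.min(fitnesses), ]
    cand <- propose_cuckoo(positions[i, ], best, params, space)
    j <- sample.int(n, 1L)
    upd <- greedy_replace(positions, fitnesses, j, cand, objective)
    positions <- upd$positions
    fitnesses <- upd$fitnesses
  }
  abandon_nests(positions, fitnesses, params, objective, space)
}

#' Run the standalone cuckoo-search optimizer
#'
#' Minimizes `objective` with generations of Levy-flight proposals, greedy
#' host-nest replacement and worst-nest abandonment.
#'
#' @inheritParams hho_run
#' @param params A [cs_params()].
#' @return A `hawk_opt` object (see [hho_run()]).
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- cs_run(sphere, search_space(-5, 5, dim = 2), n_iter = 50, seed = 1)
#' res$best_fitness
#' @export
cs_run <- function(objective, space, n_agents = 30, n_iter = 100,
                   seed = NULL, params = cs_params()) {
  if (!is.null(seed)) set.seed(seed)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  positions <- init_population(space, n_agents)
  fitnesses <- apply(positions, 1, objective)
  trace <- numeric(n_iter)
  for (t in seq_len(n_iter)) {
    gen <- cs_generation(positions, fitnesses, params, objective, space)
    positions <- gen$positions
    fitnesses <- gen$fitnesses
    trace[t] <- min(if (t > 1) trace[t - 1] else Inf, min(fitnesses))
  }
  ibest <- which.min(fitnesses)
  eng <- list(
    best_position = positions[ibest, ],
    best_fitness = trace[n_iter],
    trace = trace
  )
  new_hawk_opt(eng, "cs", n_agents, n_iter, seed)
}
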