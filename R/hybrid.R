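#' Chaotic escape-energy schedule
#'
#' Replaces the baseline uniform draw of the initial escape energy with a
#' chaotic iterate: the map state advances once per iteration, the normalized
#' value \eqn{c \in [0,1]} is mapped affinely to \eqn{E_0 = 2c - 1 \in
#' (-1,1)}, and the usual linear envelope gives \eqn{E = 2 E_0 (1 - t/T)}.
#' The schedule is non-linear in `t` because `c` varies chaotically, while
#' \eqn{|E| \le 2(1 - t/T)} always holds and \eqn{E(T) = 0} exactly.
#'
#' @param map A [chaotic_map()].
#' @param state Current chaotic state (list `x`, `k`).
#' @param t Current iteration (0 <= t <= T).
#' @param T_max Total iterations.
#' @return List with `E0`, `E` and the advanced `state`.
#' @export
chaotic_escape_energy <- function(map, state, t, T_max) {
  state <- chaos_step(map, state)
  E0 <- 2 * state$x - 1
  list(E0 = E0, E = escaping_energy(E0, t, T_max), state = state)
}

#' Cuckoo-search refinement of a hawk population
#'
#' Runs one cuckoo-search generation treating the hawks as nests. Individual
#' hawks improved by the Levy proposals (or resampled by abandonment)
#' re-enter the population — from which the exploration operator draws
#' \eqn{X_{rand}} — and if the refined best strictly improves on the prey,
#' the prey is updated; otherwise the incumbent stands.
#'
#' @param positions Hawk position matrix.
#' @param fitnesses Hawk fitness vector (minimization).
#' @param x_rabbit,f_rabbit Current prey (best-so-far) position and fitness.
#' @param cs A [cs_params()].
#' @param objective Objective function (minimized).
#' @param space A [search_space()].
#' @return List with updated `positions`, `fitnesses`, `x_rabbit`,
#'   `f_rabbit`.
#' @export
cs_refinement <- function(positions, fitnesses, x_rabbit, f_rabbit,
                          cs, objective, space) {
  gen <- cs_generation(positions, fitnesses, cs, objective, space)
  ib <- which.min(gen$fitnesses)
  if (gen$fitnesses[ib] < f_rabbit) {
    f_rabbit <- gen$fitnesses[ib]
    x_rabbit <- gen$positions[ib, ]
  }
  list(
    positions = gen$positions, fitnesses = gen$fitnesses,
    x_rabbit = x_rabbit, f_rabbit = f_rabbit
  )
}

#' Run the chaotic HHO / cuckoo-search hybrid
#'
#' The hybrid augments baseline HHO with three independently switchable
#' strategies: chaotic-map population initialization, a chaotic escape-energy
#' schedule (one chaotic draw per iteration, see
#' [chaotic_escape_energy()]), and a per-iteration cuckoo-search refinement
#' of the hawk population that may replace the prey ([cs_refinement()]).
#' With all three switches off the run is identical to [hho_run()] for the
#' same seed. The variant with only the chaotic switches off is the plain
#' HHO–CS hybrid.
#'
#' @inheritParams hho_run
#' @param map A [chaotic_map()] (default piecewise, the best-performing map).
#' @param cs A [cs_params()].
#' @param chaotic_init,chaotic_energy,cs_refine Logical switches for the
#'   three hybrid strategies (all `TRUE` by default).
#' @return A `hawk_opt` object (see [hho_run()]); the `optimizer` label is
#'   `"chho-cs-<map>"` (e.g. `"chho-cs-piecewise"`), `"hho-cs"` when both
#'   chaotic switches are off, or `"hho"` when all switches are off.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- chho_cs_run(sphere, search_space(-5, 5, dim = 2),
#'   n_iter = 50, seed = 1
#' )
#' res$best_fitness
#' @export
chho_cs_run <- function(objective, space, n_agents = 30, n_iter = 100,
                        seed = NULL, map = chaotic_map("piecewise"),
                        cs = cs_params(),
                        chaotic_init = TRUE, chaotic_energy = TRUE,
                        cs_refine = TRUE, beta = 1.5) {
  if (!is.null(seed)) set.seed(seed)
  eng <- hawk_engine(
    objective, space, n_agents, n_iter,
    chaotic_init = chaotic_init, chaotic_energy = chaotic_energy,
    cs_refine = cs_refine, map = map, cs = cs, beta = beta
  )
  label <- if (!chaotic_init && !chaotic_energy) {
    if (cs_refine) "hho-cs" else "hho"
  } else {
    paste0("chho-cs-", map$name)
  }
  new_hawk_opt(eng, label, n_agents, n_iter, seed)
}
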