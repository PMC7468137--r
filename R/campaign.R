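#' Run a seeded multi-run feature-selection campaign
#'
#' Executes `runs` independent seeded wrapper runs (seeds `seed`,
#' `seed + 1`, ...) per optimizer and aggregates the maximized fitness into
#' the Mean / Std / Best / Worst statistics, alongside the mean
#' classification metrics (reported as percentages). Deterministic given the
#' configuration.
#'
#' @inheritParams select_features
#' @param optimizers Character vector of optimizer names (see
#'   [select_features()]); summary rows keep this order.
#' @param runs Number of independent runs per optimizer; default 5.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param ... Further arguments passed to [select_features()] (e.g. `map`,
#'   `cs`, `alpha`, `beta`, `tau`).
#' @return A `hawk_campaign` object with a `summary` tibble (one row per
#'   optimizer: `mean`, `std`, `best`, `worst` fitness and mean metrics in
#'   percent), a `runs` tibble of per-run results, and the list of
#'   `hawk_fs` fits in `fits`.
#' @examples
#' \donttest{
#' d <- synth_descriptors(n_samples = 100, n_informative = 3, n_noise = 4,
#'   seed = 7)
#' cmp <- run_campaign(d, "class", optimizers = "hho", runs = 2,
#'   n_agents = 8, n_iter = 5, seed = 1)
#' cmp$summary
#' }
#' @export
run_campaign <- function(data, label = "class", optimizers = "chho-cs",
                         runs = 5, n_agents = 20, n_iter = 50, seed = 1,
                         ...) {
  stopifnot(runs >= 1)
  optimizers <- vapply(optimizers, check_optimizer, character(1),
    USE.NAMES = FALSE
  )
  fits <- list()
  rows <- list()
  for (opt in optimizers) {
    for (i in seq_len(runs)) {
      run_seed <- seed + i - 1L
      fit <- select_features(data, label,
        optimizer = opt, n_agents = n_agents,
        n_iter = n_iter, seed = run_seed, ...
      )
      fits[[length(fits) + 1L]] <- fit
      rows[[length(rows) + 1L]] <- tibble::tibble(
        optimizer = opt, run = i, seed = run_seed,
        fitness = fit$fitness,
        n_selected = length(fit$selected),
        accuracy = fit$report$accuracy,
        sensitivity = fit$report$sensitivity,
        specificity = fit$report$specificity,
        recall = fit$report$recall,
        precision = fit$report$precision,
        f_measure = fit$report$f_measure
      )
    }
  }
  per_run <- dplyr::bind_rows(rows)
  summary <- per_run |>
    dplyr::group_by(.data$optimizer) |>
    dplyr::summarise(
      runs = dplyr::n(),
      mean = mean(.data$fitness),
      std = stats::sd(.data$fitness),
      best = max(.data$fitness),
      worst = min(.data$fitness),
      mean_selected = mean(.data$n_selected),
      accuracy = 100 * mean(.data$accuracy),
      sensitivity = 100 * mean(.data$sensitivity),
      specificity = 100 * mean(.data$specificity),
      recall = 100 * mean(.data$recall),
      precision = 100 * mean(.data$precision),
      f_measure = 100 * mean(.data$f_measure),
      .groups = "drop"
    ) |>
    dplyr::mutate(std = ifelse(is.na(.data$std), 0, .data$std)) |>
    dplyr::arrange(match(.data$optimizer, optimizers))
  structure(
    list(summary = summary, runs = per_run, fits = fits, base_seed = seed),
    class = "hawk_campaign"
  )
}

#' @export
print.hawk_campaign <- function(x, ...) {
  cat("<hawk_campaign> ", nrow(x$runs), " runs, base seed ", x$base_seed,
    "\n\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' Export convergence traces
#'
#' Writes the per-iteration best objective value (internal minimization
#' scale, monotone non-increasing) of every run to a delimited file: one
#' column per run named `seed_<seed>`, one row per iteration. Reloading
#' reproduces the traces exactly.
#'
#' @param campaign A `hawk_campaign`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
export_convergence <- function(campaign, path) {
  stopifnot(length(campaign$fits) > 0)
  cols <- lapply(campaign$fits, function(f) f$trace$objective)
  names(cols) <- vapply(campaign$fits, function(f) {
    paste0("seed_", f$seed, "_", f$optimizer)
  }, character(1))
  names(cols) <- make.unique(names(cols))
  readr::write_csv(tibble::as_tibble(cols), path)
  invisible(path)
}

#' Export the campaign summary table
#'
#' Writes the Mean / Std / Best / Worst fitness statistics and the mean
#' classification metrics (percent) per optimizer, mirroring the standard
#' benchmark-table layout.
#'
#' @inheritParams export_convergence
#' @return `path`, invisibly.
#' @export
export_summary <- function(campaign, path) {
  stopifnot(nrow(campaign$summary) > 0)
  readr::write_csv(campaign$summary, path)
  invisible(path)
}
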