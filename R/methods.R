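#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an optimizer run into its convergence trace
#'
#' @param x A `hawk_opt` from [hho_run()], [cs_run()] or [chho_cs_run()].
#' @param ... Unused.
#' @return Tibble with `iteration` and `best` (best-so-far objective value,
#'   minimized).
#' @export
tidy.hawk_opt <- function(x, ...) {
  x$trace
}

#' One-row summary of an optimizer run
#'
#' @inheritParams tidy.hawk_opt
#' @return Tibble with `optimizer`, `best_fitness`, `dim`, `n_agents`,
#'   `n_iter`, `seed`.
#' @export
glance.hawk_opt <- function(x, ...) {
  tibble::tibble(
    optimizer = x$optimizer,
    best_fitness = x$best_fitness,
    dim = length(x$best_position),
    n_agents = x$n_agents,
    n_iter = x$n_iter,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Per-feature view of a selection fit
#'
#' @param x A `hawk_fs` from [select_features()].
#' @param ... Unused.
#' @return Tibble with one row per descriptor: `feature`, the continuous
#'   `position` coordinate and the binarized `selected` flag.
#' @export
tidy.hawk_fs <- function(x, ...) {
  tibble::tibble(
    feature = names(x$mask),
    position = unname(x$position),
    selected = unname(x$mask)
  )
}

#' One-row summary of a selection fit
#'
#' @inheritParams tidy.hawk_fs
#' @return Tibble with the optimizer label, maximized fitness, subset size,
#'   and the held-out classification metrics.
#' @export
glance.hawk_fs <- function(x, ...) {
  tibble::tibble(
    optimizer = x$optimizer,
    fitness = x$fitness,
    n_selected = length(x$selected),
    n_features = x$n_features,
    accuracy = x$report$accuracy,
    sensitivity = x$report$sensitivity,
    specificity = x$report$specificity,
    recall = x$report$recall,
    precision = x$report$precision,
    f_measure = x$report$f_measure,
    seed = x$seed
  )
}

#' Per-run view of a campaign
#'
#' @param x A `hawk_campaign` from [run_campaign()].
#' @param ... Unused.
#' @return The per-run tibble (`optimizer`, `run`, `seed`, fitness, subset
#'   size and metrics).
#' @export
tidy.hawk_campaign <- function(x, ...) {
  x$runs
}

#' Campaign summary statistics
#'
#' @inheritParams tidy.hawk_campaign
#' @return The summary tibble: Mean / Std / Best / Worst fitness and mean
#'   metrics (percent) per optimizer.
#' @export
glance.hawk_campaign <- function(x, ...) {
  x$summary
}

#' Long-format metrics of a classification report
#'
#' @param x A `hawk_report` from [evaluate_subset()].
#' @param ... Unused.
#' @return Tibble with `metric` and `value` columns.
#' @export
tidy.hawk_report <- function(x, ...) {
  m <- c(
    "accuracy", "sensitivity", "specificity", "recall",
    "precision", "f_measure"
  )
  tibble::tibble(metric = m, value = unlist(x[m], use.names = FALSE))
}

#' @rdname tidy.hawk_report
#' @export
glance.hawk_report <- function(x, ...) {
  confusion_metrics(x$confusion)
}

#' Convergence curve of an optimizer run
#'
#' @param object A `hawk_opt`.
#' @param ... Unused.
#' @return A ggplot of best-so-far objective value versus iteration.
#' @export
autoplot.hawk_opt <- function(object, ...) {
  ggplot2::ggplot(
    object$trace,
    ggplot2::aes(x = .data$iteration, y = .data$best)
  ) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Iteration", y = "Best objective value",
      title = paste0("Convergence (", object$optimizer, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Convergence curve of a feature-selection run
#'
#' @param object A `hawk_fs`.
#' @param ... Unused.
#' @return A ggplot of the maximized wrapper fitness versus iteration.
#' @export
autoplot.hawk_fs <- function(object, ...) {
  ggplot2::ggplot(
    object$trace,
    ggplot2::aes(x = .data$iteration, y = .data$fitness)
  ) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(
      x = "Iteration", y = "Wrapper fitness",
      title = paste0("Feature selection (", object$optimizer, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Convergence curves of all campaign runs
#'
#' @param object A `hawk_campaign`.
#' @param ... Unused.
#' @return A ggplot with one fitness curve per run, coloured by optimizer.
#' @export
autoplot.hawk_campaign <- function(object, ...) {
  traces <- purrr::map_dfr(object$fits, function(f) {
    dplyr::mutate(f$trace,
      optimizer = f$optimizer, seed = f$seed,
      run_id = paste(f$optimizer, f$seed, sep = "/")
    )
  })
  ggplot2::ggplot(
    traces,
    ggplot2::aes(
      x = .data$iteration, y = .data$fitness,
      group = .data$run_id, colour = .data$optimizer
    )
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(
      x = "Iteration", y = "Wrapper fitness",
      colour = "Optimizer"
    ) +
    ggplot2::theme_minimal()
}

#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"
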