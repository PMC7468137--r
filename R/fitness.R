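#' Binarize a continuous position into a feature mask
#'
#' Coordinates strictly above the threshold `tau` select the corresponding
#' feature. If no coordinate exceeds the threshold, the single largest
#' coordinate is selected so the mask is never empty.
#'
#' @param position Numeric vector in \eqn{[0,1]^C}.
#' @param tau Binarization threshold in (0, 1); default 0.5.
#' @return Logical vector of the same length.
#' @examples
#' binarize_position(c(0.2, 0.7, 0.5))
#' @export
binarize_position <- function(position, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  mask <- position > tau
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Wrapper fitness of a feature subset
#'
#' The selection objective balances classification performance against
#' subset size:
#' \deqn{fitness = \alpha \cdot accuracy + \beta \left(1 -
#'   \frac{|selected|}{C}\right)}
#' with \eqn{\alpha + \beta = 1} (defaults 0.99 / 0.01), maximized. The
#' optimizer cores minimize its negation.
#'
#' @param accuracy Held-out classification accuracy in \[0, 1\].
#' @param n_selected Number of selected features.
#' @param n_features Total number of features `C`.
#' @param alpha Accuracy weight; default 0.99.
#' @param beta Sparsity weight; default 0.01.
#' @return The scalar fitness in \[0, 1\].
#' @examples
#' fs_fitness(1, 1, 100) # near-perfect: high accuracy, tiny subset
#' @export
fs_fitness <- function(accuracy, n_selected, n_features,
                       alpha = 0.99, beta = 0.01) {
  stopifnot(n_selected >= 1, n_selected <= n_features)
  alpha * accuracy + beta * (1 - n_selected / n_features)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the report columns accuracy, sensitivity, specificity, recall,
#' precision and F-measure from a square confusion matrix (rows = truth,
#' columns = predicted). For two classes the first row/column is treated as
#' the positive class; with more classes each metric is computed one-vs-rest
#' per class and macro-averaged. Rates with a zero denominator are defined
#' as 0. Recall equals sensitivity by construction.
#'
#' @param confusion Square numeric matrix of non-negative counts.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `recall`, `precision`, `f_measure`, all in \[0, 1\].
#' @examples
#' confusion_metrics(matrix(c(40, 5, 10, 45), 2, 2))
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(
    nrow(confusion) == ncol(confusion),
    all(confusion >= 0)
  )
  total <- sum(confusion)
  k <- nrow(confusion)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  per_class <- function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, -i])
    fp <- sum(confusion[-i, i])
    tn <- total - tp - fn - fp
    sens <- safe_div(tp, tp + fn)
    spec <- safe_div(tn, tn + fp)
    prec <- safe_div(tp, tp + fp)
    f <- safe_div(2 * prec * sens, prec + sens)
    c(sensitivity = sens, specificity = spec, precision = prec, f_measure = f)
  }
  rates <- if (k == 2) {
    per_class(1)
  } else {
    rowMeans(vapply(seq_len(k), per_class, numeric(4)))
  }
  tibble::tibble(
    accuracy = safe_div(sum(diag(confusion)), total),
    sensitivity = rates[["sensitivity"]],
    specificity = rates[["specificity"]],
    recall = rates[["sensitivity"]],
    precision = rates[["precision"]],
    f_measure = rates[["f_measure"]]
  )
}

# SVM evaluation of a feature subset; returns the confusion matrix
# (rows = truth). folds >= 2 gives stratified k-fold cross-validation with
# confusions summed over folds; folds = 1 gives a stratified hold-out at
# split_ratio. RNG use is isolated so optimizer streams are untouched.
svm_eval <- function(x, y, mask, folds = 5, split_ratio = 0.8, seed = 1,
                     kernel = "radial", cost = 1, gamma = NULL) {
  x <- as.matrix(x)[, mask, drop = FALSE]
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit_fold <- function(idx_train, idx_test) {
    if (length(unique(y[idx_train])) < nlevels(y)) {
      stop("a class is absent from the training fold", call. = FALSE)
    }
    fit <- suppressWarnings(e1071::svm(
      x = x[idx_train, , drop = FALSE], y = y[idx_train],
      kernel = kernel, cost = cost, gamma = gamma, scale = TRUE
    ))
    pred <- stats::predict(fit, x[idx_test, , drop = FALSE])
    table(truth = y[idx_test], predicted = factor(pred, levels = levels(y)))
  }
  if (folds >= 2) {
    fold_id <- withr::with_seed(seed, stratified_folds(y, folds))
    confs <- lapply(seq_len(folds), function(k) {
      fit_fold(which(fold_id != k), which(fold_id == k))
    })
    Reduce(`+`, confs)
  } else {
    idx_train <- withr::with_seed(seed, stratified_indices(y, split_ratio))
    fit_fold(idx_train, setdiff(seq_along(y), idx_train))
  }
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold sizes differ by at most one sample per class.
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (ii in split(seq_along(y), y)) {
    if (length(ii) < folds) {
      stop("stratified ", folds, "-fold CV needs >= ", folds,
        " samples per class",
        call. = FALSE
      )
    }
    fold_id[sample(ii)] <- rep_len(seq_len(folds), length(ii))
  }
  fold_id
}

# Per-class sampled training indices preserving class proportions.
stratified_indices <- function(y, ratio) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ii) {
    if (length(ii) < 2) {
      stop("stratified split needs >= 2 samples per class", call. = FALSE)
    }
    n_tr <- max(1L, min(length(ii) - 1L, round(ratio * length(ii))))
    sample(ii, n_tr)
  }), use.names = FALSE)
  sort(idx)
}

#' Evaluate a feature subset with the SVM classifier
#'
#' Restricts the descriptor table to the selected columns, standardizes on
#' each training fold, trains an RBF-kernel support vector machine and
#' evaluates on the held-out samples. The default protocol is stratified
#' 5-fold cross-validation with the per-fold confusion matrices summed;
#' `folds = 1` switches to a single stratified hold-out split at
#' `split_ratio`. Defaults: `cost = 1`, `gamma = 1 / n_selected`.
#'
#' @param data A data frame / tibble of numeric descriptor columns plus one
#'   label column.
#' @param label Name of the label column.
#' @param features Character vector of feature names, or a logical mask over
#'   the feature columns (in `data`'s column order, label excluded). `NULL`
#'   selects all features.
#' @param folds Number of cross-validation folds (default 5); `1` uses a
#'   hold-out split instead.
#' @param split_ratio Training fraction in (0, 1) for the hold-out protocol;
#'   default 0.8.
#' @param seed Integer seed controlling the split (RNG state is restored
#'   afterwards).
#' @param kernel,cost,gamma SVM hyperparameters (see [e1071::svm()]);
#'   `gamma = NULL` uses `1 / n_selected`.
#' @return A `hawk_report` object: the confusion matrix plus the metric
#'   columns of [confusion_metrics()].
#' @examples
#' d <- synth_descriptors(n_samples = 80, seed = 1)
#' evaluate_subset(d, "class", attr(d, "informative"), seed = 1)
#' @export
evaluate_subset <- function(data, label = "class", features = NULL,
                            folds = 5, split_ratio = 0.8, seed = 1,
                            kernel = "radial", cost = 1, gamma = NULL) {
  ds <- as_fs_dataset(data, label)
  mask <- resolve_mask(features, colnames(ds$x))
  conf <- svm_eval(
    ds$x, ds$y, mask,
    folds = folds, split_ratio = split_ratio, seed = seed,
    kernel = kernel, cost = cost, gamma = gamma
  )
  new_hawk_report(conf)
}

resolve_mask <- function(features, feature_names) {
  c_total <- length(feature_names)
  if (is.null(features)) {
    return(rep(TRUE, c_total))
  }
  if (is.logical(features)) {
    stopifnot(length(features) == c_total)
    mask <- features
  } else {
    bad <- setdiff(features, feature_names)
    if (length(bad)) {
      stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    mask <- feature_names %in% features
  }
  if (!any(mask)) stop("empty feature subset", call. = FALSE)
  mask
}

new_hawk_report <- function(confusion) {
  structure(
    c(list(confusion = confusion), as.list(confusion_metrics(confusion))),
    class = "hawk_report"
  )
}

#' @export
print.hawk_report <- function(x, ...) {
  cat("<hawk_report>\n")
  print(x$confusion)
  m <- unlist(x[c(
    "accuracy", "sensitivity", "specificity", "recall",
    "precision", "f_measure"
  )])
  cat("\n")
  print(round(m, 4))
  invisible(x)
}

# Build the (minimized) wrapper objective over [0,1]^C: binarize, evaluate
# the subset with the SVM, negate the fitness. Mask-level results are
# memoized — the fold assignment is fixed per run so a mask's fitness is a
# constant. Evaluation failures score as worst (accuracy 0).
make_fs_objective <- function(x, y, alpha = 0.99, beta = 0.01, tau = 0.5,
                              folds = 5, split_ratio = 0.8, seed = 1,
                              kernel = "radial", cost = 1, gamma = NULL) {
  cache <- new.env(parent = emptyenv())
  c_total <- ncol(x)
  function(position) {
    mask <- binarize_position(position, tau)
    key <- paste0("m", paste(which(mask), collapse = "_"))
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    acc <- tryCatch(
      {
        conf <- svm_eval(x, y, mask,
          folds = folds, split_ratio = split_ratio, seed = seed,
          kernel = kernel, cost = cost, gamma = gamma
        )
        sum(diag(conf)) / sum(conf)
      },
      error = function(e) 0
    )
    val <- -fs_fitness(acc, sum(mask), c_total, alpha, beta)
    assign(key, val, envir = cache)
    val
  }
}

#' Wrapper feature selection with the hybrid metaheuristic
#'
#' Searches the continuous cube \eqn{[0,1]^C} (one coordinate per descriptor
#' column, binarized at `tau`) for the feature subset maximizing
#' \eqn{\alpha \cdot accuracy + \beta (1 - |selected|/C)}, where accuracy is
#' the held-out accuracy of an RBF-SVM trained on the selected columns.
#'
#' @inheritParams evaluate_subset
#' @param optimizer One of `"chho-cs"` (default), `"hho-cs"`, `"hho"`,
#'   `"cs"`. The baseline names `"pso"`, `"mfo"`, `"gwo"`, `"ssa"`, `"sca"`
#'   are reserved for the pluggable comparison interface and error if
#'   requested.
#' @param n_agents Swarm size; default 20.
#' @param n_iter Iteration budget; default 50.
#' @param seed Integer seed for the whole run (search and split).
#' @param map A [chaotic_map()] for the chaotic variants; default piecewise.
#' @param cs A [cs_params()].
#' @param alpha,beta Fitness weights (defaults 0.99 / 0.01).
#' @param tau Binarization threshold; default 0.5.
#' @return A `hawk_fs` object: the selected feature names and logical
#'   `mask`, the final `position`, the maximized `fitness`, the held-out
#'   `report` ([evaluate_subset()]) for the selected subset, the
#'   per-iteration `trace` (tibble with the minimized `objective` and the
#'   re-negated `fitness`), plus run metadata. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' d <- synth_descriptors(n_samples = 120, n_informative = 3, n_noise = 5,
#'   seed = 1)
#' fit <- select_features(d, "class", n_agents = 10, n_iter = 10, seed = 1)
#' glance(fit)
#' }
#' @export
select_features <- function(data, label = "class",
                            optimizer = c("chho-cs", "hho-cs", "hho", "cs"),
                            n_agents = 20, n_iter = 50, seed = 1,
                            map = chaotic_map("piecewise"), cs = cs_params(),
                            alpha = 0.99, beta = 0.01, tau = 0.5,
                            folds = 5, split_ratio = 0.8,
                            kernel = "radial", cost = 1, gamma = NULL) {
  optimizer <- check_optimizer(optimizer)
  ds <- as_fs_dataset(data, label)
  c_total <- ncol(ds$x)
  space <- search_space(0, 1, dim = c_total)
  objective <- make_fs_objective(
    ds$x, ds$y,
    alpha = alpha, beta = beta, tau = tau,
    folds = folds, split_ratio = split_ratio, seed = seed,
    kernel = kernel, cost = cost, gamma = gamma
  )
  run <- switch(optimizer,
    "chho-cs" = chho_cs_run(objective, space, n_agents, n_iter,
      seed = seed, map = map, cs = cs
    ),
    "hho-cs" = chho_cs_run(objective, space, n_agents, n_iter,
      seed = seed, map = map, cs = cs,
      chaotic_init = FALSE, chaotic_energy = FALSE
    ),
    "hho" = hho_run(objective, space, n_agents, n_iter, seed = seed),
    "cs" = cs_run(objective, space, n_agents, n_iter,
      seed = seed, params = cs
    )
  )
  mask <- binarize_position(run$best_position, tau)
  report <- evaluate_subset(data, label,
    features = mask, folds = folds, split_ratio = split_ratio,
    seed = seed, kernel = kernel, cost = cost, gamma = gamma
  )
  structure(
    list(
      selected = colnames(ds$x)[mask],
      mask = stats::setNames(mask, colnames(ds$x)),
      position = stats::setNames(run$best_position, colnames(ds$x)),
      fitness = -run$best_fitness,
      report = report,
      trace = dplyr::mutate(run$trace,
        objective = .data$best, fitness = -.data$best, best = NULL
      ),
      optimizer = run$optimizer,
      n_features = c_total,
      n_agents = n_agents,
      n_iter = n_iter,
      alpha = alpha,
      beta = beta,
      tau = tau,
      seed = seed,
      label = label
    ),
    class = "hawk_fs"
  )
}

reserved_baselines <- c("pso", "mfo", "gwo", "ssa", "sca")

check_optimizer <- function(optimizer) {
  valid <- c("chho-cs", "hho-cs", "hho", "cs")
  optimizer <- optimizer[1]
  if (optimizer %in% reserved_baselines) {
    stop("optimizer '", optimizer,
      "' is not implemented - pluggable interface only",
      call. = FALSE
    )
  }
  if (!optimizer %in% valid) {
    stop("unknown optimizer '", optimizer, "'; valid names: ",
      paste(valid, collapse = ", "),
      call. = FALSE
    )
  }
  optimizer
}

#' @export
print.hawk_fs <- function(x, ...) {
  cat("<hawk_fs> ", x$optimizer, ": ", length(x$selected), "/",
    x$n_features, " features selected\n",
    sep = ""
  )
  cat("  fitness:  ", format(round(x$fitness, 6)), "\n")
  cat("  accuracy: ", format(round(x$report$accuracy, 4)), "\n")
  cat("  selected: ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
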