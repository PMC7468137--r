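# Internal canonical form: numeric feature matrix + factor labels.
as_fs_dataset <- function(data, label) {
  stopifnot(is.data.frame(data))
  if (!label %in% names(data)) {
    stop("label column '", label, "' not found", call. = FALSE)
  }
  y <- droplevels(factor(data[[label]], levels = unique(data[[label]])))
  feats <- data[setdiff(names(data), label)]
  if (ncol(feats) < 1) stop("no feature columns", call. = FALSE)
  not_num <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(not_num)) {
    stop("non-numeric feature column(s): ", paste(not_num, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(table(y) < 2)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  list(x = as.matrix(feats), y = y)
}

#' Generate a synthetic descriptor table with known informative columns
#'
#' Emulates a QSAR-style compound-by-descriptor table for verifying
#' selection quality without external downloads: a binary activity label,
#' `n_informative` descriptor columns whose class-conditional means differ
#' by `effect_size` within-class standard deviations, and `n_noise` columns
#' of standard normal noise independent of the class.
#'
#' @param n_samples Number of compounds (rows); default 200.
#' @param n_informative Number of class-informative descriptors; default 5.
#' @param n_noise Number of pure-noise descriptors; default 15.
#' @param effect_size Between-class mean shift in the informative columns,
#'   in units of the within-class standard deviation; default 2.
#' @param class_balance Proportion of the positive (`"active"`) class;
#'   default 0.5.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A tibble with descriptor columns `f01`, `f02`, ... and a factor
#'   `class` column (`"active"` / `"inactive"`). The names of the truly
#'   informative columns are attached as `attr(, "informative")`.
#' @examples
#' d <- synth_descriptors(n_samples = 50, seed = 1)
#' attr(d, "informative")
#' @export
synth_descriptors <- function(n_samples = 200, n_informative = 5,
                              n_noise = 15, effect_size = 2,
                              class_balance = 0.5, seed = NULL) {
  stopifnot(
    n_informative >= 1, n_noise >= 0, effect_size >= 0,
    class_balance > 0, class_balance < 1, n_samples >= 8
  )
  gen <- function() {
    n_pos <- round(n_samples * class_balance)
    y <- factor(
      rep(c("active", "inactive"), c(n_pos, n_samples - n_pos)),
      levels = c("active", "inactive")
    )
    shift <- ifelse(y == "active", effect_size / 2, -effect_size / 2)
    p <- n_informative + n_noise
    x <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    x[, seq_len(n_informative)] <-
      x[, seq_len(n_informative), drop = FALSE] + shift
    colnames(x) <- sprintf("f%02d", seq_len(p))
    out <- tibble::as_tibble(as.data.frame(x))
    out$class <- y
    attr(out, "informative") <- colnames(x)[seq_len(n_informative)]
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Read a descriptor table from a delimited file
#'
#' Loads a compound-by-descriptor table (header row required; one row per
#' compound, numeric descriptor columns, one label column). Feature columns
#' are coerced to numeric; a non-numeric cell is an error naming its row and
#' column. Rows with missing values are dropped with a message giving the
#' count.
#'
#' @param path Path to the delimited file.
#' @param label Name of the label column; default `"class"`.
#' @param delimiter Field delimiter; default `","`.
#' @return A tibble of numeric descriptor columns plus the factor label
#'   column.
#' @export
read_descriptor_table <- function(path, label = "class", delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path,
    delim = delimiter, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!label %in% names(raw)) {
    stop("label column '", label, "' not found in ", path, call. = FALSE)
  }
  feat_names <- setdiff(names(raw), label)
  for (nm in feat_names) {
    v <- raw[[nm]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", v[bad[1]], "' in column '", nm,
        "', row ", bad[1],
        call. = FALSE
      )
    }
    raw[[nm]] <- num
  }
  complete <- stats::complete.cases(raw)
  if (any(!complete)) {
    message("dropping ", sum(!complete), " row(s) with missing values")
    raw <- raw[complete, ]
  }
  raw[[label]] <- factor(raw[[label]], levels = unique(raw[[label]]))
  tibble::as_tibble(raw)
}

#' Write a descriptor table to CSV
#'
#' Round-trip companion of [read_descriptor_table()]: values survive a
#' write/read cycle to full double precision.
#'
#' @param data Descriptor tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Split a dataset into training and test partitions
#'
#' Disjoint, exhaustive partition; with `stratified = TRUE` class
#' proportions are preserved within one sample per class.
#'
#' @param data Descriptor tibble with a label column.
#' @param label Name of the label column; default `"class"`.
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param stratified Preserve class proportions; default `TRUE`.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, label = "class", ratio = 0.8,
                          stratified = TRUE, seed = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  y <- factor(data[[label]])
  pick <- function() {
    if (stratified) {
      stratified_indices(y, ratio)
    } else {
      sort(sample(nrow(data), round(ratio * nrow(data))))
    }
  }
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  list(train = data[idx, ], test = data[-idx, ])
}
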