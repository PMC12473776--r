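#' Labeled multivariate time series
#'
#' A `series_matrix` holds one multivariate series as a numeric matrix with
#' one row per time step and one column per sensor/variable, together with a
#' single class label inherited by every window cut from it.
#'
#' @param values Numeric matrix (`T` time steps x `v` variables), `v >= 2`,
#'   no missing entries.
#' @param label Class label (length-1 atomic).
#' @param variable_names Optional character vector of `v` unique names;
#'   defaults to the column names of `values` or `V1..Vv`.
#' @return An object of class `series_matrix`.
#' @export
series_matrix <- function(values, label, variable_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("series must have at least one time step")
  if (ncol(values) < 2L) stop("series must have at least two variables")
  if (anyNA(values)) stop("series contains missing values")
  if (length(label) != 1L) stop("label must be length 1")
  if (is.null(variable_names)) {
    variable_names <- colnames(values)
    if (is.null(variable_names)) variable_names <- paste0("V", seq_len(ncol(values)))
  }
  if (length(variable_names) != ncol(values) || anyDuplicated(variable_names))
    stop("variable_names must be unique and match the number of columns")
  colnames(values) <- variable_names
  structure(list(values = values, label = label,
                 variable_names = variable_names),
            class = "series_matrix")
}

#' Sliding-window configuration
#'
#' @param t Window length in time steps.
#' @param s Step (stride) in time steps between consecutive window starts.
#' @return An object of class `window_config`.
#' @export
window_config <- function(t, s) {
  t <- as.integer(t); s <- as.integer(s)
  if (is.na(t) || t < 1L) stop("window length t must be >= 1")
  if (is.na(s) || s < 1L) stop("step s must be >= 1")
  structure(list(t = t, s = s), class = "window_config")
}

#' Construct a windowed dataset
#'
#' Container for a stack of equally shaped windows: an `N x t x v` array of
#' values, `N` labels and per-window provenance (source series id and start
#' offset). Each window is a single-channel `(1, t, v)` input to the models;
#' the channel axis is implicit.
#'
#' @param windows Numeric array `N x t x v`.
#' @param labels Vector of `N` class labels.
#' @param provenance Data frame with columns `series_id`, `start` (1-based
#'   time step of the first row of each window).
#' @return An object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(windows, labels, provenance = NULL) {
  if (length(dim(windows)) != 3L) stop("windows must be an N x t x v array")
  n <- dim(windows)[1L]
  if (length(labels) != n) stop("labels must match the number of windows")
  if (is.null(provenance))
    provenance <- data.frame(series_id = rep(NA_character_, n),
                             start = rep(NA_integer_, n))
  if (nrow(provenance) != n) stop("provenance must have one row per window")
  structure(list(windows = windows, labels = labels, provenance = provenance),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<windowed_dataset> %d windows of %d x %d, %d classes\n",
              d[1L], d[2L], d[3L], length(unique(x$labels))))
  invisible(x)
}

#' Number of windows in a windowed dataset
#' @param x A `windowed_dataset`.
#' @return Integer count.
#' @export
n_windows <- function(x) dim(x$windows)[1L]

#' Segment a series into fixed-length windows
#'
#' Cuts a length-`T` series into `floor((T - t)/s) + 1` windows of `t`
#' consecutive time steps, advancing the start by `s` steps each time.
#' Window `m` covers steps `1 + (m-1)s` to `t + (m-1)s`; trailing steps
#' that do not fill a complete window are dropped. Every window inherits
#' the parent series label.
#'
#' @param series A [series_matrix()].
#' @param cfg A [window_config()].
#' @param series_id Identifier recorded in the provenance (default "s1").
#' @return A [windowed_dataset()].
#' @export
slide_windows <- function(series, cfg, series_id = "s1") {
  stopifnot(inherits(series, "series_matrix"), inherits(cfg, "window_config"))
  Tlen <- nrow(series$values)
  v <- ncol(series$values)
  if (cfg$t > Tlen) stop("window length t exceeds series length T")
  n <- (Tlen - cfg$t) %/% cfg$s + 1L
  starts <- 1L + (seq_len(n) - 1L) * cfg$s
  w <- array(0, dim = c(n, cfg$t, v))
  for (m in seq_len(n))
    w[m, , ] <- series$values[starts[m]:(starts[m] + cfg$t - 1L), ]
  windowed_dataset(w, rep(series$label, n),
                   data.frame(series_id = rep(series_id, n), start = starts))
}

#' Concatenate windowed datasets
#'
#' @param datasets List of `windowed_dataset` objects sharing window shape.
#' @return A single [windowed_dataset()]; counts add, provenance preserved.
#' @export
stack_sources <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  if (length(datasets) == 1L) return(datasets[[1L]])
  shapes <- vapply(datasets, function(d) dim(d$windows)[2:3], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("all datasets must share window shape (t, v)")
  ns <- vapply(datasets, n_windows, integer(1))
  tot <- sum(ns)
  w <- array(0, dim = c(tot, shapes[1, 1], shapes[2, 1]))
  off <- 0L
  for (d in datasets) {
    idx <- off + seq_len(n_windows(d))
    w[idx, , ] <- d$windows
    off <- off + n_windows(d)
  }
  windowed_dataset(w, unlist(lapply(datasets, `[[`, "labels"), use.names = FALSE),
                   do.call(rbind, lapply(datasets, `[[`, "provenance")))
}

#' Subset a windowed dataset by window index
#' @param x A `windowed_dataset`.
#' @param idx Integer indices of windows to keep.
#' @return A [windowed_dataset()] with the selected windows.
#' @export
subset_windows <- function(x, idx) {
  windowed_dataset(x$windows[idx, , , drop = FALSE], x$labels[idx],
                   x$provenance[idx, , drop = FALSE])
}

#' Stratified train/validation/test split
#'
#' Splits a windowed dataset into three disjoint, exhaustive parts with the
#' given proportions, stratified by class: within each class the validation
#' and test counts are floor-rounded and the remainder goes to the training
#' split. The assignment is a seeded random permutation within class.
#'
#' @param dataset A [windowed_dataset()].
#' @param fractions Numeric length 3 (train, validation, test); must sum to 1.
#' @param seed Integer seed for the permutation.
#' @return Named list `train`, `validation`, `test` of windowed datasets.
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) || any(fractions > 1))
    stop("fractions must be three proportions in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  labs <- dataset$labels
  idx_tr <- idx_va <- idx_te <- integer(0)
  set.seed(as.integer(seed))
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_va <- floor(n * fractions[2L])
    n_te <- floor(n * fractions[3L])
    n_tr <- n - n_va - n_te
    idx_tr <- c(idx_tr, idx[seq_len(n_tr)])
    if (n_va > 0) idx_va <- c(idx_va, idx[n_tr + seq_len(n_va)])
    if (n_te > 0) idx_te <- c(idx_te, idx[n_tr + n_va + seq_len(n_te)])
  }
  list(train = subset_windows(dataset, sort(idx_tr)),
       validation = subset_windows(dataset, sort(idx_va)),
       test = subset_windows(dataset, sort(idx_te)))
}

#' Read a delimited series file
#'
#' Reads a plain-text multivariate series (one row per time step, one column
#' per sensor; comma or tab separated, optional header). The label is given
#' explicitly or taken from a designated label column (constant per series).
#'
#' @param path File path.
#' @param label Class label for the whole series (ignored when
#'   `label_column` is given).
#' @param sep Field separator; `NULL` auto-detects comma vs tab.
#' @param header Logical; does the first row hold column names?
#' @param label_column Optional name or index of a label column.
#' @param columns Optional character vector giving the variable column order
#'   to use (for sources whose on-disk order is ambiguous).
#' @return A [series_matrix()].
#' @export
read_series <- function(path, label = NULL, sep = NULL, header = FALSE,
                        label_column = NULL, columns = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (!is.null(label_column)) {
    label <- unique(df[[label_column]])
    if (length(label) != 1L) stop("label column is not constant in ", path)
    df[[label_column]] <- NULL
  }
  if (is.null(label)) stop("no label supplied for ", path)
  if (!is.null(columns)) df <- df[, columns, drop = FALSE]
  series_matrix(as.matrix(df), label)
}

#' Read a set of labeled series via a manifest
#'
#' The manifest is a two-column delimited file (`file,label`) mapping series
#' files (relative to the manifest directory) to class labels.
#'
#' @param manifest_path Path to the manifest file.
#' @param ... Passed to [read_series()].
#' @return List of [series_matrix()] objects.
#' @export
read_series_manifest <- function(manifest_path, ...) {
  man <- utils::read.table(manifest_path, sep = ",", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("file", "label") %in% names(man)))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i)
    read_series(file.path(base, man$file[i]), label = man$label[i], ...))
}

#' Persist a windowed dataset
#'
#' Writes the window array and labels to an R-native archive (`.rds`) with a
#' JSON provenance sidecar (`<path>.json`).
#'
#' @param x A [windowed_dataset()].
#' @param path Output path (conventionally ending in `.rds`).
#' @return `path`, invisibly.
#' @export
write_windowed <- function(x, path) {
  stopifnot(inherits(x, "windowed_dataset"))
  saveRDS(list(windows = x$windows, labels = x$labels), path)
  jsonlite::write_json(x$provenance, paste0(path, ".json"), dataframe = "rows")
  invisible(path)
}

#' Read a windowed dataset written by [write_windowed()]
#' @param path Path passed to [write_windowed()].
#' @return A [windowed_dataset()].
#' @export
read_windowed <- function(path) {
  obj <- readRDS(path)
  side <- paste0(path, ".json")
  prov <- if (file.exists(side))
    as.data.frame(jsonlite::read_json(side, simplifyVector = TRUE)) else NULL
  windowed_dataset(obj$windows, obj$labels, prov)
}
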