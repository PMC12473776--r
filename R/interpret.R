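#' Extract flattened feature vectors from a trained model
#'
#' Runs the forward pass up to (and excluding) the classification head and
#' returns one flattened feature row per window, with the producing model's
#' block index attached. Extraction is done in batches; the result is
#' independent of the batch partitioning.
#'
#' @param model A trained [incnn_init()] model.
#' @param data A [windowed_dataset()] (or `N x t x v` array).
#' @param batch_size Extraction batch size (memory knob only).
#' @return An object of class `feature_table`: list with `features`
#'   (`N x F` matrix), `labels` (or NULL), `block_index`.
#' @export
extract_features <- function(model, data, batch_size = 512L) {
  X <- if (inherits(data, "windowed_dataset")) data$windows else data
  if (length(dim(X)) != 3L) stop("data must be an N x t x v array")
  if (dim(X)[2L] != model$arch$t || dim(X)[3L] != model$arch$v)
    stop("window shape (", dim(X)[2L], ",", dim(X)[3L],
         ") does not match the architecture (", model$arch$t, ",", model$arch$v, ")")
  N <- dim(X)[1L]
  Fdim <- attr(model$block_index, "n_features")
  out <- matrix(0, N, Fdim)
  for (b0 in seq(1L, N, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, N)
    out[idx, ] <- .forward(model, X[idx, , , drop = FALSE])$features
  }
  structure(list(features = out,
                 labels = if (inherits(data, "windowed_dataset")) data$labels,
                 block_index = model$block_index),
            class = "feature_table")
}

#' Tree-ensemble configuration
#'
#' @param n_trees Number of trees (paper settings: 100).
#' @param max_depth Maximum tree depth (10 for the simulation study, 20 for
#'   the activity-recognition study).
#' @param seed Integer seed.
#' @param mtry Features tried per split; default `floor(sqrt(F))`.
#' @param bootstrap Bootstrap-resample per tree (default TRUE).
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 100L, max_depth = 10L, seed = 1L,
                            mtry = NULL, bootstrap = TRUE) {
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (max_depth < 1L) stop("max_depth must be >= 1")
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 seed = as.integer(seed),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 bootstrap = isTRUE(bootstrap)),
            class = "ensemble_config")
}

#' Fit the interpretable ensemble on a feature table
#'
#' Fits a seeded random forest (CART/Gini) and returns per-node (that is,
#' per flattened-feature) mean-decrease-in-impurity importances normalized
#' to sum 1.
#'
#' @param table A [extract_features()] table, or a plain matrix (then
#'   `labels` must be given).
#' @param cfg An [ensemble_config()].
#' @param labels Class labels when `table` is a matrix.
#' @return An object of class `incnn_forest`: list `forest`, `importances`
#'   (length F, sums to 1), `class_levels`, `block_index` (may be NULL),
#'   `cfg`.
#' @export
fit_interpretable <- function(table, cfg = ensemble_config(), labels = NULL) {
  if (inherits(table, "feature_table")) {
    X <- table$features
    labels <- if (is.null(labels)) table$labels else labels
    index <- table$block_index
  } else {
    X <- as.matrix(table)
    index <- NULL
  }
  if (is.null(labels)) stop("labels are required")
  levels <- sort(unique(labels))
  if (length(levels) < 2L) stop("need at least 2 classes to fit a classifier")
  y <- match(labels, levels) - 1L
  mtry <- if (!is.null(cfg$mtry)) cfg$mtry else max(1L, floor(sqrt(ncol(X))))
  set.seed(cfg$seed)
  fit <- .rf_fit_cpp(X, as.integer(y), length(levels), cfg$n_trees,
                     cfg$max_depth, mtry, cfg$bootstrap)
  imp <- as.numeric(fit$importance)
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  structure(list(forest = fit, importances = imp, class_levels = levels,
                 block_index = index, cfg = cfg),
            class = "incnn_forest")
}

#' Predict with a fitted interpretable ensemble
#' @param object An `incnn_forest` from [fit_interpretable()].
#' @param newdata Feature matrix or [extract_features()] table.
#' @param ... Unused.
#' @return Predicted class labels (majority vote).
#' @export
predict.incnn_forest <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$features else as.matrix(newdata)
  cls <- .rf_predict_cpp(object$forest, X, length(object$class_levels)) + 1L
  object$class_levels[cls]
}

#' Aggregate per-node importances into block scores
#'
#' Sums the per-feature importances over the contiguous feature block of
#' each individual variable and each variable pair. With node importances
#' normalized to sum 1, the block scores also sum to 1 (conservation).
#'
#' @param importances Numeric vector of per-feature importances.
#' @param index A [feature_block_index()].
#' @param accuracy Optional classifier test accuracy to record.
#' @return An object of class `importance_report`: data frame with columns
#'   `entity`, `kind`, `var1`, `var2`, `score`, `rank` (pairs ranked
#'   descending, ties broken lexicographically by `(var1, var2)`).
#' @export
aggregate_block_importance <- function(importances, index, accuracy = NULL) {
  if (length(importances) != attr(index, "n_features"))
    stop("importance length ", length(importances),
         " does not match the block index (", attr(index, "n_features"), ")")
  score <- vapply(seq_len(nrow(index)), function(b)
    sum(importances[index$start[b]:index$end[b]]), numeric(1))
  rep <- data.frame(entity = block_labels(index), kind = index$kind,
                    var1 = index$var1, var2 = index$var2, score = score)
  is_pair <- rep$kind == "pair"
  rnk <- rep(NA_integer_, nrow(rep))
  if (any(is_pair)) {
    p <- rep[is_pair, ]
    ord <- order(-p$score, p$var1, p$var2)
    rnk[which(is_pair)[ord]] <- seq_len(sum(is_pair))
  }
  rep$rank <- rnk
  attr(rep, "accuracy") <- accuracy
  class(rep) <- c("importance_report", "data.frame")
  rep
}

#' @export
print.importance_report <- function(x, ...) {
  if (!all(c("kind", "score") %in% names(x))) return(NextMethod())
  cat("<importance_report>\n")
  print.data.frame(x[order(x$kind, -x$score), ], row.names = FALSE)
  if (!is.null(attr(x, "accuracy")))
    cat(sprintf("classifier test accuracy: %.3f\n", attr(x, "accuracy")))
  invisible(x)
}

#' Rank pairwise interactions by importance
#'
#' @param report An [aggregate_block_importance()] report.
#' @param top_k How many pairs to return (clamped to the pair count).
#' @return Data frame of the top pairs, descending by score, ties broken
#'   lexicographically by `(var1, var2)`.
#' @export
rank_interactions <- function(report, top_k = Inf) {
  p <- report[report$kind == "pair", , drop = FALSE]
  p <- p[order(p$rank), , drop = FALSE]
  utils::head(p, min(top_k, nrow(p)))
}

#' Write an importance report to CSV and JSON
#' @param report An [aggregate_block_importance()] report.
#' @param path Output path stem; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_importance_report <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(report = df, accuracy = attr(report, "accuracy")),
                       paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(path)
}

#' Permutation importance (alternative to MDI)
#'
#' Mean drop in ensemble accuracy when one feature column is permuted;
#' offered as a model-agnostic cross-check of the MDI scores. Not used by
#' the experiment harnesses.
#'
#' @param fit An [fit_interpretable()] ensemble.
#' @param table Feature table (or matrix) with labels.
#' @param labels Labels when `table` is a matrix.
#' @param n_repeats Permutations per feature.
#' @param seed Integer seed.
#' @return Numeric vector of length F (non-negative values clipped at 0).
#' @export
permutation_importance <- function(fit, table, labels = NULL, n_repeats = 3L,
                                   seed = 1L) {
  X <- if (inherits(table, "feature_table")) table$features else as.matrix(table)
  labels <- if (is.null(labels) && inherits(table, "feature_table"))
    table$labels else labels
  base <- mean(predict(fit, X) == labels)
  set.seed(seed)
  out <- numeric(ncol(X))
  for (f in seq_len(ncol(X))) {
    drop_f <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      Xp <- X
      Xp[, f] <- Xp[sample.int(nrow(X)), f]
      drop_f[r] <- base - mean(predict(fit, Xp) == labels)
    }
    out[f] <- max(0, mean(drop_f))
  }
  out
}
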