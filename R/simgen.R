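#' Simulation specification for pairwise-interaction datasets
#'
#' Describes one synthetic dataset: `n_vars` independent Uniform(-1, 1)
#' variables, a dependent variable equal to the product of one chosen pair,
#' min-max normalization of the product over the whole pool followed by
#' binning into five classes (edges 0, .2, .4, .6, .8, 1), and assembly of
#' same-class rows into `rows_per_matrix x n_vars` matrices.
#'
#' @param causal_pair Integer pair `c(a, b)`, `a < b`: variables whose
#'   product drives the class.
#' @param n_vars Number of independent variables (default 5).
#' @param n_raw Raw-sample pool size drawn before binning (default 60000;
#'   the product distribution concentrates in the middle bins, so the pool
#'   must be much larger than the balanced matrix count).
#' @param bins Class edges on the normalized product (default
#'   `c(0, .2, .4, .6, .8, 1)`; bins are half-open on the right except the
#'   last, which includes 1).
#' @param rows_per_matrix Rows per assembled matrix (default 5).
#' @param n_matrices Total matrices to assemble when balancing (default
#'   2000); must be divisible by the class count.
#' @param balance Down-sample classes to equal matrix counts (default TRUE).
#' @param seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(causal_pair = c(1L, 2L), n_vars = 5L,
                            n_raw = 60000L, bins = c(0, .2, .4, .6, .8, 1),
                            rows_per_matrix = 5L, n_matrices = 2000L,
                            balance = TRUE, seed = 1L) {
  causal_pair <- as.integer(causal_pair)
  if (length(causal_pair) != 2L || causal_pair[1L] >= causal_pair[2L] ||
      causal_pair[1L] < 1L || causal_pair[2L] > n_vars)
    stop("causal_pair must satisfy 1 <= a < b <= n_vars")
  n_classes <- length(bins) - 1L
  if (n_raw < rows_per_matrix * n_classes)
    stop("n_raw too small for even one matrix per class")
  structure(list(causal_pair = causal_pair, n_vars = as.integer(n_vars),
                 n_raw = as.integer(n_raw), bins = bins,
                 rows_per_matrix = as.integer(rows_per_matrix),
                 n_matrices = as.integer(n_matrices),
                 n_classes = n_classes, balance = isTRUE(balance),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw the raw sample pool
#'
#' `n_raw` iid rows of `n_vars` Uniform(-1, 1) variables with the dependent
#' variable `y = x_a * x_b`.
#'
#' @param spec A [simulation_spec()].
#' @return Data frame with columns `x1..xv` and `y`.
#' @export
generate_raw_pool <- function(spec) {
  set.seed(spec$seed)
  X <- matrix(stats::runif(spec$n_raw * spec$n_vars, -1, 1),
              spec$n_raw, spec$n_vars)
  colnames(X) <- paste0("x", seq_len(spec$n_vars))
  pool <- as.data.frame(X)
  pool$y <- X[, spec$causal_pair[1L]] * X[, spec$causal_pair[2L]]
  pool
}

#' Bin the dependent variable into class labels
#'
#' Min-max normalizes `y` over the whole pool (before any split) to `[0, 1]`
#' and assigns the class as the half-open bin index `[0,.2), [.2,.4), ...,
#' [.8,1]`; a normalized value of exactly 1 falls in the last class.
#'
#' @param pool Data frame from [generate_raw_pool()].
#' @param bins Class edges on the normalized scale.
#' @return The pool with added columns `y_norm` and `class` (0-based bin
#'   index), plus attributes `y_min`, `y_max` for label re-derivation.
#' @export
label_by_bins <- function(pool, bins = c(0, .2, .4, .6, .8, 1)) {
  if (nrow(pool) == 0L) stop("empty pool")
  rng <- range(pool$y)
  if (rng[1L] == rng[2L]) stop("degenerate pool: constant dependent variable")
  yn <- (pool$y - rng[1L]) / (rng[2L] - rng[1L])
  cls <- findInterval(yn, bins, rightmost.closed = TRUE, left.open = FALSE) - 1L
  pool$y_norm <- yn
  pool$class <- cls
  attr(pool, "y_min") <- rng[1L]
  attr(pool, "y_max") <- rng[2L]
  pool
}

#' Assemble labeled rows into same-class matrices
#'
#' Randomly draws `rows_per_matrix` rows of a single class (without
#' replacement within a dataset: no row is reused across matrices) to form
#' each matrix; the matrix inherits the class. With `balance`, classes are
#' down-sampled to equal matrix counts (`n_matrices / n_classes` each).
#'
#' @param labeled Pool from [label_by_bins()].
#' @param spec A [simulation_spec()].
#' @return A [windowed_dataset()] of `(rows_per_matrix, n_vars)` windows
#'   with 0-based class labels; provenance records the matrix serial.
#' @export
assemble_matrices <- function(labeled, spec) {
  r <- spec$rows_per_matrix
  # balanced assembly needs every class; otherwise work with those present
  classes <- if (spec$balance) 0:(spec$n_classes - 1L)
             else sort(unique(labeled$class))
  avail <- vapply(classes, function(cl) sum(labeled$class == cl), integer(1))
  if (any(avail < r))
    stop("class ", classes[which.min(avail)], " has fewer than ", r, " rows")
  per_class <- avail %/% r
  if (spec$balance) {
    target <- spec$n_matrices %/% spec$n_classes
    if (any(per_class < target))
      stop("not enough rows to assemble ", target, " matrices for class ",
           classes[which.min(per_class)], " (have ", min(per_class),
           "); increase n_raw")
    per_class <- rep(target, spec$n_classes)
  }
  Xcols <- paste0("x", seq_len(spec$n_vars))
  total <- sum(per_class)
  w <- array(0, c(total, r, spec$n_vars))
  labs <- integer(total)
  m <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    idx <- which(labeled$class == cl)
    idx <- idx[sample.int(length(idx))]      # shuffle, then consume in chunks
    for (k in seq_len(per_class[ci])) {
      m <- m + 1L
      rows <- idx[((k - 1L) * r + 1L):(k * r)]
      w[m, , ] <- as.matrix(labeled[rows, Xcols])
      labs[m] <- cl
    }
  }
  ds <- windowed_dataset(w, labs,
                         data.frame(series_id = paste0("sim_m", seq_len(total)),
                                    start = rep(1L, total)))
  attr(ds, "spec") <- spec
  attr(ds, "y_min") <- attr(labeled, "y_min")
  attr(ds, "y_max") <- attr(labeled, "y_max")
  ds
}

#' Generate one synthetic pairwise-interaction dataset
#'
#' Convenience composition of [generate_raw_pool()], [label_by_bins()] and
#' [assemble_matrices()].
#'
#' @param spec A [simulation_spec()].
#' @return A [windowed_dataset()] (see [assemble_matrices()]).
#' @export
simulate_interaction_data <- function(spec = simulation_spec()) {
  assemble_matrices(label_by_bins(generate_raw_pool(spec), spec$bins), spec)
}

#' Causal pair of dataset number `i` in the 10-dataset suite
#'
#' The suite enumerates all pairs of five variables in the order used by
#' the simulation study: adjacent pairs first, then increasing offsets:
#' (1,2), (2,3), (3,4), (4,5), (1,3), (2,4), (3,5), (1,4), (2,5), (1,5).
#'
#' @param i Dataset number 1..10.
#' @return Integer pair `c(a, b)`.
#' @export
suite_causal_pair <- function(i) {
  pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(1L, 3L),
                c(2L, 4L), c(3L, 5L), c(1L, 4L), c(2L, 5L), c(1L, 5L))
  if (i < 1L || i > 10L) stop("dataset number must be in 1..10")
  pairs[[i]]
}

#' Generate the 10-dataset simulation suite
#'
#' One dataset per pair of five variables, ordered as [suite_causal_pair()].
#' Dataset `i` uses seed `seed + i` so the pools are distinct.
#'
#' @param seed Base integer seed.
#' @param n_matrices,n_raw Passed to [simulation_spec()].
#' @return List of 10 [windowed_dataset()] objects.
#' @export
make_dataset_suite <- function(seed = 1L, n_matrices = 2000L, n_raw = 60000L) {
  lapply(1:10, function(i)
    simulate_interaction_data(simulation_spec(causal_pair = suite_causal_pair(i),
                                              n_matrices = n_matrices,
                                              n_raw = n_raw,
                                              seed = seed + i)))
}
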