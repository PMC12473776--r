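#' @useDynLib incnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal helpers -------------------------------------------------------

# Height-axis im2col: X (N, t, v) -> (N, H, k, v), H = t - k + 1.
.im2col <- function(X, k) {
  d <- dim(X)
  H <- d[2L] - k + 1L
  out <- array(0, c(d[1L], H, k, d[3L]))
  for (h in seq_len(H)) out[, h, , ] <- X[, h:(h + k - 1L), , drop = FALSE]
  out
}

.act <- function(x, activation) if (activation == "relu") pmax(x, 0) else x

# Block index for a model kind: incnn enumerates variables + pairs; the
# plain baseline has v variable blocks; the 1D baseline one undifferentiated
# block spanning the whole vector.
.block_index_for <- function(arch, kind) {
  if (kind == "incnn") return(feature_block_index(arch))
  B <- final_height(arch) * final_channels(arch)
  W <- if (kind == "plain") arch$v else 1L
  idx <- data.frame(block = seq_len(W),
                    kind = if (kind == "plain") "variable" else "all",
                    var1 = if (kind == "plain") seq_len(W) else NA_integer_,
                    var2 = NA_integer_,
                    start = (seq_len(W) - 1L) * B + 1L,
                    end = seq_len(W) * B)
  attr(idx, "block_length") <- B
  attr(idx, "n_features") <- B * W
  class(idx) <- c("feature_block_index", "data.frame")
  idx
}

.runif_arr <- function(dim, bound) array(stats::runif(prod(dim), -bound, bound), dim)

# ---- model construction -----------------------------------------------------

#' Initialize an InCNN (or baseline) model
#'
#' Builds the parameter set for an architecture. For `kind = "incnn"` there
#' are `v` parallel branches with filter widths `1..v`; interior filter
#' columns (width >= 3) are structurally zero and never updated. The
#' classification head is a single affine map from the flattened feature
#' vector to class scores; for `kind = "incnn"` the head rows attached to
#' pairwise-interaction blocks start at exactly zero, so a freshly
#' initialized InCNN computes the same scores as its individual-variable
#' reduction.
#'
#' Weights are drawn from `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` (fan-in of a
#' masked filter counts only its two active columns); head bias starts at 0.
#'
#' @param arch An [incnn_arch()].
#' @param kind `"incnn"`, `"plain"` (no-interaction baseline) or `"one_d"`
#'   (full-width first-layer filter baseline).
#' @param seed Optional integer seed (calls `set.seed` when given).
#' @param class_levels Optional vector of class labels the head maps to.
#' @return An object of class `incnn_model`.
#' @export
incnn_init <- function(arch, kind = c("incnn", "plain", "one_d"), seed = NULL,
                       class_levels = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- arch$v; k1 <- arch$k1; c1 <- arch$c1
  widths <- switch(kind, incnn = seq_len(v), plain = 1L, one_d = v)
  branches <- lapply(widths, function(wd) {
    ncol_eff <- if (kind == "one_d") wd else min(wd, 2L)
    bound <- 1 / sqrt(k1 * ncol_eff)
    W <- .runif_arr(c(k1, wd, c1), bound)
    if (kind != "one_d") W <- apply_interior_mask(W)
    list(W = W, b = if (arch$bias) stats::runif(c1, -bound, bound) else NULL)
  })
  c_in <- c1
  subsequent <- lapply(arch$subsequent, function(lc) {
    k <- lc[1L]; c_out <- lc[2L]
    bound <- 1 / sqrt(k * c_in)
    layer <- list(W = .runif_arr(c(k, c_in, c_out), bound),
                  b = if (arch$bias) stats::runif(c_out, -bound, bound) else NULL)
    c_in <<- c_out
    layer
  })
  index <- .block_index_for(arch, kind)
  Fdim <- attr(index, "n_features")
  bound <- 1 / sqrt(Fdim)
  Wh <- matrix(stats::runif(Fdim * arch$n_classes, -bound, bound),
               Fdim, arch$n_classes)
  if (kind == "incnn" && v >= 2L) {
    inter <- index$kind == "pair"
    rows <- unlist(mapply(seq, index$start[inter], index$end[inter],
                          SIMPLIFY = FALSE))
    Wh[rows, ] <- 0
  }
  structure(list(arch = arch, kind = kind,
                 params = list(branches = branches, subsequent = subsequent,
                               head = list(W = Wh,
                                           b = if (arch$bias) rep(0, arch$n_classes) else NULL)),
                 block_index = index, class_levels = class_levels),
            class = "incnn_model")
}

#' @export
print.incnn_model <- function(x, ...) {
  cat(sprintf("<incnn_model kind=%s> v=%d t=%d, %d feature blocks, %d features, %d classes\n",
              x$kind, x$arch$v, x$arch$t, nrow(x$block_index),
              attr(x$block_index, "n_features"), x$arch$n_classes))
  invisible(x)
}

# ---- batched forward / backward engine -------------------------------------

# Forward pass over a batch X (N, t, v). Returns logits, features and, when
# cache = TRUE, the intermediate activated maps needed for the backward pass.
# Feature maps are carried as (N, H, C, W) arrays; flattening permutes to
# (N, C, H, W) so that within a column the channel index varies fastest.
.forward <- function(model, X, cache = FALSE) {
  arch <- model$arch; p <- model$params
  act <- arch$activation
  N <- dim(X)[1L]; v <- arch$v; k1 <- arch$k1; c1 <- arch$c1
  H1 <- arch$t - k1 + 1L
  Xim <- .im2col(X, k1)                       # (N, H1, k1, v)
  NM <- N * H1
  if (model$kind == "one_d") {
    Mfull <- matrix(Xim, NM, k1 * v)
    Z <- Mfull %*% matrix(p$branches[[1L]]$W, k1 * v, c1)
    if (!is.null(p$branches[[1L]]$b))
      Z <- Z + rep(p$branches[[1L]]$b, each = NM)
    A <- array(.act(Z, act), c(N, H1, c1, 1L))
    Ms <- list(Mfull)
  } else {
    Ms <- lapply(seq_len(v), function(j) matrix(Xim[, , , j], NM, k1))
    offsets <- if (model$kind == "incnn") 0:(v - 1L) else 0L
    Wn <- sum(v - offsets)
    A <- array(0, c(N, H1, c1, Wn))
    col <- 0L
    for (d in offsets) {
      br <- p$branches[[d + 1L]]
      Wf <- matrix(br$W[, 1L, ], k1, c1)
      Wl <- if (d > 0L) matrix(br$W[, d + 1L, ], k1, c1)
      for (j in seq_len(v - d)) {
        col <- col + 1L
        Z <- Ms[[j]] %*% Wf
        if (d > 0L) Z <- Z + Ms[[j + d]] %*% Wl
        if (!is.null(br$b)) Z <- Z + rep(br$b, each = NM)
        A[, , , col] <- .act(Z, act)
      }
    }
  }
  maps <- list(A)                             # activated maps, layer by layer
  for (layer in p$subsequent) {
    In <- maps[[length(maps)]]
    k <- dim(layer$W)[1L]; Cin <- dim(layer$W)[2L]; Cout <- dim(layer$W)[3L]
    H <- dim(In)[2L]; Wn <- dim(In)[4L]
    Hout <- H - k + 1L
    if (Hout < 1L) stop("feature-map height ", H, " smaller than filter height ", k)
    Wmat <- matrix(layer$W, k * Cin, Cout)
    Out <- array(0, c(N, Hout, Cout, Wn))
    for (h in seq_len(Hout)) {
      Sm <- matrix(aperm(In[, h:(h + k - 1L), , , drop = FALSE], c(1, 4, 2, 3)),
                   N * Wn, k * Cin)
      Z <- Sm %*% Wmat
      if (!is.null(layer$b)) Z <- Z + rep(layer$b, each = N * Wn)
      Out[, h, , ] <- aperm(array(.act(Z, act), c(N, Wn, Cout)), c(1, 3, 2))
    }
    maps <- c(maps, list(Out))
  }
  final <- maps[[length(maps)]]
  dm <- dim(final)
  feats <- matrix(aperm(final, c(1, 3, 2, 4)), N, dm[2L] * dm[3L] * dm[4L])
  logits <- feats %*% p$head$W
  if (!is.null(p$head$b)) logits <- logits + rep(p$head$b, each = N)
  out <- list(features = feats, logits = logits)
  if (cache) out$cache <- list(Ms = Ms, maps = maps)
  out
}

# Backward pass for mean softmax cross-entropy. Y1 is the N x K one-hot
# matrix. Returns gradients in the same nested structure as model$params.
# Interior columns of masked filters receive structurally zero gradients.
.backward <- function(model, X, Y1, fwd) {
  arch <- model$arch; p <- model$params
  act <- arch$activation
  N <- dim(X)[1L]; v <- arch$v; k1 <- arch$k1; c1 <- arch$c1
  H1 <- arch$t - k1 + 1L
  maps <- fwd$cache$maps; Ms <- fwd$cache$Ms
  # softmax + CE
  lg <- fwd$logits
  lg <- lg - apply(lg, 1L, max)
  Pr <- exp(lg); Pr <- Pr / rowSums(Pr)
  dL <- (Pr - Y1) / N
  gh <- list(W = crossprod(fwd$features, dL), b = if (!is.null(p$head$b)) colSums(dL))
  dF <- dL %*% t(p$head$W)
  final <- maps[[length(maps)]]
  dm <- dim(final)
  dA <- aperm(array(dF, c(N, dm[3L], dm[2L], dm[4L])), c(1, 3, 2, 4))
  gsub <- vector("list", length(p$subsequent))
  if (length(p$subsequent) > 0L) {
    for (l in rev(seq_along(p$subsequent))) {
      layer <- p$subsequent[[l]]
      In <- maps[[l]]; Out <- maps[[l + 1L]]
      if (act == "relu") dA <- dA * (Out > 0)
      k <- dim(layer$W)[1L]; Cin <- dim(layer$W)[2L]; Cout <- dim(layer$W)[3L]
      Hout <- dim(Out)[2L]; Wn <- dim(Out)[4L]
      Wmat <- matrix(layer$W, k * Cin, Cout)
      dWmat <- matrix(0, k * Cin, Cout)
      db <- if (!is.null(layer$b)) numeric(Cout)
      dIn <- array(0, dim(In))
      for (h in seq_len(Hout)) {
        Dm <- matrix(aperm(array(dA[, h, , ], c(N, Cout, Wn)), c(1, 3, 2)),
                     N * Wn, Cout)
        Sm <- matrix(aperm(In[, h:(h + k - 1L), , , drop = FALSE], c(1, 4, 2, 3)),
                     N * Wn, k * Cin)
        dWmat <- dWmat + crossprod(Sm, Dm)
        if (!is.null(db)) db <- db + colSums(Dm)
        G <- Dm %*% t(Wmat)                   # (N*Wn) x (k*Cin)
        dIn[, h:(h + k - 1L), , ] <- dIn[, h:(h + k - 1L), , , drop = FALSE] +
          aperm(array(G, c(N, Wn, k, Cin)), c(1, 3, 4, 2))
      }
      gsub[[l]] <- list(W = array(dWmat, dim(layer$W)), b = db)
      dA <- dIn
    }
  }
  A1 <- maps[[1L]]
  if (act == "relu") dA <- dA * (A1 > 0)
  NM <- N * H1
  gbr <- vector("list", length(p$branches))
  if (model$kind == "one_d") {
    Dcol <- matrix(dA[, , , 1L], NM, c1)
    gbr[[1L]] <- list(W = array(crossprod(Ms[[1L]], Dcol), c(k1, v, c1)),
                      b = if (!is.null(p$branches[[1L]]$b)) colSums(Dcol))
  } else {
    offsets <- if (model$kind == "incnn") 0:(v - 1L) else 0L
    col <- 0L
    for (d in offsets) {
      br <- p$branches[[d + 1L]]
      dW <- array(0, dim(br$W))
      db <- if (!is.null(br$b)) numeric(c1)
      for (j in seq_len(v - d)) {
        col <- col + 1L
        Dcol <- matrix(dA[, , , col], NM, c1)
        dW[, 1L, ] <- dW[, 1L, ] + crossprod(Ms[[j]], Dcol)
        if (d > 0L)
          dW[, d + 1L, ] <- dW[, d + 1L, ] + crossprod(Ms[[j + d]], Dcol)
        if (!is.null(db)) db <- db + colSums(Dcol)
      }
      gbr[[d + 1L]] <- list(W = dW, b = db)
    }
  }
  list(branches = gbr, subsequent = gsub, head = gh,
       loss = -mean(log(pmax(rowSums(Pr * Y1), 1e-300))),
       prob = Pr)
}

# ---- public single-sample operations ---------------------------------------

#' Forward pass of one parallel branch
#'
#' Applies one branch's masked filter bank to a single window, returning the
#' feature map in the `(channels, height, width)` orientation. Column `j` of
#' the output depends only on input variables `j` and `j + d` (variable `j`
#' alone when the branch offset `d` is 0).
#'
#' @param window A `t x v` matrix (or `(1, t, v)` array).
#' @param bank A [masked_filter_bank()].
#' @param activation `"relu"` (default) or `"identity"`.
#' @return Numeric array `(c1, t - k1 + 1, v - d)`.
#' @export
branch_forward <- function(window, bank, activation = "relu") {
  if (length(dim(window)) == 3L) window <- array(window, dim(window)[2:3])
  window <- as.matrix(window)
  k1 <- dim(bank$weights)[1L]; wd <- dim(bank$weights)[2L]
  c1 <- dim(bank$weights)[3L]
  d <- wd - 1L
  v <- ncol(window)
  if (d >= v) stop("branch offset d = ", d, " requires at least ", d + 1L, " variables")
  H <- nrow(window) - k1 + 1L
  if (H < 1L) stop("window shorter than filter height")
  out <- array(0, c(c1, H, v - d))
  for (ch in seq_len(c1)) for (j in seq_len(v - d)) for (h in seq_len(H)) {
    z <- sum(window[h:(h + k1 - 1L), j] * bank$weights[, 1L, ch])
    if (d > 0L)
      z <- z + sum(window[h:(h + k1 - 1L), j + d] * bank$weights[, wd, ch])
    if (!is.null(bank$bias)) z <- z + bank$bias[ch]
    out[ch, h, j] <- z
  }
  .act(out, activation)
}

#' Concatenate branch feature maps into the integrated map
#'
#' Joins the per-branch maps column-wise in branch-offset order
#' (`d = 0, 1, ..., v-1`) into a `(c, H, v(v+1)/2)`-shaped integrated
#' feature map.
#'
#' @param branch_maps List of `(c, H, w_d)` arrays ordered by offset.
#' @param v Number of variables.
#' @return Numeric array `(c, H, v(v+1)/2)`.
#' @export
integrate_maps <- function(branch_maps, v) {
  stopifnot(length(branch_maps) == v)
  dims <- vapply(branch_maps, function(m) dim(m)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("branch maps must share channel count and height")
  widths <- vapply(branch_maps, function(m) dim(m)[3L], integer(1))
  if (!all(widths == v:1)) stop("branch map widths must be v, v-1, ..., 1")
  W <- v * (v + 1L) / 2L
  out <- array(0, c(dims[1, 1], dims[2, 1], W))
  col <- 0L
  for (m in branch_maps) for (j in seq_len(dim(m)[3L])) {
    col <- col + 1L
    out[, , col] <- m[, , j]
  }
  out
}

#' Forward pass of one width-1 subsequent convolution layer
#'
#' Applies the same `(k, 1)` filters to every column of a `(c, H, W)` map;
#' columns never mix.
#'
#' @param map Numeric array `(c_in, H, W)`.
#' @param weights Numeric array `(k, c_in, c_out)`.
#' @param bias Optional numeric vector of `c_out` biases.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return Numeric array `(c_out, H - k + 1, W)`.
#' @export
subsequent_forward <- function(map, weights, bias = NULL, activation = "relu") {
  k <- dim(weights)[1L]; Cin <- dim(weights)[2L]; Cout <- dim(weights)[3L]
  stopifnot(dim(map)[1L] == Cin)
  H <- dim(map)[2L]; Wn <- dim(map)[3L]
  if (H < k) stop("feature-map height ", H, " smaller than filter height ", k)
  Hout <- H - k + 1L
  out <- array(0, c(Cout, Hout, Wn))
  for (co in seq_len(Cout)) for (w in seq_len(Wn)) for (h in seq_len(Hout)) {
    z <- sum(map[, h:(h + k - 1L), w] * t(weights[, , co]))
    if (!is.null(bias)) z <- z + bias[co]
    out[co, h, w] <- z
  }
  .act(out, activation)
}

#' Flatten a feature map column by column
#'
#' Serializes a `(c, H, W)` map into a vector of length `c * H * W` grouped
#' column-by-column (block-contiguous); within a column the channel index
#' varies fastest, then the height index. This fixed bijection is what makes
#' feature positions attributable to variables and pairs.
#'
#' @param map Numeric array `(c, H, W)`.
#' @return Numeric vector of length `c * H * W`.
#' @export
flatten_ordered <- function(map) {
  stopifnot(length(dim(map)) == 3L)
  as.vector(map)   # (c, H, W) column-major: channel fastest, then height, then column
}

#' Classification head
#'
#' The hidden-layer-free affine map from flattened features to class scores.
#'
#' @param features Numeric vector of length F (or N x F matrix).
#' @param W Numeric `F x K` weight matrix.
#' @param b Optional numeric length-K bias.
#' @param probabilities If `TRUE`, return softmax probabilities.
#' @return Length-K score (or probability) vector, or an N x K matrix.
#' @export
head_forward <- function(features, W, b = NULL, probabilities = FALSE) {
  f <- if (is.matrix(features)) features else matrix(features, 1L)
  if (ncol(f) != nrow(W)) stop("feature length ", ncol(f),
                               " does not match head input size ", nrow(W))
  sc <- f %*% W
  if (!is.null(b)) sc <- sc + rep(b, each = nrow(f))
  if (probabilities) {
    sc <- sc - apply(sc, 1L, max)
    sc <- exp(sc); sc <- sc / rowSums(sc)
  }
  if (is.matrix(features)) sc else drop(sc)
}

#' Branch filter banks of a model
#' @param model An [incnn_model()][incnn_init].
#' @return List of [masked_filter_bank()] objects (one per branch).
#' @export
filter_banks <- function(model) {
  lapply(model$params$branches, function(br) {
    bank <- structure(list(weights = br$W, bias = br$b,
                           offset = dim(br$W)[2L] - 1L),
                      class = "masked_filter_bank")
    bank
  })
}

#' Predict classes, scores or probabilities
#'
#' @param object An `incnn_model`.
#' @param newdata A [windowed_dataset()] or an `N x t x v` array.
#' @param type `"class"`, `"prob"` or `"score"`.
#' @param ... Unused.
#' @return Predicted labels, an N x K probability matrix, or raw scores.
#' @export
predict.incnn_model <- function(object, newdata,
                                type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "windowed_dataset")) newdata$windows else newdata
  if (length(dim(X)) == 2L) X <- array(X, c(1L, dim(X)))
  lg <- .forward(object, X)$logits
  if (type == "score") return(lg)
  if (type == "prob") {
    lg <- lg - apply(lg, 1L, max)
    pr <- exp(lg); return(pr / rowSums(pr))
  }
  cls <- max.col(lg, ties.method = "first")
  if (!is.null(object$class_levels)) object$class_levels[cls] else cls
}

# ---- checkpointing ----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes all weight arrays to a single `.rds` archive, with the
#' architecture configuration and block index as JSON sidecars
#' (`<path>.arch.json`, `<path>.blocks.json`).
#'
#' @param model An `incnn_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_incnn <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$arch[c("v", "t", "k1", "c1", "n_classes", "activation", "bias")]
  cfg$subsequent <- model$arch$subsequent
  cfg$kind <- model$kind
  jsonlite::write_json(cfg, paste0(path, ".arch.json"), auto_unbox = TRUE)
  write_block_index(model$block_index, paste0(path, ".blocks.json"))
  invisible(path)
}

#' Load a model checkpoint written by [save_incnn()]
#' @param path Checkpoint path.
#' @return An `incnn_model`.
#' @export
load_incnn <- function(path) readRDS(path)
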