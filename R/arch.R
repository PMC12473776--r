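#' InCNN architecture configuration
#'
#' Describes the shared shape of the InCNN and its baselines: `v` input
#' variables, window length `t`, a parallel first layer of filters of height
#' `k1` with `c1` channels, and an optional stack of subsequent width-1
#' convolution layers `(k_l, c_l)`. All convolutions use stride 1 and no
#' padding; the classification head maps the flattened features directly to
#' `n_classes` scores with no hidden layer.
#'
#' @param v Number of variables (>= 1; >= 2 for interaction branches).
#' @param t Window length in time steps.
#' @param k1 Height of the parallel-branch filters.
#' @param c1 Channel count of the parallel branches.
#' @param subsequent List of `c(k, c)` pairs for layers 2..L (heights of the
#'   width-1 filters and their channel counts); may be empty.
#' @param n_classes Number of output classes.
#' @param activation `"relu"` (default) or `"identity"`, applied after every
#'   convolution; the head is always linear.
#' @param bias Logical; include bias terms in convolutions and the head.
#' @return An object of class `incnn_arch`.
#' @export
incnn_arch <- function(v, t, k1, c1, subsequent = list(), n_classes,
                       activation = c("relu", "identity"), bias = TRUE) {
  activation <- match.arg(activation)
  v <- as.integer(v); t <- as.integer(t)
  k1 <- as.integer(k1); c1 <- as.integer(c1)
  n_classes <- as.integer(n_classes)
  if (v < 1L) stop("v must be >= 1")
  if (t < 1L || k1 < 1L || k1 > t) stop("need 1 <= k1 <= t")
  if (c1 < 1L) stop("channel counts must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  heights <- k1
  channels <- c1
  for (lc in subsequent) {
    if (length(lc) != 2L) stop("subsequent entries must be c(k, c) pairs")
    if (any(lc < 1L)) stop("heights and channel counts must be >= 1")
    heights <- c(heights, as.integer(lc[1L]))
    channels <- c(channels, as.integer(lc[2L]))
  }
  H_L <- t - sum(heights - 1L)
  if (H_L < 1L)
    stop("final feature-map height t - sum(k_l - 1) = ", H_L, " must be >= 1")
  structure(list(v = v, t = t, k1 = k1, c1 = c1,
                 subsequent = lapply(subsequent, as.integer),
                 heights = heights, channels = channels,
                 n_classes = n_classes, activation = activation,
                 bias = isTRUE(bias)),
            class = "incnn_arch")
}

#' Final feature-map height of an architecture
#' @param arch An [incnn_arch()].
#' @return Integer height `H_L = t - sum(k_l - 1)`.
#' @export
final_height <- function(arch) arch$t - sum(arch$heights - 1L)

#' Final channel count of an architecture
#' @param arch An [incnn_arch()].
#' @return Integer `c_L`.
#' @export
final_channels <- function(arch) arch$channels[length(arch$channels)]

#' Convolution output shape
#'
#' Shape arithmetic for a 2-D convolution on an input of shape
#' `(c, h, w)` (channels, height, width) with `n` filters of spatial size
#' `(k_h, k_w)`, padding `p` and stride `s`:
#' `(n, (h + 2p - k_h)/s + 1, (w + 2p - k_w)/s + 1)`. InCNN always uses
#' `p = 0`, `s = 1`.
#'
#' @param input Integer length-3 `(c, h, w)`.
#' @param filter Integer length-2 `(k_h, k_w)`.
#' @param n Number of filters (output channels).
#' @param p Padding (default 0).
#' @param s Stride (default 1).
#' @return Integer length-3 output shape `(n, h', w')`.
#' @export
conv_output_shape <- function(input, filter, n, p = 0L, s = 1L) {
  stopifnot(length(input) == 3L, length(filter) == 2L)
  h_out <- (input[2L] + 2L * p - filter[1L]) / s + 1L
  w_out <- (input[3L] + 2L * p - filter[2L]) / s + 1L
  if (h_out < 1 || w_out < 1 || h_out != floor(h_out) || w_out != floor(w_out))
    stop("invalid convolution configuration: output shape (", n, ",",
         h_out, ",", w_out, ")")
  as.integer(c(n, h_out, w_out))
}

#' Feature-block index
#'
#' The bijection between positions of the flattened feature vector and
#' variable / pair identities. Columns of the integrated feature map are
#' ordered by branch offset `d`: first the `v` individual variables
#' (`d = 0`), then pairs at offset `d = 1` by increasing left variable
#' `(1,2), (2,3), ..., (v-1,v)`, then `d = 2`: `(1,3), ...`, up to
#' `d = v-1`: `(1,v)`. Every block is a contiguous run of
#' `B = H_L * c_L` positions; within a block the channel index varies
#' fastest, then the height index.
#'
#' @param arch An [incnn_arch()].
#' @return A data frame of class `feature_block_index` with columns
#'   `block`, `kind` ("variable"/"pair"), `var1`, `var2` (NA for variables),
#'   `start`, `end` (1-based inclusive positions), and attributes
#'   `block_length`, `n_features`.
#' @export
feature_block_index <- function(arch) {
  v <- arch$v
  B <- final_height(arch) * final_channels(arch)
  var1 <- integer(0); var2 <- integer(0); kind <- character(0)
  for (d in 0:(v - 1L)) {
    for (j in seq_len(v - d)) {
      if (d == 0L) {
        var1 <- c(var1, j); var2 <- c(var2, NA_integer_)
        kind <- c(kind, "variable")
      } else {
        var1 <- c(var1, j); var2 <- c(var2, j + d)
        kind <- c(kind, "pair")
      }
    }
  }
  W <- length(var1)
  idx <- data.frame(block = seq_len(W), kind = kind, var1 = var1, var2 = var2,
                    start = (seq_len(W) - 1L) * B + 1L,
                    end = seq_len(W) * B)
  attr(idx, "block_length") <- B
  attr(idx, "n_features") <- B * W
  class(idx) <- c("feature_block_index", "data.frame")
  idx
}

#' Human-readable block labels
#' @param index A [feature_block_index()].
#' @return Character vector like `"x1"`, `"x1:x3"`.
#' @export
block_labels <- function(index) {
  ifelse(index$kind == "variable", paste0("x", index$var1),
         paste0("x", index$var1, ":x", index$var2))
}

#' Export a block index as JSON
#'
#' Writes each block with a half-open 0-based `[start, end)` position range.
#'
#' @param index A [feature_block_index()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_block_index <- function(index, path) {
  out <- data.frame(block = block_labels(index), kind = index$kind,
                    start = index$start - 1L, end = index$end)
  jsonlite::write_json(out, path, dataframe = "rows")
  invisible(path)
}

#' Masked convolution filter bank
#'
#' Weights of one parallel branch: `c1` filters of height `k1` and width
#' `d + 1`, where `d` is the branch offset (column distance between the two
#' variables a filter spans). For widths of 3 or more, every interior column
#' is structurally zero, so each filter reads only its first and last input
#' columns. Construction applies the mask.
#'
#' @param weights Numeric array `k1 x width x c1`.
#' @param bias Optional numeric vector of `c1` biases.
#' @return An object of class `masked_filter_bank` with fields `weights`,
#'   `bias`, `offset` (= width - 1).
#' @export
masked_filter_bank <- function(weights, bias = NULL) {
  if (length(dim(weights)) != 3L) stop("weights must be a k1 x width x c1 array")
  if (!is.null(bias) && length(bias) != dim(weights)[3L])
    stop("bias length must equal the channel count")
  bank <- structure(list(weights = weights, bias = bias,
                         offset = dim(weights)[2L] - 1L),
                    class = "masked_filter_bank")
  apply_interior_mask(bank)
}

#' Zero the interior columns of a filter bank
#'
#' For filters of width >= 3, sets columns `2..(width-1)` to exactly zero;
#' widths 1 and 2 are returned unchanged. Idempotent.
#'
#' @param bank A [masked_filter_bank()] (or a bare weight array).
#' @return The masked bank (or array).
#' @export
apply_interior_mask <- function(bank) {
  if (is.array(bank)) {
    if (dim(bank)[2L] >= 3L) bank[, 2:(dim(bank)[2L] - 1L), ] <- 0
    return(bank)
  }
  bank$weights <- apply_interior_mask(bank$weights)
  bank
}

#' Check the interior-mask invariant
#' @param bank A [masked_filter_bank()] or weight array.
#' @return `TRUE` if all interior columns are exactly zero.
#' @export
mask_holds <- function(bank) {
  w <- if (is.array(bank)) bank else bank$weights
  if (dim(w)[2L] < 3L) return(TRUE)
  all(w[, 2:(dim(w)[2L] - 1L), ] == 0)
}
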