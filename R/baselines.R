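#' No-interaction baseline CNN
#'
#' Identical to the InCNN with every interaction branch removed: the first
#' layer has only width-1 filters (one column per variable), followed by the
#' same width-1 subsequent layers and a hidden-layer-free head. Flatten
#' length is `H_L * c_L * v`. With the same seed its first-layer branch
#' initializes identically to the InCNN's offset-0 branch.
#'
#' @param arch An [incnn_arch()].
#' @param seed Optional integer seed.
#' @param class_levels Optional class labels.
#' @return An `incnn_model` of kind `"plain"`.
#' @export
build_plain_cnn <- function(arch, seed = NULL, class_levels = NULL) {
  incnn_init(arch, kind = "plain", seed = seed, class_levels = class_levels)
}

#' 1D-convolution baseline CNN
#'
#' The standard multivariate-series CNN: the first-layer filter spans all
#' `v` variables (width `v`, no masking), so its output width is 1 and all
#' variables mix immediately. Subsequent layers and head as in the InCNN.
#' Flatten length is `H_L * c_L`.
#'
#' @inheritParams build_plain_cnn
#' @return An `incnn_model` of kind `"one_d"`.
#' @export
build_1d_cnn <- function(arch, seed = NULL, class_levels = NULL) {
  incnn_init(arch, kind = "one_d", seed = seed, class_levels = class_levels)
}

#' Reduce an InCNN to its no-interaction baseline
#'
#' Copies the offset-0 branch, subsequent layers and the individual-variable
#' head rows of an InCNN into a plain-CNN model. If the InCNN's interaction
#' head rows are zero, the two models produce identical outputs — the
#' equivalence oracle for the baseline construction.
#'
#' @param model An `incnn_model` of kind `"incnn"`.
#' @return An `incnn_model` of kind `"plain"` sharing the relevant weights.
#' @export
as_plain_cnn <- function(model) {
  stopifnot(model$kind == "incnn")
  plain <- incnn_init(model$arch, kind = "plain",
                      class_levels = model$class_levels)
  plain$params$branches[[1L]] <- model$params$branches[[1L]]
  plain$params$subsequent <- model$params$subsequent
  rows <- which(model$block_index$kind == "variable")
  keep <- unlist(mapply(seq, model$block_index$start[rows],
                        model$block_index$end[rows], SIMPLIFY = FALSE))
  plain$params$head$W <- model$params$head$W[keep, , drop = FALSE]
  plain$params$head$b <- model$params$head$b
  plain
}
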