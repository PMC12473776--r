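#' Training configuration
#'
#' @param phase1_epochs Pre-training epochs (individual-variable path).
#' @param phase2_epochs Fine-tuning epochs (whole network).
#' @param learning_rate Positive learning rate (paper setting: 0.01).
#' @param optimizer Only `"adam"` is implemented.
#' @param batch_size Mini-batch size (default 64).
#' @param seed Optional integer seed controlling initialization and batching.
#' @param loss Only `"cross_entropy"` is implemented.
#' @param early_stop If `TRUE`, stop a phase once the training loss has not
#'   improved by at least `min_delta` for `patience` consecutive epochs.
#' @param patience Early-stop patience in epochs.
#' @param min_delta Minimum loss improvement counted as progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(phase1_epochs = 40L, phase2_epochs = 40L,
                         learning_rate = 0.01, optimizer = "adam",
                         batch_size = 64L, seed = NULL,
                         loss = "cross_entropy", early_stop = FALSE,
                         patience = 5L, min_delta = 1e-4) {
  if (phase1_epochs < 0L || phase2_epochs < 0L) stop("epochs must be >= 0")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "cross_entropy")
  structure(list(phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 batch_size = as.integer(batch_size),
                 seed = if (!is.null(seed)) as.integer(seed),
                 loss = loss, early_stop = isTRUE(early_stop),
                 patience = as.integer(patience), min_delta = min_delta),
            class = "train_config")
}

#' Read a training configuration from YAML
#' @param path YAML file with `train_config` fields.
#' @return A [train_config()].
#' @export
read_train_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(train_config, yaml::read_yaml(path))
}

#' Write a training log as CSV
#' @param log Data frame returned in `$log` by the training functions.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

# ---- Adam -------------------------------------------------------------------

.zero_like <- function(x) if (is.null(x)) NULL else x * 0

.adam_init <- function(params) {
  zl <- function(p) lapply(p, function(e) list(W = .zero_like(e$W), b = .zero_like(e$b)))
  list(m = list(branches = zl(params$branches), subsequent = zl(params$subsequent),
                head = list(W = .zero_like(params$head$W), b = .zero_like(params$head$b))),
       v = list(branches = zl(params$branches), subsequent = zl(params$subsequent),
                head = list(W = .zero_like(params$head$W), b = .zero_like(params$head$b))),
       t = 0L)
}

# One Adam update over the nested parameter structure. `frozen_branches` is
# an integer vector of branch indices whose parameters are left untouched;
# `frozen_head_rows` rows of the head weight matrix receive zero gradient.
.adam_step <- function(params, grads, state, lr,
                       frozen_branches = integer(0),
                       frozen_head_rows = integer(0),
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  if (length(frozen_head_rows) > 0L) grads$head$W[frozen_head_rows, ] <- 0
  for (grp in c("branches", "subsequent")) {
    for (i in seq_along(params[[grp]])) {
      if (grp == "branches" && i %in% frozen_branches) next
      for (nm in c("W", "b")) {
        if (is.null(params[[grp]][[i]][[nm]])) next
        r <- upd(params[[grp]][[i]][[nm]], grads[[grp]][[i]][[nm]],
                 state$m[[grp]][[i]][[nm]], state$v[[grp]][[i]][[nm]])
        params[[grp]][[i]][[nm]] <- r$p
        state$m[[grp]][[i]][[nm]] <- r$m
        state$v[[grp]][[i]][[nm]] <- r$v
      }
    }
  }
  for (nm in c("W", "b")) {
    if (is.null(params$head[[nm]])) next
    r <- upd(params$head[[nm]], grads$head[[nm]],
             state$m$head[[nm]], state$v$head[[nm]])
    params$head[[nm]] <- r$p
    state$m$head[[nm]] <- r$m
    state$v$head[[nm]] <- r$v
  }
  list(params = params, state = state)
}

# ---- training loop ----------------------------------------------------------

.one_hot <- function(labels, levels) {
  k <- match(labels, levels)
  if (anyNA(k)) stop("labels outside the model's class levels")
  Y <- matrix(0, length(k), length(levels))
  Y[cbind(seq_along(k), k)] <- 1
  Y
}

.epoch_metrics <- function(model, X, Y1) {
  fwd <- .forward(model, X)
  lg <- fwd$logits - apply(fwd$logits, 1L, max)
  pr <- exp(lg); pr <- pr / rowSums(pr)
  list(loss = -mean(log(pmax(rowSums(pr * Y1), 1e-300))),
       acc = mean(max.col(fwd$logits, ties.method = "first") ==
                    max.col(Y1, ties.method = "first")))
}

.train_phase <- function(model, data, cfg, phase,
                         frozen_branches = integer(0),
                         frozen_head_rows = integer(0),
                         epochs, validation = NULL) {
  if (!inherits(data, "windowed_dataset")) stop("data must be a windowed_dataset")
  N <- n_windows(data)
  if (N == 0L) stop("cannot train on an empty dataset")
  if (is.null(model$class_levels))
    model$class_levels <- sort(unique(data$labels))
  X <- data$windows
  Y1 <- .one_hot(data$labels, model$class_levels)
  Yv <- if (!is.null(validation)) .one_hot(validation$labels, model$class_levels)
  log <- data.frame()
  if (epochs == 0L) return(list(model = model, log = log))
  state <- .adam_init(model$params)
  best <- Inf; stall <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    tot_loss <- 0; tot_correct <- 0
    for (b0 in seq(1L, N, by = cfg$batch_size)) {
      idx <- perm[b0:min(b0 + cfg$batch_size - 1L, N)]
      Xb <- X[idx, , , drop = FALSE]
      Yb <- Y1[idx, , drop = FALSE]
      fwd <- .forward(model, Xb, cache = TRUE)
      g <- .backward(model, Xb, Yb, fwd)
      tot_loss <- tot_loss + g$loss * length(idx)
      tot_correct <- tot_correct +
        sum(max.col(fwd$logits, ties.method = "first") ==
              max.col(Yb, ties.method = "first"))
      r <- .adam_step(model$params, g, state, cfg$learning_rate,
                      frozen_branches, frozen_head_rows)
      model$params <- r$params
      state <- r$state
    }
    loss <- tot_loss / N
    row <- data.frame(epoch = ep, phase = phase, loss = loss,
                      acc = tot_correct / N,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(validation)) {
      vm <- .epoch_metrics(model, validation$windows, Yv)
      row$val_loss <- vm$loss; row$val_acc <- vm$acc
    }
    log <- rbind(log, row)
    if (cfg$early_stop) {
      if (best - loss > cfg$min_delta) { best <- loss; stall <- 0L }
      else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  }
  list(model = model, log = log)
}

.interaction_head_rows <- function(model) {
  inter <- model$block_index$kind == "pair"
  if (!any(inter)) return(integer(0))
  unlist(mapply(seq, model$block_index$start[inter],
                model$block_index$end[inter], SIMPLIFY = FALSE))
}

#' Phase 1: pre-train the individual-variable path
#'
#' Trains only the offset-0 branch, the subsequent layers and the head rows
#' attached to individual-variable blocks. Interaction-branch weights are
#' untouched and interaction-block head rows are held at zero, so phase-1
#' predictions depend only on individual-variable features.
#'
#' @param model An [incnn_init()] model.
#' @param data Training [windowed_dataset()].
#' @param cfg A [train_config()]; `phase1_epochs` is used.
#' @param validation Optional validation [windowed_dataset()].
#' @return List `model` (updated), `log` (per-epoch data frame).
#' @export
pretrain_individual <- function(model, data, cfg, validation = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  frozen <- if (model$kind == "incnn" && model$arch$v >= 2L)
    2:model$arch$v else integer(0)
  rows <- .interaction_head_rows(model)
  if (length(rows) > 0L) model$params$head$W[rows, ] <- 0
  .train_phase(model, data, cfg, phase = 1L,
               frozen_branches = frozen,
               frozen_head_rows = rows,
               epochs = cfg$phase1_epochs, validation = validation)
}

#' Phase 2: fine-tune the whole network
#'
#' Updates every parameter except the structurally zero interior columns of
#' the masked filters. Because interaction head rows start (and are kept
#' during phase 1) at zero, the phase-2 model's step-0 predictions equal the
#' phase-1 model's predictions. Optimizer state is reset at phase entry.
#'
#' @inheritParams pretrain_individual
#' @return List `model`, `log`.
#' @export
finetune_full <- function(model, data, cfg, validation = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  .train_phase(model, data, cfg, phase = 2L, epochs = cfg$phase2_epochs,
               validation = validation)
}

#' Two-phase training from scratch
#'
#' Initializes a model and runs [pretrain_individual()] followed by
#' [finetune_full()] under a single seed controlling initialization,
#' batching and shuffling.
#'
#' @param arch An [incnn_arch()].
#' @param data Training [windowed_dataset()].
#' @param cfg A [train_config()].
#' @param kind Model kind passed to [incnn_init()].
#' @param validation Optional validation [windowed_dataset()].
#' @return List `model`, `log` (phases concatenated).
#' @export
train_two_phase <- function(arch, data, cfg, kind = "incnn", validation = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  model <- incnn_init(arch, kind = kind, seed = NULL,
                      class_levels = sort(unique(data$labels)))
  cfg_inner <- cfg
  cfg_inner$seed <- NULL   # one seed for the whole run; do not reset between phases
  p1 <- pretrain_individual(model, data, cfg_inner, validation = validation)
  p2 <- finetune_full(p1$model, data, cfg_inner, validation = validation)
  list(model = p2$model, log = rbind(p1$log, p2$log))
}
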