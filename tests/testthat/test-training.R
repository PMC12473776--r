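test_that("train_config validates its fields", {
  expect_error(train_config(phase1_epochs = -1), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
  cfg <- train_config(phase1_epochs = 50, phase2_epochs = 550)
  expect_identical(cfg$phase1_epochs, 50L)   # the activity-study schedule
  expect_identical(cfg$phase2_epochs, 550L)
})

test_that("phase 1 freezes interaction branches and keeps their head rows at zero", {
  data <- tiny_dataset(n_per_class = 20, n_classes = 3, seed = 2)
  arch <- incnn_arch(v = 5, t = 5, k1 = 3, c1 = 2, subsequent = list(),
                     n_classes = 3)
  model <- incnn_init(arch, seed = 4, class_levels = 0:2)
  cfg <- train_config(phase1_epochs = 4, phase2_epochs = 0, batch_size = 16,
                      seed = 21)
  p1 <- pretrain_individual(model, data, cfg)
  # interaction branches untouched bit-for-bit
  for (b in 2:5)
    expect_identical(p1$model$params$branches[[b]], model$params$branches[[b]])
  # individual path did move
  expect_false(identical(p1$model$params$branches[[1]], model$params$branches[[1]]))
  # interaction head rows exactly zero
  rows <- incnn:::.interaction_head_rows(model)
  expect_true(all(p1$model$params$head$W[rows, ] == 0))
  expect_identical(nrow(p1$log), 4L)

  # phase-1 predictions equal the reduced individual-variable model's
  plain <- as_plain_cnn(p1$model)
  X <- data$windows[1:7, , , drop = FALSE]
  expect_equal(predict(plain, X, type = "score"),
               predict(p1$model, X, type = "score"))

  # zero-epoch phase is the identity
  p0 <- pretrain_individual(model, data, train_config(phase1_epochs = 0,
                                                      phase2_epochs = 0))
  expect_same_params(p0$model, model)
  expect_error(pretrain_individual(model, subset_windows(data, integer(0)), cfg),
               "empty")
})

test_that("phase 2 starts from the phase-1 decision function and keeps the mask", {
  data <- tiny_dataset(n_per_class = 20, n_classes = 3, seed = 5)
  arch <- incnn_arch(v = 5, t = 5, k1 = 3, c1 = 2, subsequent = list(),
                     n_classes = 3)
  cfg <- train_config(phase1_epochs = 5, phase2_epochs = 5, batch_size = 16,
                      seed = 33)
  set.seed(33)
  model <- incnn_init(arch, class_levels = 0:2)
  p1 <- pretrain_individual(model, data, train_config(phase1_epochs = 5,
                                                      phase2_epochs = 0,
                                                      batch_size = 16))
  # step-0 equivalence: the phase-2 starting model (with its interaction
  # branches active but their head rows at zero) predicts exactly like the
  # phase-1 individual-variable reduction
  X <- data$windows[1:9, , , drop = FALSE]
  expect_equal(predict(as_plain_cnn(p1$model), X, type = "score"),
               predict(p1$model, X, type = "score"))
  p2 <- finetune_full(p1$model, data, train_config(phase1_epochs = 0,
                                                   phase2_epochs = 5,
                                                   batch_size = 16))
  # mask-zero invariant after training
  for (bank in filter_banks(p2$model)) expect_true(mask_holds(bank))
  # training reduced the loss from the phase-2 start
  m0 <- incnn:::.epoch_metrics(p1$model, data$windows,
                               incnn:::.one_hot(data$labels, 0:2))
  m1 <- incnn:::.epoch_metrics(p2$model, data$windows,
                               incnn:::.one_hot(data$labels, 0:2))
  expect_lt(m1$loss, m0$loss)
  # interaction branches moved in phase 2
  expect_false(identical(p2$model$params$branches[[2]],
                         p1$model$params$branches[[2]]))
})

test_that("two-phase training is deterministic given a seed", {
  data <- tiny_dataset(n_per_class = 15, n_classes = 3, seed = 6)
  arch <- incnn_arch(v = 5, t = 5, k1 = 3, c1 = 2, subsequent = list(),
                     n_classes = 3)
  cfg <- train_config(phase1_epochs = 3, phase2_epochs = 3, batch_size = 16,
                      seed = 77)
  a <- train_two_phase(arch, data, cfg)
  b <- train_two_phase(arch, data, cfg)
  expect_same_params(a$model, b$model)
  expect_equal(a$log, b$log)
  # phase2_epochs = 0 reproduces pretraining exactly
  cfg0 <- train_config(phase1_epochs = 3, phase2_epochs = 0, batch_size = 16,
                       seed = 77)
  c1 <- train_two_phase(arch, data, cfg0)
  set.seed(77)
  m <- incnn_init(arch, class_levels = sort(unique(data$labels)))
  c2 <- pretrain_individual(m, data, train_config(phase1_epochs = 3,
                                                  phase2_epochs = 0,
                                                  batch_size = 16))
  expect_same_params(c1$model, c2$model)
})

test_that("disabling interactions reproduces the plain CNN weight-for-weight", {
  # identical seeds: the plain baseline and the InCNN's d=0 path share the
  # same initialization draw order for branch 1
  arch <- incnn_arch(v = 4, t = 6, k1 = 3, c1 = 2, subsequent = list(c(2, 3)),
                     n_classes = 3)
  a <- incnn_init(arch, kind = "incnn", seed = 13)
  b <- build_plain_cnn(arch, seed = 13)
  expect_equal(a$params$branches[[1]], b$params$branches[[1]])

  # training the plain model with the single-phase trainer == training an
  # InCNN whose interaction path is removed, given shared weights
  data <- tiny_dataset(n_per_class = 15, t = 6, v = 4, n_classes = 3, seed = 7)
  cfg <- train_config(phase1_epochs = 0, phase2_epochs = 4, batch_size = 16,
                      seed = 5)
  reduced <- as_plain_cnn(a)
  reduced$class_levels <- sort(unique(data$labels))
  tr1 <- finetune_full(reduced, data, cfg)
  b$class_levels <- sort(unique(data$labels))
  b$params <- reduced$params   # shared starting point
  tr2 <- finetune_full(b, data, cfg)
  expect_same_params(tr1$model, tr2$model)
})

test_that("early stopping halts on a training-loss plateau", {
  data <- tiny_dataset(n_per_class = 10, n_classes = 2, seed = 8)
  arch <- incnn_arch(v = 5, t = 5, k1 = 3, c1 = 1, subsequent = list(),
                     n_classes = 2)
  cfg <- train_config(phase1_epochs = 200, phase2_epochs = 0, batch_size = 32,
                      seed = 3, early_stop = TRUE, patience = 3,
                      min_delta = 1e-3)
  model <- incnn_init(arch, seed = 3, class_levels = 0:1)
  p <- pretrain_individual(model, data, cfg)
  expect_lt(nrow(p$log), 200L)
})

test_that("train config round-trips through YAML and logs through CSV", {
  skip_if_not_installed("yaml")
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(phase1_epochs = 9, phase2_epochs = 36,
                        learning_rate = 0.01, batch_size = 32),
                   file.path(dir, "cfg.yaml"))
  cfg <- read_train_config(file.path(dir, "cfg.yaml"))
  expect_identical(cfg$phase1_epochs, 9L)
  log <- data.frame(epoch = 1:2, phase = 1L, loss = c(1, 0.5),
                    acc = c(0.4, 0.6), val_loss = NA_real_, val_acc = NA_real_)
  write_train_log(log, file.path(dir, "log.csv"))
  expect_equal(read.csv(file.path(dir, "log.csv"))$loss, c(1, 0.5))
})
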