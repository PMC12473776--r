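test_that("conv_output_shape matches the formula and rejects bad configs", {
  expect_identical(conv_output_shape(c(1, 10, 6), c(5, 1), n = 3), c(3L, 6L, 6L))
  expect_identical(conv_output_shape(c(1, 5, 5), c(3, 2), n = 3), c(3L, 3L, 4L))
  # (1,1) kernel: shape unchanged except channels
  expect_identical(conv_output_shape(c(4, 7, 9), c(1, 1), n = 1), c(1L, 7L, 9L))
  expect_error(conv_output_shape(c(1, 4, 4), c(5, 1), n = 2), "invalid")
  expect_error(incnn_arch(v = 5, t = 5, k1 = 3, c1 = 3,
                          subsequent = list(c(4, 2)), n_classes = 5),
               "height")
})

test_that("interior mask zeroes interior columns, is idempotent, keeps small widths", {
  w3 <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  m1 <- apply_interior_mask(w3)
  expect_true(all(m1[, 2, ] == 0))
  expect_equal(m1[, c(1, 3), ], w3[, c(1, 3), ])
  expect_identical(apply_interior_mask(m1), m1)
  w2 <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  expect_identical(apply_interior_mask(w2), w2)
  w1 <- array(rnorm(2 * 1 * 4), c(2, 1, 4))
  expect_identical(apply_interior_mask(w1), w1)
  expect_true(mask_holds(masked_filter_bank(w3)))
})

test_that("feature block index is a bijection with equal-length contiguous blocks", {
  for (arch in list(sim_arch(), arem_arch())) {
    idx <- feature_block_index(arch)
    v <- arch$v
    expect_identical(nrow(idx), as.integer(v * (v + 1) / 2))
    B <- attr(idx, "block_length")
    expect_true(all(idx$end - idx$start + 1L == B))
    covered <- unlist(mapply(seq, idx$start, idx$end, SIMPLIFY = FALSE))
    expect_identical(sort(covered), seq_len(attr(idx, "n_features")))
    # order: variables 1..v, then pairs by offset then left variable
    expect_identical(idx$kind[1:v], rep("variable", v))
    offs <- ifelse(is.na(idx$var2), 0L, idx$var2 - idx$var1)
    expect_true(all(diff(offs) >= 0))
    within <- split(idx$var1, offs)
    expect_true(all(vapply(within, function(x) all(diff(x) == 1), logical(1))))
  }
  idx6 <- feature_block_index(arem_arch())
  expect_identical(idx6$var1[7:11], 1:5)           # offset-1 pairs (1,2)..(5,6)
  expect_identical(idx6$var2[nrow(idx6)], 6L)      # last block is (1, v)
})

test_that("branch output columns depend only on their two variables", {
  set.seed(5)
  v <- 5; t <- 7; k1 <- 3; c1 <- 2
  win <- matrix(rnorm(t * v), t, v)
  for (d in 0:(v - 1)) {
    bank <- masked_filter_bank(array(rnorm(k1 * (d + 1) * c1), c(k1, d + 1, c1)),
                               bias = rnorm(c1))
    out <- branch_forward(win, bank)
    expect_identical(dim(out), as.integer(c(c1, t - k1 + 1, v - d)))
    for (pert in seq_len(v)) {
      win2 <- win
      win2[, pert] <- win2[, pert] + rnorm(t)
      out2 <- branch_forward(win2, bank)
      for (j in seq_len(v - d)) {
        involved <- pert %in% c(j, j + d)
        if (!involved)
          expect_equal(out2[, , j], out[, , j])
      }
    }
  }
  # d = v-1: single output column
  bank <- masked_filter_bank(array(rnorm(k1 * v * c1), c(k1, v, c1)))
  expect_identical(dim(branch_forward(win, bank))[3], 1L)
  # all-zero input, zero bias: all-zero output
  zbank <- masked_filter_bank(array(rnorm(k1 * 2 * c1), c(k1, 2, c1)),
                              bias = rep(0, c1))
  expect_true(all(branch_forward(matrix(0, t, v), zbank) == 0))
  expect_error(branch_forward(win, masked_filter_bank(
    array(rnorm(k1 * (v + 1) * c1), c(k1, v + 1, c1)))), "offset")
})

test_that("integrated map width is v(v+1)/2 in branch-offset order", {
  set.seed(6)
  mk_maps <- function(v, c1 = 3, H = 4)
    lapply(0:(v - 1), function(d) array(rnorm(c1 * H * (v - d)), c(c1, H, v - d)))
  expect_identical(dim(integrate_maps(mk_maps(6), 6))[3], 21L)
  expect_identical(dim(integrate_maps(mk_maps(5), 5))[3], 15L)
  expect_identical(dim(integrate_maps(mk_maps(1), 1))[3], 1L)
  maps <- mk_maps(4)
  im <- integrate_maps(maps, 4)
  expect_equal(im[, , 1:4], maps[[1]])          # d = 0 columns first
  expect_equal(im[, , 5], maps[[2]][, , 1])     # then pair (1,2)
  bad <- mk_maps(4); bad[[2]] <- bad[[2]][, 1:3, , drop = FALSE]
  expect_error(integrate_maps(bad, 4), "height")
})

test_that("subsequent layers follow the Table-3 shape chain and never mix columns", {
  set.seed(7)
  m1 <- array(abs(rnorm(3 * 6 * 21)), c(3, 6, 21))
  w2 <- array(rnorm(3 * 3 * 5), c(3, 3, 5))
  m2 <- subsequent_forward(m1, w2, bias = rnorm(5))
  expect_identical(dim(m2), c(5L, 4L, 21L))
  w3 <- array(rnorm(3 * 5 * 7), c(3, 5, 7))
  m3 <- subsequent_forward(m2, w3)
  expect_identical(dim(m3), c(7L, 2L, 21L))
  expect_error(subsequent_forward(m3, array(rnorm(3 * 7 * 2), c(3, 7, 2))),
               "height")

  # identity: k=1, single identity filter, no bias, identity activation
  mi <- array(rnorm(1 * 4 * 9), c(1, 4, 9))
  wid <- array(1, c(1, 1, 1))
  expect_equal(subsequent_forward(mi, wid, activation = "identity"), mi)

  # column independence: permute columns then convolve == convolve then permute
  perm <- sample(21)
  expect_equal(subsequent_forward(m1[, , perm], w2, activation = "identity"),
               subsequent_forward(m1, w2, activation = "identity")[, , perm])
})

test_that("flatten is block-contiguous with channel varying fastest", {
  map <- array(seq_len(2 * 3 * 4), c(2, 3, 4))   # (c, H, W)
  fl <- flatten_ordered(map)
  expect_identical(length(fl), 24L)
  # first block = first column, channel fastest then height
  expect_equal(fl[1:6], c(map[1, 1, 1], map[2, 1, 1], map[1, 2, 1],
                          map[2, 2, 1], map[1, 3, 1], map[2, 3, 1]))
  expect_equal(fl[7:12], as.vector(map[, , 2]))
})

test_that("head is a hidden-layer-free affine map", {
  f <- rnorm(10)
  W0 <- matrix(0, 10, 4)
  expect_equal(head_forward(f, W0, b = rep(0, 4), probabilities = TRUE),
               rep(0.25, 4))
  W1 <- matrix(0, 10, 4); W1[3, 2] <- 1
  expect_equal(head_forward(f, W1)[2], f[3])
  expect_error(head_forward(rnorm(9), W0), "does not match")
  # AReM head: 294 -> 7 scores
  m <- incnn_init(arem_arch(), seed = 1)
  expect_identical(dim(m$params$head$W), c(294L, 7L))
  expect_identical(length(predict(m, array(rnorm(10 * 6), c(1, 10, 6)),
                                  type = "score")), 7L)
})

test_that("batched engine equals the composed single-window operations", {
  set.seed(8)
  arch <- incnn_arch(v = 4, t = 9, k1 = 3, c1 = 2, subsequent = list(c(2, 3)),
                     n_classes = 3)
  model <- incnn_init(arch, seed = 11)
  X <- array(rnorm(3 * 9 * 4), c(3, 9, 4))
  eng <- extract_features(model, X)
  banks <- filter_banks(model)
  for (n in 1:3) {
    maps <- lapply(banks, function(b) branch_forward(X[n, , ], b))
    im <- integrate_maps(maps, arch$v)
    for (l in model$params$subsequent)
      im <- subsequent_forward(im, l$W, l$b)
    expect_equal(eng$features[n, ], flatten_ordered(im))
  }
})

test_that("shape chain property holds for random valid configurations", {
  set.seed(9)
  for (i in 1:12) {
    v <- sample(2:6, 1)
    t <- sample(6:14, 1)
    k1 <- sample(2:4, 1)
    c1 <- sample(1:4, 1)
    nsub <- sample(0:2, 1)
    subsequent <- list()
    hleft <- t - k1 + 1
    for (s in seq_len(nsub)) {
      k <- sample(1:max(1, min(3, hleft - 1)), 1)
      subsequent <- c(subsequent, list(c(k, sample(1:4, 1))))
      hleft <- hleft - k + 1
    }
    arch <- incnn_arch(v, t, k1, c1, subsequent, n_classes = 3)
    model <- incnn_init(arch, seed = i)
    X <- array(rnorm(2 * t * v), c(2, t, v))
    ft <- extract_features(model, X)
    expect_identical(ncol(ft$features),
                     as.integer(final_height(arch) * final_channels(arch) *
                                  v * (v + 1) / 2))
  }
})

test_that("pair blocks respond only to their own variables (finite difference)", {
  set.seed(10)
  arch <- incnn_arch(v = 5, t = 8, k1 = 3, c1 = 2, subsequent = list(c(2, 2)),
                     n_classes = 4)
  model <- incnn_init(arch, seed = 3)
  X <- array(rnorm(1 * 8 * 5), c(1, 8, 5))
  base <- extract_features(model, X)$features[1, ]
  idx <- model$block_index
  for (pert in 1:5) {
    X2 <- X
    X2[1, , pert] <- X2[1, , pert] + rnorm(8)
    f2 <- extract_features(model, X2)$features[1, ]
    for (b in seq_len(nrow(idx))) {
      members <- c(idx$var1[b], idx$var2[b])
      rng <- idx$start[b]:idx$end[b]
      if (!pert %in% members)
        expect_equal(f2[rng], base[rng])
    }
  }
})

test_that("checkpoints round-trip and export the block index", {
  dir <- withr::local_tempdir()
  m <- incnn_init(sim_arch(), seed = 2, class_levels = 0:4)
  p <- file.path(dir, "m.rds")
  save_incnn(m, p)
  m2 <- load_incnn(p)
  expect_equal(m2$params, m$params)
  blocks <- jsonlite::read_json(paste0(p, ".blocks.json"), simplifyVector = TRUE)
  expect_identical(nrow(blocks), 15L)
  expect_identical(blocks$end[1] - blocks$start[1],
                   attr(m$block_index, "block_length"))
  X <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  expect_equal(predict(m2, X, type = "score"), predict(m, X, type = "score"))
})
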