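# Shared fixtures: everything is generated in code, no stored data.

# The activity-recognition shapes: input (1, 10, 6), heights 5/3/3,
# channels 3/5/7, 7 classes.
arem_arch <- function() {
  incnn_arch(v = 6, t = 10, k1 = 5, c1 = 3,
             subsequent = list(c(3, 5), c(3, 7)), n_classes = 7)
}

# The simulation-study shapes: input (1, 5, 5), k1 = 3, c1 = 3, no
# subsequent layers, 5 classes.
sim_arch <- function() {
  incnn_arch(v = 5, t = 5, k1 = 3, c1 = 3, subsequent = list(), n_classes = 5)
}

# A tiny labeled windowed dataset with a learnable signal: class shifts the
# mean of every variable.
tiny_dataset <- function(n_per_class = 30, t = 5, v = 5, n_classes = 3,
                         seed = 1) {
  set.seed(seed)
  n <- n_per_class * n_classes
  w <- array(rnorm(n * t * v, 0, 0.3), c(n, t, v))
  labs <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  for (i in seq_len(n)) w[i, , ] <- w[i, , ] + labs[i]
  windowed_dataset(w, labs)
}

# A constant-value series for windowing arithmetic.
const_series <- function(T, v = 6, label = "a") {
  series_matrix(matrix(seq_len(T * v), T, v), label)
}

expect_same_params <- function(a, b, tol = 0) {
  expect_equal(a$params, b$params, tolerance = tol)
}
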