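# incnn

Interpretable convolutional feature extraction for multivariate time-series
classification, with quantified importance scores for individual variables
**and every pairwise variable interaction**.

## Who this is for

Analysts of multivariate sensor data — activity recognition from wearables,
manufacturing fault diagnosis, clinical monitoring — who need CNN-level
classification accuracy *and* an answer to "which sensor, or which pair of
sensors acting jointly, drives the prediction?" Standard CNNs mix all
variables in their first layer and cannot attribute decisions to variables,
let alone to statistical interactions (effects of one variable that depend
on another's value).

## The idea

The InCNN feature extractor makes attribution a property of the
architecture rather than a post-hoc explanation:

* **Parallel masked filter banks.** For a window of `t` time steps by `v`
  variables, the first layer holds `v` parallel branches. Branch `d = 0`
  uses width-1 filters (one output column per variable). Branch `d ≥ 1`
  uses width-`(d+1)` filters whose interior columns are *structurally
  zero*, so each output column sees exactly the variable pair `(j, j+d)`.
* **Integrated feature map.** All branch outputs share height and channel
  count and concatenate into a map of width `v(v+1)/2` — one column per
  variable and per pair. Deeper layers use width-1 filters only, so
  columns never mix.
* **Block-ordered flattening.** The final map is flattened column by
  column: the feature vector of length `H_L · c_L · v(v+1)/2` decomposes
  into contiguous blocks, each owned by one variable or one pair
  (`H_L = t − Σ(k_l − 1)` with stride 1, no padding). The classification
  head is a single affine map — no hidden layer to re-mix features.
* **Two-phase training.** Phase 1 pre-trains the individual-variable path
  (interaction branches frozen, interaction head rows held at zero) —
  lower-order effects first, per the hierarchical ordering principle;
  phase 2 fine-tunes everything, starting exactly from the phase-1
  decision function.
* **Importance scores.** Extracted features feed a random forest; mean
  decrease in impurity (MDI) per feature, normalized to sum 1, is summed
  over each block to score every variable and pair. Scores conserve mass:
  variables + pairs sum to 1.

Baselines with the same trainer and head are included: a no-interaction
CNN (width-1 first-layer filters only) and a 1D CNN (first-layer filter
width `v`), plus hand-crafted pairwise-product features.

## Worked example

Recover a planted interaction: five Uniform(−1,1) variables where the
class is the binned product `x1·x3`, assembled into 2000 same-class 5×5
matrices.

```r
library(incnn)
spec <- simulation_spec(causal_pair = c(1, 3), n_matrices = 2000, seed = 42)
data <- simulate_interaction_data(spec)
split <- split_dataset(data, c(0.7, 0, 0.3), seed = 42)

arch <- incnn_arch(v = 5, t = 5, k1 = 3, c1 = 3, n_classes = 5)
fit <- train_two_phase(arch, split$train,
                       train_config(phase1_epochs = 40, phase2_epochs = 40,
                                    learning_rate = 0.01, seed = 42))

feats <- extract_features(fit$model, split$train)
forest <- fit_interpretable(feats, ensemble_config(n_trees = 100,
                                                   max_depth = 10, seed = 42))
acc <- mean(predict(forest, extract_features(fit$model, split$test)) ==
              split$test$labels)
report <- aggregate_block_importance(forest$importances,
                                     fit$model$block_index, accuracy = acc)
rank_interactions(report, top_k = 3)
```

```
 entity kind var1 var2      score rank
  x1:x3 pair    1    3 0.29603623    1
  x3:x4 pair    3    4 0.07117419    2
  x1:x2 pair    1    2 0.06000229    3
classifier test accuracy: 0.980
```

The planted pair `x1:x3` ranks first by a wide margin, and its two
constituent variables dominate the individual scores
(`x1` 0.178, `x3` 0.189 vs ≤ 0.015 for the rest) — the signature pattern
of a real pairwise interaction. Test accuracy of the forest on the
extracted features is 0.980 here; at full published scale (~4700
matrices) it averages ≈ 0.997.

Long series are segmented with `slide_windows()` /`stack_sources()` /
`split_dataset()` (a 480-step, 6-variable series at window 10, step 5
yields 95 windows; 6 series × 7 classes → 3990 windows split
2394/798/798 at 60/20/20). `run_simulation_experiment()` and
`run_comparison_experiment()` wrap the two study harnesses, and a CLI
(`incnn_cli()`, or the installed `inst/cli/incnn` script) exposes
`simulate`, `window`, `train`, `extract`, `importance`, and
`experiment sim|compare` verbs.

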