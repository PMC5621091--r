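# harsvm

Energy-efficient human activity recognition from a phone's accelerometer
and barometer, for researchers in mobile/wearable sensing who need a
recogniser that runs at very low sampling rates without giving up
accuracy.

Continuously sampling an IMU at the usual 10–100 Hz dominates the power
budget of an always-on activity recogniser. `harsvm` implements a
recognition chain built around three ideas:

1. **Low-rate sampling with longer windows.** Activity recognition needs
   the *statistical* properties of the motion signal, not its waveform.
   When the rate FS₃ drops below the Nyquist rate 2·Fa of the activity
   (human gait has Fa ≈ 2 Hz), the window is lengthened to
   T₃ = (2·Fa·T)/FS₃ so each window still holds the same number of
   samples, and pooled means/variances are preserved
   (`equivalent_window()`, `scheme_equivalence_stats()`, `decimate()`).
   The default operating point is 1 Hz with 5 s windows.

2. **A hierarchical binary SVM (H-SVM) grown by k-means splits.** Six
   cheap per-window features are used — signed and absolute barometric
   pressure change Pd = pₙ − p₀ and |Pd| (stairs detection: pressure falls
   while climbing), per-axis acceleration means X̄, Ȳ, Z̄ (gravity
   included; Ȳ drops when a pocket-carried phone's wearer sits), and the
   motion wave Twave = Σᵢ ‖aᵢ₊₁ − aᵢ‖ (standing < walking < running).
   Features are ranked by sensor then compute cost; at each tree node,
   candidate features are clustered with 2-means and the split with
   sufficient purity and maximal class balance ("equilibrium") gets a
   linear binary SVM. An N-class problem always yields N−1 nodes, and a
   classification evaluates only the features on its root-to-leaf path.

3. **Context-based correction.** Activities are continuous, so each raw
   prediction is corrected by the mode of a sliding window of 2k+1
   predictions centred on it. Under i.i.d. per-window error probability
   ψ, the corrected accuracy is the binomial tail
   Σ_{i=0..k} C(2k+1, i) ψⁱ (1−ψ)^{2k+1−i}
   (`majority_accuracy()`), which motivates k = 1 (window of 3) for
   realistic ψ: at ψ = 0.3 accuracy rises from 0.700 to 0.784, and the
   marginal gain shrinks quickly beyond that while the reporting delay
   (k windows) keeps growing (`choose_k()`).

Because no public recordings accompany the method, the package ships a
seeded six-activity generator (`generate_session()`,
`generate_training_set()`) that reproduces the statistical structure the
classifier relies on: gravity on the Y axis when upright, a tilted device
while sitting, amplitude-ordered gait oscillation with per-stride random
phase, and signed barometric drift on stairs.

## Worked example

Train on the canonical 90-window set (15 windows per activity at
1 Hz / 5 s, first and last window of every session trimmed), then run the
full pipeline on an unseen session:

```r
library(harsvm)

cfg   <- synthetic_config(rate_hz = 1, seed = 42)
train <- generate_training_set(cfg, windows_per_class = 15, window_s = 5)
tree  <- train_tree(feature_table(train), seed = 1)
tree
#> <hsvm_tree> 6 classes, 5 binary SVM nodes (seed 1)
#> [Pdabs] {running,sitting,standing,walking} | {downstairs,upstairs}  acc=1.00
#>   [Ymeans] {sitting} | {running,standing,walking}  acc=1.00
#>     * sitting
#>     [Twave] {standing,walking} | {running}  acc=1.00
#>       [Twave] {standing} | {walking}  acc=1.00
#>         * standing
#>         * walking
#>       * running
#>   [Pd] {upstairs} | {downstairs}  acc=1.00
#>     * upstairs
#>     * downstairs
```

The root detects stair climbing from |Pd|, the stairs subtree separates
up from down on the sign of Pd, Ȳ isolates sitting, and the motion wave
resolves the remaining flat-ground activities — five binary nodes for six
classes.

```r
sched <- data.frame(
  activity   = c("sitting", "standing", "walking", "running",
                 "upstairs", "downstairs"),
  duration_s = 200)
test <- generate_session(synthetic_config(rate_hz = 50, schedule = sched,
                                          seed = 7))

res <- run_pipeline(train, decimate(test, 1),
                    pipeline_config(rate_hz = 1, window_s = 5, k = 1, seed = 3))
res
#> <har_pipeline> 1 Hz / 5 s windows / k = 1
#> raw macro accuracy:      0.9917
#> smoothed macro accuracy: 1.0000 (improvement +0.0083)
```

At 1 Hz the raw tree mislabels 2 of 240 windows; the k = 1 context
correction removes both isolated errors, at the price of a one-window
reporting delay. The closed-form model says the same thing:

```r
majority_accuracy(0.3, 0:1)   # 0.700 0.784  (an 8-point gain at k = 1)
choose_k(0.1)                 # 1
```

A thin command-line wrapper over these functions is installed as
`exec/harsvm` (subcommands `simulate`, `features`, `train`, `classify`,
`smooth`, `evaluate`, `pipeline`, `accuracy-model`).

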