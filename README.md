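# mectox

Quantifying individual toxicants in multi-component mixtures from the
current–time response of microbial electrochemical cell (MEC) biosensors.

An MEC biosensor carries an electroactive anode biofilm whose steady
current drops when toxicants inhibit microbial electron transfer. A single
chronoamperometric trace is informative about *total* toxic pressure, but
mixtures of toxicants overlap in one shared signal, so reading *per-component*
concentrations from a trace is an inverse problem. `mectox` implements a
feature-engineering + machine-learning pipeline for that problem:

1. **Design** — enumerate the full exposure plan for a four-toxicant panel
   (formaldehyde 200 ppm, tetracycline 5 ppm, silver 100 ppm, copper
   100 ppm): 4 singles, 18 binary, 16 ternary and 5 quaternary setups
   (43 in total), each at equivalent concentrations (EC) 1, 3, 5, 7, 10
   with replicates. Component *j* of a setup with volume-ratio weight
   *v_j* receives `c_max_j * (v_j / Σv) * (ec / 10)` ppm.
2. **Synthesis** — generate current traces with toxicokinetic structure
   (baseline, transient stress rise, dose-dependent inhibition decline,
   adaptive recovery, mixture interaction factor λ, measurement noise),
   with stored ground truth.
3. **Features** — convert each trace into 22 engineered indicators
   (extremes `I_max`, `I_min` and their times; `ΔI`, `ΔI/I₀`; secant
   slopes; increments `I_max − I₀`, `I₀ − I_min`; endpoint descriptors;
   binary `up`/`back` stress/adaptation flags; the curve integral; and
   smoothed-derivative extremes `D_max`, `D_min` with times).
4. **Mixture statistics** — the Interaction Index
   `II = (ΔI/I₀)_mixture / Σ (ΔI/I₀)_single`, with II > 1 synergy and
   II < 1 antagonism, plus fixed-time (30/60/300 s) linear calibrations of
   response against EC.
5. **Models** — per-toxicant concentration regressors (radial SVM, KNN
   with k = 200, PLS with 2 components, 100-tree random forest) compared
   under ten-fold cross-validation with the random seed fixed at 42;
   MAE, RMSE and R² per model and toxicant.
6. **Validation** — learning curves, replicate-grouped train/test splits,
   out-of-bag vs held-out R² agreement, and normalized Gini feature
   importances.

## Worked example

```r
library(mectox)

panel    <- default_panel()
setups   <- enumerate_setups(panel)            # 43 exposure setups
manifest <- expand_manifest(setups, panel)     # 1290 samples (43 x 5 EC x 6)

sim   <- simulate_dataset(manifest, sim_params(), seed = 42)
feats <- featurize_dataset(sim$traces)         # 1290 x 22 feature table

scores <- compare_models(feats, sim$truth)$scores
subset(as.data.frame(scores), model == "rf")
```

```
   model     toxicant    mae   rmse     r2
13    rf       copper 2.3710 3.6367 0.9523
14    rf formaldehyde 4.4412 7.4359 0.9502
15    rf       silver 2.0069 3.0827 0.9658
16    rf tetracycline 0.1303 0.1929 0.9464
```

The random forest reads all four concentrations back from the 22 features
with R² above 0.94 (MAE/RMSE in ppm), and it beats SVM, KNN and PLS on
every toxicant — e.g. SVM reaches only R² 0.59 for formaldehyde
(MAE 11.9 ppm) under the same folds. Interaction analysis on the additive
(pure-inhibition, noise-free) configuration recovers the injected mixture
interactions exactly:

```r
add <- simulate_dataset(expand_manifest(setups, panel, n_replicates = 1),
                        sim_params("additive"), seed = 42)
ii  <- interaction_table(featurize_dataset(add$traces), add$truth)
subset(as.data.frame(ii), ec_level == 10 & classification != "additive")
```

```
                                         setup_id ec_level ... ii   classification
           formaldehyde+tetracycline:2:1       10 ...     1.60          synergy
copper+formaldehyde+silver+tetracycline:1:1:1:1  10 ...     0.18       antagonism
```

Overfitting diagnostics (`learning_curve()`, `train_test_split_eval()`,
`oob_vs_test()`, `importance_table()`) confirm converging error bands and
out-of-bag scores within 0.01–0.02 of held-out R². `run_all(run_config(),
"out/")` executes the whole pipeline and writes each stage as CSV plus a
JSON validation report with MD5 hashes for reproducibility.

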