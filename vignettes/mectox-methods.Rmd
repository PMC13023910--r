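---
title: "Methods: simulating and decoding MEC biosensor responses to toxicant mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding MEC biosensor responses to toxicant mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mectox)
```

## The problem

A microbial electrolysis cell (MEC) biosensor holds an electroactive anode
biofilm under applied voltage; its output current is a proxy for the
biofilm's metabolic electron flux. Toxicants depress that flux, so a
chronoamperometric current–time (I–t) trace recorded over a short exposure
(here: 60 s of baseline plus 300 s of exposure, sampled every 12 s) carries
the sensor's toxicity read-out. For a *mixture* of toxicants the traces of
the components superimpose into one signal, and the task is to recover the
individual component concentrations from that shared signal.

`mectox` treats this as a supervised-learning problem on engineered trace
features, and ships a synthetic-data generator so the entire pipeline —
design, feature extraction, interaction statistics, model comparison,
overfitting diagnostics — is testable end to end with known ground truth.

## Exposure design

The default panel is formaldehyde (200 ppm), tetracycline (5 ppm), silver
(100 ppm) and copper (100 ppm); each `c_max` is the concentration at which
the sensor is expected to respond with comparable magnitude, which anchors
the *equivalent concentration* (EC) scale. The design crosses all
single-toxicant exposures with every 2-, 3- and 4-component combination at
fixed volume-ratio sets (binary 1:1, 2:1, 1:2; ternary 1:1:1 plus the three
single double-ups; quaternary 1:1:1:1 plus the four double-ups), giving
4 + 18 + 16 + 5 = 43 setups. Each setup runs at EC ∈ {1, 3, 5, 7, 10} with
6 replicates: 1290 samples. The replicate count is configurable; 6 is the
default so that the full factorial reaches the dataset size the package's
model comparison is calibrated for.

Volume ratios map to concentrations by equal-strength stock mixing:
component *j* with ratio weight *v_j* receives
`c_max_j · (v_j/Σv) · (ec/10)` ppm. A useful invariant follows: the summed
toxic units `Σ_j ppm_j / c_max_j` of any sample equal `ec/10`.

## The trace generator

For a sample with per-component toxic units `tu_j = ppm_j / c_max_j` and
interaction factor λ (see below), the noise-free current on the
post-injection clock `t` is

```
I(t) = I0 · (1 + Σ_j P_j(t)) · (1 − min(Σ_j D_j(t), f_cap)) + I0 · Σ_j R_j(t)

P_j(t) = λ · tu_j · a_j · (t/τ_up,j) · e^(1 − t/τ_up,j)          (stress pulse)
D_j(t) = β_j · 10 · λ · tu_j · (1 − e^(−max(0, t − lag_j)/τ_dec,j)) (inhibition)
R_j(t) = λ · tu_j · ρ_j · (1 − e^(−max(0, t − t_r)/τ_rec))       (adaptation)
```

with `I(t) = I0` before injection, i.i.d. Gaussian noise (sd `noise_sd`,
clipped at 5 sd) added pointwise, and `I0 ~ N(i0_mean, i0_sd)` drawn per
trace. Every mechanism is *additive in toxic units*: a mixture's pulse,
inhibition and adaptation terms are the sums of what its components would
contribute alone. This is the concentration-addition construction, and it
is what makes the Interaction Index identifiable (below).

### Why component-wise kinetics

An earlier design iteration used a single effective dose
`λ·10·Σ tu_j` driving one shared set of kinetics. That generator is
dose-identifiable but *component-blind*: a silver-only exposure and a
copper-only exposure at equal toxic units produce identical traces, so no
model can recover per-component concentrations — the core task. The
component-wise form keeps each per-component response curve linearly
independent, so the mixture trace carries (in principle) enough
information to invert for all four `tu_j`. The default kinetics place each
toxicant at an extreme of a different mechanism so that the 22 summary
features — which only record global extrema and aggregate shape — can
separate them:

| toxicant | β (per EC unit) | τ_dec (s) | lag (s) | a | τ_up (s) | ρ | mechanistic reading |
|---|---|---|---|---|---|---|---|
| formaldehyde | 0.035 | 70 | 0 | 0.45 | 22 | 0 | organic stressor: strong early stress pulse, moderate decline |
| tetracycline | 0.055 | 200 | 60 | 0.30 | 90 | 0 | protein-synthesis inhibitor: delayed onset, slow deep decline, broad mid pulse |
| silver | 0.050 | 13 | 0 | 0.15 | 12 | 0 | free heavy-metal ion: near-instant electron-transfer shutdown |
| copper | 0.012 | 45 | 0 | 0.35 | 160 | 0.50 | adaptable metal stress: weak net inhibition, late pulse, sustained adaptive stimulation |

Shared defaults: `f_cap = 0.95`, `i0_mean = 1` mA, `i0_sd = 0.03` mA,
`noise_sd = 0.005` mA (a realistic potentiostat noise floor on a ~1 mA
signal), `t_r = 100` s, `τ_rec = 70` s, grid 12 s, 60 s baseline, 300 s
exposure (31 samples per trace).

Two deliberate exaggerations relative to observed sensor behaviour are
worth naming. First, pulse amplitudes up to 0.45 per toxic unit exceed the
few-percent transient rises typically seen in measured traces; they are
set high enough that the stress channel stays machine-resolvable at the
chosen noise level. Second, copper's adaptation term can lift the late
current above baseline — a hormesis-like stimulation. Sub-lethal metal
doses stimulating microbial metabolism is a documented phenomenon, but
here its amplitude is chosen for identifiability, not fitted to any
measurement. Conclusions from this generator are therefore statements
about the *pipeline* (can the features and models decode a mixture whose
components differ kinetically?), not about any particular sensor.

### Mixture interaction

λ multiplies every per-component term: λ > 1 amplifies the mixture response
(synergy), λ < 1 damps it (antagonism). The default map injects λ = 1.6
into the formaldehyde–tetracycline 2:1 binary and λ = 0.18 into the
equal-ratio quaternary; all other setups are additive (λ = 1). These two
magnitudes give the interaction analysis one strong synergist and one
strong antagonist to recover.

### The three parameter profiles

* `sim_params("full")` — the defaults above; the dataset used for model
  comparison and overfitting diagnostics.
* `sim_params("additive")` — stress and adaptation off, noise off. With
  only the inhibition terms left, the measured response
  `ΔI/I0 = Σ_j D_j(300 s)` is *exactly* additive across components (the
  pulse–decline product coupling that breaks exactness is absent), the cap
  is never reached under the default design, and the Interaction Index
  recovers λ to machine precision. This is the configuration for
  interaction and calibration analysis.
* `sim_params("stress_coupled")` — an isolation experiment for importance
  validation: all toxicants share pulse timing (τ_up = 22 s) and decline
  kinetics (τ_dec = 60 s, β = 0.04), no lag or adaptation, and only the
  stress amplitudes differ (0.35/0.75/0.15/0.55) with a wider baseline
  spread (`i0_sd = 0.08`). Here the stress amplitude is the sole
  discriminating mechanism tied to dose, so the feature that measures it
  (`i_rise = I_max − I0`) must surface near the top of every toxicant's
  Gini importance ranking — a sanity check that the importance machinery
  credits the mechanism that actually carries the signal. Under the
  heterogeneous full profile that credit is split across the correlated
  pulse features (`i_rise`, `k_max0`, `i_max`, `d_max`), and no single one
  of them is guaranteed a top rank.

## Feature extraction

The 22 indicators are computed on the post-injection window only (the
injection instant included), times reported in seconds after injection.
Numerical conventions, chosen once and frozen:

* **Baseline**: `I0` is the mean of the pre-injection samples in a
  trailing 60 s window; `σ0` their standard deviation. With no
  pre-injection samples the first sample is used with `σ0 = 0`.
* **Ties** in extrema resolve to the earliest sample.
* **Degenerate traces** featurize rather than error: a constant trace has
  `ΔI = 0`, all slopes 0 (`k_secant` is defined as 0 when `Δt = 0`), and
  both binary flags 0.
* **Derivatives** are central finite differences of a centered moving
  average (window 5 samples = 60 s, shrinking at the edges); extremes are
  taken over interior points. The wide window deliberately suppresses
  narrow pulses in the derivative features — the raw-extremum features
  retain them.
* **`up`** fires when the raw current within the first 60 s after
  injection strictly exceeds `I0 + κσ0`; **`back`** fires when a smoothed
  sample after the current minimum strictly exceeds `I_min + κσ0`
  (κ = 3). Strict inequalities keep both flags at 0 on a flat trace.
* **Integral**: trapezoidal rule over the post-injection window.
* Units are fixed throughout: currents mA, times s, concentrations ppm;
  nothing is normalized except `ΔI/I0`.

Correctness is asserted against an independently written loop-based oracle
on hundreds of random traces, plus scale-equivariance and time-shift
invariance properties.

## Interaction Index and calibration

`II = (ΔI/I0)_mixture / Σ_j (ΔI/I0)_single(ppm_j)`: the additivity
expectation in the denominator uses single-toxicant responses *at each
component's actual concentration in the mixture*, obtained by linear
interpolation of the tabulated mean single responses against ppm with
clamped extrapolation. Each toxicant's table carries a (0 ppm, 0) anchor:
a mixture component's ppm is always below that toxicant's single-exposure
maximum, and at EC 1 it falls below the lowest tested single
concentration, where interpolation through the origin is exact for a
response that vanishes at zero dose. Negative measured mixture responses
(noise) are floored at 0 before division.

Fixed-time calibrations read the response `(I0 − I(t))/I0` at 30, 60 and
300 s — mapped to the nearest 12 s grid sample, with equidistant ties
resolved to the *later* sample (30 s → 36 s) — and fit ordinary least
squares against EC per toxicant. On additive-profile data the responses
are exactly linear in EC through the origin, the 300 s slope is steeper
than the 30 s slope for every toxicant (inhibition accumulates), and
tetracycline's lagged onset makes its 30 and 60 s responses identically
zero — such uninformative fits report slope 0 and are excluded from the
linearity check.

## Models and evaluation protocol

One independent single-output regressor per toxicant (per-toxicant R² is
the reported quantity, and single-output models keep the comparison
clean). Pinned hyperparameters: radial-kernel ε-SVR with C = 1, ε = 0.1,
γ = 1/d; KNN with k = 200 (clamped to the training-fold size with a
warning when it exceeds it) and Euclidean distance; PLS with 2 components;
random forest with 100 trees. Features are standardized (z-score fitted on
the training portion only) for SVM, KNN and PLS; trees are scale-free.
Evaluation is ten-fold cross-validation with fold assignment drawn once at
seed 42 and shared across toxicants and model families; reported MAE,
RMSE and R² are computed on the pooled out-of-fold predictions (one number
per model × toxicant). The raw-trace baseline stacks the 26 post-injection
currents as a 26-column design matrix through the same protocol.

## Overfitting diagnostics

Two split protocols answer two different questions, and they are kept
distinct on purpose:

* `train_test_split_eval()` holds out whole conditions
  (`setup_id × ec_level`), stratified per setup, so replicates never
  straddle the split. This measures generalization to *unseen conditions*
  and yields the lower, conservative test R².
* `oob_vs_test()` uses a plain random 80/20 sample split next to the
  forest's out-of-bag score. Both sides of that comparison see replicate
  "twins" of their evaluation points during training, which is exactly the
  regime in which OOB is an honest stand-in for a random test set — the
  observed gaps are below 0.03. Comparing OOB against the *grouped* test
  R² instead would conflate two protocols: OOB would look optimistic by
  0.1–0.3 simply because grouped holdout is a harder question, not because
  the forest memorized noise.

Learning curves subsample the training portion of each CV fold at
increasing sizes and track training vs validation RMSE (mean ± sd over
folds); the bands converge as size grows. Gini importances are the
forest's impurity decreases normalized to sum to one per toxicant.

## Problem sizes and determinism

The standard analyses run the full 1290-sample design (feature table
1290 × 22) for model comparison and diagnostics, a 215-sample
single-replicate additive dataset for interaction and calibration, and the
215-condition grid for property checks — sizes chosen so the complete
suite executes in a few minutes on one core. All randomness flows from
explicit seeds: the master simulation seed fans out to per-trace seeds, and
model folds are pinned at seed 42, so every table in the package's
documentation is bit-reproducible.

## What the surrogate does not show

The generator omits baseline drift, autocorrelated noise, electrode
fouling, biofilm aging and history effects, cross-reactor variability
beyond the baseline draw, and any real dose–response nonlinearity beyond
the inhibition cap; its dose–response is linear in EC by construction to
match the linear fixed-time calibrations. Passing tests therefore
demonstrate that the pipeline is correct and that the models can decode
kinetically distinct components at realistic noise levels — not that any
particular real-world accuracy will be achieved. Real-trace ingestion uses
the same long-format CSV interface (`read_traces_csv()`), so the pipeline
applies unchanged once measured data exist.
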