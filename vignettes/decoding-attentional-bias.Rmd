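---
title: "Decoding dynamic attentional-bias states: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding dynamic attentional-bias states: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decabt)
```

This vignette documents the science inside `decabt`: the behavioural model
of trial-level attentional bias, the pre-stimulus decoding pipeline, the
sparse Bayesian classifier, the evaluation machinery, the closed-loop
trigger simulator, and — since the package ships its own synthetic-data
generator — exactly what that generator does and does not emulate. Design
choices that were genuinely open are called out as such.

## 1. Trial-level attentional bias from approach–avoidance RTs

In the approach–avoidance task (AAT) a participant pulls (approach) or
pushes (avoid) a joystick according to a frame-colour cue around a gaming or
neutral image. The behavioural model holds that when attention is captured
by gaming content, approach responses to gaming stimuli are facilitated
(faster) and avoidance responses impeded (slower), relative to that block's
neutral trials.

`block_baselines()` computes, per (participant, block), the arithmetic mean
RT of valid neutral trials by direction (`BL_app`, `BL_avo`).
`label_trials()` then labels each gaming trial

* **positive** — biased toward gaming — iff `RT < BL_app` (approach) or
  `RT > BL_avo` (avoidance),
* **negative** on the strict opposite inequality,
* **excluded** on an exact tie or when the block baseline is undefined.

Ties are measure-zero for continuous RTs but must be deterministic for
discrete fixtures; we exclude rather than assign because only strict
inequalities are defined. Applying the same rule to the *neutral* trials
against their own baselines yields the **fake index**, a control for generic
RT fluctuation. Its literal definition includes each trial in its own
baseline; because self-inclusion shrinks deviations toward zero (their
within-block mean is exactly zero), a leave-one-out variant is available via
`label_trials(..., fake_loo = TRUE)`.

**Trial exclusion.** The published exclusion rules are not fully specified,
so `filter_config()` reconstructs them as configurable filters: wrong or
missing responses, RT below 150 ms, and per-participant slow outliers beyond
`mean + 3 s.d.`. The outlier moments are computed leave-one-out over the
participant's responded trials: with self-inclusive moments a single
outlier among *n* trials can never exceed `mean + k·sd` for
`k > (n−1)/√n` (≈ 2.85 at n = 10), i.e. the rule could not remove exactly
the trial it is aimed at; leave-one-out restores that behaviour and makes
filtering idempotent. All thresholds are configurable.

**Reliability.** `split_half_reliability()` splits each participant's
labelled trials chronologically (pooled across blocks; the first half takes
`ceiling(n/2)` trials), computes the per-half mean RT deviation per label,
correlates the halves across participants (Pearson by default — the
"Spearman–Brown ρ" names the step-up correction `2r/(1+r)`, not rank
correlation; a rank-based option exists), and applies the correction.

## 2. Pre-stimulus feature extraction

The decoding target is the brain state *before* the stimulus appears, so
features must not touch stimulus-evoked signal:

1. **Voxel QC** (`voxel_qc()`): a voxel is kept iff its raw run mean ≥ 80
   and raw s.d. ≤ 8. These thresholds are meaningful only in raw BOLD
   units, so QC always precedes normalization; multi-run fits use the
   intersection of per-run retained sets.
2. **Detrend + z-score** (`detrend_normalize()`): per retained voxel and per
   block, an OLS linear trend is removed and residuals standardized to mean
   0 / s.d. 1. The per-block scope matches the per-block z-scoring that
   minimizes baseline differences across blocks; whether detrending should
   instead span the run is ambiguous, so `scope = "run"` is provided
   (default `"block"`). Voxels with zero-variance residuals (e.g. a pure
   ramp) are dropped with a warning.
3. **Extraction** (`extract_features()`): the feature vector of trial *t*
   is the normalized signal at volume `iti_onset(t) + shift_tr`, i.e. the
   first TR of the pre-stimulus fixation period read `shift_tr = 3` TRs
   (5.25 s at TR = 1.75 s) later to account for hemodynamic delay. The
   indexing arithmetic ("first TR of the pre-stimulus period", then a 3-TR
   shift) is implicit in the source protocol; we resolve it as
   extraction-time shifting, which differs from shifting the whole time
   course only at block edges. Trials whose shifted index falls off the run
   or at/after the next trial's stimulus onset are excluded and logged.

Volume indexing is 0-based half-open throughout. The suite asserts a
no-leakage property: zeroing all volumes from `onset + shift` onwards leaves
a trial's features unchanged.

## 3. Sparse Bayesian logistic regression and the iterative wrapper

The classifier (`fit_slr()`, C++ core) is Bayesian logistic regression with
an independent zero-mean Gaussian prior per weight, `w_i ~ N(0, 1/α_i)`.
The precisions are optimized by evidence maximization with MacKay
fixed-point updates around a Laplace approximation:

* inner loop: damped Newton (step-halving on the penalized log-likelihood)
  to the MAP weights given `α`;
* outer loop: `γ_i = 1 − α_i Σ_ii` (with `Σ` the Laplace posterior
  covariance), `α_i ← γ_i / w_i²`;
* features with `α_i > prune_alpha` are pruned: weight exactly 0, removed
  from the model.

The cited method does not print its update equations; MacKay fixed-point
updates are the standard realization of automatic relevance determination,
and the suite pins the implementation against a brute-force grid search of
the Laplace evidence on a two-feature instance (the fixed point lands within
one grid step of the grid argmax; its evidence is within 0.1 nats — the
expected gap of the fixed-point approximation, which ignores the dependence
of `Σ` on `α`). Unstated numerical constants are chosen for reproducibility
and are all configurable through `slr_control()`: `prune_alpha = 1e8`,
`max_outer = 200`, convergence at `max |Δw| < 1e-6`, and a fixed weak
intercept prior `α_0 = 1e-6` (the intercept is never pruned). The fit is
deterministic: no random initialization (`w = 0`, `α = 1`).

**iSLR** (`fit_islr()`): iteration *k* is fit on the feature space minus
everything selected by iterations `1..k−1`, for `n_iter = 10` iterations,
yielding pairwise-disjoint selected sets. This matters for fMRI because
informative voxels are mutually correlated and ARD deliberately prunes
redundant ones; re-fitting on the remainder recovers them. Iteration stops
early when no features remain or when a stage selects none; that last stage
is kept (an intercept-only model still emits probabilities).

**Prediction** (`predict_islr()`): per-stage probabilities combine as
`P = Π p_k / (Π p_k + Π (1 − p_k))` (computed in log space), with the binary
label `P > 0.5`. "Multiplied probability entering a logit function" admits a
raw-product reading too, so `combine = "product"` thresholds `Π p_k` at 0.5
instead; when stages are symmetric the two agree on the sign of the
evidence. Stage probabilities are clipped to `[1e-12, 1 − 1e-12]`.

## 4. Evaluation

`loro_cv()` implements leave-one-run-out cross-validation: each run is held
out once; within every training fold the majority class is downsampled
**without replacement** (the protocol says only "downsampled") to the
minority size, independently `n_resamples = 10` times; accuracy is the mean
over resamples, then over folds. `cross_condition_decode()` generalizes
this to the four crossings (gaming, gaming→neutral, neutral,
neutral→gaming) by training on condition A's trials from runs ≠ r and
testing on condition B's trials of run r — the same fold skeleton for every
crossing so accuracies are comparable (fold handling for crossings is not
spelled out in the protocol; this is our resolution).
`direction_split_accuracy()` pools held-out predictions and reports
approach/avoidance separately; on pooled predictions the overall accuracy is
exactly the trial-count-weighted mean of the two.

`group_tests()` runs two-sided one-sample t-tests of per-participant
accuracies against the 50% theoretical chance level and adjusts with
Benjamini–Hochberg over the declared family — all cells of one call (e.g.
7 ROIs × 4 conditions = 28 tests; or all regions of a search sweep).
`search_roi_sweep()` repeats the *entire* pipeline (QC → normalize →
extract → balanced LORO-CV) inside every region of a parcellation.

`bootstrap_balance_test()` handles unequal group sizes by drawing `n_sub`
participants from the larger group without replacement `B = 100000` times
and evaluating a statistic (default difference of means) per draw. The
two-sided p-value is `(2·min(#stat ≤ 0, #stat ≥ 0) + 1)/(B + 1)`, capped at
1; the `+1` continuity correction keeps p > 0. Equal groups give p ≈ 1 and
fully separated groups give the floor `1/(B+1)`. The statistic and its
sidedness are configurable, and an exhaustive-enumeration mode exists for
small inputs.

## 5. Closed-loop DecABT simulation

`run_decabt_block()` walks a per-TR stream — either precomputed
probabilities (so trigger logic is testable without a decoder) or feature
vectors decoded online with `predict_islr()`. Per trial, the first TR with
probability **strictly** above `prob_threshold = 0.95` ("above 95%" is read
as strict) triggers a stimulus: gaming with probability `p_gaming`, else
neutral. Gaming stimuli carry the avoidance cue (green frame), neutral the
approach cue (red frame), so participants are trained to avoid gaming
content exactly when their decoded bias is high. Without a crossing within
`window_tr = 15` TRs, the trial is NG (no-go: no stimulus). The threshold
applies to the single-TR probability (no smoothing — unstated in the
protocol, single-TR assumed). Two constants are not printed in the
protocol and are therefore configuration: the post-trigger epoch
(`post_trigger_tr = 3` TRs for stimulus + response) and the design gaming
probability, set to `p_gaming = 0.7` to match the reported ~69% empirical
gaming appearance rate. A new trial starts only if a full NG window fits in
the remaining run (210 volumes), so NG trials always observe exactly
`window_tr` probabilities.

## 6. The synthetic-data generator

`simulate_trials()` / `simulate_run_series()` emulate the decoding-session
design: each run holds one block — 12 baseline volumes
(`ceiling(21 s / 1.75 s)`), then a pseudo-randomized sequence of 56 gaming
and 24 neutral trials — inside a 348-volume run. Per trial the layout is
`iti_tr = 2` fixation volumes then `stim_tr = 2` stimulus/response volumes
(the true inter-trial timing is only shown schematically in the source
protocol; two fixation TRs guarantee a first pre-stimulus volume exists).
That fits comfortably: 12 + 80×4 = 332 ≤ 348. The DecABT-protocol
assessment preset `decabt_aat_config()` is two runs of (20 gaming + 20
neutral), i.e. 80 trials (40/40) over two blocks, in 210-volume runs.

**Behaviour.** A latent two-state (biased/unbiased) first-order Markov
chain with switch probability `state_transition_prob = 0.2` evolves per
trial — trial-level granularity matches the labelling, so no within-trial
dynamics. RTs are lognormal (`rt_median_ms = 600`,
`rt_noise_sd_log = 0.15`), right-skewed like real RT data, with the state
shifting the gaming-trial median by `rt_state_effect_ms = 150` ms: biased →
approach faster / avoidance slower, unbiased → the opposite signs. The
symmetric shift is required for the labelling rule to recover the state
(with a one-sided shift, unbiased trials would label 50/50 and no generator
setting could reach high label/state agreement). Directions are balanced
within condition per block so both neutral baselines exist. Defaults were
chosen once as values a behavioural scientist would call realistic
(~600 ms median AAT RTs, ~15% lognormal CV, a 150 ms bias effect,
moderately persistent states) and are not tuned.

**BOLD.** Live voxels sit at a raw baseline of 100 with AR(1) noise
(`ar1_coef = 0.3`, marginal s.d. `noise_sd = 2`) and a per-block linear
drift with slope uniform in ±0.01 units/volume. `n_dead_voxels = 10` voxels
have raw mean < 80 and `n_noisy_voxels = 10` have raw s.d. > 8, exercising
QC. Of 200 voxels, `n_informative_voxels = 20` carry the state: at each
gaming trial's *feature volume* (pre-stimulus ITI start + 3-TR shift) their
signal is offset by `± signal_effect × noise_sd` (`signal_effect = 1`)
according to the latent state. Signal is injected directly at the volume
the pipeline reads rather than through a hemodynamic forward model: the
pipeline only ever uses that volume, so this isolates exactly what is
tested. Only gaming trials carry signal by default, so fake-index decoding
stays at chance and condition crossings are asymmetric by construction.

`simulate_parcellation()` stands in for a whole-brain atlas (default 166
regions) with a lattice Voronoi partition grown from random seed voxels:
contiguous-ish regions, every voxel labelled, every region non-empty.

**What passing tests do and do not show.** The generator has no
hemodynamic response, no physiological noise, no head motion, no spatial
autocorrelation beyond the planted pattern, and its informative voxels all
encode one latent state. Green tests therefore certify the *pipeline* —
indexing, leakage-freedom, balancing, statistics, trigger logic — under the
stated statistical structure; they say nothing about decodability of real
scanner data.

## 7. Numerical choices and degenerate inputs

* Ties: RT exactly at baseline → excluded; combined probability exactly 0.5
  → predicted negative (`P > 0.5` strict). On permuted-label runs this tie
  convention plus a mild prevalence of negative labels (mean-based baselines
  on right-skewed RTs run ≈ 51% negative) can push empirical chance about a
  point above 50% — visible in the chance-level benchmark, and well inside
  its acceptance band.
* Sphere masks use voxel-centre distance with an inclusive boundary
  (≤ radius, with a 1e-9 mm² slack against floating-point ties); the
  convention is not stated in the source. The published VTA right-hemisphere
  x = 4.1 mm is taken verbatim even though it looks mirrored from the left
  coordinate.
* Baselines use *filtered* neutral trials (whether the original used
  filtered or unfiltered is unstated).
* Blocks shorter than 3 volumes cannot be detrended (error); a block with no
  valid neutral trials in a direction yields an undefined baseline and
  excluded labels, not an error; zero-voxel QC results error with the
  thresholds named.
* All randomness is seeded: generators take `seed` fields, CV takes a
  `seed` for its balancing draws, and identical seeds reproduce results
  byte-for-byte.

## 8. Problem sizes used by the shipped checks

The acceptance benchmark (`scripts/acceptance.R` and the corresponding
test) runs the study-scale design — 4 runs × (56 + 24) trials, 200 voxels —
across 20 permuted-label simulations. Property suites (label balance,
monotonicity in the RT effect and in `signal_effect`, type-I control at
α = 0.05 over 500 null simulations) run on a reduced design (3 runs of
24 + 12 trials, 40 voxels) so that many-seed sweeps stay quick; these sizes
are the package's own choice of sweep resolution and are set in the test
helpers, not in the API defaults.

## 9. Known limitations

* The ARD fixed point is a local evidence optimizer; heavily correlated
  features are intentionally represented sparsely (iSLR's iterations exist
  to recover the remainder).
* The closed-loop simulator models trigger logic and stimulus contingency
  only — no joystick responses, no feedback epoch content, no scanner
  real-time constraints.
* `search_roi_sweep()` decodes one participant at a time; group-level maps
  are assembled by mapping over participants and feeding `group_tests()`.
* The linear mixed-effects condition × experiment interaction analysis and
  whole-brain univariate GLMs are out of scope; standard tooling covers
  them.
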