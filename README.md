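# decabt

Decoding dynamic attentional-bias states from pre-stimulus fMRI, and
simulating closed-loop decoded attentional-bias training (DecABT).

## What this package is for

In gaming disorder, attention drifts toward game-related stimuli, but not
constantly: the bias waxes and wanes from trial to trial. This package
implements a complete, testable pipeline for studying those *dynamic* bias
states:

1. **Trial-level bias labelling from behaviour.** In an approach–avoidance
   task (AAT), participants pull (approach) or push (avoid) a joystick in
   response to a frame-colour cue around gaming or neutral images. Within
   each block, the mean reaction time of neutral trials per direction gives
   the baselines `BL_app` and `BL_avo`. A gaming trial is labelled
   **positive** (biased toward gaming) when `RT < BL_app` on approach or
   `RT > BL_avo` on avoidance, **negative** on the strict opposite, and
   excluded on ties. The same rule applied to the neutral trials themselves
   yields a *fake index* used as a control, and split-half reliability is
   assessed with the Spearman–Brown step-up `rho = 2r / (1 + r)`.
2. **Pre-stimulus multivoxel decoding.** Per run, voxels failing quality
   control (raw mean < 80 or raw s.d. > 8) are discarded; time courses are
   linearly detrended and z-scored per voxel within each block; the feature
   of every trial is the first TR of its pre-stimulus fixation period, read
   3 TRs (5.25 s at TR = 1.75 s) later to account for the hemodynamic delay.
   Classification uses **iterative sparse logistic regression (iSLR)**:
   Bayesian logistic regression with one Gaussian prior precision per weight
   optimized by evidence maximization (automatic relevance determination),
   run for 10 iterations where each iteration removes the voxels it selected
   and refits on the remainder. Test probabilities multiply across
   iterations, `P = prod(p_k) / (prod(p_k) + prod(1 - p_k))`.
3. **Evaluation the way decoding studies do it.** Leave-one-run-out
   cross-validation with the majority class randomly downsampled to the
   minority size 10 times per fold; four condition crossings (gaming,
   gaming→neutral, neutral, neutral→gaming); direction-split accuracies;
   search-ROI sweeps over a whole-brain parcellation; one-sample and paired
   t-tests against the 50% chance level with Benjamini–Hochberg FDR control;
   and a bootstrap subsample test for comparing groups of unequal size.
4. **Closed-loop DecABT simulation.** During fixation a decoder emits one
   bias probability per TR; the first TR above 95% triggers a stimulus
   (gaming with probability 0.7, cueing avoidance; neutral cueing approach);
   if no TR crosses within 15 TRs the trial ends without a stimulus (NG
   trial).
5. **A synthetic-data generator** that emulates the study design — blocks of
   56 gaming + 24 neutral trials after a 21 s baseline, 348-volume runs at
   TR = 1.75 s (210 for DecABT), lognormal RTs driven by a latent two-state
   Markov process, and voxel series with a sparse informative subset, linear
   drift, AR(1) noise, and planted dead/noisy voxels — so every stage is
   testable without scanner data.

ROI masks (spheres at published MNI coordinates, e.g. bilateral ventral
striatum at (±12, 10, −6) with 12 mm radius, and the mesolimbic SN ∪ VTA ∪ VS
composite) can be built on any grid and written as NIfTI.

The API is tibble-first: trial tables go in, tibbles come out, results have
`tidy()` / `glance()` methods and `autoplot()` visualizations.

## Worked example

```r
library(decabt)

cfg <- sim_config(seed = 42)            # 4 runs x (56 gaming + 24 neutral)
sim  <- simulate_trials(cfg)
runs <- simulate_run_series(sim)

trials    <- filter_trials(sim$trials)
baselines <- block_baselines(trials)
labelled  <- label_trials(trials, baselines, condition = "gaming")
table(labelled$label)
#> excluded negative positive
#>        1      105      118

feats <- build_features(runs, labelled) # QC -> detrend/z-score -> extract
feats
#> <bias_features> 223 trials x 180 voxels (118 positive / 105 negative)

cv <- loro_cv(feats, n_resamples = 10, seed = 42)
cv
#> <cv_result> accuracy 0.930 over 4 fold(s) x 10 resample(s)

direction_split_accuracy(cv)
#>   direction     n accuracy
#> 1 approach   1120    0.901
#> 2 avoidance  1110    0.959

loro_cv(permute_labels(feats, seed = 7), n_resamples = 10, seed = 42)
#> <cv_result> accuracy 0.544 over 4 fold(s) x 10 resample(s)
```

The generator planted a bias signal in 20 of 200 voxels (20 more are dead or
noisy and removed by QC, leaving 180): the decoder reaches 93% held-out
accuracy, decodes both directions above chance, and collapses toward 50%
once the labels are permuted. A closed-loop block from a probability stream:

```r
model <- fit_islr(feats$X, feats$meta$y)
set.seed(1); stream <- rbeta(210, 8, 2)
session <- run_decabt_block(stream, closed_loop_config(seed = 9))
session
#> <decabt_session> 17 trial(s), 7 NG; threshold 0.95, window 15 TR
summarize_session(session)
#>   n_blocks n_trials ng_mean ng_sem gaming_fraction latency_mean_tr ...
#> 1        1       17       7     NA             0.9             6.5
```

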