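#' Configuration for the synthetic approach-avoidance / fMRI generator
#'
#' Bundles every knob of the synthetic-data generator. The defaults reproduce
#' the decoding-session study design: blocks of 56 gaming and 24 neutral
#' trials after a 21 s baseline, runs of 348 volumes at TR = 1.75 s, and a
#' latent two-state (biased / unbiased) attentional process that modulates
#' gaming-trial reaction times and plants a multivoxel signal in the
#' pre-stimulus volume of a sparse set of informative voxels.
#'
#' Each run holds one task block: a baseline of `ceiling(21 / 1.75) = 12`
#' volumes followed by trials of `iti_tr` fixation volumes and `stim_tr`
#' stimulus/response volumes, which fits comfortably in the 348-volume run
#' (12 + 80 x 4 = 332).
#'
#' @param n_participants Number of simulated participants.
#' @param n_runs_per_participant Runs (= blocks) per participant; leave-one-run-out
#'   cross-validation needs at least 2.
#' @param n_gaming_per_block,n_neutral_per_block Trials per block by condition.
#'   At least one neutral trial per block is required, otherwise the block
#'   baseline is undefined downstream.
#' @param baseline_duration_s Baseline (fixation) period opening each block, seconds.
#' @param tr_s Repetition time in seconds.
#' @param volumes_per_run Volumes acquired per run.
#' @param n_voxels Voxels per run.
#' @param n_informative_voxels Voxels carrying the latent-state signal.
#' @param signal_effect Standardized mean difference (in units of the noise
#'   s.d.) between bias states in informative voxels at the pre-stimulus
#'   feature volume.
#' @param state_transition_prob Per-trial probability that the latent bias
#'   state switches (first-order Markov chain; persistence is one minus this).
#' @param rt_state_effect_ms Shift of the gaming-trial RT median induced by the
#'   latent state (ms). In the biased state approach medians shift by
#'   `-rt_state_effect_ms` and avoidance medians by `+rt_state_effect_ms`;
#'   the unbiased state shifts with the opposite signs, so the baseline
#'   labelling rule recovers the state.
#' @param rt_noise_sd_log Lognormal sigma of RTs.
#' @param rt_median_ms Median RT of neutral trials (ms).
#' @param drift_slope_range Per-block linear drift slopes are drawn uniformly
#'   from `[-drift_slope_range, drift_slope_range]` (signal units per volume).
#' @param ar1_coef Lag-1 autocorrelation of the voxel noise.
#' @param noise_sd Marginal s.d. of live-voxel noise in raw signal units.
#' @param n_dead_voxels Voxels with raw mean below the QC floor of 80.
#' @param n_noisy_voxels Voxels with raw s.d. above the QC ceiling of 8.
#' @param iti_tr Fixation (inter-trial interval) volumes before each stimulus;
#'   at least 2 so a first pre-stimulus volume always exists.
#' @param stim_tr Stimulus + response volumes per trial.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_runs_per_participant = 2, n_voxels = 40)
#' cfg$volumes_per_run
sim_config <- function(n_participants = 1,
                       n_runs_per_participant = 4,
                       n_gaming_per_block = 56,
                       n_neutral_per_block = 24,
                       baseline_duration_s = 21,
                       tr_s = 1.75,
                       volumes_per_run = 348,
                       n_voxels = 200,
                       n_informative_voxels = 20,
                       signal_effect = 1.0,
                       state_transition_prob = 0.2,
                       rt_state_effect_ms = 150,
                       rt_noise_sd_log = 0.15,
                       rt_median_ms = 600,
                       drift_slope_range = 0.01,
                       ar1_coef = 0.3,
                       noise_sd = 2,
                       n_dead_voxels = 10,
                       n_noisy_voxels = 10,
                       iti_tr = 2,
                       stim_tr = 2,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_runs_per_participant = as.integer(n_runs_per_participant),
    n_gaming_per_block = as.integer(n_gaming_per_block),
    n_neutral_per_block = as.integer(n_neutral_per_block),
    baseline_duration_s = baseline_duration_s,
    tr_s = tr_s,
    volumes_per_run = as.integer(volumes_per_run),
    n_voxels = as.integer(n_voxels),
    n_informative_voxels = as.integer(n_informative_voxels),
    signal_effect = signal_effect,
    state_transition_prob = state_transition_prob,
    rt_state_effect_ms = rt_state_effect_ms,
    rt_noise_sd_log = rt_noise_sd_log,
    rt_median_ms = rt_median_ms,
    drift_slope_range = drift_slope_range,
    ar1_coef = ar1_coef,
    noise_sd = noise_sd,
    n_dead_voxels = as.integer(n_dead_voxels),
    n_noisy_voxels = as.integer(n_noisy_voxels),
    iti_tr = as.integer(iti_tr),
    stim_tr = as.integer(stim_tr),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participant(s) x %d run(s); block: %d gaming + %d neutral trials\n",
              x$n_participants, x$n_runs_per_participant,
              x$n_gaming_per_block, x$n_neutral_per_block))
  cat(sprintf("  run: %d volumes at TR %.3g s; %d voxels (%d informative, %d dead, %d noisy)\n",
              x$volumes_per_run, x$tr_s, x$n_voxels,
              x$n_informative_voxels, x$n_dead_voxels, x$n_noisy_voxels))
  cat(sprintf("  signal effect %.3g sd; RT state effect %.3g ms; seed %d\n",
              x$signal_effect, x$rt_state_effect_ms, x$seed))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_participants", "n_runs_per_participant", "n_gaming_per_block",
              "n_neutral_per_block", "volumes_per_run", "n_voxels",
              "n_informative_voxels", "n_dead_voxels", "n_noisy_voxels",
              "iti_tr", "stim_tr")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(sprintf("`%s` must be a non-negative count", nm), call. = FALSE)
    }
  }
  if (cfg$n_neutral_per_block < 1) {
    stop("`n_neutral_per_block` must be >= 1: a block without neutral trials has no baseline",
         call. = FALSE)
  }
  if (cfg$state_transition_prob < 0 || cfg$state_transition_prob > 1) {
    stop("`state_transition_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$tr_s <= 0) stop("`tr_s` must be positive", call. = FALSE)
  if (cfg$n_informative_voxels + cfg$n_dead_voxels + cfg$n_noisy_voxels > cfg$n_voxels) {
    stop("informative + dead + noisy voxel counts exceed `n_voxels`", call. = FALSE)
  }
  need <- baseline_volumes(cfg) +
    (cfg$n_gaming_per_block + cfg$n_neutral_per_block) * (cfg$iti_tr + cfg$stim_tr)
  if (need > cfg$volumes_per_run) {
    stop(sprintf("block design needs %d volumes but `volumes_per_run` is %d",
                 need, cfg$volumes_per_run), call. = FALSE)
  }
  invisible(cfg)
}

baseline_volumes <- function(cfg) as.integer(ceiling(cfg$baseline_duration_s / cfg$tr_s))

#' Generator preset for the DecABT-protocol bias assessment
#'
#' The attentional-bias assessment bracketing decoded attentional-bias
#' training uses 80 trials (40 gaming / 40 neutral images) over two blocks,
#' acquired in 210-volume runs. This preset encodes that layout (two runs of
#' one 20 gaming + 20 neutral block each); all other knobs inherit the
#' [sim_config()] defaults and can be overridden through `...`.
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
#' @examples
#' cfg <- decabt_aat_config()
#' 2 * (cfg$n_gaming_per_block + cfg$n_neutral_per_block)  # 80 trials
decabt_aat_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_runs_per_participant = 2,
    n_gaming_per_block = 20,
    n_neutral_per_block = 20,
    volumes_per_run = 210
  )
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}
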