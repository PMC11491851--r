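#' Simulate approach-avoidance task trials with a latent bias state
#'
#' Generates one trial table per (participant, run). Each run holds one block:
#' a pseudo-randomized sequence of `n_gaming_per_block` gaming and
#' `n_neutral_per_block` neutral trials after the baseline period. A latent
#' two-state Markov chain (biased / unbiased, persistence
#' `1 - state_transition_prob`) evolves across trials. Gaming-trial RT medians
#' shift by `rt_state_effect_ms`: in the biased state approach trials get
#' faster and avoidance trials slower than the neutral distribution (and the
#' reverse in the unbiased state), so the block-baseline labelling rule
#' recovers the state. Neutral RTs are state-independent. RTs are lognormal.
#' Directions are balanced within condition in each block so both neutral
#' baselines are defined.
#'
#' @param config A [sim_config()].
#' @return A list of class `aat_sim` with elements
#'   * `trials`: tibble with columns `participant_id`, `run`, `block`, `trial`,
#'     `condition`, `direction`, `rt_ms`, `onset_volume` (0-based),
#'     `iti_onset_volume`, `response_correct`, `valid`;
#'   * `truth`: ground truth for parameter-recovery tests — `latent_states`
#'     (tibble keyed like `trials` with `state`), plus disjoint
#'     `informative_voxel_ids`, `dead_voxel_ids`, `noisy_voxel_ids`.
#' @export
#' @examples
#' sim <- simulate_trials(sim_config(n_runs_per_participant = 1, n_voxels = 40,
#'                                   n_informative_voxels = 4, n_dead_voxels = 2,
#'                                   n_noisy_voxels = 2))
#' table(sim$trials$condition)
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  base_tr <- baseline_volumes(config)
  trial_len <- config$iti_tr + config$stim_tr
  n_trials <- config$n_gaming_per_block + config$n_neutral_per_block

  one_block <- function(pid, run) {
    condition <- sample(rep(c("gaming", "neutral"),
                            c(config$n_gaming_per_block, config$n_neutral_per_block)))
    direction <- character(n_trials)
    for (cond in c("gaming", "neutral")) {
      idx <- which(condition == cond)
      half <- length(idx) %/% 2
      dirs <- c(rep("approach", half), rep("avoidance", length(idx) - half))
      direction[idx] <- sample(dirs)
    }
    state <- character(n_trials)
    state[1] <- sample(c("biased", "unbiased"), 1)
    if (n_trials > 1) {
      flips <- runif(n_trials - 1) < config$state_transition_prob
      for (i in 2:n_trials) {
        state[i] <- if (flips[i - 1]) setdiff(c("biased", "unbiased"), state[i - 1]) else state[i - 1]
      }
    }
    shift <- ifelse(condition == "neutral", 0,
                    ifelse((state == "biased") == (direction == "approach"),
                           -config$rt_state_effect_ms, config$rt_state_effect_ms))
    med <- pmax(config$rt_median_ms + shift, 50)
    rt <- rlnorm(n_trials, meanlog = log(med), sdlog = config$rt_noise_sd_log)
    idx0 <- seq_len(n_trials) - 1L
    tibble::tibble(
      participant_id = pid,
      run = run,
      block = run,
      trial = seq_len(n_trials),
      condition = condition,
      direction = direction,
      rt_ms = rt,
      onset_volume = base_tr + idx0 * trial_len + config$iti_tr,
      iti_onset_volume = base_tr + idx0 * trial_len,
      response_correct = TRUE,
      valid = 1L,
      .state = state
    )
  }

  grid <- expand.grid(run = seq_len(config$n_runs_per_participant),
                      pid = seq_len(config$n_participants))
  trials <- purrr::map2_dfr(grid$pid, grid$run,
                            function(p, r) one_block(sprintf("sub%02d", p), r))

  vox <- sample.int(config$n_voxels,
                    config$n_informative_voxels + config$n_dead_voxels + config$n_noisy_voxels)
  informative <- sort(vox[seq_len(config$n_informative_voxels)])
  dead <- sort(vox[config$n_informative_voxels + seq_len(config$n_dead_voxels)])
  noisy <- sort(vox[config$n_informative_voxels + config$n_dead_voxels +
                      seq_len(config$n_noisy_voxels)])

  truth <- list(
    latent_states = dplyr::select(trials, "participant_id", "run", "block",
                                  "trial", state = ".state"),
    informative_voxel_ids = informative,
    dead_voxel_ids = dead,
    noisy_voxel_ids = noisy
  )
  trials <- dplyr::select(trials, -".state")
  structure(list(trials = trials, truth = truth, config = config), class = "aat_sim")
}

#' @export
print.aat_sim <- function(x, ...) {
  cat("<aat_sim> ", nrow(x$trials), " trials, ",
      dplyr::n_distinct(x$trials$participant_id), " participant(s)\n", sep = "")
  invisible(x)
}

#' Simulate voxel-by-volume BOLD series for generated trials
#'
#' Builds one `run_series` per (participant, run) in `trials`. Live voxels sit
#' at a raw baseline of 100 with AR(1) noise of marginal s.d. `noise_sd` and a
#' per-block linear drift; dead voxels have raw mean < 80 and noisy voxels raw
#' s.d. > 8 so that quality control has something to catch. At the volume the
#' preprocessing stage will extract as the trial feature (first pre-stimulus
#' fixation volume plus the hemodynamic shift), informative voxels carry an
#' offset of `+/- signal_effect * noise_sd` whose sign follows the trial's
#' latent state; by default only gaming trials carry this signal so that
#' fake-index (neutral) decoding stays at chance.
#'
#' @param sim An `aat_sim` from [simulate_trials()], or a list with `trials`,
#'   `truth` and `config` components.
#' @param shift_tr Hemodynamic shift in TRs used to place the signal; must
#'   match the shift used at feature extraction (default 3).
#' @param signal_conditions Conditions whose trials carry the voxel signal.
#' @param seed RNG seed for the noise; defaults to `config$seed + 1` so the
#'   trial and voxel generators use distinct, reproducible streams.
#' @return A list of `run_series` objects, one per participant x run, each with
#'   fields `data` (voxels x volumes), `tr_s`, `block_bounds`, `voxel_coords`
#'   (integer lattice coordinates used to align with a parcellation),
#'   `participant_id`, `run`, `normalized`.
#' @export
simulate_run_series <- function(sim, shift_tr = 3, signal_conditions = "gaming",
                                seed = NULL) {
  config <- sim$config
  trials <- sim$trials
  truth <- sim$truth
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(as.integer(seed))

  nv <- config$n_voxels
  nt <- config$volumes_per_run
  if (any(trials$onset_volume + config$stim_tr > nt)) {
    stop("trial onsets fall outside `volumes_per_run`", call. = FALSE)
  }
  if (any(trials$iti_onset_volume + shift_tr >= nt)) {
    stop("shifted pre-stimulus feature index falls beyond the run end; reject configuration",
         call. = FALSE)
  }

  side <- ceiling(nv^(1 / 3))
  coords <- arrayInd(seq_len(nv), .dim = c(side, side, side))

  kind <- rep("live", nv)
  kind[truth$dead_voxel_ids] <- "dead"
  kind[truth$noisy_voxel_ids] <- "noisy"
  base_mean <- ifelse(kind == "dead", 50, 100)
  marg_sd <- c(live = config$noise_sd, dead = 0.5, noisy = 12)[kind]

  states <- dplyr::left_join(
    trials, truth$latent_states,
    by = c("participant_id", "run", "block", "trial")
  )

  keys <- dplyr::distinct(trials, .data$participant_id, .data$run)
  purrr::pmap(keys, function(participant_id, run) {
    tr <- states[states$participant_id == participant_id & states$run == run, ]
    innov_sd <- marg_sd * sqrt(1 - config$ar1_coef^2)
    noise <- matrix(rnorm(nv * nt), nv, nt) * innov_sd
    if (config$ar1_coef != 0) {
      noise <- t(apply(noise, 1, function(e) {
        as.numeric(stats::filter(e, config$ar1_coef, method = "recursive"))
      }))
    }
    tcen <- seq_len(nt) - (nt + 1) / 2
    slope <- runif(nv, -config$drift_slope_range, config$drift_slope_range)
    dat <- base_mean + noise + outer(slope, tcen)
    sig_tr <- tr[tr$condition %in% signal_conditions, ]
    if (nrow(sig_tr) && config$n_informative_voxels > 0 && config$signal_effect != 0) {
      fv <- sig_tr$iti_onset_volume + shift_tr + 1L  # 1-based column
      sgn <- ifelse(sig_tr$state == "biased", 1, -1)
      amp <- config$signal_effect * config$noise_sd
      dat[truth$informative_voxel_ids, fv] <-
        dat[truth$informative_voxel_ids, fv] +
        matrix(sgn * amp, length(truth$informative_voxel_ids), length(fv), byrow = TRUE)
    }
    new_run_series(
      data = dat, tr_s = config$tr_s,
      block_bounds = tibble::tibble(block = tr$block[1], start = 0L,
                                    end = max(tr$onset_volume) + config$stim_tr),
      voxel_coords = coords, participant_id = participant_id, run = run
    )
  })
}

new_run_series <- function(data, tr_s, block_bounds, voxel_coords,
                           participant_id, run, normalized = FALSE,
                           retained = NULL) {
  stopifnot(is.matrix(data), tr_s > 0)
  bb <- block_bounds[order(block_bounds$start), ]
  if (nrow(bb) > 1 && any(bb$start[-1] < bb$end[-nrow(bb)])) {
    stop("block bounds must be disjoint", call. = FALSE)
  }
  if (any(bb$start < 0) || any(bb$end > ncol(data))) {
    stop("block bounds must lie within the run", call. = FALSE)
  }
  structure(list(data = data, tr_s = tr_s, block_bounds = bb,
                 voxel_coords = voxel_coords, participant_id = participant_id,
                 run = run, normalized = normalized, retained = retained),
            class = "run_series")
}

#' @export
print.run_series <- function(x, ...) {
  cat(sprintf("<run_series> %s run %s: %d voxels x %d volumes (TR %.3g s)%s\n",
              x$participant_id, x$run, nrow(x$data), ncol(x$data), x$tr_s,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Simulate a whole-brain parcellation
#'
#' Stand-in for an anatomical atlas: grows `n_regions` contiguous-ish regions
#' on a voxel grid by assigning every voxel to its nearest of `n_regions`
#' randomly seeded voxels (a lattice Voronoi partition). The default region
#' count matches the 166-region whole-brain atlas used for search-ROI sweeps.
#'
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @param n_regions Number of regions (each gets at least its seed voxel).
#' @param seed RNG seed.
#' @return An integer 3-D array of class `label_volume` with labels in
#'   `1:n_regions` covering every voxel.
#' @export
#' @examples
#' parc <- simulate_parcellation(c(6, 6, 6), n_regions = 4, seed = 1)
#' length(unique(as.vector(parc)))
simulate_parcellation <- function(grid_shape, n_regions = 166, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  nv <- prod(grid_shape)
  if (n_regions < 1 || n_regions > nv) {
    stop("`n_regions` must be between 1 and the number of in-brain voxels",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  coords <- arrayInd(seq_len(nv), .dim = grid_shape)
  centers <- coords[sample.int(nv, n_regions), , drop = FALSE]
  # squared distance of every voxel to every seed; nearest seed wins,
  # ties broken by lowest region id (max.col with ties.method = "first")
  d2 <- outer(rowSums(coords^2), rep(1, n_regions)) -
    2 * coords %*% t(centers) +
    outer(rep(1, nv), rowSums(centers^2))
  lab <- max.col(-d2, ties.method = "first")
  structure(array(as.integer(lab), dim = grid_shape), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s grid, %d regions\n",
              paste(dim(x), collapse = " x "), length(unique(as.vector(x)))))
  invisible(x)
}
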