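#' Configuration of a simulated DecABT block
#'
#' Decoded attentional-bias training (DecABT) presents a stimulus only when
#' the decoded probability of a biased attentional state exceeds a threshold:
#' during each trial's fixation, the decoder emits one probability per TR; the
#' first TR with probability strictly above `prob_threshold` triggers a
#' stimulus (gaming with probability `p_gaming`, else neutral). Gaming stimuli
#' carry the avoidance cue (green frame) and neutral stimuli the approach cue
#' (red frame). If no TR within `window_tr` TRs crosses the threshold, the
#' trial ends without a stimulus (NG trial).
#'
#' @param prob_threshold Trigger threshold on the decoded probability,
#'   strictly exceeded (default 0.95).
#' @param window_tr Fixation window per trial in TRs (default 15).
#' @param p_gaming Probability that a triggered stimulus is gaming (default
#'   0.7, matching the observed ~69% gaming appearance rate).
#' @param trials_per_block Number of trials; `NULL` (default) fits as many
#'   trials as the stream allows.
#' @param volumes_per_run Volumes per DecABT run (default 210).
#' @param post_trigger_tr Stimulus + response TRs consumed after a trigger
#'   (default 3).
#' @param seed RNG seed for the stimulus-type draws.
#' @return A list of class `closed_loop_config`.
#' @export
closed_loop_config <- function(prob_threshold = 0.95, window_tr = 15,
                               p_gaming = 0.7, trials_per_block = NULL,
                               volumes_per_run = 210, post_trigger_tr = 3,
                               seed = 1L) {
  stopifnot(prob_threshold > 0, prob_threshold < 1, window_tr >= 1,
            p_gaming >= 0, p_gaming <= 1, post_trigger_tr >= 0)
  structure(list(prob_threshold = prob_threshold,
                 window_tr = as.integer(window_tr),
                 p_gaming = p_gaming,
                 trials_per_block = if (is.null(trials_per_block)) NULL
                                    else as.integer(trials_per_block),
                 volumes_per_run = as.integer(volumes_per_run),
                 post_trigger_tr = as.integer(post_trigger_tr),
                 seed = as.integer(seed)),
            class = "closed_loop_config")
}

#' Simulate one DecABT block
#'
#' Walks a per-TR stream and applies the just-in-time trigger rule of
#' [closed_loop_config()]. The stream is either a numeric vector of
#' precomputed decoder probabilities (so the trigger logic is testable
#' independently of the decoder) or a TR x feature matrix decoded online with
#' `predict_islr(decoder, ...)`.
#'
#' @param stream Numeric probability vector, or matrix of per-TR feature
#'   vectors (rows = TRs).
#' @param config A [closed_loop_config()].
#' @param decoder An `islr_fit`; required when `stream` is a feature matrix.
#' @return A `decabt_session`: `events` (one row per observed TR: `tr`,
#'   `trial`, `within_trial_tr`, `probability`), `trials` (one row per trial:
#'   `outcome` triggered/NG, `trigger_tr`, `latency_tr`, `n_probs`,
#'   `stimulus`, `cue_colour`, `required_response`), and the `config`.
#' @export
run_decabt_block <- function(stream, config = closed_loop_config(),
                             decoder = NULL) {
  stopifnot(inherits(config, "closed_loop_config"))
  if (is.matrix(stream)) {
    if (is.null(decoder)) stop("a feature-matrix stream needs a `decoder`", call. = FALSE)
    if (ncol(stream) != decoder$feature_space_size) {
      stop("stream feature dimension does not match the decoder", call. = FALSE)
    }
    probs <- predict_islr(decoder, stream)$probability
  } else {
    probs <- as.numeric(stream)
    stopifnot(all(probs >= 0 & probs <= 1))
  }
  n_tr <- min(length(probs), config$volumes_per_run)
  set.seed(config$seed)

  events <- list(); trials <- list()
  cursor <- 1L; trial <- 0L
  repeat {
    if (!is.null(config$trials_per_block) && trial >= config$trials_per_block) break
    # a new trial needs a full NG window available
    if (cursor + config$window_tr - 1L > n_tr) break
    trial <- trial + 1L
    trig_at <- NA_integer_
    n_probs <- 0L
    for (k in seq_len(config$window_tr)) {
      p <- probs[cursor + k - 1L]
      n_probs <- n_probs + 1L
      events[[length(events) + 1L]] <- tibble::tibble(
        tr = cursor + k - 1L, trial = trial, within_trial_tr = k,
        probability = p
      )
      if (p > config$prob_threshold) { trig_at <- k; break }
    }
    if (is.na(trig_at)) {
      trials[[trial]] <- tibble::tibble(
        trial = trial, outcome = "NG", trigger_tr = NA_integer_,
        latency_tr = NA_integer_, n_probs = n_probs,
        stimulus = NA_character_, cue_colour = NA_character_,
        required_response = NA_character_
      )
      cursor <- cursor + config$window_tr
    } else {
      stim <- if (runif(1) < config$p_gaming) "gaming" else "neutral"
      trials[[trial]] <- tibble::tibble(
        trial = trial, outcome = "triggered", trigger_tr = cursor + trig_at - 1L,
        latency_tr = trig_at, n_probs = n_probs,
        stimulus = stim,
        cue_colour = if (stim == "gaming") "green" else "red",
        required_response = if (stim == "gaming") "avoidance" else "approach"
      )
      cursor <- cursor + trig_at + config$post_trigger_tr
    }
    if (cursor > n_tr) break
  }
  structure(list(events = dplyr::bind_rows(events),
                 trials = dplyr::bind_rows(trials),
                 config = config),
            class = "decabt_session")
}

#' @export
print.decabt_session <- function(x, ...) {
  ng <- sum(x$trials$outcome == "NG")
  cat(sprintf("<decabt_session> %d trial(s), %d NG; threshold %.2f, window %d TR\n",
              nrow(x$trials), ng, x$config$prob_threshold, x$config$window_tr))
  invisible(x)
}

#' Summaries across simulated DecABT blocks
#'
#' @param logs A `decabt_session` or list of them (one per block).
#' @return A one-row tibble: `n_blocks`, `n_trials`, `ng_mean` / `ng_sem`
#'   (NG count per block), `gaming_fraction` among triggered trials,
#'   `latency_mean_tr`, `latency_median_tr`.
#' @export
summarize_session <- function(logs) {
  if (inherits(logs, "decabt_session")) logs <- list(logs)
  if (!length(logs)) stop("no session logs supplied", call. = FALSE)
  stopifnot(all(vapply(logs, inherits, logical(1), "decabt_session")))
  per_block <- purrr::map_dfr(seq_along(logs), function(i) {
    tr <- logs[[i]]$trials
    tibble::tibble(block = i, n_trials = nrow(tr),
                   n_ng = sum(tr$outcome == "NG"),
                   n_gaming = sum(tr$stimulus == "gaming", na.rm = TRUE),
                   n_triggered = sum(tr$outcome == "triggered"))
  })
  lat <- unlist(lapply(logs, function(l) l$trials$latency_tr))
  lat <- lat[!is.na(lat)]
  tibble::tibble(
    n_blocks = nrow(per_block),
    n_trials = sum(per_block$n_trials),
    ng_mean = mean(per_block$n_ng),
    ng_sem = if (nrow(per_block) > 1) sd(per_block$n_ng) / sqrt(nrow(per_block)) else NA_real_,
    gaming_fraction = if (sum(per_block$n_triggered) > 0)
      sum(per_block$n_gaming) / sum(per_block$n_triggered) else NA_real_,
    latency_mean_tr = if (length(lat)) mean(lat) else NA_real_,
    latency_median_tr = if (length(lat)) median(lat) else NA_real_
  )
}
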