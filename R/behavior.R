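#' Trial-exclusion rules for approach-avoidance RT data
#'
#' The published exclusion rules are reconstructed as configurable filters:
#' wrong or missing responses, anticipations below an RT floor, and
#' per-participant slow outliers beyond `mean + rt_max_sd * sd`. For each
#' trial the mean and s.d. are computed over the participant's *other*
#' responded trials (leave-one-out, regardless of the current validity flag):
#' a single extreme value cannot inflate its own threshold, and filtering is
#' idempotent.
#'
#' @param rt_min RT floor in ms (default 150); set `NULL` to disable.
#' @param rt_max_sd Outlier cut in s.d. above the participant mean (default 3);
#'   `NULL` disables.
#' @param require_correct Drop wrong / missing responses (default `TRUE`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(rt_min = 150, rt_max_sd = 3, require_correct = TRUE) {
  structure(list(rt_min = rt_min, rt_max_sd = rt_max_sd,
                 require_correct = require_correct),
            class = "filter_config")
}

#' Flag inappropriate trials
#'
#' Applies the enabled [filter_config()] rules and sets `valid = 0` (with a
#' `filter_reason`) for failing trials. Trials already invalid stay invalid.
#'
#' @param trials A trial table (tibble with at least `participant_id`, `rt_ms`,
#'   `valid`; `response_correct` if `require_correct` is on).
#' @param rules A [filter_config()].
#' @return The trial table with updated `valid` and a `filter_reason` column.
#' @export
filter_trials <- function(trials, rules = filter_config()) {
  stopifnot(is.data.frame(trials), inherits(rules, "filter_config"))
  out <- tibble::as_tibble(trials)
  if (!"filter_reason" %in% names(out)) out$filter_reason <- NA_character_
  reason <- out$filter_reason
  bad <- out$valid == 0L

  if (isTRUE(rules$require_correct) && "response_correct" %in% names(out)) {
    hit <- !bad & (is.na(out$response_correct) | !out$response_correct | is.na(out$rt_ms))
    reason[hit] <- "bad_response"
    bad <- bad | hit
  }
  if (!is.null(rules$rt_min)) {
    hit <- !bad & !is.na(out$rt_ms) & out$rt_ms < rules$rt_min
    reason[hit] <- "rt_below_floor"
    bad <- bad | hit
  }
  if (!is.null(rules$rt_max_sd)) {
    # leave-one-out mean/s.d. over the participant's responded trials, so a
    # single extreme value cannot mask itself and repeated filtering is stable
    resp <- !is.na(out$rt_ms)
    mom <- out[resp, ] |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(n = dplyr::n(), s = sum(.data$rt_ms),
                       ssq = sum(.data$rt_ms^2), .groups = "drop")
    ix <- match(out$participant_id, mom$participant_id)
    n <- mom$n[ix]; s <- mom$s[ix]; ssq <- mom$ssq[ix]
    loo_mean <- (s - out$rt_ms) / (n - 1)
    loo_var <- pmax((ssq - out$rt_ms^2 - (n - 1) * loo_mean^2) / (n - 2), 0)
    hit <- !bad & resp & !is.na(n) & n >= 3 &
      out$rt_ms > loo_mean + rules$rt_max_sd * sqrt(loo_var)
    reason[hit] <- "rt_outlier"
    bad <- bad | hit
  }
  out$valid <- ifelse(bad, 0L, 1L)
  out$filter_reason <- reason
  removed_blocks <- out |>
    dplyr::group_by(.data$participant_id, .data$run, .data$block) |>
    dplyr::summarise(gone = all(.data$valid == 0L), .groups = "drop") |>
    dplyr::filter(.data$gone)
  if (nrow(removed_blocks)) {
    warning(sprintf("all trials removed in block(s): %s",
                    paste(sprintf("%s/run %s/block %s", removed_blocks$participant_id,
                                  removed_blocks$run, removed_blocks$block),
                          collapse = ", ")), call. = FALSE)
  }
  out
}

#' Block-wise neutral baselines
#'
#' For every (participant, run, block), the approach and avoidance baselines
#' are the arithmetic mean RTs of the valid neutral trials in that direction.
#' A baseline backed by fewer than `min_n` trials is undefined (`NA`), and
#' trials depending on it are later excluded rather than erroring.
#'
#' @param trials A (filtered) trial table.
#' @param min_n Minimum valid neutral trials per direction (default 1).
#' @return A tibble with one row per block: `BL_app`, `BL_avo`, `n_app`, `n_avo`.
#' @export
block_baselines <- function(trials, min_n = 1) {
  stopifnot(is.data.frame(trials))
  neutral <- dplyr::filter(trials, .data$condition == "neutral", .data$valid == 1L,
                           !is.na(.data$rt_ms))
  if (!nrow(dplyr::filter(trials, .data$valid == 1L))) {
    stop("no valid trials to compute baselines from", call. = FALSE)
  }
  blocks <- dplyr::distinct(trials, .data$participant_id, .data$run, .data$block)
  stats <- neutral |>
    dplyr::group_by(.data$participant_id, .data$run, .data$block, .data$direction) |>
    dplyr::summarise(bl = mean(.data$rt_ms), n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "direction",
                       values_from = c("bl", "n"),
                       values_fill = list(n = 0L))
  for (col in c("bl_approach", "bl_avoidance")) {
    if (!col %in% names(stats)) stats[[col]] <- NA_real_
  }
  for (col in c("n_approach", "n_avoidance")) {
    if (!col %in% names(stats)) stats[[col]] <- 0L
  }
  out <- dplyr::left_join(blocks, stats,
                          by = c("participant_id", "run", "block")) |>
    dplyr::transmute(
      .data$participant_id, .data$run, .data$block,
      BL_app = ifelse(!is.na(.data$n_approach) & .data$n_approach >= min_n,
                      .data$bl_approach, NA_real_),
      BL_avo = ifelse(!is.na(.data$n_avoidance) & .data$n_avoidance >= min_n,
                      .data$bl_avoidance, NA_real_),
      n_app = dplyr::coalesce(.data$n_approach, 0L),
      n_avo = dplyr::coalesce(.data$n_avoidance, 0L)
    )
  tibble::as_tibble(out)
}

#' Label trials as positive / negative attentional-bias states
#'
#' Implements the block-baseline rule: an approach trial is `positive` when
#' its RT is faster than the block's neutral approach baseline, an avoidance
#' trial is `positive` when slower than the avoidance baseline; the strict
#' opposites are `negative`, and exact ties or trials without a defined
#' baseline are `excluded`. With `condition = "gaming"` this is the real
#' trial-level bias index; with `condition = "neutral"` the same rule applied
#' to neutral trials yields the fake index used as a control (by default the
#' baseline then includes the trial itself, the literal definition; a
#' leave-one-out variant is available).
#'
#' @param trials A filtered trial table.
#' @param baselines Output of [block_baselines()] on the same table.
#' @param condition `"gaming"` (real index) or `"neutral"` (fake index).
#' @param fake_loo If `TRUE` and `condition = "neutral"`, each neutral trial is
#'   compared against a baseline recomputed without itself.
#' @return A tibble of the selected trials with `label`
#'   (`positive`/`negative`/`excluded`), `deviation_ms` (RT minus baseline),
#'   `index_kind` (`real`/`fake`) and `exclusion_reason`.
#' @export
label_trials <- function(trials, baselines, condition = c("gaming", "neutral"),
                         fake_loo = FALSE) {
  condition <- match.arg(condition)
  sel <- dplyr::filter(tibble::as_tibble(trials), .data$condition == !!condition)
  out <- dplyr::left_join(sel, baselines,
                          by = c("participant_id", "run", "block"))
  bl <- ifelse(out$direction == "approach", out$BL_app, out$BL_avo)
  if (condition == "neutral" && isTRUE(fake_loo)) {
    n_dir <- ifelse(out$direction == "approach", out$n_app, out$n_avo)
    bl <- ifelse(n_dir > 1, (n_dir * bl - out$rt_ms) / (n_dir - 1), NA_real_)
  }
  dev <- out$rt_ms - bl
  faster <- dev < 0
  positive <- ifelse(out$direction == "approach", faster, !faster)

  label <- dplyr::case_when(
    out$valid == 0L ~ "excluded",
    is.na(bl) ~ "excluded",
    dev == 0 ~ "excluded",
    positive ~ "positive",
    TRUE ~ "negative"
  )
  reason <- dplyr::case_when(
    out$valid == 0L ~ "invalid_trial",
    is.na(bl) ~ "undefined_baseline",
    dev == 0 ~ "tie_with_baseline",
    TRUE ~ NA_character_
  )
  out$label <- label
  out$deviation_ms <- ifelse(label == "excluded" & is.na(bl), NA_real_, dev)
  out$index_kind <- if (condition == "gaming") "real" else "fake"
  out$exclusion_reason <- reason
  out
}

#' Split-half reliability of the trial-level bias index
#'
#' For each participant and label (`positive`, `negative`), trials are ordered
#' chronologically (run, block, trial) and split into first and second halves;
#' the per-half mean RT deviations are correlated across participants and the
#' correlation is stepped up with the Spearman-Brown formula
#' `rho = 2 r / (1 + r)`.
#'
#' @param labeled Labelled trials from [label_trials()] (any number of
#'   participants; excluded trials are ignored).
#' @param method Correlation for the half-means: `"pearson"` (default) or
#'   `"spearman"`.
#' @return A tibble of class `reliability_result` with one row per label:
#'   `n_participants`, `r_half`, `rho_sb`, `p_value`. The per-participant half
#'   means sit in the `"halves"` attribute.
#' @export
split_half_reliability <- function(labeled, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  lab <- dplyr::filter(tibble::as_tibble(labeled), .data$label %in% c("positive", "negative"))
  halves <- lab |>
    dplyr::arrange(.data$participant_id, .data$run, .data$block, .data$trial) |>
    dplyr::group_by(.data$participant_id, .data$label) |>
    dplyr::mutate(.half = ifelse(dplyr::row_number() <= ceiling(dplyr::n() / 2), 1L, 2L)) |>
    dplyr::group_by(.data$participant_id, .data$label, .data$.half) |>
    dplyr::summarise(mean_dev = mean(.data$deviation_ms), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(id_cols = c("participant_id", "label"),
                       names_from = ".half", values_from = c("mean_dev", "n"),
                       names_sep = "_half")
  for (col in c("mean_dev_half1", "mean_dev_half2")) {
    if (!col %in% names(halves)) halves[[col]] <- NA_real_
  }

  res <- purrr::map_dfr(c("positive", "negative"), function(lb) {
    h <- dplyr::filter(halves, .data$label == lb)
    incomplete <- is.na(h$mean_dev_half1) | is.na(h$mean_dev_half2)
    if (any(incomplete)) {
      warning(sprintf("%d participant(s) lack '%s' trials in one half; dropped",
                      sum(incomplete), lb), call. = FALSE)
      h <- h[!incomplete, ]
    }
    if (nrow(h) < 3) {
      stop(sprintf("split-half reliability for label '%s' needs >= 3 participants, got %d",
                   lb, nrow(h)), call. = FALSE)
    }
    ct <- cor.test(h$mean_dev_half1, h$mean_dev_half2, method = method,
                   alternative = "two.sided", exact = FALSE)
    r <- unname(ct$estimate)
    tibble::tibble(label = lb, n_participants = nrow(h), r_half = r,
                   rho_sb = spearman_brown(r), p_value = ct$p.value)
  })
  structure(res, halves = halves,
            class = c("reliability_result", class(res)))
}

#' Spearman-Brown step-up correction
#'
#' `rho = 2 r / (1 + r)`, the predicted full-length reliability of a split-half
#' correlation `r`.
#'
#' @param r A correlation in `[-1, 1]`.
#' @return The corrected reliability.
#' @export
#' @examples
#' spearman_brown(0.5)  # 0.667
spearman_brown <- function(r) {
  stopifnot(all(is.na(r) | (r >= -1 & r <= 1)))
  2 * r / (1 + r)
}
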