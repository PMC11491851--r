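#' Group-level tests of decoding accuracy against chance
#'
#' One-sample two-sided t-tests of per-participant accuracies against the
#' theoretical chance level in every (ROI, condition) cell, with
#' Benjamini-Hochberg adjustment over the declared family — by construction,
#' all rows produced by one call (e.g. 7 ROIs x 4 conditions = 28 tests for
#' the ROI analysis, or 166 regions for the search-ROI analysis). Cohen's d
#' is the mean deviation from chance over its s.d.
#'
#' @param accuracies Tibble with columns `participant_id`, `roi`, `condition`,
#'   `accuracy` (any of `roi` / `condition` may be absent; cells are the
#'   distinct combinations of those present).
#' @param chance Chance level (default 0.5).
#' @param fdr_q FDR threshold used for the `significant` flag (default 0.05).
#' @return A tibble with one row per cell: `n`, `mean_accuracy`, `sem`,
#'   `t`, `df`, `p`, `cohens_d`, `p_fdr`, `significant`. Zero-variance cells
#'   report `NA` statistics.
#' @export
group_tests <- function(accuracies, chance = 0.5, fdr_q = 0.05) {
  acc <- tibble::as_tibble(accuracies)
  stopifnot(all(c("participant_id", "accuracy") %in% names(acc)))
  keys <- intersect(c("roi", "condition"), names(acc))
  if (dplyr::n_distinct(acc$participant_id) < 2) {
    stop("group tests need at least 2 participants", call. = FALSE)
  }
  out <- acc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sem = sd(.data$accuracy) / sqrt(dplyr::n()),
      .t = list(one_sample_t(.data$accuracy, chance)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider(".t")
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < fdr_q
  out
}

one_sample_t <- function(x, mu) {
  if (length(x) < 2 || sd(x) < .Machine$double.eps^0.5) {
    if (length(x) >= 2 && all(x == mu)) {
      return(list(t = 0, df = length(x) - 1, p = 1, cohens_d = 0))
    }
    return(list(t = NA_real_, df = length(x) - 1, p = NA_real_,
                cohens_d = NA_real_))
  }
  tt <- t.test(x, mu = mu, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohens_d = mean(x - mu) / sd(x))
}

#' Paired condition contrasts of decoding accuracy
#'
#' Paired two-sided t-tests between two conditions within each ROI, BH-adjusted
#' across the ROIs of the call.
#'
#' @param accuracies Tibble with `participant_id`, `roi`, `condition`, `accuracy`.
#' @param condition_a,condition_b The two condition levels to contrast.
#' @param fdr_q FDR threshold for the `significant` flag.
#' @return Tibble with one row per ROI: `mean_diff`, `t`, `df`, `p`,
#'   `cohens_dz`, `p_fdr`, `significant`.
#' @export
paired_condition_tests <- function(accuracies, condition_a, condition_b,
                                   fdr_q = 0.05) {
  acc <- tibble::as_tibble(accuracies)
  wide <- acc |>
    dplyr::filter(.data$condition %in% c(condition_a, condition_b)) |>
    tidyr::pivot_wider(id_cols = c("participant_id", "roi"),
                       names_from = "condition", values_from = "accuracy")
  out <- wide |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_diff = mean(.data[[condition_a]] - .data[[condition_b]]),
      .t = list({
        d <- .data[[condition_a]] - .data[[condition_b]]
        one_sample_t(d, 0)
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider(".t")
  names(out)[names(out) == "cohens_d"] <- "cohens_dz"
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < fdr_q
  out
}

#' Bootstrap subsample test for unequal group sizes
#'
#' Tests whether a statistic computed on a larger group survives matching the
#' smaller group's size: `B` subsamples of `n_sub` participants are drawn from
#' `group_a` without replacement within each draw, the statistic (default
#' `mean(subsample) - mean(group_b)`) is evaluated per draw, and the two-sided
#' p-value is `(2 * min(#stat <= 0, #stat >= 0) + 1) / (B + 1)`, capped at 1
#' (the +1 is a continuity correction so p is never 0). With
#' `method = "exhaustive"` every subset is enumerated and the exact
#' proportion `min(1, 2 * min(#<=0, #>=0) / N)` is returned.
#'
#' @param group_a Numeric per-participant statistics of the larger group.
#' @param group_b Numeric per-participant statistics of the smaller group.
#' @param n_sub Subsample size drawn from `group_a` (default `length(group_b)`).
#' @param B Number of bootstrap draws (default 100000).
#' @param seed RNG seed.
#' @param statistic Function of `(a_sub, b)` returning a scalar.
#' @param method `"resample"` (default) or `"exhaustive"`.
#' @return A one-row tibble: `p_value`, `n_draws`, `n_le`, `n_ge`, `observed`
#'   (the statistic on the full groups).
#' @export
bootstrap_balance_test <- function(group_a, group_b,
                                   n_sub = length(group_b), B = 100000L,
                                   seed = 1L,
                                   statistic = function(a_sub, b) mean(a_sub) - mean(b),
                                   method = c("resample", "exhaustive")) {
  method <- match.arg(method)
  if (n_sub > length(group_a)) {
    stop("`n_sub` exceeds the size of `group_a`", call. = FALSE)
  }
  if (method == "exhaustive") {
    subsets <- combn(length(group_a), n_sub)
    stats <- apply(subsets, 2, function(ix) statistic(group_a[ix], group_b))
    n_draws <- ncol(subsets)
    p <- min(1, 2 * min(sum(stats <= 0), sum(stats >= 0)) / n_draws)
  } else {
    stopifnot(B >= 1)
    set.seed(as.integer(seed))
    stats <- vapply(seq_len(B), function(i) {
      statistic(group_a[sample.int(length(group_a), n_sub)], group_b)
    }, numeric(1))
    n_draws <- B
    p <- min(1, (2 * min(sum(stats <= 0), sum(stats >= 0)) + 1) / (B + 1))
  }
  tibble::tibble(
    p_value = p, n_draws = n_draws,
    n_le = sum(stats <= 0), n_ge = sum(stats >= 0),
    observed = statistic(group_a, group_b)
  )
}
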