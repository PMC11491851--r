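#' Plot cross-validated decoding accuracy
#'
#' Per-(fold, resample) accuracies as points, fold means as crossbars, the
#' overall accuracy as a solid line and the chance level as a dashed line.
#'
#' @param object A `cv_result`.
#' @param chance Chance level to mark (default 0.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, chance = 0.5, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = object$accuracy, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::labs(x = "held-out run", y = "decoding accuracy",
                  title = sprintf("LORO-CV accuracy %.1f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot split-half reliability
#'
#' Per-participant mean RT deviations in the first versus second half of
#' trials, one panel per label, with the identity line.
#'
#' @param object A `reliability_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reliability_result <- function(object, ...) {
  halves <- attr(object, "halves")
  ggplot2::ggplot(halves, ggplot2::aes(x = .data$mean_dev_half1,
                                       y = .data$mean_dev_half2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(x = "first half mean deviation (ms)",
                  y = "second half mean deviation (ms)") +
    ggplot2::theme_minimal()
}

#' Plot a simulated DecABT session
#'
#' Per-TR decoded probabilities with the trigger threshold; triggered TRs are
#' marked and NG trials shaded.
#'
#' @param object A `decabt_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decabt_session <- function(object, ...) {
  ev <- object$events
  trig <- dplyr::filter(object$trials, .data$outcome == "triggered")
  trig_ev <- dplyr::semi_join(ev, trig, by = "trial") |>
    dplyr::group_by(.data$trial) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$tr, y = .data$probability)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$trial), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$config$prob_threshold,
                        linetype = "dashed") +
    ggplot2::geom_point(data = trig_ev, colour = "red", size = 2) +
    ggplot2::labs(x = "TR", y = "decoded bias probability") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-region search-ROI accuracies
#'
#' @param sweep Output of [search_roi_sweep()].
#' @param chance Chance level to mark.
#' @return A ggplot.
#' @export
plot_region_accuracy <- function(sweep, chance = 0.5) {
  dat <- dplyr::filter(sweep, .data$decodable)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(factor(.data$region),
                                                       .data$accuracy),
                                    y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$accuracy - .data$sem,
                                        ymax = .data$accuracy + .data$sem),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "region", y = "decoding accuracy") +
    ggplot2::theme_minimal()
}
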