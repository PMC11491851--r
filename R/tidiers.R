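#' Tidy an SLR fit
#'
#' @param x An `slr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term (intercept first): `term`,
#'   `estimate`, `alpha`, `selected`.
#' @export
tidy.slr_fit <- function(x, ...) {
  nm <- x$feature_names
  if (is.null(nm)) nm <- paste0("x", seq_along(x$coef))
  tibble::tibble(
    term = c("(Intercept)", nm),
    estimate = c(x$intercept, x$coef),
    alpha = c(x$control$intercept_alpha, x$alphas),
    selected = c(TRUE, seq_along(x$coef) %in% x$selected_features)
  )
}

#' @rdname tidy.slr_fit
#' @export
glance.slr_fit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$coef),
    n_selected = length(x$selected_features),
    converged = x$converged,
    n_em_iters = x$n_em_iters
  )
}

#' Tidy an iSLR fit
#'
#' @param x An `islr_fit`.
#' @param ... Unused.
#' @return One row per (stage, selected feature): `stage`, `feature`,
#'   `estimate`, `alpha`.
#' @export
tidy.islr_fit <- function(x, ...) {
  purrr::imap_dfr(x$stages, function(s, k) {
    loc <- match(s$selected, s$feature_ids)
    tibble::tibble(
      stage = k,
      feature = s$selected,
      estimate = s$fit$coef[loc],
      alpha = s$fit$alphas[loc]
    )
  })
}

#' @rdname tidy.islr_fit
#' @export
glance.islr_fit <- function(x, ...) {
  tibble::tibble(
    n_stages = length(x$stages),
    n_selected_total = sum(vapply(x$stages, function(s) length(s$selected), integer(1))),
    feature_space_size = x$feature_space_size,
    n_iter = x$n_iter
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-(fold, resample) accuracy table. `glance()`: a
#'   one-row summary.
#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_folds = nrow(x$fold_accuracies),
    n_resamples = x$n_resamples,
    n_predictions = nrow(x$per_trial)
  )
}

#' @export
tidy.reliability_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
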