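#' Hyperparameters for sparse Bayesian logistic regression
#'
#' @param prune_alpha Features whose ARD precision exceeds this are pruned
#'   (weight set exactly to 0); default `1e8`.
#' @param max_outer Maximum evidence-maximization (alpha update) iterations.
#' @param tol Convergence tolerance on `max |delta w|`.
#' @param intercept_alpha Fixed weak prior precision of the intercept, which
#'   is never pruned.
#' @param max_inner Maximum damped-Newton steps per MAP inner loop.
#' @return A list of class `slr_control`.
#' @export
slr_control <- function(prune_alpha = 1e8, max_outer = 200, tol = 1e-6,
                        intercept_alpha = 1e-6, max_inner = 25) {
  stopifnot(prune_alpha > 0, max_outer >= 1, tol > 0, intercept_alpha > 0,
            max_inner >= 1)
  structure(list(prune_alpha = prune_alpha, max_outer = as.integer(max_outer),
                 tol = tol, intercept_alpha = intercept_alpha,
                 max_inner = as.integer(max_inner)),
            class = "slr_control")
}

as_binary_y <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary (0/1)", call. = FALSE)
  as.numeric(y)
}

#' Fit a sparse Bayesian logistic regression (SLR) with ARD
#'
#' Bayesian logistic regression with an independent zero-mean Gaussian prior
#' per weight whose precision is optimized by evidence maximization: a damped
#' Newton inner loop finds the MAP weights, and MacKay fixed-point updates
#' `alpha_i <- gamma_i / w_i^2` with `gamma_i = 1 - alpha_i * Sigma_ii` (the
#' Laplace posterior variance) adapt the precisions. Features whose precision
#' exceeds `prune_alpha` are pruned: their weight is exactly zero and they
#' leave the model. The fit is deterministic given `x`, `y` and `control`.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Binary labels (0/1, logical, or 2-level factor); both classes must
#'   have at least 2 samples.
#' @param control An [slr_control()].
#' @return An object of class `slr_fit` with `intercept`, `coef` (length
#'   `ncol(x)`, pruned entries exactly 0), `alphas`, `selected_features`,
#'   `converged`, `n_em_iters`.
#' @export
fit_slr <- function(x, y, control = slr_control()) {
  x <- as.matrix(x)
  y <- as_binary_y(y)
  stopifnot(nrow(x) == length(y))
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("`y` has a single class", call. = FALSE)
  if (any(tab < 2)) stop("each class needs at least 2 samples", call. = FALSE)

  fit <- ard_logistic_cpp(x, y, control$prune_alpha, control$max_outer,
                          control$tol, control$intercept_alpha,
                          control$max_inner)
  structure(list(
    intercept = fit$weights[1],
    coef = fit$weights[-1],
    alphas = fit$alphas[-1],
    selected_features = sort(fit$selected + 1L),
    converged = fit$converged,
    n_em_iters = fit$n_em_iters,
    feature_names = colnames(x),
    control = control
  ), class = "slr_fit")
}

#' @export
print.slr_fit <- function(x, ...) {
  cat(sprintf("<slr_fit> %d/%d features selected; %s in %d iterations\n",
              length(x$selected_features), length(x$coef),
              if (x$converged) "converged" else "not converged", x$n_em_iters))
  invisible(x)
}

#' Predict class probabilities from an SLR fit
#'
#' Logistic link on the fitted weights; probabilities are clipped away from
#' 0 and 1 by `eps`.
#'
#' @param model An `slr_fit`.
#' @param x New data, samples x features (same feature count as at fit time).
#' @param eps Clipping margin (default 1e-12).
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict_slr <- function(model, x, eps = 1e-12) {
  stopifnot(inherits(model, "slr_fit"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$coef)) {
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 length(model$coef), ncol(x)), call. = FALSE)
  }
  p <- plogis(model$intercept + drop(x %*% model$coef))
  pmin(pmax(p, eps), 1 - eps)
}

#' @export
predict.slr_fit <- function(object, newdata, ...) predict_slr(object, newdata, ...)

#' Fit an iterative SLR (iSLR)
#'
#' Runs SLR repeatedly: the features selected at each iteration are removed
#' from the feature space, and the next iteration is fit on the remainder
#' only, yielding pairwise-disjoint selected sets. Iteration stops after
#' `n_iter` stages, when no features remain, or right after a stage that
#' selects none (an intercept-only stage still contributes a probability).
#'
#' @param x Numeric matrix, samples x features.
#' @param y Binary labels.
#' @param n_iter Maximum number of stages (default 10).
#' @param control An [slr_control()] shared by all stages.
#' @return An object of class `islr_fit`: `stages` (list of per-stage records
#'   with the `slr_fit`, the feature ids the stage saw, and the globally
#'   indexed selected set), `feature_space_size`, `n_iter`.
#' @export
fit_islr <- function(x, y, n_iter = 10, control = slr_control()) {
  x <- as.matrix(x)
  p <- ncol(x)
  remaining <- seq_len(p)
  stages <- list()
  for (k in seq_len(n_iter)) {
    if (!length(remaining)) break
    fit <- fit_slr(x[, remaining, drop = FALSE], y, control = control)
    selected_global <- remaining[fit$selected_features]
    stages[[k]] <- list(fit = fit, feature_ids = remaining,
                        selected = selected_global)
    remaining <- setdiff(remaining, selected_global)
    if (!length(selected_global)) break
  }
  structure(list(stages = stages, feature_space_size = p, n_iter = n_iter,
                 feature_names = colnames(x)),
            class = "islr_fit")
}

#' @export
print.islr_fit <- function(x, ...) {
  nsel <- vapply(x$stages, function(s) length(s$selected), integer(1))
  cat(sprintf("<islr_fit> %d stage(s) over %d features; selected per stage: %s\n",
              length(x$stages), x$feature_space_size,
              paste(nsel, collapse = ", ")))
  invisible(x)
}

#' Combine per-stage probabilities multiplicatively
#'
#' The iSLR test-time rule: with per-stage probabilities `p_k`, the combined
#' probability is `P = prod(p_k) / (prod(p_k) + prod(1 - p_k))` (computed in
#' log space), and the binary label is `P > 0.5`. The raw-product alternative
#' (`P = prod(p_k)` thresholded at 0.5) is available via `combine = "product"`.
#'
#' @param p Matrix of probabilities, samples x stages (or a vector for one
#'   sample).
#' @param combine `"normalized"` (default) or `"product"`.
#' @return Numeric vector of combined probabilities.
#' @export
#' @examples
#' combine_stage_probs(c(0.8, 0.9))  # 0.72 / (0.72 + 0.02) = 0.973
combine_stage_probs <- function(p, combine = c("normalized", "product")) {
  combine <- match.arg(combine)
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  stopifnot(all(p > 0 & p < 1))
  if (combine == "product") return(exp(rowSums(log(p))))
  lp <- rowSums(log(p))
  lq <- rowSums(log1p(-p))
  1 / (1 + exp(lq - lp))
}

#' Predict from an iSLR model
#'
#' @param model An `islr_fit`.
#' @param x New data in the full feature space of the fit.
#' @param combine Probability combination rule, see [combine_stage_probs()].
#' @param eps Per-stage probability clipping margin.
#' @return A tibble with `probability` (combined across stages) and `label`
#'   (1 if `probability > 0.5`).
#' @export
predict_islr <- function(model, x, combine = c("normalized", "product"),
                         eps = 1e-12) {
  stopifnot(inherits(model, "islr_fit"))
  combine <- match.arg(combine)
  if (!length(model$stages)) stop("model has no stages", call. = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != model$feature_space_size) {
    stop(sprintf("feature count mismatch: model space is %d, data has %d",
                 model$feature_space_size, ncol(x)), call. = FALSE)
  }
  P <- vapply(model$stages, function(s) {
    predict_slr(s$fit, x[, s$feature_ids, drop = FALSE], eps = eps)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) P <- matrix(P, nrow = 1)
  prob <- combine_stage_probs(P, combine = combine)
  tibble::tibble(probability = prob, label = as.integer(prob > 0.5))
}

#' @export
predict.islr_fit <- function(object, newdata, ...) predict_islr(object, newdata, ...)

#' Serialize an iSLR model to JSON
#'
#' Writes weights, precisions, per-stage selected indices and hyperparameters
#' so the model can be reloaded exactly with [read_islr_json()].
#'
#' @param model An `islr_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_islr_json <- function(model, path) {
  stopifnot(inherits(model, "islr_fit"))
  obj <- list(
    feature_space_size = model$feature_space_size,
    n_iter = model$n_iter,
    stages = lapply(model$stages, function(s) {
      list(feature_ids = s$feature_ids, selected = s$selected,
           intercept = s$fit$intercept, coef = s$fit$coef,
           alphas = s$fit$alphas, converged = s$fit$converged,
           n_em_iters = s$fit$n_em_iters, control = unclass(s$fit$control))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reload an iSLR model written by [write_islr_json()]
#'
#' @param path JSON file.
#' @return An `islr_fit`.
#' @export
read_islr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stages <- lapply(obj$stages, function(s) {
    feature_ids <- as.integer(unlist(s$feature_ids))
    selected <- as.integer(unlist(s$selected))
    fit <- structure(list(
      intercept = as.numeric(s$intercept),
      coef = as.numeric(unlist(s$coef)),
      alphas = as.numeric(unlist(s$alphas)),
      selected_features = sort(match(selected, feature_ids)),
      converged = isTRUE(s$converged),
      n_em_iters = as.integer(s$n_em_iters),
      feature_names = NULL,
      control = do.call(slr_control, s$control)
    ), class = "slr_fit")
    list(fit = fit, feature_ids = feature_ids, selected = selected)
  })
  structure(list(stages = stages,
                 feature_space_size = as.integer(obj$feature_space_size),
                 n_iter = as.integer(obj$n_iter), feature_names = NULL),
            class = "islr_fit")
}
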