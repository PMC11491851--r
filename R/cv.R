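#' Cross-condition decoding with leave-one-run-out structure
#'
#' Generalizes leave-one-run-out cross-validation to train and test feature
#' sets from (possibly) different conditions over the same voxel space and
#' runs: for each held-out run `r`, an iSLR is trained on the training-set
#' trials of all other runs and tested on the test-set trials of run `r`, so
#' the four condition crossings (gaming, gaming->neutral, neutral,
#' neutral->gaming) are directly comparable. Within each training fold the
#' majority class is downsampled without replacement to the minority size,
#' independently `n_resamples` times; fold accuracy is the mean over
#' resamples and the overall accuracy the mean over folds.
#'
#' When `train` and `test` are the same object this is exactly [loro_cv()].
#'
#' @param train,test `bias_features` objects sharing `voxel_ids`.
#' @param n_resamples Balancing resamples per fold (default 10).
#' @param seed RNG seed for the downsampling draws.
#' @param n_iter,control iSLR settings, see [fit_islr()].
#' @param combine Probability combination rule, see [combine_stage_probs()].
#' @return A `cv_result`: `accuracy` (mean over folds of mean over resamples),
#'   `per_fold` (fold x resample accuracies), `per_trial` (held-out
#'   predictions), `n_resamples`, `seed`.
#' @export
cross_condition_decode <- function(train, test, n_resamples = 10, seed = 1L,
                                   n_iter = 10, control = slr_control(),
                                   combine = "normalized") {
  stopifnot(inherits(train, "bias_features"), inherits(test, "bias_features"))
  if (!identical(train$voxel_ids, test$voxel_ids)) {
    stop("train and test feature sets use different retained voxel spaces",
         call. = FALSE)
  }
  if (dplyr::n_distinct(train$meta$participant_id) > 1 ||
      dplyr::n_distinct(test$meta$participant_id) > 1) {
    stop("decoding is per participant; split the feature sets first", call. = FALSE)
  }
  runs <- sort(unique(train$meta$run))
  if (length(runs) < 2) stop("leave-one-run-out needs at least 2 runs", call. = FALSE)

  set.seed(as.integer(seed))
  per_fold <- list()
  per_trial <- list()
  for (r in runs) {
    tr_idx <- which(train$meta$run != r)
    te_idx <- which(test$meta$run == r)
    ytr <- train$meta$y[tr_idx]
    if (length(unique(ytr)) < 2) {
      warning(sprintf("fold %s skipped: training data has a single class", r),
              call. = FALSE)
      next
    }
    if (!length(te_idx)) {
      warning(sprintf("fold %s skipped: no test trials in held-out run", r),
              call. = FALSE)
      next
    }
    pos <- tr_idx[ytr == 1]
    neg <- tr_idx[ytr == 0]
    n_min <- min(length(pos), length(neg))
    for (j in seq_len(n_resamples)) {
      bal <- balance_downsample(pos, neg)
      model <- fit_islr(train$X[bal, , drop = FALSE], train$meta$y[bal],
                        n_iter = n_iter, control = control)
      pred <- predict_islr(model, test$X[te_idx, , drop = FALSE],
                           combine = combine)
      correct <- pred$label == test$meta$y[te_idx]
      per_fold[[length(per_fold) + 1L]] <- tibble::tibble(
        fold = r, resample = j, n_test = length(te_idx),
        accuracy = mean(correct)
      )
      per_trial[[length(per_trial) + 1L]] <- tibble::tibble(
        fold = r, resample = j,
        participant_id = test$meta$participant_id[te_idx],
        run = test$meta$run[te_idx],
        trial = test$meta$trial[te_idx],
        direction = test$meta$direction[te_idx],
        y = test$meta$y[te_idx],
        probability = pred$probability,
        pred = pred$label,
        correct = correct
      )
    }
  }
  if (!length(per_fold)) stop("no usable folds", call. = FALSE)
  per_fold <- dplyr::bind_rows(per_fold)
  fold_means <- per_fold |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  structure(list(
    accuracy = mean(fold_means$accuracy),
    fold_accuracies = fold_means,
    per_fold = per_fold,
    per_trial = dplyr::bind_rows(per_trial),
    n_resamples = n_resamples,
    seed = as.integer(seed)
  ), class = "cv_result")
}

# one balancing draw: majority class downsampled without replacement to the
# minority size; a no-op (and no RNG use) when classes are already balanced
balance_downsample <- function(pos, neg) {
  n_min <- min(length(pos), length(neg))
  c(if (length(pos) > n_min) sample(pos, n_min) else pos,
    if (length(neg) > n_min) sample(neg, n_min) else neg)
}

#' Leave-one-run-out cross-validated decoding
#'
#' Each run serves once as the held-out test set; within every training fold
#' the majority class is randomly downsampled (without replacement) to the
#' minority size `n_resamples` times, an iSLR is fit per resample, and
#' accuracy is averaged over resamples then over folds.
#'
#' @inheritParams cross_condition_decode
#' @param features A `bias_features` object for one participant.
#' @return A `cv_result`, see [cross_condition_decode()].
#' @export
loro_cv <- function(features, n_resamples = 10, seed = 1L, n_iter = 10,
                    control = slr_control(), combine = "normalized") {
  cross_condition_decode(features, features, n_resamples = n_resamples,
                         seed = seed, n_iter = n_iter, control = control,
                         combine = combine)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> accuracy %.3f over %d fold(s) x %d resample(s)\n",
              x$accuracy, nrow(x$fold_accuracies), x$n_resamples))
  invisible(x)
}

#' All four condition crossings for one participant
#'
#' Runs [cross_condition_decode()] for gaming, gaming->neutral, neutral and
#' neutral->gaming over a shared fold structure and seed.
#'
#' @param gaming,neutral `bias_features` for the real (gaming) and fake
#'   (neutral) indices of the same participant and runs.
#' @param ... Passed to [cross_condition_decode()].
#' @return A tibble with one row per crossing: `condition`, `accuracy`, and a
#'   `result` list-column of `cv_result` objects.
#' @export
decode_condition_grid <- function(gaming, neutral, ...) {
  crossings <- list(
    gaming = list(gaming, gaming),
    `gaming->neutral` = list(gaming, neutral),
    neutral = list(neutral, neutral),
    `neutral->gaming` = list(neutral, gaming)
  )
  res <- purrr::imap(crossings, function(pair, nm) {
    cross_condition_decode(pair[[1]], pair[[2]], ...)
  })
  tibble::tibble(
    condition = names(res),
    accuracy = vapply(res, `[[`, numeric(1), "accuracy"),
    result = unname(res)
  )
}

#' Decoding accuracy split by trial direction
#'
#' Pools the held-out predictions of a `cv_result` and reports accuracy
#' separately for approach and avoidance trials. On the pooled predictions
#' the overall accuracy equals the trial-count-weighted mean of the two
#' directions; a direction absent from the held-out data gets `NA`.
#'
#' @param result A `cv_result`.
#' @return A tibble with rows `approach`, `avoidance` (`n` pooled predictions,
#'   `accuracy`) and the pooled overall accuracy in the `"overall"` attribute.
#' @export
direction_split_accuracy <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  pt <- result$per_trial
  out <- purrr::map_dfr(c("approach", "avoidance"), function(d) {
    rows <- pt[pt$direction == d, ]
    tibble::tibble(direction = d, n = nrow(rows),
                   accuracy = if (nrow(rows)) mean(rows$correct) else NA_real_)
  })
  structure(out, overall = mean(pt$correct))
}
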