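#' Voxel quality control
#'
#' Retains a voxel iff its raw (pre-normalization) mean over the whole run is
#' at least `mean_min` and its raw s.d. at most `sd_max`. The default
#' thresholds drop voxels with exceptionally low BOLD intensity (mean < 80)
#' and voxels with considerable variance (s.d. > 8).
#'
#' @param run A raw `run_series`.
#' @param mean_min,sd_max QC thresholds on the raw signal.
#' @return Sorted integer vector of retained voxel indices.
#' @export
voxel_qc <- function(run, mean_min = 80, sd_max = 8) {
  stopifnot(inherits(run, "run_series"))
  if (isTRUE(run$normalized)) {
    stop("voxel_qc() must be run on the raw series, before normalization",
         call. = FALSE)
  }
  m <- rowMeans(run$data)
  s <- apply(run$data, 1, sd)
  keep <- which(m >= mean_min & s <= sd_max)
  if (!length(keep)) {
    stop(sprintf("no voxels retained at mean >= %g and s.d. <= %g", mean_min, sd_max),
         call. = FALSE)
  }
  keep
}

#' Intersection of per-run retained voxel sets
#'
#' When a decoder is fit across several runs, the voxel space is the
#' intersection of the per-run QC survivors.
#'
#' @param runs List of raw `run_series`.
#' @param ... Passed to [voxel_qc()].
#' @return Sorted integer vector of voxels retained in every run.
#' @export
qc_intersect <- function(runs, ...) {
  keep <- Reduce(intersect, lapply(runs, voxel_qc, ...))
  if (!length(keep)) stop("QC intersection across runs is empty", call. = FALSE)
  sort(keep)
}

#' Detrend and z-score a run
#'
#' For every retained voxel and every block, removes an ordinary
#' least-squares linear trend and standardizes the residuals to mean 0 /
#' s.d. 1 within the block. Volumes outside any block are left untouched.
#' With `scope = "run"` the whole run is treated as a single block.
#'
#' @param run A raw `run_series`.
#' @param retained Voxel indices from [voxel_qc()] / [qc_intersect()];
#'   defaults to all voxels.
#' @param scope Detrending/normalization scope, `"block"` (default) or `"run"`.
#' @return The `run_series` with normalized data and `retained` recorded;
#'   voxels with a zero-variance residual in some block are dropped from
#'   `retained` with a warning.
#' @export
detrend_normalize <- function(run, retained = NULL,
                              scope = c("block", "run")) {
  stopifnot(inherits(run, "run_series"))
  scope <- match.arg(scope)
  if (isTRUE(run$normalized)) return(run)
  if (is.null(retained)) retained <- seq_len(nrow(run$data))
  bounds <- if (scope == "run") {
    tibble::tibble(block = NA_integer_, start = 0L, end = ncol(run$data))
  } else {
    run$block_bounds
  }
  dat <- run$data
  drop_vox <- integer(0)
  for (b in seq_len(nrow(bounds))) {
    cols <- (bounds$start[b] + 1L):bounds$end[b]
    m <- length(cols)
    if (m < 3) stop("block shorter than 3 volumes cannot be detrended", call. = FALSE)
    Y <- dat[retained, cols, drop = FALSE]
    tt <- seq_len(m) - (m + 1) / 2
    beta <- drop(Y %*% tt) / sum(tt^2)
    resid <- Y - rowMeans(Y) - outer(beta, tt)
    sds <- sqrt(rowSums(resid^2) / (m - 1))
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero)) {
      drop_vox <- union(drop_vox, retained[zero])
      sds[zero] <- 1
    }
    dat[retained, cols] <- resid / sds
  }
  if (length(drop_vox)) {
    warning(sprintf("%d voxel(s) with zero-variance residuals dropped from the retained set",
                    length(drop_vox)), call. = FALSE)
    retained <- setdiff(retained, drop_vox)
    if (!length(retained)) stop("no voxels left after dropping zero-variance residuals",
                                call. = FALSE)
  }
  run$data <- dat
  run$normalized <- TRUE
  run$retained <- sort(retained)
  run
}

#' Extract pre-stimulus feature vectors
#'
#' The feature of a trial is the normalized signal at volume
#' `iti_onset_volume + shift_tr` across the retained voxels: the first TR of
#' the pre-stimulus fixation period, read `shift_tr` volumes later to account
#' for the hemodynamic delay (5.25 s = 3 TRs at TR 1.75 s by default). Trials
#' whose shifted index falls outside the run or at/after the next trial's
#' stimulus onset are excluded and logged.
#'
#' @param runs A normalized `run_series` or list of them (one per run).
#' @param labeled Labelled trials from [label_trials()]; only `positive` /
#'   `negative` trials become rows.
#' @param shift_tr Hemodynamic shift in TRs (default 3).
#' @return A `bias_features` object: `X` (trials x retained voxels), `meta`
#'   (per-trial tibble with `y` = 1 for positive), `voxel_ids`, `shift_tr`.
#'   Excluded trials are recorded in the `"excluded"` attribute.
#' @export
extract_features <- function(runs, labeled, shift_tr = 3) {
  if (inherits(runs, "run_series")) runs <- list(runs)
  stopifnot(all(vapply(runs, inherits, logical(1), "run_series")))
  if (!all(vapply(runs, function(r) isTRUE(r$normalized), logical(1)))) {
    stop("runs must be normalized with detrend_normalize() first", call. = FALSE)
  }
  retained_sets <- lapply(runs, `[[`, "retained")
  if (length(unique(lapply(retained_sets, identity))) > 1) {
    stop("all runs must share the same retained voxel set (use qc_intersect())",
         call. = FALSE)
  }
  retained <- retained_sets[[1]]

  keys <- vapply(runs, function(r) paste(r$participant_id, r$run, sep = "\r"),
                 character(1))
  lab <- dplyr::filter(tibble::as_tibble(labeled),
                       .data$label %in% c("positive", "negative")) |>
    dplyr::arrange(.data$participant_id, .data$run, .data$block, .data$trial) |>
    dplyr::group_by(.data$participant_id, .data$run) |>
    dplyr::mutate(.next_onset = dplyr::lead(as.numeric(.data$onset_volume),
                                            default = Inf)) |>
    dplyr::ungroup()

  feat_vol <- lab$iti_onset_volume + shift_tr
  run_len <- vapply(runs, function(r) ncol(r$data), integer(1))
  lab_key <- paste(lab$participant_id, lab$run, sep = "\r")
  run_idx <- match(lab_key, keys)
  if (anyNA(run_idx)) stop("labelled trials reference runs not supplied", call. = FALSE)

  beyond <- feat_vol >= run_len[run_idx]
  overlap <- feat_vol >= lab$.next_onset
  drop <- beyond | overlap
  excluded <- lab[drop, c("participant_id", "run", "block", "trial")]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(beyond[drop], "shifted_index_beyond_run",
                              "inside_next_stimulus_window")
  } else {
    excluded$reason <- character(0)
  }

  keep <- which(!drop)
  X <- matrix(NA_real_, length(keep), length(retained))
  for (i in seq_along(keep)) {
    k <- keep[i]
    X[i, ] <- runs[[run_idx[k]]]$data[retained, feat_vol[k] + 1L]
  }
  colnames(X) <- paste0("v", retained)
  meta <- lab[keep, c("participant_id", "run", "block", "trial", "condition",
                      "direction", "label")]
  meta$y <- as.integer(meta$label == "positive")
  new_bias_features(X, meta, retained, shift_tr, excluded)
}

new_bias_features <- function(X, meta, voxel_ids, shift_tr, excluded = NULL) {
  stopifnot(nrow(X) == nrow(meta), !anyNA(X))
  structure(list(X = X, meta = tibble::as_tibble(meta),
                 voxel_ids = voxel_ids, shift_tr = shift_tr),
            excluded = excluded, class = "bias_features")
}

#' @export
print.bias_features <- function(x, ...) {
  cat(sprintf("<bias_features> %d trials x %d voxels (%d positive / %d negative)\n",
              nrow(x$X), ncol(x$X), sum(x$meta$y == 1), sum(x$meta$y == 0)))
  invisible(x)
}

#' @export
as_tibble.bias_features <- function(x, ...) {
  dplyr::bind_cols(x$meta, tibble::as_tibble(x$X))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Raw runs to feature matrix in one step
#'
#' Convenience pipeline: QC intersection across runs, per-block detrend and
#' z-score, then pre-stimulus feature extraction.
#'
#' @param runs List of raw `run_series`.
#' @param labeled Labelled trials from [label_trials()].
#' @param mean_min,sd_max QC thresholds, see [voxel_qc()].
#' @param shift_tr Hemodynamic shift, see [extract_features()].
#' @param detrend_scope `"block"` (default) or `"run"`, see [detrend_normalize()].
#' @return A `bias_features` object.
#' @export
build_features <- function(runs, labeled, mean_min = 80, sd_max = 8,
                           shift_tr = 3, detrend_scope = "block") {
  if (inherits(runs, "run_series")) runs <- list(runs)
  retained <- qc_intersect(runs, mean_min = mean_min, sd_max = sd_max)
  norm <- lapply(runs, detrend_normalize, retained = retained,
                 scope = detrend_scope)
  post <- Reduce(intersect, lapply(norm, `[[`, "retained"))
  if (length(post) < length(retained)) {
    norm <- lapply(norm, function(r) { r$retained <- post; r })
  }
  extract_features(norm, labeled, shift_tr = shift_tr)
}

#' Permute class labels of a feature set
#'
#' Uniform random permutation of the positive/negative labels, used for
#' empirical chance-level analyses.
#'
#' @param features A `bias_features` object.
#' @param seed RNG seed.
#' @return The feature set with permuted `y` (and `label`) columns.
#' @export
permute_labels <- function(features, seed = 1L) {
  stopifnot(inherits(features, "bias_features"))
  set.seed(as.integer(seed))
  ord <- sample.int(nrow(features$meta))
  features$meta$y <- features$meta$y[ord]
  features$meta$label <- features$meta$label[ord]
  features
}
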