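#' Search-ROI sweep: decode every region of a parcellation
#'
#' Repeats the full decoding pipeline (voxel QC, per-block detrend +
#' z-scoring, pre-stimulus feature extraction, balanced leave-one-run-out
#' iSLR cross-validation) independently inside every region of a
#' parcellation, for one participant. Regions are matched to voxels through
#' the integer lattice coordinates carried by the `run_series`.
#'
#' The per-region t and Cohen's d are computed over the fold-mean accuracies
#' against the chance level, mirroring the columns of a region accuracy
#' table; with several participants, run the sweep per participant and feed
#' the accuracies to [group_tests()].
#'
#' @param runs List of raw `run_series` for one participant.
#' @param labeled Labelled trials from [label_trials()].
#' @param parcellation A `label_volume` (or an integer vector giving the
#'   region of each voxel directly).
#' @param chance Chance accuracy (default 0.5).
#' @param ... Passed to [loro_cv()] (e.g. `n_resamples`, `seed`) and
#'   [build_features()] defaults apply for QC/extraction.
#' @return A tibble with one row per region: `region`, `n_voxels`,
#'   `n_retained`, `accuracy`, `sem`, `t`, `cohens_d`, `decodable`. Regions
#'   whose voxels all fail QC (or that cannot be cross-validated) are marked
#'   `decodable = FALSE` with `NA` accuracy.
#' @export
search_roi_sweep <- function(runs, labeled, parcellation, chance = 0.5, ...) {
  if (inherits(runs, "run_series")) runs <- list(runs)
  n_vox <- nrow(runs[[1]]$data)
  if (is.array(parcellation)) {
    coords <- runs[[1]]$voxel_coords
    stopifnot(max(coords) <= max(dim(parcellation)))
    region_of <- parcellation[cbind(coords[, 1], coords[, 2], coords[, 3])]
  } else {
    region_of <- as.integer(parcellation)
  }
  if (length(region_of) != n_vox) {
    stop("parcellation is not aligned with the run series voxels", call. = FALSE)
  }
  regions <- sort(unique(region_of))
  purrr::map_dfr(regions, function(reg) {
    vox <- which(region_of == reg)
    res <- tryCatch({
      sub_runs <- lapply(runs, function(r) {
        new_run_series(r$data[vox, , drop = FALSE], r$tr_s, r$block_bounds,
                       r$voxel_coords[vox, , drop = FALSE],
                       r$participant_id, r$run)
      })
      feats <- build_features(sub_runs, labeled)
      cv <- loro_cv(feats, ...)
      fold_acc <- cv$fold_accuracies$accuracy
      st <- one_sample_t(fold_acc, chance)
      tibble::tibble(region = reg, n_voxels = length(vox),
                     n_retained = length(feats$voxel_ids),
                     accuracy = cv$accuracy,
                     sem = sd(fold_acc) / sqrt(length(fold_acc)),
                     t = st$t, cohens_d = st$cohens_d, decodable = TRUE)
    }, error = function(e) {
      tibble::tibble(region = reg, n_voxels = length(vox), n_retained = 0L,
                     accuracy = NA_real_, sem = NA_real_, t = NA_real_,
                     cohens_d = NA_real_, decodable = FALSE)
    })
    res
  })
}
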