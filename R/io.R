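#' Read / write trial tables as TSV
#'
#' Column layout: `participant_id`, `run`, `block`, `trial`,
#' `condition` (gaming/neutral), `direction` (approach/avoidance), `rt_ms`,
#' `onset_volume` (0-based), `iti_onset_volume`, `valid` (0/1), plus any
#' labelling columns already added.
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns a tibble.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read a feature set as TSV plus a JSON sidecar
#'
#' The TSV holds one row per trial (metadata then voxel features); the JSON
#' sidecar records the retained voxel ids and provenance (hemodynamic shift).
#'
#' @param features A `bias_features` object.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_feature_set()` returns `path` invisibly;
#'   `read_feature_set()` returns a `bias_features`.
#' @export
write_feature_set <- function(features, path) {
  stopifnot(inherits(features, "bias_features"))
  readr::write_tsv(as_tibble(features), path)
  jsonlite::write_json(
    list(retained_voxel_ids = features$voxel_ids,
         shift_tr = features$shift_tr),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vox_cols <- paste0("v", side$retained_voxel_ids)
  meta <- tab[, setdiff(names(tab), vox_cols)]
  X <- as.matrix(tab[, vox_cols])
  new_bias_features(X, meta, as.integer(side$retained_voxel_ids),
                    side$shift_tr)
}

#' Write / read a DecABT session log
#'
#' Events are stored as JSON lines (one record per observed TR); the per-trial
#' outcomes and configuration ride along in a JSON sidecar so the session can
#' be reloaded exactly.
#'
#' @param session A `decabt_session`.
#' @param path Output path for the JSONL event stream; the sidecar is
#'   `<path>.json`.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a `decabt_session`.
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "decabt_session"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(session$events))) {
    writeLines(jsonlite::toJSON(as.list(session$events[i, ]), digits = NA,
                                auto_unbox = TRUE), con)
  }
  jsonlite::write_json(
    list(trials = session$trials, config = unclass(session$config)),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  events <- purrr::map_dfr(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  })
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg_args <- side$config
  cfg <- closed_loop_config(
    prob_threshold = cfg_args$prob_threshold, window_tr = cfg_args$window_tr,
    p_gaming = cfg_args$p_gaming,
    trials_per_block = cfg_args$trials_per_block,
    volumes_per_run = cfg_args$volumes_per_run,
    post_trigger_tr = cfg_args$post_trigger_tr, seed = cfg_args$seed
  )
  structure(list(events = events, trials = tibble::as_tibble(side$trials),
                 config = cfg),
            class = "decabt_session")
}

#' NIfTI export of masks and label volumes
#'
#' Masks and parcellations are written as 3-D NIfTI with the grid's affine as
#' sform; run series as 4-D NIfTI (x, y, z, volume) with the TR recorded in
#' `pixdim`. Reading restores the array and grid.
#'
#' @param mask A `roi_mask` or `label_volume` (any 3-D array works; an
#'   attached `vox_grid` provides the affine, else 2 mm isotropic is assumed).
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `write_mask_nifti()` returns `path` invisibly; `read_mask_nifti()`
#'   returns the array with the affine as attribute.
#' @export
write_mask_nifti <- function(mask, path) {
  grid <- attr(mask, "grid")
  arr <- array(as.numeric(mask), dim = dim(mask))
  img <- RNifti::asNifti(arr)
  if (!is.null(grid)) {
    xf <- structure(grid$affine, code = 2L)
    img <- RNifti::`sform<-`(img, xf)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  structure(arr, affine = unclass(RNifti::xform(img)))
}

#' Write a run series as 4-D NIfTI plus JSON sidecar
#'
#' Voxels are placed at their lattice coordinates in a dense 4-D volume;
#' the sidecar records TR, block bounds, voxel coordinates and ids so
#' [read_run_series_nifti()] can reconstruct the `run_series` exactly.
#'
#' @param run A `run_series`.
#' @param path NIfTI path; sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_run_series_nifti <- function(run, path) {
  stopifnot(inherits(run, "run_series"))
  dims <- apply(run$voxel_coords, 2, max)
  arr <- array(0, dim = c(dims, ncol(run$data)))
  for (v in seq_len(nrow(run$data))) {
    arr[run$voxel_coords[v, 1], run$voxel_coords[v, 2], run$voxel_coords[v, 3], ] <-
      run$data[v, ]
  }
  img <- RNifti::asNifti(arr, pixdim = c(2, 2, 2, run$tr_s))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(tr_s = run$tr_s,
         block_bounds = run$block_bounds,
         voxel_coords = run$voxel_coords,
         participant_id = run$participant_id, run = run$run,
         normalized = run$normalized, retained = run$retained),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_run_series_nifti
#' @export
read_run_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  coords <- as.matrix(side$voxel_coords)
  arr <- array(as.numeric(img), dim = dim(img))
  n_vol <- dim(arr)[4]
  dat <- matrix(NA_real_, nrow(coords), n_vol)
  for (v in seq_len(nrow(coords))) {
    dat[v, ] <- arr[coords[v, 1], coords[v, 2], coords[v, 3], ]
  }
  new_run_series(dat, side$tr_s, tibble::as_tibble(side$block_bounds),
                 coords, side$participant_id, side$run,
                 normalized = isTRUE(side$normalized),
                 retained = if (is.null(side$retained)) NULL
                            else as.integer(side$retained))
}
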