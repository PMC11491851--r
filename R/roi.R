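#' A voxel grid with a world (mm) affine
#'
#' Light container pairing array dimensions with a 4x4 RAS+ affine mapping
#' 1-based voxel indices to mm coordinates. By default the grid is 2 mm
#' isotropic and centred on the origin, so mm (0, 0, 0) falls at the grid
#' centre.
#'
#' @param dim Integer vector of 3 array dimensions.
#' @param spacing Voxel size in mm per axis (default 2 mm isotropic).
#' @param origin mm coordinate of voxel (1, 1, 1); default centres the grid.
#' @return A list of class `vox_grid` with `dim`, `affine`.
#' @export
vox_grid <- function(dim, spacing = c(2, 2, 2), origin = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), length(spacing) == 3,
            all(spacing > 0))
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  affine <- diag(4)
  affine[cbind(1:3, 1:3)] <- spacing
  affine[1:3, 4] <- origin - spacing  # voxel index 1 maps to `origin`
  structure(list(dim = dim, affine = affine), class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %s voxels, spacing %s mm\n",
              paste(x$dim, collapse = " x "),
              paste(signif(x$affine[cbind(1:3, 1:3)], 3), collapse = " x ")))
  invisible(x)
}

voxel_centers_mm <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$dim)), .dim = grid$dim)
  sweep(idx %*% t(grid$affine[1:3, 1:3]), 2, grid$affine[1:3, 4], `+`)
}

#' Spherical ROI mask on a voxel grid
#'
#' A voxel is included iff the Euclidean distance from its centre (in mm) to
#' `center_mm` is at most `radius_mm` (inclusive boundary). Radius 0 at a
#' voxel centre therefore yields exactly that voxel.
#'
#' @param center_mm Numeric length-3 mm coordinate of the sphere centre.
#' @param radius_mm Sphere radius in mm (>= 0).
#' @param grid A [vox_grid()].
#' @return A logical 3-D array of class `roi_mask` with the grid attached as
#'   attribute `"grid"`.
#' @export
sphere_mask <- function(center_mm, radius_mm, grid) {
  stopifnot(inherits(grid, "vox_grid"), length(center_mm) == 3,
            is.finite(radius_mm), radius_mm >= 0)
  centers <- voxel_centers_mm(grid)
  d2 <- rowSums(sweep(centers, 2, center_mm, `-`)^2)
  inside <- d2 <= radius_mm^2 + 1e-9
  if (!any(inside)) {
    stop("sphere does not cover any voxel centre (entirely off-grid or too small)",
         call. = FALSE)
  }
  structure(array(inside, dim = grid$dim), grid = grid, class = "roi_mask")
}

#' Union of ROI masks
#'
#' Voxelwise logical OR of masks defined on the same grid.
#'
#' @param masks List of `roi_mask` (or logical arrays of identical dimension).
#' @return A `roi_mask`.
#' @export
union_masks <- function(masks) {
  stopifnot(length(masks) >= 1)
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1) stop("masks live on different grids", call. = FALSE)
  grids <- Filter(Negate(is.null), lapply(masks, attr, "grid"))
  if (length(grids) > 1 &&
      !all(vapply(grids[-1], function(g) identical(g, grids[[1]]), logical(1)))) {
    stop("masks live on different grids", call. = FALSE)
  }
  out <- Reduce(`|`, masks)
  structure(array(out, dim = dims[[1]]),
            grid = if (length(grids)) grids[[1]] else NULL,
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s grid, %d voxel(s)\n",
              paste(dim(x), collapse = " x "), sum(x)))
  invisible(x)
}

#' Sphere specifications of the a-priori reward-circuit ROIs
#'
#' MNI mm coordinates and radii of the sphere-defined regions of interest:
#' bilateral ventral striatum (VS, 12 mm at x = +/-12, y = 10, z = -6),
#' ventromedial prefrontal cortex (vmPFC, 8 mm at 0, 46, -7), substantia
#' nigra (SN, 3 mm) and ventral tegmental area (VTA, 3 mm). The mesolimbic
#' composite ROI is the union of the SN, VTA and VS spheres.
#'
#' @return A tibble with columns `roi`, `hemisphere`, `x`, `y`, `z`,
#'   `radius_mm`.
#' @export
roi_sphere_specs <- function() {
  tibble::tribble(
    ~roi,     ~hemisphere, ~x,    ~y,    ~z,    ~radius_mm,
    "VS",     "left",      -12,   10,    -6,    12,
    "VS",     "right",     12,    10,    -6,    12,
    "vmPFC",  "midline",   0,     46,    -7,    8,
    "SN",     "left",      -10.1, -18.9, -11.6, 3,
    "SN",     "right",     11.3,  -18.7, -11.7, 3,
    "VTA",    "left",      -2.7,  -15.9, -13.9, 3,
    "VTA",    "right",     4.1,   -15.9, -13.9, 3
  )
}

#' Build a (possibly composite) ROI mask from sphere specs
#'
#' @param specs Rows of [roi_sphere_specs()] (or any tibble with `x`, `y`,
#'   `z`, `radius_mm`).
#' @param grid A [vox_grid()].
#' @return A `roi_mask`: the union of all spheres in `specs`.
#' @export
#' @examples
#' g <- vox_grid(c(40, 40, 30))
#' # mesolimbic composite: the six SN / VTA / VS spheres
#' specs <- subset(roi_sphere_specs(), roi %in% c("SN", "VTA", "VS"))
#' meso <- build_roi_mask(specs, g)
#' sum(meso)
build_roi_mask <- function(specs, grid) {
  stopifnot(nrow(specs) >= 1)
  masks <- purrr::pmap(specs[, c("x", "y", "z", "radius_mm")],
                       function(x, y, z, radius_mm) {
                         sphere_mask(c(x, y, z), radius_mm, grid)
                       })
  union_masks(masks)
}
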