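#' Voxel volume and ROI mask containers
#'
#' A `vox_volume` is a 3D array of intensities in Hounsfield units together
#' with per-axis voxel spacing (mm) and a physical origin (mm). A `roi_mask`
#' is an aligned 3D logical array marking the tumor region of interest; any
#' nonzero voxel of the source image counts as foreground.
#'
#' All feature computations are spacing-agnostic and operate in voxel space;
#' spacing and origin are carried for provenance and file round-trips only.
#'
#' @param data 3D numeric array of intensities (HU). Must be finite.
#' @param spacing numeric length-3, voxel size per axis in mm (positive).
#' @param origin numeric length-3, physical offset in mm.
#' @return An object of class `vox_volume`.
#' @examples
#' v <- vox_volume(array(rnorm(27), c(3, 3, 3)))
#' dim(v$data)
#' @export
vox_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stopf("volume must be 3D, got %d dimensions", length(dim(data)))
  if (!all(is.finite(data)))
    stopf("volume contains non-finite intensities")
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "vox_volume")
}

#' @rdname vox_volume
#' @param flags 3D array; nonzero entries mark the ROI.
#' @export
roi_mask <- function(flags) {
  flags <- as.array(flags)
  if (length(dim(flags)) != 3L)
    stopf("mask must be 3D")
  flags <- flags != 0
  n <- sum(flags)
  if (n < 1L) stopf("empty mask: no foreground voxel")
  structure(list(flags = flags, voxel_count = as.integer(n)),
            class = "roi_mask")
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vox_volume> %d x %d x %d, spacing %.3g x %.3g x %.3g mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$flags)
  cat(sprintf("<roi_mask> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], x$voxel_count))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$flags)))
    stopf("volume (%s) and mask (%s) shapes differ",
          paste(dim(volume$data), collapse = "x"),
          paste(dim(mask$flags), collapse = "x"))
  invisible(TRUE)
}

#' Extract the ROI bounding subvolume
#'
#' Crops volume and mask to the tight bounding box of the mask, expanded by
#' `pad` voxels on every side and clipped to the grid. Features depend only
#' on within-mask voxels, so values computed before and after extraction are
#' identical; cropping just bounds the work of the texture engines.
#'
#' @param volume a [vox_volume()].
#' @param mask an aligned [roi_mask()].
#' @param pad non-negative integer padding in voxels.
#' @return A list with elements `volume` and `mask`, cropped identically.
#' @export
extract_roi <- function(volume, mask, pad = 0L) {
  check_aligned(volume, mask)
  if (pad < 0) stopf("pad must be >= 0")
  idx <- which(mask$flags, arr.ind = TRUE)
  d <- dim(mask$flags)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  new_origin <- volume$origin + (lo - 1L) * volume$spacing
  list(volume = vox_volume(sub(volume$data), volume$spacing, new_origin),
       mask = roi_mask(sub(mask$flags)))
}
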