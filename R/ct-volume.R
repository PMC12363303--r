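#' CT-like volume container
#'
#' A minimal 3-D scalar volume with per-axis voxel spacing, an origin offset
#' and an acquisition time relative to injection start. Intensities are on a
#' Hounsfield-unit-like scale (air around -1000, soft tissue near 0-100,
#' iodinated contrast in the thousands).
#'
#' Voxel `i` along an axis with spacing `s` covers the interval
#' `((i-1)*s, i*s]` mm, so its center sits at `(i - 0.5)*s`. The third array
#' axis is the depth axis: index 1 is deepest tissue, the highest index is
#' exterior air above the skin.
#'
#' @param values 3-D numeric array of intensities (HU-like).
#' @param spacing numeric length-3, voxel spacing in mm per axis (all > 0).
#' @param origin numeric length-3 mm offset of the grid (default zeros).
#' @param acquisition_time_s scan time in seconds relative to injection
#'   start, or `NA` if unknown.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0),
                      acquisition_time_s = NA_real_) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (any(dim(values) < 1L)) stop("grid must be non-empty")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         acquisition_time_s = as.numeric(acquisition_time_s)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f] HU, t = %s s\n",
              min(x$values), max(x$values),
              format(x$acquisition_time_s)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

# volume of one voxel in mm^3
voxel_volume_mm3 <- function(volume) prod(volume$spacing)

#' Write / read a CT volume as NIfTI-1
#'
#' The voxel spacing is stored in the NIfTI header; origin and acquisition
#' time go to a small JSON sidecar (`<path>.json`) because NIfTI-1 has no
#' native slot for a scan-schedule timestamp.
#'
#' @param volume a [ct_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `write_ct_volume` returns `path` invisibly; `read_ct_volume`
#'   returns a [ct_volume()].
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  sidecar <- list(origin_mm = volume$origin,
                  acquisition_time_s = volume$acquisition_time_s)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  origin <- c(0, 0, 0)
  t_s <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$origin_mm)) origin <- as.numeric(meta$origin_mm)
    if (!is.null(meta$acquisition_time_s)) t_s <- as.numeric(meta$acquisition_time_s)
  }
  ct_volume(vals, spacing, origin, t_s)
}
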