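#' Extract the skin surface as a lateral height map
#'
#' For each lateral position, scans the depth axis from the exterior (the
#' top of the grid) inward and records the height of the first voxel whose
#' intensity reaches `air_threshold` — i.e. the top of the tissue. Heights
#' are in mm above the deep end of the grid. Columns containing no tissue
#' are marked missing (`NA`), not fatal.
#'
#' @param volume a [ct_volume()]; axis 3 is the depth axis with exterior air
#'   at the high-index end.
#' @param air_threshold intensity separating air from tissue (HU); any value
#'   well above air (-1000) and below soft tissue works, default -500.
#' @return An object of class `skin_surface`: `height_map` (matrix, mm),
#'   lateral `spacing` (mm).
#' @export
extract_skin_surface <- function(volume, air_threshold = -500) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- volume$values
  d <- dim(v)
  sz <- volume$spacing[3]
  hit <- v >= air_threshold
  # highest-index TRUE per column = first tissue voxel seen from the exterior
  idx <- apply(hit, c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) max(w) else NA_integer_
  })
  height <- idx * sz  # top face of the first tissue voxel
  structure(list(height_map = height, spacing = volume$spacing[1:2]),
            class = "skin_surface")
}

#' Half-ellipsoid volume
#'
#' Volume of half an ellipsoid with semi-axes a, b and height c:
#' `V = (2/3) * pi * a * b * c`, converted from mm^3 to mL. This is the
#' model used for the skin raised above its pre-injection surface.
#'
#' @param a,b lateral semi-axes (mm), >= 0.
#' @param c peak height (mm), >= 0.
#' @return Volume in mL.
#' @export
half_ellipsoid_volume <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("semi-axes must be >= 0")
  mm3_to_ml(2 / 3 * pi * a * b * c)
}

#' Measure skin distension from pre/post surface overlay
#'
#' Differences the post- and pre-injection skin-surface height maps,
#' thresholds the difference at `min_height_mm`, keeps the largest
#' connected lateral region (8-connectivity), and summarizes it as a
#' half-ellipsoid: `a`, `b` are half the axis-aligned lateral extents of
#' the region, `c` is the maximum height difference inside it. An empty
#' protrusion region yields an all-zero measurement, not an error.
#'
#' @param pre_surface,post_surface congruent [extract_skin_surface()]
#'   results.
#' @param min_height_mm minimum height difference counted as distension
#'   (mm); the default 0.5 mm suppresses voxel-rounding jitter.
#' @param time_s optional timestamp carried through to the result.
#' @return An object of class `distension_measurement`: `a_mm`, `b_mm`,
#'   `c_mm`, `volume_ml`, `time_s`.
#' @export
measure_distension <- function(pre_surface, post_surface, min_height_mm = 0.5,
                               time_s = NA_real_) {
  stopifnot(inherits(pre_surface, "skin_surface"),
            inherits(post_surface, "skin_surface"))
  if (!identical(dim(pre_surface$height_map), dim(post_surface$height_map)))
    stop("surfaces are not congruent (different lateral grids)")
  if (all(is.na(pre_surface$height_map)) || all(is.na(post_surface$height_map)))
    stop("surface contains no tissue (all columns missing)")
  delta <- post_surface$height_map - pre_surface$height_map
  delta[is.na(delta)] <- 0
  above <- delta >= min_height_mm
  if (!any(above)) {
    return(structure(list(a_mm = 0, b_mm = 0, c_mm = 0, volume_ml = 0,
                          time_s = time_s),
                     class = "distension_measurement"))
  }
  comps <- label_components(above, connectivity = 26L)  # 8-connectivity in 2-D
  region <- comps[[1L]]
  ai <- arrayInd(which(region), dim(region))
  sp <- pre_surface$spacing
  ext <- (apply(ai, 2, max) - apply(ai, 2, min) + 1) * sp
  a <- ext[1] / 2
  b <- ext[2] / 2
  cc <- max(delta[region])
  structure(list(a_mm = a, b_mm = b, c_mm = cc,
                 volume_ml = half_ellipsoid_volume(a, b, cc),
                 time_s = time_s),
            class = "distension_measurement")
}

#' @export
print.distension_measurement <- function(x, ...) {
  cat(sprintf(
    "<distension> a = %.2f, b = %.2f mm, height = %.2f mm, V = %.4g mL (t = %s s)\n",
    x$a_mm, x$b_mm, x$c_mm, x$volume_ml, format(x$time_s)))
  invisible(x)
}

#' Check pre/post volume alignment outside the injection region
#'
#' The overlay-based distension measurement assumes the pre- and
#' post-injection scans are aligned everywhere except where the injectate
#' changed the anatomy (reduced-respiration acquisition). This scores the
#' mean absolute intensity difference outside an exclusion region (the bleb
#' plus the distension cap), normalized by the noise s.d. For two aligned
#' scans differing only by independent Gaussian noise the expected score is
#' `E|N(0, 2 sd^2)| / sd = 2/sqrt(pi)` (about 1.13).
#'
#' @param pre,post congruent [ct_volume()]s.
#' @param exclusion_mask logical array marking the bleb and cap region to
#'   ignore.
#' @param noise_sd noise s.d. (HU) used for normalization; if `NULL`,
#'   estimated from the median absolute difference outside the exclusion.
#' @param tolerance maximum acceptable score (default 2, comfortably above
#'   the pure-noise expectation).
#' @return A list with `score`, `pass`, `mean_abs_diff_hu`, `noise_sd`.
#' @export
check_alignment <- function(pre, post, exclusion_mask = NULL,
                            noise_sd = NULL, tolerance = 2) {
  stopifnot(inherits(pre, "ct_volume"), inherits(post, "ct_volume"))
  if (!identical(dim(pre$values), dim(post$values)))
    stop("volumes are not congruent")
  keep <- if (is.null(exclusion_mask)) array(TRUE, dim(pre$values)) else !exclusion_mask
  if (!any(keep)) stop("exclusion region covers the whole grid")
  d <- (post$values - pre$values)[keep]
  mad_abs <- mean(abs(d))
  if (is.null(noise_sd)) {
    # |diff| ~ half-normal with sd sqrt(2)*noise_sd; median = sqrt(2)*sd*qnorm(.75)
    noise_sd <- stats::median(abs(d)) / (sqrt(2) * stats::qnorm(0.75))
  }
  score <- if (mad_abs == 0) 0 else mad_abs / noise_sd
  list(score = score, pass = score <= tolerance,
       mean_abs_diff_hu = mad_abs, noise_sd = noise_sd)
}

#' Average distension volume over a time window
#'
#' @param measurements list of [measure_distension()] results with
#'   timestamps.
#' @param window_s closed time window `(lo, hi)` in seconds; the default
#'   90-120 s covers the early post-injection plateau.
#' @return Mean `volume_ml` over measurements inside the window.
#' @export
distension_summary <- function(measurements, window_s = c(90, 120)) {
  times <- vapply(measurements, function(m) as.numeric(m$time_s), numeric(1))
  vols <- vapply(measurements, function(m) as.numeric(m$volume_ml), numeric(1))
  sel <- !is.na(times) & times >= window_s[1] & times <= window_s[2]
  if (!any(sel))
    stop(sprintf("no distension measurements in the [%g, %g] s window",
                 window_s[1], window_s[2]))
  mean(vols[sel])
}
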