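#' Specification of a layered-tissue CT phantom with an injection bleb
#'
#' The phantom reduces the abdominal anatomy to flat slabs stacked along the
#' depth axis (array axis 3): deep tissue at the bottom, a subcutaneous
#' layer, a thin skin layer, and exterior air above the skin surface. The
#' post-injection phantom adds (i) a high-contrast ellipsoidal bleb inside
#' the subcutaneous layer and (ii) a half-ellipsoidal raise of the skin
#' surface (the distension cap) centered laterally over the bleb.
#'
#' @param grid_shape integer length-3, voxel counts per axis.
#' @param spacing numeric length-3, mm per voxel per axis (anisotropic
#'   spacing, e.g. 3 mm slices, is supported).
#' @param background_hu intensity of the subcutaneous layer (HU-like).
#' @param skin_hu intensity of the skin layer.
#' @param deep_hu intensity of the deep (muscle-like) layer.
#' @param air_hu intensity of exterior air.
#' @param contrast_hu intensity inside the bleb; must exceed
#'   `background_hu + 5 * noise_sd` so the bleb is separable.
#' @param bleb_center numeric length-3, mm coordinates of the bleb center.
#' @param bleb_axes numeric length-3, bleb semi-axes (a, b, c) in mm; the
#'   third component is along the depth axis.
#' @param cap_axes numeric length-3, distension-cap semi-axes (a, b, height)
#'   in mm; `c(0, 0, 0)` means no distension.
#' @param surface_height_mm height of the (pre-injection) skin surface above
#'   the deep end of the grid; default 70% of the depth extent.
#' @param skin_thickness_mm thickness of the skin slab.
#' @param noise_sd i.i.d. Gaussian noise s.d. in HU (0 for noiseless).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         spacing = c(1, 1, 1),
                         background_hu = 50,
                         skin_hu = 150,
                         deep_hu = 60,
                         air_hu = -1000,
                         contrast_hu = 3000,
                         bleb_center = NULL,
                         bleb_axes = c(20, 15, 8),
                         cap_axes = c(10, 8, 4),
                         surface_height_mm = NULL,
                         skin_thickness_mm = 3,
                         noise_sd = 20,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  extent <- grid_shape * spacing
  if (is.null(surface_height_mm)) surface_height_mm <- 0.7 * extent[3]
  if (is.null(bleb_center)) {
    depth_mid <- (surface_height_mm - skin_thickness_mm) / 2
    bleb_center <- c(extent[1] / 2, extent[2] / 2, depth_mid + 4)
  }
  spec <- structure(
    list(grid_shape = grid_shape, spacing = spacing,
         background_hu = background_hu, skin_hu = skin_hu,
         deep_hu = deep_hu, air_hu = air_hu, contrast_hu = contrast_hu,
         bleb_center = as.numeric(bleb_center),
         bleb_axes = as.numeric(bleb_axes),
         cap_axes = as.numeric(cap_axes),
         surface_height_mm = surface_height_mm,
         skin_thickness_mm = skin_thickness_mm,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$bleb_axes <= 0))
    stop("all bleb semi-axes must be > 0")
  if (any(spec$cap_axes < 0))
    stop("cap semi-axes must be >= 0")
  if (spec$contrast_hu <= spec$background_hu + 5 * spec$noise_sd)
    stop("contrast_hu must exceed background_hu + 5*noise_sd; ",
         "the bleb would not be separable from tissue")
  extent <- spec$grid_shape * spec$spacing
  lo <- spec$bleb_center - spec$bleb_axes
  hi <- spec$bleb_center + spec$bleb_axes
  if (any(lo < 0) || any(hi > extent))
    stop(sprintf(
      "bleb extends outside the grid: it spans [%s] .. [%s] mm in a %s mm grid",
      paste(sprintf("%.1f", lo), collapse = ", "),
      paste(sprintf("%.1f", hi), collapse = ", "),
      paste(sprintf("%.1f", extent), collapse = ", ")))
  cap_lo <- spec$bleb_center[1:2] - spec$cap_axes[1:2]
  cap_hi <- spec$bleb_center[1:2] + spec$cap_axes[1:2]
  if (any(cap_lo < 0) || any(cap_hi > extent[1:2]) ||
      spec$surface_height_mm + spec$cap_axes[3] > extent[3])
    stop("distension cap extends outside the grid")
  invisible(spec)
}

# voxel-center coordinates along one axis, in mm
axis_centers <- function(n, s) (seq_len(n) - 0.5) * s

# rasterize an ellipsoid: TRUE where the voxel center is inside
rasterize_ellipsoid <- function(grid_shape, spacing, center, axes) {
  x <- (axis_centers(grid_shape[1], spacing[1]) - center[1]) / axes[1]
  y <- (axis_centers(grid_shape[2], spacing[2]) - center[2]) / axes[2]
  z <- (axis_centers(grid_shape[3], spacing[3]) - center[3]) / axes[3]
  q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  q <= 1
}

# half-ellipsoid cap profile over the lateral grid: extra surface height in
# mm at each lateral voxel center (0 outside the cap footprint)
cap_profile <- function(grid_shape, spacing, center_xy, cap_axes) {
  if (any(cap_axes[1:2] <= 0) || cap_axes[3] <= 0)
    return(matrix(0, grid_shape[1], grid_shape[2]))
  x <- (axis_centers(grid_shape[1], spacing[1]) - center_xy[1]) / cap_axes[1]
  y <- (axis_centers(grid_shape[2], spacing[2]) - center_xy[2]) / cap_axes[2]
  q <- outer(x^2, y^2, `+`)
  h <- cap_axes[3] * sqrt(pmax(0, 1 - q))
  h
}

# build a layered volume from a lateral height field (mm above the deep end)
layered_values <- function(spec, surface_height) {
  n <- spec$grid_shape
  zc <- axis_centers(n[3], spec$spacing[3])
  vals <- array(spec$air_hu, n)
  # broadcast: for each z slice, compare voxel-center depth with the column's
  # surface height and layer boundaries
  skin_bottom <- surface_height - spec$skin_thickness_mm
  deep_top <- 0.25 * spec$surface_height_mm  # deep slab: bottom quarter
  for (k in seq_len(n[3])) {
    z <- zc[k]
    slab <- matrix(spec$air_hu, n[1], n[2])
    slab[z <= surface_height] <- spec$skin_hu
    slab[z <= skin_bottom] <- spec$background_hu
    slab[z <= deep_top] <- spec$deep_hu
    vals[, , k] <- slab
  }
  vals
}

#' Generate a pre/post-injection phantom pair with ground truth
#'
#' The pre-injection volume is the layered slab phantom; the post-injection
#' volume is identical except that voxels inside the bleb ellipsoid take
#' `contrast_hu` and the skin surface is raised by the half-ellipsoid cap
#' profile. Independent Gaussian noise (s.d. `noise_sd`) is added to each
#' volume, deterministically from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `pre` and `post` ([ct_volume()]s) and
#'   `truth`, a list recording the exact bleb center/axes, cap axes, the
#'   rasterized bleb mask and its voxel volume in mL, and the analytic
#'   ellipsoid volume.
#' @export
generate_phantom_pair <- function(spec) {
  validate_phantom_spec(spec)
  res <- phantom_at(spec, bleb_axes = spec$bleb_axes, cap_axes = spec$cap_axes,
                    noise_seed_pre = spec$seed, noise_seed_post = spec$seed + 1L)
  res$pre$acquisition_time_s <- 0
  res$post$acquisition_time_s <- 0
  res
}

# core phantom builder shared by pair and series generators
phantom_at <- function(spec, bleb_axes, cap_axes,
                       noise_seed_pre = NULL, noise_seed_post = NULL) {
  n <- spec$grid_shape
  flat <- matrix(spec$surface_height_mm, n[1], n[2])
  pre_vals <- layered_values(spec, flat)
  cap <- cap_profile(n, spec$spacing, spec$bleb_center[1:2], cap_axes)
  post_vals <- if (all(cap == 0)) pre_vals else
    layered_values(spec, flat + cap)
  bleb <- rasterize_ellipsoid(n, spec$spacing, spec$bleb_center, bleb_axes)
  post_vals[bleb] <- spec$contrast_hu
  if (spec$noise_sd > 0) {
    if (!is.null(noise_seed_pre))
      pre_vals <- pre_vals + with_local_seed(
        noise_seed_pre, array(stats::rnorm(prod(n), 0, spec$noise_sd), n))
    if (!is.null(noise_seed_post))
      post_vals <- post_vals + with_local_seed(
        noise_seed_post, array(stats::rnorm(prod(n), 0, spec$noise_sd), n))
  }
  truth <- list(
    bleb_center_mm = spec$bleb_center,
    bleb_axes_mm = bleb_axes,
    cap_axes_mm = cap_axes,
    bleb_mask = bleb,
    bleb_voxel_volume_ml = mm3_to_ml(sum(bleb) * prod(spec$spacing)),
    bleb_analytic_volume_ml = mm3_to_ml(4 / 3 * pi * prod(bleb_axes)),
    cap_analytic_volume_ml = mm3_to_ml(2 / 3 * pi * prod(cap_axes)),
    surface_height_mm = spec$surface_height_mm
  )
  list(pre = ct_volume(pre_vals, spec$spacing),
       post = ct_volume(post_vals, spec$spacing),
       truth = truth)
}

#' Saturating bleb dispersion model
#'
#' Advances the bleb's semi-axes over the scan schedule. Lateral semi-axes
#' grow by a saturating factor `1 + growth * (1 - exp(-t / tau))`; the
#' depth semi-axis keeps its initial value, so the rasterized bleb volume is
#' non-decreasing in time. Hyaluronidase (HLN) is emulated by
#' `hln_factor >= 1`: it multiplies the lateral growth amplitude (more
#' dispersion) and divides the distension-cap height (less skin raise).
#'
#' @param initial_axes numeric length-3, bleb semi-axes at t = 0 (mm).
#' @param growth dimensionless saturating lateral growth amplitude
#'   (fractional increase as t -> Inf at `hln_factor = 1`).
#' @param tau_s saturation time constant (s).
#' @param hln_factor dimensionless multiplier >= 1 (1 = no HLN).
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(initial_axes = c(20, 15, 8), growth = 0.3,
                             tau_s = 120, hln_factor = 1) {
  if (hln_factor < 1) stop("hln_factor must be >= 1")
  if (growth < 0) stop("growth must be >= 0")
  if (tau_s <= 0) stop("tau_s must be > 0")
  structure(list(initial_axes = as.numeric(initial_axes), growth = growth,
                 tau_s = tau_s, hln_factor = hln_factor),
            class = "dispersion_model")
}

# bleb semi-axes at time t under the dispersion model
axes_at_time <- function(model, t) {
  g <- 1 + model$growth * model$hln_factor * (1 - exp(-t / model$tau_s))
  c(model$initial_axes[1] * g, model$initial_axes[2] * g,
    model$initial_axes[3])
}

#' Generate a timed post-injection phantom series
#'
#' One post-injection volume per scan time, with the bleb semi-axes advanced
#' by the dispersion model and the cap height divided by the model's
#' `hln_factor`. The default schedule follows a typical large-volume
#' injection imaging session: baseline plus 5, 30, 60, 90, 120, 180 and
#' 600 s.
#'
#' @param spec a [phantom_spec()]; its `bleb_axes` are ignored in favour of
#'   the model's `initial_axes`.
#' @param model a [dispersion_model()].
#' @param times_s non-negative, strictly increasing scan times (s).
#' @return A list with `pre` (the shared pre-injection [ct_volume()]) and
#'   `series`, a list of per-timepoint records `(time_s, volume, truth)`.
#' @export
generate_phantom_series <- function(spec, model,
                                    times_s = c(0, 5, 30, 60, 90, 120, 180, 600)) {
  if (any(times_s < 0) || any(diff(times_s) <= 0))
    stop("times_s must be non-negative and strictly increasing")
  cap <- spec$cap_axes
  cap[3] <- cap[3] / model$hln_factor
  # containment check at the final (largest) time
  final_axes <- axes_at_time(model, max(times_s))
  check_spec <- spec
  check_spec$bleb_axes <- final_axes
  check_spec$cap_axes <- cap
  validate_phantom_spec(check_spec)

  pre <- NULL
  series <- vector("list", length(times_s))
  for (i in seq_along(times_s)) {
    t <- times_s[i]
    res <- phantom_at(spec, bleb_axes = axes_at_time(model, t),
                      cap_axes = cap,
                      noise_seed_pre = if (i == 1L) spec$seed else NULL,
                      noise_seed_post = spec$seed + i)
    if (i == 1L) {
      pre <- res$pre
      pre$acquisition_time_s <- 0
    }
    vol <- res$post
    vol$acquisition_time_s <- t
    series[[i]] <- list(time_s = t, volume = vol, truth = res$truth)
  }
  list(pre = pre, series = series)
}
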