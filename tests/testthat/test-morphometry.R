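test_that("seeded segmentation recovers the truth mask on a noisy phantom", {
  spec <- small_phantom_spec(noise_sd = 20, seed = 3)
  pp <- generate_phantom_pair(spec)
  m <- segment_bleb(pp$post, c(32, 28, 16), threshold = 1000)
  expect_gte(dice_overlap(m$mask, pp$truth$bleb_mask), 0.95)
  # auto threshold lands between tissue and contrast and gives the same quality
  m_auto <- segment_bleb(pp$post, c(32, 28, 16), threshold = "auto")
  expect_gt(m_auto$threshold_hu, spec$background_hu)
  expect_lt(m_auto$threshold_hu, spec$contrast_hu)
  expect_gte(dice_overlap(m_auto$mask, pp$truth$bleb_mask), 0.95)
})

test_that("segmentation failure modes are explicit", {
  spec <- small_phantom_spec(noise_sd = 0)
  pp <- generate_phantom_pair(spec)
  expect_error(segment_bleb(pp$pre, c(32, 28, 16), threshold = 1000),
               "no-bleb-found")
  expect_error(segment_bleb(pp$post, c(2, 2, 2), threshold = 1000),
               "seed-outside-bleb")
  expect_error(segment_bleb(pp$post, c(999, 1, 1), threshold = 1000),
               "inside the grid")
})

test_that("the grown region stays inside the seeded blob of a two-blob volume", {
  vals <- array(50, c(60, 40, 40))
  mk <- function(center, axes) {
    x <- ((1:60 - 0.5) - center[1]) / axes[1]
    y <- ((1:40 - 0.5) - center[2]) / axes[2]
    z <- ((1:40 - 0.5) - center[3]) / axes[3]
    outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
  }
  blob1 <- mk(c(15, 20, 20), c(8, 6, 5))
  blob2 <- mk(c(45, 20, 20), c(8, 6, 5))
  vals[blob1 | blob2] <- 3000
  vol <- ct_volume(vals, c(1, 1, 1))
  m <- segment_bleb(vol, c(15, 20, 20), threshold = 1000)
  expect_true(all(!m$mask[blob2]))
  expect_gte(dice_overlap(m$mask, blob1), 0.99)
})

test_that("semi-axes are half the axis-aligned extents, in descending order", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  m1 <- structure(list(mask = one, spacing = c(1, 1, 1)), class = "bleb_mask")
  expect_equal(unname(measure_semi_axes(m1)), c(0.5, 0.5, 0.5))

  box <- array(FALSE, c(20, 20, 20)); box[1:10, 1:4, 1:2] <- TRUE
  m2 <- structure(list(mask = box, spacing = c(1, 2, 3)), class = "bleb_mask")
  expect_equal(unname(measure_semi_axes(m2)), c(5, 4, 3))

  spec <- small_phantom_spec(noise_sd = 0)
  pp <- generate_phantom_pair(spec)
  m3 <- segment_bleb(pp$post, c(32, 28, 16), threshold = 1000)
  ax <- measure_semi_axes(m3)
  expect_true(all(abs(ax - c(20, 15, 8)) <= 1))

  empty <- structure(list(mask = array(FALSE, c(3, 3, 3)), spacing = c(1, 1, 1)),
                     class = "bleb_mask")
  expect_error(measure_semi_axes(empty), "empty")
})

test_that("surface-area formula: sphere exactness, symmetry, oracle agreement, monotonicity", {
  for (r in c(0.5, 1, 7, 20))
    expect_equal(ellipsoid_surface_area(r, r, r), 4 * pi * r^2, tolerance = 1e-14)

  perms <- list(c(3, 2, 1), c(3, 1, 2), c(2, 3, 1), c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  vals <- vapply(perms, function(p) ellipsoid_surface_area(p[1], p[2], p[3]),
                 numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)

  # vs independent Simpson oracle across aspect ratios up to 10
  for (axes in list(c(2, 1, 1), c(5, 3, 1), c(10, 1, 1), c(10, 5, 2),
                    c(4, 4, 1), c(20, 15, 8))) {
    s_formula <- ellipsoid_surface_area(axes[1], axes[2], axes[3])
    s_true <- oracle_ellipsoid_surface(axes[1], axes[2], axes[3])
    expect_lt(abs(s_formula - s_true) / s_true, 0.02)
  }
  # the package's own quadrature agrees with the independent oracle
  expect_equal(ellipsoid_surface_area_quadrature(10, 5, 2),
               oracle_ellipsoid_surface(10, 5, 2), tolerance = 1e-4)

  # strictly increasing in each axis over a grid of triples
  grid <- expand.grid(a = c(1, 3, 8), b = c(1, 2, 5), c = c(0.5, 1, 4))
  for (i in seq_len(nrow(grid))) {
    s0 <- ellipsoid_surface_area(grid$a[i], grid$b[i], grid$c[i])
    expect_gt(ellipsoid_surface_area(grid$a[i] + 0.5, grid$b[i], grid$c[i]), s0)
    expect_gt(ellipsoid_surface_area(grid$a[i], grid$b[i] + 0.5, grid$c[i]), s0)
    expect_gt(ellipsoid_surface_area(grid$a[i], grid$b[i], grid$c[i] + 0.5), s0)
  }
  expect_error(ellipsoid_surface_area(0, 1, 1), "> 0")
})

test_that("mask volume converts voxel counts to millilitres", {
  cube <- array(FALSE, c(12, 12, 12)); cube[1:10, 1:10, 1:10] <- TRUE
  m <- structure(list(mask = cube, spacing = c(1, 1, 1)), class = "bleb_mask")
  expect_equal(mask_volume_ml(m), 1)

  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  m2 <- structure(list(mask = one, spacing = c(3, 1, 1)), class = "bleb_mask")
  expect_equal(mask_volume_ml(m2), 0.003)

  # phantom sized to the smaller injected volume: (4/3)pi*a*b*c = 4.5 mL
  axes <- c(14.086, 11, 7)  # abc = 1084.6 mm^3 -> 4.543 mL analytic
  spec <- phantom_spec(grid_shape = c(64, 56, 48), spacing = c(1, 1, 1),
                       bleb_center = c(32, 28, 16), bleb_axes = axes,
                       cap_axes = c(0, 0, 0), noise_sd = 0, seed = 2)
  pp <- generate_phantom_pair(spec)
  m3 <- segment_bleb(pp$post, c(32, 28, 16), threshold = 1000)
  analytic <- 4 / 3 * pi * prod(axes) / 1000
  expect_lt(abs(mask_volume_ml(m3) - analytic) / analytic, 0.10)
})

test_that("morphometry over a series: stability, HLN contrast, per-row failures", {
  spec <- small_phantom_spec(noise_sd = 10)
  spec$bleb_axes <- c(16, 12, 8)
  m0 <- dispersion_model(initial_axes = spec$bleb_axes, growth = 0)
  ser <- generate_phantom_series(spec, m0, times_s = c(0, 60, 600))
  tab <- surface_area_timeseries(ser$series, c(32, 28, 16), threshold = 1000)
  expect_true(all(tab$ok))
  expect_lt(diff(range(tab$surface_area_mm2)) / mean(tab$surface_area_mm2), 0.02)

  m_hln <- dispersion_model(initial_axes = spec$bleb_axes, growth = 0.2,
                            hln_factor = 1.5)
  m_ctl <- dispersion_model(initial_axes = spec$bleb_axes, growth = 0.2,
                            hln_factor = 1)
  t_hln <- surface_area_timeseries(
    generate_phantom_series(spec, m_hln, c(0, 600))$series,
    c(32, 28, 16), threshold = 1000)
  t_ctl <- surface_area_timeseries(
    generate_phantom_series(spec, m_ctl, c(0, 600))$series,
    c(32, 28, 16), threshold = 1000)
  expect_gt(t_hln$surface_area_mm2[2], t_ctl$surface_area_mm2[2])

  # a timepoint without contrast is recorded as a failed row, not an abort
  broken <- ser$series
  broken[[2]]$volume$values[broken[[2]]$volume$values > 1000] <- 50
  tab2 <- surface_area_timeseries(broken, c(32, 28, 16), threshold = 1000)
  expect_false(tab2$ok[2])
  expect_match(tab2$message[2], "no-bleb-found|seed-outside-bleb")
  expect_true(tab2$ok[1] && tab2$ok[3])

  expect_error(surface_area_timeseries(list(), c(1, 1, 1)), "empty")
})
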