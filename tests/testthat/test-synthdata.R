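test_that("phantom pair: pre and post differ only at the bleb when there is no cap", {
  spec <- small_phantom_spec(noise_sd = 0, cap = c(0, 0, 0))
  pp <- generate_phantom_pair(spec)
  outside <- !pp$truth$bleb_mask
  expect_identical(pp$pre$values[outside], pp$post$values[outside])
  expect_true(all(pp$post$values[pp$truth$bleb_mask] == spec$contrast_hu))
})

test_that("rasterized bleb volume matches the analytic ellipsoid volume", {
  spec <- small_phantom_spec()
  pp <- generate_phantom_pair(spec)
  analytic <- 4 / 3 * pi * 20 * 15 * 8 / 1000
  expect_lt(abs(pp$truth$bleb_voxel_volume_ml - analytic) / analytic, 0.05)
  # voxel-counting oracle: count centers inside the ellipsoid directly
  raster <- sum(pp$truth$bleb_mask)
  expect_equal(pp$truth$bleb_voxel_volume_ml, raster / 1000)
})

test_that("rasterization error vs analytic volume shrinks as spacing refines", {
  errs <- vapply(c(2, 1, 0.5), function(s) {
    spec <- phantom_spec(grid_shape = round(c(64, 56, 48) / s),
                         spacing = rep(s, 3), bleb_center = c(32, 28, 16),
                         bleb_axes = c(20, 15, 8), cap_axes = c(0, 0, 0),
                         noise_sd = 0, seed = 1)
    pp <- generate_phantom_pair(spec)
    abs(pp$truth$bleb_voxel_volume_ml - pp$truth$bleb_analytic_volume_ml) /
      pp$truth$bleb_analytic_volume_ml
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("generation is bit-identical for identical spec and seed", {
  spec <- small_phantom_spec(noise_sd = 20)
  a <- generate_phantom_pair(spec)
  b <- generate_phantom_pair(spec)
  expect_identical(a$pre$values, b$pre$values)
  expect_identical(a$post$values, b$post$values)
})

test_that("a bleb that would leave the grid is rejected with an explanation", {
  expect_error(
    phantom_spec(grid_shape = c(30, 30, 30), spacing = c(1, 1, 1),
                 bleb_center = c(15, 15, 10), bleb_axes = c(20, 15, 8),
                 cap_axes = c(0, 0, 0), noise_sd = 0),
    "outside the grid")
  expect_error(
    phantom_spec(contrast_hu = 100, background_hu = 50, noise_sd = 20),
    "separable")
})

test_that("phantom series: zero growth repeats the t = 0 phantom; times = 0 matches the pair", {
  spec <- small_phantom_spec(noise_sd = 0)
  model0 <- dispersion_model(initial_axes = spec$bleb_axes, growth = 0)
  ser <- generate_phantom_series(spec, model0, times_s = c(0, 30, 600))
  expect_identical(ser$series[[1]]$volume$values, ser$series[[2]]$volume$values)
  expect_identical(ser$series[[1]]$volume$values, ser$series[[3]]$volume$values)

  one <- generate_phantom_series(spec, model0, times_s = 0)
  pp <- generate_phantom_pair(spec)
  expect_identical(one$series[[1]]$volume$values, pp$post$values)
  expect_identical(one$pre$values, pp$pre$values)
})

test_that("hyaluronidase factor enlarges the truth surface area at every t > 0", {
  spec <- small_phantom_spec(noise_sd = 0)
  # slightly smaller bleb so the grown HLN bleb still fits the test grid
  spec$bleb_axes <- c(16, 12, 8)
  m1 <- dispersion_model(initial_axes = spec$bleb_axes, growth = 0.2, hln_factor = 1)
  m2 <- dispersion_model(initial_axes = spec$bleb_axes, growth = 0.2, hln_factor = 1.5)
  times <- c(0, 30, 120, 600)
  s1 <- generate_phantom_series(spec, m1, times)
  s2 <- generate_phantom_series(spec, m2, times)
  for (i in 2:length(times)) {
    ax1 <- s1$series[[i]]$truth$bleb_axes_mm
    ax2 <- s2$series[[i]]$truth$bleb_axes_mm
    expect_gt(ellipsoid_surface_area(ax2[1], ax2[2], ax2[3]),
              ellipsoid_surface_area(ax1[1], ax1[2], ax1[3]))
  }
  # rasterized bleb volume is non-decreasing over the schedule
  vols <- vapply(s2$series, function(el) el$truth$bleb_voxel_volume_ml, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("simulated pressure traces follow the piecewise rise/decay model", {
  prot <- injection_protocol(4.5, 10)
  spec <- pressure_sim_spec(prot, baseline_kpa = 1.5, A1 = 10, A2 = 5,
                            k1 = 0.5, k2 = 0.05, noise_sd = 0, t_start_s = 5)
  tr <- generate_pressure_trace(spec)
  t_cess <- attr(tr, "t_cess_s")
  expect_equal(t_cess, 32)
  expect_equal(tr$pressure_kpa[tr$time_s == t_cess], 1.5 + 10 + 5)
  # continuity at cessation: one-sample jump bounded by the model increment
  i_cess <- which.min(abs(tr$time_s - t_cess))
  p_before <- tr$pressure_kpa[i_cess - 1L]
  p_after <- tr$pressure_kpa[i_cess + 1L]
  increment <- (10 + 5) / 27 * 0.1 + (10 * 0.5 + 5 * 0.05) * 0.1
  expect_lt(max(abs(c(p_before, p_after) - (1.5 + 15))), increment + 1e-12)

  # closed-form decay sample: A2 = 0, value at t_cess + 2 is baseline + A1/e
  spec1 <- pressure_sim_spec(prot, baseline_kpa = 1.5, A1 = 10, A2 = 0,
                             k1 = 0.5, k2 = 0.5, noise_sd = 0, t_start_s = 5)
  tr1 <- generate_pressure_trace(spec1)
  expect_equal(tr1$pressure_kpa[tr1$time_s == 34], 1.5 + 10 * exp(-1),
               tolerance = 1e-12)
})

test_that("trace noise is zero-mean at the CLT scale and seeded deterministically", {
  prot <- injection_protocol(4.5, 10)
  spec <- pressure_sim_spec(prot, noise_sd = 0.5, duration_s = 180, seed = 9)
  noisy <- generate_pressure_trace(spec)
  spec0 <- spec; spec0$noise_sd <- 0
  clean <- generate_pressure_trace(spec0)
  resid <- noisy$pressure_kpa - clean$pressure_kpa
  n <- length(resid)
  expect_gte(n, 1000)
  expect_lt(abs(mean(resid)), 4 * 0.5 / sqrt(n))
  again <- generate_pressure_trace(spec)
  expect_identical(noisy$pressure_kpa, again$pressure_kpa)
})

test_that("invalid pressure simulation specs are rejected", {
  prot <- injection_protocol(4.5, 10)
  expect_error(pressure_sim_spec(prot, k1 = 0.05, k2 = 0.5), "k1 >= k2")
  expect_error(pressure_sim_spec(prot, k1 = 0.5, k2 = -0.1), "k1 >= k2")
  expect_error(pressure_sim_spec(prot, A1 = -1), ">= 0")
  expect_error(pressure_sim_spec(prot, duration_s = 100), "120 s")
})
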