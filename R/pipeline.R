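#' Configuration of an in-silico injection experiment
#'
#' Describes a factorial study: injection volumes crossed with
#' with/without-hyaluronidase arms, `n` replicates each, imaged over a scan
#' schedule and recorded by an inline pressure sensor. Defaults replicate a
#' two-volume (4.5 and 9 mL at 10 mL/min) design with n = 3 per arm and the
#' schedule baseline, 5, 30, 60, 90, 120, 180, 600 s.
#'
#' Generator settings per arm are derived from the protocol: bleb semi-axes
#' are scaled so the analytic ellipsoid volume equals the injected volume;
#' HLN arms use a lateral dispersion multiplier > 1 (more spread, smaller
#' cap) and reduced pressure amplitudes.
#'
#' @param volumes_ml injection volumes (mL) to cross with the HLN factor.
#' @param n replicates per arm (>= 2 for statistics).
#' @param scan_times_s scan schedule (s).
#' @param seed base integer seed; per-replicate seeds are derived from it
#'   and are unique.
#' @param hln_factor dispersion multiplier for HLN arms (>= 1).
#' @param hln_pressure_factor multiplier (< 1) on pressure amplitudes in HLN
#'   arms.
#' @param spacing_mm phantom voxel spacing.
#' @param grid_shape phantom grid.
#' @param threshold segmentation threshold (HU) or `"auto"`.
#' @param min_height_mm distension threshold (mm).
#' @param distension_window_s averaging window for distension volume (s).
#' @param noise_sd_hu CT noise (HU).
#' @param pressure_noise_frac pressure noise as a fraction of peak amplitude.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(volumes_ml = c(4.5, 9), n = 3,
                              scan_times_s = c(0, 5, 30, 60, 90, 120, 180, 600),
                              seed = 1L,
                              hln_factor = 1.5,
                              hln_pressure_factor = 0.6,
                              spacing_mm = c(1.5, 1.5, 1.5),
                              grid_shape = c(80, 80, 44),
                              threshold = 1000,
                              min_height_mm = 0.5,
                              distension_window_s = c(90, 120),
                              noise_sd_hu = 20,
                              pressure_noise_frac = 0.02) {
  if (n < 1) stop("n must be >= 1")
  arms <- expand.grid(volume_ml = volumes_ml, hln = c(FALSE, TRUE),
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(arms = arms, n = as.integer(n),
                 scan_times_s = scan_times_s, seed = as.integer(seed),
                 hln_factor = hln_factor,
                 hln_pressure_factor = hln_pressure_factor,
                 spacing_mm = spacing_mm, grid_shape = grid_shape,
                 threshold = threshold, min_height_mm = min_height_mm,
                 distension_window_s = distension_window_s,
                 noise_sd_hu = noise_sd_hu,
                 pressure_noise_frac = pressure_noise_frac),
            class = "experiment_config")
}

# bleb semi-axes (a, b, c) whose ellipsoid volume equals volume_ml, with a
# flattened aspect typical of subcutaneous depots (a : b : c = 2.4 : 2.1 : 1)
bleb_axes_for_volume <- function(volume_ml) {
  ratio <- c(2.4, 2.1, 1)
  scale <- (volume_ml * 1000 * 3 / (4 * pi * prod(ratio)))^(1 / 3)
  ratio * scale
}

# phantom + pressure generator settings for one arm; each replicate carries
# ~5% lognormal between-subject variability on bleb and cap geometry and on
# pressure amplitudes (animals differ), seeded from the replicate seed
arm_generators <- function(config, volume_ml, hln, seed) {
  axes <- bleb_axes_for_volume(volume_ml)
  jit <- with_local_seed(seed + 900000L, exp(stats::rnorm(4, 0, 0.05)))
  axes <- axes * jit[1:3]
  cap <- c(0.6 * axes[1], 0.6 * axes[2], 0.45 * axes[3]) * jit[4]
  extent <- config$grid_shape * config$spacing_mm
  surface_h <- 0.72 * extent[3]
  center_z <- (surface_h - 3) / 2 + 2
  spec <- phantom_spec(
    grid_shape = config$grid_shape, spacing = config$spacing_mm,
    bleb_center = c(extent[1] / 2, extent[2] / 2, center_z),
    bleb_axes = axes, cap_axes = cap,
    surface_height_mm = surface_h, noise_sd = config$noise_sd_hu,
    seed = seed)
  model <- dispersion_model(
    initial_axes = axes, growth = 0.2, tau_s = 120,
    hln_factor = if (hln) config$hln_factor else 1)
  protocol <- injection_protocol(volume_ml, 10, hln = hln)
  pf <- if (hln) config$hln_pressure_factor else 1
  # peak pressure grows with injected volume; HLN lowers it and speeds decay
  A_tot <- (20 + (volume_ml - 4.5) / 4.5 * 10) * pf *
    with_local_seed(seed + 910000L, exp(stats::rnorm(1, 0, 0.05)))
  kf <- if (hln) 1.3 else 1
  psim <- pressure_sim_spec(
    protocol, baseline_kpa = 2,
    A1 = 0.7 * A_tot, A2 = 0.3 * A_tot,
    k1 = 0.5 * kf, k2 = 0.05 * kf,
    noise_sd = config$pressure_noise_frac * A_tot,
    rate_hz = 10, t_start_s = 5, seed = seed + 500000L)
  list(phantom = spec, model = model, protocol = protocol, pressure = psim)
}

#' Run a full in-silico injection experiment
#'
#' For every arm and replicate: generates the phantom series and pressure
#' trace, runs bleb morphometry over the schedule, measures distension per
#' timepoint, and extracts the four study endpoints — bleb surface area at
#' the final (600 s / 10 min) scan, distension volume averaged over the
#' configured window, maximum pressure within 2 s of cessation, and the
#' effective decay constant of the post-injection pressure decay. Stage
#' failures are recorded per replicate; an arm aborts only if all its
#' replicates fail. Finishes with per-endpoint two-sample t-tests of HLN vs
#' control within each volume (skipped with a notice when `n < 2`).
#'
#' @param config an [experiment_config()].
#' @return A list with `results` (one row per replicate) and `comparisons`
#'   (one [two_sample_t()] record per endpoint and volume, or `NULL` when
#'   statistics are skipped).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  final_t <- max(config$scan_times_s)
  rows <- list()
  rep_counter <- 0L
  for (a in seq_len(nrow(config$arms))) {
    volume_ml <- config$arms$volume_ml[a]
    hln <- config$arms$hln[a]
    arm_ok <- FALSE
    for (r in seq_len(config$n)) {
      rep_counter <- rep_counter + 1L
      seed <- config$seed + 1000L * rep_counter
      gen <- arm_generators(config, volume_ml, hln, seed)
      row <- data.frame(volume_ml = volume_ml, hln = hln, replicate = r,
                        seed = seed, surface_area_mm2 = NA_real_,
                        distension_ml = NA_real_, max_pressure_kpa = NA_real_,
                        keff_per_s = NA_real_, ok = FALSE, message = "")
      res <- tryCatch({
        ph <- generate_phantom_series(gen$phantom, gen$model,
                                      config$scan_times_s)
        seed_vox <- as.integer(round(gen$phantom$bleb_center /
                                       gen$phantom$spacing))
        morpho <- surface_area_timeseries(
          ph$series, seed_vox, threshold = config$threshold)
        s_final <- morpho$surface_area_mm2[morpho$time_s == final_t]
        pre_surf <- extract_skin_surface(ph$pre)
        dists <- lapply(ph$series, function(el) {
          measure_distension(pre_surf, extract_skin_surface(el$volume),
                             config$min_height_mm, time_s = el$time_s)
        })
        dist_ml <- distension_summary(dists, config$distension_window_s)
        trace <- generate_pressure_trace(gen$pressure)
        pk <- max_pressure(trace)
        fit <- fit_decay(trace)
        row$surface_area_mm2 <- s_final
        row$distension_ml <- dist_ml
        row$max_pressure_kpa <- pk$max_kpa
        row$keff_per_s <- fit$keff
        row$ok <- TRUE
        row
      }, error = function(e) {
        row$message <- conditionMessage(e)
        row
      })
      if (res$ok) arm_ok <- TRUE
      rows[[rep_counter]] <- res
    }
    if (!arm_ok)
      stop(sprintf("all replicates failed in arm volume = %g mL, hln = %s",
                   volume_ml, hln))
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  comparisons <- NULL
  if (config$n >= 2) {
    endpoints <- c(surface_area_mm2 = "bleb surface area at final scan",
                   distension_ml = "distension volume",
                   max_pressure_kpa = "maximum pressure",
                   keff_per_s = "effective decay constant")
    comparisons <- list()
    for (v in unique(results$volume_ml)) {
      for (ep in names(endpoints)) {
        x <- results[[ep]][results$volume_ml == v & !results$hln & results$ok]
        y <- results[[ep]][results$volume_ml == v & results$hln & results$ok]
        if (length(x) >= 2 && length(y) >= 2) {
          cmp <- tryCatch(
            two_sample_t(x, y,
                         endpoint = sprintf("%s (%g mL)", endpoints[[ep]], v)),
            error = function(e) conditionMessage(e))
          comparisons[[sprintf("%s_%gml", ep, v)]] <- cmp
        }
      }
    }
  } else {
    message("n = 1 per arm: group statistics skipped")
  }
  list(results = results, comparisons = comparisons)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical equal-variance two-sample t-test, two-sided, as used for
#' per-endpoint group comparisons (significance at `alpha`, no
#' multiple-testing correction). A Welch variant is available via
#' `var_equal = FALSE`.
#'
#' @param x,y numeric endpoint values for the two groups (each length >= 2,
#'   finite).
#' @param alpha significance level.
#' @param var_equal pooled-variance (TRUE, default) or Welch.
#' @param endpoint optional endpoint label.
#' @return A list (`group_comparison`): group means and s.d.s, `t`, `df`,
#'   `p`, `significant`.
#' @export
two_sample_t <- function(x, y, alpha = 0.05, var_equal = TRUE,
                         endpoint = NA_character_) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite endpoint values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
                 p.value = 1)
    } else {
      stop("zero variance in both groups with unequal means: t undefined")
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = var_equal)
  }
  structure(list(endpoint = endpoint,
                 mean_x = mean(x), sd_x = stats::sd(x), n_x = length(x),
                 mean_y = mean(y), sd_y = stats::sd(y), n_y = length(y),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, alpha = alpha,
                 significant = tt$p.value < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s\n", x$endpoint))
  cat(sprintf("  %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d)\n",
              x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y))
  cat(sprintf("  t = %.3f, df = %g, p = %.4g%s\n", x$t, x$df, x$p,
              if (x$significant) " *" else " (NS)"))
  invisible(x)
}

#' Summarize one experimental arm
#'
#' @param values numeric endpoint values.
#' @return A list with `mean`, `sd` (NA with a flag when n = 1) and `n`,
#'   matching the mean +/- s.d. of n reporting convention.
#' @export
summarize_arm <- function(values) {
  n <- length(values)
  if (n < 1) stop("need at least one value")
  list(mean = mean(values),
       sd = if (n >= 2) stats::sd(values) else NA_real_,
       n = n,
       sd_defined = n >= 2)
}

#' Type-I error calibration of the pipeline's group test
#'
#' Simulates many null experiments: both arms use identical pressure-trace
#' generators (differing only in seed), the per-replicate endpoint is the
#' maximum pressure near cessation computed by the analysis chain, and the
#' pooled two-sample t-test is applied at level `alpha`. Returns the
#' rejection rate, which should match `alpha` for a calibrated test.
#'
#' @param n_experiments number of simulated experiments.
#' @param n_per_arm replicates per arm.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return A list with `rejection_rate`, `n_experiments`, `n_per_arm`.
#' @export
calibrate_type1_error <- function(n_experiments = 500, n_per_arm = 20,
                                  alpha = 0.05, seed = 1L) {
  protocol <- injection_protocol(4.5, 10)
  base <- pressure_sim_spec(protocol, noise_sd = 0.4, seed = 1L)
  endpoint <- function(s) {
    spec <- base
    spec$seed <- s
    tr <- generate_pressure_trace(spec)
    max_pressure(tr)$max_kpa
  }
  rejections <- 0L
  sub_seeds <- with_local_seed(seed, sample.int(2^30, 2 * n_experiments * n_per_arm))
  idx <- 0L
  for (e in seq_len(n_experiments)) {
    x <- vapply(seq_len(n_per_arm), function(i) endpoint(sub_seeds[idx + i]), numeric(1))
    idx <- idx + n_per_arm
    y <- vapply(seq_len(n_per_arm), function(i) endpoint(sub_seeds[idx + i]), numeric(1))
    idx <- idx + n_per_arm
    if (two_sample_t(x, y, alpha = alpha)$significant) rejections <- rejections + 1L
  }
  list(rejection_rate = rejections / n_experiments,
       n_experiments = n_experiments, n_per_arm = n_per_arm, alpha = alpha)
}
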