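#' Uniformly sampled subcutaneous pressure trace
#'
#' @param time_s strictly increasing sample times (s), uniform to within 1%
#'   of the nominal sampling interval.
#' @param pressure_kpa pressure samples (kPa), same length as `time_s`.
#' @param rate_hz sampling rate; inferred from the median time step if
#'   omitted. Inline sensors in this application typically log at 10 Hz.
#' @param t_start_s,t_cess_s optional injection start / cessation markers (s).
#' @return An object of class `pressure_trace`: a data frame with columns
#'   `time_s`, `pressure_kpa` and attributes `rate_hz`, `t_start_s`,
#'   `t_cess_s`.
#' @export
pressure_trace <- function(time_s, pressure_kpa, rate_hz = NULL,
                           t_start_s = NA_real_, t_cess_s = NA_real_) {
  time_s <- as.numeric(time_s)
  pressure_kpa <- as.numeric(pressure_kpa)
  if (length(time_s) != length(pressure_kpa))
    stop("time and pressure must have equal length")
  if (anyNA(time_s) || anyNA(pressure_kpa)) {
    bad <- which(is.na(time_s) | is.na(pressure_kpa))[1L]
    stop(sprintf("NA in trace at row %d", bad))
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf("time not strictly increasing at row %d", bad))
  }
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(dt)
  if (rate_hz <= 0) stop("rate_hz must be > 0")
  nominal <- 1 / rate_hz
  if (length(dt) > 0 && any(abs(dt - nominal) > 0.01 * nominal)) {
    bad <- which(abs(dt - nominal) > 0.01 * nominal)[1L] + 1L
    stop(sprintf("non-uniform sampling at row %d (step %.4g s, nominal %.4g s)",
                 bad, dt[bad - 1L], nominal))
  }
  structure(data.frame(time_s = time_s, pressure_kpa = pressure_kpa),
            rate_hz = rate_hz, t_start_s = t_start_s, t_cess_s = t_cess_s,
            class = c("pressure_trace", "data.frame"))
}

#' Pressure unit conversions to kilopascal
#'
#' @param x pressure values in psi / mmHg.
#' @return values in kPa.
#' @export
kpa_from_psi <- function(x) x * 6.894757

#' @rdname kpa_from_psi
#' @export
kpa_from_mmhg <- function(x) x * 0.1333224

#' Read / write a pressure trace as CSV with a JSON sidecar
#'
#' The CSV holds two columns (`time_s`, `pressure_<unit>`); the sidecar
#' (`<path>.json`) carries the sampling rate, injection markers and the
#' pressure unit. On read, psi or mmHg traces are converted to kPa.
#'
#' @param trace a [pressure_trace()].
#' @param path CSV file path.
#' @param unit pressure unit of the file: `"kpa"`, `"psi"` or `"mmhg"`.
#'   `write_pressure_trace` always writes kPa.
#' @return `read_pressure_trace` returns a [pressure_trace()] in kPa.
#' @export
write_pressure_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  side <- list(rate_hz = attr(trace, "rate_hz"),
               t_start_s = attr(trace, "t_start_s"),
               t_cess_s = attr(trace, "t_cess_s"),
               unit = "kpa")
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pressure_trace
#' @export
read_pressure_trace <- function(path, unit = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("trace CSV must have time and pressure columns")
  side <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(unit)) unit <- if (!is.null(side$unit)) side$unit else "kpa"
  unit <- tolower(unit)
  p <- df[[2L]]
  p <- switch(unit,
              kpa = p,
              psi = kpa_from_psi(p),
              mmhg = kpa_from_mmhg(p),
              stop(sprintf("unknown pressure unit '%s'", unit)))
  pressure_trace(
    df[[1L]], p,
    rate_hz = if (!is.null(side$rate_hz)) side$rate_hz else NULL,
    t_start_s = if (!is.null(side$t_start_s)) side$t_start_s else NA_real_,
    t_cess_s = if (!is.null(side$t_cess_s)) side$t_cess_s else NA_real_)
}

#' Injection protocol
#'
#' @param volume_ml injected volume (mL); the study design this package
#'   targets uses 4.5 or 9 mL.
#' @param flow_rate_ml_min pump flow rate (mL/min); a syringe pump at
#'   10 mL/min is the reference condition.
#' @param hln whether hyaluronidase is co-formulated in the injectate.
#' @param hln_conc_u_ml HLN concentration (U/mL), informational.
#' @return An object of class `injection_protocol`.
#' @export
injection_protocol <- function(volume_ml, flow_rate_ml_min = 10,
                               hln = FALSE, hln_conc_u_ml = 750) {
  if (volume_ml <= 0) stop("volume_ml must be > 0")
  if (flow_rate_ml_min <= 0) stop("flow_rate_ml_min must be > 0")
  structure(list(volume_ml = volume_ml, flow_rate_ml_min = flow_rate_ml_min,
                 hln = isTRUE(hln), hln_conc_u_ml = hln_conc_u_ml),
            class = "injection_protocol")
}

#' Injection cessation time
#'
#' The pump stops after `volume / flow rate`; e.g. 4.5 mL at 10 mL/min is
#' delivered over 27 s and 9 mL over 54 s.
#'
#' @param protocol an [injection_protocol()].
#' @param t_start_s injection start time (s).
#' @return Cessation time (s).
#' @export
cessation_time <- function(protocol, t_start_s = 0) {
  stopifnot(inherits(protocol, "injection_protocol"))
  t_start_s + protocol$volume_ml / protocol$flow_rate_ml_min * 60
}

#' Specification of a simulated pressure recording
#'
#' The simulated trace rises from baseline during the infusion (linear ramp
#' by default, or a normalized first-order rise), reaches
#' `baseline + A1 + A2` at cessation, then decays as the two-component
#' exponential `A1 exp(-k1 t') + A2 exp(-k2 t')` above baseline, with
#' i.i.d. Gaussian noise.
#'
#' @param protocol an [injection_protocol()].
#' @param baseline_kpa resting gauge offset (kPa).
#' @param A1,A2 decay component amplitudes (kPa), both >= 0.
#' @param k1,k2 decay rate constants (1/s), `k1 >= k2 > 0`.
#' @param rise `"linear"` or `"first_order"`.
#' @param rise_tau_s time constant of the first-order rise (s).
#' @param noise_sd Gaussian noise s.d. (kPa).
#' @param rate_hz sampling rate (default 10 Hz).
#' @param duration_s total recording length; must exceed the infusion
#'   duration by more than 120 s so the decay window is fully covered.
#' @param t_start_s injection start (s).
#' @param seed integer RNG seed.
#' @return An object of class `pressure_sim_spec`.
#' @export
pressure_sim_spec <- function(protocol, baseline_kpa = 2,
                              A1 = 14, A2 = 6, k1 = 0.5, k2 = 0.05,
                              rise = c("linear", "first_order"),
                              rise_tau_s = 10, noise_sd = 0.4,
                              rate_hz = 10, duration_s = NULL,
                              t_start_s = 5, seed = 1L) {
  rise <- match.arg(rise)
  stopifnot(inherits(protocol, "injection_protocol"))
  if (!(k1 >= k2) || k2 <= 0) stop("rate constants must satisfy k1 >= k2 > 0")
  if (A1 < 0 || A2 < 0) stop("amplitudes must be >= 0")
  if (rate_hz <= 0) stop("rate_hz must be > 0")
  infusion_s <- protocol$volume_ml / protocol$flow_rate_ml_min * 60
  if (is.null(duration_s)) duration_s <- t_start_s + infusion_s + 150
  if (duration_s <= t_start_s + infusion_s + 120)
    stop("duration_s must exceed the infusion duration by more than 120 s")
  structure(list(protocol = protocol, baseline_kpa = baseline_kpa,
                 A1 = A1, A2 = A2, k1 = k1, k2 = k2, rise = rise,
                 rise_tau_s = rise_tau_s, noise_sd = noise_sd,
                 rate_hz = rate_hz, duration_s = duration_s,
                 t_start_s = t_start_s, seed = as.integer(seed)),
            class = "pressure_sim_spec")
}

# noiseless model value of the simulated trace at times t
pressure_model_values <- function(spec, t) {
  t_cess <- cessation_time(spec$protocol, spec$t_start_s)
  peak <- spec$A1 + spec$A2
  p <- rep(spec$baseline_kpa, length(t))
  infusing <- t > spec$t_start_s & t <= t_cess
  if (any(infusing)) {
    tt <- t[infusing] - spec$t_start_s
    te <- t_cess - spec$t_start_s
    frac <- if (spec$rise == "linear") tt / te
            else (1 - exp(-tt / spec$rise_tau_s)) / (1 - exp(-te / spec$rise_tau_s))
    p[infusing] <- spec$baseline_kpa + peak * frac
  }
  after <- t > t_cess
  if (any(after)) {
    tau <- t[after] - t_cess
    p[after] <- spec$baseline_kpa +
      spec$A1 * exp(-spec$k1 * tau) + spec$A2 * exp(-spec$k2 * tau)
  }
  p
}

#' Simulate a subcutaneous pressure recording
#'
#' @param spec a [pressure_sim_spec()].
#' @return A [pressure_trace()] with start/cessation markers embedded.
#' @export
generate_pressure_trace <- function(spec) {
  stopifnot(inherits(spec, "pressure_sim_spec"))
  # integer sample counts over the rate keep grid times exact (e.g. 32.0 s
  # at 10 Hz is 320/10, not an accumulated 0.1 sum)
  t <- seq.int(0L, floor(spec$duration_s * spec$rate_hz)) / spec$rate_hz
  p <- pressure_model_values(spec, t)
  if (spec$noise_sd > 0)
    p <- p + with_local_seed(spec$seed,
                             stats::rnorm(length(t), 0, spec$noise_sd))
  pressure_trace(t, p, rate_hz = spec$rate_hz,
                 t_start_s = spec$t_start_s,
                 t_cess_s = cessation_time(spec$protocol, spec$t_start_s))
}
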