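#' Peak pressure near injection cessation
#'
#' Finds the maximum pressure sample within a symmetric closed window around
#' the cessation marker (default +/- 2 s). Ties are broken by the earliest
#' sample time.
#'
#' @param trace a [pressure_trace()].
#' @param t_cess_s injection cessation time (s); defaults to the trace's
#'   embedded marker.
#' @param window_s half-width of the search window (s).
#' @return A list with `max_kpa` and `t_peak_s`.
#' @export
max_pressure <- function(trace, t_cess_s = attr(trace, "t_cess_s"),
                         window_s = 2) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (is.na(t_cess_s)) stop("cessation time is required (no marker in trace)")
  lo <- t_cess_s - window_s
  hi <- t_cess_s + window_s
  if (min(trace$time_s) > lo || max(trace$time_s) < hi)
    stop(sprintf("trace does not cover the window [%.2f, %.2f] s", lo, hi))
  in_win <- trace$time_s >= lo & trace$time_s <= hi
  tw <- trace$time_s[in_win]
  pw <- trace$pressure_kpa[in_win]
  i <- which(pw == max(pw))[1L]  # earliest on ties
  list(max_kpa = pw[i], t_peak_s = tw[i])
}

#' Fit a double-exponential pressure decay
#'
#' Fits `baseline + A1 exp(-k1 t') + A2 exp(-k2 t')` to the samples in the
#' decay window following the injection, by constrained Levenberg-Marquardt
#' least squares. The decay clock `t'` starts at the detected peak time
#' (within `peak_window_s` of cessation) rather than at nominal cessation,
#' since the two need not coincide. Starting values come from curve peeling:
#' a log-linear fit of the final third of the window seeds the slow
#' component, a log-linear fit of the early residual seeds the fast one;
#' a fixed set of jittered restarts guards against local minima.
#'
#' @param trace a [pressure_trace()].
#' @param t_cess_s injection cessation time (s); defaults to the embedded
#'   marker.
#' @param fit_window_s length of the decay window after cessation (s);
#'   2 min by default.
#' @param peak_window_s half-width of the peak search window (s).
#' @param baseline `"free"` to estimate the resting gauge offset jointly
#'   (default), or a fixed numeric value (kPa) to pin it.
#' @param restarts number of jittered restarts of the optimizer.
#' @return An object of class `decay_fit`: amplitudes `A1 >= 0`, `A2 >= 0`
#'   (kPa), rate constants `k1 >= k2 > 0` (1/s), `keff` (1/s),
#'   `baseline_kpa`, residual sum of squares `rss`, `converged`,
#'   `identifiable` (FALSE when the fitted amplitudes are negligible),
#'   `t_peak_s` and `n_obs`.
#' @export
fit_decay <- function(trace, t_cess_s = attr(trace, "t_cess_s"),
                      fit_window_s = 120, peak_window_s = 2,
                      baseline = "free", restarts = 5L) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (is.na(t_cess_s)) stop("cessation time is required (no marker in trace)")
  n_after <- sum(trace$time_s > t_cess_s &
                   trace$time_s <= t_cess_s + fit_window_s)
  if (n_after < 50L)
    stop(sprintf("need >= 50 samples in the %.0f s decay window, have %d",
                 fit_window_s, n_after))
  pk <- max_pressure(trace, t_cess_s, peak_window_s)
  # decay clock starts at the detected peak, clamped not to precede
  # cessation: a noise-elevated sample on the rising ramp must not pull
  # pre-cessation (still rising) samples into the decay fit
  t0 <- max(pk$t_peak_s, t_cess_s)
  sel <- trace$time_s >= t0 &
    trace$time_s <= t_cess_s + fit_window_s
  tau <- trace$time_s[sel] - t0
  y <- trace$pressure_kpa[sel]

  fixed_baseline <- !identical(baseline, "free")
  b_fix <- if (fixed_baseline) as.numeric(baseline) else NA_real_

  start <- peel_start(tau, y, if (fixed_baseline) b_fix else NULL)
  span <- max(y) - min(y)
  fits <- list()
  with_local_seed(20210607L, {
    for (r in seq_len(restarts + 1L)) {
      st <- start
      if (r > 1L) {  # jittered restart
        st$A1 <- st$A1 * exp(stats::rnorm(1, 0, 0.4))
        st$A2 <- st$A2 * exp(stats::rnorm(1, 0, 0.4))
        st$k1 <- st$k1 * exp(stats::rnorm(1, 0, 0.4))
        st$k2 <- st$k2 * exp(stats::rnorm(1, 0, 0.4))
      }
      f <- try_biexp_fit(tau, y, st, b_fix, fixed_baseline)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
  })
  if (length(fits) == 0L)
    stop("double-exponential fit failed to converge from all starts")
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  best <- fits[[which.min(rss)]]

  # order components so k1 >= k2
  if (best$k1 < best$k2) {
    best[c("A1", "A2")] <- best[c("A2", "A1")]
    best[c("k1", "k2")] <- best[c("k2", "k1")]
  }
  amp <- best$A1 + best$A2
  keff <- if (amp > 0)
    (best$A1 * best$k1 + best$A2 * best$k2) / amp else NA_real_
  structure(
    list(A1 = best$A1, A2 = best$A2, k1 = best$k1, k2 = best$k2,
         keff = keff, baseline_kpa = best$baseline, rss = best$rss,
         converged = best$converged,
         identifiable = amp > 1e-6 * max(span, 1),
         t_peak_s = pk$t_peak_s, n_obs = length(y)),
    class = "decay_fit")
}

# curve-peeling starting values for the bi-exponential decay
peel_start <- function(tau, y, b_fix = NULL) {
  b0 <- if (!is.null(b_fix)) b_fix else min(y) - 0.05 * (max(y) - min(y)) - 1e-9
  third <- max(5L, floor(length(tau) / 3))
  tail_i <- seq.int(length(tau) - third + 1L, length(tau))
  yt <- pmax(y[tail_i] - b0, 1e-9)
  slow <- stats::lm.fit(cbind(1, tau[tail_i]), log(yt))$coefficients
  k2 <- max(1e-4, -slow[2L])
  A2 <- max(1e-6, exp(slow[1L]))
  resid <- y - b0 - A2 * exp(-k2 * tau)
  head_i <- seq_len(third)
  pos <- head_i[resid[head_i] > 0]
  if (length(pos) >= 3L) {
    fast <- stats::lm.fit(cbind(1, tau[pos]), log(resid[pos]))$coefficients
    k1 <- max(k2 * 1.5, -fast[2L])
    A1 <- max(1e-6, exp(fast[1L]))
  } else {
    k1 <- k2 * 10
    A1 <- max(1e-6, y[1L] - b0 - A2)
  }
  list(A1 = A1, A2 = A2, k1 = k1, k2 = k2, baseline = b0)
}

# one constrained nlsLM attempt; returns NULL on failure
try_biexp_fit <- function(tau, y, start, b_fix, fixed_baseline) {
  df <- data.frame(tau = tau, y = y)
  out <- tryCatch({
    if (fixed_baseline) {
      fit <- minpack.lm::nlsLM(
        y ~ b_fix + A1 * exp(-k1 * tau) + A2 * exp(-k2 * tau),
        data = df,
        start = start[c("A1", "k1", "A2", "k2")],
        lower = c(A1 = 0, k1 = 1e-8, A2 = 0, k2 = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      fit <- minpack.lm::nlsLM(
        y ~ b + A1 * exp(-k1 * tau) + A2 * exp(-k2 * tau),
        data = df,
        start = c(start[c("A1", "k1", "A2", "k2")], b = start$baseline),
        lower = c(A1 = 0, k1 = 1e-8, A2 = 0, k2 = 1e-8, b = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
    cf <- stats::coef(fit)
    list(A1 = unname(cf["A1"]), A2 = unname(cf["A2"]),
         k1 = unname(cf["k1"]), k2 = unname(cf["k2"]),
         baseline = if (fixed_baseline) b_fix else unname(cf["b"]),
         rss = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE)
  }, error = function(e) NULL)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> A1 = %.3g, A2 = %.3g kPa; k1 = %.4g, k2 = %.4g 1/s\n",
    x$A1, x$A2, x$k1, x$k2))
  cat(sprintf("  keff = %.4g 1/s, baseline = %.3g kPa, rss = %.3g (n = %d)\n",
              x$keff, x$baseline_kpa, x$rss, x$n_obs))
  if (!x$identifiable) cat("  warning: amplitudes negligible (non-identifiable)\n")
  invisible(x)
}

#' Effective decay constant of a double-exponential fit
#'
#' The amplitude-weighted mean of the two rate constants,
#' `keff = (A1 k1 + A2 k2) / (A1 + A2)`, which always lies between
#' `min(k1, k2)` and `max(k1, k2)`.
#'
#' @param fit a `decay_fit`, or a list/vector with elements `A1`, `k1`,
#'   `A2`, `k2`.
#' @return `keff` in 1/s.
#' @export
effective_decay_constant <- function(fit) {
  A1 <- fit$A1; A2 <- fit$A2; k1 <- fit$k1; k2 <- fit$k2
  if (A1 + A2 <= 0) stop("effective decay constant undefined: A1 + A2 = 0")
  (A1 * k1 + A2 * k2) / (A1 + A2)
}
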