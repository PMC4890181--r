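## Electrochromic-shift dark-interval relaxation analysis: flash
## normalization, proton-motive-force partitioning and H+ conductivity.

#' Dark-interval windows of an ECS trace
#'
#' @param trace An [ecs_trace()].
#' @return Two-column matrix of `(start, end)` times in s, one row per
#'   dark interval (light-off to light-resume).
#' @export
dark_intervals <- function(trace) {
  stopifnot(inherits(trace, "ecs_trace"))
  pr <- trace$protocol
  if (!length(pr$dark_intervals)) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = pr$dark_intervals, end = pr$dark_intervals + pr$interval_s)
}

#' Measure the single-turnover flash amplitude
#'
#' For each annotated flash, the amplitude is the signal peak within 5 ms
#' after the flash minus the mean of the 10 ms immediately preceding it;
#' the per-flash amplitudes are averaged.
#'
#' @param trace An [ecs_trace()] with at least one annotated flash.
#' @param peak_ms Post-flash peak-search window, ms.
#' @param baseline_ms Pre-flash baseline window, ms.
#' @return Flash amplitude (relative signal units).
#' @export
measure_ecs_st <- function(trace, peak_ms = 5, baseline_ms = 10) {
  stopifnot(inherits(trace, "ecs_trace"))
  flashes <- trace$protocol$flashes
  if (!length(flashes)) {
    stop_thylakoidr("no flashes annotated in the protocol", "no_flashes")
  }
  t_max <- trace$time[length(trace$time)]
  amps <- vapply(flashes, function(tf) {
    if (tf < trace$time[1] + baseline_ms / 1000 || tf + peak_ms / 1000 > t_max) {
      stop_thylakoidr(
        sprintf("flash at %g s lies outside the usable trace range", tf),
        "flash_out_of_range")
    }
    base <- window_mean(trace$time, trace$signal,
                        tf - baseline_ms / 1000, tf - 1e-12)
    idx <- trace$time >= tf & trace$time <= tf + peak_ms / 1000
    max(trace$signal[idx]) - base
  }, numeric(1))
  mean(amps)
}

#' Normalize total-ECS amplitudes by their flash amplitudes
#'
#' Each total amplitude is multiplied by the correction factor
#' `max(ecs_st) / ecs_st`, so the measurement with the largest flash
#' amplitude is unchanged and the others are scaled up to it.  The
#' operation is idempotent on its own output scale and invariant to a
#' common rescaling of all flash amplitudes.
#'
#' @param ecs_t_raw Total ECS amplitudes (one per measurement).
#' @param ecs_st Matching single-turnover flash amplitudes (> 0).
#' @return Normalized amplitudes, same length.
#' @export
normalize_ecs_t <- function(ecs_t_raw, ecs_st) {
  if (!length(ecs_t_raw)) stop("empty measurement list", call. = FALSE)
  stopifnot(length(ecs_t_raw) == length(ecs_st))
  if (any(!is.finite(ecs_st)) || any(ecs_st <= 0)) {
    stop("flash amplitudes must be positive", call. = FALSE)
  }
  ecs_t_raw * (max(ecs_st) / ecs_st)
}

#' Partition the proton-motive force from a dark-interval relaxation
#'
#' Reduces the dark-interval relaxation to three level estimates: the
#' light steady state (mean of the last `light_ms` before light-off), the
#' inverted quasi-stable level (mean of the last `inv_ms` of the
#' interval), and the dark baseline (mean of the annotated baseline
#' window).  The total amplitude is `S_light - S_inv`; the electric
#' fraction is `(S_light - S_base) / ecs_t`, clipped to \[0, 1\] with a
#' warning (an out-of-range value flags an underestimated total), and the
#' pH fraction is its complement.  The decay time constant and proton
#' conductivity are taken from [fit_gh_plus()] on the same interval.
#'
#' @param trace An [ecs_trace()] with an annotated dark baseline.
#' @param interval Length-2 numeric `(start, end)` of the dark interval in
#'   s (default: the first interval of the protocol); must span at least
#'   300 ms.
#' @param light_ms,inv_ms Averaging windows, ms (defaults 20 and 50).
#' @return A `pmf_partition`: `ecs_t_raw`, `ecs_st` (`NA` without
#'   flashes), `ecs_t_norm` (`NA` until [normalize_ecs_t()] across a data
#'   set), `f_dpsi`, `f_dph`, `tau` (ms) and `g_h` (s^-1).
#' @export
partition_pmf <- function(trace, interval = NULL, light_ms = 20,
                          inv_ms = 50) {
  stopifnot(inherits(trace, "ecs_trace"))
  if (is.null(interval)) {
    di <- dark_intervals(trace)
    if (!nrow(di)) {
      stop_thylakoidr("no dark interval annotated", "no_dark_interval")
    }
    interval <- di[1, ]
  }
  stopifnot(length(interval) == 2L, interval[2] > interval[1])
  if (interval[2] - interval[1] < 0.3) {
    stop_thylakoidr("dark interval shorter than 300 ms", "interval_too_short")
  }
  base_win <- trace$protocol$baseline
  if (is.null(base_win)) {
    stop_thylakoidr("missing dark baseline window", "no_baseline")
  }
  s_light <- window_mean(trace$time, trace$signal,
                         interval[1] - light_ms / 1000, interval[1] - 1e-12)
  s_inv <- window_mean(trace$time, trace$signal,
                       interval[2] - inv_ms / 1000, interval[2])
  s_base <- window_mean(trace$time, trace$signal, base_win[1], base_win[2])
  ecs_t_raw <- s_light - s_inv
  if (ecs_t_raw <= 0) {
    stop_thylakoidr("no PMF signal: non-positive total ECS amplitude",
                    "no_pmf_signal")
  }
  f_dpsi <- (s_light - s_base) / ecs_t_raw
  if (f_dpsi < 0 || f_dpsi > 1) {
    warning(sprintf(
      "electric fraction %.3f outside [0, 1], clipped (total amplitude may be underestimated)",
      f_dpsi), call. = FALSE)
    f_dpsi <- min(max(f_dpsi, 0), 1)
  }
  gh <- tryCatch(fit_gh_plus(trace, interval),
                 thylakoidr_error = function(e) list(tau = NA_real_,
                                                     g_h = NA_real_))
  ecs_st <- if (length(trace$protocol$flashes)) measure_ecs_st(trace)
            else NA_real_
  structure(
    list(ecs_t_raw = ecs_t_raw, ecs_st = ecs_st, ecs_t_norm = NA_real_,
         f_dpsi = f_dpsi, f_dph = 1 - f_dpsi,
         tau = gh$tau, g_h = gh$g_h,
         levels = c(light = s_light, baseline = s_base, inverted = s_inv),
         interval = interval),
    class = "pmf_partition"
  )
}

#' Fit the ECS decay and report the proton conductivity
#'
#' Nonlinear least-squares fit of `S(t) = S_inf + dS * exp(-t / tau)` over
#' the first `fit_ms` (default 100 ms) after light-off, initialized from a
#' log-linear regression with the asymptote seeded from the last 5 ms of
#' the fit window.  The proton conductivity is the reciprocal decay time
#' constant, `g_h = 1 / tau` with `tau` in seconds.
#'
#' @param trace An [ecs_trace()].
#' @param interval Length-2 `(start, end)` of the dark interval in s
#'   (default: first protocol interval).
#' @param fit_ms Fit window after light-off, ms; at least 20 samples must
#'   fall inside it.
#' @return List with `tau` (ms), `g_h` (s^-1) and the `nls` fit object.
#' @export
fit_gh_plus <- function(trace, interval = NULL, fit_ms = 100) {
  stopifnot(inherits(trace, "ecs_trace"))
  if (is.null(interval)) {
    di <- dark_intervals(trace)
    if (!nrow(di)) {
      stop_thylakoidr("no dark interval annotated", "no_dark_interval")
    }
    interval <- di[1, ]
  }
  t0 <- interval[1]
  idx <- trace$time > t0 & trace$time <= t0 + fit_ms / 1000 &
    trace$time <= interval[2]
  if (sum(idx) < 20) {
    stop_thylakoidr(
      "fewer than 20 samples in the decay fit window; sampling inadequate",
      "too_few_samples")
  }
  tt <- trace$time[idx] - t0
  y <- trace$signal[idx]
  if (diff(range(y)) < 1e-12) {
    stop_thylakoidr("no decay: signal is constant after light-off",
                    "no_decay")
  }
  ## initialization: asymptote from the last 5 ms, log-linear for tau
  s_inf0 <- mean(y[tt >= max(tt) - 5e-3])
  pos <- y - s_inf0 > 0
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(y[pos] - s_inf0) ~ tt[pos])
    tau0 <- unname(-1 / stats::coef(lf)[2])
    ds0 <- unname(exp(stats::coef(lf)[1]))
  } else {
    tau0 <- fit_ms / 4000
    ds0 <- y[1] - s_inf0
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- fit_ms / 4000
  if (!is.finite(ds0) || ds0 <= 0) ds0 <- max(y[1] - s_inf0, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ s_inf + ds * exp(-tt / tau),
      start = list(s_inf = s_inf0, ds = ds0, tau = tau0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop_thylakoidr("no decay: exponential fit did not converge", "no_decay")
  }
  cf <- stats::coef(fit)
  resid_sd <- stats::sd(stats::residuals(fit))
  if (cf[["tau"]] <= 0 || cf[["ds"]] <= 0 ||
      (is.finite(resid_sd) && cf[["ds"]] < 2 * resid_sd)) {
    stop_thylakoidr("no decay: fitted segment is not a positive-amplitude decay",
                    "no_decay")
  }
  tau_ms <- 1000 * cf[["tau"]]
  list(tau = tau_ms, g_h = 1000 / tau_ms, fit = fit)
}

#' @export
print.pmf_partition <- function(x, ...) {
  cat(sprintf(
    "<pmf_partition> ECS_t = %.4g, f_dPsi = %.3f, f_dpH = %.3f, tau = %.3g ms, g_H+ = %.3g 1/s\n",
    x$ecs_t_raw, x$f_dpsi, x$f_dph, x$tau, x$g_h))
  invisible(x)
}
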