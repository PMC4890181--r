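## Pulse-amplitude-modulated fluorescence quenching analysis and psi-type
## circular-dichroism band amplitudes.

#' Extract per-pulse fluorescence levels
#'
#' For each annotated saturating pulse, the maximal fluorescence in the
#' light `F_m'` is the trace maximum within `window_ms` centred on the
#' pulse time, and the steady-state level `F` is the mean over the
#' `steady_ms` immediately preceding that window.
#'
#' @param trace A [fluor_trace()].
#' @param window_ms Width of the pulse window, ms (default 800).
#' @param steady_ms Pre-window averaging time for `F`, ms (default 200).
#' @return Data frame with one row per pulse: `time`, `f_m_prime`,
#'   `f_steady`.
#' @export
extract_pulse_values <- function(trace, window_ms = 800, steady_ms = 200) {
  stopifnot(inherits(trace, "fluor_trace"))
  pt <- trace$pulse_times
  if (!length(pt)) {
    return(data.frame(time = numeric(0), f_m_prime = numeric(0),
                      f_steady = numeric(0)))
  }
  half <- window_ms / 2000
  if (length(pt) > 1L && any(diff(pt) < 2 * half)) {
    stop_thylakoidr("overlapping pulse windows", "overlapping_pulses")
  }
  t_max <- trace$time[length(trace$time)]
  out <- lapply(pt, function(tp) {
    if (tp - half - steady_ms / 1000 < trace$time[1] || tp + half > t_max) {
      stop_thylakoidr(
        sprintf("pulse window at %g s extends outside the trace", tp),
        "pulse_out_of_range")
    }
    idx <- trace$time >= tp - half & trace$time <= tp + half
    fmp <- max(trace$fluorescence[idx])
    fst <- window_mean(trace$time, trace$fluorescence,
                       tp - half - steady_ms / 1000, tp - half - 1e-12)
    data.frame(time = tp, f_m_prime = fmp, f_steady = fst)
  })
  do.call(rbind, out)
}

#' Non-photochemical quenching
#'
#' `NPQ = (F_m - F_m') / F_m'`.  A value of `F_m'` exceeding the
#' dark-adapted `F_m` yields a negative NPQ and a warning (anomalous
#' trace), not an error.
#'
#' @param f_m Dark-adapted maximal fluorescence.
#' @param f_m_prime Maximal fluorescence in the light (> 0).
#' @return NPQ (dimensionless), vectorized over inputs.
#' @export
compute_npq <- function(f_m, f_m_prime) {
  if (any(f_m_prime <= 0)) stop("F_m' must be > 0", call. = FALSE)
  npq <- (f_m - f_m_prime) / f_m_prime
  if (any(npq < 0)) {
    warning("F_m' exceeds F_m: negative NPQ returned", call. = FALSE)
  }
  npq
}

#' Photosystem II quantum yield
#'
#' `Phi_II = (F_m' - F) / F_m'`.
#'
#' @param f_m_prime Maximal fluorescence in the light (> 0).
#' @param f_steady Steady-state fluorescence in the light.
#' @return Quantum yield (dimensionless), vectorized over inputs.
#' @export
compute_phi_ii <- function(f_m_prime, f_steady) {
  if (any(f_m_prime <= 0)) stop("F_m' must be > 0", call. = FALSE)
  (f_m_prime - f_steady) / f_m_prime
}

#' Full quenching analysis of a pulse-annotated trace
#'
#' Combines [extract_pulse_values()], [compute_npq()] and
#' [compute_phi_ii()] using the trace's own dark-adapted `F_m`.  On a
#' noiseless generator trace this is the exact inverse of
#' [simulate_pam_trace()].
#'
#' @inheritParams extract_pulse_values
#' @return A `pam_series` data frame: `time`, `f_m_prime`, `f_steady`,
#'   `npq`, `phi_ii`.
#' @export
analyze_pam <- function(trace, window_ms = 800, steady_ms = 200) {
  vals <- extract_pulse_values(trace, window_ms, steady_ms)
  vals$npq <- compute_npq(trace$f_m, vals$f_m_prime)
  vals$phi_ii <- compute_phi_ii(vals$f_m_prime, vals$f_steady)
  class(vals) <- c("pam_series", "data.frame")
  vals
}

#' Normalize a CD spectrum to the red-most absorption peak
#'
#' Divides the whole spectrum by the supplied absorption value and records
#' the cumulative factor, so applying factors `a` then `b` equals applying
#' `a * b` once.
#'
#' @param spectrum A [cd_spectrum()].
#' @param red_peak_absorption Absorption of the red-most peak (> 0).
#' @return The normalized [cd_spectrum()].
#' @export
normalize_cd <- function(spectrum, red_peak_absorption) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  check_number(red_peak_absorption, "red_peak_absorption",
               lower = 0, strict_lower = TRUE)
  prev <- if (is.null(spectrum$normalization)) 1 else spectrum$normalization
  cd_spectrum(spectrum$wavelength, spectrum$cd_signal / red_peak_absorption,
              normalization = prev * red_peak_absorption,
              metadata = spectrum$metadata)
}

#' Default psi-type band / reference wavelength pairs
#'
#' The three psi-type bands near (+)505, (-)675 and (+)690 nm with their
#' conventional reference wavelengths 550, 600 and 750 nm.
#'
#' @return Data frame with columns `band` and `reference` (nm).
#' @export
psi_band_pairs <- function() {
  data.frame(band = c(505, 675, 690), reference = c(550, 600, 750))
}

#' Psi-type CD band amplitude against a reference wavelength
#'
#' Two-point difference `cd(band_nm) - cd(reference_nm)` with linear
#' interpolation between grid points; invariant to a constant offset of
#' the whole spectrum.
#'
#' @param spectrum A [cd_spectrum()].
#' @param band_nm Band wavelength, nm.
#' @param reference_nm Reference wavelength, nm.
#' @return Signed band amplitude (signal units).
#' @export
psi_band_amplitude <- function(spectrum, band_nm, reference_nm) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  rng <- range(spectrum$wavelength)
  for (wl in c(band_nm, reference_nm)) {
    if (wl < max(rng[1], 400) || wl > min(rng[2], 800)) {
      stop_thylakoidr(
        sprintf("wavelength %g nm outside the 400-800 nm spectral range", wl),
        "wavelength_out_of_range")
    }
  }
  at <- function(wl) {
    stats::approx(spectrum$wavelength, spectrum$cd_signal, xout = wl)$y
  }
  at(band_nm) - at(reference_nm)
}

#' Amplitudes of the three psi-type bands
#'
#' @param spectrum A [cd_spectrum()].
#' @param pairs Band/reference pairs as from [psi_band_pairs()].
#' @return Data frame `band`, `reference`, `amplitude`.
#' @export
psi_band_amplitudes <- function(spectrum, pairs = psi_band_pairs()) {
  pairs$amplitude <- vapply(seq_len(nrow(pairs)), function(j) {
    psi_band_amplitude(spectrum, pairs$band[j], pairs$reference[j])
  }, numeric(1))
  pairs
}
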