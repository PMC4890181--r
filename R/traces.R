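## Constructors and print methods for the core data containers.  All are
## plain S3 lists over numeric vectors; units are fixed package-wide
## (time s, current pA, voltage mV, conductance pS, concentration mM,
## q in inverse angstrom, repeat distance angstrom, wavelength nm).

#' Single-channel current trace
#'
#' @param time Time in s, uniform strictly increasing grid.
#' @param current Current in pA; positive current is carried by cations
#'   flowing from the cis to the trans compartment.
#' @param holding_potential Holding potential in mV (cis relative to trans).
#' @param ionic An [ionic_condition()].
#' @param sampling_rate Sampling rate in Hz.
#' @param metadata Optional list (ground truth, seed, state path).
#' @return A `current_trace` object.
#' @export
current_trace <- function(time, current, holding_potential, ionic,
                          sampling_rate, metadata = list()) {
  stopifnot(length(time) == length(current), length(time) >= 1L)
  if (any(!is.finite(current)) || any(!is.finite(time))) {
    stop("trace values must be finite", call. = FALSE)
  }
  if (length(time) > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (max(abs(dt - 1 / sampling_rate)) > 1e-9 / sampling_rate + 1e-12) {
      stop("time grid inconsistent with declared sampling_rate",
           call. = FALSE)
    }
  }
  stopifnot(inherits(ionic, "ionic_condition"))
  structure(
    list(time = time, current = current,
         holding_potential = holding_potential, ionic = ionic,
         sampling_rate = sampling_rate, metadata = metadata),
    class = "current_trace"
  )
}

#' Electrochromic-shift trace
#'
#' @param time Time in s.
#' @param signal Absorbance-difference signal, relative units.
#' @param protocol An [ecs_protocol()]; all events must fall inside the
#'   recorded time range.
#' @param sampling_rate Sampling rate in Hz.
#' @param metadata Optional list.
#' @return An `ecs_trace` object.
#' @export
ecs_trace <- function(time, signal, protocol, sampling_rate,
                      metadata = list()) {
  stopifnot(length(time) == length(signal), length(time) >= 2L,
            inherits(protocol, "ecs_protocol"))
  if (any(!is.finite(signal))) stop("signal must be finite", call. = FALSE)
  if (any(protocol$events$time < time[1] - 1e-9) ||
      any(protocol$events$time > time[length(time)] + 1e-9)) {
    stop("protocol events fall outside the recorded time range",
         call. = FALSE)
  }
  structure(
    list(time = time, signal = signal, protocol = protocol,
         sampling_rate = sampling_rate, metadata = metadata),
    class = "ecs_trace"
  )
}

#' Pulse-annotated chlorophyll fluorescence trace
#'
#' @param time Time in s.
#' @param fluorescence Fluorescence, arbitrary units.
#' @param pulse_times Saturating-pulse times in s, sorted, inside the
#'   recorded range.
#' @param f_m Dark-adapted maximal fluorescence (> 0) for this trace.
#' @param sampling_rate Sampling rate in Hz.
#' @param metadata Optional list.
#' @return A `fluor_trace` object.
#' @export
fluor_trace <- function(time, fluorescence, pulse_times, f_m, sampling_rate,
                        metadata = list()) {
  stopifnot(length(time) == length(fluorescence), length(time) >= 2L)
  check_number(f_m, "f_m", lower = 0, strict_lower = TRUE)
  if (length(pulse_times)) {
    if (is.unsorted(pulse_times, strictly = TRUE)) {
      stop("`pulse_times` must be strictly increasing", call. = FALSE)
    }
    if (any(pulse_times < time[1]) || any(pulse_times > time[length(time)])) {
      stop("pulse times fall outside the recorded range", call. = FALSE)
    }
  }
  structure(
    list(time = time, fluorescence = fluorescence,
         pulse_times = pulse_times, f_m = f_m,
         sampling_rate = sampling_rate, metadata = metadata),
    class = "fluor_trace"
  )
}

#' Small-angle scattering curve
#'
#' @param q Scattering vector in inverse angstroms, positive, strictly
#'   increasing.
#' @param intensity Scattered intensity, counts-like units.
#' @param sigma Optional pointwise uncertainties.
#' @param metadata Optional list.
#' @return A `sans_curve` object.
#' @export
sans_curve <- function(q, intensity, sigma = NULL, metadata = list()) {
  stopifnot(length(q) == length(intensity), length(q) >= 2L)
  if (any(q <= 0) || is.unsorted(q, strictly = TRUE)) {
    stop("q must be positive and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("intensity must be finite", call. = FALSE)
  }
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 metadata = metadata),
            class = "sans_curve")
}

#' Circular-dichroism spectrum
#'
#' @param wavelength Wavelength in nm, strictly increasing.
#' @param cd_signal CD signal, arbitrary units.
#' @param normalization Cumulative normalization factor already applied
#'   (`NULL` for a raw spectrum).
#' @param metadata Optional list.
#' @return A `cd_spectrum` object.
#' @export
cd_spectrum <- function(wavelength, cd_signal, normalization = NULL,
                        metadata = list()) {
  stopifnot(length(wavelength) == length(cd_signal), length(wavelength) >= 2L)
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelength = wavelength, cd_signal = cd_signal,
                 normalization = normalization, metadata = metadata),
            class = "cd_spectrum")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %d samples @ %g Hz, V = %+g mV, %g s\n",
    length(x$time), x$sampling_rate, x$holding_potential,
    length(x$time) / x$sampling_rate))
  invisible(x)
}

#' @export
print.ecs_trace <- function(x, ...) {
  cat(sprintf("<ecs_trace> %d samples @ %g Hz, %d flashes, %d dark interval(s)\n",
              length(x$time), x$sampling_rate, length(x$protocol$flashes),
              length(x$protocol$dark_intervals)))
  invisible(x)
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples @ %g Hz, %d pulses, F_m = %g\n",
              length(x$time), x$sampling_rate, length(x$pulse_times), x$f_m))
  invisible(x)
}

#' @export
print.sans_curve <- function(x, ...) {
  cat(sprintf("<sans_curve> %d points, q in [%g, %g] 1/Angstrom\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d points, %g-%g nm%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              if (is.null(x$normalization)) "" else
                sprintf(", normalized (factor %g)", x$normalization)))
  invisible(x)
}
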