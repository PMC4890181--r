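#' Ionic condition on the two sides of a planar lipid bilayer
#'
#' Concentrations are given per side for the species the recording used
#' (K+, Cl-, NO3-).  The cis side is the protein-addition side; holding
#' potentials are cis relative to trans.
#'
#' @param cis,trans Named numeric vectors of concentrations in mM, names
#'   among `"K"`, `"Cl"`, `"NO3"`.  Species declared on one side must be
#'   declared on both.
#' @param temperature_k Temperature in kelvin (273--320).
#' @return An `ionic_condition` object.
#' @examples
#' ionic_condition(c(K = 300, Cl = 300), c(K = 100, Cl = 100))
#' @export
ionic_condition <- function(cis, trans, temperature_k = 298.15) {
  ok_species <- c("K", "Cl", "NO3")
  for (side in list(cis = cis, trans = trans)) {
    if (!is.numeric(side) || is.null(names(side)) ||
        !all(names(side) %in% ok_species)) {
      stop("concentrations must be named numeric vectors with names among ",
           paste(ok_species, collapse = ", "), call. = FALSE)
    }
    if (any(side <= 0)) {
      stop("declared concentrations must be > 0 mM", call. = FALSE)
    }
  }
  if (!setequal(names(cis), names(trans))) {
    stop("cis and trans must declare the same species", call. = FALSE)
  }
  check_number(temperature_k, "temperature_k", lower = 273, upper = 320)
  structure(
    list(cis = cis[sort(names(cis))], trans = trans[sort(names(trans))],
         temperature_k = temperature_k),
    class = "ionic_condition"
  )
}

#' Ground-truth gating parameters for the synthetic channel generator
#'
#' A two-state (closed/open) continuous-time Markov gate per channel.  The
#' opening rate carries the voltage dependence through a Boltzmann factor,
#' `k_open(V) = k_open_0 * exp(z_gate * V / (RT/F))`, reproducing channels
#' that are more active at positive than at negative potentials; the closing
#' rate is voltage independent.  Openings can enter a partial-conductance
#' substate, and several identical channels superpose independently.
#'
#' @param gamma_pos,gamma_neg Slope conductance (pS) applying at voltages
#'   above / below `v_rev`.
#' @param v_rev Reversal potential in mV.
#' @param k_open_0 Opening rate at 0 mV, s^-1 (may be 0 for an always-closed
#'   control).
#' @param z_gate Dimensionless voltage sensitivity of the opening rate.
#' @param k_close Closing rate, s^-1.
#' @param n_channels Number of independent channels in the bilayer (>= 1).
#' @param substate_fraction Fraction of the full unitary current carried by
#'   a substate opening, in \[0, 1\].
#' @param substate_prob Probability that an opening is a substate, in \[0, 1\].
#' @return A `channel_gating_params` object.
#' @export
channel_gating_params <- function(gamma_pos, gamma_neg = gamma_pos,
                                  v_rev = 0, k_open_0 = 50, z_gate = 0.3,
                                  k_close = 50, n_channels = 1L,
                                  substate_fraction = 0.5,
                                  substate_prob = 0) {
  check_number(gamma_pos, "gamma_pos", lower = 0, strict_lower = TRUE)
  check_number(gamma_neg, "gamma_neg", lower = 0, strict_lower = TRUE)
  check_number(v_rev, "v_rev")
  check_number(k_open_0, "k_open_0", lower = 0)
  check_number(z_gate, "z_gate")
  check_number(k_close, "k_close", lower = 0, strict_lower = TRUE)
  check_number(n_channels, "n_channels", lower = 1)
  check_number(substate_fraction, "substate_fraction", lower = 0, upper = 1)
  check_number(substate_prob, "substate_prob", lower = 0, upper = 1)
  structure(
    list(gamma_pos = gamma_pos, gamma_neg = gamma_neg, v_rev = v_rev,
         k_open_0 = k_open_0, z_gate = z_gate, k_close = k_close,
         n_channels = as.integer(n_channels),
         substate_fraction = substate_fraction,
         substate_prob = substate_prob),
    class = "channel_gating_params"
  )
}

#' Recording configuration for the synthetic channel generator
#'
#' @param ionic An [ionic_condition()].
#' @param holding_potentials Holding potentials in mV (one trace each).
#' @param duration Trace duration in seconds.
#' @param sampling_rate Sampling rate in Hz; `duration * sampling_rate`
#'   must give at least 10 samples.
#' @param noise_sd Gaussian recording noise standard deviation in pA.
#' @param seed Integer master seed; each holding potential uses its own
#'   sub-stream.
#' @return A `recording_config` object.
#' @export
recording_config <- function(ionic, holding_potentials, duration = 60,
                             sampling_rate = 5000, noise_sd = 0.8,
                             seed = NULL) {
  stopifnot(inherits(ionic, "ionic_condition"))
  if (!is.numeric(holding_potentials) || length(holding_potentials) < 1L) {
    stop("`holding_potentials` must be a non-empty numeric vector",
         call. = FALSE)
  }
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (duration * sampling_rate < 10) {
    stop("duration * sampling_rate must give at least 10 samples",
         call. = FALSE)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(ionic = ionic, holding_potentials = holding_potentials,
         duration = duration, sampling_rate = sampling_rate,
         noise_sd = noise_sd, seed = seed),
    class = "recording_config"
  )
}

#' Parameters for the phenomenological electrochromic-shift generator
#'
#' The generator emulates the 550--515 nm absorbance-difference signal:
#' single-turnover flashes step the signal by `ecs_st_amp`, actinic light
#' raises it to a steady level `s_light` above the dark baseline, and each
#' dark interval relaxes exponentially (time constant `tau_decay`) to an
#' inverted quasi-stable level set by the membrane-potential fraction
#' `f_dpsi` of the total amplitude.
#'
#' @param s_light Steady-state light signal level (relative units above the
#'   dark baseline, which sits at 0).
#' @param f_dpsi Electric (membrane potential) fraction of the total
#'   proton-motive force, in \[0, 1\]; the total amplitude is
#'   `s_light / f_dpsi` and the inverted level `-(1 - f_dpsi)` times it.
#' @param tau_decay Relaxation time constant in ms (also used for flash
#'   relaxation, both proceeding through ATP synthase).
#' @param ecs_st_amp Single-turnover flash amplitude, same units.
#' @param noise_sd Additive Gaussian noise sd, relative units.
#' @param protocol An [ecs_protocol()].
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return An `ecs_sim_params` object.
#' @export
ecs_sim_params <- function(s_light = 1, f_dpsi = 0.6, tau_decay = 25,
                           ecs_st_amp = 0.5, noise_sd = 0,
                           protocol = ecs_protocol(), sampling_rate = 1000,
                           seed = NULL) {
  check_number(s_light, "s_light", lower = 0, strict_lower = TRUE)
  check_number(f_dpsi, "f_dpsi", lower = 0, upper = 1)
  if (f_dpsi == 0) stop("`f_dpsi` must be > 0 (s_light fixes the electric component)",
                        call. = FALSE)
  check_number(tau_decay, "tau_decay", lower = 0, strict_lower = TRUE)
  check_number(ecs_st_amp, "ecs_st_amp", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(protocol, "ecs_protocol"))
  structure(
    list(s_light = s_light, f_dpsi = f_dpsi, tau_decay = tau_decay,
         ecs_st_amp = ecs_st_amp, noise_sd = noise_sd, protocol = protocol,
         sampling_rate = sampling_rate, seed = seed),
    class = "ecs_sim_params"
  )
}

#' Light/flash protocol for an electrochromic-shift recording
#'
#' Defines, in seconds from trace start: a dark baseline window, saturating
#' single-turnover flash times (in darkness, before illumination), the
#' actinic light-on time, and one or more dark-interval windows during
#' which the light is switched off (600 ms by default) before resuming.
#' The trace ends `tail` seconds after the last event.
#'
#' @param baseline Length-2 numeric, dark baseline window \[start, end\] s.
#' @param flashes Flash times in s (must fall before `light_on`).
#' @param light_on Actinic light onset, s.
#' @param dark_intervals Numeric vector of light-off times, s.
#' @param interval_s Dark-interval length in s (default 0.6).
#' @param tail Trailing recorded time after the last event, s.
#' @return An `ecs_protocol` object with a `$events` data frame
#'   (`event`, `time`).
#' @export
ecs_protocol <- function(baseline = c(0, 1), flashes = c(1.2, 1.6, 2.0),
                         light_on = 2.5, dark_intervals = c(12.5),
                         interval_s = 0.6, tail = 1) {
  stopifnot(is.numeric(baseline), length(baseline) == 2L,
            baseline[1] < baseline[2])
  if (length(flashes) && any(flashes >= light_on)) {
    stop("flashes must precede light_on", call. = FALSE)
  }
  if (any(flashes < baseline[1])) {
    stop("flashes must fall inside the recorded trace", call. = FALSE)
  }
  check_number(light_on, "light_on", lower = baseline[2])
  check_number(interval_s, "interval_s", lower = 0, strict_lower = TRUE)
  if (length(dark_intervals)) {
    dark_intervals <- sort(dark_intervals)
    if (any(dark_intervals <= light_on)) {
      stop("dark intervals must start after light_on", call. = FALSE)
    }
    if (any(diff(dark_intervals) < interval_s)) {
      stop("dark-interval windows overlap", call. = FALSE)
    }
  }
  events <- rbind(
    data.frame(event = "baseline_start", time = baseline[1]),
    data.frame(event = "baseline_end", time = baseline[2]),
    if (length(flashes)) data.frame(event = "flash", time = sort(flashes)),
    data.frame(event = "light_on", time = light_on),
    if (length(dark_intervals)) rbind(
      data.frame(event = "light_off", time = dark_intervals),
      data.frame(event = "light_resume", time = dark_intervals + interval_s)
    )
  )
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(baseline = baseline, flashes = sort(flashes), light_on = light_on,
         dark_intervals = dark_intervals, interval_s = interval_s,
         tail = tail, events = events),
    class = "ecs_protocol"
  )
}

#' Parameters for the pulse-amplitude-modulated fluorescence generator
#'
#' The generator is the exact inverse of the quenching analysis: at each
#' saturating pulse the maximal fluorescence in the light is
#' `f_m / (1 + NPQ)` and the steady-state level `F` preceding it is
#' `F_m' * (1 - Phi_II)`.
#'
#' @param f_m Dark-adapted maximal fluorescence (arbitrary units, > 0).
#' @param npq_course Target NPQ at each pulse time (>= 0).
#' @param phi_course Target photosystem II quantum yield at each pulse time,
#'   in \[0, 1\].
#' @param pulse_times Saturating-pulse times in s (sorted).
#' @param baseline_noise_sd Additive Gaussian noise sd, fluorescence units.
#' @param sampling_rate Sampling rate in Hz.
#' @param pulse_width Saturating-pulse duration in s.
#' @param seed Integer seed.
#' @return A `pam_sim_params` object.
#' @export
pam_sim_params <- function(f_m = 2, npq_course, phi_course, pulse_times,
                           baseline_noise_sd = 0, sampling_rate = 100,
                           pulse_width = 0.3, seed = NULL) {
  check_number(f_m, "f_m", lower = 0, strict_lower = TRUE)
  n <- length(pulse_times)
  if (n < 1L) stop("at least one pulse time is required", call. = FALSE)
  if (is.unsorted(pulse_times, strictly = TRUE)) {
    stop("`pulse_times` must be strictly increasing", call. = FALSE)
  }
  if (length(npq_course) != n || length(phi_course) != n) {
    stop("courses must have one value per pulse time", call. = FALSE)
  }
  if (any(npq_course < 0)) stop("NPQ targets must be >= 0", call. = FALSE)
  if (any(phi_course < 0 | phi_course > 1)) {
    stop("Phi_II targets must lie in [0, 1]", call. = FALSE)
  }
  check_number(baseline_noise_sd, "baseline_noise_sd", lower = 0)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(pulse_width, "pulse_width", lower = 0, strict_lower = TRUE)
  structure(
    list(f_m = f_m, npq_course = npq_course, phi_course = phi_course,
         pulse_times = pulse_times, baseline_noise_sd = baseline_noise_sd,
         sampling_rate = sampling_rate, pulse_width = pulse_width,
         seed = seed),
    class = "pam_sim_params"
  )
}

#' Parameters for the lamellar small-angle scattering generator
#'
#' Curves follow the lamellar Bragg-peak model
#' `I(q) = i0 + a_const * q^(-p_exp) + b_const * exp(-(q - q_star)^2 /
#' (2 c_width^2))` with multiplicative Gaussian noise as a stand-in for
#' counting statistics.
#'
#' @param i0,a_const,b_const Intensity constants (flat background, power-law
#'   amplitude, Bragg-peak amplitude).
#' @param p_exp Power-law exponent (> 0).
#' @param q_star Bragg-peak position in reciprocal angstroms; must lie
#'   inside `q_grid`.
#' @param c_width Gaussian standard deviation in reciprocal angstroms.
#' @param q_grid Scattering-vector grid in reciprocal angstroms (> 0,
#'   increasing).
#' @param rel_noise Relative noise scale (sd = `rel_noise * I(q)`).
#' @param seed Integer seed.
#' @return A `sans_sim_params` object.
#' @export
sans_sim_params <- function(i0 = 0.02, a_const = 2e-6, b_const = 0.2,
                            p_exp = 3, q_star = 0.025, c_width = 0.004,
                            q_grid = seq(0.012, 0.045, by = 2.5e-4),
                            rel_noise = 0, seed = NULL) {
  check_number(i0, "i0", lower = 0)
  check_number(a_const, "a_const", lower = 0)
  check_number(b_const, "b_const", lower = 0)
  check_number(p_exp, "p_exp", lower = 0, strict_lower = TRUE)
  check_number(c_width, "c_width", lower = 0, strict_lower = TRUE)
  check_number(rel_noise, "rel_noise", lower = 0)
  if (!is.numeric(q_grid) || length(q_grid) < 2L || any(q_grid <= 0) ||
      is.unsorted(q_grid, strictly = TRUE)) {
    stop("`q_grid` must be a strictly increasing positive grid",
         call. = FALSE)
  }
  check_number(q_star, "q_star", lower = min(q_grid), upper = max(q_grid))
  structure(
    list(i0 = i0, a_const = a_const, b_const = b_const, p_exp = p_exp,
         q_star = q_star, c_width = c_width, q_grid = q_grid,
         rel_noise = rel_noise, seed = seed),
    class = "sans_sim_params"
  )
}

#' Parameters for the synthetic circular-dichroism spectrum generator
#'
#' Spectra are sums of Gaussian bands on a smooth polynomial baseline,
#' emulating psi-type bands of leaf CD spectra (positive bands near 505 and
#' 690 nm, a negative band near 675 nm).
#'
#' @param bands Data frame with columns `center` (nm), `amplitude`
#'   (signal units, signed) and `width` (Gaussian sd, nm).  Centers must
#'   lie inside `wavelength_grid`.
#' @param baseline_poly Polynomial baseline coefficients (intercept first),
#'   evaluated in the variable `(wavelength - 600)/100`.
#' @param wavelength_grid Wavelengths in nm, strictly increasing.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @return A `cd_sim_params` object.
#' @export
cd_sim_params <- function(bands = data.frame(
                            center = c(505, 675, 690),
                            amplitude = c(4, -6, 5),
                            width = c(12, 10, 8)),
                          baseline_poly = 0,
                          wavelength_grid = seq(400, 800, by = 1),
                          noise_sd = 0, seed = NULL) {
  if (!is.numeric(wavelength_grid) || length(wavelength_grid) < 2L ||
      is.unsorted(wavelength_grid, strictly = TRUE)) {
    stop("`wavelength_grid` must be strictly increasing", call. = FALSE)
  }
  if (nrow(bands)) {
    stopifnot(all(c("center", "amplitude", "width") %in% names(bands)))
    if (any(bands$center < min(wavelength_grid) |
            bands$center > max(wavelength_grid))) {
      stop("band centers must lie inside the wavelength grid", call. = FALSE)
    }
    if (any(bands$width <= 0)) stop("band widths must be > 0", call. = FALSE)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(bands = bands, baseline_poly = baseline_poly,
         wavelength_grid = wavelength_grid, noise_sd = noise_sd, seed = seed),
    class = "cd_sim_params"
  )
}
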