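## Synthetic-data generators.  Every analysis stage in the package can be
## exercised by parameter recovery against these, with ground truth carried
## in `metadata$truth` and full determinism under a fixed seed.

#' Unitary current of the gating model at a holding potential
#'
#' `i(V) = gamma * (V - v_rev) / 1000` in pA, with the conductance branch
#' (`gamma_pos` / `gamma_neg`) selected by the sign of `V - v_rev`.
#'
#' @param params A [channel_gating_params()].
#' @param v Holding potential in mV.
#' @return Unitary current in pA (0 at the reversal potential).
#' @examples
#' unitary_current(channel_gating_params(gamma_pos = 96.1), 80) # 7.688 pA
#' @export
unitary_current <- function(params, v) {
  stopifnot(inherits(params, "channel_gating_params"))
  gamma <- ifelse(v >= params$v_rev, params$gamma_pos, params$gamma_neg)
  gamma * (v - params$v_rev) / 1000
}

## One two-state dwell path over [0, duration]: returns per-sample openness
## in [0, 1] (1 full open, substate_fraction for substate openings).
simulate_gating_path <- function(params, v, duration, n_samples) {
  rtf <- rtf_mv()
  k_open <- params$k_open_0 * exp(params$z_gate * v / rtf)
  k_close <- params$k_close
  if (k_open <= 0) return(numeric(n_samples))
  p_open <- k_open / (k_open + k_close)
  state0 <- stats::rbinom(1L, 1L, p_open)  # start at stationarity
  ## generate alternating dwell times until the trace is covered
  mean_cycle <- 1 / k_open + 1 / k_close
  dwells <- numeric(0)
  states <- integer(0)
  total <- 0
  s <- state0
  while (total < duration) {
    n_more <- max(32L, ceiling((duration - total) / mean_cycle * 2.5))
    rates <- ifelse(seq_len(n_more) %% 2L == 1L,
                    if (s == 1L) k_close else k_open,
                    if (s == 1L) k_open else k_close)
    d <- stats::rexp(n_more, rate = rates)
    dwells <- c(dwells, d)
    states <- c(states, (s + seq_len(n_more) - 1L) %% 2L)
    total <- total + sum(d)
    s <- (s + n_more) %% 2L
  }
  bounds <- cumsum(c(0, dwells))
  t_samp <- (seq_len(n_samples) - 1L) / (n_samples / duration)
  seg <- findInterval(t_samp, bounds, rightmost.closed = TRUE)
  level <- as.numeric(states[seg])
  ## substate assignment per opening (contiguous open dwell)
  if (params$substate_prob > 0) {
    open_segs <- which(states == 1L)
    is_sub <- stats::runif(length(open_segs)) < params$substate_prob
    sub_map <- rep(1, length(states))
    sub_map[open_segs[is_sub]] <- params$substate_fraction
    level <- level * sub_map[seg]
  }
  level
}

#' Simulate single-channel current traces
#'
#' Each channel gates as an independent continuous-time two-state Markov
#' chain with voltage-dependent opening rate
#' `k_open(V) = k_open_0 * exp(z_gate * V / (RT/F))` and constant closing
#' rate; openings may enter a partial-conductance substate.  Open channels
#' add the unitary current `gamma * (V - v_rev) / 1000` pA and Gaussian
#' recording noise is superposed.  One trace is returned per holding
#' potential, each drawn from its own seed sub-stream so individual traces
#' are reproducible in isolation.
#'
#' @param params A [channel_gating_params()].
#' @param config A [recording_config()]; the ionic condition must declare a
#'   permeant anion (Cl- or NO3-).
#' @return A list of [current_trace()] objects (one per holding potential).
#'   `metadata$truth` holds the generating parameters and
#'   `metadata$state_level` the noise-free per-sample openness (sum over
#'   channels, in units of the full unitary current).
#' @export
simulate_channel_trace <- function(params, config) {
  stopifnot(inherits(params, "channel_gating_params"),
            inherits(config, "recording_config"))
  if (!any(c("Cl", "NO3") %in% names(config$ionic$cis))) {
    stop_thylakoidr(
      "unsupported ionic species: no permeant anion (Cl or NO3) declared",
      "unsupported_ionic")
  }
  n_samples <- round(config$duration * config$sampling_rate)
  if (n_samples < 1L) stop_thylakoidr("zero-length trace", "empty_trace")
  traces <- vector("list", length(config$holding_potentials))
  for (k in seq_along(config$holding_potentials)) {
    v <- config$holding_potentials[k]
    traces[[k]] <- local_seed(substream_seed(config$seed, k), {
      level <- numeric(n_samples)
      for (ch in seq_len(params$n_channels)) {
        level <- level +
          simulate_gating_path(params, v, config$duration, n_samples)
      }
      i_unit <- unitary_current(params, v)
      current <- level * i_unit
      if (config$noise_sd > 0) {
        current <- current + stats::rnorm(n_samples, sd = config$noise_sd)
      }
      current_trace(
        time = (seq_len(n_samples) - 1L) / config$sampling_rate,
        current = current,
        holding_potential = v,
        ionic = config$ionic,
        sampling_rate = config$sampling_rate,
        metadata = list(truth = unclass(params),
                        seed = substream_seed(config$seed, k),
                        state_level = level)
      )
    })
  }
  names(traces) <- sprintf("%+g_mV", config$holding_potentials)
  traces
}

#' Simulate an electrochromic-shift trace
#'
#' Produces the 550--515 nm absorbance-difference signal for a
#' dark-baseline / flash / actinic-light / dark-interval protocol.  The
#' dark baseline sits at 0; single-turnover flashes step the signal by
#' `ecs_st_amp` and relax exponentially; under actinic light the signal
#' approaches `s_light`; within each dark interval it relaxes with time
#' constant `tau_decay` towards the inverted level
#' `s_light - ecs_t` where `ecs_t = s_light / f_dpsi`, so that the electric
#' fraction of the total amplitude is `f_dpsi` and the pH fraction
#' `1 - f_dpsi`.
#'
#' @param params An [ecs_sim_params()].
#' @return An [ecs_trace()] with ground truth in `metadata$truth`.
#' @export
simulate_ecs_trace <- function(params) {
  stopifnot(inherits(params, "ecs_sim_params"))
  pr <- params$protocol
  fs <- params$sampling_rate
  t_end <- max(pr$events$time) + pr$tail
  time <- seq(0, t_end, by = 1 / fs)
  tau <- params$tau_decay / 1000      # ms -> s
  ecs_t <- params$s_light / params$f_dpsi
  s_inv <- params$s_light - ecs_t     # <= 0; equals baseline when f_dpsi = 1

  ## piecewise-exponential base signal, continuous across segments
  signal <- numeric(length(time))
  segs <- pr$events[pr$events$event %in%
                      c("light_on", "light_off", "light_resume"), ]
  bounds <- c(-Inf, segs$time, Inf)
  s_at <- 0                            # level entering the first segment
  for (j in seq_len(length(bounds) - 1L)) {
    idx <- time >= bounds[j] & time < bounds[j + 1L]
    ev <- if (j == 1L) "dark_baseline" else segs$event[j - 1L]
    target <- switch(ev,
                     dark_baseline = 0,
                     light_on = params$s_light,
                     light_resume = params$s_light,
                     light_off = s_inv)
    t0 <- if (j == 1L) 0 else segs$time[j - 1L]
    if (any(idx)) {
      signal[idx] <- target + (s_at - target) * exp(-(time[idx] - t0) / tau)
    }
    t1 <- if (j == length(bounds) - 1L) t_end else segs$time[j]
    s_at <- target + (s_at - target) * exp(-(t1 - t0) / tau)
  }
  ## additive flash relaxations (flashes precede actinic light)
  for (tf in pr$flashes) {
    idx <- time >= tf
    signal[idx] <- signal[idx] +
      params$ecs_st_amp * exp(-(time[idx] - tf) / tau)
  }
  signal <- local_seed(params$seed, {
    if (params$noise_sd > 0) {
      signal + stats::rnorm(length(signal), sd = params$noise_sd)
    } else signal
  })
  ecs_trace(time, signal, pr, fs,
            metadata = list(truth = list(
              s_light = params$s_light, f_dpsi = params$f_dpsi,
              tau_decay = params$tau_decay, ecs_t = ecs_t,
              ecs_st_amp = params$ecs_st_amp, seed = params$seed)))
}

#' Simulate a pulse-amplitude-modulated fluorescence trace
#'
#' Exact inverse of the quenching analysis: at each saturating pulse the
#' trace jumps to `F_m' = f_m / (1 + NPQ_target)` for the pulse duration,
#' and the steady-state level preceding each pulse is
#' `F = F_m' * (1 - Phi_target)`.  Analysing the noiseless trace with
#' [analyze_pam()] therefore returns the target courses exactly.
#'
#' @param params A [pam_sim_params()].
#' @return A [fluor_trace()] with the target courses in `metadata$truth`.
#' @export
simulate_pam_trace <- function(params) {
  stopifnot(inherits(params, "pam_sim_params"))
  pt <- params$pulse_times
  if (length(pt) > 1L && any(diff(pt) <= params$pulse_width)) {
    stop("pulses overlap: spacing must exceed the pulse width",
         call. = FALSE)
  }
  fs <- params$sampling_rate
  t_end <- pt[length(pt)] + 1
  time <- seq(0, t_end, by = 1 / fs)
  f_m_prime <- params$f_m / (1 + params$npq_course)
  f_steady <- f_m_prime * (1 - params$phi_course)

  ## steady level between pulses is the F of the upcoming pulse
  next_pulse <- findInterval(time, pt + params$pulse_width) + 1L
  next_pulse[next_pulse > length(pt)] <- length(pt)
  fl <- f_steady[next_pulse]
  for (p in seq_along(pt)) {
    fl[time >= pt[p] & time <= pt[p] + params$pulse_width] <- f_m_prime[p]
  }
  fl <- local_seed(params$seed, {
    if (params$baseline_noise_sd > 0) {
      fl + stats::rnorm(length(fl), sd = params$baseline_noise_sd)
    } else fl
  })
  fluor_trace(time, fl, pt, params$f_m, fs,
              metadata = list(truth = list(
                npq_course = params$npq_course,
                phi_course = params$phi_course,
                f_m_prime = f_m_prime, f_steady = f_steady,
                seed = params$seed)))
}

#' Lamellar Bragg-peak scattering model
#'
#' `I(q) = i0 + a_const * q^(-p_exp) +
#'   b_const * exp(-(q - q_star)^2 / (2 * c_width^2))`:
#' a flat background, a power-law term for diffuse small-angle scattering,
#' and a Gaussian Bragg peak whose position `q_star` carries the lamellar
#' repeat distance.
#'
#' @param q Scattering vector, inverse angstroms.
#' @param i0,a_const,p_exp,b_const,q_star,c_width Model parameters (see
#'   [sans_sim_params()]).
#' @return Model intensity at `q`.
#' @export
bragg_model <- function(q, i0, a_const, p_exp, b_const, q_star, c_width) {
  i0 + a_const * q^(-p_exp) +
    b_const * exp(-(q - q_star)^2 / (2 * c_width^2))
}

#' Simulate a small-angle scattering curve
#'
#' Evaluates [bragg_model()] on the configured q grid and applies
#' multiplicative Gaussian noise (sd `rel_noise * I(q)`) as a desk-scale
#' proxy for counting statistics.  Pointwise uncertainties are reported as
#' `rel_noise * I(q)` when noise is on.
#'
#' @param params A [sans_sim_params()].
#' @return A [sans_curve()] with ground truth in `metadata$truth`.
#' @export
simulate_sans_curve <- function(params) {
  stopifnot(inherits(params, "sans_sim_params"))
  q <- params$q_grid
  ideal <- bragg_model(q, params$i0, params$a_const, params$p_exp,
                       params$b_const, params$q_star, params$c_width)
  intensity <- local_seed(params$seed, {
    if (params$rel_noise > 0) {
      ideal * (1 + stats::rnorm(length(q), sd = params$rel_noise))
    } else ideal
  })
  sigma <- if (params$rel_noise > 0) params$rel_noise * ideal else NULL
  truth <- unclass(params)
  truth$q_grid <- NULL
  sans_curve(q, intensity, sigma, metadata = list(truth = truth))
}

#' Simulate a circular-dichroism spectrum
#'
#' Sum of Gaussian bands on a smooth polynomial baseline plus additive
#' Gaussian noise, emulating leaf psi-type CD spectra (positive bands near
#' 505 and 690 nm and a negative band near 675 nm).
#'
#' @param params A [cd_sim_params()].
#' @return A [cd_spectrum()] with band truth in `metadata$truth`.
#' @export
simulate_cd_spectrum <- function(params) {
  stopifnot(inherits(params, "cd_sim_params"))
  wl <- params$wavelength_grid
  if (!length(wl)) stop("empty wavelength grid", call. = FALSE)
  x <- (wl - 600) / 100
  signal <- rep(0, length(wl))
  for (j in seq_along(params$baseline_poly)) {
    signal <- signal + params$baseline_poly[j] * x^(j - 1)
  }
  bands <- params$bands
  for (b in seq_len(nrow(bands))) {
    signal <- signal + bands$amplitude[b] *
      exp(-(wl - bands$center[b])^2 / (2 * bands$width[b]^2))
  }
  signal <- local_seed(params$seed, {
    if (params$noise_sd > 0) {
      signal + stats::rnorm(length(signal), sd = params$noise_sd)
    } else signal
  })
  cd_spectrum(wl, signal,
              metadata = list(truth = list(bands = bands,
                                           baseline_poly = params$baseline_poly,
                                           seed = params$seed)))
}
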