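test_that("channel generator honours trivial limits", {
  # no openings: constant zero trace
  p <- channel_gating_params(96.1, k_open_0 = 0)
  tr <- simulate_channel_trace(
    p, recording_config(sym_kcl(), 80, duration = 0.1, noise_sd = 0))[[1]]
  expect_equal(tr$current, rep(0, length(tr$time)))
  expect_length(tr$time, 0.1 * 5000)

  # unitary current at +80 mV with the positive-branch KCl conductance
  expect_equal(unitary_current(channel_gating_params(96.1), 80), 7.688)
  # negative branch picks gamma_neg
  expect_equal(unitary_current(channel_gating_params(96.1, 60), -50),
               60 * (-50) / 1000)
})

test_that("channel generator rejects anion-free conditions and validates config", {
  p <- channel_gating_params(96.1)
  k_only <- ionic_condition(c(K = 100), c(K = 100))
  expect_error(
    simulate_channel_trace(p, recording_config(k_only, 80, duration = 0.1)),
    class = "unsupported_ionic")
  expect_error(recording_config(sym_kcl(), 80, duration = 1e-4,
                                sampling_rate = 5000),
               "at least 10 samples")
  expect_error(channel_gating_params(-5), ">")
  expect_error(channel_gating_params(96.1, substate_prob = 1.5), "<=")
})

test_that("long-run open probability matches the two-state stationary value", {
  # z_gate = 0 makes k_open = k_close at every voltage: P_open = 0.5.
  # For a two-state chain the time-average fraction open over T has
  # variance ~ 2 p (1-p) tau_c / T, tau_c = 1/(k_open + k_close):
  # sd ~ 0.0091 for 60 s at 50/50 Hz rates; allow 3 sd.
  p <- channel_gating_params(96.1, k_open_0 = 50, k_close = 50, z_gate = 0)
  tr <- simulate_channel_trace(
    p, recording_config(sym_kcl(), 60, duration = 60, noise_sd = 0,
                        seed = 404))[[1]]
  p_emp <- mean(tr$metadata$state_level > 0.5)
  expect_lt(abs(p_emp - 0.5), 3 * 0.0091)
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- channel_gating_params(96.1, substate_prob = 0.3)
  cfg <- recording_config(sym_kcl(), c(40, 80), duration = 0.5, seed = 42)
  t1 <- simulate_channel_trace(p, cfg)
  t2 <- simulate_channel_trace(p, cfg)
  expect_identical(t1[[1]]$current, t2[[1]]$current)
  expect_identical(t1[[2]]$current, t2[[2]]$current)

  e1 <- simulate_ecs_trace(ecs_sim_params(noise_sd = 0.02, seed = 7))
  e2 <- simulate_ecs_trace(ecs_sim_params(noise_sd = 0.02, seed = 7))
  expect_identical(e1$signal, e2$signal)

  s1 <- simulate_sans_curve(sans_sim_params(rel_noise = 0.02, seed = 7))
  s2 <- simulate_sans_curve(sans_sim_params(rel_noise = 0.02, seed = 7))
  expect_identical(s1$intensity, s2$intensity)

  c1 <- simulate_cd_spectrum(cd_sim_params(noise_sd = 0.1, seed = 7))
  c2 <- simulate_cd_spectrum(cd_sim_params(noise_sd = 0.1, seed = 7))
  expect_identical(c1$cd_signal, c2$cd_signal)

  f1 <- simulate_pam_trace(pam_sim_params(npq_course = 1, phi_course = 0.5,
                                          pulse_times = 30,
                                          baseline_noise_sd = 0.01,
                                          seed = 7))
  f2 <- simulate_pam_trace(pam_sim_params(npq_course = 1, phi_course = 0.5,
                                          pulse_times = 30,
                                          baseline_noise_sd = 0.01,
                                          seed = 7))
  expect_identical(f1$fluorescence, f2$fluorescence)
})

test_that("ECS generator realises the configured level structure", {
  # f_dpsi = 1: the inverted level coincides with the dark baseline
  tr1 <- simulate_ecs_trace(ecs_sim_params(f_dpsi = 1))
  di <- dark_intervals(tr1)
  s_end <- tr1$signal[max(which(tr1$time <= di[1, 2]))]
  expect_lt(abs(s_end - 0), 1e-6)

  # exponential definition: one time constant into the interval the
  # signal has fallen to S_inv + (S_light - S_inv)/e
  tau <- 25
  tr <- simulate_ecs_trace(ecs_sim_params(s_light = 1, f_dpsi = 0.6,
                                          tau_decay = tau))
  di <- dark_intervals(tr)
  ecs_t <- 1 / 0.6
  s_inv <- 1 - ecs_t
  idx <- which.min(abs(tr$time - (di[1, 1] + tau / 1000)))
  expect_equal(tr$signal[idx], s_inv + (1 - s_inv) * exp(-1),
               tolerance = 1e-6)

  # noiseless amplitude: S_light - S_inv equals the configured total
  s_light_obs <- tr$signal[max(which(tr$time < di[1, 1]))]
  s_inv_obs <- tr$signal[max(which(tr$time <= di[1, 2]))]
  expect_equal(s_light_obs - s_inv_obs, ecs_t, tolerance = 1e-6)

  # overlapping dark intervals are rejected
  expect_error(ecs_protocol(dark_intervals = c(5, 5.3), interval_s = 0.6),
               "overlap")
})

test_that("PAM generator inverts the quenching formulas", {
  # NPQ = 0 leaves F_m' at the dark F_m; F_m = 2, NPQ = 1 halves it
  pm <- pam_sim_params(f_m = 2, npq_course = c(0, 1), phi_course = c(0.5, 0),
                       pulse_times = c(10, 20))
  tr <- simulate_pam_trace(pm)
  expect_equal(tr$metadata$truth$f_m_prime, c(2, 1))
  # Phi = 0: steady level equals F_m'
  expect_equal(tr$metadata$truth$f_steady[2], 1)
  expect_error(pam_sim_params(npq_course = 1, phi_course = 1.2,
                              pulse_times = 10),
               "\\[0, 1\\]")
})

test_that("SANS generator follows the Bragg-peak model exactly", {
  pars <- sans_sim_params()
  cv <- simulate_sans_curve(pars)
  expect_equal(cv$intensity,
               bragg_model(pars$q_grid, pars$i0, pars$a_const, pars$p_exp,
                           pars$b_const, pars$q_star, pars$c_width))
  # no peak: pure power law + constant
  p0 <- sans_sim_params(b_const = 0)
  cv0 <- simulate_sans_curve(p0)
  expect_equal(cv0$intensity, p0$i0 + p0$a_const * p0$q_grid^(-p0$p_exp))
  # value at the peak position
  iq <- cv$intensity[which.min(abs(cv$q - pars$q_star))]
  expect_equal(iq, pars$i0 + pars$a_const * pars$q_star^(-pars$p_exp) +
                 pars$b_const, tolerance = 1e-12)
  expect_error(sans_sim_params(q_star = 0.5), "<=")
})

test_that("CD generator realises bands on the configured grid", {
  flat <- simulate_cd_spectrum(cd_sim_params(
    bands = data.frame(center = numeric(0), amplitude = numeric(0),
                       width = numeric(0))))
  expect_equal(flat$cd_signal, rep(0, length(flat$wavelength)))

  one <- simulate_cd_spectrum(cd_sim_params(
    bands = data.frame(center = 505, amplitude = 5, width = 10)))
  expect_equal(one$cd_signal[one$wavelength == 505], 5)

  # narrow-width limit approximates a spike on a fine grid
  spike <- simulate_cd_spectrum(cd_sim_params(
    bands = data.frame(center = 505, amplitude = 5, width = 0.05),
    wavelength_grid = seq(500, 510, by = 0.01)))
  expect_equal(spike$cd_signal[spike$wavelength == 505], 5)
  expect_lt(max(abs(spike$cd_signal[abs(spike$wavelength - 505) > 1])), 1e-8)

  expect_error(cd_sim_params(bands = data.frame(center = 300, amplitude = 1,
                                                width = 5)),
               "inside the wavelength grid")
})
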