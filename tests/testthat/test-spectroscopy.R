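test_that("quenching formulas follow their definitions", {
  expect_equal(compute_npq(2, 2), 0)
  expect_equal(compute_npq(2, 1), 1)
  expect_warning(npq_neg <- compute_npq(1, 2), "negative NPQ")
  expect_equal(npq_neg, -0.5)
  expect_error(compute_npq(2, 0), "> 0")

  expect_equal(compute_phi_ii(1, 1), 0)
  expect_equal(compute_phi_ii(1, 0.4), 0.6)
  expect_equal(compute_phi_ii(1, 0), 1)
  expect_error(compute_phi_ii(0, 0.4), "> 0")

  # joint rescaling of all fluorescence levels cancels
  expect_equal(compute_npq(2 * 7, 1 * 7), compute_npq(2, 1))
  expect_equal(compute_phi_ii(1 * 7, 0.4 * 7), compute_phi_ii(1, 0.4))
})

test_that("pulse extraction inverts the PAM generator exactly", {
  npq <- c(0.2, 0.8, 1.4, 1.1)
  phi <- c(0.7, 0.55, 0.42, 0.47)
  tr <- simulate_pam_trace(pam_sim_params(
    f_m = 2, npq_course = npq, phi_course = phi,
    pulse_times = c(20, 50, 80, 110)))
  ser <- analyze_pam(tr)
  expect_equal(ser$npq, npq, tolerance = 1e-9)
  expect_equal(ser$phi_ii, phi, tolerance = 1e-9)
  expect_equal(ser$f_m_prime, 2 / (1 + npq), tolerance = 1e-9)

  # no pulses: empty series
  no_pulse <- fluor_trace(time = seq(0, 10, by = 0.01),
                          fluorescence = rep(1, 1001),
                          pulse_times = numeric(0), f_m = 2,
                          sampling_rate = 100)
  expect_equal(nrow(extract_pulse_values(no_pulse)), 0L)

  # overlapping pulse windows are refused
  close_pulses <- fluor_trace(seq(0, 10, by = 0.01), rep(1, 1001),
                              pulse_times = c(5, 5.5), f_m = 2,
                              sampling_rate = 100)
  expect_error(extract_pulse_values(close_pulses),
               class = "overlapping_pulses")
  # pulse window running past the trace end is refused
  edge <- fluor_trace(seq(0, 10, by = 0.01), rep(1, 1001),
                      pulse_times = 9.9, f_m = 2, sampling_rate = 100)
  expect_error(extract_pulse_values(edge), class = "pulse_out_of_range")
})

test_that("CD normalization composes multiplicatively", {
  sp <- simulate_cd_spectrum(cd_sim_params())
  expect_equal(normalize_cd(sp, 1)$cd_signal, sp$cd_signal)
  expect_equal(normalize_cd(sp, 2)$cd_signal, sp$cd_signal / 2)
  ab <- normalize_cd(normalize_cd(sp, 2), 3)
  once <- normalize_cd(sp, 6)
  expect_equal(ab$cd_signal, once$cd_signal)
  expect_equal(ab$normalization, once$normalization)
  expect_error(normalize_cd(sp, 0), "> 0")
})

test_that("psi-type band amplitudes are two-point differences", {
  flat <- cd_spectrum(seq(400, 800, 2), rep(1.3, 201))
  for (j in seq_len(nrow(psi_band_pairs()))) {
    pr <- psi_band_pairs()[j, ]
    expect_equal(psi_band_amplitude(flat, pr$band, pr$reference), 0)
  }
  expect_equal(psi_band_amplitude(flat, 505, 505), 0)

  # synthetic spectrum with known values at band and reference
  wl <- seq(400, 800, 1)
  sig <- rep(2, length(wl)); sig[wl == 505] <- 5
  sp <- cd_spectrum(wl, sig)
  expect_equal(psi_band_amplitude(sp, 505, 550), 3)

  # constant offsets cancel
  sp_off <- cd_spectrum(wl, sig + 11)
  expect_equal(psi_band_amplitude(sp_off, 505, 550),
               psi_band_amplitude(sp, 505, 550))

  expect_error(psi_band_amplitude(sp, 390, 550),
               class = "wavelength_out_of_range")

  # generated spectrum: all three bands recovered with correct signs
  amps <- psi_band_amplitudes(simulate_cd_spectrum(cd_sim_params()))
  expect_equal(sign(amps$amplitude), c(1, -1, 1))
})
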