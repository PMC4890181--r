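test_that("amplitude histograms conserve samples and resolve levels", {
  # constant trace: everything in one bin
  tr0 <- current_trace(time = (0:99) / 5000, current = rep(0, 100),
                       holding_potential = 80, ionic = sym_kcl(),
                       sampling_rate = 5000)
  h0 <- build_amplitude_histogram(tr0, 0.1)
  expect_equal(sum(h0$counts > 0), 1L)
  expect_equal(sum(h0$counts), 100L)

  # count conservation on a noisy generated trace
  tr <- simulate_channel_trace(
    channel_gating_params(96.1),
    recording_config(sym_kcl(), 80, duration = 1, noise_sd = 0.8,
                     seed = 1))[[1]]
  h <- build_amplitude_histogram(tr, 0.05)
  expect_equal(sum(h$counts), length(tr$current))
  expect_true(all(diff(h$bin_edges) > 0))

  # noiseless two-level alternation: exactly two occupied bins, one
  # unitary current apart
  i_open <- 7.688
  h2 <- build_amplitude_histogram(two_level_trace(i_open), 0.1)
  occ <- which(h2$counts > 0)
  expect_length(occ, 2L)
  centers <- (h2$bin_edges[-1] + h2$bin_edges[-length(h2$bin_edges)]) / 2
  expect_equal(diff(centers[occ]), i_open, tolerance = h2$bin_width)

  expect_error(build_amplitude_histogram(tr, 0), ">")
})

test_that("unitary current is recovered from histogram mixture fits", {
  # clean separation: exact two-mode histogram
  h <- build_amplitude_histogram(two_level_trace(7.688), 0.1)
  expect_equal(as.numeric(estimate_unitary_current(h)), 7.688,
               tolerance = 0.02)

  # noisy generated recording: within 2% of the true separation
  tr <- simulate_channel_trace(
    channel_gating_params(96.1),
    recording_config(sym_kcl(), 80, duration = 20, noise_sd = 0.8,
                     seed = 11))[[1]]
  sep <- estimate_unitary_current(build_amplitude_histogram(tr, 0.1))
  expect_equal(as.numeric(sep), 7.688, tolerance = 0.02)

  # all-closed trace: no open events signal
  closed <- simulate_channel_trace(
    channel_gating_params(96.1, k_open_0 = 0),
    recording_config(sym_kcl(), 80, duration = 2, noise_sd = 0.8,
                     seed = 2))[[1]]
  expect_error(
    estimate_unitary_current(build_amplitude_histogram(closed, 0.1)),
    class = "no_open_events")
})

test_that("half-amplitude idealization labels dwells and open probability", {
  # noiseless 50/50 alternation
  tr <- two_level_trace(7.688, n = 1000, period = 10)
  id <- idealize_half_amplitude(tr, 7.688)
  expect_equal(id$open_probability, 0.5)
  # segments tile the trace exactly
  expect_equal(sum(id$segments$duration), length(tr$time) / tr$sampling_rate)
  expect_equal(id$segments$start,
               cumsum(c(0, head(id$segments$duration, -1))))

  # all-closed trace
  tr0 <- current_trace((0:99) / 5000, rep(0, 100), 80, sym_kcl(), 5000)
  expect_equal(idealize_half_amplitude(tr0, 7.688)$open_probability, 0)
  expect_error(idealize_half_amplitude(tr0, 0), class = "zero_unitary")

  # against the generator's stored state path at modest noise
  sim <- simulate_channel_trace(
    channel_gating_params(96.1),
    recording_config(sym_kcl(), 80, duration = 5, noise_sd = 0.5,
                     seed = 3))[[1]]
  id2 <- idealize_half_amplitude(sim, 7.688)
  truth <- ifelse(sim$metadata$state_level > 0.5, "open", "closed")
  expect_gte(mean(id2$per_sample == truth), 0.99)
})

test_that("branch conductance fits slope through the reversal point", {
  pts <- data.frame(voltage = c(-80, -40, 40, 80),
                    current = 0.1 * c(-80, -40, 40, 80))
  fit <- fit_branch_conductance(pts)
  expect_equal(fit$gamma_pos, 100)
  expect_equal(fit$gamma_neg, 100)

  # positive-branch-only data: negative branch unavailable, positive kept
  pos <- data.frame(voltage = c(40, 60, 80),
                    current = 96.1 * c(40, 60, 80) / 1000)
  fp <- fit_branch_conductance(pos)
  expect_equal(fp$gamma_pos, 96.1)
  expect_true(is.na(fp$gamma_neg))

  # single-branch mode pools all voltages
  fs <- fit_branch_conductance(pts, branches = "single")
  expect_equal(fs$gamma_single, 100)

  expect_error(fit_branch_conductance(pos[1, , drop = FALSE]),
               class = "too_few_points")
})

test_that("GHK reversal potential obeys its limiting cases", {
  # symmetric salt: 0 mV at any permeability ratio
  expect_equal(ghk_reversal_potential(0.5, sym_kcl()), 0)
  # pure anion conduction: Nernst potential for Cl-, (RT/F) ln 3
  expect_equal(ghk_reversal_potential(0, asym_kcl()),
               rtf_mv(298.15) * log(3), tolerance = 1e-12)
  expect_lt(abs(ghk_reversal_potential(0, asym_kcl()) - 28.2), 0.05)
  # equal permeabilities in a pure salt gradient: 0 mV
  expect_equal(ghk_reversal_potential(1, asym_kcl()), 0)
})

test_that("GHK inversion is the exact inverse and monotone", {
  ion <- asym_kcl()
  for (p in c(0, 0.05, 0.17, 0.5, 1, 2, 5, 10)) {
    v <- ghk_reversal_potential(p, ion)
    expect_equal(fit_permeability_ratio(v, ion)$p_ratio, p,
                 tolerance = 1e-12)
  }
  # strictly monotone (decreasing) in p_ratio for this gradient
  vs <- vapply(seq(0, 10, by = 0.25), ghk_reversal_potential,
               numeric(1), ionic = ion)
  expect_true(all(diff(vs) < 0))
  # Nernst Cl- limit inverts to zero K+ permeability
  expect_equal(
    fit_permeability_ratio(rtf_mv() * log(3), ion)$p_ratio, 0,
    tolerance = 1e-12)
  expect_error(fit_permeability_ratio(0, sym_kcl()),
               class = "unidentifiable")
  expect_error(fit_permeability_ratio(40, ion),
               class = "vrev_out_of_range")
})

test_that("GHK current model crosses zero at the GHK reversal potential", {
  ion <- asym_kcl()
  for (p in c(0.17, 1, 3)) {
    v_rev <- ghk_reversal_potential(p, ion)
    expect_lt(abs(ghk_current(v_rev, p, ion)), 1e-9)
    # crossing recovered from a dense noiseless curve
    v <- seq(-60, 60, by = 1)
    expect_lt(abs(estimate_reversal_potential(v, ghk_current(v, p, ion)) -
                    v_rev), 0.05)
    expect_lt(abs(estimate_reversal_potential(v, ghk_current(v, p, ion),
                                              "poly") - v_rev), 0.5)
  }
  expect_error(estimate_reversal_potential(c(10, 20), c(1, 2)),
               class = "no_crossing")
})

test_that("end-to-end conductance recovery stays within 5%", {
  sim <- simulate_channel_trace(
    channel_gating_params(96.1, 60),
    recording_config(sym_kcl(), c(-60, -40, 40, 60), duration = 15,
                     noise_sd = 0.7, seed = 21))
  pts <- do.call(rbind, lapply(sim, function(tr) {
    sep <- estimate_unitary_current(build_amplitude_histogram(tr, 0.1))
    data.frame(voltage = tr$holding_potential,
               current = sign(tr$holding_potential) * as.numeric(sep))
  }))
  fit <- fit_branch_conductance(pts)
  expect_lt(abs(fit$gamma_pos - 96.1), 0.05 * 96.1)
  expect_lt(abs(fit$gamma_neg - 60), 0.05 * 60)
})
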