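test_that("flash amplitude is the mean over flashes", {
  # generator flashes all share one amplitude
  tr <- simulate_ecs_trace(ecs_sim_params(ecs_st_amp = 0.5))
  expect_equal(measure_ecs_st(tr), 0.5, tolerance = 1e-6)

  # distinct step amplitudes average arithmetically: build a trace with
  # instantaneous steps of 1, 2, 3 at the flash times
  fs <- 1000
  time <- seq(0, 3, by = 1 / fs)
  pr <- ecs_protocol(baseline = c(0, 0.5), flashes = c(0.8, 1.5, 2.2),
                     light_on = 2.8, dark_intervals = numeric(0), tail = 0.2)
  sig <- numeric(length(time))
  for (j in seq_along(pr$flashes)) {
    k <- which(time >= pr$flashes[j] & time < pr$flashes[j] + 0.004)
    sig[k] <- j
  }
  tr2 <- ecs_trace(time, sig, pr, fs)
  expect_equal(measure_ecs_st(tr2), 2)

  # flash annotated at the very end of the trace is unusable
  pr_bad <- ecs_protocol(baseline = c(0, 0.5), flashes = 2.999,
                         light_on = 3, dark_intervals = numeric(0), tail = 0)
  tr3 <- ecs_trace(time, sig, pr_bad, fs)
  expect_error(measure_ecs_st(tr3), class = "flash_out_of_range")
  # and a protocol without flashes errors
  pr0 <- ecs_protocol(flashes = numeric(0))
  tr0 <- simulate_ecs_trace(ecs_sim_params(protocol = pr0))
  expect_error(measure_ecs_st(tr0), class = "no_flashes")
})

test_that("flash normalization scales to the largest flash amplitude", {
  # all flash amplitudes equal: values unchanged
  expect_equal(normalize_ecs_t(c(0.5, 0.8), c(1, 1)), c(0.5, 0.8))
  # correction factor maxECS_ST / ECS_ST
  expect_equal(normalize_ecs_t(c(0.8, 1.0), c(1.0, 2.0))[1], 1.6)
  # a single measurement is its own maximum
  expect_equal(normalize_ecs_t(0.7, 1.3), 0.7)
  # idempotence: the measurement with the max flash is the anchor
  x <- normalize_ecs_t(c(0.8, 1.0, 0.6), c(1, 2, 1.6))
  expect_equal(normalize_ecs_t(x, c(2, 2, 2)), x)
  # scale equivariance in the flash amplitudes
  expect_equal(normalize_ecs_t(c(0.8, 1.0), 5 * c(1.0, 2.0)),
               normalize_ecs_t(c(0.8, 1.0), c(1.0, 2.0)))
  expect_error(normalize_ecs_t(numeric(0), numeric(0)), "empty")
  expect_error(normalize_ecs_t(1, 0), "positive")
})

test_that("PMF partitioning reads the three levels", {
  # pure electric PMF: no undershoot, pH fraction 0
  pp1 <- suppressWarnings(
    partition_pmf(simulate_ecs_trace(ecs_sim_params(f_dpsi = 1))))
  expect_equal(pp1$f_dph, 0, tolerance = 1e-6)

  # hand-built levels: S_light = 1, S_base = 0.4, S_inv = 0
  fs <- 1000
  time <- seq(0, 6, by = 1 / fs)
  pr <- ecs_protocol(baseline = c(0, 1), flashes = numeric(0), light_on = 2,
                     dark_intervals = 4.5, interval_s = 0.6, tail = 0.9)
  sig <- rep(0.4, length(time))
  sig[time >= 2 & time < 4.5] <- 1
  sig[time >= 4.5 & time <= 5.1] <- 0
  tr <- ecs_trace(time, sig, pr, fs)
  pp <- partition_pmf(tr)
  expect_equal(pp$ecs_t_raw, 1)
  expect_equal(pp$f_dpsi, 0.6)
  expect_equal(pp$f_dph, 0.4)

  # noiseless generator round trip is exact
  prm <- ecs_sim_params(s_light = 1, f_dpsi = 0.6, tau_decay = 25)
  pp2 <- partition_pmf(simulate_ecs_trace(prm))
  expect_equal(pp2$ecs_t_raw, 1 / 0.6, tolerance = 1e-6)
  expect_equal(pp2$f_dpsi, 0.6, tolerance = 1e-6)
  expect_equal(pp2$tau, 25, tolerance = 25 * 1e-6)

  expect_error(partition_pmf(tr, interval = c(4.5, 4.7)),
               class = "interval_too_short")
})

test_that("partition fractions always complement to one", {
  set.seed(31)
  for (r in 1:20) {
    f <- runif(1, 0.1, 0.95)
    pp <- suppressWarnings(partition_pmf(simulate_ecs_trace(
      ecs_sim_params(s_light = runif(1, 0.5, 2), f_dpsi = f,
                     tau_decay = runif(1, 10, 60),
                     noise_sd = 0.01, seed = r))))
    expect_equal(pp$f_dpsi + pp$f_dph, 1, tolerance = 1e-9)
    expect_gte(pp$f_dpsi, 0); expect_lte(pp$f_dpsi, 1)
  }
})

test_that("electric fraction is recovered without bias under noise", {
  # 100 replicates at 2% amplitude noise: mean recovered f_dpsi +/- 0.02
  f_hat <- vapply(1:100, function(s) {
    partition_pmf(simulate_ecs_trace(
      ecs_sim_params(s_light = 1, f_dpsi = 0.5, tau_decay = 25,
                     noise_sd = 0.02 * 2, seed = s)))$f_dpsi
  }, numeric(1))
  expect_lt(abs(mean(f_hat) - 0.5), 0.02)
})

test_that("proton conductivity is the reciprocal decay time constant", {
  for (tau in c(25, 10)) {
    gh <- fit_gh_plus(simulate_ecs_trace(ecs_sim_params(tau_decay = tau)))
    expect_equal(gh$tau, tau, tolerance = tau * 1e-6)
    expect_equal(gh$g_h, 1000 / tau, tolerance = 1e-3)
  }
  # non-decaying segment raises the no-decay signal
  fs <- 1000
  time <- seq(0, 6, by = 1 / fs)
  pr <- ecs_protocol(baseline = c(0, 1), flashes = numeric(0), light_on = 2,
                     dark_intervals = 4.5, tail = 0.9)
  flat <- ecs_trace(time, rep(1, length(time)), pr, fs)
  expect_error(fit_gh_plus(flat), class = "no_decay")
})

test_that("decay fitting tolerates realistic noise", {
  # 2% of the decay amplitude, 100 seeds: tau within 5% in >= 95 runs
  ecs_t <- 1 / 0.6
  ok <- vapply(1:100, function(s) {
    gh <- fit_gh_plus(simulate_ecs_trace(
      ecs_sim_params(s_light = 1, f_dpsi = 0.6, tau_decay = 25,
                     noise_sd = 0.02 * ecs_t, seed = 1000 + s)))
    abs(gh$tau - 25) / 25 < 0.05
  }, logical(1))
  expect_gte(sum(ok), 95)
})
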