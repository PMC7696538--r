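test_that("background generator honors length, mean, determinism and errors", {
  bg <- generate_background(10, 500, 1, 10, seed = 1)
  expect_length(bg$samples, 5000L)
  expect_lt(abs(mean(bg$samples)), 1e-9)
  expect_equal(sd(bg$samples), 10, tolerance = 1e-10)

  bg2 <- generate_background(10, 500, 1, 10, seed = 1)
  expect_identical(bg$samples, bg2$samples)
  bg3 <- generate_background(10, 500, 1, 10, seed = 2)
  expect_false(identical(bg$samples, bg3$samples))

  expect_error(generate_background(0, 500), "positive")
  expect_error(generate_background(10, -1), "positive")
})

test_that("background periodogram slope matches the requested 1/f exponent", {
  for (beta in c(0.5, 1, 1.5)) {
    bg <- generate_background(60, 1000, beta, 10, seed = 42)
    sp <- spec.pgram(ts(bg$samples, frequency = 1000), plot = FALSE,
                     taper = 0, detrend = FALSE)
    sel <- sp$freq >= 1 & sp$freq <= 499
    slope <- unname(coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
    expect_lt(abs(slope + beta), 0.2)
  }
})

test_that("coupled oscillations implement the normalized modulation model", {
  fs <- 1000
  quiet <- signal_trace(numeric(40 * fs) + 0, fs)

  # kappa = 0: constant fast-band envelope (CV < 0.05 after edge trimming)
  tr0 <- add_coupled_oscillations(quiet, 2.5, 20,
    data.frame(fa_carrier = 80, fa_amp = 5, kappa = 0))
  env <- band_envelope_phase(tr0, 70, 90)$envelope
  core <- env[(2 * fs):(38 * fs)]
  expect_lt(sd(core) / mean(core), 0.05)

  # kappa = 1: envelope maxima at delta phase 0 within +-10 ms
  tr1 <- add_coupled_oscillations(quiet, 2.5, 20,
    data.frame(fa_carrier = 80, fa_amp = 5, kappa = 1))
  env1 <- band_envelope_phase(tr1, 70, 90)$envelope
  tt <- trace_times(tr1)
  # expected delta-phase-zero instants: t = k / 2.5
  for (k in 6:20) {
    t0 <- k / 2.5
    win <- which(abs(tt - t0) <= 0.2)
    t_peak <- tt[win[which.max(env1[win])]]
    expect_lt(abs(t_peak - t0), 0.010 + 1 / fs)
  }

  # carriers at or above Nyquist are rejected
  expect_error(add_coupled_oscillations(quiet, 2.5, 20,
    data.frame(fa_carrier = 600, fa_amp = 1, kappa = 0.5)), "Nyquist")
  expect_error(synthetic_spec(coupling = data.frame(fa_carrier = 80,
    fa_amp = 1, kappa = 1.2)), "kappa")
})

test_that("stronger imposed coupling yields stronger measured tPAC", {
  c_hi <- tpac(coupled_trace(0.8, seed = 11), gamma_cfg(), "gamma")
  c_lo <- tpac(coupled_trace(0.2, seed = 11), gamma_cfg(), "gamma")
  expect_gt(c_hi$mean_coupling, c_lo$mean_coupling)
})

test_that("discharge injection is Poisson-driven, complete and reproducible", {
  tr <- generate_background(600, 500, 1, 10, seed = 5)
  inj <- inject_ied_events(tr, c(spike = 3.61), 6, seed = 9)
  inj2 <- inject_ied_events(tr, c(spike = 3.61), 6, seed = 9)
  expect_identical(inj$trace$samples, inj2$trace$samples)
  expect_identical(inj$ground_truth, inj2$ground_truth)

  # mean count over seeds close to rate * duration (light refractory thinning)
  counts <- vapply(1:12, function(s)
    nrow(inject_ied_events(tr, c(spike = 3.61), 6, seed = s)$ground_truth),
    numeric(1))
  expect_gt(mean(counts), 0.85 * 36.1)
  expect_lt(mean(counts), 1.05 * 36.1)

  # all rates zero: unchanged trace, empty ground truth
  inj0 <- inject_ied_events(tr, c(spike = 0, polyspike = 0, sharp_wave = 0))
  expect_identical(inj0$trace$samples, tr$samples)
  expect_identical(nrow(inj0$ground_truth), 0L)

  # event support and widths by construction
  gt <- inj$ground_truth
  expect_true(all(gt$time_s >= 0 & gt$time_s < 600))
  expect_true(all(gt$duration_ms >= 20 & gt$duration_ms <= 70))
  expect_error(inject_ied_events(tr, c(spike = -1)), ">= 0")
})

test_that("sessions are deterministic and reproduce imposed band structure", {
  g1 <- small_session(seed = 3)
  g2 <- small_session(seed = 3)
  expect_identical(g1$session$traces$left_hipp$samples,
                   g2$session$traces$left_hipp$samples)
  expect_identical(g1$ground_truth$ied_events, g2$ground_truth$ied_events)

  # left/right share discharge times but not noise
  expect_false(identical(g1$session$traces$left_hipp$samples,
                         g1$session$traces$right_hipp$samples))

  # schedule longer than the recording is rejected
  expect_error(generate_session(
    synthetic_spec(duration_s = 100, fs = 500), small_schedule()), "longer")
})

test_that("post-train theta multiplier raises post-epoch relative theta", {
  gen <- small_session(seed = 7, post_theta_mult = 1.3)
  ep <- extract_epochs(gen$session)
  pre <- epoch_trace(gen$session, ep, "pre30", "left_hipp")
  post <- epoch_trace(gen$session, ep, "post30", "left_hipp")
  expect_gt(relative_band_power(post, "theta"),
            relative_band_power(pre, "theta"))
})

test_that("post-train kappa multiplier lowers post-epoch MaxPAC", {
  sched <- build_schedule(n_trains = 2, train_s = 10, pause_s = 30,
                          pre_s = 90, post_s = 90)
  spec <- synthetic_spec(duration_s = 230, fs = 1500, post_kappa_mult = 0.5,
                         coupling = data.frame(fa_carrier = 80, fa_amp = 8,
                                               kappa = 0.5),
                         seed = 7)
  gen <- generate_session(spec, sched)
  pt <- epoch_pac(gen$session, config = gamma_cfg())
  for (ch in c("left_hipp", "right_hipp")) {
    pre <- pt$max_pac[pt$epoch == "pre5" & pt$channel == ch]
    post <- pt$max_pac[pt$epoch == "post5" & pt$channel == ch]
    expect_gt(pre, post)
  }
})

test_that("noiseless deterministic components match the Parseval bookkeeping", {
  spec <- synthetic_spec(duration_s = 120, fs = 1500, noise_scale = 0,
                         ied_rates = c(spike = 0), delta_jitter_hz = 0,
                         seed = 1)
  gen <- generate_session(spec, NULL)
  bp <- band_powers(compute_psd(gen$session$traces$left_hipp))
  measured <- unname(bp$absolute["theta"] / bp$total_power)
  expect_equal(measured, gen$ground_truth$imposed_theta_fraction,
               tolerance = 0.02)
})

test_that("cohort seizure log reproduces the imposed design", {
  # null effect: rate change centered on zero
  null_spec <- cohort_spec(n_animals = 150, dbs_rate_multiplier = 1,
                           dbs_duration_multiplier = 1, seed = 4)
  coh0 <- generate_seizure_log(null_spec)
  se <- sd(coh0$animals$rate_change) / sqrt(nrow(coh0$animals))
  expect_lt(abs(mean(coh0$animals$rate_change)), 3 * se)

  # multiplier 0.77 -> ~23% cohort-level decrease (averaged over seeds)
  dec <- vapply(1:5, function(s) {
    coh <- generate_seizure_log(cohort_spec(n_animals = 200, seed = s))
    100 * (mean(coh$animals$rate_before) - mean(coh$animals$rate_dbs)) /
      mean(coh$animals$rate_before)
  }, numeric(1))
  expect_lt(abs(mean(dec) - 23), 3)

  # negative PAC-outcome slope shows up as negative sample correlation
  coh <- generate_seizure_log(cohort_spec(n_animals = 200,
                                          pac_outcome_slope = -0.01, seed = 2))
  expect_lt(cor(coh$animals$pac_level, coh$animals$rate_change), 0)

  # durations follow the lognormal mean within sampling error
  expect_equal(mean(coh$log$duration_s[coh$log$phase == "before"]), 60.84,
               tolerance = 0.1)
  expect_error(generate_seizure_log(cohort_spec(n_animals = 1)), ">= 2")
})
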