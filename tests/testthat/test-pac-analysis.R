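test_that("tPAC recovers the imposed carrier and is scale invariant", {
  tr <- coupled_trace(1, seed = 11)
  fit <- tpac(tr, gamma_cfg(), "gamma")
  expect_lt(abs(fit$max_pac_fa - 80), 0.5)
  expect_true(all(abs(fit$per_window$dominant_fa - 80) < 0.5))
  expect_true(all(fit$per_window$coupling >= 0 & fit$per_window$coupling <= 1))

  scaled <- signal_trace(tr$samples * 10, tr$fs, tr$channel)
  fit10 <- tpac(scaled, gamma_cfg(), "gamma")
  expect_equal(fit10$per_window$coupling, fit$per_window$coupling,
               tolerance = 1e-10)
  expect_equal(fit10$max_pac, fit$max_pac, tolerance = 1e-10)

  expect_error(tpac(tr, gamma_cfg(), c(2, 50)), "overlaps")
  expect_error(tpac(crop_trace(tr, 0, 10), gamma_cfg(), "gamma"), "shorter")
})

test_that("measured coupling rises monotonically with modulation depth", {
  for (s in 1:2) {
    vals <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(k)
      tpac(coupled_trace(k, seed = s), gamma_cfg(), "gamma")$mean_coupling,
      numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("window arithmetic matches the sliding-window definition", {
  # 300 s epoch, 18 s windows, 50% overlap -> 32 windows
  tr <- generate_background(300, 200, 1, 10, seed = 3)
  tr <- add_coupled_oscillations(tr, 2.5, 20,
    data.frame(fa_carrier = 60, fa_amp = 8, kappa = 0.5))
  fit <- tpac(tr, pac_config(fa_bands = data.frame(name = "g", f_low = 30,
                                                   f_high = 90)), "g")
  expect_identical(fit$n_windows, 32L)
})

test_that("a session yields one result per epoch x channel x band", {
  gen <- small_session(seed = 4, fs = 1250)
  pt <- epoch_pac(gen$session)
  expect_identical(nrow(pt), 16L)
  expect_setequal(unique(pt$fa_band), c("gamma", "hfo", "ripple",
                                        "fast_ripple"))
  expect_setequal(unique(pt$epoch), c("pre5", "post5"))
  # MaxPAC of realistic weak coupling sits in the 1e-2 decade
  g <- pt$max_pac[pt$fa_band == "gamma"]
  expect_true(all(g > 1e-2 & g < 1e-1))
})

test_that("comodulogram peaks at the imposed frequency pair", {
  tr <- coupled_trace(0.9, seed = 2, fs = 500, delta_freq = 2, fa_amp = 12,
                      noise_scale = 20, jitter = 0.2)
  cm <- comodulogram(tr, fp_grid = 1:4, fa_grid = seq(40, 120, 10))
  expect_identical(dim(cm$matrix), c(4L, 9L))
  # the winning cell's bands contain the imposed (2, 80) Hz pair
  expect_lte(abs(cm$peak$fp - 2), 1)
  expect_lte(abs(cm$peak$fa - 80), max(1:4) + 1)
  expect_error(comodulogram(tr, numeric(0), 40), "non-empty")
})

test_that("modulation index has the analytic limits", {
  set.seed(9)
  n <- 120 * 200
  ph <- runif(n, -pi, pi)
  # phase-independent envelope -> MI near 0
  expect_lte(modulation_index(ph, rexp(n) + 1), 0.01)
  # envelope concentrated in one bin -> MI = 1
  conc <- as.numeric(ph > -pi & ph < -pi + 2 * pi / 18)
  expect_equal(modulation_index(ph, conc), 1, tolerance = 1e-12)
  expect_error(modulation_index(ph, numeric(n)), "zero")
})

test_that("tPAC and the modulation-index oracle agree in rank over kappa", {
  kappas <- c(0, 0.2, 0.5, 0.8, 1)
  tp <- numeric(); mi <- numeric()
  for (k in kappas) {
    tr <- coupled_trace(k, seed = 1)
    tp <- c(tp, tpac(tr, gamma_cfg(), "gamma")$mean_coupling)
    mi <- c(mi, tort_mi(tr, c(1, 4), c(76, 84)))
  }
  expect_gte(cor(tp, mi, method = "spearman"), 0.9)
})

test_that("surrogate thresholds separate coupled from uncoupled signals", {
  tr1 <- coupled_trace(1, seed = 21, jitter = 0.3)
  thr1 <- surrogate_threshold(tr1, gamma_cfg(), "gamma", 200, 0.05, seed = 1)
  expect_gt(attr(thr1, "observed"), thr1)

  tr0 <- coupled_trace(0, seed = 22, jitter = 0.3)
  thr0 <- surrogate_threshold(tr0, gamma_cfg(), "gamma", 200, 0.05, seed = 1)
  expect_lt(attr(thr0, "observed"), thr0)

  # quantile definition and determinism
  thr_min <- surrogate_threshold(tr0, gamma_cfg(), "gamma", 50, 1, seed = 5)
  expect_equal(as.numeric(thr_min), min(attr(thr_min, "surrogates")))
  a <- surrogate_threshold(tr0, gamma_cfg(), "gamma", 50, 0.05, seed = 7)
  b <- surrogate_threshold(tr0, gamma_cfg(), "gamma", 50, 0.05, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(surrogate_threshold(tr0, gamma_cfg(), "gamma", 10), "20")

  # longer epochs tighten the threshold at fixed alpha
  thr_long <- surrogate_threshold(coupled_trace(0, seed = 23, jitter = 0.3,
                                                duration_s = 120),
                                  gamma_cfg(), "gamma", 100, 0.05, seed = 2)
  thr_short <- surrogate_threshold(coupled_trace(0, seed = 23, jitter = 0.3,
                                                 duration_s = 30),
                                   gamma_cfg(), "gamma", 100, 0.05, seed = 2)
  expect_lt(as.numeric(thr_long), as.numeric(thr_short))
})
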