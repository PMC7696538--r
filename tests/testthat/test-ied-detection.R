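test_that("background SD estimator is unbiased and event-robust", {
  ests <- vapply(1:8, function(s) {
    set.seed(s)
    estimate_background_sd(signal_trace(rnorm(60 * 500, 0, 10), 500))
  }, numeric(1))
  expect_true(all(ests > 9.5 & ests < 10.5))

  # constant trace: 0 with a degenerate-signal warning
  flat <- signal_trace(rep(3, 20 * 500), 500)
  expect_warning(s0 <- estimate_background_sd(flat), "degenerate")
  expect_identical(s0, 0)

  # 10 large events barely move the robust estimate (unlike the plain SD)
  set.seed(1)
  x <- rnorm(60 * 500, 0, 10)
  at <- round(seq(1000, 29000, length.out = 10))
  for (i in at) x[i:(i + 25)] <- x[i:(i + 25)] + 200
  tr <- signal_trace(x, 500)
  expect_lt(abs(estimate_background_sd(tr) - 10) / 10, 0.05)
  expect_gt(sd(x), 10.5)

  expect_error(estimate_background_sd(signal_trace(rnorm(100), 500)),
               "short")
})

test_that("detector recovers injected events with high recall and precision", {
  for (s in c(3, 13)) {
    tr <- generate_background(600, 1000, 1, 10, seed = s)
    inj <- inject_ied_events(tr, c(spike = 2.6, polyspike = 0.4,
                                   sharp_wave = 0.61), 8, seed = s + 1)
    ev <- detect_ieds(inj$trace, k = 2)
    m <- match_events(inj$ground_truth, ev)
    expect_gte(m$recall, 0.9)
    expect_gte(m$precision, 0.8)
  }
})

test_that("false-positive rate on pure noise stays below 1 event/min", {
  set.seed(2)
  gauss <- signal_trace(rnorm(600 * 1000, 0, 10), 1000)
  expect_lt(nrow(detect_ieds(gauss, k = 2)) / 10, 1)
  pink <- generate_background(600, 1000, 1, 10, seed = 3)
  expect_lt(nrow(detect_ieds(pink, k = 2)) / 10, 1)
})

test_that("empty and flat traces yield no events", {
  expect_identical(nrow(detect_ieds(signal_trace(rep(1, 5000), 500))), 0L)
})

test_that("detection is invariant under amplitude scaling", {
  tr <- generate_background(300, 1000, 1, 10, seed = 21)
  inj <- inject_ied_events(tr, c(spike = 3), 8, seed = 22)
  ev1 <- detect_ieds(inj$trace)
  ev10 <- detect_ieds(signal_trace(inj$trace$samples * 10, 1000))
  expect_equal(ev1$peak_time_s, ev10$peak_time_s)
  expect_equal(ev1$subtype, ev10$subtype)
  expect_equal(ev1$amplitude_sd_ratio, ev10$amplitude_sd_ratio,
               tolerance = 1e-10)
})

test_that("subtype classification follows the duration conventions", {
  fs <- 1000
  set.seed(5)
  noise <- rnorm(2 * fs, 0, 1)

  snip <- function(widths_s, gaps_s = NULL) {
    x <- noise
    t0 <- fs                               # event at 1 s
    pos <- t0
    for (i in seq_along(widths_s)) {
      m <- round(widths_s[i] * fs)
      x[pos:(pos + m - 1L)] <- x[pos:(pos + m - 1L)] +
        8 * sin(pi * (seq_len(m) - 0.5) / m)
      if (i < length(widths_s)) pos <- pos + m + round(gaps_s[i] * fs)
    }
    signal_trace(x, fs)
  }

  expect_identical(classify_ied(snip(0.040)), "spike")
  expect_identical(classify_ied(snip(0.120)), "sharp_wave")
  expect_identical(classify_ied(snip(c(0.03, 0.03, 0.03), c(0.05, 0.05))),
                   "polyspike")
  # a 3-peak burst within 300 ms is detected as ONE polyspike event
  tr <- generate_background(120, 1000, 1, 5, seed = 8)
  x <- tr$samples
  for (off in c(0, 0.08, 0.16)) {
    i0 <- round((60 + off) * 1000)
    x[i0:(i0 + 29)] <- x[i0:(i0 + 29)] + 40 * sin(pi * (1:30 - 0.5) / 30)
  }
  ev <- detect_ieds(signal_trace(x, 1000))
  near <- ev[abs(ev$peak_time_s - 60.1) < 0.4, ]
  expect_identical(nrow(near), 1L)
  expect_identical(near$subtype, "polyspike")
})

test_that("rate summaries implement bilateral averaging and lateralization", {
  ev <- function(n) data.frame(peak_time_s = as.numeric(seq_len(n)),
                               channel = rep("c", n),
                               subtype = rep("spike", n),
                               peak_amplitude_uv = rep(1, n),
                               duration_ms = rep(30, n),
                               amplitude_sd_ratio = rep(5, n),
                               n_deflections = rep(1L, n))
  r <- compute_rates(ev(36), ev(36), 10)
  expect_equal(r$bilateral_mean_rate, 3.6)

  r2 <- compute_rates(ev(40), ev(20), 10)
  expect_equal(r2$bilateral_mean_rate, 3)
  expect_equal(r2$lateralization_index, 1 / 3)

  r0 <- compute_rates(ev(0), ev(0), 10)
  expect_equal(r0$bilateral_mean_rate, 0)
  expect_equal(r0$lateralization_index, 0)
  expect_error(compute_rates(ev(1), ev(1), -5), "> 0")

  # rates are additive over disjoint time partitions
  tr <- generate_background(600, 1000, 1, 10, seed = 31)
  inj <- inject_ied_events(tr, c(spike = 3), 8, seed = 32)
  ev_all <- detect_ieds(inj$trace)
  halves <- c(sum(ev_all$peak_time_s < 300), sum(ev_all$peak_time_s >= 300))
  rate_full <- nrow(ev_all) / 10
  expect_equal(rate_full, mean(halves / 5))
})

test_that("events inside stimulation trains are excluded from counting", {
  gen <- small_session(seed = 9, fs = 1000,
                       ied_rates = c(spike = 12))   # dense for coverage
  sess <- gen$session
  ev <- detect_ieds(sess$traces$left_hipp, exclude = sess$schedule)
  tr_iv <- sess$schedule$trains
  for (j in seq_len(nrow(tr_iv)))
    expect_false(any(ev$peak_time_s >= tr_iv$onset_s[j] &
                     ev$peak_time_s < tr_iv$onset_s[j] + tr_iv$duration_s[j]))
})
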