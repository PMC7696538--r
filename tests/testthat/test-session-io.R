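test_that("schedule arithmetic follows the stimulation protocol", {
  sched <- build_schedule()
  expect_equal(schedule_total_s(sched), 1700)
  expect_equal(sched$trains$onset_s, c(300, 650, 1000, 1350))
  expect_equal(sched$trains$onset_s[4] + sched$trains$duration_s[4], 1400)

  one <- build_schedule(n_trains = 1, train_s = 50, pre_s = 120, post_s = 90)
  expect_equal(schedule_total_s(one), 120 + 50 + 90)
  expect_error(build_schedule(train_s = 0), "positive")
  expect_error(build_schedule(amplitude_uA = 50), "100")
})

test_that("epoch extraction reproduces the analysis windows", {
  sched <- build_schedule()
  traces <- list(
    left_hipp = signal_trace(numeric(1700 * 50) + 1, 50, "left_hipp"),
    right_hipp = signal_trace(numeric(1700 * 50) + 1, 50, "right_hipp"))
  sess <- recording_session(traces, schedule = sched)
  ep <- extract_epochs(sess)
  left <- ep[ep$channel == "left_hipp", ]
  get <- function(lab) unlist(left[left$label == lab, c("start_s", "end_s")],
                              use.names = FALSE)
  expect_equal(get("pre5"), c(0, 300))
  expect_equal(get("post5"), c(1400, 1700))
  expect_equal(get("pre30"), c(270, 300))
  expect_equal(get("post30"), c(1400, 1430))
  expect_equal(get("train_4"), c(1350, 1400))
  # one epoch set per hippocampal channel
  expect_equal(nrow(ep), 2 * nrow(left))

  # epochs never overlap a train interval
  trains <- left[grepl("^train_", left$label), ]
  others <- left[!grepl("^train_", left$label), ]
  for (i in seq_len(nrow(others))) for (j in seq_len(nrow(trains)))
    expect_true(others$end_s[i] <= trains$start_s[j] ||
                others$start_s[i] >= trains$end_s[j])

  # idempotent and content-independent
  expect_identical(extract_epochs(sess), ep)
})

test_that("SHAM sessions without a schedule get first/last windows", {
  traces <- list(left_hipp = signal_trace(rep(0.5, 1800 * 20), 20, "left_hipp"),
                 right_hipp = signal_trace(rep(0.5, 1800 * 20), 20, "right_hipp"))
  sess <- recording_session(traces, group = "SHAM-Control")
  ep <- extract_epochs(sess)
  left <- ep[ep$channel == "left_hipp", ]
  expect_equal(unlist(left[left$label == "pre5", c("start_s", "end_s")],
                      use.names = FALSE), c(0, 300))
  expect_equal(unlist(left[left$label == "post5", c("start_s", "end_s")],
                      use.names = FALSE), c(1500, 1800))
})

test_that("half-open cropping uses floor(t * fs) sample indexing", {
  tr <- signal_trace(1:100, 10, "x")        # 10 s at 10 Hz
  cr <- crop_trace(tr, 2, 4.5)
  expect_identical(cr$samples, as.numeric(21:45))
  expect_equal(cr$t0, 2)
  expect_error(crop_trace(tr, -1, 5), "outside")
  expect_error(crop_trace(tr, 5, 11), "outside")
})

test_that("EDF round trip preserves samples to 16-bit quantization", {
  gen <- small_session(seed = 5, fs = 500)
  path <- tempfile(fileext = ".edf")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_session(gen$session, path, "edf")
  back <- read_session(path)
  for (ch in names(gen$session$traces)) {
    x <- gen$session$traces[[ch]]$samples
    step <- 2 * max(abs(x)) * 1.0001 / 65535
    expect_lt(max(abs(back$traces[[ch]]$samples - x)), 1.5 * step)
    expect_equal(back$traces[[ch]]$fs, 500)
  }
  expect_equal(schedule_total_s(back$schedule), 170)
  expect_equal(back$group, gen$session$group)
})

test_that("raw format round trip is bit-exact", {
  gen <- small_session(seed = 6, fs = 500)
  path <- tempfile()
  on.exit(unlink(paste0(path, c(".bin", ".json"))), add = TRUE)
  write_session(gen$session, path, "raw")
  back <- read_session(path)
  expect_identical(back$traces$left_hipp$samples,
                   gen$session$traces$left_hipp$samples)
  expect_identical(back$traces$right_hipp$samples,
                   gen$session$traces$right_hipp$samples)
})

test_that("missing hippocampal channels are reported by name", {
  traces <- list(left_hipp = signal_trace(rnorm(5000), 500, "left_hipp"),
                 epidural_1 = signal_trace(rnorm(5000), 500, "epidural_1"))
  path <- tempfile(fileext = ".edf")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_edf(traces, path)
  jsonlite::write_json(list(animal_id = "r", group = "DBS-Pilo",
                            day_index = 1, format = "edf", fs = 500,
                            n_samples = 5000,
                            channels = names(traces)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_session(path), "right_hipp")
  expect_error(read_session("no/such/file"), "missing|cannot")
})

test_that("session invariants are enforced", {
  tr1 <- signal_trace(rnorm(1000), 100, "left_hipp")
  tr2 <- signal_trace(rnorm(500), 100, "right_hipp")
  expect_error(recording_session(list(left_hipp = tr1, right_hipp = tr2)),
               "share")
  expect_error(recording_session(list(left_hipp = tr1), day_index = 11),
               "day_index")
  sched <- build_schedule()                 # 1700 s > 10 s trace
  expect_error(recording_session(list(left_hipp = tr1), schedule = sched),
               "beyond")
})
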