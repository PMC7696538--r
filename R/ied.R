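# Robust SD: 1.4826 * median absolute deviation (Gaussian-consistent),
# insensitive to sparse large transients such as the discharges themselves.
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

#' Estimate the background SD of a trace
#'
#' Robust estimate `1.4826 * MAD` of the demeaned trace. Computed on the full
#' epoch, events included: the MAD is essentially unaffected by sparse large
#' discharges, which avoids any circular event-masking step. This is the SD
#' to which the detection threshold (`k` SD, default 2) refers.
#'
#' @param trace A [signal_trace] of at least 10 s.
#' @return Background SD in microvolts. A constant (degenerate) trace returns
#'   0 with a warning.
#' @export
estimate_background_sd <- function(trace) {
  assert_trace(trace)
  if (duration(trace) < 10)
    stop("trace too short for background estimation (< 10 s)", call. = FALSE)
  s <- robust_sd(trace$samples - stats::median(trace$samples))
  if (s == 0) warning("degenerate signal: background SD is 0")
  s
}

moving_avg <- function(x, m) {
  if (m <= 1L) return(x)
  s <- stats::filter(x, rep(1 / m, m), sides = 2)
  s <- as.numeric(s)
  na <- is.na(s)
  s[na] <- x[na]
  s
}

#' Detect interictal epileptiform discharges
#'
#' Candidate events are local extrema of the smoothed trace whose absolute
#' amplitude exceeds `k` background SDs (robust MAD estimate). The amplitude
#' floor alone fires constantly on noise, so two further gates make automated
#' counting feasible: the principal deflection must last 20-200 ms (width
#' between the baseline crossings flanking the peak), and its sharpness --
#' the largest amplitude change over a lag of a quarter of the measured
#' duration -- must exceed 3 times the background SD of same-lag changes.
#' Peaks closer than 500 ms are merged into one event (a polyspike is one
#' discharge, not several). Events whose peak falls inside an exclusion
#' interval (stimulation trains) are dropped.
#'
#' @param trace A [signal_trace].
#' @param k Detection threshold in background-SD units (default 2).
#' @param exclude Optional data frame of intervals (`start_s`, `end_s`) to
#'   exclude, or a `stim_schedule` whose train intervals are excluded.
#' @return A data frame with one row per event: `peak_time_s`, `channel`,
#'   `subtype` (`spike`, `polyspike`, `sharp_wave` or `unclassified`),
#'   `peak_amplitude_uv`, `duration_ms`, `amplitude_sd_ratio`, `n_deflections`.
#' @export
detect_ieds <- function(trace, k = 2, exclude = NULL) {
  assert_trace(trace)
  fs <- trace$fs
  x <- trace$samples - stats::median(trace$samples)
  sd_bg <- robust_sd(x)
  empty <- data.frame(peak_time_s = numeric(), channel = character(),
                      subtype = character(), peak_amplitude_uv = numeric(),
                      duration_ms = numeric(), amplitude_sd_ratio = numeric(),
                      n_deflections = integer())
  if (sd_bg == 0) return(empty)

  # detection signal: events (20-200 ms) live in roughly 2.5-80 Hz; removing
  # slower content stabilizes the baseline under delta rhythm and 1/f drift,
  # removing faster content acts as the smoothing stage
  s <- if (fs > 180) bandpass(x, fs, 2.5, 80, transition = 1.5)
       else moving_avg(x, max(1L, round(0.005 * fs)))
  thr <- k * sd_bg
  a <- abs(s)
  n <- length(s)

  over <- a > thr
  if (!any(over)) return(empty)
  # local maxima of |s| above threshold
  pk <- which(over &
                a >= c(-Inf, a[-n]) &
                a > c(a[-1], -Inf))
  if (!length(pk)) return(empty)

  gap <- diff(pk) > 0.5 * fs
  grp <- cumsum(c(TRUE, gap))

  if (inherits(exclude, "stim_schedule"))
    exclude <- data.frame(start_s = exclude$trains$onset_s,
                          end_s = exclude$trains$onset_s +
                            exclude$trains$duration_s)

  rows <- list()
  for (g in unique(grp)) {
    idx <- pk[grp == g]
    main <- idx[which.max(a[idx])]
    meas <- measure_deflection(s, main, fs)
    if (is.null(meas)) next
    dur_ms <- meas$duration_ms
    if (dur_ms < 20 || dur_ms > 200) next

    # the supra-threshold part of the deflection must itself be discernible
    # (>= 10 ms), not a grazing threshold crossing
    run <- threshold_run(a, main, thr)
    if ((run[2] - run[1] + 1L) < round(0.010 * fs)) next

    lag <- max(round(0.002 * fs),
               min(round(dur_ms / 4 / 1000 * fs), round(0.05 * fs)))
    d <- s[(lag + 1L):n] - s[1:(n - lag)]
    sharp_bg <- robust_sd(d)
    span0 <- max(1L, meas$start - lag)
    span1 <- min(n - lag, meas$end)
    sharp_ev <- max(abs(d[span0:span1]))
    if (sharp_bg > 0 && sharp_ev <= 3 * sharp_bg) next

    t_peak <- trace$t0 + (main - 1L) / fs
    if (!is.null(exclude) && nrow(exclude) &&
        any(t_peak >= exclude$start_s & t_peak < exclude$end_s)) next

    n_defl <- count_deflections(s * sign(s[main]), idx, thr, fs)
    subtype <- if (n_defl >= 2L) "polyspike"
      else if (dur_ms <= 70) "spike"
      else "sharp_wave"
    rows[[length(rows) + 1L]] <- data.frame(
      peak_time_s = t_peak, channel = trace$channel, subtype = subtype,
      peak_amplitude_uv = x[main], duration_ms = dur_ms,
      amplitude_sd_ratio = a[main] / sd_bg, n_deflections = n_defl)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$peak_time_s), , drop = FALSE]
}

# Width of the deflection containing sample `peak`: distance between the
# baseline (zero) crossings flanking the peak on the smoothed trace.
measure_deflection <- function(s, peak, fs) {
  sgn <- sign(s[peak])
  if (sgn == 0) return(NULL)
  v <- s * sgn
  n <- length(v)
  left <- peak
  while (left > 1L && v[left - 1L] > 0) left <- left - 1L
  right <- peak
  while (right < n && v[right + 1L] > 0) right <- right + 1L
  list(duration_ms = (right - left + 1L) / fs * 1000,
       start = left, end = right)
}

# Extent of the contiguous supra-threshold run containing `peak`.
threshold_run <- function(a, peak, thr) {
  n <- length(a)
  left <- peak
  while (left > 1L && a[left - 1L] > thr) left <- left - 1L
  right <- peak
  while (right < n && a[right + 1L] > thr) right <- right + 1L
  c(left, right)
}

# Number of distinct supra-threshold deflections in a merged event group:
# contiguous runs of the signed signal above thr lasting at least 10 ms
# within the group span (sign-matched, so a filter rebound of opposite
# polarity is not mistaken for a second deflection).
count_deflections <- function(a, peak_idx, thr, fs) {
  pad <- round(0.05 * fs)
  i0 <- max(1L, min(peak_idx) - pad)
  i1 <- min(length(a), max(peak_idx) + pad)
  seg <- a[i0:i1] > thr
  r <- rle(seg)
  sum(r$values & r$lengths >= round(0.010 * fs))
}

#' Classify one discharge waveform
#'
#' Applies the duration and deflection-count conventions to a waveform
#' snippet containing a single event with at least 100 ms margins: a
#' principal deflection of 20-70 ms is a spike, 70-200 ms a sharp wave, and
#' two or more supra-threshold deflections within 500 ms a polyspike.
#' Out-of-range durations return `"unclassified"` (excluded from subtype
#' proportions but still counted in total rates).
#'
#' @param waveform A [signal_trace] snippet, or a numeric vector with `fs`.
#' @param fs Sampling rate, required when `waveform` is a bare vector.
#' @param sd_bg Background SD in microvolts; estimated robustly from the
#'   snippet when omitted.
#' @param k Threshold in SD units (default 2).
#' @return Character subtype.
#' @export
classify_ied <- function(waveform, fs = NULL, sd_bg = NULL, k = 2) {
  if (is_trace(waveform)) { fs <- waveform$fs; x <- waveform$samples }
  else { stopifnot(!is.null(fs)); x <- as.numeric(waveform) }
  x <- x - stats::median(x)
  if (is.null(sd_bg)) sd_bg <- robust_sd(x)
  if (sd_bg == 0) return("unclassified")
  m <- max(1L, round(0.005 * fs))
  s <- moving_avg(x, m)
  a <- abs(s)
  peak <- which.max(a)
  if (a[peak] <= k * sd_bg) return("unclassified")
  meas <- measure_deflection(s, peak, fs)
  if (is.null(meas)) return("unclassified")
  pk <- which(a > k * sd_bg &
                a >= c(-Inf, a[-length(a)]) & a > c(a[-1], -Inf))
  pk <- pk[abs(pk - peak) <= 0.5 * fs]
  n_defl <- count_deflections(s * sign(s[peak]), pk, k * sd_bg, fs)
  if (n_defl >= 2L) return("polyspike")
  d <- meas$duration_ms
  if (d >= 20 && d <= 70) "spike"
  else if (d > 70 && d <= 200) "sharp_wave"
  else "unclassified"
}

#' Match detected events against a ground-truth list
#'
#' A ground-truth event is recovered when a detection peak falls within the
#' event's temporal extent plus a tolerance (default 50 ms); the extent
#' matters because a multi-deflection discharge is anchored at its first
#' deflection while a detector may report the largest one. Each detection is
#' consumed by at most one ground-truth event.
#'
#' @param ground_truth Data frame with `time_s` and `duration_ms` (as from
#'   [inject_ied_events()]).
#' @param events Detection table from [detect_ieds()].
#' @param tol_s Matching tolerance in seconds.
#' @return List with `recall`, `precision`, `n_matched` and the logical
#'   vectors `truth_matched`, `event_matched`.
#' @export
match_events <- function(ground_truth, events, tol_s = 0.05) {
  gt <- as.data.frame(ground_truth)
  ev <- as.data.frame(events)
  used <- logical(nrow(ev))
  hit <- logical(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    lo <- gt$time_s[i] - tol_s
    hi <- gt$time_s[i] + gt$duration_ms[i] / 1000 + tol_s
    cand <- which(!used & ev$peak_time_s >= lo & ev$peak_time_s <= hi)
    if (length(cand)) {
      j <- cand[which.min(abs(ev$peak_time_s[cand] - gt$time_s[i]))]
      used[j] <- TRUE
      hit[i] <- TRUE
    }
  }
  list(recall = if (nrow(gt)) mean(hit) else NA_real_,
       precision = if (nrow(ev)) mean(used) else NA_real_,
       n_matched = sum(hit), truth_matched = hit, event_matched = used)
}

#' Per-channel and bilateral discharge rates
#'
#' Left and right hippocampal counts are converted to events/min and
#' averaged; the lateralization index `(L - R) / (L + R)` quantifies the
#' side asymmetry (0 by convention when no events occur). Subtype
#' proportions pool both sides and exclude unclassified events.
#'
#' @param events_left,events_right Event tables from [detect_ieds()].
#' @param duration_min Analyzed duration in minutes (> 0).
#' @return An object of class `ied_rate_summary`: list with
#'   `per_channel_rate` (named, events/min), `bilateral_mean_rate`,
#'   `subtype_proportions`, `lateralization_index`, `n_events`.
#' @export
compute_rates <- function(events_left, events_right, duration_min) {
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("`duration_min` must be > 0", call. = FALSE)
  nl <- nrow(events_left); nr <- nrow(events_right)
  rl <- nl / duration_min; rr <- nr / duration_min
  lat <- if (nl + nr == 0) 0 else (rl - rr) / (rl + rr)
  st <- c(events_left$subtype, events_right$subtype)
  st <- st[st != "unclassified"]
  props <- if (length(st))
    prop.table(table(factor(st, levels = c("spike", "polyspike",
                                           "sharp_wave"))))
  else table(factor(character(), levels = c("spike", "polyspike",
                                            "sharp_wave")))
  structure(list(
    per_channel_rate = c(left = rl, right = rr),
    bilateral_mean_rate = (rl + rr) / 2,
    subtype_proportions = props,
    lateralization_index = lat,
    n_events = c(left = nl, right = nr)
  ), class = "ied_rate_summary")
}

#' @export
print.ied_rate_summary <- function(x, ...) {
  cat(sprintf("<ied_rate_summary> bilateral %.2f events/min (L %.2f, R %.2f), lateralization %+.2f\n",
              x$bilateral_mean_rate, x$per_channel_rate["left"],
              x$per_channel_rate["right"], x$lateralization_index))
  if (sum(x$n_events)) {
    p <- round(100 * as.numeric(x$subtype_proportions))
    cat(sprintf("  subtypes: spike %d%%, polyspike %d%%, sharp wave %d%%\n",
                p[1], p[2], p[3]))
  }
  invisible(x)
}

#' Detect and rate discharges for a whole session
#'
#' Runs [detect_ieds()] on both hippocampal channels with the session's
#' stimulation trains excluded, and summarizes with [compute_rates()] over
#' the out-of-train recording time.
#'
#' @param session A [recording_session].
#' @param k Threshold in SD units.
#' @return An `ied_rate_summary` with the per-channel event tables attached
#'   as attribute `"events"`.
#' @export
session_ied_rates <- function(session, k = 2) {
  stopifnot(inherits(session, "recording_session"))
  sched <- session$schedule
  ev_l <- detect_ieds(session$traces$left_hipp, k, exclude = sched)
  ev_r <- detect_ieds(session$traces$right_hipp, k, exclude = sched)
  train_s <- if (is.null(sched)) 0 else sum(sched$trains$duration_s)
  dur_min <- (session_duration_s(session) - train_s) / 60
  out <- compute_rates(ev_l, ev_r, dur_min)
  attr(out, "events") <- list(left = ev_l, right = ev_r)
  out
}
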