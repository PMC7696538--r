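#' Build a stimulation schedule
#'
#' The daily stimulation package: `n_trains` trains of `train_s` seconds at
#' `pulse_rate` Hz, separated by `pause_s` pauses, with recording starting
#' `pre_s` seconds before the first train and ending `post_s` seconds after
#' the last. Train k (1-based) starts at `pre_s + (k - 1) * (train_s +
#' pause_s)`. With the defaults (4 x 50 s trains, 5 min pauses, 5 min pre and
#' post windows) the schedule spans 300 + 4*50 + 3*300 + 300 = 1700 s.
#'
#' @param n_trains Number of trains.
#' @param train_s Train duration in seconds.
#' @param pause_s Pause between trains in seconds.
#' @param pre_s,post_s Recording window before the first / after the last
#'   train, in seconds.
#' @param pulse_rate Pulse rate within a train, Hz.
#' @param pulse_width_us Pulse width in microseconds (metadata).
#' @param amplitude_uA Stimulation current in microamperes, 100-500
#'   (metadata; titrated per animal in vivo).
#' @return An object of class `stim_schedule` with a `trains` data frame
#'   (`onset_s`, `duration_s`, `pulse_rate`, `pulse_width_us`,
#'   `amplitude_uA`) and the window parameters.
#' @examples
#' sched <- build_schedule()
#' schedule_total_s(sched)   # 1700
#' @export
build_schedule <- function(n_trains = 4, train_s = 50, pause_s = 300,
                           pre_s = 300, post_s = 300, pulse_rate = 4,
                           pulse_width_us = 100, amplitude_uA = 500) {
  vals <- c(n_trains, train_s, pause_s, pre_s, post_s, pulse_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all schedule parameters must be positive", call. = FALSE)
  if (amplitude_uA < 100 || amplitude_uA > 500)
    stop("`amplitude_uA` must lie in [100, 500]", call. = FALSE)
  onsets <- pre_s + (seq_len(n_trains) - 1) * (train_s + pause_s)
  structure(list(
    trains = data.frame(onset_s = onsets, duration_s = train_s,
                        pulse_rate = pulse_rate,
                        pulse_width_us = pulse_width_us,
                        amplitude_uA = amplitude_uA),
    pre_s = pre_s, post_s = post_s, pause_s = pause_s
  ), class = "stim_schedule")
}

#' Total span of a stimulation schedule in seconds
#' @param schedule A `stim_schedule`.
#' @return `pre_s + n*train + (n-1)*pause + post_s`, in seconds.
#' @export
schedule_total_s <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  last_train_offset_s(schedule) + schedule$post_s
}

# Offset (end time) of the last train, seconds from recording start.
last_train_offset_s <- function(schedule) {
  n <- nrow(schedule$trains)
  schedule$trains$onset_s[n] + schedule$trains$duration_s[n]
}

#' @export
print.stim_schedule <- function(x, ...) {
  n <- nrow(x$trains)
  cat(sprintf("<stim_schedule> %d train(s) of %g s at %g Hz, pauses %g s\n",
              n, x$trains$duration_s[1], x$trains$pulse_rate[1], x$pause_s))
  cat(sprintf("  pre %g s, post %g s, total %g s\n",
              x$pre_s, x$post_s, schedule_total_s(x)))
  invisible(x)
}

#' Assemble a multichannel recording session
#'
#' @param traces Named list of [signal_trace] objects; hippocampal analyses
#'   expect channels `left_hipp` and `right_hipp` (epidural channels
#'   optional). All traces must share sampling rate and duration.
#' @param animal_id Animal identifier.
#' @param group One of `"DBS-Pilo"`, `"DBS-Control"`, `"SHAM-Control"`.
#' @param day_index Stimulation day, 1-10.
#' @param schedule A `stim_schedule` or `NULL` (SHAM sessions).
#' @param meta Optional named list of acquisition metadata (e.g. the hardware
#'   filter chain; recorded, never applied).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(traces, animal_id = "rat01",
                              group = c("DBS-Pilo", "DBS-Control",
                                        "SHAM-Control"),
                              day_index = 1L, schedule = NULL, meta = list()) {
  group <- match.arg(group)
  if (!length(traces) || is.null(names(traces)) || any(names(traces) == ""))
    stop("`traces` must be a named list of signal_trace objects", call. = FALSE)
  lapply(traces, assert_trace)
  fs <- vapply(traces, function(tr) tr$fs, numeric(1))
  ns <- vapply(traces, function(tr) length(tr$samples), integer(1))
  if (length(unique(fs)) != 1L || length(unique(ns)) != 1L)
    stop("all traces must share sampling rate and duration", call. = FALSE)
  if (!(day_index >= 1 && day_index <= 10))
    stop("`day_index` must lie in [1, 10]", call. = FALSE)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "stim_schedule"))
    if (schedule_total_s(schedule) > ns[1] / fs[1] + 1e-9)
      stop("schedule extends beyond the recording", call. = FALSE)
  }
  structure(list(traces = traces, animal_id = animal_id, group = group,
                 day_index = as.integer(day_index), schedule = schedule,
                 meta = meta),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  tr <- x$traces[[1]]
  cat(sprintf("<recording_session> %s (%s), day %d\n",
              x$animal_id, x$group, x$day_index))
  cat(sprintf("  channels: %s\n", paste(names(x$traces), collapse = ", ")))
  cat(sprintf("  fs=%g Hz, duration=%.1f s, schedule: %s\n", tr$fs,
              duration(tr), if (is.null(x$schedule)) "none" else
                sprintf("%d trains", nrow(x$schedule$trains))))
  invisible(x)
}

session_duration_s <- function(session) duration(session$traces[[1]])

#' Extract the analysis epochs of a session
#'
#' For a stimulated session the epochs are defined by the schedule:
#' `pre5` is the pre-stimulation window ending at the first train onset,
#' `post5` the window starting at the last train offset, `pre30`/`post30`
#' the 30-s windows immediately before the first / after the last train, and
#' `train_k` the k-th train interval itself (excluded from all analyses).
#' SHAM sessions without a schedule get first/last windows of the same
#' nominal length. One epoch set is emitted per hippocampal channel present.
#' Intervals are half-open `[start_s, end_s)`.
#'
#' @param session A [recording_session].
#' @param short_s Length of the short pre/post comparison windows in seconds
#'   (default 30).
#' @return A data frame with columns `label`, `start_s`, `end_s`, `channel`.
#' @export
extract_epochs <- function(session, short_s = 30) {
  stopifnot(inherits(session, "recording_session"))
  dur <- session_duration_s(session)
  chans <- intersect(c("left_hipp", "right_hipp"), names(session$traces))
  if (!length(chans))
    stop("session has no hippocampal channels (left_hipp/right_hipp)",
         call. = FALSE)
  sched <- session$schedule
  if (is.null(sched)) {
    w <- min(300, dur / 2)
    base <- data.frame(
      label = c("pre5", "post5", "pre30", "post30"),
      start_s = c(0, dur - w, max(0, w - short_s), dur - w),
      end_s = c(w, dur, w, dur - w + short_s))
  } else {
    t_on <- sched$trains$onset_s[1]
    t_off <- last_train_offset_s(sched)
    if (schedule_total_s(sched) > dur + 1e-9)
      stop("epochs out of range: schedule extends beyond the recording",
           call. = FALSE)
    base <- data.frame(
      label = c("pre5", "post5", "pre30", "post30",
                sprintf("train_%d", seq_len(nrow(sched$trains)))),
      start_s = c(t_on - sched$pre_s, t_off, t_on - short_s, t_off,
                  sched$trains$onset_s),
      end_s = c(t_on, t_off + sched$post_s, t_on, t_off + short_s,
                sched$trains$onset_s + sched$trains$duration_s))
  }
  if (any(base$start_s < -1e-9) || any(base$end_s > dur + 1e-9))
    stop("epochs out of range for this recording", call. = FALSE)
  out <- do.call(rbind, lapply(chans, function(ch)
    cbind(base, channel = ch, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Fetch the trace of one epoch
#'
#' @param session A [recording_session].
#' @param epochs Epoch table from [extract_epochs()].
#' @param label Epoch label, e.g. `"pre5"`.
#' @param channel Channel name.
#' @return The cropped [signal_trace].
#' @export
epoch_trace <- function(session, epochs, label, channel) {
  row <- epochs[epochs$label == label & epochs$channel == channel, ]
  if (nrow(row) != 1L)
    stop(sprintf("no unique epoch `%s` for channel `%s`", label, channel),
         call. = FALSE)
  crop_trace(session$traces[[channel]], row$start_s, row$end_s)
}

# ---- on-disk formats -------------------------------------------------------

#' Write a session to disk
#'
#' `format = "edf"` writes a standard European Data Format file (16-bit,
#' physical dimension uV) plus a JSON sidecar (`<path>.json`) holding the
#' session metadata and schedule. `format = "raw"` writes a JSON header and a
#' float64 binary sample file, which round-trips bit-exactly (useful for
#' fixtures where 16-bit quantization would matter).
#'
#' @param session A [recording_session].
#' @param path Output file path (the sidecar adds `.json`).
#' @param format `"edf"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("edf", "raw")) {
  format <- match.arg(format)
  stopifnot(inherits(session, "recording_session"))
  if (format == "edf") {
    write_edf(session$traces, path)
  } else {
    con <- file(paste0(path, ".bin"), "wb")
    on.exit(close(con), add = TRUE)
    for (tr in session$traces) writeBin(tr$samples, con, size = 8,
                                        endian = "little")
  }
  meta <- list(
    animal_id = session$animal_id, group = session$group,
    day_index = session$day_index, format = format,
    fs = session$traces[[1]]$fs,
    n_samples = length(session$traces[[1]]$samples),
    channels = names(session$traces),
    schedule = schedule_to_list(session$schedule),
    meta = session$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a session from disk
#'
#' Reads a session written by [write_session()] (EDF or raw format; the JSON
#' sidecar restores metadata and the stimulation schedule). A session lacking
#' a hippocampal channel raises an error naming the absent channel.
#'
#' @param path Path given to [write_session()].
#' @param require_hippocampal Check that both hippocampal channels are
#'   present (default `TRUE`).
#' @return A [recording_session].
#' @export
read_session <- function(path, require_hippocampal = TRUE) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop(sprintf("cannot read session: missing sidecar `%s`", side),
         call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (identical(meta$format, "raw")) {
    bin <- paste0(path, ".bin")
    if (!file.exists(bin)) stop("missing raw sample file", call. = FALSE)
    con <- file(bin, "rb")
    on.exit(close(con), add = TRUE)
    traces <- list()
    for (ch in meta$channels)
      traces[[ch]] <- signal_trace(
        readBin(con, "double", meta$n_samples, size = 8, endian = "little"),
        meta$fs, ch)
  } else {
    traces <- read_edf(path)
  }
  if (require_hippocampal) {
    for (ch in c("left_hipp", "right_hipp"))
      if (!ch %in% names(traces))
        stop(sprintf("session is missing hippocampal channel `%s`", ch),
             call. = FALSE)
  }
  recording_session(traces, animal_id = meta$animal_id, group = meta$group,
                    day_index = meta$day_index,
                    schedule = schedule_from_list(meta$schedule),
                    meta = as.list(meta$meta))
}

schedule_to_list <- function(schedule) {
  if (is.null(schedule)) return(NULL)
  list(trains = schedule$trains, pre_s = schedule$pre_s,
       post_s = schedule$post_s, pause_s = schedule$pause_s)
}

schedule_from_list <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  structure(list(trains = as.data.frame(x$trains), pre_s = x$pre_s,
                 post_s = x$post_s, pause_s = x$pause_s),
            class = "stim_schedule")
}
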