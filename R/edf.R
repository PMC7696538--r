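#' Minimal European Data Format (EDF) writer
#'
#' Writes a plain EDF file: 16-bit samples, physical dimension uV, one
#' record per second when the sample count divides evenly, otherwise a single
#' record spanning the whole signal. All channels must share sampling rate
#' and length. The physical range is the symmetric envelope of each channel,
#' so round-tripping preserves samples to within the 16-bit quantization step
#' (physical range / 65535).
#'
#' @param traces Named list of [signal_trace] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(traces, path) {
  if (!length(traces) || is.null(names(traces)))
    stop("`traces` must be a named list", call. = FALSE)
  lapply(traces, assert_trace)
  fs <- traces[[1]]$fs
  n <- length(traces[[1]]$samples)
  if (any(vapply(traces, function(tr) tr$fs != fs ||
                   length(tr$samples) != n, logical(1))))
    stop("all channels must share fs and length", call. = FALSE)
  nsig <- length(traces)

  if (n %% fs == 0 && fs == round(fs)) {
    rec_dur <- 1; ns_rec <- as.integer(fs); n_rec <- n %/% as.integer(fs)
  } else {
    rec_dur <- n / fs; ns_rec <- n; n_rec <- 1L
  }

  pad <- function(s, w) {
    s <- substr(as.character(s), 1L, w)
    sprintf(paste0("%-", w, "s"), s)
  }
  num_field <- function(v, w = 8L) {
    s <- formatC(v, format = "g", digits = 6)
    if (nchar(s) > w) s <- formatC(v, format = "g", digits = 4)
    if (nchar(s) > w) s <- formatC(v, format = "g", digits = 2)
    s
  }

  # physical ranges (symmetric); re-parse the ASCII field so the scale used
  # for encoding matches exactly what a reader will recover
  pm <- vapply(traces, function(tr) {
    m <- max(abs(tr$samples)); if (m == 0) 1 else m * 1.0001
  }, numeric(1))
  pm_str <- vapply(pm, num_field, character(1))
  pm_used <- as.numeric(pm_str)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  wr(pad("0", 8)); wr(pad("X", 80)); wr(pad("lfpac session", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + nsig), 8)); wr(pad("", 44))
  wr(pad(n_rec, 8)); wr(pad(num_field(rec_dur), 8)); wr(pad(nsig, 4))

  for (nm in names(traces)) wr(pad(nm, 16))
  for (i in seq_len(nsig)) wr(pad("synthetic", 80))
  for (i in seq_len(nsig)) wr(pad("uV", 8))
  for (i in seq_len(nsig)) wr(pad(num_field(-pm_used[i]), 8))
  for (i in seq_len(nsig)) wr(pad(pm_str[i], 8))
  for (i in seq_len(nsig)) wr(pad("-32768", 8))
  for (i in seq_len(nsig)) wr(pad("32767", 8))
  for (i in seq_len(nsig)) wr(pad("", 80))
  for (i in seq_len(nsig)) wr(pad(ns_rec, 8))
  for (i in seq_len(nsig)) wr(pad("", 32))

  digitize <- function(x, lim) {
    d <- round((x + lim) / (2 * lim) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  }
  dig <- lapply(seq_len(nsig), function(i)
    digitize(traces[[i]]$samples, pm_used[i]))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * ns_rec + 1L):(r * ns_rec)
    for (i in seq_len(nsig))
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Minimal EDF reader
#'
#' Reads an EDF file written by [write_edf()] (or any plain EDF whose
#' channels share a common sampling rate). Samples are returned in physical
#' units (uV).
#'
#' @param path EDF file path.
#' @return Named list of [signal_trace] objects.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot open `%s`", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    trimws(rawToChar(raw))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header byte count (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  if (is.na(nsig) || nsig < 1L) stop("malformed EDF header", call. = FALSE)

  labels <- vapply(seq_len(nsig), function(i) rd(16), character(1))
  for (i in seq_len(nsig)) rd(80)          # transducer
  for (i in seq_len(nsig)) rd(8)           # physical dimension
  pmin_ <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nsig)) rd(80)          # prefiltering
  ns_rec <- vapply(seq_len(nsig), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nsig)) rd(32)

  out <- lapply(seq_len(nsig), function(i) numeric(n_rec * ns_rec[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nsig)) {
      d <- readBin(con, "integer", ns_rec[i], size = 2L, signed = TRUE,
                   endian = "little")
      phys <- pmin_[i] + (d - dmin_[i]) *
        (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      out[[i]][((r - 1L) * ns_rec[i] + 1L):(r * ns_rec[i])] <- phys
    }
  }
  traces <- lapply(seq_len(nsig), function(i)
    signal_trace(out[[i]], ns_rec[i] / rec_dur, labels[i]))
  names(traces) <- labels
  traces
}
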