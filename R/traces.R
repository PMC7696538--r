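#' Construct a single-channel LFP trace
#'
#' A `signal_trace` is the basic substrate for all signal operations: one
#' channel of local field potential samples in microvolts, together with its
#' sampling rate, channel label and start time.
#'
#' @param samples Numeric vector of samples in microvolts. Must be finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel Channel label, e.g. `"left_hipp"`.
#' @param t0 Time of the first sample in seconds from recording start.
#'
#' @return An object of class `signal_trace` (a list with elements
#'   `samples`, `fs`, `channel`, `t0`).
#' @examples
#' tr <- signal_trace(sin(2 * pi * 6 * seq(0, 1, by = 1 / 500)), fs = 500)
#' duration(tr)
#' @export
signal_trace <- function(samples, fs, channel = "unknown", t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)", call. = FALSE)
  if (length(samples) == 0L)
    stop("`samples` must contain at least one sample", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite (no NA/Inf)", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, channel = as.character(channel)[1L],
         t0 = as.numeric(t0)[1L]),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> channel=%s  fs=%g Hz  n=%d  duration=%.3f s  t0=%g s\n",
              x$channel, x$fs, length(x$samples), duration(x), x$t0))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace A [signal_trace].
#' @return Duration in seconds (`n / fs`).
#' @export
duration <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  length(trace$samples) / trace$fs
}

is_trace <- function(x) inherits(x, "signal_trace")

assert_trace <- function(x, arg = "trace") {
  if (!is_trace(x)) stop(sprintf("`%s` must be a signal_trace", arg), call. = FALSE)
  invisible(x)
}

#' Crop a trace to a half-open time interval
#'
#' Time intervals are half-open `[start, end)` in seconds from recording
#' start; the sample index of time `t` is `floor((t - t0) * fs)`.
#'
#' @param trace A [signal_trace].
#' @param start_s,end_s Interval bounds in seconds (recording time).
#' @return A [signal_trace] covering `[start_s, end_s)` with `t0 = start_s`.
#' @export
crop_trace <- function(trace, start_s, end_s) {
  assert_trace(trace)
  if (!(start_s < end_s)) stop("need start_s < end_s", call. = FALSE)
  i0 <- floor((start_s - trace$t0) * trace$fs)
  i1 <- floor((end_s - trace$t0) * trace$fs)
  n <- length(trace$samples)
  if (i0 < 0 || i1 > n)
    stop(sprintf("interval [%g, %g) outside trace support [%g, %g)",
                 start_s, end_s, trace$t0, trace$t0 + n / trace$fs),
         call. = FALSE)
  signal_trace(trace$samples[(i0 + 1L):i1], trace$fs, trace$channel, start_s)
}

#' Time axis of a trace
#' @param trace A [signal_trace].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  assert_trace(trace)
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$fs
}

# ---- numerical core: analytic signal and zero-phase band-pass --------------

#' Analytic signal via the frequency domain
#'
#' Standard construction: zero the negative frequencies of the DFT and double
#' the positive ones. `Mod()` of the result is the instantaneous amplitude
#' envelope, `Arg()` the instantaneous phase.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for analytic signal", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain filter with raised-cosine transition edges: unit gain on
#' `[f_lo, f_hi]`, cosine roll-off over `transition` Hz outside each edge,
#' zero elsewhere. Being applied in the frequency domain the filter is exactly
#' zero-phase, which matters for phase-amplitude coupling where a phase bias
#' between the slow and fast filtered components would bias the preferred
#' coupling phase.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate (Hz).
#' @param f_lo,f_hi Pass-band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @param transition Transition bandwidth in Hz. Default scales with the
#'   lower edge (narrow for delta, wider for fast bands), capped at 2 Hz.
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs, f_lo, f_hi, transition = NULL) {
  n <- length(x)
  if (!(f_lo >= 0 && f_lo < f_hi)) stop("need 0 <= f_lo < f_hi", call. = FALSE)
  if (f_hi > fs / 2) stop("f_hi exceeds the Nyquist frequency", call. = FALSE)
  if (is.null(transition))
    transition <- max(0.25, min(2, if (f_lo > 0) f_lo / 2 else 1))
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)              # fold to [0, fs/2]
  gain <- raised_cosine_gain(freq, f_lo, f_hi, transition)
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE) / n)
}

raised_cosine_gain <- function(freq, f_lo, f_hi, tr) {
  g <- numeric(length(freq))
  inside <- freq >= f_lo & freq <= f_hi
  g[inside] <- 1
  lo_ramp <- freq < f_lo & freq > (f_lo - tr)
  g[lo_ramp] <- 0.5 * (1 + cos(pi * (f_lo - freq[lo_ramp]) / tr))
  hi_ramp <- freq > f_hi & freq < (f_hi + tr)
  g[hi_ramp] <- 0.5 * (1 + cos(pi * (freq[hi_ramp] - f_hi) / tr))
  g
}

#' Band-pass a trace and return envelope and phase
#'
#' @param trace A [signal_trace].
#' @param f_lo,f_hi Band edges in Hz.
#' @param transition Transition bandwidth in Hz; see [bandpass()].
#' @return List with `filtered`, `envelope` and `phase` numeric vectors.
#' @export
band_envelope_phase <- function(trace, f_lo, f_hi, transition = NULL) {
  assert_trace(trace)
  xf <- bandpass(trace$samples - mean(trace$samples), trace$fs, f_lo, f_hi,
                 transition)
  z <- analytic_signal(xf)
  list(filtered = xf, envelope = Mod(z), phase = Arg(z))
}

# Run RNG-dependent code under a given seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("`seed` must be a single finite number", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
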