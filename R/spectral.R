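#' Canonical frequency band table
#'
#' The four analysis bands: delta (1-4 Hz), theta (4-12 Hz), beta (15-30 Hz)
#' and gamma-fast ripple (30-600 Hz). Intervals are half-open
#' `[f_low, f_high)`, so the shared 4 Hz edge belongs to theta.
#'
#' @return Data frame with columns `name`, `f_low`, `f_high`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "beta", "gamma_fast_ripple"),
             f_low = c(1, 4, 15, 30),
             f_high = c(4, 12, 30, 600))
}

#' Welch power spectral density
#'
#' Averaged periodogram over sliding windows (default 10 s, 50% overlap)
#' with a Hann taper; each window is demeaned before tapering. The one-sided
#' PSD is scaled so that its integral equals the signal variance (Parseval),
#' with frequency resolution `1 / window_s`.
#'
#' @param trace A [signal_trace] at least one window long.
#' @param window_s Window length in seconds (default 10).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return An object of class `psd_estimate`: list with `freq` (Hz), `psd`
#'   (uV^2/Hz), `df`, `n_windows`, `fs`.
#' @export
compute_psd <- function(trace, window_s = 10, overlap = 0.5) {
  assert_trace(trace)
  fs <- trace$fs
  nw <- round(window_s * fs)
  n <- length(trace$samples)
  if (n < nw)
    stop("trace shorter than one analysis window", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)

  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nw) - 1L) / (nw - 1L)))  # Hann
  norm <- fs * sum(w^2)
  n_half <- floor(nw / 2)

  acc <- numeric(n_half + 1L)
  for (s0 in starts) {
    seg <- trace$samples[s0:(s0 + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / norm
    p1 <- P[1:(n_half + 1L)]
    p1[2:(n_half + if (nw %% 2L == 0L) 0L else 1L)] <-
      2 * p1[2:(n_half + if (nw %% 2L == 0L) 0L else 1L)]
    acc <- acc + p1
  }
  structure(list(freq = (0:n_half) * fs / nw, psd = acc / length(starts),
                 df = fs / nw, n_windows = length(starts), fs = fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d windows, df=%.3g Hz, 0-%.4g Hz\n",
              x$n_windows, x$df, max(x$freq)))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, ..., log = "y") {
  graphics::plot(x$freq[-1], x$psd[-1], type = "l", log = log,
                 xlab = "frequency (Hz)",
                 ylab = expression(PSD ~ (mu * V^2 / Hz)), ...)
  invisible(x)
}

#' Absolute and relative band powers
#'
#' Integrates the PSD over each half-open band `[f_low, f_high)`. Relative
#' power normalizes by the total power over \[1, 600) Hz -- the union support
#' of the named bands -- so relative powers are invariant under global
#' amplitude scaling. Bands must not overlap.
#'
#' @param psd A `psd_estimate` from [compute_psd()].
#' @param bands Band table as from [default_bands()].
#' @param total_range Normalization range in Hz (default `c(1, 600)`),
#'   clipped to the Nyquist frequency.
#' @return An object of class `band_power_result`: list with `absolute`
#'   (uV^2, named), `relative` (fractions), `total_power`, `bands`.
#' @export
band_powers <- function(psd, bands = default_bands(),
                        total_range = c(1, 600)) {
  stopifnot(inherits(psd, "psd_estimate"))
  bands <- as.data.frame(bands)
  if (any(bands$f_low >= bands$f_high))
    stop("each band needs f_low < f_high", call. = FALSE)
  o <- order(bands$f_low)
  b <- bands[o, ]
  if (nrow(b) > 1L && any(b$f_high[-nrow(b)] > b$f_low[-1L] + 1e-12))
    stop("bands must not overlap", call. = FALSE)
  nyq <- psd$fs / 2
  hi <- min(total_range[2], nyq)
  band_int <- function(lo, hi) {
    sel <- psd$freq >= lo & psd$freq < hi
    sum(psd$psd[sel]) * psd$df
  }
  absolute <- mapply(band_int, bands$f_low, pmin(bands$f_high, nyq))
  names(absolute) <- bands$name
  total <- band_int(total_range[1], hi)
  structure(list(absolute = absolute,
                 relative = if (total > 0) absolute / total else
                   absolute * NA_real_,
                 total_power = total, bands = bands),
            class = "band_power_result")
}

#' @export
print.band_power_result <- function(x, ...) {
  cat("<band_power_result>\n")
  for (i in seq_along(x$absolute))
    cat(sprintf("  %-18s %10.4g uV^2  (%5.1f%%)\n", names(x$absolute)[i],
                x$absolute[i], 100 * x$relative[i]))
  cat(sprintf("  total [1,600) Hz   %10.4g uV^2\n", x$total_power))
  invisible(x)
}

#' Relative power of one band for a trace
#'
#' Convenience wrapper: Welch PSD then band partitioning.
#'
#' @param trace A [signal_trace].
#' @param band Band name in the table (default `"theta"`).
#' @param window_s,overlap Passed to [compute_psd()].
#' @param bands Band table.
#' @return Relative power (fraction of the \[1, 600) Hz total).
#' @export
relative_band_power <- function(trace, band = "theta", window_s = 10,
                                overlap = 0.5, bands = default_bands()) {
  bp <- band_powers(compute_psd(trace, window_s, overlap), bands)
  unname(bp$relative[band])
}

#' Pre- vs post-stimulation theta comparison
#'
#' Computes the relative theta power of the short windows immediately before
#' the first and immediately after the last stimulation train and the percent
#' change `100 * (post - pre) / pre`. Inputs are either single traces or
#' named lists (e.g. `list(left_hipp = ..., right_hipp = ...)`), in which
#' case per-side changes and the left/right mean are reported.
#'
#' @param pre30,post30 [signal_trace] or named list of traces (the ~30 s
#'   pre/post windows).
#' @param window_s PSD window; defaults to 10 s as elsewhere.
#' @return An object of class `theta_change`: list with `per_side` (data
#'   frame `channel`, `rel_theta_pre`, `rel_theta_post`, `change_pct`),
#'   `mean_pre`, `mean_post`, `change_pct` (percent change of the
#'   side-averaged relative theta).
#' @export
theta_change <- function(pre30, post30, window_s = 10) {
  as_list <- function(x) if (is_trace(x)) {
    out <- list(x); names(out) <- x$channel; out
  } else x
  pre <- as_list(pre30); post <- as_list(post30)
  if (!identical(names(pre), names(post)))
    stop("pre and post channel sets differ", call. = FALSE)
  per <- do.call(rbind, lapply(names(pre), function(ch) {
    rp <- relative_band_power(pre[[ch]], "theta", window_s)
    ra <- relative_band_power(post[[ch]], "theta", window_s)
    if (!is.finite(rp) || rp <= 0)
      stop("undefined change: pre-stimulation theta power is zero",
           call. = FALSE)
    data.frame(channel = ch, rel_theta_pre = rp, rel_theta_post = ra,
               change_pct = 100 * (ra - rp) / rp)
  }))
  mp <- mean(per$rel_theta_pre); ma <- mean(per$rel_theta_post)
  structure(list(per_side = per, mean_pre = mp, mean_post = ma,
                 change_pct = 100 * (ma - mp) / mp),
            class = "theta_change")
}

#' @export
print.theta_change <- function(x, ...) {
  cat(sprintf("<theta_change> relative theta %.1f%% -> %.1f%% (%+.1f%%)\n",
              100 * x$mean_pre, 100 * x$mean_post, x$change_pct))
  invisible(x)
}
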