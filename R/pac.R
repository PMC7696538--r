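#' Default fast-frequency (fA) band table
#'
#' Gamma 30-100 Hz, high-frequency oscillations (HFO) 100-150 Hz, ripples
#' 150-250 Hz, fast ripples 250-600 Hz.
#'
#' @return Data frame with columns `name`, `f_low`, `f_high`.
#' @export
default_fa_bands <- function() {
  data.frame(name = c("gamma", "hfo", "ripple", "fast_ripple"),
             f_low = c(30, 100, 150, 250),
             f_high = c(100, 150, 250, 600))
}

#' Configuration for time-resolved phase-amplitude coupling
#'
#' @param fp_band Frequency-for-phase band in Hz (default delta, 1-4).
#' @param fa_bands Frequency-for-amplitude band table (default
#'   [default_fa_bands()]); every band must lie above `fp_band` and bands
#'   must be disjoint.
#' @param window_s Sliding-window length in seconds (default 18, giving 18
#'   delta cycles at the 1 Hz lower edge).
#' @param overlap Fractional window overlap (default 0.5).
#' @param edge_trim_s Seconds trimmed from each end of every window's
#'   envelope and phase before averaging, absorbing filter and Hilbert edge
#'   artifacts at delta frequencies (default 2).
#' @param n_surrogates Default surrogate count for significance thresholds.
#' @return An object of class `pac_config`.
#' @export
pac_config <- function(fp_band = c(1, 4), fa_bands = default_fa_bands(),
                       window_s = 18, overlap = 0.5, edge_trim_s = 2,
                       n_surrogates = 200) {
  stopifnot(length(fp_band) == 2L, fp_band[1] > 0, fp_band[1] < fp_band[2])
  fa_bands <- as.data.frame(fa_bands)
  if (any(fa_bands$f_low <= fp_band[2]))
    stop("every fA band must lie above the phase band", call. = FALSE)
  o <- order(fa_bands$f_low)
  fb <- fa_bands[o, ]
  if (nrow(fb) > 1L && any(fb$f_high[-nrow(fb)] > fb$f_low[-1L] + 1e-12))
    stop("fA bands must be disjoint", call. = FALSE)
  if (window_s <= 2 * edge_trim_s + 1 / fp_band[1])
    stop("window too short for the edge trim and phase band", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)",
                                        call. = FALSE)
  structure(list(fp_band = as.numeric(fp_band), fa_bands = fa_bands,
                 window_s = window_s, overlap = overlap,
                 edge_trim_s = edge_trim_s, n_surrogates = n_surrogates),
            class = "pac_config")
}

# Envelope of the dominant fast rhythm and delta phase for one segment.
# Returns trimmed envelope A, phase ph and the dominant fA frequency.
pac_window_core <- function(x, fs, fp, fa, trim_n) {
  x <- x - mean(x)
  n <- length(x)
  # 1) dominant fA: peak of the band-limited power spectrum
  xf <- bandpass(x, fs, fa[1], fa[2])
  P <- Mod(stats::fft(xf))^2
  freq <- (seq_len(n) - 1L) * fs / n
  half <- freq <= fs / 2
  sel <- which(half & freq >= fa[1] & freq < fa[2])
  if (!length(sel)) stop("fA band empty at this resolution", call. = FALSE)
  dom <- freq[sel[which.max(P[sel])]]
  # 2) envelope around the dominant fA, bandwidth 2x the phase-band top so
  #    the modulation sidebands are retained
  hw <- fp[2]
  lo2 <- max(dom - hw, fp[2] + 0.5)
  hi2 <- min(dom + hw, fs / 2 * 0.999)
  A <- Mod(analytic_signal(bandpass(x, fs, lo2, hi2)))
  # 3) delta phase
  ph <- Arg(analytic_signal(bandpass(x, fs, fp[1], fp[2],
                                     transition = fp[1] / 2)))
  keep <- (trim_n + 1L):(n - trim_n)
  list(A = A[keep], phase = ph[keep], dominant_fa = dom)
}

coupling_stat <- function(A, phase) {
  mv <- mean(A * exp(1i * phase))
  denom <- sqrt(mean(A^2))
  list(coupling = if (denom > 0) Mod(mv) / denom else 0,
       preferred_phase = Arg(mv))
}

#' Time-resolved phase-amplitude coupling (tPAC)
#'
#' For each sliding window (default 18 s, 50% overlap): (1) band-pass to the
#' fA band and locate the dominant fast frequency as the peak of the
#' band-limited power spectrum; (2) band-pass around that frequency with a
#' bandwidth of twice the phase-band top and take the analytic-signal
#' envelope `A(t)`; (3) extract the delta phase `phi(t)`; (4) measure the
#' coupling as the normalized mean vector
#' `|mean(A * exp(i*phi))| / sqrt(mean(A^2))`, a unitless value in \[0, 1\]
#' that is invariant under amplitude scaling of the trace. The preferred
#' phase is the argument of the mean vector. MaxPAC is the maximum over the
#' fA grid of the across-window mean coupling (ties toward the lowest
#' frequency).
#'
#' @param trace A [signal_trace] covering at least one window.
#' @param config A [pac_config].
#' @param fa_band Length-2 numeric fA range in Hz, or the name of a band in
#'   `config$fa_bands` (default the first band).
#' @return An object of class `tpac`: list with `per_window` (data frame
#'   `t_center_s`, `coupling`, `dominant_fa`, `preferred_phase`), `max_pac`,
#'   `max_pac_fa`, `mean_coupling`, `n_windows`, `fa_band`, `fp_band`,
#'   `channel`, `config`.
#' @examples
#' tr <- generate_background(40, 400, seed = 1)
#' tr <- add_coupled_oscillations(tr, 2.5, 20,
#'   data.frame(fa_carrier = 80, fa_amp = 10, kappa = 1))
#' fit <- tpac(tr, pac_config(), c(30, 100))
#' fit
#' @export
tpac <- function(trace, config = pac_config(), fa_band = NULL) {
  assert_trace(trace)
  stopifnot(inherits(config, "pac_config"))
  fa <- resolve_fa_band(config, fa_band)
  fp <- config$fp_band
  if (fa[1] <= fp[2])
    stop("fA band overlaps the phase band", call. = FALSE)
  if (fa[2] > trace$fs / 2)
    stop("fA band exceeds the Nyquist frequency", call. = FALSE)
  fs <- trace$fs
  nw <- round(config$window_s * fs)
  n <- length(trace$samples)
  if (n < nw) stop("trace shorter than one tPAC window", call. = FALSE)
  step <- max(1L, round(nw * (1 - config$overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  trim_n <- round(config$edge_trim_s * fs)

  res <- lapply(starts, function(s0) {
    core <- pac_window_core(trace$samples[s0:(s0 + nw - 1L)], fs, fp, fa,
                            trim_n)
    cs <- coupling_stat(core$A, core$phase)
    data.frame(t_center_s = trace$t0 + (s0 - 1L + nw / 2) / fs,
               coupling = cs$coupling, dominant_fa = core$dominant_fa,
               preferred_phase = cs$preferred_phase)
  })
  pw <- do.call(rbind, res)
  by_fa <- tapply(pw$coupling, pw$dominant_fa, mean)
  fa_vals <- as.numeric(names(by_fa))
  best <- which(by_fa == max(by_fa))
  best <- best[which.min(fa_vals[best])]          # ties: lowest frequency
  structure(list(per_window = pw,
                 max_pac = unname(by_fa[best]),
                 max_pac_fa = fa_vals[best],
                 mean_coupling = mean(pw$coupling),
                 n_windows = nrow(pw),
                 fa_band = fa, fp_band = fp,
                 channel = trace$channel, config = config),
            class = "tpac")
}

resolve_fa_band <- function(config, fa_band) {
  if (is.null(fa_band)) fa_band <- config$fa_bands$name[1]
  if (is.character(fa_band)) {
    row <- config$fa_bands[config$fa_bands$name == fa_band, ]
    if (nrow(row) != 1L)
      stop(sprintf("unknown fA band `%s`", fa_band), call. = FALSE)
    return(c(row$f_low, row$f_high))
  }
  stopifnot(length(fa_band) == 2L, fa_band[1] < fa_band[2])
  as.numeric(fa_band)
}

#' @export
print.tpac <- function(x, ...) {
  cat(sprintf("<tpac> %s, fP %g-%g Hz, fA %g-%g Hz, %d windows\n",
              x$channel, x$fp_band[1], x$fp_band[2], x$fa_band[1],
              x$fa_band[2], x$n_windows))
  cat(sprintf("  MaxPAC %.4g at fA = %.3g Hz; mean coupling %.4g\n",
              x$max_pac, x$max_pac_fa, x$mean_coupling))
  invisible(x)
}

#' @export
summary.tpac <- function(object, ...) {
  pw <- object$per_window
  out <- list(max_pac = object$max_pac, max_pac_fa = object$max_pac_fa,
              mean_coupling = object$mean_coupling,
              coupling_range = range(pw$coupling),
              dominant_fa_mode = as.numeric(names(which.max(
                table(pw$dominant_fa)))),
              n_windows = object$n_windows)
  class(out) <- "summary.tpac"
  out
}

#' @export
print.summary.tpac <- function(x, ...) {
  cat(sprintf("tPAC summary: MaxPAC %.4g (fA %.3g Hz), coupling %.4g-%.4g over %d windows, modal fA %.3g Hz\n",
              x$max_pac, x$max_pac_fa, x$coupling_range[1],
              x$coupling_range[2], x$n_windows, x$dominant_fa_mode))
  invisible(x)
}

#' @export
plot.tpac <- function(x, ...) {
  pw <- x$per_window
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(pw$t_center_s, pw$coupling, type = "b", pch = 16,
                 xlab = "time (s)", ylab = "coupling", ...)
  graphics::plot(pw$t_center_s, pw$dominant_fa, type = "p", pch = 16,
                 xlab = "time (s)", ylab = "dominant fA (Hz)",
                 ylim = x$fa_band)
  invisible(x)
}

#' PAC comodulogram over a phase x amplitude frequency grid
#'
#' Cell (i, j) holds the across-window mean of the normalized mean-vector
#' coupling between the phase of the band centered on `fp_grid[i]` and the
#' envelope of the band centered on `fa_grid[j]`. The phase bands have
#' half-width `fp_halfwidth`; the amplitude bands half-width equal to the
#' top of the phase range so modulation sidebands are retained.
#'
#' @param trace A [signal_trace].
#' @param fp_grid Numeric vector of phase-frequency centers (Hz).
#' @param fa_grid Numeric vector of amplitude-frequency centers (Hz).
#' @param config A [pac_config] (windowing and edge trim).
#' @param fp_halfwidth Half-width of the phase bands in Hz (default 1).
#' @return An object of class `comodulogram`: list with `matrix`
#'   (`length(fp_grid)` x `length(fa_grid)`), `fp_grid`, `fa_grid`, `peak`
#'   (list `fp`, `fa`, `value`).
#' @export
comodulogram <- function(trace, fp_grid, fa_grid, config = pac_config(),
                         fp_halfwidth = 1) {
  assert_trace(trace)
  if (!length(fp_grid) || !length(fa_grid))
    stop("frequency grids must be non-empty", call. = FALSE)
  if (any(fa_grid >= trace$fs / 2))
    stop("fA grid exceeds the Nyquist frequency", call. = FALSE)
  fs <- trace$fs
  nw <- round(config$window_s * fs)
  n <- length(trace$samples)
  if (n < nw) stop("trace shorter than one window", call. = FALSE)
  step <- max(1L, round(nw * (1 - config$overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  trim_n <- round(config$edge_trim_s * fs)
  hw_a <- max(fp_grid) + fp_halfwidth

  acc <- matrix(0, length(fp_grid), length(fa_grid))
  for (s0 in starts) {
    x <- trace$samples[s0:(s0 + nw - 1L)]
    x <- x - mean(x)
    keep <- (trim_n + 1L):(nw - trim_n)
    phases <- lapply(fp_grid, function(fc) {
      lo <- max(fc - fp_halfwidth, 0.2)
      Arg(analytic_signal(bandpass(x, fs, lo, fc + fp_halfwidth,
                                   transition = max(lo / 2, 0.2))))[keep]
    })
    envs <- lapply(fa_grid, function(fc) {
      lo <- max(fc - hw_a, max(fp_grid) + fp_halfwidth + 0.5)
      Mod(analytic_signal(bandpass(x, fs, lo,
                                   min(fc + hw_a, fs / 2 * 0.999))))[keep]
    })
    for (i in seq_along(fp_grid))
      for (j in seq_along(fa_grid))
        acc[i, j] <- acc[i, j] + coupling_stat(envs[[j]], phases[[i]])$coupling
  }
  m <- acc / length(starts)
  dimnames(m) <- list(fp = fp_grid, fa = fa_grid)
  pk <- which(m == max(m), arr.ind = TRUE)[1L, ]
  structure(list(matrix = m, fp_grid = fp_grid, fa_grid = fa_grid,
                 peak = list(fp = fp_grid[pk[1]], fa = fa_grid[pk[2]],
                             value = max(m)),
                 n_windows = length(starts)),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d x %d grid, %d windows; peak %.4g at (fP %.3g, fA %.3g) Hz\n",
              length(x$fp_grid), length(x$fa_grid), x$n_windows,
              x$peak$value, x$peak$fp, x$peak$fa))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$fp_grid, x$fa_grid, x$matrix,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "frequency for phase (Hz)",
                  ylab = "frequency for amplitude (Hz)", ...)
  graphics::points(x$peak$fp, x$peak$fa, pch = 1, cex = 2, col = "white",
                   lwd = 2)
  invisible(x)
}

#' tPAC over every epoch, hippocampal channel and fA band
#'
#' Runs [tpac()] for each combination of epoch in `{pre5, post5}`, channel in
#' `{left_hipp, right_hipp}` (those present) and fA band of the
#' configuration: 2 x 2 x 4 = 16 results for a standard session.
#'
#' @param session A [recording_session].
#' @param epochs Epoch table from [extract_epochs()]; extracted from the
#'   session when omitted.
#' @param config A [pac_config].
#' @return Data frame with one row per result: `animal_id`, `day_index`,
#'   `epoch`, `channel`, `fa_band`, `max_pac`, `max_pac_fa`,
#'   `mean_coupling`, `n_windows`.
#' @export
epoch_pac <- function(session, epochs = NULL, config = pac_config()) {
  stopifnot(inherits(session, "recording_session"))
  if (is.null(epochs)) epochs <- extract_epochs(session)
  chans <- intersect(c("left_hipp", "right_hipp"), unique(epochs$channel))
  labels <- intersect(c("pre5", "post5"), unique(epochs$label))
  rows <- list()
  for (lab in labels) for (ch in chans) {
    tr <- epoch_trace(session, epochs, lab, ch)
    for (b in seq_len(nrow(config$fa_bands))) {
      fit <- tpac(tr, config, config$fa_bands$name[b])
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = session$animal_id, day_index = session$day_index,
        epoch = lab, channel = ch, fa_band = config$fa_bands$name[b],
        max_pac = fit$max_pac, max_pac_fa = fit$max_pac_fa,
        mean_coupling = fit$mean_coupling, n_windows = fit$n_windows)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- independent oracle and surrogate control ------------------------------

#' Kullback-Leibler modulation index from phase and amplitude series
#'
#' Bins the phase into `n_bins` equal bins, averages the amplitude per bin,
#' normalizes to a distribution `P` and returns `KL(P || uniform) /
#' log(n_bins)`, a value in \[0, 1\]: 0 for a phase-independent amplitude,
#' 1 when all amplitude concentrates in a single bin.
#'
#' @param phase Phase series in radians.
#' @param amplitude Non-negative amplitude series (same length).
#' @param n_bins Number of phase bins (default 18).
#' @return Normalized modulation index.
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude))
  if (all(amplitude == 0))
    stop("undefined modulation index: amplitude is identically zero",
         call. = FALSE)
  bins <- floor((phase + pi) / (2 * pi) * n_bins) + 1L
  bins[bins > n_bins] <- n_bins
  pj <- tapply(amplitude, factor(bins, levels = seq_len(n_bins)), mean)
  pj[is.na(pj)] <- 0
  P <- pj / sum(pj)
  nz <- P > 0
  sum(P[nz] * log(P[nz] * n_bins)) / log(n_bins)
}

#' Modulation-index PAC measure for a trace
#'
#' Independent reference measure used to cross-validate the tPAC estimator:
#' filters the trace to the phase and amplitude bands, applies the Hilbert
#' transform and computes the normalized Kullback-Leibler [modulation_index()]
#' on the whole trace (edges trimmed).
#'
#' @param trace A [signal_trace] spanning at least 10 phase-band cycles.
#' @param fp_band Phase band, Hz (default delta 1-4).
#' @param fa_band Amplitude band, Hz.
#' @param n_bins Phase bins (default 18).
#' @param edge_trim_s Seconds trimmed from each end (default 2).
#' @return Modulation index in \[0, 1\].
#' @export
tort_mi <- function(trace, fp_band = c(1, 4), fa_band = c(30, 100),
                    n_bins = 18, edge_trim_s = 2) {
  assert_trace(trace)
  if (duration(trace) < 10 / fp_band[1])
    stop("trace shorter than 10 phase-band cycles", call. = FALSE)
  bp_a <- band_envelope_phase(trace, fa_band[1], fa_band[2])
  bp_p <- band_envelope_phase(trace, fp_band[1], fp_band[2],
                              transition = fp_band[1] / 2)
  n <- length(trace$samples)
  tr <- round(edge_trim_s * trace$fs)
  keep <- (tr + 1L):(n - tr)
  modulation_index(bp_p$phase[keep], bp_a$envelope[keep], n_bins)
}

#' Surrogate significance threshold for PAC
#'
#' Null distribution by circular time shifts: the fast-band envelope is
#' rotated relative to the delta phase by uniform random offsets of at least
#' one phase-band cycle, destroying any true phase-amplitude relation while
#' preserving both marginal spectra. Returns the `1 - alpha` quantile of the
#' surrogate couplings; the observed whole-trace coupling is attached as
#' attribute `"observed"`.
#'
#' @param trace A [signal_trace].
#' @param config A [pac_config].
#' @param fa_band fA range (numeric or band name).
#' @param n_surrogates Number of surrogates (>= 20).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed for reproducible thresholds.
#' @return Numeric threshold with attributes `observed` (coupling of the
#'   unshifted data) and `surrogates` (the null couplings).
#' @export
surrogate_threshold <- function(trace, config = pac_config(), fa_band = NULL,
                                n_surrogates = 200, alpha = 0.05,
                                seed = NULL) {
  assert_trace(trace)
  if (n_surrogates < 20)
    stop("at least 20 surrogates are required", call. = FALSE)
  fa <- resolve_fa_band(config, fa_band)
  fp <- config$fp_band
  fs <- trace$fs
  n <- length(trace$samples)
  trim_n <- round(config$edge_trim_s * fs)
  core <- pac_window_core(trace$samples, fs, fp, fa, trim_n)
  A <- core$A; ph <- core$phase
  m <- length(A)
  obs <- coupling_stat(A, ph)$coupling
  min_shift <- ceiling(fs / fp[1])               # >= one slow cycle
  eiph <- exp(1i * ph)
  denom <- sqrt(mean(A^2))
  sur <- with_seed(seed, {
    shifts <- sample(seq(min_shift, m - min_shift), n_surrogates,
                     replace = TRUE)
    vapply(shifts, function(s) {
      As <- c(A[(s + 1L):m], A[1:s])
      Mod(mean(As * eiph)) / denom
    }, numeric(1))
  })
  thr <- unname(stats::quantile(sur, 1 - alpha, type = 7))
  attr(thr, "observed") <- obs
  attr(thr, "surrogates") <- sur
  thr
}
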