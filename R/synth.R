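#' Specification for one synthetic LFP session
#'
#' Describes the generative model for a single recording day: a 1/f^beta
#' broadband background, a delta rhythm whose phase modulates one or more
#' fast carriers (the phenomenon probed by phase-amplitude coupling), a theta
#' component, and injected interictal discharges of three subtypes. The
#' defaults emulate the chronic-epileptic study condition: a prominent delta,
#' relative theta power near 26% of broadband power, weak gamma-band coupling
#' whose measured strength falls in the 1e-2 decade, a total discharge rate
#' of 3.61 events/min split roughly 72/11/17% across spikes, polyspikes and
#' sharp waves, and after the last stimulation train a modest theta increase
#' (amplitude x1.11, i.e. ~17% relative-theta gain) together with a reduction
#' of the modulation depth (x0.8).
#'
#' @param duration_s Session duration in seconds.
#' @param fs Sampling rate in Hz (default 5000).
#' @param noise_exponent Power-law slope beta of the background spectrum
#'   (power ~ 1/f^beta), default 1.
#' @param noise_scale Background RMS amplitude in microvolts.
#' @param delta_freq,delta_amp Delta rhythm frequency (Hz, in 1-4) and
#'   amplitude (microvolts).
#' @param theta_freq,theta_amp Theta component frequency (Hz, in 4-12) and
#'   amplitude (microvolts).
#' @param coupling Data frame with columns `fa_carrier` (Hz), `fa_amp`
#'   (microvolts) and `kappa` (modulation depth in \[0, 1\]). Each carrier is
#'   amplitude-modulated by the delta phase with normalized envelope
#'   `(1 + kappa * cos(phase)) / (1 + kappa)` so its peak amplitude is
#'   independent of `kappa`.
#' @param ied_rates Named numeric vector of event rates in events/min for
#'   subtypes `spike`, `polyspike`, `sharp_wave`.
#' @param ied_amp_sd_multiple Event peak amplitude as a multiple of the
#'   background robust SD (default 6).
#' @param delta_jitter_hz SD of the delta instantaneous-frequency drift (see
#'   [drifting_phase()]); 0 gives a strictly sinusoidal delta.
#' @param post_theta_mult,post_kappa_mult Multipliers applied to the theta
#'   amplitude and to every coupling depth after the last stimulation train
#'   of the session's schedule (1 = no change).
#' @param seed Integer seed; fixed seed gives bit-identical sessions.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_session()], [generate_background()]
#' @export
synthetic_spec <- function(duration_s = 1700, fs = 5000,
                           noise_exponent = 1, noise_scale = 50,
                           delta_freq = 2.5, delta_amp = 60,
                           theta_freq = 7, theta_amp = 38,
                           coupling = data.frame(fa_carrier = 80,
                                                 fa_amp = 8,
                                                 kappa = 0.25),
                           ied_rates = c(spike = 2.60, polyspike = 0.40,
                                         sharp_wave = 0.61),
                           ied_amp_sd_multiple = 6,
                           delta_jitter_hz = 0.3,
                           post_theta_mult = 1.11, post_kappa_mult = 0.8,
                           seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be > 0", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  coupling <- as.data.frame(coupling)
  if (nrow(coupling)) {
    stopifnot(all(c("fa_carrier", "fa_amp", "kappa") %in% names(coupling)))
    if (any(coupling$kappa < 0 | coupling$kappa > 1))
      stop("every coupling `kappa` must lie in [0, 1]", call. = FALSE)
    if (any(coupling$fa_carrier >= fs / 2))
      stop("every coupling carrier must lie below fs/2", call. = FALSE)
  }
  if (any(ied_rates < 0)) stop("`ied_rates` must be >= 0", call. = FALSE)
  if (!(delta_freq >= 1 && delta_freq <= 4))
    stop("`delta_freq` must lie in [1, 4] Hz", call. = FALSE)
  if (!(theta_freq >= 4 && theta_freq <= 12))
    stop("`theta_freq` must lie in [4, 12] Hz", call. = FALSE)
  structure(list(
    duration_s = duration_s, fs = fs, noise_exponent = noise_exponent,
    noise_scale = noise_scale, delta_freq = delta_freq,
    delta_amp = delta_amp, theta_freq = theta_freq, theta_amp = theta_amp,
    coupling = coupling, ied_rates = ied_rates,
    ied_amp_sd_multiple = ied_amp_sd_multiple,
    delta_jitter_hz = delta_jitter_hz,
    post_theta_mult = post_theta_mult, post_kappa_mult = post_kappa_mult,
    seed = seed
  ), class = "synthetic_spec")
}

#' Generate 1/f^beta background noise
#'
#' Synthesized directly in the frequency domain: independent complex Gaussian
#' Fourier coefficients with expected power proportional to `f^-beta`, zero
#' DC, inverse transform, then rescaled to the requested RMS and demeaned.
#' This gives direct spectral control at O(n log n) cost.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param noise_exponent Spectral slope beta (power ~ 1/f^beta).
#' @param noise_scale Target RMS in microvolts.
#' @param seed Integer seed (optional); fixed seed reproduces the trace.
#' @param channel Channel label for the returned trace.
#' @return A [signal_trace] of `round(duration_s * fs)` zero-mean samples.
#' @examples
#' bg <- generate_background(10, 500, seed = 1)
#' sd(bg$samples)
#' @export
generate_background <- function(duration_s, fs, noise_exponent = 1,
                                noise_scale = 50, seed = NULL,
                                channel = "background") {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a positive scalar", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar", call. = FALSE)
  n <- round(duration_s * fs)
  if (n < 8L) stop("duration too short at this sampling rate", call. = FALSE)
  x <- with_seed(seed, {
    n_pos <- floor(n / 2)
    f <- (1:n_pos) * fs / n
    mag <- f^(-noise_exponent / 2)
    re <- stats::rnorm(n_pos) * mag
    im <- stats::rnorm(n_pos) * mag
    X <- complex(length.out = n)
    X[2:(n_pos + 1L)] <- complex(real = re, imaginary = im)
    if (n %% 2L == 0L) X[n_pos + 1L] <- complex(real = re[n_pos], imaginary = 0)
    # hermitian symmetry for a real signal
    X[n:(n - n_pos + 2L)] <- Conj(X[2:n_pos])
    Re(stats::fft(X, inverse = TRUE) / n)
  })
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (noise_scale / s)
  signal_trace(x, fs, channel)
}

#' Instantaneous phase of a slowly drifting rhythm
#'
#' Integrated phase of an oscillation whose instantaneous frequency wanders
#' around `f0` as an Ornstein-Uhlenbeck process (SD `jitter_hz`, correlation
#' time `tau_s`). In vivo delta is narrowband, not a pure sinusoid; the drift
#' makes the rhythm aperiodic, which matters when circular-shift surrogates
#' are used (shifting a strictly periodic envelope only rotates the coupling
#' vector without shrinking it).
#'
#' @param duration_s,fs Duration (s) and sampling rate (Hz).
#' @param f0 Center frequency in Hz.
#' @param jitter_hz SD of the instantaneous-frequency deviation (0 gives the
#'   pure sinusoid phase `2*pi*f0*t`).
#' @param tau_s Correlation time of the frequency drift in seconds.
#' @param seed Optional integer seed.
#' @return Phase vector in radians, length `round(duration_s * fs)`.
#' @export
drifting_phase <- function(duration_s, fs, f0, jitter_hz = 0.3, tau_s = 2,
                           seed = NULL) {
  n <- round(duration_s * fs)
  if (jitter_hz <= 0) return(2 * pi * f0 * (0:(n - 1L)) / fs)
  ar <- exp(-1 / (tau_s * fs))
  innov_sd <- jitter_hz * sqrt(1 - ar^2)
  df <- with_seed(seed,
    as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar,
                             method = "recursive")))
  2 * pi * cumsum(f0 + df) / fs
}

#' Add a delta rhythm and delta-phase-modulated fast carriers
#'
#' Adds `delta_amp * cos(phi(t))` with `phi(t) = 2*pi*delta_freq*t`, plus for
#' each coupling entry a carrier
#' `fa_amp * (1 + kappa * cos(phi(t))) / (1 + kappa) * cos(2*pi*fa_carrier*t)`.
#' The envelope normalization by `1 + kappa` keeps the carrier's peak
#' amplitude independent of the modulation depth, so coupling strength is
#' varied without changing fast-band peak power. With `kappa = 0` the fast
#' envelope is constant; with `kappa = 1` it vanishes at the delta trough.
#'
#' @param trace A [signal_trace] (typically background noise).
#' @param delta_freq Delta frequency in Hz.
#' @param delta_amp Delta amplitude in microvolts.
#' @param couplings Data frame with columns `fa_carrier`, `fa_amp`, `kappa`
#'   (may have zero rows).
#' @param kappa_scale Optional numeric vector (length of the trace) scaling
#'   every `kappa` over time; used to lower the modulation depth after the
#'   stimulation trains.
#' @param amp_scale Optional per-sample scaling of the carrier amplitudes.
#' @param phase Optional precomputed delta phase in radians (e.g. from
#'   [drifting_phase()]); defaults to the pure sinusoid phase.
#' @return The trace with the deterministic components added.
#' @export
add_coupled_oscillations <- function(trace, delta_freq, delta_amp, couplings,
                                     kappa_scale = NULL, amp_scale = NULL,
                                     phase = NULL) {
  assert_trace(trace)
  t <- trace_times(trace)
  phi <- if (is.null(phase)) 2 * pi * delta_freq * t else phase
  stopifnot(length(phi) == length(t))
  x <- trace$samples + delta_amp * cos(phi)
  couplings <- as.data.frame(couplings)
  if (nrow(couplings)) {
    if (any(couplings$fa_carrier >= trace$fs / 2))
      stop("coupling carrier at or above the Nyquist frequency", call. = FALSE)
    if (any(couplings$kappa < 0 | couplings$kappa > 1))
      stop("kappa must lie in [0, 1]", call. = FALSE)
    cphi <- cos(phi)
    for (i in seq_len(nrow(couplings))) {
      k <- couplings$kappa[i]
      kt <- if (is.null(kappa_scale)) k else pmin(pmax(k * kappa_scale, 0), 1)
      env <- (1 + kt * cphi) / (1 + kt)
      if (!is.null(amp_scale)) env <- env * amp_scale
      x <- x + couplings$fa_amp[i] * env * cos(2 * pi * couplings$fa_carrier[i] * t)
    }
  }
  signal_trace(x, trace$fs, trace$channel, trace$t0)
}

#' Add a plain sinusoidal component to a trace
#'
#' @param trace A [signal_trace].
#' @param freq Frequency in Hz (below Nyquist).
#' @param amp Amplitude in microvolts; may be a per-sample vector, which is
#'   how the post-stimulation theta increase is imposed.
#' @param phase Initial phase in radians.
#' @return The trace with the sinusoid added.
#' @export
add_oscillation <- function(trace, freq, amp, phase = 0) {
  assert_trace(trace)
  if (freq >= trace$fs / 2) stop("frequency at or above Nyquist", call. = FALSE)
  t <- trace_times(trace)
  signal_trace(trace$samples + amp * sin(2 * pi * freq * t + phase),
               trace$fs, trace$channel, trace$t0)
}

# Half-sine deflection template of total width `width_s`, unit peak.
ied_template <- function(width_s, fs) {
  m <- max(3L, round(width_s * fs))
  sin(pi * (seq_len(m) - 0.5) / m)
}

# Build the pure event component: a numeric vector of length n containing the
# injected discharges, plus the ground-truth table. Deterministic given seed.
# Successive discharges keep a refractory spacing (>= 0.55 s between the end
# of one event and the start of the next) so that every injected event stays
# individually countable under per-discharge (500 ms merge) counting.
make_ied_signal <- function(n, fs, rates, amp0, seed = NULL) {
  dur <- n / fs
  x <- numeric(n)
  empty <- data.frame(time_s = numeric(), subtype = character(),
                      amplitude_uv = numeric(), duration_ms = numeric())
  gt <- with_seed(seed, {
    rows <- list()
    margin <- 0.6                       # keep full event support inside trace
    # draw all candidate times first, then thin for refractory spacing
    cand <- list()
    for (st in names(rates)) {
      if (rates[[st]] <= 0 || dur <= 2 * margin) next
      n_ev <- stats::rpois(1L, rates[[st]] * dur / 60)
      if (n_ev == 0L) next
      cand[[st]] <- data.frame(time = stats::runif(n_ev, margin, dur - margin),
                               subtype = st)
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$time), , drop = FALSE]
      keep <- logical(nrow(cand))
      last_end <- -Inf
      for (i in seq_len(nrow(cand))) {
        if (cand$time[i] - last_end >= 0.55) {
          keep[i] <- TRUE
          last_end <- cand$time[i] +
            if (cand$subtype[i] == "polyspike") 0.5 else 0.2
        }
      }
      cand <- cand[keep, , drop = FALSE]
    } else cand <- data.frame(time = numeric(), subtype = character())
    for (i_ev in seq_len(nrow(cand))) {
      tt <- cand$time[i_ev]
      st <- cand$subtype[i_ev]
      {
        sign_ev <- sample(c(-1, 1), 1L)
        if (st == "spike" || st == "sharp_wave") {
          w <- if (st == "spike") stats::runif(1, 0.020, 0.070)
               else stats::runif(1, 0.070, 0.200)
          tmpl <- ied_template(w, fs) * amp0 * sign_ev
          i0 <- round((tt - w / 2) * fs)
          idx <- i0 + seq_along(tmpl)
          x[idx] <- x[idx] + tmpl
          rows[[length(rows) + 1L]] <- data.frame(
            time_s = tt, subtype = st, amplitude_uv = amp0 * sign_ev,
            duration_ms = 1000 * w)
        } else {                        # polyspike: 2-4 deflections / 500 ms
          n_sub <- sample(2:4, 1L)
          widths <- stats::runif(n_sub, 0.020, 0.060)
          gaps <- stats::runif(n_sub - 1L, 0.030, 0.080)
          onsets <- cumsum(c(0, widths[-n_sub] + gaps))
          total <- onsets[n_sub] + widths[n_sub]
          if (total > 0.5) { sc <- 0.5 / total; onsets <- onsets * sc
                             widths <- widths * sc; total <- 0.5 }
          for (j in seq_len(n_sub)) {
            tmpl <- ied_template(widths[j], fs) * amp0 * sign_ev
            i0 <- round((tt + onsets[j]) * fs)
            idx <- i0 + seq_along(tmpl)
            x[idx] <- x[idx] + tmpl
          }
          rows[[length(rows) + 1L]] <- data.frame(
            time_s = tt + widths[1] / 2, subtype = st,
            amplitude_uv = amp0 * sign_ev, duration_ms = 1000 * total)
        }
      }
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out[order(out$time_s), , drop = FALSE]
    } else empty
  })
  rownames(gt) <- NULL
  list(signal = x, ground_truth = gt)
}

#' Inject interictal discharge events into a trace
#'
#' Event times are drawn from a homogeneous Poisson process per subtype.
#' Spikes are single half-sine deflections 20-70 ms wide, sharp waves 70-200
#' ms wide, and a polyspike is a burst of 2-4 spike deflections within 500 ms
#' counted as one event (rates are per discharge, not per deflection).
#' Deflection sign is random; peak amplitude is `ied_amp_sd_multiple` times
#' the robust (MAD-based) SD of the input trace, so detector performance is
#' controlled by SNR rather than absolute scale.
#'
#' @param trace A [signal_trace].
#' @param ied_rates Named rates in events/min for `spike`, `polyspike`,
#'   `sharp_wave`; all must be >= 0.
#' @param ied_amp_sd_multiple Peak amplitude in background-SD units.
#' @param seed Optional integer seed.
#' @return A list with `trace` (the trace with events added) and
#'   `ground_truth`, a data frame with one row per injected event:
#'   `time_s` (peak time of the first deflection), `subtype`,
#'   `amplitude_uv`, `duration_ms`.
#' @export
inject_ied_events <- function(trace, ied_rates, ied_amp_sd_multiple = 6,
                              seed = NULL) {
  assert_trace(trace)
  if (any(ied_rates < 0)) stop("`ied_rates` must be >= 0", call. = FALSE)
  rates <- c(spike = 0, polyspike = 0, sharp_wave = 0)
  rates[names(ied_rates)] <- ied_rates
  amp0 <- ied_amp_sd_multiple * robust_sd(trace$samples)
  ev <- make_ied_signal(length(trace$samples), trace$fs, rates, amp0, seed)
  list(trace = signal_trace(trace$samples + ev$signal, trace$fs,
                            trace$channel, trace$t0),
       ground_truth = ev$ground_truth)
}

#' Generate recording sessions for a whole synthetic cohort
#'
#' Builds one recording session per animal of a seizure cohort. Each
#' animal's imposed coupling depth is scaled by its latent PAC level
#' relative to the cohort mean (clamped to \[0.02, 1\]), so the measured
#' MaxPAC inherits the cohort's PAC-outcome link; background noise and
#' discharge times are independent across animals.
#'
#' @param cohort A `seizure_cohort` from [generate_seizure_log()].
#' @param spec A [synthetic_spec] used as the per-animal template.
#' @param schedule Stimulation schedule attached to every session.
#' @param pac_mean Cohort-mean PAC level the template's `kappa` corresponds
#'   to (defaults to the mean latent level of the cohort).
#' @param day_index Day label for the sessions.
#' @return Named list of `generate_session()` results, one per animal.
#' @export
generate_cohort_sessions <- function(cohort, spec, schedule = NULL,
                                     pac_mean = NULL, day_index = 1L) {
  stopifnot(inherits(cohort, "seizure_cohort"), inherits(spec, "synthetic_spec"))
  if (is.null(pac_mean)) pac_mean <- mean(cohort$animals$pac_level)
  out <- list()
  for (i in seq_len(nrow(cohort$animals))) {
    an <- cohort$animals[i, ]
    sp <- spec
    sp$coupling$kappa <- pmin(pmax(spec$coupling$kappa *
                                     an$pac_level / pac_mean, 0.02), 1)
    sp$seed <- (if (is.null(spec$seed)) 0L else as.integer(spec$seed)) +
      1000L * i
    out[[an$animal_id]] <- generate_session(sp, schedule,
                                            animal_id = an$animal_id,
                                            day_index = day_index)
  }
  out
}

#' Assemble a full synthetic recording session
#'
#' Builds the two hippocampal channels (shared deterministic structure and
#' shared discharge times, independent background noise) plus two epidural
#' background channels, attaches the stimulation schedule, and returns the
#' ground truth of everything that was injected. If the spec's
#' `post_theta_mult` / `post_kappa_mult` differ from 1, the theta amplitude
#' and coupling depths change at the offset of the last stimulation train,
#' emulating the short-term post-stimulation effects.
#'
#' @param spec A [synthetic_spec].
#' @param schedule A stimulation schedule from [build_schedule()], or `NULL`
#'   for an unstimulated (SHAM-style) session.
#' @param animal_id,group,day_index Session metadata.
#' @return A list with `session` (a [recording_session]) and `ground_truth`
#'   (list with `ied_events`, `imposed_couplings`, `imposed_theta_fraction`).
#' @export
generate_session <- function(spec, schedule = NULL, animal_id = "rat01",
                             group = "DBS-Pilo", day_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "stim_schedule"))
    if (schedule_total_s(schedule) > spec$duration_s + 1e-9)
      stop("stimulation schedule longer than the session duration", call. = FALSE)
  }
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1L) / spec$fs
  t_post <- if (!is.null(schedule)) last_train_offset_s(schedule) else Inf
  post <- t >= t_post
  kappa_scale <- ifelse(post, spec$post_kappa_mult, 1)
  theta_amp_t <- spec$theta_amp * ifelse(post, spec$post_theta_mult, 1)

  base_seed <- if (is.null(spec$seed)) NULL else as.integer(spec$seed)
  sub <- function(off) if (is.null(base_seed)) NULL else
    (base_seed + off) %% .Machine$integer.max
  # bilaterally coherent drifting delta phase shared by both hippocampi
  phi <- drifting_phase(spec$duration_s, spec$fs, spec$delta_freq,
                        spec$delta_jitter_hz, seed = sub(606L))[seq_len(n)]
  make_channel <- function(label, sub_seed, full = TRUE) {
    tr <- generate_background(spec$duration_s, spec$fs, spec$noise_exponent,
                              spec$noise_scale, seed = sub(sub_seed),
                              channel = label)
    if (!full) return(tr)
    tr <- add_coupled_oscillations(tr, spec$delta_freq, spec$delta_amp,
                                   spec$coupling, kappa_scale = kappa_scale,
                                   phase = phi)
    add_oscillation(tr, spec$theta_freq, theta_amp_t)
  }
  left <- make_channel("left_hipp", 101L)
  right <- make_channel("right_hipp", 202L)

  # discharges: identical waveforms on the two hippocampal channels,
  # amplitude keyed to the left channel's robust SD
  ev_seed <- if (is.null(base_seed)) NULL else (base_seed + 303L) %% .Machine$integer.max
  rates <- c(spike = 0, polyspike = 0, sharp_wave = 0)
  rates[names(spec$ied_rates)] <- spec$ied_rates
  amp0 <- spec$ied_amp_sd_multiple * robust_sd(left$samples)
  ev <- make_ied_signal(n, spec$fs, rates, amp0, seed = ev_seed)
  gt_events <- ev$ground_truth
  left <- signal_trace(left$samples + ev$signal, spec$fs, "left_hipp")
  right <- signal_trace(right$samples + ev$signal, spec$fs, "right_hipp")

  epi1 <- make_channel("epidural_1", 404L, full = FALSE)
  epi2 <- make_channel("epidural_2", 505L, full = FALSE)

  session <- recording_session(
    traces = list(left_hipp = left, right_hipp = right,
                  epidural_1 = epi1, epidural_2 = epi2),
    animal_id = animal_id, group = group, day_index = day_index,
    schedule = schedule)

  det_ms <- function(amp, kap) amp^2 * (1 + kap^2 / 2) / (2 * (1 + kap)^2)
  carrier_ms <- if (nrow(spec$coupling))
    sum(det_ms(spec$coupling$fa_amp, spec$coupling$kappa)) else 0
  theta_ms <- spec$theta_amp^2 / 2
  delta_ms <- spec$delta_amp^2 / 2
  gt <- list(
    ied_events = gt_events,
    imposed_couplings = spec$coupling,
    imposed_theta_fraction = theta_ms / (theta_ms + delta_ms + carrier_ms))
  list(session = session, ground_truth = gt)
}
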