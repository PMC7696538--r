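# Shared fixture builders. Test problem sizes are scaled down from the
# in-vivo protocol (1700 s at 5 kHz): short sessions at 1-2 kHz sampling,
# which keeps the Nyquist frequency above the 600 Hz fast-ripple edge where
# needed while keeping the suite fast.

# single gamma band: most PAC tests probe the imposed 80 Hz carrier
gamma_cfg <- function() {
  pac_config(fa_bands = data.frame(name = "gamma", f_low = 30, f_high = 100))
}

# background + delta-modulated 80 Hz carrier, optionally with drifting
# delta phase (needed whenever circular-shift surrogates are involved)
coupled_trace <- function(kappa, seed, duration_s = 60, fs = 1000,
                          noise_scale = 30, delta_amp = 40, fa_amp = 10,
                          carrier = 80, delta_freq = 2.5, jitter = 0) {
  tr <- generate_background(duration_s, fs, 1, noise_scale, seed = seed)
  ph <- if (jitter > 0)
    drifting_phase(duration_s, fs, delta_freq, jitter, seed = seed + 5000L)
  else NULL
  add_coupled_oscillations(tr, delta_freq, delta_amp,
                           data.frame(fa_carrier = carrier, fa_amp = fa_amp,
                                      kappa = kappa),
                           phase = ph)
}

# reduced-scale stimulated session: 2 x 10 s trains, 30 s pauses,
# 60 s pre/post windows (total 170 s)
small_schedule <- function() {
  build_schedule(n_trains = 2, train_s = 10, pause_s = 30,
                 pre_s = 60, post_s = 60)
}

small_session <- function(seed = 7, fs = 1500, post_kappa_mult = 1,
                          post_theta_mult = 1, ...) {
  spec <- synthetic_spec(duration_s = 170, fs = fs,
                         post_kappa_mult = post_kappa_mult,
                         post_theta_mult = post_theta_mult,
                         seed = seed, ...)
  generate_session(spec, small_schedule())
}
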