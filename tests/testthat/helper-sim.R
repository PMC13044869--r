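# Shared fixtures for the test suite: quiet/noise-free simulation settings
# and a scaled-down oddball design used wherever full-scale sequences are
# not the thing under test.

noise_free <- function(...) {
  noise_params(white_sd_frac = 0, artifact_sd = 0, bleach_iso_scale = 1, ...)
}

small_oddball <- function(n_deviants = 10, n_blocks = 1, ...) {
  oddball_spec(n_deviants_per_block = n_deviants, n_blocks = n_blocks, ...)
}

# single-presentation events shifted so the 2-s pre-onset baseline fits
simple_events <- function(n_events = 10, duration_s = 6) {
  ev <- stim_simple(duration_s = duration_s, n_events = n_events)
  ev$onset_s <- ev$onset_s + 3
  ev
}

# full quiet pipeline: events -> recording -> global z -> epochs
quiet_epochs <- function(ev, seed = 1, window = c(-2, 8), noise = noise_free()) {
  rec <- simulate_recording(ev, noise = noise, seed = seed)
  ztr <- normalize_z(correct_isosbestic(rec))
  suppressMessages(extract_epochs(ztr, ev, window = window))
}
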