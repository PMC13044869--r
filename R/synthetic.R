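# Synthetic two-channel photometry recordings and behavioral sessions.
#
# The generator encodes the stimulus-locked dopamine response as a sum of
# four smooth components -- onset-positive, onset-negative, intra-stimulus
# dip, offset-positive -- plus a drop-positive component after mid-stimulus
# intensity decrements. Component amplitudes are expressed in "kernel
# units": the z-score units in which the analysis reports response
# features. The rendered fluorescence maps kernel units to fractional
# fluorescence through `dff_scale`, multiplies in per-channel
# photobleaching, and adds a shared (common-mode) artifact plus white
# noise to both channels.

#' Dopamine response kernel parameters
#'
#' Peak latencies (ms, relative to the anchoring event), amplitudes
#' (kernel z units) and rise/fall widths (ms, the standard deviations of
#' an asymmetric Gaussian) for each response component. Defaults follow
#' the grand-average response to 6-s broadband noise: onset-positive
#' +0.224 at 96 ms, onset-negative -0.860 at 602 ms, intra-stimulus dip
#' -0.327 (mean over the final second), offset-positive +0.744 at 549 ms
#' after offset. The drop-positive component is anchored to a
#' mid-stimulus intensity decrement and scales linearly with its
#' magnitude via `intensity_gain` (z per dB); the default gain makes a
#' -40 dB step match the offset-positive amplitude. `deviant_gain`
#' multiplies the value-encoding components (onset-negative and
#' intra-stimulus dip) for deviant-role events. `offset_relief_tau_s`
#' saturates the offset-positive (and drop-positive) amplitude with the
#' time spent in the preceding state, so very brief stimuli produce only
#' a weak relief peak; set it to 0 for a duration-independent offset
#' component.
#'
#' @param onset_positive,onset_negative,offset_positive Named numeric
#'   vectors `c(latency_ms=, amplitude_z=, rise_ms=, fall_ms=)`.
#' @param intra_dip_z Mean depth of the intra-stimulus dip (z units).
#' @param drop_positive Named vector `c(latency_ms=, rise_ms=, fall_ms=)`
#'   for the drop-positive shape (its amplitude comes from
#'   `intensity_gain`).
#' @param intensity_gain z units per dB of intensity decrement.
#' @param deviant_gain Multiplier (> 0) on the value components for
#'   events with role `deviant`.
#' @param offset_relief_tau_s Saturation time constant (s) of the relief
#'   amplitude; 0 disables the scaling.
#' @return A list of class `kernel_params`.
#' @export
kernel_params <- function(onset_positive = c(latency_ms = 96, amplitude_z = 0.224, rise_ms = 35, fall_ms = 50),
                          onset_negative = c(latency_ms = 602, amplitude_z = -0.860, rise_ms = 100, fall_ms = 120),
                          offset_positive = c(latency_ms = 549, amplitude_z = 0.744, rise_ms = 100, fall_ms = 120),
                          intra_dip_z = -0.327,
                          drop_positive = c(latency_ms = 549, rise_ms = 100, fall_ms = 120),
                          intensity_gain = 0.744 / 40,
                          deviant_gain = 1,
                          offset_relief_tau_s = 0.3) {
  for (comp in list(onset_positive, onset_negative, offset_positive, drop_positive)) {
    if (any(comp[c("rise_ms", "fall_ms")] <= 0)) rlang::abort("component widths must be > 0")
  }
  if (deviant_gain <= 0) rlang::abort("`deviant_gain` must be > 0")
  structure(
    list(
      onset_positive = onset_positive, onset_negative = onset_negative,
      offset_positive = offset_positive, intra_dip_z = intra_dip_z,
      drop_positive = drop_positive, intensity_gain = intensity_gain,
      deviant_gain = deviant_gain, offset_relief_tau_s = offset_relief_tau_s
    ),
    class = "kernel_params"
  )
}

#' Dopamine sensor kinetics
#'
#' Models the sensor as a causal difference-of-exponentials impulse
#' response. The rise time constant is solved numerically so that the
#' 10--90% rise time of the impulse response equals `rise_time_ms`
#' (defaults to the ~70 ms rise of fast GRAB-type dopamine sensors); the
#' decay constant is exposed directly.
#'
#' @param rise_time_ms Target 10--90% rise time of the impulse response, ms.
#' @param decay_ms Decay time constant, ms; must exceed the implied rise
#'   constant.
#' @return A list of class `sensor_params` with elements `tau_rise_ms`,
#'   `tau_decay_ms`, `rise_time_ms`.
#' @export
sensor_params <- function(rise_time_ms = 70, decay_ms = 700) {
  stopifnot(rise_time_ms > 0, decay_ms > 0)
  f <- function(tau_r) rise_time_diffexp(tau_r, decay_ms) - rise_time_ms
  upper <- decay_ms * 0.999
  if (f(upper) < 0) rlang::abort("`decay_ms` too small for the requested rise time")
  tau_rise <- stats::uniroot(f, c(1e-3, upper), tol = 1e-10)$root
  if (decay_ms <= tau_rise) rlang::abort("decay constant must exceed the rise constant")
  structure(
    list(tau_rise_ms = tau_rise, tau_decay_ms = decay_ms, rise_time_ms = rise_time_ms),
    class = "sensor_params"
  )
}

# 10-90% rise time (ms) of h(t) = exp(-t/tau_d) - exp(-t/tau_r), continuous.
rise_time_diffexp <- function(tau_r, tau_d) {
  t_peak <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  h <- function(t) exp(-t / tau_d) - exp(-t / tau_r)
  hp <- h(t_peak)
  t_at <- function(frac) {
    stats::uniroot(function(t) h(t) - frac * hp, c(1e-12, t_peak), tol = 1e-12)$root
  }
  t_at(0.9) - t_at(0.1)
}

#' Sensor impulse response
#'
#' Evaluates the difference-of-exponentials impulse response on a uniform
#' grid, normalized to unit peak.
#'
#' @param sensor A [sensor_params()].
#' @param dt_s Sample interval, seconds.
#' @param t_max_s Duration of the evaluated response, seconds.
#' @return A tibble with columns `time_s` and `response`.
#' @export
sensor_impulse_response <- function(sensor = sensor_params(), dt_s = 0.001, t_max_s = 5) {
  t <- seq(0, t_max_s, by = dt_s)
  h <- exp(-t / (sensor$tau_decay_ms / 1000)) - exp(-t / (sensor$tau_rise_ms / 1000))
  tibble::tibble(time_s = t, response = h / max(h))
}

#' 10--90% rise time of a response
#'
#' Time between the first crossings of 10% and 90% of the peak on the
#' rising edge, with linear interpolation between samples.
#'
#' @param time_s,y Uniformly sampled response.
#' @return Rise time in the units of `time_s`.
#' @export
rise_time_10_90 <- function(time_s, y) {
  peak <- which.max(y)
  cross <- function(frac) {
    thr <- frac * y[peak]
    i <- which(y[seq_len(peak)] >= thr)[1]
    if (i == 1L) return(time_s[1])
    # linear interpolation between samples i-1 and i
    t0 <- time_s[i - 1L]
    t0 + (thr - y[i - 1L]) / (y[i] - y[i - 1L]) * (time_s[i] - t0)
  }
  cross(0.9) - cross(0.1)
}

#' Convolve a concentration trace with the sensor response
#'
#' Causal convolution with the difference-of-exponentials impulse
#' response. With `normalize = "peak"` the kernel has unit peak (an
#' impulse maps to a unit-peak transient); with `normalize = "area"` the
#' kernel has unit area, so a constant input maps to the same constant
#' (unit steady-state gain).
#'
#' @param x Uniformly sampled input.
#' @param sensor A [sensor_params()].
#' @param dt_s Sample interval of `x`, seconds.
#' @param normalize `"peak"` or `"area"`.
#' @return Numeric vector, same length as `x`.
#' @export
sensor_response <- function(x, sensor = sensor_params(), dt_s = 0.01,
                            normalize = c("peak", "area")) {
  normalize <- match.arg(normalize)
  if (sensor$tau_decay_ms <= sensor$tau_rise_ms) {
    rlang::abort("sensor decay constant must exceed the rise constant")
  }
  t_max <- 8 * sensor$tau_decay_ms / 1000
  t <- seq(0, t_max, by = dt_s)
  h <- exp(-t / (sensor$tau_decay_ms / 1000)) - exp(-t / (sensor$tau_rise_ms / 1000))
  h <- switch(normalize, peak = h / max(h), area = h / sum(h))
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(h))), rev(h), type = "open")
  out[seq_len(n)]
}

# Asymmetric Gaussian bump: unit amplitude, peak at mu (s), distinct
# rise/fall standard deviations (s).
asym_gauss <- function(t, mu, rise_s, fall_s) {
  s <- ifelse(t < mu, rise_s, fall_s)
  exp(-((t - mu)^2) / (2 * s^2))
}

# Single-event composite response on a relative grid (times = offset_i*dt
# .. upward in steps of dt around the event onset). Matches the per-event
# evaluation in dopamine_kernel() exactly on on-grid onsets.
event_template <- function(duration_s, gain, change_s, step_db,
                           kernel, tau_r, tau_d, dt) {
  comps <- list(kernel$onset_positive, kernel$onset_negative,
                kernel$offset_positive, kernel$drop_positive)
  lo <- min(vapply(comps, function(c) (c[["latency_ms"]] - 6 * c[["rise_ms"]]) / 1000,
                   numeric(1)))
  hi <- duration_s + 8 * tau_d +
    (kernel$offset_positive[["latency_ms"]] + 6 * kernel$offset_positive[["fall_ms"]]) / 1000
  i_lo <- as.integer(floor(lo / dt)) - 1L
  i_hi <- as.integer(ceiling(hi / dt)) + 1L
  t <- (i_lo:i_hi) * dt
  relief <- function(dwell) {
    if (kernel$offset_relief_tau_s <= 0) 1 else 1 - exp(-dwell / kernel$offset_relief_tau_s)
  }
  bump <- function(anchor, comp, amp) {
    mu <- anchor + comp[["latency_ms"]] / 1000
    amp * asym_gauss(t, mu, comp[["rise_ms"]] / 1000, comp[["fall_ms"]] / 1000) *
      (t >= mu - 6 * comp[["rise_ms"]] / 1000 & t <= mu + 6 * comp[["fall_ms"]] / 1000)
  }
  v <- bump(0, kernel$onset_positive, kernel$onset_positive[["amplitude_z"]]) +
    bump(0, kernel$onset_negative, gain * kernel$onset_negative[["amplitude_z"]]) +
    bump(duration_s, kernel$offset_positive,
         relief(duration_s) * kernel$offset_positive[["amplitude_z"]])
  if (kernel$intra_dip_z != 0) {
    ref_t <- seq(5, 6, by = 0.001)
    dip_norm <- mean(step_response(ref_t, tau_r, tau_d))
    dip_on <- t > dt / 2 - 1e-12 & t <= duration_s + 8 * tau_d
    box <- step_response(t, tau_r, tau_d) - step_response(t - duration_s, tau_r, tau_d)
    v <- v + gain * kernel$intra_dip_z * (box / dip_norm) * dip_on
  }
  if (!is.na(change_s) && step_db > 0) {
    amp <- kernel$intensity_gain * step_db * relief(change_s)
    v <- v + bump(change_s, kernel$drop_positive, amp)
  }
  list(offset_i = i_lo, values = v)
}

# Analytic step response of the (unnormalized) difference-of-exponentials
# sensor: integral of h from 0 to t.
step_response <- function(t, tau_r, tau_d) {
  t <- pmax(t, 0)
  tau_d * (1 - exp(-t / tau_d)) - tau_r * (1 - exp(-t / tau_r))
}

#' Render the stimulus-locked dopamine response for an event sequence
#'
#' Evaluates the sum of the component kernels for every event on a
#' uniform time grid. Peaks and troughs are asymmetric Gaussians anchored
#' to stimulus onset (onset-positive, onset-negative), stimulus offset
#' (offset-positive) or a mid-stimulus intensity decrement
#' (drop-positive, amplitude `intensity_gain * |level step|`). The
#' intra-stimulus dip is a boxcar over the stimulus convolved
#' (analytically) with the sensor kinetics, scaled so that for the
#' default 6-s stimulus its mean over the final second equals
#' `intra_dip_z`. Value components (onset-negative, dip) are multiplied
#' by `deviant_gain` for deviant-role events.
#'
#' @param events A `stim_seq` or event tibble.
#' @param kernel A [kernel_params()].
#' @param sensor A [sensor_params()] (shapes the dip saturation).
#' @param t_s Time grid (seconds); defaults to a 100-Hz grid covering the
#'   sequence plus a 10-s tail.
#' @param sampling_rate_hz Grid rate when `t_s` is not supplied.
#' @return A tibble with columns `time_s` and `response` (kernel z units).
#' @export
dopamine_kernel <- function(events, kernel = kernel_params(),
                            sensor = sensor_params(),
                            t_s = NULL, sampling_rate_hz = 100) {
  ev <- tibble::as_tibble(events)
  if (is.null(t_s)) {
    t_end <- if (nrow(ev)) max(ev$onset_s + ev$duration_s) + 10 else 10
    t_s <- seq(0, t_end, by = 1 / sampling_rate_hz)
  }
  resp <- numeric(length(t_s))
  if (nrow(ev) == 0L) return(tbl_fast(list(time_s = t_s, response = resp)))
  tau_r <- sensor$tau_rise_ms / 1000
  tau_d <- sensor$tau_decay_ms / 1000
  dt <- t_s[2] - t_s[1]
  t0 <- t_s[1]
  n_t <- length(t_s)
  uniform <- isTRUE(all.equal(diff(range(diff(t_s))), 0, tolerance = 1e-9))
  # fast path: uniform grid with all onsets on the grid -- render one
  # template per unique (duration, gain, change) shape and scatter-add it
  onset_off <- (ev$onset_s - t0) / dt
  if (uniform && all(abs(onset_off - round(onset_off)) < 1e-6)) {
    gain <- ifelse(ev$role == "deviant", kernel$deviant_gain, 1)
    step_db <- ifelse(is.na(ev$change_s), 0,
                      pmax(ev$intensity_db - ev$intensity2_db, 0))
    key <- paste(ev$duration_s, gain, ev$change_s, step_db)
    for (k in unique(key)) {
      i <- which(key == k)[1]
      tmpl <- event_template(ev$duration_s[i], gain[i], ev$change_s[i],
                             step_db[i], kernel, tau_r, tau_d, dt)
      lo_rel <- tmpl$offset_i
      vals <- tmpl$values
      for (j in which(key == k)) {
        i1 <- as.integer(round(onset_off[j])) + 1L + lo_rel
        i2 <- i1 + length(vals) - 1L
        s1 <- max(1L, i1); s2 <- min(n_t, i2)
        if (s1 <= s2) {
          resp[s1:s2] <- resp[s1:s2] + vals[(s1 - i1 + 1L):(s2 - i1 + 1L)]
        }
      }
    }
    return(tbl_fast(list(time_s = t_s, response = resp)))
  }
  idx_in <- function(lo, hi) {
    if (!uniform) return(which(t_s >= lo & t_s <= hi))
    i1 <- max(1L, as.integer(ceiling((lo - t0) / dt - 1e-9)) + 1L)
    i2 <- min(n_t, as.integer(floor((hi - t0) / dt + 1e-9)) + 1L)
    if (i1 > i2) integer(0) else i1:i2
  }
  relief_frac <- function(dwell_s) {
    if (kernel$offset_relief_tau_s <= 0) rep(1, length(dwell_s))
    else 1 - exp(-dwell_s / kernel$offset_relief_tau_s)
  }
  # dip normalization: mean of the saturating boxcar response over the
  # final 1 s of the reference 6-s stimulus
  ref_t <- seq(5, 6, by = 0.001)
  dip_norm <- mean(step_response(ref_t, tau_r, tau_d))
  add_bump <- function(anchor, comp, amp) {
    mu <- anchor + comp[["latency_ms"]] / 1000
    rise <- comp[["rise_ms"]] / 1000
    fall <- comp[["fall_ms"]] / 1000
    idx <- idx_in(mu - 6 * rise, mu + 6 * fall)
    if (length(idx)) {
      resp[idx] <<- resp[idx] + amp * asym_gauss(t_s[idx], mu, rise, fall)
    }
  }
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset_s[i]
    dur <- ev$duration_s[i]
    off <- on + dur
    gain <- if (ev$role[i] == "deviant") kernel$deviant_gain else 1
    add_bump(on, kernel$onset_positive, kernel$onset_positive[["amplitude_z"]])
    add_bump(on, kernel$onset_negative, gain * kernel$onset_negative[["amplitude_z"]])
    add_bump(off, kernel$offset_positive,
             relief_frac(dur) * kernel$offset_positive[["amplitude_z"]])
    # intra-stimulus dip: saturating onset, relaxing after offset
    if (kernel$intra_dip_z != 0) {
      idx <- idx_in(on + dt / 2, off + 8 * tau_d)
      if (length(idx)) {
        box <- step_response(t_s[idx] - on, tau_r, tau_d) -
          step_response(t_s[idx] - off, tau_r, tau_d)
        resp[idx] <- resp[idx] + gain * kernel$intra_dip_z * box / dip_norm
      }
    }
    # drop-positive after a mid-stimulus decrement
    if (!is.na(ev$change_s[i])) {
      step_db <- ev$intensity_db[i] - ev$intensity2_db[i]
      if (step_db > 0) {
        amp <- kernel$intensity_gain * step_db * relief_frac(ev$change_s[i])
        add_bump(on + ev$change_s[i], kernel$drop_positive, amp)
      }
    }
  }
  tbl_fast(list(time_s = t_s, response = resp))
}

#' Noise and acquisition parameters for the recording simulator
#'
#' Baseline fluorescence, double-exponential photobleaching (per channel),
#' white measurement noise, a shared common-mode artifact present
#' identically in both channels, and the mapping from kernel z units to
#' fractional fluorescence.
#'
#' @param sampling_rate_hz Sampling rate (>= 20 Hz).
#' @param f0_excitation,f0_isosbestic Baseline fluorescence (a.u.).
#' @param bleach_frac Length-2 amplitudes of the two bleaching
#'   exponentials, as fractions of baseline (applied to both channels,
#'   with the isosbestic fractions scaled by `bleach_iso_scale`).
#' @param bleach_tau_s Length-2 time constants (s) of the bleaching
#'   exponentials.
#' @param bleach_iso_scale Multiplier on the isosbestic bleaching
#'   fractions (slight channel mismatch leaves a realistic slow residual
#'   in delta-F/F).
#' @param white_sd_frac White-noise standard deviation per channel, as a
#'   fraction of that channel's baseline.
#' @param artifact_sd Standard deviation (a.u.) of the shared artifact.
#' @param artifact_tau_s Correlation time (s) of the shared artifact
#'   (Ornstein-Uhlenbeck process).
#' @param dff_scale Fractional fluorescence per kernel z unit.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(sampling_rate_hz = 100,
                         f0_excitation = 100, f0_isosbestic = 50,
                         bleach_frac = c(0.10, 0.20),
                         bleach_tau_s = c(60, 600),
                         bleach_iso_scale = 1.1,
                         white_sd_frac = 0.0015,
                         artifact_sd = 0.3,
                         artifact_tau_s = 2,
                         dff_scale = 0.05) {
  stopifnot(sampling_rate_hz >= 20, all(bleach_tau_s > 0), white_sd_frac >= 0,
            artifact_sd >= 0, artifact_tau_s > 0, dff_scale > 0)
  structure(
    list(
      sampling_rate_hz = sampling_rate_hz,
      f0_excitation = f0_excitation, f0_isosbestic = f0_isosbestic,
      bleach_frac = bleach_frac, bleach_tau_s = bleach_tau_s,
      bleach_iso_scale = bleach_iso_scale,
      white_sd_frac = white_sd_frac,
      artifact_sd = artifact_sd, artifact_tau_s = artifact_tau_s,
      dff_scale = dff_scale
    ),
    class = "noise_params"
  )
}

# Ornstein-Uhlenbeck sample path, stationary sd `sd`, correlation time tau.
ou_process <- function(n, dt, sd, tau) {
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, sd = sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

bleach_curve <- function(t, f0, frac, tau) {
  base <- 1 - sum(frac)
  f0 * (base + frac[1] * exp(-t / tau[1]) + frac[2] * exp(-t / tau[2]))
}

#' Simulate a two-channel photometry recording
#'
#' Renders the stimulus-locked dopamine response of `events` (see
#' [dopamine_kernel()]) into an excitation channel, with per-channel
#' photobleaching, a shared common-mode artifact, and white noise:
#' `excitation = bleach_exc(t) * (1 + dff_scale * response) + artifact + noise`,
#' `isosbestic = bleach_iso(t) + artifact + noise`.
#' The per-event ground truth (component amplitudes after gains, nominal
#' latencies) is attached for parameter-recovery tests.
#'
#' @param events A `stim_seq` or event tibble.
#' @param kernel,sensor,noise Parameter objects.
#' @param duration_s Recording length (s); defaults to the last offset
#'   plus 10 s.
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return A `photometry_rec`: tibble with columns `time_s`,
#'   `excitation`, `isosbestic`, carrying attributes `sampling_rate_hz`,
#'   `events`, `truth` (per-event component table) and `noise`.
#' @export
simulate_recording <- function(events, kernel = kernel_params(),
                               sensor = sensor_params(),
                               noise = noise_params(),
                               duration_s = NULL, seed = NULL) {
  ev <- tibble::as_tibble(events)
  sr <- noise$sampling_rate_hz
  if (is.null(duration_s)) {
    duration_s <- (if (nrow(ev)) max(ev$onset_s + ev$duration_s) else 0) + 10
  }
  t <- seq(0, duration_s, by = 1 / sr)
  if (nrow(ev) && max(ev$onset_s + ev$duration_s) > duration_s) {
    rlang::abort("event sequence does not fit within the recording duration")
  }
  resp <- dopamine_kernel(ev, kernel, sensor, t_s = t)$response
  n <- length(t)
  channels <- with_seed(seed, {
    artifact <- ou_process(n, 1 / sr, noise$artifact_sd, noise$artifact_tau_s)
    b_exc <- bleach_curve(t, noise$f0_excitation, noise$bleach_frac, noise$bleach_tau_s)
    b_iso <- bleach_curve(t, noise$f0_isosbestic,
                          noise$bleach_frac * noise$bleach_iso_scale, noise$bleach_tau_s)
    exc <- b_exc * (1 + noise$dff_scale * resp) + artifact +
      stats::rnorm(n, sd = noise$white_sd_frac * noise$f0_excitation)
    iso <- b_iso + artifact +
      stats::rnorm(n, sd = noise$white_sd_frac * noise$f0_isosbestic)
    list(exc = exc, iso = iso)
  })
  gain <- ifelse(ev$role == "deviant", kernel$deviant_gain, 1)
  relief <- if (kernel$offset_relief_tau_s <= 0) rep(1, nrow(ev)) else 1 - exp(-ev$duration_s / kernel$offset_relief_tau_s)
  nev <- nrow(ev)
  truth <- tbl_fast(list(
    trial_index = ev$trial_index, role = ev$role,
    onset_positive_z = rep(kernel$onset_positive[["amplitude_z"]], nev),
    onset_positive_ms = rep(kernel$onset_positive[["latency_ms"]], nev),
    onset_negative_z = gain * kernel$onset_negative[["amplitude_z"]],
    onset_negative_ms = rep(kernel$onset_negative[["latency_ms"]], nev),
    offset_positive_z = relief * kernel$offset_positive[["amplitude_z"]],
    offset_positive_ms = rep(kernel$offset_positive[["latency_ms"]], nev),
    intra_dip_z = gain * kernel$intra_dip_z,
    drop_positive_z = ifelse(
      !is.na(ev$change_s) & ev$intensity_db > ev$intensity2_db,
      kernel$intensity_gain * (ev$intensity_db - ev$intensity2_db), NA_real_)
  ))
  structure(
    tbl_fast(list(time_s = t, excitation = channels$exc, isosbestic = channels$iso)),
    class = c("photometry_rec", class(tibble::tibble())),
    sampling_rate_hz = sr, events = events, truth = truth, noise = noise
  )
}

#' Behavioral simulation parameters
#'
#' Conditions with attraction weights for the place-preference simulator.
#' Fields are split evenly among the conditions (so `n_fields` must be a
#' multiple of the number of conditions), the field-condition mapping is
#' reshuffled every session, and each session is a 20-s sound
#' presentation followed by a 5-s interval.
#'
#' @param weights Named non-negative attraction weights, one per condition.
#' @param n_fields Number of virtual fields (default 8).
#' @param session_s,interval_s Session and inter-session interval lengths (s).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(weights = c(silence = 1, noise = 1),
                            n_fields = 8, session_s = 20, interval_s = 5) {
  stopifnot(all(weights >= 0), length(weights) >= 2, n_fields >= length(weights),
            n_fields %% length(weights) == 0)
  if (is.null(names(weights))) names(weights) <- paste0("cond", seq_along(weights))
  structure(
    list(weights = weights, n_fields = as.integer(n_fields),
         session_s = session_s, interval_s = interval_s),
    class = "behavior_params"
  )
}

#' Simulate place-preference sessions
#'
#' For each session the field-condition mapping is shuffled (each
#' condition covering `n_fields / n_conditions` fields), the start field
#' is uniform, and the goal field is drawn with probability proportional
#' to the attraction weight of the condition mapped to each field. Equal
#' weights give an unbiased walker whose Preference Index is 0 in
#' expectation.
#'
#' @param params A [behavior_params()].
#' @param n_sessions Number of sessions.
#' @param seed Integer seed (or `NULL`).
#' @return A tibble with columns `session`, `start_field`, `goal_field`,
#'   `start_condition`, `goal_condition` (fields are 0-based indices, as
#'   in the assay's field labels 0-7).
#' @export
simulate_place_sessions <- function(params = behavior_params(), n_sessions = 100,
                                    seed = NULL) {
  k <- length(params$weights)
  per <- params$n_fields / k
  conds <- names(params$weights)
  with_seed(seed, {
    out <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      mapping <- sample(rep(conds, per))          # condition of field 1..n
      w <- params$weights[mapping]
      start <- sample.int(params$n_fields, 1)
      goal <- sample.int(params$n_fields, 1, prob = w)
      out[[s]] <- tibble::tibble(
        session = s,
        start_field = start - 1L, goal_field = goal - 1L,
        start_condition = mapping[start], goal_condition = mapping[goal]
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a free-moving trajectory in the assay arena
#'
#' A reflected random walk in a square arena with a central square pillar
#' that the trajectory cannot enter; intended for occupancy-heatmap
#' demonstrations, not as a model of rat locomotion.
#'
#' @param n_steps Number of samples.
#' @param dt_s Sample interval, s.
#' @param arena_cm Side length of the square arena.
#' @param pillar_cm Side length of the central pillar.
#' @param step_sd_cm Per-step displacement standard deviation.
#' @param seed Integer seed (or `NULL`).
#' @return A tibble with columns `time_s`, `x_cm`, `y_cm`.
#' @export
simulate_trajectory <- function(n_steps = 2000, dt_s = 0.1, arena_cm = 35,
                                pillar_cm = 7, step_sd_cm = 1.5, seed = NULL) {
  half <- arena_cm / 2
  phalf <- pillar_cm / 2
  with_seed(seed, {
    x <- numeric(n_steps); y <- numeric(n_steps)
    x[1] <- -half / 2; y[1] <- 0
    for (i in 2:n_steps) {
      repeat {
        nx <- x[i - 1] + stats::rnorm(1, sd = step_sd_cm)
        ny <- y[i - 1] + stats::rnorm(1, sd = step_sd_cm)
        nx <- pmin(pmax(nx, -half), half)
        ny <- pmin(pmax(ny, -half), half)
        if (!(abs(nx) < phalf && abs(ny) < phalf)) break
      }
      x[i] <- nx; y[i] <- ny
    }
    tibble::tibble(time_s = (seq_len(n_steps) - 1) * dt_s, x_cm = x, y_cm = y)
  })
}
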