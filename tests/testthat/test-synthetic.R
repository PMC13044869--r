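test_that("dopamine kernel anchors its components where specified", {
  ev <- stim_simple(n_events = 1)
  # zero-amplitude kernel gives an identically zero trace
  k0 <- kernel_params(
    onset_positive = c(latency_ms = 96, amplitude_z = 0, rise_ms = 35, fall_ms = 50),
    onset_negative = c(latency_ms = 602, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    offset_positive = c(latency_ms = 549, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    intra_dip_z = 0, intensity_gain = 0
  )
  expect_equal(dopamine_kernel(ev, k0, sampling_rate_hz = 200)$response,
               rep(0, 3201))

  # default kernel: early maximum lands at the onset-positive latency
  tr <- dopamine_kernel(ev, sampling_rate_hz = 1000)
  early <- tr[tr$time_s > 0 & tr$time_s <= 0.3, ]
  expect_lt(abs(early$time_s[which.max(early$response)] * 1000 - 96), 10)
  # trough near the onset-negative latency
  upto <- tr[tr$time_s > 0 & tr$time_s <= 0.8, ]
  expect_lt(abs(upto$time_s[which.min(upto$response)] * 1000 - 602), 10)
})

test_that("drop-positive amplitude follows the linear intensity-gain law", {
  # isolate the drop component, then the 80->60 vs 80->20 ratio is 20/60
  k <- kernel_params(
    onset_positive = c(latency_ms = 96, amplitude_z = 0, rise_ms = 35, fall_ms = 50),
    onset_negative = c(latency_ms = 602, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    offset_positive = c(latency_ms = 549, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    intra_dip_z = 0
  )
  mk_ev <- function(second) {
    ev <- stim_simple(n_events = 1)
    ev$intensity2_db <- second
    ev$change_s <- 3
    ev
  }
  peak <- function(second) max(dopamine_kernel(mk_ev(second), k,
                                               sampling_rate_hz = 1000)$response)
  expect_equal(peak(60) / peak(20), 20 / 60, tolerance = 1e-12)
  # upward steps produce no drop component
  expect_equal(peak(80), 0)
})

test_that("sensor impulse response has the configured 10-90% rise time", {
  ir <- sensor_impulse_response(dt_s = 0.001)
  expect_equal(rise_time_10_90(ir$time_s, ir$response) * 1000, 70, tolerance = 0.01)
  # a different target is honored too
  ir2 <- sensor_impulse_response(sensor_params(rise_time_ms = 40), dt_s = 0.001)
  expect_equal(rise_time_10_90(ir2$time_s, ir2$response) * 1000, 40, tolerance = 0.01)
  expect_error(sensor_params(rise_time_ms = 500, decay_ms = 100), "too small")
})

test_that("sensor convolution is linear and gain-preserving under area normalization", {
  sp <- sensor_params()
  x1 <- c(1, rep(0, 399))
  x2 <- c(rep(0, 100), 1, rep(0, 299))
  y1 <- sensor_response(x1, sp)
  y2 <- sensor_response(x2, sp)
  y12 <- sensor_response(x1 + x2, sp)
  expect_equal(y12, y1 + y2, tolerance = 1e-12)
  # impulse maps to a unit-peak transient under peak normalization
  expect_equal(max(y1), 1, tolerance = 1e-9)
  # constant input -> same constant under area normalization (LTI steady state)
  const <- rep(2, 3000)
  out <- sensor_response(const, sp, normalize = "area")
  expect_equal(out[3000], 2, tolerance = 1e-6)
})

test_that("recordings are deterministic and clean in the no-signal limit", {
  ev <- simple_events(3)
  k0 <- kernel_params(
    onset_positive = c(latency_ms = 96, amplitude_z = 0, rise_ms = 35, fall_ms = 50),
    onset_negative = c(latency_ms = 602, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    offset_positive = c(latency_ms = 549, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    intra_dip_z = 0, intensity_gain = 0
  )
  rec <- simulate_recording(ev, kernel = k0, noise = noise_free(), seed = 1)
  dff <- compute_dff(rec$excitation,
                     fit_isosbestic(rec$excitation, rec$isosbestic)$fitted)
  expect_lt(max(abs(dff)), 1e-12)

  a <- simulate_recording(ev, seed = 42)
  b <- simulate_recording(ev, seed = 42)
  expect_identical(a$excitation, b$excitation)
  expect_identical(a$isosbestic, b$isosbestic)
  expect_false(identical(a$excitation, simulate_recording(ev, seed = 43)$excitation))

  expect_error(simulate_recording(ev, duration_s = 5), "does not fit")
})

test_that("noise-free simulation recovers the injected onset-positive latency", {
  ev <- simple_events(5)
  ep <- quiet_epochs(ev, seed = 3)
  f <- component_features(ep)
  expect_true(all(abs(f$onset_positive_ms - 96) <= 10))
})

test_that("a common-mode artifact is strongly attenuated by the isosbestic reference", {
  ev <- simple_events(3)
  k0 <- kernel_params(
    onset_positive = c(latency_ms = 96, amplitude_z = 0, rise_ms = 35, fall_ms = 50),
    onset_negative = c(latency_ms = 602, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    offset_positive = c(latency_ms = 549, amplitude_z = 0, rise_ms = 100, fall_ms = 120),
    intra_dip_z = 0, intensity_gain = 0
  )
  nz <- noise_params(bleach_frac = c(0, 0), white_sd_frac = 1e-5,
                     artifact_sd = 5, artifact_tau_s = 2)
  rec <- simulate_recording(ev, kernel = k0, noise = nz, seed = 8)
  dff_iso <- compute_dff(rec$excitation,
                         fit_isosbestic(rec$excitation, rec$isosbestic)$fitted)
  dff_single <- (rec$excitation - mean(rec$excitation)) / mean(rec$excitation)
  expect_gt(stats::sd(dff_single) / stats::sd(dff_iso), 10)
})

test_that("component parameters are recovered across subjects at default noise", {
  n_subj <- 20
  lat_err <- matrix(NA_real_, n_subj, 3)
  amp_err <- matrix(NA_real_, n_subj, 3)
  ev <- simple_events(10)
  # noise-free reference epoch (the realized composite ground truth)
  ref <- colMeans(epoch_matrix(quiet_epochs(ev, seed = 1)))
  t_rel <- attr(epoch_matrix(quiet_epochs(ev, seed = 1)), "t_rel_s")
  ref_f <- component_features(
    tibble::tibble(trial_index = 1L, role = "plain", t_rel_s = t_rel, z = ref),
    stimulus_duration_s = 6)
  for (s in seq_len(n_subj)) {
    rec <- simulate_recording(ev, seed = 1000 + s)
    ztr <- normalize_z(correct_isosbestic(rec))
    m <- epoch_matrix(suppressMessages(extract_epochs(ztr, ev)))
    avg <- colMeans(m)
    # extract from the subject's trial-averaged epoch, rescaled to the
    # noise-free reference amplitude scale via the known simulation gain
    f <- component_features(
      tibble::tibble(trial_index = 1L, role = "plain",
                     t_rel_s = attr(m, "t_rel_s"), z = avg),
      stimulus_duration_s = 6)
    lat_err[s, ] <- abs(c(f$onset_positive_ms - 96, f$onset_negative_ms - 602,
                          f$offset_positive_ms - 549))
    amp_err[s, ] <- abs(c(
      f$onset_positive_z - ref_f$onset_positive_z,
      f$onset_negative_z - ref_f$onset_negative_z,
      f$offset_positive_z - ref_f$offset_positive_z
    ) / c(ref_f$onset_positive_z, ref_f$onset_negative_z, ref_f$offset_positive_z))
  }
  # latency: median error below 2 samples at 100 Hz
  expect_true(all(apply(lat_err, 2, stats::median) < 20))
  # amplitude: median relative error below 10%
  expect_true(all(apply(amp_err, 2, stats::median) < 0.10))
})

test_that("extracted drop-positive amplitude is monotone in the programmed step", {
  ev <- stim_change("dynamic", second_db = c(60, 40, 20), n_reps = 2, seed = 3)
  ev$onset_s <- ev$onset_s + 3
  ep <- quiet_epochs(ev, seed = 5)
  d <- drop_positive(ep)
  steps <- ev$intensity_db[match(d$trial_index, ev$trial_index)] -
    ev$intensity2_db[match(d$trial_index, ev$trial_index)]
  agg <- tapply(d$drop_positive_z, steps, mean)
  expect_equal(stats::cor(as.numeric(names(agg)), agg, method = "spearman"), 1)
})

test_that("place-session simulation matches closed-form preferences", {
  # equal weights: no preference
  s <- simulate_place_sessions(behavior_params(), 4000, seed = 2)
  expect_lt(abs(preference_index(s, "noise")$pi), 0.05)

  # two conditions with weights (1, 3): PI for the heavy condition is
  # (3 - 1) / (3 + 1) = 0.5 (goal is weight-proportional and start-free)
  p <- behavior_params(weights = c(light = 1, heavy = 3))
  s2 <- simulate_place_sessions(p, 20000, seed = 3)
  expect_equal(preference_index(s2, "heavy")$pi, 0.5, tolerance = 0.03)

  # zero-weight condition is never the goal, so its PI cannot be positive
  p0 <- behavior_params(weights = c(x = 0, a = 1, b = 1, c = 1))
  s3 <- simulate_place_sessions(p0, 2000, seed = 4)
  expect_true(all(s3$goal_condition != "x"))
  expect_lte(preference_index(s3, "x")$pi, 0)

  # mapping reshuffles: both conditions visit every field
  expect_gt(length(unique(s$start_field)), 4)
})

test_that("simulated trajectories respect the arena and pillar bounds", {
  tr <- simulate_trajectory(n_steps = 500, seed = 1)
  expect_true(all(abs(tr$x_cm) <= 17.5 + 1e-9))
  expect_true(all(abs(tr$y_cm) <= 17.5 + 1e-9))
  expect_false(any(abs(tr$x_cm) < 3.5 & abs(tr$y_cm) < 3.5))
})
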