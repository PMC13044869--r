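mk_epoch <- function(z, sr = 100, window = c(-2, 8), role = "plain") {
  t_rel <- seq(window[1], window[2], by = 1 / sr)
  stopifnot(length(z) == length(t_rel))
  tibble::tibble(trial_index = 1L, role = role, t_rel_s = t_rel, z = z)
}

test_that("component features find constructed extrema and handle flat input", {
  sr <- 100
  t_rel <- seq(-2, 8, by = 1 / sr)
  z <- numeric(length(t_rel))
  z[abs(t_rel - 0.15) < 1e-9] <- 1.0           # onset-positive at 150 ms
  z[abs(t_rel - 0.5) < 1e-9] <- -0.8           # onset-negative at 500 ms
  z[abs(t_rel - 6.4) < 1e-9] <- 0.6            # offset-positive at 400 ms post-offset
  f <- component_features(mk_epoch(z), stimulus_duration_s = 6)
  expect_equal(f$onset_positive_z, 1.0)
  expect_equal(f$onset_positive_ms, 150)
  expect_equal(f$onset_negative_z, -0.8)
  expect_equal(f$onset_negative_ms, 500)
  expect_equal(f$offset_positive_z, 0.6)
  expect_equal(f$offset_positive_ms, 400)
  expect_equal(f$rel_onset_negative_z, -1.8)
  expect_equal(f$baseline_at_onset_z, 0)

  flat <- component_features(mk_epoch(numeric(length(t_rel))),
                             stimulus_duration_s = 6)
  expect_equal(flat$onset_positive_z, 0)
  expect_equal(flat$intra_dip_z, 0)
  # ties broken by the earliest sample
  expect_equal(flat$onset_positive_ms, 10)

  short <- mk_epoch(rnorm(301), window = c(-2, 1))
  expect_error(component_features(short, stimulus_duration_s = 6),
               "offset-positive")
})

test_that("windows are half-open and latencies stay inside them under fuzzing", {
  set.seed(99)
  for (i in 1:50) {
    z <- rnorm(1001)
    f <- component_features(mk_epoch(z), stimulus_duration_s = 6)
    expect_gt(f$onset_positive_ms, 0); expect_lte(f$onset_positive_ms, 300)
    expect_gt(f$onset_negative_ms, 0); expect_lte(f$onset_negative_ms, 800)
    expect_gt(f$offset_positive_ms, 0); expect_lte(f$offset_positive_ms, 800)
    d <- drop_positive(mk_epoch(z), change_s = 3)
    expect_gt(d$drop_positive_ms, 0); expect_lte(d$drop_positive_ms, 800)
  }
})

test_that("the full-pipeline latencies match the injected kernel parameters", {
  ep <- quiet_epochs(simple_events(5), seed = 2)
  f <- component_features(ep)
  expect_true(all(abs(f$onset_positive_ms - 96) <= 10))
  expect_true(all(abs(f$onset_negative_ms - 602) <= 10))
  expect_true(all(abs(f$offset_positive_ms - 549) <= 10))
  # the intra-stimulus dip mean is negative, the relief peak positive
  expect_true(all(f$intra_dip_z < 0))
  expect_true(all(f$offset_positive_z > 0))
})

test_that("drop-positive quantification tracks the intensity step", {
  sr <- 100
  t_rel <- seq(-2, 8, by = 1 / sr)
  z <- numeric(length(t_rel))
  z[abs(t_rel - 3.4) < 1e-9] <- 0.9            # constructed bump 400 ms after the change
  d <- drop_positive(mk_epoch(z), change_s = 3)
  expect_equal(d$drop_positive_z, 0.9)
  expect_equal(d$drop_positive_ms, 400)

  ev <- stim_change("dynamic", second_db = c(60, 20), n_reps = 1, seed = 1)
  ev$onset_s <- ev$onset_s + 3
  ep <- quiet_epochs(ev, seed = 1)
  d2 <- drop_positive(ep)
  amp60 <- d2$drop_positive_z[match(ev$trial_index[ev$intensity2_db == 60],
                                    d2$trial_index)]
  amp20 <- d2$drop_positive_z[match(ev$trial_index[ev$intensity2_db == 20],
                                    d2$trial_index)]
  expect_gt(amp20, amp60)

  # no-change control carries no drop component: its window maximum stays
  # at the dip level, well below any true step response
  ev0 <- stim_change("dynamic", second_db = c(80, 20), n_reps = 1, seed = 2)
  ev0$onset_s <- ev0$onset_s + 3
  d0 <- drop_positive(quiet_epochs(ev0, seed = 1))
  amp_none <- d0$drop_positive_z[match(ev0$trial_index[ev0$intensity2_db == 80],
                                       d0$trial_index)]
  expect_lt(amp_none, 0)
  expect_error(drop_positive(mk_epoch(rnorm(401), window = c(-2, 2)),
                             change_s = 3), "window")
})

test_that("peak-to-trough is a span and is invariant to sign flips", {
  sr <- 100
  t_rel <- seq(0, 0.8 - 1 / sr, by = 1 / sr)
  flat <- tibble::tibble(trial_index = 1L, role = "plain", t_rel_s = t_rel,
                         z = numeric(length(t_rel)))
  expect_equal(peak_to_trough(flat, 0.8)$peak_to_trough_z, 0)

  sine <- flat; sine$z <- sin(2 * pi * t_rel / 0.8)
  expect_equal(peak_to_trough(sine, 0.8)$peak_to_trough_z, 2, tolerance = 1e-3)

  neg <- sine; neg$z <- -neg$z
  expect_equal(peak_to_trough(neg, 0.8)$peak_to_trough_z,
               peak_to_trough(sine, 0.8)$peak_to_trough_z)
})

test_that("a deviant gain above one raises the deviant peak-to-trough", {
  cfg <- experiment_config(n_subjects = 3, seed = 21, oddball = small_oddball(),
                           kernel = kernel_params(deviant_gain = 1.5),
                           compute_bf = FALSE, include_ms = FALSE)
  ex <- suppressMessages(run_oddball_experiment(cfg))
  expect_true(all(ex$contrasts$dev > ex$contrasts$std))
})

test_that("the onset/offset ratio is clamped, bounded and errs when undefined", {
  expect_equal(onset_offset_ratio(0.5, 0.5), 0.5)
  expect_equal(onset_offset_ratio(0.7, 0), 1.0)
  expect_equal(onset_offset_ratio(0.224, 0.744), 0.224 / (0.224 + 0.744),
               tolerance = 1e-12)
  expect_equal(onset_offset_ratio(0.224, 0.744), 0.2314050, tolerance = 1e-6)
  # negative (noisy) inputs are clamped to keep the ratio in [0, 1]
  expect_equal(onset_offset_ratio(-0.2, 0.5), 0)
  expect_error(onset_offset_ratio(0, 0), "undefined")
  expect_error(onset_offset_ratio(-0.1, -0.2), "undefined")
})

test_that("site projection matches the vector-algebra oracle", {
  expect_equal(project_site(0, 8), 0)
  expect_equal(project_site(8, 1.5), sqrt(8^2 + 6.5^2), tolerance = 1e-12)
  # independent dot-product computation for an interior point
  v <- c(8, 1.5 - 8); u <- v / sqrt(sum(v^2))
  expect_equal(project_site(1.2, 7), sum(c(1.2 - 0, 7 - 8) * u), tolerance = 1e-12)
  # vectorized
  expect_equal(project_site(c(0, 8), c(8, 1.5)), c(0, sqrt(8^2 + 6.5^2)))
})

test_that("trial stability contrasts first and last trials correctly", {
  f <- component_features(quiet_epochs(simple_events(6), seed = 3))
  st <- trial_stability(f)
  expect_setequal(st$component,
                  c("onset_positive", "onset_negative", "intra_dip", "offset_positive"))
  # literally identical trials: first and last means agree exactly
  fid <- f[rep(1, 4), ]
  fid$trial_index <- 1:4
  stid <- trial_stability(fid)
  expect_equal(stid$first_mean, stid$last_mean)

  # linear drift: difference equals slope x trial gap
  n <- 10; slope <- 0.2
  fd <- f[rep(1, n), ]
  fd$trial_index <- 1:n
  fd$onset_positive_z <- 1 + slope * (1:n)
  std <- trial_stability(fd)
  got <- std$last_mean[std$component == "onset_positive"] -
    std$first_mean[std$component == "onset_positive"]
  expect_equal(got, slope * (n - 2))

  expect_error(trial_stability(f[1:3, ]), "at least 4")
})

test_that("stationary trials rarely flag spurious habituation", {
  set.seed(5)
  n_rep <- 200; n_subj <- 37
  nonsig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    first <- matrix(rnorm(n_subj * 2, 0.7, 0.2), n_subj)
    last <- matrix(rnorm(n_subj * 2, 0.7, 0.2), n_subj)
    w <- wilcoxon_signed_rank(rowMeans(first), rowMeans(last),
                              exact_threshold = 0L)
    nonsig[r] <- w$p_value >= 0.05
  }
  expect_gte(mean(nonsig), 0.9)
})

test_that("long-format features mirror the wide table", {
  f <- component_features(quiet_epochs(simple_events(3), seed = 1))
  long <- features_long(f)
  expect_equal(nrow(long), 3 * 4)
  got <- long$amplitude_z[long$component == "onset_negative" & long$trial_index == 2]
  expect_equal(got, f$onset_negative_z[f$trial_index == 2])
  expect_true(all(is.na(long$latency_ms[long$component == "intra_dip"])))
})
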