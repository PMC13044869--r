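# End-to-end orchestration: simulate -> preprocess -> features -> stats.

#' Experiment configuration
#'
#' Bundles the paradigm, simulation and analysis settings for the
#' end-to-end runners. Defaults mirror the study design: a cohort of 21
#' subjects, the full oddball specification (10% deviants, runs of at
#' least 4 standards, 300 deviants per block with a role swap, 150-ms
#' stimuli at an 800-ms SOA), an equally long many-standards control, the
#' 3-back analysis standard, and +/- 3.2-s local z windows anchored at
#' each deviant onset.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed; per-subject seeds derive from it.
#' @param oddball An [oddball_spec()].
#' @param ms_n_events Events in the many-standards sequence (defaults to
#'   the oddball sequence length).
#' @param kernel,sensor,noise Simulation parameters; `ms_deviant_gain`
#'   is the gain applied to the deviant-equivalent in the many-standards
#'   sequence (default 1: rarity alone adds nothing).
#' @param ms_deviant_gain Gain for the many-standards deviant-equivalent.
#' @param pair_offset Trials back to the analysis standard (default 3).
#' @param z_half_width_s Local z window half-width (s), default 3.2.
#' @param compute_bf Also compute Bayes factors in contrast tests.
#' @param include_ms Simulate the many-standards arm (default `TRUE`);
#'   disable for runs that only need the within-oddball contrast.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 21, seed = 1L,
                              oddball = oddball_spec(),
                              ms_n_events = NULL,
                              kernel = kernel_params(),
                              sensor = sensor_params(),
                              noise = noise_params(),
                              ms_deviant_gain = 1,
                              pair_offset = 3L,
                              z_half_width_s = 3.2,
                              compute_bf = TRUE,
                              include_ms = TRUE) {
  stopifnot(n_subjects >= 2, inherits(oddball, "oddball_spec"))
  n_ob <- oddball$n_blocks * round(oddball$n_deviants_per_block / oddball$deviant_prob)
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      oddball = oddball,
      ms_n_events = as.integer(ms_n_events %||% n_ob),
      kernel = kernel, sensor = sensor, noise = noise,
      ms_deviant_gain = ms_deviant_gain,
      pair_offset = as.integer(pair_offset),
      z_half_width_s = z_half_width_s,
      compute_bf = isTRUE(compute_bf),
      include_ms = isTRUE(include_ms)
    ),
    class = "experiment_config"
  )
}

subject_seeds <- function(config) {
  with_seed(config$seed, sample.int(.Machine$integer.max - 1L, config$n_subjects))
}

# Vectorized local-window peak-to-trough: for each reference onset,
# z-score the +/- half-width window around it and take max - min over
# [target_onset, target_onset + soa). Returns one value per reference
# (NA where the window does not fit).
local_p2t <- function(dff, sr, ref_onsets_s, target_onsets_s, soa_s, half_width_s) {
  n <- length(dff)
  hw <- round(half_width_s * sr)
  win_len <- 2L * hw + 1L
  ref_i <- round(ref_onsets_s * sr) + 1L
  ok <- ref_i - hw >= 1L & ref_i + hw <= n
  out <- rep(NA_real_, length(ref_i))
  if (!any(ok)) return(out)
  starts <- ref_i[ok] - hw
  idx <- outer(starts, seq_len(win_len) - 1L, `+`)
  w <- matrix(dff[idx], nrow = length(starts))
  mu <- rowMeans(w)
  sdv <- sqrt(rowSums((w - mu)^2) / (win_len - 1L))
  z <- (w - mu) / sdv
  # target slice, relative to window start
  off <- round((target_onsets_s[ok] - ref_onsets_s[ok]) * sr) + hw + 1L
  len <- round(soa_s * sr)
  p2t <- vapply(seq_along(starts), function(k) {
    sl <- z[k, off[k]:(off[k] + len - 1L)]
    max(sl) - min(sl)
  }, numeric(1))
  out[ok] <- p2t
  out
}

simulate_subject_contrast <- function(config, seed) {
  soa <- config$oddball$soa_s
  hw <- config$z_half_width_s
  sr <- config$noise$sampling_rate_hz
  pad <- hw + 1
  # --- oddball session ---
  ob <- stim_oddball(config$oddball, seed = seed)
  ob_shift <- ob
  ob_shift$onset_s <- ob_shift$onset_s + pad
  rec <- simulate_recording(ob_shift, config$kernel, config$sensor, config$noise,
                            duration_s = max(ob_shift$onset_s) + soa + pad,
                            seed = seed + 1L)
  dff <- compute_dff(rec$excitation,
                     fit_isosbestic(rec$excitation, rec$isosbestic)$fitted)
  pairs <- analysis_standards(ob, offset_trials = config$pair_offset)
  dev_on <- ob_shift$onset_s[pairs$deviant_index]
  std_on <- ob_shift$onset_s[pairs$standard_index]
  dev_p2t <- local_p2t(dff, sr, dev_on, dev_on, soa, hw)
  std_p2t <- local_p2t(dff, sr, dev_on, std_on, soa, hw)
  if (!config$include_ms) {
    return(c(dev = mean(dev_p2t, na.rm = TRUE),
             std = mean(std_p2t, na.rm = TRUE), ms = NA_real_))
  }
  # --- many-standards session ---
  ms_kernel <- config$kernel
  ms_kernel$deviant_gain <- config$ms_deviant_gain
  ms <- stim_many_standards(
    n_events = config$ms_n_events,
    stimulus_duration_s = config$oddball$stimulus_duration_s,
    soa_s = soa, seed = seed + 2L
  )
  # render the deviant-equivalent with the configured gain by relabeling
  ms_render <- ms
  ms_render$role[ms$role == "deviant_equivalent"] <- "deviant"
  ms_render$onset_s <- ms_render$onset_s + pad
  rec_ms <- simulate_recording(ms_render, ms_kernel, config$sensor, config$noise,
                               duration_s = max(ms_render$onset_s) + soa + pad,
                               seed = seed + 3L)
  dff_ms <- compute_dff(rec_ms$excitation,
                        fit_isosbestic(rec_ms$excitation, rec_ms$isosbestic)$fitted)
  de_idx <- which(ms$role == "deviant_equivalent")
  de_idx <- de_idx[de_idx > config$pair_offset]
  de_on <- ms_render$onset_s[de_idx]
  ms_p2t <- local_p2t(dff_ms, sr, de_on, de_on, soa, hw)
  c(dev = mean(dev_p2t, na.rm = TRUE),
    std = mean(std_p2t, na.rm = TRUE),
    ms = mean(ms_p2t, na.rm = TRUE))
}

#' Run the oddball versus many-standards experiment on a synthetic cohort
#'
#' For each synthetic subject: generate an oddball and a many-standards
#' sequence, render two-channel recordings, correct against the
#' isosbestic channel, z-score locally in +/- 3.2-s windows around each
#' deviant (or deviant-equivalent) onset, pair deviants with their
#' 3-back analysis standards, and average the peak-to-trough amplitude
#' within the SOA window per role. The cohort is then tested with the
#' Wilcoxon signed-rank test (and, optionally, the JZS Bayes factor) on
#' the contrasts deviant vs standard, deviant vs deviant-equivalent, and
#' standard vs deviant-equivalent.
#'
#' @param config An [experiment_config()].
#' @return A list of class `da_experiment` with elements `contrasts`
#'   (tibble: subject, dev, std, ms) and `tests` (tidy tibble of the
#'   three paired contrasts).
#' @export
run_oddball_experiment <- function(config = experiment_config()) {
  seeds <- subject_seeds(config)
  rows <- matrix(NA_real_, config$n_subjects, 3,
                 dimnames = list(NULL, c("dev", "std", "ms")))
  for (s in seq_len(config$n_subjects)) {
    rows[s, ] <- simulate_subject_contrast(config, seeds[s])
  }
  contrasts <- tibble::tibble(subject = seq_len(config$n_subjects),
                              dev = rows[, "dev"], std = rows[, "std"],
                              ms = rows[, "ms"])
  pairs <- list(c("dev", "std"), c("dev", "ms"), c("std", "ms"))
  if (!config$include_ms) pairs <- pairs[1]
  tests <- dplyr::bind_rows(lapply(pairs, function(p) {
    w <- wilcoxon_signed_rank(contrasts[[p[1]]], contrasts[[p[2]]])
    bf <- if (config$compute_bf) {
      bayes_paired_t(contrasts[[p[1]]], contrasts[[p[2]]])$bf10
    } else NA_real_
    tibble::tibble(contrast = paste(p, collapse = " vs "),
                   statistic = w$statistic, p_value = w$p_value,
                   bf10 = bf, n = w$n, method = w$method)
  }))
  structure(list(contrasts = contrasts, tests = tests, config = config),
            class = "da_experiment")
}

#' @export
print.da_experiment <- function(x, ...) {
  cat(sprintf("<da_experiment: %d subjects>\n", nrow(x$contrasts)))
  print(x$tests)
  invisible(x)
}

#' Cohort-level summary of an experiment
#'
#' @param x A `da_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with the cohort size, mean peak-to-trough per
#'   role, and the deviant-vs-standard p-value and Bayes factor.
#' @export
glance.da_experiment <- function(x, ...) {
  ds <- x$tests[x$tests$contrast == "dev vs std", ]
  tibble::tibble(
    n_subjects = nrow(x$contrasts),
    mean_dev = mean(x$contrasts$dev), mean_std = mean(x$contrasts$std),
    mean_ms = mean(x$contrasts$ms),
    p_dev_std = ds$p_value, bf10_dev_std = ds$bf10
  )
}

#' Tidy the contrast tests of an experiment
#'
#' @param x A `da_experiment`.
#' @param ... Unused.
#' @return The tidy test table (one row per contrast).
#' @export
tidy.da_experiment <- function(x, ...) x$tests

#' Characterize the response components on a synthetic cohort
#'
#' Runs the single-presentation paradigm for each synthetic subject and
#' summarizes: the grand-average epoch (mean +/- SEM across subjects),
#' per-component amplitude/latency summaries, and the first-two versus
#' last-two trial stability contrast. Optionally adds the duration
#' series (offset-positive vs duration, Friedman), the intensity-change
#' series (drop-positive vs step size, Friedman + monotonicity) and the
#' SOA series (baseline at onset and peak-to-trough vs SOA, Friedman).
#'
#' @param config An [experiment_config()] (kernel/sensor/noise and
#'   cohort size are used).
#' @param parts Character subset of
#'   `c("single", "duration", "change", "soa")`.
#' @param n_trials Trials per condition for each subject (default 10).
#' @return A list of class `da_characterization` with tibbles
#'   `grand_average`, `components`, `stability`, `stability_tests`, and
#'   (by part) `duration_series`, `duration_test`, `change_series`,
#'   `change_test`, `soa_series`, `soa_tests`.
#' @export
run_component_characterization <- function(config = experiment_config(),
                                           parts = c("single", "duration", "change", "soa"),
                                           n_trials = 10) {
  parts <- match.arg(parts, several.ok = TRUE)
  seeds <- subject_seeds(config)
  sr <- config$noise$sampling_rate_hz
  out <- list(config = config)

  epochs_for <- function(events, seed, window = c(-2, 8)) {
    rec <- simulate_recording(events, config$kernel, config$sensor, config$noise,
                              seed = seed)
    ztr <- normalize_z(correct_isosbestic(rec))
    extract_epochs(ztr, events, window = window)
  }

  if ("single" %in% parts) {
    per_subj <- vector("list", config$n_subjects)
    feats <- vector("list", config$n_subjects)
    stab <- vector("list", config$n_subjects)
    ev <- stim_simple(n_events = n_trials)
    ev$onset_s <- ev$onset_s + 3  # room for the pre-onset baseline
    for (s in seq_len(config$n_subjects)) {
      ep <- epochs_for(ev, seeds[s])
      m <- epoch_matrix(ep)
      per_subj[[s]] <- colMeans(m)
      f <- component_features(ep)
      feats[[s]] <- dplyr::summarise(f, dplyr::across(dplyr::where(is.numeric), mean))
      stab[[s]] <- dplyr::mutate(trial_stability(f), subject = s)
    }
    grand <- do.call(rbind, per_subj)
    t_rel <- attr(epoch_matrix(epochs_for(ev, seeds[1])), "t_rel_s")
    out$grand_average <- tibble::tibble(
      t_rel_s = t_rel,
      mean_z = colMeans(grand),
      sem_z = apply(grand, 2, stats::sd) / sqrt(nrow(grand))
    )
    fs <- dplyr::bind_rows(feats, .id = "subject")
    out$components <- fs
    stab_all <- dplyr::bind_rows(stab)
    out$stability <- stab_all
    out$stability_tests <- dplyr::bind_rows(lapply(
      split(stab_all, stab_all$component), function(d) {
        # first/last means can coincide exactly in noise-free simulations
        tryCatch({
          w <- suppressMessages(wilcoxon_signed_rank(d$first_mean, d$last_mean))
          bf <- bayes_paired_t(d$first_mean, d$last_mean)$bf10
          tibble::tibble(component = d$component[1], statistic = w$statistic,
                         p_value = w$p_value, bf10 = bf, n = w$n)
        }, error = function(e) {
          tibble::tibble(component = d$component[1], statistic = NA_real_,
                         p_value = NA_real_, bf10 = NA_real_, n = nrow(d))
        })
      }))
  }

  if ("duration" %in% parts) {
    durs <- c(0.5, 1, 1.5, 2, 3, 5)
    offp <- matrix(NA_real_, config$n_subjects, length(durs),
                   dimnames = list(NULL, paste0(durs * 1000, "ms")))
    for (s in seq_len(config$n_subjects)) {
      ev <- stim_durations(durations_s = durs, n_reps = n_trials, seed = seeds[s])
      ev$onset_s <- ev$onset_s + 3
      ep <- epochs_for(ev, seeds[s] + 1L, window = c(-2, max(durs) + 1))
      f <- component_features(ep)
      dmap <- attr(ep, "durations")
      f$duration_s <- dmap$duration_s[match(f$trial_index, dmap$trial_index)]
      agg <- dplyr::summarise(dplyr::group_by(f, duration_s),
                              offset_positive_z = mean(offset_positive_z),
                              .groups = "drop")
      offp[s, ] <- agg$offset_positive_z[match(durs, agg$duration_s)]
    }
    out$duration_series <- tibble::as_tibble(offp) |>
      dplyr::mutate(subject = dplyr::row_number()) |>
      tidyr::pivot_longer(-subject, names_to = "duration",
                          values_to = "offset_positive_z")
    out$duration_test <- tidy.da_test(friedman_rank(offp))
  }

  if ("change" %in% parts) {
    second <- c(60, 40, 20)  # exclude the no-change 80->80 control
    dp <- matrix(NA_real_, config$n_subjects, length(second),
                 dimnames = list(NULL, paste0("to", second, "dB")))
    for (s in seq_len(config$n_subjects)) {
      ev <- stim_change("dynamic", second_db = second, n_reps = n_trials,
                        seed = seeds[s])
      ev$onset_s <- ev$onset_s + 3
      ep <- epochs_for(ev, seeds[s] + 2L)
      d <- drop_positive(ep)
      dmap <- attr(ep, "durations")
      ev_i2 <- ev$intensity2_db[match(d$trial_index, ev$trial_index)]
      agg <- tapply(d$drop_positive_z, ev_i2, mean)
      dp[s, ] <- agg[as.character(second)]
    }
    out$change_series <- tibble::as_tibble(dp) |>
      dplyr::mutate(subject = dplyr::row_number()) |>
      tidyr::pivot_longer(-subject, names_to = "condition",
                          values_to = "drop_positive_z")
    out$change_test <- tidy.da_test(friedman_rank(dp))
  }

  if ("soa" %in% parts) {
    soas <- c(0.8, 0.6, 0.4, 0.2)
    base <- p2t <- matrix(NA_real_, config$n_subjects, length(soas),
                          dimnames = list(NULL, paste0(soas * 1000, "ms")))
    for (s in seq_len(config$n_subjects)) {
      for (j in seq_along(soas)) {
        ev <- stim_repetitive(soas[j], n_events = 10 * n_trials)
        ev$onset_s <- ev$onset_s + 3
        rec <- simulate_recording(ev, config$kernel, config$sensor, config$noise,
                                  seed = seeds[s] + 10L + j)
        ztr <- normalize_z(correct_isosbestic(rec))
        ep <- extract_epochs(ztr, ev, window = c(-0.1, soas[j]))
        em <- epoch_matrix(ep)
        tr <- attr(em, "t_rel_s")
        on_i <- which.min(abs(tr))
        # skip the first trials of each run so the train has reached its
        # quasi-steady state
        late <- as.integer(rownames(em)) > 5
        base[s, j] <- mean(em[late, on_i])
        win <- tr >= 0 & tr < soas[j]
        p2t[s, j] <- mean(apply(em[late, win, drop = FALSE], 1,
                                function(v) max(v) - min(v)))
      }
    }
    mk <- function(m, value) tibble::as_tibble(m) |>
      dplyr::mutate(subject = dplyr::row_number()) |>
      tidyr::pivot_longer(-subject, names_to = "soa", values_to = value)
    out$soa_series <- dplyr::left_join(mk(base, "baseline_at_onset_z"),
                                       mk(p2t, "peak_to_trough_z"),
                                       by = c("subject", "soa"))
    out$soa_tests <- dplyr::bind_rows(
      dplyr::mutate(tidy.da_test(friedman_rank(base)), measure = "baseline_at_onset"),
      dplyr::mutate(tidy.da_test(friedman_rank(p2t)), measure = "peak_to_trough")
    )
  }
  structure(out, class = "da_characterization")
}

#' Write an analysis report
#'
#' Writes each table to delimited text plus a JSON summary recording the
#' seed, a configuration hash and the package version; reading the
#' tables back yields identical contents.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @param config Optional configuration to hash into the summary.
#' @param seed Optional seed to record.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, path, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(names(tables) != ""))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(tables[[nm]]), f, na = "")
    files <- c(files, f)
  }
  summary <- list(
    package = "photoddball",
    version = as.character(utils::packageVersion("photoddball")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config) else NULL,
    tables = lapply(tables, function(t) list(rows = nrow(t), cols = names(t)))
  )
  sf <- file.path(path, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(files, sf))
}
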