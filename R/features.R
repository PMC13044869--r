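# Response-component feature extraction.
#
# Component windows (relative to their anchor, half-open (0, w]):
#   onset-positive  max z in (0, 300] ms after onset
#   onset-negative  min z in (0, 800] ms after onset
#   offset-positive max z in (0, 800] ms after offset
#   intra-stimulus dip: mean z over the final min(1 s, duration) of the
#   stimulus (for stimuli shorter than 1 s, the whole stimulus)
# Ties are broken by the earliest sample. Amplitudes are the raw z value
# at the extremum (negative for troughs); relative amplitudes of the
# onset-negative and offset-positive components are measured from the
# immediately preceding state (the onset-positive peak and the
# intra-stimulus dip, respectively).

extremum_in <- function(t_rel, z, lo, hi, what = c("max", "min")) {
  what <- match.arg(what)
  idx <- which(t_rel > lo & t_rel <= hi)
  if (!length(idx)) return(NULL)
  v <- z[idx]
  j <- if (what == "max") which(v == max(v))[1] else which(v == min(v))[1]
  list(amplitude = v[j], t = t_rel[idx[j]])
}

#' Extract the response components from event-aligned epochs
#'
#' Computes per-trial component amplitudes and latencies from an
#' `epoch_set` (see [extract_epochs()]). Latencies are reported in ms
#' relative to each component's anchor (onset or offset).
#'
#' @param epochs An `epoch_set`, or a plain tibble with columns
#'   `trial_index`, `role`, `t_rel_s`, `z` aligned to stimulus onset.
#' @param stimulus_duration_s Stimulus duration (s); taken per trial from
#'   the `durations` attribute when available.
#' @return A tibble with one row per trial: `trial_index`, `role`,
#'   component amplitudes (`*_z`) and latencies (`*_ms`), the
#'   intra-stimulus dip mean `intra_dip_z`, relative amplitudes
#'   `rel_onset_negative_z` / `rel_offset_positive_z`, and
#'   `baseline_at_onset_z` (the z value at the onset sample).
#' @export
component_features <- function(epochs, stimulus_duration_s = NULL) {
  df <- tibble::as_tibble(epochs)
  durs <- attr(epochs, "durations")
  split_t <- split(df, df$trial_index)
  rows <- lapply(split_t, function(tr) {
    trial <- tr$trial_index[1]
    dur <- stimulus_duration_s %||%
      (if (!is.null(durs)) durs$duration_s[match(trial, durs$trial_index)] else NULL)
    if (is.null(dur) || is.na(dur)) {
      rlang::abort("stimulus duration is required (supply `stimulus_duration_s`)")
    }
    t <- tr$t_rel_s; z <- tr$z
    need <- function(x, comp) {
      if (is.null(x)) rlang::abort(sprintf("epoch does not cover the %s window", comp))
      x
    }
    onp <- need(extremum_in(t, z, 0, 0.3, "max"), "onset-positive")
    onn <- need(extremum_in(t, z, 0, 0.8, "min"), "onset-negative")
    offp <- need(extremum_in(t, z, dur, dur + 0.8, "max"), "offset-positive")
    dip_w <- min(1, dur)
    dip_idx <- which(t > dur - dip_w & t <= dur)
    if (!length(dip_idx)) rlang::abort("epoch does not cover the intra-stimulus dip window")
    dip <- mean(z[dip_idx])
    onset_i <- which.min(abs(t))
    tibble::tibble(
      trial_index = trial, role = tr$role[1],
      onset_positive_z = onp$amplitude, onset_positive_ms = onp$t * 1000,
      onset_negative_z = onn$amplitude, onset_negative_ms = onn$t * 1000,
      offset_positive_z = offp$amplitude,
      offset_positive_ms = (offp$t - dur) * 1000,
      intra_dip_z = dip,
      rel_onset_negative_z = onn$amplitude - onp$amplitude,
      rel_offset_positive_z = offp$amplitude - dip,
      baseline_at_onset_z = z[onset_i]
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), trial_index)
}

#' Long-format feature table
#'
#' Pivots the wide per-trial output of [component_features()] into the
#' tidy `(trial, role, component, amplitude, latency)` layout.
#'
#' @param features Output of [component_features()].
#' @return A long tibble with columns `trial_index`, `role`,
#'   `component`, `amplitude_z`, `latency_ms`.
#' @export
features_long <- function(features) {
  amp <- tidyr::pivot_longer(
    features[c("trial_index", "role", "onset_positive_z", "onset_negative_z",
               "offset_positive_z", "intra_dip_z")],
    cols = -c("trial_index", "role"),
    names_to = "component", values_to = "amplitude_z"
  )
  amp$component <- sub("_z$", "", amp$component)
  lat <- tidyr::pivot_longer(
    features[c("trial_index", "onset_positive_ms", "onset_negative_ms",
               "offset_positive_ms")],
    cols = -"trial_index", names_to = "component", values_to = "latency_ms"
  )
  lat$component <- sub("_ms$", "", lat$component)
  dplyr::left_join(amp, lat, by = c("trial_index", "component"))
}

#' Drop-positive component after a mid-stimulus intensity decrement
#'
#' Maximum z in the window (0, `window_s`] after the intensity change
#' (the window mirrors the offset-positive definition).
#'
#' @param epochs An `epoch_set` aligned to stimulus onset.
#' @param change_s Time of the level change after onset (s); taken per
#'   trial from the `durations` attribute when absent.
#' @param window_s Search window after the change (s), default 0.8.
#' @return A tibble with `trial_index`, `role`, `drop_positive_z`,
#'   `drop_positive_ms` (latency relative to the change).
#' @export
drop_positive <- function(epochs, change_s = NULL, window_s = 0.8) {
  df <- tibble::as_tibble(epochs)
  durs <- attr(epochs, "durations")
  rows <- lapply(split(df, df$trial_index), function(tr) {
    trial <- tr$trial_index[1]
    ch <- change_s %||%
      (if (!is.null(durs)) durs$change_s[match(trial, durs$trial_index)] else NULL)
    if (is.null(ch) || is.na(ch)) rlang::abort("change time is required (supply `change_s`)")
    if (max(tr$t_rel_s) < ch + window_s) {
      rlang::abort("epoch does not cover the drop-positive window")
    }
    ex <- extremum_in(tr$t_rel_s, tr$z, ch, ch + window_s, "max")
    tibble::tibble(trial_index = trial, role = tr$role[1],
                   drop_positive_z = ex$amplitude,
                   drop_positive_ms = (ex$t - ch) * 1000)
  })
  dplyr::arrange(dplyr::bind_rows(rows), trial_index)
}

#' Peak-to-trough amplitude within the SOA window
#'
#' `max(z) - min(z)` over the half-open window [0, `soa_s`) after onset:
#' the response measure under continuous stimulation, where no stable
#' pre-stimulus baseline exists.
#'
#' @param epochs An `epoch_set` aligned to stimulus onset.
#' @param soa_s Stimulus onset asynchrony (s).
#' @return A tibble with `trial_index`, `role`, `peak_to_trough_z`.
#' @export
peak_to_trough <- function(epochs, soa_s) {
  df <- tibble::as_tibble(epochs)
  df <- df[df$t_rel_s >= 0 & df$t_rel_s < soa_s, ]
  if (nrow(df) == 0L) rlang::abort("epoch does not cover the SOA window")
  out <- dplyr::summarise(
    dplyr::group_by(df, trial_index, role),
    peak_to_trough_z = max(z) - min(z), .groups = "drop"
  )
  dplyr::arrange(out, trial_index)
}

#' Onset/offset amplitude ratio
#'
#' `onset / (onset + offset)` after clamping both amplitudes at zero, so
#' the ratio stays in `[0, 1]` in noisy trials. Undefined (error) when
#' both clamped amplitudes are zero.
#'
#' @param onset_amp,offset_amp Onset-positive and offset-positive
#'   amplitudes (vectors recycle as usual).
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
onset_offset_ratio <- function(onset_amp, offset_amp) {
  a <- pmax(onset_amp, 0); b <- pmax(offset_amp, 0)
  if (any(a + b == 0)) {
    rlang::abort("onset/offset ratio undefined: both amplitudes are zero")
  }
  a / (a + b)
}

#' Project a recording site onto the ventromedial-dorsolateral axis
#'
#' Scalar projection of the site (ML, DV) onto the unit vector of the
#' axis from the ventromedial anchor (ML 0.0, DV 8.0) to the dorsolateral
#' anchor (ML 8.0, DV 1.5), which runs approximately orthogonal to the
#' accumbens shell-core boundary.
#'
#' @param ml_mm,dv_mm Mediolateral and dorsoventral coordinates (mm).
#' @param from,to Axis anchors `c(ML, DV)`.
#' @return Projected position along the axis (mm).
#' @export
project_site <- function(ml_mm, dv_mm, from = c(0, 8), to = c(8, 1.5)) {
  v <- to - from
  u <- v / sqrt(sum(v^2))
  (ml_mm - from[1]) * u[1] + (dv_mm - from[2]) * u[2]
}

#' First-trials versus last-trials component means
#'
#' Means of each component over the first two and last two trials of an
#' ordered feature table, the per-subject summary used to test
#' trial-by-trial stability (habituation) with a paired test across
#' subjects.
#'
#' @param features Output of [component_features()], ordered by trial.
#' @param n_edge Number of trials averaged at each end (default 2).
#' @return A tibble with `component`, `first_mean`, `last_mean`.
#' @export
trial_stability <- function(features, n_edge = 2L) {
  n <- nrow(features)
  if (n < 2L * n_edge) rlang::abort(sprintf("need at least %d trials", 2L * n_edge))
  comps <- c("onset_positive_z", "onset_negative_z", "intra_dip_z", "offset_positive_z")
  first <- features[seq_len(n_edge), comps]
  last <- features[seq(n - n_edge + 1L, n), comps]
  tibble::tibble(
    component = sub("_z$", "", comps),
    first_mean = unname(vapply(first, mean, numeric(1))),
    last_mean = unname(vapply(last, mean, numeric(1)))
  )
}
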