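# Raw fluorescence -> delta-F/F -> z-scored traces -> event-aligned epochs.

#' Least-squares fit of the isosbestic channel to the excitation channel
#'
#' Regresses the isosbestic signal onto the excitation signal so that the
#' fitted trace `slope * isosbestic + intercept` tracks the
#' ligand-independent component (bleaching, motion) of the excitation
#' channel. A constant isosbestic channel degenerates to an
#' intercept-only fit (fitted = mean of the excitation), with a note.
#'
#' @param excitation,isosbestic Equal-length numeric vectors (n >= 2).
#' @return A list with `slope`, `intercept` and `fitted`.
#' @export
fit_isosbestic <- function(excitation, isosbestic) {
  if (length(excitation) != length(isosbestic)) {
    rlang::abort("excitation and isosbestic channels must have equal length")
  }
  if (length(excitation) < 2L) rlang::abort("need at least 2 samples")
  if (stats::sd(isosbestic) == 0) {
    rlang::inform("constant isosbestic channel: falling back to an intercept-only fit")
    m <- mean(excitation)
    return(list(slope = 0, intercept = m, fitted = rep(m, length(excitation))))
  }
  mx <- mean(isosbestic); my <- mean(excitation)
  slope <- sum((isosbestic - mx) * (excitation - my)) / sum((isosbestic - mx)^2)
  intercept <- my - slope * mx
  list(slope = slope, intercept = intercept,
       fitted = slope * isosbestic + intercept)
}

#' Fractional fluorescence change
#'
#' `dff = (excitation - fitted) / fitted`, pointwise. The reference must
#' be strictly positive everywhere.
#'
#' @param excitation Excitation channel.
#' @param fitted Fitted reference (e.g. from [fit_isosbestic()]).
#' @return Numeric vector of delta-F/F values.
#' @export
compute_dff <- function(excitation, fitted) {
  if (length(excitation) != length(fitted)) {
    rlang::abort("excitation and fitted reference must have equal length")
  }
  bad <- which(fitted <= 0)
  if (length(bad)) {
    rlang::abort(sprintf("fitted reference is non-positive at sample %d", bad[1]))
  }
  (excitation - fitted) / fitted
}

#' Isosbestic correction of a two-channel recording
#'
#' Fits the isosbestic channel to the excitation channel over the whole
#' session and adds a `dff` column; the regression coefficients are kept
#' in the `fit` attribute. This is the data-frame-first entry point for
#' the preprocessing chain:
#' `rec |> correct_isosbestic() |> normalize_z() |> extract_epochs(...)`.
#'
#' @param rec A `photometry_rec` or any tibble with columns `time_s`,
#'   `excitation`, `isosbestic`.
#' @return The input tibble with a `dff` column and a `fit` attribute
#'   (class `dff_trace` added).
#' @export
correct_isosbestic <- function(rec) {
  stopifnot(all(c("time_s", "excitation", "isosbestic") %in% names(rec)))
  fit <- fit_isosbestic(rec$excitation, rec$isosbestic)
  out <- dplyr::mutate(tibble::as_tibble(rec), dff = compute_dff(excitation, fit$fitted))
  out <- restore_rec_attrs(out, rec)
  attr(out, "fit") <- fit[c("slope", "intercept")]
  class(out) <- unique(c("dff_trace", class(rec), class(out)))
  out
}

restore_rec_attrs <- function(out, rec) {
  for (a in c("sampling_rate_hz", "events", "truth", "noise", "fit")) {
    if (!is.null(attr(rec, a))) attr(out, a) <- attr(rec, a)
  }
  out
}

# (x - mean) / sd over the reference indices; unbiased sd.
zscore_vec <- function(x, ref = seq_along(x)) {
  m <- mean(x[ref]); s <- stats::sd(x[ref])
  if (!is.finite(s) || s == 0) rlang::abort("degenerate signal: zero standard deviation")
  (x - m) / s
}

#' z-score a delta-F/F trace
#'
#' Global mode normalizes by the mean and (unbiased) standard deviation
#' over the entire session. Local mode normalizes a window around a
#' reference event onset (default +/- 3.2 s) by that window's own mean
#' and standard deviation, and returns only the window; normalizing the
#' whole window at once puts a deviant and its paired k-back standard
#' (which lies inside the window at short SOAs) in a shared local
#' reference frame, insulating the comparison from slow drift.
#'
#' @param x A tibble with columns `time_s` and `dff` (e.g. from
#'   [correct_isosbestic()]).
#' @param mode `"global"` or `"local"`.
#' @param center_s Reference onset (s) for local mode.
#' @param half_width_s Local window half-width (s), default 3.2.
#' @return The tibble with a `z` column (local mode: restricted to the
#'   window, with a `t_rel_s` column); the normalization is described in
#'   the `normalization` attribute.
#' @export
normalize_z <- function(x, mode = c("global", "local"), center_s = NULL,
                        half_width_s = 3.2) {
  mode <- match.arg(mode)
  stopifnot(all(c("time_s", "dff") %in% names(x)))
  if (mode == "global") {
    out <- dplyr::mutate(tibble::as_tibble(x), z = zscore_vec(dff))
    out <- restore_rec_attrs(out, x)
    attr(out, "normalization") <- list(mode = "global", sd = "unbiased")
  } else {
    if (is.null(center_s)) rlang::abort("local mode needs `center_s`")
    eps <- 1e-9 * max(1, abs(center_s))
    keep <- x$time_s >= center_s - half_width_s - eps &
      x$time_s <= center_s + half_width_s + eps
    if (!any(keep)) rlang::abort("local window lies outside the recording")
    if (min(x$time_s) > center_s - half_width_s + eps ||
        max(x$time_s) < center_s + half_width_s - eps) {
      rlang::abort("local window extends beyond the recording")
    }
    out <- tibble::as_tibble(x)[keep, ]
    out$z <- zscore_vec(out$dff)
    out$t_rel_s <- out$time_s - center_s
    out <- restore_rec_attrs(out, x)
    attr(out, "normalization") <- list(
      mode = "local", center_s = center_s, half_width_s = half_width_s,
      sd = "unbiased")
  }
  class(out) <- unique(c("z_trace", class(tibble::tibble())))
  out
}

#' Extract event-aligned epochs from a z-scored trace
#'
#' Cuts one aligned window per event (nearest-sample onset alignment, no
#' sub-sample interpolation) and computes each trial's baseline as the
#' mean over the pre-onset baseline window (default the 2 s before
#' onset). Events whose window would run past either end of the
#' recording are dropped with a note.
#'
#' @param z A tibble with columns `time_s` and `z` (see [normalize_z()]).
#' @param events A `stim_seq` or event tibble.
#' @param window Length-2 window around onset, seconds (default `c(-2, 8)`).
#' @param baseline_window Length-2 pre-onset window for the baseline mean
#'   (default `c(-2, 0)`: the half-open interval [-2, 0) s).
#' @param sampling_rate_hz Grid rate; taken from the `sampling_rate_hz`
#'   attribute when absent.
#' @return An `epoch_set`: long tibble with columns `trial_index`,
#'   `role`, `t_rel_s`, `z`, and attributes `window`, `sampling_rate_hz`,
#'   `baseline` (tibble of per-trial baseline means) and `durations`
#'   (per-trial stimulus durations).
#' @export
extract_epochs <- function(z, events, window = c(-2, 8),
                           baseline_window = c(-2, 0),
                           sampling_rate_hz = NULL) {
  stopifnot(all(c("time_s", "z") %in% names(z)), length(window) == 2L)
  sr <- sampling_rate_hz %||% attr(z, "sampling_rate_hz")
  if (is.null(sr)) sr <- round(1 / stats::median(diff(z$time_s)))
  ev <- tibble::as_tibble(events)
  t0 <- z$time_s[1]
  n <- nrow(z)
  rel_idx <- seq(round(window[1] * sr), round(window[2] * sr))
  base_idx <- seq(round(baseline_window[1] * sr), round(baseline_window[2] * sr) - 1L)
  keep <- logical(nrow(ev))
  pieces <- vector("list", nrow(ev))
  baselines <- rep(NA_real_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    onset_i <- round((ev$onset_s[i] - t0) * sr) + 1L
    idx <- onset_i + rel_idx
    bidx <- onset_i + base_idx
    if (idx[1] < 1L || idx[length(idx)] > n || bidx[1] < 1L) next
    keep[i] <- TRUE
    baselines[i] <- mean(z$z[bidx])
    pieces[[i]] <- tibble::tibble(
      trial_index = ev$trial_index[i], role = ev$role[i],
      t_rel_s = rel_idx / sr, z = z$z[idx]
    )
  }
  if (any(!keep)) {
    rlang::inform(sprintf("extract_epochs: dropped %d event(s) too close to the recording edge",
                          sum(!keep)))
  }
  out <- dplyr::bind_rows(pieces[keep])
  structure(out,
    class = c("epoch_set", class(tibble::tibble())),
    window = window, sampling_rate_hz = sr,
    baseline = tibble::tibble(trial_index = ev$trial_index[keep],
                              baseline_z = baselines[keep]),
    durations = tibble::tibble(trial_index = ev$trial_index[keep],
                               duration_s = ev$duration_s[keep],
                               change_s = ev$change_s[keep])
  )
}

#' Epochs as a trial-by-time matrix
#'
#' @param epochs An `epoch_set` from [extract_epochs()].
#' @return A numeric matrix (rows = trials, in `trial_index` order;
#'   columns = time samples) with the relative time grid in the
#'   `t_rel_s` attribute.
#' @export
epoch_matrix <- function(epochs) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(epochs)[c("trial_index", "t_rel_s", "z")],
                             names_from = "t_rel_s", values_from = "z")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$trial_index
  attr(m, "t_rel_s") <- as.numeric(colnames(wide)[-1])
  m
}
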