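# Sound-preference assay metrics: length of stay and the Preference Index.

#' Cumulative length of stay per condition
#'
#' Sums dwell time per condition across sessions from a timestamped
#' occupancy series. Dwell time of each sample extends to the next
#' timestamp; the final sample of a session extends to that session's
#' end. Conditioning is at the condition level because the
#' field-condition mapping is reshuffled every session.
#'
#' @param occupancy Tibble with columns `session`, `time_s`, `field`
#'   (timestamps increasing within each session).
#' @param mappings Tibble with columns `session`, `field`, `condition`
#'   giving each session's field-condition mapping.
#' @param session_s Session duration (s), default 20.
#' @return A tibble with `condition` and `stay_s`, whose total equals the
#'   summed session durations.
#' @export
length_of_stay <- function(occupancy, mappings, session_s = 20) {
  occ <- dplyr::left_join(tibble::as_tibble(occupancy),
                          tibble::as_tibble(mappings),
                          by = c("session", "field"))
  if (anyNA(occ$condition)) {
    rlang::abort("occupancy contains a field with no condition mapping")
  }
  occ <- dplyr::mutate(
    dplyr::group_by(occ, session),
    dwell_s = dplyr::lead(time_s, default = session_s) - time_s
  )
  if (any(occ$dwell_s < 0)) rlang::abort("occupancy timestamps must be increasing within sessions")
  dplyr::summarise(dplyr::group_by(dplyr::ungroup(occ), condition),
                   stay_s = sum(dwell_s), .groups = "drop")
}

#' Preference Index
#'
#' `PI = Pr(Goal = X | Start != X) - Pr(Goal != X | Start = X)`, where
#' Start and Goal are the conditions mapped to the animal's field at the
#' beginning and end of each session. The index isolates movement:
#' chance level is 0, attraction toward condition X gives PI > 0, and
#' avoidance gives PI < 0; sustained immobility (freezing, sleep)
#' contributes equally to both terms and cancels.
#'
#' @param sessions Tibble with columns `start_condition`,
#'   `goal_condition`, optionally `animal` (see
#'   [simulate_place_sessions()]).
#' @param condition The condition X.
#' @param by `"animal"` computes a PI per animal (requires an `animal`
#'   column); `"pooled"` pools all sessions.
#' @return A tibble with columns (`animal`,) `pi`, `n_start_other`,
#'   `n_start_x`.
#' @export
preference_index <- function(sessions, condition, by = c("pooled", "animal")) {
  by <- match.arg(by)
  df <- tibble::as_tibble(sessions)
  pi_one <- function(d) {
    start_other <- d$start_condition != condition
    start_x <- !start_other
    if (!any(start_other)) {
      rlang::abort("PI undefined: Pr(Goal = X | Start != X) has no qualifying sessions")
    }
    if (!any(start_x)) {
      rlang::abort("PI undefined: Pr(Goal != X | Start = X) has no qualifying sessions")
    }
    p_in <- mean(d$goal_condition[start_other] == condition)
    p_out <- mean(d$goal_condition[start_x] != condition)
    tibble::tibble(pi = p_in - p_out,
                   n_start_other = sum(start_other), n_start_x = sum(start_x))
  }
  if (by == "pooled") return(pi_one(df))
  if (!"animal" %in% names(df)) rlang::abort("`by = \"animal\"` needs an `animal` column")
  dplyr::group_modify(dplyr::group_by(df, animal), ~ pi_one(.x)) |> dplyr::ungroup()
}

#' Occupancy heatmap
#'
#' Bins a trajectory into an `n_bins` x `n_bins` grid over the arena and
#' reports the percentage of total recording time spent in each bin
#' (samples are equally weighted, so the grid sums to 100).
#'
#' @param trajectory Tibble with columns `x_cm`, `y_cm` (see
#'   [simulate_trajectory()]).
#' @param n_bins Bins per axis (default 20).
#' @param arena_cm Arena side length; bins span `[-arena_cm/2, arena_cm/2]`.
#' @return A tibble with `x_bin`, `y_bin` (1-based), bin centers
#'   `x_cm`, `y_cm`, and `pct`.
#' @export
occupancy_heatmap <- function(trajectory, n_bins = 20, arena_cm = 35) {
  half <- arena_cm / 2
  brk <- seq(-half, half, length.out = n_bins + 1)
  xb <- cut(trajectory$x_cm, brk, include.lowest = TRUE, labels = FALSE)
  yb <- cut(trajectory$y_cm, brk, include.lowest = TRUE, labels = FALSE)
  if (anyNA(xb) || anyNA(yb)) rlang::abort("trajectory leaves the arena bounds")
  tab <- table(factor(xb, levels = seq_len(n_bins)),
               factor(yb, levels = seq_len(n_bins)))
  centers <- (brk[-1] + brk[-length(brk)]) / 2
  grid <- tidyr::expand_grid(x_bin = seq_len(n_bins), y_bin = seq_len(n_bins))
  grid$x_cm <- centers[grid$x_bin]
  grid$y_cm <- centers[grid$y_bin]
  grid$pct <- 100 * as.vector(tab[cbind(grid$x_bin, grid$y_bin)]) / length(xb)
  grid
}
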