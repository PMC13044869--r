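# Stimulus paradigm generators.
#
# Every generator returns a "stim_seq": a tibble of stimulus events with one
# row per presentation and a fixed column schema, carrying the paradigm label,
# the nominal stimulus onset asynchrony (SOA, onset-to-onset) where one exists,
# and the seed used. Band-limited noises are encoded as closed Hz intervals
# [band_lo_hz, band_hi_hz]; broadband white noise is encoded as NA bounds.

STIM_ROLES <- c("standard", "deviant", "deviant_equivalent", "plain")

EVENT_COLS <- c(
  "onset_s", "duration_s", "intensity_db", "intensity2_db", "change_s",
  "band_lo_hz", "band_hi_hz", "role", "trial_index"
)

new_stim_seq <- function(events, paradigm, soa_s = NA_real_, seed = NA_integer_) {
  events <- tibble::as_tibble(events)[EVENT_COLS]
  events$trial_index <- as.integer(events$trial_index)
  validate_stim_seq(events)
  structure(events,
    class = c("stim_seq", class(tibble::tibble())),
    paradigm = paradigm, soa_s = soa_s, seed = seed
  )
}

validate_stim_seq <- function(events) {
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$onset_s < 0)) rlang::abort("stimulus onsets must be >= 0")
  if (any(events$duration_s <= 0)) rlang::abort("stimulus durations must be > 0")
  if (any(diff(events$onset_s) <= 0)) {
    rlang::abort("stimulus events must be strictly ordered by onset")
  }
  if (!all(events$role %in% STIM_ROLES)) {
    rlang::abort(paste0("role must be one of: ", paste(STIM_ROLES, collapse = ", ")))
  }
  two_stage <- !is.na(events$change_s)
  if (any(two_stage & (events$change_s <= 0 | events$change_s >= events$duration_s))) {
    rlang::abort("two-stage events must change level strictly inside (0, duration)")
  }
  invisible(events)
}

#' @export
print.stim_seq <- function(x, ...) {
  cat(sprintf(
    "<stim_seq: %s, %d events, SOA %s s, seed %s>\n",
    attr(x, "paradigm"), nrow(x),
    format(attr(x, "soa_s")), format(attr(x, "seed"))
  ))
  NextMethod()
}

event_row <- function(onset, duration, intensity, intensity2 = NA_real_,
                      change = NA_real_, band = NULL, role = "plain", trial = 1L) {
  tibble::tibble(
    onset_s = onset, duration_s = duration,
    intensity_db = intensity, intensity2_db = intensity2, change_s = change,
    band_lo_hz = if (is.null(band)) NA_real_ else band[1],
    band_hi_hz = if (is.null(band)) NA_real_ else band[2],
    role = role, trial_index = as.integer(trial)
  )
}

#' Single-presentation paradigm: repeated identical stimuli
#'
#' Generates `n_events` identical broadband white-noise presentations
#' separated by a fixed inter-stimulus interval. The interval is an
#' offset-to-next-onset gap, so the onset period equals
#' `duration_s + isi_s` (6-s stimuli with a 3-s gap recur every 9 s).
#'
#' @param duration_s Stimulus duration in seconds.
#' @param intensity_db Stimulus level in dB SPL.
#' @param n_events Number of presentations.
#' @param isi_s Offset-to-next-onset gap in seconds.
#' @param seed Unused (the paradigm is deterministic); kept so that all
#'   generators share one signature and the seed is recorded in the output.
#' @return A `stim_seq` tibble of events.
#' @examples
#' stim_simple() # 10 x 6-s white noise at 80 dB SPL, onsets every 9 s
#' @export
stim_simple <- function(duration_s = 6, intensity_db = 80, n_events = 10,
                        isi_s = 3, seed = NULL) {
  stopifnot(duration_s > 0, isi_s >= 0)
  if (!is.numeric(n_events) || n_events < 1) {
    rlang::abort("`n_events` must be a positive count")
  }
  n_events <- as.integer(n_events)
  onsets <- (seq_len(n_events) - 1L) * (duration_s + isi_s)
  ev <- event_row(
    onset = onsets, duration = duration_s, intensity = intensity_db,
    role = "plain", trial = seq_len(n_events)
  )
  new_stim_seq(ev, "simple", soa_s = duration_s + isi_s,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Duration-series paradigm: white noise of varying durations
#'
#' Each duration condition is presented `n_reps` times; conditions are
#' interleaved in randomized order.
#'
#' @param durations_s Vector of stimulus durations in seconds (defaults to
#'   0.5, 1, 1.5, 2, 3 and 5 s).
#' @param intensity_db Level in dB SPL.
#' @param n_reps Presentations per duration condition.
#' @param isi_s Offset-to-next-onset gap in seconds.
#' @param seed Integer seed controlling the condition order.
#' @return A `stim_seq` tibble of events.
#' @export
stim_durations <- function(durations_s = c(0.5, 1, 1.5, 2, 3, 5),
                           intensity_db = 80, n_reps = 10, isi_s = 3,
                           seed = 1L) {
  stopifnot(all(durations_s > 0), n_reps >= 1)
  durs <- rep(durations_s, each = n_reps)
  durs <- durs[with_seed(seed, sample.int(length(durs)))]
  onsets <- cumsum(c(0, utils::head(durs, -1) + isi_s))
  ev <- event_row(
    onset = onsets, duration = durs, intensity = intensity_db,
    role = "plain", trial = seq_along(durs)
  )
  new_stim_seq(ev, "durations", seed = as.integer(seed))
}

#' Intensity-change paradigms: mid-stimulus level steps
#'
#' Generates the two level-step paradigms. In `"dynamic"` mode the initial
#' level is fixed and the post-change level varies (default 80 dB SPL
#' stepping to 80, 60, 40 or 20 dB SPL at 3 s). In `"constant"` mode the
#' decrement is fixed (default -40 dB SPL) and the initial level varies
#' (default 80, 70, 60, 50 dB SPL). Only downward (or zero) steps are
#' supported; the zero step (e.g. 80 to 80) is the no-change control,
#' recognizable by `intensity2_db == intensity_db`.
#'
#' @param mode `"dynamic"` or `"constant"`.
#' @param initial_db Initial level(s) in dB SPL: a scalar for `"dynamic"`,
#'   a vector for `"constant"`.
#' @param second_db Post-change levels for `"dynamic"` mode.
#' @param step_db Fixed level step for `"constant"` mode (non-positive).
#' @param change_s Time of the level change within each stimulus, seconds.
#' @param duration_s Stimulus duration, seconds.
#' @param n_reps Presentations per condition.
#' @param isi_s Offset-to-next-onset gap, seconds.
#' @param seed Integer seed controlling condition interleaving.
#' @return A `stim_seq` tibble of events.
#' @export
stim_change <- function(mode = c("dynamic", "constant"),
                        initial_db = if (mode == "dynamic") 80 else c(80, 70, 60, 50),
                        second_db = c(80, 60, 40, 20),
                        step_db = -40,
                        change_s = 3, duration_s = 6, n_reps = 10, isi_s = 3,
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(change_s > 0, change_s < duration_s, n_reps >= 1)
  if (mode == "dynamic") {
    stopifnot(length(initial_db) == 1L)
    cond <- tibble::tibble(i1 = initial_db, i2 = second_db)
  } else {
    stopifnot(length(step_db) == 1L)
    if (step_db > 0) rlang::abort("only level decrements are supported")
    cond <- tibble::tibble(i1 = initial_db, i2 = initial_db + step_db)
  }
  if (any(cond$i2 > cond$i1)) {
    rlang::abort("post-change level above the initial level is not supported")
  }
  idx <- rep(seq_len(nrow(cond)), each = n_reps)
  idx <- idx[with_seed(seed, sample.int(length(idx)))]
  n <- length(idx)
  onsets <- (seq_len(n) - 1L) * (duration_s + isi_s)
  ev <- event_row(
    onset = onsets, duration = duration_s,
    intensity = cond$i1[idx], intensity2 = cond$i2[idx], change = change_s,
    role = "plain", trial = seq_len(n)
  )
  new_stim_seq(ev, paste0(mode, "_change"), soa_s = duration_s + isi_s,
               seed = as.integer(seed))
}

#' Repetitive-train paradigm: brief bursts at a fixed SOA with pauses
#'
#' Generates a train of brief bursts presented at a fixed onset-to-onset
#' interval. After every `pause_every`-th stimulus a pause is inserted: by
#' default the pause is added on top of the nominal SOA (an "inserted"
#' pause), so `onset[11] - onset[10] == soa_s + pause_s` for the default
#' block length; set `pause_adds = FALSE` to have the pause replace the SOA.
#'
#' @param soa_s Stimulus onset asynchrony in seconds (e.g. 0.8, 0.6, 0.4,
#'   0.2). Overlap with the burst duration is not required to be absent: a
#'   200-ms SOA with 100-ms bursts is legal.
#' @param n_events Presentations in the train.
#' @param pause_every Insert a pause after every this many stimuli.
#' @param pause_s Pause length in seconds.
#' @param duration_s Burst duration in seconds.
#' @param intensity_db Level in dB SPL.
#' @param pause_adds If `TRUE` (default) the pause adds to the SOA;
#'   otherwise it replaces it.
#' @param seed Unused (deterministic); recorded in the output.
#' @return A `stim_seq` tibble of events.
#' @export
stim_repetitive <- function(soa_s, n_events = 1000, pause_every = 10,
                            pause_s = 2, duration_s = 0.1, intensity_db = 80,
                            pause_adds = TRUE, seed = NULL) {
  stopifnot(soa_s > 0, n_events >= 1, pause_every >= 1, pause_s >= 0)
  n_events <- as.integer(n_events)
  gaps <- rep(soa_s, n_events - 1L)
  after_pause <- which(seq_len(n_events - 1L) %% pause_every == 0L)
  gaps[after_pause] <- if (pause_adds) soa_s + pause_s else pause_s
  onsets <- cumsum(c(0, gaps))
  ev <- event_row(
    onset = onsets, duration = duration_s, intensity = intensity_db,
    role = "plain", trial = seq_len(n_events)
  )
  new_stim_seq(ev, "repetitive", soa_s = soa_s,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Oddball paradigm specification
#'
#' Collects the design constants of the auditory oddball sequence: two
#' band-limited noises, one serving as the frequently repeated standard and
#' the other as the rare deviant, presented pseudo-randomly under a
#' minimum-run constraint, with standard/deviant bands swapped after a fixed
#' number of deviants.
#'
#' @param standard_band,deviant_band Closed Hz intervals `c(lo, hi)`.
#' @param deviant_prob Deviant probability (fraction of events), in (0, 1).
#' @param min_standard_run Minimum number of consecutive standards before
#'   every deviant (also enforced at the start of each block).
#' @param n_deviants_per_block Deviants per block; the bands swap roles
#'   after each block.
#' @param n_blocks Number of blocks (2 gives one role swap).
#' @param stimulus_duration_s Burst duration, seconds.
#' @param soa_s Onset-to-onset interval, seconds.
#' @return A list of class `oddball_spec`.
#' @export
oddball_spec <- function(standard_band = c(2250, 2750),
                         deviant_band = c(3250, 3750),
                         deviant_prob = 0.1,
                         min_standard_run = 4,
                         n_deviants_per_block = 300,
                         n_blocks = 2,
                         stimulus_duration_s = 0.15,
                         soa_s = 0.8) {
  stopifnot(
    deviant_prob > 0, deviant_prob < 1, min_standard_run >= 1,
    n_deviants_per_block >= 0, n_blocks >= 1,
    stimulus_duration_s > 0, soa_s > 0
  )
  structure(
    list(
      standard_band = standard_band, deviant_band = deviant_band,
      deviant_prob = deviant_prob, min_standard_run = as.integer(min_standard_run),
      n_deviants_per_block = as.integer(n_deviants_per_block),
      n_blocks = as.integer(n_blocks),
      stimulus_duration_s = stimulus_duration_s, soa_s = soa_s
    ),
    class = "oddball_spec"
  )
}

#' Generate an oddball stimulus sequence
#'
#' Places deviants by randomizing the lengths of the standard runs that
#' separate them, so the deviant fraction is exactly `deviant_prob` per
#' block (not Bernoulli), every pair of successive deviants is separated by
#' at least `min_standard_run` standards, and each block opens with at
#' least `min_standard_run` standards. After `n_deviants_per_block`
#' deviants, the standard and deviant bands are exchanged and generation
#' continues; the role labels always mark the rare stimulus as `deviant`.
#'
#' @param spec An [oddball_spec()].
#' @param seed Integer seed.
#' @return A `stim_seq` tibble of events.
#' @export
stim_oddball <- function(spec = oddball_spec(), seed = 1L) {
  stopifnot(inherits(spec, "oddball_spec"))
  d <- spec$n_deviants_per_block
  n_block <- if (d == 0L) {
    as.integer(spec$min_standard_run)  # degenerate all-standard block
  } else {
    as.integer(round(d / spec$deviant_prob))
  }
  s_block <- n_block - d
  extra <- s_block - spec$min_standard_run * d
  if (extra < 0) {
    rlang::abort(sprintf(
      "infeasible oddball design: %d deviants with runs of >= %d standards need more than %d slots",
      d, spec$min_standard_run, n_block
    ))
  }
  roles_block <- function() {
    if (d == 0L) return(rep("standard", n_block))
    # distribute the spare standards over the d pre-deviant runs + tail
    cell <- sample.int(d + 1L, extra, replace = TRUE)
    runs <- tabulate(cell, nbins = d + 1L)
    runs[seq_len(d)] <- runs[seq_len(d)] + spec$min_standard_run
    unlist(lapply(seq_len(d + 1L), function(i) {
      c(rep("standard", runs[i]), if (i <= d) "deviant")
    }), use.names = FALSE)
  }
  roles <- with_seed(seed, unlist(
    lapply(seq_len(spec$n_blocks), function(b) roles_block()),
    use.names = FALSE
  ))
  n <- length(roles)
  block <- rep(seq_len(spec$n_blocks), each = n_block)[seq_len(n)]
  swap <- block %% 2L == 0L
  std_lo <- ifelse(swap, spec$deviant_band[1], spec$standard_band[1])
  std_hi <- ifelse(swap, spec$deviant_band[2], spec$standard_band[2])
  dev_lo <- ifelse(swap, spec$standard_band[1], spec$deviant_band[1])
  dev_hi <- ifelse(swap, spec$standard_band[2], spec$deviant_band[2])
  is_dev <- roles == "deviant"
  ev <- event_row(
    onset = (seq_len(n) - 1L) * spec$soa_s,
    duration = spec$stimulus_duration_s, intensity = 80,
    band = NULL, role = roles, trial = seq_len(n)
  )
  ev$band_lo_hz <- ifelse(is_dev, dev_lo, std_lo)
  ev$band_hi_hz <- ifelse(is_dev, dev_hi, std_hi)
  out <- new_stim_seq(ev, "oddball", soa_s = spec$soa_s, seed = as.integer(seed))
  attr(out, "spec") <- spec
  out
}

#' Pair each deviant with its analysis standard
#'
#' The standard used for analysis is the stimulus presented a fixed number
#' of trials before each deviant (default three trials back), which buffers
#' the comparison against the temporal interaction of consecutive
#' responses at short SOAs. Deviants whose k-back position is out of range
#' or is not a standard are skipped (a note reports how many).
#'
#' @param seq A `stim_seq`, typically from [stim_oddball()].
#' @param offset_trials How many trials before the deviant to take the
#'   standard from (>= 1; default 3).
#' @return A tibble with columns `deviant_index` and `standard_index`
#'   (trial indices into `seq`).
#' @export
analysis_standards <- function(seq, offset_trials = 3L) {
  stopifnot(inherits(seq, "stim_seq"), offset_trials >= 1)
  offset_trials <- as.integer(offset_trials)
  dev_idx <- which(seq$role == "deviant")
  std_idx <- dev_idx - offset_trials
  ok <- std_idx >= 1L & seq$role[pmax(std_idx, 1L)] == "standard"
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    rlang::inform(sprintf("analysis_standards: skipped %d deviant(s) without a valid %d-back standard",
                          n_skip, offset_trials))
  }
  tibble::tibble(deviant_index = dev_idx[ok], standard_index = std_idx[ok])
}

#' Many-standards control sequence
#'
#' Presents a set of band-limited noises with exact per-band counts (a
#' balanced shuffle of the target proportions, default 10 bands at 10%
#' each), so no single stimulus forms a repeating standard. Events whose
#' band equals `deviant_equivalent_band` -- the stimulus physically
#' identical to the oddball deviant -- carry the role `deviant_equivalent`;
#' all others are `plain`.
#'
#' @param bands List of closed Hz intervals `c(lo, hi)`. The default is ten
#'   500-Hz-wide bands with lower edges from 1000 to 5500 Hz.
#' @param prob_each Probability per band; must sum to 1.
#' @param n_events Total number of presentations.
#' @param deviant_equivalent_band The band to label `deviant_equivalent`;
#'   must be one of `bands`.
#' @param stimulus_duration_s,soa_s Burst duration and onset interval (s).
#' @param seed Integer seed.
#' @return A `stim_seq` tibble of events.
#' @export
stim_many_standards <- function(bands = lapply(seq(1000, 5500, by = 500), function(lo) c(lo, lo + 500)),
                                prob_each = rep(1 / length(bands), length(bands)),
                                n_events = 3000,
                                deviant_equivalent_band = bands[[6]],
                                stimulus_duration_s = 0.15, soa_s = 0.8,
                                seed = 1L) {
  stopifnot(length(prob_each) == length(bands), n_events >= 1)
  if (abs(sum(prob_each) - 1) > 1e-9) rlang::abort("band probabilities must sum to 1")
  dev_i <- which(vapply(bands, function(b) isTRUE(all.equal(b, deviant_equivalent_band)), logical(1)))
  if (length(dev_i) != 1L) rlang::abort("`deviant_equivalent_band` must match exactly one entry of `bands`")
  k <- length(bands)
  counts <- floor(n_events * prob_each)
  rem <- n_events - sum(counts)
  band_of <- with_seed(seed, {
    if (rem > 0) {
      rlang::warn(sprintf(
        "n_events = %d is not divisible into the band probabilities; %d leftover event(s) assigned at random",
        n_events, rem))
      extra <- sample.int(k, rem, replace = FALSE, prob = prob_each)
      counts[extra] <- counts[extra] + 1L
    }
    sample(rep.int(seq_len(k), counts))
  })
  ev <- event_row(
    onset = (seq_len(n_events) - 1L) * soa_s,
    duration = stimulus_duration_s, intensity = 80,
    role = ifelse(band_of == dev_i, "deviant_equivalent", "plain"),
    trial = seq_len(n_events)
  )
  ev$band_lo_hz <- vapply(bands, `[`, numeric(1), 1)[band_of]
  ev$band_hi_hz <- vapply(bands, `[`, numeric(1), 2)[band_of]
  new_stim_seq(ev, "many_standards", soa_s = soa_s, seed = as.integer(seed))
}

#' Read or write an event table
#'
#' Event tables round-trip through delimited text with a mandatory header
#' and the fixed column schema used by all generators; a missing second
#' stage is an empty field.
#'
#' @param seq A `stim_seq` (or plain event tibble) to write.
#' @param path File path.
#' @return `read_events()` returns a `stim_seq`; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(seq, path) {
  readr::write_csv(tibble::as_tibble(seq)[EVENT_COLS], path, na = "")
  invisible(path)
}

#' @rdname write_events
#' @param paradigm,soa_s,seed Metadata to attach on read (the CSV carries
#'   only the event table itself).
#' @export
read_events <- function(path, paradigm = "imported", soa_s = NA_real_, seed = NA_integer_) {
  ev <- readr::read_csv(path, col_types = readr::cols(
    onset_s = "d", duration_s = "d", intensity_db = "d", intensity2_db = "d",
    change_s = "d", band_lo_hz = "d", band_hi_hz = "d", role = "c",
    trial_index = "i"
  ))
  new_stim_seq(ev, paradigm = paradigm, soa_s = soa_s, seed = seed)
}

# Checked fast tibble construction for hot paths (equal-length columns).
tbl_fast <- function(cols) {
  tibble::new_tibble(cols, nrow = length(cols[[1]]))
}

# Run code under a temporary RNG state (seed = NULL leaves the RNG alone).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
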