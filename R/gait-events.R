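#' Detect heel strikes from a vertical ground reaction force trace
#'
#' A heel strike is the instant at which the vertical ground reaction
#' force exceeds a threshold (strictly greater than 50 N by default) and
#' remains above it for at least a persistence time (200 ms). The event
#' time is the first suprathreshold sample of the run, at the trace's own
#' sampling granularity; runs already above threshold at the start of the
#' trace carry no upward crossing and are ignored.
#'
#' @param vgrf numeric vector, vertical ground reaction force in N.
#' @param fs sampling rate in Hz.
#' @param threshold force threshold in N (default 50).
#' @param persist_ms minimum suprathreshold duration in ms (default 200).
#' @param time optional time vector matching `vgrf`; defaults to
#'   `(seq_along(vgrf) - 1) / fs`.
#' @return numeric vector of heel-strike times, s.
#' @export
detect_heel_strikes <- function(vgrf, fs, threshold = 50, persist_ms = 200,
                                time = NULL) {
  event_crossings(vgrf, fs, threshold, persist_ms, time, above = TRUE)
}

#' Detect toe offs from a vertical ground reaction force trace
#'
#' Mirror of [detect_heel_strikes()]: a toe off is the instant the
#' vertical force drops below the threshold and remains below it for at
#' least the persistence time. The event time is the first subthreshold
#' sample; runs already below threshold at the start of the trace are
#' ignored (no downward crossing).
#'
#' @inheritParams detect_heel_strikes
#' @return numeric vector of toe-off times, s.
#' @export
detect_toe_offs <- function(vgrf, fs, threshold = 50, persist_ms = 200,
                            time = NULL) {
  event_crossings(vgrf, fs, threshold, persist_ms, time, above = FALSE)
}

event_crossings <- function(vgrf, fs, threshold, persist_ms, time, above) {
  stopifnot(fs > 0)
  n <- length(vgrf)
  if (n == 0L) stop("empty force trace")
  persist_n <- ceiling(persist_ms / 1000 * fs)
  if (n <= persist_n) stop("trace shorter than the persistence window")
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  state <- if (above) vgrf > threshold else vgrf < threshold
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= persist_n & starts > 1L
  time[starts[ok]]
}

#' Pair heel-strike and toe-off events into alternating sequences
#'
#' Enforces the within-leg alternation invariant (HS, TO, HS, TO, ...):
#' starting from the first heel strike, each heel strike must be followed
#' by exactly one toe off before the next heel strike. Events violating
#' alternation (e.g. two consecutive heel strikes from a missed toe off)
#' are dropped and counted, as are unpaired leading/trailing events.
#'
#' @param hs_times,to_times sorted numeric vectors of candidate event
#'   times, s.
#' @return a list with `hs` and `to` (equal-length alternating times, each
#'   `hs[i] < to[i] < hs[i+1]`) and `dropped`, the number of discarded
#'   events.
#' @export
pair_events <- function(hs_times, to_times) {
  stopifnot(!is.unsorted(hs_times), !is.unsorted(to_times))
  dropped <- 0L
  hs_keep <- numeric(0)
  to_keep <- numeric(0)
  i <- 1L; j <- 1L
  nh <- length(hs_times); nt <- length(to_times)
  ## discard toe offs before the first heel strike
  while (j <= nt && nh >= 1L && to_times[j] <= hs_times[1]) {
    j <- j + 1L; dropped <- dropped + 1L
  }
  while (i <= nh) {
    hs <- hs_times[i]
    nxt_hs <- if (i < nh) hs_times[i + 1L] else Inf
    ## toe offs between this heel strike and the next
    js <- j
    while (j <= nt && to_times[j] < nxt_hs) j <- j + 1L
    n_to <- j - js
    if (n_to == 0L) {
      ## missed toe off: stance unpaired, drop this heel strike
      dropped <- dropped + 1L
    } else {
      hs_keep <- c(hs_keep, hs)
      to_keep <- c(to_keep, to_times[js])
      dropped <- dropped + (n_to - 1L)     # surplus toe offs
    }
    i <- i + 1L
  }
  list(hs = hs_keep, to = to_keep, dropped = dropped)
}

#' Linearly interpolate short marker gaps
#'
#' Gaps (runs of missing samples) strictly shorter than `max_gap` samples
#' are filled by per-coordinate linear interpolation; longer gaps, and
#' gaps touching the trace boundary, are left missing. Applying the
#' function twice gives the same result as applying it once.
#'
#' @param track data frame with a `time_s` column and coordinate columns
#'   (any of `x`/`y`/`z` suffixes); missing samples are `NA`.
#' @param max_gap maximum gap length in samples; gaps of exactly
#'   `max_gap` samples are not filled (default 25, i.e. gaps under 50 ms
#'   at 500 Hz are repaired).
#' @return the track with short gaps filled; attribute `"gaps"` holds a
#'   data frame `(column, start, length, filled)` describing every gap.
#' @export
interpolate_gaps <- function(track, max_gap = 25L) {
  stopifnot(is.data.frame(track), "time_s" %in% names(track))
  dt <- diff(track$time_s)
  if (any(abs(dt - dt[1]) > 1e-6))
    stop("marker track must be uniformly sampled")
  gap_log <- list()
  for (col in setdiff(names(track), "time_s")) {
    x <- track[[col]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      warning("column '", col, "' is entirely missing; left unchanged")
      gap_log[[length(gap_log) + 1L]] <-
        data.frame(column = col, start = 1L, length = length(x),
                   filled = FALSE)
      next
    }
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      len <- r$lengths[g]
      interior <- starts[g] > 1L && ends[g] < length(x)
      fill <- interior && len < max_gap
      if (fill) {
        i0 <- starts[g] - 1L; i1 <- ends[g] + 1L
        idx <- starts[g]:ends[g]
        x[idx] <- x[i0] + (x[i1] - x[i0]) * (idx - i0) / (i1 - i0)
      }
      gap_log[[length(gap_log) + 1L]] <-
        data.frame(column = col, start = starts[g], length = len,
                   filled = fill)
    }
    track[[col]] <- x
  }
  attr(track, "gaps") <- if (length(gap_log)) do.call(rbind, gap_log) else
    data.frame(column = character(), start = integer(),
               length = integer(), filled = logical())
  track
}

#' Detect and pair gait events for both legs of a trial
#'
#' Convenience wrapper: low-pass filters the force traces (once), runs
#' threshold/persistence heel-strike and toe-off detection per leg, and
#' enforces alternation via [pair_events()].
#'
#' @param trial a `gait_trial`.
#' @return a list of class `gait_events` with per-leg elements `L` and
#'   `R`, each a list `(hs, to, dropped)`.
#' @export
detect_gait_events <- function(trial) {
  stopifnot(inherits(trial, "gait_trial"))
  trial <- filter_forces(trial)
  fs <- trial$meta$rates$force_hz
  out <- list()
  for (leg in c("L", "R")) {
    vg <- trial$forces[[paste0("fz_", leg)]]
    hs <- detect_heel_strikes(vg, fs, time = trial$forces$time_s)
    to <- detect_toe_offs(vg, fs, time = trial$forces$time_s)
    out[[leg]] <- pair_events(hs, to)
  }
  class(out) <- "gait_events"
  out
}
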