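#' Peak anterior ground reaction force
#'
#' The maximum of the anterior (positive) component of the
#' antero-posterior ground reaction force within a gait cycle, normalized
#' by bodyweight. Returns 0 when the segment has no positive samples
#' (an all-braking cycle).
#'
#' @param ap_grf numeric vector, antero-posterior force over one gait
#'   cycle, N (anterior positive).
#' @param bodyweight_N bodyweight in N (> 0).
#' @return peak anterior force as a fraction of bodyweight.
#' @export
peak_agrf <- function(ap_grf, bodyweight_N) {
  if (!length(ap_grf)) stop("empty force segment")
  stopifnot(bodyweight_N > 0)
  max(c(ap_grf, 0)) / bodyweight_N
}

#' Propulsive impulse
#'
#' The area under the positive (anterior) portion of the antero-posterior
#' ground reaction force over a gait cycle, by trapezoidal integration,
#' normalized by bodyweight. Units: bodyweight-seconds.
#'
#' @inheritParams peak_agrf
#' @param fs sampling rate of the segment, Hz.
#' @return propulsive impulse in BW·s (>= 0).
#' @export
propulsive_impulse <- function(ap_grf, fs, bodyweight_N) {
  if (!length(ap_grf)) stop("empty force segment")
  stopifnot(fs > 0, bodyweight_N > 0)
  pos <- pmax(ap_grf, 0)
  if (length(pos) == 1L) return(0)
  sum((pos[-1] + pos[-length(pos)]) / 2) / fs / bodyweight_N
}

#' Trailing limb angle
#'
#' The sagittal-plane angle between the vertical and the hip-to-ankle
#' line, evaluated at toe off: positive when the ankle is posterior to
#' the hip (trailing limb extended behind the body), so a larger angle
#' reflects a better push-off posture. Invariant to translating both
#' markers by the same offset and to scaling both about their midpoint.
#'
#' @param hip,ankle numeric length-3 vectors `(x, y, z)` in m, with `x`
#'   the antero-posterior axis (anterior positive) and `z` vertical (up).
#' @return angle in degrees.
#' @export
trailing_limb_angle <- function(hip, ankle) {
  stopifnot(length(hip) == 3L, length(ankle) == 3L)
  dx <- hip[[1]] - ankle[[1]]     # positive when ankle posterior
  dz <- hip[[3]] - ankle[[3]]
  if (abs(dx) < 1e-12 && abs(dz) < 1e-12)
    stop("hip and ankle markers coincide")
  atan2(dx, dz) * 180 / pi
}

#' Stride length on a treadmill
#'
#' The distance between the start and end location of a stride: the
#' change in antero-posterior ankle-marker position between consecutive
#' ipsilateral heel strikes plus the belt travel integrated between them,
#' `SL = dP_HS + integral(v dt)`.
#'
#' @param ankle_ap data frame with columns `time_s` and `x` (ankle
#'   antero-posterior position, m); `NA` positions at a heel strike cause
#'   the stride to be flagged.
#' @param events list with `hs`, ordered heel-strike times of the leg, s.
#' @param belt_speed data frame `(time_s, v)` with belt speed covering
#'   the strides, m/s.
#' @return data frame `(stride, t_hs, t_hs_next, sl, valid)`, one row per
#'   stride; `sl` is `NA` and `valid` `FALSE` where the marker is missing
#'   at either heel strike.
#' @export
stride_length <- function(ankle_ap, events, belt_speed) {
  hs <- events$hs
  if (length(hs) < 2L)
    return(data.frame(stride = integer(), t_hs = numeric(),
                      t_hs_next = numeric(), sl = numeric(),
                      valid = logical()))
  if (min(belt_speed$time_s) > min(hs) || max(belt_speed$time_s) < max(hs))
    stop("belt trace does not cover the stride interval")
  xf <- stats::approxfun(ankle_ap$time_s, ankle_ap$x)
  tb <- belt_speed$time_s
  B <- c(0, cumsum((belt_speed$v[-1] + belt_speed$v[-length(tb)]) / 2 *
                     diff(tb)))
  Bf <- stats::approxfun(tb, B, rule = 2)
  n <- length(hs) - 1L
  x_hs <- xf(hs)
  sl <- (x_hs[-1] - x_hs[-(n + 1L)]) + (Bf(hs[-1]) - Bf(hs[-(n + 1L)]))
  data.frame(stride = seq_len(n), t_hs = hs[-(n + 1L)], t_hs_next = hs[-1],
             sl = sl, valid = !is.na(sl))
}

#' Mean belt speed over each gait cycle
#'
#' Stride velocity is the average belt speed between consecutive
#' ipsilateral heel strikes.
#'
#' @inheritParams stride_length
#' @return numeric vector, one mean speed per stride, m/s.
#' @export
stride_velocity <- function(belt_speed, events) {
  hs <- events$hs
  if (length(hs) < 2L) return(numeric(0))
  tb <- belt_speed$time_s
  B <- c(0, cumsum((belt_speed$v[-1] + belt_speed$v[-length(tb)]) / 2 *
                     diff(tb)))
  Bf <- stats::approxfun(tb, B, rule = 2)
  (Bf(hs[-1]) - Bf(hs[-length(hs)])) / diff(hs)
}

#' Stride and stance durations
#'
#' Stride duration is the interval between consecutive ipsilateral heel
#' strikes; stance duration is the interval from a heel strike to the
#' same leg's toe off. A stride with a missing toe off keeps its stride
#' duration and gets an `NA` stance duration.
#'
#' @param events list with ordered, paired `hs` and `to` times for one
#'   leg (as returned by [pair_events()]).
#' @return data frame `(stride, stride_duration, stance_duration)`.
#' @export
stride_durations <- function(events) {
  hs <- events$hs; to <- events$to
  n <- length(hs) - 1L
  if (n < 1L)
    return(data.frame(stride = integer(), stride_duration = numeric(),
                      stance_duration = numeric()))
  stance <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    j <- which(to > hs[k] & to < hs[k + 1L])
    if (length(j)) stance[k] <- to[j[1]] - hs[k]
  }
  data.frame(stride = seq_len(n), stride_duration = diff(hs),
             stance_duration = stance)
}

#' Per-stride propulsion metrics for a trial
#'
#' Computes the full per-stride outcome table for both legs: peak
#' anterior ground reaction force and propulsive impulse (bodyweight
#' normalized, over each heel-strike-to-heel-strike cycle), trailing limb
#' angle at toe off, stride length, stride velocity, and durations.
#' Forces are low-pass filtered once upstream; marker gaps under 25
#' samples are repaired before use.
#'
#' @param trial a `gait_trial`.
#' @param events a `gait_events` object from [detect_gait_events()];
#'   computed if missing.
#' @return data frame with one row per stride per leg: `leg`, `role`
#'   (`paretic`/`nonparetic`), `stride`, `t_hs`, `t_to`, `t_hs_next`,
#'   `peak_agrf` (fraction of BW), `pi` (BW·s), `tla` (deg), `sl` (m),
#'   `velocity` (m/s), `stride_duration`, `stance_duration` (s).
#' @export
stride_metrics <- function(trial, events = NULL) {
  stopifnot(inherits(trial, "gait_trial"))
  trial <- filter_forces(trial)
  if (is.null(events)) events <- detect_gait_events(trial)
  bw <- trial$meta$bodyweight_N
  fs <- trial$meta$rates$force_hz
  mk <- interpolate_gaps(trial$markers)
  out <- list()
  for (leg in c("L", "R")) {
    ev <- events[[leg]]
    n <- length(ev$hs) - 1L
    if (n < 1L) next
    dur <- stride_durations(ev)
    ank <- data.frame(time_s = mk$time_s, x = mk[[paste0("LM_", leg, "_x")]])
    belt <- data.frame(time_s = trial$belt$time_s,
                       v = trial$belt[[paste0("v_", leg)]])
    sl <- stride_length(ank, ev, belt)
    vel <- stride_velocity(belt, ev)
    hipx <- stats::approxfun(mk$time_s, mk[[paste0("GT_", leg, "_x")]])
    hipz <- stats::approxfun(mk$time_s, mk[[paste0("GT_", leg, "_z")]])
    ankx <- stats::approxfun(mk$time_s, mk[[paste0("LM_", leg, "_x")]])
    ankz <- stats::approxfun(mk$time_s, mk[[paste0("LM_", leg, "_z")]])
    fy <- trial$forces[[paste0("fy_", leg)]]
    tf <- trial$forces$time_s
    pk <- pi_v <- tla <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      idx <- which(tf >= ev$hs[k] & tf < ev$hs[k + 1L])
      seg <- fy[idx]
      pk[k] <- peak_agrf(seg, bw)
      pi_v[k] <- propulsive_impulse(seg, fs, bw)
      to_k <- ev$to[k]
      if (!is.na(to_k)) {
        h <- c(hipx(to_k), 0, hipz(to_k))
        a <- c(ankx(to_k), 0, ankz(to_k))
        if (!anyNA(c(h, a))) tla[k] <- trailing_limb_angle(h, a)
      }
    }
    role <- if (leg == trial$meta$paretic_side) "paretic" else "nonparetic"
    out[[leg]] <- data.frame(
      leg = leg, role = role, stride = seq_len(n),
      t_hs = ev$hs[seq_len(n)], t_to = ev$to[seq_len(n)],
      t_hs_next = ev$hs[-1],
      peak_agrf = pk, pi = pi_v, tla = tla, sl = sl$sl, velocity = vel,
      stride_duration = dur$stride_duration,
      stance_duration = dur$stance_duration)
  }
  do.call(rbind, out)
}
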