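#' EMG linear envelope
#'
#' Band-pass filters the raw EMG at 20–500 Hz (4th-order zero-shift
#' Butterworth), full-wave rectifies, and low-pass filters at 10 Hz
#' (4th-order zero-shift Butterworth). Residual negative values from
#' filter ringing are clipped at zero.
#'
#' @param raw numeric vector, raw EMG.
#' @param fs sampling rate, Hz; must exceed 1000 Hz so the 500 Hz band
#'   edge lies below Nyquist.
#' @param band band-pass edges, Hz.
#' @param lowpass envelope cutoff, Hz.
#' @return non-negative envelope, same length as `raw`.
#' @export
emg_envelope <- function(raw, fs, band = c(20, 500), lowpass = 10) {
  if (fs <= 1000)
    stop("EMG sampling rate must exceed 1000 Hz for a 20-500 Hz band")
  x <- butter_zero_shift(raw, fs, band, "pass")
  pmax(butter_zero_shift(abs(x), fs, lowpass, "low"), 0)
}

#' Resample an envelope stride onto a fixed phase grid
#'
#' Segments one stride of an envelope by gait events and linearly
#' resamples each phase to exactly 100 points. Two schemes are used:
#' `"stance_swing"` (plantarflexors, and tibialis anterior for the
#' co-contraction index) concatenates 0–100% of stance and 0–100% of
#' swing (200 points); `"ta"` concatenates 0–100% of double support
#' (heel strike to contralateral toe off), 0–100% between the two legs'
#' toe offs, and 0–100% of swing (300 points).
#'
#' @param envelope data frame `(time_s, value)`, the envelope trace.
#' @param stride_events list with `hs`, `to`, `hs_next` (s) and, for the
#'   `"ta"` scheme, `to_contra` (contralateral toe off inside the
#'   stride).
#' @param scheme `"stance_swing"` or `"ta"`.
#' @return an object of class `envelope_stride`: list with `samples`
#'   (length 200 or 300), `phase_breaks` (segment boundary indices) and
#'   `scheme`.
#' @export
resample_stride <- function(envelope, stride_events,
                            scheme = c("stance_swing", "ta")) {
  scheme <- match.arg(scheme)
  ev <- stride_events
  need <- if (scheme == "ta") c("hs", "to", "hs_next", "to_contra")
          else c("hs", "to", "hs_next")
  miss <- vapply(need, function(f) is.null(ev[[f]]) || is.na(ev[[f]]),
                 logical(1))
  if (any(miss))
    stop("missing events for stride: ", paste(need[miss], collapse = ", "))
  ef <- stats::approxfun(envelope$time_s, envelope$value, rule = 2)
  resample_segments(ef, ev, scheme)
}

## fast path sharing one interpolator across strides of a channel
resample_segments <- function(ef, ev, scheme) {
  segs <- if (scheme == "ta") {
    if (!(ev$hs < ev$to_contra && ev$to_contra < ev$to && ev$to < ev$hs_next))
      stop("stride events out of order")
    list(c(ev$hs, ev$to_contra), c(ev$to_contra, ev$to), c(ev$to, ev$hs_next))
  } else {
    if (!(ev$hs < ev$to && ev$to < ev$hs_next))
      stop("stride events out of order")
    list(c(ev$hs, ev$to), c(ev$to, ev$hs_next))
  }
  samples <- unlist(lapply(segs, function(s)
    ef(seq(s[1], s[2], length.out = 100))))
  out <- list(samples = samples,
              phase_breaks = seq_len(length(segs) - 1L) * 100L,
              scheme = scheme)
  class(out) <- "envelope_stride"
  out
}

## region-of-interest indices within a resampled stride
roi_indices <- function(muscle, scheme) {
  if (muscle %in% c("SOL", "LGAS", "MGAS", "TACC")) {
    stopifnot(scheme == "stance_swing")
    51:100                      # second half of stance
  } else if (muscle == "TA") {
    stopifnot(scheme == "ta")
    list(swing = 201:300, ds = 1:100)
  } else stop("unknown muscle: ", muscle)
}

#' Region-of-interest activation of a resampled stride
#'
#' Plantarflexor activation (and the tibialis anterior co-contraction
#' index TACC) is the mean envelope over the second half of stance.
#' Tibialis anterior activation is the mean envelope surrounding heel
#' strike: this stride's swing segment plus the following stride's
#' double-support segment (pass it as `next_stride`); without a following
#' stride the activation is `NA`.
#'
#' @param stride an [resample_stride()] result.
#' @param muscle one of `"SOL"`, `"LGAS"`, `"MGAS"`, `"TA"`, `"TACC"`.
#' @param next_stride the next stride's `envelope_stride` (`"ta"`
#'   scheme), required for `muscle = "TA"`.
#' @return list `(value, roi, roi_peak)`: the mean activation, the ROI
#'   label, and the maximum envelope within the ROI (used for baseline
#'   normalization).
#' @export
roi_activation <- function(stride, muscle, next_stride = NULL) {
  if (muscle %in% c("SOL", "LGAS", "MGAS", "TACC")) {
    idx <- roi_indices(muscle, stride$scheme)
    vals <- stride$samples[idx]
    list(value = mean(vals), roi = "second_half_stance",
         roi_peak = max(vals))
  } else if (muscle == "TA") {
    stopifnot(stride$scheme == "ta")
    idx <- roi_indices("TA", "ta")
    if (is.null(next_stride))
      return(list(value = NA_real_, roi = "swing_plus_double_support",
                  roi_peak = NA_real_))
    stopifnot(next_stride$scheme == "ta")
    vals <- c(stride$samples[idx$swing], next_stride$samples[idx$ds])
    list(value = mean(vals), roi = "swing_plus_double_support",
         roi_peak = max(vals))
  } else stop("unknown muscle: ", muscle)
}

#' Normalize activations by baseline peak activation
#'
#' The divisor is the mean, over the baseline strides, of each stride's
#' maximum envelope within the region of interest; every activation is
#' divided by it. Doubling the raw gain therefore leaves normalized
#' activations unchanged.
#'
#' @param activations numeric vector of per-stride ROI-mean activations.
#' @param roi_peaks numeric vector of per-stride ROI-maximum envelope
#'   values (same length).
#' @param baseline_idx indices of the baseline strides (after outlier
#'   removal).
#' @return list `(values, baseline_norm, usable)`; when the divisor is
#'   (numerically) zero — a flatline channel — `usable` is `FALSE` and
#'   values are `NA`.
#' @export
normalize_activation <- function(activations, roi_peaks, baseline_idx) {
  stopifnot(length(activations) == length(roi_peaks))
  baseline_idx <- baseline_idx[!is.na(roi_peaks[baseline_idx])]
  if (!length(baseline_idx))
    stop("no baseline strides available for normalization")
  divisor <- mean(roi_peaks[baseline_idx])
  if (!is.finite(divisor) || divisor <= 1e-12) {
    warning("flatline channel: baseline peak activation is zero; ",
            "channel flagged unusable")
    return(list(values = rep(NA_real_, length(activations)),
                baseline_norm = divisor, usable = FALSE))
  }
  list(values = activations / divisor, baseline_norm = divisor,
       usable = TRUE)
}

## one screening pass: trim the top and bottom 5% of the statistic, take
## mean and sd of the remainder, flag values beyond 10 sd (two-sided)
screen_pass <- function(stat, n_sd = 10, trim = 0.05) {
  ok <- !is.na(stat)
  n <- sum(ok)
  if (n < 3L) return(rep(FALSE, length(stat)))
  k <- ceiling(trim * n)
  srt <- sort(stat[ok])
  trimmed <- if (n - 2L * k >= 2L) srt[(k + 1L):(n - k)] else srt
  m <- mean(trimmed)
  s <- stats::sd(trimmed)
  ## dispersion at numerical precision is treated as zero (identical
  ## strides must produce no removals)
  if (!is.finite(s) || s <= 1e-8 * (abs(m) + 1e-12))
    return(rep(FALSE, length(stat)))
  out <- rep(FALSE, length(stat))
  out[ok] <- stat[ok] < m - n_sd * s | stat[ok] > m + n_sd * s
  out
}

#' Automatic stride-outlier removal for EMG envelopes
#'
#' Screens the per-stride resampled envelopes of one muscle with three
#' parallel passes, each trimming the top and bottom 5% of its statistic
#' before computing mean and standard deviation and flagging strides
#' whose untrimmed statistic lies beyond 10 standard deviations
#' (two-sided): (1) the maximum envelope within the region of interest,
#' (2) the mean envelope within the region of interest, (3) the value at
#' each point of the stride (one screen per point; any flagged point
#' flags the stride). The passes are evaluated on the original stride
#' set and their flags are combined, making the result independent of
#' pass order. Identical strides (zero dispersion) produce no removals.
#'
#' @param stride_matrix numeric matrix, strides in rows (200 or 300
#'   columns).
#' @param roi_idx integer indices of the region of interest within a row.
#' @param n_sd flagging threshold in standard deviations (default 10).
#' @param trim tail fraction trimmed before mean/sd (default 0.05).
#' @return logical keep mask (length `nrow(stride_matrix)`; `TRUE` =
#'   stride survives all passes).
#' @export
remove_outlier_strides <- function(stride_matrix, roi_idx, n_sd = 10,
                                   trim = 0.05) {
  stopifnot(is.matrix(stride_matrix))
  n <- nrow(stride_matrix)
  if (n < 5L) stop("outlier screening needs at least 5 strides")
  roi <- stride_matrix[, roi_idx, drop = FALSE]
  f_max <- screen_pass(apply(roi, 1L, max), n_sd, trim)
  f_mean <- screen_pass(rowMeans(roi), n_sd, trim)
  f_point <- rep(FALSE, n)
  for (j in seq_len(ncol(stride_matrix))) {
    f_point <- f_point | screen_pass(stride_matrix[, j], n_sd, trim)
  }
  !(f_max | f_mean | f_point)
}

#' EMG activations for a trial
#'
#' Full EMG pipeline for all eight channels: envelope extraction, stride
#' segmentation and phase resampling (200-point stance/swing scheme for
#' SOL/LGAS/MGAS and for the TA co-contraction index TACC; 300-point
#' double-support/inter-toe-off/swing scheme for TA), automatic
#' stride-outlier removal per muscle, region-of-interest activation, and
#' baseline-peak normalization.
#'
#' @param trial a `gait_trial`.
#' @param events a `gait_events` object; computed if missing.
#' @param baseline_window length-2 time window (s) whose strides define
#'   the normalization baseline; default: the first 60 s of the trial.
#'   Only baseline strides surviving outlier removal feed the divisor.
#' @param remove_outliers logical; set `FALSE` to skip the automatic
#'   stride screening (all strides kept).
#' @return data frame with one row per stride, leg and muscle (muscles
#'   SOL, LGAS, MGAS, TA, TACC): `raw` (ROI mean), `normalized`,
#'   `roi_peak`, `outlier` (flag from the muscle's screening),
#'   `channel_usable`.
#' @export
emg_activations <- function(trial, events = NULL, baseline_window = NULL,
                            remove_outliers = TRUE) {
  stopifnot(inherits(trial, "gait_trial"))
  if (is.null(events)) events <- detect_gait_events(trial)
  fs <- trial$meta$rates$emg_hz
  if (is.null(baseline_window))
    baseline_window <- c(0, min(60, trial$meta$duration_s))
  out <- list()
  for (leg in c("L", "R")) {
    ev <- events[[leg]]
    contra <- setdiff(c("L", "R"), leg)
    ev_c <- events[[contra]]
    n <- length(ev$hs) - 1L
    if (n < 1L) next
    ## contralateral toe off within each stride's double support
    to_c <- vapply(seq_len(n + 1L), function(k) {
      h <- ev$hs[k]
      j <- which(ev_c$to >= h)
      if (length(j) && (k > n || ev_c$to[j[1]] < ev$hs[k + 1L]))
        ev_c$to[j[1]] else NA_real_
    }, numeric(1))
    for (mus in c("SOL", "LGAS", "MGAS", "TA")) {
      ef <- stats::approxfun(
        trial$emg$time_s,
        emg_envelope(trial$emg[[paste(mus, leg, sep = "_")]], fs),
        rule = 2)
      schemes <- if (mus == "TA") c("stance_swing", "ta") else "stance_swing"
      mats <- list()
      for (sch in schemes) {
        rows <- lapply(seq_len(n), function(k) {
          sev <- list(hs = ev$hs[k], to = ev$to[k], hs_next = ev$hs[k + 1L],
                      to_contra = to_c[k])
          tryCatch(resample_segments(ef, sev, sch)$samples,
                   error = function(e) NULL)
        })
        ok <- !vapply(rows, is.null, logical(1))
        m <- matrix(NA_real_, nrow = n,
                    ncol = if (sch == "ta") 300L else 200L)
        if (any(ok)) m[ok, ] <- do.call(rbind, rows[ok])
        mats[[sch]] <- m
      }
      report <- if (mus == "TA") c("TA", "TACC") else mus
      for (rep_mus in report) {
        sch <- if (rep_mus == "TA") "ta" else "stance_swing"
        m <- mats[[sch]]
        complete <- stats::complete.cases(m)
        keep <- rep(TRUE, n)
        if (remove_outliers && sum(complete) >= 5L) {
          ridx <- if (rep_mus == "TA") {
            ri <- roi_indices("TA", "ta"); c(ri$ds, ri$swing)
          } else roi_indices(rep_mus, "stance_swing")
          keep[complete] <- remove_outlier_strides(
            m[complete, , drop = FALSE], ridx)
        }
        raw <- peaks <- rep(NA_real_, n)
        for (k in seq_len(n)) {
          if (!complete[k]) next
          stride_k <- list(samples = m[k, ], scheme = sch)
          class(stride_k) <- "envelope_stride"
          nxt <- if (rep_mus == "TA" && k < n && complete[k + 1L]) {
            s2 <- list(samples = m[k + 1L, ], scheme = sch)
            class(s2) <- "envelope_stride"
            s2
          } else NULL
          act <- roi_activation(stride_k, rep_mus, nxt)
          raw[k] <- act$value
          peaks[k] <- act$roi_peak
        }
        bl <- which(ev$hs[seq_len(n)] >= baseline_window[1] &
                      ev$hs[seq_len(n)] < baseline_window[2] & keep &
                      !is.na(peaks))
        norm <- if (length(bl)) {
          normalize_activation(raw, peaks, bl)
        } else {
          list(values = rep(NA_real_, n), baseline_norm = NA_real_,
               usable = FALSE)
        }
        out[[length(out) + 1L]] <- data.frame(
          leg = leg, muscle = rep_mus, stride = seq_len(n),
          t_hs = ev$hs[seq_len(n)],
          raw = raw, normalized = norm$values, roi_peak = peaks,
          outlier = !keep, channel_usable = norm$usable)
      }
    }
  }
  do.call(rbind, out)
}
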