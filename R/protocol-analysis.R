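#' Assign strides to protocol time-point bins
#'
#' Bins per-stride outcomes into the protocol's five time points:
#' Baseline (BL, strides whose heel strike falls in the last 60 s of the
#' baseline phase), Early Exposure (EE, first 20 exposure strides), Late
#' Exposure (LE, last 20 exposure strides), Early Post-Exposure (EPE,
#' first 25% of post-exposure strides) and Late Post-Exposure (LPE, last
#' 25%). Exposure starts at full acceleration magnitude (after the
#' ramp). Percent bins use `floor(0.25 n)` strides with a minimum of 1.
#' If the exposure phase has fewer than 40 strides, EE and LE overlap
#' and the result carries the attribute `overlap = TRUE`.
#'
#' @param strides data frame with columns `t_hs` (heel-strike time, s)
#'   and optionally `leg` (bins are computed within each leg).
#' @param phase_bounds named numeric vector with the phase end times, s:
#'   `baseline`, `ramp`, `exposure`, `post` (as produced by
#'   [simulate_session()]).
#' @param bl_window length of the baseline window before the ramp, s
#'   (default 60).
#' @return the input data frame with added columns `phase` (`baseline`,
#'   `ramp`, `exposure`, `post`) and `bin` (`BL`, `EE`, `LE`, `EPE`,
#'   `LPE` or `NA`); EE/LE overlap strides are labeled `EE`, with the
#'   full assignment in attribute `"bins"` (a list of row-index sets).
#' @export
bin_timepoints <- function(strides, phase_bounds, bl_window = 60) {
  stopifnot(all(c("baseline", "ramp", "exposure", "post") %in%
                  names(phase_bounds)))
  t_bl <- phase_bounds[["baseline"]]
  t_rp <- phase_bounds[["ramp"]]
  t_ex <- phase_bounds[["exposure"]]
  t_po <- phase_bounds[["post"]]
  th <- strides$t_hs
  phase <- ifelse(th < t_bl, "baseline",
                  ifelse(th < t_rp, "ramp",
                         ifelse(th < t_ex, "exposure",
                                ifelse(th <= t_po, "post", NA))))
  legs <- if ("leg" %in% names(strides)) strides$leg else rep("all", nrow(strides))
  bin <- rep(NA_character_, nrow(strides))
  sets <- list(BL = integer(), EE = integer(), LE = integer(),
               EPE = integer(), LPE = integer())
  overlap <- FALSE
  for (lg in unique(legs)) {
    li <- which(legs == lg)
    bl <- li[phase[li] == "baseline" & th[li] >= t_bl - bl_window]
    expo <- li[phase[li] == "exposure"]
    post <- li[phase[li] == "post"]
    if (!length(expo)) stop("empty exposure phase for leg ", lg)
    if (!length(post)) stop("empty post-exposure phase for leg ", lg)
    ee <- expo[seq_len(min(20L, length(expo)))]
    le <- expo[seq.int(max(1L, length(expo) - 19L), length(expo))]
    if (length(expo) < 40L) overlap <- TRUE
    np <- max(1L, floor(0.25 * length(post)))
    epe <- post[seq_len(np)]
    lpe <- post[seq.int(length(post) - np + 1L, length(post))]
    sets$BL <- c(sets$BL, bl); sets$EE <- c(sets$EE, ee)
    sets$LE <- c(sets$LE, le); sets$EPE <- c(sets$EPE, epe)
    sets$LPE <- c(sets$LPE, lpe)
    bin[bl] <- "BL"
    bin[le] <- "LE"; bin[ee] <- "EE"      # EE wins on overlap
    bin[lpe] <- "LPE"; bin[epe] <- "EPE"
  }
  strides$phase <- phase
  strides$bin <- bin
  attr(strides, "bins") <- sets
  attr(strides, "overlap") <- overlap
  strides
}

#' Resample a per-stride series onto 0-100% of post-exposure
#'
#' Post-exposure durations differ across sessions, so stride-indexed
#' post-exposure outcomes are linearly interpolated onto a common
#' 0–100% axis before averaging across sessions.
#'
#' @param series numeric vector, one value per post-exposure stride (at
#'   least 2).
#' @param n_points number of output points spanning 0–100% (default 100).
#' @return numeric vector of length `n_points`.
#' @export
resample_post_exposure <- function(series, n_points = 100L) {
  series <- as.numeric(series)
  if (length(series) < 2L) stop("need at least 2 post-exposure strides")
  x <- seq(0, 100, length.out = length(series))
  stats::approx(x, series, xout = seq(0, 100, length.out = n_points))$y
}

#' Per-bin summaries and change from baseline
#'
#' Averages an outcome across the strides of each time-point bin and
#' reports the change of each bin mean from the baseline bin, with
#' stride-count-weighted standard errors
#' (`sqrt(sd_bin^2 / n_bin + sd_BL^2 / n_BL)`).
#'
#' @param strides a data frame from [bin_timepoints()] (columns `bin`,
#'   `leg` optional).
#' @param outcome name of the outcome column to summarize.
#' @return data frame `(leg, bin, n, mean, se, delta_from_BL, delta_se)`;
#'   `delta_from_BL` is 0 for BL by construction.
#' @export
change_from_baseline <- function(strides, outcome) {
  stopifnot(outcome %in% names(strides), "bin" %in% names(strides))
  legs <- if ("leg" %in% names(strides)) unique(strides$leg) else "all"
  lcol <- if ("leg" %in% names(strides)) strides$leg else rep("all", nrow(strides))
  out <- list()
  for (lg in legs) {
    rows <- list()
    bl_vals <- strides[[outcome]][lcol == lg & strides$bin %in% "BL"]
    bl_vals <- bl_vals[!is.na(bl_vals)]
    if (!length(bl_vals)) stop("empty baseline bin for leg ", lg)
    m_bl <- mean(bl_vals)
    v_bl <- stats::var(bl_vals) / length(bl_vals)
    for (b in c("BL", "EE", "LE", "EPE", "LPE")) {
      vals <- strides[[outcome]][lcol == lg & strides$bin %in% b]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      m <- mean(vals)
      v <- stats::var(vals) / length(vals)
      if (!is.finite(v)) v <- 0
      rows[[b]] <- data.frame(
        leg = lg, bin = b, n = length(vals), mean = m,
        se = sqrt(v),
        delta_from_BL = if (b == "BL") 0 else m - m_bl,
        delta_se = if (b == "BL") 0 else sqrt(v + v_bl))
    }
    out[[lg]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age-predicted maximum heart rate and safety threshold
#'
#' `HRmax = 220 - age`; the protocol's cardiovascular safety threshold is
#' 85% of it. Ages outside the study's inclusion range (18–85 years)
#' produce a warning but are still computed.
#'
#' @param age age in years.
#' @param frac threshold fraction of `HRmax` (default 0.85).
#' @return `hr_max()`: maximum heart rate, bpm. `hr_threshold()`: the
#'   safety threshold, bpm.
#' @export
hr_max <- function(age) {
  if (any(age < 18 | age > 85))
    warning("age outside the 18-85 year inclusion range")
  220 - age
}

#' @rdname hr_max
#' @export
hr_threshold <- function(age, frac = 0.85) {
  frac * hr_max(age)
}

#' Bonferroni-corrected significance threshold
#'
#' Familywise threshold for `k` planned contrasts: `alpha / k` (0.0125
#' for four contrasts at alpha = 0.05).
#'
#' @param alpha familywise error rate, in (0, 1).
#' @param k number of contrasts (>= 1).
#' @return per-contrast p-value threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, k = 4L) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  alpha / k
}
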