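#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

default_emg_bursts <- function() {
  data.frame(
    muscle = c("SOL", "LGAS", "MGAS", "TA", "TA"),
    center = c(45, 42, 43, 95, 62),
    width  = c(8, 8, 8, 6, 6),
    amp    = c(1.0, 0.9, 0.9, 0.8, 0.6),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic gait generator
#'
#' Bundles every parameter of the synthetic walking-trial generator:
#' treadmill speed, cadence and its variability, per-leg stance fractions
#' and phase offset (which jointly determine double-support duration),
#' ground-reaction-force amplitudes, trailing-limb geometry, phase-locked
#' EMG burst parameters, and noise levels. Defaults emulate a hemiparetic
#' walker (paretic side `"L"`): reduced paretic propulsive force and
#' trailing limb angle, self-selected speed 0.7 m/s.
#'
#' @param base_speed treadmill belt speed, m/s (> 0).
#' @param duration_s trial duration, s.
#' @param stride_duration_mean per-leg named vector `c(L=, R=)`, s. The two
#'   legs of one walker share long-run cadence, so the common gait-cycle
#'   duration is the mean of the two entries (a warning is issued if they
#'   differ); express asymmetry through `stance_fraction`, `agrf_peak_frac`
#'   and `tla_deg` instead.
#' @param stride_duration_cv coefficient of variation of stride duration
#'   (>= 0); stride-to-stride Gaussian variability, truncated at 3 sd.
#' @param stance_fraction per-leg stance duration as a fraction of the gait
#'   cycle, in (0, 1).
#' @param phase_offset fraction of the cycle after a left heel strike at
#'   which the right heel strike occurs, in (0, 1). Double support emerges
#'   from `stance_fraction` and `phase_offset`.
#' @param bodyweight_N bodyweight in newtons.
#' @param agrf_peak_frac per-leg peak anterior (propulsive) ground reaction
#'   force as a fraction of bodyweight.
#' @param brake_peak_frac per-leg peak braking (posterior) force fraction.
#' @param tla_deg per-leg trailing limb angle at toe off, degrees.
#' @param paretic_side `"L"` or `"R"`.
#' @param hip_height,ankle_height marker heights, m.
#' @param swing_lift peak ankle lift during swing, m.
#' @param hip_sway_amp,hip_bob_amp amplitude of hip antero-posterior sway
#'   and vertical bob, m.
#' @param load_ramp_s duration of the raised-cosine loading/unloading ramps
#'   of the vertical ground reaction force, s.
#' @param emg_bursts data frame `(muscle, center, width, amp)` of Gaussian
#'   EMG bursts; `center`/`width` in % of the leg's gait cycle (heel strike
#'   = 0%), `amp` in arbitrary units. A muscle may have several rows.
#' @param emg_carrier_hz named per-muscle carrier frequency, Hz. The
#'   synthetic EMG is a deterministic sinusoidal carrier amplitude-modulated
#'   by the burst profile, so the rectified mean (2/pi x modulation) is
#'   analytic and serves as exact ground truth for activation recovery.
#' @param emg_tonic baseline tonic modulation level, arbitrary units.
#' @param noise_sd list with elements `force` (N), `marker` (m), `emg`
#'   (arbitrary units): additive Gaussian noise standard deviations.
#' @param seed integer RNG seed; identical `(config, seed)` gives
#'   bit-identical trials.
#' @return an object of class `gait_config`.
#' @seealso [generate_trial()], [gait_config_for_speed()]
#' @export
gait_config <- function(base_speed = 0.7,
                        duration_s = 60,
                        stride_duration_mean = c(L = 1.2, R = 1.2),
                        stride_duration_cv = 0.03,
                        stance_fraction = c(L = 0.62, R = 0.62),
                        phase_offset = 0.5,
                        bodyweight_N = 700,
                        agrf_peak_frac = c(L = 0.08, R = 0.12),
                        brake_peak_frac = c(L = 0.08, R = 0.10),
                        tla_deg = c(L = 12, R = 18),
                        paretic_side = "L",
                        hip_height = 0.92,
                        ankle_height = 0.10,
                        swing_lift = 0.08,
                        hip_sway_amp = 0.01,
                        hip_bob_amp = 0.005,
                        load_ramp_s = 0.12,
                        emg_bursts = default_emg_bursts(),
                        emg_carrier_hz = c(SOL = 95, LGAS = 115,
                                           MGAS = 135, TA = 155),
                        emg_tonic = 0.05,
                        noise_sd = list(force = 1, marker = 5e-4,
                                        emg = 0.01),
                        seed = 1L) {
  two <- function(x) {
    if (length(x) == 1L) x <- c(L = unname(x), R = unname(x))
    stopifnot(all(c("L", "R") %in% names(x)))
    x[c("L", "R")]
  }
  stride_duration_mean <- two(stride_duration_mean)
  stance_fraction <- two(stance_fraction)
  agrf_peak_frac <- two(agrf_peak_frac)
  brake_peak_frac <- two(brake_peak_frac)
  tla_deg <- two(tla_deg)

  if (!(base_speed > 0)) stop("base_speed must be > 0")
  if (stride_duration_cv < 0) stop("stride_duration_cv must be >= 0")
  if (any(stance_fraction <= 0) || any(stance_fraction >= 1))
    stop("stance_fraction must lie in (0, 1): stance may not exceed the stride")
  if (phase_offset <= 0 || phase_offset >= 1)
    stop("phase_offset must lie in (0, 1)")
  if (stance_fraction["L"] <= phase_offset)
    stop("no double support: stance_fraction['L'] must exceed phase_offset")
  if (stance_fraction["R"] <= 1 - phase_offset)
    stop("no double support: stance_fraction['R'] must exceed 1 - phase_offset")
  if (bodyweight_N <= 100)
    stop("bodyweight_N implausibly small")
  if (abs(diff(stride_duration_mean)) > 1e-9) {
    warning("per-leg stride_duration_mean differ; both legs share cadence, ",
            "using their mean as the common cycle duration")
  }
  noise_sd <- utils::modifyList(list(force = 0, marker = 0, emg = 0),
                                as.list(noise_sd))
  cfg <- list(
    base_speed = base_speed, duration_s = duration_s,
    stride_duration_mean = stride_duration_mean,
    stride_duration_cv = stride_duration_cv,
    stance_fraction = stance_fraction, phase_offset = phase_offset,
    bodyweight_N = bodyweight_N,
    agrf_peak_frac = agrf_peak_frac, brake_peak_frac = brake_peak_frac,
    tla_deg = tla_deg, paretic_side = match.arg(paretic_side, c("L", "R")),
    hip_height = hip_height, ankle_height = ankle_height,
    swing_lift = swing_lift, hip_sway_amp = hip_sway_amp,
    hip_bob_amp = hip_bob_amp, load_ramp_s = load_ramp_s,
    emg_bursts = emg_bursts, emg_carrier_hz = emg_carrier_hz,
    emg_tonic = emg_tonic, noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "gait_config"
  cfg
}

#' Gait configuration matched to the controller's timing design
#'
#' The belt controller anticipates toe off so that the belt starts
#' accelerating a fixed time (`Tdes`) before toe off. Its anticipation
#' scaling assumes a particular relation between walking speed and
#' double-support duration: below 0.5 m/s double support is long enough
#' that the lead window alone sets the timing, while for 0.5 < v < 1 m/s
#' the anticipation term implies a double support of
#' `TTOT - Tant(v)`. This helper builds a noiseless periodic
#' configuration at speed `v` whose double-support duration follows that
#' design relation, for controller-timing simulations.
#'
#' @param v walking speed, m/s.
#' @param params controller parameters, see [controller_params()].
#' @param ds_low_s double-support duration used in the low-speed regime
#'   (v <= 0.5 m/s), s; any value above `TTOT` gives the same timing.
#' @param ... overrides passed to [gait_config()].
#' @return a `gait_config`.
#' @export
gait_config_for_speed <- function(v, params = controller_params(),
                                  ds_low_s = 0.30, ...) {
  stopifnot(v > 0)
  dots <- list(...)
  bw <- dots$bodyweight_N %||% 700
  ramp <- dots$load_ramp_s %||% 0.12
  dt <- 1 / 500
  ## cycle duration on the force sample grid (and its half), so periodic
  ## threshold-crossing events repeat exactly and predictions are exact
  Tcyc <- round((1.45 - 0.3 * v) / (2 * dt)) * 2 * dt
  ## double-support target between threshold-crossing events
  ds <- if (v <= params$speed_low) ds_low_s else
    max(0.04, (params$TTOT_ms - anticipation_time(v, params)) / 1000)
  ds_grid <- round(ds / dt) * dt
  ## place the nominal toe off so its 50 N down-crossing lands on the grid
  ## exactly ds_grid after the contralateral heel strike's up-crossing
  delta <- ramp_cross_frac(bw, 50) * ramp
  hs_c_true <- grid_after(0.5 * Tcyc + delta, dt)   # relative to own HS
  to_nom <- hs_c_true + ds_grid + delta - dt / 2
  stance <- to_nom / Tcyc
  args <- c(list(base_speed = v,
                 stride_duration_mean = c(L = Tcyc, R = Tcyc),
                 stride_duration_cv = 0,
                 stance_fraction = c(L = stance, R = stance),
                 phase_offset = 0.5,
                 noise_sd = list(force = 0, marker = 0, emg = 0),
                 hip_sway_amp = 0, hip_bob_amp = 0),
            dots)
  do.call(gait_config, args[!duplicated(names(args))])
}

## fraction of the loading ramp at which the raised-cosine vertical GRF
## crosses `threshold` (ramp value = plateau/2 * (1 - cos(pi * u)))
ramp_cross_frac <- function(plateau, threshold) {
  acos(1 - 2 * threshold / plateau) / pi
}

## first sample-grid time strictly after a continuous crossing time
grid_after <- function(tc, dt) dt * (floor(tc / dt + 1e-9) + 1)

## build the nominal and threshold-crossing event timeline for both legs
build_timeline <- function(config) {
  Tbar <- mean(config$stride_duration_mean)
  cv <- config$stride_duration_cv
  dur <- config$duration_s
  t0 <- 2.0
  n_max <- ceiling((dur + 4 * Tbar - t0) / (Tbar * max(0.5, 1 - 3 * cv))) + 2L
  z <- if (cv > 0) pmax(-3, pmin(3, stats::rnorm(n_max))) else numeric(n_max)
  Tk <- Tbar * (1 + cv * z)
  hs_L <- t0 + c(0, cumsum(Tk))
  keep <- hs_L <= dur + 2 * Tbar
  hs_L <- hs_L[keep]
  m <- length(hs_L) - 1L                      # complete left strides
  Tk <- Tk[seq_len(m)]
  po <- config$phase_offset
  hs_R <- hs_L[seq_len(m)] + po * Tk
  to_L <- hs_L[seq_len(m)] + config$stance_fraction["L"] * Tk
  T_R <- diff(hs_R)
  to_R <- hs_R[seq_len(m - 1L)] + config$stance_fraction["R"] * T_R

  dt <- 1 / 500
  uc <- ramp_cross_frac(config$bodyweight_N, 50)
  delta <- uc * config$load_ramp_s
  ev <- function(hs, to) {
    list(hs_nom = hs, to_nom = to,
         hs_true = grid_after(hs + delta, dt),
         to_true = grid_after(to - delta, dt))
  }
  list(Tbar = Tbar, t0 = t0, dt = dt, dur = dur,
       L = c(ev(hs_L[seq_len(m)], to_L), list(n = m)),
       R = c(ev(hs_R, to_R), list(n = m - 1L)))
}

## vertical and antero-posterior GRF for one leg on time grid `t`
build_forces_leg <- function(t, tl_leg, config, leg) {
  bw <- config$bodyweight_N
  ramp <- config$load_ramp_s
  fz <- numeric(length(t))
  fy <- numeric(length(t))
  a_prop <- config$agrf_peak_frac[leg] * bw
  a_brk <- config$brake_peak_frac[leg] * bw
  for (k in seq_len(tl_leg$n)) {
    hs <- tl_leg$hs_nom[k]; to <- tl_leg$to_nom[k]
    idx <- which(t >= hs & t <= to)
    if (!length(idx)) next
    u_up <- (t[idx] - hs) / ramp
    u_dn <- (to - t[idx]) / ramp
    shape <- pmin(1,
                  0.5 * (1 - cos(pi * pmin(u_up, 1))),
                  0.5 * (1 - cos(pi * pmin(u_dn, 1))))
    fz[idx] <- bw * shape
    s <- (t[idx] - hs) / (to - hs)
    fy[idx] <- ifelse(s < 0.5,
                      -a_brk * sin(2 * pi * s)^2,
                      a_prop * sin(2 * pi * (s - 0.5))^2)
  }
  list(fz = fz, fy = fy)
}

hip_traj <- function(t, config, leg, Tbar, t0) {
  phi <- if (leg == "L") 0 else pi
  list(x = config$hip_sway_amp * sin(2 * pi * (t - t0) / Tbar + phi),
       z = config$hip_height +
         config$hip_bob_amp * sin(4 * pi * (t - t0) / Tbar + phi))
}

## ankle antero-posterior / vertical trajectory for one leg given a belt
## displacement function Bf; landing positions x_land are anchored so the
## trailing limb angle at the (threshold-crossing) toe off equals the
## configured value under the belt profile present when x_land is computed
build_ankle_leg <- function(t, tl_leg, config, leg, Bf, Tbar, t0,
                            x_land = NULL) {
  n <- tl_leg$n
  theta <- config$tla_deg[leg] * pi / 180
  az <- config$ankle_height
  hipf_x <- function(tt) {
    phi <- if (leg == "L") 0 else pi
    config$hip_sway_amp * sin(2 * pi * (tt - t0) / Tbar + phi)
  }
  hipf_z <- function(tt) {
    phi <- if (leg == "L") 0 else pi
    config$hip_height + config$hip_bob_amp * sin(4 * pi * (tt - t0) / Tbar + phi)
  }
  if (is.null(x_land)) {
    x_land <- numeric(n)
    for (k in seq_len(n)) {
      tau <- tl_leg$to_true[k]
      D <- hipf_z(tau) - az
      x_land[k] <- hipf_x(tau) - D * tan(theta) +
        Bf(tau) - Bf(tl_leg$hs_nom[k])
    }
  }
  x <- numeric(length(t)); z <- rep(az, length(t))
  ## lead-in before the first heel strike: foot riding the belt
  idx <- which(t < tl_leg$hs_nom[1])
  if (length(idx)) x[idx] <- x_land[1] + (Bf(tl_leg$hs_nom[1]) - Bf(t[idx]))
  for (k in seq_len(n)) {
    hs <- tl_leg$hs_nom[k]; to <- tl_leg$to_nom[k]
    idx <- which(t >= hs & t < to)
    x[idx] <- x_land[k] - (Bf(t[idx]) - Bf(hs))
    x_to <- x_land[k] - (Bf(to) - Bf(hs))
    hs_next <- if (k < n) tl_leg$hs_nom[k + 1] else t[length(t)] + 1
    idx <- which(t >= to & t < hs_next)
    if (length(idx)) {
      if (k < n) {
        u <- (t[idx] - to) / (hs_next - to)
        sstep <- 0.5 * (1 - cos(pi * u))
        x[idx] <- x_to + (x_land[k + 1] - x_to) * sstep
        z[idx] <- az + config$swing_lift * sin(pi * u)
      } else {
        x[idx] <- x_to  # tail after the last toe off
      }
    }
  }
  list(x = x, z = z, x_land = x_land)
}

## circular distance in percent-of-cycle units
circ_dist <- function(phi, center) {
  d <- abs(phi - center)
  pmin(d, 100 - d)
}

## EMG modulation profile (burst envelope) for one muscle at phases `phi`
emg_modulation <- function(phi, muscle, config) {
  m <- rep(config$emg_tonic, length(phi))
  b <- config$emg_bursts[config$emg_bursts$muscle == muscle, , drop = FALSE]
  for (i in seq_len(nrow(b))) {
    d <- circ_dist(phi, b$center[i])
    m <- m + b$amp[i] * exp(-d^2 / (2 * b$width[i]^2))
  }
  m
}

## gait phase (% of cycle) at times `t`, piecewise by nominal heel strikes
gait_phase <- function(t, hs, Tbar) {
  idx <- findInterval(t, hs)
  phi <- numeric(length(t))
  n <- length(hs)
  pre <- idx == 0
  phi[pre] <- 100 * (1 - ((hs[1] - t[pre]) %% Tbar) / Tbar)
  inside <- idx >= 1 & idx < n
  i <- idx[inside]
  phi[inside] <- 100 * (t[inside] - hs[i]) / (hs[i + 1] - hs[i])
  post <- idx == n
  phi[post] <- 100 * (((t[post] - hs[n]) %% Tbar) / Tbar)
  phi %% 100
}

## contralateral toe off immediately following each heel strike (double
## support end); NA when none exists in the record
contra_to_after <- function(hs_times, contra_to) {
  vapply(hs_times, function(h) {
    j <- which(contra_to >= h - 1e-9)
    if (length(j)) contra_to[j[1]] else NA_real_
  }, numeric(1))
}

## analytic ideal rectified-mean envelope value: (2/pi) * modulation
ideal_envelope <- function(tt, leg, muscle, tl, config) {
  phi <- gait_phase(tt, tl[[leg]]$hs_nom, tl$Tbar)
  (2 / pi) * emg_modulation(phi, muscle, config)
}

## ground-truth per-stride activations on the canonical phase grids
truth_activations <- function(tl, config) {
  out <- list()
  dur <- tl$dur
  for (leg in c("L", "R")) {
    other <- setdiff(c("L", "R"), leg)
    tll <- tl[[leg]]
    ## strides need a following heel strike, inside the trial
    n_str <- sum(tll$hs_true[-1] <= dur)
    if (n_str < 1L) next
    to_c <- contra_to_after(tll$hs_true, tl[[other]]$to_true)
    for (k in seq_len(n_str)) {
      hs <- tll$hs_true[k]; to <- tll$to_true[k]
      hs_next <- tll$hs_true[k + 1]
      g_st <- seq(hs, to, length.out = 100)
      g_sw <- seq(to, hs_next, length.out = 100)
      for (mus in c("SOL", "LGAS", "MGAS")) {
        v <- mean(ideal_envelope(g_st[51:100], leg, mus, tl, config))
        out[[length(out) + 1L]] <- data.frame(leg = leg, stride = k,
                                              muscle = mus, value = v)
      }
      out[[length(out) + 1L]] <- data.frame(
        leg = leg, stride = k, muscle = "TACC",
        value = mean(ideal_envelope(g_st[51:100], leg, "TA", tl, config)))
      ds_next_end <- if (k + 1L <= length(to_c)) to_c[k + 1L] else NA_real_
      ta <- if (!is.na(ds_next_end)) {
        g_ds <- seq(hs_next, ds_next_end, length.out = 100)
        mean(ideal_envelope(c(g_sw, g_ds), leg, "TA", tl, config))
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(leg = leg, stride = k,
                                            muscle = "TA", value = ta)
    }
  }
  do.call(rbind, out)
}

## ground-truth per-stride kinematic/kinetic table from noiseless signals
truth_strides <- function(tl, config, ank, Bfuns, t_mk) {
  rows <- list()
  for (leg in c("L", "R")) {
    tll <- tl[[leg]]
    n_str <- sum(tll$hs_true[-1] <= tl$dur)
    if (n_str < 1L) next
    Bf <- Bfuns[[leg]]
    xi <- stats::approxfun(t_mk, ank[[leg]]$x)
    zi <- stats::approxfun(t_mk, ank[[leg]]$z)
    hip <- hip_traj(tll$to_true[seq_len(n_str)], config, leg, tl$Tbar, tl$t0)
    for (k in seq_len(n_str)) {
      hs <- tll$hs_true[k]; hs_next <- tll$hs_true[k + 1]
      to <- tll$to_true[k]
      dphs <- xi(hs_next) - xi(hs)
      sl <- dphs + (Bf(hs_next) - Bf(hs))
      tla <- atan2(hip$x[k] - xi(to), hip$z[k] - zi(to)) * 180 / pi
      ## analytic kinetics of the generated squared-sine propulsive lobe
      stance_nom <- tll$to_nom[k] - tll$hs_nom[k]
      rows[[length(rows) + 1L]] <- data.frame(
        leg = leg, stride = k, t_hs = hs, t_to = to, t_hs_next = hs_next,
        stride_duration = hs_next - hs, stance_duration = to - hs,
        sl = sl, tla = tla,
        peak_agrf = unname(config$agrf_peak_frac[leg]),
        pi = unname(config$agrf_peak_frac[leg]) * stance_nom / 4)
    }
  }
  do.call(rbind, rows)
}

#' Generate a labeled synthetic walking trial
#'
#' Produces synchronized multi-rate streams for a treadmill walking trial
#' (per-belt vertical and antero-posterior ground reaction forces and
#' marker trajectories at 500 Hz, eight EMG channels at 1925 Hz, per-belt
#' speed) together with exact ground-truth labels: gait events (on the
#' force sample grid), per-stride stride length, trailing limb angle,
#' durations, and per-muscle activations. Deterministic given
#' `config$seed`.
#'
#' The vertical force is a raised-cosine loading ramp / plateau / unloading
#' ramp per stance; the antero-posterior force is a smooth braking then
#' propulsive pair of squared-sine lobes; the ankle marker rides the belt
#' backwards during stance and swings forward to the next ground-truth
#' landing position; EMG channels are deterministic carriers
#' amplitude-modulated by phase-locked Gaussian bursts plus Gaussian noise.
#'
#' @param config a [gait_config()].
#' @return an object of class `gait_trial`: a list with data frames
#'   `forces` (`time_s`, `fz_L`, `fy_L`, `fz_R`, `fy_R`), `markers`
#'   (`time_s` plus `x/y/z` columns for `GT_L`, `GT_R`, `LM_L`, `LM_R`),
#'   `emg` (`time_s` plus 8 channels `SOL_L` ... `TA_R`), `belt` (`time_s`,
#'   `v_L`, `v_R`), a `meta` list (bodyweight, paretic side, rates), and a
#'   `truth` list (`events`, `strides`, `activation`, `artifact_strides`,
#'   internal anchors).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  tl <- build_timeline(config)
  if (tl$R$n < 3L)
    stop("trial too short: fewer than 3 complete strides")
  dur <- config$duration_s
  fs_f <- 500; fs_e <- 1925
  t_f <- seq(0, dur, by = 1 / fs_f)
  t_e <- seq(0, dur, by = 1 / fs_e)

  ## belt: constant base speed at generation time
  belt <- data.frame(time_s = t_f,
                     v_L = rep(config$base_speed, length(t_f)),
                     v_R = rep(config$base_speed, length(t_f)))

  trial <- list(meta = list(bodyweight_N = config$bodyweight_N,
                            paretic_side = config$paretic_side,
                            base_speed = config$base_speed,
                            duration_s = dur,
                            rates = list(force_hz = fs_f, marker_hz = fs_f,
                                         emg_hz = fs_e)),
                config = config, timeline = tl,
                forces_filtered = FALSE)
  class(trial) <- "gait_trial"

  ## forces
  fL <- build_forces_leg(t_f, tl$L, config, "L")
  fR <- build_forces_leg(t_f, tl$R, config, "R")
  nsd <- config$noise_sd
  addn <- function(x, sd) if (sd > 0) x + stats::rnorm(length(x), 0, sd) else x
  trial$forces <- data.frame(time_s = t_f,
                             fz_L = addn(fL$fz, nsd$force),
                             fy_L = addn(fL$fy, nsd$force),
                             fz_R = addn(fR$fz, nsd$force),
                             fy_R = addn(fR$fy, nsd$force))

  ## EMG: carrier x burst modulation + noise
  emg <- data.frame(time_s = t_e)
  for (leg in c("L", "R")) {
    phi <- gait_phase(t_e, tl[[leg]]$hs_nom, tl$Tbar)
    for (mus in c("SOL", "LGAS", "MGAS", "TA")) {
      m <- emg_modulation(phi, mus, config)
      x <- m * sin(2 * pi * config$emg_carrier_hz[[mus]] * t_e)
      emg[[paste(mus, leg, sep = "_")]] <- addn(x, nsd$emg)
    }
  }
  trial$emg <- emg

  ## marker noise drawn once and kept so that re-deriving kinematics under a
  ## new belt profile (apply_belt_profile) perturbs positions identically
  mk_noise <- if (nsd$marker > 0)
    matrix(stats::rnorm(length(t_f) * 12L, 0, nsd$marker), ncol = 12L)
  else matrix(0, nrow = length(t_f), ncol = 12L)
  trial$marker_noise <- mk_noise
  trial$belt <- belt

  trial <- rebuild_kinematics(trial, x_land = NULL)
  trial$truth$activation <- truth_activations(tl, config)
  trial$truth$artifact_strides <-
    data.frame(leg = character(), muscle = character(),
               stride = integer(), kind = character())
  trial
}

## (re)derive marker trajectories and kinematic ground truth for the
## trial's current belt profile; x_land = NULL re-anchors landing positions
rebuild_kinematics <- function(trial, x_land = NULL) {
  config <- trial$config; tl <- trial$timeline
  t_f <- trial$belt$time_s
  dt <- t_f[2] - t_f[1]
  Bfuns <- list()
  for (leg in c("L", "R")) {
    v <- trial$belt[[paste0("v_", leg)]]
    B <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt))
    af <- stats::approxfun(t_f, B, rule = 2)
    t_max <- t_f[length(t_f)]
    B_end <- B[length(B)]
    v_end <- v[length(v)]
    ## linear extrapolation beyond the trial: belt keeps its last speed
    ## (landing anchors of the last timeline strides depend on it)
    Bfuns[[leg]] <- local({
      af <- af; t_max <- t_max; B_end <- B_end; v_end <- v_end
      function(tt) ifelse(tt > t_max, B_end + v_end * (tt - t_max), af(tt))
    })
  }
  ank <- list()
  for (leg in c("L", "R")) {
    ank[[leg]] <- build_ankle_leg(t_f, tl[[leg]], config, leg, Bfuns[[leg]],
                                  tl$Tbar, tl$t0,
                                  x_land = x_land[[leg]] %||% NULL)
  }
  mk <- data.frame(time_s = t_f)
  ncol_i <- 1L
  nz <- trial$marker_noise
  put <- function(mk, name, x, y, z) {
    mk[[paste0(name, "_x")]] <- x + nz[, ncol_i]
    mk[[paste0(name, "_y")]] <- y + nz[, ncol_i + 1L]
    mk[[paste0(name, "_z")]] <- z + nz[, ncol_i + 2L]
    ncol_i <<- ncol_i + 3L
    mk
  }
  for (leg in c("L", "R")) {
    hip <- hip_traj(t_f, config, leg, tl$Tbar, tl$t0)
    ysign <- if (leg == "L") -0.10 else 0.10
    mk <- put(mk, paste0("GT_", leg), hip$x, rep(ysign, length(t_f)), hip$z)
  }
  for (leg in c("L", "R")) {
    ysign <- if (leg == "L") -0.10 else 0.10
    mk <- put(mk, paste0("LM_", leg), ank[[leg]]$x,
              rep(ysign, length(t_f)), ank[[leg]]$z)
  }
  trial$markers <- mk
  trial$truth$x_land <- list(L = ank$L$x_land, R = ank$R$x_land)
  trial$truth$events <- list(
    L = list(hs = tl$L$hs_true[tl$L$hs_true <= config$duration_s],
             to = tl$L$to_true[tl$L$to_true <= config$duration_s]),
    R = list(hs = tl$R$hs_true[tl$R$hs_true <= config$duration_s],
             to = tl$R$to_true[tl$R$to_true <= config$duration_s]))
  trial$truth$strides <- truth_strides(tl, config, ank, Bfuns, t_f)
  trial
}

#' Impose a belt-speed profile on a generated trial
#'
#' Replaces the trial's belt traces and re-derives the stance-foot
#' kinematics: during stance the ankle marker's antero-posterior velocity
#' equals minus the belt speed, while the per-stride landing positions
#' anchored at generation time stay fixed. Ground-truth stride length is
#' updated through the treadmill stride-length relation (marker
#' displacement between heel strikes plus integrated belt travel), and
#' ground-truth trailing limb angle is recomputed from the new
#' trajectories — a belt acceleration in late stance therefore increases
#' the trailing limb angle, as it does in real walking.
#'
#' @param trial a `gait_trial`.
#' @param belt data frame `(time_s, v_L, v_R)` covering the trial duration;
#'   speeds must be non-negative.
#' @return the modified trial (truth updated in place).
#' @export
apply_belt_profile <- function(trial, belt) {
  stopifnot(inherits(trial, "gait_trial"),
            all(c("time_s", "v_L", "v_R") %in% names(belt)))
  if (any(belt$v_L < 0) || any(belt$v_R < 0))
    stop("belt speed must be non-negative")
  if (min(belt$time_s) > 0 || max(belt$time_s) < trial$meta$duration_s)
    stop("belt trace must cover the trial duration")
  t_f <- trial$forces$time_s
  trial$belt <- data.frame(
    time_s = t_f,
    v_L = stats::approx(belt$time_s, belt$v_L, t_f, rule = 2)$y,
    v_R = stats::approx(belt$time_s, belt$v_R, t_f, rule = 2)$y)
  rebuild_kinematics(trial, x_land = trial$truth$x_land)
}

#' Inject labeled EMG artifacts into a trial
#'
#' Corrupts EMG channels with the kinds of artifact seen in practice —
#' impact-like spikes, loss-of-contact dropouts, flatlines — and returns
#' the exact set of corrupted strides, so the automatic stride-outlier
#' remover can be scored for recall and false positives.
#'
#' @param trial a `gait_trial`.
#' @param spec a list of artifact specifications, each a list with elements
#'   `kind` (`"spike"`, `"dropout"` or `"flatline"`), either `rate`
#'   (per-stride probability in `[0, 1]`) or `strides` (explicit stride
#'   indices), optional `amplitude` (spike scale relative to the channel's
#'   peak burst amplitude, default 50), optional `muscles` and `legs`
#'   subsets.
#' @param seed integer seed for artifact placement.
#' @return a list with `trial` (modified copy) and `artifact_strides`, a
#'   data frame `(leg, muscle, stride, kind)`.
#' @export
inject_emg_artifacts <- function(trial, spec, seed = 1L) {
  stopifnot(inherits(trial, "gait_trial"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  if (!is.null(spec$kind)) spec <- list(spec)   # single entry convenience
  tl <- trial$timeline
  t_e <- trial$emg$time_s
  fs_e <- trial$meta$rates$emg_hz
  rows <- list()
  for (entry in spec) {
    kind <- entry$kind %||% stop("artifact entry needs a 'kind'")
    if (!kind %in% c("spike", "dropout", "flatline"))
      stop("unknown artifact kind: ", kind)
    rate <- entry$rate %||% NA_real_
    if (!is.na(rate) && (rate < 0 || rate > 1))
      stop("artifact rate must lie in [0, 1]")
    amp_scale <- entry$amplitude %||% 50
    muscles <- entry$muscles %||% c("SOL", "LGAS", "MGAS", "TA")
    legs <- entry$legs %||% c("L", "R")
    for (leg in legs) {
      tll <- tl[[leg]]
      n_str <- tll$n - 1L
      for (mus in muscles) {
        sel <- if (!is.null(entry$strides)) {
          intersect(as.integer(entry$strides), seq_len(n_str))
        } else if (!is.na(rate)) {
          which(stats::runif(n_str) < rate)
        } else integer()
        if (!length(sel)) next
        ch <- paste(mus, leg, sep = "_")
        x <- trial$emg[[ch]]
        burst_amp <- max(trial$config$emg_bursts$amp[
          trial$config$emg_bursts$muscle == mus], trial$config$emg_tonic)
        for (k in sel) {
          i0 <- tll$hs_true[k]; i1 <- tll$hs_true[k + 1]
          if (kind == "spike") {
            tc <- i0 + stats::runif(1, 0.05, 0.95) * (i1 - i0)
            idx <- which(t_e >= tc & t_e < tc + 0.015)
            x[idx] <- x[idx] + amp_scale * burst_amp *
              sin(2 * pi * 200 * t_e[idx])
          } else if (kind == "dropout") {
            idx <- which(t_e >= i0 & t_e < i1)
            x[idx] <- 0
          } else {                       # flatline
            idx <- which(t_e >= i0 & t_e < i1)
            x[idx] <- mean(x)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            leg = leg, muscle = mus, stride = k, kind = kind)
        }
        trial$emg[[ch]] <- x
      }
    }
  }
  art <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(leg = character(), muscle = character(),
               stride = integer(), kind = character())
  trial$truth$artifact_strides <- art
  list(trial = trial, artifact_strides = art)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial>", x$meta$duration_s, "s,",
      "base speed", x$meta$base_speed, "m/s,",
      "paretic side", x$meta$paretic_side, "\n")
  cat("  strides (L/R):", x$timeline$L$n, "/", x$timeline$R$n, "\n")
  invisible(x)
}
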