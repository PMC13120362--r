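## action codes shared by the controller and its reference evaluator
ACT_HOLD <- 0L
ACT_ACCEL <- 1L
ACT_END <- 2L
ACT_PAUSE <- 3L
action_labels <- c("HOLD", "ACCELERATE", "END_ACCELERATION", "PAUSE")

#' Belt-acceleration controller parameters
#'
#' Constants of the belt-acceleration control logic. The controller
#' accelerates the belt under the trailing limb for a fixed duration
#' before the predicted toe off; the total lead time `TTOT` is the desired
#' acceleration duration `Tdes` plus the treadmill actuation delay `Tdel`.
#'
#' @param TantBase_ms base anticipation time, ms (default 175).
#' @param Tdes_ms desired acceleration duration, ms (default 180).
#' @param Tdel_ms treadmill actuation delay, ms (default 40).
#' @param THSdelay_ms tolerated lateness of the contralateral heel strike
#'   relative to its prediction, ms (default 70).
#' @param TmaxDur_ms hard bound on acceleration duration from its command
#'   onset, ms (default 250).
#' @param accel_magnitude belt acceleration magnitude, m/s^2 (default 5).
#' @param pause_steps number of steps accelerations are paused after a
#'   missed event or timeout (default 3; a step is a heel strike of the
#'   controlled leg).
#' @param speed_low,speed_high regime boundaries, m/s: at or below
#'   `speed_low` the controller waits for the detected contralateral heel
#'   strike; between the two it anticipates the predicted heel strike.
#' @param debounce_ms persistence required by the causal in-loop event
#'   detector before a threshold crossing is confirmed, ms (default 20;
#'   the offline 200 ms rule is non-causal).
#' @param tick_s control loop period, s (default 0.001).
#' @return an object of class `controller_params`; `TTOT_ms` is derived.
#' @export
controller_params <- function(TantBase_ms = 175, Tdes_ms = 180,
                              Tdel_ms = 40, THSdelay_ms = 70,
                              TmaxDur_ms = 250, accel_magnitude = 5,
                              pause_steps = 3L, speed_low = 0.5,
                              speed_high = 1.0, debounce_ms = 20,
                              tick_s = 0.001) {
  stopifnot(TantBase_ms >= 0, Tdes_ms > 0, Tdel_ms >= 0, THSdelay_ms > 0,
            TmaxDur_ms > 0, accel_magnitude > 0, pause_steps >= 0,
            speed_low < speed_high, tick_s > 0)
  p <- list(TantBase_ms = TantBase_ms, Tdes_ms = Tdes_ms, Tdel_ms = Tdel_ms,
            TTOT_ms = total_lead_time(Tdes_ms, Tdel_ms),
            THSdelay_ms = THSdelay_ms, TmaxDur_ms = TmaxDur_ms,
            accel_magnitude = accel_magnitude,
            pause_steps = as.integer(pause_steps),
            speed_low = speed_low, speed_high = speed_high,
            debounce_ms = debounce_ms, tick_s = tick_s)
  class(p) <- "controller_params"
  p
}

#' Anticipation time as a function of walking speed
#'
#' At low speeds double support is long and no anticipation is needed; at
#' intermediate speeds the anticipation time is scaled linearly with
#' speed; at and above 1 m/s the full base anticipation is used:
#' `Tant = 0` for `v <= 0.5`, `TantBase * (2 v - 1)` for `0.5 < v < 1`,
#' `TantBase` otherwise.
#'
#' @param v walking speed, m/s (>= 0); vectorized.
#' @param params [controller_params()].
#' @return anticipation time in ms.
#' @export
anticipation_time <- function(v, params = controller_params()) {
  if (any(v < 0)) stop("speed must be non-negative")
  ifelse(v <= params$speed_low, 0,
         ifelse(v < params$speed_high,
                params$TantBase_ms * (2 * v - 1),
                params$TantBase_ms))
}

#' Total lead time of the acceleration command
#'
#' The acceleration command must lead the predicted toe off by the desired
#' acceleration duration plus the treadmill actuation delay.
#'
#' @param Tdes_ms desired acceleration duration, ms (>= 0).
#' @param Tdel_ms actuation delay, ms (>= 0).
#' @return `Tdes_ms + Tdel_ms`, ms.
#' @export
total_lead_time <- function(Tdes_ms, Tdel_ms) {
  stopifnot(Tdes_ms >= 0, Tdel_ms >= 0)
  Tdes_ms + Tdel_ms
}

#' Next-event prediction from recent intervals
#'
#' The next event time is the last observed event plus the median of up
#' to the last `max_intervals` inter-event intervals; `NA` when fewer
#' than two events are known.
#'
#' @param times ordered event times, s.
#' @param max_intervals number of recent intervals fed to the median.
#' @return predicted next event time, s (or `NA`).
#' @export
predict_next <- function(times, max_intervals = 3L) {
  n <- length(times)
  if (n < 2L) return(NA_real_)
  iv <- diff(times)
  iv <- iv[max(1L, length(iv) - max_intervals + 1L):length(iv)]
  times[n] + stats::median(iv)
}

#' Predict the next contralateral heel strike and toe off
#'
#' Predictions are built from the previous gait cycles: the next event is
#' the last observed event plus the median of up to the last three
#' inter-event intervals. With fewer than two events of a kind the
#' corresponding prediction is `NA` ("unavailable" is a value, not an
#' error); this is the state the controller is in during the pause-reset
#' window.
#'
#' @param event_history list with numeric vectors `hs_contra`
#'   (contralateral heel-strike times) and `to_self` (controlled-leg
#'   toe-off times), s.
#' @return list `(THS_pred, TTO_pred)` in s, `NA` when unavailable.
#' @export
predict_events <- function(event_history) {
  list(THS_pred = predict_next(event_history$hs_contra %||% numeric()),
       TTO_pred = predict_next(event_history$to_self %||% numeric()))
}

#' Fresh controller state
#'
#' The controller state is an environment mutated in place by
#' [controller_step()]: predicted event times, acceleration bookkeeping
#' (`taccel`, flags), the pause counter, and the recent per-leg event
#' history that feeds [predict_events()].
#'
#' @param params [controller_params()].
#' @return an environment of class `controller_state`.
#' @export
new_controller_state <- function(params = controller_params()) {
  st <- new.env(parent = emptyenv())
  st$THS_pred <- NA_real_
  st$TTO_pred <- NA_real_
  st$taccel <- NA_real_
  st$accelerating <- FALSE
  st$TO_detected <- FALSE
  st$HScont_evt <- FALSE
  st$contra_stance <- FALSE
  st$self_stance <- FALSE
  st$pause_remaining <- 0L
  st$hs_contra <- numeric(0)
  st$to_self <- numeric(0)
  class(st) <- c("controller_state", "environment")
  st
}

#' One tick of the belt-acceleration control logic
#'
#' Implements the per-tick decision table. Events confirmed at this tick
#' are ingested first (stance flags, toe-off detection, pause-step
#' counting); the decision is then taken with the predictions as refreshed
#' at the previous controlled-leg toe off; finally the predictions are
#' refreshed if a controlled-leg toe off was ingested. Event predictions
#' are cleared when a pause is triggered and rebuilt from the steps
#' observed during the pause.
#'
#' Decision, in order: outside the lead window (`t <= TTO_pred - TTOT`)
#' the belt is not accelerated. In the high-speed regime the belt is
#' accelerated throughout `[THS_pred - Tant, THS_pred + THSdelay)`. When
#' either the contralateral foot is in stance (low speed) or the
#' heel-strike window has elapsed (high speed): a detected toe off ends
#' the acceleration; a missing contralateral stance or an acceleration
#' older than `TmaxDur` pauses accelerations for `pause_steps` steps;
#' otherwise the belt is (kept) accelerating, with `taccel` recorded at
#' the first accelerating tick.
#'
#' @param state a [new_controller_state()] environment (mutated).
#' @param params [controller_params()].
#' @param t current time, s.
#' @param v commanded base speed used for regime switching, m/s.
#' @param sensors list of numeric vectors (possibly empty): `hs_self`,
#'   `to_self`, `hs_contra`, `to_contra` — event timestamps confirmed at
#'   this tick.
#' @param enabled when `FALSE` (protocol phase without accelerations) the
#'   step only tracks events and predictions, holds, and keeps no
#'   acceleration in progress.
#' @return a list `(action, timestamp)`; `action` is one of `"HOLD"`,
#'   `"ACCELERATE"`, `"END_ACCELERATION"`, `"PAUSE"`.
#' @export
controller_step <- function(state, params, t, v, sensors, enabled = TRUE) {
  ## --- ingest events confirmed at this tick ------------------------------
  for (tt in sensors$hs_contra %||% numeric()) {
    state$contra_stance <- TRUE
    state$HScont_evt <- TRUE
    state$hs_contra <- c(state$hs_contra, tt)
  }
  for (tt in sensors$to_contra %||% numeric()) {
    state$contra_stance <- FALSE
  }
  for (tt in sensors$hs_self %||% numeric()) {
    state$self_stance <- TRUE
    if (state$pause_remaining > 0L)
      state$pause_remaining <- state$pause_remaining - 1L
  }
  to_self_now <- sensors$to_self %||% numeric()
  for (tt in to_self_now) {
    if (!state$self_stance)
      stop("inconsistent sensor state: toe off detected while the leg ",
           "is not in stance")
    state$self_stance <- FALSE
    if (state$accelerating) state$TO_detected <- TRUE
    state$HScont_evt <- FALSE
    state$to_self <- c(state$to_self, tt)
  }

  ## --- decision ----------------------------------------------------------
  ttot <- params$TTOT_ms / 1000
  hsdelay <- params$THSdelay_ms / 1000
  tmax <- params$TmaxDur_ms / 1000
  act <- ACT_HOLD
  if (!enabled) {
    state$accelerating <- FALSE
    state$TO_detected <- FALSE
    state$taccel <- NA_real_
  } else if (state$pause_remaining == 0L &&
      !is.na(state$TTO_pred) && t > state$TTO_pred - ttot) {
    tant <- anticipation_time(v, params) / 1000
    high <- v > params$speed_low
    highwin <- high && !is.na(state$THS_pred) &&
      t >= state$THS_pred - tant && t < state$THS_pred + hsdelay
    if (highwin) {
      if (!state$accelerating) {
        state$accelerating <- TRUE
        state$taccel <- t
        state$TO_detected <- FALSE
      }
      act <- ACT_ACCEL
    } else if ((!high && state$contra_stance) ||
               (high && !is.na(state$THS_pred) &&
                t >= state$THS_pred + hsdelay)) {
      if (state$TO_detected) {
        act <- ACT_END
        state$accelerating <- FALSE
        state$TO_detected <- FALSE
        state$taccel <- NA_real_
      } else if (!state$contra_stance ||
                 (state$accelerating && t > state$taccel + tmax)) {
        act <- ACT_PAUSE
        state$pause_remaining <- params$pause_steps
        state$accelerating <- FALSE
        state$TO_detected <- FALSE
        state$HScont_evt <- FALSE
        state$taccel <- NA_real_
        state$hs_contra <- numeric(0)   # reset gait event predictions
        state$to_self <- numeric(0)
        state$THS_pred <- NA_real_
        state$TTO_pred <- NA_real_
      } else {
        if (!state$accelerating) {
          if (high || state$HScont_evt) {
            state$accelerating <- TRUE
            state$taccel <- t
            state$TO_detected <- FALSE
            state$HScont_evt <- FALSE    # consumed by the acceleration
            act <- ACT_ACCEL
          }
        } else {
          act <- ACT_ACCEL
        }
      }
    }
  }

  ## --- refresh predictions at controlled-leg toe offs --------------------
  if (length(to_self_now)) {
    p <- predict_events(list(hs_contra = state$hs_contra,
                             to_self = state$to_self))
    state$THS_pred <- p$THS_pred
    state$TTO_pred <- p$TTO_pred
  }
  list(action = action_labels[act + 1L], timestamp = t, code = act)
}

## causal threshold-crossing event detector: a crossing of `threshold` is
## confirmed after it persists `debounce_ms`; the event keeps the crossing
## timestamp. Returns a data frame (type, t_cross, t_confirm).
causal_event_detector <- function(vgrf, time, threshold = 50,
                                  debounce_ms = 20) {
  fs <- 1 / (time[2] - time[1])
  nb <- ceiling(debounce_ms / 1000 * fs)
  state <- vgrf > threshold
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (g in seq_along(r$lengths)) {
    if (starts[g] == 1L) next                      # no crossing at start
    if (r$lengths[g] < nb) next                    # bounce, never confirmed
    rows[[length(rows) + 1L]] <- data.frame(
      type = if (r$values[g]) "hs" else "to",
      t_cross = time[starts[g]],
      t_confirm = time[starts[g]] + debounce_ms / 1000)
  }
  if (!length(rows))
    return(data.frame(type = character(), t_cross = numeric(),
                      t_confirm = numeric()))
  do.call(rbind, rows)
}

#' Per-leg sensor event tables for the closed loop
#'
#' Builds the event streams the controller consumes, either from the
#' generator's ground-truth events (`"truth"`: confirmation instantaneous)
#' or from the causal in-loop detector (`"causal"`: 50 N crossing with a
#' debounce; events are timestamped at the crossing but only become
#' visible to the controller after confirmation).
#'
#' @param trial a `gait_trial`.
#' @param source `"causal"` or `"truth"`.
#' @param params [controller_params()] (supplies the debounce).
#' @return list with per-leg data frames `(type, t_cross, t_confirm)`.
#' @export
build_sensor_streams <- function(trial, source = c("causal", "truth"),
                                 params = controller_params()) {
  source <- match.arg(source)
  out <- list()
  for (leg in c("L", "R")) {
    if (source == "truth") {
      ev <- trial$truth$events[[leg]]
      out[[leg]] <- rbind(
        data.frame(type = "hs", t_cross = ev$hs, t_confirm = ev$hs),
        data.frame(type = "to", t_cross = ev$to, t_confirm = ev$to))
    } else {
      out[[leg]] <- causal_event_detector(
        trial$forces[[paste0("fz_", leg)]], trial$forces$time_s,
        debounce_ms = params$debounce_ms)
    }
    out[[leg]] <- out[[leg]][order(out[[leg]]$t_confirm), ]
  }
  out
}

#' Run the controller over a session for one belt
#'
#' Steps the control logic at the fixed control tick over `[0, t_end]`,
#' feeding it the confirmed sensor events of the controlled leg and its
#' contralateral leg, and returns the per-tick action trace.
#'
#' @param sensors list with data frames `self` and `contra`, columns
#'   `(type, t_cross, t_confirm)` as built from event detection.
#' @param params [controller_params()].
#' @param v commanded base speed, m/s (regime switching uses this, not the
#'   instantaneous belt speed).
#' @param t_end end of the run, s.
#' @param active optional length-2 window, s: outside it the controller
#'   holds (used for protocol phases); events are still tracked.
#' @return integer vector of per-tick action codes (0 = HOLD,
#'   1 = ACCELERATE, 2 = END_ACCELERATION, 3 = PAUSE); attribute
#'   `"tick_s"` gives the tick.
#' @export
run_controller <- function(sensors, params, v, t_end,
                           active = c(0, Inf)) {
  dt <- params$tick_s
  n <- floor(t_end / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  st <- new_controller_state(params)
  actions <- integer(n)

  ev_self <- sensors$self
  ev_contra <- sensors$contra
  i_s <- 1L; i_c <- 1L
  n_s <- nrow(ev_self); n_c <- nrow(ev_contra)
  for (i in seq_len(n)) {
    t <- times[i]
    sn <- list(hs_self = numeric(0), to_self = numeric(0),
               hs_contra = numeric(0), to_contra = numeric(0))
    while (i_s <= n_s && ev_self$t_confirm[i_s] <= t + 1e-9) {
      key <- paste0(ev_self$type[i_s], "_self")
      sn[[key]] <- c(sn[[key]], ev_self$t_cross[i_s])
      i_s <- i_s + 1L
    }
    while (i_c <= n_c && ev_contra$t_confirm[i_c] <= t + 1e-9) {
      key <- paste0(ev_contra$type[i_c], "_contra")
      sn[[key]] <- c(sn[[key]], ev_contra$t_cross[i_c])
      i_c <- i_c + 1L
    }
    enabled <- t >= active[1] && t <= active[2]
    actions[i] <- controller_step(st, params, t, v, sn, enabled)$code
  }
  attr(actions, "tick_s") <- dt
  actions
}

#' Belt speed response to a command trace
#'
#' The treadmill plant: the belt accelerates at the (possibly
#' time-varying) acceleration magnitude starting one actuation delay after
#' the acceleration command, stops rising one delay after the command
#' ends, and returns to base speed at the controller's acceleration
#' magnitude. Speed never drops below the base speed and never below
#' zero.
#'
#' @param actions per-tick integer action codes from [run_controller()]
#'   (only `ACCELERATE` ticks drive the belt).
#' @param params [controller_params()].
#' @param base_speed base belt speed, m/s.
#' @param accel_profile optional per-tick acceleration magnitude vector,
#'   m/s^2 (default: constant `params$accel_magnitude`); used for the
#'   protocol's ramp phase.
#' @return numeric belt-speed vector, one value per tick.
#' @export
plant_response <- function(actions, params, base_speed,
                           accel_profile = NULL) {
  dt <- attr(actions, "tick_s") %||% params$tick_s
  n <- length(actions)
  A <- accel_profile %||% rep(params$accel_magnitude, n)
  stopifnot(length(A) == n)
  d <- round(params$Tdel_ms / 1000 / dt)
  cmd <- actions == ACT_ACCEL
  if (d > 0) cmd <- c(rep(FALSE, d), cmd[seq_len(n - d)])
  v <- numeric(n)
  v[1] <- base_speed
  dec <- params$accel_magnitude
  for (i in 2:n) {
    v[i] <- if (cmd[i]) v[i - 1] + A[i] * dt
            else max(base_speed, v[i - 1] - dec * dt)
  }
  pmax(v, 0)
}

## per-stride acceleration dose bookkeeping from a belt-speed trace
dose_table <- function(actions, params, trial, leg, window = c(0, Inf)) {
  dt <- attr(actions, "tick_s") %||% params$tick_s
  n <- length(actions)
  cmd <- actions == ACT_ACCEL
  r <- rle(cmd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- which(r$values)
  ev <- trial$truth$events[[leg]]
  contra <- setdiff(c("L", "R"), leg)
  ev_c <- trial$truth$events[[contra]]
  rows <- list()
  for (g in ep) {
    t_cmd <- (starts[g] - 1L) * dt
    dur_ms <- r$lengths[g] * dt * 1000
    onset <- t_cmd + params$Tdel_ms / 1000
    if (onset < window[1] || onset > window[2]) next
    k <- findInterval(onset, ev$hs)
    if (k > length(ev$to)) k <- length(ev$to)
    if (k < 1L) next
    ## assign to the stride whose toe off the onset precedes
    while (k <= length(ev$to) && ev$to[k] < onset) k <- k + 1L
    if (k > length(ev$to)) next
    to_k <- ev$to[k]
    kc <- findInterval(to_k, ev_c$hs)              # double-support start
    hs_c <- if (kc >= 1L) ev_c$hs[kc] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      leg = leg, stride = k,
      t_onset = onset,
      onset_lead_ms = (to_k - onset) * 1000,
      realized_duration_ms = dur_ms,
      in_double_support = !is.na(hs_c) && onset >= hs_c && onset <= to_k)
  }
  if (!length(rows))
    return(data.frame(leg = character(), stride = integer(),
                      t_onset = numeric(), onset_lead_ms = numeric(),
                      realized_duration_ms = numeric(),
                      in_double_support = logical()))
  do.call(rbind, rows)
}

#' Closed-loop belt-acceleration training session
#'
#' Generates a synthetic walking trial, runs the belt-acceleration
#' controller against its (causal or ground-truth) event stream for each
#' accelerated belt, produces the belt-speed response, and imposes the
#' resulting belt profile back onto the trial's kinematics. Phases follow
#' the training protocol: baseline (no accelerations), a ramp over which
#' the acceleration magnitude grows linearly to its maximum, exposure at
#' full magnitude, and post-exposure.
#'
#' @param config a [gait_config()]; its duration is overridden by the sum
#'   of the phase durations.
#' @param params [controller_params()].
#' @param phases named numeric vector of phase durations in s
#'   (`baseline`, `ramp`, `exposure`, `post`).
#' @param mode `"symmetric"` (both belts accelerated) or `"asymmetric"`
#'   (paretic belt only).
#' @param sensor `"causal"` (in-loop 50 N crossing with debounce) or
#'   `"truth"` (generator ground-truth events).
#' @param seed overrides `config$seed` when not `NULL`.
#' @return a list of class `accel_session`: `trial` (with belt profile
#'   applied and truth updated), `commands` (data frame `t`, `leg`,
#'   `action` of non-hold commands), `actions` (per-tick code vectors per
#'   leg), `belt`, `dose` (per-stride onset lead, realized duration,
#'   double-support flag), `phases` (boundary times), `params`, `mode`.
#' @export
simulate_session <- function(config, params = controller_params(),
                             phases = c(baseline = 120, ramp = 60,
                                        exposure = 300, post = 120),
                             mode = c("symmetric", "asymmetric"),
                             sensor = c("causal", "truth"),
                             seed = NULL) {
  mode <- match.arg(mode)
  sensor <- match.arg(sensor)
  stopifnot(all(c("baseline", "ramp", "exposure", "post") %in% names(phases)))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  t_end <- sum(phases)
  config$duration_s <- t_end
  trial <- generate_trial(config)

  bounds <- cumsum(phases[c("baseline", "ramp", "exposure", "post")])
  t_ramp0 <- bounds[["baseline"]]
  t_exp0 <- bounds[["ramp"]]
  t_exp1 <- bounds[["exposure"]]
  active <- c(t_ramp0, t_exp1)

  streams <- build_sensor_streams(trial, sensor, params)
  legs <- if (mode == "symmetric") c("L", "R") else trial$meta$paretic_side

  dt <- params$tick_s
  n_tick <- floor(t_end / dt) + 1L
  tick_t <- (seq_len(n_tick) - 1L) * dt
  ramp_len <- phases[["ramp"]]
  accel_profile <- ifelse(
    tick_t < t_ramp0, 0,
    ifelse(tick_t < t_exp0,
           params$accel_magnitude * (tick_t - t_ramp0) / ramp_len,
           ifelse(tick_t <= t_exp1, params$accel_magnitude, 0)))

  actions <- list()
  belt <- data.frame(time_s = tick_t)
  for (leg in c("L", "R")) {
    if (leg %in% legs) {
      contra <- setdiff(c("L", "R"), leg)
      acts <- run_controller(list(self = streams[[leg]],
                                  contra = streams[[contra]]),
                             params, config$base_speed, t_end, active)
      actions[[leg]] <- acts
      belt[[paste0("v_", leg)]] <-
        plant_response(acts, params, config$base_speed, accel_profile)
    } else {
      actions[[leg]] <- NULL
      belt[[paste0("v_", leg)]] <- rep(config$base_speed, n_tick)
    }
  }

  trial <- apply_belt_profile(trial, belt)

  cmd_rows <- list()
  dose <- list()
  for (leg in legs) {
    acts <- actions[[leg]]
    nz <- which(acts != ACT_HOLD)
    if (length(nz))
      cmd_rows[[leg]] <- data.frame(t = (nz - 1L) * dt, leg = leg,
                                    action = action_labels[acts[nz] + 1L])
    dose[[leg]] <- dose_table(acts, params, trial, leg,
                              window = c(t_exp0, t_exp1))
  }
  out <- list(trial = trial,
              commands = if (length(cmd_rows)) do.call(rbind, cmd_rows)
                         else data.frame(t = numeric(), leg = character(),
                                         action = character()),
              actions = actions, belt = belt,
              dose = do.call(rbind, dose),
              phases = c(baseline = unname(bounds[["baseline"]]),
                         ramp = unname(t_exp0), exposure = unname(t_exp1),
                         post = unname(bounds[["post"]])),
              params = params, mode = mode, sensor = sensor)
  class(out) <- "accel_session"
  out
}

#' Reference tick-by-tick evaluation of the control logic
#'
#' A deliberately naive re-evaluation of the decision table: at every tick
#' it rescans the confirmed event tables and recomputes stance flags and
#' event predictions from scratch (predictions frozen at the last
#' controlled-leg toe off, cleared by pauses), with no incremental state
#' beyond the acceleration bookkeeping the logic itself requires. Used as
#' an independent oracle for the optimized controller's command log.
#'
#' @inheritParams run_controller
#' @return integer per-tick action-code vector, comparable to
#'   [run_controller()]'s output.
#' @export
reference_command_log <- function(sensors, params, v, t_end,
                                  active = c(0, Inf)) {
  dt <- params$tick_s
  n <- floor(t_end / dt) + 1L
  ttot <- params$TTOT_ms / 1000
  hsdelay <- params$THSdelay_ms / 1000
  tmax <- params$TmaxDur_ms / 1000
  tant <- anticipation_time(v, params) / 1000
  high <- v > params$speed_low

  es <- sensors$self; ec <- sensors$contra
  s_hs_cf <- es$t_confirm[es$type == "hs"]; s_hs_cr <- es$t_cross[es$type == "hs"]
  s_to_cf <- es$t_confirm[es$type == "to"]; s_to_cr <- es$t_cross[es$type == "to"]
  c_hs_cf <- ec$t_confirm[ec$type == "hs"]; c_hs_cr <- ec$t_cross[ec$type == "hs"]
  c_to_cf <- ec$t_confirm[ec$type == "to"]

  accelerating <- FALSE; taccel <- NA_real_
  t_pause <- -Inf; paused <- FALSE
  t_clear <- -Inf           # history cleared at the last pause
  t_consume <- -Inf         # HScont,evt consumed by an acceleration start
  actions <- integer(n)
  eps <- 1e-9
  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    ## stance flags from the latest confirmed events
    last_c_hs <- suppressWarnings(max(c_hs_cf[c_hs_cf <= t + eps]))
    last_c_to <- suppressWarnings(max(c_to_cf[c_to_cf <= t + eps]))
    contra_stance <- is.finite(last_c_hs) && last_c_hs > last_c_to
    last_s_to_cf <- suppressWarnings(max(s_to_cf[s_to_cf <= t + eps]))
    hscont_evt <- is.finite(last_c_hs) &&
      last_c_hs > max(last_s_to_cf, t_consume, t_clear)
    ## pause over after pause_steps controlled-leg heel strikes
    if (paused &&
        sum(s_hs_cf > t_pause + dt / 2 & s_hs_cf <= t + eps) >=
          params$pause_steps)
      paused <- FALSE
    ## predictions frozen at the last controlled-leg toe off ingested
    ## strictly before this tick
    vis <- s_to_cf <= t - dt / 2 & s_to_cf > t_clear
    to_hist <- s_to_cr[vis]
    ths <- tto <- NA_real_
    if (length(to_hist) >= 2L) {
      t_ref <- max(s_to_cf[vis])
      tto <- predict_next(to_hist)
      hs_hist <- c_hs_cr[c_hs_cf <= t_ref + eps & c_hs_cf > t_clear]
      if (length(hs_hist) >= 2L) ths <- predict_next(hs_hist)
    }
    to_detected <- accelerating &&
      any(s_to_cf <= t + eps &
            s_to_cf >= (if (is.na(taccel)) Inf else taccel))
    inactive <- t < active[1] || t > active[2]

    act <- ACT_HOLD
    if (!paused && !inactive && !is.na(tto) && t > tto - ttot) {
      if (high && !is.na(ths) && t >= ths - tant && t < ths + hsdelay) {
        if (!accelerating) { accelerating <- TRUE; taccel <- t }
        act <- ACT_ACCEL
      } else if ((!high && contra_stance) ||
                 (high && !is.na(ths) && t >= ths + hsdelay)) {
        if (to_detected) {
          act <- ACT_END; accelerating <- FALSE; taccel <- NA_real_
        } else if (!contra_stance ||
                   (accelerating && t > taccel + tmax)) {
          act <- ACT_PAUSE
          paused <- TRUE; t_pause <- t; t_clear <- t
          accelerating <- FALSE; taccel <- NA_real_
        } else if (accelerating) {
          act <- ACT_ACCEL
        } else if (high || hscont_evt) {
          accelerating <- TRUE; taccel <- t; t_consume <- t
          act <- ACT_ACCEL
        }
      }
    } else if (inactive || paused) {
      accelerating <- FALSE; taccel <- NA_real_
    }
    actions[i] <- act
  }
  attr(actions, "tick_s") <- dt
  actions
}

#' @export
print.accel_session <- function(x, ...) {
  cat("<accel_session>", x$mode, "mode,", x$sensor, "sensing,",
      nrow(x$commands), "non-hold commands,",
      nrow(x$dose), "dosed strides\n")
  invisible(x)
}
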