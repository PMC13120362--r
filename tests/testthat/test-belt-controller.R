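test_that("anticipation time follows the piecewise speed scaling", {
  p <- controller_params()
  expect_equal(anticipation_time(0.4, p), 0)
  expect_equal(anticipation_time(0.5, p), 0)
  expect_equal(anticipation_time(0.75, p), 87.5)
  expect_equal(anticipation_time(1.2, p), 175)
  expect_equal(anticipation_time(1.0, p), 175)
  expect_error(anticipation_time(-0.1, p), "non-negative")
})

test_that("total lead time is the sum of duration and delay", {
  expect_equal(total_lead_time(180, 40), 220)
  expect_equal(total_lead_time(0, 0), 0)
  expect_equal(total_lead_time(100, 50), 150)
  expect_equal(controller_params()$TTOT_ms, 220)
})

test_that("event prediction uses the median of recent intervals", {
  ## perfectly periodic events: prediction error zero
  h <- list(hs_contra = seq(0, 6, by = 1.2), to_self = seq(0.7, 6.7, by = 1.2))
  p <- predict_events(h)
  expect_equal(p$THS_pred, 7.2)
  expect_equal(p$TTO_pred, 7.9)
  ## median of [1.0, 1.2, 1.1] is 1.1
  p2 <- predict_events(list(hs_contra = c(0, 1.0, 2.2, 3.3),
                            to_self = numeric()))
  expect_equal(p2$THS_pred, 3.3 + 1.1)
  expect_true(is.na(p2$TTO_pred))
  ## fewer than two events: unavailable, not an error
  expect_true(is.na(predict_events(list(hs_contra = 1.0,
                                        to_self = numeric()))$THS_pred))
})

test_that("prediction error scales with cadence variability as derived", {
  ## Monte-Carlo oracle for the last-event + median-of-3-intervals
  ## predictor on i.i.d. stride-duration noise: the median absolute
  ## prediction error sits near 0.8 x the stride sd (the sum of the
  ## next-duration noise and the median-estimator noise), and far below
  ## the stride mean
  set.seed(7)
  err <- c()
  for (rep in 1:10) {
    Tk <- 1.2 * (1 + 0.05 * rnorm(200))
    hs <- cumsum(Tk)
    for (k in 5:199) {
      pred <- predict_next(hs[max(1, k - 3):k])
      err <- c(err, abs(pred - hs[k + 1]))
    }
  }
  sd_stride <- 1.2 * 0.05
  expect_lt(stats::median(err), 0.95 * sd_stride)
  expect_gt(stats::median(err), 0.5 * sd_stride)   # matches the MC oracle
})

test_that("plant integrates commands with actuation delay", {
  p <- controller_params()
  n <- 2000
  acts <- integer(n)
  acts[501:680] <- 1L                 # 180 ms ACCELERATE command
  attr(acts, "tick_s") <- 0.001
  v <- plant_response(acts, p, base_speed = 0.7)
  expect_equal(max(v) - 0.7, 5 * 0.18, tolerance = 1e-6)
  ## rise starts one delay after the command
  expect_equal(v[540], 0.7)
  expect_gt(v[545], 0.7)
  ## returns to base at the same magnitude, never below base
  expect_equal(v[n], 0.7)
  expect_true(all(v >= 0.7 - 1e-12))
  ## no commands: constant speed
  expect_equal(unique(plant_response(integer(100), p, 0.8)), 0.8)
  ## two separated commands: two identical bumps
  acts2 <- integer(3000)
  acts2[301:480] <- 1L
  acts2[2001:2180] <- 1L
  attr(acts2, "tick_s") <- 0.001
  v2 <- plant_response(acts2, p, 0.7)
  expect_equal(max(v2[1:1000]), max(v2[1500:2800]), tolerance = 1e-9)
})

test_that("low-speed logic accelerates after contralateral heel strike", {
  p <- controller_params()
  ps <- periodic_streams(T = 1.3, ds = 0.30)
  a <- run_controller(list(self = ps$self, contra = ps$contra), p,
                      v = 0.45, t_end = 19)
  ## once predictions exist, the acceleration command spans
  ## (TTO_pred - TTOT, TO]: lead of the command start is TTOT - 1 tick
  r <- rle(a == 1L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ep_start <- (starts[r$values] - 1L) / 1000
  ep_len <- r$lengths[r$values]
  expect_gt(length(ep_start), 5)
  for (ts in ep_start) {
    to_next <- min(ps$self_to[ps$self_to >= ts])
    expect_equal((to_next - ts) * 1000, p$TTOT_ms, tolerance = 1.5)
  }
  ## hard bound: no episode exceeds TmaxDur
  expect_true(all(ep_len <= p$TmaxDur_ms))
  ## END is emitted at each toe off
  expect_equal(sum(a == 2L), length(ep_start))
})

test_that("high-speed heel-strike miss pauses exactly three steps", {
  p <- controller_params()
  T <- 1.2; n <- 14; v <- 0.8
  self_hs <- 2 + (0:n) * T
  contra_hs <- self_hs + T / 2
  self_to <- contra_hs + 0.115          # double support 220 - Tant(0.8)
  contra_to <- self_to + T / 2
  k <- 7                                 # miss this stride's contra HS
  sens <- list(self = sensor_table(self_hs, self_to),
               contra = sensor_table(contra_hs[-(k + 1)], contra_to))
  a <- run_controller(sens, p, v, 20)
  expect_equal(sum(a == 3L), 1)          # one PAUSE command
  t_pause <- (which(a == 3L) - 1) / 1000
  ## pause triggered THSdelay after the predicted (missed) heel strike
  expect_equal(t_pause, contra_hs[k + 1] + 0.070, tolerance = 0.003)
  acc <- accel_strides(a, self_hs)
  ## the stride with the miss (m) has its acceleration aborted; the next
  ## two strides are fully acceleration-free; the third step after the
  ## pause is accelerated again
  m <- k + 1                             # stride interval of the miss
  expect_false(any(c(m + 1, m + 2) %in% acc))
  expect_true((m + 3) %in% acc)
  ## no ACCELERATE between the pause and the third subsequent heel strike
  resume <- self_hs[self_hs > t_pause][3]
  acc_t <- (which(a == 1L) - 1) / 1000
  expect_false(any(acc_t > t_pause & acc_t < resume))
})

test_that("toe-off timeout pauses accelerations for three steps", {
  p <- controller_params()
  ps <- periodic_streams(T = 1.3, ds = 0.30)
  k <- 7
  to2 <- ps$self_to
  to2[k + 1] <- to2[k + 1] + 0.30       # toe off 300 ms late
  sens <- list(self = sensor_table(ps$self_hs, to2),
               contra = sensor_table(ps$contra_hs, ps$contra_to))
  a <- run_controller(sens, p, 0.45, 19)
  pauses <- (which(a == 3L) - 1) / 1000
  expect_gte(length(pauses), 1)
  ## first pause fires TmaxDur after the episode's acceleration start
  acc_t <- (which(a == 1L) - 1) / 1000
  t_acc0 <- max(acc_t[acc_t < pauses[1]])
  ep_start <- min(acc_t[acc_t > t_acc0 - 0.3])
  expect_lte(pauses[1] - ep_start, p$TmaxDur_ms / 1000 + 0.002)
  ## after every pause: no acceleration until 3 controlled-leg steps passed
  for (tp in pauses) {
    resume <- ps$self_hs[ps$self_hs > tp][3]
    expect_false(any(acc_t > tp & acc_t < resume))
  }
})

test_that("inconsistent sensor input raises a diagnostic error", {
  p <- controller_params()
  st <- new_controller_state(p)
  expect_error(
    controller_step(st, p, t = 1, v = 0.6,
                    sensors = list(to_self = 1.0)),
    "not in stance")
})

test_that("asymmetric sessions command only the paretic belt", {
  cfg <- gait_config_for_speed(0.7, duration_s = 10)
  ses <- simulate_session(cfg, controller_params(),
                          phases = c(baseline = 3, ramp = 1, exposure = 8,
                                     post = 2),
                          mode = "asymmetric", sensor = "truth")
  expect_equal(unique(ses$commands$leg), cfg$paretic_side)
  other <- setdiff(c("L", "R"), cfg$paretic_side)
  expect_equal(unique(ses$belt[[paste0("v_", other)]]), cfg$base_speed)
  expect_true(all(ses$dose$leg == cfg$paretic_side))
  ## dose never exceeds the hard duration bound
  expect_true(all(ses$dose$realized_duration_ms <=
                    controller_params()$TmaxDur_ms))
})
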