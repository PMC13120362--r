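test_that("configuration invariants are enforced", {
  expect_error(gait_config(base_speed = 0), "base_speed")
  expect_error(gait_config(stride_duration_cv = -0.1), "cv")
  expect_error(gait_config(stance_fraction = c(L = 1.1, R = 0.6)),
               "stance")
  expect_error(gait_config(stance_fraction = c(L = 0.55, R = 0.62),
                           phase_offset = 0.6), "double support")
  expect_warning(gait_config(stride_duration_mean = c(L = 1.1, R = 1.3)),
                 "cadence")
})

test_that("identical config and seed give bit-identical trials", {
  cfg <- gait_config(duration_s = 12, seed = 42)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(t1$forces, t2$forces)
  expect_identical(t1$markers, t2$markers)
  expect_identical(t1$emg, t2$emg)
  expect_identical(t1$truth$strides, t2$truth$strides)
  t3 <- generate_trial(gait_config(duration_s = 12, seed = 43))
  expect_false(identical(t1$forces, t3$forces))
})

test_that("noiseless periodic trials recover ground-truth events exactly", {
  tr <- generate_trial(quiet_config())
  ev <- detect_gait_events(tr)
  fs <- tr$meta$rates$force_hz
  for (leg in c("L", "R")) {
    tru <- tr$truth$events[[leg]]
    n <- min(length(ev[[leg]]$hs), length(tru$hs))
    expect_lte(max(abs(ev[[leg]]$hs[1:n] - tru$hs[1:n])) * fs, 1)
    m <- min(length(ev[[leg]]$to), length(tru$to))
    expect_lte(max(abs(ev[[leg]]$to[1:m] - tru$to[1:m])) * fs, 1)
    ## identical cadence: all strides the same duration
    expect_lt(stats::sd(diff(tru$hs)), 1e-9)
  }
})

test_that("configured trailing limb angle is recovered on every stride", {
  tr <- generate_trial(quiet_config(tla_deg = c(L = 10, R = 10)))
  m <- stride_metrics(tr)
  expect_true(all(abs(m$tla - 10) <= 0.1))
})

test_that("streams run at the advertised rates and stay synchronized", {
  tr <- generate_trial(quiet_config(duration_s = 10))
  expect_equal(1 / median(diff(tr$forces$time_s)), 500, tolerance = 1e-9)
  expect_equal(1 / median(diff(tr$markers$time_s)), 500, tolerance = 1e-9)
  expect_equal(1 / median(diff(tr$emg$time_s)), 1925, tolerance = 1e-9)
  expect_identical(tr$forces$time_s, tr$markers$time_s)
  ## vertical force stays above threshold over mid-stance
  tru <- tr$truth$strides
  s1 <- tru[tru$leg == "L" & tru$stride == 3, ]
  idx <- tr$forces$time_s > s1$t_hs + 0.15 & tr$forces$time_s < s1$t_to - 0.15
  expect_true(all(tr$forces$fz_L[idx] > 50))
})

test_that("artifact injection labels exactly what it corrupts", {
  tr <- generate_trial(quiet_config(duration_s = 15))
  ## rate 0: unchanged trial, empty artifact set
  r0 <- inject_emg_artifacts(tr, list(kind = "spike", rate = 0), seed = 5)
  expect_identical(r0$trial$emg, tr$emg)
  expect_equal(nrow(r0$artifact_strides), 0)
  ## a single targeted spike marks that stride
  r1 <- inject_emg_artifacts(tr, list(kind = "spike", strides = 4,
                                      amplitude = 100,
                                      muscles = "SOL", legs = "L"),
                             seed = 5)
  expect_equal(r1$artifact_strides$stride, 4)
  expect_equal(r1$artifact_strides$muscle, "SOL")
  expect_false(identical(r1$trial$emg$SOL_L, tr$emg$SOL_L))
  expect_identical(r1$trial$emg$LGAS_L, tr$emg$LGAS_L)
  ## fixed seed reproduces the artifact set
  r2 <- inject_emg_artifacts(tr, list(kind = "dropout", rate = 0.3), seed = 9)
  r3 <- inject_emg_artifacts(tr, list(kind = "dropout", rate = 0.3), seed = 9)
  expect_identical(r2$artifact_strides, r3$artifact_strides)
  expect_error(inject_emg_artifacts(tr, list(kind = "nope", rate = 0.1)),
               "unknown artifact kind")
  expect_error(inject_emg_artifacts(tr, list(kind = "spike", rate = 1.2)),
               "rate")
})

test_that("belt profile drives stance kinematics and stride length", {
  cfg <- quiet_config(duration_s = 16, hip_sway_amp = 0, hip_bob_amp = 0)
  tr <- generate_trial(cfg)
  v <- cfg$base_speed
  tru <- tr$truth$strides
  ## constant belt, periodic gait: SL = v * stride duration
  expect_true(all(abs(tru$sl - v * tru$stride_duration) < 1e-6))
  ## ankle antero-posterior velocity during stance equals -belt speed
  s <- tru[tru$leg == "L" & tru$stride == 4, ]
  idx <- which(tr$markers$time_s > s$t_hs + 0.05 &
                 tr$markers$time_s < s$t_to - 0.05)
  vel <- diff(tr$markers$LM_L_x[idx]) * 500
  expect_true(all(abs(vel + v) < 1e-6))

  ## zero belt: only marker displacement remains (here zero)
  belt0 <- data.frame(time_s = tr$belt$time_s, v_L = 0, v_R = 0)
  tr0 <- apply_belt_profile(tr, belt0)
  expect_true(all(abs(tr0$truth$strides$sl) < 1e-9))

  ## a pulse inside one cycle changes only that stride's SL, by its area
  tb <- tr$belt$time_s
  s5 <- tru[tru$leg == "L" & tru$stride == 5, ]
  pulse <- ifelse(tb >= s5$t_hs + 0.05 & tb < s5$t_hs + 0.15, 0.5, 0)
  beltp <- data.frame(time_s = tb, v_L = v + pulse, v_R = v + pulse)
  trp <- apply_belt_profile(tr, beltp)
  dp <- merge(trp$truth$strides, tru, by = c("leg", "stride"),
              suffixes = c("_p", ""))
  dsl <- dp$sl_p - dp$sl
  changed <- abs(dsl) > 1e-6
  area <- 0.5 * 0.1
  for (leg in c("L", "R")) {
    ch <- dp[changed & dp$leg == leg, ]
    expect_equal(nrow(ch), 1)       # exactly one cycle per leg contains it
    expect_equal(ch$sl_p - ch$sl, area, tolerance = 1e-6)
  }
  ## negative belt speed is rejected
  expect_error(apply_belt_profile(tr, data.frame(time_s = tb, v_L = -0.1,
                                                 v_R = v)),
               "non-negative")
})

test_that("trial directories round-trip through plain-text files", {
  tr <- generate_trial(quiet_config(duration_s = 8))
  dir <- tempfile("trial")
  write_trial(tr, dir)
  expect_true(all(file.exists(file.path(dir,
    c("forces.csv", "markers.csv", "emg.csv", "belt.csv", "meta.json",
      "truth.json")))))
  tr2 <- read_trial(dir)
  expect_equal(tr2$forces$fz_L, tr$forces$fz_L, tolerance = 1e-9)
  expect_equal(tr2$meta$bodyweight_N, tr$meta$bodyweight_N)
  ev <- detect_gait_events(tr2)
  expect_gt(length(ev$L$hs), 3)
  unlink(dir, recursive = TRUE)
})
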