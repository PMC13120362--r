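test_that("envelope rejects DC and tracks a rectified sine", {
  fs <- 1925
  t <- seq(0, 3, by = 1 / fs)
  env_dc <- emg_envelope(rep(1, length(t)), fs)
  mid <- env_dc[2000:4000]
  expect_lt(max(mid), 1e-3)
  ## 100 Hz sine of amplitude A: steady-state envelope ~ 2A/pi
  A <- 0.8
  env_s <- emg_envelope(A * sin(2 * pi * 100 * t), fs)
  expect_equal(mean(env_s[2000:4000]), 2 * A / pi,
               tolerance = 0.05 * 2 * A / pi)
  expect_true(all(env_s >= 0))
  expect_error(emg_envelope(rep(0, 100), 900), "exceed 1000")
})

test_that("envelope peaks align with burst centers", {
  fs <- 1925
  t <- seq(0, 6, by = 1 / fs)
  centers <- c(1, 2.5, 4, 5.5)
  m <- rowSums(vapply(centers, function(c0)
    exp(-(t - c0)^2 / (2 * 0.05^2)), numeric(length(t))))
  set.seed(8)
  x <- m * stats::rnorm(length(t))
  env <- emg_envelope(x, fs)
  for (c0 in centers) {
    w <- which(t > c0 - 0.3 & t < c0 + 0.3)
    t_peak <- t[w][which.max(env[w])]
    expect_lt(abs(t_peak - c0), 0.010)
  }
})

test_that("phase resampling emits exactly 200 or 300 points", {
  fs <- 1925
  t <- seq(0, 3, by = 1 / fs)
  env <- data.frame(time_s = t, value = 0.5 + 0.1 * sin(2 * pi * t))
  ev <- list(hs = 1, to = 1.7, hs_next = 2.2, to_contra = 1.15)
  s1 <- resample_stride(env, ev, "stance_swing")
  expect_length(s1$samples, 200)
  expect_equal(s1$phase_breaks, 100L)
  s2 <- resample_stride(env, ev, "ta")
  expect_length(s2$samples, 300)
  expect_equal(s2$phase_breaks, c(100L, 200L))
  ## constant envelope resamples to the constant
  envc <- data.frame(time_s = t, value = 0.37)
  expect_equal(unique(resample_stride(envc, ev, "stance_swing")$samples),
               0.37)
  expect_equal(unique(resample_stride(envc, ev, "ta")$samples), 0.37)
  ## missing events abort the stride
  expect_error(resample_stride(env, list(hs = 1, to = NA, hs_next = 2.2),
                               "stance_swing"), "missing events")
  ## every accepted stride of a real trial has the exact length
  tr <- generate_trial(quiet_config(duration_s = 12))
  act <- emg_activations(tr, baseline_window = c(0, 12))
  expect_true(all(table(act$muscle) > 0))
})

test_that("region-of-interest activation isolates the right phase", {
  ev_t <- list(hs = 1, to = 1.7, hs_next = 2.2, to_contra = 1.15)
  fs <- 1925
  t <- seq(0, 3, by = 1 / fs)
  ## constant envelope: activation equals the constant for every muscle
  envc <- data.frame(time_s = t, value = 0.42)
  st <- resample_stride(envc, ev_t, "stance_swing")
  for (mus in c("SOL", "LGAS", "MGAS", "TACC"))
    expect_equal(roi_activation(st, mus)$value, 0.42)
  sta <- resample_stride(envc, ev_t, "ta")
  expect_equal(roi_activation(sta, "TA", next_stride = sta)$value, 0.42)
  ## envelope 0 in first half of stance, 1 in second half: activation 1
  env01 <- data.frame(time_s = t,
                      value = ifelse(t >= 1.35 & t < 1.7, 1, 0))
  st2 <- resample_stride(env01, ev_t, "stance_swing")
  expect_equal(roi_activation(st2, "SOL")$value, 1, tolerance = 0.03)
  ## index-set oracle on random strides
  set.seed(10)
  for (rep in 1:20) {
    s <- list(samples = stats::runif(200), scheme = "stance_swing")
    class(s) <- "envelope_stride"
    expect_equal(roi_activation(s, "MGAS")$value, mean(s$samples[51:100]))
    expect_equal(roi_activation(s, "MGAS")$roi_peak, max(s$samples[51:100]))
  }
  ## TA: swing segment plus the following stride's double support
  s1 <- list(samples = c(rep(0.2, 100), rep(0, 100), rep(0.6, 100)),
             scheme = "ta")
  s2 <- list(samples = c(rep(0.4, 100), rep(0, 200)), scheme = "ta")
  class(s1) <- class(s2) <- "envelope_stride"
  expect_equal(roi_activation(s1, "TA", s2)$value, mean(c(0.6, 0.4)))
  expect_true(is.na(roi_activation(s1, "TA")$value))
})

test_that("normalization divides by mean baseline peak and is gain invariant", {
  set.seed(12)
  act <- stats::runif(30, 0.2, 0.5)
  peaks <- act * stats::runif(30, 1.2, 1.6)
  nz <- normalize_activation(act, peaks, baseline_idx = 1:10)
  ## two-pass oracle
  expect_equal(nz$baseline_norm, mean(peaks[1:10]))
  expect_equal(nz$values, act / mean(peaks[1:10]))
  ## identical strides: normalized per-stride peak is 1
  nid <- normalize_activation(rep(0.3, 8), rep(0.9, 8), 1:8)
  expect_equal(unique(nid$values * 3), 1)
  ## gain invariance
  k <- 7.7
  nk <- normalize_activation(k * act, k * peaks, 1:10)
  expect_equal(nk$values, nz$values, tolerance = 1e-12)
  ## flatline channel flagged unusable
  expect_warning(nf <- normalize_activation(act, rep(0, 30), 1:10),
                 "flatline")
  expect_false(nf$usable)
  expect_true(all(is.na(nf$values)))
})

test_that("outlier screening flags spikes and spares homogeneous data", {
  ## homogeneous strides: zero dispersion, nothing removed
  m0 <- matrix(0.5, nrow = 10, ncol = 200)
  expect_true(all(remove_outlier_strides(m0, 51:100)))
  expect_error(remove_outlier_strides(m0[1:4, ], 51:100), "at least 5")
  ## one 100x spike among 50 clean strides: exactly that stride removed
  set.seed(13)
  base <- matrix(stats::runif(50 * 200, 0.4, 0.6), nrow = 50)
  base[23, 120] <- 50
  keep <- remove_outlier_strides(base, 51:100)
  expect_equal(which(!keep), 23)
  ## spike inside the ROI is caught by the max pass as well
  base2 <- matrix(stats::runif(50 * 200, 0.4, 0.6), nrow = 50)
  base2[7, 60] <- 50
  expect_equal(which(!remove_outlier_strides(base2, 51:100)), 7)
  ## permutation equivariance
  perm <- sample(50)
  keep_p <- remove_outlier_strides(base[perm, ], 51:100)
  expect_equal(keep_p, keep[perm])
  ## idempotence on survivors (homogeneous remainder)
  keep2 <- remove_outlier_strides(base[keep, ], 51:100)
  expect_true(all(keep2))
})

test_that("activation recovery and screening work end to end", {
  tr <- generate_trial(quiet_config(duration_s = 18))
  act <- emg_activations(tr, baseline_window = c(0, 18))
  cmp <- merge(act, tr$truth$activation,
               by = c("leg", "muscle", "stride"))
  cmp <- cmp[!is.na(cmp$raw) & !is.na(cmp$value), ]
  expect_gt(nrow(cmp), 50)
  expect_lt(max(abs(cmp$raw - cmp$value) / cmp$value), 0.01)
  expect_equal(sum(cmp$outlier), 0)
  ## identical strides: normalized per-stride ROI peak is 1
  npk <- act$roi_peak * act$normalized / act$raw
  expect_true(all(abs(npk[!is.na(npk)] - 1) < 1e-3))
})
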