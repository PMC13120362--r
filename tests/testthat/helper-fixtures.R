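# shared fixtures built in code

## compact noiseless configuration for recovery tests
quiet_config <- function(duration_s = 20, seed = 1L, ...) {
  gait_config(duration_s = duration_s, stride_duration_cv = 0,
              noise_sd = list(force = 0, marker = 0, emg = 0),
              seed = seed, ...)
}

## sensor event table from explicit heel-strike / toe-off times
sensor_table <- function(hs, to, confirm_delay = 0) {
  d <- data.frame(type = rep(c("hs", "to"), c(length(hs), length(to))),
                  t_cross = c(hs, to),
                  t_confirm = c(hs, to) + confirm_delay)
  d[order(d$t_confirm), ]
}

## periodic two-leg event streams (self + contra) for controller scenarios
periodic_streams <- function(T = 1.3, n = 14, t0 = 2, po = 0.5,
                             ds = 0.30) {
  self_hs <- t0 + (0:n) * T
  contra_hs <- self_hs + po * T
  self_to <- contra_hs + ds
  contra_to <- self_hs[-1] + ds
  list(self = sensor_table(self_hs, self_to),
       contra = sensor_table(contra_hs, contra_to),
       self_hs = self_hs, self_to = self_to,
       contra_hs = contra_hs, contra_to = contra_to)
}

## stride index of each tick time, by the controlled leg's heel strikes
accel_strides <- function(actions, self_hs, tick_s = 0.001) {
  t_acc <- (which(actions == 1L) - 1L) * tick_s
  sort(unique(findInterval(t_acc, self_hs)))
}
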