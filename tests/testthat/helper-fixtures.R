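# recording with constant per-foot force wherever the foot is "on"
square_recording <- function(left_on, right_on, fs = 100, force = 700,
                             subject_id = "SQ") {
  n <- length(left_on)
  mk <- function(on) matrix(on * force / 8, n, 8)
  insole_recording(subject_id, (seq_len(n) - 1) / fs,
                   mk(left_on), mk(right_on), sampling_rate = fs)
}

# per-foot contact vectors for k identical cycles with the phase pattern
# DLS1 -> SLS-R -> DLS2 -> SLS-L (durations in samples), plus a lead-in
# (mid SLS-L) and a trailing DLS so every cycle is observable
cycle_pattern <- function(k, dls1, slsr, dls2, slsl, lead = 20, tail = 15) {
  l1 <- c(rep(TRUE, dls1), rep(FALSE, slsr), rep(TRUE, dls2 + slsl))
  r1 <- c(rep(TRUE, dls1 + slsr + dls2), rep(FALSE, slsl))
  list(left = c(rep(TRUE, lead), rep(l1, k), rep(TRUE, tail)),
       right = c(rep(FALSE, lead), rep(r1, k), rep(TRUE, tail)))
}

# deterministic gait profile: fixed stride, 60% stance, 10% DLS episodes
rigid_profile <- function(...) {
  args <- list(stride_time_mean = 1.0, stride_time_cv = 0,
               stance_fraction_mean = 0.60, stance_fraction_sd = 0,
               double_support_fraction_mean = 0.10,
               double_support_fraction_sd = 0, sensor_noise_sd = 0)
  extra <- list(...)
  do.call(gait_profile, utils::modifyList(args, extra))
}

# per-boundary sample errors of the detected cycles against the ground truth
boundary_errors <- function(truth, cycleset) {
  seg <- attr(cycleset, "segmentation")
  v <- seg[seg$valid, , drop = FALSE]
  m <- vapply(v$start, function(st) which.min(abs(truth$cycles$i_start - st)), 0L)
  cbind(v$start - truth$cycles$i_start[m],
        v$i_slsr - truth$cycles$i_slsr[m],
        v$i_dls2 - truth$cycles$i_dls2[m],
        v$i_slsl - truth$cycles$i_slsl[m],
        v$end - truth$cycles$i_end[m])
}

# minimal per-cycle parameter table for feature-level tests
params_from_swing <- function(swing_left_s, stride_s = 1) {
  n <- length(swing_left_s)
  stride <- rep_len(stride_s, n)
  df <- data.frame(start = seq_len(n), end = seq_len(n) + 1,
                   stride_s = stride,
                   stance_left_s = stride - swing_left_s,
                   stance_right_s = stride - swing_left_s,
                   swing_left_s = swing_left_s, swing_right_s = swing_left_s,
                   dls_s = stride - 2 * swing_left_s,
                   sls_left_s = swing_left_s, sls_right_s = swing_left_s,
                   step_left_s = stride / 2, step_right_s = stride / 2)
  for (col in setdiff(names(df), c("start", "end", "stride_s")))
    df[[sub("_s$", "_pct", col)]] <- 100 * df[[col]] / stride
  df
}
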