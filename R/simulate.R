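#' Two-peak stance-phase VGRF waveform
#'
#' Smooth template of the vertical ground reaction force of one foot over one
#' stance phase, as a multiple of body weight against normalized stance phase
#' `u` in \[0, 1\]. Piecewise raised-cosine interpolation through the classic
#' "M" shape: zero at heel strike and toe off, a fast loading/unloading
#' transient over the first and last 1.5% of stance, peaks at 25% and 75% of
#' stance, and a mid-stance valley below body weight.
#'
#' @param u normalized stance phase, clipped to \[0, 1\].
#' @param peak_ratio peak height as a multiple of body weight.
#' @param valley mid-stance valley as a multiple of body weight.
#' @param shoulder force level at the end of the loading transient (multiple
#'   of body weight).
#' @param rise duration of the loading transient as a fraction of stance.
#' @return numeric vector of force multipliers.
#' @export
stance_waveform <- function(u, peak_ratio = 1.15, valley = 0.75,
                            shoulder = 0.55, rise = 0.015) {
  u <- clamp(u, 0, 1)
  uk <- c(0, rise, 0.25, 0.5, 0.75, 1 - rise, 1)
  vk <- c(0, shoulder, peak_ratio, valley, peak_ratio, shoulder, 0)
  seg <- findInterval(u, uk, rightmost.closed = TRUE)
  s <- (u - uk[seg]) / (uk[seg + 1] - uk[seg])
  vk[seg] + (vk[seg + 1] - vk[seg]) * (1 - cos(pi * s)) / 2
}

# heel-to-toe activation schedule: Gaussian windows over stance phase,
# sensor 1 = heel ... sensor 8 = toe; rows renormalized to preserve the total
sensor_weights <- function(u, centers = seq(0.10, 0.90, length.out = 8),
                           sigma = 0.18) {
  w <- exp(-0.5 * outer(u, centers, "-")^2 / sigma^2)
  w / rowSums(w)
}

#' Simulate one subject's insole trial
#'
#' Generates a two-foot, eight-sensor VGRF recording with the phase structure
#' DLS1 -> SLS-R -> DLS2 -> SLS-L per gait cycle, together with the exact
#' ground-truth gait events and a metadata row. During each foot's stance the
#' total force follows [stance_waveform()] scaled by the subject's body
#' weight and is distributed across the eight sensors by a heel-to-toe
#' activation schedule; force is exactly zero during swing before noise.
#' Additive Gaussian sensor noise is truncated at zero and totals are
#' recomputed as sensor sums after noise.
#'
#' Per-cycle phase fractions are drawn as: both swing fractions and both DLS
#' episodes from their stated Gaussians, after which the two DLS episodes
#' absorb (equally) the closure residual so the four phases tile the stride
#' exactly. Swing and stance fractions therefore carry exactly the programmed
#' stride-to-stride SD, while the DLS episodes inherit some extra variance.
#'
#' The trial starts mid-SLS-L (a short left-foot-only lead-in) and ends with
#' a trailing DLS, so every programmed cycle boundary appears as an observable
#' phase transition.
#'
#' @param profile a [gait_profile()].
#' @param duration target trial duration, seconds; must cover at least 3
#'   stride times.
#' @param sampling_rate sampling rate, Hz.
#' @param seed integer seed; the call is fully deterministic given it.
#' @param subject_id,group,cohort metadata fields.
#' @return list with elements `recording` ([insole_recording()]), `truth`
#'   (class `gait_truth`; see Details) and `meta` (one-row data.frame).
#'   `truth$cycles` has one row per programmed cycle with the continuous
#'   event times (`t_start`, `t_slsr`, `t_dls2`, `t_slsl`, `t_end`), the
#'   matching first-sample indices (`i_*`, 1-based, half-open ends), the
#'   stride time and the four phase fractions; `truth$left_contact` /
#'   `truth$right_contact` are the per-foot contact intervals.
#' @export
simulate_subject <- function(profile, duration = 60, sampling_rate = 100,
                             seed = 1L, subject_id = "S01", group = "HS",
                             cohort = 1L) {
  stopifnot(inherits(profile, "gait_profile"))
  p <- profile
  fs <- sampling_rate
  set.seed(as.integer(as.numeric(seed) %% 2147483647))

  # subject-level parameter draws (between-subject heterogeneity)
  T_bar <- clamp(stats::rnorm(1, p$stride_time_mean, p$stride_time_between_sd),
                 0.6 * p$stride_time_mean, 1.6 * p$stride_time_mean)
  cv <- clamp(stats::rnorm(1, p$stride_time_cv, p$stride_time_cv_between_sd),
              0, 0.25)
  st_f <- clamp(stats::rnorm(1, p$stance_fraction_mean, p$stance_fraction_between_sd),
                0.52, 0.78)
  st_sd <- clamp(stats::rnorm(1, p$stance_fraction_sd, p$stance_fraction_sd_between_sd),
                 0, 0.08)
  # subject stance shift moves the DLS episodes equally, preserving tiling
  d_f <- clamp(p$double_support_fraction_mean + (st_f - p$stance_fraction_mean),
               0.02, 0.35)
  d_sd <- clamp(stats::rnorm(1, p$double_support_fraction_sd,
                             p$double_support_fraction_sd_between_sd),
                0, 0.05)
  bw <- clamp(stats::rnorm(1, p$body_weight, p$body_weight_between_sd), 300, 1500)

  lead <- 0.5 * (1 - st_f) * T_bar
  tail <- 0.25
  n_cyc <- floor((duration - lead - tail) / T_bar)
  if (duration < 3 * p$stride_time_mean || n_cyc < 3)
    gm_stop("duration must cover at least 3 stride times",
            "gaitmark_validation_error")

  # per-cycle draws
  Ti <- clamp(stats::rnorm(n_cyc, T_bar, cv * T_bar), 0.5 * T_bar, 1.6 * T_bar)
  sR <- clamp(stats::rnorm(n_cyc, 1 - st_f, st_sd), 0.12, 0.47) # left swing
  sL <- clamp(stats::rnorm(n_cyc, 1 - st_f, st_sd), 0.12, 0.47) # right swing
  d1 <- clamp(stats::rnorm(n_cyc, d_f, d_sd), 0.02, 0.34)
  d2 <- clamp(stats::rnorm(n_cyc, d_f, d_sd), 0.02, 0.34)
  resid <- 1 - (sR + sL + d1 + d2)
  d1 <- d1 + resid / 2
  d2 <- d2 + resid / 2
  # repair rare negative DLS episodes by shortening the swings
  short <- pmax(0.015 - d1, 0) + pmax(0.015 - d2, 0)
  d1 <- pmax(d1, 0.015); d2 <- pmax(d2, 0.015)
  sR <- sR - short / 2; sL <- sL - short / 2

  t0 <- lead + c(0, cumsum(Ti))[seq_len(n_cyc)]
  t1 <- t0 + d1 * Ti
  t2 <- t1 + sR * Ti
  t3 <- t2 + d2 * Ti
  t4 <- t0 + Ti
  t_end <- lead + sum(Ti)
  total_dur <- t_end + tail
  n_samp <- floor(total_dur * fs)
  time <- (seq_len(n_samp) - 1) / fs

  right_iv <- rbind(cbind(t0, t3), c(t_end, total_dur + 1 / fs))
  left_iv <- rbind(c(0, t1[1]),
                   if (n_cyc > 1) cbind(t2[-n_cyc], t1[-1]),
                   c(t2[n_cyc], total_dur + 1 / fs))

  foot_channels <- function(iv) {
    total <- numeric(n_samp)
    u_all <- rep(NA_real_, n_samp)
    for (k in seq_len(nrow(iv))) {
      a <- iv[k, 1]; b <- min(iv[k, 2], total_dur)
      i0 <- time_to_index(a, fs)
      i1 <- min(floor(b * fs + 1 - 1e-9), n_samp)
      if (i1 < i0) next
      idx <- i0:i1
      # quarter-sample floor: a sample landing exactly on the contact onset
      # carries the force a quarter sample-period into stance, so sampled
      # force is strictly positive on every in-contact sample
      u <- pmax((time[idx] - a) / (iv[k, 2] - a), 0.25 / (fs * (iv[k, 2] - a)))
      total[idx] <- bw * stance_waveform(u, p$peak_ratio)
      u_all[idx] <- clamp(u, 0, 1)
    }
    sens <- matrix(0, n_samp, 8)
    on <- !is.na(u_all)
    if (any(on)) sens[on, ] <- total[on] * sensor_weights(u_all[on])
    sens
  }

  ls <- foot_channels(left_iv)
  rs <- foot_channels(right_iv)
  if (p$sensor_noise_sd > 0) {
    ls <- pmax(ls + stats::rnorm(length(ls), 0, p$sensor_noise_sd), 0)
    rs <- pmax(rs + stats::rnorm(length(rs), 0, p$sensor_noise_sd), 0)
  }

  rec <- insole_recording(subject_id, time, ls, rs,
                          sampling_rate = fs, units = "newton")

  truth <- structure(list(
    cycles = data.frame(
      t_start = t0, t_slsr = t1, t_dls2 = t2, t_slsl = t3, t_end = t4,
      i_start = time_to_index(t0, fs), i_slsr = time_to_index(t1, fs),
      i_dls2 = time_to_index(t2, fs), i_slsl = time_to_index(t3, fs),
      i_end = time_to_index(t4, fs),
      stride = Ti, dls1 = d1, sls_r = sR, dls2 = d2, sls_l = sL),
    left_contact = data.frame(start = left_iv[, 1],
                              end = pmin(left_iv[, 2], total_dur)),
    right_contact = data.frame(start = right_iv[, 1],
                               end = pmin(right_iv[, 2], total_dur)),
    sampling_rate = fs, body_weight = bw, subject = list(
      stride_time_mean = T_bar, stride_time_cv = cv, stance_fraction = st_f,
      stance_fraction_sd = st_sd, dls_fraction = d_f, dls_fraction_sd = d_sd)),
    class = "gait_truth")

  meta <- data.frame(
    subject_id = subject_id, group = group, cohort = cohort,
    age = round(clamp(stats::rnorm(1, if (group == "PD") 67 else 62, 9), 30, 90)),
    gender = sample(c("M", "F"), 1, prob = c(0.6, 0.4)),
    gait_speed = clamp(stats::rnorm(1, p$gait_speed_mean, p$gait_speed_sd), 0.2, 3),
    tug = clamp(stats::rnorm(1, p$tug_mean, p$tug_sd), 3, 60),
    hoehn_yahr = if (group == "PD")
      round(clamp(stats::rnorm(1, 2.4, 0.4), 2, 3), 1) else NA_real_,
    updrs = if (group == "PD")
      round(clamp(stats::rnorm(1, 31, 11), 5, 80)) else NA_real_,
    stringsAsFactors = FALSE)

  list(recording = rec, truth = truth, meta = meta)
}

#' Simulate a two-group cohort
#'
#' Runs [simulate_subject()] for `n_hs` healthy-like and `n_pd` PD-like
#' subjects, with per-subject seeds derived deterministically from the master
#' seed via [subject_seed()] (HS subjects take indices `1..n_hs`, PD subjects
#' the following ones, so a subject's data depends only on the master seed
#' and its index).
#'
#' @param hs_profile,pd_profile group [gait_profile()]s.
#' @param n_hs,n_pd group sizes (default 88 and 108).
#' @param duration,sampling_rate passed to [simulate_subject()].
#' @param seed master seed.
#' @return list with `recordings` (list), `truths` (list) and `meta`
#'   (data.frame, HS rows first).
#' @export
simulate_cohort <- function(hs_profile = hs_gait_profile(),
                            pd_profile = pd_gait_profile(),
                            n_hs = 88, n_pd = 108,
                            duration = 60, sampling_rate = 100, seed = 1L) {
  stopifnot(n_hs >= 1, n_pd >= 1)
  groups <- c(rep("HS", n_hs), rep("PD", n_pd))
  ids <- c(sprintf("HS%03d", seq_len(n_hs)), sprintf("PD%03d", seq_len(n_pd)))
  recs <- vector("list", n_hs + n_pd)
  truths <- vector("list", n_hs + n_pd)
  metas <- vector("list", n_hs + n_pd)
  for (i in seq_along(groups)) {
    prof <- if (groups[i] == "HS") hs_profile else pd_profile
    sim <- simulate_subject(prof, duration, sampling_rate,
                            seed = subject_seed(seed, i),
                            subject_id = ids[i], group = groups[i])
    recs[[i]] <- sim$recording
    truths[[i]] <- sim$truth
    metas[[i]] <- sim$meta
  }
  names(recs) <- names(truths) <- ids
  list(recordings = recs, truths = truths, meta = do.call(rbind, metas))
}

#' Degrade a calibrated recording to raw voltages
#'
#' Emulates uncalibrated insole hardware: maps force linearly onto the ADC
#' voltage range, `volt = force / max_output * volt_full_scale`, where
#' `max_output` is the maximal force the electronic system can represent.
#' Forces above `max_output` saturate: they are clipped with a warning, and
#' the clipped-sample count is attached as attribute `"clipped"`.
#' [normalize_voltage()] inverts this map up to the percent scale.
#'
#' @param recording an [insole_recording()] in newtons.
#' @param max_output full-scale force of the device, newtons.
#' @param volt_full_scale ADC reference voltage (default 3.3 V).
#' @return an `insole_recording` with `units = "volt"`.
#' @export
degrade_to_voltage <- function(recording, max_output, volt_full_scale = 3.3) {
  if (recording$units != "newton")
    gm_stop("degrade_to_voltage expects a recording in newtons",
            "gaitmark_validation_error")
  if (max_output <= 0) gm_stop("max_output must be > 0", "gaitmark_validation_error")
  gain <- volt_full_scale / max_output
  conv <- function(x) clamp(x * gain, 0, volt_full_scale)
  n_clip <- sum(recording$left_sensors > max_output) +
    sum(recording$right_sensors > max_output)
  if (n_clip > 0)
    warning(sprintf("%d sensor samples above device full scale were clipped", n_clip),
            call. = FALSE)
  ls <- conv(recording$left_sensors)
  rs <- conv(recording$right_sensors)
  # each sensor channel saturates individually; totals are re-summed
  out <- insole_recording(recording$subject_id, recording$time, ls, rs,
                          rowSums(ls), rowSums(rs),
                          sampling_rate = recording$sampling_rate,
                          units = "volt", validate = FALSE)
  attr(out, "clipped") <- n_clip
  attr(out, "volt_full_scale") <- volt_full_scale
  out
}
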