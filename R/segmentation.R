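#' Differential ground reaction force
#'
#' The differential GRF is the difference between the total right-foot and
#' total left-foot force, `delta = R_tot - L_tot`, evaluated at every sample.
#' It is the signal on which gait-cycle segmentation is anchored and the
#' standard QC trace: positive during right single-limb support, negative
#' during left single-limb support, near the inter-foot difference during
#' double support.
#'
#' @param recording an [insole_recording()].
#' @return data.frame of class `differential_grf` with columns `time` and
#'   `delta`, same length as the recording.
#' @export
differential_grf <- function(recording) {
  structure(data.frame(time = recording$time,
                       delta = recording$right_total - recording$left_total),
            class = c("differential_grf", "data.frame"),
            units = recording$units)
}

# flip runs (of either state) shorter than min_len samples into their
# neighbours, shortest first; runs at the trial edges are never flipped.
# operates on the run-length encoding (flipping run j merges j-1, j, j+1)
debounce <- function(x, min_len) {
  if (min_len <= 1) return(x)
  r <- rle(x)
  len <- r$lengths; val <- r$values
  repeat {
    k <- length(len)
    if (k <= 2) break
    short <- which(len < min_len)
    short <- short[short > 1 & short < k]
    if (length(short) == 0) break
    j <- short[which.min(len[short])]
    len <- c(len[seq_len(j - 2)], len[j - 1] + len[j] + len[j + 1],
             len[-seq_len(j + 1)])
    val <- val[-c(j, j + 1)]
  }
  rep(val, len)
}

#' Detect per-foot ground contact
#'
#' A foot is in contact wherever its total force exceeds the contact
#' threshold, after debouncing: contact/no-contact runs shorter than
#' `min_phase_duration` are merged into their neighbours (suppresses sensor
#' chatter at heel strike and noise spikes during swing).
#'
#' @param recording an [insole_recording()].
#' @param contact_threshold force threshold. `NULL` picks the default for
#'   the recording's units: 20 N for newton-calibrated data, 3% of the
#'   per-subject maximum total force otherwise; `"auto"` uses
#'   [suggest_contact_threshold()], which is robust to a truncation-noise
#'   floor on uncalibrated hardware.
#' @param min_phase_duration minimum credible phase duration in seconds
#'   (default 0.05 s, i.e. 5 samples at 100 Hz).
#' @return list of class `contact_series` with logical vectors `left` and
#'   `right`, the thresholds used, and the time axis.
#' @export
detect_contact <- function(recording, contact_threshold = NULL,
                           min_phase_duration = 0.05) {
  fs <- recording$sampling_rate
  thr <- contact_threshold
  if (is.null(thr)) {
    thr <- if (recording$units == "newton") c(20, 20) else
      0.03 * c(max(recording$left_total), max(recording$right_total))
  } else if (identical(thr, "auto")) {
    thr <- c(suggest_contact_threshold(recording$left_total),
             suggest_contact_threshold(recording$right_total))
  } else {
    thr <- rep_len(as.numeric(thr), 2)
  }
  if (any(thr <= 0)) gm_stop("contact threshold must be > 0", "gaitmark_validation_error")
  min_len <- max(1L, round(min_phase_duration * fs))
  left <- debounce(recording$left_total > thr[1], min_len)
  right <- debounce(recording$right_total > thr[2], min_len)
  if (!any(left) || !any(right))
    gm_stop("no gait detected: a foot never crosses the contact threshold",
            "gaitmark_nogait_error")
  structure(list(left = left, right = right, contact_threshold = thr,
                 min_phase_duration = min_phase_duration,
                 sampling_rate = fs, time = recording$time),
            class = "contact_series")
}

#' Noise-robust contact threshold suggestion
#'
#' Estimates the no-load baseline of a total-force channel from its
#' lowest-35% samples (swing occupies roughly 40% of a walking trial) and
#' places the threshold eight baseline-SDs above the baseline mean, with a
#' 20 N floor. On clean data this returns 20 N; on data with a
#' truncated-at-zero noise floor it clears the floor with high margin.
#'
#' @param total numeric total-force channel.
#' @return threshold on the channel's scale.
#' @export
suggest_contact_threshold <- function(total) {
  base <- total[total <= stats::quantile(total, 0.35)]
  max(20, mean(base) + 8 * stats::sd(base))
}

#' Label gait phases per sample
#'
#' Pure per-sample truth table on the two contact series: both feet loaded
#' is double limb support (DLS), only the left foot is left single limb
#' support (SLS-L), only the right is SLS-R, neither is airborne (cannot
#' occur in walking; flagged downstream).
#'
#' @param contact a [detect_contact()] result.
#' @return list of class `phase_labels` with `labels` (factor with levels
#'   DLS, SLS-R, SLS-L, airborne), the time axis and sampling rate.
#' @export
label_phases <- function(contact) {
  lab <- ifelse(contact$left & contact$right, "DLS",
                ifelse(contact$right, "SLS-R",
                       ifelse(contact$left, "SLS-L", "airborne")))
  structure(list(labels = factor(lab, levels = c("DLS", "SLS-R", "SLS-L", "airborne")),
                 time = contact$time, sampling_rate = contact$sampling_rate),
            class = "phase_labels")
}

#' Segment gait cycles from phase labels
#'
#' A gait cycle is anchored between the first double limb support and the end
#' of the subsequent left single limb support: it starts at the onset of a
#' DLS run that is immediately followed by SLS-R, and ends at the onset of
#' the next such DLS (half-open sample interval `[start, end)`), so cycles
#' are non-overlapping and exhaustive. Candidate cycles whose interior is not
#' exactly DLS -> SLS-R -> DLS -> SLS-L are kept in the output but marked
#' rejected: reason `"airborne gap"` if they contain airborne samples,
#' `"irregular phase pattern"` otherwise. Leading and trailing fragments are
#' dropped.
#'
#' @param phases a [label_phases()] result.
#' @return data.frame of class `gait_cycles` with 1-based sample indices
#'   `start`, `i_slsr`, `i_dls2`, `i_slsl`, `end` and columns `valid`
#'   (logical) and `reason`; attribute `"sampling_rate"`.
#' @export
segment_cycles <- function(phases) {
  lab <- as.character(phases$labels)
  r <- rle(lab)
  k <- length(r$lengths)
  run_start <- cumsum(c(1, r$lengths[-k]))
  starts_at <- which(r$values == "DLS" & c(r$values[-1], "") == "SLS-R")
  if (length(starts_at) < 1)
    gm_stop("insufficient gait: fewer than 1 complete cycle", "gaitmark_nogait_error")
  # a complete cycle needs its four phase runs plus the onset of the next
  # DLS (which closes the SLS-L); otherwise it is a fragment or malformed
  j0 <- starts_at
  ok <- j0 + 4 <= k &
    c(r$values, "")[j0 + 1] == "SLS-R" & c(r$values, "", "")[j0 + 2] == "DLS" &
    c(r$values, "", "", "")[j0 + 3] == "SLS-L" &
    c(r$values, "", "", "", "")[pmin(j0 + 4, k)] == "DLS"
  n_c <- length(j0)
  cycles <- data.frame(
    start = run_start[j0],
    i_slsr = ifelse(ok, run_start[pmin(j0 + 1, k)], NA_integer_),
    i_dls2 = ifelse(ok, run_start[pmin(j0 + 2, k)], NA_integer_),
    i_slsl = ifelse(ok, run_start[pmin(j0 + 3, k)], NA_integer_),
    end = ifelse(ok, run_start[pmin(j0 + 4, k)],
                 c(run_start[j0[-1]], NA_integer_)),
    valid = ok, reason = NA_character_, stringsAsFactors = FALSE)
  # malformed spans run to the next candidate start; a malformed or
  # incomplete trailing fragment is dropped
  airborne_at <- run_start[r$values == "airborne"]
  for (i in which(!ok)) {
    if (is.na(cycles$end[i])) next
    cycles$reason[i] <- if (any(airborne_at >= cycles$start[i] &
                                airborne_at < cycles$end[i])) "airborne gap"
    else "irregular phase pattern"
  }
  cycles <- cycles[cycles$valid | !is.na(cycles$reason), , drop = FALSE]
  if (nrow(cycles) == 0)
    gm_stop("insufficient gait: fewer than 1 complete cycle", "gaitmark_nogait_error")
  if (!any(cycles$valid))
    gm_stop("insufficient gait: fewer than 1 complete cycle", "gaitmark_nogait_error")
  structure(cycles, class = c("gait_cycles", "data.frame"),
            sampling_rate = phases$sampling_rate)
}

#' Per-cycle kinematic parameters
#'
#' For each valid cycle computes stride duration SL and, from the per-foot
#' contact series restricted to the cycle, the stance and swing durations of
#' each foot, the total double-limb-support duration (DLS1 + DLS2), the two
#' single-limb-support durations, and the left/right step durations (interval
#' between contralateral and ipsilateral initial contacts: left step =
#' DLS1 + SLS-R, right step = DLS2 + SLS-L). All durations are reported in
#' seconds and as a percentage of SL; stance% + swing% = 100 per foot by
#' construction.
#'
#' @param cycles a [segment_cycles()] result.
#' @param contact the matching [detect_contact()] result.
#' @return data.frame with one row per valid cycle.
#' @export
cycle_parameters <- function(cycles, contact) {
  fs <- attr(cycles, "sampling_rate")
  v <- cycles[cycles$valid, , drop = FALSE]
  n <- nrow(v)
  dur <- function(a, b) (b - a) / fs
  sl <- dur(v$start, v$end)
  cl <- cumsum(contact$left); cr <- cumsum(contact$right)
  csum <- function(cum, a, b) cum[b - 1] - ifelse(a > 1, cum[a - 1], 0)
  stance_l <- csum(cl, v$start, v$end) / fs
  stance_r <- csum(cr, v$start, v$end) / fs
  out <- data.frame(
    start = v$start, end = v$end,
    stride_s = sl,
    stance_left_s = stance_l, stance_right_s = stance_r,
    swing_left_s = sl - stance_l, swing_right_s = sl - stance_r,
    dls_s = dur(v$start, v$i_slsr) + dur(v$i_dls2, v$i_slsl),
    sls_left_s = dur(v$i_slsl, v$end), sls_right_s = dur(v$i_slsr, v$i_dls2),
    step_left_s = dur(v$start, v$i_dls2), step_right_s = dur(v$i_dls2, v$end))
  for (col in setdiff(names(out), c("start", "end", "stride_s")))
    out[[sub("_s$", "_pct", col)]] <- 100 * out[[col]] / sl
  out
}

#' Reject outlier cycles by stride duration
#'
#' One-sided upper rejection: with SL-bar the mean stride duration and
#' SD(SL) its standard deviation, both computed once over all segmented
#' cycles (not iteratively), every cycle with SL > SL-bar + 2 SD(SL) is
#' marked and discarded. Shortened cycles are never rejected. With a single
#' cycle the rule passes it through unmarked.
#'
#' @param params per-cycle parameter table from [cycle_parameters()].
#' @param subject_id carried through for reporting.
#' @return list of class `cycle_set`: `accepted` and `rejected` parameter
#'   tables, `sl_mean`, `sl_sd`, `bound` and `n_total`.
#' @export
reject_outlier_cycles <- function(params, subject_id = NA_character_) {
  sl <- params$stride_s
  if (length(sl) >= 2) {
    sl_mean <- mean(sl); sl_sd <- stats::sd(sl)
    bound <- sl_mean + 2 * sl_sd
    out <- sl > bound
  } else {
    sl_mean <- mean(sl); sl_sd <- NA_real_; bound <- Inf
    out <- rep(FALSE, length(sl))
  }
  rejected <- params[out, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "stride duration outlier"
  structure(list(subject_id = subject_id,
                 accepted = params[!out, , drop = FALSE],
                 rejected = rejected,
                 sl_mean = sl_mean, sl_sd = sl_sd, bound = bound,
                 n_total = length(sl)),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> subject %s: %d cycles, %d rejected (SL-bar=%.3fs, bound=%.3fs)\n",
              x$subject_id, x$n_total, nrow(x$rejected), x$sl_mean, x$bound))
  invisible(x)
}

#' One-call segmentation of a recording
#'
#' Convenience wrapper chaining [detect_contact()], [label_phases()],
#' [segment_cycles()], [cycle_parameters()] and (optionally)
#' [reject_outlier_cycles()].
#'
#' @param recording an [insole_recording()].
#' @param contact_threshold,min_phase_duration passed to [detect_contact()].
#' @param outlier_rule apply the stride-duration outlier rejection
#'   (default `TRUE`).
#' @return a `cycle_set`; attribute `"segmentation"` holds the intermediate
#'   `gait_cycles` table (including invalid cycles and their reasons).
#' @export
segment_recording <- function(recording, contact_threshold = NULL,
                              min_phase_duration = 0.05, outlier_rule = TRUE) {
  contact <- detect_contact(recording, contact_threshold, min_phase_duration)
  cycles <- segment_cycles(label_phases(contact))
  params <- cycle_parameters(cycles, contact)
  cs <- if (outlier_rule) reject_outlier_cycles(params, recording$subject_id)
  else structure(list(subject_id = recording$subject_id, accepted = params,
                      rejected = params[0, , drop = FALSE],
                      sl_mean = mean(params$stride_s),
                      sl_sd = if (nrow(params) >= 2) stats::sd(params$stride_s) else NA_real_,
                      bound = Inf, n_total = nrow(params)),
                 class = "cycle_set")
  attr(cs, "segmentation") <- cycles
  cs
}
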