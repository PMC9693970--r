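#' Two-foot eight-sensor insole recording
#'
#' Container for a vertical ground-reaction-force (VGRF) trial recorded by a
#' pair of instrumented insoles, eight pressure-sensitive sensors per foot.
#' Channels are the per-sensor forces plus the per-foot totals (the sum of
#' the eight sensors of that foot), sampled on a common time axis.
#'
#' @param subject_id character scalar.
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param left_sensors,right_sensors numeric matrices, one column per sensor
#'   (8 columns), one row per sample.
#' @param left_total,right_total per-foot total force channels. If `NULL`
#'   they are computed as the row sums of the sensor matrices.
#' @param sampling_rate sampling rate in Hz. If `NULL` it is estimated from
#'   the median sampling interval.
#' @param units one of `"newton"`, `"volt"`, `"percent_max"`.
#' @param validate run invariant checks (default `TRUE`).
#'
#' @return An object of class `insole_recording`: a list with the fields
#'   above.
#' @export
insole_recording <- function(subject_id, time, left_sensors, right_sensors,
                             left_total = NULL, right_total = NULL,
                             sampling_rate = NULL,
                             units = c("newton", "volt", "percent_max"),
                             validate = TRUE) {
  units <- match.arg(units)
  left_sensors <- as.matrix(left_sensors)
  right_sensors <- as.matrix(right_sensors)
  if (is.null(left_total)) left_total <- rowSums(left_sensors)
  if (is.null(right_total)) right_total <- rowSums(right_sensors)
  if (is.null(sampling_rate)) {
    if (length(time) < 2) gm_stop("cannot estimate sampling rate from < 2 samples",
                                  "gaitmark_validation_error")
    sampling_rate <- 1 / stats::median(diff(time))
  }
  x <- structure(list(subject_id = as.character(subject_id),
                      time = as.numeric(time),
                      left_sensors = left_sensors,
                      right_sensors = right_sensors,
                      left_total = as.numeric(left_total),
                      right_total = as.numeric(right_total),
                      sampling_rate = sampling_rate,
                      units = units),
                 class = "insole_recording")
  if (validate) validate_insole_recording(x)
  x
}

#' Validate an insole recording
#'
#' Checks the container invariants: 18 equal-length channels (>= 2 samples),
#' strictly increasing time whose median interval matches the declared
#' sampling rate within 1%, non-negative forces for calibrated units, and
#' totals consistent with sensor sums (warning only; file totals win).
#'
#' @param x an `insole_recording`.
#' @return `x`, invisibly.
#' @export
validate_insole_recording <- function(x) {
  n <- length(x$time)
  if (n < 2) gm_stop("recording must have at least 2 samples",
                     "gaitmark_validation_error")
  if (ncol(x$left_sensors) != 8 || ncol(x$right_sensors) != 8)
    gm_stop("sensor matrices must have 8 columns per foot",
            "gaitmark_validation_error")
  lens <- c(nrow(x$left_sensors), nrow(x$right_sensors),
            length(x$left_total), length(x$right_total))
  if (any(lens != n))
    gm_stop("all 18 channels must have the same length as the time axis",
            "gaitmark_validation_error")
  if (any(diff(x$time) <= 0))
    gm_stop("time must be strictly increasing", "gaitmark_validation_error")
  med_dt <- stats::median(diff(x$time))
  if (abs(med_dt - 1 / x$sampling_rate) > 0.01 / x$sampling_rate)
    gm_stop(sprintf(
      "median sampling interval (%.4g s) is not within 1%% of 1/sampling_rate (%.4g s)",
      med_dt, 1 / x$sampling_rate), "gaitmark_validation_error")
  if (x$units %in% c("newton", "percent_max")) {
    if (min(x$left_sensors, x$right_sensors, x$left_total, x$right_total) < -1e-9)
      gm_stop("calibrated forces must be non-negative", "gaitmark_validation_error")
  }
  invisible(x)
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole_recording> subject %s: %d samples @ %.4g Hz (%.1f s), units=%s\n",
              x$subject_id, length(x$time), x$sampling_rate,
              diff(range(x$time)), x$units))
  cat(sprintf("  left total:  [%.3g, %.3g]\n", min(x$left_total), max(x$left_total)))
  cat(sprintf("  right total: [%.3g, %.3g]\n", min(x$right_total), max(x$right_total)))
  invisible(x)
}

#' Swap the two feet of a recording
#'
#' Mirror utility used by symmetry checks: exchanges left and right sensor
#' and total channels. The differential GRF of the result is the negation of
#' the original.
#'
#' @param recording an `insole_recording`.
#' @return the mirrored `insole_recording`.
#' @export
swap_feet <- function(recording) {
  insole_recording(recording$subject_id, recording$time,
                   left_sensors = recording$right_sensors,
                   right_sensors = recording$left_sensors,
                   left_total = recording$right_total,
                   right_total = recording$left_total,
                   sampling_rate = recording$sampling_rate,
                   units = recording$units, validate = FALSE)
}
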