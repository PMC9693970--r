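# canonical variable vocabulary: labels follow the usual reporting style of
# insole gait studies ("Ave left SWING", "SD right STANCE %", "IQR Force left")
kinematic_parameter_map <- function() {
  c("left SWING" = "swing_left_s",    "right SWING" = "swing_right_s",
    "left SWING %" = "swing_left_pct", "right SWING %" = "swing_right_pct",
    "left STANCE" = "stance_left_s",  "right STANCE" = "stance_right_s",
    "left STANCE %" = "stance_left_pct", "right STANCE %" = "stance_right_pct",
    "DOUBLE SUPPORT" = "dls_s",       "DOUBLE SUPPORT %" = "dls_pct")
}

#' Canonical kinematic variable names
#' @return character vector of the 42 kinematic variables (4 indices x 10
#'   cycle parameters, plus gait speed and TUG).
#' @export
kinematic_variables <- function() {
  pars <- names(kinematic_parameter_map())
  c("Gait Speed (m/s)", "Time Up and Go (s)",
    as.vector(t(outer(c("Ave", "Med", "SD", "IQR"), pars, paste))))
}

#' Canonical dynamic variable names
#' @return character vector of the 8 whole-trial force variables.
#' @export
dynamic_variables <- function() {
  as.vector(t(outer(c("Ave", "Med", "SD", "IQR"),
                    c("Force left", "Force right"), paste)))
}

feature_row <- function(subject_id, block, class, variable, value) {
  data.frame(subject_id = subject_id, block = block, class = class,
             variable = variable, value = value, stringsAsFactors = FALSE)
}

#' Per-subject kinematic features
#'
#' Aggregates the accepted cycles of a subject into central-tendency (average
#' and median) and dispersion (SD and interquartile range) indices for each
#' of the ten cycle parameters (left/right swing and stance in seconds and in
#' % of stride, and double support in seconds and %). The dispersion indices
#' are the stride-to-stride variability markers. Gait speed and TUG are
#' copied from the metadata: insoles carry no spatial information, so these
#' covariates are dataset-provided, single-valued, and get no dispersion
#' indices.
#'
#' SD is the sample standard deviation (n-1); IQR is Q3 - Q1 with
#' linear-interpolation quantiles (`quantile_type`, default 7, R's default).
#' With fewer than 2 accepted cycles the dispersion indices are `NA`.
#'
#' @param cycleset a [reject_outlier_cycles()] / [segment_recording()] result.
#' @param meta optional one-row metadata data.frame providing `gait_speed`
#'   and `tug`.
#' @param quantile_type quantile algorithm for the median and IQR.
#' @return long-format data.frame: `subject_id`, `block` ("kinematic"),
#'   `class` ("central"/"dispersion"), `variable`, `value`.
#' @export
kinematic_features <- function(cycleset, meta = NULL, quantile_type = 7) {
  acc <- cycleset$accepted
  if (nrow(acc) == 0)
    gm_stop(sprintf("subject %s has no accepted cycles", cycleset$subject_id),
            "gaitmark_nocycles_error")
  pm <- kinematic_parameter_map()
  qfun <- function(x, p) unname(stats::quantile(x, p, type = quantile_type))
  rows <- list()
  for (lab in names(pm)) {
    x <- acc[[pm[lab]]]
    disp <- nrow(acc) >= 2
    rows[[length(rows) + 1]] <- feature_row(
      cycleset$subject_id, "kinematic",
      c("central", "central", "dispersion", "dispersion"),
      paste(c("Ave", "Med", "SD", "IQR"), lab),
      c(mean(x), qfun(x, 0.5),
        if (disp) stats::sd(x) else NA_real_,
        if (disp) qfun(x, 0.75) - qfun(x, 0.25) else NA_real_))
  }
  covs <- feature_row(
    cycleset$subject_id, "kinematic", "central",
    c("Gait Speed (m/s)", "Time Up and Go (s)"),
    c(if (!is.null(meta) && !is.null(meta$gait_speed)) meta$gait_speed else NA_real_,
      if (!is.null(meta) && !is.null(meta$tug)) meta$tug else NA_real_))
  rbind(covs, do.call(rbind, rows))
}

#' Whole-trial dynamic force features
#'
#' Mean, SD, median and IQR of each foot's total-force channel over every
#' sample of the trial, swing-phase near-zero samples included. Order-free by
#' definition. Refuses uncalibrated (volt) input: normalize first, and never
#' mix newton- and percent-scale subjects in one comparison.
#'
#' @param recording an [insole_recording()] in newtons or percent of the
#'   maximal detectable force.
#' @param quantile_type quantile algorithm for the median and IQR.
#' @return long-format data.frame (`block` = "dynamic").
#' @export
dynamic_features <- function(recording, quantile_type = 7) {
  if (recording$units == "volt")
    gm_stop("dynamic features require calibrated (newton) or normalized (percent_max) data; see normalize_voltage()",
            "gaitmark_units_error")
  qfun <- function(x, p) unname(stats::quantile(x, p, type = quantile_type))
  one <- function(x, foot) feature_row(
    recording$subject_id, "dynamic",
    c("central", "central", "dispersion", "dispersion"),
    paste(c("Ave", "Med", "SD", "IQR"), "Force", foot),
    c(mean(x), qfun(x, 0.5), stats::sd(x), qfun(x, 0.75) - qfun(x, 0.25)))
  rbind(one(recording$left_total, "left"), one(recording$right_total, "right"))
}

#' Normalize an uncalibrated (volt) recording to percent of full scale
#'
#' Divides every channel by the maximal output of the electronic system and
#' scales to percent, yielding signals in percent of the maximal detectable
#' force. Values above full scale indicate saturation: they are clipped at
#' 100% with a warning. The per-foot totals are expressed in percent of the
#' maximal detectable *total* force (8 sensors at full scale), i.e. the mean
#' sensor percent, so they stay on a 0-100 scale too.
#'
#' @param recording an [insole_recording()] with `units = "volt"`.
#' @param max_output maximal output of the device electronics (volts).
#' @return an `insole_recording` with `units = "percent_max"`.
#' @export
normalize_voltage <- function(recording, max_output) {
  if (max_output <= 0) gm_stop("max_output must be > 0", "gaitmark_validation_error")
  if (recording$units != "volt")
    gm_stop("normalize_voltage expects a recording in volts", "gaitmark_units_error")
  over <- sum(recording$left_sensors > max_output) +
    sum(recording$right_sensors > max_output)
  if (over > 0)
    warning(sprintf("%d samples above max_output clipped at 100%%", over), call. = FALSE)
  conv <- function(x) clamp(100 * x / max_output, 0, 100)
  ls <- conv(recording$left_sensors); rs <- conv(recording$right_sensors)
  insole_recording(recording$subject_id, recording$time, ls, rs,
                   rowSums(ls) / 8, rowSums(rs) / 8,
                   sampling_rate = recording$sampling_rate,
                   units = "percent_max", validate = FALSE)
}

#' All features of one subject
#'
#' @param recording an [insole_recording()] (newton or percent_max).
#' @param cycleset its `cycle_set`.
#' @param meta optional one-row metadata data.frame.
#' @param quantile_type quantile algorithm.
#' @return long-format data.frame with the kinematic and dynamic blocks.
#' @export
subject_features <- function(recording, cycleset, meta = NULL, quantile_type = 7) {
  rbind(kinematic_features(cycleset, meta, quantile_type),
        dynamic_features(recording, quantile_type))
}
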