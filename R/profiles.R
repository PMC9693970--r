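#' Gait profile for the synthetic insole simulator
#'
#' A gait profile states the walking pattern the simulator generates: stride
#' timing and its cycle-to-cycle variability, the split of the stride into
#' stance/swing and the two double-limb-support (DLS) episodes, the force
#' scale, and the distributions of the two clinical covariates (gait speed
#' and Timed-Up-and-Go) that insole data sets provide as metadata.
#'
#' Two layers of variability are modelled. *Within-subject* (stride-to-stride)
#' variability is what the dispersion indices of the analysis measure:
#' `stride_time_cv`, `stance_fraction_sd` and `double_support_fraction_sd`.
#' *Between-subject* heterogeneity (`*_between_sd` fields) perturbs each
#' subject's personal means and personal variability levels; without it every
#' subject of a group would be statistically identical and even trivial group
#' mean differences would reach any significance threshold at realistic
#' cohort sizes.
#'
#' Phase fractions are fractions of the stride. Consistency of the phase
#' tiling (DLS1 + SLS-R + DLS2 + SLS-L = stride) forces
#' `stance_fraction_mean = 0.5 + double_support_fraction_mean` for symmetric
#' gait; the constructor checks feasibility
#' (`2 * double_support_fraction_mean < stance_fraction_mean`).
#'
#' @param stride_time_mean mean stride (gait-cycle) duration, seconds.
#' @param stride_time_cv coefficient of variation of stride time (fraction).
#' @param stance_fraction_mean per-foot stance fraction of the stride.
#' @param stance_fraction_sd stride-to-stride SD of the swing/stance split
#'   (fraction of stride).
#' @param double_support_fraction_mean fraction of the stride spent in one
#'   DLS episode (there are two per stride).
#' @param double_support_fraction_sd stride-to-stride SD of one DLS episode.
#' @param body_weight subject body weight in newtons.
#' @param peak_ratio height of the two stance-phase VGRF peaks as a multiple
#'   of body weight.
#' @param sensor_noise_sd SD of the additive, truncated-at-zero noise on each
#'   of the 16 sensor channels, newtons.
#' @param gait_speed_mean,gait_speed_sd metadata gait speed distribution, m/s.
#' @param tug_mean,tug_sd metadata Timed-Up-and-Go distribution, seconds.
#' @param stride_time_between_sd between-subject SD of the personal stride
#'   time mean, seconds.
#' @param stride_time_cv_between_sd between-subject SD of the personal stride
#'   time CV.
#' @param stance_fraction_between_sd between-subject SD of the personal
#'   stance fraction.
#' @param stance_fraction_sd_between_sd between-subject SD of the personal
#'   stride-to-stride stance-fraction SD.
#' @param double_support_fraction_sd_between_sd between-subject SD of the
#'   personal DLS-episode SD.
#' @param body_weight_between_sd between-subject SD of body weight, newtons.
#' @return a list of class `gait_profile`.
#' @seealso [hs_gait_profile()], [pd_gait_profile()], [simulate_subject()]
#' @export
gait_profile <- function(stride_time_mean = 1.06,
                         stride_time_cv = 0.03,
                         stance_fraction_mean = 0.582,
                         stance_fraction_sd = 0.017,
                         double_support_fraction_mean = stance_fraction_mean - 0.5,
                         double_support_fraction_sd = 0.010,
                         body_weight = 700,
                         peak_ratio = 1.15,
                         sensor_noise_sd = 2,
                         gait_speed_mean = 1.26, gait_speed_sd = 0.166,
                         tug_mean = 9.3, tug_sd = 1.6,
                         stride_time_between_sd = 0,
                         stride_time_cv_between_sd = 0,
                         stance_fraction_between_sd = 0,
                         stance_fraction_sd_between_sd = 0,
                         double_support_fraction_sd_between_sd = 0,
                         body_weight_between_sd = 0) {
  p <- as.list(environment())
  if (p$stance_fraction_mean <= 0 || p$stance_fraction_mean >= 1)
    gm_stop("stance_fraction_mean must be in (0, 1)", "gaitmark_validation_error")
  if (2 * p$double_support_fraction_mean >= p$stance_fraction_mean)
    gm_stop("infeasible phase fractions: need 2*double_support_fraction_mean < stance_fraction_mean",
            "gaitmark_validation_error")
  if (p$double_support_fraction_mean <= 0)
    gm_stop("double_support_fraction_mean must be > 0", "gaitmark_validation_error")
  sds <- c(p$stride_time_cv, p$stance_fraction_sd, p$double_support_fraction_sd,
           p$sensor_noise_sd, p$gait_speed_sd, p$tug_sd,
           p$stride_time_between_sd, p$stride_time_cv_between_sd,
           p$stance_fraction_between_sd, p$stance_fraction_sd_between_sd,
           p$double_support_fraction_sd_between_sd, p$body_weight_between_sd)
  if (any(sds < 0))
    gm_stop("variability parameters must be >= 0", "gaitmark_validation_error")
  if (p$stride_time_mean <= 0 || p$body_weight <= 0 || p$peak_ratio <= 0)
    gm_stop("stride_time_mean, body_weight and peak_ratio must be > 0",
            "gaitmark_validation_error")
  structure(p, class = "gait_profile")
}

#' Default healthy-like gait profile
#'
#' Timing means and between-subject spreads follow published group summaries
#' for healthy elderly subjects walking at comfortable speed (stride around
#' 1.06 s, stance around 58% of stride, gait speed 1.260 +/- 0.166 m/s,
#' TUG 9.3 +/- 1.6 s); stride-to-stride variability indices are set so the
#' per-subject SD of swing time is around 0.022 s (1.7% of stride).
#'
#' @return a `gait_profile`.
#' @export
hs_gait_profile <- function() {
  gait_profile(stride_time_mean = 1.06, stride_time_cv = 0.030,
               stance_fraction_mean = 0.582, stance_fraction_sd = 0.0169,
               double_support_fraction_mean = 0.082,
               double_support_fraction_sd = 0.010,
               body_weight = 700, peak_ratio = 1.15, sensor_noise_sd = 2,
               gait_speed_mean = 1.260, gait_speed_sd = 0.166,
               tug_mean = 9.300, tug_sd = 1.604,
               stride_time_between_sd = 0.10,
               stride_time_cv_between_sd = 0.009,
               stance_fraction_between_sd = 0.0314,
               stance_fraction_sd_between_sd = 0.0051,
               double_support_fraction_sd_between_sd = 0.0030,
               body_weight_between_sd = 120)
}

#' Default parkinsonian-like gait profile
#'
#' Slower, more variable gait: lower gait speed (1.019 +/- 0.227 m/s), longer
#' TUG (12.056 +/- 3.962 s), slightly longer stride and stance fraction, and
#' clearly larger stride-to-stride variability (swing-time SD around 0.032 s).
#' Force-scale parameters are identical to [hs_gait_profile()], reflecting
#' the force/rhythm dichotomy: group contrasts live in timing, not in the
#' whole-trial force distribution.
#'
#' @return a `gait_profile`.
#' @export
pd_gait_profile <- function() {
  gait_profile(stride_time_mean = 1.076, stride_time_cv = 0.044,
               stance_fraction_mean = 0.592, stance_fraction_sd = 0.0236,
               double_support_fraction_mean = 0.092,
               double_support_fraction_sd = 0.0147,
               body_weight = 700, peak_ratio = 1.15, sensor_noise_sd = 2,
               gait_speed_mean = 1.019, gait_speed_sd = 0.227,
               tug_mean = 12.056, tug_sd = 3.962,
               stride_time_between_sd = 0.13,
               stride_time_cv_between_sd = 0.013,
               stance_fraction_between_sd = 0.0402,
               stance_fraction_sd_between_sd = 0.0071,
               double_support_fraction_sd_between_sd = 0.0044,
               body_weight_between_sd = 120)
}
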