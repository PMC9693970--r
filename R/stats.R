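#' Pooled-variance two-sample t from summary statistics
#'
#' Student's two-sample t-test with pooled variance,
#' `t = (mean1 - mean2) / (sp * sqrt(1/n1 + 1/n2))` with
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`; two-sided p from the t distribution. The pooled (not
#' Welch) form is used throughout because reported degrees of freedom in this
#' literature are `n1 + n2 - 2`. Group 1 is conventionally HS, so positive t
#' means HS larger.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (HS).
#' @param mean2,sd2,n2 summary statistics of group 2 (PD).
#' @return list with `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) gm_stop("need n >= 2 per group", "gaitmark_validation_error")
  if (sd1 < 0 || sd2 < 0) gm_stop("sds must be >= 0", "gaitmark_validation_error")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    gm_stop("zero pooled variance with unequal means: t undefined",
            "gaitmark_degenerate_error")
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pooled-variance two-sample t-test on raw samples
#'
#' Sign convention (HS - PD): positive t means the healthy group has the
#' larger mean. Equivalent to [t_from_summary()] applied to the samples'
#' means and SDs.
#'
#' @param values_hs,values_pd numeric samples (NA dropped).
#' @param variable label carried into the result.
#' @return one-row data.frame (a group comparison): `variable`, per-group
#'   `n`/`mean`/`sd`, `t`, `df`, `p`.
#' @export
t_test_pooled <- function(values_hs, values_pd, variable = "") {
  x <- values_hs[is.finite(values_hs)]
  y <- values_pd[is.finite(values_pd)]
  res <- t_from_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y))
  data.frame(variable = variable,
             n_hs = length(x), mean_hs = mean(x), sd_hs = stats::sd(x),
             n_pd = length(y), mean_pd = mean(y), sd_pd = stats::sd(y),
             t = res$t, df = res$df, p = res$p, stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level.
#' @param m number of tests (correction factor).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 50) {
  if (alpha <= 0 || alpha >= 1 || m < 1)
    gm_stop("need alpha in (0,1) and m >= 1", "gaitmark_validation_error")
  alpha / m
}

#' ROC analysis of one feature for PD-vs-HS discrimination
#'
#' AUC is the Mann-Whitney probability that a PD value exceeds an HS value
#' (ties count 1/2), with PD as the positive class and *higher* feature
#' values scored as more PD-like. No orientation flipping is performed, so a
#' marker that is lower in PD (e.g. gait speed) yields AUC < 0.5. The
#' standard error follows Hanley & McNeil's formula by default (DeLong's
#' variance is available via `method`), the 95% CI is the normal
#' `AUC +/- 1.96 SE` clipped to \[0, 1\], and p is the two-sided normal test
#' of AUC against 0.5.
#'
#' @param values numeric feature values.
#' @param labels group labels, "PD"/"HS".
#' @param method `"hanley"` (default) or `"delong"` for the SE.
#' @param variable label carried into the result.
#' @return one-row data.frame: `variable`, `auc`, `se`, `p`, `ci_lower`,
#'   `ci_upper`.
#' @export
roc_analysis <- function(values, labels, method = c("hanley", "delong"),
                         variable = "") {
  method <- match.arg(method)
  keep <- is.finite(values) & labels %in% c("PD", "HS")
  values <- values[keep]; labels <- labels[keep]
  n_pd <- sum(labels == "PD"); n_hs <- sum(labels == "HS")
  if (n_pd < 2 || n_hs < 2)
    gm_stop("roc_analysis needs >= 2 subjects in each class", "gaitmark_validation_error")
  r <- rank(values) # midranks handle ties as 1/2
  auc <- (sum(r[labels == "PD"]) - n_pd * (n_pd + 1) / 2) / (n_pd * n_hs)
  if (method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n_pd - 1) * (q1 - auc^2) +
                  (n_hs - 1) * (q2 - auc^2)) / (n_pd * n_hs))
  } else {
    pd <- values[labels == "PD"]; hs <- values[labels == "HS"]
    v10 <- vapply(pd, function(x) mean((x > hs) + 0.5 * (x == hs)), 0)
    v01 <- vapply(hs, function(y) mean((pd > y) + 0.5 * (pd == y)), 0)
    se <- sqrt(stats::var(v10) / n_pd + stats::var(v01) / n_hs)
  }
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se)
  else as.numeric(auc == 0.5)
  data.frame(variable = variable, auc = auc, se = se, p = p,
             ci_lower = max(0, auc - 1.96 * se),
             ci_upper = min(1, auc + 1.96 * se), stringsAsFactors = FALSE)
}

#' Group comparison suite over a feature table
#'
#' Runs the pooled-variance t-test (HS - PD) for every kinematic and dynamic
#' variable of a long-format feature table, flags significance at the
#' Bonferroni-corrected threshold `alpha / m` (the correction factor counts
#' the full planned variable set, 50 by default, regardless of how many
#' variables are present), and then performs ROC analysis only for the
#' kinematic variables whose t-test passed the corrected threshold. ROC
#' significance is marked separately, at the same corrected threshold.
#' Subjects missing a variable are dropped for that variable only, and the
#' per-variable group counts are reported.
#'
#' @param features long-format feature table ([subject_features()] /
#'   [read_feature_table()]).
#' @param meta metadata table with `subject_id` and `group`.
#' @param alpha family-wise level (default 0.05).
#' @param m Bonferroni correction factor (default 50).
#' @param roc_method SE method for [roc_analysis()].
#' @return list of class `comparison_suite`: `kinematic` and `dynamic`
#'   comparison tables (with `significant` flags), `roc` table, and
#'   `threshold`.
#' @export
run_comparison_suite <- function(features, meta, alpha = 0.05, m = 50,
                                 roc_method = "hanley") {
  thr <- bonferroni_threshold(alpha, m)
  grp <- meta$group[match(features$subject_id, meta$subject_id)]
  if (anyNA(grp))
    gm_stop("features contain subjects absent from the metadata",
            "gaitmark_validation_error")
  features$group <- grp

  run_block <- function(block, vars) {
    fb <- features[features$block == block, ]
    rows <- lapply(vars[vars %in% fb$variable], function(v) {
      fv <- fb[fb$variable == v & is.finite(fb$value), ]
      hs <- fv$value[fv$group == "HS"]; pd <- fv$value[fv$group == "PD"]
      if (length(hs) < 2 || length(pd) < 2) return(NULL)
      t_test_pooled(hs, pd, variable = v)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) out$significant <- out$p < thr
    out
  }
  kin <- run_block("kinematic", kinematic_variables())
  dyn <- run_block("dynamic", dynamic_variables())

  sig_vars <- kin$variable[kin$significant]
  roc <- do.call(rbind, lapply(sig_vars, function(v) {
    fv <- features[features$block == "kinematic" & features$variable == v &
                     is.finite(features$value), ]
    roc_analysis(fv$value, fv$group, method = roc_method, variable = v)
  }))
  if (!is.null(roc)) roc$significant <- roc$p < thr
  structure(list(kinematic = kin, dynamic = dyn, roc = roc, threshold = thr,
                 alpha = alpha, m = m),
            class = "comparison_suite")
}

#' @export
print.comparison_suite <- function(x, ...) {
  cat(sprintf("<comparison_suite> threshold p < %g (alpha %g / m %d)\n",
              x$threshold, x$alpha, x$m))
  cat(sprintf("  kinematic: %d variables, %d significant\n",
              nrow(x$kinematic), sum(x$kinematic$significant)))
  cat(sprintf("  dynamic:   %d variables, %d significant\n",
              nrow(x$dynamic), sum(x$dynamic$significant)))
  cat(sprintf("  ROC:       %d markers, %d significant\n",
              NROW(x$roc), if (is.null(x$roc)) 0 else sum(x$roc$significant)))
  invisible(x)
}

#' Published group summary statistics (kinematic and dynamic variables)
#'
#' Reference table of printed per-group means, SDs, Ns, t, df and p for the
#' 42 kinematic and 8 dynamic variables from a published PD-vs-HS insole
#' cohort comparison (88 HS, 108 PD pooled over four cohorts; TUG available
#' for 62/90). `p_ref` is `NA` where the source prints only "< 0.001";
#' `significant` is the printed star marking. Used by the validation tests
#' that recompute t from printed summaries.
#'
#' @return data.frame with one row per variable.
#' @export
reference_group_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_group_summary.csv",
                              package = "gaitmark"), check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Published ROC reference table
#'
#' AUC, SE, p and 95% CI limits for the 18 kinematic markers that reached the
#' corrected t-test threshold in the same published comparison (see
#' [reference_group_summary()]).
#'
#' @return data.frame with one row per marker.
#' @export
reference_roc <- function() {
  utils::read.csv(system.file("extdata", "reference_roc.csv",
                              package = "gaitmark"), check.names = FALSE,
                  stringsAsFactors = FALSE)
}
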