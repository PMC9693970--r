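test_that("pooled t from summaries matches published rows recomputable from print", {
  # TUG row: printed t = -5.187, df = 150 (62 + 90 - 2)
  r <- t_from_summary(9.300, 1.604, 62, 12.056, 3.962, 90)
  expect_equal(r$t, -5.187913, tolerance = 1e-6)
  expect_equal(r$df, 150)
  # whole-trial left force row: printed t = -0.813, p = 0.417
  r2 <- t_from_summary(372.346, 181.982, 88, 392.385, 162.683, 108)
  expect_equal(r2$t, -0.813145, tolerance = 1e-6)
  expect_equal(r2$p, 0.417, tolerance = 1e-3)
  expect_equal(r2$df, 194)
  # gait-speed row: recomputation from 3-decimal inputs gives 8.3105; the
  # printed 8.278 comes from unrounded data and lies inside the interval
  # reachable by perturbing the printed summaries by half a printing ulp
  r3 <- t_from_summary(1.260, 0.166, 88, 1.019, 0.227, 108)
  expect_equal(r3$t, 8.310518, tolerance = 1e-6)
  expect_equal(t_from_summary(1.2595, 0.166, 88, 1.0194, 0.227, 108)$t,
               8.278, tolerance = 1e-3)
})

test_that("every published t is consistent with the pooled formula under input rounding", {
  d <- reference_group_summary()
  e <- 5e-4 # half a printing ulp on 3-decimal summaries
  grid <- as.matrix(expand.grid(dm1 = c(-e, e), ds1 = c(-e, e),
                                dm2 = c(-e, e), ds2 = c(-e, e)))
  for (i in seq_len(nrow(d))) {
    ts <- apply(grid, 1, function(z)
      t_from_summary(d$mean_hs[i] + z[1], max(d$sd_hs[i] + z[2], 1e-9), d$n_hs[i],
                     d$mean_pd[i] + z[3], max(d$sd_pd[i] + z[4], 1e-9), d$n_pd[i])$t)
    expect_gte(d$t_ref[i], min(ts) - 1e-3)
    expect_lte(d$t_ref[i], max(ts) + 1e-3)
  }
})

test_that("t edge cases: identical samples, degenerate variance, quadrature oracle", {
  x <- c(1, 2, 3, 4)
  r <- t_test_pooled(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(unlist(t_from_summary(5, 0, 4, 5, 0, 6)[c("t", "p")]), c(t = 0, p = 1))
  expect_error(t_from_summary(5, 0, 4, 6, 0, 6), class = "gaitmark_degenerate_error")
  expect_error(t_from_summary(5, 1, 1, 6, 1, 6), class = "gaitmark_validation_error")

  # p equals numerical integration of the t density at small df
  r2 <- t_test_pooled(c(0.1, 0.9, 0.4), c(1.2, 2.0, 1.1, 1.8))
  quad <- 2 * integrate(function(z) dt(z, r2$df), abs(r2$t), Inf)$value
  expect_equal(r2$p, quad, tolerance = 1e-8)

  # raw-data path agrees exactly with the summary path
  rs <- t_from_summary(mean(c(0.1, 0.9, 0.4)), sd(c(0.1, 0.9, 0.4)), 3,
                       mean(c(1.2, 2.0, 1.1, 1.8)), sd(c(1.2, 2.0, 1.1, 1.8)), 4)
  expect_equal(r2$t, rs$t)
})

test_that("Bonferroni threshold arithmetic", {
  expect_identical(bonferroni_threshold(0.05, 50), 0.001)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.04, 8), 0.005)
  expect_error(bonferroni_threshold(0, 5), class = "gaitmark_validation_error")
})

test_that("the corrected threshold reproduces the published star marking", {
  d <- reference_group_summary()
  thr <- bonferroni_threshold(0.05, 50)
  p_new <- mapply(function(m1, s1, n1, m2, s2, n2)
    t_from_summary(m1, s1, n1, m2, s2, n2)$p,
    d$mean_hs, d$sd_hs, d$n_hs, d$mean_pd, d$sd_pd, d$n_pd)
  expect_equal(p_new < thr, d$significant)
})

test_that("Mann-Whitney AUC equals exhaustive pair counting (oracle)", {
  set.seed(7)
  for (rep in 1:50) {
    n_pd <- sample(2:15, 1); n_hs <- sample(2:15, 1)
    v <- c(sample(0:8, n_pd, replace = TRUE), sample(0:8, n_hs, replace = TRUE))
    lab <- c(rep("PD", n_pd), rep("HS", n_hs))
    r <- roc_analysis(v, lab)
    pd <- v[lab == "PD"]; hs <- v[lab == "HS"]
    pairs <- outer(pd, hs, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(pairs))
  }
})

test_that("ROC orientation, antisymmetry, separation and null behaviour", {
  lab <- c(rep("PD", 20), rep("HS", 20))
  v <- c(rnorm(20, 10), rnorm(20, 0))
  r <- roc_analysis(c(11:30, 1:20 * 0.1), lab)
  expect_equal(r$auc, 1) # perfectly separated, PD higher
  expect_lt(r$p, 1e-10)

  set.seed(3)
  v2 <- rnorm(400)
  lab2 <- rep(c("PD", "HS"), 200)
  r2 <- roc_analysis(v2, lab2)
  expect_lt(abs(r2$auc - 0.5), 0.08)
  expect_equal(roc_analysis(v2, lab2)$auc, 1 - roc_analysis(-v2, lab2)$auc)

  expect_error(roc_analysis(1:5, rep("PD", 5)), class = "gaitmark_validation_error")
})

test_that("Hanley-McNeil SE matches hand arithmetic; DeLong available", {
  v <- c(2, 0, 2, 2, 1, 1, 1) # AUC = 9/12 = 0.75
  lab <- c(rep("PD", 4), rep("HS", 3))
  r <- roc_analysis(v, lab)
  expect_equal(r$auc, 0.75)
  q1 <- 0.75 / 1.25; q2 <- 2 * 0.75^2 / 1.75
  se <- sqrt((0.75 * 0.25 + 3 * (q1 - 0.5625) + 2 * (q2 - 0.5625)) / 12)
  expect_equal(r$se, se)
  expect_equal(r$ci_lower, max(0, 0.75 - 1.96 * se))
  rd <- roc_analysis(v, lab, method = "delong")
  expect_equal(rd$auc, 0.75)
  expect_gt(rd$se, 0)
})

test_that("comparison suite gates ROC on the corrected t threshold", {
  set.seed(10)
  n <- 30
  ids <- sprintf("S%02d", 1:n)
  meta <- data.frame(subject_id = ids, group = rep(c("HS", "PD"), each = n / 2))
  mk <- function(var, values, block = "kinematic")
    data.frame(subject_id = ids, block = block, class = "central",
               variable = var, value = values)
  feats <- rbind(
    mk("Gait Speed (m/s)", c(rnorm(15, 10, 0.5), rnorm(15, 2, 0.5))), # huge effect
    mk("Ave left SWING", rnorm(n)),                                   # null
    mk("Ave Force left", rnorm(n), block = "dynamic"))                # null
  suite <- run_comparison_suite(feats, meta, alpha = 0.05, m = 50)
  expect_equal(suite$threshold, 0.001)
  expect_equal(nrow(suite$kinematic), 2)
  expect_equal(nrow(suite$dynamic), 1)
  expect_true(suite$kinematic$significant[suite$kinematic$variable == "Gait Speed (m/s)"])
  # ROC exists exactly for the significant kinematic variables
  expect_equal(suite$roc$variable, "Gait Speed (m/s)")
  expect_lt(suite$roc$auc, 0.5) # PD lower, no orientation flipping
  # missing-variable subjects are dropped per variable with counts reported
  feats2 <- feats[-2, ]
  suite2 <- run_comparison_suite(feats2, meta)
  gs <- suite2$kinematic[suite2$kinematic$variable == "Gait Speed (m/s)", ]
  expect_equal(gs$n_hs, 14)
  expect_equal(gs$df, 27)
})
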