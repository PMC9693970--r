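test_that("simulation is deterministic for a fixed seed", {
  a <- simulate_subject(hs_gait_profile(), duration = 10, seed = 42)
  b <- simulate_subject(hs_gait_profile(), duration = 10, seed = 42)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth$cycles, b$truth$cycles)
  expect_identical(a$meta, b$meta)
  c <- simulate_subject(hs_gait_profile(), duration = 10, seed = 43)
  expect_false(identical(a$recording$left_total, c$recording$left_total))
})

test_that("degenerate variability gives exactly equal cycles and exact tiling", {
  s <- simulate_subject(rigid_profile(), duration = 15, seed = 1)
  expect_equal(s$truth$cycles$stride, rep(1.0, nrow(s$truth$cycles)))
  # the four phase fractions tile each cycle exactly
  fr <- with(s$truth$cycles, dls1 + sls_r + dls2 + sls_l)
  expect_equal(fr, rep(1, length(fr)), tolerance = 1e-12)
  expect_equal(s$truth$cycles$t_end - s$truth$cycles$t_start,
               s$truth$cycles$stride, tolerance = 1e-12)
  # cycles are contiguous
  expect_equal(s$truth$cycles$t_start[-1],
               s$truth$cycles$t_end[-nrow(s$truth$cycles)], tolerance = 1e-12)
})

test_that("noise-free force is positive exactly on ground-truth stance intervals", {
  s <- simulate_subject(rigid_profile(), duration = 12, seed = 7)
  tm <- s$recording$time
  for (foot in c("left", "right")) {
    iv <- s$truth[[paste0(foot, "_contact")]]
    on <- rep(FALSE, length(tm))
    for (i in seq_len(nrow(iv)))
      on <- on | (tm >= iv$start[i] - 1e-9 & tm < iv$end[i] - 1e-9)
    expect_equal(s$recording[[paste0(foot, "_total")]] > 0, on)
  }
})

test_that("programmed stance and phase boundaries are recovered by segmentation", {
  # stance 60%, DLS episodes 10%: every boundary within 1 sample period
  for (seed in 1:3) {
    s <- simulate_subject(rigid_profile(), duration = 20, seed = seed)
    cs <- segment_recording(s$recording, outlier_rule = FALSE)
    errs <- boundary_errors(s$truth, cs)
    expect_lte(max(abs(errs)), 1)
    expect_equal(mean(cs$accepted$stance_left_pct), 60, tolerance = 0.01)
  }
})

test_that("cohort simulation is deterministic, ordered, and seed-split per subject", {
  co <- simulate_cohort(n_hs = 2, n_pd = 3, duration = 8, seed = 9)
  expect_length(co$recordings, 5)
  expect_equal(co$meta$group, c("HS", "HS", "PD", "PD", "PD"))
  expect_equal(names(co$recordings), co$meta$subject_id)
  # per-subject seed derivation: subject 4 reproducible in isolation
  lone <- simulate_subject(pd_gait_profile(), duration = 8,
                           seed = subject_seed(9, 4),
                           subject_id = "PD002", group = "PD")
  expect_identical(lone$recording$left_total, co$recordings[["PD002"]]$left_total)
})

test_that("voltage degradation and normalization are an inverse pair", {
  s <- simulate_subject(hs_gait_profile(), duration = 8, seed = 2)
  volt <- degrade_to_voltage(s$recording, max_output = 1200)
  expect_equal(volt$units, "volt")
  expect_equal(max(volt$left_sensors) <= 3.3, TRUE)
  pct <- normalize_voltage(volt, max_output = 3.3)
  expect_equal(pct$units, "percent_max")
  # proportional to the original with a constant ratio
  nz <- s$recording$left_total > 1
  ratio <- pct$left_total[nz] / s$recording$left_total[nz]
  expect_lt(diff(range(ratio)), 1e-9)
  # zero force stays zero
  expect_equal(pct$left_total[s$recording$left_total == 0],
               rep(0, sum(s$recording$left_total == 0)))
})

test_that("saturation clipping is counted exactly", {
  s <- simulate_subject(rigid_profile(), duration = 8, seed = 3)
  full <- 0.9 * max(s$recording$left_sensors, s$recording$right_sensors)
  n_over <- sum(s$recording$left_sensors > full) +
    sum(s$recording$right_sensors > full)
  expect_gt(n_over, 0)
  expect_warning(volt <- degrade_to_voltage(s$recording, full), "clipped")
  expect_equal(attr(volt, "clipped"), n_over)
})

test_that("infeasible profiles and durations are rejected", {
  expect_error(gait_profile(stance_fraction_mean = 0.55,
                            double_support_fraction_mean = 0.30),
               "infeasible", class = "gaitmark_validation_error")
  expect_error(gait_profile(stride_time_cv = -0.1),
               class = "gaitmark_validation_error")
  expect_error(simulate_subject(hs_gait_profile(), duration = 2, seed = 1),
               "3 stride", class = "gaitmark_validation_error")
})

test_that("programmed dispersion is recovered within 15% at >= 100 cycles", {
  p <- rigid_profile(stride_time_cv = 0.02, stance_fraction_sd = 0.015,
                     sensor_noise_sd = 2)
  # analytic swing-time SD of the generating model: swing = fraction * stride
  sigma <- sqrt((0.4 * 0.02 * 1.0)^2 + (1.0 * 0.015)^2 + (0.015 * 0.02)^2)
  for (seed in 1:3) {
    s <- simulate_subject(p, duration = 115, seed = seed)
    cs <- segment_recording(s$recording)
    expect_gte(nrow(cs$accepted), 100)
    expect_lt(abs(sd(cs$accepted$swing_left_s) - sigma) / sigma, 0.15)
  }
})
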