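test_that("differential GRF is R - L, with its symmetries", {
  rec <- square_recording(rep(TRUE, 10), rep(TRUE, 10), force = 700)
  d <- differential_grf(rec)
  expect_equal(d$delta, rep(0, 10)) # R == L

  rec2 <- square_recording(rep(FALSE, 10), rep(TRUE, 10), force = 700)
  expect_equal(differential_grf(rec2)$delta, rep(700, 10))

  sim <- simulate_subject(hs_gait_profile(), duration = 8, seed = 4)
  expect_equal(differential_grf(swap_feet(sim$recording))$delta,
               -differential_grf(sim$recording)$delta)
})

test_that("contact detection matches clean square waves and debounces spikes", {
  pat <- cycle_pattern(5, 10, 40, 10, 40)
  rec <- square_recording(pat$left, pat$right)
  ct <- detect_contact(rec)
  expect_equal(ct$left, pat$left)
  expect_equal(ct$right, pat$right)

  # single-sample spike during swing is ignored at min_phase_duration 50 ms
  spiked <- pat$right
  off <- which(!spiked)
  spiked[off[25]] <- TRUE
  rec2 <- square_recording(pat$left, spiked)
  expect_equal(detect_contact(rec2, min_phase_duration = 0.05)$right, pat$right)
  # ...but kept when debouncing is disabled
  expect_equal(detect_contact(rec2, min_phase_duration = 0)$right, spiked)

  # a foot that never crosses the threshold is no gait
  rec3 <- square_recording(pat$left, rep(FALSE, length(pat$left)))
  expect_error(detect_contact(rec3), "no gait",
               class = "gaitmark_nogait_error")
})

test_that("phase labels equal the per-sample truth table (brute-force oracle)", {
  set.seed(1)
  for (rep in 1:20) {
    n <- 200
    left <- runif(n) < 0.7
    right <- runif(n) < 0.7
    rec <- square_recording(left, right)
    lab <- label_phases(detect_contact(rec, min_phase_duration = 0))$labels
    oracle <- ifelse(left & right, "DLS",
                     ifelse(right, "SLS-R", ifelse(left, "SLS-L", "airborne")))
    expect_equal(as.character(lab), oracle)
  }
  # everyone on the ground: all DLS
  rec <- square_recording(rep(TRUE, 50), rep(TRUE, 50))
  expect_equal(unique(as.character(label_phases(detect_contact(rec,
    min_phase_duration = 0))$labels)), "DLS")
})

test_that("periodic patterns segment into identical cycles; missing SLS-R finds none", {
  pat <- cycle_pattern(6, 10, 40, 10, 40)
  rec <- square_recording(pat$left, pat$right)
  cyc <- segment_cycles(label_phases(detect_contact(rec)))
  v <- cyc[cyc$valid, ]
  expect_equal(nrow(v), 6)
  expect_equal(unique(v$end - v$start), 100L)

  # right foot never leaves the ground: DLS <-> SLS-L alternation, no cycle
  left <- rep(c(rep(TRUE, 50), rep(FALSE, 50)), 4)
  expect_error(segment_cycles(label_phases(detect_contact(
    square_recording(left, rep(TRUE, length(left)))))),
    "insufficient gait", class = "gaitmark_nogait_error")
})

test_that("airborne gaps invalidate the enclosing cycle with a reason", {
  pat <- cycle_pattern(4, 10, 40, 10, 40)
  left <- pat$left; right <- pat$right
  # lift the left foot during part of cycle 2's SLS-L: neither foot loaded
  left[185:195] <- FALSE
  cyc <- segment_cycles(label_phases(detect_contact(square_recording(left, right))))
  expect_true(any(!cyc$valid & cyc$reason == "airborne gap"))
  expect_true(sum(cyc$valid) < 4)
})

test_that("cycle parameters reproduce the phase algebra (hand-computed case)", {
  # SL = 1.0 s: DLS1 = DLS2 = 0.1, SLS-R = SLS-L = 0.4
  pat <- cycle_pattern(5, 10, 40, 10, 40)
  rec <- square_recording(pat$left, pat$right)
  ct <- detect_contact(rec)
  par <- cycle_parameters(segment_cycles(label_phases(ct)), ct)
  expect_equal(unique(par$stride_s), 1.0)
  expect_equal(unique(par$stance_left_s), 0.6)   # DLS1 + DLS2 + SLS-L
  expect_equal(unique(par$swing_left_s), 0.4)
  expect_equal(unique(par$stance_left_pct), 60)
  expect_equal(unique(par$swing_left_pct), 40)
  expect_equal(unique(par$dls_s), 0.2)
  expect_equal(unique(par$dls_pct), 20)
  expect_equal(unique(par$sls_right_s), 0.4)
  expect_equal(unique(par$step_left_s), 0.5)  # DLS1 + SLS-R
  expect_equal(unique(par$step_right_s), 0.5) # DLS2 + SLS-L
  # complements and symmetry
  expect_equal(par$stance_left_pct + par$swing_left_pct, rep(100, nrow(par)))
  expect_equal(par$stance_right_pct + par$swing_right_pct, rep(100, nrow(par)))
  expect_equal(par$stance_left_s, par$stance_right_s)
})

test_that("swapping feet mirrors the per-cycle parameters", {
  s <- simulate_subject(rigid_profile(), duration = 15, seed = 11)
  a <- segment_recording(s$recording, outlier_rule = FALSE)$accepted
  b <- segment_recording(swap_feet(s$recording), outlier_rule = FALSE)$accepted
  expect_lte(abs(nrow(a) - nrow(b)), 1)
  # identical cycles: left parameters of the mirror equal right of the original
  expect_equal(unique(round(b$stance_left_s, 2)),
               unique(round(a$stance_right_s, 2)))
  expect_equal(unique(round(b$sls_left_s, 2)),
               unique(round(a$sls_right_s, 2)))
})

test_that("stride-duration outlier rule is one-sided and single-pass", {
  par <- params_from_swing(rep(0.4, 10))
  par$stride_s <- c(rep(1.0, 9), 2.0)
  cs <- reject_outlier_cycles(par, "X")
  # SL-bar = 1.1, SD = 0.3162, bound = 1.7325: only the 2.0 s cycle goes
  expect_equal(cs$sl_mean, 1.1)
  expect_equal(cs$bound, 1.1 + 2 * sd(par$stride_s))
  expect_equal(cs$bound, 1.732456, tolerance = 1e-6)
  expect_equal(nrow(cs$rejected), 1)
  expect_equal(cs$rejected$stride_s, 2.0)
  expect_equal(nrow(cs$accepted), 9)

  # one-sided: a shortened cycle is never rejected
  par$stride_s <- c(rep(1.0, 9), 0.2)
  expect_equal(nrow(reject_outlier_cycles(par)$rejected), 0)

  # all equal: SD = 0, nothing rejected
  par$stride_s <- rep(1.0, 10)
  expect_equal(nrow(reject_outlier_cycles(par)$rejected), 0)

  # single cycle: passed through unmarked
  expect_equal(nrow(reject_outlier_cycles(par[1, , drop = FALSE])$rejected), 0)
})

test_that("an added extreme cycle is rejected whenever it exceeds the recomputed bound", {
  set.seed(42)
  for (rep in 1:25) {
    base <- runif(sample(5:30, 1), 0.9, 1.2)
    extreme <- max(base) + runif(1, 0, 3)
    par <- params_from_swing(rep(0.4, length(base) + 1))
    par$stride_s <- c(base, extreme)
    cs <- reject_outlier_cycles(par)
    expect_equal(extreme %in% cs$rejected$stride_s, extreme > cs$bound)
    # mean/SD computed over all cycles before any rejection
    expect_equal(cs$sl_mean, mean(par$stride_s))
  }
})
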