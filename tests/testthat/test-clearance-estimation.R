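test_that("hematocrit-corrected clearance matches hand arithmetic and limits", {
  s <- dialysis_settings(bfr = 300, hematocrit = 0.35)
  expect_equal(hct_corrected_clearance(10, 10, s), 0)
  expect_equal(hct_corrected_clearance(10, 4, s), 117)
  s30 <- dialysis_settings(bfr = 300, hematocrit = 0.3)
  expect_equal(hct_corrected_clearance(10, 0, s30), 210)  # complete extraction
  s_ufr <- dialysis_settings(bfr = 300, ufr = 10, hematocrit = 0.35)
  expect_equal(hct_corrected_clearance(10, 4, s_ufr),
               0.65 * (3000 - 1160) / 10)  # 119.6
  expect_error(hct_corrected_clearance(0, 4, s), "c_pre")
  # negative estimates are returned, never clamped
  expect_lt(hct_corrected_clearance(4, 10, s), 0)
})

test_that("uncorrected clearance drops the (1 - Hc) factor consistently", {
  s <- dialysis_settings(bfr = 300, hematocrit = 0.35)
  expect_equal(uncorrected_clearance(10, 4, s), 180)
  expect_equal(uncorrected_clearance(10, 10, s), 0)
  s0 <- dialysis_settings(bfr = 300, hematocrit = 0)
  expect_equal(uncorrected_clearance(10, 4, s0),
               hct_corrected_clearance(10, 4, s0))
  # exact ordering identity at UFR = 0
  for (hc in c(0.2, 0.35, 0.5)) {
    sh <- dialysis_settings(bfr = 300, hematocrit = hc)
    expect_equal(hct_corrected_clearance(10, 4, sh),
                 (1 - hc) * uncorrected_clearance(10, 4, sh), tolerance = 1e-12)
  }
})

test_that("the alternate C_post denominator is available behind a flag", {
  s <- dialysis_settings(bfr = 300, hematocrit = 0.35)
  expect_equal(hct_corrected_clearance(10, 4, s, denominator = "c_post"),
               0.65 * 300 * 6 / 4)
})

test_that("dialysate-side clearance and saturation coefficient follow their definitions", {
  s <- dialysis_settings(bfr = 300, dfr = 500, hematocrit = 0.35)
  expect_equal(dialysate_side_clearance(10, 2, s), 100)
  expect_equal(dialysate_side_clearance(10, 0, s), 0)
  expect_true(is.na(dialysate_side_clearance(10, NA, s)))  # missing, not zero
  expect_equal(saturation_coefficient(10, 6, 4), 0.5)
  expect_equal(saturation_coefficient(5, 5, 5), 1)
  expect_equal(saturation_coefficient(10, 6, 0), 0)
  expect_equal(saturation_coefficient(10, 6, 4, convention = "c_pre"), 0.4)
  expect_error(saturation_coefficient(0, 0, 1), "denominator")
})

test_that("blood-side and dialysate-side clearance agree on noiseless runs", {
  for (hc in c(0, 0.35)) for (cl in c(50, 117)) {
    s <- dialysis_settings(bfr = 300, dfr = 500, hematocrit = hc)
    run <- simulate_run(fixed_membrane(cl), s, drug_spec("g", 10))
    tc <- clearance_time_course(run)
    expect_equal(tc$cl_corrected, tc$cl_dialysate_side, tolerance = 1e-6)
  }
})

test_that("clearance time course recovers the configured clearance and flags degenerates", {
  run <- simulate_run(fixed_membrane(117), std_settings(), drug_spec("g", 10))
  tc <- clearance_time_course(run)
  expect_equal(nrow(tc), 8)
  expect_equal(tc$cl_corrected, rep(117, 8), tolerance = 1e-9)
  expect_false(any(tc$flagged))
  # one zero c_pre: that timepoint flagged, others computed
  run$c_pre[3] <- 0
  tc2 <- clearance_time_course(run)
  expect_true(tc2$flagged[3])
  expect_true(is.na(tc2$cl_corrected[3]))
  expect_equal(tc2$cl_corrected[-3], rep(117, 7), tolerance = 1e-9)
})

test_that("noisy per-run clearance means land near truth", {
  run <- simulate_run(fixed_membrane(117), std_settings(), drug_spec("g", 10))
  noisy <- add_noise(run, noise_model(0.05, 123))
  tc <- clearance_time_course(noisy)
  expect_lt(abs(mean(tc$cl_corrected[!tc$flagged]) - 117) / 117, 0.10)
})

test_that("trapezoidal AUC matches geometry and the closed-form integral", {
  expect_equal(auc_trapezoid(c(0, 60), c(10, 10)), 600)
  expect_equal(auc_trapezoid(c(0, 10), c(10, 0)), 50)
  tt <- c(1, 5, 10, 15, 20, 30, 40, 60)
  cc <- 10 * exp(-0.09 * tt)
  analytic <- 10 / 0.09 * (exp(-0.09 * 1) - exp(-0.09 * 60))
  expect_lt(abs(auc_trapezoid(tt, cc) - analytic) / analytic, 0.05)
  expect_error(auc_trapezoid(1, 10), "2 points")
  expect_error(auc_trapezoid(c(1, 1), c(1, 2)), "increasing")
})

test_that("log-linear elimination fit recovers rate, half-life and volume", {
  tt <- c(1, 5, 10, 15, 20, 30, 40, 60)
  fit <- elimination_fit(tt, 10 * exp(-0.05 * tt))
  expect_equal(fit$k_el, 0.05, tolerance = 1e-9)
  expect_equal(fit$half_life, log(2) / 0.05, tolerance = 1e-9)
  flat <- elimination_fit(tt, rep(5, 8))
  expect_equal(flat$k_el, 0, tolerance = 1e-12)
  # from a simulated run: k_el = CL/Vp, vd recovers the plasma volume
  run <- simulate_run(fixed_membrane(117), std_settings(), drug_spec("g", 10))
  pk <- pk_summary(run)
  expect_equal(pk$k_el, 117 / 1300, tolerance = 1e-9)
  expect_equal(pk$half_life, log(2) * 1300 / 117, tolerance = 1e-9)
  expect_equal(pk$vd, 1300, tolerance = 1e-6)
  expect_error(elimination_fit(tt[1:3], c(1, -1, 0)), "3 positive")
})

test_that("condition summaries use the sample SD and report exclusions", {
  s <- summarize_condition(c(100, 110, 120))
  expect_equal(s$mean, 110); expect_equal(s$sd, 10); expect_equal(s$n, 3)
  one <- summarize_condition(105)
  expect_equal(one$n, 1); expect_true(is.na(one$sd))
  withneg <- summarize_condition(c(100, 110, -5, NA))
  expect_equal(withneg$n, 2); expect_equal(withneg$n_excluded, 2)
  expect_error(summarize_condition(c(-1, NA)), "no retained")
})

test_that("study-level estimation pools replicates into condition rows", {
  conds <- list(
    study_condition(fixed_membrane(117, name = "F80s"), std_settings(),
                    drug_spec("gentamicin", 10), replicates = 3),
    study_condition(fixed_membrane(90, name = "CAHP-170"), std_settings(),
                    drug_spec("gentamicin", 10), replicates = 2))
  runs <- generate_study(conds)
  est <- estimate_study(runs)
  est <- est[order(est$membrane), ]
  expect_equal(est$cl_ml_min, c(90, 117), tolerance = 1e-9)
  expect_equal(est$sd_ml_min, c(0, 0), tolerance = 1e-9)   # noiseless replicates
  expect_equal(est$n, c(16, 24))  # 8 timepoints x replicates
  # within-run-first alternative counts runs
  est2 <- estimate_study(runs, within_run_first = TRUE)
  est2 <- est2[order(est2$membrane), ]
  expect_equal(est2$n, c(2, 3))
  expect_equal(est2$cl_ml_min, c(90, 117), tolerance = 1e-9)
})

test_that("estimator is consistent across the hematocrit and flow grid", {
  for (hc in c(0, 0.2, 0.35, 0.5))
    for (bfr in c(250, 300, 400))
      for (dfr in c(500, 800)) {
        s <- dialysis_settings(bfr = bfr, dfr = dfr, hematocrit = hc)
        cl_true <- 0.5 * plasma_flow(s)
        run <- simulate_run(fixed_membrane(cl_true), s, drug_spec("g", 10))
        tc <- clearance_time_course(run)
        expect_equal(tc$cl_corrected, rep(cl_true, 8), tolerance = 1e-9)
      }
})
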