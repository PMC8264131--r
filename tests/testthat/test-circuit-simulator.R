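test_that("plasma flow is blood flow times plasma fraction", {
  expect_equal(plasma_flow(dialysis_settings(bfr = 300, hematocrit = 0)), 300)
  expect_equal(plasma_flow(dialysis_settings(bfr = 300, hematocrit = 0.35)), 195)
  expect_equal(plasma_flow(dialysis_settings(bfr = 400, hematocrit = 0.30)), 280)
})

test_that("type constructors enforce their invariants", {
  expect_error(dialysis_settings(hematocrit = 1.2), "hematocrit")
  expect_error(dialysis_settings(bfr = 0), "bfr")
  expect_error(dialysis_settings(ufr = 300, bfr = 300), "ufr")
  expect_error(membrane_spec("x", "polysulfone", -1, "fixed_clearance",
                             cl_membrane = 100), "area")
  expect_error(membrane_spec("x", "polysulfone", 1.8, "k0a"), "k0a")
  expect_error(membrane_spec("x", "polysulfone", 1.8, "fixed_clearance"),
               "cl_membrane")
  expect_error(drug_spec("g", c0 = 0), "c0")
  expect_error(sampling_grid(c(5, 5, 10)), "increasing")
  expect_error(sampling_grid(c(0, 5)), "> 0")
  expect_error(noise_model(-0.1), "cv")
  expect_error(adsorption_spec(-1, 0.1), "capacity")
})

test_that("K0A clearance matches limits and the segmented dialyzer oracle", {
  expect_equal(clearance_from_k0a(0, 195, 500), 0)
  # perfect-exchange limit: min of the two flows
  expect_equal(clearance_from_k0a(1e9, 195, 500), 195)
  expect_equal(clearance_from_k0a(1e9, 600, 500), 500)
  # equal flows: continuous limit Qp*N/(N+1)
  expect_equal(clearance_from_k0a(300, 300, 300), 300 * 1 / 2, tolerance = 1e-9)
  for (k0a in c(50, 200, 600, 1200, 2000)) {
    closed <- clearance_from_k0a(k0a, 195, 500)
    oracle <- segmented_dialyzer_cl(k0a, 195, 500)
    expect_lt(abs(closed - oracle) / oracle, 0.005)
  }
  expect_error(clearance_from_k0a(100, 0, 500), "qp")
})

test_that("K0A clearance is monotone in K0A and dialysate flow", {
  k0as <- seq(50, 2000, by = 50)
  cls <- clearance_from_k0a(k0as, 195, 500)
  expect_true(all(diff(cls) > 0))
  dfrs <- seq(300, 800, by = 50)
  cls_d <- vapply(dfrs, function(qd) clearance_from_k0a(600, 195, qd),
                  numeric(1))
  expect_true(all(diff(cls_d) > 0))
  expect_true(all(cls <= pmin(195, 500)))
})

test_that("noiseless simulation matches the mono-exponential closed form", {
  run <- simulate_run(fixed_membrane(117), std_settings(),
                      drug_spec("gentamicin", 10), sampling_grid())
  expect_equal(run$c_pre[1], 10 * exp(-117 * 1 / 1300), tolerance = 1e-9)
  expect_equal(run$c_pre, 10 * exp(-117 * run$times / 1300), tolerance = 1e-9)
  expect_equal(run$c_pre[run$times == 10], 4.0657, tolerance = 1e-4)
  # extraction ratio constant and equal to CL_m / Qp
  expect_equal(run$c_post / run$c_pre, rep(1 - 117 / 195, 8), tolerance = 1e-9)
  # dialysate concentration from mass balance across the filter
  expect_equal(run$c_dial, 117 * run$c_pre / 500, tolerance = 1e-9)
  expect_true(all(run$c_post <= run$c_pre))
})

test_that("zero membrane clearance leaves the reservoir untouched", {
  run <- simulate_run(fixed_membrane(0), std_settings(),
                      drug_spec("gentamicin", 10))
  expect_equal(run$c_pre, rep(10, 8))
  expect_equal(run$c_post, rep(10, 8))
  expect_equal(run$c_dial, rep(0, 8))
})

test_that("simulation rejects impossible extraction", {
  expect_error(simulate_run(fixed_membrane(200), std_settings(),
                            drug_spec("g", 10)),
               "extraction ratio")
})

test_that("mass balance holds on noiseless runs, checked by trapezoid integration", {
  # independent route: integrate DFR * C_dial over a dense grid and compare
  # reservoir + effluent with the initial mass
  dense <- sampling_grid(seq(0.05, 60, by = 0.05))
  for (cl in c(30, 117, 180)) {
    run <- simulate_run(fixed_membrane(cl), std_settings(),
                        drug_spec("gentamicin", 10), dense)
    efflux <- 500 * run$c_dial / 1000                    # mg/min
    m_dial <- auc_trapezoid(c(0, run$times), c(500 * 10 * cl / 500 / 1000, efflux))
    m_res <- run$c_pre[length(run$c_pre)] * 1300 / 1000
    m0 <- 10 * 1300 / 1000
    expect_lt(abs(m_res + m_dial - m0) / m0, 1e-3)
    # and the simulator's own accounting is exact
    expect_equal(run$mass$reservoir + run$mass$dialysate + run$mass$adsorbed,
                 run$mass$initial, tolerance = 1e-12)
  }
})

test_that("saturable membrane adsorption conserves mass and relaxes after saturation", {
  ads <- adsorption_spec(capacity = 10, rate = 0.05)
  run <- simulate_run(fixed_membrane(20, ads = ads), std_settings(),
                      drug_spec("teicoplanin", 25), sampling_grid())
  m <- run$mass
  expect_lt(abs(m$reservoir + m$dialysate + m$adsorbed - m$initial) / m$initial,
            1e-3)
  expect_equal(m$adsorbed, 10, tolerance = 1e-6)  # pool exhausted by 60 min
  # while the pool is active the blood-side extraction exceeds the diffusive
  # extraction; afterwards it returns to CL_m / Qp
  e <- 1 - run$c_post / run$c_pre
  expect_gt(e[1], 20 / 195)
  expect_equal(e[length(e)], 20 / 195, tolerance = 1e-9)
  # teicoplanin-like signature: dialysate-side clearance stays at CL_m even
  # while total plasma loss is faster
  expect_equal(run$c_dial, 20 * run$c_pre / 500, tolerance = 1e-9)
})

test_that("faster membranes give faster decline", {
  slow <- simulate_run(fixed_membrane(50), std_settings(), drug_spec("g", 10))
  fast <- simulate_run(fixed_membrane(150), std_settings(), drug_spec("g", 10))
  expect_true(all(fast$c_pre < slow$c_pre))
})

test_that("ultrafiltration adds convective loss and shifts the outlet balance", {
  s <- dialysis_settings(bfr = 300, dfr = 500, ufr = 10, hematocrit = 0.35)
  run <- simulate_run(fixed_membrane(117), s, drug_spec("g", 10))
  expect_equal(run$c_pre, 10 * exp(-(117 + 10) * run$times / 1300),
               tolerance = 1e-9)
  expect_equal(run$c_post / run$c_pre, rep((195 - 127) / 185, 8),
               tolerance = 1e-9)
  m <- run$mass
  expect_equal(m$reservoir + m$dialysate, m$initial, tolerance = 1e-12)
})

test_that("lognormal noise has median 1, the right CV, and is seed-deterministic", {
  run <- simulate_run(fixed_membrane(117), std_settings(), drug_spec("g", 10))
  expect_identical(add_noise(run, noise_model(0, 1)), run)
  n1 <- add_noise(run, noise_model(0.05, 42))
  n2 <- add_noise(run, noise_model(0.05, 42))
  expect_identical(n1, n2)
  n3 <- add_noise(run, noise_model(0.05, 43))
  expect_false(identical(n1$c_pre, n3$c_pre))
  # Monte-Carlo check of the deviate generator via a long constant series
  flat <- run; flat$times <- seq_len(3334); flat$c_pre <- rep(1, 3334)
  flat$c_post <- rep(1, 3334); flat$c_dial <- rep(1, 3334)
  dev <- add_noise(flat, noise_model(0.05, 7))
  devs <- c(dev$c_pre, dev$c_post, dev$c_dial)  # 10002 deviates
  cv_hat <- stats::sd(devs) / mean(devs)
  expect_gt(cv_hat, 0.045); expect_lt(cv_hat, 0.055)
  expect_equal(stats::median(devs), 1, tolerance = 0.01)
})

test_that("add_noise leaves the global RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  run <- simulate_run(fixed_membrane(117), std_settings(), drug_spec("g", 10))
  invisible(add_noise(run, noise_model(0.05, 1)))
  expect_identical(.Random.seed, before)
})

test_that("generate_study emits the right run count with reproducible streams", {
  cond <- study_condition(fixed_membrane(117), std_settings(),
                          drug_spec("gentamicin", 10), replicates = 3)
  noiseless <- generate_study(list(cond))
  expect_length(noiseless, 3)
  expect_identical(noiseless[[1]]$c_pre, noiseless[[2]]$c_pre)
  expect_false(anyDuplicated(vapply(noiseless, `[[`, character(1), "run_id")) > 0)

  s1 <- generate_study(list(cond), noise = noise_model(0.05, 11))
  s2 <- generate_study(list(cond), noise = noise_model(0.05, 11))
  expect_identical(s1, s2)
  expect_false(identical(s1[[1]]$c_pre, s1[[2]]$c_pre))  # independent streams

  # replicate-weighted condition grid: 12+12+17+12+12+12 = 77 runs
  reps <- c(12, 12, 17, 12, 12, 12)
  conds <- lapply(seq_along(reps), function(i)
    study_condition(fixed_membrane(100 + i, name = paste0("M", i)),
                    std_settings(), drug_spec("gentamicin", 10), reps[i]))
  expect_length(generate_study(conds), 77)
})

test_that("duplicate condition labels are rejected", {
  cond <- study_condition(fixed_membrane(117), std_settings(),
                          drug_spec("gentamicin", 10), 2)
  expect_error(generate_study(list(cond, cond)), "duplicate")
})
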