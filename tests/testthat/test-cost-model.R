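test_that("expected_cost combines the age gradient with compounded inflation", {
  flat <- flat_profile(1720)
  expect_equal(expected_cost(flat, 40, 0, inflation = 0.03), 1720)
  expect_equal(expected_cost(flat, 40, 1, inflation = 0.03), 1771.60)
  # pi = 0 on a flat profile is the identity at every offset
  for (off in c(0, 1, 5, 30))
    expect_equal(expected_cost(flat, 40, off, inflation = 0), 1720)
  # gradient and inflation both move the cost
  grad <- generate_profile("log_linear", c0 = 1000, beta = log(1.02), a0 = 50L)
  expect_equal(expected_cost(grad, 50, 2, inflation = 0.03),
               1000 * 1.02^2 * 1.03^2)
})

test_that("expected_cost enforces its contract", {
  flat <- flat_profile(100, age_range = c(30L, 50L))
  expect_error(expected_cost(flat, 29, 0), class = "ltra_range_error")
  expect_error(expected_cost(flat, 45, 10), class = "ltra_range_error")
  expect_error(expected_cost(flat, 40, 1.5), class = "ltra_contract_error")
  expect_error(expected_cost(flat, 40, 0, inflation = -1),
               class = "ltra_contract_error")
})

test_that("baseline_trajectory projects costs year by year", {
  flat <- flat_profile(100)
  expect_equal(baseline_trajectory(flat, 30, 3, inflation = 0)$values,
               c(100, 100, 100))
  expect_equal(baseline_trajectory(flat, 30, 3, inflation = 0.1)$values,
               c(100, 110, 121))
  expect_error(baseline_trajectory(flat_profile(100, c(30L, 35L)), 30, 10),
               class = "ltra_range_error")
  # strictly increasing whenever gradient and inflation are both positive
  up <- generate_profile("log_linear", c0 = 800, beta = 0.01, a0 = 20L)
  tr <- baseline_trajectory(up, 20, 15, inflation = 0.02)
  expect_true(all(diff(tr$values) > 0))
})

test_that("a calibrated constant-growth path reproduces a printed period total", {
  g <- calibrate_growth(1720, 23211, 10)
  prof <- generate_profile("log_linear", c0 = 1720,
                           beta = log((1 + g) / 1.03), a0 = 40L)
  tr <- baseline_trajectory(prof, 40, 10, inflation = 0.03)
  expect_equal(tr$values[1], 1720)
  expect_equal(sum(tr$values), 23211, tolerance = 1e-8)
})

test_that("apply_intervention scales the intervention year and the savings years", {
  flat <- flat_profile(1720)
  base <- baseline_trajectory(flat, 40, 10, inflation = 0)
  ivp <- apply_intervention(base, intervention(1, kappa = 2, sigma = 0.3))
  expect_equal(ivp$values[1], 3440)
  expect_equal(ivp$values[2:10], rep(0.7 * 1720, 9))
  expect_identical(ivp$label, "intervention")

  # savings anchored to originally expected costs, lag leaves a gap year
  base2 <- cost_trajectory(c(500, 1000, 1500, 2000), start_age = 40)
  ivp2 <- apply_intervention(base2, intervention(1, kappa = 2, sigma = 0.3,
                                                 cost_onset_lag = 2,
                                                 payment_onset_lag = 2))
  expect_equal(ivp2$values, c(1000, 1000, 0.7 * 1500, 0.7 * 2000))

  # null intervention is the identity
  null_iv <- intervention(1, kappa = 1, sigma = 0)
  expect_equal(apply_intervention(base, null_iv)$values, base$values)

  expect_error(intervention(1, sigma = 1.2), class = "ltra_contract_error")
  expect_error(intervention(1, kappa = -1), class = "ltra_contract_error")
  expect_error(apply_intervention(ivp, null_iv), class = "ltra_contract_error")
})

test_that("total intervention cost is monotone in sigma and kappa", {
  base <- baseline_trajectory(flat_profile(1000), 40, 8, inflation = 0.03)
  sig <- seq(0, 1, by = 0.2)
  totals_sig <- vapply(sig, function(s)
    total_amount(apply_intervention(base, intervention(2, kappa = 2, sigma = s))),
    0)
  expect_true(all(diff(totals_sig) <= 1e-9))
  kap <- seq(0, 4, by = 0.5)
  totals_kap <- vapply(kap, function(k)
    total_amount(apply_intervention(base, intervention(2, kappa = k, sigma = 0.3))),
    0)
  expect_true(all(diff(totals_kap) >= -1e-9))
})

test_that("calibrate_growth matches independent annuity oracles", {
  expect_equal(calibrate_growth(100, 1000, 10), 0, tolerance = 1e-9)
  # oracle: 100 * (1 + (1+g)) = 300  =>  g = 1
  expect_equal(oracle_growth_bisect(100, 300, 2), 1, tolerance = 1e-6)
  expect_equal(calibrate_growth(100, 300, 2), 1, tolerance = 1e-9)
  expect_equal(calibrate_growth(1720, 23211, 10),
               oracle_growth_bisect(1720, 23211, 10), tolerance = 1e-6)
  expect_error(calibrate_growth(100, 1e12, 2), class = "ltra_convergence_error")
  expect_error(calibrate_growth(100, 300, 1), class = "ltra_contract_error")
})

test_that("growth calibration round-trips through the annuity sum", {
  set.seed(11)
  for (i in 1:25) {
    first <- stats::runif(1, 10, 5000)
    g <- stats::runif(1, -0.5, 0.5)
    H <- sample(2:30, 1)
    expect_lt(abs(calibrate_growth(first, annuity_sum(first, g, H), H) - g),
              1e-6)
  }
})

test_that("anchor_trajectory_total rescales only from the onset year", {
  base <- cost_trajectory(c(100, 200, 300, 400), start_age = 40)
  out <- anchor_trajectory_total(base, 1100, from_year = 2)
  expect_equal(out$values[1], 100)
  expect_equal(sum(out$values), 1100)
  expect_equal(out$values[2:4] / base$values[2:4], rep(1000 / 900, 3))
  expect_error(anchor_trajectory_total(base, 50, from_year = 2),
               class = "ltra_contract_error")
})

test_that("profiles round-trip through CSV bit-identically", {
  prof <- generate_profile("log_linear", c0 = 1720, beta = log(1.034),
                           a0 = 40L, age_range = c(20L, 60L))
  expect_equal(profile_cost(prof, 41) / profile_cost(prof, 40), 1.034,
               tolerance = 1e-12)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, f1)
  back <- read_profile_csv(f1)
  write_profile_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_profile("log_linear", c0 = -5),
               class = "ltra_contract_error")
})
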