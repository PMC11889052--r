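test_that("the age-dependent horizon rule uses exclusive thresholds", {
  cfg <- scheme_config("long_term")
  expect_equal(horizon_for_age(cfg, c(0, 40, 70, 71, 80, 81, 99)),
               c(10, 10, 10, 5, 5, 1, 1))
  expect_error(scheme_config(horizons = c(5, 10, 1)),
               class = "ltra_contract_error")
  expect_error(horizon_for_age(cfg, -1), class = "ltra_contract_error")
})

test_that("one-year payments track the annually reassessed expected costs", {
  flat <- flat_profile(1000)
  base <- baseline_trajectory(flat, 40, 4, inflation = 0)
  iv <- intervention(1, kappa = 2, sigma = 0.3, cost_onset_lag = 1,
                     payment_onset_lag = 2)
  expect_equal(reassessed_payment_path(base, iv), c(1000, 1000, 700, 700))

  # sigma = 0: payments identical to the no-intervention stream
  iv0 <- intervention(1, kappa = 2, sigma = 0)
  expect_equal(reassessed_payment_path(base, iv0), base$values)

  # no intervention: payments equal baseline costs, surplus 0
  ps <- one_year_payments(base)
  expect_equal(ps$payments, base$values)
  expect_equal(total_surplus(ledger(ps, base)), 0)
  expect_error(one_year_payments(base, window = 9), class = "ltra_range_error")
})

test_that("a long-term assessment freezes the schedule from the baseline", {
  flat <- flat_profile(100)
  base <- baseline_trajectory(flat, 40, 5, inflation = 0)
  a <- long_term_assessment(base, horizon = 5)
  expect_equal(a$scheduled_payments, rep(100, 5))
  # H = 1 degenerates to the one-year payment for that year
  a1 <- long_term_assessment(base, horizon = 1)
  expect_equal(a1$scheduled_payments, one_year_payments(base, 1)$payments)
  expect_error(long_term_assessment(base, horizon = 6),
               class = "ltra_range_error")
  # horizon picked from the age rule at the assessment date
  prof <- flat_profile(100)
  old <- baseline_trajectory(prof, 75, 5, inflation = 0)
  expect_equal(long_term_assessment(old)$horizon, 5)
})

test_that("switch settlements transfer the expectation change over remaining years", {
  base <- baseline_trajectory(flat_profile(1000), 40, 10, inflation = 0)
  a <- long_term_assessment(base, horizon = 10)
  # switch after 3 of 10 years leaves r = 7
  s <- switch_settlement(a, rep(1000, 7), switch_year = 4)
  expect_equal(s$remaining_years, 7)
  expect_equal(s$transfer, 0)
  # costs up 100/year: departing insurer pays 700 to the scheme
  s2 <- switch_settlement(a, rep(1100, 7), switch_year = 4)
  expect_equal(s2$transfer, 700)
  # costs down: the scheme pays the departing insurer
  s3 <- switch_settlement(a, rep(900, 7), switch_year = 4)
  expect_equal(s3$transfer, -700)
  # switch after the final horizon year: r = 0, transfer 0
  s4 <- switch_settlement(a, numeric(0), switch_year = 11)
  expect_equal(s4$transfer, 0)
  expect_error(switch_settlement(a, rep(1000, 6), switch_year = 4),
               class = "ltra_contract_error")
  expect_error(switch_settlement(a, rep(1000, 10), switch_year = 1),
               class = "ltra_contract_error")
})

test_that("scheme_payment_stream composes assessments, switches and settlements", {
  prof <- flat_profile(1000)
  h_plain <- enrollee_history(prof, 40, inflation = 0)
  one <- scheme_payment_stream(scheme_config("one_year"), h_plain, 10)
  expect_equal(one$payments, rep(1000, 10))

  # long-term, no events: one assessment covers the whole window
  lt <- scheme_payment_stream(scheme_config("long_term"), h_plain, 10)
  expect_equal(lt$payments, rep(1000, 10))
  expect_equal(unique(lt$details$assessment_id), 1L)

  # switch at year 4 with unchanged risk: settlement 0, stream seamless
  h_sw <- enrollee_history(prof, 40, inflation = 0, switch_years = 4L)
  lt_sw <- scheme_payment_stream(scheme_config("long_term"), h_sw, 10)
  expect_equal(lt_sw$payments, rep(1000, 10))
  expect_length(lt_sw$settlements, 1)
  expect_equal(lt_sw$settlements[[1]]$transfer, 0)
  expect_equal(lt_sw$settlements[[1]]$remaining_years, 7)
  expect_equal(unique(lt_sw$details$insurer), c(1L, 2L))

  # deterioration before the switch is charged to the departing insurer
  state <- c(1, 1, 1.5, 1.5, rep(1.5, 6))
  h_bad <- enrollee_history(prof, 40, inflation = 0,
                            state_multipliers = state, switch_years = 4L)
  lt_bad <- scheme_payment_stream(scheme_config("long_term"), h_bad, 10)
  expect_equal(lt_bad$settlements[[1]]$transfer, 7 * (1500 - 1000))
  # post-switch payments reflect the new, higher assessment
  expect_equal(lt_bad$payments[4:10], rep(1500, 7))
  expect_equal(lt_bad$payments[1:3], rep(1000, 3))
})

test_that("post-assessment health shocks never move the frozen schedule", {
  prof <- generate_profile("log_linear", c0 = 1500, beta = 0.02, a0 = 40L)
  cfg <- scheme_config("long_term")
  h0 <- enrollee_history(prof, 40, state_multipliers = rep(1, 10))
  ref <- scheme_payment_stream(cfg, h0, 10)$payments
  set.seed(42)
  for (i in 1:50) {
    state <- c(1, stats::rlnorm(9, 0, 0.5))
    h <- enrollee_history(prof, 40, state_multipliers = state)
    expect_identical(scheme_payment_stream(cfg, h, 10)$payments, ref)
  }
})

test_that("long-term with H = 1 reproduces the one-year stream on any history", {
  prof <- generate_profile("log_linear", c0 = 1200, beta = 0.015, a0 = 30L)
  cfg1 <- scheme_config("one_year")
  cfgH1 <- scheme_config("long_term", horizons = c(1L, 1L, 1L))
  set.seed(7)
  for (i in 1:10) {
    h <- enrollee_history(prof, sample(30:60, 1),
                          state_multipliers = stats::rlnorm(10, 0, 0.3),
                          switch_years = sample(2:9, 1))
    expect_equal(scheme_payment_stream(cfg1, h, 10)$payments,
                 scheme_payment_stream(cfgH1, h, 10)$payments)
  }
  # an 81-year-old under the default rule gets H = 1, i.e. one-year payments
  h81 <- enrollee_history(prof, 81, state_multipliers = stats::rlnorm(10, 0, 0.3))
  expect_equal(scheme_payment_stream(scheme_config("long_term"), h81, 10)$payments,
               scheme_payment_stream(cfg1, h81, 10)$payments)
})

test_that("mid-horizon ageing past a threshold honours the running schedule", {
  prof <- flat_profile(2000)
  # enters at 68: first assessment H = 10 runs to age 77 untouched
  h <- enrollee_history(prof, 68, inflation = 0)
  st <- scheme_payment_stream(scheme_config("long_term"), h, 15)
  expect_equal(st$details$assessment_id[1:10], rep(1L, 10))
  # the next assessment at age 78 uses the shorter horizon (H = 5)
  expect_equal(st$details$assessment_id[11:15], rep(2L, 5))
})

test_that("exit cancels remaining payments and settles no-fault years at zero", {
  prof <- flat_profile(1000)
  h <- enrollee_history(prof, 40, inflation = 0, exit_year = 4L)
  st <- scheme_payment_stream(scheme_config("long_term"), h, 10)
  expect_equal(st$payments, c(rep(1000, 3), rep(0, 7)))
  expect_equal(st$details$flag[4:10], rep("exit", 7))
  expect_length(st$settlements, 1)
  expect_equal(st$settlements[[1]]$reason, "exit")
  expect_equal(st$settlements[[1]]$transfer, -7000)
})
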