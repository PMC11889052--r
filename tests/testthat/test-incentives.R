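test_that("the ledger books surplus year by year", {
  led <- ledger(c(100, 100, 100), c(80, 120, 90))
  expect_equal(led$surplus, c(20, -20, 10))
  expect_equal(led$cumulative_surplus, c(20, 0, 10))
  expect_equal(total_surplus(led), 10)
  # payments identical to expenditures: surplus identically zero
  x <- stats::runif(10, 100, 5000)
  expect_equal(total_surplus(ledger(x, x)), 0)
  expect_error(ledger(1:3, 1:4), class = "ltra_contract_error")
})

test_that("a null intervention has zero NPV under every scheme", {
  fx <- load_fixture("null_intervention")
  scen <- list(profile = fx$profile, start_age = 40, horizon = 10,
               inflation = fx$inflation, intervention = fx$intervention)
  expect_equal(intervention_npv(scheme_config("long_term"), scen), 0)
  expect_equal(intervention_npv(scheme_config("one_year"), scen), 0)
  expect_false(investment_decision(scheme_config("long_term"), scen))
})

test_that("the worked example pays off long-term but not one-year", {
  fx <- load_fixture("paper_example")
  scen <- list(profile = fx$profile, start_age = 40, horizon = 10,
               inflation = fx$inflation, intervention = fx$intervention)
  npv_long <- intervention_npv(scheme_config("long_term"), scen)
  npv_one <- intervention_npv(scheme_config("one_year"), scen)
  # ledger-based oracle for the long-term NPV: payments are frozen either
  # way, so the NPV is the expenditure saving
  base <- baseline_trajectory(fx$profile, 40, 10, fx$inflation)
  ivp <- apply_intervention(base, fx$intervention)
  sched <- long_term_assessment(base, config = fx$scheme)$scheduled_payments
  oracle_long <- total_surplus(ledger(sched, ivp)) -
    total_surplus(ledger(sched, base))
  expect_equal(npv_long, oracle_long)
  expect_gt(npv_long, 0)
  # one-year: savings clawed back, the kappa premium never recouped
  expect_lt(npv_one, 0)
})

test_that("long-term NPV is monotone in sigma and kappa", {
  prof <- flat_profile(1000)
  cfg <- scheme_config("long_term")
  npv_at <- function(k, s) intervention_npv(cfg, list(
    profile = prof, start_age = 40, horizon = 10, inflation = 0.02,
    intervention = intervention(1, kappa = k, sigma = s)))
  sig <- seq(0, 1, 0.25)
  expect_true(all(diff(vapply(sig, function(s) npv_at(2, s), 0)) >= -1e-9))
  kap <- seq(0, 4, 0.5)
  expect_true(all(diff(vapply(kap, function(k) npv_at(k, 0.3), 0)) <= 1e-9))
})

test_that("discounting shrinks a deferred-payoff NPV toward its up-front cost", {
  prof <- flat_profile(1000)
  cfg <- scheme_config("long_term")
  scen <- list(profile = prof, start_age = 40, horizon = 10, inflation = 0,
               intervention = intervention(1, kappa = 2, sigma = 0.3))
  npv0 <- intervention_npv(cfg, scen, discount_rate = 0)
  npv5 <- intervention_npv(cfg, scen, discount_rate = 0.05)
  expect_lt(npv5, npv0)
  # at an extreme discount rate only the up-front premium matters
  expect_equal(intervention_npv(cfg, scen, discount_rate = 1e9), -1000,
               tolerance = 1e-6)
})

test_that("selection diagnostics separate observable from unobservable error", {
  # zero prediction error: every group breaks exactly even
  df0 <- data.frame(group = rep(c("A", "B"), each = 10), profit = 0,
                    prediction_error = 0)
  d0 <- selection_diagnostics(df0, error = "prediction_error")
  expect_equal(d0$group_summary$mean_profit, c(0, 0))
  expect_equal(d0$max_pairwise_gap, 0)

  # group means weighted by size always reproduce the overall mean
  set.seed(3)
  dfr <- data.frame(group = sample(c("A", "B", "C"), 300, replace = TRUE),
                    profit = stats::rnorm(300, 50, 200))
  dr <- selection_diagnostics(dfr)
  expect_equal(
    sum(dr$group_summary$mean_profit * dr$group_summary$n) /
      sum(dr$group_summary$n),
    dr$overall_mean_profit
  )

  expect_error(selection_diagnostics(data.frame(group = "A", profit = 1)),
               class = "ltra_contract_error")
})

test_that("uncorrelated prediction error creates no group profit gap", {
  sim <- simulate_selection_experiment(10000, seed = 101, error_sd = 500,
                                       group_shift = 0)
  d <- selection_diagnostics(sim, error = "prediction_error")
  ns <- d$group_summary$n
  se_gap <- 500 * sqrt(1 / ns[1] + 1 / ns[2])
  expect_lt(d$max_pairwise_gap, 3 * se_gap)
  expect_lt(abs(d$signal_error_cor), 3 / sqrt(10000))
  # profits are minus the prediction error by construction
  expect_equal(sim$profit, -sim$prediction_error)
})

test_that("error correlated with an observable flag depresses that group's profit", {
  sim <- simulate_selection_experiment(4000, seed = 202, error_sd = 300,
                                       group_shift = 800)
  d <- selection_diagnostics(sim, error = "prediction_error")
  gs <- d$group_summary
  expect_lt(gs$mean_profit[gs$group == "flagged"],
            gs$mean_profit[gs$group == "plain"])
  expect_gt(d$max_pairwise_gap, 500)
})
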