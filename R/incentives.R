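#' Insurer-enrollee ledger
#'
#' The per-year book for one insurer-enrollee pair: surplus in year t is
#' payment minus expenditure, and the cumulative surplus over the horizon is
#' the quantity that drives the insurer's investment decision. Values are
#' kept at full precision; euro rounding happens only in the print method.
#'
#' @param payments A `payment_stream`, [cost_trajectory()], or numeric
#'   vector of annual payments.
#' @param expenditures A [cost_trajectory()] or numeric vector of annual
#'   expenditures; must match `payments` in length.
#' @param scheme Optional scheme kind recorded in the report.
#' @param scenario_id Optional scenario identifier.
#' @return A `ledger_report`: data.frame with columns `year`, `payment`,
#'   `expenditure`, `surplus`, `cumulative_surplus`.
#' @seealso [total_surplus()]
#' @export
ledger <- function(payments, expenditures, scheme = NULL, scenario_id = NULL) {
  pay <- stream_values(payments)
  cost <- stream_values(expenditures)
  if (length(pay) != length(cost))
    stop_contract(sprintf("payments (%d) and expenditures (%d) differ in length",
                          length(pay), length(cost)))
  surplus <- pay - cost
  out <- data.frame(
    year = seq_along(pay), payment = pay, expenditure = cost,
    surplus = surplus, cumulative_surplus = cumsum(surplus)
  )
  if (is.null(scheme) && inherits(payments, "payment_stream"))
    scheme <- payments$kind
  structure(out, class = c("ledger_report", "data.frame"),
            scheme = scheme, scenario_id = scenario_id)
}

#' Cumulative surplus of a ledger
#'
#' @param x A `ledger_report`.
#' @return Total payments minus total expenditures, in euros (unrounded).
#' @export
total_surplus <- function(x) {
  stopifnot(inherits(x, "ledger_report"))
  x$cumulative_surplus[nrow(x)]
}

#' @export
print.ledger_report <- function(x, ...) {
  kind <- attr(x, "scheme")
  cat(sprintf("Ledger%s: %d years\n",
              if (is.null(kind)) "" else paste0(" (", kind, " scheme)"),
              nrow(x)))
  shown <- data.frame(
    year = x$year,
    payment = round_euros(x$payment),
    expenditure = round_euros(x$expenditure),
    surplus = round_euros(x$surplus),
    cumulative = round_euros(x$cumulative_surplus)
  )
  print.data.frame(shown, row.names = FALSE)
  cat(sprintf("Cumulative surplus: %s EUR\n",
              format(round_euros(total_surplus(x)), big.mark = ",")))
  invisible(x)
}

#' Net present value of a health investment under a payment scheme
#'
#' Computes the insurer's cumulative (optionally discounted) surplus with
#' the intervention minus without it, under the given scheme. Under the
#' long-term scheme payments are frozen at the original assessment, so the
#' NPV is the retained cost saving minus the up-front premium; under the
#' one-year scheme the reassessed allocations fall once the scheme observes
#' the improved health state, clawing the saving back after the payment
#' lag. The investment decision rule is strict: invest iff NPV > 0 (an
#' exactly zero NPV means no investment).
#'
#' @param config A [scheme_config()].
#' @param scenario A list with elements `profile` ([age_cost_profile()]),
#'   `start_age`, `horizon`, `intervention` ([intervention()]) and
#'   optionally `inflation` (default 0.03).
#' @param discount_rate Annual discount rate (default 0: the undiscounted
#'   sums of the scheme-comparison argument).
#' @return NPV in euros (a bare number).
#' @seealso [investment_decision()]
#' @export
intervention_npv <- function(config, scenario, discount_rate = 0) {
  stopifnot(inherits(config, "scheme_config"))
  iv <- scenario$intervention
  if (!inherits(iv, "intervention"))
    stop_contract("`scenario$intervention` must be an intervention object")
  if (!is_number(discount_rate) || discount_rate <= -1)
    stop_contract("`discount_rate` must be a finite rate > -1")
  infl <- if (is.null(scenario$inflation)) 0.03 else scenario$inflation
  H <- scenario$horizon
  base <- baseline_trajectory(scenario$profile, scenario$start_age, H,
                              inflation = infl)
  ivp <- apply_intervention(base, iv)
  disc <- (1 / (1 + discount_rate))^(seq_len(H) - 1L)
  if (config$kind == "long_term") {
    # payments frozen at the pre-intervention assessment either way
    sum(disc * (base$values - ivp$values))
  } else {
    pay_iv <- reassessed_payment_path(base, iv)
    # without intervention payments track baseline costs exactly: surplus 0
    sum(disc * (pay_iv - ivp$values))
  }
}

#' Investment decision rule
#'
#' @inheritParams intervention_npv
#' @return `TRUE` iff the intervention has strictly positive NPV under the
#'   scheme.
#' @export
investment_decision <- function(config, scenario, discount_rate = 0) {
  intervention_npv(config, scenario, discount_rate) > 0
}

#' Selection-incentive diagnostics
#'
#' Whether a longer prediction period increases risk-selection incentives
#' hinges on one question: is the cost-prediction error correlated with
#' information the insurer can observe? These diagnostics take per-enrollee
#' profits (total payment minus total true expected cost) together with an
#' insurer-observable grouping, and report per-group mean profit, its
#' dispersion, and the correlation between the observable signal and the
#' prediction error. Under independent (unobservable) errors the group mean
#' profits converge to a common value as n grows — no group is worth
#' selecting; a correlated error makes the flagged group systematically
#' less profitable.
#'
#' The prediction-error convention is `error = true expected cost -
#' predicted cost`: positive error means the enrollee's costs were
#' under-predicted, so payments fall short and profit is lower.
#'
#' @param data A data.frame with one row per enrollee.
#' @param group Name of the insurer-observable grouping column (>= 2 groups,
#'   >= 2 enrollees per group, no empty groups).
#' @param profit Name of the profit column (euros).
#' @param error Optional name of the prediction-error column; when present,
#'   the signal/error correlation is computed against the group coded as
#'   integers (for two groups this is the point-biserial correlation).
#' @return A `selection_diagnostics` object: list with `group_summary`
#'   (group, n, mean_profit, sd_profit), `overall_mean_profit`,
#'   `max_pairwise_gap` and `signal_error_cor` (NA without an error column).
#' @export
selection_diagnostics <- function(data, group = "group", profit = "profit",
                                  error = NULL) {
  if (!is.data.frame(data)) stop_contract("`data` must be a data.frame")
  for (col in c(group, profit, error))
    if (!col %in% names(data))
      stop_contract(sprintf("column `%s` not found", col))
  g <- factor(data[[group]])
  if (any(tabulate(g) == 0L) || nlevels(g) < 2L)
    stop_contract("need >= 2 non-empty groups")
  if (any(table(g) < 2L))
    stop_contract("every group needs >= 2 enrollees")
  p <- data[[profit]]
  means <- tapply(p, g, mean)
  sds <- tapply(p, g, stats::sd)
  ns <- as.integer(table(g))
  summary_df <- data.frame(
    group = levels(g), n = ns,
    mean_profit = as.numeric(means), sd_profit = as.numeric(sds)
  )
  cor_val <- NA_real_
  if (!is.null(error)) {
    e <- data[[error]]
    # a degenerate (constant) error carries no signal: correlation undefined
    cor_val <- if (stats::sd(e) == 0) NA_real_ else stats::cor(as.numeric(g), e)
  }
  structure(
    list(
      group_summary = summary_df,
      overall_mean_profit = mean(p),
      max_pairwise_gap = max(means) - min(means),
      signal_error_cor = cor_val
    ),
    class = "selection_diagnostics"
  )
}

#' @export
print.selection_diagnostics <- function(x, ...) {
  cat("Selection-incentive diagnostics\n")
  shown <- x$group_summary
  shown$mean_profit <- round_euros(shown$mean_profit)
  shown$sd_profit <- round_euros(shown$sd_profit)
  print.data.frame(shown, row.names = FALSE)
  cat(sprintf("Overall mean profit: %.2f EUR; max pairwise group gap: %.2f EUR\n",
              x$overall_mean_profit, x$max_pairwise_gap))
  if (!is.na(x$signal_error_cor))
    cat(sprintf("Observable signal vs prediction error correlation: %.4f\n",
                x$signal_error_cor))
  invisible(x)
}

#' Simulate a selection experiment under long-horizon prediction error
#'
#' Generates `n` enrollees whose H-year expected costs are predicted with an
#' additive error and pays each the predicted amount, so per-enrollee profit
#' equals minus the prediction error. The error is
#' `group_shift * flag + Normal(0, error_sd)` with `flag ~ Bernoulli(0.5)`
#' observable to the insurer: `group_shift = 0` is the null in which a long
#' prediction period creates no selection incentive; `group_shift > 0`
#' under-predicts the flagged group's costs, making it less profitable.
#'
#' @param n Number of enrollees (>= 4).
#' @param seed Integer seed; the experiment is a pure function of its
#'   arguments.
#' @param horizon Prediction horizon H in years.
#' @param error_sd Standard deviation (euros) of the idiosyncratic error on
#'   the H-year total.
#' @param group_shift Mean error shift (euros) added to the flagged group.
#' @param profile,inflation,age_low,age_high Cost surface and entry-age
#'   range of the simulated enrollees.
#' @return A data.frame with columns `enrollee_id`, `group`, `true_total`,
#'   `predicted_total`, `profit`, `prediction_error`.
#' @export
simulate_selection_experiment <- function(n, seed, horizon = 10L,
                                          error_sd = 500, group_shift = 0,
                                          profile = NULL, inflation = 0.03,
                                          age_low = 20L, age_high = 60L) {
  if (!is_count(n, min = 4L)) stop_contract("`n` must be >= 4")
  if (is.null(profile))
    profile <- generate_profile("log_linear", c0 = 1500, beta = 0.03, a0 = 30)
  set.seed(as.integer(seed))
  ages <- sample(age_low:age_high, n, replace = TRUE)
  flag <- sample(c(0L, 1L), n, replace = TRUE)
  noise <- stats::rnorm(n, 0, error_sd)
  true_total <- vapply(ages, function(a)
    total_amount(baseline_trajectory(profile, a, horizon, inflation)), 0)
  err <- group_shift * flag + noise
  predicted <- true_total - err
  data.frame(
    enrollee_id = seq_len(n),
    group = ifelse(flag == 1L, "flagged", "plain"),
    true_total = true_total,
    predicted_total = predicted,
    profit = predicted - true_total,
    prediction_error = err
  )
}
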