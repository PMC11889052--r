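#' Payment scheme configuration
#'
#' A scheme is either the classical `one_year` risk-adjustment allocation —
#' the insurer receives, each year, the enrollee's reassessed expected cost
#' for the following year — or the `long_term` scheme, in which expected
#' costs are computed once for an H-year horizon and the resulting schedule
#' of annual payments is frozen: later health changes do not alter it.
#'
#' The horizon rule makes H age-dependent to defuse end-of-life incentives,
#' where better health and lower cost can diverge: by default H = 10 up to
#' age 70, H = 5 up to 80, and H = 1 above 80 ("older than" — the thresholds
#' themselves keep the longer horizon). Age is taken at the assessment date,
#' in integer years.
#'
#' @param kind `"long_term"` or `"one_year"`.
#' @param age_breaks Increasing ages above which the horizon shortens
#'   (default `c(70, 80)`).
#' @param horizons Horizons in years, one more than `age_breaks`, each >= 1
#'   and non-increasing (default `c(10, 5, 1)`).
#' @param payment_onset_lag Default payment lag (years) used by the
#'   one-year kind when reassessing after an intervention.
#' @return An object of class `scheme_config`.
#' @export
scheme_config <- function(kind = c("long_term", "one_year"),
                          age_breaks = c(70L, 80L),
                          horizons = c(10L, 5L, 1L),
                          payment_onset_lag = 2L) {
  kind <- match.arg(kind)
  if (length(horizons) != length(age_breaks) + 1L)
    stop_contract("`horizons` must have one more element than `age_breaks`")
  if (any(horizons < 1) || any(horizons != round(horizons)))
    stop_contract("every horizon must be a whole number >= 1")
  if (any(diff(horizons) > 0))
    stop_contract("horizons must be non-increasing in age")
  if (length(age_breaks) && any(diff(age_breaks) <= 0))
    stop_contract("`age_breaks` must be strictly increasing")
  if (!is_count(payment_onset_lag))
    stop_contract("`payment_onset_lag` must be a whole number >= 1")
  structure(
    list(kind = kind, age_breaks = as.integer(age_breaks),
         horizons = as.integer(horizons),
         payment_onset_lag = as.integer(payment_onset_lag)),
    class = "scheme_config"
  )
}

#' Assessment horizon for an age
#'
#' Thresholds are exclusive: an enrollee aged exactly 70 is not "older than
#' 70" and keeps the ten-year horizon.
#'
#' @param config A [scheme_config()].
#' @param age Age at the assessment date (integer years, >= 0).
#' @return Horizon H in years.
#' @examples
#' cfg <- scheme_config("long_term")
#' horizon_for_age(cfg, 70)  # 10
#' horizon_for_age(cfg, 71)  # 5
#' horizon_for_age(cfg, 81)  # 1
#' @export
horizon_for_age <- function(config, age) {
  stopifnot(inherits(config, "scheme_config"))
  if (!is.numeric(age) || any(age < 0))
    stop_contract("`age` must be >= 0")
  idx <- vapply(age, function(a) sum(a > config$age_breaks), 0L) + 1L
  config$horizons[idx]
}

new_payment_stream <- function(payments, kind, provenance, start_year = 1L,
                               details = NULL, settlements = list()) {
  structure(
    list(payments = as.numeric(payments), kind = kind,
         provenance = provenance, start_year = as.integer(start_year),
         details = details, settlements = settlements),
    class = "payment_stream"
  )
}

#' @export
length.payment_stream <- function(x) length(x$payments)

#' @export
print.payment_stream <- function(x, ...) {
  cat(sprintf("Payment stream (%s): %d years, total %s EUR, %d settlement(s)\n",
              x$kind, length(x$payments),
              format(round_euros(sum(x$payments)), big.mark = ","),
              length(x$settlements)))
  invisible(x)
}

#' @export
as.data.frame.payment_stream <- function(x, ...) {
  if (!is.null(x$details)) return(x$details)
  data.frame(
    year = x$start_year + seq_along(x$payments) - 1L,
    payment = x$payments, source = x$provenance
  )
}

#' Annually reassessed expected-payment path after an intervention
#'
#' Under a one-year scheme the allocation tracks the enrollee's reassessed
#' expected cost. After a successful intervention the scheme observes the
#' improved health state only with a delay: payments stay at the baseline
#' expectation until `payment_onset_lag` years after the intervention year
#' and equal `(1 - sigma)` times the baseline expectation from then on. The
#' up-front `kappa` premium never enters the payments — it is borne by the
#' insurer alone.
#'
#' @param baseline A baseline [cost_trajectory()].
#' @param iv An [intervention()].
#' @return Numeric vector of per-year expected payments, same length as
#'   `baseline`.
#' @export
reassessed_payment_path <- function(baseline, iv) {
  stopifnot(inherits(baseline, "cost_trajectory"), inherits(iv, "intervention"))
  H <- length(baseline$values)
  pay <- baseline$values
  from <- iv$year + iv$payment_onset_lag
  if (from <= H) pay[from:H] <- (1 - iv$sigma) * baseline$values[from:H]
  pay
}

#' One-year scheme payments
#'
#' Wraps a path of annually reassessed expected costs into a payment stream:
#' payment in year t is the expected cost for year t given the enrollee's
#' state as the scheme sees it. With no intervention and no shocks the
#' payments equal the baseline costs exactly — the scheme is actuarially
#' fair year by year.
#'
#' @param expected_path The reassessed expected-cost path: a
#'   [cost_trajectory()], the output of [reassessed_payment_path()], or a
#'   numeric vector.
#' @param window Number of years to pay (default: full path length); must
#'   not exceed the path.
#' @return A `payment_stream` of kind `"one_year"`.
#' @export
one_year_payments <- function(expected_path, window = NULL) {
  vals <- stream_values(expected_path)
  if (is.null(window)) window <- length(vals)
  if (!is_count(window)) stop_contract("`window` must be a whole number >= 1")
  if (window > length(vals))
    stop_range(sprintf("window %d exceeds expected path length %d",
                       window, length(vals)))
  start_year <- if (inherits(expected_path, "cost_trajectory"))
    expected_path$start_year else 1L
  yrs <- seq_len(window)
  new_payment_stream(vals[yrs], kind = "one_year",
                     provenance = sprintf("reassessment:%d", yrs),
                     start_year = start_year)
}

#' Long-term assessment
#'
#' At an assessment date, the expected expenditures of the enrollee are
#' computed for the following H years from current characteristics and
#' frozen into a schedule of annual payments. The insurer then receives the
#' initially calculated amount for each year of the horizon regardless of
#' how the enrollee's health develops — the mechanism that lets cost savings
#' from health investments stay with the insurer.
#'
#' @param baseline A [cost_trajectory()] of expected costs covering the
#'   horizon from the assessment year.
#' @param assessment_year Year index at which the assessment is made
#'   (default: first year of `baseline`).
#' @param config A [scheme_config()] supplying the age-dependent horizon
#'   rule.
#' @param horizon Optional explicit horizon overriding the rule.
#' @return An object of class `assessment` with fields `assessment_year`,
#'   `horizon`, `scheduled_payments` (length H, immutable once issued) and
#'   `basis` (enrollee characteristics snapshot).
#' @export
long_term_assessment <- function(baseline, assessment_year = NULL,
                                 config = scheme_config("long_term"),
                                 horizon = NULL) {
  stopifnot(inherits(baseline, "cost_trajectory"))
  if (is.null(assessment_year)) assessment_year <- baseline$start_year
  offset <- assessment_year - baseline$start_year
  if (offset < 0 || offset >= length(baseline))
    stop_range("`assessment_year` outside the trajectory")
  age_at <- baseline$start_age + offset
  H <- if (is.null(horizon)) horizon_for_age(config, age_at) else as.integer(horizon)
  if (!is_count(H)) stop_contract("`horizon` must be a whole number >= 1")
  if (offset + H > length(baseline))
    stop_range(sprintf(
      "horizon %d from year %d exceeds trajectory of length %d",
      H, assessment_year, length(baseline)
    ))
  structure(
    list(
      assessment_year = as.integer(assessment_year),
      horizon = H,
      scheduled_payments = baseline$values[offset + seq_len(H)],
      basis = list(age = age_at, start_age = baseline$start_age)
    ),
    class = "assessment"
  )
}

#' @export
print.assessment <- function(x, ...) {
  cat(sprintf("Assessment at year %d (age %d): H = %d, scheduled total %s EUR\n",
              x$assessment_year, x$basis$age, x$horizon,
              format(round_euros(sum(x$scheduled_payments)), big.mark = ",")))
  invisible(x)
}

#' Settlement when an enrollee switches insurer
#'
#' When an enrollee leaves insurer A during a running long-term horizon, the
#' receiving insurer obtains a fresh assessment and the scheme squares the
#' books with A over the `r` years the enrollee would otherwise have
#' remained: the transfer is the sum of (newly expected minus originally
#' scheduled) costs over those years. Positive transfer flows from the
#' departing insurer to the scheme (expected costs rose — A caused or at
#' least presided over the deterioration and compensates the scheme);
#' negative flows from the scheme to A (costs fell — A keeps the fruits of
#' the health improvement). With unbiased reassessment the switch is in
#' expectation financially neutral for both insurers.
#'
#' @param old An [long_term_assessment()] issued to the departing insurer.
#' @param new_expected_remaining Numeric vector of newly assessed expected
#'   costs for the remaining `r` years of the old horizon (`r = H - years
#'   elapsed`); may have length 0 when the switch falls after the final
#'   horizon year.
#' @param switch_year Year index of the switch; must lie strictly after the
#'   assessment year and within one horizon of it.
#' @return An object of class `settlement_record` with fields `switch_year`,
#'   `remaining_years`, `old_scheduled`, `new_expected` and `transfer`
#'   (euros, positive = departing insurer pays the scheme).
#' @export
switch_settlement <- function(old, new_expected_remaining, switch_year) {
  stopifnot(inherits(old, "assessment"))
  elapsed <- switch_year - old$assessment_year
  if (elapsed < 1L || elapsed > old$horizon)
    stop_contract(sprintf(
      "switch year %d not inside horizon (%d..%d] of the old assessment",
      switch_year, old$assessment_year, old$assessment_year + old$horizon
    ))
  r <- old$horizon - elapsed
  if (length(new_expected_remaining) != r)
    stop_contract(sprintf(
      "`new_expected_remaining` has length %d; %d remaining year(s) expected",
      length(new_expected_remaining), r
    ))
  old_sched <- if (r > 0) old$scheduled_payments[(elapsed + 1L):old$horizon]
  else numeric(0)
  structure(
    list(
      switch_year = as.integer(switch_year),
      remaining_years = as.integer(r),
      old_scheduled = old_sched,
      new_expected = as.numeric(new_expected_remaining),
      transfer = sum(new_expected_remaining - old_sched),
      reason = "switch"
    ),
    class = "settlement_record"
  )
}

#' @export
print.settlement_record <- function(x, ...) {
  dir <- if (x$transfer >= 0) "departing insurer -> scheme"
  else "scheme -> departing insurer"
  cat(sprintf("Settlement at year %d (%s): %d remaining year(s), transfer %s EUR (%s)\n",
              x$switch_year, x$reason, x$remaining_years,
              format(round_euros(x$transfer), big.mark = ","), dir))
  invisible(x)
}

#' Enrollee history for a payment-stream simulation
#'
#' Bundles everything a scheme needs to pay one enrollee over a simulation
#' window: the cost surface, the enrollee's entry age, a fixed latent risk
#' multiplier, the per-year observable morbidity state (multiplicative,
#' mean 1 when unbiased; the value in force at an assessment date is frozen
#' into that assessment), switch years and an optional exit year.
#'
#' @param profile An [age_cost_profile()].
#' @param start_age Age at the start of the window.
#' @param inflation Annual health-cost inflation rate.
#' @param risk_multiplier Fixed latent risk multiplier (> 0).
#' @param state_multipliers Numeric vector of per-year observable morbidity
#'   multipliers (recycled to the window if length 1).
#' @param switch_years Integer years (>= 2) at which the enrollee switches
#'   insurer.
#' @param exit_year Optional year at which the enrollee leaves the system
#'   (death or emigration); payments stop and the remaining schedule is
#'   settled at zero expected cost.
#' @param start_year First year index (default 1).
#' @return An object of class `enrollee_history`.
#' @export
enrollee_history <- function(profile, start_age, inflation = 0.03,
                             risk_multiplier = 1, state_multipliers = 1,
                             switch_years = integer(0), exit_year = NULL,
                             start_year = 1L) {
  stopifnot(inherits(profile, "age_cost_profile"))
  check_inflation(inflation)
  if (!is_number(risk_multiplier) || risk_multiplier <= 0)
    stop_contract("`risk_multiplier` must be finite and > 0")
  if (any(!is.finite(state_multipliers)) || any(state_multipliers < 0))
    stop_contract("`state_multipliers` must be finite and >= 0")
  switch_years <- sort(unique(as.integer(switch_years)))
  if (length(switch_years) && any(switch_years < 2L))
    stop_contract("switches cannot precede year 2")
  structure(
    list(profile = profile, start_age = as.integer(start_age),
         inflation = inflation, risk_multiplier = risk_multiplier,
         state_multipliers = as.numeric(state_multipliers),
         switch_years = switch_years,
         exit_year = if (is.null(exit_year)) NULL else as.integer(exit_year),
         start_year = as.integer(start_year)),
    class = "enrollee_history"
  )
}

#' Simulate the full payment stream for one enrollee
#'
#' Composes the scheme mechanics over a simulation window. Under the
#' one-year kind, every year is a fresh reassessment: the payment equals the
#' expected cost given the enrollee's current observable state. Under the
#' long-term kind, an assessment is issued in year 1 with the age-dependent
#' horizon; its schedule is honoured to completion (even across the 70/80
#' age thresholds — the new horizon rule applies only at the next
#' assessment); at horizon expiry a fresh assessment is issued from
#' then-current characteristics; at a switch, the receiving insurer gets a
#' fresh assessment and a [switch_settlement()] squares the departing
#' insurer's remaining years; at exit, remaining payments are cancelled and
#' the no-fault years settle at zero expected cost (flagged `"exit"`).
#'
#' Every simulated year carries exactly one payment, traceable through the
#' stream's `details` to the assessment (or annual reassessment) that
#' produced it.
#'
#' @param config A [scheme_config()].
#' @param history An [enrollee_history()].
#' @param window Number of years to simulate (>= 1).
#' @return A `payment_stream` whose `details` data.frame has columns
#'   `year`, `payment`, `insurer`, `assessment_id`, `flag`; settlements are
#'   in `$settlements`, each with the paying insurer attached.
#' @export
scheme_payment_stream <- function(config, history, window) {
  stopifnot(inherits(config, "scheme_config"),
            inherits(history, "enrollee_history"))
  if (!is_count(window)) stop_contract("`window` must be a whole number >= 1")
  state <- rep_len(history$state_multipliers, window)
  m <- history$risk_multiplier
  exit <- history$exit_year
  last_covered <- if (is.null(exit)) window else min(window, exit - 1L)

  exp_cost_at <- function(year, state_mult) {
    expected_cost(history$profile, history$start_age, year - 1L,
                  history$inflation) * m * state_mult
  }

  payments <- rep(0, window)
  paid <- rep(FALSE, window)
  insurer <- rep(NA_integer_, window)
  assess_id <- rep(NA_integer_, window)
  flag <- rep("", window)
  provenance <- rep("none", window)
  settlements <- list()
  cur_insurer <- 1L

  mark_paid <- function(yrs) {
    if (any(paid[yrs]))
      stop_consistency("overlapping assessments: a year was paid twice")
    paid[yrs] <<- TRUE
  }

  if (config$kind == "one_year") {
    if (last_covered >= 1L) {
      yrs <- seq_len(last_covered)
      payments[yrs] <- vapply(yrs, function(t) exp_cost_at(t, state[t]), 0)
      mark_paid(yrs)
      insurer[yrs] <- cumsum(c(1L, as.integer(yrs[-1] %in% history$switch_years)))
      assess_id[yrs] <- yrs
      provenance[yrs] <- sprintf("reassessment:%d", yrs)
    }
  } else {
    aid <- 0L
    t <- 1L
    pending_switches <- history$switch_years
    while (t <= last_covered) {
      aid <- aid + 1L
      age_t <- history$start_age + (t - 1L)
      H <- horizon_for_age(config, age_t)
      sched_end <- t + H - 1L
      sched <- vapply(t:sched_end, function(y) exp_cost_at(y, state[t]), 0)
      assessment <- structure(
        list(assessment_year = t, horizon = H, scheduled_payments = sched,
             basis = list(age = age_t, state = state[t])),
        class = "assessment"
      )
      sw <- pending_switches[pending_switches > t &
                               pending_switches <= sched_end &
                               pending_switches <= last_covered]
      sw <- if (length(sw)) sw[1] else NA_integer_
      exiting <- !is.null(exit) && exit <= sched_end &&
        (is.na(sw) || exit <= sw)
      pay_end <- min(sched_end, last_covered,
                     if (!is.na(sw)) sw - 1L else window)
      if (pay_end >= t) {
        yrs <- t:pay_end
        payments[yrs] <- sched[yrs - t + 1L]
        mark_paid(yrs)
        insurer[yrs] <- cur_insurer
        assess_id[yrs] <- aid
        provenance[yrs] <- sprintf("assessment:%d", aid)
      }
      if (exiting) {
        # cancel the rest of the schedule; no-fault years settle at zero
        elapsed <- exit - t
        if (elapsed >= 1L && elapsed <= H) {
          s <- switch_settlement(assessment, numeric(H - elapsed), exit)
          s$reason <- "exit"
          s$payer_insurer <- cur_insurer
          settlements[[length(settlements) + 1L]] <- s
        }
        break
      }
      if (!is.na(sw)) {
        elapsed <- sw - t
        new_exp <- if (H - elapsed > 0)
          vapply(sw:sched_end, function(y) exp_cost_at(y, state[sw]), 0)
        else numeric(0)
        s <- switch_settlement(assessment, new_exp, sw)
        s$payer_insurer <- cur_insurer
        settlements[[length(settlements) + 1L]] <- s
        cur_insurer <- cur_insurer + 1L
        pending_switches <- pending_switches[pending_switches > sw]
        t <- sw
      } else {
        t <- sched_end + 1L
      }
    }
  }

  if (!is.null(exit) && exit <= window) flag[exit:window] <- "exit"

  details <- data.frame(
    year = history$start_year + seq_len(window) - 1L,
    payment = payments, insurer = insurer, assessment_id = assess_id,
    flag = flag, stringsAsFactors = FALSE
  )
  new_payment_stream(payments, kind = config$kind, provenance = provenance,
                     start_year = history$start_year, details = details,
                     settlements = settlements)
}

#' Export a payment stream as CSV
#'
#' Columns: `year`, `payment`, `source_assessment_id`, `insurer`, `flag`.
#'
#' @param stream A `payment_stream` with details (from
#'   [scheme_payment_stream()]) or any payment stream.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_payment_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "payment_stream"))
  df <- as.data.frame(stream)
  names(df)[names(df) == "assessment_id"] <- "source_assessment_id"
  names(df)[names(df) == "source"] <- "source_assessment_id"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
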