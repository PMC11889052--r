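#' Expected cost of an enrollee some years ahead
#'
#' The expected annual healthcare cost of an enrollee aged `age` today,
#' `year_offset` years from now, combines two movements along the cost
#' surface: the enrollee is older (the age-cost gradient of `profile`) and
#' health costs have inflated (`inflation` per year, compounded). Overall
#' price inflation is deliberately ignored so that payments are comparable
#' across time; `inflation` is health-cost inflation in excess of it.
#'
#' @param profile An [age_cost_profile()].
#' @param age Enrollee age today (integer years).
#' @param year_offset Whole years ahead (0 = this year). Must be
#'   integer-valued; `age + year_offset` must stay inside the profile range.
#' @param inflation Annual health-cost inflation rate as a fraction
#'   (default 0.03); must exceed -1.
#' @return Expected annual cost in euros:
#'   `profile_cost(profile, age + year_offset) * (1 + inflation)^year_offset`.
#' @examples
#' p <- generate_profile("log_linear", c0 = 1720, beta = 0, a0 = 40)
#' expected_cost(p, 40, 0)            # 1720
#' expected_cost(p, 40, 1)            # 1720 * 1.03
#' @export
expected_cost <- function(profile, age, year_offset = 0L, inflation = 0.03) {
  check_inflation(inflation)
  if (!is.numeric(year_offset) || any(!is.finite(year_offset)) ||
      any(year_offset != round(year_offset)))
    stop_contract("`year_offset` must be integer-valued")
  profile_cost(profile, age + year_offset) * (1 + inflation)^year_offset
}

check_inflation <- function(inflation) {
  if (!is_number(inflation) || inflation <= -1)
    stop_contract("`inflation` must be a finite rate > -1")
  invisible(inflation)
}

#' Cost trajectory
#'
#' A cost trajectory is the ordered sequence of expected annual expenditures
#' (euros) for one enrollee over a horizon: element `t` is year
#' `start_year + t - 1`. The `label` records whether the path is the
#' untreated `"baseline"` or the post-`"intervention"` path.
#'
#' @param values Numeric vector of non-negative annual expenditures.
#' @param start_age Enrollee age in the first year.
#' @param start_year Index of the first year (default 1).
#' @param label `"baseline"` or `"intervention"`.
#' @return An object of class `cost_trajectory`.
#' @export
cost_trajectory <- function(values, start_age, start_year = 1L,
                            label = c("baseline", "intervention")) {
  label <- match.arg(label)
  if (!is.numeric(values) || length(values) < 1L)
    stop_contract("`values` must be a non-empty numeric vector")
  if (any(!is.finite(values)) || any(values < 0))
    stop_contract("trajectory values must be finite and >= 0")
  structure(
    list(values = as.numeric(values), start_age = as.integer(start_age),
         start_year = as.integer(start_year), label = label),
    class = "cost_trajectory"
  )
}

#' @export
length.cost_trajectory <- function(x) length(x$values)

#' @export
as.data.frame.cost_trajectory <- function(x, ...) {
  data.frame(
    year = x$start_year + seq_along(x$values) - 1L,
    age = x$start_age + seq_along(x$values) - 1L,
    cost = x$values
  )
}

#' @export
print.cost_trajectory <- function(x, ...) {
  cat(sprintf("Cost trajectory (%s): %d years from year %d (age %d), total %s EUR\n",
              x$label, length(x$values), x$start_year, x$start_age,
              format(round_euros(sum(x$values)), big.mark = ",")))
  invisible(x)
}

#' Total of a cost trajectory or payment stream
#'
#' @param x A `cost_trajectory`, `payment_stream`, or numeric vector.
#' @return Sum of annual values in euros (unrounded).
#' @export
total_amount <- function(x) {
  sum(stream_values(x))
}

# Accept trajectories, payment streams, or bare numeric vectors wherever a
# per-year euro sequence is needed.
stream_values <- function(x) {
  if (inherits(x, "cost_trajectory")) return(x$values)
  if (inherits(x, "payment_stream")) return(x$payments)
  if (inherits(x, "assessment")) return(x$scheduled_payments)
  if (is.numeric(x)) return(as.numeric(x))
  stop_contract("expected a cost trajectory, payment stream, or numeric vector")
}

#' Baseline expected-cost trajectory
#'
#' Projects an enrollee's expected annual expenditures over `horizon` years:
#' element `t` is [expected_cost()] at offset `t - 1`, i.e. the cost of an
#' enrollee one year older each year, inflated by the health-cost inflation
#' rate. Under a one-year risk-adjustment scheme with no intervention this
#' path is also, year by year, the allocation the insurer receives.
#'
#' @inheritParams expected_cost
#' @param start_age Enrollee age in the first year.
#' @param horizon Number of years (>= 1).
#' @param start_year Index of the first year (default 1).
#' @return A [cost_trajectory()] labelled `"baseline"`.
#' @export
baseline_trajectory <- function(profile, start_age, horizon,
                                inflation = 0.03, start_year = 1L) {
  if (!is_count(horizon)) stop_contract("`horizon` must be a whole number >= 1")
  rng <- age_range(profile)
  if (start_age < rng[1] || start_age + horizon - 1L > rng[2])
    stop_range(sprintf(
      "ages %d-%d exceed profile range [%d, %d]",
      start_age, start_age + horizon - 1L, rng[1], rng[2]
    ))
  vals <- expected_cost(profile, start_age, seq_len(horizon) - 1L, inflation)
  cost_trajectory(vals, start_age = start_age, start_year = start_year,
                  label = "baseline")
}

#' Health-investment intervention
#'
#' An intervention made in year `year` (the paper-style "year T") costs
#' `kappa` times the originally expected expenditure of that year and saves
#' the fraction `sigma` of the originally expected costs thereafter. Two lags
#' separate cause and consequence: expenditures fall `cost_onset_lag` years
#' after the intervention (default 1: reduced spending from year T+1), while
#' under an annually reassessed scheme the allocations only fall
#' `payment_onset_lag` years after it (default 2: the scheme observes the
#' better health state with a one-year reporting delay).
#'
#' @param year Intervention year T within the horizon (1-based).
#' @param kappa Cost multiplier in the intervention year (>= 0).
#' @param sigma Fraction of originally expected costs saved afterwards,
#'   in `[0, 1]`.
#' @param cost_onset_lag Years after T at which expenditures fall (>= 1).
#' @param payment_onset_lag Years after T at which annually reassessed
#'   payments fall (>= `cost_onset_lag`).
#' @return An object of class `intervention`.
#' @export
intervention <- function(year = 1L, kappa = 2, sigma = 0.3,
                         cost_onset_lag = 1L, payment_onset_lag = 2L) {
  if (!is_count(year)) stop_contract("intervention `year` must be >= 1")
  if (!is_number(kappa) || kappa < 0) stop_contract("`kappa` must be >= 0")
  if (!is_number(sigma) || sigma < 0 || sigma > 1)
    stop_contract("`sigma` must lie in [0, 1]")
  if (!is_count(cost_onset_lag)) stop_contract("`cost_onset_lag` must be >= 1")
  if (!is_count(payment_onset_lag, min = cost_onset_lag))
    stop_contract("`payment_onset_lag` must be >= `cost_onset_lag`")
  structure(
    list(year = as.integer(year), kappa = kappa, sigma = sigma,
         cost_onset_lag = as.integer(cost_onset_lag),
         payment_onset_lag = as.integer(payment_onset_lag)),
    class = "intervention"
  )
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf(
    "Intervention: year T=%d, cost multiplier kappa=%g, savings sigma=%g, lags cost+%d / payment+%d\n",
    x$year, x$kappa, x$sigma, x$cost_onset_lag, x$payment_onset_lag))
  invisible(x)
}

#' Apply an intervention to a baseline trajectory
#'
#' Returns the post-intervention expenditure path: the intervention-year
#' value is multiplied by `kappa`; from `cost_onset_lag` years later onward,
#' each value is `(1 - sigma)` times the *originally expected* (baseline)
#' cost of that year; years strictly between are unchanged. Savings are
#' anchored to the original expectations, not to any later realization —
#' the intervention saves a fraction of what the enrollee was expected to
#' cost.
#'
#' @param baseline A [cost_trajectory()] labelled `"baseline"`.
#' @param iv An [intervention()]; its year must lie within the trajectory.
#' @return A [cost_trajectory()] labelled `"intervention"`.
#' @export
apply_intervention <- function(baseline, iv) {
  stopifnot(inherits(baseline, "cost_trajectory"), inherits(iv, "intervention"))
  if (baseline$label != "baseline")
    stop_contract("`baseline` must be a baseline-labelled trajectory")
  H <- length(baseline$values)
  if (iv$year > H)
    stop_contract(sprintf("intervention year %d outside horizon %d", iv$year, H))
  v <- baseline$values
  v[iv$year] <- iv$kappa * v[iv$year]
  from <- iv$year + iv$cost_onset_lag
  if (from <= H) {
    idx <- from:H
    v[idx] <- (1 - iv$sigma) * baseline$values[idx]
  }
  cost_trajectory(v, start_age = baseline$start_age,
                  start_year = baseline$start_year, label = "intervention")
}

#' Sum of a geometrically growing annuity
#'
#' `annuity_sum(first, g, H)` is `sum(first * (1 + g)^(0:(H-1)))`: the total
#' of `H` annual amounts starting at `first` and growing at constant rate
#' `g`. It is the closed-form companion of [calibrate_growth()].
#'
#' @param first First annual amount (euros).
#' @param g Constant annual growth rate (> -1).
#' @param H Number of years (>= 1).
#' @return Total over the `H` years.
#' @export
annuity_sum <- function(first, g, H) {
  if (!is_count(H)) stop_contract("`H` must be a whole number >= 1")
  if (!is_number(g) || g <= -1) stop_contract("`g` must be a finite rate > -1")
  sum(first * (1 + g)^(seq_len(H) - 1L))
}

#' Calibrate a constant growth rate to a horizon total
#'
#' Finds the constant effective annual growth rate `g` such that `H` annual
#' amounts starting at `first_cost` and growing at `g` sum to
#' `horizon_total`. This reconstructs a cost path consistent with a printed
#' period total when the underlying age-cost table is not available: the
#' recovered `g` bundles the age gradient and health-cost inflation into one
#' effective rate.
#'
#' Solved by bracketed root finding ([stats::uniroot()]) on
#' `annuity_sum(first_cost, g, H) - horizon_total` over `g` in (-0.99, 10);
#' the result satisfies the annuity identity to within 1e-8 relative.
#'
#' @param first_cost First-year cost (euros, > 0).
#' @param horizon_total Target total over the horizon (euros, > 0).
#' @param H Horizon in years (>= 2).
#' @return The growth rate `g` (may be negative).
#' @examples
#' calibrate_growth(100, 300, 2)   # 1, since 100 + 100 * (1 + 1) = 300
#' @export
calibrate_growth <- function(first_cost, horizon_total, H) {
  if (!is_count(H, min = 2L)) stop_contract("`H` must be a whole number >= 2")
  if (!is_number(first_cost) || first_cost <= 0)
    stop_contract("`first_cost` must be > 0")
  if (!is_number(horizon_total) || horizon_total <= 0)
    stop_contract("`horizon_total` must be > 0")
  f <- function(g) annuity_sum(first_cost, g, H) - horizon_total
  lo <- -0.99
  hi <- 10
  if (f(lo) * f(hi) > 0)
    stop_convergence(sprintf(
      "no growth rate in (-0.99, 10) yields total %g from first cost %g over %d years",
      horizon_total, first_cost, H
    ))
  g <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(annuity_sum(first_cost, g, H) - horizon_total) >
      1e-8 * abs(horizon_total))
    stop_convergence("growth calibration did not reach 1e-8 relative tolerance")
  g
}

#' Reconcile a trajectory to a known period total
#'
#' Rescales the values of `traj` from `from_year` (trajectory-relative,
#' 1-based) onward by a common factor so that the trajectory total equals
#' `total`. Used to reconcile a parametric post-intervention path with a
#' period total that is known (e.g. reported for an empirical age-cost curve
#' that is not itself available) while keeping the path's shape and its
#' pre-onset years untouched.
#'
#' @param traj A [cost_trajectory()].
#' @param total Target total in euros.
#' @param from_year First trajectory year (1-based) allowed to move.
#' @return The rescaled [cost_trajectory()], with attribute
#'   `anchored_total = total`.
#' @export
anchor_trajectory_total <- function(traj, total, from_year = 2L) {
  stopifnot(inherits(traj, "cost_trajectory"))
  H <- length(traj$values)
  if (!is_count(from_year) || from_year > H)
    stop_contract("`from_year` must lie within the trajectory")
  fixed <- if (from_year > 1L) sum(traj$values[seq_len(from_year - 1L)]) else 0
  free <- sum(traj$values[from_year:H])
  if (free <= 0) stop_contract("no positive mass to rescale from `from_year`")
  lambda <- (total - fixed) / free
  if (lambda < 0)
    stop_contract("target total smaller than the fixed pre-onset years")
  v <- traj$values
  v[from_year:H] <- lambda * v[from_year:H]
  out <- cost_trajectory(v, start_age = traj$start_age,
                         start_year = traj$start_year, label = traj$label)
  attr(out, "anchored_total") <- total
  out
}

#' Write baseline and intervention trajectories as tidy CSV
#'
#' Columns: `year`, `baseline_cost`, and (if given) `intervention_cost`.
#'
#' @param baseline A baseline [cost_trajectory()].
#' @param path Output CSV path.
#' @param intervention_path Optional post-intervention [cost_trajectory()]
#'   of the same length.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(baseline, path, intervention_path = NULL) {
  stopifnot(inherits(baseline, "cost_trajectory"))
  df <- data.frame(
    year = baseline$start_year + seq_along(baseline$values) - 1L,
    baseline_cost = baseline$values
  )
  if (!is.null(intervention_path)) {
    if (length(intervention_path) != length(baseline))
      stop_contract("trajectories must have equal length")
    df$intervention_cost <- stream_values(intervention_path)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Round euros for reporting
#'
#' Monetary values are kept at full floating precision internally and
#' rounded to whole euros only in reports, using round-half-away-from-zero
#' (so 0.5 becomes 1 and -0.5 becomes -1, the convention of printed
#' financial tables).
#'
#' @param x Numeric vector of euro amounts.
#' @return Integer-valued numeric vector.
#' @export
round_euros <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
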