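#' Age-cost profile
#'
#' An age-cost profile maps integer age to the expected annual healthcare
#' cost (in euros) of an average enrollee of that age in a base year. It is
#' the risk-adjuster table that every payment scheme in this package starts
#' from: allocations are expected costs read off this profile, inflated
#' forward in time with [expected_cost()].
#'
#' Lookups outside the profile's age range are an error, never a silent
#' extrapolation: a simulation that would age an enrollee past the table
#' stops instead of inventing costs.
#'
#' @param costs Numeric vector of expected annual costs (euros), one per age.
#'   All values must be finite and non-negative.
#' @param ages Integer vector of ages the costs belong to; must be contiguous
#'   and increasing. Defaults to `0:(length(costs) - 1)`.
#' @param base_year Calendar year the costs refer to (default 2021).
#'
#' @return An object of class `age_cost_profile` with fields `base_year`,
#'   `ages` and `costs`.
#' @seealso [generate_profile()], [profile_cost()], [read_profile_csv()]
#' @examples
#' p <- age_cost_profile(c(1500, 1600, 1720), ages = 38:40)
#' profile_cost(p, 40)
#' @export
age_cost_profile <- function(costs, ages = seq_along(costs) - 1L,
                             base_year = 2021L) {
  if (!is.numeric(costs) || length(costs) < 1L)
    stop_contract("`costs` must be a non-empty numeric vector")
  if (any(!is.finite(costs)) || any(costs < 0))
    stop_contract("all profile costs must be finite and >= 0")
  if (!is.numeric(ages) || length(ages) != length(costs))
    stop_contract("`ages` must be numeric and match `costs` in length")
  ages <- as.integer(ages)
  if (length(ages) > 1L && any(diff(ages) != 1L))
    stop_contract("`ages` must be contiguous increasing integers")
  structure(
    list(base_year = as.integer(base_year), ages = ages,
         costs = as.numeric(costs)),
    class = "age_cost_profile"
  )
}

#' @export
print.age_cost_profile <- function(x, ...) {
  cat(sprintf(
    "Age-cost profile (base year %d): ages %d-%d, cost %s-%s EUR\n",
    x$base_year, min(x$ages), max(x$ages),
    format(round(min(x$costs))), format(round(max(x$costs)))
  ))
  invisible(x)
}

#' Valid age range of a profile
#'
#' @param profile An [age_cost_profile()].
#' @return Integer vector `c(min_age, max_age)`.
#' @export
age_range <- function(profile) {
  stopifnot(inherits(profile, "age_cost_profile"))
  range(profile$ages)
}

#' Look up the base-year expected cost at an age
#'
#' @param profile An [age_cost_profile()].
#' @param age Integer age(s); every age must lie inside the profile's range.
#' @return Expected annual cost(s) in euros.
#' @export
profile_cost <- function(profile, age) {
  stopifnot(inherits(profile, "age_cost_profile"))
  if (!is.numeric(age) || any(!is.finite(age)) || any(age != round(age)))
    stop_contract("`age` must be integer-valued")
  idx <- match(as.integer(age), profile$ages)
  if (anyNA(idx))
    stop_range(sprintf(
      "age %s outside profile range [%d, %d]; no extrapolation",
      paste(age[is.na(idx)], collapse = ", "),
      min(profile$ages), max(profile$ages)
    ))
  profile$costs[idx]
}

#' Generate a parametric age-cost profile
#'
#' `log_linear` builds `cost(a) = c0 * exp(beta * (a - a0))`, a monotone
#' age-cost gradient anchored at cost `c0` for age `a0`. `table` wraps an
#' explicit `data.frame(age, cost)`.
#'
#' @param shape `"log_linear"` or `"table"`.
#' @param c0 Anchor cost in euros (log-linear shape); must be positive.
#' @param beta Log-slope per year of age (log-linear shape). `beta = 0` gives
#'   a flat profile.
#' @param a0 Anchor age (log-linear shape).
#' @param age_range Integer `c(min_age, max_age)` covered by the profile.
#' @param table `data.frame` with columns `age` and `cost` (table shape).
#' @param base_year Calendar base year of the costs.
#' @return An [age_cost_profile()].
#' @examples
#' generate_profile("log_linear", c0 = 1720, beta = log(1.034), a0 = 40)
#' @export
generate_profile <- function(shape = c("log_linear", "table"), c0 = NULL,
                             beta = 0, a0 = 0L, age_range = c(0L, 100L),
                             table = NULL, base_year = 2021L) {
  shape <- match.arg(shape)
  if (shape == "log_linear") {
    if (!is_number(c0) || c0 <= 0)
      stop_contract("log-linear profile needs a positive anchor cost `c0`")
    if (!is_number(beta)) stop_contract("`beta` must be a finite number")
    ages <- seq.int(age_range[1], age_range[2])
    age_cost_profile(c0 * exp(beta * (ages - a0)), ages = ages,
                     base_year = base_year)
  } else {
    if (!is.data.frame(table) || !all(c("age", "cost") %in% names(table)))
      stop_contract("table profile needs a data.frame with `age` and `cost`")
    ord <- order(table$age)
    age_cost_profile(table$cost[ord], ages = table$age[ord],
                     base_year = base_year)
  }
}

#' Read / write an age-cost profile as CSV
#'
#' The on-disk format is a two-column CSV `age,cost` with a header row;
#' writing a profile that was read back produces a byte-identical file.
#'
#' @param path Path to the CSV file.
#' @param base_year Calendar base year to attach on read.
#' @return `read_profile_csv()` returns an [age_cost_profile()];
#'   `write_profile_csv()` returns `path` invisibly.
#' @export
read_profile_csv <- function(path, base_year = 2021L) {
  df <- utils::read.csv(path)
  if (!all(c("age", "cost") %in% names(df)))
    stop_config(sprintf("profile CSV %s must have columns age,cost", path))
  generate_profile("table", table = df, base_year = base_year)
}

#' @rdname read_profile_csv
#' @param profile An [age_cost_profile()] to write.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "age_cost_profile"))
  utils::write.csv(
    data.frame(age = profile$ages, cost = profile$costs),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
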