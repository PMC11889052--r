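#' Deterministic per-enrollee random substream seed
#'
#' Derives an enrollee-level seed from the master seed and the enrollee id,
#' so that enrollee i is identical whether the population has 100 or
#' 100,000 members — growing a population extends it without reshuffling.
#'
#' @param master Master seed (integer).
#' @param id Enrollee id (positive integer).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
enrollee_seed <- function(master, id) {
  as.integer((as.numeric(master) %% 2147483647 * 7919 + id * 104729) %%
               2147483647)
}

#' Generate a synthetic enrollee population
#'
#' Draws `n` enrollees with entry ages, fixed latent risk multipliers,
#' per-year multiplicative morbidity shocks, an insurer-observable group
#' label, and plan-switching times. Generation is a pure function of
#' `(parameters, seed)`, with one deterministic substream per enrollee.
#'
#' Shocks and risk multipliers are lognormal with mean exactly 1
#' (`meanlog = -sdlog^2 / 2`): positivity plus unbiasedness, which the
#' settlement-neutrality property of the long-term scheme relies on. Switch
#' times are geometric: from year 2 on, each year the enrollee switches
#' insurer with probability `switch_rate`; only the first switch inside the
#' window is recorded.
#'
#' @param n Population size (>= 1).
#' @param seed Master seed (integer).
#' @param shock_sd Log-scale SD of the per-year morbidity shocks (>= 0).
#' @param switch_rate Per-year switching probability in `[0, 1]`.
#' @param window Simulation window in years.
#' @param age_low,age_high Entry-age range (inclusive).
#' @param risk_sd Log-scale SD of the fixed latent risk multiplier (>= 0).
#' @return An `enrollee_population`: list with `enrollees` (data.frame:
#'   `id`, `entry_age`, `risk_multiplier`, `group`, `switch_year` (NA if
#'   none), `exit_year` (NA)), `shocks` (n x window matrix), `params`,
#'   `seed`.
#' @export
generate_population <- function(n, seed, shock_sd = 0.2, switch_rate = 0.05,
                                window = 10L, age_low = 20L, age_high = 60L,
                                risk_sd = 0.3) {
  if (!is_count(n)) stop_contract("`n` must be a whole number >= 1")
  if (!is_number(switch_rate) || switch_rate < 0 || switch_rate > 1)
    stop_contract("`switch_rate` must lie in [0, 1]")
  if (!is_number(shock_sd) || shock_sd < 0)
    stop_contract("`shock_sd` must be >= 0")
  if (!is_number(risk_sd) || risk_sd < 0)
    stop_contract("`risk_sd` must be >= 0")
  if (!is_count(window)) stop_contract("`window` must be >= 1")

  entry_age <- integer(n)
  riskm <- numeric(n)
  group <- character(n)
  switch_year <- rep(NA_integer_, n)
  shocks <- matrix(1, n, window)
  for (i in seq_len(n)) {
    set.seed(enrollee_seed(seed, i))
    entry_age[i] <- sample(age_low:age_high, 1L)
    riskm[i] <- stats::rlnorm(1, meanlog = -risk_sd^2 / 2, sdlog = risk_sd)
    group[i] <- sample(c("A", "B"), 1L)
    if (shock_sd > 0)
      shocks[i, ] <- stats::rlnorm(window, meanlog = -shock_sd^2 / 2,
                                   sdlog = shock_sd)
    if (switch_rate > 0) {
      sw <- 2L + stats::rgeom(1L, switch_rate)
      if (sw <= window) switch_year[i] <- sw
    }
  }
  structure(
    list(
      enrollees = data.frame(
        id = seq_len(n), entry_age = entry_age, risk_multiplier = riskm,
        group = group, switch_year = switch_year,
        exit_year = rep(NA_integer_, n), stringsAsFactors = FALSE
      ),
      shocks = shocks,
      params = list(n = n, shock_sd = shock_sd, switch_rate = switch_rate,
                    window = window, age_low = age_low, age_high = age_high,
                    risk_sd = risk_sd),
      seed = as.integer(seed)
    ),
    class = "enrollee_population"
  )
}

#' @export
print.enrollee_population <- function(x, ...) {
  cat(sprintf(
    "Synthetic population: %d enrollees, ages %d-%d, window %d y, switch rate %g, seed %d\n",
    x$params$n, x$params$age_low, x$params$age_high, x$params$window,
    x$params$switch_rate, x$seed))
  invisible(x)
}

#' History of one population member
#'
#' Builds the [enrollee_history()] of enrollee `i` over the population's
#' window, on the given cost surface.
#'
#' @param pop An `enrollee_population`.
#' @param i Enrollee id.
#' @param profile An [age_cost_profile()].
#' @param inflation Annual health-cost inflation rate.
#' @return An [enrollee_history()].
#' @export
population_history <- function(pop, i, profile, inflation = 0.03) {
  stopifnot(inherits(pop, "enrollee_population"))
  e <- pop$enrollees[i, ]
  enrollee_history(
    profile, start_age = e$entry_age, inflation = inflation,
    risk_multiplier = e$risk_multiplier,
    state_multipliers = pop$shocks[i, ],
    switch_years = if (is.na(e$switch_year)) integer(0) else e$switch_year,
    exit_year = if (is.na(e$exit_year)) NULL else e$exit_year
  )
}
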