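# Small scenario builders shared across the suite; everything is generated
# in code, nothing is read from disk.

flat_profile <- function(cost, age_range = c(0L, 100L)) {
  generate_profile("log_linear", c0 = cost, beta = 0, a0 = 0L,
                   age_range = age_range)
}

# independent oracle: plain arithmetic sum of a growing annuity
oracle_annuity_sum <- function(first, g, H) {
  total <- 0
  x <- first
  for (t in seq_len(H)) {
    total <- total + x
    x <- x * (1 + g)
  }
  total
}

# independent oracle: bisection on the annuity sum, no shared code path
oracle_growth_bisect <- function(first, total, H, lo = -0.9, hi = 5,
                                 iters = 200) {
  f <- function(g) oracle_annuity_sum(first, g, H) - total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

random_scenario <- function() {
  c0 <- stats::runif(1, 500, 3000)
  beta <- stats::runif(1, 0, 0.05)
  list(
    profile = generate_profile("log_linear", c0 = c0, beta = beta, a0 = 20L),
    inflation = stats::runif(1, 0, 0.06),
    start_age = sample(20:60, 1),
    horizon = sample(2:12, 1)
  )
}
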