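# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Brute-force Efron log partial likelihood by explicit risk-set
# enumeration, straight from the definition.
efron_brute <- function(time, event, eta) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    s <- sum(exp(eta[D]))
    rs <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D]) -
      sum(vapply(0:(d - 1), function(l) log(rs - l / d * s), numeric(1)))
  }
  ll
}

# Grid-search least-squares normal fit to three quantiles: 4 rounds of
# 41x41 refinement gives ~1e-4 resolution on (mean, sd).
grid_fit_oracle <- function(q025, q50, q975) {
  q <- c(q025, q50, q975)
  targets <- c(0.025, 0.5, 0.975)
  obj <- function(m, s) sum((pnorm(q, m, s) - targets)^2)
  s0 <- (q975 - q025) / 3.92
  m_range <- c(q50 - 2, q50 + 2)
  s_range <- c(max(s0 / 5, 1e-4), s0 * 5)
  best <- c(q50, s0)
  for (round in 1:4) {
    ms <- seq(m_range[1], m_range[2], length.out = 41)
    ss <- seq(s_range[1], s_range[2], length.out = 41)
    vals <- outer(ms, ss, Vectorize(obj))
    idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(ms[idx[1]], ss[idx[2]])
    dm <- diff(m_range) / 40
    ds <- diff(s_range) / 40
    m_range <- best[1] + c(-2, 2) * dm
    s_range <- pmax(best[2] + c(-2, 2) * ds, 1e-5)
  }
  list(mean = best[1], sd = best[2])
}

# Minimal valid trial table with custom survival columns; subgroup and
# covariates default to inert values.
tiny_trial <- function(time, event, arm, subgroup = NULL) {
  n <- length(time)
  if (is.null(subgroup)) subgroup <- rep(0L, n)
  df <- data.frame(id = seq_len(n), arm = arm, subgroup = subgroup,
                   age_gt70 = 0L, female = 0L, creat_gt160 = 0L,
                   ef_lt50 = 0L, angio_5d = 0L,
                   time_days = time, event = event)
  trial_table(df)
}

# Random valid elicited inputs for property tests.
random_inputs <- function() {
  s1 <- runif(1, 0.05, 0.6)
  s20 <- runif(1, 0.05, 0.6)
  s2d <- runif(1, 0.05, 0.6)
  d <- runif(1, 0.1, 0.6)
  elicited_prior_inputs(
    theta1 = loghr_distribution(runif(1, -0.5, 0.5), s1),
    theta2 = loghr_distribution(runif(1, -0.5, 0.5), runif(1, 0.05, 0.6)),
    theta2_given_null = loghr_distribution(runif(1, -0.5, 0.5), s20),
    theta2_given_benefit = loghr_distribution(runif(1, -0.5, 0.5), s2d),
    d = d)
}
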