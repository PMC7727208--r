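make_draws <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "theta1"))

test_that("posterior summaries follow their definitions", {
  s <- summarise_posterior(make_draws(abs(rnorm(2000)) + 0.01), "theta1")
  expect_identical(s$p_hr_gt1, 1)
  sym <- rep(c(-1, 1), 600) * rep(seq(0.1, 6, length.out = 600), each = 2)
  s2 <- summarise_posterior(make_draws(sym), "theta1")
  expect_equal(s2$median_hr, 1, tolerance = 1e-12)
  expect_equal(s2$p_hr_gt1, 0.5)
  set.seed(8)
  s3 <- summarise_posterior(make_draws(rnorm(1e5)), "theta1")
  expect_equal(s3$ci_lower, exp(-1.959964), tolerance = 0.02)
  expect_equal(s3$ci_upper, exp(1.959964), tolerance = 0.02)
  expect_error(summarise_posterior(make_draws(rnorm(999)), "theta1"),
               "at least 1000")
  expect_error(summarise_posterior(make_draws(rnorm(2000)), "theta9"),
               "no column")
})

test_that("a near-degenerate informative prior dominates weak data", {
  tt <- generate_trial(simulation_config(n = 60, seed = 31,
                                         n_missing_subgroup = 0))
  prior <- bivariate_prior("clinical", c(0.3, -0.2), diag(1e-6, 2))
  post <- suppressMessages(
    fit_bayes(tt, model_spec(prior), mcmc_settings(chains = 2, iter = 1500,
                                                   seed = 4)))
  expect_equal(log(post$summary$median_hr[1]), 0.3, tolerance = 0.01)
  expect_equal(log(post$summary$median_hr[2]), -0.2, tolerance = 0.01)
})

test_that("exponential data with one covariate matches the conjugate approximation", {
  set.seed(14)
  n <- 300
  arm <- rbinom(n, 1, 0.5)
  beta_true <- 0.4
  time <- rexp(n, rate = 0.15 * exp(beta_true * arm))
  tt <- tiny_trial(time = time, event = rep(1, n), arm = arm)
  spec_free <- model_spec(build_vague_prior(), covariates = character(0),
                          subgroup_main = FALSE)
  mle <- suppressMessages(fit_mle(tt, spec_free))
  info <- 1 / mle$vcov[1, 1]
  m0 <- 0.2; s0 <- 0.25
  prior <- bivariate_prior("clinical", c(m0, 0), diag(c(s0^2, 1e4)))
  post <- suppressMessages(
    fit_bayes(tt, model_spec(prior, covariates = character(0),
                             subgroup_main = FALSE),
              mcmc_settings(seed = 9)))
  conj_prec <- 1 / s0^2 + info
  conj_mean <- (m0 / s0^2 + mle$coefficients[1] * info) / conj_prec
  draws <- post$draws[, "theta1"]
  # 5% agreement with the normal-normal conjugate approximation
  expect_equal(mean(draws), unname(conj_mean), tolerance = 0.05)
  expect_equal(var(draws), 1 / conj_prec, tolerance = 0.05)
})

test_that("sampling is reproducible bit-for-bit given the seed", {
  tt <- generate_trial(simulation_config(n = 80, seed = 12,
                                         n_missing_subgroup = 0))
  prior <- bivariate_prior("sceptical", c(0, 0), diag(0.25, 2))
  run <- function() suppressMessages(
    fit_bayes(tt, model_spec(prior), mcmc_settings(chains = 2, iter = 1200,
                                                   seed = 77)))
  a <- run(); b <- run()
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  c2 <- suppressMessages(
    fit_bayes(tt, model_spec(prior), mcmc_settings(chains = 2, iter = 1200,
                                                   seed = 78)))
  expect_false(identical(a$draws, c2$draws))
})

test_that("single-subgroup data fall back to the marginal prior", {
  set.seed(15)
  n <- 120
  arm <- rbinom(n, 1, 0.5)
  time <- ceiling(rexp(n, 0.1 * exp(0.2 * arm)))
  tt <- tiny_trial(time = time, event = rep(1, n), arm = arm,
                   subgroup = rep(1L, n))
  prior <- bivariate_prior("clinical", c(0.1, 0.2),
                           matrix(c(0.04, 0.01, 0.01, 0.09), 2))
  post <- suppressMessages(
    fit_bayes(tt, model_spec(prior, covariates = character(0),
                             subgroup_main = FALSE),
              mcmc_settings(chains = 2, iter = 1500, seed = 3)))
  expect_identical(post$summary$parameter, "theta2")
  expect_true(all(post$summary$rhat < 1.01))
})

test_that("the shrinkage report flags direction and precision gain", {
  tt <- generate_trial(simulation_config(n = 300, theta1 = 0.2, theta2 = 0.2,
                                         seed = 44, n_missing_subgroup = 0))
  vague <- build_vague_prior()
  mle <- suppressMessages(fit_mle(tt, model_spec(vague)))
  post_v <- suppressMessages(fit_bayes(tt, model_spec(vague),
                                       mcmc_settings(seed = 6)))
  rep_v <- shrinkage_report(vague, mle, post_v)
  expect_equal(rep_v$width_ratio, c(1, 1), tolerance = 0.1)
  expect_equal(rep_v$posterior_median, rep_v$mle, tolerance = 0.05)
  informative <- bivariate_prior("clinical", c(0, 0), diag(0.04, 2))
  post_i <- suppressMessages(fit_bayes(tt, model_spec(informative),
                                       mcmc_settings(seed = 6)))
  rep_i <- shrinkage_report(informative, mle, post_i)
  expect_true(all(rep_i$width_ratio < 1))
  expect_true(all(rep_i$between))
})
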