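test_that("probability pairs map to log hazard ratios as the transform dictates", {
  expect_identical(prob_pair_to_loghr(0.5, 0.5), 0)
  # the two hypothesised-benefit anchors, high-precision formula values
  expect_equal(prob_pair_to_loghr(0.70, 0.60), 0.27304833, tolerance = 1e-7)
  expect_equal(prob_pair_to_loghr(0.65, 0.50), 0.41513367, tolerance = 1e-7)
  expect_equal(hypothesised_benefit("renal_risk"), 0.27304833, tolerance = 1e-7)
  expect_equal(hypothesised_benefit("glucose_management"), 0.41513367,
               tolerance = 1e-7)
  expect_error(prob_pair_to_loghr(0, 0.5), "p_treat.*0")
  expect_error(prob_pair_to_loghr(0.5, 1), "p_control.*1")
})

test_that("the transform is antisymmetric, monotone, and inverted by loghr_to_prob", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 0.01, 0.99); b <- runif(1, 0.01, 0.99)
    expect_equal(prob_pair_to_loghr(a, b), -prob_pair_to_loghr(b, a),
                 tolerance = 1e-12)
    expect_equal(loghr_to_prob(prob_pair_to_loghr(a, b), b), a,
                 tolerance = 1e-12)
  }
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(prob_pair_to_loghr(p, 0.6)) > 0))
  expect_gt(prob_pair_to_loghr(0.7, 0.6), 0)
  expect_lt(prob_pair_to_loghr(0.5, 0.6), 0)
})

test_that("quantile fitting recovers exact normal quantiles and beats no grid point", {
  fit <- fit_normal_from_quantiles(-1.959964, 0, 1.959964)
  expect_equal(fit$mean, 0, tolerance = 1e-6)
  expect_equal(fit$sd, 1, tolerance = 1e-6)
  fit2 <- fit_normal_from_quantiles(2.16, 10, 17.84)
  expect_equal(fit2$mean, 10, tolerance = 1e-3)
  expect_equal(fit2$sd, 4, tolerance = 1e-3)
  # fitted CDF reproduces the targets when inputs are exact quantiles
  q <- qnorm(c(0.025, 0.5, 0.975), -0.3, 0.7)
  fit3 <- fit_normal_from_quantiles(q[1], q[2], q[3])
  expect_equal(pnorm(q, fit3$mean, fit3$sd), c(0.025, 0.5, 0.975),
               tolerance = 1e-6)
  expect_error(fit_normal_from_quantiles(1, 1, 2), "strictly increasing")
})

test_that("asymmetric triples match the grid-search oracle", {
  cases <- list(c(-0.5, 0, 2.0), c(-1, -0.2, 0.5), c(0.1, 0.9, 1.4))
  for (q in cases) {
    fit <- fit_normal_from_quantiles(q[1], q[2], q[3])
    oracle <- grid_fit_oracle(q[1], q[2], q[3])
    expect_lt(abs(fit$mean - oracle$mean), 1e-3)
    expect_lt(abs(fit$sd - oracle$sd), 1e-3)
  }
})

test_that("expert answers convert to log-HR distributions", {
  # median count equal to the comparator puts the median log-HR at 0
  d <- answer_to_loghr_distribution(
    list(q025 = 50, q50 = 60, q975 = 70, usual_care_ref = 60))
  expect_equal(d$mean, 0, tolerance = 0.02)
  # generic answer agrees with the manual transform + grid oracle
  ans <- list(q025 = 55, q50 = 65, q975 = 75, usual_care_ref = 50)
  d2 <- answer_to_loghr_distribution(ans)
  q <- prob_pair_to_loghr(c(55, 65, 75) / 100, 0.5)
  oracle <- grid_fit_oracle(q[1], q[2], q[3])
  expect_lt(abs(d2$mean - oracle$mean), 1e-3)
  expect_lt(abs(d2$sd - oracle$sd), 1e-3)
  expect_error(answer_to_loghr_distribution(
    list(q025 = 60, q50 = 60, q975 = 60, usual_care_ref = 60)),
    "strictly increasing|widen")
  expect_warning(answer_to_loghr_distribution(
    list(q025 = 50, q50 = 70, q975 = 100, usual_care_ref = 60)),
    "clamped")
})

test_that("linear opinion pooling matches closed-form and Monte-Carlo moments", {
  one <- pool_experts(list(loghr_distribution(0.2, 0.1)))
  expect_equal(one$mean, 0.2)
  expect_equal(one$sd, 0.1)
  two <- pool_experts(list(loghr_distribution(0, 1), loghr_distribution(2, 1)))
  expect_equal(two$mean, 1)
  expect_equal(two$sd^2, 2)
  # identical components are a fixed point, any weights
  same <- replicate(4, loghr_distribution(-0.3, 0.4), simplify = FALSE)
  pooled <- pool_experts(same, weights = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(pooled$mean, -0.3)
  expect_equal(pooled$sd, 0.4)
  # Monte-Carlo oracle for the seven-expert fixture mixture
  ans <- generate_expert_answers(elicitation_fixture_config())
  dists <- lapply(split(ans, ans$expert_id), function(rows)
    answer_to_loghr_distribution(rows[rows$question == "uncond_more_severe", ]))
  pooled7 <- pool_experts(dists)
  set.seed(42)
  comp <- sample(length(dists), 1e6, replace = TRUE)
  m <- vapply(dists, `[[`, numeric(1), "mean")[comp]
  s <- vapply(dists, `[[`, numeric(1), "sd")[comp]
  draws <- rnorm(1e6, m, s)
  expect_equal(pooled7$mean, mean(draws), tolerance = 0.01)
  expect_equal(pooled7$sd, sd(draws), tolerance = 0.01)
  expect_error(pool_experts(list()), "at least one")
  expect_error(pool_experts(same, weights = c(1, 1, 1, 1)), "sum to 1")
})

test_that("pooled variance dominates the weighted mean of component variances", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    dists <- lapply(seq_len(k), function(j)
      loghr_distribution(runif(1, -1, 1), runif(1, 0.05, 1)))
    w <- runif(k); w <- w / sum(w)
    pooled <- pool_experts(dists, w)
    vbar <- sum(w * vapply(dists, function(d) d$sd^2, numeric(1)))
    expect_gte(pooled$sd^2, vbar - 1e-12)
  }
})

test_that("the answers CSV round-trips and is validated", {
  ans <- generate_expert_answers(elicitation_fixture_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_expert_answers(ans, path)
  back <- read_expert_answers(path)
  expect_equal(back, ans, ignore_attr = TRUE)
  bad <- as.data.frame(ans)
  bad$q50[1] <- bad$q975[1] + 5
  expect_error(read_expert_answers(bad), "q025 <= q50 <= q975")
  bad2 <- as.data.frame(ans)
  bad2$question[1] <- "mystery"
  expect_error(read_expert_answers(bad2), "unknown question")
})
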