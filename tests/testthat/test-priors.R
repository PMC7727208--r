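fixture_inputs <- function() {
  elicited_prior_inputs(
    theta1 = loghr_distribution(0.10, 0.2),
    theta2 = loghr_distribution(0.18, 0.25),
    theta2_given_null = loghr_distribution(0.10, 0.1),
    theta2_given_benefit = loghr_distribution(0.20, sqrt(0.03)),
    d = 0.25)
}

test_that("the regression coefficient is the conditional-mean slope", {
  inp <- fixture_inputs()
  expect_equal(derive_regression_coefficient(inp), (0.20 - 0.10) / 0.25)
  inp0 <- fixture_inputs()
  inp0$theta2_given_benefit$mean <- inp0$theta2_given_null$mean
  expect_equal(derive_regression_coefficient(inp0), 0)
  expect_error(elicited_prior_inputs(inp$theta1, inp$theta2,
                                     inp$theta2_given_null,
                                     inp$theta2_given_benefit, d = -1),
               "positive")
})

test_that("the clinical prior reproduces the plug-in covariance arithmetic", {
  prior <- build_clinical_prior(fixture_inputs())
  expect_equal(prior$m, c(0.10, 0.18))
  expect_equal(prior$V, matrix(c(0.04, 0.016, 0.016, 0.0264), 2, 2),
               tolerance = 1e-12)
  # independence case: b12 = 0 gives a diagonal V
  inp0 <- fixture_inputs()
  inp0$theta2_given_benefit <- loghr_distribution(0.10, sqrt(0.03))
  p0 <- build_clinical_prior(inp0)
  expect_equal(p0$V[1, 2], 0)
  expect_equal(p0$V[2, 2], (0.1^2 + 0.03) / 2)
  # regression-mean sensitivity
  pr <- build_clinical_prior(fixture_inputs(), mean_mode = "regression")
  expect_equal(pr$m[2], 0.10 + 0.4 * 0.10)
  # unconditional-variance sensitivity accepted when PD
  pu <- build_clinical_prior(fixture_inputs(), v22_mode = "unconditional")
  expect_equal(pu$V[2, 2], 0.25^2)
})

test_that("a non-positive-definite sensitivity derivation is rejected", {
  inp <- elicited_prior_inputs(
    theta1 = loghr_distribution(0.1, 0.5),
    theta2 = loghr_distribution(0.1, 0.3), # s2^2 = 0.09 < b12^2 V11 = 0.25
    theta2_given_null = loghr_distribution(0.0, 0.2),
    theta2_given_benefit = loghr_distribution(0.5, 0.2),
    d = 0.5)
  expect_error(build_clinical_prior(inp, v22_mode = "unconditional"),
               "sensitivity derivation rejected")
  # the default conditional derivation is PD by construction
  expect_s3_class(build_clinical_prior(inp), "bivariate_prior")
})

test_that("the sceptical prior keeps V and zeroes the mean, idempotently", {
  clin <- build_clinical_prior(fixture_inputs())
  sc <- build_sceptical_prior(clin)
  expect_equal(sc$m, c(0, 0))
  expect_identical(sc$V, clin$V)
  clin0 <- bivariate_prior("clinical", c(0, 0), clin$V)
  sc0 <- build_sceptical_prior(clin0)
  expect_equal(sc0$m, clin0$m)
  expect_identical(sc0$V, clin0$V)
})

test_that("the interaction prior matches the worked identity-matrix example", {
  for (L in c(1e2, 1e4)) {
    op <- reparam_operator(L)
    clin <- bivariate_prior("clinical", c(0.1, 0.2), diag(2))
    inter <- build_interaction_prior(clin, op)
    expect_equal(inter$V,
                 matrix(c(L + 0.5, L - 0.5, L - 0.5, L + 0.5), 2, 2),
                 tolerance = 1e-9)
    expect_equal(inter$m, clin$m)
    iv <- build_interaction_prior(clin, op, null_mean = TRUE)
    expect_equal(iv$m, c(0, 0))
    expect_identical(iv$V, inter$V)
  }
  # equal effects have an exactly null interaction component
  op <- reparam_operator()
  expect_equal(drop(op$C %*% c(0.7, 0.7)), c(0.7, 0))
})

test_that("re-parameterisation algebra holds for random covariance matrices", {
  set.seed(99)
  op <- reparam_operator(1e4)
  for (i in 1:25) {
    A <- matrix(rnorm(4), 2)
    V <- A %*% t(A) + diag(0.05, 2)
    clin <- bivariate_prior("clinical", c(0, 0), V)
    W <- op$C %*% V %*% t(op$C)
    # round trip to machine precision
    expect_equal(op$Cinv %*% W %*% t(op$Cinv), V, tolerance = 1e-12)
    inter <- build_interaction_prior(clin, op)
    # var(theta2 - theta1) under V* equals W22 = V11 + V22 - 2 V12
    a <- c(-1, 1)
    expect_equal(drop(t(a) %*% inter$V %*% a),
                 V[1, 1] + V[2, 2] - 2 * V[1, 2], tolerance = 1e-8)
  }
})

test_that("V* is vague about the mean effect but informative about the interaction", {
  clin <- build_clinical_prior(fixture_inputs())
  w22 <- drop(t(c(-1, 1)) %*% clin$V %*% c(-1, 1))
  psi1_var <- c()
  for (L in c(1e2, 1e4, 1e6)) {
    inter <- build_interaction_prior(clin, reparam_operator(L))
    psi1_var <- c(psi1_var, drop(t(c(0.5, 0.5)) %*% inter$V %*% c(0.5, 0.5)))
    expect_equal(drop(t(c(-1, 1)) %*% inter$V %*% c(-1, 1)), w22,
                 tolerance = 1e-6 * max(1, L * 1e-4))
  }
  expect_true(all(diff(psi1_var) > 0))
  expect_equal(psi1_var, c(1e2, 1e4, 1e6), tolerance = 1e-2)
})

test_that("the community holds the five specifications of the summary table", {
  comm <- build_community(fixture_inputs())
  expect_named(comm, c("clinical", "sceptical", "interaction",
                       "interaction_variance", "vague"))
  for (p in comm) {
    expect_true(is_positive_definite(p$V))
    expect_equal(p$V, t(p$V))
  }
  expect_identical(comm$sceptical$V, comm$clinical$V)
  expect_identical(comm$interaction_variance$V, comm$interaction$V)
  expect_equal(comm$vague$V, diag(1e4, 2))
  expect_equal(comm$vague$m, c(0, 0))
  expect_equal(comm$sceptical$m, c(0, 0))
  expect_equal(comm$interaction$m, comm$clinical$m)
  # the clinical conditional slope recovers the elicited regression coefficient
  expect_equal(comm$clinical$V[1, 2] / comm$clinical$V[1, 1],
               derive_regression_coefficient(fixture_inputs()))
})

test_that("prior sets serialise to parseable JSON with full precision", {
  comm <- build_community(fixture_inputs())
  path <- withr::local_tempfile(fileext = ".json")
  priors_to_json(comm, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_named(back, names(comm))
  expect_equal(unlist(back$clinical$m), comm$clinical$m, ignore_attr = TRUE)
  expect_equal(matrix(unlist(back$interaction$V), 2, 2, byrow = TRUE),
               comm$interaction$V, ignore_attr = TRUE, tolerance = 1e-12)
})
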