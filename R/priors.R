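#' Elicited inputs for the bivariate prior construction
#'
#' Bundles the four pooled (or single-expert) log-HR normals and the
#' hypothesised benefit `d`: the unconditional beliefs about the
#' less-severe effect (theta1) and more-severe effect (theta2), and the
#' conditional beliefs about theta2 given theta1 = 0 and theta1 = d.
#'
#' @param theta1,theta2 [loghr_distribution()]s for the unconditional
#'   subgroup effects
#' @param theta2_given_null,theta2_given_benefit [loghr_distribution()]s
#'   for theta2 conditional on a null / beneficial less-severe effect
#' @param d positive log hazard ratio used in the conditional question
#' @return object of class `elicited_prior_inputs`
#' @export
elicited_prior_inputs <- function(theta1, theta2, theta2_given_null,
                                  theta2_given_benefit, d) {
  for (nm in c("theta1", "theta2", "theta2_given_null", "theta2_given_benefit")) {
    obj <- get(nm)
    if (!inherits(obj, "loghr_distribution"))
      stopf("%s must be a loghr_distribution", nm)
  }
  if (!is.finite(d) || d <= 0) stopf("d must be a positive log-HR, got %s", format(d))
  structure(list(theta1 = theta1, theta2 = theta2,
                 theta2_given_null = theta2_given_null,
                 theta2_given_benefit = theta2_given_benefit, d = d),
            class = "elicited_prior_inputs")
}

#' Regression coefficient of the more-severe on the less-severe effect
#'
#' The slope implied by the two conditional questions:
#' `b12 = (mean(theta2 | theta1 = d) - mean(theta2 | theta1 = 0)) / d`.
#' A slope of zero means the expert's belief about the more-severe
#' subgroup does not update with the less-severe effect (independence).
#'
#' @param inputs an [elicited_prior_inputs()] object
#' @return numeric slope
#' @export
derive_regression_coefficient <- function(inputs) {
  stopifnot(inherits(inputs, "elicited_prior_inputs"))
  (inputs$theta2_given_benefit$mean - inputs$theta2_given_null$mean) / inputs$d
}

#' Bivariate normal prior on the two subgroup treatment effects
#'
#' @param label one of `clinical`, `sceptical`, `interaction`,
#'   `interaction_variance`, `vague`
#' @param m length-2 mean vector (log-HR scale)
#' @param V symmetric positive-definite 2x2 covariance matrix
#' @param provenance free-form list recording how the prior was built
#' @return object of class `bivariate_prior`
#' @export
bivariate_prior <- function(label, m, V, provenance = list()) {
  labels <- c("clinical", "sceptical", "interaction",
              "interaction_variance", "vague")
  if (!label %in% labels)
    stopf("label must be one of %s", paste(labels, collapse = ", "))
  m <- as.numeric(m)
  if (length(m) != 2 || any(!is.finite(m))) stopf("m must be a finite 2-vector")
  V <- as.matrix(V)
  if (!identical(dim(V), c(2L, 2L))) stopf("V must be 2x2")
  V <- (V + t(V)) / 2
  if (!is_positive_definite(V))
    stopf("V is not symmetric positive definite (smallest eigenvalue %.3g)",
          min(eigen(V, symmetric = TRUE, only.values = TRUE)$values))
  structure(list(label = label, m = m, V = V, provenance = provenance),
            class = "bivariate_prior")
}

#' @export
print.bivariate_prior <- function(x, ...) {
  cat(sprintf("%s prior on (theta1, theta2):\n", x$label))
  cat(sprintf("  m = (%.4f, %.4f)\n", x$m[1], x$m[2]))
  cat(sprintf("  V = [%.4g %.4g; %.4g %.4g]\n",
              x$V[1, 1], x$V[1, 2], x$V[2, 1], x$V[2, 2]))
  invisible(x)
}

#' Re-parameterisation operator for the interaction prior
#'
#' The fixed unit-determinant matrix `C = [[1/2, 1/2], [-1, 1]]` maps
#' `(theta1, theta2)` to `psi = ((theta1 + theta2)/2, theta2 - theta1)`:
#' the mean treatment effect and the interaction. `L` is the "arbitrarily
#' large" variance placed on components meant to be uninformative; the
#' default 1e4 corresponds to a prior SD of 100 on a log hazard ratio,
#' overwhelmingly flat for any plausible survival effect.
#'
#' @param L large variance constant (> 0)
#' @return object of class `reparam_operator` with elements `C`, `Cinv`, `L`
#' @export
reparam_operator <- function(L = 1e4) {
  if (!is.finite(L) || L <= 0) stopf("L must be positive")
  C <- matrix(c(0.5, -1, 0.5, 1), 2, 2)
  structure(list(C = C, Cinv = solve(C), L = L), class = "reparam_operator")
}

#' Build the clinical prior from elicited inputs
#'
#' The clinical prior uses the experts' beliefs for both the means and
#' the covariance: `m = (mean(theta1), mean(theta2))`, `V11 = s1^2`,
#' `V12 = b12 * V11`, and `V22 = (s20^2 + s2d^2)/2 + b12^2 * V11`
#' (conditional-variance derivation, the default). Two sensitivity
#' derivations are exposed as flags rather than community members:
#' `v22_mode = "unconditional"` takes `V22 = s2^2` directly from the
#' second unconditional question and is only accepted when the resulting
#' matrix is positive definite; `mean_mode = "regression"` replaces the
#' theta2 mean by the regression value `p20 + b12 * p1`.
#'
#' @param inputs an [elicited_prior_inputs()] object
#' @param v22_mode `"conditional"` (default) or `"unconditional"`
#' @param mean_mode `"elicited"` (default) or `"regression"`
#' @return a [bivariate_prior()] labelled `clinical`
#' @export
build_clinical_prior <- function(inputs,
                                 v22_mode = c("conditional", "unconditional"),
                                 mean_mode = c("elicited", "regression")) {
  stopifnot(inherits(inputs, "elicited_prior_inputs"))
  v22_mode <- match.arg(v22_mode)
  mean_mode <- match.arg(mean_mode)
  b12 <- derive_regression_coefficient(inputs)
  p1 <- inputs$theta1$mean
  V11 <- inputs$theta1$sd^2
  V12 <- b12 * V11
  V22 <- switch(v22_mode,
    conditional = (inputs$theta2_given_null$sd^2 +
                   inputs$theta2_given_benefit$sd^2) / 2 + b12^2 * V11,
    unconditional = inputs$theta2$sd^2)
  m2 <- switch(mean_mode,
    elicited = inputs$theta2$mean,
    regression = inputs$theta2_given_null$mean + b12 * p1)
  V <- matrix(c(V11, V12, V12, V22), 2, 2)
  if (!is_positive_definite(V))
    stopf(paste("sensitivity derivation rejected: variance-covariance matrix",
                "is not positive definite (V11 = %.4g, V12 = %.4g, V22 = %.4g)"),
          V11, V12, V22)
  bivariate_prior("clinical", c(p1, m2), V,
                  provenance = list(b12 = b12, v22_mode = v22_mode,
                                    mean_mode = mean_mode, d = inputs$d))
}

#' Centre a clinical prior on the null (sceptical prior)
#'
#' Keeps the elicited covariance but sets the mean to (0, 0), expressing
#' scepticism about any treatment effect while retaining the experts'
#' uncertainty structure.
#'
#' @param clinical a [bivariate_prior()]
#' @return a [bivariate_prior()] labelled `sceptical`
#' @export
build_sceptical_prior <- function(clinical) {
  stopifnot(inherits(clinical, "bivariate_prior"))
  bivariate_prior("sceptical", c(0, 0), clinical$V,
                  provenance = clinical$provenance)
}

#' Build the interaction prior by re-parameterisation
#'
#' Transforms the elicited covariance to the (mean effect, interaction)
#' basis, `W = C V C'`, replaces it by `W* = diag(L, W22)` — vague about
#' the mean effect, informative about the interaction `theta2 - theta1`,
#' and with no covariance belief between the two — and back-transforms
#' to `V* = C^-1 W* C^-T`. With `null_mean = FALSE` (the default and the
#' trial's primary analysis) the elicited mean `m` is kept; with
#' `null_mean = TRUE` the mean is (0, 0) (the interaction-variance
#' prior), which avoids manufacturing qualitative interactions when both
#' true effects are null.
#'
#' @param clinical a [bivariate_prior()] carrying the elicited m and V
#' @param operator a [reparam_operator()]
#' @param null_mean centre the prior mean on the null?
#' @return a [bivariate_prior()] labelled `interaction` or
#'   `interaction_variance`
#' @export
build_interaction_prior <- function(clinical, operator = reparam_operator(),
                                    null_mean = FALSE) {
  stopifnot(inherits(clinical, "bivariate_prior"),
            inherits(operator, "reparam_operator"))
  C <- operator$C; Cinv <- operator$Cinv
  W <- C %*% clinical$V %*% t(C)
  Wstar <- diag(c(operator$L, W[2, 2]))
  Vstar <- Cinv %*% Wstar %*% t(Cinv)
  bivariate_prior(if (null_mean) "interaction_variance" else "interaction",
                  if (null_mean) c(0, 0) else clinical$m,
                  Vstar,
                  provenance = c(clinical$provenance,
                                 list(L = operator$L, W22 = W[2, 2])))
}

#' Build the vague reference prior
#'
#' `N2(0, L * I)`: no information about either subgroup effect. The
#' posterior under this prior should closely reproduce the maximum
#' likelihood estimate.
#'
#' @param operator a [reparam_operator()] supplying `L`
#' @return a [bivariate_prior()] labelled `vague`
#' @export
build_vague_prior <- function(operator = reparam_operator()) {
  stopifnot(inherits(operator, "reparam_operator"))
  bivariate_prior("vague", c(0, 0), diag(operator$L, 2),
                  provenance = list(L = operator$L))
}

#' Build the full community of priors
#'
#' Returns the five standard specifications used for the robustness
#' assessment: clinical `(m, V)`, sceptical `(0, V)`, interaction
#' `(m, V*)` — the primary analysis — interaction-variance `(0, V*)`,
#' and vague `(0, L I)`.
#'
#' @param inputs an [elicited_prior_inputs()] object
#' @param operator a [reparam_operator()]
#' @param ... passed to [build_clinical_prior()] (sensitivity flags)
#' @return named list of five [bivariate_prior()]s
#' @export
build_community <- function(inputs, operator = reparam_operator(), ...) {
  clinical <- build_clinical_prior(inputs, ...)
  out <- list(
    clinical = clinical,
    sceptical = build_sceptical_prior(clinical),
    interaction = build_interaction_prior(clinical, operator, null_mean = FALSE),
    interaction_variance = build_interaction_prior(clinical, operator,
                                                   null_mean = TRUE),
    vague = build_vague_prior(operator))
  stopifnot(identical(names(out),
                      unname(vapply(out, `[[`, character(1), "label"))))
  out
}

#' Serialise a community of priors to JSON
#'
#' @param priors named list of [bivariate_prior()]s
#' @param path optional output path; when `NULL` the JSON string is returned
#' @return the JSON string (invisibly when written to `path`)
#' @export
priors_to_json <- function(priors, path = NULL) {
  payload <- lapply(priors, function(p)
    list(label = p$label, m = p$m, V = p$V, provenance = p$provenance))
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Prior summary on the hazard-ratio scale
#'
#' Median HR and central 95% interval implied by the marginal normals of
#' a bivariate prior, one row per subgroup effect.
#'
#' @param prior a [bivariate_prior()]
#' @return data frame with columns `parameter`, `median_hr`, `ci_lower`,
#'   `ci_upper`
#' @export
prior_hr_summary <- function(prior) {
  stopifnot(inherits(prior, "bivariate_prior"))
  sds <- sqrt(diag(prior$V))
  data.frame(
    parameter = c("theta1", "theta2"),
    median_hr = exp(prior$m),
    ci_lower = exp(prior$m - qnorm(0.975) * sds),
    ci_upper = exp(prior$m + qnorm(0.975) * sds),
    row.names = NULL)
}
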