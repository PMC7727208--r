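trial_covariates <- c("age_gt70", "female", "creat_gt160", "ef_lt50", "angio_5d")

#' Validate a per-patient trial table
#'
#' Columns: `id`; `arm` (0 = usual care, 1 = treated); `subgroup`
#' (0 = less severe, 1 = more severe, `NA` = missing); the five binary
#' adjustment covariates `age_gt70`, `female`, `creat_gt160`, `ef_lt50`,
#' `angio_5d`; `time_days` (> 0); `event` (1 = fit-for-discharge
#' observed, 0 = administratively censored).
#'
#' @param df data frame in the layout above
#' @return the validated data frame with class `trial_table`
#' @export
trial_table <- function(df) {
  need <- c("id", "arm", "subgroup", trial_covariates, "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(!df$arm %in% c(0, 1))) stopf("arm must be 0/1")
  if (any(!df$subgroup %in% c(0, 1) & !is.na(df$subgroup)))
    stopf("subgroup must be 0/1/NA")
  for (col in trial_covariates)
    if (any(!df[[col]] %in% c(0, 1))) stopf("covariate %s must be 0/1", col)
  if (any(!is.finite(df$time_days) | df$time_days <= 0))
    stopf("time_days must be positive")
  if (any(!df$event %in% c(0, 1))) stopf("event must be 0/1")
  for (a in 0:1)
    if (sum(df$event[df$arm == a]) < 1)
      stopf("no events in arm %d; the model cannot be fitted", a)
  structure(as.data.frame(df), class = c("trial_table", "data.frame"))
}

#' Read / write the trial table CSV format
#'
#' Header: `id,arm,subgroup,age_gt70,female,creat_gt160,ef_lt50,angio_5d,time_days,event`.
#'
#' @param path file path
#' @return a validated [trial_table()]
#' @export
read_trial_table <- function(path) {
  trial_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trial_table
#' @param data a [trial_table()]
#' @export
write_trial_table <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model specification for the subgroup Cox analysis
#'
#' The linear predictor contains the two treatment-by-subgroup effects
#' `theta1 = arm * (1 - subgroup)` and `theta2 = arm * subgroup` (the
#' only parameters receiving the informative bivariate prior), a
#' subgroup main effect (so the thetas read as within-subgroup treatment
#' effects), and the binary adjustment covariates — each of the latter
#' with an independent vague `N(0, vague_variance)` prior.
#'
#' @param prior a [bivariate_prior()] on (theta1, theta2)
#' @param covariates adjustment covariate names (subset of the five
#'   trial minimisation criteria)
#' @param subgroup_main include the subgroup main effect?
#' @param vague_variance prior variance for non-theta coefficients
#' @return object of class `model_spec`
#' @export
model_spec <- function(prior, covariates = trial_covariates,
                       subgroup_main = TRUE, vague_variance = 1e4) {
  stopifnot(inherits(prior, "bivariate_prior"))
  bad <- setdiff(covariates, trial_covariates)
  if (length(bad)) stopf("unknown covariates: %s", paste(bad, collapse = ", "))
  structure(list(prior = prior, covariates = covariates,
                 subgroup_main = isTRUE(subgroup_main),
                 vague_variance = vague_variance),
            class = "model_spec")
}

# Build the design matrix for a model_spec. Rows with missing subgroup are
# dropped (count messaged); constant columns are dropped so degenerate
# designs (e.g. a single-subgroup dataset) remain estimable.
build_design <- function(data, spec) {
  data <- trial_table(data)
  n_missing <- sum(is.na(data$subgroup))
  if (n_missing > 0) {
    message(sprintf("excluding %d patient(s) with missing subgroup", n_missing))
    data <- data[!is.na(data$subgroup), , drop = FALSE]
  }
  X <- cbind(theta1 = data$arm * (1 - data$subgroup),
             theta2 = data$arm * data$subgroup)
  if (spec$subgroup_main) X <- cbind(X, subgroup = data$subgroup)
  for (col in spec$covariates) X <- cbind(X, data[[col]])
  colnames(X) <- c("theta1", "theta2",
                   if (spec$subgroup_main) "subgroup", spec$covariates)
  keep <- apply(X, 2, function(col) var(col) > 0)
  if (any(!keep))
    message(sprintf("dropping constant column(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")))
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("design matrix is rank deficient")
  list(X = X, time = data$time_days, event = as.integer(data$event),
       n_missing = n_missing, data = data)
}

#' Efron-corrected Cox log partial likelihood
#'
#' Computes the log partial likelihood with Efron's correction for tied
#' event times. Censored observations sharing an event time stay in the
#' risk set. The value is invariant to adding a constant to all event
#' times (only ranks matter) and to adding a constant to the linear
#' predictor.
#'
#' @param time positive observation times
#' @param event 0/1 event indicators (at least one event required)
#' @param x covariate matrix (or vector for a single covariate)
#' @param beta coefficient vector, finite, length `ncol(x)`
#' @return the scalar log partial likelihood
#' @export
cox_partial_loglik <- function(time, event, x, beta) {
  x <- as.matrix(x)
  if (length(time) != nrow(x) || length(event) != nrow(x))
    stopf("time, event and x must agree in length")
  if (sum(event == 1) == 0) stopf("no events: partial likelihood undefined")
  if (any(!is.finite(beta))) stopf("non-finite coefficients")
  if (length(beta) != ncol(x))
    stopf("length(beta) = %d does not match ncol(x) = %d", length(beta), ncol(x))
  cox_loglik_efron_cpp(as.numeric(time), as.integer(event),
                       cox_linpred_cpp(x, as.numeric(beta)))
}

#' Maximum likelihood fit of the subgroup Cox model
#'
#' Maximises the Efron partial likelihood by quasi-Newton optimisation
#' and reports Wald 95% confidence intervals from the observed
#' information. Serves as the frequentist baseline against which every
#' Bayesian posterior is compared.
#'
#' @param data a [trial_table()]
#' @param spec a [model_spec()] (its prior is ignored here)
#' @return object of class `cox_mle`: coefficients, `vcov`, `loglik`,
#'   and a `summary` data frame on the hazard-ratio scale
#' @export
fit_mle <- function(data, spec) {
  d <- build_design(data, spec)
  p <- ncol(d$X)
  if (sum(d$event) < p)
    stopf("only %d events for %d parameters", sum(d$event), p)
  negll <- function(beta) -cox_loglik_efron_cpp(d$time, d$event,
                                                cox_linpred_cpp(d$X, beta))
  fit <- optim(rep(0, p), negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    g <- numeric(p)
    h <- 1e-5
    for (j in seq_len(p)) {
      e <- numeric(p); e[j] <- h
      g[j] <- (negll(fit$par + e) - negll(fit$par - e)) / (2 * h)
    }
    stopf("MLE did not converge (gradient norm %.3g)", sqrt(sum(g^2)))
  }
  if (any(abs(fit$par) > 10))
    warnf("possible separation: |beta| > 10 for %s",
          paste(colnames(d$X)[abs(fit$par) > 10], collapse = ", "))
  vcov <- tryCatch(solve(fit$hessian), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- qnorm(0.975)
  est <- setNames(fit$par, colnames(d$X))
  structure(list(
    coefficients = est,
    vcov = vcov,
    loglik = -fit$value,
    n = nrow(d$X), n_events = sum(d$event), n_missing = d$n_missing,
    summary = data.frame(
      parameter = colnames(d$X),
      estimate = fit$par,
      se = se,
      hr = exp(fit$par),
      ci_lower = exp(fit$par - z * se),
      ci_upper = exp(fit$par + z * se),
      row.names = NULL)),
    class = "cox_mle")
}

#' @export
print.cox_mle <- function(x, ...) {
  cat(sprintf("Cox PH maximum likelihood fit (%d patients, %d events)\n",
              x$n, x$n_events))
  print(x$summary, digits = 4)
  invisible(x)
}
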