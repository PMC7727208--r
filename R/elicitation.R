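#' Normal distribution on the log hazard-ratio scale
#'
#' Lightweight container for a univariate normal belief about a log
#' hazard ratio, the common currency of the elicitation pipeline.
#'
#' @param mean finite log hazard ratio
#' @param sd positive standard deviation
#' @return an object of class `loghr_distribution`
#' @export
loghr_distribution <- function(mean, sd) {
  if (!is.finite(mean)) stopf("mean must be finite, got %s", format(mean))
  if (!is.finite(sd) || sd <= 0) stopf("sd must be positive, got %s", format(sd))
  structure(list(mean = mean, sd = sd), class = "loghr_distribution")
}

#' @export
print.loghr_distribution <- function(x, ...) {
  cat(sprintf("log-HR ~ N(%.4f, %.4f^2)  [median HR %.3f, 95%% %.3f-%.3f]\n",
              x$mean, x$sd, exp(x$mean),
              exp(x$mean - 1.959964 * x$sd), exp(x$mean + 1.959964 * x$sd)))
  invisible(x)
}

#' Transform a pair of event probabilities to a log hazard ratio
#'
#' Under proportional hazards, if a fraction `p_treat` of treated
#' patients and `p_control` of control patients experience the event by a
#' fixed landmark time, the hazard ratio satisfies
#' `log(HR) = log(log(1 - p_treat) / log(1 - p_control))`. The sign is
#' positive exactly when `p_treat > p_control`, i.e. when treatment
#' accelerates the event (here: being fit for discharge).
#'
#' @param p_treat probability in (0, 1) under treatment
#' @param p_control probability in (0, 1) under the comparator
#' @return log hazard ratio (vectorised over its arguments)
#' @export
prob_pair_to_loghr <- function(p_treat, p_control) {
  bad <- function(p, what) {
    out <- which(!is.finite(p) | p <= 0 | p >= 1)
    if (length(out))
      stopf("%s must lie strictly in (0, 1); offending value: %s",
            what, format(p[out[1]]))
  }
  bad(p_treat, "p_treat"); bad(p_control, "p_control")
  log(log1p(-p_treat) / log1p(-p_control))
}

#' Invert the probability-to-log-hazard-ratio transform
#'
#' Given a log hazard ratio and the comparator probability, returns the
#' treated-arm probability that maps back to that log-HR. Used by the
#' synthetic elicitation generator.
#'
#' @param loghr log hazard ratio
#' @param p_control comparator probability in (0, 1)
#' @return treated-arm probability in (0, 1)
#' @export
loghr_to_prob <- function(loghr, p_control) {
  if (any(p_control <= 0 | p_control >= 1))
    stopf("p_control must lie strictly in (0, 1)")
  -expm1(exp(loghr) * log1p(-p_control))
}

#' Fit a normal distribution to three elicited quantiles
#'
#' Finds the normal whose CDF, evaluated at the 2.5th, 50th and 97.5th
#' elicited points, is closest in least squares to (0.025, 0.5, 0.975).
#' For symmetric triples this reduces to the closed form
#' `mean = q50`, `sd = (q975 - q025) / (2 * 1.959964)`, which is also the
#' optimiser's starting point; the search is bounded (`sd` in
#' `[1e-6, 10]` on the log-HR scale) and deterministic.
#'
#' @param q025,q50,q975 strictly increasing quantile values (log-HR scale)
#' @return a [loghr_distribution()] with attribute `"objective"` carrying
#'   the residual sum of squares of the fit
#' @export
fit_normal_from_quantiles <- function(q025, q50, q975) {
  q <- c(q025, q50, q975)
  if (any(!is.finite(q))) stopf("quantiles must be finite")
  if (!(q025 < q50 && q50 < q975))
    stopf("quantiles must be strictly increasing, got (%s, %s, %s)",
          format(q025), format(q50), format(q975))
  targets <- c(0.025, 0.5, 0.975)
  obj <- function(par) {
    if (par[2] < 1e-6 || par[2] > 10 || abs(par[1]) > 20) return(1e6)
    sum((pnorm(q, par[1], par[2]) - targets)^2)
  }
  start <- c(q50, (q975 - q025) / (2 * qnorm(0.975)))
  # Nelder-Mead is robust when the symmetric start is already optimal
  # (L-BFGS-B line searches can abort there); a bounded polish follows.
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  polish <- tryCatch(
    optim(fit$par, obj, method = "L-BFGS-B",
          lower = c(-20, 1e-6), upper = c(20, 10)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < fit$value) fit <- polish
  if (fit$value > 1e-3)
    stopf("quantile fit did not converge (residual %.3g)", fit$value)
  out <- loghr_distribution(fit$par[1], fit$par[2])
  attr(out, "objective") <- fit$value
  out
}

#' Convert one expert's elicited counts to a log-hazard-ratio normal
#'
#' Each elicited quantile count (out of 100 treated patients) is divided
#' by 100 and pushed through [prob_pair_to_loghr()] against the expert's
#' usual-care reference count, then the three transformed points are
#' fitted with [fit_normal_from_quantiles()]. Boundary counts of 0 or 100
#' are nudged to 0.5 / 99.5 with a warning, since the transform is
#' undefined at the boundary.
#'
#' @param answer a list or one-row data frame with fields `q025`, `q50`,
#'   `q975` and `usual_care_ref` (counts out of 100)
#' @return a [loghr_distribution()]
#' @export
answer_to_loghr_distribution <- function(answer) {
  need <- c("q025", "q50", "q975", "usual_care_ref")
  if (!all(need %in% names(answer)))
    stopf("answer must carry fields %s", paste(need, collapse = ", "))
  counts <- as.numeric(c(answer$q025, answer$q50, answer$q975))
  ref <- as.numeric(answer$usual_care_ref)
  if (any(counts < 0 | counts > 100) || ref < 0 || ref > 100)
    stopf("counts must lie in [0, 100]")
  if (!(counts[1] <= counts[2] && counts[2] <= counts[3]))
    stopf("elicited counts must be non-decreasing: (%d, %d, %d)",
          counts[1], counts[2], counts[3])
  clamp <- function(x, what) {
    hit <- x <= 0 | x >= 100
    if (any(hit)) {
      warnf("%s count(s) at the 0/100 boundary clamped to 0.5/99.5", what)
      x[x <= 0] <- 0.5
      x[x >= 100] <- 99.5
    }
    x
  }
  counts <- clamp(counts, "elicited")
  ref <- clamp(ref, "usual-care reference")
  loghr <- prob_pair_to_loghr(counts / 100, ref / 100)
  if (!(loghr[1] < loghr[2] && loghr[2] < loghr[3]))
    stopf("transformed quantiles are not strictly increasing; widen the elicited range")
  fit_normal_from_quantiles(loghr[1], loghr[2], loghr[3])
}

#' Pool expert distributions by linear opinion pooling
#'
#' Forms the weighted mixture of the experts' normals and returns the
#' moment-matched normal summary (the bivariate prior construction
#' downstream needs normal parameters). The mixture mean is the weighted
#' mean of the component means; the mixture variance is
#' `sum(w * (s^2 + m^2)) - mean^2`, which always dominates the weighted
#' mean of the component variances. The raw mixture is retained in the
#' `"mixture"` attribute for plotting.
#'
#' @param dists list of [loghr_distribution()] objects
#' @param weights optional non-negative weights summing to 1 (default equal)
#' @return a [loghr_distribution()] with attribute `"mixture"`
#' @export
pool_experts <- function(dists, weights = NULL) {
  if (length(dists) == 0) stopf("at least one distribution is required")
  if (!all(vapply(dists, inherits, logical(1), "loghr_distribution")))
    stopf("dists must be loghr_distribution objects")
  k <- length(dists)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k) stopf("need %d weights, got %d", k, length(weights))
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stopf("weights must sum to 1 (got %.12f)", sum(weights))
  m <- vapply(dists, `[[`, numeric(1), "mean")
  s <- vapply(dists, `[[`, numeric(1), "sd")
  mu <- sum(weights * m)
  v <- sum(weights * (s^2 + m^2)) - mu^2
  out <- loghr_distribution(mu, sqrt(v))
  attr(out, "mixture") <- list(means = m, sds = s, weights = weights)
  out
}

elicitation_questions <- c("uncond_less_severe", "uncond_more_severe",
                           "cond_null", "cond_benefit")

#' Read and validate an elicitation answers file
#'
#' Expects a UTF-8 CSV with header
#' `expert_id,subgroup_factor,question,q025,q50,q975,usual_care_ref`,
#' one row per (expert, factor, question). Questions are
#' `uncond_less_severe`, `uncond_more_severe` and — for the more-severe
#' subgroup only — `cond_null` (belief about the more-severe effect if
#' the less-severe effect were null) and `cond_benefit` (if it were
#' beneficial by the hypothesised amount `d`).
#'
#' @param path file path, or a data frame already in the same layout
#' @return validated data frame of class `expert_answers`
#' @export
read_expert_answers <- function(path) {
  df <- if (is.data.frame(path)) as.data.frame(path)
        else read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "subgroup_factor", "question",
            "q025", "q50", "q975", "usual_care_ref")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (!all(df$question %in% elicitation_questions))
    stopf("unknown question label(s): %s",
          paste(unique(setdiff(df$question, elicitation_questions)), collapse = ", "))
  num <- c("q025", "q50", "q975", "usual_care_ref")
  for (col in num) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0 | v > 100))
      stopf("column %s must hold counts in [0, 100]", col)
  }
  if (any(df$q025 > df$q50 | df$q50 > df$q975))
    stopf("quantile counts must satisfy q025 <= q50 <= q975 in every row")
  structure(df, class = c("expert_answers", "data.frame"))
}

#' Write an elicitation answers table to CSV
#'
#' @param answers an `expert_answers` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expert_answers <- function(answers, path) {
  write.csv(as.data.frame(answers), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive pooled prior inputs from an elicitation table
#'
#' For one subgroup factor, converts every expert's answer to each of the
#' four questions into a log-HR normal, pools across experts question by
#' question, and assembles the four pooled distributions plus the
#' hypothesised benefit `d` into the inputs of the bivariate prior
#' construction.
#'
#' @param answers `expert_answers` data (see [read_expert_answers()])
#' @param subgroup_factor which factor's rows to use
#' @param d hypothesised beneficial log hazard ratio in the less-severe
#'   subgroup (defaults via [hypothesised_benefit()] when the factor is
#'   one of the built-in labels)
#' @param experts optional subset of expert ids (per-expert sensitivity)
#' @param weights optional pooling weights over the selected experts
#' @return an [elicited_prior_inputs()] object
#' @export
elicit_prior_inputs <- function(answers, subgroup_factor, d = NULL,
                                experts = NULL, weights = NULL) {
  answers <- read_expert_answers(answers)
  df <- answers[answers$subgroup_factor == subgroup_factor, , drop = FALSE]
  if (nrow(df) == 0) stopf("no rows for subgroup factor '%s'", subgroup_factor)
  if (!is.null(experts)) {
    df <- df[df$expert_id %in% experts, , drop = FALSE]
    if (nrow(df) == 0) stopf("no rows left after expert filter")
  }
  if (is.null(d)) d <- hypothesised_benefit(subgroup_factor)
  pool_question <- function(question) {
    rows <- df[df$question == question, , drop = FALSE]
    if (nrow(rows) == 0) stopf("no answers for question '%s'", question)
    dists <- lapply(seq_len(nrow(rows)), function(i)
      answer_to_loghr_distribution(rows[i, ]))
    pool_experts(dists, weights)
  }
  elicited_prior_inputs(
    theta1 = pool_question("uncond_less_severe"),
    theta2 = pool_question("uncond_more_severe"),
    theta2_given_null = pool_question("cond_null"),
    theta2_given_benefit = pool_question("cond_benefit"),
    d = d)
}

#' Built-in hypothesised benefits for the two trial subgroup factors
#'
#' The conditional elicitation question asks experts to suppose the
#' less-severe subgroup truly benefits by `d` on the log-HR scale. For
#' the renal-risk factor, `d` corresponds to 70 rather than 60 of 100
#' usual-care patients recovering normally; for the glucose-management
#' factor, 65 rather than 50.
#'
#' @param subgroup_factor `"renal_risk"` or `"glucose_management"`
#' @return positive log hazard ratio
#' @export
hypothesised_benefit <- function(subgroup_factor) {
  switch(subgroup_factor,
    renal_risk = prob_pair_to_loghr(0.70, 0.60),
    glucose_management = prob_pair_to_loghr(0.65, 0.50),
    stopf("no built-in benefit d for factor '%s'; pass d explicitly",
          subgroup_factor))
}
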