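#' Baseline counts of the UK trial used for simulation defaults
#'
#' Published baseline characteristics of the 121 UK participants:
#' per-arm counts for the five minimisation criteria and the two
#' subgroup variables. These anchor the default prevalences of the
#' synthetic generator and the count identities checked by the
#' acceptance suite (75 + 45 + 1 missing = 121 for the renal factor;
#' 65 + 56 = 121 for the glucose factor).
#'
#' @return list with elements `n_usual_care`, `n_treated`, `criteria`
#'   (data frame of per-arm counts), `subgroups` (data frame with
#'   less-severe counts per arm and the number missing)
#' @export
uk_trial_baseline <- function() {
  list(
    n_usual_care = 61L,
    n_treated = 60L,
    criteria = data.frame(
      covariate = trial_covariates,
      usual_care = c(17L, 10L, 3L, 49L, 5L),
      treated = c(17L, 10L, 4L, 49L, 7L)),
    subgroups = data.frame(
      factor = c("renal_risk", "glucose_management"),
      less_severe_usual_care = c(37L, 30L),
      less_severe_treated = c(38L, 35L),
      n_missing = c(1L, 0L)))
}

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the 121-patient UK trial: 61/60 allocation, subgroup
#' prevalence 75/120 less-severe for the renal factor (65/121 for the
#' glucose factor), covariate prevalences from the baseline table, and a
#' Weibull time-to-fit-for-discharge with shape 1.5 whose baseline
#' median is 6 days (the registry median length of stay used to anchor
#' the elicitation questions). Administrative censoring at 30 days.
#' Event times are recorded in whole days (ceiling), producing the ties
#' a discharge-day outcome really has.
#'
#' @param n number of patients
#' @param subgroup_factor `"renal_risk"` or `"glucose_management"`
#' @param theta1,theta2 true treatment log-HRs in the less/more severe
#'   subgroup
#' @param subgroup_prevalence probability of being less severe (default
#'   from the baseline table for the chosen factor)
#' @param n_missing_subgroup patients with subgroup set missing (default
#'   from the baseline table)
#' @param covariate_prevalence named vector over the five covariates
#' @param covariate_effects named vector of log-HRs (default all 0:
#'   pure nuisance adjustment)
#' @param subgroup_effect log-HR of the subgroup main effect on recovery
#' @param shape,scale Weibull shape and scale of the baseline
#'   time-to-event; default scale makes the baseline median 6 days
#' @param horizon administrative censoring horizon in days
#' @param round_days record times as whole days?
#' @param seed integer seed
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n = 121,
                              subgroup_factor = "renal_risk",
                              theta1 = 0, theta2 = 0,
                              subgroup_prevalence = NULL,
                              n_missing_subgroup = NULL,
                              covariate_prevalence = NULL,
                              covariate_effects = NULL,
                              subgroup_effect = 0,
                              shape = 1.5,
                              scale = 6 / log(2)^(1 / shape),
                              horizon = 30,
                              round_days = TRUE,
                              seed = 1) {
  if (n <= 0) stopf("n must be positive")
  if (shape <= 0 || scale <= 0) stopf("Weibull shape and scale must be positive")
  if (horizon <= 0) stopf("censoring horizon must be positive")
  base <- uk_trial_baseline()
  sg <- base$subgroups[base$subgroups$factor == subgroup_factor, ]
  if (is.null(subgroup_prevalence)) {
    if (nrow(sg) == 0)
      stopf("no default prevalence for factor '%s'; set subgroup_prevalence",
            subgroup_factor)
    less <- sg$less_severe_usual_care + sg$less_severe_treated
    subgroup_prevalence <- less / (base$n_usual_care + base$n_treated - sg$n_missing)
  }
  if (subgroup_prevalence < 0 || subgroup_prevalence > 1)
    stopf("subgroup_prevalence must lie in [0, 1]")
  if (is.null(n_missing_subgroup))
    n_missing_subgroup <- if (nrow(sg)) sg$n_missing else 0L
  if (is.null(covariate_prevalence)) {
    covariate_prevalence <- setNames(
      (base$criteria$usual_care + base$criteria$treated) /
        (base$n_usual_care + base$n_treated),
      base$criteria$covariate)
  }
  if (any(covariate_prevalence < 0 | covariate_prevalence > 1))
    stopf("covariate prevalences must lie in [0, 1]")
  if (is.null(covariate_effects))
    covariate_effects <- setNames(numeric(length(trial_covariates)),
                                  trial_covariates)
  structure(list(n = as.integer(n), subgroup_factor = subgroup_factor,
                 theta1 = theta1, theta2 = theta2,
                 subgroup_prevalence = subgroup_prevalence,
                 n_missing_subgroup = as.integer(n_missing_subgroup),
                 covariate_prevalence = covariate_prevalence,
                 covariate_effects = covariate_effects,
                 subgroup_effect = subgroup_effect,
                 shape = shape, scale = scale, horizon = horizon,
                 round_days = isTRUE(round_days), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic trial table
#'
#' Simulates a two-arm trial under proportional hazards: arms are
#' assigned 1:1 (the extra patient to usual care, as in the UK trial),
#' subgroup and covariates are independent Bernoulli draws at the
#' configured prevalences, and event times follow a Weibull whose hazard
#' is multiplied by `exp(eta)` with
#' `eta = theta1 * arm * (1 - subgroup) + theta2 * arm * subgroup +
#' subgroup_effect * subgroup + covariate effects`. Times beyond the
#' horizon are administratively censored. Deterministic given the seed.
#'
#' @param config a [simulation_config()]
#' @return a [trial_table()] with attribute `"config"`
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n
  n_treated <- n %/% 2
  arm <- sample(rep(c(0L, 1L), c(n - n_treated, n_treated)))
  subgroup_latent <- rbinom(n, 1, 1 - config$subgroup_prevalence) # 1 = more severe
  covs <- vapply(trial_covariates, function(cv)
    rbinom(n, 1, config$covariate_prevalence[[cv]]), integer(n))
  eta <- config$theta1 * arm * (1 - subgroup_latent) +
         config$theta2 * arm * subgroup_latent +
         config$subgroup_effect * subgroup_latent +
         as.numeric(covs %*% config$covariate_effects[trial_covariates])
  u <- runif(n)
  t_raw <- config$scale * (-log(u) * exp(-eta))^(1 / config$shape)
  event <- as.integer(t_raw <= config$horizon)
  time <- pmin(t_raw, config$horizon)
  if (config$round_days) time <- as.integer(ceiling(time))
  subgroup <- subgroup_latent
  if (config$n_missing_subgroup > 0) {
    miss <- sample(n, min(config$n_missing_subgroup, n))
    subgroup[miss] <- NA_integer_
  }
  df <- data.frame(id = seq_len(n), arm = arm, subgroup = subgroup)
  df <- cbind(df, as.data.frame(covs))
  df$time_days <- time
  df$event <- event
  out <- trial_table(df)
  attr(out, "config") <- config
  out
}

#' Configuration for the synthetic elicitation generator
#'
#' Emulates a panel of clinicians asked, per subgroup, how many of 100
#' treated patients would be fit for discharge by day 6 (median, 2.5th,
#' 97.5th percentile), plus the two conditional questions for the
#' more-severe subgroup. Defaults describe a panel of 7 with one sceptic
#' (expert A) and two enthusiasts (E, F), centred on a modest benefit
#' that is larger in the more-severe subgroup — the pattern reported for
#' the real panel.
#'
#' @param n_experts number of experts
#' @param expert_ids identifiers (default `LETTERS`)
#' @param subgroup_factor factor label written to the answers
#' @param usual_care_ref comparator count out of 100 (default 60 for the
#'   renal factor, 50 for glucose — the anchors of the hypothesised `d`)
#' @param theta1_mean,theta2_mean panel-centre log-HRs
#' @param offsets per-expert optimism shifts added to both means
#' @param widths per-expert prior SDs on the log-HR scale
#' @param b12 conditional slope of theta2 on theta1 each expert implies
#' @param d hypothesised benefit used for the `cond_benefit` question
#' @param seed unused at default settings (generation is deterministic);
#'   kept for interface symmetry
#' @return object of class `elicitation_fixture_config`
#' @export
elicitation_fixture_config <- function(n_experts = 7,
                                       expert_ids = LETTERS[seq_len(n_experts)],
                                       subgroup_factor = "renal_risk",
                                       usual_care_ref = NULL,
                                       theta1_mean = 0.10,
                                       theta2_mean = 0.18,
                                       offsets = NULL,
                                       widths = rep(0.25, n_experts),
                                       b12 = 0.5,
                                       d = NULL,
                                       seed = 1) {
  if (is.null(usual_care_ref))
    usual_care_ref <- switch(subgroup_factor, renal_risk = 60,
                             glucose_management = 50, 60)
  if (is.null(offsets)) {
    base <- c(-0.30, -0.05, 0, 0.05, 0.30, 0.30, 0.10)
    offsets <- rep_len(base, n_experts)
  }
  if (is.null(d)) d <- tryCatch(hypothesised_benefit(subgroup_factor),
                                error = function(e) prob_pair_to_loghr(0.70, 0.60))
  if (length(offsets) != n_experts || length(widths) != n_experts)
    stopf("offsets and widths must have one entry per expert")
  if (any(widths <= 0)) stopf("widths must be positive")
  if (abs(b12) >= 1)
    stopf("|b12| must be < 1 so the conditional variance stays positive")
  structure(list(n_experts = as.integer(n_experts), expert_ids = expert_ids,
                 subgroup_factor = subgroup_factor,
                 usual_care_ref = usual_care_ref,
                 theta1_mean = theta1_mean, theta2_mean = theta2_mean,
                 offsets = offsets, widths = widths, b12 = b12, d = d,
                 seed = as.integer(seed)),
            class = "elicitation_fixture_config")
}

#' Generate synthetic expert answers with known ground truth
#'
#' For expert e with means `(m1, m2) = (theta1_mean, theta2_mean) +
#' offset_e` and SD `w_e`, the three quantiles of each log-HR normal are
#' pushed back through the inverse probability transform against the
#' usual-care reference and rounded to integer counts. Conditional
#' questions use the self-consistent decomposition
#' `mean(theta2 | theta1 = t) = m2 + b12 (t - m1)` and
#' `sd = w_e * sqrt(1 - b12^2)`, so the configured `(m2, w_e)` are
#' recovered when the bivariate prior is rebuilt from the answers.
#'
#' @param config an [elicitation_fixture_config()]
#' @return an `expert_answers` data frame with attribute `"config"`
#' @export
generate_expert_answers <- function(config) {
  stopifnot(inherits(config, "elicitation_fixture_config"))
  ref <- config$usual_care_ref
  probs <- c(0.025, 0.5, 0.975)
  quantile_counts <- function(mean, sd) {
    q <- qnorm(probs, mean, sd)
    counts <- as.integer(round(100 * loghr_to_prob(q, ref / 100)))
    if (any(counts <= 0 | counts >= 100))
      stopf(paste("configured width implies counts outside (0, 100)",
                  "(got %s); narrow the expert's uncertainty"),
            paste(counts, collapse = ", "))
    counts
  }
  rows <- list()
  for (e in seq_len(config$n_experts)) {
    m1 <- config$theta1_mean + config$offsets[e]
    m2 <- config$theta2_mean + config$offsets[e]
    w <- config$widths[e]
    w_cond <- w * sqrt(1 - config$b12^2)
    qs <- list(
      uncond_less_severe = quantile_counts(m1, w),
      uncond_more_severe = quantile_counts(m2, w),
      cond_null = quantile_counts(m2 + config$b12 * (0 - m1), w_cond),
      cond_benefit = quantile_counts(m2 + config$b12 * (config$d - m1), w_cond))
    for (qn in names(qs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        expert_id = config$expert_ids[e],
        subgroup_factor = config$subgroup_factor,
        question = qn,
        q025 = qs[[qn]][1], q50 = qs[[qn]][2], q975 = qs[[qn]][3],
        usual_care_ref = as.integer(ref))
    }
  }
  out <- read_expert_answers(do.call(rbind, rows))
  attr(out, "config") <- config
  out
}

#' Default simulation scenario pack
#'
#' Three scenarios used by the end-to-end checks: `null` (no effect in
#' either subgroup, trial-sized), `common_benefit` (HR 1.2 in both
#' subgroups, trial-sized), and `qualitative_interaction` (opposite
#' effects, theta1 = +0.35, theta2 = -0.35, emulating the observed
#' pattern of a lower hazard ratio in the more-severe subgroup; n = 484,
#' four times the trial, so the subgroup MLEs are stable enough for
#' direction checks).
#'
#' @param seed base seed; scenario i uses `seed + i - 1`
#' @return named list of [simulation_config()]s
#' @export
trial_scenarios <- function(seed = 1) {
  list(
    null = simulation_config(n = 121, theta1 = 0, theta2 = 0, seed = seed),
    common_benefit = simulation_config(n = 121, theta1 = log(1.2),
                                       theta2 = log(1.2), seed = seed + 1),
    qualitative_interaction = simulation_config(n = 484, theta1 = 0.35,
                                                theta2 = -0.35,
                                                seed = seed + 2))
}
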