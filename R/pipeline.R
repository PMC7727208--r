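#' Configuration for a full subgroup analysis run
#'
#' Exactly one trial source and one elicitation source must be given:
#' either file paths / in-memory tables, or generator configurations
#' (simulation mode). One subgroup factor is analysed per run.
#'
#' @param trial path to a trial CSV, a [trial_table()], or a
#'   [simulation_config()]
#' @param answers path to an elicitation CSV, an `expert_answers` data
#'   frame, or an [elicitation_fixture_config()]
#' @param subgroup_factor factor analysed (must match the answers)
#' @param priors community labels to fit (default all five)
#' @param v22_mode,mean_mode sensitivity flags for the clinical prior
#' @param experts optional expert subset for a per-expert sensitivity run
#' @param d hypothesised benefit (default from [hypothesised_benefit()])
#' @param L large-variance constant of the re-parameterisation
#' @param mcmc an [mcmc_settings()]
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(trial, answers,
                            subgroup_factor = "renal_risk",
                            priors = c("clinical", "sceptical", "interaction",
                                       "interaction_variance", "vague"),
                            v22_mode = "conditional",
                            mean_mode = "elicited",
                            experts = NULL,
                            d = NULL,
                            L = 1e4,
                            mcmc = mcmc_settings()) {
  all_labels <- c("clinical", "sceptical", "interaction",
                  "interaction_variance", "vague")
  if (length(priors) == 0) stopf("community selection must not be empty")
  bad <- setdiff(priors, all_labels)
  if (length(bad)) stopf("unknown prior label(s): %s", paste(bad, collapse = ", "))
  structure(list(trial = trial, answers = answers,
                 subgroup_factor = subgroup_factor, priors = unique(priors),
                 v22_mode = v22_mode, mean_mode = mean_mode,
                 experts = experts, d = d, L = L, mcmc = mcmc),
            class = "analysis_config")
}

resolve_trial <- function(trial) {
  if (inherits(trial, "simulation_config")) generate_trial(trial)
  else if (inherits(trial, "trial_table")) trial
  else if (is.character(trial)) read_trial_table(trial)
  else trial_table(trial)
}

resolve_answers <- function(answers) {
  if (inherits(answers, "elicitation_fixture_config"))
    generate_expert_answers(answers)
  else read_expert_answers(answers)
}

#' Run the full elicitation-to-posterior analysis
#'
#' Pipeline: load or simulate the trial table and elicitation answers;
#' pool the experts and build the community of priors; fit the Cox model
#' by maximum likelihood and by MCMC under each selected prior; attach
#' posterior and shrinkage summaries. MCMC non-convergence for one prior
#' is recorded and the remaining priors still run; failures in earlier
#' stages abort with the stage name.
#'
#' @param config an [analysis_config()]
#' @return a `report_bundle`: list with `meta`, `inputs`, `priors`
#'   (with HR summaries), `mle`, `posteriors` (per label: summary or
#'   error message), `shrinkage`
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  data <- stage("load_trial", resolve_trial(config$trial))
  answers <- stage("load_answers", resolve_answers(config$answers))
  inputs <- stage("elicitation",
    elicit_prior_inputs(answers, config$subgroup_factor, d = config$d,
                        experts = config$experts))
  community <- stage("prior_construction",
    build_community(inputs, reparam_operator(config$L),
                    v22_mode = config$v22_mode, mean_mode = config$mean_mode))
  community <- community[config$priors]
  mle <- stage("mle", fit_mle(data, model_spec(community[[1]])))

  posteriors <- list()
  shrinkage <- list()
  for (label in names(community)) {
    prior <- community[[label]]
    fit <- tryCatch(fit_bayes(data, model_spec(prior), config$mcmc),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      posteriors[[label]] <- list(error = conditionMessage(fit))
    } else {
      posteriors[[label]] <- fit
      shrinkage[[label]] <- shrinkage_report(prior, mle, fit)
    }
  }
  structure(list(
    meta = list(subgroup_factor = config$subgroup_factor,
                priors = names(community),
                v22_mode = config$v22_mode, mean_mode = config$mean_mode,
                experts = config$experts, L = config$L,
                mcmc = unclass(config$mcmc),
                n = mle$n, n_events = mle$n_events,
                n_missing_subgroup = mle$n_missing,
                package_version = as.character(utils::packageVersion("survprior"))),
    inputs = inputs,
    priors = lapply(community, function(p)
      list(prior = p, hr_summary = prior_hr_summary(p))),
    mle = mle,
    posteriors = posteriors,
    shrinkage = shrinkage),
    class = "report_bundle")
}

theta_rows <- function(df) df[df$parameter %in% c("theta1", "theta2"), ]

bundle_records <- function(bundle) {
  recs <- list()
  for (label in names(bundle$posteriors)) {
    post <- bundle$posteriors[[label]]
    pri <- bundle$priors[[label]]$hr_summary
    for (i in 1:2) {
      nm <- c("theta1", "theta2")[i]
      mrow <- bundle$mle$summary[bundle$mle$summary$parameter == nm, ]
      rec <- list(prior = label, parameter = nm,
                  subgroup = c("less_severe", "more_severe")[i],
                  prior_median_hr = pri$median_hr[i],
                  prior_ci = c(pri$ci_lower[i], pri$ci_upper[i]),
                  mle_hr = mrow$hr, mle_ci = c(mrow$ci_lower, mrow$ci_upper))
      if (!is.null(post$error)) {
        rec$error <- post$error
      } else {
        prow <- post$summary[post$summary$parameter == nm, ]
        srow <- bundle$shrinkage[[label]]
        srow <- srow[srow$parameter == nm, ]
        rec <- c(rec, list(
          posterior_median_hr = prow$median_hr,
          posterior_ci = c(prow$ci_lower, prow$ci_upper),
          p_hr_gt1 = prow$p_hr_gt1, rhat = prow$rhat, ess = prow$ess,
          shrinkage_between = srow$between,
          width_ratio = srow$width_ratio))
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  recs
}

#' Render a report bundle to files
#'
#' Writes `report.json` (machine-readable; byte-identical on re-render),
#' `report.txt` (human-readable table), `priors.json`,
#' `posteriors/<label>.json` and `forest.svg` (a forest-style plot of
#' prior, MLE and posterior HRs per subgroup) under `outdir`.
#'
#' @param bundle a `report_bundle` from [run_analysis()]
#' @param outdir output directory (created if needed)
#' @return named character vector of the files written, invisibly
#' @export
render_report <- function(bundle, outdir) {
  if (!inherits(bundle, "report_bundle")) stopf("not a report_bundle")
  missing <- setdiff(c("meta", "priors", "mle", "posteriors"), names(bundle))
  if (length(missing))
    stopf("incomplete bundle; missing: %s", paste(missing, collapse = ", "))
  if (length(bundle$posteriors) == 0)
    stopf("incomplete bundle; missing: posterior results for every prior")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "posteriors"), showWarnings = FALSE)

  recs <- bundle_records(bundle)
  report_json <- file.path(outdir, "report.json")
  jsonlite::write_json(list(meta = bundle$meta, records = recs),
                       report_json, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")

  priors_json <- file.path(outdir, "priors.json")
  priors_to_json(lapply(bundle$priors, `[[`, "prior"), priors_json)

  for (label in names(bundle$posteriors)) {
    post <- bundle$posteriors[[label]]
    payload <- if (!is.null(post$error)) list(label = label, error = post$error)
      else list(label = label, summary = post$summary,
                accept_rate = post$accept_rate,
                seed = post$settings$seed, mcmc = unclass(post$settings))
    jsonlite::write_json(payload, file.path(outdir, "posteriors",
                                            paste0(label, ".json")),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
  }

  txt <- file.path(outdir, "report.txt")
  lines <- c(sprintf("Subgroup analysis: %s (n = %d, events = %d)",
                     bundle$meta$subgroup_factor, bundle$meta$n,
                     bundle$meta$n_events),
             sprintf("%-22s %-12s %28s %28s %8s", "prior", "subgroup",
                     "prior HR (95%)", "posterior HR (95% CrI)", "P(HR>1)"),
             sprintf("%-22s %-12s %28s", "MLE", "less_severe",
                     fmt_ci(bundle$mle$summary[1, c("hr", "ci_lower", "ci_upper")])),
             sprintf("%-22s %-12s %28s", "MLE", "more_severe",
                     fmt_ci(bundle$mle$summary[2, c("hr", "ci_lower", "ci_upper")])))
  for (rec in recs) {
    lines <- c(lines, if (!is.null(rec$error))
      sprintf("%-22s %-12s  MCMC failed: %s", rec$prior, rec$subgroup, rec$error)
    else
      sprintf("%-22s %-12s %28s %28s %8.3f", rec$prior, rec$subgroup,
              fmt_ci(c(rec$prior_median_hr, rec$prior_ci)),
              fmt_ci(c(rec$posterior_median_hr, rec$posterior_ci)),
              rec$p_hr_gt1))
  }
  writeLines(lines, txt)

  svg <- file.path(outdir, "forest.svg")
  writeLines(forest_svg(recs, bundle), svg)

  invisible(c(report = report_json, priors = priors_json, text = txt,
              forest = svg))
}

fmt_ci <- function(v) {
  v <- as.numeric(v)
  one <- function(x) {
    if (!is.finite(x)) return("Inf")
    if (x >= 1000 || (x > 0 && x < 0.001)) sprintf("%.2g", x)
    else sprintf("%.2f", x)
  }
  sprintf("%s (%s-%s)", one(v[1]), one(v[2]), one(v[3]))
}

# Hand-rolled deterministic SVG forest plot: one row per
# (prior, subgroup) showing prior, MLE and posterior HR with intervals
# on a log axis. Avoids any graphics-device dependency.
forest_svg <- function(recs, bundle) {
  row_h <- 26; left <- 200; width <- 720; plot_w <- width - left - 30
  all_hr <- c(1, unlist(lapply(recs, function(r)
    c(r$prior_ci, r$mle_ci, r$posterior_ci))))
  all_hr <- all_hr[is.finite(all_hr) & all_hr > 0]
  lim <- range(all_hr)
  lim <- c(max(lim[1], 0.05), min(lim[2], 20))
  xmap <- function(hr) left + plot_w *
    (log(pmin(pmax(hr, lim[1]), lim[2])) - log(lim[1])) / diff(log(lim))
  n <- length(recs)
  height <- 70 + n * row_h
  es <- function(x) sprintf("%.2f", x)
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif" font-size="11">',
                   width, height),
           sprintf('<text x="10" y="20" font-size="14">Subgroup treatment effects (%s): prior, MLE, posterior</text>',
                   bundle$meta$subgroup_factor),
           sprintf('<line x1="%s" y1="35" x2="%s" y2="%d" stroke="#999" stroke-dasharray="4 3"/>',
                   es(xmap(1)), es(xmap(1)), height - 25),
           sprintf('<text x="%s" y="%d">HR = 1</text>', es(xmap(1) - 18), height - 10))
  y <- 50
  seg <- function(lo, hi, yy, col, wd) sprintf(
    '<line x1="%s" y1="%d" x2="%s" y2="%d" stroke="%s" stroke-width="%s"/>',
    es(xmap(lo)), yy, es(xmap(hi)), yy, col, wd)
  dot <- function(hr, yy, col) sprintf(
    '<circle cx="%s" cy="%d" r="3" fill="%s"/>', es(xmap(hr)), yy, col)
  for (rec in recs) {
    out <- c(out, sprintf('<text x="10" y="%d">%s / %s</text>',
                          y + 4, rec$prior, rec$subgroup))
    out <- c(out, seg(rec$prior_ci[1], rec$prior_ci[2], y - 6, "#000000", "1"),
             dot(rec$prior_median_hr, y - 6, "#000000"),
             seg(rec$mle_ci[1], rec$mle_ci[2], y, "#888888", "1"),
             dot(rec$mle_hr, y, "#888888"))
    if (is.null(rec$error))
      out <- c(out, seg(rec$posterior_ci[1], rec$posterior_ci[2], y + 6,
                        "#1f77b4", "1.5"),
               dot(rec$posterior_median_hr, y + 6, "#1f77b4"))
    y <- y + row_h
  }
  c(out, "</svg>")
}
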