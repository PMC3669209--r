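#' Configuration of the outcome-misclassification bias simulation
#'
#' Describes a two-group survival study in which the death outcome is
#' ascertained with imperfect, possibly group-specific sensitivity (and
#' near-perfect specificity): event times are exponential at group-specific
#' hazards, censoring is administrative (plus optional random censoring),
#' and the claims-based outcome keeps a true event with the group's
#' sensitivity and flips a non-event with probability 1 - specificity.
#'
#' @param n_exposed,n_reference group sizes.
#' @param true_hr true hazard ratio (exposed vs reference).
#' @param baseline_rate event rate in the reference group, per 100
#'   person-years.
#' @param followup_months administrative censoring time.
#' @param sensitivity_exposed,sensitivity_reference per-group probabilities
#'   that a true death is ascertained.
#' @param specificity probability a survivor is not falsely called dead;
#'   defaults to 1 (claims-based death definitions have specificity above
#'   99.9%).
#' @param censoring_rate rate of random (drop-out) censoring per 100
#'   person-years; 0 disables it.
#' @param replicates Monte-Carlo replicates for [run_bias_experiment()].
#' @return A list of class `"bias_sim_config"`.
#' @export
bias_sim_config <- function(n_exposed, n_reference, true_hr,
                            baseline_rate, followup_months,
                            sensitivity_exposed = 1,
                            sensitivity_reference = 1,
                            specificity = 1,
                            censoring_rate = 0,
                            replicates = 500L) {
  cfg <- list(n_exposed = as.integer(n_exposed),
              n_reference = as.integer(n_reference),
              true_hr = true_hr, baseline_rate = baseline_rate,
              followup_months = followup_months,
              sensitivity_exposed = sensitivity_exposed,
              sensitivity_reference = sensitivity_reference,
              specificity = specificity, censoring_rate = censoring_rate,
              replicates = as.integer(replicates))
  probs <- c(cfg$sensitivity_exposed, cfg$sensitivity_reference,
             cfg$specificity)
  if (any(probs < 0 | probs > 1))
    stop("sensitivities and specificity must lie in [0, 1]", call. = FALSE)
  if (cfg$true_hr <= 0 || cfg$baseline_rate <= 0 ||
      cfg$followup_months <= 0)
    stop("true_hr, baseline_rate and followup_months must be positive",
         call. = FALSE)
  if (cfg$censoring_rate < 0)
    stop("censoring_rate must be non-negative", call. = FALSE)
  if (cfg$n_exposed < 1L || cfg$n_reference < 1L)
    stop("group sizes must be >= 1", call. = FALSE)
  structure(cfg, class = "bias_sim_config")
}

#' Preset study configurations
#'
#' Two named presets emulate the structure of example pharmacoepidemiology
#' studies run with a claims-based death outcome.  `"study1"` is a small
#' two-arm anticancer-drug comparison in a high-sensitivity subgroup
#' (ascertainment nearly complete in both arms).  `"study2"` is an
#' antidepressant-class comparison with strongly differential sensitivity:
#' the exposed (SSRI) arm consists of patients in whom claims-based
#' ascertainment misses most deaths, while the reference arm is enriched
#' with advanced-cancer patients whose deaths are almost always captured.
#' Group sizes, death counts and rates follow the published example
#' studies; sensitivities are the observed claims/gold death-count ratios.
#'
#' @param name `"study1"` or `"study2"`.
#' @param replicates Monte-Carlo replicates.
#' @return A [bias_sim_config()].
#' @export
bias_preset <- function(name = c("study1", "study2"), replicates = 500L) {
  name <- match.arg(name)
  switch(name,
    study1 = bias_sim_config(
      n_exposed = 146L, n_reference = 27L, true_hr = 0.71,
      baseline_rate = 34.0, followup_months = 18,
      sensitivity_exposed = 1, sensitivity_reference = 9 / 10,
      replicates = replicates),
    study2 = bias_sim_config(
      n_exposed = 3362L, n_reference = 878L, true_hr = 0.27,
      baseline_rate = 2.07, followup_months = 20,
      sensitivity_exposed = 7 / 23, sensitivity_reference = 27 / 30,
      replicates = replicates))
}

#' Simulate one two-group survival dataset with misclassified outcomes
#'
#' Event times are exponential with the reference hazard
#' `baseline_rate / 100 / 12` per month and the exposed hazard scaled by
#' `true_hr`; follow-up is cut administratively at `followup_months` (and
#' by random censoring when configured).  The misclassified indicator
#' keeps a true observed event with the group's sensitivity and flips a
#' censored patient to an event (at the censoring time) with probability
#' `1 - specificity`.  Age and sex covariates are generated independently
#' of group, so they are pure noise in the Cox fit.
#'
#' @param config a [bias_sim_config()].
#' @param seed integer seed.
#' @return data.frame: `group` (1 exposed / 0 reference), `age`, `sex`,
#'   `time` (months), `event_true`, `event_obs`.
#' @export
simulate_two_group <- function(config, seed = 1L) {
  stopifnot(inherits(config, "bias_sim_config"))
  set.seed(seed)
  n <- config$n_exposed + config$n_reference
  group <- rep(c(1L, 0L), c(config$n_exposed, config$n_reference))
  h0 <- config$baseline_rate / 100 / 12
  hazard <- h0 * ifelse(group == 1L, config$true_hr, 1)
  t_event <- stats::rexp(n, hazard)
  t_cens <- rep(config$followup_months, n)
  if (config$censoring_rate > 0)
    t_cens <- pmin(t_cens, stats::rexp(n, config$censoring_rate / 100 / 12))
  time <- pmin(t_event, t_cens)
  event_true <- as.integer(t_event <= t_cens)

  sens <- ifelse(group == 1L, config$sensitivity_exposed,
                 config$sensitivity_reference)
  keep <- stats::runif(n) < sens
  flip <- stats::runif(n) < (1 - config$specificity)
  event_obs <- as.integer(ifelse(event_true == 1L, keep, flip))

  data.frame(group = group,
             age = round(stats::rnorm(n, 50, 10)),
             sex = rep_len(c(0L, 1L), n),
             time = time, event_true = event_true, event_obs = event_obs)
}

#' Age- and sex-adjusted hazard ratio
#'
#' Cox proportional-hazards fit of the chosen event indicator on group,
#' adjusted for age and sex, with the model-based (Wald) confidence
#' interval and the precision defined as the inverse variance of the log
#' hazard ratio.
#'
#' @param data a dataset from [simulate_two_group()].
#' @param outcome which indicator to use: `"event_true"` or `"event_obs"`.
#' @param level confidence level.
#' @return A list of class `"hr_estimate"`: `hr`, `ci`, `log_hr`,
#'   `log_hr_variance`, `precision`, `n_events`.
#' @export
estimate_hazard_ratio <- function(data, outcome = c("event_true",
                                                    "event_obs"),
                                  level = 0.95) {
  outcome <- match.arg(outcome)
  ev <- data[[outcome]]
  by_group <- tapply(ev, data$group, sum)
  if (any(by_group == 0))
    stop("no events in group(s): ",
         paste(names(by_group)[by_group == 0], collapse = ", "),
         call. = FALSE)
  fit <- survival::coxph(
    survival::Surv(time, ev) ~ group + age + sex,
    data = cbind(data, ev = ev))
  b <- stats::coef(fit)[["group"]]
  v <- stats::vcov(fit)["group", "group"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(hr = exp(b),
                 ci = c(lo = exp(b - z * sqrt(v)), hi = exp(b + z * sqrt(v))),
                 log_hr = b, log_hr_variance = v, precision = 1 / v,
                 n_events = sum(ev)),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("HR %.3f (%.3f-%.3f), precision %.1f, %d events\n",
              x$hr, x$ci[["lo"]], x$ci[["hi"]], x$precision, x$n_events))
  invisible(x)
}

#' Expected observed hazard ratio under differential sensitivity
#'
#' In the rare-outcome, perfect-specificity regime, thinning each group's
#' events by its sensitivity multiplies the hazard ratio by the sensitivity
#' ratio: `true_hr * sens_exposed / sens_reference`.  Non-differential
#' sensitivity therefore leaves the hazard ratio unchanged, while lower
#' sensitivity in the exposed group biases it downward.
#'
#' @param true_hr true hazard ratio.
#' @param sens_exposed,sens_reference group sensitivities.
#' @return Numeric.
#' @examples
#' expected_observed_hr(0.27, 7 / 23, 27 / 30)   # about 0.091
#' @export
expected_observed_hr <- function(true_hr, sens_exposed, sens_reference) {
  if (sens_reference <= 0)
    stop("sens_reference must be positive", call. = FALSE)
  true_hr * sens_exposed / sens_reference
}

#' Monte-Carlo bias experiment
#'
#' Replicates the two-group study, estimating the hazard ratio once with
#' the true outcome (gold standard) and once with the misclassified one
#' (claims-based), and summarises bias, precision and CI coverage.
#' Precision is reported both model-based (mean inverse variance of the
#' log HR) and empirical (inverse variance of the log HR across
#' replicates).
#'
#' @param config a [bias_sim_config()] or [bias_preset()].
#' @param seed integer seed; replicate r uses seed + r.
#' @return An object of class `"bias_experiment"` with the per-replicate
#'   estimates and a summary list.
#' @export
run_bias_experiment <- function(config, seed = 1L) {
  stopifnot(inherits(config, "bias_sim_config"))
  if (config$replicates < 100L)
    warning("fewer than 100 replicates: summaries will be noisy",
            call. = FALSE)
  reps <- lapply(seq_len(config$replicates), function(r) {
    d <- simulate_two_group(config, seed = seed + r)
    gold <- estimate_hazard_ratio(d, "event_true")
    obs <- tryCatch(estimate_hazard_ratio(d, "event_obs"),
                    error = function(e) NULL)
    data.frame(replicate = r,
               hr_gold = gold$hr, log_hr_gold = gold$log_hr,
               var_gold = gold$log_hr_variance,
               hr_obs = if (is.null(obs)) NA_real_ else obs$hr,
               log_hr_obs = if (is.null(obs)) NA_real_ else obs$log_hr,
               var_obs = if (is.null(obs)) NA_real_ else obs$log_hr_variance,
               lo_obs = if (is.null(obs)) NA_real_ else obs$ci[["lo"]],
               hi_obs = if (is.null(obs)) NA_real_ else obs$ci[["hi"]])
  })
  reps <- do.call(rbind, reps)
  ok <- !is.na(reps$log_hr_obs)
  expected <- expected_observed_hr(config$true_hr,
                                   config$sensitivity_exposed,
                                   config$sensitivity_reference)
  summary <- list(
    true_hr = config$true_hr,
    expected_observed_hr = expected,
    mean_hr_gold = exp(mean(reps$log_hr_gold)),
    mean_hr_obs = exp(mean(reps$log_hr_obs[ok])),
    mean_log_hr_bias_gold = mean(reps$log_hr_gold) - log(config$true_hr),
    mean_log_hr_bias_obs = mean(reps$log_hr_obs[ok]) - log(config$true_hr),
    mc_se_log_hr_obs = stats::sd(reps$log_hr_obs[ok]) / sqrt(sum(ok)),
    precision_model_gold = mean(1 / reps$var_gold),
    precision_model_obs = mean(1 / reps$var_obs[ok]),
    precision_empirical_gold = 1 / stats::var(reps$log_hr_gold),
    precision_empirical_obs = 1 / stats::var(reps$log_hr_obs[ok]),
    coverage_obs = mean(reps$lo_obs[ok] <= expected &
                          expected <= reps$hi_obs[ok]),
    n_failed = sum(!ok),
    replicates = config$replicates)
  structure(list(replicates = reps, summary = summary, config = config),
            class = "bias_experiment")
}

#' @export
print.bias_experiment <- function(x, ...) {
  s <- x$summary
  cat("Outcome-misclassification bias experiment\n")
  cat(sprintf("  %d replicates; true HR %.3f, thinning-expected observed HR %.3f\n",
              s$replicates, s$true_hr, s$expected_observed_hr))
  cat(sprintf("  mean HR  gold %.3f | claims-based %.3f\n",
              s$mean_hr_gold, s$mean_hr_obs))
  cat(sprintf("  mean log-HR bias vs true: gold %+.4f | claims-based %+.4f\n",
              s$mean_log_hr_bias_gold, s$mean_log_hr_bias_obs))
  cat(sprintf("  precision (1/var log HR, model-based): gold %.1f | claims-based %.1f\n",
              s$precision_model_gold, s$precision_model_obs))
  cat(sprintf("  95%% CI coverage of expected observed HR: %.1f%%\n",
              100 * s$coverage_obs))
  if (s$n_failed > 0)
    cat(sprintf("  %d replicate(s) had no observed events in a group\n",
                s$n_failed))
  invisible(x)
}

#' @export
summary.bias_experiment <- function(object, ...) object$summary
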