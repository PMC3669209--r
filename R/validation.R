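#' Patient-level confusion table against the enrollment gold standard
#'
#' Cross-classifies definition-positive status against the gold-standard
#' death flag at the patient level; assigned months are deliberately not
#' matched to death months (agreement is about who died, not when).
#'
#' @param calls death calls from [ascertain_cohort()].
#' @param cohort the [claims_cohort()] the calls were produced from.
#' @param reclassify_ambiguous_disenrollment treat a patient whose
#'   disenrollment month equals the call month but whose disenrollment
#'   reason is not death as a true death rather than a false positive.
#'   Default `FALSE`: such patients count against the definition, the
#'   conservative reading of the enrollment file.
#' @return A list of class `"confusion_table"` with integer fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion <- function(calls, cohort,
                      reclassify_ambiguous_disenrollment = FALSE) {
  stopifnot(inherits(cohort, "claims_cohort"))
  enr <- cohort$enrollment
  unknown <- setdiff(calls$patient_id, enr$patient_id)
  if (length(unknown))
    stop("death call(s) for patient id(s) absent from the cohort: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  positive <- enr$patient_id %in% calls$patient_id
  gold <- enr$gold_dead
  if (reclassify_ambiguous_disenrollment) {
    i <- match(enr$patient_id, calls$patient_id)
    call_month <- unclass(calls$call_month)[i]
    ambiguous <- positive & !gold &
      !is.na(unclass(enr$disenroll_month)) &
      unclass(enr$disenroll_month) == call_month &
      (is.na(enr$disenroll_reason) | enr$disenroll_reason != "death")
    gold <- gold | ambiguous
  }
  confusion_table(tp = sum(positive & gold), fp = sum(positive & !gold),
                  fn = sum(!positive & gold), tn = sum(!positive & !gold))
}

#' Build a confusion table from its four cells
#'
#' @param tp,fp,fn,tn non-negative integer cell counts (definition-positive
#'   vs gold-standard dead).
#' @return A list of class `"confusion_table"`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0))
    stop("confusion cells must be non-negative", call. = FALSE)
  structure(stats::setNames(as.list(as.integer(cells)), names(cells)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(`gold standard` = c("dead", "alive"),
                              definition = c("positive", "negative")))
  cat("Patient-level agreement with the enrollment gold standard\n")
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param level confidence level, default 0.95.
#' @return `c(lo, hi)` on the proportion scale; `lo = 0` when `k = 0` and
#'   `hi = 1` when `k = n`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  stopifnot(k >= 0, k <= n)
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

wilson_interval <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, mid - half), hi = min(1, mid + half))
}

#' Sensitivity, specificity and PPV of a definition
#'
#' Point estimates are percentages: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, PPV `tp/(tp+fp)`.  Reporting convention: percentages are
#' rounded half-up to one decimal except specificity, reported to two
#' decimals (it lives above 99.9% for usable definitions).  A metric whose
#' denominator is zero is returned as `NA` and flagged, never silently 0.
#'
#' @param table a [confusion_table()].
#' @param level confidence level for the intervals, default 0.95.
#' @param ci_method `"clopper-pearson"` (exact, the default) or `"wilson"`.
#' @return A list of class `"validity_metrics"`: for each metric the raw
#'   proportion, the rounded percentage and the CI bounds (percent), plus
#'   `n_positive` and `n_true_positive`.
#' @export
validity_metrics <- function(table, level = 0.95,
                             ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(table, "confusion_table"))
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, "clopper-pearson" = clopper_pearson,
                   "wilson" = wilson_interval)
  one <- function(k, n, digits) {
    if (n == 0)
      return(list(prop = NA_real_, pct = NA_real_, lo = NA_real_,
                  hi = NA_real_, undefined = TRUE))
    ci <- ci_fun(k, n, level)
    list(prop = k / n, pct = round_half_up(100 * k / n, digits),
         lo = round_half_up(100 * ci[["lo"]], digits),
         hi = round_half_up(100 * ci[["hi"]], digits), undefined = FALSE)
  }
  structure(list(
    sensitivity = one(table$tp, table$tp + table$fn, 1),
    specificity = one(table$tn, table$tn + table$fp, 2),
    ppv = one(table$tp, table$tp + table$fp, 1),
    n_positive = table$tp + table$fp,
    n_true_positive = table$tp,
    level = level, ci_method = ci_method,
    table = table
  ), class = "validity_metrics")
}

#' @export
print.validity_metrics <- function(x, ...) {
  fmt <- function(m, name) {
    if (m$undefined) sprintf("  %-12s undefined (zero denominator)\n", name)
    else sprintf("  %-12s %s%% (%s-%s)\n", name,
                 format(m$pct), format(m$lo), format(m$hi))
  }
  cat(sprintf("Validity vs gold standard (%d positive, %d true positive)\n",
              x$n_positive, x$n_true_positive))
  cat(fmt(x$sensitivity, "sensitivity"))
  cat(fmt(x$specificity, "specificity"))
  cat(fmt(x$ppv, "PPV"))
  cat(sprintf("  %g%% CIs by %s\n", 100 * x$level, x$ci_method))
  invisible(x)
}

#' Standardized difference of two proportions
#'
#' `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`, the scale-free
#' imbalance measure used to compare characteristics between groups.
#' Returns 0 when both variances vanish and the proportions are equal.
#'
#' @param p1,p2 proportions in `[0, 1]`.
#' @return Non-negative numeric.
#' @examples
#' standardized_difference(66/285, 43/395)
#' @export
standardized_difference <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (denom == 0) {
    if (p1 == p2) return(0)
    return(Inf)
  }
  abs(p1 - p2) / denom
}

#' Validate death definitions against the gold standard
#'
#' The central validation engine: applies each requested definition to the
#' cohort, cross-classifies against the enrollment gold standard and
#' reports sensitivity, specificity and PPV with exact binomial confidence
#' intervals — one row per definition, the layout of a validation-study
#' results table.
#'
#' @param cohort a [claims_cohort()].
#' @param definitions character vector of definition ids (default all nine).
#' @param params a [definition_params()].
#' @param map a [cci_map()].
#' @param level confidence level, default 0.95.
#' @param ci_method `"clopper-pearson"` or `"wilson"`.
#' @param reclassify_ambiguous_disenrollment see [confusion()].
#' @return An object of class `"death_validation"`: a data.frame with one
#'   row per definition (`definition`, `n_positive`, `tp`, `fp`, `fn`, `tn`,
#'   point estimates and CI bounds in percent), with the calls and cohort
#'   sizes in attributes.  Has `print`, `summary` and `plot` methods.
#' @export
validate_definitions <- function(cohort,
                                 definitions = death_definitions(),
                                 params = definition_params(),
                                 map = cci_map(),
                                 level = 0.95,
                                 ci_method = c("clopper-pearson", "wilson"),
                                 reclassify_ambiguous_disenrollment = FALSE) {
  ci_method <- match.arg(ci_method)
  bad <- setdiff(definitions, death_definitions())
  if (length(bad)) stop("unknown definition id(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  features <- definition_features(cohort, params, map)
  calls <- lapply(definitions, function(d)
    ascertain_cohort(cohort, d, params, map, features = features,
                     quiet = TRUE))
  names(calls) <- definitions
  rows <- lapply(definitions, function(d) {
    ct <- confusion(calls[[d]], cohort,
                    reclassify_ambiguous_disenrollment)
    vm <- validity_metrics(ct, level, ci_method)
    data.frame(definition = d, n_positive = vm$n_positive,
               tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
               sensitivity = vm$sensitivity$pct,
               sens_lo = vm$sensitivity$lo, sens_hi = vm$sensitivity$hi,
               specificity = vm$specificity$pct,
               spec_lo = vm$specificity$lo, spec_hi = vm$specificity$hi,
               ppv = vm$ppv$pct, ppv_lo = vm$ppv$lo, ppv_hi = vm$ppv$hi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("death_validation", "data.frame"),
            calls = calls,
            n_gold_dead = sum(cohort$enrollment$gold_dead),
            n_beneficiaries = nrow(cohort$enrollment),
            level = level, ci_method = ci_method)
}

#' @export
print.death_validation <- function(x, ...) {
  cat(sprintf(
    "Claims-based death definitions vs enrollment gold standard\n"))
  cat(sprintf("  %d beneficiaries, %d gold-standard deaths\n\n",
              attr(x, "n_beneficiaries"), attr(x, "n_gold_dead")))
  df <- as.data.frame(x)
  show <- data.frame(
    definition = df$definition,
    `N (TP)` = sprintf("%d (%d)", df$n_positive, df$tp),
    sensitivity = sprintf("%.1f (%.1f-%.1f)", df$sensitivity, df$sens_lo,
                          df$sens_hi),
    specificity = sprintf("%.2f (%.2f-%.2f)", df$specificity, df$spec_lo,
                          df$spec_hi),
    PPV = sprintf("%.1f (%.1f-%.1f)", df$ppv, df$ppv_lo, df$ppv_hi),
    check.names = FALSE)
  print(show, row.names = FALSE, right = FALSE)
  cat(sprintf("\n  percentages; %g%% CIs by %s\n",
              100 * attr(x, "level"), attr(x, "ci_method")))
  invisible(x)
}

#' @export
summary.death_validation <- function(object, ...) {
  df <- as.data.frame(object)
  best <- df$definition[which.max(df$sensitivity)]
  cat(sprintf("%d definitions validated on %d beneficiaries (%d deaths)\n",
              nrow(df), attr(object, "n_beneficiaries"),
              attr(object, "n_gold_dead")))
  cat(sprintf("  sensitivity range %.1f-%.1f%%, highest under definition %s\n",
              min(df$sensitivity), max(df$sensitivity), best))
  cat(sprintf("  specificity >= %.2f%%, PPV range %.1f-%.1f%%\n",
              min(df$specificity), min(df$ppv), max(df$ppv)))
  invisible(object)
}

#' @export
plot.death_validation <- function(x, metric = c("sensitivity", "ppv"), ...) {
  metric <- match.arg(metric)
  df <- as.data.frame(x)
  lo <- df[[if (metric == "ppv") "ppv_lo" else "sens_lo"]]
  hi <- df[[if (metric == "ppv") "ppv_hi" else "sens_hi"]]
  est <- df[[metric]]
  n <- nrow(df)
  graphics::plot(est, seq_len(n), xlim = c(0, 100), yaxt = "n",
                 xlab = paste(metric, "(%)"), ylab = "",
                 pch = 19, ...)
  graphics::segments(lo, seq_len(n), hi, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = df$definition, las = 1)
  invisible(x)
}

#' Subgroup predicates for stratified validation
#'
#' Builders returning named predicate functions over a per-patient
#' data.frame (the enrollment table augmented with claims-derived columns;
#' see [subgroup_validate()]).  Available strata mirror the usual
#' validation-study breakdown: sex, age bands at observation end,
#' beneficiary type, hospitalization in the year before observation end,
#' setting of the last claim, an ICD-10 diagnosis flag and a drug-code flag.
#'
#' @param prefixes character vector of ICD-10 prefixes (dot-insensitive).
#' @param codes character vector of drug codes.
#' @param name stratum label.
#' @return Named list of predicate functions.
#' @export
subgroup_sex <- function() {
  list(male = function(p) p$sex == "M",
       female = function(p) p$sex == "F")
}

#' @rdname subgroup_sex
#' @export
subgroup_age_bands <- function() {
  list(`age 20-39` = function(p) p$age <= 39,
       `age 40-59` = function(p) p$age >= 40 & p$age <= 59,
       `age 60-74` = function(p) p$age >= 60)
}

#' @rdname subgroup_sex
#' @export
subgroup_beneficiary <- function() {
  list(employee = function(p) p$beneficiary_type == "employee",
       `family member` = function(p) p$beneficiary_type == "family")
}

#' @rdname subgroup_sex
#' @export
subgroup_hospitalized_prior_year <- function() {
  list(`hospitalized in preceding year` = function(p) p$hospitalized_prior_year)
}

#' @rdname subgroup_sex
#' @export
subgroup_last_claim_setting <- function() {
  list(`last claim outpatient` = function(p)
         !is.na(p$last_claim_setting) & p$last_claim_setting == "outpatient",
       `last claim inpatient` = function(p)
         !is.na(p$last_claim_setting) & p$last_claim_setting == "inpatient")
}

#' @rdname subgroup_sex
#' @export
subgroup_icd10_flag <- function(prefixes, name = paste0("diagnosis ",
                                                        prefixes[1])) {
  prefixes <- normalize_icd10(prefixes)
  out <- list(function(p) vapply(p$icd10_all, function(codes)
    any(outer(normalize_icd10(codes), prefixes, startsWith)), logical(1)))
  names(out) <- name
  out
}

#' @rdname subgroup_sex
#' @export
subgroup_drug_flag <- function(codes, name = paste0("drug ", codes[1])) {
  out <- list(function(p) vapply(p$drug_all, function(d)
    any(d %in% codes), logical(1)))
  names(out) <- name
  out
}

# per-patient table the subgroup predicates evaluate on
subgroup_frame <- function(cohort) {
  enr <- cohort$enrollment
  cl <- cohort$claims
  ids <- enr$patient_id
  m <- unclass(cl$claim_month)
  age <- ym_year(enr$observation_end) - enr$birth_year
  obs_end <- unclass(enr$observation_end)

  inp <- cl$setting == "inpatient"
  oe_of <- obs_end[match(cl$patient_id, ids)]
  recent_inp <- inp & m >= oe_of - 11L & m <= oe_of
  hosp <- ids %in% cl$patient_id[recent_inp]

  last_any <- group_max(m, cl$patient_id, ids)
  # setting of (a) claim in the patient's last claim month; inpatient wins
  # when both settings appear in that month
  at_last <- m == last_any[match(cl$patient_id, ids)]
  at_last[is.na(at_last)] <- FALSE
  last_setting <- rep(NA_character_, length(ids))
  lo <- tapply(inp[at_last], cl$patient_id[at_last], any)
  last_setting[match(names(lo), ids)] <-
    ifelse(unlist(lo), "inpatient", "outpatient")

  icd_all <- lapply(split(cl$icd10_codes, factor(cl$patient_id, ids)),
                    function(s) unique(unlist(lapply(s, split_codes))))
  drug_all <- lapply(split(cl$drug_codes, factor(cl$patient_id, ids)),
                     function(s) unique(unlist(lapply(s, split_codes))))

  out <- enr
  out$age <- age
  out$hospitalized_prior_year <- hosp
  out$last_claim_setting <- last_setting
  out$icd10_all <- unname(icd_all)
  out$drug_all <- unname(drug_all)
  out
}

#' Stratified validation of one definition
#'
#' Restricts the confusion computation to the patients satisfying each
#' subgroup predicate, using the stratum's own denominators for all three
#' metrics.  Empty strata are flagged rather than divided by zero.
#'
#' @param cohort a [claims_cohort()].
#' @param calls death calls for one definition (see [ascertain_cohort()]).
#' @param subgroups named list of predicate functions, e.g.
#'   `c(subgroup_sex(), subgroup_age_bands())`.
#' @param level confidence level.
#' @param ci_method `"clopper-pearson"` or `"wilson"`.
#' @return data.frame, one row per stratum: stratum size, confusion cells,
#'   the three metrics (percent) and their CIs; `empty` flags strata with
#'   no patients.
#' @export
subgroup_validate <- function(cohort, calls, subgroups,
                              level = 0.95,
                              ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  frame <- subgroup_frame(cohort)
  positive <- frame$patient_id %in% calls$patient_id
  gold <- frame$gold_dead
  rows <- lapply(names(subgroups), function(nm) {
    sel <- subgroups[[nm]](frame)
    if (anyNA(sel)) sel[is.na(sel)] <- FALSE
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(stratum = nm, n = 0L, n_deaths = 0L, tp = 0L,
                        fp = 0L, fn = 0L, tn = 0L, sensitivity = NA_real_,
                        sens_lo = NA_real_, sens_hi = NA_real_,
                        specificity = NA_real_, spec_lo = NA_real_,
                        spec_hi = NA_real_, ppv = NA_real_,
                        ppv_lo = NA_real_, ppv_hi = NA_real_, empty = TRUE))
    ct <- confusion_table(tp = sum(sel & positive & gold),
                          fp = sum(sel & positive & !gold),
                          fn = sum(sel & !positive & gold),
                          tn = sum(sel & !positive & !gold))
    vm <- validity_metrics(ct, level, ci_method)
    data.frame(stratum = nm, n = n, n_deaths = ct$tp + ct$fn,
               tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
               sensitivity = vm$sensitivity$pct,
               sens_lo = vm$sensitivity$lo, sens_hi = vm$sensitivity$hi,
               specificity = vm$specificity$pct,
               spec_lo = vm$specificity$lo, spec_hi = vm$specificity$hi,
               ppv = vm$ppv$pct, ppv_lo = vm$ppv$lo, ppv_hi = vm$ppv$hi,
               empty = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
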