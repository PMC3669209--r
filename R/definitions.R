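#' Tuning parameters of the claims-based death definitions
#'
#' @param zombie_short_max_months largest gap (months after the index claim)
#'   at which a post-index claim still counts as a short-term "zombie"
#'   (reimbursement lag); gaps beyond it are long-term (presumed miscoding).
#'   Default 2.
#' @param cci_threshold Charlson score at or above which an admission counts
#'   as "serious". Default 6.
#' @param blank_min_months minimum claim-free months between the last claim
#'   and the study end for the blank-period criterion. Default 6.
#' @param lookback_months length of the window before the last inpatient
#'   month searched for an earlier high-CCI claim. Default 12.
#' @return A list of class `"definition_params"`.
#' @export
definition_params <- function(zombie_short_max_months = 2L,
                              cci_threshold = 6L,
                              blank_min_months = 6L,
                              lookback_months = 12L) {
  out <- list(zombie_short_max_months = as.integer(zombie_short_max_months),
              cci_threshold = as.integer(cci_threshold),
              blank_min_months = as.integer(blank_min_months),
              lookback_months = as.integer(lookback_months))
  if (any(vapply(out, function(v) is.na(v) || v < 1L, logical(1))))
    stop("all definition parameters must be positive integers",
         call. = FALSE)
  structure(out, class = "definition_params")
}

#' Read definition parameters from a YAML file
#'
#' The file may set any subset of the [definition_params()] fields; the
#' rest keep their defaults.
#'
#' @param path YAML file.
#' @return A `definition_params` object.
#' @export
read_params_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs",
         call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(definition_params))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown parameter(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(definition_params, vals)
}

#' The nine definition identifiers
#' @return Character vector `"1.1"` ... `"3.3"`.
#' @export
death_definitions <- function() {
  c("1.1", "1.2", "1.3", "2.1", "2.2", "2.3", "3.1", "3.2", "3.3")
}

#' Index claim of a patient
#'
#' The index claim is the earliest claim (inpatient or outpatient) whose
#' discharge/disease status is "death".  When several death-status claims
#' exist, the earliest one is the index; later death-status claims are
#' neither zombies nor new index claims.
#'
#' @param history a `patient_history` (see [patient_histories()]).
#' @return A one-row claims data.frame, or `NULL` when the patient has no
#'   death-status claim.
#' @export
find_index_claim <- function(history) {
  cl <- history$claims
  dead <- which(cl$status == "death")
  if (!length(dead)) return(NULL)
  best <- dead[which.min(unclass(cl$claim_month)[dead])]
  cl[best, , drop = FALSE]
}

#' Zombie-claim status after the index claim
#'
#' Zombie claims are claims without death status issued in months after the
#' index claim.  Classified by the largest month gap among them: `"none"`
#' (no such claim), `"short_term"` (all within `zombie_short_max_months`,
#' the reimbursement-lag pattern) or `"long_term"` (some gap beyond it,
#' the presumed-miscoding pattern).  Later death-status claims are not
#' zombies.
#'
#' @param history a `patient_history`.
#' @param index the index claim, as returned by [find_index_claim()].
#' @param params a [definition_params()].
#' @return `"none"`, `"short_term"` or `"long_term"`.
#' @export
zombie_status <- function(history, index, params = definition_params()) {
  stopifnot(!is.null(index), index$status == "death")
  cl <- history$claims
  gaps <- unclass(cl$claim_month) - unclass(index$claim_month)
  gaps <- gaps[cl$status != "death" & gaps > 0L]
  if (!length(gaps)) return("none")
  if (max(gaps) <= params$zombie_short_max_months) "short_term"
  else "long_term"
}

#' Charlson score of the last inpatient claim
#'
#' Finds the latest month holding any inpatient claim and scores the ICD-10
#' codes pooled across that month's inpatient claims (monthly claims
#' fragment one admission, so same-month inpatient claims are one episode).
#'
#' @param history a `patient_history`.
#' @param map a [cci_map()].
#' @return `list(month = <ym>, score = <int>)`, or `NULL` when the patient
#'   has no inpatient claim.
#' @export
last_inpatient_cci <- function(history, map = cci_map()) {
  cl <- history$claims
  inp <- cl[cl$setting == "inpatient", , drop = FALSE]
  if (!nrow(inp)) return(NULL)
  m <- max(unclass(inp$claim_month))
  codes <- unlist(lapply(inp$icd10_codes[unclass(inp$claim_month) == m],
                         split_codes))
  list(month = new_ym(m), score = cci_score(codes, map))
}

#' Claim-free months before the study end
#'
#' Number of whole months strictly after the patient's last claim of any
#' kind, counted through the study end month; 0 when a claim falls in the
#' final month.
#'
#' @param history a `patient_history`.
#' @param study_end the study end month (defaults to the cohort's).
#' @return Integer, or `NA` for a claimless patient.
#' @export
blank_months <- function(history, study_end = history$study_end) {
  if (!nrow(history$claims)) return(NA_integer_)
  unclass(as_ym_scalar(study_end)) - max(unclass(history$claims$claim_month))
}

#' High-CCI claim in the lookback window
#'
#' Tests whether any claim (either setting, scored claim by claim) issued in
#' the `lookback_months` months preceding the anchor month — the window
#' `[anchor - lookback, anchor - 1]`, boundary included, anchor excluded —
#' reaches the CCI threshold.
#'
#' @param history a `patient_history`.
#' @param anchor anchor month (`ym`), normally the last-inpatient month.
#' @param map a [cci_map()].
#' @param params a [definition_params()].
#' @return Logical.
#' @export
lookback_cci_met <- function(history, anchor, map = cci_map(),
                             params = definition_params()) {
  cl <- history$claims
  if (!nrow(cl)) return(FALSE)
  a <- unclass(as_ym_scalar(anchor))
  m <- unclass(cl$claim_month)
  inwin <- m >= a - params$lookback_months & m <= a - 1L
  if (!any(inwin)) return(FALSE)
  any(cci_score_strings(cl$icd10_codes[inwin], map) >= params$cci_threshold)
}

#' Apply one death definition to one patient
#'
#' The definition family:
#' \describe{
#'   \item{1.1}{a death-status claim exists (the index claim).}
#'   \item{1.2}{1.1 and no zombie claims at all.}
#'   \item{1.3}{1.1 and no long-term zombie claims.}
#'   \item{2.1}{Charlson score of the last inpatient claim at or above the
#'     threshold.}
#'   \item{2.2}{2.1 and a claim-free period of at least `blank_min_months`
#'     through the study end.}
#'   \item{2.3}{2.2 and a high-CCI claim in the lookback window before the
#'     last inpatient month.}
#'   \item{3.k}{1.3 or 2.k (k = 1, 2, 3).}
#' }
#' The assigned death month is the index-claim month for 1.x, the
#' last-inpatient month for 2.x, and the earlier of the two for 3.x.
#'
#' @param history a `patient_history`.
#' @param definition_id one of [death_definitions()].
#' @param params a [definition_params()].
#' @param map a [cci_map()].
#' @return A one-row data.frame (`patient_id`, `definition_id`, `call_month`,
#'   `basis`) or `NULL` when the definition is negative.
#' @export
ascertain <- function(history, definition_id, params = definition_params(),
                      map = cci_map()) {
  definition_id <- as.character(definition_id)
  if (!definition_id %in% death_definitions())
    stop("unknown definition id: ", definition_id, call. = FALSE)

  index <- find_index_claim(history)
  zs <- if (is.null(index)) NULL else zombie_status(history, index, params)
  d1 <- list(
    "1.1" = !is.null(index),
    "1.2" = !is.null(index) && zs == "none",
    "1.3" = !is.null(index) && zs != "long_term")

  li <- last_inpatient_cci(history, map)
  d21 <- !is.null(li) && li$score >= params$cci_threshold
  d22 <- d21 && {
    b <- blank_months(history)
    !is.na(b) && b >= params$blank_min_months
  }
  d23 <- d22 && lookback_cci_met(history, li$month, map, params)
  d2 <- list("2.1" = d21, "2.2" = d22, "2.3" = d23)

  part <- substr(definition_id, 1, 1)
  k <- paste0("2.", substr(definition_id, 3, 3))
  pos1 <- if (part == "1") d1[[definition_id]] else d1[["1.3"]]
  pos2 <- if (part == "1") FALSE
          else d2[[if (part == "2") definition_id else k]]
  positive <- switch(part, "1" = pos1, "2" = pos2, "3" = pos1 || pos2)
  if (!positive) return(NULL)

  month1 <- if (pos1 && part != "2") unclass(index$claim_month) else NA_integer_
  month2 <- if (pos2 && part != "1") unclass(li$month) else NA_integer_
  call_month <- new_ym(min(month1, month2, na.rm = TRUE))
  basis <- if (part == "1") "status_claim"
           else if (part == "2") "cci_admission"
           else if (pos1 && pos2) "either"
           else if (pos1) "status_claim" else "cci_admission"
  out <- data.frame(patient_id = history$patient_id,
                    definition_id = definition_id, basis = basis)
  out$call_month <- call_month
  out[c("patient_id", "definition_id", "call_month", "basis")]
}

# Vectorised per-patient ingredients of every definition, computed in one
# pass over the claims table (patients absent from it are all-negative).
definition_features <- function(cohort, params = definition_params(),
                                map = cci_map()) {
  stopifnot(inherits(cohort, "claims_cohort"))
  ids <- cohort$enrollment$patient_id
  cl <- cohort$claims
  pid <- cl$patient_id
  m <- unclass(cl$claim_month)

  is_death <- cl$status == "death"
  index_month <- group_min(m[is_death], pid[is_death], ids)

  # largest gap of a non-death claim after the index claim
  idx_of <- index_month[match(pid, ids)]
  after <- !is_death & !is.na(idx_of) & m > idx_of
  max_after <- group_max(m[after], pid[after], ids)
  gap <- max_after - index_month
  zombie <- ifelse(is.na(index_month), NA_character_,
            ifelse(is.na(gap), "none",
            ifelse(gap <= params$zombie_short_max_months,
                   "short_term", "long_term")))

  inp <- cl$setting == "inpatient"
  last_inpat <- group_max(m[inp], pid[inp], ids)
  li_of <- last_inpat[match(pid, ids)]
  at_last <- inp & !is.na(li_of) & m == li_of
  pooled <- tapply(cl$icd10_codes[at_last], pid[at_last],
                   function(s) paste(s, collapse = ";"))
  last_inpat_cci <- rep(NA_integer_, length(ids))
  if (length(pooled))
    last_inpat_cci[match(names(pooled), ids)] <-
      cci_score_strings(unname(unlist(pooled)), map)

  last_any <- group_max(m, pid, ids)
  blank <- unclass(cohort$study_end) - last_any

  # any claim reaching the threshold within the lookback window before the
  # last inpatient month (scored claim by claim)
  claim_cci <- cci_score_strings(cl$icd10_codes, map)
  anchor <- last_inpat[match(pid, ids)]
  inwin <- !is.na(anchor) & m >= anchor - params$lookback_months &
    m <= anchor - 1L & claim_cci >= params$cci_threshold
  lookback_met <- ids %in% pid[inwin]

  out <- data.frame(patient_id = ids, zombie = zombie,
                    last_inpat_cci = last_inpat_cci, blank = blank,
                    lookback_met = lookback_met, stringsAsFactors = FALSE)
  out$index_month <- new_ym(index_month)
  out$last_inpat_month <- new_ym(last_inpat)
  out
}

# logical positives per patient for one definition, from the feature table
definition_positive <- function(features, definition_id,
                                params = definition_params()) {
  f <- features
  d11 <- !is.na(unclass(f$index_month))
  pos1 <- switch(substr(definition_id, 1, 1),
    "1" = switch(definition_id,
      "1.1" = d11,
      "1.2" = d11 & f$zombie == "none",
      "1.3" = d11 & f$zombie != "long_term"),
    d11 & f$zombie != "long_term")           # the 1.3 arm of 3.k
  pos1[is.na(pos1)] <- FALSE
  part <- substr(definition_id, 1, 1)
  if (part == "1") return(list(pos = pos1, pos1 = pos1,
                               pos2 = rep(FALSE, nrow(f))))
  k <- substr(definition_id, 3, 3)
  d21 <- !is.na(f$last_inpat_cci) & f$last_inpat_cci >= params$cci_threshold
  pos2 <- switch(k,
    "1" = d21,
    "2" = d21 & f$blank >= params$blank_min_months,
    "3" = d21 & f$blank >= params$blank_min_months & f$lookback_met)
  pos2[is.na(pos2)] <- FALSE
  if (part == "2") list(pos = pos2, pos1 = rep(FALSE, nrow(f)), pos2 = pos2)
  else list(pos = pos1 | pos2, pos1 = pos1, pos2 = pos2)
}

#' Apply a death definition to a whole cohort
#'
#' Vectorised equivalent of calling [ascertain()] on every patient; emits
#' the per-definition positive count as a message.
#'
#' @param cohort a [claims_cohort()].
#' @param definition_id one of [death_definitions()].
#' @param params a [definition_params()].
#' @param map a [cci_map()].
#' @param features optional precomputed feature table (internal reuse).
#' @param quiet suppress the count message.
#' @return data.frame of death calls: `patient_id`, `definition_id`,
#'   `call_month` (`ym`), `basis`.
#' @export
ascertain_cohort <- function(cohort, definition_id,
                             params = definition_params(), map = cci_map(),
                             features = NULL, quiet = FALSE) {
  definition_id <- as.character(definition_id)
  if (!definition_id %in% death_definitions())
    stop("unknown definition id: ", definition_id, call. = FALSE)
  if (is.null(features)) features <- definition_features(cohort, params, map)
  p <- definition_positive(features, definition_id, params)
  part <- substr(definition_id, 1, 1)
  month1 <- ifelse(p$pos1, unclass(features$index_month), NA_integer_)
  month2 <- ifelse(p$pos2, unclass(features$last_inpat_month), NA_integer_)
  call_month <- switch(part, "1" = month1, "2" = month2,
                       "3" = pmin(month1, month2, na.rm = TRUE))
  basis <- switch(part, "1" = "status_claim", "2" = "cci_admission",
                  "3" = ifelse(p$pos1 & p$pos2, "either",
                        ifelse(p$pos1, "status_claim", "cci_admission")))
  if (length(basis) == 1L) basis <- rep(basis, nrow(features))
  keep <- which(p$pos)
  if (!quiet)
    message("definition ", definition_id, ": ", length(keep), " positive of ",
            nrow(features), " beneficiaries")
  out <- data.frame(patient_id = features$patient_id[keep],
                    definition_id = rep(definition_id, length(keep)),
                    basis = basis[keep],
                    stringsAsFactors = FALSE)
  out$call_month <- new_ym(call_month[keep])
  rownames(out) <- NULL
  out[c("patient_id", "definition_id", "call_month", "basis")]
}
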