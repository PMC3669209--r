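#' Assemble a claims cohort
#'
#' Bundles monthly claims and enrollment records into a `claims_cohort`
#' object, the container every other function in the package operates on.
#' Per-patient observation end is derived as the earlier of the disenrollment
#' month and the administrative study end; the enrollment death month is the
#' gold-standard vital status.  Patients without any claim are retained: they
#' can never be definition-positive but they belong in the specificity
#' denominator.
#'
#' Claims dated after the study end month are dropped with a warning.  Claims
#' dated after a patient's disenrollment are kept: claims issued in the months
#' following a death-month disenrollment are exactly the "zombie" claims the
#' death definitions must screen, so they stay visible to ascertainment.
#'
#' @param claims data.frame with columns `patient_id`, `claim_month` (`ym` or
#'   "YYYY-MM"), `setting` ("inpatient"/"outpatient"), `status` ("death",
#'   "cure", "termination", "others"), `icd10_codes` (semicolon-separated,
#'   may be blank) and optionally `drug_codes`.
#' @param enrollment data.frame with columns `patient_id`, `sex` ("M"/"F"),
#'   `birth_year`, `beneficiary_type` ("employee"/"family"), `enroll_month`,
#'   `disenroll_month` (blank allowed), `disenroll_reason` ("death", "other",
#'   "unknown" or blank) and `death_month` (blank allowed).
#' @param study_end administrative end of the study period, a `ym` scalar or
#'   "YYYY-MM" string.
#' @return A list of class `"claims_cohort"` with elements `claims`,
#'   `enrollment` (augmented with `observation_end` and `gold_dead`) and
#'   `study_end`.
#' @seealso [read_cohort()] to load the documented CSV schema,
#'   [simulate_cohort()] to generate synthetic cohorts.
#' @export
claims_cohort <- function(claims, enrollment, study_end) {
  study_end <- as_ym_scalar(study_end)
  enrollment <- validate_enrollment(enrollment)
  claims <- validate_claims(claims)

  unknown <- setdiff(claims$patient_id, enrollment$patient_id)
  if (length(unknown))
    stop("claims reference patient ids absent from enrollment: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  late <- unclass(claims$claim_month) > unclass(study_end)
  if (any(late)) {
    warning(sum(late), " claim(s) after the study end month dropped",
            call. = FALSE)
    claims <- claims[!late, , drop = FALSE]
  }
  # stable sort: patients keep their input claim order within a month
  claims <- claims[order(match(claims$patient_id, enrollment$patient_id),
                         unclass(claims$claim_month)), , drop = FALSE]
  rownames(claims) <- NULL

  enrollment$observation_end <- observation_end(enrollment, study_end)
  enrollment$gold_dead <- !is.na(unclass(enrollment$death_month))

  bad <- !is.na(unclass(enrollment$disenroll_month)) &
    unclass(enrollment$enroll_month) > unclass(enrollment$disenroll_month)
  if (any(bad))
    stop("enrollment precedes disenrollment violated for patient(s): ",
         paste(utils::head(enrollment$patient_id[bad], 5), collapse = ", "),
         call. = FALSE)

  structure(list(claims = claims, enrollment = enrollment,
                 study_end = study_end),
            class = "claims_cohort")
}

as_ym_scalar <- function(x) {
  if (is.character(x)) x <- ym_parse(x)
  if (!inherits(x, "ym") || length(x) != 1L || is.na(unclass(x)))
    stop("expected a single non-missing month stamp", call. = FALSE)
  x
}

enum_check <- function(x, allowed, field, allow_na = FALSE) {
  bad <- !(x %in% allowed) & !(allow_na & is.na(x))
  if (any(bad))
    stop("invalid ", field, " value(s) in row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(utils::head(unique(x[bad]), 5), collapse = ", "),
         call. = FALSE)
  x
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

validate_claims <- function(claims) {
  require_columns(claims,
                  c("patient_id", "claim_month", "setting", "status",
                    "icd10_codes"), "claims table")
  claims$patient_id <- as.character(claims$patient_id)
  if (!inherits(claims$claim_month, "ym"))
    claims$claim_month <- ym_parse(claims$claim_month)
  claims$claim_month <- as_ym_column(claims$claim_month)
  if (anyNA(unclass(claims$claim_month)))
    stop("claim_month missing in row(s) ",
         paste(utils::head(which(is.na(unclass(claims$claim_month))), 5),
               collapse = ", "), call. = FALSE)
  enum_check(claims$setting, c("inpatient", "outpatient"), "setting")
  enum_check(claims$status, c("death", "cure", "termination", "others"),
             "status")
  claims$icd10_codes <- blank_to_empty(claims$icd10_codes)
  claims$drug_codes <- blank_to_empty(claims$drug_codes %||%
                                        rep("", nrow(claims)))
  claims[c("patient_id", "claim_month", "setting", "status",
           "icd10_codes", "drug_codes")]
}

validate_enrollment <- function(enrollment) {
  require_columns(enrollment,
                  c("patient_id", "sex", "birth_year", "beneficiary_type",
                    "enroll_month", "disenroll_month", "disenroll_reason",
                    "death_month"), "enrollment table")
  enrollment$patient_id <- as.character(enrollment$patient_id)
  if (anyDuplicated(enrollment$patient_id))
    stop("duplicated patient_id in enrollment", call. = FALSE)
  enum_check(enrollment$sex, c("M", "F"), "sex")
  enrollment$birth_year <- as.integer(enrollment$birth_year)
  enum_check(enrollment$beneficiary_type, c("employee", "family"),
             "beneficiary_type")
  for (col in c("enroll_month", "disenroll_month", "death_month")) {
    if (!inherits(enrollment[[col]], "ym"))
      enrollment[[col]] <- ym_parse(enrollment[[col]])
    enrollment[[col]] <- as_ym_column(enrollment[[col]])
  }
  if (anyNA(unclass(enrollment$enroll_month)))
    stop("enroll_month missing in enrollment row(s) ",
         paste(utils::head(which(is.na(unclass(enrollment$enroll_month))), 5),
               collapse = ", "), call. = FALSE)
  reason <- as.character(enrollment$disenroll_reason)
  reason[!is.na(reason) & !nzchar(trimws(reason))] <- NA_character_
  enrollment$disenroll_reason <-
    enum_check(reason, c("death", "other", "unknown"), "disenroll_reason",
               allow_na = TRUE)
  enrollment[c("patient_id", "sex", "birth_year", "beneficiary_type",
               "enroll_month", "disenroll_month", "disenroll_reason",
               "death_month")]
}

blank_to_empty <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  trimws(x)
}

#' End of the observation period
#'
#' The observation period ends at the disenrollment month or the
#' administrative study end, whichever comes first; patients still enrolled
#' at study end are observed through it.
#'
#' @param enrollment an enrollment data.frame (needs `disenroll_month`).
#' @param study_end `ym` scalar or "YYYY-MM" string.
#' @return `ym` vector, one entry per enrollment row.
#' @examples
#' enr <- data.frame(disenroll_month = I(ym_parse(c("2008-05", "", "2010-01"))))
#' format(observation_end(enr, "2009-08"))  # "2008-05" "2009-08" "2009-08"
#' @export
observation_end <- function(enrollment, study_end) {
  study_end <- as_ym_scalar(study_end)
  dis <- unclass(enrollment$disenroll_month)
  new_ym(pmin(ifelse(is.na(dis), unclass(study_end), dis),
              unclass(study_end)))
}

#' Read a cohort from the documented CSV schema
#'
#' `claims.csv`: `patient_id, claim_month, setting, status, icd10_codes,
#' drug_codes` (codes semicolon-separated; `drug_codes` optional).
#' `enrollment.csv`: `patient_id, sex, birth_year, beneficiary_type,
#' enroll_month, disenroll_month, disenroll_reason, death_month` (blank =
#' missing).  Files are UTF-8 with a header row; months are "YYYY-MM".
#' Malformed rows are reported by row number.
#'
#' @param claims_path,enrollment_path paths to the CSV files.
#' @param study_end administrative study end, "YYYY-MM" or `ym` scalar.
#' @return A [claims_cohort()] object.
#' @export
read_cohort <- function(claims_path, enrollment_path, study_end) {
  claims <- utils::read.csv(claims_path, colClasses = "character",
                            na.strings = NULL, fileEncoding = "UTF-8")
  enrollment <- utils::read.csv(enrollment_path, colClasses = "character",
                                na.strings = NULL, fileEncoding = "UTF-8")
  claims_cohort(claims, enrollment, study_end)
}

#' Write a cohort back to the CSV schema
#'
#' @param cohort a [claims_cohort()] object.
#' @param claims_path,enrollment_path output paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, claims_path, enrollment_path) {
  stopifnot(inherits(cohort, "claims_cohort"))
  cl <- cohort$claims
  cl$claim_month <- format(cl$claim_month)
  utils::write.csv(cl, claims_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  en <- cohort$enrollment[c("patient_id", "sex", "birth_year",
                            "beneficiary_type", "enroll_month",
                            "disenroll_month", "disenroll_reason",
                            "death_month")]
  for (col in c("enroll_month", "disenroll_month", "death_month")) {
    f <- format(en[[col]])
    en[[col]] <- ifelse(is.na(f), "", f)
  }
  en$disenroll_reason[is.na(en$disenroll_reason)] <- ""
  utils::write.csv(en, enrollment_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(cohort)
}

#' Per-patient timelines
#'
#' Splits a cohort into one `patient_history` per enrollment record: the
#' enrollment row, the patient's claims in month order, the observation end
#' and the gold-standard death flag.  Patients without claims get an empty
#' claims table.
#'
#' @param cohort a [claims_cohort()] object.
#' @param ids optional character vector restricting to some patients.
#' @return Named list of `patient_history` objects.
#' @export
patient_histories <- function(cohort, ids = NULL) {
  stopifnot(inherits(cohort, "claims_cohort"))
  enr <- cohort$enrollment
  if (!is.null(ids)) {
    miss <- setdiff(ids, enr$patient_id)
    if (length(miss)) stop("unknown patient id(s): ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    enr <- enr[match(ids, enr$patient_id), , drop = FALSE]
  }
  idx <- split(seq_len(nrow(cohort$claims)),
               factor(cohort$claims$patient_id, levels = enr$patient_id))
  out <- lapply(seq_len(nrow(enr)), function(i) {
    structure(list(
      patient_id = enr$patient_id[i],
      enrollment = enr[i, , drop = FALSE],
      claims = cohort$claims[idx[[i]], , drop = FALSE],
      observation_end = enr$observation_end[i],
      study_end = cohort$study_end,
      gold_dead = enr$gold_dead[i]
    ), class = "patient_history")
  })
  names(out) <- enr$patient_id
  out
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat("<claims_cohort>\n")
  cat(sprintf("  %d beneficiaries, %d claims, study end %s\n",
              nrow(x$enrollment), nrow(x$claims), format(x$study_end)))
  cat(sprintf("  gold-standard deaths: %d\n", sum(x$enrollment$gold_dead)))
  invisible(x)
}

#' @export
print.patient_history <- function(x, ...) {
  cat(sprintf("<patient_history> %s (%s, born %d, %s)\n", x$patient_id,
              x$enrollment$sex, x$enrollment$birth_year,
              x$enrollment$beneficiary_type))
  cat(sprintf("  observed %s .. %s; gold standard: %s\n",
              format(x$enrollment$enroll_month), format(x$observation_end),
              if (x$gold_dead) paste0("died ", format(x$enrollment$death_month))
              else "alive"))
  cat(sprintf("  %d claim(s)\n", nrow(x$claims)))
  invisible(x)
}

#' Cohort descriptives
#'
#' Summarises a cohort the way validation studies tabulate their population:
#' sex, age bands (20--39 / 40--59 / 60--74, age taken at observation end),
#' beneficiary type, mean observation months and the proportion with at
#' least one claim.
#'
#' @param cohort a [claims_cohort()] object.
#' @return data.frame with columns `characteristic`, `n`, `pct` (`NA` where a
#'   row is a mean rather than a share).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "claims_cohort"))
  enr <- cohort$enrollment
  n <- nrow(enr)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  age <- ym_year(enr$observation_end) - enr$birth_year
  obs_months <- unclass(enr$observation_end) - unclass(enr$enroll_month) + 1L
  has_claim <- enr$patient_id %in% cohort$claims$patient_id
  row <- function(chr, k, pct = NA_real_)
    data.frame(characteristic = chr, n = k, pct = pct)
  pct <- function(k) round_half_up(100 * k / n, 1)
  rbind(
    row("beneficiaries", n),
    row("male", sum(enr$sex == "M"), pct(sum(enr$sex == "M"))),
    row("age 20-39", sum(age <= 39), pct(sum(age <= 39))),
    row("age 40-59", sum(age >= 40 & age <= 59),
        pct(sum(age >= 40 & age <= 59))),
    row("age 60-74", sum(age >= 60), pct(sum(age >= 60))),
    row("mean age", round_half_up(mean(age), 1)),
    row("employee", sum(enr$beneficiary_type == "employee"),
        pct(sum(enr$beneficiary_type == "employee"))),
    row("family member", sum(enr$beneficiary_type == "family"),
        pct(sum(enr$beneficiary_type == "family"))),
    row("mean observation months", round_half_up(mean(obs_months), 1)),
    row("claim issued", sum(has_claim), pct(sum(has_claim))),
    row("gold-standard deaths", sum(enr$gold_dead), pct(sum(enr$gold_dead)))
  )
}

#' @export
summary.claims_cohort <- function(object, ...) {
  out <- summarize_cohort(object)
  class(out) <- c("claims_cohort_summary", class(out))
  out
}

#' @export
print.claims_cohort_summary <- function(x, ...) {
  cat("Cohort characteristics\n")
  df <- as.data.frame(x)
  df$pct <- ifelse(is.na(df$pct), "", sprintf("%.1f%%", df$pct))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
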