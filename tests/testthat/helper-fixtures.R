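# Builders for small hand-written cohorts.

mk_claims <- function(patient_id, claim_month, setting = "outpatient",
                      status = "others", icd10_codes = "",
                      drug_codes = "") {
  data.frame(patient_id = patient_id, claim_month = claim_month,
             setting = setting, status = status,
             icd10_codes = icd10_codes, drug_codes = drug_codes,
             stringsAsFactors = FALSE)
}

mk_enrollment <- function(patient_id, sex = "M", birth_year = 1960L,
                          beneficiary_type = "employee",
                          enroll_month = "2005-01", disenroll_month = "",
                          disenroll_reason = "", death_month = "") {
  data.frame(patient_id = patient_id, sex = sex, birth_year = birth_year,
             beneficiary_type = beneficiary_type,
             enroll_month = enroll_month,
             disenroll_month = disenroll_month,
             disenroll_reason = disenroll_reason,
             death_month = death_month, stringsAsFactors = FALSE)
}

mk_cohort <- function(claims, enrollment, study_end = "2009-08") {
  claims_cohort(claims, enrollment, study_end)
}

# single-patient cohort -> patient_history, for primitive-level tests
mk_history <- function(claims, enrollment = mk_enrollment("p1"),
                       study_end = "2009-08") {
  patient_histories(mk_cohort(claims, enrollment, study_end))[[1]]
}

# Fuzz cohort: random histories with every claim pattern the definitions
# must classify, plus loosely consistent enrollment records.
random_cohort <- function(n, seed, study_start = "2005-01",
                          study_end = "2009-08") {
  set.seed(seed)
  start <- unclass(ym_parse(study_start))
  end <- unclass(ym_parse(study_end))
  pool <- c("", "J06.9", "I10;E78.5", "C78.0", "C78.0;C18.9", "E11.2",
            "K70.3;K72.9", "I21.9", "N18;G81", "B20")
  claims <- list()
  enr <- list()
  for (i in seq_len(n)) {
    id <- sprintf("F%05d", i)
    k <- sample(0:8, 1)
    if (k > 0) {
      months <- sort(sample(start:end, k, replace = TRUE))
      claims[[length(claims) + 1L]] <- data.frame(
        patient_id = id,
        claim_month = sprintf("%04d-%02d", months %/% 12, months %% 12 + 1),
        setting = sample(c("inpatient", "outpatient"), k, replace = TRUE),
        status = sample(c("death", "cure", "termination", "others"), k,
                        replace = TRUE, prob = c(0.15, 0.1, 0.1, 0.65)),
        icd10_codes = sample(pool, k, replace = TRUE),
        drug_codes = "", stringsAsFactors = FALSE)
    }
    dead <- runif(1) < 0.3
    dm <- if (dead) sample(start:end, 1) else NA
    enr[[length(enr) + 1L]] <- data.frame(
      patient_id = id, sex = sample(c("M", "F"), 1),
      birth_year = sample(1935:1985, 1),
      beneficiary_type = sample(c("employee", "family"), 1),
      enroll_month = sprintf("%04d-%02d", start %/% 12, start %% 12 + 1),
      disenroll_month = if (dead)
        sprintf("%04d-%02d", dm %/% 12, dm %% 12 + 1) else "",
      disenroll_reason = if (dead) "death" else "",
      death_month = if (dead)
        sprintf("%04d-%02d", dm %/% 12, dm %% 12 + 1) else "",
      stringsAsFactors = FALSE)
  }
  claims_cohort(do.call(rbind, claims), do.call(rbind, enr), study_end)
}
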