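#' Configuration of the synthetic claims generator
#'
#' Defaults emulate the source population of a working-age Japanese
#' insurance claims validation cohort: ~195k beneficiaries aged 20-74
#' observed January 2005 to August 2009, ~60% male, ~66% employees, a crude
#' death risk of ~0.35% over follow-up, and the ascertainment mechanisms the
#' death definitions exploit — death recorded on a final claim with
#' probability `p_status_recorded` (the target sensitivity), short-term
#' "zombie" claims trailing some recorded deaths (reimbursement lag),
#' rare miscoded death-status claims on living patients followed by claims
#' three or more months later (long-term zombies), Charlson-severe terminal
#' admissions concentrated in decedents, and occasional deaths recorded only
#' as a reasonless disenrollment.
#'
#' @param n_patients number of beneficiaries.
#' @param study_start,study_end study window ("YYYY-MM" or `ym`).
#' @param p_male,p_employee demographic mix.
#' @param age_band_probs probabilities of age bands 20-39 / 40-59 / 60-74
#'   (age at study end).
#' @param p_enrolled_at_start share enrolled at the window start; the rest
#'   enroll uniformly during the window.
#' @param monthly_disenroll_rate monthly hazard of non-death disenrollment.
#' @param p_never_user share of beneficiaries who never generate claims.
#' @param monthly_outpatient_rate,monthly_inpatient_rate monthly claim
#'   probabilities per enrolled patient-month.
#' @param p_death probability a patient truly dies during follow-up.
#' @param p_status_recorded probability a true death yields a death-status
#'   claim in the death month (the definition-1.1 target sensitivity).
#' @param p_short_zombie probability a recorded death is followed by 1-2
#'   months of trailing non-death claims.
#' @param p_long_zombie_false_positive probability a living patient carries
#'   a miscoded death-status claim with later claims >= 3 months after.
#' @param p_disenroll_no_reason probability a true death is recorded in the
#'   enrollment file as a reasonless disenrollment (no death date).
#' @param p_cci_death probability a decedent's final admission is
#'   Charlson-severe (metastatic-level codes).
#' @param p_cci_lookback probability a severe decedent also had a severe
#'   claim 1-12 months earlier.
#' @param p_cci_alive probability a living patient has a Charlson-severe
#'   admission.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 195193,
                       study_start = "2005-01", study_end = "2009-08",
                       p_male = 0.599,
                       age_band_probs = c(0.577, 0.312, 0.111),
                       p_employee = 0.657,
                       p_enrolled_at_start = 0.4,
                       monthly_disenroll_rate = 0.003,
                       p_never_user = 0.13,
                       monthly_outpatient_rate = 0.15,
                       monthly_inpatient_rate = 0.005,
                       p_death = 694 / 195193,
                       p_status_recorded = 0.581,
                       p_short_zombie = 9 / 395,
                       p_long_zombie_false_positive = 4 / 194513,
                       p_disenroll_no_reason = 14 / 694,
                       p_cci_death = 215 / 680,
                       p_cci_lookback = 0.8,
                       p_cci_alive = 75 / 194513) {
  cfg <- list(n_patients = as.integer(n_patients),
              study_start = as_ym_scalar(study_start),
              study_end = as_ym_scalar(study_end),
              p_male = p_male, age_band_probs = age_band_probs,
              p_employee = p_employee,
              p_enrolled_at_start = p_enrolled_at_start,
              monthly_disenroll_rate = monthly_disenroll_rate,
              p_never_user = p_never_user,
              monthly_outpatient_rate = monthly_outpatient_rate,
              monthly_inpatient_rate = monthly_inpatient_rate,
              p_death = p_death, p_status_recorded = p_status_recorded,
              p_short_zombie = p_short_zombie,
              p_long_zombie_false_positive = p_long_zombie_false_positive,
              p_disenroll_no_reason = p_disenroll_no_reason,
              p_cci_death = p_cci_death, p_cci_lookback = p_cci_lookback,
              p_cci_alive = p_cci_alive)
  probs <- c(cfg$p_male, cfg$age_band_probs, cfg$p_employee,
             cfg$p_enrolled_at_start, cfg$p_never_user, cfg$p_death,
             cfg$p_status_recorded, cfg$p_short_zombie,
             cfg$p_long_zombie_false_positive, cfg$p_disenroll_no_reason,
             cfg$p_cci_death, cfg$p_cci_lookback, cfg$p_cci_alive,
             cfg$monthly_disenroll_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$age_band_probs) - 1) > 1e-8)
    stop("age_band_probs must sum to 1", call. = FALSE)
  if (cfg$monthly_outpatient_rate < 0 || cfg$monthly_outpatient_rate > 1 ||
      cfg$monthly_inpatient_rate < 0 || cfg$monthly_inpatient_rate > 1)
    stop("claim intensities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (unclass(cfg$study_start) >= unclass(cfg$study_end))
    stop("study_start must precede study_end", call. = FALSE)
  structure(cfg, class = "sim_config")
}

BENIGN_ICD10 <- c("J06.9", "M54.5", "I10", "K29.7", "F32.9", "E78.5",
                  "L20.9", "H10.9")
SEVERE_ICD10 <- "C78.0;C18.9"   # metastatic solid tumour: Charlson 6

#' Simulate a claims cohort with known mechanism truth
#'
#' Generates enrollment and monthly claims for `config$n_patients`
#' beneficiaries, reproducibly for a given seed, together with a truth table
#' recording for every patient whether they truly died and which recording
#' mechanism fired (death-status claim, short zombie, long-zombie miscode,
#' reasonless disenrollment, severe terminal admission).  The truth table
#' is the oracle the validation tests score definitions against; the
#' enrollment file carries a death month only for deaths that were not
#' reasonless disenrollments, exactly the information an insurer's file
#' would hold.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A [claims_cohort()] whose `"truth"` attribute (also via
#'   [cohort_truth()]) is the per-patient mechanism table.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_patients
  start <- unclass(config$study_start)
  end <- unclass(config$study_end)
  horizon <- end - start

  id <- sprintf("P%07d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$p_male, "M", "F")
  band <- sample.int(3L, n, replace = TRUE, prob = config$age_band_probs)
  age <- c(20L, 40L, 60L)[band] +
    floor(stats::runif(n) * c(20L, 20L, 15L)[band])
  birth_year <- ym_year(config$study_end) - age
  beneficiary <- ifelse(stats::runif(n) < config$p_employee,
                        "employee", "family")

  enroll <- ifelse(stats::runif(n) < config$p_enrolled_at_start, start,
                   start + floor(stats::runif(n) * horizon))
  # non-death disenrollment (geometric waiting time from enrollment)
  dis_wait <- if (config$monthly_disenroll_rate > 0)
    stats::rgeom(n, config$monthly_disenroll_rate) else rep(Inf, n)
  dis_nd <- enroll + dis_wait
  dis_nd[dis_nd > end] <- NA

  truly_dead <- stats::runif(n) < config$p_death
  death <- rep(NA_integer_, n)
  death[truly_dead] <- enroll[truly_dead] +
    floor(stats::runif(sum(truly_dead)) *
            (end - enroll[truly_dead] + 1L))
  # death pre-empts non-death disenrollment
  dis_nd[truly_dead] <- NA
  follow_end <- ifelse(truly_dead, death, ifelse(is.na(dis_nd), end, dis_nd))

  status_recorded <- truly_dead & stats::runif(n) < config$p_status_recorded
  short_zombie <- status_recorded & stats::runif(n) < config$p_short_zombie
  reasonless <- truly_dead & stats::runif(n) < config$p_disenroll_no_reason
  severe_death <- truly_dead & stats::runif(n) < config$p_cci_death
  severe_lookback <- severe_death & stats::runif(n) < config$p_cci_lookback
  can_zombie <- !truly_dead & follow_end - enroll >= 3L
  long_zombie <- can_zombie &
    stats::runif(n) < config$p_long_zombie_false_positive
  severe_alive <- !truly_dead & stats::runif(n) < config$p_cci_alive

  # ---- background claims on the (patient, month) grid -----------------
  user <- stats::runif(n) >= config$p_never_user
  n_months <- pmax(follow_end - enroll + 1L, 0L)
  grid_id <- rep(seq_len(n), n_months)
  grid_month <- unlist(lapply(seq_len(n), function(i)
    if (n_months[i] > 0L) seq.int(enroll[i], follow_end[i]) else integer(0)))
  keep_out <- user[grid_id] &
    stats::runif(length(grid_id)) < config$monthly_outpatient_rate
  keep_inp <- user[grid_id] &
    stats::runif(length(grid_id)) < config$monthly_inpatient_rate

  benign <- function(k) sample(BENIGN_ICD10, k, replace = TRUE)
  claims <- list(
    data.frame(pid = grid_id[keep_out], month = grid_month[keep_out],
               setting = "outpatient", status = "others",
               icd10 = benign(sum(keep_out)), drugs = ""),
    data.frame(pid = grid_id[keep_inp], month = grid_month[keep_inp],
               setting = "inpatient", status = "others",
               icd10 = benign(sum(keep_inp)), drugs = ""))

  # ---- mechanism claims ----------------------------------------------
  rec <- which(status_recorded)
  if (length(rec)) {
    sev <- severe_death[rec]
    claims <- c(claims, list(data.frame(
      pid = rec, month = death[rec],
      setting = ifelse(sev | stats::runif(length(rec)) < 0.7,
                       "inpatient", "outpatient"),
      status = "death",
      icd10 = ifelse(sev, SEVERE_ICD10, benign(length(rec))),
      drugs = ifelse(sev, "L01", ""))))
  }
  # unrecorded severe deaths still show the terminal admission
  usev <- which(severe_death & !status_recorded)
  if (length(usev))
    claims <- c(claims, list(data.frame(
      pid = usev, month = death[usev], setting = "inpatient",
      status = "others", icd10 = SEVERE_ICD10, drugs = "L01")))
  lb <- which(severe_lookback)
  if (length(lb)) {
    lb_month <- pmax(death[lb] - (1L + floor(stats::runif(length(lb)) * 12)),
                     enroll[lb])
    ok <- lb_month < death[lb]
    claims <- c(claims, list(data.frame(
      pid = lb[ok], month = lb_month[ok], setting = "inpatient",
      status = "others", icd10 = SEVERE_ICD10, drugs = "L01")))
    severe_lookback[lb[!ok]] <- FALSE
  }
  sz <- which(short_zombie)
  if (length(sz)) {
    z1 <- pmin(death[sz] + 1L, end)
    ok <- z1 > death[sz]
    claims <- c(claims, list(data.frame(
      pid = sz[ok], month = z1[ok], setting = "outpatient",
      status = "others", icd10 = benign(sum(ok)), drugs = "")))
    short_zombie[sz[!ok]] <- FALSE
    two <- sz[ok][stats::runif(sum(ok)) < 0.5 & death[sz[ok]] + 2L <= end]
    if (length(two))
      claims <- c(claims, list(data.frame(
        pid = two, month = death[two] + 2L, setting = "outpatient",
        status = "others", icd10 = benign(length(two)), drugs = "")))
  }
  lz <- which(long_zombie)
  if (length(lz)) {
    span <- follow_end[lz] - enroll[lz]  # >= 3 by construction
    mis <- enroll[lz] + floor(stats::runif(length(lz)) * (span - 2L))
    claims <- c(claims, list(
      data.frame(pid = lz, month = mis, setting = "outpatient",
                 status = "death", icd10 = benign(length(lz)), drugs = ""),
      data.frame(pid = lz, month = pmin(mis + 3L, follow_end[lz]),
                 setting = "outpatient", status = "others",
                 icd10 = benign(length(lz)), drugs = "")))
  }
  sa <- which(severe_alive)
  if (length(sa)) {
    sa_month <- enroll[sa] +
      floor(stats::runif(length(sa)) * (follow_end[sa] - enroll[sa] + 1L))
    claims <- c(claims, list(data.frame(
      pid = sa, month = sa_month, setting = "inpatient",
      status = "others", icd10 = SEVERE_ICD10, drugs = "L01")))
  }

  claims <- do.call(rbind, claims)
  claims <- data.frame(patient_id = id[claims$pid],
                       claim_month = I(new_ym(claims$month)),
                       setting = claims$setting, status = claims$status,
                       icd10_codes = claims$icd10, drug_codes = claims$drugs,
                       stringsAsFactors = FALSE)

  disenroll <- ifelse(truly_dead, death, dis_nd)
  reason <- rep(NA_character_, n)
  reason[truly_dead & !reasonless] <- "death"
  reason[!truly_dead & !is.na(dis_nd)] <- "other"
  death_rec <- death
  death_rec[reasonless] <- NA_integer_
  enrollment <- data.frame(
    patient_id = id, sex = sex, birth_year = birth_year,
    beneficiary_type = beneficiary,
    enroll_month = I(new_ym(enroll)),
    disenroll_month = I(new_ym(disenroll)),
    disenroll_reason = reason,
    death_month = I(new_ym(death_rec)),
    stringsAsFactors = FALSE)

  cohort <- claims_cohort(claims, enrollment, config$study_end)
  truth <- data.frame(
    patient_id = id, truly_dead = truly_dead,
    status_recorded = status_recorded,
    short_zombie = short_zombie,
    long_zombie_miscode = long_zombie,
    reasonless_disenroll = reasonless,
    severe_last_admission = severe_death | severe_alive,
    severe_lookback = severe_lookback,
    stringsAsFactors = FALSE)
  truth$death_month <- new_ym(death)
  attr(cohort, "truth") <- truth
  attr(cohort, "config") <- config
  cohort
}

#' Mechanism truth table of a simulated cohort
#' @param cohort a cohort from [simulate_cohort()].
#' @return The per-patient truth data.frame, or `NULL` for loaded cohorts.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' Deterministic cohort realizing a prescribed mechanism mix
#'
#' Builds, without randomness, a cohort in which every ascertainment
#' mechanism appears in prescribed numbers: true deaths with a clean
#' death-status claim, with short-term zombie claims, deaths never recorded
#' on claims, living patients with a miscoded death claim followed by
#' long-term zombies, deaths recorded only as a reasonless disenrollment,
#' and Charlson-severe admission patterns nested by blank-period and
#' lookback criteria.  The defaults reproduce, cell by cell, the mechanism
#' mix of the validation study this package models (413/400/409 positives
#' under definitions 1.1/1.2/1.3 with 680 gold-standard deaths); shrink or
#' grow the cell counts for smaller or larger fixtures.
#'
#' @param n_tp_clean true deaths with a clean death-status claim.
#' @param n_tp_short_zombie true deaths whose death claim is followed by a
#'   claim 1 month later (reimbursement lag).
#' @param n_fp_ambiguous living-per-enrollment patients with a death claim
#'   in their disenrollment month but no death reason recorded.
#' @param n_fp_long_zombie living patients with a miscoded death claim and
#'   claims 3 months later.
#' @param n_fn true deaths without any death-status claim.
#' @param cci_tp,cci_fn,cci_fp_ambiguous nested counts (meeting the severe
#'   admission criterion; + blank period; + lookback) within the clean TP,
#'   FN and ambiguous FP blocks.
#' @param cci_fp_alive nested counts of living patients positive only
#'   through the severe-admission criteria.
#' @param age_tp,age_fn counts in age bands 20-39/40-59/60-74 among
#'   death-claim true positives and among missed deaths.
#' @param cancer_young_tp,cancer_young_fn how many of the young patients in
#'   each block carry a cancer diagnosis code.
#' @param n_alive_claims,n_alive_claimless plain true-negative filler, with
#'   and without claims.
#' @param study_start,study_end study window.
#' @return A [claims_cohort()].
#' @export
mechanism_cohort <- function(n_tp_clean = 386L, n_tp_short_zombie = 9L,
                             n_fp_ambiguous = 14L, n_fp_long_zombie = 4L,
                             n_fn = 285L,
                             cci_tp = c(186L, 169L, 131L),
                             cci_fn = c(29L, 25L, 24L),
                             cci_fp_ambiguous = c(7L, 5L, 3L),
                             cci_fp_alive = c(68L, 19L, 9L),
                             age_tp = c(43L, 210L, 142L),
                             age_fn = c(66L, 117L, 102L),
                             cancer_young_tp = 18L, cancer_young_fn = 2L,
                             n_alive_claims = 300L,
                             n_alive_claimless = 100L,
                             study_start = "2005-01",
                             study_end = "2009-08") {
  start <- unclass(as_ym_scalar(study_start))
  end <- unclass(as_ym_scalar(study_end))
  stopifnot(end - start >= 24)
  for (v in list(cci_tp, cci_fn, cci_fp_ambiguous, cci_fp_alive))
    if (any(diff(v) > 0))
      stop("nested severity counts must be non-increasing", call. = FALSE)
  if (cci_tp[1] > n_tp_clean || cci_fn[1] > n_fn ||
      cci_fp_ambiguous[1] > n_fp_ambiguous)
    stop("severity counts exceed their block", call. = FALSE)
  if (sum(age_tp) != n_tp_clean + n_tp_short_zombie || sum(age_fn) != n_fn)
    stop("age band counts must partition their block", call. = FALSE)
  if (cancer_young_tp > age_tp[1] || cancer_young_fn > age_fn[1])
    stop("cancer-in-young counts exceed the young band", call. = FALSE)

  far <- end - 14L       # death month leaving a long blank period
  near <- end - 2L       # death month leaving a short blank period
  mid <- end - 11L
  amb <- end - 17L       # index month of ambiguous disenrollments

  rows_claims <- list()
  rows_enr <- list()
  counter <- 0L
  nid <- function(k) {
    out <- sprintf("M%06d", counter + seq_len(k))
    counter <<- counter + k
    out
  }
  add <- function(ids, death = NA_integer_, disenroll = NA_integer_,
                  reason = NA_character_, death_rec = NA_integer_,
                  birth_year = 1959L) {
    k <- length(ids)
    i <- counter - k + seq_len(k)   # global position, for sex mix
    rows_enr[[length(rows_enr) + 1L]] <<- data.frame(
      patient_id = ids,
      sex = ifelse(i %% 10L < 6L, "M", "F"),
      birth_year = rep_len(birth_year, k),
      beneficiary_type = ifelse(i %% 3L < 2L, "employee", "family"),
      enroll_month = format(new_ym(rep(start, k))),
      disenroll_month = ifelse(is.na(disenroll), "",
                               format(new_ym(disenroll))),
      disenroll_reason = ifelse(is.na(reason), "", reason),
      death_month = ifelse(is.na(death_rec), "",
                           format(new_ym(death_rec))),
      stringsAsFactors = FALSE)
  }
  claim <- function(ids, month, setting, status, icd10 = "J06.9") {
    k <- length(ids)
    rows_claims[[length(rows_claims) + 1L]] <<- data.frame(
      patient_id = ids, claim_month = format(new_ym(rep_len(month, k))),
      setting = rep_len(setting, k), status = rep_len(status, k),
      icd10_codes = rep_len(icd10, k), drug_codes = "",
      stringsAsFactors = FALSE)
  }
  # nested severity layout: within a block of size n, members 1..c[3] meet
  # all three criteria, ..c[2] the blank criterion, ..c[1] severity only
  severity_pattern <- function(ids, cci, dead) {
    k3 <- cci[3]; k2 <- cci[2] - cci[3]; k1 <- cci[1] - cci[2]
    g3 <- ids[seq_len(k3)]
    g2 <- ids[k3 + seq_len(k2)]
    g1 <- ids[cci[2] + seq_len(k1)]
    status <- if (dead) "death" else "others"
    if (length(g3)) {
      claim(g3, far, "inpatient", status, SEVERE_ICD10)
      claim(g3, far - 6L, "inpatient", "others", SEVERE_ICD10)
    }
    if (length(g2)) {
      claim(g2, far, "inpatient", status, SEVERE_ICD10)
      claim(g2, far - 6L, "inpatient", "others", "J06.9")
    }
    if (length(g1)) claim(g1, near, "inpatient", status, SEVERE_ICD10)
    # death month per member, for enrollment bookkeeping
    rep(c(far, far, near), c(k3, k2, k1))
  }
  band_years <- function(counts)
    rep(c(1979L, 1959L, 1944L), counts)   # ages 30 / 50 / 65 at study end

  ## -- true positives: death-status claim, gold-standard death ---------
  tp_ids <- nid(n_tp_clean + n_tp_short_zombie)
  clean <- tp_ids[seq_len(n_tp_clean)]
  shortz <- tp_ids[n_tp_clean + seq_len(n_tp_short_zombie)]
  sev <- clean[seq_len(cci_tp[1])]
  d_sev <- severity_pattern(sev, cci_tp, dead = TRUE)
  rest <- clean[-seq_len(cci_tp[1])]
  claim(rest, mid, "outpatient", "death", "J06.9")
  claim(shortz, mid, "outpatient", "death", "J06.9")
  claim(shortz, mid + 1L, "outpatient", "others", "J06.9")
  tp_death <- c(d_sev, rep(mid, length(rest) + length(shortz)))
  # oldest first: the severe-admission members sit at the block head
  add(tp_ids, death = tp_death, disenroll = tp_death, reason = "death",
      death_rec = tp_death, birth_year = rev(band_years(age_tp)))
  young_tp <- utils::tail(tp_ids, age_tp[1])
  if (cancer_young_tp > 0)
    claim(young_tp[seq_len(cancer_young_tp)], start, "outpatient",
          "others", "C18.9")

  ## -- false negatives: gold-standard deaths, no death claim -----------
  fn_ids <- nid(n_fn)
  sev_fn <- fn_ids[seq_len(cci_fn[1])]
  d_fn <- severity_pattern(sev_fn, cci_fn, dead = FALSE)
  plain_fn <- fn_ids[-seq_len(cci_fn[1])]
  with_claim <- plain_fn[seq_len(floor(length(plain_fn) / 2))]
  claim(with_claim, mid, "outpatient", "others", "J06.9")
  fn_death <- c(d_fn, rep(mid, length(plain_fn)))
  add(fn_ids, death = fn_death, disenroll = fn_death, reason = "death",
      death_rec = fn_death, birth_year = rev(band_years(age_fn)))
  young_fn <- utils::tail(fn_ids, age_fn[1])
  if (cancer_young_fn > 0)
    claim(young_fn[seq_len(cancer_young_fn)], start, "outpatient",
          "others", "C18.9")

  ## -- ambiguous disenrollments: death claim, no death reason ----------
  ab_ids <- nid(n_fp_ambiguous)
  sev_ab <- ab_ids[seq_len(cci_fp_ambiguous[1])]
  d_ab <- severity_pattern(sev_ab, cci_fp_ambiguous, dead = TRUE)
  rest_ab <- ab_ids[-seq_len(cci_fp_ambiguous[1])]
  claim(rest_ab, amb, "outpatient", "death", "J06.9")
  ab_month <- c(d_ab, rep(amb, length(rest_ab)))
  add(ab_ids, disenroll = ab_month, reason = NA_character_)

  ## -- long-term zombies: miscoded death claim on living patients ------
  lz_ids <- nid(n_fp_long_zombie)
  claim(lz_ids, amb, "outpatient", "death", "J06.9")
  claim(lz_ids, amb + 3L, "outpatient", "others", "J06.9")
  add(lz_ids)

  ## -- living patients positive only through severity ------------------
  sa_ids <- nid(cci_fp_alive[1])
  severity_pattern(sa_ids, cci_fp_alive, dead = FALSE)
  add(sa_ids)

  ## -- plain true negatives --------------------------------------------
  tn_ids <- nid(n_alive_claims)
  if (n_alive_claims > 0)
    claim(tn_ids, start + 4L, "outpatient", "others", "J06.9")
  add(tn_ids)
  add(nid(n_alive_claimless))

  claims_cohort(do.call(rbind, rows_claims), do.call(rbind, rows_enr),
                study_end)
}
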