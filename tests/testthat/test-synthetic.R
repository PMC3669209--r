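test_that("identical seeds give identical cohorts", {
  cfg <- sim_config(n_patients = 500, p_death = 0.1)
  a <- simulate_cohort(cfg, seed = 4)
  b <- simulate_cohort(cfg, seed = 4)
  expect_identical(a$claims, b$claims)
  expect_identical(a$enrollment, b$enrollment)
  expect_identical(cohort_truth(a), cohort_truth(b))
  c <- simulate_cohort(cfg, seed = 5)
  expect_false(identical(a$claims, c$claims))
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(p_death = 1.5), "probabilities")
  expect_error(sim_config(monthly_outpatient_rate = -0.1), "intensities")
  expect_error(sim_config(age_band_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(study_start = "2009-08", study_end = "2005-01"),
               "precede")
})

test_that("switching mechanisms off empties the definitions", {
  cfg <- sim_config(n_patients = 400, p_death = 0,
                    p_long_zombie_false_positive = 0, p_cci_alive = 0)
  co <- simulate_cohort(cfg, seed = 9)
  expect_equal(sum(co$enrollment$gold_dead), 0)
  expect_false(any(co$claims$status == "death"))
  for (d in death_definitions())
    expect_equal(nrow(ascertain_cohort(co, d, quiet = TRUE)), 0)
})

test_that("perfect recording makes definition 1.1 a perfect test", {
  cfg <- sim_config(n_patients = 2000, p_death = 0.1,
                    p_status_recorded = 1, p_short_zombie = 0,
                    p_long_zombie_false_positive = 0,
                    p_disenroll_no_reason = 0)
  co <- simulate_cohort(cfg, seed = 10)
  vm <- validity_metrics(confusion(ascertain_cohort(co, "1.1",
                                                    quiet = TRUE), co))
  expect_equal(vm$sensitivity$pct, 100)
  expect_equal(vm$ppv$pct, 100)
})

test_that("every mechanism flag is verifiable from the generated claims", {
  cfg <- sim_config(n_patients = 1200, p_death = 0.15,
                    p_status_recorded = 0.6, p_short_zombie = 0.3,
                    p_long_zombie_false_positive = 0.02,
                    p_disenroll_no_reason = 0.1,
                    p_cci_death = 0.4, p_cci_alive = 0.01)
  co <- simulate_cohort(cfg, seed = 11)
  tr <- cohort_truth(co)
  enr <- co$enrollment
  cl <- co$claims
  m <- unclass(cl$claim_month)
  dm <- unclass(tr$death_month)

  for (i in seq_len(nrow(tr))) {
    id <- tr$patient_id[i]
    mine <- cl$patient_id == id
    if (tr$status_recorded[i])
      expect_true(any(mine & cl$status == "death" & m == dm[i]))
    else
      expect_false(tr$truly_dead[i] && any(mine & cl$status == "death"))
    if (tr$short_zombie[i]) {
      gaps <- m[mine & cl$status != "death"] - dm[i]
      gaps <- gaps[gaps > 0]
      expect_true(length(gaps) > 0 && max(gaps) <= 2)
    }
    if (tr$long_zombie_miscode[i]) {
      expect_false(tr$truly_dead[i])
      idx <- min(m[mine & cl$status == "death"])
      expect_true(any(m[mine & cl$status != "death"] - idx >= 3))
    }
    if (tr$reasonless_disenroll[i]) {
      expect_true(tr$truly_dead[i])
      expect_true(is.na(unclass(enr$death_month))[i])
      expect_equal(unclass(enr$disenroll_month)[i], dm[i])
      expect_true(is.na(enr$disenroll_reason[i]))
    }
    # enrollment death month present iff died and not reasonless
    expect_equal(!is.na(unclass(enr$death_month))[i],
                 tr$truly_dead[i] && !tr$reasonless_disenroll[i])
  }

  # severe-admission flags match a recomputation of the last-inpatient CCI
  feats <- deathproxy:::definition_features(co)
  sev <- !is.na(feats$last_inpat_cci) & feats$last_inpat_cci >= 6
  expect_equal(unname(sev), unname(tr$severe_last_admission))
})

test_that("measured sensitivity tracks the configured recording rate", {
  cfg <- sim_config(n_patients = 4000, p_death = 0.5,
                    p_status_recorded = 0.58, p_disenroll_no_reason = 0,
                    p_long_zombie_false_positive = 0)
  co <- simulate_cohort(cfg, seed = 12)
  vm <- validity_metrics(confusion(ascertain_cohort(co, "1.1",
                                                    quiet = TRUE), co))
  n_dead <- sum(co$enrollment$gold_dead)
  sigma <- sqrt(0.58 * 0.42 / n_dead)
  expect_lt(abs(vm$sensitivity$prop - 0.58), 3 * sigma)
})

test_that("summary statistics track the configured demographic mix", {
  cfg <- sim_config(n_patients = 3000, p_male = 0.6)
  co <- simulate_cohort(cfg, seed = 13)
  s <- summarize_cohort(co)
  male_pct <- s$pct[s$characteristic == "male"]
  expect_lt(abs(male_pct / 100 - 0.6), 3 * sqrt(0.6 * 0.4 / 3000))
  bands <- s$pct[s$characteristic %in% c("age 20-39", "age 40-59",
                                         "age 60-74")]
  expect_equal(sum(bands), 100, tolerance = 0.2)
})

test_that("the engineered cohort validates its prescribed counts", {
  expect_error(mechanism_cohort(cci_tp = c(10L, 20L, 5L)),
               "non-increasing")
  expect_error(mechanism_cohort(cci_tp = c(500L, 400L, 300L)),
               "exceed")
  expect_error(mechanism_cohort(age_tp = c(1L, 1L, 1L)), "partition")
  co <- mechanism_cohort(n_tp_clean = 20L, n_tp_short_zombie = 2L,
                         n_fp_ambiguous = 2L, n_fp_long_zombie = 1L,
                         n_fn = 10L, cci_tp = c(6L, 4L, 2L),
                         cci_fn = c(3L, 2L, 1L),
                         cci_fp_ambiguous = c(1L, 1L, 1L),
                         cci_fp_alive = c(4L, 2L, 1L),
                         age_tp = c(2L, 10L, 10L), age_fn = c(2L, 4L, 4L),
                         cancer_young_tp = 1L, cancer_young_fn = 1L,
                         n_alive_claims = 20L, n_alive_claimless = 5L)
  v <- validate_definitions(co)
  np <- stats::setNames(v$n_positive, v$definition)
  expect_equal(np[["1.1"]], 25L)   # 22 dead + 2 ambiguous + 1 zombie
  expect_equal(np[["1.2"]], 22L)
  expect_equal(np[["1.3"]], 24L)
  expect_equal(np[["2.1"]], 6L + 3L + 1L + 4L)
  expect_equal(np[["3.3"]], 24L + 1L + 1L)
})
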