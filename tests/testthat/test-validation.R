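test_that("confusion cross-classifies patients against the gold standard", {
  co <- mk_cohort(mk_claims(c("a", "b"), "2007-01",
                            status = c("death", "death")),
                  mk_enrollment(c("a", "b", "c"),
                                disenroll_month = c("2007-01", "", ""),
                                disenroll_reason = c("death", "", ""),
                                death_month = c("2007-01", "", "")))
  calls <- ascertain_cohort(co, "1.1", quiet = TRUE)
  ct <- confusion(calls, co)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 0L, tn = 1L))
  expect_error(confusion(data.frame(patient_id = "zz",
                                    call_month = I(ym(2007, 1))), co),
               "absent")
  # empty calls, no gold deaths
  co2 <- mk_cohort(mk_claims("a", "2007-01"), mk_enrollment(c("a", "b")))
  ct2 <- confusion(data.frame(patient_id = character(0)), co2)
  expect_equal(ct2$tn, 2L)
  expect_equal(ct2$tp + ct2$fp + ct2$fn, 0L)
})

test_that("validity metrics flag undefined denominators instead of zeroing", {
  vm <- validity_metrics(confusion_table(0, 0, 5, 95))
  expect_equal(vm$sensitivity$pct, 0)
  expect_true(vm$ppv$undefined)
  expect_false(vm$specificity$undefined)
  vm2 <- validity_metrics(confusion_table(3, 0, 1, 0))
  expect_true(vm2$specificity$undefined)
  expect_error(confusion_table(-1, 0, 0, 0), "non-negative")
})

test_that("CI bounds bracket the point estimate within [0, 100]", {
  set.seed(8)
  for (i in 1:25) {
    ct <- confusion_table(sample(0:50, 1), sample(0:50, 1),
                          sample(0:50, 1), sample(0:500, 1))
    for (method in c("clopper-pearson", "wilson")) {
      vm <- validity_metrics(ct, ci_method = method)
      for (m in list(vm$sensitivity, vm$specificity, vm$ppv)) {
        if (m$undefined) next
        expect_true(m$lo >= 0 && m$hi <= 100)
        expect_true(m$lo <= m$pct + 1e-9 && m$pct <= m$hi + 1e-9)
      }
    }
  }
})

test_that("exact binomial interval matches the beta-quantile oracle", {
  expect_equal(clopper_pearson(0, 10)[["lo"]], 0)
  expect_equal(clopper_pearson(10, 10)[["hi"]], 1)
  # independent evaluation via binom.test
  for (kn in list(c(395, 680), c(18, 500), c(0, 7), c(42, 42))) {
    got <- clopper_pearson(kn[1], kn[2])
    ref <- stats::binom.test(kn[1], kn[2])$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-8)
  }
  expect_error(clopper_pearson(1, 0), "positive")
})

test_that("standardized difference handles degenerate proportions", {
  expect_equal(standardized_difference(0.3, 0.3), 0)
  expect_equal(standardized_difference(1, 1), 0)
  expect_equal(standardized_difference(0, 0), 0)
  expect_true(is.infinite(standardized_difference(0, 1)))
  expect_error(standardized_difference(-0.1, 0.5))
})

test_that("the validation table carries nested true-positive counts", {
  co <- mechanism_cohort(n_alive_claims = 100L, n_alive_claimless = 20L)
  v <- validate_definitions(co)
  tp <- stats::setNames(v$tp, v$definition)
  expect_lte(tp[["1.2"]], tp[["1.3"]])
  expect_lte(tp[["1.3"]], tp[["1.1"]])
  expect_lte(tp[["2.3"]], tp[["2.2"]])
  expect_lte(tp[["2.2"]], tp[["2.1"]])
  sens <- stats::setNames(v$sensitivity, v$definition)
  for (k in 1:3)
    expect_gte(sens[[paste0("3.", k)]],
               max(sens[["1.3"]], sens[[paste0("2.", k)]]))
  expect_true(all(v$sensitivity >= 0 & v$sensitivity <= 100))
  expect_true(all(v$ppv >= 0 & v$ppv <= 100))
})

test_that("ambiguous disenrollments can be re-classified as deaths", {
  co <- mechanism_cohort(n_alive_claims = 100L, n_alive_claimless = 20L)
  conservative <- validate_definitions(co, "1.1")
  expect_equal(conservative$tp, 395L)
  expect_equal(conservative$fp, 18L)
  lenient <- validate_definitions(co, "1.1",
                                  reclassify_ambiguous_disenrollment = TRUE)
  expect_equal(lenient$tp, 409L)   # the 14 ambiguous cases flip to TP
  expect_equal(lenient$fp, 4L)     # only the long-term zombies remain
})

test_that("subgroup strata partition the cohort and sum their cells", {
  co <- mechanism_cohort(n_alive_claims = 100L, n_alive_claimless = 20L)
  calls <- ascertain_cohort(co, "3.3", quiet = TRUE)
  overall <- confusion(calls, co)
  by_sex <- subgroup_validate(co, calls, subgroup_sex())
  expect_equal(sum(by_sex$tp), overall$tp)
  expect_equal(sum(by_sex$n), nrow(co$enrollment))
  bands <- subgroup_validate(co, calls, subgroup_age_bands())
  expect_equal(sum(bands$n), nrow(co$enrollment))
  expect_equal(sum(bands$n_deaths), sum(co$enrollment$gold_dead))
  more <- subgroup_validate(co, calls,
                            c(subgroup_beneficiary(),
                              subgroup_hospitalized_prior_year(),
                              subgroup_last_claim_setting()))
  expect_false(any(more$empty))
  # empty stratum flagged, not divided by zero
  none <- subgroup_validate(co, calls,
                            list(nobody = function(p) rep(FALSE, nrow(p))))
  expect_true(none$empty)
  expect_true(is.na(none$sensitivity))
})

test_that("diagnosis-flag strata recover the generator's cancer labels", {
  cfg <- sim_config(n_patients = 1500, p_death = 0.1, p_cci_death = 0.5,
                    p_cci_alive = 0.01)
  co <- simulate_cohort(cfg, seed = 21)
  truth <- cohort_truth(co)
  calls <- ascertain_cohort(co, "3.3", quiet = TRUE)
  res <- subgroup_validate(co, calls, subgroup_icd10_flag("C", "cancer"))
  expect_equal(res$n[res$stratum == "cancer"],
               sum(truth$severe_last_admission | truth$severe_lookback))
  drugs <- subgroup_validate(co, calls, subgroup_drug_flag("L01"))
  expect_equal(drugs$n, res$n)   # the generator ties L01 to severe codes
})
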