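map <- cci_map()
params <- definition_params()

test_that("index claim is the earliest death-status claim in any setting", {
  h <- mk_history(mk_claims("p1", c("2007-01", "2007-02")))
  expect_null(find_index_claim(h))
  h <- mk_history(mk_claims("p1", "2007-03", setting = "inpatient",
                            status = "death"))
  expect_equal(format(find_index_claim(h)$claim_month), "2007-03")
  h <- mk_history(mk_claims("p1", c("2007-05", "2007-03"),
                            setting = c("inpatient", "outpatient"),
                            status = "death"))
  expect_equal(format(find_index_claim(h)$claim_month), "2007-03")
})

test_that("zombie status classifies by the largest post-index gap", {
  base <- function(extra_month, extra_status = "others") {
    mk_history(mk_claims("p1", c("2007-03", extra_month),
                         status = c("death", extra_status)))
  }
  h <- base("2007-05")
  expect_equal(zombie_status(h, find_index_claim(h), params), "short_term")
  h <- base("2007-06")
  expect_equal(zombie_status(h, find_index_claim(h), params), "long_term")
  h <- base("2007-06", "death")  # death-status claims are never zombies
  expect_equal(zombie_status(h, find_index_claim(h), params), "none")
  h <- mk_history(mk_claims("p1", "2007-03", status = "death"))
  expect_equal(zombie_status(h, find_index_claim(h), params), "none")
})

test_that("last inpatient claim pools same-month diagnoses for scoring", {
  h <- mk_history(mk_claims("p1", c("2008-01", "2008-04"),
                            setting = "inpatient",
                            icd10_codes = c("I21", "C78.0")))
  li <- last_inpatient_cci(h, map)
  expect_equal(format(li$month), "2008-04")
  expect_equal(li$score, 6L)
  h <- mk_history(mk_claims("p1", c("2008-04", "2008-04"),
                            setting = "inpatient",
                            icd10_codes = c("C78.0", "E11.2")))
  expect_equal(last_inpatient_cci(h, map)$score, 8L)
  h <- mk_history(mk_claims("p1", "2008-04", icd10_codes = "C78.0"))
  expect_null(last_inpatient_cci(h, map))
})

test_that("blank months count from the last claim to the study end", {
  expect_equal(blank_months(mk_history(mk_claims("p1", "2009-01"))), 7L)
  expect_equal(blank_months(mk_history(mk_claims("p1", "2009-04"))), 4L)
  expect_equal(blank_months(mk_history(mk_claims("p1", "2009-08"))), 0L)
  expect_equal(blank_months(
    mk_history(mk_claims("p1", c("2008-01", "2009-01")))), 7L)
})

test_that("lookback window is [anchor-12, anchor-1]", {
  anchor <- ym(2008, 12)
  h <- mk_history(mk_claims("p1", c("2008-02", "2008-12"),
                            setting = "inpatient",
                            icd10_codes = c("C78.0", "C78.0")))
  expect_true(lookback_cci_met(h, anchor, map, params))    # 10 months before
  h <- mk_history(mk_claims("p1", c("2007-11", "2008-12"),
                            setting = "inpatient",
                            icd10_codes = c("C78.0", "C78.0")))
  expect_false(lookback_cci_met(h, anchor, map, params))   # 13 months before
  h <- mk_history(mk_claims("p1", c("2007-12", "2008-12"),
                            setting = "inpatient",
                            icd10_codes = c("C78.0", "C78.0")))
  expect_true(lookback_cci_met(h, anchor, map, params))    # exactly 12
  # the anchor month itself is excluded
  h <- mk_history(mk_claims("p1", "2008-12", setting = "inpatient",
                            icd10_codes = "C78.0"))
  expect_false(lookback_cci_met(h, anchor, map, params))
})

test_that("single-patient ascertainment follows the definition table", {
  # clean death-status claim: positive under all of 1.1-1.3
  h <- mk_history(mk_claims("p1", "2007-03", status = "death"))
  for (d in c("1.1", "1.2", "1.3"))
    expect_equal(ascertain(h, d, params, map)$basis, "status_claim")
  # long-term zombie: only 1.1
  h <- mk_history(mk_claims("p1", c("2007-03", "2007-06"),
                            status = c("death", "others")))
  expect_false(is.null(ascertain(h, "1.1", params, map)))
  expect_null(ascertain(h, "1.2", params, map))
  expect_null(ascertain(h, "1.3", params, map))
  # severe admission, long blank, no lookback: 2.1, 2.2, 3.1, 3.2 only
  h <- mk_history(mk_claims("p1", "2008-06", setting = "inpatient",
                            icd10_codes = "C78.0"))
  pos <- vapply(death_definitions(), function(d)
    !is.null(ascertain(h, d, params, map)), logical(1))
  expect_equal(unname(pos),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(ascertain(h, "2.2", params, map)$basis, "cci_admission")
  expect_error(ascertain(h, "4.1", params, map), "unknown definition")
})

test_that("assigned death month is index, admission, or the earlier", {
  h <- mk_history(mk_claims("p1", c("2007-03", "2008-06"),
                            setting = c("outpatient", "inpatient"),
                            status = c("death", "others"),
                            icd10_codes = c("", "C78.0")))
  # post-index claim 15 months later: long-term zombie kills 1.2/1.3,
  # so 3.x fire through the severity arm at the admission month
  expect_equal(format(ascertain(h, "1.1", params, map)$call_month),
               "2007-03")
  expect_equal(format(ascertain(h, "2.2", params, map)$call_month),
               "2008-06")
  d33 <- ascertain(h, "3.2", params, map)
  expect_equal(format(d33$call_month), "2008-06")
  expect_equal(d33$basis, "cci_admission")
  # both arms positive (post-index admission within the short-zombie
  # window keeps 1.3 alive): earlier month, basis "either"
  h2 <- mk_history(mk_claims("p1", c("2008-02", "2008-04"),
                             setting = c("outpatient", "inpatient"),
                             status = c("death", "others"),
                             icd10_codes = c("", "C78.0")))
  d <- ascertain(h2, "3.2", params, map)
  expect_equal(format(d$call_month), "2008-02")
  expect_equal(d$basis, "either")
})

test_that("vectorised cohort ascertainment matches per-patient and oracle", {
  co <- random_cohort(300, seed = 99)
  hists <- patient_histories(co)
  feats <- NULL
  for (d in death_definitions()) {
    calls <- ascertain_cohort(co, d, params, map, quiet = TRUE)
    single <- Filter(Negate(is.null),
                     lapply(hists, ascertain, definition_id = d,
                            params = params, map = map))
    expect_setequal(calls$patient_id, vapply(single, `[[`, "",
                                             "patient_id"))
    expect_setequal(calls$patient_id,
                    oracle_positive_ids(co, d, params, map))
    # call months agree with the naive derivation
    om <- vapply(hists[calls$patient_id], function(h)
      oracle_ascertain(h, d, params, map)$call_month, numeric(1))
    expect_equal(unname(unclass(calls$call_month)), unname(om))
  }
})

test_that("definition nesting holds on any cohort", {
  for (seed in c(5, 6)) {
    co <- random_cohort(250, seed = seed)
    ids <- lapply(death_definitions(), function(d)
      ascertain_cohort(co, d, params, map, quiet = TRUE)$patient_id)
    names(ids) <- death_definitions()
    expect_true(all(ids[["1.2"]] %in% ids[["1.3"]]))
    expect_true(all(ids[["1.3"]] %in% ids[["1.1"]]))
    expect_true(all(ids[["2.3"]] %in% ids[["2.2"]]))
    expect_true(all(ids[["2.2"]] %in% ids[["2.1"]]))
    for (k in 1:3) {
      d3 <- ids[[paste0("3.", k)]]
      expect_setequal(d3, union(ids[["1.3"]], ids[[paste0("2.", k)]]))
      expect_lte(length(d3),
                 length(ids[["1.3"]]) + length(ids[[paste0("2.", k)]]))
    }
  }
})

test_that("call months never exceed the observation end", {
  co <- mechanism_cohort(n_alive_claims = 50L, n_alive_claimless = 10L)
  enr <- co$enrollment
  for (d in death_definitions()) {
    calls <- ascertain_cohort(co, d, quiet = TRUE)
    oe <- enr$observation_end[match(calls$patient_id, enr$patient_id)]
    expect_true(all(unclass(calls$call_month) <= unclass(oe)))
  }
})

test_that("parameters can be overridden and read from YAML", {
  p <- definition_params(zombie_short_max_months = 4)
  h <- mk_history(mk_claims("p1", c("2007-03", "2007-07"),
                            status = c("death", "others")))
  expect_equal(zombie_status(h, find_index_claim(h), p), "short_term")
  expect_error(definition_params(blank_min_months = 0), "positive")
  skip_if_not_installed("yaml")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("cci_threshold: 3", "blank_min_months: 12"), f)
  p2 <- read_params_yaml(f)
  expect_equal(p2$cci_threshold, 3L)
  expect_equal(p2$blank_min_months, 12L)
  expect_equal(p2$lookback_months, 12L)
  writeLines("nonsense: 1", f)
  expect_error(read_params_yaml(f), "unknown parameter")
})
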