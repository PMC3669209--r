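# Naive per-patient re-derivation of every definition, written as plain
# loops straight from the definition table.  Kept deliberately independent
# of the package's vectorised implementation.

oracle_ascertain <- function(history, definition_id,
                             params = definition_params(),
                             map = cci_map()) {
  cl <- history$claims
  months <- unclass(cl$claim_month)
  study_end <- unclass(history$study_end)

  index_month <- NA
  for (i in seq_along(months))
    if (cl$status[i] == "death" &&
        (is.na(index_month) || months[i] < index_month))
      index_month <- months[i]

  zombie <- "none"
  if (!is.na(index_month)) {
    worst <- 0
    for (i in seq_along(months))
      if (cl$status[i] != "death" && months[i] > index_month)
        worst <- max(worst, months[i] - index_month)
    if (worst > params$zombie_short_max_months) zombie <- "long_term"
    else if (worst > 0) zombie <- "short_term"
  }

  pos11 <- !is.na(index_month)
  pos12 <- pos11 && zombie == "none"
  pos13 <- pos11 && zombie != "long_term"

  inpat_months <- months[cl$setting == "inpatient"]
  pos21 <- pos22 <- pos23 <- FALSE
  anchor <- NA
  if (length(inpat_months)) {
    anchor <- max(inpat_months)
    codes <- character(0)
    for (i in seq_along(months))
      if (cl$setting[i] == "inpatient" && months[i] == anchor)
        codes <- c(codes, strsplit(cl$icd10_codes[i], ";")[[1]])
    codes <- codes[nzchar(codes)]
    pos21 <- cci_score(codes, map) >= params$cci_threshold
    blank <- study_end - max(months)
    pos22 <- pos21 && blank >= params$blank_min_months
    look <- FALSE
    for (i in seq_along(months))
      if (months[i] >= anchor - params$lookback_months &&
          months[i] <= anchor - 1) {
        ci <- strsplit(cl$icd10_codes[i], ";")[[1]]
        if (cci_score(ci[nzchar(ci)], map) >= params$cci_threshold)
          look <- TRUE
      }
    pos23 <- pos22 && look
  }

  pos <- switch(definition_id,
                "1.1" = pos11, "1.2" = pos12, "1.3" = pos13,
                "2.1" = pos21, "2.2" = pos22, "2.3" = pos23,
                "3.1" = pos13 || pos21, "3.2" = pos13 || pos22,
                "3.3" = pos13 || pos23)
  if (!pos) return(NULL)
  part <- substr(definition_id, 1, 1)
  month <- if (part == "1") index_month
           else if (part == "2") anchor
           else min(c(if (pos13) index_month,
                      if (switch(definition_id, "3.1" = pos21,
                                 "3.2" = pos22, "3.3" = pos23)) anchor))
  list(patient_id = history$patient_id, call_month = month)
}

oracle_positive_ids <- function(cohort, definition_id,
                                params = definition_params(),
                                map = cci_map()) {
  hists <- patient_histories(cohort)
  out <- character(0)
  for (h in hists)
    if (!is.null(oracle_ascertain(h, definition_id, params, map)))
      out <- c(out, h$patient_id)
  out
}
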