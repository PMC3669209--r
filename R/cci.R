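#' Charlson comorbidity index map (ICD-10)
#'
#' Loads a Charlson category map: one row per ICD-10 prefix with the category
#' it belongs to and the original Charlson weight (1, 2, 3 or 6).  The
#' package bundles an ICD-10 adaptation of the 17 Charlson categories in the
#' style of the published administrative-data adaptations, with hierarchy
#' pairs (uncomplicated/complicated diabetes, mild/moderate-severe liver
#' disease, non-metastatic/metastatic malignancy) in which the severe member
#' suppresses the mild one.  An alternative map can be supplied as a CSV file
#' with columns `category,weight,prefix`.
#'
#' @param path CSV file to load; default is the bundled map.
#' @param hierarchy named character vector mapping the milder category to the
#'   severe category that suppresses it.
#' @return A list of class `"cci_map"` with elements `table` (data.frame) and
#'   `hierarchy`.
#' @export
cci_map <- function(path = NULL,
                    hierarchy = c(
                      diabetes = "diabetes_with_complications",
                      mild_liver_disease = "moderate_severe_liver_disease",
                      malignancy = "metastatic_solid_tumour")) {
  if (is.null(path))
    path <- system.file("extdata", "cci_map_charlson_icd10.csv",
                        package = "deathproxy", mustWork = TRUE)
  tab <- utils::read.csv(path, colClasses = c("character", "integer",
                                              "character"))
  require_columns(tab, c("category", "weight", "prefix"), "CCI map")
  if (!all(tab$weight %in% c(1L, 2L, 3L, 6L)))
    stop("CCI weights must be 1, 2, 3 or 6", call. = FALSE)
  tab$prefix <- normalize_icd10(tab$prefix)
  if (length(hierarchy)) {
    known <- unique(tab$category)
    bad <- setdiff(c(names(hierarchy), unname(hierarchy)), known)
    if (length(bad))
      stop("hierarchy references unknown categor(ies): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(table = tab, hierarchy = hierarchy), class = "cci_map")
}

#' @export
print.cci_map <- function(x, ...) {
  w <- tapply(x$table$weight, x$table$category, unique)
  cat(sprintf("<cci_map> %d categories, %d ICD-10 prefixes\n",
              length(w), nrow(x$table)))
  for (cat_ in names(w))
    cat(sprintf("  %-32s weight %d (%d prefixes)\n", cat_, w[[cat_]],
                sum(x$table$category == cat_)))
  invisible(x)
}

# dot-insensitive, case-insensitive canonical form
normalize_icd10 <- function(codes) toupper(gsub(".", "", codes, fixed = TRUE))

# category index for each code via longest-prefix match; NA when unmapped.
match_categories <- function(codes, map) {
  codes <- normalize_icd10(codes)
  prefixes <- map$table$prefix
  ord <- order(nchar(prefixes), decreasing = TRUE)  # longest prefix wins
  out <- rep(NA_integer_, length(codes))
  for (j in ord) {
    hit <- is.na(out) & startsWith(codes, prefixes[j])
    out[hit] <- j
  }
  out
}

#' Charlson categories present in a code list
#'
#' Matches each ICD-10 code to its Charlson category by longest prefix
#' (dot- and case-insensitive), ignores unmapped codes, then applies
#' hierarchy suppression: when both members of a mild/severe pair are
#' present only the severe one is retained.
#'
#' @param codes character vector of ICD-10 codes (may be empty).
#' @param map a [cci_map()]; defaults to the bundled map.
#' @param apply_hierarchy suppress the mild member of each hierarchy pair
#'   (default `TRUE`, the standard Charlson practice).
#' @return Character vector of category names (possibly empty), sorted.
#' @examples
#' charlson_categories(c("K70.3", "K72.9"))  # severe liver only
#' @export
charlson_categories <- function(codes, map = cci_map(),
                                apply_hierarchy = TRUE) {
  if (length(codes) == 0L) return(character(0))
  idx <- match_categories(codes, map)
  cats <- unique(map$table$category[idx[!is.na(idx)]])
  if (apply_hierarchy && length(map$hierarchy)) {
    mild <- names(map$hierarchy)
    suppressed <- mild[map$hierarchy %in% cats]
    cats <- setdiff(cats, suppressed)
  }
  sort(cats)
}

#' Charlson comorbidity index score
#'
#' Sum of the original Charlson weights over the categories surviving
#' hierarchy suppression.  Order- and duplicate-invariant in the code list;
#' unmapped codes contribute nothing.  A score of 6 or more is reachable
#' from a single code only through metastatic solid tumour or AIDS/HIV.
#'
#' @inheritParams charlson_categories
#' @return Non-negative integer.
#' @examples
#' cci_score(c("C78.0", "E11.2"))  # metastatic 6 + complicated diabetes 2
#' @export
cci_score <- function(codes, map = cci_map(), apply_hierarchy = TRUE) {
  cats <- charlson_categories(codes, map, apply_hierarchy)
  if (!length(cats)) return(0L)
  weights <- map$table$weight[match(cats, map$table$category)]
  sum(weights)
}

# Vectorised scorer for semicolon-joined code strings; scores each unique
# string once (cohort-scale claims tables repeat few distinct code sets).
cci_score_strings <- function(code_strings, map, apply_hierarchy = TRUE) {
  u <- unique(code_strings)
  scores <- vapply(u, function(s)
    cci_score(split_codes(s), map, apply_hierarchy), integer(1))
  unname(scores[match(code_strings, u)])
}
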