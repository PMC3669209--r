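# Internal helpers shared across modules.

# Round half away from zero (the convention used when reporting percentages;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# last value of x within each group, with groups ordered by `levels`;
# NA where a group has no rows.  Both x and g are plain vectors.
group_max <- function(x, g, levels) {
  ord <- order(match(g, levels), x)
  x <- x[ord]; g <- g[ord]
  last <- !duplicated(g, fromLast = TRUE)
  out <- rep(NA_integer_, length(levels))
  out[match(g[last], levels)] <- x[last]
  out
}

group_min <- function(x, g, levels) {
  ord <- order(match(g, levels), x)
  x <- x[ord]; g <- g[ord]
  first <- !duplicated(g)
  out <- rep(NA_integer_, length(levels))
  out[match(g[first], levels)] <- x[first]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# force a month column to plain class "ym" (drops any AsIs wrapper)
as_ym_column <- function(x) {
  x <- as.integer(unclass(x))
  class(x) <- "ym"
  x
}

# split a semicolon-delimited code field into a character vector
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}
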