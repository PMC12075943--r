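#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used when published tables print `64.66` for `64.665`), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Percentage with half-up rounding at two decimals
#'
#' The percentage rule used throughout the descriptive tables:
#' `100 * count / denom`, rounded half-up to two decimals.
#'
#' @param count numerator count(s).
#' @param denom denominator count.
#' @param digits decimals (default 2).
#' @return numeric percentage(s).
#' @export
pct_half_up <- function(count, denom, digits = 2) {
  round_half_up(100 * count / denom, digits)
}

#' Normalize a drug name for matching
#'
#' Uppercases, trims, collapses internal whitespace and strips trailing
#' punctuation, so that `"Kineret."` and `"KINERET"` compare equal.
#'
#' @param x character vector of drug names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("[[:punct:][:space:]]+$", "", x)
  x
}

## case/space normalization for MedDRA terms (used as grouping keys)
normalize_term <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

## escape a literal string for use inside a regular expression
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

## does each element of `x` match any query name: whole-string equality or
## whole-word containment of a query name in x (both already normalized)
name_matches <- function(x, names) {
  names <- names[nzchar(names)]
  if (!length(names)) return(rep(FALSE, length(x)))
  pat <- paste0("\\b(", paste(regex_escape(names), collapse = "|"), ")\\b")
  (x %in% names) | grepl(pat, x, perl = TRUE)
}

## evaluate expr with a locally-set RNG seed, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read an analysis configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration holding file
#' paths, drug queries, exclusion lists and threshold settings.
#'
#' @param path path to a YAML/JSON config file.
#' @return a named list.
#' @export
read_analysis_config <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}
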