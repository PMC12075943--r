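## Drug-event 2x2 contingency tables and the frequentist disproportionality
## statistics (ROR, PRR, Pearson chi-square).
##
## The counting unit is the reaction record (one drug-event pair per coded
## PT occurrence): for a target drug and term,
##   a = target-drug records with the term,   b = target drug, other terms,
##   c = other drugs with the term,           d = other drugs, other terms,
## N = a+b+c+d and E = (a+b)(a+c)/N, the count expected under independence.

#' Build the corpus-wide event table
#'
#' One row per reaction record, labelled with the report's primary-suspect
#' drug (first PS record by sequence number). Reports matching `query` are
#' relabelled with the query's canonical label so that generic and trade
#' names pool into one target drug.
#'
#' @param corpus a `faers_corpus`.
#' @param query optional [drug_query()] pooling the target drug's names.
#' @param dict optional `meddra_dict` adding a `soc` column.
#' @param keys report keys to keep (default: deduplicated DEMO keys).
#' @return `data.table` with columns `primaryid`, `drug`, `term` (and
#'   `soc`).
#' @export
build_event_table <- function(corpus, query = NULL, dict = NULL, keys = NULL) {
  stopifnot(inherits(corpus, "faers_corpus"))
  if (is.null(keys)) keys <- dedup_reports(corpus$demo)$primaryid
  ps <- as.data.table(corpus$drug)[role_cod == "PS" & primaryid %in% keys]
  setorder(ps, primaryid, drug_seq)
  ps <- ps[, .(drug = normalize_drug_name(drugname[1L])), by = primaryid]
  if (!is.null(query)) {
    hit <- match_target_reports(corpus$drug, query)
    ps[primaryid %in% hit, drug := query$label]
  }
  ev <- as.data.table(corpus$reac)[primaryid %in% keys]
  ev[, term := trimws(pt)]
  ev <- ps[ev, on = "primaryid", nomatch = NULL][, .(primaryid, drug, term)]
  if (!is.null(dict)) ev[, soc := map_pt_to_soc(term, dict)]
  ev[]
}

#' Tabulate 2x2 cells for every drug-term pair
#'
#' @param events event table from [build_event_table()].
#' @param level `"pt"` (term column) or `"soc"`.
#' @param include_zero include structural-zero pairs (full drug x term
#'   cross join, `a = 0`)? These matter when fitting the empirical-Bayes
#'   prior over the whole database (default `TRUE`).
#' @return `data.table` with columns `drug`, `term`, `a`, `b`, `c_`, `d`,
#'   `N`, `E` (the `c` cell is named `c_` to avoid masking [base::c()]);
#'   at SOC level `term` holds the SOC. Attribute `level`.
#' @export
pair_counts <- function(events, level = c("pt", "soc"), include_zero = TRUE) {
  level <- match.arg(level)
  ev <- as.data.table(events)
  if (level == "soc") {
    stopifnot("soc" %in% names(ev))
    ev <- ev[, .(primaryid, drug, term = soc)]
  }
  counts <- ev[, .(a = .N), by = .(drug, term)]
  if (include_zero) {
    grid <- CJ(drug = unique(ev$drug), term = unique(ev$term))
    counts <- counts[grid, on = c("drug", "term")]
    counts[is.na(a), a := 0L]
  }
  Ntot <- nrow(ev)
  counts[, drug_tot := sum(a), by = drug]
  counts[, term_tot := sum(a), by = term]
  counts[, b := drug_tot - a]
  counts[, c_ := term_tot - a]
  counts[, d := Ntot - a - b - c_]
  counts[, N := Ntot]
  counts[, E := as.numeric(drug_tot) * term_tot / Ntot]
  counts[, c("drug_tot", "term_tot") := NULL]
  setorder(counts, drug, term)
  setattr(counts, "level", level)
  counts[]
}

#' Construct a single 2x2 contingency table
#'
#' @param a,b,c,d the four cells (target drug & term, target drug & other
#'   terms, other drugs & term, other drugs & other terms).
#' @return list with the cells plus `N = a+b+c+d` and
#'   `E = (a+b)(a+c)/N`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || anyNA(cells)) stop("cells must be non-negative counts")
  N <- a + b + c + d
  list(a = a, b = b, c = c, d = d, N = N,
       E = if (N > 0) (a + b) * (a + c) / N else NA_real_)
}

## published disproportionality formulas quote the 95% normal quantile as
## the conventional 1.96, not qnorm(0.975); other levels fall back to qnorm
wald_z <- function(conf) if (conf == 0.95) 1.96 else qnorm(1 - (1 - conf) / 2)

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = ad / bc`; `CI = exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell leaves the statistic undefined (`NA`); no continuity
#' correction is applied by default.
#'
#' @param a,b,c,d cell count vectors.
#' @param conf confidence level (default 0.95).
#' @return `data.table` with `ror`, `ror_lo95`, `ror_hi95`.
#' @export
ror_stats <- function(a, b, c, d, conf = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  z <- wald_z(conf)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- lo <- hi <- rep(NA_real_, length(a))
  ror[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  lo[ok] <- exp(log(ror[ok]) - z * se)
  hi[ok] <- exp(log(ror[ok]) + z * se)
  data.table(ror = ror, ror_lo95 = lo, ror_hi95 = hi)
}

#' Proportional reporting ratio with confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`;
#' `CI = exp(ln PRR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' Undefined (`NA`) when `a = 0` or `c = 0`.
#'
#' @inheritParams ror_stats
#' @return `data.table` with `prr`, `prr_lo95`, `prr_hi95`.
#' @export
prr_stats <- function(a, b, c, d, conf = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  z <- wald_z(conf)
  ok <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  prr <- lo <- hi <- rep(NA_real_, length(a))
  prr[ok] <- (a[ok] / (a[ok] + b[ok])) / (c[ok] / (c[ok] + d[ok]))
  se <- sqrt(1 / a[ok] - 1 / (a[ok] + b[ok]) + 1 / c[ok] - 1 / (c[ok] + d[ok]))
  lo[ok] <- exp(log(prr[ok]) - z * se)
  hi[ok] <- exp(log(prr[ok]) + z * se)
  data.table(prr = prr, prr_lo95 = lo, prr_hi95 = hi)
}

#' Pearson chi-square for a 2x2 table
#'
#' With `yates = TRUE` (default) the Yates continuity correction subtracts
#' 0.5 from each `|O - E|` before squaring, as is common in PRR practice.
#' Undefined (`NA`) when any margin is zero.
#'
#' @inheritParams ror_stats
#' @param yates apply the continuity correction?
#' @return numeric chi-square vector.
#' @export
chisq_stat <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  out <- rep(NA_real_, length(a))
  ## all four cells share |O - E| = |ad - bc| / N
  dev <- abs(a * d - b * c)[ok] / N[ok]
  if (yates) dev <- pmax(dev - 0.5, 0)
  E11 <- (r1 * c1 / N)[ok]; E12 <- (r1 * c2 / N)[ok]
  E21 <- (r2 * c1 / N)[ok]; E22 <- (r2 * c2 / N)[ok]
  out[ok] <- dev^2 * (1 / E11 + 1 / E12 + 1 / E21 + 1 / E22)
  out
}
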