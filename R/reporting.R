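## Descriptive tables: demographics/outcomes/time-to-onset summary with
## percentages, top indications and concomitant medications, and the
## formatted five-statistic signal table.

.outcome_labels <- c(DE = "Death", LT = "Life threatening",
                     HO = "Hospitalization", DS = "Disability",
                     CA = "Congenital anomaly",
                     RI = "Required intervention", OT = "Other serious")
.occp_labels <- c(MD = "Physician", PH = "Pharmacist",
                  OT = "Other health-professional", RN = "Registered nurse",
                  CN = "Consumer", LW = "Lawyer")

## one summary block: counts per category with half-up percentages
pct_block <- function(block, category, count, denom) {
  data.table(block = block, category = as.character(category),
             count = as.integer(count), denom = as.integer(denom),
             pct = pct_half_up(count, denom))
}

#' Demographics / outcomes / time-to-onset summary table
#'
#' Category blocks with counts and percentages. Denominators follow the
#' conventions of published report-characteristics tables: the age, sex,
#' reporter, country and route blocks use the total number of
#' deduplicated reports; the outcomes block uses the total number of
#' outcome *records* (a report can carry several outcomes); the
#' time-to-onset block uses its own block total (known bins + unknown).
#' Every row exposes its denominator, and percentages are rounded half-up
#' to two decimals.
#'
#' @param cases a `faers_cases` object.
#' @param country_top_k how many individual countries to list before
#'   pooling into `"Other"` (default 3).
#' @param route_top_k likewise for administration routes.
#' @return a `data.table` with columns `block`, `category`, `count`,
#'   `denom`, `pct`; empty for an empty corpus.
#' @export
demographics_table <- function(cases, country_top_k = 3L, route_top_k = 3L) {
  stopifnot(inherits(cases, "faers_cases"))
  cc <- cases$cases
  n_rep <- nrow(cc)
  if (!n_rep) return(pct_block(character(), character(), integer(), integer())[0])

  top_pool <- function(x, k, unknown = "Unknown") {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- unknown
    tab <- sort(table(x[x != unknown]), decreasing = TRUE)
    keep <- head(names(tab), k)
    x[!x %in% c(keep, unknown)] <- "Other"
    x
  }

  out <- rbind(
    { t <- table(cc$age_group); pct_block("age", names(t), as.integer(t), n_rep) },
    { s <- ifelse(cc$sex %in% c("F", "M"),
                  c(F = "Female", M = "Male")[cc$sex], "Unknown")
      t <- table(factor(s, levels = c("Female", "Male", "Unknown")))
      pct_block("sex", names(t), as.integer(t), n_rep) },
    { occ <- unname(.occp_labels[cc$occp_cod])
      occ[is.na(occ)] <- "Unknown"
      t <- sort(table(occ), decreasing = TRUE)
      pct_block("reporter", names(t), as.integer(t), n_rep) },
    { ctry <- top_pool(cc$reporter_country, country_top_k)
      t <- sort(table(ctry), decreasing = TRUE)
      pct_block("country", names(t), as.integer(t), n_rep) },
    { rt <- top_pool(cc$route, route_top_k)
      t <- sort(table(rt), decreasing = TRUE)
      pct_block("route", names(t), as.integer(t), n_rep) },
    { oc <- unname(.outcome_labels[cases$outcomes$outc_cod])
      t <- sort(table(oc), decreasing = TRUE)
      pct_block("outcomes", names(t), as.integer(t), sum(t)) },
    { t <- table(cc$tto_bin)
      pct_block("tto", names(t), as.integer(t), sum(t)) }
  )
  out[]
}

#' Top indications and concomitant medications
#'
#' Indications are counted from the matched primary-suspect drug's
#' indication PTs; concomitants by normalized name of the report's
#' non-suspect drug records. Both ranked descending, ties alphabetical.
#'
#' @param cases a `faers_cases`.
#' @param top rows per list (default 5).
#' @return list with `indications` (`term`, `n`) and `concomitants`
#'   (`name`, `n`).
#' @export
top_indications_concomitants <- function(cases, top = 5L) {
  stopifnot(inherits(cases, "faers_cases"))
  ind <- cases$indications[, .(n = .N), by = .(term = trimws(indi_pt))]
  ind <- ind[order(-n, term)][seq_len(min(top, .N))]
  con <- cases$concomitants[, .(n = .N), by = name]
  con <- con[order(-n, name)][seq_len(min(top, .N))]
  list(indications = ind[], concomitants = con[])
}

fmt2 <- function(x) {
  ifelse(is.na(x), "NA", formatC(round_half_up(x, 2), format = "f", digits = 2))
}
fmt_ci <- function(est, lo, hi) {
  ifelse(is.na(est), "NA",
         sprintf("%s (%s, %s)", fmt2(est), fmt2(lo), fmt2(hi)))
}

#' Format a signal table in the published five-statistic layout
#'
#' Renders `SOC, PT, case reports, ROR (95% CI), PRR (95% CI), Chisq,
#' IC (IC025), EBGM (EBGM05)` with all numbers at two decimals and `NA`
#' for undefined statistics. Deterministic: identical input yields
#' identical text.
#'
#' @param stats a signal statistics table (see [compute_signal_stats()]).
#' @return a character `data.table` in the published column layout.
#' @export
format_signal_table <- function(stats) {
  s <- as.data.table(stats)
  data.table(
    SOC = if ("soc" %in% names(s)) s$soc else "unmapped",
    PT = s$term,
    `Case reports` = s$n,
    `ROR (95% CI)` = fmt_ci(s$ror, s$ror_lo95, s$ror_hi95),
    `PRR (95% CI)` = fmt_ci(s$prr, s$prr_lo95, s$prr_hi95),
    Chisq = fmt2(s$chisq),
    `IC (IC025)` = ifelse(is.na(s$ic), "NA",
                          sprintf("%s (%s)", fmt2(s$ic), fmt2(s$ic025))),
    `EBGM (EBGM05)` = ifelse(is.na(s$ebgm), "NA",
                             sprintf("%s (%s)", fmt2(s$ebgm), fmt2(s$ebgm05))))
}

#' Published reference demographics counts for the two IL-1 blockers
#'
#' Category counts (and the printed percentages) from a published FAERS
#' report-characteristics table for anakinra and canakinumab, shipped as
#' plain text. Used to validate the percentage rule of
#' [demographics_table()]: feeding these counts through [pct_half_up()]
#' with the block's denominator must reproduce each printed percentage at
#' two decimals.
#'
#' @return `data.table` with columns `drug`, `block`, `category`, `count`,
#'   `printed_pct`.
#' @export
reference_demographics <- function() {
  data.table::fread(system.file("extdata", "il1_demographics_reference.tsv",
                                package = "faersignal", mustWork = TRUE),
                    sep = "\t")
}

#' Published reference signal table for the two IL-1 blockers
#'
#' The top-20 PT-level disproportionality signals per drug (40 rows) from
#' a published FAERS analysis: case counts, ROR and PRR with 95% CIs,
#' chi-square, IC (IC025) and EBGM (EBGM05). Used for
#' internal-consistency checks (`IC = log2(EBGM)` to rounding,
#' `ROR >= PRR`).
#'
#' @return a `data.table`, one row per drug-PT signal.
#' @export
reference_signals <- function() {
  data.table::fread(system.file("extdata", "il1_signal_reference.tsv",
                                package = "faersignal", mustWork = TRUE),
                    sep = "\t")
}

#' Apply the block percentage rule to a reference count table
#'
#' Recomputes each category's percentage from the counts alone, using the
#' same denominators as [demographics_table()]: report totals for
#' age/sex/reporter/route, the outcome-record total for outcomes, and the
#' block's own total for time-to-onset.
#'
#' @param ref a table as returned by [reference_demographics()].
#' @return the table with a recomputed `pct` column added.
#' @export
reference_percentages <- function(ref = reference_demographics()) {
  r <- copy(as.data.table(ref))
  totals <- r[block == "reports", .(n_rep = sum(count)), by = drug]
  r <- merge(r, totals, by = "drug")
  r[, denom := n_rep]
  r[block %in% c("outcomes", "tto"), denom := sum(count), by = .(drug, block)]
  r[, pct := pct_half_up(count, denom)]
  r[, n_rep := NULL]
  r[block != "reports"][]
}
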