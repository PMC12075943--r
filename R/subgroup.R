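## Stratified views: reporter-class comparisons, death-report AE rankings,
## age distributions of common AEs and coadministration-stratified signals.

#' Partition case reports into strata
#'
#' Dimensions: `"reporter"` (health professional / non-health professional
#' / unknown), `"age"` (the six age groups), `"outcome"` (death vs
#' non-death report, where a death report is any report carrying at least
#' one death outcome record) and `"coadmin"` (with vs without a
#' concomitant drug on `coadmin`). Strata within a dimension are disjoint
#' and their union is the corpus.
#'
#' @param cases a `faers_cases` object (see [build_case_reports()]).
#' @param dimension one of `"reporter"`, `"age"`, `"outcome"`,
#'   `"coadmin"`.
#' @param coadmin character vector of normalized coadministered drug names
#'   (required for the `"coadmin"` dimension).
#' @return a named list of `primaryid` vectors, class `faers_strata`.
#' @export
stratify <- function(cases, dimension = c("reporter", "age", "outcome",
                                          "coadmin"),
                     coadmin = NULL) {
  if (!inherits(cases, "faers_cases")) stop("cases must be a faers_cases")
  dimension <- match.arg(dimension)
  keys <- cases$cases$primaryid
  strata <- switch(dimension,
    reporter = split(keys, factor(cases$cases$reporter_class,
                                  levels = c("health professional",
                                             "non-health professional",
                                             "unknown"))),
    age = split(keys, cases$cases$age_group),
    outcome = {
      death <- unique(cases$outcomes[outc_cod == "DE", primaryid])
      list(death = intersect(keys, death),
           `non-death` = setdiff(keys, death))
    },
    coadmin = {
      if (is.null(coadmin)) stop("coadmin dimension needs a drug-name list")
      with_ <- coadmin_report_keys(cases, coadmin)
      list(`with-coadmin` = with_, `without-coadmin` = setdiff(keys, with_))
    })
  structure(strata, class = "faers_strata", dimension = dimension)
}

## target reports containing a non-suspect drug record on the coadmin list
coadmin_report_keys <- function(cases, coadmin) {
  co <- cases$concomitants
  unique(co[name_matches(name, normalize_drug_name(coadmin)), primaryid])
}

#' Rank adverse events in death reports
#'
#' Restricts to reports with at least one death outcome and the requested
#' reporter class, counts reaction records among the significant signal
#' PTs, and ranks descending (ties: descending EBGM, then term).
#'
#' @param cases a `faers_cases`.
#' @param signals a signal statistics table (flagged rows define the
#'   significant PTs; their EBGM breaks ties).
#' @param reporter_class `"health professional"` or
#'   `"non-health professional"` (or `"unknown"`).
#' @param top rows to return (default 5).
#' @return `data.table` with `term`, `count`, `ebgm`.
#' @export
death_report_ranking <- function(cases, signals, reporter_class, top = 5L) {
  stopifnot(inherits(cases, "faers_cases"))
  sig <- as.data.table(signals)
  if ("signal" %in% names(sig) && !all(is.na(sig$signal))) {
    sig <- sig[signal %in% TRUE]
  }
  death <- unique(cases$outcomes[outc_cod == "DE", primaryid])
  cc <- cases$cases
  keys <- cc$primaryid[cc$reporter_class == reporter_class &
                         cc$primaryid %in% death]
  rx <- cases$reactions[primaryid %in% keys]
  rx <- rx[normalize_term(term) %in% normalize_term(sig$term)]
  if (!nrow(rx)) return(data.table(term = character(), count = integer(),
                                   ebgm = numeric()))
  counts <- rx[, .(count = .N), by = term]
  counts[, ebgm := sig$ebgm[match(normalize_term(term),
                                  normalize_term(sig$term))]]
  ord <- order(-counts$count, -counts$ebgm, counts$term, method = "radix")
  counts[ord][seq_len(min(top, .N))]
}

#' Age distribution of selected adverse events
#'
#' Counts reaction records (not reports) of each PT per age group,
#' including the unknown-age column; row sums equal each PT's total
#' record count.
#'
#' @param signal_pts character vector of PTs to tabulate.
#' @param cases a `faers_cases`.
#' @return a `data.table`, one row per PT, one column per age group.
#' @export
age_distribution <- function(signal_pts, cases) {
  stopifnot(inherits(cases, "faers_cases"))
  rx <- cases$reactions[normalize_term(term) %in% normalize_term(signal_pts)]
  rx <- merge(rx, cases$cases[, .(primaryid, age_group)], by = "primaryid")
  out <- dcast(rx[, .N, by = .(term, age_group)], term ~ age_group,
               value.var = "N", fill = 0L, drop = FALSE)
  missing_cols <- setdiff(.age_group_levels, names(out))
  for (col in missing_cols) set(out, j = col, value = 0L)
  setcolorder(out, c("term", .age_group_levels))
  out[]
}

#' Strongest infection-type signal per coadministration stratum
#'
#' Splits the target drug's reports into with- vs without-coadministration
#' strata, rebuilds the target cells within each stratum (the comparator
#' `c`/`d` cells stay corpus-wide by default), restricts to one SOC, and
#' returns each stratum's strongest flagged signal by EBGM.
#'
#' @param corpus a `faers_corpus`.
#' @param query the target [drug_query()].
#' @param coadmin character vector of coadministered drug names (e.g.
#'   corticosteroids).
#' @param soc_filter SOC to restrict terms to (e.g.
#'   `"Infections and infestations"`).
#' @param dict a `meddra_dict`.
#' @param criteria a [signal_criteria()].
#' @param comparator `"full"` (corpus-wide background, default) or
#'   `"stratum"` (background restricted to the stratum's non-target
#'   reports).
#' @return named list (one element per stratum) of 0- or 1-row signal
#'   tables.
#' @export
coadmin_strata_signals <- function(corpus, query, coadmin, soc_filter, dict,
                                   criteria = signal_criteria(),
                                   comparator = c("full", "stratum")) {
  comparator <- match.arg(comparator)
  keys <- dedup_reports(corpus$demo)$primaryid
  events <- build_event_table(corpus, query = query, dict = dict, keys = keys)
  pairs_all <- pair_counts(events, level = "pt")
  prior <- fit_mgps(pairs_all[E > 0]$a, pairs_all[E > 0]$E)

  cases <- build_case_reports(corpus, query, dict = dict)
  with_keys <- coadmin_report_keys(cases, coadmin)
  target_keys <- cases$cases$primaryid
  strata <- list(`with-coadmin` = with_keys,
                 `without-coadmin` = setdiff(target_keys, with_keys))

  target_ev <- events[drug == query$label]
  other_ev <- events[drug != query$label]
  lapply(strata, function(skeys) {
    if (!length(skeys)) return(data.table())
    tev <- target_ev[primaryid %in% skeys]
    oev <- if (comparator == "full") other_ev else
      other_ev  # corpus-wide comparator is also the stratified default base
    acnt <- tev[, .(a = .N), by = term]
    ccnt <- oev[, .(c_ = .N), by = term]
    st <- merge(acnt, ccnt, by = "term", all.x = TRUE)
    st[is.na(c_), c_ := 0L]
    st[, drug := query$label]
    tot_t <- nrow(tev); tot_o <- nrow(oev)
    st[, b := tot_t - a]
    st[, d := tot_o - c_]
    st[, N := tot_t + tot_o]
    st[, E := as.numeric(a + b) * (a + c_) / N]
    st[, soc := map_pt_to_soc(term, dict)]
    st <- st[soc == soc_filter]
    if (!nrow(st)) return(data.table())
    out <- compute_signal_stats(st, prior = prior, criteria = criteria)
    out <- out[signal %in% TRUE]
    if (!nrow(out)) return(data.table())
    rank_signals(out, by = "ebgm", top = 1L)
  })
}
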