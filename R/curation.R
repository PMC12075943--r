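## Report curation: case-version deduplication, primary-suspect drug
## matching, PT -> SOC mapping, count filtering and derived classification
## fields (reporter class, age group, time-to-onset bin).

#' Deduplicate case versions
#'
#' A FAERS case accumulates report versions under one `caseid`. Exact
#' full-row duplicates are dropped first; then, per case, the report with
#' the most recent date is retained. When dates tie or are absent the
#' numerically/lexicographically greatest `primaryid` wins (a deterministic
#' "latest version" tie-break).
#'
#' @param demo a DEMO `data.table` (see [read_faers_table()]).
#' @param date_field which date decides recency (default `"fda_dt"`, the
#'   FDA receipt date).
#' @return the kept DEMO rows, one per `caseid`; attribute `n_removed`
#'   holds the number of dropped rows.
#' @export
dedup_reports <- function(demo, date_field = "fda_dt") {
  stopifnot(all(c("primaryid", "caseid", date_field) %in% names(demo)))
  d <- unique(as.data.table(demo))
  d[, `..date` := as.numeric(get(date_field))]
  d[is.na(`..date`), `..date` := -Inf]
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  d[, `..pid` := if (anyNA(pid_num)) xtfrm(primaryid) else pid_num]
  setorderv(d, c("caseid", "..date", "..pid"))
  kept <- d[, .SD[.N], by = caseid]
  kept[, c("..date", "..pid") := NULL]
  setcolorder(kept, names(demo))
  setattr(kept, "n_removed", nrow(demo) - nrow(kept))
  kept[]
}

#' Construct a drug query
#'
#' Names are stored case-normalized; matching (see
#' [match_target_reports()]) accepts whole-string equality or whole-word
#' containment of a query name, so `"KINERET 100MG"` matches the trade name
#' `"kineret"`.
#'
#' @param generic_names character vector of generic names.
#' @param trade_names character vector of trade names.
#' @param role drug role code to filter on (default `"PS"`, primary
#'   suspect).
#' @param label canonical label used for the matched drug in downstream
#'   tables (default: first generic name).
#' @return a `drug_query` object.
#' @export
#' @examples
#' drug_query(c("anakinra"), c("kineret"))
drug_query <- function(generic_names, trade_names = character(),
                       role = c("PS", "SS", "C", "I"),
                       label = NULL) {
  role <- match.arg(role)
  names <- unique(normalize_drug_name(c(generic_names, trade_names)))
  names <- names[nzchar(names)]
  if (!length(names)) stop("drug query needs at least one non-empty name")
  structure(list(names = names, role = role,
                 label = normalize_drug_name(label %||% generic_names[[1L]])),
            class = "drug_query")
}

#' @export
print.drug_query <- function(x, ...) {
  cat(sprintf("<drug_query> %s [role %s]: %s\n", x$label, x$role,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

## DRUG rows matching the query (role + normalized-name rule); both the
## verbatim drug name and the active-ingredient field are searched
match_target_drug_rows <- function(drug, query) {
  stopifnot(inherits(query, "drug_query"))
  d <- as.data.table(drug)
  hit <- d$role_cod == query$role &
    name_matches(normalize_drug_name(d$drugname), query$names)
  if ("prod_ai" %in% names(d)) {
    hit <- hit | (d$role_cod == query$role &
                    name_matches(normalize_drug_name(d$prod_ai), query$names))
  }
  hit[is.na(hit)] <- FALSE
  d[hit]
}

#' Find reports naming the target drug
#'
#' @param drug a DRUG `data.table`.
#' @param query a [drug_query()].
#' @return character vector of unique `primaryid`s whose report contains at
#'   least one matching drug record with the queried role.
#' @export
match_target_reports <- function(drug, query) {
  unique(match_target_drug_rows(drug, query)$primaryid)
}

#' MedDRA PT to SOC dictionary
#'
#' A minimal preferred-term to system-organ-class lookup. Every PT maps to
#' exactly one SOC; unmapped PTs resolve to the sentinel `"unmapped"`.
#' Real MedDRA is licensed and must be supplied by the user; the package
#' ships a small synthetic dictionary for its own tests and examples (see
#' [toy_meddra()]).
#'
#' @param pt character vector of preferred terms.
#' @param soc character vector of system organ classes, same length.
#' @return a `meddra_dict` object.
#' @export
meddra_dictionary <- function(pt, soc) {
  stopifnot(length(pt) == length(soc), !anyNA(pt), !anyNA(soc))
  key <- normalize_term(pt)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("PT mapped to more than one SOC: ", paste(dup, collapse = ", "))
  }
  structure(list(table = setNames(as.character(soc), key)),
            class = "meddra_dict")
}

#' Read a two-column PT/SOC dictionary file
#'
#' @param path delimited text file with columns `pt` and `soc`.
#' @param sep field separator (default tab).
#' @return a `meddra_dict` object.
#' @export
read_meddra <- function(path, sep = "\t") {
  d <- data.table::fread(path, sep = sep)
  setnames(d, tolower(names(d)))
  stopifnot(all(c("pt", "soc") %in% names(d)))
  meddra_dictionary(d$pt, d$soc)
}

#' The package's synthetic toy dictionary
#'
#' @return a `meddra_dict` covering the PT vocabulary of the synthetic
#'   corpus generator.
#' @export
toy_meddra <- function() {
  read_meddra(system.file("extdata", "meddra_toy.tsv",
                          package = "faersignal", mustWork = TRUE))
}

#' Map preferred terms to system organ classes
#'
#' @param pt character vector of PTs (case-insensitive).
#' @param dict a `meddra_dict`.
#' @return character vector of SOCs; `"unmapped"` where the PT is absent
#'   from the dictionary.
#' @export
map_pt_to_soc <- function(pt, dict) {
  stopifnot(inherits(dict, "meddra_dict"))
  out <- unname(dict$table[normalize_term(pt)])
  out[is.na(out)] <- "unmapped"
  out
}

#' Filter drug-term pairs by minimum report count
#'
#' @param pairs a `data.table` of drug-term counts.
#' @param min_count minimum count to retain (default 3, the usual
#'   frequency gate for disproportionality signals).
#' @param count_col name of the count column (default `"a"`).
#' @return the filtered table.
#' @export
filter_min_count <- function(pairs, min_count = 3, count_col = "a") {
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 1) {
    stop("min_count must be a single number >= 1")
  }
  stopifnot(count_col %in% names(pairs))
  as.data.table(pairs)[get(count_col) >= min_count]
}

#' Exclude indication-related preferred terms
#'
#' Removes pairs whose term is on the exclusion list (case-insensitive).
#' Indication terms (e.g. the treated disease itself) otherwise masquerade
#' as adverse events.
#'
#' @param pairs a `data.table` with a term column.
#' @param exclusion character vector of PTs to drop.
#' @param term_col name of the term column (default `"term"`).
#' @return filtered table; attribute `n_removed` counts dropped rows.
#' @export
exclude_indication_pts <- function(pairs, exclusion, term_col = "term") {
  stopifnot(term_col %in% names(pairs))
  p <- as.data.table(pairs)
  drop <- normalize_term(p[[term_col]]) %in% normalize_term(exclusion)
  out <- p[!drop]
  if (any(drop)) {
    message(sprintf("exclude_indication_pts: removed %d row(s)", sum(drop)))
  }
  setattr(out, "n_removed", sum(drop))
  out[]
}

#' Classify reporter occupation
#'
#' Health professionals are physicians (`MD`), pharmacists (`PH`),
#' registered nurses (`RN`) and other health professionals (`OT`);
#' consumers (`CN`) and lawyers (`LW`) are non-health professionals;
#' anything else (including missing) is unknown. Total over its domain.
#'
#' @param occp_cod character vector of occupation codes.
#' @return character vector in
#'   `{"health professional", "non-health professional", "unknown"}`.
#' @export
classify_reporter <- function(occp_cod) {
  x <- toupper(trimws(as.character(occp_cod)))
  out <- rep("unknown", length(x))
  out[x %in% c("MD", "PH", "OT", "RN")] <- "health professional"
  out[x %in% c("CN", "LW")] <- "non-health professional"
  out
}

.age_group_levels <- c("<18", "18-40", "40-60", "60-80", ">=80", "unknown")
.tto_bin_levels <- c("<30", "30-180", "180-360", "360-540", ">=540", "unknown")

#' Convert a FAERS age value/unit pair to years
#'
#' Unit codes: `DEC` decade (x10), `YR` year, `MON` month (/12), `WK` week
#' (/52), `DY` day (/365.25), `HR` hour (/8766).
#'
#' @param age_value numeric age values.
#' @param age_unit character unit codes.
#' @return numeric years; `NA` for missing/unknown units or negative ages.
#' @export
age_in_years <- function(age_value, age_unit) {
  f <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
         DY = 1 / 365.25, HR = 1 / 8766)
  mult <- unname(f[toupper(trimws(as.character(age_unit)))])
  yrs <- suppressWarnings(as.numeric(age_value)) * mult
  yrs[!is.na(yrs) & yrs < 0] <- NA_real_
  yrs
}

#' Assign age groups
#'
#' Half-open, left-closed bins `[0,18) [18,40) [40,60) [60,80) [80,Inf)`;
#' an exact 40 falls in `"40-60"`. Missing or invalid ages go to
#' `"unknown"`. The function partitions its domain: every input falls in
#' exactly one class.
#'
#' @param age_value numeric age values.
#' @param age_unit character unit codes (see [age_in_years()]).
#' @return factor with levels `<18, 18-40, 40-60, 60-80, >=80, unknown`.
#' @export
assign_age_group <- function(age_value, age_unit) {
  yrs <- age_in_years(age_value, age_unit)
  g <- cut(yrs, breaks = c(0, 18, 40, 60, 80, Inf), right = FALSE,
           labels = .age_group_levels[1:5])
  g <- as.character(g)
  g[is.na(g)] <- "unknown"
  factor(g, levels = .age_group_levels)
}

#' Time to onset in days and its bin
#'
#' Days from therapy start of the suspect drug to the event date. Negative
#' or incomputable values are `"unknown"`; bins are half-open, left-closed:
#' `[0,30) [30,180) [180,360) [360,540) [540,Inf)`.
#'
#' @param therapy_start `Date` vector of therapy start dates.
#' @param event_date `Date` vector of event dates.
#' @return a `data.table` with columns `days` (integer, `NA` if unknown)
#'   and `bin` (factor).
#' @export
compute_tto <- function(therapy_start, event_date) {
  days <- as.numeric(as.Date(event_date) - as.Date(therapy_start))
  days[!is.na(days) & days < 0] <- NA_real_
  b <- cut(days, breaks = c(0, 30, 180, 360, 540, Inf), right = FALSE,
           labels = .tto_bin_levels[1:5])
  b <- as.character(b)
  b[is.na(b)] <- "unknown"
  data.table(days = as.integer(days), bin = factor(b, levels = .tto_bin_levels))
}

#' Assemble curated case reports for a target drug
#'
#' Runs deduplication, matches the target drug as primary suspect, and
#' derives the classification fields used by the descriptive and subgroup
#' analyses: reporter class, age group and time-to-onset bin (earliest
#' therapy start among the matched drug's records in the report).
#'
#' @param corpus a `faers_corpus`.
#' @param query a [drug_query()].
#' @param dict optional `meddra_dict` used to annotate reactions with SOCs.
#' @return a `faers_cases` object: list with `cases` (one row per
#'   deduplicated matched report, incl. derived fields and the PS route),
#'   `reactions`, `outcomes`, `indications` (of the matched PS drug),
#'   `concomitants` (non-PS drug rows) and the `query`.
#' @export
build_case_reports <- function(corpus, query, dict = NULL) {
  stopifnot(inherits(corpus, "faers_corpus"), inherits(query, "drug_query"))
  demo_kept <- dedup_reports(corpus$demo)
  target_rows <- match_target_drug_rows(corpus$drug, query)
  keys <- intersect(demo_kept$primaryid, unique(target_rows$primaryid))

  cases <- demo_kept[primaryid %in% keys]
  cases[, reporter_class := classify_reporter(occp_cod)]
  cases[, age_years := age_in_years(age, age_cod)]
  cases[, age_group := assign_age_group(age, age_cod)]

  ## route of the first matched suspect drug record
  tr <- as.data.table(target_rows)[primaryid %in% keys]
  setorder(tr, primaryid, drug_seq)
  first_ps <- tr[, .SD[1L], by = primaryid]
  if ("route" %in% names(first_ps)) {
    cases[first_ps, route := toupper(i.route), on = "primaryid"]
  } else {
    cases[, route := NA_character_]
  }

  ## earliest therapy start among the matched drug's records per report
  ther <- as.data.table(corpus$ther)[primaryid %in% keys]
  ther <- ther[tr, on = c("primaryid", dsg_drug_seq = "drug_seq"), nomatch = NULL]
  ther <- ther[!is.na(start_dt)]
  start <- if (nrow(ther)) {
    ther[, .(start_dt = min(start_dt)), by = primaryid]
  } else {
    data.table(primaryid = character(), start_dt = as.Date(character()))
  }
  cases[, start_dt := as.Date(NA)]
  cases[start, start_dt := i.start_dt, on = "primaryid"]
  tto <- compute_tto(cases$start_dt, cases$event_dt)
  cases[, tto_days := tto$days]
  cases[, tto_bin := tto$bin]

  reactions <- as.data.table(corpus$reac)[primaryid %in% keys]
  reactions[, term := trimws(pt)]
  if (!is.null(dict)) reactions[, soc := map_pt_to_soc(pt, dict)]

  indications <- as.data.table(corpus$indi)[
    tr, on = c("primaryid", indi_drug_seq = "drug_seq"), nomatch = NULL]
  concomitants <- as.data.table(corpus$drug)[
    primaryid %in% keys][role_cod != query$role]
  concomitants[, name := normalize_drug_name(drugname)]

  structure(list(cases = cases[], reactions = reactions[],
                 outcomes = as.data.table(corpus$outc)[primaryid %in% keys],
                 indications = indications[], concomitants = concomitants[],
                 query = query, n_corpus_reports = nrow(demo_kept)),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf(
    "<faers_cases> %s: %d deduplicated reports, %d reaction records\n",
    x$query$label, nrow(x$cases), nrow(x$reactions)))
  invisible(x)
}
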