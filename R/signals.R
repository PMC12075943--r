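## Signal calling: per-algorithm thresholds, the combination rule, ranking
## and the end-to-end analysis wrapper.

#' Signal-calling criteria
#'
#' Default thresholds: ROR -- `n >= 3` and lower 95% CI `> 1`; PRR --
#' `PRR >= 2`, chi-square `>= 4`, `n >= 3`; BCPNN -- `IC025 > 0`; MGPS --
#' `EBGM05 > 2`. The combined flag defaults to the conjunction of all four
#' algorithms; `"any"` takes their disjunction and `"per-algorithm"`
#' reports only the per-algorithm verdicts.
#'
#' @param n_min minimum report count (frequency gate).
#' @param ror_lo_gt threshold the ROR lower bound must exceed.
#' @param prr_min,chisq_min PRR point estimate and chi-square thresholds.
#' @param ic025_gt threshold for the IC lower bound.
#' @param ebgm05_gt threshold for EBGM05.
#' @param rule combination rule.
#' @return a `signal_criteria` object.
#' @export
signal_criteria <- function(n_min = 3, ror_lo_gt = 1, prr_min = 2,
                            chisq_min = 4, ic025_gt = 0, ebgm05_gt = 2,
                            rule = c("all-four", "any", "per-algorithm")) {
  rule <- match.arg(rule)
  stopifnot(n_min >= 0, ror_lo_gt > 0, prr_min > 0, chisq_min >= 0,
            ebgm05_gt > 0)
  structure(list(n_min = n_min, ror_lo_gt = ror_lo_gt, prr_min = prr_min,
                 chisq_min = chisq_min, ic025_gt = ic025_gt,
                 ebgm05_gt = ebgm05_gt, rule = rule),
            class = "signal_criteria")
}

#' Evaluate signal criteria
#'
#' Adds per-algorithm boolean verdicts (`sig_ror`, `sig_prr`, `sig_bcpnn`,
#' `sig_mgps`) and the combined `signal` flag. Undefined statistics never
#' flag.
#'
#' @param stats a `data.table` of signal statistics (see
#'   [compute_signal_stats()]).
#' @param criteria a [signal_criteria()].
#' @return the table with verdict columns added (by reference semantics of
#'   a copy).
#' @export
evaluate_signals <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  s <- copy(as.data.table(stats))
  isT <- function(x) !is.na(x) & x
  s[, sig_ror := isT(n >= criteria$n_min & ror_lo95 > criteria$ror_lo_gt)]
  s[, sig_prr := isT(n >= criteria$n_min & prr >= criteria$prr_min &
                       chisq >= criteria$chisq_min)]
  s[, sig_bcpnn := isT(ic025 > criteria$ic025_gt)]
  s[, sig_mgps := isT(ebgm05 > criteria$ebgm05_gt)]
  s[, signal := switch(criteria$rule,
    "all-four" = sig_ror & sig_prr & sig_bcpnn & sig_mgps,
    "any" = sig_ror | sig_prr | sig_bcpnn | sig_mgps,
    "per-algorithm" = NA)]
  s[]
}

#' Compute all four algorithms' statistics for drug-term pairs
#'
#' @param pairs a [pair_counts()] table (all pairs; the prior is fitted on
#'   the full database unless supplied).
#' @param target optional drug label; statistics are returned for that
#'   drug's rows only (the prior still uses every pair).
#' @param prior optional pre-fitted `mgps_prior`.
#' @param criteria a [signal_criteria()].
#' @param ic_mode see [ic_stats()].
#' @param yates see [chisq_stat()].
#' @return a `data.table` with one row per pair: `drug`, `term`, `n`, the
#'   ROR/PRR/chi-square/IC/EBGM statistics, verdicts and combined `signal`;
#'   attribute `prior` holds the fitted prior.
#' @export
compute_signal_stats <- function(pairs, target = NULL, prior = NULL,
                                 criteria = signal_criteria(),
                                 ic_mode = c("mgps", "closed"),
                                 yates = TRUE) {
  ic_mode <- match.arg(ic_mode)
  p <- as.data.table(pairs)
  stopifnot(all(c("drug", "term", "a", "b", "c_", "d", "E") %in% names(p)))
  if (is.null(prior)) {
    fitable <- p[E > 0]
    prior <- fit_mgps(fitable$a, fitable$E)
  }
  s <- if (is.null(target)) copy(p) else p[drug == target]
  if (!nrow(s)) {
    stop("no pairs for target drug ", target %||% "<all>")
  }
  s[, n := a]
  s <- cbind(s, ror_stats(s$a, s$b, s$c_, s$d), prr_stats(s$a, s$b, s$c_, s$d))
  s[, chisq := chisq_stat(a, b, c_, d, yates = yates)]
  ok <- s$E > 0
  ebtab <- ebgm_stats(s$a[ok], s$E[ok], prior)
  ictab <- ic_stats(s$a[ok], s$E[ok], prior, mode = ic_mode)
  s[, `:=`(ebgm = NA_real_, ebgm05 = NA_real_, ic = NA_real_, ic025 = NA_real_)]
  s[ok, `:=`(ebgm = ebtab$ebgm, ebgm05 = ebtab$ebgm05,
             ic = ictab$ic, ic025 = ictab$ic025)]
  s <- evaluate_signals(s, criteria)
  setattr(s, "prior", prior)
  setattr(s, "criteria", criteria)
  s[]
}

#' Rank signal rows
#'
#' Stable descending sort by the chosen key; ties broken by descending
#' EBGM, then term text ascending.
#'
#' @param stats a signal statistics table.
#' @param by sort key: `"n"`, `"ebgm"` or `"ic"`.
#' @param top number of rows to keep (whole table if larger).
#' @return the ordered, truncated table.
#' @export
rank_signals <- function(stats, by = c("n", "ebgm", "ic"), top = 20L) {
  by <- match.arg(by)
  s <- as.data.table(stats)
  ord <- order(-s[[by]], -s[["ebgm"]], s[["term"]], method = "radix")
  s[ord][seq_len(min(top, .N))]
}

#' Run the full signal-detection analysis for one target drug
#'
#' Deduplicates the corpus, pools the target drug's names, builds the
#' corpus-wide pair counts at the requested MedDRA level, fits the MGPS
#' prior on every pair, applies the indication-term exclusion and minimum
#' count gate to the target's rows, computes all four algorithms and flags
#' signals.
#'
#' @param corpus a `faers_corpus`.
#' @param query a [drug_query()].
#' @param dict a `meddra_dict` (required at SOC level).
#' @param level `"pt"` or `"soc"`.
#' @param min_count frequency gate (default 3).
#' @param exclusion character vector of indication PTs to exclude.
#' @param criteria a [signal_criteria()].
#' @param ic_mode,yates see [ic_stats()], [chisq_stat()].
#' @return a `faers_signal_analysis`: list with `stats` (target rows,
#'   ranked by `n`), `prior`, `pairs` (all-pair counts), `events`,
#'   `n_reports` (deduplicated corpus size) and `n_target_reports`.
#' @export
run_signal_analysis <- function(corpus, query, dict = NULL,
                                level = c("pt", "soc"), min_count = 3,
                                exclusion = character(),
                                criteria = signal_criteria(),
                                ic_mode = c("mgps", "closed"),
                                yates = TRUE) {
  level <- match.arg(level)
  ic_mode <- match.arg(ic_mode)
  if (level == "soc" && is.null(dict)) stop("SOC level requires a dictionary")
  keys <- dedup_reports(corpus$demo)$primaryid
  events <- build_event_table(corpus, query = query, dict = dict, keys = keys)
  pairs <- pair_counts(events, level = level)
  fitable <- pairs[E > 0]
  prior <- fit_mgps(fitable$a, fitable$E)
  stats <- compute_signal_stats(pairs, target = query$label, prior = prior,
                                criteria = criteria, ic_mode = ic_mode,
                                yates = yates)
  if (!is.null(dict) && level == "pt") {
    stats[, soc := map_pt_to_soc(term, dict)]
  }
  if (length(exclusion) && level == "pt") {
    stats <- exclude_indication_pts(stats, exclusion)
  }
  stats <- filter_min_count(stats, min_count = min_count, count_col = "n")
  stats <- rank_signals(stats, by = "n", top = nrow(stats))
  structure(list(stats = stats, prior = prior, pairs = pairs,
                 events = events, n_reports = length(keys),
                 n_target_reports = length(unique(
                   events[drug == query$label, primaryid])),
                 query = query, level = level, criteria = criteria),
            class = "faers_signal_analysis")
}

#' @export
print.faers_signal_analysis <- function(x, ...) {
  cat(sprintf(
    "<faers_signal_analysis> %s at %s level: %d tabulated pairs (n >= gate), %d flagged\n",
    x$query$label, toupper(x$level), nrow(x$stats),
    sum(x$stats$signal, na.rm = TRUE)))
  invisible(x)
}
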