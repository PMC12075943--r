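---
title: "Disproportionality signal detection for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(data.table)
```

## The problem

Spontaneous reporting systems such as FAERS collect adverse-event (AE)
reports without a denominator: there is no count of treated patients, only
of reports. Safety signals are therefore mined by *disproportionality*: a
drug–event pair is suspicious when the pair is reported more often than the
database background predicts under independence. `faersignal` implements
the complete desk pipeline — curation of the raw quarterly ASCII tables,
2×2 tabulation, four detection algorithms, threshold-based signal calling,
and the descriptive and stratified summaries that accompany such analyses —
plus a synthetic corpus generator with planted associations so the whole
chain is testable without any data download.

## Data model and curation

A FAERS quarter ships six `$`-delimited case-level tables: `DEMO`
(demographics and administrative dates), `DRUG` (medications with role
codes: primary suspect `PS`, secondary suspect, concomitant, interacting),
`REAC` (MedDRA preferred terms, PTs), `OUTC` (seven outcome codes), `INDI`
(indication PTs per drug) and `THER` (therapy dates). The parser is total:
a malformed line is logged and skipped, never fatal, and the skip counter
always equals input lines minus parsed records. Modern (post-2014) column
names are assumed; legacy quarters are mapped through a user-supplied
column map rather than auto-detected, because schema archaeology is
orthogonal to the statistics.

Curation follows the conventions of published FAERS analyses:

* **Deduplication.** A case accumulates versions under one `caseid`; exact
  duplicate rows are dropped, then the version with the latest receipt date
  is kept. Receipt date (`fda_dt`) decides recency; this is configurable
  since the field is not uniquely determined by convention. Ties (and
  missing dates) fall back to the greatest `primaryid`, a deterministic
  stand-in for "latest version".
* **Drug matching.** Generic and trade names are searched together.
  Names are uppercased, trimmed, whitespace-collapsed and stripped of
  trailing punctuation; a query name matches by whole-string equality or
  whole-word containment, so `KINERET 100MG` matches `kineret` but
  `KINERETOL` does not. Both the verbatim name and the active-ingredient
  field are searched.
* **Dates.** FAERS dates are `YYYYMMDD` with truncated `YYYYMM`/`YYYY`
  variants. Truncated dates resolve to *absent* by default; a
  first-of-period imputation is available but off, to avoid silently
  fabricating time-to-onset values.
* **Derived fields.** Reporter class groups physicians, pharmacists,
  registered nurses and other health professionals as *health
  professional*; consumers and lawyers as *non-health professional*;
  everything else unknown. Ages convert to years (decade ×10, month /12,
  week /52, day /365.25, hour /8766) and bin into the left-closed groups
  `[0,18) [18,40) [40,60) [60,80) [80,∞)` — contiguous strata are only
  non-overlapping under one closure convention, and an exact 40 falls in
  `40-60`. Time to onset is event date minus the *earliest* therapy start
  of the matched suspect drug (the conservative choice when several
  therapy records exist), binned `[0,30) [30,180) [180,360) [360,540)
  [540,∞)` with negatives treated as unknown.

## The 2×2 table and the four algorithms

The counting unit is the reaction record (one coded PT occurrence), so a
report with four PTs contributes four records; a per-report mode exists
behind a flag. For a target drug and term,

|              | target term | other terms |
|--------------|------------:|------------:|
| target drug  | $a$         | $b$         |
| other drugs  | $c$         | $d$         |

with $N = a+b+c+d$ and the independence expectation
$E = (a+b)(a+c)/N$. The four statistics are the canonical literature
forms used with this five-column table layout:

* **ROR** $= ad/bc$ with Wald interval
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with
  $\exp(\ln \mathrm{PRR} \pm 1.96\sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)})$,
  paired with the Pearson $\chi^2$; the Yates continuity correction is on
  by default (the common practice in PRR screening) and removable by flag.
  Note $\mathrm{ROR}/\mathrm{PRR} = (1+a/b)/(1+c/d)$, so
  $\mathrm{ROR} \ge \mathrm{PRR}$ exactly when $\mathrm{ROR} \ge 1$.
* **MGPS / EBGM.** The multi-item gamma-Poisson shrinker models
  $a \sim \mathrm{Poisson}(\lambda E)$ with
  $\lambda \sim P\,\Gamma(\alpha_1,\beta_1) + (1-P)\,\Gamma(\alpha_2,\beta_2)$.
  The five hyperparameters are estimated by maximizing the
  negative-binomial mixture marginal over all drug–term pairs of the
  database (structural zeros included; corpora here are desk-scale, so no
  data squashing is needed). The posterior for a pair is again a gamma
  mixture with weight $Q$; $\mathrm{EBGM} = 2^{E[\log_2 \lambda \mid a]}$
  has a digamma closed form, and EBGM05 is the 5th posterior percentile
  obtained by monotone root finding on the mixture CDF to
  $|F - 0.05| \le 10^{-8}$.
* **BCPNN / IC.** Two parameterizations are provided. The default links
  the information component to the same posterior as EBGM:
  $\mathrm{IC} = \log_2 \mathrm{EBGM}$, $\mathrm{IC025} = \log_2$ (2.5th
  posterior percentile) — the parameterization under which published
  five-statistic tables satisfy $\mathrm{IC} = \log_2 \mathrm{EBGM}$ to
  rounding in every row (the shipped 40-row reference table has maximum
  discrepancy 0.0066). The shrunk closed form
  $\mathrm{IC} = \log_2\frac{a+0.5}{E+0.5}$ with
  $\mathrm{IC025} = \mathrm{IC} - 3.3(a{+}0.5)^{-1/2} - 2(a{+}0.5)^{-3/2}$
  is available for comparability with other studies. In the reference
  table the printed IC025 sits slightly below $\log_2(\mathrm{EBGM05})$,
  consistent with a 2.5% posterior quantile; both readings are
  implemented and neither is asserted as the published computation.

```{r example}
pr <- mgps_prior(2, 2, 2, 4, P = 1)      # degenerate single-gamma prior
ebgm_stats(a = 5, E = 1, pr)             # posterior Gamma(7, 3)
```

### Signal thresholds

Defaults follow the usual screening conventions: ROR — $n \ge 3$ and lower
95% bound $> 1$; PRR — $\mathrm{PRR} \ge 2$, $\chi^2 \ge 4$, $n \ge 3$;
BCPNN — $\mathrm{IC025} > 0$; MGPS — $\mathrm{EBGM05} > 2$. The combined
flag is the conjunction of all four (published unified signal lists use
this), with `"any"` and per-algorithm modes available. A pair with any
undefined statistic is never flagged, and no continuity corrections are
added to ROR/PRR for zero cells: the $n \ge 3$ gate makes the $a = 0$
case irrelevant, and corrections would silently change the published
formulas.

## Numerical choices

* MGPS optimization runs BFGS on log-transformed shapes/rates and a
  logit-transformed weight, from the fixed initialization
  $(\alpha_1, \beta_1, \alpha_2, \beta_2, P) = (0.2, 0.1, 2, 4, 1/3)$.
  The likelihood is multimodal — a collapsed prior concentrated at
  $\lambda = 1$ is a local maximum on mostly-null databases — so a fixed
  panel of diverse starts plus one data-driven start (a thin component at
  the largest observed $a/E$) is always explored, and up to 20 seeded
  jittered restarts follow on failure. The fit reports its final
  log-likelihood and never returns a fit below its initialization.
* Posterior quantiles bracket between the two component quantiles, solve
  by `uniroot`, then polish with Newton steps on the CDF because an
  x-tolerance is insufficient when the posterior is sharply peaked.
* Percentages in descriptive tables round half-up at two decimals,
  matching how published tables print `64.66` for `64.6659…`.
* Denominators differ by block, the only convention under which the
  published outcome percentages are arithmetically consistent: age, sex,
  reporter, country and route use total deduplicated reports; outcomes
  use total outcome *records*; time-to-onset uses its own block total.
  Published country percentages are not consistent with the report
  denominator (they plausibly use reports with a known country), so the
  country block exposes its denominator in the output instead of
  asserting one.

## The synthetic corpus generator

`generate_faers()` emits the six ASCII tables with a structure chosen to
emulate a two-decade single-biologic corpus; its defaults *are* the study
conditions used throughout the tests:

* 20,000 reports; a 20-drug vocabulary with the target at a 5% share;
  reactions per report $1 + \mathrm{Poisson}(2)$ truncated at 10, giving
  a records-to-reports ratio near 3 (large published corpora for these
  biologics show ≈3.9);
* a 45-PT background multinomial over the toy dictionary (10 SOCs), with
  a common tier, a mid tier and a rare tail;
* one planted association — target × "Injection site pain", the dominant
  event family for injected biologics — at relative reporting rate
  $\rho = 5$, yielding an expected signal cell of roughly 50 records;
* missingness near what spontaneous systems show (≈48% of ages unknown,
  ≈55% of time-to-onset unrecoverable, ≈3% of sexes missing), a 5%
  duplicate-version rate (duplicates change only receipt date and add one
  reaction, so deduplication is observable), demographic mixtures close
  to published report-characteristics tables;
* one seeded stream drives every draw, so the same configuration is
  byte-identical across runs.

A planted multiplier $\rho$ acts on the background probability *before*
renormalization: the realized contrast against other drugs is
$\rho / Z$ with $Z = 1 + p_0(\rho - 1)$, and the observed-over-expected
ratio the estimators can reach is further damped to
$\rho / (f_t \rho + (1 - f_t) Z)$ because the planted counts sit inside
their own term margin ($f_t$ = target share of records; ≈6.75 for
$\rho = 10$). The recovery tests compare against these generator-implied
values rather than the nominal $\rho$.

What the generator does *not* emulate: real drug ontologies and name
misspellings, reporting-delay dynamics, correlated event syndromes,
legacy schema drift, multi-suspect reports. Passing tests therefore
demonstrate correctness of the machinery and calibration under a clean
background — not performance on the full heterogeneity of real FAERS.

## Operating characteristics the tests establish

On the default conditions (sizes chosen to keep a full run in minutes on
one core): the null corpus (no planted pair) flags ≤5% of pairs at the
frequency gate under the all-four rule (observed: 0); the planted
$\rho = 5$ pair is flagged by all four algorithms in ≥95% of 20 seeded
replicates (observed: 20/20); the MGPS prior mean is recovered within 10%
from 5,000 pairs simulated from a known $\Gamma(2,2)$ prior; ROR tracks
the generator-implied contrast within ±30% for $\rho \in \{2, 5, 10\}$.

## Known limitations

* **EBGM is conservative for weak signals.** At $\rho = 2$ with ~20
  expected records against an otherwise perfectly null 900-pair
  background, the mixture MLE is the collapsed prior and EBGM shrinks to
  1.0 — that is the correct maximum-likelihood answer, not an optimizer
  failure (profiling from a forced two-component start reaches the same
  maximum). ROR retains power there. Real databases are heterogeneous,
  which keeps the fitted second component broad and the shrinkage milder.
* **EBGM05 ≤ EBGM is not a theorem.** For a sharply bimodal posterior
  (near-degenerate null component, <5% weight on the diffuse one) the
  geometric mean can dip a fraction of a percent below the 5th
  percentile. Flagged pairs in practice have effectively unimodal
  posteriors where the ordering holds.
* Within-stratum analyses reuse the corpus-wide comparator cells by
  default (a flag restricts them); published stratified analyses rarely
  state which convention they use.
* The shipped dictionary is a 45-term toy; real MedDRA is licensed and
  must be supplied by the user as a two-column PT→SOC table.
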