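## Synthetic FAERS-format corpus generator.
##
## Emulates the structure of a spontaneous reporting system: case-level
## reports with demographics and heavy missingness, one primary-suspect
## drug plus concomitants, several MedDRA-coded reactions per report drawn
## from a background multinomial, outcome codes, therapy/event dates,
## duplicate case versions -- and planted drug-event associations whose
## relative reporting rate rho multiplies the background probability of
## one PT within one drug's reports. The planted truth is recoverable for
## scoring.

#' Declare a planted drug-event association
#'
#' @param drug normalized drug name (must be in the generator vocabulary).
#' @param pt preferred term (must be in the toy dictionary).
#' @param rho relative reporting rate multiplying the background PT
#'   probability within the drug's reports (`> 0`).
#' @param coadmin optional drug-name vector: the association only applies
#'   to reports also carrying one of these concomitants.
#' @param pediatric if `TRUE`, reports containing the planted PT draw
#'   their age from the `<18` group with probability 0.8 (an age-skewed
#'   event).
#' @return a `planted_association` object.
#' @export
planted_association <- function(drug, pt, rho, coadmin = NULL,
                                pediatric = FALSE) {
  stopifnot(rho > 0)
  structure(list(drug = normalize_drug_name(drug), pt = pt, rho = rho,
                 coadmin = coadmin, pediatric = isTRUE(pediatric)),
            class = "planted_association")
}

## default PT vocabulary: the toy dictionary's terms with a skewed
## background multinomial (a few common events, a mid tier, a rare tail
## that includes the default planted ISR term)
default_pt_table <- function() {
  d <- data.table::fread(system.file("extdata", "meddra_toy.tsv",
                                     package = "faersignal", mustWork = TRUE),
                         sep = "\t")
  w <- rep(1, nrow(d))
  common <- c("Pyrexia", "Malaise", "Headache", "Nausea", "Rash",
              "Arthralgia", "Off label use", "Diarrhoea", "Cough",
              "Abdominal pain")
  rare <- c("Injection site pain", "Injection site erythema",
            "Injection site pruritus", "Injection site reaction",
            "Septic shock", "Sepsis", "Measles",
            "Necrotising fasciitis streptococcal", "Intestinal sepsis",
            "Pulmonary embolism", "Pancytopenia", "Mouth ulceration",
            "Condition aggravated", "Haemoglobin decreased",
            "C-reactive protein increased")
  w[d$pt %in% common] <- 3
  w[d$pt %in% rare] <- 0.2
  data.table(pt = d$pt, soc = d$soc, prob = w / sum(w))
}

## default drug vocabulary: one target biologic plus 19 background drugs
default_drug_table <- function() {
  data.table(name = c("ANAKINRA", sprintf("DRUG%02d", 1:19)),
             prob = rep(0.05, 20))
}

default_concomitant_table <- function() {
  data.table(
    name = c("PREDNISONE", "METHYLPREDNISOLONE", "METHOTREXATE",
             "ACETAMINOPHEN", "OMEPRAZOLE", "COLCHICINE", "ASPIRIN",
             "IBUPROFEN", "FOLIC ACID", "AMOXICILLIN"),
    prob = c(0.28, 0.06, 0.15, 0.10, 0.08, 0.08, 0.08, 0.07, 0.06, 0.04))
}

#' Synthetic corpus configuration
#'
#' Defaults emulate a two-decade spontaneous-report corpus for one
#' biologic: 20,000 reports, a 20-drug vocabulary with the target holding
#' a 5% share, 1 + Poisson(2) reactions per report (truncated at 10,
#' giving a records-to-reports ratio near 3), report-level missingness
#' close to what spontaneous systems show (about half of ages unknown,
#' about half of time-to-onset unrecoverable), 5% duplicate case
#' versions, and one planted association (target drug x "Injection site
#' pain") at relative reporting rate 5 with an expected signal cell of
#' roughly 50 records.
#'
#' @param n_reports number of distinct cases.
#' @param drugs `data.table(name, prob)` primary-suspect drug vocabulary.
#' @param pts `data.table(pt, soc, prob)` background reaction multinomial.
#' @param associations list of [planted_association()]s.
#' @param duplicate_fraction fraction of cases emitted twice as a later
#'   version (distinct `primaryid`, receipt date + 30 days, one extra
#'   reaction).
#' @param reactions_lambda Poisson mean of (reactions per report - 1).
#' @param reactions_max per-report reaction cap.
#' @param missing_age,missing_sex,missing_event_date,missing_occupation,missing_start_date
#'   per-field missingness probabilities.
#' @param sex_probs,occupation_probs,country_probs,route_probs,age_group_probs
#'   named probability vectors for the demographic mixture.
#' @param concomitants `data.table(name, prob)`; each report draws 0-3.
#' @param n_concomitant_probs probabilities of 0,1,2,3 concomitants.
#' @param indication_probs named probability vector of indication PTs
#'   (drawn for 85% of reports).
#' @param outcome_count_probs probabilities of 0,1,2 outcome records.
#' @param outcome_probs named probability vector over outcome codes.
#' @param seed integer seed; the whole corpus is reproducible from it.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(
    n_reports = 20000L,
    drugs = default_drug_table(),
    pts = default_pt_table(),
    associations = list(planted_association("ANAKINRA", "Injection site pain",
                                            rho = 5)),
    duplicate_fraction = 0.05,
    reactions_lambda = 2,
    reactions_max = 10L,
    missing_age = 0.48,
    missing_sex = 0.03,
    missing_event_date = 0.35,
    missing_occupation = 0.05,
    missing_start_date = 0.30,
    sex_probs = c(F = 0.65, M = 0.35),
    occupation_probs = c(CN = 0.66, MD = 0.16, PH = 0.08, OT = 0.06,
                         RN = 0.02, LW = 0.02),
    country_probs = c(US = 0.71, FR = 0.08, DE = 0.06, GB = 0.05, JP = 0.05,
                      CA = 0.05),
    route_probs = c(SUBCUTANEOUS = 0.72, OTHER = 0.26, INTRAVENOUS = 0.02),
    age_group_probs = c(`<18` = 0.25, `18-40` = 0.21, `40-60` = 0.29,
                        `60-80` = 0.23, `>=80` = 0.02),
    concomitants = default_concomitant_table(),
    n_concomitant_probs = c(0.35, 0.30, 0.20, 0.15),
    indication_probs = c(`Rheumatoid arthritis` = 0.25,
                         `Still's disease` = 0.20,
                         `Product used for unknown indication` = 0.20,
                         `Juvenile idiopathic arthritis` = 0.15,
                         `Cryopyrin-associated periodic syndrome` = 0.10,
                         `Pericardial disease` = 0.05,
                         Gout = 0.05),
    outcome_count_probs = c(0.45, 0.45, 0.10),
    outcome_probs = c(OT = 0.45, HO = 0.33, DE = 0.10, LT = 0.05, DS = 0.03,
                      CA = 0.02, RI = 0.02),
    seed = 1L) {
  stopifnot(n_reports >= 1, duplicate_fraction >= 0, duplicate_fraction < 1,
            abs(sum(drugs$prob) - 1) < 1e-8, abs(sum(pts$prob) - 1) < 1e-8,
            all(drugs$prob >= 0), all(pts$prob >= 0))
  for (as_ in associations) {
    stopifnot(inherits(as_, "planted_association"))
    if (!as_$drug %in% drugs$name)
      stop("planted drug not in vocabulary: ", as_$drug)
    if (!as_$pt %in% pts$pt)
      stop("planted PT not in dictionary: ", as_$pt)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Ground-truth table of planted associations
#'
#' @param config a [synthetic_config()].
#' @return `data.table` with columns `drug`, `pt`, `rho`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!length(config$associations)) {
    return(data.table(drug = character(), pt = character(), rho = numeric()))
  }
  rbindlist(lapply(config$associations, function(x)
    data.table(drug = x$drug, pt = x$pt, rho = x$rho)))
}

fmt_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

#' Generate a synthetic FAERS-format corpus
#'
#' Writes DEMO/DRUG/REAC/OUTC/INDI/THER files in the "$"-delimited ASCII
#' dialect read by [read_faers_table()]. Fully reproducible from
#' `config$seed`: the same configuration yields byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   ([planted_truth()]) and the `config`.
#' @export
generate_faers <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cf <- config
  n <- as.integer(cf$n_reports)

  with_local_seed(cf$seed, {
    caseid <- 3000000L + seq_len(n)
    primaryid <- caseid * 10L + 1L

    ## primary-suspect drug and concomitants
    drug_idx <- sample.int(nrow(cf$drugs), n, replace = TRUE,
                           prob = cf$drugs$prob)
    ps_drug <- cf$drugs$name[drug_idx]
    n_con <- sample(0:3, n, replace = TRUE, prob = cf$n_concomitant_probs)
    con_rep <- rep(seq_len(n), n_con)
    con_all <- sample(cf$concomitants$name, sum(n_con), replace = TRUE,
                      prob = cf$concomitants$prob)

    ## reactions: per-report weight profile determined by which planted
    ## associations apply (PS drug match + optional coadmin condition)
    K <- pmin(1L + rpois(n, cf$reactions_lambda), cf$reactions_max)
    sig <- rep("", n)
    for (j in seq_along(cf$associations)) {
      as_ <- cf$associations[[j]]
      sel <- ps_drug == as_$drug
      if (!is.null(as_$coadmin)) {
        co_hit <- unique(con_rep[normalize_drug_name(con_all) %in%
                                   normalize_drug_name(as_$coadmin)])
        sel <- sel & seq_len(n) %in% co_hit
      }
      sig[sel] <- paste0(sig[sel], ",", j)
    }
    rep_id <- rep(seq_len(n), K)
    pt_idx <- integer(length(rep_id))
    for (s in unique(sig)) {
      w <- cf$pts$prob
      if (nzchar(s)) {
        for (j in as.integer(strsplit(sub("^,", "", s), ",")[[1L]])) {
          as_ <- cf$associations[[j]]
          w[cf$pts$pt == as_$pt] <- w[cf$pts$pt == as_$pt] * as_$rho
        }
        w <- w / sum(w)
      }
      rows <- which(sig[rep_id] == s)
      pt_idx[rows] <- sample.int(nrow(cf$pts), length(rows), replace = TRUE,
                                 prob = w)
    }
    reac <- unique(data.table(report = rep_id, pt = cf$pts$pt[pt_idx]))

    ## demographics
    sex <- sample(names(cf$sex_probs), n, replace = TRUE, prob = cf$sex_probs)
    agegrp <- sample(names(cf$age_group_probs), n, replace = TRUE,
                     prob = cf$age_group_probs)
    for (as_ in cf$associations) {
      if (isTRUE(as_$pediatric)) {
        hit <- unique(reac[pt == as_$pt, report])
        skew <- hit[runif(length(hit)) < 0.8]
        agegrp[skew] <- "<18"
      }
    }
    lo <- c(`<18` = 1, `18-40` = 18, `40-60` = 40, `60-80` = 60, `>=80` = 80)
    hi <- c(`<18` = 17, `18-40` = 39, `40-60` = 59, `60-80` = 79, `>=80` = 94)
    age_yr <- floor(runif(n, lo[agegrp], hi[agegrp] + 1))
    age_cod <- rep("YR", n)
    ## a share of pediatric ages is reported in months
    in_months <- agegrp == "<18" & runif(n) < 0.3
    age_val <- ifelse(in_months, age_yr * 12, age_yr)
    age_cod[in_months] <- "MON"
    occp <- sample(names(cf$occupation_probs), n, replace = TRUE,
                   prob = cf$occupation_probs)
    ctry <- sample(names(cf$country_probs), n, replace = TRUE,
                   prob = cf$country_probs)
    route <- sample(names(cf$route_probs), n, replace = TRUE,
                    prob = cf$route_probs)

    ## dates: therapy start in 2004-2023; time-to-onset a short/long
    ## exponential mixture; receipt shortly after the event
    start_dt <- as.Date("2004-01-01") +
      sample.int(as.integer(as.Date("2023-06-30") - as.Date("2004-01-01")),
                 n, replace = TRUE)
    tto <- ifelse(runif(n) < 0.6, rexp(n, 1 / 30), rexp(n, 1 / 400))
    event_dt <- start_dt + floor(tto)
    fda_dt <- event_dt + 1L + rpois(n, 20)

    ## missingness
    age_val[runif(n) < cf$missing_age] <- NA
    sex[runif(n) < cf$missing_sex] <- ""
    occp[runif(n) < cf$missing_occupation] <- ""
    event_miss <- runif(n) < cf$missing_event_date
    start_miss <- runif(n) < cf$missing_start_date

    ## outcomes
    n_out <- sample(0:2, n, replace = TRUE, prob = cf$outcome_count_probs)
    out_rep <- rep(seq_len(n), n_out)
    outc <- unique(data.table(
      report = out_rep,
      outc_cod = sample(names(cf$outcome_probs), length(out_rep),
                        replace = TRUE, prob = cf$outcome_probs)))

    ## indications for the PS drug
    has_ind <- runif(n) < 0.85
    indi <- data.table(
      report = which(has_ind),
      indi_pt = sample(names(cf$indication_probs), sum(has_ind),
                       replace = TRUE, prob = cf$indication_probs))

    ## duplicate case versions: same caseid, later primaryid and receipt
    ## date, one extra reaction
    dup <- which(runif(n) < cf$duplicate_fraction)

    demo <- data.table(
      primaryid = primaryid, caseid = caseid,
      fda_dt = fmt_faers_date(fda_dt),
      event_dt = ifelse(event_miss, "", fmt_faers_date(event_dt)),
      age = ifelse(is.na(age_val), "", age_val),
      age_cod = ifelse(is.na(age_val), "", age_cod),
      sex = sex, occp_cod = occp, reporter_country = ctry)

    drug_rows <- rbind(
      data.table(primaryid = primaryid, caseid = caseid, drug_seq = 1L,
                 role_cod = "PS", drugname = ps_drug, prod_ai = ps_drug,
                 route = route),
      if (sum(n_con)) data.table(
        primaryid = primaryid[con_rep], caseid = caseid[con_rep],
        drug_seq = 1L + sequence(n_con[n_con > 0]),
        role_cod = "C",
        drugname = con_all, prod_ai = con_all,
        route = ""))
    reac_rows <- data.table(primaryid = primaryid[reac$report],
                            caseid = caseid[reac$report], pt = reac$pt)
    outc_rows <- data.table(primaryid = primaryid[outc$report],
                            caseid = caseid[outc$report],
                            outc_cod = outc$outc_cod)
    indi_rows <- data.table(primaryid = primaryid[indi$report],
                            caseid = caseid[indi$report],
                            indi_drug_seq = 1L, indi_pt = indi$indi_pt)
    ther_rows <- data.table(
      primaryid = primaryid, caseid = caseid, dsg_drug_seq = 1L,
      start_dt = ifelse(start_miss, "", fmt_faers_date(start_dt)))

    if (length(dup)) {
      dup_pid <- caseid[dup] * 10L + 2L
      pid_map <- setNames(dup_pid, primaryid[dup])
      redo <- function(dt) {
        x <- dt[primaryid %in% names(pid_map)]
        x[, primaryid := unname(pid_map[as.character(primaryid)])]
        x
      }
      d2 <- redo(demo)
      d2[, fda_dt := fmt_faers_date(parse_faers_date(fda_dt) + 30L)]
      extra_pt <- sample(cf$pts$pt, length(dup), replace = TRUE,
                         prob = cf$pts$prob)
      r2 <- rbind(redo(reac_rows),
                  data.table(primaryid = dup_pid, caseid = caseid[dup],
                             pt = extra_pt))
      r2 <- unique(r2)
      demo <- rbind(demo, d2)
      drug_rows <- rbind(drug_rows, redo(drug_rows))
      reac_rows <- rbind(reac_rows, r2)
      outc_rows <- rbind(outc_rows, redo(outc_rows))
      indi_rows <- rbind(indi_rows, redo(indi_rows))
      ther_rows <- rbind(ther_rows, redo(ther_rows))
    }

    tables <- list(DEMO = demo, DRUG = drug_rows, REAC = reac_rows,
                   OUTC = outc_rows, INDI = indi_rows, THER = ther_rows)
    paths <- character(0)
    for (nm in names(tables)) {
      t <- copy(tables[[nm]])
      setorderv(t, intersect(c("primaryid", "drug_seq", "pt", "outc_cod",
                               "indi_pt"), names(t)))
      p <- file.path(out_dir, paste0(nm, ".txt"))
      data.table::fwrite(t, p, sep = "$", quote = FALSE, na = "", eol = "\n")
      paths[nm] <- p
    }
    invisible(list(paths = paths, truth = planted_truth(cf), config = cf))
  })
}
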