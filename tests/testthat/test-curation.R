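make_demo <- function(primaryid, caseid, fda_dt) {
  data.table::data.table(primaryid = as.character(primaryid),
                         caseid = as.character(caseid),
                         fda_dt = as.Date(fda_dt))
}

test_that("deduplication keeps the most recent case version", {
  demo <- make_demo(c("1", "2", "3"), c("X", "X", "Y"),
                    c("2020-01-01", "2021-06-01", "2019-05-05"))
  kept <- dedup_reports(demo)
  expect_equal(sort(kept$primaryid), c("2", "3"))   # 2021-06-01 wins for X
  expect_equal(attr(kept, "n_removed"), 1L)
})

test_that("dedup tie-break, idempotence and permutation invariance match a brute-force oracle", {
  demo <- make_demo(c("100", "250", "7", "8", "9"),
                    c("X", "X", "Y", "Y", "Z"),
                    c("2020-01-01", "2020-01-01", "2020-02-01", NA, NA))
  # independent oracle: per case, max date (NA lowest) then max numeric id
  oracle <- vapply(split(seq_len(nrow(demo)), demo$caseid), function(idx) {
    d <- demo[idx]
    key <- as.numeric(d$fda_dt); key[is.na(key)] <- -Inf
    best <- idx[order(key, as.numeric(d$primaryid))]
    demo$primaryid[best[length(best)]]
  }, character(1))
  for (perm in list(1:5, 5:1, c(2, 4, 1, 5, 3), c(3, 1, 5, 2, 4))) {
    kept <- dedup_reports(demo[perm])
    expect_setequal(kept$primaryid, unname(oracle))
    expect_identical(sort(dedup_reports(kept)$primaryid),
                     sort(kept$primaryid))            # idempotent
    expect_false(anyDuplicated(kept$caseid) > 0)
    expect_lte(nrow(kept), nrow(demo))
  }
  expect_true("250" %in% dedup_reports(demo)$primaryid)  # ties -> larger id
})

test_that("exact full-row duplicates are removed before version selection", {
  demo <- make_demo(c("1", "1", "2"), c("X", "X", "X"),
                    c("2020-01-01", "2020-01-01", "2019-01-01"))
  kept <- dedup_reports(demo)
  expect_equal(kept$primaryid, "1")
  expect_equal(attr(kept, "n_removed"), 2L)
})

test_that("drug matching normalizes names, honours the role filter and word boundaries", {
  drug <- data.table::data.table(
    primaryid = c("1", "2", "3", "4", "5"),
    drug_seq = 1L,
    role_cod = c("PS", "C", "PS", "PS", "PS"),
    drugname = c("KINERET.", "anakinra", "KINERET 100MG SYRINGE",
                 "KINERETOL", "unrelated"),
    prod_ai = c(NA, NA, NA, NA, "ANAKINRA"))
  q <- drug_query("anakinra", "kineret")
  hits <- match_target_reports(drug, q)
  expect_true("1" %in% hits)      # trailing punctuation stripped
  expect_false("2" %in% hits)     # right name, wrong role
  expect_true("3" %in% hits)      # whole-word containment
  expect_false("4" %in% hits)     # no partial-word match
  expect_true("5" %in% hits)      # active-ingredient field searched
  # a report with both a matching PS drug and unrelated drugs matches once
  drug2 <- rbind(drug, data.table::data.table(
    primaryid = "1", drug_seq = 2L, role_cod = "C",
    drugname = "PREDNISONE", prod_ai = NA))
  expect_equal(sum(match_target_reports(drug2, q) == "1"), 1L)
})

test_that("PT to SOC mapping uses the dictionary with an unmapped sentinel", {
  dict <- toy_meddra()
  expect_equal(map_pt_to_soc("Injection site pain", dict),
               "General disorders and administration site conditions")
  expect_equal(map_pt_to_soc("Pyrexia", dict),
               "General disorders and administration site conditions")
  expect_equal(map_pt_to_soc("pyrexia  ", dict),
               "General disorders and administration site conditions")
  expect_equal(map_pt_to_soc("No such term", dict), "unmapped")
  expect_error(meddra_dictionary(c("A", "a"), c("S1", "S2")), "more than one")
})

test_that("minimum-count filter keeps rows at or above the gate", {
  tab <- data.table::data.table(term = c("A", "B", "C"), a = c(5L, 3L, 2L))
  expect_equal(filter_min_count(tab, 3)$term, c("A", "B"))
  expect_equal(nrow(filter_min_count(tab, 1)), 3L)    # min 1 is identity
  expect_error(filter_min_count(tab, 0), "min_count")
  set.seed(99)
  big <- data.table::data.table(term = paste0("T", 1:100),
                                a = c(sample(0:2, 40, TRUE),
                                      sample(3:50, 60, TRUE)))
  expect_equal(nrow(filter_min_count(big, 3)), 60L)
})

test_that("indication-term exclusion removes exactly the listed PTs", {
  tab <- data.table::data.table(
    term = c("Rheumatoid arthritis", "Pyrexia", "Still's disease",
             "Gout", "Rash"), a = 1:5)
  out <- suppressMessages(
    exclude_indication_pts(tab, c("rheumatoid arthritis", "STILL'S DISEASE",
                                  "Gout", "Absent one", "Another absent")))
  expect_equal(out$term, c("Pyrexia", "Rash"))
  expect_equal(attr(out, "n_removed"), 3L)            # 3 of 5 present
  expect_equal(exclude_indication_pts(tab, character())$term, tab$term)
})

test_that("exclusion and count filtering commute", {
  tab <- data.table::data.table(term = c("A", "B", "C", "D"),
                                a = c(5L, 2L, 9L, 1L))
  ex <- c("C")
  ab <- filter_min_count(suppressMessages(exclude_indication_pts(tab, ex)), 3)
  ba <- suppressMessages(exclude_indication_pts(filter_min_count(tab, 3), ex))
  expect_equal(ab$term, ba$term)
  expect_equal(ab$a, ba$a)
})

test_that("reporter classification partitions its domain", {
  expect_equal(classify_reporter("PH"), "health professional")
  expect_equal(classify_reporter(c("MD", "OT", "RN")),
               rep("health professional", 3))
  expect_equal(classify_reporter(c("CN", "LW")),
               rep("non-health professional", 2))
  expect_equal(classify_reporter(c(NA, "", "XX")), rep("unknown", 3))
  inputs <- c("MD", "PH", "OT", "RN", "CN", "LW", "", "Z", NA)
  cls <- classify_reporter(inputs)
  expect_true(all(cls %in% c("health professional", "non-health professional",
                             "unknown")))
  expect_equal(length(cls), length(inputs))           # total, one class each
})

test_that("age groups use unit conversion and left-closed bins", {
  expect_equal(as.character(assign_age_group(17, "YR")), "<18")
  expect_equal(as.character(assign_age_group(40, "YR")), "40-60") # boundary
  expect_equal(as.character(assign_age_group(6, "MON")), "<18")
  expect_equal(as.character(assign_age_group(3, "DEC")), "18-40")
  expect_equal(as.character(assign_age_group(8, "DEC")), ">=80")
  expect_equal(as.character(assign_age_group(-5, "YR")), "unknown")
  expect_equal(as.character(assign_age_group(NA, "YR")), "unknown")
  expect_equal(as.character(assign_age_group(10, "ZZ")), "unknown")
  # partition: every generated input lands in exactly one bin
  set.seed(1)
  g <- assign_age_group(c(runif(500, -10, 120), rep(NA, 20)),
                        sample(c("YR", "MON", "DEC", "WK", "DY", "HR", "??"),
                               520, TRUE))
  expect_false(anyNA(g))
  expect_equal(length(g), 520L)
})

test_that("time to onset uses calendar arithmetic with half-open bins", {
  t1 <- compute_tto(as.Date("2020-01-01"), as.Date("2020-01-15"))
  expect_equal(t1$days, 14L)
  expect_equal(as.character(t1$bin), "<30")
  t2 <- compute_tto(as.Date("2020-01-15"), as.Date("2020-01-01"))
  expect_true(is.na(t2$days))                         # event before start
  expect_equal(as.character(t2$bin), "unknown")
  # independent calendar oracle for a >540-day span
  oracle_days <- as.integer(difftime(as.Date("2021-07-01"),
                                     as.Date("2020-01-01"), units = "days"))
  expect_equal(oracle_days, 547L)
  t3 <- compute_tto(as.Date("2020-01-01"), as.Date("2021-07-01"))
  expect_equal(t3$days, oracle_days)
  expect_equal(as.character(t3$bin), ">=540")
  expect_equal(as.character(compute_tto(as.Date(NA), as.Date("2020-01-01"))$bin),
               "unknown")
})

test_that("case-report assembly derives classification fields on the tiny corpus", {
  corpus <- read_faers_corpus(tiny_corpus_dir())
  cases <- build_case_reports(corpus, drug_query("target"), dict = tiny_dict())
  expect_equal(nrow(cases$cases), 1L)
  cc <- cases$cases
  expect_equal(cc$primaryid, "101")
  expect_equal(cc$reporter_class, "health professional")
  expect_equal(as.character(cc$age_group), "18-40")
  expect_equal(cc$tto_days, 14L)                      # 2019-12-20 -> 2020-01-03
  expect_equal(as.character(cc$tto_bin), "<30")
  expect_equal(cc$route, "SUBCUTANEOUS")
  expect_equal(nrow(cases$reactions), 2L)
  expect_equal(cases$concomitants$name, "PREDNISONE")
  expect_equal(cases$indications$indi_pt, "Rheumatoid arthritis")
})
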