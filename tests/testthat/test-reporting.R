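test_that("the percentage rule reproduces every printed reference percentage", {
  r <- reference_percentages()
  expect_gt(nrow(r), 60)
  expect_equal(r$pct, r$printed_pct)   # exact at two decimals, all blocks
  # spot checks with the block denominators the rule implies
  expect_equal(pct_half_up(4878, 7544), 64.66)   # female share of reports
  expect_equal(pct_half_up(486, 2280 + 1628 + 486 + 122 + 49 + 24 + 13),
               10.56)                            # death share of outcomes
  expect_equal(pct_half_up(1827, 1827 + 241 + 85 + 60 + 251 + 3116),
               32.74)                            # onset <30d share of block
})

test_that("percentages round half-up at two decimals", {
  expect_equal(round_half_up(2.675, 2), 2.68)    # base round() would give 2.67
  expect_equal(round_half_up(2.665, 2), 2.67)
  expect_equal(round_half_up(-2.675, 2), -2.68)
  expect_equal(pct_half_up(1, 3), 33.33)
  expect_equal(pct_half_up(2, 3), 66.67)
})

test_that("demographics blocks use their stated denominators and sum to 100", {
  corpus <- read_faers_corpus(subgroup_corpus_dir())
  cases <- build_case_reports(corpus, drug_query("target"), dict = toy_meddra())
  tab <- demographics_table(cases)
  n_rep <- nrow(cases$cases)
  expect_true(all(tab[block %in% c("age", "sex", "reporter", "country",
                                   "route"), denom] == n_rep))
  expect_equal(unique(tab[block == "outcomes", denom]),
               nrow(cases$outcomes))             # outcome records, not reports
  for (b in unique(tab$block)) {
    expect_equal(sum(tab[block == b, pct]), 100, tolerance = 0.05)
    expect_equal(sum(tab[block == b, count]), tab[block == b, denom][1])
  }
  # a single-report corpus puts 100.00 in every populated category
  one <- build_case_reports(read_faers_corpus(tiny_corpus_dir()),
                            drug_query("target"))
  t1 <- demographics_table(one)
  expect_true(all(t1[count > 0, pct] == 100.00))
})

test_that("top indications and concomitants rank by count then name", {
  dir <- tempfile("t2"); dir.create(dir)
  writeLines(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$reporter_country",
    sprintf("%d$C%d$20200101$$$$F$MD$US", 1:5, 1:5)),
    file.path(dir, "DEMO.txt"))
  writeLines(c(
    "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai$route",
    sprintf("%d$C%d$1$PS$TARGET$TARGET$SC", 1:5, 1:5),
    "1$C1$2$C$METHOTREXATE$METHOTREXATE$ORAL",
    "2$C2$2$C$METHOTREXATE$METHOTREXATE$ORAL",
    "3$C3$2$C$ASPIRIN$ASPIRIN$ORAL"),
    file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$caseid$pt", sprintf("%d$C%d$Pyrexia", 1:5, 1:5)),
             file.path(dir, "REAC.txt"))
  writeLines("primaryid$caseid$outc_cod", file.path(dir, "OUTC.txt"))
  writeLines(c("primaryid$caseid$indi_drug_seq$indi_pt",
               "1$C1$1$Rheumatoid arthritis",
               "2$C2$1$Rheumatoid arthritis",
               "3$C3$1$Rheumatoid arthritis",
               "4$C4$1$Gout",
               "5$C5$1$Still's disease"),
             file.path(dir, "INDI.txt"))
  writeLines("primaryid$caseid$dsg_drug_seq$start_dt", file.path(dir, "THER.txt"))
  cases <- build_case_reports(read_faers_corpus(dir), drug_query("target"))
  tic <- top_indications_concomitants(cases, top = 5)
  expect_equal(tic$indications$term[1], "Rheumatoid arthritis")
  expect_equal(tic$indications$n[1], 3L)
  expect_equal(nrow(tic$indications), 3L)        # top 5 over 3 distinct
  expect_equal(tic$concomitants$name[1], "METHOTREXATE")
  expect_equal(tic$concomitants$n, c(2L, 1L))
  # ties break alphabetically
  expect_equal(tic$indications$term[2:3], c("Gout", "Still's disease"))
})

test_that("no concomitants yields an empty second list", {
  cases <- build_case_reports(read_faers_corpus(subgroup_corpus_dir()),
                              drug_query("target"))
  cases$concomitants <- cases$concomitants[0]
  expect_equal(nrow(top_indications_concomitants(cases)$concomitants), 0L)
})

test_that("signal-table formatting matches the published cell style", {
  s <- data.table::data.table(
    soc = "General disorders and administration site conditions",
    term = "Injection site pain", n = 895L,
    ror = 6.554, ror_lo95 = 6.131, ror_hi95 = 7.008,
    prr = 6.38, prr_lo95 = 6.02, prr_hi95 = 6.77, chisq = 4067.63,
    ic = 2.67, ic025 = 2.57, ebgm = 6.36, ebgm05 = 6.02)
  f <- format_signal_table(s)
  expect_equal(f$`ROR (95% CI)`, "6.55 (6.13, 7.01)")
  expect_equal(f$`IC (IC025)`, "2.67 (2.57)")
  expect_equal(f$`EBGM (EBGM05)`, "6.36 (6.02)")
  expect_identical(format_signal_table(s), f)    # deterministic
  s_na <- data.table::copy(s)[, c("ror", "ror_lo95", "ror_hi95") := NA_real_]
  expect_equal(format_signal_table(s_na)$`ROR (95% CI)`, "NA")
})

test_that("rendering then parsing a formatted table recovers two-decimal values", {
  s <- data.table::data.table(
    soc = "S", term = "T", n = 42L,
    ror = 3.14159, ror_lo95 = 2.71828, ror_hi95 = 3.62,
    prr = 3.1, prr_lo95 = 2.7, prr_hi95 = 3.6, chisq = 123.456,
    ic = 1.65, ic025 = 1.2, ebgm = 3.11, ebgm05 = 2.69)
  f <- format_signal_table(s)
  got <- as.numeric(regmatches(f$`ROR (95% CI)`,
                               regexec("^([0-9.]+) \\(([0-9.]+), ([0-9.]+)\\)$",
                                       f$`ROR (95% CI)`))[[1]][2:4])
  expect_equal(got, round_half_up(c(s$ror, s$ror_lo95, s$ror_hi95), 2))
})
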