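# independent brute-force oracles, written against the textbook formulas
oracle_ror <- function(a, b, c, d) {
  r <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(r, exp(log(r) - 1.96 * se), exp(log(r) + 1.96 * se))
}
oracle_prr <- function(a, b, c, d) {
  r <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(r, exp(log(r) - 1.96 * se), exp(log(r) + 1.96 * se))
}
oracle_chisq <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("ROR and PRR match direct arithmetic on the canonical example", {
  r <- ror_stats(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0)
  o <- oracle_ror(10, 90, 100, 9900)
  expect_equal(unlist(r, use.names = FALSE), o, tolerance = 1e-12)
  p <- prr_stats(10, 90, 100, 9900)
  expect_equal(p$prr, 10.0)
  expect_equal(unlist(p, use.names = FALSE), oracle_prr(10, 90, 100, 9900),
               tolerance = 1e-12)
  expect_equal(chisq_stat(10, 90, 100, 9900, yates = FALSE),
               oracle_chisq(10, 90, 100, 9900), tolerance = 1e-12)
})

test_that("independent tables give ROR = PRR = 1 and zero Pearson chi-square", {
  expect_equal(ror_stats(10, 10, 10, 10)$ror, 1.0)
  expect_equal(prr_stats(10, 10, 10, 10)$prr, 1.0)
  expect_equal(chisq_stat(10, 10, 10, 10, yates = FALSE), 0)
  # a/(a+b) = c/(c+d) but asymmetric margins
  expect_equal(prr_stats(5, 45, 20, 180)$prr, 1.0)
  expect_equal(chisq_stat(5, 45, 20, 180, yates = FALSE), 0)
  expect_equal(ic_stats(10, 10, mode = "closed")$ic, 0)  # a = E
})

test_that("all three statistics match brute-force oracles on 1000 random tables", {
  tabs <- random_tables(1000, seed = 7)
  r <- ror_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- prr_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  x2 <- chisq_stat(tabs$a, tabs$b, tabs$c, tabs$d, yates = FALSE)
  for (i in seq_len(nrow(tabs))) {
    o1 <- oracle_ror(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    o2 <- oracle_prr(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(c(r$ror[i], r$ror_lo95[i], r$ror_hi95[i]), o1,
                 tolerance = 1e-10)
    expect_equal(c(p$prr[i], p$prr_lo95[i], p$prr_hi95[i]), o2,
                 tolerance = 1e-10)
    expect_equal(x2[i],
                 oracle_chisq(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]),
                 tolerance = 1e-10)
  }
})

test_that("the ROR/PRR algebraic identity holds and orders the two statistics", {
  tabs <- random_tables(500, seed = 11)
  r <- ror_stats(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  p <- prr_stats(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  identity <- (1 + tabs$a / tabs$b) / (1 + tabs$c / tabs$d)
  expect_equal(r / p, identity, tolerance = 1e-12)
  elevated <- r >= 1
  expect_true(all(r[elevated] >= p[elevated]))
  expect_true(all(r[!elevated] <= p[!elevated]))
})

test_that("the Yates correction strictly shrinks a non-degenerate chi-square", {
  expect_lt(chisq_stat(10, 90, 100, 9900, yates = TRUE),
            chisq_stat(10, 90, 100, 9900, yates = FALSE))
})

test_that("zero cells flag statistics as undefined", {
  expect_true(is.na(ror_stats(5, 0, 3, 10)$ror))
  expect_true(is.na(ror_stats(0, 5, 3, 10)$ror))
  expect_true(is.na(prr_stats(5, 5, 0, 10)$prr))
  expect_true(is.na(chisq_stat(0, 0, 3, 10)))
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("contingency cells on the tiny corpus match the hand count", {
  corpus <- read_faers_corpus(tiny_corpus_dir())
  events <- build_event_table(corpus, query = drug_query("target"))
  pairs <- pair_counts(events, level = "pt")
  expect_equal(nrow(events), 6L)
  row <- pairs[drug == "TARGET" & term == "PT_A"]
  expect_equal(row$a, 1L); expect_equal(row$b, 1L)
  expect_equal(row$c_, 1L); expect_equal(row$d, 3L)
  expect_equal(row$N, 6L)
  expect_equal(row$E, 2 * 2 / 6)
  # a term absent from the target drug is still tabulated with a = 0
  expect_equal(pairs[drug == "TARGET" & term == "PT_C", a], 0L)
  # margin conservation: sum(a+b) per drug = the drug's AE record count,
  # and the term margins over one drug's rows add to the corpus total
  tgt <- pairs[drug == "TARGET"]
  expect_equal(tgt$a + tgt$b, rep(2L, nrow(tgt)))
  expect_equal(sum(tgt$a), 2L)
  expect_equal(tgt$a + tgt$c_, sapply(
    tgt$term, function(t) sum(events$term == t)), ignore_attr = TRUE)
  expect_true(all(pairs[a > 0, E] > 0))
})

test_that("SOC-level tabulation rolls terms up through the dictionary", {
  corpus <- read_faers_corpus(tiny_corpus_dir())
  events <- build_event_table(corpus, query = drug_query("target"),
                              dict = tiny_dict())
  pairs <- pair_counts(events, level = "soc")
  expect_setequal(unique(pairs$term), c("SOC_1", "SOC_2"))
  expect_equal(pairs[drug == "TARGET" & term == "SOC_1", a], 2L)
  expect_equal(sum(pairs$a), 6L)
})
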