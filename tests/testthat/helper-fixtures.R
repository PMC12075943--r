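# fixtures are built in code at test time; nothing binary ships with the
# package

write_dollar_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# a minimal 4-report corpus with 6 reaction records and one target pair:
#   report 101 (TARGET):  PT_A, PT_B
#   report 102 (OTHER1):  PT_A
#   report 103 (OTHER2):  PT_B, PT_C
#   report 104 (OTHER1):  PT_C
# hand-counted cells for (TARGET, PT_A): a=1, b=1, c=1, d=3
tiny_corpus_dir <- function() {
  dir <- tempfile("corpus")
  dir.create(dir)
  writeLines(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$reporter_country",
    "101$C1$20200105$20200103$34$YR$F$MD$US",
    "102$C2$20200210$20200201$5$YR$M$CN$US",
    "103$C3$20200315$$45$YR$F$PH$FR",
    "104$C4$20200402$20200330$$$$CN$US"),
    file.path(dir, "DEMO.txt"))
  writeLines(c(
    "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai$route",
    "101$C1$1$PS$TARGET$TARGET$SUBCUTANEOUS",
    "101$C1$2$C$PREDNISONE$PREDNISONE$ORAL",
    "102$C2$1$PS$OTHER1$OTHER1$ORAL",
    "103$C3$1$PS$OTHER2$OTHER2$ORAL",
    "104$C4$1$PS$OTHER1$OTHER1$ORAL"),
    file.path(dir, "DRUG.txt"))
  writeLines(c(
    "primaryid$caseid$pt",
    "101$C1$PT_A", "101$C1$PT_B",
    "102$C2$PT_A",
    "103$C3$PT_B", "103$C3$PT_C",
    "104$C4$PT_C"),
    file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$caseid$outc_cod",
               "101$C1$DE", "102$C2$HO"),
    file.path(dir, "OUTC.txt"))
  writeLines(c("primaryid$caseid$indi_drug_seq$indi_pt",
               "101$C1$1$Rheumatoid arthritis"),
    file.path(dir, "INDI.txt"))
  writeLines(c("primaryid$caseid$dsg_drug_seq$start_dt",
               "101$C1$1$20191220"),
    file.path(dir, "THER.txt"))
  dir
}

tiny_dict <- function() {
  meddra_dictionary(
    pt = c("PT_A", "PT_B", "PT_C", "Rheumatoid arthritis"),
    soc = c("SOC_1", "SOC_1", "SOC_2",
            "Musculoskeletal and connective tissue disorders"))
}

# random 2x2 tables with all-positive cells
random_tables <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(a = as.numeric(sample(1:200, n, TRUE)),
             b = as.numeric(sample(1:2000, n, TRUE)),
             c = as.numeric(sample(1:2000, n, TRUE)),
             d = as.numeric(sample(1:50000, n, TRUE)))
}

# hand-built corpus: 6 deduplicated reports, all with the target as PS
subgroup_corpus_dir <- function() {
  dir <- tempfile("sub"); dir.create(dir)
  writeLines(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$reporter_country",
    "1$C1$20200101$$10$YR$F$MD$US",
    "2$C2$20200101$$45$YR$M$MD$US",
    "3$C3$20200101$$70$YR$F$MD$US",
    "4$C4$20200101$$30$YR$F$MD$US",
    "5$C5$20200101$$$$M$CN$US",
    "6$C6$20200101$$51$YR$F$$US"),
    file.path(dir, "DEMO.txt"))
  writeLines(c(
    "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai$route",
    sprintf("%d$C%d$1$PS$TARGET$TARGET$SC", 1:6, 1:6),
    "1$C1$2$C$PREDNISONE$PREDNISONE$ORAL"),
    file.path(dir, "DRUG.txt"))
  writeLines(c(
    "primaryid$caseid$pt",
    "1$C1$Septic shock", "1$C1$Pyrexia",
    "2$C2$Septic shock", "2$C2$Rash",
    "3$C3$Septic shock",
    "4$C4$Headache", "4$C4$Nausea", "4$C4$Diarrhoea", "4$C4$Cough",
    "4$C4$Malaise", "4$C4$Dizziness", "4$C4$Arthralgia", "4$C4$Pruritus",
    "5$C5$Pyrexia",
    "6$C6$Rash"),
    file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$caseid$outc_cod",
               "1$C1$DE", "2$C2$DE", "3$C3$DE", "3$C3$HO", "4$C4$DE",
               "5$C5$HO"),
    file.path(dir, "OUTC.txt"))
  writeLines("primaryid$caseid$indi_drug_seq$indi_pt",
             file.path(dir, "INDI.txt"))
  writeLines("primaryid$caseid$dsg_drug_seq$start_dt",
             file.path(dir, "THER.txt"))
  dir
}

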