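make_cohort <- function(n = 50, seed = 7, ...) {
  generate_reports(sim_config(n, n_drugs = 4, n_events = 20, seed = seed,
                              ...))
}

test_that("FAERS ASCII round trip reproduces the cohort field for field", {
  coh <- make_cohort(60)
  dir <- withr::local_tempdir()
  write_srs(coh, dir, dialect = "faers_ascii")
  srs <- read_faers_quarter(dir)
  expect_equal(nrow(srs$demo), nrow(coh$data$demo))
  for (tb in c("demo", "drug", "reac", "ther", "outc", "indi")) {
    expect_equal(srs[[tb]], coh$data[[tb]], ignore_attr = TRUE)
  }
  expect_equal(sum(attr(srs, "skipped")), 0L)
})

test_that("an empty cohort writes header-only files that read back empty", {
  dir <- withr::local_tempdir()
  write_srs(generate_reports(sim_config(0)), dir, "faers_ascii")
  lines <- readLines(file.path(dir, "DEMO.txt"))
  expect_length(lines, 1L)
  expect_match(lines, "primaryid\\$caseid")
  srs <- read_faers_quarter(dir)
  expect_equal(nrow(srs$demo), 0L)
})

test_that("every written data line has exactly the header's field count", {
  coh <- make_cohort(40, missingness = list(wt = 0.9))
  dir <- withr::local_tempdir()
  write_srs(coh, dir, "faers_ascii")
  for (f in list.files(dir, full.names = TRUE)) {
    lines <- readLines(f)
    counts <- lengths(regmatches(lines, gregexpr("$", lines,
                                                 fixed = TRUE)))
    expect_true(all(counts == counts[1]), label = basename(f))
  }
})

test_that("malformed rows are skipped and counted, not fatal", {
  coh <- make_cohort(10)
  dir <- withr::local_tempdir()
  write_srs(coh, dir, "faers_ascii")
  cat("too$few$fields\n", file = file.path(dir, "DEMO.txt"),
      append = TRUE)
  srs <- read_faers_quarter(dir)
  expect_equal(nrow(srs$demo), 10L)
  expect_equal(attr(srs, "skipped")[["demo"]], 1L)
})

test_that("missing mandatory tables and bad headers are format errors", {
  coh <- make_cohort(5)
  dir <- withr::local_tempdir()
  write_srs(coh, dir, "faers_ascii")
  file.remove(file.path(dir, "REAC.txt"))
  expect_error(read_faers_quarter(dir), "REAC")
  writeLines(c("bad$$header", "1$2$3"), file.path(dir, "REAC.txt"))
  expect_error(read_faers_quarter(dir), "header")
})

test_that("a hand-written three-case file set parses to its literals", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt$event_dt$sex$age$age_cod",
               "1001$500$20230101$20221215$F$34$YR",
               "1002$501$20230102$$M$$",
               "1003$502$20230215$20230201$$719$DY"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname",
               "1001$1$PS$CASPOFUNGIN",
               "1002$1$C$CANCIDAS 50 mg vial",
               "1003$1$PS$MICAFUNGIN"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "1001$Hepatotoxicity", "1001$RASH",
               "1002$PYREXIA", "1003$RASH"),
             file.path(dir, "REAC.txt"))
  srs <- read_faers_quarter(dir)
  expect_equal(srs$demo$primaryid, c("1001", "1002", "1003"))
  expect_equal(srs$demo$sex, c("F", "M", NA))
  expect_equal(srs$demo$age, c(34, NA, 719))
  expect_true(is.na(srs$demo$event_dt[2]))
  clean <- as_clean_reports(srs)
  # reaction PTs uppercase-normalized, age units converted to years
  expect_setequal(clean$reactions$pt[clean$reactions$report_id == "1001"],
                  c("HEPATOTOXICITY", "RASH"))
  expect_equal(clean$reports$age_years[3], 719 / 365.25)
})

test_that("generic CSV dialect round-trips and joins on the key", {
  coh <- make_cohort(25, seed = 13)
  dir <- withr::local_tempdir()
  write_srs(coh, dir, "generic_csv", key_column = "Report_ID")
  srs <- read_generic_csv(dir, key_column = "Report_ID")
  expect_equal(srs$demo, coh$data$demo, ignore_attr = TRUE)
  expect_equal(srs$reac, coh$data$reac, ignore_attr = TRUE)
  expect_error(read_generic_csv(dir, key_column = "nope"), "key column")
})

test_that("generic CSV drops exact-duplicate rows and assembles cases", {
  dir <- withr::local_tempdir()
  writeLines(c("report_id,caseid,sex", "r1,c1,F", "r2,c2,M", "r2,c2,M"),
             file.path(dir, "demo.csv"))
  writeLines(c("report_id,drug_seq,role_cod,drugname",
               "r1,1,suspected drug,CASPOFUNGIN",
               "r2,1,PS,CANCIDAS"),
             file.path(dir, "drug.csv"))
  writeLines(c("report_id,pt", "r1,NAUSEA", "r1,RASH", "r2,NAUSEA"),
             file.path(dir, "reac.csv"))
  srs <- read_generic_csv(dir)
  expect_equal(nrow(srs$demo), 2L)
  expect_equal(sum(srs$reac$primaryid == "r1"), 2L)
  # generic role spelling normalizes to PS
  clean <- as_clean_reports(srs)
  expect_equal(clean$drugs$role, c("PS", "PS"))
})

test_that("deduplication keeps the latest receipt date, larger id on ties,
           and is idempotent", {
  demo <- data.frame(
    primaryid = c("11", "12", "2001", "2009", "31"),
    caseid = c("100", "100", "200", "200", "300"),
    fda_dt = c("20230101", "20230201", "20230501", "20230501",
               "20230301"))
  srs <- srs_data(demo, data.frame(primaryid = demo$primaryid,
                                   drug_seq = 1, role_cod = "PS",
                                   drugname = "X"),
                  data.frame(primaryid = demo$primaryid, pt = "P"))
  dd <- deduplicate(srs)
  expect_setequal(dd$demo$primaryid, c("12", "2009", "31"))
  expect_equal(attr(dd, "n_removed"), 2L)
  dd2 <- deduplicate(dd)
  expect_equal(dd2$demo, dd$demo, ignore_attr = TRUE)
  expect_equal(attr(dd2, "n_removed"), 0L)
  # child tables are subset to the surviving versions
  expect_setequal(dd$drug$primaryid, dd$demo$primaryid)
})

test_that("drug-name matching is case-insensitive substring on names", {
  names <- c("CASPOFUNGIN", "CANCIDAS")
  expect_true(match_drug_names("Cancidas 50 mg vial", names))
  expect_true(match_drug_names("CASPOFUNGIN ACETATE", names))
  expect_false(match_drug_names("MICAFUNGIN", names))
  expect_equal(match_drug_names(c("caspofungin msd", NA), names),
               c(TRUE, FALSE))
  expect_error(match_drug_names("X", character(0)), "nonempty")
})

test_that("primary-suspect filtering honours the role code", {
  clean <- toy_clean()
  # report 2 has CANCIDAS with role PS -> included; change to C -> out
  ps <- filter_primary_suspect(clean, c("CASPOFUNGIN", "CANCIDAS"))
  expect_setequal(ps$reports$report_id, c("1", "2", "3"))
  clean$drugs$role[clean$drugs$report_id == "2"] <- "C"
  ps2 <- filter_primary_suspect(clean, c("CASPOFUNGIN", "CANCIDAS"))
  expect_setequal(ps2$reports$report_id, c("1", "3"))
  # the filtered ids are a subset of the input ids
  expect_true(all(ps$reports$report_id %in% clean$reports$report_id))
})

test_that("primary-suspect count on a synthetic cohort matches truth", {
  coh <- make_cohort(500, seed = 17)
  clean <- filter_primary_suspect(as_clean_reports(coh$data), "DRUG_002")
  expect_equal(nrow(clean$reports), sum(coh$truth$drug_of_report == 2))
})

test_that("PT to SOC mapping annotates, counts unmapped, is many-to-one", {
  clean <- toy_clean()
  tm <- data.frame(pt = c("EVENT X", "EVENT Y"),
                   soc = c("Hepatobiliary disorders",
                           "Hepatobiliary disorders"))
  ann <- map_pt_to_soc(clean, tm)
  expect_equal(ann$reactions$soc[ann$reactions$pt == "EVENT X"][1],
               "Hepatobiliary disorders")
  expect_equal(sum(ann$reactions$soc == "UNMAPPED"), 1L)  # EVENT Z
  expect_equal(attr(ann, "n_unmapped"), 1L)
  expect_error(map_pt_to_soc(clean, tm[0, ]), "empty")
  expect_error(map_pt_to_soc(clean, data.frame(
    pt = c("EVENT X", "EVENT X"), soc = c("A", "B"))), "many-to-one")
})

test_that("a report with three PTs in two SOCs yields a SOC multiset of
           size three with two distinct values", {
  demo <- data.frame(primaryid = "1", caseid = "1", fda_dt = "20230101")
  drug <- data.frame(primaryid = "1", drug_seq = 1, role_cod = "PS",
                     drugname = "CASPOFUNGIN")
  reac <- data.frame(primaryid = "1", pt = c("A", "B", "C"))
  clean <- as_clean_reports(srs_data(demo, drug, reac))
  ann <- map_pt_to_soc(clean, data.frame(pt = c("A", "B", "C"),
                                         soc = c("S1", "S1", "S2")))
  expect_length(ann$reactions$soc, 3L)
  expect_length(unique(ann$reactions$soc), 2L)
})

test_that("demographic percentages reproduce printed-table arithmetic", {
  n <- 2270
  demo <- data.frame(
    primaryid = as.character(seq_len(n)), caseid = as.character(seq_len(n)),
    fda_dt = "20230101",
    sex = rep(c("F", "M", NA), times = c(802, 1192, 276)))
  drug <- data.frame(primaryid = demo$primaryid, drug_seq = 1,
                     role_cod = "PS", drugname = "CASPOFUNGIN")
  reac <- data.frame(primaryid = demo$primaryid, pt = "EVENT")
  outc <- data.frame(
    primaryid = demo$primaryid[seq_len(n - 281)],
    outc_cod = rep(c("HO", "LT", "DS", "RI", "DE", "OT"),
                   times = c(489, 130, 18, 6, 919, 427)))
  clean <- as_clean_reports(srs_data(demo, drug, reac, outc = outc))
  tab <- summarize_demographics(clean)
  pct <- function(ch, cat) round(tab$pct[tab$characteristic == ch &
                                         tab$category == cat], 1)
  expect_equal(pct("sex", "male"), 52.5)
  expect_equal(pct("sex", "female"), 35.3)
  expect_equal(pct("sex", "unknown"), 12.2)
  expect_equal(pct("outcome", "DE"), 40.5)
  expect_equal(pct("outcome", "HO"), 21.5)
  expect_equal(pct("outcome", "unknown"), 12.4)
})

test_that("multi-valued outcome tallies use the tally total as denominator", {
  # 161 reports carrying 384 outcome rows in total: percentages are of 384
  n <- 161
  demo <- data.frame(primaryid = as.character(seq_len(n)),
                     caseid = as.character(seq_len(n)),
                     fda_dt = "20230101")
  drug <- data.frame(primaryid = demo$primaryid, drug_seq = 1,
                     role_cod = "PS", drugname = "CASPOFUNGIN")
  reac <- data.frame(primaryid = demo$primaryid, pt = "EVENT")
  codes <- rep(c("RECOVERY", "REHAB", "MINOR REHAB", "DEATH",
                 "NON-REHAB", "MISSING"),
               times = c(1, 77, 47, 109, 38, 112))
  outc <- data.frame(primaryid = rep(demo$primaryid,
                                     length.out = length(codes)),
                     outc_cod = codes)
  clean <- as_clean_reports(srs_data(demo, drug, reac, outc = outc))
  tab <- summarize_demographics(clean)
  death <- tab[tab$characteristic == "outcome" & tab$category == "DEATH", ]
  expect_equal(death$n, 109)
  expect_equal(round(death$pct, 1), 28.4)
})

test_that("an all-unknown input concentrates every percentage in the
           unknown rows", {
  demo <- data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                     fda_dt = "20230101")
  drug <- data.frame(primaryid = c("1", "2"), drug_seq = 1,
                     role_cod = "PS", drugname = "X")
  reac <- data.frame(primaryid = c("1", "2"), pt = "P")
  tab <- summarize_demographics(as_clean_reports(srs_data(demo, drug,
                                                          reac)))
  for (ch in c("sex", "age_years", "weight_kg", "outcome")) {
    sub <- tab[tab$characteristic == ch, ]
    expect_equal(sub$pct[sub$category == "unknown"], 100)
    expect_true(all(sub$pct[sub$category != "unknown"] == 0))
  }
})
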