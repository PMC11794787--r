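test_that("reading a table parses header-led dollar-delimited lines", {
  tf <- withr::local_tempfile()
  writeLines(c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occr_country$occp_cod",
               "100000011$10000001$20230105$20230101$12$YR$M$US$MD"), tf)
  tb <- read_faers_table(tf, "DEMO")
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$primaryid, "100000011")
  expect_equal(tb$age, "12")
  expect_equal(attr(tb, "skipped"), 0L)
})

test_that("malformed data lines are skipped and counted, never fatal", {
  tf <- withr::local_tempfile()
  writeLines(c("primaryid$caseid$pt", "1$2"), tf)
  expect_warning(tb <- read_faers_table(tf, "REAC"), "skipped 1")
  expect_equal(nrow(tb), 0L)
  expect_equal(attr(tb, "skipped"), 1L)
})

test_that("extra columns are ignored by name, trailing empties preserved", {
  tf <- withr::local_tempfile()
  writeLines(c("primaryid$caseid$pt$extra_col", "9$8$Pyrexia$junk",
               "7$6$$"), tf)
  tb <- read_faers_table(tf, "REAC")
  expect_equal(names(tb), faers_schema$REAC)
  expect_equal(tb$pt, c("Pyrexia", ""))
})

test_that("unknown table names and empty streams error", {
  tf <- withr::local_tempfile()
  writeLines("x$y", tf)
  expect_error(read_faers_table(tf, "INDI"), "unknown table")
  tf2 <- withr::local_tempfile()
  file.create(tf2)
  expect_error(read_faers_table(tf2, "DEMO"), "empty stream")
})

test_that("write-then-read round trips a generated quarter unchanged", {
  g <- generate_reports(generator_config(seed = 7, n_reports = 500))
  dir <- withr::local_tempdir()
  write_quarter(g$bundle, dir, "23Q1")
  back <- read_quarter(dir, "23Q1")
  for (tb in c("demo", "drug", "reac", "outc", "ther")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(g$bundle[[tb]]),
                 ignore_attr = TRUE, info = tb)
  }
  expect_equal(back$deleted_caseids, g$bundle$deleted_caseids)
})

test_that("deletion lists have set semantics and tolerate junk", {
  tf <- withr::local_tempfile()
  writeLines(c("101", "102", "101", "", "abc"), tf)
  expect_warning(ids <- read_deletion_list(tf), "non-numeric")
  expect_equal(ids, c(101, 102))
  tf2 <- withr::local_tempfile()
  file.create(tf2)
  expect_length(read_deletion_list(tf2), 0L)
})

test_that("assemble_quarter drops orphan child rows and keeps consistent ones", {
  demo <- tibble::tibble(primaryid = "1", caseid = "10", fda_dt = "20230101",
                         event_dt = "", age = "", age_cod = "", sex = "",
                         occr_country = "", occp_cod = "")
  drug <- tibble::tibble(primaryid = c("1", "2"), caseid = c("10", "20"),
                         drug_seq = "1", role_cod = "PS",
                         drugname = "X", prod_ai = "X")
  empty_reac <- tibble::tibble(primaryid = character(), caseid = character(),
                               pt = character())
  empty_outc <- tibble::tibble(primaryid = character(), caseid = character(),
                               outc_cod = character())
  empty_ther <- tibble::tibble(primaryid = character(), caseid = character(),
                               dsg_drug_seq = character(),
                               start_dt = character())
  suppressMessages(b <- assemble_quarter(demo, drug, empty_reac, empty_outc,
                                         empty_ther))
  expect_equal(nrow(b$drug), 1L)
  expect_equal(unname(b$dropped[["drug"]]), 1L)

  # generator output is referentially consistent: zero drops
  g <- generate_reports(generator_config(seed = 3, n_reports = 300))
  expect_true(all(g$bundle$dropped == 0L))
})

test_that("shipped mapping tables load through the TSV readers", {
  pt <- read_pt_map(system.file("extdata", "pt_soc_map.tsv",
                                package = "faersignal"))
  expect_true(all(c("pt", "soc") %in% names(pt)))
  expect_true("Hypotension" %in% pt$pt)
  atc <- read_atc_map(system.file("extdata", "atc_level1_map.tsv",
                                  package = "faersignal"))
  expect_true(all(grepl("^[A-V]$", atc$atc1)))
  # duplicated PTs collapse (case-insensitive) with a warning
  tf <- withr::local_tempfile()
  writeLines(c("pt\tsoc", "X\tCardiac disorders", "x\tVascular disorders"), tf)
  expect_warning(m <- read_pt_map(tf), "duplicated")
  expect_equal(nrow(m), 1L)
})
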