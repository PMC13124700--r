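write_quarter <- function(dir, demo, drug = NULL, reac = NULL, ther = NULL) {
  tabs <- make_tables(demo, drug, reac, ther)
  write_faers_tables(tabs, dir)
}

test_that("a complete row round-trips through the quarterly dialect", {
  dir <- withr::local_tempdir()
  p <- write_quarter(dir, make_demo("100", "A", sex = "F", age = "81"),
                     drug = tibble::tibble(primaryid = "100", drug_seq = "1",
                                           role_cod = "PS",
                                           drugname = "OFLOXACIN"),
                     reac = tibble::tibble(primaryid = "100",
                                           pt = "Pemphigoid"),
                     ther = tibble::tibble(primaryid = "100",
                                           dsg_drug_seq = "1",
                                           start_dt = "20200101"))
  tabs <- read_faers_tables(p["demo"], p["drug"], p["reac"], p["ther"])
  expect_identical(nrow(tabs$demo), 1L)
  expect_identical(tabs$demo$sex, "F")
  expect_equal(tabs$demo$age_years, 81)
  expect_identical(tabs$drug$role_cod, "PS")
  expect_identical(tabs$reac$pt, "Pemphigoid")
})

test_that("missing code fields normalize to NS", {
  dir <- withr::local_tempdir()
  p <- write_quarter(dir, make_demo("1", sex = "", occp_cod = "",
                                    outc_cod = "XX"))
  tabs <- read_faers_tables(p["demo"], p["drug"], p["reac"], p["ther"])
  expect_identical(tabs$demo$sex, "NS")
  expect_identical(tabs$demo$occp_cod, "NS")
  expect_identical(tabs$demo$outc_cod, "NS")
})

test_that("partial dates are missing for arithmetic but keep the year", {
  dir <- withr::local_tempdir()
  p <- write_quarter(dir, make_demo(c("1", "2", "3"),
                                    fda_dt = c("2023", "202304",
                                               "20230405")))
  tabs <- read_faers_tables(p["demo"], p["drug"], p["reac"], p["ther"])
  expect_identical(is.na(tabs$demo$fda_date), c(TRUE, TRUE, FALSE))
  expect_identical(tabs$demo$report_year, c(2023L, 2023L, 2023L))
  expect_identical(unname(tabs$log$partial_dates["fda_dt"]), 2L)
})

test_that("age and weight units normalize to years and kilograms", {
  demo <- make_demo(as.character(1:4),
                    age = c("7", "780", "14610", "65"),
                    age_cod = c("DEC", "MON", "DY", "YR"),
                    wt = c("154.3", "70", "", ""),
                    wt_cod = c("LBS", "KG", "", ""))
  nd <- normalize_demo(demo)
  expect_equal(nd$age_years, c(70, 65, 40, 65))
  expect_equal(nd$weight_kg[1], 154.3 * 0.45359237)
  expect_equal(nd$weight_kg[2], 70)
  expect_true(all(is.na(nd$weight_kg[3:4])))
})

test_that("a missing mandatory column names the file and column", {
  dir <- withr::local_tempdir()
  bad <- tibble::tibble(primaryid = "1", caseid = "A") # no fda_dt
  utils::write.table(bad, file.path(dir, "DEMO.txt"), sep = "$",
                     quote = FALSE, row.names = FALSE)
  tabs <- make_tables(make_demo("1"))
  p <- write_faers_tables(tabs, dir2 <- withr::local_tempdir())
  expect_error(
    read_faers_tables(file.path(dir, "DEMO.txt"), p["drug"], p["reac"],
                      p["ther"]),
    "DEMO.txt.*fda_dt"
  )
})

test_that("the retention rule keeps the largest primaryid per case", {
  demo <- make_demo(c("100", "101"), caseid = c("A", "A"))
  expect_identical(deduplicate_reports(demo)$primaryid, "101")

  demo <- make_demo(c("1", "2", "3", "4"), caseid = c("A", "B", "A", "C"))
  out <- deduplicate_reports(demo)
  expect_identical(out$primaryid, c("3", "2", "4"))
  expect_identical(out$caseid, c("A", "B", "C"))

  single <- make_demo("7", "Z")
  expect_identical(deduplicate_reports(single), single)
})

test_that("deduplication is idempotent, order-invariant and counts cases", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    demo <- make_demo(sample(as.character(1000 + 1:n)),
                      caseid = as.character(sample.int(max(2, n %/% 2), n,
                                                       replace = TRUE)))
    out <- deduplicate_reports(demo)
    expect_identical(deduplicate_reports(out), out)
    expect_identical(nrow(out), length(unique(demo$caseid)))
    perm <- demo[sample.int(n), , drop = FALSE]
    expect_identical(deduplicate_reports(perm), out)
  }
})

test_that("duplicate primaryid values raise an integrity error", {
  demo <- make_demo(c("5", "5"), caseid = c("A", "B"))
  expect_error(deduplicate_reports(demo), "integrity")
})
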