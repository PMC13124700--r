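dict <- read_drug_dictionary()

test_that("drug-name standardization maps synonyms and flags the unmapped", {
  expect_identical(standardize_drug("Cipro XR", dict), "CIPROFLOXACIN")
  expect_identical(standardize_drug("OFLOXACIN", dict), "OFLOXACIN")
  expect_identical(standardize_drug("  ofloxacin  ", dict), "OFLOXACIN")
  expect_true(is.na(standardize_drug("tobramycin", dict)))
})

test_that("synonyms may not map to several canonical names", {
  expect_error(
    drug_dictionary(c("A", "B"), list("X", "X"), c("20000101", "20000101")),
    "several canonical"
  )
})

cohort_tables <- function() {
  demo <- normalize_demo(make_demo(
    as.character(1:4), caseid = as.character(1:4),
    fda_dt = c("20200110", "20200110", "19890110", "20200110")))
  drug <- tibble::tibble(
    primaryid = c("1", "2", "3", "4"),
    drug_seq = "1",
    role_cod = c("PS", "C", "PS", "PS"),
    drugname = c("OFLOXACIN", "OFLOXACIN", "OFLOXACIN", "Floxin")
  )
  reac <- tibble::tibble(primaryid = c("1", "2", "3", "4"),
                         pt = c("Pemphigoid", "Pemphigoid", "PEMPHIGOID",
                                "Nausea"))
  make_tables(demo, drug, reac)
}

test_that("cohort membership needs PS role inside the approval window", {
  co <- build_cohort(cohort_tables(), dict)
  # report 1: PS + in window -> included with event
  # report 2: concomitant role -> excluded
  # report 3: receipt before ofloxacin approval -> excluded
  # report 4: synonym Floxin, PS, no target event -> included, event FALSE
  expect_setequal(co$primaryid, c("1", "4"))
  expect_identical(co$event[co$primaryid == "1"], TRUE)
  expect_identical(co$event[co$primaryid == "4"], FALSE)
  expect_identical(unique(co$drug), "OFLOXACIN")
})

test_that("event matching is case-insensitive and configurable", {
  tabs <- cohort_tables()
  co <- build_cohort(tabs, dict, event_terms("PEMPHIGOID"))
  expect_identical(co$event[co$primaryid == "1"], TRUE)
  co2 <- build_cohort(tabs, dict, event_terms("Nausea"))
  expect_identical(co2$event[co2$primaryid == "4"], TRUE)
  expect_error(event_terms(character(0)), "empty")
})

test_that("an empty dictionary is a configuration error", {
  d0 <- drug_dictionary("X", list(character(0)), "20000101", include = FALSE)
  expect_error(build_cohort(cohort_tables(), d0), "configuration")
})

test_that("contingency cells follow the fourfold partition and conserve", {
  # universe of 10: 2 drug-and-event, 3 drug-only, 1 event-only, 4 neither
  demo <- normalize_demo(make_demo(as.character(1:10),
                                   caseid = as.character(1:10)))
  drug <- tibble::tibble(primaryid = as.character(1:5), drug_seq = "1",
                         role_cod = "PS", drugname = "OFLOXACIN")
  reac <- tibble::tibble(primaryid = c("1", "2", "6"), pt = "Pemphigoid")
  tabs <- make_tables(demo, drug, reac)
  ct <- contingency_tables(tabs, dict, drugs = "OFLOXACIN")
  expect_identical(c(ct$a, ct$b, ct$c, ct$d), c(2L, 3L, 1L, 4L))
  expect_identical(ct$a + ct$b + ct$c + ct$d, ct$n_universe)
})

test_that("degenerate universes give zero cells, not errors", {
  demo <- normalize_demo(make_demo(as.character(1:3),
                                   caseid = as.character(1:3)))
  tabs <- make_tables(demo)  # no drug rows at all
  ct <- contingency_tables(tabs, dict, drugs = "OFLOXACIN")
  expect_identical(c(ct$a, ct$b), c(0L, 0L))
  # all exposed and evented
  drug <- tibble::tibble(primaryid = as.character(1:3), drug_seq = "1",
                         role_cod = "PS", drugname = "OFLOXACIN")
  reac <- tibble::tibble(primaryid = as.character(1:3), pt = "Pemphigoid")
  ct2 <- contingency_tables(make_tables(demo, drug, reac), dict,
                            drugs = "OFLOXACIN")
  expect_identical(c(ct2$a, ct2$b, ct2$c, ct2$d), c(3L, 0L, 0L, 0L))
})

test_that("explicit-count construction rejects impossible cells", {
  ct <- contingency_from_counts(10, 2, 3, 1)
  expect_identical(c(ct$a, ct$b, ct$c, ct$d), c(2, 3, 1, 4))
  expect_error(contingency_from_counts(4, 2, 3, 1), "integrity")
})

test_that("a report never double-counts inside one drug's table", {
  demo <- normalize_demo(make_demo(c("1", "2"), caseid = c("1", "2")))
  # report 1 lists ofloxacin twice (brand + generic), still one exposed report
  drug <- tibble::tibble(primaryid = c("1", "1", "2"),
                         drug_seq = c("1", "2", "1"),
                         role_cod = "PS",
                         drugname = c("OFLOXACIN", "Floxin", "METFORMIN"))
  tabs <- make_tables(demo, drug)
  ct <- contingency_tables(tabs, dict, drugs = "OFLOXACIN")
  expect_identical(ct$b, 1L)
  expect_identical(ct$n_universe, 2L)
  co <- build_cohort(tabs, dict)
  expect_identical(nrow(co[co$drug == "OFLOXACIN", ]), 1L)
})

test_that("cohort order does not depend on input row order", {
  tabs <- cohort_tables()
  perm <- tabs
  perm$demo <- perm$demo[c(3, 1, 4, 2), ]
  perm$drug <- perm$drug[c(4, 2, 1, 3), ]
  co1 <- build_cohort(tabs, dict)
  co2 <- build_cohort(perm, dict)
  expect_setequal(co1$primaryid, co2$primaryid)
  ct1 <- contingency_tables(tabs, dict)
  ct2 <- contingency_tables(perm, dict)
  expect_identical(ct1, ct2)
})
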