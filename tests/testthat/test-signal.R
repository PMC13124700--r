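test_that("worked 2x2 examples match hand evaluation of the formulas", {
  r <- ror(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_equal(r$ror_lo, exp(-1.96 * sqrt(0.8)), tolerance = 1e-12)
  expect_equal(round(r$ror_lo, 4), 0.1732)
  expect_equal(round(r$ror_hi, 4), 5.7723)

  r <- ror(3, 97, 100, 9900)
  expect_equal(r$ror, (3 / 97) / (100 / 9900), tolerance = 1e-12)
  expect_equal(round(r$ror, 4), 3.0619)
  expect_equal(round(r$ror_lo, 3), 0.954)
  expect_equal(round(r$ror_hi, 3), 9.823)

  p <- prr(3, 97, 100, 9900)
  expect_equal(p$prr, 3)
  expect_equal(round(p$chi2, 3), 2.192)
  expect_equal(prr(5, 5, 5, 5)$chi2, 0.2)              # Yates at equality
  expect_equal(prr(5, 5, 5, 5, chi2 = "pearson")$chi2, 0)

  b <- bcpnn(1, 9, 9, 81)
  expect_equal(b$ic, 0)                                 # independence
  expect_equal(bcpnn(4, 6, 16, 74)$ic, 1)               # aN = 2 * margins
  expect_equal(bcpnn(3, 97, 100, 9900)$ic, log2(30300 / 10300),
               tolerance = 1e-12)
  expect_equal(round(bcpnn(3, 97, 100, 9900)$ic, 4), 1.5567)
})

test_that("zero cells are flagged undefined, not errors, unless corrected", {
  r <- ror(3, 0, 10, 100)
  expect_false(r$ror_defined)
  expect_true(is.na(r$ror))
  expect_true(ror(3, 0, 10, 100, correction = "haldane")$ror_defined)
  p <- prr(0, 10, 10, 100)
  expect_equal(p$prr, 0)
  expect_false(p$prr_defined)
  b <- bcpnn(0, 10, 10, 100)
  expect_true(is.na(b$ic))
  expect_false(is.na(b$ic025))   # posterior bound exists from the priors
})

test_that("signal criteria apply the published thresholds strictly", {
  # fewer than 3 cases never signals ROR/PRR however large the estimate
  s <- signal_stats(data.frame(a = 2, b = 1, c = 5, d = 5000))
  expect_false(s$ror_signal)
  expect_false(s$prr_signal)
  # the worked example: a >= 3 but lower bound < 1 and chi2 < 4
  s <- signal_stats(data.frame(a = 3, b = 97, c = 100, d = 9900))
  expect_false(s$ror_signal)
  expect_false(s$prr_signal)
  # boundary: ic025 exactly 0 is not a signal
  fake <- tibble::tibble(a = 10, ror_lo = 2, prr = 3, chi2 = 10, ic025 = 0)
  expect_false(evaluate_signals(fake)$bcpnn_signal)
  expect_true(evaluate_signals(fake)$ror_signal)
})

test_that("algebraic identities hold across random positive tables", {
  tabs <- random_tables(1000, seed = 1)
  s <- signal_stats(tabs)
  # ROR = ad/(bc) exactly
  expect_equal(s$ror, with(tabs, a * d / (b * c)), tolerance = 1e-12)
  # ROR >= PRR iff ROR >= 1
  expect_true(all((s$ror >= s$prr - 1e-12) == (s$ror >= 1 - 1e-12)))
  # sign(IC) = sign(ln ROR)
  expect_true(all(sign(s$ic) == sign(log(s$ror)) |
                    abs(s$ic) < 1e-12))
  # point estimates inside their intervals
  expect_true(all(s$ror_lo <= s$ror & s$ror <= s$ror_hi))
  expect_true(all(s$prr_lo <= s$prr & s$prr <= s$prr_hi))
  expect_true(all(s$ic025 <= s$ic_e))
})

test_that("chi-squared agrees with the stats::chisq.test oracle", {
  tabs <- random_tables(400, seed = 2)
  s_p <- prr(tabs$a, tabs$b, tabs$c, tabs$d, chi2 = "pearson")
  s_y <- prr(tabs$a, tabs$b, tabs$c, tabs$d, chi2 = "yates")
  n <- tabs$a + tabs$b + tabs$c + tabs$d
  overshoot <- abs(tabs$a * tabs$d - tabs$b * tabs$c) < n / 2
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(as.numeric(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])),
                2, byrow = TRUE)
    expect_equal(s_p$chi2[i],
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-9)
    if (!overshoot[i]) {
      # where the continuity correction does not cross zero the closed form
      # and the oracle coincide
      expect_equal(s_y$chi2[i],
                   unname(suppressWarnings(
                     stats::chisq.test(m, correct = TRUE))$statistic),
                   tolerance = 1e-9)
    }
  }
})

test_that("scaling all cells tightens intervals and ic025 approaches ic", {
  base <- c(a = 6, b = 194, c = 150, d = 9650)
  prev_width <- Inf
  prev_gap <- Inf
  for (k in c(1, 10, 100, 1000, 10000)) {
    s <- signal_stats(data.frame(a = base["a"] * k, b = base["b"] * k,
                                 c = base["c"] * k, d = base["d"] * k))
    width <- log(s$ror_hi) - log(s$ror_lo)
    gap <- abs(s$ic - s$ic025)
    expect_lt(width, prev_width)
    expect_lte(gap, prev_gap)
    prev_width <- width; prev_gap <- gap
  }
  # at k = 1e4 the residual spread reflects a ~ 6e4 counts: O(1/sqrt(a))
  expect_lt(prev_gap, 0.05)
  expect_lt(prev_width, 0.05)
})

test_that("stratified analysis keeps strata disjoint and non-evaluable flags", {
  demo <- normalize_demo(make_demo(as.character(1:8),
                                   caseid = as.character(1:8),
                                   sex = rep(c("F", "M"), each = 4)))
  drug <- tibble::tibble(primaryid = as.character(c(1, 2, 5, 6)),
                         drug_seq = "1", role_cod = "PS",
                         drugname = "OFLOXACIN")
  reac <- tibble::tibble(primaryid = c("1", "5"), pt = "Pemphigoid")
  tabs <- make_tables(demo, drug, reac)
  st <- stratified_signals(tabs, read_drug_dictionary(), by = "sex")
  oflox <- st[st$drug == "OFLOXACIN", ]
  expect_setequal(oflox$stratum, c("F", "M"))
  expect_identical(sum(oflox$n_universe), 8L)
  expect_true(all(!oflox$evaluable))  # a = 1 < 3 in both strata
  expect_error(stratified_signals(tabs, read_drug_dictionary(),
                                  by = "nonsense"))
})
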