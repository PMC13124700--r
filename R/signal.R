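Z975 <- 1.96  # the interval formulas use the printed 1.96, not qnorm(0.975)

# coerce to double (margin products overflow 32-bit integers) and apply the
# optional Haldane-Anscombe zero-cell correction
apply_correction <- function(a, b, c, d, correction) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (correction == "haldane") {
    list(a = a + 0.5, b = b + 0.5, c = c + 0.5, d = d + 0.5)
  } else {
    list(a = a, b = b, c = c, d = d)
  }
}

#' Reporting odds ratio with Wald 95% CI
#'
#' `ROR = (a/b)/(c/d)` with
#' `95% CI = exp(ln(ROR) +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' With `correction = "none"` (default) a zero in any cell makes the
#' statistic undefined (flagged, never an exception); `"haldane"` adds 0.5
#' to every cell first.
#'
#' @param a,b,c,d contingency cells (vectors recycle).
#' @param correction `"none"` or `"haldane"`.
#' @return tibble with `ror`, `ror_lo`, `ror_hi`, `ror_defined`.
#' @export
#' @examples
#' ror(5, 5, 5, 5) # estimate 1, CI (0.173, 5.77)
ror <- function(a, b, c, d, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  k <- apply_correction(a, b, c, d, correction)
  defined <- k$a > 0 & k$b > 0 & k$c > 0 & k$d > 0
  est <- lo <- hi <- rep(NA_real_, length(defined))
  i <- which(defined)
  est[i] <- (k$a[i] / k$b[i]) / (k$c[i] / k$d[i])
  se <- sqrt(1 / k$a[i] + 1 / k$b[i] + 1 / k$c[i] + 1 / k$d[i])
  lo[i] <- exp(log(est[i]) - Z975 * se)
  hi[i] <- exp(log(est[i]) + Z975 * se)
  tibble::tibble(ror = est, ror_lo = lo, ror_hi = hi, ror_defined = defined)
}

#' Proportional reporting ratio with 95% CI and chi-squared
#'
#' `PRR = (a/(a+b))/(c/(c+d))`. The default confidence interval follows the
#' companion formula `exp(ln(PRR) +- 1.96 * sqrt(1/a + 1/(a+b) + 1/c +
#' 1/(c+d)))`; `ci = "conventional"` uses the variance
#' `1/a - 1/(a+b) + 1/c - 1/(c+d)` common elsewhere in the
#' disproportionality literature (see the methods vignette). The chi-squared
#' statistic is the 2x2 Pearson statistic, Yates-continuity-corrected by
#' default via the closed form `N(|ad-bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @inheritParams ror
#' @param ci `"printed"` (default) or `"conventional"` interval variance.
#' @param chi2 `"yates"` (default) or `"pearson"`.
#' @return tibble with `prr`, `prr_lo`, `prr_hi`, `prr_defined`, `chi2`,
#'   `chi2_defined`.
#' @export
prr <- function(a, b, c, d, correction = c("none", "haldane"),
                ci = c("printed", "conventional"),
                chi2 = c("yates", "pearson")) {
  correction <- match.arg(correction)
  ci <- match.arg(ci)
  chi2 <- match.arg(chi2)
  k <- apply_correction(a, b, c, d, correction)
  n <- k$a + k$b + k$c + k$d
  est <- lo <- hi <- rep(NA_real_, length(n))
  ok_point <- (k$a + k$b) > 0 & (k$c + k$d) > 0 & k$c > 0
  i <- which(ok_point)
  est[i] <- (k$a[i] / (k$a[i] + k$b[i])) / (k$c[i] / (k$c[i] + k$d[i]))
  ok_ci <- ok_point & k$a > 0
  i <- which(ok_ci)
  v <- if (ci == "printed") {
    1 / k$a[i] + 1 / (k$a[i] + k$b[i]) + 1 / k$c[i] + 1 / (k$c[i] + k$d[i])
  } else {
    1 / k$a[i] - 1 / (k$a[i] + k$b[i]) + 1 / k$c[i] - 1 / (k$c[i] + k$d[i])
  }
  lo[i] <- exp(log(est[i]) - Z975 * sqrt(v))
  hi[i] <- exp(log(est[i]) + Z975 * sqrt(v))

  m1 <- k$a + k$b; m0 <- k$c + k$d; e1 <- k$a + k$c; e0 <- k$b + k$d
  chi_ok <- m1 > 0 & m0 > 0 & e1 > 0 & e0 > 0
  stat <- rep(NA_real_, length(n))
  j <- which(chi_ok)
  dev <- k$a[j] * k$d[j] - k$b[j] * k$c[j]
  if (chi2 == "yates") {
    stat[j] <- n[j] * (abs(dev) - n[j] / 2)^2 /
      (m1[j] * m0[j] * e1[j] * e0[j])
  } else {
    stat[j] <- n[j] * dev^2 / (m1[j] * m0[j] * e1[j] * e0[j])
  }
  tibble::tibble(prr = est, prr_lo = lo, prr_hi = hi,
                 prr_defined = ok_ci, chi2 = stat, chi2_defined = chi_ok)
}

#' BCPNN information component with closed-form 95% lower bound
#'
#' The point information component is
#' `IC = log2( a * N / ((a+b) * (a+c)) )`, the observed-vs-expected
#' dependency of the drug-event pair in bits. The posterior expectation and
#' variance use the classical closed-form Bayesian approximation with
#' standard priors (`alpha1 = beta1 = 1`, `alpha = beta = 2`,
#' `gamma11 = 1`, `gamma = gamma11 * (N+alpha)(N+beta) /
#' ((a+b+alpha1)(a+c+beta1))`), and `IC025 = E(IC) - 2 * sqrt(V(IC))`.
#'
#' @inheritParams ror
#' @return tibble with `ic` (point form, `NA` when `a = 0`), `ic_e`, `ic_v`,
#'   `ic025`, `ic_defined`.
#' @export
bcpnn <- function(a, b, c, d, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  k <- apply_correction(a, b, c, d, correction)
  n <- k$a + k$b + k$c + k$d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  m1 <- k$a + k$b; e1 <- k$a + k$c
  ok <- m1 > 0 & e1 > 0 & n > 0
  ic <- ic_e <- ic_v <- ic025 <- rep(NA_real_, length(n))
  i <- which(ok & k$a > 0)
  ic[i] <- log2(k$a[i] * n[i] / (m1[i] * e1[i]))
  j <- which(ok)
  g <- g11 * (n[j] + al) * (n[j] + be) / ((m1[j] + a1) * (e1[j] + b1))
  ic_e[j] <- log2((k$a[j] + g11) * (n[j] + al) * (n[j] + be) /
                    ((n[j] + g) * (m1[j] + a1) * (e1[j] + b1)))
  ic_v[j] <- (1 / log(2)^2) * (
    (n[j] - k$a[j] + g - g11) / ((k$a[j] + g11) * (1 + n[j] + g)) +
    (n[j] - m1[j] + al - a1) / ((m1[j] + a1) * (1 + n[j] + al)) +
    (n[j] - e1[j] + be - b1) / ((e1[j] + b1) * (1 + n[j] + be))
  )
  ic025[j] <- ic_e[j] - 2 * sqrt(ic_v[j])
  tibble::tibble(ic = ic, ic_e = ic_e, ic_v = ic_v, ic025 = ic025,
                 ic_defined = ok)
}

#' Apply the three signal criteria
#'
#' A drug-event pair is an ROR signal when `a >= 3` and the ROR 95% lower
#' bound exceeds 1; a PRR signal when `a >= 3`, `PRR >= 2` and
#' `chi-squared >= 4`; a BCPNN signal when `IC025 > 0` (strict). `any_signal`
#' is the disjunction.
#'
#' @param stats tibble holding `a`, `ror_lo`, `prr`, `chi2`, `ic025` (as from
#'   \code{\link{signal_stats}}).
#' @return the input with logical columns `ror_signal`, `prr_signal`,
#'   `bcpnn_signal`, `any_signal` appended.
#' @export
evaluate_signals <- function(stats) {
  isTRUE_v <- function(x) !is.na(x) & x
  stats$ror_signal <- stats$a >= 3 & isTRUE_v(stats$ror_lo > 1)
  stats$prr_signal <- stats$a >= 3 & isTRUE_v(stats$prr >= 2) &
    isTRUE_v(stats$chi2 >= 4)
  stats$bcpnn_signal <- isTRUE_v(stats$ic025 > 0)
  stats$any_signal <- stats$ror_signal | stats$prr_signal |
    stats$bcpnn_signal
  stats
}

#' All disproportionality statistics for a table of 2x2 counts
#'
#' @param ct data frame with columns `a`, `b`, `c`, `d` (and optionally
#'   `drug` or other id columns, which are preserved).
#' @param correction zero-cell handling, `"none"` (default) or `"haldane"`.
#' @param prr_ci PRR interval variant, see \code{\link{prr}}.
#' @param chi2 chi-squared variant, see \code{\link{prr}}.
#' @return tibble: input columns, `n`, all ROR/PRR/chi2/IC columns and the
#'   signal flags of \code{\link{evaluate_signals}}.
#' @export
#' @examples
#' signal_stats(data.frame(a = 3, b = 97, c = 100, d = 9900))
signal_stats <- function(ct, correction = c("none", "haldane"),
                         prr_ci = c("printed", "conventional"),
                         chi2 = c("yates", "pearson")) {
  correction <- match.arg(correction)
  prr_ci <- match.arg(prr_ci)
  chi2 <- match.arg(chi2)
  stopifnot(all(c("a", "b", "c", "d") %in% names(ct)))
  out <- tibble::as_tibble(ct)
  out$n <- as.numeric(out$a) + out$b + out$c + out$d
  out <- dplyr::bind_cols(
    out,
    ror(ct$a, ct$b, ct$c, ct$d, correction),
    prr(ct$a, ct$b, ct$c, ct$d, correction, prr_ci, chi2),
    bcpnn(ct$a, ct$b, ct$c, ct$d, correction)
  )
  evaluate_signals(out)
}

# report-level stratum labels for the built-in stratifications
stratum_labels <- function(demo, by) {
  switch(by,
    sex = demo$sex,
    age = age_band(demo$age_years),
    reporter = demo$occp_cod,
    stop(sprintf("configuration error: unknown stratification \"%s\"", by),
         call. = FALSE)
  )
}

#' Stratified (subgroup) signal analysis
#'
#' Partitions the deduplicated report universe by sex, age band or reporter
#' occupation and computes each drug's 2x2 table and statistics within each
#' stratum, so the comparator is restricted to the same stratum. Strata with
#' `a < 3` are reported but flagged non-evaluable for the count-based ROR and
#' PRR criteria.
#'
#' @param tables normalized, deduplicated `faers_tables`.
#' @param dict a `drug_dictionary`.
#' @param events an `event_terms` set.
#' @param by `"sex"`, `"age"` or `"reporter"`.
#' @param ... passed to \code{\link{signal_stats}}.
#' @return tibble with `stratum`, the contingency columns, statistics, flags
#'   and `evaluable` (`a >= 3`).
#' @export
stratified_signals <- function(tables, dict, events = event_terms(),
                               by = c("sex", "age", "reporter"), ...) {
  by <- match.arg(by)
  labels <- stratum_labels(tables$demo, by)
  out <- lapply(sort(unique(labels)), function(s) {
    ids <- tables$demo$primaryid[labels == s]
    sub <- tables
    sub$demo <- tables$demo[labels == s, , drop = FALSE]
    sub$drug <- tables$drug[tables$drug$primaryid %in% ids, , drop = FALSE]
    sub$reac <- tables$reac[tables$reac$primaryid %in% ids, , drop = FALSE]
    st <- signal_stats(contingency_tables(sub, dict, events), ...)
    st$stratum <- s
    st
  })
  res <- dplyr::bind_rows(out)
  res$evaluable <- res$a >= 3
  dplyr::select(res, "drug", "stratum", dplyr::everything())
}

#' Forest-plot-ready ROR table
#'
#' @param stats output of \code{\link{signal_stats}} (optionally stratified).
#' @return tibble `drug` (+ `stratum` if present), `n_cases`, `ror`, `lo`,
#'   `hi`.
#' @export
forest_table <- function(stats) {
  keep <- intersect(c("drug", "stratum"), names(stats))
  out <- stats[, c(keep, "a", "ror", "ror_lo", "ror_hi")]
  dplyr::rename(out, n_cases = "a", lo = "ror_lo", hi = "ror_hi")
}
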