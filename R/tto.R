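TTO_BINS <- c("0-30", "31-60", "61-90", "91-359", ">=360")

#' Latency bin assignment
#'
#' Closed integer-day bins `[0,30]`, `[31,60]`, `[61,90]`, `[91,359]`,
#' `[360, Inf)`: a total partition of the non-negative integers. "Within one
#' month" means <= 30 days; "after one year" means >= 360 days.
#'
#' @param latency_days non-negative integer days.
#' @return factor with levels `0-30`, `31-60`, `61-90`, `91-359`, `>=360`.
#' @export
latency_bin <- function(latency_days) {
  stopifnot(all(latency_days >= 0, na.rm = TRUE))
  cut(latency_days, breaks = c(-0.5, 30.5, 60.5, 90.5, 359.5, Inf),
      labels = TTO_BINS)
}

#' Compute time-to-onset records for a cohort
#'
#' Latency is the difference in days between the event onset date and the
#' earliest therapy start date of the suspect drug. Rows with missing or
#' partial dates, or with onset before therapy start, are excluded and
#' counted in the exclusion log attached as the `"exclusions"` attribute.
#'
#' @param cohort tibble from \code{\link{build_cohort}} (columns
#'   `primaryid`, `drug`, `start_date_min`, `event_date`).
#' @return tibble `primaryid`, `drug`, `latency_days`, `bin`; attribute
#'   `exclusions` is a named count vector.
#' @export
compute_latency <- function(cohort) {
  no_start <- is.na(cohort$start_date_min)
  no_event <- is.na(cohort$event_date)
  lat <- as.integer(cohort$event_date - cohort$start_date_min)
  negative <- !no_start & !no_event & lat < 0
  keep <- !no_start & !no_event & !negative
  out <- tibble::tibble(
    primaryid = cohort$primaryid[keep],
    drug = cohort$drug[keep],
    latency_days = lat[keep]
  )
  out$bin <- latency_bin(out$latency_days)
  attr(out, "exclusions") <- c(
    missing_start = sum(no_start),
    missing_event = sum(no_event & !no_start),
    negative_latency = sum(negative)
  )
  out
}

#' Time-to-onset summary for one drug
#'
#' Per-bin counts and percentages (half-up, two decimals; denominator is the
#' number of reports with computable latency) and the cumulative onset curve,
#' which is non-decreasing and ends at 100.00.
#'
#' @param records latency records (from \code{\link{compute_latency}}) or any
#'   tibble with `drug` and `latency_days`.
#' @param drug canonical drug name to summarize.
#' @return tibble `drug`, `bin`, `count`, `percent`, `cum_percent`; zero
#'   records yield an empty tibble with attribute `empty = TRUE`.
#' @export
#' @examples
#' rec <- tibble::tibble(drug = "X",
#'                       latency_days = c(rep(10, 25), rep(40, 3), 400))
#' tto_summary(rec, "X")
tto_summary <- function(records, drug) {
  lat <- records$latency_days[records$drug == drug]
  if (!length(lat)) {
    out <- tibble::tibble(drug = character(0), bin = character(0),
                          count = integer(0), percent = numeric(0),
                          cum_percent = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  counts <- table(latency_bin(lat))
  n <- sum(counts)
  pct <- round_half_up(100 * as.numeric(counts) / n, 2)
  cum <- round_half_up(100 * cumsum(as.numeric(counts)) / n, 2)
  tibble::tibble(drug = drug, bin = TTO_BINS,
                 count = as.integer(counts), percent = pct,
                 cum_percent = cum)
}

#' Time-to-onset summaries for every drug present
#'
#' @param records latency records.
#' @return tibble stacking \code{\link{tto_summary}} over drugs.
#' @export
tto_summary_all <- function(records) {
  dplyr::bind_rows(lapply(sort(unique(records$drug)),
                          function(d) tto_summary(records, d)))
}
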