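TOP3_QUINOLONES <- c("CIPROFLOXACIN", "LEVOFLOXACIN", "OFLOXACIN")

#' Read a literature case table
#'
#' Comma-separated file with header
#' `drug,age_years,sex,latency_days,hospitalized,outcome`. The packaged
#' default `literature_cases_synthetic.csv` is a synthetic stand-in for a
#' curated set of nine published quinolone-associated pemphigoid case
#' reports, constructed to carry the published marginal summaries.
#'
#' @param path CSV path; defaults to the packaged synthetic table.
#' @return validated tibble of cases.
#' @export
read_literature_cases <- function(path = system.file(
                                    "extdata",
                                    "literature_cases_synthetic.csv",
                                    package = "pvdispro")) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("drug", "age_years", "sex", "latency_days", "hospitalized",
            "outcome")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("literature table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$hospitalized <- as.logical(df$hospitalized)
  if (any(df$latency_days < 1) || any(df$age_years <= 0)) {
    stop("literature cases must have latency_days >= 1 and age_years > 0",
         call. = FALSE)
  }
  df
}

#' Summarize a literature case series
#'
#' Shares are percentages of all cases, rounded half-up to one decimal; the
#' drug mix is the combined share of ciprofloxacin, levofloxacin and
#' ofloxacin; latency is summarized by median (mean of the central pair for
#' even n) and range.
#'
#' @param cases tibble from \code{\link{read_literature_cases}} or
#'   \code{\link{simulate_literature_cases}}.
#' @return named numeric vector with elements `drug_mix_pct`, `pct_elderly`,
#'   `pct_under_45`, `pct_female`, `pct_hospitalized`,
#'   `median_latency_days`, `latency_min_days`, `latency_max_days`.
#' @export
summarize_literature <- function(cases) {
  if (!nrow(cases)) stop("no literature cases to summarize", call. = FALSE)
  n <- nrow(cases)
  pct <- function(x) round_half_up(100 * sum(x) / n, 1)
  c(
    drug_mix_pct = pct(norm_name(cases$drug) %in% TOP3_QUINOLONES),
    pct_elderly = pct(cases$age_years >= 65),
    pct_under_45 = pct(cases$age_years < 45),
    pct_female = pct(cases$sex == "F"),
    pct_hospitalized = pct(cases$hospitalized),
    median_latency_days = as.numeric(stats::median(cases$latency_days)),
    latency_min_days = as.numeric(min(cases$latency_days)),
    latency_max_days = as.numeric(max(cases$latency_days))
  )
}

#' Summarize a FAERS cohort on the concordance dimensions
#'
#' Same keys as \code{\link{summarize_literature}}, computed from the
#' analysis cohort (denominators include `NS` levels, matching the
#' descriptive tables) and from the pooled latency records.
#'
#' @param cohort tibble from \code{\link{build_cohort}}.
#' @param latency_records tibble from \code{\link{compute_latency}}; pass
#'   `NULL` to leave the latency entries `NA`.
#' @return named numeric vector, keys as in
#'   \code{\link{summarize_literature}}.
#' @export
faers_summary <- function(cohort, latency_records = NULL) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)
  pct <- function(x) round_half_up(100 * sum(x, na.rm = TRUE) / n, 1)
  band <- age_band(cohort$age_years)
  lat <- latency_records$latency_days
  c(
    drug_mix_pct = pct(cohort$drug %in% TOP3_QUINOLONES),
    pct_elderly = pct(band == ">=65"),
    pct_under_45 = pct(band %in% c("<18", "18-44")),
    pct_female = pct(cohort$sex == "F"),
    pct_hospitalized = pct(cohort$outc_cod == "HO"),
    median_latency_days = if (length(lat)) as.numeric(stats::median(lat))
                          else NA_real_,
    latency_min_days = if (length(lat)) as.numeric(min(lat)) else NA_real_,
    latency_max_days = if (length(lat)) as.numeric(max(lat)) else NA_real_
  )
}

#' Dimension-by-dimension concordance of literature and FAERS summaries
#'
#' Pairs the two summaries on identical keys and reports absolute
#' differences; dimensions differing by more than `threshold` are flagged in
#' the coherence column (descriptive only - no inferential test is applied).
#'
#' @param lit_summary,faers_summary named numeric vectors on identical keys.
#' @param threshold flag threshold (percentage points / days), default 25.
#' @return tibble `dimension`, `literature`, `faers`, `diff`, `flagged`.
#' @export
#' @examples
#' concordance(c(pct_female = 55.6), c(pct_female = 55.7))
concordance <- function(lit_summary, faers_summary, threshold = 25) {
  missing <- union(setdiff(names(lit_summary), names(faers_summary)),
                   setdiff(names(faers_summary), names(lit_summary)))
  if (length(missing)) {
    stop(sprintf("summaries disagree on dimensions: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  keys <- names(lit_summary)
  diff <- abs(lit_summary[keys] - faers_summary[keys])
  tibble::tibble(
    dimension = keys,
    literature = unname(lit_summary[keys]),
    faers = unname(faers_summary[keys]),
    diff = unname(diff),
    flagged = unname(!is.na(diff) & diff > threshold)
  )
}
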