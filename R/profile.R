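#' Age bands used in the descriptive tables
#'
#' Whole-year bands `<18`, `18-44`, `45-64`, `>=65`, with `NS` for missing
#' ages. The upper band is inclusive at 65.
#'
#' @param age_years numeric ages in years (`NA` allowed).
#' @return character band labels.
#' @export
age_band <- function(age_years) {
  out <- rep("NS", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 45] <- "18-44"
  out[ok & age_years >= 45 & age_years < 65] <- "45-64"
  out[ok & age_years >= 65] <- ">=65"
  out
}

weight_band <- function(weight_kg) {
  out <- rep("NS", length(weight_kg))
  ok <- !is.na(weight_kg)
  out[ok & weight_kg < 80] <- "<80"
  out[ok & weight_kg >= 80] <- ">=80"
  out
}

#' Percentages from per-level counts
#'
#' Turns a named vector of level counts into the long profile rows, with
#' percentages `100 * count / total` rounded half-up to one decimal (the
#' rounding every descriptive table uses; banker's rounding would print
#' 42/183 as 22.9 instead of 23.0).
#'
#' @param counts named integer vector of counts for one characteristic.
#' @param characteristic label for the characteristic column.
#' @return tibble `characteristic`, `level`, `count`, `percent`.
#' @export
#' @examples
#' profile_from_counts(c(F = 102, M = 57, NS = 24), "sex")
profile_from_counts <- function(counts, characteristic = "characteristic") {
  total <- sum(counts)
  tibble::tibble(
    characteristic = characteristic,
    level = names(counts),
    count = as.integer(counts),
    percent = round_half_up(100 * as.numeric(counts) / total, 1)
  )
}

count_levels <- function(x, levels = NULL) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "NS"
  tab <- table(x)
  if (is.null(levels)) levels <- sort(names(tab))
  out <- setNames(rep(0L, length(levels)), levels)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Descriptive characteristics profile of a cohort
#'
#' Counts and percentages by drug, sex, age band, weight band, reporter
#' occupation, region and outcome, with `NS` a first-class level in every
#' characteristic and half-up one-decimal rounding.
#'
#' @param cohort tibble from \code{\link{build_cohort}}.
#' @return long tibble `characteristic`, `level`, `count`, `percent`.
#' @export
profile_cohort <- function(cohort) {
  if (!nrow(cohort)) {
    stop("cannot profile an empty cohort", call. = FALSE)
  }
  pieces <- list(
    profile_from_counts(count_levels(cohort$drug), "drug"),
    profile_from_counts(count_levels(cohort$sex, c("F", "M", "NS")), "sex"),
    profile_from_counts(
      count_levels(age_band(cohort$age_years),
                   c("<18", "18-44", "45-64", ">=65", "NS")), "age"),
    profile_from_counts(
      count_levels(weight_band(cohort$weight_kg), c("<80", ">=80", "NS")),
      "weight"),
    profile_from_counts(count_levels(cohort$occp_cod), "occupation"),
    profile_from_counts(count_levels(cohort$occr_country), "region"),
    profile_from_counts(count_levels(cohort$outc_cod), "outcome")
  )
  dplyr::bind_rows(pieces)
}

#' Reports per year
#'
#' Dense per-year counts over the observed year range (zeros filled), with
#' missing report years counted under `NS`.
#'
#' @param cohort tibble with a `report_year` column.
#' @return tibble `year` (character; includes `"NS"` when applicable),
#'   `count`.
#' @export
yearly_counts <- function(cohort) {
  yr <- cohort$report_year
  ns <- sum(is.na(yr))
  yr <- yr[!is.na(yr)]
  if (length(yr)) {
    rng <- seq(min(yr), max(yr))
    tab <- table(factor(yr, levels = rng))
    out <- tibble::tibble(year = as.character(rng), count = as.integer(tab))
  } else {
    out <- tibble::tibble(year = character(0), count = integer(0))
  }
  if (ns > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(year = "NS", count = ns))
  }
  out
}
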