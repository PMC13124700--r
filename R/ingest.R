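SEX_CODES <- c("F", "M")
OCCP_CODES <- c("CN", "MD", "PH", "OT")
OUTC_CODES <- c("DE", "HO", "OT")
ROLE_CODES <- c("PS", "SS", "C", "I")

# normalize a code field to its closed set; anything else (incl. blank) -> NS
norm_code <- function(x, codes) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | !(x %in% codes)] <- "NS"
  x
}

read_dollar_file <- function(path, required, strict = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "$", quote = "", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE,
                          na.strings = NULL, check.names = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("file %s is missing mandatory column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  bad <- !nzchar(trimws(df$primaryid))
  n_bad <- sum(bad)
  if (n_bad > 0) {
    if (strict) {
      stop(sprintf("file %s: %d row(s) with empty primaryid",
                   basename(path), n_bad), call. = FALSE)
    }
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "n_malformed") <- n_bad
  tibble::as_tibble(df)
}

#' Read FAERS-style quarterly ASCII tables
#'
#' Reads the four "$"-delimited quarterly files (DEMO, DRUG, REAC, THER),
#' types and normalizes fields, and records a parse log. Codes outside their
#' closed sets (sex, reporter occupation, outcome) become `"NS"`; ages are
#' converted to years (decades x10, months /12, days /365.25), weights to kg
#' (lbs x 0.45359237); dates with fewer than eight digits are treated as
#' missing for day-level arithmetic but still populate `report_year`, and are
#' counted as partial-date warnings.
#'
#' @param demo,drug,reac,ther file paths.
#' @param strict if `TRUE` (default) malformed rows (empty primaryid) raise an
#'   error; otherwise they are dropped and counted in the log.
#' @return a `faers_tables` object whose `demo` tibble carries the derived
#'   columns `fda_date`, `event_date` (Date), `report_year`, `age_years`,
#'   `weight_kg` and normalized `sex`, `occp_cod`, `outc_cod`; `drug` carries
#'   normalized `role_cod`; `ther` carries `start_date`. A `log` element
#'   counts malformed rows and partial/unparseable dates per table.
#' @export
read_faers_tables <- function(demo, drug, reac, ther, strict = TRUE) {
  d <- read_dollar_file(demo, c("primaryid", "caseid", "fda_dt"), strict)
  g <- read_dollar_file(drug, c("primaryid", "drugname", "role_cod"), strict)
  r <- read_dollar_file(reac, c("primaryid", "pt"), strict)
  t <- read_dollar_file(ther, c("primaryid", "start_dt"), strict)
  log <- list(
    malformed = c(demo = attr(d, "n_malformed"), drug = attr(g, "n_malformed"),
                  reac = attr(r, "n_malformed"), ther = attr(t, "n_malformed"))
  )
  out <- list(demo = normalize_demo(d), drug = normalize_drug(g),
              reac = normalize_reac(r), ther = normalize_ther(t))
  log$partial_dates <- c(
    fda_dt = sum(attr(out$demo, "fda_partial")),
    event_dt = sum(attr(out$demo, "event_partial")),
    start_dt = sum(attr(out$ther, "start_partial"))
  )
  structure(c(out, list(log = log)), class = "faers_tables")
}

#' Normalize a raw DEMO table
#'
#' Applies the code-set, unit and date normalization of
#' \code{\link{read_faers_tables}} to an in-memory DEMO tibble (as produced by
#' \code{\link{simulate_faers}}).
#'
#' @param demo tibble with the raw character DEMO columns.
#' @return tibble with added derived columns (see
#'   \code{\link{read_faers_tables}}).
#' @export
normalize_demo <- function(demo) {
  fda <- parse_faers_date(demo$fda_dt)
  evt <- parse_faers_date(demo$event_dt %||% rep("", nrow(demo)))
  age_v <- suppressWarnings(as.numeric(demo$age %||% rep("", nrow(demo))))
  age_c <- toupper(trimws(demo$age_cod %||% rep("", nrow(demo))))
  age_years <- ifelse(age_c == "DEC", age_v * 10,
               ifelse(age_c == "MON", age_v / 12,
               ifelse(age_c == "DY",  age_v / 365.25,
               age_v)))  # YR or blank unit: value taken as years
  wt_v <- suppressWarnings(as.numeric(demo$wt %||% rep("", nrow(demo))))
  wt_c <- toupper(trimws(demo$wt_cod %||% rep("", nrow(demo))))
  weight_kg <- ifelse(wt_c == "LBS", wt_v * 0.45359237, wt_v)
  out <- dplyr::mutate(
    demo,
    sex = norm_code(demo$sex %||% rep("", nrow(demo)), SEX_CODES),
    occp_cod = norm_code(demo$occp_cod %||% rep("", nrow(demo)), OCCP_CODES),
    outc_cod = norm_code(demo$outc_cod %||% rep("", nrow(demo)), OUTC_CODES),
    fda_date = fda$date,
    event_date = evt$date,
    report_year = fda$year,
    age_years = age_years,
    weight_kg = weight_kg
  )
  attr(out, "fda_partial") <- fda$partial
  attr(out, "event_partial") <- evt$partial
  out
}

#' @rdname normalize_demo
#' @param drug raw DRUG tibble.
#' @export
normalize_drug <- function(drug) {
  dplyr::mutate(drug, role_cod = norm_code(drug$role_cod, ROLE_CODES))
}

#' @rdname normalize_demo
#' @param reac raw REAC tibble.
#' @export
normalize_reac <- function(reac) {
  out <- dplyr::mutate(reac, pt = trimws(reac$pt))
  out[nzchar(out$pt), , drop = FALSE]
}

#' @rdname normalize_demo
#' @param ther raw THER tibble.
#' @export
normalize_ther <- function(ther) {
  st <- parse_faers_date(ther$start_dt)
  out <- dplyr::mutate(ther, start_date = st$date)
  attr(out, "start_partial") <- st$partial
  out
}

#' Normalize all four tables in memory
#'
#' Convenience wrapper applying the per-table normalizers to a
#' `faers_tables` object that has not been round-tripped through files
#' (e.g. straight from \code{\link{simulate_faers}}).
#'
#' @param tables a `faers_tables` object with raw character columns.
#' @return a normalized `faers_tables` object.
#' @export
normalize_tables <- function(tables) {
  out <- tables
  out$demo <- normalize_demo(tables$demo)
  out$drug <- normalize_drug(tables$drug)
  out$reac <- normalize_reac(tables$reac)
  out$ther <- normalize_ther(tables$ther)
  out
}

#' Deduplicate report versions by the FDA retention rule
#'
#' FAERS cases accumulate follow-up versions sharing a CASEID; the FDA
#' recommendation retains, for each case, only the version with the largest
#' PRIMARYID. Output is sorted by (caseid, primaryid) and the operation is
#' idempotent.
#'
#' @param demo a DEMO tibble with `primaryid` and `caseid` columns.
#' @return the retained rows, one per distinct caseid.
#' @export
#' @examples
#' demo <- tibble::tibble(primaryid = c("100", "101"), caseid = c("A", "A"))
#' deduplicate_reports(demo)$primaryid # "101"
deduplicate_reports <- function(demo) {
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  if (anyNA(pid)) {
    # fallback: lexicographic on equal-length strings for non-numeric ids
    pid <- rank(demo$primaryid, ties.method = "first")
  }
  if (anyDuplicated(demo$primaryid)) {
    stop("integrity error: duplicate primaryid values in DEMO", call. = FALSE)
  }
  o <- order(demo$caseid, pid)
  demo <- demo[o, , drop = FALSE]
  keep <- !duplicated(demo$caseid, fromLast = TRUE)
  demo[keep, , drop = FALSE]
}

#' Deduplicate a full set of tables
#'
#' Applies \code{\link{deduplicate_reports}} to DEMO and restricts DRUG, REAC
#' and THER to the retained primaryids.
#'
#' @param tables a `faers_tables` object.
#' @return a `faers_tables` object with one version per case.
#' @export
deduplicate_tables <- function(tables) {
  demo <- deduplicate_reports(tables$demo)
  keep <- demo$primaryid
  out <- tables
  out$demo <- demo
  out$drug <- tables$drug[tables$drug$primaryid %in% keep, , drop = FALSE]
  out$reac <- tables$reac[tables$reac$primaryid %in% keep, , drop = FALSE]
  out$ther <- tables$ther[tables$ther$primaryid %in% keep, , drop = FALSE]
  out
}
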