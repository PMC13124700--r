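#' Build a drug standardization dictionary
#'
#' Maps verbatim drug names to canonical names via case- and
#' whitespace-insensitive exact synonym matching, and carries each drug's
#' approval date (start of its reporting window) and an include flag.
#'
#' @param canonical character vector of canonical names.
#' @param synonyms list of character vectors, one per canonical name.
#' @param approval_date YYYYMMDD strings, one per canonical name.
#' @param include logical, whether the drug enters the analysis (drugs with
#'   unreliable naming or no target-event reports are kept in the dictionary
#'   but excluded from cohorts).
#' @return an object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(canonical, synonyms, approval_date,
                            include = rep(TRUE, length(canonical))) {
  stopifnot(length(synonyms) == length(canonical),
            length(approval_date) == length(canonical))
  keys <- norm_name(canonical)
  map <- character(0)
  for (i in seq_along(canonical)) {
    syn <- unique(c(keys[i], norm_name(synonyms[[i]])))
    clash <- syn[syn %in% names(map) & map[syn] != canonical[i]]
    if (length(clash)) {
      stop(sprintf("synonym(s) mapped to several canonical names: %s",
                   paste(clash, collapse = ", ")), call. = FALSE)
    }
    map[syn] <- canonical[i]
  }
  appr <- parse_faers_date(approval_date)
  if (anyNA(appr$date)) {
    stop("approval_date must be full YYYYMMDD dates", call. = FALSE)
  }
  structure(
    list(canonical = canonical, map = map,
         approval = setNames(appr$date, canonical),
         include = setNames(include, canonical)),
    class = "drug_dictionary"
  )
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("drug dictionary:", length(x$canonical), "drugs (",
      sum(x$include), "included ),", length(x$map), "synonym keys\n")
  invisible(x)
}

#' Read a drug dictionary from a CSV file
#'
#' Expected columns: `canonical`, `synonyms` (";"-separated), `approval_date`
#' (YYYYMMDD), `include` (TRUE/FALSE). The packaged default covers the five
#' analysed quinolones plus three excluded ones.
#'
#' @param path CSV path; defaults to the packaged dictionary.
#' @return a `drug_dictionary`.
#' @export
read_drug_dictionary <- function(path = system.file("extdata",
                                                    "quinolone_dictionary.csv",
                                                    package = "pvdispro")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  drug_dictionary(
    canonical = df$canonical,
    synonyms = lapply(strsplit(df$synonyms, ";", fixed = TRUE), trimws),
    approval_date = as.character(df$approval_date),
    include = as.logical(df$include)
  )
}

#' Standardize verbatim drug names
#'
#' Case- and whitespace-insensitive exact match against the dictionary's
#' synonym table. Unmapped names are returned as `NA` (a value, not an
#' error), so they can be counted and reviewed.
#'
#' @param verbatim character vector of reported drug names.
#' @param dict a `drug_dictionary`.
#' @return character vector of canonical names, `NA` where unmapped.
#' @export
#' @examples
#' dict <- read_drug_dictionary()
#' standardize_drug(c("Cipro XR", "ofloxacin", "tobramycin"), dict)
standardize_drug <- function(verbatim, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  unname(dict$map[norm_name(verbatim)])
}

#' Event term set
#'
#' @param terms character vector of preferred terms defining the outcome;
#'   matching is case-insensitive and exact.
#' @return normalized non-empty character vector (class `event_terms`).
#' @export
event_terms <- function(terms = "Pemphigoid") {
  terms <- unique(norm_name(terms))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) {
    stop("configuration error: event term set is empty", call. = FALSE)
  }
  structure(terms, class = "event_terms")
}

#' Read an event term set from a CSV file
#'
#' One-column (`term`) CSV; the packaged default holds the single preferred
#' term "Pemphigoid".
#'
#' @param path CSV path; defaults to the packaged term list.
#' @return an `event_terms` set.
#' @export
read_event_terms <- function(path = system.file("extdata",
                                                "event_terms.csv",
                                                package = "pvdispro")) {
  event_terms(utils::read.csv(path, stringsAsFactors = FALSE)$term)
}

# primaryids (character) whose reports document any target event term
event_primaryids <- function(reac, events) {
  unique(reac$primaryid[norm_name(reac$pt) %in% unlist(events)])
}

#' Build the analysis cohort
#'
#' One row per (report, drug) pair where the deduplicated report lists an
#' included dictionary drug as primary suspect (PS) and its FDA receipt date
#' falls on or after that drug's approval date. Each row carries the report's
#' demographics, an event flag (any reaction preferred term in the event
#' set), and latency fields (earliest therapy start for the suspect drug
#' occurrence, event onset date).
#'
#' @param tables normalized, deduplicated `faers_tables`.
#' @param dict a `drug_dictionary`.
#' @param events an `event_terms` set.
#' @return tibble cohort.
#' @export
build_cohort <- function(tables, dict, events = event_terms()) {
  stopifnot(inherits(dict, "drug_dictionary"))
  if (!length(dict$canonical) || !sum(dict$include)) {
    stop("configuration error: drug dictionary has no included drugs",
         call. = FALSE)
  }
  demo <- tables$demo
  drug <- tables$drug
  drug$canonical <- standardize_drug(drug$drugname, dict)
  ps <- drug[drug$role_cod == "PS" & !is.na(drug$canonical) &
               dict$include[drug$canonical], , drop = FALSE]
  # one cohort candidate per (report, drug): collapse repeated mentions,
  # keeping every drug_seq so therapy rows can be matched
  ps$key <- paste(ps$primaryid, ps$canonical)
  first <- !duplicated(ps$key)
  cand <- ps[first, c("primaryid", "canonical"), drop = FALSE]

  # earliest therapy start among the suspect drug's episodes in the report
  th <- tables$ther
  th_key <- paste(th$primaryid, th$dsg_drug_seq)
  ps_th <- th[th_key %in% paste(ps$primaryid, ps$drug_seq), , drop = FALSE]
  if (nrow(ps_th)) {
    seq_to_can <- setNames(ps$canonical, paste(ps$primaryid, ps$drug_seq))
    ps_th$canonical <- seq_to_can[paste(ps_th$primaryid, ps_th$dsg_drug_seq)]
    ps_th <- ps_th[!is.na(ps_th$start_date), , drop = FALSE]
  }
  if (nrow(ps_th)) {
    agg <- stats::aggregate(start_date ~ primaryid + canonical, data = ps_th,
                            FUN = min)
    names(agg)[names(agg) == "start_date"] <- "start_date_min"
    cand <- dplyr::left_join(cand, agg, by = c("primaryid", "canonical"))
  } else {
    cand$start_date_min <- as.Date(NA)
  }

  ev_ids <- event_primaryids(tables$reac, events)
  cohort <- dplyr::left_join(cand, demo, by = "primaryid")
  cohort$event <- cohort$primaryid %in% ev_ids
  cohort <- cohort[!is.na(cohort$fda_date) &
                     cohort$fda_date >= dict$approval[cohort$canonical], ,
                   drop = FALSE]
  dplyr::rename(tibble::as_tibble(cohort), drug = "canonical")
}

#' 2x2 contingency table for one drug-event pair
#'
#' Partitions a deduplicated report universe by target-drug primary-suspect
#' exposure and target-event occurrence:
#' `a` = drug and event, `b` = drug only, `c` = event only, `d` = neither.
#' The universe for a drug is restricted to reports received on or after its
#' approval date (both exposed and comparator sides).
#'
#' @param tables normalized, deduplicated `faers_tables`.
#' @param dict a `drug_dictionary`.
#' @param events an `event_terms` set.
#' @param drugs canonical names to tabulate; default all included drugs.
#' @return tibble with columns `drug`, `a`, `b`, `c`, `d`, `n_universe`.
#' @export
contingency_tables <- function(tables, dict, events = event_terms(),
                               drugs = NULL) {
  stopifnot(inherits(dict, "drug_dictionary"))
  if (is.null(drugs)) drugs <- dict$canonical[dict$include]
  demo <- tables$demo
  dtab <- tables$drug
  dtab$canonical <- standardize_drug(dtab$drugname, dict)
  ev_ids <- event_primaryids(tables$reac, events)
  evented <- demo$primaryid %in% ev_ids
  out <- lapply(drugs, function(D) {
    ps_ids <- unique(dtab$primaryid[dtab$role_cod == "PS" &
                                      !is.na(dtab$canonical) &
                                      dtab$canonical == D])
    in_win <- !is.na(demo$fda_date) & demo$fda_date >= dict$approval[[D]]
    exposed <- demo$primaryid %in% ps_ids
    a <- sum(in_win & exposed & evented)
    b <- sum(in_win & exposed & !evented)
    cc <- sum(in_win & !exposed & evented)
    d <- sum(in_win & !exposed & !evented)
    tibble::tibble(drug = D, a = a, b = b, c = cc, d = d,
                   n_universe = sum(in_win))
  })
  res <- dplyr::bind_rows(out)
  if (any(res$a + res$b + res$c + res$d != res$n_universe)) {
    stop("integrity error: contingency cells do not sum to universe size",
         call. = FALSE)
  }
  res
}

#' Contingency table from explicit counts
#'
#' @param universe_n number of in-window deduplicated reports.
#' @param drug_event reports with the target drug (PS) and target event (`a`).
#' @param drug_only reports with the drug and other events (`b`).
#' @param event_only reports with other drugs and the target event (`c`).
#' @return single-row tibble with `a`, `b`, `c`, `d`.
#' @export
contingency_from_counts <- function(universe_n, drug_event, drug_only,
                                    event_only) {
  d <- universe_n - drug_event - drug_only - event_only
  if (min(drug_event, drug_only, event_only, d) < 0) {
    stop("integrity error: negative contingency cell", call. = FALSE)
  }
  tibble::tibble(a = drug_event, b = drug_only, c = event_only, d = d)
}
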