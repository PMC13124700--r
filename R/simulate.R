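#' Default quinolone drug profiles
#'
#' The five quinolones analysed by the pipeline, with name synonyms that the
#' standardization step must resolve, background exposure probabilities (the
#' per-case probability that a report lists the drug at all), and US approval
#' dates that define each drug's reporting window.
#'
#' @return a tibble with columns `canonical`, `synonyms` (list column),
#'   `exposure_prob`, `approval_date` (YYYYMMDD string).
#' @export
drug_profiles <- function() {
  tibble::tibble(
    canonical = c("CIPROFLOXACIN", "LEVOFLOXACIN", "MOXIFLOXACIN",
                  "NORFLOXACIN", "OFLOXACIN"),
    synonyms = list(
      c("CIPRO", "CIPRO XR", "CIPROXIN", "CIPROFLOXACIN HYDROCHLORIDE"),
      c("LEVAQUIN", "TAVANIC", "LEVOFLOXACIN HEMIHYDRATE"),
      c("AVELOX", "MOXIFLOXACIN HYDROCHLORIDE"),
      c("NOROXIN", "NORFLOXACIN SANDOZ"),
      c("FLOXIN", "OFLOXACIN OTIC", "TARIVID")
    ),
    exposure_prob = c(0.02, 0.015, 0.006, 0.003, 0.03),
    approval_date = c("19871022", "19961220", "19991210",
                      "19861031", "19901228")
  )
}

# non-quinolone suspects/concomitants carried by every synthetic case
BACKGROUND_DRUGS <- c(
  "PARACETAMOL", "METFORMIN", "ASPIRIN", "OMEPRAZOLE", "AMOXICILLIN",
  "LISINOPRIL", "ATORVASTATIN", "AMLODIPINE", "METOPROLOL", "SERTRALINE",
  "IBUPROFEN", "PREDNISONE", "FUROSEMIDE", "GABAPENTIN", "LEVOTHYROXINE",
  "WARFARIN", "INSULIN GLARGINE", "CLOPIDOGREL", "PANTOPRAZOLE", "SIMVASTATIN"
)

# background reaction preferred terms (never the target event term)
BACKGROUND_PTS <- c(
  "Nausea", "Headache", "Rash", "Diarrhoea", "Pyrexia", "Dizziness",
  "Vomiting", "Pruritus", "Fatigue", "Arthralgia", "Dyspnoea", "Insomnia",
  "Tendonitis", "Tendon rupture", "Photosensitivity reaction",
  "Electrocardiogram QT prolonged", "Hypoglycaemia", "Anxiety", "Myalgia",
  "Urticaria"
)

#' Simulation configuration for synthetic spontaneous reports
#'
#' Builds and validates the configuration consumed by
#' \code{\link{simulate_faers}}. Defaults encode a desk-scale spontaneous
#' reporting system in which the target event ("Pemphigoid") occurs at a base
#' reporting rate among reports whose primary suspect is any other drug, and
#' at `relative_risk` times that rate when a given quinolone is the primary
#' suspect, with case duplication, field missingness and a short-latency
#' log-normal onset model.
#'
#' @param n_reports positive integer; number of raw (pre-deduplication) report
#'   versions to emit.
#' @param drugs drug profile tibble as returned by \code{\link{drug_profiles}}.
#' @param event_term target preferred term.
#' @param relative_risk scalar or per-drug named numeric (>= 0); multiplicative
#'   reporting-rate ratio for the target event when the drug is the primary
#'   suspect. 1 encodes the null.
#' @param base_rate base probability that a report documents the target event
#'   when no elevated-risk drug is the primary suspect.
#' @param duplicate_fraction probability in [0, 1) that a case emits more than
#'   one report version.
#' @param missingness named list of per-field missing probabilities
#'   (`sex`, `age`, `weight`, `occupation`, `event_dt`, `start_dt`).
#' @param demographics named list of categorical distributions (`sex`,
#'   `age_group`, `occupation`, `region`, `outcome`); each a named probability
#'   vector summing to 1.
#' @param latency_model list with `family` ("lognormal"), `meanlog`, `sdlog`;
#'   days from therapy start to event onset.
#' @param sex_rr_modifier named numeric (`F`, `M`) multiplying the excess risk
#'   (`rr_effective = 1 + (relative_risk - 1) * modifier`), enabling
#'   sex-specific simulated effects. Default no modification.
#' @param ps_prob probability that an exposed quinolone is designated primary
#'   suspect (otherwise it is a concomitant and a background drug is PS).
#' @param seed integer master seed; per-table child streams are derived from
#'   it so adding one output table never perturbs another's draws.
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_reports = 2000, relative_risk = 5, seed = 1)
sim_config <- function(n_reports = 50000,
                       drugs = drug_profiles(),
                       event_term = "Pemphigoid",
                       relative_risk = 1,
                       base_rate = 0.01,
                       duplicate_fraction = 0.1,
                       missingness = list(sex = 0.13, age = 0.17,
                                          weight = 0.70, occupation = 0.06,
                                          event_dt = 0.40, start_dt = 0.30),
                       demographics = list(
                         sex = c(F = 0.52, M = 0.48),
                         age_group = c(`<18` = 0.02, `18-44` = 0.22,
                                       `45-64` = 0.30, `>=65` = 0.46),
                         occupation = c(CN = 0.06, MD = 0.42,
                                        PH = 0.12, OT = 0.40),
                         region = c(Asia = 0.05, Europe = 0.05,
                                    `North America` = 0.02, Others = 0.88),
                         outcome = c(DE = 0.01, HO = 0.60, OT = 0.29,
                                     NS = 0.10)
                       ),
                       latency_model = list(family = "lognormal",
                                            meanlog = log(15), sdlog = 1),
                       sex_rr_modifier = c(F = 1, M = 1),
                       ps_prob = 0.85,
                       seed = 1L) {
  if (length(n_reports) != 1 || is.na(n_reports) || n_reports < 1 ||
      n_reports != floor(n_reports)) {
    stop_config("n_reports", "must be a positive integer")
  }
  stopifnot(is.data.frame(drugs),
            all(c("canonical", "synonyms", "exposure_prob",
                  "approval_date") %in% names(drugs)))
  if (any(drugs$exposure_prob < 0 | drugs$exposure_prob > 1)) {
    stop_config("drugs$exposure_prob", "must lie in [0, 1]")
  }
  rr <- relative_risk
  if (length(rr) == 1 && is.null(names(rr))) {
    rr <- setNames(rep(rr, nrow(drugs)), drugs$canonical)
  }
  if (!all(drugs$canonical %in% names(rr))) {
    missing <- setdiff(drugs$canonical, names(rr))
    stop_config("relative_risk",
                paste("missing entries for", paste(missing, collapse = ", ")))
  }
  if (any(is.na(rr)) || any(rr < 0)) {
    stop_config("relative_risk", "must be >= 0")
  }
  if (length(base_rate) != 1 || base_rate < 0 || base_rate > 1) {
    stop_config("base_rate", "must be a probability in [0, 1]")
  }
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    stop_config("duplicate_fraction", "must lie in [0, 1)")
  }
  for (f in names(missingness)) {
    p <- missingness[[f]]
    if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop_config(paste0("missingness$", f), "must be a probability in [0, 1]")
    }
  }
  for (f in names(demographics)) {
    d <- demographics[[f]]
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop_config(paste0("demographics$", f),
                  "must be a probability vector summing to 1")
    }
  }
  if (ps_prob < 0 || ps_prob > 1) {
    stop_config("ps_prob", "must be a probability in [0, 1]")
  }
  if (!identical(latency_model$family, "lognormal")) {
    stop_config("latency_model$family", "must be \"lognormal\"")
  }
  structure(
    list(n_reports = as.integer(n_reports), drugs = drugs,
         event_term = event_term, relative_risk = rr[drugs$canonical],
         base_rate = base_rate, duplicate_fraction = duplicate_fraction,
         missingness = missingness, demographics = demographics,
         latency_model = latency_model,
         sex_rr_modifier = sex_rr_modifier, ps_prob = ps_prob,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# sample a categorical distribution (named prob vector) for n cases
sample_cat <- function(n, dist) {
  sample(names(dist), n, replace = TRUE, prob = dist)
}

# blank entries of a character vector with probability p (pre-drawn u)
blank_if <- function(x, u, p) {
  x[u < p] <- ""
  x
}

#' Generate synthetic FAERS-style quarterly tables
#'
#' Draws a spontaneous-report database with the ground-truth association
#' strength, duplication, missingness, demographics and latency structure
#' described by the configuration. Cases are exposed to each drug
#' independently with its background probability; the probability that a
#' report documents the target event is `base_rate * rr_effective` when a
#' configured drug is the primary suspect and `base_rate` otherwise. Duplicate
#' case versions share a CASEID, carry strictly increasing FDA receipt dates,
#' and the version with the largest PRIMARYID is the ground truth, matching
#' the FDA retention rule applied downstream.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return an object of class `faers_tables`: a list with tibbles `demo`,
#'   `drug`, `reac`, `ther` (all columns character, FAERS column names), plus
#'   a `meta` list carrying the per-case ground truth used by calibration
#'   tests.
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  drugs <- cfg$drugs
  nd <- nrow(drugs)

  ## ---- case stream: version counts, demographics, exposure, events -------
  set.seed(sub_seed(cfg$seed, "cases"))
  n_max <- cfg$n_reports
  dup <- runif(n_max) < cfg$duplicate_fraction
  extra <- 1L + rgeom(n_max, 0.6)
  k <- ifelse(dup, 1L + extra, 1L)
  cum <- cumsum(k)
  n_cases <- which(cum >= cfg$n_reports)[1]
  k <- k[seq_len(n_cases)]
  k[n_cases] <- k[n_cases] - (cum[n_cases] - cfg$n_reports)
  n_versions <- sum(k)

  sex_true <- sample_cat(n_cases, cfg$demographics$sex)
  age_group <- sample_cat(n_cases, cfg$demographics$age_group)
  age_years <- numeric(n_cases)
  age_years[age_group == "<18"] <- runif(sum(age_group == "<18"), 1, 17)
  age_years[age_group == "18-44"] <- runif(sum(age_group == "18-44"), 18, 44)
  age_years[age_group == "45-64"] <- runif(sum(age_group == "45-64"), 45, 64)
  age_years[age_group == ">=65"] <- runif(sum(age_group == ">=65"), 65, 95)
  age_years <- floor(age_years)
  weight_kg <- round(rlnorm(n_cases, log(72), 0.2), 1)
  occp <- sample_cat(n_cases, cfg$demographics$occupation)
  region <- sample_cat(n_cases, cfg$demographics$region)
  outcome <- sample_cat(n_cases, cfg$demographics$outcome)

  expo <- matrix(runif(n_cases * nd), n_cases, nd) <
    matrix(drugs$exposure_prob, n_cases, nd, byrow = TRUE)
  n_expo <- rowSums(expo)
  # uniform choice among exposed quinolones: max of masked random scores
  pick_score <- matrix(runif(n_cases * nd), n_cases, nd) * expo
  pick <- max.col(pick_score, ties.method = "first")
  pick[n_expo == 0] <- NA_integer_
  quinolone_ps <- n_expo > 0 & runif(n_cases) < cfg$ps_prob
  ps_drug <- rep(NA_character_, n_cases)
  ps_drug[quinolone_ps] <- drugs$canonical[pick[quinolone_ps]]

  rr_case <- rep(1, n_cases)
  idx <- which(quinolone_ps)
  rr_base <- cfg$relative_risk[ps_drug[idx]]
  mod <- cfg$sex_rr_modifier[sex_true[idx]]
  mod[is.na(mod)] <- 1
  rr_case[idx] <- 1 + (rr_base - 1) * mod
  p_event <- pmin(1, cfg$base_rate * rr_case)
  event <- runif(n_cases) < p_event

  bg_drug <- sample(BACKGROUND_DRUGS, n_cases, replace = TRUE)

  ## ---- demo stream: dates, units, missingness ----------------------------
  set.seed(sub_seed(cfg$seed, "demo"))
  day0 <- as.Date("2004-01-01")
  day1 <- as.Date("2024-12-31")
  fda_date0 <- day0 + floor(runif(n_cases) * as.numeric(day1 - day0 + 1))
  start_date <- fda_date0 - floor(runif(n_cases, 60, 420))
  lat_days <- pmax(0, round(rlnorm(n_cases, cfg$latency_model$meanlog,
                                   cfg$latency_model$sdlog)))
  event_date <- start_date + lat_days

  age_cod <- sample(c("YR", "DEC", "MON", "DY"), n_cases, replace = TRUE,
                    prob = c(0.90, 0.05, 0.03, 0.02))
  age_val <- ifelse(age_cod == "YR", age_years,
             ifelse(age_cod == "DEC", round(age_years / 10, 1),
             ifelse(age_cod == "MON", age_years * 12, age_years * 365)))
  wt_cod <- sample(c("KG", "LBS"), n_cases, replace = TRUE, prob = c(0.8, 0.2))
  wt_val <- ifelse(wt_cod == "KG", weight_kg,
                   round(weight_kg / 0.45359237, 1))

  u_sex <- runif(n_cases); u_age <- runif(n_cases)
  u_wt <- runif(n_cases); u_occ <- runif(n_cases); u_evt <- runif(n_cases)
  sex_rec <- blank_if(sex_true, u_sex, cfg$missingness$sex)
  age_rec <- blank_if(as.character(age_val), u_age, cfg$missingness$age)
  age_cod_rec <- blank_if(age_cod, u_age, cfg$missingness$age)
  wt_rec <- blank_if(as.character(wt_val), u_wt, cfg$missingness$weight)
  wt_cod_rec <- blank_if(wt_cod, u_wt, cfg$missingness$weight)
  occ_rec <- blank_if(occp, u_occ, cfg$missingness$occupation)
  evt_rec <- blank_if(date_to_faers(event_date), u_evt,
                      cfg$missingness$event_dt)
  out_rec <- outcome
  out_rec[out_rec == "NS"] <- ""

  ## ---- expand cases to versions ------------------------------------------
  case_of_version <- rep.int(seq_len(n_cases), k)
  vidx <- sequence(k)                     # 1..k within case
  is_last <- vidx == rep.int(k, k)
  # receipt dates strictly increase across versions of a case
  vdelay <- ifelse(vidx == 1L, 0, floor(runif(n_versions, 1, 180)))
  ord_tmp <- order(case_of_version, vidx)
  vdelay_cum <- ave(vdelay[ord_tmp], case_of_version[ord_tmp], FUN = cumsum)
  vdelay[ord_tmp] <- vdelay_cum
  fda_date_v <- fda_date0[case_of_version] + vdelay

  sex_v <- sex_rec[case_of_version]
  age_v <- age_rec[case_of_version]
  age_cod_v <- age_cod_rec[case_of_version]
  # earlier versions may carry stale (blank) demographics; last one is truth
  stale <- !is_last & runif(n_versions) < 0.3
  sex_v[stale] <- ""
  age_v[stale] <- ""
  age_cod_v[stale] <- ""

  # primaryid ordering consistent with receipt date within each case
  ord <- order(fda_date_v, case_of_version, vidx)
  primaryid <- integer(n_versions)
  primaryid[ord] <- 100000000L + seq_len(n_versions)
  caseid <- as.character(60000000L + case_of_version)

  demo <- tibble::tibble(
    primaryid = as.character(primaryid),
    caseid = caseid,
    fda_dt = date_to_faers(fda_date_v),
    event_dt = evt_rec[case_of_version],
    sex = sex_v,
    age = age_v,
    age_cod = age_cod_v,
    wt = wt_rec[case_of_version],
    wt_cod = wt_cod_rec[case_of_version],
    occp_cod = occ_rec[case_of_version],
    occr_country = region[case_of_version],
    outc_cod = out_rec[case_of_version]
  )

  ## ---- drug stream: per-case drug lists, synonyms ------------------------
  set.seed(sub_seed(cfg$seed, "drug"))
  dr_case <- integer(0); dr_name <- character(0); dr_role <- character(0)
  for (j in seq_len(nd)) {
    cj <- which(expo[, j])
    if (!length(cj)) next
    syns <- c(drugs$canonical[j], drugs$synonyms[[j]])
    nm <- syns[sample.int(length(syns), length(cj), replace = TRUE)]
    role <- ifelse(!is.na(pick[cj]) & pick[cj] == j & quinolone_ps[cj],
                   "PS", sample(c("SS", "C"), length(cj), replace = TRUE))
    dr_case <- c(dr_case, cj); dr_name <- c(dr_name, nm)
    dr_role <- c(dr_role, role)
  }
  # one background drug per case; PS when no quinolone is primary suspect
  dr_case <- c(dr_case, seq_len(n_cases))
  dr_name <- c(dr_name, bg_drug)
  dr_role <- c(dr_role, ifelse(quinolone_ps, "C", "PS"))
  o <- order(dr_case)
  dr_case <- dr_case[o]; dr_name <- dr_name[o]; dr_role <- dr_role[o]
  m_drug <- tabulate(dr_case, nbins = n_cases)
  off_drug <- c(0L, cumsum(m_drug))[seq_len(n_cases)]
  seq_in_case <- sequence(m_drug)

  vi <- rep.int(seq_len(n_versions), m_drug[case_of_version])
  ri <- sequence(m_drug[case_of_version]) + off_drug[case_of_version[vi]]
  drug <- tibble::tibble(
    primaryid = as.character(primaryid[vi]),
    drug_seq = as.character(seq_in_case[ri]),
    role_cod = dr_role[ri],
    drugname = dr_name[ri]
  )

  ## ---- ther stream: therapy start dates ----------------------------------
  set.seed(sub_seed(cfg$seed, "ther"))
  start_case <- start_date[dr_case] + floor(runif(length(dr_case), 0, 15))
  # suspect-drug episodes anchor the latency: use the case start date exactly
  start_case[dr_role == "PS"] <- start_date[dr_case[dr_role == "PS"]]
  start_str <- date_to_faers(start_case)
  u_start <- runif(length(dr_case))
  start_str <- blank_if(start_str, u_start, cfg$missingness$start_dt)
  ther <- tibble::tibble(
    primaryid = as.character(primaryid[vi]),
    dsg_drug_seq = drug$drug_seq,
    start_dt = start_str[ri]
  )
  # occasional re-challenge: a later second episode for a PS drug row
  re <- which(dr_role[ri] == "PS" & runif(length(ri)) < 0.02 &
                start_str[ri] != "")
  if (length(re)) {
    ther2 <- tibble::tibble(
      primaryid = ther$primaryid[re],
      dsg_drug_seq = ther$dsg_drug_seq[re],
      start_dt = date_to_faers(start_case[ri[re]] +
                                 floor(runif(length(re), 30, 200)))
    )
    ther <- dplyr::bind_rows(ther, ther2)
  }

  ## ---- reac stream: preferred terms --------------------------------------
  set.seed(sub_seed(cfg$seed, "reac"))
  term <- cfg$event_term
  casing <- c(term, toupper(term), tolower(term))
  ev_cases <- which(event)
  nonev_cases <- which(!event)
  pt_ev <- casing[sample.int(3, length(ev_cases), replace = TRUE,
                             prob = c(0.7, 0.2, 0.1))]
  extra_ev <- runif(length(ev_cases)) < 0.3
  pt_bg1 <- sample(BACKGROUND_PTS, length(nonev_cases), replace = TRUE)
  rc_case <- c(ev_cases, ev_cases[extra_ev], nonev_cases)
  rc_pt <- c(pt_ev, sample(BACKGROUND_PTS, sum(extra_ev), replace = TRUE),
             pt_bg1)
  o <- order(rc_case)
  rc_case <- rc_case[o]; rc_pt <- rc_pt[o]
  m_reac <- tabulate(rc_case, nbins = n_cases)
  off_reac <- c(0L, cumsum(m_reac))[seq_len(n_cases)]
  vi_r <- rep.int(seq_len(n_versions), m_reac[case_of_version])
  ri_r <- sequence(m_reac[case_of_version]) + off_reac[case_of_version[vi_r]]
  reac <- tibble::tibble(
    primaryid = as.character(primaryid[vi_r]),
    pt = rc_pt[ri_r]
  )

  structure(
    list(demo = demo, drug = drug, reac = reac, ther = ther,
         meta = list(n_cases = n_cases, n_versions = n_versions,
                     event = event, ps_drug = ps_drug, sex_true = sex_true,
                     latency_days = lat_days, config = cfg)),
    class = "faers_tables"
  )
}

#' @export
print.faers_tables <- function(x, ...) {
  cat("FAERS-style tables:",
      nrow(x$demo), "report versions (DEMO),",
      nrow(x$drug), "drug rows,",
      nrow(x$reac), "reaction rows,",
      nrow(x$ther), "therapy rows\n")
  invisible(x)
}

#' Write FAERS-style tables as "$"-delimited quarterly ASCII files
#'
#' @param tables a `faers_tables` object (or any list with `demo`, `drug`,
#'   `reac`, `ther` data frames).
#' @param dir output directory (created if absent).
#' @return invisibly, the paths of the four files (DEMO.txt, DRUG.txt,
#'   REAC.txt, THER.txt).
#' @export
write_faers_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("DEMO.txt", "DRUG.txt", "REAC.txt", "THER.txt"))
  names(paths) <- c("demo", "drug", "reac", "ther")
  for (nm in names(paths)) {
    utils::write.table(tables[[nm]], paths[[nm]], sep = "$",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(paths)
}

#' Generate a synthetic published-case series
#'
#' Draws literature-style case reports (drug, age, sex, latency,
#' hospitalization, outcome) from configurable categorical and latency
#' distributions. This stands in for a hand-curated table of published case
#' reports when exercising the concordance module; the packaged fixture
#' `literature_cases_synthetic.csv` is a fixed instance.
#'
#' @param n number of cases (>= 1).
#' @param profile list with elements `drug` (named prob vector),
#'   `p_elderly` (probability age >= 65), `p_female`, `p_hospitalized`,
#'   `latency` (either a numeric vector sampled uniformly or a list
#'   `list(meanlog=, sdlog=)`).
#' @param seed integer seed.
#' @return tibble with columns `drug`, `age_years`, `sex`, `latency_days`,
#'   `hospitalized`, `outcome`.
#' @export
simulate_literature_cases <- function(n,
                                      profile = list(
                                        drug = c(CIPROFLOXACIN = 0.34,
                                                 LEVOFLOXACIN = 0.22,
                                                 OFLOXACIN = 0.22,
                                                 MOXIFLOXACIN = 0.11,
                                                 NORFLOXACIN = 0.11),
                                        p_elderly = 7 / 9,
                                        p_female = 5 / 9,
                                        p_hospitalized = 5 / 9,
                                        latency = list(meanlog = log(16),
                                                       sdlog = 0.5)
                                      ),
                                      seed = 1L) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop_config("n", "must be >= 1")
  }
  set.seed(sub_seed(seed, "literature"))
  drug <- sample(names(profile$drug), n, replace = TRUE, prob = profile$drug)
  elderly <- runif(n) < profile$p_elderly
  age <- ifelse(elderly, floor(runif(n, 65, 90)), floor(runif(n, 25, 64)))
  sex <- ifelse(runif(n) < profile$p_female, "F", "M")
  lat <- profile$latency
  if (is.list(lat)) {
    latency <- pmax(1, round(rlnorm(n, lat$meanlog, lat$sdlog)))
  } else {
    latency <- lat[sample.int(length(lat), n, replace = TRUE)]
  }
  hosp <- runif(n) < profile$p_hospitalized
  outcome <- ifelse(hosp, "recovered after withdrawal", "recovered")
  tibble::tibble(drug = drug, age_years = age, sex = sex,
                 latency_days = as.integer(latency), hospitalized = hosp,
                 outcome = outcome)
}
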