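# shared builders for hand-sized fixtures ------------------------------------

# minimal demo tibble; raw character columns as a quarterly file would carry
make_demo <- function(primaryid, caseid = primaryid,
                      fda_dt = "20200115", event_dt = "",
                      sex = "F", age = "70", age_cod = "YR",
                      wt = "", wt_cod = "", occp_cod = "MD",
                      occr_country = "Others", outc_cod = "HO") {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 fda_dt = fda_dt, event_dt = event_dt, sex = sex,
                 age = age, age_cod = age_cod, wt = wt, wt_cod = wt_cod,
                 occp_cod = occp_cod, occr_country = occr_country,
                 outc_cod = outc_cod)
}

make_tables <- function(demo, drug = NULL, reac = NULL, ther = NULL) {
  empty_drug <- tibble::tibble(primaryid = character(0),
                               drug_seq = character(0),
                               role_cod = character(0),
                               drugname = character(0))
  empty_reac <- tibble::tibble(primaryid = character(0), pt = character(0))
  empty_ther <- tibble::tibble(primaryid = character(0),
                               dsg_drug_seq = character(0),
                               start_dt = character(0))
  structure(list(demo = demo, drug = drug %||% empty_drug,
                 reac = reac %||% empty_reac, ther = ther %||% empty_ther),
            class = "faers_tables")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random positive-cell 2x2 tables for the property suites
random_tables <- function(n, seed, max_cell = 500) {
  set.seed(seed)
  tibble::tibble(a = sample.int(max_cell, n, replace = TRUE),
                 b = sample.int(max_cell, n, replace = TRUE),
                 c = sample.int(max_cell, n, replace = TRUE),
                 d = sample.int(max_cell, n, replace = TRUE))
}

# one simulate -> dedup -> 2x2 -> statistics replicate for a single drug
replicate_signal <- function(seed, rr_oflox = 1, dict = read_drug_dictionary(),
                             n_reports = 50000, sex_rr_modifier = c(F = 1, M = 1),
                             stratify_by = NULL) {
  cfg <- sim_config(
    n_reports = n_reports,
    relative_risk = c(CIPROFLOXACIN = 1, LEVOFLOXACIN = 1, MOXIFLOXACIN = 1,
                      NORFLOXACIN = 1, OFLOXACIN = rr_oflox),
    sex_rr_modifier = sex_rr_modifier,
    seed = seed
  )
  dd <- deduplicate_tables(normalize_tables(simulate_faers(cfg)))
  if (is.null(stratify_by)) {
    signal_stats(contingency_tables(dd, dict, drugs = "OFLOXACIN"))
  } else {
    st <- stratified_signals(dd, dict, by = stratify_by)
    st[st$drug == "OFLOXACIN", , drop = FALSE]
  }
}
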