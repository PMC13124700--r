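default_pipeline_config <- function() {
  list(
    simulate = list(n_reports = 50000, relative_risk = 1, base_rate = 0.01,
                    duplicate_fraction = 0.1),
    dictionary = NULL,   # NULL -> packaged quinolone dictionary
    event_terms = "Pemphigoid",
    literature = NULL,   # NULL -> packaged synthetic 9-case table
    stratify = c("sex", "age", "reporter")
  )
}

#' Read a pipeline configuration file
#'
#' YAML document with blocks `simulate` (fields of \code{\link{sim_config}}),
#' `dictionary` (CSV path or null for the packaged one), `event_terms`,
#' `literature` (CSV path or null) and `stratify`. Missing blocks take the
#' defaults of \code{default_pipeline_config}.
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (k in names(user)) {
    if (k == "simulate") {
      for (j in names(user$simulate)) cfg$simulate[[j]] <- user$simulate[[j]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

# order-independent cheap content hash for the manifest (no crypto intent)
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

log_stage <- function(stage, ..., quiet = FALSE) {
  if (quiet) return(invisible())
  kv <- c(...)
  msg <- paste0("stage=", stage,
                if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                  collapse = " ")))
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> ingest -> cohort -> signal -> profile ->
#' time-to-onset -> concordance from a single configuration, writing every
#' stage output as comma-separated files plus a JSON run manifest with
#' per-stage row counts and exclusion counters. A failure in any stage aborts
#' with the stage name after persisting the partial manifest.
#'
#' @param config a config list (see \code{\link{read_pipeline_config}}), a
#'   YAML path, or `NULL` for defaults.
#' @param out_dir output directory.
#' @param seed integer seed overriding the config's.
#' @param quiet suppress per-stage log lines.
#' @return the run manifest (list, class `run_manifest`), invisibly; stage
#'   outputs are also returned in its `results` element.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("pvdispro-run-"),
                         seed = 1L, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config %||% default_pipeline_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = as.character(utils::packageVersion("pvdispro")),
                   seed = as.integer(seed), config_hash = config_hash(cfg),
                   started = format(Sys.time(), tz = "UTC"), stages = list())
  persist <- function() {
    jsonlite::write_json(manifest[setdiff(names(manifest), "results")],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      persist()
      stop(sprintf("pipeline stage \"%s\" failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  }

  ## simulate ---------------------------------------------------------------
  raw <- stage("simulate", function() {
    sim_args <- cfg$simulate %||% list()
    sim_args$seed <- seed
    if (!is.null(sim_args$relative_risk) &&
        is.list(sim_args$relative_risk)) {
      sim_args$relative_risk <- unlist(sim_args$relative_risk)
    }
    sc <- do.call(sim_config, sim_args)
    tabs <- simulate_faers(sc)
    write_faers_tables(tabs, file.path(out_dir, "raw"))
    tabs
  })
  manifest$stages$simulate <- list(status = "ok",
                                   rows_out = nrow(raw$demo))
  log_stage("simulate", c(versions = nrow(raw$demo)), quiet = quiet)

  ## ingest: normalize + deduplicate ---------------------------------------
  dedup <- stage("ingest", function() {
    deduplicate_tables(normalize_tables(raw))
  })
  manifest$stages$ingest <- list(status = "ok", rows_in = nrow(raw$demo),
                                 rows_out = nrow(dedup$demo))
  log_stage("ingest", c(cases = nrow(dedup$demo)), quiet = quiet)

  dict <- if (is.null(cfg$dictionary)) read_drug_dictionary() else
    read_drug_dictionary(cfg$dictionary)
  events <- event_terms(cfg$event_terms %||% "Pemphigoid")

  ## cohort -----------------------------------------------------------------
  cohort <- stage("cohort", function() {
    co <- build_cohort(dedup, dict, events)
    utils::write.csv(
      dplyr::mutate(co, start_date_min = as.character(co$start_date_min),
                    fda_date = as.character(co$fda_date),
                    event_date = as.character(co$event_date)),
      file.path(out_dir, "cohort.csv"), row.names = FALSE)
    co
  })
  manifest$stages$cohort <- list(status = "ok", rows_in = nrow(dedup$demo),
                                 rows_out = nrow(cohort))
  log_stage("cohort", c(rows = nrow(cohort)), quiet = quiet)

  ## signal -----------------------------------------------------------------
  signals <- stage("signal", function() {
    st <- signal_stats(contingency_tables(dedup, dict, events))
    utils::write.csv(st, file.path(out_dir, "signals.csv"),
                     row.names = FALSE)
    utils::write.csv(forest_table(st), file.path(out_dir, "forest.csv"),
                     row.names = FALSE)
    st
  })
  strat <- stage("signal_stratified", function() {
    out <- lapply(cfg$stratify %||% character(0), function(by) {
      s <- stratified_signals(dedup, dict, events, by = by)
      s$stratified_by <- by
      s
    })
    s <- dplyr::bind_rows(out)
    if (nrow(s)) {
      utils::write.csv(s, file.path(out_dir, "signals_stratified.csv"),
                       row.names = FALSE)
    }
    s
  })
  manifest$stages$signal <- list(status = "ok", drugs = nrow(signals),
                                 strata_rows = nrow(strat))
  log_stage("signal", c(drugs = nrow(signals),
                        signals = sum(signals$any_signal)), quiet = quiet)

  ## profile ----------------------------------------------------------------
  prof <- stage("profile", function() {
    p <- profile_cohort(cohort)
    utils::write.csv(p, file.path(out_dir, "profile.csv"), row.names = FALSE)
    utils::write.csv(yearly_counts(cohort),
                     file.path(out_dir, "yearly_counts.csv"),
                     row.names = FALSE)
    p
  })
  manifest$stages$profile <- list(status = "ok", rows_out = nrow(prof))
  log_stage("profile", c(rows = nrow(prof)), quiet = quiet)

  ## time-to-onset ----------------------------------------------------------
  tto <- stage("tto", function() {
    rec <- compute_latency(cohort)
    summ <- tto_summary_all(rec)
    utils::write.csv(summ, file.path(out_dir, "tto.csv"), row.names = FALSE)
    list(records = rec, summary = summ)
  })
  excl <- attr(tto$records, "exclusions")
  manifest$stages$tto <- list(status = "ok", rows_in = nrow(cohort),
                              rows_out = nrow(tto$records),
                              exclusions = as.list(excl))
  log_stage("tto", c(records = nrow(tto$records)), quiet = quiet)

  ## concordance ------------------------------------------------------------
  conc <- stage("concordance", function() {
    lit <- if (is.null(cfg$literature)) read_literature_cases() else
      read_literature_cases(cfg$literature)
    cc <- concordance(summarize_literature(lit),
                      faers_summary(cohort, tto$records))
    utils::write.csv(cc, file.path(out_dir, "concordance.csv"),
                     row.names = FALSE)
    cc
  })
  manifest$stages$concordance <- list(status = "ok", rows_out = nrow(conc))
  log_stage("concordance", c(rows = nrow(conc)), quiet = quiet)

  manifest$finished <- format(Sys.time(), tz = "UTC")
  persist()
  manifest$results <- list(signals = signals, stratified = strat,
                           profile = prof, tto = tto$summary,
                           concordance = conc, cohort_rows = nrow(cohort))
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pvdispro run manifest (seed", x$seed, ", config", x$config_hash,
      ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                paste(names(s), unlist(lapply(s, paste, collapse = ",")),
                      sep = "=", collapse = " ")))
  }
  invisible(x)
}
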