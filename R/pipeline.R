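#' Configuration of an end-to-end synthetic screen
#'
#' Bundles per-stage configurations with the screen-wide thresholds: the
#' regulation-score cutoff (1.5 standardized units), the FDR level (0.05),
#' the consensus requirement (3 sources), the hit-list depth (top 50) and
#' the lifespan-extension filter (5%). All randomness flows from the single
#' root `seed`, split deterministically per stage.
#'
#' @param cohort a [cohort_config()].
#' @param drugs a [drug_library_config()].
#' @param reporter a [reporter_config()].
#' @param z_threshold regulation-score cutoff.
#' @param alpha FDR level.
#' @param min_sources consensus source minimum.
#' @param k hit-list depth.
#' @param min_extension_pct lifespan filter threshold (percent).
#' @param n_null null gene sets per regulation score.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       drugs = drug_library_config(),
                       reporter = reporter_config(),
                       z_threshold = 1.5, alpha = 0.05, min_sources = 3,
                       k = 50, min_extension_pct = 5.0, n_null = 1000,
                       seed = 1L) {
  stopifnot(z_threshold > 0, alpha > 0, min_sources >= 1, k >= 1)
  seed <- as.integer(seed)
  # derived stage seeds stay below 2^31
  stage_seed <- function(offset) (seed * 1000L + offset) %% .Machine$integer.max
  cohort$seed <- stage_seed(1L)
  drugs$seed <- stage_seed(2L)
  reporter$seed <- stage_seed(3L)
  structure(list(cohort = cohort, drugs = drugs, reporter = reporter,
                 z_threshold = z_threshold, alpha = alpha,
                 min_sources = min_sources, k = k,
                 min_extension_pct = min_extension_pct,
                 n_null = n_null, seed = seed),
            class = "run_config")
}

#' Run the full synthetic screen end to end
#'
#' Stages: simulate cohorts -> per-tissue age associations -> matrisome
#' filter -> multi-source consensus (aged) signature -> inversion and split
#' -> simulated drug library -> regulation scores and classification ->
#' per-half concordance and top-k lists -> hit compendium and lifespan
#' enrichment -> reporter dose selection. All tabular artifacts are written
#' under `out_dir` (TSV/CSV/JSON) together with the effective config and
#' its hash; re-running with the same config reproduces the numbers.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; created if missing. `NULL` skips file
#'   output.
#' @return A `run_report` list with elements `signature`, `classification`,
#'   `hits`, `enrichment`, `reporter`, `truth`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config))

  sim <- simulate_cohort(config$cohort)
  assocs <- lapply(sim$cohorts, function(co) {
    filter_matrisome(compute_age_change(co, alpha = config$alpha),
                     sim$collection)
  })
  sources <- lapply(assocs, associations_to_source)
  aged <- build_compendium(sources, min_sources = config$min_sources)
  if (!nrow(aged$entries)) stop("stage signature: empty consensus signature")
  youthful <- invert_signature(aged)
  halves <- split_signature(aged)

  lib <- simulate_drug_library(config$drugs, aged)
  reg <- regulation_scores(lib$profiles,
                           matrisome = matrisome_genes(sim$collection),
                           n_null = config$n_null,
                           seed = config$drugs$seed)
  classification <- classify_matrisome_response(reg,
                                                threshold = config$z_threshold)

  lists <- list()
  for (half in names(halves)) {
    if (!length(halves[[half]])) next
    cs <- concordance_scores(lib$profiles, halves[[half]], half = half)
    for (mode in c("reversed", "potentiated")) {
      lists[[paste(half, mode, sep = ".")]] <-
        top_k(cs[cs$mode == mode, ], k = config$k)
    }
  }
  hits <- compile_hit_sets(lists)
  flagged <- lib$profiles$annotations
  n_hit_flagged <- sum(flagged$lifespan_reported[
    flagged$compound %in% hits$unique])
  enrichment <- enrichment_stats(n_hit_flagged, hits$n_unique,
                                 sum(flagged$lifespan_reported),
                                 nrow(flagged))

  rep_sim <- simulate_reporter(config$reporter)
  rep_dr <- dose_response(rep_sim$trajectories, alpha = config$alpha)
  day_means <- tapply(
    rep_sim$trajectories$intensity[rep_sim$trajectories$drug == "control"],
    rep_sim$trajectories$day[rep_sim$trajectories$drug == "control"], mean)
  decline <- fit_decline(as.numeric(day_means),
                         as.numeric(names(day_means)))

  report <- structure(list(
    signature = aged, youthful = youthful,
    classification = classification,
    regulation = reg, concordance_lists = lists, hits = hits,
    enrichment = enrichment,
    reporter = list(dose_response = rep_dr, decline = decline),
    truth = list(cohort = sim$truth, drugs = lib$truth,
                 reporter = rep_sim$truth),
    config = config, config_hash = hash), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("matreoscreen run", x$config_hash, "\n")
  print(x$signature)
  tab <- table(x$classification$classification)
  cat(sprintf("regulation classes: %s\n",
              paste(names(tab), tab, sep = "=", collapse = " ")))
  cat(sprintf("hits: %d unique (%d list entries, overlap %d); lifespan %s%% vs background %s%%\n",
              x$hits$n_unique, x$hits$n_total_entries, x$hits$overlap_count,
              x$enrichment$pct_hit_display, x$enrichment$pct_bg_display))
  cat(sprintf("reporter: selected dose %s, control slope %.3f/day\n",
              format(x$reporter$dose_response$selected_dose),
              x$reporter$decline$slope))
  invisible(x)
}

# Serialise every report artifact under out_dir; each file carries the
# config hash either in a column (TSV/CSV) or in the JSON body.
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- report$config_hash
  stamp <- function(df) { df$config_hash <- hash; df }
  write_signature(report$signature, file.path(out_dir, "signature_aged.tsv"))
  write_signature(report$youthful,
                  file.path(out_dir, "signature_youthful.tsv"))
  utils::write.csv(stamp(report$classification),
                   file.path(out_dir, "regulation_scores.csv"),
                   row.names = FALSE)
  for (nm in names(report$concordance_lists)) {
    utils::write.csv(stamp(report$concordance_lists[[nm]]),
                     file.path(out_dir, paste0("hits_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(stamp(report$reporter$dose_response$table),
                   file.path(out_dir, "dose_response.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash,
         unique_hits = report$hits$unique,
         overlap_count = report$hits$overlap_count,
         n_unique = report$hits$n_unique,
         enrichment = report$enrichment,
         decline = report$reporter$decline,
         selected_dose = report$reporter$dose_response$selected_dose,
         config = unclass(report$config)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, na = "null")
  invisible(out_dir)
}
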