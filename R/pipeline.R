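#' Pipeline configuration
#'
#' @param climate_dialect `"terraclimate"` (VPD provided) or `"cru"`
#'   (VPD derived from temperature and humidity).
#' @param w_variant Which W populates the analysis column: `"simple"`
#'   (two-term discrimination) or `"corrected"`
#'   (mesophyll/photorespiration). Default `"simple"`.
#' @param window Analysis window, integer years. Default 1965:2015.
#' @param ai_cutoff Exclusion cutoff: observations with AI above it are
#'   dropped. Default 5.
#' @param zone_subset `"world"` or one of the deposition zones.
#' @param covariate_family Climate covariates offered to the model search:
#'   `"AI"`, `"P+PET"` or `"VPD"`.
#' @param max_power Maximum polynomial degree in the model search. Default 3.
#' @param pet_co2_adjust Apply the CO2 adjustment to PET before computing AI.
#' @param n_boot Bootstrap replicates for the breakpoint CI. Default 500.
#' @param profile Synthetic-data profile when the pipeline simulates its own
#'   inputs. Default `"small"`.
#' @param seed Seed for simulation and bootstrap. Default 1.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(climate_dialect = c("terraclimate", "cru"),
                            w_variant = c("simple", "corrected"),
                            window = 1965:2015,
                            ai_cutoff = 5,
                            zone_subset = c("world", "high", "mid",
                                            "low_north", "low_south"),
                            covariate_family = c("AI", "P+PET", "VPD"),
                            max_power = 3,
                            pet_co2_adjust = FALSE,
                            n_boot = 500,
                            profile = "small",
                            seed = 1) {
  stopifnot(ai_cutoff > 0)
  structure(list(climate_dialect = match.arg(climate_dialect),
                 w_variant = match.arg(w_variant),
                 window = window, ai_cutoff = ai_cutoff,
                 zone_subset = match.arg(zone_subset),
                 covariate_family = match.arg(covariate_family),
                 max_power = max_power,
                 pet_co2_adjust = isTRUE(pet_co2_adjust),
                 n_boot = n_boot, profile = profile, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Join isotope, environment and deposition tables
#'
#' Inner join on (site, year) of the W-annotated chronology, the site-year
#' environment and the cumulative-deposition table. Unmatched rows are
#' counted and logged; an empty join is an error.
#'
#' @param isotope W-annotated chronology (from [compute_wue_table()]).
#' @param environment Site-year environment table with `ai` (and optionally
#'   `precip`, `pet`, `vpd`).
#' @param deposition Cumulative-deposition table with `site_id`, `year`,
#'   `ndep_cum`.
#' @param quiet Suppress the join log message.
#' @return The joined analysis table, one row per retained tree-year, with
#'   `tree_uid` added; attribute `n_unmatched` counts dropped rows.
#' @export
join_tables <- function(isotope, environment, deposition, quiet = FALSE) {
  stopifnot(all(c("site_id", "year") %in% names(isotope)),
            all(c("site_id", "year", "ai") %in% names(environment)),
            all(c("site_id", "year", "ndep_cum") %in% names(deposition)))
  n0 <- nrow(isotope)
  out <- merge(isotope, environment, by = c("site_id", "year"))
  dep_cols <- intersect(c("site_id", "year", "ndep_cum", "partial"),
                        names(deposition))
  out <- merge(out, deposition[dep_cols], by = c("site_id", "year"))
  if (nrow(out) == 0L) stop("empty join: no (site, year) keys in common")
  n_drop <- n0 - nrow(out)
  if (!quiet)
    message("joined ", nrow(out), " observation(s); dropped ", n_drop,
            " unmatched record(s)")
  out$tree_uid <- paste(out$site_id, out$tree_id, sep = ":")
  attr(out, "n_unmatched") <- n_drop
  out[order(out$site_id, out$tree_id, out$year), , drop = FALSE]
}

family_candidates <- function(covariate_family) {
  switch(covariate_family,
         "AI" = c("ca", "ai", "ndep_cum"),
         "P+PET" = c("ca", "precip", "pet", "ndep_cum"),
         "VPD" = c("ca", "vpd", "ndep_cum"))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or accept) inputs, compute W, join, restrict to the
#' analysis window, exclude extreme AI, subset by deposition zone, segmented
#' W-AI fit plus AI-class summaries and grouped views, exhaustive AICc model
#' search, and relative-importance decomposition of the best model. Every
#' stage logs its record count; with the same config (and seed) the emitted
#' reports are byte-identical across runs. Input tables are never mutated.
#'
#' @param config A [pipeline_config()].
#' @param data Optional input bundle (list with `observations`, `sites`,
#'   `environment`, `ndep`, `co2`, optionally `atm_delta`, as produced by
#'   [gen_wue_dataset()]); when `NULL` a synthetic study is generated from
#'   `config$profile` and `config$seed`.
#' @param out_dir Optional directory: writes `dataset_head.csv`,
#'   `segmented.json`, `bins.csv`, `models.csv`, `importance.json`,
#'   `report.json` and `log.txt`.
#' @return list of class `"wue_report"` with elements `config`, `data`
#'   (analysis table), `n_excluded_ai`, `segmented`, `bins`, `views`,
#'   `models`, `best`, `importance`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    log <<- c(log, paste0(...))
    invisible(NULL)
  }

  if (is.null(data)) {
    gc_cfg <- generator_config(profile = config$profile, seed = config$seed)
    data <- gen_wue_dataset(gc_cfg)
    say("stage simulate: ", nrow(data$observations), " observations over ",
        nrow(data$sites), " sites")
  } else {
    say("stage input: ", nrow(data$observations), " observations supplied")
  }

  wue <- compute_wue_table(data$observations, data$co2, data$atm_delta)
  say("stage wue: ", nrow(wue), " observations annotated; ",
      sum(wue$qc_flag != "ok"), " flagged out-of-range ci/ca")

  env <- data$environment
  if (config$pet_co2_adjust) {
    ca_year <- data$co2$ca[match(env$year, data$co2$year)]
    env$pet <- pet_co2_adjust(env$pet, env$tmean, ca_year)
    env$ai <- aridity_index(env$precip, env$pet, env$site_id, env$year)
    say("stage climate: PET adjusted for CO2 before AI")
  }

  cov <- build_ndep_covariates(data$sites, data$ndep,
                               target_years = config$window)
  say("stage zones: ", nrow(cov$sites), " sites across zones [",
      paste(names(table(cov$sites$zone)), table(cov$sites$zone),
            sep = "=", collapse = ", "), "]")

  joined <- join_tables(wue, env, cov$ndep_cum, quiet = TRUE)
  say("stage join: ", nrow(joined), " rows; ",
      attr(joined, "n_unmatched"), " unmatched dropped")

  joined <- joined[joined$year %in% config$window, , drop = FALSE]
  say("stage window: ", nrow(joined), " rows in ", min(config$window), "-",
      max(config$window))

  joined$w <- joined[[paste0("w_", config$w_variant)]]
  joined <- exclude_extreme_ai(joined, config$ai_cutoff, quiet = TRUE)
  n_excluded_ai <- attr(joined, "n_removed")
  say("stage ai-exclusion: removed ", n_excluded_ai,
      " rows with AI > ", config$ai_cutoff)

  zmap <- cov$sites$zone[match(joined$site_id, cov$sites$site_id)]
  joined$zone <- zmap
  if (config$zone_subset != "world") {
    joined <- joined[joined$zone == config$zone_subset, , drop = FALSE]
    say("stage zone-subset: ", nrow(joined), " rows in zone ",
        config$zone_subset)
  }
  if (nrow(joined) == 0L) stop("stage zone-subset: no observations left")

  seg <- fit_segmented(joined$ai, joined$w, n_boot = config$n_boot,
                       seed = config$seed)
  say("stage segmented: breakpoint ",
      if (seg$identifiable) sprintf("%.4f", seg$breakpoint) else "non-identifiable",
      " on ", seg$n, " rows")

  bins <- bin_summary(joined, w_col = "w")
  say("stage bins: counts [", paste(bins$n, collapse = ", "), "] sum ",
      sum(bins$n))
  views <- list(tree = grouped_views(joined, "tree"),
                site = grouped_views(joined, "site"))

  cands <- family_candidates(config$covariate_family)
  models <- aicc_search(joined, cands, max_power = config$max_power)
  best <- attr(models, "best_fit")
  say("stage models: ", nrow(models), " candidates; best [",
      models$terms[1L], "] AICc ", sprintf("%.2f", models$aicc[1L]),
      " R2m ", sprintf("%.3f", best$r2_marginal),
      " R2c ", sprintf("%.3f", best$r2_conditional))

  imp <- relative_importance(best)
  say("stage importance: [",
      paste(names(imp), sprintf("%.3f", imp), sep = "=", collapse = ", "), "]")

  report <- structure(list(config = config, data = joined,
                           n_excluded_ai = n_excluded_ai,
                           segmented = seg, bins = bins, views = views,
                           models = models, best = best, importance = imp,
                           log = log),
                      class = "wue_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write pipeline report artifacts
#'
#' Emits delimited-text and JSON artifacts for a [run_pipeline()] report.
#' Outputs carry no timestamps, so reruns with the same config are
#' byte-identical.
#'
#' @param report A `"wue_report"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "wue_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  seg <- report$segmented
  seg_json <- list(breakpoint = seg$breakpoint,
                   breakpoint_ci = seg$breakpoint_ci,
                   slope_below = seg$slope_below, slope_above = seg$slope_above,
                   intercept = seg$intercept, p_below = seg$p_below,
                   p_above = seg$p_above, sse = seg$sse, n = seg$n,
                   identifiable = seg$identifiable)
  jsonlite::write_json(seg_json, p("segmented.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  utils::write.csv(report$bins, p("bins.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$models), p("models.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(report$importance), p("importance.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  summary_json <- list(
    n_obs = nrow(report$data),
    n_trees = length(unique(report$data$tree_uid)),
    n_excluded_ai = report$n_excluded_ai,
    w_variant = report$config$w_variant,
    covariate_family = report$config$covariate_family,
    zone_subset = report$config$zone_subset,
    seed = report$config$seed,
    best_model = report$models$terms[1L],
    r2_marginal = report$best$r2_marginal,
    r2_conditional = report$best$r2_conditional)
  jsonlite::write_json(summary_json, p("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  utils::write.csv(utils::head(report$data, 50), p("dataset_head.csv"),
                   row.names = FALSE)
  writeLines(report$log, p("log.txt"))
  invisible(vapply(c("segmented.json", "bins.csv", "models.csv",
                     "importance.json", "report.json", "dataset_head.csv",
                     "log.txt"), p, ""))
}

#' @export
print.wue_report <- function(x, ...) {
  cat("WUE analysis pipeline report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
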