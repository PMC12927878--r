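#' End-to-end analysis pipeline
#'
#' Chains the full analysis in the study's order — filter shallow
#' libraries, rarefy, diversity (alpha trend, consecutive-site partition,
#' whole-river turnover, headwater persistence), production calculus,
#' travel-time trend models, and phylotype growth — and returns a report of
#' the headline quantities. Idempotent for a fixed config and seed: every
#' random stage draws from a substream derived from the master seed by a
#' stable label.
#'
#' @param config Named list. Either `truth` (a [synthetic_truth()]) or
#'   `preset` (its name) for synthetic input, or `transect_csv`,
#'   `asv_tsv` and `sample_map_csv` paths for file input. Optional entries
#'   (defaults in parentheses): `depth` (3155), `reps` (50), `min_reads`
#'   (= depth), `seed` (1), `biomass_factor` (310), `n_head` (3),
#'   `presence_frac` (0.9), `presence_source` ("rarefied" or "raw";
#'   "rarefied"), `min_ratio` (100), `min_max_abund` (0.01),
#'   `min_prevalence` (20), `max_growth_asvs` (5), `envfit_permutations`
#'   (199), `out_dir` (NULL: nothing written).
#' @return A list of class `pipeline_report` with elements `report`
#'   (headline quantities), `production`, `diversity`, `trends`, `growth`,
#'   and the resolved `config`.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- list(depth = 3155, reps = 50L, seed = 1L, biomass_factor = 310,
                   n_head = 3L, presence_frac = 0.9,
                   presence_source = "rarefied",
                   min_ratio = 100, min_max_abund = 0.01, min_prevalence = 20L,
                   max_growth_asvs = 5L, envfit_permutations = 199L,
                   out_dir = NULL)
  defaults[names(config)] <- config
  cfg <- defaults
  if (is.null(cfg$min_reads)) cfg$min_reads <- cfg$depth

  # --- inputs ---------------------------------------------------------------
  if (!is.null(cfg$truth) || !is.null(cfg$preset)) {
    truth <- if (!is.null(cfg$truth)) cfg$truth else
      synthetic_truth(cfg$preset, seed = cfg$seed)
    transect <- generate_transect(truth)
    table <- generate_asv_table(truth, transect)
  } else {
    for (p in c("transect_csv", "asv_tsv", "sample_map_csv"))
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        stop("config error: missing input `", p, "`", call. = FALSE)
    transect <- read_transect_csv(cfg$transect_csv)
    table <- read_asv_table(cfg$asv_tsv, cfg$sample_map_csv)
    truth <- NULL
  }

  # --- production calculus --------------------------------------------------
  prod <- production_profile(transect, factor = cfg$biomass_factor)

  # --- rarefaction and diversity -------------------------------------------
  filtered <- drop_shallow(table, cfg$min_reads)
  rarefied <- rarefy(filtered, depth = cfg$depth, reps = cfg$reps,
                     seed = derive_seed(cfg$seed, "stage/rarefy"))
  richness <- observed_asvs(rarefied)
  tt <- transect$tt_cum
  site_samples <- .site_samples(rarefied, transect)
  richness_by_site <- richness[site_samples]

  consec <- consecutive_series(rarefied, transect, metric = "partition")
  wrt_end <- whole_river_turnover(rarefied, transect, method = "endpoints")
  wrt_multi <- whole_river_turnover(rarefied, transect, method = "multisite")
  pers_tab <- if (cfg$presence_source == "raw") table else rarefied
  persistence <- headwater_persistence(pers_tab, transect,
                                       n_head = cfg$n_head,
                                       presence_frac = cfg$presence_frac)

  # --- trend models ---------------------------------------------------------
  richness_fit <- fit_linear(tt, richness_by_site,
                             xname = "tt_cum_h", yname = "observed_asvs")
  tcc_fit <- fit_linear(tt, transect$sites$tcc,
                        xname = "tt_cum_h", yname = "tcc")
  bspc_fit <- fit_linear(tt, prod$sites$bsp_c,
                         xname = "tt_cum_h", yname = "bsp_c")
  rel <- relative_abundance(rarefied)
  D <- vegan::vegdist(t(rel), method = "bray")
  ord <- ordinate(D, k = 2L, method = "pcoa")
  envfit_tt <- vector_fit(ord, tt[match(colnames(rel), site_samples)],
                          permutations = cfg$envfit_permutations,
                          seed = derive_seed(cfg$seed, "stage/envfit"))

  # --- phylotype growth -----------------------------------------------------
  selected <- suppressWarnings(
    select_asvs(rel, min_ratio = cfg$min_ratio,
                min_max_abund = cfg$min_max_abund,
                min_prevalence = cfg$min_prevalence))
  growth <- NULL
  if (length(selected) > 0) {
    top <- selected[order(apply(rel[selected, , drop = FALSE], 1L, max),
                          decreasing = TRUE)]
    top <- utils::head(top, cfg$max_growth_asvs)
    tcc_by_sample <- transect$sites$tcc[match(colnames(rel), site_samples)]
    rows <- lapply(top, function(id) {
      abund <- absolute_abundance(rel[id, ], tcc_by_sample)
      sf <- fit_smoother(tt[match(colnames(rel), site_samples)], abund,
                         asv_id = id)
      mc <- max_change(derivative_series(sf))
      data.frame(asv_id = id, max_increase = mc$max_increase,
                 max_decrease = mc$max_decrease,
                 tt_increase = mc$tt_increase, tt_decrease = mc$tt_decrease,
                 peak_abundance = max(sf$fitted),
                 stringsAsFactors = FALSE)
    })
    growth <- do.call(rbind, rows)
  }

  report <- list(
    seed = cfg$seed,
    n_sites = nrow(transect$sites),
    tt_total_days = prod$totals$tt_total_days,
    median_cd_daily = prod$totals$median_cd_daily,
    median_doubling_time_days = prod$totals$median_doubling_time,
    cumulative_divisions = prod$totals$cumulative_divisions,
    cp_tot = prod$totals$cp_tot,
    standing_stock_ratio = prod$totals$standing_stock_ratio,
    turnover_endpoints = wrt_end$turnover,
    turnover_contribution_pct = wrt_end$percent_contribution,
    turnover_multisite = wrt_multi$turnover,
    persistence_fraction = persistence$fraction,
    richness_slope_per_h = richness_fit$terms$estimate[1L],
    richness_slope_se = richness_fit$terms$se[1L],
    tcc_slope_per_h = tcc_fit$terms$estimate[1L],
    tcc_slope_se = tcc_fit$terms$se[1L],
    bsp_c_atoms_per_h2 = production_to_atoms(bspc_fit$terms$estimate[1L] * 1e-15),
    envfit_tt_r2 = envfit_tt$r2,
    consecutive_turnover_median = stats::median(consec$beta_sim),
    consecutive_nestedness_median = stats::median(consec$beta_nes),
    n_growth_asvs = length(selected)
  )

  out <- structure(list(report = report, production = prod,
                        diversity = list(consecutive = consec,
                                         whole_river_endpoints = wrt_end,
                                         whole_river_multisite = wrt_multi,
                                         persistence = persistence,
                                         richness = richness_by_site),
                        trends = list(richness = richness_fit, tcc = tcc_fit,
                                      bsp_c = bspc_fit, envfit_tt = envfit_tt,
                                      ordination = ord),
                        growth = growth,
                        config = cfg),
                   class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("Pipeline report\n")
  cat(sprintf("  %d sites, %.1f travel days; median doubling time %.2f d\n",
              r$n_sites, r$tt_total_days, r$median_doubling_time_days))
  cat(sprintf("  cumulative divisions %.2f; CP_tot %.3g (%.2f x stock)\n",
              r$cumulative_divisions, r$cp_tot, r$standing_stock_ratio))
  cat(sprintf("  turnover %.3f (%.1f%% of beta); persistence %.3f\n",
              r$turnover_endpoints, r$turnover_contribution_pct,
              r$persistence_fraction))
  cat(sprintf("  richness slope %.3f +/- %.3f ASV/h\n",
              r$richness_slope_per_h, r$richness_slope_se))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the production CSVs (per-site and per-segment), the long-format
#' diversity CSV, a tidy model-registry CSV and the headline report JSON.
#' Every file name is stable; the report embeds the seed.
#'
#' @param result A `pipeline_report`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$production$sites,
                   file.path(out_dir, "production_sites.csv"),
                   row.names = FALSE)
  utils::write.csv(result$production$segments,
                   file.path(out_dir, "production_segments.csv"),
                   row.names = FALSE)
  utils::write.csv(result$diversity$consecutive,
                   file.path(out_dir, "diversity_consecutive.csv"),
                   row.names = FALSE)
  models <- do.call(rbind, lapply(names(result$trends)[1:3], function(nm) {
    m <- result$trends[[nm]]
    data.frame(model_id = nm, term = m$terms$term, estimate = m$terms$estimate,
               se = m$terms$se, p = m$terms$p, adj_r2 = m$adj_r2, n = m$n,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(models, file.path(out_dir, "model_registry.csv"),
                   row.names = FALSE)
  if (!is.null(result$growth))
    utils::write.csv(result$growth, file.path(out_dir, "growth_asvs.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Published survey summary statistics
#'
#' Loads the bundled table of published summary statistics from the two
#' whole-river Danube surveys (medians and regression slopes from the
#' survey reports), used to recompute the in-survey arithmetic chains:
#' cumulative doublings, carbon-atom conversions, standing-stock ratios and
#' the mean richness-decline rate.
#'
#' @return data.frame with columns `survey`, `quantity`, `value`, `unit`.
#' @export
survey_summary <- function() {
  path <- system.file("extdata", "danube_survey_summary.csv",
                      package = "rivermacro", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
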