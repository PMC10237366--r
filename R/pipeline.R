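# End-to-end orchestration: simulate (or ingest) -> clean -> niche models
# (neutral + constrained) -> hexagonal PAM -> clustering & cross-season
# stability -> Schoener's D statistics -> grade-of-membership motifs.

#' Pipeline configuration
#'
#' Defaults follow the study settings: 75% MVE inclusion, 70/50/30 tier
#' thresholds at breakpoints 10/40, thirds stability bands with minimum
#' cluster size 5, grade-of-membership K from 2 to 14 with tolerance 0.1 and
#' 10 restarts, and 500 random subsamples for the migrant comparison.
#'
#' @param sim a [sim_config()] describing the synthetic study system
#' @param tau MVE data-inclusion proportion
#' @param tier a [tier_rule()]
#' @param hex_area_km2 hexagon area
#' @param months months retained (June and December)
#' @param min_dist_km thinning distance
#' @param n_min minimum records per species-season
#' @param k_max largest K screened by the gap statistic
#' @param gap_B gap-statistic reference sets
#' @param gom_k K range for the motif series
#' @param gom_tol,gom_starts grade-of-membership EM settings
#' @param n_null randomized-null draws
#' @param n_subsamples random subsets for the migrant comparison
#' @param min_cluster_size minimum shared species to classify a cluster
#' @param modes model modes to run
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(), tau = 0.75,
                            tier = tier_rule(), hex_area_km2 = 164.8,
                            months = c(6L, 12L), min_dist_km = 1.0,
                            n_min = 10L, k_max = 10L, gap_B = 50L,
                            gom_k = 2:14, gom_tol = 0.1, gom_starts = 10L,
                            n_null = 1000L, n_subsamples = 500L,
                            min_cluster_size = 5L,
                            modes = c("neutral", "constrained")) {
  stopifnot(inherits(sim, "sim_config"), inherits(tier, "tier_rule"),
            tau > 0.5, tau <= 1, all(modes %in% c("neutral", "constrained")))
  structure(list(sim = sim, tau = tau, tier = tier,
                 hex_area_km2 = hex_area_km2, months = as.integer(months),
                 min_dist_km = min_dist_km, n_min = as.integer(n_min),
                 k_max = as.integer(k_max), gap_B = as.integer(gap_B),
                 gom_k = as.integer(gom_k), gom_tol = gom_tol,
                 gom_starts = as.integer(gom_starts),
                 n_null = as.integer(n_null),
                 n_subsamples = as.integer(n_subsamples),
                 min_cluster_size = as.integer(min_cluster_size),
                 modes = modes, seed = sim$seed),
            class = "pipeline_config")
}

fit_season_models <- function(cleaned, stack, regions, tau) {
  seasons <- c("6" = "june", "12" = "december")
  models <- list(june = list(), december = list())
  surfaces <- list(june = list(), december = list())
  binaries <- list(june = list(), december = list())
  slopes <- list(june = list(), december = list())
  skipped <- character()
  for (mkey in names(cleaned)) {
    season <- seasons[[mkey]]
    occ <- cleaned[[mkey]]$occurrences
    for (sp in sort(unique(occ$species))) {
      pts <- occ[occ$species == sp, , drop = FALSE]
      fit <- tryCatch({
        vals <- extract_env_values(pts, stack)
        fit_mve(vals, tau = tau, species_id = sp, season = season)
      }, error = function(e) {
        message(sprintf("skipping %s/%s: %s", sp, season, conditionMessage(e)))
        NULL
      })
      if (is.null(fit)) { skipped <- c(skipped, paste0(sp, "/", season)); next }
      models[[season]][[sp]] <- fit
      surfaces[[season]][[sp]] <- suitability_surface(fit, stack)
      binaries[[season]][[sp]] <- binarize_sdm(fit, stack)
      slopes[[season]][[sp]] <- assign_slopes(pts, regions)
    }
  }
  list(models = models, surfaces = surfaces, binaries = binaries,
       slopes = slopes, skipped = skipped)
}

clip_mode <- function(rasters, slopes, regions, mode) {
  out <- lapply(names(rasters), function(sp)
    clip_to_region(rasters[[sp]], regions, mode = mode,
                   slopes = if (mode == "constrained") slopes[[sp]]))
  names(out) <- names(rasters)
  out
}

#' Run the full analysis pipeline on a synthetic study system
#'
#' Executes every stage and returns all intermediate and final artifacts;
#' when `out_dir` is given, writes the standard file layout (occurrence and
#' PAM CSVs, cluster labels, stability and overlap tables, Newick trees,
#' summary JSON).
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory
#' @return a `pipeline_result` list; see the `summary` element for headline
#'   quantities (cluster counts, category tallies, test statistics)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  sim <- simulate_study_system(config$sim)
  cleaned <- clean_occurrences(sim$occurrences, months = config$months,
                               min_dist_km = config$min_dist_km,
                               n_min = config$n_min)

  fitted <- fit_season_models(cleaned, sim$stack, sim$regions, config$tau)

  june_sp <- names(fitted$models$june)
  dec_sp <- names(fitted$models$december)
  residents <- intersect(june_sp, dec_sp)
  if (length(residents) < 4)
    stop("run_pipeline: fewer than 4 resident species survived modeling")

  grid <- build_hex_grid(sim$regions, target_area_km2 = config$hex_area_km2)
  assignment <- map_cells_to_hexagons(sim$stack$geom, grid)

  point_counts <- data.frame(
    species = residents,
    n_june = vapply(residents, function(sp)
      sum(cleaned[["6"]]$occurrences$species == sp), 0L),
    n_december = vapply(residents, function(sp)
      sum(cleaned[["12"]]$occurrences$species == sp), 0L))

  per_mode <- list()
  for (mode in config$modes) {
    bin_j <- clip_mode(fitted$binaries$june, fitted$slopes$june, sim$regions, mode)
    bin_d <- clip_mode(fitted$binaries$december, fitted$slopes$december,
                       sim$regions, mode)
    cont_j <- clip_mode(fitted$surfaces$june, fitted$slopes$june, sim$regions, mode)
    cont_d <- clip_mode(fitted$surfaces$december, fitted$slopes$december,
                        sim$regions, mode)

    pam_j <- build_pam(bin_j, grid, assignment, config$tier, "june", mode)
    pam_d <- build_pam(bin_d, grid, assignment, config$tier, "december", mode)

    # stability clustering on residents only (migrants are single-season)
    pam_j_res <- structure(unclass(pam_j)[residents, , drop = FALSE],
                           class = class(pam_j), season = "june", mode = mode)
    pam_d_res <- structure(unclass(pam_d)[residents, , drop = FALSE],
                           class = class(pam_d), season = "december", mode = mode)

    k_cap_j <- min(config$k_max, nrow(unique(unclass(pam_j_res))) - 1L)
    k_cap_d <- min(config$k_max, nrow(unique(unclass(pam_d_res))) - 1L)
    if (k_cap_j < 2 || k_cap_d < 2)
      stop("run_pipeline: too few distinct occupancy vectors to cluster")
    gap_j <- gap_statistic(pam_j_res, k_max = k_cap_j, B = config$gap_B,
                           seed = stage_seed(seed, "gap"))
    gap_d <- gap_statistic(pam_d_res, k_max = k_cap_d, B = config$gap_B,
                           seed = stage_seed(seed, "gap"))
    km_seed <- stage_seed(seed, "kmeans")
    clus_j <- kmeans_species(pam_j_res, K = max(2L, gap_j$K), seed = km_seed)
    clus_d <- kmeans_species(pam_d_res, K = max(2L, gap_d$K), seed = km_seed)

    overlaps <- cross_season_overlap(clus_j, clus_d, residents)
    stability <- classify_stability(overlaps, min_size = config$min_cluster_size)
    stability_rev <- classify_stability(overlaps, min_size = config$min_cluster_size,
                                        direction = "reverse")

    records <- overlap_table(cont_j[residents], cont_d[residents],
                             stability = stability, june_labels = clus_j$labels,
                             point_counts = point_counts, mode = mode)
    null <- randomized_null(cont_j, cont_d, n_draws = config$n_null,
                            seed = stage_seed(seed, "null"))
    welch <- observed_vs_null_test(records$D, null)
    cats <- tryCatch(category_comparisons(records),
                     error = function(e) list(note = conditionMessage(e)))
    effort <- tryCatch(effort_bias_check(records),
                       error = function(e) list(note = conditionMessage(e)))

    # migrant-related set: residents sharing a June cluster with a migrant
    # (all-species June clustering at the resident-selected K)
    migrants_june <- setdiff(june_sp, residents)
    mig_test <- NULL
    if (length(migrants_june) >= 1) {
      clus_all <- kmeans_species(pam_j, K = max(2L, gap_j$K), seed = km_seed)
      mig_clusters <- unique(clus_all$labels[migrants_june])
      mig_set <- intersect(residents,
                           names(clus_all$labels)[clus_all$labels %in% mig_clusters])
      if (length(mig_set) >= 5 && length(mig_set) < length(residents)) {
        mig_test <- migrant_subsample_test(records, mig_set,
                                           n_subsamples = config$n_subsamples,
                                           seed = stage_seed(seed, "subsample"))
      }
    }

    gom_j <- motif_series(t(unclass(pam_j)),
                          k_range = config$gom_k[config$gom_k <= nrow(pam_j)],
                          tol = config$gom_tol, n_starts = config$gom_starts,
                          seed = seed)

    per_mode[[mode]] <- list(
      pam = list(june = pam_j, december = pam_d),
      diversity = list(june = diversity_maps(pam_j),
                       december = diversity_maps(pam_d)),
      gap = list(june = gap_j, december = gap_d),
      clusters = list(june = clus_j, december = clus_d),
      upgma = upgma_tree(pam_j_res),
      overlaps = overlaps, stability = stability,
      stability_reverse = stability_rev,
      records = records, null = null, welch = welch,
      category_tests = cats, effort = effort, migrant_test = mig_test,
      binaries = list(june = bin_j, december = bin_d),
      surfaces = list(june = cont_j, december = cont_d),
      gom = gom_j)
  }

  summary <- list(
    seed = seed,
    n_species_simulated = config$sim$n_species,
    n_species_june = length(june_sp),
    n_species_december = length(dec_sp),
    n_residents = length(residents),
    n_hexagons = sum(grid$centers$keep),
    modes = lapply(per_mode, function(m) list(
      K_june = m$clusters$june$K,
      K_december = m$clusters$december$K,
      categories = as.list(table(m$stability$category)),
      mean_D = mean(m$records$D),
      welch_t = m$welch$t, welch_p = m$welch$p,
      mean_null_D = m$welch$null[["mean"]],
      fisher_p = if (!is.null(m$migrant_test)) m$migrant_test$p else NA)))

  result <- structure(list(config = config, sim = sim, cleaned = cleaned,
                           fitted = fitted, grid = grid,
                           assignment = assignment, residents = residents,
                           per_mode = per_mode, summary = summary),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_result> %d species simulated, %d residents modeled, %d hexagons\n",
              s$n_species_simulated, s$n_residents, s$n_hexagons))
  for (mode in names(s$modes)) {
    m <- s$modes[[mode]]
    cat(sprintf("  %s: K = %d (June) / %d (December); mean D = %.3f; Welch t = %.2f (p = %.3g)\n",
                mode, m$K_june, m$K_december, m$mean_D, m$welch_t, m$welch_p))
    cat("    categories:", paste(names(m$categories), unlist(m$categories),
                                 sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (mkey in names(result$cleaned))
    write.csv(result$cleaned[[mkey]]$occurrences,
              file.path(out_dir, sprintf("occurrences_month%s.csv", mkey)),
              row.names = FALSE)
  for (mode in names(result$per_mode)) {
    m <- result$per_mode[[mode]]
    for (season in c("june", "december")) {
      write.csv(as.data.frame(unclass(m$pam[[season]])),
                file.path(out_dir, sprintf("pam_%s_%s.csv", mode, season)))
      write.csv(m$diversity[[season]],
                file.path(out_dir, sprintf("diversity_%s_%s.csv", mode, season)),
                row.names = FALSE)
      labs <- m$clusters[[season]]$labels
      write.csv(data.frame(species = names(labs), season = season,
                           mode = mode, cluster = labs),
                file.path(out_dir, sprintf("clusters_%s_%s.csv", mode, season)),
                row.names = FALSE)
      write.csv(m$gap[[season]]$table,
                file.path(out_dir, sprintf("gap_curve_%s_%s.csv", mode, season)),
                row.names = FALSE)
    }
    write.csv(as.data.frame(m$stability),
              file.path(out_dir, sprintf("stability_%s.csv", mode)),
              row.names = FALSE)
    write.csv(m$records, file.path(out_dir, sprintf("overlap_records_%s.csv", mode)),
              row.names = FALSE)
    write.csv(data.frame(D = m$null$draws),
              file.path(out_dir, sprintf("null_draws_%s.csv", mode)),
              row.names = FALSE)
    ape::write.tree(m$upgma$phylo,
                    file.path(out_dir, sprintf("upgma_%s.nwk", mode)))
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
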