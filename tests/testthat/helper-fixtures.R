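# Shared fixtures, all generated in code at test time.

# small raster from a vector of values laid out in cell-id order
# (row-major from the lower-left)
tiny_raster <- function(vals, nx, ny, cell = 1, ...) {
  eco_raster(matrix(vals, ny, nx, byrow = TRUE), grid_geom(nx, ny, cell), ...)
}

# compact synthetic system for module-level tests
quick_config <- function(seed = 1, ...) {
  args <- list(grid_nx = 40, grid_ny = 40, n_layers = 4, n_species = 8,
               detection_rate = 0.8, seasonal_shift = 0.5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# species-occupancy matrix with three planted blocks of co-occurring species
make_blob_pam <- function(seed, n_per_blob = 20, n_hex = 100,
                          p_in = 0.8, p_out = 0.05) {
  set.seed(seed)
  blocks <- split(seq_len(n_hex), rep(1:3, length.out = n_hex))
  X <- do.call(rbind, lapply(1:3, function(g) {
    t(replicate(n_per_blob, {
      v <- rbinom(n_hex, 1, p_out)
      v[blocks[[g]]] <- rbinom(length(blocks[[g]]), 1, p_in)
      v
    }))
  }))
  rownames(X) <- sprintf("sp%03d", seq_len(nrow(X)))
  X
}

# fit seasonal suitability surfaces for every species of a synthetic system
# (unclipped, neutral geometry); returns june/december surface lists and the
# resident species ids observed in both seasons
fit_seasonal_surfaces <- function(cfg) {
  sim <- simulate_study_system(cfg)
  cleaned <- suppressMessages(clean_occurrences(sim$occurrences))
  seasons <- c("6" = "june", "12" = "december")
  out <- list(june = list(), december = list())
  for (mkey in names(cleaned)) {
    occ <- cleaned[[mkey]]$occurrences
    for (sp in unique(occ$species)) {
      fit <- tryCatch(suppressMessages(
        fit_mve(extract_env_values(occ[occ$species == sp, ], sim$stack),
                species_id = sp, season = seasons[[mkey]])),
        error = function(e) NULL)
      if (!is.null(fit))
        out[[seasons[[mkey]]]][[sp]] <- suitability_surface(fit, sim$stack)
    }
  }
  out$residents <- intersect(names(out$june), names(out$december))
  out$sim <- sim
  out
}
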