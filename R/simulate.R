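# Synthetic study system: smooth correlated environmental layers on a 1-km
# grid, species with known ellipsoidal niches in environment space, June vs
# December occurrence snapshots, resident/migrant status, and a ridge barrier
# splitting the domain into a "pacific" (west) and "caribbean" (east) slope.

#' Configuration for the synthetic study system
#'
#' Defaults describe the desk-scale study conditions: a 100 x 100 km domain of
#' 1-km cells, nine correlated environmental layers, and a seasonal niche
#' shift expressed in per-layer standard deviations of the environment.
#'
#' @param grid_nx,grid_ny cell counts (>= 20)
#' @param cell_size cell edge in km
#' @param n_layers number of environmental layers (>= 2)
#' @param n_species number of species (>= 2)
#' @param n_motifs_true number of latent geographic motifs the landscape is
#'   built from (used by downstream recovery checks)
#' @param seasonal_shift displacement of each resident's December niche center
#'   from its June center, in units of per-layer environmental SD (>= 0)
#' @param migrant_fraction proportion of species present in one season only
#' @param detection_rate probability a suitable cell yields an occurrence
#' @param barrier_x column index of the ridge splitting the two slopes
#'   (default: domain midline)
#' @param seed integer seed; identical configs give byte-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(grid_nx = 100, grid_ny = 100, cell_size = 1,
                       n_layers = 9, n_species = 40, n_motifs_true = 3,
                       seasonal_shift = 0.5, migrant_fraction = 0.3,
                       detection_rate = 0.5, barrier_x = NULL, seed = 1) {
  if (is.null(barrier_x)) barrier_x <- as.integer(round(grid_nx / 2))
  cfg <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              cell_size = cell_size, n_layers = as.integer(n_layers),
              n_species = as.integer(n_species),
              n_motifs_true = as.integer(n_motifs_true),
              seasonal_shift = seasonal_shift,
              migrant_fraction = migrant_fraction,
              detection_rate = detection_rate,
              barrier_x = as.integer(barrier_x), seed = as.integer(seed))
  stopifnot(cfg$grid_nx >= 20, cfg$grid_ny >= 20, cfg$n_layers >= 2,
            cfg$n_species >= 2, cfg$seasonal_shift >= 0,
            cfg$migrant_fraction >= 0, cfg$migrant_fraction <= 1,
            cfg$detection_rate > 0, cfg$detection_rate <= 1,
            cfg$barrier_x >= 1, cfg$barrier_x <= cfg$grid_nx)
  class(cfg) <- "sim_config"
  cfg
}

# Gaussian-kernel smoothed white noise: a cheap stand-in for a Gaussian
# random field with ~`width`-cell correlation length. Reflection padding
# keeps variance roughly stationary near edges.
smooth_noise_field <- function(ny, nx, width = 10) {
  half <- max(1L, as.integer(round(2 * width)))
  k <- exp(-0.5 * (seq(-half, half) / width)^2)
  k <- k / sum(k)
  pad_reflect <- function(v, h) c(rev(v[seq_len(h)]), v, rev(v[length(v) - seq_len(h) + 1L]))
  smooth_vec <- function(v) {
    p <- pad_reflect(v, half)
    as.numeric(stats::filter(p, k, sides = 2))[(half + 1L):(half + length(v))]
  }
  z <- matrix(rnorm(ny * nx), ny, nx)
  z <- apply(z, 2, smooth_vec)
  z <- t(apply(z, 1, smooth_vec))
  (z - mean(z)) / sd(z)
}

#' Generate the stack of correlated environmental layers
#'
#' Layer 1 ("elev") is a ridge peaking over the barrier column; the other
#' layers mix a few shared smooth latent fields (inducing realistic pairwise
#' correlation) with layer-specific smooth noise (keeping them short of
#' collinear). All layers are standardized to mean 0, SD 1.
#'
#' @param config a [sim_config()]
#' @return an `env_stack`: list of named [eco_raster()] layers + `geom`
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "stack"), {
    geom <- grid_geom(config$grid_nx, config$grid_ny, config$cell_size)
    ny <- geom$ny; nx <- geom$nx
    cc <- cell_centroids(geom)
    X <- matrix(cc$x, ny, nx, byrow = TRUE)
    Y <- matrix(cc$y, ny, nx, byrow = TRUE)
    Xs <- (X - mean(X)) / sd(X); Ys <- (Y - mean(Y)) / sd(Y)

    n_lat <- 3L
    latents <- replicate(n_lat, smooth_noise_field(ny, nx, 10), simplify = FALSE)

    ridge_x <- config$barrier_x * config$cell_size
    ridge <- exp(-0.5 * ((X - ridge_x) / (0.15 * nx * config$cell_size))^2)
    elev <- ridge + 0.25 * smooth_noise_field(ny, nx, 10)

    layers <- vector("list", config$n_layers)
    names(layers) <- c("elev", sprintf("env%02d", seq_len(config$n_layers))[-1])
    layers[[1]] <- (elev - mean(elev)) / sd(elev)
    for (l in seq_len(config$n_layers)[-1]) {
      trend <- rnorm(1) * Xs + rnorm(1) * Ys + rnorm(1, sd = 0.5) * Xs * Ys
      mix <- Reduce(`+`, Map(`*`, latents, rnorm(n_lat, sd = 0.6)))
      own <- smooth_noise_field(ny, nx, 10)
      f <- 0.4 * trend + mix + 0.8 * own
      layers[[l]] <- (f - mean(f)) / sd(f)
    }
    stack <- list(layers = lapply(names(layers), function(nm)
      eco_raster(layers[[nm]], geom, layer = nm)),
      geom = geom, layer_names = names(layers))
    names(stack$layers) <- names(layers)
    class(stack) <- "env_stack"
    stack
  })
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s) on a %d x %d grid\n",
              length(x$layers), paste(x$layer_names, collapse = ", "),
              x$geom$ny, x$geom$nx))
  invisible(x)
}

# all-cell environment matrix (ncell x n_layers), rows in cell-id order
env_cell_matrix <- function(stack) {
  m <- vapply(stack$layers, raster_values_vec,
              numeric(stack$geom$nx * stack$geom$ny))
  colnames(m) <- stack$layer_names
  m
}

#' Draw ground-truth niches for every species
#'
#' June centers are the environment at randomly chosen cells (guaranteeing
#' they lie within the realized environmental range); December centers of
#' residents are displaced by `seasonal_shift` SD units along a random
#' direction. Migrants receive a single season; each species gets a slope
#' label (`pacific`, `caribbean` or `both`).
#'
#' @param config a [sim_config()]
#' @param stack the stack generated from `config`
#' @return a `true_niche_set`: list of niches with fields `species_id`,
#'   `season`, `center`, `covariance`, `resident`, `slope`
#' @export
generate_true_niches <- function(config, stack) {
  stopifnot(inherits(config, "sim_config"), inherits(stack, "env_stack"))
  with_seed(stage_seed(config$seed, "niches"), {
    E <- env_cell_matrix(stack)
    cc <- cell_centroids(stack$geom)
    cell_slope <- slope_of_x(cc$x, config)
    L <- config$n_layers
    sds <- apply(E, 2, sd)
    niches <- list()
    for (s in seq_len(config$n_species)) {
      id <- sprintf("sp%03d", s)
      resident <- runif(1) >= config$migrant_fraction
      slope <- sample(c("both", "pacific", "caribbean"), 1,
                      prob = c(0.5, 0.25, 0.25))
      # slope-restricted species center on a cell of their own slope
      pool <- if (slope == "both") seq_len(nrow(E)) else which(cell_slope == slope)
      center_june <- E[pool[sample.int(length(pool), 1)], ]
      scale <- runif(1, 0.25, 0.5)
      W <- rWishart(1, df = L + 3, Sigma = diag(L))[, , 1]
      R <- cov2cor(W)
      S <- diag(scale * sds) %*% R %*% diag(scale * sds)
      dimnames(S) <- list(stack$layer_names, stack$layer_names)
      mk <- function(season, center)
        list(species_id = id, season = season, center = center,
             covariance = S, resident = resident, slope = slope)
      if (resident) {
        u <- rnorm(L); u <- u / sqrt(sum(u^2))
        center_dec <- center_june + config$seasonal_shift * u * sds
        niches <- c(niches, list(mk("june", center_june),
                                 mk("december", center_dec)))
      } else {
        season <- sample(c("june", "december"), 1)
        niches <- c(niches, list(mk(season, center_june)))
      }
    }
    structure(niches, class = "true_niche_set")
  })
}

#' @export
print.true_niche_set <- function(x, ...) {
  ids <- unique(vapply(x, `[[`, "", "species_id"))
  res <- vapply(x, `[[`, TRUE, "resident")
  cat(sprintf("<true_niche_set> %d species (%d resident), %d species-season niches\n",
              length(ids), sum(res[!duplicated(vapply(x, `[[`, "", "species_id"))]),
              length(x)))
  invisible(x)
}

month_of_season <- function(season) c(june = 6L, december = 12L)[[season]]

# slope of a point given the ridge line x = barrier_x * cell_size
slope_of_x <- function(x, config) {
  ridge <- config$barrier_x * config$cell_size
  ifelse(x < ridge, "pacific", "caribbean")
}

#' Sample occurrence records from the true niches
#'
#' A cell is suitable for a species-season niche when its squared Mahalanobis
#' distance to the true center is within the 0.95 chi-square quantile on
#' `n_layers` degrees of freedom; suitable cells on the wrong slope are
#' removed, and each remaining cell is retained with probability
#' `detection_rate`. Occurrences are placed at cell centroids.
#'
#' @param niches a [generate_true_niches()] result
#' @param stack the matching environment stack
#' @param config the [sim_config()] used throughout
#' @return an occurrence table: data.frame `species, x, y, month`
#' @export
sample_occurrences <- function(niches, stack, config) {
  stopifnot(inherits(niches, "true_niche_set"), inherits(stack, "env_stack"))
  with_seed(stage_seed(config$seed, "occurrences"), {
    E <- env_cell_matrix(stack)
    cc <- cell_centroids(stack$geom)
    cut <- qchisq(0.95, df = config$n_layers)
    out <- vector("list", length(niches))
    for (i in seq_along(niches)) {
      nic <- niches[[i]]
      m2 <- mahalanobis(E, nic$center, nic$covariance)
      keep <- which(m2 <= cut)
      if (nic$slope != "both" && length(keep)) {
        keep <- keep[slope_of_x(cc$x[keep], config) == nic$slope]
      }
      if (length(keep) && config$detection_rate < 1) {
        keep <- keep[rbinom(length(keep), 1, config$detection_rate) == 1]
      }
      if (!length(keep)) {
        warning(sprintf("species %s (%s): no suitable cells, emitting 0 rows",
                        nic$species_id, nic$season), call. = FALSE)
        out[[i]] <- data.frame(species = character(), x = numeric(),
                               y = numeric(), month = integer())
      } else {
        out[[i]] <- data.frame(species = nic$species_id,
                               x = cc$x[keep], y = cc$y[keep],
                               month = month_of_season(nic$season))
      }
    }
    occ <- do.call(rbind, out)
    rownames(occ) <- NULL
    occ
  })
}

#' Region polygons: full domain and the two slopes
#'
#' The ridge line sits at `x = barrier_x * cell_size`; the pacific slope is
#' `x <` the line and the caribbean slope `x >=` it, so the two slopes
#' partition the domain exactly.
#'
#' @param config a [sim_config()]
#' @return a `region_set`: named list of polygons (`domain`, `pacific`,
#'   `caribbean`), each an n x 2 vertex matrix
#' @export
generate_region_polygons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  W <- config$grid_nx * config$cell_size
  H <- config$grid_ny * config$cell_size
  bx <- config$barrier_x * config$cell_size
  rect <- function(x0, x1) cbind(x = c(x0, x1, x1, x0), y = c(0, 0, H, H))
  structure(list(domain = rect(0, W), pacific = rect(0, bx),
                 caribbean = rect(bx, W), ridge_x = bx),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> domain %.0f km2, pacific %.0f, caribbean %.0f (ridge at x = %g km)\n",
              polygon_area(x$domain), polygon_area(x$pacific),
              polygon_area(x$caribbean), x$ridge_x))
  invisible(x)
}

#' Generate the full synthetic bundle in one call
#'
#' @param config a [sim_config()]
#' @return list with `config`, `stack`, `niches`, `occurrences`, `regions`
#' @export
simulate_study_system <- function(config = sim_config()) {
  stack <- generate_env_stack(config)
  niches <- generate_true_niches(config, stack)
  occ <- sample_occurrences(niches, stack, config)
  regions <- generate_region_polygons(config)
  list(config = config, stack = stack, niches = niches,
       occurrences = occ, regions = regions)
}
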