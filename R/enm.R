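# Presence-only ellipsoidal niche models. A model is the ellipsoid
# m2(x) = (x - mu)' Sigma^-1 (x - mu) <= c in environment space, fitted so
# that at least ceil(tau * n) of the training points fall inside; projecting
# m2 over the raster grid gives the continuous suitability surface and the
# binary species distribution model.

#' Extract environmental values at occurrence points
#'
#' @param points occurrence table (`species, x, y, month`), one species-season
#' @param stack an `env_stack`
#' @return numeric matrix, one row per retained point, one column per layer;
#'   points outside the grid or on NODATA cells are dropped with a message
#' @export
extract_env_values <- function(points, stack) {
  stopifnot(inherits(stack, "env_stack"))
  check_occurrence_table(points)
  if (!nrow(points)) stop("extract_env_values: empty point set")
  idx <- xy_to_cell(stack$geom, points$x, points$y)
  inside <- !is.na(idx[, "ix"])
  E <- env_cell_matrix(stack)
  cell_id <- (idx[inside, "iy"] - 1L) * stack$geom$nx + idx[inside, "ix"]
  vals <- E[cell_id, , drop = FALSE]
  ok <- stats::complete.cases(vals)
  dropped <- sum(!inside) + sum(!ok)
  if (dropped > 0)
    message(sprintf("extract_env_values: dropped %d points (outside grid or NODATA)",
                    dropped))
  vals <- vals[ok, , drop = FALSE]
  if (!nrow(vals))
    stop(sprintf("extract_env_values: all points for species '%s' fall on NODATA",
                 points$species[1]))
  vals
}

unit_ball_volume <- function(d) pi^(d / 2) / gamma(d / 2 + 1)

# moment ellipsoid of a point set: mean/covariance with the cutoff at the
# farthest point, so every point is enclosed
moment_ellipsoid <- function(X) {
  mu <- colMeans(X)
  S <- cov(X)
  m2 <- mahalanobis(X, mu, S)
  list(center = mu, sigma = S, cutoff = max(m2), method = "moment")
}

# exact minimum-volume enclosing ellipsoid of X; Khachiyan when n >= 2d,
# moment form otherwise (per the fitting policy); cutoff re-tightened to the
# farthest enclosed point so coverage is exact
exact_enclosing_ellipsoid <- function(X, tol = 1e-7) {
  n <- nrow(X); d <- ncol(X)
  if (n >= 2 * d) {
    k <- khachiyan_mvee(X, tol = tol)
    sigma <- solve(k$A)
    sigma <- (sigma + t(sigma)) / 2
    m2 <- mahalanobis(X, k$center, sigma)
    list(center = as.numeric(k$center), sigma = sigma, cutoff = max(m2),
         method = "khachiyan")
  } else {
    moment_ellipsoid(X)
  }
}

ellipsoid_volume_ <- function(sigma, cutoff) {
  d <- ncol(sigma)
  unit_ball_volume(d) * sqrt(det(sigma)) * cutoff^(d / 2)
}

#' Volume of a fitted ellipsoid model
#' @param model an `ellipsoid_model`
#' @return ellipsoid volume in environment-space units
#' @export
mve_volume <- function(model) ellipsoid_volume_(model$sigma, model$cutoff)

fit_subset <- function(X, idx, tol) {
  e <- exact_enclosing_ellipsoid(X[idx, , drop = FALSE], tol = tol)
  e$volume <- ellipsoid_volume_(e$sigma, e$cutoff)
  e$idx <- idx
  e
}

#' Fit a minimum-volume ellipsoid niche model
#'
#' With `tau < 1` the training subset holding `ceiling(tau * n)` points is
#' found exactly — enumerating every subset — whenever the number of subsets
#' is at most `exhaustive_cap`; otherwise by iterative trimming (fit an
#' enclosing ellipsoid, keep the `ceiling(tau * n)` points closest in squared
#' Mahalanobis distance, refit to a fixed point, at most `max_rounds`
#' rounds), followed for `n <= swap_refine_max` by a deterministic local
#' search swapping kept against dropped points while the volume shrinks.
#' The exact enclosing ellipsoid of a subset uses Khachiyan's algorithm
#' (moment ellipsoid when `n < 2d`).
#'
#' @param values n x d matrix of environmental values (duplicates removed)
#' @param tau data-inclusion proportion in (0.5, 1], default 0.75
#' @param tol Khachiyan convergence tolerance
#' @param max_rounds trimming iteration cap
#' @param swap_refine_max largest n for which swap refinement runs
#' @param exhaustive_cap largest subset count for which the search is exact
#' @param species_id,season optional provenance
#' @return an `ellipsoid_model` with fields `center`, `sigma`, `cutoff`,
#'   `tau`, `n_train`, `n_kept`, `method`, `layers`, `kept` (row indices)
#' @export
fit_mve <- function(values, tau = 0.75, tol = 1e-7, max_rounds = 20L,
                    swap_refine_max = 60L, exhaustive_cap = 5e4,
                    species_id = NA_character_, season = NA_character_) {
  stopifnot(is.matrix(values), tau > 0.5, tau <= 1)
  X <- unique(values)
  n <- nrow(X); d <- ncol(X)
  if (n < d + 1)
    stop(sprintf("insufficient records for MVE: %d distinct points for %d layers (need >= %d)",
                 n, d, d + 1))
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("singular covariance: degenerate layer(s) ",
         paste(colnames(X)[sds == 0], collapse = ", "))

  m <- ceiling(tau * n)
  idx <- seq_len(n)
  fit <- fit_subset(X, idx, tol)
  if (m < n) {
    if (m >= 2 * d && choose(n, m) <= exhaustive_cap) {
      best <- mvee_best_subset(X, m, tol = tol)
      fit <- fit_subset(X, sort(best), tol)
      fit$search <- "exhaustive"
    } else {
      for (round in seq_len(max_rounds)) {
        m2 <- mahalanobis(X, fit$center, fit$sigma)
        new_idx <- sort(order(m2)[seq_len(m)])
        if (identical(new_idx, fit$idx)) break
        fit <- fit_subset(X, new_idx, tol)
      }
      if (n <= swap_refine_max) fit <- swap_refine(X, fit, tol)
      fit$search <- "trim"
    }
  } else fit$search <- "full"

  structure(list(center = fit$center, sigma = fit$sigma, cutoff = fit$cutoff,
                 tau = tau, n_train = n, n_kept = length(fit$idx),
                 method = fit$method, search = fit$search,
                 layers = colnames(values),
                 kept = fit$idx, species_id = species_id, season = season),
            class = "ellipsoid_model")
}

# deterministic local search: swap kept/dropped pairs while volume decreases
swap_refine <- function(X, fit, tol, max_passes = 10L) {
  n <- nrow(X)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    dropped <- setdiff(seq_len(n), fit$idx)
    for (out_i in fit$idx) {
      for (in_j in dropped) {
        cand_idx <- sort(c(setdiff(fit$idx, out_i), in_j))
        cand <- tryCatch(fit_subset(X, cand_idx, tol), error = function(e) NULL)
        if (!is.null(cand) && cand$volume < fit$volume * (1 - 1e-9)) {
          fit <- cand
          improved <- TRUE
          dropped <- setdiff(seq_len(n), fit$idx)
          break
        }
      }
    }
    if (!improved) break
  }
  fit
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat(sprintf("<ellipsoid_model> %s/%s: d=%d, n=%d, kept=%d (tau=%.2f), cutoff=%.3f, %s\n",
              x$species_id, x$season, length(x$center), x$n_train, x$n_kept,
              x$tau, x$cutoff, x$method))
  invisible(x)
}

model_m2_surface <- function(model, stack) {
  missing <- setdiff(model$layers, stack$layer_names)
  if (length(missing))
    stop("stack is missing model layers: ", paste(missing, collapse = ", "))
  E <- env_cell_matrix(stack)[, model$layers, drop = FALSE]
  m2 <- rep(NA_real_, nrow(E))
  ok <- stats::complete.cases(E)
  if (any(ok)) m2[ok] <- mahalanobis(E[ok, , drop = FALSE], model$center, model$sigma)
  matrix(m2, stack$geom$ny, stack$geom$nx, byrow = TRUE)
}

#' Continuous suitability surface of a fitted model
#'
#' Cell value is `exp(-m2/2)` rescaled so the maximum over valid cells is 1 —
#' a strictly decreasing function of the squared Mahalanobis distance.
#'
#' @param model an `ellipsoid_model`
#' @param stack an `env_stack` whose layers cover the model's
#' @return a `suitability_raster` ([eco_raster()] with values in \[0, 1\])
#' @export
suitability_surface <- function(model, stack) {
  m2 <- model_m2_surface(model, stack)
  if (all(is.na(m2))) return(eco_raster(m2, stack$geom,
                                        species = model$species_id,
                                        season = model$season, type = "cont"))
  s <- exp(-m2 / 2)
  s <- s / max(s, na.rm = TRUE)
  eco_raster(s, stack$geom, species = model$species_id,
             season = model$season, type = "cont")
}

#' Binary species distribution model
#'
#' Cell is 1 iff the squared Mahalanobis distance of its environment to the
#' model center is within the fitted cutoff.
#'
#' @inheritParams suitability_surface
#' @return a binary [eco_raster()] (values 0/1, NODATA = `NA`)
#' @export
binarize_sdm <- function(model, stack) {
  m2 <- model_m2_surface(model, stack)
  b <- ifelse(m2 <= model$cutoff, 1, 0)
  eco_raster(b, stack$geom, species = model$species_id,
             season = model$season, type = "bin")
}

#' Slopes occupied by a set of occurrence points
#'
#' A species is assigned every slope containing at least one of its cleaned
#' occurrence points.
#'
#' @param points occurrence table for one species-season
#' @param regions a `region_set`
#' @return character vector, subset of `c("pacific", "caribbean")`
#' @export
assign_slopes <- function(points, regions) {
  stopifnot(inherits(regions, "region_set"))
  slopes <- c("pacific", "caribbean")
  hit <- vapply(slopes, function(s)
    any(point_in_polygon(points$x, points$y, regions[[s]])), TRUE)
  slopes[hit]
}

#' Clip a raster to the study region (neutral) or slope polygons (constrained)
#'
#' Both modes mark cells outside the study domain as NODATA (unmodeled).
#' Constrained mode additionally zeroes cells inside the domain but outside
#' the species' occupied slope polygons: the accessible-area restriction
#' asserts the species is absent there, not unobserved, which keeps
#' constrained occupancy nested inside neutral occupancy after hexagon
#' aggregation.
#'
#' @param r an [eco_raster()] (binary or continuous)
#' @param regions a `region_set`
#' @param mode `"neutral"` or `"constrained"`
#' @param slopes for constrained mode, slope names from [assign_slopes()]
#' @return masked [eco_raster()], with `mode` recorded in its metadata
#' @export
clip_to_region <- function(r, regions, mode = c("neutral", "constrained"),
                           slopes = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(r, "eco_raster"), inherits(regions, "region_set"))
  cc <- cell_centroids(r$geom)
  in_domain <- point_in_polygon(cc$x, cc$y, regions$domain)
  v <- r$values
  v[!matrix(in_domain, r$geom$ny, r$geom$nx, byrow = TRUE)] <- NA
  if (mode == "constrained") {
    stopifnot(length(slopes) >= 1, all(slopes %in% c("pacific", "caribbean")))
    in_slope <- Reduce(`|`, lapply(regions[slopes], function(p)
      point_in_polygon(cc$x, cc$y, p)))
    zero <- matrix(in_domain & !in_slope, r$geom$ny, r$geom$nx, byrow = TRUE)
    v[zero] <- 0
  }
  if (all(is.na(v))) stop("clip_to_region: empty intersection with region")
  out <- eco_raster(v, r$geom)
  out$meta <- c(r$meta[setdiff(names(r$meta), "mode")], list(mode = mode))
  out
}
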