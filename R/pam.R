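# Hexagonal sampling array and the presence-absence matrix (PAM). Raster
# cells are assigned to the hexagon containing their centroid, and a tiered
# coverage rule converts per-hexagon SDM cell counts into hexagon presence.

#' Tiered coverage rule for hexagon presence
#'
#' With `n` assigned SDM cells of which `k` are present, the hexagon is
#' present iff `k / n >= t`, where `t` is 0.70 for `n <= 10`, 0.50 for
#' `11 <= n <= 40`, and 0.30 for `n > 40`. Comparisons are inclusive.
#'
#' @param breakpoints integer length-2, tier breakpoints on `n` (default 10, 40)
#' @param thresholds numeric length-3, decreasing proportions (default
#'   0.70, 0.50, 0.30)
#' @return a `tier_rule`
#' @export
tier_rule <- function(breakpoints = c(10L, 40L), thresholds = c(0.70, 0.50, 0.30)) {
  stopifnot(length(breakpoints) == 2, length(thresholds) == 3,
            breakpoints[1] < breakpoints[2],
            thresholds[1] > thresholds[2], thresholds[2] > thresholds[3])
  structure(list(breakpoints = as.integer(breakpoints),
                 thresholds = as.numeric(thresholds)), class = "tier_rule")
}

tier_threshold <- function(rule, n) {
  ifelse(n <= rule$breakpoints[1], rule$thresholds[1],
         ifelse(n <= rule$breakpoints[2], rule$thresholds[2],
                rule$thresholds[3]))
}

#' Build a flat-top hexagonal sampling grid over a region
#'
#' Regular flat-top hexagons of area `target_area_km2`, lattice anchored at
#' the lower-left corner of the region's bounding box; hexagons intersecting
#' the region are retained. Nearest-neighbor centroid spacing is
#' `sqrt(2 * A / sqrt(3))`.
#'
#' @param region polygon (n x 2 vertex matrix) or a `region_set` (its domain
#'   is used)
#' @param target_area_km2 area of a full hexagon (default 164.8)
#' @return a `hex_grid` with `centers` (data.frame `id, cx, cy, col, row,
#'   keep`), circumradius `a`, `spacing`, `target_area`
#' @export
build_hex_grid <- function(region, target_area_km2 = 164.8) {
  if (inherits(region, "region_set")) region <- region$domain
  stopifnot(is.matrix(region), ncol(region) == 2, nrow(region) >= 3)
  if (polygon_area(region) < target_area_km2)
    stop("build_hex_grid: region smaller than one hexagon")
  a <- sqrt(2 * target_area_km2 / (3 * sqrt(3)))   # circumradius
  dy <- sqrt(3) * a                                # row spacing (= centroid spacing)
  dx <- 1.5 * a                                    # column spacing
  x0 <- min(region[, 1]); y0 <- min(region[, 2])
  x1 <- max(region[, 1]); y1 <- max(region[, 2])
  ncol_ <- ceiling((x1 - x0) / dx) + 2L
  nrow_ <- ceiling((y1 - y0) / dy) + 2L
  cols <- seq.int(0L, ncol_) ; rows <- seq.int(0L, nrow_)
  grid <- expand.grid(col = cols, row = rows)
  grid <- grid[order(grid$col, grid$row), ]
  cx <- x0 + grid$col * dx
  cy <- y0 + grid$row * dy + ifelse(grid$col %% 2 == 1, dy / 2, 0)
  centers <- data.frame(cx = cx, cy = cy, col = grid$col, row = grid$row)
  verts <- hex_vertices(a)
  keep <- vapply(seq_len(nrow(centers)), function(i) {
    hexpoly <- cbind(verts[, 1] + centers$cx[i], verts[, 2] + centers$cy[i])
    convex_polys_intersect(hexpoly, region)
  }, TRUE)
  centers$keep <- keep
  centers$id <- NA_character_
  centers$id[keep] <- sprintf("h%03d", seq_len(sum(keep)))
  rownames(centers) <- NULL
  structure(list(centers = centers, a = a, spacing = dy,
                 target_area = target_area_km2, region = region),
            class = "hex_grid")
}

# vertex offsets of a flat-top regular hexagon with circumradius a
hex_vertices <- function(a) {
  th <- seq(0, 300, by = 60) * pi / 180
  cbind(a * cos(th), a * sin(th))
}

#' Polygon of one hexagon
#' @param grid a `hex_grid`
#' @param id hexagon id
#' @return 6 x 2 vertex matrix
#' @export
hex_polygon <- function(grid, id) {
  i <- match(id, grid$centers$id)
  stopifnot(!is.na(i))
  v <- hex_vertices(grid$a)
  cbind(v[, 1] + grid$centers$cx[i], v[, 2] + grid$centers$cy[i])
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d hexagons kept (of %d lattice), area %.1f km2, spacing %.2f km\n",
              sum(x$centers$keep), nrow(x$centers), x$target_area, x$spacing))
  invisible(x)
}

#' Assign raster cells to hexagons by centroid
#'
#' Each cell goes to the hexagon whose center is nearest its centroid (for a
#' regular hexagonal lattice this is exactly the hexagon containing the
#' centroid); distance ties break to the lowest hexagon index. Cells whose
#' hexagon is not retained map to `NA`.
#'
#' @param geom a [grid_geom()] describing the raster
#' @param grid a `hex_grid`
#' @return character vector of hexagon ids, one per cell (cell-id order)
#' @export
map_cells_to_hexagons <- function(geom, grid) {
  stopifnot(inherits(geom, "grid_geom"), inherits(grid, "hex_grid"))
  cc <- cell_centroids(geom)
  cxy <- as.matrix(grid$centers[, c("cx", "cy")])
  n <- nrow(cc)
  nearest <- integer(n)
  block <- 2000L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    dx <- outer(cc$x[s:e], cxy[, 1], `-`)
    dy <- outer(cc$y[s:e], cxy[, 2], `-`)
    nearest[s:e] <- max.col(-(dx * dx + dy * dy), ties.method = "first")
  }
  grid$centers$id[nearest]
}

#' Aggregate a binary SDM to hexagon presence with the tier rule
#'
#' @param sdm binary [eco_raster()]
#' @param assignment cell-to-hexagon ids from [map_cells_to_hexagons()]
#' @param grid the `hex_grid`
#' @param rule a [tier_rule()]
#' @return named 0/1 integer vector over retained hexagon ids (hexagons with
#'   no assigned valid cell are absent = 0)
#' @export
aggregate_presence <- function(sdm, assignment, grid, rule = tier_rule()) {
  stopifnot(inherits(sdm, "eco_raster"), inherits(rule, "tier_rule"))
  v <- raster_values_vec(sdm)
  stopifnot(length(v) == length(assignment))
  ids <- grid$centers$id[grid$centers$keep]
  ok <- !is.na(v) & !is.na(assignment)
  n <- table(factor(assignment[ok], levels = ids))
  k <- table(factor(assignment[ok & v == 1], levels = ids))
  pres <- as.integer(n > 0 & as.numeric(k) / pmax(as.numeric(n), 1) >=
                       tier_threshold(rule, as.numeric(n)))
  names(pres) <- ids
  pres
}

#' Build a species-by-hexagon presence-absence matrix
#'
#' @param sdms named list of binary [eco_raster()]s (names = species ids)
#' @param grid a `hex_grid`
#' @param assignment cell-to-hexagon assignment on the shared geometry
#' @param rule a [tier_rule()]
#' @param season,mode provenance strings
#' @return a `pam`: binary matrix (rows = species in lexicographic order,
#'   columns = hexagon ids) with attributes `season` and `mode`
#' @export
build_pam <- function(sdms, grid, assignment, rule = tier_rule(),
                      season = NA_character_, mode = NA_character_) {
  stopifnot(length(sdms) >= 1, !is.null(names(sdms)))
  g <- sdms[[1]]$geom
  for (s in sdms) if (!same_geom(s$geom, g))
    stop("build_pam: SDM geometry mismatch")
  species <- sort(names(sdms))
  rows <- lapply(species, function(sp)
    aggregate_presence(sdms[[sp]], assignment, grid, rule))
  m <- do.call(rbind, rows)
  rownames(m) <- species
  structure(m, class = c("pam", class(m)), season = season, mode = mode)
}

#' Richness and mean-range-size maps from a PAM
#'
#' Richness is the per-hexagon species count; mean range size is the average,
#' over species present in a hexagon, of those species' total occupied-hexagon
#' counts. Hexagons with richness 0 get `NA` mean range size.
#'
#' @param pam a `pam` matrix
#' @return data.frame `hexagon, richness, mean_range_size`
#' @export
diversity_maps <- function(pam) {
  stopifnot(nrow(pam) >= 1)
  m <- unclass(pam)
  richness <- colSums(m)
  range_size <- rowSums(m)
  mrs <- vapply(seq_len(ncol(m)), function(j) {
    pres <- m[, j] == 1
    if (!any(pres)) NA_real_ else mean(range_size[pres])
  }, 0)
  data.frame(hexagon = colnames(m), richness = as.numeric(richness),
             mean_range_size = mrs, row.names = NULL)
}
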