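#' @useDynLib nichecohesion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom qchisq quantile sd cov cor dist
#'   hclust kmeans t.test wilcox.test fisher.test cor.test qt setNames
#'   complete.cases aggregate mahalanobis cov2cor rWishart
#' @importFrom utils write.csv read.csv head combn
NULL

# ---------------------------------------------------------------------------
# Grid geometry: a regular raster grid in a local projected CRS (km), origin
# at the lower-left corner of the domain, cell (1,1) at lower-left, centroids
# at ((ix - 0.5) * cell, (iy - 0.5) * cell).
# ---------------------------------------------------------------------------

#' Grid geometry for a regular raster in local km coordinates
#'
#' @param nx,ny cell counts in x and y
#' @param cell_size cell edge length in km
#' @param origin numeric length-2, lower-left corner (km)
#' @return an object of class `grid_geom`
#' @export
grid_geom <- function(nx, ny, cell_size = 1, origin = c(0, 0)) {
  stopifnot(nx >= 1, ny >= 1, cell_size > 0, length(origin) == 2)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_size = cell_size, origin = as.numeric(origin)),
            class = "grid_geom")
}

#' @export
print.grid_geom <- function(x, ...) {
  cat(sprintf("<grid_geom> %d x %d cells, %.3g km cells, origin (%g, %g)\n",
              x$nx, x$ny, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Centroid coordinates of every grid cell
#'
#' Cells are enumerated row-major from the lower-left: cell id
#' `(iy - 1) * nx + ix`.
#'
#' @param geom a [grid_geom()]
#' @return data.frame with columns `ix, iy, x, y`
#' @export
cell_centroids <- function(geom) {
  stopifnot(inherits(geom, "grid_geom"))
  ix <- rep(seq_len(geom$nx), times = geom$ny)
  iy <- rep(seq_len(geom$ny), each = geom$nx)
  data.frame(ix = ix, iy = iy,
             x = geom$origin[1] + (ix - 0.5) * geom$cell_size,
             y = geom$origin[2] + (iy - 0.5) * geom$cell_size)
}

# map x/y (km) to cell indices; NA outside the grid
xy_to_cell <- function(geom, x, y) {
  ix <- floor((x - geom$origin[1]) / geom$cell_size) + 1L
  iy <- floor((y - geom$origin[2]) / geom$cell_size) + 1L
  bad <- ix < 1L | ix > geom$nx | iy < 1L | iy > geom$ny
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  cbind(ix = ix, iy = iy)
}

# ---------------------------------------------------------------------------
# eco_raster: one single-band layer on a grid_geom. Values stored as an
# ny x nx matrix (row = iy, col = ix); NA encodes NODATA.
# ---------------------------------------------------------------------------

#' Single-band raster layer on a regular grid
#'
#' @param values numeric matrix, `ny` rows by `nx` columns; `NA` = NODATA
#' @param geom a [grid_geom()]
#' @param ... provenance fields stored as attributes (species, season, mode,
#'   type, ...)
#' @return an `eco_raster`
#' @export
eco_raster <- function(values, geom, ...) {
  stopifnot(inherits(geom, "grid_geom"),
            is.matrix(values), nrow(values) == geom$ny, ncol(values) == geom$nx)
  r <- structure(list(values = values, geom = geom, meta = list(...)),
                 class = "eco_raster")
  r
}

#' @export
print.eco_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<eco_raster> %d x %d, %d valid cells, range [%.4g, %.4g]\n",
              x$geom$ny, x$geom$nx, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(m) is.character(m) || is.numeric(m), TRUE)
    cat("  ", paste(names(x$meta)[keep], unlist(x$meta[keep]),
                    sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# values at cells, vector in row-major cell-id order
raster_values_vec <- function(r) as.vector(t(r$values))

same_geom <- function(a, b) {
  identical(a$nx, b$nx) && identical(a$ny, b$ny) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

# ---------------------------------------------------------------------------
# Polygons. A polygon is a closed ring given as an n x 2 matrix of vertices
# (not repeating the first vertex). Regions are named lists of polygons.
# ---------------------------------------------------------------------------

#' Test points against a polygon ring (even-odd ray casting)
#'
#' Points exactly on a boundary follow the half-open convention of the
#' crossing test: lower/left edges count as inside, upper/right as outside,
#' so a set of polygons that tile the plane assigns every point exactly once.
#'
#' @param x,y point coordinates (vectors)
#' @param poly n x 2 matrix of ring vertices
#' @return logical vector
#' @export
point_in_polygon <- function(x, y, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Area of a polygon ring (shoelace formula)
#' @param poly n x 2 matrix of ring vertices
#' @return area in squared coordinate units
#' @export
polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# convex-convex intersection test by separating axis theorem
convex_polys_intersect <- function(a, b) {
  axes <- function(p) {
    n <- nrow(p)
    e <- p[c(2:n, 1), , drop = FALSE] - p
    cbind(-e[, 2], e[, 1])
  }
  for (ax in list(axes(a), axes(b))) {
    for (i in seq_len(nrow(ax))) {
      v <- ax[i, ]
      pa <- a %*% v; pb <- b %*% v
      if (max(pa) < min(pb) || max(pb) < min(pa)) return(FALSE)
    }
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Seeded evaluation that does not disturb the caller's RNG stream.
# ---------------------------------------------------------------------------
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a bounded stage seed from a base seed and a stage tag
stage_seed <- function(seed, stage) {
  offsets <- c(stack = 11L, niches = 23L, occurrences = 37L, regions = 41L,
               kmeans = 53L, gap = 67L, null = 71L, subsample = 83L,
               gom = 97L, blobs = 101L)
  off <- offsets[[stage]]
  (as.integer(seed) * 127L + off) %% 2147483587L
}
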