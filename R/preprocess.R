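# Occurrence cleaning: monthly split, per-species spatial thinning, and the
# minimum-record filter, applied in that order.

check_occurrence_table <- function(occ) {
  stopifnot(is.data.frame(occ),
            all(c("species", "x", "y", "month") %in% names(occ)))
  if (nrow(occ)) {
    stopifnot(all(is.finite(occ$x)), all(is.finite(occ$y)),
              all(occ$month %in% 1:12))
  }
  invisible(occ)
}

#' Split an occurrence table by month
#'
#' Rows whose month is outside `months` are dropped; the drop count is
#' attached as attribute `n_dropped` and reported.
#'
#' @param occ occurrence data.frame (`species, x, y, month`)
#' @param months integer months to keep (default June and December)
#' @return named list of occurrence tables, one per requested month
#' @export
split_by_month <- function(occ, months = c(6L, 12L)) {
  check_occurrence_table(occ)
  stopifnot(length(months) >= 1)
  months <- sort(unique(as.integer(months)))
  dropped <- sum(!occ$month %in% months)
  if (dropped > 0)
    message(sprintf("split_by_month: dropped %d rows outside months {%s}",
                    dropped, paste(months, collapse = ",")))
  out <- lapply(months, function(m) {
    d <- occ[occ$month == m, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(out) <- as.character(months)
  attr(out, "n_dropped") <- dropped
  out
}

# greedy thin of one species' coordinate matrix, in input-row order:
# keep a point iff its distance to every already-kept point is >= min_dist
greedy_thin_idx <- function(xy, min_dist) {
  n <- nrow(xy)
  if (n <= 1) return(seq_len(n))
  kept <- 1L
  for (i in 2L:n) {
    d2 <- (xy[kept, 1] - xy[i, 1])^2 + (xy[kept, 2] - xy[i, 2])^2
    if (all(d2 >= min_dist^2)) kept <- c(kept, i)
  }
  kept
}

#' Spatially thin occurrences per species
#'
#' Greedy scan in input-row order: a point is kept iff it lies at least
#' `min_dist_km` (Euclidean, projected km) from every already-kept point of
#' the same species. "Within 1 km" removal is strict, so two points exactly
#' 1 km apart are both kept. Deterministic given row order; idempotent.
#'
#' @param occ occurrence table, typically a single month
#' @param min_dist_km minimum allowed distance between retained points (km)
#' @return thinned occurrence table
#' @export
thin_spatial <- function(occ, min_dist_km = 1.0) {
  check_occurrence_table(occ)
  stopifnot(min_dist_km > 0)
  if (!nrow(occ)) return(occ)
  keep <- logical(nrow(occ))
  for (sp in unique(occ$species)) {
    rows <- which(occ$species == sp)
    idx <- greedy_thin_idx(cbind(occ$x[rows], occ$y[rows]), min_dist_km)
    keep[rows[idx]] <- TRUE
  }
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop species with too few records
#'
#' Applied after thinning; species with fewer than `n_min` rows are removed
#' entirely and listed. Surviving rows are untouched.
#'
#' @param occ occurrence table (one month, already thinned)
#' @param n_min minimum rows per species (default 10)
#' @return list with `occurrences` (filtered table) and `excluded`
#'   (data.frame `species, n_records, reason`)
#' @export
filter_min_records <- function(occ, n_min = 10L) {
  check_occurrence_table(occ)
  stopifnot(n_min >= 1)
  if (!nrow(occ)) {
    return(list(occurrences = occ,
                excluded = data.frame(species = character(),
                                      n_records = integer(),
                                      reason = character())))
  }
  counts <- table(occ$species)
  bad <- names(counts)[counts < n_min]
  excluded <- data.frame(species = bad,
                         n_records = as.integer(counts[bad]),
                         reason = rep(sprintf("fewer than %d records", n_min),
                                      length(bad)))
  out <- occ[!occ$species %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  list(occurrences = out, excluded = excluded)
}

#' Full cleaning pipeline for one occurrence table
#'
#' Split by month, thin each month independently per species, then apply the
#' minimum-record filter per month.
#'
#' @param occ raw occurrence table
#' @param months months to retain
#' @param min_dist_km thinning distance
#' @param n_min minimum records per species and month
#' @return named list per month: `occurrences`, `excluded`
#' @export
clean_occurrences <- function(occ, months = c(6L, 12L), min_dist_km = 1.0,
                              n_min = 10L) {
  by_month <- split_by_month(occ, months)
  lapply(by_month, function(tab) filter_min_records(thin_spatial(tab, min_dist_km), n_min))
}
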