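# Schoener's D niche similarity between seasonal suitability surfaces,
# randomization nulls, and the category-level statistical comparisons.

#' Schoener's D between two continuous surfaces
#'
#' Both surfaces are normalized to sum to 1 over the union of valid cells
#' (a cell masked out of one surface, e.g. by a biogeographic clip, carries
#' zero suitability there), then `D = 1 - 0.5 * sum(|p - q|)`. D is symmetric
#' and lies in \[0, 1\]: 1 for identical surfaces, 0 for disjoint support.
#'
#' @param r1,r2 [eco_raster()]s on the same geometry
#' @return Schoener's D
#' @export
schoener_d <- function(r1, r2) {
  stopifnot(inherits(r1, "eco_raster"), inherits(r2, "eco_raster"))
  if (!same_geom(r1$geom, r2$geom)) stop("schoener_d: geometry mismatch")
  a <- r1$values; b <- r2$values
  ok <- !is.na(a) | !is.na(b)
  if (!any(ok)) stop("schoener_d: no valid cells")
  p <- a[ok]; q <- b[ok]
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  if (sum(p) <= 0 || sum(q) <= 0)
    stop("schoener_d: surface with no positive mass")
  p <- p / sum(p); q <- q / sum(q)
  1 - 0.5 * sum(abs(p - q))
}

#' Per-species June vs December niche similarity records
#'
#' One record per resident species present in both seasons: its Schoener's D
#' between seasonal suitability surfaces, the stability category of its June
#' cluster, and the June-minus-December record-count difference.
#'
#' @param june_surfaces,december_surfaces named lists of suitability rasters
#'   (names = species ids)
#' @param stability a `stability_report` (or `NULL` to set category `"none"`)
#' @param june_labels named June cluster labels (needed to join categories)
#' @param point_counts data.frame `species, n_june, n_december` (or `NULL`)
#' @param mode provenance string
#' @return data.frame `species, D, category, delta_points, mode`
#' @export
overlap_table <- function(june_surfaces, december_surfaces, stability = NULL,
                          june_labels = NULL, point_counts = NULL,
                          mode = NA_character_) {
  shared <- intersect(names(june_surfaces), names(december_surfaces))
  skipped <- setdiff(union(names(june_surfaces), names(december_surfaces)), shared)
  if (length(skipped))
    message("overlap_table: skipping species missing a season: ",
            paste(skipped, collapse = ", "))
  if (!length(shared)) stop("overlap_table: no species present in both seasons")
  cat_of <- function(sp) {
    if (is.null(stability) || is.null(june_labels) || !sp %in% names(june_labels))
      return("none")
    cl <- june_labels[[sp]]
    i <- match(cl, stability$cluster)
    if (is.na(i)) "none" else stability$category[i]
  }
  delta_of <- function(sp) {
    if (is.null(point_counts)) return(NA_integer_)
    i <- match(sp, point_counts$species)
    if (is.na(i)) NA_integer_ else
      as.integer(point_counts$n_june[i] - point_counts$n_december[i])
  }
  data.frame(
    species = shared,
    D = vapply(shared, function(sp)
      schoener_d(june_surfaces[[sp]], december_surfaces[[sp]]), 0),
    category = vapply(shared, cat_of, ""),
    delta_points = vapply(shared, delta_of, 1L),
    mode = mode, row.names = NULL)
}

#' Randomized Schoener's D null distribution
#'
#' Each draw pairs a uniformly sampled June species i with a December species
#' j, i != j, and records D between their surfaces; self-pairings are
#' excluded so a species' own seasonal conservatism cannot enter the null.
#'
#' @param june_surfaces,december_surfaces named lists of suitability rasters
#' @param n_draws number of randomized pairings
#' @param seed integer seed
#' @return a `null_distribution`: list with `draws`, `pairs`, `n_draws`, `seed`
#' @export
randomized_null <- function(june_surfaces, december_surfaces,
                            n_draws = 1000L, seed = 1L) {
  jn <- names(june_surfaces); dn <- names(december_surfaces)
  stopifnot(length(jn) >= 2, length(dn) >= 2)
  pairs <- with_seed(seed, {
    i <- sample(jn, n_draws, replace = TRUE)
    j <- character(n_draws)
    for (t in seq_len(n_draws)) {
      cand <- setdiff(dn, i[t])
      j[t] <- cand[sample.int(length(cand), 1)]
    }
    data.frame(june = i, december = j)
  })
  key <- paste(pairs$june, pairs$december)
  uk <- !duplicated(key)
  dvals <- setNames(vapply(which(uk), function(t)
    schoener_d(june_surfaces[[pairs$june[t]]],
               december_surfaces[[pairs$december[t]]]), 0), key[uk])
  structure(list(draws = as.numeric(dvals[key]), pairs = pairs,
                 n_draws = n_draws, seed = seed),
            class = "null_distribution")
}

mean_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  half <- if (n > 1 && sd(x) > 0) qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n) else 0
  c(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Welch test of observed vs randomized D
#'
#' @param observed numeric vector of observed per-species D
#' @param null a `null_distribution` (or numeric vector)
#' @return list with `t`, `df`, `p`, and mean with 95% CI for both groups
#' @export
observed_vs_null_test <- function(observed, null) {
  nullv <- if (inherits(null, "null_distribution")) null$draws else null
  stopifnot(length(observed) >= 1, length(nullv) >= 1)
  if (sd(observed) == 0 && sd(nullv) == 0) {
    if (isTRUE(all.equal(mean(observed), mean(nullv))))
      return(list(t = 0, df = NA_real_, p = 1,
                  observed = mean_ci(observed), null = mean_ci(nullv)))
    return(list(t = Inf * sign(mean(observed) - mean(nullv)), df = NA_real_,
                p = 0, observed = mean_ci(observed), null = mean_ci(nullv)))
  }
  tt <- t.test(observed, nullv, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, observed = mean_ci(observed), null = mean_ci(nullv))
}

#' Pairwise Wilcoxon comparisons of D across stability categories
#'
#' Two-sided rank-sum tests between every pair of categories with at least
#' two records (exact when the combined sample is small and untied, normal
#' approximation with continuity correction otherwise), plus per-category
#' mean D with 95% CI.
#'
#' @param records an [overlap_table()] data.frame
#' @param categories categories to compare
#' @return list with `tests` (data.frame `group1, group2, W, p, n1, n2`) and
#'   `category_means` (data.frame `category, mean, lower, upper, n`)
#' @export
category_comparisons <- function(records,
                                 categories = c("stable", "split", "diffuse")) {
  present <- intersect(categories, unique(records$category))
  groups <- lapply(present, function(cg) records$D[records$category == cg])
  names(groups) <- present
  usable <- present[vapply(groups, length, 0L) >= 2]
  skipped <- setdiff(present, usable)
  if (length(skipped))
    message("category_comparisons: skipping categories with < 2 records: ",
            paste(skipped, collapse = ", "))
  if (length(usable) < 2)
    stop("category_comparisons: need >= 2 categories with >= 2 records")
  combos <- combn(usable, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    exact <- (length(groups[[g1]]) + length(groups[[g2]])) <= 50
    wt <- suppressWarnings(
      wilcox.test(groups[[g1]], groups[[g2]], exact = exact, correct = TRUE))
    data.frame(group1 = g1, group2 = g2, W = unname(wt$statistic),
               p = wt$p.value, n1 = length(groups[[g1]]),
               n2 = length(groups[[g2]]))
  }))
  means <- do.call(rbind, lapply(usable, function(cg) {
    ci <- mean_ci(groups[[cg]])
    data.frame(category = cg, mean = ci[["mean"]], lower = ci[["lower"]],
               upper = ci[["upper"]], n = as.integer(ci[["n"]]))
  }))
  list(tests = tests, category_means = means)
}

#' Association between D and seasonal effort difference
#'
#' Spearman rank correlation of each species' D against the absolute
#' June-minus-December record-count difference.
#'
#' @param records an [overlap_table()] data.frame with `delta_points`
#' @return list with `rho`, `p`, `n` (`rho = NA` when the inputs are constant)
#' @export
effort_bias_check <- function(records) {
  ok <- !is.na(records$D) & !is.na(records$delta_points)
  d <- records$D[ok]; e <- abs(records$delta_points[ok])
  if (length(d) < 3) stop("effort_bias_check: need at least 3 records")
  if (sd(d) == 0 || sd(e) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(d),
                note = "constant input; correlation undefined"))
  ct <- suppressWarnings(cor.test(d, e, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(d))
}

#' Fisher test of migrant-related category counts vs random subsets
#'
#' Tabulates stability categories for the migrant-related species set and for
#' `n_subsamples` random same-size subsets of the records; tests the migrant
#' table against the rounded mean random table as a 2 x C contingency table
#' (zero-count categories dropped).
#'
#' @param records an [overlap_table()] data.frame
#' @param migrant_related_set species ids (subset of `records$species`)
#' @param n_subsamples number of random subsets
#' @param seed integer seed
#' @return list with `p`, `migrant_counts`, `random_expected`, `table`
#' @export
migrant_subsample_test <- function(records, migrant_related_set,
                                   n_subsamples = 500L, seed = 1L) {
  stopifnot(all(migrant_related_set %in% records$species),
            length(migrant_related_set) >= 5)
  cats <- c("stable", "split", "diffuse", "unknown", "none")
  count_cats <- function(sp) {
    table(factor(records$category[records$species %in% sp], levels = cats))
  }
  mig <- count_cats(migrant_related_set)
  m <- length(migrant_related_set)
  rand <- with_seed(seed, {
    sums <- numeric(length(cats))
    for (b in seq_len(n_subsamples)) {
      sub <- sample(records$species, m)
      sums <- sums + as.numeric(count_cats(sub))
    }
    sums / n_subsamples
  })
  expected <- round(rand)
  tab <- rbind(migrant = as.numeric(mig), random = expected)
  colnames(tab) <- cats
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  ft <- fisher.test(tab)
  list(p = ft$p.value, migrant_counts = setNames(as.numeric(mig), cats),
       random_expected = setNames(expected, cats), table = tab,
       n_subsamples = n_subsamples, seed = seed)
}
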