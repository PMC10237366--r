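# Species clustering on hexagon-occupancy vectors: k-means with
# gap-statistic K selection, a UPGMA dendrogram for visualization, and the
# stable/split/diffuse classification of cross-season cluster cohesion.

pam_rows <- function(pam) {
  m <- unclass(pam)
  stopifnot(is.matrix(m))
  storage.mode(m) <- "double"
  m
}

#' K-means clustering of species occupancy vectors
#'
#' Euclidean k-means on the rows of the binary PAM; best of `n_init` seeded
#' restarts by total within-cluster sum of squares.
#'
#' @param pam a `pam` (species x hexagon binary matrix)
#' @param K number of clusters (>= 2)
#' @param seed integer seed (restarts are drawn inside this seed)
#' @param n_init number of random restarts
#' @return a `cluster_solution`: list with `K`, `labels` (named integer
#'   vector), `inertia`, `centers`, `seed`
#' @export
kmeans_species <- function(pam, K, seed = 1L, n_init = 25L) {
  m <- pam_rows(pam)
  K <- as.integer(K)
  n_distinct <- nrow(unique(m))
  if (K > n_distinct)
    stop(sprintf("K = %d exceeds the %d distinct occupancy vectors", K, n_distinct))
  stopifnot(K >= 2)
  fit <- with_seed(seed, kmeans(m, centers = K, nstart = n_init, iter.max = 100))
  labels <- setNames(as.integer(fit$cluster), rownames(m))
  structure(list(K = K, labels = labels, inertia = fit$tot.withinss,
                 centers = fit$centers, seed = seed,
                 season = attr(pam, "season"), mode = attr(pam, "mode")),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> K=%d over %d species (inertia %.3f)\n",
              x$K, length(x$labels), x$inertia))
  print(table(x$labels))
  invisible(x)
}

#' Gap-statistic selection of the number of clusters
#'
#' Gap(k) compares observed log within-cluster dispersion to that of `B`
#' reference sets drawn uniformly over each feature's observed range
#' (`cluster::clusGap` with `spaceH0 = "original"`). The chosen K is the
#' smallest k with `Gap(k) >= Gap(k+1) - SE(k+1)`
#' (`cluster::maxSE(method = "Tibs2001SEmax")`).
#'
#' @param pam a `pam` or plain numeric matrix (rows clustered)
#' @param k_max largest k considered (>= 2)
#' @param B number of reference sets
#' @param seed integer seed
#' @param n_init k-means restarts used inside the gap computation
#' @return list with `K` (optimal), `table` (data.frame `k, logW, E_logW,
#'   gap, SE`), `B`, `seed`
#' @export
gap_statistic <- function(pam, k_max, B = 50L, seed = 1L, n_init = 10L) {
  m <- pam_rows(pam)
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 2, k_max < nrow(m))
  km_fun <- function(x, k) kmeans(x, centers = k, nstart = n_init, iter.max = 100)
  cg <- with_seed(seed,
    cluster::clusGap(m, FUNcluster = km_fun, K.max = k_max, B = B,
                     spaceH0 = "original", verbose = FALSE))
  tab <- as.data.frame(cg$Tab)
  K <- cluster::maxSE(tab$gap, tab$SE.sim, method = "Tibs2001SEmax")
  list(K = as.integer(K),
       table = data.frame(k = seq_len(k_max), logW = tab$logW,
                          E_logW = tab$E.logW, gap = tab$gap, SE = tab$SE.sim),
       B = B, seed = seed, rule = "Tibs2001SEmax")
}

#' UPGMA dendrogram of species occupancy (visualization only)
#'
#' Average-linkage hierarchical clustering on Euclidean or Jaccard distances
#' between occupancy vectors, returned as an `ape` phylogeny for Newick
#' export.
#'
#' @param pam a `pam`
#' @param metric `"euclidean"` or `"jaccard"` (binary distance)
#' @return list with `phylo` (an [ape::as.phylo()] tree), `hclust`
#' @export
upgma_tree <- function(pam, metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  m <- pam_rows(pam)
  stopifnot(nrow(m) >= 2)
  d <- if (metric == "euclidean") dist(m) else dist(m, method = "binary")
  hc <- hclust(d, method = "average")
  list(phylo = ape::as.phylo(hc), hclust = hc, metric = metric)
}

#' Cross-season cluster overlap fractions
#'
#' For each June cluster `c` (restricted to the shared resident species),
#' `f(c)` is the largest fraction of its members landing in a single December
#' cluster. The reverse direction (December into June) is computed as well.
#'
#' @param june,december `cluster_solution`s
#' @param shared_species species present in both solutions (residents)
#' @return an `overlap_table`: list with `forward` and `reverse` data.frames
#'   (`cluster, size, best_match, overlap`), `direction`
#' @export
cross_season_overlap <- function(june, december, shared_species) {
  stopifnot(inherits(june, "cluster_solution"),
            inherits(december, "cluster_solution"),
            length(shared_species) >= 1,
            all(shared_species %in% names(june$labels)),
            all(shared_species %in% names(december$labels)))
  a <- june$labels[shared_species]
  b <- december$labels[shared_species]
  one_dir <- function(from, to) {
    out <- lapply(sort(unique(from)), function(cl) {
      members <- from == cl
      size <- sum(members)
      tab <- table(to[members])
      best <- which.max(tab)
      data.frame(cluster = cl, size = size,
                 best_match = as.integer(names(tab)[best]),
                 overlap = as.numeric(tab[best]) / size)
    })
    do.call(rbind, out)
  }
  structure(list(forward = one_dir(a, b), reverse = one_dir(b, a),
                 direction = "june_to_december", n_shared = length(shared_species)),
            class = "overlap_table")
}

#' Classify cluster cohesion as stable, split, diffuse or unknown
#'
#' Bands on the best-match overlap fraction f: stable if `f > 2/3`, split if
#' `1/3 < f <= 2/3`, diffuse if `f <= 1/3`; clusters with fewer than
#' `min_size` shared species are `unknown`.
#'
#' @param overlaps an `overlap_table` from [cross_season_overlap()]
#' @param min_size minimum shared species for classification (default 5)
#' @param direction `"forward"` (June into December) or `"reverse"`
#' @return a `stability_report`: data.frame `cluster, size, best_match,
#'   overlap, category` with the direction as an attribute
#' @export
classify_stability <- function(overlaps, min_size = 5L,
                               direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(overlaps, "overlap_table"))
  tab <- overlaps[[direction]]
  band <- function(f) if (f > 2 / 3) "stable" else if (f > 1 / 3) "split" else "diffuse"
  tab$category <- ifelse(tab$size < min_size, "unknown",
                         vapply(tab$overlap, band, ""))
  structure(tab, class = c("stability_report", "data.frame"),
            direction = direction, min_size = min_size)
}
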