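test_that("k-means separates identical-vector groups and is deterministic", {
  A <- matrix(rep(c(1, 1, 0, 0, 0, 0), 4), 4, 6, byrow = TRUE)
  B <- matrix(rep(c(0, 0, 0, 0, 1, 1), 4), 4, 6, byrow = TRUE)
  pam <- rbind(A, B)
  rownames(pam) <- sprintf("sp%02d", 1:8)
  s1 <- kmeans_species(pam, K = 2, seed = 5)
  expect_equal(s1$inertia, 0)
  expect_length(unique(s1$labels[1:4]), 1)
  expect_length(unique(s1$labels[5:8]), 1)
  expect_false(s1$labels[1] == s1$labels[5])
  s2 <- kmeans_species(pam, K = 2, seed = 5)
  expect_identical(s1$labels, s2$labels)
  expect_error(kmeans_species(pam, K = 5, seed = 1), "distinct")
})

test_that("k-means matches the exhaustive 2-partition oracle on a toy PAM", {
  set.seed(41)
  pam <- matrix(rbinom(6 * 8, 1, 0.5), 6, 8)
  pam[1:3, 1:4] <- 1; pam[1:3, 5:8] <- 0
  rownames(pam) <- letters[1:6]
  # brute force over all 2-partitions, minimizing within-cluster SS
  best <- Inf; best_part <- NULL
  for (mask in 1:(2^5)) {
    part <- c(1, as.integer(intToBits(mask))[1:5] + 1)
    if (length(unique(part)) < 2) next
    ss <- sum(vapply(1:2, function(g) {
      rows <- pam[part == g, , drop = FALSE]
      sum(scale(rows, scale = FALSE)^2)
    }, 0))
    if (ss < best - 1e-12) { best <- ss; best_part <- part }
  }
  fit <- kmeans_species(pam, K = 2, seed = 7, n_init = 50)
  expect_equal(fit$inertia, best, tolerance = 1e-9)
  same <- fit$labels == fit$labels[1]
  oracle_same <- best_part == best_part[1]
  expect_true(all(same == oracle_same) || all(same == !oracle_same))
})

test_that("gap statistic recovers planted structure and stays conservative", {
  X <- make_blob_pam(seed = 1)
  g <- gap_statistic(X, k_max = 6, B = 30, seed = 1)
  expect_equal(g$K, 3L)
  # W_k decreases in k (nested partitions, best-of-restarts)
  expect_true(all(diff(g$table$logW) <= 1e-6))
  expect_equal(nrow(g$table), 6)

  # one homogeneous blob: no spurious large K
  set.seed(2)
  flat <- matrix(rbinom(40 * 60, 1, 0.5), 40, 60)
  gf <- gap_statistic(flat, k_max = 6, B = 30, seed = 2)
  expect_lte(gf$K, 3L)
})

test_that("UPGMA reproduces the hand-computed merge structure", {
  # coordinates chosen so d(A,B) = 1 and d(A,C) = d(B,C) = 4:
  # hand UPGMA merges (A,B) at height 1, then C at the average distance 4
  pam <- rbind(A = c(0, 0), B = c(0, 1), C = c(sqrt(15.75), 0.5))
  tr <- upgma_tree(pam, metric = "euclidean")
  expect_equal(sort(tr$hclust$height), c(1, 4), tolerance = 1e-9)
  expect_equal(sort(tr$hclust$height)[1], 1)   # A,B first
  # ultrametric: root-to-tip depths all equal (= 2 height-units)
  ph <- tr$phylo
  depths <- ape::node.depth.edgelength(ph)[1:3]
  expect_true(all(abs(depths - depths[1]) < 1e-9))
  # identical vectors merge at height 0
  tr0 <- upgma_tree(rbind(a = c(1, 0), b = c(1, 0)), metric = "euclidean")
  expect_equal(tr0$hclust$height, 0)
  # newick export round-trips
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr$phylo, f)
  expect_equal(sort(ape::read.tree(f)$tip.label), c("A", "B", "C"))
  unlink(f)
})

test_that("cross-season overlap fractions follow the construction", {
  labs <- function(v, sp) structure(list(K = max(v), labels = setNames(v, sp),
                                         inertia = 0, seed = 1),
                                    class = "cluster_solution")
  sp <- sprintf("r%02d", 1:12)
  june <- labs(rep(1:2, each = 6), sp)
  # identical partition -> f = 1 everywhere
  ov1 <- cross_season_overlap(june, labs(rep(c(2, 1), each = 6), sp), sp)
  expect_true(all(ov1$forward$overlap == 1))
  # cluster 1 split evenly across two december clusters -> f = 0.5
  dec <- labs(c(rep(1, 3), rep(2, 3), rep(3, 6)), sp)
  ov2 <- cross_season_overlap(june, dec, sp)
  expect_equal(ov2$forward$overlap[1], 0.5)
  expect_equal(ov2$forward$overlap[2], 1)
  # reverse direction is reported too
  expect_equal(nrow(ov2$reverse), 3)
})

test_that("random relabeling drives overlap toward the Monte-Carlo expectation", {
  sp <- sprintf("r%03d", 1:100)
  june <- structure(list(K = 2, labels = setNames(rep(1:2, each = 50), sp),
                         inertia = 0, seed = 1), class = "cluster_solution")
  set.seed(43)
  f_obs <- replicate(30, {
    dec <- structure(list(K = 10, labels = setNames(sample(1:10, 100, TRUE), sp),
                          inertia = 0, seed = 1), class = "cluster_solution")
    mean(cross_season_overlap(june, dec, sp)$forward$overlap)
  })
  # expected max share of a 50-point multinomial over 10 bins: ~0.15-0.2
  mc <- replicate(400, max(tabulate(sample(1:10, 50, TRUE), 10)) / 50)
  expect_lt(abs(mean(f_obs) - mean(mc)), 0.03)
})

test_that("stability bands classify the quoted boundary cases", {
  mk <- function(f, size) {
    structure(list(forward = data.frame(cluster = 1, size = size,
                                        best_match = 1, overlap = f),
                   reverse = data.frame(cluster = 1, size = size,
                                        best_match = 1, overlap = f),
                   direction = "june_to_december"),
              class = "overlap_table")
  }
  cat_of <- function(f, size) classify_stability(mk(f, size))$category
  expect_equal(cat_of(1.0, 10), "stable")
  expect_equal(cat_of(0.5, 10), "split")
  expect_equal(cat_of(0.25, 10), "diffuse")
  expect_equal(cat_of(0.5, 4), "unknown")
  # exact thirds: 2/3 is split (stable requires > 2/3), 1/3 is diffuse
  expect_equal(cat_of(2 / 3, 9), "split")
  expect_equal(cat_of(1 / 3, 9), "diffuse")
  expect_equal(cat_of(2 / 3 + 1e-9, 9), "stable")
})
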