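test_that("Schoener's D identities hold", {
  r1 <- tiny_raster(c(0.5, 0.5, 0, 0), 2, 2)
  uni <- tiny_raster(rep(0.25, 4), 2, 2)
  expect_equal(schoener_d(r1, r1), 1)
  expect_equal(schoener_d(r1, uni), 0.5)    # 1 - 0.5*(0.25+0.25+0.25+0.25)
  r2 <- tiny_raster(c(0, 0, 0.3, 0.7), 2, 2)
  expect_equal(schoener_d(r1, r2), 0)       # disjoint supports
  expect_error(schoener_d(r1, tiny_raster(rep(0, 4), 2, 2)), "positive")
  expect_error(schoener_d(r1, tiny_raster(1, 1, 1)), "geometry")
  # NODATA in one surface counts as zero suitability there
  r3 <- tiny_raster(c(1, NA, NA, NA), 2, 2)
  expect_equal(schoener_d(r3, uni), 0.25)
})

test_that("Schoener's D is symmetric and normalized on random rasters", {
  set.seed(51)
  for (i in 1:25) {
    a <- tiny_raster(runif(36), 6, 6)
    b <- tiny_raster(runif(36), 6, 6)
    d1 <- schoener_d(a, b); d2 <- schoener_d(b, a)
    expect_lt(abs(d1 - d2), 1e-12)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("overlap tables join categories and respect residency", {
  js <- list(r1 = tiny_raster(runif(9), 3, 3), r2 = tiny_raster(runif(9), 3, 3),
             mig = tiny_raster(runif(9), 3, 3))
  set.seed(52)
  ds <- list(r1 = js$r1, r2 = tiny_raster(runif(9), 3, 3))
  stab <- structure(data.frame(cluster = c(1, 2), size = c(6, 6),
                               best_match = c(1, 2), overlap = c(1, 0.5),
                               category = c("stable", "split")),
                    class = c("stability_report", "data.frame"))
  labels <- c(r1 = 1L, r2 = 2L)
  counts <- data.frame(species = c("r1", "r2"), n_june = c(30, 12),
                       n_december = c(25, 20))
  rec <- suppressMessages(
    overlap_table(js, ds, stability = stab, june_labels = labels,
                  point_counts = counts, mode = "neutral"))
  expect_equal(nrow(rec), 2)                 # migrant absent
  expect_false("mig" %in% rec$species)
  expect_equal(rec$D[rec$species == "r1"], 1)
  expect_equal(rec$category, c("stable", "split"))
  expect_equal(rec$delta_points, c(5L, -8L))
})

test_that("randomized nulls are seeded and exclude self-pairings", {
  set.seed(53)
  js <- setNames(lapply(1:5, function(i) tiny_raster(runif(16), 4, 4)),
                 sprintf("s%d", 1:5))
  ds <- setNames(lapply(1:5, function(i) tiny_raster(runif(16), 4, 4)),
                 sprintf("s%d", 1:5))
  n1 <- randomized_null(js, ds, n_draws = 200, seed = 9)
  n2 <- randomized_null(js, ds, n_draws = 200, seed = 9)
  expect_identical(n1$draws, n2$draws)
  expect_true(all(n1$pairs$june != n1$pairs$december))
  expect_true(all(n1$draws >= 0 & n1$draws <= 1))
  # degenerate case: all species share one surface -> every draw D = 1
  same <- setNames(rep(list(js[[1]]), 3), c("a", "b", "c"))
  nd <- randomized_null(same, same, n_draws = 50, seed = 1)
  expect_true(all(nd$draws == 1))
})

test_that("Welch comparison matches the textbook formula", {
  obs <- c(0.91, 0.88, 0.93, 0.90, 0.87, 0.92, 0.89, 0.94, 0.90, 0.91)
  nul <- c(0.55, 0.60, 0.52, 0.58, 0.61, 0.54, 0.57, 0.59, 0.53, 0.56)
  res <- observed_vs_null_test(obs, nul)
  # independent Welch computation
  s1 <- var(obs) / 10; s2 <- var(nul) / 10
  t_hand <- (mean(obs) - mean(nul)) / sqrt(s1 + s2)
  df_hand <- (s1 + s2)^2 / (s1^2 / 9 + s2^2 / 9)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)
  expect_true(res$observed[["lower"]] <= mean(obs),
              res$observed[["upper"]] >= mean(obs))
  # identical samples -> t = 0, p = 1
  res0 <- observed_vs_null_test(obs, obs)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # zero-variance equal-mean convention
  resc <- observed_vs_null_test(rep(0.5, 4), rep(0.5, 6))
  expect_equal(resc$p, 1)
})

test_that("category comparisons match rank-sum enumeration", {
  rec <- data.frame(species = sprintf("s%d", 1:6),
                    D = c(1, 2, 3, 4, 5, 6),
                    category = rep(c("stable", "diffuse"), each = 3),
                    delta_points = 0, mode = "neutral")
  res <- category_comparisons(rec, categories = c("stable", "diffuse"))
  # exhaustive enumeration of the rank-sum distribution for n1 = n2 = 3
  ranksum <- function(x, y) sum(rank(c(x, y))[seq_along(x)]) -
    length(x) * (length(x) + 1) / 2
  W_obs <- ranksum(c(1, 2, 3), c(4, 5, 6))
  combos <- combn(6, 3)
  W_all <- apply(combos, 2, function(ix) {
    v <- 1:6
    ranksum(v[ix], v[-ix])
  })
  p_exact <- mean(W_all <= W_obs | W_all >= (9 - W_obs))  # two-sided
  expect_equal(res$tests$W, W_obs)
  expect_equal(res$tests$p, p_exact, tolerance = 1e-12)
  # identical multisets -> p = 1
  rec2 <- rec; rec2$D <- rep(c(1, 2, 3), 2)
  res2 <- category_comparisons(rec2, categories = c("stable", "diffuse"))
  expect_equal(res2$tests$p, 1)
  # CI contains the mean
  cm <- res$category_means
  expect_true(all(cm$lower <= cm$mean & cm$mean <= cm$upper))
})

test_that("effort-bias association behaves at the extremes", {
  rec <- data.frame(species = sprintf("s%d", 1:8), D = 8:1,
                    category = "stable", delta_points = 1:8, mode = "m")
  res <- effort_bias_check(rec)
  expect_equal(res$rho, -1)
  expect_error(effort_bias_check(rec[1:2, ]), "at least 3")
  recc <- rec; recc$D <- 0.5
  expect_true(is.na(effort_bias_check(recc)$rho))
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  # 2x2 table [[3,1],[1,3]]: enumerate P(X = k) for margins (4,4),(4,4)
  p_hyper <- dhyper(0:4, 4, 4, 4)
  p_two_sided <- sum(p_hyper[p_hyper <= dhyper(3, 4, 4, 4) + 1e-12])
  ft <- fisher.test(matrix(c(3, 1, 1, 3), 2))
  expect_equal(ft$p.value, p_two_sided, tolerance = 1e-12)
  expect_equal(ft$p.value, 0.4857143, tolerance = 1e-6)

  # migrant subsample test: identical category structure -> p near 1
  set.seed(54)
  rec <- data.frame(species = sprintf("s%03d", 1:60),
                    D = runif(60),
                    category = rep(c("stable", "split", "diffuse"), 20),
                    delta_points = 0, mode = "m")
  mig <- rec$species[rec$category == "stable"][1:6]
  res <- migrant_subsample_test(rec, mig, n_subsamples = 100, seed = 3)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(sum(res$migrant_counts), 6)
  res2 <- migrant_subsample_test(rec, mig, n_subsamples = 100, seed = 3)
  expect_identical(res$p, res2$p)
})
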