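manual_stack <- function(layer_list, nx, ny) {
  g <- grid_geom(nx, ny)
  layers <- lapply(names(layer_list), function(nm)
    eco_raster(matrix(layer_list[[nm]], ny, nx, byrow = TRUE), g, layer = nm))
  names(layers) <- names(layer_list)
  structure(list(layers = layers, geom = g, layer_names = names(layers)),
            class = "env_stack")
}

test_that("environmental extraction looks up the containing cell", {
  # 3x2 grid, values = cell ids so the lookup is self-evident
  st <- manual_stack(list(a = 1:6, b = 11:16), nx = 3, ny = 2)
  pts <- data.frame(species = "s", x = c(0.5, 2.5, 1.1), y = c(0.5, 1.5, 0.2),
                    month = 6L)
  v <- extract_env_values(pts, st)
  expect_equal(v[, "a"], c(1, 6, 2))
  expect_equal(v[, "b"], c(11, 16, 12))

  # out-of-extent and NODATA points are dropped with a message
  st$layers$a$values[1, 1] <- NA
  pts2 <- rbind(pts, data.frame(species = "s", x = 99, y = 99, month = 6L))
  expect_message(v2 <- extract_env_values(pts2, st), "dropped 2")
  expect_equal(nrow(v2), 2)

  pts3 <- data.frame(species = "lost", x = 0.5, y = 0.5, month = 6L)
  expect_error(extract_env_values(pts3, st), "lost")
})

test_that("full-coverage MVE encloses every training point", {
  set.seed(21)
  for (d in 2:3) {
    X <- matrix(rnorm(30 * d), 30, d)
    fit <- fit_mve(X, tau = 1)
    m2 <- mahalanobis(X, fit$center, fit$sigma)
    expect_true(all(m2 <= fit$cutoff * (1 + 1e-9)))
    # cross-check volume against the independent exact-MVE implementation
    v_ref <- cluster::volume(cluster::ellipsoidhull(X, tol = 1e-9))
    expect_equal(mve_volume(fit), v_ref, tolerance = 1e-4)
  }
  expect_error(fit_mve(matrix(rnorm(4), 2, 2), tau = 1), "insufficient")
  degen <- cbind(rnorm(10), 1)
  expect_error(fit_mve(degen, tau = 1), "degenerate|singular")
})

test_that("trimmed MVE excludes planted outliers", {
  set.seed(22)
  th <- runif(18, 0, 2 * pi)
  inliers <- cbind(cos(th), sin(th)) * runif(18, 0, 1)
  outliers <- rbind(c(10, 10), c(-12, 8))
  X <- rbind(inliers, outliers)
  fit <- fit_mve(X, tau = 0.9)   # keep 18 of 20
  m2 <- mahalanobis(X, fit$center, fit$sigma)
  expect_true(all(m2[19:20] > fit$cutoff))
  expect_true(sum(m2 <= fit$cutoff * (1 + 1e-9)) >= ceiling(0.9 * 20))
})

test_that("coverage invariant holds across random trimmed fits", {
  set.seed(23)
  for (r in 1:8) {
    n <- sample(15:40, 1)
    d <- sample(2:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    tau <- sample(c(0.6, 0.75, 0.9), 1)
    fit <- fit_mve(X, tau = tau)
    m2 <- mahalanobis(X, fit$center, fit$sigma)
    expect_gte(sum(m2 <= fit$cutoff * (1 + 1e-9)), ceiling(tau * n))
  }
})

test_that("suitability is 1 at the niche center and decreasing in distance", {
  cfg <- quick_config(seed = 24, n_species = 3)
  sim <- suppressWarnings(simulate_study_system(cfg))
  occ <- suppressMessages(clean_occurrences(sim$occurrences))[["6"]]$occurrences
  sp <- names(which.max(table(occ$species)))
  fit <- fit_mve(extract_env_values(occ[occ$species == sp, ], sim$stack),
                 species_id = sp, season = "june")
  s <- suitability_surface(fit, sim$stack)
  expect_true(all(s$values >= 0 & s$values <= 1, na.rm = TRUE))
  expect_equal(max(s$values, na.rm = TRUE), 1)
  # monotone: suitability ordering is the reverse of the m2 ordering
  m2 <- nichecohesion:::model_m2_surface(fit, sim$stack)
  o <- order(m2)
  expect_true(all(diff(s$values[o]) <= 1e-12))

  b <- binarize_sdm(fit, sim$stack)
  expect_true(all(b$values %in% c(0, 1)))
  # at least tau of the training points sit in cells valued 1
  pts <- occ[occ$species == sp, ]
  idx <- nichecohesion:::xy_to_cell(sim$stack$geom, pts$x, pts$y)
  inside <- b$values[cbind(idx[, "iy"], idx[, "ix"])] == 1
  expect_gte(mean(inside), fit$tau)
  # unbounded cutoff -> every valid cell present
  fit_inf <- fit
  fit_inf$cutoff <- 1e12
  expect_true(all(binarize_sdm(fit_inf, sim$stack)$values == 1))
})

test_that("region clipping respects slopes and containment", {
  cfg <- quick_config(seed = 25, n_species = 4)
  sim <- suppressWarnings(simulate_study_system(cfg))
  occ <- suppressMessages(clean_occurrences(sim$occurrences))[["6"]]$occurrences
  reg <- sim$regions
  ridge <- reg$ridge_x
  cc <- cell_centroids(sim$stack$geom)
  for (sp in unique(occ$species)) {
    pts <- occ[occ$species == sp, ]
    fit <- fit_mve(extract_env_values(pts, sim$stack), species_id = sp,
                   season = "june")
    b <- binarize_sdm(fit, sim$stack)
    neutral <- clip_to_region(b, reg, "neutral")
    slopes <- assign_slopes(pts, reg)
    constrained <- clip_to_region(b, reg, "constrained", slopes = slopes)
    # constrained support is a subset of neutral support
    ns <- !is.na(neutral$values) & neutral$values == 1
    cs <- !is.na(constrained$values) & constrained$values == 1
    expect_true(all(ns[cs]))
    if (identical(sort(slopes), c("caribbean", "pacific"))) {
      expect_equal(constrained$values, neutral$values)
    } else if (identical(slopes, "pacific")) {
      # off-slope cells inside the domain carry asserted absence
      off <- matrix(cc$x, nrow(b$values), ncol(b$values), byrow = TRUE) >= ridge
      expect_true(all(constrained$values[off] == 0))
    }
    # neutral mode support equals the binary support inside the domain
    expect_equal(neutral$values, b$values)
  }
})
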