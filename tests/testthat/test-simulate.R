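test_that("environment stacks are deterministic, complete and not collinear", {
  cfg <- quick_config(seed = 1, n_layers = 9)
  s1 <- generate_env_stack(cfg)
  s2 <- generate_env_stack(cfg)
  expect_identical(s1, s2)
  expect_length(s1$layers, 9)
  for (l in s1$layers) {
    expect_equal(dim(l$values), c(40, 40))
    expect_false(anyNA(l$values))
  }
  C <- cor(nichecohesion:::env_cell_matrix(s1))
  diag(C) <- 0
  expect_lt(max(abs(C)), 0.95)
  # the elevation layer peaks around the barrier column
  elev <- s1$layers$elev$values
  col_means <- colMeans(elev)
  expect_lt(abs(which.max(col_means) - cfg$barrier_x), 8)
})

test_that("true niches honor the seasonal-shift and migrant controls", {
  cfg0 <- quick_config(seed = 2, seasonal_shift = 0, migrant_fraction = 0)
  stack <- generate_env_stack(cfg0)
  n0 <- generate_true_niches(cfg0, stack)
  ids <- vapply(n0, `[[`, "", "species_id")
  expect_true(all(vapply(n0, `[[`, TRUE, "resident")))
  expect_equal(length(n0), 2 * cfg0$n_species)  # both seasons for everyone
  for (sp in unique(ids)) {
    pair <- n0[ids == sp]
    expect_equal(pair[[1]]$center, pair[[2]]$center)
  }
  for (nic in n0) {
    ev <- eigen(nic$covariance, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }

  # displacement magnitude in SD units matches the configured shift
  cfg2 <- quick_config(seed = 3, n_species = 60, seasonal_shift = 2,
                       migrant_fraction = 0)
  stack2 <- generate_env_stack(cfg2)
  n2 <- generate_true_niches(cfg2, stack2)
  sds <- apply(nichecohesion:::env_cell_matrix(stack2), 2, sd)
  ids2 <- vapply(n2, `[[`, "", "species_id")
  disp <- vapply(unique(ids2), function(sp) {
    pair <- n2[ids2 == sp]
    sqrt(sum(((pair[[2]]$center - pair[[1]]$center) / sds)^2))
  }, 0)
  expect_lt(abs(mean(disp) - 2) / 2, 0.1)
})

test_that("occurrence sampling respects detection rate and slope limits", {
  # detection_rate = 1: occurrences are exactly the suitable cells
  cfg1 <- quick_config(seed = 4, detection_rate = 1, n_species = 6)
  sim1 <- suppressWarnings(simulate_study_system(cfg1))
  E <- nichecohesion:::env_cell_matrix(sim1$stack)
  cc <- cell_centroids(sim1$stack$geom)
  cut <- qchisq(0.95, cfg1$n_layers)
  ids <- vapply(sim1$niches, `[[`, "", "species_id")
  for (nic in sim1$niches) {
    m2 <- mahalanobis(E, nic$center, nic$covariance)
    suit <- which(m2 <= cut)
    if (nic$slope != "both")
      suit <- suit[nichecohesion:::slope_of_x(cc$x[suit], cfg1) == nic$slope]
    got <- sim1$occurrences[sim1$occurrences$species == nic$species_id &
                              sim1$occurrences$month ==
                              nichecohesion:::month_of_season(nic$season), ]
    expect_setequal(paste(got$x, got$y), paste(cc$x[suit], cc$y[suit]))
  }

  # slope-restricted species never cross the ridge
  ridge <- cfg1$barrier_x * cfg1$cell_size
  for (nic in sim1$niches) {
    got <- sim1$occurrences[sim1$occurrences$species == nic$species_id, ]
    if (nic$slope == "pacific") expect_true(all(got$x < ridge))
    if (nic$slope == "caribbean") expect_true(all(got$x >= ridge))
  }

  # detection_rate = 0.3: per-species retention is binomial around 0.3
  cfg3 <- quick_config(seed = 4, detection_rate = 0.3, n_species = 6)
  sim3 <- suppressWarnings(simulate_study_system(cfg3))
  n_suit <- nrow(sim1$occurrences)   # same seed => same niches/suitable sets
  n_kept <- nrow(sim3$occurrences)
  expect_lt(abs(n_kept - 0.3 * n_suit), 3 * sqrt(n_suit * 0.3 * 0.7) + 1)
})

test_that("region polygons partition the domain exactly", {
  cfg <- quick_config(seed = 5)
  reg <- generate_region_polygons(cfg)
  expect_equal(polygon_area(reg$pacific) + polygon_area(reg$caribbean),
               polygon_area(reg$domain))
  # midline barrier => equal slopes
  expect_equal(polygon_area(reg$pacific), polygon_area(reg$caribbean))
  # every cell centroid lies in exactly one slope polygon
  cc <- cell_centroids(grid_geom(cfg$grid_nx, cfg$grid_ny, cfg$cell_size))
  in_p <- point_in_polygon(cc$x, cc$y, reg$pacific)
  in_c <- point_in_polygon(cc$x, cc$y, reg$caribbean)
  expect_true(all(xor(in_p, in_c)))
})

test_that("fixture bundles round-trip and are reproducible byte for byte", {
  cfg <- quick_config(seed = 6, n_species = 4, grid_nx = 25, grid_ny = 25)
  sim <- suppressWarnings(simulate_study_system(cfg))
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  man1 <- write_fixture_bundle(sim$stack, sim$niches, sim$occurrences,
                               sim$regions, d1, cfg)
  expect_true(all(vapply(man1$files, function(f) nchar(f$md5) == 32, TRUE)))

  back <- read_env_stack(d1)
  expect_equal(back$layer_names, sim$stack$layer_names)
  for (nm in back$layer_names)
    expect_equal(back$layers[[nm]]$values, sim$stack$layers[[nm]]$values,
                 tolerance = 1e-6, ignore_attr = TRUE)

  sim_b <- suppressWarnings(simulate_study_system(cfg))
  man2 <- write_fixture_bundle(sim_b$stack, sim_b$niches, sim_b$occurrences,
                               sim_b$regions, d2, cfg)
  expect_identical(vapply(man1$files, `[[`, "", "md5"),
                   vapply(man2$files, `[[`, "", "md5"))
  unlink(c(d1, d2), recursive = TRUE)
})
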