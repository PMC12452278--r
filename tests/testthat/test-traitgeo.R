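test_that("trait stacking takes per-cell means and sample SDs across species", {
  maps <- list(
    sp_a = fake_hsi_map(c(0.2, 0.2, 1.0), id = "sp_a"),
    sp_b = fake_hsi_map(c(0.8, 0.8, 1.0), id = "sp_b")
  )
  traits <- tibble::tibble(
    species_id = c("sp_a", "sp_b"),
    trait_label = c("CM", "eSNCM") # both coarse mixotrophs
  )
  st <- stack_trait(maps, traits, "mixotroph")
  expect_equal(st$grid$mean, c(0.5, 0.5, 1.0))
  expect_equal(st$grid$sd, c(0.4242641, 0.4242641, 0), tolerance = 1e-6)
  expect_equal(st$n_species, 2)

  # identical members give zero SD everywhere
  same <- stack_trait(list(sp_a = maps$sp_a, sp_b = maps$sp_a), traits, "mixotroph")
  expect_true(all(same$grid$sd == 0))

  # a single member yields NA SD, flagged by n_species
  solo <- stack_trait(maps["sp_a"], traits, "mixotroph")
  expect_equal(solo$n_species, 1)
  expect_true(all(is.na(solo$grid$sd)))

  expect_error(stack_trait(maps, traits, "strict_phagotroph"), "no species map")
})

test_that("latitudinal profiles detect poleward trends and handle flatness", {
  g <- world_grid(15)
  gt <- tibble::as_tibble(g)
  # strictly poleward-decreasing suitability
  dec <- fake_trait_map(1 - abs(gt$lat) / 90, cell_ids = gt$cell_id)
  lp <- lat_profile(dec, g)
  expect_equal(lp$correlations$rho, c(-1, -1))
  expect_equal(lp$correlations$rho_abs, c(1, 1))
  expect_true(all(lp$correlations$p_value < 0.01))
  expect_equal(nrow(lp$profile), length(unique(gt$lat)))
  # zonal means are exact since the field is a function of latitude only
  expect_equal(lp$profile$hsi, 1 - abs(sort(unique(gt$lat))) / 90)

  # poleward-increasing flips the sign
  inc <- fake_trait_map(abs(gt$lat) / 90, cell_ids = gt$cell_id)
  expect_equal(lat_profile(inc, g)$correlations$rho, c(1, 1))

  # flat map: defined as no trend, not NA
  flat <- fake_trait_map(rep(0.7, nrow(gt)), cell_ids = gt$cell_id)
  lpf <- lat_profile(flat, g)
  expect_equal(lpf$correlations$rho, c(0, 0))
  expect_equal(lpf$correlations$p_value, c(1, 1))
})

test_that("map correlation is a symmetric rank correlation over cells", {
  set.seed(1)
  v <- runif(200)
  a <- fake_hsi_map(v)
  expect_equal(map_correlation(a, a)$rho, 1)
  expect_equal(map_correlation(a, fake_hsi_map(1 - v))$rho, -1)
  # invariant under strictly monotone transforms
  expect_equal(map_correlation(a, fake_hsi_map(v^3))$rho, 1)
  b <- fake_hsi_map(runif(200))
  expect_equal(map_correlation(a, b)$rho, map_correlation(b, a)$rho)
  expect_lt(abs(map_correlation(a, b)$rho), 0.2)
  expect_equal(map_correlation(a, b)$n_cells, 200)
  expect_error(map_correlation(a, fake_hsi_map(runif(10))), "grid mismatch")
})

test_that("biome summaries are area-weighted and bracket the cell values", {
  e <- tiny_env()
  g <- attr(e, "grid") %||% e$grid
  grid <- if (inherits(g, "world_grid")) g else world_grid(15)
  biomes <- generate_biomes(e)
  gt <- tibble::as_tibble(grid)

  # constant map: every biome mean is exactly the constant
  const <- fake_trait_map(rep(0.6, nrow(gt)), cell_ids = gt$cell_id)
  bs <- biome_stats(const, biomes, grid)
  expect_true(all(abs(bs$mean_hsi[bs$n_cells > 0] - 0.6) < 1e-12))
  expect_equal(sum(bs$n_cells), nrow(gt))

  # arbitrary map: each biome mean lies within its cell-value range
  set.seed(2)
  vals <- runif(nrow(gt))
  bs2 <- biome_stats(fake_trait_map(vals, cell_ids = gt$cell_id), biomes, grid)
  occupied <- bs2[bs2$n_cells > 0, ]
  for (i in seq_len(nrow(occupied))) {
    rng <- range(occupied$values[[i]])
    expect_gte(occupied$mean_hsi[i], rng[1] - 1e-12)
    expect_lte(occupied$mean_hsi[i], rng[2] + 1e-12)
  }

  # identical trait maps: pairwise Wilcoxon cannot reject anywhere
  pair <- list(t1 = fake_trait_map(vals, cell_ids = gt$cell_id),
               t2 = fake_trait_map(vals, cell_ids = gt$cell_id))
  both <- biome_stats(pair, biomes, grid)
  expect_true(all(both$tests$p_value > 0.9))
  expect_equal(nrow(both$means), 2 * nrow(bs))
})

test_that("intra-group variability orders traits by their SD fields", {
  e <- tiny_env()
  grid <- world_grid(15)
  gt <- tibble::as_tibble(grid)
  biomes <- generate_biomes(e)
  n <- nrow(gt)
  tight <- fake_trait_map(runif(n), sd = rep(0.1, n), cell_ids = gt$cell_id,
                          n_species = 3, label = "mixotroph")
  loose <- fake_trait_map(runif(n), sd = rep(0.4, n), cell_ids = gt$cell_id,
                          n_species = 3, label = "strict_phagotroph")
  iv <- intragroup_variability(
    list(mixotroph = tight, strict_phagotroph = loose), biomes, grid)
  expect_equal(iv$global$mean_sd[iv$global$trait == "mixotroph"], 0.1,
    tolerance = 1e-12)
  expect_equal(iv$global$mean_sd[iv$global$trait == "strict_phagotroph"], 0.4,
    tolerance = 1e-12)
  expect_true(all(iv$tests$p_value < 1e-10)) # disjoint SD distributions
  want <- ifelse(iv$by_biome$trait == "mixotroph", 0.1, 0.4)
  expect_equal(iv$by_biome$mean_sd, want, tolerance = 1e-9)

  solo <- fake_trait_map(runif(n), sd = NA_real_, cell_ids = gt$cell_id,
                         n_species = 1, label = "strict_phototroph")
  expect_warning(
    iv2 <- intragroup_variability(
      list(mixotroph = tight, strict_phototroph = solo), biomes, grid),
    "excluded"
  )
  expect_equal(iv2$global$trait, "mixotroph")
  expect_error(
    suppressWarnings(intragroup_variability(list(s = solo), biomes, grid)),
    "no trait"
  )
})

test_that("environment PCA with HSI overlays reports faithful correlations", {
  e <- tiny_env()
  ann <- env_annual(e)
  # supplementary map that copies SST: its component correlations must match
  # the direct correlation of SST with the scores
  sst_map <- fake_hsi_map(ann$SST, cell_ids = ann$cell_id, id = "sstcopy")
  p <- hsi_env_pca(e, list(sstcopy = sst_map))
  direct <- cor(ann$SST, p$scores)
  s <- p$supplementary_correlations
  s <- s[s$variable == "sstcopy", ]
  got <- s$correlation[match(colnames(p$scores), s$component)]
  expect_equal(got, as.numeric(direct), tolerance = 1e-10)
  expect_true(all(abs(s$correlation) <= 1 + 1e-12))

  # constant overlay is degenerate, not an error
  flat_map <- fake_hsi_map(rep(0.5, nrow(ann)), cell_ids = ann$cell_id)
  p2 <- hsi_env_pca(e, list(flat = flat_map))
  expect_true(all(p2$supplementary_correlations$degenerate))
})
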