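test_that("Jaccard index matches its set definition and handles empty unions", {
  expect_equal(jaccard_index(3, 1, 2), 0.5)
  expect_equal(jaccard_index(0, 0, 0), 0)
  expect_equal(jaccard_index(5, 0, 0), 1)

  # brute-force oracle on random binary vectors
  set.seed(1)
  for (i in 1:50) {
    obs <- rbinom(40, 1, 0.4)
    pred <- rbinom(40, 1, 0.4)
    inter <- sum(obs & pred)
    uni <- sum(obs | pred)
    want <- if (uni == 0) 0 else inter / uni
    expect_equal(
      jaccard_index(sum(obs & pred), sum(!obs & pred), sum(obs & !pred)),
      want
    )
  }
})

test_that("threshold search maximises Jaccard on the grid, ties to lower", {
  set.seed(2)
  for (i in 1:20) {
    obs <- rbinom(60, 1, 0.5)
    prob <- runif(60)
    bt <- best_threshold(obs, prob)
    grid <- seq(0.01, 0.99, by = 0.01)
    js <- vapply(grid, function(t) {
      pr <- as.integer(prob >= t)
      tp <- sum(obs & pr); fp <- sum(!obs & pr); fn <- sum(obs & !pr)
      if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
    }, numeric(1))
    expect_equal(bt$jaccard, max(js))
    expect_equal(bt$threshold, grid[which(js == max(js))[1]])
  }
  # perfectly separated probabilities reach Jaccard 1 at the lowest such cut
  obs <- c(0, 0, 1, 1)
  bt <- best_threshold(obs, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(bt$jaccard, 1)
  expect_equal(bt$threshold, 0.21)
})

test_that("presence-absence assembly labels, skips, and predictor lookup", {
  e <- tiny_env()
  counts <- rbind(
    common = c(5, 0, 2, 1, 0, 3),
    absent_everywhere_but_one = c(0, 0, 0, 9, 0, 0),
    everywhere = c(1, 2, 3, 4, 5, 6)
  )
  comm <- toy_community(counts)
  pa <- build_pa(comm, "common", e, min_occurrences = 2)
  expect_s3_class(pa, "sdm_pa")
  expect_equal(pa$labels, c(1L, 0L, 1L, 1L, 0L, 1L))
  expect_equal(nrow(pa$predictors), 6)
  expect_true(all(ENV_VARIABLES %in% colnames(pa$predictors)))
  # predictor rows are the climatology at each site's cell and month
  row1 <- e$monthly[e$monthly$cell_id == comm$sites$cell_id[1] &
                      e$monthly$month == comm$sites$month[1], ]
  expect_equal(unname(pa$predictors[1, "SST"]), row1$SST)

  sk <- build_pa(comm, "absent_everywhere_but_one", e, min_occurrences = 20)
  expect_s3_class(sk, "sdm_skip")
  expect_match(sk$reason, "1 presences")
  sk2 <- build_pa(comm, "everywhere", e, min_occurrences = 2)
  expect_s3_class(sk2, "sdm_skip")
  expect_match(sk2$reason, "no absences")
  expect_error(build_pa(comm, "ghost", e), "absent from table")
})

test_that("collinearity screening keeps the more important of each pair", {
  set.seed(3)
  a <- rnorm(100)
  X <- cbind(a = a, b = a + rnorm(100, sd = 1e-3), c = rnorm(100))
  # b duplicates a; importance decides which survives
  expect_equal(screen_collinearity(X, c(a = 0.9, b = 0.1, c = 0.5)), c("a", "c"))
  expect_equal(screen_collinearity(X, c(a = 0.1, b = 0.9, c = 0.5)), c("b", "c"))
  # with the maximal cutoff nothing is dropped
  expect_equal(screen_collinearity(X, c(a = 1, b = 1, c = 1), rho_cut = 1),
    c("a", "b", "c"))
  # chain a~b~c with c most important keeps c and drops both neighbours
  Xc <- cbind(a = a, b = a + rnorm(100, sd = 1e-3), c = a + rnorm(100, sd = 1e-3))
  kept <- screen_collinearity(Xc, c(a = 0.2, b = 0.3, c = 0.9))
  expect_equal(kept, "c")
  expect_equal(screen_collinearity(X[, "a", drop = FALSE], c(a = 1)), "a")
})

test_that("permutation importance ranks the informative predictor first", {
  e <- tiny_env()
  set.seed(4)
  n <- 200
  sst <- runif(n, -2, 30)
  noise <- rnorm(n)
  p <- plogis(3 - 0.15 * (sst - 20)^2)
  y <- rbinom(n, 1, p)
  pa <- structure(
    list(species_id = "toy", site_ids = as.character(1:n), labels = y,
         predictors = cbind(SST = sst, junk = noise)),
    class = "sdm_pa"
  )
  imp <- preliminary_importance(pa, seed = 1)
  expect_gt(imp[["SST"]], imp[["junk"]])
  expect_true(all(imp >= 0 & imp <= 1))
  # constant predictor gets zero importance
  pa$predictors <- cbind(pa$predictors, flat = 1)
  imp2 <- preliminary_importance(pa, seed = 1)
  expect_equal(unname(imp2[["flat"]]), 0)
  # determinism
  expect_equal(preliminary_importance(pa, seed = 1), imp2)
})

test_that("quadratic logistic family recovers planted coefficients", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n)
  eta <- 0.5 + 1.2 * x - 0.8 * x^2
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_glm_quadratic(cbind(x = x), y)
  expect_equal(fit$status, "ok")
  b <- fit$coefficients
  expect_lt(abs(b[["(Intercept)"]] - 0.5) / 0.5, 0.3)
  expect_lt(abs(b[["x"]] - 1.2) / 1.2, 0.15)
  expect_lt(abs(b[["x_sq"]] - (-0.8)) / 0.8, 0.15)
  # predictions agree with the closed form at the fitted coefficients
  newx <- cbind(x = c(-1, 0, 2))
  expect_equal(
    fit$predict(newx),
    as.numeric(plogis(b[1] + b[2] * newx[, 1] + b[3] * newx[, 1]^2))
  )
})

test_that("all four families fit a separable niche and stay in [0, 1]", {
  set.seed(6)
  n <- 300
  sst <- runif(n, 0, 30)
  chla <- runif(n, 0, 2)
  y <- as.integer(sst > 12 & sst < 22)
  pa <- structure(
    list(species_id = "toy", site_ids = as.character(1:n), labels = y,
         predictors = cbind(SST = sst, Chla = chla)),
    class = "sdm_pa"
  )
  for (fam in SDM_FAMILIES) {
    m <- fit_family(pa, fam, seed = 11)
    expect_equal(m$status, "ok", label = fam)
    p <- m$predict(pa$predictors)
    expect_true(all(p >= 0 & p <= 1), label = fam)
    # in-sample threshold-optimal Jaccard should be high for this easy niche
    expect_gt(best_threshold(y, p)$jaccard, 0.8, label = fam)
  }
  # ANN refits identically under the same seed
  a1 <- fit_family(pa, "ANN", seed = 3)
  a2 <- fit_family(pa, "ANN", seed = 3)
  expect_equal(a1$predict(pa$predictors), a2$predict(pa$predictors))
})

test_that("fit scheduling enumerates species x family x repetition", {
  sched <- schedule_fits(sprintf("sp%02d", 1:72), n_reps = 5)
  expect_equal(nrow(sched), 72 * 4 * 5)
  expect_equal(nrow(dplyr::distinct(sched)), nrow(sched))
  sched1 <- schedule_fits("a", families = "GLM", n_reps = 2)
  expect_equal(sched1$cv_rep, 1:2)
})

test_that("cross-validation retains good members and respects the cutoff", {
  set.seed(7)
  n <- 250
  sst <- runif(n, 0, 30)
  y <- as.integer(sst > 10 & sst < 20)
  pa <- structure(
    list(species_id = "toy", site_ids = as.character(1:n), labels = y,
         predictors = cbind(SST = sst, junk = rnorm(n))),
    class = "sdm_pa"
  )
  ens <- cross_validate(pa, families = c("GLM", "GAM"), n_reps = 3, seed = 1)
  expect_equal(ens$n_trained, 6)
  expect_equal(nrow(ens$manifest), 6)
  expect_equal(ens$n_retained, sum(ens$manifest$retained))
  # an easy separable niche retains nearly everything with high Jaccard
  expect_gte(ens$n_retained, 5)
  expect_true(all(ens$manifest$jaccard_validation[ens$manifest$retained] > 0.3))
  # retention honours a prohibitive cutoff
  ens2 <- cross_validate(pa, families = "GLM", n_reps = 2,
                         retention_cutoff = 1, seed = 1)
  expect_equal(ens2$n_retained, 0)
  # determinism of the manifest under a fixed seed
  ens3 <- cross_validate(pa, families = c("GLM", "GAM"), n_reps = 3, seed = 1)
  expect_equal(ens$manifest, ens3$manifest)
  # stratum starvation errors out
  pa_few <- pa
  pa_few$labels <- c(1L, rep(0L, n - 1))
  expect_error(cross_validate(pa_few), "stratum is empty")
})

test_that("projection takes the committee mean of member binary maps", {
  e <- tiny_env()
  nm <- nrow(e$monthly)
  always <- fake_member(function(X) rep(1, nrow(as.matrix(X))))
  never <- fake_member(function(X) rep(0, nrow(as.matrix(X))))
  ens <- fake_ensemble(list(always, never), predictor_names = c("SST", "Chla"))
  hm <- project_hsi(ens, e)
  expect_true(all(hm$monthly$hsi == 0.5))
  expect_true(all(hm$annual$hsi == 0.5))
  expect_equal(nrow(hm$annual), nrow(e$grid))

  # single member: HSI is its binary map, here cold cells of month 1
  cold <- fake_member(function(X) as.numeric(as.matrix(X)[, "SST"] < 10),
                      threshold = 0.5)
  h1 <- project_hsi(fake_ensemble(list(cold), c("SST")), e)
  m1 <- h1$monthly[h1$monthly$month == 1, ]
  sst1 <- e$monthly[e$monthly$month == 1, ]
  expect_equal(m1$hsi, as.numeric(sst1$SST < 10))
  expect_true(all(h1$monthly$hsi %in% c(0, 1)))

  # duplicating a member leaves the committee fraction unchanged
  h2 <- project_hsi(fake_ensemble(list(cold, cold), c("SST")), e)
  expect_equal(h2$annual$hsi, h1$annual$hsi)

  expect_error(project_hsi(fake_ensemble(list(), c("SST")), e), "empty ensemble")
  expect_error(
    project_hsi(fake_ensemble(list(always), c("NOTAVAR")), e),
    "missing from climatology"
  )
})

test_that("the per-community driver models, skips and projects end to end", {
  e <- tiny_env()
  set.seed(8)
  n_sites <- 120
  cells <- sample(nrow(e$grid), n_sites, replace = TRUE)
  months <- sample(1:12, n_sites, replace = TRUE)
  envm <- dplyr::left_join(
    tibble::tibble(cell_id = cells, month = months),
    e$monthly, by = c("cell_id", "month")
  )
  suit <- plogis(4 - 0.1 * (envm$SST - 18)^2)
  counts <- rbind(
    nicheic = rbinom(n_sites, 20, suit * 0.8),
    rareling = c(rep(1, 5), rep(0, n_sites - 5))
  )
  colnames(counts) <- sprintf("site%03d", seq_len(n_sites))
  sites <- tibble::tibble(
    site_id = colnames(counts), cell_id = cells,
    lat = e$grid$lat[cells], lon = e$grid$lon[cells],
    depth_m = 10, month = months, mld_m = 60
  )
  species <- tibble::tibble(species_id = rownames(counts), genus_assigned = TRUE)
  comm <- community_tbl(counts, sites, species)
  run <- sdm_all(comm, e, families = c("GLM", "GAM"), n_reps = 2,
                 min_occurrences = 20, seed = 2)
  expect_s3_class(run, "sdm_run")
  expect_true("rareling" %in% run$skipped$species_id)
  expect_true("nicheic" %in% names(run$ensembles))
  expect_lte(length(run$ensembles$nicheic$predictor_names), 4)
  if (run$ensembles$nicheic$n_retained > 0) {
    expect_true("nicheic" %in% names(run$maps))
    expect_true(all(run$maps$nicheic$annual$hsi >= 0 &
                      run$maps$nicheic$annual$hsi <= 1))
  }
  expect_equal(nrow(run$manifest), length(run$ensembles) * 2 * 2)
})
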