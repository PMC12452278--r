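ENV_SITE_VARIABLES <- c(
  "SST", "SSS", "NO3", "PO4", "Si", "MLD", "PAR", "O2",
  "Sistar", "Nstar", "Chla"
)

#' Default end-to-end pipeline configuration
#'
#' Stage blocks mirror the pipeline order: simulate, community, envspace,
#' ordination, sdm, traitmaps; every default named here is the corresponding
#' function default. Unknown keys are rejected by [run_pipeline()].
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    resolution = 5,
    simulate = list(
      n_sites = 300, depth = 2000,
      n_per_trait = c(mixotroph = 20, strict_phototroph = 20,
                      strict_phagotroph = 20),
      overdispersion = NULL
    ),
    community = list(
      min_reads = 100, k_categories = 3, euphotic_max_depth = 200,
      counts_path = NULL, sites_path = NULL, traits_path = NULL
    ),
    envspace = list(k = 4, variance_threshold = 0.8),
    ordination = list(rv_threshold = 0.9, max_species = 90),
    sdm = list(
      families = SDM_FAMILIES, n_reps = 5, retention = 0.3,
      min_occ = 20, top_n = 4
    ),
    traitmaps = list(weights = "cos")
  )
}

validate_config <- function(config, template = default_pipeline_config(),
                            path = "config") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown) > 0) {
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(config[[nm]])) {
      validate_config(config[[nm]], template[[nm]], paste0(path, "$", nm))
    }
  }
  invisible(TRUE)
}

merge_config <- function(config) {
  validate_config(config)
  utils::modifyList(default_pipeline_config(), config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic-to-trait-maps pipeline
#'
#' Executes simulate, community, envspace, ordination, sdm and traitmaps in
#' order, writing every artifact under `out_dir` and returning a manifest
#' with a content hash per file; identical `(config, seed)` give identical
#' hashes. When `community$counts_path`/`sites_path`/`traits_path` are set
#' the simulate stage is skipped and the pipeline starts from the supplied
#' tables (trait maps are then only produced for species with annotations).
#'
#' @param config Configuration list (see [default_pipeline_config()];
#'   partial lists are merged over the defaults, unknown keys rejected
#'   before any stage runs).
#' @param seed Global integer seed, fanned out to per-stage seeds.
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_run`: `manifest` (tibble `file`,
#'   `md5`), `results` (per-stage R objects), `log` (stage timing tibble).
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = tempfile("run")) {
  cfg <- merge_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log <- list()
  results <- list()
  tick <- function(stage, t0) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, seconds = as.numeric(Sys.time() - t0, units = "secs"))
  }
  path <- function(...) file.path(out_dir, paste0(...))

  grid <- world_grid(cfg$resolution)
  env <- generate_environment(grid, seed = seed)
  biomes <- generate_biomes(env)

  user_input <- !is.null(cfg$community$counts_path)
  t0 <- Sys.time()
  if (user_input) {
    comm <- run_stage("community", read_community(
      cfg$community$counts_path, cfg$community$sites_path))
    traits <- run_stage("community", read_traits(cfg$community$traits_path))
    truth <- NULL
  } else {
    sim <- run_stage("simulate", {
      specs <- generate_species(cfg$simulate$n_per_trait, env, seed = seed)
      simulate_sampling(specs, env,
        n_sites = cfg$simulate$n_sites, depth = cfg$simulate$depth,
        seed = seed, overdispersion = cfg$simulate$overdispersion)
    })
    comm <- sim$community
    traits <- sim$traits
    truth <- sim$truth
    run_stage("simulate", {
      write_env_clim(env, path("environment.tsv"))
      write_biomes(biomes, grid, path("biomes.tsv"))
      write_community(comm, path("counts.tsv"), path("sites.tsv"),
                      path("species.tsv"))
      write_traits(traits, path("traits.csv"))
    })
    files <- c(files, path("environment.tsv"), path("biomes.tsv"),
               path("biomes.tsv.vocab.csv"), path("counts.tsv"),
               path("sites.tsv"), path("species.tsv"), path("traits.csv"))
    results$simulate <- sim
  }
  tick("simulate", t0)

  t0 <- Sys.time()
  commres <- run_stage("community", {
    filtered <- filter_community(comm, min_reads = cfg$community$min_reads,
      euphotic_max_depth = cfg$community$euphotic_max_depth)
    metrics <- species_metrics(filtered)
    metrics <- classify_ubiquity(metrics, k = cfg$community$k_categories)
    tests <- dplyr::bind_rows(
      trait_group_test(metrics, traits, "occupancy"),
      trait_group_test(metrics, traits, "evenness")
    )
    out <- dplyr::left_join(metrics,
      traits[, c("species_id", "trait_label", "coarse_label")],
      by = "species_id")
    write_csv_plain(out, path("species_metrics.csv"))
    write_csv_plain(tests, path("trait_group_tests.csv"))
    list(filtered = filtered, metrics = metrics, tests = tests)
  })
  files <- c(files, path("species_metrics.csv"), path("trait_group_tests.csv"))
  results$community <- commres
  tick("community", t0)

  filtered <- commres$filtered
  site_env <- dplyr::left_join(filtered$sites[, c("site_id", "cell_id")],
                               env_annual(env), by = "cell_id")

  t0 <- Sys.time()
  envres <- run_stage("envspace", {
    pca <- env_pca(site_env[, ENV_SITE_VARIABLES])
    hc <- env_hcpc(pca, k = cfg$envspace$k,
                   variance_threshold = cfg$envspace$variance_threshold)
    write_csv_plain(tidy(pca), path("pca_loadings.csv"))
    write_csv_plain(
      data.frame(site_id = site_env$site_id, cluster = hc$cluster),
      path("site_clusters.csv"))
    list(pca = pca, hcpc = hc)
  })
  files <- c(files, path("pca_loadings.csv"), path("site_clusters.csv"))
  results$envspace <- envres
  tick("envspace", t0)

  t0 <- Sys.time()
  ordres <- run_stage("ordination", {
    Y <- relative_hellinger(filtered)
    sel <- escoufier_select(Y, threshold = cfg$ordination$rv_threshold,
                            max_k = min(cfg$ordination$max_species, ncol(Y)))
    Ysel <- Y[, sel$selected, drop = FALSE]
    X <- site_env[, ENV_SITE_VARIABLES]
    aic <- aic_backward_select(Ysel, X)
    rda <- rda_fit(Ysel, X[, aic$selected, drop = FALSE])
    write_csv_plain(
      data.frame(step = seq_along(sel$rv_trajectory),
                 species = sel$selected, rv = sel$rv_trajectory),
      path("escoufier_trace.csv"))
    write_csv_plain(aic$trace, path("aic_trace.csv"))
    write_csv_plain(
      tibble::as_tibble(rda$site_scores) |>
        dplyr::mutate(site_id = rownames(Y), .before = 1),
      path("rda_site_scores.csv"))
    write_csv_plain(
      tibble::as_tibble(rda$species_scores, rownames = "species_id"),
      path("rda_species_scores.csv"))
    write_csv_plain(
      tibble::as_tibble(rda$biplot_scores, rownames = "predictor"),
      path("rda_biplot_scores.csv"))
    list(escoufier = sel, aic = aic, rda = rda)
  })
  files <- c(files, path("escoufier_trace.csv"), path("aic_trace.csv"),
             path("rda_site_scores.csv"), path("rda_species_scores.csv"),
             path("rda_biplot_scores.csv"))
  results$ordination <- ordres
  tick("ordination", t0)

  t0 <- Sys.time()
  sdmres <- run_stage("sdm", {
    annotated <- traits$species_id[traits$coarse_label != "unannotated"]
    run <- sdm_all(filtered, env,
      species_ids = intersect(rownames(filtered$counts), annotated),
      min_occurrences = cfg$sdm$min_occ, families = cfg$sdm$families,
      n_reps = cfg$sdm$n_reps, retention_cutoff = cfg$sdm$retention,
      top_n = cfg$sdm$top_n, seed = seed)
    write_csv_plain(run$manifest, path("sdm_manifest.csv"))
    ann <- purrr::imap(run$maps, function(m, sp) {
      dplyr::mutate(m$annual, species_id = sp, .before = 1)
    }) |> purrr::list_rbind()
    write_tsv_plain(ann, path("species_hsi_annual.tsv"))
    run
  })
  files <- c(files, path("sdm_manifest.csv"), path("species_hsi_annual.tsv"))
  results$sdm <- sdmres
  tick("sdm", t0)

  t0 <- Sys.time()
  traitres <- run_stage("traitmaps", {
    present <- intersect(
      c("mixotroph", "strict_phototroph", "strict_phagotroph"),
      unique(traits$coarse_label[traits$species_id %in% names(sdmres$maps)]))
    tmaps <- setNames(
      purrr::map(present, ~ stack_trait(sdmres$maps, traits, .x)), present)
    for (tr in present) {
      write_hsi(tmaps[[tr]], grid, path("trait_hsi_", tr, ".tsv"))
      files <- c(files, path("trait_hsi_", tr, ".tsv"))
    }
    profs <- purrr::map(tmaps, lat_profile, grid = grid)
    cors <- if (length(tmaps) >= 2) {
      prs <- utils::combn(present, 2, simplify = FALSE)
      purrr::map(prs, function(p) {
        dplyr::mutate(map_correlation(tmaps[[p[1]]], tmaps[[p[2]]]),
                      trait_a = p[1], trait_b = p[2], .before = 1)
      }) |> purrr::list_rbind()
    } else NULL
    bstats <- biome_stats(tmaps, biomes, grid)
    ivar <- suppressWarnings(intragroup_variability(tmaps, biomes, grid))
    hpca <- hsi_env_pca(env, tmaps)
    write_csv_plain(
      dplyr::select(bstats$means, -"values"), path("biome_means.csv"))
    write_csv_plain(ivar$global, path("intragroup_sd.csv"))
    if (!is.null(cors)) write_csv_plain(cors, path("map_correlations.csv"))
    write_csv_plain(
      purrr::imap(profs, ~ dplyr::mutate(.x$correlations, trait = .y,
                                         .before = 1)) |> purrr::list_rbind(),
      path("lat_profile_correlations.csv"))
    list(trait_maps = tmaps, profiles = profs, correlations = cors,
         biomes = bstats, intragroup = ivar, env_pca = hpca)
  })
  files <- c(files, path("biome_means.csv"), path("intragroup_sd.csv"),
             path("lat_profile_correlations.csv"))
  if (!is.null(traitres$correlations)) {
    files <- c(files, path("map_correlations.csv"))
  }
  results$traitmaps <- traitres
  tick("traitmaps", t0)

  files <- unique(files[file.exists(files)])
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  write_csv_plain(manifest, file.path(out_dir, "manifest.csv"))
  structure(
    list(manifest = manifest, results = results,
         log = purrr::list_rbind(log), out_dir = out_dir,
         truth = if (user_input) NULL else results$simulate$truth),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$manifest), "artifacts in", x$out_dir, "\n")
  print(x$log)
  invisible(x)
}
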