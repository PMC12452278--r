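#' Stack species HSI maps into a trait-level map
#'
#' Per-cell unweighted mean of the annual HSI grids of every species
#' carrying the coarse trait, plus the per-cell across-species sample
#' standard deviation (n - 1 denominator), which measures how much species
#' sharing the trait disagree about a location.
#'
#' @param maps Named list of `hsi_map` objects (names = species ids) or an
#'   `sdm_run`.
#' @param traits Tibble with `species_id` and `trait_label` and/or
#'   `coarse_label`.
#' @param trait_label Coarse trait to stack (e.g. `"mixotroph"`).
#' @return Object of class `trait_hsi`: `trait_label`, `grid` tibble
#'   (`cell_id`, `mean`, `sd`), `n_species`, `species_ids`. With a single
#'   member species the SD is undefined and returned as `NA` (flagged by
#'   `n_species`).
#' @export
stack_trait <- function(maps, traits, trait_label) {
  if (inherits(maps, "sdm_run")) maps <- maps$maps
  if (!"coarse_label" %in% colnames(traits)) {
    traits$coarse_label <- coarse_trait(traits$trait_label)
  }
  ids <- traits$species_id[traits$coarse_label == trait_label]
  ids <- intersect(names(maps), ids)
  if (length(ids) == 0) stop("no species map with trait label ", trait_label)
  grids <- vapply(ids, function(sp) maps[[sp]]$annual$hsi,
                  numeric(nrow(maps[[ids[1]]]$annual)))
  grids <- matrix(grids, ncol = length(ids))
  grid <- tibble::tibble(
    cell_id = maps[[ids[1]]]$annual$cell_id,
    mean = rowMeans(grids),
    sd = if (length(ids) >= 2) apply(grids, 1, stats::sd) else NA_real_
  )
  structure(
    list(trait_label = trait_label, grid = grid,
         n_species = length(ids), species_ids = ids),
    class = "trait_hsi"
  )
}

#' @export
print.trait_hsi <- function(x, ...) {
  cat("Trait HSI map (", x$trait_label, "): ", x$n_species,
      " species, mean annual HSI ", sprintf("%.3f", mean(x$grid$mean)),
      "\n", sep = "")
  invisible(x)
}

#' Latitudinal profile of a trait HSI map and its poleward trend
#'
#' Zonal (area-weighted over longitudes) mean HSI per latitude band, and
#' Spearman correlations between band HSI and absolute band latitude
#' computed separately for the northern and southern hemispheres, the
#' equator-adjacent band entering both. A poleward decrease yields a
#' negative signed rho; `rho_abs` reports its magnitude.
#'
#' @param map A `trait_hsi` (or `hsi_map`; the annual grid is used).
#' @param grid The `world_grid` the map lives on.
#' @return Object of class `lat_profile`: `profile` tibble (`lat`, `hsi`)
#'   and `correlations` tibble (`hemisphere`, `rho`, `rho_abs`, `p_value`,
#'   `n_bands`).
#' @export
lat_profile <- function(map, grid) {
  assert_world_grid(grid)
  vals <- trait_values(map)
  d <- dplyr::left_join(vals, tibble::as_tibble(grid), by = "cell_id")
  prof <- d |>
    dplyr::group_by(lat = .data$lat) |>
    dplyr::summarise(hsi = weighted_mean_w(.data$value, .data$area_w),
                     .groups = "drop")
  hemis <- list(north = prof$lat >= 0, south = prof$lat <= 0)
  # ensure the band nearest the equator joins both hemispheres
  nearest <- which.min(abs(prof$lat))
  hemis$north[nearest] <- TRUE
  hemis$south[nearest] <- TRUE
  cors <- purrr::imap(hemis, function(sel, hemi) {
    p <- prof[sel, ]
    if (nrow(p) < 3) stop("need >= 3 latitude bands per hemisphere")
    if (stats::sd(p$hsi) <= 1e-10 * (1 + abs(mean(p$hsi)))) {
      # flat profile has no trend: report zero, not NA
      rho <- 0
      pval <- 1
    } else {
      ct <- suppressWarnings(
        stats::cor.test(p$hsi, abs(p$lat), method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate)
      pval <- ct$p.value
    }
    tibble::tibble(
      hemisphere = hemi, rho = rho, rho_abs = abs(rho), p_value = pval,
      n_bands = nrow(p)
    )
  }) |> purrr::list_rbind()
  structure(list(profile = prof, correlations = cors), class = "lat_profile")
}

# annual cell values of a trait_hsi or hsi_map as tibble(cell_id, value)
trait_values <- function(map) {
  if (inherits(map, "trait_hsi")) {
    tibble::tibble(cell_id = map$grid$cell_id, value = map$grid$mean)
  } else if (inherits(map, "hsi_map")) {
    tibble::tibble(cell_id = map$annual$cell_id, value = map$annual$hsi)
  } else {
    stop("expected a trait_hsi or hsi_map")
  }
}

#' @export
print.lat_profile <- function(x, ...) {
  print(x$correlations)
  invisible(x)
}

#' Spearman correlation between two HSI maps
#'
#' Rank correlation over all (pairwise-complete) ocean cells; the standard
#' comparison of how similarly two traits perceive the global environment.
#'
#' @param a,b `trait_hsi` or `hsi_map` objects on the same grid.
#' @return Tibble with `rho`, `p_value`, `n_cells`.
#' @export
map_correlation <- function(a, b) {
  va <- trait_values(a)
  vb <- trait_values(b)
  if (!identical(va$cell_id, vb$cell_id)) stop("grid mismatch between maps")
  ok <- is.finite(va$value) & is.finite(vb$value)
  ct <- suppressWarnings(stats::cor.test(va$value[ok], vb$value[ok],
    method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_cells = sum(ok))
}

#' Biome-level HSI summaries and cross-trait comparisons
#'
#' Per biome: the area-weighted mean of the trait's mean HSI grid and the
#' distribution of cell values. Given several trait maps (a named list),
#' also performs two-sided Wilcoxon rank-sum tests between every trait pair
#' within each biome, Holm-adjusted.
#'
#' @param map A `trait_hsi`/`hsi_map`, or a named list of them.
#' @param biomes A `biome_mask` aligned to the maps' grid.
#' @param grid The `world_grid` (for area weights).
#' @return For a single map: tibble (`biome`, `mean_hsi`, `n_cells`, and a
#'   list-column `values`); biomes without cells are reported with `NA`.
#'   For a list: list with `means` (tibble with `trait` column) and `tests`
#'   (pairwise Wilcoxon results per biome).
#' @export
biome_stats <- function(map, biomes, grid) {
  assert_world_grid(grid)
  if (is.list(map) && !inherits(map, c("trait_hsi", "hsi_map"))) {
    means <- purrr::imap(map, function(m, nm) {
      dplyr::mutate(biome_stats(m, biomes, grid), trait = nm, .before = 1)
    }) |> purrr::list_rbind()
    tests <- cross_trait_tests(purrr::map(map, trait_values), biomes)
    return(list(means = means, tests = tests))
  }
  vals <- trait_values(map)
  d <- vals |>
    dplyr::left_join(tibble::as_tibble(biomes), by = "cell_id") |>
    dplyr::left_join(tibble::as_tibble(grid), by = "cell_id")
  vocab <- attr(biomes, "vocabulary") %||% sort(unique(biomes$biome))
  purrr::map(vocab, function(bm) {
    cells <- d[d$biome == bm & !is.na(d$biome), ]
    tibble::tibble(
      biome = bm,
      mean_hsi = if (nrow(cells) == 0) NA_real_ else
        weighted_mean_w(cells$value, cells$area_w),
      n_cells = nrow(cells),
      values = list(cells$value)
    )
  }) |> purrr::list_rbind()
}

# two-sided Wilcoxon rank-sum across traits within each biome, Holm adjusted
cross_trait_tests <- function(value_tabs, biomes) {
  traits <- names(value_tabs)
  if (length(traits) < 2) return(NULL)
  bm <- tibble::as_tibble(biomes)
  res <- list()
  for (b in unique(bm$biome)) {
    cells <- bm$cell_id[bm$biome == b]
    for (i in seq_along(traits)) {
      for (j in seq_along(traits)) {
        if (i >= j) next
        xi <- value_tabs[[i]]$value[value_tabs[[i]]$cell_id %in% cells]
        xj <- value_tabs[[j]]$value[value_tabs[[j]]$cell_id %in% cells]
        xi <- xi[is.finite(xi)]; xj <- xj[is.finite(xj)]
        if (length(xi) == 0 || length(xj) == 0) next
        wt <- suppressWarnings(stats::wilcox.test(xi, xj))
        res[[length(res) + 1]] <- tibble::tibble(
          biome = b, trait_a = traits[i], trait_b = traits[j],
          statistic = unname(wt$statistic), p_value = wt$p.value
        )
      }
    }
  }
  out <- purrr::list_rbind(res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Intra-group variability of species responses
#'
#' How divergent are species within each trophic strategy? For each trait
#' with at least two mapped species: the area-weighted global mean of the
#' per-cell across-species HSI standard deviation, the per-biome SD
#' distributions, and pairwise cross-trait Wilcoxon tests on the SD cells
#' (Holm-adjusted).
#'
#' @param trait_maps Named list of `trait_hsi` objects (one per trait).
#' @param biomes A `biome_mask`.
#' @param grid The `world_grid`.
#' @return List: `global` tibble (`trait`, `mean_sd`, `n_species`),
#'   `by_biome` tibble (`trait`, `biome`, `mean_sd`, `n_cells`), `tests`
#'   (pairwise Wilcoxon on SD distributions). Traits with fewer than two
#'   species are excluded with a warning.
#' @export
intragroup_variability <- function(trait_maps, biomes, grid) {
  assert_world_grid(grid)
  usable <- purrr::keep(trait_maps, ~ .x$n_species >= 2)
  dropped <- setdiff(names(trait_maps), names(usable))
  if (length(dropped) > 0) {
    warning("trait(s) with < 2 species excluded: ", paste(dropped, collapse = ", "))
  }
  if (length(usable) == 0) stop("no trait with >= 2 species")
  gw <- tibble::as_tibble(grid)[, c("cell_id", "area_w")]
  sd_tabs <- purrr::map(usable, function(m) {
    tibble::tibble(cell_id = m$grid$cell_id, value = m$grid$sd)
  })
  global <- purrr::imap(usable, function(m, nm) {
    d <- dplyr::left_join(sd_tabs[[nm]], gw, by = "cell_id")
    tibble::tibble(trait = nm,
                   mean_sd = weighted_mean_w(d$value, d$area_w),
                   n_species = m$n_species)
  }) |> purrr::list_rbind()
  bm <- tibble::as_tibble(biomes)
  by_biome <- purrr::imap(sd_tabs, function(tab, nm) {
    d <- tab |>
      dplyr::left_join(bm, by = "cell_id") |>
      dplyr::left_join(gw, by = "cell_id") |>
      dplyr::filter(!is.na(.data$biome)) |>
      dplyr::group_by(trait = nm, biome = .data$biome) |>
      dplyr::summarise(mean_sd = weighted_mean_w(.data$value, .data$area_w),
                       n_cells = dplyr::n(), .groups = "drop")
    d
  }) |> purrr::list_rbind()
  tests <- cross_trait_tests(sd_tabs, biomes)
  list(global = global, by_biome = by_biome, tests = tests)
}

#' Environmental-space PCA with HSI maps as supplementary variables
#'
#' PCA of the 13 annual environmental fields over all ocean cells, with
#' trait-level or species-level annual HSI grids supplied as supplementary
#' quantitative variables: they do not shape the axes, but their
#' correlations with the leading components show where each trait (or
#' species) sits along the main environmental gradients.
#'
#' @param env An `env_clim`.
#' @param maps Named list of `trait_hsi` and/or `hsi_map` objects aligned to
#'   the climatology grid.
#' @param variables Active variables (default: all 13).
#' @return An [env_pca()] result whose `supplementary_correlations` has one
#'   block per map.
#' @export
hsi_env_pca <- function(env, maps, variables = ENV_VARIABLES) {
  stopifnot(inherits(env, "env_clim"))
  ann <- env_annual(env)
  supp <- purrr::map(maps, function(m) {
    v <- trait_values(m)
    if (!identical(v$cell_id, ann$cell_id)) stop("grid mismatch with climatology")
    v$value
  })
  env_pca(ann[, variables], standardize = TRUE,
          supplementary = tibble::as_tibble(supp))
}
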