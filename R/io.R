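# Plain-text readers/writers for every artifact the pipeline touches.
# Gridded fields travel as long-format TSV keyed by (month,) lat, lon;
# tables as TSV/CSV. Each writer has a matching reader (round-trip tested).

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

write_csv_plain <- function(x, path) {
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_csv_plain <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Write / read a community table
#'
#' The count matrix travels as TSV with species in rows and one column per
#' site id (first column `species_id`); site metadata and the per-species
#' genus flag travel as separate TSVs.
#'
#' @param table A `community_tbl`.
#' @param counts_path,sites_path,species_path File paths.
#' @return `write_community()` returns the paths invisibly;
#'   `read_community()` returns a `community_tbl`.
#' @export
write_community <- function(table, counts_path, sites_path,
                            species_path = NULL) {
  stopifnot(inherits(table, "community_tbl"))
  cts <- data.frame(species_id = rownames(table$counts), table$counts,
                    check.names = FALSE)
  write_tsv_plain(cts, counts_path)
  write_tsv_plain(table$sites, sites_path)
  if (!is.null(species_path)) write_tsv_plain(table$species, species_path)
  invisible(c(counts_path, sites_path, species_path))
}

#' @rdname write_community
#' @export
read_community <- function(counts_path, sites_path, species_path = NULL) {
  cts <- read_tsv_plain(counts_path)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$species_id
  storage.mode(m) <- "integer"
  sites <- read_tsv_plain(sites_path)
  species <- if (!is.null(species_path)) read_tsv_plain(species_path) else NULL
  community_tbl(m, sites, species)
}

#' Write / read a trophic-annotation table
#'
#' @param traits Tibble with `species_id`, `trait_label` (and optionally
#'   `coarse_label`, which is recomputed on read).
#' @param path CSV path.
#' @export
write_traits <- function(traits, path) {
  write_csv_plain(traits[, intersect(c("species_id", "trait_label"),
                                     colnames(traits))], path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  tr <- read_csv_plain(path)
  tr$coarse_label <- coarse_trait(tr$trait_label)
  tr
}

#' Write / read a monthly climatology as long-format TSV
#'
#' Columns: `month`, `lat`, `lon`, then one column per variable; the grid
#' is reconstructed from the latitude step on read.
#'
#' @param env An `env_clim`.
#' @param path TSV path.
#' @export
write_env_clim <- function(env, path) {
  stopifnot(inherits(env, "env_clim"))
  tab <- dplyr::left_join(env$monthly,
    tibble::as_tibble(env$grid)[, c("cell_id", "lat", "lon")], by = "cell_id")
  tab <- dplyr::select(tab, "month", "lat", "lon",
                       dplyr::all_of(attr(env, "variables")))
  write_tsv_plain(tab, path)
}

#' @rdname write_env_clim
#' @export
read_env_clim <- function(path) {
  tab <- read_tsv_plain(path)
  res <- min(diff(sort(unique(tab$lat))))
  grid <- world_grid(res)
  monthly <- dplyr::left_join(tab,
    tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")], by = c("lat", "lon"))
  vars <- setdiff(colnames(tab), c("month", "lat", "lon"))
  monthly <- dplyr::arrange(
    dplyr::select(monthly, "cell_id", "month", dplyr::all_of(vars)),
    .data$month, .data$cell_id)
  structure(list(grid = grid, monthly = monthly),
            variables = vars, class = "env_clim")
}

#' Write / read a biome mask (gridded labels + vocabulary sidecar)
#'
#' @param biomes A `biome_mask`.
#' @param grid The `world_grid` it lives on.
#' @param path TSV path for the labels; the ordered vocabulary goes to
#'   `<path>.vocab.csv`.
#' @export
write_biomes <- function(biomes, grid, path) {
  d <- dplyr::left_join(tibble::as_tibble(biomes),
    tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")], by = "cell_id")
  write_tsv_plain(d[, c("lat", "lon", "biome")], path)
  vocab <- attr(biomes, "vocabulary") %||% sort(unique(biomes$biome))
  write_csv_plain(data.frame(biome = vocab), paste0(path, ".vocab.csv"))
  invisible(path)
}

#' @rdname write_biomes
#' @export
read_biomes <- function(grid, path) {
  d <- read_tsv_plain(path)
  d <- dplyr::left_join(d, tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")],
                        by = c("lat", "lon"))
  vocab <- read_csv_plain(paste0(path, ".vocab.csv"))$biome
  out <- tibble::tibble(cell_id = d$cell_id, biome = d$biome)
  out <- dplyr::arrange(out, .data$cell_id)
  structure(out, vocabulary = vocab, class = c("biome_mask", class(out)))
}

#' Write an annual HSI grid (species or trait level) as TSV
#'
#' @param map `hsi_map` or `trait_hsi`.
#' @param grid The `world_grid`.
#' @param path TSV path.
#' @export
write_hsi <- function(map, grid, path) {
  g <- tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")]
  if (inherits(map, "trait_hsi")) {
    d <- dplyr::left_join(map$grid, g, by = "cell_id")
    write_tsv_plain(d[, c("lat", "lon", "mean", "sd")], path)
  } else {
    d <- dplyr::left_join(map$annual, g, by = "cell_id")
    write_tsv_plain(d[, c("lat", "lon", "hsi")], path)
  }
  invisible(path)
}
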