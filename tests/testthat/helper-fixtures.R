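# Small in-code fixtures shared across test files.

# coarse world + climatology, cached per session (deterministic)
tiny_env <- local({
  cache <- NULL
  function(res = 15, seed = 1) {
    if (is.null(cache)) {
      cache <<- generate_environment(world_grid(res), seed = seed)
    }
    cache
  }
})

# hand-built community table: counts species x sites, default metadata
toy_community <- function(counts, depth_m = NULL, mld_m = NULL, month = NULL,
                          genus_assigned = NULL) {
  ns <- ncol(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("sp%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("site%02d", seq_len(ns))
  }
  sites <- tibble::tibble(
    site_id = colnames(counts),
    cell_id = seq_len(ns),
    lat = seq(-60, 60, length.out = ns),
    lon = rep(0, ns),
    depth_m = depth_m %||% rep(10, ns),
    month = month %||% rep(6, ns),
    mld_m = mld_m %||% rep(50, ns)
  )
  species <- tibble::tibble(
    species_id = rownames(counts),
    genus_assigned = genus_assigned %||% rep(TRUE, nrow(counts))
  )
  community_tbl(counts, sites, species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..n as rows of a matrix
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# hsi_map built from a plain vector of annual values
fake_hsi_map <- function(values, cell_ids = seq_along(values), id = "sp") {
  structure(
    list(
      species_id = id,
      monthly = tibble::tibble(cell_id = cell_ids, month = 1L, hsi = values),
      annual = tibble::tibble(cell_id = cell_ids, hsi = values)
    ),
    class = "hsi_map"
  )
}

fake_trait_map <- function(mean, sd = NA_real_, cell_ids = seq_along(mean),
                           n_species = 2, label = "trait") {
  structure(
    list(
      trait_label = label,
      grid = tibble::tibble(cell_id = cell_ids, mean = mean, sd = sd),
      n_species = n_species, species_ids = character(n_species)
    ),
    class = "trait_hsi"
  )
}

# ensemble member with a fixed prediction closure (for projection tests)
fake_member <- function(value_fun, threshold = 0.5) {
  structure(
    list(
      family = "GLM", status = "ok",
      calibration_threshold = threshold, jaccard_validation = 1,
      predict = value_fun
    ),
    class = "sdm_member"
  )
}

fake_ensemble <- function(members, predictor_names, species_id = "sp") {
  structure(
    list(
      species_id = species_id, members = members,
      manifest = NULL, n_trained = length(members),
      n_retained = length(members), predictor_names = predictor_names
    ),
    class = "sdm_ensemble"
  )
}
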