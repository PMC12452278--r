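#' @importFrom rlang .data
#' @importFrom stats rnorm runif rlnorm rmultinom setNames
NULL

ENV_VARIABLES <- c(
  "SST", "SSS", "MLD", "PAR", "O2", "PIC", "Chla",
  "NO3", "PO4", "Si", "Nstar", "Sistar", "NPP"
)
SIMULATED_VARIABLES <- setdiff(ENV_VARIABLES, c("Nstar", "Sistar"))

#' Default configuration for the synthetic environment generator
#'
#' One entry per simulated variable with three knobs: `amplitude` scales the
#' latitudinally structured signal, `seasonality` the peak-to-trough monthly
#' cycle (in the variable's own units), `noise_sd` the i.i.d. per-cell,
#' per-month Gaussian noise. The nutrient-excess indices N* and Si* are never
#' simulated: they are recomputed from their parents.
#'
#' @return Named list of per-variable parameter lists.
#' @export
default_env_config <- function() {
  list(
    SST  = list(amplitude = 1, seasonality = 3.0, noise_sd = 0.4),
    SSS  = list(amplitude = 1, seasonality = 0.2, noise_sd = 0.15),
    MLD  = list(amplitude = 1, seasonality = 1.0, noise_sd = 3),
    PAR  = list(amplitude = 1, seasonality = 1.0, noise_sd = 10),
    O2   = list(amplitude = 1, seasonality = 2.0, noise_sd = 3),
    PIC  = list(amplitude = 1, seasonality = 0.0005, noise_sd = 0.0004),
    Chla = list(amplitude = 1, seasonality = 1.0, noise_sd = 0.05),
    NO3  = list(amplitude = 1, seasonality = 1.0, noise_sd = 0.5),
    PO4  = list(amplitude = 1, seasonality = 0.05, noise_sd = 0.03),
    Si   = list(amplitude = 1, seasonality = 1.0, noise_sd = 0.8),
    NPP  = list(amplitude = 1, seasonality = 1.0, noise_sd = 25)
  )
}

# Latitudinal "climatological" shapes. lat in degrees, lon in degrees,
# month 1..12. All shapes return the noise-free field; the local-summer
# index L is cos-phased so that July peaks in the north, January in the south.
env_shapes <- function(lat, lon, month, cfg) {
  rad <- lat * pi / 180
  alat <- abs(lat)
  phase <- cos(2 * pi * (month - 7) / 12) # +1 in July, -1 in January
  L <- phase * sin(rad)                   # local-summer index in [-1, 1]

  sst0 <- -2 + 31 * cos(rad)^1.3
  sst <- cfg$SST$amplitude * sst0 + cfg$SST$seasonality * L

  # equatorial productivity band + seasonal high-latitude bloom +
  # an eastern-boundary upwelling tongue giving longitudinal contrast
  npp0 <- 150 + 700 * exp(-(lat / 12)^2) +
    350 * exp(-((lon + 120) / 25)^2) * exp(-(lat / 30)^2)
  bloom <- 500 * exp(-((alat - 55) / 15)^2)
  npp <- cfg$NPP$amplitude * npp0 +
    cfg$NPP$seasonality * bloom * pmax(L, 0)

  chla0 <- 0.08 + 1.2 * exp(-(lat / 12)^2) + 0.8 * exp(-((alat - 55) / 15)^2)
  chla <- cfg$Chla$amplitude * chla0 +
    cfg$Chla$seasonality * 0.8 * exp(-((alat - 55) / 15)^2) * pmax(L, 0)

  no30 <- 24 * (alat / 90)^1.6 + 6 * exp(-(lat / 10)^2)
  no3 <- cfg$NO3$amplitude * no30 + cfg$NO3$seasonality * (-pmax(L, 0))
  po4 <- cfg$PO4$amplitude * (no30 / 14 + 0.05) +
    cfg$PO4$seasonality * (-pmax(L, 0))
  si <- cfg$Si$amplitude * (1.15 * no30 + 1) +
    cfg$Si$seasonality * (-pmax(L, 0))

  sss <- cfg$SSS$amplitude *
    (34 + 2.2 * exp(-((alat - 22) / 15)^2) - 1.2 * exp(-(lat / 10)^2) -
      1.5 * (alat / 90)^2) + cfg$SSS$seasonality * (-L)

  mld <- cfg$MLD$amplitude * (25 + 140 * (alat / 90)^1.5) *
    (1 - 0.7 * cfg$MLD$seasonality * L)

  par0 <- 450 * cos(rad)^1.2
  par <- cfg$PAR$amplitude * par0 * (1 + 0.45 * cfg$PAR$seasonality * L)

  o2 <- cfg$O2$amplitude * (190 + 3.4 * (30 - sst0)) +
    cfg$O2$seasonality * (-L)

  pic <- cfg$PIC$amplitude * (5e-4 + 4e-3 * exp(-((alat - 50) / 15)^2)) +
    cfg$PIC$seasonality * pmax(L, 0)

  list(
    SST = sst, SSS = sss, MLD = mld, PAR = par, O2 = o2, PIC = pic,
    Chla = chla, NO3 = no3, PO4 = po4, Si = si, NPP = npp
  )
}

#' Generate a synthetic monthly environmental climatology
#'
#' Builds 12 monthly gridded fields for 11 simulated variables plus the two
#' derived nutrient-excess indices. The fields are qualitative analogues of
#' surface-ocean climatologies: temperature decreases from equator to poles,
#' macronutrients anticorrelate with temperature, chlorophyll and primary
#' production show an equatorial band plus a seasonal high-latitude bloom.
#' N* = NO3 - 16 PO4 and Si* = Si - NO3 are always recomputed from their
#' parent fields, never simulated independently.
#'
#' @param grid A [world_grid()].
#' @param config Per-variable generation parameters; see
#'   [default_env_config()]. Names must be simulated variables.
#' @param seed Integer seed; the output is deterministic given
#'   `(config, seed)`.
#' @return An object of class `env_clim`: list with `grid` and `monthly`,
#'   a tibble with columns `cell_id`, `month` and the 13 variables.
#' @export
generate_environment <- function(grid, config = default_env_config(), seed = 1) {
  assert_world_grid(grid)
  cfg <- default_env_config()
  if (!is.null(config)) {
    unknown <- setdiff(names(config), SIMULATED_VARIABLES)
    if (length(unknown) > 0) {
      stop("unknown variable name(s) in config: ", paste(unknown, collapse = ", "))
    }
    for (v in names(config)) cfg[[v]] <- utils::modifyList(cfg[[v]], config[[v]])
  }
  monthly <- withr::with_seed(derive_seed(seed, "env"), {
    tab <- tidyr::expand_grid(month = 1:12, cell_id = grid$cell_id)
    tab <- dplyr::left_join(tab, grid, by = "cell_id")
    fields <- env_shapes(tab$lat, tab$lon, tab$month, cfg)
    n <- nrow(tab)
    for (v in SIMULATED_VARIABLES) {
      x <- fields[[v]] + rnorm(n, sd = cfg[[v]]$noise_sd)
      if (v %in% c("NO3", "PO4", "Si", "Chla", "NPP", "PAR", "MLD"))
        x <- pmax(x, 0)
      tab[[v]] <- x
    }
    tab$Nstar <- tab$NO3 - 16 * tab$PO4
    tab$Sistar <- tab$Si - tab$NO3
    dplyr::select(tab, "cell_id", "month", dplyr::all_of(ENV_VARIABLES))
  })
  structure(list(grid = grid, monthly = monthly),
    variables = ENV_VARIABLES, seed = seed, class = "env_clim"
  )
}

#' Annual-mean environmental fields
#'
#' @param env An `env_clim` object.
#' @return A tibble with `cell_id`, `lat`, `lon`, `area_w` and the per-cell
#'   annual mean (over the 12 months) of every variable.
#' @export
env_annual <- function(env) {
  stopifnot(inherits(env, "env_clim"))
  ann <- env$monthly |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(ENV_VARIABLES), mean),
      .groups = "drop"
    )
  dplyr::left_join(tibble::as_tibble(env$grid), ann, by = "cell_id")
}

#' @export
print.env_clim <- function(x, ...) {
  cat(
    "Synthetic monthly climatology:", nrow(x$grid), "cells x 12 months x",
    length(attr(x, "variables")), "variables\n"
  )
  invisible(x)
}

#' Default biome partition rules over SST x NPP space
#'
#' Seven open-ocean biome labels assigned from annual mean SST (degrees C)
#' and annual mean NPP (mg C m-2 d-1): high-latitude (HIL), high-latitude
#' transition (HIT), mid-latitude transition (MTR), subtropical (SUS),
#' warm productive sector (WIS), tropical oligotrophic (TRP) and equatorial
#' upwelling (PEU). Intervals are closed below, open above.
#'
#' @return Tibble with columns `label`, `sst_min`, `sst_max`, `npp_min`,
#'   `npp_max`.
#' @export
default_biome_rules <- function() {
  tibble::tribble(
    ~label, ~sst_min, ~sst_max, ~npp_min, ~npp_max,
    "HIL", -Inf, 5, -Inf, Inf,
    "HIT", 5, 10, -Inf, Inf,
    "MTR", 10, 18, -Inf, Inf,
    "SUS", 18, 25, -Inf, 250,
    "WIS", 18, 25, 250, Inf,
    "TRP", 25, Inf, -Inf, 500,
    "PEU", 25, Inf, 500, Inf
  )
}

#' Partition grid cells into biomes from SST x NPP rules
#'
#' @param env An `env_clim` object.
#' @param rules A rules tibble as in [default_biome_rules()]; the rules must
#'   label every cell exactly once (checked on the realized cells).
#' @return A tibble of class `biome_mask` with `cell_id` and `biome`
#'   (character); the rule vocabulary is kept in attribute `vocabulary`.
#' @export
generate_biomes <- function(env, rules = default_biome_rules()) {
  stopifnot(inherits(env, "env_clim"))
  ann <- env_annual(env)
  if (nrow(ann) == 0) stop("empty-ocean grid: no cells to label")
  hits <- vapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    (ann$SST >= r$sst_min & ann$SST < r$sst_max &
      ann$NPP >= r$npp_min & ann$NPP < r$npp_max)
  }, logical(nrow(ann)))
  hits <- matrix(hits, nrow = nrow(ann))
  n_hit <- rowSums(hits)
  if (any(n_hit == 0)) stop("non-exhaustive biome rules: some cells unlabeled")
  if (any(n_hit > 1)) stop("overlapping biome rules: some cells match several rules")
  lab <- rules$label[apply(hits, 1, which.max)]
  out <- tibble::tibble(cell_id = ann$cell_id, biome = lab)
  structure(out,
    vocabulary = rules$label,
    class = c("biome_mask", class(out))
  )
}

TROPHIC_VOCAB <- c(
  "CM", "GNCM", "pSNCM", "eSNCM",
  "strict_phototroph", "strict_phagotroph", "unannotated"
)
COARSE_VOCAB <- c("mixotroph", "strict_phototroph", "strict_phagotroph", "unannotated")

#' Map fine trophic classes to coarse trophic strategies
#'
#' Constitutive (CM) and non-constitutive (GNCM, pSNCM, eSNCM) mixotroph
#' classes pool into "mixotroph"; the two specialist classes and
#' "unannotated" map to themselves.
#'
#' @param trait_label Character vector in the 7-class vocabulary.
#' @return Character vector of coarse labels.
#' @export
coarse_trait <- function(trait_label) {
  bad <- setdiff(unique(trait_label), TROPHIC_VOCAB)
  if (length(bad) > 0) stop("unknown trait label(s): ", paste(bad, collapse = ", "))
  dplyr::case_when(
    trait_label %in% c("CM", "GNCM", "pSNCM", "eSNCM") ~ "mixotroph",
    TRUE ~ trait_label
  )
}

#' Default trait-conditioned niche priors
#'
#' Sampling distributions for species niche optima and tolerances on the SST
#' and NPP axes, one set per coarse trophic strategy. They encode the
#' contrast the pipeline must later detect: mixotroph optima cluster tightly
#' in warm, low-production (oligotrophic) conditions; strict phagotroph
#' optima are spread widely along both the temperature and production axes;
#' strict phototrophs sit in between. Each entry gives, per predictor,
#' `center = c(mean, sd)` and `breadth = c(mean, sd)` (breadths truncated
#' strictly positive).
#'
#' @return Nested named list keyed by coarse trait then predictor.
#' @export
default_trait_priors <- function() {
  list(
    mixotroph = list(
      SST = list(center = c(26, 1.2), breadth = c(4, 0.5)),
      NPP = list(center = c(250, 60), breadth = c(400, 50))
    ),
    strict_phototroph = list(
      SST = list(center = c(20, 4), breadth = c(5, 0.7)),
      NPP = list(center = c(400, 150), breadth = c(450, 60))
    ),
    strict_phagotroph = list(
      SST = list(center = c(12, 8), breadth = c(6, 1)),
      NPP = list(center = c(600, 300), breadth = c(500, 80))
    )
  )
}

FINE_FROM_COARSE <- list(
  mixotroph = c(CM = 0.8, pSNCM = 0.1, eSNCM = 0.1),
  strict_phototroph = c(strict_phototroph = 1),
  strict_phagotroph = c(strict_phagotroph = 1)
)

#' Generate trait-conditioned synthetic species
#'
#' Draws Gaussian niche parameters per species from trait-specific priors.
#' Mixotroph species receive a fine class (mostly CM, some pSNCM/eSNCM) to
#' exercise the 7-class vocabulary downstream.
#'
#' @param n_per_trait Named integer vector of species counts keyed by coarse
#'   trait (or a fine class, which is used verbatim).
#' @param env An `env_clim`; niche predictors must exist in it.
#' @param trait_priors Priors as in [default_trait_priors()].
#' @param seed Integer seed.
#' @return Tibble of class `species_specs`: `species_id`, `trait_label`
#'   (fine), `coarse_label`, `max_abundance`, and list-columns
#'   `niche_centers`, `niche_breadths` (named numeric vectors).
#' @export
generate_species <- function(n_per_trait, env,
                             trait_priors = default_trait_priors(),
                             seed = 1) {
  stopifnot(inherits(env, "env_clim"))
  labs <- names(n_per_trait)
  if (is.null(labs) || any(!labs %in% c(COARSE_VOCAB, TROPHIC_VOCAB))) {
    stop("unknown trait label in n_per_trait")
  }
  if (all(unlist(n_per_trait) == 0)) stop("zero species requested for all traits")
  withr::with_seed(derive_seed(seed, "species"), {
    rows <- purrr::imap(n_per_trait, function(n, lab) {
      if (n == 0) return(NULL)
      coarse <- coarse_trait(ifelse(lab %in% TROPHIC_VOCAB, lab, "CM"))
      if (lab %in% COARSE_VOCAB) coarse <- lab
      prior <- trait_priors[[coarse]]
      if (is.null(prior)) stop("no prior for trait ", coarse)
      preds <- names(prior)
      missing <- setdiff(preds, attr(env, "variables"))
      if (length(missing) > 0) stop("niche predictor(s) absent from climatology: ",
        paste(missing, collapse = ", "))
      fine <- if (lab %in% TROPHIC_VOCAB) rep(lab, n) else {
        p <- FINE_FROM_COARSE[[coarse]]
        sample(names(p), n, replace = TRUE, prob = p)
      }
      purrr::map(seq_len(n), function(i) {
        centers <- vapply(preds, function(v) {
          rnorm(1, prior[[v]]$center[1], prior[[v]]$center[2])
        }, numeric(1))
        breadths <- vapply(preds, function(v) {
          b <- rnorm(1, prior[[v]]$breadth[1], prior[[v]]$breadth[2])
          max(b, prior[[v]]$breadth[1] / 10) # strictly positive
        }, numeric(1))
        prefix <- c(mixotroph = "mixo", strict_phototroph = "phot",
                    strict_phagotroph = "phag")[[coarse]]
        tibble::tibble(
          species_id = sprintf("%s_%03d", prefix, i),
          trait_label = fine[i], coarse_label = coarse,
          max_abundance = rlnorm(1, log(500), 1.5),
          niche_centers = list(setNames(centers, preds)),
          niche_breadths = list(setNames(breadths, preds))
        )
      }) |> purrr::list_rbind()
    })
    specs <- purrr::list_rbind(rows)
    specs$species_id <- make.unique(specs$species_id, sep = "_")
    structure(specs, class = c("species_specs", class(specs)))
  })
}

# Gaussian product-kernel suitability of each species at rows of env values.
# envtab: tibble/data.frame with the niche predictor columns.
species_suitability <- function(specs, envtab) {
  vapply(seq_len(nrow(specs)), function(j) {
    mu <- specs$niche_centers[[j]]
    sg <- specs$niche_breadths[[j]]
    z <- rep(0, nrow(envtab))
    for (v in names(mu)) {
      z <- z + (envtab[[v]] - mu[[v]])^2 / (2 * sg[[v]]^2)
    }
    exp(-z)
  }, numeric(nrow(envtab)))
}

#' Simulate metabarcoding sampling of synthetic species
#'
#' Draws sampling sites among grid cells, assigns each a uniform random
#' month and a shallow sampling depth, computes true Gaussian-niche
#' suitabilities from the site's monthly environment, and draws read counts
#' from one multinomial per sample with expected shares proportional to
#' suitability times the species' maximum abundance. True per-species
#' annual suitability grids are stored for downstream validation.
#'
#' @param species A `species_specs` tibble.
#' @param env An `env_clim`.
#' @param n_sites Number of sites (cells sampled without replacement).
#' @param depth Reads per sample (>= 1).
#' @param seed Integer seed.
#' @param overdispersion Optional Dirichlet-multinomial concentration; `NULL`
#'   (default) gives a plain multinomial.
#' @return A list of class `synth_data`: `community` (a `community_tbl`),
#'   `truth` (species x cells matrix of annual suitabilities in `[0, 1]`),
#'   `traits` (trait table tibble), `env`, `biomes`, `seed`.
#' @export
simulate_sampling <- function(species, env, n_sites = 300, depth = 2000,
                              seed = 1, overdispersion = NULL) {
  stopifnot(inherits(env, "env_clim"))
  if (nrow(species) == 0) stop("empty species list")
  if (depth < 1) stop("depth must be >= 1")
  grid <- env$grid
  if (n_sites > nrow(grid)) stop("n_sites exceeds number of ocean cells")
  withr::with_seed(derive_seed(seed, "sampling"), {
    cells <- sample(grid$cell_id, n_sites)
    months <- sample(1:12, n_sites, replace = TRUE)
    sites <- tibble::tibble(
      site_id = sprintf("site_%04d", seq_len(n_sites)),
      cell_id = cells, month = months,
      depth_m = round(runif(n_sites, 5, 20), 1)
    )
    sites <- dplyr::left_join(sites, grid[, c("cell_id", "lat", "lon")],
      by = "cell_id"
    )
    envm <- dplyr::left_join(sites, env$monthly, by = c("cell_id", "month"))
    sites$mld_m <- envm$MLD
    suit <- species_suitability(species, envm) # sites x species
    w <- sweep(suit, 2, species$max_abundance, `*`)
    counts <- matrix(0L, nrow(species), n_sites,
      dimnames = list(species$species_id, sites$site_id)
    )
    for (i in seq_len(n_sites)) {
      p <- w[i, ] + 1e-12
      if (!is.null(overdispersion)) {
        g <- stats::rgamma(length(p), shape = p / sum(p) * overdispersion)
        p <- g + 1e-15
      }
      counts[, i] <- rmultinom(1, size = depth, prob = p)
    }
    truth <- t(species_suitability(species, env_annual(env)))
    rownames(truth) <- species$species_id
    colnames(truth) <- as.character(grid$cell_id)
    traits <- tibble::tibble(
      species_id = species$species_id,
      trait_label = species$trait_label,
      coarse_label = species$coarse_label
    )
    community <- community_tbl(
      counts = counts,
      sites = dplyr::select(
        sites, "site_id", "cell_id", "lat", "lon",
        "depth_m", "month", "mld_m"
      ),
      species = tibble::tibble(
        species_id = species$species_id,
        genus_assigned = TRUE
      )
    )
    biomes <- generate_biomes(env)
    structure(
      list(
        community = community, truth = truth, traits = traits,
        env = env, biomes = biomes, seed = seed
      ),
      class = "synth_data"
    )
  })
}

#' @export
print.synth_data <- function(x, ...) {
  cat(
    "Synthetic metabarcoding dataset:", nrow(x$truth), "species,",
    ncol(x$community$counts), "sites, seed", x$seed, "\n"
  )
  invisible(x)
}
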