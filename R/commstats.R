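#' Construct a community table
#'
#' The central observational object: a species-by-sites read-count matrix
#' plus per-site metadata and a per-species flag recording whether the
#' lineage is taxonomically assigned at least at the genus level.
#'
#' @param counts Non-negative integer matrix, species in rows, sites in
#'   columns; dimnames must match `species`/`sites` ids.
#' @param sites Tibble with at least `site_id`, `lat`, `lon`, `depth_m`,
#'   `month`, `mld_m`.
#' @param species Tibble with `species_id` and optionally `genus_assigned`
#'   (defaults to `TRUE`).
#' @return An object of class `community_tbl`.
#' @export
community_tbl <- function(counts, sites, species = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(species)) {
    species <- tibble::tibble(species_id = rownames(counts), genus_assigned = TRUE)
  }
  if (is.null(species$genus_assigned)) species$genus_assigned <- TRUE
  if (anyDuplicated(species$species_id)) stop("duplicate species ids")
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  stopifnot(
    identical(rownames(counts), species$species_id),
    identical(colnames(counts), sites$site_id),
    all(is.finite(sites$lat)), all(is.finite(sites$lon))
  )
  structure(
    list(counts = counts, sites = tibble::as_tibble(sites),
         species = tibble::as_tibble(species)),
    class = "community_tbl"
  )
}

#' @export
print.community_tbl <- function(x, ...) {
  cat("Community table:", nrow(x$counts), "species x", ncol(x$counts),
      "sites,", sum(x$counts), "reads\n")
  invisible(x)
}

#' Long-format view of a community table
#'
#' @param x A `community_tbl`.
#' @param ... Unused.
#' @return Tibble with `species_id`, `site_id`, `reads` (zero cells dropped).
#' @export
tidy.community_tbl <- function(x, ...) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  tibble::tibble(
    species_id = rownames(x$counts)[idx[, 1]],
    site_id = colnames(x$counts)[idx[, 2]],
    reads = x$counts[idx]
  )
}

#' Filter a community table on read totals, taxonomy and sampling depth
#'
#' Species are dropped when their global read total is below `min_reads`
#' (the bound is inclusive: a species with exactly `min_reads` reads is
#' kept) or when they are not assigned at genus level. Sites are dropped
#' when sampled below the climatological mixed layer depth or below the
#' euphotic-zone cutoff. Survivor order is preserved.
#'
#' @param table A `community_tbl`.
#' @param min_reads Minimum global read total per species (default 100).
#' @param euphotic_max_depth Euphotic-zone depth cutoff in metres
#'   (default 200).
#' @return A filtered `community_tbl`.
#' @export
filter_community <- function(table, min_reads = 100, euphotic_max_depth = 200) {
  stopifnot(inherits(table, "community_tbl"), min_reads >= 0)
  keep_sp <- rowSums(table$counts) >= min_reads & table$species$genus_assigned
  keep_si <- table$sites$depth_m <= table$sites$mld_m &
    table$sites$depth_m <= euphotic_max_depth
  if (!any(keep_sp)) stop("filtering removed every species")
  if (!any(keep_si)) stop("filtering removed every site")
  community_tbl(
    counts = table$counts[keep_sp, keep_si, drop = FALSE],
    sites = table$sites[keep_si, , drop = FALSE],
    species = table$species[keep_sp, , drop = FALSE]
  )
}

#' Relative-abundance Hellinger transform
#'
#' Normalises each sample to relative abundances and takes square roots:
#' entry (i, j) becomes sqrt(reads_ij / total_i), so each sample row has
#' unit Euclidean norm. This is the standard pre-treatment that makes
#' Euclidean-based ordination of count data well behaved.
#'
#' @param table A `community_tbl` or a samples-in-rows count matrix.
#' @return Numeric matrix, samples in rows, species in columns.
#' @export
relative_hellinger <- function(table) {
  m <- if (inherits(table, "community_tbl")) t(table$counts) else as.matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    bad <- rownames(m)[tot == 0]
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  sqrt(m / tot)
}

#' Per-species ubiquity metrics
#'
#' Computes for every species its occupancy (number of sites with at least
#' one read), total read abundance, and Pielou evenness of its read
#' distribution across the sites it occupies: J = H' / ln(S_occ) with
#' Shannon entropy H' over occupied sites. A species found at a single site
#' has no defined evenness (ln 1 = 0); by convention it is reported as 1.0
#' with `degenerate = TRUE`.
#'
#' @param table A (filtered) `community_tbl`.
#' @return Tibble with `species_id`, `occupancy`, `total_abundance`,
#'   `evenness`, `degenerate`.
#' @export
species_metrics <- function(table) {
  stopifnot(inherits(table, "community_tbl"))
  counts <- table$counts
  if (nrow(counts) == 0) stop("empty community table")
  purrr::map(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    occ <- sum(x > 0)
    tot <- sum(x)
    if (occ <= 1) {
      ev <- 1.0
      deg <- TRUE
    } else {
      p <- x[x > 0] / tot
      ev <- -sum(p * log(p)) / log(occ)
      deg <- FALSE
    }
    tibble::tibble(
      species_id = rownames(counts)[i], occupancy = occ,
      total_abundance = tot, evenness = ev, degenerate = deg
    )
  }) |> purrr::list_rbind()
}

#' Classify species into ubiquity categories
#'
#' Ward-linkage hierarchical clustering on z-scored (occupancy, evenness),
#' cut at `k` clusters. Clusters are mapped to labels by mean occupancy:
#' the highest-occupancy cluster is "ubiquitous", the lowest is "rare",
#' everything else "intermediate".
#'
#' @param metrics Output of [species_metrics()].
#' @param k Number of categories (default 3, must be >= 2).
#' @return `metrics` with an added `category` column. If all species have
#'   identical metrics the partition is degenerate: every species is labeled
#'   "intermediate" and attribute `degenerate_partition` is set.
#' @export
classify_ubiquity <- function(metrics, k = 3) {
  if (k < 2) stop("k must be >= 2")
  if (nrow(metrics) < k) stop("fewer species than k clusters")
  m <- cbind(metrics$occupancy, metrics$evenness)
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) {
    metrics$category <- "intermediate"
    attr(metrics, "degenerate_partition") <- TRUE
    return(metrics)
  }
  z <- scale(m)
  z[, sds == 0] <- 0
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  mean_occ <- tapply(metrics$occupancy, cl, mean)
  ord <- rank(mean_occ, ties.method = "first")
  lab <- rep("intermediate", k)
  lab[which.max(ord)] <- "ubiquitous"
  lab[which.min(ord)] <- "rare"
  metrics$category <- lab[cl]
  attr(metrics, "degenerate_partition") <- FALSE
  metrics
}

#' Compare a ubiquity metric across trophic strategies
#'
#' Kruskal-Wallis rank test of occupancy or evenness distributions across
#' coarse trophic strategies (unannotated species excluded).
#'
#' @param metrics Output of [species_metrics()].
#' @param traits Tibble with `species_id` and `trait_label` (7-class) or
#'   `coarse_label`.
#' @param variable `"occupancy"` or `"evenness"`.
#' @param drop_degenerate Exclude single-site species (their evenness is a
#'   convention, not a measurement) from evenness tests; default `FALSE`.
#' @return Tibble with `variable`, `statistic` (Kruskal-Wallis H), `df`,
#'   `p_value`, `n_groups`.
#' @export
trait_group_test <- function(metrics, traits,
                             variable = c("occupancy", "evenness"),
                             drop_degenerate = FALSE) {
  variable <- match.arg(variable)
  if (!"coarse_label" %in% colnames(traits)) {
    traits$coarse_label <- coarse_trait(traits$trait_label)
  }
  d <- dplyr::inner_join(metrics, traits, by = "species_id") |>
    dplyr::filter(.data$coarse_label != "unannotated")
  if (drop_degenerate && variable == "evenness") {
    d <- dplyr::filter(d, !.data$degenerate)
  }
  groups <- unique(d$coarse_label)
  if (length(groups) < 2) stop("need at least two trophic groups with members")
  kt <- stats::kruskal.test(d[[variable]], factor(d$coarse_label))
  tibble::tibble(
    variable = variable,
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, n_groups = length(groups)
  )
}
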