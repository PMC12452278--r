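#' Derive nutrient-excess indices
#'
#' Adds the nitrate excess N* = NO3 - 16 PO4 (departure from Redfield
#' stoichiometry) and the silicate excess Si* = Si - NO3, elementwise.
#'
#' @param env Data frame with columns `NO3`, `PO4`, `Si`.
#' @return The input with `Nstar` and `Sistar` columns added/overwritten.
#' @export
derive_indices <- function(env) {
  for (v in c("NO3", "PO4", "Si")) {
    if (is.null(env[[v]])) stop("missing parent column: ", v)
  }
  dplyr::mutate(env,
    Nstar = .data$NO3 - 16 * .data$PO4,
    Sistar = .data$Si - .data$NO3
  )
}

#' Principal component analysis with supplementary variables
#'
#' SVD-based PCA of a numeric matrix, optionally standardized (centred,
#' unit variance; the default). Supplementary variables take no part in the
#' decomposition; only their Pearson correlations with the component scores
#' are reported, the device used to project habitat-suitability fields into
#' an environmental ordination without letting them shape it. Each loading
#' vector is oriented so that its largest-magnitude element is positive,
#' making axis signs reproducible.
#'
#' @param env Data frame or matrix of active variables (rows = sites or
#'   cells).
#' @param standardize Centre and scale columns first (default `TRUE`).
#' @param supplementary Optional data frame of extra numeric columns,
#'   row-aligned with `env`.
#' @return Object of class `env_pca` with `eigenvalues`,
#'   `explained_variance`, `loadings` (variables x components), `scores`,
#'   `center`, `scale`, and `supplementary_correlations` (tibble, one row
#'   per supplementary variable per component). Constant supplementary
#'   columns get `NA` correlations and a `degenerate` flag.
#' @export
env_pca <- function(env, standardize = TRUE, supplementary = NULL) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(env), dplyr::where(is.numeric)))
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 rows and 2 columns")
  ctr <- colMeans(x)
  scl <- rep(1, ncol(x))
  if (standardize) {
    scl <- apply(x, 2, stats::sd)
    if (any(scl == 0)) {
      stop("constant column(s) under standardization: ",
        paste(colnames(x)[scl == 0], collapse = ", "))
    }
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  sv <- svd(z)
  npc <- length(sv$d)
  eig <- sv$d^2 / (nrow(z) - 1)
  loadings <- sv$v
  scores <- z %*% loadings
  # orientation: largest-|loading| element positive, per component
  for (j in seq_len(npc)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(npc)))
  colnames(scores) <- paste0("PC", seq_len(npc))
  supp <- NULL
  if (!is.null(supplementary)) {
    supplementary <- tibble::as_tibble(supplementary)
    stopifnot(nrow(supplementary) == nrow(z))
    supp <- purrr::imap(supplementary, function(col, nm) {
      degen <- stats::sd(col) == 0 || !all(is.finite(col))
      r <- if (degen) rep(NA_real_, npc) else {
        as.numeric(stats::cor(col, scores))
      }
      tibble::tibble(
        variable = nm, component = paste0("PC", seq_len(npc)),
        correlation = r, degenerate = degen
      )
    }) |> purrr::list_rbind()
  }
  structure(
    list(
      eigenvalues = eig,
      explained_variance = eig / sum(eig),
      loadings = loadings, scores = scores,
      center = ctr, scale = scl, standardized = standardize,
      supplementary_correlations = supp
    ),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  cat("PCA:", nrow(x$loadings), "variables,", nrow(x$scores), "rows; PC1-2 explain",
      sprintf("%.2f%%", 100 * sum(x$explained_variance[1:2])), "of variance\n")
  invisible(x)
}

#' @rdname env_pca
#' @param x An `env_pca` object.
#' @param ... Unused.
#' @export
tidy.env_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component", values_to = "loading")
}

#' @rdname env_pca
#' @export
glance.env_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$eigenvalues),
    var_pc1 = x$explained_variance[1],
    var_pc2 = x$explained_variance[2],
    var_pc1_pc2 = sum(x$explained_variance[1:2])
  )
}

#' Hierarchical classification on principal component scores
#'
#' Ward-linkage clustering of rows on their first PCA score columns, the
#' standard way of regionalising sites from an environmental ordination.
#'
#' @param pca_result An [env_pca()] result.
#' @param k Number of clusters (>= 2).
#' @param n_components Number of leading score columns to use; default is
#'   the smallest number reaching 80% cumulative explained variance.
#' @param variance_threshold Cumulative-variance target used when
#'   `n_components` is `NULL`.
#' @return Object of class `env_hcpc`: `cluster` (integer labels in 1..k,
#'   renumbered by first appearance in row order so ties and labels are
#'   deterministic), `k`, `n_components`, `hclust` (the linkage record).
#' @export
env_hcpc <- function(pca_result, k, n_components = NULL,
                     variance_threshold = 0.8) {
  stopifnot(inherits(pca_result, "env_pca"), k >= 2)
  if (k > nrow(pca_result$scores)) stop("k exceeds row count")
  if (is.null(n_components)) {
    cum <- cumsum(pca_result$explained_variance)
    n_components <- which(cum >= variance_threshold)[1]
    if (is.na(n_components)) n_components <- length(cum)
  }
  if (n_components > ncol(pca_result$scores)) {
    stop("n_components exceeds available components")
  }
  s <- pca_result$scores[, seq_len(n_components), drop = FALSE]
  hc <- stats::hclust(stats::dist(s), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  cl <- as.integer(factor(cl, levels = unique(cl))) # renumber by appearance
  structure(
    list(cluster = cl, k = k, n_components = n_components, hclust = hc),
    class = "env_hcpc"
  )
}

#' @export
print.env_hcpc <- function(x, ...) {
  cat("HCPC:", x$k, "clusters on", x$n_components, "components; sizes:",
      paste(table(x$cluster), collapse = ", "), "\n")
  invisible(x)
}
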