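#' Escoufier's RV coefficient between two matrices
#'
#' Matrix correlation in `[0, 1]` between two multivariate data sets on the
#' same observations: RV = tr(S_AB S_BA) / sqrt(tr(S_AA^2) tr(S_BB^2)) with
#' S the cross-product matrices of the column-centred inputs. Invariant to
#' orthogonal rotation of either block.
#'
#' @param A,B Numeric matrices with the same number of rows (>= 2). Columns
#'   are centred internally.
#' @return A single number in `[0, 1]`.
#' @export
rv_coefficient <- function(A, B) {
  A <- scale(as.matrix(A), scale = FALSE)
  B <- scale(as.matrix(B), scale = FALSE)
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 2)
  if (all(A == 0) || all(B == 0)) stop("all-zero matrix after centering")
  sab2 <- sum(crossprod(A, B)^2) # tr(S_AB S_BA)
  saa2 <- sum(crossprod(A)^2)
  sbb2 <- sum(crossprod(B)^2)
  sab2 / sqrt(saa2 * sbb2)
}

#' Escoufier equivalent-vectors selection of response columns
#'
#' Greedy forward search for the subset of columns (species) whose matrix
#' best resembles the full response matrix: at each step the column
#' maximising RV(full, selected + candidate) is added; the search stops when
#' the RV reaches `threshold` (the "similarity" level) or `max_k` columns
#' are selected. Ties break toward the lower column index.
#'
#' @param Y Numeric response matrix (rows = samples, columns = species).
#' @param threshold RV stopping level in (0, 1]; default 0.90.
#' @param max_k Maximum number of columns to select; default all.
#' @return Object of class `escoufier_selection`: `selected` (ordered
#'   column names), `rv_trajectory` (RV after each addition), `threshold`.
#' @export
escoufier_select <- function(Y, threshold = 0.90, max_k = ncol(Y)) {
  Y <- as.matrix(Y)
  if (length(Y) == 0 || ncol(Y) == 0) stop("empty response matrix")
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("V", seq_len(ncol(Y)))
  Yc <- scale(Y, scale = FALSE)
  selected <- integer(0)
  trajectory <- numeric(0)
  remaining <- seq_len(ncol(Y))
  repeat {
    rvs <- vapply(remaining, function(j) {
      sub <- Yc[, c(selected, j), drop = FALSE]
      if (all(sub == 0)) return(0)
      rv_coefficient(Yc, sub)
    }, numeric(1))
    best <- remaining[which.max(rvs)] # which.max takes the first tie
    selected <- c(selected, best)
    trajectory <- c(trajectory, max(rvs))
    remaining <- setdiff(remaining, best)
    if (max(rvs) >= threshold || length(selected) >= max_k ||
        length(remaining) == 0) {
      break
    }
  }
  structure(
    list(
      selected = colnames(Y)[selected],
      rv_trajectory = trajectory, threshold = threshold
    ),
    class = "escoufier_selection"
  )
}

#' @export
print.escoufier_selection <- function(x, ...) {
  cat("Escoufier selection:", length(x$selected), "columns, final RV =",
      sprintf("%.4f", utils::tail(x$rv_trajectory, 1)),
      "(threshold", x$threshold, ")\n")
  invisible(x)
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of a multivariate response on environmental
#' predictors: the response is column-centred, regressed on the centred
#' predictors, and the fitted values are decomposed by PCA to give the
#' canonical axes; the residuals give the unconstrained axes. Intended for
#' Hellinger-transformed community matrices against standardized predictors.
#'
#' @param Y Response matrix (samples x species), e.g. from
#'   [relative_hellinger()].
#' @param X Predictor matrix or data frame (samples x predictors), centred
#'   and standardized internally.
#' @return Object of class `rda_fit` with `canonical_eigenvalues`,
#'   `residual_eigenvalues`, `proportion_explained` (per canonical axis, of
#'   total response variance), `r_squared`, `adj_r_squared`, `site_scores`
#'   (fitted-value scores), `species_scores`, `biplot_scores` (predictor
#'   correlations with canonical axes), `predictor_names`, `n`, `m`.
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(dplyr::select(tibble::as_tibble(X), dplyr::where(is.numeric)))
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(Y)
  m <- ncol(X)
  if (n <= m + 1) stop("need more samples than predictors + 1")
  Yc <- scale(Y, scale = FALSE)
  sdx <- apply(X, 2, stats::sd)
  if (any(sdx == 0)) stop("constant predictor column(s)")
  Xs <- scale(X)
  xtx <- crossprod(Xs)
  if (rcond_sym(xtx) < 1e-12) {
    stop("singular predictor cross-product; screen predictors for collinearity")
  }
  B <- solve(xtx, crossprod(Xs, Yc))
  Yhat <- Xs %*% B
  Yres <- Yc - Yhat
  sv_c <- svd(Yhat)
  sv_r <- svd(Yres)
  can_eig <- sv_c$d^2 / (n - 1)
  res_eig <- sv_r$d^2 / (n - 1)
  can_eig <- can_eig[can_eig > 1e-12 * max(can_eig, 1)]
  res_eig <- res_eig[res_eig > 1e-12 * max(res_eig, 1)]
  total <- sum(Yc^2) / (n - 1)
  naxes <- length(can_eig)
  V <- sv_c$v[, seq_len(naxes), drop = FALSE]
  # orientation convention: largest-|element| species loading positive
  for (j in seq_len(naxes)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  site_scores <- Yhat %*% V
  species_scores <- V
  dimnames(species_scores) <- list(colnames(Y), paste0("RDA", seq_len(naxes)))
  colnames(site_scores) <- paste0("RDA", seq_len(naxes))
  biplot <- stats::cor(Xs, site_scores)
  r2 <- sum(Yhat^2) / sum(Yc^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  structure(
    list(
      canonical_eigenvalues = can_eig, residual_eigenvalues = res_eig,
      proportion_explained = can_eig / total,
      r_squared = r2, adj_r_squared = adj,
      site_scores = site_scores, species_scores = species_scores,
      biplot_scores = biplot, predictor_names = colnames(X),
      n = n, m = m, rss = sum(Yres^2), total_variance = total
    ),
    class = "rda_fit"
  )
}

# reciprocal condition number of a symmetric psd matrix
rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf(
    "RDA: %d samples, %d predictors; first two axes explain %.2f%% of variance; adj R2 = %.3f\n",
    x$n, x$m, 100 * sum(x$proportion_explained[seq_len(min(2, length(x$proportion_explained)))]),
    x$adj_r_squared
  ))
  invisible(x)
}

#' @rdname rda_fit
#' @param x An `rda_fit` object.
#' @param ... Unused.
#' @export
glance.rda_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
    prop_axes12 = sum(x$proportion_explained[seq_len(min(2, length(x$proportion_explained)))]),
    n = x$n, n_predictors = x$m
  )
}

# AIC of a multivariate linear fit on centred response:
# n * log(RSS/n) + 2 * (m + 1), RSS pooled over response columns.
# The least squares are rank-tolerant (pivoted QR), so exactly collinear
# candidate sets (e.g. nutrient indices alongside their parent nutrients)
# are scored rather than refused; because m counts requested columns, a
# redundant column always costs 2 AIC and backward selection removes it.
rda_aic <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  n <- nrow(Yc)
  if (is.null(X) || ncol(as.matrix(X)) == 0) {
    rss <- sum(Yc^2)
    m <- 0
  } else {
    X <- as.matrix(dplyr::select(tibble::as_tibble(X), dplyr::where(is.numeric)))
    sdx <- apply(X, 2, stats::sd)
    if (any(sdx == 0)) stop("constant predictor column(s)")
    fit <- stats::lm.fit(scale(X), Yc)
    rss <- sum(as.matrix(fit$residuals)^2)
    m <- ncol(X)
  }
  n * log(rss / n) + 2 * (m + 1)
}

#' Backward predictor selection for RDA by AIC
#'
#' Starting from all candidates, repeatedly drops the predictor whose
#' removal most decreases AIC = n log(RSS/n) + 2 (m + 1), where RSS is the
#' pooled residual sum of squares of the constrained fit; stops when no
#' single removal lowers the AIC. The trace is deterministic; the final set
#' may be empty when every candidate is noise.
#'
#' @param Y Response matrix (samples x species).
#' @param X Predictor data frame/matrix containing at least the candidates.
#' @param candidates Character vector of candidate predictor names
#'   (default: all columns of `X`).
#' @return Object of class `rda_selection`: `selected` names and `trace`
#'   tibble (`step`, `dropped`, `aic`, `n_predictors`).
#' @export
aic_backward_select <- function(Y, X, candidates = colnames(X)) {
  X <- tibble::as_tibble(as.data.frame(X))
  if (length(candidates) < 1) stop("need at least 1 candidate predictor")
  current <- candidates
  trace <- tibble::tibble(
    step = 0L, dropped = NA_character_,
    aic = rda_aic(Y, X[current]), n_predictors = length(current)
  )
  step <- 0L
  repeat {
    aic_now <- trace$aic[nrow(trace)]
    drops <- vapply(current, function(v) {
      rda_aic(Y, X[setdiff(current, v)])
    }, numeric(1))
    if (min(drops) >= aic_now) break
    step <- step + 1L
    victim <- current[which.min(drops)]
    current <- setdiff(current, victim)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, dropped = victim,
      aic = min(drops), n_predictors = length(current)
    ))
    if (length(current) == 0) break
  }
  structure(list(selected = current, trace = trace), class = "rda_selection")
}

#' @export
print.rda_selection <- function(x, ...) {
  cat("AIC backward selection kept", length(x$selected), "predictors:",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
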