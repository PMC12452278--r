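SDM_FAMILIES <- c("GLM", "GAM", "MARS", "ANN")

#' Jaccard index from a confusion-count decomposition
#'
#' For presence-absence prediction the Jaccard index is the set overlap
#' |A intersect B| / |A union B| = TP / (TP + FP + FN).
#'
#' @param tp,fp,fn True-positive, false-positive, false-negative counts.
#' @return A number in `[0, 1]`; 0 when the union is empty.
#' @export
jaccard_index <- function(tp, fp, fn) {
  u <- tp + fp + fn
  ifelse(u == 0, 0, tp / u)
}

# Jaccard between observed and predicted binary vectors
jaccard_binary <- function(obs, pred) {
  jaccard_index(sum(obs == 1 & pred == 1),
                sum(obs == 0 & pred == 1),
                sum(obs == 1 & pred == 0))
}

# Threshold maximizing Jaccard(obs, prob >= t) over the 0.01..0.99 grid;
# ties break toward the lower threshold.
best_threshold <- function(obs, prob, grid = seq(0.01, 0.99, by = 0.01)) {
  js <- vapply(grid, function(t) jaccard_binary(obs, as.integer(prob >= t)),
               numeric(1))
  list(threshold = grid[which.max(js)], jaccard = max(js))
}

#' Build presence-absence data for one species
#'
#' Presence = at least one read at the site; every sampled site without the
#' species is a true absence (no pseudo-absences). Predictor values are the
#' monthly climatology at each site's grid cell and sampling month. Species
#' with too few presences, or with no absences, return a skip marker instead
#' of a modelable object.
#'
#' @param table A (filtered) `community_tbl`.
#' @param species_id Species to extract.
#' @param env An `env_clim` providing the predictors.
#' @param predictors Predictor names (default: the 11 simulated variables
#'   plus the two nutrient-excess indices).
#' @param min_occurrences Minimum number of presences (default 20).
#' @return An object of class `sdm_pa` (`species_id`, `site_ids`, `labels`,
#'   `predictors` matrix) or of class `sdm_skip` with a `reason`.
#' @export
build_pa <- function(table, species_id, env,
                     predictors = ENV_VARIABLES, min_occurrences = 20) {
  stopifnot(inherits(table, "community_tbl"), inherits(env, "env_clim"))
  if (!species_id %in% rownames(table$counts)) {
    stop("species absent from table: ", species_id)
  }
  labels <- as.integer(table$counts[species_id, ] > 0)
  if (sum(labels) < min_occurrences) {
    return(structure(list(species_id = species_id,
      reason = sprintf("only %d presences (min %d)", sum(labels), min_occurrences)),
      class = "sdm_skip"))
  }
  if (all(labels == 1)) {
    return(structure(list(species_id = species_id,
      reason = "no absences: species present at every site"),
      class = "sdm_skip"))
  }
  envm <- dplyr::left_join(table$sites, env$monthly, by = c("cell_id", "month"))
  missing <- setdiff(predictors, colnames(envm))
  if (length(missing) > 0) {
    stop("predictor(s) missing from climatology: ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(envm[, predictors, drop = FALSE])
  rownames(X) <- table$sites$site_id
  structure(
    list(species_id = species_id, site_ids = table$sites$site_id,
         labels = labels, predictors = X),
    class = "sdm_pa"
  )
}

#' @export
print.sdm_pa <- function(x, ...) {
  cat("Presence-absence data for", x$species_id, ":", sum(x$labels),
      "presences /", length(x$labels), "sites,", ncol(x$predictors),
      "predictors\n")
  invisible(x)
}

#' Drop collinear predictors, keeping the more important one
#'
#' Inspects pairwise Spearman correlations; whenever a surviving pair
#' exceeds `rho_cut` in absolute value (pairs visited in decreasing |rho|),
#' the member with the lower importance score is dropped.
#'
#' @param predictors Numeric matrix/data frame of predictor columns.
#' @param importance Named numeric vector covering every predictor.
#' @param rho_cut Correlation cutoff (default 0.7).
#' @return Retained predictor names, in original column order.
#' @export
screen_collinearity <- function(predictors, importance, rho_cut = 0.7) {
  X <- as.matrix(predictors)
  nm <- colnames(X)
  stopifnot(all(nm %in% names(importance)))
  if (ncol(X) < 2) return(nm)
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  ord <- order(-abs(rho[pairs]))
  alive <- setNames(rep(TRUE, length(nm)), nm)
  for (p in ord) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- rho[i, j]
    if (!is.finite(r) || abs(r) <= rho_cut) next
    a <- nm[i]; b <- nm[j]
    if (alive[a] && alive[b]) {
      drop <- if (importance[a] >= importance[b]) b else a
      alive[drop] <- FALSE
    }
  }
  nm[alive[nm]]
}

#' Permutation importance from a preliminary quadratic GLM
#'
#' Fits one logistic GLM with linear and quadratic terms on the full
#' predictor set, then scores each predictor as one minus the mean Pearson
#' correlation between the model's predictions and its predictions with that
#' predictor's column permuted (5 seeded permutations), clipped to `[0, 1]`.
#' If the preliminary fit is degenerate, falls back to the absolute
#' point-biserial correlation of each predictor with the labels.
#'
#' @param pa An `sdm_pa`.
#' @param seed Integer seed for the permutations.
#' @param n_perm Number of permutations per predictor (default 5).
#' @return Named numeric vector of importances in `[0, 1]`.
#' @export
preliminary_importance <- function(pa, seed = 1, n_perm = 5) {
  stopifnot(inherits(pa, "sdm_pa"))
  X <- pa$predictors
  y <- pa$labels
  fit <- tryCatch(fit_glm_quadratic(X, y), error = function(e) NULL)
  fallback <- function() {
    imp <- abs(suppressWarnings(apply(X, 2, function(x) {
      if (stats::sd(x) == 0) return(0)
      stats::cor(x, y)
    })))
    imp[!is.finite(imp)] <- 0
    imp
  }
  if (is.null(fit) || fit$status != "ok") {
    warning("preliminary model degenerate; using univariate correlations")
    return(fallback())
  }
  p0 <- fit$predict(X)
  withr::with_seed(derive_seed(seed, paste0("importance_", pa$species_id)), {
    imp <- vapply(colnames(X), function(v) {
      if (stats::sd(X[, v]) == 0) return(0)
      cors <- vapply(seq_len(n_perm), function(r) {
        Xp <- X
        Xp[, v] <- sample(Xp[, v])
        cc <- suppressWarnings(stats::cor(p0, fit$predict(Xp)))
        if (!is.finite(cc)) 1 else cc
      }, numeric(1))
      1 - mean(cors)
    }, numeric(1))
  })
  pmin(pmax(imp, 0), 1)
}

#' Select a species-specific predictor set
#'
#' Combines [preliminary_importance()] and [screen_collinearity()], then
#' keeps the `top_n` surviving predictors by importance.
#'
#' @param pa An `sdm_pa`.
#' @param rho_cut Spearman cutoff for collinearity screening (default 0.7).
#' @param top_n Number of predictors to retain (default 4).
#' @param seed Seed for the permutation importance.
#' @return Character vector of predictor names.
#' @export
select_predictors <- function(pa, rho_cut = 0.7, top_n = 4, seed = 1) {
  imp <- suppressWarnings(preliminary_importance(pa, seed = seed))
  keep <- screen_collinearity(pa$predictors, imp, rho_cut = rho_cut)
  keep[order(-imp[keep])][seq_len(min(top_n, length(keep)))]
}

# ---- model families ------------------------------------------------------

# quadratic-design logistic GLM on a raw matrix; rank-deficient coefficients
# are dropped (set to zero) at prediction time
fit_glm_quadratic <- function(X, y) {
  D <- cbind(X, X^2)
  colnames(D) <- c(colnames(X), paste0(colnames(X), "_sq"))
  fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, D), y,
    family = stats::binomial()))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  # non-convergence under complete separation still yields a usable ranking;
  # the cross-validation Jaccard retention is the quality gate
  status <- "ok"
  vars <- colnames(X)
  list(
    family = "GLM", status = status, coefficients = beta,
    predict = function(newX) {
      newX <- as.matrix(newX)[, vars, drop = FALSE]
      Dn <- cbind(1, newX, newX^2)
      as.numeric(stats::plogis(Dn %*% beta))
    }
  )
}

fit_gam_family <- function(X, y, k_basis = 4) {
  df <- as.data.frame(X)
  df$.y <- y
  vars <- colnames(X)
  useable <- vars[apply(X, 2, function(x) length(unique(x)) > k_basis)]
  terms <- c(
    sprintf("s(%s, k = %d)", useable, k_basis),
    setdiff(vars, useable)
  )
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  # smoothing-parameter iteration warnings are noise here; the converged
  # flag below still reports the outcome
  fit <- suppressWarnings(
    mgcv::gam(fml, family = stats::binomial(), data = df, method = "REML"))
  list(
    family = "GAM", status = if (fit$converged) "ok" else "failed",
    model = fit,
    predict = function(newX) {
      as.numeric(stats::predict(fit,
        newdata = as.data.frame(as.matrix(newX)[, vars, drop = FALSE]),
        type = "response"))
    }
  )
}

# Hinge-basis regression splines: additive forward growth of reflected hinge
# pairs selected by least-squares RSS, generalized-cross-validation pruning,
# then a logistic refit on the pruned basis.
fit_mars_family <- function(X, y, max_terms = 11, gcv_penalty = 2) {
  n <- nrow(X)
  knot_probs <- seq(0.1, 0.9, by = 0.1)
  cands <- purrr::map(colnames(X), function(v) {
    kn <- unique(stats::quantile(X[, v], knot_probs, names = FALSE))
    purrr::map(kn, function(t) list(var = v, knot = t))
  }) |> purrr::flatten()
  hinge_cols <- function(X, cand) {
    x <- as.matrix(X)[, cand$var]
    cbind(pmax(x - cand$knot, 0), pmax(cand$knot - x, 0))
  }
  basis <- list() # list of cands in the model (each contributes 2 columns)
  B <- matrix(1, n, 1)
  rss <- function(B) sum(stats::residuals(stats::lm.fit(B, y))^2)
  used <- rep(FALSE, length(cands))
  while (ncol(B) + 2 <= max_terms && any(!used)) {
    scores <- vapply(seq_along(cands), function(i) {
      if (used[i]) return(Inf)
      rss(cbind(B, hinge_cols(X, cands[[i]])))
    }, numeric(1))
    best <- which.min(scores)
    if (!is.finite(scores[best])) break
    used[best] <- TRUE
    basis <- c(basis, list(cands[[best]]))
    B <- cbind(B, hinge_cols(X, cands[[best]]))
  }
  # backward pruning by GCV over the nested deletion sequence
  gcv <- function(B) {
    M <- ncol(B)
    C <- M + gcv_penalty * (M - 1) / 2
    if (C >= n) return(Inf)
    (rss(B) / n) / (1 - C / n)^2
  }
  keep <- seq_along(basis)
  build_B <- function(idx) {
    cols <- purrr::map(basis[idx], ~ hinge_cols(X, .x))
    do.call(cbind, c(list(matrix(1, n, 1)), cols))
  }
  best_keep <- keep
  best_gcv <- gcv(build_B(keep))
  cur <- keep
  while (length(cur) > 0) {
    cand_gcv <- vapply(seq_along(cur), function(i) gcv(build_B(cur[-i])),
                       numeric(1))
    i <- which.min(cand_gcv)
    cur <- cur[-i]
    if (cand_gcv[i] < best_gcv) {
      best_gcv <- cand_gcv[i]
      best_keep <- cur
    }
  }
  final_basis <- basis[best_keep]
  build_new <- function(newX) {
    cols <- purrr::map(final_basis, function(cand) {
      x <- as.matrix(newX)[, cand$var]
      cbind(pmax(x - cand$knot, 0), pmax(cand$knot - x, 0))
    })
    do.call(cbind, c(list(matrix(1, nrow(as.matrix(newX)), 1)), cols))
  }
  Bf <- build_new(X)
  fit <- suppressWarnings(stats::glm.fit(Bf, y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  list(
    family = "MARS", status = "ok", basis = final_basis, coefficients = beta,
    predict = function(newX) {
      as.numeric(stats::plogis(build_new(newX) %*% beta))
    }
  )
}

fit_ann_family <- function(X, y, size = 4, decay = 0.01, maxit = 300, seed = 1) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  vars <- colnames(X)
  fit <- withr::with_seed(seed, {
    nnet::nnet(Z, y, size = size, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE)
  })
  list(
    family = "ANN", status = if (fit$convergence %in% c(0, 1)) "ok" else "failed",
    model = fit,
    predict = function(newX) {
      Zn <- scale(as.matrix(newX)[, vars, drop = FALSE], center = ctr, scale = scl)
      as.numeric(stats::predict(fit, Zn))
    }
  )
}

#' Fit one model family on presence-absence data
#'
#' Families follow a low-complexity configuration to limit overfitting:
#' GLM with linear + quadratic terms and logit link; GAM with small-basis
#' smooths (k = 4) per predictor; hinge-basis regression splines grown
#' forward to a small term budget then pruned by generalized cross
#' validation, with a logistic link; single-hidden-layer neural network
#' (<= 8 units, weight decay, seeded initialisation).
#'
#' @param pa An `sdm_pa` (optionally subset via `rows`).
#' @param family One of `"GLM"`, `"GAM"`, `"MARS"`, `"ANN"`.
#' @param hyper Optional family-specific settings (`size`, `decay`,
#'   `k_basis`, `max_terms`).
#' @param seed Integer seed (only the neural network is stochastic).
#' @param rows Optional integer subset of sites to train on.
#' @return List of class `sdm_member` with `family`, `status` (`"ok"` or
#'   `"failed"`) and a `predict(newX)` closure returning values in `[0, 1]`.
#' @export
fit_family <- function(pa, family, hyper = list(), seed = 1, rows = NULL) {
  stopifnot(inherits(pa, "sdm_pa"))
  family <- match.arg(family, SDM_FAMILIES)
  X <- pa$predictors
  y <- pa$labels
  if (!is.null(rows)) {
    X <- X[rows, , drop = FALSE]
    y <- y[rows]
  }
  fit <- tryCatch(
    switch(family,
      GLM = fit_glm_quadratic(X, y),
      GAM = do.call(fit_gam_family, c(list(X, y), hyper[intersect(names(hyper), "k_basis")])),
      MARS = do.call(fit_mars_family, c(list(X, y), hyper[intersect(names(hyper), c("max_terms", "gcv_penalty"))])),
      ANN = do.call(fit_ann_family, c(list(X, y, seed = seed), hyper[intersect(names(hyper), c("size", "decay", "maxit"))]))
    ),
    error = function(e) list(family = family, status = "failed",
                             predict = function(newX) rep(NA_real_, nrow(as.matrix(newX))),
                             error = conditionMessage(e))
  )
  structure(fit, class = "sdm_member")
}

#' Enumerate the individual model fits a modelling run will schedule
#'
#' Pure bookkeeping: one row per (species, family, cross-validation
#' repetition).
#'
#' @param species_ids Character vector of species.
#' @param families Character vector of model-family registry entries.
#' @param n_reps Number of cross-validation repetitions.
#' @return Tibble with `species_id`, `family`, `cv_rep`.
#' @export
schedule_fits <- function(species_ids, families = SDM_FAMILIES, n_reps = 5) {
  tidyr::expand_grid(
    species_id = species_ids, family = families, cv_rep = seq_len(n_reps)
  )
}

#' Repeated stratified cross-validation and Jaccard member retention
#'
#' For each (family, repetition): split sites 80/20 stratified by label,
#' fit on the calibration split, pick the probability threshold maximising
#' the calibration Jaccard index over the 0.01..0.99 grid, then score the
#' Jaccard on the held-out split at that threshold. Members whose validation
#' Jaccard exceeds `retention_cutoff` form the species' ensemble committee.
#'
#' @param pa An `sdm_pa`.
#' @param families Model families to train (default all four).
#' @param n_reps Repetitions (default 5).
#' @param split Calibration fraction (default 0.8).
#' @param retention_cutoff Validation-Jaccard retention bound, strict
#'   (default 0.3).
#' @param seed Integer seed controlling splits and network initialisation.
#' @param hyper Optional per-family hyper-parameter lists keyed by family.
#' @return Object of class `sdm_ensemble`: `species_id`, `members` (list of
#'   retained fitted members each carrying `calibration_threshold` and
#'   `jaccard_validation`), `manifest` (one row per trained member),
#'   `n_trained`, `n_retained`, `predictor_names`.
#' @export
cross_validate <- function(pa, families = SDM_FAMILIES, n_reps = 5,
                           split = 0.8, retention_cutoff = 0.3, seed = 1,
                           hyper = list()) {
  stopifnot(inherits(pa, "sdm_pa"), n_reps >= 1, split > 0, split < 1)
  n <- length(pa$labels)
  pres <- which(pa$labels == 1)
  abs_ <- which(pa$labels == 0)
  if (floor(length(pres) * split) < 1 || floor(length(abs_) * split) < 1 ||
      length(pres) - floor(length(pres) * split) < 1 ||
      length(abs_) - floor(length(abs_) * split) < 1) {
    stop("a label stratum is empty under this split; lower `split` or add data")
  }
  splits <- withr::with_seed(derive_seed(seed, paste0("cv_", pa$species_id)), {
    purrr::map(seq_len(n_reps), function(r) {
      calib <- c(sample(pres, floor(length(pres) * split)),
                 sample(abs_, floor(length(abs_) * split)))
      list(calib = sort(calib), valid = setdiff(seq_len(n), calib))
    })
  })
  members <- list()
  manifest <- list()
  for (fam in families) {
    for (r in seq_len(n_reps)) {
      sp <- splits[[r]]
      fit_seed <- derive_seed(seed, paste(pa$species_id, fam, r, sep = "_"))
      fit <- fit_family(pa, fam, hyper = hyper[[fam]] %||% list(),
                        seed = fit_seed, rows = sp$calib)
      if (fit$status != "ok") {
        manifest[[length(manifest) + 1]] <- tibble::tibble(
          species_id = pa$species_id, family = fam, cv_rep = r,
          threshold = NA_real_, jaccard_validation = NA_real_,
          status = "failed", retained = FALSE
        )
        next
      }
      p_cal <- fit$predict(pa$predictors[sp$calib, , drop = FALSE])
      th <- best_threshold(pa$labels[sp$calib], p_cal)
      p_val <- fit$predict(pa$predictors[sp$valid, , drop = FALSE])
      jv <- jaccard_binary(pa$labels[sp$valid], as.integer(p_val >= th$threshold))
      retained <- jv > retention_cutoff
      if (retained) {
        fit$calibration_threshold <- th$threshold
        fit$jaccard_validation <- jv
        fit$cv_rep <- r
        members[[length(members) + 1]] <- fit
      }
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        species_id = pa$species_id, family = fam, cv_rep = r,
        threshold = th$threshold, jaccard_validation = jv,
        status = "ok", retained = retained
      )
    }
  }
  manifest <- purrr::list_rbind(manifest)
  structure(
    list(
      species_id = pa$species_id, members = members, manifest = manifest,
      n_trained = length(families) * n_reps, n_retained = length(members),
      predictor_names = colnames(pa$predictors)
    ),
    class = "sdm_ensemble"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("Ensemble for", x$species_id, ":", x$n_retained, "of", x$n_trained,
      "members retained\n")
  invisible(x)
}

#' @rdname cross_validate
#' @param x An `sdm_ensemble`.
#' @param ... Unused.
#' @export
tidy.sdm_ensemble <- function(x, ...) x$manifest

#' Project an ensemble onto monthly climatologies
#'
#' Each retained member predicts a presence probability for every grid cell
#' of every month and binarizes it at its own calibration threshold; the
#' species' monthly habitat suitability index (HSI) is the committee
#' fraction, i.e. the mean of the member binary grids, and the annual HSI
#' is the mean over the 12 months.
#'
#' @param ensemble A non-empty `sdm_ensemble`.
#' @param env An `env_clim` providing every predictor monthly.
#' @return Object of class `hsi_map`: `species_id`, `monthly` tibble
#'   (`cell_id`, `month`, `hsi`), `annual` tibble (`cell_id`, `hsi`).
#' @export
project_hsi <- function(ensemble, env) {
  stopifnot(inherits(ensemble, "sdm_ensemble"), inherits(env, "env_clim"))
  if (length(ensemble$members) == 0) {
    stop("empty ensemble: no retained members to project")
  }
  missing <- setdiff(ensemble$predictor_names, colnames(env$monthly))
  if (length(missing) > 0) {
    stop("predictor field(s) missing from climatology: ",
         paste(missing, collapse = ", "))
  }
  Xall <- as.matrix(env$monthly[, ensemble$predictor_names, drop = FALSE])
  bin <- vapply(ensemble$members, function(m) {
    as.integer(m$predict(Xall) >= m$calibration_threshold)
  }, integer(nrow(Xall)))
  monthly <- tibble::tibble(
    cell_id = env$monthly$cell_id, month = env$monthly$month,
    hsi = rowMeans(matrix(bin, nrow = nrow(Xall)))
  )
  annual <- monthly |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(hsi = mean(.data$hsi), .groups = "drop")
  structure(
    list(species_id = ensemble$species_id, monthly = monthly, annual = annual),
    class = "hsi_map"
  )
}

#' @export
print.hsi_map <- function(x, ...) {
  cat("HSI map for", x$species_id, ": mean annual HSI",
      sprintf("%.3f", mean(x$annual$hsi)), "over", nrow(x$annual), "cells\n")
  invisible(x)
}

#' Fit ensembles for every modelable species in a community
#'
#' Runs the full per-species workflow: presence-absence assembly,
#' species-specific predictor selection (permutation importance +
#' collinearity screening), repeated cross-validation with Jaccard
#' retention, and optional projection.
#'
#' @param table A filtered `community_tbl`.
#' @param env An `env_clim`.
#' @param species_ids Species to model (default: all rows of `table`).
#' @param min_occurrences Presence threshold below which a species is
#'   skipped (default 20).
#' @param families,n_reps,retention_cutoff,seed Passed to
#'   [cross_validate()].
#' @param rho_cut,top_n Passed to [select_predictors()].
#' @param project Also compute each species' HSI map (default `TRUE`).
#' @return List of class `sdm_run`: `ensembles` (named list), `maps`
#'   (named list of `hsi_map`, possibly empty entries dropped), `skipped`
#'   tibble, `manifest` tibble over all trained members.
#' @export
sdm_all <- function(table, env, species_ids = rownames(table$counts),
                    min_occurrences = 20, families = SDM_FAMILIES,
                    n_reps = 5, retention_cutoff = 0.3,
                    rho_cut = 0.7, top_n = 4, seed = 1, project = TRUE) {
  ensembles <- list()
  maps <- list()
  skipped <- list()
  for (sp in species_ids) {
    pa <- build_pa(table, sp, env, min_occurrences = min_occurrences)
    if (inherits(pa, "sdm_skip")) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        species_id = sp, reason = pa$reason)
      next
    }
    preds <- select_predictors(pa, rho_cut = rho_cut, top_n = top_n, seed = seed)
    pa$predictors <- pa$predictors[, preds, drop = FALSE]
    ens <- tryCatch(
      cross_validate(pa, families = families, n_reps = n_reps,
                     retention_cutoff = retention_cutoff, seed = seed),
      error = function(e) e
    )
    if (inherits(ens, "error")) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        species_id = sp, reason = conditionMessage(ens))
      next
    }
    ensembles[[sp]] <- ens
    if (project && ens$n_retained > 0) {
      maps[[sp]] <- project_hsi(ens, env)
    }
  }
  structure(
    list(
      ensembles = ensembles, maps = maps,
      skipped = purrr::list_rbind(skipped),
      manifest = purrr::list_rbind(purrr::map(ensembles, "manifest"))
    ),
    class = "sdm_run"
  )
}

#' @export
print.sdm_run <- function(x, ...) {
  cat("SDM run:", length(x$ensembles), "species modeled,",
      if (is.null(x$skipped)) 0 else nrow(x$skipped), "skipped;",
      sum(x$manifest$retained, na.rm = TRUE), "of", nrow(x$manifest),
      "members retained\n")
  invisible(x)
}
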