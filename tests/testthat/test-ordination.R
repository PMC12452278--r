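# brute-force RV via explicit cross-product matrices and matrix products
rv_oracle <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  Sab <- t(A) %*% B
  Sba <- t(B) %*% A
  Saa <- t(A) %*% A
  Sbb <- t(B) %*% B
  sum(diag(Sab %*% Sba)) / sqrt(sum(diag(Saa %*% Saa)) * sum(diag(Sbb %*% Sbb)))
}

test_that("RV coefficient: identity, rotation invariance, null level", {
  set.seed(1)
  A <- matrix(rnorm(60), 20, 3)
  expect_equal(rv_coefficient(A, A), 1, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(rv_coefficient(A, A %*% Q), 1, tolerance = 1e-12)
  expect_equal(rv_coefficient(A, A * 7 + 2), 1, tolerance = 1e-12)

  B <- matrix(rnorm(60), 20, 3)
  expect_equal(rv_coefficient(A, B), rv_oracle(A, B), tolerance = 1e-12)

  set.seed(2)
  A2 <- matrix(rnorm(3e4), 1e4, 3)
  B2 <- matrix(rnorm(3e4), 1e4, 3)
  expect_lt(rv_coefficient(A2, B2), 0.05)

  expect_error(rv_coefficient(matrix(0, 5, 2), A[1:5, ]), "all-zero")
})

test_that("Escoufier selection is greedy-optimal with a sane trajectory", {
  set.seed(3)
  Y <- matrix(rnorm(40 * 6), 40, 6)
  Y[, 4] <- Y[, 1] # exact duplicate
  colnames(Y) <- paste0("s", 1:6)
  sel <- escoufier_select(Y, threshold = 1)
  # first pick is the single column with the highest RV against the full set
  rv1 <- vapply(colnames(Y), function(v) {
    rv_coefficient(Y[, v, drop = FALSE], Y)
  }, numeric(1))
  expect_equal(sel$selected[1], names(which.max(rv1)))
  expect_equal(sel$rv_trajectory[1], max(rv1), tolerance = 1e-12)
  expect_true(all(diff(sel$rv_trajectory) >= -1e-12))

  # threshold 1 on full-rank independent columns selects everything
  set.seed(4)
  Z <- matrix(rnorm(30 * 5), 30, 5)
  colnames(Z) <- paste0("v", 1:5)
  sel_all <- escoufier_select(Z, threshold = 1)
  expect_setequal(sel_all$selected, colnames(Z))
  expect_equal(sel_all$rv_trajectory[length(sel_all$rv_trajectory)], 1,
    tolerance = 1e-10)

  expect_error(escoufier_select(matrix(numeric(0), 5, 0)), "empty")
})

# dense-algebra oracle: explicit hat matrix + full eigendecomposition
rda_oracle <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xs <- scale(as.matrix(X))
  H <- Xs %*% solve(t(Xs) %*% Xs) %*% t(Xs)
  Yhat <- H %*% Yc
  n <- nrow(Yc)
  ev_c <- eigen(t(Yhat) %*% Yhat / (n - 1), symmetric = TRUE)$values
  ev_r <- eigen(t(Yc - Yhat) %*% (Yc - Yhat) / (n - 1), symmetric = TRUE)$values
  r2 <- sum(Yhat^2) / sum(Yc^2)
  list(
    can = ev_c[ev_c > 1e-12 * max(ev_c, 1)],
    res = ev_r[ev_r > 1e-12 * max(ev_r, 1)],
    r2 = r2,
    adj = 1 - (1 - r2) * (n - 1) / (n - ncol(Xs) - 1)
  )
}

test_that("RDA reproduces exact fits, nulls, and the dense-algebra oracle", {
  # noiseless linear response: everything explained
  set.seed(5)
  X <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "x"))
  Y <- cbind(2 * X[, 1], -X[, 1] + 3)
  f <- rda_fit(Y, X)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_length(f$residual_eigenvalues, 0)

  # worked toy: 4 sites x 2 species x 1 predictor against the oracle
  Xt <- matrix(c(-1, 0, 1, 2), 4, 1, dimnames = list(NULL, "sst"))
  Yt <- cbind(c(0.2, 0.4, 0.5, 0.9), c(0.8, 0.7, 0.4, 0.1))
  ft <- rda_fit(Yt, Xt)
  ot <- rda_oracle(Yt, Xt)
  expect_equal(ft$canonical_eigenvalues, ot$can, tolerance = 1e-10)
  expect_equal(ft$residual_eigenvalues, ot$res, tolerance = 1e-10)
  expect_equal(ft$r_squared, ot$r2, tolerance = 1e-10)
  expect_equal(ft$adj_r_squared, ot$adj, tolerance = 1e-10)

  # pure-noise predictor: adjusted R^2 near zero
  set.seed(6)
  Xn <- matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "noise"))
  Yn <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(abs(rda_fit(Yn, Xn)$adj_r_squared), 0.02)

  # eigenvalue conservation: canonical + residual = total variance
  set.seed(7)
  Y3 <- matrix(rnorm(25 * 4), 25, 4)
  X3 <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("a", "b")))
  f3 <- rda_fit(Y3, X3)
  expect_equal(
    sum(f3$canonical_eigenvalues) + sum(f3$residual_eigenvalues),
    f3$total_variance, tolerance = 1e-8
  )

  # collinear predictors are refused with advice
  Xc <- cbind(a = rnorm(30), b = 0)
  Xc[, "b"] <- 2 * Xc[, "a"]
  expect_error(rda_fit(matrix(rnorm(60), 30, 2), Xc), "collinearity")
})

test_that("RDA agrees with vegan on R2 and eigenvalue structure", {
  expect_true(requireNamespace("vegan", quietly = TRUE))
  set.seed(8)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  f <- rda_fit(Y, X)
  v <- vegan::rda(Y ~ a + b, data = X)
  expect_equal(unname(f$canonical_eigenvalues),
    unname(v$CCA$eig[v$CCA$eig > 1e-10]), tolerance = 1e-6)
  expect_equal(f$r_squared, vegan::RsquareAdj(v)$r.squared, tolerance = 1e-8)
  expect_equal(f$adj_r_squared, vegan::RsquareAdj(v)$adj.r.squared,
    tolerance = 1e-8)
})

test_that("AIC backward selection keeps drivers and drops noise", {
  set.seed(9)
  n <- 500
  driver <- rnorm(n)
  noise <- rnorm(n)
  Y <- cbind(driver + rnorm(n, sd = 0.3), -0.5 * driver + rnorm(n, sd = 0.3))
  X <- data.frame(driver = driver, noise = noise)
  runs <- lapply(1:20, function(i) {
    set.seed(100 + i)
    nz <- rnorm(n)
    aic_backward_select(Y, data.frame(driver = driver, noise = nz))$selected
  })
  # the true driver is never dropped; pure noise is dropped most of the time
  expect_true(all(vapply(runs, function(s) "driver" %in% s, logical(1))))
  expect_gte(mean(vapply(runs, function(s) !"noise" %in% s, logical(1))), 0.7)

  # all-noise candidates: AIC trace is non-increasing, set may empty out
  set.seed(10)
  Yn <- matrix(rnorm(200), 100, 2)
  Xn <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  seln <- aic_backward_select(Yn, Xn)
  expect_true(all(diff(seln$trace$aic) <= 1e-10))

  # a single exact generator survives
  sel1 <- aic_backward_select(Y, X["driver"])
  expect_equal(sel1$selected, "driver")
})
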