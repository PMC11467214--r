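# Decomposition engine: unfolding conventions, Khatri-Rao, censored least
# squares, initialization, ALS fitting and the variance-explained metrics.

test_that("unfold obeys the shape law and folds back exactly", {
  x <- array(1:8, dim = c(2, 2, 2))
  expect_equal(dim(unfold(x, 1)), c(2L, 4L))
  y <- withr::with_seed(4, array(rnorm(120), dim = c(4, 5, 3, 2)))
  for (m in 1:4)
    expect_identical(foldTensor(unfold(y, m), m, dim(y)), y)
  expect_error(unfold(y, 5), "mode")
})

test_that("unfolding satisfies X_(1) = A (C o B)^T for a known rank-2 tensor", {
  withr::with_seed(2, {
    A <- matrix(rnorm(8), 4, 2)
    B <- matrix(rnorm(10), 5, 2)
    C <- matrix(rnorm(12), 6, 2)
  })
  X <- array(0, dim = c(4, 5, 6))
  for (r in 1:2) X <- X + A[, r] %o% B[, r] %o% C[, r]
  expect_lt(max(abs(unfold(X, 1) - tcrossprod(A, khatriRao(list(C, B))))),
            1e-10)
})

test_that("khatriRao matches the column-wise Kronecker oracle", {
  expect_equal(dim(khatriRao(list(matrix(1, 2, 2), matrix(1, 3, 2)))),
               c(6L, 2L))
  # unit basis columns land at the Kronecker index
  e <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
  out <- khatriRao(list(cbind(e(1, 2), e(2, 2)), cbind(e(3, 3), e(1, 3))))
  expect_equal(out[, 1], e(3, 6))
  expect_equal(out[, 2], e(4, 6))
  # random case vs explicit kronecker() per column, and vs Matrix::KhatriRao
  withr::with_seed(3, {
    a <- matrix(rnorm(6), 3, 2)
    b <- matrix(rnorm(8), 4, 2)
  })
  out <- khatriRao(list(a, b))
  for (r in 1:2) expect_equal(out[, r], as.vector(kronecker(a[, r], b[, r])))
  expect_equal(out, as.matrix(Matrix::KhatriRao(a, b)), ignore_attr = TRUE)
  expect_error(khatriRao(list(a, matrix(1, 4, 3))), "column count")
})

test_that("censored least squares reduces to OLS on full masks and matches row-deleted solves", {
  withr::with_seed(6, {
    A <- matrix(rnorm(40), 10, 4)
    B <- matrix(rnorm(30), 10, 3)
  })
  full <- matrix(TRUE, 10, 3)
  ols <- qr.coef(qr(A), B)
  expect_equal(censoredLstsq(A, B, full), ols, tolerance = 1e-10,
               ignore_attr = TRUE)

  # one masked row in one column: normal equations on the row subset
  obs <- full; obs[4, 2] <- FALSE
  got <- censoredLstsq(A, B, obs)
  sub <- solve(crossprod(A[-4, ]), crossprod(A[-4, ], B[-4, 2]))
  expect_equal(got[, 2], as.vector(sub), tolerance = 1e-10)
  expect_equal(got[, c(1, 3)], ols[, c(1, 3)], tolerance = 1e-10,
               ignore_attr = TRUE)

  # batching by shared pattern is an optimization, not a semantic
  obs2 <- full; obs2[c(2, 7), ] <- FALSE  # identical pattern in all columns
  batched <- censoredLstsq(A, B, obs2)
  oneByOne <- vapply(1:3, function(j)
    censoredLstsq(A, B[, j, drop = FALSE], obs2[, j, drop = FALSE])[, 1],
    numeric(4))
  expect_equal(batched, oneByOne, tolerance = 1e-12)

  # zero observed rows: zeros plus a warning
  obs3 <- full; obs3[, 1] <- FALSE
  expect_warning(z <- censoredLstsq(A, B, obs3), "zero observed")
  expect_equal(z[, 1], rep(0, 4))
})

test_that("SVD initialization recovers rank-1 structure and matches a dense SVD oracle", {
  a <- c(1, 0, 0); b <- c(0, 1, 0, 0); c_ <- c(0, 0, 1, 0, 0)
  X <- a %o% b %o% c_
  ini <- initializeSVD(makeTensor(X), 1)
  expect_equal(abs(ini[[1]][, 1]), a)
  expect_equal(abs(ini[[2]][, 1]), b)
  expect_equal(abs(ini[[3]][, 1]), c_)

  Y <- withr::with_seed(9, array(rnorm(60), dim = c(5, 4, 3)))
  lt <- makeTensor(Y)
  ini2 <- initializeSVD(lt, 2)
  expect_identical(ini2, initializeSVD(lt, 2))  # deterministic
  for (m in 1:3) {
    ref <- svd(unfold(Y, m))$u[, 1:2]
    expect_equal(abs(ini2[[m]]), abs(ref), tolerance = 1e-10)
  }
})

test_that("ALS recovers noiseless low-rank tensors", {
  s <- smallStudy(n_subjects = 4, n_bc = 1,
                  mode_sizes = c(treatment = 5, marker = 6), rank = 2,
                  seed = 23)
  fit <- fitCPD(s$tensor, 2, tol = 1e-12)
  expect_gte(r2x(fit$decomposition, s$tensor), 1 - 1e-8)
  expect_gte(factorMatchScore(fit$decomposition,
                              CPDecomposition(s$truth$factors,
                                              s$truth$weights)), 0.99)

  # all-ones tensor is rank 1 with ones-proportional factors
  ones <- makeTensor(array(1, dim = c(3, 3, 3)))
  f1 <- fitCPD(ones, 1, tol = 1e-12)
  expect_lt(max(abs(reconstruct(f1$decomposition) - 1)), 1e-8)
  for (f in factorMatrices(f1$decomposition))
    expect_equal(f[, 1], rep(1 / sqrt(3), 3), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("censored and plain ALS produce identical iterates on complete tensors", {
  x <- withr::with_seed(14, array(rnorm(10 * 8 * 6), dim = c(10, 8, 6)))
  lt <- makeTensor(x)
  f1 <- fitCPD(lt, 3, tol = 0, maxIter = 10, trace = TRUE, censored = TRUE)
  f2 <- fitCPD(lt, 3, tol = 0, maxIter = 10, trace = TRUE, censored = FALSE)
  for (i in seq_along(f1$report$factor_trajectory)) {
    d <- max(mapply(function(a, b) max(abs(a - b)),
                    f1$report$factor_trajectory[[i]],
                    f2$report$factor_trajectory[[i]]))
    expect_lt(d, 1e-10)
  }
  expect_error(fitCPD(smallStudy(missing_fraction = 0.1,
                                 missing_mode = "entrywise")$tensor,
                      2, censored = FALSE), "fully observed")
})

test_that("accepted R2X trajectories are non-decreasing", {
  for (seed in c(2, 5)) {
    s <- smallStudy(n_subjects = 10, n_bc = 4,
                    mode_sizes = c(treatment = 6, marker = 5), rank = 3,
                    noise_sd = 0.3, missing_fraction = 0.1,
                    missing_mode = "entrywise", seed = seed)
    fit <- fitCPD(s$tensor, 3)
    expect_true(all(diff(fit$report$r2x_trajectory) > -1e-10))
  }
})

test_that("reconstruct has the stated closed forms", {
  u <- rep(1 / sqrt(2), 2)
  cp <- CPDecomposition(list(a = cbind(u), b = cbind(u)), weights = 3)
  expect_equal(reconstruct(cp), matrix(3 / 2, 2, 2), ignore_attr = TRUE)
  cp0 <- CPDecomposition(list(a = cbind(u), b = cbind(u)), weights = 0)
  expect_equal(reconstruct(cp0), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("r2x matches an explicit two-loop summation and has its fixed points", {
  s <- smallStudy(noise_sd = 0.4, missing_fraction = 0.15,
                  missing_mode = "entrywise", seed = 44)
  fit <- fitCPD(s$tensor, 2)
  v <- tensorValues(s$tensor); m <- tensorMask(s$tensor)
  xhat <- reconstruct(fit$decomposition)
  num <- 0; den <- 0
  for (i in which(m)) {
    num <- num + (v[i] - xhat[i])^2
    den <- den + v[i]^2
  }
  expect_equal(r2x(fit$decomposition, s$tensor), 1 - num / den,
               tolerance = 1e-12)

  # perfect reconstruction -> 1; zero decomposition -> 0
  noiseless <- smallStudy(seed = 2)
  tcp <- CPDecomposition(noiseless$truth$factors, noiseless$truth$weights)
  expect_equal(r2x(tcp, noiseless$tensor), 1, tolerance = 1e-12)
  zcp <- CPDecomposition(lapply(noiseless$truth$factors, function(f) f),
                         weights = rep(0, 2))
  expect_equal(r2x(zcp, noiseless$tensor), 0, tolerance = 1e-12)
})

test_that("r2x and reconstruct are invariant to component permutation and weight-scale moves", {
  s <- smallStudy(rank = 3, seed = 6, noise_sd = 0.2)
  fit <- fitCPD(s$tensor, 3)
  f <- factorMatrices(fit$decomposition)
  w <- componentWeights(fit$decomposition)
  perm <- c(3, 1, 2)
  cpPerm <- CPDecomposition(lapply(f, function(m) m[, perm]), w[perm])
  expect_equal(reconstruct(cpPerm), reconstruct(fit$decomposition),
               tolerance = 1e-12)
  # moving scale from weights into one mode's columns leaves recon unchanged
  f2 <- f
  f2[[2]] <- sweep(f2[[2]], 2, w, "*")
  cp2 <- CPDecomposition(f2, weights = rep(1, 3))
  expect_equal(reconstruct(cp2), reconstruct(fit$decomposition),
               tolerance = 1e-10)
})

test_that("Q2X is near-perfect at the true rank on noiseless data and degrades at rank 1", {
  s <- smallStudy(n_subjects = 10, n_bc = 4,
                  mode_sizes = c(treatment = 8, marker = 6), rank = 3,
                  seed = 12)
  q3 <- q2xImputation(s$tensor, 3, 0.1, n_repeats = 2, seed = 3,
                      tol = 1e-12)
  q1 <- q2xImputation(s$tensor, 1, 0.1, n_repeats = 2, seed = 3,
                      tol = 1e-12)
  expect_gte(q3$q2x, 0.999)
  expect_lt(q1$q2x, q3$q2x)
  expect_error(q2xImputation(s$tensor, 3, holdout_fraction = 0), "holdout")
})
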