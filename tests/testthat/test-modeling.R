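# Classification and association statistics on subject factors.

test_that("L1 logistic separates a clean margin and zeroes out on empty features", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- cbind(feat = c(-3, -2.5, -2, 2, 2.5, 3))
  fit <- fitL1Logistic(x, y, seed = 1)
  eta <- fit$intercept + x %*% fit$coefficients
  expect_equal(as.integer(eta > 0), y)

  z <- matrix(0, 8, 2)
  yz <- c(0, 0, 0, 1, 1, 1, 1, 1)
  fitz <- fitL1Logistic(z, yz, seed = 1)
  expect_equal(unname(fitz$coefficients), c(0, 0))
  # prediction falls back to the majority class via the intercept
  expect_true(all((fitz$intercept > 0) == 1))

  expect_error(fitL1Logistic(x, rep(1, 6)), "both classes")
})

test_that("at near-zero penalty the decision function agrees with an unpenalized likelihood fit", {
  withr::with_seed(21, {
    x <- cbind(a = rnorm(6, c(0, 0, 0, 2, 2, 2)),
               b = rnorm(6))
  })
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fitL1Logistic(x, y, reg_grid = 1e6, cv_folds = 0, seed = 1)
  oracle <- suppressWarnings(glm(y ~ x, family = binomial))
  etaFit <- fit$intercept + x %*% fit$coefficients
  etaOracle <- predict(oracle)
  expect_equal(sign(etaFit), sign(etaOracle), ignore_attr = TRUE)
})

test_that("repeated CV is deterministic in its seed and centered on chance under the null", {
  withr::with_seed(30, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- rep(c(0, 1), each = 20)   # balanced; features carry no signal
  })
  cv1 <- repeatedCVAccuracy(X, y, folds = 5, repeats = 3, seed = 9)
  cv2 <- repeatedCVAccuracy(X, y, folds = 5, repeats = 3, seed = 9)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  # 99% binomial band around 0.5 with n = 40 effective predictions
  band <- 2.576 * sqrt(0.25 / 40)
  expect_lt(abs(cv1$mean_accuracy - 0.5), band + 0.1)

  expect_warning(repeatedCVAccuracy(X[1:7, ], y[c(1:4, 21:23)],
                                    folds = 10, repeats = 1, seed = 2),
                 "reducing folds")
})

test_that("strongly separated subject factors classify accurately", {
  s <- smallStudy(n_subjects = 36, n_bc = 14,
                  mode_sizes = c(treatment = 6, marker = 4), rank = 3,
                  effect_size = 4, noise_sd = 0.1, seed = 2)
  cv <- repeatedCVAccuracy(s$truth$factors[[1]], s$labels, folds = 10,
                           repeats = 3, seed = 5)
  expect_gte(cv$mean_accuracy, 0.9)
})

test_that("rank selection returns the trivial grid and is unaffected by adding a noise rank", {
  s <- smallStudy(n_subjects = 20, n_bc = 8,
                  mode_sizes = c(treatment = 6, marker = 5), rank = 3,
                  effect_size = 4, noise_sd = 0.05, seed = 3,
                  disease_components = 2)
  cvOpts <- list(folds = 5, repeats = 2, seed = 7)
  one <- selectRank(s$tensor, s$labels, 1, cv_options = cvOpts)
  expect_equal(one$best_rank, 1)
  expect_equal(nrow(one$curve), 1L)

  scanA <- selectRank(s$tensor, s$labels, 1:3, cv_options = cvOpts,
                      fit_options = list(tol = 1e-8))
  scanB <- selectRank(s$tensor, s$labels, 1:4, cv_options = cvOpts,
                      fit_options = list(tol = 1e-8))
  expect_gte(scanA$best_rank, 2)
  expect_equal(scanB$best_rank, scanA$best_rank)
})

test_that("component-status correlation: perfect predictor, closed-form point-biserial, constant flag", {
  # perfect predictor at n = 20: no shuffle reproduces |r| = 1, so the
  # permutation p attains its floor 1/(1 + n_perm)
  y20 <- rep(c(0, 1), each = 10)
  resP <- componentStatusCorrelation(cbind(y20), y20, n_perm = 500, seed = 3)
  expect_equal(resP$r[1], 1, tolerance = 1e-12)
  expect_equal(resP$p_perm[1], 1 / 501, tolerance = 1e-12)

  y <- c(0, 0, 0, 1, 1, 1)
  X <- cbind(toy = c(1.2, 0.7, -0.3, 2.5, 3.1, 2.0), flat = rep(2, 6))
  names(y) <- rownames(X) <- sprintf("s%d", 1:6)
  res <- componentStatusCorrelation(X, y, n_perm = 500, seed = 3)
  # point-biserial closed form: r = (m1 - m0)/s_n * sqrt(p*q)
  x <- X[, 1]
  n <- length(x)
  sn <- sqrt(sum((x - mean(x))^2) / n)
  rOracle <- (mean(x[y == 1]) - mean(x[y == 0])) / sn * sqrt(0.5 * 0.5)
  expect_equal(res$r[1], rOracle, tolerance = 1e-12)
  expect_true(res$constant[2])
  expect_equal(res$p_perm[2], 1)
})

test_that("Mann-Whitney U: exact enumeration, tie handling, symmetry", {
  # enumeration oracle over all C(4,2) = 6 label arrangements
  pool <- c(1, 2, 3, 4)
  Ufun <- function(a, b) sum(rank(c(a, b))[1:2]) - 3
  allU <- apply(combn(4, 2), 2, function(ix) Ufun(pool[ix], pool[-ix]))
  obs <- Ufun(c(1, 2), c(3, 4))
  pEnum <- mean(allU <= obs) + mean(allU >= 4 - obs)
  got <- mannwhitneyU(c(1, 2), c(3, 4))
  expect_equal(got$U, 0)
  expect_equal(got$method, "exact")
  expect_equal(got$p, pEnum)        # 1/3
  expect_equal(got$p, 1 / 3, tolerance = 1e-12)

  tied <- mannwhitneyU(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$U, 4.5)
  expect_equal(tied$p, 1)

  withr::with_seed(40, {
    a <- rnorm(9); b <- rnorm(7)
  })
  f <- mannwhitneyU(a, b)
  g <- mannwhitneyU(b, a)
  expect_equal(g$U, length(a) * length(b) - f$U)
  expect_equal(f$p, g$p, tolerance = 1e-12)
  # against the standard implementation on tie-free data
  ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(f$U, unname(ref$statistic))
  expect_equal(f$p, ref$p.value, tolerance = 1e-10)
})

test_that("hierarchical ordering merges duplicates first and keeps blobs contiguous", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  ho <- hierarchicalOrder(X)
  expect_equal(ho$height[1], 0)
  expect_equal(sort(ho$merge[1, ]), c(-2, -1))

  withr::with_seed(50, {
    blob1 <- matrix(rnorm(10 * 2, 0, 0.3), 10, 2)
    blob2 <- matrix(rnorm(8 * 2, 6, 0.3), 8, 2)
  })
  Y <- rbind(blob1, blob2)
  ho2 <- hierarchicalOrder(Y)
  grp <- (ho2$order > 10) * 1
  expect_equal(sum(diff(grp) != 0), 1L)  # one contiguous switch

  # permutation invariance of the merge heights
  perm <- withr::with_seed(51, sample(nrow(Y)))
  ho3 <- hierarchicalOrder(Y[perm, ])
  expect_equal(sort(ho3$height), sort(ho2$height), tolerance = 1e-12)
})

test_that("partial correlations: 2-variable case equals Pearson, structural zeros recovered, symmetric unit diagonal", {
  X2 <- withr::with_seed(60, matrix(rnorm(200), 100, 2))
  X2[, 2] <- X2[, 2] + 0.6 * X2[, 1]
  pc <- partialCorrelationMatrix(X2)
  expect_equal(pc[1, 2], cor(X2)[1, 2], tolerance = 1e-12)

  # chain graph X1 - X2 - X3 - X4: Omega has a structural zero at (1, 3)
  Omega <- diag(4)
  Omega[1, 2] <- Omega[2, 1] <- 0.4
  Omega[2, 3] <- Omega[3, 2] <- 0.4
  Omega[3, 4] <- Omega[4, 3] <- 0.4
  Sigma <- solve(Omega)
  L <- chol(Sigma)
  Z <- withr::with_seed(61, matrix(rnorm(2000 * 4), 2000, 4)) %*% L
  pcz <- partialCorrelationMatrix(Z)
  expect_lt(abs(pcz[1, 3]), 0.05)
  expect_lt(abs(pcz[1, 4]), 0.05)
  expect_gt(abs(pcz[1, 2]), 0.2)
  expect_equal(pcz, t(pcz))
  expect_equal(unname(diag(pcz)), rep(1, 4))
})

test_that("ROC endpoints, trapezoid identity with U, and oracle agreement", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(rocAuc(c(1, 2, 3, 9, 10), y)$auc, 1)
  expect_equal(rocAuc(rep(4, 5), y)$auc, 0.5)

  withr::with_seed(70, s <- rnorm(8))
  y8 <- c(0, 1, 0, 1, 1, 0, 0, 1)
  got <- rocAuc(s, y8)
  mw <- mannwhitneyU(s[y8 == 1], s[y8 == 0])
  expect_equal(got$auc, mw$U / (4 * 4), tolerance = 1e-12)
  ref <- suppressMessages(pROC::auc(pROC::roc(y8, s, quiet = TRUE,
                                              direction = "<")))
  expect_equal(got$auc, as.numeric(ref), tolerance = 1e-12)
})
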