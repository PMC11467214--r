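# Downstream statistics on subject factors and raw slices: L1-penalized
# logistic classification with repeated stratified cross-validation,
# classification-based rank selection, permutation correlation tests,
# Mann-Whitney U, hierarchical ordering, shrinkage partial correlations,
# and ROC/AUC.

# Align a labels vector (possibly named) with a feature matrix; returns an
# integer 0/1 vector in row order.
alignLabels <- function(features, labels) {
  if (!is.null(names(labels)) && !is.null(rownames(features))) {
    stopIfNot(all(rownames(features) %in% names(labels)),
              "labels missing for subject(s): %s",
              paste(setdiff(rownames(features), names(labels)), collapse = ", "))
    labels <- labels[rownames(features)]
  }
  stopIfNot(length(labels) == nrow(features),
            "labels length (%d) does not match rows (%d)", length(labels),
            nrow(features))
  as.integer(labels)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt into folds round-robin. Deterministic given the seed.
stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Default regularization grid: 10 logarithmically spaced inverse strengths
# C in [1e-4, 1e4]; glmnet's lambda is 1/(n * C).
defaultRegGrid <- function() 10^seq(-4, 4, length.out = 10)

#' L1-penalized logistic regression with internal CV-chosen regularization
#'
#' Fits a lasso-penalized logistic model (via coordinate descent, iteration
#' cap 5000 and tolerance 1e-6). The regularization strength is chosen by
#' stratified cross-validation over a grid of 10 log-spaced inverse
#' strengths C spanning 1e-4..1e4 (ties resolved toward the sparser model).
#'
#' @param features numeric matrix, subjects x features.
#' @param labels 0/1 vector (or named vector matched by row names).
#' @param reg_grid inverse regularization strengths C (default
#'   `10^seq(-4, 4, length.out = 10)`).
#' @param cv_folds inner folds for choosing C (default 5, reduced to the
#'   minority class count when smaller).
#' @param seed RNG seed for the inner fold assignment.
#' @return list with `coefficients` (sparse, exact zeros possible),
#'   `intercept`, `chosen_C`, `chosen_lambda`, and the per-grid-point inner
#'   CV accuracy.
#' @export
fitL1Logistic <- function(features, labels, reg_grid = defaultRegGrid(),
                          cv_folds = 5, seed = 1L) {
  features <- as.matrix(features)
  y <- alignLabels(features, labels)
  stopIfNot(length(unique(y)) == 2, "both classes must be present")
  stopIfNot(all(is.finite(features)), "features must be finite")
  stopIfNot(min(table(y)) >= 2, "need at least 2 subjects per class")
  n <- nrow(features)
  lambdaGrid <- sort(1 / (n * reg_grid), decreasing = TRUE)
  k <- min(cv_folds, min(table(y)))
  cvAcc <- rep(0, length(lambdaGrid))
  if (k >= 2) {
    fold <- stratifiedFolds(y, k, seed)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (min(table(y[tr])) < 2) next
      fit <- glmnetBinomial(features[tr, , drop = FALSE], y[tr], lambdaGrid)
      pr <- predictGlmnetGrid(fit, features[!tr, , drop = FALSE], lambdaGrid)
      cvAcc <- cvAcc + colMeans(pr == y[!tr]) / k
    }
  }
  # best accuracy; ties toward larger lambda (stronger penalty, sparser)
  best <- which(cvAcc == max(cvAcc))[1]  # grid is sorted decreasing in lambda
  lam <- lambdaGrid[best]
  fit <- glmnetBinomial(features, y, lambdaGrid)
  beta <- coefAtLambda(fit, lam, ncol(features))
  list(coefficients = beta$coef, intercept = beta$intercept,
       chosen_lambda = lam, chosen_C = 1 / (n * lam),
       grid_lambda = lambdaGrid, grid_accuracy = cvAcc)
}

# glmnet refuses single-column design matrices; pad with an all-zero dummy
# column (its coefficient is identically zero) and strip it on extraction.
# Degenerate designs (every predictor constant) reduce to the
# intercept-only model, whose MLE is the log-odds of the class frequency.
glmnetBinomial <- function(x, y, lambdaGrid) {
  if (all(apply(x, 2, function(col) max(col) == min(col)))) {
    p <- mean(y == 1)
    out <- list(intercept = stats::qlogis(min(max(p, 1e-12), 1 - 1e-12)),
                p = ncol(x))
    class(out) <- "interceptOnly"
    return(out)
  }
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, 0)
  # the weakest penalties in the C grid routinely exhaust the iteration cap;
  # glmnet falls back to the converged stronger penalties, which is fine for
  # CV-based selection, so silence just that message
  fit <- withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 1, lambda = lambdaGrid, standardize = FALSE,
                   maxit = 5000, thresh = 1e-6),
    warning = function(w) {
      if (grepl("glmnet C\\+\\+ code|dangerous ground", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  attr(fit, "padded") <- padded
  fit
}

predictGlmnetGrid <- function(fit, newx, lambdaGrid) {
  if (inherits(fit, "interceptOnly"))
    return(matrix((fit$intercept > 0) * 1L, nrow(newx), length(lambdaGrid)))
  if (isTRUE(attr(fit, "padded"))) newx <- cbind(newx, 0)
  eta <- stats::predict(fit, newx = newx, s = lambdaGrid, type = "link")
  (eta > 0) * 1L
}

coefAtLambda <- function(fit, lam, p) {
  if (inherits(fit, "interceptOnly"))
    return(list(intercept = fit$intercept, coef = rep(0, p)))
  cf <- as.matrix(stats::predict(fit, s = lam, type = "coefficients",
                                 exact = FALSE))
  list(intercept = cf[1, 1], coef = cf[1 + seq_len(p), 1])
}

#' Repeated stratified cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation repeated `repeats` times; within each
#' training split the regularization strength is re-selected by inner CV
#' ([fitL1Logistic()]). Deterministic given the seed.
#'
#' @param features subjects x features matrix.
#' @param labels 0/1 cohort codes (named vectors matched by row names).
#' @param folds outer folds (default 10; reduced with a warning when a class
#'   is smaller).
#' @param repeats number of repeats (default 20).
#' @param seed RNG seed.
#' @param reg_grid passed to [fitL1Logistic()].
#' @return a `CVResult` list: `fold_accuracies` (folds x repeats matrix),
#'   `mean_accuracy`, `folds`, `repeats`, `seed`.
#' @export
repeatedCVAccuracy <- function(features, labels, folds = 10, repeats = 20,
                               seed = 1L, reg_grid = defaultRegGrid()) {
  features <- as.matrix(features)
  y <- alignLabels(features, labels)
  stopIfNot(length(unique(y)) == 2, "both classes must be present")
  minClass <- min(table(y))
  if (minClass < folds) {
    warning(sprintf("reducing folds from %d to minority class count %d",
                    folds, minClass))
    folds <- minClass
  }
  stopIfNot(folds >= 2, "need at least 2 folds")
  acc <- matrix(NA_real_, folds, repeats)
  for (r in seq_len(repeats)) {
    fold <- stratifiedFolds(y, folds, childSeed(seed, r))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (min(table(y[tr])) < 2) next  # degenerate split; fold left NA
      model <- fitL1Logistic(features[tr, , drop = FALSE], y[tr],
                             reg_grid = reg_grid,
                             seed = childSeed(seed, r * 1000L + f))
      eta <- model$intercept +
        features[!tr, , drop = FALSE] %*% model$coefficients
      acc[f, r] <- mean((eta > 0) == (y[!tr] == 1))
    }
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc, na.rm = TRUE),
                 folds = folds, repeats = repeats, seed = seed),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("Repeated stratified CV: %d folds x %d repeats, mean accuracy %.3f\n",
              x$folds, x$repeats, x$mean_accuracy))
  invisible(x)
}

#' Rank selection by disease-status classification
#'
#' For each candidate rank, fits the CPD, extracts the subject factors, and
#' scores [repeatedCVAccuracy()]; returns the rank maximizing mean accuracy
#' (ties resolved toward the smallest rank) and the full accuracy curve.
#'
#' @param tensor a [LabeledTensor-class] with subjects on the first axis.
#' @param labels cohort codes (subject -> 0/1).
#' @param rank_grid candidate ranks.
#' @param fit_options list of arguments for [fitCPD()].
#' @param cv_options list of arguments for [repeatedCVAccuracy()].
#' @return list with `best_rank` and `curve` (`data.frame` of rank,
#'   accuracy; NA where a fit failed).
#' @export
selectRank <- function(tensor, labels, rank_grid, fit_options = list(),
                       cv_options = list()) {
  stopIfNot(length(rank_grid) >= 1, "rank_grid must be nonempty")
  accs <- vapply(rank_grid, function(R) {
    tryCatch({
      fit <- do.call(fitCPD, c(list(tensor = tensor, rank = R), fit_options))
      sf <- factorMatrices(fit$decomposition)[[1]]
      do.call(repeatedCVAccuracy,
              c(list(features = sf, labels = labels), cv_options))$mean_accuracy
    }, error = function(e) {
      warning(sprintf("rank %d skipped: %s", R, conditionMessage(e)))
      NA_real_
    })
  }, numeric(1))
  ok <- which(!is.na(accs))
  stopIfNot(length(ok) > 0, "every candidate rank failed")
  best <- ok[which.max(accs[ok])]  # which.max takes the first (smallest rank) on ties
  list(best_rank = rank_grid[best],
       curve = data.frame(rank = rank_grid, accuracy = accs))
}

#' Component-status correlations with permutation p-values
#'
#' Pearson correlation of each subject-factor column against the 0/1 status
#' vector, with a two-sided permutation p-value
#' `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)` under label shuffling, plus
#' the analytic (t-distribution) p-value for reference.
#'
#' @param subject_factors subjects x components matrix.
#' @param labels cohort codes (subject -> 0/1).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed for the shuffles.
#' @return `data.frame` with columns `component`, `r`, `p_perm`,
#'   `p_analytic`, `constant` (flag for zero-variance columns, reported as
#'   r = 0, p = 1).
#' @export
componentStatusCorrelation <- function(subject_factors, labels,
                                       n_perm = 1000, seed = 1L) {
  X <- as.matrix(subject_factors)
  y <- alignLabels(X, labels)
  stopIfNot(nrow(X) >= 3, "need at least 3 subjects")
  stopIfNot(length(unique(y)) == 2, "both classes must be present")
  perms <- withSeed(seed, replicate(n_perm, sample(y)))
  res <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0)
      return(data.frame(component = j, r = 0, p_perm = 1, p_analytic = 1,
                        constant = TRUE))
    r <- stats::cor(x, y)
    rPerm <- as.vector(stats::cor(x, perms))
    pPerm <- (1 + sum(abs(rPerm) >= abs(r))) / (1 + n_perm)
    pAna <- stats::cor.test(x, y)$p.value
    data.frame(component = j, r = r, p_perm = pPerm, p_analytic = pAna,
               constant = FALSE)
  })
  do.call(rbind, res)
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling. The two-sided p-value uses the
#' exact rank-sum null distribution when `m + n <= 12` and there are no
#' ties, and otherwise a normal approximation with tie-corrected variance
#' and continuity correction (p = 1 when the tie-corrected variance is 0).
#'
#' @param group_a,group_b numeric vectors (per-subject measurements).
#' @return list with `U` (for `group_a`), `p`, and `method`.
#' @examples
#' mannwhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannwhitneyU <- function(group_a, group_b) {
  stopIfNot(length(group_a) > 0 && length(group_b) > 0,
            "both groups must be nonempty")
  m <- length(group_a)
  n <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(pooled)
  hasTies <- any(ties > 1)
  if (m + n <= 12 && !hasTies) {
    p <- min(1, 2 * min(stats::pwilcox(U, m, n),
                        stats::pwilcox(m * n - U, m, n)))
    method <- "exact"
  } else {
    mu <- m * n / 2
    tieTerm <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
    sigma2 <- m * n / 12 * ((m + n + 1) - tieTerm)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  list(U = U, p = p, method = method)
}

#' Hierarchical ordering of subjects
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of the subject-factor rows; returns the deterministic leaf
#' order and the merge tree.
#'
#' @param subject_factors subjects x components matrix (>= 2 rows).
#' @param method linkage (default `"average"`).
#' @param metric distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @return list with `order` (leaf indices), `labels` (row names in leaf
#'   order, when present), `merge`, `height`, and the `hclust` object.
#' @export
hierarchicalOrder <- function(subject_factors, method = "average",
                              metric = "euclidean") {
  X <- as.matrix(subject_factors)
  stopIfNot(nrow(X) >= 2, "need at least 2 subjects")
  hc <- stats::hclust(stats::dist(X, method = metric), method = method)
  list(order = hc$order,
       labels = if (!is.null(rownames(X))) rownames(X)[hc$order] else NULL,
       merge = hc$merge, height = hc$height, hclust = hc)
}

# Ledoit-Wolf-type shrinkage intensity toward the scaled identity target.
ledoitWolfLambda <- function(X) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  mu <- mean(diag(S))
  p <- ncol(S)
  d2 <- sum((S - mu * diag(p))^2) / p
  if (d2 == 0) return(0)
  b2bar <- 0
  for (k in seq_len(n)) {
    xk <- Xc[k, ]
    b2bar <- b2bar + sum((tcrossprod(xk) - S)^2) / p
  }
  b2bar <- b2bar / n^2
  min(b2bar, d2) / d2
}

#' Partial correlation matrix with covariance shrinkage
#'
#' Partial correlations from the precision matrix of a (possibly shrunk)
#' covariance estimate: `rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`,
#' with unit diagonal. Shrinkage is toward the scaled identity with a
#' Ledoit-Wolf intensity; the `"auto"` policy uses zero shrinkage when the
#' sample covariance is well-conditioned (more subjects than variables),
#' so with two variables the partial correlation is exactly the Pearson
#' correlation.
#'
#' @param measurements subjects x variables matrix (> 2 subjects).
#' @param shrinkage `"auto"` (default) or a numeric intensity in \[0, 1\].
#' @return symmetric variables x variables matrix with unit diagonal.
#' @export
partialCorrelationMatrix <- function(measurements, shrinkage = "auto") {
  X <- as.matrix(measurements)
  n <- nrow(X)
  p <- ncol(X)
  stopIfNot(n > 2, "need more than 2 subjects")
  S <- stats::cov(X)
  lam <- if (identical(shrinkage, "auto")) {
    wellCond <- p < n - 1 && kappa(S, exact = FALSE) < 1e10
    if (wellCond) 0 else ledoitWolfLambda(X)
  } else {
    stopIfNot(is.numeric(shrinkage) && shrinkage >= 0 && shrinkage <= 1,
              "shrinkage must be 'auto' or in [0, 1]")
    shrinkage
  }
  mu <- mean(diag(S))
  Sstar <- (1 - lam) * S + lam * mu * diag(p)
  Omega <- tryCatch(solve(Sstar), error = function(e)
    stop("covariance not invertible even after shrinkage", call. = FALSE))
  dOm <- sqrt(diag(Omega))
  rho <- -Omega / tcrossprod(dOm)
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- list(colnames(X), colnames(X))
  rho
}

#' ROC curve and AUC
#'
#' Threshold-sweep ROC for a per-subject score against 0/1 status; AUC by
#' the rank (Mann-Whitney) identity `AUC = U / (m n)`, which handles ties
#' by rank-averaging and equals the trapezoid area under the swept curve.
#' Higher scores are taken to indicate the positive (1) class.
#'
#' @param score numeric vector, one value per subject.
#' @param labels 0/1 cohort codes (named vectors matched by score names).
#' @return list with `points` (`data.frame` of fpr, tpr including the
#'   (0,0) and (1,1) endpoints) and `auc`.
#' @export
rocAuc <- function(score, labels) {
  if (!is.null(names(labels)) && !is.null(names(score)))
    labels <- labels[names(score)]
  y <- as.integer(labels)
  stopIfNot(length(y) == length(score), "score and labels lengths differ")
  stopIfNot(length(unique(y)) == 2, "both classes must be present")
  pos <- y == 1
  m <- sum(pos)
  n <- sum(!pos)
  r <- rank(score)
  U <- sum(r[pos]) - m * (m + 1) / 2
  auc <- U / (m * n)
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(score[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(score[!pos] >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  list(points = pts, auc = auc)
}
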