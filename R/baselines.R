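# Compression baselines: Tucker decomposition (higher-order orthogonal
# iteration) and PCA on the subject-flattened matrix, for side-by-side
# size/variance comparisons with CPD.

# mode-n product with t(U): contracts dims[n] down to ncol(U)
ttm <- function(x, U, mode) {
  d <- dim(x)
  Y <- crossprod(U, unfold(x, mode))
  d[mode] <- ncol(U)
  foldTensor(Y, mode, d)
}

#' Fit a Tucker decomposition by higher-order orthogonal iteration
#'
#' Comparison baseline only: requires complete data (missing entries are
#' mean-imputed with a warning). Initialized from per-mode SVDs, iterated
#' until the relative reconstruction-error change drops below `tol`.
#'
#' @param tensor a [LabeledTensor-class] or numeric array.
#' @param ranks integer vector of per-mode core sizes (clipped to the mode
#'   sizes with a warning).
#' @param tol relative error-change threshold (default `1e-8`).
#' @param maxIter maximum HOOI sweeps.
#' @return a [TuckerDecomposition-class].
#' @export
fitTucker <- function(tensor, ranks, tol = 1e-8, maxIter = 200) {
  if (is(tensor, "LabeledTensor")) {
    v <- tensorValues(tensor)
    if (!all(tensorMask(tensor))) {
      warning("Tucker baseline requires complete data; mean-imputing missing entries")
      v[is.na(v)] <- mean(v, na.rm = TRUE)
    }
  } else v <- tensor
  d <- dim(v)
  N <- length(d)
  stopIfNot(length(ranks) == N, "need one rank per mode")
  if (any(ranks > d)) {
    warning("ranks exceeding mode sizes clipped")
    ranks <- pmin(ranks, d)
  }
  U <- lapply(seq_len(N), function(n) svd(unfold(v, n), nu = ranks[n], nv = 0)$u)
  normX <- sqrt(sum(v^2))
  relErr <- Inf
  for (iter in seq_len(maxIter)) {
    for (n in seq_len(N)) {
      Y <- v
      for (k in seq_len(N)[-n]) Y <- ttm(Y, U[[k]], k)
      U[[n]] <- svd(unfold(Y, n), nu = ranks[n], nv = 0)$u
    }
    core <- v
    for (k in seq_len(N)) core <- ttm(core, U[[k]], k)
    # for orthonormal factors, ||X - recon||^2 = ||X||^2 - ||core||^2
    newErr <- sqrt(max(0, normX^2 - sum(core^2))) / normX
    if (is.finite(relErr) && abs(relErr - newErr) < tol * max(1, relErr)) {
      relErr <- newErr
      break
    }
    relErr <- newErr
  }
  new("TuckerDecomposition", core = core, factors = U)
}

#' Reconstruct the dense tensor from a Tucker decomposition
#'
#' @param tucker a [TuckerDecomposition-class].
#' @return numeric array.
#' @export
reconstructTucker <- function(tucker) {
  x <- tucker@core
  for (n in seq_along(tucker@factors)) {
    d <- dim(x)
    d[n] <- nrow(tucker@factors[[n]])
    x <- foldTensor(tucker@factors[[n]] %*% unfold(x, n), n, d)
  }
  x
}

#' Greedy Pareto-front Tucker rank search
#'
#' Walks the Pareto front of (parameter count, reconstruction error):
#' starting from all-ones ranks, repeatedly increments the single mode rank
#' whose increase yields the lowest reconstruction error, recording each
#' visited configuration.
#'
#' @param tensor a [LabeledTensor-class] or array (complete data).
#' @param max_ranks per-mode upper bounds (default the mode sizes).
#' @param ... further arguments to [fitTucker()].
#' @return `data.frame` with one row per visited configuration: the per-mode
#'   ranks, `n_parameters`, and relative reconstruction `error`.
#' @export
tuckerRankSearch <- function(tensor, max_ranks = NULL, ...) {
  v <- if (is(tensor, "LabeledTensor")) tensorValues(tensor) else tensor
  d <- dim(v)
  if (is.null(max_ranks)) max_ranks <- d
  max_ranks <- pmin(max_ranks, d)
  normX <- sqrt(sum(v^2))
  evalRanks <- function(r) {
    tk <- fitTucker(tensor, r, ...)
    sqrt(sum((v - reconstructTucker(tk))^2)) / normX
  }
  ranks <- rep(1L, length(d))
  rows <- list()
  rows[[1]] <- c(ranks, nParams = prod(ranks) + sum(ranks * d),
                 error = evalRanks(ranks))
  while (any(ranks < max_ranks)) {
    cand <- lapply(which(ranks < max_ranks), function(n) {
      r <- ranks; r[n] <- r[n] + 1L; r
    })
    errs <- vapply(cand, evalRanks, numeric(1))
    best <- which.min(errs)
    ranks <- cand[[best]]
    rows[[length(rows) + 1]] <- c(ranks,
                                  nParams = prod(ranks) + sum(ranks * d),
                                  error = errs[best])
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(sprintf("rank_mode%d", seq_along(d)), "n_parameters",
                  "error")
  out
}

#' PCA compression curve on the subject-flattened matrix
#'
#' Flattens the tensor to subjects x (all remaining conditions),
#' mean-imputes missing entries (baseline only), and reports cumulative
#' variance explained and parameter count per component count, for
#' side-by-side size comparison with CPD (whose parameter count is
#' [cpdParameterCount()]).
#'
#' @param tensor a [LabeledTensor-class].
#' @return `data.frame` with columns `components`, `variance_explained`
#'   (cumulative), `n_parameters` (`k * (n_subjects + n_columns)`).
#' @export
pcaCompressionCurve <- function(tensor) {
  X <- unfold(tensorValues(tensor), 1)
  for (j in seq_len(ncol(X))) {
    if (anyNA(X[, j])) {
      mu <- mean(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- if (is.finite(mu)) mu else 0
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  varex <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- seq_along(varex)
  data.frame(components = k,
             variance_explained = varex,
             n_parameters = k * (nrow(X) + ncol(X)))
}

#' CPD parameter count
#'
#' @param dims tensor mode sizes.
#' @param rank number of components.
#' @return `rank * sum(dims)`.
#' @examples
#' cpdParameterCount(c(36, 8, 23, 6), 12)  # 876
#' @export
cpdParameterCount <- function(dims, rank) rank * sum(dims)
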