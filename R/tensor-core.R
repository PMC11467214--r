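# Canonical polyadic decomposition by censored alternating least squares.
#
# Conventions follow the standard matricization in which the mode-1 unfolding
# of a rank-R tensor with factor matrices A, B, C satisfies
#   X_(1) = A (C o B)^T
# (o = Khatri-Rao product, remaining modes in reverse order), so the ALS
# normal equations hold literally for every mode.

#' Unfold (matricize) a tensor along one mode
#'
#' @param x numeric array (or [LabeledTensor-class], whose values are used).
#' @param mode mode index (1-based).
#' @return matrix of shape `(dim(x)[mode], prod(dim(x)[-mode]))`; columns are
#'   mode-`mode` fibers ordered so that the lowest remaining mode varies
#'   fastest.
#' @examples
#' x <- array(1:8, dim = c(2, 2, 2))
#' dim(unfold(x, 1))  # 2 x 4
#' @export
unfold <- function(x, mode) {
  if (is(x, "LabeledTensor")) x <- tensorValues(x)
  d <- dim(x)
  stopIfNot(mode >= 1 && mode <= length(d), "mode %d out of range", mode)
  matrix(aperm(x, c(mode, seq_along(d)[-mode])), nrow = d[mode])
}

#' Fold a matrix back into a tensor
#'
#' Inverse of [unfold()]: `foldTensor(unfold(x, m), m, dim(x))` recovers `x`.
#'
#' @param m matrix produced by [unfold()].
#' @param mode the mode that was unfolded.
#' @param dims the dimensions of the original tensor.
#' @return numeric array of dimensions `dims`.
#' @export
foldTensor <- function(m, mode, dims) {
  perm <- c(mode, seq_along(dims)[-mode])
  aperm(array(as.numeric(m), dim = dims[perm]), order(perm))
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' Column r of the result is the Kronecker product of the r-th columns of the
#' inputs, taken in list order (so the last matrix's index varies fastest).
#'
#' @param mats list of numeric matrices sharing a common column count R.
#' @return matrix with `prod(nrows)` rows and R columns.
#' @export
khatriRao <- function(mats) {
  stopIfNot(length(mats) >= 1, "need at least one matrix")
  ncols <- vapply(mats, ncol, integer(1))
  stopIfNot(length(unique(ncols)) == 1,
            "all matrices must share the column count (got %s)",
            paste(ncols, collapse = ", "))
  Reduce(function(a, b) {
    na <- nrow(a); nb <- nrow(b)
    a[rep(seq_len(na), each = nb), , drop = FALSE] *
      b[rep_len(seq_len(nb), na * nb), , drop = FALSE]
  }, mats)
}

#' Censored least squares
#'
#' Solves `design %*% coef ~ targets` column by column, using for each target
#' column only the rows where that column is observed. Columns sharing an
#' identical missingness pattern are solved in one batched call; with a fully
#' observed mask this reduces exactly to ordinary least squares.
#'
#' @param design numeric matrix (m x R).
#' @param targets numeric matrix (m x k); unobserved entries may hold any
#'   value (they are never read).
#' @param observed logical matrix (m x k), `TRUE` where `targets` is observed.
#' @param groups optional precomputed pattern grouping from
#'   `patternGroups(observed)`; supplied by [fitCPD()] to avoid re-hashing the
#'   fixed mask every sweep.
#' @return coefficient matrix (R x k). A target column with zero observed
#'   rows yields zero coefficients with a warning.
#' @export
censoredLstsq <- function(design, targets, observed, groups = NULL) {
  m <- nrow(design); R <- ncol(design); k <- ncol(targets)
  stopIfNot(nrow(targets) == m && all(dim(observed) == dim(targets)),
            "design, targets and observed must have matching rows")
  out <- matrix(0, R, k)
  if (is.null(groups)) groups <- patternGroups(observed)
  for (g in groups) {
    rows <- observed[, g[1]]
    if (!any(rows)) {
      warning(sprintf("target column(s) %s have zero observed rows; coefficients set to 0",
                      paste(g, collapse = ",")))
      next
    }
    if (all(rows)) {
      out[, g] <- qr.coef(qr(design, LAPACK = TRUE), targets[, g, drop = FALSE])
    } else {
      out[, g] <- qr.coef(qr(design[rows, , drop = FALSE], LAPACK = TRUE),
                          targets[rows, g, drop = FALSE])
    }
  }
  out[is.na(out)] <- 0  # rank-deficient row subsets: drop redundant directions
  out
}

# Group target-column indices by identical missingness pattern.
patternGroups <- function(observed) {
  if (all(observed)) return(list(seq_len(ncol(observed))))
  key <- apply(observed, 2, function(z) paste(as.integer(z), collapse = ""))
  unname(split(seq_len(ncol(observed)), key))
}

#' SVD initialization for CPD
#'
#' Per-mode starting factors are the leading R left singular vectors of that
#' mode's unfolding; unobserved entries are treated as zero for
#' initialization only. Deterministic.
#'
#' @param tensor a [LabeledTensor-class] (or plain array).
#' @param rank number of components R.
#' @return list of per-mode factor matrices (mode size x R). If R exceeds a
#'   mode's size, the factor is padded with extra orthonormal columns.
#' @export
initializeSVD <- function(tensor, rank) {
  v <- if (is(tensor, "LabeledTensor")) tensorValues(tensor) else tensor
  v[is.na(v)] <- 0
  d <- dim(v)
  lapply(seq_along(d), function(n) {
    Xn <- unfold(v, n)
    k <- min(rank, d[n], ncol(Xn))
    U <- svd(Xn, nu = k, nv = 0)$u
    if (k < rank) {
      # over-factored mode: pad with a deterministic orthonormal complement
      pad <- withSeed(childSeed(1L, n), matrix(stats::rnorm(d[n] * (rank - k)), d[n]))
      U <- qr.Q(qr(cbind(U, pad)))[, seq_len(rank), drop = FALSE]
    }
    U
  })
}

#' Construct (and canonicalize) a CPDecomposition
#'
#' Absorbs column norms into the weights, sorts components by weight in
#' descending order, and fixes signs: each non-leading mode's largest-|entry|
#' element is made positive with the flip pushed into the first (subject)
#' mode, then any remaining negative leading-mode column is fixed by a joint
#' flip with the last mode, so every component carries an even number of
#' flips and the reconstruction is unchanged.
#'
#' @param factors list of per-mode factor matrices sharing a column count R.
#' @param weights optional R nonnegative scalars (default all 1 before
#'   normalization).
#' @return a validated [CPDecomposition-class].
#' @export
CPDecomposition <- function(factors, weights = NULL) {
  R <- ncol(factors[[1]])
  if (is.null(weights)) weights <- rep(1, R)
  N <- length(factors)
  factors <- lapply(factors, function(m) {
    storage.mode(m) <- "double"
    m
  })
  for (nmode in seq_len(N)) {
    nrm <- sqrt(colSums(factors[[nmode]]^2))
    zero <- nrm < .Machine$double.eps
    if (any(zero)) {
      factors[[nmode]][, zero] <- 1 / sqrt(nrow(factors[[nmode]]))
      nrm[zero] <- 0
    }
    factors[[nmode]] <- sweep(factors[[nmode]], 2,
                              ifelse(nrm > 0, nrm, 1), "/")
    weights <- weights * ifelse(nrm > 0, nrm, 0)
  }
  # sign convention
  for (nmode in seq_len(N)[-1]) {
    s <- apply(factors[[nmode]], 2, function(col) {
      v <- col[which.max(abs(col))]
      if (v < 0) -1 else 1
    })
    factors[[nmode]] <- sweep(factors[[nmode]], 2, s, "*")
    factors[[1]] <- sweep(factors[[1]], 2, s, "*")
  }
  s1 <- apply(factors[[1]], 2, function(col) {
    v <- col[which.max(abs(col))]
    if (v < 0) -1 else 1
  })
  factors[[1]] <- sweep(factors[[1]], 2, s1, "*")
  factors[[N]] <- sweep(factors[[N]], 2, s1, "*")
  ord <- order(weights, decreasing = TRUE)
  factors <- lapply(factors, function(m) m[, ord, drop = FALSE])
  weights <- weights[ord]
  new("CPDecomposition", factors = factors, weights = as.numeric(weights))
}

#' Reconstruct the dense tensor from a CPD
#'
#' @param cpd a [CPDecomposition-class].
#' @return numeric array `sum_r weights[r] * outer(a_r, b_r, ...)`, with
#'   dimnames taken from the factor row names when present.
#' @export
reconstruct <- function(cpd) {
  f <- factorMatrices(cpd)
  w <- componentWeights(cpd)
  reconFactors(f, w)
}

# reconstruction from raw factor list + weights (internal hot path)
reconFactors <- function(f, w = NULL) {
  d <- vapply(f, nrow, integer(1))
  A <- f[[1]]
  if (!is.null(w)) A <- sweep(A, 2, w, "*")
  Z <- khatriRao(rev(f[-1]))
  out <- array(tcrossprod(A, Z), dim = d)
  dn <- lapply(f, rownames)
  if (!any(vapply(dn, is.null, logical(1)))) {
    names(dn) <- names(f)
    dimnames(out) <- dn
  }
  out
}

#' Variance explained on observed entries (R2X)
#'
#' `1 - sum((x - xhat)^2) / sum(x^2)` over observed entries only.
#'
#' @param cpd a [CPDecomposition-class].
#' @param tensor a [LabeledTensor-class] of matching shape.
#' @return scalar, at most 1 (can be negative for a bad model).
#' @export
r2x <- function(cpd, tensor) {
  v <- tensorValues(tensor)
  m <- tensorMask(tensor)
  stopIfNot(all(dim(v) == vapply(factorMatrices(cpd), nrow, integer(1))),
            "tensor and decomposition shapes differ")
  ss <- sum(v[m]^2)
  stopIfNot(ss > 0, "all-zero observed tensor: R2X undefined")
  xhat <- reconstruct(cpd)
  1 - sum((v[m] - xhat[m])^2) / ss
}

#' Fit a CPD by censored alternating least squares
#'
#' Each sweep solves every mode by (censored) least squares against the
#' Khatri-Rao product of the other modes' factors, starting from the SVD
#' initialization. When `lineSearch` is on, after two full sweeps each sweep
#' is followed by a Bro-style extrapolation from the previous iterate by a
#' step of `N^(1/l)` (N the sweep number; l the line-search quotient,
#' initially 2), accepted only when the observed-entry error decreases
#' relative to the plain ALS update; after four consecutive rejections l is
#' incremented, and the rejection counter resets on acceptance.
#'
#' @param tensor a [LabeledTensor-class].
#' @param rank number of components R.
#' @param tol convergence threshold on the change in R2X between sweeps
#'   (default `1e-6`).
#' @param maxIter maximum number of ALS sweeps (default 1000).
#' @param lineSearch enable the extrapolation step (default `TRUE`).
#' @param censored use the censored solver on the observed-mask (default
#'   `TRUE`). `FALSE` requires a fully observed tensor and runs plain ALS;
#'   on complete data both paths produce identical iterates.
#' @param init optional starting factor list (default [initializeSVD()]).
#' @param trace keep the per-sweep factor trajectory in the report (testing
#'   aid; default `FALSE`).
#' @return list with elements `decomposition` (a canonicalized
#'   [CPDecomposition-class]) and `report` (iterations, R2X trajectory,
#'   line-search accept/reject counts, convergence flag).
#' @examples
#' spec <- syntheticSpec(n_subjects = 12, n_bc = 5,
#'                       mode_sizes = c(treatment = 4, marker = 3),
#'                       rank = 2, noise_sd = 0, missing_fraction = 0)
#' truth <- generateGroundTruth(spec)
#' study <- synthesizeStudy(truth, spec)
#' fit <- fitCPD(study$tensor, rank = 2, tol = 1e-10)
#' fit$report$converged
#' @export
fitCPD <- function(tensor, rank, tol = 1e-6, maxIter = 1000,
                   lineSearch = TRUE, censored = TRUE, init = NULL,
                   trace = FALSE) {
  v <- tensorValues(tensor)
  mask <- tensorMask(tensor)
  stopIfNot(all(is.finite(v[mask])), "tensor contains non-finite observed values")
  d <- dim(v)
  N <- length(d)
  if (rank > min(d))
    warning(sprintf("rank %d exceeds the smallest mode size %d (over-factoring)",
                    rank, min(d)))
  anyMissing <- !all(mask)
  stopIfNot(censored || !anyMissing,
            "plain ALS (censored = FALSE) requires a fully observed tensor")
  v0 <- v
  v0[!mask] <- 0
  # per-mode unfoldings of values/mask and column-pattern groupings (mask is
  # fixed during the fit, so hash the patterns once)
  unfV <- lapply(seq_len(N), function(n) t(unfold(v0, n)))
  unfM <- lapply(seq_len(N), function(n) t(unfold(mask, n)))
  grps <- lapply(unfM, patternGroups)
  ssObs <- sum(v[mask]^2)
  stopIfNot(ssObs > 0, "all-zero observed tensor cannot be factored")
  obsErr <- function(f) {
    xhat <- reconFactors(f)
    sum((v[mask] - xhat[mask])^2)
  }
  factors <- if (is.null(init)) initializeSVD(tensor, rank) else init
  sweepOnce <- function(f) {
    for (n in seq_len(N)) {
      Z <- khatriRao(rev(f[-n]))
      if (censored) {
        coefs <- censoredLstsq(Z, unfV[[n]], unfM[[n]], groups = grps[[n]])
      } else {
        coefs <- qr.coef(qr(Z, LAPACK = TRUE), unfV[[n]])
        coefs[is.na(coefs)] <- 0
      }
      f[[n]] <- t(coefs)
    }
    f
  }
  r2xTraj <- numeric(0)
  traj <- if (trace) list() else NULL
  err <- obsErr(factors)
  lsQuotient <- 2
  lsRejects <- 0
  nAccept <- 0L
  nReject <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    prevFactors <- factors
    prevErr <- err
    factors <- sweepOnce(factors)
    err <- obsErr(factors)
    if (lineSearch && iter > 2) {
      step <- iter^(1 / lsQuotient)
      cand <- mapply(function(old, new) old + step * (new - old),
                     prevFactors, factors, SIMPLIFY = FALSE)
      candErr <- obsErr(cand)
      if (candErr < err) {
        factors <- cand
        err <- candErr
        nAccept <- nAccept + 1L
        lsRejects <- 0
      } else {
        nReject <- nReject + 1L
        lsRejects <- lsRejects + 1
        if (lsRejects >= 4) {
          lsQuotient <- lsQuotient + 1
          lsRejects <- 0
        }
      }
    }
    r2xTraj <- c(r2xTraj, 1 - err / ssObs)
    if (trace) traj[[iter]] <- factors
    if (iter > 1 && abs(r2xTraj[iter] - r2xTraj[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  dn <- dimnames(v)
  for (n in seq_len(N)) {
    rownames(factors[[n]]) <- dn[[n]]
    colnames(factors[[n]]) <- sprintf("comp_%d", seq_len(rank))
  }
  names(factors) <- names(dn)
  cpd <- CPDecomposition(factors)
  report <- list(n_iterations = iter,
                 r2x_trajectory = r2xTraj,
                 line_search_accepts = nAccept,
                 line_search_rejects = nReject,
                 converged = converged)
  if (trace) report$factor_trajectory <- traj
  list(decomposition = cpd, report = report)
}
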