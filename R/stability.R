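# Factor match score with optimal component pairing, and jackknife
# stability across subjects.

# Minimum-cost linear sum assignment (Hungarian / shortest augmenting path,
# O(n^3)) on a square cost matrix. Returns, for each row, the assigned
# column. Used to pair components between two factorizations.
lsapMin <- function(cost) {
  n <- nrow(cost)
  stopIfNot(ncol(cost) == n, "cost matrix must be square")
  INF <- .Machine$double.xmax
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j + 1]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) ans[p[j + 1]] <- j
  ans
}

#' Factor match score between two CP decompositions
#'
#' For every component pair (i, j) the similarity is a weight-agreement term
#' `1 - |w_i - w_j| / max(w_i, w_j)` times the product over the compared
#' modes of the absolute cosine between the paired factor columns.
#' Component weights are compared only when every mode is compared: when a
#' mode is excluded (the resampled subject mode, in the jackknife) the
#' component scale is attributed to the excluded mode, whose size differs
#' by construction, so the weight term is 1 and only the factor directions
#' are scored. Components are paired by a linear sum assignment maximizing
#' the total similarity, and the score is the mean over the R matched
#' pairs. A score of 1 indicates perfectly consistent factors; mutually
#' orthogonal factorizations score 0.
#'
#' @param ref,other [CPDecomposition-class] objects of equal rank whose
#'   compared modes have equal sizes.
#' @param modes axis names or indices of the modes to compare (default: all
#'   shared modes). The jackknife excludes the resampled axis here.
#' @return scalar in \[0, 1\].
#' @examples
#' f <- list(subject = matrix(rnorm(12), 6), marker = matrix(rnorm(8), 4))
#' cp <- CPDecomposition(f)
#' factorMatchScore(cp, cp)  # 1
#' @export
factorMatchScore <- function(ref, other, modes = NULL) {
  fr <- factorMatrices(ref)
  fo <- factorMatrices(other)
  R <- nComponents(ref)
  stopIfNot(nComponents(other) == R,
            "decompositions have different ranks (%d vs %d)", R,
            nComponents(other))
  nTotal <- length(fr)
  stopIfNot(length(fo) == nTotal, "decompositions have different orders")
  if (is.null(modes)) modes <- seq_len(nTotal)
  if (is.character(modes)) {
    idx <- match(modes, names(fr))
    stopIfNot(!anyNA(idx), "unknown mode name(s): %s",
              paste(modes[is.na(idx)], collapse = ", "))
    modes <- idx
  }
  stopIfNot(length(modes) >= 1, "need at least one compared mode")
  for (m in modes)
    stopIfNot(nrow(fr[[m]]) == nrow(fo[[m]]),
              "compared mode %d sizes differ (%d vs %d)", m, nrow(fr[[m]]),
              nrow(fo[[m]]))
  if (length(modes) == nTotal) {
    wr <- componentWeights(ref)
    wo <- componentWeights(other)
  } else {
    # scale is attributed to the uncompared modes
    wr <- wo <- rep(1, R)
  }
  wmax <- outer(wr, wo, pmax)
  wTerm <- 1 - abs(outer(wr, wo, "-")) / wmax
  wTerm[wmax == 0] <- 1  # both components vanish: weights agree trivially
  sim <- wTerm
  for (m in modes) sim <- sim * abs(crossprod(fr[[m]], fo[[m]]))
  assign <- lsapMin(-sim)
  score <- mean(sim[cbind(seq_len(R), assign)])
  min(max(score, 0), 1)
}

#' Jackknife stability of a CP decomposition
#'
#' Leave-one-label-out resampling along `drop_axis` (subjects, in the
#' study design): for each label the corresponding slice is removed, the
#' CPD is refit at the same rank, and the factor match score against the
#' full-data decomposition is computed over all modes except `drop_axis`.
#'
#' @param tensor a [LabeledTensor-class].
#' @param rank CPD rank.
#' @param drop_axis axis to jackknife across (default `"subject"`); must
#'   have at least 3 labels.
#' @param fit_options list of arguments passed on to [fitCPD()].
#' @param reference optional precomputed full-data fit (a
#'   [CPDecomposition-class]); refit if omitted.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`.
#' @return a `StabilityResult` list: `fms_per_replicate` (named scores, NA
#'   where a replicate fit failed), `mean`, `sd`, `modes_compared`.
#' @export
jackknifeStability <- function(tensor, rank, drop_axis = "subject",
                               fit_options = list(), reference = NULL,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  ax <- axisIndex(tensor, drop_axis)
  labs <- axisLabels(tensor)[[ax]]
  stopIfNot(length(labs) >= 3, "drop axis needs at least 3 labels (got %d)",
            length(labs))
  if (is.null(reference))
    reference <- do.call(fitCPD,
                         c(list(tensor = tensor, rank = rank),
                           fit_options))$decomposition
  modes <- axisNames(tensor)[-ax]
  scores <- vapply(labs, function(lab) {
    sub <- dropSlice(tensor, ax, lab)
    fit <- tryCatch(
      do.call(fitCPD, c(list(tensor = sub, rank = rank), fit_options)),
      error = function(e) {
        warning(sprintf("jackknife refit failed for '%s': %s", lab,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) return(NA_real_)
    factorMatchScore(reference, fit$decomposition, modes = modes)
  }, numeric(1))
  valid <- scores[!is.na(scores)]
  mu <- mean(valid)
  sdv <- if (sd_type == "population")
    sqrt(mean((valid - mu)^2)) else stats::sd(valid)
  structure(list(fms_per_replicate = scores, mean = mu, sd = sdv,
                 modes_compared = modes, drop_axis = axisNames(tensor)[ax]),
            class = "StabilityResult")
}

#' @export
print.StabilityResult <- function(x, ...) {
  n <- length(x$fms_per_replicate)
  cat(sprintf("Jackknife stability across %d %s replicates (modes: %s)\n",
              n, x$drop_axis, paste(x$modes_compared, collapse = ", ")))
  cat(sprintf("  mean FMS = %.3f, SD = %.3f (%d failed refits)\n",
              x$mean, x$sd, sum(is.na(x$fms_per_replicate))))
  invisible(x)
}
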