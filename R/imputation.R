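# Imputation-based rank validation: hold out observed entries, refit, score
# the reconstruction on the held-out set (Q2X).

#' Held-out variance explained (Q2X) by imputation
#'
#' For each repeat, a random `holdout_fraction` of the observed entries is
#' additionally masked, the CPD is refit at the given rank on the remaining
#' entries, and the reconstruction is scored on the held-out entries as
#' `1 - sum((x - xhat)^2) / sum(x^2)`. Holdouts that would leave an axis
#' label with no observed entry are resampled (bounded retries).
#'
#' @param tensor a [LabeledTensor-class].
#' @param rank CPD rank to fit.
#' @param holdout_fraction fraction of observed entries to hold out
#'   (must be > 0).
#' @param n_repeats number of random holdouts to average over.
#' @param seed RNG seed; holdout `i` uses a seed derived from it.
#' @param ... further arguments to [fitCPD()] (e.g. `tol`).
#' @return list with `q2x` (mean across repeats) and `per_repeat` scores.
#' @export
q2xImputation <- function(tensor, rank, holdout_fraction = 0.1,
                          n_repeats = 5, seed = 1L, ...) {
  stopIfNot(holdout_fraction > 0 && holdout_fraction < 1,
            "holdout_fraction must be in (0, 1)")
  m <- tensorMask(tensor)
  v <- tensorValues(tensor)
  obsIdx <- which(m)
  nHold <- round(holdout_fraction * length(obsIdx))
  stopIfNot(nHold >= 1, "holdout fraction leaves no entries to score")
  scores <- vapply(seq_len(n_repeats), function(rep) {
    train <- NULL
    hold <- NULL
    for (try in seq_len(100)) {
      hold <- withSeed(childSeed(seed, rep * 131L + try),
                       sample(obsIdx, nHold))
      extra <- array(FALSE, dim = dim(m))
      extra[hold] <- TRUE
      cand <- maskEntries(tensor, extra)
      ok <- all(vapply(seq_along(dim(m)), function(ax)
        all(apply(tensorMask(cand), ax, any)), logical(1)))
      if (ok) { train <- cand; break }
    }
    stopIfNot(!is.null(train),
              "could not draw a holdout keeping every label observed")
    fit <- fitCPD(train, rank, ...)
    xhat <- reconstruct(fit$decomposition)
    ss <- sum(v[hold]^2)
    stopIfNot(ss > 0, "held-out entries are all zero: Q2X undefined")
    1 - sum((v[hold] - xhat[hold])^2) / ss
  }, numeric(1))
  list(q2x = mean(scores), per_repeat = scores)
}
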