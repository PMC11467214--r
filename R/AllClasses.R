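#' @import methods
NULL

#' Labeled n-way tensor with explicit missingness
#'
#' Dense n-way value array with named axes, per-axis labels and a boolean
#' observed-mask of identical shape. Missing measurements are represented by
#' the mask, never by sentinel values; entries where the mask is `FALSE` are
#' stored as `NA` and ignored by every fitting and scoring routine.
#'
#' @slot values numeric array; `dimnames` carry the per-axis labels and
#'   `names(dimnames())` the axis names.
#' @slot mask logical array of the same shape; `TRUE` marks observed entries.
#'
#' @seealso [LabeledTensor()], [assembleTensor()], [fitCPD()]
#' @export
setClass("LabeledTensor",
  representation(values = "array", mask = "array"))

setValidity("LabeledTensor", function(object) {
  v <- object@values
  m <- object@mask
  msgs <- character()
  if (!identical(dim(v), dim(m)))
    msgs <- c(msgs, "values and mask must have identical dimensions")
  if (!is.logical(m))
    msgs <- c(msgs, "mask must be a logical array")
  dn <- dimnames(v)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    msgs <- c(msgs, "all axes must carry labels (dimnames)")
  else {
    if (is.null(names(dn)) || any(!nzchar(names(dn))))
      msgs <- c(msgs, "all axes must be named (names(dimnames))")
    if (any(vapply(dn, anyDuplicated, integer(1)) > 0L))
      msgs <- c(msgs, "axis labels must be unique within each axis")
  }
  if (length(msgs) == 0 && any(is.na(m)))
    msgs <- c(msgs, "mask must not contain NA")
  if (length(msgs) == 0 && any(!is.na(v) != m & m))
    msgs <- c(msgs, "observed entries must be non-missing values")
  if (length(msgs) == 0) {
    # every label along every axis must retain at least one observed entry
    for (ax in seq_along(dim(v))) {
      obs <- apply(m, ax, any)
      if (!all(obs))
        msgs <- c(msgs, sprintf(
          "axis '%s' has fully unobserved label(s): %s",
          names(dn)[ax], paste(dn[[ax]][!obs], collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Canonical polyadic decomposition
#'
#' Rank-R factorization of an n-way tensor: one factor matrix per mode with
#' unit-norm columns, plus nonnegative component weights in descending order.
#' The rank-one component r contributes
#' `weights[r] * outer(factors[[1]][, r], factors[[2]][, r], ...)`.
#'
#' @slot factors list of numeric matrices, one per mode, each of shape
#'   (mode size x R) with unit Euclidean-norm columns; row names carry axis
#'   labels, list names the axis names.
#' @slot weights numeric vector of R nonnegative component weights, sorted
#'   in descending order.
#'
#' @seealso [fitCPD()], [reconstruct()], [factorMatchScore()]
#' @export
setClass("CPDecomposition",
  representation(factors = "list", weights = "numeric"))

setValidity("CPDecomposition", function(object) {
  f <- object@factors
  w <- object@weights
  msgs <- character()
  if (length(f) < 2)
    msgs <- c(msgs, "need at least two factor matrices")
  if (!all(vapply(f, is.matrix, logical(1))))
    msgs <- c(msgs, "factors must be matrices")
  else {
    R <- unique(vapply(f, ncol, integer(1)))
    if (length(R) != 1)
      msgs <- c(msgs, "all factor matrices must share the column count R")
    else {
      if (length(w) != R)
        msgs <- c(msgs, "length(weights) must equal the rank")
      nrm <- unlist(lapply(f, function(m) sqrt(colSums(m^2))))
      if (any(abs(nrm - 1) > 1e-8))
        msgs <- c(msgs, "factor columns must be unit-norm (within 1e-8)")
    }
  }
  if (any(w < 0))
    msgs <- c(msgs, "weights must be nonnegative")
  if (is.unsorted(rev(w), strictly = FALSE))
    msgs <- c(msgs, "weights must be in descending order")
  if (length(msgs)) msgs else TRUE
})

#' Tucker decomposition
#'
#' Core-array factorization with per-mode orthonormal factor matrices; used
#' as a compression baseline against CPD.
#'
#' @slot core numeric array of shape (r1 x ... x rn).
#' @slot factors list of per-mode matrices with orthonormal columns.
#'
#' @seealso [fitTucker()], [tuckerRankSearch()]
#' @export
setClass("TuckerDecomposition",
  representation(core = "array", factors = "list"))

setValidity("TuckerDecomposition", function(object) {
  msgs <- character()
  if (length(dim(object@core)) != length(object@factors))
    msgs <- c(msgs, "core order must equal the number of factor matrices")
  for (i in seq_along(object@factors)) {
    U <- object@factors[[i]]
    if (ncol(U) != dim(object@core)[i]) {
      msgs <- c(msgs, sprintf("factor %d column count must match core dim", i))
      next
    }
    dev <- max(abs(crossprod(U) - diag(ncol(U))))
    if (dev > 1e-8)
      msgs <- c(msgs, sprintf("factor %d columns not orthonormal (dev %.2e)", i, dev))
  }
  if (length(msgs)) msgs else TRUE
})
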