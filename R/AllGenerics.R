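# Accessor generics and show methods for the core containers.

#' @rdname LabeledTensor-accessors
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname LabeledTensor-accessors
#' @export
setGeneric("tensorMask", function(x) standardGeneric("tensorMask"))

#' @rdname LabeledTensor-accessors
#' @export
setGeneric("axisNames", function(x) standardGeneric("axisNames"))

#' @rdname LabeledTensor-accessors
#' @export
setGeneric("axisLabels", function(x, axis) standardGeneric("axisLabels"))

#' @rdname CPDecomposition-accessors
#' @export
setGeneric("factorMatrices", function(x) standardGeneric("factorMatrices"))

#' @rdname CPDecomposition-accessors
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))

#' @rdname CPDecomposition-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Accessors for LabeledTensor
#'
#' @param x a [LabeledTensor-class] object.
#' @param axis axis name or index; if missing, all label lists are returned.
#' @return `tensorValues` the value array (`NA` at unobserved entries);
#'   `tensorMask` the logical observed-mask; `axisNames` the axis names;
#'   `axisLabels` the label vector(s).
#' @name LabeledTensor-accessors
NULL

#' @rdname LabeledTensor-accessors
#' @export
setMethod("tensorValues", "LabeledTensor", function(x) x@values)

#' @rdname LabeledTensor-accessors
#' @export
setMethod("tensorMask", "LabeledTensor", function(x) x@mask)

#' @rdname LabeledTensor-accessors
#' @export
setMethod("axisNames", "LabeledTensor", function(x) names(dimnames(x@values)))

#' @rdname LabeledTensor-accessors
#' @export
setMethod("axisLabels", "LabeledTensor", function(x, axis) {
  dn <- dimnames(x@values)
  if (missing(axis)) return(dn)
  dn[[axis]]
})

setMethod("dim", "LabeledTensor", function(x) dim(x@values))

setMethod("show", "LabeledTensor", function(object) {
  d <- dim(object)
  dn <- dimnames(object@values)
  cat(sprintf("LabeledTensor: %s (%d entries, %.1f%% observed)\n",
              paste(d, collapse = " x "), prod(d),
              100 * mean(object@mask)))
  for (i in seq_along(d)) {
    lab <- dn[[i]]
    preview <- paste(utils::head(lab, 3), collapse = ", ")
    if (length(lab) > 3) preview <- paste0(preview, ", ...")
    cat(sprintf("  %s [%d]: %s\n", names(dn)[i], d[i], preview))
  }
})

#' Accessors for CPDecomposition
#'
#' @param x a [CPDecomposition-class] object.
#' @return `factorMatrices` the list of per-mode factor matrices (unit-norm
#'   columns); `componentWeights` the descending nonnegative weights;
#'   `nComponents` the rank R.
#' @name CPDecomposition-accessors
NULL

#' @rdname CPDecomposition-accessors
#' @export
setMethod("factorMatrices", "CPDecomposition", function(x) x@factors)

#' @rdname CPDecomposition-accessors
#' @export
setMethod("componentWeights", "CPDecomposition", function(x) x@weights)

#' @rdname CPDecomposition-accessors
#' @export
setMethod("nComponents", "CPDecomposition", function(x) length(x@weights))

setMethod("show", "CPDecomposition", function(object) {
  sizes <- vapply(object@factors, nrow, integer(1))
  cat(sprintf("CPDecomposition: rank %d over modes (%s)\n",
              length(object@weights),
              paste(sprintf("%s=%d", names(object@factors), sizes),
                    collapse = ", ")))
  cat("  weights:", paste(signif(object@weights, 4), collapse = ", "), "\n")
})

setMethod("show", "TuckerDecomposition", function(object) {
  cat(sprintf("TuckerDecomposition: core %s, modes (%s)\n",
              paste(dim(object@core), collapse = " x "),
              paste(vapply(object@factors, nrow, integer(1)),
                    collapse = ", ")))
})
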