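#' Construct a LabeledTensor
#'
#' @param values numeric array. `NA` entries are treated as unobserved when
#'   `mask` is not supplied.
#' @param mask logical array of the same shape marking observed entries;
#'   defaults to `!is.na(values)`.
#' @param axes character vector of axis names; defaults to
#'   `names(dimnames(values))`.
#' @param labels list of per-axis label vectors; defaults to
#'   `dimnames(values)`.
#' @return a validated [LabeledTensor-class].
#' @examples
#' x <- array(rnorm(24), dim = c(2, 3, 4))
#' lt <- LabeledTensor(x, axes = c("subject", "cell_type", "marker"))
#' dim(lt)
#' @export
LabeledTensor <- function(values, mask = NULL, axes = NULL, labels = NULL) {
  stopIfNot(is.array(values) || is.matrix(values),
            "values must be an array")
  d <- dim(values)
  if (is.null(labels)) labels <- dimnames(values)
  if (is.null(labels)) {
    stopIfNot(!is.null(axes), "supply axis names when values has no dimnames")
    labels <- lapply(seq_along(d), function(i)
      sprintf("%s_%02d", axes[i], seq_len(d[i])))
  }
  if (is.null(axes)) axes <- names(labels)
  stopIfNot(!is.null(axes) && all(nzchar(axes)),
            "axis names are required (axes= or names(dimnames))")
  names(labels) <- axes
  dimnames(values) <- labels
  if (is.null(mask)) mask <- !is.na(values)
  mask <- array(as.logical(mask), dim = unname(d))
  dim(values) <- unname(d)
  dimnames(values) <- labels
  dimnames(mask) <- labels
  values[!mask] <- NA_real_
  storage.mode(values) <- "double"
  new("LabeledTensor", values = values, mask = mask)
}

#' Drop one label (slice) from an axis
#'
#' Used by the jackknife: removes the full slice belonging to `label` along
#' `axis`, shrinking that axis by one.
#'
#' @param tensor a [LabeledTensor-class].
#' @param axis axis name or index.
#' @param label the label to remove.
#' @return a [LabeledTensor-class] with the slice removed.
#' @export
dropSlice <- function(tensor, axis, label) {
  ax <- axisIndex(tensor, axis)
  labs <- axisLabels(tensor)[[ax]]
  stopIfNot(label %in% labs, "label '%s' not found on axis", label)
  idx <- rep(list(quote(expr = )), length(dim(tensor)))
  idx[[ax]] <- which(labs != label)
  v <- do.call(`[`, c(list(tensorValues(tensor)), idx, list(drop = FALSE)))
  m <- do.call(`[`, c(list(tensorMask(tensor)), idx, list(drop = FALSE)))
  new("LabeledTensor", values = v, mask = m)
}

#' Fraction of observed entries
#'
#' @param tensor a [LabeledTensor-class].
#' @return scalar in (0, 1].
#' @export
observedFraction <- function(tensor) mean(tensorMask(tensor))

# Apply an additional mask (e.g. imputation holdout), returning a new tensor.
# Does not validate per-label observedness; callers resample if invalid.
maskEntries <- function(tensor, extra) {
  m <- tensorMask(tensor) & !extra
  v <- tensorValues(tensor)
  v[!m] <- NA_real_
  new("LabeledTensor", values = v, mask = m)
}
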