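# Preprocessing: long-format MFI tables -> normalized labeled tensors with
# explicit missingness. Normalizations act only on observed entries; masks
# are invariant under every operation except assembly.

#' Assemble a labeled tensor from a long-format profile table
#'
#' Key combinations absent from the table become masked (unobserved)
#' entries. Label order on each axis is first-appearance order in the table.
#'
#' @param table long-format `data.frame` with a `subject` column, one column
#'   per condition axis, and a numeric `mfi` value column (a `cohort` column
#'   is tolerated and ignored here; see [cohortLabelsFromTable()]).
#' @param axis_order character vector of axis names, `subject` first;
#'   default is `subject` followed by the condition columns in table order.
#' @param value_col name of the value column (default `"mfi"`).
#' @return a [LabeledTensor-class].
#' @examples
#' df <- expand.grid(subject = c("s1", "s2"), treatment = c("a", "b"),
#'                   marker = c("m1", "m2"), stringsAsFactors = FALSE)
#' df$mfi <- rnorm(8)
#' dim(assembleTensor(df))
#' @export
assembleTensor <- function(table, axis_order = NULL, value_col = "mfi") {
  stopIfNot(is.data.frame(table) && nrow(table) > 0,
            "profile table is empty or not a data.frame")
  stopIfNot(value_col %in% names(table), "missing value column '%s'", value_col)
  cond <- setdiff(names(table), c("subject", "cohort", value_col))
  if (is.null(axis_order)) axis_order <- c("subject", cond)
  stopIfNot(axis_order[1] == "subject", "subject axis must come first")
  stopIfNot(setequal(axis_order, c("subject", cond)),
            "axis_order must cover the condition columns exactly once")
  stopIfNot(all(is.finite(table[[value_col]])), "mfi values must be finite")
  labs <- lapply(axis_order, function(a) unique(as.character(table[[a]])))
  names(labs) <- axis_order
  dims <- lengths(labs)
  idx <- vapply(axis_order, function(a)
    match(as.character(table[[a]]), labs[[a]]), integer(nrow(table)))
  idx <- matrix(idx, ncol = length(axis_order))
  dup <- duplicated(idx)
  if (any(dup)) {
    j <- which(dup)[1]
    stop(sprintf("duplicate key combination: %s",
                 paste(sprintf("%s=%s", axis_order, table[j, axis_order]),
                       collapse = ", ")), call. = FALSE)
  }
  values <- array(NA_real_, dim = dims, dimnames = labs)
  values[idx] <- table[[value_col]]
  LabeledTensor(values)
}

#' Extract cohort labels from a profile table
#'
#' @param table long-format `data.frame` with `subject` and `cohort`
#'   columns (`"healthy"` -> 0, `"bc"` -> 1).
#' @return named integer vector (subject -> status code).
#' @export
cohortLabelsFromTable <- function(table) {
  stopIfNot(all(c("subject", "cohort") %in% names(table)),
            "table needs subject and cohort columns")
  u <- unique(table[, c("subject", "cohort")])
  stopIfNot(!anyDuplicated(u$subject),
            "subject(s) with conflicting cohort labels: %s",
            paste(u$subject[duplicated(u$subject)], collapse = ", "))
  code <- match(tolower(u$cohort), c("healthy", "bc")) - 1L
  stopIfNot(!anyNA(code), "cohort values must be 'healthy' or 'bc'")
  cohortLabels(u$subject, code)
}

# Broadcast a per-(key axes) lookup across the full tensor shape using
# slice.index; returns an array of the tensor's shape.
broadcastLookup <- function(tensor, lookup, keyAxes) {
  v <- tensorValues(tensor)
  ax <- vapply(keyAxes, function(a) axisIndex(tensor, a), integer(1))
  idx <- vapply(ax, function(a) as.vector(slice.index(v, a)),
                integer(length(v)))
  array(lookup[idx], dim = dim(v))
}

#' Subtract per-subject, per-cell-type background
#'
#' Each observed entry has its matching background value (one per
#' subject/cell_type/marker triple) subtracted; the mask is unchanged and
#' negative results are retained.
#'
#' @param tensor a [LabeledTensor-class] with `subject`, `cell_type` and
#'   `marker` axes.
#' @param background `data.frame` with columns `subject`, `cell_type`,
#'   `marker`, `mfi` supplying one background value per triple.
#' @return a [LabeledTensor-class].
#' @export
subtractBackground <- function(tensor, background) {
  keyAxes <- c("subject", "cell_type", "marker")
  stopIfNot(all(keyAxes %in% axisNames(tensor)),
            "tensor must have subject, cell_type and marker axes")
  stopIfNot(all(c(keyAxes, "mfi") %in% names(background)),
            "background table needs subject, cell_type, marker, mfi columns")
  labs <- axisLabels(tensor)
  dims <- lengths(labs[keyAxes])
  bg <- array(NA_real_, dim = dims, dimnames = labs[keyAxes])
  kidx <- cbind(match(as.character(background$subject), labs$subject),
                match(as.character(background$cell_type), labs$cell_type),
                match(as.character(background$marker), labs$marker))
  keep <- stats::complete.cases(kidx)
  bg[kidx[keep, , drop = FALSE]] <- background$mfi[keep]
  bgFull <- broadcastLookup(tensor, bg, keyAxes)
  m <- tensorMask(tensor)
  bad <- m & is.na(bgFull)
  if (any(bad)) {
    miss <- unique(do.call(paste, c(lapply(keyAxes, function(a)
      dimnames(tensorValues(tensor))[[a]][slice.index(m, axisIndex(tensor, a))[bad]]),
      list(sep = "/"))))
    stop(sprintf("no background for observed entries at (subject/cell_type/marker): %s",
                 paste(utils::head(miss, 10), collapse = ", ")), call. = FALSE)
  }
  v <- tensorValues(tensor) - bgFull
  v[!m] <- NA_real_
  new("LabeledTensor", values = v, mask = m)
}

# Per-label statistics over observed entries along one axis.
observedSlabStat <- function(tensor, axis, fn) {
  ax <- axisIndex(tensor, axis)
  apply(tensorValues(tensor), ax, fn)
}

#' Normalize each marker to its maximum observed signal
#'
#' Every observed entry is divided by the maximum observed value of its
#' marker slab (across all subjects, treatments and cell types), so each
#' marker's observed maximum becomes exactly 1.
#'
#' @param tensor a [LabeledTensor-class].
#' @param axis marker axis name (default `"marker"`).
#' @return a [LabeledTensor-class].
#' @export
normalizeMarkerMax <- function(tensor, axis = "marker") {
  ax <- axisIndex(tensor, axis)
  mx <- observedSlabStat(tensor, ax, function(s) max(s, na.rm = TRUE))
  bad <- !is.finite(mx) | mx <= 0
  stopIfNot(!any(bad), "marker slab(s) with non-positive observed maximum: %s",
            paste(axisLabels(tensor)[[ax]][bad], collapse = ", "))
  v <- sweep(tensorValues(tensor), ax, mx, "/")
  new("LabeledTensor", values = v, mask = tensorMask(tensor))
}

#' Z-score each receptor's signal
#'
#' Per receptor slab, observed entries are centered to mean 0 and scaled to
#' sample (n-1) standard deviation 1.
#'
#' @param tensor a [LabeledTensor-class].
#' @param axis receptor axis name (default `"receptor"`).
#' @return a [LabeledTensor-class].
#' @export
zscoreReceptors <- function(tensor, axis = "receptor") {
  ax <- axisIndex(tensor, axis)
  labs <- axisLabels(tensor)[[ax]]
  n <- observedSlabStat(tensor, ax, function(s) sum(!is.na(s)))
  stopIfNot(all(n >= 2), "receptor slab(s) with fewer than 2 observed entries: %s",
            paste(labs[n < 2], collapse = ", "))
  mu <- observedSlabStat(tensor, ax, function(s) mean(s, na.rm = TRUE))
  sdv <- observedSlabStat(tensor, ax, function(s) stats::sd(s, na.rm = TRUE))
  bad <- !is.finite(sdv) | sdv == 0
  stopIfNot(!any(bad), "zero-variance receptor slab(s): %s",
            paste(labs[bad], collapse = ", "))
  v <- sweep(sweep(tensorValues(tensor), ax, mu, "-"), ax, sdv, "/")
  new("LabeledTensor", values = v, mask = tensorMask(tensor))
}

#' Fold-change transform against a baseline treatment
#'
#' Each entry is divided by its matching (subject, cell_type, marker)
#' baseline entry; the baseline slice becomes identically 1. Masked entries
#' stay masked.
#'
#' @param tensor a [LabeledTensor-class] with a treatment axis.
#' @param baseline_treatment label of the baseline (untreated) condition.
#' @param axis treatment axis name (default `"treatment"`).
#' @return a [LabeledTensor-class].
#' @export
foldChangeTransform <- function(tensor, baseline_treatment,
                                axis = "treatment") {
  ax <- axisIndex(tensor, axis)
  labs <- axisLabels(tensor)[[ax]]
  stopIfNot(baseline_treatment %in% labs,
            "baseline treatment '%s' not on the %s axis", baseline_treatment,
            axis)
  b <- match(baseline_treatment, labs)
  v <- tensorValues(tensor)
  m <- tensorMask(tensor)
  idx <- rep(list(quote(expr = )), length(dim(v)))
  idx[[ax]] <- b
  base <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  baseMask <- do.call(`[`, c(list(m), idx, list(drop = FALSE)))
  # broadcast the baseline slice along the treatment axis
  baseFull <- do.call(`[`, c(list(base),
    lapply(seq_along(dim(v)), function(i)
      if (i == ax) rep(1L, dim(v)[ax]) else seq_len(dim(v)[i])),
    list(drop = FALSE)))
  bad <- m & (is.na(baseFull) | baseFull <= 0)
  stopIfNot(!any(bad),
            "%d observed entr(ies) have missing or non-positive baseline values",
            sum(bad))
  out <- v / baseFull
  out[!m] <- NA_real_
  new("LabeledTensor", values = out, mask = m)
}
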