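# Synthetic cohort generator: known low-rank factors, cohort-associated
# subject components, additive Gaussian noise and study-like fiber
# missingness, so every downstream stage can be validated against ground
# truth.

# Default label vocabularies mirroring the profiling design: 8 treatment
# conditions (7 cytokines + untreated), 23 gated immune populations, 6
# phospho-markers, 14 receptors.
.treatmentLabels <- c("Untreated", "IL2", "IL4", "IL6", "IL10", "IFNg",
                      "TGFb", "IFNg_IL6")
.cellTypeLabels <- c(
  "B", "B_naive", "B_memory", "Breg",
  "CD4_T", "CD4_naive", "CD4_TCM", "CD4_TEM",
  "Treg", "Treg_I", "Treg_II", "Treg_III",
  "CD8_T", "CD8_naive", "CD8_TCM", "CD8_TEM", "CD8_TEMRA",
  "NK", "NKT", "CD16_NK",
  "Monocyte_classical", "Monocyte_nonclassical", "CD33_myeloid")
.markerLabels <- c("pSTAT1", "pSTAT3", "pSTAT4", "pSTAT5", "pSTAT6",
                   "pSmad23")
.receptorLabels <- c("IFNgR1", "IL2Ra", "IL2Rb", "IL2Rg", "IL4Ra", "IL6Ra",
                     "IL6Rb", "IL7Ra", "IL10R", "IL12RI", "IL12RII",
                     "TGFbRII", "PD1", "PDL1")

defaultAxisLabels <- function(axis, k) {
  vocab <- switch(axis,
    treatment = .treatmentLabels,
    cell_type = .cellTypeLabels,
    marker = .markerLabels,
    receptor = .receptorLabels,
    NULL)
  if (!is.null(vocab) && k <= length(vocab)) vocab[seq_len(k)]
  else sprintf("%s_%02d", axis, seq_len(k))
}

#' Specify a synthetic cohort
#'
#' Bundles the generator settings: cohort sizes, tensor shape, true rank,
#' disease effect, noise level and missingness pattern. Defaults emulate the
#' profiled study design: 36 subjects (22 healthy, 14 BC), a
#' treatment x cell_type x marker grid of 8 x 23 x 6, ~10.4% of entries
#' missing as whole treatment fibers, a rank-4 signal whose third component
#' carries a cohort mean-shift of 3 subject-factor standard deviations, and
#' relative Gaussian noise of 0.3 (the noiseless signal is scaled to unit
#' per-entry root-mean-square, so `noise_sd` reads as a relative level).
#'
#' @param n_subjects total number of subjects.
#' @param n_bc number of disease (BC) subjects; the rest are healthy.
#' @param mode_sizes named integer vector of non-subject axis sizes, e.g.
#'   `c(treatment = 8, cell_type = 23, marker = 6)` or
#'   `c(cell_type = 23, receptor = 14)`.
#' @param rank true component count R.
#' @param n_disease_components how many subject-factor columns carry the
#'   cohort mean-shift.
#' @param disease_components indices of the shifted columns; default places
#'   them ending at component `min(3, rank)`.
#' @param effect_size cohort mean-shift in subject-factor standard-deviation
#'   units.
#' @param noise_sd standard deviation of additive Gaussian noise, relative
#'   to the unit per-entry RMS of the noiseless signal.
#' @param missing_fraction target fraction of unobserved entries.
#' @param missing_mode `"fiber"` (whole treatment slices per subject, the
#'   pattern profiling panels produce) or `"entrywise"`.
#' @param seed RNG seed; every draw in the generator is derived from it.
#' @return a `SyntheticSpec` list, validated.
#' @examples
#' spec <- syntheticSpec()
#' spec$mode_sizes
#' @export
syntheticSpec <- function(n_subjects = 36, n_bc = 14,
                          mode_sizes = c(treatment = 8, cell_type = 23,
                                         marker = 6),
                          rank = 4, n_disease_components = 1,
                          disease_components = NULL,
                          effect_size = 3, noise_sd = 0.3,
                          missing_fraction = 0.104,
                          missing_mode = c("fiber", "entrywise"),
                          seed = 42L) {
  missing_mode <- match.arg(missing_mode)
  stopIfNot(!is.null(names(mode_sizes)) && all(nzchar(names(mode_sizes))),
            "mode_sizes must be a named vector of non-subject axis sizes")
  dims <- c(subject = as.integer(n_subjects), as.integer(mode_sizes))
  stopIfNot(rank >= 1, "rank must be >= 1")
  stopIfNot(rank <= min(dims),
            "rank %d exceeds the smallest mode size %d", rank, min(dims))
  stopIfNot(missing_fraction >= 0 && missing_fraction < 1,
            "missing_fraction must be in [0, 1)")
  stopIfNot(n_bc < n_subjects, "n_bc must be smaller than n_subjects")
  stopIfNot(n_bc >= 1, "need at least one BC subject")
  stopIfNot(noise_sd >= 0, "noise_sd must be nonnegative")
  stopIfNot(n_disease_components >= 0 && n_disease_components <= rank,
            "n_disease_components must lie in [0, rank]")
  if (is.null(disease_components)) {
    if (n_disease_components > 0) {
      end <- min(3, rank)
      disease_components <- seq(to = end, length.out = n_disease_components)
      if (any(disease_components < 1))
        disease_components <- seq_len(n_disease_components)
    } else disease_components <- integer(0)
  }
  stopIfNot(length(disease_components) == n_disease_components &&
              all(disease_components >= 1 & disease_components <= rank),
            "disease_components must be %d indices within 1..rank",
            n_disease_components)
  structure(list(
    n_subjects = as.integer(n_subjects), n_bc = as.integer(n_bc),
    mode_sizes = mode_sizes, rank = as.integer(rank),
    n_disease_components = as.integer(n_disease_components),
    disease_components = as.integer(disease_components),
    effect_size = effect_size, noise_sd = noise_sd,
    missing_fraction = missing_fraction, missing_mode = missing_mode,
    seed = as.integer(seed)), class = "SyntheticSpec")
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf("SyntheticSpec: %d subjects (%d BC), modes (%s), rank %d\n",
              x$n_subjects, x$n_bc,
              paste(sprintf("%s=%d", names(x$mode_sizes), x$mode_sizes),
                    collapse = ", "), x$rank))
  cat(sprintf("  disease components: %s (effect %.2g), noise_sd %.2g, %s missingness %.1f%%\n",
              paste(x$disease_components, collapse = ","), x$effect_size,
              x$noise_sd, x$missing_mode, 100 * x$missing_fraction))
  invisible(x)
}

#' Cohort labels
#'
#' @param subjects character vector of subject identifiers.
#' @param status integer vector of 0 (healthy) / 1 (BC), recycled checkable.
#' @return named integer vector mapping subject id to status code.
#' @export
cohortLabels <- function(subjects, status) {
  stopIfNot(length(subjects) == length(status),
            "subjects and status lengths differ")
  status <- as.integer(status)
  stopIfNot(all(status %in% c(0L, 1L)), "status codes must be 0 or 1")
  stats::setNames(status, subjects)
}

#' Generate ground-truth factors for a synthetic cohort
#'
#' Factor entries are drawn i.i.d. standard normal; the cohort mean-shift
#' (`effect_size`) is added to the BC subjects' rows of the designated
#' subject-factor columns before column normalization, so the standardized
#' group mean difference of those columns is approximately `effect_size` and
#' scale identifiability lives entirely in the weights. Weights decay
#' linearly with component index and are scaled so the noiseless tensor has
#' unit per-entry RMS. The observed-mask is also drawn here so the whole
#' study is reproducible from the spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @return a `GroundTruth` list: `factors` (per-mode, unit-norm columns),
#'   `weights`, `disease_component_indices`, `labels` (subject -> 0/1),
#'   `mask` (observed-array).
#' @export
generateGroundTruth <- function(spec) {
  stopIfNot(inherits(spec, "SyntheticSpec"), "spec must come from syntheticSpec()")
  dims <- c(subject = spec$n_subjects, spec$mode_sizes)
  axes <- names(dims)
  R <- spec$rank
  nH <- spec$n_subjects - spec$n_bc
  subjects <- sprintf("subject_%02d", seq_len(spec$n_subjects))
  labels <- cohortLabels(subjects, c(rep(0L, nH), rep(1L, spec$n_bc)))
  factors <- withSeed(childSeed(spec$seed, 1L), {
    lapply(seq_along(dims), function(i)
      matrix(stats::rnorm(dims[i] * R), dims[i], R))
  })
  if (length(spec$disease_components))
    factors[[1]][labels == 1L, spec$disease_components] <-
      factors[[1]][labels == 1L, spec$disease_components] + spec$effect_size
  # unit-norm columns; linearly decaying weights at unit per-entry signal RMS
  factors <- lapply(factors, function(m)
    sweep(m, 2, sqrt(colSums(m^2)), "/"))
  base <- (R + 1 - seq_len(R))
  weights <- base * sqrt(prod(dims) / sum(base^2))
  for (i in seq_along(factors)) {
    rownames(factors[[i]]) <- defaultAxisLabels(axes[i], dims[i])
    colnames(factors[[i]]) <- sprintf("comp_%d", seq_len(R))
  }
  rownames(factors[[1]]) <- subjects
  names(factors) <- axes
  mask <- generateMask(spec, dims)
  structure(list(factors = factors, weights = weights,
                 disease_component_indices = spec$disease_components,
                 labels = labels, mask = mask),
            class = "GroundTruth")
}

# Draw the observed-mask for a spec. Fiber mode mirrors the profiling
# design: randomly chosen subjects lose their TGFb-analog and
# combination-treatment-analog slices (the last two treatment labels).
# Entrywise mode masks individual
# entries, resampling (bounded) until every axis label keeps >= 1 observed
# entry.
generateMask <- function(spec, dims) {
  mask <- array(TRUE, dim = dims)
  if (spec$missing_fraction == 0) return(mask)
  if (spec$missing_mode == "fiber") {
    stopIfNot("treatment" %in% names(dims),
              "fiber missingness requires a treatment axis; use missing_mode = 'entrywise'")
    tAxis <- which(names(dims) == "treatment")
    nT <- dims[tAxis]
    maskedTreat <- c(nT - 1L, nT)  # TGFb and IFNg_IL6 under default labels
    nSubj <- round(spec$missing_fraction * dims[1] * nT / length(maskedTreat))
    stopIfNot(nSubj < dims[1],
              "fiber missing_fraction would remove slices from every subject")
    subj <- withSeed(childSeed(spec$seed, 2L),
                     sort(sample.int(dims[1], nSubj)))
    idx <- rep(list(quote(expr = )), length(dims))
    idx[[1]] <- subj
    idx[[tAxis]] <- maskedTreat
    mask <- do.call(`[<-`, c(list(mask), idx, list(value = FALSE)))
  } else {
    total <- prod(dims)
    nMask <- round(spec$missing_fraction * total)
    ok <- FALSE
    for (try in seq_len(100)) {
      cand <- array(TRUE, dim = dims)
      drop <- withSeed(childSeed(spec$seed, 2L + try),
                       sample.int(total, nMask))
      cand[drop] <- FALSE
      ok <- all(vapply(seq_along(dims), function(ax)
        all(apply(cand, ax, any)), logical(1)))
      if (ok) { mask <- cand; break }
    }
    stopIfNot(ok, "could not draw an entrywise mask keeping every label observed")
  }
  mask
}

#' Synthesize the study tensor from ground truth
#'
#' Builds the weighted sum of rank-one outer products of the truth factors,
#' adds `N(0, noise_sd^2)` noise, and applies the mask.
#'
#' @param truth a [generateGroundTruth()] result.
#' @param spec the [syntheticSpec()] it was generated from.
#' @return list with `tensor` (a [LabeledTensor-class]) and `labels`
#'   (subject -> 0/1 cohort codes).
#' @export
synthesizeStudy <- function(truth, spec) {
  stopIfNot(inherits(truth, "GroundTruth"), "truth must come from generateGroundTruth()")
  signal <- reconFactors(truth$factors, truth$weights)
  if (spec$noise_sd > 0) {
    noise <- withSeed(childSeed(spec$seed, 3L),
                      array(stats::rnorm(length(signal), sd = spec$noise_sd),
                            dim = dim(signal)))
    signal <- signal + noise
  }
  dn <- lapply(truth$factors, rownames)
  names(dn) <- names(truth$factors)
  dimnames(signal) <- dn
  tensor <- LabeledTensor(signal, mask = truth$mask)
  list(tensor = tensor, labels = truth$labels)
}

#' Write a cohort table (long-format CSV)
#'
#' Emits the long-format schema consumed by [assembleTensor()]:
#' `subject,cohort,<condition axes...>,mfi`, observed entries only, rows
#' sorted by subject then condition labels (in tensor label order) so the
#' write/read/write cycle is byte-identical.
#'
#' @param tensor a [LabeledTensor-class] with the subject axis first.
#' @param labels cohort labels (subject -> 0/1) from [cohortLabels()].
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
writeCohortTables <- function(tensor, labels, file) {
  axes <- axisNames(tensor)
  stopIfNot(axes[1] == "subject", "subject axis must come first")
  labs <- axisLabels(tensor)
  stopIfNot(all(labs$subject %in% names(labels)),
            "every subject needs a cohort label")
  grid <- expand.grid(labs, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- as.vector(tensorMask(tensor))
  df <- grid[keep, , drop = FALSE]
  df$mfi <- as.vector(tensorValues(tensor))[keep]
  df$cohort <- ifelse(labels[df$subject] == 1L, "bc", "healthy")
  # lexicographic row order makes the sort intrinsic to the file, so a
  # write -> read -> write cycle is byte-identical whatever the tensor's
  # internal label order
  ord <- do.call(order, lapply(axes, function(a) df[[a]]))
  df <- df[ord, c("subject", "cohort", axes[-1], "mfi")]
  df$mfi <- formatC(df$mfi, digits = 17, format = "g")
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Read a cohort table
#'
#' @param file CSV path with columns `subject,cohort,<condition axes...>,mfi`.
#' @return a long-format `data.frame` (a profile table).
#' @export
readCohortTable <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject", "cohort", "mfi")
  stopIfNot(all(need %in% names(df)),
            "cohort table must contain columns %s", paste(need, collapse = ", "))
  stopIfNot(nrow(df) > 0, "cohort table is empty")
  df
}
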