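# Full-pipeline orchestration: simulate (or load) -> preprocess ->
# rank-scan -> decompose -> stability -> classify -> associate, with one
# config, reproducible seeds and a run manifest.

#' Build a pipeline configuration
#'
#' Either `input` (paths to long-format cohort CSVs) or `spec` (a
#' [syntheticSpec()]) must be supplied, not both. All stochastic stages
#' draw their seeds from `seed`, so a rerun with the same config reproduces
#' every output bit-for-bit.
#'
#' @param spec a [syntheticSpec()] for a simulated cohort, or `NULL`.
#' @param input list with `signaling` (CSV path) and optionally
#'   `background` (CSV path), or `NULL`.
#' @param normalize normalization to apply: `"marker_max"`, `"zscore"`, or
#'   `"none"`.
#' @param fold_change if `TRUE`, apply [foldChangeTransform()] against
#'   `baseline_treatment` after assembly.
#' @param baseline_treatment baseline label for the fold-change transform.
#' @param rank_grid candidate ranks for classification-based rank selection.
#' @param cv list of cross-validation settings: `folds`, `repeats`.
#' @param stability list with `drop_axis`, or `NULL` to skip the jackknife.
#' @param n_perm permutations for the component-status correlation test.
#' @param fit list of [fitCPD()] options (`tol`, `max_iter`, ...).
#' @param seed master seed.
#' @return validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(spec = NULL, input = NULL,
                           normalize = c("marker_max", "zscore", "none"),
                           fold_change = FALSE,
                           baseline_treatment = "Untreated",
                           rank_grid = 1:6,
                           cv = list(folds = 10, repeats = 20),
                           stability = list(drop_axis = "subject"),
                           n_perm = 1000, fit = list(), seed = 1L) {
  normalize <- match.arg(normalize)
  stopIfNot(xor(is.null(spec), is.null(input)),
            "exactly one of spec or input must be supplied")
  if (!is.null(spec))
    stopIfNot(inherits(spec, "SyntheticSpec"),
              "spec must come from syntheticSpec()")
  if (!is.null(input))
    stopIfNot(is.list(input) && !is.null(input$signaling),
              "input must list at least a signaling CSV path")
  stopIfNot(length(rank_grid) >= 1, "rank_grid must be nonempty")
  structure(list(spec = spec, input = input, normalize = normalize,
                 fold_change = fold_change,
                 baseline_treatment = baseline_treatment,
                 rank_grid = rank_grid, cv = cv, stability = stability,
                 n_perm = n_perm, fit = fit, seed = as.integer(seed)),
            class = "PipelineConfig")
}

# serialize a config to canonical JSON for hashing / the manifest
configJSON <- function(config) {
  x <- unclass(config)
  x$spec <- if (is.null(x$spec)) NULL else unclass(x$spec)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing, classification-based rank scan,
#' the CPD fit at the selected rank, jackknife stability, repeated-CV
#' classification and component-status association, writing a report bundle
#' to `out_dir`: per-mode factor CSVs, `fit_report.json`,
#' `rank_scan.csv`, `stability.json`, `cv.json`, `associations.csv` and a
#' `manifest.json` recording the config hash, seed and package version.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results
#'   (`tensor`, `labels`, `best_rank`, `decomposition`, `report`,
#'   `rank_scan`, `stability`, `cv`, `associations`, `files`).
#' @export
runPipeline <- function(config, out_dir) {
  stopIfNot(inherits(config, "PipelineConfig"),
            "config must come from pipelineConfig()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  # -- simulate or load ------------------------------------------------
  dat <- stage("input", {
    if (!is.null(config$spec)) {
      truth <- generateGroundTruth(config$spec)
      synthesizeStudy(truth, config$spec)
    } else {
      tab <- readCohortTable(config$input$signaling)
      list(tensor = assembleTensor(tab), labels = cohortLabelsFromTable(tab))
    }
  })
  tensor <- dat$tensor
  labels <- dat$labels
  # -- preprocess ------------------------------------------------------
  tensor <- stage("preprocess", {
    if (!is.null(config$input) && !is.null(config$input$background))
      tensor <- subtractBackground(
        tensor, readCohortTable(config$input$background))
    if (config$fold_change)
      tensor <- foldChangeTransform(tensor, config$baseline_treatment)
    switch(config$normalize,
           marker_max = normalizeMarkerMax(tensor),
           zscore = zscoreReceptors(tensor),
           none = tensor)
  })
  # -- rank scan -------------------------------------------------------
  scan <- stage("rank_scan", selectRank(
    tensor, labels, config$rank_grid, fit_options = config$fit,
    cv_options = c(config$cv, list(seed = childSeed(config$seed, 10L)))))
  bestRank <- scan$best_rank
  # -- decompose -------------------------------------------------------
  fit <- stage("decompose", do.call(
    fitCPD, c(list(tensor = tensor, rank = bestRank), config$fit)))
  cpd <- fit$decomposition
  # -- stability -------------------------------------------------------
  stab <- if (!is.null(config$stability))
    stage("stability", jackknifeStability(
      tensor, bestRank, drop_axis = config$stability$drop_axis,
      fit_options = config$fit, reference = cpd))
  else NULL
  # -- classify --------------------------------------------------------
  sf <- factorMatrices(cpd)[[1]]
  cv <- stage("classify", do.call(repeatedCVAccuracy, c(
    list(features = sf, labels = labels),
    config$cv, list(seed = childSeed(config$seed, 20L)))))
  # -- associate -------------------------------------------------------
  assoc <- stage("associate", componentStatusCorrelation(
    sf, labels, n_perm = config$n_perm,
    seed = childSeed(config$seed, 30L)))
  # -- report bundle ---------------------------------------------------
  files <- character(0)
  wjson <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
  }
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  for (m in seq_along(factorMatrices(cpd))) {
    fm <- factorMatrices(cpd)[[m]]
    df <- data.frame(label = rownames(fm), as.data.frame(fm),
                     check.names = FALSE)
    wcsv(df, sprintf("factors_%s.csv", names(factorMatrices(cpd))[m]))
  }
  wjson(fit$report, "fit_report.json")
  wcsv(scan$curve, "rank_scan.csv")
  if (!is.null(stab))
    wjson(list(mean = stab$mean, sd = stab$sd,
               modes_compared = stab$modes_compared,
               fms_per_replicate = as.list(stab$fms_per_replicate)),
          "stability.json")
  wjson(list(mean_accuracy = cv$mean_accuracy, folds = cv$folds,
             repeats = cv$repeats, seed = cv$seed,
             fold_accuracies = cv$fold_accuracies), "cv.json")
  wcsv(assoc, "associations.csv")
  cfgPath <- file.path(out_dir, "config.json")
  writeLines(configJSON(config), cfgPath)
  files <- c(files, cfgPath)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfgPath)),
    seed = config$seed,
    best_rank = bestRank,
    package_version = as.character(utils::packageVersion("cytoTensor")))
  wjson(manifest, "manifest.json")
  invisible(list(tensor = tensor, labels = labels, best_rank = bestRank,
                 decomposition = cpd, report = fit$report,
                 rank_scan = scan$curve, stability = stab, cv = cv,
                 associations = assoc, files = files))
}
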