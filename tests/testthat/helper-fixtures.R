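# Shared fixtures, all generated in code.

# A random canonicalized CPD with the given mode sizes and rank.
randomCPD <- function(dims, rank, seed = 1, axes = NULL) {
  if (is.null(axes)) axes <- sprintf("mode%d", seq_along(dims))
  factors <- withr::with_seed(seed, lapply(dims, function(d)
    matrix(rnorm(d * rank), d, rank)))
  names(factors) <- axes
  weights <- withr::with_seed(seed + 1, sort(runif(rank, 1, 5),
                                             decreasing = TRUE))
  CPDecomposition(factors, weights)
}

# A fully observed LabeledTensor from a plain array.
makeTensor <- function(x, axes = NULL) {
  if (is.null(axes)) axes <- sprintf("mode%d", seq_along(dim(x)))
  LabeledTensor(x, axes = axes)
}

# A small noiseless synthetic study (truth + tensor + labels).
smallStudy <- function(n_subjects = 12, n_bc = 5,
                       mode_sizes = c(treatment = 5, marker = 4),
                       rank = 2, noise_sd = 0, missing_fraction = 0,
                       seed = 7, ...) {
  spec <- syntheticSpec(n_subjects = n_subjects, n_bc = n_bc,
                        mode_sizes = mode_sizes, rank = rank,
                        noise_sd = noise_sd,
                        missing_fraction = missing_fraction, seed = seed, ...)
  truth <- generateGroundTruth(spec)
  study <- synthesizeStudy(truth, spec)
  list(spec = spec, truth = truth, tensor = study$tensor,
       labels = study$labels)
}

# Brute-force optimal assignment value for a similarity matrix (maximize).
bruteForceBestAssignment <- function(sim) {
  n <- nrow(sim)
  perms <- gtoolsPerms(n)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    tot <- sum(sim[cbind(seq_len(n), perms[i, ])])
    if (tot > best) best <- tot
  }
  best
}

# All permutations of 1..n (tiny n only).
gtoolsPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtoolsPerms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
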