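---
title: "Censored CPD of cytokine signaling profiles: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored CPD of cytokine signaling profiles: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoTensor)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open. No empirical claim is made here beyond what the package's test suite
and acceptance script themselves compute.

## 1. Data model

The central container is the `LabeledTensor`: a dense n-way array with
named axes, per-axis labels, and a boolean observed-mask of the same shape.
Missingness is always represented by the mask — never by sentinel values —
and every operation that fits or scores a model touches observed entries
only. A validity rule requires each label on each axis to retain at least
one observed entry; an axis label with no data identifies nothing and is
rejected at construction.

Signaling profiles form a 4-way tensor (subject × treatment × cell type ×
marker), receptor panels a 3-way one (subject × cell type × receptor).
Long-format CSV tables (`subject,cohort,treatment,cell_type,marker,mfi`)
are assembled with `assembleTensor()`; absent key combinations become
masked entries, so fiber missingness (a subject never profiled under a
treatment) appears naturally as an all-masked slice.

Preprocessing mirrors standard practice for this kind of panel:

- **Background subtraction** per (subject, cell type, marker) against a
  separately supplied control table. The untreated condition is *retained*
  as a treatment level — basal signal is informative and must stay in the
  tensor — so background is a distinct control measurement, not the
  untreated slice. Negative differences are kept.
- **Marker-max normalization**: each marker slab is divided by its global
  observed maximum (across subjects, treatments and cell types), putting
  all markers on a common [~0, 1] scale without destroying relative
  response magnitudes within a marker.
- **Receptor z-scoring** per receptor slab, using the sample (n−1)
  standard deviation (the choice between n and n−1 is immaterial
  downstream — the decomposition is scale-equivariant per slab — but a
  convention must be fixed; the sample SD is the one `stats::sd` computes).
- An optional **fold-change transform** divides each entry by its matched
  untreated baseline; baselines must be positive, and the baseline slice
  becomes identically 1.

Masks are invariant under every preprocessing operation except assembly.

## 2. Censored alternating least squares

The rank-R canonical polyadic model writes the tensor as a sum of rank-one
outer products, one factor matrix per mode. Each ALS sweep solves every
mode in turn: with the unfolding convention chosen here (mode-n fibers as
columns, remaining modes in reverse order inside the Khatri–Rao product),
the mode-1 subproblem is literally `min_A ||X_(1) − A (C ⊙ B)^T||²`, a
linear least-squares problem.

Missing data enter through the *censored* solve: target columns of the
unfolded system are grouped by their missingness pattern, and each group is
solved with its unobserved rows deleted. Nothing is imputed during
fitting. On a fully observed tensor the censored path reduces exactly to
ordinary least squares — the test suite asserts bitwise-identical iterates
between the censored and plain solvers — and fiber missingness is the
favorable case, since whole slices share one pattern and batch into a
single solve. A target column with zero observed rows (pathological but
possible under entrywise masks) yields zero coefficients with a warning
rather than aborting the fit.

**Initialization** is deterministic: each mode's starting factor is the
leading R left singular vectors of that mode's unfolding, with masked
entries set to zero *for initialization only*. When R exceeds a mode's
size, the factor is padded with a deterministic orthonormal complement.

**Line search.** After two full sweeps, each sweep is followed by a Bro
extrapolation: the factors are pushed beyond the ALS update along the
difference from the previous iterate by a step of `N^(1/l)` (N the sweep
number, l the line-search quotient starting at 2). The step is accepted
only if the observed-entry error decreases relative to the plain ALS
update; after four consecutive rejections l is incremented (shrinking
future steps), and the rejection counter resets on acceptance — the
standard behavior where the reset rule is otherwise unspecified. Because
acceptance requires improvement and every ALS solve is itself monotone,
the recorded R2X trajectory is non-decreasing; the suite asserts this.

**Convergence and normalization.** Iteration stops when the change in R2X
(variance explained on observed entries, `1 − Σ(x − x̂)²/Σx²`) falls below
`tol`, default `1e-6` with at most 1000 sweeps — well below the 2–3
significant digits at which such fits are reported. Tests that certify
near-exact recovery (R2X ≥ 1 − 1e-8) pass `tol = 1e-12` instead: a
convergence tolerance must sit below the accuracy being certified. The
returned decomposition is canonicalized to remove CPD's scale and sign
indeterminacy: unit-norm columns, nonnegative weights in descending order,
and per-component sign flips arranged in pairs (each non-leading mode's
largest-magnitude entry made positive, flips absorbed by the subject mode,
any residual negative subject column fixed jointly with the last mode) so
the reconstruction is unchanged and factor comparisons are well-defined.

## 3. Rank validation

Two complementary selectors are provided.

**Q2X by imputation** (`q2xImputation`): a random fraction of *observed*
entries is additionally masked, the model is refit, and the reconstruction
is scored on the held-out entries only. A rank that merely chases noise
cannot impute; on noiseless low-rank data Q2X at the true rank is ~1 and
strictly exceeds Q2X at rank 1 (both asserted in the suite). Holdouts that
would orphan an axis label are resampled with bounded retries.

**Classification of subject factors** (`selectRank`): for each candidate
rank the CPD is fit, the subject factor matrix is extracted, and a
disease-status classifier is scored by repeated stratified
cross-validation. The returned rank maximizes mean accuracy, with ties
resolved toward the smallest rank (parsimony).

## 4. Stability: factor match score and jackknife

The **factor match score** between two decompositions multiplies, per
matched component pair, a weight-agreement term
`1 − |w_i − w_j| / max(w_i, w_j)` with the product over compared modes of
the absolute cosine between factor columns; components are paired by a
linear sum assignment (an exact O(R³) Hungarian solver, verified in tests
against brute-force enumeration of all R! pairings for small R) and the
score is the mean over the R pairs, so self-comparison gives exactly 1.
Absolute cosines make the score blind to paired sign flips, and the
assignment makes it blind to component order.

One scope decision deserves note: with unit-norm factors the component
scale lives in a single global weight. When a mode is *excluded* from the
comparison — the subject mode during the jackknife, whose size differs
between fits by construction — the scale is attributed to that excluded
mode and the weight term is dropped (set to 1). Otherwise a leave-one-out
refit would be penalized by the purely mechanical `√((n−1)/n)` shrinkage
of its weights, and even a noiseless jackknife could not reach FMS ≈ 1.
When all modes are compared, weights are compared.

`jackknifeStability` drops each subject in turn, refits at the same rank,
and scores FMS against the full-data decomposition over all modes except
the dropped axis. The replicate SD uses population (n) normalization by
default, the usual convention for jackknife spread; it is configurable.

## 5. Downstream statistics

- **L1-penalized logistic regression** on subject factors, solved by
  glmnet's coordinate descent with the iteration cap (5000) and tolerance
  (1e-6) fixed; the penalty is chosen by stratified inner cross-validation
  over 10 log-spaced inverse strengths C in [1e-4, 1e4], ties toward the
  sparser model. Outer evaluation uses repeated, stratified, 10-fold
  cross-validation with 20 repeats; the penalty is re-selected inside each
  training split only, so no information leaks from the held-out fold.
  Degenerate designs (all-constant features) reduce to the intercept-only
  model, i.e. majority-class prediction.
- **Component–status correlations**: Pearson r of each subject-factor
  column against the 0/1 status vector; two-sided permutation p-value
  `(1 + #{|r_perm| ≥ |r_obs|})/(1 + n_perm)` under label shuffling (the
  +1 keeps the test valid at any n_perm), with the analytic t-based
  p-value reported alongside. Constant columns are flagged and reported as
  r = 0, p = 1.
- **Mann–Whitney U** with midrank ties; the p-value uses the exact
  rank-sum null distribution when the pooled sample is small (m + n ≤ 12)
  and tie-free, otherwise a normal approximation with tie-corrected
  variance and continuity correction; a fully tied comparison (variance 0)
  returns p = 1.
- **Hierarchical ordering** of subjects: Euclidean distance with average
  linkage by default (the common compromise between single-linkage
  chaining and complete-linkage compactness); both are configurable.
- **Partial correlations** from the precision matrix of a shrunk
  covariance (Ledoit–Wolf-type intensity toward the scaled identity).
  The `"auto"` policy applies *zero* shrinkage when the sample covariance
  is well-conditioned (more subjects than variables), so the two-variable
  case reduces exactly to the Pearson correlation; shrinkage engages only
  when variables rival or exceed subjects, the regime where the plain
  precision matrix is unusable.
- **ROC/AUC** via the rank identity `AUC = U/(mn)`, which handles ties by
  midranks and equals the trapezoid area under the threshold-swept curve.
- Tucker (higher-order orthogonal iteration, complete data only, with a
  greedy Pareto walk over per-mode ranks) and subject-flattened PCA serve
  as compression baselines; the CPD parameter count is `R · Σ mode sizes`
  against `k · (subjects + columns)` for PCA.

## 6. The synthetic cohort generator

The generator exists so that every stage can be tested against known
truth. Its defaults fix the study conditions once:

| parameter | default | rationale |
|---|---|---|
| subjects | 36 (22 healthy / 14 disease) | the profiled cohort design |
| treatment axis | 8 (7 cytokines + untreated) | the stimulation panel |
| cell types / markers | 23 / 6 | the gating and phospho panels |
| receptors | 14 | the receptor stain panel |
| true rank | 4 | small enough to fit quickly, large enough that the disease component is not the dominant one |
| disease component | index min(3, rank), shift 3 | a 3-SD cohort shift on a mid-strength component, so rank selection must go past the leading components to find it |
| weights | linearly decaying, scaled to unit per-entry RMS | makes `noise_sd` read as a relative noise level |
| noise | Gaussian, sd 0.3 | population-MFI noise is not otherwise characterized; homoscedastic Gaussian is the simplest model consistent with the normalizations applied |
| missingness | 10.4%, fiber mode | the missing-slice fraction of the emulated cohort; by default 15 randomly chosen subjects lose their TGFβ and combination-treatment slices (15 of 36 subjects × 2 of 8 treatments = 10.42%) |

Factor entries are i.i.d. standard normal; the cohort shift is added to
the designated subject-factor columns *before* column normalization, so
the standardized group-mean difference equals the nominal effect size and
all scale identifiability lives in the weights. Everything is drawn from
seeds derived from the spec seed, making the full study bitwise
reproducible.

What the generator does **not** emulate: event-level cytometry, spectral
spillover, per-cell distributions (only population MFIs), heteroscedastic
or marker-specific noise, batch effects, and any real biological
correlation structure between treatments or cell types beyond low-rankness.
A passing synthetic suite therefore demonstrates algorithmic correctness —
recovery, calibration, stability under the assumed model — not that the
model assumptions hold for any particular real dataset.

## 7. Problem sizes used in validation

The test suite and acceptance checks run at deliberately modest sizes,
chosen as the smallest problems that still exercise each property:
censored/plain equivalence on 10×8×6 tensors over 20 seeds; exact recovery
of noiseless rank-3 structure on 20×8×12×6 over 20 seeds; imputation
validation with 10% holdouts on the same shape; classification recovery,
rank scan and the 36-replicate jackknife on the full default 36×8×23×6
cohort; permutation-test calibration over 200 null simulations. The
statistical acceptance thresholds (accuracy ≥ 0.9 at effect size 3, FMS
bounds, binomial bands) are properties of these fixed study conditions,
not tuned quantities.

## 8. Known limitations

- Tucker fitting requires complete data (mean-imputation fallback with a
  warning); it is a compression baseline only.
- The censored solver's pattern grouping is efficient for fiber
  missingness but degrades toward one solve per column under adversarial
  entrywise masks.
- Over-factoring (R above a mode size) is permitted with a warning, with
  orthonormal padding of the SVD initialization; recovery guarantees
  apply only at R ≤ min mode size.
- The L1 path uses coordinate descent; solutions match any other convex
  solver at the optimum, but iteration-capped behavior on pathological
  designs may differ from stochastic-gradient implementations.
- Permutation p-values have resolution 1/(1 + n_perm); with few subjects,
  duplicate permutations make the attainable floor coarser than this.
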