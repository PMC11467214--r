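# cytoTensor

Tensor-based systems analysis of cytokine signaling responses and receptor
abundances in peripheral blood immune cells.

## The problem

Cytokine perturbation experiments profile how peripheral blood mononuclear
cells (PBMCs) respond to a panel of stimulations: per-population mean
fluorescence intensities (MFIs) of phosphorylated transcription factors
(pSTAT1/3/4/5/6, pSmad2/3) are gathered across **subjects × treatments ×
cell types × markers**, and receptor stains across **subjects × cell types
× receptors**. Differences between a disease cohort and healthy controls
are spread across all of these dimensions at once, and whole treatment
slices can be missing for some subjects. Flattening such data for PCA
destroys the factorial structure; per-measurement testing misses
coordinated patterns.

`cytoTensor` analyzes these profiles in their natural tensor form, for
immunologists and computational biologists working with gated
flow-cytometry summaries of perturbation panels.

## The method

The core is the **canonical polyadic decomposition (CPD)**: the data tensor
is modeled as a sum of R rank-one components,

    X ≈ Σ_{r=1..R}  λ_r · a_r ⊗ b_r ⊗ c_r ⊗ d_r

with one unit-norm factor vector per mode (subject, treatment, cell type,
marker) and nonnegative weights λ_r. Fitting is by **censored alternating
least squares**: each mode is solved in turn as a least-squares problem
against the Khatri–Rao product of the other modes, where target columns are
grouped by their missingness pattern and the unobserved rows are dropped
from each solve — missing entries are never imputed during fitting. The ALS
is initialized from per-mode SVDs of the unfoldings and accelerated by a
Bro-style line search (extrapolation step N^(1/l), accepted only when the
observed-entry error decreases).

Around the decomposition the package provides:

- rank selection by held-out **imputation** (Q2X) and by **disease-status
  classification** of the subject factors (L1-penalized logistic regression
  with repeated, stratified 10×20 cross-validation);
- **jackknife stability**: leave-one-subject-out refits scored by the
  **factor match score** (FMS), with components paired by an optimal linear
  sum assignment;
- association statistics: component–status Pearson correlations with
  permutation p-values, Mann–Whitney U (exact where feasible), hierarchical
  subject ordering, shrinkage partial correlations, ROC/AUC;
- Tucker and PCA compression baselines;
- a **synthetic cohort generator** with known low-rank factors,
  cohort-associated components, noise and study-like fiber missingness, so
  the whole pipeline can be validated against ground truth.

## Worked example

Simulate a cohort with the default study-like design — 36 subjects
(22 healthy, 14 disease), 8 treatments (7 cytokines + untreated), 23 cell
types, 6 markers, ~10.4% of entries missing as whole treatment fibers, and
a rank-4 signal whose third component carries the cohort shift:

```r
library(cytoTensor)

spec  <- syntheticSpec(seed = 42)
truth <- generateGroundTruth(spec)
study <- synthesizeStudy(truth, spec)
study$tensor
#> LabeledTensor: 36 x 8 x 23 x 6 (39744 entries, 89.6% observed)
#>   subject [36]: subject_01, subject_02, subject_03, ...
#>   treatment [8]: Untreated, IL2, IL4, ...
#>   cell_type [23]: B, B_naive, B_memory, ...
#>   marker [6]: pSTAT1, pSTAT3, pSTAT4, ...

fit <- fitCPD(study$tensor, rank = 4)
fit$decomposition
#> CPDecomposition: rank 4 over modes (subject=36, treatment=8, cell_type=23, marker=6)
#>   weights: 145.5, 109.5, 73.2, 36.9
r2x(fit$decomposition, study$tensor)
#> [1] 0.924
```

92% of the observed variance is captured; the remaining 8% is the additive
noise. The subject factors classify disease status well above the 22/36
majority-class chance level, and the correct component is flagged:

```r
sf <- factorMatrices(fit$decomposition)[[1]]
repeatedCVAccuracy(sf, study$labels, seed = 1)
#> Repeated stratified CV: 10 folds x 20 repeats, mean accuracy 0.970

componentStatusCorrelation(sf, study$labels, n_perm = 1000, seed = 1)
#>   component       r   p_perm p_analytic constant
#> 1         1 -0.1577 0.357642   3.58e-01    FALSE
#> 2         2 -0.0474 0.777223   7.84e-01    FALSE
#> 3         3  0.8547 0.000999   3.26e-11    FALSE
#> 4         4 -0.0443 0.777223   7.98e-01    FALSE
```

Component 3 — the component the generator endowed with the cohort shift —
is the only one correlated with status (r = 0.85, permutation p at its
floor of 1/1001). Finally, the factorization is stable under
leave-one-subject-out resampling:

```r
jackknifeStability(study$tensor, 4, reference = fit$decomposition)
#> Jackknife stability across 36 subject replicates (modes: treatment, cell_type, marker)
#>   mean FMS = 1.000, SD = 0.000 (0 failed refits)
```

`runPipeline(pipelineConfig(spec = spec), "out/")` chains all of the above
(rank scan → decomposition → stability → classification → association) and
writes factor CSVs, JSON reports and a run manifest.

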