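# pasl — Pathway Activity Score Learning

`pasl` is an R package for unsupervised dimensionality reduction of
gene-expression data in which the learned dimensions are directly
interpretable: each latent coordinate is an activity score of a known
pathway (geneset). It is aimed at transcriptomics analysts who want the
compression and denoising of PCA-family methods without giving up the
pathway-level vocabulary that biological interpretation actually uses, plus
a geneset-level analog of differential expression testing.

## The method

Given samples-by-features expression data `X` and a binary geneset
membership matrix `G` (m genesets by p features), the standardized data are
decomposed as

    X_z = L · D + noise,      D = [D1; D2],      L = X_z · D⁺

where the dictionary rows (atoms) are unit-norm and sparse. Rows of `D1`
are each constrained to the features of one geneset; rows of `D2` are
unconstrained but have a fixed number `nz` of non-zeros. `L` holds the
pathway activity scores (`D⁺` is the Moore–Penrose pseudo-inverse).

* **Inference phase** — greedy: rank all (geneset, principal component)
  pairs by explained variance normalized for geneset size through a
  Box-Cox transform (`λ = 1/3` by default; larger genesets are penalized so
  they do not dominate by sheer coefficient count), repeatedly extract the
  leading restricted principal component of the current residual as the
  next atom, and deflate. A threshold `t` (default 0.9) controls how
  eagerly the ranking is recomputed when deflation makes its expectations
  stale — `t = 0` is a fully static ordering, `t = 1` fully dynamic.
* **Discovery phase** — cardinality-constrained sparse PCA (truncated power
  iteration with hard thresholding, exactly `nz` non-zeros per atom) on the
  inference residual, capturing structured variance outside known genesets.
* **Projection** — new samples are standardized with the training
  parameters and mapped by the cached pseudo-inverse; works for a single
  sample.
* **Differential activation analysis (DAA)** — per-atom Welch t statistics
  between two classes with shared-permutation two-sided p-values
  (exhaustive enumeration when feasible).

A planted-model simulator (`pasl_simulate()`, `pasl_simulate_two_class()`)
generates datasets with known ground truth for validation: random genesets
with sizes in {30, 50, 100, 200}, signed-uniform loadings and scores on
[−1.5, −0.5] ∪ [0.5, 1.5], Gaussian noise.

## Worked example

Simulate a two-class dataset in which the first planted factor is shifted
between classes, fit a dictionary, project, and test for differential
activation:

```r
library(pasl)

spec <- pasl_sim_spec(n = 120, p = 300, n_genesets = 10, n_active = 6,
                      sizes = c(20, 40), noise_sd = 0.1, seed = 42)
sim <- pasl_simulate_two_class(spec, effect = c(2, 0, 0, 0, 0, 0),
                               class_sizes = c(60, 60))

fit <- pasl_fit(sim$X, sim$truth$G, a1 = 6, a2 = 2, nz = 50, seed = 1)
print(fit)
#> <pasl_model>
#>   atoms: 6 inference + 2 discovery, p = 300 features
#>   hyper: t = 0.9, lambda = 0.3333333, nz = 50
#>   reevaluations during inference: 0

head(fit$atom_meta)
#>        atom     phase geneset geneset_index variance_removed
#> 1 GS:GS05#1 inference    GS05             5         4416.991
#> 2 GS:GS01#1 inference    GS01             1         2201.364
#> 3 GS:GS09#1 inference    GS09             9         2148.120
#> 4 GS:GS03#1 inference    GS03             3         1902.035
#> 5 GS:GS02#1 inference    GS02             2         1844.798
#> 6 GS:GS04#1 inference    GS04             4         1722.698

L <- pasl_transform(sim$X, fit)
explained_variance(sim$X, fit)          # 0.426
permuted_baseline(sim$X, fit, seed = 7) # 0.012

daa <- differential_activation(L, sim$labels, n_perm = 999, seed = 2)
head(as.data.frame(daa), 3)
#>        atom geneset          t     p rank
#> 1 GS:GS01#1    GS01 -9.5794768 0.001    1
#> 2 GS:GS04#1    GS04 -1.1388411 0.241    2
#> 3    DISC#2    <NA> -0.7739127 0.441    3
```

Reading the output: the six inference atoms each carry one geneset's
leading expression mode, ordered by size-normalized variance;
`variance_removed` is the squared Frobenius mass each atom took out of the
standardized data. The fitted dictionary explains 42.6% of the variance of
this noisy 120 × 300 dataset, versus 1.2% for a column-permuted random
projection of the same sparsity. DAA recovers the planted shift: the atom
of geneset `GS01` — the factor that was shifted by 2 between classes —
ranks first at the near-minimal permutation p-value, while unshifted
genesets and the discovery atoms are quiet.

Models round-trip through a portable JSON archive (`save_pasl()` /
`load_pasl()`), and `exec/pasl` exposes `fit`, `transform`, `daa`,
`simulate`, and `evaluate` subcommands for shell pipelines.

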