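# viperImpute

Cell-based imputation of dropout zeros in single-cell RNA-seq count
matrices, implementing VIPER (variability-preserving imputation for
expression recovery), together with a synthetic-data generator and the
masking / down-sampling benchmark experiments used to evaluate it.

## Who this is for

Analysts working with scRNA-seq count matrices in which excess zeros —
dropouts, transcripts present in the cell but missed by the protocol —
distort normalization, differential expression or visualization. Unlike
diffusion-style smoothers, this method imputes **only the zero entries**
and leaves every observed non-zero count untouched, preserving
cross-cell expression variability (the per-gene coefficient of variation)
instead of collapsing it.

## The method

For cell *i* with normalized expression `X[i,j] = log(RPM + 0.1)`, the
mean model is a sparse convex combination of the other cells:

    E(X[i,j]) = Σ_{l≠i} X[l,j] · b[i,l],   b[i,l] ≥ 0,  Σ_l b[i,l] = 1.

The weights are estimated in two steps per cell: (1) **pre-selection** of
a moderate candidate pool by cross-validated lasso/elastic-net regression
over a random subset of up to 5,000 low-zero "fitting" genes, and (2)
**estimation** by solving the constrained least squares exactly as a
quadratic program on the simplex, followed by hard thresholding at
`t = 0.001` and renormalization. A zero count in a *neighbour* cell may
itself be a dropout, so before imputation each such predictor is adjusted
with a zero-inflated Poisson log-normal mixed model

    C[l,j] ~ p·δ₀ + (1−p)·Poisson(N_l · exp(mu + ε_l)),  ε_l ~ N(0, ψ),

fitted by EM (monotone in the observed-data likelihood); the predictor
becomes the posterior mean rate on the log-RPM scale. Zeros in the target
cell are then imputed as `X̂[i,j] = Σ_l x*[l,j] · b[i,l]`.

See `vignettes/variability-preserving-imputation.Rmd` for the full model,
numerical choices, and known limitations.

## Worked example

```r
library(viperImpute)

sim <- simulate_counts(n_cells = 150, n_genes = 500, n_subpops = 3,
                       depth_range = c(5e4, 1e5), seed = 42)
sim
#> <synthetic_dataset> 150 cells x 500 genes, 3 subpopulations, 31.8% dropout events

res <- impute_matrix(sim$counts, viper_config(seed = 7, fitting_gene_floor = 200))
res
#> <imputation_result> 150 cells x 500 genes; 25347 imputed entries; 0 failed cells
#>   median candidates 18 -> median neighbours 17

truth <- log_transform(compute_rpm(sim$truth_counts)$rpm)
ents  <- which(sim$dropout_mask, arr.ind = TRUE)
metric_correlation_median(res$imputed, truth$X, ents)
#> 0.812
cv_preservation(res)$frac_within_band
#> 0.918
```

The simulator plants dropout events at known positions, so the imputed
matrix can be scored against the truth: the median per-cell Pearson
correlation between imputed and true values at dropout entries is 0.81
(zeros left unimputed give no signal at all), and 92% of genes keep their
post-imputation coefficient of variation within ±25% of the
pre-imputation non-zero CV — the imputed values follow the distribution
of the observed ones instead of shrinking toward a mean.

`impute_matrix()` returns the imputed log-RPM matrix, a mask of replaced
entries, and the sparse cell × cell weight matrix; `write_imputed()`
saves all three. A command-line wrapper with `impute`, `simulate`,
`mask`, `downsample` and `evaluate` subcommands is installed at
`inst/cli/viper-impute`.

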