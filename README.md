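# nucite

Joint analysis of single-nucleus RNA and intranuclear antibody-capture
(inCITE-seq) data: nuclear protein quantification against a histone H3
reference, and regression-based association of nuclear protein levels with
gene expression.

## What problem this solves

inCITE-seq measures nuclear protein epitopes (via oligo-conjugated
antibodies) and RNA in the same nuclei — for example TDP-43, p65/NF-κB and
β-catenin in capillary endothelial and microglial nuclei from postmortem
brain cohorts spanning healthy aging and neurodegenerative disease. Raw
antibody counts are dominated by per-nucleus antibody access and capture
efficiency, which scale the whole panel of a nucleus together. `nucite`
implements the analysis stack for this design:

* **Reference normalization and nCLR.** Each antibody count is divided by
  the nucleus's histone H3 count, `n_p = (A_p + c) / (A_H3 + c)`, which
  cancels the panel-wide capture factor; ratios are then transformed to
  centered natural log ratios, `nCLR_p = ln(n_p / g_p)`, where `g_p` is
  the per-antibody geometric mean over a centering cohort, so each
  antibody's cohort log-mean is exactly 0.
* **Two-step association model.** Per gene: (1) OLS of log-normalized
  expression on `log_ncounts + log_hashtag_counts + batch`, keeping
  residuals (genes detected in ≥ 25 nuclei only); (2) regression of those
  residuals on the protein nCLR columns jointly, with per-coefficient
  t tests and Benjamini–Hochberg control at FDR 0.05 across all
  gene × protein tests. Protein columns are residualized on the same
  covariates by default, so the coefficients equal the joint-regression
  coefficients (Frisch–Waugh–Lovell).
* **Supporting stages.** Nucleus/gene QC (≥ 50 genes, ≤ 5% mitochondrial,
  hashtag ≤ 4,000, TDP-43 antibody ≤ 3,000, genes in ≥ 5 nuclei), depth
  normalization to counts-per-10k with `ln(x+1)`, variable-gene selection,
  PCA/kNN/Leiden clustering, embedding density of protein-high nuclei,
  percentile stratification with pooled-t contrasts and Cohen's
  *d* = *t*·√(1/n₁ + 1/n₂), protein–protein stoichiometry curves,
  donor-level pseudobulk with the ≥ 10 cells / ≥ 800 counts filters,
  donor-correlation dendrograms, cluster-composition ANOVA + Tukey HSD
  and Spearman age trends, and Fisher-exact overlap of association sets
  with external gene sets.
* **Synthetic cohort generator.** Multi-donor, multi-batch
  negative-binomial simulator with latent nuclear protein levels, shared
  capture-efficiency nuisance, planted gene–protein effects and exported
  ground truth, used by all calibration and recovery tests.

## Worked example

```r
library(nucite)

sim <- simulate_incite(sim_config(seed = 42))   # synthetic 20-donor cohort
ds  <- qc_filter(sim$dataset)$dataset
ds
#> <nucleus_dataset> 4193 nuclei x 300 genes; 4 antibodies (reference: H3)
#>   donors: 20  groups: AD/aged/ALS/FTD/young  batches: 4

fit <- protein_assoc(ds)                        # two-step model, joint fit
fit
#> <protein_assoc> joint fit of 300 genes x 3 proteins on 4193 nuclei
#>   629 of 900 tests significant at BH q < 0.05
summary(fit)
#>        protein n_genes n_positive n_negative
#> 1 beta-catenin     300        142          2
#> 2          p65     300        190          5
#> 3       TDP-43     300         10        280

# nucleus-level protein contrast between capillary states
ct <- percentile_contrast(fit$nclr[, "TDP-43"],
                          ds$meta$cluster == "HC",
                          ds$meta$cluster == "REV1", c("HC", "REV1"))
ct
#> HC (n=1268, mean=0.15) vs REV1 (n=829, mean=-0.6515)
#>   pooled t = 16.466, p = 2.23e-57, Cohen's d = 0.735
```

The ten genes planted with a positive TDP-43 effect surface among the
`n_positive` TDP-43 rows; the many weak negative rows are the expected
compositional echo of planting strong effects on well-expressed genes
(see the vignette). The contrast shows the generator's planted TDP-43
depletion in reactive (REV1) versus homeostatic (HC) capillary nuclei,
on the same scale as published nucleus-level contrasts — e.g.
`cohens_d_from_t(12.91, 6297, 4507)` = 0.252 and
`cohens_d_from_t(31.96, 6297, 4507)` = 0.624.

The methods vignette
(`vignettes/nuclear-protein-association.Rmd`) documents the model,
parameter choices, generator design and limitations.

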