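# hybridqg

Quantitative genetics of immortalized F2 hybrid populations: simulation,
variance decomposition, QTL scanning and genomic prediction for the
two-population design in which a biparental doubled-haploid (DH) panel and
the single-cross hybrids made among its lines are analyzed jointly.

## The problem and who this is for

Hybrid breeding programs need to know how much of hybrid performance is
additive (transmitted through parental means, exploitable by selecting
parents), how much is dominance (cross-specific, exploitable only by
picking specific combinations), and how much is epistatic. An
*immortalized F2* — a set of hybrids among DH lines all descending from one
F1 — is the sharpest design for this question: every segregating locus has
expected allele frequency one half (maximizing dominance variance), hybrid
genotypes are fully determined by their parents, and the additive variance
among the DH lines is exactly twice that among the hybrids. `hybridqg` is
for quantitative geneticists and breeders who want to run this entire
analysis — or test analysis code against a population with known ground
truth — without access to restricted field data.

## What is inside

| Stage | Functions |
|---|---|
| Simulation with known truth | `simulate_dh_population`, `make_crossing_design`, `calibrate_truth`, `simulate_trait`, `simulate_validation_scenario` |
| Marker QC & design matrices | `qc_filter`, `dedup_perfect_ld`, `infer_hybrid_genotypes`, `f_infinity_design` |
| Relationship kernels | `rogers_kinship`, `additive_relationship`, `dominance_relationship`, `gaussian_kernel`, `kernel_cross` |
| Phenotypic analysis | `detect_outliers`, `adjust_means_within_env`, `adjust_means_across_env`, `fit_gca_sca`, `heritability` |
| QTL mapping | `main_effect_scan`, `epistasis_scan_2d`, `holm_correct`, `permutation_threshold`, `explained_variance`, `cv_mapping_accuracy` |
| Genomic prediction | `fit_gblup`, `predict_new`, `crossvalidate`, `independent_validate`, `bayesian_variance_partition` |
| Orchestration | `run_pipeline`, `default_config`, `hybridqg_cli` (+ `inst/cli/hybridqg`) |

The statistical core: the one-step mixed model
`y = mu + group + p + (pl) + m + f + s + (ml) + (fl) + (sl) + l + e`
decomposes line and hybrid variation into GCA/SCA components (REML, with
both parental GCA factors constrained to one variance since all parents
come from one DH panel); broad-sense heritability is
`H2 = s2_G / (s2_G + s2_GxE/N_E + s2_E/(N_E N_R))`; scans fit
`Y = X beta + S s + Z u + e` with `u ~ N(0, K s2_u)` and `K` = one minus
the Rogers distance matrix, via one spectral decomposition (P3D reuses the
null components per marker; an exact mode re-estimates them); the
two-locus scan adds the eight F-infinity terms (a1, a2, d1, d2, AxA, AxD,
DxA, DxD) with permutation-based genome-wide thresholds; prediction is
GBLUP with additive, dominance and Gaussian (epistasis-capturing) kernels
and the design-specific cross-validation (estimation sets hold 100% of
lines and 80% of hybrids; accuracy = Pearson correlation / sqrt(H2)).

## Worked example

```r
library(hybridqg)

map   <- default_map(n_markers = 20)                    # 19 chromosomes, 380 markers
dh    <- simulate_dh_population(map, n_lines = 180, seed = 42)
des   <- make_crossing_design(180, 318, seed = 42, parent_ids = dh$ids)
truth <- calibrate_truth(dh, des, n_qtl = 60, seed = 42)  # published variance targets
plots <- simulate_trait(dh, des, truth, n_env = 3, n_rep = 2)

vc <- fit_gca_sca(detect_outliers(plots)$pheno, des)
vc
#> variance_components (n_env = 3 , n_rep = 2 )
#>         sigma2_genotype              sigma2_gca              sigma2_sca
#>                 0.02328                 0.01222                 0.01106
#>              sigma2_gxe        sigma2_env_x_gca        sigma2_env_x_sca
#>                 0.08030                 0.02220                 0.05810
#>         sigma2_residual              sigma2_env sigma2_genotype_parents
#>                 0.02015                 0.00461                 0.02160
#>      sigma2_gxe_parents
#>                 0.07466
#> H2 = 0.4359
```

The generator was calibrated to GCA 0.0110, SCA 0.0156, ExGCA 0.0243,
ExSCA 0.0561, residual 0.0211 (H2 0.47); one seed's REML estimates land
near those targets, and averaging over 20 seeds recovers every component
within 30% (that is acceptance criterion 7). Prediction:

```r
geno  <- bind_individuals(dh, infer_hybrid_genotypes(dh, des))
dsg   <- f_infinity_design(qc_filter(geno)$markers)
means <- adjust_means_across_env(adjust_means_within_env(detect_outliers(plots)$pheno))
K     <- list(additive  = additive_relationship(dsg),
              dominance = dominance_relationship(dsg),
              gaussian  = gaussian_kernel(dsg))
cv <- crossvalidate(means, K, setNames(geno$group, geno$ids),
                    h2 = vc$heritability, folds = 5, n_repeats = 2, seed = 42)
attr(cv, "summary")
#>   model accuracy.mean accuracy.sd
#> 1     A     0.5923347   0.1314662
#> 2    AD     0.8416377   0.1548728
#> 3   ADE     0.8406729   0.1551030
```

Adding the dominance kernel raises five-fold CV accuracy sharply (here
0.59 to 0.84) because a world calibrated to the published components is dominance-rich —
the same ordering the published study reports (0.49 < 0.65 <= 0.72).

The whole chain also runs from one JSON config:

```r
run_pipeline(default_config())          # or: inst/cli/hybridqg run --config run.json
```

## Documentation

`vignettes/hybridqg-methods.Rmd` documents the models, estimation
choices, the simulator's stated world (and what a green test does and does
not establish), numerical conventions, and known limitations.
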