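# cecaldriver

Prioritizing microbial drivers of abdominal fat deposition from paired
metagenome (MG) and metatranscriptome (MT) species-abundance tables.

## The problem

Differential-abundance lists from DNA-level profiling are dominated by
passengers. A microbe that *drives* a host adiposity phenotype should be
(i) enriched in the fat group on both the DNA and RNA layers, (ii) more
transcriptionally active per unit of genomic abundance in that group, and
(iii) have that activity track the phenotype across individuals.
`cecaldriver` implements this prioritization for two-group designs (e.g.
fat- vs lean-line cecal donors phenotyped for body weight BW, abdominal
fat weight AFW and abdominal fat percentage AFP = AFW/BW), together with
the validation analytics such a study needs downstream.

## The method

Per layer, a LEfSe-style screen calls differential species: a two-sided
Mann–Whitney rank-sum test (exact at small n, midrank normal
approximation otherwise) gated by a bootstrapped linear-discriminant
effect size on total-sum-scaled abundances,

    score(f) = log10(1 + mean_b ½(|Δ_raw,b(f)| + |Δ_LDA,b(f)|)),

with defaults p < 0.05 and score > 2.5. For species differential on both
layers, per-sample transcriptional activity is the RNA/DNA ratio of
relative abundances,

    activity(f, s) = (relMT + ε) / (relMG + ε),

with a shared pseudocount ε = half the minimum non-zero relative
abundance. A species is reported as a candidate driver when its
enrichment is concordant across layers, its activity is significantly
higher in the enriched group (Mann–Whitney), and its activity correlates
positively with both AFP and AFW (Spearman, p < 0.05).

Companion modules: alpha diversity (classic Chao1, EstimateS-style ACE,
Shannon), Bray–Curtis + PCoA + PERMANOVA/ANOSIM with automatic exhaustive
label enumeration on small designs, adipocyte stereology
(V̄ = (π/6)(3s²d̄ + d̄³), N = W/(0.915·V̄)), villus morphometry
comparison, 2^−ΔΔCt qPCR relative expression, untargeted-metabolomics
preprocessing (80% prevalence → minimum imputation → sum normalization →
QC-RSD ≤ 30% → log10) with PLS-DA VIP scoring and the
FDR < 0.05 / VIP > 1 / FC > 1 gate, Fisher-exact set enrichment, and a
synthetic-data generator that plants a ground-truth driver so the whole
chain is testable offline.

## Worked example

```r
library(cecaldriver)

sim <- simulate_paired_omics(omics_sim_config(seed = 1))  # 30/group, 200 species
fit <- driver_screen(sim$mg, sim$mt, sim$metadata,
                     config = lefse_config(seed = 1))
print(fit)
#> Driver screen (paired MG/MT)
#>   samples: 60 (fat n=30, lean n=30)
#>   differential species: 20 MG, 31 MT, 12 overlapping
#>   selected candidate driver(s): sp_015

sim$truth$driver_id
#> [1] "sp_015"

head(coef(fit)[, c("feature", "mg_enriched_group", "activity_p",
                   "rho_AFP", "rho_AFW", "selected", "rank")], 4)
#>   feature mg_enriched_group activity_p rho_AFP rho_AFW selected rank
#> 1  sp_015               fat   3.02e-11   0.595   0.605     TRUE    1
#> 2  sp_018              lean   3.63e-01  -0.156  -0.185    FALSE   NA
#> 3  sp_065              lean   1.86e-01  -0.252  -0.227    FALSE   NA
#> 4  sp_101               fat   3.39e-02  -0.159  -0.151    FALSE   NA
```

Twelve species pass both per-layer screens, but only the planted driver
combines concordant enrichment with significantly elevated activity
(p ≈ 3e−11) and a positive activity–phenotype correlation (ρ_AFW ≈ 0.61)
— the others are passengers or discordant. The companion analytics work
the same way:

```r
alpha_diversity(c(5, 1, 1, 2, 3))
#>   S_obs chao1      ACE shannon
#> 1     5     7 6.654545 1.42413
```

A config-driven end-to-end run (`pipeline_config()` + `run_pipeline()`)
executes ecology verification, the screen, and optional metabolomics,
writing TSV outputs and a checksummed JSON report that is byte-identical
under a fixed seed.

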