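---
title: "Screening paired metagenome/metatranscriptome profiles for adiposity-driving microbes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening paired metagenome/metatranscriptome profiles for adiposity-driving microbes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecaldriver)
```

## The problem

Gut-microbiome studies of host adiposity routinely produce long lists of
taxa whose DNA-level abundance differs between fat and lean animals. Most
of those associations are passengers. A microbe that *drives* fat
deposition should show three signals at once: it is enriched in the fat
group at the DNA level (metagenome, MG), enriched at the RNA level
(metatranscriptome, MT), and — crucially — *more transcriptionally active
per unit of genomic abundance* in the fat group, with that activity
tracking the host phenotype across individuals. `cecaldriver` implements
this prioritization as a single estimator, `driver_screen()`, plus the
surrounding validation analytics a transplantation/gavage study needs
(community ecology, adipocyte stereology, villus morphometry, qPCR
relative expression, untargeted metabolomics).

The motivating design is a chicken study: cecal contents from fat- and
lean-line donors (n = 30 per line), phenotyped for body weight (BW, g),
abdominal fat weight (AFW, g) and abdominal fat percentage
(AFP = AFW/BW), profiled on both omics layers over a common species
panel.

## The screen

Per layer, differential species are called by a LEfSe-style screen: a
two-sided Mann–Whitney rank-sum test (`p < alpha`) gated by a
linear-discriminant effect size on total-sum-scaled abundances
(default per-sample total $10^6$). The published method this emulates
specifies only the gates (LDA score > 2.5 with p < 0.05, or > 2.0 for
coarser contrasts); its internals are not fully standardized, so this
implementation fixes a deterministic variant and exposes every knob in
`lefse_config()`:

* `n_bootstrap = 30` rounds, each subsampling `2/3` of every class
  without replacement (a class must keep at least 3 samples);
* per round, the per-feature effect is
  $\tfrac12\left(|\Delta_{\text{raw}}| + |\Delta_{\text{LDA}}|\right)$,
  where $\Delta_{\text{raw}}$ is the class-mean difference on the scaled
  abundances and $\Delta_{\text{LDA}}$ is the feature's additive
  contribution to the projected class-mean separation along the
  one-dimensional regularized linear discriminant
  ($w \propto (S_w + \lambda I)^{-1}(\mu_1-\mu_2)$, unit norm, diagonal
  loading $\lambda = 10^{-6}\,\mathrm{tr}(S_w)$ for small-n stability);
* the reported score is $\log_{10}(1 + \text{mean effect})$, so a
  constant feature scores exactly 0.

There is no subclass (within-class) stage: the supported designs have two
classes. The bootstrap is internally run over samples and features in
canonical (sorted-id) order, so scores are invariant to the order in
which columns and rows arrive.

**Activity.** For every species present on both layers,
$$\text{activity}_{fs} = \frac{\mathrm{rel MT}_{fs} + \varepsilon}
                              {\mathrm{rel MG}_{fs} + \varepsilon},$$
computed per sample on relative abundances, with one shared pseudocount
$\varepsilon$ = half the smallest non-zero relative abundance across both
layers, so MG and MT zeros are treated symmetrically. Activity is
computed per sample (not on group-aggregated abundances) because the
downstream Mann–Whitney test of activity and the phenotype correlation
both need per-sample values. Species with MG zeros in more than half the
samples are flagged low-support — their ratios are pseudocount artifacts —
and are never selectable.

**Candidate gate.** A species is reported as a candidate driver when all
of the following hold at level `alpha` (default 0.05):

1. differential on both layers with the *same* enriched group
   (concordance mirrors the fat-enriched overlap logic of the motivating
   study);
2. activity differs between groups (rank-sum test), higher in that group;
3. Spearman correlation of activity with AFP **and** AFW is positive and
   significant.

Spearman was fixed as the correlation statistic (the alternative, Pearson,
is fragile on ratio-scaled data); midranks handle ties, the p-value uses
the t-approximation, switching to exact permutation below n = 10.
Selected species are ranked by descending `rho_AFP`, ties broken by the
smaller activity p-value.

## What the generator emulates — and what it does not

`simulate_paired_omics()` generates the full study: log-normal latent
species abundances (per-species baseline `base_logsd = 1`, per-sample
biological noise `sample_logsd = 0.7` on the natural-log scale), planted
differentials as multiplicative folds (`diff_fold = 4`) on the latent
scale, multinomial count sampling at `depth = 1e5` per sample and layer
(so tables are compositional and contain realistic zeros), and one
planted driver among the five species differential on both layers. The
driver's MT latent carries an extra per-sample activity factor —
log-normal around `driver_activity_fold = 3` in the fat group — and the
host phenotype is coupled to that *latent* activity
(`AFW = 30 + 20 × activity + N(0, 30)` g), not to the observed counts,
which makes correlation recovery a genuine inference problem. With the
default coupling the population Spearman correlation between driver
activity and AFW is ≈ 0.6, the regime the screen is designed for; the
noise scale was fixed once to realize that design point. The driver's
baseline abundance is pinned one baseline standard deviation above the
panel mean: a driver below the sampling depth would conflate detection
with inference failure.

Two deliberate consequences of this construction are worth knowing.
First, species planted as differential on *one* layer only have genuinely
shifted activity ratios (RNA up without DNA up is transcriptional
activation) — they are correct positives for the activity test and are
excluded from candidacy only by the concordance and correlation gates.
Second, because the driver can carry an appreciable share of MT reads in
the fat group, every other species' relative MT abundance — and hence its
activity ratio — is weakly *anti*-correlated with the driver's activity.
This compositional coupling is a property of real data too, and it is why
the positive-correlation gate is directional.

The generator does **not** emulate: sequencing error, taxonomic
misassignment, strain-level variation, batch effects, or overdispersion
beyond the log-normal/multinomial hierarchy. Passing tests therefore
certify the statistical machinery under a clean compositional model, not
robustness to annotation noise.

The metabolome generator plants multiplicative fold changes
(default 4) on features sampled from the quantifiable part of the
intensity distribution (above the 40th percentile of baselines): zeros
are generated by left-censoring at the detection limit (the
`zero_fraction` quantile of all intensities), as in LC–MS, and a feature
pushed below the detection limit is censored rather than recoverable
truth. Per-sample dispersion defaults to 0.15 on the log10 scale (≈ 40%
CV), typical of pooled-extraction untargeted runs; QC injections are
drawn around each feature's grand mean with 5% RSD.

## Validation analytics

**Community ecology.** Chao1 uses the classic estimator
$S_{obs} + F_1^2/(2F_2)$, falling back to the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ when no doubletons exist; ACE follows
the EstimateS convention (rare cutoff 10; when every rare species is a
singleton the sample-coverage estimate degenerates and the bias-corrected
Chao1 is reported instead). Bray–Curtis distances come from vegan; a pair
of all-zero samples has an undefined dissimilarity, which is set to 0
with a log notice. PCoA eigendecomposes the Gower-centred matrix and
discards (but reports) negative eigenvalues. PERMANOVA and ANOSIM
enumerate the label assignments exhaustively whenever there are at most
10,000 of them — the p-value is then exact — and otherwise use Monte-Carlo
permutations with the $(b+1)/(m+1)$ estimator, which never reports zero.
ANOSIM uses midranks under ties. Counts are used as given (no
rarefaction); total-sum scaling is available as a switch in
`bray_curtis()`.

**Stereology.** Adipocytes are modelled as spheres sectioned at the
equator: $d_i = 2\sqrt{A_i/\pi}$,
$\bar V = \tfrac{\pi}{6}(3 s^2 \bar d + \bar d^3)$ with the n−1 sample
standard deviation (computed per individual, not pooled), and
$N = W / (0.915\,\bar V)$ using the literature fat density 0.915 g/mL and
the fixed unit chain µm² → µm³ → mL (10¹² µm³/mL), W in grams. The
volume formula is exact when the diameter distribution has zero third
central moment; the generator's truncated-normal diameters (lower bound
1 µm) keep that property to well under 1% for $s \ll \bar d$. At 100
cells per bird the per-bird cell-number estimate carries ≈ 6% sampling
error; round-trip accuracy is therefore asserted on the panel mean.

**qPCR.** The 2^−ΔΔCt method with group-mean ΔCt (the supported designs
are two-group bulk comparisons, n ≈ 6); per-sample 2^−ΔCt values are
returned for t-testing. Fold changes are invariant to global Ct shifts
and to sample order.

**Metabolomics.** The preprocessing chain is ordered exactly as the
standard platform workflow: ≥ 80% non-zero prevalence over test samples
(boundary inclusive; QC samples are excluded from the denominator because
pooled QCs are always non-zero), minimum-value imputation, per-sample sum
normalization (the platform convention names no method; sum
normalization is the simplest that respects total-signal differences),
QC-RSD ≤ 30% filter (skipped with a notice when no QCs exist), log10.
The processed object carries a `processed` flag and a second application
returns it unchanged — the chain is idempotent at the object level, which
is the property a pipeline needs. VIP scores come from a PLS1-NIPALS
fit against a centred ±1 class vector with the standard VIP formula;
plain PLS-DA is implemented rather than OPLS-DA (the orthogonal
filtering changes score rotation, not the gating behaviour, and PLS-DA
is what the motivating figures actually show) — a deliberate
simplification. The identity $\sum_j \mathrm{VIP}_j^2 = p$ is asserted on
every fit. The DAM gate is `q < 0.05` (BH) **and** `VIP > 1` **and**
fold-change magnitude `max(r, 1/r) > 1`, with the fold change computed on
the raw (de-logged, normalized) scale and direction reported separately;
"FC > 1" is read as a magnitude condition so that up- and down-regulated
metabolites fall under one gate. Note that with many strongly shifted
features, sum normalization induces small opposite shifts in null
features; at stringent `q` this occasionally admits false DAMs — a known
cost of sum normalization, visible in the calibration runs.

**Welch everywhere.** All two-group mean comparisons outside the rank
tests use the unequal-variance t-test: under equal variances it is
indistinguishable from the pooled test, and it is safer when the
variances differ.

## Numerical choices and degenerate inputs

* Exact Mann–Whitney p-values: closed-form distribution when tie-free,
  full enumeration of midrank assignments under ties (auto mode switches
  to exact at n + m ≤ 12); the normal approximation applies midranks, the
  tie correction and a continuity correction.
* PERMANOVA with zero within-group sum of squares reports an infinite
  pseudo-F with a flag rather than failing.
* All-zero samples are rejected by `alpha_diversity()` (an empty sample
  has no diversity) but tolerated by `bray_curtis()`.
* Permutation p-values compare with a 1e−12 slack so exhaustive
  enumeration is immune to floating-point ties.
* One global integer seed is split deterministically per sub-generator
  and per pipeline stage; `run_pipeline()` outputs, including the JSON
  report, are byte-identical under a fixed seed.

## Problem sizes used in the shipped checks

The validation suite and `scripts/acceptance.R` run the screen at the
donor design (30 samples per group, 200 species, depth 10⁵, 50
replicates), the null calibration at 15 per group and 100 species over
200 replicates, the stereology oracle at 10⁶ Monte-Carlo draws, and the
exact-test oracles over every group size with n + m ≤ 12 (rank-sum) and
n = 8 (PERMANOVA/ANOSIM). These sizes were chosen so the whole suite
completes in about a minute on one core while keeping every rate estimate
within tight binomial error.

## Known limitations

* The LEfSe variant is *a* fixed member of the LEfSe family, not a
  re-implementation of any specific release; scores are comparable within
  a run, and the 2.5 gate behaves as intended on planted effects, but
  scores are not numerically interchangeable with other tools.
* The activity ratio is undefined where MG support is absent; such
  species are flagged, not rescued. A species transcribed from a genome
  below MG detection cannot be prioritized by this design.
* The candidate gate is a conjunction of marginal tests; it controls
  false selections well in calibration but is not a joint model — effect
  sizes across gates are not combined.
* Fold changes after sum normalization are relative to total signal;
  absolute concentration changes are out of reach without spike-ins.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_paired_omics(omics_sim_config(seed = 1))
fit <- driver_screen(sim$mg, sim$mt, sim$metadata,
                     config = lefse_config(seed = 1))
print(fit)
summary(fit)
plot(fit)
sim$truth$driver_id   # the planted answer
```
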