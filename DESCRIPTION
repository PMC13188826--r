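Package: cecaldriver
Title: Prioritizing Microbial Drivers of Abdominal Fat Deposition from
    Paired Metagenome and Metatranscriptome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens paired metagenome (DNA) and metatranscriptome (RNA)
    species-abundance tables for microbes driving a host adiposity
    phenotype. Differentially abundant species are detected on each layer
    with a LEfSe-style screen (Mann-Whitney rank-sum test gated by a
    bootstrapped linear-discriminant effect size), the intersection is
    scored for per-sample transcriptional activity (RNA/DNA relative
    abundance ratio), and candidate drivers are selected by concordant
    enrichment, elevated activity, and positive Spearman correlation of
    activity with abdominal fat weight and percentage. Companion tools
    cover the surrounding validation analytics: alpha diversity (Chao1,
    ACE, Shannon), Bray-Curtis ordination with PERMANOVA and ANOSIM
    (exhaustive label enumeration on small designs), adipocyte stereology
    from section areas, villus morphometry comparison, 2^-ddCt qPCR
    relative expression, untargeted-metabolomics preprocessing with PLS-DA
    VIP scoring and FDR/VIP/fold-change gating, Fisher-exact set
    enrichment, and a synthetic-data generator with planted ground truth
    for offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
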