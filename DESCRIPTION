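Package: exomesim
Title: Simulation of Exome-Style Rare-Variant Genotypes and Liability-Threshold Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation engine for complex-disease study designs built on
    exome-style sequence variation. Generates phased founder haplotype panels
    that emulate a rare-variant-dominated minor-allele-frequency spectrum,
    drops haplotypes through multi-generation extended pedigrees with
    recombination, and composes a common dichotomous disease (liability
    threshold, rank-based prevalence) together with three quantitative risk
    factors driven by per-variant additive effect tables, correlated residual
    polygenic and environmental components, covariate effects, and a
    genotype-by-smoking interaction. Includes per-gene identity-by-descent
    matrices from fully informative markers, Haseman-Elston heritability
    recovery, and deterministic replicate management, for evaluating
    statistical-genetic methods on known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
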