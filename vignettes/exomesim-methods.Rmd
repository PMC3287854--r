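---
title: "Simulation model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

exomesim re-creates, with known truth, the kind of data set an exome screen
of a common complex disease would produce: a dichotomous disease of 30%
prevalence, three quantitative risk factors (Q1, Q2, Q4), and called
genotypes for thousands of mostly rare autosomal variants, in two sampling
designs of equal size — 697 unrelated individuals, and 697 individuals in 8
extended four-generation pedigrees whose 202 founders are drawn from the
unrelated panel. This vignette documents the model, its tunable parameters,
the choices made where the design was genuinely open, and what the synthetic
data do and do not emulate.

## Trait model

Each quantitative trait is a sum of independent components on a common
*residual scale*: for every trait the residual (polygenic + environmental)
variance is 1, split as $h^2$ polygenic and $1 - h^2$ environmental. Variant
effects and covariate effects are displacements on this scale. The packaged
effect tables give, per functional variant, its gene, its `C#S#` marker
label, its reference minor allele frequency, and $\beta$, the shift in trait
mean per copy of the minor allele; all $\beta > 0$ (the minor allele always
raises the trait), and all effects are additive in dosage.

* **Q1** — 39 variants in 9 genes (effect table `Q1`), residual
  $h^2 = 0.44$; increases with age and smoking. Effects of the *KDR*
  variants are multiplied by 1.5 in smokers (the table betas are the
  non-smoker effects); this is the only genotype-by-environment term.
* **Q2** — 72 variants in 13 genes, residual $h^2 = 0.29$; no covariate
  effects.
* **Q4** — no effects from the sequenced variants at all; $h^2 = 0.70$
  from background polygenes; lower in smokers and in females, decreases
  with age. Q4 is protective.
* **Latent liability** — 51 variants in 15 genes (table `LIABILITY`);
  higher in smokers, increases with age; withheld from distributed
  phenotype files unless `emit_latent = TRUE`.

The liability score is

$$\text{liability} = \text{latent} + Q1 + Q2 - Q4,$$

and in every replicate the top `round(0.30 * N)` individuals by liability
(209 of 697) are declared affected. The threshold is empirical per
replicate — a rank rule, not a fixed cutoff — so every replicate has exactly
the same number of affected individuals while their identities vary. Ties
(possible only in degenerate noise-free configurations) are broken by stable
individual order. The raw trait values, not standardized versions, enter the
liability sum.

The residual polygenic deviations of (Q1, Q2, latent) are drawn from a
multivariate normal with cross-trait covariance
$D\,\rho_g\,D,\; D = \mathrm{diag}(\sqrt{h^2})$, and between-individual
covariance $2\Phi$ (the kinship matrix doubled; the identity for
unrelateds). Environmental deviations are independent across individuals
with cross-trait covariance built the same way from $\rho_e$. Q4's genetic
deviation shares the $2\Phi$ structure but is uncorrelated with the other
traits.

**Defaults chosen here, not published.** The source material states
directions but not magnitudes for several quantities; the package fixes
defaults once and exposes them in `default_config()`:

* covariate effects: Q1 age $+0.01$/yr, Q1 smoking $+0.3$; Q4 age
  $-0.01$/yr, Q4 female $-0.5$, Q4 smoking $-0.3$; latent age $+0.01$/yr,
  latent smoking $+0.3$ (signs as stated, magnitudes invented);
* cross-trait correlations: $\rho_g$ off-diagonals 0.5 ("correlated"),
  $\rho_e$ off-diagonals 0.2 ("weakly correlated");
* latent residual heritability 0.35. The latent trait's residual genetic
  component is described as correlated with those of Q1 and Q2, which
  requires nonzero polygenic variance, but no value is given; 0.35 is a
  middle-ground choice and purely conventional.
* ages: normal with SD 15 years truncated to [16, 91], centre solved so the
  truncated mean is 41.8; rounded to whole years; within each family,
  sampled ages are reassigned so earlier generations are older. Ages and
  sexes are fixed across replicates.
* smoking: Bernoulli(0.25) per individual, redrawn each replicate
  (`resample_smoking = FALSE` freezes it); only genotype, age, sex and
  pedigree structure are required to be constant across replicates.

## Genotypes

The functional variants are placed on the chromosome encoded in their label
at positions preserving their S-index order, and founder panels place
`round(2n * maf)` minor-allele copies on random distinct haplotypes, so the
effect-model MAFs hold by construction (a variant listed at MAF 0.000717 is
a single copy among 697 diploids — 0.07%). Background markers take
independent per-haplotype Bernoulli draws at target MAFs sampled from a
binned spectrum.

The default spectrum is dominated by rare variation, as permissive variant
calling produces: 38.4% private variants (exactly one copy), 74% of
variants at MAF $\le$ 0.01, 12.8% at MAF $\ge$ 0.05, median MAF near 0.002
(three copies in 697 diploids). The generator reproduces the *reported*
spectrum, not the calling-artifact process that produced it. The default
map scale is 24,487 markers in 3,205 genes across the 22 autosomes
(NCBI36-style coordinates); genes per chromosome are proportional to
chromosome length and SNPs-per-gene follow a truncated negative binomial
targeting mean 7.64, SD 14, maximum 231 — only these aggregates are
targeted, the true gene-size distribution being unpublished. Marker labels
`C#S#` encode the marker's rank on its chromosome; after functional
injection the published functional labels take priority, so the
rank-equals-index rule is guaranteed for the auto-named background markers
only. Linkage disequilibrium between background markers is not modeled
(functional variants are described as nearly equilibrium apart from shared
private carriers).

## Pedigrees, gene dropping, IBD

`generate_pedigree_set()` builds non-inbred families from a single founding
couple, with married-in spouses (who count as founders) in the middle
generations and an unmarried last generation; sibship sizes are balanced
deterministically to hit the requested totals exactly. The default design —
8 families, 697 members, 202 founders, 4 generations, containing
second-cousin pairs — matches the aggregate structure of the original
family sample; the true pedigree shapes are not public. Pedigree founders
are drawn from the unrelated panel without replacement, which restricts
familial diversity exactly as subsetting should: panel-polymorphic markers
can be monomorphic in the families, and a rare founder allele can be
amplified to dozens of copies by a prolific lineage.

Gene dropping transmits each parent's haplotypes with **exactly one
obligate crossover per chromosome per meiosis**: a grandparental starting
phase is drawn, then switched at a position uniform over the chromosome's
bp extent — no interference, no sex-specific map (none is published), and
the whole chromosome (not the arm) is assumed to be the crossover unit. No
mutation is introduced, so Mendelian consistency and allele conservation
hold by construction.

Per-gene IBD matrices use *fully informative markers*: every founder
haplotype carries a unique label, and each individual's two labels at a
gene are read from the inheritance vectors at the gene's bp midpoint
(recombination is not allowed within genes — gene-atomic inheritance). The
sharing proportion $\hat\pi_{ij}$ is the number of label matches divided by
2, giving values in $\{0, 0.5, 1\}$, exactly 0.5 for parent-offspring, 0
for founder pairs, and $E[\hat\pi] = 2\Phi$. If a crossover falls inside a
gene's span the genotype drop still recombines marker by marker while the
IBD label follows the midpoint; the discrepancy window is at most one gene
span. The pipeline writes IBD matrices for the functional genes by default;
any gene set can be requested.

## Parameter recovery

`he_recovery()` closes the loop: Haseman-Elston regression of pairwise
trait cross-products on $2\Phi$ over related pairs recovers the configured
heritabilities from freshly simulated family data. Fixed effects are
removed first (Q4: age/sex/smoking; Q1: its SNP genetic values including
the interaction, plus covariates; Q2: its SNP genetic values), since the
quoted heritabilities are fractions of *residual* variance.
Haseman-Elston was chosen over REML for transparency and zero external
dependencies; pairs with $\Phi = 0$ are excluded as uninformative. Plain
HE on deep pedigrees has a small finite-sample downward bias (global
demeaning with correlated data), on the order of 0.02–0.03 here — visible
in the recovered means but within the 0.05 agreement the tests demand.
`gxe_recovery()` fits `Q1 ~ dosage * smoker` on a large unrelated cohort
carrying the common *KDR* variant (MAF 0.165) and reports the interaction
to main-effect ratio, which estimates the multiplier minus one; at 50,000
individuals the uplift's Monte-Carlo standard error is around 0.14, so
single-seed estimates scatter widely around 0.5 — the recovery check is
calibrated in standard errors, not absolute points.

## Numerical choices

* Affected count: `round(prevalence * N)` (no rounding rule was stated).
* $2\Phi$ Cholesky factors get a $10^{-9}$ diagonal jitter;
  correlation-matrix square roots are eigendecomposition-based so zero
  heritabilities (positive semidefinite, singular) are legal.
* Haseman-Elston slopes are clamped to [0, 1] after estimation.
* Replicate substreams come from a 32-bit FNV-1a hash of
  (master seed, stage label, index), so any replicate is reproducible in
  isolation and streams do not overlap by construction; all seeds stay
  below $2^{31}$.
* Age centring uses the sample mean, making covariate effects mean-zero in
  every data set.

## Problem sizes in the test-suite

The shipped tests run the full-size designs where the quantity under test
demands it (697-member pedigree, 100-replicate heritability recovery,
50,000-individual interaction regression, 200-replicate smoking check) and
reduced maps (the 160 functional markers, or a few hundred background
markers) elsewhere; spectrum and IBD expectations average over 20 and 500
seeds respectively. These sizes were chosen so each check's Monte-Carlo
error sits well inside the tolerance it asserts.

## Limitations

* Population structure of the source panels is deliberately not emulated
  (it was unused in the original phenotype simulations); the panel is
  panmictic.
* Background LD, genotype-calling artifacts, and the founder-genotype
  merging corruption present in the original distributed files are not
  reproduced.
* Real per-SNP MAFs and counts tied to the original sequence data (24,487
  called SNPs, 9,433 private, 10,703 monomorphic-in-families) are generator
  *targets*, not reproducible facts; only their qualitative analogues are
  asserted.
* Variant-calling from alignments, imputation and phasing are out of scope:
  genotype input is either synthesized or supplied phased.
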