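---
title: "Rhizobiome traits as quantitative phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhizobiome traits as quantitative phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrait)
```

# The scientific setting

Rhizosphere microbial communities are shaped in part by the host plant.
When a diverse panel of crop genotypes is grown in a common field, the
abundance of individual microbial groups around the roots can be treated as
a *quantitative trait of the plant*: it has a heritable component, it can
covary with plant fitness, and the plant loci that influence it can be
mapped. `rhizotrait` implements that whole chain of analysis for a maize
diversity panel grown under contrasting nitrogen treatments (fertilised
"+N" vs unfertilised "-N"), together with a synthetic-data generator that
reproduces the study's structure with known ground truth so that every
estimator in the chain is testable by parameter recovery.

The pipeline stages, each exported as ordinary functions returning tibbles:

1. **Trait construction** — filter a curated ASV count table, cluster ASVs
   into microbial groups ("rhizobiome traits"), transform to natural-log
   relative abundance, and classify each group's nitrogen response.
2. **Community analysis** — Bray-Curtis / weighted UniFrac dissimilarities,
   PCoA, constrained ordination over the field design, and PERMANOVA.
3. **Heritability** — single-random-term REML, the repeatability-style
   statistic `h2 = Vg / (Vg + Ve/n)`, and a genotype-label permutation null.
4. **BLUPs** — the four-random-term field model
   `y ~ (1|genotype) + (1|block) + (1|sp) + (1|spb)` per treatment.
5. **Selection** — relative fitness from canopy coverage, a GAM-smoothed
   fitness function per trait, average-derivative linear and quadratic
   selection differentials, and a genotype-resampling bootstrap.
6. **Genetic architecture** — LD pruning and a BayesS spike-slab Gibbs
   sampler in which SNP effect variance scales as `(2p(1-p))^S`.
7. **GWAS and MAPLs** — EMMAX/P3D mixed-model association with kinship and
   principal components, effective-SNP Bonferroni thresholds, fixed 10-kb
   hotspot windows (microbe-associated plant loci), gene containment, and
   allele-stratified comparisons.
8. **Integration** — microbe-phenotype correlations with a permutation null
   on the count of significant groups, an expression set test, and the
   per-group summary ledger.

# Models and their assumptions

## Rhizobiome traits

A trait value is `ln((group count + pseudocount) / total sample count)`.
The pseudocount (default 1) is added to the *group* count rather than per
ASV, so the plain formula is preserved whenever the group is observed; a
zero group yields `ln(1/T)`. ASV filtering demands both a minimum mean
relative abundance (default `1e-4`) and a minimum prevalence (default 10%)
within *every* level of a grouping column (default `year`), so only taxa
reproducible across years survive. Those two defaults are configuration
values, not biology: the appropriate cutoffs depend on sequencing depth and
panel size.

Clustering uses taxonomy (genus first, family fallback with an
`"f_<Family> Unknown Genus"` label) plus a response-splitting rule: a taxon
whose member ASVs respond to nitrogen with significantly *opposite* signs
is split into numbered subgroups. This approximates, but is not identical
to, clustering on 16S sequence similarity; outputs label the grouping as
taxonomy-derived so downstream users are not misled.

## Heritability

The estimator is the repeatability-style line-mean heritability
`h2 = Vg / (Vg + Ve/n)` with `n = 6` samples per genotype-treatment (two
replicate plots times three samples). `Vg` and `Ve` come from REML for the
one-way random-intercept model with genotype as the only random term. The
likelihood is profiled analytically down to one dimension (the ratio
`lambda = Vg/Ve`), which makes a single fit cheap enough that the
permutation null — shuffle genotype labels, refit, repeat `B` times,
`p = (#{h2_perm >= h2_obs} + 1)/(B + 1)` — is practical at `B = 1000` for
hundreds of traits. Variance components are constrained to the boundary
(`>= 0`); the fit is validated in the test suite against `lme4` on
unbalanced data and against the closed-form ANOVA estimator on balanced
data, where the two coincide.

Design terms (block, split plot, split-plot block) are deliberately *not*
in the heritability model: the statistic's definition leaves no slot for
them, and they are available through `extra_random` for sensitivity
analysis. Note the structural caveat: any variance carried by plot-level
design effects is partially confounded with genotype (a genotype's six
samples share two plots), so adding real plot variance biases the
single-term estimator upward. This is a property of the design, not of the
implementation, and it is the reason the synthetic generator defaults those
variances to zero (below).

## Selection differentials

Relative fitness is `w = CC / mean(CC)` from genotype-level canopy
coverage, so `mean(w) = 1` exactly and the differentials are on the
Lande-Arnold scale. For each trait (univariately, per treatment) the
fitness function `w(z)` over standardized BLUPs `z` is fitted as a
penalized cubic regression spline with GCV-chosen smoothness; because the
linear part is unpenalized, exactly linear data is reproduced exactly. The
linear and quadratic differentials are *average derivatives* over the
observed `z`: `s = mean w'(z_i)`, `c = mean w''(z_i)` (central finite
differences of the smooth; exact for polynomial surfaces). The quadratic
differential is reported as the raw mean second derivative — no additional
factor of 2 or 1/2 — and that convention is recorded here because published
quadratic-differential conventions differ. Significance is a
genotype-resampling bootstrap with the two-sided sign-crossing p-value
`p = 2 min(frac(s_b <= 0), frac(s_b >= 0))` under the `+1/(B+1)`
correction, so `p` can never be exactly zero.

## BayesS genetic architecture

The spike-slab regression `y = mu + X beta + e` sets `beta_j = 0` with
probability `1 - pi` and otherwise `beta_j ~ N(0, sigma2_b (2 p_j q_j)^S)`.
`S` couples effect size to minor allele frequency: `S < 0` (larger effects
at rarer alleles) is the signature of purifying selection, `S > 0` of
positive selection, and a 95% credible interval containing 0 is classified
neutral. The Gibbs sampler (compiled code, single-threaded, R's RNG, hence
bit-reproducible under a seed) uses residual-update spike-slab draws per
SNP, conjugate updates for `pi` (Beta) and the variances
(scaled-inverse-chi-squared), and random-walk Metropolis for `S` with step
size adapted to a 20-40% acceptance rate during burn-in and frozen
afterwards.

Priors: `pi ~ Beta(1, n_snp/100)`; `S ~ N(0,1)` truncated to `[-5, 5]`;
variance scales set from the data — the residual scale at half the trait
variance, and the effect-variance scale at the other half spread over the
prior-expected number of non-zero SNPs at the panel's mean heterozygosity.
That last choice matters: a grossly mis-scaled `sigma2_b` prior drags `S`
along the ridge `log sigma2_b + S E[log 2pq] ~ const` and biases it; the
data-adaptive scale keeps the null centred (verified by the null-coverage
acceptance check). Identification of `S` comes entirely from the spread of
`log 2pq` among non-zero SNPs, so panels whose MAF distribution is
compressed (all-common SNPs) cannot estimate it well; the architecture
simulations therefore use an SFS-like log-uniform MAF distribution, and `S`
is intrinsically easier to detect when negative (rare alleles with large
effects are conspicuous) than when positive.

The desk-scale default chain is 25,000 iterations with 5,000 burn-in;
full-scale analyses (the published analyses used chains of 410,000 with
10,000 burn-in) are a configuration change, not a code change.

## Mixed-model GWAS and MAPLs

Association uses genotype BLUPs as the response under
`y = X0 alpha + x beta + u + e` with `u ~ N(0, sigma2_g K)`, `K` the
centred (VanRaden) kinship and `X0` an intercept plus the top three
genotype principal components. The kinship is eigendecomposed once; the
default P3D/EMMAX approximation estimates the variance ratio
`delta = sigma2_e/sigma2_g` once under the null and applies generalized
least-squares Wald tests per SNP; `mode = "exact"` re-optimises `delta` per
SNP and is used in tests to bound the approximation (the two agree within
0.2 `-log10(p)` units for ≥99% of SNPs in the calibration simulations).
Genomic-control lambda is reported with every scan.

Multiple testing uses `-log10(alpha / Meff)` with `Meff` either the Li-Ji
eigenvalue estimator (blockwise per chromosome) or a user-supplied
panel-wide value; with the published maize panel value of 769,690
independent markers and `alpha = 0.05` the threshold is 7.19 (7.2 at one
decimal).

MAPL hotspots are fixed, non-overlapping 10-kb windows anchored at
position zero of each chromosome — the anchoring is a convention choice;
windows are *not* merged when adjacent. Every significant SNP-trait
association contributes one signal (the same SNP significant for two traits
counts twice), `min_signals = 1` gives the full region list and
`min_signals = 2` the stricter hotspot subset. Gene annotation attaches
only genes *completely contained* within ±10 kb of a window; partial
overlaps are excluded deliberately.

## Integration

Microbe-phenotype correlations are computed between genotype-level BLUPs
and genotype-level plant-trait values, per treatment — correlating at the
sample level would inflate the effective n. The "more groups than chance"
statement is quantified by permuting the plant trait's genotype labels
within treatment and counting significant groups per permutation.
Expression set comparisons use Mann-Whitney U on log2 expression (gene
expression is heavy-tailed; the rank test does not assume a scale), with
the effect reported as the difference in mean log2 expression.

# What the synthetic generator emulates — and what it does not

`simulate_design()` reproduces the split-plot structure: each genotype once
per replicate quadrant per treatment, three samples per plot, incomplete
blocks of 30 genotypes, two quadrants per treatment (defaults mirror the
field layout: roughly 200-230 genotypes, 2 treatments, n = 6 samples per
genotype-treatment). `simulate_genotypes()` builds SNP panels with block
LD through a first-order haplotype-copying chain. `simulate_group_traits()`
generates a latent log-abundance per group —
`y = mu + treatment + g(genotype) + block + sp + spb + e` with `g` a sum
over causal SNPs whose effect variances follow the BayesS law — and then
realises counts as negative binomial draws around `depth * softmax(y)`,
split multinomially over member ASVs. `simulate_fitness()` produces canopy
coverage on the mean-one relative-fitness scale so the generating `s` and
`c` *are* the true differentials.

Choices that matter for interpreting test results:

* **Heritability targets.** The genotype variance is scaled so that
  `Vg / (Vg + Vng/n)` hits the target, with `Vng` the total non-genetic
  sample-level variance. Design-term variances default to **zero**: with
  non-zero plot-level variance, a genotype's samples are correlated through
  their two shared plots, the single-term estimator absorbs that
  correlation into `Vg`, and genotype-label exchangeability — the premise
  of the permutation null — fails even for traits with no genetic signal.
  Setting the defaults to zero makes "no signal" mean exactly that; raising
  `v_design` is the supported way to study the confounding itself.
* **Compositional leakage.** Because counts are compositional (softmax
  denominator shared across groups), heritable groups leak a small genuine
  genotype signal into nominally-null groups. Null calibration experiments
  therefore set *every* group's target to zero.
* **Count noise.** The negative-binomial/multinomial layer adds
  measurement variance on the log scale that the latent targets do not
  include; at the default depth (30,000) and overdispersion (size 25) this
  biases recovered h2 downward by well under the acceptance tolerance, and
  it is the realistic direction of bias for amplicon data.
* **Not emulated:** spatial field autocorrelation, multi-year environments
  (a single year is generated), chimeras/contamination, taxonomy errors,
  and any microbiome interaction structure beyond compositionality. Passing
  recovery tests on this generator therefore demonstrates estimator
  correctness under the study design, not robustness to every property of
  real surveys.

# Numerical choices

* REML: 1-D profiled criterion optimised over `log lambda` on `[-25, 25]`
  with an explicit boundary comparison at `Vg = 0`; constant responses
  return `(0, 0)` by convention.
* PERMANOVA p-values use `(#{F >= F_obs} + 1)/(B + 1)`; an exact mode
  enumerates all label permutations for small n (used by the test oracles).
  PCoA reports negative eigenvalues without Cailliez/Lingoes correction.
* Finite-difference step for fitness-function derivatives:
  `1e-3 * max(sd(z), 1)` — central differences are exact for the quadratic
  surfaces the differentials summarise, and the step is far above the
  prediction roundoff floor.
* The S sampler's proposal step adapts only during burn-in (valid adaptive
  MCMC); chains are bit-reproducible for a fixed seed because all draws
  come from R's RNG stream, single-threaded.
* LD pruning removes the lower-MAF member of an offending pair, breaking
  ties toward the larger position, exactly as stated in the function
  contract — so pruned panels are reproducible.
* Missing dosages: kinship, GWAS and BayesS mean-impute per site (standard
  GWAS practice); readers preserve missingness otherwise, and the
  orientation of the minor allele is recorded per SNP at load time so
  major/minor stratification is stable.

# Problem sizes used in the validation suite

The bundled acceptance analyses run at sizes a workstation handles in
minutes, chosen to keep Monte-Carlo error comfortably inside each
tolerance: heritability recovery uses 200 genotypes x 51 traits (plus 500
all-null traits at B = 199 permutations for calibration); selection
recovery uses 230 genotypes x 50 replicate simulations at B = 199
bootstraps; the architecture study uses 500 individuals x 2,000 SNPs with
20,000-iteration chains (10 null, 5 per sign); GWAS calibration uses 250
individuals x 1,500-2,000 SNPs with 20 planted-causal replicates. The same
estimators accept full-scale inputs unchanged.

# Known limitations

* The taxonomy-plus-response clustering is an approximation to
  sequence-similarity clustering; groups are labelled accordingly.
* The quadratic-differential convention (raw mean second derivative) is
  one of several in the literature; compare magnitudes across studies with
  care.
* `S` estimation is asymmetric in power (purifying architectures are
  easier to detect than positive ones) and requires MAF spread; neutral
  classifications on compressed panels are weak evidence.
* The permutation heritability test inherits the design confounding
  discussed above when real plot variance exists; in field data the
  reported h2 should be read as repeatability under that design.
* P3D underestimates significance slightly for very large single-SNP
  effects; `mode = "exact"` exists for final candidate loci.
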