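---
title: "Cross-trait pleiotropy from GWAS summary statistics: methods and design"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait pleiotropy from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The problem

Two complex traits can share causal variants even when neither GWAS is
powered to detect those variants on its own. `pleioscan` implements a
summary-statistics pipeline for quantifying that overlap between a primary
trait and a panel of comparison traits: conditional Q-Q and fold-enrichment
stratification to visualize enrichment, conditional/conjunctional FDR to
call shared loci, a method-of-moments genetic correlation, and a two-sample
Mendelian randomization (MR) battery to probe causal direction. Everything
operates on per-SNP association summaries (effect, SE, p, N) plus a
reference genotype panel for LD; no individual-level data are required.

## Data model and harmonization

`SummaryStats` holds validated records sorted by (chrom, pos) with a
reason-coded log of every dropped row, so record counts always balance
(input = output + logged drops). Coordinates are 1-based GRCh37 and region
filters use closed intervals; the default `excludeRegion()` call removes
the MHC (chr6:24,000,000–35,000,000), whose LD structure breaks both the
moment estimators and FDR locus calling.

Harmonization aligns the second study's records to the first's effect
allele: swapped allele labels negate the effect, strand complements are
relabelled, and palindromic A/T and C/G SNPs — where swap and strand flip
are indistinguishable — are dropped by default. A `maf_infer` mode keeps a
palindromic SNP when both studies report an informative allele frequency
(MAF < 0.42 on both sides, orientations matched by frequency agreement).
Harmonization is idempotent and preserves |z| for every retained SNP.
Other per-record policies, chosen once and logged: p = 0 is clamped to the
smallest positive double; duplicate SNP ids keep the smallest-SE record;
z is reconciled from beta/se when available, with disagreements beyond
|Δz| = 0.1 flagged and the beta-derived value winning.

## Genomic control and LD pruning

Inflation from stratification or over-counting is estimated from SNPs
declared intergenic by the caller-supplied annotation, treated as an
empirical null: `lambda = median(z²)/qchisq(0.5, 1)`, applied as
`z → z/sqrt(lambda)` with p recomputed (beta and SE are left on their
original scale and flagged). Each GWAS is corrected with its own lambda.
At least 100 intergenic SNPs are required; the estimator is
order-invariant and uses only flagged SNPs.

Pruning follows the plink-clump convention: visit SNPs by ascending
p-value (ties broken by position), keep the visited SNP, remove unkept
SNPs within 250 kb at panel r² > 0.2. The post-condition — no retained
pair within the window above the threshold — is verified exhaustively in
the tests. SNPs absent from the panel pass through (conservative) and are
reported. For a trait pair the workflow prunes once, seeded by the primary
trait's p-values; this keeps one shared pruned set for both conditional
directions and makes the bundle deterministic.

## Enrichment stratification

For conditioning thresholds c ∈ {0, 1, 2, 3} on −log₁₀(p₂), the
conditional Q-Q curve pairs the observed −log₁₀(p₁) order statistics of
the stratum {−log₁₀(p₂) > c} with −log₁₀(i/(n+1)); fold enrichment uses
inclusive strata ({−log₁₀(p₂) ≥ c}, so the baseline stratum is all SNPs
and its curve is identically 1) and reports the ratio of stratum to
overall tail fractions at each grid point, NA where the overall tail is
empty. The two conventions (strict for Q-Q, inclusive for fold
enrichment) follow the standard presentation of these displays. The x
grid defaults to 200 even points up to the largest observed −log₁₀(p₁).
Enrichment is computed on the pruned set by default; a single pruning
pass is used (an iteration hook would average over random prunings, which
we deliberately leave out of scope).

## Conditional and conjunctional FDR

The conditional FDR of SNP i for trait 1 given trait 2 is the conservative
empirical-Bayes quantity

```
cfdr(i) = p1_i * #{j : p2_j <= p2_i} / #{j : p1_j <= p1_i and p2_j <= p2_i}
```

i.e. p₁ divided by the empirical conditional cdf of p₁ given P₂ ≤ p₂, with
the null proportion π₀ fixed at 1. It is computed exactly for all n via a
Fenwick-tree dominance count (`O(n log n)`, C++); a 101×101 bilinear grid
approximation is available for panels beyond ~10⁶ SNPs. cfdr ≥ p₁ always,
values are clipped to (0, 1], and a lookup form supports assign-back
scoring of unpruned SNPs against the pruned set's cdfs. The conjunctional
FDR is the maximum of the two conditional directions. No isotonic
post-processing is applied (monotonicity in p₂ is not enforced).

Loci are called from SNPs with FDR strictly below 0.01 — the threshold at
which one hundred reported associations carry one expected false positive —
by single linkage under (distance ≤ 250 kb) OR (panel r² > 0.6), with the
lowest-FDR member as index SNP (ties: smaller p₁, then position). This
replaces web-service locus definition with a local, reproducible rule.

### What calibration does and does not mean under LD

The cFDR tests the *association* null. In LD-aware simulations a SNP that
tags a shared causal variant is genuinely associated with both traits even
though its own causal effects are zero, so judging discoveries by
causal-status labels mixes two different nulls: under the default
simulation LD (AR(1), ρ = 0.8) the causal-level false discovery
proportion at conjFDR < 0.01 is dominated by such truly-associated tags.
The calibration test therefore runs the generator's independence
configuration (ρ = 0), where causal status and association coincide; there
the π₀ = 1 estimator is near-nominal (mean FDP ≈ 0.011 at the 0.01
threshold over 20 seeds of m = 50,000). Passing that test says the
estimator controls the FDR of its own null hypothesis — not that every
reported SNP in real LD'd data is itself causal; index SNPs should always
be read as locus representatives.

## Genetic correlation

The estimators are single-annotation method-of-moments:

```
h2    = m (mean(z^2) - 1) / (n * mean(l))
rho_g = m  mean(z1 z2)    / (sqrt(n1 n2) * mean(l))
r_g   = rho_g / sqrt(h2_1 h2_2)
```

where `l` are LD scores (windowed sums of r², 1 Mb default, self term
included). The −1 in the h² moment is the null expectation of z²; the
cross moment has no such offset under the assumed absence of sample
overlap between the two studies (overlap correction is out of scope and
documented as a limitation). Panel r² is biased upward by roughly
(1 − r²)/(n_ref − 2) at finite panel size, so LD scores apply the standard
small-sample adjustment; without it, heritability at n_ref ≈ 200 would be
attenuated by ~30%. Uncertainty comes from a delete-one jackknife over 100
contiguous position-ordered SNP blocks applied to the full r_g pipeline;
r_g is clipped to [−1, 1] with the raw value retained, and nonpositive h²
flags the result rather than silently truncating. In simulations the
jackknife SE tracks the between-seed spread of the estimate
(0.05 vs 0.04–0.07 at m = 20,000).

## Mendelian randomization

Instruments are genome-wide-significant exposure SNPs (p < 5×10⁻⁸),
clumped greedily at r² < 0.001 within 10 Mb; when at most one independent
locus survives, selection reruns at the relaxed 10⁻⁶ threshold and records
the switch — the standard fallback for underpowered exposures. Zero
candidates yield an explicit "no instruments" result, never an exception.

Per instrument the Wald ratio β_y/β_x, its first-order SE (se_y/|β_x|) and
F = (β_x/se_x)² are computed after delegating allele alignment to the same
harmonization code used genome-wide. The estimators:

- **IVW (random effects)**: inverse-ratio-SE²-weighted mean; the
  fixed-effect SE is inflated by max(1, √(Q/(k−1))) — multiplicative
  overdispersion with a floor at no underdispersion, the default of the
  established two-sample MR tooling. k = 1 degrades to the Wald ratio.
- **MR-Egger** (k ≥ 3): weighted regression with intercept after orienting
  β_x ≥ 0; slope is the causal estimate, the intercept tests directional
  pleiotropy; inference uses t with k − 2 df and a residual-SD floor of 1.
- **Cochran's Q**, **leave-one-out**, **F statistics** as standard
  reporting companions; Q inside IVW and standalone are the same quantity.
- **PRESSO-style outliers** (k ≥ 4): observed RSS against a parametric
  bootstrap under no pleiotropy, per-SNP empirical p Bonferroni-adjusted
  over k, worst-first step-wise removal (never below 4 instruments) with
  IVW re-estimation. The distortion test of the original procedure is not
  reproduced.

Power for a binary outcome uses the linear-approximation noncentrality
`NCP = n · r²_xz · K(1−K) · log(OR)²` with a chi-square(1) two-sided test,
so power equals α exactly at OR = 1 and is monotone in n and r²_xz. A
Monte-Carlo two-sample MR simulation in the test suite confirms the
formula's rejection rates. (An algebraically distinct form that cancels
the K(1−K) factor circulates; it contradicts the case-fraction dependence
of the score-test SE, so the form above is used and verified by
simulation.)

## The synthetic-data generator

`simConfig()` fixes the generative model; its defaults are the study
conditions used throughout the tests and were chosen once:

| parameter | default | rationale |
|---|---|---|
| mSnps / nBlocks | 10,000 / 50 | desk-scale panels; blocks of 200 SNPs at 1 kb spacing |
| ar1Rho | 0.8 | adjacent r² ≈ 0.64, decaying past 0.2 within ~3 SNPs — a compact stand-in for European-panel local LD |
| n1, n2 | 50,000 | the scale of contemporary psychiatric GWAS |
| pi10, pi01, pi11 | 0.004 / 0.004 / 0.002 | ~1% causal SNPs overall, modest shared fraction |
| h2 | 0.3 per trait | common-variant heritability typical of psychiatric traits |
| rhoShared | 0.5 | moderate effect correlation within the shared component |
| lambdaInflation | 1 | no confounding unless requested |
| intergenicFraction | 0.5 | labels assigned to causal-free SNPs first |

Summary statistics follow the standard multivariate-normal model per LD
block: `z = sqrt(n) R beta + e`, `e ~ N(0, R)`, with R the block AR(1)
correlation (computed by O(m) forward/backward recursions, no Cholesky),
noise independent between traits, and optional multiplicative variance
inflation — exactly what genomic control corrects. Genotypes are
standardized Gaussian rather than binomial: r² is then exact at the
population level and the panel is cheap; allele-frequency-dependent
effects are deliberately not modelled. Effects scale by the realized
causal count so the expected summed squared effect equals the h² target,
and the implied genetic correlation
`rhoShared · pi11 / sqrt((pi10+pi11)(pi01+pi11))` is attached to the
output. Inter-block gaps of 1 Mb make blocks independent loci for
pruning and clumping tests. Allele codings can be perturbed (palindromic,
strand-flipped, swapped fractions) to exercise harmonization.

What the generator does **not** emulate: allele-frequency spectra and
frequency-dependent architecture, population stratification, sample
overlap between studies, sex chromosomes, and realistic LD beyond AR(1)
blocks. Passing tests on this generator therefore validates estimator
logic and calibration under the stated model, not robustness to every
feature of real cohorts.

## Problem sizes and numerical choices

The test suite runs the calibration studies at m = 50,000 (FDR
calibration, genomic control) and m = 20,000 (genetic correlation, 20
seeds per setting), with reference panels of 150–200 individuals; MR
studies use k = 15–50 instruments, 200 datasets for the size check, and
400–1000 bootstrap replicates for PRESSO. These sizes put Monte-Carlo
error well below the tested tolerances while keeping a full run in
minutes. All randomness flows through explicit seeds; the workflow
derives per-stage streams from one master seed, and rerunning a
configuration reproduces its artifact bundle byte for byte.

Degenerate inputs are handled explicitly rather than by crashing:
empty enrichment strata are omitted with a warning, zero-denominator
fold-enrichment points are NA, nonpositive h² flags the correlation
result (rho_g still reported), β_x = 0 instruments are dropped with a
reason, and k below each MR method's minimum raises an informative error
(or, for selection, returns an explicit empty result).

## Known limitations

- No sample-overlap correction in the genetic covariance (the no-overlap
  moment form is implemented; overlapping cohorts bias rho_g).
- π₀ = 1 makes the cFDR conservative for highly polygenic conditioning
  traits; no isotonic smoothing is applied.
- Locus definition is a local distance/LD rule, not a functional
  annotation pipeline; "closest gene" is a passthrough column when an
  annotation is supplied, never computed.
- Single-pass pruning; no averaging over random pruning iterations.
- MR power is a reporting utility based on a linear approximation; it is
  not an acceptance-grade quantity because its inputs (r²_xz, K) are
  study-specific.
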