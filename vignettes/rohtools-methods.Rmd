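---
title: "Homozygosity, inbreeding and SNP heritability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity, inbreeding and SNP heritability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohtools)
```

`rohtools` analyses case-control SNP genotypes for signatures of
recessive disease architecture: runs of homozygosity (ROH), genomic
inbreeding, and the share of phenotypic variance tagged by common
SNPs. This vignette explains each model, the tunable parameters and
their defaults, the synthetic-data generator that the test suite runs
against, and the numerical and design choices that were genuinely
open.

## Data model

A `GenotypeDataset` wraps a `RangedSummarizedExperiment`: one integer
assay of allele-B dosages (0/1/2, `NA` for missing) over biallelic
autosomal SNPs (chromosomes 1–22, 1-based positions, sorted), with
0/1 phenotypes in `colData`. Dosage `x`, in-sample allele frequency
`p` and `q = 1 - p` are the primitives of every formula below.
Samples with missing phenotype are carried through I/O but excluded
from all case-control statistics. Coordinates are 1-based and
intervals inclusive at both ends, so a segment's length in kb is
`(end - start + 1)/1000`.

## ROH detection

The caller reproduces the PLINK 1 sliding-window logic. Per
individual and chromosome:

1. every window of `windowSnp` consecutive SNPs is scored
   *homozygous* if it holds at most `windowHet` heterozygous and
   `windowMissing` missing calls;
2. each SNP receives the fraction of its overlapping windows that are
   homozygous and is *eligible* when the fraction exceeds
   `windowThreshold`;
3. maximal runs of consecutive eligible SNPs become candidates; a
   heterozygous call always terminates a run (missing calls do not),
   and runs split where adjacent SNPs are more than `maxGapKb` apart;
4. candidates pass if they hold ≥ `minSnp` SNPs, span ≥ `minKb` kb
   and are no sparser than `minDensityKbPerSnp`.

Defaults are PLINK 1.07's documented defaults (`windowSnp = 50`,
`windowMissing = 5`, `windowThreshold = 0.05`, `minKb = 1000`,
density 50 kb/SNP, gap 1000 kb) with two pipeline-specific settings:
`windowHet = 0`, so that no heterozygous call is tolerated anywhere in
a scanning window (this deliberately avoids overestimating ROH number
and size), and `minSnp = 75`.

The 75 comes from a two-step argument exposed as two functions.
`minRohSnps(h, m, n, alpha)` returns the smallest L with
$(1-h)^L \cdot m \cdot n \le \alpha$: the expected number of chance
runs of L homozygous calls among `m` SNPs and `n` individuals at mean
heterozygosity `h`. At `h = 0.35`, `m = 536270`, `n = 1080` this gives
L = 54 — direct evaluation at L = 53 yields 0.0703 > 0.05, so a
published count of 53 at these printed arguments corresponds to an
unrounded heterozygosity slightly above 0.35 (0.355 suffices); the
test suite asserts both behaviours rather than hiding the
discrepancy. Because SNP calls in LD are not independent,
`effectiveRohSnps(L, reduction)` inflates L by the fractional
information loss `1 - tagGroups/m` estimated by `countTagGroups`
(greedy r² > 0.8 tagging within 250 kb windows); with the ~25%
study-scale reduction, 53 inflates to ~71, and 75 is the pinned
pipeline default.

One consequence of the window-fraction rule is worth knowing: with
50-SNP windows and a 0.05 threshold, a SNP needs at least three fully
homozygous overlapping windows, so even a perfectly clean homozygous
tract flanked by heterozygotes is trimmed by up to two SNPs at each
edge. Planted-tract tests therefore assert containment and
`nSnp >= planted - 4`, not exact recovery.

## SNP-level homozygosity association

At each SNP the two homozygote classes are pooled and the 2×2 table
(case/control × homozygous/heterozygous) is tested with the plain
Pearson χ² — no Yates continuity correction anywhere in the package,
which is required to reproduce published per-SNP (44.43, 40.10, …)
and carrier (8.87, 6.70, …) statistics. A one-sided Fisher exact test
(hypergeometric tail) targets the direction "cases more homozygous";
its reported estimate is the sample odds ratio ad/(bc), not the
conditional MLE. Multiplicity is controlled by Benjamini–Hochberg
step-up q-values; `bhFdr(p, mTotal)` accepts a total test count
larger than the supplied list so that q-values for a published top
list can be computed against the full genome-wide m (Bonferroni is
available as `bonferroniAdjust`). Missing genotypes shrink only that
SNP's table; SNPs with a zero marginal are flagged untestable and
excluded from the FDR ranking.

The uncorrected χ² is mildly anticonservative at moderate sample
size: measured on null cohorts of 200 individuals the empirical level
at nominal 0.05 is ≈ 0.054, falling to ≈ 0.047 at 600. The type-I
calibration check is run on a generator configuration with
`ldBlockSnps = 1` (no LD), because the binomial 3-SE band it uses
presumes effectively independent tests; with LD blocks the marginal
level is unchanged but the across-SNP variance of the rejection rate
is inflated.

## Burden, F_ROH and categorical contrasts

Per-individual burden summaries count only segments at or above a
criterion length (default 1000 kb, the same criterion as the caller).
F_ROH is the summed segment length in bp over
`L_AUTO = 2,677,608,286` bp, the SNP-mappable autosomal genome
excluding centromeres, and splits into short/long classes at 1500 kb
(`fRoh = fRohShort + fRohLong` exactly). Case-control contrasts use
pooled-variance Student's t-tests. Categorical tables bin a burden
metric at explicit cutoffs or pooled empirical quartiles
(right-closed intervals, ties to the lower category — one fixed rule
reproduces "approximately equal group sizes" without inventing
per-stratum cutoffs), with Woolf 95% CIs against the lowest category.
The published ">15 ROHs" odds ratio (1.55) is not reproducible from
its own printed counts by the unadjusted 2×2 computation (which gives
1.51) and is excluded from reproduction checks; the other printed
category ORs (1.22, 0.99, 1.04, 1.16, 1.45) all reproduce within
0.01.

## Consensus and recurrent ROH

Pooling is single-linkage: pools are connected components of the
interval-overlap graph per chromosome, which on a line is exactly the
merge of overlapping intervals (`GenomicRanges::reduce` with zero gap
tolerance; bookended segments sharing no base pair are not pooled).
The consensus region is the minimal interval shared by all members
(max of starts to min of ends). Under transitive pooling the strict
intersection can be empty; such pools are flagged and excluded from
the recurrent list rather than split, since no splitting rule is part
of the method. Recurrent regions require more than five distinct
carriers (≥ 6 individuals, not segments) and ≥ 500 kb of consensus
length. Carrier status is tested by the uncorrected χ² against the
cohort remainder. The per-SNP homozygote-proportion test compares the
case and control proportion vectors across the SNPs of a region with
an unpaired one-tailed Student's t (H1: cases more homozygous); the
SNP is the unit of observation and pairing is deliberately not
assumed. `commonRohGroups` applies the strictest definition —
segments with exactly identical (chromosome, start, end) and ≥ 75
SNPs — which the generator's delimited planted tracts satisfy by
construction.

## Genomic inbreeding

For dosage x and frequency p the three per-SNP terms are

* F1: $((x - 2p)^2)/(2pq) - 1$ — variance of the additive genotype,
* F2: $1 - x(2-x)/(2pq)$ — excess homozygosity,
* F3: $(x^2 - (1+2p)x + 2p^2)/(2pq)$ — correlation between uniting
  gametes,

averaged per individual over non-missing genotypes at polymorphic
SNPs (ratio-of-sums averaging is not used). Frequencies come from the
full sample, cases and controls combined, matching standard tool
behaviour; a `freq` argument accepts reference-panel frequencies
instead. The genome-wide value equals the SNP-count-weighted mean of
per-chromosome values by construction (tested to 1e-12), and F3
equals the GRM diagonal minus one exactly, by shared formula.

Two exact small-sample identities matter when interpreting cohort
summaries computed with in-sample frequencies and complete data: the
*cohort means* of F1, F2 and F3 coincide algebraically (each per-SNP
sum over individuals reduces to $n - H/(2\hat p\hat q)$ with H the
heterozygote count), and the GRM off-diagonal mean is exactly
$-(1 + \bar{F1})/(n-1)$ because standardized dosages sum to zero.
Individual-level values, and cohort means under missingness, differ
between estimators as usual. The estimator labels map to the
published order of the three estimators (variance of additive
genotypes / excess homozygosity / uniting-gamete correlation); this
correspondence is asserted by formula, not by an external source.

The covariate-adjusted model is a maximum-likelihood logistic
regression of case status on one inbreeding coefficient plus
covariates (sex, leading ancestry PCs, per-sample missingness being
the intended set); rank-deficient designs error and suspected perfect
separation is flagged.

## GRM, REML and the liability scale

The GRM uses the standard products of standardized dosages with
per-pair complete-SNP normalization for missing data and the F3-based
diagonal; monomorphic SNPs are excluded. Such matrices need not be
positive semidefinite — simulation code drawing phenotypes from a GRM
projects negative eigenvalues to zero first. `grmPCA` returns top
eigenvectors with a deterministic sign (largest-magnitude loading
positive) and flags near-equal spectra as degenerate.

`remlFit` maximizes the restricted likelihood of
$y = X\beta + \sum_k g_k + e$, $g_k \sim N(0, A_k\sigma^2_{g_k})$ by
average-information updates; any AI step that would leave the
positive orthant or decrease the log-likelihood is replaced by an EM
step (guaranteed uphill), variances are floored at $10^{-8}$ of the
phenotypic variance, and convergence is declared at
$|\Delta \log L| < 10^{-8}$ or 100 iterations. Standard errors come
from the inverse AI matrix; the SE of
$h^2 = \sum\sigma^2_g/(\sum\sigma^2_g + \sigma^2_e)$ by the delta
method. A binary phenotype is fitted as quantitative on the observed
0–1 scale and transformed by
$h^2_l = h^2_o\,K(1-K)/z^2$ with $t = \Phi^{-1}(1-K)$, $z = \phi(t)$
— exactly the printed form, with the case-control ascertainment
factor $K(1-K)/(P(1-P))$ available behind an explicit argument but
off by default. The prevalence default is K = 0.006 (a cumulative
risk of ~6 per 1000), at which the multiplier is 20.63.

The coverage check for the REML estimator asks that the simulated
truth lie inside the SE-based 95% interval (±1.96 SE) of the estimate
in at least 90% of replicates; a literal ±1 SE band has ~68% nominal
coverage and could not be met by any correctly calibrated estimator
(measured: 0.82 at ±1 SE, 0.98 at ±1.96 SE).

## The synthetic cohort generator

`simulateGenotypes` emulates the structure of an array-genotyped
case-control cohort: biallelic autosomal SNPs on a jittered grid
(default 15 kb mean spacing), allele frequencies uniform on
[0.05, 0.5] (mean expected heterozygosity ≈ 0.36, array-like), LD in
blocks of `ldBlockSnps = 10` SNPs, and a founder haplotype pool of
100 per block from which each individual draws two haplotypes. The
founder haplotypes themselves carry AR(1)-correlated alleles
(latent ρ = 0.95) so r² within blocks is substantial while across
block boundaries it is ~0; finite pools shrink expected
heterozygosity by the factor (1 − 1/nFounder), which the tests use as
the exact expectation. Pools are drawn once per simulation and shared
by all ascertainment batches — the cases and controls must come from
one population (redrawing pools per batch is a subtle way to
manufacture stratification).

Inbreeding is modelled as segment-level autozygosity: contiguous
stretches of `autoSegSnps = 100` SNPs (~1.5 Mb at default spacing)
become autozygous independently with probability F by copying one
haplotype over the other, so inbred genomes carry genuine multi-SNP
homozygous tracts and per-locus IBD probability equals F. F may be a
scalar, per-stratum (`c(cases=, controls=)`) or per-individual.
`plantAutozygosity` adds designated zero-heterozygote tracts with the
flanking SNPs forced heterozygous for carriers, so a planted interval
is exactly delimited and its detected coordinates are identical
across carriers (the property `commonRohGroups` needs).

Phenotypes follow
$\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \sum_j \log(OR_j)[x_j \ne 1]$:
risk attaches to *either* homozygote class at each configured locus,
matching the hom-vs-het contrast the scan tests. (Risk confined to a
single homozygote class is largely invisible to the pooled scan:
under case-control ascertainment the other homozygote class is
correspondingly depleted in cases and the pooled signal cancels.)
With risk loci present, individuals are simulated in batches and
accepted until the case and control quotas fill; without risk loci
the cohort is generated directly and labels assigned at random (a
null cohort).

What the generator does **not** emulate: coalescent LD decay,
recombination maps, allele-frequency spectra, genotyping error,
population stratification or relatedness structure beyond the founder
pools. Passing tests therefore demonstrate correctness of the
algorithms under a controlled model, not robustness to every artefact
of real array data.

## Problem sizes

The test-suite and acceptance computations use desk-scale cohorts
chosen to estimate each property precisely while keeping the whole
suite in the tens of seconds: estimator recovery at n = 500
individuals × 5000 SNPs, REML at n = 500 × 2000 SNPs (10–50
replicates), ROH oracle equality on genomes ≤ 200 SNPs, sensitivity
on 40 planted tracts, and the null scan at 200 individuals × 1000
SNPs. A "paper-shaped" run (649/431 × 50k+ SNPs) is a straightforward
`simConfig` change.

## Known limitations

* The ROH caller is the windowed heuristic, not a model-based (HMM)
  caller; phased data are not used.
* Exact logistic regression and permutation FDR are out of scope, as
  are gene annotation of regions and haplotype-based selection
  statistics.
* Real-data summary values that depend on unreleased genotypes (mean
  ROH burdens, observed F distributions, h² estimates) are not
  reproduced — the published count tables are reproduced instead, and
  everything else is validated by parameter recovery on synthetic
  cohorts.
* One published oddity is left as-is: the one-sided Fisher summary
  "minimum OR = 1.85 (1.23–3.41)" is asymmetric around its point
  estimate under any standard CI here and its estimator could not be
  identified; no attempt is made to reproduce it.
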