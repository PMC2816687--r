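---
title: "Divergence scans across hybrid zones: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence scans across hybrid zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzscan)
```

## The problem

Hybrid zones between colour-pattern races of mimetic butterflies (the
motivating system is *Heliconius melpomene*, where the `HmYb` region controls
the yellow hindwing bar and `HmB` the red forewing band) offer a natural
association-mapping design: strong divergent selection maintains alternative
pattern alleles across a genomic background homogenized by gene flow. Scanning
sequenced candidate regions for sites whose genotypes track the phenotype,
and contrasting their differentiation and linkage structure with unlinked
control loci, localizes the functional interval without crosses.

`hzscan` implements that analysis as a reusable pipeline over per-locus
haplotype alignments (FASTA, two haplotypes per diploid), a sample table, and
a locus table: variant extraction and dosage coding, diversity and
neutrality statistics, Hudson's FST with a linked-vs-unlinked contrast,
per-SNP trend tests with Bonferroni control, phase-free composite LD with
decay analysis, and a qPCR expression module. A seeded generator produces
two-population datasets with the statistical structure the analyses assume,
so every stage is testable and calibratable without field data.

## Statistical models and conventions

**Variant sites and dosage.** Alignment columns containing any gap are
excluded entirely (indel regions are trimmed before analysis); `N` is
missing. Multi-allelic sites are condensed to biallelic by merging all
non-major alleles; when the rarest allele is below frequency 0.05 this is
the standard rare-minor merge, otherwise the site is still condensed
major-vs-rest but flagged (`condensedRule`) so users can exclude it — the
flag keeps one dosage axis per site without hiding the unusual cases.
Genotypes are minor-allele dosage in {0, 0.5, 1}, the same scale as
phenotype scores (0/1 alternative homozygotes, 0.5 heterozygotes; under the
dominance rule, hybrids carrying the dominant band allele together with
rayed-locus evidence are scored 0.5). If exactly one haplotype is missing at
a site the genotype is missing. At a frequency tie (maf = 0.5) the
alphabetically later allele is called minor — an arbitrary but deterministic
convention that no statistic depends on (the trend test and r² are invariant
to orientation flips, which the suite verifies).

**Diversity and neutrality.** π is the mean pairwise difference proportion
over retained columns, with pairwise deletion of missing bases and per-pair
length normalization, and no multiple-hit correction. Tajima's D uses all
segregating sites with the standard constants, and its significance comes
from the rescaled beta approximation to the null: shape parameters are
chosen so the distribution has mean 0 and variance 1 on the support
`[Dmin, Dmax]` obtained from the singleton-only and maximally-even extremes
of the frequency spectrum; the two-tailed p is `2·min(F(D), 1−F(D))`. The
approximation is known to be approximate: on neutral coalescent samples
(n = 10, θ = 5) the empirical rejection rate at α = 0.05 sits near 0.035–0.04,
inside the 0.02–0.09 band the test suite asserts.

**Hudson's FST.** `fst = 1 − Hw/Hb` with `Hw` the unweighted mean of the two
within-population mean pairwise differences (a pair-count-weighted option
exists) and `Hb` the mean difference across populations. This is the
distinct-pair estimator (the one that reproduces the package's worked
fixture, Hw = 0.2, Hb = 0.82, fst = 0.756098 for 9A/1a vs 1A/9a). Two
small-sample properties follow and are asserted exactly in the tests rather
than idealized away: two samples with identical sequence multisets give
`−1/(n−1)`, not 0, and duplicating every haplotype rescales `Hw` by
`2(n−1)/(2n−1)`. Estimates can therefore be slightly negative and are
reported unclamped.

**Trend test.** The genotype-phenotype association test is the score form of
the Armitage trend test, `χ² = n·r²` on 1 df, with pairwise-complete
individuals as units. The `(n−1)·r²` variant differs negligibly and is not
offered. Bonferroni control uses `−log10(α/m)` with strict `>`; `m` defaults
to the number of testable sites in the scan and can be overridden
(`mTotal`) to correct jointly across several scans — with α = 0.05 over 866
sites the cutoff is 4.24.

**Composite LD.** Burrows' Δ is `cov(X, Y)/2` on allele counts with the 1/n
covariance, identical to the count formula `n_AB/n − 2·p_A·p_B`; it requires
neither phase nor Hardy-Weinberg equilibrium. The only r² form offered is
the squared composite correlation with the HW-departure-corrected
denominator `(p_A q_A + D_A)(p_B q_B + D_B)` — identically the squared
Pearson correlation of the dosage vectors. The uncorrected denominator is
not a bounded correlation (the perfectly-associated two-class fixture would
give r = 2) and is deliberately absent. Pairs are computed for all site
pairs with at least `minN = 20` complete individuals; failing pairs are kept
in the output with a counted reason rather than dropped. Distances come
from the shared genomic-offset axis; pairs involving an unplaced locus keep
their r² but are excluded from decay binning. Pooling the two populations
is the intended analysis mode for the divergence signal: pooling inflates
LD at divergent sites, which is the signal, not an artifact.

**Mann-Whitney contrast.** The linked-vs-unlinked FST comparison reports
per-class means ± sd (n − 1 denominator) and a two-sided Mann-Whitney test.
U comes from midrank sums; for pooled sizes ≤ 14 the p-value is exact by
full enumeration of labelings (ties included), otherwise a normal
approximation with tie and continuity corrections is used. The switch point
is our own choice (the original analyses used closed-source software whose
rule is unknown); at the boundary the two routes agree within 0.02 on
random data, which the suite checks.

**qPCR and model averaging.** Relative expression is the classic ΔCt ratio
`E^(Ct_ref − Ct_target)` with efficiency fixed at 2 (a config knob;
products were melt-curve-validated rather than standard-curved, so no
per-primer efficiency is estimated). Technical replicates are checked
against the < 0.05 spread criterion on the expression scale and averaged.
Fold changes between groups use geometric means. The model-averaging module
enumerates all 2^K covariate subsets of a linear model for log2 expression,
weights each by `exp(−BIC/2)` with `BIC = n·ln(RSS/n) + k·ln(n)`, and
reports each covariate's posterior inclusion probability Pr(β≠0) on the
percent scale plus model-averaged coefficients. This BIC-weight scheme (the
unit-information-prior approximation) is the package's own specification of
the BMA step; the original supplementary description of priors and any
random-effect handling is not public, so repeated wings per individual are
accommodated only by offering `individual` as an optional fixed covariate.
Rank-deficient subsets are skipped with a warning and the weights
renormalized; a zero-RSS model takes all the weight.

## The synthetic-data generator

`simulateTwoPopDataset()` draws two diploid population samples at multiple
loci. Neutral sites are independent with a frequency shared between
populations, drawn from Uniform(0.1, 0.9) by default — a flat, featureless
background chosen for transparency rather than coalescent realism. Selected
sites have population-specific derived-allele frequencies; sites within a
`blockLength` window are inherited jointly from one of two block haplotypes
(one Bernoulli draw per haplotype per block), a deliberately simple
two-haplotype model of the long-range association structure around a
divergently selected region — it is analytically checkable and reproduces
the qualitative signature (high pooled r² across the block, rapid decay to
background elsewhere) without simulating recombination genealogies.
Admixed individuals draw one haplotype from each population and are scored
0.5.

Defaults mirror the study conditions of the red-band comparison: 30
individuals per population; eight linked loci carrying 40 sites plus three
unlinked loci carrying 20; five strongly selected sites (fixed in the
banded population, derived frequency 0.05 in the rayed one) spanning < 14 kb
in one block across three adjacent loci, plus one moderately divergent site
(0.2 vs 0.8) in each remaining linked locus. Under these defaults the
linked-locus mean FST lands near 0.28–0.30 against ~0 at unlinked loci, and
the Mann-Whitney contrast rejects in essentially every seed.

What the generator does *not* emulate: coalescent correlation among neutral
sites within a locus, recombination gradients, indels (gap handling is
exercised on hand-built fixtures instead), sequencing error beyond uniform
`N` masking, and demography. Passing tests therefore certify the statistics
and their wiring, not robustness to every property of field data.

`simulateCoalescentSample()` provides the neutral null: a standard
n-coalescent without recombination with Poisson mutations under infinite
sites, giving `E[S] = θ·a₁` for calibration.

## Numerical choices and degenerate inputs

* Monomorphic vectors in the trend test or LD return `NA` with reason
  `"monomorphic"`, never an error; scans with no testable site warn and
  return an empty result.
* `Hb = 0` makes FST `NA`; populations with fewer than two haplotypes are
  errors.
* D outside the beta support by more than 1e-9 is clamped with a warning;
  `S = 0` gives `NA`, and `n < 4` gives `NA` with a warning because the
  variance constants degenerate.
* Site MAFs are computed from allele counts, not accumulated frequencies,
  so threshold comparisons (strict `> 0.05`) are float-exact at boundary
  cases like 1/20.
* p-values are computed on the log scale (`pchisq(..., log.p = TRUE)`), so
  `−log10(p)` stays finite for very large χ².
* Tail p-values are never reported as 0; `p ∈ (0, 1]` throughout.

## Calibration sizes used by the test suite

The null-calibration checks run 2000 coalescent replicates (n = 10, θ = 5)
for the segregating-site expectation and beta-test rejection rate, and one
all-neutral two-population dataset of 2000 sites for trend-test uniformity.
The uniformity check uses 200 diploids per population: the trend statistic
is discrete, and at small samples the event "group dosage sums tie exactly"
has non-trivial probability (~7% at 30 + 30 with a binary phenotype),
leaving an atom of p-values at exactly 1. The χ²(1) null is an asymptotic
claim; at 200 per population the Kolmogorov-Smirnov distance from uniform
(~0.034) is essentially the residual atom. Power and FST-contrast
recoveries use the generator defaults (30 per population) over 50–100
seeded replicates.

## Known limitations

* π carries no finite-sites correction, matching the conventions of the
  alignment-based tools this pipeline mirrors; per-bp values at high
  divergence would be underestimates.
* The beta approximation for Tajima's D is itself approximate; its nominal
  α = 0.05 behaves like ~0.04 at n = 10.
* The closed-form FST oracle `1 − (p_A q_A + p_B q_B)/(p_A q_B + q_A p_B)`
  is the large-sample limit; the mean of the ratio estimator differs by a
  Jensen term of order 1/n (≈ 0.01 at 30 haplotypes per population).
* BMA results depend on the BIC-weight choice; with flat model priors and
  small n, inclusion probabilities are conservative relative to g-prior
  implementations.
* The Mann-Whitney normal approximation is used above pooled size 14 even
  with heavy ties; with the per-locus counts this pipeline produces
  (≤ ~25 loci), the exact path covers most real contrasts.

## Worked example

```{r example, eval = FALSE}
cfg <- synthConfig(seed = 42)
sim <- simulateTwoPopDataset(cfg)
gm  <- genotypeMatrixFromAlignments(sim$alignments, sim$samples)
scan <- associationScan(gm, scorePhenotypes(sim$samples), mTotal = 866)
ld  <- partitionSitesByAssociation(
  ldMatrix(filterInformative(gm), minN = 20), scan)
ft  <- fstTable(sim$alignments, sim$popHaplotypes$popA,
                sim$popHaplotypes$popB)
compareFstClasses(ft)
```

The README shows this run with the numbers it prints.
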