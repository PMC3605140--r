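---
title: "Models and methods behind nahrhotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nahrhotspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nahrhotspot)
```

This vignette documents the statistical models, the parameter choices
and the deliberate design decisions in `nahrhotspot`. The package is
built around the *DPY19L2* configuration — two ~28 kb low-copy repeats
(LCRs) at ~98% identity, ~200 kb apart, whose non-allelic homologous
recombination (NAHR) deletes or reciprocally duplicates the intervening
gene — but every constant below is an argument, not a hard-coded value.

## The zero-well model for limiting-dilution digital PCR

A plate distributes `N` template copies over `wellsTotal` wells of
`W = N / wellsTotal` copies each. Because each well receives a sample
of the finite input pool *without replacement*, the number of
recombinants per well is hypergeometric, and the probability that a
well contains none of the `R` recombinants is

$$P_0(R) = \frac{\binom{N-R}{W}}{\binom{N}{W}}
         = \prod_{i=0}^{R-1}\left(1 - \frac{W}{N-i}\right).$$

`pZero()` evaluates the product form as a cumulative sum of
`log1p(-W/(N - i))`, which is numerically stable, exact for fractional
`W`, and vectorised over `R` (the whole tabulation grid is one
`cumsum`). Poisson and binomial approximations are common in the
digital-PCR literature; they are unnecessary here — the direct
calculation is as cheap — and the test suite quantifies both: at plate
scale (`W/N = 1/96`) the with-replacement form `(1 - W/N)^R` agrees
with the hypergeometric to better than $10^{-3}$ relative error for
`R <= 200`, whereas the Poisson form `exp(-RW/N)` deviates by up to
~1% and only converges as the well fraction `W/N` shrinks at fixed
per-well load.

`estimateRecombinants()` recovers `R` as the integer whose $P_0$ is
closest to the observed negative-well fraction (the tabulation
estimator). Numerical choices:

* **Tie-break:** the smaller `R` wins. Ties have measure zero in real
  data but determinism is required.
* **Search bound:** `R` is tabulated up to `10 × wellsTotal`; beyond
  that $P_0$ is far below any achievable negative fraction.
* **Degenerate plates:** all-negative plates give `R = 0`; saturated
  plates (no negative well) are an error, since the zero-well model
  carries no information there.
* **Copy accounting:** 50 ng of DNA at 3 pg per haploid genome is
  16,667 copies per well — the unrounded value, so that a 96-well
  plate holds 1.6×10⁶ copies. Rates are reported to 2 significant
  figures.

Pooling plates (`poolPlates()`) sums wells, positives and copies and
requires a shared `W`; estimation is then re-run on the pooled
negative fraction. This is deliberately *not* the sum of per-plate
estimates — the tabulation is nonlinear, and on the three duplication
plates of the reference assay it yields 74 where the per-plate counts
sum to 73.

Confidence intervals model the `R` successes among `N` copies as
binomial and use the exact Clopper–Pearson interval via
`stats::binom.test()`. For comparing two assays, `compareRates()` uses
a conditional exact binomial test (is `R_a` of `R_a + R_b` compatible
with the copy-share `N_a/(N_a+N_b)`?). The comparison method is a
package choice: the study design fixes the estimator and the CI but
not a two-sample test. Simulation in the suite shows the test holds
its nominal type-I error (rejection frequency near 0.05 on equal-rate
plates).

## Marker classification

Candidate sites are positions whose *reference* alleles differ between
LCR1 and LCR2. Resequencing both repeats in a control panel decides
which candidates are usable as breakpoint markers:

* `LCR_SPECIFIC`: every control call homozygous within each repeat,
  fixed for different alleles between repeats;
* `SHARED_SNP`: anything that segregates — including a *single*
  heterozygous control call in either repeat. This strict demotion
  rule is a deliberate choice: a marker that is ever heterozygous
  within a repeat cannot prove copy-of-origin, and the cost of losing
  an informative site is an honest widening of breakpoint intervals,
  never a wrong call.
* `UNCLASSIFIABLE`: sites with no informative calls in one or both
  repeats are flagged, never silently dropped. Missing calls in *some*
  individuals are ignored; no imputation is attempted.

Classification is idempotent and independent of individual ordering,
and on noise-free generator output it recovers the truth labels
exactly (both are tested).

## Breakpoint calling

Only LCR-specific markers enter the call. For a deleted amplicon the
expected pattern along the marker order is a proximal-repeat (LCR1)
prefix followed by a distal-repeat (LCR2) suffix; duplicated amplicons
are the reciprocal junction, so the repeat roles swap. The call is the
*maximal* interval: (last proximal-type marker, first distal-type
marker). Conventions:

* Intervals are open marker pairs; widths in bp come from marker
  coordinates (the BP1–BP3 region spans 1153 bp in the default
  geometry).
* Missing marker calls widen the interval to the nearest called
  markers — intervals are never interpolated.
* Entirely one-repeat genotypes are `OUTSIDE` (crossover beyond the
  amplified window); non-monotone patterns are `UNRESOLVED` with a
  diagnostic, since they indicate double crossovers or genotyping
  error, and guessing would corrupt the distribution tables.
* The bin map (`defaultBinMap()`) is configuration. Defaults: BP1 =
  (17,18), BP2 = (18,24), BP3 = (25,28), plus flanking bins BP4 =
  (16,17) and BP5 = (28,29) for the two bins seen only in sperm data,
  which have no published marker bounds. A widened interval that
  contains exactly one configured bin is assigned to it; ambiguity is
  `UNRESOLVED`.

A compound heterozygote (two different recombined alleles in one
sample) is heterozygous exactly at the specific markers between the
two crossovers; those markers must form one contiguous run, and the
unique monotone haplotype pair switches at the start and after the end
of that run. Anything else (non-contiguous heterozygosity,
inconsistent flanking homozygotes) returns an `UNRESOLVED` pair rather
than a forced phasing.

Haplotype counting treats two alleles as one founder event only when
they share both the bin and the full shared-SNP vector; the count is
therefore a lower bound on independent NAHR events. Distribution
tables report percentages to one decimal; note that 16/34 = 47.06%
prints as 47.1.

## The General Selection Model

Genotype fitnesses are sex-averaged: homozygous deleted men are
sterile and women unaffected, so the homozygote fitness is 0.5;
heterozygous women are assumed unaffected, so the sex-averaged
heterozygote fitness `W` maps to a male relative fitness `2W - 1`.
For a rare allele (`q` of order 10⁻³) the recurrence simplifies to

$$\Delta q = -q\,[\,W(q-p) + p - q/2\,], \qquad p = 1 - q,$$

which is exactly $-q^2/2$ at `W = 1`. `solveHetFitness()` inverts the
same expression in closed form; the two functions are exact mutual
inverses (property-tested to $10^{-10}$), and the inversion is
undefined at `q = 1/2`, which is rejected.

Two numerical conventions matter for reproducing the published
arithmetic: `q` is kept unrounded internally (30/17148, not 1.7×10⁻³
— the rounded value would give 1.4×10⁻⁶ instead of 1.5×10⁻⁶ for
$q^2/2$), and rounding to 2 significant figures happens only at
reporting. CI propagation through $\Delta q$ uses endpoint
transformation, valid because $|\Delta q|$ is monotone in `q` over the
relevant range. `equilibriumCheck()` reports both intervals and
whether they overlap; with `W = 1` the mutation–selection equilibrium
solves $q^2/2 = \mu$, i.e. $q^* = \sqrt{2\mu}$.

## Motif analysis

The degenerate PRDM9 13-mer `CCNCCNTNNCCNC` is scanned on both strands
with IUPAC-aware matching (`Biostrings::matchPattern(fixed = FALSE)`),
overlaps allowed. The reverse-strand pattern is the *formally derived*
degenerate reverse complement `GNGGNNANGGNGG`; published figure
legends sometimes print partially instantiated variants, which are not
reverse complements of the stated core and are not used here. The test
suite validates the scanner against a naive position-by-position
matcher with its own IUPAC table, and checks strand symmetry under
reverse complementation.

The 39-mer extended recognition context is scored by per-position
identity against a consensus supplied by configuration — the extended
consensus comes from the hotspot-motif literature and is not derivable
from one locus, so the package treats it as an external input.
Truncated contexts at sequence ends are flagged, not scored. Integer
percentages truncate toward zero (21/39 reports as 53%). The
chance-proximity probability for `m` uniformly placed sites within `d`
bp of a fixed centre in a sequence of length `L` is
$1 - (1 - m/L)^{2d}$, increasing in `m` and `d`.

## What the generator emulates — and what it does not

`simConfig()` pins the study conditions as defaults: 28 kb repeats at
98% identity; 34 candidate sites of which 20 are LCR-specific and 14
shared SNPs, laid out so the markers 17–28 span 1153 bp; bin weights
proportional to the observed sperm-deletion counts (2/56/10/2/4);
true rates 1.8×10⁻⁵ (deletion) and 7.7×10⁻⁶ (duplication) per haploid
genome; founder counts 3/2/2 for BP1–BP3 matching the observed
somatic-cohort haplotype structure; 96-well plates at 50 or 100 ng per
well and 3 pg per haploid genome; a 20-control panel.

Generator mechanics worth knowing:

* Well allocation is sequential sampling without replacement
  (multivariate hypergeometric), matching the estimator's model
  exactly — this is deliberate, since the estimator's claim to
  exactness is the point under test.
* Exactly five motif instances are planted per repeat copy (one at the
  hotspot centre, four decoys on mixed strands); chance matches in the
  random background are detected and disrupted, so a scan returns
  exactly the planted set. Substitution repairs are applied to both
  copies at the same coordinate to leave the pairwise identity
  untouched.
* Every SNP site is given at least one heterozygous control call, so
  the truth labels are recoverable without genotyping noise. The panel
  emulates *clean* Sanger calls: no base-calling error, no allele
  dropout, no missingness by default.
* Founder haplotypes are drawn once per bin and recycled round-robin,
  so a bin with `k` founders and at least `k` alleles shows exactly
  `k` distinct haplotypes.
* The population recurrence is an infinite-population deterministic
  map; mutation is added after selection each generation (the order
  affects terms of order $\mu q$, which are negligible at these
  scales). There is no drift, no population structure, no
  consanguinity — so passing trajectory tests says nothing about
  finite-population behaviour, which the deterministic model cannot
  capture.

Because the generator shares the hypergeometric allocation with the
estimator's assumptions, estimator-recovery results (median relative
bias of the rate within ±5%, CI coverage between 0.93 and 0.97 across
500 simulated plates at the deletion-assay scale — both asserted in
the suite) validate the *inference*, not the wet-lab assay: real
plates add pipetting variance, amplification failure and inhibition,
none of which are modelled.

## Problem sizes and runtime

The suite's stochastic checks use sizes chosen to make sampling error
a small fraction of each tolerance while keeping the default run in
tens of seconds: 500 plates for estimator recovery and coverage, 400
plate pairs for the type-I error of the rate comparison, 10⁴ alleles
for bin-weight convergence, 10⁵ Monte-Carlo draws for the
chance-proximity probability, 25 random 28 kb sequences for scanner
validation, and 3000 generations for trajectory equilibrium (the
approach to $q^*$ has a time constant of roughly $2/q^* \approx 330$
generations from a standing start).

## Known limitations

* Sequences must be pre-aligned/coordinate-matched; there is no
  alignment, and indel divergence between repeat copies is not
  represented (real LCR pairs contain gaps).
* The zero-well model ignores amplification efficiency; a recombinant
  molecule that fails to amplify is invisible, so rates are estimates
  of *detectable* events.
* Triplications are indistinguishable from duplications in this assay
  design and are not modelled.
* Phasing beyond the two-allele monotone decomposition (e.g. three
  alleles, or double crossovers on one molecule) is out of scope and
  surfaces as `UNRESOLVED`.
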