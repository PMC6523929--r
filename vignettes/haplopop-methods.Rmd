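---
title: "Methods: multilocus MHC haplotype population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilocus MHC haplotype population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopop)
```

`haplopop` compares adaptive variation at a haplotype-coded MHC marker with
a neutral microsatellite panel across small, serially founded populations of
the crested ibis. This vignette documents the statistical machinery, the
parameter choices, the design decisions taken where the method left room,
and what the test suite does and does not establish.

## The haplotype system

Seven Core-Region haplotypes are defined by the combination of a *DAB*
allele (`*01`–`*04`) and a *UAA* allele (`*01`/`*02`); the class II copy
number structure (which IIαβ units a haplotype carries) is determined by
the *DAB* allele alone. One of the eight possible allele combinations
(*DAB\*01* with *UAA\*02*) has never been observed and has no haplotype, so
an unphased two-locus genotype is compatible with exactly one or two
diplotypes (`compatible_diplotypes()`). That small state space is what makes
rule-based phasing essentially exact here, and why haplotype-level coding is
attractive for markers too depauperate to be informative locus by locus.

## Phasing

Phase is assigned in three tiers, in a fixed order:

1. **Unambiguous** — at most one locus heterozygous: the two gametes are
   fully determined. Doubly heterozygous genotypes are deliberately left
   undecided even when only one diplotype is catalog-compatible, so that the
   tier semantics stay simple ("≤1 heterozygous locus ⇒ decided").
2. **Pedigree** — one haplotype must be transmissible from each phased
   parent. When no recombination-free assignment exists, gametes carrying
   the *DAB* block of one parental haplotype and the *UAA* allele of the
   other are considered; the minimum-recombination solution is taken and
   each implied event recorded. Solutions requiring two recombinant gametes
   are rejected as unparsimonious — a child that truly received two
   recombinant gametes will therefore be phased to the zero-recombination
   alternative, an unavoidable blind spot of parsimony that our simulations
   quantify (it requires two independent events in one birth, probability
   `≈ r_rec²`).
3. **Frequency** — the compatible diplotype maximizing the product of the
   haplotype frequencies in the individual's *own* population; exact ties
   break lexicographically and are flagged low-confidence. Ties were left
   unspecified by the original procedure; a deterministic flagged rule was
   chosen over randomization so reruns are identical.

The EM estimator (`em_haplotype_frequencies()`) provides the program-style
cross-check: on simulated data the pooled three-tier frequencies and the EM
frequencies agree within 0.02 at n ≥ 200. The permutation LD test uses the
likelihood-ratio between the EM fit and the independence fit, permuting one
locus among individuals; p-values use the `(hits + 1)/(B + 1)` convention
and every permutation procedure in the package takes and records a seed.

## Diversity

* Unbiased gene diversity `H_E = (2N/(2N−1))(1 − Σ p²)`. The `2N/(2N−1)`
  correction is not optional: with N = 8 birds in the wild sample, the
  uncorrected estimator misses the published values, the corrected one
  reproduces the whole published row at two decimals.
* Allelic richness by hypergeometric rarefaction to `g` gene copies,
  computed with log-factorial combinatorics. The default `g` is the
  smallest sample (16 copies here), the standard choice that makes richness
  comparable across unequal samples. The formula is validated against
  Monte-Carlo subsampling (10,000 draws, agreement < 0.02).
* The bottleneck test simulates, per locus, a Kingman coalescent of the
  sample's gene copies with stepwise (±1) mutations, tunes the scaled
  mutation rate θ so the mean simulated allele count matches the observed
  count (bracketed bisection on batches of 30 simulations), and keeps only
  simulations with exactly the observed allele number. The standardized
  excess `DH = (H_E − mean H_eq)/sd H_eq` is combined over loci by a
  one-tailed Wilcoxon signed-rank test. The published analysis used a
  closed-source program whose conditioning scheme is not fully documented;
  this reconstruction reproduces its logic (accept–reject on the allele
  count), so p-values are comparable but not bit-identical by construction.
  Type-I error is checked by self-consistency at equilibrium and power on a
  simulated two-pair crash.

## Differentiation

AMOVA treats each gene copy as the unit with the 0/1 haplotype-mismatch
distance — haplotypes are unordered classes, so no molecular distance is
imposed (a distance hook was considered and rejected: the copy-number
structure would impose an arbitrary metric). Sums of squares reduce to
`N(1 − Σp²)/2` per stratum and variance components use the classical
unequal-sample-size coefficients. Significance: `F_CT` permutes whole
populations among groups, `F_SC` permutes gene copies among populations
within groups, `F_ST` permutes gene copies among all populations; 1,023
permutations by default for a single AMOVA, 50,000 for the grouping search
(both overridable). The two-population reduction is checked against an
independently coded Weir–Cockerham θ to 1e−9.

`G_ST`/`G'_ST` use the Nei–Chesser sample-size-corrected `H_S` and `H_T`
(harmonic-mean sample size, unweighted mean allele frequencies). Two
consequences worth knowing: identical populations give a slightly *negative*
corrected `G_ST`, and the statistic is only asymptotically invariant to
scaling all counts — both are properties of the estimator, not bugs, and the
tests assert them with appropriate bands. Multilocus panels combine loci by
averaging `H_S` and `H_T` before taking ratios (default) because averaging
per-locus ratios lets nearly monomorphic loci dominate; the alternative is
exposed as `combine = "mean_ratio"`. The published global values could not
be reproduced from the printed frequency table under either rule (the
original estimator variant is unspecified), so global `G'_ST` is reported
but not used as a reference point; pairwise comparisons, which drive all the
biological conclusions, are fully supported.

The neutral envelope bootstraps *loci* (with replacement, percentile
interval). The locus is the only resampling unit that expresses
among-marker sampling variance when one haplotype locus is compared against
an 11-locus panel; the original description says only "1000 bootstrap
replications", so this is an interpretation, documented as such. Intervals
are closed: an adaptive value exactly on a bound is *inside*; outlier calls
require strict exceedance. Envelope coverage is calibrated on simulated
neutral panels (≈95% nominal within binomial bounds).

Chord-distance NJ trees use
`D_c = (2/(πL)) Σ_l √(2(1 − Σ_i √(x_i y_i)))` with `ape`'s NJ; node support
is the fraction of bootstrap trees (gene copies resampled within
populations) containing each bipartition.

## Selection

The Nei–Gojobori method counts synonymous sites per codon with stop-codon
changes excluded, and differences by equal-pathway averaging over
substitution orders, skipping pathways through stop codons (verified against
brute-force path enumeration over codon pairs). Proportions are
Jukes–Cantor corrected, `d = −(3/4)ln(1 − 4p/3)`; a proportion ≥ 3/4 is an
error, not a clamp — this genuinely occurs for very short partitions (a
single synonymous difference on a synonymous-site-poor codon) and refusing
is the honest behaviour. Sequences enter with integer weights equal to their
sample frequencies; identical-sequence pairs contribute zero distance with
multiplicity `C(w,2)`. The Z-test uses bootstrap variance over codons
within the partition (1,000 replicates by default) — a deliberate choice
over the analytical variance, matching common practice for this test; the
two can differ for short partitions. The ABS partition is data, not code: a
one-index-per-line codon mask file. The packaged exon-2 allele set is a
synthetic stand-in (so labelled) with the same reported substitution
structure as the real integrated four-allele *DBB* set — all ABS
substitutions nonsynonymous — because the deposited sequences cannot be
redistributed inside the package.

## The simulator

`simulate_populations()` is a forward-in-time founder-effect model:
discrete non-overlapping generations, monogamous random pairing (two pairs
per cage, cage-mates recorded as candidate parents), Poisson offspring per
pair truncated at a carrying capacity, Mendelian transmission of the
haplotype block with block recombination at `r_rec` per meiosis, and
unlinked microsatellites under stepwise ±1 mutation at `mu` per meiosis.
The default founding graph mirrors the documented establishment history
(6-bird wild source; BJ 4; SD 5; LGT 60; DQ 10; HN 11+2; the YX founder
count is unrecorded and set to 10), compressed to nine generations for a
38-year history with a ≈4-year generation time.

Parameter defaults and why:

* `offspring_lambda = 6`. A Poisson(2) litter per monogamous pair has
  growth rate 1 and cannot take 6 birds to populations of 45–185 while
  exporting founders, and it makes 2-pair populations extinction-prone;
  Poisson(6) per ≈4-year generation (≈3× growth) matches the observed rapid
  managed recovery. Extinction and infeasible founder draws raise
  informative errors rather than being silently patched.
* `r_rec = 0.01`. Nine recombination events were observed among the phased
  parentages but the number of scorable meioses is unknown, so this is an
  order-of-magnitude setting, configurable. Recombinants whose allele
  combination is undefined in the catalog (the unobserved *DAB\*01–UAA\*02*)
  are not formed.
* `mu = 5e-4`, 11 loci (8 di-, 3 tri-allelic): typical avian microsatellite
  mutation rates and the published panel's polymorphism levels.
* Founder haplotype frequencies default to the wild sample's spectrum with
  a small HT07 share (HT07 is documented in an early wild-born founder) and
  HT06 at zero (both observed HT06 copies were recombination products).

What the simulator emulates: founder sampling, serial bottlenecks, drift,
rare block recombination, stepwise microsatellite evolution, cage-induced
pedigree ambiguity. What it does not: overlapping generations, sex ratio
and mate choice, migration after founding, selection on haplotypes (a
deliberate non-goal — the package *tests* for selection footprints, so the
validation data must be neutral), genotyping error, and null alleles.
Passing tests on simulator output therefore validate the statistical
machinery under the stated model, not the biological conclusions about the
real populations.

The presets trade realism for statistical contrast: `drift_only` founds
five populations with strongly varying founder numbers (30/4/24/4/12) so
both marker classes share a demographic differentiation gradient;
`isolated_pop` adds a two-pair isolate (the BJ analogue); and
`bottleneck_panel` crashes a large population to two pairs and regrows it.

## Numerical and reproducibility choices

* Count reconstruction from printed percentages enumerates all integer
  vectors within ±0.05 percentage points per entry that sum to 2N, and
  fails on zero or multiple solutions — printed tables are either recovered
  exactly or declared irrecoverable, never guessed. All seven population
  columns of the packaged fixture reconstruct uniquely.
* Every stochastic routine takes an explicit seed and is bit-reproducible;
  permutation and bootstrap p-values use `(hits + 1)/(B + 1)`.
* EM convergence is on the maximum absolute frequency change (`1e-8`
  default) with a non-decreasing log-likelihood; the likelihood-grid oracle
  in the tests guards against silent stalls.
* Rarefaction and pairwise-difference computations use log-scale
  combinatorics; no factorials are formed.
* Test problem sizes: simulations of ~500–3,000 individuals, bottleneck
  calibration at 24 equilibrium runs × 6 loci with 100 retained replicates
  per locus, envelope coverage at 40 panels × 150 bootstrap replicates.
  These sizes were chosen to give the property checks clear statistical
  resolution (binomial confidence bands around each nominal rate) at
  interactive runtimes; the full published settings (2,000 bottleneck
  replicates, 50,000 grouping permutations, 1,000–2,000 bootstraps) remain
  the function defaults.

## Known limitations

* The pedigree tier needs parents phased first; founder-generation double
  heterozygotes fall through to the frequency tier, whose error rate is
  governed by how skewed the haplotype frequencies are (here strongly, so
  the rate is low, as the phase-frequency analysis in the source data also
  found).
* The bottleneck test's conditional equilibrium distribution depends mildly
  on the θ-calibration batch size; p-values are approximate reconstructions
  of the published program's, not replicas.
* Global multilocus `G'_ST` is estimator-variant-sensitive at these sample
  sizes; use pairwise values for inference.
* The dN/dS machinery refuses saturated partitions rather than truncating
  the correction; for the short, closely related alleles this package
  targets that is the right failure mode, but it means very long branches
  are out of scope.
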