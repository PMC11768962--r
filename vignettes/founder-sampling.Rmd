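---
title: "Founder sampling for synthetic varieties: exact inbreeding and retention probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder sampling for synthetic varieties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synvar)
```

## The problem

A synthetic variety is the open-pollinated population obtained by randomly
mating plants that represent a set of `l` unrelated parental inbred lines.
Its appeal — a genotypic structure that is reproducible across cycles once
Hardy–Weinberg equilibrium is reached — rests on each line being represented
by a "large" sample. In practice each line contributes only `m` plants, and
with small `m` three finite-sample effects appear:

* the variety's inbreeding coefficient rises above its Hardy–Weinberg value,
* genotypes of a line's progeny array can be missing from the sample, and
* an allele can be lost outright, or the sample's allele frequencies can
  drift away from the parental 1/2 : 1/2.

`synvar` quantifies all three exactly, at a single biallelic locus, and
backs every analytic quantity with a seeded gene-dropping Monte Carlo
estimator.

## The genetic model

Selfing a heterozygous line A1A2 produces the ordered genotypic array

$$\mathrm{GA} = \tfrac14\,A_1A_1 + \tfrac14\,A_1A_2 + \tfrac14\,A_2A_1 + \tfrac14\,A_2A_2 ,$$

where the two heterozygote orders are kept distinct as sampling outcomes;
merging them gives the collapsed array GA3 with probabilities
(1/4, 1/2, 1/4). The line's inbreeding coefficient `F` is the probability
that its two founder alleles are identical by descent (IBD), so the progeny
inbreeding coefficient of a mating between two sampled plants is linear in
`F`: 1 for selfing a homozygote, `F` for the cross of opposite homozygotes,
and `(1+F)/2` for every other pairing (`progenyIC()`, `matingICTable()`).

### Inbreeding coefficient of the synthetic

The `m` plants of one line are organised as `g = floor(m/4)` complete groups
containing all four array genotypes plus `e = m mod 4` leftover plants with
distinct genotypes. Averaging the progeny coefficient over all `m²l` ordered
matings (selfings included) of the variety gives

$$F_{SynL} \;=\; \frac{m\frac{3+F}{4} \;+\; \bigl(12g + e(e-1)\bigr)\frac{5+7F}{12}
\;+\; \bigl(16g(g-1) + 8ge\bigr)\frac{1+F}{2}}{m^2\,l},$$

implemented in `syntheticIC()`. The three weights are the number of
selfings, of within-group crosses (average `(5+7F)/12`, pulled below the
Hardy–Weinberg value by the two opposite-homozygote crosses), and of
between-group crosses (average `(1+F)/2`). Whenever `m` is a multiple of 4
the per-line value `l·F_SynL` equals `(1+F)/2` exactly, and for any `m` it is
sandwiched between `(1+F)/2` and the `m = 1` maximum `(3+F)/4`
(`icAsymptote()`, `meanSelfingIC()`).

The grouped structure is not an arbitrary accounting device: a sample of `m`
*independent* draws from the array has the strictly larger inbreeding value
$[(3+F)/4 + (m-1)(1+F)/2]/(m\,l)$ (9/16 instead of 1/2 at `m = 4`, `F = 0`).
The package treats the grouped construction as the model proper — it is the
one the closed form weights — and exposes the independent-draws reading as
`simulateFSyn(..., scheme = "iid")` with its own analytic value, so the gap
between the two readings is itself measurable rather than hidden. This was
a genuinely open design point; we resolved it in favour of the construction
that the closed-form weights `12g + e(e-1)` actually count, and validate both
schemes against their respective expectations.

```{r}
syntheticIC(5, F = 0.5, l = 1)
head(icTable(), 5)
```

## Genotype retention

For the retention questions the sample *is* modelled as `m` independent
multinomial draws from the array (that is what "a random sample of the
progeny" means there, and it is also what the multinomial algebra below
assumes; the two models answer different questions and are deliberately not
unified). The probability that the sample contains at least one plant of
every genotype class is assembled set by set:

1. enumerate the **frequency sets** — integer partitions of `m` into 3 or 4
   positive parts (`enumerateFrequencySets()`);
2. expand each set into its **distinct permutations**, the ordered
   assignments of counts to labelled genotypes (`ndp()`);
3. weight each permutation by its exact multinomial mass
   (`multinomialMass()`) and sum (`inclusionProbability()`,
   `inclusionBreakdown()`).

An independent inclusion–exclusion closed form over genotype subsets,
$\sum_{S}(-1)^{|S|}\bigl(1-\sum_{q\in S}p_q\bigr)^m$
(`inclusionClosedForm()`), must agree with the enumeration as an exact
rational, and the test suite verifies that identity for every `m` up to 30 on
both arrays. Collapsing the heterozygotes can only help retention, so the
three-class probability dominates the four-class one at every `m`.

```{r}
ratRound(inclusionProbability(15, selfedLineArray()), 4)
breakdownTable(inclusionBreakdown(6, collapseToGA3(selfedLineArray())))
```

## Allele statistics

* **Allele loss** requires the sample to be all-A1A1 or all-A2A2:
  probability `2(1/4)^m` (`geneLossProbability()`), negligible from about
  `m = 5` but catastrophic when it happens (the sample's inbreeding
  coefficient hits 1).
* **Equal allele frequencies** — the sample carrying exactly `m` copies of
  each allele — has probability `choose(2m, m)/4^m`
  (`equalAlleleFreqProbability()` enumerates genotype count vectors; the
  binomial form is the cross-check). It *decreases* in `m` (3/8 at `m = 2`,
  about 0.125 at `m = 20`), a reminder that larger samples protect against
  loss, not against drift around the target frequencies.
* **Implied progeny inbreeding**: a sample with A1-frequency `p` mates to a
  Hardy–Weinberg progeny array whose inbreeding coefficient is
  `(p² + q²) + 2pq·F` (`progenyICFromSample()`), minimised at exactly 1/2
  + F/2 when `p = q`.

## Exact arithmetic

Every analytic module computes on `Rational`, an exact rational class with
arbitrary-precision integer numerator and denominator built into the package
(values such as `15!·4^{-15}` overflow double-precision integers). Floating
point appears only in presentation helpers. Two rendering conventions are
exposed because published tables use both: `ratRound()` rounds
half-away-from-zero (0.9375 → 0.94) and `ratTruncate()` truncates toward
zero (0.001953 → 0.0019). Decimal output in the CLI always travels alongside
the exact numerator/denominator pair (`ratToJSON()`), so no round trip loses
exactness.

Where a printed reference value disagrees with its own defining expression —
this happens for a handful of cells in the source tables (for example the
three-class `m = 15` grand total, which is exactly 0.97327, and the `m = 4`
equal-frequency probability, exactly 35/128 = 0.2734) — the package computes
the exact value and relies on the dual-route identities (enumeration versus
inclusion–exclusion, genotype-space enumeration versus binomial closed form)
rather than reproducing the misprint.

## The Monte Carlo oracle

`simulateFSyn()` gene-drops: per replicate it picks two parents uniformly
with replacement from the `ml` plants, transmits one uniformly chosen allele
from each, and scores IBD — alleles from different lines are never IBD,
within a line the two founder alleles are IBD with probability `F`. Under
the grouped scheme, two distinct plants of one group form a uniform ordered
pair of *distinct* genotypes and plants of different groups are independent,
which reproduces the closed form's three mating classes exactly.
`simulateStatistic()` estimates the retention and allele statistics from
multinomial draws. Results carry the empirical proportion, its binomial
standard error, the exact analytic value and a z-score (when every replicate
agrees, the binomial standard error at the analytic value replaces the
degenerate empirical one).

All estimators are vectorised, so the default validation grid —
`m = 1..16`, `F ∈ {0, 1/2, 1}`, `l ∈ {1, 4}`, 100 000 replicates per cell,
every |z| below 4 — runs in well under a minute. Unit tests use 20 000 to
40 000 replicates per cell; the exact-identity suites use `m ≤ 30` for the
inclusion identities, `m ≤ 20` for completeness-of-mass sums and `m ≤ 9` for
the full brute-force mating oracle, sizes at which the reference
computations are still exhaustive.

What the simulator does *not* emulate: real founder samples are taken
without replacement from finite seed lots, lines can be related, loci are
linked and multiple, and selection or migration may intervene. Passing
oracle checks therefore validate the package's formulas under their own
assumptions — one unlinked biallelic locus, unrelated lines, sampling with
replacement, one generation of random mating — not the behaviour of a real
breeding nursery.

## Limitations

* Single locus, two alleles, equal parental allele frequencies; no mutation,
  migration or selection.
* Lines are unrelated and enter with a common `F`; synthetics built from
  hybrids or related lines need a different recurrence.
* One generation of random mating; no multi-generation drift tracking.
* The grouped sampling model and the multinomial retention model are
  intentionally different idealisations of "a sample of m plants"; see the
  design discussion above.
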