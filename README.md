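# synvar

Exact inbreeding and founder-sample stability of synthetic varieties.

A synthetic variety is an open-pollinated population formed by randomly
mating plants that represent `l` unrelated parental inbred lines. Breeders
like synthetics because their genotypic structure is reproducible: a farmer
can resow harvested seed and get the same variety back. That reproducibility
assumes each line is represented by a "large" sample. When each line
contributes only `m` plants, random drift in the founder sample inflates the
variety's inbreeding coefficient and can drop genotypes — or whole alleles —
from a line's contribution. `synvar` quantifies those risks exactly, at a
single biallelic locus, for anyone choosing `m` when assembling founder
seed.

## What it computes

For a line A1A2 with inbreeding coefficient `F` (the probability its two
alleles are identical by descent), selfing yields the genotypic array
`(1/4) A1A1 + (1/4) A1A2 + (1/4) A2A1 + (1/4) A2A2`. With the `m` sampled
plants organised as `g = floor(m/4)` complete four-genotype groups plus
`e = m mod 4` distinct leftovers, the variety's inbreeding coefficient after
one round of random mating of all `m·l` plants is

    F_SynL = [ m(3+F)/4 + (12g + e(e-1))(5+7F)/12
               + (16g(g-1) + 8ge)(1+F)/2 ] / (m² l)

which tends to `(1+F)/2l` as `m` grows and equals it exactly when `m` is a
multiple of 4 (`syntheticIC()`, `icTable()`, `icAsymptote()`).

Around that core the package provides, all in exact rational arithmetic:

* **Genotype retention** — the probability that a sample of `m` multinomial
  draws contains every genotype class, assembled from integer partitions of
  `m` and their distinct permutations (`inclusionProbability()`,
  `inclusionBreakdown()`, `setJointProbability()`), with an independent
  inclusion–exclusion closed form (`inclusionClosedForm()`) that must agree
  rational-for-rational.
* **Allele statistics** — allele-loss probability `2(1/4)^m`
  (`geneLossProbability()`), the probability the sample keeps equal allele
  frequencies, `choose(2m, m)/4^m` (`equalAlleleFreqProbability()`), and the
  progeny inbreeding form `(p²+q²) + 2pq·F` implied by any sample
  (`progenyICFromSample()`).
* **A Monte Carlo oracle** — seeded, vectorised gene dropping that recovers
  every analytic value within sampling error (`simulateFSyn()`,
  `simulateStatistic()`).

## Worked example

```r
library(synvar)

syntheticIC(5, F = 0.5, l = 1)
#> Synthetic-variety inbreeding coefficient
#>   m = 5, F = 1/2, l = 1
#>   F_SynL        = 151/200 (0.755)
#>   l * F_SynL    = 151/200 (0.755)
```

Five plants of a half-inbred line leave the variety at inbreeding 0.755,
still above the large-sample limit (1+F)/2 = 0.75; the exact fraction
151/200 is carried, not a floating-point approximation. The classic grid of
per-line values over m and F:

```r
head(icTable(), 5)
#>   m e F0.0000 F0.5000 F0.7500 F0.8750 F1.0000
#> 1 1 1    0.75    0.88    0.94    0.97       1
#> 2 2 2    0.58    0.79    0.90    0.95       1
#> 3 3 3    0.53    0.76    0.88    0.94       1
#> 4 4 0    0.50    0.75    0.88    0.94       1
#> 5 5 1    0.51    0.76    0.88    0.94       1
```

How likely is a 15-plant sample to retain all four ordered genotypes, and
does simulation agree that a 2-plant sample keeps equal allele frequencies
with probability 3/8?

```r
ratRound(inclusionProbability(15, selfedLineArray()), 4)
#> [1] 0.9467

simulateStatistic("equal_freq", m = 2, nReps = 2e4, seed = 11)
#> SimResult [equal_freq]
#>   estimate = 0.374400 (SE 0.003422, n = 20000)
#>   analytic = 0.375000   z = -0.175
```

The same functionality is scriptable from a shell via the thin wrapper in
`inst/scripts/synvar`, e.g.
`Rscript inst/scripts/synvar inclusion --m 15 --array ga4` or
`Rscript inst/scripts/synvar ic-table --m-max 24 --format csv`.

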