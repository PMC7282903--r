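---
title: "Methods: allele capture, minimum collection sizes, and the conservation gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele capture, minimum collection sizes, and the conservation gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelecap)
```

## The problem

Living *ex situ* collections (botanic gardens, arboreta) are the only viable
genetic safeguard for plants whose seeds cannot be banked. Space is scarce,
so curators need to know (i) what fraction of a species' wild allelic
diversity their collection already holds, and (ii) the smallest collection
size that would hold a target fraction under good sampling. `allelecap`
answers both from diploid multilocus genotype tables — typically around ten
microsatellite loci scored on wild (*in situ*) and collection (*ex situ*)
individuals.

## Model and procedure

**Accounting.** All distinct alleles of the wild dataset are tabulated per
locus; missing genotypes are excluded from numerator and denominator, so
each locus keeps its own denominator of non-missing copies. A wild allele is
*captured* when it occurs at least once among the collection individuals at
the same locus; capture percentages pool alleles across loci (captured total
over existing total), never averaging per-locus ratios. Collection alleles
absent from the wild table are ignored: wild diversity is the conservation
target, so categories and denominators are frozen from the wild frequencies.

**Categories.** Frequency bands use strict inequalities: very common
(> 0.10), common (> 0.05), low frequency (< 0.10 and > 0.01), rare
(< 0.01), plus "all". They overlap by design (very common ⊂ common) and an
allele at exactly 0.10 is common only; one at exactly 0.01 is in no named
band. We read the band definitions literally rather than closing the
boundary gaps, because the boundaries are conventions, the behaviour is
documented, and the measure-zero boundary cases are decided one way for
every caller.

**Full vs reduced datasets.** The reduced dataset drops alleles with at most
2 copies in the wild sample (in 200 diploids, 2 copies is frequency 0.005);
such alleles are both hard to capture and possibly artefactual. The filter
uses wild copy counts only, and frequencies are *not* renormalized
afterwards: capture ratios are counts of alleles, so renormalization cannot
change any result, and keeping the original frequencies preserves the
category assignments.

**Resampling.** For each collection size $n$ from 2 to the wild sample size
$N$, the engine estimates the mean and SD (over replicates, default 75,000)
of the percent of alleles captured by $n$ individuals drawn without
replacement, pooled across populations. Implementation note: each replicate
draws one uniform permutation of the $N$ individuals and reads every $n$
off its prefixes — the size-$n$ prefix of a uniform permutation is exactly a
simple random sample, so per-size means and SDs are unchanged while the work
per replicate drops from $O(N)$ samples to one permutation (the kernel is in
C++ on R's RNG stream, so runs are bit-reproducible under a seed). Within a
replicate the grid points are correlated, which no reported statistic uses.

The closed form for one allele carried by $m$ individuals,
$P = 1 - \binom{N-m}{n}/\binom{N}{n}$, is exposed as
`expected_capture_oracle()` and kept strictly independent of the engine; the
test suite requires the two routes to agree within Monte-Carlo error.

**Sufficiency.** `minimum_sufficient_size()` returns the first grid size
whose *mean* capture strictly exceeds the target ("greater than", not
"at least"); 70% (GSPC Target 9) and 95% (the customary research goal) are
the default targets. A curve that never crosses — common for the rare band —
reports "not attainable" (`NA`), never a clamped size.

**The genetic conservation gap.** Two forms, per taxon and variant:
`gap_size_ratio` = (sufficiency at the collection's measured capture) /
(collection size); `gap_diversity_ratio` = (curve mean at the collection
size) / (measured capture). The size form uses the measured capture as its
target, not a fixed 95%. The diversity form is undefined when the collection
outnumbers the genotyped wild sample, because the curve's grid ends at $N$;
it is serialized as the literal `NA`. Ratios are computed from unrounded
capture values and only rounded (2 d.p.) for display, so table-text
arithmetic on rounded percentages may differ in the last digit.

**Attrition.** Minimum sizes refer to *surviving* plants;
`attrition_adjust(n, s) = ceiling(n / s)` converts a minimum size to the
number of propagules to collect when a fraction $s$ survives to adulthood
(82 plants at 10% survival → 820 seeds).

## Predictor statistics

Pairwise population differentiation uses Weir–Cockerham (1984) multilocus
$\theta$, as the ratio of summed variance components over alleles and loci
per population pair; the estimator is the field default, handles unequal
sample sizes, and may legitimately go slightly negative (retained, not
clamped — clamping would bias the mean-FST predictor upward). The spectrum
summaries report the proportion of alleles strictly below each cutoff
(default 0.001, 0.01, 0.05 — kept in ascending order). `log_capture_fit` is
OLS of percent captured on $\log(n)$ with adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-2)$; two points are accepted (an exact
interpolation with adjusted $R^2$ undefined, reported `NA`). `one_way_anova`
and `bh_adjust` are classical textbook implementations so that the test
suite can cross-check them against independent oracles rather than testing a
wrapper against itself.

## The synthetic world

The generator emulates the kind of dataset this analysis is designed for: a
threatened woody taxon, a handful of wild populations, ~10 microsatellites,
moderate structure, and a heavy rare tail.

- **Structure** uses the Balding–Nichols construction: per-locus ancestral
  frequencies follow a geometric profile (`decay`, default 0.7 — uneven, as
  microsatellite spectra are), and each population draws its frequency
  vector from a Dirichlet centred on the ancestral with concentration
  $(1-F)/F$. The $F$ parameter *is* the expected FST, giving a clean
  round-trip test: generate at $F$, estimate with WC84, recover within
  ±0.02. A coalescent simulator would be more realistic but adds no
  testable surface for this pipeline.
- **Hardy–Weinberg** holds within populations (two independent draws per
  individual per locus); the chi-square screen in the test suite checks it.
- **Rare tail.** Field datasets show on the order of 21% of alleles in 1–2
  copies; `shape_rare_tail()` converts single copies of well-represented
  alleles (≥ 4 copies, so the donor never drops into the rare band) into
  novel private alleles until that proportion crosses the target, warning
  and stopping at best effort when no donor remains.
- **Collections.** `simulate_ex_situ_collection()` offers random sampling
  (the idealized benchmark), single-population sampling, and maternal
  clusters (each mother contributes `cluster_size` open-pollinated
  offspring: one maternal allele plus one draw from her population's
  observed pool per locus). The biased strategies exist to demonstrate the
  capture penalty of real-world collecting; they ignore selfing, mutation
  and dispersal on purpose.

**What a green test does not establish.** The generator has no linkage, no
mutation model, no age structure, no clonality, and its missingness is
absent unless injected; real microsatellite data also carry genotyping
error. Green acceptance tests establish that the accounting, the engine, the
gap algebra and the estimators are correct on data whose truth is known —
not that any particular empirical dataset will show any particular capture
percentage.

## Numerical choices and edge cases

- Half-missing genotypes are normalized to fully missing (keeps per-locus
  copy counts even); the missing CSV cell is `-9/-9` by convention.
- Allele pairs are unordered within an individual; GenePop input carries no
  provenance flag, so its individuals default to `in_situ` (the wild dataset
  is the resampling substrate), overridable.
- A category with zero existing alleles reports `NA` (printed "NA"), never
  0% — 0% would claim a failure where there is nothing to capture.
- Curves store per-size replicate SDs so oracle agreement can be tested in
  standard-error units; means in `[0, 100]` exactly, grid point $N$ exactly
  100 for every non-empty category.
- Per-taxon RNG streams are derived from the master seed
  (`seed + 99991 * i mod 2^31 - 1`), so adding a taxon to a configuration
  never changes another taxon's numbers.
- Tests run at 2,000–5,000 replicates with fixed seeds; study-scale runs use
  75,000. The 3-standard-error oracle comparison is applied family-wise
  across the ~500 compared grid points (under 1% may exceed 3 SE, none 6 SE),
  since a literal per-point rule at that multiplicity rejects a correct
  engine with near certainty; grid points whose replicate SD is zero are
  checked against the Poisson resolution bound instead.

## Known limitations

Only diploid codominant data; no polyploids, no dominant markers, no
VCF/PLINK import. Resampling is by individuals pooled across populations —
resampling by number of populations is a different design question and out
of scope, as are duplication/backup sizing and heterozygosity or rarefied
allelic-richness metrics. FST is the only differentiation statistic. The
maternal-cluster simulator is deliberately minimal.
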