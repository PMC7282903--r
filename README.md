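# allelecap

Allele-capture accounting and optimization for *ex situ* conservation
collections.

Botanic gardens and arboreta safeguard threatened plants — especially
"exceptional" species whose seeds cannot be banked — as living collections.
Two questions decide whether such a collection actually protects a species'
genetic diversity:

1. **How much wild genetic diversity does the collection hold today?**
   Measured as the percentage of distinct *in situ* (wild) alleles present in
   at least one *ex situ* (collection) plant.
2. **How much could a collection of a given size hold under ideal random
   sampling of the wild populations?** Estimated by Monte-Carlo resampling of
   the wild genotype dataset over every possible collection size.

`allelecap` implements both calculations for diploid multilocus genotype data
(typically ~10 microsatellite loci per taxon), plus the summary statistics a
comparative analysis needs.

## The statistics

For an allele carried by $m$ of $N$ genotyped wild individuals, a random
collection of $n$ individuals (without replacement) captures it with
probability

$$P_{\text{capture}}(m, n, N) \;=\; 1 - \binom{N-m}{n}\Big/\binom{N}{n},$$

and the expected percent captured over an allele set is the mean of these
probabilities × 100. The package estimates the full capture-vs-size curve by
Monte-Carlo resampling (default 75,000 replicates) and verifies it against
this closed form, which is also exported as `expected_capture_oracle()`.

Derived quantities:

- **Categories.** Alleles are classified from their wild frequencies with
  strict inequalities: very common (> 0.10), common (> 0.05), low frequency
  (0.01–0.10 exclusive), rare (< 0.01), and "all". The *reduced dataset*
  excludes alleles seen in only 1–2 copies (likely transient or genotyping
  artefacts); the *full dataset* keeps everything.
- **Sufficiency** ($N_i$): the smallest $n$ whose mean capture strictly
  exceeds a target (70% after GSPC Target 9, and 95%).
- **Genetic conservation gap**: either the proportion of the current
  collection size that random sampling would need for the same capture
  (`gap_size_ratio`), or the proportional capture increase possible at the
  same size (`gap_diversity_ratio`).
- **Predictors**: pairwise Weir–Cockerham (1984) multilocus $\theta$
  (`pairwise_fst_matrix`), allele-frequency-spectrum tails
  (`spectrum_summaries`), log-size regression (`log_capture_fit`), one-way
  ANOVA and Benjamini–Hochberg adjustment.
- **Synthetic data**: a Balding–Nichols generator
  (`generate_structured_population`) whose $F$ parameter maps onto expected
  FST, with `shape_rare_tail()` to inject the heavy 1–2-copy tail real
  datasets show, and `simulate_ex_situ_collection()` for random,
  single-population, and maternal-family acquisition strategies.

## Worked example

```r
library(allelecap)

# a synthetic taxon: 3 wild populations x 12 plants, 10 microsatellites,
# FST 0.15, 21% of alleles in 1-2 copies
wild <- generate_structured_population(
  synthetic_spec(n_populations = 3, n_per_pop = 12, n_loci = 10,
                 n_alleles = 12, target_fst = 0.15, decay = 0.45,
                 rare_tail_target = 0.21, seed = 8))

# a garden collection of 12 plants, all sampled from a single population
garden <- simulate_ex_situ_collection(wild, "single_population", n = 12, seed = 2)

wild_alleles <- tabulate_alleles(wild, "in_situ")
capture_percentages(wild_alleles, garden)
#>        category n_existing n_captured  percent
#> 1           all         47         34 72.34043
#> 2   very_common         28         26 92.85714
#> 3        common         35         30 85.71429
#> 4 low_frequency         19          8 42.10526
#> 5          rare          0          0       NA

curve <- resample_capture_curve(wild, replicates = 5000, seed = 21)
minimum_sufficient_size(curve, 95, "all")
#>   category threshold minimum_size attainable variant
#> 1      all        95           27       TRUE    full

# the collection gap: random sampling of 12 wild plants would hold
# 1.15x the diversity this single-population collection holds
gap_diversity_ratio(curve, current_n = 12, current_capture_percent = 72.34043)
#> [1] 1.149012
```

So this 12-plant, one-population collection holds 72% of wild alleles
overall but only 42% of the low-frequency ones; 27 randomly sampled wild
plants would be needed to exceed 95% capture, and 12 random plants would
already hold ~83% (1.15 × 72%).

End-to-end runs (per-taxon capture tables, curves, sufficiency, gap tables,
FST and spectrum summaries, manifest) are driven by `run_full_analysis()`
with `analysis_config()` or a YAML file; a command-line front end is in
`inst/cli/allelecap.R`.

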