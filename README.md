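# pardassess

Conservation-genetic assessment of small, fragmented populations from
reduced-representation SNP panels — an R package built around the workflow
used for island/peninsula bird systems such as the endangered forty-spotted
pardalote: a handful of sampled populations, uneven sample sizes, a
DArT-style biallelic SNP report, and five management questions:

1. **How clean is the panel?** A QC cascade filters SNPs by technical
   repeatability, monomorphism, call rate, secondary SNPs on one sequence
   tag (keeping the highest polymorphic information content,
   `PIC = 1 − (p² + q²) − 2p²q²`), per-individual call rate, and
   near-duplicate sequence tags (Hamming distance), with an auditable
   retention log.
2. **How much diversity, how much divergence?** Per-population Ho, He,
   F_IS (with Nei's small-sample Hs and bootstrap CIs) and pairwise
   Weir–Cockerham θ (variance components a, b, c; ratio of sums over loci)
   with bootstrap CIs and permutation p-values.
3. **How many genetic units?** PCoA, k-means + BIC cluster selection,
   DAPC, and a Gibbs sampler for the admixture model (independent or
   correlated-frequency F-model priors, `α = 1/K` default) with Evanno
   ΔK model choice and CLUMPP-style alignment/averaging of replicate runs.
4. **Who moved?** Leave-one-out self-assignment to reporting units under
   HWE likelihoods with a Dirichlet (1/2 per allele) frequency prior, and
   migrant counting at a posterior threshold — giving per-population
   immigration rates.
5. **How big are the populations, genetically, and what should we
   protect?** Single-sample LD effective population size (Burrows
   composite r², Waples bias correction, random-mating and monogamy
   inversions, Pcrit screening, jackknife CIs) and prioritisation by
   rarefied allelic richness (hypergeometric, standardised to g gene
   copies), per-population contribution `CT_i = (AR(t) − AR(−i))/(AR(t) − 1)`,
   and exact maximum-coverage selection of the best k-population network.

A synthetic-data module (`simulate_fmodel`, `simulate_wf`,
`inject_migrants`, `add_technical_replicates`, `preset_pardalote`)
generates Balding–Nichols and forward Wright–Fisher data with known truth,
so the whole chain is verifiable without any field data.

## Worked example

Simulate a study-shaped archipelago (six populations, sizes 79/25/113/16/12/3,
one drifted isolate, six immigrants into the 25-bird peninsula sample),
filter it, and ask who moved:

```r
library(pardassess)
cfg <- preset_pardalote(n_loci = 500)
sim <- simulate_fmodel(cfg, seed = 1)
mig <- attr(cfg, "migration")
sim <- inject_migrants(sim, mig$from, mig$to, mig$n)

gm  <- filter_cascade(sim$gm)
filter_log(gm)[, 1:4]
#>                  step   parameters loci_before loci_after
#> 1       repeatability min_rep=0.95         500        500
#> 2         monomorphic                      500        500
#> 3      locus_callrate  min_cr=0.95         500        499
#> 4         secondaries                      499        499
#> 5 individual_callrate   min_cr=0.9         499        499
#> 6             hamming min_dist=0.2         499        499

ar <- loo_self_assign(gm, sim$popmap)
count_migrants(ar, sim$popmap)$rates
#>   population   n migrants immigration_rate
#> 1      Maria  79        0        0.0000000
#> 2 NorthBruny 113        0        0.0000000
#> 3  Partridge  12        0        0.0000000
#> 4 SouthBruny  16        0        0.0000000
#> 5  Southport   3        2        0.6666667
#> 6  Tinderbox  25        6        0.2400000
```

All six injected immigrants into Tinderbox are recovered (a 24%
immigration rate) with no false positives in the larger populations; the
three-bird Southport sample behaves exactly as tiny baselines do —
its birds cross-assign to the neighbouring southern populations. Ne
estimation and prioritisation run the same way:

```r
wf  <- simulate_wf(sim_config("P", 50, census_n = 100, n_loci = 2000),
                   generations = 50, seed = 1)
estimate_ne(wf$gm, pcrit = 0.05, mating = "random")
#> LD Ne estimate (random mating, Pcrit = 0.05)
#>   S = 50 individuals, 1607 loci, 1290421 pairs (harmonic-mean S 50.0)
#>   mean r2 = 0.025330, E[r2|S] = 0.021276, adjusted = 0.004054
#>   Ne = 80.1  (95% CI 63.3-108.4)

prioritise(gm, sim$popmap, n_std_individuals = 12, scenarios = 1:3)
```

`run_pipeline(gm, popmap, pipeline_config(...), out_dir = "report/")`
chains every stage (filter → diversity/θ → structure scan → assignment →
Ne → prioritisation) under one seed hierarchy and writes tab-separated
tables plus a provenance JSON. See the methods vignette
(`vignettes/genetic-assessment-methods.Rmd`) for the models, priors,
defaults and their rationale.

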