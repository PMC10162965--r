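---
title: "Methods: conservation-genetic assessment of fragmented populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation-genetic assessment of fragmented populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pardassess` implements the standard analysis chain for assessing the
genetic health of small, fragmented vertebrate populations genotyped on a
reduced-representation SNP panel (DArT-style or VCF): quality-control
filtering, diversity and differentiation statistics, population-structure
inference, migrant identification, effective-population-size estimation,
and genetic conservation prioritisation. This vignette records the models,
the tunable parameters, and the numerical and design choices, so that every
number the package produces can be traced to a stated assumption.

## Data model

Genotypes are biallelic SNP dosages: 0, 1, 2 copies of the alternate
allele, or missing. A `genotype_matrix` stores the loci x individuals
dosage matrix plus per-locus metadata used by the filters: the trimmed
sequence tag the SNP was called from, the clone id grouping "secondary"
SNPs from one tag, the call rate, and the technical-replicate
repeatability. A `pop_map` assigns each individual to a sampled population
and each population to a reporting unit (used by the assignment stage).
Missing calls use one sentinel (`NA`) across all input dialects;
half-missing VCF genotypes are treated as missing because their dosage is
undefined.

## Filter cascade

The QC cascade mirrors standard practice for reduced-representation
panels, in this order: repeatability >= 0.95, removal of monomorphic loci,
per-locus call rate >= 0.95, one SNP per sequence tag (keeping the highest
polymorphic information content, `PIC = 1 - (p^2+q^2) - 2p^2q^2`, first
listed on ties), per-individual call rate >= 0.90, and removal of loci
whose tags are too similar (proportional Hamming distance < 0.2, dropping
the lower-call-rate locus of each offending pair, iterated to closure).
Choices worth stating:

* Thresholds retain at the boundary (>=); this matches the behaviour of
  the widely used filtering toolchains even where method sections print
  strict inequalities.
* All-missing loci are vacuously monomorphic and dropped: no frequency is
  defined for them.
* Tags of unequal length are compared over the shorter length, making the
  distance deterministic.
* The Hamming drop rule (lower call rate first, then later file position)
  is a package convention; the literature rarely states one.
* A minor-allele-frequency screen (`filter_maf`, the `Pcrit` of the Ne
  stage) and an LD pruner (`filter_ld`) are separate functions because
  different stages need them at different settings.

Every filter is pure, idempotent, and appends a row to a retained-counts
log, so a cascade can be audited after the fact.

## Diversity and differentiation

Observed heterozygosity is the heterozygote fraction; expected
heterozygosity is reported as unadjusted gene diversity `He = 2p(1-p)`
(with small samples He can drop below Ho, which is the convention of the
standard basic-statistics tables). Inside the inbreeding coefficient,
however, `F_IS = 1 - mean(Ho)/mean(Hs)` uses Nei's small-sample-corrected
gene diversity `Hs = n/(n-1) (2p(1-p) - Ho/2n)`, keeping F_IS consistent
with the population-genetics convention. Confidence intervals are
percentile bootstraps over loci (default 100 replicates, seeded).

Differentiation is Weir and Cockerham's theta: per-locus variance
components `a` (among populations), `b` (among individuals within
populations), `c` (within individuals), combined as a ratio of sums across
loci. Loci unusable in a pair (fewer than 2 calls in either population, or
monomorphic across both) are skipped. Pairwise p-values permute
individuals between the two populations (the test the field's tables
imply but rarely name); the permutation count is configurable and the
p-value uses the add-one correction, so its floor is `1/(n_perm+1)`. The
test suite pins theta to an independent allele-level nested-ANOVA
implementation at 1e-10.

## Population structure

*Ordination.* PCoA on Euclidean distances of mean-imputed, column-centred
dosages (classical MDS with Gower centring). Mean imputation is used only
here and in DAPC/k-means, which need a complete matrix; model-based stages
skip missing calls instead. Negative eigenvalues are reported but excluded
from percent-variance.

*Cluster number by BIC.* k-means on retained principal components for
`K = 1..k_max`, scored by `BIC(K) = n log(WSS_K/n) + K log(n)`. The
default retains `min(n/2, 40)` components deliberately: with too few
retained dimensions, splitting unstructured noise reduces within-cluster
variance by roughly `K^(-2/d)` and outruns the `K log(n)` penalty, so the
criterion over-splits; keeping `d` of order `n/2` makes noise splits
unprofitable while real clusters still dominate the first axes.

*DAPC.* PCA reduction (default `min(n/3, 40)` axes, a standard overfitting
guard) followed by linear discriminant analysis; memberships are the
Gaussian class posteriors on the discriminant axes. When groups are
perfectly separated the within-group covariance collapses and the LDA is
regularised with a deterministic hair of noise (1e-3 of the overall
standard deviation).

*Admixture model.* A Gibbs sampler for the standard admixture model:
memberships `q_i ~ Dirichlet(alpha)`, cluster allele frequencies `p_kl`,
and latent origins for every allele copy. Frequencies follow either
independent Beta(1,1) priors or the correlated F-model,
`p_kl ~ Beta(p^A_l (1-F_k)/F_k, (1-p^A_l)(1-F_k)/F_k)`, with ancestral
frequencies `p^A` (uniform prior) and per-cluster drift `F_k` updated by
Metropolis steps (proposal sd 0.05 and 0.01; `F_k` prior centred at 0.01
with sd 0.05, following the original model description). `alpha` defaults
to `1/K`, the recommended setting for unbalanced samples, and can instead
be cluster-specific with Metropolis updates (the alternative ancestry
prior). Model evidence is estimated as `ln P(X|K) = mean(lnL) -
var(lnL)/2` over retained iterations. Defaults are desk-scale - burn-in
2,000 and 5,000 retained iterations - because the package's accuracy
checks are parameter-recovery tests on data of desk-scale size; users
reproducing production runs simply raise both (the classical setting is
100,000/100,000). The per-copy origin update is the hot loop and is
implemented in C++ (drawing from R's RNG, so runs are seed-reproducible).

*Choosing K and averaging runs.* The Evanno table reports, per K, the mean
and sd of `ln P(X|K)` over replicate runs, the first and absolute second
differences, and `deltaK = |L''(K)| / sd(L(K))`; endpoints have no deltaK
and a zero sd leaves it undefined rather than infinite. Replicate runs are
aligned CLUMPP-style: each run's columns are permuted to maximise the
trace against the first run (exact search over K! permutations, fine for
K <= 8), then averaged and renormalised.

## Migrant identification

Leave-one-out self-assignment: for each individual, every candidate
collection's allele frequencies are posterior means under a Dirichlet
prior with weight 1/2 per allele (the default of the standard assignment
framework), recomputed without the focal individual when scoring its own
collection - self-inclusion otherwise biases the home likelihood upward,
and a test asserts that inequality. Genotype likelihoods assume
Hardy-Weinberg proportions per locus and skip missing loci (the likelihood
factorises). Collection likelihoods are normalised and summed into
reporting-unit posteriors. Collections below 2 individuals are excluded as
candidate sources. A bird sampled in A whose top unit is B with posterior
>= 0.9 counts as a migrant B to A; 0.9 operationalises the informal
"probabilities near 1" convention and is configurable. The immigration
rate into A is migrants over A's sample size.

## Effective population size (LD method)

The single-sample bias-corrected linkage-disequilibrium method. The pair
statistic is the squared Burrows composite-disequilibrium correlation for
unphased diploids:

* `Delta = (S/(S-1)) (mean(xy)/2 - 2 p_x p_y)` over the jointly observed
  individuals,
* `r^2 = Delta^2 / ((p_x(1-p_x)+D_x)(p_y(1-p_y)+D_y))`, `D` the
  within-locus Hardy-Weinberg disequilibrium.

This exact form matters: the published sampling-bias curves
(`E[r^2|S] = 1/S + 3.19/S^2` for S >= 30, `0.0018 + 0.907/S + 4.44/S^2`
below) were calibrated for this statistic, and we verified by simulation
that its no-LD expectation matches the curve within ~0.3% at S = 20-100,
whereas the plain squared Pearson dosage correlation sits ~3% low
(expectation near `1/(S-1)`), which propagates into a ~40% upward bias in
Ne on truth-100 simulations. `pair_r2(method = "pearson")` remains
available for comparison.

Rare alleles below `Pcrit` (0.02 or 0.05 in practice) are screened out
within the focal population first. All pair r^2 values are averaged with
pair-sample-size weights; the sampling expectation at the harmonic-mean S
is subtracted; and the adjusted r^2 is inverted to Ne with the published
constants - random mating `(1/3 + sqrt(1/9 - 2.76 r^2))/(2 r^2)` for
S >= 30 (0.308/2.08 below), monogamy `(2/3 + sqrt(4/9 - 7.2 r^2))/(2 r^2)`
(0.618/5.24 below). Non-positive adjusted r^2 returns infinity: no
detectable drift signal. Confidence intervals use a delete-one-individual
jackknife on the adjusted r^2 mapped through the Ne formula; we jackknife
individuals rather than locus pairs because pairs sharing a locus are
strongly dependent. Physical linkage is ignored (no positions available on
reduced-representation panels), as the reference implementations do. Known
limitation: with S/Ne well below ~0.3 the signal shrinks toward the
sampling floor and estimates become upper-bound-like; the package reports
infinity rather than a spurious finite value when the adjusted r^2 is
non-positive.

## Conservation prioritisation

Allelic richness per locus is rarefied to a standardised sample of `g`
gene copies (default 2 x 25 individuals) by hypergeometric inclusion
probabilities, `AR = sum_a [1 - C(N-N_a, g)/C(N, g)]`, computed on the
log-gamma scale. At loci where missing data leaves a population below `g`
copies, all populations are rarefied at the per-locus minimum count, which
keeps the comparison standardised under missingness; loci with an empty
population are skipped. The contribution of population i to total richness
is `CT_i = (AR(t) - AR(-i))/(AR(t) - 1)`.

Reserve-type selection ("which k populations best represent the species'
allelic diversity") is solved by exact enumeration of all `C(n, k)`
subsets with equal unit costs, maximising the count of covered alleles -
with at most a handful of sampled populations the optimum is certain, so a
stochastic optimiser would add noise without generality. Ties prefer
higher summed within-population frequencies of the covered alleles, then
earlier-listed populations. "Allele" means each SNP allele observed at
least once in the filtered panel, so monomorphic-within-panel loci
contribute one covered allele by construction.

## Synthetic data: what it does and does not emulate

The generator exists so every stage has a ground truth.

* `simulate_fmodel`: Balding-Nichols structure. Ancestral frequencies
  `Uniform(0.05, 0.95)`; population frequencies Beta-distributed around
  them with per-population drift F; genotypes binomial. This reproduces
  the differentiation geometry of an archipelago of partially isolated
  populations (Weir-Cockerham theta recovers the configured F), plus
  missing data, technical-replicate error, spiked monomorphic and
  low-call-rate loci for the filters, and injected migrants with recorded
  identities. It generates *no* background LD, which matches the
  assumptions of the structure, assignment and rarefaction stages but
  makes it useless for Ne.
* `simulate_wf`: a forward Wright-Fisher population (constant census N,
  non-overlapping generations, unlinked loci, no mutation; monogamy pairs
  the population each generation). Drift builds genuine inter-locus LD -
  this is the truth source for the Ne estimator. Fifty generations is the
  default because LD among unlinked loci equilibrates within a few tens of
  generations while heterozygosity losses stay moderate.
* The study-shaped preset (`preset_pardalote`) fixes six populations with
  sample sizes 79, 25, 113, 16, 12, 3, one strongly drifted isolate
  (F = 0.20) and two weakly diverged southern clusters (F = 0.03-0.06),
  with 6 immigrants in the 25-bird peninsula sample (a 24% immigration
  rate) - the sampling structure of the motivating field system. Nuisance
  defaults (2% missing calls, 1% replicate error) are typical of
  post-QC reduced-representation panels.

What passing tests on these data do *not* show: robustness to genotyping
error that is structured by locus or by batch, to null alleles, to
physical linkage, or to continuous (isolation-by-distance) structure
rather than discrete clusters. Real-data behaviour on those axes has to be
judged against the literature of the underlying methods.

## Verification scale and reproducibility

The automated checks run at desk scale, chosen to finish in minutes on one
CPU while leaving comfortable signal: Ne recovery uses Wright-Fisher truth
Ne = 100 with S = 50 and 2,000 loci over 20 replicates (median within
15%); structure recovery uses 3 clusters of 20 at F = 0.2 with 150 loci, a
5 x 5 run grid at 2,000/5,000 MCMC iterations (Evanno argmax and BIC both
3, membership accuracy >= 90%); migrant recovery injects 6 immigrants into
a 25-bird sample at F = 0.2 over 10 seeds (exact recovery, no false
positives). Closed-form oracles (exhaustive rarefaction enumeration, exact
reserve-selection brute force, ANOVA theta) are checked at machine-level
tolerances. All stochastic stages take explicit integer seeds; the
pipeline derives per-stage sub-seeds from one global seed, so reports are
byte-reproducible.
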