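---
title: "Methods: population and landscape genetics of a pond-breeding amphibian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population and landscape genetics of a pond-breeding amphibian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popland)
```

`popland` implements the complete analysis chain used to characterize a
network of amphibian breeding sites genotyped at microsatellite loci: data
screening and sibling pruning, diversity and differentiation statistics,
linkage-disequilibrium effective population size, bottleneck diagnostics,
Bayesian individual assignment, circuit-theory landscape resistance, and
matrix-based landscape-genetic inference. The motivating system is the
Arizona treefrog (*Hyla wrightorum*) in the Huachuca Mountains and Canelo
Hills of southeastern Arizona: roughly ten breeding ponds within an
~85 km² area, sampled as a mix of adults and larval full-sib broods at 17
polymorphic microsatellites. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions behind the
implementation.

## Genotype data and screening

A `genotype_dataset` stores diploid allele-size calls (integer fragment
sizes), a population label and a life stage per individual. Two
conventions matter downstream:

* **Missingness is per locus.** A half-called genotype is treated as fully
  missing — conservative, and standard for fragment data. Individuals
  missing more than 25% of loci (`filter_missing`, `max_missing = 0.25`)
  are discarded, mirroring the usual multi-attempt genotyping protocol.
* **Sites too small for population-level statistics are dropped whole**
  (`exclude_small_pops`). The default threshold of 10 reproduces the
  study-design split in which sites of 5 and 1 individuals were excluded
  while a site of 19 was kept; any threshold in (5, 19] gives the same
  split.

GenePop is the exchange format (2- or 3-digit alleles, auto-detected);
life stage and site coordinates travel in sidecar CSVs because the format
cannot express them.

Marker screens are the standard pair: an exact test of Hardy–Weinberg
proportions per population × locus (probability-ordering test conditional
on allele counts; full enumeration where the table space is small, Monte
Carlo pairing of the gene pool otherwise) and a G-statistic permutation
test of linkage disequilibrium per population × locus pair. Both screens
report Bonferroni flags with the family size equal to the number of tests
actually performed (`0.05 / m`).

## Sibling pruning

Larval samples inflate differentiation through family structure, so full
sibs are pruned to one representative per family. Full-pedigree MCMC
samplers exist for this task; `popland` deliberately ships a lighter
behavioral stand-in:

1. For every pair of larvae in a population, the likelihood ratio of
   *full-sib* versus *unrelated* is computed from population allele
   frequencies using the Mendelian IBD mixture (¼, ½, ¼), skipping
   missing loci.
2. Pairs whose mean per-locus log-LR exceeds `llr_threshold` are linked;
   families are the single-linkage components.
3. `prune_to_one_per_family` keeps the member with the least missing data
   (ties to the lowest id). Adults are never grouped or pruned.

Two numerical choices were calibrated against simulated pedigrees before
the test suite was frozen. First, allele frequencies enter the likelihood
as posterior means with a 1/k pseudocount, because raw sample proportions
let a rare allele observed only in the compared pair dominate the ratio.
Second, the default `llr_threshold = 0.15` sits at roughly the 99.9th
percentile of the log-LR distribution for truly unrelated pairs at
study-like diversity (17 loci, expected heterozygosity ≈ 0.65–0.75); about
90% of true full-sib edges exceed it, and single-linkage closure
consolidates those edges into near-complete family recovery. The naive
`LR > 1` rule (threshold 0) admits enough chance matches to merge
unrelated larvae into spurious families. The stand-in recovers family
*partitions* well but is not a pedigree sampler: published family-count
tables are used in the package only as sampling-design shapes, never as
values this algorithm is expected to reproduce.

## Diversity statistics

* Observed heterozygosity `Ho` is the fraction of heterozygous genotypes
  among called individuals.
* Expected heterozygosity `He` is Nei's unbiased gene diversity,
  `2n/(2n-1) * (1 - sum p^2)`.
* Allelic richness is rarefied by the exact hypergeometric formula on gene
  counts, `AR = sum_a [1 - C(N - n_a, g)/C(N, g)]` — deterministic, no
  resampling — with `g` defaulting to the smallest per-locus called gene
  count across populations.
* `FIS` is the Weir–Cockerham small-sample `f`, combined across loci and
  alleles by summing variance components.

## Differentiation

Global and pairwise differentiation use the Weir–Cockerham variance
components, with the multi-locus estimator formed as a ratio of summed
components (not a mean of ratios), and negative estimates retained.
Pairwise significance bootstraps loci: `p` is the fraction of replicates
at or below zero, flagged at `0.05/28` for eight sites. Hedrick's
standardized `G'ST` divides `GST` by its maximum
`((k-1)(1-HS))/(k-1+HS)`, averaging `HS` and `HT` over loci before the
ratio. `Dps` is one minus the mean over loci of population
allele-frequency overlap `sum_a min(p_a, q_a)` — the population-level
variant, matching the convention of the classic microsatellite toolkits.
Slatkin's linearized transform `FST/(1-FST)` is applied cell-wise.

The two-level AMOVA partitions gene-level variance into among-population,
among-individual-within-population, and within-individual components via
nested variance components on allele indicator variables (the
allele-identity distance), with unequal-size coefficients. Significance
permutes individuals among populations (among-population level) and gene
copies among individuals within populations (inbreeding level).

## Effective population size

`ldne` implements the single-sample linkage-disequilibrium method:
Burrows composite disequilibrium `r²` averaged over allele pairs of all
locus pairs (alleles rarer than `pcrit = 0.02` excluded; per-pair complete
cases with the comparison-weighted harmonic-mean sample size), corrected
by the expected sampling contribution (`1/S + 3.19/S²` for `S ≥ 30`, the
small-sample polynomial otherwise) and inverted through the random-mating
drift expectation (the published quadratic with the negative
discriminant). When the corrected `r²` is non-positive the estimate is
infinite — drift is indistinguishable from sampling noise.

Design choices settled empirically against a Wright–Fisher oracle:

* The confidence interval jackknifes **whole loci** (each deletion removes
  the block of correlated locus pairs sharing that locus) and converts the
  jackknife variance to chi-square degrees of freedom. Deleting single
  locus pairs ignores their correlation and under-covers badly (≈69%
  measured coverage versus ≈93% for locus blocks at true Ne = 50).
* The companion simulator's default mating is ideal monoecious
  Wright–Fisher with random selfing — the model under which the bias
  corrections were calibrated — with `selfing = FALSE` available for
  biological realism.

The hierarchical total over a structured set of sites is
`Total Ne = (sum of local Ne) / (1 - FST)`, applied separately to point
estimates and both CI bounds, with infinite local entries replaced by a
cap of 10,000 before summation.

## Bottleneck tests

A recent bottleneck leaves a transient signature: allele count drops
faster than gene diversity, so observed `He` exceeds its equilibrium
expectation given `k`. For each locus the equilibrium distribution of
`He` conditional on the observed allele count and gene sample size is
simulated under the infinite allele model. Rather than rejection-sampling
a coalescent over the mutation parameter, `popland` samples the
allele-size partition directly from the Ewens sampling formula
conditioned on `k` — the same law, exact and fast, via a Stirling-number
sequential construction (`esf_he_conditional`). The geometric-step
variance parameter of the two-phase model is accepted for interface
parity but is inert at a 100% IAM fraction.

Loci are combined with a one-tailed Wilcoxon signed-rank test for excess.
One calibration detail is deliberate: the classical standardized
difference `DH = (He_obs - mean)/sd` has mean zero but is left-skewed
under the exact null (its median reaches +0.24 at high diversity), which
makes a signed-rank test on `DH` anticonservative (≈15% rejection at
α = 0.05 in our measurements). The test therefore ranks each locus's
`He_obs` within its simulated equilibrium distribution and applies the
Wilcoxon to the centered conditional quantiles, which are uniform — hence
symmetric — under the null. `DH` is still reported per locus. Measured
null rejection is 0.041 over 1,000 equilibrium datasets; power against a
95% crash is essentially 1 at n = 30 with 17 loci.

The mode-shift diagnostic pools alleles across loci into ten frequency
classes of width 0.1 and declares a shift when the rarest class (0–0.1)
is not the mode.

## Individual assignment

`rm_likelihood` scores a multilocus genotype against a population with
the Bayesian posterior-predictive formula: Dirichlet(1/k) prior on allele
frequencies (k = alleles known at the locus dataset-wide), sequential
predictive for the two genes, missing loci skipped, and leave-one-out
counts when scoring an individual against its own sampled population.
Unseen alleles retain prior mass, so likelihoods are always finite.

`assign_all` assigns each individual to its maximum-likelihood population
(ties broken toward the sampled population) and computes per-population
exclusion probabilities by ranking the individual's likelihood within
`mc_individuals` genotypes simulated from the population's posterior
predictive — for the home population, simulated and scored against the
same leave-one-out counts, so resident exclusion probabilities are
approximately uniform. They are not exactly uniform: with ~30 individuals
the Dirichlet posterior understates frequency uncertainty and the lower
tail is mildly inflated (a property shared by the classical
implementation of this test). Individuals excluded everywhere
(`threshold = 0.05`) are flagged `"Other"` — candidate migrants from
unsampled sources, the `L_home` criterion.

## Landscape resistance

Resistance surfaces encode four gene-flow hypotheses on a 1–100 scale:
uniform (isolation by distance), linear in slope (steep = resistant),
reverse-linear in canopy (closed canopy = permeable), and binary around
streams (1 within a 100 m buffer, 100 outside). The study's rasters are
30 m; `build_surface` is resolution-agnostic.

`effective_resistance` treats the lattice as a resistor network: node per
cell, neighbor conductance equal to the mean of the two cells'
conductances (1/resistance), diagonal neighbors divided by √2, an
eight-neighbor scheme by default. Pairwise effective resistance comes
from solving the grounded sparse Laplacian (Cholesky, one solve per site
column): `R_ij = x_ii + x_jj - 2 x_ij`. This matches the dense
pseudo-inverse identity `R = L⁺_ii + L⁺_jj - 2 L⁺_ij` to below 1e-8 in
the tests. Sites snap to the nearest cell center; nodata placement is an
error; disconnected pairs are flagged infinite. Collinearity between
resistance matrices is screened with Pearson r on lower triangles at the
0.7 threshold; flagged pairs never enter the same model.

## Matrix inference

Simple Mantel tests correlate lower triangles with one-tailed
significance over simultaneous row/column permutations
(`p = (count+1)/(permutations+1)`, never zero; 9,999 permutations by
default). Partial Mantel residualizes both matrices on the covariate and
permutes the residualized predictor matrix (the residual-permutation
method). A covariate identical to a matrix annihilates it; the partial
association is then zero by convention rather than undefined. The
causal-model table crosses every predictor with every controlling
covariate, the grid used to separate correlated landscape hypotheses.

The MLPE (maximum-likelihood population effects) model regresses a
pairwise response on mean-centered pairwise predictors with the error
structure induced by an additive random effect per site:
`cor(e_ij, e_kl) = ρ` when the pairs share exactly one site. One algebraic
point: on a complete pairwise design the correlation matrix `I + ρA` is
positive definite only for `ρ < 1/2` (the share-one-site adjacency has
minimum eigenvalue −2), so ρ is profiled by golden-section search on
(0, 0.5) — not (0, 1) — with the boundary ρ = 0 (ordinary least squares)
checked explicitly. Model comparison uses AICc and BIC with the number of
site pairs as the effective sample size (an acknowledged approximation:
pairs are dependent) and `R²β`, computed from the Wald F of the fixed
effects against the intercept-plus-random-effect null under the ML fit —
the ML-scaled variant of the statistic, chosen because no
denominator-degree-of-freedom machinery is available or needed at this
scale.

## The synthetic generator

`simulate_metapopulation` runs a forward-time diploid Wright–Fisher
metapopulation with stepwise-mutating microsatellites to quasi-equilibrium
(default `10 × deme Ne` generations) and draws the study-style sample:
adults as independent draws from the final generation, larvae as full-sib
broods of size `1 + Poisson(λ)` from parent pairs drawn without
replacement within a site (so distinct broods are unrelated — the family
partition the sibship filter assumes). Missing calls are injected at 2%.

Defaults emulate the motivating study's conditions: 10 sites with the
published per-site adult/larva counts (299 individuals, 82 adults), 17
loci, deme size 100, per-site brood-size means following the published
family table, and migration derived from landscape resistance
(`m_ij ∝ 1/R_ij`, row-normalized to a total emigration rate of 0.06 —
chosen so the realized global FST sits near the observed 0.04). The
mutation rate default of 1.25e-3 puts the stepwise-mutation equilibrium
heterozygosity at the study's observed 0.67–0.74 (metapopulation
θ ≈ 5); rates of this size are standard for microsatellites. A
four-deme island-model configuration reproduces the finite-deme island
closed form `FST = 1/(4Nm(d/(d-1))² + 1)` within a few percent.

`simulate_landscape` produces Gaussian-blurred random fields for slope
and canopy, a multi-channel random-walk stream network (several channels
in alternating orientations, so corridor structure is not simply a proxy
for distance), and spaced site coordinates. The generator's synthetic
rasters default to 120 m cells over extents honoring a 7 km margin —
resolution chosen so lattice solves stay desk-sized; `build_surface`
accepts the study's 30 m convention unchanged. An optional
canopy-from-distance mode reproduces the canopy–distance collinearity
confound observed in the real landscape, and the screen flags it.

What the generator does *not* emulate: genotyping error and null alleles,
selection, pond hydrology and temporal variation in deme sizes, and
half-sib family structure. Passing recovery tests on this generator
therefore demonstrates correctness of the estimators under their own
model assumptions, not robustness to those real-data complications.

## Simulation sizes used by the automated checks

The package's property checks run at these sizes, chosen as the smallest
that leave the conclusions statistically unambiguous: LD-Ne recovery at
200 Wright–Fisher replicates (true Ne 50, sample 50, 17 loci);
bottleneck null calibration at 1,000 equilibrium datasets with 200
conditional replicates per locus; MLPE slope recovery at 60 replicates
and model selection over 30 independent landscape realizations with a
clear isolation-by-distance signal (`R²β ≈ 0.6`). At study-strength
signal (`R²β ≈ 0.3`) AICc model selection with correlated predictors is
only ~75% accurate on 28 pairs — a real limitation of information-
criterion selection at this design size, worth remembering when reading
such model tables.

## Known limitations

* The sibship stand-in is pairwise + single linkage; it does not jointly
  infer parentage and can split large low-diversity families.
* Exclusion probabilities in the assignment test are mildly
  anticonservative for small samples, as discussed above.
* LD-Ne assumes unlinked loci and closed random-mating populations;
  migration inflates and admixture deflates estimates (the package's
  mixture-bias test demonstrates the latter), and the hierarchical total
  only partially compensates.
* Mantel-family tests have known inflated type-I error under spatial
  autocorrelation; the MLPE route is the primary inference and the
  causal-modeling grid is diagnostic.
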