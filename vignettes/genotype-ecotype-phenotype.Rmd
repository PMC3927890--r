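---
title: "Linking genotype, ecotype and phenotype in a managed bear population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking genotype, ecotype and phenotype in a managed bear population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogenlink)
```

## The scientific problem

In intensively managed wildlife populations, three layers of individual
variation are routinely collected but rarely analysed together: multilocus
genotypes (here, 15 diploid microsatellites), habitat-use profiles derived
from GPS collars (proportions of fixes over 7 land-cover classes), and
fitness-proxy morphometrics (mass, straight-line body length, body
condition). `ecogenlink` implements the full chain of analyses that connects
them for a grizzly-bear-style study system:

1. **Clustering**: ecotypes from habitat use (simulated-annealing K-means,
   selected by pseudo-F and a spherical-Gaussian BIC) and genetic clusters
   from genotypes (admixture-model Gibbs sampling, selected by the Evanno
   delta-K second-difference criterion), plus the Pearson correlation of the
   two assignment vectors.
2. **Individual-based isolation-by-ecology (IBE)**: Mantel and partial Mantel
   permutation tests among pairwise matrices — genetic similarity *G*
   (Queller–Goodnight relatedness and allele-sharing molecular coancestry),
   geographic distance *D*, a sex-combination matrix *S* (0 / 0.5 / 1), and
   ecological distances *E* (absolute differences of habitat-use PC scores).
3. **Heterozygosity–fitness correlation (HFC)**: Bayesian hierarchical linear
   models of log-mass, log-length and body condition with management-unit
   intercepts, compared by DIC, with homozygosity-by-loci (HL) as the focal
   covariate; a nested-OLS F-test checks whether an HL association is driven
   by a single locus.
4. **Management context**: translocation-history summaries and per-unit
   habitat-availability profiles, their chi-squared heterogeneity test, L1
   distances and a neighbor-joining tree.

Because no real data ship with the package, a first-class synthetic-data
module generates all inputs with known ground truth, and every claim the test
suite makes is a property of that stated world.

## The synthetic world

`sim_config()` fixes the generating assumptions; its defaults are the
conditions the package targets and are **not** tuned against test outcomes.

* **Genotypes** follow the Balding–Nichols construction: ancestral allele
  frequencies per locus from a symmetric Dirichlet(1); each of `k_gen`
  subpopulations draws its frequencies from Dirichlet(p_anc (1−fst)/fst), so
  a single parameter `fst` controls cluster separability; genotypes are two
  independent draws from the subpopulation frequencies. Defaults: 88
  individuals (the collared sample size), 15 loci, 8 alleles per locus (the
  reported mean is 8.5), `k_gen = 3` (the number of genetic clusters found in
  the real system), `fst = 0.10`. The fst default is our choice: the real
  study reports weak structure (the first three genetic PCs explain 7/6/5% of
  variance), and 0.10 gives comparably subtle, but recoverable, clusters.
* **Habitat use** is one Dirichlet draw per individual from its ecotype's
  concentration vector. The two default ecotype profiles are a closed-forest
  profile (upland forest ≈ 60% of use) and an open/regenerating profile;
  upland forest dominating use matches the reported ~53%, and concentration
  totals of ≈ 27–31 give realistic individual spread. The ecotype label
  equals the genetic cluster index folded modulo `k_eco` with probability
  `coupling` (default 0.6), otherwise uniform over the *other* ecotypes, so
  `coupling` is exactly the probability that the two labels agree.
* **Phenotypes**: log-mass and log-length are linear in sex (male = 1), age
  (truncated-geometric integers 2–25), northing, season dummies (fall is the
  reference) and HL, plus a N(0, σ_unit²) management-unit intercept and
  N(0, σ_resid²) residual. Default coefficients echo the magnitudes of the
  published mass/length models (e.g. HL effect +0.65 on log-mass, +0.15 on
  log-length; intercepts 3.9 and 4.89); σ_unit = 0.1 and σ_resid = 0.15 are
  our choices for a log-scale morphometric trait. Coefficients apply on
  natural covariate scales, so parameter-recovery runs fit with
  `standardize = FALSE`; the standardised scale remains the reporting default
  because the published tables are on an (unrecoverable) standardised scale.
* **Coordinates are planar.** Units occupy south-to-north boxes; no geodesy
  anywhere in the package.
* **Translocations**: each event crosses units with probability `p_cross`
  and, if it crosses, moves north with probability `p_north`; defaults
  reproduce the recorded history (362 events, 229/362 cross-unit, 204/229
  northward, years 1974–2012). Sources of cross-unit events are drawn so the
  intended direction is always feasible.
* **Seeding**: one integer master seed is expanded into fixed per-stage
  substreams, so any stage regenerates independently and byte-identically.

What the generator deliberately does **not** emulate: GPS fix-level spatial
and temporal autocorrelation (`expand_fixes()` is a plain multinomial
expansion; the real study used 146 602 fixes over 9 years), raster-based
land-cover extraction (fixes arrive pre-annotated), home-range estimation,
and pedigree structure (relatedness arises only through shared subpopulation
frequencies). A green test therefore establishes that the *estimators and
samplers* behave as claimed on data satisfying the stated model — not that
the model captures free-ranging bear movement.

## Estimators and numerical choices

**Homozygosity by loci.** HL weights each locus by its expected
heterozygosity in the full sample: HL = Σ E(hom) / (Σ E(hom) + Σ E(het)),
missing loci excluded from both sums. The sample He is used for the weights
(the unbiased 2n/(2n−1) variant is available via `unbiased = TRUE`); which
variant the original analysis used is not recoverable from the text.

**Queller–Goodnight relatedness.** Locus-summed numerator over locus-summed
denominator, symmetrised as the mean of the two ordered estimates. Allele
frequencies come from the full sample including the focal pair — at n ≈ 88
the leave-two-out correction is negligible and omitting it keeps the
estimator a pure function of the frequency table. Values slightly outside
[−1, 1] can occur with rare alleles and are reported raw, never clamped.

**Molecular coancestry.** The pedigree-reconstruction coancestry of the
original analysis (simulated annealing over virtual ancestors) is replaced by
direct allele sharing, f = mean over shared loci of (matches)/4. The
downstream matrix tests need only a similarity matrix, and allele sharing is
deterministic, seedless and exactly testable.

**Hardy–Weinberg.** A Monte-Carlo exact test: gene copies are permuted and
re-paired; two-sided via the deviation of the heterozygote count from its
null mean, with the add-one correction so p is never 0.

**PCA.** Covariance PCA throughout (`prcomp`, centered, unscaled); genotypes
enter as 0/1/2 allele counts with mean imputation of the (rare) missing
genotypes. Axis signs are fixed by making the largest-|loading| element
positive, so outputs are reproducible across platforms.

**K-means by simulated annealing.** Squaring the absolute difference in
proportions makes squared Euclidean distance the exact objective, so the SSE
against group centroids is minimised directly. Proposals move one random
individual to a random other group; acceptance is Metropolis with geometric
cooling from T₀ = 1% of the initial SSE to 10⁻⁶ T₀. The published schedule
(5 × 10⁶ steps, 100 restarts, k = 1..20) is expressible; desk-scale defaults
are 20 000 steps and 10 restarts. The best solution *seen* is returned, so
the algorithm can only improve on its own trajectory. Rows are keyed by id
internally, making results row-order invariant.

**Cluster number.** Pseudo-F is Calinski–Harabasz; BIC is the
spherical-Gaussian form n·d·ln(SSE/(n·d)) + k·d·ln(n). On cluster-structured
data this BIC prefers ever-finer partitions (the n·d·ln term dominates the
penalty for any Gaussian-ish split), so it runs to the top of the profiled
range while pseudo-F recovers planted structure — precisely the disagreement
the original study reported (BIC "could not resolve" a cluster count while
pseudo-F chose 2). Both are reported; selection guidance: trust pseudo-F.

**Admixture model.** A Gibbs sampler over latent per-copy origins with
conjugate Dirichlet updates for cluster allele frequencies (λ = 1) and
individual admixture proportions (α = 1). The correlated-allele-frequency
F-model of the original software is deliberately replaced by independent
Dirichlet priors: conjugate, desk-scale, and only less sensitive at very low
divergence. Q is the posterior mean of the admixture proportions; hard
assignment is the highest Q. Replicate mean log-likelihoods feed
`evanno_delta_k()`. Desk-scale defaults (2 000 sweeps, 20% burn-in, 3
replicates) replace the published 10⁶ iterations; at the acceptance scale
(20 000 sweeps) the sampler recovers planted clusters at fst = 0.25
essentially perfectly.

**Mantel machinery.** r is the Pearson correlation of strictly-lower-triangle
vectors; the null simultaneously permutes rows and columns of one matrix
(which preserves the off-diagonal multiset — exploited for speed); p uses the
add-one correction. The default p is one-sided *toward the sign of the
observed r*, matching signed one-sided reporting conventions; note this
adaptive direction doubles the effective type-I level (a fixed direction or
`two.sided` is available, and calibration checks use a fixed direction).
Partial tests residualise both triangle vectors by OLS on the controls and
permute the *reconstituted residual matrix* (residual-permutation method),
which controls type-I error better than raw-matrix permutation when controls
are autocorrelated. Confidence intervals default to a percentile bootstrap
over individuals — permutation quantiles describe the null distribution, not
the uncertainty of the estimate — but a permutation-quantile mode is provided
for fidelity with analyses that reported CIs "from permutations". Matrices
are used in their native orientation (G is a similarity), so a negative G ~ E
correlation means ecologically similar pairs are more related.

**Hierarchical models.** Gibbs sampling with fully conjugate updates; vague
priors N(0, 100²) on fixed effects and means, inverse-gamma(0.001, 0.001) on
variances (the original JAGS code is unavailable; these are the conventional
choices). There is no global intercept column — the mean of the unit
intercepts μ_α *is* the overall intercept, matching how the published tables
report "overall intercept (μ_α)" and "overall homozygosity (μ_γ)" for the
unit-varying-slope variant. DIC uses the conditional (given unit effects)
Gaussian likelihood, the common JAGS convention, with pD = D̄ − D(posterior
means). Convergence is judged by Gelman–Rubin R̂ < 1.1 across chains started
from overdispersed points; non-convergence is a flag, never an error. The
model suite is M1 (sex, age, northing, season), M2 (+HL), M3 (+cluster
dummies; a 3-level genetic clustering contributes two dummies relative to the
third cluster), M4 (+PC1/2 scores), with "x" (HL × sex) and "y" (unit-varying
HL slopes) variants fitted for the DIC-best model. Complete cases only,
mirroring the original analysis (its n dropped from 88 to 64).

**Single-locus F-test.** Restricted model: base covariates + combined HL;
full model: base covariates + the L per-locus homozygosity indicators;
F = ((RSS_r − RSS_f)/(L−1)) / (RSS_f/(n − p_f)), df1 = L − 1 (14 for 15
loci). The exact construction behind the published test is not in the
available text; this nested decomposition is consistent with its printed
degrees of freedom and has ~5% size under a pure general effect.

**Neighbor joining and formats.** NJ is delegated to `ape::nj` (the tool the
original analysis used) behind a validating wrapper; negative limb lengths
are retained unless `clamp = TRUE`. Genotypes round-trip through Genepop
(2- or 3-digit codes auto-detected, width must be consistent, `0…0` =
missing); tables are strict comma/period/UTF-8 CSV; trees are Newick.

## Design choices that were genuinely open

* **Availability distance**: "absolute difference" is ambiguous between the
  sum and the mean over classes; the sum (L1) is the default, switchable.
* **Chi-squared input**: the heterogeneity test runs on counts reconstructed
  as proportions × sampled points — it is meaningless on proportions alone.
* **Ecotype folding**: with `k_gen = 3` folding onto `k_eco = 2`, clusters 1
  and 3 share a base ecotype, so the *true-label* Pearson correlation is ~0
  by parity at any coupling; with equal k the correlation is positive and
  monotone in `coupling`. The assignment-correlation report therefore
  includes a relabeling-sensitivity range (max/min r over permutations of the
  smaller label set) instead of silently re-aligning labels.
* **SA temperatures**: the published analysis gives steps and restarts but no
  temperatures; T₀ = 1% of initial SSE with geometric decay to 10⁻⁶ T₀ makes
  early moves nearly free and late moves nearly greedy across data scales.
* **Fix counts**: the real distribution of fixes per animal is unreported;
  `expand_fixes()` defaults to 1 000 per individual and is configurable.

## Known limitations

* The admixture sampler reports per-replicate mean log-likelihoods, not the
  harmonic-mean marginal likelihood of the original software; delta-K is
  computed on those means, which is the quantity the criterion actually needs.
* Label switching is not aligned across replicates beyond the hard
  assignment; Q matrices from different replicates may be column-permuted.
* The spherical BIC is reported for fidelity but over-partitions by
  construction (see above).
* Bootstrap CIs for Mantel r resample individuals with replacement, which
  puts zero-distance duplicate pairs into the resampled triangles; at n ≈ 50+
  the effect is small but the intervals are approximate.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
study <- simulate_study(cfg)
res <- run_ibe_pipeline(study, seed = 1)
res$assignment_cor       # ecotype/genotype assignment correlation + sensitivity
tibble::as_tibble(res$ibe)  # the Mantel / partial-Mantel battery
res$hfc$table            # DIC ranking of the phenotype model suite
res$single_locus         # single-locus F-test (df1 = 14 with 15 loci)
write_newick(res$nj_tree)   # habitat-availability NJ tree
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` performs this
end-to-end run and additionally recomputes the two self-contained
translocation percentages from the recorded counts.
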