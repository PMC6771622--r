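---
title: "Methods: admixture mapping in hybrid zones with hybridmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture mapping in hybrid zones with hybridmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`hybridmap` implements an admixture-mapping workflow for natural hybrid
zones between two divergent species (the motivating system is a white
poplar x European aspen hybrid zone, but nothing is species-specific).
The chain of analyses is:

1. genome-wide ancestry `q` per individual, estimated by EM directly
   from genotype likelihoods, plus Hudson's F_ST between the parental
   species;
2. diploid local ancestry along chromosomes by a forward-backward HMM,
   summarized as the expected ancestry dosage (0–2 copies of one
   species' ancestry) used as the mapping genotype;
3. admixture LD: pairwise squared correlation of ancestry dosages and
   its decay with physical distance;
4. a Bayesian sparse linear mixed model (BSLMM) per trait, fitted by
   Metropolis-within-Gibbs MCMC, yielding posteriors for PVE, PGE,
   narrow-sense heritability `h2 = PVE * PGE`, the sparse-locus count
   `n_gamma`, and per-marker posterior inclusion probabilities (PIPs);
5. PIP sums in nonoverlapping 0.5 Mb windows, selection of windows with
   summed PIP >= 0.4, a three-class genomic-architecture call per trait,
   the variance each trait shares with `q` (1000-replicate bootstrap),
   and gene annotation of selected windows from a GFF3.

A synthetic hybrid-zone generator stands in for the field data: it
produces ground truth (tracts, `q`, QTL positions and effects, variance
components) for every recovery test in the package.

# The synthetic hybrid zone

**Parental divergence.** Ancestral allele frequencies are drawn
uniformly on [0.05, 0.95]; species frequencies follow the
Balding–Nichols construction with `F = fst_target` (default 0.39), so
the expected Hudson F_ST equals the target; with 5000 sites the realized
ratio-of-averages estimate is within ±0.03. Pure Balding–Nichols at
F = 0.39 yields well under 5% of sites with allele-frequency difference
> 0.95; real marker panels in strongly diverged species pairs often
contain an ascertained excess of diagnostic sites, so the generator has
a `diag_frac` knob (default 0) that replaces a fraction of sites with
near-diagnostic frequencies (0.99/0.01). It is used where a test
requires a stated fraction of fixed differences.

**The swarm.** Generation 1 is F1; each later generation (default
`g_max = 5`) mates random members of the previous generation, with
probability `backcross_prob = 0.15` per parent of drawing a pure
parental individual instead. This default balances two features of real
hybrid-zone panels: genome-wide ancestry spread over (0, 1) (more
backcrossing widens the `q` range) against ancestry tracts that shorten
over generations (less backcrossing shortens them; fresh parental
gametes carry unbroken tracts). At 0.15 the simulated admixture LD
decays from R² ≈ 0.95 near zero distance to ≈ 0.3 at 5 Mb, and the
5–95% `q` range is about 0.11–0.89. Crossovers are Poisson on the
genetic map (`recomb_rate_cM_per_Mb = 5`), i.e. the Haldane model
without interference. Alleles are drawn site-independently within
tracts from the carrying species' frequency track: within-species
background LD (which decays over hundreds of bp in the motivating
system) is deliberately not modeled, as it is negligible at the 0.5 Mb
window scale.

**Sequencing.** Read depth is Poisson (default mean 8) with extra
dropout (`missing_rate`); alternate read counts are binomial with
per-read error `seq_error` and a heterozygote allelic bias knob
(0.5 = unbiased). Genotype likelihoods follow the standard binomial
read model, normalized to max 1; depth-0 entries carry the flat triple.
Calls under 5 reads are masked before analysis, matching common
RAD-seq practice.

**Phenotypes.** A trait is the sum of covariate terms (`q`, common
garden, planting year), sparse ancestry-QTL effects, a polygenic term
drawn from N(0, K) with K the ancestry kinship matrix, and residual
noise. Components are centered and rescaled so realized sample variance
fractions hit the targets (`covar_frac`, `h2`, `pve`); cross-component
sample covariances leave realized fractions within a few percent of
targets. Zero-inflated traits are produced by liability thresholding:
abundance = max(liability − threshold, 0), with the threshold at the
liability's normal quantile for the target zero fraction. Three
architecture classes are supported: *first* (sparse + polygenic),
*second* (polygenic only), *third* (no genetic variance).

The generator reproduces the statistical structure the mapping model
assumes — admixture LD, ancestry-covariate confounding, RAD-like noise —
but not several features of real data: within-species LD, variable
recombination along chromosomes, genotyping bias that differs across
restriction-site alleles, shared family structure between the reference
panels and the mapping panel, or selection against hybrid genotypes.
Passing recovery tests therefore demonstrates internal consistency of
the pipeline under its own assumptions, not performance on any
particular empirical data set.

# Genome-wide ancestry and F_ST

The two-ancestry admixture model treats each allele copy independently:
a copy is of "alba" ancestry with probability `q` and carries the
alternate allele with probability `p_A` (else `p_T`), so the individual
allele frequency is `f = q p_A + (1-q) p_T` and genotypes are
Binomial(2, f). The EM algorithm maximizes the likelihood summed over
the genotype-likelihood triples; with a reference panel the parental
frequencies are held fixed (supervised), otherwise they are updated
from expected ancestry-specific allele counts (unsupervised), optionally
initialized from labeled parentals. The log-likelihood is checked to be
non-decreasing at every iteration. Non-identifiable input (identical
parental frequencies) returns `q = 0.5` with an infinite-width interval
and a flag. Uncertainty is a 200-replicate site bootstrap (the data
points are sites, resampled with replacement; each replicate re-runs
the supervised EM). Individuals are classed as pure tremula
(`q < 0.05`), pure alba (`q > 0.95`) or hybrid.

Hudson's F_ST uses the finite-sample-corrected per-site numerator and
denominator, combined as a ratio of averages (sums of numerators over
sums of denominators) — the bias-robust convention. Sites where both
populations are fixed for the same allele are excluded.

# Local ancestry

The hidden state is the unphased diploid ancestry {TT, het, AA}. Each
haploid ancestry chain switches to its stationary distribution
(`q` for alba) with probability `1 - exp(-g d_M)` over `d_M` Morgans
(`g` generations since admixture, default 5; map from the cM/Mb rate,
default 5); the diploid kernel is the product of two independent
haploid chains collapsed onto the unphased space. Emissions use
parental panel frequencies smoothed by a miscopying rate
(default 0.06): a haplotype of one ancestry emits alleles from
`(1-eps) p_own + eps p_pooled`, which absorbs shared polymorphism and
panel error. Phase is not tracked (both heterospecific orderings are
one state), and the haplotype-copying machinery of phased-panel methods
is deliberately replaced by this frequency-based emission: the pipeline
only consumes posterior ancestry probabilities, and the frequency model
is exactly enumerable for testing. Posteriors come from standard scaled
forward-backward; masked sites are uninformative emissions; a
chromosome with no usable sites falls back to the stationary posterior
(dosage `2q`, flagged by a warning). The expected dosage
`P(het) + 2 P(AA)` is the mapping genotype. A grid scan over
(`g`, miscopying) reports total log-likelihood per combination,
mirroring model selection by likelihood.

# The sparse mixed model

The mapping model is `y = X_g beta_g + u + e` with
`u ~ N(0, sigma_b^2 K)`, `e ~ N(0, sigma_e^2 I)`, a spike-and-slab
prior on marker effects, and hyperpriors `h ~ U(0,1)`, `rho ~ U(0,1)`,
`log pi ~ U(log(1/L), 0)`. The variance map is
`lambda = sigma_b^2/sigma_e^2 = h(1-rho)/(1-h)` and
`sigma_a^2 = h rho / ((1-h) max(pi L, 1))` on standardized phenotype
and markers, with K scaled to mean diagonal 1. K is eigendecomposed
once; in the rotated basis the marginal covariance is diagonal and
`beta` and `sigma_e^2` (Jeffreys prior) integrate out analytically, so
the Metropolis-within-Gibbs moves — add/remove/swap on the sparse set
(0.4/0.4/0.2 at interior states), reflected random walks on `h`, `rho`
(half-width 0.25) and `log pi` (half-width 1) — need only an `s x s`
Cholesky per evaluation. Per retained draw (thinning 10), effects and
`sigma_e^2` are sampled back and PVE, PGE are computed as empirical
variance fractions of the sampled linear predictors, so
`h2 = PVE * PGE` holds exactly per draw and a draw with an empty sparse
set has `PGE = 0`. Chains are pooled after burn-in; PIP is the pooled
inclusion frequency per marker.

Numerical and tuning choices:

* **Sparse-set cap** `s_max = 30`. Under null traits the set size is
  prior-driven (the log-uniform `pi` prior has a heavy tail over the
  set size) and each marginal-likelihood evaluation costs O(n s^2);
  the architectures of interest involve few sparse loci, so the cap
  binds only where the sparse set carries no signal.
* **Presets.** The desk preset (3 chains x 50,000 iterations, 10%
  burn-in) is the default working scale used by all tests and scripts;
  a `paper` preset (10 chains x 12 million iterations, 2 million
  burn-in) names the full-size setting for real analyses.
* **Degenerate mode.** `pi_zero = TRUE` disables the sparse component,
  reducing the model to the kinship-only mixed model (PGE identically
  0); useful as a baseline and for testing.
* **Reproducibility.** Chain k uses `seed + k - 1`; identical inputs,
  seeds and configuration give identical draws.

Covariates (`q`, common garden, planting year, as declared per trait)
are regressed out of the phenotype first — OLS residuals for
quantitative traits, response residuals from a binomial logistic fit
for presence/absence traits (chosen for scale interpretability; a trait
is mapped as binary when more than 10% of individuals have zero
abundance). An `in_model` alternative is simply to include the
covariate columns alongside the dosages.

A caveat worth knowing: ancestry dosages are collinear with `q`
(typically r² ≈ 0.3–0.5 in a wide-`q` panel), and the kinship matrix is
built from the same dosages, so a polygenic explanation of a sparse
trait is genuinely competitive when sparse effects are a modest share
of the genetic variance. Posteriors for traits with PGE near 0.5 can
honestly straddle the first/second class boundary — in this setting
sparse effects are underestimated rather than overstated, so first-class
calls are conservative.

# Windows, classes, and genes

PIPs are summed in nonoverlapping windows (default 0.5 Mb, 0-based
half-open, grid anchored at coordinate 0 of each chromosome — the
anchor is a convention); window sums conserve total marker PIP exactly.
Windows with summed PIP >= 0.4 (inclusive) are selected. Architecture
classes are assigned in precedence order:

* first: `P(h2 >= 0.01) > 0.95`;
* second: `P(PVE >= 0.05) > 0.97`;
* third: `P(h2 < 0.01) >= 0.30`;
* otherwise unassigned.

The second and third rules can hold simultaneously; precedence resolves
the overlap and the rule trace records all three probabilities plus an
overlap flag. An explicit `promote` argument can force a borderline
trait into the first class with a recorded reason (mirroring a
judgment call for traits with a sharp PIP peak that barely miss the
threshold); it is never automatic. Variance explained by `q` is the R²
of the simple regression of the raw trait on `q`, with a nonparametric
case-resampling bootstrap percentile interval (default 1000
replicates). Genes from a GFF3 are reported per overlapped window with
overlap lengths; a gene spanning a window boundary appears once per
window with split overlaps.

# Problem sizes and what the tests show

The test-suite and acceptance-script study conditions are: frequency
tracks of 5,000 sites for F_ST recovery (10 seeds, 51 + 51 reference
diploids); local-ancestry recovery on 2-generation hybrids at one
marker per 50 kb with >= 10% diagnostic sites (3 seeds x 20
individuals); single-QTL mapping recovery at n = 300 individuals and
L = 1,000 dosage markers on two 12.5 Mb chromosomes (20 replicates);
the classifier truth table at the same panel size (10 replicates per
class, desk MCMC preset); LD decay on one 10 Mb chromosome (10 seeds,
60 individuals); and 100 seeded replicates of the bootstrap-calibration
check at n = 266. The forward-backward algorithm is checked against
exhaustive path enumeration (3^L paths, L <= 8) to 1e-10, and the MCMC
against a 10x longer reference run within batch-means Monte Carlo
error. These sizes were chosen so each property is measured with
comfortable Monte Carlo margins while the whole suite stays desk-scale.

Known limitations: no phasing and no haplotype-copying emissions in the
HMM; no probit/logistic BSLMM for binary traits (response residuals +
Gaussian model instead); no inference of `g` or the miscopying rate
beyond the likelihood grid scan; window re-analysis at other sizes is
available only through the `window_bp` argument; and the generator's
caveats listed above.
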