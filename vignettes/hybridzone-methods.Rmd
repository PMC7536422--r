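---
title: "Models and methods behind hybridzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hybridzone` characterises a secondary-contact hybrid zone in a
spruce-associated longhorn beetle from three evidence streams — nuclear
microsatellites, demographic coalescent modelling, and wing geometric
morphometrics — and quantifies how well the genetic and morphological views
of individual ancestry agree.  This vignette explains the models, the
defaults and why they were chosen, what the synthetic-data generators do and
do not emulate, and the numerical decisions a maintainer would want written
down.

## The study system the package emulates

The design assumes three regional samples of a spruce-feeding beetle:
a southern *Alpine–Carpathian* population, a *northeastern European*
population, and an *Asian* population, genotyped at six microsatellite loci
(3–12 alleles per locus) with sample sizes near 91/48/22 after removing
incomplete multilocus genotypes, plus hind-wing landmark data (23 landmarks,
about 316 specimens of both sexes).  The central biological question is
whether the northeastern European population is a recently admixed product
of secondary contact between the southern and eastern lineages.  All
components run on fully synthetic data generated under exactly these
conditions, because the specimen data themselves are not redistributable.

## Population-genetic statistics

* **Diversity.** Per locus and population: allele count $A$, effective
  allele number $A_e = 1/\sum_j p_j^2$, observed heterozygosity $H_o$, and
  rarefied allelic richness
  $AR(g) = \sum_a \left[1 - \binom{N - N_a}{g}\big/\binom{N}{g}\right]$,
  evaluated by default at $g = 44$ gene copies — twice the smallest regional
  sample (22 diploid individuals).  The total allele count over all loci is
  extrapolated with the incidence-based Chao2 estimator (individuals as
  sampling units, $(T-1)/T$ correction, bias-corrected form when $Q_2 = 0$)
  with a log-normal 95% CI; allele accumulation curves interpolate by the
  rarefaction expectation and extrapolate along the Chao2 asymptote with a
  bootstrap-over-individuals band.
* **Hardy–Weinberg.** The exact test conditions on allele counts; the
  probability of a genotype array is $\propto 2^H / \prod_{i\le j} n_{ij}!$.
  Biallelic loci are enumerated exhaustively; loci with more alleles use the
  Guo–Thompson Monte-Carlo shuffle of gene copies (default $10^5$ shuffles,
  add-one p-value).  Enumerating general multi-allelic arrays is only
  feasible for tiny tables where the Monte-Carlo answer is equally accurate,
  so the enumeration path is restricted to the biallelic case.
* **Linkage.** The standardised index of association $\bar r_d$ over
  per-locus allele-mismatch distances, with a null distribution obtained by
  permuting genotypes among individuals independently at each locus.
  Because the multiset of distances at each locus is invariant under that
  permutation, only cross-locus covariances are recomputed per permutation
  (the C++ kernel exploits this).
* **Null alleles.** A population-level EM estimator of a single null-allele
  frequency explaining homozygote excess under random mating, conditional on
  observed (non-blank) genotypes; the genotyping-failure rate is reported as
  the observed missing fraction.  This deliberately replaces a full Bayesian
  individual-inbreeding model: the pipeline only needs to check that
  estimated null frequencies are negligible, which a likelihood point
  estimate answers.  On all-homozygote degenerate data the likelihood is
  maximised on the boundary; the estimate is clipped to $[0,1]$.
* **Differentiation.** Pairwise Weir–Cockerham $\theta$ from the per-allele
  variance components $a, b, c$ summed over alleles and loci.  Significance
  is a permutation test shuffling individuals between the pair (default
  $10^5$ permutations, add-one rule so p-values never reach 0); the 95% CI
  is a percentile bootstrap over loci, the conventional choice with six
  loci.
* **Multiple testing.** Storey q-values with $\pi_0$ estimated on a
  $\lambda$-grid with a cubic smoother; with fewer than ten p-values
  $\pi_0$ is fixed at 1, which reduces to Benjamini–Hochberg.

## Ancestry inference

`admixture_mcmc()` implements the admixture model with **correlated allele
frequencies**: locus-wise ancestral frequencies $p_A$, per-cluster
frequencies $p_k \mid p_A \sim \mathrm{Dir}\!\big(p_A (1-F_k)/F_k\big)$ with
drift parameters $F_k$, individual ancestry vectors
$q_i \sim \mathrm{Dir}(\alpha,\dots,\alpha)$, and a latent cluster of origin
for every gene copy.  Gene-copy origins, $q$ and $p_k$ are Gibbs-updated;
$F_k$ (logit random walk, Beta(1,3) prior), $p_A$ (Dirichlet random-walk
proposal) and $\alpha$ (normal step 0.05, uniform(0,10) prior) move by
Metropolis.  The model likelihood estimate uses the running mean/variance
convention $\ln P(D) \approx \overline{\ln L} - \widehat{\mathrm{Var}}(\ln
L)/2$.  Reported per-individual "confidence intervals" are 2.5/97.5%
posterior quantiles of thinned $q$ samples, and a split-half discrepancy
above 0.1 triggers a mixing warning.  Chain defaults (burn-in $10^4$, length
$5\times10^4$, 10 replicates over $K \in 1..5$) are deliberately generous;
the bundled tests use shorter, seed-fixed chains that mix easily at the
synthetic data's signal strength.

$K$ is chosen by the Evanno second-difference statistic
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}\,L(K)$,
which is undefined at the boundary $K$ values — like any user of this
heuristic, the package cannot score $K = 1$ directly and relies on the
interior maximum.

DAPC provides the model-free cross-check: centred allele counts, PCA
(default retention: smallest number of components reaching 90% variance,
capped below $n - $ number of groups), then `MASS::lda()`; cluster overlap
along the first discriminant axis is the integral of the pointwise minimum
of two Gaussian KDEs (Silverman bandwidth, trapezoid rule).  When groups are
perfectly separable the within-group covariance is singular and a
deterministic perturbation five orders of magnitude below the between-group
signal is added before the discriminant step.

Following the reporting convention for admixture surveys, an individual is
flagged a *possible admixture* when more than 0.1 of its ancestry points to
the opposite cluster, and *significant* only when its 95% credible interval
excludes pure ancestry.

## Coalescent simulator and demographic ABC

The structured coalescent is implemented natively (C++): exponential waiting
times with per-population pair rates $1/(2N)$ (gene-copy scale), population
splits merging lineage sets, an admixture event routing each lineage of the
target population to one parental source with probability $r$, and
population-size changes at events.  Microsatellites mutate under the
generalised stepwise model — Poisson numbers of mutations per branch,
geometric step sizes with parameter $P_{GSM}$, signs symmetric — on a ladder
of 40 contiguous allele states with reflecting bounds (prevents unbounded
walks, the convention of coalescent microsatellite simulators).  mtDNA uses
Jukes–Cantor substitutions on a single non-recombining locus with haploid
(female) population sizes.

Four nuclear scenarios are built in: the secondary-contact hypothesis
(scenario 2: the northeastern population founded at $t_2$ as a mixture of
the southern lineage with proportion $r$ and the eastern lineage with
$1-r$, which merge at $t_1$) and three pure-bifurcation alternatives —
((NE,Asia),AC), ((NE,AC),Asia) and a simultaneous trichotomy.  The mtDNA
family contains five constraint variants on $(N_1, N_2, N_A)$, anchored by
the variant with $N_2 = N_A$ and the all-free variant.  Both catalogues are
plain R builders and can be overridden wholesale.  Default priors
(uniform $N \in [10^2, 3\times10^5]$, times uniform with $t_2 < t_1$,
$r \in [0.001, 0.999]$, $\mu_{SSR}$ log-uniform $[10^{-4}, 10^{-3}]$,
$P_{GSM} \in [0.1, 0.3]$, mtDNA $\mu$ log-uniform $[10^{-8}, 10^{-7}]$,
$L = 658$ bp) are package choices bracketing the magnitudes typical for
insect microsatellites and COI; all are config keys, not constants.  One
generation is treated as one year for interpretation only — internal times
are generations.

Summary statistics follow the standard microsatellite-ABC repertoire: per
population the mean allele number, expected heterozygosity, allele-size
variance and Garza–Williamson $M$; per pair Weir–Cockerham $\theta$,
$(\delta\mu)^2$ and the shared-allele distance; for sequences the haplotype
count, segregating sites, mean pairwise differences, Tajima's $D$, plus
between-population differences and $1 - \pi_W/\pi_B$ per pair.  Undefined
statistics (e.g. $D$ at $S = 0$) are recorded as 0.

Scenario choice standardises the statistics by their reference-table spread,
retains the nearest 1% of simulations (Euclidean), and fits a multinomial
logistic regression of the scenario label on the statistics, evaluated at
the observed point; CIs come from the fit's asymptotic covariance via the
delta method, and near-separation triggers a ridge-stabilised refit.
Parameter posteriors use the local-linear regression adjustment with
Epanechnikov weights; parameters with finite prior bounds are
logit-transformed before adjustment and back-transformed after, the mode
comes from a weighted kernel density, and intervals from weighted quantiles.
Fewer than 50 retained draws are refused as too unstable for a density.

At desk scale the package validates this machinery by self-consistency: with
reference tables of a few thousand simulations per scenario and
pseudo-observed data generated under the secondary-contact scenario with
well-separated parental populations ($t_1/2N = 5$, $r = 0.3$, recent
contact), the true scenario wins the posterior comparison in well over 70%
of trials and the 95% interval for $r$ covers the truth at close to nominal
rate.  Paper-scale inference (a $10^6$-trial table against real genotypes)
is the intended production use but is deliberately outside the test
envelope.

## Wing morphometrics

`gpa()` is classical generalised Procrustes analysis: centre, scale to unit
centroid size, iteratively rotate each configuration to the consensus by the
SVD solution (reflections forbidden — the determinant sign is corrected),
re-estimate and re-normalise the consensus until the update falls below
$10^{-10}$.  After convergence the whole set is rotated so the consensus
lies on its principal axes with a fixed sign convention; this costs nothing
statistically and makes aligned coordinates invariant to the orientation of
the input, which the test suite exploits (any similarity transform of the
raw landmarks changes downstream statistics by less than $10^{-6}$).

Shape PCA acts on the tangent-space projection at the consensus (standard
practice; the projection removes the curvature direction).  The default
retains 20 components; a scree rule (largest eigenvalue-ratio drop) is
available because "choose by scree" is inherently subjective and should be
inspectable.  Size is analysed separately (two-way ANOVA of centroid size
with type-II sums of squares, which are the appropriate choice for the
unbalanced sex-by-region design; a constant factor collapses to one-way).
Shape is analysed by MANCOVA of the retained scores on population, sex and
centroid size — allometry is handled via the size covariate rather than by
residualising scores.  Interactions are screened first; if none is
significant the main-effects model is reported.  Wilks' $\Lambda$ with
Rao's $F$ approximation is computed per effect, reducing exactly to the
univariate ANCOVA $F$ when one dimension is retained.  Between-population
divergence is the squared Mahalanobis distance under the pooled within-group
covariance (pseudo-inverse with a warning if singular), clustered by UPGMA
into an ultrametric phenogram, and individual assignment between the
southern and eastern ranges uses a linear discriminant with equal priors,
optionally leave-one-out for honest posteriors.

### The wing generator

`simulate_wings()` adds, to a stylised 23-landmark base outline (synthetic
artifact data, not digitised from specimens), tangent-space displacement
vectors for population, sex and allometry, then isotropic Gaussian
digitising noise, then nuisance rotation/translation/scale.  Effects live in
the tangent space so their magnitudes read directly as Procrustes distances
— a population effect of 0.012 means the group means sit 0.012 Procrustes
units apart, making recovery tests quantitative.  Defaults (population
effects 0.012/0.004/0, sex shape effect 0.006, allometric slope 0.01 per log
centroid size, noise 0.004, female size shift 0.03 on the log scale across
316 specimens) were chosen once so the synthetic data reproduce the
qualitative pattern of the emulated study: a clear population effect with
the northeastern group intermediate but nearer the eastern group, detectable
sex dimorphism in both size and shape, and significant allometry.  When the
generator is driven by per-individual ancestry (the pipeline ties wings and
genotypes to one latent ancestry), hybrids get proportionally intermediate
wings.  What the generator does *not* emulate: correlated landmark noise,
digitisation error that scales with wing size, asymmetry, or measurement
batch effects — so passing tests demonstrate the estimators, not robustness
to those artefacts.

## Genetic–morphometric integration

The agreement between genetic ancestry $q$ (toward the eastern cluster) and
the morphological assignment probability is modelled by fractional-response
regression: a GLM with logit link and quasibinomial variance, fitted by
IRLS.  Because the quasi-likelihood has no true likelihood, the McFadden
pseudo-$R^2$ is computed from the binomial log-likelihood kernel with the
dispersion ignored, which is the convention behind the reported statistic;
the slope test is the deviance $\chi^2$ with one degree of freedom.  Both a
model with the MCMC $q$ and one with the DAPC membership as the response are
fitted.  A constant response is flagged and reported with pseudo-$R^2 = 0$.

## The pipeline and its synthetic conditions

`run_pipeline()` draws one latent eastern-ancestry value per individual —
pure 0 for the 91 southern, pure 1 for the 22 eastern, and Beta(7, 3) for
the 48 northeastern individuals, encoding the "prevailing (~70%) eastern
contribution" of the admixed population — and generates both the genotypes
(F-model generator at pairwise $F_{ST} = 0.18$, 6 loci, 8 alleles) and the
wings from it.  Stages run in order (diversity, FST, ancestry scan with
$\Delta K$, DAPC, optional ABC, GPA→PCA→ANOVA/MANCOVA→Mahalanobis/UPGMA→LDA,
fractional logit); each stage's seed derives deterministically from the
master seed, failures mark the report partial without destroying the rest,
and the JSON digest excludes timestamps so one seed gives a byte-identical
report.

The F-model generator (`simulate_admixed_genotypes()`) is the second,
non-coalescent synthetic route: cluster allele frequencies Dirichlet-drifted
around an ancestral vector so the realised pairwise Weir–Cockerham $\theta$
between pure clusters is approximately the `fst` argument, with gene copies
drawn by individual ancestry and an `f1` flag forcing one copy from each
cluster (true first-generation hybrids).  It generates the ancestry-layer
test conditions directly, with known individual-level truth that a
demographic coalescent cannot provide.

## Problem sizes used by the tests

The suite chooses sizes that keep every stochastic check statistically
meaningful while remaining quick to re-run: 300 drift replicates of 30 loci for the
$\theta$ calibration; 1,000 loci for the HWE type-I band; 20 synthetic
datasets at the 91/48/22 study conditions for the $\Delta K$/recovery/F1
checks (chains of 2,600 sweeps, two replicates over $K\in1..4$); an ABC
reference table of 5,000 simulations per scenario with 100 pseudo-observed
datasets; 200 null replicates for the MANCOVA calibration; and a complete
double run of the pipeline for reproducibility.  These are the package's own
validation scales; production analyses should use the generous defaults.

## Known limitations

* The admixture sampler implements the correlated-frequency model only — no
  linkage model, no location priors, and label switching is handled by
  post-hoc alignment rather than online relabelling.
* The coalescent has no continuous migration and no recombination; admixture
  is a single pulse.
* The Evanno statistic cannot evaluate $K = 1$; a data set truly without
  structure will still return some interior $K$, and the $\ln P(D)$ values
  should be inspected.
* Chao2 extrapolation inherits the usual caveat that it estimates a lower
  bound on the asymptotic richness.
* The logistic-regression CIs for scenario probabilities are asymptotic;
  with small retained sets they can be wide or touch the unit interval
  bounds.
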