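# hybridzone

Comparative-phylogeography toolkit for characterising a secondary-contact
hybrid zone in a forest insect from three evidence streams:

* **Microsatellite population genetics** — diversity (A, Ae, rarefied
  allelic richness, observed heterozygosity), Chao2 extrapolation of total
  allele counts with accumulation curves, Hardy–Weinberg exact tests
  (Guo–Thompson), multilocus linkage (r̄d), EM null-allele estimates,
  pairwise Weir–Cockerham θ with permutation tests and
  bootstrap-over-loci CIs, Storey q-values.
* **Individual ancestry** — a native Gibbs sampler for the admixture model
  with correlated allele frequencies (the F-model behind STRUCTURE-style
  analyses), Evanno ΔK model selection across replicate chains, DAPC with
  kernel-density overlap along the first discriminant axis.
* **Demographic inference by ABC** — a native structured-coalescent
  simulator (splits, single-pulse admixture, size changes; generalised
  stepwise microsatellite mutation on a bounded allele ladder; Jukes–Cantor
  mtDNA), reference tables over a four-scenario nuclear catalogue (and a
  five-scenario mtDNA catalogue), logistic-regression scenario choice and
  Beaumont local-linear parameter posteriors (mean/median/mode/q025/q975).
* **Wing geometric morphometrics** — generalised Procrustes analysis,
  tangent-space shape PCA, centroid-size ANOVA, shape MANCOVA with Wilks' Λ,
  pairwise Mahalanobis D² with UPGMA phenograms, and discriminant
  assignment between ranges.
* **Integration** — fractional-response (quasibinomial-logit) regression of
  genetic ancestry on morphological assignment probability with deviance χ²
  and McFadden pseudo-R².

The core demographic model: three regional populations (southern
Alpine–Carpathian, northeastern European, Asian/eastern) descend from an
ancestor of size N_A; under the secondary-contact scenario the northeastern
population is founded at time t₂ as an admixture of the southern lineage
(proportion r) and the eastern lineage (1 − r), which coalesce at t₁.
A synthetic-data layer (coalescent and F-model genotype generators, a
23-landmark wing generator with population/sex/allometry effects in tangent
space) reproduces the study conditions — samples of 91/48/22 individuals at
six loci with cluster differentiation near F_ST = 0.18, and 316 wings —
so the entire pipeline runs and validates without specimen data.

## Worked example

```r
library(hybridzone)

report <- run_pipeline(pipeline_config(), seed = 7)
print(report)
#> hybridzone pipeline report (seed 7 )
#>   chosen K: 2
#>   pairwise FST: 0.13, 0.266, 0.0407
#>   genetic~morphological agreement: slope 3.46  pseudo-R2 0.255
#>   elapsed: 44.9 s
```

Reading the output: the Evanno ΔK scan over replicate admixture chains
picks two genetic clusters (southern vs eastern); the pairwise
Weir–Cockerham θ values show moderate southern–northeastern and
southern–eastern differentiation but weak northeastern–eastern
differentiation, the signature of a northeastern population dominated by
eastern ancestry; and the fractional-logit fit of per-individual genetic
ancestry on wing-shape assignment has a positive slope with a McFadden
pseudo-R² of about 0.26 — on the 0.2–0.4 scale usually read as an excellent
fit for this statistic, i.e. wings and genes tell a consistent story about
who is a hybrid.

Individual stages compose with pipes and return tibbles or tidy-able
objects:

```r
gm <- simulate_admixed_genotypes(q = c(rep(0, 91), rbeta(48, 7, 3), rep(1, 22)),
                                 fst = 0.18, n_loci = 6,
                                 pop = rep(c("AlpineCarpathian", "NEEuropean",
                                             "Asian"), c(91, 48, 22)),
                                 seed = 1)
diversity(gm) |> tidy()
pairwise_fst(gm, n_perm = 999, n_boot = 999, seed = 2) |> tidy()
fit <- admixture_mcmc(gm, K = 2, burn_in = 2000, length = 8000, seed = 3)
autoplot(fit)
```

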