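Package: hybridzone
Title: Comparative Phylogeography of Secondary-Contact Hybrid Zones from
    Microsatellites, Coalescent ABC and Wing Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise a secondary-contact hybrid zone in a
    forest insect from three evidence streams: classical microsatellite
    population genetics (diversity, rarefied allelic richness, Chao
    extrapolation, Hardy-Weinberg exact tests, multilocus linkage, null
    alleles, Weir-Cockerham FST with permutation tests), individual
    ancestry inference (a Gibbs sampler for the correlated-allele-frequency
    admixture model with Evanno delta-K model selection, plus DAPC with
    density-overlap summaries), coalescent approximate Bayesian computation
    over divergence-plus-admixture demographic scenarios (reference tables,
    logistic-regression model choice, local-linear parameter posteriors),
    and landmark-based wing geometric morphometrics (generalised Procrustes
    analysis, shape PCA, MANCOVA, Mahalanobis distances, UPGMA, discriminant
    assignment). A synthetic-data layer simulates genotypes, mtDNA sequences
    and wing landmark configurations so the whole pipeline runs and is
    validated without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    MASS,
    car,
    nnet,
    ape,
    phangorn,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
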