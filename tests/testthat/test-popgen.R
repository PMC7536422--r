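test_that("effective allele number is exact for equifrequent alleles", {
  # 4 alleles, 10 copies each: genotypes (1,2) x5, (3,4) x5
  gm <- genotype_tbl(tibble::tibble(
    id = sprintf("i%02d", 1:10), pop = "A", locus = "L1",
    a1 = rep(c(101L, 103L), each = 5), a2 = rep(c(102L, 104L), each = 5)))
  d <- diversity(gm, rarefaction_genes = 4)
  expect_equal(d$by_locus$Ae, 4.0)
  expect_equal(d$by_locus$A, 4)
})

test_that("rarefied richness matches the hypergeometric closed form", {
  # copies {A:30, B:10}, g = 2 -> 2 - (C(30,2)+C(10,2))/C(40,2) = 1.3846...
  set.seed(5)
  gm <- geno_from_copies(rep(c(101L, 102L), c(30, 10)), rep(101L, 10))
  d <- diversity(gm, rarefaction_genes = 2)
  ar <- d$by_locus$AR[d$by_locus$pop == "A"]
  expect_equal(ar, 2 - (choose(30, 2) + choose(10, 2)) / choose(40, 2),
               tolerance = 1e-12)
  expect_equal(ar, 1.38461538, tolerance = 1e-7)
})

test_that("Chao2 reproduces its closed form and the bias-corrected variant", {
  # T = 10, S_obs = 12, Q1 = 3, Q2 = 2 -> 12 + (9/10) * 9 / 4 = 14.025
  Y <- c(rep(1, 3), rep(2, 2), rep(5, 7))
  cz <- hybridzone:::chao2(Y, 10)
  expect_equal(unname(cz["estimate"]), 14.025, tolerance = 1e-12)
  expect_gte(unname(cz["lo"]), 12)
  expect_gte(unname(cz["hi"]), unname(cz["estimate"]))
  # Q2 = 0 switches to the bias-corrected form
  Y0 <- c(rep(1, 4), rep(3, 5))
  cz0 <- hybridzone:::chao2(Y0, 8)
  expect_equal(unname(cz0["estimate"]), 9 + (7 / 8) * 4 * 3 / 2,
               tolerance = 1e-12)
})

test_that("AR(g = N) recovers A exactly and AR is monotone in g (fuzz)", {
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    gm <- random_geno(n_a = n, n_b = n, n_loci = 2, n_alleles = 5)
    d_full <- diversity(gm, rarefaction_genes = 2 * n)
    expect_equal(d_full$by_locus$AR, as.numeric(d_full$by_locus$A),
                 tolerance = 1e-10)
    ar_seq <- sapply(2:(2 * n), function(g)
      diversity(gm, rarefaction_genes = g)$by_locus$AR[1])
    expect_true(all(diff(ar_seq) >= -1e-12))
  }
})

test_that("accumulation curve starts at the observed richness and is monotone", {
  set.seed(7)
  gm <- random_geno(n_a = 15, n_b = 5, n_loci = 4, n_alleles = 6)
  cv <- accumulation_curve(gm, "A", n_boot = 50, seed = 8)
  d <- diversity(gm)
  S_obs <- d$by_pop$S_obs[d$by_pop$pop == "A"]
  expect_equal(cv$S[cv$t == 15], S_obs, tolerance = 1e-9)
  expect_true(all(diff(cv$S) >= -1e-9))
  expect_equal(unique(cv$method[cv$t > 15]), "extrapolated")
})

test_that("single-individual expectation equals the mean per-individual allele count", {
  set.seed(9)
  gm <- random_geno(n_a = 12, n_b = 4, n_loci = 3, n_alleles = 5)
  cv <- accumulation_curve(gm, "A", n_boot = 20, seed = 10)
  # direct resampling oracle: alleles carried by each single individual
  per_ind <- sapply(unique(gm$id[gm$pop == "A"]), function(i) {
    sub <- gm[gm$id == i, ]
    length(unique(paste(sub$locus, c(sub$a1, sub$a2))))
  })
  expect_equal(cv$S[cv$t == 1], mean(per_ind), tolerance = 1e-9)
})

test_that("HWE exact test handles monomorphic and biallelic enumeration", {
  gm <- genotype_tbl(tibble::tibble(
    id = sprintf("m%d", 1:6), pop = "A", locus = "L1",
    a1 = 101L, a2 = 101L))
  expect_equal(hwe_exact(gm, "A", "L1"), 1.0)

  # AA = 3, Aa = 4, aa = 3: compare with an independent shuffling oracle
  gm2 <- genotype_tbl(tibble::tibble(
    id = sprintf("b%d", 1:10), pop = "A", locus = "L1",
    a1 = c(rep(101L, 3), rep(101L, 4), rep(102L, 3)),
    a2 = c(rep(101L, 3), rep(102L, 4), rep(102L, 3))))
  p_pkg <- hwe_exact(gm2, "A", "L1")
  # oracle: sample many random pairings of the 20 gene copies
  set.seed(11)
  copies <- c(rep(1L, 10), rep(2L, 10))
  prob_of <- function(h) {
    n11 <- (10 - h) / 2; n22 <- 10 - n11 - h
    exp(lgamma(11) - lgamma(n11 + 1) - lgamma(h + 1) - lgamma(n22 + 1) +
          h * log(2) + lgamma(11) + lgamma(11) - lgamma(21))
  }
  p_obs <- prob_of(4)
  hets <- replicate(30000, {
    s <- sample(copies)
    sum(s[seq(1, 19, 2)] != s[seq(2, 20, 2)])
  })
  p_mc <- mean(sapply(hets, prob_of) <= p_obs * (1 + 1e-9))
  expect_lt(abs(p_pkg - p_mc), 0.015)
})

test_that("r_bar_d is 1 for a duplicated locus and matches a hand computation", {
  set.seed(12)
  one <- random_geno(n_a = 12, n_b = 0, n_loci = 1, n_alleles = 4)
  dup <- one; dup$locus <- "L2"
  gm <- genotype_tbl(dplyr::bind_rows(one, dup))
  r <- rbar_d(gm, n_perm = 49, seed = 13)
  expect_equal(r$rbar_d, 1, tolerance = 1e-10)

  # 4-individual toy: direct covariance-formula computation
  gm4 <- genotype_tbl(tibble::tibble(
    id = rep(c("a", "b", "c", "d"), each = 2),
    pop = "A",
    locus = rep(c("L1", "L2"), 4),
    a1 = c(101L, 201L, 101L, 202L, 102L, 201L, 102L, 202L),
    a2 = c(101L, 201L, 102L, 202L, 102L, 202L, 102L, 202L)))
  r4 <- rbar_d(gm4, n_perm = 19, seed = 14)
  # per-locus allele-mismatch distances over all 6 individual pairs
  dist_of <- function(g1, g2) {
    shared <- 0; b <- g2
    for (x in g1) { hit <- match(x, b); if (!is.na(hit)) { shared <- shared + 1; b <- b[-hit] } }
    2 - shared
  }
  genos <- list(a = list(c(101, 101), c(201, 201)),
                b = list(c(101, 102), c(202, 202)),
                c = list(c(102, 102), c(201, 202)),
                d = list(c(102, 102), c(202, 202)))
  pairs <- combn(names(genos), 2)
  dmat <- sapply(1:2, function(l)
    apply(pairs, 2, function(pr) dist_of(genos[[pr[1]]][[l]], genos[[pr[2]]][[l]])))
  vcov_n <- function(x, y) mean(x * y) - mean(x) * mean(y)
  expected <- vcov_n(dmat[, 1], dmat[, 2]) /
    sqrt(vcov_n(dmat[, 1], dmat[, 1]) * vcov_n(dmat[, 2], dmat[, 2]))
  expect_equal(r4$rbar_d, expected, tolerance = 1e-12)
})

test_that("r_bar_d is near zero for independent loci", {
  set.seed(15)
  gm <- random_geno(n_a = 200, n_b = 0, n_loci = 6, n_alleles = 6)
  r <- rbar_d(gm, n_perm = 99, seed = 16)
  expect_lt(abs(r$rbar_d), 0.02)
  expect_gt(r$p, 0.01)
})

test_that("null-allele EM matches a grid-search ML oracle on all-homozygote data", {
  gm <- genotype_tbl(tibble::tibble(
    id = sprintf("n%02d", 1:10), pop = "A", locus = "L1",
    a1 = rep(c(101L, 102L), c(6, 4)), a2 = rep(c(101L, 102L), c(6, 4))))
  est <- null_allele_freq(gm, "A", "L1")
  # conditional log-likelihood over a 2-D grid (pn, pA), pB = 1 - pn - pA
  loglik <- function(pn, pA) {
    pB <- 1 - pn - pA
    6 * log(pA^2 + 2 * pA * pn) + 4 * log(pB^2 + 2 * pB * pn) -
      10 * log(1 - pn^2)
  }
  grid <- expand.grid(pn = seq(0.001, 0.998, 1e-3), pA = seq(0.001, 0.998, 1e-3))
  grid <- grid[grid$pn + grid$pA < 0.999, ]
  ll <- loglik(grid$pn, grid$pA)
  pn_hat <- grid$pn[which.max(ll)]
  # the likelihood is nearly flat at the boundary; require the EM estimate to
  # attain the grid maximum (profile over pA) within a small likelihood gap
  prof_em <- max(loglik(est$null_freq,
                        seq(0.001, 1 - est$null_freq - 0.001, 1e-3)))
  expect_lt(max(ll) - prof_em, 0.02)
  expect_lt(abs(est$null_freq - pn_hat), 0.05)
})

test_that("null-allele EM reports no excess under HWE and recovers a true 0.2", {
  set.seed(17)
  ests0 <- replicate(60, {
    gm <- hwe_locus_geno(n = 80)
    null_allele_freq(gm, "A", "L1")$null_freq
  })
  expect_lt(mean(ests0), 0.02)

  ests <- replicate(100, {
    # true null allele at frequency 0.2; null homozygotes appear as missing
    freqs <- c(rep(0.8 / 6, 6), 0.2)
    a1 <- sample.int(7, 120, TRUE, prob = freqs)
    a2 <- sample.int(7, 120, TRUE, prob = freqs)
    null1 <- a1 == 7; null2 <- a2 == 7
    obs1 <- ifelse(null1 & null2, NA, ifelse(null1, a2, a1))
    obs2 <- ifelse(null1 & null2, NA, ifelse(null1 | null2,
                                             ifelse(null1, a2, a1), a2))
    lo <- pmin(obs1, obs2) + 100L; hi <- pmax(obs1, obs2) + 100L
    gm <- genotype_tbl(tibble::tibble(
      id = sprintf("x%03d", 1:120), pop = "A", locus = "L1",
      a1 = lo, a2 = hi))
    null_allele_freq(gm, "A", "L1")$null_freq
  })
  expect_lt(abs(mean(ests) - 0.2), 0.05)
})

test_that("Weir-Cockerham theta: fixed differences, toy oracle and fuzzing", {
  # reciprocally fixed populations
  gm_fix <- genotype_tbl(tibble::tibble(
    id = sprintf("f%02d", 1:12), pop = rep(c("A", "B"), each = 6),
    locus = "L1", a1 = rep(c(101L, 102L), each = 6),
    a2 = rep(c(101L, 102L), each = 6)))
  f <- suppressWarnings(pairwise_fst(gm_fix, n_perm = 99, n_boot = 50, seed = 18))
  expect_equal(f$theta[1, 2], 1)
  expect_lte(f$p[1, 2], 0.05)

  # 5 + 5 diploids with allele copies {A:8,B:2} vs {A:2,B:8}
  set.seed(19)
  gm_toy <- geno_from_copies(rep(c(101L, 102L), c(8, 2)),
                             rep(c(101L, 102L), c(2, 8)))
  f_toy <- suppressWarnings(pairwise_fst(gm_toy, n_perm = 9, n_boot = 9, seed = 20))
  expect_equal(f_toy$theta[1, 2], wc_theta_oracle(gm_toy), tolerance = 1e-12)

  # fuzz: 20 random datasets against the independent transcription
  for (i in 1:20) {
    gm <- random_geno(n_a = sample(4:9, 1), n_b = sample(4:9, 1),
                      n_loci = sample(2:4, 1))
    f2 <- suppressWarnings(pairwise_fst(gm, n_perm = 2, n_boot = 2))
    expect_equal(f2$theta[1, 2], wc_theta_oracle(gm), tolerance = 1e-12)
  }
})

test_that("monomorphic pairs report theta 0 with p 1; permutation p never 0", {
  gm <- genotype_tbl(tibble::tibble(
    id = sprintf("z%02d", 1:8), pop = rep(c("A", "B"), each = 4),
    locus = "L1", a1 = 101L, a2 = 101L))
  f <- pairwise_fst(gm, n_perm = 9, n_boot = 9, seed = 21)
  expect_equal(f$theta[1, 2], 0)
  expect_equal(f$p[1, 2], 1)

  set.seed(22)
  gm2 <- random_geno()
  f2 <- suppressWarnings(pairwise_fst(gm2, n_perm = 19, n_boot = 9, seed = 23))
  expect_gte(f2$p[1, 2], 1 / 20)
})

test_that("q-values fall back to Benjamini-Hochberg and handle edge cases", {
  set.seed(24)
  p <- runif(8)
  expect_equal(qvalues(p), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(qvalues(rep(1, 12)), rep(1, 12))
  expect_equal(qvalues(0.37), 0.37)
  # with pi0 estimated, q <= BH q never by more than pi0 inflation
  p2 <- c(runif(50, 0, 0.02), runif(150))
  q2 <- qvalues(p2)
  expect_true(all(q2 <= p.adjust(p2, "BH") + 1e-12))
  expect_true(all(q2 >= 0 & q2 <= 1))
})

test_that("the locus-screening report assembles HWE, linkage and null tables", {
  set.seed(30)
  gm <- random_geno(n_a = 20, n_b = 15, n_loci = 3, n_alleles = 5)
  lt <- suppressWarnings(locus_tests(gm, n_mc = 500, n_perm = 49, seed = 31))
  expect_equal(nrow(lt$hwe), 6)           # 2 pops x 3 loci
  expect_true(all(lt$hwe$p_hwe >= 0 & lt$hwe$p_hwe <= 1, na.rm = TRUE))
  expect_true(all(lt$hwe$q_hwe >= lt$hwe$p_hwe * 0 , na.rm = TRUE))
  expect_equal(nrow(lt$linkage), 2)
  expect_true(all(lt$null_alleles$null_freq >= 0 &
                    lt$null_alleles$null_freq <= 1))
})
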