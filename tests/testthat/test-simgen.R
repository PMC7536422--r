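test_that("prior draws honour degenerate, uniform and conditioned specs", {
  pr <- list(params = list(x = list(dist = "unif", min = 10, max = 10)),
             conditions = list())
  expect_equal(draw_prior(pr, 5, seed = 1)$x, rep(10, 5))

  pr2 <- list(params = list(N1 = list(dist = "unif", min = 100, max = 3e5)),
              conditions = list())
  d <- draw_prior(pr2, 1e5, seed = 2)
  expect_lt(abs(mean(d$N1) - 150050) / 150050, 0.01)

  pr3 <- list(params = list(t2 = list(dist = "unif", min = 0, max = 1000),
                            t1 = list(dist = "unif", min = 0, max = 1000)),
              conditions = list(c("t2", "t1")))
  d3 <- draw_prior(pr3, 2e4, seed = 3)
  expect_true(all(d3$t2 < d3$t1))
  # t2 | t2 < t1 has the decreasing triangular density on (0, T): mean T/3
  expect_lt(abs(mean(d3$t2) - 1000 / 3), 12)
  expect_gt(suppressWarnings(stats::ks.test(d3$t2 / 1000,
            function(q) 1 - (1 - q)^2)$p.value), 0.001)
})

test_that("log-uniform priors stay in bounds with the right median", {
  pr <- list(params = list(mu = list(dist = "logunif", min = 1e-4, max = 1e-3)),
             conditions = list())
  d <- draw_prior(pr, 2e4, seed = 4)
  expect_true(all(d$mu >= 1e-4 & d$mu <= 1e-3))
  expect_lt(abs(median(log10(d$mu)) - (-3.5)), 0.02)
})

test_that("a degenerate prior condition errors instead of spinning", {
  pr <- list(params = list(a = list(dist = "unif", min = 0, max = 1),
                           b = list(dist = "unif", min = 5, max = 6)),
             conditions = list(c("b", "a")))  # b < a impossible
  expect_error(draw_prior(pr, 10, seed = 5), "degenerate prior")
})

test_that("panmictic scenario yields theta centred on zero", {
  set.seed(10)
  scn <- panmictic_scenario()
  th <- replicate(100, {
    gm <- simulate_ssr(scn, mutation_model(), c(20, 15, 10), n_loci = 4)
    suppressWarnings(pairwise_fst(gm, n_perm = 2, n_boot = 2))$theta[1, 2]
  })
  expect_lt(abs(mean(th)), 0.01)
})

test_that("full admixture (r = 1) is indistinguishable from a pure split", {
  set.seed(11)
  pops <- c("AC", "NE", "AS")
  mk_admix <- demographic_scenario(pops, sizes = c(5000, 5000, 5000),
    events = tibble::tibble(time = c(2000, 20000, 20000),
                            type = c("admix", "split", "resize"),
                            a = c(2, 3, 1), b = c(1, 1, NA), c = c(3, NA, NA),
                            r = c(1, NA, 5000)))
  mk_split <- demographic_scenario(pops, sizes = c(5000, 5000, 5000),
    events = tibble::tibble(time = c(2000, 20000, 20000),
                            type = c("split", "split", "resize"),
                            a = c(2, 3, 1), b = c(1, 1, NA), c = NA,
                            r = c(NA, NA, 5000)))
  theta_ne_ac <- function(scn) replicate(60, {
    gm <- simulate_ssr(scn, mutation_model(), c(15, 15, 0), n_loci = 5)
    suppressWarnings(pairwise_fst(gm, n_perm = 2, n_boot = 2))$theta[1, 2]
  })
  ta <- theta_ne_ac(mk_admix); tb <- theta_ne_ac(mk_split)
  se <- sqrt(var(ta) / 60 + var(tb) / 60)
  expect_lt(abs(mean(ta) - mean(tb)), 3.5 * se + 0.005)
})

test_that("segregating sites match Watterson's expectation", {
  set.seed(12)
  N <- 5000; mu <- 1e-6; L <- 500; n <- 10
  scn <- demographic_scenario("A", sizes = N,
    events = tibble::tibble(time = numeric(0), type = character(0),
                            a = integer(0), b = integer(0), c = integer(0),
                            r = numeric(0)))
  S <- replicate(400, {
    ss <- simulate_mtdna(scn, mutation_model(mu_site = mu, seq_length = L), n)
    m <- do.call(rbind, strsplit(ss$seq, ""))
    sum(apply(m, 2, function(col) length(unique(col)) > 1))
  })
  a_n <- sum(1 / seq_len(n - 1))
  expected <- a_n * 2 * N * mu * L           # theta_W = 2 N mu L (haploid)
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))
})

test_that("zero mutation rate gives identical sequences", {
  scn <- panmictic_scenario()
  ss <- simulate_mtdna(scn, mutation_model(mu_site = 0, seq_length = 100),
                       c(5, 5, 5), seed = 13)
  expect_equal(length(unique(ss$seq)), 1)
})

test_that("divergence time zero gives no mtDNA differentiation", {
  set.seed(14)
  scn <- demographic_scenario(c("A", "B"), sizes = c(3000, 3000),
    events = tibble::tibble(time = c(0, 0), type = c("split", "resize"),
                            a = 2, b = c(1, NA), c = NA, r = c(NA, 3000)))
  phist <- replicate(80, {
    ss <- simulate_mtdna(scn, mutation_model(mu_site = 2e-6, seq_length = 400),
                         c(10, 10))
    s <- summarize(ss)
    s[["phist_AB"]]
  })
  expect_lt(abs(mean(phist)), 0.02)
})

test_that("identical seed and config give bit-identical simulations", {
  scn <- panmictic_scenario()
  g1 <- simulate_ssr(scn, mutation_model(), c(10, 5, 5), n_loci = 3, seed = 99)
  g2 <- simulate_ssr(scn, mutation_model(), c(10, 5, 5), n_loci = 3, seed = 99)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  s1 <- simulate_mtdna(scn, mutation_model(), c(5, 5, 5), seed = 98)
  s2 <- simulate_mtdna(scn, mutation_model(), c(5, 5, 5), seed = 98)
  expect_identical(s1$seq, s2$seq)
})

test_that("summary statistics are exchangeable under within-population relabelling", {
  gm <- simulate_ssr(panmictic_scenario(), mutation_model(), c(10, 8, 6),
                     n_loci = 4, seed = 21)
  s1 <- summarize(gm)
  # permute individuals within each population block
  set.seed(22)
  ids <- unique(gm$id)
  meta <- dplyr::distinct(gm[, c("id", "pop")])
  perm <- unlist(lapply(split(meta$id, meta$pop), sample))
  gm2 <- gm[order(match(gm$id, perm), gm$locus), ]
  gm2 <- genotype_tbl(gm2, loci = attr(gm, "loci"), pops = attr(gm, "pops"))
  expect_equal(summarize(gm2), s1)
})

test_that("scenario validation rejects malformed event lists", {
  expect_error(demographic_scenario(c("A", "B"), c(100, 100),
    tibble::tibble(time = c(10, 5), type = c("split", "split"),
                   a = c(2, 1), b = c(1, 2), c = NA, r = NA)),
    "non-decreasing")
  expect_error(demographic_scenario(c("A", "B"), c(100, 100),
    tibble::tibble(time = 5, type = "admix", a = 2, b = 1, c = 1, r = 1.4)),
    "r must lie")
  expect_error(demographic_scenario(c("A", "B", "C"), c(100, 100, 100),
    tibble::tibble(time = 5, type = "split", a = 2, b = 1, c = NA, r = NA)),
    "exactly one lineage pool")
})

test_that("F-model generator hits its target differentiation and marks F1s", {
  set.seed(23)
  th <- replicate(25, {
    gm <- simulate_admixed_genotypes(c(rep(0, 40), rep(1, 40)), fst = 0.18,
                                     pop = rep(c("A", "B"), each = 40))
    suppressWarnings(pairwise_fst(gm, n_perm = 2, n_boot = 2))$theta[1, 2]
  })
  expect_lt(abs(mean(th) - 0.18), 0.04)
  # F1 individuals carry one copy from each cluster: with near-fixed clusters
  # they are heterozygous carrying both cluster-diagnostic alleles
  gm <- simulate_admixed_genotypes(c(0, 1, 0.5), fst = 0.45,
                                   f1 = c(FALSE, FALSE, TRUE), seed = 24)
  expect_equal(length(attr(gm, "true_q")), 3)
})

test_that("the mtDNA scenario catalogue applies its size constraints", {
  cats <- scenario_catalogue("mtdna")
  expect_length(cats, 5)
  par <- list(N1 = 1000, N2 = 2000, NA_ = 3000, ta = 500)
  expect_equal(cats$scenario1(par)$sizes, c(1000, 2000))
  expect_equal(cats$scenario2(par)$sizes, c(3000, 2000))   # N1 = NA
  expect_equal(cats$scenario3(par)$sizes, c(1000, 1000))   # N2 = N1
  expect_equal(cats$scenario4(par)$sizes, c(3000, 3000))   # all equal
  expect_equal(cats$scenario5(par)$sizes, c(1000, 3000))   # N2 = NA
  scn <- cats$scenario5(par)
  expect_equal(scn$events$time, c(500, 500))
  ss <- simulate_mtdna(scn, mutation_model(mu_site = 1e-6, seq_length = 200),
                       c(6, 6), seed = 71)
  expect_equal(nrow(ss), 12)
})
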