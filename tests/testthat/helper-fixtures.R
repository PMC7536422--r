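# Fixtures and independent oracles shared across the suite.  Everything is
# generated in code; no binary data.

options(hybridzone.verbosity = "WARN")

# small genotype table built by hand
toy_geno <- function() {
  genotype_tbl(tibble::tibble(
    id = rep(c("i1", "i2", "i3", "i4"), each = 2),
    pop = rep(c("A", "A", "B", "B"), each = 2),
    locus = rep(c("L1", "L2"), 4),
    a1 = c(101L, 201L, 101L, 202L, 102L, 201L, 102L, 202L),
    a2 = c(102L, 202L, 101L, 203L, 102L, 203L, 103L, 202L)))
}

# two-population genotypes with given allele copies at one locus
geno_from_copies <- function(copies_a, copies_b) {
  pair_up <- function(copies, pop, off) {
    copies <- sample(copies)   # random pairing
    n <- length(copies) / 2
    tibble::tibble(
      id = paste0(pop, seq_len(n) + off),
      pop = pop, locus = "L1",
      a1 = pmin(copies[2 * seq_len(n) - 1], copies[2 * seq_len(n)]),
      a2 = pmax(copies[2 * seq_len(n) - 1], copies[2 * seq_len(n)]))
  }
  genotype_tbl(dplyr::bind_rows(pair_up(copies_a, "A", 0),
                                pair_up(copies_b, "B", 0)))
}

# ---- independent Weir-Cockerham (1984) transcription --------------------
# Literal per-allele transcription of the variance-component formulas,
# written directly from the published definitions and kept independent of
# the package implementation (plain loops, no shared helpers).
wc_theta_oracle <- function(gm) {
  loci <- unique(gm$locus)
  pops <- unique(gm$pop)
  r <- length(pops)
  num <- 0; den <- 0
  for (loc in loci) {
    sub <- gm[gm$locus == loc & !is.na(gm$a1), ]
    n_i <- sapply(pops, function(p) sum(sub$pop == p))
    if (any(n_i < 1)) next
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    alleles <- sort(unique(c(sub$a1, sub$a2)))
    for (al in alleles) {
      p_i <- sapply(pops, function(p) {
        s <- sub[sub$pop == p, ]
        (sum(s$a1 == al) + sum(s$a2 == al)) / (2 * nrow(s))
      })
      h_i <- sapply(pops, function(p) {
        s <- sub[sub$pop == p, ]
        mean(s$a1 != s$a2 & (s$a1 == al | s$a2 == al))
      })
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
           ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# random small two-population genotype dataset for fuzzing
random_geno <- function(n_a = 8, n_b = 6, n_loci = 3, n_alleles = 4) {
  ids <- sprintf("r%02d", seq_len(n_a + n_b))
  pop <- rep(c("A", "B"), c(n_a, n_b))
  recs <- lapply(seq_len(n_loci), function(l) {
    a1 <- sample.int(n_alleles, n_a + n_b, replace = TRUE) + 100L
    a2 <- sample.int(n_alleles, n_a + n_b, replace = TRUE) + 100L
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    tibble::tibble(id = ids, pop = pop, locus = paste0("L", l),
                   a1 = lo, a2 = hi)
  })
  genotype_tbl(dplyr::bind_rows(recs))
}

# forward Wright-Fisher drift of a biallelic frequency
wf_drift <- function(p0, n_dip, t) {
  p <- p0
  for (g in seq_len(t)) p <- rbinom(1, 2 * n_dip, p) / (2 * n_dip)
  p
}

# drift-divergence dataset: loci diverge by pure drift (no mutation) from
# ancestral frequencies for t generations in two populations of N diploids
wf_divergence_geno <- function(n_loci = 20, N = 50, t = 100, n_sample = 25) {
  recs <- list()
  ids <- sprintf("w%02d", seq_len(2 * n_sample))
  pop <- rep(c("A", "B"), each = n_sample)
  for (l in seq_len(n_loci)) {
    p0 <- runif(1, 0.2, 0.8)
    pa <- wf_drift(p0, N, t); pb <- wf_drift(p0, N, t)
    draw <- function(p, n) matrix(rbinom(2 * n, 1, p), n, 2)
    ga <- draw(pa, n_sample); gb <- draw(pb, n_sample)
    g <- rbind(ga, gb) + 101L
    recs[[l]] <- tibble::tibble(id = ids, pop = pop, locus = paste0("L", l),
                                a1 = pmin(g[, 1], g[, 2]),
                                a2 = pmax(g[, 1], g[, 2]))
  }
  genotype_tbl(dplyr::bind_rows(recs))
}

# genotypes drawn exactly under Hardy-Weinberg at one locus
hwe_locus_geno <- function(n = 50, freqs = rep(1 / 8, 8), pop = "A") {
  a1 <- sample.int(length(freqs), n, replace = TRUE, prob = freqs) + 100L
  a2 <- sample.int(length(freqs), n, replace = TRUE, prob = freqs) + 100L
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  genotype_tbl(tibble::tibble(
    id = sprintf("h%03d", seq_len(n)), pop = pop, locus = "L1",
    a1 = lo, a2 = hi))
}

# null model for panmictic scenario used in several tests
panmictic_scenario <- function(N = 1000) {
  demographic_scenario(
    c("A", "B", "C"), sizes = rep(N, 3),
    events = tibble::tibble(time = c(0, 0), type = c("split", "split"),
                            a = c(2, 3), b = c(1, 1), c = NA, r = NA))
}

# canonical ordering for round-trip comparisons (readers and simulators may
# emit rows individual-major or locus-major)
geno_sorted <- function(g) {
  as.data.frame(dplyr::arrange(as.data.frame(g), id, locus))
}
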