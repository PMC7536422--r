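# Classical microsatellite population-genetic statistics: diversity with
# rarefaction and Chao extrapolation, exact HWE tests, multilocus linkage
# (r_bar_d), EM null-allele frequencies, Weir-Cockerham pairwise FST with
# permutation tests and bootstrap-over-loci confidence intervals, and Storey
# q-values for multiple testing.

# ---- diversity ----------------------------------------------------------

# rarefied allelic richness at g gene copies from allele copy counts
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

# incidence-based Chao2 estimator with (T-1)/T correction and log-normal CI;
# Y = incidence counts (number of sampling units holding each species)
chao2 <- function(Y, T_units, conf = 0.95) {
  S_obs <- sum(Y > 0)
  Q1 <- sum(Y == 1); Q2 <- sum(Y == 2)
  k <- (T_units - 1) / T_units
  if (Q2 > 0) {
    S <- S_obs + k * Q1^2 / (2 * Q2)
    R <- Q1 / Q2
    v <- Q2 * (k * R^2 / 2 + k^2 * R^3 + k^2 * R^4 / 4)
  } else {
    S <- S_obs + k * Q1 * (Q1 - 1) / 2
    v <- k * Q1 * (Q1 - 1) / 2 + k^2 * Q1 * (2 * Q1 - 1)^2 / 4 -
      k^2 * Q1^4 / (4 * max(S, 1))
    v <- max(v, 0)
  }
  T_est <- max(S - S_obs, 1e-10)
  z <- qnorm(1 - (1 - conf) / 2)
  Kf <- exp(z * sqrt(log(1 + v / T_est^2)))
  c(estimate = S, lo = S_obs + T_est / Kf, hi = S_obs + T_est * Kf)
}

#' Per-population genetic diversity summary
#'
#' Per locus and population: number of alleles A, effective number of
#' alleles Ae = 1 / sum(p^2), rarefied allelic richness AR at
#' `rarefaction_genes` gene copies, and observed heterozygosity Ho.  Per
#' population, the Chao2 incidence-based extrapolation (individuals as
#' sampling units, alleles at all loci pooled) estimates the total allele
#' count At with a log-normal 95% CI.
#'
#' @param gm a `geno_tbl` (missing calls are ignored per locus)
#' @param rarefaction_genes standardised subsample size in gene copies
#' @return an `hz_diversity` object; `tidy()` returns the per-population table
#' @export
diversity <- function(gm, rarefaction_genes = 44) {
  enc <- geno_encode(gm)
  L <- length(enc$loci)
  by_locus <- list()
  for (pi in seq_along(enc$pop_levels)) {
    rows <- which(enc$pop == pi)
    for (l in seq_len(L)) {
      a1 <- enc$alleles[rows, 2 * l - 1]; a2 <- enc$alleles[rows, 2 * l]
      ok <- a1 > 0
      if (!any(ok)) next
      counts <- tabulate(c(a1[ok], a2[ok]), nbins = enc$nall[l])
      counts <- counts[counts > 0]
      p <- counts / sum(counts)
      ar <- rarefied_richness(counts, rarefaction_genes)
      if (is.na(ar))
        hz_log("WARN", "AR undefined for locus ", enc$loci[l], " in ",
               enc$pop_levels[pi], ": g > sampled gene copies")
      by_locus[[length(by_locus) + 1L]] <- tibble(
        pop = enc$pop_levels[pi], locus = enc$loci[l],
        n = sum(ok), A = length(counts), Ae = 1 / sum(p^2),
        AR = ar, Ho = mean(a1[ok] != a2[ok]))
    }
  }
  by_locus <- bind_rows(by_locus)
  by_pop <- by_locus |>
    group_by(.data$pop) |>
    summarise(n = max(.data$n), A = mean(.data$A), Ae = mean(.data$Ae),
              AR = mean(.data$AR), Ho = mean(.data$Ho), .groups = "drop")
  # Chao2 over pooled allele incidences (individuals = sampling units)
  chao <- lapply(seq_along(enc$pop_levels), function(pi) {
    rows <- which(enc$pop == pi)
    Y <- unlist(lapply(seq_len(L), function(l) {
      a1 <- enc$alleles[rows, 2 * l - 1]; a2 <- enc$alleles[rows, 2 * l]
      ok <- a1 > 0
      vapply(seq_len(enc$nall[l]), function(j)
        sum(ok & (a1 == j | a2 == j)), integer(1))
    }))
    cz <- chao2(Y, length(rows))
    tibble(pop = enc$pop_levels[pi], At = cz["estimate"],
           At_lo = cz["lo"], At_hi = cz["hi"],
           S_obs = sum(Y > 0))
  }) |> bind_rows()
  by_pop <- left_join(by_pop, chao, by = "pop")
  by_pop <- by_pop[match(enc$pop_levels, by_pop$pop), ]
  structure(list(by_pop = by_pop, by_locus = by_locus,
                 rarefaction_genes = rarefaction_genes),
            class = "hz_diversity")
}

#' @export
print.hz_diversity <- function(x, ...) {
  cat("Genetic diversity (AR at", x$rarefaction_genes, "genes):\n")
  print(as.data.frame(x$by_pop), digits = 4)
  invisible(x)
}

#' Allele accumulation curve with Chao2-anchored extrapolation
#'
#' Interpolation is the incidence-based rarefaction expectation of the total
#' allele count (all loci pooled) over t individuals; extrapolation beyond
#' the observed sample approaches the Chao2 asymptote exponentially.  The
#' 95% band comes from a bootstrap over individuals.
#'
#' @param gm a `geno_tbl`
#' @param pop population to assess
#' @param max_extrap largest sample size on the curve (default 2x observed)
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @return a tibble with columns `t`, `method`, `S`, `lo`, `hi`
#' @export
accumulation_curve <- function(gm, pop, max_extrap = NULL, n_boot = 200,
                               seed = NULL) {
  with_seed_logged(seed, "accumulation_curve")
  enc <- geno_encode(gm)
  pi <- match(pop, enc$pop_levels)
  if (is.na(pi)) stop("unknown population: ", pop)
  rows <- which(enc$pop == pi)
  T_obs <- length(rows)
  if (T_obs < 2) stop("need at least 2 individuals")
  max_extrap <- max_extrap %||% (2L * T_obs)

  incidence <- function(rws) {
    unlist(lapply(seq_along(enc$loci), function(l) {
      a1 <- enc$alleles[rws, 2 * l - 1]; a2 <- enc$alleles[rws, 2 * l]
      ok <- a1 > 0
      vapply(seq_len(enc$nall[l]), function(j)
        sum(ok & (a1 == j | a2 == j)), integer(1))
    }))
  }
  curve_of <- function(Y, T_units) {
    Y <- Y[Y > 0]
    S_obs <- length(Y)
    interp <- vapply(seq_len(T_units), function(t)
      sum(1 - exp(lchoose(T_units - Y, t) - lchoose(T_units, t))), numeric(1))
    ex_t <- seq_len(max(0, max_extrap - T_units))
    if (length(ex_t)) {
      cz <- chao2(Y, T_units)
      Q1 <- sum(Y == 1)
      Q0 <- max(cz["estimate"] - S_obs, 0)
      extr <- if (Q0 > 0 && Q1 > 0)
        S_obs + Q0 * (1 - (1 - Q1 / (T_units * Q0 + Q1))^ex_t)
      else rep(S_obs, length(ex_t))
    } else extr <- numeric(0)
    c(interp, extr)
  }
  S_hat <- curve_of(incidence(rows), T_obs)
  boot <- matrix(NA_real_, n_boot, length(S_hat))
  for (b in seq_len(n_boot)) {
    rws <- sample(rows, T_obs, replace = TRUE)
    bc <- curve_of(incidence(rws), T_obs)
    boot[b, seq_along(bc)] <- bc
  }
  lo <- apply(boot, 2, quantile, 0.025, na.rm = TRUE)
  hi <- apply(boot, 2, quantile, 0.975, na.rm = TRUE)
  tibble(t = seq_along(S_hat), method = ifelse(seq_along(S_hat) <= T_obs,
                                               "interpolated", "extrapolated"),
         S = S_hat, lo = lo, hi = hi)
}

# ---- HWE exact test -----------------------------------------------------

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on allele counts, the probability of a genotype array is
#' proportional to 2^H / prod(n_ij!).  The p-value is the probability of
#' arrays no more probable than the observed one: computed by full
#' enumeration for biallelic loci, and by Guo-Thompson Monte-Carlo
#' permutation of gene copies otherwise (add-one rule).
#'
#' @param gm a `geno_tbl`
#' @param pop population label
#' @param locus locus name
#' @param n_mc Monte-Carlo shuffles
#' @param seed RNG seed
#' @return the p-value
#' @export
hwe_exact <- function(gm, pop, locus, n_mc = 100000, seed = NULL) {
  with_seed_logged(seed, "hwe_exact")
  sub <- gm[gm$pop == pop & gm$locus == locus & !is.na(gm$a1), ]
  if (nrow(sub) < 3) stop("need at least 3 complete genotypes")
  sz <- sort(unique(c(sub$a1, sub$a2)))
  if (length(sz) < 2) return(1.0)
  i1 <- match(sub$a1, sz); i2 <- match(sub$a2, sz)
  if (length(sz) == 2) return(hwe_enumerate_biallelic(i1, i2))
  cnt <- cpp_hwe_mc(i1, i2, length(sz), as.integer(n_mc))
  (cnt + 1) / (n_mc + 1)
}

# exact enumeration over heterozygote counts for two alleles
hwe_enumerate_biallelic <- function(i1, i2) {
  n <- length(i1)
  nA <- sum(i1 == 1) + sum(i2 == 1)
  het_obs <- sum(i1 != i2)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    n11 <- (nA - h) / 2; n22 <- n - n11 - h
    lgamma(n + 1) - lgamma(n11 + 1) - lgamma(h + 1) - lgamma(n22 + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(het_obs, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}

# ---- multilocus linkage -------------------------------------------------

#' Standardised index of association r_bar_d
#'
#' Multilocus linkage disequilibrium: per-locus genetic distances between
#' individuals (number of allele differences, 0/1/2), with
#' r_bar_d = sum cov(d_j, d_k) / sum sqrt(var d_j var d_k) over locus pairs.
#' The null distribution permutes genotypes among individuals independently
#' at each locus.
#'
#' @param gm a `geno_tbl` (one population; subset first)
#' @param pop optional population label to subset
#' @param n_perm permutations
#' @param seed RNG seed
#' @return list with `rbar_d`, `p`, `n_perm`
#' @export
rbar_d <- function(gm, pop = NULL, n_perm = 999, seed = NULL) {
  with_seed_logged(seed, "rbar_d")
  if (!is.null(pop)) gm <- gm[gm$pop == pop, ]
  gm <- filter_complete(gm)
  enc <- geno_encode(gm)
  L <- length(enc$loci); n <- length(enc$ids)
  if (L < 2) stop("need at least 2 loci")
  dists <- list()
  for (l in seq_len(L)) {
    a1 <- enc$alleles[, 2 * l - 1]; a2 <- enc$alleles[, 2 * l]
    if (length(unique(c(a1, a2))) < 2) {
      warning("monomorphic locus ", enc$loci[l], " excluded from r_bar_d")
      next
    }
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sh <- length(intersect_multiset(c(a1[i], a2[i]), c(a1[j], a2[j])))
      D[i, j] <- D[j, i] <- 2 - sh
    }
    dists[[length(dists) + 1L]] <- D
  }
  if (length(dists) < 2) stop("fewer than 2 polymorphic loci")
  vecs <- vapply(dists, function(D) D[lower.tri(D)], numeric(n * (n - 1) / 2))
  Cv <- cov(vecs) * (nrow(vecs) - 1) / nrow(vecs)
  num <- sum(Cv[lower.tri(Cv)])
  den <- 0
  for (j in seq_len(ncol(Cv) - 1)) for (k in (j + 1):ncol(Cv))
    den <- den + sqrt(Cv[j, j] * Cv[k, k])
  obs <- num / den
  perms <- cpp_rbard_perm(dists, as.integer(n_perm))
  p <- (sum(perms >= obs - 1e-12) + 1) / (n_perm + 1)
  list(rbar_d = obs, p = p, n_perm = n_perm)
}

intersect_multiset <- function(a, b) {
  out <- c()
  for (x in a) {
    hit <- match(x, b)
    if (!is.na(hit)) { out <- c(out, x); b <- b[-hit] }
  }
  out
}

# ---- null alleles -------------------------------------------------------

#' EM estimate of the null-allele frequency at a locus
#'
#' Maximum-likelihood frequency of a single unobservable null allele
#' explaining homozygote excess under random mating, conditional on the
#' observed (non-blank) genotypes; the genotyping-failure rate is reported
#' as the observed missing fraction.
#'
#' @param gm a `geno_tbl`
#' @param pop population label
#' @param locus locus name
#' @param max_iter,tol EM controls
#' @return list with `null_freq`, `failure_rate`, `n`
#' @export
null_allele_freq <- function(gm, pop, locus, max_iter = 500, tol = 1e-9) {
  sub <- gm[gm$pop == pop & gm$locus == locus, ]
  miss <- is.na(sub$a1)
  obs <- sub[!miss, ]
  n_obs <- nrow(obs)
  if (n_obs < 10) hz_log("WARN", "null_allele_freq: fewer than 10 complete genotypes")
  sz <- sort(unique(c(obs$a1, obs$a2)))
  A <- length(sz)
  i1 <- match(obs$a1, sz); i2 <- match(obs$a2, sz)
  hom <- i1 == i2
  # counts
  hom_cnt <- tabulate(i1[hom], nbins = A)
  copy_cnt <- tabulate(c(i1, i2), nbins = A)
  pn <- 0.05
  p <- copy_cnt / sum(copy_cnt) * (1 - pn)
  for (it in seq_len(max_iter)) {
    # E: each observed homozygote i/i is a null het with prob w_i
    w <- ifelse(p > 0, 2 * pn / (p[seq_len(A)] + 2 * pn), 0)
    null_from_hom <- sum(hom_cnt * w)
    # unobserved null/null individuals, conditional on observation
    m <- n_obs * pn^2 / max(1 - pn^2, 1e-12)
    tot <- 2 * (n_obs + m)
    pn_new <- (null_from_hom + 2 * m) / tot
    p_new <- (copy_cnt - hom_cnt * w) / tot
    if (abs(pn_new - pn) < tol) { pn <- pn_new; p <- p_new; break }
    pn <- pn_new; p <- p_new
  }
  list(null_freq = min(max(pn, 0), 1), failure_rate = mean(miss), n = n_obs)
}

# ---- FST ----------------------------------------------------------------

#' Pairwise Weir-Cockerham FST with permutation tests and bootstrap CIs
#'
#' Variance components a, b, c summed over alleles and loci give
#' theta = sum(a) / sum(a + b + c) for each population pair.  Significance:
#' individuals shuffled between the pair (add-one permutation p-value).
#' 95% CI: percentile bootstrap over loci.
#'
#' @param gm a `geno_tbl`
#' @param n_perm permutations per pair
#' @param n_boot bootstrap replicates over loci
#' @param seed RNG seed
#' @return an `hz_fst` object; `tidy()` returns one row per pair
#' @export
pairwise_fst <- function(gm, n_perm = 100000, n_boot = 10000, seed = NULL) {
  with_seed_logged(seed, "pairwise_fst")
  enc <- geno_encode(gm)
  pops <- enc$pop_levels
  npop <- length(pops)
  if (npop < 2) stop("need at least 2 populations")
  theta <- matrix(NA_real_, npop, npop, dimnames = list(pops, pops))
  pmat <- theta; lo <- theta; hi <- theta
  rows_of <- function(pi) which(enc$pop == pi)
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    rows <- c(rows_of(i), rows_of(j))
    if (length(rows_of(i)) < 2 || length(rows_of(j)) < 2)
      stop("each population needs at least 2 individuals")
    sub <- enc$alleles[rows, , drop = FALSE]
    popv <- c(rep(1L, length(rows_of(i))), rep(2L, length(rows_of(j))))
    comp <- cpp_wc_components(sub, enc$nall, popv, 2L)
    num <- sum(comp[, 1]); den <- sum(comp)
    th <- if (den > 0) num / den else 0
    theta[j, i] <- theta[i, j] <- th
    if (den <= 0) { pmat[j, i] <- pmat[i, j] <- 1; lo[i, j] <- hi[i, j] <- 0; next }
    perms <- cpp_wc_perm(sub, enc$nall, popv, 2L, as.integer(n_perm))
    pmat[j, i] <- pmat[i, j] <- (sum(perms >= th - 1e-12) + 1) / (n_perm + 1)
    bs <- vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(nrow(comp), replace = TRUE)
      a <- sum(comp[pick, 1]); d <- sum(comp[pick, ])
      if (d > 0) a / d else 0
    }, numeric(1))
    qs <- quantile(bs, c(0.025, 0.975))
    lo[i, j] <- lo[j, i] <- qs[1]; hi[i, j] <- hi[j, i] <- qs[2]
  }
  structure(list(theta = theta, p = pmat, ci_lo = lo, ci_hi = hi,
                 n_perm = n_perm, n_boot = n_boot),
            class = "hz_fst")
}

#' @export
print.hz_fst <- function(x, ...) {
  cat("Pairwise Weir-Cockerham theta (lower), permutation p (upper):\n")
  m <- x$theta
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, 4))
  invisible(x)
}

# single multi-locus theta for summary statistics (two populations)
wc_theta <- function(alleles, nall, popv) {
  comp <- cpp_wc_components(alleles, nall, popv, max(popv))
  den <- sum(comp)
  if (den > 0) sum(comp[, 1]) / den else 0
}

# ---- q-values -----------------------------------------------------------

#' Storey q-values
#'
#' pi0 is estimated on a lambda grid with a cubic smoother extrapolated to
#' lambda = 1; monotonicity of q is enforced.  With fewer than 10 p-values
#' pi0 is fixed at 1 (Benjamini-Hochberg), logged.
#'
#' @param p vector of p-values in `[0, 1]`
#' @param lambda grid for the pi0 smoother
#' @return vector of q-values
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (m < 10) {
    hz_log("INFO", "qvalues: <10 p-values, pi0 fixed at 1 (BH)")
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  rank_desc <- m:1
  q[ord] <- cummin(pi0 * m * p[ord] / rank_desc)
  pmin(q, 1)
}

#' Per-locus HWE, linkage and null-allele report
#'
#' Convenience wrapper mirroring the locus-screening table of a
#' population-genetic survey: HWE exact p (and Storey q across all tests),
#' per-population r_bar_d with permutation p, and per-locus null-allele and
#' failure-rate estimates.
#'
#' @param gm a `geno_tbl`
#' @param n_mc Monte-Carlo shuffles for the HWE test
#' @param n_perm permutations for r_bar_d
#' @param seed RNG seed
#' @return an `hz_locus_tests` list of tibbles
#' @export
locus_tests <- function(gm, n_mc = 10000, n_perm = 999, seed = NULL) {
  with_seed_logged(seed, "locus_tests")
  enc <- geno_encode(gm)
  hwe <- list()
  for (p in enc$pop_levels) for (l in enc$loci) {
    pv <- tryCatch(hwe_exact(gm, p, l, n_mc = n_mc), error = function(e) NA_real_)
    hwe[[length(hwe) + 1L]] <- tibble(pop = p, locus = l, p_hwe = pv)
  }
  hwe <- bind_rows(hwe)
  hwe$q_hwe <- NA_real_
  ok <- !is.na(hwe$p_hwe)
  hwe$q_hwe[ok] <- qvalues(hwe$p_hwe[ok])
  link <- bind_rows(lapply(enc$pop_levels, function(p) {
    r <- tryCatch(rbar_d(gm, pop = p, n_perm = n_perm),
                  error = function(e) list(rbar_d = NA_real_, p = NA_real_))
    tibble(pop = p, rbar_d = r$rbar_d, p = r$p)
  }))
  nulls <- list()
  for (p in enc$pop_levels) for (l in enc$loci) {
    nf <- null_allele_freq(gm, p, l)
    nulls[[length(nulls) + 1L]] <- tibble(
      pop = p, locus = l, null_freq = nf$null_freq,
      failure_rate = nf$failure_rate)
  }
  structure(list(hwe = hwe, linkage = link, null_alleles = bind_rows(nulls)),
            class = "hz_locus_tests")
}
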