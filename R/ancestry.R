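# Individual ancestry inference: Gibbs sampler for the admixture model with
# correlated allele frequencies (F-model), Evanno delta-K model selection,
# DAPC, and kernel-density overlap along discriminant axes.

#' Fit the admixture model by MCMC
#'
#' Gibbs sampler for the correlated-allele-frequency admixture model:
#' ancestral allele frequencies with per-cluster drift parameters F_k,
#' allele-origin augmentation, Dirichlet updates of the ancestry vectors q
#' and cluster frequencies, and a random-walk Metropolis update of the
#' symmetric Dirichlet parameter alpha (uniform(0, 10) prior, step 0.05).
#' The model log-likelihood estimate uses the running mean/variance
#' convention: ln P(D) = mean(lnL) - var(lnL)/2.
#'
#' @param gm a `geno_tbl` with complete genotypes
#' @param K number of clusters (>= 1)
#' @param burn_in,length chain settings (iterations)
#' @param seed RNG seed
#' @param thin store every `thin`-th post-burn-in sample for the q quantiles
#' @param update_alpha fix alpha when FALSE
#' @return an `admixture_fit`; `tidy()` gives one row per individual and
#'   cluster with posterior mean and 2.5/97.5% quantiles
#' @export
admixture_mcmc <- function(gm, K, burn_in = 10000, length = 50000,
                           seed = NULL, thin = NULL, update_alpha = TRUE) {
  if (K < 1) stop("K must be >= 1")
  with_seed_logged(seed, "admixture_mcmc")
  gm <- filter_complete(gm)
  enc <- geno_encode(gm)
  if (any(enc$alleles == 0L)) stop("admixture_mcmc requires complete genotypes")
  thin <- thin %||% max(1L, as.integer(length / 1000))
  fit <- cpp_admixture_gibbs(enc$alleles, enc$nall, as.integer(K),
                             as.integer(burn_in), as.integer(length),
                             as.integer(thin), 1.0, 0.05, 10.0, update_alpha)
  n <- length(enc$ids)
  qs <- fit$q_samples[seq_len(fit$n_stored), , drop = FALSE]
  qlo <- matrix(NA_real_, n, K); qhi <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) for (k in seq_len(K)) {
    col <- (i - 1) * K + k
    qq <- quantile(qs[, col], c(0.025, 0.975))
    qlo[i, k] <- qq[1]; qhi[i, k] <- qq[2]
  }
  # split-half mixing check on posterior mean q
  if (fit$n_stored >= 20 && K > 1) {
    half <- floor(fit$n_stored / 2)
    d <- abs(colMeans(qs[seq_len(half), , drop = FALSE]) -
             colMeans(qs[(half + 1):fit$n_stored, , drop = FALSE]))
    if (max(d) > 0.1)
      warning("admixture chain may not have mixed (split-half q discrepancy ",
              round(max(d), 3), "); consider a longer run")
  }
  structure(list(
    K = K, ids = enc$ids, pop = enc$pop_levels[enc$pop],
    q_mean = fit$q_mean, q_lo = qlo, q_hi = qhi,
    ln_pd = fit$ln_pd, ln_lik_mean = fit$ln_lik_mean,
    ln_lik_var = fit$ln_lik_var,
    alpha = fit$alpha_mean, F_k = as.numeric(fit$F_mean),
    settings = list(burn_in = burn_in, length = length, thin = thin,
                    seed = seed)),
    class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("Admixture model fit: K =", x$K, " ln P(D) =", round(x$ln_pd, 1), "\n")
  cat("  alpha =", round(x$alpha, 3), " F_k =",
      paste(round(x$F_k, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Replicate admixture runs over a range of K
#'
#' @param gm a `geno_tbl`
#' @param k_range K values (consecutive integers)
#' @param n_rep replicate chains per K
#' @param burn_in,length chain settings
#' @param seed master seed; each run gets a derived sub-seed
#' @return tibble with columns K, rep, ln_pd plus a list-column of fits
#' @export
admixture_scan <- function(gm, k_range = 1:5, n_rep = 10,
                           burn_in = 10000, length = 50000, seed = NULL) {
  out <- list()
  run <- 0L
  for (K in k_range) for (r in seq_len(n_rep)) {
    run <- run + 1L
    fit <- admixture_mcmc(gm, K, burn_in = burn_in, length = length,
                          seed = derive_seed(seed, run))
    out[[run]] <- tibble(K = K, rep = r, ln_pd = fit$ln_pd, fit = list(fit))
  }
  bind_rows(out)
}

#' Evanno delta-K model selection
#'
#' delta-K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)),
#' defined for interior K only; the chosen K maximises delta-K.
#'
#' @param scan a tibble with columns `K`, `rep`, `ln_pd` (>= 3 consecutive
#'   K values, >= 2 replicates each)
#' @return a `delta_k_table` with the per-K table and `chosen_k`
#' @export
delta_k <- function(scan) {
  tab <- scan |>
    group_by(K = .data$K) |>
    summarise(n_rep = dplyr::n(), mean_l = mean(.data$ln_pd),
              sd_l = sd(.data$ln_pd), .groups = "drop") |>
    arrange(.data$K)
  if (nrow(tab) < 3) stop("need at least 3 consecutive K values")
  if (any(tab$n_rep < 2)) stop("need at least 2 replicates per K")
  if (any(tab$sd_l == 0))
    stop("sd of ln P(D) is zero at some K: identical replicates are implausible")
  if (any(diff(tab$K) != 1)) stop("K values must be consecutive")
  dk <- rep(NA_real_, nrow(tab))
  for (i in 2:(nrow(tab) - 1)) {
    dk[i] <- abs(tab$mean_l[i + 1] - 2 * tab$mean_l[i] + tab$mean_l[i - 1]) /
      tab$sd_l[i]
  }
  tab$delta_k <- dk
  chosen <- tab$K[which.max(dk)]
  structure(list(table = tab, chosen_k = chosen), class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(as.data.frame(x$table), digits = 4)
  cat("chosen K:", x$chosen_k, "\n")
  invisible(x)
}

#' Flag possibly admixed individuals
#'
#' Applies the reporting rule used for hybrid-zone surveys: an individual is
#' a "possible admixture" when more than `threshold` of its ancestry points
#' to the opposite cluster, and "significant" only when the 95% credible
#' interval of its home-cluster ancestry excludes 1.
#'
#' @param fit an `admixture_fit` with K = 2
#' @param home named vector mapping population label to home cluster (1 or 2)
#' @param threshold opposite-cluster ancestry threshold
#' @return tibble per individual with q, interval, and the two flags
#' @export
flag_admixed <- function(fit, home, threshold = 0.1) {
  stopifnot(fit$K == 2)
  hk <- home[fit$pop]
  idx <- cbind(seq_along(fit$ids), hk)
  q_home <- fit$q_mean[idx]
  tibble(id = fit$ids, pop = fit$pop, home_cluster = hk,
         q_home = q_home,
         q_lo = fit$q_lo[idx], q_hi = fit$q_hi[idx],
         possible_admixture = 1 - q_home > threshold,
         significant = fit$q_hi[idx] < 1 - 1e-6 &
           (1 - q_home > threshold) & fit$q_hi[idx] < 1)
}

# ---- DAPC ---------------------------------------------------------------

#' Discriminant analysis of principal components
#'
#' Centred allele-count table -> PCA -> linear discriminant analysis on the
#' retained components; group-membership probabilities come from the
#' Gaussian model in discriminant space.
#'
#' @param gm a `geno_tbl`
#' @param groups grouping vector (default: population labels)
#' @param n_pca retained principal components (default: smallest number
#'   explaining >= 90% of variance, capped below n - n_groups)
#' @param n_da retained discriminant axes (default: n_groups - 1)
#' @param seed unused, kept for interface symmetry (DAPC is deterministic)
#' @return a `dapc_fit`
#' @export
dapc <- function(gm, groups = NULL, n_pca = NULL, n_da = NULL, seed = NULL) {
  gm <- filter_complete(gm)
  enc <- geno_encode(gm)
  groups <- groups %||% enc$pop_levels[enc$pop]
  groups <- factor(groups)
  G <- nlevels(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  X <- allele_count_matrix(enc)
  X <- scale(X, center = TRUE, scale = FALSE)
  pc <- prcomp(X, center = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  if (is.null(n_pca)) n_pca <- which(cum >= 0.9)[1]
  max_pca <- nrow(X) - G - 1L
  if (n_pca > max_pca) {
    hz_log("INFO", "dapc: reducing n_pca from ", n_pca, " to ", max_pca)
    n_pca <- max_pca
  }
  n_pca <- max(1L, min(n_pca, sum(ev > 1e-10)))
  scores <- pc$x[, seq_len(n_pca), drop = FALSE]
  n_da <- min(n_da %||% (G - 1L), G - 1L)
  ld <- tryCatch(MASS::lda(scores, grouping = groups),
                 error = function(e) NULL)
  if (is.null(ld)) {
    # degenerate within-group covariance (e.g. perfectly separated
    # clusters): add a deterministic perturbation far below any real signal
    hz_log("INFO", "dapc: singular within-group covariance, regularising")
    eps <- 1e-5 * max(apply(scores, 2, sd), 1e-12)
    scores <- scores + eps * outer(seq_len(nrow(scores)), seq_len(ncol(scores)),
                                   function(i, j) sin(1.7 * i + 0.9 * j))
    ld <- MASS::lda(scores, grouping = groups, tol = 1e-9)
  }
  pr <- predict(ld, as.data.frame(scores))
  coord <- pr$x[, seq_len(min(n_da, ncol(pr$x))), drop = FALSE]
  structure(list(
    ids = enc$ids, groups = groups, n_pca = n_pca, n_da = n_da,
    var_explained = cum[n_pca], coord = coord, posterior = pr$posterior,
    lda = ld), class = "dapc_fit")
}

allele_count_matrix <- function(enc) {
  n <- length(enc$ids); L <- length(enc$loci)
  cols <- sum(enc$nall)
  X <- matrix(0, n, cols)
  off <- 0L
  for (l in seq_len(L)) {
    a1 <- enc$alleles[, 2 * l - 1]; a2 <- enc$alleles[, 2 * l]
    for (j in seq_len(enc$nall[l])) {
      X[, off + j] <- (a1 == j) + (a2 == j)
    }
    off <- off + enc$nall[l]
  }
  X
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat("DAPC:", x$n_pca, "PCs (", round(100 * x$var_explained, 1),
      "% variance ),", ncol(x$coord), "discriminant axes,",
      nlevels(x$groups), "groups\n")
  invisible(x)
}

#' Overlap of two kernel density estimates
#'
#' Gaussian KDE with Silverman's bandwidth on a shared grid; the overlap
#' coefficient is the integral of the pointwise minimum (trapezoid rule),
#' in `[0, 1]`.
#'
#' @param values_a,values_b numeric samples (>= 5 each)
#' @param n_grid grid resolution
#' @return the overlap coefficient
#' @export
density_overlap <- function(values_a, values_b, n_grid = 1024) {
  if (length(values_a) < 5 || length(values_b) < 5)
    stop("need at least 5 values per group")
  if (sd(values_a) == 0 || sd(values_b) == 0)
    stop("degenerate density: zero-variance sample")
  bw_a <- stats::bw.nrd0(values_a); bw_b <- stats::bw.nrd0(values_b)
  from <- min(values_a, values_b) - 4 * max(bw_a, bw_b)
  to <- max(values_a, values_b) + 4 * max(bw_a, bw_b)
  fa <- density(values_a, bw = bw_a, from = from, to = to, n = n_grid)
  fb <- density(values_b, bw = bw_b, from = from, to = to, n = n_grid)
  trapz(fa$x, pmin(fa$y, fb$y))
}

#' Pairwise density overlaps along the first discriminant axis
#' @param fit a `dapc_fit`
#' @return tibble with one row per group pair
#' @export
dapc_overlaps <- function(fit) {
  ax <- fit$coord[, 1]
  gl <- levels(fit$groups)
  out <- list()
  for (i in seq_len(length(gl) - 1)) for (j in (i + 1):length(gl)) {
    ov <- density_overlap(ax[fit$groups == gl[i]], ax[fit$groups == gl[j]])
    out[[length(out) + 1L]] <- tibble(group_a = gl[i], group_b = gl[j],
                                      overlap = ov)
  }
  bind_rows(out)
}
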