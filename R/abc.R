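# Approximate Bayesian computation: summary statistics, reference tables,
# logistic-regression scenario choice, and local-linear (Beaumont) parameter
# posteriors.

# ---- summary statistics -------------------------------------------------

#' Summary-statistic vector for ABC
#'
#' Microsatellite data: per population the mean allele number, mean expected
#' heterozygosity, mean allele-size variance and mean Garza-Williamson M
#' (alleles / (size range + 1)); per pair Weir-Cockerham FST, the
#' (delta mu)^2 distance (squared difference of mean allele sizes), and the
#' mean shared-allele distance.  mtDNA data: per population the haplotype
#' count, segregating sites, mean pairwise differences and Tajima's D (0 with
#' a flag when S = 0); per pair the between-population mean pairwise
#' differences and 1 - pi_within / pi_between.
#'
#' @param dataset a `geno_tbl` or `seq_tbl`
#' @return a named numeric vector with a fixed ordering
#' @export
summarize <- function(dataset) UseMethod("summarize")

#' @rdname summarize
#' @export
summarize.geno_tbl <- function(dataset) {
  enc <- geno_encode(dataset)
  pops <- enc$pop_levels
  out <- c()
  for (pi in seq_along(pops)) {
    rows <- which(enc$pop == pi)
    A <- He <- V <- M <- numeric(length(enc$loci))
    for (l in seq_along(enc$loci)) {
      a1 <- enc$alleles[rows, 2 * l - 1]; a2 <- enc$alleles[rows, 2 * l]
      ok <- a1 > 0
      sz <- enc$sizes[[l]]
      copies <- sz[c(a1[ok], a2[ok])]
      tabs <- table(copies)
      p <- as.numeric(tabs) / length(copies)
      A[l] <- length(tabs)
      He[l] <- 1 - sum(p^2)
      V[l] <- if (length(copies) > 1) var(copies) else 0
      M[l] <- A[l] / (diff(range(copies)) + 1)
    }
    out <- c(out, setNames(c(mean(A), mean(He), mean(V), mean(M)),
                           paste0(c("A_", "He_", "Vsz_", "M_"), pops[pi])))
  }
  if (length(pops) > 1) {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      ri <- which(enc$pop == i); rj <- which(enc$pop == j)
      sub <- enc$alleles[c(ri, rj), , drop = FALSE]
      popv <- c(rep(1L, length(ri)), rep(2L, length(rj)))
      fst <- wc_theta(sub, enc$nall, popv)
      dmu <- das <- numeric(length(enc$loci))
      for (l in seq_along(enc$loci)) {
        a1 <- enc$alleles[, 2 * l - 1]; a2 <- enc$alleles[, 2 * l]
        sz <- enc$sizes[[l]]
        mi <- mean(sz[c(a1[ri], a2[ri])], na.rm = TRUE)
        mj <- mean(sz[c(a1[rj], a2[rj])], na.rm = TRUE)
        dmu[l] <- (mi - mj)^2
        das[l] <- cpp_das_locus(sub[, 2 * l - 1], sub[, 2 * l], popv)
      }
      tag <- paste0(substr(pops[i], 1, 3), substr(pops[j], 1, 3))
      out <- c(out, setNames(c(fst, mean(dmu), mean(das)),
                             paste0(c("fst_", "dmu2_", "das_"), tag)))
    }
  }
  out
}

#' @rdname summarize
#' @export
summarize.seq_tbl <- function(dataset) {
  pops <- unique(dataset$pop)
  mat <- do.call(rbind, strsplit(dataset$seq, ""))
  pairdiff <- function(m) {
    n <- nrow(m)
    if (n < 2) return(0)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
    tot / (n * (n - 1) / 2)
  }
  out <- c()
  for (p in pops) {
    m <- mat[dataset$pop == p, , drop = FALSE]
    n <- nrow(m)
    S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
    pi_w <- pairdiff(m)
    H <- nrow(unique(m))
    D <- if (S > 0 && n > 3) tajimas_d(S, pi_w, n) else 0
    out <- c(out, setNames(c(H, S, pi_w, D),
                           paste0(c("nhap_", "S_", "pi_", "tajD_"), p)))
  }
  if (length(pops) > 1) {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      mi <- mat[dataset$pop == pops[i], , drop = FALSE]
      mj <- mat[dataset$pop == pops[j], , drop = FALSE]
      db <- mean(vapply(seq_len(nrow(mi)), function(a)
        mean(vapply(seq_len(nrow(mj)), function(b)
          sum(mi[a, ] != mj[b, ]), numeric(1))), numeric(1)))
      pw <- (pairdiff(mi) + pairdiff(mj)) / 2
      phist <- if (db > 0) 1 - pw / db else 0
      tag <- paste0(substr(pops[i], 1, 3), substr(pops[j], 1, 3))
      out <- c(out, setNames(c(db, phist), paste0(c("dxy_", "phist_"), tag)))
    }
  }
  out
}

# standard Tajima's D from S, pi and sample size
tajimas_d <- function(S, pi, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(0)
  (pi - S / a1) / denom
}

# ---- reference table ----------------------------------------------------

#' Build an ABC reference table
#'
#' Streams prior draws through the coalescent simulator and the summary
#' statistics, with equal simulation counts per scenario.  Deterministic
#' given `seed` (simulations run in a fixed order).
#'
#' @param scenarios named list of scenario builders (see
#'   [scenario_catalogue()])
#' @param priors prior specification (see [draw_prior()])
#' @param n_sim_per_scenario simulations per scenario
#' @param sample_sizes samples per population (individuals for SSR,
#'   sequences for mtDNA)
#' @param type "ssr" or "mtdna"
#' @param n_loci SSR loci per dataset
#' @param mut_base baseline `mutation_model`; per-draw mutation parameters in
#'   the prior (mu_ssr, p_gsm, mu_site) override its fields
#' @param seed RNG seed
#' @return an `abc_reftable` tibble: `scenario`, parameter columns, then
#'   `ss_`-prefixed summary statistics
#' @export
build_reference <- function(scenarios, priors, n_sim_per_scenario,
                            sample_sizes, type = c("ssr", "mtdna"),
                            n_loci = 6, mut_base = mutation_model(),
                            seed = NULL) {
  type <- match.arg(type)
  with_seed_logged(seed, "build_reference")
  stopifnot(length(scenarios) >= 1, n_sim_per_scenario >= 1)
  draws <- draw_prior(priors, n = n_sim_per_scenario * length(scenarios))
  rows <- vector("list", nrow(draws))
  idx <- 0L
  for (s in seq_along(scenarios)) {
    for (i in seq_len(n_sim_per_scenario)) {
      idx <- idx + 1L
      par <- as.list(draws[idx, ])
      mut <- mut_base
      for (f in intersect(names(par), c("mu_ssr", "p_gsm", "mu_site")))
        mut[[f]] <- par[[f]]
      stat <- NULL
      for (try in 1:2) {
        stat <- tryCatch({
          scn <- scenarios[[s]](par)
          ds <- if (type == "ssr")
            simulate_ssr(scn, mut, sample_sizes, n_loci = n_loci)
          else simulate_mtdna(scn, mut, sample_sizes)
          summarize(ds)
        }, error = function(e) NULL)
        if (!is.null(stat)) break
      }
      if (is.null(stat)) {
        hz_log("WARN", "simulation failed twice (scenario ", s, ", draw ", i,
               "); skipped")
        next
      }
      rows[[idx]] <- c(list(scenario = names(scenarios)[s]), par,
                       as.list(setNames(stat, paste0("ss_", names(stat)))))
    }
    hz_log("INFO", "build_reference: scenario ", names(scenarios)[s], " done")
  }
  out <- bind_rows(lapply(rows[!vapply(rows, is.null, logical(1))], as_tibble))
  attr(out, "type") <- type
  attr(out, "priors") <- priors
  attr(out, "seed") <- seed
  class(out) <- c("abc_reftable", class(out))
  out
}

#' Write / read a reference table as CSV with a JSON metadata sidecar
#' @param rt an `abc_reftable`
#' @param path CSV path (`path`.json holds the metadata)
#' @return `path`, invisibly
#' @export
write_reference <- function(rt, path) {
  utils::write.csv(as.data.frame(rt), path, row.names = FALSE)
  meta <- list(type = attr(rt, "type"), seed = attr(rt, "seed"),
               priors = attr(rt, "priors"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  mpath <- paste0(path, ".json")
  if (file.exists(mpath)) {
    meta <- jsonlite::read_json(mpath, simplifyVector = FALSE)
    attr(out, "type") <- meta$type
    attr(out, "seed") <- meta$seed
    if (!is.null(meta$priors)) {
      pr <- meta$priors
      pr$conditions <- lapply(pr$conditions, unlist)
      attr(out, "priors") <- pr
    }
  }
  class(out) <- c("abc_reftable", class(out))
  out
}

ref_stat_matrix <- function(rt) {
  cols <- grep("^ss_", names(rt), value = TRUE)
  as.matrix(rt[, cols])
}

# ---- model choice -------------------------------------------------------

#' ABC scenario choice by local logistic regression
#'
#' Summary statistics are standardised by their reference-table spread, the
#' `n_keep` simulations nearest the observed vector (Euclidean) are
#' retained, and a multinomial logistic regression of the scenario indicator
#' on the statistics is evaluated at the observed point.  95% CIs come from
#' the asymptotic covariance of the fitted coefficients via the delta
#' method.
#'
#' @param rt an `abc_reftable`
#' @param observed a named summary-statistic vector (as from [summarize()])
#' @param n_keep retained simulations (default 1% of the table)
#' @return an `abc_model_choice` with per-scenario posterior probabilities
#' @export
model_choice <- function(rt, observed, n_keep = NULL) {
  X <- ref_stat_matrix(rt)
  obs <- observed[sub("^ss_", "", colnames(X))]
  if (any(is.na(obs))) stop("observed vector is missing statistics present in the table")
  n_keep <- n_keep %||% max(50L, ceiling(0.01 * nrow(X)))
  if (n_keep > nrow(X)) stop("n_keep exceeds the reference table size")
  scen <- factor(rt$scenario)
  if (nlevels(scen) == 1) {
    return(structure(list(
      table = tibble(scenario = levels(scen), pp = 1, lo = 1, hi = 1),
      n_keep = n_keep), class = "abc_model_choice"))
  }
  sds <- apply(X, 2, sd); sds[sds == 0] <- 1
  Z <- sweep(X, 2, colMeans(X)) |> sweep(2, sds, "/")
  z_obs <- (obs - colMeans(X)) / sds
  d <- sqrt(rowSums(sweep(Z, 2, z_obs)^2))
  keep <- order(d)[seq_len(n_keep)]
  df <- data.frame(scen = droplevels(scen[keep]), Z[keep, , drop = FALSE])
  missing_scen <- setdiff(levels(scen), levels(df$scen))
  if (length(missing_scen))
    warning("scenario(s) absent from retained set: ",
            paste(missing_scen, collapse = ", "), " (PP floored at 0)")
  fit <- suppressWarnings(nnet::multinom(scen ~ ., data = df, trace = FALSE,
                                         decay = 1e-6, maxit = 500))
  big <- max(abs(coef(fit)))
  if (!is.finite(big) || big > 50) {
    hz_log("INFO", "model_choice: near-separation, refitting with ridge penalty")
    fit <- suppressWarnings(nnet::multinom(scen ~ ., data = df, trace = FALSE,
                                           decay = 0.01, maxit = 500))
  }
  nd <- as.data.frame(as.list(setNames(z_obs, colnames(Z))))
  pp_kept <- as.numeric(predict(fit, newdata = nd, type = "probs"))
  lev <- levels(df$scen)
  if (length(lev) == 2) pp_kept <- c(1 - pp_kept, pp_kept)
  names(pp_kept) <- lev
  # delta-method CI on each probability
  th <- as.vector(t(coef(fit)))
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- rep(NA_real_, length(lev))
  if (!is.null(V) && all(is.finite(V))) {
    pfun <- function(thv) {
      B <- matrix(thv, nrow = length(lev) - 1, byrow = TRUE)
      eta <- c(0, B %*% c(1, as.numeric(z_obs)))
      ex <- exp(eta - max(eta)); ex / sum(ex)
    }
    eps <- 1e-5
    Jg <- vapply(seq_along(th), function(j) {
      tp <- th; tp[j] <- tp[j] + eps
      (pfun(tp) - pfun(th)) / eps
    }, numeric(length(lev)))
    se <- sqrt(pmax(diag(Jg %*% V %*% t(Jg)), 0))
  }
  pp <- setNames(rep(0, nlevels(scen)), levels(scen))
  pp[lev] <- pp_kept
  lo <- hi <- setNames(rep(NA_real_, nlevels(scen)), levels(scen))
  lo[lev] <- pmax(pp_kept - 1.96 * se, 0)
  hi[lev] <- pmin(pp_kept + 1.96 * se, 1)
  # direct-rejection PPs for reference
  rej <- table(factor(scen[keep], levels = levels(scen))) / n_keep
  structure(list(
    table = tibble(scenario = levels(scen), pp = as.numeric(pp),
                   lo = as.numeric(lo), hi = as.numeric(hi),
                   pp_rejection = as.numeric(rej)),
    n_keep = n_keep), class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (", x$n_keep, "retained simulations):\n")
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}

# ---- parameter posterior ------------------------------------------------

#' ABC parameter posterior by local-linear regression adjustment
#'
#' Beaumont regression: retained draws are weighted by an Epanechnikov
#' kernel in standardised statistic space, each (logit-transformed, using
#' its prior bounds) parameter is regressed linearly on the statistics, and
#' the residuals are translated to the observed point before
#' back-transformation.  Summaries: weighted mean, median, mode (kernel
#' density) and 2.5/97.5% quantiles.
#'
#' @param rt an `abc_reftable` restricted (or restrictable via `scenario`)
#'   to one scenario
#' @param observed named summary-statistic vector
#' @param n_keep retained simulations (>= 50)
#' @param scenario optional scenario name to subset
#' @param params parameters to summarise (default: all prior parameters)
#' @param adjust apply the local-linear regression adjustment (disable to
#'   inspect the raw rejection posterior)
#' @param weighted use Epanechnikov weights (uniform weights otherwise)
#' @return an `abc_posterior` tibble: parameter, mean, median, mode, q025,
#'   q975; the per-parameter adjusted draws and weights are attached as
#'   attribute `"draws"` for diagnostics
#' @export
parameter_posterior <- function(rt, observed, n_keep = NULL, scenario = NULL,
                                params = NULL, adjust = TRUE,
                                weighted = TRUE) {
  priors <- attr(rt, "priors")
  if (!is.null(scenario)) rt <- rt[rt$scenario == scenario, ]
  X <- ref_stat_matrix(rt)
  n_keep <- n_keep %||% max(50L, ceiling(0.01 * nrow(X)))
  if (n_keep < 50) stop("n_keep < 50 gives an unstable posterior density")
  if (n_keep > nrow(X)) n_keep <- nrow(X)
  obs <- observed[sub("^ss_", "", colnames(X))]
  sds <- apply(X, 2, sd); sds[sds == 0] <- 1
  Z <- sweep(X, 2, colMeans(X)) |> sweep(2, sds, "/")
  z_obs <- (obs - colMeans(X)) / sds
  d <- sqrt(rowSums(sweep(Z, 2, z_obs)^2))
  delta <- sort(d)[n_keep]
  keep <- which(d <= delta)
  if (weighted) {
    w <- 1 - (d[keep] / max(delta, 1e-12))^2
    w[w <= 0] <- min(w[w > 0], 1e-6)
  } else {
    w <- rep(1, length(keep))
  }
  params <- params %||% setdiff(names(rt)[!grepl("^ss_", names(rt))], "scenario")
  A <- cbind(1, Z[keep, , drop = FALSE])
  a_obs <- c(1, as.numeric(z_obs))
  out <- list(); draws <- list()
  for (pm in params) {
    x <- rt[[pm]][keep]
    bounds <- priors$params[[pm]]
    tr <- function(v) v; inv <- function(v) v
    if (!is.null(bounds) && is.finite(bounds$min) && is.finite(bounds$max) &&
        bounds$max > bounds$min) {
      lo <- bounds$min; hi <- bounds$max
      tr <- function(v) {
        u <- (v - lo) / (hi - lo)
        u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
        log(u / (1 - u))
      }
      inv <- function(v) lo + (hi - lo) / (1 + exp(-v))
    }
    y <- tr(x)
    if (adjust) {
      fit <- stats::lm.wfit(A, y, w)
      adj <- sum(coef(fit) * a_obs, na.rm = TRUE) + fit$residuals
    } else {
      adj <- y
    }
    vals <- inv(adj)
    dens <- density(vals, weights = w / sum(w), bw = stats::bw.nrd0(vals))
    draws[[pm]] <- vals
    out[[pm]] <- tibble(
      parameter = pm,
      mean = weighted.mean(vals, w),
      median = weighted_quantile(vals, w, 0.5),
      mode = dens$x[which.max(dens$y)],
      q025 = weighted_quantile(vals, w, 0.025),
      q975 = weighted_quantile(vals, w, 0.975))
  }
  out <- bind_rows(out)
  class(out) <- c("abc_posterior", class(out))
  attr(out, "draws") <- list(values = draws, weights = w)
  out
}
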