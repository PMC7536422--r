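# Cross-modality agreement: fractional-response (quasibinomial-logit)
# regression of genetic ancestry probability on morphometric assignment
# probability, plus the end-to-end pipeline orchestrator.

#' Fractional-response logit regression
#'
#' GLM for proportions in `[0, 1]`: binomial-logit mean model fitted by
#' IRLS, quasibinomial dispersion (Pearson chi^2 / df), deviance chi^2 for
#' the slope, and McFadden pseudo-R^2 computed from the binomial
#' log-likelihood kernel (the quasi-likelihood has no true likelihood; the
#' dispersion factor is ignored, which matches common reporting practice).
#'
#' @param data optional data frame holding `y` and `x`
#' @param y,x probabilities in `[0, 1]` (columns of `data`, or vectors)
#' @return a `fractional_fit`; `glance()` gives the one-row summary
#' @export
fractional_logit <- function(data = NULL, y, x) {
  if (!is.null(data)) {
    y <- rlang::eval_tidy(rlang::enquo(y), data)
    x <- rlang::eval_tidy(rlang::enquo(x), data)
  }
  stopifnot(length(y) == length(x), all(y >= 0 & y <= 1), all(x >= 0 & x <= 1))
  constant_y <- var(y) == 0
  fit <- suppressWarnings(glm(y ~ x, family = quasibinomial("logit")))
  cf <- coef(fit)
  if (any(abs(cf) > 30)) {
    warning("perfect separation: coefficients capped")
    cf <- pmin(pmax(cf, -30), 30)
  }
  mu <- fitted(fit)
  disp <- sum((y - mu)^2 / (mu * (1 - mu))) / fit$df.residual
  loglik_kernel <- function(m) sum(ifelse(y %in% c(0, 1) & (m == y), 0,
                                          y * log(m) + (1 - y) * log(1 - m)))
  mu0 <- rep(mean(y), length(y))
  ll1 <- loglik_kernel(pmin(pmax(mu, 1e-12), 1 - 1e-12))
  ll0 <- loglik_kernel(pmin(pmax(mu0, 1e-12), 1 - 1e-12))
  chi2 <- max(fit$null.deviance - fit$deviance, 0)
  pseudo_r2 <- if (constant_y || ll0 == 0) 0 else max(1 - ll1 / ll0, 0)
  structure(list(
    coefficients = cf, dispersion = disp,
    chi2 = if (constant_y) NA_real_ else chi2, df = 1L,
    p_value = if (constant_y) NA_real_ else pchisq(chi2, 1, lower.tail = FALSE),
    pseudo_r2 = pseudo_r2, constant_response = constant_y,
    n = length(y), glm = fit), class = "fractional_fit")
}

#' @export
print.fractional_fit <- function(x, ...) {
  cat("Fractional logit: logit(E y) =", round(x$coefficients[1], 3), "+",
      round(x$coefficients[2], 3), "x\n")
  cat("  chi2(", x$df, ") =", round(x$chi2, 2), " p =", signif(x$p_value, 3),
      " McFadden pseudo-R2 =", round(x$pseudo_r2, 3),
      " dispersion =", round(x$dispersion, 3), "\n")
  if (x$constant_response) cat("  [flag] constant response: slope test undefined\n")
  invisible(x)
}

#' Run the full synthetic hybrid-zone pipeline
#'
#' Generates genotypes and wings from a shared latent ancestry, runs the
#' population-genetic, ancestry, (optional) ABC and morphometric stages, and
#' fits the genetic-vs-morphological agreement model.  Every stage's seed is
#' derived from `seed` and logged; the same config + seed reproduce the
#' report bit-for-bit (modulo timestamps).
#'
#' @param config nested list (see [pipeline_config()])
#' @param seed master seed
#' @return an `hz_report` list; see [write_report()]
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1) {
  t0 <- Sys.time()
  report <- list(config = config, seed = seed, timestamp = format(t0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      hz_log("WARN", "stage ", name, " failed: ", conditionMessage(e))
      report$partial <<- TRUE
      report$stage_errors <<- c(report$stage_errors, setNames(conditionMessage(e), name))
      NULL
    })
  }

  # --- latent ancestry and genotypes
  gcfg <- config$genetics
  set.seed(derive_seed(seed, 1))
  q_ne <- rbeta(gcfg$n_ne, gcfg$ne_beta[1], gcfg$ne_beta[2])
  q_east <- c(rep(0, gcfg$n_south), q_ne, rep(1, gcfg$n_asian))
  pop <- c(rep("AlpineCarpathian", gcfg$n_south),
           rep("NEEuropean", gcfg$n_ne), rep("Asian", gcfg$n_asian))
  gm <- simulate_admixed_genotypes(
    q = q_east, fst = gcfg$fst, n_loci = gcfg$n_loci,
    n_alleles = gcfg$n_alleles, pop = pop, seed = derive_seed(seed, 2))
  report$true_q_east <- q_east

  # --- population genetics
  report$diversity <- stage("diversity", diversity(gm))
  report$fst <- stage("fst", pairwise_fst(gm, n_perm = config$popgen$n_perm,
                                          n_boot = config$popgen$n_boot,
                                          seed = derive_seed(seed, 3)))
  if (isTRUE(config$popgen$locus_tests))
    report$locus_tests <- stage("locus_tests",
                                locus_tests(gm, n_mc = config$popgen$n_mc,
                                            seed = derive_seed(seed, 4)))

  # --- ancestry
  acfg <- config$ancestry
  scan <- stage("ancestry_scan",
                admixture_scan(gm, k_range = acfg$k_range, n_rep = acfg$n_rep,
                               burn_in = acfg$burn_in, length = acfg$length,
                               seed = derive_seed(seed, 5)))
  fit2 <- NULL
  if (!is.null(scan)) {
    report$delta_k <- stage("delta_k", delta_k(scan))
    report$chosen_k <- report$delta_k$chosen_k
    fit2 <- stage("admixture_k2",
                  admixture_mcmc(gm, 2, burn_in = acfg$burn_in,
                                 length = acfg$length,
                                 seed = derive_seed(seed, 6)))
  }
  q_structure <- NULL
  if (!is.null(fit2)) {
    # identify the eastern cluster as the one the Asian samples load on
    asian <- fit2$pop == "Asian"
    east_cl <- which.max(colMeans(fit2$q_mean[asian, , drop = FALSE]))
    q_structure <- fit2$q_mean[, east_cl]
    report$admixture <- fit2
    report$q_structure_east <- q_structure
  }
  dp <- stage("dapc", dapc(gm, seed = derive_seed(seed, 7)))
  q_dapc <- NULL
  if (!is.null(dp)) {
    report$dapc_overlaps <- stage("overlap", dapc_overlaps(dp))
    east_pops <- c("NEEuropean", "Asian")
    q_dapc <- rowSums(dp$posterior[, intersect(east_pops, colnames(dp$posterior)),
                                   drop = FALSE])
    report$q_dapc_east <- q_dapc
  }

  # --- demographic ABC (optional)
  if (isTRUE(config$abc$enabled)) {
    bcfg <- config$abc
    cat_ssr <- scenario_catalogue("ssr")
    priors <- default_config()$priors_ssr
    rt <- stage("abc_reference",
                build_reference(cat_ssr, priors, bcfg$n_sim_per_scenario,
                                sample_sizes = bcfg$sample_sizes,
                                n_loci = gcfg$n_loci,
                                seed = derive_seed(seed, 8)))
    if (!is.null(rt)) {
      obs_stats <- summarize(gm)
      mc <- stage("abc_model_choice",
                  model_choice(rt, obs_stats, n_keep = bcfg$n_keep))
      report$abc_model_choice <- mc
      if (!is.null(mc)) {
        best <- mc$table$scenario[which.max(mc$table$pp)]
        report$abc_posterior <- stage("abc_posterior",
          parameter_posterior(rt, obs_stats, n_keep = bcfg$n_keep,
                              scenario = best,
                              params = c("N1", "N2", "N3", "NA_", "t1", "t2", "r")))
        report$abc_best_scenario <- best
      }
    }
  }

  # --- morphometrics on wings tied to the same latent ancestry
  wcfg <- config$wings
  # wing ancestry weight is toward the first pop_effect entry (the southern
  # cluster), i.e. 1 - eastern ancestry
  anc <- tibble(id = unique(gm$id), pop = pop,
                sex = rep_len(c("M", "F"), length(pop)), q = 1 - q_east)
  wings <- stage("wingsim", simulate_wings(
    wing_sim_config(pop_effect = wcfg$pop_effect, sex_effect = wcfg$sex_effect,
                    allometry_slope = wcfg$allometry_slope,
                    noise_sd = wcfg$noise_sd, seed = derive_seed(seed, 9)),
    ancestry = anc))
  p_morpho <- NULL
  if (!is.null(wings)) {
    g <- stage("gpa", gpa(wings))
    if (!is.null(g)) {
      ssp <- stage("shape_pca", shape_pca(g, retain = min(
        config$morpho$n_pcs, dim(g$aligned)[3] - nlevels(factor(pop)) - 3)))
      report$size_anova <- stage("size_anova",
                                 size_anova(g$csize, g$meta$pop, g$meta$sex))
      if (!is.null(ssp)) {
        report$mancova <- stage("mancova", shape_mancova(ssp))
        report$mahalanobis <- stage("mahalanobis", mahalanobis_upgma(ssp))
        region <- ifelse(ssp$meta$pop == "AlpineCarpathian", "southern", "eastern")
        la <- stage("lda_assign",
                    lda_assign(ssp, region, positive = "eastern", loo = TRUE))
        if (!is.null(la)) {
          p_morpho <- la$posterior[match(anc$id, la$id)]
          report$p_morpho_east <- p_morpho
        }
      }
    }
  }

  # --- integration
  if (!is.null(q_structure) && !is.null(p_morpho)) {
    report$integration_structure <- stage("integration",
      fractional_logit(y = q_structure, x = p_morpho))
  }
  if (!is.null(q_dapc) && !is.null(p_morpho)) {
    report$integration_dapc <- stage("integration_dapc",
      fractional_logit(y = q_dapc, x = p_morpho))
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$partial <- isTRUE(report$partial)
  class(report) <- "hz_report"
  report
}

#' Default pipeline configuration
#'
#' The genetics block mirrors the study conditions the package emulates:
#' three regional samples of 91 / 48 / 22 individuals, six microsatellite
#' loci, cluster differentiation around 0.18, and a northeastern sample of
#' admixed ancestry with a prevailing (~70%) eastern contribution.
#'
#' @param abc_enabled include the (slower) demographic ABC stage
#' @return nested config list
#' @export
pipeline_config <- function(abc_enabled = FALSE) {
  list(
    genetics = list(n_south = 91, n_ne = 48, n_asian = 22,
                    fst = 0.18, n_loci = 6, n_alleles = 8,
                    ne_beta = c(7, 3)),
    popgen = list(n_perm = 999, n_boot = 999, n_mc = 10000, locus_tests = FALSE),
    ancestry = list(k_range = 1:4, n_rep = 3, burn_in = 1000, length = 4000),
    abc = list(enabled = abc_enabled, n_sim_per_scenario = 500,
               sample_sizes = c(30, 20, 10), n_keep = 100),
    wings = list(pop_effect = c(AlpineCarpathian = 0.012, NEEuropean = 0.004,
                                Asian = 0),
                 sex_effect = 0.006, allometry_slope = 0.01, noise_sd = 0.004),
    morpho = list(n_pcs = 20)
  )
}

#' Write a pipeline report as JSON + CSV tables
#' @param report an `hz_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- report_json(report)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$diversity))
    utils::write.csv(as.data.frame(report$diversity$by_pop),
                     file.path(dir, "diversity.csv"), row.names = FALSE)
  if (!is.null(report$fst))
    utils::write.csv(as.data.frame(report$fst$theta),
                     file.path(dir, "fst.csv"))
  if (!is.null(report$abc_posterior))
    utils::write.csv(as.data.frame(report$abc_posterior),
                     file.path(dir, "abc_posterior.csv"), row.names = FALSE)
  invisible(dir)
}

# JSON-able digest of a report (timestamps excluded so that equal seeds give
# byte-identical digests)
report_json <- function(report) {
  out <- list(seed = report$seed, partial = report$partial)
  if (!is.null(report$fst)) {
    th <- report$fst$theta
    pairs <- which(upper.tri(th), arr.ind = TRUE)
    out$fst <- lapply(seq_len(nrow(pairs)), function(r) list(
      pair = paste(rownames(th)[pairs[r, 1]], colnames(th)[pairs[r, 2]], sep = "-"),
      theta = th[pairs[r, 1], pairs[r, 2]],
      p = report$fst$p[pairs[r, 1], pairs[r, 2]]))
  }
  if (!is.null(report$diversity))
    out$diversity <- as.list(as.data.frame(report$diversity$by_pop))
  if (!is.null(report$chosen_k)) out$chosen_k <- report$chosen_k
  if (!is.null(report$delta_k))
    out$delta_k <- as.list(as.data.frame(report$delta_k$table))
  if (!is.null(report$q_structure_east))
    out$q_structure_east <- report$q_structure_east
  if (!is.null(report$dapc_overlaps))
    out$dapc_overlaps <- as.list(as.data.frame(report$dapc_overlaps))
  if (!is.null(report$abc_model_choice))
    out$abc_model_choice <- as.list(as.data.frame(report$abc_model_choice$table))
  if (!is.null(report$abc_posterior))
    out$abc_posterior <- as.list(as.data.frame(report$abc_posterior))
  if (!is.null(report$size_anova))
    out$size_anova <- as.list(as.data.frame(report$size_anova))
  if (!is.null(report$mancova))
    out$mancova <- as.list(as.data.frame(report$mancova$table))
  if (!is.null(report$mahalanobis)) {
    out$mahalanobis_d2 <- as.list(as.data.frame(report$mahalanobis$d2))
    out$upgma_newick <- report$mahalanobis$newick
  }
  if (!is.null(report$integration_structure))
    out$integration_structure <- glance_fractional(report$integration_structure)
  if (!is.null(report$integration_dapc))
    out$integration_dapc <- glance_fractional(report$integration_dapc)
  out
}

glance_fractional <- function(f) {
  list(intercept = unname(f$coefficients[1]), slope = unname(f$coefficients[2]),
       chi2 = f$chi2, df = f$df, p_value = f$p_value,
       pseudo_r2 = f$pseudo_r2, dispersion = f$dispersion, n = f$n)
}

#' @export
print.hz_report <- function(x, ...) {
  cat("hybridzone pipeline report (seed", x$seed, ")\n")
  if (x$partial) cat("  PARTIAL: stages failed:",
                     paste(names(x$stage_errors), collapse = ", "), "\n")
  if (!is.null(x$chosen_k)) cat("  chosen K:", x$chosen_k, "\n")
  if (!is.null(x$fst)) {
    th <- x$fst$theta
    cat("  pairwise FST:", paste(signif(th[upper.tri(th)], 3), collapse = ", "), "\n")
  }
  if (!is.null(x$integration_structure))
    cat("  genetic~morphological agreement: slope",
        round(x$integration_structure$coefficients[2], 2),
        " pseudo-R2", round(x$integration_structure$pseudo_r2, 3), "\n")
  cat("  elapsed:", round(x$elapsed_s, 1), "s\n")
  invisible(x)
}
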