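# Geometric-morphometrics pipeline: generalised Procrustes analysis,
# centroid sizes, tangent-space shape PCA, size ANOVA, shape MANCOVA with
# Wilks' lambda, Mahalanobis distances with UPGMA clustering, and
# discriminant assignment.

lm_array <- function(lm) {
  ids <- unique(lm$id)
  k <- attr(lm, "n_landmarks") %||% max(lm$lm)
  arr <- array(NA_real_, c(k, 2, length(ids)), dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    d <- lm[lm$id == ids[i], ]
    d <- d[order(d$lm), ]
    arr[, , i] <- cbind(d$x, d$y)
  }
  meta <- distinct(lm[, c("id", "sex", "pop")])
  list(arr = arr, meta = meta[match(ids, meta$id), ])
}

centroid_size_of <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  sqrt(sum(c0^2))
}

# optimal rotation of m onto target (both centred), reflections forbidden
opa_rotate <- function(m, target) {
  s <- svd(crossprod(target, m))
  R <- s$v %*% t(s$u)
  if (det(R) < 0) {
    s$v[, ncol(s$v)] <- -s$v[, ncol(s$v)]
    R <- s$v %*% t(s$u)
  }
  m %*% R
}

#' Generalised Procrustes analysis
#'
#' Each configuration is centred and scaled to unit centroid size, then
#' iteratively rotated to the current consensus by the orthogonal
#' (rotation-only) least-squares solution from the SVD of the cross-product;
#' the consensus is re-estimated until its change drops below `tol`.
#' Reflections are never permitted.
#'
#' @param lm a `wing_tbl`
#' @param tol convergence tolerance on the consensus update
#' @param max_iter iteration cap
#' @return a `gpa_fit`: consensus (unit centroid size), aligned array,
#'   centroid sizes, iteration metadata
#' @export
gpa <- function(lm, tol = 1e-10, max_iter = 100) {
  la <- lm_array(lm)
  arr <- la$arr
  n <- dim(arr)[3]
  if (n < 2) stop("need at least 2 specimens")
  csize <- apply(arr, 3, centroid_size_of)
  for (i in seq_len(n)) {
    m <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
    arr[, , i] <- m / csize[i]
  }
  consensus <- arr[, , 1]
  delta <- Inf; iter <- 0L
  while (delta > tol) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("GPA did not converge in ", max_iter,
           " iterations (last delta ", signif(delta, 3), ")")
    for (i in seq_len(n)) arr[, , i] <- opa_rotate(arr[, , i], consensus)
    newc <- apply(arr, c(1, 2), mean)
    newc <- newc / centroid_size_of(newc)
    delta <- sqrt(sum((newc - consensus)^2))
    consensus <- newc
  }
  # orientation standardisation: rotate everything so the consensus lies on
  # its principal axes (rotation only, 180-degree ambiguity fixed by sign);
  # makes aligned coordinates invariant to the input orientation
  M <- crossprod(consensus)
  E <- eigen(M, symmetric = TRUE)$vectors
  if (det(E) < 0) E[, 2] <- -E[, 2]
  rot <- consensus %*% E
  if (rot[which.max(abs(rot[, 1])), 1] < 0) E <- -E
  consensus <- consensus %*% E
  for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% E
  structure(list(consensus = consensus, aligned = arr, csize = csize,
                 meta = la$meta, iterations = iter, delta = delta),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("GPA:", dim(x$aligned)[3], "specimens,", dim(x$aligned)[1],
      "landmarks; converged in", x$iterations, "iterations\n")
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#' @param a,b k x 2 matrices
#' @return the root summed squared difference
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Shape PCA in the tangent space of the consensus
#'
#' Aligned coordinates are orthogonally projected to the tangent space at
#' the consensus and decomposed by PCA.  `retain` is an explicit count
#' (default 20) or "scree" for the largest eigenvalue-ratio drop.
#'
#' @param fit a `gpa_fit`
#' @param retain number of components or "scree"
#' @return a `shape_space`: scores, eigenvalues, labels
#' @export
shape_pca <- function(fit, retain = 20) {
  arr <- fit$aligned
  X <- t(apply(arr, 3, as.numeric))           # n x 2k
  cvec <- as.numeric(fit$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  Xc <- sweep(X, 2, colMeans(X))
  Xt <- Xc - (Xc %*% cvec) %*% t(cvec)        # tangent projection
  pc <- prcomp(Xt, center = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-10)
  if (identical(retain, "scree")) {
    ratios <- ev[seq_len(rank - 1)] / ev[2:rank]
    retain <- which.max(ratios)
  }
  if (retain > rank) {
    warning("retain > rank; clipped to ", rank)
    retain <- rank
  }
  structure(list(scores = pc$x[, seq_len(retain), drop = FALSE],
                 eigenvalues = ev, retained = retain,
                 total_variance = sum(ev),
                 meta = fit$meta, csize = fit$csize),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space:", x$retained, "retained PCs;",
      round(100 * sum(x$eigenvalues[seq_len(x$retained)]) / sum(x$eigenvalues), 1),
      "% of shape variance\n")
  invisible(x)
}

#' Two-way ANOVA of centroid size
#'
#' Fixed-effects population x sex ANOVA with interaction, type-II sums of
#' squares (unbalanced designs); an empty design cell drops the interaction
#' with a log note.
#'
#' @param sizes centroid sizes
#' @param population,sex factors
#' @return tibble ANOVA table (term, df, sumsq, F, p)
#' @export
size_anova <- function(sizes, population, sex) {
  df <- data.frame(size = sizes, population = factor(population),
                   sex = factor(sex))
  two_factor <- nlevels(df$population) > 1 && nlevels(df$sex) > 1
  if (!two_factor) {
    # single-factor collapse: ordinary one-way ANOVA
    fac <- if (nlevels(df$population) > 1) "population" else "sex"
    fit <- lm(stats::reformulate(fac, "size"), data = df)
    a <- car::Anova(fit, type = 2)
    return(tibble(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
                  statistic = a$`F value`, p_value = a$`Pr(>F)`))
  }
  has_interaction <- all(table(df$population, df$sex) > 0)
  if (!has_interaction)
    hz_log("INFO", "size_anova: empty design cell, interaction dropped")
  form <- if (has_interaction) size ~ population * sex else size ~ population + sex
  fit <- lm(form, data = df)
  a <- car::Anova(fit, type = 2)
  tibble(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
         statistic = a$`F value`, p_value = a$`Pr(>F)`)
}

#' Shape MANCOVA with Wilks' lambda
#'
#' Multivariate linear model of the retained shape scores on population,
#' sex and centroid size.  Interactions are screened first; if none is
#' significant at `alpha` the main-effects model is reported.  Wilks'
#' lambda with Rao's F approximation per effect (type-II).
#'
#' @param ss a `shape_space`
#' @param population,sex factors (default from the shape space labels)
#' @param size_covariate numeric covariate (default centroid size)
#' @param alpha screening level for the interaction terms
#' @return a `mancova_fit`: per-effect Wilks table and the model formula used
#' @export
shape_mancova <- function(ss, population = NULL, sex = NULL,
                          size_covariate = NULL, alpha = 0.05) {
  Y <- ss$scores
  population <- factor(population %||% ss$meta$pop)
  sex <- factor(sex %||% ss$meta$sex)
  size <- size_covariate %||% ss$csize
  if (ncol(Y) >= nrow(Y) - nlevels(population) - nlevels(sex) - 1)
    stop("retained dimension too large for the residual df")
  dat <- data.frame(population = population, sex = sex, size = size)
  screen <- lm(Y ~ population * sex + size, data = dat)
  wilks_table <- function(fit) {
    if (!inherits(fit, "mlm")) {
      # one retained dimension: Wilks reduces to the univariate ANCOVA
      a <- car::Anova(fit, type = 2)
      terms <- setdiff(rownames(a), "Residuals")
      sse <- a["Residuals", "Sum Sq"]
      return(bind_rows(lapply(terms, function(trm) tibble(
        term = trm, wilks = sse / (sse + a[trm, "Sum Sq"]),
        statistic = a[trm, "F value"], df1 = a[trm, "Df"],
        df2 = a["Residuals", "Df"], p_value = a[trm, "Pr(>F)"]))))
    }
    mv <- summary(car::Manova(fit, type = 2, test.statistic = "Wilks"))
    tests <- mv$multivariate.tests
    bind_rows(lapply(names(tests), function(trm) {
      h <- tests[[trm]]$SSPH; e <- tests[[trm]]$SSPE
      dfh <- tests[[trm]]$df
      dfe <- tests[[trm]]$df.residual
      wk <- wilks_stat(h, e, dfh, dfe)
      tibble(term = trm, wilks = wk$lambda, statistic = wk$F,
             df1 = wk$df1, df2 = wk$df2, p_value = wk$p)
    }))
  }
  tab_int <- wilks_table(screen)
  int_row <- tab_int[tab_int$term == "population:sex", ]
  if (nrow(int_row) == 1 && !is.na(int_row$p_value) && int_row$p_value < alpha) {
    structure(list(table = tab_int, model = "population * sex + size",
                   interaction_significant = TRUE), class = "mancova_fit")
  } else {
    main <- lm(Y ~ population + sex + size, data = dat)
    structure(list(table = wilks_table(main), model = "population + sex + size",
                   interaction_significant = FALSE,
                   screen_table = tab_int), class = "mancova_fit")
  }
}

# Wilks' lambda and Rao's F approximation from hypothesis / error SSP
wilks_stat <- function(H, E, df_h, df_e) {
  p <- nrow(E)
  lambda <- det(E) / det(E + H)
  r <- df_e - (p - df_h + 1) / 2
  t <- if (p^2 + df_h^2 - 5 > 0) sqrt((p^2 * df_h^2 - 4) / (p^2 + df_h^2 - 5)) else 1
  df1 <- p * df_h
  df2 <- r * t - (p * df_h - 2) / 2
  L <- lambda^(1 / t)
  Fstat <- (1 - L) / L * df2 / df1
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' @export
print.mancova_fit <- function(x, ...) {
  cat("Shape MANCOVA (", x$model, "):\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Pairwise Mahalanobis distances and UPGMA phenogram
#'
#' Squared Mahalanobis distances between group means under the pooled
#' within-group covariance of the retained shape scores; the distance
#' matrix is clustered by UPGMA into an ultrametric tree.
#'
#' @param ss a `shape_space`
#' @param groups grouping factor (default population labels)
#' @return list: `d2` matrix, `tree` (phylo), `newick`
#' @export
mahalanobis_upgma <- function(ss, groups = NULL) {
  groups <- factor(groups %||% ss$meta$pop)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  X <- ss$scores
  S <- pooled_cov(X, groups)
  Si <- tryCatch(solve(S), error = function(e) {
    warning("singular pooled covariance: using pseudo-inverse")
    MASS::ginv(S)
  })
  mus <- do.call(rbind, lapply(levels(groups), function(g)
    colMeans(X[groups == g, , drop = FALSE])))
  rownames(mus) <- levels(groups)
  G <- nlevels(groups)
  d2 <- matrix(0, G, G, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    d <- mus[i, ] - mus[j, ]
    d2[i, j] <- d2[j, i] <- as.numeric(t(d) %*% Si %*% d)
  }
  tree <- phangorn::upgma(as.dist(d2))
  list(d2 = d2, tree = tree, newick = ape::write.tree(tree))
}

pooled_cov <- function(X, groups) {
  G <- levels(groups)
  S <- 0; df <- 0
  for (g in G) {
    Xi <- X[groups == g, , drop = FALSE]
    if (nrow(Xi) > 1) {
      S <- S + cov(Xi) * (nrow(Xi) - 1)
      df <- df + nrow(Xi) - 1
    }
  }
  S / df
}

#' Linear discriminant assignment between two regions
#'
#' Linear discriminant with equal priors on the retained shape scores;
#' posterior probabilities of membership in `positive` (e.g. the eastern
#' range).  `loo = TRUE` uses leave-one-out posteriors for honest
#' assignment.
#'
#' @param ss a `shape_space`
#' @param labels two-level grouping (default: population labels collapsed
#'   via `positive_pops`)
#' @param positive the label whose posterior is reported
#' @param loo leave-one-out cross-validated posteriors
#' @return tibble: id, label, posterior toward `positive`
#' @export
lda_assign <- function(ss, labels, positive = NULL, loo = FALSE) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  positive <- positive %||% levels(labels)[2]
  X <- ss$scores
  if (min(table(labels)) <= ncol(X))
    stop("each group needs more members than retained dimensions")
  fit <- MASS::lda(X, grouping = labels, prior = c(0.5, 0.5), CV = loo)
  post <- if (loo) fit$posterior else predict(fit)$posterior
  tibble(id = ss$meta$id, label = as.character(labels),
         posterior = post[, positive])
}
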