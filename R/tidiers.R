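# broom-style tidy() / glance() methods for the fitted-object classes.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.hz_diversity <- function(x, ...) x$by_pop

#' @export
tidy.hz_fst <- function(x, ...) {
  pops <- rownames(x$theta)
  out <- list()
  for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
    out[[length(out) + 1L]] <- tibble(
      pop_a = pops[i], pop_b = pops[j], theta = x$theta[i, j],
      p_value = x$p[i, j], ci_lo = x$ci_lo[i, j], ci_hi = x$ci_hi[i, j])
  }
  bind_rows(out)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  K <- x$K
  bind_rows(lapply(seq_len(K), function(k) tibble(
    id = x$ids, pop = x$pop, cluster = k,
    q = x$q_mean[, k], q_lo = x$q_lo[, k], q_hi = x$q_hi[, k])))
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, ln_pd = x$ln_pd, ln_lik_mean = x$ln_lik_mean,
         ln_lik_var = x$ln_lik_var, alpha = x$alpha)
}

#' @export
tidy.delta_k_table <- function(x, ...) x$table

#' @export
tidy.dapc_fit <- function(x, ...) {
  out <- tibble(id = x$ids, group = as.character(x$groups))
  for (j in seq_len(ncol(x$coord))) out[[paste0("LD", j)]] <- x$coord[, j]
  for (g in colnames(x$posterior)) out[[paste0("p_", g)]] <- x$posterior[, g]
  out
}

#' @export
tidy.gpa_fit <- function(x, ...) {
  fit <- x
  n <- dim(fit$aligned)[3]; k <- dim(fit$aligned)[1]
  bind_rows(lapply(seq_len(n), function(i) tibble(
    id = fit$meta$id[i], pop = fit$meta$pop[i], sex = fit$meta$sex[i],
    lm = seq_len(k), x = fit$aligned[, 1, i], y = fit$aligned[, 2, i],
    csize = fit$csize[i])))
}

#' @export
tidy.shape_space <- function(x, ...) {
  out <- tibble(id = x$meta$id, pop = x$meta$pop, sex = x$meta$sex,
                csize = x$csize)
  for (j in seq_len(x$retained)) out[[paste0("PC", j)]] <- x$scores[, j]
  out
}

#' @export
tidy.mancova_fit <- function(x, ...) x$table

#' @export
tidy.abc_model_choice <- function(x, ...) x$table

#' @export
glance.fractional_fit <- function(x, ...) {
  tibble(intercept = unname(x$coefficients[1]),
         slope = unname(x$coefficients[2]),
         chi2 = x$chi2, df = x$df, p_value = x$p_value,
         pseudo_r2 = x$pseudo_r2, dispersion = x$dispersion, n = x$n)
}

#' @export
tidy.fractional_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}
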