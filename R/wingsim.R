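# Synthetic wing-landmark generator: population shape effects, sex
# dimorphism, allometry and digitising noise in the tangent space of a base
# shape, with nuisance rotation / translation / scale applied afterwards so
# Procrustes alignment has real work to do.

# stylised 23-landmark wing outline (unit centroid size after scaling);
# synthetic artifact data, not digitised from any specimen
base_wing_shape <- function() {
  xy <- cbind(
    x = c(0.00, 0.12, 0.25, 0.38, 0.52, 0.66, 0.80, 0.92, 1.00,
          0.95, 0.85, 0.72, 0.60, 0.47, 0.34, 0.21, 0.10, 0.05,
          0.30, 0.45, 0.60, 0.72, 0.50),
    y = c(0.18, 0.26, 0.31, 0.34, 0.35, 0.33, 0.28, 0.20, 0.10,
          0.03, -0.02, -0.05, -0.06, -0.06, -0.05, -0.03, 0.02, 0.10,
          0.12, 0.13, 0.12, 0.09, 0.02))
  xy <- scale(xy, scale = FALSE)
  xy / sqrt(sum(xy^2))
}

# unit tangent-space direction at `base`: random vector with translations,
# rotation and scaling of the base projected out, so effect magnitudes are
# Procrustes-distance-interpretable
tangent_direction <- function(base) {
  k <- nrow(base)
  v <- matrix(rnorm(2 * k), k, 2)
  basis <- cbind(c(rep(1, k), rep(0, k)), c(rep(0, k), rep(1, k)),
                 c(-base[, 2], base[, 1]), c(base[, 1], base[, 2]))
  vv <- as.numeric(v)
  for (j in seq_len(ncol(basis))) {
    b <- basis[, j] / sqrt(sum(basis[, j]^2))
    vv <- vv - sum(vv * b) * b
  }
  matrix(vv / sqrt(sum(vv^2)), k, 2)
}

#' Configuration for the wing-landmark generator
#'
#' Effects are tangent-space vectors at the base shape, so their magnitudes
#' are (approximately) Procrustes distances from the base.
#'
#' @param n_per_group named list / vector: specimens per population x sex,
#'   or a tibble with columns pop, sex, n
#' @param pop_effect named magnitudes of the population shape displacement
#' @param sex_effect magnitude of the female-minus-male displacement
#' @param allometry_slope magnitude of the shape change per unit log
#'   centroid size
#' @param log_cs_range range of log centroid size (image units)
#' @param noise_sd isotropic digitising noise sd per landmark coordinate
#'   (shape units)
#' @param sex_size_effect additive female log-CS shift (size dimorphism)
#' @param rot_range nuisance rotation range (radians)
#' @param trans_range nuisance translation half-width (image units)
#' @param seed RNG seed (also fixes the effect directions)
#' @return a `wing_sim_config`
#' @export
wing_sim_config <- function(n_per_group = NULL,
                            pop_effect = c(AlpineCarpathian = 0.012,
                                           NEEuropean = 0.004, Asian = 0),
                            sex_effect = 0.006,
                            allometry_slope = 0.01,
                            log_cs_range = c(5.8, 6.2),
                            noise_sd = 0.004,
                            sex_size_effect = 0.03,
                            rot_range = c(0, 2 * pi),
                            trans_range = 100,
                            seed = NULL) {
  if (is.null(n_per_group)) {
    n_per_group <- tidyr::expand_grid(
      pop = c("AlpineCarpathian", "NEEuropean", "Asian"),
      sex = c("M", "F"))
    # 316 specimens (161 males, 155 females) split over three regions
    n_per_group$n <- c(54, 52, 54, 52, 53, 51)
  }
  stopifnot(noise_sd >= 0, all(is.finite(unlist(pop_effect))))
  structure(list(n_per_group = as_tibble(n_per_group),
                 pop_effect = pop_effect, sex_effect = sex_effect,
                 allometry_slope = allometry_slope,
                 log_cs_range = log_cs_range, noise_sd = noise_sd,
                 sex_size_effect = sex_size_effect,
                 rot_range = rot_range, trans_range = trans_range, seed = seed),
            class = "wing_sim_config")
}

#' Simulate wing landmark configurations
#'
#' shape_i = base + population effect + sex effect +
#' slope * (log CS_i - mean log CS) + isotropic Gaussian noise, then a
#' random rotation / translation / scale is applied and labels attached.
#' Optionally, per-specimen ancestry weights blend the population effects
#' (hybrids get intermediate wings).
#'
#' @param cfg a `wing_sim_config`
#' @param ancestry optional tibble with columns `id`, `sex`, `q` (ancestry
#'   toward the *first* population in `pop_effect`), and `pop`; overrides
#'   `n_per_group` so wings can be tied to simulated genotypes
#' @return a `wing_tbl` with attribute `true_shape_score`
#' @export
simulate_wings <- function(cfg, ancestry = NULL) {
  with_seed_logged(cfg$seed, "simulate_wings")
  base <- base_wing_shape()
  if (sqrt(sum(scale(base, scale = FALSE)^2)) < 1e-9)
    stop("degenerate base shape: zero centroid size")
  k <- nrow(base)
  dir_pop <- tangent_direction(base)
  dir_sex <- tangent_direction(base)
  dir_allo <- tangent_direction(base)

  if (is.null(ancestry)) {
    grid <- cfg$n_per_group
    spec <- tibble(
      pop = rep(grid$pop, grid$n),
      sex = rep(grid$sex, grid$n))
    spec$id <- sprintf("wing_%03d", seq_len(nrow(spec)))
    spec$w <- cfg$pop_effect[spec$pop]   # per-pop magnitude directly
  } else {
    spec <- tibble(id = ancestry$id, pop = ancestry$pop, sex = ancestry$sex)
    eff <- cfg$pop_effect
    # blend the extreme population magnitudes by ancestry q
    spec$w <- ancestry$q * eff[[1]] + (1 - ancestry$q) * eff[[length(eff)]]
  }
  n <- nrow(spec)
  logcs <- runif(n, cfg$log_cs_range[1], cfg$log_cs_range[2]) +
    ifelse(spec$sex == "F", cfg$sex_size_effect, 0)
  csize <- exp(logcs)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    shapes[[i]] <- base + spec$w[i] * dir_pop +
      (spec$sex[i] == "F") * cfg$sex_effect * dir_sex +
      cfg$allometry_slope * (logcs[i] - mean(cfg$log_cs_range)) * dir_allo +
      matrix(rnorm(2 * k, sd = cfg$noise_sd), k, 2)
  }
  # nuisance transforms drawn after all shape randomness, so configs that
  # differ only in nuisance ranges share identical underlying shapes
  out <- vector("list", n)
  for (i in seq_len(n)) {
    th <- runif(1, cfg$rot_range[1], cfg$rot_range[2])
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sh <- shapes[[i]] %*% R * csize[i]
    sh <- sweep(sh, 2, runif(2, -cfg$trans_range, cfg$trans_range), "+")
    out[[i]] <- tibble(id = spec$id[i], sex = spec$sex[i], pop = spec$pop[i],
                       lm = seq_len(k), x = sh[, 1], y = sh[, 2])
  }
  res <- landmark_tbl(bind_rows(out), n_landmarks = k)
  attr(res, "true_shape_score") <- spec$w
  res
}
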