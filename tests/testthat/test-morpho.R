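# build a shape_space object directly (for tests of downstream operations)
fake_shape_space <- function(scores, pop, sex = NULL, csize = NULL) {
  n <- nrow(scores)
  structure(list(
    scores = scores, eigenvalues = rep(1, ncol(scores)),
    retained = ncol(scores), total_variance = sum(apply(scores, 2, var)),
    meta = tibble::tibble(id = sprintf("f%03d", seq_len(n)), pop = pop,
                          sex = sex %||% rep("M", n)),
    csize = csize %||% rep(1, n)), class = "shape_space")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_config <- function(k = 23) matrix(rnorm(2 * k), k, 2)

similarity_transform <- function(m, theta, scale, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(m %*% R * scale, 2, shift, "+")
}

wing_from_configs <- function(configs) {
  landmark_tbl(dplyr::bind_rows(lapply(seq_along(configs), function(i)
    tibble::tibble(id = sprintf("s%02d", i), sex = "M", pop = "P",
                   lm = seq_len(nrow(configs[[i]])),
                   x = configs[[i]][, 1], y = configs[[i]][, 2]))),
    n_landmarks = nrow(configs[[1]]))
}

test_that("centroid size of the unit square is sqrt(2)", {
  sq <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2)
  expect_equal(hybridzone:::centroid_size_of(sq), sqrt(2), tolerance = 1e-12)
})

test_that("GPA removes pure similarity transforms of one configuration", {
  set.seed(61)
  base <- random_config()
  configs <- lapply(1:8, function(i)
    similarity_transform(base, runif(1, 0, 2 * pi), runif(1, 0.5, 3),
                         runif(2, -50, 50)))
  g <- gpa(wing_from_configs(configs))
  for (i in 1:7)
    expect_lt(procrustes_distance(g$aligned[, , i], g$aligned[, , i + 1]), 1e-8)
})

test_that("two-specimen alignment attains the closed-form Procrustes minimum", {
  set.seed(62)
  a <- random_config(3); b <- random_config(3)
  g <- gpa(wing_from_configs(list(a, b)), tol = 1e-14)
  d_gpa <- procrustes_distance(g$aligned[, , 1], g$aligned[, , 2])
  # SVD oracle: full Procrustes distance between unit-size centred shapes
  cen <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  sv <- svd(crossprod(cen(a), cen(b)))   # 2 x 2 in the plane
  sig <- sv$d[1] + sign(det(sv$u %*% t(sv$v))) * sv$d[2]
  expect_equal(d_gpa, sqrt(max(0, 2 - 2 * sig)), tolerance = 1e-7)
})

test_that("shape PCA scores are uncorrelated and conserve variance", {
  set.seed(63)
  w <- simulate_wings(wing_sim_config(seed = 64))
  g <- gpa(w)
  ss <- shape_pca(g, retain = 42)        # full tangent-space rank (2k - 4)
  cv <- cov(ss$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  expect_equal(diag(cv), ss$eigenvalues[1:42], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(diag(cv)) / sum(ss$eigenvalues), 1, tolerance = 1e-6)
})

test_that("rank-one simulated variation loads on a single component", {
  set.seed(65)
  base <- hybridzone:::base_wing_shape()
  dir <- hybridzone:::tangent_direction(base)
  configs <- lapply(rnorm(15, sd = 0.01), function(a) base + a * dir)
  g <- gpa(wing_from_configs(configs))
  ss <- suppressWarnings(shape_pca(g, retain = 5))
  expect_gt(ss$eigenvalues[1] / sum(ss$eigenvalues), 0.99)
})

test_that("retain > rank clips with a warning", {
  set.seed(66)
  configs <- lapply(1:5, function(i) random_config())
  g <- gpa(wing_from_configs(configs))
  expect_warning(ss <- shape_pca(g, retain = 40), "clipped")
  expect_lte(ss$retained, 4)
})

test_that("size ANOVA matches hand-computed sums of squares on a balanced toy", {
  pop <- rep(c("A", "B"), each = 8)
  sex <- rep(c("M", "F"), 8)
  size <- c(10, 12, 11, 13, 10, 12, 11, 13, 14, 16, 15, 17, 14, 16, 15, 17)
  tab <- size_anova(size, pop, sex)
  # balanced two-way design: SS_pop = 16 * (mean_B - mean)^2 * ...
  gm <- mean(size)
  ss_pop <- sum(tapply(size, pop, function(v) 8 * (mean(v) - gm)^2))
  ss_sex <- sum(tapply(size, sex, function(v) 8 * (mean(v) - gm)^2))
  cell <- tapply(size, interaction(pop, sex), mean)
  ss_int <- 4 * sum((cell - rep(tapply(size, pop, mean), 2) -
                       tapply(size, sex, mean)[rep(c("F", "M"), each = 2)] + gm)^2)
  ss_res <- sum((size - ave(size, interaction(pop, sex)))^2)
  expect_equal(tab$sumsq[tab$term == "population"], ss_pop, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "sex"], ss_sex, tolerance = 1e-9)
  expect_equal(tab$statistic[tab$term == "population"],
               (ss_pop / 1) / (ss_res / 12), tolerance = 1e-9)
})

test_that("size ANOVA collapses to one-way when a factor is constant", {
  set.seed(67)
  size <- rnorm(30, rep(c(10, 12, 13), each = 10))
  pop <- rep(c("A", "B", "C"), each = 10)
  tab <- size_anova(size, pop, rep("M", 30))
  f_oneway <- anova(lm(size ~ factor(pop)))
  expect_equal(tab$statistic[tab$term == "population"],
               f_oneway$`F value`[1], tolerance = 1e-10)
})

test_that("Wilks' lambda equals the univariate ANCOVA F in one dimension", {
  set.seed(68)
  n <- 40
  pop <- rep(c("A", "B"), each = n / 2)
  sex <- rep(c("M", "F"), n / 2)
  csize <- runif(n, 1, 2)
  y <- 0.5 * (pop == "B") + 0.2 * csize + rnorm(n, sd = 0.3)
  ss <- fake_shape_space(matrix(y, ncol = 1), pop, sex, csize)
  m <- shape_mancova(ss)
  uni <- car::Anova(lm(y ~ factor(pop) + factor(sex) + csize), type = 2)
  for (trm in c("population", "sex", "size")) {
    uterm <- c(population = "factor(pop)", sex = "factor(sex)", size = "csize")[trm]
    expect_equal(m$table$statistic[m$table$term == trm],
                 uni[uterm, "F value"], tolerance = 1e-10)
    expect_equal(m$table$p_value[m$table$term == trm],
                 uni[uterm, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("a strong constructed population effect is overwhelmingly significant", {
  set.seed(69)
  w <- simulate_wings(wing_sim_config(
    pop_effect = c(AlpineCarpathian = 0.03, NEEuropean = 0.015, Asian = 0),
    seed = 70))
  ss <- shape_pca(gpa(w), retain = 15)
  m <- shape_mancova(ss)
  expect_lt(m$table$p_value[m$table$term == "population"], 1e-6)
  expect_true(all(m$table$wilks > 0 & m$table$wilks <= 1))
})

test_that("Mahalanobis distances: zero for identical groups, 4 for a 2-sd shift", {
  set.seed(71)
  x <- rnorm(40)
  ss0 <- fake_shape_space(matrix(c(x, x), ncol = 1), rep(c("A", "B"), each = 40))
  expect_equal(mahalanobis_upgma(ss0)$d2["A", "B"], 0, tolerance = 1e-12)

  # exact construction: means 0 and 2, pooled variance 1
  y <- c(scale(rnorm(40)), scale(rnorm(40)) + 2)
  ssd <- fake_shape_space(matrix(y, ncol = 1), rep(c("A", "B"), each = 40))
  expect_equal(mahalanobis_upgma(ssd)$d2["A", "B"], 4, tolerance = 1e-9)
})

test_that("UPGMA on the hand example gives the ((A,B),C) ultrametric tree", {
  # exact group means and pooled identity covariance by construction
  a <- sqrt(1.5)
  cloud <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  mk <- function(mu) sweep(cloud, 2, mu, "+")
  X <- rbind(mk(c(0, 0)), mk(c(2, 0)), mk(c(1, sqrt(7))))
  ss <- fake_shape_space(X, rep(c("A", "B", "C"), each = 4))
  res <- mahalanobis_upgma(ss)
  expect_equal(res$d2["A", "B"], 4, tolerance = 1e-9)   # distance 2 squared
  # D2(AB) = 4, D2(AC) = D2(BC) = 8: UPGMA joins A,B at 2, C at 4
  coph <- ape::cophenetic.phylo(res$tree)
  expect_equal(coph["A", "B"], 4, tolerance = 1e-9)
  expect_equal(coph["A", "C"], 8, tolerance = 1e-9)
  expect_equal(coph["B", "C"], 8, tolerance = 1e-9)
  # ultrametric: root-to-leaf depths equal
  expect_true(ape::is.ultrametric(res$tree, tol = 1e-9))
})

test_that("UPGMA trees from simulated shape data are ultrametric", {
  set.seed(72)
  w <- simulate_wings(wing_sim_config(seed = 73))
  ss <- shape_pca(gpa(w), retain = 10)
  res <- mahalanobis_upgma(ss)
  expect_true(ape::is.ultrametric(res$tree, tol = 1e-9))
  expect_true(grepl(";$", res$newick))
})

test_that("Mahalanobis D2 is invariant under invertible affine score maps", {
  set.seed(74)
  X <- matrix(rnorm(240), 80, 3)
  X[41:80, ] <- X[41:80, ] + matrix(rep(c(1, -0.5, 0.25), each = 40), 40, 3)
  pop <- rep(c("A", "B"), each = 40)
  d2_raw <- mahalanobis_upgma(fake_shape_space(X, pop))$d2["A", "B"]
  A <- matrix(c(2, 0.3, -1, 0.5, 1.5, 0.2, 0, -0.7, 3), 3, 3)
  Y <- X %*% A + matrix(rep(c(5, -2, 1), each = 80), 80, 3)
  d2_aff <- mahalanobis_upgma(fake_shape_space(Y, pop))$d2["A", "B"]
  expect_equal(d2_aff, d2_raw, tolerance = 1e-9)
})

test_that("LDA posteriors behave at the group means and the midpoint", {
  set.seed(75)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(4, 0), "+"))
  pop <- rep(c("west", "east"), each = n)
  ss <- fake_shape_space(X, pop)
  la <- lda_assign(ss, pop, positive = "east")
  expect_gt(mean(la$posterior[pop == "east"] > 0.5), 0.95)
  # symmetric midpoint: construct a perfectly symmetric two-point dataset
  Xs <- rbind(matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE) + rnorm(40, sd = 1),
              matrix(rep(c(4, 0), 20), ncol = 2, byrow = TRUE) + rnorm(40, sd = 1))
  # use the fitted discriminant directly: a point equidistant from both means
  ssm <- fake_shape_space(Xs, rep(c("a", "b"), each = 20))
  fit <- MASS::lda(ssm$scores, grouping = factor(rep(c("a", "b"), each = 20)),
                   prior = c(0.5, 0.5))
  mid <- (fit$means[1, ] + fit$means[2, ]) / 2
  p <- predict(fit, matrix(mid, 1))$posterior
  expect_equal(unname(p[1, 1]), 0.5, tolerance = 1e-6)
  # LOO accuracy on well-separated groups
  la_loo <- lda_assign(ss, pop, positive = "east", loo = TRUE)
  acc <- mean((la_loo$posterior > 0.5) == (pop == "east"))
  expect_gt(acc, 0.95)
})

test_that("the whole morphometric pipeline is invariant to input similarity transforms", {
  set.seed(76)
  w <- simulate_wings(wing_sim_config(seed = 77))
  run <- function(wt) {
    g <- gpa(wt)
    ss <- shape_pca(g, retain = 8)
    list(d2 = mahalanobis_upgma(ss)$d2,
         wilks = shape_mancova(ss)$table$wilks,
         csize_ratio = g$csize / g$csize[1])
  }
  r1 <- run(w)
  w2 <- w
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- as.matrix(w[, c("x", "y")]) %*% R * 3.7
  w2$x <- xy[, 1] + 1000; w2$y <- xy[, 2] - 500
  r2 <- run(w2)
  expect_lt(max(abs(r1$d2 - r2$d2)), 1e-6)
  expect_lt(max(abs(r1$wilks - r2$wilks)), 1e-6)
  expect_equal(r1$csize_ratio, r2$csize_ratio, tolerance = 1e-9)
})
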