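# ggplot2 visualisations for the main result types.

#' Membership barplot for an admixture fit
#'
#' The familiar stacked-bar ancestry plot: one bar per individual, filled by
#' cluster ancestry, grouped by population.
#'
#' @param object an `admixture_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.admixture_fit <- function(object, ...) {
  d <- tidy(object)
  d$id <- factor(d$id, levels = unique(d$id[order(d$pop, -d$q)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$q,
                                  fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~pop, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_brewer(palette = "Set1", name = "cluster") +
    ggplot2::labs(x = NULL, y = "ancestry q") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Evanno delta-K plot
#' @param object a `delta_k_table`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.delta_k_table <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d[!is.na(d$delta_k), ],
                  ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Allele accumulation curve with extrapolation band
#' @param curve output of [accumulation_curve()]
#' @return a ggplot
#' @export
plot_accumulation <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t, y = .data$S)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$method)) +
    ggplot2::labs(x = "individuals sampled", y = "alleles (all loci)") +
    ggplot2::theme_minimal()
}

#' Density plot along the first discriminant axis
#' @param object a `dapc_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.dapc_fit <- function(object, ...) {
  d <- tibble(axis1 = object$coord[, 1], group = object$groups)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "discriminant axis 1", y = "density") +
    ggplot2::theme_minimal()
}

#' Consensus-shape comparison plot
#'
#' Overlays the magnified mean shapes of two groups on the overall
#' consensus (the classic "twice-enlarged" mean-shape comparison).
#'
#' @param fit a `gpa_fit`
#' @param group_a,group_b population labels to compare
#' @param magnify displacement magnification factor
#' @return a ggplot
#' @export
plot_shape_comparison <- function(fit, group_a, group_b, magnify = 2) {
  mean_of <- function(g) apply(fit$aligned[, , fit$meta$pop == g, drop = FALSE],
                               c(1, 2), mean)
  cons <- fit$consensus
  ma <- cons + magnify * (mean_of(group_a) - cons)
  mb <- cons + magnify * (mean_of(group_b) - cons)
  d <- bind_rows(
    tibble(group = group_a, lm = seq_len(nrow(ma)), x = ma[, 1], y = ma[, 2]),
    tibble(group = group_b, lm = seq_len(nrow(mb)), x = mb[, 1], y = mb[, 2]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = .data$group), alpha = 0.5) +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Genetic-vs-morphological assignment scatter with fitted curve
#' @param object a `fractional_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.fractional_fit <- function(object, ...) {
  g <- object$glm
  d <- tibble(x = g$model$x, y = g$model$y)
  xs <- seq(0, 1, length.out = 200)
  cf <- object$coefficients
  pred <- tibble(x = xs, y = 1 / (1 + exp(-(cf[1] + cf[2] * xs))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::labs(x = "morphological assignment probability",
                  y = "genetic ancestry probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
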