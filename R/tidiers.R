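#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col facet_wrap labs scale_linetype_manual theme_minimal
#'   position_dodge geom_errorbar
#' @export
ggplot2::autoplot

#' @export
tidy.klk_bifurcation <- function(x, ...) x$diagram

#' @export
glance.klk_bifurcation <- function(x, ...) {
  sm <- classify_pattern(x)
  n_per_mu <- dplyr::count(x$diagram, .data$mu)
  tibble(pattern = sm$pattern, mu_on = sm$mu_on, mu_off = sm$mu_off,
         delta_mu = sm$delta_mu, n_mu = length(x$mu_grid),
         max_states = if (nrow(n_per_mu)) max(n_per_mu$n) else 0L)
}

#' @export
tidy.klk_par2_score <- function(x, ...) x$scores

#' @export
glance.klk_par2_score <- function(x, ...) {
  sc <- x$scores
  tibble(n_samples = nrow(sc), B = x$B, n_background = x$n_background,
         hc_median = median(sc$score[sc$group == "HC"]),
         lad_median = median(sc$score[sc$group == "LAD"]))
}

#' @export
tidy.klk_sensitivity <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.klk_sensitivity <- function(x, ...) {
  d <- attr(x, "design")
  tibble(n_parameters = nrow(x), omega_max = d$omega_max, M = d$M,
         n_per_curve = d$n_per_curve, resamples = d$resamples,
         seed = d$seed)
}

#' Bifurcation diagram plot
#'
#' Inflammation level against stimulus, stable branches solid and unstable
#' branches dotted.
#'
#' @param object A `klk_bifurcation` from [scan_mu()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.klk_bifurcation <- function(object, ...) {
  d <- mutate(object$diagram,
              stable = ifelse(.data$stability == "stable",
                              "stable", "unstable"))
  ggplot(d, aes(.data$mu, .data$Pact, group = .data$branch,
                linetype = .data$stable)) +
    geom_point(size = 0.4) +
    scale_linetype_manual(values = c(stable = "solid",
                                     unstable = "dotted")) +
    labs(x = "external stimulus μ", y = "inflammation level [PAR2*]",
         linetype = NULL,
         title = paste0("Model ", object$params$variant, ", ",
                        object$params$condition)) +
    theme_minimal()
}

#' Feedback-strength sweep maps
#'
#' Pattern, inflammation-threshold and bistability-range heatmaps over the
#' (`alphaK`, `alphaL`) grid of [sweep_feedback_grid()].
#'
#' @param sweep Tibble returned by [sweep_feedback_grid()].
#' @param fill One of `"pattern"`, `"mu_on"`, `"delta_mu"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, fill = c("pattern", "mu_on", "delta_mu")) {
  fill <- match.arg(fill)
  ggplot(sweep, aes(.data$alphaK, .data$alphaL,
                    fill = .data[[fill]])) +
    geom_tile() +
    facet_wrap(~ condition) +
    labs(x = "feedback to KLK5 (αK)", y = "feedback to LEKTI (αL)",
         fill = fill) +
    theme_minimal()
}

#' Sensitivity index bar chart
#'
#' First- and total-order eFAST indices per parameter.
#'
#' @param object A `klk_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.klk_sensitivity <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object), c("Si", "STi"),
                           names_to = "index", values_to = "value")
  ggplot(d, aes(stats::reorder(.data$parameter, -.data$value),
                .data$value, fill = .data$index)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "sensitivity index") +
    theme_minimal()
}

#' PAR2 score versus marker expression scatter
#'
#' @param score A `klk_par2_score` object.
#' @param X The [expr_matrix()] the score was computed from.
#' @param probe Probe column to plot against.
#' @return A ggplot object.
#' @export
plot_score_vs_gene <- function(score, X, probe) {
  stopifnot(inherits(score, "klk_par2_score"), inherits(X, "expr_matrix"))
  d <- mutate(score$scores, expression = X$x[.data$sample, probe])
  ggplot(d, aes(.data$score, .data$expression, colour = .data$group)) +
    geom_point() +
    labs(x = "PAR2 score", y = paste(probe, "expression")) +
    theme_minimal()
}
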