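#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_hline geom_vline labs theme_minimal facet_wrap
#'   coord_flip
NULL

#' Plot a K-means selection profile
#'
#' SSE, BIC and pseudo-F against k; the pseudo-F panel is where the ecotype
#' k is read off (argmax), the BIC panel at the argmin.
#'
#' @param object a `kmeans_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kmeans_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object$stats, c("sse", "bic", "pseudo_f"),
                              names_to = "statistic", values_to = "value")
  ggplot(long, aes(x = .data$k, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~statistic, scales = "free_y") +
    labs(x = "number of groups k", y = NULL,
         title = "Ecotype K-means selection profile") +
    theme_minimal()
}

#' Plot the Evanno delta-K profile
#'
#' @param object an `admixture_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.admixture_profile <- function(object, ...) {
  dk <- object$delta_k
  ggplot(dk[!is.na(dk$delta_k), ], aes(x = .data$k, y = .data$delta_k)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$best_k, linetype = 2) +
    labs(x = "number of clusters k", y = expression(Delta * K),
         title = "Evanno delta-K profile") +
    theme_minimal()
}

#' Stacked admixture (Q) barplot
#'
#' @param object an `admixture_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.admixture_fit <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$id, y = .data$q, fill = .data$component)) +
    geom_col(width = 1) +
    labs(x = NULL, y = "membership Q",
         title = paste0("Admixture proportions (k = ", object$k, ")")) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Forest plot of an isolation-by-ecology test battery
#'
#' Matrix correlations with 95% CIs, one row per test, faceted by genetic
#' metric (null-model rows shown once).
#'
#' @param object an `ibe_suite` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ibe_suite <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$test <- factor(df$test, levels = rev(unique(df$test)))
  ggplot(df, aes(x = .data$test, y = .data$r, colour = .data$significant)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ci_lower, ymax = .data$ci_upper), width = 0.2) +
    coord_flip() +
    facet_wrap(~metric, nrow = 1) +
    labs(x = NULL, y = "matrix correlation r",
         title = "Isolation-by-ecology test battery") +
    theme_minimal()
}

#' Coefficient plot of a hierarchical model fit
#'
#' Posterior means and 95% credible intervals; intervals excluding zero are
#' highlighted.
#'
#' @param object an `hfc_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hfc_fit <- function(object, ...) {
  df <- object$summary
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot(df, aes(x = .data$term, y = .data$estimate,
                 colour = .data$significant)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ci_lower, ymax = .data$ci_upper), width = 0.2) +
    coord_flip() +
    labs(x = NULL, y = "posterior mean (95% CrI)",
         title = "Hierarchical model coefficients") +
    theme_minimal()
}

#' Posterior-predictive band for one covariate of a fitted model
#'
#' Plain export of the posterior predictive mean response over the observed
#' range of one standardised covariate, holding the others at zero: the
#' unadorned counterpart of a visually weighted effect display.
#'
#' @param fit an `hfc_fit`.
#' @param term covariate name.
#' @param n_grid grid points.
#' @return tibble `value`, `median`, `lower`, `upper` (95% band of the
#'   linear predictor mu_alpha + beta * value).
#' @export
posterior_effect_band <- function(fit, term, n_grid = 50) {
  draws <- do.call(rbind, fit$draws)
  if (!term %in% colnames(draws)) stop("unknown term: ", term)
  grid <- seq(-2, 2, length.out = n_grid)
  eta <- outer(draws[, term], grid) + draws[, "mu_alpha"]
  tibble::tibble(value = grid,
                 median = apply(eta, 2, stats::median),
                 lower = apply(eta, 2, quantile, 0.025),
                 upper = apply(eta, 2, quantile, 0.975))
}
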