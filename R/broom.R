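#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a quantile-regression cell
#'
#' @param x An `fc_quantreg` object.
#' @param ... Unused.
#' @return One row per term (intercept, slope); the slope row carries the
#'   species-bootstrap interval and species-permutation p-value.
#' @export
tidy.fc_quantreg <- function(x, ...) {
  tibble(
    term = c("(Intercept)", x$predictor),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, x$ci_low),
    conf.high = c(NA_real_, x$ci_high),
    p.value = c(NA_real_, x$p_perm)
  )
}

#' @rdname tidy.fc_quantreg
#' @export
glance.fc_quantreg <- function(x, ...) {
  tibble(
    response = x$response, predictor = x$predictor, subset = x$subset,
    tau = x$tau, slope = x$slope, ci_low = x$ci_low, ci_high = x$ci_high,
    p_perm = x$p_perm, n_pairs = x$n_pairs, df = x$df,
    B_perm = x$B_perm, B_boot = x$B_boot
  )
}

#' Tidy a Pagel's lambda fit
#' @param x An `fc_lambda` object.
#' @param ... Unused.
#' @export
tidy.fc_lambda <- function(x, ...) {
  tibble(
    trait = x$trait, statistic = "lambda", estimate = x$lambda_ml,
    p_labile = x$p_labile, p_brownian = x$p_brownian
  )
}

#' @rdname tidy.fc_lambda
#' @export
glance.fc_lambda <- function(x, ...) {
  tibble(
    trait = x$trait, lambda_ml = x$lambda_ml, loglik_ml = x$loglik_ml,
    loglik0 = x$loglik0, loglik1 = x$loglik1,
    p_labile = x$p_labile, p_brownian = x$p_brownian,
    sigma2_ml = x$sigma2_ml, mean_ml = x$mean_ml
  )
}

#' Tidy a D-statistic result
#' @param x An `fc_dstat` object.
#' @param ... Unused.
#' @export
tidy.fc_dstat <- function(x, ...) {
  tibble(
    statistic = "D", estimate = x$D, d_obs = x$d_obs,
    p_random = x$p_random, p_brownian = x$p_brownian, n_sims = x$n_sims
  )
}

#' Scatter of co-occurrence against a pairwise distance
#'
#' @param object An `fc_pairs` table.
#' @param predictor Column to use on the x axis (e.g. `"phylo_dist"`).
#' @param response `"cij_small"` or `"cij_large"`.
#' @param tau Quantile level for the overlaid fitted line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_pairs <- function(object, predictor = "phylo_dist",
                              response = "cij_small", tau = 0.5, ...) {
  df <- as_tibble(object)
  df <- df[is.finite(df[[predictor]]) & is.finite(df[[response]]), ]
  fit <- quantile_fit(df[[predictor]], df[[response]], tau)
  ggplot2::ggplot(df, ggplot2::aes(.data[[predictor]], .data[[response]])) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         linetype = "dashed") +
    ggplot2::labs(
      x = predictor, y = response,
      subtitle = sprintf("tau = %.2f quantile line, slope = %.3g", tau, fit$slope)
    ) +
    ggplot2::theme_minimal()
}

#' Node-age versus divergence plot
#'
#' Mirrors the standard node-age diagnostic: absolute standardized
#' contrasts against node age, the through-origin least-squares line
#' dashed, and significant outliers (|studentized residual| > 3) as solid
#' points.
#'
#' @param object An `fc_contrasts` table from [node_age_divergence()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_contrasts <- function(object, ...) {
  df <- as_tibble(object)
  if (is.null(df$age)) df$age <- df$age_mean
  if (is.null(df$outlier)) df$outlier <- FALSE
  slope <- attr(object, "slope")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$abs_std_contrast)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outlier), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                guide = "none") +
    ggplot2::labs(x = "node age", y = "|standardized contrast|") +
    ggplot2::theme_minimal()
  if (!is.null(slope)) {
    p <- p + ggplot2::geom_abline(intercept = 0, slope = slope,
                                  linetype = "dashed")
  }
  p
}
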