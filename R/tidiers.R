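# broom-style tidiers and ggplot2 autoplot methods for the fit and result
# classes. tidy() returns one row per term / component; glance() one row of
# model-level summaries.

fit_tidy <- function(x) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$statistic),
                 p.value = unname(x$p.value))
}

#' @exportS3Method generics::tidy
tidy.gls_fit <- function(x, ...) fit_tidy(x)

#' @exportS3Method generics::glance
glance.gls_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, logLik = x$logLik, AIC = x$AIC,
                 nobs = x$n, df.residual = x$df_residual)
}

#' @exportS3Method generics::tidy
tidy.mlpe_fit <- function(x, ...) fit_tidy(x)

#' @exportS3Method generics::glance
glance.mlpe_fit <- function(x, ...) {
  tibble::tibble(sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2,
                 logLik = x$logLik, logLik.REML = x$logLik_REML,
                 AIC = x$AIC, AICc = x$AICc, nobs = x$n,
                 n.pops = x$n_pops, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.heritability_fit <- function(x, ...) {
  tibble::tibble(term = c("sigma_u2", "sigma_e2"),
                 estimate = c(x$sigma_u2, x$sigma_e2))
}

#' @exportS3Method generics::glance
glance.heritability_fit <- function(x, ...) {
  tibble::tibble(heritability = x$estimate, conf.low = x$ci[1],
                 conf.high = x$ci[2], kind = x$kind,
                 n.strains = x$n_strains, nobs = x$n_obs,
                 boundary = x$boundary)
}

#' @exportS3Method generics::tidy
tidy.qtl_variance_fit <- function(x, ...) {
  tibble::tibble(term = c("sigma_u2", "sigma_v2", "sigma_e2"),
                 estimate = c(x$sigma_u2, x$sigma_v2, x$sigma_e2))
}

#' @exportS3Method generics::glance
glance.qtl_variance_fit <- function(x, ...) {
  tibble::tibble(qtl.fraction = x$fraction, logLik.REML = x$logLik_REML,
                 converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.pgls_selection <- function(x, ...) x$ranking

#' Plot an aggregation time series
#'
#' @param object An `agg_series` from [aggregation_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.agg_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$A)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "aggregation magnitude A(t)") +
    ggplot2::theme_minimal()
}

#' Plot an autocorrelation function with its running integral
#'
#' Shades the running integral of C(tau) whose maximum defines the
#' temporal persistence tau_A.
#'
#' @param object An `acf_result` from [autocorrelation()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.acf_result <- function(object, ...) {
  tau <- temporal_persistence(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$C)) +
    ggplot2::geom_area(fill = "#fee391", alpha = 0.6) +
    ggplot2::geom_line(colour = "#cc4c02") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "lag (s)", y = "C(tau)",
                  subtitle = sprintf("tau_A = %.2f s", tau)) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap distribution of a heritability estimate
#'
#' @param object A `heritability_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.heritability_fit <- function(object, ...) {
  d <- tibble::tibble(h2 = object$boot)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h2)) +
    ggplot2::geom_histogram(bins = 30, fill = "#74a9cf", colour = "white") +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "#d7301f") +
    ggplot2::labs(
      x = if (object$kind == "broad") "broad-sense H2" else "narrow-sense h2",
      y = "bootstrap count") +
    ggplot2::theme_minimal()
}

#' Plot per-frame cluster-size totals and QC flags
#'
#' @param object A `frame_sizes` object from [per_frame_sizes()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.frame_sizes <- function(object, ...) {
  qc <- attr(object, "qc")
  d <- tibble::tibble(frame = object$frame, total = object$total,
                      flagged = object$flagged)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$total,
                                  colour = .data$flagged)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(yintercept = qc$n_worms, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#d7301f")) +
    ggplot2::labs(x = "frame", y = "sum of estimated sizes") +
    ggplot2::theme_minimal()
}
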