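# ggplot2 displays for each result type. All plots are headless-safe (they
# return ggplot objects; nothing opens a device).

#' Plot trial-structured activity
#'
#' @param object a [trial_array()].
#' @param max_trials draw at most this many trials (default 10).
#' @param ... unused.
#' @return a ggplot object: activity vs time, one line per trial.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.trial_array <- function(object, max_trials = 10, ...) {
  df <- tidy.trial_array(object) |>
    dplyr::filter(.data$trial <= max_trials)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$activity,
                                   group = .data$trial,
                                   colour = factor(.data$trial))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::labs(x = sprintf("time (%s)", dtunit_of(object)),
                  y = "activity (events / bin)", colour = "trial") +
    ggplot2::theme_minimal()
}

#' Plot estimated correlation coefficients, optionally with fits
#'
#' @param object an `mr_coefficients` result.
#' @param fits an `mr_fit` or list of them to overlay as curves.
#' @param log_y log-scale the coefficient axis (useful to read the decay
#'   slope; drops non-positive points).
#' @param ... unused.
#' @return a ggplot object: `r_k` vs physical lag, bootstrap-error ribbon
#'   when available, one curve per fit.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mr_coefficients <- function(object, fits = NULL, log_y = FALSE,
                                     ...) {
  df <- tidy.mr_coefficients(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$coefficient)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6)
  if (!is.null(df[["stderr"]])) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$coefficient - .data$stderr,
                   ymax = .data$coefficient + .data$stderr),
      alpha = 0.2)
  }
  if (!is.null(fits)) {
    if (inherits(fits, "mr_fit")) fits <- list(fits)
    curves <- purrr::map_dfr(fits, function(ft) {
      if (identical(ft$fitfunc, "log_slope")) return(NULL)
      lag <- df$lag
      tibble::tibble(lag = lag,
                     value = evaluate_fitfunc(ft$fitfunc, lag, ft$params),
                     fitfunc = ft$fitfunc)
    })
    if (nrow(curves) > 0) {
      p <- p + ggplot2::geom_line(
        data = curves,
        ggplot2::aes(.data$lag, .data$value, colour = .data$fitfunc),
        linewidth = 0.7)
    }
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p + ggplot2::labs(x = sprintf("lag k · dt (%s)", object$dtunit),
                    y = expression(r[k]), colour = "fit") +
    ggplot2::theme_minimal()
}

#' Four-panel overview of a full analysis
#'
#' Activity traces, per-trial mean and standard deviation, coefficients with
#' the fitted curves, and the numeric estimates as text — the at-a-glance
#' check that the fit describes the data and the trials are comparable.
#' Uses patchwork to lay out the panels when it is installed, otherwise
#' returns the coefficient panel alone.
#'
#' @param object an `mr_report`.
#' @param trials the trial array the report was computed from (optional; the
#'   activity panel is skipped without it).
#' @param ... unused.
#' @return a ggplot / patchwork object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mr_report <- function(object, trials = NULL, ...) {
  p_coef <- autoplot.mr_coefficients(object$coefficients,
                                     fits = object$fits)
  p_means <- ggplot2::ggplot(object$trial_summary,
                             ggplot2::aes(.data$trial, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             linewidth = 0.3, size = 0.3) +
    ggplot2::labs(x = "trial", y = "activity mean ± sd") +
    ggplot2::theme_minimal()
  lab <- paste(vapply(names(object$fits), function(nm) {
    ft <- object$fits[[nm]]
    if (identical(ft$fitfunc, "log_slope")) {
      sprintf("%s: supercritical, m = %.3g", nm, ft$mre)
    } else {
      sprintf("%s: tau = %.4g %s%s, m = %.4g", nm, ft$tau, ft$dtunit,
              if (!is.null(ft$tau_ci)) {
                sprintf(" [%.4g, %.4g]", ft$tau_ci[1], ft$tau_ci[2])
              } else "",
              ft$mre)
    }
  }, character(1)), collapse = "\n")
  p_text <- ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = lab, hjust = 0,
                      size = 3) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_void()
  panels <- list(p_means, p_coef, p_text)
  if (!is.null(trials)) {
    panels <- c(list(autoplot.trial_array(trials)), panels)
  }
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(panels, ncol = 2)
  } else {
    p_coef
  }
}

#' Plot a simulated short-trial bias study
#'
#' @param study the tibble returned by [bias_study()].
#' @param tau,dt passed through to draw the analytic leading-order curve
#'   `y = 1 / (1 + 4/x)`.
#' @return a ggplot object: mean `tau_hat / tau` vs normalized trial length
#'   per method, with the analytic bias curve.
#' @export
plot_bias_study <- function(study, tau = NULL, dt = 1) {
  xs <- exp(seq(log(min(study$ratio)), log(max(study$ratio)),
                length.out = 100))
  curve <- tibble::tibble(ratio = xs, y = tau_ratio_leading_order(xs))
  ggplot2::ggplot(study, ggplot2::aes(.data$ratio, .data$mean_ratio,
                                      colour = .data$method)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$ratio, .data$y),
                       inherit.aes = FALSE, linetype = "dotted") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_ratio - .data$se_ratio,
                   ymax = .data$mean_ratio + .data$se_ratio)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(T / tau),
                  y = expression(hat(tau) / tau), colour = "method") +
    ggplot2::theme_minimal()
}
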