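#' Tidiers and plots for simulation results
#'
#' broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods
#' for the package's result objects.
#'
#' @name methods
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s mg x %d q%gh%s\n", format(x$regimen$dose),
              x$regimen$n_doses, x$regimen$interval,
              if (!is.null(x$perpetrator)) paste0(" + ", x$perpetrator$name) else ""))
  print(x$metrics)
  invisible(x)
}

#' @rdname methods
#' @param x A result object.
#' @param ... Unused.
#' @export
tidy.pbpk_sim <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname methods
#' @export
glance.pbpk_sim <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(dose_mg = x$regimen$dose, n_doses = x$regimen$n_doses,
                   balance_error = x$balance_error,
                   perpetrator = x$perpetrator$name %||% NA_character_)
  )
}

#' @rdname methods
#' @export
tidy.ddi_result <- function(x, ...) {
  dplyr::mutate(x$summary, perpetrator = x$perpetrator, .before = 1)
}

#' @rdname methods
#' @export
glance.ddi_result <- function(x, ...) {
  auc <- x$summary[x$summary$metric == "auc_0_24_ss", ]
  tibble::tibble(perpetrator = x$perpetrator, auc_gmr = auc$gmr,
                 auc_lo = auc$lo, auc_hi = auc$hi,
                 clinically_significant = auc$clinically_significant)
}

#' @rdname methods
#' @export
tidy.sweep_result <- function(x, ...) x$stats

#' @rdname methods
#' @export
glance.sweep_result <- function(x, ...) {
  auc <- x$stats[x$stats$metric == "auc_0_24_ss", ]
  tibble::tibble(parameter = x$parameter, n_levels = length(x$values),
                 auc_fold_change = auc$fold_change_extremes,
                 p_kruskal_wallis = auc$p_kruskal_wallis)
}

#' @rdname methods
#' @export
tidy.outcome_comparison <- function(x, ...) tibble::as_tibble(x)

#' Concentration-time plot of a simulation
#'
#' @param object A `pbpk_sim`.
#' @param ... Unused.
#' @export
autoplot.pbpk_sim <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$time_h, y = .data$conc_mg_per_L)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Time (h)", y = "Plasma imatinib (µg/mL)") +
    ggplot2::theme_minimal()
}

#' Forest plot of DDI geometric mean ratios
#'
#' @param object A `ddi_result`.
#' @param ... Unused.
#' @export
autoplot.ddi_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$gmr, y = .data$metric)) +
    ggplot2::annotate("rect", xmin = 0.8, xmax = 1.25, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = sprintf("GMR with %s (90%% CI)", object$perpetrator),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Geometric mean exposure across sweep levels
#'
#' @param object A `sweep_result`.
#' @param metric Metric column to display.
#' @param ... Unused.
#' @export
autoplot.sweep_result <- function(object, metric = "auc_0_24_ss", ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$level), y = .data[[metric]],
                               group = 1)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = object$parameter, y = paste("GM", metric)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
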