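#' Plot a global-epistasis scan
#'
#' deltaF against background function F, one point per background, with the
#' measured OLS line (dotted) and, when a fit with a defined carbon share is
#' supplied, the analytic line `deltaF = alpha*C0*beta_j - alpha*F` (dashed).
#'
#' @param scan An `epistasis_scan`.
#' @param fit Optional `epistasis_fit` for the same scan.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scan needs ggplot2", call. = FALSE)
  g <- ggplot2::ggplot(scan$points, ggplot2::aes(x = F, y = deltaF)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::labs(
      x = "background function F", y = expression(Delta * F),
      title = paste0("focal ", scan$focal_kind, " '", scan$focal_id, "' (",
                     scan$family, ")")) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    g <- g + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  linetype = "dotted")
    if (is.finite(fit$analytic_slope))
      g <- g + ggplot2::geom_abline(slope = fit$analytic_slope,
                                    intercept = fit$analytic_intercept,
                                    linetype = "dashed", colour = "red")
  }
  g
}

#' Plot a leakage sweep
#'
#' Guild-averaged density-weighted correlation against leakage pp, with a
#' plus/minus one standard deviation band across community replicates.
#'
#' @param sweep A `sweep_result`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep needs ggplot2", call. = FALSE)
  s <- sweep$summary
  ggplot2::ggplot(s, ggplot2::aes(x = pp, y = mean_rho_w, colour = guild,
                                  fill = guild)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_rho_w - sd_rho_w,
                                      ymax = mean_rho_w + sd_rho_w),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "leakage pp",
                  y = expression(rho[w]),
                  title = "guild-averaged density-weighted correlation") +
    ggplot2::theme_minimal()
}
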