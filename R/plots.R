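#' Plot the HKB potential landscape
#'
#' Draws \eqn{V(\phi)} over \eqn{[-\pi, \pi]} with its stationary points
#' marked (filled = stable attractor, open = unstable).
#'
#' @param params An [hkb_params()] object.
#' @param n Grid resolution (default 721).
#' @return A ggplot object.
#' @export
plot_potential <- function(params, n = 721) {
  params <- check_hkb_params(params)
  grid <- tibble::tibble(phi = seq(-pi, pi, length.out = n))
  grid$V <- hkb_potential(grid$phi, params)
  fps <- hkb_fixed_points(params)
  fps$V <- hkb_potential(fps$phi_star, params)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$phi, y = .data$V)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = fps,
                        ggplot2::aes(x = .data$phi_star, y = .data$V,
                                     shape = .data$stable), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "stable") +
    ggplot2::labs(x = expression(phi ~ "(rad)"),
                  y = expression(V(phi) ~ "(1/s)")) +
    ggplot2::theme_minimal()
}

#' Plot a trial's folded continuous relative phase over time
#'
#' @param trial Kinematics tibble (`t_s`, `yL_m`, `yR_m`).
#' @param intended_deg Optional intended phase to mark (0 or 180).
#' @return A ggplot object.
#' @export
plot_crp_series <- function(trial, intended_deg = NULL) {
  df <- tibble::tibble(t_s = trial$t_s,
                       crp_deg = crp(trial$yR_m, trial$yL_m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$crp_deg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 180)) +
    ggplot2::labs(x = "time (s)", y = "CRP (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(intended_deg)) {
    p <- p + ggplot2::geom_hline(yintercept = intended_deg,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Deviation from intended phase by load condition
#'
#' Box-and-jitter plot of per-trial deviation from the intended phase,
#' faceted by analysis stratum, with matched and mismatched conditions
#' distinguished by colour.
#'
#' @param table A condition table from [build_condition_table()].
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(table) {
  stopifnot(all(c("load_condition", "deviation_deg", "stratum")
                %in% names(table)))
  tab <- dplyr::mutate(
    table,
    matched = ifelse(.data$load_left == .data$load_right,
                     "matched", "mismatched"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$load_condition,
                                    y = .data$deviation_deg,
                                    colour = .data$matched)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "load condition (left/right)",
                  y = "|mean CRP - intended| (deg)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Autoplot a fitted condition model
#'
#' Estimated marginal means per load condition with confidence intervals.
#'
#' @param object A `coord_lme` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coord_lme
#' @export
autoplot.coord_lme <- function(object, ...) {
  em <- pairwise_emm(object)$emmeans
  em$load_condition <- factor(em$load_condition,
                              levels = em$load_condition)
  ggplot2::ggplot(em, ggplot2::aes(x = .data$load_condition,
                                   y = .data$emmean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(
      x = "load condition (left/right)",
      y = sprintf("%s CRP (deg), estimated marginal mean",
                  if (object$response == "mean") "mean" else "SD of"),
      title = object$stratum) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
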