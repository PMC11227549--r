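# ggplot2 visualisations for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.psych_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(
      x = if (attr(object, "axis") == "reward") "Reward level" else "Cost level",
      y = if (attr(object, "feature") == "choice") "Approach rate"
          else attr(object, "feature"),
      size = "trials"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.logistic1d_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(min(object$curve$x), max(object$curve$x), length.out = 200)
  )
  grid$y <- object$predict(grid$x)
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = paste(object$axis, "level"), y = "Approach rate",
                  subtitle = sprintf("a = %.3g, b = %.3g, R² = %.3f",
                                     object$a, object$b, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted choice surface with its decision boundary
#'
#' @param fit A `logistic2d_fit`.
#' @param r_range,c_range Axis ranges (reward, cost).
#' @param n Grid resolution.
#' @return A ggplot object.
#' @export
plot_choice_surface <- function(fit, r_range = c(0, 5), c_range = c(0, 4),
                                n = 80) {
  grid <- tidyr::expand_grid(
    R = seq(r_range[1], r_range[2], length.out = n),
    C = seq(c_range[1], c_range[2], length.out = n)
  )
  grid$p <- fit$predict(grid$R, grid$C)
  bd <- decision_boundary(fit, seq(c_range[1], c_range[2], length.out = 100))
  bd <- bd[bd$exists & bd$R_star >= r_range[1] & bd$R_star <= r_range[2], ]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$C, y = .data$R)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$p)) +
    ggplot2::geom_line(data = bd, ggplot2::aes(x = .data$C, y = .data$R_star),
                       colour = "white", linewidth = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Cost level", y = "Reward level",
                  fill = "P(approach)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fcm_fit <- function(object, points = NULL, ...) {
  ctr <- tibble::as_tibble(as.data.frame(object$centers))
  axes <- names(ctr)[1:2]
  p <- ggplot2::ggplot()
  if (!is.null(points)) {
    df <- tibble::as_tibble(as.data.frame(points))
    df$cluster <- factor(object$cluster)
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                   colour = .data$cluster),
      alpha = 0.7
    )
  }
  p +
    ggplot2::geom_point(data = ctr,
                        ggplot2::aes(x = .data[[axes[1]]],
                                     y = .data[[axes[2]]]),
                        shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(subtitle = sprintf("c = %d, MPC = %.3f",
                                     object$c, object$mpc)) +
    ggplot2::theme_minimal()
}

#' Radar-style plot of per-rat strategy profiles
#'
#' @param profiles A `strategy_profiles` tibble.
#' @param feature Feature to display.
#' @return A ggplot object (polar coordinates, one panel per rat).
#' @export
plot_strategy_profiles <- function(profiles, feature = NULL) {
  df <- profiles
  if (!is.null(feature)) df <- dplyr::filter(df, .data$feature == !!feature)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$probability,
                                   group = .data$rat_id)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.4,
                          colour = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~rat_id) +
    ggplot2::labs(x = "Cluster", y = "Session probability") +
    ggplot2::theme_minimal()
}
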