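#' Plot a simulated trajectory
#'
#' Time series of the three populations on a free y scale per stage.
#'
#' @param object A `cbb_trajectory` from [cbb_simulate].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbb_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("A", "I", "H"),
    names_to = "population", values_to = "count"
  )
  long$population <- factor(long$population,
    levels = c("A", "I", "H"),
    labels = c("adult borers (A)", "immature borers (I)", "ants (H)")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$count)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~population, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "average number of individuals") +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Equilibrium branches of one coordinate against the adult death rate
#' `mu`; solid lines are locally asymptotically stable branches, dashed
#' lines unstable ones, and vertical lines mark the bifurcation values.
#' Branches without biological sense are omitted.
#'
#' @param object A `cbb_bifurcation` from [bifurcation_diagram].
#' @param coord Which coordinate to display: `"A"`, `"I"` or `"H"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbb_bifurcation <- function(object, coord = c("I", "A", "H"), ...) {
  coord <- match.arg(coord)
  dat <- dplyr::filter(tibble::as_tibble(object), .data$biological_sense)
  dat$value <- dat[[coord]]
  bifs <- attr(object, "bif_points")
  ggplot2::ggplot(dat, ggplot2::aes(.data$mu, .data$value,
    colour = .data$label,
    linetype = .data$stable, group = .data$label
  )) +
    ggplot2::geom_line(linewidth = 0.5, na.rm = TRUE) +
    ggplot2::geom_vline(
      xintercept = bifs[bifs > 0],
      linetype = "dotted", colour = "grey40"
    ) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      na.value = "blank", name = "stable"
    ) +
    ggplot2::labs(
      x = expression(mu ~ "(adult death rate, 1/day)"),
      y = paste0(coord, " at equilibrium"), colour = "equilibrium"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a predation-rate sweep
#'
#' Required daily adult borer deaths against the predation rate on
#' adults, one line per predation rate on immatures.
#'
#' @param object A `cbb_sweep` from [predation_sweep].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbb_sweep <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$alpha, .data$required_deaths,
    colour = factor(.data$delta), group = factor(.data$delta)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(alpha ~ "(predation rate on adults)"),
      y = "required daily adult deaths (other causes)",
      colour = expression(delta)
    ) +
    ggplot2::theme_minimal()
}
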