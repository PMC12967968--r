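#' Heatmap of the competence surface
#'
#' Score heatmap over the deviation-instability plane with contour
#' lines at the band cut points (0.3, 0.5, 0.7 by default).
#'
#' @param object An [competence_surface()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nx_surface <- function(object, ...) {
  cuts <- attr(object, "bands")$cuts
  ggplot2::ggplot(object, ggplot2::aes(x = d, y = s)) +
    ggplot2::geom_raster(ggplot2::aes(fill = S)) +
    ggplot2::geom_contour(ggplot2::aes(z = S), breaks = cuts,
                          colour = "white", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "deviation d (mm)", y = "instability s",
                  fill = "S") +
    ggplot2::theme_minimal()
}

#' Membership-profile curves
#'
#' T, I and F along deviation, one panel per instability level.
#'
#' @param profiles Output of [membership_profiles()].
#' @return A ggplot object.
#' @export
plot_membership_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = d, y = value, colour = membership)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~s_level, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "deviation d (mm)", y = "membership") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Decision-region map
#'
#' Band classification of every grid cell in the deviation-instability
#' plane.
#'
#' @param regions Output of [decision_regions()] (or a surface).
#' @return A ggplot object.
#' @export
plot_decision_regions <- function(regions) {
  ggplot2::ggplot(regions, ggplot2::aes(x = d, y = s, fill = band)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_d() +
    ggplot2::labs(x = "deviation d (mm)", y = "instability s",
                  fill = "band") +
    ggplot2::theme_minimal()
}

#' Cohort scatter in the deviation-instability plane
#'
#' One point per attempt, coloured by competence score, shaped by
#' group when present.
#'
#' @param data An evaluated cohort.
#' @return A ggplot object.
#' @export
plot_cohort <- function(data) {
  check_cohort(data, need_group = FALSE)
  aes <- if ("group" %in% names(data)) {
    ggplot2::aes(x = d, y = s, colour = S, shape = group)
  } else {
    ggplot2::aes(x = d, y = s, colour = S)
  }
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "deviation d (mm)", y = "instability s") +
    ggplot2::theme_minimal()
}
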