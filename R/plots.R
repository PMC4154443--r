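#' Plot a depth-stratified contact profile
#'
#' Mirror-style stratification plot: contact area per unit IPL depth bin,
#' one panel colour per signal-flow category, depth increasing downwards
#' (amacrine cell layer at the top, ganglion cell layer at the bottom).
#'
#' @param object A `depth_profile` from [depth_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_lo + 0.5, y = .data$area_um2,
                               fill = .data$category)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::scale_x_reverse(breaks = c(0, 10, 15, 25)) +
    ggplot2::labs(x = "IPL depth (0 = ACL, 25 = GCL)",
                  y = expression("contact area (" * mu * m^2 * ")")) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot gap-junction size statistics
#'
#' The 25 nm binned diameter histogram with the cumulative frequency curve
#' overlaid (secondary axis), as used to compare homocellular and
#' heterocellular coupling strength.
#'
#' @param object A `gj_size_stats` from [size_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gj_size_stats <- function(object, ...) {
  h <- object$histogram
  scale <- max(h$count)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = 25,
                      fill = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_freq * scale),
                       colour = "firebrick") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "cumulative frequency")) +
    ggplot2::labs(title = object$pairing,
                  subtitle = sprintf("n = %d, %.0f +/- %.0f nm, max %.0f nm",
                                     object$n, object$mean_nm, object$sd_nm,
                                     object$max_nm),
                  x = "gap junction diameter (nm)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a cell mosaic with its Voronoi tessellation
#'
#' Soma positions, Voronoi tile edges and the circular field boundary;
#' interior tiles (used for the jitter statistic) are shaded.
#'
#' @param points Tibble with `x_um`, `y_um`.
#' @param field_diameter_mm Field diameter, mm.
#' @return A ggplot object.
#' @export
plot_mosaic <- function(points, field_diameter_mm) {
  tiles <- voronoi_tiles(points, field_diameter_mm)
  polys <- purrr::imap(tiles, function(tl, i) {
    tibble(tile = i, x_um = tl$x, y_um = tl$y, interior = tl$interior)
  }) |> list_rbind()
  r_um <- field_diameter_mm * 1000 / 2
  circ <- tibble(
    x_um = r_um + r_um * cos(seq(0, 2 * pi, length.out = 181)),
    y_um = r_um + r_um * sin(seq(0, 2 * pi, length.out = 181))
  )
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(.data$x_um, .data$y_um,
                                       group = .data$tile,
                                       fill = .data$interior),
                          colour = "grey40", linewidth = 0.3, alpha = 0.4) +
    ggplot2::geom_point(data = points, ggplot2::aes(.data$x_um, .data$y_um),
                        size = 1.2) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x_um, .data$y_um),
                       colour = "grey20") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "lightsteelblue",
                                          `FALSE` = "white"), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot per-partner coupling and synapse weights for a focal cell
#'
#' Horizontal bar chart of a partner summary: contacts per partner cell,
#' coloured by contact kind.
#'
#' @param object A `partner_summary` from [aggregate_partners()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.partner_summary <- function(object, ...) {
  dat <- object |>
    mutate(partner = sprintf("%s %d", .data$partner_class, .data$partner_cell))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = stats::reorder(.data$partner, .data$n_contacts),
                               y = .data$n_contacts, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contacts",
                  title = sprintf("partners of cell %d",
                                  object$focal_cell[1])) +
    ggplot2::theme_minimal()
}
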