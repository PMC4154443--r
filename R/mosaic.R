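#' Planar density of a cell mosaic
#'
#' @param points Tibble with `x_um`, `y_um` soma positions (or any points
#'   inside the circular field).
#' @param field_diameter_mm Field diameter, mm.
#' @return Density in cells per square millimetre.
#' @export
#' @examples
#' pts <- tibble::tibble(x_um = runif(39, 0, 243), y_um = runif(39, 0, 243))
#' planar_density(pts, 0.243)
planar_density <- function(points, field_diameter_mm) {
  if (nrow(points) < 1) abort("need at least one point")
  nrow(points) / (pi * (field_diameter_mm / 2)^2)
}

#' Centre-to-centre tile spacing implied by a density
#'
#' Square-measure convention: a mosaic of density `d` tiles the plane with
#' unit cells of area `1/d`, giving a centre-to-centre spacing of
#' `1/sqrt(d)`. At 841 cells/mm^2 this is 34.5 um.
#'
#' @param density_mm2 Density, cells/mm^2.
#' @return Spacing in micrometres.
#' @export
tile_spacing <- function(density_mm2) {
  if (density_mm2 <= 0) abort("density must be positive")
  1000 / sqrt(density_mm2)
}

# distance of points from the circular field boundary, um; field centred at
# (r, r) with radius r (origin at field top-left corner)
boundary_distance <- function(points, field_diameter_mm) {
  r_um <- field_diameter_mm * 1000 / 2
  r_um - sqrt((points$x_um - r_um)^2 + (points$y_um - r_um)^2)
}

#' Nearest-neighbour spacing of a mosaic
#'
#' Per-point nearest-neighbour distances with a guard-zone edge correction:
#' points closer than `edge_guard_um` to the circular field boundary are not
#' used as focal points (their true nearest neighbour may lie outside the
#' field), but remain available as neighbours.
#'
#' @param points Tibble with `x_um`, `y_um`.
#' @param field_diameter_mm Field diameter, mm.
#' @param edge_guard_um Guard-zone width, um (default 0: no exclusion).
#' @return List with `mean_um`, `sd_um`, `n_pairs` and the per-focal-point
#'   distances `nn_um`.
#' @export
nn_spacing <- function(points, field_diameter_mm, edge_guard_um = 0) {
  if (nrow(points) < 2) abort("need at least two points")
  d <- as.matrix(dist(cbind(points$x_um, points$y_um)))
  diag(d) <- Inf
  nn_all <- apply(d, 1, min)
  focal <- boundary_distance(points, field_diameter_mm) >= edge_guard_um
  if (!any(focal)) abort("no focal points remain after edge-guard exclusion")
  nn <- nn_all[focal]
  list(
    mean_um = mean(nn),
    sd_um = if (length(nn) > 1) sd(nn) else 0,
    n_pairs = length(nn),
    nn_um = nn
  )
}

# Voronoi tiles of a point set within the circular field, via deldir.
# Returns a list of per-point tiles: vertices, centroid, whether the tile is
# interior (no vertex clipped by the bounding window and all vertices inside
# the circular field).
voronoi_tiles <- function(points, field_diameter_mm) {
  if (nrow(points) < 3) abort("need at least three points")
  d_um <- field_diameter_mm * 1000
  dd <- deldir::deldir(points$x_um, points$y_um, rw = c(0, d_um, 0, d_um),
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  r_um <- d_um / 2
  purrr::map(tiles, function(tl) {
    inside <- sqrt((tl$x - r_um)^2 + (tl$y - r_um)^2) <= r_um
    on_window <- if (!is.null(tl$bp)) any(tl$bp) else FALSE
    cx <- sum(tl$x) / length(tl$x)  # placeholder, replaced by polygon centroid
    # polygon centroid (area-weighted)
    x <- tl$x; y <- tl$y; n <- length(x)
    j <- c(n, seq_len(n - 1))
    cross <- x[j] * y - x * y[j]
    a <- sum(cross) / 2
    cx <- sum((x[j] + x) * cross) / (6 * a)
    cy <- sum((y[j] + y) * cross) / (6 * a)
    list(
      pt = c(tl$pt[["x"]], tl$pt[["y"]]),
      x = x, y = y,
      centroid = c(cx, cy),
      area = abs(a),
      interior = all(inside) && !on_window
    )
  })
}

#' Voronoi positional jitter of a mosaic
#'
#' Somas are rarely centred on their Voronoi tile; the jitter statistic is
#' the mean, over interior tiles, of the soma-to-tile-centroid offset
#' divided by the nominal tile spacing (`1/sqrt(density)`). A perfectly
#' regular lattice has jitter 0; the AII mosaic shows about 10%.
#'
#' @param points Tibble with `x_um`, `y_um`.
#' @param field_diameter_mm Field diameter, mm.
#' @return List with `jitter` (dimensionless), `n_interior`, `spacing_um`
#'   and the per-tile offsets `offset_um`.
#' @export
voronoi_jitter <- function(points, field_diameter_mm) {
  tiles <- voronoi_tiles(points, field_diameter_mm)
  interior <- purrr::keep(tiles, "interior")
  if (length(interior) == 0) {
    abort("no interior tiles: all Voronoi tiles are clipped by the field boundary")
  }
  spacing <- tile_spacing(planar_density(points, field_diameter_mm))
  offsets <- purrr::map_dbl(interior, function(tl) {
    sqrt(sum((tl$pt - tl$centroid)^2))
  })
  list(
    jitter = mean(offsets) / spacing,
    n_interior = length(interior),
    spacing_um = spacing,
    offset_um = offsets
  )
}

#' Coverage factor of an arbor over a mosaic
#'
#' Arbor area relative to the per-cell tile area, in the squared
#' diameter-over-spacing convention: `C = (arbor_diameter / tile_spacing)^2`.
#' An arbor spanning twice the tile spacing covers `C = 4`.
#'
#' @param arbor_diameter_um Arbor field diameter, um.
#' @param tile_spacing_um Centre-to-centre tile spacing, um.
#' @return Dimensionless coverage factor.
#' @export
coverage_factor <- function(arbor_diameter_um, tile_spacing_um) {
  if (arbor_diameter_um <= 0 || tile_spacing_um <= 0) {
    abort("arbor diameter and tile spacing must be positive")
  }
  (arbor_diameter_um / tile_spacing_um)^2
}

#' Predicted grid connectivity at a given coverage factor
#'
#' On an ideal square lattice with unit spacing, a cell whose arbor diameter
#' is `sqrt(C)` lattice units strictly overlaps the arbor of every lattice
#' neighbour at centre distance less than twice the arbor radius, i.e. all
#' integer offsets `(dx, dy) != (0, 0)` with `dx^2 + dy^2 < C`. At the ideal
#' coverage factor of 4 this predicts 8-connectivity.
#'
#' @param coverage Coverage factor `C > 0`.
#' @return Number of connected lattice neighbours.
#' @export
#' @examples
#' predicted_grid_connectivity(4)  # 8
predicted_grid_connectivity <- function(coverage) {
  if (coverage <= 0) abort("coverage factor must be positive")
  rmax <- ceiling(sqrt(coverage))
  offs <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  sum(offs$dx^2 + offs$dy^2 < coverage) - 1L  # minus the origin
}

#' Mosaic summary statistics
#'
#' Density, implied tile spacing, nearest-neighbour spacing, Voronoi jitter
#' and (when an arbor diameter is supplied) coverage factor and predicted
#' grid connectivity, in one tidy row.
#'
#' @param points Tibble with `x_um`, `y_um` soma positions.
#' @param field_diameter_mm Field diameter, mm.
#' @param arbor_diameter_um Optional arbor field diameter, um.
#' @param edge_guard_um Edge guard for NN statistics; defaults to one
#'   nominal tile spacing.
#' @return One-row tibble of class `mosaic_stats`.
#' @export
mosaic_stats <- function(points, field_diameter_mm, arbor_diameter_um = NULL,
                         edge_guard_um = NULL) {
  dens <- planar_density(points, field_diameter_mm)
  spacing <- tile_spacing(dens)
  if (is.null(edge_guard_um)) edge_guard_um <- spacing
  nn <- nn_spacing(points, field_diameter_mm, edge_guard_um)
  vj <- tryCatch(voronoi_jitter(points, field_diameter_mm),
                 error = function(e) list(jitter = NA_real_, n_interior = 0L))
  cov <- if (is.null(arbor_diameter_um)) NA_real_ else
    coverage_factor(arbor_diameter_um, spacing)
  out <- tibble(
    n_cells = nrow(points),
    density_mm2 = dens,
    tile_spacing_um = spacing,
    nn_mean_um = nn$mean_um,
    nn_sd_um = nn$sd_um,
    nn_n = nn$n_pairs,
    jitter = vj$jitter,
    n_interior_tiles = vj$n_interior,
    coverage_factor = cov,
    grid_connectivity = if (is.na(cov)) NA_integer_ else
      predicted_grid_connectivity(cov)
  )
  class(out) <- c("mosaic_stats", class(out))
  out
}
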