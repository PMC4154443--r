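#' Generator configuration for synthetic connectomes
#'
#' Study conditions for the synthetic connectome generator: the cell-class
#' census, AII mosaic geometry, morphology envelopes, and the contact count
#' and size distributions. Defaults emulate the annotated rabbit retinal
#' volume the package's analyses are designed for: a 0.243 mm circular
#' field with 39 AII cells (841 cells/mm^2, ~10% Voronoi jitter), 104 rod
#' bipolar cells expressing 31 +/- 3.9 ribbons each, an AII ribbon intake
#' regulated to 75.6 +/- 3, 525 homocellular (267 +/- 95 nm) and 172
#' heterocellular (238 +/- 95 nm) gap junctions, seven CBb7 cells each
#' making 1-3 ribbons and 2-7 gap junctions, and input area weights of 8:1
#' (ON amacrine : rod bipolar ribbon) and 1:3 (TH1 : coupling).
#'
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @param field_diameter_mm,section_thickness_nm,n_sections,ipl_top_z,ipl_bottom_z
#'   Volume calibration, see [volume_meta()].
#' @param census Named integer vector of cells per class.
#' @param aii_density_mm2 AII mosaic density, cells/mm^2.
#' @param jitter_frac Lattice jitter SD as a fraction of the tile spacing.
#' @param arboreal_span_um,lobule_reach_um,rod_input_field_um,rodbc_terminal_span_um
#'   Morphology envelopes, um.
#' @param ribbons_per_rodbc_mean,ribbons_per_rodbc_sd Ribbon output per rod
#'   bipolar cell (truncated normal, >= 1).
#' @param aii_ribbon_intake_mean,aii_ribbon_intake_sd Regulated per-AII
#'   ribbon intake distribution.
#' @param n_gj_homo,n_gj_hetero Gap junction counts (AII::AII, AII::CBb).
#' @param gj_homo_mean_nm,gj_homo_sd_nm,gj_hetero_mean_nm,gj_hetero_sd_nm,gj_trunc_nm
#'   Gap junction Feret diameter distributions (normal, truncated to
#'   `gj_trunc_nm`).
#' @param cbb7_ribbons_range,cbb7_gj_range Per-CBb7 contact count ranges.
#' @param offbc_ribbons_range OFF cone bipolar ribbon inputs per AII.
#' @param ac_on_per_aii_range,ac_off_per_aii_range Amacrine conventional
#'   inputs per AII (ON and OFF sublaminae).
#' @param th1_per_aii_range TH1 synapses per AII (neck).
#' @param out_bc_per_aii_range,out_ac_per_aii_range Lobular outputs per AII.
#' @param n_offgc_synapses,n_offgc_aii OFF alpha ganglion cell: total lobule
#'   synapses and number of distinct presynaptic AII cells.
#' @param n_gc_touches Non-synaptic arboreal touches with ganglion cells.
#' @param n_ai_adherens AII-AI adherens junctions (arboreal).
#' @param syn_diameter_mean_nm,syn_diameter_sd_nm Default chemical synapse
#'   Feret diameter distribution, nm.
#' @param ratio_on_ac_to_rodbc Target ON amacrine : rod bipolar input area
#'   ratio (calibrated by scaling ON amacrine synapse sizes).
#' @param ratio_th1_to_coupling Target TH1 : coupling input area ratio.
#' @param ratio_coupling_homo_hetero Homocellular : heterocellular coupling
#'   area ratio per AII endpoint implied by the junction counts and size
#'   distributions (recorded as planted truth; not separately calibrated).
#' @return Object of class `generator_config` (a named list).
#' @export
generator_config <- function(
    seed = 1,
    field_diameter_mm = 0.243,
    section_thickness_nm = 80,
    n_sections = 401,
    ipl_top_z = 60,
    ipl_bottom_z = 360,
    census = c(
      AII = 39, RodBC = 104,
      CBb3 = 40, CBb4w = 35, CBb5w = 35, `CBb4-5i` = 30, `CBb5-6i` = 33,
      CBb6 = 20, CBb7 = 7,
      CBa1 = 30, CBa2 = 30, CBa3 = 30, CBa4 = 30, CBa5 = 30, CBa6 = 30,
      TH1 = 4, AI = 8, gammaAC = 30, GAC = 20,
      `OFF-alpha-GC` = 1, `OFF-delta-GC` = 2),
    aii_density_mm2 = 841,
    jitter_frac = 0.10,
    arboreal_span_um = 70,
    lobule_reach_um = 15,
    rod_input_field_um = 60,
    rodbc_terminal_span_um = 25,
    ribbons_per_rodbc_mean = 31,
    ribbons_per_rodbc_sd = 3.9,
    aii_ribbon_intake_mean = 75.6,
    aii_ribbon_intake_sd = 3,
    n_gj_homo = 525,
    n_gj_hetero = 172,
    gj_homo_mean_nm = 267,
    gj_homo_sd_nm = 95,
    gj_hetero_mean_nm = 238,
    gj_hetero_sd_nm = 95,
    gj_trunc_nm = c(50, 800),
    cbb7_ribbons_range = c(1, 3),
    cbb7_gj_range = c(2, 7),
    offbc_ribbons_range = c(2, 5),
    ac_on_per_aii_range = c(40, 60),
    ac_off_per_aii_range = c(18, 25),
    th1_per_aii_range = c(1, 3),
    out_bc_per_aii_range = c(3, 6),
    out_ac_per_aii_range = c(5, 10),
    n_offgc_synapses = 23,
    n_offgc_aii = 12,
    n_gc_touches = 11,
    n_ai_adherens = 12,
    syn_diameter_mean_nm = 250,
    syn_diameter_sd_nm = 60,
    ratio_on_ac_to_rodbc = 8,
    ratio_th1_to_coupling = 1 / 3,
    ratio_coupling_homo_hetero = 7) {
  if (any(census < 0)) abort("census counts must be non-negative")
  if (any(gj_trunc_nm <= 0) || gj_trunc_nm[1] >= gj_trunc_nm[2]) {
    abort("gj_trunc_nm must be an increasing positive pair")
  }
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  seed %d, field %.3f mm, %g nm sections\n",
              x$seed, x$field_diameter_mm, x$section_thickness_nm))
  cat(sprintf("  census: %d cells in %d classes\n",
              sum(x$census), length(x$census)))
  invisible(x)
}

#' Write or read a generator configuration as JSON
#' @param config A `generator_config`.
#' @param path File path.
#' @return `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  out <- unclass(config)
  out$census <- as.list(out$census)  # keep class names as JSON keys
  jsonlite::write_json(out, path, pretty = TRUE, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$census <- unlist(raw$census)
  do.call(generator_config, raw)
}

# deterministic per-stage child seed below 2^31
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

# truncated normal via vectorised rejection
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a jittered-lattice AII soma mosaic
#'
#' Soma positions are laid on a square lattice at the spacing implied by the
#' configured density (`1/sqrt(density)`), jittered isotropically with SD
#' `jitter_frac` of the spacing, and clipped to the circular field. The
#' expected count equals density times field area.
#'
#' @param config A [generator_config()].
#' @return Tibble with `x_um`, `y_um`.
#' @export
generate_mosaic <- function(config) {
  set.seed(stage_seed(config$seed, 1))
  d_um <- config$field_diameter_mm * 1000
  r_um <- d_um / 2
  spacing <- tile_spacing(config$aii_density_mm2)
  # lattice covering the field, centred on the field centre
  k <- ceiling(r_um / spacing) + 1
  grid <- expand.grid(i = -k:k, j = -k:k)
  x <- r_um + grid$i * spacing
  y <- r_um + grid$j * spacing
  sdj <- config$jitter_frac * spacing
  x <- x + rnorm(length(x), 0, sdj)
  y <- y + rnorm(length(y), 0, sdj)
  keep <- (x - r_um)^2 + (y - r_um)^2 <= r_um^2
  tibble(x_um = x[keep], y_um = y[keep])
}

# uniform points in the circular field, um
runif_field <- function(n, field_diameter_mm) {
  r_um <- field_diameter_mm * 1000 / 2
  th <- runif(n, 0, 2 * pi)
  rr <- r_um * sqrt(runif(n))
  tibble(x_um = r_um + rr * cos(th), y_um = r_um + rr * sin(th))
}

#' Generate the cell inventory with compartment scaffolds
#'
#' Builds the cell table and one `cell`-kind structure per cell whose disc
#' stack sketches the class's stratification: AII cells get soma/neck discs
#' above the IPL, lobule discs in the OFF sublamina within the lobular
#' reach, waist discs, and an arboreal disc ring spanning the configured
#' arboreal field; bipolar cells get soma plus terminal discs at their
#' stratification depth; wide-field amacrine, axonal and ganglion cells get
#' coarse scaffolds. AII somas come from the mosaic; other classes are
#' placed uniformly (rod bipolar cells on their own jittered lattice).
#'
#' @param config A [generator_config()].
#' @param mosaic AII soma positions from [generate_mosaic()].
#' @return List with `cells`, `structures`, `discs` tibbles and `meta`.
#' @export
generate_cells <- function(config, mosaic) {
  set.seed(stage_seed(config$seed, 2))
  meta <- volume_meta(config$field_diameter_mm, config$section_thickness_nm,
                      config$n_sections, config$ipl_top_z, config$ipl_bottom_z)
  census <- config$census
  census[["AII"]] <- nrow(mosaic)
  classes <- names(census)[census > 0]
  if (length(classes) == 0) {
    return(list(
      cells = tibble(cell_id = integer(), cell_class = character(),
                     polarity = character(), transmitter = character(),
                     soma_x_nm = double(), soma_y_nm = double()),
      structures = tibble(structure_id = integer(), kind = character(),
                          parent_cell = integer()),
      discs = tibble(structure_id = integer(), z = integer(), x_nm = double(),
                     y_nm = double(), radius_nm = double()),
      meta = meta
    ))
  }

  # soma positions per class
  pos <- purrr::map(classes, function(cl) {
    n <- census[[cl]]
    if (cl == "AII") {
      mosaic
    } else if (cl == "RodBC") {
      # rod bipolar somas on their own jittered lattice
      dens <- n / (pi * (config$field_diameter_mm / 2)^2)
      sp <- tile_spacing(dens)
      d_um <- config$field_diameter_mm * 1000
      r_um <- d_um / 2
      k <- ceiling(r_um / sp) + 1
      grid <- expand.grid(i = -k:k, j = -k:k)
      x <- r_um + grid$i * sp + rnorm(nrow(grid), 0, 0.15 * sp)
      y <- r_um + grid$j * sp + rnorm(nrow(grid), 0, 0.15 * sp)
      keep <- which((x - r_um)^2 + (y - r_um)^2 <= r_um^2)
      # force the census count: sample or pad with uniform points
      if (length(keep) >= n) {
        keep <- sample(keep, n)
        tibble(x_um = x[keep], y_um = y[keep])
      } else {
        dplyr::bind_rows(tibble(x_um = x[keep], y_um = y[keep]),
                         runif_field(n - length(keep), config$field_diameter_mm))
      }
    } else {
      runif_field(n, config$field_diameter_mm)
    }
  })
  cells <- tibble(
    cell_class = rep(classes, times = purrr::map_int(pos, nrow)),
    soma_x_nm = unlist(purrr::map(pos, "x_um")) * 1e3,
    soma_y_nm = unlist(purrr::map(pos, "y_um")) * 1e3
  ) |>
    mutate(
      cell_id = dplyr::row_number(),
      polarity = class_polarity(.data$cell_class),
      transmitter = class_transmitter(.data$cell_class)
    ) |>
    select("cell_id", "cell_class", "polarity", "transmitter",
           "soma_x_nm", "soma_y_nm")

  structures <- tibble(
    structure_id = cells$cell_id,
    kind = "cell",
    parent_cell = cells$cell_id
  )

  discs <- purrr::pmap(
    list(cells$cell_id, cells$cell_class, cells$soma_x_nm, cells$soma_y_nm),
    function(id, cl, sx, sy) scaffold_discs(id, cl, sx, sy, config, meta)
  ) |> list_rbind()

  list(cells = cells, structures = structures, discs = discs, meta = meta)
}

# per-cell scaffold disc stack; depths are converted to integer sections
scaffold_discs <- function(id, cl, sx, sy, config, meta) {
  zd <- function(depth) as.integer(round(depth_to_z(depth, meta)))
  ring <- function(n, radius_um, depth_lo, depth_hi, r_nm) {
    th <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    tibble(
      z = zd(runif(n, depth_lo, depth_hi)),
      x_nm = sx + radius_um * 1e3 * cos(th),
      y_nm = sy + radius_um * 1e3 * sin(th),
      radius_nm = r_nm
    )
  }
  scatter <- function(n, reach_um, depth_lo, depth_hi, r_nm) {
    th <- runif(n, 0, 2 * pi)
    rr <- reach_um * 1e3 * sqrt(runif(n))
    tibble(
      z = zd(runif(n, depth_lo, depth_hi)),
      x_nm = sx + rr * cos(th),
      y_nm = sy + rr * sin(th),
      radius_nm = r_nm
    )
  }
  soma <- function(depth, r_nm) {
    tibble(z = zd(depth), x_nm = sx, y_nm = sy, radius_nm = r_nm)
  }
  sup <- class_superclass(cl)
  d <- if (cl == "AII") {
    dplyr::bind_rows(
      soma(-3, 4500),                       # soma above the IPL
      soma(-1.5, 600), soma(-0.5, 600),     # neck
      scatter(6, config$lobule_reach_um, 1, 9, 1200),    # lobules
      soma(11, 700), soma(13, 700),         # waist
      ring(8, config$arboreal_span_um / 2, 16, 24, 500), # arboreal rim
      scatter(12, config$arboreal_span_um / 2, 16, 24, 500)
    )
  } else if (cl == "RodBC") {
    dplyr::bind_rows(
      soma(-5, 3000),
      scatter(5, config$rodbc_terminal_span_um / 2, 20, 24, 1000)
    )
  } else if (sup == "CBa") {
    dplyr::bind_rows(soma(-5, 3000), scatter(3, 15, 2, 8, 800))
  } else if (cl == "CBb7") {
    dplyr::bind_rows(soma(-5, 3500), scatter(4, 60, 16, 22, 800))
  } else if (sup == "CBb") {
    dplyr::bind_rows(soma(-5, 3000), scatter(3, 20, 12, 22, 800))
  } else if (cl == "TH1") {
    dplyr::bind_rows(soma(-5, 4000), scatter(6, 100, 0, 2, 400))
  } else if (sup == "GC") {
    dplyr::bind_rows(soma(28, 6000), scatter(6, 80, 2, 8, 900))
  } else {
    # wide-field amacrine classes
    dplyr::bind_rows(soma(-4, 4000), scatter(6, 60, 2, 22, 500))
  }
  d$structure_id <- id
  select(d, "structure_id", "z", "x_nm", "y_nm", "radius_nm")
}

#' Slice an intended structure into per-section disc annotations
#'
#' Converts an intended Feret diameter into a per-slice disc stack with a
#' circular chord profile: an odd number of slices `2*floor(d/2t)+1`
#' centred on `z_center`, with the central slice carrying the full Feret
#' diameter. The stack's maximum diameter therefore equals the intended
#' Feret diameter exactly, and its diameter-times-thickness sum (the
#' contact area convention of [structure_area()]) approximates the area of
#' a circular junction of that diameter.
#'
#' @param diameter_nm Intended Feret diameter (> 0).
#' @param z_center Central section index.
#' @param meta A [volume_meta()].
#' @param n_slices Optional odd slice count; by default the slice count is
#'   chosen from the diameter and section thickness.
#' @return Tibble with `z`, `radius_nm` (one row per slice).
#' @export
slice_structure <- function(diameter_nm, z_center, meta, n_slices = NULL) {
  if (diameter_nm <= 0) abort("intended diameter must be positive")
  t_nm <- meta$section_thickness_nm
  half <- if (is.null(n_slices)) {
    floor(diameter_nm / (2 * t_nm))
  } else {
    if (n_slices < 1 || n_slices %% 2 == 0) abort("n_slices must be odd and >= 1")
    (n_slices - 1) / 2
  }
  u <- (-half:half) * t_nm
  chord <- diameter_nm * sqrt(pmax(0, 1 - (2 * u / diameter_nm)^2))
  chord[half + 1] <- diameter_nm  # central slice carries the Feret diameter
  z <- as.integer(round(z_center)) + (-half:half)
  z <- pmin(pmax(z, 0L), meta$n_sections - 1L)
  filter(tibble(z = z, radius_nm = chord / 2), .data$radius_nm > 0)
}

# vectorised slicing of many structures: returns a disc tibble keyed by
# `plan_row`, plus per-row realised area
slice_many <- function(diameter_nm, z_center, x_nm, y_nm, meta) {
  t_nm <- meta$section_thickness_nm
  half <- floor(diameter_nm / (2 * t_nm))
  m <- 2 * half + 1
  row <- rep(seq_along(diameter_nm), times = m)
  offs <- unlist(purrr::map(half, function(h) -h:h))
  d <- diameter_nm[row]
  u <- offs * t_nm
  chord <- d * sqrt(pmax(0, 1 - (2 * u / d)^2))
  chord[offs == 0] <- d[offs == 0]
  filter(
    tibble(
      plan_row = row,
      z = pmin(pmax(as.integer(round(z_center[row])) + offs, 0L),
               meta$n_sections - 1L),
      x_nm = x_nm[row],
      y_nm = y_nm[row],
      radius_nm = chord / 2
    ),
    .data$radius_nm > 0
  )
}
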