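#' Feret diameter of a child structure
#'
#' Each per-slice annotation of a child structure records the Feret (maximum
#' caliper) diameter of its profile as a disc; the structure's Feret diameter
#' is the maximum over its slices.
#'
#' @param discs Disc tibble for a single structure (columns `radius_nm`, one
#'   row per slice).
#' @return Feret diameter in nm.
#' @export
#' @examples
#' feret_diameter(tibble::tibble(radius_nm = c(100, 250, 180)))  # 500
feret_diameter <- function(discs) {
  if (nrow(discs) == 0) abort("structure has no discs")
  max(2 * discs$radius_nm)
}

#' Membrane contact area of a child structure
#'
#' Per-slice Feret-diameter discs, summed over slices, give the structure's
#' contact area: each slice contributes its Feret diameter times the section
#' thickness. This treats the annotation stack as a planar profile through
#' the junction; for a roughly circular junction sliced through its centre
#' the chord sum converges to the true disc area (pi/4 d^2).
#'
#' @param discs Disc tibble for a single structure.
#' @param section_thickness_nm Section thickness, nm.
#' @return Area in square micrometres.
#' @export
#' @examples
#' structure_area(tibble::tibble(radius_nm = 250), 80)  # 0.04 um^2
structure_area <- function(discs, section_thickness_nm) {
  if (nrow(discs) == 0) abort("structure has no discs")
  if (any(discs$radius_nm <= 0)) abort("zero or negative disc radius")
  sum(2 * discs$radius_nm * section_thickness_nm) / NM2_PER_UM2
}

#' Per-structure size measures for a whole database
#'
#' Vectorised Feret diameter, contact area, mean position and area-weighted
#' mean IPL depth for every child structure (cells are excluded: a whole-cell
#' Feret diameter is not defined).
#'
#' @param db An [annotation_db()].
#' @return Tibble with one row per non-cell structure: `structure_id`,
#'   `kind`, `parent_cell`, `feret_nm`, `area_um2`, `x_nm`, `y_nm`, `depth`.
#' @export
structure_measures <- function(db) {
  t_nm <- db$meta$section_thickness_nm
  child <- filter(db$structures, .data$kind != "cell")
  discs <- semi_join(db$discs, child, by = "structure_id")
  measures <- discs |>
    mutate(slice_area = 2 * .data$radius_nm * t_nm) |>
    group_by(.data$structure_id) |>
    summarise(
      feret_nm = max(2 * .data$radius_nm),
      area_um2 = sum(.data$slice_area) / NM2_PER_UM2,
      x_nm = sum(.data$x_nm * .data$slice_area) / sum(.data$slice_area),
      y_nm = sum(.data$y_nm * .data$slice_area) / sum(.data$slice_area),
      mean_z = sum(.data$z * .data$slice_area) / sum(.data$slice_area),
      .groups = "drop"
    ) |>
    mutate(depth = ipl_depth(.data$mean_z, db$meta)) |>
    select(-"mean_z")
  left_join(child, measures, by = "structure_id")
}

#' Normalized IPL depth of a section index
#'
#' Linear map of section index to the normalized inner-plexiform-layer depth
#' scale, where 0 is the amacrine cell layer border and 25 the ganglion cell
#' layer border. Values outside `[0, 25]` are permitted (somas and necks sit
#' above the IPL).
#'
#' @param z Section index (vectorised).
#' @param meta A [volume_meta()].
#' @return Depth in IPL depth units.
#' @export
ipl_depth <- function(z, meta) {
  25 * (z - meta$ipl_top_z) / (meta$ipl_bottom_z - meta$ipl_top_z)
}

#' Inverse of [ipl_depth()]: section index at a given depth
#' @param depth IPL depth units.
#' @param meta A [volume_meta()].
#' @return Fractional section index.
#' @export
depth_to_z <- function(depth, meta) {
  meta$ipl_top_z + depth / 25 * (meta$ipl_bottom_z - meta$ipl_top_z)
}

#' AII compartment at a given IPL depth
#'
#' The AII amacrine cell is multistratified with depth-segregated
#' compartments: the neck above the IPL, vesicle-rich lobules in the OFF
#' sublamina (depth 0-10), the waist (10-15), and the arboreal dendrites in
#' the ON sublamina (15 and deeper). The OFF/ON sublamina border is fixed at
#' depth 10 (40% depth).
#'
#' @param depth IPL depth units (vectorised).
#' @return Character vector: `"neck"`, `"lobule"`, `"waist"` or `"arboreal"`.
#' @export
#' @examples
#' assign_compartment(c(-2, 5, 12, 20))
assign_compartment <- function(depth) {
  dplyr::case_when(
    depth < 0 ~ "neck",
    depth < 10 ~ "lobule",
    depth < 15 ~ "waist",
    TRUE ~ "arboreal"
  )
}

#' Is a depth in the OFF or ON sublamina?
#' @param depth IPL depth units.
#' @return `"OFF"` for depth < 10, else `"ON"`.
#' @export
sublamina <- function(depth) ifelse(depth < 10, "OFF", "ON")

# Map a (pre_class, post_class, kind, depth) combination to the signal-flow
# category used for partner maps and depth profiles.
contact_category <- function(pre_class, post_class, kind, depth) {
  pre_sup <- class_superclass(pre_class)
  post_sup <- class_superclass(post_class)
  dplyr::case_when(
    kind == "gap_junction" & pre_class == "AII" & post_class == "AII" ~ "coupling_AII_AII",
    kind == "gap_junction" &
      ((pre_class == "AII" & pre_sup != post_sup & post_sup %in% c("CBb", "CBb7")) |
         (post_class == "AII" & pre_sup %in% c("CBb", "CBb7"))) ~ "coupling_AII_CBb",
    kind == "ribbon_input" & pre_class == "RodBC" & post_class == "AII" ~ "rodBC_input",
    kind == "ribbon_input" & pre_sup == "CBa" & post_class == "AII" ~ "OFF_BC_input",
    kind == "ribbon_input" & pre_class == "CBb7" & post_class == "AII" ~ "CBb7_ribbon_input",
    kind == "ribbon_input" & pre_sup == "CBb" & post_class == "AII" ~ "CBb_ribbon_input",
    kind == "conventional_synapse" & pre_class == "TH1" & post_class == "AII" ~ "TH1_input",
    kind == "conventional_synapse" & pre_sup == "AC" & pre_class != "AII" &
      post_class == "AII" & depth >= 10 ~ "AC_input_ON",
    kind == "conventional_synapse" & pre_sup == "AC" & pre_class != "AII" &
      post_class == "AII" & depth < 10 ~ "AC_input_OFF",
    kind == "conventional_synapse" & pre_class == "AII" & post_sup %in% c("CBa", "CBb", "CBb7", "BC") ~ "output_BC",
    kind == "conventional_synapse" & pre_class == "AII" & post_sup == "AC" ~ "output_AC",
    kind == "conventional_synapse" & pre_class == "AII" & post_sup == "GC" ~ "output_GC",
    kind %in% c("adherens", "touch") ~ "non_synaptic",
    TRUE ~ "other"
  )
}

#' Resolve linked child structures into contact pairs
#'
#' Joins the link relation to structure kinds and parents to produce one
#' contact per presynapse-PSD link and per gap junction / adherens / touch
#' link. The two linked annotations trace the same membrane apposition, so
#' the contact takes the mean of their areas, the larger of their Feret
#' diameters, and the area-weighted mean depth over both disc stacks.
#' Signal-flow categories (rod bipolar input, coupling, outputs, ...) are
#' assigned from the two cell classes, the contact kind and the depth.
#'
#' @param db An [annotation_db()].
#' @return Tibble with one row per contact: `pre_cell`, `post_cell`,
#'   `pre_class`, `post_class`, `kind`, `category`, `pre_structure`,
#'   `post_structure`, `area_um2`, `diameter_nm`, `depth`, `pre_compartment`,
#'   `post_compartment`.
#' @export
resolve_contacts <- function(db) {
  if (nrow(db$links) == 0) {
    return(tibble(
      pre_cell = integer(), post_cell = integer(), pre_class = character(),
      post_class = character(), kind = character(), category = character(),
      pre_structure = integer(), post_structure = integer(),
      area_um2 = double(), diameter_nm = double(), depth = double(),
      pre_compartment = character(), post_compartment = character()
    ))
  }
  meas <- structure_measures(db)
  skind <- setNames(db$structures$kind, as.character(db$structures$structure_id))
  sparent <- setNames(db$structures$parent_cell, as.character(db$structures$structure_id))
  cls <- setNames(db$cells$cell_class, as.character(db$cells$cell_id))

  lk <- db$links |>
    mutate(
      kind_a = unname(skind[as.character(.data$structure_id)]),
      kind_b = unname(skind[as.character(.data$linked_id)])
    )

  presyn_kinds <- c("ribbon_presyn", "conventional_presyn")
  both_pre <- lk$kind_a %in% presyn_kinds & lk$kind_b %in% presyn_kinds
  if (any(both_pre)) {
    abort(sprintf("malformed link: two presynaptic structures linked (%d-%d)",
                  lk$structure_id[which(both_pre)[1]], lk$linked_id[which(both_pre)[1]]))
  }
  sym_kinds <- c("gap_junction", "adherens", "touch")
  mismatched_sym <- (lk$kind_a %in% sym_kinds | lk$kind_b %in% sym_kinds) &
    lk$kind_a != lk$kind_b
  if (any(mismatched_sym)) {
    abort(sprintf("malformed link: %s linked to %s",
                  lk$kind_a[which(mismatched_sym)[1]], lk$kind_b[which(mismatched_sym)[1]]))
  }
  bad_syn <- (lk$kind_a %in% presyn_kinds & lk$kind_b != "psd") |
    (lk$kind_b %in% presyn_kinds & lk$kind_a != "psd")
  if (any(bad_syn)) {
    abort(sprintf("malformed link: presynapse linked to %s",
                  ifelse(lk$kind_a[which(bad_syn)[1]] %in% presyn_kinds,
                         lk$kind_b[which(bad_syn)[1]], lk$kind_a[which(bad_syn)[1]])))
  }

  # orient: presynaptic structure (or smaller id for symmetric kinds) first
  a_is_pre <- lk$kind_a %in% presyn_kinds |
    (lk$kind_a %in% sym_kinds & lk$structure_id <= lk$linked_id)
  lk <- lk |>
    mutate(
      pre_structure = ifelse(a_is_pre, .data$structure_id, .data$linked_id),
      post_structure = ifelse(a_is_pre, .data$linked_id, .data$structure_id),
      pre_kind = unname(skind[as.character(.data$pre_structure)])
    )

  m_pre <- meas |>
    select("structure_id", pre_area = "area_um2", pre_feret = "feret_nm",
           pre_depth = "depth")
  m_post <- meas |>
    select("structure_id", post_area = "area_um2", post_feret = "feret_nm",
           post_depth = "depth")

  out <- lk |>
    left_join(m_pre, by = c(pre_structure = "structure_id")) |>
    left_join(m_post, by = c(post_structure = "structure_id")) |>
    mutate(
      pre_cell = unname(sparent[as.character(.data$pre_structure)]),
      post_cell = unname(sparent[as.character(.data$post_structure)]),
      pre_class = unname(cls[as.character(.data$pre_cell)]),
      post_class = unname(cls[as.character(.data$post_cell)]),
      kind = dplyr::case_when(
        .data$pre_kind == "ribbon_presyn" ~ "ribbon_input",
        .data$pre_kind == "conventional_presyn" ~ "conventional_synapse",
        TRUE ~ .data$pre_kind
      ),
      area_um2 = ifelse(is.na(.data$post_area), .data$pre_area,
                        (.data$pre_area + .data$post_area) / 2),
      diameter_nm = pmax(.data$pre_feret, .data$post_feret, na.rm = TRUE),
      depth = ifelse(is.na(.data$post_depth), .data$pre_depth,
                     (.data$pre_depth + .data$post_depth) / 2),
      category = contact_category(.data$pre_class, .data$post_class,
                                  .data$kind, .data$depth),
      pre_compartment = assign_compartment(.data$depth),
      post_compartment = assign_compartment(.data$depth)
    ) |>
    select("pre_cell", "post_cell", "pre_class", "post_class", "kind",
           "category", "pre_structure", "post_structure", "area_um2",
           "diameter_nm", "depth", "pre_compartment", "post_compartment")
  out
}

#' Depth-stratified contact area profile
#'
#' Bins contact areas into unit-width, half-open IPL depth bins `[i, i+1)`,
#' per signal-flow category. The bin range spans `[-5, 30)` so that contacts
#' above the IPL (neck) and at its lower margin are conserved; the core of
#' the profile lies in `[0, 25)`. The summed profile equals the summed
#' contact area exactly.
#'
#' @param contacts Contact tibble from [resolve_contacts()].
#' @param categories Optional character vector restricting the categories
#'   profiled; default: all categories present.
#' @return A tibble of class `depth_profile`: `category`, `bin_lo`,
#'   `bin_hi`, `area_um2`.
#' @export
depth_profile <- function(contacts, categories = NULL) {
  if (is.null(categories)) {
    categories <- sort(unique(contacts$category))
  }
  edges <- -5:29
  grid <- tidyr::expand_grid(category = categories, bin_lo = edges) |>
    mutate(bin_hi = .data$bin_lo + 1)
  binned <- contacts |>
    filter(.data$category %in% categories) |>
    mutate(bin_lo = pmin(pmax(floor(.data$depth), -5), 29)) |>
    group_by(.data$category, .data$bin_lo) |>
    summarise(area_um2 = sum(.data$area_um2), .groups = "drop")
  out <- grid |>
    left_join(binned, by = c("category", "bin_lo")) |>
    mutate(area_um2 = ifelse(is.na(.data$area_um2), 0, .data$area_um2)) |>
    arrange(.data$category, .data$bin_lo)
  class(out) <- c("depth_profile", class(out))
  out
}

#' Lateral extent of a stratified zone, per cell and summarised
#'
#' For each cell, takes the XY-projected discs of its cell scaffold falling
#' in the requested compartment and measures the maximum pairwise distance
#' (the zone's lateral extent). Extents are summarised as mean and sample SD
#' across cells (SD reported as 0 with a flag when only one cell is given).
#'
#' @param db An [annotation_db()].
#' @param cell_ids Cells to measure.
#' @param zone `"neck"`, `"lobule"`, `"waist"` or `"arboreal"`.
#' @return List with `per_cell` (tibble: `cell_id`, `extent_um`, `n_discs`),
#'   `mean_um`, `sd_um`, `n`, and `single_cell` flag.
#' @export
lateral_spread <- function(db, cell_ids, zone) {
  if (length(cell_ids) < 1) abort("need at least one cell")
  cell_structs <- db$structures |>
    filter(.data$kind == "cell", .data$parent_cell %in% cell_ids)
  discs <- db$discs |>
    semi_join(cell_structs, by = "structure_id") |>
    left_join(select(cell_structs, "structure_id", "parent_cell"),
              by = "structure_id") |>
    mutate(depth = ipl_depth(.data$z, db$meta)) |>
    filter(assign_compartment(.data$depth) == zone)
  per_cell <- discs |>
    group_by(cell_id = .data$parent_cell) |>
    summarise(
      extent_um = if (dplyr::n() < 2) 0 else
        max(dist(cbind(.data$x_nm, .data$y_nm))) / 1e3,
      n_discs = dplyr::n(),
      .groups = "drop"
    )
  n <- nrow(per_cell)
  list(
    per_cell = per_cell,
    mean_um = if (n > 0) mean(per_cell$extent_um) else NA_real_,
    sd_um = if (n > 1) sd(per_cell$extent_um) else 0,
    n = n,
    single_cell = n == 1
  )
}

# polygon area by the shoelace formula; vertices in order
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Convex hull of a cell's zone field
#'
#' The planar field covered by a cell's processes in one compartment,
#' summarised as the convex hull of its XY disc centres.
#'
#' @param db An [annotation_db()].
#' @param cell_id Cell to measure.
#' @param zone Compartment name.
#' @return List with `polygon` (tibble `x_um`, `y_um`, hull vertices in
#'   order) and `area_um2`.
#' @export
convex_hull_field <- function(db, cell_id, zone) {
  cell_structs <- db$structures |>
    filter(.data$kind == "cell", .data$parent_cell == cell_id)
  discs <- db$discs |>
    semi_join(cell_structs, by = "structure_id") |>
    mutate(depth = ipl_depth(.data$z, db$meta)) |>
    filter(assign_compartment(.data$depth) == zone)
  pts <- unique(cbind(discs$x_nm, discs$y_nm)) / 1e3
  if (nrow(pts) < 3) abort("degenerate hull: fewer than 3 distinct points in zone")
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(idx) < 3) abort("degenerate hull: points are collinear")
  poly <- tibble(x_um = pts[idx, 1], y_um = pts[idx, 2])
  list(polygon = poly, area_um2 = shoelace_area(poly$x_um, poly$y_um))
}
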