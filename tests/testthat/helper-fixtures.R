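# Shared fixtures: small hand-built annotation databases and a cached
# default synthetic connectome (generating the full volume takes a few
# seconds, so it is built once per test run).

.cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.cache$bundle)) {
    .cache$bundle <- run_connectome(generator_config(seed = 1))
  }
  .cache$bundle
}

test_meta <- function(thickness = 80) {
  volume_meta(field_diameter_mm = 0.243, section_thickness_nm = thickness,
              n_sections = 401, ipl_top_z = 60, ipl_bottom_z = 360)
}

# Build a small annotation db from a cell table and a contact table.
# `cells`: tibble(cell_id, cell_class) (+ optional soma coords).
# `contacts`: tibble(pre_cell, post_cell, pre_kind, post_kind, depth,
#             diameter_nm) one row per contact; each side gets a one-slice
#             disc at the contact position.
build_db <- function(cells, contacts, meta = test_meta()) {
  cells <- dplyr::mutate(
    cells,
    polarity = aiinet::cell_class_table()$polarity[
      match(cell_class, aiinet::cell_class_table()$cell_class)],
    transmitter = aiinet::cell_class_table()$transmitter[
      match(cell_class, aiinet::cell_class_table()$cell_class)],
    soma_x_nm = if ("soma_x_nm" %in% names(cells)) soma_x_nm else
      100000 + 10000 * seq_len(nrow(cells)),
    soma_y_nm = if ("soma_y_nm" %in% names(cells)) soma_y_nm else
      100000
  )
  cell_structs <- tibble::tibble(
    structure_id = cells$cell_id, kind = "cell", parent_cell = cells$cell_id)
  cell_discs <- tibble::tibble(
    structure_id = cells$cell_id, z = 100L,
    x_nm = cells$soma_x_nm, y_nm = cells$soma_y_nm, radius_nm = 4000)

  id0 <- if (nrow(cells) > 0) max(cells$cell_id) + 100L else 100L
  n <- nrow(contacts)
  if (n > 0) {
    contacts$pre_structure <- id0 + seq_len(n)
    contacts$post_structure <- id0 + n + seq_len(n)
    z <- as.integer(round(depth_to_z(contacts$depth, meta)))
    x <- if ("x_nm" %in% names(contacts)) contacts$x_nm else
      cells$soma_x_nm[match(contacts$pre_cell, cells$cell_id)]
    y <- if ("y_nm" %in% names(contacts)) contacts$y_nm else
      cells$soma_y_nm[match(contacts$pre_cell, cells$cell_id)]
    child_structs <- dplyr::bind_rows(
      tibble::tibble(structure_id = contacts$pre_structure,
                     kind = contacts$pre_kind, parent_cell = contacts$pre_cell),
      tibble::tibble(structure_id = contacts$post_structure,
                     kind = contacts$post_kind, parent_cell = contacts$post_cell))
    child_discs <- dplyr::bind_rows(
      tibble::tibble(structure_id = contacts$pre_structure, z = z,
                     x_nm = x, y_nm = y, radius_nm = contacts$diameter_nm / 2),
      tibble::tibble(structure_id = contacts$post_structure, z = z,
                     x_nm = x, y_nm = y, radius_nm = contacts$diameter_nm / 2))
    links <- tibble::tibble(structure_id = contacts$pre_structure,
                            linked_id = contacts$post_structure)
  } else {
    child_structs <- cell_structs[0, ]
    child_discs <- cell_discs[0, ]
    links <- tibble::tibble(structure_id = integer(), linked_id = integer())
  }
  annotation_db(meta, cells,
                dplyr::bind_rows(cell_structs, child_structs),
                dplyr::bind_rows(cell_discs, child_discs),
                links)
}

# append one extra linked contact (pair of child structures) to a db
inject_contact <- function(db, pre_cell, post_cell, pre_kind, post_kind,
                           depth, diameter_nm = 300) {
  id0 <- max(db$structures$structure_id)
  z <- as.integer(round(depth_to_z(depth, db$meta)))
  x <- db$cells$soma_x_nm[match(pre_cell, db$cells$cell_id)]
  y <- db$cells$soma_y_nm[match(pre_cell, db$cells$cell_id)]
  db$structures <- dplyr::bind_rows(
    db$structures,
    tibble::tibble(structure_id = id0 + 1:2, kind = c(pre_kind, post_kind),
                   parent_cell = c(pre_cell, post_cell)))
  db$discs <- dplyr::bind_rows(
    db$discs,
    tibble::tibble(structure_id = rep(id0 + 1:2, each = 1), z = z,
                   x_nm = x, y_nm = y, radius_nm = diameter_nm / 2))
  db$links <- dplyr::bind_rows(
    db$links, tibble::tibble(structure_id = id0 + 1L, linked_id = id0 + 2L))
  validate_db(db)
  db
}

# random small annotation db for round-trip property tests
random_db <- function(seed) {
  set.seed(seed)
  classes <- sample(c("AII", "RodBC", "CBb3", "CBa1", "gammaAC"), 6,
                    replace = TRUE)
  cells <- tibble::tibble(
    cell_id = 1:6, cell_class = classes,
    soma_x_nm = runif(6, 0, 243000), soma_y_nm = runif(6, 0, 243000))
  contacts <- tibble::tibble(
    pre_cell = sample(1:6, 8, replace = TRUE),
    post_cell = sample(1:6, 8, replace = TRUE),
    pre_kind = "conventional_presyn", post_kind = "psd",
    depth = runif(8, 1, 24), diameter_nm = runif(8, 100, 600))
  build_db(cells, contacts)
}
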