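#' Volume metadata
#'
#' Calibration of an annotated serial-section volume: physical field size,
#' nominal section thickness, and the section indices that anchor the
#' normalized inner-plexiform-layer (IPL) depth scale. Depth 0 corresponds to
#' the amacrine cell layer side of the IPL and depth 25 to the ganglion cell
#' layer side; structures above the IPL (somas, necks) map to negative depth.
#'
#' @param field_diameter_mm Diameter of the circular sample field, mm.
#' @param section_thickness_nm Nominal section thickness, nm; must lie in
#'   the 70-90 nm range typical of serial-section TEM volumes.
#' @param n_sections Number of sections in the volume.
#' @param ipl_top_z,ipl_bottom_z Section indices of the IPL borders
#'   (`ipl_top_z` = amacrine cell layer side, depth 0; `ipl_bottom_z` =
#'   ganglion cell layer side, depth 25).
#' @param pixel_size_nm Image pixel size, nm (metadata only).
#' @return An object of class `volume_meta`.
#' @export
#' @examples
#' volume_meta()
volume_meta <- function(field_diameter_mm = 0.243,
                        section_thickness_nm = 80,
                        n_sections = 401,
                        ipl_top_z = 60,
                        ipl_bottom_z = 360,
                        pixel_size_nm = 2.18) {
  if (!is.numeric(field_diameter_mm) || field_diameter_mm <= 0) {
    abort("`field_diameter_mm` must be a positive number.")
  }
  if (section_thickness_nm < 70 || section_thickness_nm > 90) {
    abort("`section_thickness_nm` must lie in [70, 90] nm.")
  }
  if (ipl_top_z >= ipl_bottom_z) {
    abort("`ipl_top_z` must be smaller than `ipl_bottom_z`.")
  }
  structure(
    list(
      field_diameter_mm = field_diameter_mm,
      section_thickness_nm = section_thickness_nm,
      n_sections = as.integer(n_sections),
      ipl_top_z = ipl_top_z,
      ipl_bottom_z = ipl_bottom_z,
      pixel_size_nm = pixel_size_nm
    ),
    class = "volume_meta"
  )
}

#' @export
print.volume_meta <- function(x, ...) {
  cat("<volume_meta>\n")
  cat(sprintf("  field diameter : %.3f mm\n", x$field_diameter_mm))
  cat(sprintf("  sections       : %d x %g nm\n", x$n_sections, x$section_thickness_nm))
  cat(sprintf("  IPL calibration: z %g (depth 0) .. z %g (depth 25)\n",
              x$ipl_top_z, x$ipl_bottom_z))
  invisible(x)
}

STRUCTURE_KINDS <- c("cell", "ribbon_presyn", "conventional_presyn", "psd",
                     "gap_junction", "adherens", "touch")

#' Assemble an annotation database
#'
#' Bundles the relational tables of a disc-annotated connectome volume:
#' cells, structures (cells and their child specializations), per-slice disc
#' annotations, and links between child structures (presynapse to
#' postsynaptic density, gap junction to gap junction, touch to touch).
#' Referential integrity is checked on construction.
#'
#' @param meta A [volume_meta()].
#' @param cells Tibble with columns `cell_id`, `cell_class`, `polarity`,
#'   `transmitter`, `soma_x_nm`, `soma_y_nm`.
#' @param structures Tibble with columns `structure_id`, `kind`,
#'   `parent_cell`.
#' @param discs Tibble with columns `structure_id`, `z`, `x_nm`, `y_nm`,
#'   `radius_nm`.
#' @param links Tibble with columns `structure_id`, `linked_id`; symmetric
#'   links (gap junctions, adherens, touches) are stored once with the
#'   smaller id first.
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(meta, cells, structures, discs, links) {
  db <- structure(
    list(
      meta = meta,
      cells = as_tibble(cells),
      structures = as_tibble(structures),
      discs = as_tibble(discs),
      links = as_tibble(links)
    ),
    class = "annotation_db"
  )
  validate_db(db)
  db
}

#' Validate referential integrity of an annotation database
#'
#' Checks that every structure's parent cell exists, every disc belongs to a
#' known structure, every link endpoint resolves, structure ids are unique,
#' all non-touch structures carry at least one disc, and structure kinds are
#' drawn from the recognised vocabulary.
#'
#' @param db An [annotation_db()].
#' @return `db`, invisibly; aborts with an informative message on the first
#'   integrity failure.
#' @export
validate_db <- function(db) {
  need <- function(tbl, cols, name) {
    missing <- setdiff(cols, names(tbl))
    if (length(missing) > 0) {
      abort(sprintf("table `%s` is missing column(s): %s",
                    name, paste(missing, collapse = ", ")))
    }
  }
  need(db$cells, c("cell_id", "cell_class", "polarity", "transmitter",
                   "soma_x_nm", "soma_y_nm"), "cells")
  need(db$structures, c("structure_id", "kind", "parent_cell"), "structures")
  need(db$discs, c("structure_id", "z", "x_nm", "y_nm", "radius_nm"), "discs")
  need(db$links, c("structure_id", "linked_id"), "links")

  dup <- db$structures$structure_id[duplicated(db$structures$structure_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate structure_id: %s", paste(head(dup, 5), collapse = ", ")))
  }
  dup <- db$cells$cell_id[duplicated(db$cells$cell_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate cell_id: %s", paste(head(dup, 5), collapse = ", ")))
  }
  bad_kind <- setdiff(unique(db$structures$kind), STRUCTURE_KINDS)
  if (length(bad_kind) > 0) {
    abort(sprintf("unknown structure kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  orphan <- setdiff(db$structures$parent_cell, db$cells$cell_id)
  if (length(orphan) > 0) {
    abort(sprintf("structure parent_cell not in cells: %s",
                  paste(head(orphan, 5), collapse = ", ")))
  }
  orphan <- setdiff(db$discs$structure_id, db$structures$structure_id)
  if (length(orphan) > 0) {
    abort(sprintf("disc references unknown structure_id: %s",
                  paste(head(orphan, 5), collapse = ", ")))
  }
  dangling <- setdiff(c(db$links$structure_id, db$links$linked_id),
                      db$structures$structure_id)
  if (length(dangling) > 0) {
    abort(sprintf("dangling link reference: %s",
                  paste(head(dangling, 5), collapse = ", ")))
  }
  if (any(db$discs$radius_nm <= 0)) {
    abort("disc radius_nm must be positive")
  }
  # every non-touch structure needs at least one disc
  has_disc <- db$structures$structure_id %in% db$discs$structure_id
  bare <- db$structures$structure_id[!has_disc & db$structures$kind != "touch"]
  if (length(bare) > 0) {
    abort(sprintf("structure without discs: %s", paste(head(bare, 5), collapse = ", ")))
  }
  invisible(db)
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db>\n")
  cat(sprintf("  %d cells, %d structures, %d discs, %d links\n",
              nrow(x$cells), nrow(x$structures), nrow(x$discs), nrow(x$links)))
  census <- dplyr::count(x$cells, .data$cell_class, sort = TRUE)
  cat("  cell census: ",
      paste(sprintf("%s=%d", census$cell_class, census$n), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

db_file_names <- c(meta = "meta.tsv", cells = "cells.tsv",
                   structures = "structures.tsv", discs = "discs.tsv",
                   links = "links.tsv")

#' Write an annotation database to tab-separated tables
#'
#' Writes the five-table on-disk representation (`meta.tsv`, `cells.tsv`,
#' `structures.tsv`, `discs.tsv`, `links.tsv`) with deterministic row
#' ordering (by id), so repeated writes of the same database are
#' byte-identical.
#'
#' @param db An [annotation_db()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_db <- function(db, dir) {
  validate_db(db)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta_tbl <- tibble(
    key = c("field_diameter_mm", "section_thickness_nm", "n_sections",
            "ipl_top_z", "ipl_bottom_z", "pixel_size_nm"),
    value = as.character(c(db$meta$field_diameter_mm, db$meta$section_thickness_nm,
                           db$meta$n_sections, db$meta$ipl_top_z,
                           db$meta$ipl_bottom_z, db$meta$pixel_size_nm))
  )
  # doubles written at 17 significant digits so load_db(write_db(db)) is
  # bit-exact
  fmt <- function(tbl) mutate(tbl, across(dplyr::where(is.double),
                                          ~ sprintf("%.17g", .x)))
  readr::write_tsv(meta_tbl, file.path(dir, "meta.tsv"))
  readr::write_tsv(fmt(arrange(db$cells, .data$cell_id)),
                   file.path(dir, "cells.tsv"))
  readr::write_tsv(arrange(db$structures, .data$structure_id),
                   file.path(dir, "structures.tsv"))
  readr::write_tsv(fmt(arrange(db$discs, .data$structure_id, .data$z)),
                   file.path(dir, "discs.tsv"))
  readr::write_tsv(arrange(db$links, .data$structure_id, .data$linked_id),
                   file.path(dir, "links.tsv"))
  invisible(dir)
}

#' Load an annotation database from tab-separated tables
#'
#' Inverse of [write_db()]: reads the five-table layout and re-validates
#' referential integrity, so a dangling link or duplicated structure id in
#' the files is reported as a load error.
#'
#' @param dir Directory containing `meta.tsv`, `cells.tsv`, `structures.tsv`,
#'   `discs.tsv` and `links.tsv`.
#' @return An [annotation_db()].
#' @export
load_db <- function(dir) {
  paths <- setNames(file.path(dir, db_file_names), names(db_file_names))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing table file(s): %s", paste(missing, collapse = ", ")))
  }
  meta_tbl <- readr::read_tsv(paths[["meta"]], show_col_types = FALSE,
                              col_types = "cc")
  mval <- function(key) as.numeric(meta_tbl$value[match(key, meta_tbl$key)])
  meta <- volume_meta(
    field_diameter_mm = mval("field_diameter_mm"),
    section_thickness_nm = mval("section_thickness_nm"),
    n_sections = mval("n_sections"),
    ipl_top_z = mval("ipl_top_z"),
    ipl_bottom_z = mval("ipl_bottom_z"),
    pixel_size_nm = mval("pixel_size_nm")
  )
  # doubles are read as text and converted with as.numeric: correctly-rounded
  # parsing makes load_db(write_db(db)) bit-exact
  num <- function(tbl, cols) mutate(tbl, across(dplyr::all_of(cols), as.numeric))
  cells <- readr::read_tsv(paths[["cells"]], show_col_types = FALSE,
                           col_types = readr::cols(
                             cell_id = "i", cell_class = "c", polarity = "c",
                             transmitter = "c", soma_x_nm = "c", soma_y_nm = "c")) |>
    num(c("soma_x_nm", "soma_y_nm"))
  structures <- readr::read_tsv(paths[["structures"]], show_col_types = FALSE,
                                col_types = readr::cols(
                                  structure_id = "i", kind = "c", parent_cell = "i"))
  discs <- readr::read_tsv(paths[["discs"]], show_col_types = FALSE,
                           col_types = readr::cols(
                             structure_id = "i", z = "i", x_nm = "c",
                             y_nm = "c", radius_nm = "c")) |>
    num(c("x_nm", "y_nm", "radius_nm"))
  links <- readr::read_tsv(paths[["links"]], show_col_types = FALSE,
                           col_types = readr::cols(structure_id = "i", linked_id = "i"))
  annotation_db(meta, cells, structures, discs, links)
}

#' Export resolved contacts as a graph file
#'
#' Writes the contact list either as GraphML (via igraph, with node class /
#' polarity / transmitter attributes and edge kind / sign / count / area
#' attributes) or as a plain CSV edge list with one row per aggregated edge.
#'
#' @param contacts Contact tibble from [resolve_contacts()].
#' @param cells Cell table (for node attributes).
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(contacts, cells, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- build_graph(contacts, cells)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    readr::write_csv(as_tibble(el), path)
  }
  invisible(path)
}
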