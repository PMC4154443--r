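#' Run the full synthetic-connectome analysis pipeline
#'
#' Orchestrates generate, write/load (optional round-trip through the
#' on-disk tables), resolve, and all quantitative analyses: mosaic
#' statistics, sampling-precision reports, partner summaries for the five
#' best-connected AII cells, the class contact matrix, depth profiles, gap
#' junction size statistics, the rule audit, encounter audit and weight
#' report. Every number in the returned bundle is traceable to one of the
#' package's analysis functions.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory: when given, the annotation tables,
#'   profile / statistics CSVs and a GraphML export are written there.
#' @param allow_violations If `FALSE` (default) the run aborts when the
#'   rule audit reports violations (a rule-compliant generator must produce
#'   none).
#' @return Object of class `connectome_report`: list with elements
#'   `mosaic_stats`, `precision` (tibble), `partner_summaries` (list),
#'   `class_matrix`, `depth_profiles`, `gj_stats` (list homo/hetero),
#'   `rule_audit`, `encounter_audit`, `weight_report`, `hops`, `contacts`,
#'   `ledger`, and `provenance` (seed, config hash, package version).
#' @export
run_connectome <- function(config = generator_config(), out_dir = NULL,
                           allow_violations = FALSE) {
  gen <- generate_connectome(config)
  db <- gen$db
  contacts <- resolve_contacts(db)
  ruleset <- default_ruleset()

  audit <- validate_contacts(contacts, ruleset)
  if (!allow_violations && audit$n_violations > 0) {
    abort(sprintf("rule audit reports %d violation(s); rerun with allow_violations = TRUE to inspect",
                  audit$n_violations))
  }
  enc <- encounter_audit(contacts, ruleset)

  aii <- filter(db$cells, .data$cell_class == "AII")
  mosaic_pts <- tibble(x_um = aii$soma_x_nm / 1e3, y_um = aii$soma_y_nm / 1e3)
  mstats <- mosaic_stats(mosaic_pts, db$meta$field_diameter_mm,
                         arbor_diameter_um = config$arboreal_span_um)

  # sampling precision: rod bipolar partners and ribbons per AII cell
  rod_in <- filter(contacts, .data$category == "rodBC_input")
  per_aii <- rod_in |>
    group_by(cell_id = .data$post_cell) |>
    summarise(n_partners = dplyr::n_distinct(.data$pre_cell),
              n_ribbons = dplyr::n(), .groups = "drop")
  precision <- dplyr::bind_rows(
    precision_report(per_aii$n_partners, unit = "rod bipolar partners per AII"),
    precision_report(per_aii$n_ribbons, unit = "rod ribbons per AII")
  )

  top_aii <- contacts |>
    filter(.data$pre_class == "AII" | .data$post_class == "AII") |>
    mutate(aii = ifelse(.data$pre_class == "AII", .data$pre_cell, .data$post_cell)) |>
    count(.data$aii, sort = TRUE) |>
    head(5)
  partner_summaries <- purrr::map(top_aii$aii,
                                  function(id) aggregate_partners(contacts, id))
  names(partner_summaries) <- as.character(top_aii$aii)

  gj <- list(
    homo = size_histogram(
      contacts$diameter_nm[contacts$category == "coupling_AII_AII"],
      pairing = "AII::AII"),
    hetero = size_histogram(
      contacts$diameter_nm[contacts$category == "coupling_AII_CBb"],
      pairing = "AII::CBb")
  )

  graph <- build_graph(contacts, db$cells)
  hops <- hop_distances(graph, "AII")

  bundle <- list(
    mosaic_stats = mstats,
    precision = precision,
    partner_summaries = partner_summaries,
    class_matrix = class_contact_matrix(contacts, db$cells),
    depth_profiles = depth_profile(contacts),
    gj_stats = gj,
    rule_audit = audit,
    encounter_audit = enc,
    weight_report = weight_report(contacts),
    hops = hops,
    contacts = contacts,
    ledger = gen$ledger,
    db = db,
    provenance = list(
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("aiinet")),
      timestamp = NA_character_  # kept reproducible: no wall-clock in hash
    )
  )
  class(bundle) <- "connectome_report"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_db(db, file.path(out_dir, "db"))
    readr::write_csv(bundle$depth_profiles, file.path(out_dir, "depth_profiles.csv"))
    readr::write_csv(bundle$mosaic_stats, file.path(out_dir, "mosaic_stats.csv"))
    readr::write_csv(bundle$precision, file.path(out_dir, "precision.csv"))
    readr::write_csv(bundle$weight_report$totals,
                     file.path(out_dir, "category_totals.csv"))
    readr::write_csv(bundle$encounter_audit, file.path(out_dir, "encounter_audit.csv"))
    export_graph(contacts, db$cells, file.path(out_dir, "network.graphml"),
                 "graphml")
  }
  bundle
}

#' @export
print.connectome_report <- function(x, ...) {
  cat("<connectome_report>\n")
  cat(sprintf("  seed %s | %d contacts | %d proper, %d violations\n",
              x$provenance$seed, nrow(x$contacts),
              x$rule_audit$n_proper, x$rule_audit$n_violations))
  cat(sprintf("  mosaic: %d AII cells, %.0f cells/mm^2, jitter %.2f\n",
              x$mosaic_stats$n_cells, x$mosaic_stats$density_mm2,
              x$mosaic_stats$jitter))
  cat(sprintf("  coupling: %d homo (%.0f nm), %d hetero (%.0f nm)\n",
              x$gj_stats$homo$n, x$gj_stats$homo$mean_nm,
              x$gj_stats$hetero$n, x$gj_stats$hetero$mean_nm))
  invisible(x)
}

#' Compare a report bundle against the published reference values
#'
#' Tabulates the bundle's computed quantities next to the published values
#' for the volume the generator emulates (AII mosaic density, sampling
#' CVs, coupling statistics, rule-audit counts), with a tolerance and
#' verdict per row. Rows whose quantity cannot be computed from the bundle
#' are reported as `not computed`.
#'
#' @param bundle A `connectome_report` from [run_connectome()].
#' @return Tibble: `quantity`, `computed`, `expected`, `tolerance`,
#'   `verdict`.
#' @export
reference_checks <- function(bundle) {
  row <- function(quantity, computed, expected, tolerance) {
    verdict <- if (is.na(computed)) "not computed" else
      if (abs(computed - expected) <= tolerance) "pass" else "fail"
    tibble(quantity = quantity, computed = computed, expected = expected,
           tolerance = tolerance, verdict = verdict)
  }
  ms <- bundle$mosaic_stats
  prec <- bundle$precision
  cv_cells <- prec$cv[1] %||% NA_real_
  cv_ribbons <- prec$cv[2] %||% NA_real_
  dplyr::bind_rows(
    row("AII density (cells/mm^2)", round(ms$density_mm2), 841, 25),
    row("cell-sampling CV", cv_cells, 0.28, 0.10),
    row("ribbon-sampling CV", cv_ribbons, 0.04, 0.03),
    row("precision fold", if (!is.na(cv_ribbons) && cv_ribbons > 0)
      cv_cells / cv_ribbons else NA_real_, 7, 3.5),
    row("rule violations", bundle$rule_audit$n_violations, 0, 0),
    row("grid connectivity at ideal C=4", predicted_grid_connectivity(4), 8, 0),
    row("homocellular GJ mean (nm)", bundle$gj_stats$homo$mean_nm, 267, 10),
    row("heterocellular GJ mean (nm)", bundle$gj_stats$hetero$mean_nm, 238, 10),
    row("ON-AC : rodBC area ratio", bundle$weight_report$ratios$on_ac_to_rodbc,
        8, 0.8),
    tibble(quantity = "max hop from AII set (upper bound)",
           computed = bundle$hops$max_hop, expected = 2, tolerance = 0,
           verdict = ifelse(bundle$hops$max_hop <= 2, "pass", "fail"))
  )
}
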