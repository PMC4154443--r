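#' Partner summary for a focal cell
#'
#' Groups a focal cell's resolved contacts by partner cell and contact kind,
#' with contact counts, summed areas and the compartments involved — the
#' tabular form of a single-cell partnership map.
#'
#' @param contacts Contact tibble from [resolve_contacts()].
#' @param focal Focal `cell_id`.
#' @return Tibble of class `partner_summary`: `focal_cell`, `partner_cell`,
#'   `partner_class`, `kind`, `category`, `n_contacts`, `total_area_um2`,
#'   `compartments`.
#' @export
aggregate_partners <- function(contacts, focal) {
  rows <- contacts |>
    filter(.data$pre_cell == focal | .data$post_cell == focal) |>
    mutate(
      partner_cell = ifelse(.data$pre_cell == focal, .data$post_cell, .data$pre_cell),
      partner_class = ifelse(.data$pre_cell == focal, .data$post_class, .data$pre_class),
      compartment = assign_compartment(.data$depth)
    )
  out <- rows |>
    group_by(.data$partner_cell, .data$partner_class, .data$kind, .data$category) |>
    summarise(
      n_contacts = dplyr::n(),
      total_area_um2 = sum(.data$area_um2),
      compartments = paste(sort(unique(.data$compartment)), collapse = ","),
      .groups = "drop"
    ) |>
    mutate(focal_cell = focal, .before = 1) |>
    arrange(dplyr::desc(.data$n_contacts))
  class(out) <- c("partner_summary", class(out))
  out
}

#' Build the weighted signed multigraph of a contact list
#'
#' One edge per aggregated (cell pair, kind) combination: directed for
#' chemical synapses with the sign of the presynaptic transmitter
#' (glutamate +1; GABA and glycine -1), undirected sign-conserving (+1) for
#' gap junctions, sign 0 for adherens and touches. Dopamine co-release
#' (TH1) is carried as a `dopamine` edge attribute, not a sign. Edge weight
#' is the summed contact area; `n_contacts` preserves the multiplicity.
#'
#' @param contacts Contact tibble from [resolve_contacts()].
#' @param cells Cell table (node attributes: class, polarity, transmitter).
#' @return An igraph graph (directed; gap-junction edges are marked
#'   `bidirectional = TRUE` and treated as undirected for reachability).
#' @export
build_graph <- function(contacts, cells) {
  edges <- contacts |>
    group_by(.data$pre_cell, .data$post_cell, .data$kind) |>
    summarise(n_contacts = dplyr::n(),
              area_um2 = sum(.data$area_um2),
              .groups = "drop") |>
    mutate(
      pre_class = cells$cell_class[match(.data$pre_cell, cells$cell_id)],
      transmitter = class_transmitter(.data$pre_class),
      sign = dplyr::case_when(
        .data$kind == "gap_junction" ~ 1,
        .data$kind %in% c("adherens", "touch") ~ 0,
        .data$transmitter %in% c("GABA", "glycine") ~ -1,
        TRUE ~ 1
      ),
      dopamine = .data$transmitter == "glutamate+dopamine",
      bidirectional = .data$kind %in% SYMMETRIC_KINDS
    ) |>
    select("pre_cell", "post_cell", "kind", "sign", "dopamine",
           "bidirectional", "n_contacts", "area_um2")
  if (!"polarity" %in% names(cells)) {
    cells$polarity <- class_polarity(cells$cell_class)
  }
  if (!"transmitter" %in% names(cells)) {
    cells$transmitter <- class_transmitter(cells$cell_class)
  }
  nodes <- cells |>
    transmute(name = as.character(.data$cell_id),
              cell_class = .data$cell_class,
              polarity = .data$polarity,
              transmitter = .data$transmitter)
  used <- unique(c(edges$pre_cell, edges$post_cell))
  nodes <- filter(nodes, .data$name %in% as.character(used))
  igraph::graph_from_data_frame(
    d = edges |>
      mutate(from = as.character(.data$pre_cell),
             to = as.character(.data$post_cell), .before = 1) |>
      select(-"pre_cell", -"post_cell"),
    directed = TRUE,
    vertices = nodes
  )
}

#' Hop distances from a source cell class
#'
#' Minimum hop count from any source-class node to every other node, with
#' synapses and gap junctions both counting as one hop and edge direction
#' ignored for reachability (the hub question is about proximity, not signal
#' direction).
#'
#' @param graph Graph from [build_graph()].
#' @param source_class Cell class of the source set (default `"AII"`).
#' @return List with `per_node` (tibble: `cell_id`, `cell_class`, `hops`),
#'   `histogram` (tibble: `hops`, `n`), `frac_within_1` (fraction of
#'   non-source nodes directly connected) and `max_hop`.
#' @export
hop_distances <- function(graph, source_class = "AII") {
  if (igraph::vcount(graph) == 0) abort("graph is empty")
  cls <- igraph::vertex_attr(graph, "cell_class")
  src <- which(cls == source_class)
  if (length(src) == 0) abort(sprintf("no nodes of class %s", source_class))
  d <- igraph::distances(graph, v = src, mode = "all")
  hops <- apply(d, 2, min)
  per_node <- tibble(
    cell_id = as.integer(igraph::vertex_attr(graph, "name")),
    cell_class = cls,
    hops = as.numeric(hops)
  )
  non_source <- filter(per_node, .data$cell_class != source_class)
  histogram <- per_node |>
    count(hops = .data$hops) |>
    arrange(.data$hops)
  list(
    per_node = per_node,
    histogram = histogram,
    frac_within_1 = mean(non_source$hops <= 1),
    max_hop = max(per_node$hops[is.finite(per_node$hops)])
  )
}

#' Class-level contact matrix
#'
#' Counts and summed areas of contacts between cell classes, by contact
#' kind, in long form, plus the derived hub statistics: the number of
#' distinct partner classes contacting the focal class and the number of
#' distinct (partner class, kind, direction) contact kinds.
#'
#' @param contacts Contact tibble from [resolve_contacts()].
#' @param cells Cell table.
#' @param focal_class Class whose partner repertoire is summarised
#'   (default `"AII"`).
#' @return Object of class `class_contact_matrix`: list with `matrix`
#'   (tibble: `pre_class`, `post_class`, `kind`, `n_contacts`,
#'   `total_area_um2`), `n_partner_classes`, `n_contact_kinds`.
#' @export
class_contact_matrix <- function(contacts, cells, focal_class = "AII") {
  mat <- contacts |>
    group_by(.data$pre_class, .data$post_class, .data$kind) |>
    summarise(n_contacts = dplyr::n(),
              total_area_um2 = sum(.data$area_um2),
              .groups = "drop")
  focal_rows <- mat |>
    filter(.data$pre_class == focal_class | .data$post_class == focal_class) |>
    mutate(partner = ifelse(.data$pre_class == focal_class,
                            .data$post_class, .data$pre_class),
           direction = ifelse(.data$kind %in% SYMMETRIC_KINDS, "symmetric",
                              ifelse(.data$pre_class == focal_class,
                                     "focal_pre", "focal_post")))
  out <- list(
    matrix = mat,
    n_partner_classes = dplyr::n_distinct(focal_rows$partner),
    n_contact_kinds = nrow(distinct(focal_rows, .data$partner, .data$kind,
                                    .data$direction))
  )
  class(out) <- "class_contact_matrix"
  out
}

#' @export
print.class_contact_matrix <- function(x, ...) {
  cat(sprintf("<class_contact_matrix> %d partner classes, %d contact kinds\n",
              x$n_partner_classes, x$n_contact_kinds))
  print(x$matrix, n = 10)
  invisible(x)
}

#' Synaptic weight report: category area totals and ratios
#'
#' Sums contact area per signal-flow category and derives the weight ratios
#' used to compare input modalities:
#'
#' * `on_ac_to_rodbc`: ON amacrine input area over rod bipolar ribbon area;
#' * `ac_lobule_to_offbc`: OFF amacrine input contact count over OFF cone
#'   bipolar input count (lobule drive);
#' * `coupling_homo_to_hetero`: homocellular over heterocellular coupling
#'   area **per AII endpoint** — an AII::AII junction couples two AII cells
#'   and contributes its area to both, so the homocellular total is doubled
#'   relative to raw area (this reproduces the approximately 7-fold
#'   homocellular coupling advantage);
#' * `th1_to_coupling`: TH1 input area over total (raw) coupling area.
#'
#' Ratios with an empty denominator category are returned as `NA` and
#' flagged in `undefined`.
#'
#' @param contacts Contact tibble from [resolve_contacts()].
#' @return Object of class `weight_report`: list with `totals` (tibble:
#'   `category`, `n_contacts`, `total_area_um2`), `ratios` (named list) and
#'   `undefined` (character vector of ratios with empty denominators).
#' @export
weight_report <- function(contacts) {
  totals <- contacts |>
    group_by(.data$category) |>
    summarise(n_contacts = dplyr::n(),
              total_area_um2 = sum(.data$area_um2),
              .groups = "drop")
  area_of <- function(cat) {
    i <- match(cat, totals$category)
    if (is.na(i)) 0 else totals$total_area_um2[i]
  }
  n_of <- function(cat) {
    i <- match(cat, totals$category)
    if (is.na(i)) 0 else totals$n_contacts[i]
  }
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  coupling_area <- area_of("coupling_AII_AII") + area_of("coupling_AII_CBb")
  ratios <- list(
    on_ac_to_rodbc = safe_ratio(area_of("AC_input_ON"), area_of("rodBC_input")),
    ac_lobule_to_offbc = safe_ratio(n_of("AC_input_OFF"), n_of("OFF_BC_input")),
    coupling_homo_to_hetero = safe_ratio(2 * area_of("coupling_AII_AII"),
                                         area_of("coupling_AII_CBb")),
    th1_to_coupling = safe_ratio(area_of("TH1_input"), coupling_area)
  )
  out <- list(
    totals = totals,
    ratios = ratios,
    undefined = names(ratios)[vapply(ratios, is.na, logical(1))]
  )
  class(out) <- "weight_report"
  out
}

#' @export
print.weight_report <- function(x, ...) {
  cat("<weight_report>\n")
  print(x$totals)
  cat("ratios:\n")
  for (nm in names(x$ratios)) {
    cat(sprintf("  %-24s %s\n", nm,
                ifelse(is.na(x$ratios[[nm]]), "undefined",
                       sprintf("%.3f", x$ratios[[nm]]))))
  }
  invisible(x)
}
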