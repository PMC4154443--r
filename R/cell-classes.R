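#' Cell class inventory
#'
#' The fixed lookup from cell class to response polarity, transmitter content
#' and superclass used throughout the package. AII amacrine cells are
#' glycinergic; rod bipolar and all cone bipolar classes are glutamatergic;
#' TH1 axonal cells carry a dual glutamate/dopamine signature; the wide-field
#' amacrine classes are GABAergic. The CBb (ON cone bipolar) superclass is
#' split into its stratification classes, with CBb7 kept distinct because its
#' contact repertoire with AII cells (ribbons *and* gap junctions) is unique.
#'
#' @return A tibble with columns `cell_class`, `superclass`, `polarity` and
#'   `transmitter`.
#' @export
#' @examples
#' cell_class_table()
cell_class_table <- function() {
  tribble(
    ~cell_class,    ~superclass, ~polarity, ~transmitter,
    "AII",          "AC",        "ON-OFF",  "glycine",
    "RodBC",        "BC",        "ON",      "glutamate",
    "CBa1",         "CBa",       "OFF",     "glutamate",
    "CBa2",         "CBa",       "OFF",     "glutamate",
    "CBa3",         "CBa",       "OFF",     "glutamate",
    "CBa4",         "CBa",       "OFF",     "glutamate",
    "CBa5",         "CBa",       "OFF",     "glutamate",
    "CBa6",         "CBa",       "OFF",     "glutamate",
    "CBb3",         "CBb",       "ON",      "glutamate",
    "CBb4w",        "CBb",       "ON",      "glutamate",
    "CBb5w",        "CBb",       "ON",      "glutamate",
    "CBb4-5i",      "CBb",       "ON",      "glutamate",
    "CBb5-6i",      "CBb",       "ON",      "glutamate",
    "CBb6",         "CBb",       "ON",      "glutamate",
    "CBb7",         "CBb7",      "ON",      "glutamate",
    "TH1",          "AxC",       "ON",      "glutamate+dopamine",
    "AI",           "AC",        "ON",      "GABA",
    "gammaAC",      "AC",        "ON-OFF",  "GABA",
    "GAC",          "AC",        "n/a",     "GABA",
    "OFF-alpha-GC", "GC",        "OFF",     "glutamate",
    "OFF-delta-GC", "GC",        "OFF",     "glutamate",
    "other",        "other",     "n/a",     "n/a"
  )
}

#' Expand a partner group label to its member cell classes
#'
#' Rule tables and contact categories refer to class groups (e.g. "CBb" for
#' all non-CBb7 ON cone bipolar classes, "GC" for ganglion cells). This
#' resolves a group label to the concrete class labels it covers.
#'
#' @param group A group or class label.
#' @return Character vector of member `cell_class` values.
#' @export
class_group_members <- function(group) {
  tab <- cell_class_table()
  if (group == "any") return(setdiff(tab$cell_class, "other"))
  if (group == "CBbAll") {
    return(tab$cell_class[tab$superclass %in% c("CBb", "CBb7")])
  }
  if (group %in% tab$cell_class) return(group)
  members <- tab$cell_class[tab$superclass == group]
  if (length(members) == 0) group else members
}

class_polarity <- function(cell_class) {
  tab <- cell_class_table()
  tab$polarity[match(cell_class, tab$cell_class)]
}

class_transmitter <- function(cell_class) {
  tab <- cell_class_table()
  tab$transmitter[match(cell_class, tab$cell_class)]
}

class_superclass <- function(cell_class) {
  tab <- cell_class_table()
  tab$superclass[match(cell_class, tab$cell_class)]
}
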