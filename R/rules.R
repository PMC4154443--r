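SYMMETRIC_KINDS <- c("gap_junction", "adherens", "touch")

#' Default AII contact-rule set
#'
#' The stereotyped compartment- and class-specific contact rules of the AII
#' amacrine cell, encoded as a machine-readable table:
#'
#' * arboreal dendrites are always postsynaptic to rod bipolar cells and
#'   never presynaptic to them, and never make gap junctions with them;
#' * every encountered ON cone bipolar cell (CBb) is coupled by gap
#'   junctions in the waist/arboreal zone, but no CBb ribbon input is
#'   accepted except from the CBb7 class;
#' * lobules exchange synapses with OFF cone bipolar cells (CBa) in either
#'   direction but never form gap junctions with them;
#' * AII::AII gap junctions occur at every arboreal encounter and never
#'   between lobules (AII connexins are excluded from lobules);
#' * synaptic output is made only from lobules; every lobule encountered by
#'   the OFF alpha ganglion cell is presynaptic to it, while arboreal
#'   touches with ganglion cells make no specializations;
#' * AI amacrine contacts in the OFF layer are non-synaptic (adherens only,
#'   at the arboreal level);
#' * TH1 axonal cells synapse onto the neck; GABAergic amacrine input is
#'   accepted in both sublaminae.
#'
#' @return Tibble of class `rule_set` with columns `rule_id`, `focal_class`,
#'   `partner_group`, `focal_compartment`, `kind`, `mode`
#'   (`required_on_encounter` / `permitted` / `forbidden`) and `direction`
#'   (`focal_pre` / `focal_post` / `symmetric` / `any`).
#' @export
default_ruleset <- function() {
  rs <- tribble(
    ~rule_id, ~focal_class, ~partner_group, ~focal_compartment, ~kind, ~mode, ~direction,
    # --- rod bipolar cells ---
    "rod_ribbon_arboreal",   "AII", "RodBC", "arboreal", "ribbon_input",         "required_on_encounter", "focal_post",
    "rod_no_output",         "AII", "RodBC", "any",      "conventional_synapse", "forbidden",             "focal_pre",
    "rod_no_coupling",       "AII", "RodBC", "any",      "gap_junction",         "forbidden",             "symmetric",
    # --- ON cone bipolar cells (non-CBb7) ---
    "cbb_coupling_waist",    "AII", "CBbAll", "waist",    "gap_junction",        "required_on_encounter", "symmetric",
    "cbb_coupling_arboreal", "AII", "CBbAll", "arboreal", "gap_junction",        "required_on_encounter", "symmetric",
    "cbb_no_coupling_off",   "AII", "CBbAll", "lobule",   "gap_junction",        "forbidden",             "symmetric",
    "cbb_no_ribbon",         "AII", "CBb",    "any",      "ribbon_input",        "forbidden",             "focal_post",
    # --- CBb7: the one ON cone bipolar making both ribbons and coupling ---
    "cbb7_ribbon",           "AII", "CBb7", "arboreal", "ribbon_input",          "permitted",             "focal_post",
    "cbb7_ribbon_waist",     "AII", "CBb7", "waist",    "ribbon_input",          "permitted",             "focal_post",
    # --- OFF cone bipolar cells ---
    "cba_input",             "AII", "CBa", "lobule", "ribbon_input",             "permitted",             "focal_post",
    "cba_output",            "AII", "CBa", "lobule", "conventional_synapse",     "permitted",             "focal_pre",
    "cba_no_coupling",       "AII", "CBa", "any",    "gap_junction",             "forbidden",             "symmetric",
    # --- AII::AII coupling ---
    "aii_coupling_arboreal", "AII", "AII", "arboreal", "gap_junction",           "required_on_encounter", "symmetric",
    "aii_coupling_waist",    "AII", "AII", "waist",    "gap_junction",           "permitted",             "symmetric",
    "aii_no_lobule_coupling","AII", "AII", "lobule",   "gap_junction",           "forbidden",             "symmetric",
    # --- ganglion cells ---
    "offgc_lobule_output",   "AII", "OFF-alpha-GC", "lobule", "conventional_synapse", "required_on_encounter", "focal_pre",
    "gc_lobule_output",      "AII", "GC", "lobule",   "conventional_synapse",    "permitted",             "focal_pre",
    "gc_arboreal_touch_only","AII", "GC", "arboreal", "any_specialization",      "forbidden",             "any",
    # --- amacrine cells ---
    "ai_no_off_synapse",     "AII", "AI", "lobule",   "conventional_synapse",    "forbidden",             "any",
    "ai_adherens",           "AII", "AI", "arboreal", "adherens",                "permitted",             "symmetric",
    "ac_input",              "AII", "gammaAC", "any", "conventional_synapse",    "permitted",             "focal_post",
    "gac_output",            "AII", "GAC", "lobule",  "conventional_synapse",    "permitted",             "focal_pre",
    # --- TH1 axonal cells ---
    "th1_input",             "AII", "TH1", "neck",    "conventional_synapse",    "permitted",             "focal_post",
    # --- outputs only from lobules (catch-all) ---
    "output_lobule_only_n",  "AII", "any", "neck",     "conventional_synapse",   "forbidden",             "focal_pre",
    "output_lobule_only_w",  "AII", "any", "waist",    "conventional_synapse",   "forbidden",             "focal_pre",
    "output_lobule_only_a",  "AII", "any", "arboreal", "conventional_synapse",   "forbidden",             "focal_pre"
  )
  key <- paste(rs$focal_class, rs$partner_group, rs$focal_compartment,
               rs$kind, rs$direction)
  stopifnot(!anyDuplicated(key))
  class(rs) <- c("rule_set", class(rs))
  rs
}

#' Read or write a rule set as JSON
#'
#' Rule sets are editable structured text; these helpers round-trip the rule
#' table through a JSON file.
#'
#' @param ruleset A `rule_set` tibble.
#' @param path File path.
#' @return `read_ruleset()` returns a `rule_set`; `write_ruleset()` returns
#'   `path` invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  jsonlite::write_json(as.data.frame(ruleset), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  rs <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(rs) <- c("rule_set", class(rs))
  rs
}

# Decorate AII-involving contacts with focal/partner columns used by the
# rule matcher. Contacts not involving an AII cell are out of audit scope.
focalise_contacts <- function(contacts) {
  aii <- contacts |>
    filter(.data$pre_class == "AII" | .data$post_class == "AII") |>
    mutate(
      focal_is_pre = .data$pre_class == "AII",
      focal_cell = ifelse(.data$focal_is_pre, .data$pre_cell, .data$post_cell),
      partner_cell = ifelse(.data$focal_is_pre, .data$post_cell, .data$pre_cell),
      partner_class = ifelse(.data$focal_is_pre, .data$post_class, .data$pre_class),
      direction = dplyr::case_when(
        .data$kind %in% SYMMETRIC_KINDS ~ "symmetric",
        .data$focal_is_pre ~ "focal_pre",
        TRUE ~ "focal_post"
      ),
      compartment = assign_compartment(.data$depth)
    )
  aii
}

# logical vector: which focalised contacts match one rule row
match_rule <- function(fc, rule) {
  ok_partner <- fc$partner_class %in% class_group_members(rule$partner_group)
  ok_comp <- rule$focal_compartment == "any" | fc$compartment == rule$focal_compartment
  ok_kind <- if (rule$kind == "any_specialization") {
    fc$kind %in% c("ribbon_input", "conventional_synapse", "gap_junction", "adherens")
  } else {
    fc$kind == rule$kind
  }
  ok_dir <- rule$direction == "any" | fc$direction == rule$direction
  ok_partner & ok_comp & ok_kind & ok_dir
}

#' Audit resolved contacts against a rule set
#'
#' Classifies every AII-involving, non-touch contact as *proper* (matches a
#' permitted or required rule and no forbidden rule), a *violation* (matches
#' a forbidden rule), or *unmatched* (no rule covers it). Contacts with a
#' partner of unknown class are excluded with a warning; contacts not
#' involving an AII cell are out of audit scope. The classification is
#' complete: proper + violations + unmatched equals the number of classified
#' contacts.
#'
#' @param contacts Contact tibble from [resolve_contacts()] (or an
#'   [annotation_db()], which is resolved first).
#' @param ruleset A rule set from [default_ruleset()] or [read_ruleset()].
#' @return Object of class `rule_audit`: list with `n_proper`,
#'   `n_violations`, `violations` (tibble: `rule_id`, `pre_structure`,
#'   `post_structure`, `description`), `n_unmatched`, `unmatched`,
#'   `n_unclassified`, `n_out_of_scope`, `n_touches`, `n_classified`.
#' @export
validate_contacts <- function(contacts, ruleset = default_ruleset()) {
  if (inherits(contacts, "annotation_db")) contacts <- resolve_contacts(contacts)
  fc_all <- focalise_contacts(contacts)
  n_out_of_scope <- nrow(contacts) - nrow(fc_all)
  n_touches <- sum(fc_all$kind == "touch")
  fc <- filter(fc_all, .data$kind != "touch")
  unknown <- is.na(fc$partner_class) | fc$partner_class == "other"
  if (any(unknown)) {
    warn(sprintf("%d contact(s) with unclassified partner excluded from audit",
                 sum(unknown)))
  }
  n_unclassified <- sum(unknown)
  fc <- fc[!unknown, ]

  forbidden_rules <- filter(ruleset, .data$mode == "forbidden")
  allowed_rules <- filter(ruleset, .data$mode %in% c("permitted", "required_on_encounter"))

  forb_hit <- rep(FALSE, nrow(fc))
  forb_rule <- rep(NA_character_, nrow(fc))
  for (i in seq_len(nrow(forbidden_rules))) {
    r <- forbidden_rules[i, ]
    m <- match_rule(fc, r)
    forb_rule[m & !forb_hit] <- r$rule_id
    forb_hit <- forb_hit | m
  }
  allow_hit <- rep(FALSE, nrow(fc))
  for (i in seq_len(nrow(allowed_rules))) {
    allow_hit <- allow_hit | match_rule(fc, allowed_rules[i, ])
  }

  violations <- fc[forb_hit, ] |>
    mutate(rule_id = forb_rule[forb_hit],
           description = sprintf(
             "%s %s %s-%s (%s, depth %.1f) violates rule %s",
             .data$pre_class, .data$kind, .data$pre_cell, .data$post_cell,
             .data$compartment, .data$depth, .data$rule_id)) |>
    select("rule_id", "pre_structure", "post_structure", "pre_cell",
           "post_cell", "kind", "compartment", "description")
  unmatched <- fc[!forb_hit & !allow_hit, ] |>
    select("pre_structure", "post_structure", "pre_cell", "post_cell",
           "kind", "compartment")
  out <- list(
    n_proper = sum(allow_hit & !forb_hit),
    n_violations = sum(forb_hit),
    violations = violations,
    n_unmatched = nrow(unmatched),
    unmatched = unmatched,
    n_unclassified = n_unclassified,
    n_out_of_scope = n_out_of_scope,
    n_touches = n_touches,
    n_classified = nrow(fc)
  )
  class(out) <- "rule_audit"
  out
}

#' @export
print.rule_audit <- function(x, ...) {
  cat("<rule_audit>\n")
  cat(sprintf("  proper connections : %d\n", x$n_proper))
  cat(sprintf("  improper (violations): %d\n", x$n_violations))
  cat(sprintf("  unmatched          : %d\n", x$n_unmatched))
  cat(sprintf("  unclassified       : %d\n", x$n_unclassified))
  cat(sprintf("  touches (audited separately): %d\n", x$n_touches))
  invisible(x)
}

#' Encounter audit for required-on-encounter rules
#'
#' An *encounter* between an AII compartment and a partner cell is any touch
#' or specialization annotated between the two cells in that compartment.
#' For every `required_on_encounter` rule, counts how many encounters are
#' honoured (the required contact kind is present for that cell pair and
#' compartment) versus violated (the pair touches but declines the
#' required contact). Honoured + violated = encounters, per rule.
#'
#' @param contacts Contact tibble from [resolve_contacts()] (or an
#'   [annotation_db()]).
#' @param ruleset A rule set.
#' @return Tibble: `rule_id`, `n_encounters`, `honored`, `violated`.
#' @export
encounter_audit <- function(contacts, ruleset = default_ruleset()) {
  if (inherits(contacts, "annotation_db")) contacts <- resolve_contacts(contacts)
  fc <- focalise_contacts(contacts)
  req <- filter(ruleset, .data$mode == "required_on_encounter")
  purrr::pmap(req, function(...) {
    r <- tibble(...)
    in_scope <- fc$partner_class %in% class_group_members(r$partner_group) &
      (r$focal_compartment == "any" | fc$compartment == r$focal_compartment)
    enc <- fc[in_scope, ] |>
      distinct(.data$focal_cell, .data$partner_cell)
    honoured_pairs <- fc[in_scope & match_rule(fc, r), ] |>
      distinct(.data$focal_cell, .data$partner_cell)
    n_hon <- nrow(semi_join(enc, honoured_pairs,
                            by = c("focal_cell", "partner_cell")))
    tibble(rule_id = r$rule_id, n_encounters = nrow(enc),
           honored = n_hon, violated = nrow(enc) - n_hon)
  }) |>
    list_rbind()
}
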