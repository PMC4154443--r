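#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a rule audit
#'
#' One row per violation, with the rule cited and the offending structures;
#' an empty tibble for a clean audit.
#'
#' @param x A `rule_audit` from [validate_contacts()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.rule_audit <- function(x, ...) {
  as_tibble(x$violations)
}

#' Glance at a rule audit
#'
#' @param x A `rule_audit`.
#' @param ... Unused.
#' @return One-row tibble with the audit's summary counts.
#' @exportS3Method generics::glance
glance.rule_audit <- function(x, ...) {
  tibble(
    n_classified = x$n_classified,
    n_proper = x$n_proper,
    n_violations = x$n_violations,
    n_unmatched = x$n_unmatched,
    n_unclassified = x$n_unclassified,
    n_touches = x$n_touches
  )
}

#' Tidy gap-junction size statistics
#'
#' @param x A `gj_size_stats` from [size_histogram()].
#' @param ... Unused.
#' @return The binned histogram tibble with the pairing label attached.
#' @exportS3Method generics::tidy
tidy.gj_size_stats <- function(x, ...) {
  mutate(x$histogram, pairing = x$pairing, .before = 1)
}

#' Glance at gap-junction size statistics
#'
#' @param x A `gj_size_stats`.
#' @param ... Unused.
#' @return One-row tibble: `pairing`, `n`, `mean_nm`, `sd_nm`, `max_nm`.
#' @exportS3Method generics::glance
glance.gj_size_stats <- function(x, ...) {
  tibble(pairing = x$pairing, n = x$n, mean_nm = x$mean_nm, sd_nm = x$sd_nm,
         max_nm = x$max_nm)
}

#' Tidy a weight report
#'
#' @param x A `weight_report` from [weight_report()].
#' @param ... Unused.
#' @return Per-category totals tibble.
#' @exportS3Method generics::tidy
tidy.weight_report <- function(x, ...) {
  x$totals
}

#' Glance at a weight report
#'
#' @param x A `weight_report`.
#' @param ... Unused.
#' @return One-row tibble of the derived weight ratios.
#' @exportS3Method generics::glance
glance.weight_report <- function(x, ...) {
  as_tibble(x$ratios)
}

#' Glance at a connectome report bundle
#'
#' Headline quantities of a full pipeline run in one row: mosaic density
#' and jitter, sampling CVs, coupling statistics, audit counts and hub
#' reach.
#'
#' @param x A `connectome_report` from [run_connectome()].
#' @param ... Unused.
#' @return One-row tibble.
#' @exportS3Method generics::glance
glance.connectome_report <- function(x, ...) {
  tibble(
    seed = x$provenance$seed,
    n_cells = nrow(x$db$cells),
    n_contacts = nrow(x$contacts),
    density_mm2 = x$mosaic_stats$density_mm2,
    jitter = x$mosaic_stats$jitter,
    cv_cells = x$precision$cv[1],
    cv_ribbons = x$precision$cv[2],
    gj_homo_mean_nm = x$gj_stats$homo$mean_nm,
    gj_hetero_mean_nm = x$gj_stats$hetero$mean_nm,
    n_proper = x$rule_audit$n_proper,
    n_violations = x$rule_audit$n_violations,
    max_hop = x$hops$max_hop
  )
}
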