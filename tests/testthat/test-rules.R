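test_that("the default rule set encodes the stereotyped contact rules", {
  rs <- default_ruleset()
  # no gap junctions with rod bipolar cells, ever
  expect_true(any(rs$partner_group == "RodBC" & rs$kind == "gap_junction" &
                    rs$mode == "forbidden"))
  # every lobule encountered by the OFF alpha ganglion cell synapses
  expect_true(any(rs$partner_group == "OFF-alpha-GC" &
                    rs$focal_compartment == "lobule" &
                    rs$kind == "conventional_synapse" &
                    rs$mode == "required_on_encounter" &
                    rs$direction == "focal_pre"))
  # ribbon input from non-CBb7 ON cone bipolar cells is an error
  expect_true(any(rs$partner_group == "CBb" & rs$kind == "ribbon_input" &
                    rs$mode == "forbidden"))
  # rule keys are unique
  key <- paste(rs$focal_class, rs$partner_group, rs$focal_compartment,
               rs$kind, rs$direction)
  expect_equal(anyDuplicated(key), 0)
  # rule sets round-trip through JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset(rs, path)
  expect_identical(as.data.frame(read_ruleset(path)), as.data.frame(rs))
})

test_that("a compliant synthetic connectome audits clean at scale", {
  b <- default_bundle()
  audit <- b$rule_audit
  expect_gte(audit$n_classified, 1773)
  expect_equal(audit$n_violations, 0)
  expect_equal(audit$n_unmatched, 0)
  # completeness: every classified contact is accounted for
  expect_equal(audit$n_proper + audit$n_violations + audit$n_unmatched,
               audit$n_classified)
})

test_that("one injected forbidden contact yields exactly one cited violation", {
  b <- default_bundle()
  aii <- b$db$cells$cell_id[b$db$cells$cell_class == "AII"][1]
  rod <- b$db$cells$cell_id[b$db$cells$cell_class == "RodBC"][1]
  db2 <- inject_contact(b$db, aii, rod, "gap_junction", "gap_junction",
                        depth = 20)
  bad_structure <- max(db2$structures$structure_id) - 1L
  audit <- validate_contacts(resolve_contacts(db2))
  expect_equal(audit$n_violations, 1)
  expect_equal(audit$violations$rule_id, "rod_no_coupling")
  expect_true(bad_structure %in%
                c(audit$violations$pre_structure, audit$violations$post_structure))
})

test_that("fuzzed forbidden contacts are all and only the reported violations", {
  b <- default_bundle()
  cls <- function(cl) b$db$cells$cell_id[b$db$cells$cell_class == cl]
  # catalogue of rule-breaking contact templates
  forbidden <- list(
    list(pre = cls("AII")[1], post = cls("RodBC")[2],
         pre_kind = "gap_junction", post_kind = "gap_junction", depth = 19),
    list(pre = cls("CBa2")[1], post = cls("AII")[2],
         pre_kind = "gap_junction", post_kind = "gap_junction", depth = 6),
    list(pre = cls("CBb3")[1], post = cls("AII")[3],
         pre_kind = "ribbon_presyn", post_kind = "psd", depth = 18),
    list(pre = cls("AII")[4], post = cls("AII")[5],
         pre_kind = "gap_junction", post_kind = "gap_junction", depth = 4),
    list(pre = cls("AII")[6], post = cls("CBa1")[2],
         pre_kind = "conventional_presyn", post_kind = "psd", depth = 20),
    list(pre = cls("AI")[1], post = cls("AII")[7],
         pre_kind = "conventional_presyn", post_kind = "psd", depth = 5),
    list(pre = cls("AII")[8], post = cls("OFF-delta-GC")[1],
         pre_kind = "adherens", post_kind = "adherens", depth = 20)
  )
  set.seed(17)
  for (k in c(1, 3, 7)) {
    db2 <- b$db
    picks <- sample(length(forbidden), k)
    planted <- integer(0)
    for (p in picks) {
      f <- forbidden[[p]]
      db2 <- inject_contact(db2, f$pre, f$post, f$pre_kind, f$post_kind,
                            f$depth)
      planted <- c(planted, max(db2$structures$structure_id) - 1L)
    }
    audit <- validate_contacts(resolve_contacts(db2))
    expect_equal(audit$n_violations, k)
    expect_setequal(audit$violations$pre_structure, planted)
  }
})

test_that("validation is idempotent and excludes unknown classes with a warning", {
  cells <- tibble::tibble(cell_id = 1:3,
                          cell_class = c("AII", "RodBC", "other"))
  contacts <- resolve_contacts(build_db(cells, tibble::tibble(
    pre_cell = c(2L, 3L), post_cell = c(1L, 1L),
    pre_kind = c("ribbon_presyn", "conventional_presyn"),
    post_kind = c("psd", "psd"),
    depth = c(20, 20), diameter_nm = 250)))
  expect_warning(a1 <- validate_contacts(contacts), "unclassified")
  expect_equal(a1$n_unclassified, 1)
  expect_equal(a1$n_proper, 1)
  a2 <- suppressWarnings(validate_contacts(contacts))
  expect_identical(glance(a1), glance(a2))
  expect_identical(a1$violations, a2$violations)
})

test_that("encounter audits count honoured versus declined touches", {
  # ten AII lobules touched by the OFF alpha ganglion cell, all synapsing
  cells <- tibble::tibble(
    cell_id = c(1:10, 99L),
    cell_class = c(rep("AII", 10), "OFF-alpha-GC"))
  touches <- tibble::tibble(
    pre_cell = 1:10, post_cell = 99L,
    pre_kind = "touch", post_kind = "touch", depth = 5, diameter_nm = 200)
  synapses <- tibble::tibble(
    pre_cell = 1:10, post_cell = 99L,
    pre_kind = "conventional_presyn", post_kind = "psd", depth = 5,
    diameter_nm = 300)
  full <- resolve_contacts(build_db(cells, dplyr::bind_rows(touches, synapses)))
  audit <- encounter_audit(full)
  row <- audit[audit$rule_id == "offgc_lobule_output", ]
  expect_equal(row$n_encounters, 10)
  expect_equal(row$honored, 10)
  expect_equal(row$violated, 0)

  # remove one synapse: 9 honoured, 1 declined
  partial <- resolve_contacts(build_db(
    cells, dplyr::bind_rows(touches, synapses[-4, ])))
  row2 <- encounter_audit(partial)
  row2 <- row2[row2$rule_id == "offgc_lobule_output", ]
  expect_equal(row2$honored, 9)
  expect_equal(row2$violated, 1)
  expect_equal(row2$honored + row2$violated, row2$n_encounters)
})

test_that("encounter audits on the synthetic volume have full conservation", {
  b <- default_bundle()
  enc <- b$encounter_audit
  expect_true(all(enc$honored + enc$violated == enc$n_encounters))
  expect_true(all(enc$violated == 0))
  # the OFF alpha ganglion cell rule is exercised
  expect_gt(enc$n_encounters[enc$rule_id == "offgc_lobule_output"], 0)
})
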