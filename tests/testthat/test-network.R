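# the worked coupling example: eight ON cone bipolar partners with known
# per-partner gap junction counts
aii476_db <- function() {
  partners <- tibble::tibble(
    cell_id = c(6155L, 4569L, 170L, 324L, 483L, 6156L, 419L, 4570L),
    cell_class = c("CBb3", "CBb3", "CBb4w", "CBb4w", "CBb5w", "CBb4-5i",
                   "CBb5-6i", "CBb5-6i"),
    n_gj = c(1L, 9L, 2L, 1L, 2L, 2L, 8L, 3L))
  cells <- dplyr::bind_rows(
    tibble::tibble(cell_id = 476L, cell_class = "AII", n_gj = NA_integer_),
    partners)
  contacts <- tibble::tibble(
    pre_cell = rep(partners$cell_id, times = partners$n_gj),
    post_cell = 476L,
    pre_kind = "gap_junction", post_kind = "gap_junction",
    depth = 18, diameter_nm = 250)
  build_db(dplyr::select(cells, -n_gj), contacts)
}

test_that("partner aggregation recovers the 28 coupling sites of AII 476", {
  contacts <- resolve_contacts(aii476_db())
  agg <- aggregate_partners(contacts, 476L)
  expect_equal(nrow(agg), 8)
  expect_equal(sum(agg$n_contacts), 28)
  expect_equal(agg$n_contacts[agg$partner_cell == 4569], 9)
  expect_equal(agg$n_contacts[agg$partner_cell == 419], 8)
  expect_true(all(agg$kind == "gap_junction"))
})

test_that("partner aggregation matches an independent group-by recount", {
  empty <- aggregate_partners(resolve_contacts(aii476_db())[0, ], 476L)
  expect_equal(nrow(empty), 0)

  b <- default_bundle()
  contacts <- b$contacts
  focal <- contacts$post_cell[contacts$category == "rodBC_input"][1]
  agg <- aggregate_partners(contacts, focal)
  # oracle: base-R tapply over the same rows
  rows <- contacts[contacts$pre_cell == focal | contacts$post_cell == focal, ]
  partner <- ifelse(rows$pre_cell == focal, rows$post_cell, rows$pre_cell)
  key <- paste(partner, rows$kind)
  oracle_n <- tapply(rep(1, nrow(rows)), key, sum)
  got <- setNames(agg$n_contacts, paste(agg$partner_cell, agg$kind))
  # aggregate_partners additionally splits by category; collapse
  got <- tapply(agg$n_contacts, paste(agg$partner_cell, agg$kind), sum)
  expect_equal(sort(names(got)), sort(names(oracle_n)))
  expect_equal(as.numeric(got[sort(names(got))]),
               as.numeric(oracle_n[sort(names(oracle_n))]))
  expect_equal(sum(agg$n_contacts), nrow(rows))
})

test_that("the multigraph carries signs, weights and multiplicities", {
  cells <- tibble::tibble(cell_id = 1:3,
                          cell_class = c("AII", "CBa1", "AII"))
  contacts <- resolve_contacts(build_db(cells, tibble::tibble(
    pre_cell = c(1L, 1L), post_cell = c(2L, 3L),
    pre_kind = c("conventional_presyn", "gap_junction"),
    post_kind = c("psd", "gap_junction"),
    depth = c(5, 18), diameter_nm = c(300, 250))))
  g <- build_graph(contacts, cells)
  ed <- igraph::as_data_frame(g, what = "edges")
  syn <- ed[ed$kind == "conventional_synapse", ]
  expect_equal(syn$sign, -1)  # glycinergic output
  expect_false(syn$bidirectional)
  gj <- ed[ed$kind == "gap_junction", ]
  expect_equal(gj$sign, 1)
  expect_true(gj$bidirectional)
  # edge weights conserve contact areas per kind
  expect_equal(sum(ed$area_um2), sum(contacts$area_um2))
})

test_that("graph censuses match the planted ledger", {
  b <- default_bundle()
  g <- build_graph(b$contacts, b$db$cells)
  ed <- igraph::as_data_frame(g, what = "edges")
  expect_equal(sum(ed$n_contacts), nrow(b$ledger$contacts))
  per_kind <- tapply(ed$area_um2, ed$kind, sum)
  got <- tapply(b$contacts$area_um2, b$contacts$kind, sum)
  expect_equal(per_kind[sort(names(per_kind))], got[sort(names(got))],
               tolerance = 1e-9)
})

test_that("hop distances agree with a hand-rolled BFS", {
  # star: one AII synapsing onto five partners -> all at hop 1
  cells <- tibble::tibble(cell_id = 1:6,
                          cell_class = c("AII", rep("CBa1", 5)))
  star <- resolve_contacts(build_db(cells, tibble::tibble(
    pre_cell = 1L, post_cell = 2:6,
    pre_kind = "conventional_presyn", post_kind = "psd",
    depth = 5, diameter_nm = 250)))
  h <- hop_distances(build_graph(star, cells), "AII")
  expect_true(all(h$per_node$hops[h$per_node$cell_class != "AII"] == 1))
  expect_equal(h$frac_within_1, 1)

  # chain AII -> a -> b: b sits at hop 2 even against edge direction
  cells3 <- tibble::tibble(cell_id = 1:3,
                           cell_class = c("AII", "gammaAC", "GAC"))
  chain <- resolve_contacts(build_db(cells3, tibble::tibble(
    pre_cell = c(2L, 3L), post_cell = c(1L, 2L),
    pre_kind = "conventional_presyn", post_kind = "psd",
    depth = 5, diameter_nm = 250)))
  h3 <- hop_distances(build_graph(chain, cells3), "AII")
  expect_equal(h3$per_node$hops[h3$per_node$cell_id == 3], 2)

  # random graphs vs BFS oracle
  set.seed(64)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    cls <- c("AII", sample(c("CBa1", "gammaAC", "GAC", "RodBC"), n - 1,
                           replace = TRUE))
    cellsn <- tibble::tibble(cell_id = seq_len(n), cell_class = cls)
    m <- sample(5:20, 1)
    ctc <- tibble::tibble(
      pre_cell = sample(seq_len(n), m, replace = TRUE),
      post_cell = sample(seq_len(n), m, replace = TRUE),
      pre_kind = "conventional_presyn", post_kind = "psd",
      depth = 5, diameter_nm = 250)
    ctc <- ctc[ctc$pre_cell != ctc$post_cell, ]
    if (nrow(ctc) == 0 || !any(c(ctc$pre_cell, ctc$post_cell) == 1)) next
    contacts <- resolve_contacts(build_db(cellsn, ctc))
    h <- hop_distances(build_graph(contacts, cellsn), "AII")
    # BFS on the undirected adjacency list
    adj <- lapply(seq_len(n), function(v) integer(0))
    for (r in seq_len(nrow(ctc))) {
      adj[[ctc$pre_cell[r]]] <- c(adj[[ctc$pre_cell[r]]], ctc$post_cell[r])
      adj[[ctc$post_cell[r]]] <- c(adj[[ctc$post_cell[r]]], ctc$pre_cell[r])
    }
    dist <- rep(Inf, n)
    frontier <- which(cls == "AII")
    dist[frontier] <- 0
    hop <- 0
    while (length(frontier) > 0) {
      hop <- hop + 1
      nxt <- setdiff(unique(unlist(adj[frontier])), which(is.finite(dist)))
      dist[nxt] <- hop
      frontier <- nxt
    }
    present <- h$per_node$cell_id
    expect_equal(h$per_node$hops, dist[present])
  }
})

test_that("class contact matrix conserves marginals", {
  cells <- tibble::tibble(cell_id = 1:2, cell_class = c("RodBC", "AII"))
  one <- resolve_contacts(build_db(cells, tibble::tibble(
    pre_cell = 1L, post_cell = 2L, pre_kind = "ribbon_presyn",
    post_kind = "psd", depth = 20, diameter_nm = 250)))
  m1 <- class_contact_matrix(one, cells)
  expect_equal(nrow(m1$matrix), 1)
  expect_equal(m1$n_partner_classes, 1)

  b <- default_bundle()
  mat <- class_contact_matrix(b$contacts, b$db$cells)
  expect_equal(sum(mat$matrix$n_contacts), nrow(b$contacts))
  expect_equal(sum(mat$matrix$total_area_um2), sum(b$contacts$area_um2),
               tolerance = 1e-9)
  # planted census recount
  want <- b$ledger$contacts |>
    dplyr::count(category) |>
    dplyr::arrange(category)
  got <- b$contacts |>
    dplyr::count(category) |>
    dplyr::arrange(category)
  expect_equal(got, want)
  # the AII partner repertoire spans many classes (hub behaviour)
  expect_gte(mat$n_partner_classes, 10)
})

test_that("weight report ratios follow their definitions", {
  mk <- function(category, n, area_each) {
    tibble::tibble(category = rep(category, n), area_um2 = area_each,
                   kind = "x", pre_cell = 1L, post_cell = 2L)
  }
  eq <- dplyr::bind_rows(
    mk("AC_input_ON", 4, 0.25), mk("rodBC_input", 4, 0.25),
    mk("AC_input_OFF", 4, 0.25), mk("OFF_BC_input", 4, 0.25),
    mk("TH1_input", 4, 0.25),
    mk("coupling_AII_CBb", 4, 0.25))
  wr <- weight_report(eq)
  expect_equal(wr$ratios$on_ac_to_rodbc, 1)
  expect_equal(wr$ratios$ac_lobule_to_offbc, 1)
  # per-endpoint convention doubles homocellular area; with no homocellular
  # contacts the coupling ratio is 0
  expect_equal(wr$ratios$coupling_homo_to_hetero, 0)
  expect_equal(wr$ratios$th1_to_coupling, 1)

  homo <- dplyr::bind_rows(mk("coupling_AII_AII", 7, 0.5),
                           mk("coupling_AII_CBb", 2, 0.5))
  expect_equal(weight_report(homo)$ratios$coupling_homo_to_hetero, 7)

  none <- mk("rodBC_input", 2, 0.1)
  wr0 <- weight_report(none)
  expect_true(is.na(wr0$ratios$on_ac_to_rodbc) ||
                wr0$ratios$on_ac_to_rodbc == 0)
  expect_true("coupling_homo_to_hetero" %in% wr0$undefined)
})

test_that("every non-AII neuron is within two hops of the AII set", {
  b <- default_bundle()
  h <- b$hops
  non_aii <- h$per_node[h$per_node$cell_class != "AII", ]
  expect_true(all(non_aii$hops <= 2))
  expect_gt(h$frac_within_1, 0.4)
})
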