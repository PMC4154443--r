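test_that("feret diameter is the max disc diameter over slices", {
  expect_equal(feret_diameter(tibble::tibble(radius_nm = 133.5)), 267)
  expect_equal(feret_diameter(tibble::tibble(radius_nm = c(100, 250, 180))), 500)
  expect_error(feret_diameter(tibble::tibble(radius_nm = double())), "no discs")
})

test_that("contact area sums diameter x thickness over slices", {
  expect_equal(structure_area(tibble::tibble(radius_nm = 250), 80), 0.04)
  expect_equal(structure_area(tibble::tibble(radius_nm = rep(125, 5)), 80), 0.10)
  expect_error(structure_area(tibble::tibble(radius_nm = c(100, 0)), 80), "zero")
})

test_that("feret and area match brute-force oracles on random stacks", {
  set.seed(404)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    r <- runif(n, 10, 900)
    t_nm <- runif(1, 70, 90)
    discs <- tibble::tibble(radius_nm = r)
    # exhaustive scan oracle
    fmax <- -Inf
    asum <- 0
    for (j in seq_len(n)) {
      if (2 * r[j] > fmax) fmax <- 2 * r[j]
      asum <- asum + 2 * r[j] * t_nm
    }
    expect_identical(feret_diameter(discs), fmax)
    expect_equal(structure_area(discs, t_nm), asum / 1e6, tolerance = 1e-12)
    # invariance under disc reordering
    perm <- sample.int(n)
    expect_identical(feret_diameter(discs[perm, , drop = FALSE]),
                     feret_diameter(discs))
    expect_equal(structure_area(discs[perm, , drop = FALSE], t_nm),
                 structure_area(discs, t_nm))
  }
})

test_that("IPL depth is a linear map anchored at the layer borders", {
  meta <- test_meta()
  expect_equal(ipl_depth(meta$ipl_top_z, meta), 0)
  expect_equal(ipl_depth(meta$ipl_bottom_z, meta), 25)
  expect_equal(ipl_depth((meta$ipl_top_z + meta$ipl_bottom_z) / 2, meta), 12.5)
  expect_equal(depth_to_z(ipl_depth(123, meta), meta), 123)
})

test_that("compartments partition the depth axis at 0/10/15", {
  expect_equal(assign_compartment(c(-2, 5, 12, 20)),
               c("neck", "lobule", "waist", "arboreal"))
  expect_equal(assign_compartment(c(0, 10, 15)),
               c("lobule", "waist", "arboreal"))
  expect_equal(sublamina(c(5, 9.99, 10, 20)), c("OFF", "OFF", "ON", "ON"))
})

test_that("contacts resolve with the right categories and compartments", {
  cells <- tibble::tibble(cell_id = c(476L, 419L, 2L, 3L),
                          cell_class = c("AII", "CBb5-6i", "RodBC", "TH1"))
  db <- build_db(cells, tibble::tibble(
    pre_cell = c(2L, 476L, 3L),
    post_cell = c(476L, 419L, 476L),
    pre_kind = c("ribbon_presyn", "gap_junction", "conventional_presyn"),
    post_kind = c("psd", "gap_junction", "psd"),
    depth = c(20, 18, -1), diameter_nm = c(250, 300, 200)))
  contacts <- resolve_contacts(db)
  expect_equal(nrow(contacts), 3)
  rod <- contacts[contacts$kind == "ribbon_input", ]
  expect_equal(rod$category, "rodBC_input")
  expect_equal(rod$post_compartment, "arboreal")
  gj <- contacts[contacts$kind == "gap_junction", ]
  expect_equal(gj$category, "coupling_AII_CBb")
  expect_equal(sort(c(gj$pre_cell, gj$post_cell)), c(419, 476))
  th1 <- contacts[contacts$category == "TH1_input", ]
  expect_equal(th1$pre_compartment, "neck")
  # single-slice discs: area = diameter x thickness, diameter = planted
  expect_equal(rod$diameter_nm, 250)
  expect_equal(rod$area_um2, 250 * 80 / 1e6)
})

test_that("a link between two presynaptic structures is malformed", {
  cells <- tibble::tibble(cell_id = 1:2, cell_class = c("AII", "RodBC"))
  db <- build_db(cells, tibble::tibble(
    pre_cell = 2L, post_cell = 1L,
    pre_kind = "ribbon_presyn", post_kind = "conventional_presyn",
    depth = 20, diameter_nm = 250))
  expect_error(resolve_contacts(db), "malformed link")
})

test_that("resolved contacts recover the generator's planted ledger", {
  b <- default_bundle()
  contacts <- b$contacts
  plan <- b$ledger$contacts
  expect_equal(nrow(contacts), nrow(plan))
  # per-category counts and areas agree exactly
  got <- contacts |>
    dplyr::count(category) |>
    dplyr::arrange(category)
  want <- plan |>
    dplyr::count(category) |>
    dplyr::arrange(category)
  expect_equal(got, want)
  # per-contact join on the planted pre structure: diameter and area exact
  j <- dplyr::inner_join(
    dplyr::select(contacts, pre_structure, diameter_nm, area_um2),
    dplyr::select(plan, pre_structure, d0 = diameter_nm, a0 = area_um2),
    by = "pre_structure")
  expect_equal(nrow(j), nrow(plan))
  expect_equal(j$diameter_nm, j$d0, tolerance = 1e-12)
  expect_equal(j$area_um2, j$a0, tolerance = 1e-12)
})

test_that("depth profiles conserve category area and respect binning", {
  empty <- depth_profile(
    tibble::tibble(category = character(), depth = double(),
                   area_um2 = double()),
    categories = "rodBC_input")
  expect_true(all(empty$area_um2 == 0))

  one <- depth_profile(tibble::tibble(category = "rodBC_input", depth = 7.3,
                                      area_um2 = 0.42))
  expect_equal(one$area_um2[one$bin_lo == 7], 0.42)
  expect_equal(sum(one$area_um2), 0.42)

  b <- default_bundle()
  prof <- b$depth_profiles
  per_cat <- b$contacts |>
    dplyr::group_by(category) |>
    dplyr::summarise(area = sum(area_um2))
  for (cc in per_cat$category) {
    expect_equal(sum(prof$area_um2[prof$category == cc]),
                 per_cat$area[per_cat$category == cc],
                 tolerance = 1e-9)
  }
})

test_that("outputs and coupling are depth-segregated on compliant volumes", {
  b <- default_bundle()
  out <- b$contacts[grepl("^output_", b$contacts$category), ]
  coup <- b$contacts[grepl("^coupling_", b$contacts$category), ]
  expect_gt(nrow(out), 0)
  expect_gt(nrow(coup), 0)
  expect_true(all(out$depth < 10))
  expect_true(all(coup$depth >= 10))
  # zero bin overlap
  prof <- b$depth_profiles
  out_bins <- unique(prof$bin_lo[grepl("^output_", prof$category) &
                                   prof$area_um2 > 0])
  coup_bins <- unique(prof$bin_lo[grepl("^coupling_", prof$category) &
                                    prof$area_um2 > 0])
  expect_length(intersect(out_bins, coup_bins), 0)
})

test_that("lateral spread measures zone extents per cell", {
  cells <- tibble::tibble(cell_id = 1L, cell_class = "AII",
                          soma_x_nm = 50000, soma_y_nm = 50000)
  meta <- test_meta()
  z <- as.integer(round(depth_to_z(20, meta)))
  db <- annotation_db(
    meta, dplyr::mutate(cells, polarity = "ON-OFF", transmitter = "glycine"),
    tibble::tibble(structure_id = 1L, kind = "cell", parent_cell = 1L),
    tibble::tibble(structure_id = 1L, z = z, x_nm = c(50000, 60000),
                   y_nm = 50000, radius_nm = 500),
    tibble::tibble(structure_id = integer(), linked_id = integer()))
  ls1 <- lateral_spread(db, 1L, "arboreal")
  expect_equal(ls1$mean_um, 10)
  expect_equal(ls1$sd_um, 0)
  expect_true(ls1$single_cell)
  expect_error(lateral_spread(db, integer(), "arboreal"), "at least one")
})

test_that("lateral spread equals the pairwise-distance oracle and SD 0 for clones", {
  set.seed(91)
  meta <- test_meta()
  z <- as.integer(round(depth_to_z(18, meta)))
  n_pts <- 7
  base <- tibble::tibble(dx = runif(n_pts, -30000, 30000),
                         dy = runif(n_pts, -30000, 30000))
  centers <- c(60000, 120000, 180000)
  cells <- tibble::tibble(cell_id = 1:3, cell_class = "AII",
                          polarity = "ON-OFF", transmitter = "glycine",
                          soma_x_nm = centers, soma_y_nm = 100000)
  discs <- purrr::map(1:3, function(i) {
    tibble::tibble(structure_id = i, z = z, x_nm = centers[i] + base$dx,
                   y_nm = 100000 + base$dy, radius_nm = 400)
  }) |> purrr::list_rbind()
  db <- annotation_db(
    meta, cells,
    tibble::tibble(structure_id = 1:3, kind = "cell", parent_cell = 1:3),
    discs, tibble::tibble(structure_id = integer(), linked_id = integer()))
  ls3 <- lateral_spread(db, 1:3, "arboreal")
  # identical (translated) arbors: SD exactly 0
  expect_equal(ls3$sd_um, 0)
  # brute-force max pairwise distance
  dmax <- 0
  for (i in seq_len(n_pts)) for (j in seq_len(n_pts)) {
    dd <- sqrt((base$dx[i] - base$dx[j])^2 + (base$dy[i] - base$dy[j])^2)
    if (dd > dmax) dmax <- dd
  }
  expect_equal(ls3$mean_um, dmax / 1e3, tolerance = 1e-12)
})

test_that("convex hull fields match known polygons and a gift-wrap oracle", {
  meta <- test_meta()
  z <- as.integer(round(depth_to_z(20, meta)))
  mk <- function(x_um, y_um) {
    cells <- tibble::tibble(cell_id = 1L, cell_class = "AII",
                            polarity = "ON-OFF", transmitter = "glycine",
                            soma_x_nm = 0, soma_y_nm = 0)
    annotation_db(meta, cells,
                  tibble::tibble(structure_id = 1L, kind = "cell",
                                 parent_cell = 1L),
                  tibble::tibble(structure_id = 1L, z = z, x_nm = x_um * 1e3,
                                 y_nm = y_um * 1e3, radius_nm = 300),
                  tibble::tibble(structure_id = integer(),
                                 linked_id = integer()))
  }
  sq <- convex_hull_field(mk(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1L, "arboreal")
  expect_equal(sq$area_um2, 1)
  tr <- convex_hull_field(mk(c(0, 4, 0), c(0, 0, 3)), 1L, "arboreal")
  expect_equal(tr$area_um2, 6)
  expect_error(convex_hull_field(mk(c(0, 1), c(0, 0)), 1L, "arboreal"),
               "degenerate")
  expect_error(convex_hull_field(mk(c(0, 1, 2), c(0, 1, 2)), 1L, "arboreal"),
               "degenerate")

  # gift-wrapping (Jarvis march) area oracle on random point sets
  jarvis_area <- function(x, y) {
    pts <- unique(cbind(x, y))
    n <- nrow(pts)
    start <- which.min(pts[, 1])
    hull <- start
    repeat {
      p <- hull[length(hull)]
      cand <- setdiff(seq_len(n), p)
      q <- cand[1]
      for (r in cand[-1]) {
        cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
          (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
        if (cr < 0 || (cr == 0 &&
                       sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2))) {
          q <- r
        }
      }
      if (q == start) break
      hull <- c(hull, q)
    }
    hx <- pts[hull, 1]; hy <- pts[hull, 2]
    j <- c(length(hx), seq_len(length(hx) - 1))
    abs(sum(hx[j] * hy - hx * hy[j])) / 2
  }
  set.seed(15)
  for (i in 1:50) {
    x <- runif(sample(4:12, 1), 0, 50)
    y <- runif(length(x), 0, 50)
    got <- convex_hull_field(mk(x, y), 1L, "arboreal")
    expect_equal(got$area_um2, jarvis_area(x, y), tolerance = 1e-9)
  }
})
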