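# Contact planting. Each planted contact is one row of a "plan": the two
# parent cells, the structure kinds on each side, an intended Feret
# diameter, a position and a depth. Assembly slices each plan row once and
# gives both linked child structures the same disc stack, so the analysis
# pipeline recovers the planted diameter and area exactly.

plan_row <- function(pre_cell, post_cell, pre_kind, post_kind, category,
                     diameter_nm, x_nm, y_nm, depth) {
  tibble(pre_cell = pre_cell, post_cell = post_cell, pre_kind = pre_kind,
         post_kind = post_kind, category = category,
         diameter_nm = diameter_nm, x_nm = x_nm, y_nm = y_nm, depth = depth)
}

# nearest-cell candidate lookup: for each query point, ids of target cells
# within reach_um (falling back to the single nearest)
nearby_cells <- function(qx, qy, targets, reach_um) {
  purrr::map(seq_along(qx), function(i) {
    d <- sqrt((targets$soma_x_nm - qx[i])^2 + (targets$soma_y_nm - qy[i])^2) / 1e3
    hit <- targets$cell_id[d <= reach_um]
    if (length(hit) == 0) targets$cell_id[which.min(d)] else hit
  })
}

#' Plant rule-compliant contacts for a generated cell inventory
#'
#' Draws every contact cohort of the default study conditions — rod bipolar
#' ribbon input balanced across AII cells, homo- and heterocellular gap
#' junctions, CBb7 ribbons and coupling, OFF cone bipolar input, amacrine
#' and TH1 input, lobular outputs (including the fully honoured OFF alpha
#' ganglion cell encounters), AI adherens and non-synaptic ganglion cell
#' touches — at depths and compartments where the default rule set permits
#' them. ON amacrine and TH1 synapse sizes are calibrated so the planted
#' area ratios match the configured targets.
#'
#' @param config A [generator_config()].
#' @param inventory Output of [generate_cells()].
#' @return List with `plan` (one row per planted contact) and bookkeeping
#'   tibbles `per_rodbc_ribbons`, `per_aii_intake`.
#' @export
generate_contacts <- function(config, inventory) {
  set.seed(stage_seed(config$seed, 3))
  cells <- inventory$cells
  meta <- inventory$meta
  by_class <- function(cl) filter(cells, .data$cell_class %in% cl)
  aii <- by_class("AII")
  rodbc <- by_class("RodBC")
  cba <- by_class(class_group_members("CBa"))
  cbb <- by_class(class_group_members("CBb"))
  cbb7 <- by_class("CBb7")
  plan <- list()

  syn_d <- function(n) rnorm_trunc(n, config$syn_diameter_mean_nm,
                                   config$syn_diameter_sd_nm, 80, 800)
  jit <- function(n, um) rnorm(n, 0, um * 1e3)

  ## --- rod bipolar ribbons ---
  # Two regulated distributions coexist: rod bipolar cells express a set
  # number of ribbons (~31 +/- 3.9) while AII cells regulate their ribbon
  # intake (~75.6 +/- 3) regardless of how many rod bipolar cells their
  # arbor happens to overlap ("cells count synapses, not cells"). Each AII
  # draws an intake quota and fills it from the residual ribbon supply of
  # rod bipolar cells within its rod-input field; leftover ribbons target
  # wide-field GABAergic amacrine cells (the other dyad partners).
  per_rodbc <- integer(0)
  per_aii_intake <- integer(0)
  if (nrow(rodbc) > 0 && nrow(aii) > 0) {
    supply <- pmax(1L, as.integer(round(rnorm_trunc(
      nrow(rodbc), config$ribbons_per_rodbc_mean, config$ribbons_per_rodbc_sd,
      lo = 0.5))))
    per_rodbc <- supply
    quota <- pmax(0L, as.integer(round(rnorm(
      nrow(aii), config$aii_ribbon_intake_mean, config$aii_ribbon_intake_sd))))
    remaining <- supply
    cand <- nearby_cells(aii$soma_x_nm, aii$soma_y_nm, rodbc,
                         config$rod_input_field_um / 2)
    cand_idx <- purrr::map(cand, function(ids) match(ids, rodbc$cell_id))
    alloc <- matrix(0L, nrow = nrow(rodbc), ncol = nrow(aii))
    for (i in sample.int(nrow(aii))) {
      loc <- cand_idx[[i]]
      for (k in seq_len(quota[i])) {
        pool <- loc[remaining[loc] > 0]
        if (length(pool) == 0) {
          # local supply exhausted: reach to the nearest rod bipolar cell
          # that still has ribbons
          open <- which(remaining > 0)
          if (length(open) == 0) break
          d <- (rodbc$soma_x_nm[open] - aii$soma_x_nm[i])^2 +
            (rodbc$soma_y_nm[open] - aii$soma_y_nm[i])^2
          j <- open[which.min(d)]
        } else {
          j <- pool[which.max(remaining[pool])]
        }
        alloc[j, i] <- alloc[j, i] + 1L
        remaining[j] <- remaining[j] - 1L
      }
    }
    per_aii_intake <- colSums(alloc)
    hit <- which(alloc > 0, arr.ind = TRUE)
    pre_idx <- rep(hit[, 1], times = alloc[hit])
    post_idx <- rep(hit[, 2], times = alloc[hit])
    n <- length(pre_idx)
    plan$rod <- plan_row(rodbc$cell_id[pre_idx], aii$cell_id[post_idx],
                         "ribbon_presyn", "psd", "rodBC_input", syn_d(n),
                         rodbc$soma_x_nm[pre_idx] + jit(n, 5),
                         rodbc$soma_y_nm[pre_idx] + jit(n, 5),
                         runif(n, 15.5, 24.5))
    gac_pool <- by_class("gammaAC")$cell_id
    if (length(gac_pool) > 0 && sum(remaining) > 0) {
      pre_idx <- rep(seq_len(nrow(rodbc)), times = remaining)
      n <- length(pre_idx)
      plan$rod_other <- plan_row(
        rodbc$cell_id[pre_idx],
        gac_pool[sample.int(length(gac_pool), n, replace = TRUE)],
        "ribbon_presyn", "psd", "other", syn_d(n),
        rodbc$soma_x_nm[pre_idx] + jit(n, 5),
        rodbc$soma_y_nm[pre_idx] + jit(n, 5),
        runif(n, 15.5, 24.5))
    }
  }

  ## --- homocellular AII::AII gap junctions at arboreal overlaps ---
  if (nrow(aii) >= 2 && config$n_gj_homo > 0) {
    dmat <- as.matrix(dist(cbind(aii$soma_x_nm, aii$soma_y_nm))) / 1e3
    pairs <- which(upper.tri(dmat) & dmat < config$arboreal_span_um, arr.ind = TRUE)
    if (nrow(pairs) == 0) {
      pairs <- which(upper.tri(dmat), arr.ind = TRUE)
    }
    pick <- pairs[sample.int(nrow(pairs), config$n_gj_homo, replace = TRUE), ,
                  drop = FALSE]
    dd <- rnorm_trunc(config$n_gj_homo, config$gj_homo_mean_nm,
                      config$gj_homo_sd_nm, config$gj_trunc_nm[1],
                      config$gj_trunc_nm[2])
    plan$gj_homo <- plan_row(
      aii$cell_id[pick[, 1]], aii$cell_id[pick[, 2]],
      "gap_junction", "gap_junction", "coupling_AII_AII", dd,
      (aii$soma_x_nm[pick[, 1]] + aii$soma_x_nm[pick[, 2]]) / 2 +
        jit(config$n_gj_homo, 5),
      (aii$soma_y_nm[pick[, 1]] + aii$soma_y_nm[pick[, 2]]) / 2 +
        jit(config$n_gj_homo, 5),
      runif(config$n_gj_homo, 15.5, 24.5))
  }

  ## --- CBb7 cells: ribbons AND coupling onto the same partner AII ---
  # Each CBb7 picks a primary AII partner; its 1-3 ribbons and its first
  # gap junction target that cell's arboreal zone (an encountered ON cone
  # bipolar cell is always coupled), with any further gap junctions spread
  # over neighbouring AII cells.
  n_gj7 <- 0L
  if (nrow(cbb7) > 0 && nrow(aii) > 0) {
    cand7 <- nearby_cells(cbb7$soma_x_nm, cbb7$soma_y_nm, aii, 60)
    primary <- purrr::map_int(cand7, function(v) if (length(v) == 1) v else sample(v, 1))
    n_rib7 <- sample(config$cbb7_ribbons_range[1]:config$cbb7_ribbons_range[2],
                     nrow(cbb7), replace = TRUE)
    n7 <- sample(config$cbb7_gj_range[1]:config$cbb7_gj_range[2],
                 nrow(cbb7), replace = TRUE)
    rib_src <- rep(seq_len(nrow(cbb7)), times = n_rib7)
    n <- length(rib_src)
    plan$cbb7_rib <- plan_row(cbb7$cell_id[rib_src], primary[rib_src],
                              "ribbon_presyn", "psd", "CBb7_ribbon_input",
                              syn_d(n),
                              cbb7$soma_x_nm[rib_src] + jit(n, 10),
                              cbb7$soma_y_nm[rib_src] + jit(n, 10),
                              runif(n, 15.5, 24.5))
    gj_src <- rep(seq_len(nrow(cbb7)), times = n7)
    first_gj <- !duplicated(gj_src)
    gj_post <- purrr::map_int(seq_along(gj_src), function(k) {
      i <- gj_src[k]
      if (first_gj[k] || length(cand7[[i]]) == 1) primary[i]
      else sample(cand7[[i]], 1)
    })
    n <- length(gj_src)
    n_gj7 <- n
    dd <- rnorm_trunc(n, config$gj_hetero_mean_nm, config$gj_hetero_sd_nm,
                      config$gj_trunc_nm[1], config$gj_trunc_nm[2])
    plan$cbb7_gj <- plan_row(cbb7$cell_id[gj_src], gj_post,
                             "gap_junction", "gap_junction", "coupling_AII_CBb",
                             dd,
                             cbb7$soma_x_nm[gj_src] + jit(n, 10),
                             cbb7$soma_y_nm[gj_src] + jit(n, 10),
                             # the partner-consistent first junction sits in
                             # the arboreal zone with the ribbons
                             ifelse(first_gj, runif(n, 15.5, 24.5),
                                    runif(n, 10.5, 24.5)))
  }

  ## --- heterocellular AII::CBb coupling (non-CBb7 balance) ---
  if (nrow(aii) > 0 && nrow(cbb) > 0 && config$n_gj_hetero > n_gj7) {
    n_rest <- config$n_gj_hetero - n_gj7
    bc_ids <- sample(cbb$cell_id, n_rest, replace = TRUE)
    bc <- cells[match(bc_ids, cells$cell_id), ]
    cand <- nearby_cells(bc$soma_x_nm, bc$soma_y_nm, aii, 40)
    post <- purrr::map_int(cand, function(v) if (length(v) == 1) v else sample(v, 1))
    dd <- rnorm_trunc(n_rest, config$gj_hetero_mean_nm, config$gj_hetero_sd_nm,
                      config$gj_trunc_nm[1], config$gj_trunc_nm[2])
    plan$gj_hetero <- plan_row(bc_ids, post, "gap_junction", "gap_junction",
                               "coupling_AII_CBb", dd,
                               bc$soma_x_nm + jit(n_rest, 5),
                               bc$soma_y_nm + jit(n_rest, 5),
                               runif(n_rest, 10.5, 24.5))
  }

  ## --- OFF cone bipolar ribbon input to lobules ---
  if (nrow(aii) > 0 && nrow(cba) > 0) {
    n_off <- sample(config$offbc_ribbons_range[1]:config$offbc_ribbons_range[2],
                    nrow(aii), replace = TRUE)
    post <- rep(aii$cell_id, times = n_off)
    tg <- cells[match(post, cells$cell_id), ]
    cand <- nearby_cells(tg$soma_x_nm, tg$soma_y_nm, cba, 30)
    pre <- purrr::map_int(cand, function(v) if (length(v) == 1) v else sample(v, 1))
    n <- length(post)
    plan$off_bc <- plan_row(pre, post, "ribbon_presyn", "psd", "OFF_BC_input",
                            syn_d(n),
                            tg$soma_x_nm + jit(n, config$lobule_reach_um / 2),
                            tg$soma_y_nm + jit(n, config$lobule_reach_um / 2),
                            runif(n, 0.5, 9.5))
  }

  ## --- amacrine conventional input, ON and OFF sublaminae ---
  gam <- by_class("gammaAC")
  if (nrow(aii) > 0 && nrow(gam) > 0) {
    mk_ac <- function(range, d_lo, d_hi, category, spread_um) {
      n_per <- sample(range[1]:range[2], nrow(aii), replace = TRUE)
      post <- rep(aii$cell_id, times = n_per)
      tg <- cells[match(post, cells$cell_id), ]
      pre <- sample(gam$cell_id, length(post), replace = TRUE)
      n <- length(post)
      plan_row(pre, post, "conventional_presyn", "psd", category, syn_d(n),
               tg$soma_x_nm + jit(n, spread_um), tg$soma_y_nm + jit(n, spread_um),
               runif(n, d_lo, d_hi))
    }
    plan$ac_on <- mk_ac(config$ac_on_per_aii_range, 10.5, 24.5, "AC_input_ON",
                        config$arboreal_span_um / 4)
    plan$ac_off <- mk_ac(config$ac_off_per_aii_range, 0.5, 9.5, "AC_input_OFF",
                         config$lobule_reach_um / 2)
  }

  ## --- TH1 axonal input at the neck ---
  th1 <- by_class("TH1")
  if (nrow(aii) > 0 && nrow(th1) > 0) {
    n_per <- sample(config$th1_per_aii_range[1]:config$th1_per_aii_range[2],
                    nrow(aii), replace = TRUE)
    post <- rep(aii$cell_id, times = n_per)
    tg <- cells[match(post, cells$cell_id), ]
    pre <- sample(th1$cell_id, length(post), replace = TRUE)
    n <- length(post)
    plan$th1 <- plan_row(pre, post, "conventional_presyn", "psd", "TH1_input",
                         syn_d(n), tg$soma_x_nm + jit(n, 3),
                         tg$soma_y_nm + jit(n, 3), runif(n, -2, -0.2))
  }

  ## --- lobular outputs: OFF cone bipolar, GABAergic amacrine, GCs ---
  gac <- by_class("GAC")
  mk_out <- function(range, targets, category) {
    if (nrow(aii) == 0 || nrow(targets) == 0) return(NULL)
    n_per <- sample(range[1]:range[2], nrow(aii), replace = TRUE)
    pre <- rep(aii$cell_id, times = n_per)
    src <- cells[match(pre, cells$cell_id), ]
    cand <- nearby_cells(src$soma_x_nm, src$soma_y_nm, targets, 30)
    post <- purrr::map_int(cand, function(v) if (length(v) == 1) v else sample(v, 1))
    n <- length(pre)
    plan_row(pre, post, "conventional_presyn", "psd", category, syn_d(n),
             src$soma_x_nm + jit(n, config$lobule_reach_um / 2),
             src$soma_y_nm + jit(n, config$lobule_reach_um / 2),
             runif(n, 0.5, 9.5))
  }
  plan$out_bc <- mk_out(config$out_bc_per_aii_range, cba, "output_BC")
  plan$out_ac <- mk_out(config$out_ac_per_aii_range, gac, "output_AC")

  ## --- the OFF alpha ganglion cell: every encountered lobule synapses ---
  offa <- by_class("OFF-alpha-GC")
  if (nrow(offa) > 0 && nrow(aii) >= 1 && config$n_offgc_synapses > 0) {
    n_src <- min(config$n_offgc_aii, nrow(aii))
    src_ids <- sample(aii$cell_id, n_src)
    pre <- c(src_ids,
             sample(src_ids, max(config$n_offgc_synapses - n_src, 0),
                    replace = TRUE))
    src <- cells[match(pre, cells$cell_id), ]
    n <- length(pre)
    plan$offgc <- plan_row(pre, offa$cell_id[1], "conventional_presyn", "psd",
                           "output_GC", syn_d(n),
                           src$soma_x_nm + jit(n, config$lobule_reach_um / 2),
                           src$soma_y_nm + jit(n, config$lobule_reach_um / 2),
                           runif(n, 0.5, 9.5))
  }

  ## --- sparse OFF delta ganglion cell output ---
  offd <- by_class("OFF-delta-GC")
  if (nrow(offd) > 0 && nrow(aii) > 0) {
    n <- min(6, nrow(aii))
    pre <- sample(aii$cell_id, n)
    src <- cells[match(pre, cells$cell_id), ]
    plan$offd <- plan_row(pre, sample(offd$cell_id, n, replace = TRUE),
                          "conventional_presyn", "psd", "output_GC", syn_d(n),
                          src$soma_x_nm + jit(n, config$lobule_reach_um / 2),
                          src$soma_y_nm + jit(n, config$lobule_reach_um / 2),
                          runif(n, 0.5, 9.5))
  }

  ## --- AI adherens at the arboreal level ---
  ai <- by_class("AI")
  if (nrow(ai) > 0 && nrow(aii) > 0 && config$n_ai_adherens > 0) {
    n <- config$n_ai_adherens
    a_ids <- sample(aii$cell_id, n, replace = TRUE)
    src <- cells[match(a_ids, cells$cell_id), ]
    plan$ai_adh <- plan_row(a_ids, sample(ai$cell_id, n, replace = TRUE),
                            "adherens", "adherens", "non_synaptic",
                            rnorm_trunc(n, 400, 80, 100, 800),
                            src$soma_x_nm + jit(n, 20),
                            src$soma_y_nm + jit(n, 20),
                            runif(n, 15.5, 24.5))
  }

  ## --- non-synaptic arboreal touches with ganglion cells ---
  gcs <- by_class(c("OFF-alpha-GC", "OFF-delta-GC"))
  if (nrow(gcs) > 0 && nrow(aii) > 0 && config$n_gc_touches > 0) {
    n <- config$n_gc_touches
    a_ids <- sample(aii$cell_id, n, replace = TRUE)
    src <- cells[match(a_ids, cells$cell_id), ]
    plan$gc_touch <- plan_row(a_ids, sample(gcs$cell_id, n, replace = TRUE),
                              "touch", "touch", "non_synaptic", 200,
                              src$soma_x_nm + jit(n, 25),
                              src$soma_y_nm + jit(n, 25),
                              runif(n, 15.5, 24.5))
  }

  plan <- list_rbind(purrr::compact(plan))

  ## --- calibrate planted area ratios (ON amacrine vs rod; TH1 vs coupling)
  # realised area after slicing is ~quadratic in diameter; two fixed-point
  # passes bring the planted ratio within a fraction of a percent
  realised_area <- function(d) {
    # area of the sliced chord profile, um^2 (same convention as
    # structure_area); vectorised
    t_nm <- meta$section_thickness_nm
    half <- floor(d / (2 * t_nm))
    purrr::map_dbl(seq_along(d), function(i) {
      u <- (-half[i]:half[i]) * t_nm
      chord <- d[i] * sqrt(pmax(0, 1 - (2 * u / d[i])^2))
      chord[half[i] + 1] <- d[i]
      sum(chord * t_nm) / NM2_PER_UM2
    })
  }
  rescale_category <- function(plan, category, target_area) {
    idx <- which(plan$category == category)
    if (length(idx) == 0 || target_area <= 0) return(plan)
    for (pass in 1:2) {
      cur <- sum(realised_area(plan$diameter_nm[idx]))
      s <- sqrt(target_area / cur)
      plan$diameter_nm[idx] <- pmin(pmax(plan$diameter_nm[idx] * s, 60), 3000)
    }
    plan
  }
  area_rod <- sum(realised_area(plan$diameter_nm[plan$category == "rodBC_input"]))
  plan <- rescale_category(plan, "AC_input_ON",
                           config$ratio_on_ac_to_rodbc * area_rod)
  area_coupling <- sum(realised_area(
    plan$diameter_nm[plan$category %in% c("coupling_AII_AII", "coupling_AII_CBb")]))
  plan <- rescale_category(plan, "TH1_input",
                           config$ratio_th1_to_coupling * area_coupling)

  list(
    plan = plan,
    per_rodbc_ribbons = tibble(cell_id = rodbc$cell_id,
                               n_ribbons = per_rodbc),
    per_aii_intake = tibble(
      cell_id = aii$cell_id,
      n_ribbons = if (length(per_aii_intake) == nrow(aii))
        as.integer(per_aii_intake) else integer(nrow(aii)))
  )
}

#' Generate a complete synthetic connectome with planted truth
#'
#' Runs the full generator: mosaic, cell inventory, contact planting and
#' slicing to per-section disc annotations, returning a referentially
#' complete [annotation_db()] plus the planted-truth ledger the analysis
#' pipeline is expected to recover.
#'
#' @param config A [generator_config()].
#' @return List with `db` (an `annotation_db`), `ledger` (list: `mosaic`,
#'   `contacts` with realised structure ids and areas, `per_rodbc_ribbons`,
#'   `per_aii_intake`, `category_areas`) and `config`.
#' @export
generate_connectome <- function(config = generator_config()) {
  n_aii <- if ("AII" %in% names(config$census)) config$census[["AII"]] else 0
  mosaic <- if (n_aii > 0) {
    generate_mosaic(config)
  } else {
    tibble(x_um = double(), y_um = double())
  }
  inventory <- generate_cells(config, mosaic)
  meta <- inventory$meta
  if (nrow(inventory$cells) == 0) {
    db <- annotation_db(meta, inventory$cells, inventory$structures,
                        inventory$discs,
                        tibble(structure_id = integer(), linked_id = integer()))
    return(list(db = db,
                ledger = list(mosaic = mosaic, contacts = tibble(),
                              per_rodbc_ribbons = tibble(),
                              per_aii_intake = tibble(),
                              category_areas = tibble()),
                config = config))
  }
  contacts <- generate_contacts(config, inventory)
  plan <- contacts$plan

  # assign structure ids: pre then post, after the cell scaffolds
  id0 <- max(inventory$structures$structure_id)
  n <- nrow(plan)
  plan$pre_structure <- id0 + seq_len(n)
  plan$post_structure <- id0 + n + seq_len(n)

  child_structures <- dplyr::bind_rows(
    tibble(structure_id = plan$pre_structure, kind = plan$pre_kind,
           parent_cell = plan$pre_cell),
    tibble(structure_id = plan$post_structure, kind = plan$post_kind,
           parent_cell = plan$post_cell)
  )

  sliced <- slice_many(plan$diameter_nm, depth_to_z(plan$depth, meta),
                       plan$x_nm, plan$y_nm, meta)
  child_discs <- dplyr::bind_rows(
    sliced |> mutate(structure_id = plan$pre_structure[.data$plan_row]),
    sliced |> mutate(structure_id = plan$post_structure[.data$plan_row])
  ) |>
    select("structure_id", "z", "x_nm", "y_nm", "radius_nm")

  # planted (realised) per-contact area, for the ledger
  t_nm <- meta$section_thickness_nm
  plan$area_um2 <- sliced |>
    group_by(.data$plan_row) |>
    summarise(a = sum(2 * .data$radius_nm * t_nm) / NM2_PER_UM2,
              .groups = "drop") |>
    arrange(.data$plan_row) |>
    dplyr::pull("a")

  # symmetric links stored once, smaller id first (holds by construction)
  links <- tibble(structure_id = plan$pre_structure,
                  linked_id = plan$post_structure)

  db <- annotation_db(
    meta,
    inventory$cells,
    dplyr::bind_rows(inventory$structures, child_structures),
    dplyr::bind_rows(inventory$discs, child_discs),
    links
  )
  category_areas <- plan |>
    group_by(.data$category) |>
    summarise(n_contacts = dplyr::n(),
              total_area_um2 = sum(.data$area_um2), .groups = "drop")
  list(
    db = db,
    ledger = list(
      mosaic = mosaic,
      contacts = plan,
      per_rodbc_ribbons = contacts$per_rodbc_ribbons,
      per_aii_intake = contacts$per_aii_intake,
      category_areas = category_areas
    ),
    config = config
  )
}
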