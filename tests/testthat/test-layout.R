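test_that("an anterior anchor lands on the forehead midline", {
  ph <- default_phantom()
  arr <- place_array(ph$volume, c(0, 1, 0.35), c(1, 0, 0))
  expect_lt(abs(arr$center[1]), ph$volume$grid$spacing[1])
  expect_gt(arr$center[2], 60)
})

test_that("every disc center sits on a scalp/air boundary voxel", {
  ph <- default_phantom()
  lay <- named_configuration("PA_HORIZONTAL", ph$volume)
  g <- ph$volume$grid
  lab <- ph$volume$labels
  surf <- lab == TISSUE_LABELS[["SCALP"]] &
    ttfplan:::neighbor_any(lab == TISSUE_LABELS[["AIR"]], g$shape)
  surf_xyz <- voxel_to_world(g, which(surf, arr.ind = TRUE) - 1L)
  discs <- layout_discs(lay)
  for (d in seq_len(nrow(discs))) {
    p <- as.numeric(discs[d, c("x", "y", "z")])
    nearest <- min(sqrt(colSums((t(surf_xyz) - p)^2)))
    expect_lt(nearest, sqrt(3) * max(g$spacing))
  }
})

test_that("named configurations are deterministic and validated", {
  ph <- mini_phantom()
  a <- named_configuration("PA_VERTICAL_CENTER", ph$volume)
  b <- named_configuration("PA_VERTICAL_CENTER", ph$volume)
  expect_identical(layout_discs(a), layout_discs(b))
  expect_error(named_configuration("SIDEWAYS", ph$volume), "SUPRATENTORIAL")
})

test_that("lateral PA shifts move the PA center by exactly the shift in x", {
  ph <- default_phantom()
  base <- named_configuration("PA_HORIZONTAL", ph$volume)
  right <- named_configuration("PA_HORIZONTAL_RIGHT", ph$volume)
  left <- named_configuration("PA_HORIZONTAL_LEFT", ph$volume)
  expect_equal(right$PA$center[1] - base$PA$center[1], 20)
  expect_equal(left$PA$center[1] - base$PA$center[1], -20)
  for (id in c("AP", "LEFT", "RIGHT")) {
    expect_identical(layout_discs(base)[layout_discs(base)$array == id, ],
                     layout_discs(right)[layout_discs(right)$array == id, ])
  }
})

test_that("PA anchor heights are ordered as the montage family intends", {
  ph <- default_phantom()
  z <- sapply(c("SUPRATENTORIAL", "PA_VERTICAL_SUPERIOR",
                "PA_VERTICAL_CENTER", "PA_HORIZONTAL"),
              function(nm) named_configuration(nm, ph$volume)$PA$center[3])
  expect_lt(z[["PA_VERTICAL_CENTER"]], z[["PA_VERTICAL_SUPERIOR"]])
  expect_lt(z[["PA_HORIZONTAL"]], z[["SUPRATENTORIAL"]])
})

test_that("left/right structures are mirror images on the symmetric phantom", {
  ph <- default_phantom()
  sup <- named_configuration("SUPRATENTORIAL", ph$volume)
  expect_equal(sup$LEFT$center * c(-1, 1, 1), sup$RIGHT$center,
               tolerance = 1e-9)
  l <- named_configuration("PA_HORIZONTAL_LEFT", ph$volume)
  r <- named_configuration("PA_HORIZONTAL_RIGHT", ph$volume)
  expect_equal(l$PA$center * c(-1, 1, 1), r$PA$center, tolerance = 1e-9)
  # the mirrored PA disc sets coincide as point sets
  ld <- layout_discs(l); rd <- layout_discs(r)
  lpts <- as.matrix(ld[ld$array == "PA", c("x", "y", "z")]) %*% diag(c(-1, 1, 1))
  rpts <- as.matrix(rd[rd$array == "PA", c("x", "y", "z")])
  ord1 <- order(round(lpts[, 1], 6), round(lpts[, 2], 6), round(lpts[, 3], 6))
  ord2 <- order(round(rpts[, 1], 6), round(rpts[, 2], 6), round(rpts[, 3], 6))
  expect_equal(lpts[ord1, ], rpts[ord2, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rasterization yields 36 disjoint gel-capped patches and is reversible", {
  ph <- default_phantom()
  lay <- named_configuration("SUPRATENTORIAL", ph$volume)
  rast <- rasterize_electrodes(lay, ph$volume)
  expect_length(rast$patches, 36)
  all_gel <- unlist(lapply(rast$patches, `[[`, "gel"))
  all_el <- unlist(lapply(rast$patches, `[[`, "electrode"))
  expect_true(all(lengths(lapply(rast$patches, `[[`, "gel")) > 0))
  expect_true(all(lengths(lapply(rast$patches, `[[`, "electrode")) > 0))
  expect_false(any(duplicated(c(all_gel, all_el))))

  # stripping GEL and ELECTRODE restores the anatomy exactly
  lab <- rast$volume$labels
  lab[lab %in% TISSUE_LABELS[c("GEL", "ELECTRODE")]] <- TISSUE_LABELS[["AIR"]]
  expect_identical(lab, ph$volume$labels)

  # electrodes touch tissue only through gel
  dims <- ph$volume$grid$shape
  scalp_or_skull <- array(rast$volume$labels %in%
                            TISSUE_LABELS[c("SCALP", "SKULL")], dim = dims)
  near_tissue <- ttfplan:::neighbor_any(scalp_or_skull, dims)
  expect_false(any(near_tissue[all_el]))
})

test_that("patch footprint area matches the disc area on a flat surface", {
  slab <- flat_slab_volume(spacing = 2)
  arr <- place_array(slab, c(0, 0, 1), c(1, 0, 0), disc_radius = 10,
                     pitch = 22, cast_from = c(1, 1, 1),
                     projection = "parallel")
  one <- structure(list(name = "one", params = list(), AP = arr),
                   class = "array_layout")
  rast <- rasterize_electrodes(one, slab)
  gel_counts <- lengths(lapply(rast$patches, `[[`, "gel"))
  analytic <- pi * 10^2 / (2 * 2)
  expect_true(all(abs(gel_counts - analytic) / analytic < 0.2))
})

test_that("overlapping or missing placements are rejected", {
  ph <- mini_phantom()
  expect_error(place_array(ph$volume, c(0, 1, 0), c(1, 0, 0),
                           disc_radius = 12, pitch = 22), "overlap")
  expect_error(cast_to_surface(ph$volume, c(500, 500, 500), c(1, 1, 1)),
               "does not intersect")
})

test_that("layouts serialize to JSON and back", {
  ph <- mini_phantom()
  lay <- named_configuration("SUPRATENTORIAL", ph$volume)
  path <- tempfile(fileext = ".json")
  write_layout(lay, path)
  discs <- read_layout_discs(path)
  expect_equal(nrow(discs), 36)
  expect_equal(discs$x, layout_discs(lay)$x, tolerance = 1e-12)
  expect_setequal(unique(discs$array), c("AP", "PA", "LEFT", "RIGHT"))
})
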