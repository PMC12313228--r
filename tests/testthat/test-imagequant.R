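test_that("segmentation recovers the rendered geometry", {
  gen <- generate_organ_image(small_spec(1L, 2L))
  truth_fg <- gen$image$channels$cytokeratin == 1
  otsu_mask <- segment_keratinocytes(gen$image, "cytokeratin", "otsu")
  fixed_mask <- segment_keratinocytes(gen$image, "cytokeratin", "fixed:0.5")
  expect_identical(unclass(otsu_mask)[, ], truth_fg)
  expect_identical(unclass(fixed_mask)[, ], truth_fg)
  expect_identical(attr(fixed_mask, "threshold"), 0.5)
})

test_that("segmentation survives moderate intensity noise", {
  spec <- small_spec(1L, 2L, noise_sd = 0.05, seed = 21L)
  noisy <- generate_organ_image(spec)
  clean <- generate_organ_image(small_spec(1L, 2L, noise_sd = 0, seed = 21L))
  mask <- segment_keratinocytes(noisy$image, "cytokeratin", "otsu")
  truth_fg <- clean$image$channels$cytokeratin == 1
  agreement <- mean(mask == truth_fg)
  expect_gte(agreement, 0.99)
})

test_that("constant channels error under Otsu with a helpful hint", {
  img <- structure(list(channels = list(cytokeratin = matrix(0.3, 20, 20)),
                        um_per_px = 1), class = "organ_image")
  expect_error(segment_keratinocytes(img, "cytokeratin", "otsu"), "fixed")
  expect_error(segment_keratinocytes(img, "nope"), "not found")
})

test_that("island extraction finds exactly the rendered islands", {
  gen <- generate_organ_image(small_spec(2L, 2L))
  mask <- segment_keratinocytes(gen$image)
  tbl <- extract_islands(mask, gen$image$um_per_px)
  expect_identical(sum(tbl$is_sheet), 1L)
  expect_identical(sum(!tbl$is_sheet), nrow(gen$truth$islands))

  sheet_only <- generate_organ_image(small_spec(0L, 0L))
  tbl0 <- extract_islands(segment_keratinocytes(sheet_only$image), 1)
  expect_identical(sum(!tbl0$is_sheet), 0L)
})

test_that("a 1-px diagonal bridge joins islands (8-connectivity contract)", {
  mask <- matrix(FALSE, 60, 60)
  mask[1:10, ] <- TRUE                 # sheet
  mask[30:35, 10:15] <- TRUE           # island A
  mask[37:42, 17:22] <- TRUE           # island B, diagonal gap
  mask[36, 16] <- TRUE                 # 1-px diagonal bridge
  tbl <- extract_islands(mask, 1)
  expect_identical(sum(!tbl$is_sheet), 1L)
})

test_that("images with no top-border component are rejected", {
  mask <- matrix(FALSE, 40, 40)
  mask[20:30, 5:35] <- TRUE
  expect_error(extract_islands(mask, 1), "orientation")
})

test_that("nuclei counts are exact on noise-free islands", {
  gen <- generate_organ_image(small_spec(1L, 1L))
  tbl <- measure_islands(gen$image)
  isl <- tbl |> dplyr::filter(!is_sheet) |> dplyr::arrange(centroid_col)
  truth <- gen$truth$islands |> dplyr::arrange(center_col)
  expect_identical(isl$nuclei_count, truth$nuclei_count)

  # zero DAPI signal counts zero
  lab <- attr(tbl, "label_matrix")
  blank <- gen$image
  blank$channels$dapi[] <- 0
  expect_identical(count_nuclei(blank, lab == isl$label[1]), 0L)
})

test_that("depth is measured from the sheet base and clamps at zero", {
  gen <- generate_organ_image(organ_image_spec(
    width_px = 260, height_px = 320, sheet_thickness_px = 40,
    n_singular_islands = 0L, n_clustered_islands = 1L,
    island_depths_px = 175L, island_radii_px = 25L, island_cols_px = 130L
  ))
  tbl <- measure_islands(gen$image)
  # deepest island pixel sits at row 40 + 175 + 25 = 240 -> depth 200 um
  expect_equal(invasion_depth(tbl), 200)

  sheet_only <- generate_organ_image(small_spec(0L, 0L))
  expect_equal(invasion_depth(measure_islands(sheet_only$image)), 0)
})

test_that("calibration scales depths linearly and areas quadratically", {
  gen <- generate_organ_image(small_spec(1L, 1L))
  mask <- segment_keratinocytes(gen$image)
  t1 <- extract_islands(mask, 1)
  t2 <- extract_islands(mask, 2)
  i1 <- t1 |> dplyr::filter(!is_sheet)
  i2 <- t2 |> dplyr::filter(!is_sheet)
  expect_equal(i2$depth_um, 2 * i1$depth_um)
  expect_equal(i2$area_um2, 4 * i1$area_um2)
  expect_identical(i2$area_px2, i1$area_px2)
})

test_that("raising a fixed threshold never grows the segmented area", {
  gen <- generate_organ_image(small_spec(1L, 2L, noise_sd = 0.1, seed = 31L))
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t) {
    sum(segment_keratinocytes(gen$image, method = t))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("LWR measurement matches the generating ellipse", {
  disc <- generate_cell_masks(1, 1, seed = 1)
  expect_lt(abs(measure_lwr(disc$masks)$lwr - 1), 0.02)

  two <- generate_cell_masks(20, 2, seed = 2)
  lwr <- measure_lwr(two$masks)$lwr
  expect_true(all(abs(lwr - 2) / 2 < 0.05))

  # rotation by 90 degrees leaves the moment ellipse unchanged
  m <- two$masks[[1]]
  m90 <- t(m)[ncol(m):1, , drop = FALSE]
  expect_equal(measure_lwr(list(m90))$lwr, measure_lwr(list(m))$lwr,
               tolerance = 1e-12)

  expect_error(measure_lwr(list(matrix(TRUE, 1, 12))), "degenerate")
  expect_error(measure_lwr(list(matrix(c(TRUE, rep(FALSE, 24)), 5, 5))),
               "fewer than 10")
})

test_that("mean marker intensity is a plain mask mean", {
  img <- structure(list(
    channels = list(pdpn = matrix(c(rep(0, 50), rep(1, 50)), 10, 10)),
    um_per_px = 1), class = "organ_image")
  expect_equal(mean_marker_intensity(img, matrix(TRUE, 10, 10), "pdpn"), 0.5)
  img$channels$pdpn[] <- 0.4
  expect_equal(mean_marker_intensity(img, matrix(TRUE, 10, 10), "pdpn"), 0.4)
  expect_error(mean_marker_intensity(img, matrix(FALSE, 10, 10), "pdpn"),
               "empty")

  # synthetic PDPN: islands at 0.8, sheet at 0.2
  gen <- generate_organ_image(small_spec(0L, 1L))
  tbl <- measure_islands(gen$image)
  isl <- tbl |> dplyr::filter(!is_sheet)
  lab <- attr(tbl, "label_matrix")
  expect_equal(mean_marker_intensity(gen$image, lab == isl$label[1], "pdpn"),
               0.8)
  expect_equal(mean_marker_intensity(gen$image,
                                     lab == attr(tbl, "sheet_label"), "pdpn"),
               0.2)
})
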