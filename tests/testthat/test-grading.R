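island_row <- function(nuclei, area = 100, depth = 50, dist = 30) {
  tibble::tibble(label = NA_integer_, is_sheet = FALSE, area_px2 = area,
                 area_um2 = area, centroid_row = 0, centroid_col = 0,
                 max_row = 0, min_distance_to_sheet_um = dist,
                 depth_um = depth, nuclei_count = nuclei)
}

sheet_row <- tibble::tibble(label = 1L, is_sheet = TRUE, area_px2 = 1000,
                            area_um2 = 1000, centroid_row = 0, centroid_col = 0,
                            max_row = 40, min_distance_to_sheet_um = 0,
                            depth_um = 0, nuclei_count = NA_integer_)

test_that("SPOI follows the printed rule including the zero conventions", {
  expect_equal(spoi_from_counts(3, 6)$spoi, 0.5)
  expect_equal(spoi_from_counts(0, 4)$spoi, 0)
  expect_false(spoi_from_counts(0, 0)$spoi_undefined)
  undef <- spoi_from_counts(2, 0)
  expect_true(undef$spoi_undefined)
  expect_equal(undef$spoi, 2)
})

test_that("an island with exactly 15 nuclei is clustered", {
  tbl <- dplyr::bind_rows(sheet_row, island_row(15), island_row(14))
  sp <- compute_spoi(tbl)
  expect_identical(sp$n_clustered, 1L)
  expect_identical(sp$n_singular, 1L)
  expect_equal(sp$spoi, 1)
})

test_that("invasion index is the area x count x depth product", {
  expect_equal(invasion_index(sheet_row), 0)
  five <- dplyr::bind_rows(sheet_row,
                           purrr::map(1:5, ~ island_row(20, area = 200)))
  expect_equal(invasion_index(five, image_depth_um = 200), 1000 * 5 * 200)
  doubled <- five |> dplyr::mutate(area_um2 = area_um2 * 2)
  expect_equal(invasion_index(doubled, 200), 2 * invasion_index(five, 200))
})

test_that("WPOI grading follows the worst-pattern precedence", {
  sheet_only <- sheet_row
  expect_identical(grade_wpoi(sheet_only, n_protrusions = 0), 1L)
  expect_identical(grade_wpoi(sheet_only, n_protrusions = 2), 2L)

  clustered <- dplyr::bind_rows(sheet_row, island_row(20), island_row(15))
  expect_identical(grade_wpoi(clustered), 3L)

  with_singular <- dplyr::bind_rows(clustered, island_row(10))
  expect_identical(grade_wpoi(with_singular), 4L)

  far <- dplyr::bind_rows(sheet_row, island_row(10, dist = 1200))
  expect_identical(grade_wpoi(far), 5L)

  # grade 5 wins over protrusions and over singular/clustered mix
  expect_identical(grade_wpoi(far, n_protrusions = 3), 5L)
})

test_that("adding islands never lowers the grade", {
  base3 <- dplyr::bind_rows(sheet_row, island_row(20))
  expect_identical(grade_wpoi(base3), 3L)
  plus_singular <- dplyr::bind_rows(base3, island_row(5))
  expect_identical(grade_wpoi(plus_singular), 4L)
  plus_far <- dplyr::bind_rows(plus_singular, island_row(20, dist = 1500))
  expect_identical(grade_wpoi(plus_far), 5L)
})

test_that("positive SPOI implies grade >= 4 unless the 1 mm override fired", {
  withr::with_seed(17, {
    for (i in 1:20) {
      ns <- sample(0:3, 1); nc <- sample(0:3, 1)
      if (ns + nc == 0) next
      tbl <- dplyr::bind_rows(
        sheet_row,
        purrr::map(seq_len(ns), ~ island_row(sample(1:14, 1))),
        purrr::map(seq_len(nc), ~ island_row(sample(15:25, 1)))
      )
      sp <- compute_spoi(tbl)
      w <- grade_wpoi(tbl)
      if (sp$spoi > 0 && w != 5L) expect_gte(w, 4L)
    }
  })
})

test_that("experiment aggregation averages fields into one sample", {
  nine <- tibble::tibble(experiment_id = "E1", image_id = paste0("f", 1:9),
                         invasion_index = 100, spoi = 0.5, wpoi = 4L)
  s <- aggregate_experiment(nine)
  expect_identical(nrow(s), 1L)
  expect_equal(s$invasion_index_mean, 100)
  expect_equal(s$invasion_index_sem, 0)
  expect_identical(s$wpoi_mode, 4L)

  two <- tibble::tibble(experiment_id = "E2", image_id = c("a", "b"),
                        invasion_index = c(0, 100), spoi = c(0, 1),
                        wpoi = c(3L, 3L))
  expect_warning(s2 <- aggregate_experiment(two), "field count")
  expect_equal(s2$invasion_index_mean, 50)

  expect_error(aggregate_experiment(nine[0, ]), "No field")
})

test_that("SPOI fold change flags division by a zero WOF mean", {
  expect_equal(spoi_fold_change(1, 0.5)$fold_change, 2)
  expect_equal(spoi_fold_change(0.7, 0.7)$fold_change, 1)
  z <- spoi_fold_change(1, 0)
  expect_true(z$undefined)
  expect_true(is.na(z$fold_change))
})

test_that("pipeline grading equals ground truth on rendered fixtures", {
  for (s in c(101L, 102L)) {
    gen <- generate_organ_image(random_organ_image_spec(s))
    expect_exact_recovery(gen, quantify_organ_image(gen$image))
  }

  # WPOI-2 and WPOI-5 geometries grade as expected end to end
  fingers <- generate_organ_image(small_spec(0L, 0L, front_protrusions = 2L))
  expect_identical(quantify_organ_image(fingers$image)$wpoi, 2L)

  far <- generate_organ_image(organ_image_spec(
    width_px = 200, height_px = 400, um_per_px = 4,
    n_singular_islands = 0L, n_clustered_islands = 1L,
    far_island_distance_um = 1000, seed = 5L
  ))
  expect_identical(far$truth$expected_wpoi, 5L)
  expect_identical(quantify_organ_image(far$image)$wpoi, 5L)
})
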