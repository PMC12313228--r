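# Small fixture builders shared across test files.

# A compact image spec that still exercises sheet + islands.
small_spec <- function(n_singular = 1L, n_clustered = 2L, ...) {
  organ_image_spec(
    width_px = 320L, height_px = 260L, sheet_thickness_px = 40L,
    n_singular_islands = n_singular, n_clustered_islands = n_clustered,
    nuclei_per_singular = 5L, nuclei_per_clustered = 16L,
    ...
  )
}

# Hand-built long Ct table: one replicate, explicit per-gene Ct offsets.
toy_ct_table <- function(pop_offsets, panel = pemt_panel(), gapdh_ct = 20) {
  purrr::imap(pop_offsets, function(off, pop) {
    tibble::tibble(
      population_id = pop,
      gene_id = c(panel, "GAPDH"),
      replicate = 1L,
      ct = c(rep(25 + off, length(panel)), gapdh_ct)
    )
  }) |> purrr::list_rbind()
}

expect_exact_recovery <- function(gen, quant) {
  truth <- gen$truth
  expect_identical(quant$n_islands, nrow(truth$islands))
  expect_identical(quant$n_singular, sum(truth$islands$is_singular))
  expect_identical(quant$n_clustered, sum(!truth$islands$is_singular))
  expect_equal(quant$spoi, truth$expected_spoi)
  expect_equal(quant$wpoi, truth$expected_wpoi)
  expect_equal(quant$invasion_index, truth$expected_invasion_index)
}
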