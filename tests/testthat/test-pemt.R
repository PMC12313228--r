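test_that("delta-Ct subtracts the matching reference-gene Ct", {
  ct <- tibble::tibble(
    population_id = "A", replicate = 1L,
    gene_id = c("PDPN", "VIM", "MMP1", "GAPDH"),
    ct = c(25, 20, 18, 20)
  )
  d <- compute_delta_ct(ct)
  expect_equal(d$delta_ct[d$gene_id == "PDPN"], 5)
  expect_equal(d$delta_ct[d$gene_id == "VIM"], 0)
  ct2 <- ct |> dplyr::mutate(ct = c(18, 20, 25, 21))
  expect_equal(compute_delta_ct(ct2)$delta_ct[1], -3)
})

test_that("missing reference gene errors name the block", {
  ct <- tibble::tibble(
    population_id = c("A", "A", "B"),
    replicate = 1L,
    gene_id = c("PDPN", "GAPDH", "PDPN"),
    ct = c(25, 20, 24)
  )
  expect_error(compute_delta_ct(ct), "B/rep1")
})

test_that("EXP transform matches the printed definition", {
  expect_equal(exp_transform(0), 100)
  expect_equal(exp_transform(5), 3.125)
  expect_equal(exp_transform(-1), 200)
  expect_error(exp_transform(NA_real_), "finite")
})

test_that("N_val and per-gene normalization follow the printed formula", {
  expect_equal(compute_nval(1, 100), 0)
  expect_equal(compute_nval(1, 1), 1)
  expect_equal(compute_nval(3.125, 100), 212.5 / 99)
  expect_error(compute_nval(2, 1), "exceed")

  # algebra on the formula: the normalized extremes are
  # (max - min)/99 and 100 (max - min)/99
  exp_min <- 3.125; exp_max <- 100
  nv <- compute_nval(exp_min, exp_max)
  expect_equal(normalize_gene(exp_min, nv), (exp_max - exp_min) / 99)
  expect_equal(normalize_gene(exp_max, nv), 100 * (exp_max - exp_min) / 99)
  expect_equal(normalize_gene(100, 0), 100)
})

test_that("100-fold-span identity holds for random valid extreme pairs", {
  withr::with_seed(42, {
    for (i in 1:200) {
      lo <- runif(1, 1e-4, 50)
      hi <- lo + runif(1, 1e-6, 200)
      nv <- compute_nval(lo, hi)
      expect_equal(hi - nv, 100 * (lo - nv), tolerance = 1e-9)
    }
  })
})

test_that("score endpoints hit exactly 10 and 0.1 at the cohort extremes", {
  ct <- generate_ct_table(6, pemt_levels = seq(0.1, 0.9, length.out = 6),
                          noise_sd_cycles = 0, seed = 7)
  sc <- tidy(pemt_score(ct))
  expect_equal(sc$score[sc$population_id == "P6"], 10)
  expect_equal(sc$score[sc$population_id == "P1"], 0.1)
  expect_true(all(sc$score >= 0.1 & sc$score <= 10))
})

test_that("score ranking recovers the generative p-EMT ordering", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      lv <- sort(runif(5))
      ct <- generate_ct_table(5, pemt_levels = lv, noise_sd_cycles = 0,
                              seed = rep)
      sc <- tidy(pemt_score(ct)) |> dplyr::arrange(population_id)
      expect_identical(rank(sc$score), rank(lv))
    }
  })
})

test_that("Ct shifts act as exact scalings through the normalization chain", {
  ct <- generate_ct_table(4, pemt_levels = c(0.1, 0.3, 0.6, 0.9),
                          noise_sd_cycles = 0.2, seed = 3)
  base <- pemt_score(ct)

  # a cohort-wide shift of every gene rescales all raw means together,
  # so the min-max conversion cancels it exactly
  global <- ct |>
    dplyr::mutate(ct = ct + ifelse(gene_id == "GAPDH", 0, 1.7))
  expect_equal(tidy(pemt_score(global))$score, tidy(base)$score,
               tolerance = 1e-9)

  # a shift of one gene scales exactly that gene's normalized values by
  # 2^(-c) (N_val is equivariant under per-gene scaling) and no others
  shifted <- pemt_score(ct |>
    dplyr::mutate(ct = ct + ifelse(gene_id == "VIM", 2.5, 0)))
  merged <- dplyr::inner_join(
    base$genes, shifted$genes, by = c("population_id", "gene_id"),
    suffix = c("", "_shift"))
  vim <- merged |> dplyr::filter(gene_id == "VIM")
  expect_equal(vim$normalized_shift, 2^(-2.5) * vim$normalized,
               tolerance = 1e-12)
  other <- merged |> dplyr::filter(gene_id != "VIM")
  expect_equal(other$normalized_shift, other$normalized, tolerance = 1e-12)
})

test_that("raising one population's expression never lowers its score", {
  ct <- generate_ct_table(4, pemt_levels = c(0.2, 0.4, 0.6, 0.8),
                          noise_sd_cycles = 0.3, seed = 5)
  base <- tidy(pemt_score(ct))
  for (drop_cycles in c(0.5, 1, 3)) {
    up <- ct |>
      dplyr::mutate(ct = ct - ifelse(population_id == "P2" & gene_id == "MMP1",
                                     drop_cycles, 0))
    sc <- tidy(pemt_score(up))
    expect_gte(sc$score[sc$population_id == "P2"],
               base$score[base$population_id == "P2"])
  }
})

test_that("degenerate genes and cohorts are handled with warnings", {
  # one flat gene across populations
  ct <- toy_ct_table(list(A = 0, B = 1))
  ct_flat <- ct |>
    dplyr::mutate(ct = ifelse(gene_id == "PDPN", 25, ct))
  expect_warning(res <- pemt_score(ct_flat), "PDPN")
  expect_equal(res$genes$normalized[res$genes$gene_id == "PDPN"], c(0, 0))

  # fully flat cohort -> midpoint with warning
  flat <- toy_ct_table(list(A = 0, B = 0))
  expect_warning(expect_warning(res2 <- pemt_score(flat), "identical"),
                 "midpoint")
  expect_equal(tidy(res2)$score, c(5.05, 5.05))
})

test_that("scoring is invariant to row order and errors on missing genes", {
  ct <- generate_ct_table(3, pemt_levels = c(0.2, 0.5, 0.8),
                          noise_sd_cycles = 0.1, seed = 8)
  shuffled <- withr::with_seed(1, ct[sample(nrow(ct)), ])
  expect_equal(tidy(pemt_score(shuffled)) |> dplyr::arrange(population_id),
               tidy(pemt_score(ct)) |> dplyr::arrange(population_id))

  broken <- ct |> dplyr::filter(!(gene_id == "ITGA5" & population_id == "P2"))
  expect_error(pemt_score(broken), "ITGA5 in P2")
})
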