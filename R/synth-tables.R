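#' Synthetic qPCR Ct table with a known p-EMT gradient
#'
#' Generates a long-format Ct table for the nine panel genes plus the
#' reference gene across populations carrying latent p-EMT intensities
#' in \[0, 1\]. At zero noise the expected Ct of every panel gene in
#' population i is `baseline_ct - pemt_levels[i] * dynamic_range_cycles`
#' (higher p-EMT, lower Ct, higher expression); the reference gene sits
#' at `gapdh_ct` in every population.
#'
#' @param n_populations Number of populations (>= 2; the score
#'   normalization needs distinct min and max sample points).
#' @param pemt_levels Latent p-EMT intensity per population, in \[0, 1\].
#' @param baseline_ct Panel-gene Ct at p-EMT level 0 (cycles).
#' @param gapdh_ct Reference-gene Ct (cycles).
#' @param dynamic_range_cycles Ct drop from level 0 to level 1.
#' @param noise_sd_cycles Gaussian noise SD added per well (cycles).
#' @param n_replicates Replicates per (population, gene).
#' @param panel Panel genes, default [pemt_panel()].
#' @param reference_gene Reference gene symbol.
#' @param population_ids Optional population labels (default P1, P2, ...).
#' @param seed Integer seed.
#' @return Tibble `population_id, gene_id, replicate, ct, pemt_level`.
#' @export
#' @examples
#' generate_ct_table(2, pemt_levels = c(0, 1), noise_sd_cycles = 0, seed = 1)
generate_ct_table <- function(n_populations, pemt_levels,
                              baseline_ct = 30, gapdh_ct = 20,
                              dynamic_range_cycles = 5,
                              noise_sd_cycles = 0, n_replicates = 3L,
                              panel = pemt_panel(),
                              reference_gene = "GAPDH",
                              population_ids = NULL, seed = 1L) {
  if (n_populations < 2) {
    abort("`n_populations` must be >= 2: score normalization needs min and max across populations.")
  }
  if (length(pemt_levels) != n_populations) {
    abort("`pemt_levels` must have one entry per population.")
  }
  if (any(pemt_levels < 0 | pemt_levels > 1)) {
    abort("`pemt_levels` must lie in [0, 1].")
  }
  stopifnot(noise_sd_cycles >= 0, n_replicates >= 1)
  population_ids <- population_ids %||% paste0("P", seq_len(n_populations))

  grid <- tidyr::expand_grid(
    population_id = population_ids,
    gene_id = c(panel, reference_gene),
    replicate = seq_len(n_replicates)
  ) |>
    left_join(tibble(population_id = population_ids, pemt_level = pemt_levels),
              by = "population_id") |>
    mutate(ct = ifelse(.data$gene_id == reference_gene, gapdh_ct,
                       baseline_ct - .data$pemt_level * dynamic_range_cycles))
  if (noise_sd_cycles > 0) {
    grid$ct <- withr::with_seed(
      seed, grid$ct + rnorm(nrow(grid), 0, noise_sd_cycles))
  }
  grid |> select("population_id", "gene_id", "replicate", "ct", "pemt_level")
}

#' Synthetic cell masks with known length-to-width ratios
#'
#' Rasterizes filled ellipses whose major/minor semi-axis ratio equals
#' the requested value, as fixtures for 2D length-to-width (LWR)
#' measurement. Orientation is randomized per cell.
#'
#' @param n_cells Number of masks.
#' @param axis_ratios Target ratios (>= 1), recycled to `n_cells`.
#' @param seed Integer seed.
#' @param minor_axis_px Minor semi-axis in pixels (default 8).
#' @return List with `$masks` (list of binary matrices) and `$truth`
#'   (tibble `cell_id, axis_ratio, angle`).
#' @export
generate_cell_masks <- function(n_cells, axis_ratios, seed = 1L,
                                minor_axis_px = 8) {
  if (any(axis_ratios < 1)) abort("`axis_ratios` must be >= 1.")
  ratios <- rep_len(axis_ratios, n_cells)
  angles <- withr::with_seed(seed, runif(n_cells, 0, pi))
  masks <- map(seq_len(n_cells), function(i) {
    a <- ratios[i] * minor_axis_px
    b <- minor_axis_px
    half <- ceiling(a) + 2L
    d <- -half:half
    x <- matrix(d, length(d), length(d))          # rows
    y <- matrix(d, length(d), length(d), byrow = TRUE)  # cols
    th <- angles[i]
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  })
  list(
    masks = masks,
    truth = tibble(cell_id = seq_len(n_cells), axis_ratio = ratios,
                   angle = angles)
  )
}

#' Synthetic pSMAD3 densitometry with known responder status
#'
#' Emulates western-blot densitometry of phosphorylated SMAD3 (relative
#' to GAPDH) before and after TGF-beta treatment. Responders are drawn
#' with fold change in `responder_fold_range` (the 2- to 4-fold
#' stimulation seen in responsive populations); non-responders at fold
#' change 1, plus optional multiplicative noise.
#'
#' @param n_responders,n_nonresponders Population counts.
#' @param responder_fold_range Length-2 range of responder fold changes.
#' @param noise_sd Gaussian SD added to the fold change (default 0).
#' @param seed Integer seed.
#' @return Tibble `population_id, psmad3_ctrl, psmad3_tgfb,
#'   true_responder`.
#' @export
generate_densitometry <- function(n_responders, n_nonresponders,
                                  responder_fold_range = c(2, 4),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(n_responders >= 0, n_nonresponders >= 0,
            length(responder_fold_range) == 2,
            responder_fold_range[1] <= responder_fold_range[2])
  n <- n_responders + n_nonresponders
  withr::with_seed(seed, {
    ctrl <- runif(n, 0.5, 1.5)
    fold <- c(runif(n_responders, responder_fold_range[1], responder_fold_range[2]),
              rep(1, n_nonresponders))
    if (noise_sd > 0) fold <- pmax(fold + rnorm(n, 0, noise_sd), 0.05)
    tibble(
      population_id = paste0("P", seq_len(n)),
      psmad3_ctrl = ctrl,
      psmad3_tgfb = ctrl * fold,
      true_responder = rep(c(TRUE, FALSE), c(n_responders, n_nonresponders))
    )
  })
}

#' Synthetic transcription-factor expression matrix with one planted hit
#'
#' Builds a populations x TFs expression matrix in which one planted TF
#' tracks a given invasion phenotype at a chosen generative correlation
#' and the remaining TFs are independent noise, as a fixture for the
#' TF invasion screen.
#'
#' @param phenotype Numeric phenotype per population (e.g. invasion
#'   index or SPOI).
#' @param n_null Number of null (noise) TFs.
#' @param planted_r Generative correlation of the planted TF.
#' @param seed Integer seed.
#' @return Matrix with rownames from `names(phenotype)` (or P1..Pn) and
#'   columns `TF_planted, TF01, ...`.
#' @export
generate_tf_matrix <- function(phenotype, n_null = 39L, planted_r = 0.95,
                               seed = 1L) {
  stopifnot(length(phenotype) >= 3, abs(planted_r) <= 1)
  n <- length(phenotype)
  z <- as.numeric(scale(phenotype))
  withr::with_seed(seed, {
    planted <- planted_r * z + sqrt(1 - planted_r^2) * rnorm(n)
    nulls <- matrix(rnorm(n * n_null), n, n_null)
    m <- cbind(TF_planted = planted, nulls)
    colnames(m) <- c("TF_planted", sprintf("TF%02d", seq_len(n_null)))
    rownames(m) <- names(phenotype) %||% paste0("P", seq_len(n))
    m
  })
}
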