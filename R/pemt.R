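#' The default nine-gene p-EMT panel
#'
#' Nine partial-EMT marker genes scored against the reference gene GAPDH:
#' PDPN, VIM, PAI1 (SERPINE1), LAMC2, TGFBI, THBS1, MMP1, MMP10 and ITGA5.
#' The panel is an argument to [pemt_score()] and can be replaced by any
#' other set of exactly nine unique genes (the reference gene excluded).
#'
#' @return Character vector of nine gene symbols.
#' @export
#' @examples
#' pemt_panel()
pemt_panel <- function() {
  c("PDPN", "VIM", "PAI1", "LAMC2", "TGFBI", "THBS1", "MMP1", "MMP10", "ITGA5")
}

validate_panel <- function(panel, reference_gene) {
  if (length(panel) != 9L || anyDuplicated(panel) > 0L) {
    abort("`panel` must contain exactly nine unique gene symbols.")
  }
  if (reference_gene %in% panel) {
    abort("The reference gene must not be part of the panel.")
  }
  panel
}

#' Per-record delta-Ct relative to the reference gene
#'
#' For every (population, replicate) block, subtracts the reference-gene
#' Ct from each target-gene Ct: `delta_ct = ct_gene - ct_reference`.
#' Lower delta-Ct means higher expression.
#'
#' @param ct_table A data frame with columns `population_id`, `gene_id`,
#'   `replicate`, `ct` (long format, one row per well).
#' @param reference_gene Reference gene symbol, default `"GAPDH"`. Every
#'   (population, replicate) block must contain it.
#' @return A tibble `population_id, gene_id, replicate, delta_ct` with
#'   reference-gene rows removed.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   population_id = "P1", replicate = 1L,
#'   gene_id = c("PDPN", "GAPDH"), ct = c(25, 20)
#' )
#' compute_delta_ct(ct)  # delta_ct = 5
compute_delta_ct <- function(ct_table, reference_gene = "GAPDH") {
  ct_table <- as_tibble(ct_table)
  needed <- c("population_id", "gene_id", "replicate", "ct")
  if (!all(needed %in% names(ct_table))) {
    abort(paste0("`ct_table` must have columns ", paste(needed, collapse = ", "), "."))
  }
  if (!all(is.finite(ct_table$ct))) abort("All Ct values must be finite.")

  ref <- ct_table |>
    filter(.data$gene_id == reference_gene) |>
    select("population_id", "replicate", ref_ct = "ct")
  out <- ct_table |>
    filter(.data$gene_id != reference_gene) |>
    left_join(ref, by = c("population_id", "replicate"))
  if (anyNA(out$ref_ct)) {
    bad <- out |>
      filter(is.na(.data$ref_ct)) |>
      distinct(.data$population_id, .data$replicate)
    abort(paste0(
      "Missing ", reference_gene, " for block(s): ",
      paste(paste0(bad$population_id, "/rep", bad$replicate), collapse = ", ")
    ))
  }
  out |>
    mutate(delta_ct = .data$ct - .data$ref_ct) |>
    select("population_id", "gene_id", "replicate", "delta_ct")
}

#' Relative expression from delta-Ct
#'
#' `EXP = 2^(-delta_ct) * 100`: delta-Ct 0 maps to 100, each additional
#' cycle halves the value. Strictly positive and strictly decreasing in
#' delta-Ct.
#'
#' @param delta_ct Numeric vector of delta-Ct values (cycles).
#' @return Numeric vector of EXP values.
#' @export
#' @examples
#' exp_transform(c(0, 5, -1))  # 100, 3.125, 200
exp_transform <- function(delta_ct) {
  if (!all(is.finite(delta_ct))) abort("`delta_ct` must be finite.")
  2^(-delta_ct) * 100
}

#' Per-gene normalization constant
#'
#' `N_val = (100 * exp_min - exp_max) / 99`, where `exp_min` and
#' `exp_max` are that gene's extremes across the populations being
#' scored. Subtracting N_val maps the gene's observed range onto an
#' exact 100-fold span: `(exp_max - N_val) = 100 * (exp_min - N_val)`
#' whenever `exp_max > exp_min`.
#'
#' @param exp_min,exp_max Per-gene minimum and maximum EXP across
#'   populations; `exp_min <= exp_max` required.
#' @return The normalization constant (same units as EXP).
#' @export
#' @examples
#' compute_nval(1, 100)  # 0
compute_nval <- function(exp_min, exp_max) {
  if (any(exp_min > exp_max)) abort("`exp_min` must not exceed `exp_max`.")
  (100 * exp_min - exp_max) / 99
}

#' Normalized per-gene expression
#'
#' Subtracts the gene's normalization constant from an EXP value.
#'
#' @param exp EXP value(s) for one gene.
#' @param n_val The gene's normalization constant from [compute_nval()].
#' @return `exp - n_val`.
#' @export
normalize_gene <- function(exp, n_val) {
  exp - n_val
}

#' Nine-gene p-EMT score
#'
#' Scores each keratinocyte population on a 0.1-10 scale from a long
#' qPCR Ct table. The chain is: delta-Ct against the reference gene per
#' replicate; replicate-averaged delta-Ct per (population, gene);
#' `EXP = 2^(-delta_ct) * 100`; per-gene normalization by subtracting
#' `N_val = (100 * EXP_min - EXP_max)/99` (extremes across populations);
#' the nine normalized values averaged per population; and the
#' population means mapped linearly onto \[0.1, 10\] so the most
#' p-EMT-high population scores exactly 10 and the lowest exactly 0.1.
#'
#' A gene whose EXP is identical in every population carries no
#' discrimination; its normalized value is set to 0 for all populations
#' with a warning. If every population's raw mean is identical the score
#' is set to the midpoint 5.05 for all, with a warning.
#'
#' @inheritParams compute_delta_ct
#' @param panel Character vector of exactly nine panel genes; default
#'   [pemt_panel()].
#' @return An object of class `pemt_score`: a list with `$genes`
#'   (per population x gene intermediates: `delta_ct`, `exp`, `exp_min`,
#'   `exp_max`, `n_val`, `normalized`) and `$scores` (per population:
#'   `raw_mean`, `score`). Use [tidy()] for the score table.
#' @export
#' @examples
#' ct <- generate_ct_table(n_populations = 3, pemt_levels = c(0, 0.5, 1),
#'                         noise_sd_cycles = 0, seed = 1)
#' tidy(pemt_score(ct))
pemt_score <- function(ct_table, panel = pemt_panel(), reference_gene = "GAPDH") {
  panel <- validate_panel(panel, reference_gene)
  dct <- compute_delta_ct(ct_table, reference_gene) |>
    filter(.data$gene_id %in% panel)

  pops <- unique(dct$population_id)
  if (length(pops) < 2L) {
    abort("At least two populations are required (per-gene extremes must be distinct sample points).")
  }
  have <- dct |> distinct(.data$population_id, .data$gene_id)
  miss <- tidyr::expand_grid(population_id = pops, gene_id = panel) |>
    anti_join(have, by = c("population_id", "gene_id"))
  if (nrow(miss) > 0L) {
    abort(paste0(
      "Missing panel gene(s): ",
      paste(paste0(miss$gene_id, " in ", miss$population_id), collapse = ", ")
    ))
  }

  genes <- dct |>
    summarise(delta_ct = mean(.data$delta_ct), .by = c("population_id", "gene_id")) |>
    mutate(exp = exp_transform(.data$delta_ct)) |>
    mutate(
      exp_min = min(.data$exp),
      exp_max = max(.data$exp),
      .by = "gene_id"
    ) |>
    mutate(
      n_val = compute_nval(.data$exp_min, .data$exp_max),
      normalized = ifelse(.data$exp_max > .data$exp_min,
                          normalize_gene(.data$exp, .data$n_val), 0)
    )
  flat <- genes |>
    distinct(.data$gene_id, .data$exp_min, .data$exp_max) |>
    filter(.data$exp_max == .data$exp_min)
  if (nrow(flat) > 0L) {
    warn(paste0(
      "Gene(s) with identical expression in all populations contribute 0: ",
      paste(flat$gene_id, collapse = ", ")
    ))
  }

  scores <- genes |>
    summarise(raw_mean = mean(.data$normalized), .by = "population_id")
  rng <- range(scores$raw_mean)
  if (rng[1] == rng[2]) {
    warn("All populations have identical raw means; scores set to midpoint 5.05.")
    scores$score <- 5.05
  } else {
    scores$score <- 0.1 + 9.9 * (scores$raw_mean - rng[1]) / (rng[2] - rng[1])
  }

  structure(
    list(genes = genes, scores = scores, panel = panel,
         reference_gene = reference_gene),
    class = "pemt_score"
  )
}

#' @export
print.pemt_score <- function(x, ...) {
  cat("p-EMT score (", length(x$panel), "-gene panel, reference ",
      x$reference_gene, ")\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' @describeIn pemt_score Per-population score table.
#' @param x A `pemt_score` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pemt_score <- function(x, ...) {
  as_tibble(x$scores)
}

#' @describeIn pemt_score One-row summary (number of populations, genes,
#'   score range).
#' @exportS3Method generics::glance
glance.pemt_score <- function(x, ...) {
  tibble(
    n_populations = nrow(x$scores),
    n_genes = length(x$panel),
    score_min = min(x$scores$score),
    score_max = max(x$scores$score)
  )
}

#' @describeIn pemt_score Bar chart of per-population scores.
#' @param object A `pemt_score` object.
#' @exportS3Method ggplot2::autoplot
autoplot.pemt_score <- function(object, ...) {
  df <- object$scores |>
    mutate(population_id = stats::reorder(.data$population_id, .data$score))
  ggplot(df, aes(x = .data$population_id, y = .data$score)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "p-EMT score (0.1-10)") +
    theme_minimal()
}
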