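#' SPOI from singular/clustered island counts
#'
#' The single pattern of invasion (SPOI) is the number of singular
#' tumor islands (fewer than 15 nuclei) divided by the number of
#' clustered islands (15 or more nuclei). When no singular islands are
#' present the value is 0 by definition. When singular islands exist
#' but no clustered island does, the ratio is undefined; the singular
#' count is returned with `spoi_undefined = TRUE` so monotonicity in
#' the singular count is preserved and the caller can exclude or flag
#' it.
#'
#' @param n_singular,n_clustered Island counts.
#' @return List `spoi, n_singular, n_clustered, spoi_undefined`.
#' @export
#' @examples
#' spoi_from_counts(3, 6)$spoi  # 0.5
#' spoi_from_counts(0, 4)$spoi  # 0
spoi_from_counts <- function(n_singular, n_clustered) {
  stopifnot(n_singular >= 0, n_clustered >= 0)
  if (n_singular == 0) {
    spoi <- 0; undef <- FALSE
  } else if (n_clustered == 0) {
    spoi <- n_singular; undef <- TRUE
  } else {
    spoi <- n_singular / n_clustered; undef <- FALSE
  }
  list(spoi = spoi, n_singular = as.integer(n_singular),
       n_clustered = as.integer(n_clustered), spoi_undefined = undef)
}

#' SPOI of an island table
#'
#' Classifies each detached island as singular (< `nuclei_cutoff`
#' nuclei) or clustered (>= cutoff) and applies [spoi_from_counts()].
#'
#' @param island_table Island table with `nuclei_count` filled (see
#'   [measure_islands()]).
#' @param nuclei_cutoff Singular/clustered boundary, default 15.
#' @return List `spoi, n_singular, n_clustered, spoi_undefined`.
#' @export
compute_spoi <- function(island_table, nuclei_cutoff = 15L) {
  isl <- island_table |> filter(!.data$is_sheet)
  if (anyNA(isl$nuclei_count)) {
    abort("`nuclei_count` must be filled before computing SPOI (see measure_islands()).")
  }
  spoi_from_counts(sum(isl$nuclei_count < nuclei_cutoff),
                   sum(isl$nuclei_count >= nuclei_cutoff))
}

#' Worst-pattern-of-invasion rule
#'
#' Grade 5 if any island sits >= `distance_cutoff_um` (1 mm) of tissue
#' away from the tumor mass; else 4 if any detached singular island
#' (< 15 nuclei) exists; else 3 if any detached island exists (all
#' clustered); else 2 if the front shows finger-like protrusions; else
#' 1 (broad pushing front). The worst pattern wins
#' (precedence 5 > 4 > 3 > 2 > 1). An island with exactly 15 nuclei is
#' clustered, matching the SPOI dichotomy.
#'
#' @param n_islands Number of detached islands.
#' @param any_singular Whether any detached island is singular.
#' @param max_distance_um Largest island-to-sheet distance (um).
#' @param n_protrusions Number of finger-like front protrusions.
#' @param distance_cutoff_um Grade-5 distance, default 1000 um.
#' @return Integer grade in 1..5.
#' @export
wpoi_rule <- function(n_islands, any_singular, max_distance_um,
                      n_protrusions, distance_cutoff_um = 1000) {
  if (n_islands > 0 && max_distance_um >= distance_cutoff_um) return(5L)
  if (n_islands > 0 && any_singular) return(4L)
  if (n_islands > 0) return(3L)
  if (n_protrusions > 0) return(2L)
  1L
}

#' WPOI grade of an island table
#'
#' Applies [wpoi_rule()] to a measured island table, using the
#' per-island nearest distances to the sheet for the 1 mm criterion and
#' a protrusion count for the grade-1/2 distinction.
#'
#' @inheritParams compute_spoi
#' @param n_protrusions Finger count, e.g. from [detect_protrusions()].
#' @param distance_cutoff_um Grade-5 distance, default 1000 um.
#' @return Integer grade in 1..5.
#' @export
grade_wpoi <- function(island_table, n_protrusions = 0L,
                       nuclei_cutoff = 15L, distance_cutoff_um = 1000) {
  isl <- island_table |> filter(!.data$is_sheet)
  if (nrow(isl) > 0 && is.null(attr(island_table, "um_per_px")) &&
      !("min_distance_to_sheet_um" %in% names(isl))) {
    abort("Calibration missing: grade 5 (1 mm rule) is undecidable.")
  }
  if (nrow(isl) > 0 && anyNA(isl$nuclei_count)) {
    abort("`nuclei_count` must be filled before grading.")
  }
  wpoi_rule(
    n_islands = nrow(isl),
    any_singular = nrow(isl) > 0 && any(isl$nuclei_count < nuclei_cutoff),
    max_distance_um = if (nrow(isl) > 0) max(isl$min_distance_to_sheet_um) else 0,
    n_protrusions = n_protrusions,
    distance_cutoff_um = distance_cutoff_um
  )
}

#' Invasion index of an image
#'
#' The composite invasion index: total detached-island area (um^2)
#' times the number of islands times the depth of invasion (um). Zero
#' when no islands are present.
#'
#' @inheritParams compute_spoi
#' @param image_depth_um Image-level invasion depth; defaults to
#'   [invasion_depth()] of the table.
#' @return The index (dimensionless composite).
#' @export
invasion_index <- function(island_table, image_depth_um = NULL) {
  isl <- island_table |> filter(!.data$is_sheet)
  if (nrow(isl) == 0L) return(0)
  depth <- image_depth_um %||% invasion_depth(island_table)
  sum(isl$area_um2) * nrow(isl) * depth
}

#' Grade one organ-culture image end to end
#'
#' Runs the full per-image chain -- segmentation, island extraction,
#' nuclei counting, protrusion detection, depth, invasion index, SPOI
#' and WPOI -- and returns a one-row grading record.
#'
#' @param image An `organ_image`.
#' @param image_id Identifier carried into the result.
#' @param method Threshold method (see [segment_keratinocytes()]).
#' @param min_island_area,min_nucleus_area Size filters in px^2.
#' @param nuclei_cutoff Singular/clustered boundary (default 15).
#' @param distance_cutoff_um WPOI-5 distance (default 1000 um).
#' @return One-row tibble: `image_id, n_islands, n_singular,
#'   n_clustered, total_island_area_um2, depth_um, invasion_index,
#'   spoi, spoi_undefined, wpoi, n_protrusions, threshold`.
#' @export
#' @examples
#' img <- generate_organ_image(organ_image_spec(n_singular_islands = 1,
#'                                              n_clustered_islands = 2))
#' quantify_organ_image(img$image)
quantify_organ_image <- function(image, image_id = "image",
                                 method = "otsu",
                                 min_island_area = 25, min_nucleus_area = 9,
                                 nuclei_cutoff = 15L,
                                 distance_cutoff_um = 1000) {
  tbl <- measure_islands(image, method, min_island_area, min_nucleus_area,
                         nuclei_cutoff)
  npro <- detect_protrusions(tbl)
  depth <- invasion_depth(tbl)
  sp <- compute_spoi(tbl, nuclei_cutoff)
  isl <- tbl |> filter(!.data$is_sheet)
  tibble(
    image_id = image_id,
    n_islands = nrow(isl),
    n_singular = sp$n_singular,
    n_clustered = sp$n_clustered,
    total_island_area_um2 = sum(isl$area_um2),
    depth_um = depth,
    invasion_index = invasion_index(tbl, depth),
    spoi = sp$spoi,
    spoi_undefined = sp$spoi_undefined,
    wpoi = grade_wpoi(tbl, npro, nuclei_cutoff, distance_cutoff_um),
    n_protrusions = npro,
    threshold = attr(tbl, "threshold")
  )
}

#' Aggregate per-field grading results into one experiment summary
#'
#' Organ-culture experiments are imaged at nine fields (triplicate
#' images at the gel centre and one quarter from each side, over three
#' cultures); the fields are averaged into a single sample (n = 1).
#' Returns the arithmetic mean and SEM of the invasion index and SPOI,
#' and the modal WPOI, per experiment.
#'
#' @param field_results Tibble of per-image rows from
#'   [quantify_organ_image()], optionally with an `experiment_id`
#'   column.
#' @param expected_fields Warn when an experiment has a different
#'   number of fields (default 9).
#' @return One row per experiment: means, SEMs, `wpoi_mode`, `n_fields`.
#' @export
aggregate_experiment <- function(field_results, expected_fields = 9L) {
  if (nrow(field_results) == 0L) abort("No field results to aggregate.")
  if (!"experiment_id" %in% names(field_results)) {
    field_results$experiment_id <- "experiment"
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  out <- field_results |>
    summarise(
      n_fields = n(),
      invasion_index_mean = mean(.data$invasion_index),
      invasion_index_sem = sem(.data$invasion_index),
      spoi_mean = mean(.data$spoi),
      spoi_sem = sem(.data$spoi),
      wpoi_mode = as.integer(names(which.max(table(.data$wpoi)))),
      .by = "experiment_id"
    )
  off <- out |> filter(.data$n_fields != expected_fields)
  if (nrow(off) > 0L) {
    warn(paste0("Experiment(s) with field count != ", expected_fields, ": ",
                paste(off$experiment_id, collapse = ", ")))
  }
  out
}

#' SPOI fold change between conditions
#'
#' Ratio of mean SPOI with fibroblasts (WF) to mean SPOI without
#' fibroblasts (WOF). A zero WOF mean makes the ratio undefined; the
#' result is flagged and should be excluded from aggregates.
#'
#' @param spoi_wf,spoi_wof Mean SPOI under each condition (scalars or
#'   the `spoi_mean` of an experiment summary).
#' @return List `fold_change, undefined`.
#' @export
spoi_fold_change <- function(spoi_wf, spoi_wof) {
  if (spoi_wof == 0) {
    list(fold_change = NA_real_, undefined = TRUE)
  } else {
    list(fold_change = spoi_wf / spoi_wof, undefined = FALSE)
  }
}
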