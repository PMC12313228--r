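# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a small union-find pass.
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
    )
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      compact <- match(root, sort(unique(root)))
      lab[lab > 0] <- compact[lab[lab > 0]]
    }
  }
  storage.mode(lab) <- "integer"
  lab
}

otsu_masked <- function(values) {
  # EBImage's Otsu works on whole images; wrap the masked pixel values
  # into a 1-column image (the threshold is histogram-based only).
  EBImage::otsu(EBImage::Image(matrix(values, ncol = 1)), range = c(0, 1))
}

#' Segment tumor keratinocytes by thresholding
#'
#' Thresholds one channel of a calibrated organ-culture image into a
#' binary keratinocyte mask, either automatically (Otsu) or at a fixed
#' intensity. The mask is TRUE where intensity >= threshold; the
#' threshold used is recorded in the `threshold` attribute for
#' provenance.
#'
#' @param image An `organ_image` (see [generate_organ_image()]) or a
#'   list with `$channels` and `$um_per_px`.
#' @param channel Channel name, default `"cytokeratin"`.
#' @param method `"otsu"`, `"fixed:<t>"` (e.g. `"fixed:0.5"`), or a
#'   numeric threshold in \[0, 1\].
#' @return Logical matrix with attributes `threshold` and `channel`.
#' @export
segment_keratinocytes <- function(image, channel = "cytokeratin",
                                  method = "otsu") {
  ch <- image$channels[[channel]]
  if (is.null(ch)) abort(paste0("Channel '", channel, "' not found."))
  if (is.numeric(method)) {
    t <- method
  } else if (identical(method, "otsu")) {
    if (diff(range(ch)) < .Machine$double.eps) {
      abort("Channel is constant; Otsu thresholding is undefined. Use a fixed threshold, e.g. method = 'fixed:0.5'.")
    }
    t <- otsu_masked(as.vector(ch))
  } else if (startsWith(method, "fixed:")) {
    t <- as.numeric(sub("^fixed:", "", method))
  } else {
    abort("`method` must be 'otsu', 'fixed:<t>' or a numeric threshold.")
  }
  if (!is.finite(t) || t < 0 || t > 1) abort("Threshold must lie in [0, 1].")
  mask <- ch >= t
  attr(mask, "threshold") <- t
  attr(mask, "channel") <- channel
  mask
}

#' Extract the epithelial sheet and detached tumor islands
#'
#' Computes 8-connected components of a keratinocyte mask. The
#' component that touches the top image border (the air side) with the
#' largest area is the epithelial sheet; every other component of at
#' least `min_island_area` pixels is a detached tumor island. Per
#' island the area, centroid, deepest row, nearest Euclidean distance
#' to the sheet, and depth below the sheet base are recorded. The sheet
#' base row is the median over columns of the sheet's lowest occupied
#' row, which is robust to finger-like protrusions.
#'
#' @param mask Logical keratinocyte mask (from
#'   [segment_keratinocytes()]).
#' @param um_per_px Calibration, micrometres per pixel.
#' @param min_island_area Minimum island area in px^2 (default 25),
#'   suppressing single-pixel noise.
#' @return A tibble with one `is_sheet = TRUE` row plus one row per
#'   island: `label, area_px2, area_um2, centroid_row, centroid_col,
#'   max_row, min_distance_to_sheet_um, depth_um, nuclei_count` (NA
#'   until filled by [count_nuclei()]/[measure_islands()]). Attributes:
#'   `label_matrix`, `sheet_label`, `sheet_base_row`, `um_per_px`.
#' @export
extract_islands <- function(mask, um_per_px, min_island_area = 25) {
  if (!any(mask)) abort("Mask is empty; nothing to extract.")
  stopifnot(um_per_px > 0)
  lab <- label_components(mask)
  top_labels <- setdiff(unique(lab[1, ]), 0L)
  if (length(top_labels) == 0L) {
    abort("No epithelial sheet found (no component touches the top border); check image orientation.")
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  sheet <- top_labels[which.max(areas[top_labels])]

  sheet_cols <- which(apply(lab == sheet, 2, any))
  base_row <- median(vapply(sheet_cols,
                            function(j) max(which(lab[, j] == sheet)),
                            numeric(1)))

  # distance of every pixel to the nearest sheet pixel
  dm <- EBImage::imageData(EBImage::distmap(1 - (lab == sheet)))

  island_labels <- setdiff(which(areas >= min_island_area), sheet)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs_at <- lab[idx]
  rows <- vector("list", length(island_labels) + 1L)
  rows[[1]] <- tibble(
    label = as.integer(sheet), is_sheet = TRUE,
    area_px2 = areas[sheet], area_um2 = areas[sheet] * um_per_px^2,
    centroid_row = mean(idx[labs_at == sheet, 1]),
    centroid_col = mean(idx[labs_at == sheet, 2]),
    max_row = max(idx[labs_at == sheet, 1]),
    min_distance_to_sheet_um = 0,
    depth_um = 0,
    nuclei_count = NA_integer_
  )
  for (k in seq_along(island_labels)) {
    l <- island_labels[k]
    sel <- labs_at == l
    max_row <- max(idx[sel, 1])
    rows[[k + 1L]] <- tibble(
      label = as.integer(l), is_sheet = FALSE,
      area_px2 = areas[l], area_um2 = areas[l] * um_per_px^2,
      centroid_row = mean(idx[sel, 1]),
      centroid_col = mean(idx[sel, 2]),
      max_row = max_row,
      min_distance_to_sheet_um = min(dm[lab == l]) * um_per_px,
      depth_um = max(max_row - base_row, 0) * um_per_px,
      nuclei_count = NA_integer_
    )
  }
  out <- list_rbind(rows) |> arrange(desc(.data$is_sheet), .data$centroid_col)
  attr(out, "label_matrix") <- lab
  attr(out, "sheet_label") <- as.integer(sheet)
  attr(out, "sheet_base_row") <- base_row
  attr(out, "um_per_px") <- um_per_px
  out
}

#' Count nuclei inside one island
#'
#' Otsu-thresholds the DAPI channel restricted to the island mask and
#' counts 8-connected nuclear components of at least
#' `min_nucleus_area` pixels. An island with no DAPI signal (constant
#' channel within the island) counts 0.
#'
#' @param image An `organ_image` with a `dapi` channel.
#' @param island_mask Logical mask of one island.
#' @param min_nucleus_area Minimum nuclear blob area in px^2 (default 9).
#' @return Integer nucleus count.
#' @export
count_nuclei <- function(image, island_mask, min_nucleus_area = 9) {
  dapi <- image$channels$dapi
  if (is.null(dapi)) abort("Image has no 'dapi' channel.")
  if (!any(island_mask)) return(0L)
  # work in the island bounding box
  px <- which(island_mask, arr.ind = TRUE)
  rr <- range(px[, 1]); cc <- range(px[, 2])
  island_mask <- island_mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  dapi <- dapi[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  vals <- dapi[island_mask]
  if (diff(range(vals)) < 1e-8) return(0L)
  t <- otsu_masked(vals)
  nmask <- island_mask & (dapi >= t)
  lab <- label_components(nmask)
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0], nbins = max(lab)) >= min_nucleus_area)
}

#' Per-image invasion depth
#'
#' The image-level depth of tumor invasion: the maximum per-island
#' depth below the sheet base (already clamped at 0), or 0 when no
#' islands are present.
#'
#' @param island_table Result of [extract_islands()].
#' @return Depth in micrometres.
#' @export
invasion_depth <- function(island_table) {
  isl <- island_table |> filter(!.data$is_sheet)
  if (nrow(isl) == 0L) 0 else max(isl$depth_um)
}

#' Detect finger-like protrusions on the invasion front
#'
#' Finds connected sheet regions below the sheet base row (the median
#' of per-column lowest sheet rows) whose bounding-box aspect ratio
#' (height/width) is at least `aspect_min` -- the operational reading
#' of a "finger-like" pushing pattern (WPOI 2).
#'
#' @param island_table Result of [extract_islands()] (carries the sheet
#'   label matrix and base row).
#' @param aspect_min Minimum length/width ratio (default 2).
#' @param min_area Minimum protrusion area in px^2 (default 10).
#' @return Integer protrusion count.
#' @export
detect_protrusions <- function(island_table, aspect_min = 2, min_area = 10) {
  lab <- attr(island_table, "label_matrix")
  sheet <- attr(island_table, "sheet_label")
  base <- attr(island_table, "sheet_base_row")
  below <- lab == sheet
  below[seq_len(min(floor(base), nrow(below))), ] <- FALSE
  if (!any(below)) return(0L)
  pl <- label_components(below)
  n <- 0L
  for (l in seq_len(max(pl))) {
    px <- which(pl == l, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    h <- diff(range(px[, 1])) + 1
    w <- diff(range(px[, 2])) + 1
    if (h / w >= aspect_min) n <- n + 1L
  }
  n
}

#' Length-to-width ratio of 2D cell masks
#'
#' Measures each cell's major and minor axis from the eigenvalues of
#' the second central moments of its pixel set (the moment ellipse) and
#' reports the length-to-width ratio LWR = major/minor >= 1. Values
#' near 1 indicate cuboidal epithelial cells; larger values an
#' elongated mesenchymal-like shape.
#'
#' @param cell_masks List of logical matrices, one per cell; each must
#'   have at least 10 pixels and not be collinear.
#' @return Tibble `cell_id, major_axis_px, minor_axis_px, lwr`, with
#'   the population mean in attribute `mean_lwr`.
#' @export
measure_lwr <- function(cell_masks) {
  out <- imap(cell_masks, function(m, i) {
    pts <- which(m, arr.ind = TRUE)
    if (nrow(pts) < 10) abort(paste0("Cell ", i, " has fewer than 10 pixels."))
    cv <- stats::cov(pts)
    ev <- eigen(cv, symmetric = TRUE)$values
    if (ev[2] <= 1e-9) abort(paste0("Cell ", i, " is degenerate (collinear pixels)."))
    tibble(
      cell_id = i,
      major_axis_px = 4 * sqrt(ev[1]),
      minor_axis_px = 4 * sqrt(ev[2]),
      lwr = sqrt(ev[1] / ev[2])
    )
  }) |> list_rbind()
  attr(out, "mean_lwr") <- mean(out$lwr)
  out
}

#' Mean marker intensity over a mask
#'
#' Arithmetic mean of a named channel (e.g. PDPN) over the pixels of a
#' mask, the quantity used to compare marker expression between
#' conditions.
#'
#' @param image An `organ_image`.
#' @param mask Logical mask (non-empty).
#' @param channel Channel name.
#' @return Mean intensity (scalar).
#' @export
mean_marker_intensity <- function(image, mask, channel) {
  ch <- image$channels[[channel]]
  if (is.null(ch)) abort(paste0("Channel '", channel, "' not found."))
  if (!any(mask)) abort("Mask is empty.")
  mean(ch[mask])
}

#' Full per-image island measurement
#'
#' Convenience chain: segment the cytokeratin channel, extract the
#' sheet and islands, and fill each island's nucleus count from the
#' DAPI channel.
#'
#' @param image An `organ_image`.
#' @param method Threshold method for [segment_keratinocytes()].
#' @param min_island_area,min_nucleus_area Size filters in px^2.
#' @return An island table as from [extract_islands()], with
#'   `nuclei_count` and `is_singular` filled (singular = fewer than 15
#'   nuclei) and the segmentation threshold in attribute `threshold`.
#' @export
measure_islands <- function(image, method = "otsu",
                            min_island_area = 25, min_nucleus_area = 9,
                            nuclei_cutoff = 15L) {
  mask <- segment_keratinocytes(image, "cytokeratin", method)
  tbl <- extract_islands(mask, image$um_per_px, min_island_area)
  lab <- attr(tbl, "label_matrix")
  counts <- map_int(seq_len(nrow(tbl)), function(i) {
    if (tbl$is_sheet[i]) return(NA_integer_)
    count_nuclei(image, lab == tbl$label[i], min_nucleus_area)
  })
  tbl$nuclei_count <- counts
  tbl$is_singular <- !tbl$is_sheet & counts < nuclei_cutoff
  attr(tbl, "threshold") <- attr(mask, "threshold")
  tbl
}
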