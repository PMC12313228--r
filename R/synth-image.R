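# Geometry constants for rendered nuclei: disc radius 3 px, centre-to-centre
# spacing 8 px (edge gap >= 2 px) so counts are unambiguous at ground truth.
NUCLEUS_RADIUS_PX <- 3L
NUCLEUS_SPACING_PX <- 8L
PROTRUSION_LEN_PX <- 14L
PROTRUSION_WIDTH_PX <- 5L

.disc_cache <- new.env(parent = emptyenv())

disc_offsets <- function(r) {
  key <- as.character(r)
  if (!is.null(.disc_cache[[key]])) return(.disc_cache[[key]])
  d <- -r:r
  g <- expand.grid(dr = d, dc = d)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  .disc_cache[[key]] <- g
  g
}

# Paint filled discs of one radius at many centres in a single
# assignment (per-disc assignment would copy the full matrix each time).
paint_discs <- function(mat, rows, cols, r, value = 1) {
  if (length(rows) == 0L) return(mat)
  off <- disc_offsets(r)
  rr <- rep(rows, each = nrow(off)) + off$dr
  cc <- rep(cols, each = nrow(off)) + off$dc
  keep <- rr >= 1 & rr <= nrow(mat) & cc >= 1 & cc <= ncol(mat)
  mat[cbind(rr[keep], cc[keep])] <- value
  mat
}

# Candidate nucleus centres inside an island: square lattice with the
# spec'd spacing, centred on the island centre, kept strictly inside.
nucleus_grid <- function(radius_px) {
  k <- floor(radius_px / NUCLEUS_SPACING_PX) + 1L
  d <- NUCLEUS_SPACING_PX * (-k:k)
  g <- expand.grid(dr = d, dc = d)
  g <- g[sqrt(g$dr^2 + g$dc^2) <= radius_px - NUCLEUS_RADIUS_PX - 1, , drop = FALSE]
  g[order(g$dr^2 + g$dc^2, g$dr, g$dc), , drop = FALSE]
}

island_nucleus_capacity <- function(radius_px) nrow(nucleus_grid(radius_px))

# Smallest island radius that can hold n disjoint nuclei.
radius_for_nuclei <- function(n) {
  r <- NUCLEUS_RADIUS_PX + 4L
  while (island_nucleus_capacity(r) < n) r <- r + 1L
  r
}

#' Specification of a synthetic organ-culture image
#'
#' Describes a calibrated three-channel (cytokeratin / PDPN / DAPI)
#' immunofluorescence image of an organotypic culture section: an
#' epithelial sheet along the top edge (the air side), optional
#' finger-like protrusions on its invasion front, and detached tumor
#' islands below it. Islands with fewer than 15 nuclei are "singular",
#' those with 15 or more are "clustered" -- the dichotomy on which the
#' SPOI statistic and WPOI grading rest.
#'
#' Island geometry (depths, radii, columns) may be given explicitly or
#' left `NULL` for a deterministic automatic layout that spaces islands
#' in bands below the sheet. Island depths are the row offset of the
#' island centre below the sheet base. All islands must fit in the image
#' and be separated from each other and from the sheet by at least 2 px;
#' violations are an error, never a silent merge.
#'
#' @param width_px,height_px Image size in pixels.
#' @param um_per_px Calibration, micrometres per pixel (> 0).
#' @param sheet_thickness_px Rows occupied by the epithelial sheet.
#' @param n_singular_islands,n_clustered_islands Island counts.
#' @param nuclei_per_singular Nuclei per singular island, in \[1, 14\].
#' @param nuclei_per_clustered Nuclei per clustered island, >= 15.
#' @param island_depths_px,island_radii_px,island_cols_px Optional
#'   explicit geometry, one entry per island (singular islands first).
#' @param front_protrusions Number of finger-like sheet protrusions
#'   (length/width >= 2), the WPOI-2 geometry.
#' @param far_island_distance_um Optional: place the last island at
#'   least this far (micrometres) below the sheet, the WPOI-5 geometry
#'   (>= 1000 um for grade 5).
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise (intensities are clipped to \[0, 1\]).
#' @param seed Integer seed; identical specs and seeds give identical
#'   images.
#' @return An `organ_image_spec` object.
#' @seealso [generate_organ_image()], [random_organ_image_spec()]
#' @export
organ_image_spec <- function(width_px = 640L, height_px = 480L, um_per_px = 1,
                             sheet_thickness_px = 60L,
                             n_singular_islands = 3L, n_clustered_islands = 6L,
                             nuclei_per_singular = 5L, nuclei_per_clustered = 20L,
                             island_depths_px = NULL, island_radii_px = NULL,
                             island_cols_px = NULL,
                             front_protrusions = 0L,
                             far_island_distance_um = NULL,
                             noise_sd = 0, seed = 1L) {
  stopifnot(um_per_px > 0, noise_sd >= 0,
            n_singular_islands >= 0, n_clustered_islands >= 0,
            front_protrusions >= 0)
  if (n_singular_islands > 0 &&
      (nuclei_per_singular < 1 || nuclei_per_singular >= 15)) {
    abort("`nuclei_per_singular` must be in [1, 14].")
  }
  if (n_clustered_islands > 0 && nuclei_per_clustered < 15) {
    abort("`nuclei_per_clustered` must be >= 15.")
  }
  n_islands <- n_singular_islands + n_clustered_islands

  if (is.null(island_radii_px)) {
    island_radii_px <- c(
      rep(radius_for_nuclei(nuclei_per_singular), n_singular_islands),
      rep(radius_for_nuclei(nuclei_per_clustered), n_clustered_islands)
    )
  }
  if (length(island_radii_px) != n_islands) {
    abort("`island_radii_px` must have one entry per island.")
  }

  if (is.null(island_depths_px) || is.null(island_cols_px)) {
    lay <- layout_islands(island_radii_px, width_px, height_px,
                          sheet_thickness_px, front_protrusions,
                          far_island_distance_um, um_per_px)
    if (is.null(island_depths_px)) island_depths_px <- lay$depths
    if (is.null(island_cols_px)) island_cols_px <- lay$cols
  }
  if (length(island_depths_px) != n_islands || length(island_cols_px) != n_islands) {
    abort("`island_depths_px` and `island_cols_px` must have one entry per island.")
  }

  spec <- structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    um_per_px = um_per_px, sheet_thickness_px = as.integer(sheet_thickness_px),
    n_singular_islands = as.integer(n_singular_islands),
    n_clustered_islands = as.integer(n_clustered_islands),
    nuclei_per_singular = as.integer(nuclei_per_singular),
    nuclei_per_clustered = as.integer(nuclei_per_clustered),
    island_depths_px = as.integer(island_depths_px),
    island_radii_px = as.integer(island_radii_px),
    island_cols_px = as.integer(island_cols_px),
    front_protrusions = as.integer(front_protrusions),
    far_island_distance_um = far_island_distance_um,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "organ_image_spec")
  validate_island_geometry(spec)
  spec
}

# Deterministic band layout: islands side by side below the sheet (and
# below any protrusion fingers), wrapping to a deeper band when a row
# fills up; an optional far island goes in its own band at the requested
# distance.
layout_islands <- function(radii, width_px, height_px, sheet_base,
                           front_protrusions, far_island_distance_um,
                           um_per_px) {
  n <- length(radii)
  depths <- integer(n); cols <- integer(n)
  if (n == 0L) return(list(depths = depths, cols = cols))
  margin <- 6L
  n_far <- if (!is.null(far_island_distance_um)) 1L else 0L
  top0 <- sheet_base + (if (front_protrusions > 0) PROTRUSION_LEN_PX else 0L) + 10L
  band_top <- top0
  band_max_r <- 0L
  x <- margin
  for (i in seq_len(n - n_far)) {
    r <- radii[i]
    if (x + 2 * r + margin > width_px) {
      band_top <- band_top + 2L * band_max_r + margin
      band_max_r <- 0L
      x <- margin
    }
    cols[i] <- x + r
    depths[i] <- band_top + r - sheet_base
    band_max_r <- max(band_max_r, r)
    x <- x + 2L * r + margin
  }
  if (n_far == 1L) {
    r <- radii[n]
    far_px <- ceiling(far_island_distance_um / um_per_px)
    min_top <- band_top + 2L * band_max_r + margin
    top <- max(sheet_base + far_px, min_top)
    depths[n] <- top + r - sheet_base
    cols[n] <- width_px %/% 2L
  }
  list(depths = depths, cols = cols)
}

validate_island_geometry <- function(spec) {
  n <- length(spec$island_radii_px)
  if (n == 0L) return(invisible(spec))
  r <- spec$island_radii_px
  cr <- spec$sheet_thickness_px + spec$island_depths_px
  cc <- spec$island_cols_px
  if (any(cr + r > spec$height_px) || any(cc - r < 1) ||
      any(cc + r > spec$width_px)) {
    abort("Islands do not fit inside the image; enlarge the image or reduce island count/size.")
  }
  if (any(cr - r - spec$sheet_thickness_px < 2)) {
    abort("Island(s) overlap or touch the epithelial sheet; increase island depths.")
  }
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(cr, cc)))
    sep <- outer(r, r, "+") + 3
    diag(d) <- Inf
    if (any(d < sep)) {
      abort("Islands overlap or touch each other at the requested density; refusing to merge ground-truth islands.")
    }
  }
  invisible(spec)
}

#' Render a synthetic organ-culture image with exact ground truth
#'
#' Renders the three channels described by an [organ_image_spec()]:
#' cytokeratin (sheet, protrusions and islands at intensity 1),
#' PDPN (islands 0.8, sheet 0.2) and DAPI (nuclear discs at 1), plus a
#' ground-truth record of every island. Foreground is 1, background 0,
#' with optional additive Gaussian noise clipped to \[0, 1\]. The same
#' spec and seed always produce the identical image.
#'
#' The ground truth stores, per island: centre, radius, rendered pixel
#' area, nuclei count, depth below the sheet base (deepest pixel, um),
#' nearest distance to the sheet (um) and the singular/clustered call;
#' plus the expected SPOI, WPOI grade and invasion index computed from
#' those records with the same rule functions the pipeline uses
#' ([spoi_from_counts()], [wpoi_rule()]).
#'
#' @param spec An [organ_image_spec()].
#' @return A list with `$image` (an `organ_image`: named channel
#'   matrices and `um_per_px`) and `$truth` (ground-truth list).
#' @export
#' @examples
#' img <- generate_organ_image(organ_image_spec(n_singular_islands = 1,
#'                                              n_clustered_islands = 2))
#' img$truth$expected_spoi
generate_organ_image <- function(spec) {
  stopifnot(inherits(spec, "organ_image_spec"))
  validate_island_geometry(spec)
  h <- spec$height_px; w <- spec$width_px
  base <- spec$sheet_thickness_px
  cyto <- matrix(0, h, w)
  pdpn <- matrix(0, h, w)
  dapi <- matrix(0, h, w)

  cyto[seq_len(base), ] <- 1
  pdpn[seq_len(base), ] <- 0.2

  # finger-like protrusions on the invasion front (WPOI-2 geometry)
  if (spec$front_protrusions > 0) {
    gap <- max(PROTRUSION_WIDTH_PX + 10L,
               w %/% (spec$front_protrusions + 1L))
    for (k in seq_len(spec$front_protrusions)) {
      c0 <- min(k * gap, w - PROTRUSION_WIDTH_PX)
      rows <- (base + 1L):(base + PROTRUSION_LEN_PX)
      cols <- c0:(c0 + PROTRUSION_WIDTH_PX - 1L)
      cyto[rows, cols] <- 1
      pdpn[rows, cols] <- 0.2
    }
  }

  # sheet nuclei (counts not tracked; only island nuclei are ground truth)
  sheet_rows <- seq(NUCLEUS_RADIUS_PX + 2L, base - NUCLEUS_RADIUS_PX - 1L,
                    by = NUCLEUS_SPACING_PX)
  sheet_cols <- seq(NUCLEUS_RADIUS_PX + 2L, w - NUCLEUS_RADIUS_PX - 1L,
                    by = NUCLEUS_SPACING_PX)
  grid_sheet <- expand.grid(r = sheet_rows, c = sheet_cols)
  dapi <- paint_discs(dapi, grid_sheet$r, grid_sheet$c, NUCLEUS_RADIUS_PX)

  n <- length(spec$island_radii_px)
  n_sing <- spec$n_singular_islands
  islands <- vector("list", n)
  for (i in seq_len(n)) {
    r <- spec$island_radii_px[i]
    cr <- base + spec$island_depths_px[i]
    cc <- spec$island_cols_px[i]
    off <- disc_offsets(r)
    cyto[cbind(cr + off$dr, cc + off$dc)] <- 1
    pdpn[cbind(cr + off$dr, cc + off$dc)] <- 0.8
    n_nuc <- if (i <= n_sing) spec$nuclei_per_singular else spec$nuclei_per_clustered
    grid <- nucleus_grid(r)
    if (nrow(grid) < n_nuc) {
      abort(paste0("Island ", i, " (radius ", r, " px) cannot hold ", n_nuc,
                   " disjoint nuclei; increase its radius."))
    }
    j <- seq_len(n_nuc)
    dapi <- paint_discs(dapi, cr + grid$dr[j], cc + grid$dc[j], NUCLEUS_RADIUS_PX)
    islands[[i]] <- tibble(
      island_id = i,
      center_row = cr, center_col = cc, radius_px = r,
      area_px2 = nrow(off),
      nuclei_count = as.integer(n_nuc),
      depth_um = (cr + r - base) * spec$um_per_px,
      distance_to_sheet_um = (cr - r - base) * spec$um_per_px,
      is_singular = n_nuc < 15L
    )
  }
  island_tbl <- if (n > 0) list_rbind(islands) else tibble(
    island_id = integer(), center_row = integer(), center_col = integer(),
    radius_px = integer(), area_px2 = integer(), nuclei_count = integer(),
    depth_um = numeric(), distance_to_sheet_um = numeric(),
    is_singular = logical()
  )

  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, {
      cyto <- pmin(pmax(cyto + rnorm(length(cyto), 0, spec$noise_sd), 0), 1)
      pdpn <- pmin(pmax(pdpn + rnorm(length(pdpn), 0, spec$noise_sd), 0), 1)
      dapi <- pmin(pmax(dapi + rnorm(length(dapi), 0, spec$noise_sd), 0), 1)
    })
  }

  n_sing_true <- sum(island_tbl$is_singular)
  n_clust_true <- sum(!island_tbl$is_singular)
  depth_img <- if (n > 0) max(island_tbl$depth_um) else 0
  truth <- list(
    islands = island_tbl,
    sheet_base_row = base,
    n_protrusions = spec$front_protrusions,
    expected_spoi = spoi_from_counts(n_sing_true, n_clust_true)$spoi,
    expected_wpoi = wpoi_rule(
      n_islands = n,
      any_singular = n_sing_true > 0,
      max_distance_um = if (n > 0) max(island_tbl$distance_to_sheet_um) else 0,
      n_protrusions = spec$front_protrusions
    ),
    expected_invasion_index =
      sum(island_tbl$area_px2) * spec$um_per_px^2 * n * depth_img,
    spec = spec
  )

  image <- structure(
    list(channels = list(cytokeratin = cyto, pdpn = pdpn, dapi = dapi),
         um_per_px = spec$um_per_px),
    class = "organ_image"
  )
  list(image = image, truth = truth)
}

#' @export
print.organ_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("organ_image: ", d[1], " x ", d[2], " px, ",
      x$um_per_px, " um/px, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Random valid synthetic image specification
#'
#' Draws a valid [organ_image_spec()] with random island counts, nuclei
#' counts and protrusions, for parameter-recovery sweeps. Geometry is
#' laid out automatically so the spec always validates.
#'
#' @param seed Integer seed.
#' @param noise_sd Intensity noise passed through to the spec.
#' @return An `organ_image_spec`.
#' @export
random_organ_image_spec <- function(seed, noise_sd = 0) {
  withr::with_seed(seed, {
    organ_image_spec(
      width_px = 640L, height_px = 480L,
      n_singular_islands = sample(0:3, 1),
      n_clustered_islands = sample(1:4, 1),
      nuclei_per_singular = sample(1:14, 1),
      nuclei_per_clustered = sample(15:24, 1),
      front_protrusions = sample(0:2, 1),
      noise_sd = noise_sd,
      seed = seed
    )
  })
}
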