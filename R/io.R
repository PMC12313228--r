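# Readers/writers: multi-page TIFF for image channels, JSON sidecars for
# ground truth and provenance, CSV for all tables.

#' Write an organ image as a multi-page TIFF
#'
#' One page per channel, in the channel order of the image; the channel
#' names and calibration belong in the JSON sidecar
#' ([write_truth_sidecar()]) or must be supplied again on reading.
#'
#' @param image An `organ_image`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_organ_image <- function(image, path) {
  tiff::writeTIFF(unname(image$channels), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an organ image from TIFF or PNG
#'
#' TIFF pages (or PNG colour planes) become the named channels, in
#' order. If a JSON sidecar written by [write_truth_sidecar()] sits
#' next to the file (`<stem>.json`), calibration and channel names are
#' taken from it; arguments override the sidecar.
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`).
#' @param um_per_px Calibration override.
#' @param channel_names Channel name override (one per page/plane).
#' @return An `organ_image`.
#' @export
read_organ_image <- function(path, um_per_px = NULL, channel_names = NULL) {
  sidecar_path <- paste0(tools::file_path_sans_ext(path), ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    arr <- png::readPNG(path)
    pages <- if (length(dim(arr)) == 3) {
      map(seq_len(dim(arr)[3]), function(k) arr[, , k])
    } else {
      list(arr)
    }
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  channel_names <- channel_names %||% sidecar$channel_names %||%
    c("cytokeratin", "pdpn", "dapi")[seq_along(pages)]
  um_per_px <- um_per_px %||% sidecar$um_per_px
  if (is.null(um_per_px)) {
    abort("No calibration found: pass `um_per_px` or provide a sidecar.")
  }
  structure(
    list(channels = setNames(pages, channel_names), um_per_px = um_per_px),
    class = "organ_image"
  )
}

#' Write the ground-truth sidecar of a synthetic image
#'
#' JSON sidecar holding the per-island ground truth, the expected SPOI /
#' WPOI / invasion index, the channel names and calibration, and the
#' full generation spec, so any downstream result can be checked
#' against what was rendered.
#'
#' @param truth Ground-truth list from [generate_organ_image()].
#' @param path Output `.json` path.
#' @param experiment_id,image_id Optional identifiers stored alongside.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path, experiment_id = NULL,
                                image_id = NULL) {
  payload <- list(
    image_id = image_id,
    experiment_id = experiment_id,
    channel_names = c("cytokeratin", "pdpn", "dapi"),
    um_per_px = truth$spec$um_per_px,
    sheet_base_row = truth$sheet_base_row,
    n_protrusions = truth$n_protrusions,
    expected_spoi = truth$expected_spoi,
    expected_wpoi = truth$expected_wpoi,
    expected_invasion_index = truth$expected_invasion_index,
    islands = truth$islands,
    spec = unclass(truth$spec)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path Sidecar `.json` path.
#' @return List as written by [write_truth_sidecar()], with `$islands`
#'   as a tibble.
#' @export
read_truth_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$islands <- as_tibble(x$islands)
  x
}

write_provenance <- function(path, stage, config, params = list(),
                             outputs = character(), warnings = character()) {
  jsonlite::write_json(
    list(
      stage = stage,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package_version = as.character(packageVersion("spoiq")),
      config = config,
      parameters = params,
      outputs = outputs,
      warnings = warnings
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
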