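#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one place, with
#' the field defaults: Otsu segmentation, 25 px^2 minimum island area,
#' 9 px^2 minimum nucleus area, the 15-nuclei singular/clustered
#' cutoff, the 1000 um WPOI-5 distance, a 1.5-fold TGF-beta responder
#' threshold, outlier alpha 0.05, nine imaging fields per experiment
#' and a six-population cohort with four TGF-beta responders. Every
#' threshold used is echoed into the provenance log of each stage.
#'
#' @param out_dir Output directory for `run_*` stages.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param ... Overrides of any default listed above (unknown names are
#'   an error).
#' @return A named list of class `run_config`.
#' @seealso [read_run_config()] to load a YAML config file.
#' @export
run_config <- function(out_dir = "spoiq-run", seed = 1L, ...) {
  defaults <- list(
    out_dir = out_dir, seed = as.integer(seed),
    n_populations = 6L,
    pemt_levels = NULL,          # default: even gradient over [0.1, 0.9]
    n_responders = 4L, n_nonresponders = 2L,
    n_fields = 9L,
    n_replicates = 3L,
    n_cells_lwr = 50L,
    um_per_px = 1,
    image_width_px = 640L, image_height_px = 480L,
    noise_sd = 0, ct_noise_sd = 0,
    segmentation_method = "otsu",
    min_island_area = 25, min_nucleus_area = 9,
    nuclei_cutoff = 15L,
    wpoi_distance_um = 1000,
    responder_fold = 1.5,
    outlier_alpha = 0.05,
    tf_n_null = 39L, tf_planted_r = 0.95
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, dots)
  if (is.null(cfg$pemt_levels)) {
    cfg$pemt_levels <- seq(0.1, 0.9, length.out = cfg$n_populations)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read a YAML run configuration
#'
#' Values in the file override the [run_config()] defaults; anything
#' not set in the file keeps its default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

cohort_populations <- function(config) {
  n <- config$n_populations
  lv <- config$pemt_levels
  tibble(
    population_id = paste0("P", seq_len(n)),
    pemt_level = lv,
    # elongation coupled to p-EMT level: cuboidal (~1) at level 0,
    # strongly elongated (~3) at level 1
    lwr_target = 1 + 2 * lv,
    # invasion geometry coupled to p-EMT level
    n_singular = as.integer(round(lv * 4)),
    n_clustered = 2L + as.integer(round(lv * 2))
  )
}

#' Generate the full synthetic dataset on disk
#'
#' Writes a full synthetic study cohort to `config$out_dir`: per
#' population, `n_fields` organ-culture images (TIFF + ground-truth
#' JSON sidecars) whose island geometry follows its latent p-EMT
#' level; a long-format Ct table for the nine-gene panel; cell masks
#' for LWR measurement (PNG + manifest); pSMAD3 densitometry with the
#' default four responders and two non-responders; and a
#' transcription-factor matrix with one planted invasion-tracking TF.
#' Everything is deterministic in `config$seed`.
#'
#' @param config A [run_config()].
#' @return Named list of the paths written, invisibly.
#' @export
run_simulate <- function(config = run_config()) {
  out <- config$out_dir
  img_dir <- file.path(out, "images")
  mask_dir <- file.path(out, "cell_masks")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) abort(paste0("Cannot create output dir ", img_dir))
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  pops <- cohort_populations(config)

  paths <- character()
  for (i in seq_len(nrow(pops))) {
    for (f in seq_len(config$n_fields)) {
      seed_if <- config$seed * 1000L + i * 100L + f
      spec <- organ_image_spec(
        width_px = config$image_width_px, height_px = config$image_height_px,
        um_per_px = config$um_per_px,
        n_singular_islands = pops$n_singular[i],
        n_clustered_islands = pops$n_clustered[i],
        noise_sd = config$noise_sd, seed = seed_if
      )
      gen <- generate_organ_image(spec)
      stem <- file.path(img_dir, sprintf("%s_field%02d", pops$population_id[i], f))
      write_organ_image(gen$image, paste0(stem, ".tif"))
      write_truth_sidecar(gen$truth, paste0(stem, ".json"),
                          experiment_id = pops$population_id[i],
                          image_id = basename(stem))
      paths <- c(paths, paste0(stem, ".tif"))
    }
  }

  ct <- generate_ct_table(
    n_populations = config$n_populations, pemt_levels = pops$pemt_level,
    noise_sd_cycles = config$ct_noise_sd, n_replicates = config$n_replicates,
    population_ids = pops$population_id, seed = config$seed + 1L
  )
  readr::write_csv(ct, file.path(out, "ct_table.csv"))

  lwr_manifest <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    cm <- generate_cell_masks(config$n_cells_lwr,
                              axis_ratios = pops$lwr_target[i],
                              seed = config$seed + 10L + i)
    files <- character(config$n_cells_lwr)
    for (j in seq_along(cm$masks)) {
      files[j] <- file.path(mask_dir,
                            sprintf("%s_cell%03d.png", pops$population_id[i], j))
      png::writePNG(cm$masks[[j]] * 1, files[j])
    }
    lwr_manifest[[i]] <- tibble(population_id = pops$population_id[i],
                                cell_id = cm$truth$cell_id,
                                axis_ratio = cm$truth$axis_ratio,
                                file = files)
  }
  readr::write_csv(list_rbind(lwr_manifest), file.path(out, "cell_masks.csv"))

  dens <- generate_densitometry(config$n_responders, config$n_nonresponders,
                                seed = config$seed + 2L)
  readr::write_csv(dens, file.path(out, "densitometry.csv"))

  # TF matrix planted against the generative invasion phenotype (the
  # p-EMT level, which drives island geometry)
  tfm <- generate_tf_matrix(setNames(pops$pemt_level, pops$population_id),
                            n_null = config$tf_n_null,
                            planted_r = config$tf_planted_r,
                            seed = config$seed + 3L)
  readr::write_csv(as_tibble(tfm, rownames = "population_id"),
                   file.path(out, "tf_matrix.csv"))

  write_provenance(file.path(out, "provenance_simulate.json"), "simulate",
                   unclass(config),
                   outputs = c(paths, "ct_table.csv", "cell_masks.csv",
                               "densitometry.csv", "tf_matrix.csv"))
  invisible(list(
    images = img_dir, ct_table = file.path(out, "ct_table.csv"),
    cell_masks = file.path(out, "cell_masks.csv"),
    densitometry = file.path(out, "densitometry.csv"),
    tf_matrix = file.path(out, "tf_matrix.csv")
  ))
}

#' Quantify every image and aggregate per experiment
#'
#' Reads all TIFF images under `<out_dir>/images`, grades each
#' ([quantify_organ_image()]) with the thresholds in the config, and
#' averages fields per experiment ([aggregate_experiment()]). Writes
#' `grading_results.csv`, `experiment_summary.csv` and a provenance
#' log.
#'
#' @param config A [run_config()].
#' @return List with `$fields` and `$experiments` tibbles, invisibly.
#' @export
run_quantify <- function(config = run_config()) {
  img_dir <- file.path(config$out_dir, "images")
  files <- list.files(img_dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(files) == 0L) abort(paste0("No images found under ", img_dir))
  fields <- map(files, function(f) {
    img <- read_organ_image(f, um_per_px = config$um_per_px)
    sidecar_path <- paste0(tools::file_path_sans_ext(f), ".json")
    exp_id <- if (file.exists(sidecar_path)) {
      read_truth_sidecar(sidecar_path)$experiment_id
    } else {
      sub("_field[0-9]+$", "", tools::file_path_sans_ext(basename(f)))
    }
    quantify_organ_image(
      img, image_id = tools::file_path_sans_ext(basename(f)),
      method = config$segmentation_method,
      min_island_area = config$min_island_area,
      min_nucleus_area = config$min_nucleus_area,
      nuclei_cutoff = config$nuclei_cutoff,
      distance_cutoff_um = config$wpoi_distance_um
    ) |> mutate(experiment_id = exp_id %||% "experiment", .before = 1)
  }) |> list_rbind()
  experiments <- aggregate_experiment(fields, config$n_fields)
  readr::write_csv(fields, file.path(config$out_dir, "grading_results.csv"))
  readr::write_csv(experiments, file.path(config$out_dir, "experiment_summary.csv"))
  write_provenance(file.path(config$out_dir, "provenance_quantify.json"),
                   "quantify", unclass(config),
                   params = list(threshold_per_image = setNames(fields$threshold,
                                                                fields$image_id)),
                   outputs = c("grading_results.csv", "experiment_summary.csv"))
  invisible(list(fields = fields, experiments = experiments))
}

#' Score the qPCR table
#'
#' Reads `<out_dir>/ct_table.csv`, runs [pemt_score()] and writes the
#' per-gene intermediates and per-population scores.
#'
#' @param config A [run_config()].
#' @return The `pemt_score` object, invisibly.
#' @export
run_score <- function(config = run_config()) {
  ct <- readr::read_csv(file.path(config$out_dir, "ct_table.csv"),
                        show_col_types = FALSE)
  res <- pemt_score(ct)
  readr::write_csv(res$genes, file.path(config$out_dir, "pemt_genes.csv"))
  readr::write_csv(res$scores, file.path(config$out_dir, "pemt_scores.csv"))
  write_provenance(file.path(config$out_dir, "provenance_score.json"),
                   "score", unclass(config),
                   outputs = c("pemt_genes.csv", "pemt_scores.csv"))
  invisible(res)
}

#' Association analyses across the cohort
#'
#' Joins the per-population metrics produced by the other stages --
#' p-EMT score, mean LWR (measured from the cell masks), invasion
#' index and SPOI (experiment summaries) -- and correlates the standard
#' pairs (LWR vs p-EMT, invasion index vs p-EMT, invasion index vs
#' LWR, SPOI vs p-EMT). Classifies TGF-beta responders from the
#' densitometry table and, if a TF matrix is present, runs the TF
#' invasion screen against invasion index and SPOI. Writes
#' `associations.csv`, `responders.csv` and `tf_screen.csv`.
#'
#' @param config A [run_config()].
#' @return List with `$associations`, `$responders`, `$tf_screen`
#'   tibbles, invisibly.
#' @export
run_associate <- function(config = run_config()) {
  out <- config$out_dir
  scores <- readr::read_csv(file.path(out, "pemt_scores.csv"),
                            show_col_types = FALSE)
  summ <- readr::read_csv(file.path(out, "experiment_summary.csv"),
                          show_col_types = FALSE)
  manifest <- readr::read_csv(file.path(out, "cell_masks.csv"),
                              show_col_types = FALSE)
  lwr <- manifest |>
    summarise(
      mean_lwr = mean(measure_lwr(map(.data$file, function(f) {
        png::readPNG(f) > 0.5
      }))$lwr),
      .by = "population_id"
    )
  metrics <- scores |>
    rename(pemt_score = "score") |>
    inner_join(summ, by = c(population_id = "experiment_id")) |>
    inner_join(lwr, by = "population_id")
  mism <- setdiff(scores$population_id, metrics$population_id)
  if (length(mism) > 0) {
    abort(paste0("Population labels missing from joined metrics: ",
                 paste(mism, collapse = ", ")))
  }
  pairs <- list(
    c("mean_lwr", "pemt_score"),
    c("pemt_score", "invasion_index_mean"),
    c("mean_lwr", "invasion_index_mean"),
    c("pemt_score", "spoi_mean")
  )
  assoc <- map(pairs, function(p) {
    x <- metrics[[p[1]]]; y <- metrics[[p[2]]]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(x_name = p[1], y_name = p[2], n = length(x),
                    r = NA_real_, p_value = NA_real_, slope = NA_real_,
                    intercept = NA_real_))
    }
    tidy(pearson_with_regression(x, y, x_name = p[1], y_name = p[2]))
  }) |> list_rbind()
  readr::write_csv(assoc, file.path(out, "associations.csv"))

  responders <- NULL
  dens_path <- file.path(out, "densitometry.csv")
  if (file.exists(dens_path)) {
    responders <- classify_tgfb_response(
      readr::read_csv(dens_path, show_col_types = FALSE),
      threshold = config$responder_fold)
    readr::write_csv(responders, file.path(out, "responders.csv"))
  }

  screen <- NULL
  tf_path <- file.path(out, "tf_matrix.csv")
  if (file.exists(tf_path)) {
    tfd <- readr::read_csv(tf_path, show_col_types = FALSE)
    tfm <- as.matrix(tfd[, -1])
    rownames(tfm) <- tfd$population_id
    aligned <- metrics[match(rownames(tfm), metrics$population_id), ]
    if (anyNA(aligned$population_id)) {
      abort("TF matrix population labels do not match the metric tables.")
    }
    screen <- bind_rows(
      tf_screen(tfm, aligned$invasion_index_mean) |>
        mutate(phenotype = "invasion_index", .before = 1),
      tf_screen(tfm, aligned$spoi_mean) |>
        mutate(phenotype = "spoi", .before = 1)
    )
    readr::write_csv(screen, file.path(out, "tf_screen.csv"))
  }
  write_provenance(file.path(out, "provenance_associate.json"), "associate",
                   unclass(config),
                   outputs = c("associations.csv", "responders.csv",
                               "tf_screen.csv"))
  invisible(list(associations = assoc, responders = responders,
                 tf_screen = screen, metrics = metrics))
}

#' Run the whole pipeline
#'
#' [run_simulate()], [run_quantify()], [run_score()] and
#' [run_associate()] in order.
#'
#' @param config A [run_config()].
#' @return The [run_associate()] result, invisibly.
#' @export
run_all <- function(config = run_config()) {
  run_simulate(config)
  run_quantify(config)
  run_score(config)
  run_associate(config)
}
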