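# End-to-end orchestration: ingest -> polarization -> permutation test ->
# orientation -> nest clonality, with a reproducible run manifest.

#' Build and validate a pipeline configuration
#'
#' @param mode `"tables"` (delimited-text nucleus tables) or `"images"`
#'   (label-mask TIFF plus intensity TIFFs per slice).
#' @param tables character vector of nucleus-table paths (tables mode), or a
#'   list of in-memory nucleus tables via `table_data`.
#' @param table_data optional list of nucleus tables already in memory.
#' @param images images mode input: list of lists, each with `label_mask`
#'   (path), `channels` (named vector of paths), `aggregate_id`, `slice_id`.
#' @param pixel_size um per pixel; required in images mode.
#' @param channels named character vector channel -> compartment
#'   (`"Epi"`/`"VE"`).
#' @param masks optional [compartment_masks()] (re-assigns compartments).
#' @param filter list with `area_min`, `area_max`, `circ_min`;
#'   `NULL` disables filtering.
#' @param norm_exponent,n_perm,percentile_threshold,combine_rule permutation
#'   test settings (see [run_permutation_tests()]).
#' @param angle_channels length-2 character vector of channels to compare
#'   (default: first two of `channels` when available).
#' @param nest list with `channel`, `threshold`, `link_distance`, `min_size`;
#'   `NULL` disables the nest stage.
#' @param seed master seed; every randomized stage derives its sub-seed
#'   from it.
#' @param out_dir output directory for the report bundle.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("tables", "images"),
                            tables = NULL, table_data = NULL, images = NULL,
                            pixel_size = NULL, channels,
                            masks = NULL,
                            filter = list(area_min = 40, area_max = 400,
                                          circ_min = 0.5),
                            norm_exponent = 1, n_perm = 100,
                            percentile_threshold = 0.95,
                            combine_rule = "any",
                            angle_channels = NULL, nest = NULL,
                            seed = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(channels)), length(channels) >= 1,
            all(channels %in% c("Epi", "VE")))
  if (mode == "tables") {
    if (is.null(tables) && is.null(table_data)) {
      stop("tables mode needs `tables` paths or `table_data`")
    }
    for (p in tables) {
      if (!file.exists(p)) stop("input table not found: ", p)
    }
  } else {
    if (is.null(images) || length(images) == 0) {
      stop("images mode needs `images` entries")
    }
    if (is.null(pixel_size)) {
      stop("images mode needs `pixel_size` (um per pixel)")
    }
    for (im in images) {
      if (!file.exists(im$label_mask)) {
        stop("label mask not found: ", im$label_mask)
      }
      for (p in im$channels) {
        if (!file.exists(p)) stop("channel image not found: ", p)
      }
    }
  }
  if (is.null(angle_channels) && length(channels) >= 2) {
    angle_channels <- names(channels)[1:2]
  }
  if (!is.null(angle_channels)) {
    stopifnot(length(angle_channels) == 2,
              all(angle_channels %in% names(channels)))
  }
  structure(list(mode = mode, tables = tables, table_data = table_data,
                 images = images, pixel_size = pixel_size,
                 channels = channels, masks = masks, filter = filter,
                 norm_exponent = norm_exponent, n_perm = n_perm,
                 percentile_threshold = percentile_threshold,
                 combine_rule = combine_rule,
                 angle_channels = angle_channels, nest = nest,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `channels` and the
#' optional `nest`/`filter` blocks are plain mappings. Relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  if (!is.null(y$tables)) y$tables <- resolve(unlist(y$tables))
  if (!is.null(y$images)) {
    y$images <- lapply(y$images, function(im) {
      im$label_mask <- resolve(im$label_mask)
      im$channels <- vapply(im$channels, resolve, "")
      im
    })
  }
  y$channels <- unlist(y$channels)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

#' Run the full spatial-patterning pipeline
#'
#' Stages, in order: ingest (read tables or extract from images), nucleus
#' filtering, optional compartment assignment from masks, per-slice intensity
#' rescaling, polarization vectors, permutation classification, inter-domain
#' angles, and (when configured) nest detection with clonality scoring.
#' All stage tables, a JSON run manifest (config echo, seed, warning counts)
#' and a plain-text summary are written to `out_dir`; re-running with the
#' same config and inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return invisibly, a list with all stage results (`nuclei`,
#'   `polarization`, `classification`, `angles`, `angle_summary`, `nests`,
#'   `clonality`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  warnings_seen <- character(0)
  note <- function(w) warnings_seen <<- c(warnings_seen, conditionMessage(w))

  # --- ingest -------------------------------------------------------------
  tabs <- list()
  if (config$mode == "tables") {
    for (p in config$tables %||% character(0)) {
      tabs[[length(tabs) + 1]] <- read_nucleus_table(p)
    }
    for (t in config$table_data %||% list()) tabs[[length(tabs) + 1]] <- t
  } else {
    for (im in config$images) {
      mask <- read_image(im$label_mask, as_labels = TRUE)
      chans <- lapply(im$channels, read_image)
      names(chans) <- names(im$channels)
      tabs[[length(tabs) + 1]] <-
        extract_nucleus_table(mask, chans, config$pixel_size,
                              aggregate_id = im$aggregate_id %||% "img",
                              slice_id = im$slice_id %||% "s1")
    }
  }
  nuclei <- do.call(rbind, tabs)
  n_raw <- nrow(nuclei)

  removed <- NULL
  if (!is.null(config$filter)) {
    nuclei <- filter_nuclei(nuclei, config$filter$area_min %||% 40,
                            config$filter$area_max %||% 400,
                            config$filter$circ_min %||% 0.5)
    removed <- attr(nuclei, "removed")
  }
  if (!is.null(config$masks)) {
    nuclei <- assign_compartments(nuclei, config$masks)
  }
  nuclei <- withCallingHandlers(
    rescale_intensities(nuclei, names(config$channels)),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })

  # --- polarization + classification --------------------------------------
  pol <- compute_polarization(nuclei, config$channels, config$norm_exponent)
  cls <- run_permutation_tests(nuclei, config$channels,
                               n_perm = config$n_perm,
                               percentile_threshold =
                                 config$percentile_threshold,
                               norm_exponent = config$norm_exponent,
                               master_seed = config$seed,
                               combine_rule = config$combine_rule)

  # --- orientation ---------------------------------------------------------
  angles <- NULL
  angle_summary <- NULL
  if (!is.null(config$angle_channels)) {
    angles <- compute_angles(pol, config$angle_channels[1],
                             config$angle_channels[2],
                             classification = cls$slices)
    if (!is.null(angles) && any(angles$defined)) {
      grp <- ifelse(!is.na(angles$polarized_a) & angles$polarized_a,
                    "polarized", "non_polarized")
      angle_summary <- orientation_summary(
        angles, group = grp, seed = derive_seed(config$seed, "orientation"))
    }
  }

  # --- nests ---------------------------------------------------------------
  nests <- NULL
  clonality <- NULL
  sweep_tab <- NULL
  if (!is.null(config$nest)) {
    nst <- config$nest
    flagged <- flag_positive(nuclei, nst$channel, nst$threshold %||% 0.3)
    nests <- detect_nests(flagged, nst$link_distance %||% 25,
                          nst$min_size %||% 3, channel = nst$channel)
    clonality <- clonality_score(nests, flagged)
    sweep_tab <- clonality_sweep(nuclei, nst$channel,
                                 link_distance = nst$link_distance %||% 25,
                                 min_size = nst$min_size %||% 3)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("belapol")),
    seed = config$seed,
    mode = config$mode,
    n_nuclei_raw = n_raw,
    n_nuclei_kept = nrow(nuclei),
    filter_removed = removed,
    channels = as.list(config$channels),
    norm_exponent = config$norm_exponent,
    n_perm = config$n_perm,
    percentile_threshold = config$percentile_threshold,
    combine_rule = config$combine_rule,
    nest = config$nest,
    n_warnings = length(warnings_seen),
    warnings = warnings_seen)

  result <- list(nuclei = nuclei, polarization = pol,
                 classification = cls, angles = angles,
                 angle_summary = angle_summary,
                 nests = nests, clonality = clonality,
                 clonality_sweep = sweep_tab, manifest = manifest)

  if (!is.null(config$out_dir)) {
    write_report_bundle(result, config$out_dir)
  }
  invisible(result)
}

# Write every stage table plus manifest and summary to out_dir.
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stage_table(result$nuclei, file.path(out_dir, "nuclei.tsv"))
  write_stage_table(result$polarization,
                    file.path(out_dir, "polarization.tsv"))
  write_stage_table(result$classification$slices,
                    file.path(out_dir, "classification_slices.tsv"))
  if (!is.null(result$classification$aggregates)) {
    write_stage_table(result$classification$aggregates,
                      file.path(out_dir, "classification_aggregates.tsv"))
  }
  if (!is.null(result$angles)) {
    write_stage_table(result$angles, file.path(out_dir, "angles.tsv"))
  }
  if (!is.null(result$angle_summary)) {
    write_stage_table(result$angle_summary,
                      file.path(out_dir, "angle_summary.tsv"))
  }
  if (!is.null(result$nests)) {
    write_stage_table(result$nests, file.path(out_dir, "nests.tsv"))
    write_stage_table(result$clonality$summary,
                      file.path(out_dir, "clonality_summary.tsv"))
    write_stage_table(result$clonality$per_nest,
                      file.path(out_dir, "clonality_per_nest.tsv"))
    write_stage_table(result$clonality_sweep,
                      file.path(out_dir, "clonality_threshold_sweep.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  sl <- result$classification$slices
  summary_lines <- c(
    "belapol run summary",
    sprintf("nuclei analyzed: %d", nrow(result$nuclei)),
    sprintf("slices x channels tested: %d", nrow(sl)),
    sprintf("polarized slice calls: %d / %d",
            sum(sl$polarized, na.rm = TRUE), sum(!is.na(sl$polarized))))
  if (!is.null(result$clonality)) {
    s <- result$clonality$summary
    summary_lines <- c(summary_lines,
                       sprintf("nests: %d (monoclonal %d, mixed %d, unscored %d)",
                               s$n_nests, s$monoclonal, s$mixed, s$unscored))
  }
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
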