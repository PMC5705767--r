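#' Load and validate a pipeline configuration
#'
#' Configurations are nested lists (or YAML/JSON files) with blocks:
#' `input` (image `path` or a `simulate` scenario), `channels` (role ->
#' channel name), `detection`, `segmentation`, `spatial`, `registration`,
#' `output` (directory), and a global `seed`. Channel roles must be unique
#' and refer to channels present in the input.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return A validated `pipeline_config` list (defaults resolved).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    channels = list(nuclear = "nuclear", exon = "exon"),
    detection = list(),
    segmentation = list(),
    spatial = list(colocalization_radius_um = 0.3,
                   foci_merge_radius_um = 0.3, foci_min_equivalent = 2),
    output = list(dir = NULL)
  )
  for (nm in names(defaults)) {
    config[[nm]] <- if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      modifyList(defaults[[nm]], config[[nm]])
    } else config[[nm]] %||% defaults[[nm]]
  }
  ch <- unlist(config$channels)
  if (anyDuplicated(names(ch))) abort("channel roles must be unique")
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (optional) -> detect -> segment -> spatial -> quantify, writing
#' every table plus a QC report and the fully resolved configuration (with
#' its hash and package version) into the run directory, so any output
#' file is traceable to the exact parameters that produced it. Reruns with
#' the same config and seed are bit-identical for the seeded stages.
#'
#' @param config A [pipeline_config()] (or list/path coercible to one).
#' @param output_dir Run directory; created if missing. Defaults to
#'   `config$output$dir` or a temporary directory.
#' @return Invisible list with all intermediate results and `run_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  run_dir <- output_dir %||% config$output$dir %||%
    file.path(tempdir(), paste0("immunofish-run-", config_hash(config)))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("failed at stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(run_dir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # --- input ---------------------------------------------------------------
  sim <- NULL
  geometry <- NULL
  if (!is.null(config$input$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(scenario_config, config$input$simulate)
      simulate_scenario(sc, seed = config$seed)
    })
    image <- sim$image
    geometry <- sim$geometry
  } else if (!is.null(config$input$path)) {
    image <- stage("read", read_image_stack(config$input$path,
                                            config$input$voxel_size))
  } else {
    abort("config$input must provide either `simulate` or `path`")
  }
  roles <- config$channels

  # --- detection -----------------------------------------------------------
  det_cfg <- do.call(detection_config, config$detection)
  rna_roles <- intersect(c("intron", "exon", "dna"), names(roles))
  thresholds <- list()
  spots <- stage("detect", {
    res <- lapply(rna_roles, function(role) {
      s <- detect_spots(image, det_cfg, channel_name = roles[[role]])
      thresholds[[role]] <<- attr(s, "threshold")
      mutate(s, channel = role)
    })
    bind_rows(res) |> mutate(spot_id = row_number())
  })

  # --- segmentation --------------------------------------------------------
  seg <- stage("segment", {
    if (!is.null(geometry)) {
      geometry # truth masks available from simulation
    } else {
      seg_cfg <- config$segmentation
      cell_channel <- seg_cfg$cell_channel
      seg_cfg$cell_channel <- NULL
      nuc <- do.call(segment_nuclei, c(list(image), seg_cfg))
      mn <- classify_micronuclei(nuc)
      # cells: seeded watershed when a boundary-marking channel is named,
      # else distance-limited Voronoi dilation of the nuclei
      chan <- if (!is.null(cell_channel)) get_channel(image, cell_channel)
      cells <- segment_cells(mn$nuclei, chan)
      segmentation_labels(mn$nuclei, mn$micronuclei, cells, mn$parents)
    }
  })

  # --- spatial -------------------------------------------------------------
  ann <- stage("spatial", {
    a <- assign_compartments(spots, seg)
    if (all(c("intron", "exon") %in% unique(a$channel))) {
      a <- call_pre_mrna(filter(a, .data$channel == "intron"),
                         filter(a, .data$channel == "exon"),
                         config$spatial$colocalization_radius_um) |>
        bind_rows(filter(a, !.data$channel %in% c("intron", "exon")))
    }
    a
  })
  foci <- stage("foci", {
    cyt <- filter(ann, .data$channel == "exon",
                  .data$compartment == "cytoplasm")
    unit <- if (nrow(cyt) >= 5) median(cyt$integrated_intensity) else NA
    if (is.finite(unit) && unit > 0) {
      detect_foci(filter(ann, .data$channel == "exon",
                         .data$compartment %in% c("nucleus", "micronucleus")),
                  unit, config$spatial$foci_merge_radius_um,
                  config$spatial$foci_min_equivalent)
    } else NULL
  })

  # --- quantify ------------------------------------------------------------
  intens <- if ("protein" %in% names(roles)) {
    measure_cell_intensity(image, seg, per = "cell",
                           channel_name = roles[["protein"]])
  } else NULL
  profiles <- stage("quantify",
                    build_cell_profiles(ann, foci, intens, seg,
                                        condition = config$condition %||%
                                          NA_character_))

  # --- outputs -------------------------------------------------------------
  write_tables(list(spots = ann, foci = foci, profiles = profiles),
               run_dir)
  qc <- list(
    n_spots = nrow(ann),
    n_cells = nrow(profiles),
    n_nuclei = attr(profiles, "n_nuclei"),
    population_estimator = as.list(attr(profiles, "population_estimator")),
    detection_threshold = thresholds,
    intron_qc = attr(ann, "qc")
  )
  jsonlite::write_json(qc, file.path(run_dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  prov <- list(config = unclass(config), config_hash = config_hash(config),
               package_version =
                 as.character(utils::packageVersion("immunofishr")))
  jsonlite::write_json(prov, file.path(run_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(image = image, segmentation = seg, spots = ann,
                 foci = foci, profiles = profiles, qc = qc,
                 simulation = sim, run_dir = run_dir))
}

#' Write pipeline tables as CSV
#'
#' @param tables Named list of data frames (list-columns are flattened by
#'   joining elements with `"+"`).
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb)) next
    tb <- as.data.frame(lapply(tb, function(col) {
      if (is.list(col)) {
        vapply(col, function(el) paste(el, collapse = "+"), "")
      } else col
    }), stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
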