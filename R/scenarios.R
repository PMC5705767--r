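#' Simulation scenario presets
#'
#' Named bundles of generator parameters emulating the assay's study
#' designs: `steady_state` (amplified line at full expression, a few
#' transcription foci per cell, a small nuclear pre-mRNA pool),
#' `knockdown` (steady state followed by complete cytoplasmic mRNA
#' degradation, leaving roughly an eighth of the transcripts, all
#' nuclear), `timecourse` (a vector of per-condition scalings of mean
#' count and protein gain), and `two_round` (steady state plus DNA loci
#' and a second, distorted imaging round).
#'
#' @param name Scenario name.
#' @param ... Overrides merged into the preset (nested lists merged
#'   shallowly per block: `geometry`, `transcripts`, `render`,
#'   `distortion`, `knockdown`).
#' @return A `scenario_config` list with blocks `geometry`, `transcripts`,
#'   `render`, and optionally `knockdown`, `distortion`, `conditions`.
#' @export
scenario_config <- function(name = c("steady_state", "knockdown",
                                     "timecourse", "two_round"), ...) {
  name <- match.arg(name)
  base <- list(
    geometry = list(n_cells = 5, field_shape = c(40L, 448L, 448L),
                    voxel_size = c(0.2, 0.107, 0.107),
                    micronucleus_rate = 0),
    transcripts = list(mean_mature_per_cell = 100, pre_mrna_fraction = 0.03,
                       n_foci_per_cell = 0, transcripts_per_focus = 8,
                       active_locus_fraction = 0.8,
                       nuclear_mature_fraction = 0.10, dispersion = 5),
    render = list()
  )
  cfg <- switch(
    name,
    steady_state = base,
    knockdown = modifyList(base, list(
      knockdown = list(cytoplasmic_removal_fraction = 1)
    )),
    timecourse = modifyList(base, list(
      conditions = list(
        list(condition = "0h", count_scale = 1.00),
        list(condition = "7h", count_scale = 0.65),
        list(condition = "24h", count_scale = 0.86)
      )
    )),
    two_round = modifyList(base, list(
      geometry = modifyList(base$geometry,
                            list(n_cells = 4, field_shape = c(48L, 448L, 448L))),
      transcripts = modifyList(base$transcripts, list(n_foci_per_cell = 4)),
      distortion = list(shrink_factor = 0.9, deformation_amplitude = 0.4,
                        deformation_wavelength = 25, margin_um = 1)
    ))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      modifyList(cfg[[nm]], dots[[nm]])
    } else dots[[nm]]
  }
  cfg$name <- name
  structure(cfg, class = "scenario_config")
}

#' Simulate a complete scenario
#'
#' Generates geometry, transcript truth and rendered image stack(s) from a
#' [scenario_config()]. For a `knockdown` scenario both the control and
#' knocked-down truth/images are returned; for `two_round`, the distorted
#' second round (with its exact displacement field) is included.
#'
#' @param config A [scenario_config()].
#' @param seed Master seed; sub-seeds for geometry, counts, rendering and
#'   distortion are derived deterministically from it.
#' @return List with `geometry`, `truth`, `image` and scenario-specific
#'   extras (`truth_kd`/`image_kd`, or `round2` with `geometry`, `truth`,
#'   `image`, `displacement`).
#' @export
simulate_scenario <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  geom <- do.call(generate_cell_geometry,
                  c(config$geometry, list(seed = derive_seed(seed, 1))))
  truth <- do.call(generate_transcripts,
                   c(list(geometry = geom), config$transcripts,
                     list(seed = derive_seed(seed, 2))))
  rc <- do.call(render_config,
                c(config$render, list(seed = derive_seed(seed, 3))))
  image <- render_image(geom, truth, rc)
  out <- list(geometry = geom, truth = truth, image = image,
              render_config = rc, config = config)

  if (!is.null(config$knockdown)) {
    truth_kd <- simulate_knockdown(
      truth, config$knockdown$cytoplasmic_removal_fraction,
      seed = derive_seed(seed, 4))
    rc_kd <- do.call(render_config,
                     c(config$render, list(seed = derive_seed(seed, 5))))
    out$truth_kd <- truth_kd
    out$image_kd <- render_image(geom, truth_kd, rc_kd)
  }
  if (!is.null(config$distortion)) {
    dc <- do.call(distortion_config,
                  c(config$distortion, list(seed = derive_seed(seed, 6))))
    dist <- apply_cycle_distortion(geom, truth, dc)
    rc2 <- do.call(render_config,
                   c(config$render, list(seed = derive_seed(seed, 7))))
    dna_truth <- filter(dist$truth, .data$species == "dna_locus")
    out$round2 <- list(
      geometry = dist$geometry,
      truth = dist$truth,
      dna_truth = dna_truth,
      image = render_image(dist$geometry, dna_truth, rc2,
                           channels = c("nuclear", "dna")),
      displacement = dist$displacement,
      distortion_config = dc
    )
  }
  out
}
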