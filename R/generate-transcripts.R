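#' Generate ground-truth transcript positions for a cell geometry
#'
#' Draws per-cell transcript counts from a negative binomial distribution
#' (capturing cell-to-cell heterogeneity) and places molecules in the
#' geometry. Mature mRNA is placed uniformly within the cytoplasm or, for a
#' small configurable fraction, the nucleus; pre-mRNA (intron-retaining,
#' visible in both the intron and exon channels) is placed only in nuclei
#' and micronuclei; transcription foci are bright multi-transcript spots at
#' genomic loci, of which only a fraction is transcriptionally active.
#'
#' @param geometry A [generate_cell_geometry()] result.
#' @param mean_mature_per_cell Mean mature transcripts per cell.
#' @param pre_mrna_fraction Fraction of transcripts that are unspliced
#'   pre-mRNA, in \[0, 1\].
#' @param n_foci_per_cell Number of genomic loci (DNA FISH signals) per
#'   cell.
#' @param transcripts_per_focus Mean nascent transcripts per active focus
#'   (Poisson, floored at 2).
#' @param active_locus_fraction Fraction of loci carrying an RNA focus.
#' @param nuclear_mature_fraction Fraction of the mature pool that is still
#'   nuclear (awaiting export).
#' @param dispersion Negative binomial dispersion (`size`); smaller is more
#'   heterogeneous.
#' @param seed Integer seed.
#'
#' @return A tibble with one row per ground-truth spot: physical position,
#'   `species` (`mature_mRNA`, `pre_mRNA`, `dna_locus`), `channels`
#'   (list-column of channel names), `unit_count`, `compartment`, `cell_id`
#'   and `focus_id`.
#' @export
generate_transcripts <- function(geometry,
                                 mean_mature_per_cell = 100,
                                 pre_mrna_fraction = 0.03,
                                 n_foci_per_cell = 0,
                                 transcripts_per_focus = 8,
                                 active_locus_fraction = 0.8,
                                 nuclear_mature_fraction = 0.10,
                                 dispersion = 5,
                                 seed = 1L) {
  stopifnot(inherits(geometry, "cell_geometry"))
  check_scalar_number(mean_mature_per_cell, "mean_mature_per_cell", lower = 0)
  check_scalar_number(pre_mrna_fraction, "pre_mrna_fraction", 0, 1)
  check_scalar_number(active_locus_fraction, "active_locus_fraction", 0, 1)
  check_scalar_number(nuclear_mature_fraction, "nuclear_mature_fraction", 0, 1)
  vs <- geometry$voxel_size
  d <- geometry$field_shape
  n_cells <- nrow(geometry$centers)
  cyto <- cytoplasm_labels(geometry)

  # voxel index lists per cell and compartment
  vox <- list(
    nucleus = split(which(geometry$nuclei > 0L),
                    geometry$nuclei[geometry$nuclei > 0L]),
    cytoplasm = split(which(cyto > 0L), cyto[cyto > 0L]),
    micronucleus = split(which(geometry$micronuclei > 0L),
                         geometry$micronuclei[geometry$micronuclei > 0L])
  )
  micro_parent <- geometry$micronucleus_parents

  place_uniform <- function(voxel_ids, k) {
    pick <- voxel_ids[sample.int(length(voxel_ids), k, replace = TRUE)]
    zyx <- linear_to_zyx(pick, d)
    sweep(zyx - 1 + matrix(runif(3 * k), k, 3), 2, vs, `*`)
  }

  with_seed_(seed, {
    rows <- list()
    sid <- 0L
    fid <- 0L
    for (ci in seq_len(n_cells)) {
      nuc_vox <- vox$nucleus[[as.character(ci)]]
      cyt_vox <- vox$cytoplasm[[as.character(ci)]]
      mids <- micro_parent$micronucleus_id[micro_parent$cell_id == ci]
      mic_vox <- unlist(vox$micronucleus[as.character(mids)], use.names = FALSE)

      mu_tot <- mean_mature_per_cell / max(1 - pre_mrna_fraction, 1e-12)
      n_tot <- if (mu_tot > 0) rnbinom(1, size = dispersion, mu = mu_tot) else 0L
      n_pre <- if (n_tot > 0) stats::rbinom(1, n_tot, pre_mrna_fraction) else 0L
      n_mat <- n_tot - n_pre
      n_mat_nuc <- if (n_mat > 0) stats::rbinom(1, n_mat, nuclear_mature_fraction) else 0L
      n_mat_cyt <- n_mat - n_mat_nuc

      need <- c(cytoplasm = n_mat_cyt, nucleus = n_pre + n_mat_nuc)
      if (need[["cytoplasm"]] > 0 && length(cyt_vox) == 0) {
        abort(sprintf("cell %d has an empty cytoplasm but %d cytoplasmic spots requested",
                      ci, need[["cytoplasm"]]))
      }
      if (need[["nucleus"]] > 0 && length(nuc_vox) == 0) {
        abort(sprintf("cell %d has an empty nucleus but %d nuclear spots requested",
                      ci, need[["nucleus"]]))
      }

      if (n_mat_cyt > 0) {
        p <- place_uniform(cyt_vox, n_mat_cyt)
        rows[[length(rows) + 1L]] <- tibble(
          z_um = p[, 1], y_um = p[, 2], x_um = p[, 3],
          species = "mature_mRNA", channels = list("exon"),
          unit_count = 1L, compartment = "cytoplasm", cell_id = ci,
          focus_id = NA_integer_
        )
      }
      if (n_mat_nuc > 0) {
        p <- place_uniform(nuc_vox, n_mat_nuc)
        rows[[length(rows) + 1L]] <- tibble(
          z_um = p[, 1], y_um = p[, 2], x_um = p[, 3],
          species = "mature_mRNA", channels = list("exon"),
          unit_count = 1L, compartment = "nucleus", cell_id = ci,
          focus_id = NA_integer_
        )
      }
      if (n_pre > 0) {
        # pre-mRNA lives in the nucleus and, when present, micronuclei,
        # weighted by volume
        pool <- c(nuc_vox, mic_vox)
        pick <- pool[sample.int(length(pool), n_pre, replace = TRUE)]
        comp <- ifelse(pick %in% mic_vox, "micronucleus", "nucleus")
        zyx <- linear_to_zyx(pick, d)
        p <- sweep(zyx - 1 + matrix(runif(3 * n_pre), n_pre, 3), 2, vs, `*`)
        rows[[length(rows) + 1L]] <- tibble(
          z_um = p[, 1], y_um = p[, 2], x_um = p[, 3],
          species = "pre_mRNA", channels = list(c("intron", "exon")),
          unit_count = 1L, compartment = comp, cell_id = ci,
          focus_id = NA_integer_
        )
      }
      if (n_foci_per_cell > 0) {
        if (length(nuc_vox) == 0) {
          abort(sprintf("cell %d has an empty nucleus but foci were requested", ci))
        }
        p <- place_uniform(nuc_vox, n_foci_per_cell)
        for (k in seq_len(n_foci_per_cell)) {
          fid <- fid + 1L
          active <- runif(1) < active_locus_fraction
          rows[[length(rows) + 1L]] <- tibble(
            z_um = p[k, 1], y_um = p[k, 2], x_um = p[k, 3],
            species = "dna_locus", channels = list("dna"),
            unit_count = 1L, compartment = "nucleus", cell_id = ci,
            focus_id = fid
          )
          if (active) {
            uc <- max(2L, rpois(1, transcripts_per_focus))
            rows[[length(rows) + 1L]] <- tibble(
              z_um = p[k, 1], y_um = p[k, 2], x_um = p[k, 3],
              species = "pre_mRNA", channels = list(c("intron", "exon")),
              unit_count = uc, compartment = "nucleus", cell_id = ci,
              focus_id = fid
            )
          }
        }
      }
    }
    out <- if (length(rows)) bind_rows(rows) else tibble(
      z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
      species = character(0), channels = list(), unit_count = integer(0),
      compartment = character(0), cell_id = integer(0),
      focus_id = integer(0)
    )
    for (cl in c("z_um", "y_um", "x_um")) {
      out[[cl]] <- as.numeric(unname(out[[cl]]))
    }
    out <- mutate(out, spot_id = row_number(), .before = 1)
    attr(out, "voxel_size") <- vs
    attr(out, "field_shape") <- d
    out
  })
}

#' Simulate an siRNA knockdown on a transcript truth table
#'
#' RNA interference degrades target mRNA in the cytoplasm (where the RISC
#' complex resides); nuclear and micronuclear transcripts escape. This
#' removes the stated fraction of cytoplasmic mature mRNA uniformly at
#' random and leaves everything else untouched. It never creates spots: the
#' output is a subset of the input rows.
#'
#' @param truth A [generate_transcripts()] table.
#' @param cytoplasmic_removal_fraction Fraction of cytoplasmic mature mRNA
#'   removed, in \[0, 1\].
#' @param seed Integer seed for the random subset.
#' @return The filtered truth table (attributes preserved).
#' @export
simulate_knockdown <- function(truth, cytoplasmic_removal_fraction = 1,
                               seed = 1L) {
  check_scalar_number(cytoplasmic_removal_fraction,
                      "cytoplasmic_removal_fraction", 0, 1)
  victims <- which(truth$species == "mature_mRNA" &
                     truth$compartment == "cytoplasm")
  drop <- with_seed_(seed, {
    victims[runif(length(victims)) < cytoplasmic_removal_fraction]
  })
  if (cytoplasmic_removal_fraction >= 1) drop <- victims
  out <- if (length(drop)) truth[-drop, ] else truth
  attr(out, "voxel_size") <- attr(truth, "voxel_size")
  attr(out, "field_shape") <- attr(truth, "field_shape")
  out
}
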