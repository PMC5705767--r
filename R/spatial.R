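#' Assign detected spots to subcellular compartments
#'
#' Each spot is assigned the compartment of the voxel containing it
#' (voxel-centre convention): micronucleus, nucleus, cytoplasm, or
#' `"outside"` when no label covers it; the cell id is inherited from the
#' labels. Spots outside the image bounds are an error.
#'
#' @param spots Spot tibble with `z_um`, `y_um`, `x_um`.
#' @param labels A `cell_geometry` or `segmentation_labels` object.
#' @return The spots with `compartment` and `cell_id` columns added.
#' @export
assign_compartments <- function(spots, labels) {
  stopifnot(inherits(labels, "cell_geometry"))
  d <- labels$field_shape
  vs <- labels$voxel_size
  if (nrow(spots) == 0) {
    return(mutate(spots, compartment = character(0), cell_id = integer(0)))
  }
  pts <- cbind(spots$z_um, spots$y_um, spots$x_um)
  ext <- d * vs
  bad <- which(pts[, 1] < 0 | pts[, 1] > ext[1] | pts[, 2] < 0 |
                 pts[, 2] > ext[2] | pts[, 3] < 0 | pts[, 3] > ext[3])
  if (length(bad) > 0) {
    abort(sprintf("spot %d lies outside the image bounds", bad[1]))
  }
  idx <- um_to_index(pts, vs)
  for (ax in 1:3) idx[, ax] <- pmin(idx[, ax], d[ax]) # top edge inclusive
  lin <- zyx_to_linear(idx, d)
  nuc <- labels$nuclei[lin]
  mic <- labels$micronuclei[lin]
  cell <- labels$cells[lin]
  micro_parent <- labels$micronucleus_parents
  comp <- dplyr::case_when(
    mic > 0L ~ "micronucleus",
    nuc > 0L ~ "nucleus",
    cell > 0L ~ "cytoplasm",
    TRUE ~ "outside"
  )
  cid <- ifelse(mic > 0L,
                micro_parent$cell_id[match(mic, micro_parent$micronucleus_id)],
                ifelse(nuc > 0L, nuc, ifelse(cell > 0L, cell, NA_integer_)))
  mutate(spots, compartment = comp, cell_id = as.integer(cid))
}

#' Greedy mutual-nearest-neighbour colocalization of two spot sets
#'
#' Candidate pairs within `max_distance_um` are matched greedily by
#' ascending Euclidean distance (ties by spot ids), each spot used at most
#' once. Greedy matching on a sorted pair list is symmetric in its
#' arguments and deterministic.
#'
#' @param spots_a,spots_b Spot tibbles with `z_um`, `y_um`, `x_um` (and
#'   optionally `spot_id`; row numbers are used otherwise).
#' @param max_distance_um Matching cutoff (μm); the default 0.3 μm is about
#'   one particle diameter.
#' @return List with `pairs` (tibble `id_a`, `id_b`, `distance_um`) and
#'   integer vectors `unmatched_a`, `unmatched_b`.
#' @export
colocalize <- function(spots_a, spots_b, max_distance_um = 0.3) {
  ids_a <- spots_a$spot_id %||% seq_len(nrow(spots_a))
  ids_b <- spots_b$spot_id %||% seq_len(nrow(spots_b))
  na <- nrow(spots_a); nb <- nrow(spots_b)
  empty <- list(pairs = tibble(id_a = integer(0), id_b = integer(0),
                               distance_um = numeric(0)),
                unmatched_a = ids_a, unmatched_b = ids_b)
  if (na == 0 || nb == 0) return(empty)
  pa <- cbind(spots_a$z_um, spots_a$y_um, spots_a$x_um)
  pb <- cbind(spots_b$z_um, spots_b$y_um, spots_b$x_um)
  d2 <- euclid2(pa, pb)
  cand <- which(d2 <= max_distance_um^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  dd <- sqrt(d2[cand])
  ord <- order(dd, ids_a[cand[, 1]], ids_b[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  dd <- dd[ord]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  list(
    pairs = tibble(id_a = ids_a[cand[keep, 1]], id_b = ids_b[cand[keep, 2]],
                   distance_um = dd[keep]),
    unmatched_a = ids_a[!used_a],
    unmatched_b = ids_b[!used_b]
  )
}

#' Classify intron/exon spot pairs into pre-mRNA calls
#'
#' An intron-channel spot colocalized with an exon-channel spot is an
#' unspliced pre-mRNA; an exon-only spot is mature mRNA; an intron-only
#' spot is flagged `intron_orphan` for QC (intronic signal should never
#' occur without its exon partner). Compartments must already be assigned.
#'
#' @param intron_spots,exon_spots Annotated spot tibbles (with
#'   `compartment`).
#' @param max_distance_um Colocalization cutoff (μm).
#' @return Combined tibble with a `species_call` column and `partner_id`;
#'   attribute `qc` lists the nuclear fraction of intron spots (nucleus +
#'   micronucleus) and the orphan fraction.
#' @export
call_pre_mrna <- function(intron_spots, exon_spots, max_distance_um = 0.3) {
  if (!("compartment" %in% names(intron_spots)) ||
      !("compartment" %in% names(exon_spots))) {
    abort("assign compartments before calling pre-mRNA")
  }
  m <- colocalize(intron_spots, exon_spots, max_distance_um)
  intron <- mutate(
    intron_spots,
    species_call = as.character(ifelse(.data$spot_id %in% m$pairs$id_a,
                                       "pre_mRNA", "intron_orphan")),
    partner_id = m$pairs$id_b[match(.data$spot_id, m$pairs$id_a)]
  )
  exon <- mutate(
    exon_spots,
    species_call = as.character(ifelse(.data$spot_id %in% m$pairs$id_b,
                                       "pre_mRNA", "mature_mRNA")),
    partner_id = m$pairs$id_a[match(.data$spot_id, m$pairs$id_b)]
  )
  out <- bind_rows(intron, exon)
  n_intron <- nrow(intron)
  qc <- list(
    intron_nuclear_fraction = if (n_intron > 0) {
      mean(intron$compartment %in% c("nucleus", "micronucleus"))
    } else NA_real_,
    intron_orphan_fraction = if (n_intron > 0) {
      mean(intron$species_call == "intron_orphan")
    } else NA_real_,
    n_pre_mrna = nrow(m$pairs)
  )
  attr(out, "qc") <- qc
  out
}

#' Detect nuclear transcription foci by single-linkage clustering
#'
#' Nuclear spots are clustered at `merge_radius_um` (single linkage); a
#' cluster is a focus when its summed integrated intensity corresponds to
#' at least `min_equivalent` unit transcripts. `unit_intensity` is the
#' integrated intensity of a single transcript, typically the median over
#' cytoplasmic single spots.
#'
#' @param nuclear_spots Spot tibble (intended: nuclear compartment only)
#'   with `integrated_intensity`.
#' @param unit_intensity Integrated intensity of one transcript (> 0).
#' @param merge_radius_um Single-linkage merge radius (μm).
#' @param min_equivalent Minimum transcript equivalents for a focus.
#' @return Tibble of foci: centroid, `n_spots`, `integrated_intensity`,
#'   `transcript_equivalent`, `member_ids` (list-column), `cell_id`.
#' @export
detect_foci <- function(nuclear_spots, unit_intensity, merge_radius_um = 0.3,
                        min_equivalent = 2) {
  if (!is.numeric(unit_intensity) || length(unit_intensity) != 1 ||
      !is.finite(unit_intensity) || unit_intensity <= 0) {
    abort("`unit_intensity` must be a single positive number")
  }
  empty <- tibble(focus_id = integer(0), z_um = numeric(0), y_um = numeric(0),
                  x_um = numeric(0), n_spots = integer(0),
                  integrated_intensity = numeric(0),
                  transcript_equivalent = integer(0), member_ids = list(),
                  cell_id = integer(0))
  if (nrow(nuclear_spots) == 0) return(empty)
  sp <- nuclear_spots
  ids <- sp$spot_id %||% seq_len(nrow(sp))
  pts <- cbind(sp$z_um, sp$y_um, sp$x_um)
  cl <- if (nrow(sp) == 1L) {
    1L
  } else {
    hc <- hclust(dist(pts), method = "single")
    cutree(hc, h = merge_radius_um)
  }
  cellv <- sp$cell_id %||% rep(NA_integer_, nrow(sp))
  agg <- tibble(cluster = cl, id = ids,
                z = pts[, 1], y = pts[, 2], x = pts[, 3],
                w = sp$integrated_intensity, cell_id = cellv) |>
    group_by(.data$cluster) |>
    summarise(
      z_um = sum(.data$z * pmax(.data$w, 0)) / max(sum(pmax(.data$w, 0)), 1e-12),
      y_um = sum(.data$y * pmax(.data$w, 0)) / max(sum(pmax(.data$w, 0)), 1e-12),
      x_um = sum(.data$x * pmax(.data$w, 0)) / max(sum(pmax(.data$w, 0)), 1e-12),
      n_spots = n(),
      integrated_intensity = sum(.data$w),
      member_ids = list(.data$id),
      cell_id = .data$cell_id[1]
    ) |>
    mutate(transcript_equivalent =
             as.integer(round(.data$integrated_intensity / unit_intensity)))
  foci <- agg |>
    filter(.data$transcript_equivalent >= min_equivalent) |>
    mutate(focus_id = row_number()) |>
    select("focus_id", "z_um", "y_um", "x_um", "n_spots",
           "integrated_intensity", "transcript_equivalent", "member_ids",
           "cell_id")
  foci
}

#' Colocalize RNA foci with DNA FISH loci
#'
#' Matches foci to DNA loci (after registration when two rounds are
#' involved) and summarises the fraction of DNA loci carrying an RNA focus
#' — the transcriptionally active fraction of amplified loci.
#'
#' @param foci [detect_foci()] output.
#' @param dna_spots Spot tibble of DNA FISH signals.
#' @param max_distance_um Matching cutoff (μm).
#' @return List: `foci` with `colocalized_dna_locus` column, `pairs`, and
#'   `active_locus_fraction` (`NA` when there are no DNA loci).
#' @export
colocalize_foci_with_dna <- function(foci, dna_spots, max_distance_um = 0.5) {
  if (nrow(dna_spots) == 0) {
    return(list(foci = mutate(foci, colocalized_dna_locus = NA_integer_),
                pairs = tibble(id_a = integer(0), id_b = integer(0),
                               distance_um = numeric(0)),
                active_locus_fraction = NA_real_))
  }
  foci_pts <- foci |> mutate(spot_id = .data$focus_id)
  m <- colocalize(foci_pts, dna_spots, max_distance_um)
  foci2 <- mutate(foci, colocalized_dna_locus =
                    m$pairs$id_b[match(.data$focus_id, m$pairs$id_a)])
  list(foci = foci2, pairs = m$pairs,
       active_locus_fraction = nrow(m$pairs) / nrow(dna_spots))
}
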