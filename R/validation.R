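# Self-contained validation experiments: each function simulates a study
# condition with the generator, runs the analysis pipeline on the rendered
# images, and scores the result against the generator's ground truth.
# They back both the package's acceptance tests and scripts/acceptance.R.

#' Spot-detection recovery on a dense synthetic field
#'
#' Renders 200 diffraction-limited spots at peak SNR 5 into a
#' 64 x 256 x 256 stack (voxel 0.2 x 0.107 x 0.107 μm), runs
#' [detect_spots()] with default automatic thresholding, and scores
#' detections against ground truth by one-to-one matching within 0.3 μm.
#'
#' @param seed Integer seed.
#' @param n_spots Number of ground-truth spots.
#' @param snr Peak signal-to-noise ratio.
#' @return List: `f1`, `precision`, `recall`, `n_true`, `n_detected`.
#' @export
validate_spot_recovery <- function(seed = 1L, n_spots = 200L, snr = 5) {
  d <- c(64L, 256L, 256L)
  vs <- c(0.2, 0.107, 0.107)
  geom <- empty_field_geometry(d, vs)
  ext <- d * vs
  truth <- with_seed_(derive_seed(seed, 101), tibble(
    spot_id = seq_len(n_spots),
    z_um = runif(n_spots, 0.8, ext[1] - 0.8),
    y_um = runif(n_spots, 0.5, ext[2] - 0.5),
    x_um = runif(n_spots, 0.5, ext[3] - 0.5),
    species = "mature_mRNA", channels = replicate(n_spots, "exon", FALSE),
    unit_count = 1L, compartment = "cytoplasm", cell_id = 1L,
    focus_id = NA_integer_
  ))
  rc <- render_config(seed = derive_seed(seed, 102))
  rc$spot_amplitude <- amplitude_for_snr(snr, rc, vs)
  rc$nuclear_level <- 0
  rc$protein_level <- 0
  img <- render_image(geom, truth, rc, channels = "exon")
  det <- detect_spots(img, channel_name = "exon")
  m <- colocalize(det, truth, max_distance_um = 0.3)
  tp <- nrow(m$pairs)
  precision <- tp / max(nrow(det), 1)
  recall <- tp / n_spots
  list(f1 = 2 * tp / (2 * tp + (nrow(det) - tp) + (n_spots - tp)),
       precision = precision, recall = recall,
       n_true = n_spots, n_detected = nrow(det))
}

#' Per-cell transcript count recovery
#'
#' Simulates fields of cells at a stated mean transcript count (negative
#' binomial across cells), renders, segments nuclei and cells from the
#' images, detects and assigns spots, and compares both the mean of
#' per-cell counts and the population estimator (total spots over number
#' of nuclei) with the generator truth.
#'
#' @param seed Integer seed.
#' @param n_fields,cells_per_field Fields simulated and cells per field.
#' @param mean_count Mean mature transcripts per cell.
#' @param dispersion Negative binomial dispersion.
#' @return List with relative errors (percent) and the realised truth.
#' @export
validate_count_recovery <- function(seed = 1L, n_fields = 10L,
                                    cells_per_field = 4L, mean_count = 100,
                                    dispersion = 5) {
  det_counts <- truth_counts <- numeric(0)
  total_spots <- 0
  total_nuclei <- 0
  for (f in seq_len(n_fields)) {
    sc <- scenario_config(
      "steady_state",
      geometry = list(n_cells = cells_per_field),
      transcripts = list(mean_mature_per_cell = mean_count,
                         pre_mrna_fraction = 0, dispersion = dispersion)
    )
    sim <- simulate_scenario(sc, seed = derive_seed(seed, 200 + f))
    spots <- detect_spots(sim$image, channel_name = "exon")
    spots$channel <- "exon"
    seg <- segment_stack(sim$image)
    ann <- assign_compartments(spots, seg)
    prof <- build_cell_profiles(ann, labels = seg)
    det_counts <- c(det_counts, prof$n_exon)
    tr <- table(factor(sim$truth$cell_id,
                       levels = seq_len(cells_per_field)))
    truth_counts <- c(truth_counts, as.numeric(tr))
    total_spots <- total_spots + nrow(spots)
    total_nuclei <- total_nuclei + attr(prof, "n_nuclei")
  }
  mu_truth <- mean(truth_counts)
  list(
    per_cell_rel_err_pct = 100 * abs(mean(det_counts) - mu_truth) / mu_truth,
    population_rel_err_pct =
      100 * abs(total_spots / total_nuclei - mu_truth) / mu_truth,
    detected_mean = mean(det_counts),
    truth_mean = mu_truth,
    n_cells = length(det_counts)
  )
}

# Full image-driven segmentation path shared by validation experiments.
# Cells come from distance-limited Voronoi dilation of the nuclei: the
# protein channel tracks expression, so its intensity is not a reliable
# boundary marker for dim cells.
segment_stack <- function(image) {
  nuc <- segment_nuclei(image)
  mn <- classify_micronuclei(nuc)
  cells <- segment_cells(mn$nuclei)
  segmentation_labels(mn$nuclei, mn$micronuclei, cells, mn$parents)
}

#' Compartment assignment fidelity on noise-free truth
#'
#' Assigns ground-truth spot coordinates against the true label volumes
#' and checks two properties: intron-channel spots are all nuclear (the
#' defining behaviour of unspliced transcripts) and every assignment
#' agrees with an independent per-spot mask lookup.
#'
#' @param seed Integer seed.
#' @return List: `intron_nuclear_fraction`, `agreement_pct`, `n_spots`.
#' @export
validate_compartment_fidelity <- function(seed = 1L) {
  sc <- scenario_config("steady_state",
                        geometry = list(n_cells = 3,
                                        micronucleus_rate = 0.5),
                        transcripts = list(pre_mrna_fraction = 0.1))
  geom <- do.call(generate_cell_geometry,
                  c(sc$geometry, list(seed = derive_seed(seed, 301))))
  truth <- do.call(generate_transcripts,
                   c(list(geometry = geom), sc$transcripts,
                     list(seed = derive_seed(seed, 302))))
  ann <- assign_compartments(truth, geom)
  has_intron <- vapply(truth$channels, function(cs) "intron" %in% cs, TRUE)
  nuc_frac <- mean(ann$compartment[has_intron] %in%
                     c("nucleus", "micronucleus"))
  # independent voxel lookup, spot by spot
  agree <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    v <- floor(c(truth$z_um[i], truth$y_um[i], truth$x_um[i]) /
                 geom$voxel_size) + 1
    v <- pmin(pmax(v, 1), geom$field_shape)
    comp <- if (geom$micronuclei[v[1], v[2], v[3]] > 0) {
      "micronucleus"
    } else if (geom$nuclei[v[1], v[2], v[3]] > 0) {
      "nucleus"
    } else if (geom$cells[v[1], v[2], v[3]] > 0) {
      "cytoplasm"
    } else {
      "outside"
    }
    agree[i] <- comp == ann$compartment[i]
  }
  list(intron_nuclear_fraction = nuc_frac,
       agreement_pct = 100 * mean(agree),
       n_spots = nrow(truth))
}

#' Knockdown contrast between control and treated images
#'
#' Simulates the full-knockdown experiment (all cytoplasmic mature mRNA
#' degraded), renders both conditions, detects exon-channel spots and
#' assigns compartments, and reports detected cytoplasmic spots in the
#' knockdown as a percentage of the control's, plus the ratio of nuclear
#' counts (which the knockdown must not touch).
#'
#' @param seed Integer seed.
#' @return List: `cytoplasmic_pct_of_control`, `nuclear_ratio`, counts.
#' @export
validate_knockdown <- function(seed = 1L) {
  sc <- scenario_config("knockdown")
  sim <- simulate_scenario(sc, seed = derive_seed(seed, 401))
  tally <- function(image) {
    sp <- detect_spots(image, channel_name = "exon")
    ann <- assign_compartments(sp, sim$geometry)
    list(cyt = sum(ann$compartment == "cytoplasm"),
         nuc = sum(ann$compartment %in% c("nucleus", "micronucleus")))
  }
  ctrl <- tally(sim$image)
  kd <- tally(sim$image_kd)
  list(cytoplasmic_pct_of_control = 100 * kd$cyt / max(ctrl$cyt, 1),
       nuclear_ratio = kd$nuc / max(ctrl$nuc, 1),
       control = ctrl, knockdown = kd,
       truth_retained_fraction = nrow(sim$truth_kd) / nrow(sim$truth))
}

#' Two-round registration recovery
#'
#' Simulates an RNA round plus a distorted DNA round (per-nucleus shrink
#' 0.9 and 0.4 μm smooth deformation), registers the rounds from their
#' nuclear channels, and scores: the mean boundary residual after warping
#' (in in-plane voxels), residual monotonicity per nucleus, the fraction
#' of generator RNA-focus/DNA-locus pairs re-colocalized at 0.5 μm with
#' and without registration, and bit-identity of all voxels outside the
#' warp supports.
#'
#' @param seed Integer seed.
#' @return List of metrics.
#' @export
validate_registration <- function(seed = 1L) {
  sc <- scenario_config("two_round")
  sim <- simulate_scenario(sc, seed = derive_seed(seed, 501))
  r2 <- sim$round2
  reg <- register_cycles(sim$image, r2$image)

  # detected foci in round 1
  ex <- detect_spots(sim$image, channel_name = "exon")
  ann <- assign_compartments(ex, sim$geometry)
  cyt <- filter(ann, .data$compartment == "cytoplasm")
  unit <- median(cyt$integrated_intensity)
  foci <- detect_foci(filter(ann, .data$compartment %in%
                               c("nucleus", "micronucleus")), unit)
  # detected DNA spots in round 2, warped back into the round-1 frame
  dna <- detect_spots(r2$image, channel_name = "dna")
  dna_reg <- apply_warp(dna, reg$warp)

  # generator pairs: each active locus links one RNA focus (round-1
  # coordinates) to one DNA locus (round-2 coordinates)
  act <- filter(sim$truth, .data$species == "pre_mRNA",
                !is.na(.data$focus_id))
  loci2 <- filter(r2$truth, .data$species == "dna_locus",
                  .data$focus_id %in% act$focus_id)
  loci2 <- loci2[match(act$focus_id, loci2$focus_id), ]
  nn <- function(a, b) {
    d2 <- euclid2(cbind(a$z_um, a$y_um, a$x_um),
                  cbind(b$z_um, b$y_um, b$x_um))
    list(i = apply(d2, 1, which.min), d = sqrt(apply(d2, 1, min)))
  }
  fo <- nn(act, foci)
  dn <- nn(loci2, dna)
  ok <- fo$d < 0.3 & dn$d < 0.3
  f <- foci[fo$i, ]
  dr <- dna_reg[dn$i, ]
  du <- dna[dn$i, ]
  dist_reg <- sqrt((f$z_um - dr$z_um)^2 + (f$y_um - dr$y_um)^2 +
                     (f$x_um - dr$x_um)^2)
  dist_un <- sqrt((f$z_um - du$z_um)^2 + (f$y_um - du$y_um)^2 +
                    (f$x_um - du$x_um)^2)

  warped_round2 <- apply_warp(r2$image, reg$warp)
  outside <- reg$warp$supports_fixed$support == 0L
  cyto_identical <- identical(
    warped_round2$channels$dna[outside], r2$image$channels$dna[outside]) &&
    identical(warped_round2$channels$nuclear[outside],
              r2$image$channels$nuclear[outside])

  list(
    post_residual_voxel = mean(reg$residuals$post_voxel),
    pre_residual_voxel = mean(reg$residuals$pre_voxel),
    residual_monotone =
      all(reg$residuals$post_um < reg$residuals$pre_um),
    recolocalized_registered_pct = 100 * mean(dist_reg[ok] <= 0.5),
    recolocalized_unregistered_pct = 100 * mean(dist_un[ok] <= 0.5),
    cytoplasm_bit_identical = cyto_identical,
    n_pairs = sum(ok),
    residuals = reg$residuals
  )
}

#' Oracle equivalences on small instances
#'
#' Re-derives key computational steps with brute-force reference
#' implementations on small instances and reports the discrepancy of the
#' package's fast paths: Laplacian-of-Gaussian filtering vs dense
#' convolution with the explicit kernel (16^3), exact Otsu vs exhaustive
#' between-class-variance search, greedy maxima suppression vs all-pairs
#' suppression, greedy colocalization vs exhaustive matching, and Pearson
#' r vs the covariance formula.
#'
#' @param seed Integer seed.
#' @return List of maximum absolute discrepancies (counts are differences
#'   of integers).
#' @export
validate_oracle_equivalences <- function(seed = 1L) {
  vs <- c(0.2, 0.107, 0.107)
  res <- with_seed_(derive_seed(seed, 601), {
    # LoG vs dense convolution
    img <- array(rnorm(16^3), c(16, 16, 16))
    fast <- mexican_hat_filter(img, 0.106, 0.3, vs)
    ker <- mexican_hat_kernel(0.106, 0.3, vs)
    kd <- dim(ker)
    c0 <- (kd - 1) / 2
    dense <- array(0, dim(img))
    for (a in seq_len(kd[1])) {
      iz <- pmin(pmax(seq_len(16) + a - 1 - c0[1], 1), 16)
      for (b in seq_len(kd[2])) {
        iy <- pmin(pmax(seq_len(16) + b - 1 - c0[2], 1), 16)
        for (cc in seq_len(kd[3])) {
          ix <- pmin(pmax(seq_len(16) + cc - 1 - c0[3], 1), 16)
          if (ker[a, b, cc] != 0) {
            dense <- dense + ker[a, b, cc] * img[iz, iy, ix]
          }
        }
      }
    }
    log_diff <- max(abs(fast - dense))

    # Otsu vs exhaustive split with direct statistics
    xx <- exp(c(rnorm(60, 0, 0.5), rnorm(45, 3, 0.5)))
    v <- sort(log(xx))
    best <- -Inf
    thr <- v[1]
    for (k in seq_len(length(v) - 1)) {
      if (v[k] == v[k + 1]) next
      lo <- v[seq_len(k)]
      hi <- v[(k + 1):length(v)]
      bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
        (mean(lo) - mean(hi))^2
      if (bcv > best) {
        best <- bcv
        thr <- (v[k] + v[k + 1]) / 2
      }
    }
    otsu_diff <- abs(auto_threshold(xx, method = "otsu") - exp(thr))

    # suppression vs all-pairs brute force
    f <- array(0, c(12, 12, 12))
    f[sample(length(f), 50)] <- runif(50, 0.5, 5)
    cand <- detect_candidates(f, vs, min_separation = 0.4)
    c0_ <- detect_candidates(f, vs, min_separation = 0)
    ordc <- order(-c0_$response, c0_$z, c0_$y, c0_$x)
    kept <- integer(0)
    for (i in ordc) {
      ok <- TRUE
      for (j in kept) {
        dd <- (c0_$z_um[i] - c0_$z_um[j])^2 + (c0_$y_um[i] - c0_$y_um[j])^2 +
          (c0_$x_um[i] - c0_$x_um[j])^2
        if (dd < 0.4^2) {
          ok <- FALSE
          break
        }
      }
      if (ok) kept <- c(kept, i)
    }
    suppression_diff <- abs(nrow(cand) - length(kept)) +
      sum(!(paste(cand$z, cand$y, cand$x) %in%
              paste(c0_$z[kept], c0_$y[kept], c0_$x[kept])))

    # greedy vs exhaustive matching count on well-separated points
    base <- matrix(runif(24, 0, 10), 8, 3)
    a <- tibble(spot_id = 1:8, z_um = base[, 1], y_um = base[, 2],
                x_um = base[, 3])
    off <- matrix(runif(24, -0.15, 0.15), 8, 3)
    b <- tibble(spot_id = 1:8, z_um = base[, 1] + off[, 1],
                y_um = base[, 2] + off[, 2], x_um = base[, 3] + off[, 3])
    greedy <- colocalize(a, b, 0.4)$pairs
    # exhaustive: all injective assignments
    dmat <- sqrt(euclid2(as.matrix(a[, 2:4]), as.matrix(b[, 2:4])))
    best_cnt <- 0L
    rec <- function(i, used, cnt) {
      if (i > 8) {
        best_cnt <<- max(best_cnt, cnt)
        return(invisible())
      }
      rec(i + 1L, used, cnt)
      for (j in which(!used & dmat[i, ] <= 0.4)) {
        used[j] <- TRUE
        rec(i + 1L, used, cnt + 1L)
        used[j] <- FALSE
      }
    }
    rec(1L, logical(8), 0L)
    matching_diff <- abs(nrow(greedy) - best_cnt)

    # Pearson r vs covariance formula
    x <- rnorm(5)
    y <- rnorm(5)
    xt <- tibble(sample_id = 1:5, value = x)
    yt <- tibble(sample_id = 1:5, value = y)
    r_pkg <- correlate_measurements(xt, yt)$r
    r_for <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    pearson_diff <- abs(r_pkg - r_for)

    list(log_filter_max_abs_diff = log_diff,
         otsu_abs_diff = otsu_diff,
         suppression_count_diff = suppression_diff,
         matching_count_diff = matching_diff,
         pearson_abs_diff = pearson_diff)
  })
  res
}

#' Cross-line expression correlation recovery
#'
#' Simulates cell lines whose mean expression spans a 50-fold range,
#' counts transcripts per line with the detection pipeline, and
#' correlates detected totals with the generator's realised truth — the
#' synthetic analogue of benchmarking image-based counts against an
#' orthogonal assay across cell lines.
#'
#' @param seed Integer seed.
#' @param line_means Mean transcripts per cell for each simulated line.
#' @param cells_per_line Cells per line.
#' @return List: `r`, `p`, `n_lines`, plus the per-line table.
#' @export
validate_cross_line_correlation <- function(seed = 1L,
                                            line_means = c(4, 10, 20, 40,
                                                           80, 140, 200),
                                            cells_per_line = 4L) {
  truth_tot <- det_tot <- numeric(length(line_means))
  for (i in seq_along(line_means)) {
    sc <- scenario_config(
      "steady_state",
      geometry = list(n_cells = cells_per_line),
      transcripts = list(mean_mature_per_cell = line_means[i],
                         pre_mrna_fraction = 0)
    )
    sim <- simulate_scenario(sc, seed = derive_seed(seed, 700 + i))
    det <- detect_spots(sim$image, channel_name = "exon")
    truth_tot[i] <- nrow(sim$truth)
    det_tot[i] <- nrow(det)
  }
  fit <- correlate_measurements(
    tibble(sample_id = seq_along(line_means), value = truth_tot),
    tibble(sample_id = seq_along(line_means), value = det_tot)
  )
  list(r = fit$r, p = fit$p, n_lines = length(line_means),
       lines = tibble(line = seq_along(line_means),
                      mean_requested = line_means,
                      truth_total = truth_tot, detected_total = det_tot))
}

# a cell-free field used to render bare spot patterns
empty_field_geometry <- function(field_shape, voxel_size) {
  d <- as.integer(field_shape)
  structure(list(
    nuclei = array(0L, d), micronuclei = array(0L, d),
    cells = array(0L, d),
    micronucleus_parents = tibble(micronucleus_id = integer(0),
                                  cell_id = integer(0)),
    centers = tibble(cell_id = integer(0)),
    voxel_size = check_voxel_size(voxel_size), field_shape = d
  ), class = "cell_geometry")
}
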