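test_that("compartment assignment matches a per-spot mask lookup", {
  geom <- quick_geom(3, field_shape = c(24L, 192L, 192L), seed = 1,
                     micronucleus_rate = 1)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 60,
                                pre_mrna_fraction = 0.2, seed = 2)
  ann <- assign_compartments(truth, geom)
  expect_identical(ann$compartment, truth$compartment)

  # 1000 random points against the independent lookup oracle
  pts <- random_spot_table(1000, geom$field_shape, geom$voxel_size, seed = 3,
                           margin_um = 0.2)
  ann2 <- assign_compartments(pts, geom)
  expect_identical(ann2$compartment, lookup_compartment(pts, geom))
  # compartment counts partition the spot set
  expect_equal(sum(table(ann2$compartment)), nrow(pts))

  # centroid is nuclear, far corner is outside, out-of-bounds errors
  ctr <- geom$centers[1, ]
  one <- spot_table(ctr$z_um, ctr$y_um, ctr$x_um)
  expect_equal(assign_compartments(one, geom)$compartment, "nucleus")
  expect_equal(assign_compartments(one, geom)$cell_id, 1L)
  corner <- spot_table(0.1, 0.1, 0.1)
  expect_equal(assign_compartments(corner, geom)$compartment, "outside")
  expect_error(assign_compartments(spot_table(-1, 1, 1), geom), "outside the")
})

test_that("colocalization respects the cutoff and is symmetric", {
  a <- spot_table(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1))
  expect_equal(nrow(colocalize(a, a)$pairs), 3L)
  expect_equal(colocalize(a, a)$pairs$distance_um, rep(0, 3))

  b02 <- spot_table(c(1, 2, 3), c(1.2, 1.2, 1.2), c(1, 1, 1))
  expect_equal(nrow(colocalize(a, b02, 0.3)$pairs), 3L)
  b04 <- spot_table(c(1, 2, 3), c(1.4, 1.4, 1.4), c(1, 1, 1))
  expect_equal(nrow(colocalize(a, b04, 0.3)$pairs), 0L)

  set.seed(4)
  x <- spot_table(runif(8, 0, 3), runif(8, 0, 3), runif(8, 0, 3))
  y <- spot_table(runif(6, 0, 3), runif(6, 0, 3), runif(6, 0, 3))
  xy <- colocalize(x, y, 1)$pairs
  yx <- colocalize(y, x, 1)$pairs
  expect_equal(xy$id_a, yx$id_b)
  expect_equal(xy$id_b, yx$id_a)
})

test_that("greedy matching agrees with exhaustive matching when separated", {
  for (seed in 1:5) {
    set.seed(seed)
    # clusters far apart relative to the cutoff keep the problem unambiguous
    base <- matrix(runif(15, 0, 10), 5, 3)
    a <- spot_table(base[, 1], base[, 2], base[, 3])
    off <- matrix(runif(15, -0.2, 0.2), 5, 3)
    b <- spot_table(base[, 1] + off[, 1], base[, 2] + off[, 2],
                    base[, 3] + off[, 3])
    got <- colocalize(a, b, 0.5)$pairs
    best <- exhaustive_match(a, b, 0.5)
    expect_equal(nrow(got), best$count)
    expect_equal(sum(got$distance_um), best$weight, tolerance = 1e-9)
  }
})

test_that("pre-mRNA calls follow the intron/exon pairing rules", {
  # no intron spots: nothing is called pre-mRNA
  ex <- spot_table(c(1, 2), c(1, 1), c(1, 1))
  ex$compartment <- "cytoplasm"
  emp <- spot_table(numeric(0), numeric(0), numeric(0))
  emp$compartment <- character(0)
  out <- call_pre_mrna(emp, ex)
  expect_equal(sum(out$species_call == "pre_mRNA"), 0L)
  expect_true(all(out$species_call == "mature_mRNA"))

  # adversarial: intron-only spots in the cytoplasm are orphans
  orphan <- spot_table(c(5, 6), c(5, 5), c(5, 5))
  orphan$compartment <- "cytoplasm"
  far_ex <- spot_table(1, 1, 1)
  far_ex$compartment <- "cytoplasm"
  res <- call_pre_mrna(orphan, far_ex)
  qc <- attr(res, "qc")
  expect_equal(qc$intron_orphan_fraction, 1)
  expect_equal(qc$intron_nuclear_fraction, 0)

  # generator truth: colocalized intron/exon pairs recover pre-mRNA calls
  geom <- quick_geom(2, field_shape = c(24L, 160L, 160L), seed = 5)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 60,
                                pre_mrna_fraction = 0.3, seed = 6)
  has <- function(ch) vapply(truth$channels, function(cs) ch %in% cs, TRUE)
  intron <- dplyr::mutate(truth[has("intron"), ], spot_id = dplyr::row_number())
  exon <- dplyr::mutate(truth[has("exon"), ], spot_id = dplyr::row_number())
  res2 <- call_pre_mrna(intron, exon, 0.3)
  called <- res2[res2$species_call == "pre_mRNA" &
                   seq_len(nrow(res2)) <= nrow(intron), ]
  expect_gte(nrow(called) / nrow(intron), 0.9)
  expect_equal(attr(res2, "qc")$intron_nuclear_fraction, 1)
})

test_that("foci detection clusters nuclear spots by intensity equivalents", {
  # isolated unit-intensity spots are not foci
  iso <- spot_table(c(1, 3, 5), c(1, 3, 5), c(1, 3, 5))
  iso$integrated_intensity <- c(100, 105, 95)
  expect_equal(nrow(detect_foci(iso, unit_intensity = 100)), 0L)

  # five unit spots within 0.2 um merge into one focus of equivalent 5
  tight <- spot_table(rep(2, 5), 2 + c(0, 0.05, -0.05, 0.1, -0.1),
                      rep(2, 5))
  tight$integrated_intensity <- rep(100, 5)
  f <- detect_foci(tight, unit_intensity = 100, merge_radius_um = 0.3)
  expect_equal(nrow(f), 1L)
  expect_equal(f$transcript_equivalent, 5L)
  expect_equal(f$n_spots, 5L)
  expect_setequal(f$member_ids[[1]], 1:5)

  # a lone bright spot also qualifies
  lone <- spot_table(4, 4, 4)
  lone$integrated_intensity <- 800
  f2 <- detect_foci(lone, unit_intensity = 100)
  expect_equal(f2$transcript_equivalent, 8L)

  # empty input and invalid unit intensity
  expect_equal(nrow(detect_foci(iso[0, ], unit_intensity = 100)), 0L)
  expect_error(detect_foci(iso, unit_intensity = 0), "unit_intensity")
})

test_that("focus membership partitions the clustered spots", {
  set.seed(7)
  sp <- spot_table(runif(40, 0, 6), runif(40, 0, 6), runif(40, 0, 6))
  sp$integrated_intensity <- runif(40, 80, 400)
  f <- detect_foci(sp, unit_intensity = 100, merge_radius_um = 0.8,
                   min_equivalent = 2)
  members <- unlist(f$member_ids)
  expect_equal(anyDuplicated(members), 0L)
  expect_true(all(f$transcript_equivalent >= 2L))
})

test_that("DNA colocalization reports the active locus fraction", {
  foci <- tibble::tibble(focus_id = 1:3, z_um = c(1, 2, 3), y_um = 1,
                         x_um = 1, n_spots = 1L,
                         integrated_intensity = 500,
                         transcript_equivalent = 5L,
                         member_ids = list(1L, 2L, 3L), cell_id = 1L)
  # all foci coincide with loci -> fraction 1 of the matched loci
  dna <- spot_table(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1))
  res <- colocalize_foci_with_dna(foci, dna, 0.5)
  expect_equal(res$active_locus_fraction, 1)
  expect_equal(sort(res$foci$colocalized_dna_locus), 1:3)

  # extra silent loci lower the fraction
  dna2 <- spot_table(c(1, 2, 3, 9, 9), c(1, 1, 1, 9, 9), c(1, 1, 1, 9, 9))
  expect_equal(colocalize_foci_with_dna(foci, dna2, 0.5)$active_locus_fraction,
               3 / 5)

  # no DNA spots: fraction is missing, not zero
  none <- colocalize_foci_with_dna(foci, dna[0, ], 0.5)
  expect_true(is.na(none$active_locus_fraction))
})
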