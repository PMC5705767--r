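test_that("cell geometry satisfies its compartment invariants", {
  geom <- quick_geom(1, seed = 1, micronucleus_rate = 0)
  expect_equal(sort(unique(as.vector(geom$nuclei))), c(0L, 1L))
  expect_equal(sort(unique(as.vector(geom$cells))), c(0L, 1L))
  expect_equal(nrow(geom$micronucleus_parents), 0L)
  # nucleus inside cell, cytoplasm = cell minus nucleus
  expect_true(all(geom$cells[geom$nuclei > 0L] ==
                    geom$nuclei[geom$nuclei > 0L]))
  cyto <- cytoplasm_labels(geom)
  expect_true(all(cyto[geom$nuclei > 0L] == 0L))

  same <- quick_geom(1, seed = 1, micronucleus_rate = 0)
  expect_identical(geom$nuclei, same$nuclei)
  expect_identical(geom$cells, same$cells)
})

test_that("micronuclei are disjoint from and near their parent nuclei", {
  geom <- quick_geom(4, field_shape = c(24L, 192L, 192L), seed = 2,
                     micronucleus_rate = 1)
  expect_gte(nrow(geom$micronucleus_parents), 1L)
  # exhaustive voxel-level disjointness
  expect_equal(sum(geom$nuclei > 0L & geom$micronuclei > 0L), 0L)
  # each micronucleus sits within the parent's cell region
  for (k in seq_len(nrow(geom$micronucleus_parents))) {
    sel <- geom$micronuclei == k
    parent <- geom$micronucleus_parents$cell_id[k]
    expect_true(all(geom$cells[sel] == parent))
  }
})

test_that("overcrowded fields fail with an explicit error", {
  expect_error(quick_geom(50, field_shape = c(16L, 96L, 96L), seed = 1),
               "field too crowded")
})

test_that("transcript placement respects compartments and fractions", {
  geom <- quick_geom(3, field_shape = c(24L, 192L, 192L), seed = 3,
                     micronucleus_rate = 1)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 60,
                                pre_mrna_fraction = 0.2, seed = 4)
  pre <- truth[truth$species == "pre_mRNA", ]
  expect_true(all(pre$compartment %in% c("nucleus", "micronucleus")))
  expect_true(all(vapply(pre$channels, function(cs) {
    all(c("intron", "exon") %in% cs)
  }, TRUE)))

  none <- generate_transcripts(geom, mean_mature_per_cell = 60,
                               pre_mrna_fraction = 0, seed = 4)
  expect_false(any(vapply(none$channels, function(cs) "intron" %in% cs, TRUE)))

  # determinism
  again <- generate_transcripts(geom, mean_mature_per_cell = 60,
                                pre_mrna_fraction = 0.2, seed = 4)
  expect_identical(truth$z_um, again$z_um)
})

test_that("per-cell counts follow the requested mean", {
  geom <- quick_geom(8, field_shape = c(24L, 256L, 256L), seed = 5)
  reps <- lapply(1:5, function(s) {
    generate_transcripts(geom, mean_mature_per_cell = 100,
                         pre_mrna_fraction = 0, dispersion = 5, seed = s)
  })
  counts <- unlist(lapply(reps, function(tr) {
    tab <- table(factor(tr$cell_id, levels = 1:8))
    as.numeric(tab)
  }))
  # brute-force tally; NB(mu, size) has var mu + mu^2/size
  se <- sqrt((100 + 100^2 / 5) / length(counts))
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("every active locus carries an RNA focus at zero distance", {
  geom <- quick_geom(2, field_shape = c(24L, 192L, 192L), seed = 6)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 0,
                                n_foci_per_cell = 8,
                                active_locus_fraction = 1, seed = 7)
  dna <- truth[truth$species == "dna_locus", ]
  rna <- truth[truth$species == "pre_mRNA", ]
  expect_equal(nrow(dna), 16L)
  expect_setequal(rna$focus_id, dna$focus_id)
  m <- merge(as.data.frame(dna), as.data.frame(rna), by = "focus_id")
  expect_equal(m$z_um.x, m$z_um.y)
  expect_equal(m$x_um.x, m$x_um.y)
  expect_true(all(rna$unit_count >= 2L))
})

test_that("knockdown removes only cytoplasmic mature mRNA", {
  geom <- quick_geom(3, field_shape = c(24L, 192L, 192L), seed = 8)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 80,
                                pre_mrna_fraction = 0.1,
                                nuclear_mature_fraction = 0.1, seed = 9)
  # identity at fraction 0
  expect_identical(simulate_knockdown(truth, 0)$spot_id, truth$spot_id)
  # full knockdown: zero cytoplasmic mature spots, nuclear pool untouched
  kd <- simulate_knockdown(truth, 1)
  expect_equal(sum(kd$species == "mature_mRNA" &
                     kd$compartment == "cytoplasm"), 0L)
  nuc_before <- sum(truth$compartment %in% c("nucleus", "micronucleus"))
  nuc_after <- sum(kd$compartment %in% c("nucleus", "micronucleus"))
  expect_equal(nuc_after, nuc_before)
  # conservation: never creates spots
  expect_true(all(kd$spot_id %in% truth$spot_id))
})

test_that("partial knockdown removes a binomial share of cytoplasmic spots", {
  geom <- quick_geom(1, field_shape = c(24L, 160L, 160L), seed = 10)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 1000,
                                pre_mrna_fraction = 0,
                                nuclear_mature_fraction = 0, dispersion = 1e6,
                                seed = 11)
  n0 <- sum(truth$compartment == "cytoplasm")
  kd <- simulate_knockdown(truth, 0.5, seed = 12)
  n1 <- sum(kd$compartment == "cytoplasm")
  tol <- 4 * sqrt(n0 * 0.25)
  expect_lt(abs(n1 - 0.5 * n0), tol)
})

test_that("default full-knockdown scenario retains about an eighth of spots", {
  sc <- scenario_config("knockdown",
                        geometry = list(n_cells = 3,
                                        field_shape = c(40L, 448L, 448L)))
  geom <- do.call(generate_cell_geometry,
                  c(sc$geometry, list(seed = 1)))
  truth <- do.call(generate_transcripts,
                   c(list(geometry = geom), sc$transcripts, list(seed = 2)))
  kd <- simulate_knockdown(truth, sc$knockdown$cytoplasmic_removal_fraction)
  rna <- function(tr) sum(tr$species != "dna_locus")
  retained <- rna(kd) / rna(truth)
  expect_lt(abs(retained - 0.125), 0.05)
})
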