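vs_reg <- c(0.2, 0.107, 0.107)

digital_ball <- function(d, center_vox, radii_vox) {
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  inside <- ((g$z - center_vox[1]) / radii_vox[1])^2 +
    ((g$y - center_vox[2]) / radii_vox[2])^2 +
    ((g$x - center_vox[3]) / radii_vox[3])^2 <= 1
  arr <- array(0L, d)
  arr[as.matrix(g)[inside, ]] <- 1L
  structure(arr, voxel_size = vs_reg)
}

test_that("boundary control points lie on the contour at equal arc length", {
  d <- c(9L, 80L, 80L)
  mask <- digital_ball(d, c(5, 40, 40), c(3, 25, 25))
  cp <- extract_boundary_control_points(mask, vs_reg, n_per_contour = 32)
  expect_true(all(table(cp$z_index) == 32))

  # digital circle: points stay on the voxelised boundary (within the
  # half-diagonal of a voxel) and near the analytic radius
  eq <- cp[cp$z_index == 5, ]
  r <- sqrt((eq$y_um - 39.5 * vs_reg[2])^2 + (eq$x_um - 39.5 * vs_reg[3])^2)
  r_true <- 25 * vs_reg[2]
  expect_true(all(abs(r - r_true) <= 1.3 * vs_reg[2]))
  bnd <- which(immunofishr:::boundary_2d(mask[5, , ] == 1L), arr.ind = TRUE)
  bnd_um <- cbind((bnd[, 1] - 0.5) * vs_reg[2], (bnd[, 2] - 0.5) * vs_reg[3])
  d2b <- immunofishr:::euclid2(as.matrix(eq[, c("y_um", "x_um")]), bnd_um)
  expect_true(all(sqrt(apply(d2b, 1, min)) <= 0.71 * vs_reg[2]))

  # square mask: resampled arc spacing uniform within 20%
  sq <- array(0L, c(3L, 60L, 60L))
  sq[2, 15:45, 15:45] <- 1L
  sq <- structure(sq, voxel_size = vs_reg)
  cps <- extract_boundary_control_points(sq, vs_reg, n_per_contour = 32)
  pts <- as.matrix(cps[cps$z_index == 2, c("y_um", "x_um")])
  seg <- sqrt(rowSums((rbind(pts[-1, ], pts[1, ]) - pts)^2))
  expect_lt(max(abs(seg - mean(seg))) / mean(seg), 0.2)

  expect_error(extract_boundary_control_points(
    structure(array(0L, c(4, 8, 8)), voxel_size = vs_reg)), "empty mask")
})

test_that("cyclic matching recovers imposed shifts exactly", {
  set.seed(1)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  A <- cbind(3 * sin(th) + 0.2 * sin(3 * th), 3 * cos(th) + 0.2 * cos(2 * th))
  # identical contours: zero shift, zero residual
  expect_equal(round(immunofishr:::best_cyclic_shift(A, A)), 0)
  # rotated index by k: recovered against exhaustive search
  for (k in c(3, 11, 20)) {
    B <- A[c((k + 1):32, 1:k), ]
    got <- immunofishr:::best_cyclic_shift(A, B)
    ss <- immunofishr:::cyclic_ssd_profile(A, B)
    expect_equal(round(got) %% 32, (which.min(ss) - 1) %% 32)
    expect_equal(round(got) %% 32, (32 - k) %% 32)
  }
})

test_that("pure shrink produces inward displacements of the right size", {
  d <- c(13L, 120L, 120L)
  fixed <- digital_ball(d, c(7, 60, 60), c(5, 40, 40))
  moving <- digital_ball(d, c(7, 60, 60), c(5, 36, 36)) # 0.9 shrink
  cp_f <- extract_boundary_control_points(fixed, vs_reg, 32)
  cp_m <- extract_boundary_control_points(moving, vs_reg, 32)
  m <- match_control_points(cp_f, cp_m, allow_unmatched = TRUE)
  eq <- m$pairs[m$pairs$z_index == 7, ]
  disp <- cbind(eq$my - eq$fy, eq$mx - eq$fx)
  ctr <- c(mean(eq$fy), mean(eq$fx))
  radial <- cbind(eq$fy - ctr[1], eq$fx - ctr[2])
  rn <- radial / sqrt(rowSums(radial^2))
  inward <- rowSums(disp * rn)
  r <- sqrt(rowSums(radial^2))
  expect_true(all(inward < 0))
  expect_equal(inward, -0.1 * r, tolerance = 0.12)
})

test_that("identity and exact similarity transforms are recovered", {
  geom <- quick_geom(2, field_shape = c(24L, 160L, 160L), seed = 2)
  lab <- structure(geom$nuclei, voxel_size = geom$voxel_size)
  cp <- extract_boundary_control_points(lab, geom$voxel_size, 32)
  m <- match_control_points(cp, cp)
  warp <- fit_warp(m, lab, lab, geom$voxel_size)

  # identity correspondences: displacement below 1e-9 um everywhere
  pts <- cbind(runif(50, 1, 4), runif(50, 5, 12), runif(50, 5, 12))
  moved <- immunofishr:::warp_points(warp, pts)
  expect_lt(max(abs(moved - pts)), 1e-9)

  # spots pass through bit-exactly
  truth <- generate_transcripts(geom, mean_mature_per_cell = 30, seed = 3)
  warped <- apply_warp(truth, warp)
  expect_identical(warped$z_um, truth$z_um)
  expect_identical(warped$y_um, truth$y_um)

  # an exact scale-plus-translation of the control points (the shrink
  # case) is absorbed entirely by the global transform: the per-nucleus
  # residual patches stay at zero. (A small pure rotation is aliased with
  # cyclic re-indexing on arc-resampled closed contours and is only
  # partially attributed to the global term; the full warp still maps the
  # boundaries onto each other.)
  sc <- 0.96
  cp2 <- cp
  cp2$y_um <- 12 + sc * (cp$y_um - 12) + 1.3
  cp2$x_um <- 12 + sc * (cp$x_um - 12) - 0.8
  m2 <- match_control_points(cp, cp2)
  warp2 <- fit_warp(m2, lab, lab, geom$voxel_size)
  mv <- cbind(m2$pairs$mz, m2$pairs$my, m2$pairs$mx)
  glob <- immunofishr:::apply_similarity(warp2$global, mv)
  expect_lt(max(abs(glob[, 2] - m2$pairs$fy)), 1e-6)
  expect_lt(max(abs(glob[, 3] - m2$pairs$fx)), 1e-6)
  for (fid in names(warp2$nuclei)) {
    own <- m2$pairs$nucleus_id == as.integer(fid)
    resid <- immunofishr:::eval_poly_field(warp2$nuclei[[fid]]$fwd,
                                           mv[own, , drop = FALSE])
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("degenerate collinear correspondences are rejected", {
  src <- cbind(rep(1, 10), seq_len(10), seq_len(10) * 2 - 3)
  expect_error(immunofishr:::fit_poly_field(src, matrix(0, 10, 2)),
               "collinear")
  expect_error(immunofishr:::fit_poly_field(src[1:5, ], matrix(0, 5, 2)),
               "at least 8")
})

test_that("a known smooth deformation is recovered on held-out points", {
  geom <- generate_cell_geometry(2, field_shape = c(32L, 256L, 256L),
                                 seed = 4)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 0,
                                n_foci_per_cell = 5,
                                active_locus_fraction = 1, seed = 5)
  dc <- distortion_config(shrink_factor = 0.93, deformation_amplitude = 0.4,
                          deformation_wavelength = 20, seed = 6)
  out <- apply_cycle_distortion(geom, truth, dc)
  rc <- render_config(background_level = 20, read_noise_sd = 1,
                      protein_level = 0, seed = 7)
  img_f <- render_image(geom, truth[0, ], rc, channels = "nuclear")
  img_m <- render_image(out$geometry, truth[0, ], rc, channels = "nuclear")
  reg <- register_cycles(img_f, img_m)

  # held-out boundary points: true-mask contours sampled at a different
  # density than the 64-point contours the fit used
  lab_t <- structure(geom$nuclei, voxel_size = geom$voxel_size)
  held <- extract_boundary_control_points(lab_t, geom$voxel_size, 40)
  p <- cbind(held$z_um, held$y_um, held$x_um)
  true_fwd <- p + out$displacement$at(p)
  # the fitted forward field lives on the moving frame; map the distorted
  # positions back and compare against the originals. The normal component
  # of a boundary displacement is the observable one (tangential motion of
  # a closed contour is subject to the aperture problem), so it carries
  # the quantitative bound; the full vector error stays sub-particle.
  moved <- apply_warp(tibble::tibble(z_um = true_fwd[, 1],
                                     y_um = true_fwd[, 2],
                                     x_um = true_fwd[, 3]), reg$warp)
  evec <- cbind(moved$y_um - p[, 2], moved$x_um - p[, 3])
  nrm <- immunofishr:::pair_normals(held$y_um, held$x_um,
                                    paste(held$nucleus_id, held$z_index))
  e_norm <- evec[, 1] * nrm[, 1] + evec[, 2] * nrm[, 2]
  expect_lt(sqrt(mean(e_norm^2)), 0.1)
  expect_lt(sqrt(mean(rowSums(evec^2))), 0.35)

  # interior points (the true loci) are recovered to sub-particle accuracy
  loci <- truth[truth$species == "dna_locus", ]
  loci2 <- out$truth[out$truth$species == "dna_locus", ]
  back <- apply_warp(loci2, reg$warp)
  erri <- sqrt((back$z_um - loci$z_um)^2 + (back$y_um - loci$y_um)^2 +
                 (back$x_um - loci$x_um)^2)
  expect_lt(sqrt(mean(erri^2)), 0.3)
  # residual monotonicity for every nucleus
  expect_true(all(reg$residuals$post_um < reg$residuals$pre_um))
})

test_that("image warping leaves voxels outside the supports bit-identical", {
  geom <- quick_geom(1, field_shape = c(20L, 96L, 96L), seed = 7)
  truth <- generate_transcripts(geom, mean_mature_per_cell = 20, seed = 8)
  dc <- distortion_config(shrink_factor = 0.92, deformation_amplitude = 0.2,
                          deformation_wavelength = 15, seed = 9)
  out <- apply_cycle_distortion(geom, truth, dc)
  lab_f <- structure(geom$nuclei, voxel_size = geom$voxel_size)
  lab_m <- structure(out$geometry$nuclei, voxel_size = geom$voxel_size)
  cp_f <- extract_boundary_control_points(lab_f, geom$voxel_size, 32)
  cp_m <- extract_boundary_control_points(lab_m, geom$voxel_size, 32)
  m <- match_control_points(cp_f, cp_m, allow_unmatched = TRUE)
  warp <- fit_warp(m, lab_f, lab_m, geom$voxel_size)

  img <- noise_free_render(geom, truth)
  warped <- apply_warp(img, warp)
  outside <- warp$supports_fixed$support == 0L
  expect_identical(warped$channels$exon[outside], img$channels$exon[outside])
  # and spot tables outside the support are returned unchanged exactly
  cyt <- truth[truth$compartment == "cytoplasm", ]
  far <- cyt[warp$supports_moving$support[immunofishr:::zyx_to_linear(
    immunofishr:::um_to_index(cbind(cyt$z_um, cyt$y_um, cyt$x_um),
                              geom$voxel_size), geom$field_shape)] == 0L, ]
  wf <- apply_warp(far, warp)
  expect_identical(wf$y_um, far$y_um)
})

test_that("warp and unwarp round-trip a smooth pattern within 1 percent", {
  geom <- quick_geom(1, field_shape = c(20L, 96L, 96L), seed = 10)
  dc <- distortion_config(shrink_factor = 0.94, deformation_amplitude = 0.15,
                          deformation_wavelength = 15, seed = 11)
  out <- apply_cycle_distortion(geom, NULL, dc)
  lab_f <- structure(geom$nuclei, voxel_size = geom$voxel_size)
  lab_m <- structure(out$geometry$nuclei, voxel_size = geom$voxel_size)
  d <- geom$field_shape
  vs <- geom$voxel_size
  # smooth low-frequency pattern
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  pattern <- array(100 + 50 * sin(g$y * vs[2] / 8) * cos(g$x * vs[3] / 9),
                   d)

  rc <- render_config(background_level = 20, read_noise_sd = 1,
                      protein_level = 0, seed = 12)
  img_f <- render_image(geom, NULL, rc, channels = "nuclear")
  img_m <- render_image(out$geometry, NULL, rc, channels = "nuclear")
  reg_fwd <- register_cycles(img_f, img_m)
  reg_bwd <- register_cycles(img_m, img_f)
  once <- apply_warp(pattern, reg_fwd$warp)
  back <- apply_warp(once, reg_bwd$warp)
  inside <- lab_f > 0L & lab_m > 0L # fully inside both supports
  rel <- abs(back[inside] - pattern[inside]) / max(pattern)
  expect_lt(max(rel), 0.01)
})
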