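vs_default <- c(0.2, 0.107, 0.107)

test_that("mexican hat filter annihilates constants and is linear", {
  arr <- array(7.3, c(12, 14, 16))
  f <- mexican_hat_filter(arr, 0.106, 0.3, vs_default)
  expect_lt(max(abs(f)), 1e-9 * 7.3)

  set.seed(1)
  img <- array(runif(12 * 14 * 16), c(12, 14, 16))
  f1 <- mexican_hat_filter(img, 0.106, 0.3, vs_default)
  f2 <- mexican_hat_filter(3 * img + 11, 0.106, 0.3, vs_default)
  expect_equal(f2, 3 * f1, tolerance = 1e-9)
})

test_that("separable filter equals dense convolution with the full kernel", {
  set.seed(2)
  img <- array(rnorm(16^3), c(16, 16, 16))
  f <- mexican_hat_filter(img, 0.106, 0.3, vs_default)
  ker <- immunofishr:::mexican_hat_kernel(0.106, 0.3, vs_default)
  oracle <- dense_conv3(img, ker)
  expect_lt(max(abs(f - oracle)), 1e-6)
})

test_that("sub-voxel filter scales are rejected", {
  img <- array(0, c(8, 8, 8))
  expect_error(mexican_hat_filter(img, 0.01, 0.3, vs_default), "resample")
})

test_that("candidate extraction finds isolated maxima and suppresses close ones", {
  expect_equal(nrow(detect_candidates(array(0, c(8, 8, 8)), vs_default)), 0L)

  geom <- bare_geometry(c(32L, 96L, 96L))
  rc <- render_config(spot_amplitude = 1000, background_level = 0,
                      read_noise_sd = 0, poisson_noise = FALSE,
                      nuclear_level = 0, protein_level = 0)
  # two spots at twice the minimum separation -> both recovered
  tr2 <- spot_table(c(3, 3), c(5, 5.6), c(5, 5))
  f <- mexican_hat_filter(render_image(geom, tr2, rc,
                                       channels = "exon")$channels$exon,
                          0.106, 0.3, vs_default)
  cand <- detect_candidates(f, vs_default, min_separation = 0.3)
  top2 <- cand[1:2, ]
  expect_equal(sort(top2$y_um), c(5, 5.6), tolerance = 0.11)

  # two spots at half the minimum separation -> one survives
  tr1 <- spot_table(c(3, 3), c(5, 5.15), c(5, 5))
  f1 <- mexican_hat_filter(render_image(geom, tr1, rc,
                                        channels = "exon")$channels$exon,
                           0.106, 0.3, vs_default)
  c_all <- detect_candidates(f1, vs_default, min_separation = 0)
  c_sup <- detect_candidates(f1, vs_default, min_separation = 0.3)
  near <- function(tb) sum(abs(tb$y_um - 5.07) < 0.3 & abs(tb$x_um - 5) < 0.3)
  expect_gte(near(c_all), 1)
  expect_equal(near(c_sup), 1L)
})

test_that("greedy suppression matches the all-pairs brute force", {
  for (seed in 1:5) {
    set.seed(seed)
    f <- array(0, c(12, 12, 12))
    idx <- sample(length(f), 60)
    f[idx] <- runif(60, 0.5, 5)
    cand <- detect_candidates(f, vs_default, min_separation = 0.4)
    # oracle on the unsuppressed maxima
    c0 <- detect_candidates(f, vs_default, min_separation = 0)
    kept <- brute_suppress(as.matrix(c0[, c("z_um", "y_um", "x_um")]),
                           c0$response,
                           as.matrix(c0[, c("z", "y", "x")]), 0.4)
    oracle <- c0[kept, ]
    expect_equal(
      dplyr::arrange(cand[, c("z", "y", "x")], z, y, x),
      dplyr::arrange(oracle[, c("z", "y", "x")], z, y, x)
    )
  }
})

test_that("otsu threshold equals the exhaustive search oracle", {
  expect_equal(auto_threshold(c(1, 1, 1, 9, 9, 9), method = "otsu"),
               naive_otsu(c(1, 1, 1, 9, 9, 9)))
  thr <- auto_threshold(c(1, 1, 1, 9, 9, 9))
  expect_gt(thr, 1)
  expect_lt(thr, 9)
  expect_equal(sum(c(1, 1, 1, 9, 9, 9) >= thr), 3L)

  for (seed in 1:5) {
    set.seed(seed)
    x <- exp(c(rnorm(40, 0, 0.4), rnorm(25, 3, 0.4)))
    expect_equal(auto_threshold(x, method = "otsu"), naive_otsu(x))
  }

  expect_equal(auto_threshold(rep(4, 10)), 4)
  expect_error(auto_threshold(numeric(0)), "empty")
})

test_that("the default threshold separates two well-separated modes", {
  set.seed(3)
  lo <- rlnorm(500, 0, 0.3)
  hi <- rlnorm(500, 4, 0.3)
  thr <- auto_threshold(c(lo, hi))
  labels_true <- rep(c(FALSE, TRUE), each = 500)
  err <- mean((c(lo, hi) >= thr) != labels_true)
  expect_lte(err, 0.01)
})

test_that("detect_spots recovers rendered spots with sub-voxel accuracy", {
  geom <- bare_geometry(c(32L, 160L, 160L))
  rc0 <- render_config()
  amp <- amplitude_for_snr(10, rc0, geom$voxel_size)
  truth <- random_spot_table(50, geom$field_shape, geom$voxel_size, seed = 4)
  img <- render_image(geom, truth,
                      render_config(spot_amplitude = amp, nuclear_level = 0,
                                    protein_level = 0, seed = 5),
                      channels = "exon")
  det <- detect_spots(img, channel_name = "exon")
  m <- match_to_truth(det, truth, radius_um = 0.25)
  expect_equal(nrow(m), 50L) # every true spot recovered within 0.25 um
  expect_lte(nrow(det) - nrow(m), 1L) # at most one spurious detection
  expect_lt(median(m$distance_um), 0.08)
})

test_that("blank noise-free channels yield no spots", {
  det <- detect_spots(array(0, c(16, 64, 64)),
                      voxel_size = c(0.2, 0.107, 0.107))
  expect_equal(nrow(det), 0L)
})

test_that("spot count is monotone in the threshold multiplier", {
  geom <- bare_geometry(c(32L, 128L, 128L))
  truth <- random_spot_table(30, geom$field_shape, geom$voxel_size, seed = 6)
  img <- render_image(geom, truth,
                      render_config(nuclear_level = 0, protein_level = 0,
                                    seed = 7), channels = "exon")
  counts <- vapply(c(0.5, 1, 2, 4), function(m) {
    nrow(detect_spots(img, detection_config(threshold_multiplier = m),
                      channel_name = "exon"))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is shift-equivariant and intensity-scale invariant", {
  geom <- bare_geometry(c(24L, 96L, 96L))
  truth <- random_spot_table(12, geom$field_shape, geom$voxel_size, seed = 8,
                             margin_um = 2)
  img <- render_image(geom, truth,
                      render_config(nuclear_level = 0, protein_level = 0,
                                    seed = 9), channels = "exon")$channels$exon
  det <- detect_spots(img, voxel_size = geom$voxel_size)

  # whole-voxel translation moves every detection by exactly one voxel
  d <- dim(img)
  shifted <- array(median(img), d)
  shifted[, 2:d[2], ] <- img[, 1:(d[2] - 1), ]
  det_s <- detect_spots(shifted, voxel_size = geom$voxel_size)
  keep <- det$y_um < (d[2] - 12) * geom$voxel_size[2]
  a <- dplyr::arrange(det[keep, ], z_um, x_um)
  b <- dplyr::arrange(det_s[det_s$y_um > 12 * geom$voxel_size[2] &
                              det_s$y_um < (d[2] - 6) * geom$voxel_size[2], ],
                      z_um, x_um)
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$y_um - a$y_um, rep(geom$voxel_size[2], nrow(a)),
               tolerance = 1e-9)

  # multiplying intensities leaves the detected set identical
  det2 <- detect_spots(2.5 * img, voxel_size = geom$voxel_size)
  expect_equal(det2$z_um, det$z_um, tolerance = 1e-9)
  expect_equal(attr(det2, "threshold") / attr(det, "threshold"), 2.5,
               tolerance = 1e-6)
})
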