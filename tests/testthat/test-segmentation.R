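render_nuclear <- function(geom) {
  noise_free_render(geom, spot_table(numeric(0), numeric(0), numeric(0)))
}

test_that("a single rendered nucleus is recovered with its volume", {
  geom <- generate_cell_geometry(1, field_shape = c(40L, 160L, 160L),
                                 seed = 1)
  img <- render_nuclear(geom)
  lab <- segment_nuclei(img, smooth_sigma_um = 0.3)
  expect_equal(max(lab), 1L)
  vol_true <- sum(geom$nuclei > 0L) * prod(geom$voxel_size)
  vol_seg <- sum(lab > 0L) * prod(geom$voxel_size)
  expect_lt(abs(vol_seg - vol_true) / vol_true, 0.05)
})

test_that("an empty image yields zero labels with a warning", {
  img <- array(0, c(12, 32, 32))
  expect_warning(lab <- segment_nuclei(img, voxel_size = c(0.2, 0.107, 0.107)),
                 "no nuclear foreground")
  expect_equal(max(lab), 0L)
})

test_that("touching nuclei are split at their true centres", {
  # two ellipsoids placed close enough that their smoothed stains merge
  geom <- generate_cell_geometry(
    2, field_shape = c(24L, 128L, 128L), seed = 4,
    nucleus_semiaxes_xy_um = c(2.8, 3.0), nucleus_semiaxes_z_um = c(1.3, 1.5),
    cell_radius_um = 2
  )
  img <- render_nuclear(geom)
  lab <- segment_nuclei(img, split_min_distance_um = 2.5)
  expect_equal(max(lab), 2L)
  cen_seg <- immunofishr:::mask_centroids(lab, geom$voxel_size, 2)
  cen_tru <- immunofishr:::mask_centroids(geom$nuclei, geom$voxel_size, 2)
  d <- immunofishr:::euclid2(cen_seg, cen_tru)
  # each segmented centroid within 2 in-plane voxels of a distinct truth
  expect_lt(sqrt(min(d[1, ])), 2 * geom$voxel_size[2] + geom$voxel_size[1])
  expect_lt(sqrt(min(d[2, ])), 2 * geom$voxel_size[2] + geom$voxel_size[1])
  expect_false(which.min(d[1, ]) == which.min(d[2, ]))
})

test_that("micronucleus classification applies its volume and distance rule", {
  geom <- quick_geom(2, field_shape = c(24L, 160L, 160L), seed = 5,
                     micronucleus_rate = 1)
  # compose a label volume with nuclei and micronuclei as separate labels
  lab <- geom$nuclei
  n_main <- max(lab)
  sel <- geom$micronuclei > 0L
  lab[sel] <- n_main + geom$micronuclei[sel]
  lab <- structure(lab, voxel_size = geom$voxel_size)
  out <- classify_micronuclei(lab, max_fraction = 0.10, max_distance_um = 5)
  expect_equal(max(out$nuclei), n_main)
  expect_equal(max(out$micronuclei), max(geom$micronuclei))
  # parents recovered
  got <- out$parents[order(out$parents$micronucleus_id), ]
  want <- geom$micronucleus_parents
  expect_equal(nrow(got), nrow(want))

  # single component: no micronuclei possible
  solo <- quick_geom(1, seed = 6)
  one <- structure(solo$nuclei, voxel_size = solo$voxel_size)
  res <- classify_micronuclei(one)
  expect_equal(max(res$micronuclei), 0L)
})

test_that("a component at exactly the volume threshold stays a nucleus", {
  # two cuboid components, the small one exactly 10% of the median volume
  d <- c(10L, 60L, 60L)
  vs <- c(0.2, 0.1, 0.1)
  lab <- array(0L, d)
  lab[3:8, 5:24, 5:24] <- 1L # 6*20*20 = 2400 voxels
  lab[3:8, 40:47, 40:44] <- 2L # 6*8*5 = 240 voxels = 10% exactly
  lab <- structure(lab, voxel_size = vs)
  out <- classify_micronuclei(lab, max_fraction = 0.10, max_distance_um = 50)
  expect_equal(max(out$micronuclei), 0L) # strict < keeps it a nucleus

  # shave one voxel: strictly below 10% -> micronucleus
  lab2 <- lab
  lab2[3, 40, 40] <- 0L
  lab2 <- structure(lab2, voxel_size = vs)
  out2 <- classify_micronuclei(lab2, max_fraction = 0.10,
                               max_distance_um = 50)
  expect_equal(max(out2$micronuclei), 1L)
  expect_equal(out2$parents$nucleus_id, 1L)
})

test_that("micronucleus rule matches a brute-force reimplementation", {
  for (seed in 1:4) {
    set.seed(seed)
    d <- c(8L, 48L, 48L)
    vs <- c(0.25, 0.15, 0.15)
    lab <- array(0L, d)
    n <- 4
    centers <- cbind(sample(3:6, n, TRUE), sample(seq(6, 42, 12)),
                     sample(seq(6, 42, 12)))
    sizes <- sample(2:6, n, TRUE)
    for (i in seq_len(n)) {
      zr <- max(1, centers[i, 1] - 1):min(d[1], centers[i, 1] + 1)
      yr <- max(1, centers[i, 2] - sizes[i]):min(d[2], centers[i, 2] + sizes[i])
      xr <- max(1, centers[i, 3] - sizes[i]):min(d[3], centers[i, 3] + sizes[i])
      lab[zr, yr, xr] <- i
    }
    lab <- structure(lab, voxel_size = vs)
    out <- classify_micronuclei(lab, max_fraction = 0.3, max_distance_um = 3)

    # brute force: accrete main nuclei from the largest down, then check
    # pairwise boundary distances
    vols <- sapply(1:n, function(i) sum(lab == i) * prod(vs))
    present <- which(vols > 0)
    ord <- present[order(-vols[present], present)]
    main <- ord[1]
    small <- integer(0)
    for (i in ord[-1]) {
      if (vols[i] < 0.3 * median(vols[main])) small <- c(small, i)
      else main <- c(main, i)
    }
    micro <- integer(0)
    for (s_ in small) {
      vox_s <- which(lab == s_, arr.ind = TRUE)
      mind <- Inf
      for (m_ in main) {
        vox_m <- which(lab == m_, arr.ind = TRUE)
        dd <- immunofishr:::euclid2(sweep(vox_s - 0.5, 2, vs, `*`),
                                    sweep(vox_m - 0.5, 2, vs, `*`))
        mind <- min(mind, sqrt(min(dd)))
      }
      if (mind <= 3) micro <- c(micro, s_)
    }
    expect_equal(sum(out$micronuclei > 0L) > 0, length(micro) > 0)
    expect_equal(max(out$micronuclei), length(micro))
  }
})

test_that("cell segmentation equals distance-limited dilation of the nucleus", {
  geom <- quick_geom(1, field_shape = c(24L, 96L, 96L), seed = 7)
  lab <- structure(geom$nuclei, voxel_size = geom$voxel_size)
  cells <- segment_cells(lab, max_radius_um = 2)
  # brute-force distance check on a subsample of voxels
  set.seed(8)
  vox <- sample(length(cells), 4000)
  nuc_idx <- which(geom$nuclei > 0L)
  nuc_um <- immunofishr:::index_to_um(
    immunofishr:::linear_to_zyx(nuc_idx, dim(cells)), geom$voxel_size)
  vox_um <- immunofishr:::index_to_um(
    immunofishr:::linear_to_zyx(vox, dim(cells)), geom$voxel_size)
  mind <- sqrt(apply(immunofishr:::euclid2(vox_um, nuc_um), 1, min))
  expect_equal(cells[vox] > 0L, mind <= 2)
})

test_that("distant nuclei produce disjoint cells that match truth masks", {
  geom <- quick_geom(3, field_shape = c(24L, 192L, 192L), seed = 9)
  lab <- structure(geom$nuclei, voxel_size = geom$voxel_size)
  cells <- segment_cells(lab, max_radius_um = 2.5)
  expect_equal(max(cells), 3L)
  agree <- mean(cells == geom$cells)
  expect_gte(agree, 0.95)
  # watershed variant with an intensity channel also maps each nucleus to
  # one cell
  img <- noise_free_render(geom, spot_table(numeric(0), numeric(0),
                                            numeric(0)))
  prot <- (geom$cells > 0L) * 200 + 5
  cells2 <- segment_cells(lab, channel = prot, max_radius_um = 2.5)
  for (i in 1:3) expect_true(all(cells2[geom$nuclei == i] == i))
})

test_that("region intensity means are exact and transform correctly", {
  geom <- quick_geom(1, field_shape = c(16L, 64L, 64L), seed = 10)
  d <- geom$field_shape
  # uniform intensity over the region
  chan <- array(0, d)
  chan[geom$cells > 0L] <- 7
  expect_equal(measure_cell_intensity(chan, geom, per = "cell")$mean_intensity,
               7)
  # half 0 / half 10
  sel <- which(geom$cells > 0L)
  chan2 <- array(0, d)
  chan2[sel[seq_len(floor(length(sel) / 2))]] <- 10
  got <- measure_cell_intensity(chan2, geom, per = "cell")$mean_intensity
  expect_equal(got, 10 * floor(length(sel) / 2) / length(sel))

  # random intensities against a direct sum/count, to near machine precision
  set.seed(11)
  chan3 <- array(runif(prod(d)), d)
  got3 <- measure_cell_intensity(chan3, geom, per = "nucleus")
  oracle <- sum(chan3[geom$nuclei == 1L]) / sum(geom$nuclei == 1L)
  expect_equal(got3$mean_intensity, oracle, tolerance = 1e-12)

  # affine equivariance
  got4 <- measure_cell_intensity(3 * chan3 + 2, geom, per = "nucleus")
  expect_equal(got4$mean_intensity, 3 * oracle + 2, tolerance = 1e-12)

  # shape mismatch and empty-label errors
  expect_error(measure_cell_intensity(array(0, c(2, 2, 2)), geom),
               "different shapes")
  empty <- array(0L, d)
  expect_error(measure_cell_intensity(chan3, empty), "no labelled region")
})
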