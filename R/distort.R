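#' Distortion configuration for a second staining round
#'
#' Harsh re-hybridisation conditions (e.g. pepsin + high temperature for
#' DNA FISH) shrink and deform nuclei between imaging rounds. The model is
#' an in-plane isotropic contraction of each nucleus about its centroid
#' composed with a smooth sinusoidal deformation with per-nucleus random
#' phases; the displacement is tapered to zero with a cosine profile over a
#' margin outside the nuclear boundary, so the cytoplasm is untouched.
#'
#' @param shrink_factor Per-nucleus isotropic scale, 0 < s <= 1.
#' @param deformation_amplitude Amplitude of the smooth deformation (μm).
#' @param deformation_wavelength Wavelength of the deformation (μm).
#' @param margin_um Taper margin outside the nuclear boundary (μm).
#' @param seed Integer seed for the random phases.
#' @return A `distortion_config` list.
#' @export
distortion_config <- function(shrink_factor = 0.9,
                              deformation_amplitude = 0.4,
                              deformation_wavelength = 25,
                              margin_um = 1,
                              seed = 1L) {
  if (!is.numeric(shrink_factor) || length(shrink_factor) != 1L ||
      shrink_factor <= 0) {
    abort("`shrink_factor` must be a single number > 0")
  }
  if (shrink_factor > 1) abort("`shrink_factor` must be <= 1")
  check_scalar_number(deformation_amplitude, "deformation_amplitude", lower = 0)
  check_scalar_number(deformation_wavelength, "deformation_wavelength",
                      lower = 1e-6)
  check_scalar_number(margin_um, "margin_um", lower = 0)
  structure(list(shrink_factor = shrink_factor,
                 deformation_amplitude = deformation_amplitude,
                 deformation_wavelength = deformation_wavelength,
                 margin_um = margin_um, seed = seed),
            class = "distortion_config")
}

#' Apply a between-round nuclear distortion to geometry, truth and images
#'
#' Emulates the second imaging round of a sequential RNA/DNA FISH
#' experiment. Every voxel and spot outside the nuclei (plus the taper
#' margin) is left bit-identical; nuclear content moves by the forward
#' displacement field, which is returned exactly so registration can be
#' validated against ground truth.
#'
#' @param geometry A [generate_cell_geometry()] result (round-1 frame).
#' @param truth A transcript truth table in the same frame (may be `NULL`).
#' @param config A [distortion_config()].
#' @param image Optional [image_stack()] to warp into the round-2 frame.
#' @return A list with distorted `geometry`, `truth`, optional `image`, and
#'   `displacement`: per-nucleus parameters plus `at(points)`, a function
#'   returning the exact forward displacement (μm) at physical points.
#' @export
apply_cycle_distortion <- function(geometry, truth = NULL, config,
                                   image = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(config, "distortion_config"))
  d <- geometry$field_shape
  vs <- geometry$voxel_size
  n_nuc <- nrow(geometry$centers)

  cent <- mask_centroids(geometry$nuclei, vs, n_nuc)
  phases <- with_seed_(config$seed, matrix(runif(2 * n_nuc, 0, 2 * pi),
                                           n_nuc, 2))

  # support = nucleus + margin, assigned to the nearest nucleus; cosine
  # taper weight from 1 at the boundary to 0 at the margin
  ft <- edt_feature_cpp(as.numeric(ifelse(geometry$nuclei > 0L, 0, Inf)),
                        as.integer(geometry$nuclei), as.integer(d),
                        as.numeric(vs))
  dist_um <- sqrt(array(ft$dist2, d))
  support <- array(ft$label, d)
  weight <- array(0, d)
  inside <- dist_um <= config$margin_um
  weight[inside] <- 0.5 * (1 + cos(pi * dist_um[inside] /
                                     max(config$margin_um, 1e-9)))
  weight[geometry$nuclei > 0L] <- 1
  support[!inside] <- 0L

  s <- config$shrink_factor
  A <- config$deformation_amplitude
  lam <- config$deformation_wavelength

  raw_disp <- function(pts, lab) {
    # pts: n x 3 physical (z,y,x); lab: nucleus id per point
    dy <- (s - 1) * (pts[, 2] - cent[lab, 2]) +
      A * sin(2 * pi * (pts[, 3] - cent[lab, 3]) / lam + phases[lab, 1])
    dx <- (s - 1) * (pts[, 3] - cent[lab, 3]) +
      A * sin(2 * pi * (pts[, 2] - cent[lab, 2]) / lam + phases[lab, 2])
    cbind(0, dy, dx)
  }

  weight_at <- function(pts) {
    idx <- um_to_index(pts, vs)
    for (ax in 1:3) idx[, ax] <- pmin(pmax(idx[, ax], 1L), d[ax])
    lin <- zyx_to_linear(idx, d)
    list(w = weight[lin], lab = support[lin])
  }

  displacement_at <- function(pts) {
    pts <- as.matrix(pts)
    wl <- weight_at(pts)
    out <- matrix(0, nrow(pts), 3)
    sel <- wl$lab > 0L & wl$w > 0
    if (any(sel)) {
      out[sel, ] <- raw_disp(pts[sel, , drop = FALSE], wl$lab[sel]) *
        wl$w[sel]
    }
    out
  }

  # ---- distort truth ------------------------------------------------------
  truth2 <- truth
  if (!is.null(truth) && nrow(truth) > 0) {
    pts <- cbind(truth$z_um, truth$y_um, truth$x_um)
    disp <- displacement_at(pts)
    truth2$z_um <- truth$z_um + disp[, 1]
    truth2$y_um <- truth$y_um + disp[, 2]
    truth2$x_um <- truth$x_um + disp[, 3]
    attr(truth2, "voxel_size") <- vs
    attr(truth2, "field_shape") <- d
  }

  # ---- distort nucleus masks (and image if given) by inverse mapping ------
  invert_map <- function(q) {
    # find p with p + w(p) * D(p) = q; fixed-point iteration
    p <- q
    for (it in 1:8) {
      wl <- weight_at(p)
      disp <- matrix(0, nrow(p), 3)
      sel <- wl$lab > 0L & wl$w > 0
      if (any(sel)) {
        disp[sel, ] <- raw_disp(p[sel, , drop = FALSE], wl$lab[sel]) *
          wl$w[sel]
      }
      p <- q - disp
    }
    p
  }

  nuclei2 <- geometry$nuclei
  sup_idx <- which(support > 0L)
  if (length(sup_idx)) {
    q <- index_to_um(linear_to_zyx(sup_idx, d), vs)
    p <- invert_map(q)
    pi_ <- um_to_index(p, vs)
    okb <- pi_[, 1] >= 1 & pi_[, 1] <= d[1] & pi_[, 2] >= 1 &
      pi_[, 2] <= d[2] & pi_[, 3] >= 1 & pi_[, 3] <= d[3]
    val <- integer(length(sup_idx))
    val[okb] <- geometry$nuclei[zyx_to_linear(pi_[okb, , drop = FALSE], d)]
    keep <- val == support[sup_idx]
    nuclei2[sup_idx] <- ifelse(keep, val, 0L)
  }

  image2 <- NULL
  if (!is.null(image)) {
    stopifnot(inherits(image, "image_stack"))
    image2 <- image
    if (length(sup_idx)) {
      q <- index_to_um(linear_to_zyx(sup_idx, d), vs)
      p <- invert_map(q)
      for (ch in names(image$channels)) {
        image2$channels[[ch]][sup_idx] <-
          interp_trilinear(image$channels[[ch]], p, vs)
      }
    }
  }

  geometry2 <- geometry
  geometry2$nuclei <- nuclei2

  list(
    geometry = geometry2,
    truth = truth2,
    image = image2,
    displacement = list(
      at = displacement_at,
      centroids = cent,
      shrink_factor = s,
      amplitude = A,
      wavelength = lam,
      phases = phases,
      margin_um = config$margin_um,
      support = support,
      weight = weight
    )
  )
}

mask_centroids <- function(labels, voxel_size, n = max(labels)) {
  sel <- which(labels > 0L)
  lab <- labels[sel]
  zyx <- index_to_um(linear_to_zyx(sel, dim(labels)), voxel_size)
  cz <- rowsum(zyx[, 1], lab) / as.numeric(table(lab))
  cy <- rowsum(zyx[, 2], lab) / as.numeric(table(lab))
  cx <- rowsum(zyx[, 3], lab) / as.numeric(table(lab))
  out <- matrix(NA_real_, n, 3)
  ids <- as.integer(rownames(cz))
  out[ids, ] <- cbind(cz[, 1], cy[, 1], cx[, 1])
  out
}

# vectorised trilinear sampling of a (z,y,x) volume at physical points;
# out-of-range coordinates are clamped to the edge
interp_trilinear <- function(arr, pts, voxel_size) {
  d <- dim(arr)
  g <- sweep(pts, 2, voxel_size, `/`) - 0.5 # 0-based voxel-centre coords
  lo <- floor(g)
  fr <- g - lo
  i0 <- pmin(pmax(lo + 1, 1), matrix(d, nrow(pts), 3, byrow = TRUE))
  i1 <- pmin(i0 + 1, matrix(d, nrow(pts), 3, byrow = TRUE))
  at <- function(z, y, x) arr[cbind(z, y, x)]
  w <- fr
  v000 <- at(i0[, 1], i0[, 2], i0[, 3]); v100 <- at(i1[, 1], i0[, 2], i0[, 3])
  v010 <- at(i0[, 1], i1[, 2], i0[, 3]); v110 <- at(i1[, 1], i1[, 2], i0[, 3])
  v001 <- at(i0[, 1], i0[, 2], i1[, 3]); v101 <- at(i1[, 1], i0[, 2], i1[, 3])
  v011 <- at(i0[, 1], i1[, 2], i1[, 3]); v111 <- at(i1[, 1], i1[, 2], i1[, 3])
  (1 - w[, 1]) * ((1 - w[, 2]) * ((1 - w[, 3]) * v000 + w[, 3] * v001) +
                    w[, 2] * ((1 - w[, 3]) * v010 + w[, 3] * v011)) +
    w[, 1] * ((1 - w[, 2]) * ((1 - w[, 3]) * v100 + w[, 3] * v101) +
                w[, 2] * ((1 - w[, 3]) * v110 + w[, 3] * v111))
}
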