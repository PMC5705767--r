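#' Generate a ground-truthed cell geometry
#'
#' Builds a synthetic field of non-overlapping cells for forward simulation
#' of immunoFISH experiments. Nuclei are randomly oriented ellipsoids with a
#' low-order radial perturbation ("wrinkles", as lamin staining reveals on
#' real breast-cancer nuclei); micronuclei are small spheres with 1-8% of
#' the parent nuclear volume placed 1-5 μm outside the parent boundary; the
#' cell body is a distance-limited Voronoi dilation of its nucleus, and the
#' cytoplasm is the cell minus nucleus and micronuclei.
#'
#' @param n_cells Number of cells to place (>= 1).
#' @param field_shape Integer length-3 voxel counts (z, y, x).
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @param micronucleus_rate Probability in \[0, 1\] that a cell carries one
#'   micronucleus.
#' @param seed Integer seed; the seed fully determines the output.
#' @param nucleus_semiaxes_xy_um Range the in-plane nuclear semi-axis is
#'   drawn from (μm).
#' @param nucleus_semiaxes_z_um Range for the axial semi-axis (μm); nuclei
#'   of adherent cells are oblate.
#' @param axis_ratio_xy Range for the in-plane anisotropy of the ellipsoid.
#' @param wrinkle_amplitude Relative amplitude of the radial boundary
#'   perturbation.
#' @param cell_radius_um Maximum cytoplasmic extension beyond the nuclear
#'   boundary (μm).
#' @param max_tries Placement retries per object before giving up.
#'
#' @return A `cell_geometry`: integer label volumes `nuclei`, `micronuclei`,
#'   `cells` (labels are cell ids, 0 = background), a
#'   `micronucleus_parents` tibble, per-cell `centers`, plus `voxel_size`
#'   and `field_shape`.
#' @export
generate_cell_geometry <- function(n_cells,
                                   field_shape = c(40L, 384L, 384L),
                                   voxel_size = c(0.2, 0.107, 0.107),
                                   micronucleus_rate = 0,
                                   seed = 1L,
                                   nucleus_semiaxes_xy_um = c(5.5, 7.0),
                                   nucleus_semiaxes_z_um = c(2.5, 3.2),
                                   axis_ratio_xy = c(0.8, 1.0),
                                   wrinkle_amplitude = 0.04,
                                   cell_radius_um = 5,
                                   max_tries = 400L) {
  check_scalar_number(n_cells, "n_cells", lower = 1)
  check_scalar_number(micronucleus_rate, "micronucleus_rate", 0, 1)
  voxel_size <- check_voxel_size(voxel_size)
  field_shape <- as.integer(field_shape)
  ext <- field_shape * voxel_size

  with_seed_(seed, {
    # --- place nuclei ------------------------------------------------------
    centers <- matrix(NA_real_, n_cells, 3)
    ax_xy <- runif(n_cells, nucleus_semiaxes_xy_um[1], nucleus_semiaxes_xy_um[2])
    ax_z <- runif(n_cells, nucleus_semiaxes_z_um[1], nucleus_semiaxes_z_um[2])
    ratio <- runif(n_cells, axis_ratio_xy[1], axis_ratio_xy[2])
    theta <- runif(n_cells, 0, pi)
    gap <- 1.0 # clearance between nuclear envelopes, μm
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      amax <- ax_xy[i] * (1 + 2 * wrinkle_amplitude)
      if (2 * (ax_z[i] + voxel_size[1]) >= ext[1] ||
          2 * (amax + max(voxel_size[2:3])) >= min(ext[2], ext[3])) {
        abort("field too crowded: a nucleus does not fit in the field")
      }
      for (t in seq_len(max_tries)) {
        cz <- runif(1, ax_z[i] + voxel_size[1], ext[1] - ax_z[i] - voxel_size[1])
        cy <- runif(1, amax + voxel_size[2], ext[2] - amax - voxel_size[2])
        cx <- runif(1, amax + voxel_size[3], ext[3] - amax - voxel_size[3])
        ok <- TRUE
        if (i > 1) {
          for (j in seq_len(i - 1)) {
            dyx <- sqrt((cy - centers[j, 2])^2 + (cx - centers[j, 3])^2)
            if (dyx < amax + ax_xy[j] * (1 + 2 * wrinkle_amplitude) + gap) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          centers[i, ] <- c(cz, cy, cx)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "field too crowded: could not place nucleus %d after %d tries",
          i, max_tries))
      }
    }

    nuclei <- array(0L, dim = field_shape)
    wr_phase <- matrix(runif(n_cells * 2, 0, 2 * pi), n_cells, 2)
    wr_amp <- matrix(runif(n_cells * 2, 0.5, 1) * wrinkle_amplitude,
                     n_cells, 2)
    for (i in seq_len(n_cells)) {
      nuclei <- rasterize_nucleus(nuclei, i, centers[i, ],
                                  c(ax_z[i], ax_xy[i], ax_xy[i] * ratio[i]),
                                  theta[i], wr_amp[i, ], wr_phase[i, ],
                                  voxel_size)
    }

    # --- micronuclei -------------------------------------------------------
    micron <- array(0L, dim = field_shape)
    parents <- integer(0)
    nvox_nuc <- tabulate(nuclei, nbins = n_cells)
    vol_nuc <- nvox_nuc * prod(voxel_size)
    mk <- 0L
    for (i in seq_len(n_cells)) {
      if (runif(1) >= micronucleus_rate) next
      r_m <- (3 * runif(1, 0.01, 0.08) * vol_nuc[i] / (4 * pi))^(1 / 3)
      gmax <- min(5, cell_radius_um - r_m - 0.3)
      gmin <- min(1, gmax)
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        g <- runif(1, gmin, gmax)
        ang <- runif(1, 0, 2 * pi)
        # in-plane offset from the parent boundary along a random direction
        rad <- boundary_radius(ax_xy[i], ax_xy[i] * ratio[i], theta[i],
                               wr_amp[i, ], wr_phase[i, ], ang)
        cz <- centers[i, 1]
        cy <- centers[i, 2] + (rad + g + r_m) * sin(ang)
        cx <- centers[i, 3] + (rad + g + r_m) * cos(ang)
        if (cy < r_m + voxel_size[2] || cy > ext[2] - r_m - voxel_size[2] ||
            cx < r_m + voxel_size[3] || cx > ext[3] - r_m - voxel_size[3]) {
          next
        }
        rz <- min(r_m, min(cz, ext[1] - cz) - voxel_size[1])
        if (rz < 2 * voxel_size[1]) next
        cand <- rasterize_sphere(field_shape, c(cz, cy, cx), c(rz, r_m, r_m),
                                 voxel_size)
        if (length(cand) == 0) next
        if (any(nuclei[cand] != 0L) || any(micron[cand] != 0L)) next
        mk <- mk + 1L
        micron[cand] <- mk
        parents <- c(parents, i)
        placed <- TRUE
        break
      }
      if (!placed) {
        warning(sprintf("could not place a micronucleus near cell %d", i))
      }
    }

    # --- cells: distance-limited Voronoi dilation of nuclei ---------------
    cells <- voronoi_dilate(nuclei, voxel_size, cell_radius_um)
    if (any(micron > 0L)) {
      sel <- which(micron > 0L)
      cells[sel] <- parents[micron[sel]]
    }

    geom <- structure(
      list(
        nuclei = nuclei,
        micronuclei = micron,
        micronucleus_parents = tibble(
          micronucleus_id = seq_along(parents),
          cell_id = parents
        ),
        cells = cells,
        centers = tibble(
          cell_id = seq_len(n_cells),
          z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
          semiaxis_z_um = ax_z, semiaxis_xy_um = ax_xy
        ),
        voxel_size = voxel_size,
        field_shape = field_shape
      ),
      class = "cell_geometry"
    )
    geom
  })
}

# radius of the wrinkled ellipse boundary along in-plane direction `ang`
boundary_radius <- function(a, b, theta, wr_amp, wr_phase, ang) {
  phi <- ang - theta
  r0 <- 1 / sqrt((cos(phi) / a)^2 + (sin(phi) / b)^2)
  r0 * (1 + wr_amp[1] * cos(2 * phi + wr_phase[1]) +
          wr_amp[2] * cos(3 * phi + wr_phase[2]))
}

rasterize_nucleus <- function(labels, id, center, semiaxes, theta,
                              wr_amp, wr_phase, voxel_size) {
  d <- dim(labels)
  amax <- max(semiaxes[2], semiaxes[3]) * (1 + 2 * sum(wr_amp))
  zr <- index_range(center[1], semiaxes[1], voxel_size[1], d[1])
  yr <- index_range(center[2], amax, voxel_size[2], d[2])
  xr <- index_range(center[3], amax, voxel_size[3], d[3])
  z <- voxel_centers(zr - 1, voxel_size[1]) - center[1]
  y <- voxel_centers(yr - 1, voxel_size[2]) - center[2]
  x <- voxel_centers(xr - 1, voxel_size[3]) - center[3]
  # in-plane rotation by theta
  g <- expand.grid(y = y, x = x)
  u <- cos(theta) * g$y + sin(theta) * g$x
  v <- -sin(theta) * g$y + cos(theta) * g$x
  phi <- atan2(v, u)
  wr <- 1 + wr_amp[1] * cos(2 * phi + wr_phase[1]) +
    wr_amp[2] * cos(3 * phi + wr_phase[2])
  rho2 <- (u / (semiaxes[2] * wr))^2 + (v / (semiaxes[3] * wr))^2
  for (iz in seq_along(z)) {
    dz2 <- (z[iz] / semiaxes[1])^2
    inside <- rho2 + dz2 <= 1
    if (!any(inside)) next
    sl <- labels[zr[iz], yr, xr]
    sl[matrix(inside, length(yr), length(xr))] <- id
    labels[zr[iz], yr, xr] <- sl
  }
  labels
}

rasterize_sphere <- function(field_shape, center, radii, voxel_size) {
  zr <- index_range(center[1], radii[1], voxel_size[1], field_shape[1])
  yr <- index_range(center[2], radii[2], voxel_size[2], field_shape[2])
  xr <- index_range(center[3], radii[3], voxel_size[3], field_shape[3])
  if (!length(zr) || !length(yr) || !length(xr)) return(integer(0))
  z <- (voxel_centers(zr - 1, voxel_size[1]) - center[1]) / radii[1]
  y <- (voxel_centers(yr - 1, voxel_size[2]) - center[2]) / radii[2]
  x <- (voxel_centers(xr - 1, voxel_size[3]) - center[3]) / radii[3]
  g <- expand.grid(z = z, y = y, x = x)
  inside <- g$z^2 + g$y^2 + g$x^2 <= 1
  gi <- expand.grid(z = zr, y = yr, x = xr)
  zyx_to_linear(as.matrix(gi)[inside, , drop = FALSE], field_shape)
}

index_range <- function(center_um, radius_um, step_um, n) {
  lo <- max(1L, floor((center_um - radius_um) / step_um))
  hi <- min(n, ceiling((center_um + radius_um) / step_um) + 1L)
  if (lo > hi) return(integer(0))
  seq.int(lo, hi)
}

# nearest-nucleus assignment limited to a physical radius
voronoi_dilate <- function(nuclei, voxel_size, max_radius_um) {
  d <- dim(nuclei)
  d2 <- ifelse(nuclei > 0L, 0, Inf)
  ft <- edt_feature_cpp(as.numeric(d2), as.integer(nuclei), as.integer(d),
                        as.numeric(voxel_size))
  lab <- array(ft$label, dim = d)
  lab[array(ft$dist2, dim = d) > max_radius_um^2] <- 0L
  lab
}

#' Cytoplasm label volume of a geometry or segmentation
#'
#' @param x A `cell_geometry` or `segmentation_labels` object.
#' @return Integer label volume: cell label in cytoplasmic voxels, 0
#'   elsewhere.
#' @export
cytoplasm_labels <- function(x) {
  cyto <- x$cells
  cyto[x$nuclei > 0L | x$micronuclei > 0L] <- 0L
  cyto
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> %d cell(s), %d micronucleus(-ei), field %s\n",
              nrow(x$centers), nrow(x$micronucleus_parents),
              paste(x$field_shape, collapse = " x ")))
  invisible(x)
}

label_volumes <- function(labels, voxel_size, n = max(labels)) {
  nvox <- tabulate(labels[labels > 0L], nbins = n)
  tibble(label = seq_len(n), n_voxels = nvox,
         volume_um3 = nvox * prod(voxel_size))
}
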