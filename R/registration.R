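#' Extract boundary control points from nucleus masks
#'
#' For every nucleus and every z-plane it intersects, the 2D boundary
#' (foreground voxels with a 4-neighbour background) is ordered by angle
#' around the plane centroid, and the resulting closed polygon is resampled
#' to `n_per_contour` points at equal arc length. The starting point is
#' anchored at the boundary voxel of maximal x (ties by maximal y), a
#' deterministic convention shared between rounds so that corresponding
#' indices start near corresponding locations. Contours with fewer than 8
#' boundary voxels are skipped.
#'
#' @param labels Integer nucleus label volume (or logical mask for a single
#'   nucleus).
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @param n_per_contour Points per resampled contour (>= 8).
#' @return Tibble: `nucleus_id`, `z_index`, `z_um`, `t` (arc-length
#'   parameter in \[0, 1)), `y_um`, `x_um`.
#' @export
extract_boundary_control_points <- function(labels, voxel_size = NULL,
                                            n_per_contour = 32L) {
  voxel_size <- check_voxel_size(voxel_size %||% attr(labels, "voxel_size"))
  if (is.logical(labels)) labels <- array(as.integer(labels), dim(labels))
  if (n_per_contour < 8L) abort("`n_per_contour` must be at least 8")
  if (!any(labels > 0L)) abort("empty mask: no nuclei to trace")
  d <- dim(labels)
  out <- list()
  for (id in sort(unique(labels[labels > 0L]))) {
    zplanes <- which(apply(labels == id, 1, any))
    for (z in zplanes) {
      sl <- labels[z, , ] == id
      b <- boundary_2d(sl)
      if (sum(b) < 8L) next
      ii <- which(b, arr.ind = TRUE) # (y, x) 1-based
      yx <- cbind((ii[, 1] - 0.5) * voxel_size[2],
                  (ii[, 2] - 0.5) * voxel_size[3])
      ctr <- c(mean(yx[, 1]), mean(yx[, 2]))
      ang <- atan2(yx[, 1] - ctr[1], yx[, 2] - ctr[2])
      ord <- order(ang, yx[, 1], yx[, 2])
      yx <- yx[ord, , drop = FALSE]
      anchor <- which.max(yx[, 2] + yx[, 1] * 1e-9) # max x, tie: max y
      m <- nrow(yx)
      yx <- yx[c(anchor:m, seq_len(anchor - 1L)), , drop = FALSE]
      rs <- resample_closed_polygon(yx, n_per_contour)
      out[[length(out) + 1L]] <- tibble(
        nucleus_id = id, z_index = z, z_um = (z - 0.5) * voxel_size[1],
        t = (seq_len(n_per_contour) - 1) / n_per_contour,
        y_um = rs[, 1], x_um = rs[, 2]
      )
    }
  }
  if (length(out) == 0) abort("no contour had at least 8 boundary voxels")
  bind_rows(out)
}

boundary_2d <- function(sl) {
  ny <- nrow(sl); nx <- ncol(sl)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- sl
  interior <- pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
    pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  sl & !interior
}

# resample a closed polygon (rows = ordered vertices) to n points at equal
# arc length, keeping the first vertex as the first sample
resample_closed_polygon <- function(v, n) {
  m <- nrow(v)
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums((vc[-1, , drop = FALSE] - vc[-(m + 1), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[m + 1]
  target <- (seq_len(n) - 1) * L / n
  j <- findInterval(target, cs, rightmost.closed = TRUE)
  j[j > m] <- m
  frac <- (target - cs[j]) / pmax(seg[j], 1e-12)
  vc[j, , drop = FALSE] + (vc[j + 1L, , drop = FALSE] -
                             vc[j, , drop = FALSE]) * frac
}

#' Match control points between two rounds
#'
#' Nuclei are put in correspondence by mutual nearest-neighbour centroid
#' assignment (gated by `max_centroid_shift_um`); per nucleus and z-plane,
#' the moving contour is aligned to the fixed one by the exhaustive cyclic
#' shift minimising the sum of squared distances after centroid/scale
#' normalisation, which pairs the resampled points.
#'
#' @param cp_fixed,cp_moving [extract_boundary_control_points()] tibbles.
#' @param max_centroid_shift_um Maximum nucleus centroid displacement (μm).
#' @param allow_unmatched Drop unmatched nuclei with a warning instead of
#'   erroring.
#' @return List: `pairs` tibble (`nucleus_id` = fixed id, `z_index`, fixed
#'   `fz/fy/fx`, moving `mz/my/mx`, `shift`), and `nucleus_map`
#'   (`fixed_id`, `moving_id`).
#' @export
match_control_points <- function(cp_fixed, cp_moving,
                                 max_centroid_shift_um = 10,
                                 allow_unmatched = FALSE) {
  cent <- function(cp) {
    cp |>
      group_by(nucleus_id = .data$nucleus_id) |>
      summarise(z = mean(.data$z_um), y = mean(.data$y_um),
                x = mean(.data$x_um))
  }
  cf <- cent(cp_fixed); cm <- cent(cp_moving)
  d2 <- euclid2(as.matrix(cf[, c("z", "y", "x")]),
                as.matrix(cm[, c("z", "y", "x")]))
  nn_f <- apply(d2, 1, which.min)
  nn_m <- apply(d2, 2, which.min)
  mutual <- which(nn_m[nn_f] == seq_len(nrow(cf)) &
                    d2[cbind(seq_len(nrow(cf)), nn_f)] <=
                    max_centroid_shift_um^2)
  unmatched_f <- setdiff(seq_len(nrow(cf)), mutual)
  unmatched_m <- setdiff(seq_len(nrow(cm)), nn_f[mutual])
  if (length(unmatched_f) || length(unmatched_m)) {
    msg <- sprintf(
      "unmatched nuclei between rounds (fixed: %s; moving: %s)",
      paste(cf$nucleus_id[unmatched_f], collapse = ","),
      paste(cm$nucleus_id[unmatched_m], collapse = ","))
    if (!allow_unmatched) abort(msg) else warning(msg)
  }
  nucleus_map <- tibble(fixed_id = cf$nucleus_id[mutual],
                        moving_id = cm$nucleus_id[nn_f[mutual]])

  rows <- list()
  for (r in seq_len(nrow(nucleus_map))) {
    fid <- nucleus_map$fixed_id[r]
    mid <- nucleus_map$moving_id[r]
    f <- filter(cp_fixed, .data$nucleus_id == fid)
    m <- filter(cp_moving, .data$nucleus_id == mid)
    zs <- intersect(unique(f$z_index), unique(m$z_index))
    contours <- list()
    for (z in zs) {
      fz <- arrange(filter(f, .data$z_index == z), .data$t)
      mz <- arrange(filter(m, .data$z_index == z), .data$t)
      n <- nrow(fz)
      if (n != nrow(mz) || n < 3) next
      contours[[as.character(z)]] <-
        list(z = z, A = cbind(fz$y_um, fz$x_um),
             B = cbind(mz$y_um, mz$x_um), zf = fz$z_um[1], zm = mz$z_um[1])
    }
    if (!length(contours)) next
    n <- nrow(contours[[1]]$A)
    for (ct in contours) {
      k <- best_cyclic_shift(ct$A, ct$B)
      Bk <- cyclic_interp(ct$B, (seq_len(n) - 1) + k)
      rows[[length(rows) + 1L]] <- tibble(
        nucleus_id = fid, moving_nucleus_id = mid, z_index = ct$z,
        fz = ct$zf, fy = ct$A[, 1], fx = ct$A[, 2],
        mz = ct$zm, my = Bk[, 1], mx = Bk[, 2],
        shift = k
      )
    }
  }
  if (length(rows) == 0) abort("no common contours between rounds")
  list(pairs = bind_rows(rows), nucleus_map = nucleus_map)
}

contour_normalize <- function(P) {
  Pc <- sweep(P, 2, colMeans(P))
  Pc / max(sqrt(mean(rowSums(Pc^2))), 1e-12)
}

# SSD of norm(A) against every integer cyclic shift of norm(B)
cyclic_ssd_profile <- function(A, B) {
  An <- contour_normalize(A)
  Bn <- contour_normalize(B)
  n <- nrow(A)
  vapply(0:(n - 1), function(k) {
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    sum((An - Bn[idx, , drop = FALSE])^2)
  }, 0)
}

# continuous refinement of the cyclic shift around an integer start: the
# contours are resampled curves, so fractional shifts are meaningful and
# remove the tangential quantisation error of integer-only alignment
refine_cyclic_shift <- function(A, B, k0) {
  An <- contour_normalize(A)
  Bn <- contour_normalize(B)
  n <- nrow(A)
  obj <- function(k) {
    sum((An - cyclic_interp(Bn, (seq_len(n) - 1) + k))^2)
  }
  opt <- stats::optimize(obj, interval = c(k0 - 1, k0 + 1), tol = 1e-4)
  opt$minimum
}

# exhaustive integer search plus continuous refinement (single contour)
best_cyclic_shift <- function(A, B) {
  ss <- cyclic_ssd_profile(A, B)
  refine_cyclic_shift(A, B, which.min(ss) - 1L)
}

# evaluate a closed polygon of vertices P at fractional cyclic indices
# (0-based), linear interpolation between adjacent vertices
cyclic_interp <- function(P, idx) {
  n <- nrow(P)
  i0 <- floor(idx)
  fr <- idx - i0
  a <- (i0 %% n) + 1L
  b <- ((i0 + 1) %% n) + 1L
  P[a, , drop = FALSE] * (1 - fr) + P[b, , drop = FALSE] * fr
}

# support weight: 1 inside nuclei, cosine-tapered to 0 over `margin_um`,
# nearest-nucleus ownership within the margin
support_weights <- function(labels, voxel_size, margin_um) {
  d <- dim(labels)
  ft <- edt_feature_cpp(as.numeric(ifelse(labels > 0L, 0, Inf)),
                        as.integer(labels), as.integer(d),
                        as.numeric(voxel_size))
  dist_um <- sqrt(array(ft$dist2, d))
  support <- array(ft$label, d)
  weight <- array(0, d)
  inside <- dist_um <= margin_um
  weight[inside] <- 0.5 * (1 + cos(pi * dist_um[inside] / max(margin_um, 1e-9)))
  weight[labels > 0L] <- 1
  support[!inside] <- 0L
  list(weight = weight, support = support)
}

# One in-plane patch per nucleus, pooled over its z-planes: each plane
# constrains the field only on a ring, so the radial direction is
# conditioned by combining rings of different radii; z-dependent bases on
# ring data are catastrophically ill-conditioned and are not used. The
# polynomial order grows with the number of boundary samples: deformations
# whose wavelength is comparable to the nuclear diameter need more than a
# cubic across the patch.
polynomial_terms <- function(npts) {
  degree <- if (npts >= 600) 5L else if (npts >= 200) 4L else if
  (npts >= 20) 3L else 2L
  g <- expand.grid(az = 0, ay = 0:degree, ax = 0:degree)
  as.matrix(g[g$ay + g$ax <= degree, , drop = FALSE])
}

design_matrix <- function(pts, center, scale, terms) {
  zn <- (pts[, 1] - center[1]) / scale[1]
  yn <- (pts[, 2] - center[2]) / scale[2]
  xn <- (pts[, 3] - center[3]) / scale[3]
  X <- matrix(1, nrow(pts), nrow(terms))
  for (j in seq_len(nrow(terms))) {
    X[, j] <- zn^terms[j, 1] * yn^terms[j, 2] * xn^terms[j, 3]
  }
  X
}

# Least-squares polynomial displacement patch for one nucleus.
#
# Boundary correspondences from arc-length contour matching carry far more
# error tangentially than normally (tangential motion of a closed boundary
# is nearly unobservable — the aperture problem), so when contour normals
# are supplied the fit solves a joint weighted system: the normal
# projection of each correspondence enters at weight 1 and the tangential
# projection at `tangential_weight`. With boundary normals covering all
# directions the normal data alone pins down the smooth field.
fit_poly_field <- function(src_pts, targets, normals = NULL,
                           tangential_weight = 0.1) {
  # src_pts: n x 3 (z,y,x); targets: n x 2 residual displacements (dy,dx)
  n <- nrow(src_pts)
  if (n < 8) abort("at least 8 correspondences per nucleus are required")
  ctr <- colMeans(src_pts)
  dev <- sweep(src_pts, 2, ctr)
  sv <- svd(dev[, 2:3, drop = FALSE])$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    abort("degenerate correspondences: boundary points are collinear")
  }
  scl <- pmax(apply(abs(dev), 2, max), 1e-6)
  terms <- polynomial_terms(n)
  X <- design_matrix(src_pts, ctr, scl, terms)
  m <- ncol(X)
  # mild ridge on the nonlinear terms keeps the patch tame where the
  # boundary data leave it weakly constrained; constant and linear terms
  # (translation/affine) are not penalised
  pen <- sqrt(1e-4 * n) * diag(as.numeric(rowSums(terms) > 1), m)
  if (is.null(normals)) {
    A <- rbind(X, pen)
    b <- rbind(targets, matrix(0, m, 2))
    coef <- qr.coef(qr(A), b)
    coef[is.na(coef)] <- 0
  } else {
    ny <- normals[, 1]; nx <- normals[, 2]
    w <- tangential_weight
    zer <- matrix(0, m, m)
    A <- rbind(cbind(ny * X, nx * X),
               w * cbind(-nx * X, ny * X),
               cbind(pen, zer), cbind(zer, pen))
    b <- c(ny * targets[, 1] + nx * targets[, 2],
           w * (-nx * targets[, 1] + ny * targets[, 2]),
           numeric(2 * m))
    beta <- qr.coef(qr(A), b)
    beta[is.na(beta)] <- 0
    coef <- cbind(beta[seq_len(m)], beta[m + seq_len(m)])
  }
  list(center = ctr, scale = scl, terms = terms, coef = coef)
}

# unit normals of closed contours given in order within each z-plane
pair_normals <- function(y, x, z_index) {
  n <- length(y)
  ny <- numeric(n); nx <- numeric(n)
  for (z in unique(z_index)) {
    id <- which(z_index == z)
    m <- length(id)
    nxt <- id[c(seq_len(m)[-1], 1L)]
    prv <- id[c(m, seq_len(m - 1L))]
    ty <- y[nxt] - y[prv]
    tx <- x[nxt] - x[prv]
    len <- pmax(sqrt(ty^2 + tx^2), 1e-12)
    ny[id] <- -tx / len
    nx[id] <- ty / len
  }
  cbind(ny, nx)
}

eval_poly_field <- function(fit, pts) {
  design_matrix(pts, fit$center, fit$scale, fit$terms) %*% fit$coef
}

# global 2D similarity (complex least squares) moving -> fixed, plus a z shift
fit_global_similarity <- function(pairs) {
  zm <- complex(real = pairs$mx, imaginary = pairs$my)
  zf <- complex(real = pairs$fx, imaginary = pairs$fy)
  zmc <- zm - mean(zm)
  a <- sum(Conj(zmc) * (zf - mean(zf))) / max(sum(Mod(zmc)^2), 1e-300)
  b <- mean(zf) - a * mean(zm)
  list(a = a, b = b, tz = mean(pairs$fz - pairs$mz))
}

apply_similarity <- function(g, pts) {
  z <- complex(real = pts[, 3], imaginary = pts[, 2])
  w <- g$a * z + g$b
  cbind(pts[, 1] + g$tz, Im(w), Re(w))
}

apply_similarity_inv <- function(g, pts) {
  z <- complex(real = pts[, 3], imaginary = pts[, 2])
  w <- (z - g$b) / g$a
  cbind(pts[, 1] - g$tz, Im(w), Re(w))
}

#' Fit a warp field from matched boundary control points
#'
#' A global similarity transform (scale, rotation, translation) is fitted
#' first by least squares over all pairs; the per-nucleus residual
#' displacements are then interpolated by least-squares bicubic polynomial
#' patches (cubic in-plane, optionally linear in z when enough points are
#' available), supported on each nucleus plus a margin with a cosine taper
#' to zero, so the displacement is exactly zero in the cytoplasm. Both the
#' forward field (moving frame -> fixed frame, applied to spot tables) and
#' the inverse field (used to resample images onto the fixed grid) are
#' fitted.
#'
#' @param matches [match_control_points()] output.
#' @param fixed_labels,moving_labels Nucleus label volumes of the two
#'   rounds (support masks).
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @param margin_um Support margin (μm).
#' @param tangential_weight Relative weight of the tangential projection
#'   of each correspondence in the patch fit (the normal projection has
#'   weight 1); see the fitting details above.
#' @param refine_iterations Rounds of point-to-curve correspondence
#'   refinement after the initial arc-length pairing.
#' @return A `warp_field` object.
#' @export
fit_warp <- function(matches, fixed_labels, moving_labels,
                     voxel_size = NULL, margin_um = 1,
                     tangential_weight = 0.1, refine_iterations = 2L) {
  voxel_size <- check_voxel_size(voxel_size %||%
                                   attr(fixed_labels, "voxel_size"))
  pairs <- matches$pairs
  nucleus_map <- matches$nucleus_map
  g <- fit_global_similarity(pairs)

  fit_nucleus <- function(pp) {
    mv <- cbind(pp$mz, pp$my, pp$mx)
    fx <- cbind(pp$fz, pp$fy, pp$fx)
    nrm_m <- pair_normals(pp$my, pp$mx, pp$z_index)
    nrm_f <- pair_normals(pp$fy, pp$fx, pp$z_index)
    Sm <- apply_similarity(g, mv)
    fwd <- fit_poly_field(mv, fx[, 2:3, drop = FALSE] -
                            Sm[, 2:3, drop = FALSE], normals = nrm_m,
                          tangential_weight = tangential_weight)
    Sf <- apply_similarity_inv(g, fx)
    inv <- fit_poly_field(fx, mv[, 2:3, drop = FALSE] -
                            Sf[, 2:3, drop = FALSE], normals = nrm_f,
                          tangential_weight = tangential_weight)
    list(fwd = fwd, inv = inv)
  }

  nuclei <- list()
  for (r in seq_len(nrow(nucleus_map))) {
    fid <- nucleus_map$fixed_id[r]
    pp <- filter(pairs, .data$nucleus_id == fid)
    nuclei[[as.character(fid)]] <- c(
      list(fixed_id = fid, moving_id = nucleus_map$moving_id[r]),
      fit_nucleus(pp))
  }

  # Correspondence refinement (point-to-curve ICP): arc-length pairing is
  # accurate normally but slips tangentially where the deformation
  # stretches the boundary nonuniformly. Each round projects the current
  # prediction of every fixed point onto the actual moving contour, so
  # the normal coordinate comes from the data and the tangential
  # coordinate from the smooth field, then refits the patches.
  for (it in seq_len(refine_iterations)) {
    for (r in seq_len(nrow(nucleus_map))) {
      fid <- nucleus_map$fixed_id[r]
      key <- as.character(fid)
      sel <- which(pairs$nucleus_id == fid)
      pp <- pairs[sel, ]
      q <- cbind(pp$fz, pp$fy, pp$fx)
      t_inv <- apply_similarity_inv(g, q)
      t_inv[, 2:3] <- t_inv[, 2:3] + eval_poly_field(nuclei[[key]]$inv, q)
      newm <- matrix(NA_real_, nrow(pp), 2)
      for (z in unique(pp$z_index)) {
        id <- which(pp$z_index == z)
        newm[id, ] <- project_polygon(t_inv[id, 2:3, drop = FALSE],
                                      cbind(pp$my[id], pp$mx[id]))
      }
      pairs$my[sel] <- newm[, 1]
      pairs$mx[sel] <- newm[, 2]
      nuclei[[key]][c("fwd", "inv")] <- fit_nucleus(pairs[sel, ])
    }
  }

  sup_m <- support_weights(moving_labels, voxel_size, margin_um)
  sup_f <- support_weights(fixed_labels, voxel_size, margin_um)
  structure(list(global = g, nuclei = nuclei, nucleus_map = nucleus_map,
                 supports_moving = sup_m, supports_fixed = sup_f,
                 voxel_size = voxel_size, dim = dim(fixed_labels),
                 margin_um = margin_um),
            class = "warp_field")
}

# closest point on a closed polygon for each query point (2D)
project_polygon <- function(pts, poly) {
  m <- nrow(poly)
  polyc <- rbind(poly, poly[1, , drop = FALSE])
  best_d <- rep(Inf, nrow(pts))
  best <- pts
  for (s in seq_len(m)) {
    a <- polyc[s, ]; b <- polyc[s + 1, ]
    ab <- b - a
    len2 <- max(sum(ab^2), 1e-12)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    py <- a[1] + t * ab[1]
    px <- a[2] + t * ab[2]
    d <- (pts[, 1] - py)^2 + (pts[, 2] - px)^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best[upd, 1] <- py[upd]
    best[upd, 2] <- px[upd]
  }
  best
}

#' @export
print.warp_field <- function(x, ...) {
  g <- x$global
  cat(sprintf(
    "<warp_field> %d nucleus(-ei); global scale %.4f, rotation %.3f deg\n",
    length(x$nuclei), Mod(g$a), Arg(g$a) * 180 / pi))
  invisible(x)
}

# forward-map physical points (moving frame -> fixed frame)
warp_points <- function(warp, pts) {
  pts <- as.matrix(pts)
  d <- warp$dim
  idx <- um_to_index(pts, warp$voxel_size)
  for (ax in 1:3) idx[, ax] <- pmin(pmax(idx[, ax], 1L), d[ax])
  lin <- zyx_to_linear(idx, d)
  w <- warp$supports_moving$weight[lin]
  lab <- warp$supports_moving$support[lin]
  out <- pts
  mid2fid <- setNames(as.character(warp$nucleus_map$fixed_id),
                      as.character(warp$nucleus_map$moving_id))
  for (mid in unique(lab[lab > 0L & w > 0])) {
    key <- mid2fid[as.character(mid)]
    if (is.na(key)) next
    nuc <- warp$nuclei[[key]]
    sel <- which(lab == mid & w > 0)
    p <- pts[sel, , drop = FALSE]
    t_full <- apply_similarity(warp$global, p)
    t_full[, 2:3] <- t_full[, 2:3] + eval_poly_field(nuc$fwd, p)
    out[sel, ] <- p + (t_full - p) * w[sel]
  }
  out
}

#' Apply a warp field to an image stack or a spot table
#'
#' Spot tables are forward-mapped into the fixed frame; image channels are
#' resampled onto the fixed grid by inverse mapping with bicubic in-plane
#' (linear in z) intensity interpolation. Voxels and spots outside all
#' support masks are returned unchanged — cytoplasmic signal is never
#' resampled.
#'
#' @param target An [image_stack()], a 3D array, or a spot tibble with
#'   `z_um`, `y_um`, `x_um`.
#' @param warp A `warp_field` from [fit_warp()].
#' @return The warped target, same type as the input.
#' @export
apply_warp <- function(target, warp) {
  stopifnot(inherits(warp, "warp_field"))
  if (is.data.frame(target)) {
    pts <- cbind(target$z_um, target$y_um, target$x_um)
    new <- warp_points(warp, pts)
    target$z_um <- unname(new[, 1])
    target$y_um <- unname(new[, 2])
    target$x_um <- unname(new[, 3])
    return(target)
  }
  if (inherits(target, "image_stack")) {
    out <- target
    for (ch in names(target$channels)) {
      out$channels[[ch]] <- warp_channel(target$channels[[ch]], warp)
    }
    return(out)
  }
  if (is.array(target) && length(dim(target)) == 3L) {
    return(warp_channel(target, warp))
  }
  abort("`target` must be an image stack, 3D array or spot table")
}

warp_channel <- function(arr, warp) {
  d <- warp$dim
  stopifnot(all(dim(arr) == d))
  vs <- warp$voxel_size
  out <- arr
  supf <- warp$supports_fixed
  sel_all <- which(supf$support > 0L & supf$weight > 0)
  if (!length(sel_all)) return(out)
  lab <- supf$support[sel_all]
  for (fid in unique(lab)) {
    key <- as.character(fid)
    nuc <- warp$nuclei[[key]]
    if (is.null(nuc)) next
    sel <- sel_all[lab == fid]
    q <- index_to_um(linear_to_zyx(sel, d), vs)
    t_inv <- apply_similarity_inv(warp$global, q)
    t_inv[, 2:3] <- t_inv[, 2:3] + eval_poly_field(nuc$inv, q)
    disp <- (t_inv - q) * supf$weight[sel]
    if (max(abs(disp)) < 1e-9) next # identity: keep voxels bit-exact
    out[sel] <- interp_bicubic_z(arr, q + disp, vs)
  }
  out
}

# Catmull-Rom bicubic interpolation in-plane, linear along z; edge-clamped
interp_bicubic_z <- function(arr, pts, voxel_size) {
  d <- dim(arr)
  g <- sweep(pts, 2, voxel_size, `/`) - 0.5
  z0 <- floor(g[, 1]); fz <- g[, 1] - z0
  y0 <- floor(g[, 2]); fy <- g[, 2] - y0
  x0 <- floor(g[, 3]); fx <- g[, 3] - x0
  cr <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    cbind((-t3 + 2 * t2 - t) / 2,
          (3 * t3 - 5 * t2 + 2) / 2,
          (-3 * t3 + 4 * t2 + t) / 2,
          (t3 - t2) / 2)
  }
  wy <- cr(fy); wx <- cr(fx)
  clampi <- function(i, n) pmin(pmax(i, 1), n)
  acc <- 0
  for (zl in 0:1) {
    zz <- clampi(z0 + zl, d[1])
    wz <- ifelse(zl == 0, 1 - fz, fz)
    plane <- 0
    for (jy in 1:4) {
      yy <- clampi(y0 + jy - 2L, d[2])
      row <- 0
      for (jx in 1:4) {
        xx <- clampi(x0 + jx - 2L, d[3])
        row <- row + wx[, jx] * arr[cbind(zz, yy, xx)]
      }
      plane <- plane + wy[, jy] * row
    }
    acc <- acc + wz * plane
  }
  acc
}

# mean distance from each point to a closed polygon (point-to-segment)
polygon_distance <- function(pts, poly) {
  m <- nrow(poly)
  polyc <- rbind(poly, poly[1, , drop = FALSE])
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(m)) {
    a <- polyc[s, ]; b <- polyc[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) /
      max(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Register a second staining round to the first
#'
#' End-to-end registration: segment nuclei in both rounds (or take
#' provided label volumes), match nuclei and boundary control points, fit
#' the warp, and report per-nucleus mean boundary residuals (fixed control
#' points against the moving contour polygon) before and after warping.
#'
#' @param fixed,moving [image_stack()]s with a nuclear channel, or nucleus
#'   label volumes.
#' @param voxel_size Voxel size when label arrays are passed.
#' @param n_per_contour Control points per contour.
#' @param margin_um Warp support margin (μm).
#' @param max_centroid_shift_um Nucleus matching gate (μm).
#' @param tangential_weight Tangential correspondence weight for
#'   [fit_warp()].
#' @param segment_args Extra arguments for [segment_nuclei()].
#' @return List of class `registration_result`: `warp`, `residuals`
#'   (per-nucleus tibble with `pre_um`, `post_um`, `pre_voxel`,
#'   `post_voxel`), `moving_registered` (when `moving` is a stack),
#'   `fixed_labels`, `moving_labels`, `matches`.
#' @export
register_cycles <- function(fixed, moving, voxel_size = NULL,
                            n_per_contour = 64L, margin_um = 1,
                            max_centroid_shift_um = 10,
                            tangential_weight = 0.1,
                            segment_args = list()) {
  get_labels <- function(x) {
    if (inherits(x, "image_stack")) {
      do.call(segment_nuclei, c(list(x), segment_args))
    } else if (inherits(x, "cell_geometry")) {
      structure(x$nuclei, voxel_size = x$voxel_size)
    } else x
  }
  lab_f <- get_labels(fixed)
  lab_m <- get_labels(moving)
  vs <- check_voxel_size(voxel_size %||% attr(lab_f, "voxel_size"))

  cp_f <- extract_boundary_control_points(lab_f, vs, n_per_contour)
  cp_m <- extract_boundary_control_points(lab_m, vs, n_per_contour)
  matches <- match_control_points(cp_f, cp_m, max_centroid_shift_um,
                                  allow_unmatched = TRUE)
  warp <- fit_warp(matches, lab_f, lab_m, vs, margin_um,
                   tangential_weight = tangential_weight)

  # residuals: fixed control points vs (warped) moving contour polygons
  pairs <- matches$pairs
  res <- list()
  for (fid in unique(pairs$nucleus_id)) {
    pp <- filter(pairs, .data$nucleus_id == fid)
    pre <- post <- numeric(0)
    for (z in unique(pp$z_index)) {
      pz <- filter(pp, .data$z_index == z)
      fpts <- cbind(pz$fy, pz$fx)
      mpoly <- cbind(pz$my, pz$mx)
      wp <- warp_points(warp, cbind(pz$mz, pz$my, pz$mx))
      pre <- c(pre, polygon_distance(fpts, mpoly))
      post <- c(post, polygon_distance(fpts, wp[, 2:3, drop = FALSE]))
    }
    res[[length(res) + 1L]] <- tibble(
      nucleus_id = fid, n_points = length(pre),
      pre_um = mean(pre), post_um = mean(post),
      pre_voxel = mean(pre) / vs[2], post_voxel = mean(post) / vs[2]
    )
  }
  out <- list(
    warp = warp,
    residuals = bind_rows(res),
    moving_registered = if (inherits(moving, "image_stack")) {
      apply_warp(moving, warp)
    } else NULL,
    fixed_labels = lab_f, moving_labels = lab_m, matches = matches
  )
  class(out) <- "registration_result"
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> %d nucleus(-ei); mean boundary residual %.3f -> %.3f um\n",
    nrow(x$residuals), mean(x$residuals$pre_um), mean(x$residuals$post_um)))
  invisible(x)
}
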