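#' Spot detection configuration
#'
#' @param expected_spot_fwhm_xy,expected_spot_fwhm_z Expected full width at
#'   half maximum of a diffraction-limited particle, in μm. The default
#'   0.25 μm in-plane matches a high-NA widefield acquisition; the axial
#'   FWHM is wider.
#' @param min_separation Minimum distance between detected spots (μm); must
#'   be at least one voxel.
#' @param threshold_mode `"auto"` (Otsu on log candidate responses) or
#'   `"manual"`.
#' @param manual_threshold Threshold in filter-response units
#'   (`threshold_mode = "manual"`).
#' @param threshold_multiplier Deterministic refinement factor applied to
#'   the automatic threshold (the reproducible analogue of the manual
#'   threshold refinement an interactive user would perform).
#' @return A `detection_config` list.
#' @export
detection_config <- function(expected_spot_fwhm_xy = 0.25,
                             expected_spot_fwhm_z = 0.7,
                             min_separation = 0.3,
                             threshold_mode = c("auto", "manual"),
                             manual_threshold = NA_real_,
                             threshold_multiplier = 1.0) {
  threshold_mode <- match.arg(threshold_mode)
  check_scalar_number(expected_spot_fwhm_xy, "expected_spot_fwhm_xy",
                      lower = 1e-9)
  check_scalar_number(expected_spot_fwhm_z, "expected_spot_fwhm_z",
                      lower = 1e-9)
  check_scalar_number(min_separation, "min_separation", lower = 0)
  check_scalar_number(threshold_multiplier, "threshold_multiplier", lower = 0)
  if (threshold_mode == "manual") {
    check_scalar_number(manual_threshold, "manual_threshold")
  }
  structure(list(expected_spot_fwhm_xy = expected_spot_fwhm_xy,
                 expected_spot_fwhm_z = expected_spot_fwhm_z,
                 min_separation = min_separation,
                 threshold_mode = threshold_mode,
                 manual_threshold = manual_threshold,
                 threshold_multiplier = threshold_multiplier),
            class = "detection_config")
}

#' Extract candidate maxima from a filtered volume
#'
#' Returns all strict 26-neighbourhood local maxima with positive filter
#' response, then greedily suppresses candidates that lie within
#' `min_separation` (Euclidean, physical units) of a stronger candidate.
#' Ties are broken by higher response, then lexicographic (z, y, x) order,
#' so the result is deterministic.
#'
#' @param filtered Filtered 3D array (e.g. [mexican_hat_filter()] output).
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @param min_separation Minimum separation in μm.
#' @return Tibble of candidates: voxel indices (`z`, `y`, `x`, 1-based),
#'   physical coordinates and `response`, ordered by decreasing response.
#' @export
detect_candidates <- function(filtered, voxel_size, min_separation = 0.3) {
  voxel_size <- check_voxel_size(voxel_size)
  d <- dim(filtered)
  idx <- local_maxima_cpp(as.numeric(filtered), as.integer(d), 0)
  if (length(idx) == 0) {
    return(tibble(z = integer(0), y = integer(0), x = integer(0),
                  z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                  response = numeric(0)))
  }
  zyx <- linear_to_zyx(idx, d)
  um <- index_to_um(zyx, voxel_size)
  resp <- filtered[idx]
  ord <- order(-resp, zyx[, 1], zyx[, 2], zyx[, 3])
  zyx <- zyx[ord, , drop = FALSE]
  um <- um[ord, , drop = FALSE]
  resp <- resp[ord]
  if (min_separation > 0) {
    keep <- suppress_cpp(um, min_separation)
    zyx <- zyx[keep, , drop = FALSE]
    um <- um[keep, , drop = FALSE]
    resp <- resp[keep]
  }
  tibble(z = zyx[, 1], y = zyx[, 2], x = zyx[, 3],
         z_um = um[, 1], y_um = um[, 2], x_um = um[, 3], response = resp)
}

#' Automatic response threshold from candidate statistics
#'
#' Statistics-based thresholding of candidate filter responses, in log
#' space (which makes the threshold equivariant under intensity rescaling:
#' I -> a*I moves the threshold to a*t and keeps the retained set
#' identical).
#'
#' `method = "otsu"` is the exact two-class Otsu threshold: the split
#' maximising between-class variance over all cuts of the sorted log
#' values, found exhaustively; the threshold is the geometric midpoint of
#' the boundary pair. Plain Otsu assumes comparably sized classes, but in
#' a spot image the noise maxima outnumber true spots by orders of
#' magnitude and the single split then lands inside the noise mode.
#' `method = "valley"` (the default) therefore cuts at a density valley of
#' the log-response distribution: among the local minima of its kernel
#' density estimate the deepest valley wins, with near-ties resolved
#' toward the lowest threshold. On clean bimodal input this retains the
#' same set as Otsu; under heavy imbalance it finds the near-empty
#' density gap between the noise and signal modes, which plain Otsu
#' cannot.
#'
#' Degenerate unimodal input (no density valley, or all responses equal)
#' returns `min(responses)`, so all candidates are retained.
#'
#' @param responses Numeric vector of positive candidate responses (>= 1).
#' @param method `"valley"` (imbalance-robust, default) or `"otsu"`
#'   (single exhaustive split).
#' @return Threshold in response units; candidates with
#'   `response >= threshold` are retained.
#' @export
auto_threshold <- function(responses, method = c("valley", "otsu")) {
  method <- match.arg(method)
  if (length(responses) == 0) {
    abort("`responses` is empty: cannot compute an automatic threshold")
  }
  if (any(!is.finite(responses) | responses <= 0)) {
    abort("responses must be finite and > 0 (filter maxima)")
  }
  v <- sort(log(responses))
  n <- length(v)
  if (n == 1L || v[n] - v[1] < 1e-300) return(exp(v[1]))
  if (method == "otsu") {
    res <- otsu_split(v)
    if (is.null(res)) return(exp(v[1]))
    return(exp(res$threshold))
  }
  dens <- stats::density(v, n = 512L)
  y <- dens$y
  i <- 2:(length(y) - 1L)
  vall <- i[y[i] <= y[i - 1L] & y[i] <= y[i + 1L] & (y[i] < y[i - 1L] |
                                                       y[i] < y[i + 1L])]
  vall <- vall[dens$x[vall] > v[1] & dens$x[vall] < v[n]]
  # a valid cut keeps the noise bulk below (>= 40% of candidates) and a
  # non-trivial signal class above (>= max(2, 0.01% of n) candidates)
  if (length(vall) > 0L) {
    below <- findInterval(dens$x[vall], v)
    minmass <- max(2L, ceiling(1e-4 * n))
    vall <- vall[below >= 0.4 * n & (n - below) >= minmass]
  }
  if (length(vall) == 0L) return(exp(v[1])) # unimodal: retain everything
  tol <- 1e-3 * max(y)
  deep <- vall[y[vall] <= min(y[vall]) + tol]
  exp(dens$x[deep[1]])
}

# exact exhaustive between-class-variance split of sorted values;
# NULL when all values are equal
otsu_split <- function(v) {
  n <- length(v)
  if (n == 1L || v[n] - v[1] < 1e-300) return(NULL)
  cs <- cumsum(v)
  tot <- cs[n]
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  bcv <- (k / n) * ((n - k) / n) * (m1 - m2)^2
  # only cut between distinct values; first maximal cut wins (deterministic)
  valid <- v[k] < v[k + 1]
  bcv[!valid] <- -Inf
  if (all(!is.finite(bcv))) return(NULL)
  kbest <- which.max(bcv)
  list(threshold = (v[kbest] + v[kbest + 1]) / 2,
       mu_low = m1[kbest], mu_high = m2[kbest])
}

#' Detect diffraction-limited spots in a 3D channel
#'
#' The composition the assay's image analysis prescribes: Mexican-hat
#' filtering to subtract background, candidate maxima extraction,
#' statistics-based automatic thresholding (times the deterministic
#' refinement multiplier, or a manual threshold), sub-voxel localisation by
#' separable quadratic interpolation of the response peak (clipped to
#' +-0.5 voxel), and integration of raw intensity over a PSF-sized
#' background-corrected neighbourhood.
#'
#' @param channel 3D array or [image_stack()].
#' @param config A [detection_config()].
#' @param voxel_size Voxel size (z, y, x) in μm (taken from the stack when
#'   `channel` is an [image_stack()]).
#' @param channel_name When `channel` is a stack: which channel to detect
#'   in (name or role, e.g. `"exon"`).
#' @return A `spot_set` tibble: sub-voxel physical coordinates, peak
#'   `response`, `integrated_intensity` and `channel`; attributes carry the
#'   applied threshold, candidate count and a config hash.
#' @export
detect_spots <- function(channel, config = detection_config(),
                         voxel_size = NULL, channel_name = NULL) {
  if (inherits(channel, "image_stack")) {
    voxel_size <- channel$voxel_size
    arr <- get_channel(channel, channel_name %||% "exon")
  } else {
    arr <- channel
    if (is.null(voxel_size)) abort("`voxel_size` is required for plain arrays")
  }
  voxel_size <- check_voxel_size(voxel_size)
  if (config$min_separation < max(voxel_size)) {
    abort("`min_separation` must be at least one voxel")
  }
  sig_xy <- config$expected_spot_fwhm_xy / 2.355
  sig_z <- config$expected_spot_fwhm_z / 2.355
  filtered <- mexican_hat_filter(arr, sig_xy, sig_z, voxel_size)
  cand <- detect_candidates(filtered, voxel_size, config$min_separation)
  if (nrow(cand) == 0) {
    return(empty_spot_set(channel_name, NA_real_, config))
  }
  thr <- if (config$threshold_mode == "manual") {
    config$manual_threshold
  } else {
    auto_threshold(cand$response) * config$threshold_multiplier
  }
  kept <- filter(cand, .data$response >= thr)
  # a threshold that keeps a large share of tens of thousands of maxima
  # means the response distribution never separated signal from noise:
  # the channel has no detectable spots
  if (config$threshold_mode == "auto" && nrow(cand) > 1000 &&
      nrow(kept) > 0.2 * nrow(cand)) {
    warning("no signal/noise separation in candidate responses; ",
            "returning an empty spot set")
    return(empty_spot_set(channel_name, NA_real_, config))
  }
  if (nrow(kept) == 0) {
    return(empty_spot_set(channel_name, thr, config))
  }

  d <- dim(arr)
  off <- subvoxel_offsets(filtered, as.matrix(kept[, c("z", "y", "x")]), d)
  um <- index_to_um(as.matrix(kept[, c("z", "y", "x")]) + off, voxel_size)
  sig_vox <- c(sig_z, sig_xy, sig_xy) / voxel_size
  integ <- integrate_intensity(arr, as.matrix(kept[, c("z", "y", "x")]),
                               pmax(1L, ceiling(2 * sig_vox)))

  out <- tibble(
    spot_id = seq_len(nrow(kept)),
    z_um = um[, 1], y_um = um[, 2], x_um = um[, 3],
    response = kept$response,
    integrated_intensity = integ,
    channel = channel_name %||% "image"
  )
  class(out) <- c("spot_set", class(out))
  attr(out, "threshold") <- thr
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "config_hash") <- config_hash(config)
  attr(out, "voxel_size") <- voxel_size
  out
}

empty_spot_set <- function(channel_name, thr, config) {
  out <- tibble(spot_id = integer(0), z_um = numeric(0), y_um = numeric(0),
                x_um = numeric(0), response = numeric(0),
                integrated_intensity = numeric(0),
                channel = character(0))
  class(out) <- c("spot_set", class(out))
  attr(out, "threshold") <- thr
  attr(out, "n_candidates") <- 0L
  attr(out, "config_hash") <- config_hash(config)
  out
}

# separable 3-point quadratic peak interpolation, clipped to +-0.5 voxel
subvoxel_offsets <- function(filtered, zyx, d) {
  off <- matrix(0, nrow(zyx), 3)
  for (ax in 1:3) {
    ok <- zyx[, ax] > 1 & zyx[, ax] < d[ax]
    if (!any(ok)) next
    lo <- zyx[ok, , drop = FALSE]; lo[, ax] <- lo[, ax] - 1L
    hi <- zyx[ok, , drop = FALSE]; hi[, ax] <- hi[, ax] + 1L
    fm <- filtered[lo]
    f0 <- filtered[zyx[ok, , drop = FALSE]]
    fp <- filtered[hi]
    den <- fm - 2 * f0 + fp
    o <- ifelse(abs(den) > 1e-300, 0.5 * (fm - fp) / den, 0)
    off[ok, ax] <- pmin(pmax(o, -0.5), 0.5)
  }
  off
}

# background-corrected raw intensity over a box neighbourhood: the box
# shell mean estimates the local background
integrate_intensity <- function(arr, zyx, rad) {
  d <- dim(arr)
  n <- nrow(zyx)
  out <- numeric(n)
  for (i in seq_len(n)) {
    zr <- max(1L, zyx[i, 1] - rad[1]):min(d[1], zyx[i, 1] + rad[1])
    yr <- max(1L, zyx[i, 2] - rad[2]):min(d[2], zyx[i, 2] + rad[2])
    xr <- max(1L, zyx[i, 3] - rad[3]):min(d[3], zyx[i, 3] + rad[3])
    box <- arr[zr, yr, xr, drop = FALSE]
    interior <- box[-c(1, length(zr)), -c(1, length(yr)), -c(1, length(xr)),
                    drop = FALSE]
    shell_sum <- sum(box) - sum(interior)
    shell_n <- length(box) - length(interior)
    bg <- if (shell_n > 0) shell_sum / shell_n else 0
    out[i] <- sum(box) - bg * length(box)
  }
  out
}
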