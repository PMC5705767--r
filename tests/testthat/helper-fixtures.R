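# Shared fixtures: small geometries and bare fields that keep unit tests
# fast, plus brute-force oracles kept deliberately independent of the
# package's computational paths.

quick_geom <- function(n_cells = 1, field_shape = c(24L, 128L, 128L),
                       seed = 1, micronucleus_rate = 0, ...) {
  generate_cell_geometry(
    n_cells, field_shape = field_shape,
    micronucleus_rate = micronucleus_rate, seed = seed,
    nucleus_semiaxes_xy_um = c(2.5, 3.2),
    nucleus_semiaxes_z_um = c(1.2, 1.6),
    cell_radius_um = 2.5, ...
  )
}

# a geometry with no cells at all: a bare optical field for spot rendering
bare_geometry <- function(field_shape = c(32L, 128L, 128L),
                          voxel_size = c(0.2, 0.107, 0.107)) {
  d <- as.integer(field_shape)
  structure(list(
    nuclei = array(0L, d), micronuclei = array(0L, d),
    cells = array(0L, d),
    micronucleus_parents = tibble::tibble(micronucleus_id = integer(0),
                                          cell_id = integer(0)),
    centers = tibble::tibble(cell_id = integer(0)),
    voxel_size = voxel_size, field_shape = d
  ), class = "cell_geometry")
}

spot_table <- function(z, y, x, channel = "exon", unit_count = 1L) {
  n <- length(z)
  tibble::tibble(
    spot_id = seq_len(n), z_um = z, y_um = y, x_um = x,
    species = "mature_mRNA", channels = replicate(n, channel, simplify = FALSE),
    unit_count = as.integer(rep_len(unit_count, n)),
    compartment = "cytoplasm", cell_id = 1L, focus_id = NA_integer_
  )
}

random_spot_table <- function(n, field_shape, voxel_size, seed,
                              margin_um = 1) {
  ext <- field_shape * voxel_size
  withr::with_seed(seed, {
    spot_table(runif(n, margin_um, ext[1] - margin_um),
               runif(n, margin_um, ext[2] - margin_um),
               runif(n, margin_um, ext[3] - margin_um))
  })
}

noise_free_render <- function(geometry, truth, ...) {
  render_image(geometry, truth,
               render_config(background_level = 0, read_noise_sd = 0,
                             poisson_noise = FALSE, nuclear_level = 300,
                             protein_level = 0, ...))
}

# greedy matching of detections to truth for recall/precision bookkeeping
match_to_truth <- function(det, truth, radius_um = 0.3) {
  colocalize(det, truth, radius_um)$pairs
}

# ---- independent oracles ---------------------------------------------------

# dense correlation with a full 3D kernel, replicate padding; no shared
# code with the package's separable sweeps
dense_conv3 <- function(arr, ker) {
  d <- dim(arr)
  kd <- dim(ker)
  c0 <- (kd - 1) / 2
  out <- array(0, d)
  for (a in seq_len(kd[1])) {
    iz <- pmin(pmax(seq_len(d[1]) + a - 1 - c0[1], 1), d[1])
    for (b in seq_len(kd[2])) {
      iy <- pmin(pmax(seq_len(d[2]) + b - 1 - c0[2], 1), d[2])
      for (cc in seq_len(kd[3])) {
        ix <- pmin(pmax(seq_len(d[3]) + cc - 1 - c0[3], 1), d[3])
        w <- ker[a, b, cc]
        if (w != 0) out <- out + w * arr[iz, iy, ix]
      }
    }
  }
  out
}

# all-pairs greedy suppression, quadratic and explicit
brute_suppress <- function(um, resp, zyx, min_sep) {
  ord <- order(-resp, zyx[, 1], zyx[, 2], zyx[, 3])
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (sum((um[i, ] - um[j, ])^2) < min_sep^2) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# exhaustive between-class-variance threshold, direct statistics per split
naive_otsu <- function(responses) {
  v <- sort(log(responses))
  n <- length(v)
  if (length(unique(v)) == 1L) return(exp(v[1]))
  best <- -Inf
  thr <- v[1]
  for (k in seq_len(n - 1)) {
    if (v[k] == v[k + 1]) next
    lo <- v[seq_len(k)]
    hi <- v[(k + 1):n]
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best) {
      best <- bcv
      thr <- (v[k] + v[k + 1]) / 2
    }
  }
  exp(thr)
}

# exhaustive matching over all injective assignments (tiny sets only):
# maximises match count, then minimises total distance
exhaustive_match <- function(a, b, cutoff) {
  pa <- cbind(a$z_um, a$y_um, a$x_um)
  pb <- cbind(b$z_um, b$y_um, b$x_um)
  na <- nrow(pa)
  nb <- nrow(pb)
  dmat <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) -
                 2 * tcrossprod(pa, pb))
  best <- list(count = -1, weight = Inf)
  recurse <- function(i, used_b, count, weight) {
    if (i > na) {
      if (count > best$count ||
          (count == best$count && weight < best$weight)) {
        best <<- list(count = count, weight = weight)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, count, weight) # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && dmat[i, j] <= cutoff) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L, weight + dmat[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nb), 0L, 0)
  best
}

pearson_formula <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# per-spot compartment lookup written independently of assign_compartments
lookup_compartment <- function(truth, geometry) {
  vs <- geometry$voxel_size
  out <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    v <- floor(c(truth$z_um[i], truth$y_um[i], truth$x_um[i]) / vs) + 1
    v <- pmin(pmax(v, 1), geometry$field_shape)
    if (geometry$micronuclei[v[1], v[2], v[3]] > 0) {
      out[i] <- "micronucleus"
    } else if (geometry$nuclei[v[1], v[2], v[3]] > 0) {
      out[i] <- "nucleus"
    } else if (geometry$cells[v[1], v[2], v[3]] > 0) {
      out[i] <- "cytoplasm"
    } else {
      out[i] <- "outside"
    }
  }
  out
}
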