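# Internal helpers shared across modules.

# Physical coordinates use the voxel-centre convention: the centre of the
# voxel with 0-based index i lies at (i + 0.5) * voxel_size. Axis order is
# always (z, y, x), matching the storage order dim(arr) = c(nz, ny, nx).

voxel_centers <- function(idx0, voxel_size) {
  (idx0 + 0.5) * voxel_size
}

# 1-based array index (z, y, x) -> physical matrix (n x 3)
index_to_um <- function(ind, voxel_size) {
  sweep(ind - 0.5, 2, voxel_size, `*`)
}

# physical matrix -> 1-based voxel index; no clamping
um_to_index <- function(um, voxel_size) {
  floor(sweep(um, 2, voxel_size, `/`)) + 1L
}

linear_to_zyx <- function(lin1, dim) {
  i0 <- lin1 - 1L
  z <- i0 %% dim[1]
  y <- (i0 %/% dim[1]) %% dim[2]
  x <- i0 %/% (dim[1] * dim[2])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

zyx_to_linear <- function(zyx, dim) {
  (zyx[, 1] - 1L) + dim[1] * ((zyx[, 2] - 1L) + dim[2] * (zyx[, 3] - 1L)) + 1L
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive numbers (z, y, x) in μm.")
  }
  as.numeric(voxel_size)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-stream seeds derived from a master seed. Arithmetic in
# doubles (exact below 2^53), reduced into the 32-bit seed range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483562)
}

euclid2 <- function(a, b) {
  # squared distances between rows of a (n x d) and rows of b (m x d)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

config_hash <- function(x) {
  rlang::hash(x)
}
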