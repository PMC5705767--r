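# Separable Gaussian kernels and 3D convolution sweeps.

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  radius <- radius %||% max(1L, ceiling(4 * sigma_vox))
  x <- seq(-radius, radius)
  k <- dnorm(x, sd = sigma_vox)
  k / sum(k)
}

# Sampled second derivative of a Gaussian, recentred to sum exactly to zero
# so that the assembled Laplacian-of-Gaussian kernel annihilates constants.
gaussian_d2_kernel_1d <- function(sigma_vox, radius = NULL) {
  radius <- radius %||% max(1L, ceiling(4 * sigma_vox))
  x <- seq(-radius, radius)
  g <- dnorm(x, sd = sigma_vox)
  k <- g * ((x / sigma_vox^2)^2 - 1 / sigma_vox^2)
  k - mean(k)
}

conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  out <- conv_axis_cpp(as.numeric(arr), as.integer(d), as.numeric(kernel),
                       as.integer(axis))
  array(out, dim = d)
}

conv_separable <- function(arr, kz, ky, kx) {
  conv_axis(conv_axis(conv_axis(arr, kz, 1L), ky, 2L), kx, 3L)
}

gaussian_smooth <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      arr <- conv_axis(arr, gaussian_kernel_1d(sigma_vox[ax]), ax)
    }
  }
  arr
}
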