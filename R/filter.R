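#' Mexican-hat (Laplacian-of-Gaussian) filter for 3D blob enhancement
#'
#' Computes the negated, scale-normalised Laplacian of Gaussian of a 3D
#' channel, the classic band-pass that subtracts locally smooth background
#' and responds maximally to blobs whose size matches the kernel scale.
#' Anisotropy is handled by per-axis kernel scales in voxel units derived
#' from the physical scales. The second-derivative kernels are recentred to
#' sum exactly to zero, so a constant image maps to exactly zero and the
#' filter is exactly linear: `filter(a*I + b) = a * filter(I)`.
#'
#' @param channel 3D numeric array (z, y, x) or [image_stack()] channel.
#' @param scale_xy,scale_z Gaussian sigma in μm (in-plane and axial).
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @return Filtered 3D array of the same dimensions.
#' @export
mexican_hat_filter <- function(channel, scale_xy, scale_z, voxel_size) {
  arr <- if (is.array(channel)) channel else get_channel(channel, "image")
  voxel_size <- check_voxel_size(voxel_size)
  check_scalar_number(scale_xy, "scale_xy", lower = 1e-9)
  check_scalar_number(scale_z, "scale_z", lower = 1e-9)
  sig_um <- c(scale_z, scale_xy, scale_xy)
  # a blob whose FWHM (2.355 sigma) is below one voxel cannot be
  # represented on the grid
  if (any(2.355 * sig_um < voxel_size)) {
    abort(paste0("filter scale below one voxel along some axis; ",
                 "resample the image or increase the scale"))
  }
  sig <- sig_um / voxel_size
  g <- lapply(sig, gaussian_kernel_1d)
  g2 <- lapply(sig, gaussian_d2_kernel_1d)
  # scale-normalised LoG = -sum_i sigma_i^2 d2/dxi2 (G * I), separable per term
  resp <- -sig[1]^2 * conv_separable(arr, g2[[1]], g[[2]], g[[3]])
  resp <- resp - sig[2]^2 * conv_separable(arr, g[[1]], g2[[2]], g[[3]])
  resp <- resp - sig[3]^2 * conv_separable(arr, g[[1]], g[[2]], g2[[3]])
  resp
}

# dense 3D kernel equivalent of mexican_hat_filter (used by callers that
# need the explicit kernel, e.g. for validation)
mexican_hat_kernel <- function(scale_xy, scale_z, voxel_size) {
  sig <- c(scale_z, scale_xy, scale_xy) / voxel_size
  g <- lapply(sig, gaussian_kernel_1d)
  g2 <- lapply(sig, gaussian_d2_kernel_1d)
  k <- -sig[1]^2 * outer(outer(g2[[1]], g[[2]]), g[[3]]) -
    sig[2]^2 * outer(outer(g[[1]], g2[[2]]), g[[3]]) -
    sig[3]^2 * outer(outer(g[[1]], g[[2]]), g2[[3]])
  k
}
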