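#' Rendering configuration for the forward imaging model
#'
#' The point-spread function is an anisotropic Gaussian: the in-plane sigma
#' default 0.106 μm corresponds to the ~0.25 μm FWHM of a diffraction-
#' limited particle at 60x/1.42 NA (FWHM = 2.355 sigma), and the axial
#' sigma reflects widefield axial elongation. Intensities are in photons;
#' shot noise is Poisson on signal + background with additive Gaussian read
#' noise. An optional smooth low-frequency autofluorescence field emulates
#' FFPE background.
#'
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas in μm.
#' @param spot_amplitude Integrated photons of a unit spot.
#' @param background_level Uniform background photons per voxel.
#' @param read_noise_sd Gaussian read noise standard deviation.
#' @param nuclear_level Mean nuclear-stain photons per voxel.
#' @param protein_level Mean protein-channel photons per voxel for a cell of
#'   average expression.
#' @param autofluorescence_amplitude Amplitude of the smooth background
#'   field (0 disables; enable for FFPE-like images).
#' @param autofluorescence_scale_um Correlation length of that field.
#' @param poisson_noise Logical; disable for noise-free rendering.
#' @param seed Integer seed; with `poisson_noise = FALSE`,
#'   `read_noise_sd = 0` and `autofluorescence_amplitude = 0` the render is
#'   deterministic regardless.
#' @return A `render_config` list.
#' @export
render_config <- function(psf_sigma_xy = 0.106,
                          psf_sigma_z = 0.30,
                          spot_amplitude = 1200,
                          background_level = 100,
                          read_noise_sd = 2,
                          nuclear_level = 300,
                          protein_level = 150,
                          autofluorescence_amplitude = 0,
                          autofluorescence_scale_um = 3,
                          poisson_noise = TRUE,
                          seed = 1L) {
  for (nm in c("psf_sigma_xy", "psf_sigma_z")) {
    check_scalar_number(get(nm), nm, lower = 1e-6)
  }
  check_scalar_number(spot_amplitude, "spot_amplitude", lower = 0)
  check_scalar_number(background_level, "background_level", lower = 0)
  check_scalar_number(read_noise_sd, "read_noise_sd", lower = 0)
  structure(list(
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    spot_amplitude = spot_amplitude, background_level = background_level,
    read_noise_sd = read_noise_sd, nuclear_level = nuclear_level,
    protein_level = protein_level,
    autofluorescence_amplitude = autofluorescence_amplitude,
    autofluorescence_scale_um = autofluorescence_scale_um,
    poisson_noise = poisson_noise, seed = seed
  ), class = "render_config")
}

#' Spot amplitude needed for a target peak signal-to-noise ratio
#'
#' SNR is defined as the peak voxel intensity of a rendered unit spot over
#' the background noise standard deviation sqrt(background + read_noise^2).
#'
#' @param snr Target SNR.
#' @param config A [render_config()].
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @return Amplitude in integrated photons.
#' @export
amplitude_for_snr <- function(snr, config, voxel_size) {
  sig_vox <- c(config$psf_sigma_z, config$psf_sigma_xy, config$psf_sigma_xy) /
    voxel_size
  peak_frac <- prod(vapply(sig_vox, function(s) max(gaussian_kernel_1d(s)), 0))
  noise_sd <- sqrt(config$background_level + config$read_noise_sd^2)
  snr * noise_sd / peak_frac
}

#' Render a multi-channel image stack from geometry and transcript truth
#'
#' Each spot contributes an anisotropic Gaussian with integrated intensity
#' `spot_amplitude * unit_count` (the local discrete kernel is normalised,
#' so the noise-free voxel sum equals the integrated intensity exactly).
#' The nuclear channel is rendered from the nucleus + micronucleus masks,
#' and the protein channel is cell-wide intensity proportional to a
#' per-cell expression scalar (the cell's total transcript count relative
#' to the field mean), emulating protein levels tracking expression.
#'
#' @param geometry A [generate_cell_geometry()] result.
#' @param truth A [generate_transcripts()] table (may be empty).
#' @param config A [render_config()].
#' @param channels Channels to render; default: nuclear plus every RNA/DNA
#'   channel present in `truth`, plus protein when `protein_level > 0`.
#' @return An [image_stack()] with channel roles set.
#' @export
render_image <- function(geometry, truth, config = render_config(),
                         channels = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (is.null(truth)) {
    truth <- tibble(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                    species = character(0), channels = list(),
                    unit_count = integer(0), cell_id = integer(0))
  }
  d <- geometry$field_shape
  vs <- geometry$voxel_size
  ext <- d * vs
  rna_channels <- unique(unlist(truth$channels))
  channels <- channels %||% c("nuclear", rna_channels,
                              if (config$protein_level > 0) "protein")
  channels <- unique(channels)

  if (nrow(truth) > 0) {
    bad <- which(truth$z_um < 0 | truth$z_um > ext[1] |
                   truth$y_um < 0 | truth$y_um > ext[2] |
                   truth$x_um < 0 | truth$x_um > ext[3])
    if (length(bad) > 0) {
      abort(sprintf("spot(s) out of field bounds: first offending index %d",
                    bad[1]))
    }
  }

  sig_vox <- c(config$psf_sigma_z, config$psf_sigma_xy, config$psf_sigma_xy) / vs
  rad <- pmax(1, ceiling(4 * sig_vox))

  render_spots <- function(sel) {
    img <- array(0, dim = d)
    if (!length(sel)) return(img)
    for (i in sel) {
      p <- c(truth$z_um[i], truth$y_um[i], truth$x_um[i]) / vs # voxel units
      c0 <- floor(p - 0.5) + 1 # voxel whose centre is closest from below
      ks <- vector("list", 3)
      rngs <- vector("list", 3)
      for (ax in 1:3) {
        idx <- (c0[ax] - rad[ax]):(c0[ax] + rad[ax])
        keep <- idx >= 1 & idx <= d[ax]
        idx <- idx[keep]
        g <- dnorm(idx - 0.5 - p[ax], sd = sig_vox[ax])
        ks[[ax]] <- g
        rngs[[ax]] <- idx
      }
      ker <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
      s <- sum(ker)
      if (s <= 0) next
      amp <- config$spot_amplitude * truth$unit_count[i]
      img[rngs[[1]], rngs[[2]], rngs[[3]]] <-
        img[rngs[[1]], rngs[[2]], rngs[[3]]] + ker * (amp / s)
    }
    img
  }

  with_seed_(config$seed, {
    out <- list()
    for (ch in channels) {
      if (ch == "nuclear") {
        img <- (geometry$nuclei > 0L | geometry$micronuclei > 0L) *
          config$nuclear_level
        img <- gaussian_smooth(array(as.numeric(img), d), sig_vox)
      } else if (ch == "protein") {
        expr <- rep(1, nrow(geometry$centers))
        if (nrow(truth) > 0) {
          cnt <- truth |>
            filter(.data$species != "dna_locus") |>
            group_by(.data$cell_id) |>
            summarise(n = sum(.data$unit_count))
          tot <- rep(0, nrow(geometry$centers))
          tot[cnt$cell_id] <- cnt$n
          if (mean(tot) > 0) expr <- tot / mean(tot)
        }
        img <- array(0, d)
        sel <- geometry$cells > 0L
        img[sel] <- config$protein_level * expr[geometry$cells[sel]]
        img <- gaussian_smooth(img, sig_vox)
      } else {
        sel <- which(vapply(truth$channels, function(cs) ch %in% cs, TRUE))
        img <- render_spots(sel)
      }
      if (config$autofluorescence_amplitude > 0) {
        img <- img + autofluorescence_field(d, vs,
                                            config$autofluorescence_amplitude,
                                            config$autofluorescence_scale_um)
      }
      img <- img + config$background_level
      if (config$poisson_noise) {
        img <- array(as.numeric(rpois(length(img), img)), d)
      }
      if (config$read_noise_sd > 0) {
        img <- img + array(rnorm(length(img), 0, config$read_noise_sd), d)
      }
      out[[ch]] <- img
    }
    roles <- intersect(c("nuclear", "intron", "exon", "protein", "dna"),
                       names(out))
    image_stack(out, vs, channel_roles = setNames(roles, roles))
  })
}

# smooth, strictly non-negative low-frequency random field
autofluorescence_field <- function(d, voxel_size, amplitude, scale_um) {
  raw <- array(rnorm(prod(d)), d)
  sm <- gaussian_smooth(raw, scale_um / voxel_size)
  sm <- (sm - min(sm)) / max(max(sm) - min(sm), 1e-12)
  amplitude * sm
}
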