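#' Multi-channel 3D image stack
#'
#' An `image_stack` bundles one or more 3D voxel grids (axis order z, y, x)
#' with the physical voxel size in μm and a channel-role map. It is the
#' container every pipeline stage consumes and produces.
#'
#' @param channels Named list of 3D numeric arrays, all with identical
#'   dimensions. Names identify channels (e.g. `"nuclear"`, `"exon"`).
#' @param voxel_size Numeric length-3, voxel edge length in μm as (z, y, x).
#' @param channel_roles Optional named character vector mapping roles
#'   (`nuclear`, `intron`, `exon`, `protein`, `dna`) to channel names.
#'   Defaults to matching names.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size, channel_roles = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a non-empty named list of 3D arrays.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    abort("every channel must be a 3D array with dim (z, y, x)")
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    abort("all channels must share the same dimensions")
  }
  voxel_size <- check_voxel_size(voxel_size)
  roles <- channel_roles %||% setNames(names(channels), names(channels))
  missing <- setdiff(unname(roles), names(channels))
  if (length(missing) > 0) {
    abort(paste0("channel roles refer to absent channels: ",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(channels = channels, voxel_size = voxel_size,
         channel_roles = roles),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d channel(s), %d x %d x %d voxels (z y x)\n",
              length(x$channels), d[1], d[2], d[3]))
  cat(sprintf("  voxel size: %.3f x %.3f x %.3f um\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

get_channel <- function(stack, channel) {
  if (inherits(stack, "image_stack")) {
    # accept either a channel name or a role
    if (channel %in% names(stack$channels)) return(stack$channels[[channel]])
    if (channel %in% names(stack$channel_roles)) {
      return(stack$channels[[stack$channel_roles[[channel]]]])
    }
    abort(sprintf("channel '%s' not found in image stack", channel))
  }
  if (is.array(stack) && length(dim(stack)) == 3L) return(stack)
  abort("expected an `image_stack` or a 3D array")
}

physical_extent <- function(stack) {
  dim(stack$channels[[1]]) * stack$voxel_size
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z-planes of channel 1, then channel
#' 2, ...) as 32-bit float TIFF. Voxel size, axis order and channel roles go
#' into `<path>.json`, which [read_image_stack()] reads back, so stacks
#' round-trip exactly.
#'
#' @param stack An [image_stack()].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack")
  # the TIFF writer stores samples in [0, 1]; each channel is rescaled by
  # its own factor, recorded in the sidecar so reads restore intensities
  scales <- vapply(stack$channels, function(a) max(max(a), 1e-12), 0)
  pages <- list()
  for (ci in seq_along(stack$channels)) {
    a <- pmax(stack$channels[[ci]], 0) / scales[ci]
    for (z in seq_len(dim(a)[1])) {
      pages[[length(pages) + 1L]] <- a[z, , ]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    axes = "CZYX",
    shape_zyx = as.integer(dim(stack$channels[[1]])),
    voxel_size_um = as.numeric(stack$voxel_size),
    channels = names(stack$channels),
    channel_scales = as.numeric(scales),
    channel_roles = as.list(stack$channel_roles)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()] or a plain TIFF
#'
#' For plain TIFFs without a sidecar the voxel size must be supplied; a
#' single-page TIFF is accepted as a one-slice (z = 1) stack, and all pages
#' are treated as one channel unless the sidecar says otherwise. When both a
#' sidecar and `voxel_size` are given the explicit argument wins.
#'
#' @param path TIFF file path.
#' @param voxel_size Optional voxel size override (z, y, x) in μm.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      abort(sprintf("failed to read TIFF '%s': %s", path,
                                    conditionMessage(e)))
                    })
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  vs <- voxel_size %||% unlist(meta$voxel_size_um)
  if (is.null(vs)) {
    abort(paste0("no voxel size: '", path,
                 "' has no metadata sidecar and no `voxel_size` was given"))
  }
  vs <- check_voxel_size(vs)
  if (!is.null(meta)) {
    shape <- as.integer(unlist(meta$shape_zyx))
    chans <- as.character(unlist(meta$channels))
    scales <- unlist(meta$channel_scales) %||% rep(1, length(chans))
    nz <- shape[1]
    out <- list()
    for (i in seq_along(chans)) {
      a <- array(0, dim = shape)
      for (z in seq_len(nz)) a[z, , ] <- pages[[(i - 1L) * nz + z]]
      out[[chans[i]]] <- a * scales[i]
    }
    roles <- unlist(meta$channel_roles)
    return(image_stack(out, vs, channel_roles = roles))
  }
  nz <- length(pages)
  a <- array(0, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nz)) a[z, , ] <- pages[[z]]
  image_stack(list(image = a), vs)
}
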