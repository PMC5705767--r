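#' Segment nuclei from a 3D nuclear-stain channel
#'
#' A classical deterministic pipeline standing in for interactive
#' model-driven segmentation: Gaussian smoothing, global Otsu threshold,
#' 3D hole filling, optional splitting of touching nuclei by
#' distance-transform seeded watershed, and removal of components below a
#' volume floor. External masks (e.g. curated in another tool) can be used
#' instead anywhere a label volume is accepted.
#'
#' @param channel 3D array or [image_stack()] (role `"nuclear"`).
#' @param voxel_size Voxel size (z, y, x) in μm (from the stack if given).
#' @param min_volume_um3 Minimum component volume retained (μm^3).
#' @param split Split touching components by watershed on the Euclidean
#'   distance transform.
#' @param smooth_sigma_um Pre-smoothing sigma (μm).
#' @param split_min_distance_um Minimum separation between watershed seeds
#'   (μm); roughly the smallest expected nucleus radius.
#' @return Integer label volume (dense labels 1..N in scan order) with
#'   `voxel_size` attribute. Zero labels with a warning when no foreground
#'   is found.
#' @export
segment_nuclei <- function(channel, voxel_size = NULL, min_volume_um3 = 20,
                           split = TRUE, smooth_sigma_um = 0.5,
                           split_min_distance_um = 4) {
  if (inherits(channel, "image_stack")) {
    voxel_size <- channel$voxel_size
    arr <- get_channel(channel, "nuclear")
  } else {
    arr <- channel
    if (is.null(voxel_size)) abort("`voxel_size` is required for plain arrays")
  }
  voxel_size <- check_voxel_size(voxel_size)
  d <- dim(arr)
  sm <- gaussian_smooth(arr, smooth_sigma_um / voxel_size)
  thr <- otsu_image(sm)
  fg <- sm > thr
  if (!any(fg)) {
    warning("no nuclear foreground found; returning zero labels")
    out <- array(0L, d)
    attr(out, "voxel_size") <- voxel_size
    return(out)
  }
  fg <- fill_holes_3d(fg)

  if (split) {
    edt2 <- edt_feature_cpp(as.numeric(ifelse(fg, Inf, 0)),
                            array(0L, d), as.integer(d),
                            as.numeric(voxel_size))$dist2
    edt <- sqrt(array(edt2, d))
    edt_sm <- gaussian_smooth(edt, 0.4 / voxel_size)
    edt_sm[!fg] <- 0
    seeds_tbl <- detect_candidates(edt_sm, voxel_size,
                                   min_separation = split_min_distance_um)
    seeds <- array(0L, d)
    if (nrow(seeds_tbl) > 0) {
      seeds[zyx_to_linear(as.matrix(seeds_tbl[, c("z", "y", "x")]), d)] <-
        seq_len(nrow(seeds_tbl))
    }
    # guarantee every connected component owns at least one seed
    comp <- array(label_components_cpp(as.integer(fg), as.integer(d), 6L), d)
    seeded <- unique(comp[seeds > 0L])
    for (cid in setdiff(seq_len(max(comp)), c(0L, seeded))) {
      sel <- which(comp == cid)
      seeds[sel[which.max(edt_sm[sel])]] <- max(seeds) + 1L
    }
    labels <- array(
      watershed_cpp(as.numeric(-edt_sm), as.integer(seeds),
                    as.integer(fg), as.integer(d)), d)
  } else {
    labels <- array(label_components_cpp(as.integer(fg), as.integer(d), 6L), d)
  }

  labels <- drop_small_components(labels, voxel_size, min_volume_um3)
  attr(labels, "voxel_size") <- voxel_size
  labels
}

# 256-bin histogram Otsu for image intensities
otsu_image <- function(arr, n_bins = 256L) {
  r <- range(arr)
  if (r[2] - r[1] <= 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(arr, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]
  tot <- m[n_bins]
  k <- seq_len(n_bins - 1L)
  w1 <- w[k]; w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (m[k][valid] / w1[valid] - (tot - m[k][valid]) / w2[valid])^2 *
    w1[valid] * w2[valid]
  br[which.max(bcv) + 1L]
}

# fill background cavities that do not touch the volume border (6-conn)
fill_holes_3d <- function(fg) {
  d <- dim(fg)
  bg_lab <- array(label_components_cpp(as.integer(!fg), as.integer(d), 6L), d)
  border <- unique(c(bg_lab[c(1, d[1]), , ], bg_lab[, c(1, d[2]), ],
                     bg_lab[, , c(1, d[3])]))
  border <- setdiff(border, 0L)
  fg | !(bg_lab %in% border | bg_lab == 0L)
}

drop_small_components <- function(labels, voxel_size, min_volume_um3) {
  nmax <- max(labels)
  if (nmax == 0L) return(labels)
  vols <- label_volumes(labels, voxel_size, nmax)
  keep <- vols$label[vols$volume_um3 >= min_volume_um3 & vols$n_voxels > 0]
  relabel_dense(labels, keep)
}

# renumber `keep` labels to 1..K by order of first appearance in the array
relabel_dense <- function(labels, keep) {
  d <- dim(labels)
  map <- integer(max(max(labels), 1L))
  sel <- which(labels > 0L)
  lab <- labels[sel]
  first <- tapply(sel, lab, min)
  keep <- keep[order(first[as.character(keep)])]
  map[keep] <- seq_along(keep)
  out <- array(0L, d)
  out[sel] <- map[lab]
  attributes(out) <- attributes(labels)
  dim(out) <- d
  out
}

#' Separate micronuclei from main nuclei
#'
#' A labelled component is reclassified as a micronucleus when its volume
#' is strictly below `max_fraction` of the median main-nucleus volume and
#' its boundary lies within `max_distance_um` of a main nucleus, which
#' becomes its parent. With a single component no micronuclei are
#' possible.
#'
#' @param nucleus_labels Integer label volume from [segment_nuclei()].
#' @param voxel_size Voxel size (z, y, x) in μm; defaults to the attribute
#'   on `nucleus_labels`.
#' @param max_fraction Volume fraction defining "small" (strict `<`).
#' @param max_distance_um Maximum boundary distance to the parent (μm).
#' @return List with `nuclei` and `micronuclei` label volumes (both dense)
#'   and a `parents` tibble (`micronucleus_id`, `nucleus_id`).
#' @export
classify_micronuclei <- function(nucleus_labels, voxel_size = NULL,
                                 max_fraction = 0.10, max_distance_um = 5.0) {
  voxel_size <- check_voxel_size(voxel_size %||%
                                   attr(nucleus_labels, "voxel_size"))
  d <- dim(nucleus_labels)
  nmax <- max(nucleus_labels)
  empty <- list(nuclei = nucleus_labels,
                micronuclei = structure(array(0L, d),
                                        voxel_size = voxel_size),
                parents = tibble(micronucleus_id = integer(0),
                                 nucleus_id = integer(0)))
  if (nmax <= 1L) return(empty)
  vols <- label_volumes(nucleus_labels, voxel_size, nmax)
  vols <- vols[vols$n_voxels > 0, ]

  # accrete the main-nucleus set from the largest component down: a
  # component joins when its volume is at least max_fraction of the
  # current main median, otherwise it is a micronucleus candidate
  ord <- vols[order(-vols$volume_um3, vols$label), ]
  main <- ord$label[1]
  main_vols <- ord$volume_um3[1]
  small <- integer(0)
  for (i in seq_len(nrow(ord))[-1]) {
    if (ord$volume_um3[i] < max_fraction * median(main_vols)) {
      small <- c(small, ord$label[i])
    } else {
      main <- c(main, ord$label[i])
      main_vols <- c(main_vols, ord$volume_um3[i])
    }
  }
  if (length(small) == 0L) return(empty)

  # boundary distance from each small component to the nearest main nucleus
  main_mask <- array(0L, d)
  sel_main <- which(nucleus_labels %in% main)
  main_mask[sel_main] <- nucleus_labels[sel_main]
  ft <- edt_feature_cpp(as.numeric(ifelse(main_mask > 0L, 0, Inf)),
                        main_mask, as.integer(d), as.numeric(voxel_size))
  dist_um <- sqrt(ft$dist2)
  near_lab <- ft$label

  micro_ids <- integer(0)
  parents <- integer(0)
  for (sid in small) {
    sel <- which(nucleus_labels == sid)
    dmin <- min(dist_um[sel])
    if (dmin <= max_distance_um) {
      micro_ids <- c(micro_ids, sid)
      parents <- c(parents, near_lab[sel[which.min(dist_um[sel])]])
    }
  }
  if (length(micro_ids) == 0L) return(empty)

  nuc2 <- nucleus_labels
  nuc2[nuc2 %in% micro_ids] <- 0L
  nuc2 <- relabel_dense(nuc2, setdiff(vols$label, micro_ids))
  micro <- array(0L, d)
  for (i in seq_along(micro_ids)) {
    micro[nucleus_labels == micro_ids[i]] <- i
  }
  # parent ids under the new dense numbering
  old_keep <- setdiff(vols$label, micro_ids)
  sel <- which(nucleus_labels > 0L & nuc2 > 0L)
  remap <- integer(nmax)
  remap[nucleus_labels[sel]] <- nuc2[sel]
  attr(nuc2, "voxel_size") <- voxel_size
  attr(micro, "voxel_size") <- voxel_size
  list(nuclei = nuc2, micronuclei = micro,
       parents = tibble(micronucleus_id = seq_along(micro_ids),
                        nucleus_id = remap[parents]))
}

#' Derive cell regions from nuclei
#'
#' With an intensity channel (protein or membrane counterstain): marker-
#' controlled watershed on the inverted intensity, restricted to the
#' channel's Otsu foreground (nuclei always included). Without a channel:
#' distance-limited Voronoi dilation of the nuclei by `max_radius_um`.
#' Every nucleus maps to the cell with the same label.
#'
#' @param nucleus_labels Integer label volume.
#' @param channel Optional 3D intensity array or [image_stack()].
#' @param max_radius_um Maximum cytoplasmic reach beyond the nucleus (μm).
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @return Integer cell label volume.
#' @export
segment_cells <- function(nucleus_labels, channel = NULL, max_radius_um = 5,
                          voxel_size = NULL) {
  voxel_size <- check_voxel_size(voxel_size %||%
                                   attr(nucleus_labels, "voxel_size"))
  d <- dim(nucleus_labels)
  if (is.null(channel)) {
    out <- voronoi_dilate(nucleus_labels, voxel_size, max_radius_um)
  } else {
    arr <- if (inherits(channel, "image_stack")) {
      get_channel(channel, "protein")
    } else channel
    stopifnot(all(dim(arr) == d))
    fg <- arr > otsu_image(arr) | nucleus_labels > 0L
    out <- array(watershed_cpp(as.numeric(-arr), as.integer(nucleus_labels),
                               as.integer(fg), as.integer(d)), d)
  }
  attr(out, "voxel_size") <- voxel_size
  out
}

#' Bundle nucleus, micronucleus and cell labels
#'
#' @param nuclei,micronuclei,cells Integer label volumes (micronuclei and
#'   cells optional).
#' @param parents Tibble mapping micronuclei to parent nuclei.
#' @param voxel_size Voxel size (z, y, x) in μm.
#' @return A `segmentation_labels` object with the same component names as
#'   a `cell_geometry`, so truth geometry and recovered segmentation are
#'   interchangeable downstream.
#' @export
segmentation_labels <- function(nuclei, micronuclei = NULL, cells = NULL,
                                parents = NULL, voxel_size = NULL) {
  voxel_size <- check_voxel_size(voxel_size %||% attr(nuclei, "voxel_size"))
  d <- dim(nuclei)
  micronuclei <- micronuclei %||% array(0L, d)
  if (is.null(cells)) {
    cells <- voronoi_dilate(nuclei, voxel_size, 5)
  }
  parents <- parents %||% tibble(micronucleus_id = integer(0),
                                 nucleus_id = integer(0))
  structure(list(
    nuclei = nuclei, micronuclei = micronuclei, cells = cells,
    micronucleus_parents = tibble(
      micronucleus_id = parents$micronucleus_id,
      cell_id = parents[[setdiff(names(parents), "micronucleus_id")[1]]]
    ),
    voxel_size = voxel_size, field_shape = d
  ), class = c("segmentation_labels", "cell_geometry"))
}

#' Mean intensity per segmented region
#'
#' @param channel 3D intensity array or [image_stack()] with the channel
#'   named by `channel_name`.
#' @param labels Integer label volume, or a `cell_geometry`/
#'   `segmentation_labels` object combined with `per`.
#' @param per For geometry objects: `"cell"`, `"nucleus"` or
#'   `"cytoplasm"`.
#' @param channel_name Channel to measure when a stack is given.
#' @return Tibble (`region_id`, `mean_intensity`, `n_voxels`).
#' @export
measure_cell_intensity <- function(channel, labels, per = c("cell", "nucleus",
                                                            "cytoplasm"),
                                   channel_name = "protein") {
  per <- match.arg(per)
  arr <- if (inherits(channel, "image_stack")) {
    get_channel(channel, channel_name)
  } else channel
  lab <- if (inherits(labels, "cell_geometry")) {
    switch(per, cell = labels$cells, nucleus = labels$nuclei,
           cytoplasm = cytoplasm_labels(labels))
  } else labels
  if (!all(dim(arr) == dim(lab))) {
    abort("intensity channel and labels have different shapes")
  }
  sel <- which(lab > 0L)
  if (length(sel) == 0L) abort("no labelled region to measure")
  ids <- lab[sel]
  s <- rowsum(arr[sel], ids)
  cnt <- as.numeric(table(ids))
  present <- sort(unique(ids))
  nmax <- max(present)
  missing <- setdiff(seq_len(nmax), present)
  if (length(missing) > 0) {
    abort(sprintf("region id(s) with no voxels: %s",
                  paste(missing, collapse = ", ")))
  }
  tibble(region_id = present, mean_intensity = as.numeric(s[, 1] / cnt),
         n_voxels = as.integer(cnt))
}
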