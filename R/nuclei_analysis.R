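# Otsu threshold of a numeric vector (histogram criterion via EBImage),
# returning the threshold on the original scale; NA when degenerate
otsu_threshold <- function(values, levels = 256) {
  r <- range(values, finite = TRUE)
  if (!is.finite(diff(r)) || diff(r) == 0) return(NA_real_)
  img <- EBImage::Image(matrix((values - r[1]) / diff(r), nrow = 1))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  r[1] + th * diff(r)
}

#' Segment nuclei in 3D from the DNA stain
#'
#' Global Otsu intensity threshold, per-plane hole filling, 26-connected
#' component labelling and a volume filter. Integrated DNA intensity
#' (background-subtracted, for later G1 gating) is reported per nucleus.
#'
#' @param dapi_stack A `voxel_stack` of the DNA stain channel.
#' @param min_volume_um3 Minimal nucleus volume in cubic microns.
#' @return A `nucleus_masks` object: list with `labels` (integer array),
#'   `table` (nucleus_id, volume_um3, integrated_intensity,
#'   cell_cycle_label = "unassigned") and `voxel_size_nm`. Empty image gives
#'   an empty table.
#' @export
segment_nuclei <- function(dapi_stack, min_volume_um3 = 20) {
  a <- dapi_stack$data
  vs <- dapi_stack$voxel_size_nm
  voxel_um3 <- prod(vs) / 1e9
  d <- dim(a)
  empty <- structure(list(
    labels = array(0L, d),
    table = data.frame(nucleus_id = integer(0), volume_um3 = numeric(0),
                       integrated_intensity = numeric(0),
                       cell_cycle_label = character(0),
                       stringsAsFactors = FALSE),
    voxel_size_nm = vs), class = "nucleus_masks")
  th <- otsu_threshold(as.numeric(a))
  if (is.na(th)) return(empty)
  mask <- a > th
  mask <- cpp_fill_holes_2d(mask, d)
  labels <- cpp_label3d(mask, d)
  n_lab <- max(labels)
  if (n_lab == 0) return(empty)
  counts <- tabulate(labels[labels > 0], nbins = n_lab)
  keep <- which(counts * voxel_um3 >= min_volume_um3)
  if (length(keep) == 0) return(empty)
  remap <- integer(n_lab)
  remap[keep] <- seq_along(keep)
  labels[labels > 0] <- remap[labels[labels > 0]]
  bg <- stats::median(a)
  intensity <- vapply(seq_along(keep), function(i) {
    sum(a[labels == i] - bg)
  }, numeric(1))
  structure(list(
    labels = labels,
    table = data.frame(nucleus_id = seq_along(keep),
                       volume_um3 = counts[keep] * voxel_um3,
                       integrated_intensity = intensity,
                       cell_cycle_label = "unassigned",
                       stringsAsFactors = FALSE),
    voxel_size_nm = vs), class = "nucleus_masks")
}

#' @export
print.nucleus_masks <- function(x, ...) {
  cat(sprintf("nucleus_masks: %d nuclei\n", nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' Gate G1 cells by integrated DNA intensity
#'
#' Pools the integrated DNA-stain intensities of all segmented nuclei across
#' a dataset and splits the resulting histogram with an Otsu threshold: the
#' lower mode is G1, the upper mode G2/M (doubled DNA content).
#'
#' @param masks A `nucleus_masks` object or a list of them (one per field of
#'   view); gating is pooled over all of them.
#' @return The input with `cell_cycle_label` set to "G1"/"G2M", or left
#'   "unassigned" (with a warning) when the intensity histogram is degenerate
#'   or a single nucleus is available.
#' @export
g1_gate <- function(masks) {
  single <- inherits(masks, "nucleus_masks")
  lst <- if (single) list(masks) else masks
  ints <- unlist(lapply(lst, function(m) m$table$integrated_intensity))
  if (length(ints) < 2 || length(unique(ints)) < 2) {
    warning("degenerate intensity distribution; cells left unassigned")
    return(masks)
  }
  th <- otsu_threshold(ints)
  if (is.na(th)) {
    warning("degenerate intensity distribution; cells left unassigned")
    return(masks)
  }
  lst <- lapply(lst, function(m) {
    m$table$cell_cycle_label <-
      ifelse(m$table$integrated_intensity <= th, "G1", "G2M")
    m
  })
  if (single) lst[[1]] else lst
}

#' Normalized 3D distance of dots to the nuclear lamina
#'
#' For each dot, `d_E` is the anisotropic Euclidean distance-transform value
#' at the dot's voxel (distance to the nearest background voxel of the
#' nuclear mask) and `d_C` is the anisotropic distance to the nearest voxel
#' of the nuclear "center" (the voxels whose edge distance is in the top
#' percentile of the in-mask distribution). The normalized lamina distance is
#' `d_E / (d_E + d_C)`, 0 at the lamina and 1 at the deepest voxel.
#'
#' @param dots data.frame with `x`, `y`, `z` (px; z in axial px).
#' @param masks A `nucleus_masks` object.
#' @param center_percentile Percentile of the edge-distance distribution
#'   defining the center set (default 99).
#' @return `dots` with added columns `nucleus_id` (NA outside every mask),
#'   `d_e_um`, `d_c_um`, `lamina_norm`.
#' @export
lamina_distance <- function(dots, masks, center_percentile = 99) {
  labels <- masks$labels
  d <- dim(labels)
  vs <- masks$voxel_size_nm
  edt <- cpp_edt_aniso(labels > 0, d, c(vs[2], vs[1], vs[3]))
  vox <- cbind(pmin(pmax(round(dots$y), 1), d[1]),
               pmin(pmax(round(dots$x), 1), d[2]),
               pmin(pmax(round(dots$z), 1), d[3]))
  dots$nucleus_id <- labels[vox]
  dots$nucleus_id[dots$nucleus_id == 0] <- NA_integer_
  dots$d_e_um <- NA_real_
  dots$d_c_um <- NA_real_
  for (nid in unique(stats::na.omit(dots$nucleus_id))) {
    in_mask <- labels == nid
    vals <- edt[in_mask]
    thr <- stats::quantile(vals, center_percentile / 100, names = FALSE)
    center <- in_mask & edt >= thr
    # distance of every voxel to the nearest center voxel
    d_c_map <- cpp_edt_aniso(!center, d, c(vs[2], vs[1], vs[3]))
    sel <- which(!is.na(dots$nucleus_id) & dots$nucleus_id == nid)
    dots$d_e_um[sel] <- edt[vox[sel, , drop = FALSE]] / 1000
    dots$d_c_um[sel] <- d_c_map[vox[sel, , drop = FALSE]] / 1000
  }
  dots$lamina_norm <- dots$d_e_um / (dots$d_e_um + dots$d_c_um)
  dots$lamina_norm[!is.na(dots$d_c_um) & dots$d_e_um + dots$d_c_um == 0] <- NA
  dots
}
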