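# DAPI-based segmentation and spot-to-cell assignment.
#
# Nuclei are thresholded from the DAPI canvas, holes filled, small debris
# removed, and touching nuclei split by watershed on the distance transform.
# Cell territories grow outward from the nuclei by seeded propagation on the
# distance transform, capped at a maximum expansion so territories stay
# local; expansions from different nuclei meet at equidistant ridges.

#' Segment nuclei from a DAPI canvas
#'
#' threshold -> fill holes -> drop objects smaller than `min_nucleus_px` ->
#' split touching nuclei by watershed on the distance transform -> integer
#' labels 1..N (0 = background).
#'
#' @param dapi_canvas DAPI canvas (matrix; raw or projected intensities).
#' @param dapi_threshold Intensity threshold (> 0), set per experiment.
#' @param min_nucleus_px Minimum object area kept (px).
#' @return Integer label matrix.
#' @export
segment_nuclei <- function(dapi_canvas, dapi_threshold, min_nucleus_px = 20L) {
  stopifnot(dapi_threshold > 0)
  mask <- dapi_canvas >= dapi_threshold
  if (!any(mask)) return(matrix(0L, nrow(dapi_canvas), ncol(dapi_canvas)))
  mask <- EBImage::fillHull(mask)
  dist <- EBImage::distmap(mask)
  labels <- EBImage::imageData(EBImage::watershed(dist, tolerance = 1, ext = 1))
  # drop undersized objects, then relabel contiguously
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  small <- which(areas < min_nucleus_px)
  if (length(small)) labels[labels %in% small] <- 0L
  relabel_mask(labels)
}

#' Relabel a label image to contiguous 1..N
#' @param labels Integer label matrix (0 = background).
#' @return Relabelled integer matrix.
#' @export
relabel_mask <- function(labels) {
  present <- sort(unique(labels[labels > 0]))
  if (length(present) == 0) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  out <- matrix(match(labels, present, nomatch = 0L),
                nrow(labels), ncol(labels))
  out[labels == 0] <- 0L
  storage.mode(out) <- "integer"
  out
}

#' Expand nucleus labels into approximate cell territories
#'
#' Each nucleus grows outward over the pixels within `max_expansion_px` of
#' any nucleus, by seeded propagation on spatial distance, so neighbouring
#' cells meet at the equidistant ridge; pixels farther than the cap from
#' every nucleus stay background.
#'
#' @param nucleus_mask Integer label matrix from [segment_nuclei()].
#' @param max_expansion_px Expansion cap in pixels (default 15).
#' @return A `CellLabelMask`: list with `labels` (integer matrix) and
#'   `cells` (data.frame `cell_id`, `area_px`, `centroid_y`, `centroid_x`;
#'   0-based centroids).
#' @export
expand_to_cells <- function(nucleus_mask, max_expansion_px = 15) {
  if (max(nucleus_mask) == 0) {
    return(list(labels = nucleus_mask,
                cells = data.frame(cell_id = integer(0), area_px = integer(0),
                                   centroid_y = numeric(0),
                                   centroid_x = numeric(0))))
  }
  dist_to_nuclei <- EBImage::distmap(nucleus_mask == 0)
  grow_mask <- nucleus_mask > 0 | dist_to_nuclei <= max_expansion_px
  # lambda >> 1 makes propagation purely distance-driven (Voronoi growth)
  labels <- EBImage::imageData(EBImage::propagate(
    x = matrix(0, nrow(nucleus_mask), ncol(nucleus_mask)),
    seeds = nucleus_mask, mask = grow_mask, lambda = 1e8))
  storage.mode(labels) <- "integer"
  list(labels = labels, cells = cell_table(labels))
}

#' Per-cell area and centroid of a label mask
#' @param labels Integer label matrix.
#' @return data.frame `cell_id`, `area_px`, `centroid_y`, `centroid_x`
#'   (0-based).
#' @export
cell_table <- function(labels) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(cell_id = integer(0), area_px = integer(0),
                      centroid_y = numeric(0), centroid_x = numeric(0)))
  idx <- which(labels > 0)
  lab <- factor(labels[idx], levels = seq_len(n))
  yy <- (idx - 1L) %% nrow(labels)
  xx <- (idx - 1L) %/% nrow(labels)
  area <- tabulate(labels[idx], nbins = n)
  data.frame(cell_id = seq_len(n), area_px = area,
             centroid_y = as.numeric(tapply(yy, lab, mean)),
             centroid_x = as.numeric(tapply(xx, lab, mean)))
}

#' Assign decoded spots to cells
#'
#' cell_id is the label under the spot's rounded centroid pixel; label 0
#' (background) leaves the spot unassigned (`cell_id = NA`) but retained.
#' @param spots Spot data.frame with canvas coordinates.
#' @param cells A `CellLabelMask` from [expand_to_cells()] (or a bare label
#'   matrix).
#' @return Spot table with `cell_id` filled (NA for background).
#' @export
assign_spots <- function(spots, cells) {
  labels <- if (is.list(cells)) cells$labels else cells
  if (nrow(spots) == 0) return(spots)
  py <- round(spots$y); px <- round(spots$x)
  bad <- which(py < 0 | py >= nrow(labels) | px < 0 | px >= ncol(labels))
  if (length(bad))
    stop("spot outside canvas: spot_id ",
         paste(spots$spot_id[bad], collapse = ", "))
  lab <- labels[cbind(py + 1L, px + 1L)]
  spots$cell_id <- ifelse(lab == 0L, NA_integer_, as.integer(lab))
  spots
}

#' Density-based per-cell quantification for low-magnification imaging
#'
#' For each gene's top-hat filtered canvas, foreground is the set of pixels
#' at or above `density_threshold`; a cell's density for that gene is the
#' foreground pixel count inside the cell divided by the cell area, a
#' fraction in [0, 1]. This is the low-magnification alternative to spot
#' counting, where individual RCPs are no longer resolvable.
#'
#' @param canvases_by_gene Named list of filtered canvases, one per gene.
#' @param cells A `CellLabelMask`.
#' @param density_threshold Foreground threshold (intensity units).
#' @return An `iss_quant` in density mode (entries in [0, 1]).
#' @export
density_quantify <- function(canvases_by_gene, cells, density_threshold) {
  labels <- cells$labels
  n <- max(labels)
  genes <- names(canvases_by_gene)
  stopifnot(!is.null(genes))
  m <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  if (n > 0) {
    idx <- which(labels > 0)
    lab <- labels[idx]
    for (g in seq_along(genes)) {
      fg <- canvases_by_gene[[g]][idx] >= density_threshold
      cnt <- tabulate(lab[fg], nbins = n)
      m[, g] <- cnt / cells$cells$area_px
    }
  }
  new_quant(m, cells$cells, mode = "density")
}
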