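# Projection, tile stitching and round-to-round alignment.
#
# Stitching is translation-only: pairwise offsets between adjacent tiles are
# estimated by normalized cross-correlation of the nominal overlap strips
# over a bounded integer offset search, then composed into global positions
# along a maximum-confidence spanning tree anchored at tile 1. Overlap pixels
# are blended by per-pixel maximum so seam-straddling RCP peaks survive.

#' Maximum intensity projection of a z-stack
#'
#' Collapses a z-stack to a 2-D image by the per-pixel maximum across planes.
#' @param stack List of matrices (z-planes) of identical shape, length >= 1.
#' @return Matrix of the same shape as one plane.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.list(stack) || length(stack) == 0)
    stop("max_project: stack must contain at least one plane")
  Reduce(pmax, stack)
}

#' Project every stack of a TileSet
#' @param tileset An `iss_tileset`.
#' @return List indexed `[[tile]][[round]][[channel]]` of projected matrices.
#' @export
project_tileset <- function(tileset) {
  lay <- tileset$layout
  lapply(seq_len(n_tiles(lay)), function(t)
    lapply(seq_len(lay$n_rounds), function(r)
      lapply(seq_along(lay$channel_names), function(c)
        max_project(get_stack(tileset, t, r, c)))))
}

# Normalized cross-correlation of two equally sized matrices; NA-safe.
.ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Estimate the residual translation between two overlapping images
#'
#' Searches integer offsets within `search_margin_px` of the nominal offset
#' for the translation maximizing the normalized cross-correlation of the
#' overlapping region. The nominal offset is the 0-based position of `imgB`'s
#' origin relative to `imgA`'s origin, `c(dy, dx)`.
#'
#' @param imgA,imgB Matrices.
#' @param nominal_offset Integer `c(dy, dx)` expected offset of B w.r.t. A.
#' @param search_margin_px Half-width of the residual search (px).
#' @param min_confidence Peak correlations below this return the nominal
#'   offset (residual 0) rather than an unreliable argmax.
#' @return List `dy`, `dx` (residuals to add to the nominal offset) and
#'   `confidence` (peak correlation in `[-1, 1]`). Degenerate (constant)
#'   overlaps return the nominal offset with confidence 0.
#' @export
estimate_pairwise_offset <- function(imgA, imgB, nominal_offset,
                                     search_margin_px = 8L,
                                     min_confidence = 0.2) {
  m <- as.integer(search_margin_px)
  best <- list(dy = 0L, dx = 0L, confidence = -Inf)
  for (ry in -m:m) for (rx in -m:m) {
    dy <- nominal_offset[1] + ry; dx <- nominal_offset[2] + rx
    # overlap region in A coordinates (0-based, half-open)
    y0 <- max(0L, dy); y1 <- min(nrow(imgA), dy + nrow(imgB))
    x0 <- max(0L, dx); x1 <- min(ncol(imgA), dx + ncol(imgB))
    if (y1 - y0 < 4L || x1 - x0 < 4L) next
    a <- imgA[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
    b <- imgB[(y0 - dy + 1):(y1 - dy), (x0 - dx + 1):(x1 - dx), drop = FALSE]
    cc <- .ncc(a, b)
    if (cc > best$confidence) best <- list(dy = ry, dx = rx, confidence = cc)
  }
  if (!is.finite(best$confidence))
    stop("estimate_pairwise_offset: no valid overlap within the search margin")
  if (best$confidence < min_confidence)  # degenerate or uncorrelated content:
    return(list(dy = 0L, dx = 0L,       # fall back to the nominal offset
                confidence = max(best$confidence, 0)))
  list(dy = as.integer(best$dy), dx = as.integer(best$dx),
       confidence = best$confidence)
}

#' Stitch the tiles of one (round, channel) into a canvas
#'
#' Estimates pairwise offsets for every adjacent tile pair on the grid,
#' anchors tile 1 and propagates positions along a maximum-confidence
#' spanning tree, then composes the canvas resolving overlaps by per-pixel
#' maximum.
#'
#' @param tiles List of matrices in row-major tile order (as produced by
#'   [project_tileset()] for one round and channel).
#' @param layout An `iss_layout`.
#' @param search_margin_px Residual search half-width passed to
#'   [estimate_pairwise_offset()].
#' @param min_confidence Pairs below this correlation fall back to their
#'   nominal offset (counted in diagnostics).
#' @return List with `canvas` (matrix), `offsets` (data.frame `tile`, `y0`,
#'   `x0`; 0-based, normalized to min 0), `canvas_height`, `canvas_width`,
#'   and `diagnostics` (`n_pairs`, `n_fallback`, `mean_confidence`).
#' @export
stitch <- function(tiles, layout, search_margin_px = 8L, min_confidence = 0.3) {
  nt <- n_tiles(layout)
  stopifnot(length(tiles) == nt)
  nom <- nominal_offsets(layout)
  if (nt == 1L) {
    return(list(canvas = tiles[[1]],
                offsets = data.frame(tile = 1L, y0 = 0L, x0 = 0L),
                canvas_height = nrow(tiles[[1]]),
                canvas_width = ncol(tiles[[1]]),
                diagnostics = list(n_pairs = 0L, n_fallback = 0L,
                                   mean_confidence = NA_real_)))
  }
  # adjacent pairs on the grid
  pairs <- list()
  for (i in seq_len(nt)) {
    gr <- nom$grid_row[i]; gc <- nom$grid_col[i]
    right <- which(nom$grid_row == gr & nom$grid_col == gc + 1L)
    below <- which(nom$grid_row == gr + 1L & nom$grid_col == gc)
    for (j in c(right, below)) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  n_fallback <- 0L
  edges <- data.frame(from = integer(0), to = integer(0),
                      dy = integer(0), dx = integer(0), conf = numeric(0))
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    nom_ij <- c(nom$y0[j] - nom$y0[i], nom$x0[j] - nom$x0[i])
    est <- estimate_pairwise_offset(tiles[[i]], tiles[[j]], nom_ij,
                                    search_margin_px)
    if (est$confidence < min_confidence) {
      n_fallback <- n_fallback + 1L
      est <- list(dy = 0L, dx = 0L, confidence = est$confidence)
    }
    edges <- rbind(edges, data.frame(from = i, to = j,
                                     dy = nom_ij[1] + est$dy,
                                     dx = nom_ij[2] + est$dx,
                                     conf = est$confidence))
  }
  # maximum-confidence spanning tree (igraph mst minimizes, so negate)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(nt)))
  igraph::E(g)$weight <- -edges$conf
  igraph::E(g)$edge_id <- seq_len(nrow(edges))
  tree <- igraph::mst(g)
  # propagate offsets from tile 1 by BFS over the tree
  pos <- matrix(NA_real_, nt, 2)
  pos[1, ] <- c(0, 0)
  el <- igraph::as_edgelist(tree, names = TRUE)
  eid <- igraph::E(tree)$edge_id
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (k in seq_len(nrow(el))) {
      a <- as.integer(el[k, 1]); b <- as.integer(el[k, 2])
      e <- edges[eid[k], ]
      if (a == v && is.na(pos[b, 1])) {
        pos[b, ] <- pos[a, ] + c(e$dy, e$dx) *
          (if (e$from == a) 1 else -1)
        queue <- c(queue, b)
      } else if (b == v && is.na(pos[a, 1])) {
        pos[a, ] <- pos[b, ] + c(e$dy, e$dx) *
          (if (e$from == b) 1 else -1)
        queue <- c(queue, a)
      }
    }
  }
  pos <- round(pos)
  pos[, 1] <- pos[, 1] - min(pos[, 1])
  pos[, 2] <- pos[, 2] - min(pos[, 2])
  H <- as.integer(max(pos[, 1]) + layout$tile_height_px)
  W <- as.integer(max(pos[, 2]) + layout$tile_width_px)
  canvas <- matrix(0, H, W)
  for (i in seq_len(nt)) {
    ys <- pos[i, 1] + seq_len(layout$tile_height_px)
    xs <- pos[i, 2] + seq_len(layout$tile_width_px)
    canvas[ys, xs] <- pmax(canvas[ys, xs], tiles[[i]])
  }
  list(canvas = canvas,
       offsets = data.frame(tile = seq_len(nt),
                            y0 = as.integer(pos[, 1]),
                            x0 = as.integer(pos[, 2])),
       canvas_height = H, canvas_width = W,
       diagnostics = list(n_pairs = nrow(edges), n_fallback = n_fallback,
                          mean_confidence = mean(edges$conf)))
}

#' Apply a fixed stitch layout to another channel's tiles
#'
#' Offsets are estimated once (typically on the nuclear channel) and reused
#' for every channel of the same round so all channels share one geometry.
#' @param tiles List of tile matrices in row-major order.
#' @param stitch_layout Result of [stitch()] (its `offsets` and canvas size).
#' @param layout An `iss_layout`.
#' @return Canvas matrix.
#' @export
apply_stitch <- function(tiles, stitch_layout, layout) {
  H <- stitch_layout$canvas_height; W <- stitch_layout$canvas_width
  canvas <- matrix(0, H, W)
  for (i in seq_len(n_tiles(layout))) {
    ys <- stitch_layout$offsets$y0[i] + seq_len(layout$tile_height_px)
    xs <- stitch_layout$offsets$x0[i] + seq_len(layout$tile_width_px)
    canvas[ys, xs] <- pmax(canvas[ys, xs], tiles[[i]])
  }
  canvas
}

#' Align imaging rounds to a reference round by global translation
#'
#' Registers each round's nuclear-channel canvas to the reference round's by
#' the same normalized cross-correlation search used in stitching, and
#' applies the recovered integer shift to all channels of that round.
#'
#' @param canvases List indexed `[[round]][[channel]]` of equally sized
#'   matrices.
#' @param nuclear_index 1-based index of the nuclear channel.
#' @param reference_round Round used as the fixed reference (default 1).
#' @param search_margin_px Shift search half-width (px).
#' @return List with `canvases` (same structure, shifted; vacated margins
#'   zero-filled) and `shifts` (data.frame `round`, `dy`, `dx`,
#'   `confidence`).
#' @export
align_rounds <- function(canvases, nuclear_index, reference_round = 1L,
                         search_margin_px = 8L) {
  n_rounds <- length(canvases)
  ref <- canvases[[reference_round]][[nuclear_index]]
  shifts <- data.frame(round = seq_len(n_rounds), dy = 0L, dx = 0L,
                       confidence = 1)
  out <- canvases
  for (r in seq_len(n_rounds)) {
    if (r == reference_round) next
    est <- estimate_pairwise_offset(ref, canvases[[r]][[nuclear_index]],
                                    c(0L, 0L), search_margin_px)
    # residual (dy,dx) is where round r sits relative to the reference;
    # shifting its content by (-dy,-dx)... translate_image moves content so
    # that pixel (y,x) lands at (y+dy, x+dx); we need content moved by the
    # negative of the estimated displacement of B's origin.
    shifts$dy[r] <- est$dy; shifts$dx[r] <- est$dx
    shifts$confidence[r] <- est$confidence
    out[[r]] <- lapply(canvases[[r]], translate_image,
                       dy = est$dy, dx = est$dx)
  }
  list(canvases = out, shifts = shifts)
}

#' Translate an image by an integer offset, zero-filling vacated pixels
#' @param img Matrix.
#' @param dy,dx Integer shift applied to the content (positive moves content
#'   down/right).
#' @return Matrix of the same shape.
#' @export
translate_image <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  ys_src <- max(1, 1 - dy):min(H, H - dy)
  xs_src <- max(1, 1 - dx):min(W, W - dx)
  if (length(ys_src) == 0 || length(xs_src) == 0) return(out)
  out[ys_src + dy, xs_src + dx] <- img[ys_src, xs_src]
  out
}

#' Downsample an image by block averaging
#'
#' Emulates acquisition at a lower magnification objective: each `factor` x
#' `factor` block becomes one pixel holding the block mean. Trailing rows and
#' columns that do not fill a block are dropped.
#' @param img Matrix.
#' @param factor Integer downsampling factor (default 2, e.g. 20X -> 10X).
#' @return Matrix of size `floor(dim / factor)`.
#' @export
downsample_image <- function(img, factor = 2L) {
  factor <- as.integer(factor)
  H <- (nrow(img) %/% factor) * factor
  W <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  # average rows then columns within blocks
  rowsum_idx <- rep(seq_len(H %/% factor), each = factor)
  colsum_idx <- rep(seq_len(W %/% factor), each = factor)
  m <- rowsum(img, rowsum_idx) / factor
  t(rowsum(t(m), colsum_idx)) / factor
}

#' Downsample a label mask by point sampling
#'
#' Nearest-neighbour (stride) sampling preserving label identities, for
#' carrying a segmentation to a downsampled canvas.
#' @param labels Integer label matrix.
#' @param factor Integer downsampling factor.
#' @return Integer label matrix of size `floor(dim / factor)`.
#' @export
downsample_labels <- function(labels, factor = 2L) {
  factor <- as.integer(factor)
  H <- nrow(labels) %/% factor; W <- ncol(labels) %/% factor
  out <- labels[(seq_len(H) - 1L) * factor + 1L,
                (seq_len(W) - 1L) * factor + 1L, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}
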