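# Spot calling on stitched, aligned canvases.
#
# Signals are isolated by a white top-hat (image minus its morphological
# opening with a disk), thresholded on intensity, filtered on connected-
# component area, and located at the intensity-weighted centroid. Each spot
# carries a channel-purity quality q: the intensity at its centroid on the
# channel where it was detected, divided by the summed intensities of all
# the other signal channels (DAPI excluded) at the same location.

#' White top-hat filter
#'
#' Subtracts the morphological opening (disk structuring element) from the
#' image, removing background structure larger than the disk and leaving
#' small bright features; the result is nonnegative.
#' @param image Numeric matrix.
#' @param radius_px Disk radius of the structuring element (>= 1).
#' @return Filtered matrix, same shape.
#' @export
tophat_filter <- function(image, radius_px) {
  stopifnot(radius_px >= 1)
  kern <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  # EBImage grayscale morphology clips to [0, 1]: rescale around the opening
  scale <- max(image, 1)
  opened <- EBImage::imageData(EBImage::opening(image / scale, kern)) * scale
  out <- image - opened
  out[out < 0] <- 0
  out
}

#' Detect spots on one filtered canvas
#'
#' Thresholds the image, labels 8-connected components, discards components
#' whose area falls outside `[size_min_px, size_max_px]`, and reports each
#' surviving component at its intensity-weighted centroid with its peak
#' intensity and area.
#'
#' @param image Top-hat filtered canvas (matrix).
#' @param intensity_threshold Pixels `>= intensity_threshold` are foreground.
#' @param size_min_px,size_max_px Inclusive component-area bounds.
#' @param round,channel Indices stored on the resulting spots (1-based).
#' @return Spot data.frame (canonical schema; `quality`, `gene`, `cell_id`,
#'   `Q` unset). Coordinates are 0-based canvas positions.
#' @export
detect_spots <- function(image, intensity_threshold, size_min_px = 2L,
                         size_max_px = 100L, round = 1L, channel = 1L) {
  stopifnot(intensity_threshold > 0, size_min_px <= size_max_px)
  fg <- image >= intensity_threshold
  if (!any(fg)) return(empty_spot_table())
  labels <- EBImage::imageData(EBImage::bwlabel(fg))
  n <- max(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  val <- image[idx]
  yy <- (idx - 1L) %% nrow(image)        # 0-based row
  xx <- (idx - 1L) %/% nrow(image)       # 0-based col
  flab <- factor(lab, levels = seq_len(n))
  area <- tabulate(lab, nbins = n)
  wsum <- as.numeric(tapply(val, flab, sum))
  cy <- as.numeric(tapply(val * yy, flab, sum)) / wsum
  cx <- as.numeric(tapply(val * xx, flab, sum)) / wsum
  peak <- as.numeric(tapply(val, flab, max))
  keep <- which(area >= size_min_px & area <= size_max_px)
  if (length(keep) == 0) return(empty_spot_table())
  df <- data.frame(spot_id = seq_along(keep),
                   round = as.integer(round), channel = as.integer(channel),
                   y = as.numeric(cy[keep]), x = as.numeric(cx[keep]),
                   intensity = as.numeric(peak[keep]),
                   area = as.integer(area[keep]),
                   quality = NA_real_, gene = NA_character_,
                   cell_id = NA_integer_, Q = NA_real_,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Channel-purity quality of one spot
#'
#' q = intensity on the detected channel divided by the summed intensities
#' of all the other signal channels (the nuclear channel is excluded), with
#' a configurable floor on the denominator so perfectly pure spots get a
#' finite score. Intensities are measured at the spot's centroid pixel on
#' the top-hat filtered canvases. q is invariant to a common intensity scale
#' whenever the floor is not hit.
#'
#' @param detected_channel 1-based index into `intensities`.
#' @param intensities Named or plain numeric vector of per-signal-channel
#'   intensities at the spot location (nuclear channel already excluded).
#' @param floor Denominator floor in intensity units (default 1).
#' @return Quality q >= 0.
#' @export
spot_quality <- function(detected_channel, intensities, floor = 1) {
  if (detected_channel < 1 || detected_channel > length(intensities))
    stop("detected channel ", detected_channel,
         " missing from the intensity vector")
  others <- sum(intensities[-detected_channel])
  intensities[detected_channel] / max(others, floor)
}

#' Detect and quality-score all signal channels of one round
#'
#' Runs [detect_spots()] on every signal channel of a round and attaches the
#' channel-purity quality q measured across the round's filtered canvases.
#'
#' @param filtered_by_channel List of top-hat filtered canvases indexed by
#'   channel (full channel list of the layout).
#' @param layout An `iss_layout`.
#' @param intensity_threshold Scalar or per-channel vector of thresholds.
#' @param size_min_px,size_max_px Component-area bounds.
#' @param round Round index stored on the spots.
#' @param quality_floor Denominator floor for [spot_quality()].
#' @return Spot data.frame for the whole round, qualities filled in.
#' @export
detect_round <- function(filtered_by_channel, layout, intensity_threshold,
                         size_min_px = 2L, size_max_px = 100L, round = 1L,
                         quality_floor = 1) {
  sig <- setdiff(seq_along(layout$channel_names), layout$nuclear_index)
  thr <- if (length(intensity_threshold) == 1)
    stats::setNames(rep(intensity_threshold, length(sig)), sig)
  else stats::setNames(intensity_threshold, sig)
  tabs <- list()
  for (c in sig) {
    tab <- detect_spots(filtered_by_channel[[c]], thr[[as.character(c)]],
                        size_min_px, size_max_px, round = round, channel = c)
    if (nrow(tab) == 0) next
    for (s in seq_len(nrow(tab))) {
      py <- round(tab$y[s]) + 1L; px <- round(tab$x[s]) + 1L
      ints <- vapply(sig, function(cc) filtered_by_channel[[cc]][py, px], 0)
      tab$quality[s] <- spot_quality(match(c, sig), ints, quality_floor)
    }
    tabs[[length(tabs) + 1L]] <- tab
  }
  if (length(tabs) == 0) return(empty_spot_table())
  out <- do.call(rbind, tabs)
  out$spot_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Signal-to-noise ratio of detected spots
#'
#' SNR = (peak - local background median) / local background robust sd
#' (median absolute deviation, normal-consistent), with the background taken
#' from an annulus around the spot (inner radius `2 * radius_px`, outer
#' `4 * radius_px`) on the raw, pre-top-hat canvas, excluding pixels that
#' belong to other spots. Zero background spread yields an SNR capped at
#' `cap`; a fully occluded annulus yields `NA`.
#'
#' @param spots Spot data.frame (one round/channel).
#' @param raw_canvas Raw canvas the spots were detected on.
#' @param radius_px Structuring radius used at detection (sets the annulus).
#' @param cap Cap for infinite SNR (default 1e6).
#' @return List: `per_spot` (the table with an `snr` column) and `summary`
#'   (data.frame `channel`, `median_snr`, `n`).
#' @export
measure_snr <- function(spots, raw_canvas, radius_px = 3L, cap = 1e6) {
  if (nrow(spots) == 0)
    return(list(per_spot = cbind(spots, snr = numeric(0)),
                summary = data.frame(channel = integer(0),
                                     median_snr = numeric(0), n = integer(0))))
  H <- nrow(raw_canvas); W <- ncol(raw_canvas)
  r_in <- 2 * radius_px; r_out <- 4 * radius_px
  # mark pixels near any spot so annuli exclude neighbouring signals
  occupied <- matrix(FALSE, H, W)
  for (s in seq_len(nrow(spots))) {
    py <- round(spots$y[s]); px <- round(spots$x[s])
    ys <- max(0, py - r_in):min(H - 1, py + r_in)
    xs <- max(0, px - r_in):min(W - 1, px + r_in)
    occupied[ys + 1, xs + 1] <- TRUE
  }
  snr <- numeric(nrow(spots))
  for (s in seq_len(nrow(spots))) {
    py <- round(spots$y[s]); px <- round(spots$x[s])
    ys <- max(0, py - r_out):min(H - 1, py + r_out)
    xs <- max(0, px - r_out):min(W - 1, px + r_out)
    d2 <- outer((ys - py)^2, (xs - px)^2, `+`)
    ring <- d2 >= r_in^2 & d2 <= r_out^2 & !occupied[ys + 1, xs + 1]
    bg <- raw_canvas[ys + 1, xs + 1][ring]
    if (length(bg) < 8) { snr[s] <- NA_real_; next }
    peak <- raw_canvas[py + 1, px + 1]
    spread <- stats::mad(bg)
    snr[s] <- if (spread == 0) cap
              else min((peak - stats::median(bg)) / spread, cap)
  }
  per_spot <- cbind(spots, snr = snr)
  agg <- stats::aggregate(snr ~ channel, data = per_spot[!is.na(snr), ],
                          FUN = stats::median)
  nagg <- stats::aggregate(snr ~ channel, data = per_spot[!is.na(snr), ],
                           FUN = length)
  list(per_spot = per_spot,
       summary = data.frame(channel = agg$channel, median_snr = agg$snr,
                            n = nagg$snr))
}
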