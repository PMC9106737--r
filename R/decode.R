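# Gene calling from per-round spot tables.
#
# Sequential mode is a direct (round, channel) -> gene lookup. Combinatorial
# mode links each first-cycle spot to its nearest neighbour in the next
# cycle (chains extend greedily cycle to cycle), scores each candidate
# barcode with the distance-penalized quality
#     Q = prod_{i=1}^{n-1} ( q_i * q_{i+1} - k * d_{i(i+1)} )
# (for n = 2 cycles this is exactly q1*q2 - k*d12), keeps only Q > 0,
# resolves spots shared between candidates in favour of the higher Q, and
# looks surviving channel sequences up in the codebook.

#' Label spots by sequential codebook lookup
#'
#' Every spot is labelled with the gene assigned to its (round, channel);
#' spots at unassigned slots are labelled `"unassigned"` and retained.
#' @param spots Spot data.frame.
#' @param codebook Sequential `iss_codebook`.
#' @return The spot table with the `gene` column filled.
#' @export
assign_sequential <- function(spots, codebook) {
  stopifnot(codebook$mode == "sequential")
  key <- paste(spots$round, spots$channel, sep = ":")
  cb_key <- paste(codebook$rounds, codebook$channels, sep = ":")
  hit <- match(key, cb_key)
  spots$gene <- ifelse(is.na(hit), "unassigned", codebook$genes[hit])
  spots
}

#' Link spots across cycles into barcode candidates
#'
#' For each spot of the first cycle, its nearest neighbour in the second
#' cycle within `max_radius_px` is chained; with more than two cycles the
#' chain extends greedily, each cycle's member being the nearest neighbour
#' of the previous cycle's member. A first-cycle spot with no neighbour
#' within the radius yields no candidate. A later-cycle spot may be claimed
#' by several chains at this stage; [filter_and_call()] resolves sharing.
#'
#' @param per_cycle List of spot data.frames in cycle order (>= 2 cycles),
#'   each covering all signal channels of its cycle.
#' @param max_radius_px Nearest-neighbour search radius in pixels.
#' @return List of candidates; each is a list with `spot_rows` (row index
#'   into each cycle's table), `channels`, `qualities`, `distances`
#'   (Euclidean pixel distances between consecutive members), `y`, `x`
#'   (first-cycle position).
#' @export
link_cycles <- function(per_cycle, max_radius_px = 5) {
  stopifnot(length(per_cycle) >= 2)
  n_cycles <- length(per_cycle)
  first <- per_cycle[[1]]
  out <- list()
  if (nrow(first) == 0) return(out)
  for (s in seq_len(nrow(first))) {
    rows <- s
    chs <- first$channel[s]
    qs <- first$quality[s]
    ds <- numeric(0)
    y <- first$y[s]; x <- first$x[s]
    ok <- TRUE
    for (cyc in 2:n_cycles) {
      tab <- per_cycle[[cyc]]
      if (nrow(tab) == 0) { ok <- FALSE; break }
      d <- sqrt((tab$y - y)^2 + (tab$x - x)^2)
      j <- which.min(d)
      if (d[j] > max_radius_px) { ok <- FALSE; break }
      rows <- c(rows, j)
      chs <- c(chs, tab$channel[j])
      qs <- c(qs, tab$quality[j])
      ds <- c(ds, d[j])
      y <- tab$y[j]; x <- tab$x[j]   # chain extends from the previous member
    }
    if (!ok) next
    out[[length(out) + 1L]] <- list(spot_rows = rows, channels = chs,
                                    qualities = qs, distances = ds,
                                    y = first$y[s], x = first$x[s])
  }
  out
}

#' Combined barcode quality score Q
#'
#' Q = prod over i = 1..n-1 of (q_i * q_{i+1} - k * d_{i(i+1)}), where q_i is
#' the channel-purity quality of the cycle-i member and d_{i(i+1)} the pixel
#' distance between consecutive members. For two cycles this reduces to
#' q1*q2 - k*d12. Q decreases in every distance and in k, and equals the
#' product of quality pairs at zero displacement.
#'
#' @param qualities Numeric vector q_1..q_n (n >= 2).
#' @param distances Numeric vector d_12..d_(n-1)n (length n - 1, >= 0).
#' @param k Distance penalty per pixel (>= 0).
#' @return Scalar Q.
#' @export
score_barcode <- function(qualities, distances, k) {
  n <- length(qualities)
  stopifnot(n >= 2, length(distances) == n - 1, k >= 0, all(distances >= 0))
  prod(qualities[-n] * qualities[-1] - k * distances)
}

#' Score, filter and call barcode candidates
#'
#' Scores every candidate with [score_barcode()], drops candidates with
#' Q <= 0, resolves candidates sharing a member spot in favour of the higher
#' Q (ties: smaller total distance, then first in input order), and looks
#' surviving channel sequences up in the codebook. Matching candidates
#' become gene calls; non-matching sequences are dropped from the expression
#' path and counted as invalid barcodes in the diagnostics.
#'
#' @param candidates List from [link_cycles()].
#' @param codebook Combinatorial `iss_codebook`.
#' @param k Distance penalty per pixel.
#' @return List: `spots` (decoded spot data.frame: one row per call, at the
#'   first-cycle position, with `gene`, `Q` and a `barcode` attribute
#'   column), `diagnostics` (`n_candidates`, `n_q_dropped`, `n_shared_dropped`,
#'   `n_invalid_barcode`, `n_called`).
#' @export
filter_and_call <- function(candidates, codebook, k = 0.2) {
  stopifnot(codebook$mode == "combinatorial")
  diag <- list(n_candidates = length(candidates), n_q_dropped = 0L,
               n_shared_dropped = 0L, n_invalid_barcode = 0L, n_called = 0L)
  if (length(candidates) == 0)
    return(list(spots = cbind(empty_spot_table(), barcode = character(0)),
                diagnostics = diag))
  Q <- vapply(candidates, function(cd)
    score_barcode(cd$qualities, cd$distances, k), 0)
  keep <- Q > 0
  diag$n_q_dropped <- sum(!keep)
  idx <- which(keep)
  # one-to-one resolution of shared member spots by Q rank
  # (tie: smaller total distance, then input order)
  totd <- vapply(candidates, function(cd) sum(cd$distances), 0)
  ord <- idx[order(-Q[idx], totd[idx], idx)]
  claimed <- new.env(hash = TRUE)
  survivors <- integer(0)
  for (i in ord) {
    keys <- paste(seq_along(candidates[[i]]$spot_rows),
                  candidates[[i]]$spot_rows, sep = ":")
    if (any(vapply(keys, function(kk)
          exists(kk, envir = claimed, inherits = FALSE), TRUE))) {
      diag$n_shared_dropped <- diag$n_shared_dropped + 1L
      next
    }
    for (kk in keys) assign(kk, TRUE, envir = claimed)
    survivors <- c(survivors, i)
  }
  survivors <- sort(survivors)
  cb_key <- vapply(codebook$barcodes, paste, "", collapse = "-")
  rows <- list()
  for (i in survivors) {
    cd <- candidates[[i]]
    bc <- paste(cd$channels, collapse = "-")
    gi <- match(bc, cb_key)
    if (is.na(gi)) { diag$n_invalid_barcode <- diag$n_invalid_barcode + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      spot_id = NA_integer_, round = 1L, channel = cd$channels[1],
      y = cd$y, x = cd$x, intensity = NA_real_, area = NA_integer_,
      quality = cd$qualities[1], gene = codebook$genes[gi],
      cell_id = NA_integer_, Q = Q[i], barcode = bc,
      stringsAsFactors = FALSE)
  }
  diag$n_called <- length(rows)
  spots <- if (length(rows)) do.call(rbind, rows)
           else cbind(empty_spot_table(), barcode = character(0))
  if (nrow(spots)) spots$spot_id <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  list(spots = spots, diagnostics = diag)
}

#' Detection-efficiency slope between two conditions
#'
#' Least-squares slope through the origin of condition-B totals regressed on
#' condition-A totals over matched (ROI, gene) pairs, with the Pearson
#' correlation of the pairs.
#'
#' @param counts_a,counts_b Numeric vectors of matched totals (same order).
#' @return List: `slope` (sum(a*b)/sum(a^2)), `r` (Pearson), `n`.
#' @export
efficiency_slope <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 1)
  if (all(counts_a == 0)) stop("efficiency_slope: condition-A totals are all zero")
  list(slope = sum(counts_a * counts_b) / sum(counts_a^2),
       r = if (length(counts_a) >= 3 && stats::sd(counts_a) > 0 &&
               stats::sd(counts_b) > 0)
             stats::cor(counts_a, counts_b) else NA_real_,
       n = length(counts_a))
}

#' Recover the detection-efficiency slope from a paired simulated experiment
#'
#' Machine twin of a two-chemistry benchmarking experiment: several regions
#' of interest (ROIs) are simulated as single-field acquisitions of a 4-gene
#' panel read in one cycle, in two conditions sharing cell geometry whose
#' ground-truth per-gene spot rates differ by exactly `ratio`. Both
#' conditions are run through projection, top-hat filtering, detection and
#' sequential gene assignment; per-(ROI, gene) call totals are regressed
#' through the origin with [efficiency_slope()].
#'
#' Per-ROI base rates are chosen so the reference condition yields a few
#' hundred calls per (ROI, gene) and the boosted condition stays below the
#' optical-crowding regime on a 1024 px field.
#'
#' @param seed Integer seed deriving every ROI's randomness.
#' @param ratio Ground-truth rate ratio between conditions (default 5.13).
#' @param rates Per-ROI spots-per-cell-per-gene base rates (one ROI each).
#' @param config Run configuration for the detection pipeline.
#' @return List: `slope`, `r` (Pearson), `n` pairs, `totals` (data.frame of
#'   per-(ROI, gene) reference and boosted call totals).
#' @export
slope_recovery <- function(seed = 1L, ratio = 5.13,
                           rates = c(0.67, 0.83, 1.0),
                           config = default_run_config()) {
  panel <- codebook_sequential(c("Cd24a", "Lamp5", "Slc17a7", "Mbp"),
                               rep(1L, 4), 2:5)
  lay <- acquisition_layout(grid_rows = 1, grid_cols = 1,
                            tile_height_px = 1024, tile_width_px = 1024,
                            n_rounds = 1, z_steps = 2)
  totals <- list()
  for (i in seq_along(rates)) {
    cfg <- simulation_config(layout = lay, n_cells = 300, cell_radius_px = 30,
                             spots_per_cell_per_gene = rates[i],
                             min_center_sep_px = 8, tile_offset_jitter_px = 0,
                             seed = (seed + i) %% .Machine$integer.max)
    pair <- paired_condition_fixture(cfg, panel, ratio)
    ta <- gene_call_totals(pair$reference$tiles, panel, config)
    tb <- gene_call_totals(pair$boosted$tiles, panel, config)
    totals[[i]] <- data.frame(roi = i, gene = panel$genes,
                              reference = as.integer(ta),
                              boosted = as.integer(tb))
  }
  totals <- do.call(rbind, totals)
  fit <- efficiency_slope(totals$reference, totals$boosted)
  list(slope = fit$slope, r = fit$r, n = fit$n, totals = totals)
}
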