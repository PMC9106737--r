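# Synthetic ISS experiment generator.
#
# Emulates the signal structure the pipeline assumes: non-overlapping nuclei
# rendered into the DAPI channel, rolling-circle products as isotropic
# Gaussians placed within a cytoplasmic disk around each nucleus, optional
# channel crosstalk, tiling with 10% overlap and integer stage jitter,
# z-expansion with one in-focus plane, constant background plus additive
# Gaussian noise. Everything is deterministic under the config seed and ships
# with full ground truth (spots, cell mask, tile offsets, count table).

#' Configuration of a simulated ISS experiment
#'
#' @param layout An [acquisition_layout()].
#' @param n_cells Number of cells placed on the stitched canvas.
#' @param nucleus_radius_px Mean and sd of nucleus radius, `c(mean, sd)`.
#' @param cell_radius_px Cytoplasm extent: spots fall within this radius of
#'   the nucleus centre.
#' @param spots_per_cell_per_gene Poisson rate of RCPs per cell per gene.
#' @param psf_sigma_px Gaussian PSF sigma of a rendered RCP (px).
#' @param spot_amplitude Peak intensity of a rendered RCP.
#' @param nucleus_amplitude Intensity of the rendered nucleus disk.
#' @param background_level Constant background added to every plane.
#' @param gaussian_noise_sd Additive Gaussian noise sd per plane.
#' @param crosstalk_fraction Fraction of each signal channel leaking into the
#'   other signal channels, in `[0, 0.5)`.
#' @param tile_offset_jitter_px Maximum absolute integer stage jitter per tile.
#' @param efficiency_scale Positive multiplier on all spot rates (models
#'   chemistry detection efficiency).
#' @param min_center_sep_px Minimum distance between cell centres; the default
#'   `2 * cell_radius_px` keeps cell disks disjoint so ground-truth spot
#'   ownership is unambiguous.
#' @param seed Integer seed; the same config always produces bit-identical
#'   output.
#' @return An object of class `iss_simconfig`.
#' @export
simulation_config <- function(layout = acquisition_layout(),
                              n_cells = 40L,
                              nucleus_radius_px = c(6, 1),
                              cell_radius_px = 16,
                              spots_per_cell_per_gene = 2,
                              psf_sigma_px = 1.2,
                              spot_amplitude = 6000,
                              nucleus_amplitude = 10000,
                              background_level = 500,
                              gaussian_noise_sd = 300,
                              crosstalk_fraction = 0.05,
                              tile_offset_jitter_px = 2L,
                              efficiency_scale = 1,
                              min_center_sep_px = NULL,
                              seed = 1L) {
  stopifnot(inherits(layout, "iss_layout"),
            n_cells >= 0, spots_per_cell_per_gene >= 0,
            psf_sigma_px > 0, spot_amplitude >= 0, background_level >= 0,
            gaussian_noise_sd >= 0,
            crosstalk_fraction >= 0, crosstalk_fraction < 0.5,
            tile_offset_jitter_px >= 0, efficiency_scale > 0)
  if (is.null(min_center_sep_px)) min_center_sep_px <- 2 * cell_radius_px
  structure(list(
    layout = layout, n_cells = as.integer(n_cells),
    nucleus_radius_px = nucleus_radius_px,
    cell_radius_px = cell_radius_px,
    spots_per_cell_per_gene = spots_per_cell_per_gene,
    psf_sigma_px = psf_sigma_px, spot_amplitude = spot_amplitude,
    nucleus_amplitude = nucleus_amplitude,
    background_level = background_level,
    gaussian_noise_sd = gaussian_noise_sd,
    crosstalk_fraction = crosstalk_fraction,
    tile_offset_jitter_px = as.integer(tile_offset_jitter_px),
    efficiency_scale = efficiency_scale,
    min_center_sep_px = min_center_sep_px,
    seed = as.integer(seed)
  ), class = "iss_simconfig")
}

# Place non-overlapping cells by rejection sampling; 0-based continuous
# centre coordinates kept inside the canvas by a cell_radius margin.
.sim_geometry <- function(config) {
  lay <- config$layout
  cs <- canvas_size(lay)
  H <- cs[1]; W <- cs[2]
  margin <- min(config$cell_radius_px,
                floor(min(H, W) / 2) - 1)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  attempts <- 0L
  max_attempts <- 500L * max(config$n_cells, 1L)
  while (nrow(centers) < config$n_cells) {
    if (attempts > max_attempts)
      stop("could not place ", config$n_cells, " non-overlapping cells on a ",
           H, "x", W, " canvas; reduce n_cells or cell_radius_px")
    attempts <- attempts + 1L
    y <- stats::runif(1, margin, H - 1 - margin)
    x <- stats::runif(1, margin, W - 1 - margin)
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - y)^2 + (centers[, 2] - x)^2)) >=
          config$min_center_sep_px) {
      centers <- rbind(centers, c(y, x))
      r <- stats::rnorm(1, config$nucleus_radius_px[1], config$nucleus_radius_px[2])
      radii <- c(radii, max(2, r))
    }
  }
  # true cell label mask: pixels within cell_radius of a centre, nearest wins
  mask <- matrix(0L, H, W)
  if (config$n_cells > 0) {
    best <- matrix(Inf, H, W)
    for (i in seq_len(nrow(centers))) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      r <- config$cell_radius_px
      y0 <- max(0, floor(cy - r)); y1 <- min(H - 1, ceiling(cy + r))
      x0 <- max(0, floor(cx - r)); x1 <- min(W - 1, ceiling(cx + r))
      ys <- y0:y1; xs <- x0:x1
      d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      sel <- d2 <= r^2 & d2 < best[ys + 1, xs + 1]
      sub <- mask[ys + 1, xs + 1]; sub[sel] <- i
      mask[ys + 1, xs + 1] <- sub
      bsub <- best[ys + 1, xs + 1]; bsub[sel] <- d2[sel]
      best[ys + 1, xs + 1] <- bsub
    }
  }
  list(H = H, W = W,
       centers = centers, nucleus_radii = radii, cell_mask = mask)
}

# Add an isotropic Gaussian of peak `amp` at continuous 0-based (y, x).
.add_gaussian <- function(canvas, y, x, sigma, amp) {
  r <- ceiling(3.5 * sigma)
  H <- nrow(canvas); W <- ncol(canvas)
  y0 <- max(0, floor(y) - r); y1 <- min(H - 1, floor(y) + r)
  x0 <- max(0, floor(x) - r); x1 <- min(W - 1, floor(x) + r)
  if (y0 > y1 || x0 > x1) return(canvas)
  ys <- y0:y1; xs <- x0:x1
  g <- amp * exp(-outer((ys - y)^2, (xs - x)^2, `+`) / (2 * sigma^2))
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + g
  canvas
}

.add_disk <- function(canvas, y, x, radius, amp) {
  H <- nrow(canvas); W <- ncol(canvas)
  y0 <- max(0, floor(y - radius)); y1 <- min(H - 1, ceiling(y + radius))
  x0 <- max(0, floor(x - radius)); x1 <- min(W - 1, ceiling(x + radius))
  ys <- y0:y1; xs <- x0:x1
  sel <- outer((ys - y)^2, (xs - x)^2, `+`) <= radius^2
  sub <- canvas[ys + 1, xs + 1]
  sub[sel] <- sub[sel] + amp
  canvas[ys + 1, xs + 1] <- sub
  canvas
}

# Draw ground-truth spots for a given geometry; returns data.frame.
.sim_spots <- function(config, codebook, geom) {
  genes <- codebook$genes
  rate <- config$spots_per_cell_per_gene * config$efficiency_scale
  out <- list()
  if (config$n_cells > 0 && rate > 0) {
    for (ci in seq_len(config$n_cells)) for (gi in seq_along(genes)) {
      n <- stats::rpois(1, rate)
      if (n == 0) next
      # uniform in the cytoplasm disk
      rr <- config$cell_radius_px * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      y <- pmin(pmax(geom$centers[ci, 1] + rr * sin(th), 0), geom$H - 1)
      x <- pmin(pmax(geom$centers[ci, 2] + rr * cos(th), 0), geom$W - 1)
      out[[length(out) + 1L]] <-
        data.frame(gene = genes[gi], y = y, x = x, cell = ci)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), y = numeric(0), x = numeric(0),
                      cell = integer(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Render clean per-(round, channel) canvases: nuclei + spots + crosstalk.
# Returns list indexed [[round]][[channel]] of float matrices (no background).
.sim_render <- function(config, codebook, geom, spots) {
  lay <- config$layout
  canv <- lapply(seq_len(lay$n_rounds), function(r)
    lapply(seq_along(lay$channel_names), function(c)
      matrix(0, geom$H, geom$W)))
  # nuclei into the nuclear channel of every round
  for (r in seq_len(lay$n_rounds)) {
    nuc <- canv[[r]][[lay$nuclear_index]]
    for (i in seq_len(nrow(geom$centers)))
      nuc <- .add_disk(nuc, geom$centers[i, 1], geom$centers[i, 2],
                       geom$nucleus_radii[i], config$nucleus_amplitude)
    canv[[r]][[lay$nuclear_index]] <- nuc
  }
  # spots into the channel(s) dictated by the codebook
  gene_idx <- match(spots$gene, codebook$genes)
  for (s in seq_len(nrow(spots))) {
    gi <- gene_idx[s]
    if (codebook$mode == "sequential") {
      r <- codebook$rounds[gi]; c <- codebook$channels[gi]
      canv[[r]][[c]] <- .add_gaussian(canv[[r]][[c]], spots$y[s], spots$x[s],
                                      config$psf_sigma_px, config$spot_amplitude)
    } else {
      bc <- codebook$barcodes[[gi]]
      for (r in seq_along(bc))
        canv[[r]][[bc[r]]] <- .add_gaussian(canv[[r]][[bc[r]]],
                                            spots$y[s], spots$x[s],
                                            config$psf_sigma_px,
                                            config$spot_amplitude)
    }
  }
  # crosstalk among signal channels
  if (config$crosstalk_fraction > 0) {
    sig <- setdiff(seq_along(lay$channel_names), lay$nuclear_index)
    for (r in seq_len(lay$n_rounds)) {
      orig <- canv[[r]]
      for (c in sig) {
        leak <- Reduce(`+`, orig[setdiff(sig, c)])
        canv[[r]][[c]] <- orig[[c]] + config$crosstalk_fraction * leak
      }
    }
  }
  canv
}

#' Simulate a complete ISS experiment
#'
#' Renders a full synthetic acquisition — nuclei, RCP spots per the codebook,
#' crosstalk, overlapping tiles with integer stage jitter, z-stacks with one
#' in-focus plane, background and Gaussian noise, clipped to 16-bit — and
#' returns it together with complete ground truth.
#'
#' @param config A [simulation_config()].
#' @param codebook An [codebook_sequential()] or [codebook_combinatorial()]
#'   whose channels are signal channels of `config$layout`.
#' @return List with elements:
#'   \describe{
#'     \item{tiles}{An `iss_tileset` of integer z-stacks.}
#'     \item{truth}{Ground truth: `spots` (gene, y, x, owning cell;
#'       stitched 0-based coordinates), `cell_mask` (integer label image),
#'       `cell_centers`, `nucleus_radii`, `tile_offsets` (true 0-based canvas
#'       offsets per tile, jitter included), `counts` (cell x gene matrix of
#'       true spot tallies), and `clean_canvases[[round]][[channel]]` — the
#'       noise-free pre-partition canvas (signal + background, clipped and
#'       rounded exactly as tiles are).}
#'   }
#' @export
simulate_experiment <- function(config, codebook) {
  validate_codebook(codebook, config$layout)
  set.seed(config$seed)
  geom <- .sim_geometry(config)
  spots <- .sim_spots(config, codebook, geom)
  .sim_finish(config, codebook, geom, spots)
}

# Tiling, z-expansion and noise; shared by simulate_experiment and
# paired_condition_fixture.
.sim_finish <- function(config, codebook, geom, spots) {
  lay <- config$layout
  canv <- .sim_render(config, codebook, geom, spots)
  clean <- lapply(canv, function(by_ch) lapply(by_ch, function(m) {
    m <- round(m + config$background_level)
    m[m < 0] <- 0; m[m > 65535] <- 65535
    storage.mode(m) <- "integer"
    m
  }))
  off <- nominal_offsets(lay)
  j <- config$tile_offset_jitter_px
  jit_y <- if (j > 0) sample(-j:j, nrow(off), replace = TRUE) else rep(0L, nrow(off))
  jit_x <- if (j > 0) sample(-j:j, nrow(off), replace = TRUE) else rep(0L, nrow(off))
  true_y <- pmin(pmax(off$y0 + jit_y, 0L), geom$H - lay$tile_height_px)
  true_x <- pmin(pmax(off$x0 + jit_x, 0L), geom$W - lay$tile_width_px)
  focus <- (lay$z_steps + 1L) %/% 2L
  stacks <- list()
  for (t in seq_len(nrow(off))) for (r in seq_len(lay$n_rounds))
    for (c in seq_along(lay$channel_names)) {
      crop <- canv[[r]][[c]][true_y[t] + seq_len(lay$tile_height_px),
                             true_x[t] + seq_len(lay$tile_width_px),
                             drop = FALSE]
      planes <- vector("list", lay$z_steps)
      for (z in seq_len(lay$z_steps)) {
        p <- if (z == focus) crop else matrix(0, lay$tile_height_px, lay$tile_width_px)
        p <- p + config$background_level
        if (config$gaussian_noise_sd > 0)
          p <- p + matrix(stats::rnorm(length(p), 0, config$gaussian_noise_sd),
                          nrow(p), ncol(p))
        p <- round(p)
        p[p < 0] <- 0; p[p > 65535] <- 65535
        storage.mode(p) <- "integer"
        planes[[z]] <- p
      }
      stacks[[.stack_key(t, r, c)]] <- planes
    }
  counts <- matrix(0L, config$n_cells, length(codebook$genes),
                   dimnames = list(NULL, codebook$genes))
  if (nrow(spots) > 0) {
    tab <- table(factor(spots$cell, levels = seq_len(config$n_cells)),
                 factor(spots$gene, levels = codebook$genes))
    counts <- matrix(as.integer(tab), nrow = config$n_cells,
                     dimnames = list(NULL, codebook$genes))
  }
  list(tiles = tileset(stacks, lay),
       truth = list(spots = spots,
                    cell_mask = geom$cell_mask,
                    cell_centers = geom$centers,
                    nucleus_radii = geom$nucleus_radii,
                    tile_offsets = data.frame(tile = off$tile,
                                              y0 = true_y, x0 = true_x),
                    counts = counts,
                    clean_canvases = clean))
}

#' Simulate two conditions sharing cell geometry with a known rate ratio
#'
#' Generates a pair of experiments on identical cells and tile geometry where
#' the second condition's per-gene spot rates are exactly `ratio` times the
#' first's. Used to test recovery of a detection-efficiency slope by
#' regression of condition-B totals on condition-A totals.
#'
#' @param config A [simulation_config()] describing condition A.
#' @param codebook Codebook shared by both conditions.
#' @param ratio Positive rate multiplier applied to condition B.
#' @return List with elements `reference` and `boosted`, each as returned by
#'   [simulate_experiment()], plus `ratio`.
#' @export
paired_condition_fixture <- function(config, codebook, ratio) {
  stopifnot(ratio > 0)
  validate_codebook(codebook, config$layout)
  set.seed(config$seed)
  geom <- .sim_geometry(config)
  cfg_b <- config
  cfg_b$efficiency_scale <- config$efficiency_scale * ratio
  set.seed((config$seed + 101L) %% .Machine$integer.max)
  spots_a <- .sim_spots(config, codebook, geom)
  ref <- .sim_finish(config, codebook, geom, spots_a)
  set.seed((config$seed + 202L) %% .Machine$integer.max)
  spots_b <- .sim_spots(cfg_b, codebook, geom)
  boost <- .sim_finish(cfg_b, codebook, geom, spots_b)
  list(reference = ref, boosted = boost, ratio = ratio)
}

#' Simulate a cell mixture count matrix with planted populations
#'
#' Matrix-level generator for clustering validation: `k_populations`
#' populations of cells, each with a disjoint block of marker genes expressed
#' at `marker_rate` on top of a `base_rate` background, counts Poisson.
#'
#' @param n_cells Total number of cells (split evenly across populations).
#' @param k_populations Number of planted populations.
#' @param markers_per_population Marker genes private to each population.
#' @param base_rate Background Poisson rate of every gene in every cell.
#' @param marker_rate Poisson rate of a population's own markers.
#' @param seed Integer seed.
#' @return List: `counts` (cells x genes integer matrix), `labels`
#'   (true population of each cell, 1-based).
#' @export
simulate_cell_mixture <- function(n_cells = 200L, k_populations = 2L,
                                  markers_per_population = 5L,
                                  base_rate = 0.5, marker_rate = 10,
                                  seed = 1L) {
  stopifnot(n_cells >= k_populations, k_populations >= 1)
  set.seed(seed)
  n_genes <- k_populations * markers_per_population
  labels <- rep(seq_len(k_populations), length.out = n_cells)
  counts <- matrix(stats::rpois(n_cells * n_genes, base_rate), n_cells, n_genes)
  for (k in seq_len(k_populations)) {
    gcols <- (k - 1L) * markers_per_population + seq_len(markers_per_population)
    rows <- which(labels == k)
    counts[rows, gcols] <- stats::rpois(length(rows) * length(gcols), marker_rate)
  }
  colnames(counts) <- sprintf("gene%02d", seq_len(n_genes))
  list(counts = counts, labels = labels)
}
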