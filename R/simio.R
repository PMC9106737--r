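# Coordinate convention used throughout the package:
#   pixel coordinates are 0-based, row = y, col = x, origin at the stitched
#   canvas top-left; tile rectangles are half-open [y0, y1) x [x0, x1).
# R matrices are 1-based, so matrix access always goes through y+1 / x+1.

#' Describe the acquisition geometry of a tiled, multi-round experiment
#'
#' An acquisition layout records the tile grid, tile size, overlap fraction,
#' imaging rounds, channel list (exactly one channel is the nuclear/DAPI
#' channel) and the number of z-planes per stack. It is consumed by the
#' simulator, the tile readers and the stitcher.
#'
#' @param grid_rows,grid_cols Tile grid dimensions (counts >= 1).
#' @param tile_height_px,tile_width_px Tile size in pixels.
#' @param overlap_fraction Fraction of each tile dimension shared with the
#'   neighbouring tile, in `[0, 0.5)`. Default 0.1 (10% overlap).
#' @param n_rounds Number of imaging rounds (>= 1).
#' @param channel_names Ordered character vector of channel names.
#' @param nuclear_channel Name of the nuclear (DAPI) channel; must occur
#'   exactly once in `channel_names`.
#' @param z_steps Number of z-planes acquired per tile/round/channel.
#' @return An object of class `iss_layout`.
#' @export
acquisition_layout <- function(grid_rows = 2L, grid_cols = 2L,
                               tile_height_px = 256L, tile_width_px = 256L,
                               overlap_fraction = 0.1,
                               n_rounds = 1L,
                               channel_names = c("DAPI", "ch1", "ch2", "ch3", "ch4"),
                               nuclear_channel = "DAPI",
                               z_steps = 3L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1,
            tile_height_px >= 16, tile_width_px >= 16,
            overlap_fraction >= 0, overlap_fraction < 0.5,
            n_rounds >= 1, z_steps >= 1,
            length(channel_names) >= 2)
  if (sum(channel_names == nuclear_channel) != 1L)
    stop("exactly one channel must be flagged as nuclear; got '",
         nuclear_channel, "' among [", paste(channel_names, collapse = ", "), "]")
  overlap_y <- as.integer(round(overlap_fraction * tile_height_px))
  overlap_x <- as.integer(round(overlap_fraction * tile_width_px))
  if (grid_rows > 1 && overlap_y < 1)
    stop("overlap in pixels must be >= 1 along y when grid_rows > 1")
  if (grid_cols > 1 && overlap_x < 1)
    stop("overlap in pixels must be >= 1 along x when grid_cols > 1")
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    tile_height_px = as.integer(tile_height_px),
    tile_width_px = as.integer(tile_width_px),
    overlap_fraction = overlap_fraction,
    overlap_y_px = overlap_y, overlap_x_px = overlap_x,
    n_rounds = as.integer(n_rounds),
    channel_names = as.character(channel_names),
    nuclear_channel = nuclear_channel,
    nuclear_index = which(channel_names == nuclear_channel),
    z_steps = as.integer(z_steps)
  ), class = "iss_layout")
}

#' @export
print.iss_layout <- function(x, ...) {
  cat(sprintf("iss_layout: %dx%d grid of %dx%d px tiles (%.0f%% overlap), %d round(s), %d z-steps\n",
              x$grid_rows, x$grid_cols, x$tile_height_px, x$tile_width_px,
              100 * x$overlap_fraction, x$n_rounds, x$z_steps))
  cat("  channels:", paste(x$channel_names, collapse = ", "),
      sprintf("(nuclear: %s)\n", x$nuclear_channel))
  invisible(x)
}

#' Number of tiles in a layout
#' @param layout An `iss_layout`.
#' @return Integer tile count.
#' @export
n_tiles <- function(layout) layout$grid_rows * layout$grid_cols

#' Nominal top-left offsets of every tile on the stitched canvas
#'
#' @param layout An `iss_layout`.
#' @return data.frame with columns `tile` (1-based index, row-major),
#'   `grid_row`, `grid_col`, `y0`, `x0` (0-based canvas offsets).
#' @export
nominal_offsets <- function(layout) {
  step_y <- layout$tile_height_px - layout$overlap_y_px
  step_x <- layout$tile_width_px - layout$overlap_x_px
  g <- expand.grid(grid_col = seq_len(layout$grid_cols) - 1L,
                   grid_row = seq_len(layout$grid_rows) - 1L)
  data.frame(tile = seq_len(nrow(g)),
             grid_row = g$grid_row, grid_col = g$grid_col,
             y0 = g$grid_row * step_y, x0 = g$grid_col * step_x)
}

#' Size of the stitched canvas implied by a layout
#' @param layout An `iss_layout`.
#' @return Integer vector `c(height, width)`.
#' @export
canvas_size <- function(layout) {
  off <- nominal_offsets(layout)
  c(max(off$y0) + layout$tile_height_px, max(off$x0) + layout$tile_width_px)
}

# ---- Codebook ---------------------------------------------------------------

#' Build a sequential (one gene per round x channel) codebook
#'
#' In sequential decoding every gene is probed in one dedicated
#' (round, channel) slot, so gene identity is a direct lookup; this is the
#' scheme used for low-plex panels read in a single cycle and for larger
#' panels probed over many rounds.
#'
#' @param genes Character vector of gene names.
#' @param rounds Integer vector of round indices (1-based), one per gene.
#' @param channels Integer vector of signal-channel indices (1-based, indexing
#'   into the layout's channel list; must not be the nuclear channel), one per
#'   gene.
#' @param gene_id_tags Optional character vector of 20-character probe
#'   identifier strings, one per gene.
#' @return An object of class `iss_codebook` with `mode = "sequential"`.
#' @export
codebook_sequential <- function(genes, rounds, channels, gene_id_tags = NULL) {
  stopifnot(length(genes) == length(rounds), length(genes) == length(channels),
            !anyDuplicated(genes))
  key <- paste(rounds, channels, sep = ":")
  if (anyDuplicated(key))
    stop("duplicated (round, channel) assignment in sequential codebook")
  if (!is.null(gene_id_tags)) {
    stopifnot(length(gene_id_tags) == length(genes))
    if (any(nchar(gene_id_tags) != 20L))
      stop("gene_id_tags must be 20-character identifiers")
  }
  structure(list(mode = "sequential",
                 genes = as.character(genes),
                 rounds = as.integer(rounds),
                 channels = as.integer(channels),
                 gene_id_tags = gene_id_tags),
            class = "iss_codebook")
}

#' Build a combinatorial (multi-cycle channel barcode) codebook
#'
#' @param genes Character vector of gene names.
#' @param barcodes List (or matrix with one row per gene) of signal-channel
#'   index sequences, all of identical length `n_cycles >= 2`.
#' @param gene_id_tags Optional 20-character identifier strings per gene.
#' @return An object of class `iss_codebook` with `mode = "combinatorial"`.
#' @export
codebook_combinatorial <- function(genes, barcodes, gene_id_tags = NULL) {
  if (is.matrix(barcodes))
    barcodes <- lapply(seq_len(nrow(barcodes)), function(i) barcodes[i, ])
  stopifnot(length(genes) == length(barcodes), !anyDuplicated(genes))
  lens <- lengths(barcodes)
  if (length(unique(lens)) != 1L || lens[1] < 2L)
    stop("combinatorial barcodes must all have the same length n_cycles >= 2")
  key <- vapply(barcodes, paste, "", collapse = "-")
  if (anyDuplicated(key)) stop("duplicated barcode in combinatorial codebook")
  if (!is.null(gene_id_tags)) {
    stopifnot(length(gene_id_tags) == length(genes))
    if (any(nchar(gene_id_tags) != 20L))
      stop("gene_id_tags must be 20-character identifiers")
  }
  structure(list(mode = "combinatorial",
                 genes = as.character(genes),
                 barcodes = lapply(barcodes, as.integer),
                 n_cycles = as.integer(lens[1]),
                 gene_id_tags = gene_id_tags),
            class = "iss_codebook")
}

#' @export
print.iss_codebook <- function(x, ...) {
  cat(sprintf("iss_codebook (%s): %d genes\n", x$mode, length(x$genes)))
  invisible(x)
}

#' Check a codebook against a layout
#'
#' Verifies that every channel index used by the codebook refers to a
#' non-nuclear channel of the layout and that rounds/cycles fit in
#' `layout$n_rounds`.
#' @param codebook An `iss_codebook`.
#' @param layout An `iss_layout`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_codebook <- function(codebook, layout) {
  ch <- if (codebook$mode == "sequential") codebook$channels
        else unlist(codebook$barcodes)
  if (any(ch == layout$nuclear_index))
    stop("codebook assigns the nuclear channel to a gene")
  if (any(ch < 1L | ch > length(layout$channel_names)))
    stop("codebook channel index outside the layout's channel list")
  rds <- if (codebook$mode == "sequential") codebook$rounds else codebook$n_cycles
  if (any(rds > layout$n_rounds))
    stop("codebook uses more rounds than the layout provides")
  invisible(TRUE)
}

# ---- RunConfig --------------------------------------------------------------

#' Default run configuration
#'
#' Every tunable of the downstream stages, as a flat named list. Values are
#' documented here once and consumed by the stage commands.
#'
#' \describe{
#'   \item{tophat_radius_px}{Disk radius of the top-hat structuring element (px). Default 3.}
#'   \item{intensity_threshold}{Spot detection intensity threshold on the
#'     top-hat filtered canvas (intensity units). Default 2500.}
#'   \item{size_min_px,size_max_px}{Connected-component area bounds for spots. Default 2 and 100.}
#'   \item{quality_floor}{Denominator floor of the channel-purity quality q (intensity units). Default 1.}
#'   \item{k}{Distance penalty of the barcode score Q, per pixel. Default 0.2.}
#'   \item{max_link_radius_px}{Cross-cycle nearest-neighbour search radius (px). Default 5.}
#'   \item{search_margin_px}{Offset search half-width for stitching/alignment (px). Default 8.}
#'   \item{dapi_threshold}{Nucleus segmentation intensity threshold. Default 2000.}
#'   \item{min_nucleus_px}{Minimum nucleus area kept (px). Default 20.}
#'   \item{max_expansion_px}{Cap on nucleus-to-cell expansion (px). Default 15.}
#'   \item{density_threshold}{Foreground threshold for density quantification. Default 500.}
#'   \item{min_counts_per_cell}{Cell filter: minimum total counts. Default 2.}
#'   \item{min_cells_per_gene}{Gene filter: minimum expressing cells. Default 2.}
#'   \item{n_neighbors}{kNN graph degree for clustering. Default 15.}
#'   \item{resolution}{Leiden resolution parameter. Default 1.0.}
#'   \item{n_pcs}{Principal components before the kNN graph (0 disables). Default 20.}
#'   \item{seed}{Random seed governing all stochastic stages. Default 1.}
#' }
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    tophat_radius_px = 3L,
    intensity_threshold = 2500,
    size_min_px = 2L,
    size_max_px = 100L,
    quality_floor = 1,
    k = 0.2,
    max_link_radius_px = 5,
    search_margin_px = 8L,
    dapi_threshold = 2000,
    min_nucleus_px = 20L,
    max_expansion_px = 15L,
    density_threshold = 500,
    min_counts_per_cell = 2L,
    min_cells_per_gene = 2L,
    n_neighbors = 15L,
    resolution = 1.0,
    n_pcs = 20L,
    seed = 1L
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file take their documented defaults; unknown keys are
#' rejected, all reported at once.
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list applied on top of the file
#'   (precedence: overrides > file > default).
#' @return Complete named list of config values.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  apply_keys <- function(cfg, vals, src) {
    if (is.null(vals)) return(cfg)
    bad <- setdiff(names(vals), names(cfg))
    if (length(bad))
      stop("unknown config key(s) in ", src, ": ", paste(bad, collapse = ", "))
    cfg[names(vals)] <- vals
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_keys(cfg, yaml::read_yaml(path), path)
  }
  apply_keys(cfg, overrides, "overrides")
}

#' Write a run configuration to YAML
#' @param config Named list as returned by [read_run_config()].
#' @param path Output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# ---- Tile stacks ------------------------------------------------------------

#' File name of one tile stack
#'
#' The on-disk pattern is `t{tile}_r{round}_c{channel}.tif` with 1-based
#' indices, one multi-page 16-bit TIFF per (tile, round, channel), pages being
#' z-planes.
#' @param tile,round,channel 1-based indices.
#' @return File name (no directory).
#' @export
tile_filename <- function(tile, round, channel) {
  sprintf("t%d_r%d_c%d.tif", tile, round, channel)
}

.stack_key <- function(tile, round, channel) {
  paste(tile, round, channel, sep = "_")
}

#' Retrieve one z-stack from a TileSet
#' @param tileset An `iss_tileset`.
#' @param tile,round,channel 1-based indices.
#' @return Integer matrix list (one per z-plane).
#' @export
get_stack <- function(tileset, tile, round, channel) {
  s <- tileset$stacks[[.stack_key(tile, round, channel)]]
  if (is.null(s)) stop(sprintf("no stack for tile=%d round=%d channel=%d",
                               tile, round, channel))
  s
}

#' Construct a TileSet from stacks in memory
#' @param stacks Named list keyed `tile_round_channel`, each a list of integer
#'   matrices (z-planes).
#' @param layout An `iss_layout`.
#' @return An `iss_tileset`.
#' @export
tileset <- function(stacks, layout) {
  structure(list(stacks = stacks, layout = layout), class = "iss_tileset")
}

#' @export
print.iss_tileset <- function(x, ...) {
  cat(sprintf("iss_tileset: %d stacks (%d tiles x %d rounds x %d channels)\n",
              length(x$stacks), n_tiles(x$layout), x$layout$n_rounds,
              length(x$layout$channel_names)))
  invisible(x)
}

#' Write a TileSet to a directory of multi-page 16-bit TIFFs
#'
#' Pixel values must be integers in `[0, 65535]`; they are stored losslessly.
#' @param tileset An `iss_tileset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tileset <- function(tileset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lay <- tileset$layout
  for (t in seq_len(n_tiles(lay))) for (r in seq_len(lay$n_rounds))
    for (c in seq_along(lay$channel_names)) {
      st <- get_stack(tileset, t, r, c)
      planes <- lapply(st, function(p) p / 65535)
      tiff::writeTIFF(planes, file.path(dir, tile_filename(t, r, c)),
                      bits.per.sample = 16L, compression = "none")
    }
  invisible(dir)
}

#' Read a directory of tile stacks into a TileSet
#'
#' Expects one file per (tile, round, channel) named by [tile_filename()],
#' each a z-stack of `layout$z_steps` pages. Pixel values are returned as
#' acquired (16-bit unsigned, no rescaling; 8-bit files are upcast to the
#' 16-bit range). Missing files, extra files and shape mismatches are hard
#' errors naming the offending index.
#'
#' @param dir Directory containing the TIFF files.
#' @param layout An `iss_layout` describing the expected geometry.
#' @return An `iss_tileset`.
#' @export
read_tile_stack <- function(dir, layout) {
  if (!dir.exists(dir)) stop("tile directory not found: ", dir)
  expected <- character(0)
  stacks <- list()
  for (t in seq_len(n_tiles(layout))) for (r in seq_len(layout$n_rounds))
    for (c in seq_along(layout$channel_names)) {
      fn <- tile_filename(t, r, c)
      expected <- c(expected, fn)
      path <- file.path(dir, fn)
      if (!file.exists(path))
        stop(sprintf("missing tile stack for tile=%d round=%d channel=%d: %s",
                     t, r, c, fn))
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) != layout$z_steps)
        stop(sprintf("stack %s has %d z-planes, layout expects %d",
                     fn, length(pages), layout$z_steps))
      pages <- lapply(pages, function(p) {
        if (!is.matrix(p)) stop(sprintf("stack %s: pages must be single-channel", fn))
        if (!identical(dim(p), c(layout$tile_height_px, layout$tile_width_px)))
          stop(sprintf("stack %s is %dx%d, layout expects %dx%d",
                       fn, nrow(p), ncol(p),
                       layout$tile_height_px, layout$tile_width_px))
        if (max(p) <= 255L) {  # 8-bit file: upcast to the 16-bit scale
          attr_bps <- attr(p, "bits.per.sample")
          if (!is.null(attr_bps) && attr_bps == 8L) p <- p * 257L
        }
        storage.mode(p) <- "integer"
        p
      })
      stacks[[.stack_key(t, r, c)]] <- pages
    }
  extra <- setdiff(list.files(dir, pattern = "\\.tif$"), expected)
  if (length(extra))
    stop("unexpected tile file(s) in ", dir, ": ", paste(extra, collapse = ", "))
  tileset(stacks, layout)
}

# ---- Spot tables ------------------------------------------------------------

.spot_cols <- c("spot_id", "round", "channel", "y", "x", "intensity",
                "area", "quality", "gene", "cell_id", "Q")

#' Create an empty spot table
#' @return Zero-row data.frame with the canonical spot-table schema.
#' @export
empty_spot_table <- function() {
  data.frame(spot_id = integer(0), round = integer(0), channel = integer(0),
             y = numeric(0), x = numeric(0), intensity = numeric(0),
             area = integer(0), quality = numeric(0), gene = character(0),
             cell_id = integer(0), Q = numeric(0), stringsAsFactors = FALSE)
}

.as_spot_table <- function(df) {
  for (col in .spot_cols) if (is.null(df[[col]])) {
    df[[col]] <- switch(col, gene = NA_character_,
                        y = , x = , intensity = , quality = , Q = NA_real_,
                        NA_integer_)
  }
  df[, .spot_cols, drop = FALSE]
}

#' Write a spot table to CSV
#'
#' Columns `spot_id,round,channel,y,x,intensity,area,quality,gene,cell_id,Q`;
#' floating point fields are written with 17 significant digits so that
#' read-back is lossless.
#' @param spots Spot data.frame.
#' @param path Output CSV path.
#' @export
write_spot_table <- function(spots, path) {
  spots <- .as_spot_table(spots)
  out <- spots
  for (col in c("y", "x", "intensity", "quality", "Q"))
    out[[col]] <- ifelse(is.na(spots[[col]]), "",
                         sprintf("%.17g", spots[[col]]))
  for (col in c("spot_id", "round", "channel", "area", "cell_id"))
    out[[col]] <- ifelse(is.na(spots[[col]]), "", as.character(spots[[col]]))
  out$gene <- ifelse(is.na(spots$gene), "", spots$gene)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a spot table from CSV
#' @param path CSV file written by [write_spot_table()].
#' @return Spot data.frame with the canonical schema.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  first <- readLines(path, n = 1L)
  if (!identical(strsplit(first, ",")[[1]], .spot_cols))
    stop("malformed spot table at line 1: header mismatch in ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(spot_id = "integer", round = "integer",
                                       channel = "integer", y = "numeric",
                                       x = "numeric", intensity = "numeric",
                                       area = "integer", quality = "numeric",
                                       gene = "character", cell_id = "integer",
                                       Q = "numeric"),
                        na.strings = "")
  if (nrow(df) == 0) return(empty_spot_table())
  .as_spot_table(df)
}

# ---- Expression output ------------------------------------------------------

#' Write a cell-by-gene quantification to MatrixMarket + CSV sidecars
#'
#' Writes `matrix.mtx` (cells are rows), `cells.csv`
#' (`cell_id,centroid_y,centroid_x,area_px`) and `genes.csv` (`gene`).
#' @param quant An `iss_quant` (see [build_matrix()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(quant, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(quant$matrix, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  cells <- quant$cells
  utils::write.table(
    data.frame(cell_id = cells$cell_id,
               centroid_y = sprintf("%.17g", cells$centroid_y),
               centroid_x = sprintf("%.17g", cells$centroid_x),
               area_px = cells$area_px),
    file.path(dir, "cells.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = colnames(quant$matrix)),
                     file.path(dir, "genes.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
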