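# End-to-end pipeline driver and file-based stage commands.
#
# Each cmd_* stage consumes and produces the documented formats inside one
# run directory, so stages can be run alone or chained by cmd_run_all(),
# which also writes a provenance manifest (stage order, config hash, paths,
# per-stage diagnostics). The in-memory composition lives in
# process_experiment() and is what the stage commands call.

#' Serialize an acquisition layout to YAML
#' @param layout An `iss_layout`.
#' @param path Output file.
#' @export
write_layout <- function(layout, path) {
  yaml::write_yaml(list(
    grid_rows = layout$grid_rows, grid_cols = layout$grid_cols,
    tile_height_px = layout$tile_height_px,
    tile_width_px = layout$tile_width_px,
    overlap_fraction = layout$overlap_fraction,
    n_rounds = layout$n_rounds,
    channel_names = layout$channel_names,
    nuclear_channel = layout$nuclear_channel,
    z_steps = layout$z_steps), path)
  invisible(path)
}

#' Read an acquisition layout from YAML
#' @param path YAML file written by [write_layout()].
#' @return An `iss_layout`.
#' @export
read_layout <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(acquisition_layout, v)
}

#' Serialize a codebook to YAML
#' @param codebook An `iss_codebook`.
#' @param path Output file.
#' @export
write_codebook <- function(codebook, path) {
  v <- list(mode = codebook$mode, genes = codebook$genes)
  if (codebook$mode == "sequential") {
    v$rounds <- codebook$rounds; v$channels <- codebook$channels
  } else v$barcodes <- codebook$barcodes
  if (!is.null(codebook$gene_id_tags)) v$gene_id_tags <- codebook$gene_id_tags
  yaml::write_yaml(v, path)
  invisible(path)
}

#' Read a codebook from YAML
#' @param path YAML file written by [write_codebook()].
#' @return An `iss_codebook`.
#' @export
read_codebook <- function(path) {
  v <- yaml::read_yaml(path)
  if (v$mode == "sequential")
    codebook_sequential(v$genes, unlist(v$rounds), unlist(v$channels),
                        v$gene_id_tags)
  else codebook_combinatorial(v$genes, v$barcodes, v$gene_id_tags)
}

.write_canvas <- function(canvas, path) {
  m <- round(canvas); m[m < 0] <- 0; m[m > 65535] <- 65535
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

.read_canvas <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Stitch and align a TileSet into per-(round, channel) canvases
#'
#' Projects every stack, estimates tile offsets once on the reference
#' round's nuclear channel, applies them to every round and channel, then
#' aligns rounds to the reference by global translation of each round's
#' nuclear canvas.
#'
#' @param tiles An `iss_tileset`.
#' @param config Run configuration list (uses `search_margin_px`).
#' @return List: `canvases[[round]][[channel]]`, `stitch_layout`,
#'   `shifts`, `diagnostics`.
#' @export
stitch_and_align <- function(tiles, config = default_run_config()) {
  lay <- tiles$layout
  proj <- project_tileset(tiles)
  # composite of all channels of the reference round: overlap strips then
  # carry both nuclei and RCP texture, not just the (sparser) DAPI content
  ref_tiles <- lapply(proj, function(t) Reduce(pmax, t[[1]]))
  st <- stitch(ref_tiles, lay, search_margin_px = config$search_margin_px)
  canvases <- lapply(seq_len(lay$n_rounds), function(r)
    lapply(seq_along(lay$channel_names), function(c)
      apply_stitch(lapply(proj, function(t) t[[r]][[c]]), st, lay)))
  al <- align_rounds(canvases, lay$nuclear_index,
                     search_margin_px = config$search_margin_px)
  list(canvases = al$canvases, stitch_layout = st, shifts = al$shifts,
       diagnostics = st$diagnostics)
}

#' Run the full pipeline on an in-memory TileSet
#'
#' Stitch and align, top-hat filter, detect and quality-score spots on every
#' round, decode (sequentially or combinatorially per the codebook mode),
#' segment nuclei and expand to cells, assign spots, and build the filtered
#' cell x gene matrix.
#'
#' @param tiles An `iss_tileset`.
#' @param codebook An `iss_codebook`.
#' @param config Run configuration list (see [default_run_config()]).
#' @return List with `canvases`, `filtered` (top-hat canvases), `spots`
#'   (per-round tables), `decoded` (spot table with genes), `decode_diag`,
#'   `nuclei`, `cells`, `assigned`, `quant` (unfiltered `iss_quant`),
#'   `stitch_layout`, `shifts`.
#' @export
process_experiment <- function(tiles, codebook, config = default_run_config()) {
  lay <- tiles$layout
  sa <- stitch_and_align(tiles, config)
  filtered <- lapply(sa$canvases, function(by_ch)
    lapply(by_ch, tophat_filter, radius_px = config$tophat_radius_px))
  per_round <- lapply(seq_len(lay$n_rounds), function(r)
    detect_round(filtered[[r]], lay, config$intensity_threshold,
                 config$size_min_px, config$size_max_px, round = r,
                 quality_floor = config$quality_floor))
  if (codebook$mode == "sequential") {
    all_spots <- do.call(rbind, per_round)
    if (nrow(all_spots)) all_spots$spot_id <- seq_len(nrow(all_spots))
    decoded <- assign_sequential(all_spots, codebook)
    decode_diag <- list(n_candidates = nrow(decoded),
                        n_called = sum(decoded$gene != "unassigned"))
  } else {
    cands <- link_cycles(per_round[seq_len(codebook$n_cycles)],
                         max_radius_px = config$max_link_radius_px)
    fc <- filter_and_call(cands, codebook, k = config$k)
    decoded <- fc$spots
    decode_diag <- fc$diagnostics
  }
  dapi <- sa$canvases[[1]][[lay$nuclear_index]]
  nuclei <- segment_nuclei(dapi, config$dapi_threshold, config$min_nucleus_px)
  cells <- expand_to_cells(nuclei, config$max_expansion_px)
  assigned <- assign_spots(decoded, cells)
  quant <- build_matrix(assigned, cells, codebook$genes)
  list(canvases = sa$canvases, filtered = filtered, spots = per_round,
       decoded = decoded, decode_diag = decode_diag, nuclei = nuclei,
       cells = cells, assigned = assigned, quant = quant,
       stitch_layout = sa$stitch_layout, shifts = sa$shifts)
}

# ---- File-based stage commands ---------------------------------------------

.log_stage <- function(stage, t0, ...) {
  msg <- paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
               collapse = " ")
  message(sprintf("[rcpdecode] stage=%s wall_s=%.2f %s", stage,
                  as.numeric(Sys.time()) - t0, msg))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a default fixture into a run directory
#'
#' Writes tiles, layout, codebook, config and ground truth (spots CSV, cell
#' label mask TIFF, tile offsets CSV) under `dir`.
#' @param dir Run directory (created).
#' @param mode `"sequential"` or `"combinatorial"` default fixture.
#' @param seed Simulation seed.
#' @param config Run configuration stored with the run.
#' @return Invisible list with the simulated experiment.
#' @export
cmd_simulate <- function(dir, mode = c("sequential", "combinatorial"),
                         seed = 1L, config = default_run_config()) {
  t0 <- as.numeric(Sys.time())
  mode <- match.arg(mode)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lay <- acquisition_layout(n_rounds = if (mode == "sequential") 1L else 2L)
  cb <- if (mode == "sequential")
    codebook_sequential(c("Cd24a", "Lamp5", "Slc17a7", "Mbp"),
                        rounds = rep(1L, 4), channels = 2:5)
  else default_combinatorial_codebook()
  sim <- simulate_experiment(simulation_config(layout = lay, seed = seed), cb)
  write_tileset(sim$tiles, file.path(dir, "tiles"))
  write_layout(lay, file.path(dir, "layout.yaml"))
  write_codebook(cb, file.path(dir, "codebook.yaml"))
  write_run_config(config, file.path(dir, "config.yaml"))
  tr <- file.path(dir, "truth"); dir.create(tr, showWarnings = FALSE)
  utils::write.csv(sim$truth$spots, file.path(tr, "spots.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$tile_offsets, file.path(tr, "tile_offsets.csv"),
                   row.names = FALSE)
  tiff::writeTIFF(sim$truth$cell_mask / 65535, file.path(tr, "cell_mask.tif"),
                  bits.per.sample = 16L)
  .log_stage("simulate", t0, tiles = n_tiles(lay),
             true_spots = nrow(sim$truth$spots))
  invisible(sim)
}

#' Eight-gene, two-cycle combinatorial codebook over four signal channels
#' @return An `iss_codebook`.
#' @export
default_combinatorial_codebook <- function() {
  codebook_combinatorial(
    sprintf("gene%d", 1:8),
    list(c(2L, 3L), c(3L, 2L), c(4L, 5L), c(5L, 4L),
         c(2L, 4L), c(3L, 5L), c(4L, 2L), c(5L, 3L)))
}

#' Stitch + align stage: tiles/ -> canvases/
#' @param dir Run directory holding `tiles/`, `layout.yaml`, `config.yaml`.
#' @return Invisible stage diagnostics.
#' @export
cmd_stitch <- function(dir) {
  t0 <- as.numeric(Sys.time())
  .require_inputs(dir, "stitch", c("layout.yaml", "config.yaml", "tiles"))
  lay <- read_layout(file.path(dir, "layout.yaml"))
  config <- read_run_config(file.path(dir, "config.yaml"))
  tiles <- read_tile_stack(file.path(dir, "tiles"), lay)
  sa <- stitch_and_align(tiles, config)
  cd <- file.path(dir, "canvases"); dir.create(cd, showWarnings = FALSE)
  for (r in seq_len(lay$n_rounds)) for (c in seq_along(lay$channel_names))
    .write_canvas(sa$canvases[[r]][[c]],
                  file.path(cd, sprintf("r%d_c%d.tif", r, c)))
  utils::write.csv(sa$stitch_layout$offsets,
                   file.path(cd, "stitch_offsets.csv"), row.names = FALSE)
  utils::write.csv(sa$shifts, file.path(cd, "round_shifts.csv"),
                   row.names = FALSE)
  .log_stage("stitch", t0, n_fallback = sa$diagnostics$n_fallback)
  invisible(sa$diagnostics)
}

.require_inputs <- function(dir, stage, names) {
  missing <- names[!file.exists(file.path(dir, names))]
  if (length(missing))
    stop("stage ", stage, ": missing input(s) in ", dir, ": ",
         paste(missing, collapse = ", "))
}

.read_canvases <- function(dir, lay) {
  lapply(seq_len(lay$n_rounds), function(r)
    lapply(seq_along(lay$channel_names), function(c)
      .read_canvas(file.path(dir, "canvases", sprintf("r%d_c%d.tif", r, c)))))
}

#' Detection stage: canvases/ -> spots/
#' @param dir Run directory.
#' @return Invisible list of per-round spot tables.
#' @export
cmd_detect <- function(dir) {
  t0 <- as.numeric(Sys.time())
  .require_inputs(dir, "detect", c("layout.yaml", "config.yaml", "canvases"))
  lay <- read_layout(file.path(dir, "layout.yaml"))
  config <- read_run_config(file.path(dir, "config.yaml"))
  canv <- .read_canvases(dir, lay)
  sd_dir <- file.path(dir, "spots"); dir.create(sd_dir, showWarnings = FALSE)
  per_round <- list()
  for (r in seq_len(lay$n_rounds)) {
    filt <- lapply(canv[[r]], tophat_filter, radius_px = config$tophat_radius_px)
    tab <- detect_round(filt, lay, config$intensity_threshold,
                        config$size_min_px, config$size_max_px, round = r,
                        quality_floor = config$quality_floor)
    write_spot_table(tab, file.path(sd_dir, sprintf("spots_r%d.csv", r)))
    per_round[[r]] <- tab
  }
  .log_stage("detect", t0, n_spots = sum(vapply(per_round, nrow, 0L)))
  invisible(per_round)
}

#' Decoding stage: spots/ -> decoded/
#' @param dir Run directory.
#' @return Invisible decode diagnostics.
#' @export
cmd_decode <- function(dir) {
  t0 <- as.numeric(Sys.time())
  .require_inputs(dir, "decode", c("layout.yaml", "config.yaml",
                                   "codebook.yaml", "spots"))
  lay <- read_layout(file.path(dir, "layout.yaml"))
  config <- read_run_config(file.path(dir, "config.yaml"))
  cb <- read_codebook(file.path(dir, "codebook.yaml"))
  per_round <- lapply(seq_len(lay$n_rounds), function(r) {
    p <- file.path(dir, "spots", sprintf("spots_r%d.csv", r))
    if (!file.exists(p)) stop("stage decode: missing input ", p)
    read_spot_table(p)
  })
  if (cb$mode == "sequential") {
    all_spots <- do.call(rbind, per_round)
    if (nrow(all_spots)) all_spots$spot_id <- seq_len(nrow(all_spots))
    decoded <- assign_sequential(all_spots, cb)
    diagn <- list(n_candidates = nrow(decoded),
                  n_called = sum(decoded$gene != "unassigned"))
  } else {
    cands <- link_cycles(per_round[seq_len(cb$n_cycles)],
                         config$max_link_radius_px)
    fc <- filter_and_call(cands, cb, k = config$k)
    decoded <- fc$spots
    diagn <- fc$diagnostics
  }
  dd <- file.path(dir, "decoded"); dir.create(dd, showWarnings = FALSE)
  write_spot_table(decoded, file.path(dd, "decoded.csv"))
  jsonlite::write_json(diagn, file.path(dd, "diagnostics.json"),
                       auto_unbox = TRUE)
  .log_stage("decode", t0, n_called = nrow(decoded))
  invisible(diagn)
}

#' Segmentation stage: canvases/ -> cells/
#' @param dir Run directory.
#' @return Invisible cell table.
#' @export
cmd_segment <- function(dir) {
  t0 <- as.numeric(Sys.time())
  .require_inputs(dir, "segment", c("layout.yaml", "config.yaml", "canvases"))
  lay <- read_layout(file.path(dir, "layout.yaml"))
  config <- read_run_config(file.path(dir, "config.yaml"))
  dapi <- .read_canvas(file.path(dir, "canvases",
                                 sprintf("r1_c%d.tif", lay$nuclear_index)))
  nuclei <- segment_nuclei(dapi, config$dapi_threshold, config$min_nucleus_px)
  cells <- expand_to_cells(nuclei, config$max_expansion_px)
  cd <- file.path(dir, "cells"); dir.create(cd, showWarnings = FALSE)
  tiff::writeTIFF(cells$labels / 65535, file.path(cd, "labels.tif"),
                  bits.per.sample = 16L)
  utils::write.csv(cells$cells, file.path(cd, "cells.csv"), row.names = FALSE)
  .log_stage("segment", t0, n_cells = nrow(cells$cells))
  invisible(cells$cells)
}

#' Quantification stage: decoded/ + cells/ -> expr/
#' @param dir Run directory.
#' @return Invisible `iss_quant`.
#' @export
cmd_quantify <- function(dir) {
  t0 <- as.numeric(Sys.time())
  .require_inputs(dir, "quantify", c("codebook.yaml", "decoded", "cells"))
  cb <- read_codebook(file.path(dir, "codebook.yaml"))
  decoded <- read_spot_table(file.path(dir, "decoded", "decoded.csv"))
  labels <- .read_canvas(file.path(dir, "cells", "labels.tif"))
  cells <- list(labels = labels,
                cells = utils::read.csv(file.path(dir, "cells", "cells.csv")))
  assigned <- assign_spots(decoded, cells)
  quant <- build_matrix(assigned, cells, cb$genes)
  write_expression(quant, file.path(dir, "expr"))
  .log_stage("quantify", t0, total_counts = sum(quant$matrix))
  invisible(quant)
}

#' Clustering stage: expr/ -> expr/clusters.csv
#' @param dir Run directory.
#' @return Invisible labels.
#' @export
cmd_cluster <- function(dir) {
  t0 <- as.numeric(Sys.time())
  .require_inputs(dir, "cluster", c("config.yaml", "expr"))
  config <- read_run_config(file.path(dir, "config.yaml"))
  m <- as.matrix(Matrix::readMM(file.path(dir, "expr", "matrix.mtx")))
  cells <- utils::read.csv(file.path(dir, "expr", "cells.csv"))
  genes <- utils::read.csv(file.path(dir, "expr", "genes.csv"))
  colnames(m) <- genes$gene
  quant <- new_quant(m, cells, mode = "spot_counts")
  quant <- filter_matrix(quant, config$min_counts_per_cell,
                         config$min_cells_per_gene)
  norm <- normalize_log(quant)
  n_nb <- min(config$n_neighbors, nrow(norm) - 1L)
  labels <- cluster_cells(norm, n_neighbors = n_nb,
                          resolution = config$resolution,
                          seed = config$seed, n_pcs = config$n_pcs)
  utils::write.csv(data.frame(cell_id = quant$cells$cell_id, cluster = labels),
                   file.path(dir, "expr", "clusters.csv"), row.names = FALSE)
  .log_stage("cluster", t0, n_clusters = length(unique(labels)))
  invisible(labels)
}

#' Run every stage in order and write a provenance manifest
#'
#' Chains simulate (unless `dir` already holds `tiles/`), stitch, detect,
#' decode, segment, quantify and cluster, then writes `manifest.json` with
#' the stage order, config hash, artifact paths and per-stage key counts.
#'
#' @param dir Run directory.
#' @param mode Fixture mode if simulation is needed.
#' @param seed Simulation seed.
#' @param config Run configuration.
#' @return Invisible manifest list.
#' @export
cmd_run_all <- function(dir, mode = "sequential", seed = 1L,
                        config = default_run_config()) {
  stages <- list()
  if (!dir.exists(file.path(dir, "tiles"))) {
    cmd_simulate(dir, mode = mode, seed = seed, config = config)
    stages$simulate <- list(done = TRUE)
  }
  stages$stitch <- cmd_stitch(dir)
  spots <- cmd_detect(dir)
  stages$detect <- list(n_spots = sum(vapply(spots, nrow, 0L)))
  stages$decode <- cmd_decode(dir)
  cells <- cmd_segment(dir)
  stages$segment <- list(n_cells = nrow(cells))
  quant <- cmd_quantify(dir)
  stages$quantify <- list(total_counts = sum(quant$matrix))
  labels <- cmd_cluster(dir)
  stages$cluster <- list(n_clusters = length(unique(labels)))
  cfg <- read_run_config(file.path(dir, "config.yaml"))
  manifest <- list(
    stages = names(stages),
    config_hash = .config_hash(cfg),
    outputs = list(canvases = file.path(dir, "canvases"),
                   spots = file.path(dir, "spots"),
                   decoded = file.path(dir, "decoded"),
                   cells = file.path(dir, "cells"),
                   expr = file.path(dir, "expr")),
    diagnostics = stages)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Per-gene decoded call totals for one experiment
#'
#' Runs stitching, top-hat filtering, detection and sequential assignment and
#' tallies gene calls — the quantification used when comparing conditions
#' over regions of interest.
#' @param tiles An `iss_tileset`.
#' @param codebook Sequential `iss_codebook`.
#' @param config Run configuration list.
#' @return Named integer vector of call counts per codebook gene.
#' @export
gene_call_totals <- function(tiles, codebook, config = default_run_config()) {
  stopifnot(codebook$mode == "sequential")
  lay <- tiles$layout
  sa <- stitch_and_align(tiles, config)
  per_round <- lapply(seq_len(lay$n_rounds), function(r) {
    filt <- lapply(sa$canvases[[r]], tophat_filter,
                   radius_px = config$tophat_radius_px)
    detect_round(filt, lay, config$intensity_threshold,
                 config$size_min_px, config$size_max_px, round = r,
                 quality_floor = config$quality_floor)
  })
  spots <- do.call(rbind, per_round)
  decoded <- assign_sequential(spots, codebook)
  tab <- table(factor(decoded$gene, levels = codebook$genes))
  stats::setNames(as.integer(tab), codebook$genes)
}
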