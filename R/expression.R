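# Cell x gene quantification: build, filter, normalize, cluster, compare.

#' Construct a CellQuantification
#' @param matrix Cells x genes numeric matrix (named gene columns).
#' @param cells data.frame `cell_id`, `area_px`, `centroid_y`, `centroid_x`
#'   aligned with the matrix rows.
#' @param mode `"spot_counts"` or `"density"`.
#' @param area_divided Whether density entries have already been divided by
#'   cell area (the pipeline performs that division exactly once).
#' @return Object of class `iss_quant`.
#' @export
new_quant <- function(matrix, cells, mode = c("spot_counts", "density"),
                      area_divided = (mode[1] == "density")) {
  mode <- match.arg(mode)
  stopifnot(nrow(matrix) == nrow(cells))
  structure(list(matrix = matrix, cells = cells, mode = mode,
                 area_divided = area_divided,
                 filter_provenance = list()),
            class = "iss_quant")
}

#' @export
print.iss_quant <- function(x, ...) {
  cat(sprintf("iss_quant (%s): %d cells x %d genes, total %.4g\n",
              x$mode, nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Build the cell x gene count matrix from assigned spots
#'
#' Entry (c, g) is the number of decoded spots with that cell and gene.
#' Unassigned spots (background cell) and spots without a valid gene call
#' are excluded; genes of `gene_list` with zero counts are retained as zero
#' columns. The matrix total therefore equals the number of cell-assigned,
#' gene-called spots.
#'
#' @param assigned Spot data.frame with `gene` and `cell_id` filled.
#' @param cells A `CellLabelMask` from [expand_to_cells()].
#' @param gene_list Character vector of genes (matrix columns, in order).
#' @return An `iss_quant` in spot-count mode.
#' @export
build_matrix <- function(assigned, cells, gene_list) {
  called <- assigned[!is.na(assigned$cell_id) & !is.na(assigned$gene) &
                       !(assigned$gene %in% c("unassigned", "invalid_barcode")), ]
  extra <- setdiff(unique(called$gene), gene_list)
  if (length(extra))
    stop("gene(s) absent from gene_list: ", paste(extra, collapse = ", "))
  n <- nrow(cells$cells)
  m <- matrix(0L, n, length(gene_list), dimnames = list(NULL, gene_list))
  if (nrow(called) > 0) {
    tab <- table(factor(called$cell_id, levels = cells$cells$cell_id),
                 factor(called$gene, levels = gene_list))
    m <- matrix(as.integer(tab), nrow = n, dimnames = list(NULL, gene_list))
  }
  new_quant(m, cells$cells, mode = "spot_counts")
}

#' Filter cells then genes
#'
#' First drops cells whose total count is below `min_counts_per_cell`, then
#' drops genes expressed (nonzero) in fewer than `min_cells_per_gene` of the
#' surviving cells. Removals are recorded in the quant's filter provenance.
#'
#' @param quant An `iss_quant`.
#' @param min_counts_per_cell Minimum per-cell total (>= 0).
#' @param min_cells_per_gene Minimum expressing cells per gene (>= 0).
#' @return Filtered `iss_quant`.
#' @export
filter_matrix <- function(quant, min_counts_per_cell = 2,
                          min_cells_per_gene = 2) {
  stopifnot(min_counts_per_cell >= 0, min_cells_per_gene >= 0)
  m <- quant$matrix
  keep_cells <- rowSums(m) >= min_counts_per_cell
  m2 <- m[keep_cells, , drop = FALSE]
  keep_genes <- colSums(m2 > 0) >= min_cells_per_gene
  if (!any(keep_cells) || !any(keep_genes))
    stop("filtering removed everything; lower min_counts_per_cell/",
         "min_cells_per_gene")
  out <- quant
  out$matrix <- m2[, keep_genes, drop = FALSE]
  out$cells <- quant$cells[keep_cells, , drop = FALSE]
  out$filter_provenance <- c(quant$filter_provenance, list(list(
    min_counts_per_cell = min_counts_per_cell,
    min_cells_per_gene = min_cells_per_gene,
    cells_removed = quant$cells$cell_id[!keep_cells],
    genes_removed = colnames(m)[!keep_genes])))
  out
}

#' Normalize counts per cell and log-transform
#'
#' Scales each cell's counts to a common total (`target_sum`, default the
#' median of per-cell totals), then applies log(1 + x) elementwise. Only for
#' spot-count matrices; density matrices get their size adjustment from the
#' per-cell area division instead.
#'
#' @param quant Filtered spot-count `iss_quant`.
#' @param target_sum Common per-cell total; default median of totals.
#' @return Numeric matrix of normalized log-expression.
#' @export
normalize_log <- function(quant, target_sum = NULL) {
  stopifnot(quant$mode == "spot_counts")
  m <- quant$matrix
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("zero-total cell reached normalization; filter cells first")
  if (is.null(target_sum)) target_sum <- stats::median(totals)
  log1p(m / totals * target_sum)
}

#' Area-adjust a density matrix and log-transform
#'
#' Divides raw per-cell foreground counts by cell area unless the quant's
#' entries are already fractional (the pipeline guarantees exactly one
#' division, tracked by the `area_divided` flag), then applies log(1 + x).
#'
#' @param quant Density-mode `iss_quant`.
#' @return Numeric matrix of log-densities.
#' @export
area_normalize_density <- function(quant) {
  stopifnot(quant$mode == "density")
  m <- quant$matrix
  if (!quant$area_divided) {
    if (any(quant$cells$area_px == 0)) stop("zero-area cell in density matrix")
    m <- m / quant$cells$area_px
  }
  log1p(m)
}

#' Leiden clustering of cells on a normalized matrix
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance, optionally after
#' reduction to `n_pcs` principal components) and partitions it with the
#' Leiden algorithm at the given resolution. Deterministic under a fixed
#' seed.
#'
#' @param matrix Normalized cells x genes matrix.
#' @param n_neighbors kNN degree (cells must number at least
#'   `n_neighbors + 1`).
#' @param resolution Leiden resolution parameter.
#' @param seed Integer seed.
#' @param n_pcs Principal components before the graph; 0 disables, and the
#'   reduction never exceeds `ncol(matrix) - 1` components.
#' @return Integer cluster labels `0..K-1`, one per cell.
#' @export
cluster_cells <- function(matrix, n_neighbors = 15L, resolution = 1.0,
                          seed = 1L, n_pcs = 20L) {
  n <- nrow(matrix)
  if (n <= n_neighbors)
    stop("need more cells (", n, ") than n_neighbors (", n_neighbors, ")")
  x <- matrix
  if (n_pcs > 0) {
    n_pcs <- min(n_pcs, ncol(matrix) - 1L, n - 1L)
    if (n_pcs >= 1) {
      p <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
      x <- p$x[, seq_len(n_pcs), drop = FALSE]
    }
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(n_neighbors)]
    edges <- rbind(edges, cbind(i, nb))
  }
  # undirected union of directed kNN edges
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  as.integer(igraph::membership(cl)) - 1L
}

#' Per-gene correlation of spot counts against densities
#'
#' Pearson correlation, per gene, of spot-count and density quantifications
#' over the cells present in both (matched on `cell_id`); genes need at
#' least 3 shared cells, else `NA`.
#'
#' @param counts Spot-count `iss_quant`.
#' @param densities Density `iss_quant` (cell ids comparable, e.g. from a
#'   downsampled view of the same segmentation).
#' @return List: `per_gene` (data.frame `gene`, `r`), `n_shared_cells`,
#'   `n_only_counts`, `n_only_densities`.
#' @export
spot_density_correlation <- function(counts, densities) {
  shared <- intersect(counts$cells$cell_id, densities$cells$cell_id)
  ia <- match(shared, counts$cells$cell_id)
  ib <- match(shared, densities$cells$cell_id)
  genes <- intersect(colnames(counts$matrix), colnames(densities$matrix))
  r <- vapply(genes, function(g) {
    if (length(shared) < 3) return(NA_real_)
    a <- counts$matrix[ia, g]; b <- densities$matrix[ib, g]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  list(per_gene = data.frame(gene = genes, r = as.numeric(r)),
       n_shared_cells = length(shared),
       n_only_counts = nrow(counts$cells) - length(shared),
       n_only_densities = nrow(densities$cells) - length(shared))
}

#' Per-gene histogram and mean of RCP counts per cell
#'
#' For each gene, the frequency table of per-cell counts and the mean
#' count per cell (the dashed-line statistic of a counts-per-cell
#' frequency panel).
#' @param quant Spot-count `iss_quant`.
#' @return Named list per gene: `histogram` (table), `mean`.
#' @export
summarize_rcps_per_cell <- function(quant) {
  stopifnot(quant$mode == "spot_counts")
  if (nrow(quant$matrix) == 0 || ncol(quant$matrix) == 0)
    return(stats::setNames(list(), character(0)))
  out <- lapply(colnames(quant$matrix), function(g) {
    v <- quant$matrix[, g]
    list(histogram = table(v), mean = mean(v))
  })
  stats::setNames(out, colnames(quant$matrix))
}
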