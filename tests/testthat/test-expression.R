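.mk_cells <- function(n, area = 100L) {
  list(labels = NULL,
       cells = data.frame(cell_id = seq_len(n), area_px = rep(area, n),
                          centroid_y = as.numeric(seq_len(n)),
                          centroid_x = as.numeric(seq_len(n))))
}

.mk_assigned <- function(genes, cell_ids) {
  n <- length(genes)
  data.frame(spot_id = seq_len(n), round = rep(1L, n), channel = rep(2L, n),
             y = rep(0, n), x = rep(0, n), intensity = rep(1, n),
             area = rep(1L, n), quality = rep(1, n),
             gene = genes, cell_id = cell_ids, Q = rep(NA_real_, n))
}

test_that("matrix construction counts assigned called spots and keeps zero genes", {
  cells <- .mk_cells(2)
  q0 <- build_matrix(.mk_assigned(character(0), integer(0)), cells, c("A", "B"))
  expect_equal(sum(q0$matrix), 0)
  sp <- .mk_assigned(c("A", "A", "A", "B", "A", "unassigned"),
                     c(1L, 1L, 1L, 2L, NA, 1L))
  q <- build_matrix(sp, cells, c("A", "B", "C"))
  expect_equal(unname(q$matrix[1, "A"]), 3L)
  expect_equal(unname(q$matrix[2, "B"]), 1L)
  expect_equal(sum(q$matrix), 4)          # NA cell and unassigned excluded
  expect_equal(unname(colSums(q$matrix)["C"]), 0L)
  expect_error(build_matrix(.mk_assigned("Z", 1L), cells, c("A", "B")),
               "absent from gene_list")
})

test_that("cell-then-gene filtering matches a brute-force two-pass oracle", {
  cells <- .mk_cells(3)
  m <- matrix(c(10, 2, 8, 0, 0, 0), 3, 2, dimnames = list(NULL, c("A", "B")))
  q <- new_quant(m, cells$cells, mode = "spot_counts")
  expect_equal(filter_matrix(q, 0, 0)$matrix, m)     # identity at (0, 0)
  f <- filter_matrix(q, 5, 0)
  expect_equal(nrow(f$matrix), 2)                    # middle cell removed
  expect_equal(f$cells$cell_id, c(1L, 3L))
  expect_equal(f$filter_provenance[[1]]$cells_removed, 2L)
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:20, 1); g <- sample(3:8, 1)
    mm <- matrix(rpois(n * g, 1), n, g,
                 dimnames = list(NULL, paste0("g", seq_len(g))))
    qq <- new_quant(mm, .mk_cells(n)$cells, mode = "spot_counts")
    tc <- sample(0:3, 1); tg <- sample(0:3, 1)
    got <- tryCatch(filter_matrix(qq, tc, tg), error = function(e) NULL)
    keep_c <- rowSums(mm) >= tc
    keep_g <- colSums(mm[keep_c, , drop = FALSE] > 0) >= tg
    if (is.null(got)) {
      expect_true(!any(keep_c) || !any(keep_g))
    } else {
      expect_equal(got$matrix, mm[keep_c, keep_g, drop = FALSE])
    }
  }
  expect_error(filter_matrix(q, 1000, 0), "removed everything")
})

test_that("count normalization scales rows to the target and log-transforms", {
  q1 <- new_quant(matrix(c(4, 0), 1, 2, dimnames = list(NULL, c("A", "B"))),
                  .mk_cells(1)$cells, mode = "spot_counts")
  expect_equal(normalize_log(q1, target_sum = 4),
               matrix(c(log(5), 0), 1, 2, dimnames = list(NULL, c("A", "B"))))
  m <- matrix(c(2, 2, 1, 1), 2, 2, dimnames = list(NULL, c("A", "B")))
  q2 <- new_quant(m, .mk_cells(2)$cells, mode = "spot_counts")
  norm <- normalize_log(q2)
  expect_equal(norm[1, ], norm[2, ])     # identical cells stay identical
  set.seed(7)
  mm <- matrix(rpois(60, 3) + 1, 10, 6, dimnames = list(NULL, paste0("g", 1:6)))
  q3 <- new_quant(mm, .mk_cells(10)$cells, mode = "spot_counts")
  pre_log <- expm1(normalize_log(q3, target_sum = 50))
  expect_equal(unname(rowSums(pre_log)), rep(50, 10))
  q4 <- new_quant(matrix(0, 1, 1, dimnames = list(NULL, "A")),
                  .mk_cells(1)$cells, mode = "spot_counts")
  expect_error(normalize_log(q4), "zero-total")
})

test_that("density matrices are area-divided exactly once", {
  cells <- .mk_cells(1, area = 300L)
  raw <- new_quant(matrix(30, 1, 1, dimnames = list(NULL, "A")), cells$cells,
                   mode = "density", area_divided = FALSE)
  expect_equal(area_normalize_density(raw),
               matrix(log1p(0.1), 1, 1, dimnames = list(NULL, "A")))
  frac <- new_quant(matrix(0.1, 1, 1, dimnames = list(NULL, "A")), cells$cells,
                    mode = "density", area_divided = TRUE)
  expect_equal(area_normalize_density(frac), area_normalize_density(raw))
  # density_quantify always emits pre-divided fractions
  labels <- matrix(1L, 10, 10)
  dq <- density_quantify(list(A = matrix(100, 10, 10)),
                         list(labels = labels, cells = cell_table(labels)), 10)
  expect_true(dq$area_divided)
  expect_equal(unname(area_normalize_density(dq)[1, 1]), log1p(1))
  zeros <- new_quant(matrix(0, 2, 1, dimnames = list(NULL, "A")),
                     .mk_cells(2)$cells, mode = "density")
  expect_equal(unname(area_normalize_density(zeros)), matrix(0, 2, 1))
})

test_that("clustering recovers planted populations deterministically", {
  mix <- simulate_cell_mixture(n_cells = 200, k_populations = 2, seed = 11)
  q <- new_quant(mix$counts, .mk_cells(200)$cells, mode = "spot_counts")
  q <- filter_matrix(q, 1, 1)
  truth <- mix$labels[rowSums(mix$counts) >= 1]
  norm <- normalize_log(q)
  lab <- cluster_cells(norm, n_neighbors = 15, resolution = 1, seed = 3,
                       n_pcs = 10)
  expect_gte(purity_agreement(lab, truth), 0.95)
  expect_identical(lab, cluster_cells(norm, n_neighbors = 15, resolution = 1,
                                      seed = 3, n_pcs = 10))
  # one homogeneous population at low resolution: a single cluster
  set.seed(5)
  homo <- matrix(rpois(150 * 8, 5) + 1, 150, 8,
                 dimnames = list(NULL, paste0("g", 1:8)))
  qh <- new_quant(homo, .mk_cells(150)$cells, mode = "spot_counts")
  labh <- cluster_cells(normalize_log(qh), n_neighbors = 15,
                        resolution = 0.01, seed = 2)
  expect_equal(length(unique(labh)), 1)
  expect_error(cluster_cells(norm[1:5, ], n_neighbors = 15), "more cells")
})

test_that("spot/density correlation is computed per gene over shared cells", {
  counts <- new_quant(matrix(c(1, 5, 9, 2, 4, 8), 3, 2,
                             dimnames = list(NULL, c("A", "B"))),
                      .mk_cells(3)$cells, mode = "spot_counts")
  dens <- new_quant(counts$matrix / 100, .mk_cells(3)$cells, mode = "density")
  res <- spot_density_correlation(counts, dens)
  expect_equal(res$per_gene$r, c(1, 1))
  neg <- new_quant(-counts$matrix, .mk_cells(3)$cells, mode = "density")
  expect_equal(spot_density_correlation(counts, neg)$per_gene$r, c(-1, -1))
  # mismatched cell sets: intersected and counted
  dens2 <- dens; dens2$cells$cell_id <- c(1L, 3L, 9L)
  dens2$matrix <- dens$matrix
  res2 <- spot_density_correlation(counts, dens2)
  expect_equal(res2$n_shared_cells, 2)
  expect_equal(res2$n_only_counts, 1)
  expect_true(all(is.na(res2$per_gene$r)))   # < 3 shared cells
})

test_that("per-cell RCP summaries report histograms and means per gene", {
  q <- new_quant(matrix(c(0, 0, 3), 3, 1, dimnames = list(NULL, "A")),
                 .mk_cells(3)$cells, mode = "spot_counts")
  s <- summarize_rcps_per_cell(q)
  expect_equal(s$A$mean, 1)
  expect_equal(as.integer(s$A$histogram), c(2L, 1L))
  expect_equal(names(s$A$histogram), c("0", "3"))
  q0 <- new_quant(matrix(0, 0, 0), .mk_cells(0)$cells, mode = "spot_counts")
  expect_length(summarize_rcps_per_cell(q0), 0)
  # simulated fixture: per-gene mean within sampling error of the rate
  fx <- small_seq_fixture(seed = 3, n_cells = 15L)
  qt <- new_quant(fx$sim$truth$counts,
                  data.frame(cell_id = seq_len(15), area_px = 1,
                             centroid_y = 0, centroid_x = 0),
                  mode = "spot_counts")
  st <- summarize_rcps_per_cell(qt)
  rate <- fx$config$spots_per_cell_per_gene
  for (g in names(st))
    expect_lt(abs(st[[g]]$mean - rate), 3 * sqrt(rate / 15))
})
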