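test_that("acquisition layout enforces its geometric invariants", {
  lay <- acquisition_layout(grid_rows = 2, grid_cols = 3,
                            tile_height_px = 100, tile_width_px = 200,
                            overlap_fraction = 0.1)
  expect_equal(lay$overlap_y_px, 10L)
  expect_equal(lay$overlap_x_px, 20L)
  expect_equal(n_tiles(lay), 6L)
  expect_equal(canvas_size(lay), c(100 + 90, 200 + 2 * 180))
  off <- nominal_offsets(lay)
  expect_equal(off$y0[off$tile == 4], 90)   # row-major: tile 4 starts row 2
  expect_error(acquisition_layout(channel_names = c("DAPI", "DAPI", "a"),
                                  nuclear_channel = "DAPI"),
               "exactly one channel")
  expect_error(acquisition_layout(grid_rows = 2, tile_height_px = 40,
                                  overlap_fraction = 0.01),
               "overlap in pixels")
})

test_that("codebooks validate uniqueness, length and channel use", {
  expect_error(codebook_sequential(c("a", "b"), c(1, 1), c(2, 2)),
               "duplicated")
  expect_error(codebook_combinatorial(c("a", "b"), list(c(2, 3), c(2, 3))),
               "duplicated barcode")
  expect_error(codebook_combinatorial("a", list(2L)), "n_cycles >= 2")
  lay <- acquisition_layout()
  cb_bad <- codebook_sequential("a", 1L, 1L)  # channel 1 is DAPI
  expect_error(validate_codebook(cb_bad, lay), "nuclear")
  cb <- codebook_combinatorial(c("a", "b"), list(c(2L, 3L), c(3L, 2L)))
  expect_true(validate_codebook(cb, acquisition_layout(n_rounds = 2)))
  expect_error(validate_codebook(cb, acquisition_layout(n_rounds = 1)),
               "more rounds")
})

test_that("run config merges defaults, file and overrides, rejecting unknown keys", {
  cfg <- read_run_config()
  expect_equal(cfg, default_run_config())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(list(k = 0.5, seed = 9L), path)
  cfg2 <- read_run_config(path, overrides = list(seed = 11L))
  expect_equal(cfg2$k, 0.5)
  expect_equal(cfg2$seed, 11L)          # override beats file
  expect_equal(cfg2$tophat_radius_px, cfg$tophat_radius_px)
  expect_error(read_run_config(path, overrides = list(bogus_key = 1)),
               "bogus_key")
})

test_that("tile stacks round-trip bit-identically through TIFF", {
  fx <- small_seq_fixture(seed = 3)
  dir <- withr::local_tempdir()
  write_tileset(fx$sim$tiles, dir)
  back <- read_tile_stack(dir, fx$layout)
  expect_equal(length(back$stacks), 4 * 1 * 5)
  for (key in names(fx$sim$tiles$stacks))
    expect_identical(back$stacks[[key]], fx$sim$tiles$stacks[[key]])
  # shape contract
  st <- get_stack(back, 2, 1, 3)
  expect_length(st, fx$layout$z_steps)
  expect_equal(dim(st[[1]]), c(128L, 128L))
})

test_that("tile reading fails loudly on missing, extra or misshapen files", {
  lay <- acquisition_layout(grid_rows = 1, grid_cols = 1, n_rounds = 1,
                            z_steps = 2)
  dir <- withr::local_tempdir()
  expect_error(read_tile_stack(dir, lay), "t1_r1_c1")
  for (c in 1:5)
    tiff::writeTIFF(list(matrix(0, 256, 256), matrix(0, 256, 256)),
                    file.path(dir, tile_filename(1, 1, c)),
                    bits.per.sample = 16)
  expect_silent(read_tile_stack(dir, lay))
  tiff::writeTIFF(matrix(0, 10, 10), file.path(dir, "t9_r9_c9.tif"))
  expect_error(read_tile_stack(dir, lay), "unexpected tile file")
  unlink(file.path(dir, "t9_r9_c9.tif"))
  tiff::writeTIFF(list(matrix(0, 13, 13), matrix(0, 13, 13)),
                  file.path(dir, tile_filename(1, 1, 2)),
                  bits.per.sample = 16)
  expect_error(read_tile_stack(dir, lay), "13x13")
})

test_that("spot tables round-trip losslessly, including 10^4 random spots", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_spot_table(empty_spot_table(), path)
  expect_length(readLines(path), 1L)    # header only
  expect_equal(read_spot_table(path), empty_spot_table())

  set.seed(42)
  n <- 10000L
  spots <- data.frame(
    spot_id = seq_len(n), round = sample(1:4, n, TRUE),
    channel = sample(2:5, n, TRUE),
    y = runif(n, 0, 512) , x = runif(n, 0, 512),
    intensity = rexp(n, 1e-4), area = sample(1:60, n, TRUE),
    quality = rexp(n), gene = sample(c("Mbp", "Cd24a", NA), n, TRUE),
    cell_id = sample(c(NA, 1:40), n, TRUE), Q = rnorm(n),
    stringsAsFactors = FALSE)
  write_spot_table(spots, path)
  back <- read_spot_table(path)
  for (col in names(spots)) expect_identical(back[[col]], spots[[col]], label = col)

  writeLines(c("bad,header", "1,2"), path)
  expect_error(read_spot_table(path), "line 1")
})

test_that("expression output writes valid MatrixMarket and conserves totals", {
  cells <- data.frame(cell_id = 1:2, area_px = c(10L, 20L),
                      centroid_y = c(1.5, 7.25), centroid_x = c(2, 3))
  q <- new_quant(matrix(c(1, 0, 0, 3), 2, 2,
                        dimnames = list(NULL, c("a", "b"))),
                 cells, mode = "spot_counts")
  dir <- withr::local_tempdir()
  write_expression(q, dir)
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  expect_equal(Matrix::nnzero(m), 2)
  expect_equal(sum(m), 4)
  expect_equal(nrow(utils::read.csv(file.path(dir, "cells.csv"))), 2)
  expect_equal(utils::read.csv(file.path(dir, "genes.csv"))$gene, c("a", "b"))
  # 0-cell matrix is still valid
  q0 <- new_quant(matrix(0, 0, 2, dimnames = list(NULL, c("a", "b"))),
                  cells[0, ], mode = "spot_counts")
  write_expression(q0, dir)
  expect_equal(dim(Matrix::readMM(file.path(dir, "matrix.mtx"))), c(0L, 2L))
})

test_that("layout and codebook YAML serialization round-trips", {
  lay <- acquisition_layout(grid_rows = 3, grid_cols = 2, n_rounds = 2)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_layout(lay, p)
  expect_equal(read_layout(p), lay)
  cb <- default_combinatorial_codebook()
  write_codebook(cb, p)
  expect_equal(read_codebook(p), cb)
  cb2 <- codebook_sequential("Mbp", 1L, 2L,
                             gene_id_tags = paste(rep("A", 20), collapse = ""))
  write_codebook(cb2, p)
  expect_equal(read_codebook(p), cb2)
})
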