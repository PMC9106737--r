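test_that("barcode score matches hand evaluation and its limits", {
  expect_equal(score_barcode(c(1, 1), 0, k = 0.7), 1)
  expect_equal(score_barcode(c(0.8, 0.9), 2, k = 0.05), 0.72 - 0.10)
  # k = 0: pure quality product, distances irrelevant
  expect_equal(score_barcode(c(0.5, 0.8, 0.9), c(100, 3), k = 0),
               0.5 * 0.8 * 0.9 * 0.8)
  # strictly decreasing in each distance and in k (positive qualities)
  qs <- c(0.9, 0.8, 0.95)
  for (d in seq(0, 3, by = 0.5))
    expect_gt(score_barcode(qs, c(d, 1), 0.1),
              score_barcode(qs, c(d + 0.5, 1), 0.1))
  for (k in seq(0, 0.3, by = 0.1))
    expect_gt(score_barcode(qs, c(2, 1), k), score_barcode(qs, c(2, 1), k + 0.1))
})

.mk_cycle <- function(ys, xs, channels, qualities) {
  data.frame(spot_id = seq_along(ys), round = 1L, channel = channels,
             y = ys, x = xs, intensity = 100, area = 5L,
             quality = qualities, gene = NA_character_,
             cell_id = NA_integer_, Q = NA_real_)
}

test_that("cycle linking picks nearest neighbours within the radius", {
  c1 <- .mk_cycle(0, 0, 2L, 1)
  c2 <- .mk_cycle(c(0, 0), c(3, 5), c(3L, 4L), c(1, 1))
  cand <- link_cycles(list(c1, c2), max_radius_px = 5)
  expect_length(cand, 1)
  expect_equal(cand[[1]]$distances, 3)
  expect_equal(cand[[1]]$channels, c(2L, 3L))
  # identical coordinates across 3 cycles: all distances zero
  c_same <- .mk_cycle(10, 10, 2L, 0.9)
  cand3 <- link_cycles(list(c_same, c_same, c_same), 5)
  expect_equal(cand3[[1]]$distances, c(0, 0))
  # radius gate
  far <- .mk_cycle(0, 20, 3L, 1)
  expect_length(link_cycles(list(c1, far), max_radius_px = 5), 0)
})

test_that("greedy linking agrees with a brute-force nearest-neighbour oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1); n3 <- sample(3:10, 1)
    cyc <- list(.mk_cycle(runif(n1, 0, 30), runif(n1, 0, 30),
                          sample(2:5, n1, TRUE), runif(n1)),
                .mk_cycle(runif(n2, 0, 30), runif(n2, 0, 30),
                          sample(2:5, n2, TRUE), runif(n2)),
                .mk_cycle(runif(n3, 0, 30), runif(n3, 0, 30),
                          sample(2:5, n3, TRUE), runif(n3)))
    got <- link_cycles(cyc, max_radius_px = 8)
    # oracle: exhaustive nearest-neighbour chain per cycle-1 spot
    want <- list()
    for (s in seq_len(n1)) {
      y <- cyc[[1]]$y[s]; x <- cyc[[1]]$x[s]
      chain <- s; dd <- c(); alive <- TRUE
      for (ci in 2:3) {
        best_j <- NA; best_d <- Inf
        for (j in seq_len(nrow(cyc[[ci]]))) {
          d <- sqrt((cyc[[ci]]$y[j] - y)^2 + (cyc[[ci]]$x[j] - x)^2)
          if (d < best_d) { best_d <- d; best_j <- j }
        }
        if (best_d > 8) { alive <- FALSE; break }
        chain <- c(chain, best_j); dd <- c(dd, best_d)
        y <- cyc[[ci]]$y[best_j]; x <- cyc[[ci]]$x[best_j]
      }
      if (alive) want[[length(want) + 1]] <- list(rows = chain, d = dd)
    }
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$spot_rows, want[[i]]$rows)
      expect_equal(got[[i]]$distances, want[[i]]$d)
    }
  }
})

test_that("Q filtering, codebook lookup and shared-spot resolution behave as specified", {
  cb <- codebook_combinatorial(c("gA", "gB"), list(c(2L, 3L), c(4L, 5L)))
  mk_cand <- function(rows, chs, qs, ds, y = 0, x = 0)
    list(spot_rows = rows, channels = chs, qualities = qs, distances = ds,
         y = y, x = x)
  # Q = 0.25 - 1 < 0: dropped
  res <- filter_and_call(list(mk_cand(c(1, 1), c(2L, 3L), c(0.5, 0.5), 10)),
                         cb, k = 0.1)
  expect_equal(nrow(res$spots), 0)
  expect_equal(res$diagnostics$n_q_dropped, 1L)
  # matching barcode called; unknown barcode counted invalid
  res2 <- filter_and_call(list(
    mk_cand(c(1, 1), c(2L, 3L), c(1, 1), 0),
    mk_cand(c(2, 2), c(2L, 5L), c(1, 1), 0)), cb, k = 0.2)
  expect_equal(res2$spots$gene, "gA")
  expect_equal(res2$diagnostics$n_invalid_barcode, 1L)
  # shared cycle-2 spot: higher-Q candidate wins
  res3 <- filter_and_call(list(
    mk_cand(c(1, 7), c(2L, 3L), c(0.9, 0.9), 1),
    mk_cand(c(2, 7), c(4L, 5L), c(0.99, 0.99), 0.1)), cb, k = 0.2)
  expect_equal(res3$spots$gene, "gB")
  expect_equal(res3$diagnostics$n_shared_dropped, 1L)
})

test_that("sequential assignment is a (round, channel) lookup that keeps strays", {
  cb <- codebook_sequential(c("Mbp", "Plp1"), c(2L, 1L), c(2L, 3L))
  spots <- .mk_cycle(c(1, 2, 3), c(1, 2, 3), c(2L, 3L, 4L), 1)
  spots$round <- c(2L, 1L, 1L)
  out <- assign_sequential(spots, cb)
  expect_equal(out$gene, c("Mbp", "Plp1", "unassigned"))
  expect_equal(nrow(out), 3)
})

test_that("efficiency slope is the through-origin least-squares estimate", {
  a <- c(10, 40, 25, 80)
  expect_equal(efficiency_slope(a, a)$slope, 1)
  expect_equal(efficiency_slope(a, 3 * a)$slope, 3)
  expect_equal(efficiency_slope(a, 3 * a)$r, 1)
  b <- c(31, 118, 77, 239)
  expect_equal(efficiency_slope(a, b)$slope, sum(a * b) / sum(a^2))
  expect_error(efficiency_slope(c(0, 0), c(1, 2)), "all zero")
})

test_that("a 2-cycle combinatorial simulation decodes to the right genes", {
  lay <- acquisition_layout(grid_rows = 1, grid_cols = 1,
                            tile_height_px = 400, tile_width_px = 400,
                            n_rounds = 2, z_steps = 2)
  cb <- default_combinatorial_codebook()
  cfg <- simulation_config(layout = lay, n_cells = 25,
                           spots_per_cell_per_gene = 0.6,
                           tile_offset_jitter_px = 0, seed = 19)
  sim <- simulate_experiment(cfg, cb)
  res <- process_experiment(sim$tiles, cb, default_run_config())
  tru <- sim$truth$spots
  m <- match_spots(res$decoded, tru, radius = 2, check_gene = TRUE)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
  expect_lte(res$decode_diag$n_invalid_barcode /
               max(res$decode_diag$n_candidates, 1), 0.02)
  # decoding is deterministic
  res2 <- process_experiment(sim$tiles, cb, default_run_config())
  expect_identical(res$decoded, res2$decoded)
})
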