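# Shared fixtures and independent oracles for the test suite.

# Independent spot renderer (oracle-side): Gaussians of peak `amp` and sd
# `sigma` at 0-based (y, x) positions on a flat background. Written with
# plain loops, independent of the simulator's rendering path.
render_spots_canvas <- function(H, W, ys, xs, amp, sigma, bg = 0) {
  canvas <- matrix(bg, H, W)
  for (i in seq_along(ys)) {
    for (py in 0:(H - 1)) for (px in 0:(W - 1)) {
      d2 <- (py - ys[i])^2 + (px - xs[i])^2
      if (d2 <= (4 * sigma)^2)
        canvas[py + 1, px + 1] <- canvas[py + 1, px + 1] +
          amp * exp(-d2 / (2 * sigma^2))
    }
  }
  canvas
}

# Greedy one-to-one matching of detections to ground truth within `radius`.
# Returns recall, precision, mean centroid error over matches.
match_spots <- function(det, tru, radius = 2, check_gene = FALSE) {
  if (nrow(det) == 0 || nrow(tru) == 0)
    return(list(tp = 0L, recall = 0, precision = 0, mean_err = NA_real_))
  used <- rep(FALSE, nrow(tru))
  tp <- 0L; errs <- numeric(0)
  for (i in seq_len(nrow(det))) {
    d <- sqrt((tru$y - det$y[i])^2 + (tru$x - det$x[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= radius &&
        (!check_gene || identical(tru$gene[j], det$gene[i]))) {
      tp <- tp + 1L; used[j] <- TRUE; errs <- c(errs, d[j])
    }
  }
  list(tp = tp, recall = tp / nrow(tru), precision = tp / nrow(det),
       mean_err = mean(errs))
}

# Map segmented cell ids to ground-truth cell indices by nearest centroid.
map_cell_labels <- function(cell_df, true_centers) {
  vapply(seq_len(nrow(cell_df)), function(i)
    which.min((true_centers[, 1] - cell_df$centroid_y[i])^2 +
              (true_centers[, 2] - cell_df$centroid_x[i])^2), 0L)
}

# Cluster-label agreement after best (majority) mapping of each cluster to a
# true class.
purity_agreement <- function(labels, truth) {
  tab <- table(labels, truth)
  sum(apply(tab, 1, max)) / length(truth)
}

# Small sequential 4-gene fixture shared by several tests.
small_seq_fixture <- function(seed = 7, n_rounds = 1L, grid = c(2L, 2L),
                              tile = 128L, n_cells = 12L, ...) {
  lay <- acquisition_layout(grid_rows = grid[1], grid_cols = grid[2],
                            tile_height_px = tile, tile_width_px = tile,
                            n_rounds = n_rounds, z_steps = 3L)
  cb <- codebook_sequential(c("Cd24a", "Lamp5", "Slc17a7", "Mbp"),
                            rep(1L, 4), 2:5)
  cfg <- simulation_config(layout = lay, n_cells = n_cells, seed = seed, ...)
  list(layout = lay, codebook = cb, config = cfg,
       sim = simulate_experiment(cfg, cb))
}
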