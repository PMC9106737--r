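# Brute-force white top-hat oracle: erosion (min) then dilation (max) over a
# disk of offsets, subtracted from the image. Valid away from borders.
brute_tophat <- function(img, radius) {
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  offs <- which(kern == 1, arr.ind = TRUE) - (radius + 1)
  H <- nrow(img); W <- ncol(img)
  er <- matrix(Inf, H, W); di <- matrix(-Inf, H, W)
  for (y in 1:H) for (x in 1:W) {
    ys <- y + offs[, 1]; xs <- x + offs[, 2]
    ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    er[y, x] <- min(img[cbind(ys[ok], xs[ok])])
  }
  for (y in 1:H) for (x in 1:W) {
    ys <- y + offs[, 1]; xs <- x + offs[, 2]
    ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    di[y, x] <- max(er[cbind(ys[ok], xs[ok])])
  }
  img - di
}

test_that("top-hat removes flat/ramp background and keeps point signals", {
  expect_equal(tophat_filter(matrix(5, 20, 20), 3), matrix(0, 20, 20))
  img <- matrix(0, 21, 21); img[11, 11] <- 9
  th <- tophat_filter(img, 3)
  expect_equal(th[11, 11], 9)
  expect_equal(sum(th), 9)
  # Gaussian spot on a linear ramp vs the brute-force morphological oracle
  ramp <- outer(seq(0, 50, length.out = 31), seq(0, 30, length.out = 31), `+`)
  ys <- 0:30
  spot <- 40 * exp(-outer((ys - 15)^2, (ys - 15)^2, `+`) / (2 * 1.5^2))
  img2 <- ramp + spot
  got <- tophat_filter(img2, 2)
  want <- brute_tophat(img2, 2)
  want[want < 0] <- 0
  interior <- 6:26
  expect_equal(got[interior, interior], want[interior, interior],
               tolerance = 1e-12)
  # on a sparse nonnegative image the filter is idempotent
  sparse <- matrix(0, 25, 25); sparse[5, 5] <- 3; sparse[18, 12] <- 7
  expect_equal(tophat_filter(tophat_filter(sparse, 3), 3),
               tophat_filter(sparse, 3))
})

test_that("spot detection applies intensity and size thresholds with hand-checked centroids", {
  expect_equal(nrow(detect_spots(matrix(0, 30, 30), 1)), 0)
  img <- matrix(0, 40, 40)
  img[3:4, 3:4] <- 10                        # 4 px, centroid (2.5, 2.5)
  img[20, 10:14] <- c(5, 5, 20, 5, 5)        # 5 px row, weighted centroid
  img[30:39, 30:39] <- 8                     # 100 px blob
  tab <- detect_spots(img, intensity_threshold = 5, size_min_px = 2,
                      size_max_px = 50, round = 2, channel = 3)
  expect_equal(nrow(tab), 2)                 # big blob dropped by size_max
  tab <- tab[order(tab$y), ]
  expect_equal(tab$y[1], 2.5)
  expect_equal(tab$x[1], 2.5)
  expect_equal(tab$area[1], 4L)
  expect_equal(tab$intensity[1], 10)
  expect_equal(tab$y[2], 19)
  expect_equal(tab$x[2], sum(c(5, 5, 20, 5, 5) * (9:13)) / 40)
  expect_equal(tab$round, c(2L, 2L))
  # single oversized blob with tight size_max: nothing
  expect_equal(nrow(detect_spots(img, 5, 2, 50)[detect_spots(img, 5, 2, 50)$area > 50, ]), 0)
})

test_that("channel-purity quality matches its definition and invariances", {
  expect_equal(spot_quality(1, c(50, 30, 20)), 1)           # 50 / 50
  expect_equal(spot_quality(1, c(100, 20, 20, 10)), 2)      # 100 / 50
  q1 <- spot_quality(2, c(10, 80, 30))
  expect_equal(spot_quality(2, 2 * c(10, 80, 30)), q1)      # scale invariance
  # floor engages for perfectly pure spots
  expect_equal(spot_quality(1, c(40, 0, 0), floor = 1), 40)
  expect_error(spot_quality(5, c(1, 2, 3)), "missing")
})

test_that("detection on a rendered field meets recall/precision/localization targets", {
  # 40 spots on a jittered grid (>= 10 px apart), amplitude 5x the noise sd
  set.seed(123)
  gy <- rep(seq(20, 230, by = 30), each = 5)[1:40]
  gx <- rep(seq(25, 145, by = 30), times = 8)[1:40]
  ys <- gy + runif(40, -3, 3); xs <- gx + runif(40, -3, 3)
  amp <- 1500; noise_sd <- 300
  canvas <- render_spots_canvas(256, 160, ys, xs, amp, sigma = 1.5, bg = 500)
  canvas <- canvas + matrix(rnorm(256 * 160, 0, noise_sd), 256, 160)
  filt <- tophat_filter(canvas, 3)
  tab <- detect_spots(filt, intensity_threshold = 1050, size_min_px = 4,
                      size_max_px = 100)
  m <- match_spots(tab, data.frame(y = ys, x = xs), radius = 2)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  expect_lte(m$mean_err, 1)
})

test_that("per-round detection attaches qualities from all signal channels", {
  lay <- acquisition_layout(grid_rows = 1, grid_cols = 1, n_rounds = 1,
                            z_steps = 1)
  H <- 64
  blank <- matrix(0, H, H)
  ch2 <- blank; ch2[30:31, 30:31] <- 100
  ch3 <- blank; ch3[30:31, 30:31] <- 20    # bleed-through under the spot
  filtered <- list(blank, ch2, ch3, blank, blank)
  tab <- detect_round(filtered, lay, intensity_threshold = 50,
                      size_min_px = 2, size_max_px = 20)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$channel, 2L)
  expect_equal(tab$quality, 100 / 20)
})

test_that("SNR estimates match the analytic amplitude/noise ratio", {
  set.seed(77)
  ys <- c(30, 30, 90, 90); xs <- c(30, 90, 30, 90)
  canvas <- render_spots_canvas(120, 120, ys, xs, amp = 100, sigma = 1.5,
                                bg = 500)
  canvas <- canvas + matrix(rnorm(120 * 120, 0, 10), 120, 120)
  spots <- data.frame(spot_id = 1:4, round = 1L, channel = 2L,
                      y = ys, x = xs, intensity = NA, area = 9L,
                      quality = NA, gene = NA, cell_id = NA, Q = NA)
  res <- measure_snr(spots, canvas, radius_px = 3)
  expect_true(all(abs(res$per_spot$snr - 10) / 10 < 0.25))
  expect_equal(res$summary$channel, 2L)
  expect_lt(abs(res$summary$median_snr - 10) / 10, 0.25)
  # zero noise: capped, not infinite
  clean <- render_spots_canvas(60, 60, 30, 30, amp = 100, sigma = 1.5, bg = 500)
  res0 <- measure_snr(spots[1, ], clean, radius_px = 3, cap = 1e6)
  expect_equal(res0$per_spot$snr, 1e6)
  # empty table: empty summary
  res_e <- measure_snr(empty_spot_table(), canvas)
  expect_equal(nrow(res_e$summary), 0)
})
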