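mmode_from_matrix <- function(M, fps = 140) {
  structure(list(matrix = M,
                 line_spec = list(orientation = "vertical", index = 1),
                 fps = fps), class = "mmode")
}

test_that("m-mode extraction stacks the requested pixel line over time", {
  ph <- tiny_phantom()
  seq1 <- ph$cross[[3]]$bmode
  mm <- extract_mmode(seq1, list(orientation = "vertical", index = 5))
  expect_equal(ncol(mm$matrix), dim(seq1$frames)[1])
  expect_equal(mm$matrix[, 7], seq1$frames[7, , 5])
  mh <- extract_mmode(seq1, list(orientation = "horizontal", index = 4))
  expect_equal(mh$matrix[, 2], seq1$frames[2, 4, ])
  expect_error(extract_mmode(seq1, list(orientation = "vertical",
                                        index = 10000)), "bounds")
  # constant sequence -> constant m-mode
  cseq <- seq1; cseq$frames[] <- 0.5
  expect_equal(diff(range(extract_mmode(
    cseq, list(orientation = "vertical", index = 5))$matrix)), 0)
})

test_that("string-length period estimation recovers constructed periods", {
  # exact tiling of one cycle of k columns
  set.seed(1)
  one <- matrix(rnorm(5 * 20), 5, 20)
  tiled <- mmode_from_matrix(one[, rep(1:20, 10)])
  expect_equal(as.numeric(estimate_period(tiled, c(10, 60))), 20,
               tolerance = 0.05)
  # phantom with known 56-frame period
  ph <- tiny_phantom()
  ctr <- ph$truth$center_px
  mm <- extract_mmode(ph$cross[[4]]$bmode,
                      list(orientation = "vertical", index = ctr))
  p <- estimate_period(mm)
  expect_lt(abs(as.numeric(p) - ph$truth$period_frames), 0.5)
})

test_that("period estimation tolerates speckle noise within a frame", {
  cfg <- tiny_config(speckle_noise_sd = 0.15)
  ph <- generate_phantom(cfg, seed = 5)
  ctr <- ph$truth$center_px
  mm <- extract_mmode(ph$cross[[4]]$bmode,
                      list(orientation = "vertical", index = ctr))
  expect_lt(abs(as.numeric(estimate_period(mm)) - ph$truth$period_frames), 1)
})

test_that("period estimation is invariant to affine intensity transforms", {
  ph <- tiny_phantom()
  ctr <- ph$truth$center_px
  mm <- extract_mmode(ph$cross[[3]]$bmode,
                      list(orientation = "vertical", index = ctr))
  mm2 <- mm
  mm2$matrix <- 3.7 * mm$matrix - 11
  expect_equal(as.numeric(estimate_period(mm)),
               as.numeric(estimate_period(mm2)), tolerance = 1e-8)
})

test_that("a flat m-mode is flagged, not estimated", {
  flat <- mmode_from_matrix(matrix(0.3, 10, 100))
  expect_error(estimate_period(flat), class = "oftflow_flat_mmode")
  expect_error(phase_shift(flat$matrix, flat$matrix),
               class = "oftflow_flat_mmode")
})

test_that("pooling produces a 200-bin normalized cycle and is idempotent", {
  ph <- tiny_phantom()
  ctr <- ph$truth$center_px
  mm <- extract_mmode(ph$cross[[2]]$bmode,
                      list(orientation = "vertical", index = ctr))
  pooled <- pool_cycle(mm, ph$truth$period_frames)
  expect_equal(ncol(pooled$matrix), 200)
  # pooling an already-pooled cycle with p = n_bins is the identity
  again <- pool_cycle(pooled, 200)
  expect_equal(again$matrix, pooled$matrix, tolerance = 1e-12)
  expect_error(pool_cycle(mm, -5), "positive")
})

test_that("a noiseless pooled cycle matches a resampled single cycle", {
  # build an m-mode whose columns sample a smooth cyclic signal
  p <- 37.3
  n <- 300
  phase <- ((seq_len(n) - 1) %% p) / p
  depth <- seq(0, 1, length.out = 24)
  M <- outer(depth, phase, function(d, ph) sin(2 * pi * ph) * d + cos(2 * pi * ph))
  pooled <- pool_cycle(mmode_from_matrix(M), p, n_bins = 200)
  centers <- (seq_len(200) - 0.5) / 200
  expected <- outer(depth, centers,
                    function(d, ph) sin(2 * pi * ph) * d + cos(2 * pi * ph))
  # worst-case quantization: one sample at a bin edge differs from the
  # bin-center value by (slope x half bin width) ~ 0.02 for this signal
  expect_lt(max(abs(pooled$matrix - expected)), 0.05)
  expect_lt(mean(abs(pooled$matrix - expected)), 0.01)
})

test_that("circular phase shifts are recovered with sub-bin accuracy", {
  set.seed(2)
  A <- matrix(rnorm(6 * 200), 6, 200)
  A <- t(apply(A, 1, function(x) stats::filter(x, rep(1 / 7, 7),
                                               circular = TRUE)))
  expect_equal(as.numeric(phase_shift(A, A)), 0)
  rot <- 37
  B <- A[, ((0:199 - rot) %% 200) + 1]
  expect_lt(abs(as.numeric(phase_shift(A, B)) - rot), 0.5)
  # recovered coarse shifts undo the phantom's random start phases
  ph <- tiny_phantom()
  sy <- cached("tiny_sync", sync_dataset(ph))
  err <- (sy$schedule$shift_cycles + ph$truth$slice_phase_offsets) %% 1
  err <- pmin(err, 1 - err)
  expect_lt(max(err) * 200, 2)  # within 2 pooled frames (1% of cycle)
})

test_that("cumulative neighbor shifts telescope and smooth correctly", {
  # all-zero shifts -> zero curve
  set.seed(3)
  base <- matrix(rnorm(8 * 200), 8, 200)
  base <- t(apply(base, 1, function(x) stats::filter(x, rep(1 / 9, 9),
                                                     circular = TRUE)))
  same <- replicate(6, mmode_from_matrix(base), simplify = FALSE)
  cv <- refine_and_smooth(same)
  expect_equal(max(abs(cv$cumulative_raw)), 0, tolerance = 0.2)

  # constant neighbor shift d across k slices -> (k-1) d before smoothing
  d <- 9
  shifted <- lapply(0:5, function(i) {
    mmode_from_matrix(base[, ((0:199 - i * d) %% 200) + 1])
  })
  cv2 <- refine_and_smooth(shifted)
  expect_equal(cv2$cumulative_raw[6], 5 * d, tolerance = 0.5)

  # one corrupted slice is pulled back to the smooth trend
  corrupted <- shifted
  corrupted[[4]] <- mmode_from_matrix(base[, ((0:199 - (3 * d + 30)) %% 200) + 1])
  cv3 <- refine_and_smooth(corrupted, outlier_threshold = 10)
  truth <- d * (0:5)
  expect_true(cv3$outlier[4])
  expect_lt(max(abs(cv3$cumulative_smooth - truth)), 2)
})

test_that("resequencing yields the requested normalized cycle", {
  ph <- tiny_phantom()
  res <- resequence(ph$cross[[3]]$bmode, ph$truth$period_frames, shift = 0)
  expect_equal(dim(res$frames)[1], 100)
  # shift 0 with n_out = n_bins reproduces the pooled input
  mm <- extract_mmode(ph$cross[[3]]$bmode,
                      list(orientation = "vertical", index = 5))
  pooled <- pool_cycle(mm, ph$truth$period_frames, n_bins = 200)
  res200 <- resequence(ph$cross[[3]]$bmode, ph$truth$period_frames,
                       shift = 0, n_out = 200, n_bins = 200)
  expect_equal(t(res200$frames[, , 5]), pooled$matrix, tolerance = 1e-10)
  # per-pixel time-mean of the pooled cycle is conserved
  expect_equal(apply(res200$frames, c(2, 3), mean),
               apply(res$frames, c(2, 3), mean), tolerance = 1e-6)
})

test_that("synchronized Doppler matches the longitudinal reference", {
  ph <- tiny_phantom()
  sy <- cached("tiny_sync", sync_dataset(ph))
  vs <- validate_sync(sy)
  expect_equal(nrow(vs), 4)
  expect_true(all(vs$correlation > 0.99))
  expect_true(all(abs(vs$lag_frames) <= 1))
  # self-comparison is perfect
  vs_self <- validate_sync(sy, n_points = 2)
  expect_true(all(vs_self$correlation > 0.99))
  # negative control: unsynchronized stack shows large lags somewhere
  sy0 <- sy
  for (k in seq_len(dim(sy$doppler)[4])) {
    sy0$doppler[, , , k] <- resequence(ph$cross[[k]]$doppler,
                                       sy$period_frames, 0)$frames
  }
  vs0 <- validate_sync(sy0)
  expect_gt(max(abs(vs0$lag_frames)), 2)
})
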