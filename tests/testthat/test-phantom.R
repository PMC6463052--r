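test_that("default acquisition spans at least three full cardiac cycles", {
  cfg <- phantom_config()
  cycles <- cfg$frames_per_sequence / frames_per_cycle(cfg)
  expect_gte(cycles, 3)
})

test_that("stage presets keep at least 50 frames per cardiac cycle", {
  for (stage in c("HH14", "HH15", "HH16", "HH17", "HH18")) {
    cfg <- phantom_preset(stage)
    expect_gte(frames_per_cycle(cfg), 50)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(period_ms = 10, fps = 140),
               "fewer than 2 frames")
  expect_error(phantom_config(pulsation_amplitude = 1))
  expect_error(phantom_config(cushion_depth = 1.5))
  expect_error(phantom_config(base_radius_profile = function(s) s - 0.5),
               "strictly positive")
})

test_that("seeded generation is reproducible bit-for-bit", {
  cfg <- tiny_config(n_slices = 4, frames_per_sequence = 20,
                     speckle_noise_sd = 0.05)
  a <- generate_phantom(cfg, seed = 7)
  b <- generate_phantom(cfg, seed = 7)
  expect_identical(a$cross[[2]]$bmode$frames, b$cross[[2]]$bmode$frames)
  expect_identical(a$longitudinal$doppler$frames,
                   b$longitudinal$doppler$frames)
  expect_identical(a$truth$slice_phase_offsets, b$truth$slice_phase_offsets)
  c <- generate_phantom(cfg, seed = 8)
  expect_false(identical(a$truth$slice_phase_offsets,
                         c$truth$slice_phase_offsets))
})

test_that("a motionless noiseless tube gives identical frames", {
  cfg <- tiny_config(n_slices = 4, frames_per_sequence = 12,
                     pulsation_amplitude = 0, cushion_depth = 0)
  ph <- generate_phantom(cfg, seed = 1)
  fr <- ph$cross[[2]]$bmode$frames
  for (t in 2:dim(fr)[1]) {
    expect_equal(fr[t, , ], fr[1, , ], tolerance = 1e-12)
  }
})

test_that("flow rate respects mass conservation in the deforming tube", {
  cfg <- tiny_config()
  L <- phantom_length_mm(cfg)
  sg <- seq(0, 1, length.out = 401)
  vol <- function(p) {
    A <- pi * phantom_radius(cfg, sg, p)^2
    sum((A[-1] + A[-401]) / 2) * (sg[2] - sg[1]) * L
  }
  for (phi in c(0.15, 0.4, 0.8)) {
    dp <- 1e-4
    dVdt <- (vol(phi + dp) - vol(phi - dp)) / (2 * dp) /
      (cfg$period_ms / 1000)
    q0 <- phantom_flow_rate(cfg, 0, phi)
    q1 <- phantom_flow_rate(cfg, 1, phi)
    expect_equal(q1, q0 - dVdt,
                 tolerance = 0.01 * max(abs(q0), abs(q1), 1e-6))
  }
})

test_that("analytic flow has a parabolic no-slip profile", {
  cfg <- tiny_config(pulsation_amplitude = 0, cushion_depth = 0)
  phi <- 0.25
  f <- analytic_flow(cfg, phi)
  L <- phantom_length_mm(cfg)
  R <- phantom_radius(cfg, 0.5, phi)
  Q <- phantom_flow_rate(cfg, 0.5, phi)
  # centerline velocity is twice the cross-section mean
  v_center <- f(c(0, 0, L / 2))[3]
  expect_equal(v_center, 2 * Q / (pi * R^2), tolerance = 1e-6)
  # no slip at the wall, zero outside
  expect_equal(f(c(R * 0.999, 0, L / 2))[3], 0, tolerance = 0.01 * v_center)
  expect_identical(f(c(R * 1.5, 0, L / 2))[3], 0)
})

test_that("Doppler planes are the beam projection of the axial velocity", {
  cfg0 <- tiny_config(n_slices = 4, frames_per_sequence = 10,
                      beam_tilt_deg = 90)
  ph0 <- generate_phantom(cfg0, seed = 1)
  expect_lt(max(abs(ph0$cross[[2]]$doppler$frames)), 1e-10)

  cfg45 <- tiny_config(n_slices = 4, frames_per_sequence = 10)
  ph45 <- generate_phantom(cfg45, seed = 1)
  k <- 2; t <- 5
  phi <- (ph45$truth$slice_phase_offsets[k] +
            (t - 1) / cfg45$fps / (cfg45$period_ms / 1000)) %% 1
  s <- ph45$truth$slice_s[k]
  ctr <- ph45$truth$center_px
  v_dop_center <- ph45$cross[[k]]$doppler$frames[t, ctr, ctr]
  R <- phantom_radius(cfg45, s, phi)
  Q <- phantom_flow_rate(cfg45, s, phi)
  expect_equal(v_dop_center, cos(pi / 4) * 2 * Q / (pi * R^2),
               tolerance = 1e-6 * max(1, abs(v_dop_center)))
})

test_that("the rendered wall radius matches the analytic radius within a pixel", {
  ph <- tiny_phantom()
  cfg <- ph$config
  ctr <- ph$truth$center_px
  px <- ph$truth$pixel_size_mm
  for (k in c(2, 5)) {
    t <- 9
    phi <- (ph$truth$slice_phase_offsets[k] +
              (t - 1) / cfg$fps / (cfg$period_ms / 1000)) %% 1
    Rtrue <- phantom_radius(cfg, ph$truth$slice_s[k], phi)
    ct <- segment_lumen(ph$cross[[k]]$bmode$frames[t, , ], c(ctr, ctr), px)
    expect_lt(abs(median(ct$radii_px) - Rtrue / px), 1)
  }
})

test_that("the dataset round-trips through the on-disk layout", {
  ph <- generate_phantom(tiny_config(n_slices = 3, frames_per_sequence = 8),
                         seed = 3)
  dir <- withr::local_tempdir()
  write_phantom_dataset(ph, dir)
  back <- read_phantom_dataset(dir)
  expect_identical(back$cross[[2]]$bmode$frames, ph$cross[[2]]$bmode$frames)
  expect_identical(back$truth$slice_phase_offsets,
                   ph$truth$slice_phase_offsets)
  expect_equal(back$meta$n_slices, 3)
})
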