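test_that("Poiseuille wall shear stress matches the closed form", {
  pc <- poiseuille_case(32, 4, 20)
  wsf <- wall_shear(pc$field)
  expect_lt(abs(mean(wsf$tau_mag) - pc$tau_true) / pc$tau_true, 0.05)
  # refinement decreases the error monotonically
  coarse <- poiseuille_case(16, 2, 10)
  wsf_c <- wall_shear(coarse$field)
  err_c <- abs(mean(wsf_c$tau_mag) - coarse$tau_true) / coarse$tau_true
  err_f <- abs(mean(wsf$tau_mag) - pc$tau_true) / pc$tau_true
  expect_lt(err_f, err_c)
})

test_that("wall shear vectors are tangential and vanish for hydrostatics", {
  pc <- poiseuille_case(16, 2, 10)
  wsf <- wall_shear(pc$field)
  tn <- abs(apply(wsf$tau * wsf$normal, c(1, 2), sum))
  expect_lt(max(tn / pmax(wsf$tau_mag, 1e-300)), 1e-8)
  # hydrostatic field: v = 0, p = const -> tau = 0, sigma.n = -p n
  hydro <- pc$field
  hydro$velocity[] <- 0
  hydro$pressure[] <- 7
  wsf0 <- wall_shear(hydro)
  expect_lt(max(wsf0$tau_mag), 1e-12)
  sn_norm <- sqrt(apply(wsf0$sigma_n^2, c(1, 2), sum))
  expect_equal(max(abs(sn_norm - 7)), 0, tolerance = 1e-9)
})

test_that("OSI hits its analytic anchors", {
  # constant direction -> 0
  tau_uni <- array(0, dim = c(1, 3, 100))
  tau_uni[1, 1, ] <- abs(sin(seq_len(100))) + 0.1
  expect_identical(as.numeric(osi(tau_uni)), 0)
  # equal-magnitude alternation over equal dwell times -> 0.5
  tau_alt <- array(0, dim = c(1, 3, 100))
  tau_alt[1, 1, 1:50] <- 1
  tau_alt[1, 1, 51:100] <- -1
  expect_identical(as.numeric(osi(tau_alt)), 0.5)
  # all-zero history: defined as 0 and flagged
  z <- osi(array(0, dim = c(2, 3, 10)))
  expect_identical(as.numeric(z), c(0, 0))
  expect_identical(attr(z, "zero_history"), 1:2)
})

test_that("OSI equals a brute-force accumulation and respects its bounds", {
  # sinusoidal shear checked against an independent accumulation loop
  n <- 100
  tau <- array(0, dim = c(1, 3, n))
  tau[1, 1, ] <- sin(2 * pi * (seq_len(n) - 0.5) / n)
  w <- rep(0.004, n)
  acc_num <- c(0, 0, 0); acc_den <- 0
  for (i in seq_len(n)) {
    acc_num <- acc_num + w[i] * tau[1, , i]
    acc_den <- acc_den + w[i] * sqrt(sum(tau[1, , i]^2))
  }
  brute <- 0.5 * (1 - sqrt(sum(acc_num^2)) / acc_den)
  expect_equal(as.numeric(osi(tau, time_weights = w)), brute,
               tolerance = 1e-12)
  # property: arbitrary histories stay within [0, 0.5]
  set.seed(99)
  for (rep in 1:50) {
    th <- array(rnorm(3 * 3 * 20), dim = c(3, 3, 20))
    v <- osi(th, time_weights = runif(20, 0.5, 2))
    expect_true(all(v >= 0 & v <= 0.5))
  }
})

test_that("flow rate matches Poiseuille and is station-independent", {
  pc <- poiseuille_case(32, 4, 20)
  q <- flow_rate(pc$field)
  expect_lt(abs(q - pc$q_true) / pc$q_true, 0.03)
  qs <- vapply(c(5, 11, 17), function(s) flow_rate(pc$field, s), numeric(1))
  expect_lt((max(qs) - min(qs)) / mean(qs), 0.01)
  # zero field -> zero flow
  f0 <- solve_steady(pc$mesh, fluid_props(), 0)
  expect_identical(flow_rate(f0), 0)
})

test_that("cycle volumes reproduce a hand-worked trapezoid oracle", {
  cv <- cycle_volumes(c(2, 1, -0.5, 1.5), times = c(0, 0.1, 0.2, 0.3))
  expect_equal(cv$V_F, 0.275, tolerance = 1e-12)
  expect_equal(cv$V_B, 0.05, tolerance = 1e-12)
  expect_equal(cv$SV, 0.225, tolerance = 1e-12)
  expect_equal(cv$eta, 1 - 0.05 / 0.275, tolerance = 1e-12)
  # no backflow -> eta = 1; zero-mean alternation -> SV = 0, eta = 0
  allfwd <- cycle_volumes(c(1, 2, 3), weights = rep(0.1, 3))
  expect_identical(allfwd$V_B, 0)
  expect_identical(allfwd$eta, 1)
  sym <- cycle_volumes(c(1, -1, 1, -1), weights = rep(0.25, 4))
  expect_equal(sym$SV, 0, tolerance = 1e-12)
  expect_equal(sym$eta, 0, tolerance = 1e-12)
  # degenerate: V_F = 0 flags eta undefined
  none <- cycle_volumes(c(-1, -2), weights = c(1, 1))
  expect_false(none$eta_defined)
  expect_true(is.na(none$eta))
})

test_that("unrolled maps preserve structure and area-weighted integrals", {
  e2e <- end_to_end_run()
  wss <- cached("e2e_wss", wall_shear_series(e2e$sim))
  # uniform values -> constant map
  um_const <- unroll_surface(wss, values = rep(3, dim(wss$tau)[1]))
  expect_equal(diff(range(um_const$values)), 0)
  # integral conservation under resampling
  um <- unroll_surface(wss)
  um2 <- unroll_surface(wss, n_theta_out = 2 * wss$grid_dim[2],
                        n_s_out = 2 * wss$grid_dim[1])
  i1 <- sum(um$values * um$area_weights)
  i2 <- sum(um2$values * um2$area_weights)
  expect_lt(abs(i2 - i1) / i1, 0.02)
  # orientation: inlet at the bottom (first row = s_norm 0)
  expect_equal(um$s_norm[1], 0)
})

test_that("tapered-tube WSS maps follow the local Poiseuille scaling", {
  ser <- contour_series_from_radius(function(s, p) 0.22 - 0.04 * s, 21,
                                    0.05, n_phases = 2)
  sim <- simulate_cycle(ser, rep(30, 2), fluid_props(),
                        mesh_args = list(
                          target_circumferential_divisions = 16,
                          radial_layers = 2))
  wss <- wall_shear_series(sim)
  um <- unroll_surface(wss)
  # axisymmetric: constant along each row
  row_cv <- apply(um$values, 1, function(r) sd(r) / mean(r))
  expect_lt(max(row_cv), 0.02)
  # |tau| ~ 1/r^3 between wide and narrow ends (local Poiseuille)
  interior <- c(3, nrow(um$values) - 2)
  r_at <- 0.22 - 0.04 * um$s_norm[interior]
  expected_ratio <- (r_at[1] / r_at[2])^3
  got_ratio <- mean(um$values[interior[2], ]) / mean(um$values[interior[1], ])
  expect_lt(abs(got_ratio - expected_ratio) / expected_ratio, 0.1)
  expect_gt(got_ratio, 1)
})

test_that("hemodynamic summaries satisfy their defining identities", {
  e2e <- end_to_end_run()
  wss <- cached("e2e_wss", wall_shear_series(e2e$sim))
  hs <- cached("e2e_summary", summarize_hemodynamics(e2e$sim, wss))
  expect_equal(hs$SV, hs$V_F - hs$V_B, tolerance = 1e-12)
  expect_equal(hs$eta, 1 - hs$V_B / hs$V_F, tolerance = 1e-12)
  expect_gte(hs$V_F, 0); expect_gte(hs$V_B, 0)
  expect_lte(hs$eta, 1)
  expect_true(all(wss$osi >= 0 & wss$osi <= 0.5))
  expect_gte(hs$max_wss, hs$mean_wss)
  expect_gt(hs$max_forward_velocity, 0)
  expect_lt(hs$max_backward_velocity, 0)
  td <- tidy(hs)
  expect_true(all(c("metric", "value", "units") %in% names(td)))
  expect_equal(nrow(glance(hs)), 1)
})

test_that("a single-phase uniform run has max WSS equal to mean WSS", {
  ser <- contour_series_from_radius(function(s, p) 0.2, 11, 0.1,
                                    n_phases = 2)
  sim <- simulate_cycle(ser, rep(25, 2), fluid_props(),
                        mesh_args = list(
                          target_circumferential_divisions = 16,
                          radial_layers = 2))
  hs <- summarize_hemodynamics(sim)
  # uniform straight tube: spatial variation only from discretization
  expect_lt((hs$max_wss - hs$mean_wss) / hs$mean_wss, 0.1)
})

test_that("weaker cushions increase regurgitation and lower efficiency", {
  run_cushion <- function(depth) {
    cfg <- tiny_config(cushion_depth = depth, n_slices = 10,
                       wave_speed = 2)
    ser <- phantom_contours(cfg, n_phases = 40)
    # measured centerline velocity at the monitor slice
    phases <- (seq_len(40) - 0.5) / 40
    s_mon <- 0.5
    targets <- vapply(phases, function(phi) {
      R <- phantom_radius(cfg, s_mon, phi)
      Q <- phantom_flow_rate(cfg, s_mon, phi)
      if (R < 0.045) 0 else 2 * Q / (pi * R^2)
    }, numeric(1))
    sim <- suppressWarnings(simulate_cycle(
      ser, targets, fluid_props(),
      mesh_args = list(target_circumferential_divisions = 16,
                       radial_layers = 2),
      period_s = cfg$period_ms / 1000))
    summarize_hemodynamics(sim)
  }
  weak <- cached("cushion_weak", run_cushion(0.5))
  strong <- cached("cushion_strong", run_cushion(0.95))
  expect_gt(weak$V_B, strong$V_B)
  expect_lt(weak$eta, strong$eta)
})
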