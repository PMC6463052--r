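test_that("contour areas follow the shoelace formula", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(contour_area(square), 1)
  theta <- 2 * pi * (0:63) / 64
  gon <- cbind(0.2 * cos(theta), 0.2 * sin(theta))
  expect_equal(contour_area(gon), pi * 0.04, tolerance = 0.002)
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(contour_area(bowtie), "self-intersecting")
  # closed-lumen contour has zero area
  ser <- contour_series_from_radius(function(s, p) 0.01, 3, 0.02,
                                    n_phases = 1)
  expect_identical(ser$contours[[1]][[1]]$area, 0)
})

test_that("slab volumes match closed forms and are additive", {
  cyl <- contour_series_from_radius(function(s, p) 0.2, 51, 0.02,
                                    n_phases = 1)
  expect_equal(slab_volume(cyl, 1), pi * 0.04 * 1, tolerance = 0.01)
  cone <- contour_series_from_radius(function(s, p) 0.1 + 0.2 * s, 51, 0.02,
                                     n_phases = 1)
  frustum <- pi / 3 * 1 * (0.1^2 + 0.1 * 0.3 + 0.3^2)
  expect_equal(slab_volume(cone, 1), frustum, tolerance = 0.02)
  # additivity over contiguous slice ranges (split at slice 26, shared
  # boundary slice weighted by its half-gaps on each side)
  sub1 <- cone; sub2 <- cone
  sub1$contours <- cone$contours[1:26]
  sub1$n_slices <- 26
  sub1$areas <- cone$areas[1:26, , drop = FALSE]
  sub1$centroids <- cone$centroids[1:26, , , drop = FALSE]
  sub2$contours <- cone$contours[26:51]
  sub2$n_slices <- 26
  sub2$areas <- cone$areas[26:51, , drop = FALSE]
  sub2$centroids <- cone$centroids[26:51, , , drop = FALSE]
  # the shared slice's two half-gaps in the subranges add up to its full
  # gap in the whole, so the split volumes sum exactly
  expect_equal(slab_volume(sub1, 1) + slab_volume(sub2, 1),
               slab_volume(cone, 1), tolerance = 1e-12)
})

test_that("centerline length is measured at the most closed phase", {
  straight <- contour_series_from_radius(function(s, p) 0.15, 51, 0.02,
                                         n_phases = 1)
  expect_equal(as.numeric(centerline_length(straight)), 1.0,
               tolerance = 1e-12)
  # quarter circle of radius 0.64 mm in the (x, z) plane: slices sit at
  # uniform z in [0, R], so theta = asin(z/R) and x = R (1 - cos theta)
  Rarc <- 0.64
  n <- 51
  arc <- contour_series_from_radius(
    function(s, p) 0.1, n, Rarc / (n - 1), n_phases = 1,
    centroid_fn = function(s) c(Rarc * (1 - sqrt(1 - min(s, 1)^2)), 0))
  expect_equal(as.numeric(centerline_length(arc)), pi * Rarc / 2,
               tolerance = 0.02)
  # rigid translation leaves the length unchanged
  shifted <- contour_series_from_radius(
    function(s, p) 0.15, 51, 0.02, n_phases = 1,
    centroid_fn = function(s) c(0.3, -0.2))
  expect_equal(as.numeric(centerline_length(shifted)), 1.0,
               tolerance = 1e-12)
  # the reported phase is the minimum-volume phase
  cfg <- tiny_config()
  ser <- phantom_contours(cfg, n_phases = 20)
  cl <- centerline_length(ser)
  expect_equal(attr(cl, "phase"), which.min(volume_waveform(ser)))
})

test_that("area-motion matrices capture the traveling contraction wave", {
  cfg_static <- tiny_config(pulsation_amplitude = 0, cushion_depth = 0)
  am0 <- area_motion(phantom_contours(cfg_static, n_phases = 30))
  expect_lt(max(apply(am0$values, 1, sd)), 1e-12)

  for (w in c(1.5, 2.5)) {
    cfg <- tiny_config(wave_speed = w, cushion_depth = 0, n_slices = 21)
    am <- area_motion(phantom_contours(cfg, n_phases = 100))
    expect_lt(abs(am$phase_lag_slope - 1 / w) / (1 / w), 0.05)
  }

  # lumen area never exceeds the enclosing wall-layer area
  cfg <- tiny_config()
  lum <- phantom_contours(cfg, n_phases = 20)
  wall <- contour_series_from_radius(
    function(s, p) phantom_outer_radius(cfg, s, p),
    cfg$n_slices, cfg$slice_spacing_um / 1000, n_phases = 20)
  expect_true(all(lum$areas <= wall$areas + 1e-12))
})

test_that("meshes are watertight, well-shaped and volume-consistent", {
  cyl <- contour_series_from_radius(function(s, p) 0.2, 21, 0.05,
                                    n_phases = 1)
  msh <- build_mesh(cyl, 1)
  expect_gt(msh$min_jacobian, 0)
  expect_equal(mesh_volume(msh), pi * 0.04 * 1, tolerance = 0.01)
  # extensions exist, are tagged, and are excluded from the body volume
  expect_true(msh$includes_extensions)
  expect_gt(mesh_volume(msh, body_only = FALSE), mesh_volume(msh))
  # boundary tags partition: wall nodes disjoint from interior, inlet and
  # outlet faces sit at the end sections
  expect_length(intersect(msh$wall_nodes, msh$monitor_node), 0)
  expect_true(all(msh$nodes[msh$inlet_nodes, 3] == min(msh$nodes[, 3])))
  expect_true(all(msh$nodes[msh$outlet_nodes, 3] == max(msh$nodes[, 3])))
})

test_that("slab and mesh volumes of the same phantom geometry agree within 2%", {
  cfg <- phantom_config(n_slices = 51, slice_spacing_um = 20,
                        speckle_noise_sd = 0)
  ser <- phantom_contours(cfg, n_phases = 4)
  open_phase <- which(colSums(ser$closed) == 0)[1]
  msh <- build_mesh(ser, open_phase)
  sv <- slab_volume(ser, open_phase)
  mv <- mesh_volume(msh)
  expect_lt(abs(mv - sv) / sv, 0.02)
})

test_that("mesh volume is stable under resolution doubling", {
  cyl <- contour_series_from_radius(function(s, p) 0.18 * (1 + 0.2 * s),
                                    21, 0.05, n_phases = 1)
  v1 <- mesh_volume(build_mesh(cyl, 1, target_circumferential_divisions = 16,
                               radial_layers = 2))
  v2 <- mesh_volume(build_mesh(cyl, 1, target_circumferential_divisions = 32,
                               radial_layers = 4,
                               target_axial_layers = 40))
  expect_lt(abs(v2 - v1) / v1, 0.005)
})

test_that("mesh resolution scales to tens of thousands of cells", {
  cyl <- contour_series_from_radius(function(s, p) 0.2, 21, 0.05,
                                    n_phases = 1)
  msh <- build_mesh(cyl, 1, target_circumferential_divisions = 32,
                    radial_layers = 4, target_axial_layers = 60)
  expect_gt(nrow(msh$elems), 10000)
  expect_gt(msh$min_jacobian, 0)
})

test_that("closed phases are refused by the mesher", {
  cfg <- tiny_config(cushion_depth = 1)
  ser <- phantom_contours(cfg, n_phases = 20)
  closed_phase <- which(colSums(ser$closed) > 0)[1]
  expect_error(build_mesh(ser, closed_phase),
               class = "oftflow_closed_phase")
})

test_that("meshes export to legacy VTK text format", {
  cyl <- contour_series_from_radius(function(s, p) 0.2, 6, 0.05,
                                    n_phases = 1)
  msh <- build_mesh(cyl, 1, include_extensions = FALSE)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(msh, path, point_data = list(z = msh$nodes[, 3]))
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("SCALARS z double", lines)))
})
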