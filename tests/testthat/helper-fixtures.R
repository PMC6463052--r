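# Shared fixtures, memoized across test files (helpers are sourced once
# per test run). All phantoms here are deliberately small so the whole
# suite stays fast; the generator itself is exercised at full scale by the
# acceptance script.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_config <- function(...) {
  args <- list(n_slices = 8, frames_per_sequence = 120,
               pixel_size_um = 20, slice_spacing_um = 60,
               speckle_noise_sd = 0, cushion_depth = 0.6)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

tiny_phantom <- function() {
  cached("tiny_phantom", generate_phantom(tiny_config(), seed = 42))
}

# straight cylinder r = 0.2 mm, L = 1 mm: series, mesh and unit-traction
# Stokes solution
poiseuille_case <- function(nc = 24, nr = 3, nax = 20) {
  cached(sprintf("pois_%d_%d_%d", nc, nr, nax), {
    ser <- contour_series_from_radius(function(s, p) 0.2, nax + 1, 1 / nax,
                                      n_phases = 1, n_vertices = 128)
    msh <- build_mesh(ser, 1, target_circumferential_divisions = nc,
                      radial_layers = nr, include_extensions = FALSE)
    ff <- solve_steady(msh, fluid_props(), 1, stab_alpha = 0.05)
    list(series = ser, mesh = msh, field = ff,
         v_true = 1 * 0.2^2 / (4 * 0.003 * 1),
         q_true = pi * 0.2^4 * 1 / (8 * 0.003 * 1),
         tau_true = 4 * 0.003 * (pi * 0.2^4 / (8 * 0.003 * 1)) /
           (pi * 0.2^3))
  })
}

# small but complete phantom -> sync -> segment -> flow -> hemo run
end_to_end_run <- function() {
  cached("e2e", {
    cfg <- phantom_config(n_slices = 12, frames_per_sequence = 160,
                          pixel_size_um = 18, slice_spacing_um = 50,
                          speckle_noise_sd = 0.04, cushion_depth = 0.9)
    ph <- generate_phantom(cfg, seed = 11)
    sy <- sync_dataset(ph)
    ser <- segment_series(sy)
    tg <- doppler_targets(sy, beam_tilt_deg = cfg$beam_tilt_deg)
    sim <- simulate_cycle(
      ser, tg$target_mm_s, fluid_props(),
      mesh_args = list(target_circumferential_divisions = 16,
                       radial_layers = 2),
      period_s = cfg$period_ms / 1000
    )
    list(config = cfg, phantom = ph, synced = sy, series = ser,
         targets = tg, sim = sim)
  })
}
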