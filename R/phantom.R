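#' Phantom acquisition configuration
#'
#' Builds the configuration for the synthetic 4-D acquisition phantom: a
#' peristaltically deforming tube imaged as one longitudinal b-mode sequence
#' plus a stack of cross-sectional b-mode sequences (20 um apart by default),
#' each 200 frames at 140 frames/s and each starting at an unknown random
#' cardiac phase, with paired per-pixel beam-axis (Doppler) velocity planes.
#'
#' The wall motion model is a traveling wave with an endocardial-cushion
#' constriction:
#' \deqn{R(s,\phi) = R_0(s)\,[1 + a\sin 2\pi(\phi - s/w)]\,
#'       [1 - c\,b(s)\,g(\phi)]}
#' where `s` is normalized axial position (0 = inlet), `phi` the cardiac phase
#' in cycles, `a` the pulsation amplitude, `w` the wave speed (fraction of
#' tube length traveled per cycle, so the inlet-to-outlet phase lag is `1/w`
#' cycles), `b(s)` a Gaussian bump at the cushion location and `g(phi)` a
#' smooth gate active during the backflow half of the cycle. `c = 1` closes
#' the lumen completely at the cushion.
#'
#' @param base_radius_profile function of normalized axial position
#'   `s in [0,1]` returning the baseline lumen radius in mm; must be strictly
#'   positive. Default: a smooth 0.15 mm tube with a mild mid-length bulge.
#' @param pulsation_amplitude dimensionless radial pulsation fraction,
#'   `0 <= a < 1`.
#' @param wave_speed fraction of tube length the contraction wave travels per
#'   cardiac cycle; the inlet-to-outlet phase lag is `1/wave_speed` cycles.
#' @param cushion_depth constriction factor at the cushion, 0 (none) to 1
#'   (full closure).
#' @param cushion_center,cushion_width normalized axial position and Gaussian
#'   width of the cushion bump.
#' @param period_ms cardiac period T in milliseconds.
#' @param fps acquisition frame rate (frames per second).
#' @param frames_per_sequence frames per b-mode sequence.
#' @param slice_spacing_um spacing between cross-sectional planes (micron).
#' @param n_slices number of cross-sectional sequences (inlet to outlet); the
#'   tube length is `(n_slices - 1) * slice_spacing_um / 1000` mm.
#' @param beam_tilt_deg angle between the tube axis and the imaging beam
#'   axis; Doppler planes record `cos(beam_tilt_deg)` times the axial speed.
#' @param pixel_size_um isotropic image resolution (micron per pixel).
#' @param speckle_noise_sd additive Gaussian intensity noise (image intensity
#'   is on a 0-1 scale with wall contrast about 0.9).
#' @param phase_offset_seed RNG seed for the per-slice starting phases; when
#'   `NULL` the seed passed to [generate_phantom()] is used.
#' @param peak_inlet_velocity_mm_s peak centerline velocity of the driving
#'   inlet waveform (mm/s).
#' @param backflow_fraction magnitude of the backflow half-wave relative to
#'   the forward half-wave of the inlet velocity waveform.
#' @param wall_thickness_factor outer (myocardial) boundary radius at rest as
#'   a multiple of the local baseline lumen radius; wall tissue cross-section
#'   area is conserved as the lumen deforms, so cushions bulge inward.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @seealso [generate_phantom()], [phantom_preset()]
#' @export
phantom_config <- function(base_radius_profile = NULL,
                           pulsation_amplitude = 0.22,
                           wave_speed = 2,
                           cushion_depth = 0.9,
                           cushion_center = 0.35,
                           cushion_width = 0.12,
                           period_ms = 400,
                           fps = 140,
                           frames_per_sequence = 200,
                           slice_spacing_um = 20,
                           n_slices = 31,
                           beam_tilt_deg = 45,
                           pixel_size_um = 15,
                           speckle_noise_sd = 0.05,
                           phase_offset_seed = NULL,
                           peak_inlet_velocity_mm_s = 70,
                           backflow_fraction = 0.35,
                           wall_thickness_factor = 1.45) {
  if (is.null(base_radius_profile)) {
    base_radius_profile <- function(s) 0.15 * (1 + 0.2 * sin(pi * s))
  }
  cfg <- list(
    base_radius_profile = base_radius_profile,
    pulsation_amplitude = pulsation_amplitude,
    wave_speed = wave_speed,
    cushion_depth = cushion_depth,
    cushion_center = cushion_center,
    cushion_width = cushion_width,
    period_ms = period_ms,
    fps = fps,
    frames_per_sequence = frames_per_sequence,
    slice_spacing_um = slice_spacing_um,
    n_slices = n_slices,
    beam_tilt_deg = beam_tilt_deg,
    pixel_size_um = pixel_size_um,
    speckle_noise_sd = speckle_noise_sd,
    phase_offset_seed = phase_offset_seed,
    peak_inlet_velocity_mm_s = peak_inlet_velocity_mm_s,
    backflow_fraction = backflow_fraction,
    wall_thickness_factor = wall_thickness_factor
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(
    cfg$period_ms > 0, cfg$fps > 0,
    cfg$frames_per_sequence >= 2,
    cfg$slice_spacing_um > 0, cfg$n_slices >= 2,
    cfg$pixel_size_um > 0, cfg$speckle_noise_sd >= 0,
    cfg$wave_speed > 0, cfg$wall_thickness_factor > 1
  )
  if (cfg$fps * cfg$period_ms / 1000 < 2) {
    stop("fps and period_ms give fewer than 2 frames per cardiac cycle",
         call. = FALSE)
  }
  if (cfg$pulsation_amplitude < 0 || cfg$pulsation_amplitude >= 1) {
    stop("pulsation_amplitude must be in [0, 1)", call. = FALSE)
  }
  if (cfg$cushion_depth < 0 || cfg$cushion_depth > 1) {
    stop("cushion_depth must be in [0, 1]", call. = FALSE)
  }
  r0 <- cfg$base_radius_profile(seq(0, 1, length.out = 101))
  if (any(!is.finite(r0)) || any(r0 <= 0)) {
    stop("base_radius_profile must be strictly positive on [0, 1]",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Developmental-stage phantom presets
#'
#' Returns a [phantom_config()] whose cardiac period, tube length and radius
#' scale are anchored to the Hamburger-Hamilton looping stages HH14-HH18
#' (periods about 400-507 ms, outflow-tract lengths about 0.54-0.78 mm), with
#' driving velocities chosen so peak centerline velocities fall in the
#' 43-90 mm/s range typical of these stages. Presets are plausibility
#' anchors for the synthetic phantom, not reproductions of any embryo.
#'
#' @param stage one of `"HH14"`, `"HH15"`, `"HH16"`, `"HH17"`, `"HH18"`.
#' @param ... overrides forwarded to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_preset <- function(stage = c("HH17", "HH14", "HH15", "HH16", "HH18"),
                           ...) {
  stage <- match.arg(stage)
  p <- switch(stage,
    HH14 = list(period_ms = 486, length_mm = 0.54, r = 0.13, v = 45),
    HH15 = list(period_ms = 507, length_mm = 0.59, r = 0.14, v = 50),
    HH16 = list(period_ms = 408, length_mm = 0.73, r = 0.17, v = 75),
    HH17 = list(period_ms = 410, length_mm = 0.78, r = 0.19, v = 85),
    HH18 = list(period_ms = 400, length_mm = 0.69, r = 0.18, v = 62)
  )
  args <- list(
    base_radius_profile = local({
      r <- p$r
      function(s) r * (1 + 0.15 * sin(pi * s))
    }),
    period_ms = p$period_ms,
    n_slices = round(p$length_mm / 0.02) + 1L,
    slice_spacing_um = 20,
    peak_inlet_velocity_mm_s = p$v
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  period %g ms, %g fps (%.1f frames/cycle), %d x %d frames\n",
              x$period_ms, x$fps, frames_per_cycle(x),
              x$n_slices, x$frames_per_sequence))
  cat(sprintf("  tube length %.2f mm (%d slices at %g um)\n",
              phantom_length_mm(x), x$n_slices, x$slice_spacing_um))
  cat(sprintf("  pulsation %.2f, wave speed %.2f, cushion depth %.2f\n",
              x$pulsation_amplitude, x$wave_speed, x$cushion_depth))
  invisible(x)
}

#' Frames per cardiac cycle for a configuration
#' @param config a `phantom_config`.
#' @return `fps * period_ms / 1000`.
#' @export
frames_per_cycle <- function(config) config$fps * config$period_ms / 1000

#' Tube length in mm implied by a configuration
#' @param config a `phantom_config`.
#' @export
phantom_length_mm <- function(config) {
  (config$n_slices - 1) * config$slice_spacing_um / 1000
}

cushion_bump <- function(cfg, s) {
  exp(-(s - cfg$cushion_center)^2 / (2 * cfg$cushion_width^2))
}

cushion_gate <- function(phi) pmax(0, -sin(2 * pi * phi))^2

cushion_gate_dphi <- function(phi) {
  m <- pmax(0, -sin(2 * pi * phi))
  -2 * m * cos(2 * pi * phi) * 2 * pi
}

#' Analytic lumen radius field of a phantom
#'
#' @param config a `phantom_config`.
#' @param s normalized axial position(s) in `[0, 1]`.
#' @param phase cardiac phase(s) in cycles; recycled against `s`.
#' @return Lumen radius in mm (vectorized).
#' @export
phantom_radius <- function(config, s, phase) {
  r0 <- config$base_radius_profile(s)
  wave <- 1 + config$pulsation_amplitude *
    sin(2 * pi * (phase - s / config$wave_speed))
  gate <- 1 - config$cushion_depth * cushion_bump(config, s) *
    cushion_gate(phase)
  r0 * wave * pmax(gate, 0)
}

# dR/dphase (mm per cycle)
phantom_radius_dphi <- function(config, s, phase) {
  r0 <- config$base_radius_profile(s)
  a <- config$pulsation_amplitude
  wave <- 1 + a * sin(2 * pi * (phase - s / config$wave_speed))
  dwave <- a * 2 * pi * cos(2 * pi * (phase - s / config$wave_speed))
  b <- config$cushion_depth * cushion_bump(config, s)
  gate <- 1 - b * cushion_gate(phase)
  dgate <- -b * cushion_gate_dphi(phase)
  r0 * (dwave * pmax(gate, 0) + wave * ifelse(gate > 0, dgate, 0))
}

# outer (myocardial) radius: wall tissue area conserved as the lumen deforms
phantom_outer_radius <- function(config, s, phase) {
  r0 <- config$base_radius_profile(s)
  wall_area <- pi * ((config$wall_thickness_factor * r0)^2 - r0^2)
  sqrt(phantom_radius(config, s, phase)^2 + wall_area / pi)
}

# inlet centerline velocity waveform (mm/s): forward half-wave plus a weaker
# backflow half-wave, so regurgitation exists for the cushions to block
phantom_inlet_velocity <- function(config, phase) {
  sn <- sin(2 * pi * phase)
  config$peak_inlet_velocity_mm_s *
    (pmax(sn, 0) + config$backflow_fraction * pmin(sn, 0))
}

# inlet volumetric flow rate (mm^3/s); mean velocity is half the centerline
# velocity for a parabolic profile
phantom_inlet_q <- function(config, phase) {
  0.5 * phantom_inlet_velocity(config, phase) * pi *
    phantom_radius(config, 0, phase)^2
}

#' Analytic flow rate field of a phantom
#'
#' Local volumetric flow rate `Q(s, phase)` obtained from the inlet waveform
#' minus the rate of change of the lumen volume upstream of `s` (mass
#' conservation in a deforming tube).
#'
#' @param config a `phantom_config`.
#' @param s normalized axial position(s).
#' @param phase cardiac phase(s) in cycles, same length as `s` or scalar.
#' @param n_int number of quadrature points for the upstream-volume integral.
#' @return Flow rate in mm^3/s.
#' @export
phantom_flow_rate <- function(config, s, phase, n_int = 201) {
  n <- max(length(s), length(phase))
  s <- rep_len(s, n)
  phase <- rep_len(phase, n)
  L <- phantom_length_mm(config)
  T_s <- config$period_ms / 1000
  qin <- phantom_inlet_q(config, phase)

  upstream_one <- function(s_i, phi_i) {
    if (s_i <= 0) return(0)
    sg <- seq(0, s_i, length.out = n_int)
    dadt <- 2 * pi * phantom_radius(config, sg, phi_i) *
      phantom_radius_dphi(config, sg, phi_i) / T_s
    sum((dadt[-1] + dadt[-n_int]) / 2) * (sg[2] - sg[1]) * L
  }

  if (length(unique(s)) == 1L) {
    # fixed slice, many phases: integrate dA/dt on a common grid at once
    if (s[1] <= 0) return(qin)
    sg <- seq(0, s[1], length.out = n_int)
    Rm <- outer(sg, phase, function(a, b) phantom_radius(config, a, b))
    dRm <- outer(sg, phase,
                 function(a, b) phantom_radius_dphi(config, a, b))
    dadt <- 2 * pi * Rm * dRm / T_s
    h <- sg[2] - sg[1]
    upstream <- colSums((dadt[-1, , drop = FALSE] +
                           dadt[-n_int, , drop = FALSE]) / 2) * h * L
    return(qin - upstream)
  }
  if (length(unique(phase)) == 1L) {
    # one phase, many stations: cumulative trapezoid along the tube
    sg <- seq(0, 1, length.out = n_int)
    dadt <- 2 * pi * phantom_radius(config, sg, phase[1]) *
      phantom_radius_dphi(config, sg, phase[1]) / T_s
    h <- sg[2] - sg[1]
    cum <- c(0, cumsum((dadt[-1] + dadt[-n_int]) / 2) * h * L)
    upstream <- stats::approx(sg, cum, xout = pmin(pmax(s, 0), 1))$y
    return(qin - upstream)
  }
  qin - vapply(seq_len(n), function(i) upstream_one(s[i], phase[i]),
               numeric(1))
}

#' Analytic velocity field sampler
#'
#' Returns a function sampling the phantom's quasi-Poiseuille axial velocity
#' field at a given phase: the local flow rate follows mass conservation
#' (see [phantom_flow_rate()]) and the radial profile is parabolic with
#' no-slip at the moving wall. Velocity components are expressed in the tube
#' frame (x, y transverse; z axial).
#'
#' @param config a `phantom_config`.
#' @param phase cardiac phase in `[0, 1)`.
#' @return A function `f(points)` taking an `n x 3` matrix of tube-frame
#'   coordinates in mm (`z` in `[0, L]`) and returning an `n x 3` matrix of
#'   velocities in mm/s (zero outside the lumen).
#' @export
analytic_flow <- function(config, phase) {
  stopifnot(length(phase) == 1, phase >= 0, phase < 1)
  L <- phantom_length_mm(config)
  force(config)
  function(points) {
    points <- rbind(points)
    r <- sqrt(points[, 1]^2 + points[, 2]^2)
    s <- pmin(pmax(points[, 3] / L, 0), 1)
    R <- phantom_radius(config, s, phase)
    Q <- phantom_flow_rate(config, s, rep(phase, length(s)))
    u <- ifelse(R > 1e-9 & r < R, 2 * Q / (pi * R^2) * (1 - (r / R)^2), 0)
    cbind(0, 0, u)
  }
}

# axial velocity at radial distance r, slice s (vectorized over frames)
phantom_axial_velocity <- function(config, r, R, Q) {
  ifelse(R > 1e-9 & r < R, 2 * Q / (pi * R^2) * (1 - (r / R)^2), 0)
}

new_bmode_sequence <- function(frames, fps, acquisition_start_ms = 0) {
  structure(list(frames = frames, fps = fps,
                 acquisition_start_ms = acquisition_start_ms),
            class = "bmode_sequence")
}

new_doppler_sequence <- function(frames, fps, acquisition_start_ms = 0) {
  structure(list(frames = frames, fps = fps,
                 acquisition_start_ms = acquisition_start_ms),
            class = "doppler_sequence")
}

#' @export
print.bmode_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<bmode_sequence> %d frames of %d x %d at %g fps\n",
              d[1], d[2], d[3], x$fps))
  invisible(x)
}

#' @export
print.doppler_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<doppler_sequence> %d frames of %d x %d at %g fps (mm/s)\n",
              d[1], d[2], d[3], x$fps))
  invisible(x)
}

# smoothstep edge profile used for sub-pixel wall rendering
smoothstep01 <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# render one cross-sectional intensity frame from the pixel distance map
render_annulus <- function(dist_px, r_in_px, r_out_px, edge_px,
                           lumen = 0.15, wall = 1, bg = 0.05) {
  s1 <- smoothstep01((dist_px - r_in_px) / edge_px + 0.5)
  s2 <- smoothstep01((dist_px - r_out_px) / edge_px + 0.5)
  lumen * (1 - s1) + wall * s1 * (1 - s2) + bg * s1 * s2
}

#' Generate a synthetic non-gated 4-D phantom dataset
#'
#' Produces one longitudinal b-mode/Doppler sequence along the tube plus a
#' stack of cross-sectional sequences (inlet to outlet), each starting at a
#' random cardiac phase drawn from the seeded RNG, with full ground truth.
#' The wall appears as a bright band around a dark lumen with additive
#' Gaussian speckle; Doppler planes equal the beam-axis projection
#' (`cos(beam_tilt_deg)`) of the analytic axial velocity, zero outside the
#' lumen.
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed; identical config and seed give bit-identical
#'   datasets.
#' @return An object of class `phantom_dataset`: list with elements
#'   `longitudinal` (`$bmode`, `$doppler`), `cross` (list of
#'   `$bmode`/`$doppler` pairs, inlet to outlet), `truth` (period, per-slice
#'   starting phases, analytic radius/velocity/flow-rate fields) and
#'   `config`.
#' @export
generate_phantom <- function(config, seed = 1L) {
  validate_phantom_config(config)
  set.seed(seed)
  n_sl <- config$n_slices
  offsets <- if (is.null(config$phase_offset_seed)) {
    stats::runif(n_sl)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    set.seed(config$phase_offset_seed)
    o <- stats::runif(n_sl)
    assign(".Random.seed", old, envir = globalenv())
    o
  }

  px <- config$pixel_size_um / 1000  # mm per pixel
  L <- phantom_length_mm(config)
  nf <- config$frames_per_sequence
  T_s <- config$period_ms / 1000
  ctilt <- cos(config$beam_tilt_deg * pi / 180)
  edge_px <- 1.2

  # canvas sized to the largest outer radius plus margin
  sg <- seq(0, 1, length.out = 101)
  pg <- seq(0, 1, length.out = 101)
  rmax <- max(outer(sg, pg, function(s, p) phantom_outer_radius(config, s, p)))
  half_px <- ceiling(rmax / px) + 4L
  n_pix <- 2L * half_px + 1L
  ctr <- half_px + 1L
  # pixel distance map from the tube center (pixels)
  ii <- matrix(seq_len(n_pix), n_pix, n_pix)
  jj <- t(ii)
  dist_px <- sqrt((ii - ctr)^2 + (jj - ctr)^2)

  frame_phase <- function(offset) {
    (offset + (seq_len(nf) - 1) / config$fps / T_s) %% 1
  }

  dop_noise_sd <- config$speckle_noise_sd *
    config$peak_inlet_velocity_mm_s * 0.5

  make_cross <- function(k) {
    s_k <- (k - 1) / (n_sl - 1)
    phis <- frame_phase(offsets[k])
    Rl <- phantom_radius(config, s_k, phis)
    Ro <- phantom_outer_radius(config, s_k, phis)
    Qs <- phantom_flow_rate(config, rep(s_k, nf), phis)
    bm <- array(0, dim = c(nf, n_pix, n_pix))
    dp <- array(0, dim = c(nf, n_pix, n_pix))
    for (t in seq_len(nf)) {
      img <- render_annulus(dist_px, Rl[t] / px, Ro[t] / px, edge_px)
      vel <- phantom_axial_velocity(config, dist_px * px, Rl[t], Qs[t]) * ctilt
      bm[t, , ] <- img
      dp[t, , ] <- vel
    }
    if (config$speckle_noise_sd > 0) {
      bm <- bm + array(stats::rnorm(length(bm), 0, config$speckle_noise_sd),
                       dim = dim(bm))
      dp <- dp + array(stats::rnorm(length(dp), 0, dop_noise_sd),
                       dim = dim(dp))
    }
    list(bmode = new_bmode_sequence(bm, config$fps),
         doppler = new_doppler_sequence(dp, config$fps))
  }

  cross <- lapply(seq_len(n_sl), make_cross)

  # longitudinal plane through the axis: rows = depth, cols = axial position
  n_cols <- ceiling(L / px) + 9L
  x_mm <- (seq_len(n_cols) - 5) * px
  s_col <- pmin(pmax(x_mm / L, 0), 1)
  depth_mm <- abs(seq_len(n_pix) - ctr) * px
  phis_l <- frame_phase(0)
  bm_l <- array(0, dim = c(nf, n_pix, n_cols))
  dp_l <- array(0, dim = c(nf, n_pix, n_cols))
  for (t in seq_len(nf)) {
    Rl <- phantom_radius(config, s_col, phis_l[t])
    Ro <- phantom_outer_radius(config, s_col, phis_l[t])
    Qs <- phantom_flow_rate(config, s_col, rep(phis_l[t], n_cols))
    dmat <- matrix(depth_mm, n_pix, n_cols)
    Rlm <- matrix(Rl, n_pix, n_cols, byrow = TRUE)
    Rom <- matrix(Ro, n_pix, n_cols, byrow = TRUE)
    Qm <- matrix(Qs, n_pix, n_cols, byrow = TRUE)
    bm_l[t, , ] <- render_annulus(dmat / px, Rlm / px, Rom / px, edge_px)
    dp_l[t, , ] <- phantom_axial_velocity(config, dmat, Rlm, Qm) * ctilt
  }
  if (config$speckle_noise_sd > 0) {
    bm_l <- bm_l + array(stats::rnorm(length(bm_l), 0,
                                      config$speckle_noise_sd),
                         dim = dim(bm_l))
    dp_l <- dp_l + array(stats::rnorm(length(dp_l), 0, dop_noise_sd),
                         dim = dim(dp_l))
  }

  truth <- list(
    period_ms = config$period_ms,
    period_frames = config$fps * config$period_ms / 1000,
    slice_phase_offsets = offsets,
    radius_field = function(s, phase) phantom_radius(config, s, phase),
    velocity_field = function(points, phase) analytic_flow(config, phase)(points),
    flow_rate_waveform = function(phase, s = 0) {
      phantom_flow_rate(config, rep(s, length(phase)), phase)
    },
    center_px = ctr,
    pixel_size_mm = px,
    slice_s = (seq_len(n_sl) - 1) / (n_sl - 1),
    long_col_of_slice = vapply(
      (seq_len(n_sl) - 1) / (n_sl - 1) * L,
      function(x) which.min(abs(x_mm - x)), integer(1))
  )

  structure(list(
    longitudinal = list(bmode = new_bmode_sequence(bm_l, config$fps),
                        doppler = new_doppler_sequence(dp_l, config$fps)),
    cross = cross,
    truth = truth,
    config = config
  ), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  d <- dim(x$cross[[1]]$bmode$frames)
  cat(sprintf(
    "<phantom_dataset> %d cross-sections (%d frames of %d x %d) + longitudinal\n",
    length(x$cross), d[1], d[2], d[3]))
  cat(sprintf("  true period %g ms (%.1f frames)\n",
              x$truth$period_ms, x$truth$period_frames))
  invisible(x)
}
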