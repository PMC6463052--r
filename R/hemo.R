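#' Wall shear stress vectors on the lumen wall
#'
#' Evaluates the fluid stress tensor `sigma = -p I + mu (grad v + grad v^T)`
#' at the wall and returns the tangential projection
#' `tau = sigma.n - [(sigma.n).n] n` at every wall point. On the no-slip
#' wall the velocity gradient reduces to its wall-normal part, which is
#' estimated by a one-sided three-point (quadratic) difference along the
#' structured radial node column - exact for a parabolic near-wall profile.
#' Extension-region points are flagged so they can be excluded from
#' analyses.
#'
#' @param field a `flow_field`.
#' @param mesh the `tube_mesh` (default `field$mesh`).
#' @param props a [fluid_props()] (default `field$props`).
#' @return An object of class `wall_shear_field`: arrays over the wall grid
#'   (`n_sections` x `n_circumferential`): `tau` (x 3, Pa), `tau_mag`,
#'   `sigma_n` (x 3), `normal` (x 3), `pressure`, plus `theta`, `s_norm`,
#'   `extension` flags and wall point coordinates.
#' @export
wall_shear <- function(field, mesh = field$mesh, props = field$props) {
  mu <- props$viscosity
  n_sec <- mesh$n_sections
  n_c <- mesh$template$n_c

  # outward unit normals: accumulate wall-face normals at nodes
  qf <- quad_face_integrals(mesh$nodes, mesh$wall_faces)
  nrm_acc <- matrix(0, nrow(mesh$nodes), 3)
  for (a in 1:4) {
    ids <- mesh$wall_faces[, a]
    for (k in 1:3) {
      nrm_acc[, k] <- nrm_acc[, k] +
        tabulate_add(ids, qf$normal[, k], nrow(mesh$nodes))
    }
  }

  tau <- array(0, dim = c(n_sec, n_c, 3))
  sigma_n <- array(0, dim = c(n_sec, n_c, 3))
  normal <- array(0, dim = c(n_sec, n_c, 3))
  pres <- matrix(0, n_sec, n_c)
  coords <- array(0, dim = c(n_sec, n_c, 3))

  W <- mesh$wall_grid; R1 <- mesh$ring1_grid; R2 <- mesh$ring2_grid
  for (s in seq_len(n_sec)) {
    w <- W[s, ]; r1 <- R1[s, ]; r2 <- R2[s, ]
    xw <- mesh$nodes[w, , drop = FALSE]
    n_s <- nrm_acc[w, , drop = FALSE]
    n_s <- n_s / pmax(sqrt(rowSums(n_s^2)), 1e-300)
    d1 <- sqrt(rowSums((mesh$nodes[r1, , drop = FALSE] - xw)^2))
    d2 <- sqrt(rowSums((mesh$nodes[r2, , drop = FALSE] - xw)^2))
    if (any(d2 <= d1) || any(d1 <= 0)) {
      stop("degenerate radial node column at the wall", call. = FALSE)
    }
    v1 <- field$velocity[r1, , drop = FALSE]
    v2 <- field$velocity[r2, , drop = FALSE]
    # quadratic one-sided derivative along the inward column, v(0) = 0
    a_in <- (v1 * (d2^2 / (d1 * d2 * (d2 - d1))) -
               v2 * (d1^2 / (d1 * d2 * (d2 - d1))))
    g <- -a_in  # dv/dn with n outward
    gn <- rowSums(g * n_s)
    sn <- -field$pressure[w] * n_s + mu * (g + gn * n_s)
    tang <- mu * (g - gn * n_s)
    tau[s, , ] <- tang
    sigma_n[s, , ] <- sn
    normal[s, , ] <- n_s
    pres[s, ] <- field$pressure[w]
    coords[s, , ] <- xw
  }

  structure(list(
    tau = tau, tau_mag = sqrt(apply(tau^2, c(1, 2), sum)),
    sigma_n = sigma_n, normal = normal, pressure = pres,
    coords = coords,
    theta = mesh$template$theta,
    s_norm = mesh$sections$s_norm,
    extension = mesh$sections$extension,
    n_sections = n_sec, n_c = n_c
  ), class = "wall_shear_field")
}

#' @export
print.wall_shear_field <- function(x, ...) {
  body <- !x$extension
  cat(sprintf("<wall_shear_field> %d x %d wall points, body max |tau| %.3g Pa\n",
              x$n_sections, x$n_c, max(x$tau_mag[body, ])))
  invisible(x)
}

#' Wall shear stress time series over a simulated cycle
#'
#' Collects the per-phase wall shear vectors of a [simulate_cycle()] result
#' on the fixed (angle, axial) wall parameterization of the tube body
#' (extensions excluded), together with the time weights of the simulated
#' phases, and computes the per-point oscillatory shear index.
#'
#' @param sim a `cycle_simulation` with kept fields.
#' @return An object of class `wall_shear_series`: `tau` (points x 3 x
#'   phases, Pa), `tau_mag`, `osi`, `theta`/`s_norm` grids, `phases`
#'   (simulated phase indices), `time_weights` (s, or cycle fraction when
#'   the period is unknown), `coords` (cycle-mean wall coordinates),
#'   `area_weights` (cycle-mean wall patch areas, mm^2).
#' @export
wall_shear_series <- function(sim) {
  simulated <- which(sim$status$simulated)
  if (!length(simulated)) stop("no simulated phases", call. = FALSE)
  phases <- sim$status$phase[simulated]
  first <- sim$meshes[[phases[1]]]
  if (is.null(first)) {
    stop("simulate_cycle() must be run with keep_fields = TRUE",
         call. = FALSE)
  }
  body <- which(!first$sections$extension)
  n_b <- length(body)
  n_c <- first$template$n_c
  n_pts <- n_b * n_c
  n_ph <- length(phases)

  tau <- array(0, dim = c(n_pts, 3, n_ph))
  coords_acc <- matrix(0, n_pts, 3)
  area_acc <- numeric(n_pts)
  for (i in seq_along(phases)) {
    p <- phases[i]
    mesh <- sim$meshes[[p]]
    wsf <- wall_shear(sim$fields[[p]], mesh, sim$props)
    bodyp <- which(!wsf$extension)
    tau[, , i] <- matrix(wsf$tau[bodyp, , ], n_pts, 3)
    coords_acc <- coords_acc + matrix(wsf$coords[bodyp, , ], n_pts, 3)
    # wall patch area per node: quarter of each adjacent wall face
    qf <- quad_face_integrals(mesh$nodes, mesh$wall_faces)
    aw <- numeric(nrow(mesh$nodes))
    for (a in 1:4) {
      aw <- aw + tabulate_add(mesh$wall_faces[, a], qf$area / 4,
                              nrow(mesh$nodes))
    }
    area_acc <- area_acc + aw[as.vector(mesh$wall_grid[body, ])]
  }
  dt <- if (!is.null(sim$period_s)) sim$period_s / sim$n_phases else
    1 / sim$n_phases
  w <- rep(dt, n_ph)
  s_grid <- first$sections$s_norm[body]
  res <- structure(list(
    tau = tau,
    tau_mag = sqrt(apply(tau^2, c(1, 3), sum)),
    theta = first$template$theta,
    s_norm = s_grid,
    grid_dim = c(n_b, n_c),
    phases = phases,
    time_weights = w,
    coords = coords_acc / n_ph,
    area_weights = area_acc / n_ph,
    period_s = sim$period_s
  ), class = "wall_shear_series")
  res$osi <- osi(res)
  res
}

#' @export
print.wall_shear_series <- function(x, ...) {
  cat(sprintf("<wall_shear_series> %d wall points x %d simulated phases; max |tau| %.3g Pa, max OSI %.3f\n",
              dim(x$tau)[1], dim(x$tau)[3], max(x$tau_mag), max(x$osi)))
  invisible(x)
}

#' Oscillatory shear index
#'
#' `OSI = 1/2 (1 - |int tau dt| / int |tau| dt)` with the integrals taken
#' by weighted quadrature over the simulated portion of the cycle (on the
#' uniform periodic phase grid the trapezoid and midpoint rules coincide).
#' OSI is 0 for consistently unidirectional shear (no backflow) and 0.5
#' for oscillatory shear with equivalent forward and backward parts.
#'
#' @param series a `wall_shear_series`, or a 3-D array
#'   (points x 3 x phases) of shear vectors.
#' @param time_weights per-phase durations; defaults to the series weights
#'   (or equal weights for an array input).
#' @return Numeric vector of per-point OSI values in `[0, 0.5]`. Points
#'   with an all-zero shear history get OSI 0 and are listed in the
#'   `zero_history` attribute.
#' @export
osi <- function(series, time_weights = NULL) {
  tau <- if (inherits(series, "wall_shear_series")) series$tau else series
  stopifnot(length(dim(tau)) == 3, dim(tau)[2] == 3)
  if (dim(tau)[3] < 2) stop("OSI needs at least 2 simulated phases",
                            call. = FALSE)
  w <- time_weights %||%
    (if (inherits(series, "wall_shear_series")) series$time_weights else
      rep(1 / dim(tau)[3], dim(tau)[3]))
  stopifnot(length(w) == dim(tau)[3])
  wt <- array(rep(w, each = prod(dim(tau)[1:2])), dim = dim(tau))
  mean_vec <- apply(tau * wt, c(1, 2), sum)
  num <- sqrt(rowSums(mean_vec^2))
  mag <- sqrt(apply(tau^2, c(1, 3), sum))
  den <- as.numeric(mag %*% w)
  out <- ifelse(den > 1e-300, 0.5 * (1 - num / den), 0)
  out <- pmin(pmax(out, 0), 0.5)
  attr(out, "zero_history") <- which(den <= 1e-300)
  out
}

#' Volumetric flow rate through a cross-section
#'
#' Surface integral of `v . n` over one structured cross-section of the
#' mesh, positive in the inlet-to-outlet direction.
#'
#' @param field a `flow_field`.
#' @param section section index (default: the monitor section). Must lie
#'   in the analysis region (not the extensions) unless
#'   `allow_extension = TRUE`.
#' @param mesh the mesh (default `field$mesh`).
#' @param allow_extension permit sections inside the extensions.
#' @return Flow rate in mm^3/s.
#' @export
flow_rate <- function(field, section = NULL, mesh = field$mesh,
                      allow_extension = FALSE) {
  if (is.null(section)) section <- mesh$monitor_section
  stopifnot(section >= 1, section <= mesh$n_sections)
  if (!allow_extension && mesh$sections$extension[section]) {
    stop("section lies in the inlet/outlet extensions", call. = FALSE)
  }
  faces <- mesh$template$quads + (section - 1) * mesh$n2d
  qf <- quad_face_integrals(mesh$nodes, faces)
  q <- 0
  for (a in 1:4) {
    v <- field$velocity[faces[, a], , drop = FALSE]
    q <- q + sum(v * qf$integrals[, a, ])
  }
  q
}

#' Forward/backward flow volumes, stroke volume and cardiac efficiency
#'
#' Integrates a flow-rate waveform into the forward flow volume
#' `V_F = int max(Q, 0) dt`, the backward (regurgitant) volume
#' `V_B = int max(-Q, 0) dt`, the stroke volume `SV = V_F - V_B` and the
#' cardiac efficiency `eta = 1 - V_B / V_F`, using trapezoidal integration
#' of the clipped waveform when `times` are given, or weighted sums with
#' per-sample durations `weights`.
#'
#' @param Q flow-rate waveform (mm^3/s).
#' @param times sample times in s (trapezoid integration).
#' @param weights per-sample durations in s (rectangle integration);
#'   exactly one of `times`/`weights` must be given.
#' @return A list: `V_F`, `V_B`, `SV`, `eta` (NA with `eta_defined = FALSE`
#'   when `V_F = 0`).
#' @export
cycle_volumes <- function(Q, times = NULL, weights = NULL) {
  if (is.null(times) == is.null(weights)) {
    stop("give exactly one of `times` or `weights`", call. = FALSE)
  }
  if (!is.null(times)) {
    stopifnot(length(times) == length(Q))
    trap <- function(y) sum(diff(times) * (utils::head(y, -1) +
                                             utils::tail(y, -1)) / 2)
    vf <- trap(pmax(Q, 0))
    vb <- trap(pmax(-Q, 0))
  } else {
    stopifnot(length(weights) == length(Q))
    vf <- sum(weights * pmax(Q, 0))
    vb <- sum(weights * pmax(-Q, 0))
  }
  eta_defined <- vf > 0
  list(V_F = vf, V_B = vb, SV = vf - vb,
       eta = if (eta_defined) 1 - vb / vf else NA_real_,
       eta_defined = eta_defined)
}

#' Unroll a wall-surface quantity into a 2-D map
#'
#' Represents a per-wall-point quantity on the cut-open endocardial
#' surface: the tube is "cut" along the top (`theta = pi`) and unrolled so
#' the circumferential angle runs horizontally and the axial position runs
#' vertically with the inlet at the bottom and the outlet at the top.
#'
#' @param series a `wall_shear_series` (supplies the (theta, s) grid and
#'   area weights).
#' @param values per-point values; default: the cycle-mean (temporally
#'   averaged) `|tau|`.
#' @param n_theta_out,n_s_out optional output grid resolution (bilinear
#'   resampling on the periodic angle grid).
#' @return An object of class `unrolled_map`: `values`
#'   (n_s x n_theta, inlet = first row), `theta` (cut coordinates in
#'   `[-pi, pi)` measured from the cut), `s_norm`, `area_weights`.
#' @export
unroll_surface <- function(series, values = NULL,
                           n_theta_out = NULL, n_s_out = NULL) {
  nb <- series$grid_dim[1]; nc <- series$grid_dim[2]
  if (is.null(values)) {
    w <- series$time_weights
    values <- as.numeric(series$tau_mag %*% w) / sum(w)
  }
  stopifnot(length(values) == nb * nc)
  V <- matrix(values, nb, nc)    # rows: axial (inlet first), cols: theta
  A <- matrix(series$area_weights, nb, nc)
  # cut at theta = pi: reorder columns so the map runs from -pi to pi
  # relative to the cut
  rel <- ((series$theta - pi) %% (2 * pi)) - pi
  ord <- order(rel)
  V <- V[, ord, drop = FALSE]
  A <- A[, ord, drop = FALSE]
  th <- rel[ord]
  s <- series$s_norm
  if (!is.null(n_theta_out) || !is.null(n_s_out)) {
    nt <- n_theta_out %||% nc
    ns <- n_s_out %||% nb
    th_out <- seq(-pi, pi - 2 * pi / nt, length.out = nt)
    s_out <- seq(min(s), max(s), length.out = ns)
    # periodic bilinear resampling
    V2 <- matrix(0, ns, nt)
    Vext <- cbind(V, V[, 1])
    thext <- c(th, th[1] + 2 * pi)
    tmp <- matrix(0, nb, nt)
    for (r in seq_len(nb)) {
      tmp[r, ] <- stats::approx(thext, Vext[r, ], xout = th_out,
                                rule = 2)$y
    }
    for (cc in seq_len(nt)) {
      V2[, cc] <- stats::approx(s, tmp[, cc], xout = s_out, rule = 2)$y
    }
    # resample the area density the same way, then rescale so the total
    # wall area is preserved exactly
    A2 <- matrix(0, ns, nt)
    Aext <- cbind(A, A[, 1])
    tmpA <- matrix(0, nb, nt)
    for (r in seq_len(nb)) {
      tmpA[r, ] <- stats::approx(thext, Aext[r, ], xout = th_out,
                                 rule = 2)$y
    }
    for (cc in seq_len(nt)) {
      A2[, cc] <- stats::approx(s, tmpA[, cc], xout = s_out, rule = 2)$y
    }
    A2 <- A2 * sum(A) / sum(A2)
    V <- V2; A <- A2; th <- th_out; s <- s_out
  }
  structure(list(values = V, theta = th, s_norm = s, area_weights = A),
            class = "unrolled_map")
}

#' @export
print.unrolled_map <- function(x, ...) {
  cat(sprintf("<unrolled_map> %d axial x %d circumferential, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.unrolled_map <- function(x, ...) {
  tibble::tibble(
    theta = rep(x$theta, each = nrow(x$values)),
    s_norm = rep(x$s_norm, ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Plot an unrolled endocardium map
#' @param object an `unrolled_map`.
#' @param ... unused.
#' @return A ggplot (inlet at the bottom, outlet at the top).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.unrolled_map <- function(object, ...) {
  df <- tidy.unrolled_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$s_norm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "|tau| (Pa)") +
    ggplot2::labs(x = "circumferential angle from cut (rad)",
                  y = "normalized length (inlet at bottom)",
                  title = "unrolled endocardial surface") +
    ggplot2::theme_minimal()
}

#' Hemodynamic summary of a simulated cardiac cycle
#'
#' Computes the cycle-level hemodynamic metrics from a [simulate_cycle()]
#' run: the flow-rate waveform at the monitor section, forward/backward
#' flow volumes, stroke volume and cardiac efficiency; spatial/temporal
#' maxima and means of the wall shear stress (mean WSS is the pooled
#' area-and-time-weighted space-time average; a time-then-space variant is
#' also reported) and of the oscillatory shear index; and signed centerline
#' velocity extremes.
#'
#' @param sim a `cycle_simulation` (with kept fields).
#' @param wss optional precomputed [wall_shear_series()].
#' @return An object of class `hemo_summary` (also a plain list):
#'   `Q` (per-phase waveform tibble), `V_F`, `V_B`, `SV`, `eta`,
#'   `max_wss`, `mean_wss`, `mean_wss_time_then_space`, `max_osi`,
#'   `mean_osi`, `max_forward_velocity`, `max_backward_velocity`,
#'   `max_flow_rate`, `coverage`, `diagnostics`.
#' @export
summarize_hemodynamics <- function(sim, wss = NULL) {
  simulated <- which(sim$status$simulated)
  if (!length(simulated)) stop("no simulated phases", call. = FALSE)
  phases <- sim$status$phase[simulated]
  if (is.null(wss)) wss <- wall_shear_series(sim)

  dt <- if (!is.null(sim$period_s)) sim$period_s / sim$n_phases else
    1 / sim$n_phases
  qvals <- vapply(phases, function(p) {
    flow_rate(sim$fields[[p]], mesh = sim$meshes[[p]])
  }, numeric(1))
  vols <- cycle_volumes(qvals, weights = rep(dt, length(qvals)))

  # centerline (core-center) axial velocities over body sections
  vmax_f <- -Inf; vmax_b <- Inf
  for (p in phases) {
    mesh <- sim$meshes[[p]]
    body <- which(!mesh$sections$extension)
    ids <- (body - 1) * mesh$n2d + mesh$template$center_id
    vz <- sim$fields[[p]]$velocity[ids, 3]
    vmax_f <- max(vmax_f, vz)
    vmax_b <- min(vmax_b, vz)
  }

  aw <- wss$area_weights
  w <- wss$time_weights
  # pooled space-time mean: weights = patch area x phase duration
  W2 <- outer(aw, w)
  mean_wss <- sum(wss$tau_mag * W2) / sum(W2)
  # time average per point first, then area-weighted space average
  tavg <- as.numeric(wss$tau_mag %*% w) / sum(w)
  mean_wss_ts <- sum(tavg * aw) / sum(aw)
  mean_osi <- sum(wss$osi * aw) / sum(aw)

  structure(list(
    Q = tibble::tibble(phase = phases, Q_mm3_s = qvals),
    V_F = vols$V_F, V_B = vols$V_B, SV = vols$SV, eta = vols$eta,
    max_wss = max(wss$tau_mag), mean_wss = mean_wss,
    mean_wss_time_then_space = mean_wss_ts,
    max_osi = max(wss$osi), mean_osi = mean_osi,
    max_forward_velocity = vmax_f,
    max_backward_velocity = vmax_b,
    max_flow_rate = max(qvals),
    coverage = sim$coverage,
    diagnostics = sim$diagnostics,
    period_s = sim$period_s
  ), class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat("<hemo_summary>\n")
  cat(sprintf("  V_F %.4g  V_B %.4g  SV %.4g mm^3/beat, efficiency %.3f\n",
              x$V_F, x$V_B, x$SV, x$eta))
  cat(sprintf("  WSS max %.3g / mean %.3g Pa;  OSI max %.3f / mean %.3f\n",
              x$max_wss, x$mean_wss, x$max_osi, x$mean_osi))
  cat(sprintf("  velocities: +%.3g / %.3g mm/s;  max Q %.3g mm^3/s;  coverage %.2f\n",
              x$max_forward_velocity, x$max_backward_velocity,
              x$max_flow_rate, x$coverage))
  invisible(x)
}

#' Tidy one-row-per-metric view of a hemodynamic summary
#' @param x a `hemo_summary`.
#' @param ... unused.
#' @return A tibble with `metric`, `value`, `units`.
#' @exportS3Method generics::tidy
#' @export
tidy.hemo_summary <- function(x, ...) {
  tibble::tibble(
    metric = c("max_wss", "mean_wss", "mean_osi", "max_osi",
               "max_backflow_velocity", "max_forward_velocity",
               "backflow_volume", "forward_volume", "stroke_volume",
               "cardiac_efficiency", "max_flow_rate", "coverage"),
    value = c(x$max_wss, x$mean_wss, x$mean_osi, x$max_osi,
              abs(x$max_backward_velocity), x$max_forward_velocity,
              x$V_B, x$V_F, x$SV, x$eta, x$max_flow_rate, x$coverage),
    units = c("Pa", "Pa", "", "", "mm/s", "mm/s", "mm^3/beat", "mm^3/beat",
              "mm^3/beat", "", "mm^3/s", "")
  )
}

#' One-row summary of a hemodynamic run
#' @param x a `hemo_summary`.
#' @param ... unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
#' @export
glance.hemo_summary <- function(x, ...) {
  tibble::tibble(
    V_F = x$V_F, V_B = x$V_B, SV = x$SV, eta = x$eta,
    max_wss = x$max_wss, mean_wss = x$mean_wss,
    max_osi = x$max_osi, mean_osi = x$mean_osi,
    max_flow_rate = x$max_flow_rate, coverage = x$coverage
  )
}
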