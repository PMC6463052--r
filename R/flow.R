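#' Fluid properties of embryonic blood
#'
#' Embryonic blood at looping stages has a low hematocrit (about 15%) and is
#' modeled as a Newtonian fluid.
#'
#' @param density mass density in kg/m^3 (default 1060).
#' @param viscosity dynamic viscosity in Pa s (default 0.003).
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1060, viscosity = 0.003) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' @export
print.fluid_props <- function(x, ...) {
  cat(sprintf("<fluid_props> density %g kg/m^3, viscosity %g Pa s\n",
              x$density, x$viscosity))
  invisible(x)
}

# Build the (factorized) discrete Stokes operator for one mesh.
#
# Mixed Q1-Q1 velocity/pressure discretization with Brezzi-Pitkaranta
# pressure stabilization. Internal units: mm, mm/s, Pa (consistent because
# mu [Pa s] * laplacian(v) [mm/s / mm^2] matches grad p [Pa/mm]).
#
# Weak form (gradient/pseudo-traction form, so the natural boundary
# condition on inlet/outlet faces is mu dv/dn - p n = h):
#   mu (grad v, grad w) - (p, div w) = <h, w>_Gamma_in
#   (q, div v) + sum_e alpha h_e^2/mu (grad p, grad q)_e = 0
# No-slip velocity is eliminated on wall nodes; the outlet has h = 0.
stokes_operator <- function(mesh, props, stab_alpha = 0.1) {
  nn <- nrow(mesh$nodes)
  mu <- props$viscosity
  blocks <- assemble_stokes_blocks(mesh$nodes, mesh$elems)
  S <- assemble_pressure_stab(mesh$nodes, mesh$elems, blocks$elem_volume,
                              mu, stab_alpha)
  free <- setdiff(seq_len(nn), mesh$wall_nodes)
  nf <- length(free)
  vdof_of_node <- integer(nn)
  vdof_of_node[free] <- seq_len(nf)

  Kff <- blocks$K[free, free, drop = FALSE]
  A11 <- mu * Matrix::kronecker(Kff, Matrix::Diagonal(3))
  A11 <- as(Matrix::forceSymmetric(A11), "CsparseMatrix")

  # G[p-row j, v-col (i,k)] = int N_j dN_i/dx_k over free velocity nodes
  trip <- lapply(1:3, function(k) {
    Bk <- methods::as(blocks$B[[k]][, free, drop = FALSE], "TsparseMatrix")
    list(i = Bk@i + 1L, j = (Bk@j) * 3L + k, x = Bk@x)
  })
  G <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i")),
    j = unlist(lapply(trip, `[[`, "j")),
    x = unlist(lapply(trip, `[[`, "x")),
    dims = c(nn, 3 * nf)
  )

  # unit inlet traction load: h = -1 * n_outward on the inlet face
  qi <- quad_face_integrals(mesh$nodes, mesh$inlet_faces)
  f_unit <- numeric(3 * nf)
  for (a in 1:4) {
    nodes_a <- mesh$inlet_faces[, a]
    keep <- vdof_of_node[nodes_a] > 0
    for (k in 1:3) {
      idx <- (vdof_of_node[nodes_a[keep]] - 1) * 3 + k
      contrib <- -qi$integrals[keep, a, k]
      f_unit[idx] <- f_unit[idx] + contrib
    }
  }

  # the applied traction equals a uniform pressure at the end faces (the
  # flow is developed there thanks to the extensions), so the pressure is
  # additionally imposed strongly on inlet/outlet pressure nodes; this
  # removes the stabilization's spurious boundary flux (the wall has
  # dp/dn = 0 for developed flow) and restores second-order accuracy
  p_fixed_in <- mesh$inlet_nodes
  p_fixed_out <- mesh$outlet_nodes
  p_free <- setdiff(seq_len(nn), c(p_fixed_in, p_fixed_out))

  # unit (T = 1) Dirichlet contributions: p = 1 on inlet, 0 on outlet
  gT_in <- as.numeric(Matrix::t(G[p_fixed_in, , drop = FALSE]) %*%
                        rep(1, length(p_fixed_in)))
  sP_in <- as.numeric(S[p_free, p_fixed_in, drop = FALSE] %*%
                        rep(1, length(p_fixed_in)))

  G0 <- G[p_free, , drop = FALSE]
  S00 <- S[p_free, p_free, drop = FALSE]

  # Jacobi preconditioner for the pressure Schur complement:
  # S_c = G A^-1 G^T + S behaves like (1/mu) * pressure mass + S
  prec <- blocks$mass_lumped[p_free] / mu + Matrix::diag(S00)

  list(A11 = A11, G = G, S = S, G0 = G0, S00 = S00,
       p_free = p_free, p_fixed_in = p_fixed_in, p_fixed_out = p_fixed_out,
       gT_in = gT_in, sP_in = sP_in,
       chA = NULL, f_unit = f_unit, free = free,
       vdof_of_node = vdof_of_node, n_nodes = nn, nf = nf,
       blocks = blocks, mu = mu, stab_alpha = stab_alpha,
       schur_prec = prec, mesh = mesh, props = props)
}

op_factorize <- function(op) {
  if (is.null(op$chA)) {
    op$chA <- Matrix::Cholesky(op$A11, LDL = FALSE, super = TRUE,
                               perm = TRUE)
  }
  op
}

# Solve the stabilized Stokes saddle system via the pressure Schur
# complement. With p0 the free pressures (end-face pressures imposed
# strongly at T and 0):
#   A u - G0^T p0 = f + gT_in * T
#   G0 u + S00 p0 = -sP_in * T
# gives the SPD system (G0 A^-1 G0^T + S00) p0 = rhs, solved by
# Jacobi-preconditioned CG.
op_solve <- function(op, traction, cg_tol = 1e-10, cg_max = 500) {
  u <- matrix(0, op$n_nodes, 3)
  if (traction == 0) {
    return(list(velocity = u, pressure = numeric(op$n_nodes),
                residual = 0, cg_iters = 0L))
  }
  f <- (op$f_unit + op$gT_in) * traction
  Ainv <- function(b) as.numeric(Matrix::solve(op$chA, b))
  apply_schur <- function(p) {
    as.numeric(op$G0 %*% Ainv(as.numeric(Matrix::t(op$G0) %*% p))) +
      as.numeric(op$S00 %*% p)
  }
  rhs_p <- -as.numeric(op$G0 %*% Ainv(f)) - op$sP_in * traction
  p0 <- numeric(length(op$p_free))
  r <- rhs_p
  z <- r / op$schur_prec
  d <- z
  rz <- sum(r * z)
  rhs_norm <- sqrt(sum(rhs_p^2))
  iters <- 0L
  if (rhs_norm > 0) {
    for (it in seq_len(cg_max)) {
      iters <- it
      q <- apply_schur(d)
      alpha <- rz / sum(d * q)
      p0 <- p0 + alpha * d
      r <- r - alpha * q
      if (sqrt(sum(r^2)) < cg_tol * rhs_norm) break
      z <- r / op$schur_prec
      rz_new <- sum(r * z)
      d <- z + (rz_new / rz) * d
      rz <- rz_new
    }
  }
  uf <- Ainv(f + as.numeric(Matrix::t(op$G0) %*% p0))
  u[op$free, ] <- matrix(uf, ncol = 3, byrow = TRUE)
  p <- numeric(op$n_nodes)
  p[op$p_free] <- p0
  p[op$p_fixed_in] <- traction
  mom_res <- sqrt(sum((as.numeric(op$A11 %*% uf) -
                         as.numeric(Matrix::t(op$G0) %*% p0) - f)^2)) /
    max(sqrt(sum(f^2)), 1e-300)
  cont_res <- sqrt(sum((as.numeric(op$G0 %*% uf) +
                          as.numeric(op$S00 %*% p0) +
                          op$sP_in * traction)^2))
  list(velocity = u, pressure = p,
       residual = max(mom_res, cont_res / max(rhs_norm, 1e-300)),
       cg_iters = iters)
}

new_flow_field <- function(sol, mesh, props, traction, include_inertia,
                           picard_iters = 0) {
  structure(list(
    velocity = sol$velocity, pressure = sol$pressure,
    mesh = mesh, props = props,
    inlet_traction = traction,
    include_inertia = include_inertia,
    residuals = list(linear = sol$residual, picard_iters = picard_iters)
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d nodes, inlet traction %.4g Pa, max |v| %.3g mm/s\n",
              nrow(x$velocity), x$inlet_traction,
              sqrt(max(rowSums(x$velocity^2)))))
  invisible(x)
}

#' Solve quasi-steady incompressible viscous flow on a tube mesh
#'
#' Solves steady incompressible momentum + continuity with a mixed Q1-Q1
#' velocity/pressure discretization (Brezzi-Pitkaranta stabilized) on the
#' hexahedral mesh: no-slip walls, a uniform normal traction of magnitude
#' `inlet_traction` on the inlet (natural boundary condition; positive
#' values drive inlet-to-outlet flow) and zero normal traction on the
#' outlet. At the Reynolds numbers of the embryonic outflow tract (Re < 5)
#' flow inertia is negligible and the default is the Stokes limit; with
#' `include_inertia = TRUE` the convective term is handled by Picard
#' iteration.
#'
#' @param mesh a [build_mesh()] result.
#' @param props a [fluid_props()].
#' @param inlet_traction inlet normal traction in Pa.
#' @param include_inertia include the convective term (Picard iteration).
#' @param stab_alpha pressure stabilization coefficient.
#' @param picard_tol,picard_max Picard convergence controls.
#' @return An object of class `flow_field`: per-node `velocity` (mm/s, zero
#'   on wall nodes), `pressure` (Pa), the mesh, the applied traction and
#'   solver residuals.
#' @export
solve_steady <- function(mesh, props, inlet_traction,
                         include_inertia = FALSE, stab_alpha = 0.1,
                         picard_tol = 1e-8, picard_max = 25) {
  stopifnot(is.finite(inlet_traction))
  op <- stokes_operator(mesh, props, stab_alpha)
  op <- op_factorize(op)
  sol <- op_solve(op, inlet_traction)
  iters <- 0
  if (include_inertia && inlet_traction != 0) {
    rho_scaled <- props$density * 1e-6  # kg/m^3 -> consistent mm/Pa units
    u_prev <- sol$velocity
    repeat {
      iters <- iters + 1
      C <- assemble_convection(mesh$nodes, mesh$elems, u_prev, rho_scaled)
      Cff <- C[op$free, op$free, drop = FALSE]
      A11c <- op$A11 + Matrix::kronecker(Cff, Matrix::Diagonal(3))
      Mi <- rbind(cbind(A11c, -Matrix::t(op$G0)),
                  cbind(op$G0, op$S00))
      rhs <- c((op$f_unit + op$gT_in) * inlet_traction,
               -op$sP_in * inlet_traction)
      x <- as.numeric(Matrix::solve(Mi, rhs))
      u <- matrix(0, op$n_nodes, 3)
      u[op$free, ] <- matrix(x[seq_len(3 * op$nf)], ncol = 3, byrow = TRUE)
      dv <- sqrt(sum((u - u_prev)^2)) / max(sqrt(sum(u^2)), 1e-300)
      u_prev <- u
      if (dv < picard_tol || iters >= picard_max) {
        if (dv >= picard_tol) {
          warning("Picard iteration did not converge", call. = FALSE)
        }
        p_full <- numeric(op$n_nodes)
        p_full[op$p_free] <- x[3 * op$nf + seq_along(op$p_free)]
        p_full[op$p_fixed_in] <- inlet_traction
        sol <- list(velocity = u, pressure = p_full, residual = dv)
        break
      }
    }
  }
  new_flow_field(sol, mesh, props, inlet_traction, include_inertia, iters)
}

# signed axial (z) velocity at the monitor node
monitor_velocity <- function(field, monitor_node) {
  field$velocity[monitor_node, 3]
}

#' Fit the inlet traction to a measured monitor velocity
#'
#' Inverse boundary-condition loop: the uniform inlet normal traction is
#' updated by secant iteration until the computed axial velocity at the
#' monitor point matches the measured (target) velocity to within
#' `tolerance` (default 1%). The secant starts from the known zero point
#' (zero traction gives zero velocity), so in the Stokes limit, where the
#' monitor velocity is exactly linear in the traction, convergence takes at
#' most two solves from any nonzero warm start. A zero target returns zero
#' traction without solving.
#'
#' @param mesh a `tube_mesh`.
#' @param props a [fluid_props()].
#' @param target_velocity measured axial velocity at the monitor point
#'   (mm/s; negative = backflow).
#' @param tolerance relative velocity-matching tolerance (default 0.01).
#' @param warm_start starting traction in Pa (e.g. the previous phase's
#'   fitted value); default 1 Pa.
#' @param monitor_node node index of the monitor point; default: the lumen
#'   center of the mid-body section (`mesh$monitor_node`).
#' @param max_iter iteration cap.
#' @param include_inertia,stab_alpha passed to the solver.
#' @return A list with `field` (the final `flow_field`) and `fit` (class
#'   `inverse_fit_result`: tibble `traction_history`/`velocity_history`,
#'   `converged`, `final_relative_error`, `n_solves`).
#' @export
fit_inlet_traction <- function(mesh, props, target_velocity,
                               tolerance = 0.01, warm_start = 1,
                               monitor_node = NULL, max_iter = 20,
                               include_inertia = FALSE, stab_alpha = 0.1) {
  if (is.null(monitor_node)) monitor_node <- mesh$monitor_node
  stopifnot(is.finite(target_velocity))
  mk_fit <- function(tr, vel, converged, err, n) {
    structure(list(
      traction_history = tr, velocity_history = vel,
      converged = converged, final_relative_error = err, n_solves = n
    ), class = "inverse_fit_result")
  }
  if (abs(target_velocity) < 1e-12) {
    op <- op_factorize(stokes_operator(mesh, props, stab_alpha))
    sol <- op_solve(op, 0)
    field <- new_flow_field(sol, mesh, props, 0, include_inertia)
    return(list(field = field, fit = mk_fit(0, 0, TRUE, 0, 0L)))
  }

  solve_at <- if (include_inertia) {
    function(tr) solve_steady(mesh, props, tr, include_inertia = TRUE,
                              stab_alpha = stab_alpha)
  } else {
    op <- op_factorize(stokes_operator(mesh, props, stab_alpha))
    function(tr) new_flow_field(op_solve(op, tr), mesh, props, tr, FALSE)
  }

  t_prev <- 0; v_prev <- 0
  t_cur <- if (!is.null(warm_start) && warm_start != 0) warm_start else 1
  tr_hist <- numeric(0); v_hist <- numeric(0)
  field <- NULL
  converged <- FALSE; err <- Inf
  for (it in seq_len(max_iter)) {
    field <- solve_at(t_cur)
    v_cur <- monitor_velocity(field, monitor_node)
    tr_hist <- c(tr_hist, t_cur); v_hist <- c(v_hist, v_cur)
    err <- abs(v_cur - target_velocity) / abs(target_velocity)
    if (err < tolerance) {
      converged <- TRUE
      break
    }
    dv <- v_cur - v_prev
    if (abs(dv) < 1e-300) break
    t_new <- t_cur + (target_velocity - v_cur) * (t_cur - t_prev) / dv
    t_prev <- t_cur; v_prev <- v_cur
    t_cur <- t_new
  }
  if (!converged) {
    warning(sprintf(
      "inverse traction fit did not converge (relative error %.3g)", err),
      call. = FALSE)
  }
  list(field = field,
       fit = mk_fit(tr_hist, v_hist, converged, err, length(tr_hist)))
}

#' @export
print.inverse_fit_result <- function(x, ...) {
  cat(sprintf("<inverse_fit_result> %d solve(s), %s, relative error %.3g\n",
              x$n_solves, if (x$converged) "converged" else "NOT converged",
              x$final_relative_error))
  invisible(x)
}

#' Extract per-phase target velocities from synchronized Doppler data
#'
#' Reads the beam-axis (vertical) velocity at the monitor location - the
#' lumen center of the mid-tube slice - for every phase of a synchronized
#' dataset, and optionally corrects it by the known beam angle so the
#' target is the axial velocity.
#'
#' @param synced a [sync_dataset()] result.
#' @param beam_tilt_deg angle between the tube axis and the beam axis.
#' @param slice slice index of the monitor location (default: middle).
#' @param angle_correct divide by `cos(beam_tilt_deg)` (default TRUE).
#' @return A tibble: `phase`, `doppler_mm_s`, `target_mm_s`.
#' @export
doppler_targets <- function(synced, beam_tilt_deg = 45, slice = NULL,
                            angle_correct = TRUE) {
  n_sl <- dim(synced$doppler)[4]
  if (is.null(slice)) slice <- ceiling(n_sl / 2)
  ctr <- synced$center_px
  v <- synced$doppler[, ctr, ctr, slice]
  corr <- if (angle_correct) cos(beam_tilt_deg * pi / 180) else 1
  tibble::tibble(
    phase = seq_along(v),
    doppler_mm_s = v,
    target_mm_s = v / corr
  )
}

#' Simulate the full cardiac cycle quasi-steadily
#'
#' Iterates the phases of a segmented cycle in order: phases with any fully
#' coapted slice (or an unmeshable loft) are skipped; for each remaining
#' phase a mesh is built, the inverse inlet-traction loop is run against
#' that phase's measured monitor velocity, and the fitted flow field is
#' stored. Each phase warm-starts from the previous phase's fitted
#' traction. The fraction of the cycle simulated is reported and a warning
#' is issued if it falls below 0.6.
#'
#' @param series a `cross_section_series` (lumen).
#' @param targets numeric vector of measured axial monitor velocities
#'   (mm/s), one per phase (e.g. `doppler_targets()$target_mm_s`).
#' @param props a [fluid_props()].
#' @param phases phases to attempt (default: all).
#' @param mesh_args list of arguments forwarded to [build_mesh()].
#' @param tolerance inverse-fit relative tolerance.
#' @param include_inertia,stab_alpha solver options.
#' @param period_s optional cardiac period in seconds (enables Reynolds /
#'   Womersley diagnostics and time-weighted post-processing).
#' @param keep_fields keep every phase's full flow field (default TRUE).
#' @return An object of class `cycle_simulation`: `status` tibble (phase,
#'   simulated flag, reason, traction, monitor velocity, relative error,
#'   solves), `fields` and `meshes` (lists indexed by phase), `coverage`,
#'   `diagnostics` (max Reynolds and Womersley numbers when `period_s`
#'   given), `props`, `period_s`.
#' @export
simulate_cycle <- function(series, targets, props = fluid_props(),
                           phases = NULL, mesh_args = list(),
                           tolerance = 0.01, include_inertia = FALSE,
                           stab_alpha = 0.1, period_s = NULL,
                           keep_fields = TRUE) {
  n_ph <- series$n_phases
  if (is.null(phases)) phases <- seq_len(n_ph)
  stopifnot(length(targets) >= max(phases))
  fields <- vector("list", n_ph)
  meshes <- vector("list", n_ph)
  status <- tibble::tibble(
    phase = phases, simulated = FALSE, reason = NA_character_,
    traction = NA_real_, monitor_velocity = NA_real_,
    relative_error = NA_real_, solves = NA_integer_
  )
  warm <- 1
  for (i in seq_along(phases)) {
    p <- phases[i]
    if (any(series$closed[, p])) {
      status$reason[i] <- "closed"
      next
    }
    mesh <- tryCatch(
      do.call(build_mesh, c(list(series = series, phase = p), mesh_args)),
      error = function(e) e
    )
    if (inherits(mesh, "error")) {
      status$reason[i] <- paste("mesh:", conditionMessage(mesh))
      next
    }
    res <- tryCatch(
      fit_inlet_traction(mesh, props, targets[p], tolerance = tolerance,
                         warm_start = warm, include_inertia = include_inertia,
                         stab_alpha = stab_alpha),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      status$reason[i] <- paste("solve:", conditionMessage(res))
      next
    }
    status$simulated[i] <- TRUE
    status$traction[i] <- res$field$inlet_traction
    status$monitor_velocity[i] <- monitor_velocity(res$field,
                                                   mesh$monitor_node)
    status$relative_error[i] <- res$fit$final_relative_error
    status$solves[i] <- res$fit$n_solves
    if (res$field$inlet_traction != 0) warm <- res$field$inlet_traction
    if (keep_fields) {
      fields[[p]] <- res$field
      meshes[[p]] <- mesh
    }
  }
  coverage <- mean(status$simulated)
  if (coverage < 0.6) {
    warning(sprintf("only %.0f%% of the cardiac cycle could be simulated",
                    100 * coverage), call. = FALSE)
  }

  diagnostics <- NULL
  sim <- which(status$simulated)
  if (length(sim) && !is.null(period_s)) {
    # Reynolds with mean section velocity and local diameter, SI conversion
    remax <- 0; dmax <- 0
    for (i in sim) {
      p <- phases[i]
      msh <- meshes[[p]]
      if (is.null(msh)) next
      a_mid <- msh$sections$area[msh$monitor_section]
      d_loc <- 2 * sqrt(a_mid / pi)
      u_mean <- abs(status$monitor_velocity[i]) / 2
      remax <- max(remax, props$density * u_mean * d_loc * 1e-6 /
                     props$viscosity)
      dmax <- max(dmax, d_loc)
    }
    womersley <- (dmax / 2 * 1e-3) *
      sqrt(2 * pi * props$density / (period_s * props$viscosity))
    diagnostics <- list(max_reynolds = remax, womersley = womersley)
  }

  structure(list(
    status = status, fields = fields, meshes = meshes,
    coverage = coverage, diagnostics = diagnostics,
    props = props, period_s = period_s, targets = targets,
    n_phases = n_ph
  ), class = "cycle_simulation")
}

#' @export
print.cycle_simulation <- function(x, ...) {
  cat(sprintf("<cycle_simulation> %d/%d phases simulated (coverage %.2f)\n",
              sum(x$status$simulated), nrow(x$status), x$coverage))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  max Re %.2f, Womersley %.2f\n",
                x$diagnostics$max_reynolds, x$diagnostics$womersley))
  }
  invisible(x)
}

#' Tidy per-phase summary of a cycle simulation
#' @param x a `cycle_simulation`.
#' @param ... unused.
#' @return The per-phase status tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.cycle_simulation <- function(x, ...) x$status
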