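# polygon helpers ------------------------------------------------------------

# shoelace signed area (positive for counterclockwise vertex order)
polygon_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_area <- function(v) abs(polygon_area_signed(v))

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(x = mean(x), y = mean(y)))
  c(x = sum((x + xs) * cr) / (6 * a), y = sum((y + ys) * cr) / (6 * a))
}

# O(n^2) simple-polygon test (edge pairs may share endpoints)
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  ccw <- function(ax, ay, bx, by, cx, cy) {
    (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]
      c <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- ccw(a[1], a[2], b[1], b[2], c[1], c[2])
      d2 <- ccw(a[1], a[2], b[1], b[2], d[1], d[2])
      d3 <- ccw(c[1], c[2], d[1], d[2], a[1], a[2])
      d4 <- ccw(c[1], c[2], d[1], d[2], b[1], b[2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Area of a segmented cross-section contour
#'
#' Shoelace area of the closed polygon; fully coapted (closed-lumen)
#' contours have zero area by definition.
#'
#' @param c an `oft_contour` (or a plain n x 2 vertex matrix in mm).
#' @param check verify that the polygon is simple (non-self-intersecting).
#' @return Area in mm^2.
#' @export
contour_area <- function(c, check = TRUE) {
  v <- if (inherits(c, "oft_contour")) {
    if (c$is_closed_lumen || is.null(c$vertices)) return(0)
    c$vertices
  } else c
  stopifnot(is.matrix(v), ncol(v) == 2, nrow(v) >= 3)
  if (check && !polygon_is_simple(v)) {
    stop("self-intersecting polygon", call. = FALSE)
  }
  polygon_area(v)
}

# cross-section series --------------------------------------------------------

#' Grid of segmented cross-sections over slices and phases
#'
#' Container for the per-slice, per-phase lumen (or wall) contours produced
#' by [segment_series()], with derived area and centroid grids. Closed
#' slices carry zero area.
#'
#' @param contours list (by slice) of lists (by phase) of `oft_contour`s.
#' @param slice_spacing distance between slices in mm.
#' @param n_phases number of phases (defaults to the grid width).
#' @return An object of class `cross_section_series` with elements
#'   `contours`, `areas` (n_slices x n_phases, mm^2), `centroids`
#'   (n_slices x n_phases x 2, mm), `closed` (logical matrix),
#'   `slice_spacing`, `n_slices`, `n_phases`.
#' @export
cross_section_series <- function(contours, slice_spacing,
                                 n_phases = length(contours[[1]])) {
  stopifnot(length(contours) >= 1, slice_spacing > 0)
  n_sl <- length(contours)
  areas <- matrix(0, n_sl, n_phases)
  closed <- matrix(FALSE, n_sl, n_phases)
  centroids <- array(NA_real_, dim = c(n_sl, n_phases, 2))
  for (k in seq_len(n_sl)) {
    for (p in seq_len(n_phases)) {
      ct <- contours[[k]][[p]]
      areas[k, p] <- ct$area
      closed[k, p] <- ct$is_closed_lumen || !ct$ok
      centroids[k, p, ] <- ct$centroid
    }
  }
  structure(list(contours = contours, areas = areas, centroids = centroids,
                 closed = closed, slice_spacing = slice_spacing,
                 n_slices = n_sl, n_phases = n_phases),
            class = "cross_section_series")
}

#' @export
print.cross_section_series <- function(x, ...) {
  cat(sprintf("<cross_section_series> %d slices x %d phases (%.0f%% closed)\n",
              x$n_slices, x$n_phases, 100 * mean(x$closed)))
  invisible(x)
}

#' Tidy view of a cross-section series
#' @param x a `cross_section_series`.
#' @param ... unused.
#' @return A tibble: `slice`, `phase`, `area`, `centroid_x`, `centroid_y`,
#'   `closed`.
#' @exportS3Method generics::tidy
#' @export
tidy.cross_section_series <- function(x, ...) {
  tibble::tibble(
    slice = rep(seq_len(x$n_slices), x$n_phases),
    phase = rep(seq_len(x$n_phases), each = x$n_slices),
    area = as.vector(x$areas),
    centroid_x = as.vector(x$centroids[, , 1]),
    centroid_y = as.vector(x$centroids[, , 2]),
    closed = as.vector(x$closed)
  )
}

#' Build a contour series directly from an analytic radius field
#'
#' Constructs a [cross_section_series()] of circular contours from a radius
#' function, bypassing imaging and segmentation. Used for geometry oracles
#' and for fast meshing experiments.
#'
#' @param radius_fn function `(s, phase)` giving lumen radius in mm;
#'   `s` normalized axial position, `phase` in `[0,1)`.
#' @param n_slices,slice_spacing slice count and spacing (mm).
#' @param n_phases number of phases (phase grid `(p - 0.5)/n_phases`).
#' @param n_vertices contour vertex count.
#' @param closure_radius_mm radii below this are flagged fully coapted.
#' @param centroid_fn optional function `(s)` giving the 2-D centroid (mm);
#'   default places all centroids at the origin.
#' @return A `cross_section_series`.
#' @export
contour_series_from_radius <- function(radius_fn, n_slices, slice_spacing,
                                       n_phases = 100, n_vertices = 64,
                                       closure_radius_mm = 0.045,
                                       centroid_fn = NULL) {
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  contours <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    s <- (k - 1) / max(n_slices - 1, 1)
    ctr2 <- if (is.null(centroid_fn)) c(0, 0) else centroid_fn(s)
    contours[[k]] <- lapply(seq_len(n_phases), function(p) {
      phi <- (p - 0.5) / n_phases
      r <- radius_fn(s, phi)
      if (any(!is.finite(r)) || stats::median(r) < closure_radius_mm) {
        return(structure(list(
          vertices = NULL, area = 0, centroid = c(x = ctr2[1], y = ctr2[2]),
          radii_px = NULL, theta = NULL, seed = NULL, pixel_size_mm = NA,
          is_closed_lumen = TRUE, ok = TRUE, layer = "lumen",
          slice_index = k, phase_index = p), class = "oft_contour"))
      }
      r <- rep_len(r, n_vertices)
      v <- cbind(x = ctr2[1] + r * cos(theta), y = ctr2[2] + r * sin(theta))
      structure(list(
        vertices = v, area = polygon_area(v), centroid = polygon_centroid(v),
        radii_px = NULL, theta = theta, seed = NULL, pixel_size_mm = NA,
        is_closed_lumen = FALSE, ok = TRUE, layer = "lumen",
        slice_index = k, phase_index = p), class = "oft_contour")
    })
  }
  cross_section_series(contours, slice_spacing, n_phases)
}

#' Contour series of a phantom from its analytic ground truth
#'
#' @param config a [phantom_config()].
#' @param n_phases number of phases.
#' @param ... passed to [contour_series_from_radius()].
#' @return A `cross_section_series` of the phantom's true lumen.
#' @export
phantom_contours <- function(config, n_phases = 100, ...) {
  contour_series_from_radius(
    function(s, phase) phantom_radius(config, s, phase),
    n_slices = config$n_slices,
    slice_spacing = config$slice_spacing_um / 1000,
    n_phases = n_phases, ...
  )
}

# volumes and centerline -------------------------------------------------------

# 3-D centroids (x, y, z) of every slice at one phase
slice_centerpoints <- function(series, phase) {
  z <- (seq_len(series$n_slices) - 1) * series$slice_spacing
  cbind(series$centroids[, phase, 1], series$centroids[, phase, 2], z)
}

#' Lumen volume by stacked cross-section slabs
#'
#' Estimates the lumen volume at one phase as the sum of each segmented
#' cross-section area times the distance between its centerpoint and its
#' neighbors' (half-gaps at the two ends). Works for closed geometries that
#' cannot be meshed, since closed slices simply contribute zero area.
#'
#' @param series a `cross_section_series`.
#' @param phase phase index (column of the grid).
#' @return Volume in mm^3.
#' @export
slab_volume <- function(series, phase) {
  stopifnot(series$n_slices >= 2)
  p <- slice_centerpoints(series, phase)
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  n <- series$n_slices
  gap <- numeric(n)
  gap[1] <- d[1] / 2
  gap[n] <- d[n - 1] / 2
  if (n > 2) gap[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  sum(series$areas[, phase] * gap)
}

#' Total lumen volume waveform over the cycle
#' @param series a `cross_section_series`.
#' @return Numeric vector of volumes (mm^3), one per phase.
#' @export
volume_waveform <- function(series) {
  vapply(seq_len(series$n_phases), function(p) slab_volume(series, p),
         numeric(1))
}

#' Centerline length at a closed (minimum-volume) configuration
#'
#' Polyline length through the slice centerpoints. By convention the length
#' is measured at the phase of minimum total lumen volume (the most closed
#' configuration); pass `phase` to override.
#'
#' @param series a `cross_section_series`.
#' @param phase optional phase index; default = phase of minimum volume.
#' @return Length in mm (with attribute `phase`).
#' @export
centerline_length <- function(series, phase = NULL) {
  if (is.null(phase)) phase <- which.min(volume_waveform(series))
  p <- slice_centerpoints(series, phase)
  len <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2)))
  structure(len, phase = phase)
}

# area-motion ------------------------------------------------------------------

#' Area-motion matrix: cross-sectional area over space and time
#'
#' Assembles the grid of cross-sectional areas with normalized cycle time on
#' the horizontal axis and normalized tube length (inlet at the bottom) on
#' the vertical axis, together with the fitted inlet-to-outlet phase-lag
#' slope of the contraction wave (cycles per normalized length; per-slice
#' lags measured by circular cross-correlation against the inlet slice and
#' unwrapped).
#'
#' @param series a `cross_section_series` (lumen or wall layer).
#' @param layer label stored on the result (`"lumen"` or `"wall"`).
#' @return An object of class `area_motion_matrix`: list with `values`
#'   (n_slices x n_phases, mm^2), `slice_s`, `phase`, `layer`,
#'   `phase_lag_slope` (cycles per unit normalized length; `1/wave_speed`
#'   for a traveling-wave tube) and `slice_lag` (per-slice lag, cycles).
#' @export
area_motion <- function(series, layer = "lumen") {
  A <- series$areas
  n_sl <- nrow(A); n_ph <- ncol(A)
  lag <- rep(NA_real_, n_sl)
  lag[1] <- 0
  a0 <- A[1, ]
  if (stats::sd(a0) > 1e-12) {
    for (k in 2:n_sl) {
      if (stats::sd(A[k, ]) < 1e-12) next
      sh <- tryCatch(as.numeric(phase_shift(matrix(a0, 1), matrix(A[k, ], 1))),
                     error = function(e) NA_real_)
      # downstream slice k peaks sh bins later than the inlet slice
      lag[k] <- if (is.na(sh)) NA else sh / n_ph
    }
    # unwrap: keep increments in (-0.5, 0.5]
    for (k in 2:n_sl) {
      if (is.na(lag[k])) next
      prev <- lag[max(which(!is.na(lag[1:(k - 1)])))]
      lag[k] <- prev + ((lag[k] - prev + 0.5) %% 1) - 0.5
    }
  }
  s <- (seq_len(n_sl) - 1) / max(n_sl - 1, 1)
  slope <- NA_real_
  ok <- !is.na(lag)
  if (sum(ok) >= 3 && stats::sd(lag[ok]) > 1e-12) {
    fit <- tryCatch(MASS::rlm(lag[ok] ~ s[ok], maxit = 50),
                    error = function(e) stats::lm(lag[ok] ~ s[ok]))
    slope <- unname(stats::coef(fit)[2])
  }
  structure(list(values = A, slice_s = s,
                 phase = (seq_len(n_ph) - 0.5) / n_ph,
                 layer = layer, phase_lag_slope = slope, slice_lag = lag),
            class = "area_motion_matrix")
}

#' @export
print.area_motion_matrix <- function(x, ...) {
  cat(sprintf("<area_motion_matrix> %d slices x %d phases (%s), lag slope %.3f cycles/length\n",
              nrow(x$values), ncol(x$values), x$layer,
              x$phase_lag_slope))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.area_motion_matrix <- function(x, ...) {
  tibble::tibble(
    slice_s = rep(x$slice_s, length(x$phase)),
    phase = rep(x$phase, each = length(x$slice_s)),
    area = as.vector(x$values),
    layer = x$layer
  )
}

#' Plot an area-motion matrix
#'
#' Color-coded cross-sectional areas with normalized cycle time horizontal
#' and normalized tube length vertical, inlet at the bottom.
#'
#' @param object an `area_motion_matrix`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.area_motion_matrix <- function(object, ...) {
  df <- tidy.area_motion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$slice_s,
                                   fill = .data$area)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(area ~ (mm^2))) +
    ggplot2::labs(x = "normalized cycle time",
                  y = "normalized length (inlet at bottom)",
                  title = sprintf("%s area motion", object$layer)) +
    ggplot2::theme_minimal()
}

# O-grid tube meshing -----------------------------------------------------------

# butterfly (O-grid) template on the unit disk: a Coons-patch square core
# of m x m quads surrounded by n_r rings of n_c quads; n_c = 4 m and the
# square corners sit on the 45-degree diagonals so perimeter node j lies at
# angle theta_j = 2 pi (j-1)/n_c, starting on the +x axis.
make_butterfly_template <- function(n_c, n_r) {
  stopifnot(n_c %% 8 == 0, n_r >= 1)
  m <- n_c / 4
  theta <- 2 * pi * (seq_len(n_c) - 1) / n_c
  # core corner radius: a small square core (rings cover most of the disk)
  # keeps ring cells nearly orthogonal near the wall, which benchmarks
  # substantially better against Poiseuille than the conventional 0.5
  rc <- 0.2
  h <- rc / sqrt(2)
  # square boundary point for perimeter index j (Chebyshev-norm projection)
  bx <- h * cos(theta) / pmax(abs(cos(theta)), abs(sin(theta)))
  by <- h * sin(theta) / pmax(abs(cos(theta)), abs(sin(theta)))

  # perimeter index (0-based, from bottom-right corner) -> core grid (i, k)
  grid_of_perim <- function(j0) {
    jp <- (j0 + m / 2) %% n_c
    side <- jp %/% m
    o <- jp %% m
    switch(as.character(side),
      "0" = c(m + 1, 1 + o),
      "1" = c(m + 1 - o, m + 1),
      "2" = c(1, m + 1 - o),
      "3" = c(1 + o, 1))
  }
  gx <- matrix(NA_real_, m + 1, m + 1)
  gy <- matrix(NA_real_, m + 1, m + 1)
  for (j in seq_len(n_c)) {
    ik <- grid_of_perim(j - 1)
    gx[ik[1], ik[2]] <- bx[j]
    gy[ik[1], ik[2]] <- by[j]
  }
  # discrete Coons patch for the interior
  u <- (seq_len(m + 1) - 1) / m
  for (i in 2:m) for (k in 2:m) {
    gx[i, k] <- (1 - u[i]) * gx[1, k] + u[i] * gx[m + 1, k] +
      (1 - u[k]) * gx[i, 1] + u[k] * gx[i, m + 1] -
      ((1 - u[i]) * (1 - u[k]) * gx[1, 1] + u[i] * (1 - u[k]) * gx[m + 1, 1] +
         (1 - u[i]) * u[k] * gx[1, m + 1] + u[i] * u[k] * gx[m + 1, m + 1])
    gy[i, k] <- (1 - u[i]) * gy[1, k] + u[i] * gy[m + 1, k] +
      (1 - u[k]) * gy[i, 1] + u[k] * gy[i, m + 1] -
      ((1 - u[i]) * (1 - u[k]) * gy[1, 1] + u[i] * (1 - u[k]) * gy[m + 1, 1] +
         (1 - u[i]) * u[k] * gy[1, m + 1] + u[i] * u[k] * gy[m + 1, m + 1])
  }

  core_id <- matrix(seq_len((m + 1)^2), m + 1, m + 1)
  pts <- cbind(as.vector(gx), as.vector(gy))
  # rings: level l = 1..n_r interpolates square boundary -> unit circle
  ring_ids <- matrix(0L, n_r + 1, n_c)
  ring_ids[1, ] <- vapply(seq_len(n_c), function(j) {
    ik <- grid_of_perim(j - 1)
    core_id[ik[1], ik[2]]
  }, integer(1))
  nid <- (m + 1)^2
  for (l in seq_len(n_r)) {
    t <- l / n_r
    px <- (1 - t) * bx + t * cos(theta)
    py <- (1 - t) * by + t * sin(theta)
    pts <- rbind(pts, cbind(px, py))
    ring_ids[l + 1, ] <- nid + seq_len(n_c)
    nid <- nid + n_c
  }

  quads <- matrix(0L, 0, 4)
  for (i in seq_len(m)) for (k in seq_len(m)) {
    quads <- rbind(quads, c(core_id[i, k], core_id[i + 1, k],
                            core_id[i + 1, k + 1], core_id[i, k + 1]))
  }
  for (l in seq_len(n_r)) {
    for (j in seq_len(n_c)) {
      jn <- j %% n_c + 1
      quads <- rbind(quads, c(ring_ids[l, j], ring_ids[l + 1, j],
                              ring_ids[l + 1, jn], ring_ids[l, jn]))
    }
  }
  # fix orientation: all quads counterclockwise
  for (q in seq_len(nrow(quads))) {
    v <- pts[quads[q, ], ]
    if (polygon_area_signed(v) < 0) quads[q, ] <- rev(quads[q, ])
  }
  center_id <- core_id[m / 2 + 1, m / 2 + 1]
  list(points = pts, quads = quads, ring_ids = ring_ids,
       perim_ids = ring_ids[n_r + 1, ], center_id = center_id,
       n_c = n_c, n_r = n_r, m = m, theta = theta,
       n2d = nrow(pts))
}

# radius of a contour about its centroid, resampled at n_c uniform angles,
# rescaled so the n_c-gon preserves the contour's enclosed area
contour_radii_at <- function(contour, n_c) {
  v <- contour$vertices
  ct <- contour$centroid
  rel <- sweep(v, 2, ct)
  ang <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  rad <- sqrt(rowSums(rel^2))
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  ang_ext <- c(ang[length(ang)] - 2 * pi, ang, ang[1] + 2 * pi)
  rad_ext <- c(rad[length(rad)], rad, rad[1])
  th <- 2 * pi * (seq_len(n_c) - 1) / n_c
  r <- stats::approx(ang_ext, rad_ext, xout = th)$y
  # area-preserving rescale of the inscribed polygon
  a_poly <- 0.5 * sin(2 * pi / n_c) * sum(r * c(r[-1], r[1]))
  r * sqrt(contour$area / a_poly)
}

smootherstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^3 * (t * (6 * t - 15) + 10)
}

#' Build a simulation-ready hexahedral tube mesh at one phase
#'
#' Lofts the segmented cross-section contours of one phase into a
#' structured hexahedral O-grid mesh: contours are resampled to a matching
#' angular parameterization (vertex 1 anchored to the image +x axis),
#' area-preservingly rescaled, lofted along the centerline, and filled with
#' a butterfly (square-core) radial topology so cells stay well-shaped at
#' the centerline. Straight inlet/outlet extensions (default 3 local
#' diameters, blended by a smooth taper of the end contour to its
#' area-preserving circle over the first diameter) are appended to
#' establish parabolic flow; extension cells are tagged so they can be
#' excluded from post-simulation analyses.
#'
#' @param series a `cross_section_series`.
#' @param phase phase index; must not be flagged closed at any slice.
#' @param target_axial_layers axial element layers through the body
#'   (default `n_slices - 1`, i.e. no axial resampling).
#' @param target_circumferential_divisions circumferential divisions
#'   (multiple of 8; default 24).
#' @param radial_layers number of O-grid rings between the square core and
#'   the wall (>= 2 so near-wall gradients have two interior rings).
#' @param extension_length_factor extension length in local diameters.
#' @param include_extensions logical.
#' @return An object of class `tube_mesh`: `nodes` (N x 3 mm), `elems`
#'   (E x 8), boundary tags (`wall_nodes`, `inlet_nodes`, `outlet_nodes`,
#'   `wall_faces`, `inlet_faces`, `outlet_faces`), the 2-D `template`,
#'   per-section metadata (`sections` tibble with `extension` flags and
#'   normalized body position `s_norm`), structured index matrices
#'   (`wall_grid`, `ring1_grid`, `ring2_grid`), `extension_elems`,
#'   `monitor_node` (lumen center of the mid-body section), `phase_index`.
#' @export
build_mesh <- function(series, phase,
                       target_axial_layers = NULL,
                       target_circumferential_divisions = 24,
                       radial_layers = 2,
                       extension_length_factor = 3,
                       include_extensions = TRUE) {
  n_c <- target_circumferential_divisions
  n_r <- radial_layers
  stopifnot(n_c %% 8 == 0, n_r >= 2)
  if (any(series$closed[, phase])) {
    stop(structure(class = c("oftflow_closed_phase", "error", "condition"),
                   list(message = sprintf(
                     "phase %d has fully coapted slices and cannot be meshed",
                     phase), call = sys.call())))
  }
  n_sl <- series$n_slices
  L <- (n_sl - 1) * series$slice_spacing
  radii <- t(vapply(seq_len(n_sl), function(k) {
    contour_radii_at(series$contours[[k]][[phase]], n_c)
  }, numeric(n_c)))                      # n_sl x n_c
  cents <- series$centroids[, phase, , drop = TRUE]
  if (is.null(dim(cents))) cents <- matrix(cents, ncol = 2)

  n_ax <- if (is.null(target_axial_layers)) n_sl - 1 else target_axial_layers
  z_body <- seq(0, L, length.out = n_ax + 1)
  z_slice <- (seq_len(n_sl) - 1) * series$slice_spacing
  radii_b <- apply(radii, 2, function(r) {
    stats::approx(z_slice, r, xout = z_body)$y
  })
  cent_b <- apply(cents, 2, function(cc) {
    stats::approx(z_slice, cc, xout = z_body)$y
  })
  if (is.null(dim(radii_b))) radii_b <- matrix(radii_b, ncol = n_c)

  dz <- L / n_ax
  secs <- list(z = z_body, radii = radii_b, cent = cent_b,
               ext = rep(FALSE, n_ax + 1))

  if (include_extensions && extension_length_factor > 0) {
    add_ext <- function(secs, end) {
      idx <- if (end == "inlet") 1 else length(secs$z)
      r_end <- if (end == "inlet") secs$radii[1, ] else
        secs$radii[nrow(secs$radii), ]
      a_end <- 0.5 * sin(2 * pi / n_c) * sum(r_end * c(r_end[-1], r_end[1]))
      d_loc <- 2 * sqrt(a_end / pi)
      len <- extension_length_factor * d_loc
      n_ext <- max(3L, ceiling(len / dz / 2))  # coarser axial spacing is fine
      u <- seq_len(n_ext) / n_ext * len
      r_eq <- sqrt(a_end / pi)
      sgn <- if (end == "inlet") -1 else 1
      zs <- secs$z[idx] + sgn * u
      ce <- secs$cent[idx, ]
      new_r <- t(vapply(u, function(ui) {
        w <- smootherstep(ui / d_loc)
        (1 - w) * r_end + w * r_eq
      }, numeric(n_c)))
      if (end == "inlet") {
        secs$z <- c(rev(zs), secs$z)
        secs$radii <- rbind(new_r[rev(seq_len(n_ext)), , drop = FALSE],
                            secs$radii)
        secs$cent <- rbind(matrix(ce, n_ext, 2, byrow = TRUE), secs$cent)
        secs$ext <- c(rep(TRUE, n_ext), secs$ext)
      } else {
        secs$z <- c(secs$z, zs)
        secs$radii <- rbind(secs$radii, new_r)
        secs$cent <- rbind(secs$cent, matrix(ce, n_ext, 2, byrow = TRUE))
        secs$ext <- c(secs$ext, rep(TRUE, n_ext))
      }
      secs
    }
    secs <- add_ext(secs, "inlet")
    secs <- add_ext(secs, "outlet")
  }

  tpl <- make_butterfly_template(n_c, n_r)
  n_sec <- length(secs$z)
  n2d <- tpl$n2d
  ang <- atan2(tpl$points[, 2], tpl$points[, 1]) %% (2 * pi)
  rad0 <- sqrt(rowSums(tpl$points^2))
  dir <- tpl$points / pmax(rad0, 1e-12)
  dir[rad0 < 1e-12, ] <- 0

  nodes <- matrix(0, n_sec * n2d, 3)
  for (sct in seq_len(n_sec)) {
    r_fun <- secs$radii[sct, ]
    # circular interpolation of the radius function at template angles
    th_ext <- c(tpl$theta - 2 * pi, tpl$theta, tpl$theta + 2 * pi)
    r_ext <- rep(r_fun, 3)
    rho <- stats::approx(th_ext, r_ext, xout = ang)$y
    off <- (sct - 1) * n2d
    nodes[off + seq_len(n2d), 1] <- secs$cent[sct, 1] + dir[, 1] * rad0 * rho
    nodes[off + seq_len(n2d), 2] <- secs$cent[sct, 2] + dir[, 2] * rad0 * rho
    nodes[off + seq_len(n2d), 3] <- secs$z[sct]
  }

  nq <- nrow(tpl$quads)
  elems <- matrix(0L, (n_sec - 1) * nq, 8)
  ext_elem <- logical((n_sec - 1) * nq)
  for (sct in seq_len(n_sec - 1)) {
    off1 <- (sct - 1) * n2d
    off2 <- sct * n2d
    rows <- (sct - 1) * nq + seq_len(nq)
    elems[rows, 1:4] <- as.integer(tpl$quads + off1)
    elems[rows, 5:8] <- as.integer(tpl$quads + off2)
    ext_elem[rows] <- secs$ext[sct] || secs$ext[sct + 1]
  }

  mnj <- mesh_min_jacobian(nodes, elems)
  if (mnj <= 0) {
    stop(structure(class = c("oftflow_tangled_mesh", "error", "condition"),
                   list(message = sprintf(
                     "tangled loft: minimum Jacobian %.3g <= 0", mnj),
                     call = sys.call())))
  }

  wall_grid <- t(vapply(seq_len(n_sec), function(sct) {
    as.integer((sct - 1) * n2d + tpl$perim_ids)
  }, integer(n_c)))
  ring1_grid <- t(vapply(seq_len(n_sec), function(sct) {
    as.integer((sct - 1) * n2d + tpl$ring_ids[n_r, ])
  }, integer(n_c)))
  ring2_grid <- t(vapply(seq_len(n_sec), function(sct) {
    as.integer((sct - 1) * n2d + tpl$ring_ids[n_r - 1, ])
  }, integer(n_c)))

  wall_faces <- matrix(0L, (n_sec - 1) * n_c, 4)
  wall_face_ext <- logical((n_sec - 1) * n_c)
  rix <- 1
  for (sct in seq_len(n_sec - 1)) {
    for (j in seq_len(n_c)) {
      jn <- j %% n_c + 1
      wall_faces[rix, ] <- as.integer(c(wall_grid[sct, j], wall_grid[sct, jn],
                             wall_grid[sct + 1, jn], wall_grid[sct + 1, j]))
      wall_face_ext[rix] <- secs$ext[sct] || secs$ext[sct + 1]
      rix <- rix + 1
    }
  }

  inlet_faces <- tpl$quads[, 4:1]            # outward normal = -z
  outlet_faces <- matrix(as.integer(tpl$quads + (n_sec - 1) * n2d),
                         ncol = 4)  # outward normal = +z

  body <- which(!secs$ext)
  s_norm <- rep(NA_real_, n_sec)
  s_norm[body] <- (secs$z[body] - secs$z[body[1]]) /
    (secs$z[body[length(body)]] - secs$z[body[1]])
  sec_area <- vapply(seq_len(n_sec), function(sct) {
    r <- secs$radii[sct, ]
    0.5 * sin(2 * pi / n_c) * sum(r * c(r[-1], r[1]))
  }, numeric(1))
  sections <- tibble::tibble(
    section = seq_len(n_sec), z = secs$z, extension = secs$ext,
    s_norm = s_norm, area = sec_area,
    centroid_x = secs$cent[, 1], centroid_y = secs$cent[, 2]
  )

  mid_body <- body[ceiling(length(body) / 2)]
  structure(list(
    nodes = nodes, elems = elems,
    template = tpl, n_sections = n_sec, n2d = n2d,
    sections = sections, body_sections = body,
    wall_grid = wall_grid, ring1_grid = ring1_grid, ring2_grid = ring2_grid,
    wall_nodes = unique(as.vector(wall_grid)),
    inlet_nodes = seq_len(n2d),
    outlet_nodes = (n_sec - 1) * n2d + seq_len(n2d),
    wall_faces = wall_faces, wall_face_extension = wall_face_ext,
    inlet_faces = inlet_faces, outlet_faces = outlet_faces,
    extension_elems = ext_elem,
    includes_extensions = any(secs$ext),
    monitor_node = (mid_body - 1) * n2d + tpl$center_id,
    monitor_section = mid_body,
    phase_index = phase,
    min_jacobian = mnj
  ), class = "tube_mesh")
}

#' @export
print.tube_mesh <- function(x, ...) {
  cat(sprintf("<tube_mesh> %d nodes, %d hex cells (%d sections%s), min |J| %.3g\n",
              nrow(x$nodes), nrow(x$elems), x$n_sections,
              if (x$includes_extensions) " incl. extensions" else "",
              x$min_jacobian))
  invisible(x)
}

#' Volume enclosed by a tube mesh
#'
#' @param mesh a `tube_mesh`.
#' @param body_only exclude inlet/outlet extension cells (default TRUE).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, body_only = TRUE) {
  keep <- if (body_only) !mesh$extension_elems else
    rep(TRUE, nrow(mesh$elems))
  fem_mesh_volume(mesh$nodes, mesh$elems[keep, , drop = FALSE])
}

#' Export a tube mesh in legacy VTK format
#'
#' Writes an ASCII VTK unstructured-grid file with hexahedral cells and a
#' cell array marking extension cells, plus optional point data.
#'
#' @param mesh a `tube_mesh`.
#' @param path output file path (`.vtk`).
#' @param point_data optional named list of per-node vectors/matrices.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "tube mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", e, e * 9), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(as.character(rep(12L, e)), con)
  writeLines(sprintf("CELL_DATA %d", e), con)
  writeLines(c("SCALARS extension int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$extension_elems)), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(v, digits = 9), con, row.names = FALSE,
                           col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(v), digits = 9), con)
      }
    }
  }
  invisible(path)
}
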