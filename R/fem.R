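# Trilinear hexahedral finite-element kernels.
#
# Element node ordering: nodes 1-4 = bottom quad counterclockwise (maps to
# reference (xi, eta) = (-1,-1), (1,-1), (1,1), (-1,1) at zeta = -1),
# nodes 5-8 = the same quad at the next section (zeta = +1).

hex_ref_corners <- function() {
  cbind(
    xi   = c(-1, 1, 1, -1, -1, 1, 1, -1),
    eta  = c(-1, -1, 1, 1, -1, -1, 1, 1),
    zeta = c(-1, -1, -1, -1, 1, 1, 1, 1)
  )
}

hex_gauss <- function() {
  g <- 1 / sqrt(3)
  hex_ref_corners() * g
}

# shape values and reference-space gradients at one reference point
hex_shape <- function(p) {
  rc <- hex_ref_corners()
  N <- (1 + rc[, 1] * p[1]) * (1 + rc[, 2] * p[2]) * (1 + rc[, 3] * p[3]) / 8
  dN <- cbind(
    rc[, 1] * (1 + rc[, 2] * p[2]) * (1 + rc[, 3] * p[3]) / 8,
    rc[, 2] * (1 + rc[, 1] * p[1]) * (1 + rc[, 3] * p[3]) / 8,
    rc[, 3] * (1 + rc[, 1] * p[1]) * (1 + rc[, 2] * p[2]) / 8
  )
  list(N = N, dN = dN)
}

# per-element node coordinate arrays: list of 8 matrices (n_elem x 3)
elem_coords <- function(nodes, elems) {
  lapply(seq_len(8), function(a) nodes[elems[, a], , drop = FALSE])
}

# detJ and physical shape gradients at one Gauss point, vectorized over
# elements; X = elem_coords() result
elem_geometry_at <- function(X, dN) {
  ne <- nrow(X[[1]])
  J <- array(0, dim = c(ne, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    acc <- numeric(ne)
    for (a in 1:8) acc <- acc + dN[a, i] * X[[a]][, j]
    J[, i, j] <- acc
  }
  # analytic 3x3 inverse via cofactors
  c11 <- J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]
  c12 <- J[, 2, 3] * J[, 3, 1] - J[, 2, 1] * J[, 3, 3]
  c13 <- J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1]
  detJ <- J[, 1, 1] * c11 + J[, 1, 2] * c12 + J[, 1, 3] * c13
  # inv[i, k, ] = cofactor C_ik of J, so that grad_x N = dN_xi . C / detJ
  # (using d xi_i / d x_k = C_ik / detJ for J_ij = d x_j / d xi_i)
  inv <- array(0, dim = c(3, 3, length(detJ)))
  inv[1, 1, ] <- c11; inv[1, 2, ] <- c12; inv[1, 3, ] <- c13
  inv[2, 1, ] <- J[, 1, 3] * J[, 3, 2] - J[, 1, 2] * J[, 3, 3]
  inv[2, 2, ] <- J[, 1, 1] * J[, 3, 3] - J[, 1, 3] * J[, 3, 1]
  inv[2, 3, ] <- J[, 1, 2] * J[, 3, 1] - J[, 1, 1] * J[, 3, 2]
  inv[3, 1, ] <- J[, 1, 2] * J[, 2, 3] - J[, 1, 3] * J[, 2, 2]
  inv[3, 2, ] <- J[, 1, 3] * J[, 2, 1] - J[, 1, 1] * J[, 2, 3]
  inv[3, 3, ] <- J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
  # gradN[[a]]: n_elem x 3 physical gradient of shape a
  gradN <- lapply(1:8, function(a) {
    g <- matrix(0, nrow(X[[1]]), 3)
    for (k in 1:3) {
      g[, k] <- (dN[a, 1] * inv[1, k, ] + dN[a, 2] * inv[2, k, ] +
                   dN[a, 3] * inv[3, k, ]) / detJ
    }
    g
  })
  list(detJ = detJ, gradN = gradN)
}

# minimum Jacobian determinant over all Gauss points (mesh validity)
mesh_min_jacobian <- function(nodes, elems) {
  X <- elem_coords(nodes, elems)
  gp <- hex_gauss()
  mn <- Inf
  for (g in seq_len(8)) {
    sh <- hex_shape(gp[g, ])
    geo <- elem_geometry_at(X, sh$dN)
    mn <- min(mn, min(geo$detJ))
  }
  mn
}

# integral of 1 over the mesh (sum of cell volumes)
fem_mesh_volume <- function(nodes, elems) {
  X <- elem_coords(nodes, elems)
  gp <- hex_gauss()
  v <- 0
  for (g in seq_len(8)) {
    sh <- hex_shape(gp[g, ])
    v <- v + sum(elem_geometry_at(X, sh$dN)$detJ)
  }
  v
}

# Assemble the scalar stiffness (Laplacian) K, the pressure-velocity
# coupling blocks B_k (k = 1..3, entries int N_p dN_v/dx_k), and the
# element-size vector used by the pressure stabilization.
assemble_stokes_blocks <- function(nodes, elems) {
  nn <- nrow(nodes)
  ne <- nrow(elems)
  X <- elem_coords(nodes, elems)
  gp <- hex_gauss()

  Kacc <- vector("list", 64)
  Bacc <- list(vector("list", 64), vector("list", 64), vector("list", 64))
  for (idx in 1:64) Kacc[[idx]] <- numeric(ne)
  for (k in 1:3) for (idx in 1:64) Bacc[[k]][[idx]] <- numeric(ne)
  vol <- numeric(ne)
  mass_lumped <- numeric(nn)

  for (g in seq_len(8)) {
    sh <- hex_shape(gp[g, ])
    geo <- elem_geometry_at(X, sh$dN)
    w <- geo$detJ  # Gauss weight = 1
    vol <- vol + w
    for (a in 1:8) {
      mass_lumped <- mass_lumped +
        tabulate_add(elems[, a], w * sh$N[a], nn)
    }
    for (a in 1:8) {
      ga <- geo$gradN[[a]]
      for (b in a:8) {
        gb <- geo$gradN[[b]]
        kab <- w * (ga[, 1] * gb[, 1] + ga[, 2] * gb[, 2] +
                      ga[, 3] * gb[, 3])
        Kacc[[(a - 1) * 8 + b]] <- Kacc[[(a - 1) * 8 + b]] + kab
        if (b > a) Kacc[[(b - 1) * 8 + a]] <- Kacc[[(b - 1) * 8 + a]] + kab
      }
      for (b in 1:8) {
        # B[p-node a, v-node b, comp k] = int N_a dN_b/dx_k
        for (k in 1:3) {
          Bacc[[k]][[(a - 1) * 8 + b]] <- Bacc[[k]][[(a - 1) * 8 + b]] +
            w * sh$N[a] * geo$gradN[[b]][, k]
        }
      }
    }
  }

  ii <- integer(64 * ne); jj <- integer(64 * ne)
  pos <- 1
  for (a in 1:8) for (b in 1:8) {
    rng <- pos:(pos + ne - 1)
    ii[rng] <- elems[, a]
    jj[rng] <- elems[, b]
    pos <- pos + ne
  }
  flatten <- function(acc) {
    x <- numeric(64 * ne)
    pos <- 1
    for (a in 1:8) for (b in 1:8) {
      x[pos:(pos + ne - 1)] <- acc[[(a - 1) * 8 + b]]
      pos <- pos + ne
    }
    x
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = flatten(Kacc),
                            dims = c(nn, nn))
  B <- lapply(1:3, function(k) {
    Matrix::sparseMatrix(i = ii, j = jj, x = flatten(Bacc[[k]]),
                         dims = c(nn, nn))
  })
  list(K = K, B = B, elem_volume = vol, elems = elems, n_nodes = nn,
       mass_lumped = mass_lumped)
}

# accumulate val into a length-n vector by (possibly repeated) index
tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# element-weighted pressure stabilization matrix (Brezzi-Pitkaranta):
# sum_e alpha h_e^2/mu int_e grad(N_a).grad(N_b)
assemble_pressure_stab <- function(nodes, elems, elem_volume, mu, alpha) {
  nn <- nrow(nodes)
  ne <- nrow(elems)
  X <- elem_coords(nodes, elems)
  gp <- hex_gauss()
  h2 <- elem_volume^(2 / 3)
  scale <- alpha * h2 / mu
  acc <- vector("list", 64)
  for (idx in 1:64) acc[[idx]] <- numeric(ne)
  for (g in seq_len(8)) {
    sh <- hex_shape(gp[g, ])
    geo <- elem_geometry_at(X, sh$dN)
    w <- geo$detJ * scale
    for (a in 1:8) {
      ga <- geo$gradN[[a]]
      for (b in a:8) {
        gb <- geo$gradN[[b]]
        v <- w * (ga[, 1] * gb[, 1] + ga[, 2] * gb[, 2] +
                    ga[, 3] * gb[, 3])
        acc[[(a - 1) * 8 + b]] <- acc[[(a - 1) * 8 + b]] + v
        if (b > a) acc[[(b - 1) * 8 + a]] <- acc[[(b - 1) * 8 + a]] + v
      }
    }
  }
  ii <- integer(64 * ne); jj <- integer(64 * ne); xx <- numeric(64 * ne)
  pos <- 1
  for (a in 1:8) for (b in 1:8) {
    rng <- pos:(pos + ne - 1)
    ii[rng] <- elems[, a]
    jj[rng] <- elems[, b]
    xx[rng] <- acc[[(a - 1) * 8 + b]]
    pos <- pos + ne
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
}

# convective matrix int rho' N_a (u . grad N_b) for Picard iterations;
# u is an n_nodes x 3 velocity field, rho_scaled in Pa s^2/mm^2 units
assemble_convection <- function(nodes, elems, u, rho_scaled) {
  nn <- nrow(nodes)
  ne <- nrow(elems)
  X <- elem_coords(nodes, elems)
  U <- lapply(1:8, function(a) u[elems[, a], , drop = FALSE])
  gp <- hex_gauss()
  acc <- vector("list", 64)
  for (idx in 1:64) acc[[idx]] <- numeric(ne)
  for (g in seq_len(8)) {
    sh <- hex_shape(gp[g, ])
    geo <- elem_geometry_at(X, sh$dN)
    ug <- matrix(0, ne, 3)
    for (a in 1:8) ug <- ug + sh$N[a] * U[[a]]
    w <- geo$detJ
    for (a in 1:8) {
      for (b in 1:8) {
        gb <- geo$gradN[[b]]
        conv <- ug[, 1] * gb[, 1] + ug[, 2] * gb[, 2] + ug[, 3] * gb[, 3]
        acc[[(a - 1) * 8 + b]] <- acc[[(a - 1) * 8 + b]] +
          w * sh$N[a] * conv * rho_scaled
      }
    }
  }
  ii <- integer(64 * ne); jj <- integer(64 * ne); xx <- numeric(64 * ne)
  pos <- 1
  for (a in 1:8) for (b in 1:8) {
    rng <- pos:(pos + ne - 1)
    ii[rng] <- elems[, a]
    jj[rng] <- elems[, b]
    xx[rng] <- acc[[(a - 1) * 8 + b]]
    pos <- pos + ne
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
}

# 2x2 Gauss integration of int N_a n dGamma over bilinear quad faces.
# faces: Q x 4 node-index matrix; returns per-face list with the vector
# integrals (4 x 3) and the face area and unit normal (from node order).
quad_face_integrals <- function(nodes, faces) {
  g <- 1 / sqrt(3)
  gp2 <- cbind(c(-g, g, g, -g), c(-g, -g, g, g))
  rc2 <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  P <- lapply(1:4, function(a) nodes[faces[, a], , drop = FALSE])
  nf <- nrow(faces)
  res_int <- array(0, dim = c(nf, 4, 3))
  area <- numeric(nf)
  nrm_acc <- matrix(0, nf, 3)
  for (q in 1:4) {
    xi <- gp2[q, 1]; eta <- gp2[q, 2]
    N <- (1 + rc2[, 1] * xi) * (1 + rc2[, 2] * eta) / 4
    dNxi <- rc2[, 1] * (1 + rc2[, 2] * eta) / 4
    dNeta <- rc2[, 2] * (1 + rc2[, 1] * xi) / 4
    t1 <- matrix(0, nf, 3); t2 <- matrix(0, nf, 3)
    for (a in 1:4) {
      t1 <- t1 + dNxi[a] * P[[a]]
      t2 <- t2 + dNeta[a] * P[[a]]
    }
    nvec <- cbind(
      t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
      t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
      t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1]
    )
    area <- area + sqrt(rowSums(nvec^2))
    nrm_acc <- nrm_acc + nvec
    for (a in 1:4) res_int[, a, ] <- res_int[, a, ] + N[a] * nvec
  }
  unit <- nrm_acc / pmax(sqrt(rowSums(nrm_acc^2)), 1e-300)
  list(integrals = res_int, area = area, normal = unit)
}
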