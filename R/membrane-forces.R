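# Elastic membrane forces. 3D: Skalak shear/dilation strain energy on linear
# membrane triangles (per-element deformation gradient between local tangent
# frames) and Helfrich bending with a cotangent-Laplacian mean curvature.
# 2D contour analog: a strain-hardening tension law T(lambda) =
# Gs (lambda - lambda^-3) mimicking Skalak stiffening, plus a quadratic
# curvature (fourth-difference) bending energy.

new_membrane_forces <- function(forces, energy, kind) {
  structure(list(forces = forces, energy = energy, kind = kind),
            class = "membrane_forces")
}

#' @export
print.membrane_forces <- function(x, ...) {
  cat("<membrane_forces ", x$kind, "> energy = ", format(x$energy),
      ", max |f| = ", format(max(sqrt(rowSums(x$forces^2)))), "\n", sep = "")
  invisible(x)
}

# --- Skalak (3D) -----------------------------------------------------------

# local 2D coordinates of a triangle soup: returns per-triangle edge matrices
tri_local <- function(V, F) {
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  l1 <- sqrt(rowSums(e1^2))
  u1 <- e1 / l1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(nrm^2)) # 2*area
  nh <- nrm / a2
  u2 <- cbind(nh[, 2] * u1[, 3] - nh[, 3] * u1[, 2],
              nh[, 3] * u1[, 1] - nh[, 1] * u1[, 3],
              nh[, 1] * u1[, 2] - nh[, 2] * u1[, 1])
  # 2D coords: P2 = (l1, 0), P3 = (e2.u1, e2.u2)
  list(u1 = u1, u2 = u2, a = a2 / 2,
       x2 = l1, x3 = rowSums(e2 * u1), y3 = rowSums(e2 * u2))
}

#' Skalak shear/area-dilation membrane forces
#'
#' For a 3D triangulated mesh, evaluates the Skalak strain energy density
#' W = (Gs/4) (I1^2 + 2 I1 - 2 I2) + (C Gs/4) I2^2 with strain invariants
#' I1 = lambda1^2 + lambda2^2 - 2 and I2 = (lambda1 lambda2)^2 - 1 on each
#' linear triangle, and returns the exact negative energy gradient as nodal
#' forces. For a 2D contour mesh, the strain-hardening tension analog is
#' used (see package vignette).
#'
#' @param mesh a `membrane_mesh` carrying reference coordinates.
#' @param params a [membrane_params()] object.
#' @return a `membrane_forces` object (`forces`: n x 3 or n x 2, model units
#'   of Pa um^2 per node in 3D and Pa um per node in 2D; `energy` in model
#'   units).
#' @export
skalak_forces <- function(mesh, params) {
  stopifnot(inherits(mesh, "membrane_mesh"))
  if (mesh$dim == 2L) return(contour_elastic_forces(mesh, params))
  V <- mesh$vertices; F <- mesh$faces; V0 <- mesh$reference
  Gs <- params$Gs; C <- params$C
  ref <- tri_local(V0, F)
  cur <- tri_local(V, F)
  if (any(ref$a <= 1e-12) || any(cur$a <= 1e-12)) {
    bad <- which(ref$a <= 1e-12 | cur$a <= 1e-12)[1]
    stop("degenerate (zero-area) membrane element: triangle ", bad)
  }
  # Dm = [[x2, x3], [0, y3]] (reference), Ds analogous (deformed)
  # F = Ds Dm^-1; with Dm upper-triangular, Dm^-1 = [[1/x2, -x3/(x2 y3)],
  # [0, 1/y3]]
  i11 <- 1 / ref$x2
  i12 <- -ref$x3 / (ref$x2 * ref$y3)
  i22 <- 1 / ref$y3
  F11 <- cur$x2 * i11
  F12 <- cur$x2 * i12 + cur$x3 * i22
  F21 <- 0
  F22 <- cur$y3 * i22
  # fix: F21 comes from Ds[2,1] = 0 only if deformed frame aligned; Ds =
  # [[x2, x3], [0, y3]] in its own frame, so F21 = 0 * i11 + 0 = 0 and
  # F22 = y3 * i22; F12 as above. (Both Dm and Ds are upper triangular.)
  G11 <- F11 * F11
  G12 <- F11 * F12
  G22 <- F12 * F12 + F22 * F22
  detF <- F11 * F22
  I1 <- G11 + G22 - 2
  I2 <- detF * detF - 1
  W <- (Gs / 4) * (I1 * I1 + 2 * I1 - 2 * I2) + (C * Gs / 4) * I2 * I2
  energy <- sum(ref$a * W)
  dW1 <- (Gs / 2) * (I1 + 1)
  dW2 <- -Gs / 2 + (C * Gs / 2) * I2
  # P = dW/dF = 2 dW1 F + 2 dW2 det(G) F^-T ; det(G) = detF^2
  # F^-T = (1/detF) [[F22, -F21],[-F12, F11]]^T = (1/detF)[[F22, -F12],[0, F11]]
  c2 <- 2 * dW2 * detF # 2 dW2 detG / detF
  P11 <- 2 * dW1 * F11 + c2 * F22
  P12 <- 2 * dW1 * F12
  P21 <- c2 * (-F12)
  P22 <- 2 * dW1 * F22 + c2 * F11
  # nodal forces (local 2D): H = -A_ref * P * Dm^-T; columns act on nodes 2,3
  H11 <- -ref$a * (P11 * i11 + P12 * i12)
  H21 <- -ref$a * (P21 * i11 + P22 * i12)
  H12 <- -ref$a * (P12 * i22)
  H22 <- -ref$a * (P22 * i22)
  # map to 3D via the deformed frame
  f2 <- cur$u1 * H11 + cur$u2 * H21
  f3 <- cur$u1 * H12 + cur$u2 * H22
  f1 <- -(f2 + f3)
  forces <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    forces[, k] <- forces[, k] +
      as.vector(tapply(c(f1[, k], f2[, k], f3[, k]),
                       factor(c(F[, 1], F[, 2], F[, 3]),
                              levels = seq_len(nrow(V))), sum, default = 0))
  }
  forces[is.na(forces)] <- 0
  new_membrane_forces(forces, energy, "skalak")
}

# 2D contour analog: nonlinear edge tensions
contour_elastic_forces <- function(mesh, params) {
  V <- mesh$vertices; V0 <- mesh$reference
  Gs <- params$Gs
  n <- nrow(V)
  nxt <- c(2:n, 1)
  ev <- V[nxt, ] - V
  l <- sqrt(rowSums(ev^2))
  l0 <- sqrt(rowSums((V0[nxt, ] - V0)^2))
  if (any(l0 <= 1e-12)) stop("degenerate (zero-length) contour element: ",
                             which(l0 <= 1e-12)[1])
  lam <- l / l0
  t_hat <- ev / l
  Tension <- Gs * (lam - lam^-3)
  energy <- sum(l0 * (Gs / 2) * (lam^2 + lam^-2 - 2))
  fT <- Tension * t_hat
  forces <- fT - fT[c(n, 1:(n - 1)), ]
  new_membrane_forces(forces, energy, "contour-elastic")
}

# --- Helfrich bending ------------------------------------------------------

# discrete Helfrich energy 2 kappa sum_v H_v^2 A_v with cotangent-Laplacian
# mean curvature and barycentric vertex areas; complex-safe (no abs/min/max)
bending_energy_tri <- function(Vflat, F, nv, kappa) {
  V <- matrix(Vflat, nv, 3)
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  cotan <- function(a, b) { # cot of angle between vectors a,b (rows)
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    rowSums(a * b) / sqrt(rowSums(cr * cr))
  }
  c1 <- cotan(p2 - p1, p3 - p1) # angle at vertex 1, opposite edge (2,3)
  c2 <- cotan(p1 - p2, p3 - p2)
  c3 <- cotan(p1 - p3, p2 - p3)
  cr <- {
    e1 <- p2 - p1; e2 <- p3 - p1
    cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  }
  area <- sqrt(rowSums(cr * cr)) / 2
  acc <- function(idx, val) {
    out <- matrix(0, nv, ncol(val))
    if (is.complex(val)) out <- matrix(0 + 0i, nv, ncol(val))
    for (k in seq_len(ncol(val)))
      out[, k] <- as.vector(tapply(val[, k], factor(idx, seq_len(nv)), sum,
                                   default = 0))
    out[is.na(out)] <- 0
    out
  }
  # K_v = (1/(2A_v)) sum over opposite-edge contributions
  # edge (2,3) weighted by cot at 1, etc.
  w23 <- c1; w13 <- c2; w12 <- c3
  contrib <- rbind(
    cbind(F[, 2], w23 * (p2 - p3)), cbind(F[, 3], w23 * (p3 - p2)),
    cbind(F[, 1], w13 * (p1 - p3)), cbind(F[, 3], w13 * (p3 - p1)),
    cbind(F[, 1], w12 * (p1 - p2)), cbind(F[, 2], w12 * (p2 - p1)))
  Ksum <- acc(Re(contrib[, 1]), contrib[, 2:4, drop = FALSE])
  Av <- acc(c(F[, 1], F[, 2], F[, 3]),
            matrix(rep(area, 3) / 3, ncol = 1))
  Kv <- Ksum / (4 * Av[, 1]) # factor 1/2 twice: Laplace-Beltrami & H = |K|/2
  H2 <- rowSums(Kv * Kv)
  sum(2 * kappa * H2 * Av[, 1])
}

#' Helfrich bending forces
#'
#' 3D: discrete Helfrich energy E = 2 kappa * sum_v H_v^2 A_v (zero
#' spontaneous curvature) with cotangent-Laplacian mean curvature H_v and
#' barycentric vertex areas; nodal forces are the exact negative gradient,
#' evaluated by complex-step differentiation of the discrete energy
#' (machine-precision derivatives). 2D contour: quadratic curvature energy
#' E = (kappa/2) * sum |d2 X / ds^2|^2 ds on the reference spacing, whose
#' gradient is the periodic fourth difference.
#'
#' @inheritParams skalak_forces
#' @return a `membrane_forces` object.
#' @export
bending_forces <- function(mesh, params) {
  stopifnot(inherits(mesh, "membrane_mesh"))
  if (mesh$dim == 2L) return(contour_bending_forces(mesh, params))
  V <- mesh$vertices; F <- mesh$faces
  check_closed_manifold(F, nrow(V))
  kappa <- params$kappa
  nv <- nrow(V)
  E0 <- bending_energy_tri(as.vector(V), F, nv, kappa)
  h <- 1e-20
  g <- numeric(3 * nv)
  x0 <- as.vector(V)
  for (j in seq_len(3 * nv)) {
    xz <- as.complex(x0)
    xz[j] <- xz[j] + h * 1i
    g[j] <- Im(bending_energy_tri(xz, F, nv, kappa)) / h
  }
  new_membrane_forces(-matrix(g, nv, 3), Re(E0), "helfrich")
}

#' Bending energy of a mesh (no forces)
#'
#' @inheritParams skalak_forces
#' @return scalar energy in model units (Pa um^3 in 3D, Pa um^2 in 2D).
#' @export
bending_energy <- function(mesh, params) {
  if (mesh$dim == 2L) {
    ce <- contour_bending_forces(mesh, params)
    return(ce$energy)
  }
  bending_energy_tri(as.vector(mesh$vertices), mesh$faces,
                     nrow(mesh$vertices), params$kappa)
}

contour_bending_forces <- function(mesh, params) {
  V <- mesh$vertices; V0 <- mesh$reference
  kappa <- params$kappa
  n <- nrow(V)
  nxt <- c(2:n, 1)
  ds0 <- mean(sqrt(rowSums((V0[nxt, ] - V0)^2)))
  d2 <- V[c(2:n, 1), ] - 2 * V + V[c(n, 1:(n - 1)), ]
  energy <- kappa / (2 * ds0^3) * sum(d2^2)
  d4 <- d2[c(2:n, 1), ] - 2 * d2 + d2[c(n, 1:(n - 1)), ]
  forces <- -kappa / ds0^3 * d4
  new_membrane_forces(forces, energy, "contour-bending")
}

check_closed_manifold <- function(F, nv) {
  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(key)
  if (any(tab != 2))
    stop("mesh is not a closed 2-manifold (", sum(tab != 2),
         " boundary/non-manifold edges)")
  invisible(TRUE)
}

# weak area-conservation penalty for 2D cells (keeps the enclosed area near
# its reference during long runs; the interpolated IB velocity field is not
# exactly divergence-free)
contour_area_penalty <- function(mesh, k_area) {
  V <- mesh$vertices
  A0 <- abs(contour_area(mesh$reference))
  A <- contour_area(V)
  n <- nrow(V)
  # gradient of shoelace area wrt vertices
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  dA <- 0.5 * cbind(V[nxt, 2] - V[prv, 2], V[prv, 1] - V[nxt, 1])
  sgn <- sign(A)
  err <- (abs(A) - A0) / A0
  f <- -k_area * err * sgn * dA
  list(forces = f, area = abs(A), err = err)
}
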