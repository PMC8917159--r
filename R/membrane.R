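# Red-cell membrane geometry: material parameters, the biconcave resting
# shape on a subdivided icosahedral mesh (3D) and as a closed contour (2D).

#' Membrane material parameters
#'
#' Default values describe a normal healthy red cell: 2D shear elastic
#' modulus G_S = 5e-6 N/m, area-dilation modulus ratio C = 100 (a nearly
#' area-incompressible membrane), bending modulus 2e-19 J, and an
#' interior (hemoglobin) to exterior (plasma) viscosity ratio of 5
#' (0.006 vs 0.0012 Pa s). Stiffer cells are modelled by multiplying G_S,
#' conventionally by 10.
#'
#' @param Gs_N_m membrane shear elastic modulus in N/m.
#' @param C dimensionless area-dilation modulus ratio.
#' @param kappa_J bending modulus in J.
#' @param lambda_visc interior/exterior viscosity ratio.
#' @param mu_interior_Pa_s interior (hemoglobin) viscosity in Pa s.
#' @param stiffness_multiplier factor applied to `Gs_N_m` (10 for the
#'   standard stiffer-cell condition).
#' @return a `membrane_params` list with both SI and model-unit (um, ms, Pa)
#'   fields.
#' @examples
#' membrane_params()                       # normal cells
#' membrane_params(stiffness_multiplier = 10)  # stiffer cells
#' @export
membrane_params <- function(Gs_N_m = 5e-6, C = 100, kappa_J = 2e-19,
                            lambda_visc = 5, mu_interior_Pa_s = 0.006,
                            stiffness_multiplier = 1) {
  stopifnot(Gs_N_m > 0, C > 0, kappa_J > 0, lambda_visc > 0,
            mu_interior_Pa_s > 0, stiffness_multiplier > 0)
  structure(list(
    Gs_N_m = Gs_N_m * stiffness_multiplier, C = C, kappa_J = kappa_J,
    lambda_visc = lambda_visc, mu_interior_Pa_s = mu_interior_Pa_s,
    # model units: Pa*um for Gs (1 N/m = 1e6 Pa*um... careful: 1 N/m = 1 Pa*m
    # = 1e6 Pa*um; 5e-6 N/m = 5 Pa*um), Pa*um^3 for kappa (1 J = 1e18 Pa*um^3)
    Gs = Gs_N_m * stiffness_multiplier * 1e6,
    kappa = kappa_J * 1e18,
    mu_interior = Pa_s_to_model(mu_interior_Pa_s),
    mu_plasma = Pa_s_to_model(mu_interior_Pa_s / lambda_visc),
    stiffness_multiplier = stiffness_multiplier
  ), class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params> Gs =", x$Gs_N_m, "N/m (x", x$stiffness_multiplier,
      "), C =", x$C, ", kappa =", x$kappa_J, "J, viscosity ratio",
      x$lambda_visc, "\n")
  invisible(x)
}

# --- biconcave profile -----------------------------------------------------

# Evans-Fung thickness polynomial, in units of the cell radius R0:
# z(rho) = +-(1/2) sqrt(1-rho^2) (c0 + c1 rho^2 + c2 rho^4), rho = r/R0
.ef_c <- c(0.207161, 2.002558, -1.122762)

ef_halfheight <- function(rho) {
  rho2 <- rho * rho
  0.5 * sqrt(pmax(1 - rho2, 0)) * (.ef_c[1] + .ef_c[2] * rho2 +
                                     .ef_c[3] * rho2 * rho2)
}

# --- icosphere -------------------------------------------------------------

icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    midcache <- new.env()
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(midcache[[k]])) return(midcache[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      idx <- nv + length(newv)
      midcache[[k]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c3, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  list(vertices = v, faces = f)
}

#' Biconcave discocyte mesh
#'
#' Maps a subdivided icosahedron onto the Evans-Fung biconcave profile and
#' scales it so the maximum end-to-end vertex distance equals `end_to_end`.
#' The triangle count is 20 * 4^subdivisions (5120 at the default
#' refinement, giving the standard cell surface discretization).
#'
#' @param end_to_end resting cell end-to-end distance in um (default 7.8).
#' @param subdivisions icosahedron subdivision level (default 4).
#' @return a `membrane_mesh` with `vertices` (n x 3, um), `faces` (m x 3),
#'   `reference` vertices (resting shape) and dimension tag.
#' @examples
#' m <- make_biconcave()
#' nrow(m$faces)          # 5120
#' cell_length(m)         # 7.8
#' @export
make_biconcave <- function(end_to_end = 7.8, subdivisions = 4) {
  stopifnot(end_to_end > 0, subdivisions >= 0)
  ico <- icosphere(subdivisions)
  v <- ico$vertices
  rho <- sqrt(v[, 1]^2 + v[, 2]^2)
  z <- sign(v[, 3]) * ef_halfheight(pmin(rho, 1))
  # poles of the sphere (rho ~ 0) map to the dimples; equator to the rim
  bv <- cbind(v[, 1], v[, 2], z)
  # scale so max pairwise distance equals end_to_end (the rim diameter)
  dmax <- max_pairwise_distance(bv)
  bv <- bv * (end_to_end / dmax)
  new_membrane_mesh(bv, ico$faces)
}

new_membrane_mesh <- function(vertices, faces = NULL, reference = NULL) {
  dim2 <- is.null(faces)
  out <- structure(list(
    vertices = vertices, faces = faces,
    reference = if (is.null(reference)) vertices else reference,
    dim = if (dim2) 2L else 3L), class = "membrane_mesh")
  if (dim2) out$area0 <- abs(contour_area(out$reference))
  out
}

#' @export
print.membrane_mesh <- function(x, ...) {
  if (x$dim == 3L)
    cat("<membrane_mesh 3D> ", nrow(x$vertices), " vertices, ",
        nrow(x$faces), " triangles, length ",
        round(cell_length(x), 3), " um\n", sep = "")
  else
    cat("<membrane_mesh 2D> ", nrow(x$vertices), " contour nodes, length ",
        round(cell_length(x), 3), " um\n", sep = "")
  invisible(x)
}

max_pairwise_distance <- function(v) {
  # exact max over the convex extremes; for our sizes a full dist is fine
  if (nrow(v) <= 4000) return(max(stats::dist(v)))
  idx <- unique(c(which.max(v[, 1]), which.min(v[, 1]),
                  which.max(v[, 2]), which.min(v[, 2]),
                  if (ncol(v) > 2) c(which.max(v[, 3]), which.min(v[, 3]))))
  best <- 0
  for (i in idx) best <- max(best, sqrt(rowSums(sweep(v, 2, v[i, ])^2)))
  # refine once from the current farthest pair
  best
}

#' Cell length: maximum end-to-end distance
#'
#' @param mesh a `membrane_mesh` (2D or 3D), or a numeric matrix of vertex
#'   coordinates.
#' @return the maximum pairwise vertex distance in um.
#' @export
cell_length <- function(mesh) {
  v <- if (inherits(mesh, "membrane_mesh")) mesh$vertices else as.matrix(mesh)
  stopifnot(nrow(v) >= 2)
  max_pairwise_distance(v)
}

#' Biconcave cross-section contour (2D cell)
#'
#' The 2D flow core represents each cell by the cross-section of the
#' biconcave discocyte through its axis of symmetry, as a closed polygon
#' with equal reference arc spacing. The maximum chord equals `end_to_end`.
#'
#' @param end_to_end maximum chord in um (default 7.8).
#' @param n_nodes number of contour nodes (>= 16; default 48).
#' @return a 2D `membrane_mesh`.
#' @export
make_cell_contour_2d <- function(end_to_end = 7.8, n_nodes = 48) {
  stopifnot(n_nodes >= 16, end_to_end > 0)
  # dense parametric trace: upper branch left-to-right, lower back
  rho <- seq(-1, 1, length.out = 2001)
  up <- cbind(rho, ef_halfheight(abs(rho)))
  lo <- cbind(rev(rho), -ef_halfheight(abs(rev(rho))))
  p <- rbind(up, lo[-1, ])
  p <- p[-nrow(p), ] # drop duplicated closing point
  p <- resample_closed(p, spacing = polyline_length(rbind(p, p[1, ])) / n_nodes)
  # resample_closed targets spacing; force the node count exactly
  if (nrow(p) != n_nodes) {
    q <- rbind(p, p[1, ])
    el <- sqrt(rowSums(diff(q)^2)); s <- c(0, cumsum(el))
    si <- seq(0, s[length(s)], length.out = n_nodes + 1)[-(n_nodes + 1)]
    p <- cbind(stats::approx(s, q[, 1], si, ties = "ordered")$y,
               stats::approx(s, q[, 2], si, ties = "ordered")$y)
  }
  p <- p * (end_to_end / max_pairwise_distance(p))
  new_membrane_mesh(p)
}

# shoelace area of a closed 2D contour (positive if counter-clockwise)
contour_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  0.5 * sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])
}

contour_perimeter <- function(v) polyline_length(rbind(v, v[1, ]))
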