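# Immersed-boundary coupling: Peskin 4-point cosine kernel for spreading
# membrane forces to the staggered grid and interpolating grid velocities
# back to membrane nodes. The kernel forms an exact partition of unity, so
# interpolation reproduces constants and spreading conserves total force.

ib_phi <- function(rho) {
  w <- 0.25 * (1 + cos(pi * rho / 2))
  w[abs(rho) > 2] <- 0
  w
}

# 4x4 tensor-product stencil of each point in a component grid
ib_stencil <- function(xq, yq, xs, ys) {
  h <- xs[2] - xs[1]
  i0 <- floor((xq - xs[1]) / h) + 1
  j0 <- floor((yq - ys[1]) / h) + 1
  n <- length(xq)
  offs <- -1:2
  ii <- outer(i0, offs, `+`) # n x 4
  jj <- outer(j0, offs, `+`)
  wx <- ib_phi((xq - (xs[1] + (ii - 1) * h)) / h)
  wy <- ib_phi((yq - (ys[1] + (jj - 1) * h)) / h)
  list(ii = ii, jj = jj, wx = matrix(wx, n), wy = matrix(wy, n),
       nx = length(xs), ny = length(ys))
}

# accumulate w * val into a grid matrix (sparse scatter-add; duplicate
# indices are summed in compiled code by sparseMatrix)
ib_scatter <- function(stn, val, h) {
  nx <- stn$nx; ny <- stn$ny
  a16 <- rep(1:4, each = 4); b16 <- rep(1:4, times = 4)
  ii <- stn$ii[, a16, drop = FALSE]
  jj <- stn$jj[, b16, drop = FALSE]
  w <- stn$wx[, a16, drop = FALSE] * stn$wy[, b16, drop = FALSE] *
    (val / (h * h))
  ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & w != 0
  if (!any(ok)) return(matrix(0, nx, ny))
  idx <- ii[ok] + (jj[ok] - 1) * nx
  sv <- Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)), x = w[ok],
                             dims = c(nx * ny, 1))
  matrix(as.numeric(sv), nx, ny)
}

ib_gather <- function(stn, grid) {
  n <- nrow(stn$ii)
  out <- numeric(n)
  nx <- stn$nx; ny <- stn$ny
  for (a in 1:4) for (b in 1:4) {
    ii <- stn$ii[, a]; jj <- stn$jj[, b]
    ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
    w <- stn$wx[, a] * stn$wy[, b]
    val <- numeric(n)
    val[ok] <- grid[ii[ok] + (jj[ok] - 1) * nx]
    out <- out + w * val
  }
  out
}

#' Spread membrane forces to the grid / interpolate grid velocity to nodes
#'
#' `spread_forces` distributes per-node membrane forces (units Pa um: force
#' per unit depth) onto the staggered velocity grids as a body-force density
#' using the smoothed 4-point cosine delta. `interpolate_velocity` evaluates
#' the grid velocity at membrane nodes with the same kernel, making the two
#' operations adjoint.
#'
#' @param state an `rbc_fluid_state`.
#' @param X n x 2 matrix of membrane node positions (um).
#' @param F n x 2 matrix of nodal forces.
#' @return `spread_forces`: list `fx` ((nx+1) x ny) and `fy` (nx x (ny+1))
#'   force densities; `interpolate_velocity`: n x 2 matrix of velocities
#'   (um/ms).
#' @export
spread_forces <- function(state, X, F) {
  cu <- u_coords(state); cv <- v_coords(state)
  su <- ib_stencil(X[, 1], X[, 2], cu$x, cu$y)
  sv <- ib_stencil(X[, 1], X[, 2], cv$x, cv$y)
  list(fx = ib_scatter(su, F[, 1], state$h),
       fy = ib_scatter(sv, F[, 2], state$h))
}

#' @rdname spread_forces
#' @export
interpolate_velocity <- function(state, X) {
  cu <- u_coords(state); cv <- v_coords(state)
  su <- ib_stencil(X[, 1], X[, 2], cu$x, cu$y)
  sv <- ib_stencil(X[, 1], X[, 2], cv$x, cv$y)
  cbind(ib_gather(su, state$u), ib_gather(sv, state$v))
}
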