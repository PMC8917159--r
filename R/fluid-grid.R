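# Staggered (MAC) grid fluid state and the cached linear operators of the
# flow core: implicit constant-coefficient viscous Helmholtz operators per
# velocity component with sharp-interface ghost-node wall closure, and the
# pressure-projection Poisson operator. Geometry-dependent matrices are
# assembled and factorized once per run; the variable-viscosity part of the
# stress divergence is applied explicitly (its coefficient never exceeds the
# implicit one, which keeps the splitting unconditionally stable).

# face/center type codes
.FAR <- 0L; .FLUID <- 1L; .GHOST <- 2L; .PORT_D <- 3L; .PORT_N <- 4L

#' Construct a fluid state on a staggered grid
#'
#' Builds face-centered velocity fields, cell-centered pressure and
#' viscosity, and the inside/outside classification against the vessel
#' walls. Port segments are extended beyond the domain boundary so inlets
#' and outlets are open cross-sections.
#'
#' @param graph an `rbc_network`.
#' @param h grid spacing in um.
#' @param margin extra space around the lumen bounding box (um).
#' @return an `rbc_fluid_state` (list with u, v, p, mu fields and grid
#'   metadata).
#' @export
fluid_state <- function(graph, h, margin = 4) {
  ext <- extend_ports(graph, margin + 40)
  sdf <- network_sdf(ext, blend = 1.5)
  allpts <- do.call(rbind, graph$segments$centerline)
  rmax <- max(graph$segments$diameter) / 2
  x0 <- min(allpts[, 1]); x1 <- max(allpts[, 1])
  y0 <- min(allpts[, 2]) - rmax - margin
  y1 <- max(allpts[, 2]) + rmax + margin
  # port nodes sit on the x extremes; clip the domain to the port planes so
  # the extended stubs cross the boundary there
  nx <- ceiling((x1 - x0) / h); ny <- ceiling((y1 - y0) / h)
  st <- list(h = h, nx = nx, ny = ny, x0 = x0, y0 = y0, time = 0,
             u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1),
             p = matrix(0, nx, ny), mu = matrix(.rbc_const$mu_plasma, nx, ny),
             sdf = sdf, graph = graph)
  class(st) <- "rbc_fluid_state"
  st
}

#' @export
print.rbc_fluid_state <- function(x, ...) {
  cat("<rbc_fluid_state> ", x$nx, "x", x$ny, " cells, h = ", x$h,
      " um, t = ", round(x$time, 3), " ms\n", sep = "")
  invisible(x)
}

# extend centerlines of port segments straight outward so the capsule caps
# fall outside the computational domain (ports become open sections)
extend_ports <- function(graph, ext_len) {
  g <- graph
  for (k in seq_len(nrow(g$segments))) {
    cl <- g$segments$centerline[[k]]
    fr <- g$segments$from[k]; to <- g$segments$to[k]
    if (g$nodes$role[fr] %in% c("inlet", "outlet")) {
      d <- cl[1, ] - cl[2, ]; d <- d / sqrt(sum(d^2))
      cl <- rbind(cl[1, ] + d * ext_len, cl)
    }
    if (g$nodes$role[to] %in% c("inlet", "outlet")) {
      d <- cl[nrow(cl), ] - cl[nrow(cl) - 1, ]; d <- d / sqrt(sum(d^2))
      cl <- rbind(cl, cl[nrow(cl), ] + d * ext_len)
    }
    g$segments$centerline[[k]] <- cl
  }
  g$segments$arclength <- vapply(g$segments$centerline, polyline_length,
                                 numeric(1))
  g
}

u_coords <- function(st) {
  list(x = st$x0 + (0:st$nx) * st$h,
       y = st$y0 + ((1:st$ny) - 0.5) * st$h)
}
v_coords <- function(st) {
  list(x = st$x0 + ((1:st$nx) - 0.5) * st$h,
       y = st$y0 + (0:st$ny) * st$h)
}
p_coords <- function(st) {
  list(x = st$x0 + ((1:st$nx) - 0.5) * st$h,
       y = st$y0 + ((1:st$ny) - 0.5) * st$h)
}

grid_points <- function(xs, ys) {
  cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
}

# classify one staggered component; returns type matrix and sdf values
classify_faces <- function(st, which = c("u", "v")) {
  which <- match.arg(which)
  co <- if (which == "u") u_coords(st) else v_coords(st)
  pts <- grid_points(co$x, co$y)
  phi <- st$sdf(pts)
  nxf <- length(co$x); nyf <- length(co$y)
  phim <- matrix(phi, nxf, nyf)
  type <- matrix(.FAR, nxf, nyf)
  type[phim < 0] <- .FLUID
  # ghost: exterior within 1.6 h of the wall and touching a fluid face
  fl <- phim < 0
  nb <- matrix(FALSE, nxf, nyf)
  nb[-1, ] <- nb[-1, ] | fl[-nxf, ]
  nb[-nxf, ] <- nb[-nxf, ] | fl[-1, ]
  nb[, -1] <- nb[, -1] | fl[, -nyf]
  nb[, -nyf] <- nb[, -nyf] | fl[, -1]
  gh <- !fl & nb & phim < 1.6 * st$h
  type[gh] <- .GHOST
  list(type = type, phi = phim, x = co$x, y = co$y)
}

# bilinear interpolation weights of points into a component grid;
# returns (index, weight) pairs, 4 per point
bilinear_weights <- function(xq, yq, xs, ys) {
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]
  i <- pmin(pmax(floor((xq - xs[1]) / hx) + 1, 1), length(xs) - 1)
  j <- pmin(pmax(floor((yq - ys[1]) / hy) + 1, 1), length(ys) - 1)
  tx <- (xq - xs[i]) / hx; ty <- (yq - ys[j]) / hy
  n <- length(xq); nxf <- length(xs)
  idx <- cbind(i + (j - 1) * nxf, i + 1 + (j - 1) * nxf,
               i + j * nxf, i + 1 + j * nxf)
  w <- cbind((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  list(idx = idx, w = w)
}

# sdf outward normal by central differences
sdf_normal <- function(sdf, pts, eps = 1e-3) {
  gx <- (sdf(cbind(pts[, 1] + eps, pts[, 2])) -
           sdf(cbind(pts[, 1] - eps, pts[, 2]))) / (2 * eps)
  gy <- (sdf(cbind(pts[, 1], pts[, 2] + eps)) -
           sdf(cbind(pts[, 1], pts[, 2] - eps))) / (2 * eps)
  gn <- pmax(sqrt(gx^2 + gy^2), 1e-9)
  cbind(gx / gn, gy / gn)
}

# ghost closure for one component. u[ghost] = G %*% u with
# G = -(phi/ds) * S, S the bilinear sampling of the fluid point one probe
# length inside the wall foot; linear interpolation between the ghost node
# and its probe then vanishes exactly at the wall.
ghost_matrix <- function(cls, sdf, h) {
  gidx0 <- which(cls$type == .GHOST)
  nxf <- length(cls$x); nyf <- length(cls$y)
  ntot <- nxf * nyf
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(ntot, ntot))
  if (!length(gidx0))
    return(list(G = empty, S = empty, gidx = integer(0),
                phi = numeric(0), ds = numeric(0)))
  gidx <- gidx0
  gi <- ((gidx - 1) %% nxf) + 1
  gj <- ((gidx - 1) %/% nxf) + 1
  gx <- cls$x[gi]; gy <- cls$y[gj]
  phi <- cls$phi[gidx]
  nrm <- sdf_normal(sdf, cbind(gx, gy))
  si <- integer(0); sj <- integer(0); sx_ <- numeric(0)
  coef_of <- numeric(ntot); ds_of <- numeric(ntot); phi_of <- numeric(ntot)
  fluid <- cls$type == .FLUID
  for (try in 1:3) {
    if (!length(gidx)) break
    ds <- pmax(1.2 * h, phi) + (try - 1) * h
    sxq <- gx - (phi + ds) * nrm[, 1]
    syq <- gy - (phi + ds) * nrm[, 2]
    bw <- bilinear_weights(sxq, syq, cls$x, cls$y)
    ok <- vapply(seq_along(gidx), function(k)
      all(fluid[bw$idx[k, ]] | bw$w[k, ] < 1e-12), logical(1))
    if (any(ok)) {
      kk <- which(ok)
      si <- c(si, rep(gidx[kk], 4))
      sj <- c(sj, as.vector(bw$idx[kk, , drop = FALSE]))
      sx_ <- c(sx_, as.vector(bw$w[kk, , drop = FALSE]))
      ds_of[gidx[kk]] <- ds[kk]; phi_of[gidx[kk]] <- phi[kk]
    }
    keep <- !ok
    gidx <- gidx[keep]; gx <- gx[keep]; gy <- gy[keep]; phi <- phi[keep]
    nrm <- nrm[keep, , drop = FALSE]
  }
  keepnz <- abs(sx_) > 1e-14
  S <- Matrix::sparseMatrix(i = si[keepnz], j = sj[keepnz], x = sx_[keepnz],
                            dims = c(ntot, ntot))
  coef <- -(phi_of / pmax(ds_of, 1e-12))
  G <- Matrix::Diagonal(ntot, coef) %*% S
  list(G = G, S = S, gidx = gidx0, phi = phi_of[gidx0], ds = ds_of[gidx0])
}
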