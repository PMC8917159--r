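# The flow core: unsteady Stokes with incremental pressure projection on the
# staggered grid, implicit constant-coefficient viscous operators (cached
# sparse LU), explicit variable-viscosity correction, ghost-node walls, and
# pressure / flow-rate port conditions.

# ---- boundary-condition resolution ---------------------------------------

port_nodes <- function(graph) {
  ids <- graph$nodes$id[graph$nodes$role %in% c("inlet", "outlet")]
  tibble::tibble(
    node_id = ids,
    x = graph$nodes$x[match(ids, graph$nodes$id)],
    y = graph$nodes$y[match(ids, graph$nodes$id)],
    role = graph$nodes$role[match(ids, graph$nodes$id)],
    kind = graph$bcs$kind[match(ids, graph$bcs$node_id)],
    value = graph$bcs$value[match(ids, graph$bcs$node_id)],
    diameter = vapply(ids, function(n) {
      k <- which(graph$segments$from == n | graph$segments$to == n)[1]
      graph$segments$diameter[k]
    }, numeric(1)))
}

#' Validate and resolve boundary conditions of a network
#'
#' Each inlet and outlet must carry exactly one condition, either a pressure
#' (mmHg) or a flow rate (nL/s). Flow-rate conditions are realized as a
#' prescribed parabolic inflow profile normalized to the exact per-depth
#' flux; pressure conditions as fixed pressures in port buffer cells. At
#' least one port must pin the pressure level unless a flow-rate inlet and a
#' pressure outlet are both present.
#'
#' @param graph an `rbc_network` with a `bcs` table.
#' @return tibble of resolved port conditions (node, kind, value, model-unit
#'   value).
#' @export
resolve_bcs <- function(graph) {
  pn <- port_nodes(graph)
  if (any(is.na(pn$kind)))
    stop("under-constrained boundary conditions: port node(s) ",
         paste(pn$node_id[is.na(pn$kind)], collapse = ", "), " lack a BC")
  dup <- graph$bcs$node_id[duplicated(graph$bcs$node_id)]
  if (length(dup))
    stop("over-constrained boundary conditions: node(s) ",
         paste(unique(dup), collapse = ", "), " carry multiple BCs")
  if (!any(pn$kind == "pressure"))
    stop("no pressure condition anywhere: pressure level undetermined")
  pn$value_model <- ifelse(pn$kind == "pressure", mmHg_to_Pa(pn$value),
                           nL_s_to_flux2d(pn$value, pn$diameter))
  pn
}

# ---- operator assembly ----------------------------------------------------

assemble_component <- function(cls, G, h, rho_dt, mu_imp, port) {
  nxf <- length(cls$x); nyf <- length(cls$y)
  ntot <- nxf * nyf
  typ <- as.vector(cls$type)
  typ[port$dir_idx] <- .PORT_D
  typ[port$neu_idx] <- .PORT_N
  ti <- list(); tj <- list(); tx <- list()
  push <- function(i, j, x) {
    k <- length(ti) + 1
    ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- x
  }
  fl <- which(typ == .FLUID)
  if (length(fl)) {
    i <- ((fl - 1) %% nxf) + 1
    j <- ((fl - 1) %/% nxf) + 1
    diag <- rep(rho_dt, length(fl))
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + d[1]; nj <- j + d[2]
      ok <- ni >= 1 & ni <= nxf & nj >= 1 & nj <= nyf
      nb <- ni[ok] + (nj[ok] - 1) * nxf
      push(fl[ok], nb, rep(-mu_imp / h^2, length(nb)))
      diag[ok] <- diag[ok] + mu_imp / h^2
    }
    push(fl, fl, diag)
  }
  gh <- which(typ == .GHOST)
  if (length(gh)) {
    push(gh, gh, rep(1, length(gh)))
    Gsub <- G[gh, , drop = FALSE]
    sm <- Matrix::summary(Gsub)
    if (nrow(sm)) push(gh[sm$i], sm$j, -sm$x)
  }
  oth <- which(typ %in% c(.FAR, .PORT_D))
  if (length(oth)) push(oth, oth, rep(1, length(oth)))
  pn <- port$neu_idx
  if (length(pn)) {
    push(pn, pn, rep(1, length(pn)))
    push(pn, port$neu_inner, rep(-1, length(pn)))
  }
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(ntot, ntot))
  list(A = A, lu = Matrix::lu(A), typ = typ)
}

# identify port faces of one component on the domain boundary and attach
# them to the nearest port node
component_ports <- function(cls, which, st, pn) {
  nxf <- length(cls$x); nyf <- length(cls$y)
  typ <- cls$type
  if (which == "u") {
    bidx <- c(which(typ[1, ] == .FLUID) * nxf - nxf + 1,
              which(typ[nxf, ] == .FLUID) * nxf)
  } else {
    bidx <- c(which(typ[, 1] == .FLUID),
              (which(typ[, nyf] == .FLUID)) + (nyf - 1) * nxf)
  }
  if (!length(bidx))
    return(list(dir_idx = integer(0), dir_val = numeric(0),
                neu_idx = integer(0), neu_inner = integer(0)))
  bi <- ((bidx - 1) %% nxf) + 1
  bj <- ((bidx - 1) %/% nxf) + 1
  px <- cls$x[bi]; py <- cls$y[bj]
  near <- vapply(seq_along(bidx), function(k)
    which.min((pn$x - px[k])^2 + (pn$y - py[k])^2), integer(1))
  inward <- if (which == "u") ifelse(bi == 1, 1, -1) else
    ifelse(bj == 1, 1, -1)
  inner <- if (which == "u") ifelse(bi == 1, bidx + 1, bidx - 1) else
    ifelse(bj == 1, bidx + nxf, bidx - nxf)
  isQ <- pn$kind[near] == "flow_rate"
  dir_idx <- bidx[isQ]; neu_idx <- bidx[!isQ]; neu_inner <- inner[!isQ]
  dir_val <- numeric(length(dir_idx))
  if (length(dir_idx)) {
    # parabolic profile per port, normalized to the exact per-depth flux
    for (nid in unique(near[isQ])) {
      sel <- which(near == nid & isQ)
      f <- bidx[sel]
      tcoord <- if (which == "u") cls$y[((f - 1) %/% nxf) + 1] else
        cls$x[((f - 1) %% nxf) + 1]
      t0 <- min(tcoord) - st$h / 2; t1 <- max(tcoord) + st$h / 2
      prof <- (tcoord - t0) * (t1 - tcoord)
      q <- pn$value_model[nid]
      sgn <- inward[sel]
      scale <- q / (sum(prof) * st$h)
      dir_val[match(f, dir_idx)] <- sgn * prof * scale
    }
  }
  list(dir_idx = dir_idx, dir_val = dir_val,
       neu_idx = neu_idx, neu_inner = neu_inner, near = near, bidx = bidx)
}

assemble_poisson <- function(st, pn) {
  nx <- st$nx; ny <- st$ny
  pc <- p_coords(st)
  phi <- matrix(st$sdf(grid_points(pc$x, pc$y)), nx, ny)
  ptype <- matrix(0L, nx, ny) # 0 ext, 1 lumen, 2 dirichlet
  ptype[phi < 0] <- 1L
  # pressure-port buffer cells: lumen cells in the outermost two rings close
  # to a pressure port
  bdist <- pmin(pmin(row(ptype), nx + 1 - row(ptype)),
                pmin(col(ptype), ny + 1 - col(ptype)))
  cand <- which(ptype == 1L & bdist <= 2)
  pval <- matrix(0, nx, ny)
  if (length(cand)) {
    ci <- ((cand - 1) %% nx) + 1; cj <- ((cand - 1) %/% nx) + 1
    near <- vapply(seq_along(cand), function(k)
      which.min((pn$x - pc$x[ci[k]])^2 + (pn$y - pc$y[cj[k]])^2), integer(1))
    isP <- pn$kind[near] == "pressure"
    ptype[cand[isP]] <- 2L
    pval[cand[isP]] <- pn$value_model[near[isP]]
  }
  if (!any(ptype == 2L)) { # closed box: pin the gauge at one reference cell
    ptype[which(ptype == 1L)[1]] <- 2L
  }
  typ <- as.vector(ptype)
  ti <- list(); tj <- list(); tx <- list()
  push <- function(i, j, x) {
    k <- length(ti) + 1; ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- x
  }
  lum <- which(typ == 1L)
  h <- st$h
  if (length(lum)) {
    i <- ((lum - 1) %% nx) + 1; j <- ((lum - 1) %/% nx) + 1
    diag <- rep(0, length(lum))
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + d[1]; nj <- j + d[2]
      ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny
      nb <- ni + (nj - 1) * nx
      ok[ok] <- typ[nb[ok]] != 0L # exterior neighbor: homogeneous Neumann
      nb <- nb[ok]
      push(lum[ok], nb, rep(-1 / h^2, length(nb)))
      diag[ok] <- diag[ok] + 1 / h^2
    }
    # guard fully isolated cells
    diag[diag == 0] <- 1
    push(lum, lum, diag)
  }
  oth <- which(typ != 1L)
  if (length(oth)) push(oth, oth, rep(1, length(oth)))
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(nx * ny, nx * ny))
  list(A = A, lu = Matrix::lu(A), ptype = ptype, pval = pval)
}

# ---- solver preparation ---------------------------------------------------

#' Prepare cached solver operators on a fluid state
#'
#' Classifies faces, builds ghost-node closures and the implicit viscous and
#' projection operators for a fixed time step, and initializes the pressure
#' field from the port conditions. Must be called before stepping;
#' [run_simulation()] does this internally.
#'
#' @param state an `rbc_fluid_state`.
#' @param dt time step in ms.
#' @param mu_imp implicit viscosity (defaults to the cell-interior value,
#'   the largest in the domain, which makes the explicit variable-viscosity
#'   correction unconditionally stable).
#' @param reset_pressure initialize the pressure from the port conditions
#'   (set `FALSE` to keep an already-developed field when re-preparing with
#'   a new time step).
#' @return the state with an `ops` element attached.
#' @export
prepare_solver <- function(state, dt, mu_imp = .rbc_const$mu_interior,
                           reset_pressure = TRUE) {
  st <- state
  pn <- resolve_bcs(st$graph)
  cls_u <- classify_faces(st, "u")
  cls_v <- classify_faces(st, "v")
  Gu <- ghost_matrix(cls_u, st$sdf, st$h)
  Gv <- ghost_matrix(cls_v, st$sdf, st$h)
  pu <- component_ports(cls_u, "u", st, pn)
  pv <- component_ports(cls_v, "v", st, pn)
  rho_dt <- .rbc_const$rho / dt
  Au <- assemble_component(cls_u, Gu$G, st$h, rho_dt, mu_imp, pu)
  Av <- assemble_component(cls_v, Gv$G, st$h, rho_dt, mu_imp, pv)
  Ap <- assemble_poisson(st, pn)
  # grid-sampled signed distance (p centers) for fast per-step queries
  pc <- p_coords(st)
  phi_grid <- matrix(st$sdf(grid_points(pc$x, pc$y)), st$nx, st$ny)
  gx <- matrix(0, st$nx, st$ny); gy <- matrix(0, st$nx, st$ny)
  gx[2:(st$nx - 1), ] <- (phi_grid[-(1:2), ] -
                            phi_grid[1:(st$nx - 2), ]) / (2 * st$h)
  gy[, 2:(st$ny - 1)] <- (phi_grid[, -(1:2)] -
                            phi_grid[, 1:(st$ny - 2)]) / (2 * st$h)
  st$ops <- list(dt = dt, mu_imp = mu_imp, pn = pn,
                 cls_u = cls_u, cls_v = cls_v, Gu = Gu, Gv = Gv,
                 pu = pu, pv = pv, Au = Au, Av = Av, Ap = Ap,
                 fluid_u = Au$typ == .FLUID, fluid_v = Av$typ == .FLUID,
                 phi_grid = phi_grid, phi_gx = gx, phi_gy = gy,
                 pxs = pc$x, pys = pc$y)
  if (reset_pressure) {
    # initialize pressure: port values in buffers, harmonic fill inside
    rhs <- as.vector(Ap$pval)
    rhs[as.vector(Ap$ptype) == 1L] <- 0
    p0 <- Matrix::solve(Ap$lu, rhs)
    st$p <- matrix(as.numeric(p0), st$nx, st$ny)
  }
  st
}

# ---- exported elemental operations ---------------------------------------

#' Enforce no-slip walls via the ghost-node closure
#'
#' Sets every ghost face value from its wall-mirrored fluid sample so that
#' linear interpolation along the wall normal vanishes exactly at the wall.
#'
#' @param state a prepared `rbc_fluid_state`.
#' @param walls unused placeholder for API symmetry (the state carries its
#'   geometry); may be `NULL`.
#' @return the state with updated ghost values.
#' @export
enforce_walls <- function(state, walls = NULL) {
  ops <- state$ops
  if (is.null(ops)) stop("state not prepared; call prepare_solver() first")
  uvec <- as.vector(state$u)
  gh <- which(ops$Au$typ == .GHOST)
  if (length(gh)) uvec[gh] <- as.numeric(ops$Gu$G %*% uvec)[gh]
  state$u <- matrix(uvec, state$nx + 1, state$ny)
  vvec <- as.vector(state$v)
  gh <- which(ops$Av$typ == .GHOST)
  if (length(gh)) vvec[gh] <- as.numeric(ops$Gv$G %*% vvec)[gh]
  state$v <- matrix(vvec, state$nx, state$ny + 1)
  state
}

#' Wall-sampled velocity magnitude
#'
#' The ghost-node method represents the velocity across the wall as the
#' linear interpolant along each ghost's inward normal between the ghost
#' value and its fluid probe; the wall value of that interpolant is the
#' method's wall velocity. This function evaluates it at every ghost foot
#' point, giving the no-slip constraint residual.
#'
#' @param state a prepared `rbc_fluid_state`.
#' @param walls unused; the state's geometry is authoritative.
#' @return numeric vector of wall-point speeds (um/ms), one per ghost node.
#' @export
wall_speed <- function(state, walls = NULL) {
  ops <- state$ops
  out <- numeric(0)
  for (comp in c("u", "v")) {
    gm <- if (comp == "u") ops$Gu else ops$Gv
    vec <- if (comp == "u") as.vector(state$u) else as.vector(state$v)
    if (!length(gm$gidx)) next
    us <- as.numeric(gm$S %*% vec)[gm$gidx]
    ug <- vec[gm$gidx]
    w <- gm$phi / pmax(gm$phi + gm$ds, 1e-12)
    out <- c(out, abs(ug + w * (us - ug)))
  }
  out
}

#' Project the velocity field to discrete divergence-free
#'
#' Solves the pressure-correction Poisson problem with homogeneous Neumann
#' walls and port gauge conditions, corrects the face velocities, and
#' accumulates the correction into the pressure (incremental projection).
#'
#' @param state a prepared `rbc_fluid_state`.
#' @return the state with divergence-free lumen velocity.
#' @export
project_velocity <- function(state) {
  ops <- state$ops
  if (is.null(ops)) stop("state not prepared; call prepare_solver() first")
  nx <- state$nx; ny <- state$ny; h <- state$h
  div <- (state$u[-1, , drop = FALSE] - state$u[-(nx + 1), , drop = FALSE] +
            state$v[, -1, drop = FALSE] - state$v[, -(ny + 1), drop = FALSE]) / h
  # assembled operator is -laplacian, so solve (-lap) phi = -(rho/dt) div
  rhs <- -as.vector(div) * (.rbc_const$rho / ops$dt)
  rhs[as.vector(ops$Ap$ptype) != 1L] <- 0
  phi <- matrix(as.numeric(Matrix::solve(ops$Ap$lu, rhs)), nx, ny)
  # mirror phi into exterior cells (Neumann closure), then correct faces
  ext <- ops$Ap$ptype == 0L
  cdt <- ops$dt / .rbc_const$rho
  # u faces: between cells (i-1,j) and (i,j) for i = 2..nx
  phL <- phi[-nx, , drop = FALSE]; phR <- phi[-1, , drop = FALSE]
  extL <- ext[-nx, , drop = FALSE]; extR <- ext[-1, , drop = FALSE]
  gradx <- (phR - phL) / h
  gradx[extL | extR] <- 0
  du <- matrix(0, nx + 1, ny)
  du[2:nx, ] <- gradx
  phB <- phi[, -ny, drop = FALSE]; phT <- phi[, -1, drop = FALSE]
  extB <- ext[, -ny, drop = FALSE]; extT <- ext[, -1, drop = FALSE]
  grady <- (phT - phB) / h
  grady[extB | extT] <- 0
  dv <- matrix(0, nx, ny + 1)
  dv[, 2:ny] <- grady
  fu <- matrix(ops$fluid_u, nx + 1, ny)
  fv <- matrix(ops$fluid_v, nx, ny + 1)
  state$u[fu] <- state$u[fu] - cdt * du[fu]
  state$v[fv] <- state$v[fv] - cdt * dv[fv]
  lum <- ops$Ap$ptype == 1L
  state$p[lum] <- state$p[lum] + phi[lum]
  state <- enforce_port_neumann(state)
  enforce_walls(state)
}

enforce_port_neumann <- function(state) {
  ops <- state$ops
  uvec <- as.vector(state$u)
  if (length(ops$pu$neu_idx))
    uvec[ops$pu$neu_idx] <- uvec[ops$pu$neu_inner]
  if (length(ops$pu$dir_idx))
    uvec[ops$pu$dir_idx] <- ops$pu$dir_val
  state$u <- matrix(uvec, state$nx + 1, state$ny)
  vvec <- as.vector(state$v)
  if (length(ops$pv$neu_idx))
    vvec[ops$pv$neu_idx] <- vvec[ops$pv$neu_inner]
  if (length(ops$pv$dir_idx))
    vvec[ops$pv$dir_idx] <- ops$pv$dir_val
  state$v <- matrix(vvec, state$nx, state$ny + 1)
  state
}

# explicit part of the viscous stress: div((mu_imp - mu) grad u) per
# component, with the deficit viscosity interpolated to the needed locations
viscous_correction <- function(state, mu_imp) {
  nx <- state$nx; ny <- state$ny; h <- state$h
  mud <- mu_imp - state$mu # >= 0 everywhere
  # pad by edge replication
  pad <- function(m) {
    m2 <- rbind(m[1, ], m, m[nrow(m), ])
    cbind(m2[, 1], m2, m2[, ncol(m2)])
  }
  mp <- pad(mud) # (nx+2) x (ny+2), cell centers with 1-ring pad
  # u component: x-fluxes at cell centers, y-fluxes at corners
  u <- state$u
  cu <- matrix(0, nx + 1, ny)
  # d/dx (mud du/dx): du/dx at cell centers (i=1..nx): (u[i+1,]-u[i,])/h
  dudx <- (u[-1, , drop = FALSE] - u[-(nx + 1), , drop = FALSE]) / h
  fxx <- mud * dudx # nx x ny
  cu[2:nx, ] <- (fxx[-1, , drop = FALSE] - fxx[-nx, , drop = FALSE]) / h
  # d/dy (mud du/dy): du/dy at horizontal edges between rows
  mu_corner <- (mp[1:(nx + 1), 1:(ny + 1)] + mp[2:(nx + 2), 1:(ny + 1)] +
                  mp[1:(nx + 1), 2:(ny + 2)] + mp[2:(nx + 2), 2:(ny + 2)]) / 4
  dudy <- (u[, -1, drop = FALSE] - u[, -ny, drop = FALSE]) / h # (nx+1) x (ny-1)
  fyy <- mu_corner[, 2:ny] * dudy
  cu[, 2:(ny - 1)] <- (fyy[, -1, drop = FALSE] - fyy[, -(ny - 1), drop = FALSE]) / h
  # v component
  v <- state$v
  cv <- matrix(0, nx, ny + 1)
  dvdy <- (v[, -1, drop = FALSE] - v[, -(ny + 1), drop = FALSE]) / h # nx x ny
  fy2 <- mud * dvdy
  cv[, 2:ny] <- (fy2[, -1, drop = FALSE] - fy2[, -ny, drop = FALSE]) / h
  dvdx <- (v[-1, , drop = FALSE] - v[-nx, , drop = FALSE]) / h # (nx-1) x (ny+1)
  fx2 <- mu_corner[2:nx, ] * dvdx
  cv[2:(nx - 1), ] <- (fx2[-1, , drop = FALSE] - fx2[-(nx - 1), , drop = FALSE]) / h
  list(cu = cu, cv = cv)
}

#' Update the two-fluid viscosity indicator
#'
#' Sets the cell-centered viscosity to the interior (hemoglobin) value
#' inside every cell contour and the plasma value outside, smoothed over
#' about two grid cells via a smoothed Heaviside of the signed distance to
#' each contour.
#'
#' @param state an `rbc_fluid_state`.
#' @param cells list of 2D `membrane_mesh` objects.
#' @param params a [membrane_params()]; supplies the two viscosities.
#' @return the state with an updated `mu` field.
#' @export
update_viscosity_indicator <- function(state, cells,
                                       params = membrane_params()) {
  nx <- state$nx; ny <- state$ny; h <- state$h
  pc <- p_coords(state)
  chi <- matrix(0, nx, ny)
  eps <- h
  for (cell in cells) {
    V <- cell$vertices
    i0 <- max(1, floor((min(V[, 1]) - 2 * eps - pc$x[1]) / h) + 1)
    i1 <- min(nx, ceiling((max(V[, 1]) + 2 * eps - pc$x[1]) / h) + 1)
    j0 <- max(1, floor((min(V[, 2]) - 2 * eps - pc$y[1]) / h) + 1)
    j1 <- min(ny, ceiling((max(V[, 2]) + 2 * eps - pc$y[1]) / h) + 1)
    if (i0 > i1 || j0 > j1) next
    xs <- pc$x[i0:i1]; ys <- pc$y[j0:j1]
    pts <- grid_points(xs, ys)
    d <- point_polyline_distance(pts, rbind(V, V[1, ]))
    inside <- point_in_polygon(pts, V)
    sd <- ifelse(inside, -d, d)
    loc <- smoothed_heaviside(-sd, eps)
    chi[i0:i1, j0:j1] <- pmax(chi[i0:i1, j0:j1],
                              matrix(loc, length(xs), length(ys)))
  }
  state$mu <- params$mu_plasma + (params$mu_interior - params$mu_plasma) * chi
  state
}

smoothed_heaviside <- function(z, eps) {
  out <- numeric(length(z))
  out[z >= eps] <- 1
  mid <- abs(z) < eps
  zz <- z[mid] / eps
  out[mid] <- 0.5 * (1 + zz + sin(pi * zz) / pi)
  out
}

point_in_polygon <- function(pts, V) {
  n <- nrow(V)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- V[i, 1]; yi <- V[i, 2]; xj <- V[j, 1]; yj <- V[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# ---- one time step --------------------------------------------------------

step_fluid <- function(state, cells, params, k_area = NULL) {
  ops <- state$ops
  nx <- state$nx; ny <- state$ny; h <- state$h
  rho_dt <- .rbc_const$rho / ops$dt
  if (is.null(k_area)) k_area <- params$Gs * 0.5
  # membrane forces
  fx <- matrix(0, nx + 1, ny); fy <- matrix(0, nx, ny + 1)
  area_err <- 0
  if (length(cells)) {
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      fe <- skalak_forces(cell, params)
      fb <- contour_bending_forces(cell, params)
      fa <- contour_area_penalty(cell, k_area)
      fw <- wall_repulsion(state, cell$vertices, params)
      area_err <- max(area_err, abs(fa$err))
      Fn <- fe$forces + fb$forces + fa$forces + fw
      sp <- spread_forces(state, cell$vertices, Fn)
      fx <- fx + sp$fx; fy <- fy + sp$fy
    }
  }
  corr <- viscous_correction(state, ops$mu_imp)
  # pressure gradient at faces (Neumann across exterior cells)
  ext <- ops$Ap$ptype == 0L
  dpx <- matrix(0, nx + 1, ny)
  gx <- (state$p[-1, , drop = FALSE] - state$p[-nx, , drop = FALSE]) / h
  gx[ext[-nx, , drop = FALSE] | ext[-1, , drop = FALSE]] <- 0
  dpx[2:nx, ] <- gx
  dpy <- matrix(0, nx, ny + 1)
  gy <- (state$p[, -1, drop = FALSE] - state$p[, -ny, drop = FALSE]) / h
  gy[ext[, -ny, drop = FALSE] | ext[, -1, drop = FALSE]] <- 0
  dpy[, 2:ny] <- gy
  # viscous splitting: mu L u = mu_imp L u (implicit) + (mu - mu_imp) L u
  # (explicit); the explicit part is minus the deficit-viscosity flux
  rhs_u <- rho_dt * as.vector(state$u) + as.vector(fx) - as.vector(corr$cu) -
    as.vector(dpx)
  rhs_v <- rho_dt * as.vector(state$v) + as.vector(fy) - as.vector(corr$cv) -
    as.vector(dpy)
  tu <- ops$Au$typ; tv <- ops$Av$typ
  rhs_u[tu != .FLUID] <- 0
  rhs_u[tu == .PORT_D] <- ops$pu$dir_val[match(which(tu == .PORT_D),
                                               ops$pu$dir_idx)]
  rhs_v[tv != .FLUID] <- 0
  rhs_v[tv == .PORT_D] <- ops$pv$dir_val[match(which(tv == .PORT_D),
                                               ops$pv$dir_idx)]
  state$u <- matrix(as.numeric(Matrix::solve(ops$Au$lu, rhs_u)), nx + 1, ny)
  state$v <- matrix(as.numeric(Matrix::solve(ops$Av$lu, rhs_v)), nx, ny + 1)
  state <- project_velocity(state)
  state$time <- state$time + ops$dt
  # advect membranes; then restore each contour's enclosed area by an
  # isotropic rescale about the centroid (hard per-step constraint: the
  # interpolated immersed-boundary velocity is not exactly
  # divergence-free, and under-resolved lubrication films during wall
  # squeeze would otherwise deflate the cell)
  if (length(cells)) {
    for (ci in seq_along(cells)) {
      U <- interpolate_velocity(state, cells[[ci]]$vertices)
      V <- cells[[ci]]$vertices + ops$dt * U
      A0 <- cells[[ci]]$area0 %||% abs(contour_area(cells[[ci]]$reference))
      A <- abs(contour_area(V))
      s <- sqrt(A0 / A)
      ctr <- colMeans(V)
      cells[[ci]]$vertices <- sweep(sweep(V, 2, ctr) * s, 2, ctr, "+")
    }
  }
  list(state = state, cells = cells, area_err = area_err)
}

# short-range wall repulsion: membrane nodes approaching the ghost band are
# pushed back along the inward wall normal, preventing contour collapse
# against the mirrored no-slip velocities inside the band
wall_repulsion <- function(state, X, params, range_h = 1.0) {
  ops <- state$ops
  bw <- bilinear_weights(X[, 1], X[, 2], ops$pxs, ops$pys)
  interp <- function(gr) {
    v <- as.vector(gr)
    rowSums(matrix(v[bw$idx], nrow(X)) * bw$w)
  }
  d <- interp(ops$phi_grid)
  act <- d > -range_h * state$h
  F <- matrix(0, nrow(X), 2)
  if (!any(act)) return(F)
  gx <- interp(ops$phi_gx)[act]; gy <- interp(ops$phi_gy)[act]
  gn <- pmax(sqrt(gx^2 + gy^2), 1e-9)
  w <- (d[act] + range_h * state$h) / (range_h * state$h)
  F[act, ] <- -1.5 * params$Gs * w * cbind(gx / gn, gy / gn)
  F
}

# stable time step from the membrane stiffness scales
membrane_stable_dt <- function(params, h, ds, safety = 0.35) {
  mu <- params$mu_plasma
  dt_t <- mu * min(h, ds) / params$Gs
  dt_b <- mu * ds^3 / (params$kappa * pi^3)
  dt_a <- dt_t # area penalty scales with Gs
  min(0.02, safety * min(dt_t, dt_b, dt_a))
}
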