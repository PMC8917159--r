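# Inlet cell seeding. Insertion times follow a Poisson-like renewal process
# whose rate is calibrated so that the time-averaged tube hematocrit (cell
# area fraction) at the inlet cross-section converges to the target;
# lateral offsets are randomized over the admissible band. The same schedule
# drives both the kinematic inlet measurement and the flow solver.

inlet_info <- function(graph) {
  pn <- resolve_bcs(graph)
  inl <- pn[pn$role == "inlet", ][1, ]
  seg <- which(graph$segments$from == inl$node_id |
                 graph$segments$to == inl$node_id)[1]
  cl <- graph$segments$centerline[[seg]]
  if (graph$segments$to[seg] == inl$node_id) cl <- cl[rev(seq_len(nrow(cl))), ]
  dirv <- cl[2, ] - cl[1, ]; dirv <- dirv / sqrt(sum(dirv^2))
  list(node = inl, segment = seg, origin = cl[1, ], dir = dirv,
       width = graph$segments$diameter[seg])
}

# mean axial speed at lateral offset y in a channel of width w carrying
# per-depth flux q (blunted parabola; cells ride near the local mean)
lane_speed <- function(y, w, q) {
  pmax(1.5 * (q / w) * (1 - (2 * y / w)^2), 1e-6)
}

#' Inlet seeding schedule
#'
#' Generates cell insertion times and lateral offsets at the feeding vessel
#' so that the running time-averaged inlet tube hematocrit converges to the
#' target. The arrival rate is the exact renewal-theory calibration
#' r = H w / (A_cell E\[1/v\]) for cells advected at their lane speed;
#' insertions that would overlap the previously inserted cell are delayed
#' (never dropped). Deterministic for a fixed seed.
#'
#' @param graph an `rbc_network` (the first inlet is seeded).
#' @param target_hct target tube hematocrit (area fraction), default 0.30.
#' @param t_end schedule horizon in ms.
#' @param seed RNG seed.
#' @param q_inlet per-depth inlet flux in um^2/ms; if `NULL`, taken from a
#'   flow-rate BC or estimated from a pressure BC via the two-port
#'   Poiseuille resistance of the network path.
#' @param end_to_end cell size in um.
#' @param n_contour contour nodes per cell.
#' @return tibble: cell_id, t_insert (ms), y_offset (um), speed (um/ms),
#'   with attributes `cell_area`, `width`, `q_inlet`.
#' @export
seed_cells_at_inlet <- function(graph, target_hct = 0.30, t_end = 500,
                                seed = 1, q_inlet = NULL, end_to_end = 7.8,
                                n_contour = 40) {
  stopifnot(target_hct >= 0, target_hct < 0.8)
  info <- inlet_info(graph)
  w <- info$width
  proto <- make_cell_contour_2d(end_to_end, n_contour)
  A_cell <- abs(contour_area(proto$vertices))
  half_span <- cell_length(proto) / 2 # lateral half-extent when upright
  thick <- diff(range(proto$vertices[, 2])) # axial extent when upright
  if (w < 1.05 * thick + 1)
    stop("inlet vessel too narrow for a cell (width ", w, " um)")
  if (is.null(q_inlet)) q_inlet <- estimate_inlet_flux(graph, info)
  band <- max(w / 2 - half_span - 0.6, 0.15 * w / 2)
  if (target_hct == 0)
    return(structure(tibble::tibble(cell_id = integer(0), t_insert = numeric(0),
                                    y_offset = numeric(0), speed = numeric(0)),
                     cell_area = A_cell, width = w, q_inlet = q_inlet,
                     band = band, end_to_end = end_to_end,
                     n_contour = n_contour))
  with_seed(seed, {
    # calibrated arrival rate (renewal: each cell contributes A_cell/v to the
    # time-integrated occupied area per unit gate length)
    yy <- seq(-band, band, length.out = 257)
    Einv <- mean(1 / lane_speed(yy, w, q_inlet))
    gap_target <- A_cell * Einv / (target_hct * w) # required mean spacing (ms)
    # non-overlap dead time: a new cell must wait until the previous one has
    # cleared the insertion plane; for mean inter-arrival mu with refractory
    # period c the realized mean gap is c + mu exp(-c/mu). Solve for mu.
    clearance <- 1.05 * thick + 0.4
    cbar <- clearance * Einv
    if (gap_target <= cbar * 1.02)
      stop("target hematocrit ", target_hct, " geometrically unreachable at ",
           "the inlet (cell clearance alone gives ",
           round(A_cell * Einv / (cbar * w), 3), ")")
    mu <- stats::uniroot(function(m) cbar + m * exp(-cbar / m) - gap_target,
                         c(1e-5, gap_target))$root
    rate <- 1 / mu
    ts <- numeric(0); ys <- numeric(0); sp <- numeric(0)
    t <- 0; last_t <- -Inf; last_y <- 0; last_v <- 1
    while (t < t_end) {
      t <- t + stats::rexp(1, rate)
      y <- stats::runif(1, -band, band)
      v <- lane_speed(y, w, q_inlet)
      # delay until the previous cell has cleared the insertion plane if the
      # two would overlap (lateral separation below the cell height)
      if (abs(y - last_y) < 1.05 * thick + 0.4) {
        t_clear <- last_t + (1.05 * thick + 0.4) / last_v
        if (t < t_clear) t <- t_clear
      }
      if (t >= t_end) break
      ts <- c(ts, t); ys <- c(ys, y); sp <- c(sp, v)
      last_t <- t; last_y <- y; last_v <- v
    }
    structure(tibble::tibble(cell_id = seq_along(ts), t_insert = ts,
                             y_offset = ys, speed = sp),
              cell_area = A_cell, width = w, q_inlet = q_inlet, band = band,
              end_to_end = end_to_end, n_contour = n_contour)
  })
}

# crude two-port estimate of the inlet flux under a pressure BC: series /
# parallel reduction is not attempted; a plane-Poiseuille resistance of the
# inlet path (sum over segments of a shortest path to an outlet) is used
estimate_inlet_flux <- function(graph, info = inlet_info(graph)) {
  pn <- resolve_bcs(graph)
  if (info$node$kind == "flow_rate") return(info$node$value_model)
  out <- pn[pn$role == "outlet", ]
  dp <- info$node$value_model - min(out$value_model)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = graph$segments$from, to = graph$segments$to,
               weight = 12 * .rbc_const$mu_plasma * graph$segments$arclength /
                 graph$segments$diameter^3),
    directed = FALSE, vertices = data.frame(name = graph$nodes$id))
  R <- igraph::distances(ig, v = as.character(info$node$node_id),
                         to = as.character(out$node_id[1]))[1, 1]
  dp / R
}

# clip a polygon by the vertical slab xa <= x <= xb and return its area
polygon_slab_area <- function(V, xa, xb) {
  clip_half <- function(P, a, keep_right) {
    n <- nrow(P); out <- list()
    for (i in seq_len(n)) {
      cur <- P[i, ]; nxt <- P[if (i == n) 1 else i + 1, ]
      cin <- if (keep_right) cur[1] >= a else cur[1] <= a
      nin <- if (keep_right) nxt[1] >= a else nxt[1] <= a
      if (cin) out[[length(out) + 1]] <- cur
      if (cin != nin) {
        t <- (a - cur[1]) / (nxt[1] - cur[1])
        out[[length(out) + 1]] <- cur + t * (nxt - cur)
      }
    }
    if (length(out) < 3) return(NULL)
    do.call(rbind, out)
  }
  P <- clip_half(V, xa, TRUE)
  if (is.null(P)) return(0)
  P <- clip_half(P, xb, FALSE)
  if (is.null(P)) return(0)
  abs(contour_area(P))
}

#' Kinematic inlet hematocrit measurement
#'
#' Transports the scheduled cells along the inlet vessel at their lane
#' speeds and measures the time-averaged tube hematocrit (cell area inside
#' the measurement window divided by window lumen area) at the inlet
#' cross-section. This isolates the seeding calibration from downstream
#' cell-cell hydrodynamics.
#'
#' @param schedule a schedule from [seed_cells_at_inlet()].
#' @param warmup time discarded before averaging (ms).
#' @param t_end end of the measurement (ms; default the schedule horizon).
#' @param window_length axial extent of the measurement window (um).
#' @param sample_every sampling interval (ms).
#' @return list with `H_mean`, `H_t` (tibble time, H) and the window used.
#' @export
measure_inlet_hematocrit <- function(schedule, warmup = 100, t_end = NULL,
                                     window_length = 20, sample_every = 1) {
  A_cell <- attr(schedule, "cell_area")
  w <- attr(schedule, "width")
  e2e <- attr(schedule, "end_to_end")
  nc <- attr(schedule, "n_contour")
  proto <- make_cell_contour_2d(e2e, nc)
  # upright orientation: long axis lateral
  Vp <- proto$vertices[, c(2, 1)]
  if (is.null(t_end)) t_end <- max(schedule$t_insert, warmup + 1)
  x_a <- 8; x_b <- 8 + window_length # window just downstream of insertion
  times <- seq(warmup, t_end, by = sample_every)
  H <- vapply(times, function(t) {
    act <- schedule[schedule$t_insert <= t, ]
    if (!nrow(act)) return(0)
    xc <- (t - act$t_insert) * act$speed
    near <- which(xc > x_a - e2e & xc < x_b + e2e)
    tot <- 0
    for (k in near) {
      V <- cbind(Vp[, 1] + xc[k], Vp[, 2] + act$y_offset[k])
      tot <- tot + polygon_slab_area(V, x_a, x_b)
    }
    tot / (window_length * w)
  }, numeric(1))
  list(H_mean = mean(H), H_t = tibble::tibble(time = times, H = H),
       window = c(x_a, x_b))
}
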