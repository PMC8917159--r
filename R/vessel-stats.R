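# Per-vessel hemodynamics: cell-to-vessel assignment, hematocrit and flow
# time series, resistance, lateral hematocrit profiles, cell-free layer,
# and the stiffer-vs-normal percentage deltas.

# minimal state view of a stored field snapshot (for interpolation)
field_state <- function(record, i) {
  st <- record$state
  st$u <- record$fields[[i]]$u
  st$v <- record$fields[[i]]$v
  st$p <- record$fields[[i]]$p
  st$mu <- record$fields[[i]]$mu
  st$time <- record$times_fields[i]
  st
}

#' Flux through a gate cross-section
#'
#' Integrates the normal velocity across a gate line (trapezoid rule, fine
#' sampling, extended slightly beyond the walls so the smoothed
#' immersed-boundary velocity is fully captured).
#'
#' @param state an `rbc_fluid_state` (or field-snapshot view).
#' @param gate one row of [segment_gates()].
#' @param pad wall overhang in grid cells.
#' @return per-depth flux in um^2/ms, positive along the segment direction.
#' @export
gate_flux <- function(state, gate, pad = 1) {
  whalf <- gate$width / 2 + pad * state$h
  nsamp <- 2 * ceiling(whalf / (state$h / 8)) + 1
  tt <- seq(-whalf, whalf, length.out = nsamp)
  pts <- cbind(gate$x - tt * gate$ty, gate$y + tt * gate$tx)
  U <- interpolate_velocity(state, pts)
  un <- U[, 1] * gate$tx + U[, 2] * gate$ty
  un[state$sdf(pts) >= 0] <- 0 # integrate over the lumen only
  hsp <- tt[2] - tt[1]
  sum((un[-1] + un[-nsamp]) / 2) * hsp
}

# mean pressure near a point, over lumen cells within radius r
pressure_at <- function(state, x, y, r = NULL) {
  if (is.null(r)) r <- 1.5 * state$h
  pc <- p_coords(state)
  ii <- which(abs(pc$x - x) <= r + state$h)
  jj <- which(abs(pc$y - y) <= r + state$h)
  if (!length(ii) || !length(jj)) return(NA_real_)
  sub <- expand.grid(i = ii, j = jj)
  d2 <- (pc$x[sub$i] - x)^2 + (pc$y[sub$j] - y)^2
  lum <- state$sdf(cbind(pc$x[sub$i], pc$y[sub$j])) < 0
  sel <- d2 <= r^2 & lum
  if (!any(sel)) return(NA_real_)
  mean(state$p[cbind(sub$i[sel], sub$j[sel])])
}

#' Assign cells to vessels or junction regions
#'
#' Applies the gate rule at every shape snapshot: a cell belongs to the
#' junction region when its centroid lies within the junction blend zone,
#' otherwise to the nearest segment.
#'
#' @param record an `rbc_sim_record`.
#' @param graph the network (defaults to the record's).
#' @return tibble: time, cell_id, owner_type ("segment"|"junction"),
#'   owner_id.
#' @export
assign_cells_to_vessels <- function(record, graph = record$graph) {
  out <- list()
  for (i in seq_along(record$times_shapes)) {
    cm <- record$centroids[[i]]
    if (!nrow(cm)) next
    own <- owner_of(graph, cm[, 2:3, drop = FALSE])
    out[[length(out) + 1]] <- tibble::tibble(
      time = record$times_shapes[i], cell_id = as.integer(cm[, 1]),
      owner_type = own$type, owner_id = own$id)
  }
  if (!length(out))
    return(tibble::tibble(time = numeric(0), cell_id = integer(0),
                          owner_type = character(0), owner_id = integer(0)))
  dplyr::bind_rows(out)
}

# gated measurement span of a segment (between entry and exit gates)
gated_span <- function(record, segment) {
  gs <- record$gates[record$gates$segment_id == segment, ]
  c(gs$s[gs$gate == "entry"], gs$s[gs$gate == "exit"])
}

#' Tube-hematocrit time series of one vessel
#'
#' H(t) is the total area of the cells assigned to the segment divided by
#' the gated lumen area (span between entry and exit gates times diameter);
#' junction-region content is excluded by the gate rule.
#'
#' @param record an `rbc_sim_record`.
#' @param graph network (defaults to the record's).
#' @param segment segment id.
#' @param warmup discard snapshots before this time (ms; defaults to the
#'   record's configured warmup).
#' @return list with `series` (tibble time, H), `H_mean`, `H_cv` (temporal
#'   coefficient of variation, `NA` for an empty vessel).
#' @export
hematocrit_series <- function(record, graph = record$graph, segment,
                              warmup = record$config$warmup) {
  span <- gated_span(record, segment)
  d <- graph$segments$diameter[graph$segments$id == segment]
  lumen_area <- (span[2] - span[1]) * d
  keep <- which(record$times_shapes >= warmup)
  H <- vapply(keep, function(i) {
    cm <- record$centroids[[i]]
    if (!nrow(cm)) return(0)
    own <- owner_of(graph, cm[, 2:3, drop = FALSE])
    sel <- which(own$type == "segment" & own$id == segment)
    if (!length(sel)) return(0)
    sum(vapply(sel, function(k)
      abs(contour_area(record$shapes[[i]][[k]])), numeric(1))) / lumen_area
  }, numeric(1))
  Hm <- mean(H)
  list(series = tibble::tibble(time = record$times_shapes[keep], H = H),
       H_mean = Hm,
       H_cv = if (Hm > 0) stats::sd(H) / Hm else NA_real_)
}

#' Flow-rate series, pressure drop and resistance of one vessel
#'
#' Q(t) is the flux through the segment's mid gate at each stored field
#' snapshot; the pressure drop is the mean pressure difference between the
#' entry and exit gates, and R = dp / mean(Q).
#'
#' @inheritParams hematocrit_series
#' @return list with `series` (tibble time, Q), `Q_mean`, `Q_cv`, `dp`
#'   (Pa), `R` (Pa ms / um^2, per unit depth).
#' @export
flow_series <- function(record, graph = record$graph, segment,
                        warmup = record$config$warmup) {
  gs <- record$gates[record$gates$segment_id == segment, ]
  gmid <- gs[gs$gate == "mid", ]
  gin <- gs[gs$gate == "entry", ]; gout <- gs[gs$gate == "exit", ]
  keep <- which(record$times_fields >= warmup)
  if (!length(keep)) stop("no post-warmup field snapshots")
  Q <- numeric(length(keep)); dp <- numeric(length(keep))
  for (k in seq_along(keep)) {
    stv <- field_state(record, keep[k])
    Q[k] <- gate_flux(stv, gmid)
    dp[k] <- pressure_at(stv, gin$x, gin$y) - pressure_at(stv, gout$x, gout$y)
  }
  Qm <- mean(Q)
  list(series = tibble::tibble(time = record$times_fields[keep], Q = Q),
       Q_mean = Qm,
       Q_cv = if (abs(Qm) > 0) stats::sd(Q) / abs(Qm) else NA_real_,
       dp = mean(dp), R = if (abs(Qm) > 0) mean(dp) / Qm else NA_real_)
}

# mean length of cells while assigned to the segment
vessel_cell_length <- function(record, graph, segment, warmup) {
  keep <- which(record$times_shapes >= warmup)
  lens <- c()
  for (i in keep) {
    cm <- record$centroids[[i]]
    if (!nrow(cm)) next
    own <- owner_of(graph, cm[, 2:3, drop = FALSE])
    sel <- which(own$type == "segment" & own$id == segment)
    lens <- c(lens, vapply(sel, function(k)
      cell_length(record$shapes[[i]][[k]]), numeric(1)))
  }
  if (!length(lens)) NA_real_ else mean(lens)
}

#' Per-vessel summary table of one run
#'
#' @param record an `rbc_sim_record`.
#' @param warmup analysis warmup (ms).
#' @param cfl also compute the cell-free layer at the mid gate.
#' @return tibble: segment_id, d_um, H_mean, H_cv, Q_mean, Q_cv, dp_Pa, R,
#'   cell_length_um, CFL_um.
#' @export
vessel_table <- function(record, warmup = record$config$warmup, cfl = TRUE) {
  graph <- record$graph
  rows <- lapply(graph$segments$id, function(sid) {
    hs <- hematocrit_series(record, graph, sid, warmup)
    fs <- flow_series(record, graph, sid, warmup)
    prof <- if (cfl) cross_section_profile(record, graph, sid,
                                           warmup = warmup) else NULL
    tibble::tibble(
      segment_id = sid,
      d_um = graph$segments$diameter[graph$segments$id == sid],
      H_mean = hs$H_mean, H_cv = hs$H_cv,
      Q_mean = fs$Q_mean, Q_cv = fs$Q_cv, dp_Pa = fs$dp, R = fs$R,
      cell_length_um = vessel_cell_length(record, graph, sid, warmup),
      CFL_um = if (cfl) prof$cfl else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Stiffer-vs-normal per-vessel percentage changes
#'
#' Computes the percentage deltas (stiffer - normal) / normal x 100 for
#' hematocrit, flow rate and resistance, matched by segment id. Vessels
#' whose normal-run mean flow is below `flow_floor` times the network mean
#' are flagged and their deltas suppressed.
#'
#' @param normal,stiffer per-vessel tables from [vessel_table()].
#' @param flow_floor relative flow floor (default 1e-3).
#' @return tibble: segment_id, d_um, delta_H_pct, delta_Q_pct, delta_R_pct,
#'   flagged.
#' @export
delta_metrics <- function(normal, stiffer, flow_floor = 1e-3) {
  j <- dplyr::inner_join(normal, stiffer, by = c("segment_id", "d_um"),
                         suffix = c("_n", "_s"))
  floorQ <- flow_floor * mean(abs(j$Q_mean_n), na.rm = TRUE)
  pct <- function(s, n) ifelse(abs(n) > 0, (s - n) / n * 100, NA_real_)
  out <- tibble::tibble(
    segment_id = j$segment_id, d_um = j$d_um,
    delta_H_pct = pct(j$H_mean_s, j$H_mean_n),
    delta_Q_pct = pct(j$Q_mean_s, j$Q_mean_n),
    delta_R_pct = pct(j$R_s, j$R_n),
    flagged = abs(j$Q_mean_n) < floorQ)
  out$delta_H_pct[out$flagged] <- NA_real_
  out$delta_Q_pct[out$flagged] <- NA_real_
  out$delta_R_pct[out$flagged] <- NA_real_
  out
}

# population standard deviation
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Spatial coefficient of variation of hematocrit across vessels
#'
#' Population standard deviation of the per-vessel time-averaged
#' hematocrits divided by their mean.
#'
#' @param vtab a [vessel_table()] (or any tibble with `H_mean`).
#' @return scalar CV.
#' @export
spatial_cv <- function(vtab) {
  H <- vtab$H_mean[is.finite(vtab$H_mean)]
  if (length(H) < 2) stop("need >= 2 vessels with defined hematocrit")
  sd_pop(H) / mean(H)
}

#' Lateral hematocrit profile, skewness and cell-free layer
#'
#' Time-averaged occupancy fraction in equal-width lateral bins at a
#' station along a segment (the mid gate by default). Skewness is the third
#' standardized moment of the occupancy distribution over the lateral
#' coordinate (positive = shifted toward positive lateral axis, the local
#' left of the flow direction). The cell-free layer is the mean distance
#' from each wall to the nearest cell boundary point in an axial window
#' around the station.
#'
#' @param record an `rbc_sim_record`.
#' @param graph network.
#' @param segment segment id.
#' @param station arclength position (um); default mid gate.
#' @param bins number of lateral bins (default 20).
#' @param warmup analysis warmup (ms).
#' @param axial_window half-width of the axial sampling window (um).
#' @return list: `profile` (tibble lat, occupancy), `skewness`, `cfl` (um,
#'   `NA` if no cells ever present in the window).
#' @export
cross_section_profile <- function(record, graph = record$graph, segment,
                                  station = NULL, bins = 20,
                                  warmup = record$config$warmup,
                                  axial_window = 4) {
  gs <- record$gates[record$gates$segment_id == segment, ]
  if (is.null(station)) station <- gs$s[gs$gate == "mid"]
  cl <- graph$segments$centerline[[which(graph$segments$id == segment)]]
  gp <- polyline_point(cl, station)
  d <- graph$segments$diameter[graph$segments$id == segment]
  nrm <- c(-gp$t[2], gp$t[1])
  lat <- (seq_len(bins) - 0.5) / bins * d - d / 2
  pts <- cbind(gp$p[1] + lat * nrm[1], gp$p[2] + lat * nrm[2])
  keep <- which(record$times_shapes >= warmup)
  occ <- matrix(0, length(keep), bins)
  cfl_top <- c(); cfl_bot <- c()
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    Vs <- record$shapes[[i]]
    any_near <- FALSE
    for (V in Vs) {
      # consider cells whose bounding box reaches the station
      if (max(V[, 1]) < min(pts[, 1]) - 1 || min(V[, 1]) > max(pts[, 1]) + 1)
        if (max(V[, 2]) < min(pts[, 2]) - 1 || min(V[, 2]) > max(pts[, 2]) + 1)
          next
      inside <- point_in_polygon(pts, V)
      occ[ii, ] <- pmax(occ[ii, ], as.numeric(inside))
      # axial window for the CFL: vertex distance to the two walls
      rel <- cbind(V[, 1] - gp$p[1], V[, 2] - gp$p[2])
      s_ax <- rel[, 1] * gp$t[1] + rel[, 2] * gp$t[2]
      s_lat <- rel[, 1] * nrm[1] + rel[, 2] * nrm[2]
      inwin <- abs(s_ax) <= axial_window
      if (any(inwin)) {
        any_near <- TRUE
        cfl_top <- c(cfl_top, min(d / 2 - s_lat[inwin]))
        cfl_bot <- c(cfl_bot, min(d / 2 + s_lat[inwin]))
      }
    }
  }
  prof <- colMeans(occ)
  skew <- if (sum(prof) > 0) {
    m <- sum(prof * lat) / sum(prof)
    s2 <- sum(prof * (lat - m)^2) / sum(prof)
    if (s2 > 0) sum(prof * (lat - m)^3) / sum(prof) / s2^1.5 else 0
  } else NA_real_
  list(profile = tibble::tibble(lat = lat, occupancy = prof),
       skewness = skew,
       cfl = if (length(cfl_top)) mean(c(pmax(cfl_top, 0),
                                         pmax(cfl_bot, 0))) else NA_real_)
}
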