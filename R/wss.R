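# Wall shear stress from time-averaged velocity fields: one-sided quadratic
# normal derivative of the wall-tangential velocity at wall samples, with
# the plasma viscosity (a plasma layer wets the wall), reported in
# dyn/cm^2; per-vessel wall-length-weighted averages; and the
# stiffer-vs-normal relative change with a localization report.

#' Time-averaged field of a simulation record
#'
#' Arithmetic mean of the stored post-warmup velocity (and pressure)
#' snapshots, returned as a fluid state. Averaging commutes with the linear
#' derivative operators used downstream.
#'
#' @param record an `rbc_sim_record` with field snapshots.
#' @param warmup discard snapshots before this time (ms).
#' @return an `rbc_fluid_state` holding the averaged fields.
#' @export
time_average_field <- function(record, warmup = record$config$warmup) {
  keep <- which(record$times_fields >= warmup)
  if (length(keep) < 2) stop("need >= 2 post-warmup field snapshots")
  st <- record$state
  st$u <- Reduce(`+`, lapply(keep, function(i) record$fields[[i]]$u)) /
    length(keep)
  st$v <- Reduce(`+`, lapply(keep, function(i) record$fields[[i]]$v)) /
    length(keep)
  st$p <- Reduce(`+`, lapply(keep, function(i) record$fields[[i]]$p)) /
    length(keep)
  st
}

#' Wall shear stress at wall sample points
#'
#' At every wall sample the wall-tangential velocity is sampled at 2h, 3h
#' and 4h along the inward normal (outside the immersed-boundary kernel's
#' wall smearing); a quadratic fit gives the one-sided normal derivative at
#' the wall, and tau = mu_plasma du_s/dn, converted to dyn/cm^2. Samples
#' with fewer than 3 interior points are flagged.
#'
#' @param state a (time-averaged) `rbc_fluid_state`.
#' @param walls an `rbc_walls` for the same network.
#' @param mu_plasma plasma viscosity in Pa ms.
#' @return a `rbc_wss_field`: tibble x, y, segment ownership, tau_dyn_cm2,
#'   ds (wall measure), flagged.
#' @export
wall_traction <- function(state, walls, mu_plasma = .rbc_const$mu_plasma) {
  s <- walls$samples
  h <- state$h
  dists <- c(2, 3, 4) * h
  n <- nrow(s)
  Umat <- matrix(0, n, 3)
  inside_all <- rep(TRUE, n)
  for (k in 1:3) {
    pts <- cbind(s$x - dists[k] * s$nx, s$y - dists[k] * s$ny)
    inside_all <- inside_all & (walls$sdf(pts) < 0)
    U <- interpolate_velocity(state, pts)
    # tangential component (tangent = rotated normal)
    Umat[, k] <- -U[, 1] * s$ny + U[, 2] * s$nx
  }
  # quadratic u(d) = a + b d + c d^2 through the three samples
  d1 <- dists[1]; d2 <- dists[2]; d3 <- dists[3]
  Vm <- solve(rbind(c(1, d1, d1^2), c(1, d2, d2^2), c(1, d3, d3^2)))
  b <- Umat %*% Vm[2, ]
  tau <- Pa_to_dyn_cm2(mu_plasma * as.numeric(b))
  structure(
    tibble::tibble(x = s$x, y = s$y, nx = s$nx, ny = s$ny,
                   owner_type = s$owner_type, owner_id = s$owner_id,
                   ds = s$ds, tau_dyn_cm2 = tau, flagged = !inside_all),
    class = c("rbc_wss_field", "tbl_df", "tbl", "data.frame"),
    h = h, mu_plasma = mu_plasma)
}

#' Wall-averaged WSS per vessel
#'
#' Wall-measure-weighted mean of |tau| over the samples owned by each
#' segment (the 2D reduction of the surface integral of tau over the
#' vascular surface area).
#'
#' @param wss an `rbc_wss_field`.
#' @param segment optional segment id; all segments when `NULL`.
#' @return tibble: segment_id, tau_mean_dyn_cm2, wall_length_um.
#' @export
vessel_average_wss <- function(wss, segment = NULL) {
  w <- wss[wss$owner_type == "segment" & !wss$flagged, ]
  if (!is.null(segment)) w <- w[w$owner_id %in% segment, ]
  if (!nrow(w)) stop("no wall samples owned by the requested segment(s)")
  out <- dplyr::summarise(
    dplyr::group_by(w, segment_id = .data$owner_id),
    tau_mean_dyn_cm2 = sum(abs(.data$tau_dyn_cm2) * .data$ds) / sum(.data$ds),
    wall_length_um = sum(.data$ds), .groups = "drop")
  out
}

#' Relative WSS change with localization report
#'
#' Delta tau = (tau_stiffer - tau_normal) / tau_normal at matched wall
#' samples. Points where |tau_normal| is below 1% of the network median are
#' excluded from the relative change (the absolute difference is reported
#' there instead). Each sample is tagged apex-proximal (within two feeder
#' radii of a bifurcation apex), curved-outer-side (outer wall of a curved
#' centerline), or other, and Delta tau is summarized by tag.
#'
#' @param normal,stiffer `rbc_wss_field`s on the same wall geometry.
#' @param graph the network.
#' @param floor_frac relative-floor fraction of the network median
#'   (default 0.01).
#' @return list: `samples` (tibble with delta_tau, delta_tau_abs, tag),
#'   `by_tag` (summary tibble), `per_vessel` (mean Delta tau per segment).
#' @export
delta_tau <- function(normal, stiffer, graph, floor_frac = 0.01) {
  stopifnot(nrow(normal) == nrow(stiffer))
  tn <- normal$tau_dyn_cm2; ts <- stiffer$tau_dyn_cm2
  floorv <- floor_frac * stats::median(abs(tn), na.rm = TRUE)
  rel <- ifelse(abs(tn) >= floorv, (ts - tn) / tn, NA_real_)
  tag <- rep("other", nrow(normal))
  # apex-proximal
  if (nrow(graph$junctions)) {
    for (i in seq_len(nrow(graph$junctions))) {
      ap <- graph$junctions$apex[[i]]
      if (any(!is.finite(ap))) next
      m <- graph$junctions$mothers[[i]][1]
      rf <- graph$segments$diameter[graph$segments$id == m] / 2
      d <- sqrt((normal$x - ap[1])^2 + (normal$y - ap[2])^2)
      tag[d <= 2 * rf] <- "apex"
    }
  }
  # curved-outer-side: sample on the outer (convex) side where the local
  # centerline curvature radius is below ~4 diameters
  for (k in seq_len(nrow(graph$segments))) {
    cl <- graph$segments$centerline[[k]]
    if (nrow(cl) < 5) next
    sel <- which(tag == "other" & normal$owner_type == "segment" &
                   normal$owner_id == graph$segments$id[k])
    if (!length(sel)) next
    pts <- cbind(normal$x[sel], normal$y[sel])
    # nearest centerline vertex and local curvature vector
    for (qi in seq_along(sel)) {
      dd <- (cl[, 1] - pts[qi, 1])^2 + (cl[, 2] - pts[qi, 2])^2
      i0 <- min(max(which.min(dd), 3), nrow(cl) - 2)
      kv <- cl[i0 + 2, ] + cl[i0 - 2, ] - 2 * cl[i0, ] # curvature direction
      seglen <- sqrt(sum((cl[i0 + 2, ] - cl[i0 - 2, ])^2)) / 4
      kmag <- sqrt(sum(kv^2)) / (4 * seglen^2)
      if (kmag * 4 * graph$segments$diameter[k] > 1) {
        outward <- sum((pts[qi, ] - cl[i0, ]) * kv) < 0
        if (outward) tag[sel[qi]] <- "curved-outer"
      }
    }
  }
  samples <- tibble::tibble(
    x = normal$x, y = normal$y, owner_type = normal$owner_type,
    owner_id = normal$owner_id, ds = normal$ds,
    tau_normal = tn, tau_stiffer = ts,
    delta_tau = rel, delta_tau_abs = ts - tn, tag = tag,
    floored = abs(tn) < floorv)
  by_tag <- dplyr::summarise(
    dplyr::group_by(samples, .data$tag),
    n = dplyr::n(),
    delta_tau_mean = mean(.data$delta_tau, na.rm = TRUE),
    delta_tau_min = suppressWarnings(min(.data$delta_tau, na.rm = TRUE)),
    delta_tau_max = suppressWarnings(max(.data$delta_tau, na.rm = TRUE)),
    .groups = "drop")
  per_vessel <- dplyr::summarise(
    dplyr::group_by(samples[samples$owner_type == "segment", ],
                    segment_id = .data$owner_id),
    delta_tau_mean = sum(.data$delta_tau * .data$ds, na.rm = TRUE) /
      sum(.data$ds[!is.na(.data$delta_tau)]),
    .groups = "drop")
  list(samples = samples, by_tag = by_tag, per_vessel = per_vessel)
}
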