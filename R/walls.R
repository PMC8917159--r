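# Wall geometry for the 2D flow core. The lumen is the union of capsules
# (centerline polylines swept by the local radius), blended smoothly at
# junctions via a quadratic smooth-minimum of the per-segment signed
# distances. Walls are the zero level set; inside/outside queries are just
# the sign of the distance.

#' Discretize vessel walls
#'
#' Builds the wall geometry of a network: a signed-distance function of the
#' lumen (negative inside), closed wall polylines extracted as the zero
#' contour, outward normals, and a map from every wall sample to its owning
#' segment or junction region.
#'
#' @param graph an `rbc_network`.
#' @param resolution wall sample spacing in um; must be positive and at most
#'   a quarter of the smallest diameter.
#' @param blend smooth-union blend width in um at junctions (default 1.5).
#' @param margin bounding-box margin in um beyond the lumen (default 6).
#' @return an `rbc_walls` object with elements `sdf` (vectorized closure
#'   mapping an n x 2 matrix to signed distances), `polylines` (list of
#'   closed wall loops), `samples` (tibble: x, y, nx, ny, owner_type,
#'   owner_id, ds), `bbox`, and `wall_length`.
#' @examples
#' w <- discretize_walls(build_fixture("straight_channel"), resolution = 1)
#' w$wall_length
#' @export
discretize_walls <- function(graph, resolution, blend = 1.5, margin = 6) {
  stopifnot(inherits(graph, "rbc_network"))
  dmin <- min(graph$segments$diameter)
  if (resolution <= 0 || resolution > dmin / 4)
    stop("resolution must be positive and <= smallest diameter / 4 (",
         dmin / 4, " um)")
  sdf <- network_sdf(graph, blend = blend)
  allpts <- do.call(rbind, graph$segments$centerline)
  rmax <- max(graph$segments$diameter) / 2
  bbox <- c(min(allpts[, 1]) - rmax - margin, max(allpts[, 1]) + rmax + margin,
            min(allpts[, 2]) - rmax - margin, max(allpts[, 2]) + rmax + margin)
  hs <- min(resolution / 2, dmin / 10)
  xs <- seq(bbox[1], bbox[2], by = hs)
  ys <- seq(bbox[3], bbox[4], by = hs)
  gridpts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  z <- matrix(sdf(gridpts), nrow = length(xs))
  cl <- grDevices::contourLines(xs, ys, z, levels = 0)
  if (!length(cl)) stop("no wall contour found; degenerate geometry")
  polylines <- lapply(cl, function(p) cbind(p$x, p$y))
  # resample each loop at the requested spacing and close it
  polylines <- lapply(polylines, resample_closed, spacing = resolution)
  samples <- wall_samples(graph, polylines, sdf, blend)
  structure(list(sdf = sdf, polylines = polylines, samples = samples,
                 bbox = bbox, blend = blend,
                 wall_length = sum(vapply(polylines, function(p)
                   polyline_length(rbind(p, p[1, ])), numeric(1))),
                 graph_digest = length(graph$segments$id)),
            class = "rbc_walls")
}

#' @export
print.rbc_walls <- function(x, ...) {
  cat("<rbc_walls> ", length(x$polylines), " wall loop(s), total length ",
      round(x$wall_length, 1), " um, ", nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Signed distance to the lumen boundary of a network
#'
#' Negative inside the lumen. Per-segment distances (capsule = centerline
#' swept by radius) are combined with a quadratic smooth minimum so that
#' junction corners are blended over a width `blend`.
#'
#' @param graph an `rbc_network`.
#' @param blend blend width in um.
#' @return a function taking an n x 2 matrix and returning n signed distances.
#' @export
network_sdf <- function(graph, blend = 1.5) {
  cls <- graph$segments$centerline
  radii <- graph$segments$diameter / 2
  force(blend)
  function(pts) {
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
    d <- point_polyline_distance(pts, cls[[1]]) - radii[1]
    if (length(cls) > 1) for (s in 2:length(cls)) {
      ds <- point_polyline_distance(pts, cls[[s]]) - radii[s]
      h <- pmax(blend - abs(d - ds), 0) / blend
      d <- pmin(d, ds) - h * h * blend / 4
    }
    d
  }
}

resample_closed <- function(p, spacing) {
  # p: open representation of a closed loop (first != last); resample at
  # approximately uniform arclength spacing
  q <- rbind(p, p[1, ])
  seglen <- sqrt(rowSums(diff(q)^2))
  s <- c(0, cumsum(seglen))
  L <- s[length(s)]
  n <- max(16, round(L / spacing))
  si <- seq(0, L, length.out = n + 1)[-(n + 1)]
  xi <- stats::approx(s, q[, 1], xout = si, ties = "ordered")$y
  yi <- stats::approx(s, q[, 2], xout = si, ties = "ordered")$y
  cbind(xi, yi)
}

wall_samples <- function(graph, polylines, sdf, blend) {
  pts <- do.call(rbind, polylines)
  eps <- 1e-3
  gx <- (sdf(cbind(pts[, 1] + eps, pts[, 2])) -
           sdf(cbind(pts[, 1] - eps, pts[, 2]))) / (2 * eps)
  gy <- (sdf(cbind(pts[, 1], pts[, 2] + eps)) -
           sdf(cbind(pts[, 1], pts[, 2] - eps))) / (2 * eps)
  gn <- pmax(sqrt(gx^2 + gy^2), 1e-9)
  own <- owner_of(graph, pts, blend)
  ds <- unlist(lapply(polylines, function(p) {
    q <- rbind(p, p[1, ])
    el <- sqrt(rowSums(diff(q)^2))
    (el + c(el[length(el)], el[-length(el)])) / 2
  }))
  tibble::tibble(x = pts[, 1], y = pts[, 2], nx = gx / gn, ny = gy / gn,
                 owner_type = own$type, owner_id = own$id, ds = ds,
                 loop = rep(seq_along(polylines),
                            vapply(polylines, nrow, integer(1))))
}

# owning segment or junction region of arbitrary points (used for wall
# samples and for cell-to-vessel assignment). A point belongs to a junction
# region when it lies within that junction's blend zone: distance to the
# junction node below the local feeder radius plus the blend width.
owner_of <- function(graph, pts, blend = 1.5) {
  n <- nrow(pts)
  dmat <- sapply(seq_len(nrow(graph$segments)), function(s)
    point_polyline_distance(pts, graph$segments$centerline[[s]]) -
      graph$segments$diameter[s] / 2)
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = n)
  seg_near <- graph$segments$id[apply(dmat, 1, which.min)]
  type <- rep("segment", n); id <- seg_near
  if (nrow(graph$junctions)) {
    for (i in seq_len(nrow(graph$junctions))) {
      adj <- unique(c(graph$junctions$mothers[[i]],
                      graph$junctions$daughters[[i]]))
      rj <- junction_region_radius(graph, i)
      jnode <- junction_node(graph, i)
      dj <- sqrt((pts[, 1] - jnode[1])^2 + (pts[, 2] - jnode[2])^2)
      inj <- dj < rj & (id %in% adj | type == "junction")
      type[inj] <- "junction"; id[inj] <- graph$junctions$id[i]
    }
  }
  list(type = type, id = id)
}

junction_node <- function(graph, i) {
  # the shared endpoint of the junction's segments
  m <- graph$junctions$mothers[[i]][1]
  nid <- graph$segments$to[graph$segments$id == m]
  if (graph$junctions$type[i] == "merger") {
    # mothers end at the node
    nid <- graph$segments$to[graph$segments$id == m]
  }
  c(graph$nodes$x[nid], graph$nodes$y[nid])
}

junction_region_radius <- function(graph, i) {
  adj <- unique(c(graph$junctions$mothers[[i]], graph$junctions$daughters[[i]]))
  adj <- adj[!is.na(adj)]
  max(graph$segments$diameter[match(adj, graph$segments$id)]) / 2 + 1.5
}

#' Inside test against a wall geometry
#'
#' @param walls an `rbc_walls` object.
#' @param pts n x 2 matrix of query points (um).
#' @return logical vector, `TRUE` for points inside the lumen.
#' @export
wall_inside <- function(walls, pts) walls$sdf(pts) < 0

#' Entry, mid and exit gates of every segment
#'
#' A gate is a cross-section line through the centerline, perpendicular to
#' the local tangent. The entry gate sits one local radius downstream of the
#' junction blend zone (or just inside a port); the exit gate mirrors it at
#' the far end; the mid gate is at half arclength and is used for flow
#' measurement.
#'
#' @param graph an `rbc_network`.
#' @param blend blend width used for the junction zone (um).
#' @return tibble: segment_id, gate ("entry"|"mid"|"exit"), s (arclength um),
#'   x, y, tx, ty (unit tangent, flow direction from->to).
#' @export
segment_gates <- function(graph, blend = 1.5) {
  jr <- function(node_id) {
    # radius of the junction zone around a node, 0 if not a junction node
    r <- 0
    if (nrow(graph$junctions)) for (i in seq_len(nrow(graph$junctions))) {
      if (all(abs(junction_node(graph, i) -
                    c(graph$nodes$x[node_id], graph$nodes$y[node_id])) < 1e-9))
        r <- max(r, junction_region_radius(graph, i))
    }
    r
  }
  out <- list()
  for (k in seq_len(nrow(graph$segments))) {
    cl <- graph$segments$centerline[[k]]
    L <- polyline_length(cl)
    r <- graph$segments$diameter[k] / 2
    s_in <- min(max(jr(graph$segments$from[k]) + r, 2), L * 0.4)
    s_out <- L - min(max(jr(graph$segments$to[k]) + r, 2), L * 0.4)
    for (gspec in list(c("entry", s_in), c("mid", L / 2), c("exit", s_out))) {
      gp <- polyline_point(cl, as.numeric(gspec[2]))
      out[[length(out) + 1]] <- tibble::tibble(
        segment_id = graph$segments$id[k], gate = gspec[1],
        s = as.numeric(gspec[2]), x = gp$p[1], y = gp$p[2],
        tx = gp$t[1], ty = gp$t[2], width = graph$segments$diameter[k])
    }
  }
  dplyr::bind_rows(out)
}

# point and unit tangent at arclength s along a polyline
polyline_point <- function(cl, s) {
  seglen <- sqrt(rowSums(diff(cl)^2))
  cs <- c(0, cumsum(seglen))
  s <- min(max(s, 0), cs[length(cs)])
  e <- max(1, findInterval(s, cs, rightmost.closed = TRUE))
  e <- min(e, nrow(cl) - 1)
  t <- (s - cs[e]) / max(seglen[e], 1e-12)
  p <- cl[e, ] + t * (cl[e + 1, ] - cl[e, ])
  tv <- (cl[e + 1, ] - cl[e, ]) / max(seglen[e], 1e-12)
  list(p = p, t = tv)
}
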