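# Synthetic capillary network geometries: canonical fixtures and validation.
#
# A network is a planar graph of winding vessel segments joined at
# bifurcations (one mother, two daughters) and mergers (two mothers, one
# daughter). Coordinates are in um; segment ids are one-based integers.

new_rbc_network <- function(nodes, segments, junctions, bcs) {
  structure(
    list(nodes = nodes, segments = segments, junctions = junctions, bcs = bcs,
         units = list(length = "um", time = "ms", pressure = "mmHg",
                      flow_rate = "nL/s")),
    class = "rbc_network"
  )
}

#' @export
print.rbc_network <- function(x, ...) {
  cat("<rbc_network> ", nrow(x$segments), " segments, ",
      nrow(x$junctions), " junctions, ",
      sum(x$nodes$role == "inlet"), " inlet(s), ",
      sum(x$nodes$role == "outlet"), " outlet(s)\n", sep = "")
  cat("  diameters [um]: ", paste(round(range(x$segments$diameter), 2),
                                  collapse = " - "), "\n", sep = "")
  invisible(x)
}

polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

segment_tibble <- function(id, from, to, diameter, centerline) {
  tibble::tibble(
    id = id, from = from, to = to, diameter = diameter,
    arclength = vapply(centerline, polyline_length, numeric(1)),
    centerline = centerline
  )
}

# densify a straight path with n points, optionally with a sinusoidal lateral
# perturbation (winding); amplitude in um, `periods` full waves along the path
wavy_centerline <- function(p0, p1, n = 33, amplitude = 0, periods = 1,
                            phase = 0) {
  t <- seq(0, 1, length.out = n)
  base <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  if (amplitude > 0) {
    d <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    nrm <- c(-d[2], d[1])
    off <- amplitude * sin(pi * t) * sin(2 * pi * periods * t + phase)
    base <- base + outer(off, nrm)
  }
  base
}

arc_centerline <- function(p0, radius, angle, n = 65, start_angle = -pi / 2) {
  th <- seq(start_angle, start_angle + angle, length.out = n)
  ctr <- p0 - radius * c(cos(start_angle), sin(start_angle))
  cbind(ctr[1] + radius * cos(th), ctr[2] + radius * sin(th))
}

default_bcs <- function(inlet_ids, outlet_ids, mode = c("pressure", "flow_rate"),
                        pressure_drop_mmHg = 4.8, flow_rate_nl_s = 1.25) {
  mode <- match.arg(mode)
  if (mode == "pressure") {
    tibble::tibble(
      node_id = c(inlet_ids, outlet_ids),
      kind = "pressure",
      value = c(rep(pressure_drop_mmHg, length(inlet_ids)),
                rep(0, length(outlet_ids)))
    )
  } else {
    tibble::tibble(
      node_id = c(inlet_ids, outlet_ids),
      kind = c(rep("flow_rate", length(inlet_ids)),
               rep("pressure", length(outlet_ids))),
      value = c(rep(flow_rate_nl_s, length(inlet_ids)),
                rep(0, length(outlet_ids)))
    )
  }
}

#' Canonical network fixtures
#'
#' Builds one of five small reference geometries used throughout the package:
#' a straight channel, a constant-curvature curved channel, a symmetric (or
#' asymmetric) Y bifurcation, a large feeder with a small side branch, and a
#' two-generation bifurcate-then-merge net. All coordinates are in um.
#'
#' @param name one of `"straight_channel"`, `"curved_channel"`,
#'   `"y_bifurcation"`, `"side_branch"`, `"two_generation_net"`.
#' @param params named list of geometric parameters overriding the defaults;
#'   see Details.
#' @param bc_mode `"pressure"` (default, 4.8 mmHg across ports) or
#'   `"flow_rate"` (1.25 nL/s at the inlet).
#'
#' @details Defaults: `straight_channel` (diameter 12, length 100);
#' `curved_channel` (diameter 12, radius 40, quarter turn);
#' `y_bifurcation` (mother 10, daughters 8/8 at +-30 degrees);
#' `side_branch` (feeder 17.5 with a 6 um daughter leaving at 60 degrees);
#' `two_generation_net` (two generations of bifurcations reconverging through
#' mergers to a single outlet).
#'
#' @return an `rbc_network` object.
#' @examples
#' net <- build_fixture("y_bifurcation")
#' net$segments$diameter
#' @export
build_fixture <- function(name, params = list(), bc_mode = "pressure") {
  known <- c("straight_channel", "curved_channel", "y_bifurcation",
             "side_branch", "two_generation_net")
  if (!name %in% known)
    stop("unknown fixture name '", name, "'; expected one of: ",
         paste(known, collapse = ", "))
  p <- params
  g <- switch(
    name,
    straight_channel = {
      d <- p$diameter %||% 12; L <- p$length %||% 100
      nodes <- tibble::tibble(id = 1:2, x = c(0, L), y = c(0, 0),
                              role = c("inlet", "outlet"))
      segs <- segment_tibble(1L, 1L, 2L, d,
                             list(wavy_centerline(c(0, 0), c(L, 0))))
      new_rbc_network(nodes, segs, empty_junctions(), NULL)
    },
    curved_channel = {
      d <- p$diameter %||% 12; R <- p$radius %||% 40
      ang <- p$angle %||% (pi / 2)
      cl <- arc_centerline(c(0, 0), R, ang)
      nodes <- tibble::tibble(id = 1:2, x = c(cl[1, 1], cl[nrow(cl), 1]),
                              y = c(cl[1, 2], cl[nrow(cl), 2]),
                              role = c("inlet", "outlet"))
      segs <- segment_tibble(1L, 1L, 2L, d, list(cl))
      new_rbc_network(nodes, segs, empty_junctions(), NULL)
    },
    y_bifurcation = {
      dm <- p$d_mother %||% 10
      d1 <- p$d1 %||% 8; d2 <- p$d2 %||% 8
      ang <- p$angle %||% (pi / 6); Lm <- p$L_mother %||% 50
      Ld <- p$L_daughter %||% 60
      L1 <- p$L1 %||% Ld; L2 <- p$L2 %||% Ld
      j <- c(Lm, 0)
      e1 <- j + L1 * c(cos(ang), sin(ang))
      e2 <- j + L2 * c(cos(ang), -sin(ang))
      nodes <- tibble::tibble(
        id = 1:4, x = c(0, j[1], e1[1], e2[1]), y = c(0, j[2], e1[2], e2[2]),
        role = c("inlet", "junction", "outlet", "outlet"))
      segs <- segment_tibble(
        1:3, c(1L, 2L, 2L), c(2L, 3L, 4L), c(dm, d1, d2),
        list(wavy_centerline(c(0, 0), j),
             wavy_centerline(j, e1), wavy_centerline(j, e2)))
      jn <- junction_tibble(1L, "bifurcation", list(1L), list(c(2L, 3L)),
                            graph_apex(j, c(cos(ang), sin(ang)),
                                       c(cos(ang), -sin(ang)), dm))
      new_rbc_network(nodes, segs, jn, NULL)
    },
    side_branch = {
      df <- p$d_feed %||% 17.5; db <- p$d_branch %||% 6
      ang <- p$angle %||% (pi / 3); Lf <- p$L_feed %||% 60
      Lb <- p$L_branch %||% 50; Ld <- p$L_down %||% 60
      j <- c(Lf, 0)
      eb <- j + Lb * c(cos(ang), sin(ang))
      ed <- j + c(Ld, 0)
      nodes <- tibble::tibble(
        id = 1:4, x = c(0, j[1], ed[1], eb[1]), y = c(0, j[2], ed[2], eb[2]),
        role = c("inlet", "junction", "outlet", "outlet"))
      segs <- segment_tibble(
        1:3, c(1L, 2L, 2L), c(2L, 3L, 4L), c(df, df, db),
        list(wavy_centerline(c(0, 0), j), wavy_centerline(j, ed),
             wavy_centerline(j, eb)))
      jn <- junction_tibble(1L, "bifurcation", list(1L), list(c(2L, 3L)),
                            graph_apex(j, c(1, 0), c(cos(ang), sin(ang)), df))
      new_rbc_network(nodes, segs, jn, NULL)
    },
    two_generation_net = {
      d0 <- p$d_inlet %||% 14; taper <- p$taper %||% 0.8
      Lx <- p$L_stage %||% 45; dy <- p$dy %||% 26
      d1 <- max(5.5, d0 * taper); d2 <- max(5.5, d1 * taper)
      # trunk -> bif A -> bifs B,C; each pair of branches re-merges (D,E),
      # D and E merge at F -> outlet (two generations each way)
      ns <- rbind(
        c(0, 0), c(Lx, 0),             # 1 inlet, 2 bif A
        c(2 * Lx, dy), c(2 * Lx, -dy), # 3 bif B, 4 bif C
        c(4 * Lx, dy), c(4 * Lx, -dy), # 5 merger D, 6 merger E
        c(5 * Lx, 0), c(6 * Lx, 0))    # 7 merger F, 8 outlet
      nodes <- tibble::tibble(
        id = 1:8, x = ns[, 1], y = ns[, 2],
        role = c("inlet", rep("junction", 6), "outlet"))
      bent <- function(a, w, b) rbind(wavy_centerline(a, w, n = 17),
                                      wavy_centerline(w, b, n = 17)[-1, ])
      cl <- list(
        wavy_centerline(ns[1, ], ns[2, ]),
        wavy_centerline(ns[2, ], ns[3, ]), wavy_centerline(ns[2, ], ns[4, ]),
        bent(ns[3, ], c(3 * Lx, 1.7 * dy), ns[5, ]),
        bent(ns[3, ], c(3 * Lx, 0.45 * dy), ns[5, ]),
        bent(ns[4, ], c(3 * Lx, -0.45 * dy), ns[6, ]),
        bent(ns[4, ], c(3 * Lx, -1.7 * dy), ns[6, ]),
        wavy_centerline(ns[5, ], ns[7, ]), wavy_centerline(ns[6, ], ns[7, ]),
        wavy_centerline(ns[7, ], ns[8, ]))
      segs <- segment_tibble(
        1:10,
        c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 6L, 7L),
        c(2L, 3L, 4L, 5L, 5L, 6L, 6L, 7L, 7L, 8L),
        c(d0, d1, d1, d2, d2, d2, d2, d1, d1, d0), cl)
      jn <- junction_tibble(
        1:6,
        c("bifurcation", "bifurcation", "bifurcation",
          "merger", "merger", "merger"),
        list(1L, 2L, 3L, c(4L, 5L), c(6L, 7L), c(8L, 9L)),
        list(c(2L, 3L), c(4L, 5L), c(6L, 7L), 8L, 9L, 10L),
        rep(list(c(NA_real_, NA_real_)), 6))
      # apexes of bifurcations from initial daughter directions
      for (i in 1:3) {
        jnode <- ns[c(2, 3, 4)[i], ]
        dirs <- lapply(jn$daughters[[i]], function(s) {
          cl_ <- segs$centerline[[s]]
          v <- cl_[min(5, nrow(cl_)), ] - cl_[1, ]; v / sqrt(sum(v^2))
        })
        jn$apex[[i]] <- graph_apex(jnode, dirs[[1]], dirs[[2]],
                                   segs$diameter[jn$mothers[[i]][1]])
      }
      # merger apexes: point between the two incoming branches
      for (i in 4:6) {
        jnode <- ns[c(5, 6, 7)[i - 3], ]
        dirs <- lapply(jn$mothers[[i]], function(s) {
          cl_ <- segs$centerline[[s]]
          v <- cl_[nrow(cl_) - min(4, nrow(cl_) - 1), ] - cl_[nrow(cl_), ]
          v / sqrt(sum(v^2))
        })
        jn$apex[[i]] <- graph_apex(jnode, dirs[[1]], dirs[[2]],
                                   segs$diameter[jn$daughters[[i]][1]])
      }
      new_rbc_network(nodes, segs, jn, NULL)
    })
  validate_diameters(g$segments$diameter, allow_override = isTRUE(p$allow_any_diameter))
  g$bcs <- default_bcs(g$nodes$id[g$nodes$role == "inlet"],
                       g$nodes$id[g$nodes$role == "outlet"], bc_mode)
  validate_network(g)
  g
}

empty_junctions <- function() {
  tibble::tibble(id = integer(), type = character(), mothers = list(),
                 daughters = list(), apex = list())
}

junction_tibble <- function(id, type, mothers, daughters, apex) {
  if (!is.list(apex)) apex <- list(apex)
  tibble::tibble(id = as.integer(id), type = type, mothers = mothers,
                 daughters = daughters, apex = apex)
}

# apex: the wall point between the two daughter openings, found on the
# bisector of the daughter directions, half a mother-diameter out
graph_apex <- function(jnode, dir1, dir2, d_mother) {
  b <- dir1 + dir2
  nb <- sqrt(sum(b^2))
  b <- if (nb < 1e-12) c(dir1[2], -dir1[1]) else b / nb
  jnode + b * d_mother / 2
}

validate_diameters <- function(d, allow_override = FALSE) {
  if (!allow_override && (any(d < 5.5) || any(d > 24)))
    stop("segment diameter outside the 5.5-24 um capillary range; pass ",
         "allow_any_diameter = TRUE to override")
  invisible(TRUE)
}

#' Validate a network against its structural invariants
#'
#' Checks connectivity, junction arity (one mother and two daughters at a
#' bifurcation, two mothers and one daughter at a merger), tortuosity >= 1,
#' and the presence of boundary conditions on at least one inlet and outlet.
#'
#' @param g an `rbc_network`.
#' @return `g`, invisibly; errors with a message on violation.
#' @export
validate_network <- function(g) {
  stopifnot(inherits(g, "rbc_network"))
  segs <- g$segments
  # tortuosity >= 1 (arclength >= chord)
  chord <- sqrt((g$nodes$x[segs$to] - g$nodes$x[segs$from])^2 +
                  (g$nodes$y[segs$to] - g$nodes$y[segs$from])^2)
  if (any(segs$arclength < chord - 1e-6))
    stop("segment arclength below endpoint distance (tortuosity < 1)")
  # connectivity
  ig <- igraph::graph_from_data_frame(
    data.frame(from = segs$from, to = segs$to), directed = FALSE,
    vertices = data.frame(name = g$nodes$id))
  if (igraph::components(ig)$no != 1) stop("network graph is not connected")
  # junction arity
  if (nrow(g$junctions)) {
    ok <- vapply(seq_len(nrow(g$junctions)), function(i) {
      nm <- length(g$junctions$mothers[[i]])
      nd <- length(g$junctions$daughters[[i]])
      if (g$junctions$type[i] == "bifurcation") nm == 1 && nd == 2
      else nm == 2 && nd == 1
    }, logical(1))
    if (!all(ok)) stop("junction arity violated (bifurcation: 1 mother/2 ",
                       "daughters; merger: 2 mothers/1 daughter)")
  }
  if (!is.null(g$bcs)) {
    roles <- g$nodes$role[match(g$bcs$node_id, g$nodes$id)]
    if (!any(roles == "inlet") || !any(roles == "outlet"))
      stop("boundary conditions must cover at least one inlet and one outlet")
  }
  invisible(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
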