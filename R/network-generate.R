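# Random planar network generator: sequential bifurcations fanning out from a
# single feeding vessel, then mergers reconverging to one outlet, with
# Horton-like diameter taper and sinusoidal winding.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv()))
    old <- get(".Random.seed", envir = globalenv())
  else old <- NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random planar capillary network
#'
#' Builds a network whose topology is a bifurcation tree reconverging through
#' mergers: a feeding vessel bifurcates through `generations` levels, the
#' terminal sibling branches close into capillary loops at shared merger
#' nodes, and the merged vessels pair up level by level until a single
#' draining vessel leaves the network. Daughter diameters taper by a
#' Murray-type factor (2^(-1/3)) with multiplicative log-normal noise,
#' clipped to the 5.5-24 um capillary range, so the per-generation mean
#' diameter is non-increasing. Winding is imposed as a sinusoidal
#' perturbation of straight centerlines.
#'
#' @param generations number of bifurcation generations (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the same graph.
#' @param d_inlet feeding-vessel diameter in um (default 20).
#' @param taper mean daughter/mother diameter ratio (default 2^(-1/3)).
#' @param diameter_sd standard deviation of log-normal diameter noise.
#' @param winding_amplitude lateral winding amplitude as a fraction of
#'   segment length (default 0.06).
#' @param L_stage axial length of one generation stage in um.
#' @param bc_mode boundary-condition mode, as in [build_fixture()].
#' @return an `rbc_network`; `g$segment_generation` records each segment's
#'   bifurcation generation (NA for merged-side vessels).
#' @examples
#' g <- generate_network(3, seed = 1)
#' range(g$segments$diameter)
#' @export
generate_network <- function(generations, seed, d_inlet = 20,
                             taper = 2^(-1 / 3), diameter_sd = 0.08,
                             winding_amplitude = 0.06, L_stage = 60,
                             bc_mode = "pressure") {
  stopifnot(generations >= 1)
  if (d_inlet < 5.5 || d_inlet > 24)
    stop("d_inlet must lie in the 5.5-24 um capillary diameter range")
  with_seed(seed, {
    env <- new.env()
    env$nodes <- list(); env$roles <- character(0)
    env$from <- integer(0); env$to <- integer(0); env$d <- numeric(0)
    env$cls <- list(); env$gen <- integer(0)
    new_node <- function(x, y, role) {
      env$nodes[[length(env$nodes) + 1]] <- c(x, y)
      env$roles <- c(env$roles, role)
      length(env$nodes)
    }
    add_seg <- function(a, b, d, gen = NA_integer_, amp = winding_amplitude) {
      p0 <- env$nodes[[a]]; p1 <- env$nodes[[b]]
      L <- sqrt(sum((p1 - p0)^2))
      env$cls[[length(env$cls) + 1]] <- wavy_centerline(
        p0, p1, n = 33, amplitude = amp * L * stats::runif(1, 0.5, 1),
        periods = sample(1:2, 1), phase = stats::runif(1, 0, 2 * pi))
      env$from <- c(env$from, a); env$to <- c(env$to, b)
      env$d <- c(env$d, d); env$gen <- c(env$gen, gen)
      length(env$d)
    }
    clip_d <- function(d) pmin(24, pmax(5.5, d))
    span <- max(40, 24 * 2^generations)
    ys_at <- function(k) if (k == 1) 0 else seq(-span / 2, span / 2,
                                                length.out = k)
    jn <- list(type = character(0), mothers = list(), daughters = list(),
               node = integer(0))
    add_junction <- function(type, node, mothers, daughters) {
      jn$type <<- c(jn$type, type)
      jn$mothers <<- c(jn$mothers, list(as.integer(mothers)))
      jn$daughters <<- c(jn$daughters, list(as.integer(daughters)))
      jn$node <<- c(jn$node, node)
    }

    inlet <- new_node(0, 0, "inlet")
    a0 <- new_node(L_stage, 0, "junction")
    trunk <- add_seg(inlet, a0, d_inlet, gen = 0L, amp = winding_amplitude / 2)

    # expansion: levels 1..G of bifurcations; at level G the sibling pair
    # closes into a loop at a shared merger node
    level_nodes <- a0; level_d <- d_inlet; level_in <- trunk
    for (g in seq_len(generations)) {
      last <- g == generations
      kout <- if (last) 2^(g - 1) else 2^g
      ys <- ys_at(kout)
      nxt_nodes <- integer(kout); nxt_d <- numeric(kout); nxt_in <- integer(kout)
      for (i in seq_along(level_nodes)) {
        a <- level_nodes[i]
        d1 <- clip_d(level_d[i] * taper * stats::rlnorm(1, 0, diameter_sd))
        d2 <- clip_d(level_d[i] * taper * stats::rlnorm(1, 0, diameter_sd))
        if (last) {
          b <- new_node((g + 1) * L_stage, ys[i], "junction")
          # loop: both daughters run to the shared merger node b through
          # laterally offset waypoints
          off <- max(8, 0.6 * (d1 + d2)) # loop half-opening
          p0 <- env$nodes[[a]]; p1 <- env$nodes[[b]]
          mid <- (p0 + p1) / 2
          s1 <- add_seg_via(env, a, b, d1, mid + c(0, off), gen = g)
          s2 <- add_seg_via(env, a, b, d2, mid - c(0, off), gen = g)
          add_junction("bifurcation", a, level_in[i], c(s1, s2))
          add_junction("merger", b, c(s1, s2), NA_integer_)
          nxt_nodes[i] <- b; nxt_d[i] <- clip_d(mean(c(d1, d2)) / taper)
          nxt_in[i] <- NA_integer_
        } else {
          b1 <- new_node((g + 1) * L_stage, ys[2 * i - 1], "junction")
          b2 <- new_node((g + 1) * L_stage, ys[2 * i], "junction")
          s1 <- add_seg(a, b1, d1, gen = g)
          s2 <- add_seg(a, b2, d2, gen = g)
          add_junction("bifurcation", a, level_in[i], c(s1, s2))
          nxt_nodes[2 * i - 1] <- b1; nxt_nodes[2 * i] <- b2
          nxt_d[2 * i - 1] <- d1; nxt_d[2 * i] <- d2
          nxt_in[2 * i - 1] <- s1; nxt_in[2 * i] <- s2
        }
      }
      level_nodes <- nxt_nodes; level_d <- nxt_d; level_in <- nxt_in
    }
    # contraction: nodes are mergers awaiting their daughter segment; pair
    # adjacent mergers, the two daughters ending at a shared new merger node
    lvl <- generations + 1
    while (length(level_nodes) > 1) {
      lvl <- lvl + 1
      k <- length(level_nodes) / 2
      ys <- ys_at(k * 2) # spread source of positions
      nxt_nodes <- integer(k); nxt_d <- numeric(k)
      for (i in seq_len(k)) {
        a1 <- level_nodes[2 * i - 1]; a2 <- level_nodes[2 * i]
        b <- new_node(lvl * L_stage,
                      mean(c(env$nodes[[a1]][2], env$nodes[[a2]][2])),
                      "junction")
        s1 <- add_seg(a1, b, clip_d(level_d[2 * i - 1] *
                                      stats::rlnorm(1, 0, diameter_sd)))
        s2 <- add_seg(a2, b, clip_d(level_d[2 * i] *
                                      stats::rlnorm(1, 0, diameter_sd)))
        # s1/s2 are the daughters of the mergers at a1, a2
        jn$daughters[[which(jn$node == a1 & jn$type == "merger")]] <- s1
        jn$daughters[[which(jn$node == a2 & jn$type == "merger")]] <- s2
        add_junction("merger", b, c(s1, s2), NA_integer_)
        nxt_nodes[i] <- b
        nxt_d[i] <- clip_d(mean(level_d[c(2 * i - 1, 2 * i)]) / taper)
      }
      level_nodes <- nxt_nodes; level_d <- nxt_d
      span <- span * 0.8
    }
    out <- new_node((lvl + 1) * L_stage, 0, "outlet")
    sid <- add_seg(level_nodes[1], out, clip_d(level_d[1]),
                   amp = winding_amplitude / 2)
    jn$daughters[[which(jn$node == level_nodes[1] & jn$type == "merger")]] <- sid

    nmat <- do.call(rbind, env$nodes)
    nodes_tb <- tibble::tibble(id = seq_len(nrow(nmat)), x = nmat[, 1],
                               y = nmat[, 2], role = env$roles)
    segs_tb <- segment_tibble(seq_along(env$d), env$from, env$to, env$d,
                              env$cls)
    apexes <- vector("list", length(jn$type))
    for (i in seq_along(jn$type)) {
      jnode <- nmat[jn$node[i], ]
      if (jn$type[i] == "bifurcation") {
        dirs <- lapply(jn$daughters[[i]], function(s) {
          cl_ <- env$cls[[s]]; v <- cl_[5, ] - cl_[1, ]; v / sqrt(sum(v^2))
        })
        dm <- env$d[jn$mothers[[i]][1]]
      } else {
        dirs <- lapply(jn$mothers[[i]], function(s) {
          cl_ <- env$cls[[s]]; v <- cl_[nrow(cl_) - 4, ] - cl_[nrow(cl_), ]
          v / sqrt(sum(v^2))
        })
        dm <- env$d[jn$daughters[[i]][1]]
      }
      apexes[[i]] <- graph_apex(jnode, dirs[[1]], dirs[[2]], dm)
    }
    jn_tb <- junction_tibble(seq_along(jn$type), jn$type, jn$mothers,
                             jn$daughters, apexes)
    g <- new_rbc_network(nodes_tb, segs_tb, jn_tb, NULL)
    g$bcs <- default_bcs(which(env$roles == "inlet"),
                         which(env$roles == "outlet"), bc_mode)
    g$segment_generation <- env$gen
    check_clearance(g)
    validate_network(g)
    g
  })
}

# segment routed through a waypoint, with mild winding on each leg
add_seg_via <- function(env, a, b, d, via, gen = NA_integer_) {
  p0 <- env$nodes[[a]]; p1 <- env$nodes[[b]]
  leg1 <- wavy_centerline(p0, via, n = 17)
  leg2 <- wavy_centerline(via, p1, n = 17)
  env$cls[[length(env$cls) + 1]] <- rbind(leg1, leg2[-1, ])
  env$from <- c(env$from, a); env$to <- c(env$to, b)
  env$d <- c(env$d, d); env$gen <- c(env$gen, gen)
  length(env$d)
}

# non-adjacent segments must keep a positive wall-to-wall clearance; winding
# amplitudes that violate it make the geometry infeasible
check_clearance <- function(g, min_gap = 2) {
  segs <- g$segments
  n <- nrow(segs)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      share <- length(intersect(c(segs$from[i], segs$to[i]),
                                c(segs$from[j], segs$to[j]))) > 0
      if (share) next
      a <- segs$centerline[[i]]; b <- segs$centerline[[j]]
      dmin <- min(point_polyline_distance(a, b),
                  point_polyline_distance(b, a))
      need <- (segs$diameter[i] + segs$diameter[j]) / 2 + min_gap
      if (dmin < need)
        stop("infeasible network: segments ", segs$id[i], " and ", segs$id[j],
             " approach to ", round(dmin, 1), " um (need ", round(need, 1),
             " um); reduce winding amplitude or generations")
    }
  }
  invisible(TRUE)
}

# distance from each point (rows of pts) to a polyline pl; vectorized over pts
point_polyline_distance <- function(pts, pl) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  d2 <- rep(Inf, nrow(pts))
  for (e in seq_len(nrow(pl) - 1)) {
    a <- pl[e, ]; b <- pl[e + 1, ]
    ab <- b - a; L2 <- sum(ab^2)
    t <- if (L2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                         (pts[, 2] - a[2]) * ab[2]) / L2))
    dx <- pts[, 1] - (a[1] + t * ab[1]); dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}
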