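# Ground-truthed synthetic gate-event streams and analytic velocity
# snapshots: solver-free inputs that make every analysis stage testable
# against known truth.

#' Specification of a synthetic bifurcation event stream
#'
#' Describes a single virtual bifurcation: cells arrive on the mother
#' vessel, cross the mother gate, optionally linger at the apex, and exit
#' through one of two daughters with a fixed routing probability. True
#' flow-rate ratio, routing probability and planted lingering episodes are
#' recorded so downstream statistics can be checked exactly.
#'
#' @param q_star true flow-rate ratio of daughter 1 (in (0, 1)).
#' @param p_route true probability that a cell routes to daughter 1.
#' @param rate cell arrival rate at the mother gate (cells/ms).
#' @param t_end stream duration (ms).
#' @param v transit speed along the vessels (um/ms).
#' @param L distance from mother gate to the apex (um).
#' @param gate_offset distance from the apex to each daughter gate (um).
#' @param linger tibble with columns `cell_id` and `duration` (ms) planting
#'   a stall at the apex for those cells, or an integer count of cells to
#'   plant (durations `linger_duration`).
#' @param linger_duration default planted stall duration (ms).
#' @param seed RNG seed.
#' @return a `synth_event_spec` list.
#' @export
synth_event_spec <- function(q_star = 0.6, p_route = 0.6, rate = 0.4,
                             t_end = 500, v = 2, L = 30, gate_offset = 6,
                             linger = NULL, linger_duration = 10, seed = 1) {
  stopifnot(q_star > 0, q_star < 1, p_route >= 0, p_route <= 1, rate > 0,
            t_end > 0, v > 0)
  if (!is.null(linger) && is.data.frame(linger))
    stopifnot(all(linger$duration > 0))
  structure(list(q_star = q_star, p_route = p_route, rate = rate,
                 t_end = t_end, v = v, L = L, gate_offset = gate_offset,
                 linger = linger, linger_duration = linger_duration,
                 seed = seed),
            class = "synth_event_spec")
}

#' Synthesize a gate-event stream with known truth
#'
#' Generates mother- and daughter-gate crossing events (and cell
#' trajectories at a 0.5 ms cadence) for the virtual bifurcation described
#' in its specification object. The long-run daughter-1 routing frequency
#' converges to the true routing probability; planted lingering episodes
#' appear as stalls of the specified duration at the apex.
#'
#' Geometry: mother runs along x from -L to the apex at the origin;
#' daughters leave at +-45 degrees. Segment ids: 1 = mother, 2 = daughter 1,
#' 3 = daughter 2. Mother crossings are logged at gate "exit", daughter
#' crossings at gate "entry".
#'
#' @param spec a [synth_event_spec()].
#' @param trajectories logical; also emit sampled trajectories.
#' @return list with `events` (tibble: cell_id, segment_id, gate, time,
#'   direction), `flows` (tibble: segment_id, Q, constant in time),
#'   `trajectories` (tibble: cell_id, time, x, y) and `truth` (list:
#'   p_route, q_star, routed, gamma_true, linger table, junction geometry).
#' @export
synthesize_event_stream <- function(spec, trajectories = TRUE) {
  stopifnot(inherits(spec, "synth_event_spec"))
  with_seed(spec$seed, {
    arr <- cumsum(stats::rexp(ceiling(spec$rate * spec$t_end * 1.5),
                              spec$rate))
    arr <- arr[arr < spec$t_end]
    n <- length(arr)
    route <- stats::runif(n) < spec$p_route
    lg <- spec$linger
    if (is.numeric(lg) && length(lg) == 1) {
      pick <- if (lg > 0) seq_len(min(lg, n)) * max(1, floor(n / max(lg, 1)))
      else integer(0)
      pick <- pick[pick <= n]
      lg <- tibble::tibble(cell_id = pick,
                           duration = rep(spec$linger_duration,
                                          length(pick)))
    }
    if (is.null(lg)) lg <- tibble::tibble(cell_id = integer(0),
                                          duration = numeric(0))
    stall <- numeric(n)
    stall[lg$cell_id[lg$cell_id <= n]] <- lg$duration[lg$cell_id <= n]
    v <- spec$v; L <- spec$L; g <- spec$gate_offset
    t_mother <- arr                        # mother exit-gate crossing
    t_apex_in <- arr + (L - 0) / v         # reach apex
    t_apex_out <- t_apex_in + stall        # leave apex after any stall
    t_daughter <- t_apex_out + g / v
    events <- dplyr::bind_rows(
      tibble::tibble(cell_id = seq_len(n), segment_id = 1L, gate = "exit",
                     time = t_mother, direction = 1L),
      tibble::tibble(cell_id = seq_len(n),
                     segment_id = ifelse(route, 2L, 3L), gate = "entry",
                     time = t_daughter, direction = 1L))
    events <- dplyr::arrange(events[events$time < spec$t_end, ], .data$time)
    flows <- tibble::tibble(segment_id = 1:3,
                            Q = c(1, spec$q_star, 1 - spec$q_star))
    traj <- NULL
    if (trajectories) {
      dirs <- rbind(c(sqrt(0.5), sqrt(0.5)), c(sqrt(0.5), -sqrt(0.5)))
      rows <- lapply(seq_len(n), function(i) {
        tt <- seq(arr[i] - 2, t_daughter[i] + 3 / v, by = 0.5)
        tt <- tt[tt >= 0 & tt <= spec$t_end]
        if (!length(tt)) return(NULL)
        s <- numeric(length(tt)) # distance past mother gate
        pos <- matrix(0, length(tt), 2)
        for (k in seq_along(tt)) {
          t <- tt[k]
          if (t <= t_apex_in[i]) {
            x <- -L + v * (t - arr[i]) # may start slightly upstream
            pos[k, ] <- c(x, 0)
          } else if (t <= t_apex_out[i]) {
            pos[k, ] <- c(0, 0) # stalled at the apex
          } else {
            d <- v * (t - t_apex_out[i])
            pos[k, ] <- dirs[if (route[i]) 1 else 2, ] * d
          }
        }
        tibble::tibble(cell_id = i, time = tt, x = pos[, 1], y = pos[, 2])
      })
      traj <- dplyr::bind_rows(rows)
    }
    list(events = events, flows = flows, trajectories = traj,
         truth = list(p_route = spec$p_route, q_star = spec$q_star,
                      n_cells = n, routed_d1 = sum(route),
                      gamma_true = length(unique(lg$cell_id[lg$cell_id <= n])) /
                        max(n, 1),
                      linger = lg[lg$cell_id <= n, ],
                      apex = c(0, 0), mother_gate = c(-L, 0),
                      v = v, gate_offset = g))
  })
}

#' Analytic velocity-field snapshot on a fixture
#'
#' Samples a closed-form profile on the staggered grid of a fixture
#' channel: plane Poiseuille (`parabolic`), uniform plug (`constant`), or a
#' skewed profile (parabola times a linear tilt, reducing to parabolic at
#' `skew = 0`). Used to test flow and wall-shear statistics against closed
#' forms.
#'
#' @param profile one of `"parabolic"`, `"constant"`, `"skewed"`.
#' @param graph a fixture `rbc_network` (straight channel expected).
#' @param q per-depth flux in um^2/ms (parabolic/skewed) or plug speed in
#'   um/ms (constant).
#' @param h grid spacing in um.
#' @param skew skew parameter in [-1, 1].
#' @return an `rbc_fluid_state` with the sampled field.
#' @export
synthesize_velocity_field <- function(profile = c("parabolic", "constant",
                                                  "skewed"),
                                      graph, q = 100, h = 0.5, skew = 0) {
  profile <- match.arg(profile)
  st <- fluid_state(graph, h)
  w <- graph$segments$diameter[1]
  cu <- u_coords(st)
  yy <- rep(cu$y, each = st$nx + 1)
  eta <- 2 * yy / w # -1..1 across the channel (centerline at y = 0)
  uprof <- switch(profile,
                  constant = rep(q, length(yy)),
                  parabolic = 1.5 * (q / w) * (1 - eta^2),
                  skewed = 1.5 * (q / w) * (1 - eta^2) * (1 + skew * eta))
  uprof[abs(eta) > 1] <- 0
  st$u <- matrix(uprof, st$nx + 1, st$ny)
  st$v <- matrix(0, st$nx, st$ny + 1)
  st
}
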