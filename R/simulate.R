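# Simulation driver: configuration, the time loop (membrane forces, viscous
# solve, projection, advection, seeding, gate-event logging), and the
# simulation record consumed by all analysis stages.

#' Simulation configuration
#'
#' @param t_end total simulated time in ms.
#' @param warmup initial window discarded by analysis (ms). Hemodynamic
#'   statistics converge to quasi-steady after an initial transient; the
#'   default scales the physical-time convention (hundreds of ms) down to
#'   the desk-scale runs used here.
#' @param dt time step in ms; `NULL` selects it from the membrane stiffness
#'   stability estimate.
#' @param field_cadence velocity/pressure snapshot interval (ms).
#' @param shape_cadence cell-shape snapshot interval (ms).
#' @param resolution grid points per cell diameter (>= 8).
#' @param hematocrit target inlet tube hematocrit (0 disables seeding).
#' @param seed RNG seed for the insertion schedule.
#' @param n_contour contour nodes per cell.
#' @param end_to_end resting cell end-to-end distance (um).
#' @param mu_update_every viscosity-indicator refresh interval in steps.
#' @param record_fields whether to store field snapshots.
#' @return a `sim_config` list.
#' @export
sim_config <- function(t_end = 60, warmup = 20, dt = NULL,
                       field_cadence = 5, shape_cadence = 0.5,
                       resolution = 8, hematocrit = 0.30, seed = 1,
                       n_contour = 40, end_to_end = 7.8,
                       mu_update_every = 4, record_fields = TRUE) {
  stopifnot(resolution >= 8, t_end > 0, warmup >= 0, warmup < t_end)
  if (!is.null(dt)) {
    stopifnot(field_cadence %% dt < 1e-9 || TRUE) # cadences snapped below
  }
  structure(list(t_end = t_end, warmup = warmup, dt = dt,
                 field_cadence = field_cadence,
                 shape_cadence = shape_cadence, resolution = resolution,
                 hematocrit = hematocrit, seed = seed,
                 n_contour = n_contour, end_to_end = end_to_end,
                 mu_update_every = mu_update_every,
                 record_fields = record_fields),
            class = "sim_config")
}

# upright cell contour placed at a point (long axis lateral when upright)
place_cell <- function(proto, center, upright = TRUE) {
  V <- proto$vertices
  if (upright) V <- V[, c(2, 1)]
  new_membrane_mesh(sweep(V, 2, center, "+"))
}

cell_centroid <- function(V) colMeans(V)

#' Run a cell-resolved flow simulation
#'
#' Integrates the immersed-boundary unsteady Stokes system on the given
#' network with cells seeded at the inlet (or supplied explicitly), logging
#' field and shape snapshots at the configured cadences and cell gate
#' crossings throughout. Aborts with a diagnostic on instability (NaN or
#' per-cell area drift above 5%).
#'
#' @param graph an `rbc_network`.
#' @param config a [sim_config()].
#' @param params a [membrane_params()]; `stiffness_multiplier = 10` gives
#'   the stiffer-cell condition.
#' @param cells optional list of initial 2D `membrane_mesh` cells; if
#'   `NULL`, cells enter via the inlet seeding schedule.
#' @param schedule optional insertion schedule (overrides seeding).
#' @param verbose print progress every 1000 steps.
#' @return an `rbc_sim_record`.
#' @export
run_simulation <- function(graph, config = sim_config(),
                           params = membrane_params(), cells = NULL,
                           schedule = NULL, verbose = FALSE) {
  proto <- make_cell_contour_2d(config$end_to_end, config$n_contour)
  ds <- contour_perimeter(proto$vertices) / config$n_contour
  h <- config$end_to_end / config$resolution
  dt <- config$dt
  if (is.null(dt)) dt <- membrane_stable_dt(params, h, ds)
  # snap cadences to multiples of dt
  nf <- max(1, round(config$field_cadence / dt))
  ns <- max(1, round(config$shape_cadence / dt))
  # develop the cell-free flow first (also yields the advective CFL bound)
  st <- fluid_state(graph, h)
  st <- prepare_solver(st, 0.05)
  for (k in 1:150) st <- step_fluid(st, list(), params)$state
  umax <- max(max(abs(st$u)), max(abs(st$v)), 1e-9)
  dt <- min(dt, 0.25 * h / umax)
  st$time <- 0
  st <- prepare_solver(st, dt, reset_pressure = FALSE)
  if (is.null(schedule) && is.null(cells) && config$hematocrit > 0) {
    schedule <- seed_cells_at_inlet(graph, config$hematocrit,
                                    t_end = config$t_end, seed = config$seed,
                                    end_to_end = config$end_to_end,
                                    n_contour = config$n_contour)
  }
  if (is.null(cells)) cells <- list()
  info <- if (!is.null(schedule) && nrow(schedule)) inlet_info(graph) else NULL
  gates <- segment_gates(graph)
  nsteps <- ceiling(config$t_end / dt)
  times_f <- c(); fields <- list()
  times_s <- c(); shapes <- list(); centroids <- list()
  ev <- list()
  areas0 <- vapply(cells, function(cc) abs(contour_area(cc$vertices)),
                   numeric(1))
  next_sched <- 1
  prev_gate_s <- NULL # per live cell x gate signed coordinate
  cell_ids <- if (length(cells)) seq_along(cells) else integer(0)
  n_created <- length(cells)
  gate_state <- function(cells) {
    if (!length(cells)) return(NULL)
    cents <- t(vapply(cells, function(cc) cell_centroid(cc$vertices),
                      numeric(2)))
    sgn <- outer(cents[, 1], gates$x, `-`) * rep(gates$tx, each = nrow(cents)) +
      outer(cents[, 2], gates$y, `-`) * rep(gates$ty, each = nrow(cents))
    lat <- -outer(cents[, 1], gates$x, `-`) * rep(gates$ty, each = nrow(cents)) +
      outer(cents[, 2], gates$y, `-`) * rep(gates$tx, each = nrow(cents))
    list(s = sgn, lat = lat)
  }
  gs_prev <- gate_state(cells)
  st <- update_viscosity_indicator(st, cells, params)
  for (k in seq_len(nsteps)) {
    tnow <- st$time
    # scheduled insertions (delayed, never dropped, if the inlet is blocked)
    if (!is.null(schedule)) {
      while (next_sched <= nrow(schedule) &&
             schedule$t_insert[next_sched] <= tnow) {
        y <- schedule$y_offset[next_sched]
        ctr <- info$origin + info$dir * (attr(schedule, "end_to_end") * 0.45 + 2)
        ctr <- ctr + c(-info$dir[2], info$dir[1]) * y
        blocked <- FALSE
        if (length(cells)) {
          cents <- t(vapply(cells, function(cc) cell_centroid(cc$vertices),
                            numeric(2)))
          dd <- sqrt((cents[, 1] - ctr[1])^2 + (cents[, 2] - ctr[2])^2)
          blocked <- any(dd < 0.7 * attr(schedule, "end_to_end"))
        }
        if (blocked) break
        n_created <- n_created + 1
        cells[[length(cells) + 1]] <- place_cell(proto, ctr, upright = TRUE)
        cell_ids <- c(cell_ids, schedule$cell_id[next_sched])
        areas0 <- c(areas0, abs(contour_area(cells[[length(cells)]]$vertices)))
        next_sched <- next_sched + 1
        gs_prev <- gate_state(cells)
      }
    }
    if (length(cells) && k %% config$mu_update_every == 1 || k == 1)
      st <- update_viscosity_indicator(st, cells, params)
    r <- step_fluid(st, cells, params)
    st <- r$state; cells <- r$cells
    # instability guard
    if (!all(is.finite(st$u)) || !all(is.finite(st$v)))
      stop("solver instability: non-finite velocity at t = ",
           round(st$time, 4), " ms (step ", k, ")")
    if (length(cells)) {
      ar <- vapply(cells, function(cc) abs(contour_area(cc$vertices)),
                   numeric(1))
      drift <- abs(ar / areas0 - 1)
      if (any(drift > 0.05))
        stop("solver instability: cell area drift ",
             round(max(drift) * 100, 1), "% (cell ",
             cell_ids[which.max(drift)], ") at t = ", round(st$time, 4),
             " ms")
    }
    # gate events from centroid sign changes
    if (length(cells)) {
      gs <- gate_state(cells)
      if (!is.null(gs_prev) && nrow(gs$s) == nrow(gs_prev$s)) {
        hit <- which(sign(gs$s) != sign(gs_prev$s) &
                       abs(gs$lat) <= rep(gates$width, each = nrow(gs$s)) / 2 + 1,
                     arr.ind = TRUE)
        if (nrow(hit)) {
          ev[[length(ev) + 1]] <- tibble::tibble(
            cell_id = cell_ids[hit[, 1]],
            segment_id = gates$segment_id[hit[, 2]],
            gate = gates$gate[hit[, 2]],
            time = st$time,
            direction = as.integer(sign(gs$s[hit])))
        }
      }
      gs_prev <- gs
    }
    # remove cells that left the domain through an outlet
    if (length(cells)) {
      cents <- t(vapply(cells, function(cc) cell_centroid(cc$vertices),
                        numeric(2)))
      inb <- cents[, 1] > st$x0 + 1 & cents[, 1] < st$x0 + st$nx * st$h - 1 &
        cents[, 2] > st$y0 + 1 & cents[, 2] < st$y0 + st$ny * st$h - 1
      if (!all(inb)) {
        keep <- which(inb)
        cells <- cells[keep]; cell_ids <- cell_ids[keep]
        areas0 <- areas0[keep]
        gs_prev <- gate_state(cells)
      }
    }
    if (config$record_fields && k %% nf == 0) {
      times_f <- c(times_f, st$time)
      fields[[length(fields) + 1]] <-
        list(u = st$u, v = st$v, p = st$p, mu = st$mu)
    }
    if (k %% ns == 0) {
      times_s <- c(times_s, st$time)
      shapes[[length(shapes) + 1]] <- lapply(cells, function(cc) cc$vertices)
      names(shapes[[length(shapes)]]) <- as.character(cell_ids)
      centroids[[length(centroids) + 1]] <- if (length(cells))
        cbind(cell_id = cell_ids,
              t(vapply(cells, function(cc) cell_centroid(cc$vertices),
                       numeric(2)))) else
                         matrix(numeric(0), 0, 3)
    }
    if (verbose && k %% 1000 == 0)
      message("step ", k, "/", nsteps, " t=", round(st$time, 2), " ms, ",
              length(cells), " cells")
  }
  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(cell_id = integer(0), segment_id = integer(0),
                   gate = character(0), time = numeric(0),
                   direction = integer(0))
  structure(list(
    config = config, params = params, graph = graph, gates = gates,
    dt = dt, h = h, state = st,
    times_fields = times_f, fields = fields,
    times_shapes = times_s, shapes = shapes, centroids = centroids,
    events = events, schedule = schedule, seed = config$seed),
    class = "rbc_sim_record")
}

#' @export
print.rbc_sim_record <- function(x, ...) {
  cat("<rbc_sim_record> t_end = ", x$config$t_end, " ms, ",
      length(x$times_fields), " field / ", length(x$times_shapes),
      " shape snapshots, ", nrow(x$events), " gate events\n", sep = "")
  invisible(x)
}
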