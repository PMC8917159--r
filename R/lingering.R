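# Lingering detection at bifurcation apices: a cell lingers when it stays
# near the apex while moving much slower than its own upstream transit
# speed, for at least a minimum duration. The criterion is an
# operationalization of the qualitative notion of a cell straddling the
# apex stagnation point longer than a freely flowing cell; all three
# thresholds are explicit and configurable.

#' Lingering detection thresholds
#'
#' @param d_th apex distance threshold (um); default one feeder radius.
#' @param alpha speed factor: lingering requires speed below `alpha` times
#'   the cell's own upstream mean speed (default 0.5).
#' @param T_th minimum duration (ms); default 5x the apex transit time of a
#'   centerline tracer (2 d_th / upstream centerline speed), computed per
#'   junction when `NULL`.
#' @return a `linger_thresholds` list.
#' @export
linger_thresholds <- function(d_th = NULL, alpha = 0.5, T_th = NULL) {
  structure(list(d_th = d_th, alpha = alpha, T_th = T_th),
            class = "linger_thresholds")
}

#' Detect lingering events at one junction
#'
#' @param trajectories tibble: cell_id, time, x, y, sampled at the shape
#'   cadence (gaps longer than `T_th` inside the apex zone are reported via
#'   the `gaps` element, never silently bridged).
#' @param junction list with `apex` (length-2 position), `feeder_radius`
#'   (um) and optionally `v_ref` (centerline speed, um/ms) used for the
#'   default `T_th`.
#' @param thresholds a [linger_thresholds()].
#' @return list: `events` (tibble: cell_id, t_start, duration, min_speed),
#'   `thresholds` (resolved numeric values), `gaps` (tibble of offending
#'   cells, if any).
#' @export
detect_lingering <- function(trajectories, junction,
                             thresholds = linger_thresholds()) {
  d_th <- thresholds$d_th %||% junction$feeder_radius
  alpha <- thresholds$alpha
  T_th <- thresholds$T_th
  if (is.null(T_th)) {
    vref <- junction$v_ref %||% stop("junction$v_ref needed for default T_th")
    T_th <- 5 * (2 * d_th / vref)
  }
  ev <- list(); gaps <- list()
  for (cid in unique(trajectories$cell_id)) {
    tr <- trajectories[trajectories$cell_id == cid, ]
    tr <- tr[order(tr$time), ]
    if (nrow(tr) < 3) next
    dtv <- diff(tr$time)
    vx <- diff(tr$x) / dtv; vy <- diff(tr$y) / dtv
    sp <- c(sqrt(vx^2 + vy^2), NA_real_) # speed on [i, i+1)
    dist <- sqrt((tr$x - junction$apex[1])^2 + (tr$y - junction$apex[2])^2)
    inzone <- dist <= d_th
    if (any(inzone) && any(dtv[inzone[-length(inzone)]] > T_th)) {
      gaps[[length(gaps) + 1]] <- tibble::tibble(cell_id = cid,
                                                 max_gap = max(dtv))
    }
    # upstream mean speed: samples before first zone entry, within 3 feeder
    # radii of the apex
    first_in <- which(inzone)[1]
    if (is.na(first_in) || first_in < 2) {
      vup <- junction$v_ref %||% NA_real_
    } else {
      pre <- seq_len(first_in - 1)
      nearpre <- pre[dist[pre] <= 3 * junction$feeder_radius]
      vup <- if (length(nearpre)) mean(sp[nearpre], na.rm = TRUE) else
        mean(sp[pre], na.rm = TRUE)
    }
    if (!is.finite(vup) || vup <= 0) next
    slow <- inzone & c(sp[-length(sp)] < alpha * vup, FALSE)
    slow[is.na(slow)] <- FALSE
    r <- rle(slow)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- min(ends[k] + 1, nrow(tr))
      dur <- tr$time[i1] - tr$time[i0]
      if (dur >= T_th) {
        ev[[length(ev) + 1]] <- tibble::tibble(
          cell_id = cid, t_start = tr$time[i0], duration = dur,
          min_speed = min(sp[i0:(i1 - 1)], na.rm = TRUE))
      }
    }
  }
  list(events = if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(cell_id = integer(0), t_start = numeric(0),
                   duration = numeric(0), min_speed = numeric(0)),
    thresholds = list(d_th = d_th, alpha = alpha, T_th = T_th),
    gaps = if (length(gaps)) dplyr::bind_rows(gaps) else NULL)
}

#' Lingering fraction per junction
#'
#' gamma = (distinct lingering cells) / (distinct cells crossing the mother
#' gate); the paired difference is Delta gamma = gamma_stiffer -
#' gamma_normal.
#'
#' @param events lingering events tibble (from [detect_lingering()]).
#' @param passages vector of cell ids that crossed the mother gate (or a
#'   gate-event tibble filtered to the mother's exit gate).
#' @return scalar gamma in [0, 1].
#' @export
lingering_fraction <- function(events, passages) {
  if (is.data.frame(passages)) passages <- passages$cell_id
  npass <- length(unique(passages))
  if (npass == 0) return(NA_real_)
  length(intersect(unique(events$cell_id), unique(passages))) / npass
}

#' Linkage of partitioning and hematocrit changes with lingering changes
#'
#' Builds the paired scatters (Delta gamma, Delta_N-Q) and (Delta gamma,
#' Delta H^HF) per junction and tallies the four sign quadrants with a
#' `tol` dead zone (pairs with either coordinate inside the dead zone are
#' counted separately).
#'
#' @param deltas tibble with columns junction_id, delta_NQ, delta_H_HF,
#'   delta_gamma.
#' @param tol dead-zone half-width (default 0.02).
#' @return list: `pairs` (the input, ordered by junction), `tally_NQ` and
#'   `tally_HHF` (named counts: `++`, `+-`, `-+`, `--`, `dead`).
#' @export
linkage_tables <- function(deltas, tol = 0.02) {
  tally <- function(x, y) {
    dead <- abs(x) <= tol | abs(y) <= tol | is.na(x) | is.na(y)
    q <- paste0(ifelse(x > 0, "+", "-"), ifelse(y > 0, "+", "-"))
    out <- c(`++` = sum(q == "++" & !dead), `+-` = sum(q == "+-" & !dead),
             `-+` = sum(q == "-+" & !dead), `--` = sum(q == "--" & !dead),
             dead = sum(dead))
    out
  }
  list(pairs = dplyr::arrange(deltas, .data$junction_id),
       tally_NQ = tally(deltas$delta_gamma, deltas$delta_NQ),
       tally_HHF = tally(deltas$delta_gamma, deltas$delta_H_HF))
}

# trajectories tibble from a simulation record
record_trajectories <- function(record) {
  out <- list()
  for (i in seq_along(record$times_shapes)) {
    cm <- record$centroids[[i]]
    if (!nrow(cm)) next
    out[[length(out) + 1]] <- tibble::tibble(
      cell_id = as.integer(cm[, 1]), time = record$times_shapes[i],
      x = cm[, 2], y = cm[, 3])
  }
  dplyr::bind_rows(out)
}

# junction descriptor for detect_lingering from a record
record_junction <- function(record, junction_id) {
  jn <- record$graph$junctions
  row <- which(jn$id == junction_id)
  mother <- jn$mothers[[row]][1]
  rf <- record$graph$segments$diameter[
    record$graph$segments$id == mother] / 2
  # centerline tracer speed: mean mother mid-gate centerline velocity from
  # the last stored field
  g <- record$gates[record$gates$segment_id == mother &
                      record$gates$gate == "mid", ]
  stv <- field_state(record, length(record$fields))
  U <- interpolate_velocity(stv, cbind(g$x, g$y))
  vref <- abs(U[1, 1] * g$tx + U[1, 2] * g$ty)
  list(apex = jn$apex[[row]], feeder_radius = rf, v_ref = max(vref, 1e-6),
       mother = mother, daughters = jn$daughters[[row]])
}
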