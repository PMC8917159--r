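# Serialization: network graphs to/from JSON (documented schema) and
# GraphML; gate-event streams to CSV. Units are recorded explicitly.

#' Write / read a network as JSON
#'
#' Schema: `units` (length, time, pressure, flow_rate), `nodes` (id, x, y,
#' role), `segments` (id, from, to, diameter, centerline as an n x 2 array),
#' `junctions` (id, type, mothers, daughters, apex), `bcs` (node_id, kind,
#' value).
#'
#' @param g an `rbc_network`.
#' @param path file path.
#' @return `network_to_json`: `path`, invisibly; `network_from_json`: an
#'   `rbc_network`.
#' @export
network_to_json <- function(g, path) {
  obj <- list(
    units = g$units,
    nodes = g$nodes,
    segments = lapply(seq_len(nrow(g$segments)), function(i) list(
      id = g$segments$id[i], from = g$segments$from[i],
      to = g$segments$to[i], diameter = g$segments$diameter[i],
      centerline = unname(g$segments$centerline[[i]]))),
    junctions = lapply(seq_len(nrow(g$junctions)), function(i) list(
      id = g$junctions$id[i], type = g$junctions$type[i],
      mothers = g$junctions$mothers[[i]],
      daughters = g$junctions$daughters[[i]],
      apex = unname(g$junctions$apex[[i]]))),
    bcs = g$bcs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname network_to_json
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- tibble::tibble(
    id = vapply(obj$nodes, function(n) as.integer(n$id), integer(1)),
    x = vapply(obj$nodes, function(n) as.numeric(n$x), numeric(1)),
    y = vapply(obj$nodes, function(n) as.numeric(n$y), numeric(1)),
    role = vapply(obj$nodes, function(n) n$role, character(1)))
  bcs <- tibble::tibble(
    node_id = vapply(obj$bcs, function(b) as.integer(b$node_id), integer(1)),
    kind = vapply(obj$bcs, function(b) b$kind, character(1)),
    value = vapply(obj$bcs, function(b) as.numeric(b$value), numeric(1)))
  segs <- obj$segments
  seg_tb <- segment_tibble(
    id = vapply(segs, function(s) as.integer(s$id), integer(1)),
    from = vapply(segs, function(s) as.integer(s$from), integer(1)),
    to = vapply(segs, function(s) as.integer(s$to), integer(1)),
    diameter = vapply(segs, function(s) as.numeric(s$diameter), numeric(1)),
    centerline = lapply(segs, function(s) {
      m <- do.call(rbind, lapply(s$centerline, function(r)
        as.numeric(unlist(r))))
      matrix(m, ncol = 2)
    }))
  jn <- obj$junctions
  jn_tb <- if (length(jn)) junction_tibble(
    id = vapply(jn, function(j) as.integer(j$id), integer(1)),
    type = vapply(jn, function(j) j$type, character(1)),
    mothers = lapply(jn, function(j) as.integer(unlist(j$mothers))),
    daughters = lapply(jn, function(j) as.integer(unlist(j$daughters))),
    apex = lapply(jn, function(j) as.numeric(unlist(j$apex)))) else
      empty_junctions()
  g <- new_rbc_network(nodes, seg_tb, jn_tb, bcs)
  validate_network(g)
  g
}

#' Export a network to GraphML
#'
#' Node positions, roles and segment diameters/arclengths are carried as
#' attributes; centerline geometry is not (GraphML is topological).
#'
#' @param g an `rbc_network`.
#' @param path file path.
#' @export
network_to_graphml <- function(g, path) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$segments$from, to = g$segments$to,
               diameter = g$segments$diameter,
               arclength = g$segments$arclength,
               segment_id = g$segments$id),
    directed = TRUE,
    vertices = data.frame(name = g$nodes$id, x = g$nodes$x, y = g$nodes$y,
                          role = g$nodes$role))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write gate events to CSV
#'
#' Columns: cell_id, gate_id (segment and gate name), time_ms, direction.
#'
#' @param events an event tibble (from a record or a synthetic stream).
#' @param path file path.
#' @export
events_to_csv <- function(events, path) {
  out <- tibble::tibble(
    cell_id = events$cell_id,
    gate_id = paste0("s", events$segment_id, ":", events$gate),
    time_ms = events$time,
    direction = events$direction)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write wall polylines to JSON
#'
#' @param walls an `rbc_walls`.
#' @param path file path.
#' @export
walls_to_json <- function(walls, path) {
  jsonlite::write_json(
    list(units = list(length = "um"),
         polylines = lapply(walls$polylines, unname),
         wall_length = walls$wall_length),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
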