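# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a comparison into one row per vessel
#'
#' @param x an `rbc_comparison`.
#' @param ... unused.
#' @return tibble joining the normal-run vessel statistics with the
#'   percentage deltas.
#' @export
tidy.rbc_comparison <- function(x, ...) {
  dplyr::left_join(x$vessels_normal, x$vessel_deltas,
                   by = c("segment_id", "d_um"))
}

#' One-row summary of a comparison
#'
#' @param x an `rbc_comparison`.
#' @param ... unused.
#' @return tibble: vessel and bifurcation counts, spatial hematocrit CVs,
#'   fraction of bifurcations with positive Delta_N-Q, mean |Delta tau|.
#' @export
glance.rbc_comparison <- function(x, ...) {
  dnq <- if (nrow(x$bifurcations)) x$bifurcations$delta_NQ else numeric(0)
  tibble::tibble(
    n_vessels = nrow(x$vessels_normal),
    n_bifurcations = nrow(x$bifurcations),
    cv_H_normal = tryCatch(spatial_cv(x$vessels_normal),
                           error = function(e) NA_real_),
    cv_H_stiffer = tryCatch(spatial_cv(x$vessels_stiffer),
                            error = function(e) NA_real_),
    frac_delta_NQ_pos = if (length(dnq)) mean(dnq > 0, na.rm = TRUE)
    else NA_real_,
    mean_abs_delta_tau = mean(abs(x$wss_delta$samples$delta_tau),
                              na.rm = TRUE))
}

#' @export
tidy.rbc_sim_record <- function(x, ...) {
  vessel_table(x)
}

#' @export
glance.rbc_sim_record <- function(x, ...) {
  tibble::tibble(
    t_end = x$config$t_end, warmup = x$config$warmup, dt = x$dt,
    n_field_snapshots = length(x$times_fields),
    n_shape_snapshots = length(x$times_shapes),
    n_gate_events = nrow(x$events),
    n_cells_seen = length(unique(x$events$cell_id)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Partitioning scatter (N* vs Q*)
#'
#' One point per bifurcation and condition; the diagonal separates regular
#' (above) from reverse (below) partitioning.
#'
#' @param object an `rbc_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rbc_comparison <- function(object, ...) {
  b <- object$bifurcations
  df <- if (nrow(b)) dplyr::bind_rows(
    tibble::tibble(Qstar = b$Qstar_normal, Nstar = b$Nstar_normal,
                   cells = "normal"),
    tibble::tibble(Qstar = b$Qstar_stiffer, Nstar = b$Nstar_stiffer,
                   cells = "stiffer")) else
      tibble::tibble(Qstar = numeric(0), Nstar = numeric(0),
                     cells = character(0))
  ggplot2::ggplot(df, ggplot2::aes(.data$Qstar, .data$Nstar,
                                   colour = .data$cells)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(normal = "#2e7d32",
                                            stiffer = "#c62828")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "flow-rate ratio Q*", y = "RBC flux ratio N*",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Flow and hematocrit convergence traces
#'
#' Q(t) and H(t) for selected vessels of one run, the standard check that
#' hemodynamic quantities have reached a quasi-steady state.
#'
#' @param record an `rbc_sim_record`.
#' @param segments segment ids (default: the two largest-flow vessels).
#' @return a ggplot.
#' @export
plot_convergence <- function(record, segments = NULL) {
  g <- record$graph
  if (is.null(segments))
    segments <- utils::head(g$segments$id, 2)
  rows <- list()
  for (sid in segments) {
    fs <- flow_series(record, g, sid, warmup = 0)
    hs <- hematocrit_series(record, g, sid, warmup = 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      segment = factor(sid), time = fs$series$time,
      value = fs$series$Q, what = "Q [um^2/ms]")
    rows[[length(rows) + 1]] <- tibble::tibble(
      segment = factor(sid), time = hs$series$time,
      value = hs$series$H, what = "H [-]")
  }
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time [ms]", y = NULL, colour = "vessel") +
    ggplot2::theme_minimal()
}

#' Wall shear stress map
#'
#' Wall samples coloured by time-averaged WSS (or by its relative change
#' when a delta table is supplied).
#'
#' @param wss an `rbc_wss_field`, or the `samples` element of [delta_tau()]
#'   output (then `delta = TRUE` colours by relative change).
#' @param delta colour by `delta_tau` instead of `tau`.
#' @return a ggplot.
#' @export
plot_wss_map <- function(wss, delta = FALSE) {
  if (delta) {
    ggplot2::ggplot(wss, ggplot2::aes(.data$x, .data$y,
                                      colour = .data$delta_tau)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_colour_gradient2(low = "#2166ac", high = "#b2182b",
                                      mid = "grey85", midpoint = 0) +
      ggplot2::coord_equal() +
      ggplot2::labs(colour = expression(Delta * tau), x = "x [um]",
                    y = "y [um]") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(wss, ggplot2::aes(.data$x, .data$y,
                                      colour = abs(.data$tau_dyn_cm2))) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_colour_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(colour = "|WSS| [dyn/cm2]", x = "x [um]", y = "y [um]") +
      ggplot2::theme_minimal()
  }
}

#' Network geometry plot
#'
#' Wall loops and centerlines; junction apexes marked.
#'
#' @param object an `rbc_network`.
#' @param walls optional `rbc_walls` to draw the lumen boundary.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rbc_network <- function(object, walls = NULL, ...) {
  cl <- dplyr::bind_rows(lapply(seq_len(nrow(object$segments)), function(i)
    tibble::tibble(segment = object$segments$id[i],
                   x = object$segments$centerline[[i]][, 1],
                   y = object$segments$centerline[[i]][, 2])))
  p <- ggplot2::ggplot(cl, ggplot2::aes(.data$x, .data$y,
                                        group = .data$segment)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [um]", y = "y [um]") +
    ggplot2::theme_minimal()
  if (!is.null(walls)) {
    wl <- dplyr::bind_rows(lapply(seq_along(walls$polylines), function(i)
      tibble::tibble(loop = i,
                     x = c(walls$polylines[[i]][, 1],
                           walls$polylines[[i]][1, 1]),
                     y = c(walls$polylines[[i]][, 2],
                           walls$polylines[[i]][1, 2]))))
    p <- p + ggplot2::geom_path(data = wl,
                                ggplot2::aes(.data$x, .data$y,
                                             group = .data$loop),
                                colour = "black")
  }
  if (nrow(object$junctions)) {
    ap <- do.call(rbind, object$junctions$apex)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(x = ap[, 1], y = ap[, 2]),
      ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE,
      colour = "#c62828", shape = 4)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
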