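# Paired-experiment orchestration: run normal and stiffer cells on identical
# geometry, boundary conditions and insertion schedule, then reduce both
# records to the full comparison report (per-vessel, per-bifurcation,
# lingering and wall-shear tables).

#' Paired-experiment configuration
#'
#' The two runs differ only in the membrane shear modulus: the stiffer run
#' multiplies G_S by `stiffness_multiplier` (10 by default); geometry,
#' boundary conditions, seeds, cadences and the insertion schedule are
#' identical.
#'
#' @param network an `rbc_network`, or a fixture name passed to
#'   [build_fixture()].
#' @param network_params fixture parameters (if `network` is a name).
#' @param bc_mode `"pressure"` or `"flow_rate"`.
#' @param stiffness_multiplier G_S factor of the stiffer run (default 10).
#' @param sim a [sim_config()].
#' @param window partitioning window length (ms).
#' @param linger a [linger_thresholds()].
#' @return an `rbc_experiment_config`.
#' @export
experiment_config <- function(network = "two_generation_net",
                              network_params = list(),
                              bc_mode = "pressure",
                              stiffness_multiplier = 10,
                              sim = sim_config(), window = 10,
                              linger = linger_thresholds()) {
  g <- if (inherits(network, "rbc_network")) network else
    build_fixture(network, network_params, bc_mode)
  structure(list(graph = g, stiffness_multiplier = stiffness_multiplier,
                 sim = sim, window = window, linger = linger),
            class = "rbc_experiment_config")
}

#' Run the paired normal-vs-stiffer experiment
#'
#' Runs the flow solver twice on identical geometry and insertion schedule
#' (normal cells, then stiffer cells), guards that the realized cell counts
#' match within 5%, and reduces both records with [analyze_only()].
#'
#' @param config an [experiment_config()].
#' @param verbose passed to [run_simulation()].
#' @return an `rbc_comparison` (see [analyze_only()]) with the two records
#'   attached as `record_normal` / `record_stiffer`.
#' @export
run_paired_experiment <- function(config, verbose = FALSE) {
  t_wall <- Sys.time()
  g <- config$graph
  schedule <- if (config$sim$hematocrit > 0)
    seed_cells_at_inlet(g, config$sim$hematocrit, t_end = config$sim$t_end,
                        seed = config$sim$seed,
                        end_to_end = config$sim$end_to_end,
                        n_contour = config$sim$n_contour) else NULL
  pn <- membrane_params()
  ps <- membrane_params(stiffness_multiplier = config$stiffness_multiplier)
  rec_n <- run_simulation(g, config$sim, pn, schedule = schedule,
                          verbose = verbose)
  rec_s <- run_simulation(g, config$sim, ps, schedule = schedule,
                          verbose = verbose)
  nin <- length(unique(rec_n$events$cell_id))
  nis <- length(unique(rec_s$events$cell_id))
  if (nin + nis > 0 && abs(nin - nis) / max(nin, nis, 1) > 0.05)
    warning("paired cell counts differ by more than 5% (", nin, " vs ",
            nis, ")")
  cmp <- analyze_only(rec_n, rec_s, window = config$window,
                      linger = config$linger)
  cmp$meta$wall_clock_s <- as.numeric(difftime(Sys.time(), t_wall,
                                               units = "secs"))
  cmp$meta$stiffness_multiplier <- config$stiffness_multiplier
  cmp
}

#' Reduce a pair of simulation records to the comparison report
#'
#' Computes per-vessel statistics and deltas, per-bifurcation partitioning
#' and lingering statistics and deltas, wall-shear-stress fields and their
#' relative change, and the lingering linkage tables -- entirely from the
#' records, so the same path serves archived and freshly simulated data.
#'
#' @param record_normal,record_stiffer `rbc_sim_record`s on the same
#'   geometry.
#' @param window partitioning window length (ms).
#' @param linger a [linger_thresholds()].
#' @param wall_resolution wall sample spacing for the WSS map (um).
#' @return an `rbc_comparison` list of tibbles: `vessels_normal`,
#'   `vessels_stiffer`, `vessel_deltas`, `bifurcations`, `linkage`,
#'   `wss_per_vessel`, `wss_by_tag`, `meta`.
#' @export
analyze_only <- function(record_normal, record_stiffer, window = 10,
                         linger = linger_thresholds(),
                         wall_resolution = NULL) {
  rn <- record_normal; rs <- record_stiffer
  g <- rn$graph
  vt_n <- vessel_table(rn)
  vt_s <- vessel_table(rs)
  vdel <- delta_metrics(vt_n, vt_s)
  Hn <- stats::setNames(vt_n$H_mean, vt_n$segment_id)
  Hs <- stats::setNames(vt_s$H_mean, vt_s$segment_id)
  # per-bifurcation: designation fixed by the normal run
  jn <- g$junctions
  brows <- list()
  for (i in seq_len(nrow(jn))) {
    if (jn$type[i] != "bifurcation") next
    jid <- jn$id[i]
    jin <- junction_event_inputs(rn, jid)
    jis <- junction_event_inputs(rs, jid)
    qbar_n <- vapply(jin$daughters, function(sid)
      mean(jin$flows$Q[jin$flows$segment_id == sid]), numeric(1))
    hi <- jin$daughters[which.max(abs(qbar_n))]
    t1n <- max(rn$times_fields); t1s <- max(rs$times_fields)
    fr_n <- flux_ratios(jin$events, jin$flows, jin$mother, hi,
                        window = window,
                        t_range = c(rn$config$warmup, t1n))
    fr_s <- flux_ratios(jis$events, jis$flows, jis$mother, hi,
                        window = window,
                        t_range = c(rs$config$warmup, t1s))
    # lingering per run
    jd <- record_junction(rn, jid)
    det_n <- detect_lingering(record_trajectories(rn), jd, linger)
    det_s <- detect_lingering(record_trajectories(rs),
                              record_junction(rs, jid), linger)
    pass_n <- jin$events[jin$events$segment_id == jin$mother &
                           jin$events$gate == "exit", ]
    pass_s <- jis$events[jis$events$segment_id == jis$mother &
                           jis$events$gate == "exit", ]
    gam_n <- lingering_fraction(det_n$events, pass_n)
    gam_s <- lingering_fraction(det_s$events, pass_s)
    hhf <- higher_flow_hematocrit(
      if (length(qbar_n)) abs(qbar_n[1]) / sum(abs(qbar_n)) else NA,
      jin$daughters, Hn, Hs)
    okM_n <- fr_n$M >= 1; okM_s <- fr_s$M >= 1
    brows[[length(brows) + 1]] <- tibble::tibble(
      junction_id = jid,
      D_feed_um = g$segments$diameter[g$segments$id == jin$mother],
      daughter_hi = hi,
      Qstar_normal = fr_n$Qstar_mean, Nstar_normal = fr_n$Nstar_mean,
      Qstar_stiffer = fr_s$Qstar_mean, Nstar_stiffer = fr_s$Nstar_mean,
      class_normal = if (okM_n) classify_partitioning(
        min(max(fr_n$Nstar_mean, 0), 1),
        min(max(fr_n$Qstar_mean, 0), 1)) else NA_character_,
      f_normal = if (okM_n) reverse_fraction(fr_n$windows) else NA_real_,
      f_stiffer = if (okM_s) reverse_fraction(fr_s$windows) else NA_real_,
      sigma_normal = if (fr_n$M >= 2) sigma_NQ(fr_n$windows) else NA_real_,
      sigma_stiffer = if (fr_s$M >= 2) sigma_NQ(fr_s$windows) else NA_real_,
      delta_NQ = if (okM_n && okM_s) delta_NQ(fr_n, fr_s) else NA_real_,
      delta_f = .subtract_na(
        if (okM_s) reverse_fraction(fr_s$windows) else NA_real_,
        if (okM_n) reverse_fraction(fr_n$windows) else NA_real_),
      H_HF_normal = hhf$H_HF_normal, H_HF_stiffer = hhf$H_HF_stiffer,
      delta_H_HF = hhf$delta_H_HF,
      gamma_normal = gam_n, gamma_stiffer = gam_s,
      delta_gamma = .subtract_na(gam_s, gam_n))
  }
  bif <- if (length(brows)) dplyr::bind_rows(brows) else tibble::tibble()
  link <- if (nrow(bif)) linkage_tables(
    tibble::tibble(junction_id = bif$junction_id, delta_NQ = bif$delta_NQ,
                   delta_H_HF = bif$delta_H_HF,
                   delta_gamma = bif$delta_gamma)) else NULL
  # wall shear stress
  if (is.null(wall_resolution))
    wall_resolution <- max(min(g$segments$diameter) / 8, rn$h / 2)
  walls <- discretize_walls(g, wall_resolution)
  wn <- wall_traction(time_average_field(rn), walls)
  ws <- wall_traction(time_average_field(rs), walls)
  dtau <- delta_tau(wn, ws, g)
  tau_n <- vessel_average_wss(wn)
  tau_s <- vessel_average_wss(ws)
  wpv <- dplyr::full_join(
    dplyr::rename(tau_n, tau_normal = "tau_mean_dyn_cm2"),
    dplyr::rename(tau_s[, c("segment_id", "tau_mean_dyn_cm2")],
                  tau_stiffer = "tau_mean_dyn_cm2"),
    by = "segment_id")
  wpv <- dplyr::left_join(wpv, dtau$per_vessel, by = "segment_id")
  structure(list(
    vessels_normal = vt_n, vessels_stiffer = vt_s, vessel_deltas = vdel,
    bifurcations = bif, linkage = link,
    wss_normal = wn, wss_stiffer = ws, wss_delta = dtau,
    wss_per_vessel = wpv, wss_by_tag = dtau$by_tag,
    record_normal = rn, record_stiffer = rs,
    meta = list(window = window,
                seed = rn$config$seed,
                t_end = rn$config$t_end, warmup = rn$config$warmup,
                version = as.character(utils::packageVersion("rbcnet")))),
    class = "rbc_comparison")
}

.subtract_na <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else a - b

#' @export
print.rbc_comparison <- function(x, ...) {
  cat("<rbc_comparison> ", nrow(x$vessels_normal), " vessels, ",
      nrow(x$bifurcations), " bifurcations\n", sep = "")
  if (nrow(x$vessels_normal)) {
    cat("  spatial CV of H: normal ",
        round(tryCatch(spatial_cv(x$vessels_normal), error = function(e) NA),
              3),
        ", stiffer ",
        round(tryCatch(spatial_cv(x$vessels_stiffer), error = function(e) NA),
              3), "\n", sep = "")
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' CSV tables (per-vessel, per-vessel deltas, per-bifurcation, WSS) plus a
#' JSON summary with the run metadata.
#'
#' @param cmp an `rbc_comparison`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(cmp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$vessels_normal, file.path(dir, "vessels_normal.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$vessels_stiffer, file.path(dir, "vessels_stiffer.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$vessel_deltas, file.path(dir, "vessel_deltas.csv"),
                   row.names = FALSE)
  if (nrow(cmp$bifurcations))
    utils::write.csv(cmp$bifurcations, file.path(dir, "bifurcations.csv"),
                     row.names = FALSE)
  utils::write.csv(cmp$wss_per_vessel, file.path(dir, "wss_per_vessel.csv"),
                   row.names = FALSE)
  summary <- list(
    meta = cmp$meta,
    spatial_cv_H = list(
      normal = tryCatch(spatial_cv(cmp$vessels_normal),
                        error = function(e) NA),
      stiffer = tryCatch(spatial_cv(cmp$vessels_stiffer),
                         error = function(e) NA)),
    linkage = cmp$linkage[c("tally_NQ", "tally_HHF")])
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
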