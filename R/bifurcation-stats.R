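# Partitioning statistics at bifurcations: windowed flow-rate and RBC-flux
# ratios, regular/reverse classification, reverse fraction f, the scatter
# statistic sigma_N,Q, and stiffer-vs-normal deltas.

#' Windowed flux ratios at a bifurcation
#'
#' Splits time into consecutive non-overlapping windows and computes, for
#' the designated daughter, Q* = (integral of daughter flow)/(integral of
#' mother flow) and N* = (net daughter cell crossings)/(net mother cell
#' crossings) per window. Windows with zero net mother crossings are marked
#' invalid (not NaN-propagated) and excluded from the averages.
#'
#' @param events gate-event tibble (cell_id, segment_id, gate, time,
#'   direction). Mother crossings are counted at the mother's exit gate,
#'   daughter crossings at the daughters' entry gates.
#' @param flows either a tibble `segment_id, Q` (constant flows) or
#'   `time, segment_id, Q` series.
#' @param mother,daughter,other_daughter segment ids.
#' @param window window length in ms (default 100, the 0.1 s convention).
#' @param t_range analysis interval `c(t0, t1)`; defaults to the event span.
#' @return list with `windows` (tibble: window, t0, t1, n_mother, n_daughter,
#'   Nstar, Qstar, valid), `Nstar_mean`, `Qstar_mean`, `M` (valid window
#'   count).
#' @export
flux_ratios <- function(events, flows, mother, daughter, other_daughter = NULL,
                        window = 100, t_range = NULL) {
  stopifnot(window > 0)
  ev_m <- events[events$segment_id == mother & events$gate == "exit", ]
  ev_d <- events[events$segment_id == daughter & events$gate == "entry", ]
  if (is.null(t_range)) {
    t0 <- 0
    t1 <- max(events$time, 0)
  } else { t0 <- t_range[1]; t1 <- t_range[2] }
  nW <- max(1, floor((t1 - t0) / window))
  widx <- function(tt) pmin(pmax(floor((tt - t0) / window) + 1, 0), nW + 1)
  cnt <- function(ev) {
    out <- numeric(nW)
    if (nrow(ev)) {
      w <- widx(ev$time)
      ok <- w >= 1 & w <= nW & ev$time >= t0 & ev$time < t0 + nW * window
      s <- rowsum(as.numeric(ev$direction[ok]), w[ok])
      out[as.integer(rownames(s))] <- s
    }
    out
  }
  n_m <- cnt(ev_m); n_d <- cnt(ev_d)
  qfun <- function(seg) {
    if (!"time" %in% names(flows)) {
      rep(flows$Q[flows$segment_id == seg], nW)
    } else {
      fl <- flows[flows$segment_id == seg, ]
      vapply(seq_len(nW), function(k) {
        sel <- fl$time >= t0 + (k - 1) * window & fl$time < t0 + k * window
        if (!any(sel)) NA_real_ else mean(fl$Q[sel])
      }, numeric(1))
    }
  }
  Qd <- qfun(daughter); Qm <- qfun(mother)
  Qstar <- Qd / Qm
  Nstar <- ifelse(n_m != 0, n_d / n_m, NA_real_)
  valid <- n_m > 0 & is.finite(Qstar)
  win <- tibble::tibble(window = seq_len(nW),
                        t0 = t0 + (seq_len(nW) - 1) * window,
                        t1 = t0 + seq_len(nW) * window,
                        n_mother = n_m, n_daughter = n_d,
                        Nstar = Nstar, Qstar = Qstar, valid = valid)
  list(windows = win,
       Nstar_mean = mean(Nstar[valid]),
       Qstar_mean = mean(Qstar[valid]),
       M = sum(valid))
}

#' Classify partitioning as regular, reverse or proportionate
#'
#' Evaluated for the daughter with the larger flow fraction: regular when
#' N* - Q* > tol (the higher-flow branch receives a disproportionately
#' higher cell fraction, the Zweifach-Fung tendency), reverse when
#' N* - Q* < -tol, proportionate within the tolerance band.
#'
#' @param Nstar,Qstar time-averaged ratios (vectors allowed).
#' @param tol proportionality tolerance (default 0.02).
#' @return character vector.
#' @export
classify_partitioning <- function(Nstar, Qstar, tol = 0.02) {
  stopifnot(all(is.na(Nstar) | (Nstar >= 0 & Nstar <= 1)),
            all(is.na(Qstar) | (Qstar >= 0 & Qstar <= 1)))
  d <- Nstar - Qstar
  ifelse(is.na(d), NA_character_,
         ifelse(d > tol, "regular", ifelse(d < -tol, "reverse",
                                           "proportionate")))
}

#' Change in partitioning disproportionality
#'
#' Delta_N-Q = (N* - Q*)_stiffer - (N* - Q*)_normal for the daughter that
#' carries the higher flow in the normal run (the designation is fixed by
#' the normal run so the comparison stays aligned if the flow split flips).
#'
#' @param normal,stiffer lists with `Nstar_mean` and `Qstar_mean` (e.g. from
#'   [flux_ratios()]), both for the normal run's higher-flow daughter.
#' @return scalar Delta_N-Q (positive: more regular with stiffer cells).
#' @export
delta_NQ <- function(normal, stiffer) {
  (stiffer$Nstar_mean - stiffer$Qstar_mean) -
    (normal$Nstar_mean - normal$Qstar_mean)
}

#' Fraction of time windows with reverse partitioning
#'
#' f = (number of windows with N* < Q*) / (number of valid windows) -- the
#' fraction of points below the N* = Q* line in the time-dependent
#' partitioning plot.
#'
#' @param windows the `windows` tibble from [flux_ratios()].
#' @return scalar f in [0, 1].
#' @export
reverse_fraction <- function(windows) {
  v <- windows[windows$valid, ]
  if (!nrow(v)) stop("no valid windows")
  mean(v$Nstar < v$Qstar)
}

#' Scatter of time-dependent partitioning
#'
#' sigma_N,Q = sqrt( sum over windows of (N*(t) - mean N*)^2 +
#' (Q*(t) - mean Q*)^2, divided by M ), with M the valid window count.
#'
#' @param windows the `windows` tibble from [flux_ratios()].
#' @return scalar sigma.
#' @export
sigma_NQ <- function(windows) {
  v <- windows[windows$valid, ]
  M <- nrow(v)
  if (M < 2) stop("need >= 2 valid windows")
  sqrt(sum((v$Nstar - mean(v$Nstar))^2 + (v$Qstar - mean(v$Qstar))^2) / M)
}

#' Hematocrit of the higher-flow daughter and its change
#'
#' The higher-flow daughter is identified from the normal run's
#' time-averaged flow split; Delta H^HF = H^HF_stiffer - H^HF_normal is an
#' absolute (not percentage) hematocrit difference.
#'
#' @param normal_q named numeric: time-averaged Q* of daughter 1 in the
#'   normal run (daughter 2 carries 1 - Q*).
#' @param daughters integer ids `c(d1, d2)`.
#' @param H_normal,H_stiffer named numeric vectors of per-vessel
#'   time-averaged hematocrit (names = segment ids).
#' @return list: `daughter` (id of the higher-flow branch), `H_HF_normal`,
#'   `H_HF_stiffer`, `delta_H_HF`.
#' @export
higher_flow_hematocrit <- function(normal_q, daughters, H_normal, H_stiffer) {
  hf <- if (normal_q >= 0.5) daughters[1] else daughters[2]
  hn <- H_normal[as.character(hf)]
  hs <- H_stiffer[as.character(hf)]
  list(daughter = hf, H_HF_normal = unname(hn), H_HF_stiffer = unname(hs),
       delta_H_HF = unname(hs - hn))
}

# events + flows of a junction extracted from a simulation record
junction_event_inputs <- function(record, junction_id,
                                  warmup = record$config$warmup) {
  jn <- record$graph$junctions
  row <- which(jn$id == junction_id)
  stopifnot(length(row) == 1)
  mother <- jn$mothers[[row]][1]
  daughters <- jn$daughters[[row]]
  keep <- which(record$times_fields >= warmup)
  fl <- list()
  for (sid in c(mother, daughters)) {
    g <- record$gates[record$gates$segment_id == sid &
                        record$gates$gate == ifelse(sid == mother, "exit",
                                                    "entry"), ]
    Q <- vapply(keep, function(i) gate_flux(field_state(record, i), g),
                numeric(1))
    fl[[length(fl) + 1]] <- tibble::tibble(
      time = record$times_fields[keep], segment_id = sid, Q = Q)
  }
  list(events = record$events[record$events$time >= warmup, ],
       flows = dplyr::bind_rows(fl), mother = mother, daughters = daughters)
}

#' Per-bifurcation summary of one simulation record
#'
#' @param record an `rbc_sim_record`.
#' @param window window length in ms.
#' @param warmup analysis warmup (ms).
#' @param tol classification tolerance.
#' @return tibble: junction_id, D_feed_um, daughter_hi (higher-flow daughter
#'   of THIS run), Qstar, Nstar, class, f, sigma_NQ, M.
#' @export
bifurcation_table <- function(record, window = 10,
                              warmup = record$config$warmup, tol = 0.02) {
  jn <- record$graph$junctions
  rows <- list()
  for (i in seq_len(nrow(jn))) {
    if (jn$type[i] != "bifurcation") next
    ji <- junction_event_inputs(record, jn$id[i], warmup)
    t1 <- max(record$times_fields)
    # designate the higher-flow daughter of this run
    qbar <- vapply(ji$daughters, function(sid)
      mean(ji$flows$Q[ji$flows$segment_id == sid]), numeric(1))
    qm <- mean(ji$flows$Q[ji$flows$segment_id == ji$mother])
    hi <- ji$daughters[which.max(abs(qbar))]
    fr <- flux_ratios(ji$events, ji$flows, ji$mother, hi,
                      window = window, t_range = c(warmup, t1))
    hasW <- fr$M >= 1
    rows[[length(rows) + 1]] <- tibble::tibble(
      junction_id = jn$id[i],
      D_feed_um = record$graph$segments$diameter[
        record$graph$segments$id == ji$mother],
      daughter_hi = hi,
      Qstar = fr$Qstar_mean, Nstar = fr$Nstar_mean,
      class = if (hasW) classify_partitioning(
        min(max(fr$Nstar_mean, 0), 1), min(max(fr$Qstar_mean, 0), 1), tol)
      else NA_character_,
      f = if (hasW) reverse_fraction(fr$windows) else NA_real_,
      sigma_NQ = if (fr$M >= 2) sigma_NQ(fr$windows) else NA_real_,
      M = fr$M)
  }
  dplyr::bind_rows(rows)
}
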