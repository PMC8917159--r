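# shared fixtures and a per-session cache for expensive solver runs

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, fun) {
  if (!exists(name, envir = .run_cache)) assign(name, fun(), envir = .run_cache)
  get(name, envir = .run_cache)
}

channel_graph <- function(diameter = 12, length = 100,
                          bc_mode = "pressure", q = NULL) {
  g <- build_fixture("straight_channel",
                     list(diameter = diameter, length = length), bc_mode)
  if (!is.null(q)) g$bcs$value[g$bcs$kind == "flow_rate"] <- q
  g
}

# steady cell-free channel flow at a given cross-channel resolution
steady_channel <- function(npts, nstep = 400, bc_mode = "pressure",
                           q = NULL, diameter = 12, length = 100) {
  g <- channel_graph(diameter, length, bc_mode, q)
  st <- prepare_solver(fluid_state(g, diameter / npts), dt = 0.05)
  pp <- membrane_params()
  for (k in seq_len(nstep)) st <- step_fluid(st, list(), pp)$state
  st
}

channel_flux <- function(st, x = NULL) {
  g <- st$graph
  gates <- segment_gates(g)
  gm <- gates[gates$gate == "mid" & gates$segment_id == 1, ]
  if (!is.null(x)) { gm$x <- x }
  gate_flux(st, gm)
}

# effective distance between the two pressure-fixed planes of a channel
pressure_plane_distance <- function(st) {
  buf <- st$ops$Ap$ptype == 2L
  xb <- p_coords(st)$x[((which(buf) - 1) %% st$nx) + 1]
  max(xb) - min(xb)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

fixture_chan_seeded <- function() cached("chan_seeded", function() {
  g <- channel_graph(diameter = 12, length = 70, bc_mode = "flow_rate",
                     q = 0.45)
  cfg <- sim_config(t_end = 10, warmup = 3, hematocrit = 0.2,
                    resolution = 12, seed = 4, field_cadence = 2,
                    shape_cadence = 0.5)
  run_simulation(g, cfg, membrane_params())
})

fixture_null_pair <- function() cached("null_pair", function() {
  g <- channel_graph(diameter = 12, length = 60, bc_mode = "flow_rate",
                     q = 0.45)
  cfg <- experiment_config(
    network = g, stiffness_multiplier = 1,
    sim = sim_config(t_end = 6, warmup = 2, hematocrit = 0.15,
                     resolution = 10, seed = 3, field_cadence = 2),
    window = 2)
  run_paired_experiment(cfg)
})

fixture_y_seeded <- function() cached("y_seeded", function() {
  g <- build_fixture("y_bifurcation",
                     list(d_mother = 12, d1 = 9, d2 = 9, L_mother = 35,
                          L_daughter = 40), bc_mode = "flow_rate")
  g$bcs$value[g$bcs$kind == "flow_rate"] <- 0.35
  cfg <- sim_config(t_end = 14, warmup = 4, hematocrit = 0.15,
                    resolution = 12, seed = 2, field_cadence = 2,
                    shape_cadence = 0.5)
  run_simulation(g, cfg, membrane_params())
})
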