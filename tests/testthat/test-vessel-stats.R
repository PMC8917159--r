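# a hand-built minimal record: two cells parked in a straight channel
toy_record <- function(ylift = 0) {
  g <- channel_graph(diameter = 12, length = 100, bc_mode = "flow_rate",
                     q = 1.25)
  st <- synthesize_velocity_field("parabolic", g, q = 104.1667, h = 0.5)
  st <- prepare_solver(st, dt = 0.05)
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  mk <- function(cx, cy, R) rbcnet:::new_membrane_mesh(
    cbind(cx + R * cos(th), cy + R * sin(th)))
  cells <- list(mk(30, ylift, 2.5), mk(60, ylift, 1.5))
  shapes <- lapply(cells, function(cc) cc$vertices)
  names(shapes) <- c("1", "2")
  cents <- cbind(cell_id = 1:2,
                 t(vapply(cells, function(cc) colMeans(cc$vertices),
                          numeric(2))))
  structure(list(
    config = sim_config(t_end = 2, warmup = 0, hematocrit = 0),
    graph = g, gates = segment_gates(g), dt = 0.05, h = 0.5, state = st,
    times_fields = c(1, 2),
    fields = list(list(u = st$u, v = st$v, p = st$p, mu = st$mu),
                  list(u = st$u, v = st$v, p = st$p, mu = st$mu)),
    times_shapes = c(1, 2), shapes = list(shapes, shapes),
    centroids = list(cents, cents),
    events = tibble::tibble(cell_id = integer(0), segment_id = integer(0),
                            gate = character(0), time = numeric(0),
                            direction = integer(0)),
    seed = 1), class = "rbc_sim_record")
}

test_that("hematocrit equals the exact polygon-area fraction", {
  rec <- toy_record()
  hs <- hematocrit_series(rec, segment = 1, warmup = 0)
  span <- rec$gates$s[rec$gates$segment_id == 1 & rec$gates$gate == "exit"] -
    rec$gates$s[rec$gates$segment_id == 1 & rec$gates$gate == "entry"]
  area_oracle <- sum(vapply(rec$shapes[[1]], function(V)
    abs(rbcnet:::contour_area(V)), numeric(1)))
  expect_equal(hs$H_mean, area_oracle / (span * 12), tolerance = 1e-6)
  expect_equal(hs$H_cv, 0) # identical snapshots
})

test_that("assignment follows the gate rule", {
  rec <- toy_record()
  a <- assign_cells_to_vessels(rec)
  expect_true(all(a$owner_type == "segment" & a$owner_id == 1))
  # a centroid near a junction apex lands in the junction region
  gy <- build_fixture("y_bifurcation")
  jnode <- c(gy$nodes$x[2], gy$nodes$y[2])
  own <- rbcnet:::owner_of(gy, rbind(jnode, c(10, 0)))
  expect_equal(own$type, c("junction", "segment"))
})

test_that("flow series matches the analytic Poiseuille snapshot", {
  rec <- toy_record()
  fs <- flow_series(rec, segment = 1, warmup = 0)
  expect_rel(fs$Q_mean, 104.1667, 0.01)
  expect_equal(fs$Q_cv, 0) # steady field
})

test_that("percentage deltas follow their definitions", {
  vt <- function(H, Q, R) tibble::tibble(
    segment_id = 1L, d_um = 12, H_mean = H, H_cv = 0, Q_mean = Q, Q_cv = 0,
    dp_Pa = 1, R = R, cell_length_um = NA_real_, CFL_um = NA_real_)
  d <- delta_metrics(vt(0.20, 2, 5), vt(0.25, 1.4, 6))
  expect_equal(d$delta_H_pct, 25)
  expect_equal(d$delta_Q_pct, -30)
  expect_equal(d$delta_R_pct, 20)
  d0 <- delta_metrics(vt(0.2, 2, 5), vt(0.2, 2, 5))
  expect_equal(unlist(d0[, c("delta_H_pct", "delta_Q_pct", "delta_R_pct")]),
               c(delta_H_pct = 0, delta_Q_pct = 0, delta_R_pct = 0))
  # near-zero flow is flagged and suppressed (relative to the network mean)
  vt2 <- function(H, Q, R) tibble::tibble(
    segment_id = 1:2, d_um = 12, H_mean = H, H_cv = 0, Q_mean = Q, Q_cv = 0,
    dp_Pa = 1, R = R, cell_length_um = NA_real_, CFL_um = NA_real_)
  dna <- delta_metrics(vt2(0.2, c(1e-9, 2), 5), vt2(0.2, c(1, 2), 5))
  expect_true(dna$flagged[1] && !dna$flagged[2])
  expect_true(is.na(dna$delta_Q_pct[1]))
})

test_that("spatial CV uses the population standard deviation and is
           order-invariant", {
  vt <- tibble::tibble(H_mean = c(0.2, 0.3))
  expect_equal(spatial_cv(vt), 0.2)
  expect_equal(spatial_cv(vt[2:1, ]), 0.2)
  expect_equal(spatial_cv(tibble::tibble(H_mean = rep(0.25, 5))), 0)
  expect_error(spatial_cv(tibble::tibble(H_mean = 0.2)), ">= 2")
})

test_that("cross-section profile: symmetry, sign convention and CFL", {
  rec0 <- toy_record(ylift = 0)
  pr0 <- cross_section_profile(rec0, segment = 1, station = 30, warmup = 0)
  expect_lt(abs(pr0$skewness), 1e-9)
  rec2 <- toy_record(ylift = 2.5)
  pr2 <- cross_section_profile(rec2, segment = 1, station = 30, warmup = 0)
  expect_gt(pr2$skewness, 0) # occupancy shifted to positive lateral side
  # CFL: cell of radius 2.5 centered at ylift 0: wall gap = 6 - 2.5
  expect_equal(pr0$cfl, 3.5, tolerance = 0.05)
})
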