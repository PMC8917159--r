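test_that("time averaging is exact for steady, antisymmetric and pulsed
           fields", {
  rec <- list(
    state = synthesize_velocity_field(
      "parabolic", channel_graph(), q = 100, h = 0.5),
    config = sim_config(t_end = 10, warmup = 0))
  base <- rec$state
  mk <- function(f) list(u = f * base$u, v = base$v, p = base$p, mu = base$mu)
  rec$fields <- list(mk(1), mk(1)); rec$times_fields <- c(1, 2)
  class(rec) <- "rbc_sim_record"
  av <- time_average_field(rec, warmup = 0)
  expect_equal(av$u, base$u)
  rec$fields <- list(mk(1), mk(-1))
  av0 <- time_average_field(rec, warmup = 0)
  expect_equal(max(abs(av0$u)), 0)
  # sinusoidal pulsation over whole periods averages to the mean amplitude
  ts <- seq(0, 2, length.out = 17)[-17]
  rec$fields <- lapply(ts, function(t) mk(1 + 0.5 * sin(2 * pi * t)))
  rec$times_fields <- ts
  avp <- time_average_field(rec, warmup = 0)
  expect_lt(max(abs(avp$u - base$u)), 1e-6 * max(abs(base$u)))
})

test_that("wall traction recovers the plane-Poiseuille wall shear", {
  g <- channel_graph()
  st <- synthesize_velocity_field("parabolic", g, q = 200, h = 0.375)
  w <- discretize_walls(g, resolution = 1)
  wt <- wall_traction(st, w)
  tau_a <- Pa_to_dyn_cm2(6 * 1.2 * 200 / 144) # 6 mu Q / w^2
  mid <- wt[wt$owner_type == "segment" & abs(wt$x - 50) < 25 & !wt$flagged, ]
  expect_rel(mean(abs(mid$tau_dyn_cm2)), tau_a, 0.01)
  # linearity in the flux
  st2 <- synthesize_velocity_field("parabolic", g, q = 400, h = 0.375)
  wt2 <- wall_traction(st2, w)
  mid2 <- wt2[wt$owner_type == "segment" & abs(wt$x - 50) < 25 &
                !wt$flagged, ]
  expect_equal(mid2$tau_dyn_cm2, 2 * mid$tau_dyn_cm2, tolerance = 1e-9)
  # plug flow: interior shear estimate near zero away from ports
  stp <- synthesize_velocity_field("constant", g, q = 2, h = 0.375)
  wtp <- wall_traction(stp, w)
  midp <- wtp[wt$owner_type == "segment" & abs(wt$x - 50) < 25 &
                !wtp$flagged, ]
  expect_lt(mean(abs(midp$tau_dyn_cm2)), 0.05 * tau_a)
})

test_that("vessel averages are measure-weighted and quadrature-stable", {
  g <- channel_graph()
  st <- synthesize_velocity_field("parabolic", g, q = 200, h = 0.375)
  w1 <- discretize_walls(g, resolution = 1)
  wt <- wall_traction(st, w1)
  # constant tau on a segment: average equals the constant
  wtc <- wt; wtc$tau_dyn_cm2 <- 7.5
  expect_equal(vessel_average_wss(wtc)$tau_mean_dyn_cm2, 7.5)
  # linear tau along the wall averages to the midpoint value
  wtl <- wt
  wtl$tau_dyn_cm2 <- wtl$x # linear in arclength on each straight wall
  sub <- wtl[abs(wtl$y) > 5.9 & wtl$x > 10 & wtl$x < 90, ]
  avg <- sum(sub$tau_dyn_cm2 * sub$ds) / sum(sub$ds)
  expect_rel(avg, 50, 0.02)
  # refinement of the wall sampling changes the average by < 1%
  w2 <- discretize_walls(g, resolution = 0.5)
  wt2 <- wall_traction(st, w2)
  expect_rel(vessel_average_wss(wt2)$tau_mean_dyn_cm2,
             vessel_average_wss(wt)$tau_mean_dyn_cm2, 0.01)
})

test_that("delta tau follows its definition and is scale invariant", {
  g <- channel_graph()
  st <- synthesize_velocity_field("parabolic", g, q = 200, h = 0.5)
  w <- discretize_walls(g, resolution = 1)
  wn <- wall_traction(st, w)
  ws <- wn; ws$tau_dyn_cm2 <- wn$tau_dyn_cm2 * 1.25
  dt1 <- delta_tau(wn, ws, g)
  ok <- !is.na(dt1$samples$delta_tau)
  expect_equal(dt1$samples$delta_tau[ok], rep(0.25, sum(ok)),
               tolerance = 1e-9)
  # identical fields: zero everywhere
  dt0 <- delta_tau(wn, wn, g)
  expect_true(all(abs(dt0$samples$delta_tau[ok]) < 1e-12))
  # scaling both fields leaves the relative change unchanged
  wn2 <- wn; wn2$tau_dyn_cm2 <- 2 * wn$tau_dyn_cm2
  ws2 <- ws; ws2$tau_dyn_cm2 <- 2 * ws$tau_dyn_cm2
  dt2 <- delta_tau(wn2, ws2, g)
  expect_equal(dt2$samples$delta_tau[ok], dt1$samples$delta_tau[ok],
               tolerance = 1e-12)
})

test_that("pressure unit conversions round-trip exactly", {
  expect_equal(Pa_to_dyn_cm2(1), 10)
  expect_equal(dyn_cm2_to_Pa(Pa_to_dyn_cm2(3.7)), 3.7)
  expect_equal(mmHg_to_Pa(4.8) / 133.322387415, 4.8)
})

test_that("apex-proximal wall samples are tagged", {
  g <- build_fixture("y_bifurcation")
  w <- discretize_walls(g, resolution = 0.8)
  st <- fluid_state(g, 0.5) # zero field is fine for tagging
  wn <- wall_traction(st, w)
  ws <- wn; ws$tau_dyn_cm2 <- wn$tau_dyn_cm2 + 1
  dt <- delta_tau(wn, ws, g)
  expect_true("apex" %in% dt$samples$tag)
  ap <- g$junctions$apex[[1]]
  tagged <- dt$samples[dt$samples$tag == "apex", ]
  expect_true(all(sqrt((tagged$x - ap[1])^2 + (tagged$y - ap[2])^2) <=
                    2 * 5 + 1e-9))
})
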