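test_that("routing frequency converges to the true probability", {
  spec <- synth_event_spec(q_star = 0.6, p_route = 0.75, rate = 5,
                           t_end = 2000, seed = 0)
  ss <- synthesize_event_stream(spec, trajectories = FALSE)
  n <- ss$truth$n_cells
  expect_gt(n, 5000)
  phat <- ss$truth$routed_d1 / n
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("degenerate routing and lingering specs", {
  s1 <- synthesize_event_stream(
    synth_event_spec(p_route = 1, rate = 1, t_end = 300, seed = 2),
    trajectories = FALSE)
  expect_equal(s1$truth$routed_d1, s1$truth$n_cells)
  expect_false(any(s1$events$segment_id == 3))
  s0 <- synthesize_event_stream(
    synth_event_spec(rate = 1, t_end = 200, linger = 0, seed = 3),
    trajectories = FALSE)
  expect_equal(s0$truth$gamma_true, 0)
})

test_that("event streams are deterministic under a fixed seed", {
  a <- synthesize_event_stream(synth_event_spec(seed = 9, t_end = 300))
  b <- synthesize_event_stream(synth_event_spec(seed = 9, t_end = 300))
  expect_identical(a$events, b$events)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("analytic velocity snapshots match their closed forms", {
  g <- build_fixture("straight_channel", list(diameter = 12, length = 100))
  stp <- synthesize_velocity_field("parabolic", g, q = 120, h = 0.5)
  U <- interpolate_velocity(stp, cbind(50, 0))
  expect_rel(U[1, 1], 1.5 * 120 / 12, 0.01) # centerline 3Q/(2w)
  stc <- synthesize_velocity_field("constant", g, q = 2, h = 0.5)
  icol <- round(stc$nx / 2)
  lum <- abs(u_coords(stc)$y) < 5
  expect_true(all(abs(diff(stc$u[icol, lum])) < 1e-12)) # zero interior shear
  st0 <- synthesize_velocity_field("skewed", g, q = 120, h = 0.5, skew = 0)
  expect_equal(st0$u, stp$u)
})
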