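test_that("seeding schedules are deterministic and respect the target", {
  g <- channel_graph(bc_mode = "flow_rate", q = 1.25)
  s1 <- seed_cells_at_inlet(g, 0.30, t_end = 200, seed = 9)
  s2 <- seed_cells_at_inlet(g, 0.30, t_end = 200, seed = 9)
  expect_identical(s1, s2)
  s0 <- seed_cells_at_inlet(g, 0, t_end = 100, seed = 1)
  expect_equal(nrow(s0), 0)
})

test_that("measured inlet hematocrit hits the 30% target within 3 points", {
  g <- channel_graph(bc_mode = "flow_rate", q = 1.25)
  sch <- seed_cells_at_inlet(g, 0.30, t_end = 500, seed = 1)
  m <- measure_inlet_hematocrit(sch, warmup = 100, t_end = 500)
  expect_lt(abs(m$H_mean - 0.30), 0.03)
})

test_that("unreachable hematocrit targets error out", {
  g <- channel_graph(bc_mode = "flow_rate", q = 1.25)
  expect_error(seed_cells_at_inlet(g, 0.75, t_end = 100, seed = 1),
               "unreachable")
})
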