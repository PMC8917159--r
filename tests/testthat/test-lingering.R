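test_that("planted stalls are recovered exactly; free transits are not
           flagged", {
  spec <- synth_event_spec(rate = 0.05, t_end = 1000, v = 2,
                           linger = tibble::tibble(cell_id = c(5, 12),
                                                   duration = c(15, 24)),
                           seed = 3)
  ss <- synthesize_event_stream(spec)
  jn <- list(apex = c(0, 0), feeder_radius = 5, v_ref = 2)
  det <- detect_lingering(ss$trajectories, jn,
                          linger_thresholds(d_th = 5, alpha = 0.5, T_th = 5))
  expect_setequal(det$events$cell_id, c(5, 12))
  expect_equal(sort(det$events$duration),
               sort(c(15, 24)), tolerance = 0.5 / 15)
  # recall 1, false positives 0 against the generator truth
  expect_identical(nrow(det$events), nrow(ss$truth$linger))
})

test_that("two separated stalls of one cell give two events", {
  jn <- list(apex = c(0, 0), feeder_radius = 4, v_ref = 4)
  th <- linger_thresholds(d_th = 4, alpha = 0.5, T_th = 2)
  x1 <- c(seq(-20, 0, by = 2), rep(0, 10), seq(2, 20, by = 2), rep(20, 10))
  tr1 <- tibble::tibble(cell_id = 1L,
                        time = 0.5 * (seq_along(x1) - 1), x = x1, y = 0)
  det1 <- detect_lingering(tr1, jn, th)
  expect_equal(nrow(det1$events), 1) # the far dwell at x = 20 is outside
  x2 <- c(seq(-20, 0, by = 2), rep(0, 10), seq(2, 8, by = 2),
          seq(6, 0, by = -2), rep(0, 10), seq(2, 20, by = 2))
  tr2 <- tibble::tibble(cell_id = 1L,
                        time = 0.5 * (seq_along(x2) - 1), x = x2, y = 0)
  det2 <- detect_lingering(tr2, jn, th)
  expect_equal(nrow(det2$events), 2)
})

test_that("constant-speed transit produces no event", {
  tr <- tibble::tibble(cell_id = 1L, time = seq(0, 20, 0.5),
                       x = seq(-20, 20, length.out = 41), y = 0)
  jn <- list(apex = c(0, 0), feeder_radius = 5, v_ref = 2)
  det <- detect_lingering(tr, jn, linger_thresholds(d_th = 5, alpha = 0.5,
                                                    T_th = 2))
  expect_equal(nrow(det$events), 0)
})

test_that("gamma counts distinct lingering cells over distinct passages", {
  ev <- tibble::tibble(cell_id = c(1, 3, 3))
  expect_equal(lingering_fraction(ev, 1:20), 2 / 20)
  expect_equal(lingering_fraction(ev[0, ], 1:10), 0)
  expect_equal(0.2 - 0.3, -0.1) # delta gamma definition check
})

test_that("gamma is non-increasing in the duration threshold", {
  spec <- synth_event_spec(rate = 0.1, t_end = 2000, v = 2,
                           linger = tibble::tibble(
                             cell_id = c(3, 8, 15, 30, 44),
                             duration = c(4, 8, 12, 20, 30)), seed = 5)
  ss <- synthesize_event_stream(spec)
  jn <- list(apex = c(0, 0), feeder_radius = 5, v_ref = 2)
  pass <- ss$events[ss$events$segment_id == 1, ]
  gams <- vapply(c(2, 6, 10, 16, 25), function(Tth) {
    det <- detect_lingering(ss$trajectories, jn,
                            linger_thresholds(d_th = 5, alpha = 0.5,
                                              T_th = Tth))
    lingering_fraction(det$events, pass)
  }, numeric(1))
  expect_true(all(diff(gams) <= 0))
})

test_that("linkage tallies count sign quadrants with a dead zone", {
  d <- tibble::tibble(
    junction_id = 1:8,
    delta_NQ = c(0.1, 0.2, 0.15, 0.12, 0.3, -0.1, -0.2, 0.01),
    delta_H_HF = c(0.1, 0.1, 0.1, 0.1, 0.1, -0.1, -0.1, 0),
    delta_gamma = c(-0.1, -0.2, -0.15, -0.3, -0.12, 0.2, -0.1, 0))
  lt <- linkage_tables(d)
  expect_equal(unname(lt$tally_NQ["-+"]), 5) # gamma down, more regular
  expect_equal(unname(lt$tally_NQ["dead"]), 1)
  lt2 <- linkage_tables(d[sample.int(8), ])
  expect_equal(lt$tally_NQ, lt2$tally_NQ)
  all0 <- linkage_tables(tibble::tibble(junction_id = 1:3, delta_NQ = 0,
                                        delta_H_HF = 0, delta_gamma = 0))
  expect_equal(unname(all0$tally_NQ["dead"]), 3)
})
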