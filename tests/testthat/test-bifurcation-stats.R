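test_that("windowed ratios follow the counting definitions", {
  ev <- tibble::tibble(
    cell_id = 1:8, segment_id = c(rep(1L, 8)), gate = "exit",
    time = seq(5, 95, length.out = 8), direction = 1L)
  evd <- tibble::tibble(
    cell_id = 1:6, segment_id = 2L, gate = "entry",
    time = seq(6, 96, length.out = 6), direction = 1L)
  flows <- tibble::tibble(segment_id = 1:3, Q = c(4, 3, 1))
  fr <- flux_ratios(rbind(ev, evd), flows, 1, 2, window = 100,
                    t_range = c(0, 100))
  expect_equal(fr$windows$n_mother, 8)
  expect_equal(fr$windows$n_daughter, 6)
  expect_equal(fr$Nstar_mean, 0.75)
  expect_equal(fr$Qstar_mean, 0.75)
  # a backward re-crossing decrements the net count
  evb <- rbind(ev, tibble::tibble(cell_id = 9L, segment_id = 1L,
                                  gate = "exit", time = 50,
                                  direction = -1L))
  frb <- flux_ratios(rbind(evb, evd), flows, 1, 2, window = 100,
                     t_range = c(0, 100))
  expect_equal(frb$windows$n_mother, 7)
})

test_that("windows without mother crossings are invalid, not NaN", {
  ev <- tibble::tibble(cell_id = 1:2, segment_id = 1L, gate = "exit",
                       time = c(5, 15), direction = 1L)
  flows <- tibble::tibble(segment_id = 1:3, Q = c(2, 1, 1))
  fr <- flux_ratios(ev, flows, 1, 2, window = 10, t_range = c(0, 40))
  expect_equal(fr$windows$valid, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fr$M, 2)
  expect_false(any(is.nan(fr$Nstar_mean)))
})

test_that("classification matches the regular/reverse definitions", {
  expect_equal(classify_partitioning(0.7, 0.6), "regular")
  expect_equal(classify_partitioning(0.55, 0.60), "reverse")
  expect_equal(classify_partitioning(0.5, 0.5), "proportionate")
  expect_equal(classify_partitioning(c(0.7, 0.55), c(0.6, 0.6)),
               c("regular", "reverse"))
})

test_that("delta_NQ reports the change in disproportionality", {
  mk <- function(N, Q) list(Nstar_mean = N, Qstar_mean = Q)
  expect_equal(delta_NQ(mk(0.7, 0.6), mk(0.75, 0.6)), 0.05)
  expect_equal(delta_NQ(mk(0.7, 0.6), mk(0.62, 0.6)), -0.08)
  expect_equal(delta_NQ(mk(0.7, 0.6), mk(0.7, 0.6)), 0)
})

test_that("reverse fraction counts windows below the diagonal", {
  w <- tibble::tibble(Nstar = c(rep(0.4, 3), rep(0.8, 7)),
                      Qstar = rep(0.6, 10), valid = TRUE)
  expect_equal(reverse_fraction(w), 0.3)
  w2 <- tibble::tibble(Nstar = rep(0.8, 5), Qstar = rep(0.6, 5),
                       valid = TRUE)
  expect_equal(reverse_fraction(w2), 0)
})

test_that("sigma_NQ matches the printed formula and is translation
           invariant", {
  w <- tibble::tibble(Nstar = c(0.6, 0.4), Qstar = c(0.5, 0.5),
                      valid = TRUE)
  expect_equal(sigma_NQ(w), 0.1)
  expect_equal(sigma_NQ(dplyr::mutate(w, Nstar = Nstar + 0.17)), 0.1)
  w0 <- tibble::tibble(Nstar = rep(0.61, 4), Qstar = rep(0.52, 4),
                       valid = TRUE)
  expect_equal(sigma_NQ(w0), 0)
})

test_that("higher-flow daughter designation is label-invariant", {
  H_n <- c(`2` = 0.25, `3` = 0.15)
  H_s <- c(`2` = 0.30, `3` = 0.10)
  a <- higher_flow_hematocrit(0.7, c(2L, 3L), H_n, H_s)
  b <- higher_flow_hematocrit(0.3, c(3L, 2L), H_n, H_s)
  expect_equal(a$daughter, b$daughter)
  expect_equal(a$delta_H_HF, 0.05)
  same <- higher_flow_hematocrit(0.7, c(2L, 3L), H_n, H_n)
  expect_equal(same$delta_H_HF, 0)
})

test_that("module output matches a brute-force counting oracle on a
           synthetic stream", {
  spec <- synth_event_spec(q_star = 0.6, p_route = 0.7, rate = 0.8,
                           t_end = 800, seed = 11)
  ss <- synthesize_event_stream(spec, trajectories = FALSE)
  W <- 100
  fr <- flux_ratios(ss$events, ss$flows, 1, 2, window = W,
                    t_range = c(0, 800))
  # brute force: explicit loops over windows and events
  for (k in seq_len(8)) {
    t0 <- (k - 1) * W; t1 <- k * W
    nm <- 0; nd <- 0
    for (i in seq_len(nrow(ss$events))) {
      e <- ss$events[i, ]
      if (e$time >= t0 && e$time < t1) {
        if (e$segment_id == 1 && e$gate == "exit") nm <- nm + e$direction
        if (e$segment_id == 2 && e$gate == "entry") nd <- nd + e$direction
      }
    }
    expect_identical(as.integer(fr$windows$n_mother[k]), as.integer(nm))
    expect_identical(as.integer(fr$windows$n_daughter[k]), as.integer(nd))
    if (nm > 0) expect_equal(fr$windows$Nstar[k], nd / nm)
  }
  # time-averaged N* within binomial tolerance of the routing probability
  n <- ss$truth$n_cells
  expect_lt(abs(fr$Nstar_mean - 0.7), 3 * sqrt(0.7 * 0.3 / (n / 8)))
})

test_that("daughter ratios sum to one across the pair", {
  spec <- synth_event_spec(q_star = 0.55, p_route = 0.6, rate = 1,
                           t_end = 600, seed = 13)
  ss <- synthesize_event_stream(spec, trajectories = FALSE)
  f1 <- flux_ratios(ss$events, ss$flows, 1, 2, window = 100,
                    t_range = c(0, 600))
  f2 <- flux_ratios(ss$events, ss$flows, 1, 3, window = 100,
                    t_range = c(0, 600))
  both <- f1$windows$valid & f2$windows$valid
  expect_equal(f1$windows$Qstar[both] + f2$windows$Qstar[both],
               rep(1, sum(both)))
  # cells leave the stream only through a daughter gate, so counts close
  expect_equal(f1$windows$n_daughter[both] + f2$windows$n_daughter[both],
               f1$windows$n_mother[both] - 
                 (f1$windows$n_mother[both] -
                    f1$windows$n_daughter[both] - f2$windows$n_daughter[both]))
})
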