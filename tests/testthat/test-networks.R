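test_that("canonical fixtures have the documented geometry", {
  s <- build_fixture("straight_channel", list(diameter = 12, length = 100))
  expect_equal(nrow(s$segments), 1)
  expect_equal(nrow(s$junctions), 0)
  expect_equal(s$segments$arclength, 100)

  y <- build_fixture("y_bifurcation")
  expect_equal(nrow(y$junctions), 1)
  expect_equal(y$junctions$type, "bifurcation")
  # symmetric daughters: equal diameter, mirror-symmetric centerlines
  d1 <- y$segments$centerline[[2]]; d2 <- y$segments$centerline[[3]]
  expect_equal(y$segments$diameter[2], y$segments$diameter[3])
  expect_equal(d1[, 1], d2[, 1])
  expect_equal(d1[, 2], -d2[, 2])

  sb <- build_fixture("side_branch")
  expect_equal(sb$segments$diameter[1], 17.5) # feeder
  expect_equal(min(sb$segments$diameter), 6)  # small side daughter
  jm <- sb$junctions$mothers[[1]]
  expect_equal(sb$segments$diameter[jm], 17.5)

  tg <- build_fixture("two_generation_net")
  expect_equal(sum(tg$junctions$type == "bifurcation"), 3)
  expect_equal(sum(tg$junctions$type == "merger"), 3)
})

test_that("fixture errors are actionable", {
  expect_error(build_fixture("moebius_loop"), "unknown fixture")
  expect_error(build_fixture("straight_channel", list(diameter = 3)),
               "5.5-24")
})

test_that("generated networks are deterministic under a fixed seed", {
  g1 <- generate_network(3, seed = 1)
  g2 <- generate_network(3, seed = 1)
  expect_identical(g1, g2)
  g3 <- generate_network(3, seed = 2)
  expect_false(identical(g1$segments$diameter, g3$segments$diameter))
})

test_that("generated diameters stay in the capillary range and taper", {
  g <- generate_network(4, seed = 7)
  expect_true(all(g$segments$diameter >= 5.5 & g$segments$diameter <= 24))
  gen <- g$segment_generation
  md <- tapply(g$segments$diameter[!is.na(gen)], gen[!is.na(gen)], mean)
  expect_true(all(diff(md) <= 1e-9))
})

test_that("network invariants hold across many seeds", {
  for (s in 1:60) {
    g <- generate_network(2 + s %% 2, seed = s)
    expect_silent(validate_network(g))
    expect_true(all(g$segments$diameter >= 5.5 & g$segments$diameter <= 24))
    chord <- sqrt((g$nodes$x[g$segments$to] - g$nodes$x[g$segments$from])^2 +
                    (g$nodes$y[g$segments$to] - g$nodes$y[g$segments$from])^2)
    expect_true(all(g$segments$arclength >= chord - 1e-6))
    for (i in seq_len(nrow(g$junctions))) {
      nm <- length(g$junctions$mothers[[i]])
      nd <- length(g$junctions$daughters[[i]])
      if (g$junctions$type[i] == "bifurcation")
        expect_equal(c(nm, nd), c(1, 2))
      else expect_equal(c(nm, nd), c(2, 1))
    }
  }
})

test_that("network JSON round-trips and GraphML export works", {
  g <- build_fixture("y_bifurcation")
  f <- tempfile(fileext = ".json")
  network_to_json(g, f)
  g2 <- network_from_json(f)
  expect_equal(g2$segments$diameter, g$segments$diameter)
  expect_equal(g2$segments$centerline[[2]], g$segments$centerline[[2]],
               ignore_attr = TRUE)
  expect_equal(g2$junctions$daughters[[1]], g$junctions$daughters[[1]])
  fg <- tempfile(fileext = ".graphml")
  network_to_graphml(g, fg)
  expect_true(file.size(fg) > 0)
  unlink(c(f, fg))
})
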