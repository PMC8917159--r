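test_that("straight-channel walls are two parallel lines a diameter apart", {
  g <- build_fixture("straight_channel", list(diameter = 12, length = 100))
  w <- discretize_walls(g, resolution = 1)
  mid <- w$samples[abs(w$samples$x - 50) < 25, ]
  expect_true(all(abs(abs(mid$y) - 6) < 0.05))
  # analytic perimeter of a capsule: two walls + two end caps
  expect_rel(w$wall_length, 2 * 100 + pi * 12, 0.02)
})

test_that("all centerline points are classified inside the lumen", {
  for (nm in c("straight_channel", "curved_channel", "y_bifurcation",
               "side_branch")) {
    g <- build_fixture(nm)
    w <- discretize_walls(g, resolution = 1)
    pts <- do.call(rbind, g$segments$centerline)
    expect_true(all(wall_inside(w, pts)), label = nm)
  }
})

test_that("y-bifurcation wall length matches the analytic union perimeter", {
  g <- build_fixture("y_bifurcation",
                     list(d_mother = 10, d1 = 8, d2 = 8, angle = pi / 6))
  w <- discretize_walls(g, resolution = 0.5, blend = 0.8)
  # analytic perimeter of the union of three capsules, computed by dense
  # independent sampling of the exact (unblended) boundary
  sdf_hard <- function(pts) {
    d <- Inf
    for (i in 1:3)
      d <- pmin(d, rbcnet:::point_polyline_distance(
        pts, g$segments$centerline[[i]]) - g$segments$diameter[i] / 2)
    d
  }
  # perimeter by fine polygonization of each capsule minus interior arcs:
  # use marching on a fine grid as the independent oracle
  xs <- seq(-8, 115, by = 0.15); ys <- seq(-45, 45, by = 0.15)
  z <- matrix(sdf_hard(cbind(rep(xs, times = length(ys)),
                             rep(ys, each = length(xs)))), length(xs))
  cl <- grDevices::contourLines(xs, ys, z, levels = 0)
  per <- sum(vapply(cl, function(p)
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2)), numeric(1)))
  expect_rel(w$wall_length, per, 0.02)
})

test_that("wall sample ownership covers segments and junction regions", {
  g <- build_fixture("y_bifurcation")
  w <- discretize_walls(g, resolution = 0.8)
  expect_true(all(w$samples$owner_type %in% c("segment", "junction")))
  expect_true(any(w$samples$owner_type == "junction"))
  expect_setequal(unique(w$samples$owner_id[w$samples$owner_type ==
                                              "segment"]), 1:3)
})

test_that("resolution precondition is enforced", {
  g <- build_fixture("straight_channel")
  expect_error(discretize_walls(g, resolution = 4), "resolution")
  expect_error(discretize_walls(g, resolution = 0), "resolution")
})

test_that("gates sit inside their segments with unit tangents", {
  g <- build_fixture("side_branch")
  w <- discretize_walls(g, resolution = 1)
  gt <- segment_gates(g)
  expect_equal(nrow(gt), 9)
  expect_true(all(abs(gt$tx^2 + gt$ty^2 - 1) < 1e-9))
  expect_true(all(wall_inside(w, cbind(gt$x, gt$y))))
})
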