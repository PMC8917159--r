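test_that("interpolation of a constant field returns the constant", {
  g <- build_fixture("straight_channel", list(diameter = 12, length = 60))
  st <- fluid_state(g, 0.6)
  st$u[] <- 1.7; st$v[] <- -0.4
  set.seed(4)
  X <- cbind(runif(50, 10, 50), runif(50, -4, 4))
  U <- interpolate_velocity(st, X)
  expect_equal(U[, 1], rep(1.7, 50), tolerance = 1e-12)
  expect_equal(U[, 2], rep(-0.4, 50), tolerance = 1e-12)
})

test_that("spreading conserves total force", {
  g <- build_fixture("straight_channel", list(diameter = 12, length = 60))
  st <- fluid_state(g, 0.6)
  set.seed(5)
  X <- cbind(runif(40, 10, 50), runif(40, -4, 4))
  F <- matrix(rnorm(80), ncol = 2)
  sp <- spread_forces(st, X, F)
  expect_equal(sum(sp$fx) * st$h^2, sum(F[, 1]), tolerance = 1e-12)
  expect_equal(sum(sp$fy) * st$h^2, sum(F[, 2]), tolerance = 1e-12)
})

test_that("spread and interpolate are adjoint", {
  g <- build_fixture("straight_channel", list(diameter = 12, length = 60))
  st <- fluid_state(g, 0.6)
  set.seed(6)
  X <- cbind(runif(30, 10, 50), runif(30, -4, 4))
  F <- matrix(rnorm(60), ncol = 2)
  st$u[] <- rnorm(length(st$u)); st$v[] <- rnorm(length(st$v))
  sp <- spread_forces(st, X, F)
  lhs <- (sum(sp$fx * st$u) + sum(sp$fy * st$v)) * st$h^2
  U <- interpolate_velocity(st, X)
  rhs <- sum(F * U)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})
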