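pp <- membrane_params()

test_that("biconcave mesh has the standard discretization and size", {
  m <- make_biconcave(7.8, 4)
  expect_equal(nrow(m$faces), 5120)
  expect_equal(cell_length(m), 7.8, tolerance = 1e-9)
  m0 <- make_biconcave(7.8, 0)
  expect_equal(nrow(m0$faces), 20)
})

test_that("cell length is the max end-to-end distance and is isometric", {
  expect_equal(cell_length(rbind(c(0, 0), c(3, 4))), 5)
  m <- make_biconcave(7.8, 2)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mr <- m; mr$vertices <- m$vertices %*% t(Rz)
  expect_equal(cell_length(mr), cell_length(m), tolerance = 1e-10)
})

test_that("skalak energy is zero at reference and matches the symbolic
           density under equibiaxial stretch", {
  m <- make_biconcave(7.8, 2)
  f0 <- skalak_forces(m, pp)
  expect_lt(abs(f0$energy), 1e-20)
  expect_lt(max(abs(f0$forces)), 1e-10)
  # flat patch, lambda1 = lambda2 = 1.1
  V0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 0.9, 0))
  mm <- rbcnet:::new_membrane_mesh(V0 * 1.1, faces = matrix(1:3, 1),
                                   reference = V0)
  ee <- skalak_forces(mm, pp)
  lam2 <- 1.1^2; I1 <- 2 * lam2 - 2; I2 <- lam2^2 - 1
  W <- pp$Gs / 4 * (I1^2 + 2 * I1 - 2 * I2) + pp$C * pp$Gs / 4 * I2^2
  aref <- 0.45
  expect_equal(ee$energy / aref, W, tolerance = 1e-12)
})

test_that("skalak forces equal the finite-difference energy gradient", {
  m <- make_biconcave(7.8, 2)
  set.seed(1)
  md <- m
  md$vertices <- m$vertices + 0.05 * matrix(rnorm(length(m$vertices)),
                                            ncol = 3)
  sf <- skalak_forces(md, pp)
  E <- function(V) { mm <- md; mm$vertices <- V; skalak_forces(mm, pp)$energy }
  h <- 1e-6
  for (probe in list(c(17, 2), c(80, 1), c(140, 3))) {
    i <- probe[1]; k <- probe[2]
    Vp <- md$vertices; Vp[i, k] <- Vp[i, k] + h
    Vm <- md$vertices; Vm[i, k] <- Vm[i, k] - h
    fd <- -(E(Vp) - E(Vm)) / (2 * h)
    expect_lt(abs(fd - sf$forces[i, k]) / max(abs(fd), 1e-12), 1e-4)
  }
  # translation invariance: zero net force; zero net torque about centroid
  expect_lt(max(abs(colSums(sf$forces))), 1e-10 * max(abs(sf$forces)))
  V <- sweep(md$vertices, 2, colMeans(md$vertices))
  tq <- colSums(cbind(
    V[, 2] * sf$forces[, 3] - V[, 3] * sf$forces[, 2],
    V[, 3] * sf$forces[, 1] - V[, 1] * sf$forces[, 3],
    V[, 1] * sf$forces[, 2] - V[, 2] * sf$forces[, 1]))
  expect_lt(max(abs(tq)), 1e-8 * sum(abs(V[, 1:2]) * abs(sf$forces[, 1:2])))
})

test_that("degenerate membrane elements are reported with their id", {
  V0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0)) # zero area
  mm <- rbcnet:::new_membrane_mesh(V0, faces = matrix(1:3, 1))
  expect_error(skalak_forces(mm, pp), "triangle 1")
})

test_that("sphere bending energy approaches 8 pi kappa and improves with
           refinement", {
  errs <- vapply(1:3, function(s) {
    ic <- rbcnet:::icosphere(s)
    sph <- rbcnet:::new_membrane_mesh(ic$vertices * 2.3, ic$faces)
    abs(bending_energy(sph, pp) / (8 * pi * pp$kappa) - 1)
  }, numeric(1))
  expect_lt(errs[3], 0.03)
  expect_true(all(diff(errs) < 0))
})

test_that("bending forces match the finite-difference gradient and sum to
           zero", {
  ic <- rbcnet:::icosphere(1)
  sm <- rbcnet:::new_membrane_mesh(ic$vertices * 2, ic$faces)
  set.seed(2)
  sm$vertices <- sm$vertices + 0.03 * matrix(rnorm(length(sm$vertices)),
                                             ncol = 3)
  bf <- bending_forces(sm, pp)
  Eb <- function(V) rbcnet:::bending_energy_tri(as.vector(V), sm$faces,
                                                nrow(V), pp$kappa)
  h <- 1e-6
  for (probe in list(c(5, 1), c(20, 3))) {
    i <- probe[1]; k <- probe[2]
    Vp <- sm$vertices; Vp[i, k] <- Vp[i, k] + h
    Vm <- sm$vertices; Vm[i, k] <- Vm[i, k] - h
    fd <- -(Eb(Vp) - Eb(Vm)) / (2 * h)
    expect_lt(abs(fd - bf$forces[i, k]) / max(abs(fd), 1e-12), 1e-4)
  }
  expect_lt(max(abs(colSums(bf$forces))), 1e-9 * max(abs(bf$forces)))
})

test_that("open meshes are rejected for bending", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  mm <- rbcnet:::new_membrane_mesh(V, faces = matrix(1:3, 1))
  expect_error(bending_forces(mm, pp), "manifold")
})

test_that("2D contour: scaling, simplicity and refinement convergence", {
  ct <- make_cell_contour_2d(7.8, 64)
  expect_equal(nrow(ct$vertices), 64)
  expect_equal(cell_length(ct), 7.8, tolerance = 1e-9)
  # simple polygon: no self intersection (every vertex angle finite, area
  # close to the enclosed biconcave section)
  A <- abs(rbcnet:::contour_area(ct$vertices))
  expect_gt(A, 10)
  p512 <- rbcnet:::contour_perimeter(make_cell_contour_2d(7.8, 512)$vertices)
  p4096 <- rbcnet:::contour_perimeter(make_cell_contour_2d(7.8, 4096)$vertices)
  expect_lt(abs(p512 / p4096 - 1), 0.005)
})

test_that("2D circle bending energy matches the closed form", {
  R <- 3
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  circ <- rbcnet:::new_membrane_mesh(cbind(R * cos(th), R * sin(th)))
  cb <- bending_forces(circ, pp)
  expect_rel(cb$energy, pi * pp$kappa / R, 1e-3)
})

test_that("2D elastic forces are the gradient of the tension energy", {
  ct <- make_cell_contour_2d(7.8, 48)
  set.seed(3)
  md <- ct
  md$vertices <- ct$vertices + 0.05 * matrix(rnorm(length(ct$vertices)),
                                             ncol = 2)
  sf <- skalak_forces(md, pp)
  E <- function(V) { mm <- md; mm$vertices <- V; skalak_forces(mm, pp)$energy }
  h <- 1e-7
  Vp <- md$vertices; Vp[11, 2] <- Vp[11, 2] + h
  Vm <- md$vertices; Vm[11, 2] <- Vm[11, 2] - h
  fd <- -(E(Vp) - E(Vm)) / (2 * h)
  expect_lt(abs(fd - sf$forces[11, 2]) / abs(fd), 1e-4)
  expect_lt(max(abs(colSums(sf$forces))), 1e-9 * max(abs(sf$forces)))
})

test_that("membrane parameter defaults follow the study conditions", {
  expect_equal(pp$Gs_N_m, 5e-6)
  expect_equal(pp$lambda_visc, 5)
  expect_equal(pp$mu_interior_Pa_s, 0.006)
  ps <- membrane_params(stiffness_multiplier = 10)
  expect_equal(ps$Gs / pp$Gs, 10)
})
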