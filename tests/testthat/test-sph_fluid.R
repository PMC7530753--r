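test_that("cubic-spline kernel has compact support and the right shape", {
  h <- 9e-3
  expect_equal(sph_kernel(2 * h, h), 0)
  expect_equal(sph_kernel(3 * h, h), 0)
  expect_identical(sph_kernel_gradient(2 * h, c(1, 0, 0), h), c(0, 0, 0))
  r <- seq(0, 2.5 * h, length.out = 400)
  w <- sph_kernel(r, h)
  expect_true(all(w >= 0))
  expect_true(all(diff(w) <= 1e-12))      # non-increasing
  expect_equal(which.max(w), 1)           # maximal at r = 0
  expect_error(sph_kernel(0.1, -1), "positive")
})

test_that("kernel integrates to one over 3D space", {
  h <- 9e-3
  val <- stats::integrate(function(r) 4 * pi * r^2 * sph_kernel(r, h),
                          0, 2 * h, rel.tol = 1e-10)$value
  expect_equal(val, 1, tolerance = 1e-3)
})

test_that("kernel gradient is antisymmetric under particle exchange", {
  h <- 9e-3
  e <- c(0.6, -0.64, 0.48)
  g1 <- sph_kernel_gradient(0.007, e, h)
  g2 <- sph_kernel_gradient(0.007, -e, h)
  expect_equal(g1, -g2)
})

test_that("summation density matches the isolated and lattice oracles", {
  box <- box_geometry(1)
  m <- 3e-4; h <- 9e-3
  sys <- particle_system(matrix(c(0.5, 0, 0), 1), masses = m)
  sys <- compute_density(sys, box, h)
  expect_equal(sys$densities[1], m * sph_kernel(0, h), tolerance = 1e-12)

  # uniform lattice tuned to rho0 = 1000: interior densities within 3%
  s <- 6.3e-3
  g <- seq(-4, 4) * s
  boxl <- box_geometry(0.1008)   # exactly 16 lattice planes, periodic in x
  pos <- as.matrix(expand.grid(x = seq(0, 15) * s, y = g, z = g))
  lat <- particle_system(pos, masses = s^3 * 1000)
  lat <- compute_density(lat, boxl, h)
  interior <- abs(pos[, 2]) <= s & abs(pos[, 3]) <= s
  expect_true(all(abs(lat$densities[interior] - 1000) / 1000 < 0.03))
})

test_that("mirror-symmetric configurations give identical density multisets", {
  set.seed(5)
  pos <- cbind(runif(30, 0, 0.05), rnorm(30, 0, 0.01), rnorm(30, 0, 0.01))
  box <- box_geometry(0.05)
  a <- compute_density(particle_system(pos, masses = 2e-4), box, 9e-3)
  mir <- pos; mir[, 2] <- -mir[, 2]
  b <- compute_density(particle_system(mir, masses = 2e-4), box, 9e-3)
  expect_equal(sort(a$densities), sort(b$densities), tolerance = 1e-12)
})

test_that("Tait pressure matches direct arithmetic and is invertible", {
  expect_equal(tait_pressure(1000, 10, 1000), 0)
  expect_equal(tait_pressure(1010, 10, 1000, "squared"), 1030.505,
               tolerance = 1e-6)
  # printed-prefactor mode differs by a factor c0
  expect_equal(tait_pressure(1010, 10, 1000, "as_printed") * 10,
               tait_pressure(1010, 10, 1000, "squared"), tolerance = 1e-12)
  expect_lt(tait_pressure(990, 10, 1000), 0)
  rho <- seq(500, 2000, by = 10)
  expect_true(all(diff(tait_pressure(rho, 10, 1000)) > 0))
  # bisection recovers the density from a pressure
  target <- tait_pressure(1234, 10, 1000)
  f <- function(r) tait_pressure(r, 10, 1000) - target
  root <- uniroot(f, c(500, 2000), tol = 1e-10)$root
  expect_equal(root, 1234, tolerance = 1e-6)
})

test_that("viscous term matches direct evaluation and pair symmetry", {
  # v_ij = 0 -> 0
  expect_equal(viscous_term(c(0, 0, 0), c(0.005, 0, 0), 2000, 1, 0.01, 9e-3, 10), 0)
  # direct arithmetic: a=1, h=9e-3, c0=10, rho_ij=2000, v.r=-1e-4, r=5e-3, b=0.01
  v <- c(-0.02, 0, 0); rv <- c(0.005, 0, 0)   # v.r = -1e-4
  got <- viscous_term(v, rv, 2000, 1, 0.01, 9e-3, 10)
  expect_equal(got, -1 * 9e-3 * (10 / 2000) * (-1e-4) / (5e-3^2 + 0.01 * 9e-3^2),
               tolerance = 1e-12)
  expect_gt(got, 0)   # approaching pair -> positive (repulsive/dissipative)
  # i <-> j exchange flips both signs, leaving the term unchanged
  expect_equal(viscous_term(-v, -rv, 2000, 1, 0.01, 9e-3, 10), got,
               tolerance = 1e-15)
})

test_that("fluid pair forces are antisymmetric and match the brute-force oracle", {
  cfg <- sim_config(c0 = 5)
  box <- box_geometry(0.1)
  # two particles, equal positive pressure: equal and opposite, pointing apart
  pos2 <- rbind(c(0.05, 0, 0), c(0.058, 0, 0))
  sys2 <- particle_system(pos2, masses = 2.5e-4, densities = 1100)
  f2 <- fluid_pair_forces(sys2, box, cfg)
  expect_equal(f2[1, ], -f2[2, ], tolerance = 1e-15)
  expect_lt(f2[1, 1], 0)   # pushed apart (particle 1 sits at lower x)

  set.seed(21)
  n <- 20
  pos <- cbind(runif(n, 0, 0.05), rnorm(n, 0, 0.008), rnorm(n, 0, 0.008))
  vel <- matrix(rnorm(3 * n, 0, 0.05), n)
  rho <- runif(n, 900, 1200)
  sys <- particle_system(pos, velocities = vel, masses = 2.5e-4,
                         densities = rho)
  box <- box_geometry(0.05)
  f <- fluid_pair_forces(sys, box, cfg)
  ref <- ref_fluid_forces(pos, vel, rho, rep(2.5e-4, n), 0.05, cfg)
  expect_equal(f, ref, tolerance = 1e-10)
  # Newton's third law by construction
  expect_lt(max(abs(colSums(f))) / max(abs(f)), 1e-12)

  sys$positions[2, ] <- sys$positions[1, ]
  expect_error(fluid_pair_forces(sys, box, cfg), "overlapping")
})

test_that("viscous interaction dissipates relative kinetic energy", {
  cfg <- sim_config(c0 = 5, a = 1)
  box <- box_geometry(0.1)
  pos <- rbind(c(0.05, 0, 0), c(0.056, 0, 0))
  vel <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0))   # approaching
  sys <- particle_system(pos, velocities = vel, masses = 2.5e-4,
                         densities = 1000)   # P = 0: viscous force only
  fcb <- function(s) fluid_pair_forces(s, box, cfg)
  sys$forces <- fcb(sys)
  rel_ke <- function(s) sum((s$velocities[1, ] - s$velocities[2, ])^2)
  k0 <- rel_ke(sys)
  for (step in 1:5) {
    sys <- integrate_step(sys, fcb, 1e-3, box)
    k1 <- rel_ke(sys)
    expect_lte(k1, k0 + 1e-15)
    k0 <- k1
  }
})
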