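test_that("Hooke pair force matches direct arithmetic", {
  e <- c(1, 0, 0)
  expect_equal(hooke_pair_force(6e-3, e, 9e-2, 6e-3), c(0, 0, 0))
  # stretched bond: magnitude k (r - r0), directed toward the partner (-e)
  f <- hooke_pair_force(7e-3, e, 9e-2, 6e-3)
  expect_equal(sqrt(sum(f^2)), 9e-5, tolerance = 1e-12)
  expect_lt(f[1], 0)
  # compressed bond pushes apart
  fc <- hooke_pair_force(5e-3, e, 9e-2, 6e-3)
  expect_gt(fc[1], 0)
  # antisymmetry
  expect_equal(hooke_pair_force(7e-3, -e, 9e-2, 6e-3), -f)
})

test_that("bond forces conserve momentum and respect minimum image", {
  box <- box_geometry(0.1)
  pos <- rbind(c(0.001, 0, 0), c(0.099, 0, 0), c(0.05, 0.01, 0))
  sys <- particle_system(pos, masses = 2.5e-4, phase = "solid",
                         slice_index = 0L)
  bonds <- bond_table(c(1, 2), c(2, 3), r0 = 6e-3, k = 9e-2)
  f <- bond_forces(sys, box, bonds)
  expect_lt(max(abs(colSums(f))), 1e-18)
  # bond 1-2 crosses the boundary: separation 2e-3 < r0, so compressed
  expect_gt(f[1, 1], 0)   # pushed away from image of particle 2
})

test_that("bond table rejects self-bonds and duplicates", {
  expect_error(bond_table(1, 1, 6e-3, 9e-2), "self")
  expect_error(bond_table(c(1, 2), c(2, 1), 6e-3, 9e-2), "duplicate")
})

test_that("tether forces restore solids toward anchors and ignore fluid", {
  anchors <- rbind(c(0, 0, 0), c(0.01, 0, 0))
  sys <- particle_system(rbind(c(0, 1e-3, 0), c(0.01, 1e-3, 0)),
                         masses = 2.5e-4, phase = c("solid", "fluid"),
                         slice_index = c(0L, NA))
  th <- tether_set(anchors, 5e-4)
  f <- tether_forces(sys, th)
  expect_equal(f[1, ], c(0, -5e-7, 0), tolerance = 1e-15)
  expect_equal(f[2, ], c(0, 0, 0))
  # at the anchor: zero
  sys$positions[1, ] <- anchors[1, ]
  expect_equal(tether_forces(sys, th)[1, ], c(0, 0, 0))
})

test_that("contraction forces act radially on active slices only", {
  pos <- rbind(c(0.01, 0.02, 0),     # solid, slice 0
               c(0.03, 0, -0.015),   # solid, slice 1
               c(0.02, 0.01, 0.01),  # fluid
               c(0.05, 0, 0))        # solid on the axis, slice 2
  sys <- particle_system(pos, masses = 2.5e-4,
                         phase = c("solid", "solid", "fluid", "solid"),
                         slice_index = c(0L, 1L, NA, 2L))
  expect_equal(contraction_forces(sys, integer(0), 4e-4),
               matrix(0, 4, 3))
  f <- contraction_forces(sys, c(0L, 2L), 4e-4)
  expect_equal(f[1, ], c(0, -4e-4, 0), tolerance = 1e-15)  # y > 0: pulled down
  expect_equal(f[2, ], c(0, 0, 0))                          # slice 1 inactive
  expect_equal(f[3, ], c(0, 0, 0))                          # fluid untouched
  expect_equal(f[4, ], c(0, 0, 0))                          # on-axis: undefined
  # no axial component for any activation pattern
  f2 <- contraction_forces(sys, 0:9, 4e-4)
  expect_identical(f2[, 1], rep(0, 4))
})

test_that("a perturbed membrane relaxes toward its anchors under damped dynamics", {
  m <- build_tube(tube_preset("tiny"))
  keep <- m$system$phase == "solid"
  sys <- m$system
  idx <- cumsum(keep)
  sub <- particle_system(sys$positions[keep, , drop = FALSE],
                         masses = sys$masses[keep], phase = "solid",
                         slice_index = sys$slice_index[keep])
  bonds <- bond_table(idx[m$bonds$i], idx[m$bonds$j], m$bonds$r0, m$bonds$k)
  th <- tether_set(sub$positions, m$config$k_tether)
  set.seed(4)
  sub$positions <- sub$positions + matrix(rnorm(3 * sum(keep), 0, 5e-4),
                                          ncol = 3)
  fcb <- function(s) bond_forces(s, m$box, bonds) + tether_forces(s, th)
  sub$forces <- fcb(sub)
  pe <- function(s) 0.5 * m$config$k_tether *
    sum((s$positions - th$anchors)^2)
  e_prev <- pe(sub)
  for (chunk in 1:5) {
    for (step in 1:50) sub <- integrate_step(sub, fcb, 1e-3, m$box)
    sub$velocities[] <- 0           # overdamped limit: drain kinetic energy
    e_now <- pe(sub)
    expect_lt(e_now, e_prev)
    e_prev <- e_now
  }
})

test_that("contracting one slice shrinks its mean radius within a second", {
  m <- build_tube(tube_preset("tiny"))
  env <- tube_env(m, dT = 1, actions_per_episode = 2)
  ph <- m$system$phase == "solid"
  sl <- m$system$slice_index[ph]
  r0 <- mean(sqrt(m$system$positions[ph, 2][sl == 4]^2 +
                  m$system$positions[ph, 3][sl == 4]^2))
  env$step(4)
  rad <- sqrt(env$raw$pos[ph, 2]^2 + env$raw$pos[ph, 3]^2)
  expect_lt(mean(rad[sl == 4]), 0.7 * r0)
})
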