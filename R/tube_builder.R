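#' Tube geometry specification
#'
#' Describes a cylindrical fluid-filled tube whose wall is a single layer of
#' membrane particles arranged in rings. The axis is x, the box is periodic
#' along x with length `length`, and the membrane lies at radius
#' `diameter / 2`. Fluid is placed either on a simple-cubic lattice cropped
#' to the cylinder (`fluid_ring_counts = NULL`) or on concentric rings with
#' prescribed per-ring counts (used by the full-scale preset to reproduce an
#' exact particle count).
#'
#' @param length tube length L (m), the periodic direction.
#' @param diameter membrane diameter (m).
#' @param n_slices number of equal axial slices (contraction sections);
#'   section thickness is always `length / n_slices`.
#' @param membrane_rows number of membrane rings along the axis.
#' @param membrane_per_ring particles per membrane ring.
#' @param fluid_spacing lattice spacing for cubic fluid placement (m).
#' @param fluid_axial_planes number of axial fluid planes; defaults to
#'   `round(length / fluid_spacing)` in lattice mode.
#' @param fluid_ring_counts optional integer vector: particles per concentric
#'   fluid ring (first entry is the on-axis particle when 1); switches to
#'   ring placement.
#' @param wall_gap radial clearance between the outermost fluid and the
#'   membrane (m); defaults to the interface repulsion range so the initial
#'   state carries no interface force.
#' @param fluid_mass fluid particle mass (kg); defaults to
#'   `fluid_spacing^3 * rho0` in lattice mode (consistent summation density).
#' @param solid_mass membrane particle mass (kg).
#' @param rho0 reference density used for the default fluid mass (kg m^-3).
#' @param stagger offset alternate membrane rings by half an angular step.
#'   With the near-equilateral row spacing this triangulates the shell, so
#'   the bond network acquires shear stiffness and contracted rings unfold
#'   back to circles instead of locking into creased configurations.
#' @return An object of class `tube_geometry`.
#' @export
tube_geometry <- function(length, diameter, n_slices = 10,
                          membrane_rows, membrane_per_ring,
                          fluid_spacing = 6e-3, fluid_axial_planes = NULL,
                          fluid_ring_counts = NULL, wall_gap = 6e-3,
                          fluid_mass = NULL, solid_mass = 2.5e-4,
                          rho0 = 1000, stagger = TRUE) {
  stopifnot(length > 0, diameter > 0, n_slices >= 1,
            membrane_rows >= 1, membrane_per_ring >= 3)
  if (is.null(fluid_mass)) {
    fluid_mass <- if (is.null(fluid_ring_counts)) fluid_spacing^3 * rho0
                  else 2.5e-4
  }
  if (is.null(fluid_axial_planes))
    fluid_axial_planes <- max(1L, round(length / fluid_spacing))
  structure(list(length = length, diameter = diameter, n_slices = n_slices,
                 membrane_rows = membrane_rows,
                 membrane_per_ring = membrane_per_ring,
                 fluid_spacing = fluid_spacing,
                 fluid_axial_planes = as.integer(fluid_axial_planes),
                 fluid_ring_counts = fluid_ring_counts,
                 wall_gap = wall_gap, fluid_mass = fluid_mass,
                 solid_mass = solid_mass, rho0 = rho0, stagger = stagger),
            class = "tube_geometry")
}

#' Built-in tube presets
#'
#' `"full"` is the reference-scale model: a 0.6 m tube with a 2,500-particle
#' membrane (100 rings of 25) and 12,078 fluid particles (99 axial planes of
#' 122 arranged in concentric rings), 14,578 particles in total. The
#' fluid-plane decomposition is a reconstruction chosen to reproduce the
#' reference counts exactly; see the vignette. `"desk3d"` is a 10x shorter
#' tube with the same diameter, slice count, membrane surface density and
#' fluid particle mass (~1,000 particles), the preset used for desk-scale
#' peristalsis experiments; `"desk3d_fast"` thins its fluid slightly
#' (~800 particles) for training runs; `"tiny"` (~450 particles) is a
#' narrower tube for fast structural tests (too few fluid layers for clean
#' transport physics -- see the vignette). All physical force constants are
#' identical across presets.
#'
#' @param name one of `"full"`, `"desk3d"`, `"desk3d_fast"`, `"tiny"`.
#' @return a `tube_geometry`.
#' @export
tube_preset <- function(name = c("desk3d", "desk3d_fast", "tiny", "full")) {
  name <- match.arg(name)
  switch(name,
    full = tube_geometry(
      length = 0.6, diameter = 0.05, n_slices = 10,
      membrane_rows = 100, membrane_per_ring = 25,
      fluid_axial_planes = 99,
      fluid_ring_counts = c(1, 6, 12, 18, 24, 30, 31),
      fluid_mass = 2.5e-4, solid_mass = 2.5e-4),
    desk3d = tube_geometry(
      length = 0.06, diameter = 0.05, n_slices = 10,
      membrane_rows = 11, membrane_per_ring = 25,
      fluid_spacing = 4.6e-3, fluid_mass = 2.5e-4),
    desk3d_fast = tube_geometry(
      length = 0.06, diameter = 0.05, n_slices = 10,
      membrane_rows = 11, membrane_per_ring = 25,
      fluid_spacing = 5.2e-3, fluid_mass = 2.5e-4),
    tiny = tube_geometry(
      length = 0.06, diameter = 0.03, n_slices = 10,
      membrane_rows = 10, membrane_per_ring = 15,
      fluid_spacing = 4.6e-3, fluid_mass = 2.5e-4))
}

#' Assign axial slices
#'
#' Partitions the axial interval into `n_slices` equal intervals and returns the 0-based
#' slice index of each coordinate, `floor(x / (L / n_slices))` clamped to
#' `n_slices - 1`.
#'
#' @param x axial coordinates in the half-open tube interval.
#' @param L tube length (m).
#' @param n_slices number of slices.
#' @return integer vector of slice ids in 0..(n_slices - 1).
#' @export
assign_slices <- function(x, L, n_slices) {
  idx <- floor(x / (L / n_slices))
  as.integer(pmin(pmax(idx, 0), n_slices - 1))
}

#' Build a tube model
#'
#' Deterministically places the membrane rings and the fluid, assembles the
#' bond table (neighbours within 1.1x the membrane lattice spacing, rest
#' length equal to the actual initial pair distance), tether anchors (the
#' build positions), and the slice partition.
#'
#' @param geometry a `tube_geometry`.
#' @param config a `sim_config`.
#' @return An object of class `tube_model`: a list with elements `system`
#'   (`particle_system`), `bonds`, `tethers`, `geometry`, `box`, `config`.
#' @export
build_tube <- function(geometry, config = sim_config()) {
  L <- geometry$length
  R <- geometry$diameter / 2
  box <- box_geometry(L)

  # membrane: rings of particles on the cylinder surface
  nr <- geometry$membrane_rows
  np <- geometry$membrane_per_ring
  row_x <- (seq_len(nr) - 0.5) * L / nr
  ang0 <- 2 * pi * (seq_len(np) - 1) / np
  sx <- rep(row_x, each = np)
  off <- if (isTRUE(geometry$stagger)) (rep(seq_len(nr), each = np) %% 2) *
    pi / np else 0
  ang <- rep(ang0, times = nr) + off
  sy <- R * cos(ang)
  sz <- R * sin(ang)
  n_solid <- as.integer(nr * np)

  # fluid: cubic lattice cropped to the cylinder, or prescribed rings
  rf <- R - geometry$wall_gap
  if (rf <= 0) stop("wall_gap leaves no room for fluid")
  npl <- geometry$fluid_axial_planes
  plane_x <- (seq_len(npl) - 0.5) * L / npl
  if (is.null(geometry$fluid_ring_counts)) {
    s <- geometry$fluid_spacing
    g <- seq(-floor(rf / s), floor(rf / s)) * s
    gy <- rep(g, times = length(g))
    gz <- rep(g, each = length(g))
    keep <- sqrt(gy^2 + gz^2) <= rf
    gy <- gy[keep]; gz <- gz[keep]
    if (length(gy) == 0) stop("fluid lattice spacing too coarse for this tube")
  } else {
    counts <- geometry$fluid_ring_counts
    nringf <- length(counts) - 1L
    radii <- c(0, seq_len(nringf) / nringf * rf)
    gy <- numeric(0); gz <- numeric(0)
    for (k in seq_along(counts)) {
      ck <- counts[k]
      if (ck == 0) next
      th <- 2 * pi * (seq_len(ck) - 1) / ck
      gy <- c(gy, radii[k] * cos(th))
      gz <- c(gz, radii[k] * sin(th))
    }
  }
  per_plane <- length(gy)
  fx <- rep(plane_x, each = per_plane)
  fy <- rep(gy, times = npl)
  fz <- rep(gz, times = npl)
  n_fluid <- as.integer(npl * per_plane)

  pos <- cbind(c(fx, sx), c(fy, sy), c(fz, sz))
  phase <- c(rep("fluid", n_fluid), rep("solid", n_solid))
  masses <- c(rep(geometry$fluid_mass, n_fluid),
              rep(geometry$solid_mass, n_solid))
  slice <- c(rep(NA_integer_, n_fluid),
             assign_slices(sx, L, geometry$n_slices))
  sys <- particle_system(pos, masses = masses, phase = phase,
                         slice_index = slice,
                         densities = c(rep(config$rho0, n_fluid),
                                       rep(config$rho0, n_solid)))

  # membrane bonds: solid-solid neighbours within 1.1x the lattice spacing
  # (for staggered shells the spacing includes the diagonal neighbour)
  circ_gap <- 2 * R * sin(pi / np)
  axial_gap <- L / nr
  lat <- max(circ_gap, axial_gap)
  if (isTRUE(geometry$stagger))
    lat <- max(lat, sqrt(axial_gap^2 + (circ_gap / 2)^2))
  solid_idx <- which(sys$phase == "solid")
  ssys <- particle_system(sys$positions[solid_idx, , drop = FALSE],
                          masses = sys$masses[solid_idx], phase = "solid",
                          slice_index = sys$slice_index[solid_idx])
  nl <- build_neighbor_list(ssys, box, 1.1 * lat)
  if (nrow(nl) == 0) stop("membrane spacing too coarse: no bonds formed")
  bonds <- bond_table(solid_idx[nl$i], solid_idx[nl$j], r0 = nl$dist,
                      k = config$k)

  tethers <- tether_set(sys$positions, config$k_tether)

  structure(list(system = sys, bonds = bonds, tethers = tethers,
                 geometry = geometry, box = box, config = config,
                 n_fluid = n_fluid, n_solid = n_solid),
            class = "tube_model")
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf(paste0("<tube_model> L = %g m, D = %g m, %d fluid + %d solid ",
                     "= %d particles (%d dof), %d bonds, %d slices\n"),
              x$geometry$length, x$geometry$diameter, x$n_fluid, x$n_solid,
              x$n_fluid + x$n_solid, 3 * (x$n_fluid + x$n_solid),
              nrow(x$bonds), x$geometry$n_slices))
  invisible(x)
}

#' Degrees of freedom of a tube model
#'
#' Three positional degrees of freedom per particle.
#'
#' @param model a `tube_model`.
#' @return integer.
#' @export
dof_count <- function(model) 3L * (model$n_fluid + model$n_solid)

#' Total force on every particle of a tube model
#'
#' Assembles all force terms of the coupled model: fluid pressure and
#' viscosity, cross-phase viscosity, interface repulsion, membrane bonds,
#' tethers, and the contraction actuation on the active slices.
#'
#' @param model a `tube_model` whose system carries current densities.
#' @param active_slices integer vector of contracting slice ids.
#' @return n x 3 force matrix (N).
#' @export
total_forces <- function(model, active_slices = integer(0)) {
  force_terms(model$system, model$box, model$config,
              fluid = TRUE, cross_visc = TRUE, repulsive = TRUE,
              bonds = model$bonds, tether = model$tethers,
              active_slices = active_slices,
              contraction = length(active_slices) > 0)$forces
}
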