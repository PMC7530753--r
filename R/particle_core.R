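#' Particle system container
#'
#' The shared substrate of the simulator: per-particle positions, velocities,
#' forces, masses, densities, a phase tag (fluid or solid membrane), the
#' membrane slice index, and the periodic-boundary winding count used to
#' maintain unwrapped axial coordinates.
#'
#' @param positions n x 3 numeric matrix of positions (m); the tube axis is x.
#' @param velocities n x 3 numeric matrix of velocities (m s^-1); default rest.
#' @param masses numeric vector of particle masses (kg), recycled to n.
#' @param phase character or factor, "fluid" or "solid", recycled to n.
#' @param slice_index integer slice id in 0..(n_slices-1) for solid particles,
#'   `NA` for fluid.
#' @param densities numeric vector of densities (kg m^-3); default `NA` until
#'   evaluated.
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, velocities = NULL, masses,
                            phase = "fluid", slice_index = NA_integer_,
                            densities = NA_real_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  masses <- rep_len(as.numeric(masses), n)
  phase <- rep_len(as.character(phase), n)
  if (!all(phase %in% c("fluid", "solid"))) stop("phase must be 'fluid' or 'solid'")
  slice_index <- rep_len(as.integer(slice_index), n)
  densities <- rep_len(as.numeric(densities), n)
  if (any(masses <= 0)) stop("masses must be positive")
  if (any(is.na(slice_index) & phase == "solid") ||
      any(!is.na(slice_index) & phase == "fluid"))
    stop("slice_index must be defined exactly for solid particles")
  if (nrow(velocities) != n) stop("velocities must match positions")
  structure(list(
    positions = positions, velocities = velocities,
    forces = matrix(0, n, 3), masses = masses, densities = densities,
    phase = phase, slice_index = slice_index,
    winding_count = integer(n)
  ), class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d particles (%d fluid, %d solid)\n",
              length(x$masses), sum(x$phase == "fluid"), sum(x$phase == "solid")))
  invisible(x)
}

#' Number of particles in a system
#' @param system a `particle_system`.
#' @return integer count.
#' @export
n_particles <- function(system) nrow(system$positions)

#' Periodic box geometry
#'
#' The computational box is periodic along the tube axis (x) only; the
#' transverse directions are unbounded (the membrane confines the fluid).
#'
#' @param axial_length periodic length L along x (m).
#' @return An object of class `box_geometry`.
#' @export
box_geometry <- function(axial_length) {
  if (!is.numeric(axial_length) || axial_length <= 0)
    stop("axial_length must be positive")
  structure(list(axial_length = as.numeric(axial_length)),
            class = "box_geometry")
}

#' Map kinematic viscosity to the artificial-viscosity coefficient
#'
#' The pairwise artificial-viscosity term acts as an effective kinematic
#' viscosity nu_eff ~ a h c0 / (2 (d + 2)) in d dimensions; this solves that
#' relation for `a` given a physical viscosity. Kept as a single function so
#' the mapping can be swapped.
#'
#' @param nu kinematic viscosity (m^2 s^-1).
#' @param h smoothing length (m).
#' @param c0 reference sound speed (m s^-1).
#' @param d spatial dimension.
#' @return dimensionless coefficient `a`.
#' @export
viscous_alpha_from_nu <- function(nu, h, c0, d = 3) {
  2 * (d + 2) * nu / (h * c0)
}

#' Simulation configuration
#'
#' Physical constants and numerical settings of the tube model. Defaults are
#' the model's reference values: water-like fluid (rho0 = 1000 kg m^-3,
#' dynamic viscosity 0.1 Pa s), smoothing length h = 9e-3 m, membrane spring
#' constant k = 9e-2 N m^-1 with equilibrium distance r0 = 6e-3 m, tether
#' stiffness k' = 5e-4 N m^-1, contraction force f0 = 4e-4 N, interface
#' repulsion amplitude A = 2e-6 J, stabiliser b = 0.01 and time step
#' dt = 1e-3 s.
#'
#' @param dt time step (s).
#' @param c0 reference sound speed (m s^-1). Not a physical sound speed: a
#'   weakly-compressible numerical parameter, chosen at least ~10x the fastest
#'   expected flow speed so density fluctuations stay around 1%.
#' @param rho0 reference density (kg m^-3).
#' @param h smoothing length (m).
#' @param a dimensionless artificial-viscosity coefficient; default derived
#'   from the kinematic viscosity nu = 1e-4 m^2 s^-1 via
#'   [viscous_alpha_from_nu()].
#' @param b dimensionless denominator stabiliser of the viscous term.
#' @param k membrane bond stiffness (N m^-1).
#' @param k_tether tether spring stiffness (N m^-1).
#' @param r0_bond membrane equilibrium distance (m).
#' @param f0 contraction force magnitude per membrane particle (N).
#' @param A_repulsive interface repulsion amplitude (J).
#' @param r0_repulsive interface repulsion range (m); defaults to `r0_bond`
#'   (the same symbol plays both roles in the model), exposed independently.
#' @param nu kinematic viscosity (m^2 s^-1) used to derive `a` when `a` is not
#'   given explicitly.
#' @param tait_mode `"squared"` (prefactor c0^2 rho0 / 7, dimensionally a
#'   pressure; the standard weakly-compressible form and the default) or
#'   `"as_printed"` (prefactor c0 rho0 / 7).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, c0 = 1, rho0 = 1000, h = 9e-3,
                       a = NULL, b = 0.01, k = 9e-2, k_tether = 5e-4,
                       r0_bond = 6e-3, f0 = 4e-4, A_repulsive = 2e-6,
                       r0_repulsive = r0_bond, nu = 1e-4,
                       tait_mode = c("squared", "as_printed")) {
  tait_mode <- match.arg(tait_mode)
  if (is.null(a)) a <- viscous_alpha_from_nu(nu, h, c0)
  stopifnot(dt > 0, h > 0, b > 0, c0 > 0, rho0 > 0,
            k >= 0, k_tether >= 0, A_repulsive >= 0)
  structure(list(dt = dt, c0 = c0, rho0 = rho0, h = h, a = a, b = b,
                 k = k, k_tether = k_tether, r0_bond = r0_bond, f0 = f0,
                 A_repulsive = A_repulsive, r0_repulsive = r0_repulsive,
                 nu = nu, tait_mode = tait_mode),
            class = "sim_config")
}

# internal: parameter list handed to the compiled kernels
cpp_params <- function(config, box) {
  list(L = box$axial_length, h = config$h, c0 = config$c0, rho0 = config$rho0,
       a = config$a, b = config$b, tait_squared = config$tait_mode == "squared",
       k_tether = config$k_tether, f0 = config$f0,
       A_repulsive = config$A_repulsive, A_rep = config$A_repulsive,
       r0_rep = config$r0_repulsive)
}

#' Neighbour pair list under periodic minimum image
#'
#' Returns every unordered particle pair closer than `cutoff`, with the
#' minimum-image convention applied along the periodic tube axis. Uses a
#' linked-cell grid (cell edge >= cutoff), falling back to a direct scan for
#' very small systems.
#'
#' @param system a `particle_system`.
#' @param box a `box_geometry`.
#' @param cutoff interaction cutoff (m); must not exceed half the axial
#'   length (minimum-image ambiguity).
#' @return A data.frame with columns `i`, `j` (1-based indices, `i < j`),
#'   `dist`, and `dx`, `dy`, `dz` (displacement r_i - r_j, minimum image).
#' @export
build_neighbor_list <- function(system, box, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff > box$axial_length / 2)
    stop("cutoff exceeds half the axial length: minimum image is ambiguous")
  res <- cpp_neighbor_pairs(system$positions, box$axial_length, cutoff)
  data.frame(i = res$i, j = res$j, dist = res$dist,
             dx = res$disp[, 1], dy = res$disp[, 2], dz = res$disp[, 3])
}

#' Fold axial coordinates into the periodic box
#'
#' Wraps axial (x) coordinates into the interval 0 <= x < L and updates each particle's winding
#' count so that `wrapped + winding_count * L` is a continuous unwrapped
#' trajectory. Idempotent on already-wrapped systems.
#'
#' @inheritParams build_neighbor_list
#' @return the updated `particle_system`.
#' @export
wrap_positions <- function(system, box) {
  L <- box$axial_length
  x <- system$positions[, 1]
  k <- floor(x / L)
  system$positions[, 1] <- x - k * L
  system$winding_count <- system$winding_count + as.integer(k)
  system
}

#' Unwrapped axial coordinates
#'
#' @inheritParams build_neighbor_list
#' @return numeric vector `x + winding_count * L`, continuous across periodic
#'   crossings.
#' @export
unwrapped_x <- function(system, box) {
  system$positions[, 1] + system$winding_count * box$axial_length
}

#' Advance the system one velocity-Verlet step
#'
#' Kick-drift-kick velocity Verlet: half velocity update with the stored
#' forces, full position update, force re-evaluation at the new positions,
#' second half velocity update. Symplectic for velocity-independent forces.
#'
#' @param system a `particle_system`; `system$forces` must hold the forces at
#'   the current positions (evaluate the callback once before the first step).
#' @param total_force_callback function(system) returning an n x 3 force
#'   matrix (N).
#' @param dt time step (s).
#' @param box optional `box_geometry`; when given, axial coordinates are
#'   wrapped after the drift.
#' @return the advanced `particle_system` with forces at the new positions.
#' @export
integrate_step <- function(system, total_force_callback, dt, box = NULL) {
  if (dt <= 0) stop("dt must be positive")
  f <- system$forces
  if (!all(is.finite(f))) {
    bad <- which(!apply(is.finite(f), 1, all))[1]
    stop(sprintf("non-finite force on particle %d", bad))
  }
  hdt <- dt / 2
  system$velocities <- system$velocities + f * (hdt / system$masses)
  system$positions <- system$positions + system$velocities * dt
  if (!is.null(box)) system <- wrap_positions(system, box)
  f2 <- total_force_callback(system)
  if (!all(is.finite(f2))) {
    bad <- which(!apply(is.finite(f2), 1, all))[1]
    stop(sprintf("non-finite force on particle %d", bad))
  }
  system$velocities <- system$velocities + f2 * (hdt / system$masses)
  system$forces <- f2
  system
}
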