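#' Interface repulsive potential
#'
#' Compenetration-preventing potential between fluid and membrane particles:
#' `U = A (1 + cos(pi r / r0))` for \code{r < r0}, zero beyond. Continuous at
#' \code{r = r0} with \code{U(r -> 0) = 2A}.
#'
#' @param r distance(s) (m), > 0.
#' @param A amplitude (J).
#' @param r0 range (m).
#' @return potential energy (J).
#' @export
repulsive_potential <- function(r, A, r0) {
  u <- numeric(length(r))
  inside <- r < r0
  u[inside] <- A * (1 + cos(pi * r[inside] / r0))
  u
}

#' Interface repulsive force
#'
#' Force `-dU/dr e_ij = (A pi / r0) sin(pi r / r0) e_ij` on particle i,
#' directed away from the partner, for \code{r < r0}; zero beyond. Strictly
#' repulsive on (0, r0).
#'
#' @param r scalar distance (m), > 0.
#' @param e_ij unit vector from j to i.
#' @param A amplitude (J).
#' @param r0 range (m).
#' @return length-3 force vector on i (N).
#' @export
repulsive_force <- function(r, e_ij, A, r0) {
  if (r >= r0) return(c(0, 0, 0))
  (A * pi / r0) * sin(pi * r / r0) * e_ij
}

#' Cross-phase viscous forces (approximate no-slip)
#'
#' Applies the pairwise artificial-viscosity interaction (the same form as
#' between fluid particles) to fluid-solid pairs within the kernel support,
#' which damps relative tangential motion at the wall and approximates
#' no-slip. Solid particles carry no SPH density of their own and enter the
#' `rho_ij` sum at the reference density `rho0`.
#'
#' @param system a `particle_system` with fluid densities set.
#' @param box a `box_geometry`.
#' @param config a `sim_config`.
#' @return n x 3 matrix of forces (N), pairwise antisymmetric.
#' @export
cross_viscous_forces <- function(system, box, config) {
  force_terms(system, box, config, cross_visc = TRUE)$forces
}

#' Interface repulsion forces over a system
#'
#' Repulsion applies to fluid-solid pairs only (its purpose is to stop the
#' phases compenetrating), never fluid-fluid or solid-solid.
#'
#' @inheritParams cross_viscous_forces
#' @return n x 3 matrix of forces (N).
#' @export
repulsive_pair_forces <- function(system, box, config) {
  force_terms(system, box, config, repulsive = TRUE)$forces
}
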