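#' Cubic-spline smoothing kernel
#'
#' The standard cubic B-spline SPH kernel in three dimensions with compact
#' support of radius `2h` and normalisation `1 / (pi h^3)`.
#'
#' @param r distance(s) (m), >= 0.
#' @param h smoothing length (m).
#' @return kernel weight(s) (m^-3).
#' @export
sph_kernel <- function(r, h) {
  if (h <= 0) stop("h must be positive")
  q <- r / h
  s <- 1 / (pi * h^3)
  w <- numeric(length(q))
  a <- q < 1
  b <- q >= 1 & q < 2
  w[a] <- s * (1 - 1.5 * q[a]^2 + 0.75 * q[a]^3)
  w[b] <- s * 0.25 * (2 - q[b])^3
  w
}

#' Radial derivative of the cubic-spline kernel
#' @inheritParams sph_kernel
#' @return dW/dr (m^-4).
#' @export
sph_kernel_deriv <- function(r, h) {
  if (h <= 0) stop("h must be positive")
  q <- r / h
  s <- 1 / (pi * h^4)
  d <- numeric(length(q))
  a <- q < 1
  b <- q >= 1 & q < 2
  d[a] <- s * (-3 * q[a] + 2.25 * q[a]^2)
  d[b] <- -0.75 * s * (2 - q[b])^2
  d
}

#' Kernel gradient with respect to particle i
#'
#' @param r distance (m).
#' @param e_ij unit displacement vector(s) (r_i - r_j)/r, either length 3 or
#'   an n x 3 matrix.
#' @param h smoothing length (m).
#' @return gradient vector(s) (m^-4), antisymmetric under i-j exchange.
#' @export
sph_kernel_gradient <- function(r, e_ij, h) {
  d <- sph_kernel_deriv(r, h)
  if (is.matrix(e_ij)) e_ij * d else e_ij * d
}

#' Summation density
#'
#' Kernel-weighted summation density `rho_i = sum_j m_j W(r_ij, h)` including
#' the self term, over the particles selected by `subset` (all by default).
#' Used to calibrate the initial lattice and as a diagnostic; the stepping
#' loop integrates the continuity equation instead (see the package
#' vignette).
#'
#' @param system a `particle_system`.
#' @param box a `box_geometry`.
#' @param h smoothing length (m).
#' @param subset optional logical or integer index of the particles to
#'   include (both as sources and targets), e.g. the fluid phase.
#' @return the `particle_system` with `densities` filled in for the selected
#'   particles.
#' @export
compute_density <- function(system, box, h, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(n_particles(system))
  if (is.logical(subset)) subset <- which(subset)
  rho <- cpp_summation_density(system$positions[subset, , drop = FALSE],
                               system$masses[subset], box$axial_length, h)
  system$densities[subset] <- rho
  system
}

#' Tait equation of state
#'
#' Weakly-compressible pressure-density relation
#' `P = pref * ((rho/rho0)^7 - 1)` with `pref = c0^2 rho0 / 7` in the default
#' `"squared"` mode (dimensionally a pressure) or `pref = c0 rho0 / 7` in
#' `"as_printed"` mode. Strictly increasing in `rho`, with `P(rho0) = 0`.
#'
#' @param rho density (kg m^-3), > 0; vectorised.
#' @param c0 reference sound speed (m s^-1).
#' @param rho0 reference density (kg m^-3).
#' @param mode prefactor convention, see above.
#' @return pressure (Pa).
#' @export
tait_pressure <- function(rho, c0, rho0, mode = c("squared", "as_printed")) {
  mode <- match.arg(mode)
  pref <- if (mode == "squared") c0^2 * rho0 / 7 else c0 * rho0 / 7
  pref * ((rho / rho0)^7 - 1)
}

#' Pairwise artificial-viscosity term
#'
#' The scalar viscous contribution for one interacting pair,
#' `Pi_ij = -a h (c0 / rho_ij) (v_ij . r_ij) / (r_ij^2 + b h^2)`,
#' where `rho_ij = rho_i + rho_j` (a sum, not a mean) and `v_ij . r_ij` is
#' the dot product of the relative velocity and the displacement. Symmetric
#' under exchange of i and j, and applied for all pair velocities (it models
#' physical viscosity, not a shock switch).
#'
#' @param v_ij relative velocity vector `v_i - v_j` (m s^-1), length 3 or
#'   n x 3.
#' @param r_vec displacement vector `r_i - r_j` (m), same shape.
#' @param rho_ij sum of the two densities (kg m^-3).
#' @param a dimensionless viscosity coefficient.
#' @param b dimensionless stabiliser.
#' @param h smoothing length (m).
#' @param c0 reference sound speed (m s^-1).
#' @return scalar term(s) entering the momentum equation alongside
#'   `P_i/rho_i^2 + P_j/rho_j^2`.
#' @export
viscous_term <- function(v_ij, r_vec, rho_ij, a, b, h, c0) {
  if (is.matrix(v_ij)) {
    vdotr <- rowSums(v_ij * r_vec)
    r2 <- rowSums(r_vec^2)
  } else {
    vdotr <- sum(v_ij * r_vec)
    r2 <- sum(r_vec^2)
  }
  -a * h * (c0 / rho_ij) * vdotr / (r2 + b * h^2)
}

#' Fluid pair forces (pressure + viscosity)
#'
#' Assembles the SPH momentum-equation forces over fluid-fluid pairs:
#' `F_i = -sum_j m_i m_j (P_i/rho_i^2 + P_j/rho_j^2 + Pi_ij) grad_i W`.
#' Pairwise antisymmetric, so total linear momentum is conserved by
#' construction. Densities must be current.
#'
#' @param system a `particle_system` with fluid densities set.
#' @param box a `box_geometry`.
#' @param config a `sim_config`.
#' @return n x 3 matrix of forces (N); zero rows for solid particles.
#' @export
fluid_pair_forces <- function(system, box, config) {
  force_terms(system, box, config, fluid = TRUE)$forces
}

# internal: evaluate a chosen subset of force terms through the compiled core
force_terms <- function(system, box, config, fluid = FALSE, cross_visc = FALSE,
                        repulsive = FALSE, bonds = NULL, tether = NULL,
                        active_slices = integer(0), contraction = FALSE,
                        continuity = FALSE) {
  n <- n_particles(system)
  ph <- as.integer(system$phase == "solid")
  sl <- ifelse(is.na(system$slice_index), -1L, system$slice_index)
  if (is.null(bonds)) {
    bi <- integer(0); bj <- integer(0); br0 <- numeric(0); bk <- numeric(0)
  } else {
    bi <- bonds$i; bj <- bonds$j; br0 <- bonds$r0; bk <- bonds$k
  }
  anchors <- if (is.null(tether)) matrix(0, n, 3) else tether$anchors
  rho <- system$densities
  rho[is.na(rho)] <- config$rho0
  res <- cpp_forces(system$positions, system$velocities, rho, system$masses,
                    ph, as.integer(sl), as.integer(bi), as.integer(bj),
                    as.numeric(br0), as.numeric(bk), anchors,
                    as.integer(active_slices), cpp_params(config, box),
                    list(fluid = fluid, cross_visc = cross_visc,
                         repulsive = repulsive, bonds = !is.null(bonds),
                         tether = !is.null(tether), contraction = contraction,
                         continuity = continuity))
  res
}
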