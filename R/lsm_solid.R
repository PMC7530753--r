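#' Bond table constructor
#'
#' Hookean springs between membrane particles. Each unordered pair appears at
#' most once and self-bonds are rejected.
#'
#' @param i,j 1-based particle indices of the bonded pairs.
#' @param r0 rest length(s) (m), recycled.
#' @param k stiffness(es) (N m^-1), recycled.
#' @return An object of class `bond_table` (a data.frame).
#' @export
bond_table <- function(i, j, r0, k) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i == j)) stop("self-bonds are not allowed")
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (anyDuplicated(paste(lo, hi))) stop("duplicate bonds")
  structure(data.frame(i = lo, j = hi, r0 = rep_len(r0, length(i)),
                       k = rep_len(k, length(i))),
            class = c("bond_table", "data.frame"))
}

#' Tether set constructor
#'
#' One fixed anchor per solid particle; anchors for fluid particles are
#' ignored (their tether force is identically zero).
#'
#' @param anchors n x 3 matrix of anchor positions (m).
#' @param k_tether tether stiffness (N m^-1).
#' @return An object of class `tether_set`.
#' @export
tether_set <- function(anchors, k_tether) {
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 3) stop("anchors must be n x 3")
  structure(list(anchors = anchors, k_tether = k_tether), class = "tether_set")
}

#' Hookean pair force
#'
#' Linear spring force on particle i from a bond with j: magnitude
#' `k (r_ij - r0)`, directed toward the partner when stretched and away when
#' compressed; antisymmetric under i-j exchange.
#'
#' @param r_ij scalar distance (m), > 0.
#' @param e_ij unit vector from j to i.
#' @param k stiffness (N m^-1).
#' @param r0_bond rest length (m).
#' @return length-3 force vector on i (N).
#' @export
hooke_pair_force <- function(r_ij, e_ij, k, r0_bond) {
  -k * (r_ij - r0_bond) * e_ij
}

#' Bond forces over a bond table
#'
#' @param system a `particle_system`.
#' @param box a `box_geometry` (bonds use the axial minimum image).
#' @param bonds a `bond_table`.
#' @return n x 3 matrix of forces (N).
#' @export
bond_forces <- function(system, box, bonds) {
  cfg <- sim_config()   # stiffness comes from the table, constants unused
  force_terms(system, box, cfg, bonds = bonds)$forces
}

#' Tether forces
#'
#' Restoring force `-k' (x - anchor)` on every solid particle, returning the
#' membrane to its build configuration after a contraction; identically zero
#' on fluid particles.
#'
#' @param system a `particle_system`.
#' @param tethers a `tether_set`.
#' @return n x 3 matrix of forces (N).
#' @export
tether_forces <- function(system, tethers) {
  n <- n_particles(system)
  f <- -tethers$k_tether * (system$positions - tethers$anchors)
  f[system$phase != "solid", ] <- 0
  f
}

#' Contraction actuation forces
#'
#' Applies a force of constant magnitude `f0` directed radially toward the
#' tube axis (y = z = 0) to every solid particle whose slice index is in
#' `active_slices`. The force has no axial component, so the net axial
#' actuation force is exactly zero. A particle lying exactly on the axis has
#' no defined radial direction and receives zero force.
#'
#' @param system a `particle_system`.
#' @param active_slices integer vector of activated slice ids (subset of
#'   0..9).
#' @param f0 force magnitude (N).
#' @return n x 3 matrix of forces (N).
#' @export
contraction_forces <- function(system, active_slices, f0) {
  n <- n_particles(system)
  f <- matrix(0, n, 3)
  if (length(active_slices) == 0) return(f)
  sel <- system$phase == "solid" & !is.na(system$slice_index) &
    system$slice_index %in% active_slices
  if (!any(sel)) return(f)
  y <- system$positions[sel, 2]
  z <- system$positions[sel, 3]
  r <- sqrt(y^2 + z^2)
  ok <- r > 0
  fy <- numeric(sum(sel)); fz <- numeric(sum(sel))
  fy[ok] <- -f0 * y[ok] / r[ok]
  fz[ok] <- -f0 * z[ok] / r[ok]
  f[sel, 2] <- fy
  f[sel, 3] <- fz
  f
}
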