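# Independent reference implementations used as oracles. Everything here is
# deliberately written as plain double loops / direct formula transcription,
# sharing no code with the package's compiled path.

# exhaustive O(N^2) neighbour scan with axial minimum image
ref_pairs <- function(pos, L, cutoff) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      if (d[1] > L / 2) d[1] <- d[1] - L
      if (d[1] < -L / 2) d[1] <- d[1] + L
      r <- sqrt(sum(d^2))
      if (r < cutoff) out[[length(out) + 1]] <- c(i, j, r)
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, out)
}

ref_kernel <- function(r, h) {
  q <- r / h
  s <- 1 / (pi * h^3)
  if (q < 1) s * (1 - 1.5 * q^2 + 0.75 * q^3)
  else if (q < 2) s * 0.25 * (2 - q)^3
  else 0
}

ref_kernel_deriv <- function(r, h) {
  q <- r / h
  s <- 1 / (pi * h^4)
  if (q < 1) s * (-3 * q + 2.25 * q^2)
  else if (q < 2) -0.75 * s * (2 - q)^2
  else 0
}

# brute-force SPH fluid forces (pressure + viscosity), double loop
ref_fluid_forces <- function(pos, vel, rho, mass, L, cfg) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  pref <- if (cfg$tait_mode == "squared") cfg$c0^2 * cfg$rho0 / 7
          else cfg$c0 * cfg$rho0 / 7
  P <- pmax(0, pref * ((rho / cfg$rho0)^7 - 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      if (d[1] > L / 2) d[1] <- d[1] - L
      if (d[1] < -L / 2) d[1] <- d[1] + L
      r <- sqrt(sum(d^2))
      if (r >= 2 * cfg$h || r == 0) next
      vij <- vel[i, ] - vel[j, ]
      pi_ij <- -cfg$a * cfg$h * (cfg$c0 / (rho[i] + rho[j])) *
        sum(vij * d) / (r^2 + cfg$b * cfg$h^2)
      term <- P[i] / rho[i]^2 + P[j] / rho[j]^2 + pi_ij
      grad <- ref_kernel_deriv(r, cfg$h) * d / r
      fij <- -mass[i] * mass[j] * term * grad
      f[i, ] <- f[i, ] + fij
      f[j, ] <- f[j, ] - fij
    }
  }
  f
}

# brute-force cross-phase viscous forces; solid density taken as rho0
ref_cross_viscous <- function(pos, vel, rho, mass, phase, L, cfg) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (phase[i] == phase[j]) next
      d <- pos[i, ] - pos[j, ]
      if (d[1] > L / 2) d[1] <- d[1] - L
      if (d[1] < -L / 2) d[1] <- d[1] + L
      r <- sqrt(sum(d^2))
      if (r >= 2 * cfg$h || r == 0) next
      rho_i <- if (phase[i] == "fluid") rho[i] else cfg$rho0
      rho_j <- if (phase[j] == "fluid") rho[j] else cfg$rho0
      vij <- vel[i, ] - vel[j, ]
      pi_ij <- -cfg$a * cfg$h * (cfg$c0 / (rho_i + rho_j)) *
        sum(vij * d) / (r^2 + cfg$b * cfg$h^2)
      grad <- ref_kernel_deriv(r, cfg$h) * d / r
      fij <- -mass[i] * mass[j] * pi_ij * grad
      f[i, ] <- f[i, ] + fij
      f[j, ] <- f[j, ] - fij
    }
  }
  f
}

# surrogate-task MDP: states 0 (blank) and 1..n (one-hot i-1 active);
# deterministic transition to state a+1; rewards as documented
surrogate_reward <- function(s, a, n = 10) {
  if (s == 0) return(1)
  prev <- s - 1
  if (a == (prev + 1) %% n) 1
  else if (a == prev) 0
  else -0.5
}

# value iteration on the surrogate MDP; returns (n+1) x n Q matrix
surrogate_value_iteration <- function(gamma, n = 10, tol = 1e-12,
                                      max_iter = 10000) {
  Q <- matrix(0, n + 1, n)
  for (it in seq_len(max_iter)) {
    V <- apply(Q, 1, max)
    Qn <- Q
    for (s in 0:n) for (a in 0:(n - 1))
      Qn[s + 1, a + 1] <- surrogate_reward(s, a, n) + gamma * V[a + 2]
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
  Q
}

# tabular Q-learning with the same update rule the network realises
surrogate_tabular_q <- function(gamma, episodes, n = 10, alpha = 0.2,
                                eps = 0.2, actions_per_episode = 10,
                                seed = 1) {
  set.seed(seed)
  Q <- matrix(0, n + 1, n)
  for (ep in seq_len(episodes)) {
    s <- 0
    for (t in seq_len(actions_per_episode)) {
      a <- if (runif(1) < eps) sample.int(n, 1) - 1
           else which.max(Q[s + 1, ]) - 1
      r <- surrogate_reward(s, a, n)
      s2 <- a + 1
      target <- r + gamma * max(Q[s2 + 1, ])
      Q[s + 1, a + 1] <- Q[s + 1, a + 1] + alpha * (target - Q[s + 1, a + 1])
      s <- s2
    }
  }
  Q
}

# small helper: total linear momentum of a system
momentum <- function(system) colSums(system$velocities * system$masses)

rel_err <- function(x, y) max(abs(x - y)) / max(abs(y), 1e-300)
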