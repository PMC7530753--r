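#' Encode active slices as a membrane state vector
#'
#' The membrane state seen by the agent is a 10-component (generally
#' `n_slices`-component) binary vector with 1 marking a contracting slice.
#'
#' @param active_slices integer vector of active slice ids (0-based).
#' @param n_slices state length.
#' @return binary integer vector of length `n_slices`.
#' @export
encode_state <- function(active_slices, n_slices = 10) {
  stopifnot(all(active_slices >= 0), all(active_slices < n_slices))
  v <- integer(n_slices)
  v[active_slices + 1L] <- 1L
  v
}

#' Decode a membrane state vector
#' @param state binary vector as returned by [encode_state()].
#' @return integer vector of active slice ids (0-based).
#' @export
decode_state <- function(state) {
  if (!all(state %in% c(0, 1))) stop("state components must be 0 or 1")
  which(state == 1L) - 1L
}

#' Centre-of-mass reward
#'
#' The reward of an action is the axial displacement of the fluid's
#' mass-weighted centre of mass over the action window, computed on
#' unwrapped coordinates so periodic crossings do not corrupt it. Forward
#' (positive x) displacement is a positive reward.
#'
#' @param x_before,x_after unwrapped axial fluid coordinates (m).
#' @param masses fluid particle masses (kg).
#' @return signed displacement Delta x (m).
#' @export
compute_reward <- function(x_before, x_after, masses) {
  if (length(x_before) != length(x_after) ||
      length(x_before) != length(masses))
    stop("mismatched particle counts")
  sum(masses * (x_after - x_before)) / sum(masses)
}

#' Dimensionless cumulative reward
#'
#' Episode efficiency: the ratio of the fluid volume displaced forward to the
#' total volume squeezed out of the contracting sections,
#' `R* = (Delta x_total * V_fluid / L) / V_squeezed`. The numerator converts
#' the net centre-of-mass displacement into a plug-flow equivalent volume;
#' the denominator sums, over actions, the drop from each contracted slice's
#' rest volume to its minimum volume during the action. `R*` near 1 means
#' almost all squeezed fluid went forward; 0 means symmetric splitting;
#' negative means net retrograde flow.
#'
#' @param episode an `episode_log` (see [tube_env()]).
#' @param fluid_volume total fluid volume (m^3).
#' @param L tube length (m).
#' @return scalar `R*`, or `NA` when nothing was squeezed all episode.
#' @export
dimensionless_cumulative_reward <- function(episode, fluid_volume, L) {
  v_sq <- sum(episode$squeezed, na.rm = TRUE)
  if (v_sq <= 0) return(NA_real_)
  dx_total <- sum(episode$reward)
  (dx_total * fluid_volume / L) / v_sq
}

#' Total fluid volume of a tube model
#' @param model a `tube_model`.
#' @return volume (m^3), fluid mass over reference density.
#' @export
fluid_volume <- function(model) {
  sum(model$system$masses[model$system$phase == "fluid"]) / model$config$rho0
}

# decode an agent action into active slice ids
action_slices <- function(action, mode, n_slices = 10) {
  if (mode == "single") {
    stopifnot(length(action) == 1, action >= 0, action < n_slices)
    as.integer(action)
  } else {
    stopifnot(length(action) == 1, action >= 0, action < 2^n_slices)
    which(bitwAnd(as.integer(action), bitwShiftL(1L, 0:(n_slices - 1))) != 0) - 1L
  }
}

#' Physics reinforcement-learning environment
#'
#' Wraps a `tube_model` in reset/step semantics. Each `step(action)` switches
#' the contraction force onto the chosen slice(s) for `round(dT / dt)`
#' velocity-Verlet steps, computes the centre-of-mass reward over exactly
#' that window, and returns the new membrane state (the encoding of the
#' action just taken; repeating an action leaves the state unchanged).
#' Episodes end after `actions_per_episode` actions; there is no physical
#' termination. `reset()` restores the build configuration at rest with no
#' activation.
#'
#' @param model a `tube_model`.
#' @param dT decision interval (s); the agent picks a new action every `dT`.
#' @param actions_per_episode episode length in actions.
#' @param mode `"single"` (one contracting slice per action, 10 actions) or
#'   `"general"` (any 10-bit activation pattern, 2^10 actions).
#' @return An object of class `tube_env` with elements `reset()`, `step()`,
#'   `state()`, `episode_log()`, `model()`, `n_actions`, `n_slices`, `mode`.
#' @export
tube_env <- function(model, dT = 1, actions_per_episode = 20,
                     mode = c("single", "general")) {
  mode <- match.arg(mode)
  cfg <- model$config
  nsteps <- round(dT / cfg$dt)
  if (abs(nsteps * cfg$dt - dT) > 1e-9 * dT)
    stop("dT must be divisible by dt")
  nsl <- model$geometry$n_slices
  thick <- model$geometry$length / nsl
  vfl <- fluid_volume(model)

  sys0 <- model$system
  ph <- as.integer(sys0$phase == "solid")
  sl <- ifelse(is.na(sys0$slice_index), -1L, sys0$slice_index)
  fluid <- sys0$phase == "fluid"
  # rest mean membrane radius per slice, from the tether anchors
  anc <- model$tethers$anchors
  rad0 <- sqrt(anc[, 2]^2 + anc[, 3]^2)
  rest_radius <- vapply(0:(nsl - 1), function(s)
    mean(rad0[ph == 1 & sl == s]), numeric(1))

  e <- new.env(parent = emptyenv())
  reset <- function() {
    e$pos <- sys0$positions
    e$vel <- matrix(0, nrow(sys0$positions), 3)
    e$rho <- rep(cfg$rho0, nrow(sys0$positions))
    e$wind <- integer(nrow(sys0$positions))
    e$state <- integer(nsl)
    e$log <- data.frame(action = integer(0), reward = numeric(0),
                        squeezed = numeric(0))
    e$n_done <- 0L
    invisible(e$state)
  }
  step <- function(action) {
    if (e$n_done >= actions_per_episode) stop("episode finished; call reset()")
    act <- action_slices(action, mode, nsl)
    res <- cpp_advance(e$pos, e$vel, e$rho, e$wind, sys0$masses, ph,
                       as.integer(sl),
                       model$bonds$i, model$bonds$j, model$bonds$r0,
                       model$bonds$k, model$tethers$anchors,
                       as.integer(act), cpp_params(cfg, model$box),
                       list(fluid = TRUE, cross_visc = TRUE, repulsive = TRUE,
                            bonds = TRUE, tether = TRUE,
                            contraction = length(act) > 0, continuity = TRUE),
                       nsteps, cfg$dt)
    e$pos <- res$pos; e$vel <- res$vel; e$rho <- res$rho; e$wind <- res$wind
    reward <- res$com[length(res$com)] - res$com[1]
    squeezed <- sum(vapply(act, function(s) {
      rmin <- res$min_slice_radius[s + 1]
      max(0, pi * (rest_radius[s + 1]^2 - rmin^2) * thick)
    }, numeric(1)))
    e$state <- encode_state(act, nsl)
    e$n_done <- e$n_done + 1L
    e$log <- rbind(e$log, data.frame(action = as.integer(action),
                                     reward = reward, squeezed = squeezed))
    list(state = e$state, reward = reward,
         done = e$n_done >= actions_per_episode)
  }
  episode_log <- function() {
    lg <- e$log
    class(lg) <- c("episode_log", "data.frame")
    lg
  }
  reset()
  structure(list(reset = reset, step = step,
                 state = function() e$state,
                 episode_log = episode_log,
                 rstar = function()
                   dimensionless_cumulative_reward(episode_log(), vfl,
                                                   model$geometry$length),
                 model = function() model,
                 raw = e,
                 n_actions = as.integer(if (mode == "single") nsl
                                        else 2^nsl),
                 n_slices = as.integer(nsl), mode = mode,
                 actions_per_episode = actions_per_episode),
            class = "tube_env")
}

#' Physics-free surrogate environment
#'
#' A deterministic toy task with the same state/action/reward interface as
#' [tube_env()], for fast agent tests: contracting the slice after the
#' previously contracted one (`(i_prev + 1) mod n`) yields reward +1,
#' repeating the same slice yields 0, any other slice yields -0.5; from the
#' initial all-zero state every slice is a valid wave start and yields +1.
#' The optimal policy is the travelling contraction wave, and the optimal
#' action values are computable by value iteration.
#'
#' @param n_slices number of slices (states are the zero vector plus the
#'   `n_slices` one-hot vectors).
#' @param actions_per_episode episode length.
#' @return An object of class `surrogate_env` with the same elements as a
#'   `tube_env` (the `squeezed` log column is `NA`: the surrogate has no
#'   volumes).
#' @export
surrogate_env <- function(n_slices = 10, actions_per_episode = 20) {
  e <- new.env(parent = emptyenv())
  reset <- function() {
    e$state <- integer(n_slices)
    e$log <- data.frame(action = integer(0), reward = numeric(0),
                        squeezed = numeric(0))
    e$n_done <- 0L
    invisible(e$state)
  }
  step <- function(action) {
    if (e$n_done >= actions_per_episode) stop("episode finished; call reset()")
    stopifnot(length(action) == 1, action >= 0, action < n_slices)
    prev <- decode_state(e$state)
    reward <- if (length(prev) == 0) 1
      else if (action == (prev + 1) %% n_slices) 1
      else if (action == prev) 0
      else -0.5
    e$state <- encode_state(as.integer(action), n_slices)
    e$n_done <- e$n_done + 1L
    e$log <- rbind(e$log, data.frame(action = as.integer(action),
                                     reward = reward, squeezed = NA_real_))
    list(state = e$state, reward = reward,
         done = e$n_done >= actions_per_episode)
  }
  reset()
  structure(list(reset = reset, step = step,
                 state = function() e$state,
                 episode_log = function() {
                   lg <- e$log
                   class(lg) <- c("episode_log", "data.frame")
                   lg
                 },
                 rstar = function() NA_real_,
                 model = function() NULL,
                 raw = e,
                 n_actions = as.integer(n_slices),
                 n_slices = as.integer(n_slices), mode = "single",
                 actions_per_episode = actions_per_episode),
            class = c("surrogate_env", "tube_env"))
}
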