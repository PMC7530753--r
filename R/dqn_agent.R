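# run code under a temporary RNG state so seeded construction never disturbs
# the caller's random stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Agent hyperparameters
#'
#' Defaults follow the reference training setup: discount gamma = 0.5,
#' exploration probability decaying linearly from 1.0 to 0.1 over 30,000
#' episodes, mean-squared-error loss on the Bellman target, and an Adam-type
#' optimiser (step size 1e-3, the optimiser family's conventional default).
#' Experience replay and a frozen target network are available behind flags
#' and are off by default: the agent trains online, one gradient step per
#' transition.
#'
#' @param gamma discount factor in [0, 1).
#' @param epsilon_start,epsilon_end exploration schedule endpoints.
#' @param epsilon_decay_episodes episodes over which epsilon decays linearly.
#' @param lr Adam step size.
#' @param replay_size replay buffer capacity; 0 disables replay.
#' @param batch_size transitions sampled per update when replay is on.
#' @param target_sync steps between target-network synchronisations; 0
#'   disables the target network.
#' @param reward_scale multiplier applied to rewards inside the learning
#'   update only (logged rewards stay physical). Centre-of-mass rewards are
#'   a few millimetres, orders of magnitude below the network's initial
#'   output scale; short desk runs need the targets rescaled to order one
#'   to learn in few episodes. 1 leaves rewards untouched.
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(gamma = 0.5, epsilon_start = 1.0, epsilon_end = 0.1,
                         epsilon_decay_episodes = 30000, lr = 1e-3,
                         replay_size = 0, batch_size = 32, target_sync = 0,
                         reward_scale = 1, seed = NULL) {
  stopifnot(gamma >= 0, gamma < 1, reward_scale > 0,
            epsilon_end >= 0, epsilon_end <= epsilon_start, epsilon_start <= 1)
  structure(list(gamma = gamma, epsilon_start = epsilon_start,
                 epsilon_end = epsilon_end,
                 epsilon_decay_episodes = epsilon_decay_episodes, lr = lr,
                 replay_size = replay_size, batch_size = batch_size,
                 target_sync = target_sync, reward_scale = reward_scale,
                 seed = seed),
            class = "agent_config")
}

#' Action-value network
#'
#' A fully connected value network mapping the 10-component membrane state to
#' one Q value per action: layers 10-50-50-10 with relu hidden activations
#' and a linear output. Weights are initialised uniformly scaled by layer
#' fan-in (+-1/sqrt(n_in)), reproducibly from `seed`.
#'
#' @param sizes integer vector of layer sizes.
#' @param seed RNG seed for initialisation.
#' @return An object of class `qnet`: lists `W`, `b` of weights and biases,
#'   the layer sizes, and Adam optimiser state.
#' @export
qnet <- function(sizes = c(10, 50, 50, 10), seed = 1) {
  nl <- length(sizes) - 1
  with_seed(seed, {
    W <- lapply(seq_len(nl), function(l) {
      lim <- 1 / sqrt(sizes[l])
      matrix(runif(sizes[l] * sizes[l + 1], -lim, lim), sizes[l], sizes[l + 1])
    })
  })
  b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1]))
  opt <- list(t = 0,
              mW = lapply(W, function(w) w * 0), vW = lapply(W, function(w) w * 0),
              mb = lapply(b, function(x) x * 0), vb = lapply(b, function(x) x * 0))
  structure(list(sizes = sizes, W = W, b = b, opt = opt), class = "qnet")
}

# forward pass keeping layer activations for backpropagation
qnet_forward_full <- function(net, state) {
  a <- list(as.numeric(state))
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    z <- as.numeric(a[[l]] %*% net$W[[l]]) + net$b[[l]]
    a[[l + 1]] <- if (l < nl) pmax(z, 0) else z
  }
  a
}

#' Q values of a state
#'
#' Deterministic forward pass; a pure function of the weights and the state.
#'
#' @param net a `qnet`.
#' @param state binary membrane state vector matching the input layer.
#' @return numeric vector of one Q value per action.
#' @export
q_forward <- function(net, state) {
  if (length(state) != net$sizes[1])
    stop(sprintf("state length %d does not match input layer %d",
                 length(state), net$sizes[1]))
  a <- qnet_forward_full(net, state)
  a[[length(a)]]
}

#' Bellman target
#'
#' The training target for the taken action: `r` for a terminal transition,
#' else \code{r + gamma * max(next_q_values)}.
#'
#' @param r reward.
#' @param gamma discount factor.
#' @param next_q_values Q values of the next state (ignored when terminal).
#' @param terminal logical.
#' @return scalar target.
#' @export
q_target <- function(r, gamma, next_q_values, terminal = FALSE) {
  if (terminal) r else r + gamma * max(next_q_values)
}

#' Squared temporal-difference loss
#' @param predicted_q predicted Q value of the taken action.
#' @param target Bellman target.
#' @return `(target - predicted_q)^2`.
#' @export
td_loss <- function(predicted_q, target) (target - predicted_q)^2

#' Exploration schedule
#'
#' Probability of a random action: linear interpolation from
#' `epsilon_start` at episode 0 to `epsilon_end` at
#' `epsilon_decay_episodes`, constant afterwards.
#'
#' @param episode 0-based episode index.
#' @param config an `agent_config`.
#' @return exploration probability.
#' @export
epsilon_schedule <- function(episode, config) {
  frac <- pmin(pmax(episode / config$epsilon_decay_episodes, 0), 1)
  config$epsilon_start + (config$epsilon_end - config$epsilon_start) * frac
}

#' Epsilon-greedy action selection
#'
#' With probability `alpha` a uniformly random action; otherwise the argmax
#' of the Q values, ties broken by the lowest index (reproducibility).
#'
#' @param q_values numeric vector of action values.
#' @param alpha exploration probability between 0 and 1.
#' @return 0-based action index.
#' @export
select_action <- function(q_values, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha > 0 && stats::runif(1) < alpha)
    sample.int(length(q_values), 1) - 1L
  else
    which.max(q_values) - 1L    # which.max takes the first maximum
}

#' One Q-learning gradient step
#'
#' Performs a single Adam update of the squared temporal-difference loss for
#' the transition's taken action. Only that action's output is trained: the
#' other outputs' targets equal their current predictions, so their gradient
#' contribution is zero (the standard masked-loss realisation for
#' vector-output value networks).
#'
#' @param net a `qnet`.
#' @param transition list with elements `s` (state vector), `a` (0-based
#'   action index), `r` (reward), `s_next` (next state vector), `terminal`
#'   (logical).
#' @param config an `agent_config`.
#' @param target_net optional frozen network used to evaluate the Bellman
#'   target; defaults to `net` (plain online Q-learning).
#' @return list with the updated `net` and the scalar `loss` before the
#'   update.
#' @export
train_step <- function(net, transition, config, target_net = NULL) {
  if (is.null(target_net)) target_net <- net
  nq <- q_forward(target_net, transition$s_next)
  tgt <- q_target(transition$r, config$gamma, nq,
                  isTRUE(transition$terminal))
  acts <- qnet_forward_full(net, transition$s)
  nl <- length(net$W)
  out <- acts[[nl + 1]]
  ai <- transition$a + 1L
  loss <- td_loss(out[ai], tgt)
  if (!is.finite(loss)) stop("non-finite training loss")

  # backpropagate d(loss)/d(out): nonzero only for the taken action
  delta <- numeric(length(out))
  delta[ai] <- 2 * (out[ai] - tgt)
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1) {
    gW[[l]] <- outer(acts[[l]], delta)
    gb[[l]] <- delta
    if (l > 1) {
      delta <- as.numeric(net$W[[l]] %*% delta) * (acts[[l]] > 0)
    }
  }

  # Adam
  o <- net$opt
  o$t <- o$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  c1 <- 1 - b1^o$t; c2 <- 1 - b2^o$t
  for (l in seq_len(nl)) {
    o$mW[[l]] <- b1 * o$mW[[l]] + (1 - b1) * gW[[l]]
    o$vW[[l]] <- b2 * o$vW[[l]] + (1 - b2) * gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      config$lr * (o$mW[[l]] / c1) / (sqrt(o$vW[[l]] / c2) + eps)
    o$mb[[l]] <- b1 * o$mb[[l]] + (1 - b1) * gb[[l]]
    o$vb[[l]] <- b2 * o$vb[[l]] + (1 - b2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      config$lr * (o$mb[[l]] / c1) / (sqrt(o$vb[[l]] / c2) + eps)
  }
  net$opt <- o
  list(net = net, loss = loss)
}

#' Greedy policy of a network over the reachable states
#'
#' Evaluates the argmax action in the all-zero state and each one-hot state.
#'
#' @param net a `qnet`.
#' @param n_slices number of slices.
#' @return integer vector of length `n_slices + 1`: the greedy 0-based
#'   action in the zero state followed by the one-hot states 0..n-1.
#' @export
greedy_policy <- function(net, n_slices = 10) {
  states <- c(list(integer(n_slices)),
              lapply(0:(n_slices - 1), encode_state, n_slices = n_slices))
  vapply(states, function(s) which.max(q_forward(net, s)) - 1L, integer(1))
}
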