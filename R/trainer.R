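#' Seeded training loop
#'
#' Runs Q-learning over episodes: reset the environment, act epsilon-greedily
#' on the current network, and apply one gradient step per transition
#' (optionally with experience replay / a target network when the config
#' enables them). The final transition of each episode is treated as
#' terminal. Writes one log row per episode and is fully reproducible given
#' `seed`.
#'
#' @param env a `tube_env` or `surrogate_env`.
#' @param config an `agent_config`.
#' @param episodes number of training episodes.
#' @param net optional starting `qnet`; a fresh one (seeded from `config`)
#'   is created by default.
#' @param seed RNG seed for exploration (and replay sampling); `NULL` leaves
#'   the RNG state alone.
#' @param checkpoint_path optional file; the network is checkpointed there
#'   every `checkpoint_every` episodes and at the end.
#' @param checkpoint_every checkpoint cadence in episodes.
#' @param episode_offset 0-based index of the first episode (used to resume
#'   a schedule).
#' @return list with `net` (trained network) and `log`, a data.frame with
#'   columns `episode`, `cum_reward`, `rstar`, `epsilon`, `mean_loss`.
#' @export
run_training <- function(env, config = agent_config(), episodes,
                         net = NULL, seed = NULL, checkpoint_path = NULL,
                         checkpoint_every = 0, episode_offset = 0) {
  stopifnot(episodes >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) net <- qnet(c(env$n_slices, 50, 50, env$n_actions),
                                seed = config$seed)
  target_net <- if (config$target_sync > 0) net else NULL
  buffer <- list()
  step_count <- 0L
  n_act <- env$actions_per_episode
  log <- data.frame(episode = integer(episodes), cum_reward = numeric(episodes),
                    rstar = numeric(episodes), epsilon = numeric(episodes),
                    mean_loss = numeric(episodes))
  for (ep in seq_len(episodes)) {
    ep0 <- episode_offset + ep - 1L
    eps <- epsilon_schedule(ep0, config)
    s <- env$reset()
    losses <- numeric(n_act)
    cum <- 0
    for (t in seq_len(n_act)) {
      a <- select_action(q_forward(net, s), eps)
      res <- env$step(a)
      tr <- list(s = s, a = a, r = res$reward * config$reward_scale,
                 s_next = res$state, terminal = res$done)
      cum <- cum + res$reward
      if (config$replay_size > 0) {
        buffer[[length(buffer) %% config$replay_size + 1L]] <- tr
        nb <- min(config$batch_size, length(buffer))
        idx <- sample.int(length(buffer), nb, replace = TRUE)
        lb <- 0
        for (k in idx) {
          ts <- train_step(net, buffer[[k]], config, target_net)
          net <- ts$net
          lb <- lb + ts$loss
        }
        losses[t] <- lb / nb
      } else {
        ts <- train_step(net, tr, config, target_net)
        net <- ts$net
        losses[t] <- ts$loss
      }
      step_count <- step_count + 1L
      if (config$target_sync > 0 && step_count %% config$target_sync == 0)
        target_net <- net
      s <- res$state
    }
    log$episode[ep] <- ep0
    log$cum_reward[ep] <- cum
    log$rstar[ep] <- env$rstar()
    log$epsilon[ep] <- eps
    log$mean_loss[ep] <- mean(losses)
    if (!is.null(checkpoint_path) && checkpoint_every > 0 &&
        ep %% checkpoint_every == 0)
      save_checkpoint(checkpoint_path, net = net,
                      extra = list(episode = ep0 + 1L))
  }
  if (!is.null(checkpoint_path))
    save_checkpoint(checkpoint_path, net = net,
                    extra = list(episode = episode_offset + episodes))
  list(net = net, log = log)
}

#' Evaluate a policy by rollout
#'
#' Plays `n_episodes` episodes with the given network, greedily by default
#' (exploration forced to zero, hence deterministic), logging the action
#' sequence, cumulative reward and dimensionless cumulative reward of each
#' episode, and optionally dumping trajectory frames.
#'
#' @param env a `tube_env` or `surrogate_env`.
#' @param net a `qnet`.
#' @param n_episodes episodes to play.
#' @param greedy force epsilon to 0; otherwise `epsilon` is used.
#' @param epsilon exploration probability when not greedy.
#' @param trajectory_path optional file to write frames to (extended XYZ).
#' @param dump_every frame cadence in actions (a frame every `dump_every`
#'   actions plus the initial frame of each episode); 0 disables dumping.
#' @param dT decision interval (s), used only to stamp frame times.
#' @return list with `log` (data.frame: episode, cum_reward, rstar),
#'   `actions` (list of 0-based action index vectors), and invisibly the
#'   frames written, if any.
#' @export
rollout <- function(env, net, n_episodes = 1, greedy = TRUE, epsilon = 0,
                    trajectory_path = NULL, dump_every = 0, dT = 1) {
  eps <- if (greedy) 0 else epsilon
  logs <- data.frame(episode = integer(n_episodes),
                     cum_reward = numeric(n_episodes),
                     rstar = numeric(n_episodes))
  actions <- vector("list", n_episodes)
  frames <- list()
  for (ep in seq_len(n_episodes)) {
    s <- env$reset()
    if (dump_every > 0) frames[[length(frames) + 1]] <-
      env_frame(env, time = 0)
    acts <- integer(env$actions_per_episode)
    cum <- 0
    for (t in seq_len(env$actions_per_episode)) {
      a <- select_action(q_forward(net, s), eps)
      res <- env$step(a)
      acts[t] <- a
      cum <- cum + res$reward
      s <- res$state
      if (dump_every > 0 && t %% dump_every == 0)
        frames[[length(frames) + 1]] <- env_frame(env, time = t * dT)
    }
    logs$episode[ep] <- ep
    logs$cum_reward[ep] <- cum
    logs$rstar[ep] <- env$rstar()
    actions[[ep]] <- acts
  }
  if (!is.null(trajectory_path) && length(frames) > 0)
    write_trajectory(frames, trajectory_path)
  out <- list(log = logs, actions = actions)
  if (length(frames) > 0) out$frames <- frames
  out
}

# snapshot the particle state of a physics environment as a trajectory frame
env_frame <- function(env, time = 0) {
  model <- env$model()
  if (is.null(model)) stop("the surrogate environment has no particles")
  sys <- model$system
  list(time = time,
       id = seq_len(nrow(env$raw$pos)),
       species = ifelse(sys$phase == "fluid", "F", "S"),
       slice = ifelse(is.na(sys$slice_index), -1L, sys$slice_index),
       pos = env$raw$pos)
}
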