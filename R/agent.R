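# The DQN agent family and its training loop: epsilon-greedy interaction
# with the episodic environment, uniform experience replay, MSE regression
# onto TD targets, and periodic hard target-network syncs.

#' Agent hyperparameters
#'
#' Defaults are the published training configuration: discount 0.99,
#' exploration decaying from 0.5 to a floor of 0.01 with factor 0.995, 50
#' episodes, batch size 16, Adam with learning rate 0.001, MSE loss.
#'
#' @param variant Architecture variant; see [qnet_init()]. Default
#'   `"duelcontextattn"`.
#' @param gamma Discount factor in `[0, 1]`.
#' @param epsilon,epsilon_min,epsilon_decay Exploration schedule:
#'   `epsilon <- max(epsilon * epsilon_decay, epsilon_min)`.
#' @param decay_mode Apply the decay per environment `"step"` (default; with
#'   50 short episodes a per-episode decay never approaches the 0.01 floor,
#'   leaving that parameter vacuous) or per `"episode"`.
#' @param episodes Training episodes (full dataset traversals).
#' @param batch_size Replay mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param target_update Environment steps between hard target syncs.
#' @param replay_capacity FIFO replay buffer capacity.
#' @param hidden Shared trunk widths.
#' @param double Override the variant's double-DQN target rule (`NULL`
#'   keeps the variant default).
#' @param shuffle Reshuffle sample order each episode.
#' @param seed Master seed for initialization, exploration, replay
#'   sampling and episode shuffling.
#' @return An `agent_config` object.
#' @export
agent_config <- function(variant = "duelcontextattn", gamma = 0.99,
                         epsilon = 0.5, epsilon_min = 0.01,
                         epsilon_decay = 0.995,
                         decay_mode = c("step", "episode"),
                         episodes = 50L, batch_size = 16L,
                         learning_rate = 0.001, target_update = 100L,
                         replay_capacity = 10000L, hidden = c(64L, 64L),
                         double = NULL, shuffle = TRUE, seed = 1L) {
  decay_mode <- match.arg(decay_mode)
  variant <- match.arg(variant, VARIANTS)
  stopifnot(gamma >= 0, gamma <= 1, epsilon_decay > 0, epsilon_decay <= 1,
            epsilon_min <= epsilon, episodes >= 1, batch_size >= 1)
  structure(list(variant = variant, gamma = gamma, epsilon = epsilon,
                 epsilon_min = epsilon_min, epsilon_decay = epsilon_decay,
                 decay_mode = decay_mode, episodes = as.integer(episodes),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 target_update = as.integer(target_update),
                 replay_capacity = as.integer(replay_capacity),
                 hidden = as.integer(hidden),
                 double = double %||% variant_traits(variant)$double,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "agent_config")
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action, otherwise the
#' greedy argmax of the Q-vector; exact ties resolve to the lowest action
#' index.
#'
#' @param q Q-value vector.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return Integer action in `0 .. length(q) - 1`.
#' @export
epsilon_greedy <- function(q, epsilon) {
  if (epsilon > 0 && runif(1) < epsilon) {
    sample.int(length(q), 1) - 1L
  } else {
    which.max(q) - 1L
  }
}

#' Multiplicative epsilon decay with floor
#'
#' @param epsilon Current exploration rate.
#' @param config An [agent_config()] supplying `epsilon_decay` and
#'   `epsilon_min`.
#' @return Decayed epsilon, never below the floor.
#' @export
decay_epsilon <- function(epsilon, config) {
  max(epsilon * config$epsilon_decay, config$epsilon_min)
}

# --- replay buffer: preallocated FIFO with uniform sampling ---------------

new_replay_buffer <- function(capacity, state_dim) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$states <- matrix(0, capacity, state_dim)
  b$actions <- integer(capacity)
  b$rewards <- numeric(capacity)
  b$next_states <- matrix(0, capacity, state_dim)
  b$terminals <- logical(capacity)
  b$size <- 0L
  b$head <- 0L   # next write slot (FIFO eviction once full)
  b
}

buffer_push <- function(b, state, action, reward, next_state, terminal) {
  b$head <- (b$head %% b$capacity) + 1L
  b$states[b$head, ] <- state
  b$actions[b$head] <- action
  b$rewards[b$head] <- reward
  b$next_states[b$head, ] <- next_state
  b$terminals[b$head] <- terminal
  b$size <- min(b$size + 1L, b$capacity)
  invisible(b)
}

buffer_sample <- function(b, n) {
  idx <- sample.int(b$size, min(n, b$size))
  list(states = b$states[idx, , drop = FALSE],
       actions = b$actions[idx],
       rewards = b$rewards[idx],
       next_states = b$next_states[idx, , drop = FALSE],
       terminals = b$terminals[idx])
}

#' One replay gradient step
#'
#' Computes TD targets for a sampled batch with the target network (double
#' rule optional), regresses the online network's Q-values of the taken
#' actions onto them under MSE, and applies one Adam step. Only the taken
#' actions' outputs receive gradient.
#'
#' @param online Online `qnet`.
#' @param batch Batch list (`states`, `actions`, `rewards`, `next_states`,
#'   `terminals`) as returned by the internal replay sampler.
#' @param target Target `qnet`.
#' @param config An [agent_config()].
#' @return List with the updated `online` network and the scalar `loss`.
#' @export
replay_update <- function(online, batch, target, config) {
  n <- nrow(batch$states)
  if (n == 0) abort("Empty batch.")
  if (ncol(batch$states) != online$input_dim) {
    abort("Batch state dimension does not match the network.")
  }
  y <- batch_targets(batch$rewards, batch$next_states, batch$terminals,
                     config$gamma, target, online, config$double)
  fw <- qnet_forward(online, batch$states, keep = TRUE)
  taken <- cbind(seq_len(n), batch$actions + 1L)
  pred <- fw$q[taken]
  loss <- mean((pred - y)^2)
  dq <- matrix(0, n, online$n_actions)
  dq[taken] <- 2 * (pred - y) / n
  grads <- qnet_backward(online, fw$cache, dq)
  online <- qnet_adam_step(online, grads, config$learning_rate)
  list(online = online, loss = loss)
}

#' Hard target-network synchronization
#'
#' @param online Online `qnet`.
#' @param target Target `qnet` of the same architecture.
#' @return The target network with weights replaced by exact copies of the
#'   online weights.
#' @export
sync_target <- function(online, target) {
  qnet_copy_weights(online, target)
}

#' Train a DQN agent on an episodic classification environment
#'
#' The training loop: for each of `config$episodes` full traversals of the
#' data, select actions epsilon-greedily, store transitions in the replay
#' buffer, and once the buffer holds a full batch perform one replay
#' gradient step per environment step; the target network is synced every
#' `config$target_update` steps. Per-episode cumulative reward, accuracy
#' and mean loss are logged.
#'
#' @param env A [make_env()] environment, or a labeled sample table (an
#'   environment is then built with the config's seed and shuffle flag).
#' @param config An [agent_config()].
#' @return A `dqn_policy`: the trained network, config, feature namespace,
#'   final epsilon, and an `episode_log` tibble (`episode`, `reward`,
#'   `accuracy`, `loss`).
#' @export
train_agent <- function(env, config = agent_config()) {
  if (is.data.frame(env)) {
    env <- make_env(env, shuffle = config$shuffle,
                    seed = derive_seed(config$seed, 101L))
  }
  local_seed(derive_seed(config$seed, 7L))
  d <- ncol(env$x)
  online <- qnet_init(d, env$n_actions, variant = config$variant,
                      hidden = config$hidden,
                      seed = derive_seed(config$seed, 11L))
  target <- sync_target(online, online)
  buffer <- new_replay_buffer(config$replay_capacity, d)
  eps <- config$epsilon
  step_count <- 0L
  log <- tibble(episode = seq_len(config$episodes), reward = NA_real_,
                accuracy = NA_real_, loss = NA_real_)
  for (ep in seq_len(config$episodes)) {
    state <- env_reset(env)
    rewards <- numeric(env$n)
    losses <- c()
    done <- FALSE
    i <- 0L
    while (!done) {
      i <- i + 1L
      q <- drop(qnet_forward(online, matrix(state, nrow = 1)))
      action <- epsilon_greedy(q, eps)
      res <- env_step(env, action)
      buffer_push(buffer, state, action, res$reward, res$state, res$done)
      rewards[i] <- res$reward
      if (buffer$size >= config$batch_size) {
        batch <- buffer_sample(buffer, config$batch_size)
        upd <- replay_update(online, batch, target, config)
        online <- upd$online
        losses <- c(losses, upd$loss)
      }
      step_count <- step_count + 1L
      if (config$decay_mode == "step") eps <- decay_epsilon(eps, config)
      if (step_count %% config$target_update == 0L) {
        target <- sync_target(online, target)
      }
      state <- res$state
      done <- res$done
    }
    if (config$decay_mode == "episode") eps <- decay_epsilon(eps, config)
    log$reward[ep] <- sum(rewards)
    log$accuracy[ep] <- episode_accuracy(rewards)
    log$loss[ep] <- if (length(losses)) mean(losses) else NA_real_
  }
  structure(list(net = online, config = config, epsilon_final = eps,
                 n_actions = env$n_actions,
                 features = colnames(env$x),
                 episode_log = log),
            class = "dqn_policy")
}

#' @export
print.dqn_policy <- function(x, ...) {
  cat(sprintf("<dqn_policy> %s, %d actions, %d features\n",
              x$config$variant, x$n_actions, length(x$features)))
  cat(sprintf("  %d episodes; final episode accuracy %.3f, reward %g\n",
              nrow(x$episode_log), tail(x$episode_log$accuracy, 1),
              tail(x$episode_log$reward, 1)))
  invisible(x)
}

policy_feature_matrix <- function(object, table) {
  fn <- feature_names(table)
  if (!identical(fn, object$features)) {
    abort("Feature namespace of `table` does not match the policy's.",
          class = "radqn_schema_error")
  }
  feature_matrix(table)
}

#' Greedy class predictions of a trained policy
#'
#' @param object A `dqn_policy`.
#' @param table Sample table whose feature namespace matches the policy's
#'   training namespace exactly (prediction is refused otherwise).
#' @param ... Unused.
#' @return Integer vector of predicted labels (greedy argmax, no
#'   exploration).
#' @export
predict.dqn_policy <- function(object, table, ...) {
  x <- policy_feature_matrix(object, table)
  q <- qnet_forward(object$net, x)
  max.col(q, ties.method = "first") - 1L
}

#' Softmax class probabilities of a trained policy
#'
#' Q-values mapped through a temperature-1 softmax. A convention for
#' calibration-style summaries (Brier scores, ROC/PR curves), not a claim
#' that Q-values are log-odds.
#'
#' @inheritParams predict.dqn_policy
#' @return Numeric matrix, samples x actions, rows summing to 1.
#' @export
predict_proba <- function(object, table) {
  x <- policy_feature_matrix(object, table)
  q <- qnet_forward(object$net, x)
  e <- exp(q - apply(q, 1, max))
  e / rowSums(e)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training trace of a policy
#'
#' @param x A `dqn_policy`.
#' @param ... Unused.
#' @return Tibble with one row per episode: `episode`, `reward`,
#'   `accuracy`, `loss`.
#' @export
tidy.dqn_policy <- function(x, ...) x$episode_log

#' One-row training summary of a policy
#'
#' @param x A `dqn_policy`.
#' @param ... Unused.
#' @return One-row tibble: variant, episodes, final and best episode
#'   accuracy, final cumulative reward, final epsilon.
#' @export
glance.dqn_policy <- function(x, ...) {
  tibble(variant = x$config$variant,
         episodes = nrow(x$episode_log),
         final_accuracy = tail(x$episode_log$accuracy, 1),
         best_accuracy = max(x$episode_log$accuracy),
         final_reward = tail(x$episode_log$reward, 1),
         epsilon_final = x$epsilon_final)
}

#' Save / load a policy checkpoint
#'
#' Single-file checkpoint holding the network parameters, configuration and
#' feature namespace; [predict.dqn_policy()] refuses tables whose namespace
#' does not match.
#'
#' @param policy A `dqn_policy`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_policy()` returns the policy.
#' @export
save_policy <- function(policy, path) {
  saveRDS(policy, path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  p <- readRDS(path)
  if (!inherits(p, "dqn_policy")) abort("Not a dqn_policy checkpoint.")
  p
}
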