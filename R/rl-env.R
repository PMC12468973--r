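# Episodic classification environment. One state per sample; the agent's
# action is a class prediction; reward is +1 for a correct prediction and
# -1 otherwise; an episode is one full traversal of the table. The
# transition is action-independent: the cursor advances regardless of what
# the agent predicted.

#' Create an episodic classification environment
#'
#' @param table Labeled sample table; feature vectors must be finite.
#' @param n_actions Size of the discrete action space: 2 for grading
#'   (LGG/HGG), 3 for survival classes. Defaults to `max(label) + 1`.
#' @param shuffle Reshuffle the traversal order at every reset. Default TRUE.
#' @param seed Integer seed for the traversal shuffles.
#' @return A `class_env` object (mutable environment) exposing
#'   [env_reset()] and [env_step()].
#' @export
make_env <- function(table, n_actions = NULL, shuffle = TRUE, seed = 1L) {
  validate_feature_table(table)
  if (nrow(table) == 0) abort("Empty table.")
  if (!("label" %in% names(table)) || anyNA(table$label)) {
    abort("Environment needs complete labels.")
  }
  x <- feature_matrix(table)
  if (any(!is.finite(x))) abort("Non-finite feature values.")
  e <- new.env(parent = emptyenv())
  e$x <- x
  e$labels <- as.integer(table$label)
  e$n <- nrow(x)
  e$n_actions <- as.integer(n_actions %||% (max(e$labels) + 1L))
  if (e$n_actions < 2L) e$n_actions <- 2L
  e$shuffle <- isTRUE(shuffle)
  e$seed <- as.integer(seed)
  e$episode <- 0L
  e$order <- seq_len(e$n)
  e$cursor <- 0L
  e$done <- TRUE
  class(e) <- "class_env"
  e
}

#' @export
print.class_env <- function(x, ...) {
  cat(sprintf("<class_env> %d samples, %d features, %d actions\n",
              x$n, ncol(x$x), x$n_actions))
  invisible(x)
}

#' Reset the environment to the start of a new episode
#'
#' @param env A `class_env`.
#' @param seed Optional seed overriding the environment's episode-shuffle
#'   stream; two resets with the same seed traverse in the same order.
#' @return The initial state: the first sample's feature vector.
#' @export
env_reset <- function(env, seed = NULL) {
  env$episode <- env$episode + 1L
  if (env$shuffle) {
    s <- seed %||% derive_seed(env$seed, env$episode)
    local_seed(s)
    env$order <- sample.int(env$n)
  } else {
    env$order <- seq_len(env$n)
  }
  env$cursor <- 1L
  env$done <- FALSE
  env$x[env$order[1L], ]
}

#' Advance the environment by one prediction
#'
#' Rewards +1 if `action` equals the current sample's label, -1 otherwise;
#' the cursor advances regardless of the action; `done` is TRUE after the
#' last sample, whereupon the next state is a terminal zero vector (never
#' bootstrapped from, because targets at terminals are the bare reward).
#'
#' @param env A `class_env` (must not be done; call [env_reset()] first).
#' @param action Integer action in `0 .. n_actions - 1`.
#' @return List with `state` (next feature vector), `reward` (+1/-1),
#'   `done` (flag), and `label` (the revealed true label).
#' @export
env_step <- function(env, action) {
  if (env$done) abort("Episode finished; call env_reset().",
                      class = "radqn_protocol_error")
  action <- as.integer(action)
  if (action < 0L || action >= env$n_actions) {
    abort(sprintf("Action %d outside 0..%d.", action, env$n_actions - 1L))
  }
  truth <- env$labels[env$order[env$cursor]]
  reward <- if (action == truth) 1 else -1
  env$cursor <- env$cursor + 1L
  if (env$cursor > env$n) {
    env$done <- TRUE
    state <- numeric(ncol(env$x))
  } else {
    state <- env$x[env$order[env$cursor], ]
  }
  list(state = state, reward = reward, done = env$done, label = truth)
}

#' Episode accuracy from unit rewards
#'
#' With rewards in +/-1 over an `n`-step episode, the fraction of correct
#' predictions is `(sum(rewards) + n) / (2 n)`.
#'
#' @param rewards Numeric vector of +/-1 episode rewards.
#' @return Accuracy in `[0, 1]`.
#' @export
episode_accuracy <- function(rewards) {
  n <- length(rewards)
  if (n == 0) abort("Empty reward sequence.")
  (sum(rewards) + n) / (2 * n)
}
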