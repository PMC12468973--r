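# Q-network family. A small fully connected trunk (default two hidden
# layers of 64 rectified units) feeds up to three heads: an advantage head
# (one output per action), a state-value head, and a scalar sigmoid head
# used either as a trunk gate (additive-attention ablation) or as the
# context-attention fusion weight w(s) of the final architecture. Forward,
# backward and the Adam update are written directly in matrix algebra: no
# deep-learning framework is available, the networks are tiny, and an
# explicit implementation keeps every formula testable against scalar
# oracles.

VARIANTS <- c("dqn", "double", "dueling", "dueling_double",
              "dueling_double_attn", "duelcontextattn")

variant_traits <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  list(
    use_value = variant %in% c("dueling", "dueling_double",
                               "dueling_double_attn", "duelcontextattn"),
    use_gate = variant == "dueling_double_attn",
    use_fusion = variant == "duelcontextattn",
    double = variant %in% c("double", "dueling_double",
                            "dueling_double_attn", "duelcontextattn")
  )
}

#' Dueling Q-value composition
#'
#' The dueling decomposition: `Q(s,a) = V(s) + A(s,a) - mean_a' A(s,a')`.
#' The advantage stream is mean-centered so the value stream is identified
#' as the mean Q-value of the state.
#'
#' @param value State value, scalar (or length-B vector for a batch).
#' @param advantages Advantage vector (or B x A matrix).
#' @return Q vector (or matrix) of the same shape as `advantages`.
#' @export
#' @examples
#' dueling_q(1, c(0, 2))  # c(0, 2)
dueling_q <- function(value, advantages) {
  a <- rbind(advantages)
  if (is.matrix(advantages)) a <- advantages
  q <- sweep(a - rowMeans(a), 1, value, "+")
  if (is.matrix(advantages)) q else drop(q)
}

#' Context-attention Q-value fusion
#'
#' Convex combination of the value and mean-centered advantage streams with
#' a state-dependent weight:
#' `Q(s,a) = w(s) V(s) + (1 - w(s)) (A(s,a) - mean_a' A(s,a'))`.
#' The weight must lie strictly inside (0, 1), as produced by a sigmoid
#' attention head.
#'
#' @param value State value, scalar or length-B vector.
#' @param advantages Advantage vector or B x A matrix.
#' @param weight Fusion weight(s) in (0, 1).
#' @return Q vector or matrix.
#' @export
#' @examples
#' fuse_q_values(2, c(1, 3), 0.5)  # c(0.5, 1.5)
fuse_q_values <- function(value, advantages, weight) {
  if (any(weight <= 0 | weight >= 1)) {
    abort("Fusion weight must lie strictly in (0, 1).")
  }
  a <- if (is.matrix(advantages)) advantages else rbind(advantages)
  centered <- a - rowMeans(a)
  q <- sweep(centered, 1, (1 - weight), "*") + outer(weight * value, rep(1, ncol(a)))
  if (is.matrix(advantages)) q else drop(q)
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

new_param <- function(w) list(w = w, m = array(0, dim(w)), v = array(0, dim(w)))

#' Initialize a Q-network
#'
#' @param input_dim State dimension.
#' @param n_actions Number of discrete actions.
#' @param variant Architecture variant, one of `"dqn"`, `"double"`,
#'   `"dueling"`, `"dueling_double"`, `"dueling_double_attn"`,
#'   `"duelcontextattn"`.
#' @param hidden Widths of the shared hidden layers. Default `c(64, 64)`.
#' @param seed Integer seed for the He-normal initialization.
#' @return A `qnet` object.
#' @export
qnet_init <- function(input_dim, n_actions, variant = "duelcontextattn",
                      hidden = c(64L, 64L), seed = 1L) {
  traits <- variant_traits(variant)
  local_seed(seed)
  h1 <- hidden[1]; h2 <- hidden[2]
  par <- list(
    W1 = new_param(he_init(input_dim, h1)), b1 = new_param(matrix(0, 1, h1)),
    W2 = new_param(he_init(h1, h2)), b2 = new_param(matrix(0, 1, h2)),
    Wa = new_param(he_init(h2, n_actions)), ba = new_param(matrix(0, 1, n_actions))
  )
  if (traits$use_value) {
    par$Wv <- new_param(he_init(h2, 1)); par$bv <- new_param(matrix(0, 1, 1))
  }
  if (traits$use_gate) {
    par$Wg <- new_param(he_init(h2, 1)); par$bg <- new_param(matrix(0, 1, 1))
  }
  if (traits$use_fusion) {
    par$Ww <- new_param(he_init(h2, 1)); par$bw <- new_param(matrix(0, 1, 1))
  }
  structure(list(par = par, variant = variant, traits = traits,
                 input_dim = as.integer(input_dim),
                 n_actions = as.integer(n_actions), adam_t = 0L),
            class = "qnet")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(z, b) sweep(z, 2, as.numeric(b), "+")

# Forward pass. X: B x d. Returns Q (B x A) and, if keep, the cache needed
# for the backward pass.
qnet_forward <- function(net, x, keep = FALSE) {
  p <- net$par; tr <- net$traits
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  z1 <- add_bias(x %*% p$W1$w, p$b1$w); h1 <- pmax(z1, 0)
  z2 <- add_bias(h1 %*% p$W2$w, p$b2$w); h2 <- pmax(z2, 0)
  g <- NULL
  h2h <- h2
  if (tr$use_gate) {
    g <- sigmoid(add_bias(h2 %*% p$Wg$w, p$bg$w))   # B x 1 trunk gate
    h2h <- h2 * as.numeric(g)
  }
  adv <- add_bias(h2h %*% p$Wa$w, p$ba$w)
  v <- NULL; w <- NULL
  if (tr$use_value) v <- add_bias(h2h %*% p$Wv$w, p$bv$w)
  if (tr$use_fusion) {
    # clamp away from {0,1}: sigmoid saturates to exactly 1.0 in double
    # precision for |z| > ~37, and the fusion demands an open interval
    w <- pmin(pmax(sigmoid(add_bias(h2h %*% p$Ww$w, p$bw$w)), 1e-7), 1 - 1e-7)
    q <- fuse_q_values(as.numeric(v), adv, as.numeric(w))
  } else if (tr$use_value) {
    q <- dueling_q(as.numeric(v), adv)
  } else {
    q <- adv
  }
  if (!keep) return(q)
  list(q = q, cache = list(x = x, z1 = z1, h1 = h1, z2 = z2, h2 = h2,
                           h2h = h2h, g = g, adv = adv, v = v, w = w))
}

# Backward pass from dQ (B x A); returns gradient list matching net$par.
qnet_backward <- function(net, cache, dq) {
  p <- net$par; tr <- net$traits
  grads <- list()
  nA <- ncol(dq)
  if (tr$use_fusion) {
    w <- as.numeric(cache$w); v <- as.numeric(cache$v)
    centered <- cache$adv - rowMeans(cache$adv)
    dv <- matrix(rowSums(dq) * w, ncol = 1)
    dc <- dq * (1 - w)
    dadv <- dc - rowMeans(dc)
    dwdot <- rowSums(dq * (matrix(v, nrow(dq), nA) - centered))
    dwz <- matrix(dwdot * w * (1 - w), ncol = 1)
  } else if (tr$use_value) {
    dv <- matrix(rowSums(dq), ncol = 1)
    dadv <- dq - rowMeans(dq)
    dwz <- NULL
  } else {
    dv <- NULL; dadv <- dq; dwz <- NULL
  }
  h2h <- cache$h2h
  grads$Wa <- crossprod(h2h, dadv); grads$ba <- matrix(colSums(dadv), 1)
  dh2h <- dadv %*% t(p$Wa$w)
  if (!is.null(dv)) {
    grads$Wv <- crossprod(h2h, dv); grads$bv <- matrix(sum(dv), 1, 1)
    dh2h <- dh2h + dv %*% t(p$Wv$w)
  }
  if (!is.null(dwz)) {
    grads$Ww <- crossprod(h2h, dwz); grads$bw <- matrix(sum(dwz), 1, 1)
    dh2h <- dh2h + dwz %*% t(p$Ww$w)
  }
  if (tr$use_gate) {
    g <- as.numeric(cache$g)
    dg <- rowSums(dh2h * cache$h2)
    dgz <- matrix(dg * g * (1 - g), ncol = 1)
    grads$Wg <- crossprod(cache$h2, dgz); grads$bg <- matrix(sum(dgz), 1, 1)
    dh2 <- dh2h * g + dgz %*% t(p$Wg$w)
  } else {
    dh2 <- dh2h
  }
  dz2 <- dh2 * (cache$z2 > 0)
  grads$W2 <- crossprod(cache$h1, dz2); grads$b2 <- matrix(colSums(dz2), 1)
  dh1 <- dz2 %*% t(p$W2$w)
  dz1 <- dh1 * (cache$z1 > 0)
  grads$W1 <- crossprod(cache$x, dz1); grads$b1 <- matrix(colSums(dz1), 1)
  grads
}

# One Adam step over all parameters present in grads.
qnet_adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  net$adam_t <- net$adam_t + 1L
  t <- net$adam_t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    pr <- net$par[[nm]]
    pr$m <- beta1 * pr$m + (1 - beta1) * g
    pr$v <- beta2 * pr$v + (1 - beta2) * g^2
    mhat <- pr$m / (1 - beta1^t)
    vhat <- pr$v / (1 - beta2^t)
    pr$w <- pr$w - lr * mhat / (sqrt(vhat) + eps)
    net$par[[nm]] <- pr
  }
  net
}

# Exact copy of online weights into the target network.
qnet_copy_weights <- function(from, to) {
  for (nm in names(from$par)) to$par[[nm]]$w <- from$par[[nm]]$w
  to
}

#' Temporal-difference target
#'
#' The regression target for Q-learning: the bare reward at terminal
#' transitions, otherwise `r + gamma * max_a' Q_target(s', a')`. Double
#' variants replace the target network's own maximization with the target
#' network evaluated at the online network's argmax action, which removes
#' the maximization bias.
#'
#' @param reward Transition reward.
#' @param next_state Next-state feature vector.
#' @param terminal Logical terminal flag.
#' @param gamma Discount factor.
#' @param target_net Target `qnet`.
#' @param online_net Online `qnet` (required when `double = TRUE`).
#' @param double Use the double-DQN action-selection rule. Default FALSE.
#' @return Scalar target value.
#' @export
td_target <- function(reward, next_state, terminal, gamma, target_net,
                      online_net = NULL, double = FALSE) {
  if (isTRUE(terminal)) return(reward)
  qt <- drop(qnet_forward(target_net, matrix(next_state, nrow = 1)))
  if (double) {
    if (is.null(online_net)) abort("Double targets need `online_net`.")
    qo <- drop(qnet_forward(online_net, matrix(next_state, nrow = 1)))
    a <- which.max(qo)
    reward + gamma * qt[a]
  } else {
    reward + gamma * max(qt)
  }
}

# Vectorized targets for a replay batch.
batch_targets <- function(rewards, next_states, terminals, gamma,
                          target_net, online_net, double) {
  y <- rewards
  live <- !terminals
  if (any(live)) {
    qt <- qnet_forward(target_net, next_states[live, , drop = FALSE])
    if (double) {
      qo <- qnet_forward(online_net, next_states[live, , drop = FALSE])
      a <- max.col(qo, ties.method = "first")
      boot <- qt[cbind(seq_len(nrow(qt)), a)]
    } else {
      boot <- apply(qt, 1, max)
    }
    y[live] <- rewards[live] + gamma * boot
  }
  y
}
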