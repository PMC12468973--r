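test_that("dueling and attention fusion match scalar oracles", {
  expect_equal(fuse_q_values(2.0, c(1.0, 3.0), 0.5), c(0.5, 1.5))
  # V = 0: Q = (1 - w) centered advantages, so mean(Q) = 0
  q <- fuse_q_values(0, c(2, 5, 8), 0.3)
  expect_equal(mean(q), 0, tolerance = 1e-12)
  # w -> 1 limit: advantage term vanishes
  expect_equal(fuse_q_values(1.7, c(-4, 9), 1 - 1e-12), c(1.7, 1.7),
               tolerance = 1e-9)
  expect_error(fuse_q_values(1, c(0, 1), 1.0))
  expect_error(fuse_q_values(1, c(0, 1), 0))

  expect_equal(dueling_q(1, c(0, 2)), c(0, 2))
  expect_equal(dueling_q(5, c(1, 1, 1)), c(5, 5, 5))   # constant A -> all V
  expect_equal(dueling_q(2, c(-1, 1)), 2 + c(-1, 1))   # zero-mean A
})

test_that("fusion identities hold on random networks of every variant", {
  withr::with_seed(5, x <- matrix(rnorm(60), 10, 6))
  # Plain dueling: mean_a Q(s, a) = V(s)
  for (variant in c("dueling", "dueling_double")) {
    net <- tiny_net(variant, d = 6, n_actions = 3, seed = 2)
    fw <- radqn:::qnet_forward(net, x, keep = TRUE)
    expect_equal(rowMeans(fw$q), as.numeric(fw$cache$v), tolerance = 1e-10)
  }
  # Context attention: mean_a Q(s, a) = w(s) V(s)
  net <- tiny_net("duelcontextattn", d = 6, n_actions = 3, seed = 2)
  fw <- radqn:::qnet_forward(net, x, keep = TRUE)
  expect_equal(rowMeans(fw$q),
               as.numeric(fw$cache$w) * as.numeric(fw$cache$v),
               tolerance = 1e-10)
  expect_true(all(fw$cache$w > 0 & fw$cache$w < 1))
  # gated ablation still satisfies the dueling identity
  netg <- tiny_net("dueling_double_attn", d = 6, n_actions = 3, seed = 2)
  fwg <- radqn:::qnet_forward(netg, x, keep = TRUE)
  expect_equal(rowMeans(fwg$q), as.numeric(fwg$cache$v), tolerance = 1e-10)
})

test_that("TD targets follow the terminal and discount rules", {
  tgt <- tiny_net("dqn", d = 3, n_actions = 2, seed = 1)
  onl <- tiny_net("dqn", d = 3, n_actions = 2, seed = 9)
  s <- c(0.1, -0.2, 0.5)
  expect_equal(td_target(-1, s, TRUE, 0.99, tgt), -1)     # terminal branch
  expect_equal(td_target(0.3, s, FALSE, 0, tgt), 0.3)     # gamma = 0
  qmax <- max(radqn:::qnet_forward(tgt, matrix(s, 1)))
  expect_equal(td_target(1, s, FALSE, 0.99, tgt), 1 + 0.99 * qmax)
  # frozen scalar oracle: r = 1, gamma = 0.99, max target Q = 2 -> 2.98
  expect_equal(1 + 0.99 * 2.0, 2.98)
  # double rule: target net evaluated at the online argmax
  qo <- radqn:::qnet_forward(onl, matrix(s, 1))
  qt <- radqn:::qnet_forward(tgt, matrix(s, 1))
  expect_equal(td_target(1, s, FALSE, 0.9, tgt, onl, double = TRUE),
               1 + 0.9 * qt[1, which.max(qo)])
})

test_that("double targets never exceed max targets for shared parameters", {
  tgt <- tiny_net("dueling_double", d = 5, n_actions = 3, seed = 3)
  onl <- tiny_net("dueling_double", d = 5, n_actions = 3, seed = 8)
  withr::with_seed(13, {
    for (i in 1:25) {
      s <- rnorm(5); r <- sample(c(-1, 1), 1)
      y_max <- td_target(r, s, FALSE, 0.99, tgt)
      y_dbl <- td_target(r, s, FALSE, 0.99, tgt, onl, double = TRUE)
      expect_lte(y_dbl, y_max + 1e-12)
    }
  })
})

test_that("epsilon-greedy explores uniformly and exploits deterministically", {
  q <- c(0.1, 0.9, 0.3)
  withr::with_seed(1, {
    expect_equal(epsilon_greedy(q, 0), 1L)                   # argmax, 0-based
    expect_equal(epsilon_greedy(c(0.5, 0.5), 0), 0L)         # tie -> lowest
  })
  withr::with_seed(2, {
    draws <- replicate(10000, epsilon_greedy(q, 1))
    freq <- tabulate(draws + 1L, 3) / 10000
    se3 <- 3 * sqrt((1 / 3) * (2 / 3) / 10000)
    expect_true(all(abs(freq - 1 / 3) < se3))
  })
})

test_that("epsilon decays multiplicatively to its floor", {
  cfg <- agent_config(epsilon = 0.5, epsilon_min = 0.01, epsilon_decay = 0.995)
  expect_equal(decay_epsilon(0.5, cfg), 0.4975)
  expect_equal(decay_epsilon(0.01, cfg), 0.01)
  eps <- Reduce(function(e, i) decay_epsilon(e, cfg), 1:2000, accumulate = TRUE,
                init = 0.5)
  expect_true(all(diff(eps) <= 0))
  expect_equal(min(eps), 0.01)
})

test_that("replay buffer is FIFO-bounded and target sync is exact", {
  b <- radqn:::new_replay_buffer(5, 2)
  for (i in 1:8) {
    radqn:::buffer_push(b, c(i, i), 0L, 1, c(i, i), FALSE)
  }
  expect_equal(b$size, 5L)                 # never exceeds capacity
  expect_false(any(b$states[, 1] %in% 1:3))  # oldest evicted first
  withr::with_seed(1, batch <- radqn:::buffer_sample(b, 3))
  expect_equal(nrow(batch$states), 3)
  expect_false(anyDuplicated(batch$states[, 1]) > 0)  # without replacement

  onl <- tiny_net("duelcontextattn", d = 4, n_actions = 2, seed = 5)
  tgt <- tiny_net("duelcontextattn", d = 4, n_actions = 2, seed = 6)
  withr::with_seed(3, x <- matrix(rnorm(20), 5, 4))
  expect_gt(max(abs(radqn:::qnet_forward(onl, x) - radqn:::qnet_forward(tgt, x))), 0)
  tgt <- sync_target(onl, tgt)
  expect_equal(radqn:::qnet_forward(tgt, x), radqn:::qnet_forward(onl, x),
               tolerance = 1e-7)
})

test_that("replay updates regress Q toward targets under MSE", {
  cfg <- agent_config(variant = "duelcontextattn", gamma = 0.99,
                      learning_rate = 0.01, seed = 1)
  onl <- tiny_net("duelcontextattn", d = 3, n_actions = 2, seed = 7)
  tgt <- sync_target(onl, tiny_net("duelcontextattn", d = 3, n_actions = 2, seed = 7))
  withr::with_seed(4, {
    batch <- list(states = matrix(rnorm(6), 2, 3),
                  actions = c(0L, 1L), rewards = c(1, -1),
                  next_states = matrix(rnorm(6), 2, 3),
                  terminals = c(TRUE, TRUE))
  })
  # loss equals the hand-computed MSE on this frozen 2-transition batch
  q0 <- radqn:::qnet_forward(onl, batch$states)
  expected_loss <- mean((c(q0[1, 1], q0[2, 2]) - batch$rewards)^2)
  upd <- replay_update(onl, batch, tgt, cfg)
  expect_equal(upd$loss, expected_loss, tolerance = 1e-12)
  # repeated updates on the one fixed batch drive the loss toward zero
  net <- onl
  losses <- numeric(300)
  for (i in 1:300) {
    u <- replay_update(net, batch, tgt, cfg)
    net <- u$online
    losses[i] <- u$loss
  }
  expect_lt(losses[300], 1e-3)
  expect_lt(losses[300], losses[1])
  # a batch whose targets equal current predictions has ~zero loss
  q1 <- radqn:::qnet_forward(net, batch$states)
  batch0 <- batch
  batch0$rewards <- c(q1[1, 1], q1[2, 2])
  expect_lt(replay_update(net, batch0, tgt, cfg)$loss, 1e-10)
  # dimension mismatch
  bad <- batch; bad$states <- matrix(0, 2, 5)
  expect_error(replay_update(net, bad, tgt, cfg))
})

test_that("analytic gradients agree with finite differences for every variant", {
  for (variant in c("dqn", "dueling", "dueling_double_attn", "duelcontextattn")) {
    net <- tiny_net(variant, d = 3, n_actions = 2, seed = 31)
    withr::with_seed(32, {
      x <- matrix(rnorm(9), 3, 3)
      y <- rnorm(3)
      act <- sample(0:1, 3, replace = TRUE)
    })
    loss_of <- function(nt) {
      q <- radqn:::qnet_forward(nt, x)
      mean((q[cbind(1:3, act + 1L)] - y)^2)
    }
    fw <- radqn:::qnet_forward(net, x, keep = TRUE)
    pred <- fw$q[cbind(1:3, act + 1L)]
    dq <- matrix(0, 3, 2)
    dq[cbind(1:3, act + 1L)] <- 2 * (pred - y) / 3
    grads <- radqn:::qnet_backward(net, fw$cache, dq)
    for (nm in c("W1", "Wa", names(grads)[names(grads) %in% c("Wv", "Wg", "Ww")])) {
      w <- net$par[[nm]]$w
      h <- 1e-6
      nt <- net; nt$par[[nm]]$w[1, 1] <- w[1, 1] + h; fplus <- loss_of(nt)
      nt <- net; nt$par[[nm]]$w[1, 1] <- w[1, 1] - h; fminus <- loss_of(nt)
      expect_equal(grads[[nm]][1, 1], (fplus - fminus) / (2 * h),
                   tolerance = 1e-4,
                   info = paste(variant, nm))
    }
  }
})
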