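# --- small helpers to build controlled networks and batches ---------------

fixed_batch <- function(n = 4, d = 3, K = 2, seed = 9) {
  set.seed(seed)
  list(S = matrix(rnorm(n * d), n, d),
       Snext = matrix(rnorm(n * d), n, d),
       A = matrix(rbinom(n * K, 1, 0.5), n, K),
       r = rnorm(n),
       terminal = c(TRUE, rep(FALSE, n - 1)),
       Didx = NULL)
}

small_nets <- function(d = 3, K = 2, hidden = 4, seed = 2) {
  set.seed(seed)
  list(actor = icudtr:::new_net("actor", d, K, hidden),
       critic = icudtr:::new_net("critic", d, K, hidden))
}

test_that("critic targets mask the bootstrap at termination and obey gamma", {
  nets <- small_nets()
  b <- fixed_batch()
  b$r <- c(-15, 1, 2, 3)
  y <- critic_target(b, nets$actor, nets$critic, gamma = 0.99)
  expect_equal(y[1], -15)  # terminal: reward only, networks irrelevant
  y0 <- critic_target(b, nets$actor, nets$critic, gamma = 0)
  expect_equal(y0, b$r)    # gamma = 0 collapses to the reward everywhere
})

test_that("critic targets match a hand-computed forward pass", {
  d <- 2; K <- 1
  critic <- icudtr:::new_net("critic", d, K, hidden = 2)
  actor <- icudtr:::new_net("actor", d, K, hidden = 2)
  # hand-set weights
  actor$params$W1 <- matrix(c(1, 0, 0, 1), 2, 2)
  actor$params$b1 <- c(0, 0)
  actor$params$W2 <- matrix(c(1, -1), 2, 1)
  actor$params$b2 <- 0.5
  critic$params$W1 <- matrix(0.1 * (1:6), 3, 2)  # inputs: s1, s2, a
  critic$params$b1 <- c(0.1, -0.1)
  critic$params$W2 <- matrix(c(2, 1), 2, 1)
  critic$params$b2 <- -0.3
  s_next <- matrix(c(0.4, -0.2), 1, 2)
  b <- list(S = matrix(0, 1, 2), Snext = s_next, A = matrix(1, 1, 1),
            r = 0.7, terminal = FALSE, Didx = NULL)
  gamma <- 0.9
  # oracle: explicit arithmetic, no package forward code
  h_a <- tanh(c(0.4, -0.2))
  mu <- 1 / (1 + exp(-(sum(h_a * c(1, -1)) + 0.5)))
  x <- c(0.4, -0.2, mu)
  h_c <- tanh(c(sum(x * c(0.1, 0.2, 0.3)) + 0.1,
                sum(x * c(0.4, 0.5, 0.6)) - 0.1))
  q <- sum(h_c * c(2, 1)) - 0.3
  expect_equal(critic_target(b, actor, critic, gamma), 0.7 + gamma * q,
               tolerance = 1e-12)
})

test_that("critic loss is the mean squared residual", {
  nets <- small_nets()
  b <- fixed_batch(n = 2)
  q <- icudtr:::net_forward(nets$critic, b$S, NULL, b$A)$out[, 1]
  expect_equal(critic_loss(b, nets$critic, q), 0)
  expect_equal(critic_loss(b, nets$critic, q + c(1, -3)), 5)
  expect_gte(critic_loss(b, nets$critic, rnorm(2)), 0)
})

test_that("reinforcement loss of a constant critic is flat", {
  nets <- small_nets()
  # zero first-layer weights: critic output is a constant
  nets$critic$params$W1[] <- 0
  nets$critic$params$b1[] <- 0
  const <- sum(tanh(0) * nets$critic$params$W2) + nets$critic$params$b2
  b <- fixed_batch()
  expect_equal(actor_rl_loss(b, nets$actor, nets$critic), -const)
  g <- icudtr:::actor_gradients(b, nets$actor, nets$critic, epsilon = 1)
  expect_true(all(abs(unlist(g$grads)) < 1e-12))
})

test_that("duplicating a batch leaves the mean losses unchanged", {
  nets <- small_nets()
  b <- fixed_batch(n = 3)
  b2 <- lapply(b, function(x) if (is.matrix(x)) rbind(x, x) else c(x, x))
  expect_equal(actor_rl_loss(b2, nets$actor, nets$critic),
               actor_rl_loss(b, nets$actor, nets$critic))
  expect_equal(actor_sl_loss(b2, nets$actor), actor_sl_loss(b, nets$actor))
})

test_that("supervised loss closed forms hold", {
  d <- 2; K <- 1
  actor <- icudtr:::new_net("actor", d, K, hidden = 2)
  # force probability 0.5 regardless of input
  actor$params$W1[] <- 0; actor$params$b1[] <- 0
  actor$params$W2[] <- 0; actor$params$b2[] <- 0
  b <- list(S = matrix(0, 1, 2), A = matrix(1, 1, 1), Didx = NULL)
  expect_equal(actor_sl_loss(b, actor, "bce"), log(2))
  # as-printed degeneracy: an all-zero action vector scores 0 for any actor
  b0 <- list(S = matrix(rnorm(2), 1, 2), A = matrix(0, 1, 1), Didx = NULL)
  expect_equal(actor_sl_loss(b0, actor, "as_printed"), 0)
  expect_gt(actor_sl_loss(b0, actor, "bce"), 0)
})

test_that("near-perfect prediction drives the supervised loss toward zero", {
  d <- 2; K <- 2
  actor <- icudtr:::new_net("actor", d, K, hidden = 2)
  actor$params$W1[] <- 0; actor$params$b1[] <- 0
  actor$params$W2[] <- 0
  actor$params$b2 <- c(30, -30)  # saturated probabilities ~1 and ~0
  b <- list(S = matrix(0, 3, 2), A = cbind(rep(1, 3), rep(0, 3)),
            Didx = NULL)
  expect_lt(actor_sl_loss(b, actor, "bce"), 1e-10)
})

test_that("the blended objective is the stated convex combination", {
  expect_equal(combined_loss(2, 1, 0.4), 1.4)
  expect_equal(combined_loss(2, 1, 0), 1)
  expect_equal(combined_loss(2, 1, 1), 2)
  expect_error(combined_loss(1, 1, 1.2))
})

test_that("soft updates interpolate, copy at tau 1, freeze at tau 0", {
  live <- list(W = matrix(4, 2, 2), b = c(4, 4))
  target <- list(W = matrix(0, 2, 2), b = c(0, 0))
  expect_equal(soft_update(live, target, 0.25)$W[1, 1], 1)
  expect_equal(soft_update(live, target, 1), live)
  expect_equal(soft_update(live, target, 0), target)
})

test_that("one soft update shrinks the live-target gap by exactly 1 - tau", {
  nets <- small_nets()
  live <- nets$actor$params
  target <- lapply(live, function(x) x + 1)
  tau <- 0.3
  upd <- soft_update(live, target, tau)
  gap_before <- sqrt(sum(unlist(Map(`-`, target, live))^2))
  gap_after <- sqrt(sum(unlist(Map(`-`, upd, live))^2))
  expect_equal(gap_after / gap_before, 1 - tau, tolerance = 1e-12)
})

test_that("analytic actor gradients match finite differences at the blend limits", {
  nets <- small_nets(d = 4, K = 3, hidden = 5, seed = 8)
  b <- fixed_batch(n = 6, d = 4, K = 3, seed = 12)
  coords <- pick_coords(nets$actor$params)
  for (eps in c(0, 1, 0.4)) {
    analytic <- icudtr:::actor_gradients(b, nets$actor, nets$critic, eps)
    ga <- vapply(seq_len(nrow(coords)), function(i) {
      analytic$grads[[coords$param[i]]][coords$index[i]]
    }, numeric(1))
    gn <- numeric_actor_grad(nets$actor, coords, function(a) {
      rl <- if (eps > 0) actor_rl_loss(b, a, nets$critic) else 0
      sl <- if (eps < 1) actor_sl_loss(b, a) else 0
      eps * rl + (1 - eps) * sl
    })
    denom <- max(abs(gn), 1e-8)
    expect_lt(max(abs(ga - gn)) / denom, 1e-6)
  }
})

test_that("at the blend limits the update equals the pure-loss update", {
  nets <- small_nets(d = 4, K = 3, hidden = 5, seed = 8)
  b <- fixed_batch(n = 6, d = 4, K = 3, seed = 12)
  # epsilon = 0: identical to the gradient of the supervised loss alone
  g0 <- icudtr:::actor_gradients(b, nets$actor, nets$critic, 0)$grads
  coords <- pick_coords(nets$actor$params)
  gn_sl <- numeric_actor_grad(nets$actor, coords,
                              function(a) actor_sl_loss(b, a))
  ga0 <- vapply(seq_len(nrow(coords)),
                function(i) g0[[coords$param[i]]][coords$index[i]],
                numeric(1))
  expect_lt(max(abs(ga0 - gn_sl)) / max(abs(gn_sl), 1e-8), 1e-6)
  # epsilon = 1: identical to the gradient of the reinforcement loss alone
  g1 <- icudtr:::actor_gradients(b, nets$actor, nets$critic, 1)$grads
  gn_rl <- numeric_actor_grad(nets$actor, coords,
                              function(a) actor_rl_loss(b, a, nets$critic))
  ga1 <- vapply(seq_len(nrow(coords)),
                function(i) g1[[coords$param[i]]][coords$index[i]],
                numeric(1))
  expect_lt(max(abs(ga1 - gn_rl)) / max(abs(gn_rl), 1e-8), 1e-6)
})

test_that("critic gradients match finite differences", {
  nets <- small_nets(d = 4, K = 3, hidden = 5, seed = 8)
  b <- fixed_batch(n = 6, d = 4, K = 3, seed = 12)
  y <- rnorm(6)
  analytic <- icudtr:::critic_gradients(b, nets$critic, y)$grads
  coords <- pick_coords(nets$critic$params)
  h <- 1e-5
  gn <- vapply(seq_len(nrow(coords)), function(i) {
    nm <- coords$param[i]; j <- coords$index[i]
    up <- nets$critic; up$params[[nm]][j] <- up$params[[nm]][j] + h
    dn <- nets$critic; dn$params[[nm]][j] <- dn$params[[nm]][j] - h
    (critic_loss(b, up, y) - critic_loss(b, dn, y)) / (2 * h)
  }, numeric(1))
  ga <- vapply(seq_len(nrow(coords)),
               function(i) analytic[[coords$param[i]]][coords$index[i]],
               numeric(1))
  expect_lt(max(abs(ga - gn)) / max(abs(gn), 1e-8), 1e-6)
})

test_that("diagnosis-embedding gradients match finite differences", {
  set.seed(21)
  actor <- icudtr:::new_net("actor", 3, 2, hidden = 4, embed_rows = 6,
                            embed_dim = 3)
  b <- fixed_batch(n = 5, d = 3, K = 2, seed = 14)
  b$Didx <- matrix(sample(0:6, 15, replace = TRUE), 5, 3)
  b$Didx[1, ] <- 0L  # a patient with no codes
  g <- icudtr:::actor_gradients(b, actor, NULL, epsilon = 0)$grads
  coords <- pick_coords(actor$params["E"], n_per = 8)
  gn <- numeric_actor_grad(actor, coords, function(a) actor_sl_loss(b, a))
  ga <- vapply(seq_len(nrow(coords)),
               function(i) g$E[coords$index[i]], numeric(1))
  expect_lt(max(abs(ga - gn)) / max(abs(gn), 1e-8), 1e-6)
})

test_that("training is reproducible under a fixed seed", {
  dev <- tiny_processed()$development
  cfg <- train_config(steps = 60, eval_every = 30, hidden_actor = 8,
                      hidden_critic = 8, embed_dim = 2, seed = 42)
  m1 <- train_srl(dev, cfg)
  m2 <- train_srl(dev, cfg)
  expect_identical(m1$actor$params, m2$actor$params)
  expect_identical(m1$trace, m2$trace)
})

test_that("recommendations threshold probabilities with exact limits", {
  m <- tiny_model()
  dev <- tiny_processed()$development
  rec <- recommend(m, dev)
  expect_true(all(rec$prob > 0 & rec$prob < 1))
  expect_true(all(rec$action %in% c(0L, 1L)))
  expect_identical(rec$action, matrix(as.integer(rec$prob >= 0.5),
                                      nrow(rec$prob), ncol(rec$prob)))
  expect_true(all(recommend(m, dev, threshold = 0)$action == 1L))
  # probabilities are strictly below 1, so a threshold of 1 empties the set
  expect_true(all(recommend(m, dev, threshold = 1)$action == 0L))
})

test_that("a day's window depends only on the last W days (window sufficiency)", {
  dev <- tiny_processed()$development
  W <- 5L
  S_full <- icudtr:::build_state_matrix(dev, W)
  # truncate the first admission to its first t days and rebuild
  tr <- dev$trajectories[[1]]
  t_cut <- tr$T
  trunc <- dev
  keep_rows <- which(dev$pooled$adm == 1 & dev$pooled$day <= t_cut)
  sub <- function(x) x[keep_rows, , drop = FALSE]
  trunc$trajectories <- list(tr)
  trunc$pooled <- list(feat = sub(dev$pooled$feat),
                       rhythm = sub(dev$pooled$rhythm),
                       actions = sub(dev$pooled$actions),
                       adm = rep(1L, t_cut), day = seq_len(t_cut),
                       T_len = t_cut, died = dev$pooled$died[1])
  trunc$statics_std <- dev$statics_std[1, , drop = FALSE]
  trunc$diag_idx <- dev$diag_idx[1, , drop = FALSE]
  S_trunc <- icudtr:::build_state_matrix(trunc, W)
  expect_equal(S_trunc, S_full[keep_rows, , drop = FALSE])
})

test_that("outcome-weighted policy optimization standardizes returns as stated", {
  dev <- tiny_processed()$development
  cfg <- train_config(steps = 40, eval_every = 20, hidden_actor = 8,
                      embed_dim = 2, seed = 6, gamma = 1)
  m <- train_dpo(dev, cfg)
  expect_s3_class(m, "srl_model")
  expect_identical(m$kind, "dpo")
  # with gamma = 1 every day's V equals the terminal reward, so the
  # admission-day V set has mean/SD determined by the outcome mix
  trans <- icudtr:::build_transitions(dev, 15, 15, cfg$window)
  V <- ifelse(trans$died[trans$adm], -15, 15)
  expect_equal(m$v_stats$mean, mean(V))
  expect_equal(m$v_stats$sd, sd(V))
  w <- (V - mean(V)) / sd(V)
  expect_equal(mean(w), 0, tolerance = 1e-12)
  expect_equal(sd(w), 1, tolerance = 1e-12)
})

test_that("two single-day admissions with opposite outcomes give weights 1 over root 2", {
  V <- c(15, -15) / 15  # r = +1 / -1
  w <- (V - mean(V)) / sd(V)
  expect_equal(w, c(1, -1) / sqrt(2))
})

test_that("outcome-weighted training demands a mixed-outcome cohort", {
  co <- manual_cohort(list(matrix(1L, 2, 10), matrix(0L, 3, 10)),
                      died = c(FALSE, FALSE))
  prep <- preprocess_cohort(co, config = preprocess_config(
    composites = character(0), knn_k = 2))
  expect_error(train_dpo(prep$development,
                         train_config(steps = 5, hidden_actor = 4,
                                      embed_dim = 2)),
               "outcomes identical")
})

test_that("the dual-branch classifier has K outputs and beats majority vote", {
  dev <- tiny_processed()$development
  cfg <- train_config(steps = 600, eval_every = 300, hidden_actor = 16,
                      embed_dim = 4, seed = 10)
  m <- train_dual_lstm(dev, cfg)
  rec <- recommend(m, dev)
  K <- length(dev$drug_names)
  expect_equal(ncol(rec$prob), K)
  # majority-vote baseline: prescribe each drug iff its overall rate > 0.5
  act <- dev$pooled$actions
  maj <- matrix(rep(as.integer(colMeans(act) > 0.5), each = nrow(act)),
                nrow(act), K)
  j_model <- mean_jaccard(act, rec$action, dev$pooled$adm)
  j_maj <- mean_jaccard(act, maj, dev$pooled$adm)
  expect_gt(j_model, j_maj)
  # deterministic retraining
  m2 <- train_dual_lstm(dev, cfg)
  expect_identical(m$actor$params, m2$actor$params)
})
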