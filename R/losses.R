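#' Training configuration for the actor-critic learner
#'
#' @param epsilon trade-off weight in `[0, 1]` between the reinforcement
#'   (expected-return) and supervised (clinician-matching) actor losses:
#'   `L = epsilon * L_RL + (1 - epsilon) * L_SL`. 0 is the pure supervised
#'   model, 1 the pure reinforcement model.
#' @param gamma reward discount in `[0, 1]`.
#' @param tau soft-update weight of the target networks in `(0, 1]`.
#' @param window number of past days (W) in the state window.
#' @param batch_size minibatch size N.
#' @param lr_actor,lr_critic Adam learning rates.
#' @param steps number of gradient steps (one minibatch per step).
#' @param hidden_actor,hidden_critic hidden-layer widths.
#' @param embed_dim diagnosis-embedding width per code.
#' @param use_diagnoses include the diagnosis-embedding branch.
#' @param action_threshold probability cut converting the actor's per-drug
#'   probabilities into a binary recommendation.
#' @param r_survive,r_die magnitudes of the terminal reward (+r_survive on
#'   survival, -r_die on in-hospital death; rewards are zero before the
#'   final day).
#' @param sl_mode supervised loss form: `"bce"` (full per-drug binary
#'   cross-entropy, default) or `"as_printed"` (positive-label-only
#'   cross-entropy; degenerate on its own — its unconstrained minimizer is
#'   the all-ones prediction — but kept selectable for audit).
#' @param terminal_bootstrap `"drop"` removes the discounted bootstrap term
#'   at trajectory termination; `"zero_state"` instead evaluates the target
#'   networks on the zero next-state.
#' @param clip_targets clamp the bootstrapped critic targets to the known
#'   return bound `[-r_die, r_survive]` implied by terminal-only rewards;
#'   guards the offline critic against the bootstrap overestimation spiral.
#' @param target_action how the target actor's output enters the target
#'   critic when forming bootstrap targets: `"binary"` (default) thresholds
#'   it into a drug set, keeping the critic's action inputs on the discrete
#'   action space it is trained on; `"probability"` feeds the raw
#'   probabilities (the continuous-action reading).
#' @param eval_every record the training trace (validation expected return,
#'   Jaccard, losses) every this many steps.
#' @param eval_fraction fraction of admissions held out as the trace's
#'   validation slice.
#' @param seed seed for initialization and minibatch sampling.
#' @return a `train_config` list.
#' @export
train_config <- function(epsilon = 0.4, gamma = 0.99, tau = 0.005,
                         window = 5L, batch_size = 64L,
                         lr_actor = 1e-3, lr_critic = 1e-3,
                         steps = 2000L, hidden_actor = 64L,
                         hidden_critic = 64L, embed_dim = 8L,
                         use_diagnoses = TRUE,
                         action_threshold = 0.5,
                         r_survive = 15, r_die = 15,
                         sl_mode = c("bce", "as_printed"),
                         terminal_bootstrap = c("drop", "zero_state"),
                         clip_targets = TRUE,
                         target_action = c("binary", "probability"),
                         eval_every = 200L, eval_fraction = 0.1,
                         seed = 1L) {
  sl_mode <- match.arg(sl_mode)
  terminal_bootstrap <- match.arg(terminal_bootstrap)
  target_action <- match.arg(target_action)
  stopifnot(epsilon >= 0, epsilon <= 1, gamma >= 0, gamma <= 1,
            tau > 0, tau <= 1, window >= 1, batch_size >= 1,
            action_threshold >= 0, action_threshold <= 1,
            steps >= 1, lr_actor > 0, lr_critic > 0)
  structure(list(epsilon = epsilon, gamma = gamma, tau = tau,
                 window = as.integer(window),
                 batch_size = as.integer(batch_size),
                 lr_actor = lr_actor, lr_critic = lr_critic,
                 steps = as.integer(steps),
                 hidden_actor = as.integer(hidden_actor),
                 hidden_critic = as.integer(hidden_critic),
                 embed_dim = as.integer(embed_dim),
                 use_diagnoses = use_diagnoses,
                 action_threshold = action_threshold,
                 r_survive = r_survive, r_die = r_die,
                 sl_mode = sl_mode,
                 terminal_bootstrap = terminal_bootstrap,
                 clip_targets = clip_targets,
                 target_action = target_action,
                 eval_every = as.integer(eval_every),
                 eval_fraction = eval_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

PROB_EPS <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# minibatch container: list(S, Snext, A, r, terminal, Didx)
batch_slice <- function(trans, idx) {
  list(S = trans$S[idx, , drop = FALSE],
       Snext = trans$Snext[idx, , drop = FALSE],
       A = trans$A[idx, , drop = FALSE],
       r = trans$r[idx],
       terminal = trans$terminal[idx],
       Didx = if (!is.null(trans$Didx)) trans$Didx[idx, , drop = FALSE])
}

#' Bootstrapped critic regression targets
#'
#' Computes `y_i = r_i + gamma * Q'(S_{i,t+1}, mu'(S_{i,t+1}))` from the
#' target networks; for terminal transitions (where the next state is the
#' trajectory-termination marker) the bootstrap term is dropped by default,
#' leaving `y_i = r_i`.
#'
#' @param batch a transition minibatch (list with `S`, `Snext`, `A`, `r`,
#'   `terminal`, optionally `Didx`).
#' @param target_actor,target_critic target network objects.
#' @param gamma reward discount.
#' @param terminal_bootstrap,target_action,action_threshold see
#'   [train_config()].
#' @return numeric vector of per-sample targets.
#' @export
critic_target <- function(batch, target_actor, target_critic, gamma,
                          terminal_bootstrap = "drop",
                          target_action = "probability",
                          action_threshold = 0.5) {
  mu_next <- net_forward(target_actor, batch$Snext, batch$Didx)$out
  if (target_action == "binary") {
    mu_next <- (mu_next >= action_threshold) + 0
  }
  q_next <- net_forward(target_critic, batch$Snext, batch$Didx,
                        mu_next)$out[, 1]
  if (!all(is.finite(q_next))) {
    stop("non-finite target-network output; training aborted", call. = FALSE)
  }
  if (terminal_bootstrap == "drop") {
    batch$r + gamma * ifelse(batch$terminal, 0, q_next)
  } else {
    batch$r + gamma * q_next
  }
}

#' Critic mean-square-error loss
#'
#' `(1/N) * sum((y_i - Q(S_i, A_i))^2)`.
#'
#' @param batch a transition minibatch.
#' @param critic critic network object.
#' @param targets per-sample targets from [critic_target()].
#' @return scalar loss.
#' @export
critic_loss <- function(batch, critic, targets) {
  q <- net_forward(critic, batch$S, batch$Didx, batch$A)$out[, 1]
  mean((targets - q)^2)
}

#' Reinforcement (deterministic-policy-gradient) actor loss
#'
#' The negative mean critic value of the actor's own actions,
#' `-(1/N) * sum(Q(S_i, mu(S_i)))`; its gradient flows through the action
#' input of the critic into the actor parameters.
#'
#' @param batch a transition minibatch.
#' @param actor,critic network objects.
#' @return scalar loss.
#' @export
actor_rl_loss <- function(batch, actor, critic) {
  p <- net_forward(actor, batch$S, batch$Didx)$out
  q <- net_forward(critic, batch$S, batch$Didx, p)$out[, 1]
  -mean(q)
}

#' Supervised actor loss
#'
#' Per-drug cross-entropy between the actor's probabilities and the
#' clinician's actual binary actions. The default `"bce"` form is the full
#' binary cross-entropy
#' `-(1/N) * sum_i sum_k [a log(p) + (1 - a) log(1 - p)]`; the `"as_printed"`
#' form keeps only the positive-label term `-(1/N) * sum a * log(p)`.
#' Probabilities are clamped away from 0/1 by a machine-epsilon floor before
#' taking logs.
#'
#' @param batch a transition minibatch.
#' @param actor actor network object.
#' @param mode `"bce"` or `"as_printed"`.
#' @return scalar loss.
#' @export
actor_sl_loss <- function(batch, actor, mode = c("bce", "as_printed")) {
  mode <- match.arg(mode)
  p <- clamp_prob(net_forward(actor, batch$S, batch$Didx)$out)
  a <- batch$A
  N <- nrow(a)
  if (mode == "bce") {
    -sum(a * log(p) + (1 - a) * log(1 - p)) / N
  } else {
    -sum(a * log(p)) / N
  }
}

#' Blended actor objective
#'
#' `epsilon * rl_loss + (1 - epsilon) * sl_loss`; `epsilon = 0` recovers the
#' pure supervised model and `epsilon = 1` the pure reinforcement model.
#'
#' @param rl_loss,sl_loss scalar losses.
#' @param epsilon trade-off weight in `[0, 1]`.
#' @return scalar loss.
#' @export
combined_loss <- function(rl_loss, sl_loss, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  epsilon * rl_loss + (1 - epsilon) * sl_loss
}

# Analytic actor gradients of the blended objective on one minibatch.
# Returns the parameter gradients plus the component losses; used by the
# training loop and, in the tests, checked against finite differences.
actor_gradients <- function(batch, actor, critic, epsilon,
                            sl_mode = "bce") {
  fp <- net_forward(actor, batch$S, batch$Didx)
  p <- clamp_prob(fp$out)
  N <- nrow(p)
  a <- batch$A
  dZ2 <- matrix(0, N, ncol(p))
  rl <- NA_real_
  if (epsilon > 0) {
    fq <- net_forward(critic, batch$S, batch$Didx, p)
    rl <- -mean(fq$out[, 1])
    dqda <- critic_action_grad(critic, fq$cache,
                               matrix(-1 / N, N, 1))
    dZ2 <- dZ2 + epsilon * dqda * p * (1 - p)
  }
  sl <- if (sl_mode == "bce") {
    -sum(a * log(p) + (1 - a) * log(1 - p)) / N
  } else {
    -sum(a * log(p)) / N
  }
  if (epsilon < 1) {
    dZ2_sl <- if (sl_mode == "bce") (p - a) / N else -a * (1 - p) / N
    dZ2 <- dZ2 + (1 - epsilon) * dZ2_sl
  }
  grads <- net_backward(actor, fp$cache, dZ2)
  list(grads = grads, rl_loss = rl, sl_loss = sl,
       loss = combined_loss(ifelse(is.na(rl), 0, rl), sl, epsilon))
}

# Analytic critic gradients of the MSE loss on one minibatch.
critic_gradients <- function(batch, critic, targets) {
  fq <- net_forward(critic, batch$S, batch$Didx, batch$A)
  resid <- fq$out[, 1] - targets
  dq <- matrix(2 * resid / length(resid), ncol = 1)
  list(grads = net_backward(critic, fq$cache, dq),
       loss = mean(resid^2))
}
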