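# Core offline actor-critic loop on a generic transition set. Kept separate
# from the cohort plumbing so that small controlled decision processes (e.g.
# the solvable toy problems in the tests) can exercise it directly.
ddpg_train <- function(trans, config, embed_rows = 0L, eval_fun = NULL) {
  set.seed(config$seed)
  d_state <- ncol(trans$S)
  K <- ncol(trans$A)
  use_diag <- config$use_diagnoses && embed_rows > 0L && !is.null(trans$Didx)
  er <- if (use_diag) embed_rows else 0L
  actor <- new_net("actor", d_state, K, config$hidden_actor, er,
                   config$embed_dim)
  critic <- new_net("critic", d_state, K, config$hidden_critic, er,
                    config$embed_dim)
  target_actor <- actor
  target_critic <- critic
  st_a <- adam_init(actor$params)
  st_c <- adam_init(critic$params)
  if (!use_diag) trans$Didx <- NULL

  trace <- list()
  last_good <- NULL
  for (step in seq_len(config$steps)) {
    idx <- sample.int(trans$n, min(config$batch_size, trans$n))
    batch <- batch_slice(trans, idx)

    y <- critic_target(batch, target_actor, target_critic, config$gamma,
                       config$terminal_bootstrap,
                       config$target_action %||% "probability",
                       config$action_threshold)
    if (isTRUE(config$clip_targets)) {
      y <- pmin(pmax(y, -config$r_die), config$r_survive)
    }
    cg <- critic_gradients(batch, critic, y)
    up <- adam_step(critic$params, cg$grads, st_c, config$lr_critic)
    critic$params <- up$params; st_c <- up$state

    ag <- actor_gradients(batch, actor, critic, config$epsilon,
                          config$sl_mode)
    up <- adam_step(actor$params, ag$grads, st_a, config$lr_actor)
    actor$params <- up$params; st_a <- up$state

    target_actor$params <- soft_update(actor$params, target_actor$params,
                                       config$tau)
    target_critic$params <- soft_update(critic$params, target_critic$params,
                                        config$tau)

    if (!is.finite(cg$loss) || !is.finite(ag$sl_loss)) {
      warning("non-finite loss at step ", step,
              "; returning last good checkpoint")
      if (!is.null(last_good)) return(last_good)
      stop("training diverged before the first checkpoint", call. = FALSE)
    }

    if (step %% config$eval_every == 0L || step == config$steps) {
      row <- data.frame(step = step, critic_loss = cg$loss,
                        actor_rl_loss = ag$rl_loss,
                        actor_sl_loss = ag$sl_loss)
      if (!is.null(eval_fun)) row <- cbind(row, eval_fun(actor, critic))
      trace[[length(trace) + 1L]] <- row
      last_good <- list(actor = actor, critic = critic,
                        target_actor = target_actor,
                        target_critic = target_critic,
                        trace = do.call(rbind, trace), config = config)
    }
  }
  list(actor = actor, critic = critic, target_actor = target_actor,
       target_critic = target_critic, trace = do.call(rbind, trace),
       config = config)
}

# chunked forward passes over large row sets
forward_chunked <- function(net, S, Didx = NULL, A = NULL, chunk = 4096L) {
  n <- nrow(S)
  out <- NULL
  for (lo in seq(1, n, by = chunk)) {
    sel <- lo:min(lo + chunk - 1L, n)
    o <- net_forward(net, S[sel, , drop = FALSE],
                     if (!is.null(Didx)) Didx[sel, , drop = FALSE],
                     if (!is.null(A)) A[sel, , drop = FALSE])$out
    out <- rbind(out, o)
  }
  out
}

#' Train the blended supervised/reinforcement prescription model
#'
#' Offline actor-critic training on the admission-day transitions of a
#' processed cohort. Each gradient step samples a minibatch of
#' `(S_t, A_t, S_{t+1}, r_t)` tuples, regresses the critic on the
#' bootstrapped targets of [critic_target()] (Adam), updates the actor on
#' the blended objective of [combined_loss()] (Adam), and soft-updates both
#' target networks. Rewards are terminal-only: `+r_survive` on survival,
#' `-r_die` on in-hospital death.
#'
#' The trace records, every `eval_every` steps, the minibatch losses plus
#' the mean expected return `Q(S, mu(S))` and the Jaccard similarity to the
#' clinicians on a held-out validation slice of admissions.
#'
#' @param pcohort a `processed_cohort` from [preprocess_apply()].
#' @param config a [train_config()]. `epsilon = 0` yields the pure
#'   supervised model, `epsilon = 1` the pure reinforcement model.
#' @return an `srl_model`: actor, critic, their target copies, the training
#'   trace (data frame), the config, and the preprocessing metadata.
#' @export
train_srl <- function(pcohort, config = train_config()) {
  stopifnot(inherits(pcohort, "processed_cohort"),
            inherits(config, "train_config"))
  trans <- build_transitions(pcohort, config$r_survive, config$r_die,
                             config$window)
  embed_rows <- length(pcohort$metadata$vocab) + 1L
  n_adm <- length(pcohort$trajectories)
  set.seed(config$seed)
  n_val <- max(1L, round(config$eval_fraction * n_adm))
  val_adm <- sample.int(n_adm, n_val)
  val_rows <- which(trans$adm %in% val_adm)
  use_diag <- config$use_diagnoses
  eval_fun <- function(actor, critic) {
    S <- trans$S[val_rows, , drop = FALSE]
    D <- if (use_diag) trans$Didx[val_rows, , drop = FALSE]
    p <- forward_chunked(actor, S, D)
    q <- forward_chunked(critic, S, D, p)
    rec <- p >= config$action_threshold
    act <- trans$A[val_rows, , drop = FALSE]
    data.frame(expected_return = mean(q),
               jaccard = mean(day_jaccard(act, rec)))
  }
  fit <- ddpg_train(trans, config, embed_rows, eval_fun)
  structure(list(actor = fit$actor, critic = fit$critic,
                 target_actor = fit$target_actor,
                 target_critic = fit$target_critic,
                 trace = fit$trace, config = config,
                 metadata = pcohort$metadata,
                 feature_names = pcohort$feature_names,
                 drug_names = pcohort$drug_names,
                 kind = "srl"),
            class = "srl_model")
}

#' @export
print.srl_model <- function(x, ...) {
  cat(sprintf("<srl_model:%s> epsilon = %.2f, %d steps, K = %d drugs\n",
              x$kind, x$config$epsilon, x$config$steps,
              length(x$drug_names)))
  if (!is.null(x$trace) && nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    if (!is.null(last$jaccard)) {
      cat(sprintf("  final validation: expected return %.3f, Jaccard %.4f\n",
                  last$expected_return, last$jaccard))
    }
  }
  invisible(x)
}

#' Daily drug recommendations from a trained actor
#'
#' Computes the actor's per-drug probabilities for every admission-day of a
#' processed cohort and thresholds them at the training configuration's
#' `action_threshold` (overridable) into binary recommendations.
#'
#' @param model an `srl_model` (or any model sharing its structure).
#' @param pcohort a `processed_cohort` preprocessed with the same metadata.
#' @param threshold optional probability cut overriding the config.
#' @return list with `prob` and `action` (pooled day-row x K matrices) and
#'   the pooled `adm`/`day` indices.
#' @export
recommend <- function(model, pcohort, threshold = NULL) {
  stopifnot(inherits(pcohort, "processed_cohort"))
  threshold <- threshold %||% model$config$action_threshold
  S <- build_state_matrix(pcohort, model$config$window)
  D <- if (model$actor$use_diag) {
    pcohort$diag_idx[pcohort$pooled$adm, , drop = FALSE]
  }
  p <- forward_chunked(model$actor, S, D)
  list(prob = p,
       action = matrix(as.integer(p >= threshold), nrow(p), ncol(p)),
       adm = pcohort$pooled$adm, day = pcohort$pooled$day)
}

#' Train the outcome-weighted direct-policy-optimization model
#'
#' A single actor network (same architecture as [train_srl()]'s actor)
#' minimizing the outcome-weighted likelihood surrogate: each admission-day
#' carries the discounted terminal return `V_{i,t} = gamma^(T_i - t) *
#' r_{i,T_i}`, standardized over all admission-days (mean 0, sample SD 1),
#' and the loss is the negative weighted positive-label log-likelihood.
#' Days from good-outcome admissions pull the policy toward the clinician's
#' action; days from poor-outcome admissions push away from it.
#'
#' @param pcohort a `processed_cohort`.
#' @param config a [train_config()].
#' @return an `srl_model` with `kind = "dpo"` (no critic).
#' @export
train_dpo <- function(pcohort, config = train_config()) {
  stopifnot(inherits(pcohort, "processed_cohort"))
  trans <- build_transitions(pcohort, config$r_survive, config$r_die,
                             config$window)
  if (length(unique(trans$died)) < 2L) {
    stop("all outcomes identical: the outcome-weighted loss needs both ",
         "surviving and expired admissions", call. = FALSE)
  }
  rT <- ifelse(trans$died[trans$adm], -config$r_die, config$r_survive)
  V <- config$gamma^(trans$T_len[trans$adm] - trans$day) * rT
  SV <- stats::sd(V)
  if (!is.finite(SV) || SV == 0) {
    stop("all outcomes identical: the outcome-weighted loss needs both ",
         "surviving and expired admissions", call. = FALSE)
  }
  w <- (V - mean(V)) / SV
  embed_rows <- length(pcohort$metadata$vocab) + 1L
  set.seed(config$seed)
  use_diag <- config$use_diagnoses
  er <- if (use_diag) embed_rows else 0L
  actor <- new_net("actor", ncol(trans$S), ncol(trans$A),
                   config$hidden_actor, er, config$embed_dim)
  st <- adam_init(actor$params)
  trace <- list()
  for (step in seq_len(config$steps)) {
    idx <- sample.int(trans$n, min(config$batch_size, trans$n))
    S <- trans$S[idx, , drop = FALSE]
    D <- if (use_diag) trans$Didx[idx, , drop = FALSE]
    a <- trans$A[idx, , drop = FALSE]
    wi <- w[idx]
    fp <- net_forward(actor, S, D)
    p <- clamp_prob(fp$out)
    N <- length(idx)
    loss <- -sum(wi * rowSums(a * log(p))) / N
    dZ2 <- -(wi * a) * (1 - p) / N
    g <- net_backward(actor, fp$cache, dZ2)
    up <- adam_step(actor$params, g, st, config$lr_actor)
    actor$params <- up$params; st <- up$state
    if (step %% config$eval_every == 0L || step == config$steps) {
      trace[[length(trace) + 1L]] <- data.frame(step = step, dpo_loss = loss)
    }
  }
  structure(list(actor = actor, critic = NULL, trace = do.call(rbind, trace),
                 config = config, metadata = pcohort$metadata,
                 feature_names = pcohort$feature_names,
                 drug_names = pcohort$drug_names, kind = "dpo",
                 v_stats = list(mean = mean(V), sd = SV)),
            class = "srl_model")
}

#' Train the dual-branch supervised classifier
#'
#' Treats daily recommendation as multilabel classification: the diagnosis
#' sequence is encoded by one branch (embedding + dense layer), the
#' time-series window by another, and the concatenated encodings feed a
#' K-sigmoid classification layer trained with full per-drug binary
#' cross-entropy.
#'
#' @param pcohort a `processed_cohort`.
#' @param config a [train_config()].
#' @return an `srl_model` with `kind = "dual"`.
#' @export
train_dual_lstm <- function(pcohort, config = train_config()) {
  stopifnot(inherits(pcohort, "processed_cohort"))
  trans <- build_transitions(pcohort, config$r_survive, config$r_die,
                             config$window)
  embed_rows <- length(pcohort$metadata$vocab) + 1L
  set.seed(config$seed)
  actor <- new_net("dual", ncol(trans$S), ncol(trans$A),
                   config$hidden_actor, embed_rows, config$embed_dim)
  st <- adam_init(actor$params)
  trace <- list()
  for (step in seq_len(config$steps)) {
    idx <- sample.int(trans$n, min(config$batch_size, trans$n))
    S <- trans$S[idx, , drop = FALSE]
    D <- trans$Didx[idx, , drop = FALSE]
    a <- trans$A[idx, , drop = FALSE]
    fp <- net_forward(actor, S, D)
    p <- clamp_prob(fp$out)
    N <- length(idx)
    loss <- -sum(a * log(p) + (1 - a) * log(1 - p)) / N
    dZ2 <- (p - a) / N
    g <- net_backward(actor, fp$cache, dZ2)
    up <- adam_step(actor$params, g, st, config$lr_actor)
    actor$params <- up$params; st <- up$state
    if (step %% config$eval_every == 0L || step == config$steps) {
      trace[[length(trace) + 1L]] <- data.frame(step = step, bce_loss = loss)
    }
  }
  structure(list(actor = actor, critic = NULL, trace = do.call(rbind, trace),
                 config = config, metadata = pcohort$metadata,
                 feature_names = pcohort$feature_names,
                 drug_names = pcohort$drug_names, kind = "dual"),
            class = "srl_model")
}

#' Wrap a trained actor as a simulator policy
#'
#' Produces a policy object usable with [true_policy_value()]: at each
#' simulated day the raw observations are transformed with the model's
#' frozen preprocessing metadata (composites, log/z statistics, static
#' standardization, diagnosis encoding), pushed through a rolling W-day
#' window buffer, and the actor's thresholded probabilities become the
#' day's actions. Drugs outside the model's retained drug list are never
#' prescribed.
#'
#' @param model an `srl_model`.
#' @param threshold optional probability cut overriding the config.
#' @return a policy object.
#' @export
actor_policy <- function(model, threshold = NULL) {
  threshold <- threshold %||% model$config$action_threshold
  md <- model$metadata
  W <- model$config$window
  use_diag <- model$actor$use_diag

  structure(list(
    uses_diagnoses = use_diag,
    setup = function(n, statics, diagnoses, env) {
      s_std <- sweep(sweep(statics, 2, md$static_means, `-`),
                     2, md$static_sds, `/`)
      Didx <- NULL
      if (use_diag) {
        Didx <- encode_diagnoses(diagnoses, vocab = md$vocab,
                                 pad_length = md$diagnosis_pad_length)$indices
      }
      B <- length(md$feature_names_out) + env$config$n_rhythm_categories + 1L
      list(s_std = s_std, Didx = Didx, B = B, K_env = env$config$K,
           buf = matrix(0, n, W * B), started = logical(n))
    },
    act = function(state, day, active, feats, rhythm, statics) {
      B <- state$B
      feat <- compute_composites(feats, md$composites)
      feat <- feat[, md$feature_names_out, drop = FALSE]
      feat <- transform_and_normalize(feat, stats = md$norm_stats)$features
      rh <- matrix(0, length(active), B - ncol(feat) - 1L)
      rh[cbind(seq_along(active), rhythm)] <- 1
      block <- cbind(feat, rh, 1)
      first <- !state$started[active]
      if (any(first)) {
        rows <- active[first]
        pad <- cbind(feat[first, , drop = FALSE],
                     rh[first, , drop = FALSE], 0)
        # replicate-first-day padding (mask 0), then today's block (mask 1)
        state$buf[rows, ] <- do.call(cbind, rep(list(pad), W))
        state$buf[rows, (W - 1L) * B + seq_len(B)] <-
          block[first, , drop = FALSE]
        state$started[rows] <- TRUE
      }
      if (any(!first)) {
        rows <- active[!first]
        state$buf[rows, seq_len((W - 1L) * B)] <-
          state$buf[rows, B + seq_len((W - 1L) * B), drop = FALSE]
        state$buf[rows, (W - 1L) * B + seq_len(B)] <-
          block[!first, , drop = FALSE]
      }
      S <- cbind(state$buf[active, , drop = FALSE],
                 state$s_std[active, , drop = FALSE])
      D <- if (use_diag) state$Didx[active, , drop = FALSE]
      p <- forward_chunked(model$actor, S, D)
      acts_model <- matrix(as.integer(p >= threshold), nrow(p), ncol(p))
      acts <- matrix(0L, length(active), state$K_env)
      acts[, md$drug_idx] <- acts_model
      list(actions = acts, state = state)
    }
  ), class = "sim_policy")
}
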