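#' Simulate a synthetic ICU cohort
#'
#' Generates `n_admissions` variable-length patient-admission trajectories
#' from the generative model described in [sim_config()]. Each trajectory
#' carries static demographics, a diagnosis code sequence, daily continuous
#' features with missing markers, a one-hot heart-rhythm subtype per day, a
#' binary daily drug-action matrix produced by the hidden stochastic
#' clinician policy, a terminal survival/death flag, and a terminal-only
#' reward vector (+15 on survival, -15 on death; re-assignable at training
#' time via [train_config()]).
#'
#' The generative contract: latent severity follows a bounded first-order
#' autoregressive process whose drift is perturbed by treatment adequacy
#' (the benefit-weighted fraction of beneficial drugs given); observed
#' features are noisy monotone functions of severity; each drug is drawn
#' independently with probability `plogis(score / temperature)`; death occurs
#' at trajectory end with probability logistic in mean severity and mean
#' treatment adequacy.
#'
#' @param config a [sim_config()] object.
#' @return a `cohort` object: a list with elements `trajectories` (list of
#'   `trajectory` lists), `feature_names`, `drug_names`, `static_names`,
#'   `n_rhythm_categories`, and `config`.
#' @examples
#' co <- simulate_cohort(sim_config(n_admissions = 20, seed = 7))
#' length(co$trajectories)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  env <- derive_env(config)
  set.seed(config$seed + 1e6L)
  run <- sim_run(env, n = config$n_admissions, policy = NULL,
                 keep_data = TRUE, want_diagnoses = TRUE)
  assemble_cohort(env, run)
}

# Vectorized day-synchronous simulation engine. All active episodes advance
# together; `policy` NULL means the environment's own behaviour policy.
# Returns flat per-day matrices plus per-episode outcome information.
# Assumes the RNG has already been seeded by the caller.
sim_run <- function(env, n, policy = NULL, keep_data = FALSE,
                    want_diagnoses = FALSE) {
  cfg <- env$config
  K <- cfg$K
  Fn <- cfg$n_features
  R <- cfg$n_rhythm_categories

  statics <- cbind(
    age = pmin(pmax(stats::rnorm(n, 70, 12), 18), 95),
    male = as.numeric(stats::runif(n) < 0.656),
    weight = pmin(pmax(stats::rnorm(n, 84, 21), 35), 180)
  )
  stat_std <- cbind((statics[, 1] - 70) / 12, statics[, 2],
                    (statics[, 3] - 84) / 21)

  T_len <- as.integer(
    pmin(1L + stats::rnbinom(n, size = env$stay_size, mu = env$stay_mu),
         cfg$max_days))
  # initial severity at the AR(1) stationary spread (sd ~ sigma/sqrt(1-rho^2))
  z <- pmin(pmax(stats::rnorm(n, 0, 0.8), -3), 3)

  diagnoses <- NULL
  if (want_diagnoses || (!is.null(policy) && isTRUE(policy$uses_diagnoses))) {
    n_codes <- 1L + stats::rbinom(n, cfg$max_diagnoses_per_patient - 1L,
                                  stats::plogis(0.4 * z))
    diagnoses <- lapply(seq_len(n), function(i) {
      sort(sample.int(cfg$diagnosis_vocab_size, n_codes[i],
                      prob = env$vocab_prob))
    })
  }

  total <- sum(T_len)
  starts <- cumsum(c(1L, T_len[-n]))
  if (keep_data) {
    feat_all <- matrix(NA_real_, total, Fn)
    rhythm_all <- integer(total)
    act_all <- matrix(0L, total, K)
    adm_all <- integer(total)
    day_all <- integer(total)
  }

  sum_z <- numeric(n)
  sum_adeq <- numeric(n)
  benefit_total <- sum(env$benefit)

  pstate <- if (!is.null(policy)) policy$setup(n, statics, diagnoses, env) else NULL

  for (d in seq_len(max(T_len))) {
    active <- which(T_len >= d)
    na <- length(active)
    za <- z[active]
    feats <- gen_features(env, za)
    rhythm <- gen_rhythm(env, za)
    if (is.null(policy)) {
      p <- behavior_probs(env, feats, stat_std[active, , drop = FALSE])
      acts <- matrix(as.integer(stats::runif(na * K) < p), na, K)
    } else {
      res <- policy$act(pstate, d, active, feats, rhythm,
                        statics[active, , drop = FALSE])
      acts <- res$actions
      pstate <- res$state
      storage.mode(acts) <- "integer"
    }
    adeq <- as.numeric(acts %*% env$benefit) / benefit_total
    sum_z[active] <- sum_z[active] + za
    sum_adeq[active] <- sum_adeq[active] + adeq
    if (keep_data) {
      idx <- starts[active] + d - 1L
      feat_all[idx, ] <- feats
      rhythm_all[idx] <- rhythm
      act_all[idx, ] <- acts
      adm_all[idx] <- active
      day_all[idx] <- d
    }
    cont <- T_len[active] > d
    if (any(cont)) {
      ac <- active[cont]
      z[ac] <- pmin(pmax(
        env$rho * za[cont] +
          cfg$treatment_effect_size * env$drift_scale * (0.5 - adeq[cont]) +
          stats::rnorm(sum(cont), 0, env$sigma_z), -3), 3)
    }
  }

  mean_z <- sum_z / T_len
  mean_adeq <- sum_adeq / T_len
  p_death <- stats::plogis(
    env$mortality_intercept +
      env$severity_mortality_weight * mean_z -
      env$adequacy_mortality_weight * cfg$treatment_effect_size *
        (mean_adeq - 0.5))
  died <- stats::runif(n) < p_death

  out <- list(statics = statics, T_len = T_len, died = died,
              p_death = p_death, mean_z = mean_z, mean_adeq = mean_adeq,
              diagnoses = diagnoses)
  if (keep_data) {
    # missingness mask on continuous features only
    if (cfg$missingness_rate > 0) {
      if (cfg$mnar_missingness) {
        # severity-dependent missingness, one logit unit per severity unit
        # (admission-mean severity as the day-level proxy)
        pmiss <- stats::plogis(stats::qlogis(cfg$missingness_rate) +
                                 rep(mean_z, T_len))
        mask <- matrix(stats::runif(total * Fn) < pmiss, total, Fn)
      } else {
        mask <- matrix(stats::runif(total * Fn) < cfg$missingness_rate,
                       total, Fn)
      }
      feat_all[mask] <- NA_real_
    }
    out$feat <- feat_all
    out$rhythm <- rhythm_all
    out$actions <- act_all
    out$adm <- adm_all
    out$day <- day_all
    out$starts <- starts
  }
  out
}

gen_features <- function(env, z) {
  ft <- env$features
  n <- length(z)
  nf <- nrow(ft)
  lam <- ft$lambda
  noise <- matrix(stats::rnorm(n * nf), n, nf)
  core <- outer(z, lam) + sweep(noise, 2, sqrt(1 - lam^2), `*`)
  vals <- matrix(0, n, nf)
  for (j in seq_len(nf)) {
    if (ft$skewed[j]) {
      vals[, j] <- ft$mean[j] * exp(ft$cv[j] * core[, j])
    } else {
      vals[, j] <- ft$mean[j] + ft$sd[j] * core[, j]
    }
    vals[, j] <- pmin(pmax(vals[, j], ft$lo[j]), ft$hi[j])
    if (ft$integer[j]) vals[, j] <- round(vals[, j])
  }
  colnames(vals) <- ft$name
  vals
}

gen_rhythm <- function(env, z) {
  logits <- outer(rep(1, length(z)), env$rhythm_base) +
    outer(z, env$rhythm_load)
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  R <- ncol(p)
  cum <- p %*% upper.tri(diag(R), diag = TRUE)
  u <- stats::runif(length(z))
  as.integer(rowSums(u > cum) + 1L)
}

# observed bedside severity score: the direction-corrected standardized mean
# of the day's charted values. The clinician policy conditions on this (and
# on demographics), never on the latent severity itself, so treatment is
# conditionally randomized given the observable state.
obs_severity_score <- function(env, feats) {
  ft <- env$features
  s <- matrix(0, nrow(feats), nrow(ft))
  for (j in seq_len(nrow(ft))) {
    s[, j] <- if (ft$skewed[j]) {
      log(pmax(feats[, j], 1e-8) / ft$mean[j]) / ft$cv[j]
    } else {
      (feats[, j] - ft$mean[j]) / ft$sd[j]
    }
    s[, j] <- s[, j] * sign(ft$lambda[j])
  }
  rowMeans(s)
}

behavior_probs <- function(env, feats, stat_std) {
  sev <- obs_severity_score(env, feats)
  lin <- outer(rep(1, length(sev)), env$behavior_w0) +
    outer(sev, env$behavior_wz) +
    stat_std %*% t(env$behavior_ws)
  stats::plogis(lin / env$config$behavior_temperature)
}

assemble_cohort <- function(env, run) {
  cfg <- env$config
  R <- cfg$n_rhythm_categories
  trajectories <- vector("list", cfg$n_admissions)
  for (i in seq_len(cfg$n_admissions)) {
    Ti <- run$T_len[i]
    idx <- run$starts[i] + seq_len(Ti) - 1L
    rh <- matrix(0L, Ti, R)
    rh[cbind(seq_len(Ti), run$rhythm[idx])] <- 1L
    rewards <- numeric(Ti)
    rewards[Ti] <- if (run$died[i]) -15 else 15
    trajectories[[i]] <- structure(list(
      admission_id = i,
      T = Ti,
      diagnoses = run$diagnoses[[i]],
      static_features = stats::setNames(as.numeric(run$statics[i, ]),
                                        colnames(run$statics)),
      daily_features = run$feat[idx, , drop = FALSE],
      daily_rhythm = rh,
      actions = run$actions[idx, , drop = FALSE],
      died_in_hospital = run$died[i],
      rewards = rewards
    ), class = "trajectory")
  }
  structure(list(
    trajectories = trajectories,
    feature_names = env$features$name,
    drug_names = sprintf("drug_%02d", seq_len(cfg$K)),
    static_names = colnames(run$statics),
    n_rhythm_categories = R,
    config = cfg
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$trajectories)
  Ts <- vapply(x$trajectories, `[[`, integer(1), "T")
  died <- vapply(x$trajectories, `[[`, logical(1), "died_in_hospital")
  cat(sprintf("<cohort> %d admissions, %d days, K = %d drugs, %d features\n",
              n, sum(Ts), length(x$drug_names), length(x$feature_names)))
  cat(sprintf("  stay: median %d d (range %d-%d); in-hospital mortality %.3f\n",
              as.integer(stats::median(Ts)), min(Ts), max(Ts), mean(died)))
  invisible(x)
}

#' Ground-truth value of a policy in the synthetic environment
#'
#' Monte-Carlo estimate of in-hospital mortality when daily actions are
#' chosen by `policy` instead of the environment's behaviour policy. This is
#' the simulator-truth counterpart of the off-policy estimated mortality of
#' [evaluate_policy()]; it is only available because the environment's
#' transition and outcome models are known.
#'
#' Rollout states are fully observed (no missingness): the ground-truth
#' evaluator scores a policy's decisions, not its robustness to missing data.
#'
#' @param config a [sim_config()]; hidden environment parameters are
#'   re-derived from `config$seed`, so the evaluated environment is exactly
#'   the one that generated a cohort with the same config.
#' @param policy `NULL` for the behaviour policy, or a policy object from
#'   [constant_policy()], [oracle_policy()], or [actor_policy()].
#' @param n_rollouts number of simulated admissions.
#' @param seed rollout seed (independent of `config$seed`).
#' @return a list with `mortality`, binomial `se`, and `n`.
#' @export
true_policy_value <- function(config, policy = NULL, n_rollouts = 2000L,
                              seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_rollouts) || n_rollouts < 1) {
    stop("n_rollouts must be >= 1", call. = FALSE)
  }
  n_rollouts <- as.integer(n_rollouts)
  env <- derive_env(config)
  set.seed(seed)
  run <- sim_run(env, n = n_rollouts, policy = policy, keep_data = FALSE)
  m <- mean(run$died)
  list(mortality = m,
       se = sqrt(m * (1 - m) / n_rollouts),
       n = n_rollouts)
}

#' Fixed-action policy
#'
#' A policy that prescribes the same drug combination every day.
#'
#' @param action binary vector of length K.
#' @return a policy object usable with [true_policy_value()].
#' @export
constant_policy <- function(action) {
  action <- as.integer(action)
  if (!all(action %in% c(0L, 1L))) stop("action must be binary", call. = FALSE)
  structure(list(
    uses_diagnoses = FALSE,
    setup = function(n, statics, diagnoses, env) NULL,
    act = function(state, day, active, feats, rhythm, statics) {
      list(actions = matrix(action, length(active), length(action),
                            byrow = TRUE), state = state)
    }
  ), class = "sim_policy")
}

#' Oracle policies of the synthetic environment
#'
#' Policies defined directly from the environment's hidden benefit vector,
#' used as anchors when validating the off-policy evaluator: `"all_beneficial"`
#' always gives every drug with positive benefit and nothing else;
#' `"none"` gives no drugs; `"harmful"` gives exactly the non-beneficial
#' drugs.
#'
#' @param config the [sim_config()] whose environment defines the benefit
#'   vector.
#' @param mode one of `"all_beneficial"`, `"none"`, `"harmful"`.
#' @return a policy object.
#' @export
oracle_policy <- function(config, mode = c("all_beneficial", "none", "harmful")) {
  mode <- match.arg(mode)
  env <- derive_env(config)
  act <- switch(mode,
    all_beneficial = as.integer(env$benefit > 0),
    none = rep(0L, config$K),
    harmful = as.integer(env$benefit == 0))
  constant_policy(act)
}
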