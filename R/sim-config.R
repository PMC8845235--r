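#' Configuration of the synthetic ICU environment
#'
#' Defines a generative model of ICU patient-admission trajectories: a latent
#' daily severity process observed through noisy clinical features, a
#' stochastic "clinician" behaviour policy prescribing a K-dimensional binary
#' drug combination each day, and a terminal in-hospital-mortality outcome
#' whose probability depends on average severity and on how adequately the
#' beneficial drugs were given. The same environment is used both to generate
#' cohorts ([simulate_cohort()]) and to evaluate arbitrary policies against
#' the ground truth ([true_policy_value()]).
#'
#' @param n_admissions number of patient-admission trajectories to generate.
#' @param K number of drugs in the daily binary action vector. The format
#'   supports hundreds of drugs; the default is kept small so that simulated
#'   studies run quickly.
#' @param n_features number of continuous daily clinical features. The first
#'   15 are named clinical variables (heart rate, blood pressures, GCS
#'   components, labs, urine output, ...) with realistic locations and
#'   spreads; any further features are generic standardized variables.
#' @param n_rhythm_categories number of mutually exclusive heart-rhythm
#'   subtypes, one-hot coded per observed day.
#' @param max_days maximum hospitalization length in days.
#' @param diagnosis_vocab_size size of the diagnosis-code vocabulary; codes
#'   are drawn with frequencies decaying in rank (Zipf-like).
#' @param max_diagnoses_per_patient upper bound on codes per admission;
#'   diagnosis sequences are later zero-padded to this length.
#' @param missingness_rate per feature-day probability that a measured value
#'   is missing (completely at random).
#' @param behavior_temperature softness of the clinician policy; each drug k
#'   is drawn independently with probability
#'   `plogis(linear_score_k / behavior_temperature)`.
#' @param treatment_effect_size scale of the per-day effect of treatment
#'   adequacy on the severity drift and of average adequacy on the terminal
#'   mortality logit. Zero disconnects treatment from outcome entirely.
#' @param base_mortality baseline terminal death probability for an average
#'   severity trajectory under neutral (50% adequate) treatment.
#' @param mnar_missingness if `TRUE`, missingness probability increases with
#'   latent severity (logit shift of +1 per severity unit) instead of being
#'   completely at random. Off by default.
#' @param seed integer seed; fixes both the hidden environment parameters
#'   (drug weights, benefit vector, feature loadings) and the generated
#'   trajectories.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [true_policy_value()]
#' @export
sim_config <- function(n_admissions = 500L,
                       K = 20L,
                       n_features = 15L,
                       n_rhythm_categories = 25L,
                       max_days = 40L,
                       diagnosis_vocab_size = 200L,
                       max_diagnoses_per_patient = 10L,
                       missingness_rate = 0.2,
                       behavior_temperature = 1,
                       treatment_effect_size = 0.5,
                       base_mortality = 0.1,
                       mnar_missingness = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_admissions = as.integer(n_admissions),
    K = as.integer(K),
    n_features = as.integer(n_features),
    n_rhythm_categories = as.integer(n_rhythm_categories),
    max_days = as.integer(max_days),
    diagnosis_vocab_size = as.integer(diagnosis_vocab_size),
    max_diagnoses_per_patient = as.integer(max_diagnoses_per_patient),
    missingness_rate = missingness_rate,
    behavior_temperature = behavior_temperature,
    treatment_effect_size = treatment_effect_size,
    base_mortality = base_mortality,
    mnar_missingness = isTRUE(mnar_missingness),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c("missingness_rate", "behavior_temperature",
                  "treatment_effect_size", "base_mortality")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]])) {
      stop("sim_config field '", f, "' must be a finite numeric scalar", call. = FALSE)
    }
  }
  counts <- c("n_admissions", "K", "n_features", "n_rhythm_categories",
              "max_days", "diagnosis_vocab_size", "max_diagnoses_per_patient")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("sim_config field '", f, "' must be a count >= 1", call. = FALSE)
    }
  }
  if (cfg$missingness_rate < 0 || cfg$missingness_rate >= 1) {
    stop("missingness_rate must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$base_mortality <= 0 || cfg$base_mortality >= 1) {
    stop("base_mortality must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$behavior_temperature <= 0) {
    stop("behavior_temperature must be positive", call. = FALSE)
  }
  if (cfg$treatment_effect_size < 0) {
    stop("treatment_effect_size must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  admissions: %d, drugs (K): %d, features: %d, rhythm subtypes: %d\n",
              x$n_admissions, x$K, x$n_features, x$n_rhythm_categories))
  cat(sprintf("  max stay: %d d, diagnosis vocab: %d (<= %d codes/patient)\n",
              x$max_days, x$diagnosis_vocab_size, x$max_diagnoses_per_patient))
  cat(sprintf("  missingness: %.2f%s, temperature: %.2f, effect size: %.2f, base mortality: %.2f\n",
              x$missingness_rate, if (x$mnar_missingness) " (MNAR)" else "",
              x$behavior_temperature, x$treatment_effect_size, x$base_mortality))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Reference table of clinically named daily features. Locations/spreads chosen
# to resemble an adult cardiac ICU population; `lambda` is the loading of the
# latent severity on the feature (sign = direction of derangement when
# sicker), `skewed` marks features generated on a multiplicative scale (the
# default log-transform list of the preprocessing step).
clinical_feature_table <- function() {
  data.frame(
    name = c("heart_rate", "sbp", "dbp", "resp_rate", "temp", "spo2",
             "gcs_eye", "gcs_verbal", "gcs_motor", "glucose", "creatinine",
             "lactate", "wbc", "hemoglobin", "urine_output"),
    mean = c(84, 118, 58, 20, 36.8, 96.5, 3.4, 4.2, 5.5, 130, 1.4, 1.9,
             10.5, 10.4, 1500),
    sd = c(14, 17, 10, 4, 0.6, 2.5, 0.8, 1.1, 0.9, 40, 0.9, 1.2, 5, 1.7, 900),
    lambda = c(0.55, -0.6, -0.5, 0.5, 0.25, -0.55, -0.7, -0.7, -0.7, 0.4,
               0.5, 0.65, 0.45, -0.35, -0.5),
    skewed = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
               TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    lo = c(30, 60, 30, 6, 33, 70, 1, 1, 1, 40, 0.2, 0.3, 1, 4, 0),
    hi = c(200, 220, 130, 50, 41, 100, 4, 5, 6, 600, 15, 20, 60, 18, 6000),
    integer = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Hidden environment parameters derived deterministically from the config
# seed. Everything the generator and the ground-truth evaluator share lives
# here: the feature observation model, the heart-rhythm model, the drug
# benefit vector and the behaviour-policy weights.
derive_env <- function(cfg) {
  set.seed(cfg$seed)
  ft <- clinical_feature_table()
  nf <- cfg$n_features
  if (nf <= nrow(ft)) {
    ft <- ft[seq_len(nf), , drop = FALSE]
  } else {
    extra <- nf - nrow(ft)
    ft <- rbind(ft, data.frame(
      name = sprintf("feat%02d", nrow(ft) + seq_len(extra)),
      mean = 0, sd = 1,
      lambda = stats::runif(extra, 0.3, 0.7) * sample(c(-1, 1), extra, TRUE),
      skewed = FALSE, lo = -6, hi = 6, integer = FALSE
    ))
  }
  # multiplicative-scale spread for skewed features
  ft$cv <- pmin(pmax(0.9 * ft$sd / pmax(ft$mean, 1e-8), 0.2), 0.8)

  R <- cfg$n_rhythm_categories
  rhythm_base <- c(2, stats::rnorm(R - 1, -2.2, 0.7))
  rhythm_load <- c(-0.6, stats::runif(R - 1, 0.1, 0.5))

  K <- cfg$K
  # a quarter of the formulary is outcome-relevant; concentrating the benefit
  # keeps each drug's marginal effect large enough to be learnable from
  # cohorts of a few thousand admissions
  n_beneficial <- max(1L, ceiling(K / 4))
  benefit <- c(stats::runif(n_beneficial, 0.5, 1.5), rep(0, K - n_beneficial))
  # beneficial drugs are given about every other day; the rest of the
  # formulary is touched rarely, keeping daily prescriptions sparse the way
  # real formularies are used
  w0 <- ifelse(benefit > 0, 0, -2)
  wz <- ifelse(benefit > 0, stats::runif(K, 0.3, 1.0), stats::runif(K, -0.3, 0.3))
  ws <- matrix(stats::runif(K * 3, -0.2, 0.2), nrow = K)  # age, male, weight (standardized)

  vocab_prob <- (1 / seq_len(cfg$diagnosis_vocab_size))
  vocab_prob <- vocab_prob / sum(vocab_prob)

  out <- list(
    config = cfg,
    features = ft,
    rhythm_base = rhythm_base,
    rhythm_load = rhythm_load,
    benefit = benefit,
    behavior_w0 = w0,
    behavior_wz = wz,
    behavior_ws = ws,
    vocab_prob = vocab_prob,
    # severity / outcome dynamics constants
    rho = 0.9, sigma_z = 0.35, drift_scale = 1,
    severity_mortality_weight = 0.5,
    adequacy_mortality_weight = 6,
    stay_size = 3, stay_mu = 8
  )
  out$mortality_intercept <- calibrate_mortality_intercept(out)
  out
}

# Mortality intercept calibrated so that the *marginal* death probability
# under neutral treatment equals base_mortality exactly, despite the
# nonlinear (Jensen) inflation of E[plogis(a + alpha * Zbar)]. Zbar is the
# stay-length mean of the stationary AR(1) severity; its variance is
# computed exactly from the autocovariances and the stay-length law, and
# the intercept solves the logit-normal mean equation by quadrature.
calibrate_mortality_intercept <- function(env) {
  cfg <- env$config
  var_st <- env$sigma_z^2 / (1 - env$rho^2)
  Ts <- seq_len(cfg$max_days)
  wT <- stats::dnbinom(Ts - 1L, size = env$stay_size, mu = env$stay_mu)
  wT[length(wT)] <- wT[length(wT)] +
    stats::pnbinom(cfg$max_days - 1L, size = env$stay_size, mu = env$stay_mu,
                   lower.tail = FALSE)
  wT <- wT / sum(wT)
  var_mean <- vapply(Ts, function(Tt) {
    k <- seq_len(max(Tt - 1L, 0L))
    (var_st / Tt^2) * (Tt + 2 * sum((Tt - k) * env$rho^k))
  }, numeric(1))
  v <- sum(wT * var_mean)
  alpha <- env$severity_mortality_weight
  marginal <- function(a) {
    stats::integrate(function(x) {
      stats::plogis(a + alpha * x) * stats::dnorm(x, 0, sqrt(v))
    }, -Inf, Inf)$value - cfg$base_mortality
  }
  stats::uniroot(marginal, c(stats::qlogis(cfg$base_mortality) - 4,
                             stats::qlogis(cfg$base_mortality) + 1))$root
}
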