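#' Admission-level development/test split
#'
#' Randomly partitions admissions (never days) into a development and a test
#' cohort. With fractions (0.8, 0.2) the development set receives
#' `round(0.8 * n)` admissions.
#'
#' @param cohort a `cohort`.
#' @param fractions length-2 numeric summing to 1.
#' @param seed split seed.
#' @return list with `development` and `test` cohorts.
#' @export
split_cohort <- function(cohort, fractions = c(0.8, 0.2), seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), length(fractions) == 2,
            abs(sum(fractions) - 1) < 1e-8)
  n <- length(cohort$trajectories)
  set.seed(seed)
  dev_idx <- sort(sample.int(n, round(fractions[1] * n)))
  subset_cohort <- function(idx) {
    out <- cohort
    out$trajectories <- cohort$trajectories[idx]
    out
  }
  list(development = subset_cohort(dev_idx),
       test = subset_cohort(setdiff(seq_len(n), dev_idx)))
}

# k-fold admission partition
cv_folds <- function(n_adm, k, seed) {
  set.seed(seed)
  fold <- rep_len(seq_len(k), n_adm)
  sample(fold)
}

#' Cross-validated sweep of the supervised/reinforcement trade-off
#'
#' For each value of the trade-off weight epsilon, trains the blended model
#' on each cross-validation training fold of the development cohort
#' (preprocessing refit inside the fold, so no validation information leaks
#' into the transforms) and evaluates on the held-out fold: mean Jaccard to
#' the clinicians plus state-wise and trajectory-wise estimated mortality.
#'
#' @param development a raw (unprocessed) development `cohort`.
#' @param epsilon_grid epsilon values to sweep.
#' @param folds number of cross-validation folds.
#' @param config a [train_config()] supplying everything but epsilon.
#' @param prep_config a [preprocess_config()].
#' @param n_boot bootstrap resamples for the evaluation.
#' @return data frame with one row per (epsilon, fold) plus a summary
#'   attribute of per-epsilon means and SDs.
#' @export
run_epsilon_sweep <- function(development,
                              epsilon_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                              folds = 5L,
                              config = train_config(),
                              prep_config = preprocess_config(),
                              n_boot = 500L) {
  stopifnot(inherits(development, "cohort"))
  n <- length(development$trajectories)
  fold <- cv_folds(n, folds, config$seed)
  rows <- list()
  for (f in seq_len(folds)) {
    tr_idx <- which(fold != f)
    va_idx <- which(fold == f)
    tr <- development; tr$trajectories <- development$trajectories[tr_idx]
    va <- development; va$trajectories <- development$trajectories[va_idx]
    prep <- preprocess_cohort(tr, va, prep_config)
    for (eps in epsilon_grid) {
      cfg <- config
      cfg$epsilon <- eps
      model <- train_srl(prep$development, cfg)
      rep <- evaluate_policy(model, prep$test, n_boot = n_boot,
                             seed = cfg$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        epsilon = eps, fold = f,
        jaccard = rep$jaccard,
        est_mortality_statewise = rep$estimated_mortality_statewise,
        est_mortality_trajectorywise = rep$estimated_mortality_trajectorywise)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(
    out[, c("jaccard", "est_mortality_statewise",
            "est_mortality_trajectorywise")],
    by = list(epsilon = out$epsilon),
    function(v) c(mean = mean(v), sd = stats::sd(v)))
  attr(out, "summary") <- agg
  out
}

#' Head-to-head model comparison on a held-out test cohort
#'
#' Trains each requested model on the development cohort and evaluates it on
#' the test cohort, emitting one row per model (trajectory-wise and
#' state-wise estimated mortality, Jaccard, mean recommended drugs per day)
#' plus the clinician baseline row, whose estimated mortality is the
#' self-evaluation of the behaviour policy and whose Jaccard is empty.
#'
#' Models without a critic (the pure classifiers) are scored with the
#' blended model's critic, so every policy is ranked by the same
#' return-to-mortality mapping.
#'
#' @param development,test raw `cohort`s.
#' @param models character subset of `c("srl", "sl", "rl", "dpo", "dual",
#'   "srl_multimorbidity")`.
#' @param config a [train_config()] (its epsilon is used for `"srl"`).
#' @param prep_config a [preprocess_config()].
#' @param n_boot bootstrap resamples.
#' @return data frame, one row per model plus the clinician row.
#' @export
run_comparison <- function(development, test,
                           models = c("srl", "sl", "rl", "dpo", "dual"),
                           config = train_config(),
                           prep_config = preprocess_config(),
                           n_boot = 2000L) {
  prep <- preprocess_cohort(development, test, prep_config)
  dev_p <- prep$development
  test_p <- prep$test

  srl_cfg <- config
  srl <- train_srl(dev_p, srl_cfg)

  fit_one <- function(name) {
    switch(name,
      srl = srl,
      sl = { cfg <- config; cfg$epsilon <- 0; train_srl(dev_p, cfg) },
      rl = { cfg <- config; cfg$epsilon <- 1; train_srl(dev_p, cfg) },
      dpo = train_dpo(dev_p, config),
      dual = train_dual_lstm(dev_p, config),
      srl_multimorbidity = {
        sub <- multimorbidity_features(dev_p$feature_names)
        train_srl(restrict_features(dev_p, sub), config)
      },
      stop("unknown model: ", name, call. = FALSE))
  }

  rows <- list()
  clin_rep <- evaluate_policy(srl, test_p,
                              recommended = test_p$pooled$actions,
                              n_boot = n_boot, seed = config$seed)
  rows[["clinician"]] <- data.frame(
    model = "clinician",
    est_mortality_trajectorywise = clin_rep$estimated_mortality_trajectorywise,
    est_mortality_statewise = clin_rep$estimated_mortality_statewise,
    jaccard = NA_real_,
    mean_drugs_per_day = clin_rep$mean_drugs_actual)

  for (name in models) {
    model <- fit_one(name)
    test_eval <- test_p
    if (name == "srl_multimorbidity") {
      test_eval <- restrict_features(test_p,
                                     multimorbidity_features(test_p$feature_names))
    }
    rec <- recommend(model, test_eval)$action
    scorer <- if (is.null(model$critic)) srl else model
    rep <- evaluate_policy(scorer, test_p, recommended = rec,
                           n_boot = n_boot, seed = config$seed)
    rows[[name]] <- data.frame(
      model = name,
      est_mortality_trajectorywise = rep$estimated_mortality_trajectorywise,
      est_mortality_statewise = rep$estimated_mortality_statewise,
      jaccard = rep$jaccard,
      mean_drugs_per_day = rep$mean_drugs_recommended)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-day clinician-vs-model comparison for one admission
#'
#' Emits one row per hospitalization day listing the drugs prescribed by
#' the clinician only, recommended by the model only, and agreed on by
#' both, together with the day's Jaccard coefficient.
#'
#' @param model a trained model.
#' @param pcohort a `processed_cohort` containing the admission.
#' @param admission index of the admission within the cohort.
#' @return data frame with `day`, `both`, `clinician_only`, `ai_only`,
#'   `jaccard`.
#' @export
case_report <- function(model, pcohort, admission = 1L) {
  rec <- recommend(model, pcohort)
  sel <- rec$adm == admission
  if (!any(sel)) stop("no such admission: ", admission, call. = FALSE)
  a <- pcohort$pooled$actions[sel, , drop = FALSE]
  r <- rec$action[sel, , drop = FALSE]
  drugs <- pcohort$drug_names
  fmt <- function(v) paste(drugs[v], collapse = ", ")
  data.frame(
    day = pcohort$pooled$day[sel],
    both = apply(a & r, 1, function(v) fmt(which(v))),
    clinician_only = apply(a & !r, 1, function(v) fmt(which(v))),
    ai_only = apply(!a & r, 1, function(v) fmt(which(v))),
    jaccard = day_jaccard(a, r)
  )
}
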