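#' Random-forest feature importance of a prescription policy
#'
#' Fits one random forest per drug on the pooled admission-day rows
#' (features -> that drug's binary action) and averages the impurity-based
#' importances across drugs, normalizing the result to sum to 1. The targets
#' may be the clinicians' actual actions (the behaviour policy) or a model's
#' recommended actions (the learned policy); diagnosis inputs are excluded
#' by construction of the feature matrix.
#'
#' @param features numeric day-row x feature matrix with named columns
#'   (complete, e.g. from [policy_design_matrix()]).
#' @param targets day-row x K binary action matrix.
#' @param n_trees trees per forest.
#' @param seed forest seed.
#' @return named numeric importance vector summing to 1, with attributes
#'   `per_drug` (feature x drug matrix of raw importances) and
#'   `constant_drugs` (drugs skipped because their target never varies).
#' @export
policy_feature_importance <- function(features, targets, n_trees = 200L,
                                      seed = 1L) {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  stopifnot(nrow(features) == nrow(targets))
  K <- ncol(targets)
  nf <- ncol(features)
  per_drug <- matrix(0, nf, K,
                     dimnames = list(colnames(features), colnames(targets)))
  constant <- logical(K)
  df <- as.data.frame(features)
  for (k in seq_len(K)) {
    y <- targets[, k]
    if (length(unique(y)) < 2L) {
      constant[k] <- TRUE
      next
    }
    fit <- ranger::ranger(x = df, y = as.numeric(y),
                          num.trees = n_trees, importance = "impurity",
                          seed = seed + k, num.threads = 1L)
    per_drug[, k] <- fit$variable.importance[colnames(features)]
  }
  if (all(constant)) {
    warning("every drug target is constant; importances are all zero")
    imp <- stats::setNames(rep(0, nf), colnames(features))
  } else {
    imp <- rowMeans(per_drug[, !constant, drop = FALSE])
    imp <- imp / sum(imp)
  }
  structure(imp, per_drug = per_drug, constant_drugs = which(constant))
}

#' Day-level design matrix for policy interpretation
#'
#' Binds the processed daily features, the one-hot heart-rhythm subtype
#' columns (named `rhythm_01` ...) and the standardized static features of
#' the owning admission into one complete matrix, one row per admission-day.
#'
#' @param pcohort a `processed_cohort`.
#' @return numeric matrix with named columns.
#' @export
policy_design_matrix <- function(pcohort) {
  stopifnot(inherits(pcohort, "processed_cohort"))
  pooled <- pcohort$pooled
  rh <- pooled$rhythm
  colnames(rh) <- sprintf("rhythm_%02d", seq_len(ncol(rh)))
  st <- pcohort$statics_std[pooled$adm, , drop = FALSE]
  cbind(pooled$feat, rh, st)
}

#' Collapse heart-rhythm subtype importances into one row
#'
#' The one-hot rhythm subtypes describe a single categorical variable; its
#' importance is the sum of its subtype importances. Aggregation conserves
#' the total importance mass.
#'
#' @param importances named importance vector.
#' @param prefix common prefix of the subtype columns.
#' @param name name of the aggregated entry.
#' @return named importance vector with the subtypes replaced by one entry.
#' @export
aggregate_rhythm <- function(importances, prefix = "rhythm_",
                             name = "heart_rhythm") {
  sub <- startsWith(names(importances), prefix)
  out <- c(importances[!sub],
           stats::setNames(sum(importances[sub]), name))
  attributes(out) <- list(names = names(out))
  out
}

#' Compare the important features of two policies
#'
#' Ranks features by importance for the clinician (behaviour) policy and a
#' learned policy, and reports the top-n lists, the features both agree on,
#' and each policy's exclusives.
#'
#' @param clinician,ai named importance vectors on the same feature set.
#' @param top_n size of the head-to-head ranking.
#' @return list with `table` (feature, clinician_importance, ai_importance,
#'   ranks), `top_clinician`, `top_ai`, `shared`, `clinician_only`,
#'   `ai_only`.
#' @export
compare_policies <- function(clinician, ai, top_n = 10L) {
  feats <- union(names(clinician), names(ai))
  ci <- clinician[feats]; ci[is.na(ci)] <- 0
  ai_ <- ai[feats]; ai_[is.na(ai_)] <- 0
  tab <- data.frame(feature = feats,
                    clinician_importance = as.numeric(ci),
                    ai_importance = as.numeric(ai_))
  tab$clinician_rank <- rank(-tab$clinician_importance, ties.method = "first")
  tab$ai_rank <- rank(-tab$ai_importance, ties.method = "first")
  tab <- tab[order(tab$clinician_rank), ]
  rownames(tab) <- NULL
  top_n <- min(top_n, length(feats))
  top_c <- tab$feature[order(tab$clinician_rank)][seq_len(top_n)]
  top_a <- tab$feature[order(tab$ai_rank)][seq_len(top_n)]
  list(table = tab,
       top_clinician = top_c,
       top_ai = top_a,
       shared = intersect(top_c, top_a),
       clinician_only = setdiff(top_c, top_a),
       ai_only = setdiff(top_a, top_c))
}

#' Clinician-vs-model importance table for a cohort
#'
#' Convenience wrapper: computes the design matrix, fits the per-drug
#' forests against the clinicians' actual actions and against the model's
#' recommendations, aggregates the rhythm subtypes, and returns the
#' comparison.
#'
#' @param pcohort a `processed_cohort`.
#' @param model a trained model for the learned-policy side.
#' @param n_trees,seed,top_n passed through.
#' @return the [compare_policies()] list, plus `clinician` and `ai`
#'   importance vectors.
#' @export
policy_importance_table <- function(pcohort, model, n_trees = 200L,
                                    seed = 1L, top_n = 10L) {
  X <- policy_design_matrix(pcohort)
  clin <- policy_feature_importance(X, pcohort$pooled$actions,
                                    n_trees = n_trees, seed = seed)
  rec <- recommend(model, pcohort)$action
  ai <- policy_feature_importance(X, rec, n_trees = n_trees, seed = seed)
  clin_a <- aggregate_rhythm(clin)
  ai_a <- aggregate_rhythm(ai)
  out <- compare_policies(clin_a, ai_a, top_n)
  out$clinician <- clin_a
  out$ai <- ai_a
  out
}
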