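`%||%` <- function(a, b) if (is.null(a)) b else a

# composites whose component columns are actually present
feasible_composites <- function(requested, feature_names) {
  needs <- list(
    shock_index = c(if ("pulse" %in% feature_names) "pulse" else "heart_rate",
                    "sbp"),
    gcs = c("gcs_eye", "gcs_verbal", "gcs_motor"))
  requested[vapply(requested, function(cn) {
    is.null(needs[[cn]]) || all(needs[[cn]] %in% feature_names)
  }, logical(1))]
}

#' Declarative measurement-unit conversions
#'
#' A named list mapping source column names to a target name and conversion
#' function; [apply_unit_conversions()] rewrites matching columns in place.
#' The default map converts pound weights to kilograms and Fahrenheit
#' temperatures to Celsius; entries are trivially extensible.
#'
#' @return named list of `list(to =, fun =)` entries.
#' @export
unit_conversion_map <- function() {
  list(
    weight_lb = list(to = "weight", fun = function(x) x * 0.45359237),
    temp_f = list(to = "temp", fun = function(x) (x - 32) * 5 / 9)
  )
}

#' @rdname unit_conversion_map
#' @param feat matrix or data frame with named columns.
#' @param map a conversion map as returned by [unit_conversion_map()].
#' @export
apply_unit_conversions <- function(feat, map = unit_conversion_map()) {
  for (from in intersect(names(map), colnames(feat))) {
    entry <- map[[from]]
    colnames(feat)[colnames(feat) == from] <- entry$to
    feat[, entry$to] <- entry$fun(feat[, entry$to])
  }
  feat
}

#' Fit preprocessing statistics on a development cohort
#'
#' Estimates every data-dependent preprocessing quantity on the given cohort
#' and freezes it into a metadata object: the retained drug list, composite
#' definitions, outlier cap bounds, log shifts, feature means/SDs, the
#' k-nearest-neighbour reference pool, static-feature statistics, and the
#' diagnosis vocabulary. [preprocess_apply()] then applies these statistics
#' unchanged to any cohort in the same schema, so no test-split information
#' ever leaks into the transforms.
#'
#' The per-day pipeline order is fixed: composite derivation, quantile
#' capping, log transform + z-normalization, KNN imputation.
#'
#' @param cohort a `cohort`.
#' @param config a [preprocess_config()].
#' @return a `preprocess_metadata` list.
#' @export
preprocess_fit <- function(cohort, config = preprocess_config()) {
  stopifnot(inherits(cohort, "cohort"))
  pooled <- pool_days(cohort)
  colnames(pooled$feat) <- cohort$feature_names

  drug_idx <- seq_along(cohort$drug_names)
  if (!is.null(config$top_k_drugs) &&
      config$top_k_drugs < length(drug_idx)) {
    sel <- select_top_drugs(pooled$actions, config$top_k_drugs)
    drug_idx <- sort(sel$drugs)
  }

  composites <- feasible_composites(config$composites, cohort$feature_names)
  feat <- compute_composites(pooled$feat, composites)
  cap <- cap_outliers(feat, config$cap_quantiles, config$cap_overrides)
  logf <- config$log_transform_features %||%
    default_log_features(colnames(feat))
  tn <- transform_and_normalize(cap$features, logf)

  n <- nrow(tn$features)
  pool <- if (n <= config$knn_pool_max) tn$features else {
    tn$features[unique(round(seq(1, n, length.out = config$knn_pool_max))), ,
                drop = FALSE]
  }

  statics <- do.call(rbind, lapply(cohort$trajectories, `[[`,
                                   "static_features"))
  smu <- colMeans(statics)
  ssd <- apply(statics, 2, stats::sd)
  ssd[is.na(ssd) | ssd == 0] <- 1

  codes <- lapply(cohort$trajectories, `[[`, "diagnoses")
  longest <- max(c(1L, lengths(codes)))
  pad <- config$diagnosis_pad_length %||%
    max(longest, cohort$config$max_diagnoses_per_patient %||% longest)
  enc <- encode_diagnoses(codes, pad_length = pad)

  ids <- vapply(cohort$trajectories, `[[`, numeric(1), "admission_id")
  structure(list(
    feature_names_in = cohort$feature_names,
    feature_names_out = colnames(tn$features),
    composites = composites,
    caps = cap$caps,
    cap_removed = cap$removed,
    norm_stats = tn$stats,
    knn_k = config$knn_k,
    knn_pool = pool,
    static_means = smu,
    static_sds = ssd,
    vocab = enc$vocab,
    diagnosis_pad_length = pad,
    drug_idx = drug_idx,
    drug_names = cohort$drug_names[drug_idx],
    provenance = list(n_admissions = length(ids), id_sum = sum(ids))
  ), class = "preprocess_metadata")
}

#' Apply fitted preprocessing to a cohort
#'
#' Deterministically transforms a cohort with the statistics frozen by
#' [preprocess_fit()]: derives composites, caps to the stored bounds,
#' log-transforms and z-scores with the stored shifts/means/SDs, imputes
#' missing values by KNN against the stored development reference pool,
#' standardizes statics, encodes diagnoses against the stored vocabulary and
#' restricts actions to the retained drug list.
#'
#' @param cohort a `cohort` in the same schema as the fitting cohort.
#' @param metadata a `preprocess_metadata` object.
#' @return a `processed_cohort`: the cohort with complete, normalized daily
#'   features, plus pooled day-row matrices (`$pooled`), padded diagnosis
#'   index matrix (`$diag_idx`), standardized statics (`$statics_std`) and
#'   the metadata itself.
#' @export
preprocess_apply <- function(cohort, metadata) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(metadata, "preprocess_metadata"))
  pooled <- pool_days(cohort)
  colnames(pooled$feat) <- cohort$feature_names

  feat <- compute_composites(pooled$feat, metadata$composites)
  feat <- cap_outliers(feat, caps = metadata$caps)$features
  feat <- transform_and_normalize(feat, stats = metadata$norm_stats)$features
  feat <- knn_impute(feat, k = metadata$knn_k, pool = metadata$knn_pool)
  pooled$feat <- feat
  pooled$actions <- pooled$actions[, metadata$drug_idx, drop = FALSE]

  statics <- do.call(rbind, lapply(cohort$trajectories, `[[`,
                                   "static_features"))
  statics_std <- sweep(sweep(statics, 2, metadata$static_means, `-`),
                       2, metadata$static_sds, `/`)

  codes <- lapply(cohort$trajectories, `[[`, "diagnoses")
  enc <- encode_diagnoses(codes, vocab = metadata$vocab,
                          pad_length = metadata$diagnosis_pad_length)

  trajectories <- cohort$trajectories
  for (i in seq_along(trajectories)) {
    idx <- which(pooled$adm == i)
    trajectories[[i]]$daily_features <- feat[idx, , drop = FALSE]
    trajectories[[i]]$actions <-
      trajectories[[i]]$actions[, metadata$drug_idx, drop = FALSE]
  }

  structure(list(
    trajectories = trajectories,
    feature_names = metadata$feature_names_out,
    drug_names = metadata$drug_names,
    static_names = cohort$static_names,
    n_rhythm_categories = cohort$n_rhythm_categories,
    config = cohort$config,
    metadata = metadata,
    pooled = pooled,
    diag_idx = enc$indices,
    statics_std = statics_std
  ), class = c("processed_cohort", "cohort"))
}

#' @export
print.processed_cohort <- function(x, ...) {
  cat(sprintf("<processed_cohort> %d admissions, %d days, %d features (complete), K = %d\n",
              length(x$trajectories), nrow(x$pooled$feat),
              length(x$feature_names), length(x$drug_names)))
  invisible(x)
}

#' One-call preprocessing of development and test splits
#'
#' @param development cohort used to fit all statistics.
#' @param test optional cohort transformed with the development statistics.
#' @param config a [preprocess_config()].
#' @return list with `development`, `test` (or `NULL`) and `metadata`.
#' @export
preprocess_cohort <- function(development, test = NULL,
                              config = preprocess_config()) {
  metadata <- preprocess_fit(development, config)
  list(development = preprocess_apply(development, metadata),
       test = if (!is.null(test)) preprocess_apply(test, metadata),
       metadata = metadata)
}

#' Restrict a processed cohort to a feature subset
#'
#' Drops all daily features outside `feature_subset` (and optionally the
#' diagnosis branch), producing the feature-restricted model configurations
#' such as the multimorbidity variant or the no-diagnosis ablation.
#'
#' @param pcohort a `processed_cohort`.
#' @param feature_subset names of daily features to keep.
#' @param drop_diagnoses if `TRUE`, zero out the diagnosis index matrix so
#'   models trained on the result have no diagnosis input.
#' @return a `processed_cohort`.
#' @export
restrict_features <- function(pcohort, feature_subset,
                              drop_diagnoses = FALSE) {
  stopifnot(inherits(pcohort, "processed_cohort"))
  unknown <- setdiff(feature_subset, pcohort$feature_names)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- match(feature_subset, pcohort$feature_names)
  pcohort$pooled$feat <- pcohort$pooled$feat[, keep, drop = FALSE]
  for (i in seq_along(pcohort$trajectories)) {
    pcohort$trajectories[[i]]$daily_features <-
      pcohort$trajectories[[i]]$daily_features[, keep, drop = FALSE]
  }
  pcohort$feature_names <- feature_subset
  if (drop_diagnoses) pcohort$diag_idx[] <- 0L
  pcohort
}

#' Daily features of the multimorbidity model variant
#'
#' The restricted vital-sign/lab subset used by the multimorbidity
#' comparison model (diastolic and systolic blood pressure, GCS, glucose,
#' heart rate, respiratory rate, oxygen saturation, temperature, urine
#' output, and — where recorded — inspired oxygen fraction and pH),
#' intersected with the features actually present.
#'
#' @param available character vector of available feature names.
#' @return character vector.
#' @export
multimorbidity_features <- function(available) {
  intersect(c("dbp", "fio2", "gcs", "glucose", "sbp", "heart_rate", "ph",
              "resp_rate", "spo2", "temp", "urine_output"), available)
}
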