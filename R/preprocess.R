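#' Preprocessing configuration
#'
#' Settings for turning raw trajectory tables into model-ready, fully
#' imputed, normalized feature matrices. All data-dependent statistics
#' (drug ranking, outlier caps, log shifts, means/SDs, diagnosis vocabulary,
#' imputation reference rows) are estimated once on the development split by
#' [preprocess_fit()] and frozen into a metadata object that
#' [preprocess_apply()] re-uses verbatim on any split.
#'
#' @param unit_hours width of the time-binning unit in hours (default 24, the
#'   minimum prescription interval the daily action vector assumes).
#' @param aggregation_map named character vector mapping feature names to
#'   `"mean"` or `"sum"` for within-unit aggregation. Cumulative outputs such
#'   as urine volume should be `"sum"`. A special `.default` entry supplies
#'   the statistic for unmapped features; without it, an unmapped feature in
#'   the events is an error.
#' @param cap_quantiles length-2 numeric, lower/upper empirical quantiles
#'   outside which values are treated as implausible and set missing.
#' @param cap_overrides optional named list of length-2 numeric vectors with
#'   per-feature quantile overrides.
#' @param log_transform_features character vector of right-skewed features to
#'   log before normalization; `NULL` selects the package's default skewed
#'   lab/output variables present in the data.
#' @param knn_k number of nearest neighbours for imputation.
#' @param knn_pool_max maximum number of reference day-rows retained for the
#'   neighbour search (evenly spaced subsample of the development rows, for
#'   scalability; the search itself is exact against this pool).
#' @param normalization only `"zscore"` is supported.
#' @param diagnosis_pad_length padded length of diagnosis index sequences;
#'   `NULL` uses the longest development-set sequence.
#' @param top_k_drugs retain only this many most-frequently prescribed drugs;
#'   `NULL` keeps all.
#' @param composites composite variables to derive before capping.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(unit_hours = 24,
                              aggregation_map = c(urine_output = "sum",
                                                  .default = "mean"),
                              cap_quantiles = c(0.001, 0.999),
                              cap_overrides = NULL,
                              log_transform_features = NULL,
                              knn_k = 5L,
                              knn_pool_max = 1000L,
                              normalization = "zscore",
                              diagnosis_pad_length = NULL,
                              top_k_drugs = NULL,
                              composites = c("shock_index", "gcs")) {
  stopifnot(unit_hours > 0, knn_k >= 1,
            length(cap_quantiles) == 2,
            cap_quantiles[1] >= 0, cap_quantiles[2] <= 1,
            cap_quantiles[1] < cap_quantiles[2])
  normalization <- match.arg(normalization, "zscore")
  structure(list(unit_hours = unit_hours,
                 aggregation_map = aggregation_map,
                 cap_quantiles = cap_quantiles,
                 cap_overrides = cap_overrides,
                 log_transform_features = log_transform_features,
                 knn_k = as.integer(knn_k),
                 knn_pool_max = as.integer(knn_pool_max),
                 normalization = normalization,
                 diagnosis_pad_length = diagnosis_pad_length,
                 top_k_drugs = top_k_drugs,
                 composites = composites),
            class = "preprocess_config")
}

default_log_features <- function(feature_names) {
  intersect(c("glucose", "creatinine", "lactate", "wbc", "urine_output"),
            feature_names)
}

#' Rank drugs by prescription frequency and keep the top k
#'
#' Drugs are ranked by the number of admission-days on which they were
#' prescribed; ties are broken by column (drug identifier) order. Patients
#' whose prescriptions fall outside the retained list keep their rows; only
#' the out-of-list drug columns are dropped.
#'
#' @param prescriptions binary admission-day x drug matrix.
#' @param top_k number of drugs to retain.
#' @return list with `drugs` (retained column indices, rank order),
#'   `coverage` (fraction of prescription records covered), and `counts`.
#' @export
select_top_drugs <- function(prescriptions, top_k) {
  prescriptions <- as.matrix(prescriptions)
  if (nrow(prescriptions) == 0L || ncol(prescriptions) == 0L) {
    stop("empty prescription table", call. = FALSE)
  }
  counts <- colSums(prescriptions)
  K <- length(counts)
  if (top_k >= K) {
    if (top_k > K) warning("top_k exceeds distinct drugs; all retained")
    return(list(drugs = order(-counts, seq_len(K)), coverage = 1,
                counts = counts))
  }
  ord <- order(-counts, seq_len(K))  # ties by drug identifier order
  keep <- ord[seq_len(top_k)]
  total <- sum(counts)
  list(drugs = keep,
       coverage = if (total > 0) sum(counts[keep]) / total else 1,
       counts = counts)
}

#' Bin timestamped measurements into fixed-width daily units
#'
#' Divides the time axis of one hospital admission into half-open units
#' `[u*h, (u+1)*h)` anchored at admission time (hour 0) and aggregates the
#' measurements of each feature within a unit by its mapped statistic (mean
#' for point measurements such as blood pressure, sum for cumulative outputs
#' such as urine volume). Units with no measurement for a feature get a
#' missing marker.
#'
#' @param events data frame with columns `time` (hours since admission),
#'   `feature`, `value`.
#' @param config a [preprocess_config()]; `unit_hours` and `aggregation_map`
#'   are used.
#' @param n_units number of units (rows) to emit; default spans the data.
#' @return numeric matrix, one row per unit, one column per feature.
#' @export
bin_to_daily_units <- function(events, config = preprocess_config(),
                               n_units = NULL) {
  stopifnot(all(c("time", "feature", "value") %in% names(events)))
  feats <- sort(unique(as.character(events$feature)))
  map <- config$aggregation_map
  unknown <- setdiff(feats, names(map))
  if (length(unknown) && !(".default" %in% names(map))) {
    stop("feature(s) not covered by the aggregation map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  agg <- ifelse(is.na(map[feats]), unname(map[".default"]), map[feats])
  names(agg) <- feats
  if (any(events$time < 0)) stop("negative event time", call. = FALSE)
  unit <- floor(events$time / config$unit_hours) + 1L
  if (is.null(n_units)) n_units <- max(unit)
  if (any(unit > n_units)) {
    stop("events beyond the requested number of units", call. = FALSE)
  }
  out <- matrix(NA_real_, n_units, length(feats),
                dimnames = list(NULL, feats))
  for (f in feats) {
    sel <- events$feature == f
    fun <- if (agg[[f]] == "sum") sum else mean
    v <- tapply(events$value[sel], unit[sel], fun)
    out[as.integer(names(v)), f] <- v
  }
  out
}

#' Derive composite clinical variables
#'
#' Adds `shock_index` (heart rate divided by systolic blood pressure) and
#' `gcs` (sum of the eye, verbal and motor Glasgow coma scale components).
#' A composite is missing whenever any component is missing; a zero systolic
#' pressure yields a missing shock index with a warning. If a `pulse` column
#' is requested but absent, heart rate is used in its place.
#'
#' @param feat numeric day-row x feature matrix with named columns.
#' @param composites which composites to compute.
#' @return `feat` with composite columns appended.
#' @export
compute_composites <- function(feat, composites = c("shock_index", "gcs")) {
  feat <- as.matrix(feat)
  if ("shock_index" %in% composites &&
      !("shock_index" %in% colnames(feat))) {
    hr_col <- if ("pulse" %in% colnames(feat)) "pulse" else "heart_rate"
    if (!all(c(hr_col, "sbp") %in% colnames(feat))) {
      stop("shock_index needs columns '", hr_col, "' and 'sbp'", call. = FALSE)
    }
    sbp <- feat[, "sbp"]
    zero <- !is.na(sbp) & sbp == 0
    if (any(zero)) {
      warning(sum(zero), " day(s) with systolic pressure 0; shock index set missing")
      sbp[zero] <- NA_real_
    }
    feat <- cbind(feat, shock_index = feat[, hr_col] / sbp)
  }
  if ("gcs" %in% composites && !("gcs" %in% colnames(feat))) {
    comp <- c("gcs_eye", "gcs_verbal", "gcs_motor")
    if (!all(comp %in% colnames(feat))) {
      stop("gcs needs columns ", paste(comp, collapse = ", "), call. = FALSE)
    }
    feat <- cbind(feat, gcs = feat[, "gcs_eye"] + feat[, "gcs_verbal"] +
                    feat[, "gcs_motor"])
  }
  feat
}

#' Cap implausible values at empirical quantile bounds
#'
#' Values outside the per-feature empirical quantile bounds are set missing
#' (to be re-imputed downstream); a log of removal counts is returned. When
#' `caps` is supplied the stored bounds are applied unchanged, which is how
#' test-split data are capped with development-split bounds.
#'
#' @param feat numeric matrix with named columns; `NA` = missing.
#' @param cap_quantiles global (low, high) quantile pair.
#' @param cap_overrides named list of per-feature quantile pairs.
#' @param caps optional previously fitted bounds (matrix with rows `lo`,
#'   `hi`).
#' @return list with `features`, `caps`, `removed` (count per feature).
#' @export
cap_outliers <- function(feat, cap_quantiles = c(0.001, 0.999),
                         cap_overrides = NULL, caps = NULL) {
  feat <- as.matrix(feat)
  nf <- ncol(feat)
  if (is.null(caps)) {
    caps <- matrix(NA_real_, 2, nf,
                   dimnames = list(c("lo", "hi"), colnames(feat)))
    for (j in seq_len(nf)) {
      q <- cap_quantiles
      nm <- colnames(feat)[j]
      if (!is.null(cap_overrides) && !is.null(cap_overrides[[nm]])) {
        q <- cap_overrides[[nm]]
      }
      obs <- feat[!is.na(feat[, j]), j]
      caps[, j] <- if (length(obs) >= 2L) {
        stats::quantile(obs, q, names = FALSE)
      } else c(-Inf, Inf)
    }
  }
  removed <- integer(nf)
  names(removed) <- colnames(feat)
  for (j in seq_len(nf)) {
    out <- !is.na(feat[, j]) &
      (feat[, j] < caps["lo", j] | feat[, j] > caps["hi", j])
    removed[j] <- sum(out)
    feat[out, j] <- NA_real_
  }
  list(features = feat, caps = caps, removed = removed)
}

#' Log-transform and z-normalize features
#'
#' Applies a natural log to the listed right-skewed features (shifting by
#' `1 - min` first if non-positive values are observed, with the shift
#' recorded) and then z-scores every feature on its observed values. When
#' `stats` is supplied, the stored shifts, means and SDs are applied
#' unchanged (development-split statistics on the test split). Zero-variance
#' features are centered and left at 0 with a warning.
#'
#' @param feat numeric matrix with named columns; `NA` = missing.
#' @param log_features character vector of features to log.
#' @param stats optional fitted statistics from a previous call.
#' @return list with `features` and `stats` (`log_features`, `log_shifts`,
#'   `means`, `sds`).
#' @export
transform_and_normalize <- function(feat, log_features = character(),
                                    stats = NULL) {
  feat <- as.matrix(feat)
  nms <- colnames(feat)
  if (is.null(stats)) {
    shifts <- stats::setNames(numeric(length(log_features)), log_features)
    for (f in log_features) {
      obs <- feat[!is.na(feat[, f]), f]
      if (length(obs) && min(obs) <= 0) shifts[f] <- 1 - min(obs)
    }
    stats <- list(log_features = log_features, log_shifts = shifts,
                  means = NULL, sds = NULL)
  }
  for (f in stats$log_features) {
    feat[, f] <- log(feat[, f] + stats$log_shifts[[f]])
  }
  if (is.null(stats$means)) {
    mu <- colMeans(feat, na.rm = TRUE)
    sd <- apply(feat, 2, stats::sd, na.rm = TRUE)
    zero <- !is.na(sd) & sd == 0
    if (any(zero)) {
      warning("zero-variance feature(s) left at 0 after centering: ",
              paste(nms[zero], collapse = ", "))
      sd[zero] <- 1
    }
    sd[is.na(sd) | sd == 0] <- 1
    stats$means <- mu
    stats$sds <- sd
  }
  feat <- sweep(sweep(feat, 2, stats$means, `-`), 2, stats$sds, `/`)
  list(features = feat, stats = stats)
}

#' K-nearest-neighbour imputation over pooled day-rows
#'
#' Fills each missing cell with the mean of the feature over the `k` nearest
#' reference rows. Distance between two rows is Euclidean over their mutually
#' observed features, rescaled by `sqrt(n_features / n_mutually_observed)` so
#' that rows with fewer shared observations are not artificially close.
#' Neighbours for a given cell are the nearest reference rows that actually
#' observe that feature. Observed cells are never altered.
#'
#' @param feat numeric matrix with `NA` missing markers.
#' @param k neighbourhood size.
#' @param pool optional reference row matrix (defaults to `feat` itself,
#'   subsampled evenly to `pool_max` rows).
#' @param pool_max maximum reference rows retained.
#' @param chunk number of target rows per vectorized distance block.
#' @return the completed matrix.
#' @export
knn_impute <- function(feat, k = 5L, pool = NULL, pool_max = 1000L,
                       chunk = 512L) {
  feat <- as.matrix(feat)
  nf <- ncol(feat)
  all_missing <- colSums(!is.na(feat)) == 0L
  if (any(all_missing)) {
    stop("feature(s) missing in every row: ",
         paste(colnames(feat)[all_missing], collapse = ", "), call. = FALSE)
  }
  if (!anyNA(feat)) return(feat)
  if (is.null(pool)) {
    n <- nrow(feat)
    pool <- if (n <= pool_max) feat else {
      feat[unique(round(seq(1, n, length.out = pool_max))), , drop = FALSE]
    }
  }
  Po <- pool; Po[is.na(Po)] <- 0
  Mp <- !is.na(pool)
  Po2 <- Po^2
  col_means <- colMeans(feat, na.rm = TRUE)

  targets <- which(rowSums(is.na(feat)) > 0L)
  for (lo in seq(1, length(targets), by = chunk)) {
    rows <- targets[lo:min(lo + chunk - 1L, length(targets))]
    X <- feat[rows, , drop = FALSE]
    Xo <- X; Xo[is.na(Xo)] <- 0
    Mx <- !is.na(X)
    S <- (Xo^2) %*% t(Mp) + Mx %*% t(Po2) - 2 * Xo %*% t(Po)
    cnt <- Mx %*% t(Mp)
    D2 <- ifelse(cnt > 0, S * nf / cnt, Inf)
    for (r in seq_along(rows)) {
      i <- rows[r]
      ord <- order(D2[r, ])
      for (f in which(is.na(feat[i, ]))) {
        cand <- ord[Mp[ord, f] & is.finite(D2[r, ord])]
        if (length(cand) == 0L) {
          feat[i, f] <- col_means[f]
        } else {
          nb <- cand[seq_len(min(k, length(cand)))]
          feat[i, f] <- mean(pool[nb, f])
        }
      }
    }
  }
  feat
}

#' Frequency-rank encoding of diagnosis code sequences
#'
#' Builds (or re-uses) a vocabulary of diagnosis codes sorted by descending
#' development-set frequency, replaces each patient's codes by their 1-based
#' frequency-rank indices (rank ties broken by code order), sorts each
#' patient's indices ascending (most frequent first) and zero-pads to a fixed
#' length. Codes unseen at fit time map to the reserved index
#' `length(vocab) + 1`.
#'
#' @param code_lists list of integer/character code vectors, one per patient.
#' @param vocab optional fitted vocabulary (character vector in rank order).
#' @param pad_length padded sequence length; `NULL` uses the longest input
#'   sequence. Must be at least the longest fit-time sequence.
#' @return list with `indices` (n x pad_length integer matrix) and `vocab`.
#' @export
encode_diagnoses <- function(code_lists, vocab = NULL, pad_length = NULL) {
  codes_chr <- lapply(code_lists, as.character)
  if (is.null(vocab)) {
    tab <- table(unlist(codes_chr))
    # ties in frequency broken by code lexical order (table() is sorted by
    # name already, so a stable order on -freq suffices)
    vocab <- names(tab)[order(-as.integer(tab), names(tab))]
  }
  longest <- max(c(0L, lengths(codes_chr)))
  if (is.null(pad_length)) pad_length <- longest
  if (pad_length < longest) {
    stop("pad_length (", pad_length, ") shorter than the longest sequence (",
         longest, ")", call. = FALSE)
  }
  unknown <- length(vocab) + 1L
  idx <- t(vapply(codes_chr, function(cs) {
    r <- match(cs, vocab)
    r[is.na(r)] <- unknown
    r <- sort(r)
    c(r, rep(0L, pad_length - length(r)))
  }, integer(pad_length)))
  list(indices = idx, vocab = vocab)
}

#' Distance-preservation report for a diagnosis embedding
#'
#' Compares pairwise patient distances in the raw index space with distances
#' in an embedding space. Pairs are split into three equal-size groups
#' (closer / middle / distant) by index-space distance; the report gives each
#' group's mean distance in both spaces and whether the group ordering is
#' preserved in the embedding space (a monotone embedding keeps closer groups
#' closer).
#'
#' @param index_seqs numeric matrix of padded index sequences (n x P).
#' @param embedded numeric matrix of embedded vectors (n x d).
#' @return data frame with one row per group (`group`, `n_pairs`,
#'   `mean_index_dist`, `mean_embed_dist`) carrying an
#'   `ordering_preserved` attribute.
#' @export
embedding_rationality_report <- function(index_seqs, embedded) {
  index_seqs <- as.matrix(index_seqs)
  embedded <- as.matrix(embedded)
  n <- nrow(index_seqs)
  if (nrow(embedded) != n) stop("patient sets differ", call. = FALSE)
  d_idx <- as.vector(stats::dist(index_seqs))
  d_emb <- as.vector(stats::dist(embedded))
  np <- length(d_idx)
  if (np < 3L) stop("need at least 3 patient pairs", call. = FALSE)
  ord <- order(d_idx)
  bounds <- floor(np * (0:3) / 3)
  sizes <- diff(bounds)
  if (any(sizes == 0L)) stop("empty distance group", call. = FALSE)
  grp <- integer(np)
  grp[ord] <- rep(1:3, sizes)
  res <- data.frame(
    group = c("closer", "middle", "distant"),
    n_pairs = sizes,
    mean_index_dist = tapply(d_idx, grp, mean),
    mean_embed_dist = tapply(d_emb, grp, mean),
    row.names = NULL
  )
  attr(res, "ordering_preserved") <- !is.unsorted(res$mean_embed_dist)
  res
}
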