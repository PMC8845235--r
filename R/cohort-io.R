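#' Write / read a cohort as delimited text plus a metadata sidecar
#'
#' `write_cohort()` stores a cohort as one tidy CSV table (one row per
#' admission-day, columns `admission_id`, `day`, the feature columns with
#' empty cells for missing values, `rhythm` as the 1-based subtype index,
#' drug columns `d0` .. `dK-1`, and `died`) plus a JSON sidecar
#' (`<path>.meta.json`) holding names, static features, diagnosis sequences
#' and the generating configuration. `read_cohort()` restores the cohort
#' losslessly, validating the trajectory invariants while parsing.
#'
#' @param cohort a `cohort` object.
#' @param path path of the CSV table; the sidecar is written next to it.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  K <- length(cohort$drug_names)
  rows <- lapply(cohort$trajectories, function(tr) {
    df <- data.frame(admission_id = tr$admission_id, day = seq_len(tr$T))
    feats <- as.data.frame(tr$daily_features)
    names(feats) <- cohort$feature_names
    df <- cbind(df, feats,
                rhythm = apply(tr$daily_rhythm, 1, which.max))
    acts <- as.data.frame(tr$actions)
    names(acts) <- paste0("d", seq_len(K) - 1L)
    cbind(df, acts, died = as.integer(tr$died_in_hospital))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  meta <- list(
    feature_names = cohort$feature_names,
    drug_names = cohort$drug_names,
    static_names = cohort$static_names,
    n_rhythm_categories = cohort$n_rhythm_categories,
    config = unclass(cohort$config),
    admissions = lapply(cohort$trajectories, function(tr) {
      list(admission_id = tr$admission_id,
           static_features = as.list(tr$static_features),
           diagnoses = tr$diagnoses,
           died_in_hospital = tr$died_in_hospital)
    })
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  mp <- sidecar_path(path)
  if (!file.exists(mp)) stop("missing metadata sidecar: ", mp, call. = FALSE)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  tab <- utils::read.csv(path, na.strings = "")
  fn <- unlist(meta$feature_names)
  dn <- unlist(meta$drug_names)
  R <- meta$n_rhythm_categories
  K <- length(dn)
  dcols <- paste0("d", seq_len(K) - 1L)
  need <- c("admission_id", "day", fn, "rhythm", dcols, "died")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  adm_meta <- meta$admissions
  adm_ids <- vapply(adm_meta, function(a) as.integer(a$admission_id), integer(1))
  trajectories <- vector("list", length(adm_meta))
  for (j in seq_along(adm_meta)) {
    a <- adm_meta[[j]]
    sub <- tab[tab$admission_id == adm_ids[j], , drop = FALSE]
    Ti <- nrow(sub)
    if (Ti < 1L) {
      stop("admission ", adm_ids[j], ": no rows in table (T must be >= 1)",
           call. = FALSE)
    }
    sub <- sub[order(sub$day), , drop = FALSE]
    if (!identical(as.integer(sub$day), seq_len(Ti))) {
      stop("admission ", adm_ids[j],
           ": field 'day' must run 1..T without gaps", call. = FALSE)
    }
    acts <- as.matrix(sub[, dcols, drop = FALSE])
    bad <- which(!(acts %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(acts))
      stop("admission ", adm_ids[j], ", day ", rc[1], ", field '",
           dcols[rc[2]], "': action value must be 0 or 1 (got ",
           acts[bad[1]], ")", call. = FALSE)
    }
    rh <- as.integer(sub$rhythm)
    if (anyNA(rh) || any(rh < 1L | rh > R)) {
      stop("admission ", adm_ids[j],
           ": field 'rhythm' must be an integer in 1..", R, call. = FALSE)
    }
    rhm <- matrix(0L, Ti, R)
    rhm[cbind(seq_len(Ti), rh)] <- 1L
    died <- as.logical(a$died_in_hospital)
    rewards <- numeric(Ti)
    rewards[Ti] <- if (died) -15 else 15
    storage.mode(acts) <- "integer"
    fm <- as.matrix(sub[, fn, drop = FALSE])
    dimnames(fm) <- list(NULL, fn)
    trajectories[[j]] <- structure(list(
      admission_id = adm_ids[j],
      T = Ti,
      diagnoses = as.integer(unlist(a$diagnoses)),
      static_features = unlist(a$static_features),
      daily_features = fm,
      daily_rhythm = rhm,
      actions = unname(acts),
      died_in_hospital = died,
      rewards = rewards
    ), class = "trajectory")
  }
  cfg <- meta$config
  class(cfg) <- "sim_config"
  structure(list(
    trajectories = trajectories,
    feature_names = fn,
    drug_names = dn,
    static_names = unlist(meta$static_names),
    n_rhythm_categories = R,
    config = cfg
  ), class = "cohort")
}

# Pool all admission-day rows of a cohort into flat matrices; the common
# currency of the preprocessing and training code.
pool_days <- function(cohort) {
  tr <- cohort$trajectories
  Ts <- vapply(tr, `[[`, integer(1), "T")
  feat <- do.call(rbind, lapply(tr, `[[`, "daily_features"))
  rhythm <- do.call(rbind, lapply(tr, `[[`, "daily_rhythm"))
  actions <- do.call(rbind, lapply(tr, `[[`, "actions"))
  list(
    feat = feat, rhythm = rhythm, actions = actions,
    adm = rep(seq_along(tr), Ts),
    day = unlist(lapply(Ts, seq_len)),
    T_len = Ts,
    died = vapply(tr, `[[`, logical(1), "died_in_hospital")
  )
}
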