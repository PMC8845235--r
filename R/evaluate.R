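# per-day Jaccard between two binary action matrices; the empty/empty day is
# perfect agreement on "no drugs" and scores 1
day_jaccard <- function(actual, recommended) {
  actual <- actual != 0
  recommended <- recommended != 0
  inter <- rowSums(actual & recommended)
  uni <- rowSums(actual | recommended)
  ifelse(uni == 0, 1, inter / uni)
}

#' Mean Jaccard similarity between clinician and recommended actions
#'
#' The per-day Jaccard coefficient `|A n Ahat| / |A u Ahat|` between the
#' prescribed and recommended drug sets is averaged within each admission
#' and then across admissions. A day on which both sets are empty counts as
#' perfect agreement (1). `J = 1` means every daily recommendation equals
#' the clinician's action; `J = 0` means no drug is ever shared.
#'
#' @param actual,recommended either lists of per-admission `T x K` binary
#'   matrices, or pooled day-row matrices accompanied by `adm`.
#' @param adm admission index per pooled row (when matrices are pooled).
#' @return scalar mean Jaccard in `[0, 1]`.
#' @export
mean_jaccard <- function(actual, recommended, adm = NULL) {
  if (is.list(actual)) {
    if (!is.list(recommended) || length(actual) != length(recommended)) {
      stop("actual and recommended must match admission for admission",
           call. = FALSE)
    }
    shapes_ok <- mapply(function(a, b) identical(dim(a), dim(b)),
                        actual, recommended)
    if (!all(shapes_ok)) stop("mismatched action shapes", call. = FALSE)
    adm <- rep(seq_along(actual), vapply(actual, nrow, integer(1)))
    actual <- do.call(rbind, actual)
    recommended <- do.call(rbind, recommended)
  }
  if (!identical(dim(actual), dim(recommended))) {
    stop("mismatched action shapes", call. = FALSE)
  }
  if (is.null(adm)) adm <- rep(1L, nrow(actual))
  j <- day_jaccard(actual, recommended)
  mean(tapply(j, adm, mean))
}

#' Daily treatment difference and mortality-by-difference curve
#'
#' The treatment difference of a day is the Hamming distance
#' `B = sum_k |a_k - ahat_k|` between the clinician's and the recommended
#' binary action vectors. Days are binned by B (unit-width bins up to `cap`,
#' then one overflow bin) and each bin reports the observed in-hospital
#' mortality of the admissions owning its days.
#'
#' @param actual,recommended pooled day-row x K binary matrices.
#' @param adm admission index per row.
#' @param died logical vector per admission.
#' @param cap largest unit-width bin; differences above it pool into one
#'   overflow bin.
#' @return list with `B` (per-day differences) and `curve` (data frame:
#'   `difference`, `n_days`, `mortality`).
#' @export
treatment_difference <- function(actual, recommended, adm, died, cap = 6L) {
  if (!identical(dim(actual), dim(recommended))) {
    stop("mismatched action shapes", call. = FALSE)
  }
  B <- rowSums(abs(actual - recommended))
  lab <- ifelse(B > cap, paste0(">", cap), as.character(B))
  lev <- c(as.character(0:cap), paste0(">", cap))
  lab <- factor(lab, levels = lev)
  day_died <- died[adm]
  curve <- data.frame(
    difference = lev,
    n_days = as.integer(table(lab)),
    mortality = as.numeric(tapply(day_died, lab, mean))
  )
  curve <- curve[curve$n_days > 0, ]
  rownames(curve) <- NULL
  list(B = B, curve = curve)
}

#' Bootstrapped mortality rates over expected-return quantile bins
#'
#' Discretizes the expected returns of the clinicians' actual actions into
#' quantile units (5% of states each by default) and estimates each unit's
#' mortality rate as the bootstrap mean over resampled mortality flags, with
#' a percentile interval. Duplicate quantile edges (mass points in the
#' return distribution) are merged with a note; ties at an edge fall into
#' the lower bin.
#'
#' @param returns expected return of each state-actual-action pair.
#' @param died logical mortality flag per state (the owning admission's
#'   outcome).
#' @param n_boot bootstrap resamples per bin.
#' @param bin_width quantile width per unit (0.05 = 20 bins).
#' @param seed bootstrap seed.
#' @return a `return_bin_table` data frame (`bin`, `lo`, `hi`,
#'   `median_return`, `n_states`, `n_deaths`, `rate` (bootstrap mean),
#'   `ci_lo`, `ci_hi`, `boot_se`) with the bin edges as an attribute.
#' @export
build_return_bins <- function(returns, died, n_boot = 2000L,
                              bin_width = 0.05, seed = 1L) {
  stopifnot(length(returns) == length(died))
  if (length(returns) < 1 / bin_width) {
    stop("need at least ", ceiling(1 / bin_width), " states", call. = FALSE)
  }
  probs <- seq(0, 1, by = bin_width)
  edges <- stats::quantile(returns, probs, names = FALSE)
  inner <- edges[-c(1, length(edges))]
  merged <- anyDuplicated(inner) > 0
  inner <- unique(inner)
  if (merged) {
    message("duplicate quantile edges merged: ",
            length(probs) - 1 - (length(inner) + 1),
            " bin(s) collapsed")
  }
  # left-open intervals put a value equal to an inner edge into the lower bin
  bin <- findInterval(returns, inner, left.open = TRUE) + 1L
  n_bins <- length(inner) + 1L
  set.seed(seed)
  rows <- lapply(seq_len(n_bins), function(b) {
    flags <- as.numeric(died[bin == b])
    nb <- length(flags)
    if (nb == 0L) return(NULL)
    bm <- colMeans(matrix(sample(flags, nb * n_boot, replace = TRUE),
                          nrow = nb))
    data.frame(bin = b,
               lo = if (b == 1L) -Inf else inner[b - 1L],
               hi = if (b == n_bins) Inf else inner[b],
               median_return = stats::median(returns[bin == b]),
               n_states = nb,
               n_deaths = sum(flags),
               rate = mean(bm),
               ci_lo = stats::quantile(bm, 0.025, names = FALSE),
               ci_hi = stats::quantile(bm, 0.975, names = FALSE),
               boot_se = stats::sd(bm))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, inner_edges = inner, n_boot = n_boot, seed = seed,
            merged = merged, class = c("return_bin_table", "data.frame"))
}

# assign new returns to fitted bins; out-of-range returns clamp into the
# extreme bins by construction of the (-Inf, ..., Inf) edges
assign_bins <- function(bins, returns) {
  findInterval(returns, attr(bins, "inner_edges"), left.open = TRUE) + 1L
}

# expected deaths under the fitted bin rates for a set of returns
expected_mortality_rate <- function(bins, returns) {
  b <- assign_bins(bins, returns)
  rate <- bins$rate[match(b, bins$bin)]
  mean(rate)
}

#' Monotonicity of bin mortality in expected return
#'
#' Spearman correlation between each unit's median expected return and its
#' bootstrap mortality rate. A well-calibrated critic yields a clearly
#' negative correlation: low-return treatment actions carry high mortality.
#'
#' @param bins a `return_bin_table`.
#' @return list with `spearman`, `degenerate` (constant rates) and the bin
#'   table.
#' @export
return_mortality_correlation <- function(bins) {
  degenerate <- length(unique(bins$rate)) == 1L
  rho <- if (degenerate) 0 else {
    stats::cor(bins$median_return, bins$rate, method = "spearman")
  }
  list(spearman = rho, degenerate = degenerate, bins = bins)
}

# expected returns Q(S, A) of every pooled day for given actions
critic_returns <- function(model, pcohort, actions) {
  S <- build_state_matrix(pcohort, model$config$window)
  D <- if (model$critic$use_diag) {
    pcohort$diag_idx[pcohort$pooled$adm, , drop = FALSE]
  }
  forward_chunked(model$critic, S, D, actions)[, 1]
}

#' Off-policy evaluation of a recommendation model
#'
#' Runs the full estimated-mortality procedure against a processed cohort:
#' (1) the critic scores every state under the clinicians' actual actions
#' and under the model's recommended actions; (2) actual-action returns are
#' discretized into 5%-quantile units; (3) each unit's mortality rate is the
#' bootstrap mean of its states' mortality flags; (4) recommended-action
#' returns are assigned to the same units and the expected number of deaths
#' is accumulated, giving the state-wise estimated in-hospital mortality;
#' (5) the trajectory-wise variant repeats the procedure using only each
#' admission's initial state-action pair with bins refit on initial-state
#' returns. The report also carries the mean Jaccard, the
#' treatment-difference curve, the return-bin tables and the mean number of
#' recommended drugs per day.
#'
#' @param model a trained `srl_model` with a critic.
#' @param pcohort a `processed_cohort`.
#' @param recommended optional pooled day-row x K binary matrix overriding
#'   the actor's own recommendations (e.g. the clinician's actions for a
#'   self-evaluation, or another policy's actions).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param threshold optional recommendation threshold.
#' @return an `evaluation_report` list.
#' @export
evaluate_policy <- function(model, pcohort, recommended = NULL,
                            n_boot = 2000L, seed = 1L, threshold = NULL) {
  stopifnot(inherits(pcohort, "processed_cohort"))
  if (is.null(model$critic)) {
    stop("model has no critic; off-policy evaluation needs one", call. = FALSE)
  }
  pooled <- pcohort$pooled
  state_died <- pooled$died[pooled$adm]
  if (is.null(recommended)) {
    rec <- recommend(model, pcohort, threshold)$action
  } else {
    rec <- recommended
    if (!identical(dim(rec), dim(pooled$actions))) {
      stop("recommended action matrix has the wrong shape", call. = FALSE)
    }
  }

  q_act <- critic_returns(model, pcohort, pooled$actions)
  q_rec <- critic_returns(model, pcohort, rec)

  bins_state <- build_return_bins(q_act, state_died, n_boot = n_boot,
                                  seed = seed)
  est_state <- expected_mortality_rate(bins_state, q_rec)

  first <- pooled$day == 1L
  bins_traj <- build_return_bins(q_act[first], pooled$died,
                                 n_boot = n_boot, seed = seed + 1L)
  est_traj <- expected_mortality_rate(bins_traj, q_rec[first])

  diffs <- treatment_difference(pooled$actions, rec, pooled$adm, pooled$died)

  structure(list(
    jaccard = mean_jaccard(pooled$actions, rec, pooled$adm),
    observed_mortality_trajectorywise = mean(pooled$died),
    observed_mortality_statewise = mean(state_died),
    estimated_mortality_trajectorywise = est_traj,
    estimated_mortality_statewise = est_state,
    mean_drugs_recommended = mean(rowSums(rec)),
    mean_drugs_actual = mean(rowSums(pooled$actions)),
    treatment_difference = diffs,
    bins_statewise = bins_state,
    bins_trajectorywise = bins_traj,
    return_mortality = return_mortality_correlation(bins_state)[
      c("spearman", "degenerate")]
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  Jaccard vs clinicians:            %.4f\n", x$jaccard))
  cat(sprintf("  observed mortality  (traj/state): %.4f / %.4f\n",
              x$observed_mortality_trajectorywise,
              x$observed_mortality_statewise))
  cat(sprintf("  estimated mortality (traj/state): %.4f / %.4f\n",
              x$estimated_mortality_trajectorywise,
              x$estimated_mortality_statewise))
  cat(sprintf("  mean drugs/day (recommended/actual): %.1f / %.1f\n",
              x$mean_drugs_recommended, x$mean_drugs_actual))
  cat(sprintf("  return-mortality Spearman: %.3f%s\n",
              x$return_mortality$spearman,
              if (x$return_mortality$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' State-wise and trajectory-wise estimated mortality
#'
#' Convenience accessors running the full procedure of [evaluate_policy()]
#' and returning just the requested rate.
#'
#' @inheritParams evaluate_policy
#' @return scalar estimated in-hospital mortality rate.
#' @export
estimated_mortality_statewise <- function(model, pcohort, recommended = NULL,
                                          n_boot = 2000L, seed = 1L) {
  evaluate_policy(model, pcohort, recommended, n_boot,
                  seed)$estimated_mortality_statewise
}

#' @rdname estimated_mortality_statewise
#' @export
estimated_mortality_trajectorywise <- function(model, pcohort,
                                               recommended = NULL,
                                               n_boot = 2000L, seed = 1L) {
  evaluate_policy(model, pcohort, recommended, n_boot,
                  seed)$estimated_mortality_trajectorywise
}
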