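# Small shared fixtures, built once per test run.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_admissions = 60, K = 8, n_features = 6,
         n_rhythm_categories = 5, max_days = 12,
         diagnosis_vocab_size = 30, max_diagnoses_per_patient = 5,
         missingness_rate = 0.15, seed = 101),
    list(...))
  do.call(sim_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

tiny_cohort <- function() {
  fixture("tiny_cohort", function() simulate_cohort(tiny_config()))
}

tiny_processed <- function() {
  fixture("tiny_processed", function() {
    preprocess_cohort(tiny_cohort(),
                      config = preprocess_config(knn_pool_max = 300))
  })
}

tiny_model <- function() {
  fixture("tiny_model", function() {
    train_srl(tiny_processed()$development,
              train_config(steps = 400, eval_every = 200,
                           hidden_actor = 16, hidden_critic = 16,
                           embed_dim = 4, seed = 5))
  })
}

# hand-rolled cohort with fully controlled actions, for metric tests
manual_cohort <- function(action_list, died = NULL, K = 10) {
  n <- length(action_list)
  if (is.null(died)) died <- rep(FALSE, n)
  trajectories <- lapply(seq_len(n), function(i) {
    A <- action_list[[i]]
    Ti <- nrow(A)
    rh <- matrix(0L, Ti, 5); rh[, 1] <- 1L
    rewards <- numeric(Ti); rewards[Ti] <- if (died[i]) -15 else 15
    structure(list(admission_id = i, T = Ti, diagnoses = c(1L, 2L),
                   static_features = c(age = 70, male = 1, weight = 80),
                   daily_features = matrix(stats::rnorm(Ti * 3), Ti, 3,
                                           dimnames = list(NULL, c("f1", "f2", "f3"))),
                   daily_rhythm = rh, actions = A,
                   died_in_hospital = died[i], rewards = rewards),
              class = "trajectory")
  })
  structure(list(trajectories = trajectories,
                 feature_names = c("f1", "f2", "f3"),
                 drug_names = sprintf("drug_%02d", seq_len(K)),
                 static_names = c("age", "male", "weight"),
                 n_rhythm_categories = 5,
                 config = tiny_config()),
            class = "cohort")
}
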