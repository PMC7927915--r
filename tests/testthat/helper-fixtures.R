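# Shared fixtures, built lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default-world subject used across detection/HMM tests (seed 2 is
# the first subject of run_all(seed = 1))
default_subject <- function() {
  cached("default_subject", function()
    suppressMessages(simulate_subject(2, default_sim_config())))
}

default_detection <- function() {
  cached("default_detection", function() {
    sub <- default_subject()
    clf <- train_classifiers(sub$localizer, 200)
    probs <- apply_classifiers(sub$session, clf)
    trace <- replay_probability(probs, default_sequences()$chains, 10L)
    events <- threshold_events(trace, 250, 99,
                               bad_mask = sub$session$bad_mask)
    list(clf = clf, probs = probs, trace = trace, events = events)
  })
}

default_reduced <- function() {
  cached("default_reduced", function() {
    sub <- default_subject()
    pca_reduce(embed_session(sub$session, 7), 24)
  })
}

# state time course built directly from a hard path (one-hot posteriors);
# used to exercise evoked/burst machinery against planted ground truth
# without an HMM fit in between
onehot_timecourse <- function(path, fs, K = max(path)) {
  g <- t(vapply(seq_len(K), function(k) as.numeric(path == k),
                numeric(length(path))))
  structure(list(gamma = g, viterbi = as.integer(path),
                 samples = seq_along(path),
                 valid_range = c(1L, length(path)), fs = fs),
            class = "state_timecourse")
}

# wrap a bare matrix as a tde_reduced so fit_hmm/decode can run on
# exactly-generative data
as_reduced <- function(X, fs = 250) {
  structure(list(x = X, samples = seq_len(ncol(X)), fs = fs, l = 0L,
                 n_channels = nrow(X), basis = diag(nrow(X)),
                 row_means = rep(0, nrow(X)), explained_variance = 1),
            class = "tde_reduced")
}

# sample a zero-mean Gaussian HMM exactly from its parameters
sample_gaussian_hmm <- function(covs, trans, T, seed) {
  K <- length(covs)
  path <- gen_state_path(K, trans, T, seed = seed)
  D <- nrow(covs[[1]])
  set.seed(sub_seed_test(seed, 1))
  X <- matrix(0, D, T)
  for (k in seq_len(K)) {
    idx <- which(path == k)
    if (length(idx))
      X[, idx] <- t(chol(covs[[k]])) %*% matrix(rnorm(D * length(idx)), D)
  }
  list(x = X, path = path)
}

sub_seed_test <- function(seed, offset) {
  as.integer((as.numeric(seed) * 6007 + 31 * offset) %% 2147483647)
}

# wrap reactivation probabilities without running decoders
as_probs <- function(pm, fs = 250, bad_mask = NULL) {
  structure(list(probs = pm, fs = fs,
                 bad_mask = bad_mask %||% rep(FALSE, ncol(pm)),
                 stimulus_names = sprintf("stim%d", seq_len(nrow(pm)))),
            class = "reactivation_probs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_state_match <- function(est, truth, K, min_accuracy) {
  m <- replayburst:::match_states(est, truth, K)
  expect_gt(m$accuracy, min_accuracy)
  invisible(m)
}
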