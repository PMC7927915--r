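test_that("train_classifiers fits one-vs-rest sparse decoders", {
  # noiseless, separable: perfect training accuracy
  loc <- gen_localizer(4, 40, 6, 250, snr = 50, seed = 1)
  clf <- train_classifiers(loc, 200, l1_penalty = 0.01)
  peak <- which.min(abs(localizer_times(loc) * 1000 - 200))
  X <- loc$trials[, , peak]
  scores <- X %*% t(clf$weights) + rep(clf$intercepts, each = nrow(X))
  pred <- max.col(scores) - 1L
  expect_equal(mean(pred == loc$labels), 1)
  expect_false(any(clf$degenerate))

  # overwhelming penalty zeroes all weights and flags degeneracy
  expect_warning(clf0 <- train_classifiers(loc, 200, l1_penalty = 1e6),
                 "degenerate")
  expect_true(all(clf0$degenerate))
  expect_true(all(clf0$weights == 0))

  # degenerate labels rejected
  loc1 <- loc
  loc1$labels <- rep(0L, length(loc$labels))
  expect_error(train_classifiers(loc1, 200), "single-class")
})

test_that("pick_training_time maximizes CV accuracy with earliest-tie rule", {
  loc <- gen_localizer(4, 80, 8, 250, peak_ms = 200, snr = 2, seed = 3,
                       envelope_sd_ms = 30)
  tm <- pick_training_time(loc, n_folds = 5,
                           times_ms = seq(0, 400, by = 100), seed = 1)
  expect_equal(as.numeric(tm), 200)

  # exact duplicate features at two times tie; earliest wins
  loc2 <- loc
  idx150 <- which.min(abs(localizer_times(loc) * 1000 - 150))
  idx250 <- which.min(abs(localizer_times(loc) * 1000 - 250))
  loc2$trials[, , idx250] <- loc2$trials[, , idx150]
  tm2 <- pick_training_time(loc2, n_folds = 5, times_ms = c(150, 250),
                            seed = 1)
  expect_equal(as.numeric(tm2), 150)

  # flat envelope: chance accuracy everywhere, flagged low-confidence
  loc3 <- gen_localizer(4, 64, 8, 250, snr = 0, seed = 4)
  expect_warning(tm3 <- pick_training_time(loc3, n_folds = 4,
                                           times_ms = seq(0, 400, by = 100),
                                           seed = 1),
                 "chance")
  expect_true(isTRUE(attr(tm3, "low_confidence")))
})

test_that("apply_classifiers computes sigmoid probabilities", {
  ses <- recording_session(matrix(c(0, log(3)), 1, 2), 250)
  clf <- structure(list(weights = matrix(1, 1, 1), intercepts = 0,
                        training_time_ms = 200, l1_penalty = 0,
                        degenerate = FALSE), class = "classifier_set")
  probs <- apply_classifiers(ses, clf)
  expect_equal(probs$probs[1, 1], 0.5)    # sigma(0)
  expect_equal(probs$probs[1, 2], 0.75)   # sigma(ln 3)

  ses2 <- recording_session(matrix(0, 3, 2), 250)
  expect_error(apply_classifiers(ses2, clf), "1 channels, session has 3")
})

test_that("sequence_evidence finds planted lags and stays flat on noise", {
  T <- 20000
  set.seed(5)
  base <- matrix(runif(2 * T, 0.1, 0.9), 2)
  # trace 2 is trace 1 shifted by 10 samples
  pm <- rbind(base[1, ], c(rep(0.5, 10), base[1, 1:(T - 10)]))
  probs <- as_probs(pm)
  ev <- sequence_evidence(probs, matrix(c(1L, 2L), 1),
                          lags_ms = seq(10, 200, by = 10))
  expect_equal(ev$lag_ms[which.max(ev$evidence)], 40)
  expect_equal(ev$lag_samples[ev$lag_ms == 40], 10L)

  # independent noise: |evidence| < 0.05 at every lag (T >= 60 s)
  pm2 <- matrix(runif(3 * T, 0.1, 0.9), 3)
  ev2 <- sequence_evidence(as_probs(pm2), matrix(c(1L, 2L), 1))
  expect_lt(max(abs(ev2$evidence)), 0.05)

  # constant trace contributes zero correlation, with a log message
  pm3 <- rbind(rep(0.5, T), runif(T))
  expect_message(
    ev3 <- sequence_evidence(as_probs(pm3), matrix(c(1L, 2L), 1),
                             lags_ms = 40),
    "constant")
  expect_equal(ev3$task_mean, 0)
})

test_that("replay_probability implements product/noisy-OR over six pairs", {
  chains <- list(1:4, 5:8)
  T <- 50
  # all reactivations zero-ish: R = 0
  pm <- matrix(1e-12, 8, T)
  R <- replay_probability(as_probs(pm), chains, 10L)
  expect_equal(max(R, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_true(all(is.na(tail(R, 10))))

  # one pair (0.9, 0.8), others 0: R = 0.72
  pm2 <- matrix(1e-12, 8, T)
  pm2[1, 1] <- 0.9
  pm2[2, 11] <- 0.8
  R2 <- replay_probability(as_probs(pm2), chains, 10L)
  expect_equal(R2[1], 0.72, tolerance = 1e-9)

  # all six joints q = 0.5: brute-force inclusion-exclusion oracle
  pm3 <- matrix(sqrt(0.5), 8, T)
  R3 <- replay_probability(as_probs(pm3), chains, 10L)
  # oracle: enumerate all 2^6 outcomes of six independent events
  q <- 0.5
  p_union <- 0
  for (m in 0:(2^6 - 1)) {
    on <- sum(bitwAnd(m, 2^(0:5)) > 0)
    if (on > 0) p_union <- p_union + q^on * (1 - q)^(6 - on)
  }
  expect_equal(p_union, 0.984375)
  expect_equal(R3[1], p_union, tolerance = 1e-9)

  # monotonicity: raising one reactivation probability never lowers R_t
  set.seed(8)
  pm4 <- matrix(runif(8 * T, 0.05, 0.95), 8)
  R4 <- replay_probability(as_probs(pm4), chains, 10L)
  pm5 <- pm4
  pm5[2, 11] <- min(1 - 1e-9, pm5[2, 11] + 0.04)
  R5 <- replay_probability(as_probs(pm5), chains, 10L)
  expect_true(all(R5 >= R4 - 1e-12, na.rm = TRUE))

  expect_error(replay_probability(as_probs(pm4), list(1:4, 4:7), 10L),
               "distinct")
})

test_that("threshold_events extracts merged run onsets at the stated percentile", {
  # exactly 1% of samples are suprathreshold, in two disjoint runs
  tr <- rep(0.1, 1000)
  tr[101:105] <- 0.9
  tr[301:305] <- 0.95
  ev <- threshold_events(tr, 250, 99, merge_within = 10)
  expect_equal(ev$event_onsets, c(101L, 301L))
  expect_true(all(tr[ev$event_onsets] >= ev$threshold))

  # runs closer than the merge window collapse onto the first onset
  tr2 <- rep(0.1, 1000)
  tr2[101:105] <- 0.9
  tr2[111:115] <- 0.9
  ev2 <- threshold_events(tr2, 250, 99, merge_within = 10)
  expect_equal(ev2$event_onsets, 101L)

  # positive rescaling leaves onsets unchanged (percentile invariance)
  ev3 <- threshold_events(tr * 7.3, 250, 99, merge_within = 10)
  expect_equal(ev3$event_onsets, ev$event_onsets)

  # constant trace warns and yields no events
  expect_warning(ev4 <- threshold_events(rep(0.4, 100), 250, 99),
                 "constant")
  expect_length(ev4$event_onsets, 0)

  expect_error(threshold_events(tr, 250, 0), "percentile")
})

test_that("the default fixture's planted events are recovered", {
  sub <- default_subject()
  det <- default_detection()
  m <- replayburst:::match_events(det$events$event_onsets,
                                  sub$truth$replay_times, tol = 2L)
  expect_gte(m$recall, 0.8)
  expect_gte(m$precision, 0.5)

  # sequence evidence peaks at the planted 40 ms lag
  ev <- sequence_evidence(det$probs, default_sequences()$pairs)
  expect_equal(ev$lag_ms[which.max(ev$evidence)], 40)

  # R_t stays a probability
  expect_true(all(det$trace >= 0 & det$trace <= 1, na.rm = TRUE))

  # with gain -> 0, detection falls to chance-level matching
  cf0 <- default_sim_config()
  cf0$gain <- 0
  cf0$duration_s <- 120
  sub0 <- suppressMessages(simulate_subject(2, cf0))
  clf0 <- train_classifiers(sub0$localizer, 200)
  probs0 <- apply_classifiers(sub0$session, clf0)
  tr0 <- replay_probability(probs0, default_sequences()$chains, 10L)
  ev0 <- threshold_events(tr0, 250, 99, bad_mask = sub0$session$bad_mask)
  m0 <- replayburst:::match_events(ev0$event_onsets,
                                   sub0$truth$replay_times, tol = 2L)
  expect_lt(m0$recall, 0.2)
})
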