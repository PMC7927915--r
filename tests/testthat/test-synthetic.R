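test_that("gen_state_path samples the requested Markov chain", {
  # absorbing identity chain stays put
  path <- gen_state_path(2, diag(2), 1000, seed = 1, start = 1)
  expect_true(all(path == 1L))

  # empirical transition rates converge (law of large numbers)
  K <- 3
  Th <- matrix(0.05, K, K)
  diag(Th) <- 0.9
  path <- gen_state_path(K, Th, 250000, seed = 4)
  tab <- table(head(path, -1), tail(path, -1))
  emp <- tab / rowSums(tab)
  off <- emp[row(emp) != col(emp)]
  expect_true(all(abs(off - 0.05) <= 0.005))

  # symmetric 2-state chain: occupancy near 1/2
  p2 <- gen_state_path(2, matrix(0.5, 2, 2), 100000, seed = 9)
  expect_gte(mean(p2 == 1), 0.49)
  expect_lte(mean(p2 == 1), 0.51)

  # non-stochastic rows rejected, naming the row
  bad <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, byrow = TRUE)
  expect_error(gen_state_path(2, bad, 10, seed = 1), "row 1")
})

test_that("gen_state_signals plants the stated oscillations", {
  T <- 15000
  fs <- 250
  # single state, pure 10 Hz, no noise: FFT oracle puts the peak at 10 Hz
  ses <- gen_state_signals(rep(1L, T), fs, list(list(state_component(10, 1))),
                           noise_sd = 0, seed = 1, P = 2)
  spec <- Mod(fft(ses$data[1, ]))[2:(T / 2)]
  freqs <- (1:(T / 2 - 1)) * fs / T
  expect_equal(freqs[which.max(spec)], 10)
  # amplitude of a unit sinusoid
  expect_equal(max(abs(ses$data[1, ])), 1, tolerance = 1e-3)

  # shared-phase channels are coherent at the component frequency
  ses2 <- gen_state_signals(rep(1L, T), fs,
                            list(list(state_component(10, 1:2))),
                            noise_sd = 0.05, seed = 2, P = 2)
  tc <- list(samples = seq_len(T))
  sp <- state_multitaper(ses2, tc, path = rep(1L, T))
  f10 <- which.min(abs(sp$freqs - 10))
  expect_gt(sp$coherence[1, 1, 2, f10], 0.95)

  # pure noise: flat-ish spectrum, low coherence everywhere (T = 60 s)
  ses3 <- gen_state_signals(rep(1L, T), fs, list(list()), noise_sd = 1,
                            seed = 3, P = 2)
  sp3 <- state_multitaper(ses3, tc, path = rep(1L, T))
  expect_lt(max(sp3$coherence[1, 1, 2, ]), 0.2)

  # super-Nyquist component rejected
  expect_error(
    gen_state_signals(rep(1L, 100), fs, list(list(state_component(130, 1))),
                      0, seed = 1),
    "Nyquist")
})

test_that("gen_replay_train is an MMPP with the stated rates", {
  T <- 150000
  fs <- 250  # 600 s
  # equal rates: homogeneous Poisson, Fano near 1 at 10 s (seed-averaged)
  f <- vapply(1:10, function(s) {
    path <- rep(1L, T)
    ev <- gen_replay_train(path, fs, 1L, 1, 1, seed = s)
    fano_curve(ev, T, fs, windows_s = 10)$fano
  }, numeric(1))
  expect_gte(mean(f), 0.7)
  expect_lte(mean(f), 1.3)

  # rate_out = 0: every event inside a coupled-state segment
  path <- gen_state_path(2, matrix(c(.99, .01, .01, .99), 2), T, seed = 5)
  ev <- gen_replay_train(path, fs, 1L, 3, 0, seed = 6)
  expect_true(all(path[ev] == 1L))

  # two-rate process is super-Poisson at 10 s windows
  path4 <- gen_state_path(4, default_transition(), T, seed = 7)
  ev4 <- gen_replay_train(path4, fs, c(1L, 2L), 3, 0.1, seed = 8)
  expect_gt(fano_curve(ev4, T, fs, windows_s = 10)$fano, 1)

  # degenerate configuration warns and returns an empty train
  expect_warning(out <- gen_replay_train(path, fs, integer(0), 1, 0,
                                         seed = 9),
                 "empty")
  expect_length(out, 0)
})

test_that("gen_localizer plants decodable stimulus patterns", {
  # noiseless limit: same-label trials identical at the peak sample
  loc0 <- gen_localizer(4, 16, 6, 250, snr = 1e6, seed = 1)
  peak <- which.min(abs(localizer_times(loc0) * 1000 - 200))
  same <- which(loc0$labels == 0L)
  expect_equal(loc0$trials[same[1], , peak] / loc0$trials[same[2], , peak],
               rep(1, 6), tolerance = 1e-4)

  # default-snr fixture is decodable well above chance (chance 0.125)
  loc <- gen_localizer(8, 160, 12, 250, snr = 1, seed = 2)
  acc <- replayburst:::cv_accuracy_at(
    loc, peak, 0.01, 5, rep(1:5, length.out = 160))
  expect_gt(acc, 0.5)

  # too few trials for cross-validation rejected
  expect_error(gen_localizer(8, 10, 12, 250, seed = 1), "cross-validation")
})

test_that("plant_reactivations adds pattern pairs at the planted lag", {
  T <- 5000
  fs <- 250
  ses <- recording_session(matrix(0, 4, T), fs)
  patt <- matrix(rnorm(8), 2, 4)
  pairs <- matrix(c(1L, 2L), 1)

  # gain 0 is the identity
  out0 <- plant_reactivations(ses, patt, c(100L), 40, pairs, gain = 0)
  expect_identical(out0$data, ses$data)

  # 40 ms at 250 Hz: successor exactly 10 samples later
  out <- plant_reactivations(ses, patt, c(100L), 40, pairs, gain = 1,
                             duration_ms = 4)
  expect_equal(out$data[, 100], patt[1, ])
  expect_equal(out$data[, 110], patt[2, ])
  expect_true(all(out$data[, 101:109] == 0))

  # known decoder picks the planted items up at the right samples
  clf <- structure(list(weights = patt, intercepts = c(0, 0),
                        training_time_ms = 200, l1_penalty = 0,
                        degenerate = c(FALSE, FALSE)),
                   class = "classifier_set")
  probs <- apply_classifiers(out, clf)
  expect_equal(which.max(probs$probs[1, ]), 100)
  expect_equal(which.max(probs$probs[2, ]), 110)
  expect_gt(probs$probs[1, 100], quantile(probs$probs[1, ], 0.99))

  # events too close to the end are dropped and logged
  expect_message(
    out2 <- plant_reactivations(ses, patt, c(100L, T - 2L), 40, pairs,
                                gain = 1),
    "dropped 1")
  expect_equal(attr(out2, "kept_events"), 100L)
  expect_equal(attr(out2, "dropped_events"), T - 2L)

  # non-integer lag rejected
  expect_error(plant_reactivations(ses, patt, c(100L), 3, pairs, 1),
               "integer number of samples")
})

test_that("plant_hf_bursts gates band-limited power on one state", {
  T <- 36000
  fs <- 600  # 60 s
  path <- rep(rep(1:2, each = 1800), 10)  # 3 s alternation
  ses <- recording_session(matrix(rnorm(T, sd = 0.5), 1, T), fs)

  # zero burst SD is the identity
  expect_identical(plant_hf_bursts(ses, path, 2L, c(102, 148), 0, seed = 1),
                   ses)

  out <- plant_hf_bursts(ses, path, 2L, c(102, 148), 1, seed = 1)
  tc <- list(samples = seq_len(T))
  sp <- state_multitaper(out, tc, path = path, band = c(60, 180))
  band <- sp$freqs >= 102 & sp$freqs <= 148
  gap_db <- 10 * (log10(mean(sp$psd[2, 1, band])) -
                    log10(mean(sp$psd[1, 1, band])))
  expect_gt(gap_db, 3)

  # band at or beyond Nyquist rejected
  expect_error(plant_hf_bursts(ses, path, 2L, c(102, 300), 1, seed = 1),
               "Nyquist")
})

test_that("fixtures are deterministic and preserve ground truth", {
  cf <- default_sim_config()
  cf$duration_s <- 20
  a <- suppressMessages(simulate_subject(7, cf))
  b <- suppressMessages(simulate_subject(7, cf))
  expect_identical(a$session$data, b$session$data)
  expect_identical(a$truth$replay_times, b$truth$replay_times)
  expect_identical(a$wideband$data, b$wideband$data)

  # composed fixture keeps component truths coherent
  expect_true(all(a$truth$state_path %in% 1:cf$K))
  expect_true(!is.unsorted(a$truth$replay_times, strictly = TRUE))
  expect_equal(a$truth$replay_lag_ms, cf$lag_ms)
  expect_equal(a$truth$coupled_states, cf$coupled_states)
})

test_that("per-state embedded covariance is stationary over long T", {
  T <- 250000
  fs <- 250
  Th <- matrix(c(.995, .005, .005, .995), 2)
  path <- gen_state_path(2, Th, T, seed = 3)
  spec <- list(list(state_component(5, 1)), list(state_component(25, 1)))
  ses <- gen_state_signals(path, fs, spec, noise_sd = 0.5, seed = 4, P = 3)
  emb <- embed_session(ses, 3, center = FALSE)
  half <- ncol(emb$x) %/% 2
  for (k in 1:2) {
    i1 <- which(path[emb$samples[1:half]] == k)
    i2 <- half + which(path[emb$samples[(half + 1):ncol(emb$x)]] == k)
    C1 <- tcrossprod(emb$x[, i1]) / length(i1)
    C2 <- tcrossprod(emb$x[, i2]) / length(i2)
    expect_lt(norm(C1 - C2, "F") / norm(C1, "F"), 0.05)
  }
})
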