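test_that("dpss tapers are orthonormal and band-concentrated", {
  n <- 500
  tap <- dpss_tapers(n, 4, 7)
  expect_equal(crossprod(tap), diag(7), tolerance = 1e-10)
  # leading taper concentrates its energy inside |f| <= NW/n
  h <- Mod(fft(c(tap[, 1], rep(0, 7 * n))))^2
  freqs <- seq(0, 1, length.out = 8 * n + 1)[1:(8 * n)]
  inband <- freqs <= 4 / n | freqs >= 1 - 4 / n
  expect_gt(sum(h[inband]) / sum(h), 0.999)
})

test_that("state_multitaper recovers planted spectra and coherence", {
  T <- 60000
  fs <- 250
  tc <- list(samples = seq_len(T))
  # a pure noiseless tone peaks exactly on its bin (periodogram oracle
  # agrees by construction of the grid)
  tone <- gen_state_signals(rep(1L, T), fs,
                            list(list(state_component(10, 1))), 0,
                            seed = 40, P = 1)
  sp_t <- state_multitaper(tone, tc, path = rep(1L, T))
  expect_equal(sp_t$freqs[which.max(sp_t$psd[1, 1, ])], 10)

  path <- gen_state_path(2, matrix(c(.9995, .0005, .0005, .9995), 2), T,
                         seed = 41)
  spec <- list(list(state_component(5, 1:2)),
               list(state_component(25, 1:2)))
  ses <- gen_state_signals(path, fs, spec, noise_sd = 0.3, seed = 42,
                           P = 3)
  sp <- state_multitaper(ses, tc, path = path)

  # per-state psd peaks at the planted frequencies to within one 0.5 Hz
  # bin (the 7-taper NW=4 spectral window is ~flat over +-2 Hz, so in
  # noise the argmax wobbles within the bandwidth by design)
  expect_lte(abs(sp$freqs[which.max(sp$psd[1, 1, ])] - 5), 0.5)
  expect_lte(abs(sp$freqs[which.max(sp$psd[2, 1, ])] - 25), 0.5)
  expect_equal(sp$params$resolution_Hz, 0.5)

  # coherence bounds, symmetry, unit diagonal
  expect_true(all(sp$coherence >= 0 & sp$coherence <= 1 + 1e-9,
                  na.rm = TRUE))
  expect_equal(sp$coherence[1, 1, 2, ], sp$coherence[1, 2, 1, ])
  expect_equal(max(abs(sp$coherence[1, 1, 1, ] - 1)), 0, tolerance = 1e-9)

  # identical channels: coherence 1 at every bin
  ses_id <- recording_session(rbind(ses$data[1, ], ses$data[1, ]), fs)
  sp_id <- state_multitaper(ses_id, tc, path = rep(1L, T))
  expect_equal(sp_id$coherence[1, 1, 2, ], rep(1, length(sp_id$freqs)),
               tolerance = 1e-9)

  # a state with no complete window yields NaN spectra and a message
  path_short <- c(rep(1L, T - 100), rep(2L, 100))
  expect_message(sp_s <- state_multitaper(ses, tc, path = path_short),
                 "no complete")
  expect_true(all(is.nan(sp_s$psd[2, , ])))

  expect_error(state_multitaper(ses, tc, band = c(1, 200), path = path),
               "band")
})

test_that("multitaper satisfies Parseval on white noise", {
  T <- 50000
  fs <- 250
  ses <- recording_session(matrix(rnorm(T), 1), fs)
  tc <- list(samples = seq_len(T))
  sp <- state_multitaper(ses, tc, path = rep(1L, T), band = c(0.5, 124.5))
  integ <- sum(sp$psd[1, 1, ]) * sp$params$resolution_Hz
  expect_lt(abs(integ - var(ses$data[1, ])) / var(ses$data[1, ]), 0.1)
})

test_that("nnmf_modes isolates planted frequency bands", {
  # rank-1 nonnegative input reconstructs nearly exactly
  set.seed(43)
  K <- 2; P <- 3; Fb <- 50
  w <- runif(K * P + K * P * (P - 1) / 2, 0.5, 1)
  h <- runif(Fb, 0.1, 1)
  sp1 <- structure(list(
    psd = array(outer(w[1:(K * P)], h), dim = c(K, P, Fb)),
    coherence = array(0.5, dim = c(K, P, P, Fb)),
    freqs = seq(1, 45, length.out = Fb)), class = "state_spectra")
  # make coherence rows rank-1 with the same spectral profile
  for (k in 1:K) for (p in 1:P) for (q in 1:P)
    sp1$coherence[k, p, q, ] <- 0.8 * h
  nm1 <- nnmf_modes(sp1, 1, n_restarts = 3, seed = 1)
  V <- rbind(matrix(sp1$psd, K * P, Fb),
             matrix(0.8 * h, K * P * (P - 1) / 2, Fb, byrow = TRUE))
  err <- tail(nm1$err_trace, 1) / sqrt(sum(V^2))
  expect_lt(err, 1e-6)
  # objective non-increasing
  expect_true(all(diff(nm1$err_trace) <= 1e-10))

  # two planted disjoint bands separate into two modes (> 80% mass each);
  # moderate noise is part of the design: with near-noiseless channels,
  # spectral sidelobes shared between channels keep coherence high far
  # outside the planted band
  T <- 60000
  path <- gen_state_path(2, matrix(c(.9995, .0005, .0005, .9995), 2), T,
                         seed = 44)
  spec <- list(list(state_component(5, 1:2)),
               list(state_component(25, 1:2)))
  ses <- gen_state_signals(path, 250, spec, noise_sd = 0.3, seed = 45,
                           P = 3)
  sp <- state_multitaper(ses, list(samples = seq_len(T)), path = path)
  nm <- nnmf_modes(sp, 2, seed = 2)
  low <- sp$freqs >= 3 & sp$freqs <= 7
  high <- sp$freqs >= 23 & sp$freqs <= 27
  expect_gt(sum(nm$mode_weights[1, low]), 0.8)
  expect_gt(sum(nm$mode_weights[2, high]), 0.8)

  # three bands: centroids come out sorted low/mid/high
  spec3 <- list(list(state_component(3, 1)), list(state_component(10, 1)),
                list(state_component(25, 1)))
  path3 <- gen_state_path(3, matrix(c(.9995, .00025, .00025,
                                      .00025, .9995, .00025,
                                      .00025, .00025, .9995), 3,
                                    byrow = TRUE),
                          T, seed = 46)
  ses3 <- gen_state_signals(path3, 250, spec3, noise_sd = 0.3, seed = 47,
                            P = 2)
  sp3 <- state_multitaper(ses3, list(samples = seq_len(T)), path = path3)
  nm3 <- nnmf_modes(sp3, 3, seed = 3)
  cent <- as.numeric(nm3$mode_weights %*% sp3$freqs)
  expect_true(!is.unsorted(cent))
  expect_lt(cent[1], 8)
  expect_gt(cent[3], 18)

  # negative inputs rejected
  spn <- sp1
  spn$psd[1] <- -1
  expect_error(nnmf_modes(spn, 1), "negative")
})

test_that("evoked_timefreq weights state spectra by evoked probabilities", {
  K <- 3; P <- 2; Fb <- 10; L <- 5; N <- 2
  psd <- array(rep(1:K, P * Fb), dim = c(K, P, Fb))
  coh <- array(0.5, dim = c(K, P, P, Fb))
  sp <- structure(list(psd = psd, coherence = coh,
                       freqs = seq_len(Fb)), class = "state_spectra")
  # one-hot weights select state 2's spectrum at every lag
  B <- array(0, dim = c(K, L, N))
  B[2, , ] <- 1
  ev <- structure(list(values = B, lags = seq_len(L) - 3,
                       baseline_corrected = FALSE),
                  class = "evoked_response")
  tf <- evoked_timefreq(ev, sp)
  expect_equal(tf$psd_tf, matrix(2, L, Fb))

  # uniform weights give the unweighted state mean
  Bu <- array(1 / K, dim = c(K, L, N))
  evu <- structure(list(values = Bu, lags = seq_len(L) - 3,
                        baseline_corrected = FALSE),
                   class = "evoked_response")
  tfu <- evoked_timefreq(evu, sp)
  expect_equal(tfu$psd_tf, matrix(2, L, Fb))

  # baseline-corrected input rejected
  evb <- ev
  evb$values <- ev$values - 1 / K
  expect_error(evoked_timefreq(evb, sp), "sum to 1")
})

test_that("gmm_threshold separates bimodal maps and rejects unimodal ones", {
  set.seed(48)
  lo <- rnorm(100, 0, 0.1)
  hi <- rnorm(100, 5, 0.1)
  mask <- gmm_threshold(c(lo, hi))
  expect_equal(as.logical(mask), rep(c(FALSE, TRUE), each = 100))
  expect_true(attr(mask, "separated"))

  # unimodal: no separated component, empty mask
  uni <- rnorm(200)
  mask_u <- gmm_threshold(uni)
  expect_false(any(mask_u))

  expect_error(gmm_threshold(c(1, 2)), "at least 20")
  expect_warning(mask_c <- gmm_threshold(rep(1, 30)), "constant")
  expect_false(any(mask_c))
})

test_that("high-frequency analyses find planted bursts", {
  fs <- 600
  T <- 120 * fs
  # long alternating visits so 2 s windows exist
  path <- rep(rep(1:2, each = 3 * fs), length.out = T)
  ses <- recording_session(matrix(rnorm(2 * T, sd = 0.5), 2), fs)
  ses <- plant_hf_bursts(ses, path, 2L, c(102, 148), 1, seed = 49,
                         channels = 1L)
  hf <- hf_state_psd(ses, path)
  band <- hf$freqs >= 102 & hf$freqs <= 148
  gap <- 10 * diff(log10(rowMeans(hf$mean_psd[, band])))
  expect_gt(gap, 3)

  # without bursts the states match within 1 dB
  ses0 <- recording_session(matrix(rnorm(2 * T, sd = 0.5), 2), fs)
  hf0 <- hf_state_psd(ses0, path)
  gap0 <- 10 * abs(diff(log10(rowMeans(hf0$mean_psd[, band]))))
  expect_lt(gap0, 1)

  expect_error(hf_state_psd(ses, path, band = c(1, 400)), "Nyquist")
  expect_error(hf_state_psd(ses, path[-1]), "length")

  # replay-evoked PSD: events inside bursts beat the shuffled baseline
  set.seed(53)
  sessions <- list(ses, ses)
  ev_in <- lapply(1:2, function(i) {
    on <- which(path == 2L)
    sort(sample(on[on > 20 & on < T - 20], 80))
  })
  hr <- hf_replay_psd(sessions, ev_in, seed = 50)
  # 30 ms at 600 Hz: 18-sample windows, ~33 Hz resolution documented
  expect_equal(hr$resolution_Hz, fs / 18, tolerance = 1e-9)
  b2 <- hr$freqs >= 102 & hr$freqs <= 148
  # baseline here is drawn from the same bursty trains, so compare
  # against events placed outside bursts instead
  ev_out <- lapply(1:2, function(i) {
    off <- which(path == 1L)
    sort(sample(off[off > 20 & off < T - 20], 80))
  })
  hr_out <- hf_replay_psd(sessions, ev_out, seed = 51)
  expect_gt(mean(hr$evoked_psd[b2]), 2 * mean(hr_out$evoked_psd[b2]))

  # events with no HF structure match their baseline within noise
  ses_n <- recording_session(matrix(rnorm(T, sd = 0.5), 1), fs)
  ev_r <- lapply(1:2, function(i) sort(sample(100:(T - 100), 100)))
  hr_n <- hf_replay_psd(list(ses_n, ses_n), ev_r, seed = 52)
  expect_lt(abs(mean(hr_n$evoked_psd[b2]) / mean(hr_n$baseline_psd[b2]) - 1),
            0.2)
})
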