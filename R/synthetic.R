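#' Sample a Markov state path
#'
#' @param K number of states (>= 2).
#' @param transition K x K row-stochastic matrix.
#' @param T number of samples to draw.
#' @param seed RNG seed.
#' @param start optional fixed initial state; default: drawn from the
#'   stationary distribution (power iteration).
#' @return Integer vector of length `T` with values in `1:K`.
#' @export
gen_state_path <- function(K, transition, T, seed, start = NULL) {
  transition <- as.matrix(transition)
  if (K < 2L) stop("K must be >= 2")
  if (!all(dim(transition) == c(K, K)))
    stop("transition must be K x K")
  rs <- rowSums(transition)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad))
    stop(sprintf("transition row %d sums to %.12g, not 1", bad[1], rs[bad[1]]))
  if (any(transition < 0)) stop("transition has negative entries")
  set.seed(seed)
  if (is.null(start)) {
    pi0 <- rep(1 / K, K)
    for (i in 1:200) pi0 <- as.numeric(pi0 %*% transition)
    start <- sample.int(K, 1L, prob = pi0)
  }
  cum <- t(apply(transition, 1L, cumsum))
  .markov_path(cum, as.integer(start), runif(T - 1L))
}

#' Per-state oscillatory component specification
#'
#' Helper constructing one entry of the per-state component list used by
#' [gen_state_signals()].
#'
#' @param freq oscillation frequency (Hz).
#' @param channels 1-based channel indices carrying the component.
#' @param amplitude peak amplitude (signal units).
#' @param shared_phase if `TRUE` all listed channels are driven by one
#'   phase-randomized oscillator (mutually coherent); if `FALSE` each
#'   channel gets an independent random-walk phase (incoherent).
#' @export
state_component <- function(freq, channels, amplitude = 1,
                            shared_phase = TRUE) {
  list(freq = freq, channels = as.integer(channels),
       amplitude = amplitude, shared_phase = isTRUE(shared_phase))
}

#' Generate state-gated oscillatory signals
#'
#' Emulates K spectrally distinct states: during state k's samples, the
#' listed channels carry the listed oscillations, with white noise added
#' everywhere. Shared-phase channels are drawn from a single oscillator
#' with one random initial phase and so are coherent at the component
#' frequency; non-shared channels carry independent slow phase walks.
#'
#' @param state_path integer state path (1-based).
#' @param fs sampling rate (Hz).
#' @param spec list of length K; element k is a list of components built
#'   with [state_component()] (possibly empty).
#' @param noise_sd standard deviation of the additive white noise.
#' @param seed RNG seed.
#' @param P number of channels; default: largest channel index in `spec`.
#' @return A [recording_session()].
#' @export
gen_state_signals <- function(state_path, fs, spec, noise_sd, seed,
                              P = NULL) {
  K <- length(spec)
  T <- length(state_path)
  chans <- unlist(lapply(spec, function(s) lapply(s, `[[`, "channels")))
  if (is.null(P)) P <- max(c(1L, chans))
  for (k in seq_len(K)) for (cmp in spec[[k]]) {
    if (cmp$freq >= fs / 2)
      stop(sprintf("component frequency %g Hz >= Nyquist (%g Hz)",
                   cmp$freq, fs / 2))
  }
  set.seed(seed)
  X <- matrix(rnorm(P * T, sd = noise_sd), nrow = P)
  tt <- (seq_len(T) - 1L) / fs
  for (k in seq_len(K)) {
    mask <- as.numeric(state_path == k)
    for (cmp in spec[[k]]) {
      if (cmp$shared_phase) {
        osc <- cmp$amplitude * sin(2 * pi * cmp$freq * tt + runif(1) * 2 * pi)
        for (ch in cmp$channels) X[ch, ] <- X[ch, ] + osc * mask
      } else {
        for (ch in cmp$channels) {
          phase <- runif(1) * 2 * pi + cumsum(rnorm(T, sd = 0.1))
          osc <- cmp$amplitude * sin(2 * pi * cmp$freq * tt + phase)
          X[ch, ] <- X[ch, ] + osc * mask
        }
      }
    }
  }
  recording_session(X, fs)
}

#' Generate a Markov-modulated Poisson replay event train
#'
#' Events are drawn from an inhomogeneous Poisson process with intensity
#' `rate_in` while the state path is in a coupled state and `rate_out`
#' otherwise (Bernoulli thinning at one event per sample; rates must be
#' well below `fs`). With `rate_in == rate_out` the train is homogeneous
#' Poisson.
#'
#' @param state_path integer state path (1-based).
#' @param fs sampling rate (Hz).
#' @param coupled_states state indices with elevated rate.
#' @param rate_in,rate_out event rates (Hz), `rate_in >= rate_out >= 0`.
#' @param seed RNG seed.
#' @return Integer vector of event sample indices (1-based, increasing).
#' @export
gen_replay_train <- function(state_path, fs, coupled_states, rate_in,
                             rate_out, seed) {
  if (rate_out < 0 || rate_in < rate_out)
    stop("need rate_in >= rate_out >= 0")
  if (rate_in >= fs) stop("rate_in must be well below fs")
  if (length(coupled_states) == 0L && rate_out == 0) {
    warning("empty coupled_states with rate_out = 0: empty event train")
    return(integer(0))
  }
  set.seed(seed)
  p <- ifelse(state_path %in% coupled_states, rate_in, rate_out) / fs
  which(runif(length(state_path)) < p)
}

#' Generate functional localizer trials
#'
#' Each stimulus has a fixed random spatial pattern whose amplitude
#' follows a Gaussian temporal envelope peaking at `peak_ms`; white noise
#' of unit SD is added, so `snr` is the peak pattern amplitude relative to
#' the noise SD.
#'
#' @param S number of stimuli (>= 2).
#' @param n_trials total trials (>= 2 S; balanced across stimuli).
#' @param P number of channels.
#' @param fs sampling rate (Hz).
#' @param peri_ms length-2 window (ms) relative to stimulus onset.
#' @param peak_ms envelope peak time (ms), inside `peri_ms`.
#' @param snr peak signal-to-noise amplitude ratio.
#' @param seed RNG seed.
#' @param envelope_sd_ms envelope width (ms).
#' @return A [localizer_trials()] whose `patterns` field holds the S x P
#'   planted patterns.
#' @export
gen_localizer <- function(S, n_trials, P, fs, peri_ms = c(0, 400),
                          peak_ms = 200, snr = 1, seed = 1,
                          envelope_sd_ms = 50) {
  if (S < 2L) stop("need at least 2 stimuli")
  if (peak_ms < peri_ms[1] || peak_ms > peri_ms[2])
    stop("peak_ms outside the peri-stimulus window")
  if (n_trials < 2L * S)
    stop("n_trials < 2*S: cross-validation impossible")
  set.seed(seed)
  patterns <- matrix(rnorm(S * P), nrow = S)
  times_ms <- seq(peri_ms[1], peri_ms[2], by = 1000 / fs)
  L <- length(times_ms)
  env <- exp(-(times_ms - peak_ms)^2 / (2 * envelope_sd_ms^2))
  labels <- sample(rep(seq_len(S) - 1L, length.out = n_trials))
  trials <- array(rnorm(n_trials * P * L), dim = c(n_trials, P, L))
  for (i in seq_len(n_trials)) {
    trials[i, , ] <- trials[i, , ] +
      snr * outer(patterns[labels[i] + 1L, ], env)
  }
  localizer_trials(trials, labels, fs, t0_offset = peri_ms[1] / 1000,
                   patterns = patterns)
}

#' Plant pairwise sequential reactivations into a session
#'
#' At each event time t a stimulus pattern is added for `duration_ms`,
#' and its task successor is added starting at t + `lag_ms`. Events too
#' close to the end of the recording to fit the full sequence are dropped
#' (with a message).
#'
#' @param session a [recording_session()].
#' @param patterns S x P matrix of stimulus spatial patterns.
#' @param replay_train event onset sample indices.
#' @param lag_ms inter-item lag (ms); must be an integer number of samples
#'   at the session sampling rate.
#' @param pairs 2-column matrix of ordered stimulus index pairs (1-based);
#'   one pair is drawn at random per event.
#' @param gain pattern amplitude multiplier; `gain = 0` returns the input
#'   unchanged.
#' @param duration_ms duration each pattern stays on (default `lag_ms`;
#'   the fixture default is 12 ms, short enough that the 99th-percentile
#'   sample budget spans most planted events).
#' @param seed RNG seed for the per-event pair choice.
#' @return The session with patterns added. Attributes `kept_events`,
#'   `dropped_events` and `event_pairs` record what was planted.
#' @export
plant_reactivations <- function(session, patterns, replay_train, lag_ms,
                                pairs, gain, duration_ms = lag_ms,
                                seed = 1) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$fs
  lag_exact <- lag_ms * fs / 1000
  if (abs(lag_exact - round(lag_exact)) > 1e-9)
    stop(sprintf("lag %g ms is not an integer number of samples at %g Hz",
                 lag_ms, fs))
  lag <- as.integer(round(lag_exact))
  dur <- max(1L, ms_to_samples(duration_ms, fs))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  T <- ncol(session$data)
  set.seed(seed)
  pick <- sample.int(nrow(pairs), length(replay_train), replace = TRUE)
  keep <- replay_train + lag + dur - 1L <= T
  if (any(!keep))
    message(sprintf("plant_reactivations: dropped %d event(s) too close to the recording end",
                    sum(!keep)))
  kept <- replay_train[keep]
  if (gain != 0) {
    for (e in seq_along(kept)) {
      t0 <- kept[e]
      pr <- pairs[pick[keep][e], ]
      idx1 <- t0:(t0 + dur - 1L)
      idx2 <- (t0 + lag):(t0 + lag + dur - 1L)
      session$data[, idx1] <- session$data[, idx1] + gain * patterns[pr[1], ]
      session$data[, idx2] <- session$data[, idx2] + gain * patterns[pr[2], ]
    }
  }
  attr(session, "kept_events") <- kept
  attr(session, "dropped_events") <- replay_train[!keep]
  attr(session, "event_pairs") <- pairs[pick[keep], , drop = FALSE]
  session
}

#' Plant band-limited high-frequency bursts
#'
#' Adds band-limited Gaussian noise to the listed channels only during
#' samples assigned to `hf_state`, emulating broadband high-frequency
#' power bursts tied to one state.
#'
#' @param session wideband [recording_session()] at the high sampling
#'   rate.
#' @param state_path state path resampled to the session's rate.
#' @param hf_state state carrying the bursts.
#' @param band length-2 frequency band (Hz); upper edge must be below
#'   Nyquist.
#' @param burst_sd SD of the band-limited noise; 0 returns the input.
#' @param seed RNG seed.
#' @param channels channels receiving bursts (default: all).
#' @return The session with bursts added.
#' @export
plant_hf_bursts <- function(session, state_path, hf_state, band, burst_sd,
                            seed, channels = NULL) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$fs
  T <- ncol(session$data)
  if (length(state_path) != T)
    stop("state_path length does not match the session")
  if (band[2] >= fs / 2)
    stop(sprintf("band upper edge %g Hz >= Nyquist (%g Hz)", band[2], fs / 2))
  if (band[1] < 45 && band[2] > 1)
    warning("HF band overlaps the 1-45 Hz analysis band; this will contaminate state estimation")
  if (burst_sd == 0) return(session)
  if (is.null(channels)) channels <- seq_len(nrow(session$data))
  set.seed(seed)
  mask <- as.numeric(state_path == hf_state)
  freqs <- (seq_len(T) - 1L) * fs / T
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  keepbin <- freqs >= band[1] & freqs <= band[2]
  for (ch in channels) {
    w <- rnorm(T)
    wf <- fft(w)
    wf[!keepbin] <- 0
    bl <- Re(fft(wf, inverse = TRUE)) / T
    bl <- bl / sd(bl) * burst_sd
    session$data[ch, ] <- session$data[ch, ] + bl * mask
  }
  session
}

#' Default fixture configuration
#'
#' The stated world of the synthetic fixtures: 21 virtual subjects, 300 s
#' at 250 Hz (plus a 600 Hz wideband twin), 12 channels, K = 4 states
#' with sticky Markov switching, two replay-coupled states carrying
#' alpha (10 Hz) and delta (3 Hz) coherent oscillations, a beta (25 Hz)
#' state and a background state, pairwise sequential reactivations at a
#' 40 ms lag generated by a two-rate Markov-modulated Poisson process
#' (3 Hz in coupled states, 0.1 Hz elsewhere), and 102-148 Hz bursts on
#' the delta state's channels.
#'
#' @return A named list of generator parameters.
#' @export
default_sim_config <- function() {
  list(
    n_subjects = 21L, duration_s = 300, fs = 250, fs_hi = 600,
    n_channels = 12L, K = 4L,
    n_stimuli = 8L, n_trials = 160L, peri_ms = c(0, 400), peak_ms = 200,
    snr = 1, noise_sd = 0.5,
    lag_ms = 40, rate_in = 3, rate_out = 0.1,
    coupled_states = c(1L, 2L), gain = 3, pattern_ms = 12,
    hf_state = 2L, hf_band = c(102, 148), hf_burst_sd = 1,
    n_bad_segments = 2L, bad_segment_s = 1
  )
}

#' Default per-state component specification
#' @param P number of channels (>= 12 for the default layout).
#' @param K number of states.
#' @return A list usable as the `spec` argument of [gen_state_signals()].
#' @export
default_state_spec <- function(P = 12L, K = 4L) {
  stopifnot(P >= 12L, K >= 4L)
  spec <- rep(list(list()), K)
  spec[[1]] <- list(state_component(10, 1:4, amplitude = 1.6))  # parietal-alpha analogue
  spec[[2]] <- list(state_component(3, 5:8, amplitude = 1.6))   # DMN/delta analogue
  spec[[3]] <- list(state_component(25, 9:12, amplitude = 1.6)) # beta analogue
  spec
}

#' Default sticky transition matrix
#'
#' States 1-2 (replay-coupled) have ~2 s mean visit lifetimes and rare
#' entry (long intervals between visits); states 3-4 are background
#' states with ~0.8 s lifetimes. Stationary occupancy of the coupled
#' pair is 25%, and coupled bouts last ~3 s so replay clusters over
#' multi-second timescales. Lifetimes are long enough that every state
#' accrues complete 2 s multitaper windows.
#'
#' @param K number of states (must be 4 for the default layout).
#' @export
default_transition <- function(K = 4L) {
  stopifnot(K == 4L)
  matrix(c(0.9980, 0.0008, 0.0006, 0.0006,
           0.0008, 0.9980, 0.0006, 0.0006,
           0.0002, 0.0002, 0.9950, 0.0046,
           0.0002, 0.0002, 0.0046, 0.9950),
         nrow = 4L, byrow = TRUE)
}

#' Task sequence chains for the default fixture
#'
#' Two ordered 4-item chains over the 8 stimuli; consecutive pairs within
#' each chain are the task-ordered pairs.
#' @return list with elements `chains` (list of two integer vectors) and
#'   `pairs` (6 x 2 matrix of ordered task pairs).
#' @export
default_sequences <- function() {
  chains <- list(1:4, 5:8)
  pairs <- do.call(rbind, lapply(chains, function(ch)
    cbind(ch[-length(ch)], ch[-1])))
  list(chains = chains, pairs = pairs)
}

# plant n_seg random bad segments of seg_s seconds into a mask of length T
plant_bad_mask <- function(T, fs, n_seg, seg_s, seed) {
  mask <- rep(FALSE, T)
  if (n_seg < 1L) return(mask)
  set.seed(seed)
  len <- round(seg_s * fs)
  starts <- sort(sample.int(T - len, n_seg))
  for (s in starts) mask[s:(s + len - 1L)] <- TRUE
  mask
}

# map a state path to a different sampling rate by nearest-sample lookup
resample_path <- function(path, fs_from, fs_to,
                          T_to = round(length(path) * fs_to / fs_from)) {
  idx <- pmin(length(path), floor((seq_len(T_to) - 1L) * fs_from / fs_to) + 1L)
  path[idx]
}

#' Simulate one virtual subject
#'
#' Composes the full fixture for one subject: Markov state path,
#' state-gated oscillatory resting recording (250 Hz) with bad segments,
#' a localizer, planted sequential reactivations whose event times follow
#' a Markov-modulated Poisson process coupled to the designated states,
#' and a 600 Hz wideband twin with high-frequency bursts on the
#' designated state.
#'
#' @param seed subject seed (per-subject seeds are derived as
#'   `base_seed + subject_index` by [run_all()]).
#' @param config parameter list as from [default_sim_config()].
#' @return list with elements `session`, `wideband`, `localizer`, `truth`.
#' @export
simulate_subject <- function(seed, config = default_sim_config()) {
  cf <- config
  T <- round(cf$duration_s * cf$fs)
  trans <- default_transition(cf$K)
  path <- gen_state_path(cf$K, trans, T, seed = sub_seed(seed, 1))
  spec <- default_state_spec(cf$n_channels, cf$K)
  session <- gen_state_signals(path, cf$fs, spec, cf$noise_sd,
                               seed = sub_seed(seed, 2), P = cf$n_channels)
  session$bad_mask <- plant_bad_mask(T, cf$fs, cf$n_bad_segments,
                                     cf$bad_segment_s,
                                     seed = sub_seed(seed, 3))
  loc <- gen_localizer(cf$n_stimuli, cf$n_trials, cf$n_channels, cf$fs,
                       cf$peri_ms, cf$peak_ms, cf$snr,
                       seed = sub_seed(seed, 4))
  train <- gen_replay_train(path, cf$fs, cf$coupled_states, cf$rate_in,
                            cf$rate_out, seed = sub_seed(seed, 5))
  seqs <- default_sequences()
  session <- plant_reactivations(session, loc$patterns, train, cf$lag_ms,
                                 seqs$pairs, cf$gain,
                                 duration_ms = cf$pattern_ms %||% cf$lag_ms,
                                 seed = sub_seed(seed, 6))
  kept <- attr(session, "kept_events")
  truth <- ground_truth(path, kept, cf$lag_ms, cf$coupled_states,
                        cf$hf_state)

  T_hi <- round(cf$duration_s * cf$fs_hi)
  path_hi <- resample_path(path, cf$fs, cf$fs_hi, T_hi)
  set.seed(sub_seed(seed, 8))
  wb <- recording_session(
    matrix(rnorm(cf$n_channels * T_hi, sd = cf$noise_sd),
           nrow = cf$n_channels), cf$fs_hi)
  # reuse the subject's bad segments, resampled
  wb$bad_mask <- resample_path(as.integer(session$bad_mask), cf$fs,
                               cf$fs_hi, T_hi) > 0
  wb <- plant_hf_bursts(wb, path_hi, cf$hf_state, cf$hf_band,
                        cf$hf_burst_sd, seed = sub_seed(seed, 7),
                        channels = 5:8)
  list(session = session, wideband = wb, localizer = loc, truth = truth)
}
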