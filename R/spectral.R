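#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed via the eigenvectors of the standard symmetric tridiagonal
#' matrix whose eigenvectors coincide with the DPSS; tapers are returned
#' with unit energy, polarized so that each taper's leading lobe is
#' positive.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers (`k <= 2 nw - 1` is recommended).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, k >= 1, nw > 0)
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  eig <- eigen(A, symmetric = TRUE)
  tap <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    # conventional polarity: symmetric tapers have positive mean,
    # antisymmetric ones a positive initial slope
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) {
      tap[, j] <- -tap[, j]
    }
  }
  tap
}

# Multitaper cross-spectra of complete non-overlapping windows.
# data: P x T; windows: integer vector of window start samples; n: window
# length. Returns list(psd [P x F], csd [F x P x P] complex averaged over
# windows and tapers, freqs). One-sided density scaling (x2/fs).
mtaper_windows <- function(data, fs, window_starts, n, tapers, freq_idx) {
  P <- nrow(data)
  Fb <- length(freq_idx)
  M <- ncol(tapers)
  nfft <- nrow(tapers)  # tapers zero-padded to nfft when oversampling
  pi_ <- rep(seq_len(P), times = P)
  pj_ <- rep(seq_len(P), each = P)
  acc <- matrix(0 + 0i, Fb, P * P)
  pad <- if (nfft > n) matrix(0, nfft - n, P) else NULL
  nwin <- 0L
  for (s in window_starts) {
    Y <- data[, s:(s + n - 1L), drop = FALSE]
    Yt <- t(Y - rowMeans(Y))
    if (!is.null(pad)) Yt <- rbind(Yt, pad)
    for (m in seq_len(M)) {
      Z <- stats::mvfft(tapers[, m] * Yt)  # nfft x P
      Zb <- Z[freq_idx, , drop = FALSE]
      acc <- acc + Conj(Zb[, pi_, drop = FALSE]) * Zb[, pj_, drop = FALSE]
    }
    nwin <- nwin + 1L
  }
  if (nwin == 0L) return(NULL)
  acc <- acc * 2 / fs / (M * nwin)
  csd <- array(acc, dim = c(Fb, P, P))
  psd <- matrix(0, P, Fb)
  for (p in seq_len(P)) psd[p, ] <- Re(csd[, p, p])
  list(psd = psd, csd = csd, n_windows = nwin)
}

# cut the maximal runs of each state (inside good contiguous stretches)
# into complete non-overlapping windows; returns per-state window starts
state_window_starts <- function(path, samples, n) {
  K <- max(path)
  segs <- segment_columns(samples)
  out <- rep(list(integer(0)), K)
  for (seg in segs) {
    idx <- seg[1]:seg[2]
    r <- rle(path[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      len <- r$lengths[i]
      if (len >= n) {
        nw <- len %/% n
        st <- samples[idx[starts[i]]] + (seq_len(nw) - 1L) * n
        k <- r$values[i]
        out[[k]] <- c(out[[k]], st)
      }
    }
  }
  out
}

#' State-conditioned multitaper power and coherence
#'
#' Hard-assigned contiguous state visits (Viterbi path) are cut into
#' complete non-overlapping windows; Slepian multitaper cross-spectra are
#' averaged over each state's windows. Coherence is
#' `|S_xy|^2 / (S_xx S_yy)`.
#'
#' @param session a [recording_session()].
#' @param tc a `state_timecourse` aligned to the session.
#' @param window_s taper window length (s); default 2.
#' @param n_tapers number of Slepian tapers; default 7.
#' @param resolution_Hz frequency grid spacing; default 0.5 Hz (zero-pads
#'   if finer than `1/window_s`).
#' @param band analysis band (Hz); default `c(1, 45)`.
#' @param nw time-bandwidth product; default 4 (so 7 tapers span a 2 Hz
#'   half-bandwidth with a 2 s window).
#' @param path optional hard state path per valid sample (overrides the
#'   Viterbi path, e.g. a ground-truth path).
#' @return Object of class `state_spectra`: `psd` `[K x P x F]`,
#'   `coherence` `[K x P x P x F]`, `freqs`, `n_windows`, `params`.
#'   States with no complete window get `NaN` spectra (with a message).
#' @export
state_multitaper <- function(session, tc, window_s = 2, n_tapers = 7,
                             resolution_Hz = 0.5, band = c(1, 45),
                             nw = 4, path = NULL) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$fs
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop(sprintf("band must lie within (0, %g) Hz", fs / 2))
  n <- round(window_s * fs)
  nfft <- max(n, round(fs / resolution_Hz))
  if (is.null(path)) {
    stopifnot(inherits(tc, "state_timecourse"))
    path <- tc$viterbi
    samples <- tc$samples
  } else {
    samples <- tc$samples
    stopifnot(length(path) == length(samples))
  }
  K <- max(path)
  tapers <- dpss_tapers(n, nw, n_tapers)
  if (nfft > n) tapers <- rbind(tapers, matrix(0, nfft - n, n_tapers))
  freqs_all <- (seq_len(nfft) - 1L) * fs / nfft
  freq_idx <- which(freqs_all >= band[1] & freqs_all <= band[2])
  freqs <- freqs_all[freq_idx]
  Fb <- length(freqs)
  P <- nrow(session$data)
  psd <- array(NaN, dim = c(K, P, Fb))
  coh <- array(NaN, dim = c(K, P, P, Fb))
  n_windows <- integer(K)
  starts <- state_window_starts(path, samples, n)
  for (k in seq_len(K)) {
    mt <- mtaper_windows(session$data, fs, starts[[k]], n,
                         tapers[seq_len(nfft), , drop = FALSE], freq_idx)
    if (is.null(mt)) {
      message(sprintf("state %d has no complete %g s window: NaN spectra", k,
                      window_s))
      next
    }
    psd[k, , ] <- mt$psd
    n_windows[k] <- mt$n_windows
    for (p in seq_len(P)) for (q in seq_len(P)) {
      coh[k, p, q, ] <- Mod(mt$csd[, p, q])^2 / (mt$psd[p, ] * mt$psd[q, ])
    }
  }
  structure(list(psd = psd, coherence = coh, freqs = freqs,
                 n_windows = n_windows,
                 params = list(window_s = window_s, n_tapers = n_tapers,
                               resolution_Hz = fs / nfft, band = band,
                               nw = nw)),
            class = "state_spectra")
}

# multiplicative-update NMF with Frobenius objective
nmf_once <- function(V, r, max_iter, seed) {
  set.seed(seed)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * r, 0.1, 1), n, r)
  H <- matrix(runif(r * m, 0.1, 1), r, m)
  eps <- 1e-12
  err <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err[it] <- sqrt(sum((V - W %*% H)^2))
    if (it > 10L && abs(err[it - 1L] - err[it]) < 1e-10 * err[1L]) {
      err <- err[seq_len(it)]
      break
    }
  }
  list(W = W, H = H, err = err)
}

#' NNMF spectral mode decomposition
#'
#' Factorizes the matrix of all (state, channel) power spectra and
#' (state, channel-pair) coherence spectra into nonnegative spatial
#' loadings times nonnegative spectral modes. Best of `n_restarts` by
#' reconstruction error; modes are sorted by spectral centroid
#' (ascending) and normalized to unit sum over frequency.
#'
#' @param spectra a `state_spectra`.
#' @param n_modes number of spectral modes.
#' @param n_restarts random restarts (default 10).
#' @param seed RNG seed.
#' @param max_iter update iterations per restart.
#' @return Object of class `spectral_modes`: `mode_weights`
#'   `[n_modes x F]`, `psd_maps` `[n_modes x K x P]`, `coh_maps`
#'   `[n_modes x K x P x P]`, `freqs`, `err_trace` (best restart).
#' @export
nnmf_modes <- function(spectra, n_modes, n_restarts = 10, seed = 1,
                       max_iter = 500) {
  stopifnot(inherits(spectra, "state_spectra"), n_modes >= 1)
  K <- dim(spectra$psd)[1]
  P <- dim(spectra$psd)[2]
  Fb <- dim(spectra$psd)[3]
  psd_rows <- matrix(spectra$psd, K * P, Fb)
  up <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  coh_rows <- matrix(0, K * nrow(up), Fb)
  r <- 0L
  for (k in seq_len(K)) for (e in seq_len(nrow(up))) {
    r <- r + 1L
    coh_rows[r, ] <- spectra$coherence[k, up[e, 1], up[e, 2], ]
  }
  V <- rbind(psd_rows, coh_rows)
  ok <- rowSums(!is.finite(V)) == 0L
  V <- V[ok, , drop = FALSE]
  if (any(V < 0)) stop("negative spectral inputs")
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    fit <- nmf_once(V, n_modes, max_iter, sub_seed(seed, rs))
    if (is.null(best) || tail(fit$err, 1) < tail(best$err, 1)) best <- fit
  }
  H <- best$H
  W <- matrix(0, length(ok), n_modes)
  W[ok, ] <- best$W
  # deterministic scaling + ordering
  hs <- rowSums(H)
  H <- H / hs
  W <- W * rep(hs, each = nrow(W))
  centroid <- as.numeric(H %*% spectra$freqs)
  ord <- order(centroid)
  H <- H[ord, , drop = FALSE]
  W <- W[, ord, drop = FALSE]
  psd_maps <- array(W[seq_len(K * P), , drop = FALSE],
                    dim = c(K, P, n_modes))
  psd_maps <- aperm(psd_maps, c(3, 1, 2))
  coh_maps <- array(0, dim = c(n_modes, K, P, P))
  r <- K * P
  for (k in seq_len(K)) for (e in seq_len(nrow(up))) {
    r <- r + 1L
    coh_maps[, k, up[e, 1], up[e, 2]] <- W[r, ]
    coh_maps[, k, up[e, 2], up[e, 1]] <- W[r, ]
  }
  structure(list(mode_weights = H, psd_maps = psd_maps,
                 coh_maps = coh_maps, freqs = spectra$freqs,
                 err_trace = best$err),
            class = "spectral_modes")
}

#' Event-evoked time-frequency reconstruction
#'
#' Weights each state's spectrum by the (non-baseline-corrected) evoked
#' state distribution: `TF(tau, f) = sum_k B[k, tau, n] * spec_k(f)`,
#' computed per subject then averaged. Requires probability weights
#' (columns summing to 1); a baseline-corrected input is rejected.
#'
#' @param evoked an `evoked_response` with `baseline_corrected = FALSE`.
#' @param spectra a `state_spectra` (channel-averaged internally).
#' @return list: `psd_tf` (group mean, L x F), `psd_tf_bc` (display
#'   baseline: per-subject time-mean subtracted before averaging),
#'   `coh_tf` (channel-pair mean coherence analogue), `lags`, `freqs`.
#' @export
evoked_timefreq <- function(evoked, spectra) {
  stopifnot(inherits(evoked, "evoked_response"),
            inherits(spectra, "state_spectra"))
  B <- evoked$values  # K x L x N
  sums <- apply(B, c(2, 3), sum)
  if (any(abs(sums - 1) > 1e-3))
    stop("evoked weights do not sum to 1 over states; pass the non-baseline-corrected response")
  K <- dim(B)[1]; L <- dim(B)[2]; N <- dim(B)[3]
  psd_k <- apply(spectra$psd, c(1, 3), mean)        # K x F
  P <- dim(spectra$coherence)[2]
  up <- upper.tri(matrix(0, P, P))
  coh_k <- t(apply(spectra$coherence, 1, function(m) {
    # m is P x P x F
    apply(array(m, dim = c(P, P, length(spectra$freqs))), 3,
          function(s) mean(s[up]))
  }))                                               # K x F
  Fb <- length(spectra$freqs)
  psd_subj <- array(0, dim = c(N, L, Fb))
  coh_subj <- array(0, dim = c(N, L, Fb))
  for (n in seq_len(N)) {
    psd_subj[n, , ] <- t(B[, , n]) %*% psd_k
    coh_subj[n, , ] <- t(B[, , n]) %*% coh_k
  }
  psd_bc <- sweep(psd_subj, c(1, 3), apply(psd_subj, c(1, 3), mean))
  list(psd_tf = apply(psd_subj, c(2, 3), mean),
       psd_tf_bc = apply(psd_bc, c(2, 3), mean),
       coh_tf = apply(coh_subj, c(2, 3), mean),
       lags = evoked$lags, freqs = spectra$freqs)
}

#' Gaussian-mixture threshold mask
#'
#' Fits a 2-component 1-D Gaussian mixture by EM; the mask selects values
#' whose posterior membership in the higher-mean component exceeds 0.5,
#' provided the component means are separated by more than one pooled SD.
#' If separation fails the mask is empty.
#'
#' @param values nonnegative numeric vector (>= 20 values).
#' @return Logical mask, with attributes `means`, `sds`, `weights`,
#'   `separated`.
#' @export
gmm_threshold <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 20L) stop("need at least 20 values")
  if (sd(values) == 0) {
    warning("constant input: empty mask")
    out <- rep(FALSE, length(values))
    attr(out, "separated") <- FALSE
    return(out)
  }
  mu <- quantile(values, c(0.2, 0.8), names = FALSE)
  sg <- rep(sd(values), 2)
  w <- c(0.5, 0.5)
  for (it in 1:200) {
    d1 <- w[1] * stats::dnorm(values, mu[1], max(sg[1], 1e-12))
    d2 <- w[2] * stats::dnorm(values, mu[2], max(sg[2], 1e-12))
    r2 <- d2 / (d1 + d2 + 1e-300)
    r1 <- 1 - r2
    mu_new <- c(sum(r1 * values) / sum(r1), sum(r2 * values) / sum(r2))
    sg <- c(sqrt(sum(r1 * (values - mu_new[1])^2) / sum(r1)),
            sqrt(sum(r2 * (values - mu_new[2])^2) / sum(r2)))
    w <- c(mean(r1), mean(r2))
    if (max(abs(mu_new - mu)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  hi <- which.max(mu)
  pooled_sd <- sqrt(sum(w * sg^2))
  # a genuine second mixture must both separate its means and beat a
  # single Gaussian on BIC: EM happily splits a unimodal sample into two
  # well-separated halves, which BIC rejects
  ll2 <- sum(log(w[1] * stats::dnorm(values, mu[1], max(sg[1], 1e-12)) +
                   w[2] * stats::dnorm(values, mu[2], max(sg[2], 1e-12)) +
                   1e-300))
  ll1 <- sum(stats::dnorm(values, mean(values),
                          sd(values) * sqrt((length(values) - 1) /
                                              length(values)),
                          log = TRUE))
  n <- length(values)
  bic_better <- (-2 * ll2 + 5 * log(n)) < (-2 * ll1 + 2 * log(n))
  separated <- abs(diff(mu)) > pooled_sd && bic_better
  post_hi <- if (hi == 2) r2 else 1 - r2
  mask <- separated & (post_hi > 0.5)
  attr(mask, "means") <- mu
  attr(mask, "sds") <- sg
  attr(mask, "weights") <- w
  attr(mask, "separated") <- separated
  mask
}

#' State-conditioned PSD of wideband data
#'
#' Applies the state-conditioned multitaper to a higher-rate recording
#' using state timings derived from the low-band pipeline, covering the
#' full high-frequency band.
#'
#' @param wideband a [recording_session()] at the high sampling rate.
#' @param state_path_hi hard state path resampled to the wideband rate
#'   (length = wideband samples; 0 marks invalid samples).
#' @param band analysis band (Hz), default `c(1, 160)`.
#' @param window_s,n_tapers,nw multitaper parameters (paper defaults).
#' @return A `state_spectra` (coherence omitted: `NULL`), plus
#'   `mean_psd` `[K x F]` averaged over channels.
#' @export
hf_state_psd <- function(wideband, state_path_hi, band = c(1, 160),
                         window_s = 2, n_tapers = 7, nw = 4) {
  stopifnot(inherits(wideband, "recording_session"))
  if (length(state_path_hi) != ncol(wideband$data))
    stop(sprintf("state path length %d != wideband samples %d",
                 length(state_path_hi), ncol(wideband$data)))
  if (band[2] >= wideband$fs / 2)
    stop("band beyond Nyquist")
  good <- !wideband$bad_mask & state_path_hi > 0L
  samples <- which(good)
  fake_tc <- list(samples = samples)
  sp <- state_multitaper(wideband, fake_tc, window_s = window_s,
                         n_tapers = n_tapers,
                         resolution_Hz = 1 / window_s, band = band,
                         nw = nw, path = state_path_hi[samples])
  sp$mean_psd <- apply(sp$psd, c(1, 3), mean)
  sp
}

#' Replay-evoked high-frequency PSD with subject-shuffled baseline
#'
#' Multitaper PSD averaged over short windows centered on each replay
#' event, against a baseline computed identically at event times drawn
#' from the other subjects' event trains (preserving per-subject event
#' counts and window profiles).
#'
#' @param sessions list of wideband [recording_session()]s (one per
#'   subject).
#' @param event_samples list of event sample indices at the wideband rate.
#' @param window_ms window width (ms), default 30 (coarse frequency
#'   resolution, reported in the metadata).
#' @param n_baseline_shuffles baseline draws per subject (default 10).
#' @param seed RNG seed.
#' @param n_tapers,nw multitaper parameters for the short windows
#'   (defaults 3 tapers, NW = 2).
#' @return list: `evoked_psd` (F), `baseline_psd` (F), per-subject
#'   matrices, `freqs`, `resolution_Hz`, `n_windows`.
#' @export
hf_replay_psd <- function(sessions, event_samples, window_ms = 30,
                          n_baseline_shuffles = 10, seed = 1,
                          n_tapers = 3, nw = 2) {
  N <- length(sessions)
  stopifnot(N == length(event_samples), N >= 2L)
  fs <- sessions[[1]]$fs
  n <- max(4L, ms_to_samples(window_ms, fs))
  half <- n %/% 2L
  tapers <- dpss_tapers(n, nw, n_tapers)
  freqs_all <- (seq_len(n) - 1L) * fs / n
  freq_idx <- which(freqs_all > 0 & freqs_all < fs / 2)
  freqs <- freqs_all[freq_idx]

  window_psd <- function(sess, centers) {
    T <- ncol(sess$data)
    starts <- centers - half
    ok <- starts >= 1L & starts + n - 1L <= T
    if (any(ok)) {
      bad <- sess$bad_mask
      ok[ok] <- vapply(starts[ok], function(s)
        !any(bad[s:(s + n - 1L)]), logical(1))
    }
    if (!any(ok)) return(NULL)
    mt <- mtaper_windows(sess$data, fs, starts[ok], n, tapers, freq_idx)
    list(psd = colMeans(mt$psd), n = mt$n_windows)  # channel-mean
  }

  set.seed(seed)
  ev <- matrix(NA_real_, N, length(freqs))
  bl <- matrix(NA_real_, N, length(freqs))
  nwin <- integer(N)
  for (s in seq_len(N)) {
    e <- window_psd(sessions[[s]], event_samples[[s]])
    if (is.null(e)) stop(sprintf("subject %d: all event windows bad", s))
    ev[s, ] <- e$psd
    nwin[s] <- e$n
    pool <- unlist(event_samples[-s])
    acc <- 0
    got <- 0L
    for (b in seq_len(n_baseline_shuffles)) {
      centers <- sample(pool, length(event_samples[[s]]),
                        replace = length(pool) < length(event_samples[[s]]))
      bp <- window_psd(sessions[[s]], centers)
      if (!is.null(bp)) { acc <- acc + bp$psd; got <- got + 1L }
    }
    if (got == 0L) stop(sprintf("subject %d: all baseline windows bad", s))
    bl[s, ] <- acc / got
  }
  list(evoked_psd = colMeans(ev), baseline_psd = colMeans(bl),
       evoked_by_subject = ev, baseline_by_subject = bl, freqs = freqs,
       resolution_Hz = fs / n, n_windows = nwin)
}
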