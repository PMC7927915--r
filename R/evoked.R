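#' Epoch state probabilities around events (one subject)
#'
#' Extracts the posterior state probabilities in a window around each
#' event and averages over events. With `baseline = TRUE` the subject's
#' session-mean state probability is subtracted, so positive values mean
#' above-average state probability. Epochs crossing the recording edges,
#' bad segments, or non-embeddable samples are dropped entirely.
#'
#' @param tc a `state_timecourse`.
#' @param events event onset sample indices (1-based, session samples).
#' @param T total number of session samples.
#' @param window_s half-window (s); lags run from `-window_s` to
#'   `+window_s`. Default 0.5.
#' @param baseline subtract the session-mean state probability
#'   (default `TRUE`).
#' @return Object of class `evoked_response`: `values` (K x L x 1),
#'   `lags` (s), `baseline_corrected`, `n_epochs`, `session_mean`.
#' @export
epoch_states <- function(tc, events, T, window_s = 0.5, baseline = TRUE) {
  stopifnot(inherits(tc, "state_timecourse"))
  fs <- tc$fs
  w <- round(window_s * fs)
  lags <- (-w):w
  K <- nrow(tc$gamma)
  G <- gamma_full(tc, T)
  valid <- !is.na(G[1, ])
  vcum <- c(0L, cumsum(!valid))
  keep <- events - w >= 1L & events + w <= T
  keep[keep] <- (vcum[events[keep] + w + 1L] -
                   vcum[events[keep] - w]) == 0L
  kept <- events[keep]
  if (!length(kept))
    stop("zero retained epochs for this subject")
  acc <- matrix(0, K, length(lags))
  for (t0 in kept) acc <- acc + G[, t0 + lags]
  evoked <- acc / length(kept)
  mu <- rowMeans(G[, valid, drop = FALSE])
  if (baseline) evoked <- evoked - mu
  structure(list(values = array(evoked, dim = c(K, length(lags), 1L)),
                 lags = lags / fs, baseline_corrected = baseline,
                 n_epochs = length(kept), session_mean = mu),
            class = "evoked_response")
}

#' Combine and summarize per-subject evoked responses
#'
#' @param evoked_list list of single-subject `evoked_response` objects on
#'   the same lag grid (>= 2 subjects).
#' @return An `evoked_response` with `values` K x L x N plus `mean` and
#'   `sem` (K x L, elementwise over subjects).
#' @export
group_evoked <- function(evoked_list) {
  stopifnot(length(evoked_list) >= 2L)
  dims <- vapply(evoked_list, function(e) dim(e$values)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("evoked responses have mismatched shapes")
  bc <- vapply(evoked_list, function(e) e$baseline_corrected, logical(1))
  if (length(unique(bc)) != 1L)
    stop("mixing baseline-corrected and raw responses")
  vals <- array(unlist(lapply(evoked_list, function(e) e$values[, , 1])),
                dim = c(dims[1, 1], dims[2, 1], length(evoked_list)))
  m <- apply(vals, c(1, 2), mean)
  s <- apply(vals, c(1, 2), sd) / sqrt(length(evoked_list))
  structure(list(values = vals, lags = evoked_list[[1]]$lags,
                 baseline_corrected = bc[1],
                 n_epochs = vapply(evoked_list, function(e) e$n_epochs,
                                   numeric(1)),
                 mean = m, sem = s),
            class = "evoked_response")
}

# one-sample t statistics per column of an N x L matrix; sign flips enter
# through the column means only (column sums of squares are invariant)
col_t <- function(M, ss, N) {
  v <- (ss - N * M^2) / (N - 1)
  M / sqrt(pmax(v, 1e-300) / N)
}

max_run_true <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# core sign-flip cluster permutation on one state's N x L subject matrix
cluster_perm_matrix <- function(X, t_threshold, n_perm, seed) {
  N <- nrow(X)
  L <- ncol(X)
  ss <- colSums(X^2)
  t_obs <- col_t(colMeans(X), ss, N)
  above <- t_obs > t_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  obs <- data.frame(lag_start = starts[r$values], lag_end = ends[r$values],
                    mass = r$lengths[r$values])
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * N, replace = TRUE), n_perm, N)
  Mperm <- signs %*% X / N
  Tperm <- col_t(Mperm, matrix(ss, n_perm, L, byrow = TRUE), N)
  null_max <- apply(Tperm > t_threshold, 1L, max_run_true)
  obs$p <- vapply(obs$mass, function(m)
    (sum(null_max >= m) + 1) / (n_perm + 1), numeric(1))
  list(t = t_obs, clusters = obs, null_max = null_max)
}

#' Sign-flip cluster permutation test of the group evoked response
#'
#' For each state, clusters are maximal runs of lags whose group
#' one-sample t statistic exceeds `t_threshold`; cluster mass is the run
#' length. The null distribution of the maximum cluster length is built
#' by randomly flipping the sign of each subject's evoked response;
#' `p = (#{null >= observed} + 1) / (n_perm + 1)`.
#'
#' @param evoked a group `evoked_response` (baseline-corrected; N >= 5).
#' @param t_threshold cluster-forming threshold (default 3).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @return Object of class `cluster_result`: per-state list with `t`
#'   (group t per lag), `clusters` (data frame: `lag_start`, `lag_end`,
#'   `mass`, `p`, lag indices), plus `t_threshold`, `n_perm`, `lags`.
#' @export
cluster_permutation <- function(evoked, t_threshold = 3, n_perm = 5000,
                                seed = 1) {
  stopifnot(inherits(evoked, "evoked_response"))
  N <- dim(evoked$values)[3]
  if (N < 5L) stop("need at least 5 subjects")
  K <- dim(evoked$values)[1]
  per_state <- lapply(seq_len(K), function(k)
    cluster_perm_matrix(t(evoked$values[k, , ]), t_threshold, n_perm,
                        sub_seed(seed, k)))
  structure(list(states = per_state, t_threshold = t_threshold,
                 n_perm = n_perm, lags = evoked$lags),
            class = "cluster_result")
}

#' Inflexible replication test of a cluster in a second dataset
#'
#' Takes a temporal cluster found in dataset A, sets the cluster-forming
#' threshold to the minimum dataset-B t statistic inside that window, and
#' computes the sign-flip permutation probability of a cluster of at
#' least the window's length anywhere in B at that threshold.
#'
#' @param cluster one row of a `cluster_result` cluster table (needs
#'   `lag_start`, `lag_end`, lag indices into B's grid).
#' @param evoked_b dataset-B group `evoked_response` (same lag grid).
#' @param state state index the cluster belongs to.
#' @param n_perm permutations (default 5000).
#' @param seed RNG seed.
#' @return list: `threshold` (min-t), `size`, `p`.
#' @export
replication_cluster_test <- function(cluster, evoked_b, state,
                                     n_perm = 5000, seed = 1) {
  X <- t(evoked_b$values[state, , ])
  N <- nrow(X)
  L <- ncol(X)
  idx <- cluster$lag_start:cluster$lag_end
  if (any(idx < 1L | idx > L)) stop("cluster window empty in dataset B's lag grid")
  ss <- colSums(X^2)
  t_b <- col_t(colMeans(X), ss, N)
  thr <- min(t_b[idx])
  size <- length(idx)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * N, replace = TRUE), n_perm, N)
  Tperm <- col_t(signs %*% X / N, matrix(ss, n_perm, L, byrow = TRUE), N)
  null_max <- apply(Tperm > thr, 1L, max_run_true)
  list(threshold = thr, size = size,
       p = (sum(null_max >= size) + 1) / (n_perm + 1))
}

#' Paired comparison of evoked state distributions across conditions
#'
#' Per state, a two-sided paired t test between the two conditions'
#' evoked values at the stated lags (e.g. replay at lag 0 versus
#' localizer at the classifier training time), with a Bonferroni flag at
#' `alpha / K`.
#'
#' @param evoked_a,evoked_b group `evoked_response` objects over the same
#'   subjects.
#' @param lag_a_s,lag_b_s lags (s) at which to compare.
#' @param alpha family-wise level for the Bonferroni flag (default 0.05).
#' @return data frame: `state`, `t`, `p`, `significant_bonferroni`.
#' @export
compare_conditions <- function(evoked_a, evoked_b, lag_a_s = 0,
                               lag_b_s = 0, alpha = 0.05) {
  Na <- dim(evoked_a$values)[3]
  Nb <- dim(evoked_b$values)[3]
  if (Na != Nb) stop(sprintf("subject count mismatch: %d vs %d", Na, Nb))
  K <- dim(evoked_a$values)[1]
  ia <- which.min(abs(evoked_a$lags - lag_a_s))
  ib <- which.min(abs(evoked_b$lags - lag_b_s))
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    d <- evoked_a$values[k, ia, ] - evoked_b$values[k, ib, ]
    if (isTRUE(all.equal(sd(d), 0, tolerance = 1e-12))) {
      # identical conditions give t = 0; a constant nonzero shift is an
      # infinitely reliable difference
      if (mean(d) == 0) return(data.frame(state = k, t = 0, p = 1))
      return(data.frame(state = k, t = sign(mean(d)) * Inf, p = 0))
    }
    tt <- t.test(d)
    data.frame(state = k, t = unname(tt$statistic), p = tt$p.value)
  }))
  out$significant_bonferroni <- out$p < alpha / K
  out
}

#' Percentile-threshold sweep of the evoked response at lag 0
#'
#' Repeats the replay-evoked analysis while varying the event threshold
#' percentile, recording the lag-0 baseline-corrected evoked value per
#' state. Genuine replay coupling loads the high percentiles; variance
#' artifacts are symmetric about the median, so the asymmetry statistic
#' (value at the highest minus value at the lowest percentile) separates
#' the two.
#'
#' @param trace replay probability trace.
#' @param tc a `state_timecourse`.
#' @param T total session samples.
#' @param percentiles percentile grid (default `1:99`).
#' @param window_s edge-exclusion half window (s).
#' @param bad_mask optional bad-sample mask.
#' @return list: `values` (K x length(percentiles)), `percentiles`,
#'   `asymmetry` (per state: last minus first percentile value).
#' @export
threshold_sweep <- function(trace, tc, T, percentiles = 1:99,
                            window_s = 0.5, bad_mask = NULL) {
  stopifnot(inherits(tc, "state_timecourse"))
  fs <- tc$fs
  w <- round(window_s * fs)
  K <- nrow(tc$gamma)
  G <- gamma_full(tc, T)
  valid <- !is.na(G[1, ])
  vcum <- c(0L, cumsum(!valid))
  mu <- rowMeans(G[, valid, drop = FALSE])
  vals <- matrix(NA_real_, K, length(percentiles))
  for (i in seq_along(percentiles)) {
    ev <- threshold_events(trace, fs, percentile = percentiles[i],
                           bad_mask = bad_mask)
    events <- ev$event_onsets
    keep <- events - w >= 1L & events + w <= T
    keep[keep] <- (vcum[events[keep] + w + 1L] -
                     vcum[events[keep] - w]) == 0L
    events <- events[keep]
    if (!length(events)) next
    vals[, i] <- rowMeans(G[, events, drop = FALSE]) - mu
  }
  list(values = vals, percentiles = percentiles,
       asymmetry = vals[, length(percentiles)] - vals[, 1L])
}
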