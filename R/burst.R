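#' Default Fano window grid
#'
#' 30 log-spaced window lengths from 0.1 s to 30 s.
#' @export
default_fano_grid <- function() exp(seq(log(0.1), log(30), length.out = 30))

# samples excluded from Fano windowing: bad samples plus every sample in
# an inter-event interval that overlaps bad data
excluded_samples_cum <- function(events, T, bad_mask) {
  excl <- bad_mask
  if (length(events) >= 2L) {
    badcum <- c(0L, cumsum(bad_mask))
    for (i in seq_len(length(events) - 1L)) {
      a <- events[i]
      b <- events[i + 1L]
      if (badcum[b + 1L] - badcum[a] > 0L) excl[a:b] <- TRUE
    }
  }
  c(0L, cumsum(excl))
}

#' Fano factor versus window length (one subject)
#'
#' Partitions the recording into non-overlapping windows of each length,
#' counts events per window, and returns `F_W = var / mean` of the
#' counts. Windows containing bad samples - or samples of an inter-event
#' interval that overlaps bad data - are dropped; trailing partial
#' windows are dropped; window lengths with fewer than 2 retained
#' windows give `NA`.
#'
#' @param events event sample indices (1-based, increasing).
#' @param T total samples.
#' @param fs sampling rate (Hz).
#' @param bad_mask optional logical bad-sample mask.
#' @param windows_s window-length grid in seconds
#'   (default [default_fano_grid()]).
#' @return Object of class `fano_curve`: `window_s`, `fano`,
#'   `n_windows` (retained per length).
#' @export
fano_curve <- function(events, T, fs, bad_mask = NULL,
                       windows_s = default_fano_grid()) {
  if (any(windows_s <= 0 | windows_s > T / fs))
    stop("window lengths must be in (0, T/fs]")
  events <- as.integer(events)
  have_bad <- !is.null(bad_mask) && any(bad_mask)
  if (have_bad) ecum <- excluded_samples_cum(events, T, bad_mask)
  fano <- numeric(length(windows_s))
  nw <- integer(length(windows_s))
  for (i in seq_along(windows_s)) {
    len <- max(1L, round(windows_s[i] * fs))
    n_win <- T %/% len
    if (n_win < 2L) { fano[i] <- NA_real_; next }
    counts <- tabulate(pmin((events - 1L) %/% len + 1L, n_win + 1L),
                       nbins = n_win + 1L)[seq_len(n_win)]
    if (have_bad) {
      s0 <- (seq_len(n_win) - 1L) * len
      keep <- (ecum[s0 + len + 1L] - ecum[s0 + 1L]) == 0L
      counts <- counts[keep]
    }
    nw[i] <- length(counts)
    fano[i] <- if (length(counts) < 2L || mean(counts) == 0) NA_real_
    else var(counts) / mean(counts)
  }
  structure(list(window_s = windows_s, fano = fano, n_windows = nw),
            class = "fano_curve")
}

# subjects x windows matrix of Fano factors
fano_matrix <- function(events_list, T, fs, bad_masks = NULL,
                        windows_s = default_fano_grid()) {
  t(vapply(seq_along(events_list), function(s)
    fano_curve(events_list[[s]], T, fs,
               if (is.null(bad_masks)) NULL else bad_masks[[s]],
               windows_s)$fano,
    numeric(length(windows_s))))
}

shuffle_intervals <- function(events, seed_offset = NULL) {
  if (length(events) < 2L) return(events)
  iv <- diff(events)
  events[1L] + c(0L, cumsum(sample(iv)))
}

#' Interval-shuffle surrogate test for bursty event trains
#'
#' Tests the null hypothesis that inter-event intervals are independent
#' and identically distributed: surrogate trains permute each subject's
#' intervals (first event time preserved, interval multiset unchanged),
#' the group Fano curve is recomputed per permutation, and the observed
#' group Fano is compared against the per-window maximum over surrogates.
#' Where the observed curve exceeds that maximum the null is rejected at
#' `p < 1/n_perm`.
#'
#' @param events_list per-subject event sample indices (>= 3 events
#'   each).
#' @param T total samples.
#' @param fs sampling rate (Hz).
#' @param n_perm number of interval permutations (default 1000).
#' @param windows_s Fano window grid.
#' @param seed RNG seed.
#' @param bad_masks optional per-subject bad masks (observed curve only).
#' @return list: `observed` (group Fano per window), `threshold`
#'   (max-surrogate per window), `reject` (logical per window),
#'   `p_bound` (`1/n_perm`), `window_s`.
#' @export
interval_shuffle_test <- function(events_list, T, fs, n_perm = 1000,
                                  windows_s = default_fano_grid(),
                                  seed = 1, bad_masks = NULL) {
  if (any(vapply(events_list, length, integer(1)) < 3L))
    stop("each subject needs at least 3 events")
  if (n_perm < 10L)
    warning("very few permutations: the test is near-powerless")
  obs <- colMeans(fano_matrix(events_list, T, fs, bad_masks, windows_s),
                  na.rm = TRUE)
  set.seed(seed)
  thr <- rep(-Inf, length(windows_s))
  for (p in seq_len(n_perm)) {
    surr <- lapply(events_list, shuffle_intervals)
    g <- colMeans(fano_matrix(surr, T, fs, NULL, windows_s), na.rm = TRUE)
    thr <- pmax(thr, g)
  }
  list(observed = obs, threshold = thr, reject = obs > thr,
       p_bound = 1 / n_perm, window_s = windows_s)
}

#' State-visit Fano factors and across-state tests
#'
#' Treats each state visit as an event and computes the Fano curve per
#' state and subject, then (per window length) a one-way ANOVA across
#' states and per-state two-sample t tests of one state's subject Fanos
#' against the pooled remaining states. Following the reporting
#' convention of taking the least favourable window, the maximum p value
#' over window lengths is reported (ANOVA p values Bonferroni-corrected
#' by the number of windows).
#'
#' @param vs_list per-subject `visit_statistics`.
#' @param T total samples; @param fs sampling rate (Hz).
#' @param windows_s Fano window grid.
#' @param min_visits subjects contribute a state only with at least this
#'   many visits (default 3).
#' @return list: `fano` (K x subjects x windows), `anova_p` (per
#'   window), `anova_max_p`, `anova_max_p_bonferroni`, `state_t`
#'   (data frame per state: `t` at the least favourable window,
#'   `max_p`).
#' @export
state_visit_fano <- function(vs_list, T, fs,
                             windows_s = default_fano_grid(),
                             min_visits = 3L) {
  K <- length(vs_list[[1]]$onsets)
  N <- length(vs_list)
  W <- length(windows_s)
  fano <- array(NA_real_, dim = c(K, N, W))
  for (s in seq_len(N)) for (k in seq_len(K)) {
    on <- vs_list[[s]]$onsets[[k]]
    if (length(on) < min_visits) next
    fano[k, s, ] <- fano_curve(on, T, fs, windows_s = windows_s)$fano
  }
  anova_p <- vapply(seq_len(W), function(w) {
    f <- fano[, , w]
    df <- data.frame(f = as.numeric(f),
                     state = factor(rep(seq_len(K), N)))
    df <- df[is.finite(df$f), ]
    if (nlevels(droplevels(df$state)) < 2L) return(NA_real_)
    summary(aov(f ~ state, data = df))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  state_t <- do.call(rbind, lapply(seq_len(K), function(k) {
    ps <- ts_ <- rep(NA_real_, W)
    for (w in seq_len(W)) {
      a <- fano[k, , w]
      b <- as.numeric(fano[-k, , w])
      a <- a[is.finite(a)]
      b <- b[is.finite(b)]
      if (length(a) >= 2L && length(b) >= 2L) {
        tt <- t.test(a, b)
        ps[w] <- tt$p.value
        ts_[w] <- unname(tt$statistic)
      }
    }
    wmax <- if (all(is.na(ps))) NA_integer_ else which.max(ps)
    data.frame(state = k,
               t = if (is.na(wmax)) NA_real_ else ts_[wmax],
               max_p = if (is.na(wmax)) NA_real_ else ps[wmax])
  }))
  mp <- if (all(is.na(anova_p))) NA_real_ else max(anova_p, na.rm = TRUE)
  list(fano = fano, anova_p = anova_p, anova_max_p = mp,
       anova_max_p_bonferroni = min(1, mp * sum(is.finite(anova_p))),
       state_t = state_t, window_s = windows_s)
}

#' State-conditioned inter-replay intervals (one subject)
#'
#' For each replay event, the interval to the next event and the most
#' likely active state at the event time (argmax posterior). Intervals
#' overlapping bad segments are omitted; per-state means from fewer than
#' `min_obs` observations are flagged excluded.
#'
#' @param events sorted event sample indices.
#' @param tc a `state_timecourse`.
#' @param T total samples.
#' @param bad_mask optional bad-sample mask.
#' @param min_obs minimum observations per cell (default 10).
#' @return data frame: `state`, `mean_interval_s`, `n_obs`, `excluded`.
#' @export
conditioned_intervals <- function(events, tc, T, bad_mask = NULL,
                                  min_obs = 10L) {
  stopifnot(inherits(tc, "state_timecourse"))
  if (is.unsorted(events)) stop("events must be sorted")
  K <- nrow(tc$gamma)
  fs <- tc$fs
  G <- gamma_full(tc, T)
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, T)
  badcum <- c(0L, cumsum(bad_mask))
  n <- length(events)
  if (n < 2L) stop("need at least 2 events")
  iv <- diff(events)
  a <- events[-n]
  keep <- (badcum[events[-1L] + 1L] - badcum[a]) == 0L &
    !is.na(G[1, a])
  st <- max.col(t(G[, a[keep], drop = FALSE]))
  ivs <- iv[keep] / fs
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    x <- ivs[st == k]
    data.frame(state = k,
               mean_interval_s = if (length(x)) mean(x) else NA_real_,
               n_obs = length(x),
               excluded = length(x) < min_obs)
  }))
  class(out) <- c("conditioned_intervals", class(out))
  out
}

#' Group tests of state-conditioned intervals
#'
#' One-way ANOVA across states of the per-subject mean intervals
#' (excluded cells dropped), and per-state two-sample t tests of one
#' state's subject means against all other states' combined.
#'
#' @param ci_list per-subject outputs of [conditioned_intervals()].
#' @return list: `table` (stacked cells with subject ids), `anova_p`,
#'   `state_t` (data frame `state`, `t`, `p`).
#' @export
conditioned_interval_tests <- function(ci_list) {
  tab <- do.call(rbind, Map(function(ci, s) {
    ci$subject <- s
    ci
  }, ci_list, seq_along(ci_list)))
  tab <- tab[!tab$excluded & is.finite(tab$mean_interval_s), ]
  if (!nrow(tab)) stop("all cells excluded")
  if (length(unique(tab$state)) < 2L)
    stop("fewer than 2 states with retained cells: ANOVA undefined")
  p_anova <- summary(aov(mean_interval_s ~ factor(state),
                         data = tab))[[1]][["Pr(>F)"]][1]
  states <- sort(unique(tab$state))
  state_t <- do.call(rbind, lapply(states, function(k) {
    a <- tab$mean_interval_s[tab$state == k]
    b <- tab$mean_interval_s[tab$state != k]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(state = k, t = NA_real_, p = NA_real_))
    tt <- t.test(a, b)
    data.frame(state = k, t = unname(tt$statistic), p = tt$p.value)
  }))
  list(table = tab, anova_p = p_anova, state_t = state_t)
}
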