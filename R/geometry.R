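#' Transition-derived state distances
#'
#' Excludes self-transitions (diagonal zeroed, rows renormalized to give
#' `psi`), converts transition probability to distance `d = 1 - psi`, and
#' symmetrizes `d_hat = (d + t(d)) / 2`. The diagonal of `d_hat` is forced
#' to zero (the raw formula gives a self-distance of 1, a formula
#' artifact).
#'
#' @param transition K x K row-stochastic matrix.
#' @return Object of class `state_distance` with `psi` and `dist`
#'   (`d_hat`, symmetric, zero diagonal, entries in `[0, 1]`).
#' @export
transition_distance <- function(transition) {
  Th <- as.matrix(transition)
  K <- nrow(Th)
  if (any(abs(rowSums(Th) - 1) > 1e-9)) stop("transition is not stochastic")
  if (any(diag(Th) >= 1 - 1e-12))
    stop("absorbing state (theta_ii = 1): cannot normalize off-diagonal")
  psi <- Th
  diag(psi) <- 0
  psi <- psi / rowSums(psi)
  d <- 1 - psi
  dh <- (d + t(d)) / 2
  diag(dh) <- 0
  structure(list(psi = psi, dist = dh), class = "state_distance")
}

#' Order states along the principal MDS axis
#'
#' Classical multidimensional scaling (double-centered squared-distance
#' eigendecomposition) of the symmetric state distances; states are
#' ranked by their coordinate on the first axis. The sign is fixed so the
#' state with the largest-magnitude coordinate is positive; exact
#' coordinate ties break by original state index.
#'
#' @param sd_obj a `state_distance`.
#' @return Integer permutation: `order[i]` is the original index of the
#'   state given label i. Attribute `coords` carries the 1-D coordinates.
#' @export
mds_order <- function(sd_obj) {
  stopifnot(inherits(sd_obj, "state_distance"))
  dh <- sd_obj$dist
  K <- nrow(dh)
  if (K < 2L) stop("need at least 2 states")
  off <- dh[row(dh) != col(dh)]
  if (diff(range(off)) < 1e-12) {
    # K = 2 always has one distance; larger all-equal matrices carry no
    # orderable axis at all
    if (K > 2L)
      warning("degenerate MDS axis (all distances equal): identity labeling")
    out <- seq_len(K)
    attr(out, "coords") <- rep(0, K)
    return(out)
  }
  J <- diag(K) - 1 / K
  B <- -0.5 * J %*% (dh^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (eig$values[1] <= max(abs(eig$values)) * 1e-12) {
    warning("degenerate MDS axis (all distances equal): identity labeling")
    out <- seq_len(K)
    attr(out, "coords") <- rep(0, K)
    return(out)
  }
  coord <- eig$vectors[, 1] * sqrt(eig$values[1])
  if (coord[which.max(abs(coord))] < 0) coord <- -coord
  out <- order(coord, seq_len(K))
  attr(out, "coords") <- coord
  out
}

#' State-visit lifetime and interval statistics
#'
#' A visit is a maximal run of one state in the hard path within a
#' contiguous good segment. Lifetimes are run lengths in seconds; visits
#' truncated by bad segments or the recording edges are excluded from the
#' lifetime statistics. Intervals are gaps between consecutive visit
#' onsets of the same state within a segment.
#'
#' @param tc a `state_timecourse`.
#' @param K number of states; default inferred from `tc`.
#' @param use_viterbi use the Viterbi path (default) or argmax-gamma.
#' @return Object of class `visit_statistics`: per-state `lifetimes` (s),
#'   `intervals` (s), `onsets` (sample indices), `occupancy`.
#' @export
visit_statistics <- function(tc, K = NULL, use_viterbi = TRUE) {
  stopifnot(inherits(tc, "state_timecourse"))
  if (is.null(K)) K <- nrow(tc$gamma)
  path <- if (use_viterbi) tc$viterbi else max.col(t(tc$gamma))
  fs <- tc$fs
  segs <- segment_columns(tc$samples)
  lifetimes <- vector("list", K)
  onsets <- vector("list", K)
  for (seg in segs) {
    idx <- seg[1]:seg[2]
    r <- rle(path[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      k <- r$values[i]
      onsets[[k]] <- c(onsets[[k]], tc$samples[idx[starts[i]]])
      # visits touching the segment borders are truncated: drop from
      # lifetime statistics
      if (i > 1L && i < length(r$values))
        lifetimes[[k]] <- c(lifetimes[[k]], r$lengths[i] / fs)
    }
  }
  intervals <- lapply(onsets, function(on) {
    if (length(on) < 2L) return(numeric(0))
    d <- diff(on) / fs
    d[d > 0]
  })
  occ <- tabulate(path, nbins = K) / length(path)
  for (k in seq_len(K)) {
    if (is.null(onsets[[k]])) {
      onsets[[k]] <- integer(0)
      message(sprintf("state %d never visited", k))
    }
    if (is.null(lifetimes[[k]])) lifetimes[[k]] <- numeric(0)
  }
  structure(list(lifetimes = lifetimes, intervals = intervals,
                 onsets = onsets, occupancy = occ, fs = fs),
            class = "visit_statistics")
}

#' Summarize state labeling and visit statistics as a table
#'
#' @param sd_obj a `state_distance`; @param perm output of [mds_order()];
#' @param vs a `visit_statistics`.
#' @return data.frame with columns `state_label`, `raw_state`,
#'   `mds_coord`, `mean_lifetime_ms`, `mean_interval_s`, `occupancy`.
#' @export
state_label_table <- function(sd_obj, perm, vs) {
  coords <- attr(perm, "coords")
  data.frame(
    state_label = seq_along(perm),
    raw_state = as.integer(perm),
    mds_coord = coords[perm],
    mean_lifetime_ms = vapply(vs$lifetimes[perm], function(x)
      if (length(x)) mean(x) * 1000 else NA_real_, numeric(1)),
    mean_interval_s = vapply(vs$intervals[perm], function(x)
      if (length(x)) mean(x) else NA_real_, numeric(1)),
    occupancy = vs$occupancy[perm])
}
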