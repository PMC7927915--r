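#' Time-delay embedding
#'
#' Builds the embedded observation matrix whose column at time t is the
#' stacked window `X[, (t-l):(t+l)]` (channel-major: channel 1's lags
#' first). Columns touching bad samples or the recording edges are
#' dropped; retained rows are mean-centered (the observation model is
#' zero-mean).
#'
#' @param session a [recording_session()].
#' @param l one-sided lag count; the window length is `W = 2l + 1`.
#' @param center mean-center each row over the retained columns
#'   (default `TRUE`).
#' @return Object of class `tde_embedding`: `x` (`P*W` x `T_valid`),
#'   `samples` (original 1-based sample index per column), `row_means`,
#'   `l`, `fs`, `n_channels`.
#' @export
embed_session <- function(session, l, center = TRUE) {
  stopifnot(inherits(session, "recording_session"), l >= 1L)
  X <- session$data
  P <- nrow(X)
  T <- ncol(X)
  W <- 2L * l + 1L
  if (T <= W) stop("recording too short for the requested embedding")
  centers <- (l + 1L):(T - l)
  # a column is valid iff no sample in its window is bad
  badcum <- c(0L, cumsum(session$bad_mask))
  n_bad <- badcum[centers + l + 1L] - badcum[centers - l]
  keep <- centers[n_bad == 0L]
  D <- P * W
  E <- matrix(0, D, length(keep))
  row <- 0L
  for (ch in seq_len(P)) {
    for (lag in -l:l) {
      row <- row + 1L
      E[row, ] <- X[ch, keep + lag]
    }
  }
  mu <- if (center) rowMeans(E) else rep(0, D)
  if (center) E <- E - mu
  structure(list(x = E, samples = keep, row_means = mu, l = l,
                 fs = session$fs, n_channels = P),
            class = "tde_embedding")
}

# contiguous-run segmentation of a sorted sample-index vector:
# list of (start, end) column indices
segment_columns <- function(samples) {
  if (!length(samples)) return(list())
  brk <- which(diff(samples) != 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(samples))
  Map(function(s, e) c(s, e), starts, ends)
}

#' PCA reduction of embedded data
#'
#' Projects the embedded matrix onto its top principal components. The
#' basis is stored so that held-out data can be projected identically.
#'
#' @param embedding a `tde_embedding` (rows already centered).
#' @param n_components number of components to retain (<= rank).
#' @return Object of class `tde_reduced`: `x` (n_components x T_valid),
#'   `basis`, `explained_variance` (fraction), plus the embedding's
#'   bookkeeping fields.
#' @export
pca_reduce <- function(embedding, n_components) {
  stopifnot(inherits(embedding, "tde_embedding"))
  E <- embedding$x
  C <- tcrossprod(E) / (ncol(E) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  tol <- max(eig$values) * 1e-10
  rank <- sum(eig$values > tol)
  if (n_components > rank)
    stop(sprintf("n_components = %d exceeds the data rank (%d)",
                 n_components, rank))
  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  structure(list(x = crossprod(V, E),
                 basis = V,
                 explained_variance = sum(eig$values[seq_len(n_components)]) /
                   sum(pmax(eig$values, 0)),
                 samples = embedding$samples, l = embedding$l,
                 fs = embedding$fs, n_channels = embedding$n_channels,
                 row_means = embedding$row_means),
            class = "tde_reduced")
}

# project a new embedding with a stored basis/row means
project_embedding <- function(embedding, basis, row_means) {
  E <- embedding$x + embedding$row_means - row_means
  structure(list(x = crossprod(basis, E), basis = basis,
                 explained_variance = NA_real_,
                 samples = embedding$samples, l = embedding$l,
                 fs = embedding$fs, n_channels = embedding$n_channels,
                 row_means = row_means),
            class = "tde_reduced")
}

# per-state zero-mean Gaussian log-likelihood, T x K
emission_loglik <- function(X, covs) {
  D <- nrow(X)
  T <- ncol(X)
  K <- length(covs)
  out <- matrix(0, T, K)
  for (k in seq_len(K)) {
    R <- chol(covs[[k]])
    logdet <- 2 * sum(log(diag(R)))
    Q <- backsolve(R, X, transpose = TRUE)
    out[, k] <- -0.5 * (D * log(2 * pi) + logdet + colSums(Q^2))
  }
  out
}

# covariance M-step with collapse guard
regularized_cov <- function(S, n, D) {
  C <- S / n
  C <- (C + t(C)) / 2
  scale <- mean(diag(C))
  eps <- 1e-10
  while (!is.finite(rcond(C)) || rcond(C) < 1e-10) {
    message("hmm: covariance collapse; adding ridge regularization")
    C <- C + scale * max(eps, 1e-6) * diag(D)
    eps <- eps * 10
  }
  C
}

run_em <- function(X, segments, K, covs, trans, init, max_iter, tol,
                   frozen_covs = FALSE) {
  D <- nrow(X)
  ll_trace <- numeric(0)
  gamma <- NULL
  for (it in seq_len(max_iter)) {
    ll_obs <- emission_loglik(X, covs)
    gamma <- matrix(0, ncol(X), K)
    xi <- matrix(0, K, K)
    first_cols <- integer(0)
    ll <- 0
    for (seg in segments) {
      idx <- seg[1]:seg[2]
      fb <- .fb_segment(ll_obs[idx, , drop = FALSE], trans, init)
      gamma[idx, ] <- fb$gamma
      xi <- xi + fb$xi
      ll <- ll + fb$loglik
      first_cols <- c(first_cols, seg[1])
    }
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && abs(ll - ll_trace[it - 1L]) <=
        tol * abs(ll_trace[it - 1L])) break
    # M-step
    if (!frozen_covs) {
      sc <- .weighted_scatter(X, gamma)
      covs <- lapply(seq_len(K), function(k)
        regularized_cov(sc$scatter[, , k], sc$n[k], D))
    }
    trans <- xi + 1e-12
    trans <- trans / rowSums(trans)
    init <- colMeans(gamma[first_cols, , drop = FALSE]) + 1e-12
    init <- init / sum(init)
  }
  list(covs = covs, trans = trans, init = init, gamma = gamma,
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace)
}

make_timecourse <- function(gamma, X, segments, covs, trans, init,
                            samples, fs) {
  ll_obs <- emission_loglik(X, covs)
  vit <- integer(ncol(X))
  for (seg in segments) {
    idx <- seg[1]:seg[2]
    vit[idx] <- .viterbi_segment(ll_obs[idx, , drop = FALSE], trans, init)
  }
  structure(list(gamma = t(gamma), viterbi = vit, samples = samples,
                 valid_range = range(samples), fs = fs),
            class = "state_timecourse")
}

#' Fit the TDE-HMM by multi-restart Baum-Welch EM
#'
#' Zero-mean full-covariance Gaussian emissions on the PCA-reduced
#' embedded data. Each restart initializes state responsibilities at
#' random; the restart with the highest final log-likelihood is kept.
#' Bad-sample gaps break the chain: forward-backward runs per contiguous
#' segment and no transitions are counted across gaps.
#'
#' @param reduced a `tde_reduced` object.
#' @param K number of states.
#' @param n_restarts number of EM restarts (default 5).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param tol relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param seed RNG seed; restart r uses a sub-seed derived from it.
#' @return List with `model` (class `hmm_model`: `K`, `covariances`,
#'   `transition`, `initial`, `pca_basis`, `row_means`, `embedding`,
#'   `objective`, `ll_trace`, `restart_logliks`) and `timecourse`
#'   (class `state_timecourse`: `gamma` K x T_valid, `viterbi`,
#'   `samples`, `valid_range`).
#' @export
fit_hmm <- function(reduced, K, n_restarts = 5, max_iter = 500,
                    tol = 1e-6, seed = 1) {
  stopifnot(inherits(reduced, "tde_reduced"))
  X <- reduced$x
  D <- nrow(X)
  segments <- segment_columns(reduced$samples)
  best <- NULL
  restart_lls <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(sub_seed(seed, r))
    g0 <- matrix(rgamma(ncol(X) * K, shape = 1), ncol(X), K)
    g0 <- g0 / rowSums(g0)
    sc <- .weighted_scatter(X, g0)
    covs <- lapply(seq_len(K), function(k)
      regularized_cov(sc$scatter[, , k], sc$n[k], D))
    trans <- matrix((1 - 0.9) / max(1, K - 1), K, K)
    diag(trans) <- if (K > 1) 0.9 else 1
    init <- rep(1 / K, K)
    em <- run_em(X, segments, K, covs, trans, init, max_iter, tol)
    restart_lls[r] <- em$loglik
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }
  model <- structure(list(K = K, covariances = best$covs,
                          transition = best$trans, initial = best$init,
                          pca_basis = reduced$basis,
                          row_means = reduced$row_means,
                          embedding = list(l = reduced$l,
                                           n_channels = reduced$n_channels,
                                           pca_components = D),
                          objective = best$loglik,
                          ll_trace = best$ll_trace,
                          restart_logliks = restart_lls),
                     class = "hmm_model")
  tc <- make_timecourse(best$gamma, X, segments, best$covs, best$trans,
                        best$init, reduced$samples, reduced$fs)
  list(model = model, timecourse = tc)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> K=%d states, D=%d reduced dims, logLik %.2f (%d restarts)\n",
              x$K, nrow(x$covariances[[1]]), x$objective,
              length(x$restart_logliks)))
  invisible(x)
}

#' Decode posterior state probabilities under a fitted model
#'
#' @param model an `hmm_model`.
#' @param reduced a `tde_reduced` with matching dimensionality.
#' @return A `state_timecourse` (forward-backward `gamma`, Viterbi path).
#' @export
decode_states <- function(model, reduced) {
  X <- reduced$x
  if (nrow(X) != nrow(model$covariances[[1]]))
    stop(sprintf("data dimension %d does not match model dimension %d",
                 nrow(X), nrow(model$covariances[[1]])))
  segments <- segment_columns(reduced$samples)
  ll_obs <- emission_loglik(X, model$covariances)
  gamma <- matrix(0, ncol(X), model$K)
  vit <- integer(ncol(X))
  for (seg in segments) {
    idx <- seg[1]:seg[2]
    fb <- .fb_segment(ll_obs[idx, , drop = FALSE], model$transition,
                      model$initial)
    gamma[idx, ] <- fb$gamma
    vit[idx] <- .viterbi_segment(ll_obs[idx, , drop = FALSE],
                                 model$transition, model$initial)
  }
  structure(list(gamma = t(gamma), viterbi = vit,
                 samples = reduced$samples,
                 valid_range = range(reduced$samples), fs = reduced$fs),
            class = "state_timecourse")
}

#' Re-fit fixed emission states to new data
#'
#' Holds the state covariances fixed and re-estimates the transition
#' matrix and initial distribution by EM on a new recording (projected
#' with the model's stored PCA basis).
#'
#' @param model an `hmm_model`.
#' @param session a new [recording_session()] (same channel count), or a
#'   pre-projected `tde_reduced`.
#' @param max_iter,tol EM controls.
#' @return List with `timecourse` and `transition` (the refreshed matrix).
#' @export
dual_fit <- function(model, session, max_iter = 200, tol = 1e-6) {
  reduced <- if (inherits(session, "tde_reduced")) session
  else project_embedding(embed_session(session, model$embedding$l),
                         model$pca_basis, model$row_means)
  X <- reduced$x
  segments <- segment_columns(reduced$samples)
  em <- run_em(X, segments, model$K, model$covariances, model$transition,
               model$initial, max_iter, tol, frozen_covs = TRUE)
  tc <- make_timecourse(em$gamma, X, segments, model$covariances,
                        em$trans, em$init, reduced$samples, reduced$fs)
  list(timecourse = tc, transition = em$trans, ll_trace = em$ll_trace)
}

#' Expand a state time course to the full recording length
#'
#' @param tc a `state_timecourse`.
#' @param T total number of samples of the underlying recording.
#' @return K x T matrix of posteriors with `NA` at non-embeddable or bad
#'   samples.
#' @export
gamma_full <- function(tc, T) {
  out <- matrix(NA_real_, nrow(tc$gamma), T)
  out[, tc$samples] <- tc$gamma
  out
}
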