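#' Train per-stimulus sparse logistic decoders
#'
#' One-vs-rest L1-regularized logistic regression per stimulus, trained on
#' the single-sample feature vectors extracted at `time_ms` after stimulus
#' onset.
#'
#' @param localizer a [localizer_trials()] object.
#' @param time_ms training time (ms after stimulus onset); must map to a
#'   peri-stimulus sample.
#' @param l1_penalty lasso penalty (glmnet `lambda`).
#' @return An object of class `classifier_set` with fields `weights`
#'   (S x P), `intercepts`, `training_time_ms`, `l1_penalty` and a
#'   `degenerate` flag per stimulus (all-zero weights).
#' @export
train_classifiers <- function(localizer, time_ms, l1_penalty = 0.01) {
  stopifnot(inherits(localizer, "localizer_trials"))
  times_ms <- localizer_times(localizer) * 1000
  si <- which.min(abs(times_ms - time_ms))
  if (abs(times_ms[si] - time_ms) > 1000 / localizer$fs / 2 + 1e-9)
    stop(sprintf("time %g ms does not map to a peri-stimulus sample", time_ms))
  X <- localizer$trials[, , si]
  S <- localizer$n_stimuli
  if (length(unique(localizer$labels)) < 2L)
    stop("single-class labels: cannot train")
  P <- ncol(X)
  W <- matrix(0, S, P)
  b <- numeric(S)
  degen <- logical(S)
  for (s in seq_len(S)) {
    y <- as.integer(localizer$labels == s - 1L)
    cf <- lasso_logistic(X, y, l1_penalty)
    b[s] <- cf[1]
    W[s, ] <- cf[-1]
    degen[s] <- all(W[s, ] == 0)
  }
  if (any(degen))
    warning(sprintf("degenerate (all-zero) weights for stimulus %s at lambda=%g",
                    paste(which(degen), collapse = ","), l1_penalty))
  structure(list(weights = W, intercepts = b, training_time_ms = time_ms,
                 l1_penalty = l1_penalty, degenerate = degen),
            class = "classifier_set")
}

# L1 logistic fit at an exact lambda (the path includes it, so no
# interpolation is involved); returns c(intercept, weights)
lasso_logistic <- function(X, y, l1_penalty) {
  lam_seq <- sort(unique(c(exp(seq(log(1), log(max(l1_penalty, 1e-6)),
                                   length.out = 25)), l1_penalty)),
                  decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lam_seq, standardize = FALSE)
  j <- which.min(abs(fit$lambda - l1_penalty))
  c(fit$a0[j], as.numeric(fit$beta[, j]))
}

# cross-validated multi-class accuracy of one-vs-rest decoders trained at
# one peri-stimulus sample
cv_accuracy_at <- function(localizer, sample_idx, l1_penalty, n_folds,
                           fold_id) {
  X <- localizer$trials[, , sample_idx]
  y <- localizer$labels
  S <- localizer$n_stimuli
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    scores <- matrix(0, sum(!tr), S)
    for (s in seq_len(S)) {
      ys <- as.integer(y[tr] == s - 1L)
      cf <- lasso_logistic(X[tr, , drop = FALSE], ys, l1_penalty)
      scores[, s] <- X[!tr, , drop = FALSE] %*% cf[-1] + cf[1]
    }
    pred <- max.col(scores, ties.method = "first") - 1L
    acc[f] <- mean(pred == y[!tr])
  }
  mean(acc)
}

#' Pick the decoder training time by cross-validation
#'
#' Scans peri-stimulus times and returns the one maximizing mean
#' cross-validated multi-class accuracy; exact ties are broken by the
#' earliest time. If no time beats chance meaningfully the result carries
#' a `low_confidence` attribute.
#'
#' @param localizer a [localizer_trials()] object.
#' @param l1_penalty lasso penalty.
#' @param n_folds number of CV folds (>= 2).
#' @param times_ms candidate times; default all peri-stimulus samples.
#' @param seed RNG seed for the fold assignment.
#' @return Training time in ms, with attributes `accuracy` (per candidate)
#'   and possibly `low_confidence`.
#' @export
pick_training_time <- function(localizer, l1_penalty = 0.01, n_folds = 5,
                               times_ms = NULL, seed = 1) {
  stopifnot(n_folds >= 2)
  grid_ms <- localizer_times(localizer) * 1000
  if (is.null(times_ms)) times_ms <- grid_ms
  idx <- vapply(times_ms, function(tm) which.min(abs(grid_ms - tm)),
                integer(1))
  set.seed(seed)
  n <- length(localizer$labels)
  fold_id <- sample(rep(seq_len(n_folds), length.out = n))
  acc <- vapply(idx, cv_accuracy_at, numeric(1), localizer = localizer,
                l1_penalty = l1_penalty, n_folds = n_folds,
                fold_id = fold_id)
  best <- which(acc == max(acc))[1L]  # earliest on exact ties
  out <- times_ms[best]
  attr(out, "accuracy") <- setNames(acc, times_ms)
  chance <- 1 / localizer$n_stimuli
  if (max(acc) < chance + 2 * sqrt(chance * (1 - chance) / n)) {
    attr(out, "low_confidence") <- TRUE
    warning("no time point clearly beats chance accuracy; returning earliest maximum")
  }
  out
}

#' Apply decoders to a recording
#'
#' Computes per-stimulus reactivation probabilities
#' `probs[i, t] = sigmoid(X_t . beta_i + b_i)` for every sample. Bad
#' samples are carried through and flagged via the returned `bad_mask`.
#'
#' @param session a [recording_session()].
#' @param classifiers a `classifier_set`.
#' @return Object of class `reactivation_probs` with `probs` (S x T),
#'   `fs`, `bad_mask`, `stimulus_names`.
#' @export
apply_classifiers <- function(session, classifiers) {
  stopifnot(inherits(session, "recording_session"),
            inherits(classifiers, "classifier_set"))
  P <- nrow(session$data)
  if (ncol(classifiers$weights) != P)
    stop(sprintf("classifier expects %d channels, session has %d",
                 ncol(classifiers$weights), P))
  act <- classifiers$weights %*% session$data + classifiers$intercepts
  structure(list(probs = sigmoid(act), fs = session$fs,
                 bad_mask = session$bad_mask,
                 stimulus_names = sprintf("stim%d",
                                          seq_len(nrow(classifiers$weights)))),
            class = "reactivation_probs")
}

#' Lag-resolved sequence evidence
#'
#' For each lag, the mean lagged Pearson correlation between the decoder
#' traces of task-ordered stimulus pairs minus the same mean over all
#' other ordered pairs (control). Bad samples are excluded pairwise;
#' constant traces contribute a zero correlation (logged).
#'
#' @param probs a `reactivation_probs`.
#' @param pairs 2-column matrix of task-ordered stimulus pairs (1-based).
#' @param lags_ms numeric vector of candidate lags (ms); converted by
#'   `round(lag_ms * fs / 1000)`.
#' @return Data frame with columns `lag_ms`, `lag_samples`, `evidence`,
#'   `task_mean`, `control_mean`.
#' @export
sequence_evidence <- function(probs, pairs,
                              lags_ms = seq(10, 200, by = 10)) {
  stopifnot(inherits(probs, "reactivation_probs"))
  S <- nrow(probs$probs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs < 1L | pairs > S)) stop("pairs reference invalid stimuli")
  all_pairs <- as.matrix(expand.grid(i = seq_len(S), j = seq_len(S)))
  all_pairs <- all_pairs[all_pairs[, 1] != all_pairs[, 2], , drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2])
  is_task <- key(all_pairs) %in% key(pairs)
  good <- !probs$bad_mask
  T <- ncol(probs$probs)
  out <- lapply(lags_ms, function(lm) {
    tau <- as.integer(round(lm * probs$fs / 1000))
    if (tau < 1L || tau >= T) stop("lag out of range")
    t1 <- 1:(T - tau)
    v <- good[t1] & good[t1 + tau]
    cors <- apply(all_pairs, 1L, function(pr) {
      a <- probs$probs[pr[1], t1][v]
      b <- probs$probs[pr[2], t1 + tau][v]
      if (sd(a) == 0 || sd(b) == 0) {
        message("sequence_evidence: constant trace; correlation set to 0")
        return(0)
      }
      cor(a, b)
    })
    data.frame(lag_ms = lm, lag_samples = tau,
               task_mean = mean(cors[is_task]),
               control_mean = mean(cors[!is_task]))
  })
  res <- do.call(rbind, out)
  res$evidence <- res$task_mean - res$control_mean
  res[, c("lag_ms", "lag_samples", "evidence", "task_mean", "control_mean")]
}

#' Replay probability trace
#'
#' Combines the six lagged two-item sequence probabilities of two ordered
#' four-item chains: each pair's joint probability is the product of the
#' two reactivation probabilities (independence reading of AND) and the
#' union is a noisy-OR, `R_t = 1 - prod(1 - joint)`. The last `tau`
#' samples are invalid (`NA`).
#'
#' @param probs a `reactivation_probs`.
#' @param chains list of two ordered integer vectors (stimulus chains).
#' @param tau lag in samples (>= 1).
#' @return Numeric vector `R_t` of length T in `[0, 1]` with attribute
#'   `tau`.
#' @export
replay_probability <- function(probs, chains, tau) {
  stopifnot(inherits(probs, "reactivation_probs"), tau >= 1L)
  items <- unlist(chains)
  if (anyDuplicated(items)) stop("chains must reference distinct stimuli")
  prs <- do.call(rbind, lapply(chains, function(ch)
    cbind(ch[-length(ch)], ch[-1])))
  T <- ncol(probs$probs)
  t1 <- 1:(T - tau)
  one_minus <- rep(1, length(t1))
  for (r in seq_len(nrow(prs))) {
    joint <- probs$probs[prs[r, 1], t1] * probs$probs[prs[r, 2], t1 + tau]
    one_minus <- one_minus * (1 - joint)
  }
  R <- c(1 - one_minus, rep(NA_real_, tau))
  attr(R, "tau") <- as.integer(tau)
  R
}

#' Threshold the replay trace into events
#'
#' The threshold is the stated percentile of the valid trace (bad and NA
#' samples excluded); events are the onsets of suprathreshold runs, with
#' runs closer than `merge_within` samples merged.
#'
#' @param trace replay probability trace (from [replay_probability()]).
#' @param fs sampling rate (Hz).
#' @param percentile percentile in (0, 100) (default 99).
#' @param merge_within merge runs with onset gaps smaller than this many
#'   samples; defaults to the trace's `tau` attribute (or 0).
#' @param bad_mask optional logical bad-sample mask.
#' @return Object of class `replay_events` with fields `trace`,
#'   `threshold`, `event_onsets`, `lag_samples`, `percentile`, `fs`.
#' @export
threshold_events <- function(trace, fs, percentile = 99,
                             merge_within = NULL, bad_mask = NULL) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  T <- length(trace)
  tau <- attr(trace, "tau") %||% 0L
  if (is.null(merge_within)) merge_within <- tau
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, T)
  valid <- !bad_mask & !is.na(trace)
  vals <- trace[valid]
  if (length(unique(vals)) == 1L) {
    warning("constant replay trace: no events")
    onsets <- integer(0)
    thr <- vals[1]
  } else {
    thr <- quantile(vals, percentile / 100, names = FALSE)
    above <- valid & trace >= thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    onsets <- starts[r$values]
    if (length(onsets) > 1L && merge_within > 0L) {
      run_ends <- ends[r$values]
      # successive runs each within merge_within of the previous run's
      # end collapse into the first onset
      merged <- onsets[1L]
      last_end <- run_ends[1L]
      for (i in seq_along(onsets)[-1L]) {
        if (onsets[i] - last_end > merge_within) {
          merged <- c(merged, onsets[i])
        }
        last_end <- run_ends[i]
      }
      onsets <- merged
    }
  }
  structure(list(trace = trace, threshold = thr,
                 event_onsets = as.integer(onsets),
                 lag_samples = as.integer(tau),
                 percentile = percentile, fs = fs),
            class = "replay_events")
}

#' @export
print.replay_events <- function(x, ...) {
  cat(sprintf("<replay_events> %d events, threshold %.4g (%gth percentile), lag %d samples\n",
              length(x$event_onsets), x$threshold, x$percentile,
              x$lag_samples))
  invisible(x)
}

#' Write detected events as TSV
#'
#' Columns: `subject`, `onset_sample`, `onset_sec`, `trace_value`.
#' @param events a `replay_events` object (or list of them).
#' @param path output file.
#' @param subject subject label(s).
#' @export
write_events_tsv <- function(events, path, subject = 1L) {
  if (inherits(events, "replay_events")) events <- list(events)
  df <- do.call(rbind, Map(function(ev, subj) {
    data.frame(subject = subj, onset_sample = ev$event_onsets,
               onset_sec = (ev$event_onsets - 1L) / ev$fs,
               trace_value = ev$trace[ev$event_onsets])
  }, events, as.list(rep(subject, length.out = length(events)))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
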