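#' Default pipeline configuration
#'
#' Stage parameters follow the published constants where they exist:
#' 99th-percentile event threshold, 40 ms inter-item lag, +-0.5 s evoked
#' epochs, cluster-forming t threshold 3, 5000 sign-flip and 1000
#' interval-shuffle permutations, 2 s / 0.5 Hz / 7-taper multitaper over
#' 1-45 Hz, 30 ms high-frequency windows, minimum 10 observations per
#' conditioned-interval cell, 5 EM restarts, and a K = 12 option
#' (fixtures default to K = 4 for speed).
#'
#' @param ... overrides of individual fields.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cf <- list(
    sim = default_sim_config(),
    train_time_ms = 200, l1_penalty = 0.01,
    percentile = 99, lag_ms = 40,
    hmm_K = 4L, embed_lags = 7L, pca_components = NULL,  # default 2P
    n_restarts = 5L, hmm_max_iter = 500L, hmm_tol = 1e-6,
    epoch_window_s = 0.5, t_threshold = 3, n_perm_cluster = 5000L,
    n_perm_shuffle = 1000L, min_obs = 10L,
    mt_window_s = 2, mt_n_tapers = 7L, mt_resolution_Hz = 0.5,
    mt_band = c(1, 45), hf_window_ms = 30,
    fano_windows_s = default_fano_grid(),
    run_sweep = FALSE, min_group_n = 5L
  )
  over <- list(...)
  for (nm in names(over)) cf[[nm]] <- over[[nm]]
  class(cf) <- "pipeline_config"
  cf
}

#' Smoke-scale configuration for quick end-to-end runs
#' @export
smoke_config <- function() {
  cf <- pipeline_config(n_restarts = 2L, n_perm_cluster = 500L,
                        n_perm_shuffle = 100L, hmm_max_iter = 100L)
  cf$sim$n_subjects <- 5L
  cf$sim$duration_s <- 60
  cf
}

# concatenate per-subject reduced embeddings, inserting index gaps so no
# transition is counted across subjects
concat_reduced <- function(reduced_list) {
  offset <- 0L
  xs <- list()
  samples <- integer(0)
  for (r in reduced_list) {
    xs[[length(xs) + 1L]] <- r$x
    samples <- c(samples, r$samples + offset)
    offset <- offset + max(r$samples) + 2L
  }
  out <- reduced_list[[1]]
  out$x <- do.call(cbind, xs)
  out$samples <- samples
  out$subject_col <- rep(seq_along(reduced_list),
                         vapply(reduced_list, function(r) ncol(r$x),
                                integer(1)))
  out
}

# split a concatenated timecourse back into per-subject timecourses
split_timecourse <- function(tc, reduced_list, subject_col) {
  lapply(seq_along(reduced_list), function(s) {
    cols <- which(subject_col == s)
    structure(list(gamma = tc$gamma[, cols, drop = FALSE],
                   viterbi = tc$viterbi[cols],
                   samples = reduced_list[[s]]$samples,
                   valid_range = range(reduced_list[[s]]$samples),
                   fs = reduced_list[[s]]$fs),
              class = "state_timecourse")
  })
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> detect -> fit-hmm -> label -> spectra -> evoked -> bursts,
#' with per-subject seeds derived as `seed + subject_index`. Writes TSV
#' tables and a machine-readable `summary.json` when `out_dir` is given.
#'
#' @param config a [pipeline_config()].
#' @param seed base seed.
#' @param out_dir optional output directory for artifacts.
#' @return A list report with all stage outputs (invisibly also written
#'   to `out_dir`).
#' @export
run_all <- function(config = pipeline_config(), seed = 1, out_dir = NULL) {
  cf <- config
  N <- cf$sim$n_subjects
  if (N < cf$min_group_n)
    stop(sprintf("group stages need at least %d subjects (got %d)",
                 cf$min_group_n, N))
  stage <- function(name, subject = NA, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s'%s failed: %s", name,
                   if (is.na(subject)) "" else sprintf(" (subject %d)", subject),
                   conditionMessage(e)), call. = FALSE))
  }

  subjects <- lapply(seq_len(N), function(s)
    stage("simulate", s, simulate_subject(seed + s, cf$sim)))
  T <- round(cf$sim$duration_s * cf$sim$fs)
  seqs <- default_sequences()
  tau <- ms_to_samples(cf$lag_ms, cf$sim$fs)

  # --- detection ---------------------------------------------------------
  det <- lapply(seq_len(N), function(s) {
    sub <- subjects[[s]]
    clf <- stage("detect", s,
                 train_classifiers(sub$localizer, cf$train_time_ms,
                                   cf$l1_penalty))
    probs <- apply_classifiers(sub$session, clf)
    ev_df <- sequence_evidence(probs, seqs$pairs)
    trace <- replay_probability(probs, seqs$chains, tau)
    events <- threshold_events(trace, cf$sim$fs, cf$percentile,
                               bad_mask = sub$session$bad_mask)
    list(classifiers = clf, probs = probs, evidence = ev_df,
         events = events)
  })
  group_evidence <- Reduce(`+`, lapply(det, function(d) d$evidence$evidence)) / N
  evidence_lags <- det[[1]]$evidence$lag_ms

  # --- TDE-HMM -----------------------------------------------------------
  Pn <- cf$sim$n_channels
  n_pca <- cf$pca_components %||% (2L * Pn)
  reduced_list <- lapply(seq_len(N), function(s) {
    emb <- embed_session(subjects[[s]]$session, cf$embed_lags)
    pca_reduce(emb, n_pca)
  })
  allred <- concat_reduced(reduced_list)
  fit <- stage("fit-hmm", NA,
               fit_hmm(allred, cf$hmm_K, cf$n_restarts, cf$hmm_max_iter,
                       cf$hmm_tol, seed = seed))
  tcs <- split_timecourse(fit$timecourse, reduced_list, allred$subject_col)

  # --- labeling ----------------------------------------------------------
  sdist <- transition_distance(fit$model$transition)
  perm <- mds_order(sdist)
  vstats <- lapply(tcs, visit_statistics, K = cf$hmm_K)

  # --- spectra -----------------------------------------------------------
  spectra <- stage("spectra", NA, {
    sp_list <- lapply(seq_len(N), function(s)
      state_multitaper(subjects[[s]]$session, tcs[[s]], cf$mt_window_s,
                       cf$mt_n_tapers, cf$mt_resolution_Hz, cf$mt_band))
    avg <- sp_list[[1]]
    avg$psd <- Reduce(`+`, lapply(sp_list, `[[`, "psd")) / N
    avg$coherence <- Reduce(`+`, lapply(sp_list, `[[`, "coherence")) / N
    avg
  })
  modes2 <- nnmf_modes(spectra, 2L, seed = seed)

  # --- evoked ------------------------------------------------------------
  ev_bc <- lapply(seq_len(N), function(s)
    stage("evoked", s, epoch_states(tcs[[s]], det[[s]]$events$event_onsets,
                                    T, cf$epoch_window_s)))
  group_bc <- group_evoked(ev_bc)
  clusters <- cluster_permutation(group_bc, cf$t_threshold,
                                  cf$n_perm_cluster, seed = seed)
  sweep_res <- if (isTRUE(cf$run_sweep)) {
    lapply(seq_len(N), function(s)
      threshold_sweep(det[[s]]$events$trace, tcs[[s]], T,
                      window_s = cf$epoch_window_s,
                      bad_mask = subjects[[s]]$session$bad_mask))
  } else NULL

  # --- bursts ------------------------------------------------------------
  events_list <- lapply(det, function(d) d$events$event_onsets)
  bad_list <- lapply(subjects, function(s) s$session$bad_mask)
  fano <- fano_matrix(events_list, T, cf$sim$fs, bad_list,
                      cf$fano_windows_s)
  shuffle <- interval_shuffle_test(events_list, T, cf$sim$fs,
                                   cf$n_perm_shuffle, cf$fano_windows_s,
                                   seed = seed, bad_masks = bad_list)
  svf <- state_visit_fano(vstats, T, cf$sim$fs, cf$fano_windows_s)
  ci <- lapply(seq_len(N), function(s)
    conditioned_intervals(events_list[[s]], tcs[[s]], T,
                          bad_list[[s]], cf$min_obs))
  ci_tests <- tryCatch(conditioned_interval_tests(ci),
                       error = function(e) list(error = conditionMessage(e)))

  # --- invariant checks --------------------------------------------------
  gam_sums <- range(colSums(fit$timecourse$gamma))
  checks <- list(
    gamma_columns_sum_to_1 = abs(gam_sums - 1) < 1e-6,
    evoked_sums_to_0 = max(abs(apply(group_bc$values, c(2, 3), sum))) < 1e-6,
    rt_in_unit_interval = all(det[[1]]$events$trace >= 0 &
                                det[[1]]$events$trace <= 1, na.rm = TRUE)
  )

  report <- list(
    config = cf, seed = seed,
    truth = lapply(subjects, `[[`, "truth"),
    sessions = subjects,
    detection = det, evidence_lags = evidence_lags,
    group_evidence = group_evidence,
    hmm = fit, timecourses = tcs,
    state_distance = sdist, state_order = perm, visit_stats = vstats,
    spectra = spectra, modes = modes2,
    evoked = group_bc, clusters = clusters, sweep = sweep_res,
    fano = fano, shuffle = shuffle, state_visit_fano = svf,
    conditioned = ci, conditioned_tests = ci_tests,
    checks = checks
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# serialize the machine-readable summary of a pipeline report
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev_df <- do.call(rbind, lapply(seq_along(report$detection), function(s) {
    ev <- report$detection[[s]]$events
    if (!length(ev$event_onsets)) return(NULL)
    data.frame(subject = s, onset_sample = ev$event_onsets,
               onset_sec = (ev$event_onsets - 1) / ev$fs,
               trace_value = ev$trace[ev$event_onsets])
  }))
  write.table(ev_df, file.path(out_dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lab <- state_label_table(report$state_distance, report$state_order,
                           report$visit_stats[[1]])
  write.table(lab, file.path(out_dir, "state_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cl <- do.call(rbind, lapply(seq_along(report$clusters$states), function(k) {
    cc <- report$clusters$states[[k]]$clusters
    if (!nrow(cc)) return(NULL)
    data.frame(state = k,
               lag_start_s = report$clusters$lags[cc$lag_start],
               lag_end_s = report$clusters$lags[cc$lag_end],
               mass = cc$mass, p = cc$p)
  }))
  if (!is.null(cl))
    write.table(cl, file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = report$seed,
    n_subjects = length(report$detection),
    n_events = vapply(report$detection, function(d)
      length(d$events$event_onsets), numeric(1)),
    evidence_lags_ms = report$evidence_lags,
    group_evidence = report$group_evidence,
    evidence_argmax_ms = report$evidence_lags[which.max(report$group_evidence)],
    hmm_loglik = report$hmm$model$objective,
    state_order = as.integer(report$state_order),
    occupancy = report$visit_stats[[1]]$occupancy,
    shuffle_reject = report$shuffle$reject,
    anova_max_p_bonferroni = report$state_visit_fano$anova_max_p_bonferroni,
    checks = report$checks
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# greedy (K <= 7: exhaustive) state matching; returns accuracy and the
# permutation mapping estimated -> true labels
match_states <- function(est, truth, K) {
  conf <- table(factor(est, levels = 1:K), factor(truth, levels = 1:K))
  if (K <= 7L) {
    perms <- permutations_of(K)
    accs <- vapply(seq_len(nrow(perms)), function(i)
      sum(conf[cbind(1:K, perms[i, ])]), numeric(1))
    best <- which.max(accs)
    list(accuracy = accs[best] / length(est),
         perm = unname(perms[best, ]))
  } else {
    perm <- integer(K)
    cc <- conf
    for (i in seq_len(K)) {
      ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      perm[ij[1]] <- ij[2]
      cc[ij[1], ] <- -1
      cc[, ij[2]] <- -1
    }
    acc <- sum(conf[cbind(1:K, perm)]) / length(est)
    list(accuracy = acc, perm = perm)
  }
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# greedy one-to-one event matching within a sample tolerance
match_events <- function(detected, planted, tol = 2L) {
  if (!length(detected) || !length(planted))
    return(list(precision = 0, recall = 0, n_matched = 0L))
  used <- rep(FALSE, length(planted))
  n_match <- 0L
  for (d in detected) {
    j <- which(!used & abs(planted - d) <= tol)
    if (length(j)) {
      used[j[1]] <- TRUE
      n_match <- n_match + 1L
    }
  }
  list(precision = n_match / length(detected),
       recall = sum(used) / length(planted), n_matched = n_match)
}

#' Compare a pipeline report against planted ground truth
#'
#' @param report output of [run_all()] on a synthetic fixture.
#' @param tol_samples event-matching tolerance (default 2 samples = 8 ms
#'   at 250 Hz).
#' @return list of recovery metrics: `state_accuracy` (best-permutation
#'   Viterbi match), `replay_precision`/`replay_recall` (per subject),
#'   `evoked_coupling_positive` (planted coupled states' lag-0 group
#'   evoked > 0), `fano_reject_10s` (interval-shuffle rejection at
#'   W >= 10 s).
#' @export
validate_against_truth <- function(report, tol_samples = 2L) {
  if (is.null(report$truth)) stop("report carries no ground truth")
  K <- report$hmm$model$K
  est <- unlist(lapply(report$timecourses, `[[`, "viterbi"))
  tru <- unlist(lapply(seq_along(report$truth), function(s)
    report$truth[[s]]$state_path[report$timecourses[[s]]$samples]))
  sm <- match_states(est, tru, K)
  pr <- lapply(seq_along(report$detection), function(s)
    match_events(report$detection[[s]]$events$event_onsets,
                 report$truth[[s]]$replay_times, tol_samples))
  lag0 <- which.min(abs(report$evoked$lags))
  coupled_true <- report$truth[[1]]$coupled_states
  # translate planted coupled states into fitted-state indices
  coupled_est <- which(sm$perm %in% coupled_true)
  evoked_pos <- report$evoked$mean[coupled_est, lag0] > 0
  w10 <- report$shuffle$window_s >= 10
  list(state_accuracy = sm$accuracy, state_perm = sm$perm,
       replay_precision = vapply(pr, `[[`, numeric(1), "precision"),
       replay_recall = vapply(pr, `[[`, numeric(1), "recall"),
       evoked_coupling_positive = evoked_pos,
       fano_reject_10s = all(report$shuffle$reject[w10]))
}
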