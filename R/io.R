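#' Write a synthetic fixture to a plain-text directory
#'
#' Serializes one subject's fixture (session, wideband twin, localizer,
#' ground truth) as TSV matrices plus a JSON metadata file, so fixtures
#' round-trip without binary formats.
#'
#' @param subject output of [simulate_subject()] (fields `session`,
#'   `wideband`, `localizer`, `truth`; missing fields are skipped).
#' @param dir output directory (created).
#' @param digits significant digits kept for signal data (default 6).
#' @export
write_fixture <- function(subject, dir, digits = 6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) write.table(signif(m, digits), file.path(dir, f),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE, col.names = FALSE)
  meta <- list()
  if (!is.null(subject$session)) {
    wm(subject$session$data, "session_data.tsv")
    meta$session <- list(fs = subject$session$fs,
                         channel_names = subject$session$channel_names,
                         bad = which(subject$session$bad_mask))
  }
  if (!is.null(subject$wideband)) {
    wm(subject$wideband$data, "wideband_data.tsv")
    meta$wideband <- list(fs = subject$wideband$fs,
                          bad = which(subject$wideband$bad_mask))
  }
  if (!is.null(subject$localizer)) {
    loc <- subject$localizer
    d <- dim(loc$trials)
    wm(matrix(loc$trials, d[1], d[2] * d[3]), "localizer_trials.tsv")
    if (!is.null(loc$patterns)) wm(loc$patterns, "localizer_patterns.tsv")
    meta$localizer <- list(dim = d, labels = loc$labels, fs = loc$fs,
                           t0_offset = loc$t0_offset)
  }
  if (!is.null(subject$truth)) {
    meta$truth <- unclass(subject$truth)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#' @param dir fixture directory.
#' @return list with the available fields `session`, `wideband`,
#'   `localizer`, `truth`.
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rm_ <- function(f) as.matrix(read.table(file.path(dir, f), sep = "\t"))
  out <- list()
  if (!is.null(meta$session)) {
    dat <- unname(rm_("session_data.tsv"))
    bad <- rep(FALSE, ncol(dat))
    bad[meta$session$bad] <- TRUE
    out$session <- recording_session(dat, meta$session$fs, bad,
                                     meta$session$channel_names)
  }
  if (!is.null(meta$wideband)) {
    dat <- unname(rm_("wideband_data.tsv"))
    bad <- rep(FALSE, ncol(dat))
    bad[meta$wideband$bad] <- TRUE
    out$wideband <- recording_session(dat, meta$wideband$fs, bad)
  }
  if (!is.null(meta$localizer)) {
    d <- meta$localizer$dim
    trials <- array(unname(rm_("localizer_trials.tsv")), dim = d)
    patt_f <- file.path(dir, "localizer_patterns.tsv")
    patterns <- if (file.exists(patt_f)) unname(rm_("localizer_patterns.tsv"))
    else NULL
    out$localizer <- localizer_trials(trials, meta$localizer$labels,
                                      meta$localizer$fs,
                                      meta$localizer$t0_offset, patterns)
  }
  if (!is.null(meta$truth)) {
    out$truth <- ground_truth(meta$truth$state_path,
                              meta$truth$replay_times,
                              meta$truth$replay_lag_ms,
                              meta$truth$coupled_states,
                              meta$truth$hf_state)
  }
  out
}
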