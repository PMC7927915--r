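#' Recording session container
#'
#' The universal signal container used throughout the pipeline: a channels
#' x time matrix with its sampling rate and a per-sample bad-data mask.
#'
#' @param data numeric matrix, channels P x samples T.
#' @param fs sampling rate in Hz (> 0).
#' @param bad_mask logical vector of length T; `TRUE` marks bad samples.
#'   Defaults to all good.
#' @param channel_names optional character vector of length P.
#' @return An object of class `recording_session` with fields `data`,
#'   `fs`, `bad_mask`, `channel_names`.
#' @export
recording_session <- function(data, fs, bad_mask = NULL,
                              channel_names = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("session data contains NaN/Inf")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  T <- ncol(data)
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, T)
  bad_mask <- as.logical(bad_mask)
  if (length(bad_mask) != T)
    stop(sprintf("bad_mask length %d != number of samples %d",
                 length(bad_mask), T))
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  structure(list(data = data, fs = fs, bad_mask = bad_mask,
                 channel_names = channel_names),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %d channels x %d samples @ %g Hz (%.1f s), %d bad samples\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              sum(x$bad_mask)))
  invisible(x)
}

#' Functional localizer trials
#'
#' Peri-stimulus trial data used to train stimulus decoders.
#'
#' @param trials numeric array, n_trials x channels x peri-stimulus
#'   samples.
#' @param labels integer stimulus index per trial, in `0:(S-1)`.
#' @param fs sampling rate in Hz.
#' @param t0_offset time (s) of the first peri-stimulus sample relative to
#'   stimulus onset.
#' @param patterns optional S x P matrix of the true spatial patterns
#'   (synthetic fixtures only).
#' @return An object of class `localizer_trials`.
#' @export
localizer_trials <- function(trials, labels, fs, t0_offset = 0,
                             patterns = NULL) {
  stopifnot(length(dim(trials)) == 3L)
  labels <- as.integer(labels)
  S <- max(labels) + 1L
  if (any(labels < 0L)) stop("labels must be in 0..S-1")
  if (any(tabulate(labels + 1L, nbins = S) < 2L))
    stop("every stimulus must appear at least twice (cross-validation)")
  if (dim(trials)[1] != length(labels))
    stop("number of trials does not match labels")
  structure(list(trials = trials, labels = labels, fs = fs,
                 t0_offset = t0_offset, n_stimuli = S,
                 patterns = patterns),
            class = "localizer_trials")
}

# times (s) of each peri-stimulus sample relative to stimulus onset
localizer_times <- function(loc) {
  loc$t0_offset + (seq_len(dim(loc$trials)[3]) - 1L) / loc$fs
}

#' Planted ground truth for a synthetic fixture
#'
#' @param state_path integer vector (1-based states) of length T.
#' @param replay_times strictly increasing sample indices of planted
#'   sequence onsets (1-based).
#' @param replay_lag_ms planted inter-item lag in ms.
#' @param coupled_states state indices during which replay bursts occur.
#' @param hf_state state index carrying high-frequency bursts.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(state_path, replay_times, replay_lag_ms,
                         coupled_states, hf_state) {
  state_path <- as.integer(state_path)
  replay_times <- as.integer(replay_times)
  if (is.unsorted(replay_times, strictly = TRUE))
    stop("replay_times must be strictly increasing")
  if (length(replay_times) &&
      (min(replay_times) < 1L || max(replay_times) > length(state_path)))
    stop("replay_times outside the recording")
  structure(list(state_path = state_path, replay_times = replay_times,
                 replay_lag_ms = replay_lag_ms,
                 coupled_states = as.integer(coupled_states),
                 hf_state = as.integer(hf_state)),
            class = "ground_truth")
}
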