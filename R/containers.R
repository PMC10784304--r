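#' Continuous EEG recording
#'
#' One session of continuous multi-channel EEG. Amplitudes are in
#' microvolts throughout the package.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#'   Rownames, if present, must match the montage labels.
#' @param rate sampling rate in Hz (default 256).
#' @param montage an [montage()] object; rows of `data` follow its
#'   channel order.
#' @param session_id integer session index (1-based).
#' @param participant_id participant identifier.
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(data, rate = 256, montage = biosemi64_montage(),
                      session_id = 1L, participant_id = "P01") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (rate <= 0) stop("rate must be positive")
  if (nrow(data) != length(montage$channel_names))
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage$channel_names), " channels")
  if (!all(is.finite(data))) stop("data contains non-finite amplitudes")
  rownames(data) <- montage$channel_names
  structure(list(data = data, rate = rate, montage = montage,
                 session_id = as.integer(session_id),
                 participant_id = participant_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s session %d: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$session_id, nrow(x$data), ncol(x$data),
              x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

valid_levels_db <- c(50, 60, 70)
valid_roles <- c("target", "nontarget", "frequent")

#' Per-trial stimulus event table
#'
#' One row per trial: the stimulus onset (0-based sample index into the
#' session recording), its sound level in dB, its role under the
#' session's target definition, and bookkeeping indices.
#'
#' @param onset_sample integer vector of 0-based onset samples, strictly
#'   increasing within a session.
#' @param level_db stimulus level; one of 50, 60, 70.
#' @param role one of `"target"`, `"nontarget"`, `"frequent"`.
#' @param trial_index 1-based trial number within the session.
#' @param session_id session index.
#' @param rate sampling rate the onsets refer to, stored as an attribute
#'   (default 256).
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(onset_sample, level_db, role, trial_index,
                        session_id, rate = 256) {
  df <- data.frame(onset_sample = as.integer(onset_sample),
                   level_db = as.numeric(level_db),
                   role = as.character(role),
                   trial_index = as.integer(trial_index),
                   session_id = as.integer(session_id),
                   stringsAsFactors = FALSE)
  attr(df, "rate") <- rate
  class(df) <- c("event_table", "data.frame")
  validate_event_table(df)
  df
}

validate_event_table <- function(df) {
  bad <- which(!df$level_db %in% valid_levels_db)
  if (length(bad))
    stop("invalid level_db ", df$level_db[bad[1]], " at row ", bad[1])
  bad <- which(!df$role %in% valid_roles)
  if (length(bad))
    stop("invalid role '", df$role[bad[1]], "' at row ", bad[1])
  for (s in unique(df$session_id)) {
    on <- df$onset_sample[df$session_id == s]
    if (length(on) > 1 && any(diff(on) <= 0)) {
      r <- which(df$session_id == s)[which(diff(on) <= 0)[1] + 1]
      stop("onset_sample not strictly increasing at row ", r,
           " (session ", s, ")")
    }
  }
  invisible(df)
}

#' Epoched EEG trials
#'
#' A trials x channels x samples array with a shared time axis (ms,
#' relative to stimulus onset) and per-trial labels.
#'
#' @param data numeric array, trials x channels x samples.
#' @param times_ms numeric vector of sample times in ms.
#' @param labels character vector of trial roles.
#' @param level_db numeric vector of trial stimulus levels.
#' @param rate sampling rate in Hz.
#' @param channels channel labels (length = dim 2).
#' @param participant_id,session_id,trial_index provenance.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, times_ms, labels, level_db, rate, channels,
                      participant_id = NA_character_, session_id = NA_integer_,
                      trial_index = seq_len(dim(data)[1])) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(times_ms))
    stop("times_ms length must match sample dimension")
  if (dim(data)[1] != length(labels))
    stop("labels length must match trial count")
  if (dim(data)[2] != length(channels))
    stop("channels length must match channel dimension")
  structure(list(data = data, times_ms = times_ms,
                 labels = as.character(labels),
                 level_db = as.numeric(level_db), rate = rate,
                 channels = as.character(channels),
                 participant_id = participant_id,
                 session_id = as.integer(session_id),
                 trial_index = as.integer(trial_index)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate,
              min(x$times_ms), max(x$times_ms)))
  tb <- table(x$labels)
  cat(" ", paste(names(tb), tb, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Vectorized classification features
#'
#' One row per trial (or per averaged exemplar), columns ordered
#' channel-major (all samples of channel 1, then channel 2, ...).
#'
#' @param x numeric feature matrix.
#' @param labels factor of class labels (`"target"` / `"nontarget"`).
#' @param groups data.frame of provenance (participant, session, trial).
#' @param channels,times_ms the channel and time grid behind the columns.
#' @param level_db per-row stimulus level (NA for averaged exemplars of
#'   mixed level).
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, groups, channels, times_ms,
                           level_db = rep(NA_real_, nrow(x))) {
  stopifnot(nrow(x) == length(labels))
  if (ncol(x) != length(channels) * length(times_ms))
    stop("column count must equal channels x samples")
  structure(list(x = x, labels = factor(labels,
                                        levels = c("nontarget", "target")),
                 groups = groups, channels = channels,
                 times_ms = times_ms, level_db = level_db),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d rows x %d features (%d channels x %d samples)\n",
              nrow(x$x), ncol(x$x), length(x$channels), length(x$times_ms)))
  print(table(x$labels))
  invisible(x)
}

#' Reshape a feature matrix back into an epoch array
#'
#' Inverse of the channel-major vectorization: returns a trials x
#' channels x samples array.
#'
#' @param fm a [feature_matrix()].
#' @return numeric array.
#' @export
feature_array <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$x); nc <- length(fm$channels); ns <- length(fm$times_ms)
  # columns are (channel 1: s1..sns, channel 2: ...), so fill sample-first
  arr <- array(0, dim = c(n, nc, ns))
  for (ci in seq_len(nc))
    arr[, ci, ] <- fm$x[, (ci - 1L) * ns + seq_len(ns), drop = FALSE]
  dimnames(arr) <- list(NULL, fm$channels, NULL)
  arr
}
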