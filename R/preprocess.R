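#' Preprocessing pipeline configuration
#'
#' Parameters of the fixed preprocessing chain: startle-trial removal,
#' Butterworth band-pass on the continuous record, epoching, baseline
#' correction, decimation to 32 Hz, channel selection and channel-major
#' vectorization.
#'
#' @param n_discard_initial trials removed at the start of each session
#'   (startle suppression; default 5).
#' @param band_low_hz,band_high_hz band-pass corner frequencies (0.1-8).
#' @param filter_order Butterworth design order of the band-pass
#'   (order 2 gives 4 poles in total).
#' @param zero_phase if `TRUE`, apply the filter forward and backward
#'   (zero phase lag); the default single forward pass is causal, as an
#'   online system would be.
#' @param epoch_window_ms half-open epoch window relative to stimulus
#'   onset; the default `c(-100, 900)` gives 256 samples at 256 Hz.
#' @param baseline_window_ms pre-stimulus baseline window.
#' @param decim_factor decimation factor (8: 256 Hz -> 32 Hz).
#' @param anti_alias add an extra low-pass before decimation. Off by
#'   default: the band-pass already limits the signal to 8 Hz, the new
#'   Nyquist frequency.
#' @param channel_set `"all64"`, `"roi47"`, `"cz"`, or a character
#'   vector of labels.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_discard_initial = 5, band_low_hz = 0.1,
                            band_high_hz = 8, filter_order = 2,
                            zero_phase = FALSE,
                            epoch_window_ms = c(-100, 900),
                            baseline_window_ms = c(-100, 0),
                            decim_factor = 8, anti_alias = FALSE,
                            channel_set = "all64") {
  if (baseline_window_ms[1] < epoch_window_ms[1] ||
      baseline_window_ms[2] > epoch_window_ms[2])
    stop("baseline window must lie within the epoch window")
  structure(list(n_discard_initial = n_discard_initial,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = filter_order, zero_phase = zero_phase,
                 epoch_window_ms = epoch_window_ms,
                 baseline_window_ms = baseline_window_ms,
                 decim_factor = decim_factor, anti_alias = anti_alias,
                 channel_set = channel_set),
            class = "pipeline_config")
}

#' Remove the initial trials of each session
#'
#' Drops the first `n` trials (by `trial_index`) of every session in the
#' table, removing startle-reaction contamination at session start.
#' Surviving trial indices are preserved.
#'
#' @param events an [event_table()].
#' @param n number of initial trials to drop per session.
#' @return An [event_table()].
#' @export
drop_initial_trials <- function(events, n = 5) {
  stopifnot(inherits(events, "event_table"), n >= 0)
  keep <- unlist(lapply(split(seq_len(nrow(events)), events$session_id),
                        function(ix) {
    if (n == 0) return(ix)
    thr <- sort(events$trial_index[ix])
    if (n >= length(ix)) {
      warning("n >= trial count; all trials of session ",
              events$session_id[ix[1]], " removed")
      return(integer(0))
    }
    ix[events$trial_index[ix] > thr[n]]
  }), use.names = FALSE)
  out <- events[sort(keep), , drop = FALSE]
  attr(out, "rate") <- attr(events, "rate")
  class(out) <- class(events)
  rownames(out) <- NULL
  out
}

#' Butterworth band-pass filter a continuous recording
#'
#' Band-pass of design order `order` (2 * `order` poles in total),
#' applied independently to each channel. The default is a causal
#' single forward pass; `zero_phase = TRUE` uses forward-backward
#' filtering instead.
#'
#' @param rec an [recording()].
#' @param low,high corner frequencies in Hz; `0 < low < high < rate/2`.
#' @param order Butterworth design order (default 2).
#' @param zero_phase forward-backward filtering if `TRUE`.
#' @return Filtered [recording()], same shape and rate.
#' @export
bandpass <- function(rec, low = 0.1, high = 8, order = 2,
                     zero_phase = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("need 0 < low < high < rate/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  if (any(abs(polyroot(rev(bf$a))) >= 1))
    stop("unstable filter design (band edge too close to Nyquist)")
  out <- rec
  for (ci in seq_len(nrow(rec$data))) {
    out$data[ci, ] <- if (zero_phase)
      as.numeric(signal::filtfilt(bf, rec$data[ci, ]))
    else
      as.numeric(signal::filter(bf, rec$data[ci, ]))
  }
  out
}

# ms boundaries need not be sample-aligned (100 ms is 25.6 samples at
# 256 Hz); boundaries round to the nearest sample, keeping the window
# length exact when the window spans whole seconds
ms_to_samples <- function(ms, rate) {
  as.integer(round(ms * rate / 1000))
}

#' Extract per-trial epochs from a continuous recording
#'
#' One epoch per event row over the half-open window
#' `[window_ms[1], window_ms[2])` relative to stimulus onset; the
#' default window gives 256 samples at 256 Hz.
#'
#' @param rec an [recording()].
#' @param events an [event_table()] for the same session.
#' @param window_ms epoch window in ms.
#' @return An [epoch_set()] (trials x channels x samples).
#' @export
extract_epochs <- function(rec, events, window_ms = c(-100, 900)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(events, "event_table"))
  rate <- rec$rate
  s0 <- ms_to_samples(window_ms[1], rate)
  s1 <- ms_to_samples(window_ms[2], rate)
  len <- s1 - s0
  n <- ncol(rec$data)
  arr <- array(0, dim = c(nrow(events), nrow(rec$data), len))
  for (tr in seq_len(nrow(events))) {
    a <- events$onset_sample[tr] + s0        # 0-based first sample
    if (a < 0 || a + len > n)
      stop("epoch window for trial ", events$trial_index[tr],
           " exceeds the recording bounds")
    arr[tr, , ] <- rec$data[, (a + 1):(a + len)]
  }
  times <- (s0 + seq_len(len) - 1) / rate * 1000
  epoch_set(arr, times, events$role, events$level_db, rate,
            rec$montage$channel_names,
            participant_id = rec$participant_id,
            session_id = rec$session_id, trial_index = events$trial_index)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' from the whole epoch.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_window_ms baseline window in ms (half-open).
#' @return Corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, baseline_window_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times_ms >= baseline_window_ms[1] &
    epochs$times_ms < baseline_window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over sample dim
  epochs
}

#' Decimate epochs
#'
#' Keeps every `factor`-th sample starting at the first and divides the
#' rate by `factor`. No additional filtering by default (the band-pass
#' has already limited the signal below the new Nyquist frequency); set
#' `anti_alias = TRUE` to apply a zero-phase Butterworth low-pass at
#' 80 % of the new Nyquist first.
#'
#' @param epochs an [epoch_set()].
#' @param factor decimation factor; must divide the sample count.
#' @param anti_alias add a protective low-pass before decimation.
#' @return Decimated [epoch_set()].
#' @export
decimate_epochs <- function(epochs, factor = 8, anti_alias = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  ns <- dim(epochs$data)[3]
  if (ns %% factor != 0)
    stop("sample count ", ns, " not divisible by factor ", factor)
  if (factor == 1) return(epochs)
  if (anti_alias) {
    bf <- signal::butter(4, 0.8 / factor, type = "low")
    for (tr in seq_len(dim(epochs$data)[1]))
      for (ci in seq_len(dim(epochs$data)[2]))
        epochs$data[tr, ci, ] <-
          as.numeric(signal::filtfilt(bf, epochs$data[tr, ci, ]))
  }
  keep <- seq(1, ns, by = factor)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$times_ms <- epochs$times_ms[keep]
  epochs$rate <- epochs$rate / factor
  epochs
}

resolve_channel_set <- function(channel_set) {
  if (length(channel_set) == 1 && channel_set %in% c("all64", "roi47", "cz"))
    switch(channel_set, all64 = biosemi64_labels(),
           roi47 = roi47_channels(), cz = "Cz")
  else as.character(channel_set)
}

#' Restrict epochs to a channel subset
#'
#' Channels are restricted and reordered to the canonical order of the
#' requested set: `"all64"` (identity), `"roi47"` (the 47-channel
#' central/parietal/occipital region of interest), `"cz"` (Cz only), or
#' an explicit label vector.
#'
#' @param epochs an [epoch_set()].
#' @param channel_set set name or label vector.
#' @return An [epoch_set()] with the selected channels.
#' @export
select_channels <- function(epochs, channel_set = "all64") {
  stopifnot(inherits(epochs, "epoch_set"))
  want <- resolve_channel_set(channel_set)
  miss <- setdiff(want, epochs$channels)
  if (length(miss))
    stop("channels not present: ", paste(miss, collapse = ", "))
  idx <- match(want, epochs$channels)
  epochs$data <- epochs$data[, idx, , drop = FALSE]
  epochs$channels <- want
  epochs
}

#' Vectorize epochs into a classification feature matrix
#'
#' One row per trial; columns ordered channel-major (all samples of the
#' first channel, then the second, ...). With `binary = TRUE` (the
#' default) trials with role `"frequent"` are excluded, leaving the
#' target-vs-nontarget problem.
#'
#' @param epochs an [epoch_set()] (typically decimated).
#' @param binary drop frequent-standard trials and use binary labels.
#' @return A [feature_matrix()].
#' @export
vectorize_epochs <- function(epochs, binary = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- if (binary) which(epochs$labels != "frequent")
  else seq_along(epochs$labels)
  d <- epochs$data[keep, , , drop = FALSE]
  n <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  x <- matrix(0, n, nc * ns)
  for (ci in seq_len(nc))
    x[, (ci - 1L) * ns + seq_len(ns)] <- d[, ci, ]
  groups <- data.frame(participant = rep(epochs$participant_id, n),
                       session = rep(epochs$session_id, n),
                       trial = epochs$trial_index[keep])
  feature_matrix(x, epochs$labels[keep], groups, epochs$channels,
                 epochs$times_ms, level_db = epochs$level_db[keep])
}

#' Run the full preprocessing chain on one session
#'
#' drop initial trials -> band-pass the continuous record -> epoch ->
#' baseline-correct -> decimate -> select channels -> vectorize.
#'
#' @param rec an [recording()].
#' @param events an [event_table()].
#' @param config a [pipeline_config()].
#' @return List with `features` (a [feature_matrix()] per the configured
#'   channel set) and `epochs` (baseline-corrected full-rate epochs for
#'   all channels, for ERP analysis).
#' @export
preprocess_session <- function(rec, events, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ev <- drop_initial_trials(events, config$n_discard_initial)
  filt <- bandpass(rec, config$band_low_hz, config$band_high_hz,
                   config$filter_order, config$zero_phase)
  ep <- extract_epochs(filt, ev, config$epoch_window_ms)
  ep <- baseline_correct(ep, config$baseline_window_ms)
  dec <- decimate_epochs(ep, config$decim_factor, config$anti_alias)
  dec <- select_channels(dec, config$channel_set)
  list(features = vectorize_epochs(dec, binary = TRUE), epochs = ep)
}
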