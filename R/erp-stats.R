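#' Condition-average ERP waveform
#'
#' Arithmetic mean over the trials of one condition, per channel and
#' sample, computed from baseline-corrected full-rate epochs.
#'
#' @param epochs an [epoch_set()].
#' @param condition trial role to average (`"target"`, `"nontarget"`,
#'   `"frequent"`).
#' @return Channels x samples matrix (class `erp_waveform`) with
#'   attributes `times_ms`, `n_trials`, `condition`, `rate`.
#' @export
condition_average <- function(epochs, condition = "target") {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- which(epochs$labels == condition)
  if (length(sel) == 0) stop("no trials of condition '", condition, "'")
  m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(m) <- epochs$channels
  structure(m, times_ms = epochs$times_ms, n_trials = length(sel),
            condition = condition, rate = epochs$rate,
            class = c("erp_waveform", "matrix", "array"))
}

#' Grand-average ERP across participants
#'
#' Mean of per-participant condition averages, with a pointwise normal
#' confidence band.
#'
#' @param waveforms list of `erp_waveform` matrices (same shape).
#' @param conf confidence level for the band (default 0.95).
#' @return List with `mean`, `lower`, `upper` (channels x samples) and
#'   `n_participants`.
#' @export
grand_average <- function(waveforms, conf = 0.95) {
  np <- length(waveforms)
  if (np < 1) stop("no waveforms")
  arr <- simplify2array(waveforms)          # ch x samples x participants
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), sd)
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * s / sqrt(np)
  list(mean = m, lower = m - half, upper = m + half, n_participants = np,
       times_ms = attr(waveforms[[1]], "times_ms"))
}

#' Mean ERP amplitude in 20-ms blocks
#'
#' Divides the epoch into consecutive `block_ms` blocks starting at the
#' first sample time; each sample is assigned to a block by its
#' timestamp and each block's value is the mean of its samples (at
#' 256 Hz a 20-ms block holds 5 or 6 samples).
#'
#' @param erp an `erp_waveform` from [condition_average()].
#' @param block_ms block width in ms (default 20).
#' @return Channels x blocks matrix with attributes `block_start_ms`
#'   and `samples_per_block`.
#' @export
block_amplitudes <- function(erp, block_ms = 20) {
  times <- attr(erp, "times_ms")
  rate <- attr(erp, "rate")
  if (block_ms < 1000 / rate)
    stop("block width smaller than the sample period")
  t0 <- times[1]
  block <- floor((times - t0) / block_ms)
  nb <- max(block) + 1
  out <- matrix(0, nrow(erp), nb)
  cnt <- integer(nb)
  for (b in seq_len(nb) - 1L) {
    sel <- block == b
    cnt[b + 1] <- sum(sel)
    out[, b + 1] <- rowMeans(erp[, sel, drop = FALSE])
  }
  rownames(out) <- rownames(erp)
  structure(out, block_start_ms = t0 + block_ms * (seq_len(nb) - 1),
            samples_per_block = cnt)
}

#' Across-participant ERP significance map
#'
#' Per channel x block, a paired two-sided Wilcoxon signed-rank test of
#' target vs nontarget block amplitudes across participants. No
#' multiple-comparison correction is applied by default.
#'
#' @param target_blocks,nontarget_blocks lists (one element per
#'   participant) of channels x blocks matrices from
#'   [block_amplitudes()], in matching participant order.
#' @param alpha significance threshold stored with the map.
#' @param correction a [stats::p.adjust()] method (default `"none"`).
#' @return Object of class `pvalue_map`: list with `p` and `statistic`
#'   (channels x blocks), `n`, `alpha`, `block_start_ms`.
#' @export
significance_map <- function(target_blocks, nontarget_blocks,
                             alpha = 0.05, correction = "none") {
  np <- length(target_blocks)
  if (np != length(nontarget_blocks))
    stop("participant lists differ in length")
  if (np < 3) stop("need at least 3 participants")
  dims <- dim(target_blocks[[1]])
  p <- matrix(NA_real_, dims[1], dims[2])
  w <- matrix(NA_real_, dims[1], dims[2])
  ta <- simplify2array(target_blocks)       # ch x blocks x participants
  na_ <- simplify2array(nontarget_blocks)
  for (ci in seq_len(dims[1])) {
    for (b in seq_len(dims[2])) {
      res <- suppressWarnings(
        wilcoxon_signed_rank(ta[ci, b, ], na_[ci, b, ]))
      p[ci, b] <- res$p.value
      w[ci, b] <- res$statistic
    }
  }
  if (correction != "none")
    p <- matrix(p.adjust(p, method = correction), dims[1], dims[2])
  rownames(p) <- rownames(w) <- rownames(target_blocks[[1]])
  structure(list(p = p, statistic = w, n = np, alpha = alpha,
                 block_start_ms = attr(target_blocks[[1]], "block_start_ms")),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  cat(sprintf("<pvalue_map> %d channels x %d blocks, n = %d participants\n",
              nrow(x$p), ncol(x$p), x$n))
  cat(sprintf("  %d cells with p < %g\n", sum(x$p < x$alpha, na.rm = TRUE),
              x$alpha))
  invisible(x)
}

#' Peak ERP amplitude in a time window
#'
#' Maximum of a condition-average waveform at one channel within a
#' window (default 300-500 ms, bracketing the P300 peak).
#'
#' @param erp an `erp_waveform`.
#' @param channel channel label (default `"Cz"`).
#' @param window_ms search window in ms.
#' @return Peak amplitude in microvolts.
#' @export
peak_amplitude <- function(erp, channel = "Cz", window_ms = c(300, 500)) {
  times <- attr(erp, "times_ms")
  if (!channel %in% rownames(erp)) stop("unknown channel: ", channel)
  sel <- times >= window_ms[1] & times <= window_ms[2]
  if (!any(sel)) stop("window lies outside the epoch")
  max(erp[channel, sel])
}
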