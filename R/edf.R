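#' Read and write continuous EEG in European Data Format
#'
#' Minimal EDF (16-bit) reader and writer for continuous recordings.
#' `write_recording()` stores one EDF signal per channel with physical
#' units of microvolts, one-second data records, and per-channel
#' physical scaling chosen from the data range; `read_recording()`
#' restores the recording (amplitudes are exact up to the 16-bit
#' quantization of the EDF sample encoding). All signals must share one
#' sampling rate; recordings whose duration is not a whole number of
#' seconds are zero-padded to the next full data record on write.
#'
#' @param path file path.
#' @return `read_recording()` returns an [recording()]; montage layout
#'   positions are attached when the stored labels are the standard
#'   64-channel set.
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  field <- function(s, from, n) trimws(substr(s, from, from + n - 1))
  n_records <- as.integer(field(hdr, 237, 8))
  record_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  patient <- field(hdr, 9, 80)
  rec_field <- field(hdr, 89, 80)
  if (is.na(ns) || ns < 1) stop("corrupt EDF header: no signals")
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  sub_all <- function(width, offset) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1,
                    offset + i * width)), "")
  }
  labels <- sub_all(16, 0)
  phys_min <- as.numeric(sub_all(8, ns * (16 + 80 + 8)))
  phys_max <- as.numeric(sub_all(8, ns * (16 + 80 + 8 + 8)))
  dig_min <- as.numeric(sub_all(8, ns * (16 + 80 + 8 + 8 + 8)))
  dig_max <- as.numeric(sub_all(8, ns * (16 + 80 + 8 + 8 + 8 + 8)))
  nsamp <- as.integer(sub_all(8, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  if (length(unique(nsamp)) != 1)
    stop("EDF signals have non-uniform sampling rates (signal '",
         labels[which(nsamp != nsamp[1])[1]], "')")
  rate <- nsamp[1] / record_dur
  total <- n_records * nsamp[1]
  data <- matrix(0, nrow = ns, ncol = total)
  raw <- readBin(con, "integer", n = n_records * ns * nsamp[1],
                 size = 2, endian = "little")
  if (length(raw) < n_records * ns * nsamp[1])
    stop("corrupt EDF: truncated data records")
  # records are interleaved: rec1[sig1 samples, sig2 samples, ...], rec2[...]
  arr <- array(raw, dim = c(nsamp[1], ns, n_records))
  for (i in seq_len(ns)) {
    dig <- as.numeric(arr[, i, ])
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[i, ] <- (dig - dig_min[i]) * scale + phys_min[i]
  }
  session_id <- suppressWarnings(as.integer(sub("^session ", "", rec_field)))
  if (is.na(session_id)) session_id <- 1L
  mt <- if (identical(sort(labels), sort(biosemi64_labels()))) {
    montage(labels, layout_1020(labels))
  } else montage(labels)
  recording(data, rate = rate, montage = mt, session_id = session_id,
            participant_id = if (nzchar(patient)) patient else "P01")
}

#' @param rec an [recording()] to write.
#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  rate <- rec$rate
  if (rate != round(rate))
    stop("EDF writer requires an integer sampling rate")
  n_records <- ceiling(ncol(rec$data) / rate)
  total <- n_records * rate
  pad <- total - ncol(rec$data)
  data <- if (pad > 0) cbind(rec$data, matrix(0, ns, pad)) else rec$data

  pmax_ <- apply(abs(data), 1, max)
  pmax_[pmax_ < 1e-6] <- 1
  dig_max <- 32767; dig_min <- -32768

  pad_field <- function(x, n) substr(formatC(as.character(x), width = n,
                                             flag = "-"), 1, n)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8),
                pad_field(rec$participant_id, 80),
                pad_field(paste("session", rec$session_id), 80),
                "01.01.00", "00.00.00",
                pad_field(256 + 256 * ns, 8),
                pad_field("", 44),
                pad_field(n_records, 8),
                pad_field(1, 8),
                pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  wfields <- function(vals, width)
    writeChar(paste(vapply(vals, pad_field, "", n = width), collapse = ""),
              con, eos = NULL)
  wfields(rec$montage$channel_names, 16)
  wfields(rep("", ns), 80)                       # transducer
  wfields(rep("uV", ns), 8)                      # physical dimension
  wfields(formatC(-pmax_, digits = 6, format = "g"), 8)
  wfields(formatC(pmax_, digits = 6, format = "g"), 8)
  wfields(rep(dig_min, ns), 8)
  wfields(rep(dig_max, ns), 8)
  wfields(rep("", ns), 80)                       # prefiltering
  wfields(rep(rate, ns), 8)
  wfields(rep("", ns), 32)                       # reserved
  # physical limits as written (formatted) must be used for encoding
  pmin_w <- as.numeric(formatC(-pmax_, digits = 6, format = "g"))
  pmax_w <- as.numeric(formatC(pmax_, digits = 6, format = "g"))
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    block <- vapply(seq_len(ns), function(i) {
      scale <- (pmax_w[i] - pmin_w[i]) / (dig_max - dig_min)
      d <- round((data[i, idx] - pmin_w[i]) / scale + dig_min)
      as.integer(pmin(pmax(d, dig_min), dig_max))
    }, integer(rate))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read and write per-trial event tables
#'
#' Tab-separated, UTF-8, header row with columns `onset_sample`,
#' `level_db`, `role`, `trial_index`, `session_id`. Round-trips are
#' lossless; [event_table()] invariants are validated on read with the
#' offending row reported.
#'
#' @param path file path.
#' @param rate sampling rate attached to the table on read.
#' @return `read_events()` returns an [event_table()].
#' @export
read_events <- function(path, rate = 256) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "level_db", "role", "trial_index", "session_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events file missing columns: ",
                         paste(miss, collapse = ", "))
  event_table(df$onset_sample, df$level_db, df$role, df$trial_index,
              df$session_id, rate = rate)
}

#' @param events an [event_table()] to write.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a feature matrix as plain text
#'
#' One row per trial, tab-separated; the first two columns are the label
#' and stimulus level, the remaining columns the channel-major features.
#'
#' @param fm a [feature_matrix()].
#' @param path file path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  cn <- as.vector(t(outer(fm$channels, seq_along(fm$times_ms), paste, sep = ".s")))
  df <- data.frame(label = as.character(fm$labels), level_db = fm$level_db,
                   fm$x, check.names = FALSE)
  names(df)[-(1:2)] <- cn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
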