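#' Aggregate an accuracy table with Average and SD footers
#'
#' Column means and population standard deviations (divisor `N`, the
#' convention used in the study summary tables) over the participant
#' rows. Values are kept at full precision; the print method rounds to
#' 3 decimals.
#'
#' @param x participants x conditions numeric matrix (cells in
#'   \[0, 1\]), or a named list of `accuracy_result` lists as produced
#'   by [run_condition()] (see [accuracy_matrix()]).
#' @return Object of class `accuracy_table`: list with `body`,
#'   `average`, `sd`.
#' @export
aggregate_table <- function(x) {
  if (is.list(x) && !is.matrix(x)) x <- accuracy_matrix(x)
  x <- as.matrix(x)
  if (anyNA(x)) stop("accuracy table has missing cells")
  if (any(x < 0 | x > 1)) stop("accuracies must lie in [0, 1]")
  avg <- colMeans(x)
  sdp <- apply(x, 2, function(col) sqrt(mean((col - mean(col))^2)))
  structure(list(body = x, average = avg, sd = sdp),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, digits = 3, ...) {
  m <- rbind(x$body, Average = x$average, SD = x$sd)
  print(round(m, digits))
  invisible(x)
}

#' Paired comparison of two accuracy columns
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-participant
#' accuracies (see [wilcoxon_signed_rank()]).
#'
#' @param a,b numeric vectors of per-participant accuracies, same
#'   participant order.
#' @return List with `test`, `statistic` (W+ of `b - a`), `p.value`, `n`.
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must pair the same participants")
  res <- wilcoxon_signed_rank(b, a)
  list(test = "Wilcoxon signed-rank", statistic = res$statistic,
       p.value = res$p.value, n = res$n, method = res$method)
}

#' Half-session accuracy difference
#'
#' Percentage-point drop from the first to the latter half of the
#' sessions: `(mean first - mean latter) * 100` at one trial-averaging
#' level.
#'
#' @param first,latter participants x k accuracy matrices (or
#'   `accuracy_table` objects) for sessions 1-10 and 11-20.
#' @param k column to compare (index or name).
#' @return Difference in percentage points (full precision; display
#'   convention is 1 decimal).
#' @export
halfsession_delta <- function(first, latter, k = 1) {
  fb <- if (inherits(first, "accuracy_table")) first$body else as.matrix(first)
  lb <- if (inherits(latter, "accuracy_table")) latter$body else as.matrix(latter)
  if (nrow(fb) != nrow(lb))
    stop("first and latter halves cover different participants")
  (mean(fb[, k]) - mean(lb[, k])) * 100
}

#' Wolpaw information transfer rate
#'
#' Bits per selection for an `N`-class selection made with accuracy `P`:
#' `log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, with the
#' `P = 1` and `P = 1/N` limits handled analytically, scaled by the
#' selection rate.
#'
#' @param P selection accuracy in `[1/N, 1]`.
#' @param n_classes number of classes N (>= 2).
#' @param selections_per_minute selection rate (default 60, one per
#'   second-long trial).
#' @return List with `bits_per_selection`, `bits_per_minute`, `P`,
#'   `n_classes`, `selections_per_minute`.
#' @export
wolpaw_itr <- function(P, n_classes = 2, selections_per_minute = 60) {
  N <- n_classes
  if (N < 2) stop("need at least 2 classes")
  if (P < 1 / N - 1e-12)
    stop("accuracy below chance (1/N); ITR undefined")
  if (P > 1) stop("accuracy cannot exceed 1")
  bits <- if (P >= 1) {
    log2(N)
  } else if (abs(P - 1 / N) < 1e-12) {
    0
  } else {
    log2(N) + P * log2(P) + (1 - P) * log2((1 - P) / (N - 1))
  }
  bits <- max(0, bits)
  list(bits_per_selection = bits,
       bits_per_minute = bits * selections_per_minute,
       P = P, n_classes = N,
       selections_per_minute = selections_per_minute)
}

#' Reference accuracy tables from the original sound-level oddball study
#'
#' The published per-participant classification accuracy tables
#' (shipped as plain text in `extdata`): whole-study accuracies for the
#' 1-Target (table 1) and 2-Target (table 2) designs with 1-5-trial
#' averaging, the 2-Target ROI-47 (table 3) and Cz-only (table 4)
#' channel subsets, and the half-session analyses for both designs
#' (tables 5 and 6; columns `first_k1`, `first_k4`, `latter_k1`,
#' `latter_k4`).
#'
#' @return Named list of participant x condition matrices
#'   (`table1` ... `table6`).
#' @export
reference_accuracy_tables <- function() {
  path <- system.file("extdata", "reference_accuracy_tables.tsv",
                      package = "oddvol")
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$table), function(d) {
    cols <- unique(d$column)
    parts <- unique(d$participant)
    m <- matrix(NA_real_, length(parts), length(cols),
                dimnames = list(parts, cols))
    m[cbind(match(d$participant, parts), match(d$column, cols))] <- d$value
    m
  })
  names(out) <- paste0("table", names(out))
  out
}
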