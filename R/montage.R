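#' Electrode montages and scalp topographies
#'
#' A montage is the ordered set of electrode labels of a recording plus
#' (optionally) a flat 2-D layout used for topographic weighting. The
#' default montage is the 64-channel arrangement of the extended
#' international 10-20 system in the channel order used by 64-channel
#' BioSemi amplifiers.
#'
#' @param channel_names character vector of unique electrode labels.
#' @param positions optional numeric matrix (channels x 2) of flat
#'   layout coordinates, rownames matching `channel_names`. The default
#'   montage uses an azimuthal equidistant projection of idealised
#'   spherical 10-20 positions; Cz sits at the origin and the head
#'   circumference at radius ~1.
#' @return An object of class `oddvol_montage` with elements
#'   `channel_names` and `positions`.
#' @export
montage <- function(channel_names, positions = NULL) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("montage labels must be unique")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != length(channel_names) || ncol(positions) != 2)
      stop("positions must be a channels x 2 matrix")
    rownames(positions) <- channel_names
  }
  structure(list(channel_names = channel_names, positions = positions),
            class = "oddvol_montage")
}

#' @export
print.oddvol_montage <- function(x, ...) {
  cat("<oddvol_montage> ", length(x$channel_names), " channels",
      if (is.null(x$positions)) " (no layout)" else " (with 2-D layout)",
      "\n", sep = "")
  cat(" ", paste(head(x$channel_names, 8), collapse = " "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

# Channel labels in BioSemi 64-channel order (A1..A32, B1..B32).
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

# Decompose a 10-20 label into its sagittal row and lateral index.
# Row letters map to an anterior-posterior tilt (degrees, + = front);
# digits map to a lateral arc (degrees); odd digits are left, even right.
parse_1020_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3) stop("unrecognised 10-20 label: ", label)
  row <- m[2]; num <- m[3]
  tilt <- c(Fp = 72, AF = 54, F = 36, FT = 18, FC = 18, C = 0, T = 0,
            TP = -18, CP = -18, P = -36, PO = -54, O = -72, I = -90)
  if (!row %in% names(tilt)) stop("unrecognised 10-20 row in label: ", label)
  alpha <- tilt[[row]]
  if (num == "z") {
    beta <- 0; side <- 0
  } else {
    n <- as.integer(num)
    # T7/T8 and FT/TP rows carry an implicit lateral arc of 72 degrees
    lat <- c(`1` = 18, `2` = 18, `3` = 36, `4` = 36, `5` = 54, `6` = 54,
             `7` = 72, `8` = 72, `9` = 90, `10` = 90)
    beta <- lat[[num]]
    side <- if (n %% 2 == 1) -1 else 1  # odd = left (negative x)
  }
  c(alpha = alpha, beta = side * beta)
}

# Flat layout via azimuthal equidistant projection of an idealised
# spherical head (x = right, y = front). Radius 1 corresponds to a
# polar angle of 115 degrees from the vertex.
layout_1020 <- function(labels) {
  pos <- t(vapply(labels, function(lb) {
    a <- parse_1020_label(lb)
    alpha <- a[["alpha"]] * pi / 180
    beta <- a[["beta"]] * pi / 180
    # tilt the vertex unit vector forward by alpha, then laterally by beta
    v <- c(cos(alpha) * sin(beta), sin(alpha), cos(alpha) * cos(beta))
    theta <- acos(pmin(pmax(v[3], -1), 1))
    r <- (theta * 180 / pi) / 115
    h <- sqrt(v[1]^2 + v[2]^2)
    if (h < 1e-12) c(0, 0) else r * c(v[1], v[2]) / h
  }, numeric(2)))
  rownames(pos) <- labels
  colnames(pos) <- c("x", "y")
  pos
}

#' @rdname montage
#' @export
biosemi64_montage <- function() {
  labels <- biosemi64_labels()
  montage(labels, layout_1020(labels))
}

#' Channel subsets used for classification
#'
#' `roi47_channels()` returns the 47-channel central/parietal/occipital
#' region of interest (the full 64-channel montage minus the 17 frontal
#' Fp-, AF- and F-row electrodes). `frontal17_channels()` returns the
#' excluded frontal set.
#'
#' @return Character vector of channel labels.
#' @export
roi47_channels <- function() {
  c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
}

#' @rdname roi47_channels
#' @export
frontal17_channels <- function() {
  setdiff(biosemi64_labels(), roi47_channels())
}

#' Gaussian scalp topography weights
#'
#' Per-channel weights in \[0, 1\] that decay with flat-layout distance
#' from a centre electrode: `w = exp(-d^2 / (2 * spread^2))`. Used to
#' spread simulated ERP components over the scalp.
#'
#' @param montage an `oddvol_montage` with layout positions.
#' @param center_channel label of the electrode with weight 1.
#' @param spread Gaussian width in layout units (default 0.18; head
#'   circumference is at radius ~1, adjacent rows are ~0.16 apart).
#' @return Named numeric vector of weights, one per montage channel.
#' @export
scalp_topography <- function(montage, center_channel, spread = 0.18) {
  stopifnot(inherits(montage, "oddvol_montage"))
  if (is.null(montage$positions))
    stop("montage has no layout positions")
  if (!center_channel %in% montage$channel_names)
    stop("unknown channel: ", center_channel)
  if (spread <= 0) stop("spread must be positive")
  pos <- montage$positions
  ctr <- pos[center_channel, ]
  d2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
  w <- exp(-d2 / (2 * spread^2))
  names(w) <- montage$channel_names
  w
}
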