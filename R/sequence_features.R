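# sequence_features: hydropathy profiles, transmembrane segment detection,
# hydrophobic moments, polybasic motifs, molecular weight.

check_seq <- function(seq, allow_x = TRUE) {
  letters1 <- strsplit(toupper(seq), "")[[1]]
  ok <- names(kd_scale())
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(letters1), ok)
  if (length(bad) > 0) {
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  letters1
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' The value at position `i` is the mean hydropathy over the window centered
#' at `i`. Positions whose window does not fit entirely inside the sequence
#' are `NA` (no padding). `"X"` contributes 0 and is flagged via the `n_x`
#' attribute.
#'
#' @param seq amino-acid string
#' @param window odd window width in residues (default 19, the classical
#'   transmembrane-scan width)
#' @param scale named per-residue hydropathy values (default [kd_scale()])
#' @return numeric vector of length `nchar(seq)` with `NA` at the ends;
#'   attributes `window`, `n_x`
#' @export
hydropathy_profile <- function(seq, window = 19, scale = kd_scale()) {
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer")
  letters1 <- check_seq(seq)
  n <- length(letters1)
  if (n < window) stop("sequence shorter than window (", n, " < ", window, ")")
  h <- unname(scale[letters1])
  n_x <- sum(letters1 == "X")
  if (n_x > 0) {
    warning(n_x, " 'X' residue(s) contribute 0 to the hydropathy profile")
    h[letters1 == "X"] <- 0
  }
  half <- (window - 1) / 2
  cs <- c(0, cumsum(h))
  out <- rep(NA_real_, n)
  centers <- (half + 1):(n - half)
  out[centers] <- (cs[centers + half + 1] - cs[centers - half]) / window
  structure(out, window = window, n_x = n_x)
}

#' Detect transmembrane-like hydropathy segments
#'
#' Maximal runs of profile positions at or above `threshold`, kept when at
#' least `min_len` positions long. Threshold 1.6 on a 19-residue window is
#' the classical Kyte-Doolittle criterion for membrane-spanning segments.
#'
#' @param profile [hydropathy_profile()] output (NA ends allowed)
#' @param threshold window-mean hydropathy cutoff (default 1.6)
#' @param min_len minimum run length in positions (default 15)
#' @return data.frame with `start`, `end` (positions of window centers),
#'   `length`, `max_hydropathy`, `mean_hydropathy`
#' @export
detect_tm_segments <- function(profile, threshold = 1.6, min_len = 15) {
  hit <- !is.na(profile) & profile >= threshold
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(
    start = starts[keep], end = ends[keep], length = r$lengths[keep]
  )
  out$max_hydropathy <- vapply(seq_len(nrow(out)), function(k) {
    max(profile[out$start[k]:out$end[k]])
  }, numeric(1))
  out$mean_hydropathy <- vapply(seq_len(nrow(out)), function(k) {
    mean(profile[out$start[k]:out$end[k]])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Eisenberg hydrophobic moment of a sequence window
#'
#' Magnitude of the vector sum of per-residue hydropathies placed at
#' successive angles of `delta` degrees around an ideal helical wheel,
#' normalized by window length: `|sum_i h_i (cos(i d), sin(i d))| / n`.
#' A large moment indicates segregated hydrophobic and hydrophilic faces
#' (an amphipathic helix at delta = 100 degrees).
#'
#' @param seq amino-acid window (string)
#' @param delta helical twist per residue, degrees (default 100)
#' @param scale hydropathy scale (default [kd_scale()])
#' @return non-negative scalar moment
#' @export
hydrophobic_moment <- function(seq, delta = 100, scale = kd_scale()) {
  letters1 <- check_seq(seq)
  n <- length(letters1)
  if (n < 1) stop("empty window")
  h <- unname(scale[letters1])
  h[letters1 == "X"] <- 0
  ang <- seq_len(n) * delta * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / n
}

#' Scan hydrophobic moments over all windows of a sequence
#'
#' @param seq amino-acid string
#' @param window window width (default 18, ~5 helical turns)
#' @param delta degrees per residue (default 100)
#' @return data.frame with `start`, `end`, `moment`, `mean_hydropathy`,
#'   sorted by position
#' @export
scan_hydrophobic_moment <- function(seq, window = 18, delta = 100) {
  letters1 <- check_seq(seq)
  n <- length(letters1)
  if (n < window) stop("sequence shorter than window")
  kd <- kd_scale()
  h <- unname(kd[letters1]); h[letters1 == "X"] <- 0
  starts <- seq_len(n - window + 1)
  moments <- vapply(starts, function(s) {
    hydrophobic_moment(substr(seq, s, s + window - 1), delta = delta)
  }, numeric(1))
  mh <- vapply(starts, function(s) mean(h[s:(s + window - 1)]), numeric(1))
  data.frame(start = starts, end = starts + window - 1,
             moment = moments, mean_hydropathy = mh)
}

#' Find polybasic K-x-K-K motifs
#'
#' All (overlapping) matches of lysine, any residue, lysine, lysine — the
#' phosphoinositide-binding polybasic cluster signature. Positions are
#' 1-based.
#'
#' @param seq amino-acid string
#' @param pattern regular expression for the motif (default `"K.KK"`)
#' @return data.frame with `start` and `match`; zero rows when absent
#' @export
find_polybasic <- function(seq, pattern = "K.KK") {
  seq <- toupper(seq)
  width <- 4L  # K-x-K-K is exactly four residues
  hits <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1) {
    return(data.frame(start = integer(0), match = character(0)))
  }
  starts <- as.integer(hits)
  data.frame(start = starts,
             match = vapply(starts, function(s) substr(seq, s, s + width - 1),
                            character(1)))
}

#' Average molecular weight of a peptide
#'
#' Sum of IUPAC average residue masses plus one water (18.0153 Da).
#'
#' @param seq amino-acid string (standard 20 letters)
#' @return mass in Daltons
#' @export
#' @examples
#' molecular_weight("G")   # 75.07 Da
molecular_weight <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  letters1 <- check_seq(seq, allow_x = FALSE)
  sum(AA_RESIDUE_MASS[letters1]) + WATER_MASS
}
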