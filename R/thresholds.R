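#' Maximum-entropy (Kapur) histogram threshold
#'
#' Chooses the gray level that maximizes the sum of the Shannon entropies
#' of the background (levels at or below the threshold) and foreground
#' (levels above it) class distributions, the classic maximum-entropy
#' criterion. Ties are broken toward the lower level.
#'
#' @param counts Non-negative histogram counts per gray level.
#' @param levels Gray-level values corresponding to `counts`; defaults to
#'   `0:(length(counts) - 1)`.
#' @return The threshold gray level; foreground is `level > threshold`.
#' @export
#' @examples
#' h <- tabulate(c(rep(10, 50), rep(200, 50)) + 1, nbins = 256)
#' max_entropy_threshold(h)
max_entropy_threshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels), all(counts >= 0))
  pop <- which(counts > 0)
  if (length(pop) < 2) stop("degenerate histogram: all mass at one level")
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  Ptot <- P[length(P)]
  Stot <- S[length(S)]
  # candidate thresholds: both classes must be populated
  cand <- seq_len(length(counts) - 1)
  Pb <- P[cand]; Pf <- Ptot - Pb
  ok <- Pb > 0 & Pf > 0
  obj <- rep(-Inf, length(cand))
  Hb <- log(Pb[ok]) - S[cand][ok] / Pb[ok]
  Hf <- log(Pf[ok]) - (Stot - S[cand][ok]) / Pf[ok]
  obj[ok] <- Hb + Hf
  levels[cand[which.max(obj)]]
}

#' Triangle histogram threshold
#'
#' Draws a chord from the histogram peak to the far end of its longer
#' tail and returns the gray level at which the histogram lies farthest
#' (perpendicular distance) below that chord. Ties are broken toward the
#' lower level.
#'
#' @inheritParams max_entropy_threshold
#' @return The threshold gray level; foreground is `level > threshold`.
#' @export
triangle_threshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels), all(counts >= 0))
  pop <- which(counts > 0)
  if (length(pop) < 2) stop("degenerate histogram: all mass at one level")
  peak <- which.max(counts)
  lo <- pop[1]; hi <- pop[length(pop)]
  # side with the longer tail
  if ((hi - peak) >= (peak - lo)) {
    idx <- peak:hi
  } else {
    idx <- peak:lo
  }
  x1 <- idx[1]; y1 <- counts[x1]
  x2 <- idx[length(idx)]; y2 <- counts[x2]
  # perpendicular distance from (i, counts[i]) to the chord
  dx <- x2 - x1; dy <- y2 - y1
  nrm <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (idx - x1) - dx * (counts[idx] - y1)) / nrm
  best <- idx[which.max(d)]
  levels[best]
}
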