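# Independent brute-force oracles used across the tests. These are written
# deliberately as slow, direct transcriptions of the definitions, kept
# separate from the package implementations they check.

# exhaustive Kapur maximum-entropy threshold
brute_max_entropy <- function(counts, levels = seq_along(counts) - 1) {
  p <- counts / sum(counts)
  best <- -Inf
  best_t <- NA
  for (k in seq_len(length(counts) - 1)) {
    pb <- p[1:k]; pf <- p[(k + 1):length(p)]
    Pb <- sum(pb); Pf <- sum(pf)
    if (Pb <= 0 || Pf <= 0) next
    hb <- -sum(ifelse(pb > 0, (pb / Pb) * log(pb / Pb), 0))
    hf <- -sum(ifelse(pf > 0, (pf / Pf) * log(pf / Pf), 0))
    if (hb + hf > best + 1e-12) {   # strict improvement: ties to lower level
      best <- hb + hf
      best_t <- levels[k]
    }
  }
  best_t
}

# exhaustive triangle threshold (peak-to-far-end chord distance)
brute_triangle <- function(counts, levels = seq_along(counts) - 1) {
  peak <- which.max(counts)
  pop <- which(counts > 0)
  lo <- pop[1]; hi <- pop[length(pop)]
  idx <- if ((hi - peak) >= (peak - lo)) peak:hi else peak:lo
  x1 <- idx[1]; y1 <- counts[x1]
  x2 <- idx[length(idx)]; y2 <- counts[x2]
  nrm <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  best <- -Inf; best_t <- NA
  for (i in idx) {
    d <- abs((y2 - y1) * (i - x1) - (x2 - x1) * (counts[i] - y1)) / nrm
    if (d > best + 1e-12) { best <- d; best_t <- levels[i] }
  }
  best_t
}

# per-ray scan: farthest foreground pixel along each ray, double loop
brute_radial_profile <- function(mask, center, angular_step = 2) {
  angles <- seq(0, 360 - angular_step, by = angular_step)
  radii <- numeric(length(angles))
  rmax <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    best <- 0
    for (r in seq(0.5, rmax, by = 0.5)) {
      px <- round(center[1] + r * cos(th))
      py <- round(center[2] + r * sin(th))
      if (px < 1 || px > nrow(mask) || py < 1 || py > ncol(mask)) next
      if (mask[px, py]) best <- r
    }
    radii[a] <- best
  }
  tibble::tibble(angle = angles, radius = radii)
}

# total net winding of a trajectory (signed heading integral)
brute_winding <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  keep <- sqrt(dx^2 + dy^2) > 1e-12
  h <- atan2(dy[keep], dx[keep])
  if (length(h) < 2) return(0)
  d <- diff(h)
  d <- (d + pi) %% (2 * pi) - pi
  abs(sum(d))
}

# draw a rasterized ellipse mask (independent of the package renderer)
ellipse_mask <- function(n, center, a, b, angle = 0) {
  xs <- matrix(seq_len(n), n, n) - center[1]
  ys <- matrix(seq_len(n), n, n, byrow = TRUE) - center[2]
  u <- xs * cos(angle) + ys * sin(angle)
  v <- -xs * sin(angle) + ys * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}
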