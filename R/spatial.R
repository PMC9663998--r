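#' Spatial occupancy probability density
#'
#' Counts the observed cell centers in a square grid (default 56 x 56
#' cells over a 6 x 6 mm field centered on the chamber) and normalizes
#' the counts so the density integrates to exactly 1 over the field.
#' Positions outside the field are dropped and their count reported in
#' an attribute.
#'
#' @param track Tibble with `x`, `y` (mm) and optionally `valid`.
#' @param field Field width (mm), centered on the origin.
#' @param grid Number of grid cells per side.
#' @return A `density_map` tibble with cell centers `x`, `y`, counts
#'   `n`, and `density` (1/mm^2); attributes `field`, `grid`,
#'   `cell_area`, `n_dropped`.
#' @export
occupancy_density <- function(track, field = 6, grid = 56) {
  x <- track$x; y <- track$y
  if ("valid" %in% names(track)) { x <- x[track$valid]; y <- y[track$valid] }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  half <- field / 2
  inside <- x >= -half & x < half & y >= -half & y < half
  n_dropped <- sum(!inside)
  x <- x[inside]; y <- y[inside]
  step <- field / grid
  ix <- pmin(floor((x + half) / step) + 1, grid)
  iy <- pmin(floor((y + half) / step) + 1, grid)
  counts <- matrix(0L, grid, grid)
  tb <- table(factor(ix, levels = 1:grid), factor(iy, levels = 1:grid))
  counts[] <- as.integer(tb)
  cell_area <- step^2
  total <- sum(counts)
  dens <- if (total > 0) counts / (total * cell_area) else counts * 0
  centers <- -half + (seq_len(grid) - 0.5) * step
  out <- tibble::tibble(
    x = rep(centers, times = grid),
    y = rep(centers, each = grid),
    n = as.integer(counts),
    density = as.numeric(dens)
  )
  attr(out, "field") <- field
  attr(out, "grid") <- grid
  attr(out, "cell_area") <- cell_area
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("density_map", class(out))
  out
}

#' Presence frequency in a region
#'
#' Total (non-adhered) time the cell center spends inside a region,
#' divided by the region area: s/mm^2. Frames belonging to adhesion
#' events are excluded, so the statistic measures presence while
#' behaving freely.
#'
#' @param track Tibble with `t`, `x`, `y` and attribute `fps`.
#' @param region A `chamber_region` (e.g. [crescent_mask()] or
#'   [region_complement()]).
#' @param adhesions Optional tibble of adhesion events (`start`,
#'   `duration`) whose frames are excluded.
#' @param fps Frame rate; defaults to the track attribute.
#' @return Presence frequency (s/mm^2).
#' @export
presence_frequency <- function(track, region, adhesions = NULL,
                               fps = attr(track, "fps")) {
  stopifnot(!is.null(fps), region$area > 0)
  keep <- !is.na(track$x) & !is.na(track$y)
  if ("valid" %in% names(track)) keep <- keep & track$valid
  if (!is.null(adhesions) && nrow(adhesions) > 0) {
    for (k in seq_len(nrow(adhesions))) {
      keep <- keep & !(track$t >= adhesions$start[k] &
                         track$t < adhesions$start[k] + adhesions$duration[k])
    }
  }
  inside <- region$contains(track$x[keep], track$y[keep])
  sum(inside) / fps / region$area
}

#' Detect adhesion events from a track
#'
#' Finds maximal intervals during which the cell center stays within
#' `displacement_radius` of a fixed point, and keeps those lasting at
#' least `min_duration` (shorter stops do not count as adhesion). The
#' stay criterion is implemented by a running bounding box: an interval
#' is extended while the half-diagonal of the bounding box of its
#' positions stays at or below the radius, which guarantees every point
#' lies within the radius of the box center. The event position is the
#' box center; the anterior angle is the circular mean of the per-frame
#' anterior direction (`theta1` of the radial profile) over the event,
#' when available.
#'
#' @param track Tibble with `t`, `x`, `y`, optionally `theta1` and
#'   `valid`, and attribute `fps`.
#' @param min_duration Minimum event duration (s); default 10 s.
#' @param displacement_radius Stay radius (mm); default 0.2 mm, about
#'   one cell width.
#' @param region Optional `chamber_region` used to set the
#'   `in_crescent` flag.
#' @return Tibble of events: `start`, `duration`, `x`, `y`,
#'   `anterior_angle` (degrees or `NA`), `in_crescent`.
#' @export
detect_adhesions <- function(track, min_duration = 10,
                             displacement_radius = 0.2, region = NULL) {
  fps <- attr(track, "fps")
  stopifnot(!is.null(fps))
  n <- nrow(track)
  empty <- tibble::tibble(start = numeric(), duration = numeric(),
                          x = numeric(), y = numeric(),
                          anterior_angle = numeric(),
                          in_crescent = logical())
  if (n < 2 || (n - 1) / fps < min_duration) return(empty)
  x <- track$x; y <- track$y
  ok <- !is.na(x) & !is.na(y)
  if ("valid" %in% names(track)) ok <- ok & track$valid
  ev <- list()
  i <- 1L
  r <- displacement_radius
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    xmin <- xmax <- x[i]; ymin <- ymax <- y[i]
    j <- i
    while (j < n && ok[j + 1L]) {
      nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
      nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
      if ((nxmax - nxmin)^2 + (nymax - nymin)^2 > (2 * r)^2) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    dur <- (j - i + 1L) / fps
    if (dur >= min_duration) {
      cx <- (xmin + xmax) / 2; cy <- (ymin + ymax) / 2
      ang <- NA_real_
      if ("theta1" %in% names(track)) {
        th <- track$theta1[i:j] * pi / 180
        th <- th[!is.na(th)]
        if (length(th))
          ang <- (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
      }
      ev[[length(ev) + 1L]] <- tibble::tibble(
        start = track$t[i], duration = dur, x = cx, y = cy,
        anterior_angle = ang,
        in_crescent = if (is.null(region)) NA else region$contains(cx, cy))
    }
    i <- j + 1L
  }
  if (length(ev) == 0) return(empty)
  dplyr::bind_rows(ev)
}

#' Welch's t-test from group summaries
#'
#' Unequal-variance two-sample t-test computed from printed group
#' summaries (mean, dispersion, n), with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Dispersion may be given as the
#' standard error (used directly) or the standard deviation (converted
#' by SD / sqrt(n)). When dispersions and sample sizes are equal the
#' test reduces to Student's t with df = 2n - 2.
#'
#' @param mean_a,mean_b Group means.
#' @param disp_a,disp_b Group dispersions.
#' @param n_a,n_b Group sizes (>= 2).
#' @param dispersion `"se"` or `"sd"`.
#' @return Tibble with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_test(614.9, 136.6, 12, 43.4, 11.1, 12)
welch_t_test <- function(mean_a, disp_a, n_a, mean_b, disp_b, n_b,
                         dispersion = c("se", "sd")) {
  dispersion <- match.arg(dispersion)
  stopifnot(n_a >= 2, n_b >= 2, disp_a >= 0, disp_b >= 0)
  se_a <- if (dispersion == "sd") disp_a / sqrt(n_a) else disp_a
  se_b <- if (dispersion == "sd") disp_b / sqrt(n_b) else disp_b
  va <- se_a^2; vb <- se_b^2
  tval <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(t = tval, df = df, p = p)
}

#' Welch's t-test from raw samples
#'
#' Thin wrapper around [stats::t.test()] (Welch variant) returning the
#' same tidy columns as [welch_t_test()].
#'
#' @param a,b Numeric sample vectors.
#' @return Tibble with `t`, `df`, `p`.
#' @export
welch_t_test_samples <- function(a, b) {
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}
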