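#' Instantaneous speed along a track
#'
#' Central-difference speed s_i = |0.5 (r_{i+1} - r_{i-1})| * fps from
#' the per-frame cell centers; the two endpoints get one-sided
#' differences and are flagged so they can be excluded from state
#' statistics. Frames flagged invalid yield `NA` speeds that are bridged
#' later by median smoothing.
#'
#' @param track Tibble with columns `x`, `y` (mm) and attribute `fps`
#'   (or pass `fps`).
#' @param fps Frame rate; defaults to the track attribute.
#' @return The track with `speed` (mm/s) and `speed_endpoint` columns.
#' @export
instantaneous_speed <- function(track, fps = attr(track, "fps")) {
  stopifnot(!is.null(fps), nrow(track) >= 3)
  x <- track$x; y <- track$y
  if ("valid" %in% names(track)) {
    x[!track$valid] <- NA_real_
    y[!track$valid] <- NA_real_
  }
  n <- length(x)
  vx <- c(x[2] - x[1], 0.5 * (x[3:n] - x[1:(n - 2)]), x[n] - x[n - 1]) * fps
  vy <- c(y[2] - y[1], 0.5 * (y[3:n] - y[1:(n - 2)]), y[n] - y[n - 1]) * fps
  # the one-sided endpoint differences skip the 0.5 factor but span one
  # frame instead of two
  track$speed <- sqrt(vx^2 + vy^2)
  track$speed_endpoint <- c(TRUE, rep(FALSE, n - 2), TRUE)
  track
}

#' Centered running median
#'
#' Median over a centered window of `2 * floor(half_window * fps) + 1`
#' frames, computed over valid (non-`NA`) entries only and truncated at
#' the series ends. This bridges invalid frames instead of interpolating
#' them, which is the point of using medians in the first place.
#'
#' @param x Numeric series (may contain `NA`).
#' @param fps Frame rate (1/s).
#' @param half_window Half window in seconds (default +/- 5 s).
#' @return Smoothed series; `NA` where a window holds no valid entry.
#' @export
median_smooth <- function(x, fps, half_window = 5) {
  k <- floor(half_window * fps)
  if (k < 0 || (2 * k + 1) < 1) stop("window must span at least one frame")
  n <- length(x)
  if (k == 0) return(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - k):min(n, i + k)]
    w <- w[!is.na(w)]
    if (length(w) == 0) NA_real_ else stats::median(w)
  }, numeric(1))
}

#' Smooth a track's length and speed series
#'
#' Adds `length_s` and `speed_s`, the +/- `half_window` s running
#' medians of length and speed (endpoint speeds are excluded from the
#' speed medians).
#'
#' @param track Tibble with `length`, `speed` and attribute `fps`.
#' @param half_window Half window in seconds.
#' @return The track with smoothed columns added.
#' @export
smooth_track <- function(track, half_window = 5) {
  fps <- attr(track, "fps")
  stopifnot(!is.null(fps))
  len <- track$length
  if ("valid" %in% names(track)) len[!track$valid] <- NA_real_
  sp <- track$speed
  if ("speed_endpoint" %in% names(track)) sp[track$speed_endpoint] <- NA_real_
  track$length_s <- median_smooth(len, fps, half_window)
  track$speed_s <- median_smooth(sp, fps, half_window)
  track
}

#' Normalization reference from a cone free-swimming window
#'
#' The averaged length L0 and speed s0 over a 10 s window of cone-state
#' free swimming define the normalization of the state field (cone = 1).
#' Candidate windows are `window_s`-long stretches of valid frames with
#' fast swimming (mean smoothed speed at least 80% of the 95th speed
#' percentile) and stable length (coefficient of variation below
#' `max_length_cv`). Among them the most *representative* window is
#' chosen — the one whose mean length is closest to the median length
#' over all fast frames — rather than the fastest: early cone bouts are
#' still elongating from the droplet, and picking a window by speed
#' alone can land on one of those and skew the whole normalization.
#'
#' @param track A smoothed track (see [smooth_track()]).
#' @param window_s Window duration in seconds (default 10).
#' @param max_length_cv Maximum coefficient of variation of the smoothed
#'   length within an admissible window.
#' @return List of class `normalization_ref`: `L0`, `s0`, `window`
#'   (first and last frame).
#' @export
normalization_ref <- function(track, window_s = 10, max_length_cv = 0.1) {
  fps <- attr(track, "fps")
  stopifnot(!is.null(fps), !is.null(track$length_s), !is.null(track$speed_s))
  w <- max(2L, as.integer(round(window_s * fps)))
  n <- nrow(track)
  if (n < w) stop("track shorter than the normalization window")
  len <- track$length_s; sp <- track$speed_s
  bad <- is.na(len) | is.na(sp)
  len0 <- ifelse(bad, 0, len); sp0 <- ifelse(bad, 0, sp)
  cs <- function(v) cumsum(c(0, v))
  nb <- cs(!bad); sl <- cs(len0); sl2 <- cs(len0^2); ss <- cs(sp0)
  starts <- seq_len(n - w + 1)
  ends <- starts + w - 1
  nv <- nb[ends + 1] - nb[starts]
  full <- nv == w
  mean_l <- (sl[ends + 1] - sl[starts]) / w
  var_l <- (sl2[ends + 1] - sl2[starts]) / w - mean_l^2
  mean_s <- (ss[ends + 1] - ss[starts]) / w
  cv <- sqrt(pmax(var_l, 0)) / pmax(mean_l, 1e-12)
  s_hat <- stats::quantile(sp[!bad], 0.95, na.rm = TRUE)
  fast <- !bad & sp >= 0.8 * s_hat
  ok <- full & cv <= max_length_cv & mean_s >= 0.8 * s_hat
  if (!any(ok)) ok <- full & cv <= max_length_cv
  if (!any(ok)) ok <- full
  if (!any(ok)) stop("no valid window for the normalization reference")
  if (any(fast)) {
    l_ref <- stats::median(len[fast])
    score <- ifelse(ok, -abs(mean_l - l_ref), -Inf)
  } else {
    score <- ifelse(ok, mean_s, -Inf)
  }
  b <- which.max(score)
  structure(list(L0 = mean_l[b], s0 = mean_s[b],
                 window = c(starts[b], ends[b])),
            class = "normalization_ref")
}

#' Normalize a track onto the state field
#'
#' Divides the smoothed length and speed by the reference values
#' (element-wise), placing the track on the normalized state field with
#' the cone state at (1, 1). A fixed `(L0, s0)` pair may be supplied
#' instead of a computed reference for recordings with no usable cone
#' window (e.g. a cell that adheres throughout).
#'
#' @param track A smoothed track.
#' @param ref A [normalization_ref()]; ignored when `L0` and `s0` are
#'   given.
#' @param L0,s0 Optional fixed reference values (mm, mm/s).
#' @return The track with `l_norm` and `s_norm` columns and a
#'   `normalization` attribute.
#' @export
normalize_track <- function(track, ref = NULL, L0 = NULL, s0 = NULL) {
  if (is.null(L0) != is.null(s0))
    stop("supply both L0 and s0, or neither")
  if (is.null(L0)) {
    if (is.null(ref)) ref <- normalization_ref(track)
    L0 <- ref$L0; s0 <- ref$s0
  } else {
    ref <- structure(list(L0 = L0, s0 = s0, window = NULL),
                     class = "normalization_ref")
  }
  stopifnot(L0 > 0, s0 > 0)
  track$l_norm <- track$length_s / L0
  track$s_norm <- track$speed_s / s0
  attr(track, "normalization") <- ref
  track
}
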