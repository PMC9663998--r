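#' Split a rotating trajectory into laps
#'
#' A lap is one full rotation of the local circular trajectory of the
#' non-adhered trumpet state, operationalized by the winding number: the
#' stretch over which the net (signed) cumulative heading change of the
#' displacement direction reaches 2 pi in magnitude. The signed sum is
#' used because measurement jitter adds unbounded unsigned heading
#' change but cancels from the net winding; for a consistently rotating
#' trajectory the two agree. Each supplied interval is split into
#' consecutive laps; a partial final lap is discarded, and an interval
#' with net winding below 2 pi yields no laps.
#'
#' @param track Tibble with `x`, `y` columns (and optionally `frame`).
#' @param intervals Optional two-column matrix or data frame of
#'   first/last row indices of rotating intervals; default the whole
#'   track.
#' @param min_points Minimum points for a lap to be kept.
#' @return Tibble of lap points: `lap`, `row`, `x`, `y`.
#' @export
#' @examples
#' th <- seq(0, 6 * pi, length.out = 200)
#' laps <- extract_laps(tibble::tibble(x = cos(th), y = sin(th)))
#' max(laps$lap)  # 3 full circles
extract_laps <- function(track, intervals = NULL, min_points = 10) {
  if (is.null(intervals)) intervals <- cbind(1, nrow(track))
  intervals <- as.matrix(intervals)
  out <- list()
  lap_id <- 0L
  for (k in seq_len(nrow(intervals))) {
    i0 <- intervals[k, 1]; i1 <- intervals[k, 2]
    stopifnot(i0 >= 1, i1 <= nrow(track))
    if (i1 - i0 < 2) next
    x <- track$x[i0:i1]; y <- track$y[i0:i1]
    dx <- diff(x); dy <- diff(y)
    move <- sqrt(dx^2 + dy^2) > 1e-12
    if (sum(move) < 2) next
    # heading of each displacement step; stationary steps add no winding
    head_full <- rep(NA_real_, length(dx))
    head_full[move] <- atan2(dy[move], dx[move])
    last <- NA_real_
    dturn <- numeric(length(dx))
    for (i in seq_along(dx)) {
      h <- head_full[i]
      if (is.na(h)) next
      if (!is.na(last)) {
        d <- (h - last + pi) %% (2 * pi) - pi
        dturn[i] <- d
      }
      last <- h
    }
    wind <- abs(cumsum(dturn))
    # the lap count comes from the final net winding; transient noise
    # swings of the running sum do not create laps
    n_laps <- floor(wind[length(wind)] / (2 * pi))
    if (n_laps < 1) next
    start <- 1L
    for (m in seq_len(n_laps)) {
      end <- which(wind >= 2 * pi * m)[1] + 1L
      rows <- (i0 + start - 1L):(i0 + end - 1L)
      if (length(rows) >= min_points) {
        lap_id <- lap_id + 1L
        out[[lap_id]] <- tibble::tibble(lap = lap_id, row = rows,
                                        x = track$x[rows], y = track$y[rows])
      }
      start <- end
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(lap = integer(), row = integer(),
                          x = numeric(), y = numeric()))
  dplyr::bind_rows(out)
}

#' Diameter of one lap
#'
#' Maximum pairwise Euclidean distance among the lap's positions.
#'
#' @param lap Tibble with `x`, `y` for a single lap.
#' @return Diameter (same units as the positions).
#' @export
lap_diameter <- function(lap) {
  stopifnot(nrow(lap) >= 2)
  max(stats::dist(cbind(lap$x, lap$y)))
}

#' Diameters of all laps
#'
#' @param laps Output of [extract_laps()].
#' @return Tibble with `lap`, `n_points`, `diameter`.
#' @export
lap_diameters <- function(laps) {
  laps |>
    dplyr::group_by(.data$lap) |>
    dplyr::summarise(n_points = dplyr::n(),
                     diameter = lap_diameter(dplyr::pick("x", "y")),
                     .groups = "drop")
}
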