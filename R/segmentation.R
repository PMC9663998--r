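#' Estimate a background image from a stack section
#'
#' Per-pixel statistic over a window of frames: the local median removes
#' a moving dark cell from long sections, while the local maximum is
#' robust when the cell lingers (the cell is darker than the background,
#' so the running maximum converges on the empty field).
#'
#' @param stack Numeric or integer array `width x height x n_frames`.
#' @param stat `"median"` or `"max"`.
#' @param window Frame indices to use; default all.
#' @return A background matrix of the frame dimensions.
#' @export
estimate_background <- function(stack, stat = c("median", "max"),
                                window = NULL) {
  stat <- match.arg(stat)
  stopifnot(length(dim(stack)) == 3)
  if (is.null(window)) window <- seq_len(dim(stack)[3])
  if (length(window) == 0) stop("background window is empty")
  if (length(window) == 1) {
    if (stat == "median")
      warning("single-frame window: background is that frame")
    return(stack[, , window[1]])
  }
  d <- dim(stack)
  m <- matrix(stack[, , window], d[1] * d[2], length(window))
  out <- if (stat == "median") {
    matrixStats::rowMedians(m)
  } else {
    matrixStats::rowMaxs(m)
  }
  matrix(out, d[1], d[2])
}

# component perimeter: foreground pixels with at least one 4-neighbour
# outside the component (or on the image border)
component_stats <- function(labels) {
  d <- dim(labels)
  pad <- matrix(0L, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- labels
  ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
  nb_border <- (pad[1:d[1], 2:(d[2] + 1)] != ctr) |
    (pad[3:(d[1] + 2), 2:(d[2] + 1)] != ctr) |
    (pad[2:(d[1] + 1), 1:d[2]] != ctr) |
    (pad[2:(d[1] + 1), 3:(d[2] + 2)] != ctr)
  nmax <- max(labels)
  area <- tabulate(labels[labels > 0], nbins = nmax)
  perim <- tabulate(labels[labels > 0 & nb_border], nbins = nmax)
  tibble::tibble(label = seq_len(nmax), area = area, perimeter = perim,
                 circularity = ifelse(perim > 0,
                                      pmin(4 * pi * area / perim^2, 1), 0))
}

# circularity of one labeled component, computed on its bounding box
component_circularity <- function(labels, lab) {
  fg <- which(labels == lab, arr.ind = TRUE)
  i0 <- min(fg[, 1]); i1 <- max(fg[, 1])
  j0 <- min(fg[, 2]); j1 <- max(fg[, 2])
  sub <- labels[i0:i1, j0:j1, drop = FALSE] == lab
  d <- dim(sub)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- sub
  ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
  border <- ctr & (!pad[1:d[1], 2:(d[2] + 1)] | !pad[3:(d[1] + 2), 2:(d[2] + 1)] |
                     !pad[2:(d[1] + 1), 1:d[2]] | !pad[2:(d[1] + 1), 3:(d[2] + 2)])
  perim <- sum(border)
  area <- nrow(fg)
  if (perim == 0) 0 else min(4 * pi * area / perim^2, 1)
}

#' Segment a single frame
#'
#' Background subtraction, Gaussian blur, histogram thresholding
#' (maximum-entropy or triangle), optional binary opening, removal of
#' components failing the circularity filter, and selection of the
#' largest surviving connected component. Frames where nothing credible
#' survives are flagged invalid rather than raising an error; invalid
#' frames are bridged later by median smoothing.
#'
#' @param frame,background Numeric matrices of the same shape (any
#'   common intensity scale).
#' @param params A [segmentation_params()].
#' @param min_area Smallest component area (px) accepted as a cell.
#' @param prominence_min A candidate component's mean difference
#'   intensity must exceed this multiple of the image's median absolute
#'   difference; guards against segmenting pure noise when no cell is
#'   in the frame (correlated blurred-noise clumps reach ratios around
#'   15, real cells sit far above).
#' @return List with `mask` (logical matrix), `valid`, and the selected
#'   component's `area` and `circularity`.
#' @export
segment_frame <- function(frame, background, params = segmentation_params(),
                          min_area = 6, prominence_min = 25) {
  stopifnot(all(dim(frame) == dim(background)))
  dimg <- abs(frame - background)
  rng <- max(dimg)
  if (rng <= 0)
    return(list(mask = matrix(FALSE, nrow(frame), ncol(frame)),
                valid = FALSE, area = 0, circularity = NA_real_))
  dimg <- dimg / rng
  if (params$blur_radius > 0) {
    # blur a window around the brightest difference (the cell) only; far
    # from the cell the difference is noise-level and the blur would not
    # change the histogram materially
    pk <- which.max(dimg)
    pi_ <- (pk - 1) %% nrow(dimg) + 1
    pj <- (pk - 1) %/% nrow(dimg) + 1
    hw <- max(24L, as.integer(6 * params$blur_radius))
    i0 <- max(1, pi_ - hw); i1 <- min(nrow(dimg), pi_ + hw)
    j0 <- max(1, pj - hw); j1 <- min(ncol(dimg), pj + hw)
    if ((i1 - i0 + 1) * (j1 - j0 + 1) >= length(dimg) / 4) {
      dimg <- EBImage::gblur(dimg, sigma = params$blur_radius)
    } else {
      dimg[i0:i1, j0:j1] <- EBImage::gblur(dimg[i0:i1, j0:j1],
                                           sigma = params$blur_radius)
    }
  }
  bins <- pmin(pmax(floor(dimg * 255), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  thr <- tryCatch(
    switch(params$threshold_method,
           max_entropy = max_entropy_threshold(counts),
           triangle = triangle_threshold(counts)),
    error = function(e) NA_real_)
  if (is.na(thr))
    return(list(mask = matrix(FALSE, nrow(frame), ncol(frame)),
                valid = FALSE, area = 0, circularity = NA_real_))
  mask <- bins > thr
  if (params$use_opening) {
    brush <- EBImage::makeBrush(2 * params$opening_radius + 1, shape = "disc")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  labels <- EBImage::bwlabel(mask)
  nmax <- max(labels)
  if (nmax == 0)
    return(list(mask = mask & FALSE, valid = FALSE, area = 0,
                circularity = NA_real_))
  area <- tabulate(labels[labels > 0], nbins = nmax)
  noise_level <- stats::mad(dimg) + 1e-9
  # visit components by decreasing area; the first one passing the area,
  # circularity and prominence filters is the largest surviving component
  for (lab in order(area, decreasing = TRUE)) {
    if (area[lab] < min_area) break
    circ <- component_circularity(labels, lab)
    if (circ < params$circularity_min) next
    sel <- labels == lab
    if (mean(dimg[sel]) < prominence_min * noise_level) next
    return(list(mask = sel, valid = TRUE, area = area[lab],
                circularity = circ))
  }
  list(mask = mask & FALSE, valid = FALSE, area = 0,
       circularity = NA_real_)
}

#' Centroid of a binary mask
#'
#' Pixel-coordinate mean of the foreground, scaled by `pixel_scale`.
#'
#' @param mask Logical matrix.
#' @param pixel_scale mm per pixel.
#' @return Numeric length-2 `(x, y)` in scaled units (pixel units when
#'   `pixel_scale = 1`), or `c(NA, NA)` for an empty mask.
#' @export
centroid <- function(mask, pixel_scale = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  c(mean(idx[, 1]), mean(idx[, 2])) * pixel_scale
}

#' Radial profile of a mask around a center
#'
#' For each angle, the distance from the center to the farthest
#' foreground pixel along that ray (ray marching at half-pixel steps);
#' zero where the ray hits no foreground.
#'
#' @param mask Logical matrix.
#' @param center Length-2 center in pixel coordinates.
#' @param angular_step Angular step in degrees (must divide 360).
#' @param pixel_scale mm per pixel applied to the returned radii.
#' @return Tibble with `angle` (degrees on `[0, 360)`) and `radius`.
#' @export
radial_profile <- function(mask, center, angular_step = 2, pixel_scale = 1) {
  stopifnot(360 %% angular_step == 0, length(center) == 2)
  angles <- seq(0, 360 - angular_step, by = angular_step)
  th <- angles * pi / 180
  rmax <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  rs <- seq(0.5, rmax, by = 0.5)
  px <- round(outer(rs, cos(th)) + center[1])
  py <- round(outer(rs, sin(th)) + center[2])
  ok <- px >= 1 & px <= nrow(mask) & py >= 1 & py <= ncol(mask)
  hit <- matrix(FALSE, length(rs), length(th))
  hit[ok] <- mask[cbind(px[ok], py[ok])]
  radii <- matrixStats::colMaxs(hit * rs)
  tibble::tibble(angle = angles, radius = radii * pixel_scale)
}

#' Cell length from a radial profile
#'
#' The cell length is the sum of the top two local maxima of the radial
#' profile, which pick out the anterior and posterior ends of the
#' elongated cell. The second maximum must lie at least `min_separation`
#' degrees (circularly) from the first so that both ends, not two
#' samples of one end, are used; profiles without two such maxima are
#' flagged invalid.
#'
#' @param profile Tibble from [radial_profile()].
#' @param min_separation Minimum circular separation (degrees) between
#'   the two maxima.
#' @return List with `length`, `theta1`, `theta2`, `valid`.
#' @export
length_from_profile <- function(profile, min_separation = 90) {
  r <- profile$radius
  a <- profile$angle
  n <- length(r)
  if (n < 3 || all(r == r[1]))
    return(list(length = NA_real_, theta1 = NA_real_, theta2 = NA_real_,
                valid = FALSE))
  prev <- c(r[n], r[-n]); nxt <- c(r[-1], r[1])
  is_max <- (r >= prev & r > nxt) | (r > prev & r >= nxt)
  if (!any(is_max))
    return(list(length = NA_real_, theta1 = NA_real_, theta2 = NA_real_,
                valid = FALSE))
  cand <- which(is_max)
  i1 <- cand[which.max(r[cand])]
  circ_dist <- function(x, y) {
    d <- abs(x - y) %% 360
    pmin(d, 360 - d)
  }
  far <- cand[circ_dist(a[cand], a[i1]) >= min_separation]
  if (length(far) == 0)
    return(list(length = NA_real_, theta1 = a[i1], theta2 = NA_real_,
                valid = FALSE))
  i2 <- far[which.max(r[far])]
  list(length = r[i1] + r[i2], theta1 = a[i1], theta2 = a[i2],
       valid = TRUE)
}

#' Segment a whole image stack into a track
#'
#' Runs [segment_frame()], [centroid()], [radial_profile()] and
#' [length_from_profile()] over every frame of a stack, with backgrounds
#' estimated per section of `params$background_window` frames (section
#' boundaries at fixed strides). Centroids are mapped to chamber
#' coordinates (mm, origin at the field center).
#'
#' When `track_window > 0` the search for the cell is restricted to a
#' window of that half-width (px) around the last valid position — the
#' standard single-particle tracking shortcut — falling back to the
#' full frame whenever the windowed search fails.
#'
#' @param stack Array `width x height x n_frames`.
#' @param params A [segmentation_params()].
#' @param fps Frame rate of the stack (1/s).
#' @param pixel_scale mm per pixel.
#' @param min_area Passed to [segment_frame()].
#' @param track_window Half-width (px) of the tracking search window;
#'   0 disables windowed tracking.
#' @return A track tibble: `frame`, `t`, `x`, `y`, `length`,
#'   `theta1`, `valid`, with attributes `fps` and `pixel_scale`.
#' @export
segment_stack <- function(stack, params = segmentation_params(),
                          fps, pixel_scale, min_area = 6,
                          track_window = 0) {
  n <- dim(stack)[3]
  W <- dim(stack)[1]; H <- dim(stack)[2]
  half <- c((W + 1) / 2, (H + 1) / 2)
  starts <- seq(1, n, by = params$background_window)
  x <- y <- len <- th1 <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  last <- NULL
  for (s in starts) {
    idx <- s:min(s + params$background_window - 1, n)
    # every 2nd frame suffices for a stable per-pixel statistic
    bg_idx <- if (length(idx) > 50) idx[seq(1, length(idx), by = 2)] else idx
    bg <- estimate_background(stack, params$background_stat, bg_idx)
    for (i in idx) {
      off <- c(0L, 0L)
      sf <- NULL
      if (track_window > 0 && !is.null(last)) {
        i0 <- max(1L, as.integer(last[1]) - track_window)
        i1 <- min(W, as.integer(last[1]) + track_window)
        j0 <- max(1L, as.integer(last[2]) - track_window)
        j1 <- min(H, as.integer(last[2]) + track_window)
        sf <- segment_frame(stack[i0:i1, j0:j1, i], bg[i0:i1, j0:j1],
                            params, min_area)
        if (sf$valid) off <- c(i0 - 1L, j0 - 1L) else sf <- NULL
      }
      if (is.null(sf)) {
        sf <- segment_frame(stack[, , i], bg, params, min_area)
        if (!sf$valid) { last <- NULL; next }
      }
      cpx <- centroid(sf$mask)
      # profile on the cropped component for speed
      fg <- which(sf$mask, arr.ind = TRUE)
      x0 <- min(fg[, 1]) - 1L; y0 <- min(fg[, 2]) - 1L
      sub <- sf$mask[(x0 + 1L):max(fg[, 1]), (y0 + 1L):max(fg[, 2]),
                     drop = FALSE]
      prof <- radial_profile(sub, cpx - c(x0, y0), params$angular_step)
      lf <- length_from_profile(prof)
      if (!lf$valid) { last <- NULL; next }
      cg <- cpx + off
      last <- cg
      x[i] <- (cg[1] - half[1]) * pixel_scale
      y[i] <- (cg[2] - half[2]) * pixel_scale
      len[i] <- lf$length * pixel_scale
      th1[i] <- lf$theta1
      valid[i] <- TRUE
    }
  }
  out <- tibble::tibble(frame = seq_len(n), t = (seq_len(n) - 1) / fps,
                        x = x, y = y, length = len, theta1 = th1,
                        valid = valid)
  attr(out, "fps") <- fps
  attr(out, "pixel_scale") <- pixel_scale
  out
}
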