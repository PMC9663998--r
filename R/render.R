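#' Default rendering parameters
#'
#' @param pixel_scale mm per pixel.
#' @param field Width of the square rendered field (mm), centered on the
#'   chamber center.
#' @param background_level Background intensity (fraction of full scale).
#' @param cell_contrast How much darker than background the cell body is.
#' @param noise_sd Per-pixel Gaussian noise SD (fraction of full scale).
#' @param gradient_amp Amplitude of a static slowly varying background
#'   field (fraction of full scale); 0 disables it.
#' @param n_dust Number of static dark dust specks.
#' @param aspect Cell minor/major axis ratio.
#' @param taper Teardrop taper of the cell outline toward the anterior
#'   end (0 = plain ellipse).
#' @return A list of rendering parameters.
#' @export
render_params <- function(pixel_scale = 0.04, field = 6,
                          background_level = 0.75, cell_contrast = 0.45,
                          noise_sd = 0.01, gradient_amp = 0.02,
                          n_dust = 0, aspect = 0.4, taper = 0.25) {
  stopifnot(pixel_scale > 0, field > 0, background_level > 0,
            cell_contrast > 0, noise_sd >= 0, aspect > 0, aspect <= 1,
            taper >= 0, taper < 1)
  list(pixel_scale = pixel_scale, field = field,
       background_level = background_level, cell_contrast = cell_contrast,
       noise_sd = noise_sd, gradient_amp = gradient_amp, n_dust = n_dust,
       aspect = aspect, taper = taper)
}

# Per-frame cell orientation from the motion direction; stationary frames
# carry the last moving orientation forward.
orientation_from_track <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dx <- c(x[2] - x[1], diff(x))
  dy <- c(y[2] - y[1], diff(y))
  ang <- atan2(dy, dx)
  still <- sqrt(dx^2 + dy^2) < 1e-9
  if (all(still)) return(rep(0, n))
  for (i in seq_len(n)) if (still[i] && i > 1) ang[i] <- ang[i - 1]
  # back-fill a stationary start
  first_mov <- which(!still)[1]
  if (first_mov > 1) ang[seq_len(first_mov - 1)] <- ang[first_mov]
  ang
}

#' Render a simulated recording into a synthetic image stack
#'
#' Produces 16-bit grayscale frames emulating bright-field recordings of
#' a single dark cell: a background intensity field (optionally slowly
#' varying), per-pixel Gaussian noise, a dark teardrop of major axis
#' equal to the true cell length drawn at the true position and heading,
#' and optional static dust specks.
#'
#' The noise stream is seeded from `seed` and the first frame index of
#' `recording`, while dust speck positions depend on `seed` alone, so a
#' long recording rendered in consecutive chunks has static dust and
#' non-repeating noise.
#'
#' @param recording A `stentor_recording` (or any tibble with `t`,
#'   `true_x`, `true_y`, `true_length`, `frame`).
#' @param rp Rendering parameters from [render_params()].
#' @param seed Integer seed; identical inputs give bit-identical stacks.
#' @return Integer array `height x width x n_frames` of 16-bit counts
#'   (0..65535) with attribute `pixel_scale`.
#' @export
#' @examples
#' rec <- simulate_behavior(duration = 2, fps = 5, seed = 1)
#' stack <- render_frames(rec, render_params(), seed = 1)
#' dim(stack)
render_frames <- function(recording, rp = render_params(), seed = 1) {
  stopifnot(all(c("true_x", "true_y", "true_length") %in% names(recording)))
  n <- nrow(recording)
  if (n < 1) stop("recording has no frames")
  if (min(recording$true_length) / rp$pixel_scale < 3)
    stop("pixel_scale too coarse: cell would be under 3 px long")
  W <- as.integer(round(rp$field / rp$pixel_scale))
  half <- (W + 1) / 2
  px_x <- (seq_len(W) - half) * rp$pixel_scale   # mm at pixel centers
  ang <- orientation_from_track(recording$true_x, recording$true_y)

  # static structures drawn from the bare seed
  set.seed(as.integer(seed))
  base <- matrix(rp$background_level, W, W)
  if (rp$gradient_amp > 0) {
    phx <- stats::runif(2, 0, 2 * pi)
    gx <- sin(2 * pi * px_x / rp$field + phx[1])
    gy <- cos(2 * pi * px_x / rp$field + phx[2])
    base <- base + rp$gradient_amp * outer(gx, gy)
  }
  if (rp$n_dust > 0) {
    dx <- stats::runif(rp$n_dust, -rp$field / 2, rp$field / 2)
    dy <- stats::runif(rp$n_dust, -rp$field / 2, rp$field / 2)
    for (k in seq_len(rp$n_dust)) {
      ix <- which(abs(px_x - dx[k]) <= 1.5 * rp$pixel_scale)
      iy <- which(abs(px_x - dy[k]) <= 1.5 * rp$pixel_scale)
      base[ix, iy] <- base[ix, iy] - rp$cell_contrast * 0.8
    }
  }

  set.seed(as.integer(seed) + recording$frame[1] %% 1000003L)
  out <- array(0L, dim = c(W, W, n))
  a_ratio <- rp$aspect
  for (i in seq_len(n)) {
    img <- base
    if (rp$noise_sd > 0)
      img <- img + matrix(stats::rnorm(W * W, 0, rp$noise_sd), W, W)
    a <- recording$true_length[i] / 2
    b <- a * a_ratio
    cx <- recording$true_x[i]; cy <- recording$true_y[i]
    # local window around the cell
    ix <- which(abs(px_x - cx) <= a + 3 * rp$pixel_scale)
    iy <- which(abs(px_x - cy) <= a + 3 * rp$pixel_scale)
    if (length(ix) && length(iy)) {
      u0 <- outer(px_x[ix] - cx, rep(1, length(iy)))
      v0 <- outer(rep(1, length(ix)), px_x[iy] - cy)
      ca <- cos(ang[i]); sa <- sin(ang[i])
      u <- u0 * ca + v0 * sa
      v <- -u0 * sa + v0 * ca
      wfac <- pmax(1 - rp$taper * u / a, 0.2)
      inside <- (u / a)^2 + (v / (b * wfac))^2 <= 1
      img[ix, iy][inside] <- img[ix, iy][inside] - rp$cell_contrast
    }
    out[, , i] <- as.integer(round(pmin(pmax(img, 0), 1) * 65535))
  }
  attr(out, "pixel_scale") <- rp$pixel_scale
  out
}
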