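#' Deformation rate of a length series
#'
#' eps_i = (L_i - L0) / L0, the relative length change used to quantify
#' shape-transition kinetics. For elongations L0 is the averaged length
#' over the 10 s before the transition; for the contraction it is the
#' contracted length the cell reaches by about 40 ms.
#'
#' @param lengths Length series (mm).
#' @param L0 Reference length (mm), > 0.
#' @param times Optional time axis (defaults to 0, 1, 2, ... frames).
#' @param kind Optional transition kind tag.
#' @return A `deformation_trace` tibble with `time`, `epsilon`,
#'   `length`.
#' @export
deformation_rate <- function(lengths, L0, times = seq_along(lengths) - 1,
                             kind = NULL) {
  stopifnot(L0 > 0, length(times) == length(lengths))
  out <- tibble::tibble(time = times, epsilon = (lengths - L0) / L0,
                        length = lengths)
  attr(out, "L0") <- L0
  attr(out, "kind") <- kind
  class(out) <- c("deformation_trace", class(out))
  out
}

#' Detect the start of an elongation by the line-crossing construction
#'
#' The starting point of a slow elongation is the crossing of two lines:
#' one fit to the pre-transition plateau and one fit to the initial
#' rise. A candidate rise is the first run of `persist` frames exceeding
#' the extrapolated plateau line by 3 plateau-residual SDs; the plateau
#' line is then refit to the `plateau_window` s before the candidate and
#' the rise line to the first `rise_window` s from it.
#'
#' @param x Smoothed series (length or deformation rate).
#' @param fps Sampling rate (1/s).
#' @param plateau_window,rise_window Fit windows (s).
#' @param persist Consecutive frames required above threshold.
#' @return Integer start index (attribute `"time"` holds the fractional
#'   crossing time in frames-from-start-of-series units / fps).
#' @export
detect_start_elongation_cross <- function(x, fps, plateau_window = 10,
                                          rise_window = 30, persist = 3) {
  n <- length(x)
  w0 <- max(3L, as.integer(round(plateau_window * fps)))
  if (n < w0 + persist + 2) stop("series too short for start detection")
  idx0 <- seq_len(w0)
  f0 <- stats::lm(x[idx0] ~ idx0)
  sd0 <- stats::sd(stats::residuals(f0))
  pred <- stats::coef(f0)[1] + stats::coef(f0)[2] * seq_len(n)
  above <- x > pred + 3 * sd0
  runs <- rle(above)
  pos <- cumsum(runs$lengths) - runs$lengths + 1
  cand <- pos[runs$values & runs$lengths >= persist]
  cand <- cand[cand > w0]
  if (length(cand) == 0) stop("no detectable slope change")
  cstart <- cand[1]
  pidx <- max(1, cstart - w0):(cstart - 1)
  fp <- stats::lm(x[pidx] ~ pidx)
  ridx <- cstart:min(n, cstart + as.integer(round(rise_window * fps)))
  fr <- stats::lm(x[ridx] ~ ridx)
  a1 <- stats::coef(fp)[1]; b1 <- stats::coef(fp)[2]
  a2 <- stats::coef(fr)[1]; b2 <- stats::coef(fr)[2]
  if (abs(b2 - b1) < 1e-12) stop("no detectable slope change")
  cross <- (a1 - a2) / (b2 - b1)
  # a crossing far from the candidate region means the two lines were
  # near-parallel (plateau window contaminated by a slow early rise) and
  # the construction is unreliable
  if (cross < 1 || cross > min(n, max(ridx) + rise_window * fps))
    stop("no detectable slope change: crossing ill-conditioned")
  out <- as.integer(round(cross))
  attr(out, "time") <- (cross - 1) / fps
  out
}

#' Detect the regrowth start after a contraction
#'
#' The start of the droplet-to-cone or droplet-to-trumpet elongation is
#' the point of minimum (smoothed) length between the contraction and
#' `search_window` s after it; ties take the first minimizing index.
#'
#' @param x Smoothed length series.
#' @param fps Sampling rate (1/s).
#' @param from Index of the contraction event (default 1).
#' @param search_window Search horizon (s).
#' @return Integer index of the minimum.
#' @export
detect_start_post_contraction <- function(x, fps, from = 1,
                                          search_window = 20) {
  to <- min(length(x), from + as.integer(round(search_window * fps)))
  idx <- from:to
  idx[which.min(x[idx])]
}

#' Fit the exponential elongation model
#'
#' Nonlinear least squares of eps(t) = A (1 - exp(-t / tau)) to a
#' deformation trace, the relaxation form of a slow shape transition.
#' When the trace includes a pre-transition plateau (times below zero or
#' `detect_start = TRUE`), a free transition-onset parameter t0 is fit
#' alongside, eps(t) = A (1 - exp(-(t - t0) / tau)) for t >= t0 and 0
#' before, initialized at the line-crossing start from
#' [detect_start_elongation_cross()]. Fitting the onset rather than
#' truncating at it avoids the tau bias a misplaced hard start would
#' cause. Initialization is deterministic: A from the final plateau of
#' the trace, tau from the time to 63% of it; A and tau are bounded
#' positive.
#'
#' @param trace A `deformation_trace` (columns `time`, `epsilon`).
#' @param detect_start Fit the transition onset (default when the trace
#'   carries a plateau, i.e. negative times).
#' @return An `exp_fit` object: estimates `A`, `tau` (and `t0` when
#'   fitted), standard errors, residual norm.
#' @export
fit_elongation <- function(trace, detect_start = any(trace$time < 0)) {
  t <- trace$time; e <- trace$epsilon
  if (!detect_start) {
    keep <- t >= 0
    t <- t[keep]; e <- e[keep]
  }
  if (length(t) < 4) stop("too few points to fit")
  A0 <- mean(e[t >= stats::quantile(t, 0.9)])
  if (!is.finite(A0) || abs(A0) < 1e-9)
    stop("degenerate trace: no elongation amplitude (A ~ 0)")
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  # standard errors from the Jacobian at the optimum; NA when singular
  se_from <- function(fit, k) {
    tryCatch({
      s2 <- sum(fit$fvec^2) / max(length(fit$fvec) - k, 1)
      sqrt(diag(solve(fit$hessian)) * s2)
    }, error = function(err) rep(NA_real_, k))
  }
  if (detect_start) {
    fps <- 1 / stats::median(diff(t))
    # two deterministic onset starts: the line-crossing when available,
    # and the first 10%-of-amplitude rise; keep the better fit
    t_rise <- t[which(e >= 0.1 * A0)[1]]
    t00s <- unique(c(
      tryCatch(t[1] + attr(detect_start_elongation_cross(e, fps), "time"),
               error = function(err) NULL),
      if (is.finite(t_rise)) t_rise else 0))
    resid_fn <- function(p) e - p[1] * (1 - exp(-pmax(t - p[3], 0) / p[2]))
    fit <- NULL
    for (t00 in t00s) {
      i63 <- which(e >= (1 - exp(-1)) * A0 & t > t00)[1]
      tau0 <- if (is.na(i63)) (max(t) - t00) / 3 else max(t[i63] - t00, 1 / fps)
      cand <- minpack.lm::nls.lm(par = c(A0, tau0, t00), fn = resid_fn,
                                 lower = c(1e-9, 1e-9, min(t)),
                                 upper = c(Inf, Inf, max(t)), control = ctl)
      if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
    }
    cf <- fit$par
    out <- list(A = cf[1], tau = cf[2], t0 = cf[3],
                se = stats::setNames(se_from(fit, 3), c("A", "tau", "t0")))
  } else {
    i63 <- which(e >= (1 - exp(-1)) * A0)[1]
    tau0 <- if (is.na(i63) || t[i63] <= 0) max(t) / 3 else t[i63]
    resid_fn <- function(p) e - p[1] * (1 - exp(-t / p[2]))
    fit <- minpack.lm::nls.lm(par = c(A0, tau0), fn = resid_fn,
                              lower = c(1e-9, 1e-9), control = ctl)
    cf <- fit$par
    out <- list(A = cf[1], tau = cf[2], t0 = 0,
                se = stats::setNames(se_from(fit, 2), c("A", "tau")))
  }
  out$rss <- sum(fit$fvec^2)
  out$n <- length(t)
  out$data <- tibble::tibble(t = t, e = e)
  structure(out, class = "exp_fit")
}

#' Fit the two-mode contraction model
#'
#' Nonlinear least squares of
#' eps(t) = B1 exp(-t / tau1) + B2 exp(-t / tau2) to an ultrafast
#' contraction trace (times in ms), the solution form of a damped
#' relaxation with two time scales. The result is reported with
#' tau1 < tau2. A single-exponential model is fit alongside and both
#' residual norms are returned so the two-time-scale model comparison
#' can be made explicitly; if the two-mode optimum is ever beaten by the
#' single-mode one it is refit from the nested solution, so its residual
#' norm never exceeds the single-mode norm.
#'
#' @param trace A `deformation_trace` with `time` in ms; points at
#'   `time >= 0` are fit.
#' @param init_tau Deterministic initial (tau1, tau2) in ms.
#' @return A `two_mode_fit`: `B1`, `B2`, `tau1`, `tau2`, standard
#'   errors, `rss`, and `single` (the single-mode fit: `B`, `tau`,
#'   `rss`). Warns when tau2/tau1 < 1.5 (modes unresolved).
#' @export
fit_contraction <- function(trace, init_tau = c(1, 10)) {
  keep <- trace$time >= 0
  df <- data.frame(t = trace$time[keep], e = trace$epsilon[keep])
  if (nrow(df) < 6) stop("too few points to fit")
  amp <- df$e[which.min(df$t)]
  if (!is.finite(amp) || abs(amp) < 1e-9)
    stop("degenerate trace: no contraction amplitude")
  two <- minpack.lm::nlsLM(
    e ~ B1 * exp(-t / tau1) + B2 * exp(-t / tau2), data = df,
    start = list(B1 = amp / 2, tau1 = init_tau[1],
                 B2 = amp / 2, tau2 = init_tau[2]),
    lower = rep(1e-9, 4),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  one <- minpack.lm::nlsLM(e ~ B * exp(-t / tau), data = df,
                           start = list(B = amp, tau = init_tau[2]),
                           lower = c(1e-9, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  rss2 <- sum(stats::residuals(two)^2)
  rss1 <- sum(stats::residuals(one)^2)
  if (rss2 > rss1) {
    cf1 <- stats::coef(one)
    two <- minpack.lm::nlsLM(
      e ~ B1 * exp(-t / tau1) + B2 * exp(-t / tau2), data = df,
      start = list(B1 = cf1[["B"]] * (1 - 1e-6), tau1 = cf1[["tau"]],
                   B2 = cf1[["B"]] * 1e-6, tau2 = cf1[["tau"]] * 2),
      lower = rep(1e-9, 4),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    rss2 <- min(sum(stats::residuals(two)^2), rss1)
  }
  cf <- stats::coef(two)
  se <- tryCatch(sqrt(diag(stats::vcov(two))),
                 error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  if (cf[["tau1"]] > cf[["tau2"]]) {
    cf <- cf[c("B2", "tau2", "B1", "tau1")]
    se <- se[c("B2", "tau2", "B1", "tau1")]
    names(cf) <- names(se) <- c("B1", "tau1", "B2", "tau2")
  }
  if (cf[["tau2"]] / cf[["tau1"]] < 1.5)
    warning("contraction modes unresolved: tau2/tau1 < 1.5")
  structure(list(B1 = unname(cf[["B1"]]), B2 = unname(cf[["B2"]]),
                 tau1 = unname(cf[["tau1"]]), tau2 = unname(cf[["tau2"]]),
                 se = se, rss = rss2,
                 single = list(B = unname(stats::coef(one)[["B"]]),
                               tau = unname(stats::coef(one)[["tau"]]),
                               rss = rss1),
                 n = nrow(df), data = tibble::as_tibble(df)),
            class = "two_mode_fit")
}

#' Fit the piecewise speed-length power laws
#'
#' For a cone-to-trumpet transition, speed and length are normalized so
#' that the maximum speed is 1 and the length at that moment is 1, and
#' log speed is regressed on log length by ordinary least squares within
#' each normalized-length range (default 1-1.25 and 1.25-1.45, the
#' breakpoint being fixed, not estimated).
#'
#' @param lengths,speeds Paired series from one transition (any units).
#' @param ranges List of normalized-length ranges.
#' @return A `power_law_fits` object: one element per range with
#'   `exponent`, `intercept`, `range`, `n`.
#' @export
fit_power_laws <- function(lengths, speeds,
                           ranges = list(c(1, 1.25), c(1.25, 1.45))) {
  stopifnot(length(lengths) == length(speeds))
  imax <- which.max(speeds)
  l <- lengths / lengths[imax]
  s <- speeds / speeds[imax]
  fits <- lapply(ranges, function(rg) {
    keep <- l >= rg[1] & l <= rg[2] & s > 0 & l > 0
    if (sum(keep) < 3)
      return(list(exponent = NA_real_, intercept = NA_real_,
                  range = rg, n = sum(keep)))
    fm <- stats::lm(log(s[keep]) ~ log(l[keep]))
    list(exponent = unname(stats::coef(fm)[2]),
         intercept = unname(stats::coef(fm)[1]),
         range = rg, n = sum(keep))
  })
  structure(fits, class = "power_law_fits")
}
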