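#' Simulate a deformation-rate trace for one shape transition
#'
#' Samples the deformation rate eps(t) = (L(t) - L0) / L0 of a single
#' shape transition from its model curve plus i.i.d. Gaussian noise,
#' including a pre-transition plateau segment. Elongations (droplet to
#' cone, droplet to trumpet, cone to trumpet) follow
#' eps(t) = A (1 - exp(-t / tau)) with the transition-specific time
#' constant and A set by the state target lengths; the trumpet-to-droplet
#' contraction follows the two-mode decay
#' eps(t) = B1 exp(-t / tau1) + B2 exp(-t / tau2) with times in
#' milliseconds, reflecting the damped-relaxation mechanics of the
#' ultrafast contraction.
#'
#' For elongations the reference length L0 is the pre-transition resting
#' length; for the contraction it is the contracted (droplet) length, the
#' asymptote the observed length reaches by about 40 ms.
#'
#' @param kind One of `"droplet_to_cone"`, `"droplet_to_trumpet"`,
#'   `"cone_to_trumpet"`, `"trumpet_to_droplet"`.
#' @param params A [behavior_params()].
#' @param noise_sd Gaussian noise SD added to eps (dimensionless; must be
#'   >= 0).
#' @param fps Sampling rate (1/s). The contraction requires
#'   `fps >= 2000`, matching the high-speed recordings it emulates.
#' @param seed Integer seed.
#' @param plateau Pre-transition plateau duration (s for elongations, ms
#'   for the contraction).
#' @param duration Post-transition duration; defaults to 6 tau for
#'   elongations and 50 ms for the contraction.
#' @return A `deformation_trace`: tibble with columns `time` (s, or ms
#'   for the contraction), `epsilon`, `length` (mm), and attributes
#'   `kind`, `L0`, `fps`, `time_unit` and `truth` (the generating
#'   parameters).
#' @export
#' @examples
#' tr <- simulate_deformation_trace("droplet_to_cone", noise_sd = 0, fps = 10, seed = 1)
#' fit_elongation(tr)
simulate_deformation_trace <- function(kind = c("droplet_to_cone",
                                                "droplet_to_trumpet",
                                                "cone_to_trumpet",
                                                "trumpet_to_droplet"),
                                       params = behavior_params(),
                                       noise_sd = 0, fps = 10, seed = 1,
                                       plateau = NULL, duration = NULL) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(fps > 0)
  set.seed(as.integer(seed))
  tl <- params$target_length

  if (kind == "trumpet_to_droplet") {
    if (fps < 2000)
      stop("the contraction must be sampled at >= 2000 fps")
    L0 <- tl[["droplet"]]
    amp <- (tl[["trumpet"]] - L0) / L0
    B1 <- amp * params$contraction_B1
    B2 <- amp * params$contraction_B2
    if (is.null(plateau)) plateau <- 5      # ms
    if (is.null(duration)) duration <- 50   # ms
    step <- 1000 / fps
    time <- seq(-plateau, duration, by = step)
    eps <- ifelse(time < 0, amp,
                  B1 * exp(-time / params$contraction_tau1) +
                    B2 * exp(-time / params$contraction_tau2))
    truth <- list(B1 = B1, B2 = B2, tau1 = params$contraction_tau1,
                  tau2 = params$contraction_tau2)
    unit <- "ms"
  } else {
    from <- sub("_to_.*", "", kind)
    to <- sub(".*_to_", "", kind)
    tau <- switch(kind,
                  droplet_to_cone = params$tau_droplet_to_cone,
                  droplet_to_trumpet = params$tau_droplet_to_trumpet,
                  cone_to_trumpet = params$tau_cone_to_trumpet)
    L0 <- tl[[from]]
    A <- (tl[[to]] - L0) / L0
    if (is.null(plateau)) plateau <- 10
    if (is.null(duration)) duration <- 6 * tau
    time <- seq(-plateau, duration, by = 1 / fps)
    eps <- ifelse(time < 0, 0, A * (1 - exp(-time / tau)))
    truth <- list(A = A, tau = tau)
    unit <- "s"
  }

  if (noise_sd > 0) eps <- eps + stats::rnorm(length(eps), 0, noise_sd)
  out <- tibble::tibble(time = time, epsilon = eps,
                        length = L0 * (1 + eps))
  attr(out, "kind") <- kind
  attr(out, "L0") <- L0
  attr(out, "fps") <- fps
  attr(out, "time_unit") <- unit
  attr(out, "truth") <- truth
  class(out) <- c("deformation_trace", class(out))
  out
}

#' Simulate paired length and speed series of a cone-to-trumpet transition
#'
#' Ground-truth input for the speed-length power-law analysis: length
#' relaxes from the cone toward the trumpet target with the
#' cone-to-trumpet time constant while speed follows the piecewise
#' power-law coupling of [speed_length_coupling()], with Gaussian noise
#' added to both normalized series.
#'
#' @param params A [behavior_params()].
#' @param noise_sd Noise SD on the normalized length and speed.
#' @param fps Sampling rate (1/s).
#' @param seed Integer seed.
#' @param l_end Normalized length at which the simulated transition ends.
#' @return Tibble with columns `time` (s), `length` (mm), `speed` (mm/s).
#' @export
simulate_speed_length_transition <- function(params = behavior_params(),
                                             noise_sd = 0.02, fps = 10,
                                             seed = 1, l_end = 1.48) {
  stopifnot(fps > 0, noise_sd >= 0, l_end > 1, l_end < 1.5)
  set.seed(as.integer(seed))
  L0 <- params$target_length[["cone"]]
  s0 <- params$cone_speed
  tau <- params$tau_cone_to_trumpet
  lt <- params$target_length[["trumpet"]] / L0   # 1.5 normalized
  t_end <- -tau * log((lt - l_end) / (lt - 1))
  time <- seq(0, t_end, by = 1 / fps)
  lnorm <- lt - (lt - 1) * exp(-time / tau)
  snorm <- speed_length_coupling(lnorm, params)
  if (noise_sd > 0) {
    lnorm <- lnorm + stats::rnorm(length(time), 0, noise_sd)
    snorm <- snorm + stats::rnorm(length(time), 0, noise_sd)
  }
  tibble::tibble(time = time, length = L0 * lnorm,
                 speed = pmax(s0 * snorm, 1e-6))
}
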