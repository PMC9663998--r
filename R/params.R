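#' Behavioral model parameters
#'
#' Bundles every constant of the three-state (droplet / cone / trumpet)
#' behavior model used by [simulate_behavior()] and
#' [simulate_deformation_trace()]: state target lengths, transition
#' relaxation time constants, motility constants, semi-Markov dwell means,
#' the geometry-biased adhesion hazard, and observation-noise levels.
#'
#' Time constants default to the measured relaxation times of each shape
#' transition: 16.2 s (droplet to cone), 40.1 s (droplet to trumpet),
#' 107.9 s (cone to trumpet), and the two-mode contraction constants
#' 2.1 ms and 15.6 ms (trumpet to droplet). Target lengths are scale-free
#' with ratios droplet : cone : trumpet = 0.5 : 1 : 1.5.
#'
#' Dwell means are calibrated, not measured: the source recordings report
#' state frequencies (2.0% droplet, 72.3% cone, 25.7% trumpet in a plain
#' chamber; 72.4% trumpet in a structured chamber) but no switching rates.
#' The defaults were tuned once, by long-run simulation, so that the
#' classified state frequencies of the full analysis pipeline reproduce
#' those fractions; see the package vignette for the calibration account.
#'
#' @param target_length Named numeric: resting length (mm) of each state.
#' @param tau_droplet_to_cone,tau_droplet_to_trumpet,tau_cone_to_trumpet
#'   Exponential relaxation time constants (s) of the three elongations.
#' @param contraction_tau1,contraction_tau2 Fast and slow time constants
#'   (ms) of the two-mode trumpet-to-droplet contraction; `tau1 < tau2`.
#' @param contraction_B1,contraction_B2 Amplitude fractions of the two
#'   contraction modes (they are renormalized to sum to 1).
#' @param cone_speed Free-swimming speed in the cone state (mm/s).
#' @param trumpet_orbit_diameter Diameter (mm) of the local circular
#'   trajectory in the non-adhered trumpet state.
#' @param dwell_mean_droplet,dwell_mean_cone,dwell_mean_trumpet,dwell_mean_adhered
#'   Mean dwell times (s) of the semi-Markov state process.
#'   `dwell_mean_trumpet` governs the rotating (non-adhered) trumpet,
#'   `dwell_mean_adhered` the anchored trumpet.
#' @param dwell_shape Gamma shape of the dwell-time distributions
#'   (mean fixed at the configured dwell means). The default 3 gives
#'   bout durations with a mode near the mean, as commonly observed for
#'   behavioral bouts; 1 gives exponential dwells.
#' @param p_droplet_to_cone Embedded-chain probability that a droplet
#'   elongates into a cone rather than directly into a trumpet.
#' @param adhesion_base_hazard Baseline hazard (1/s) of the cone to
#'   adhered-trumpet switch while swimming.
#' @param crescent_adhesion_multiplier Factor (>= 1) multiplying the
#'   adhesion hazard while the cell is inside a crescent dead-end area.
#' @param power_exponent_lo,power_exponent_hi Exponents of the piecewise
#'   speed-length power law during the cone-to-trumpet transition, on the
#'   normalized-length ranges (1, 1.25) and (1.25, 1.45).
#' @param heading_noise Rotational diffusion of the cone swimming heading
#'   (rad per sqrt(s)).
#' @param anterior_concentration Concentration (1/variance, rad^-2) of the
#'   anterior-end direction of adhered cells about the direction pointing
#'   away from the dead end.
#' @param noise_position_sd,noise_length_sd Gaussian observation noise
#'   (mm) added to reported positions and lengths.
#'
#' @return An object of class `behavior_params` (a named list).
#' @export
#' @examples
#' p <- behavior_params()
#' p$tau_cone_to_trumpet
behavior_params <- function(target_length = c(droplet = 0.25, cone = 0.5, trumpet = 0.75),
                            tau_droplet_to_cone = 16.2,
                            tau_droplet_to_trumpet = 40.1,
                            tau_cone_to_trumpet = 107.9,
                            contraction_tau1 = 2.1,
                            contraction_tau2 = 15.6,
                            contraction_B1 = 0.5,
                            contraction_B2 = 0.5,
                            cone_speed = 1.0,
                            trumpet_orbit_diameter = 1.4,
                            dwell_mean_droplet = 1.9,
                            dwell_mean_cone = 50,
                            dwell_mean_trumpet = 86,
                            dwell_mean_adhered = 240,
                            dwell_shape = 3,
                            p_droplet_to_cone = 0.93,
                            adhesion_base_hazard = 1 / 4000,
                            crescent_adhesion_multiplier = 20,
                            power_exponent_lo = -6.3,
                            power_exponent_hi = 0.2,
                            heading_noise = 0.2,
                            anterior_concentration = 8,
                            noise_position_sd = 0,
                            noise_length_sd = 0) {
  stopifnot(
    all(c("droplet", "cone", "trumpet") %in% names(target_length)),
    all(target_length > 0),
    tau_droplet_to_cone > 0, tau_droplet_to_trumpet > 0, tau_cone_to_trumpet > 0,
    contraction_tau1 > 0, contraction_tau2 > 0,
    contraction_tau1 < contraction_tau2,
    contraction_B1 >= 0, contraction_B2 >= 0, contraction_B1 + contraction_B2 > 0,
    cone_speed > 0, trumpet_orbit_diameter > 0,
    dwell_mean_droplet > 0, dwell_mean_cone > 0,
    dwell_mean_trumpet > 0, dwell_mean_adhered > 0, dwell_shape > 0,
    p_droplet_to_cone >= 0, p_droplet_to_cone <= 1,
    adhesion_base_hazard >= 0,
    crescent_adhesion_multiplier >= 1,
    heading_noise >= 0, anterior_concentration > 0,
    noise_position_sd >= 0, noise_length_sd >= 0
  )
  structure(list(
    target_length = target_length[c("droplet", "cone", "trumpet")],
    tau_droplet_to_cone = tau_droplet_to_cone,
    tau_droplet_to_trumpet = tau_droplet_to_trumpet,
    tau_cone_to_trumpet = tau_cone_to_trumpet,
    contraction_tau1 = contraction_tau1,
    contraction_tau2 = contraction_tau2,
    contraction_B1 = contraction_B1 / (contraction_B1 + contraction_B2),
    contraction_B2 = contraction_B2 / (contraction_B1 + contraction_B2),
    cone_speed = cone_speed,
    trumpet_orbit_diameter = trumpet_orbit_diameter,
    dwell_mean_droplet = dwell_mean_droplet,
    dwell_mean_cone = dwell_mean_cone,
    dwell_mean_trumpet = dwell_mean_trumpet,
    dwell_mean_adhered = dwell_mean_adhered,
    dwell_shape = dwell_shape,
    p_droplet_to_cone = p_droplet_to_cone,
    adhesion_base_hazard = adhesion_base_hazard,
    crescent_adhesion_multiplier = crescent_adhesion_multiplier,
    power_exponent_lo = power_exponent_lo,
    power_exponent_hi = power_exponent_hi,
    heading_noise = heading_noise,
    anterior_concentration = anterior_concentration,
    noise_position_sd = noise_position_sd,
    noise_length_sd = noise_length_sd
  ), class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("<behavior_params>\n")
  cat(sprintf("  target lengths (mm): droplet %.3g, cone %.3g, trumpet %.3g\n",
              x$target_length[["droplet"]], x$target_length[["cone"]],
              x$target_length[["trumpet"]]))
  cat(sprintf("  elongation tau (s): %.4g (D>C), %.4g (D>T), %.4g (C>T)\n",
              x$tau_droplet_to_cone, x$tau_droplet_to_trumpet,
              x$tau_cone_to_trumpet))
  cat(sprintf("  contraction tau (ms): %.3g / %.3g (B %.2f/%.2f)\n",
              x$contraction_tau1, x$contraction_tau2,
              x$contraction_B1, x$contraction_B2))
  cat(sprintf("  dwell means (s): D %.3g, C %.3g, T %.3g, adhered %.3g\n",
              x$dwell_mean_droplet, x$dwell_mean_cone,
              x$dwell_mean_trumpet, x$dwell_mean_adhered))
  invisible(x)
}

#' Classification thresholds on the normalized state field
#'
#' Cut points used by [classify_states()]: a swimming cell (normalized
#' speed at or above `speed_cut`) is a cone; a slow cell is a droplet when
#' shorter than `length_cut_low`, a trumpet when longer than
#' `length_cut_high`, and in transition in between. The cuts are inferred
#' from the well-separated normalized length and speed distributions of
#' the three states (cone = 1 by construction).
#'
#' @param speed_cut Normalized-speed threshold separating swimming from
#'   slow or adhered behavior.
#' @param length_cut_low,length_cut_high Normalized-length cuts bounding
#'   the droplet and trumpet regions; must bracket 1.
#' @return A `classification_thresholds` list.
#' @export
classification_thresholds <- function(speed_cut = 0.5,
                                      length_cut_low = 0.8,
                                      length_cut_high = 1.2) {
  stopifnot(speed_cut > 0, length_cut_low < 1, length_cut_high > 1)
  structure(list(speed_cut = speed_cut,
                 length_cut_low = length_cut_low,
                 length_cut_high = length_cut_high),
            class = "classification_thresholds")
}

#' Segmentation parameters
#'
#' Parameters of the per-frame segmentation in [segment_frame()] /
#' [segment_stack()]. Defaults follow the single-cell recordings
#' (median background over 2000-frame sections, Gaussian blur radius
#' 1.1 px, maximum-entropy threshold, 2 degree polar step); chamber-survey
#' movies use max background, blur 0.5 px, the triangle threshold and a
#' 1 degree step, with small objects removed by a circularity cut or a
#' 4 px opening.
#'
#' @param background_stat `"median"` or `"max"` per-pixel statistic.
#' @param background_window Frames per background section.
#' @param blur_radius Gaussian blur sigma in pixels.
#' @param threshold_method `"max_entropy"` or `"triangle"`.
#' @param circularity_min Minimum circularity (4 pi area / perimeter^2)
#'   for a component to be kept; the recordings state that a circularity
#'   filter was used but not its value.
#' @param opening_radius Radius (px) of the binary opening applied when
#'   `use_opening` is `TRUE`.
#' @param use_opening Apply the opening step instead of relying on the
#'   circularity filter alone.
#' @param angular_step Polar sampling step (degrees); must divide 360.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(background_stat = c("median", "max"),
                                background_window = 2000,
                                blur_radius = 1.1,
                                threshold_method = c("max_entropy", "triangle"),
                                circularity_min = 0.3,
                                opening_radius = 4,
                                use_opening = FALSE,
                                angular_step = 2) {
  background_stat <- match.arg(background_stat)
  threshold_method <- match.arg(threshold_method)
  stopifnot(background_window >= 1, blur_radius >= 0,
            circularity_min >= 0, circularity_min <= 1,
            opening_radius >= 1,
            angular_step > 0, 360 %% angular_step == 0)
  structure(list(background_stat = background_stat,
                 background_window = background_window,
                 blur_radius = blur_radius,
                 threshold_method = threshold_method,
                 circularity_min = circularity_min,
                 opening_radius = opening_radius,
                 use_opening = use_opening,
                 angular_step = angular_step),
            class = "segmentation_params")
}

#' Structured-chamber behavior calibration
#'
#' [behavior_params()] with the structured-chamber adhesion calibration
#' applied: confinement between the inner disk and the wall keeps the
#' cell in contact with surfaces, which strongly promotes holdfast
#' anchoring, so the baseline adhesion hazard is much higher than in the
#' plain chamber while the crescent multiplier still concentrates
#' adhesion in the dead ends. Calibrated once, by long-run simulation,
#' so the full pipeline recovers the structured-chamber trumpet
#' frequency (72.4%).
#'
#' @param ... Overrides passed on to [behavior_params()].
#' @return A `behavior_params` object.
#' @export
structured_behavior_params <- function(...) {
  args <- utils::modifyList(
    list(adhesion_base_hazard = 1 / 60, dwell_mean_adhered = 250),
    list(...))
  do.call(behavior_params, args)
}
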