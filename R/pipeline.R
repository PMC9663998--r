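#' Pipeline configuration
#'
#' Assembles the configuration of an end-to-end run: chamber and
#' behavior settings, rendering and segmentation parameters, stage
#' toggles, seed and output directory. Every parameter defaults to the
#' study's stated value where one exists; the configuration
#' round-trips losslessly through YAML via [write_pipeline_config()].
#'
#' @param seed Integer master seed; each stage derives its own stream.
#' @param duration Simulated duration (s).
#' @param sim_fps Integration rate of the simulator (1/s).
#' @param render_stride Keep every `render_stride`-th simulated frame
#'   for rendering and analysis.
#' @param structured Use the structured chamber (inner disk) instead of
#'   the plain one.
#' @param behavior,render,segmentation,thresholds Named lists of
#'   overrides applied to [behavior_params()], [render_params()],
#'   [segmentation_params()] and [classification_thresholds()].
#' @param stages Named logical vector toggling `render`, `states`,
#'   `kinetics`, `spatial`.
#' @param n_traces Deformation traces per transition kind in the
#'   kinetics stage.
#' @param out_dir Optional output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, duration = 43200, sim_fps = 4,
                            render_stride = 2, structured = FALSE,
                            behavior = list(), render = list(),
                            segmentation = list(), thresholds = list(),
                            stages = c(render = TRUE, states = TRUE,
                                       kinetics = FALSE, spatial = FALSE),
                            n_traces = 20, out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), duration = duration,
              sim_fps = sim_fps, render_stride = as.integer(render_stride),
              structured = isTRUE(structured), behavior = behavior,
              render = render, segmentation = segmentation,
              thresholds = thresholds,
              stages = as.list(stages), n_traces = n_traces,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file.
#' @return `path` (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$render_stride <- as.integer(cfg$render_stride)
  class(cfg) <- "pipeline_config"
  cfg
}

# build parameter objects from a config
config_objects <- function(config) {
  bp <- if (config$structured) {
    do.call(structured_behavior_params, config$behavior)
  } else {
    do.call(behavior_params, config$behavior)
  }
  geom <- chamber_geometry(inner_disk = config$structured)
  rp <- do.call(render_params, config$render)
  seg_defaults <- if (config$structured) {
    list(background_stat = "max", blur_radius = 0.5,
         threshold_method = "triangle", angular_step = 1)
  } else {
    list(background_stat = "median", blur_radius = 1.1,
         threshold_method = "max_entropy", angular_step = 2)
  }
  seg_args <- utils::modifyList(seg_defaults, config$segmentation)
  sp <- do.call(segmentation_params, seg_args)
  th <- do.call(classification_thresholds, config$thresholds)
  list(behavior = bp, geometry = geom, render = rp, segmentation = sp,
       thresholds = th)
}

#' Render, segment and classify a recording
#'
#' The measurement half of the pipeline: renders a recording to frames
#' in chunks (one background section at a time), segments every frame,
#' assembles the measured track, computes speeds, smooths, normalizes
#' against an automatically chosen cone window and classifies the
#' states. The background window is given in seconds and converted at
#' the recording's frame rate.
#'
#' @param recording A `stentor_recording` (typically thinned to the
#'   analysis frame rate).
#' @param rp,sp,thresholds Rendering, segmentation and classification
#'   parameters.
#' @param seed Seed for the renderer noise.
#' @param bg_window_s Background section length (s); defaults to 400 s
#'   for median backgrounds and 900 s (15 min) for max backgrounds.
#' @return List with `track` (classified, normalized) and `frequencies`.
#' @export
quantify_recording <- function(recording, rp = render_params(),
                               sp = segmentation_params(),
                               thresholds = classification_thresholds(),
                               seed = 1,
                               bg_window_s = if (sp$background_stat == "max") 900 else 400) {
  fps <- attr(recording, "fps")
  n <- nrow(recording)
  win <- max(25L, as.integer(round(bg_window_s * fps)))
  starts <- seq(1, n, by = win)
  pieces <- vector("list", length(starts))
  spw <- sp
  spw$background_window <- win
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + win - 1, n)
    stack <- render_frames(recording[idx, ], rp, seed = seed + k)
    piece <- segment_stack(stack, spw, fps = fps,
                           pixel_scale = rp$pixel_scale,
                           track_window = 30)
    piece$frame <- idx
    piece$t <- recording$t[idx]
    pieces[[k]] <- piece
  }
  track <- dplyr::bind_rows(pieces)
  attr(track, "fps") <- fps
  attr(track, "pixel_scale") <- rp$pixel_scale
  track <- instantaneous_speed(track)
  track <- smooth_track(track)
  track <- normalize_track(track)
  track <- classify_states(track, thresholds)
  list(track = track, frequencies = state_frequencies(track))
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order: simulate the
#' behavior, render and segment the movie (or take the simulated
#' observations directly when rendering is disabled), build the
#' normalized state series and classify states, fit the transition
#' kinetics on a battery of synthetic deformation traces, and compute
#' the spatial statistics. Returns a consolidated report and optionally
#' writes per-stage artifacts (ground-truth CSV, config YAML, report
#' JSON) to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `config`, `frequencies`, `track`,
#'   plus `kinetics` and `spatial` blocks when enabled.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  obj <- config_objects(config)
  stages <- config$stages
  rec <- simulate_behavior(obj$behavior, obj$geometry,
                           duration = config$duration,
                           fps = config$sim_fps, seed = config$seed)
  rec_a <- thin_recording(rec, config$render_stride)
  report <- list(config = config, seed = config$seed)

  if (isTRUE(stages$render)) {
    q <- quantify_recording(rec_a, obj$render, obj$segmentation,
                            obj$thresholds, seed = config$seed + 1000L)
    track <- q$track
  } else {
    track <- rec_a
    track <- instantaneous_speed(track)
    track$valid <- TRUE
    track <- smooth_track(track)
    track <- normalize_track(track)
    track <- classify_states(track, obj$thresholds)
  }
  report$frequencies <- state_frequencies(track)
  report$track <- track

  if (isTRUE(stages$states)) {
    track_v <- transition_vectors(track)
    report$vector_field <- grid_vector_field(track_v)
    steady <- exclude_transition_periods(track, attr(track, "fps"))
    report$steady_fraction <- mean(steady)
    steady_pts <- track[steady, ]
    report$clusters <- tryCatch(cluster_states(steady_pts),
                                error = function(e) NULL)
  }

  if (isTRUE(stages$kinetics)) {
    kinds <- c("droplet_to_cone", "droplet_to_trumpet", "cone_to_trumpet")
    taus <- lapply(kinds, function(kd) {
      fits <- purrr::map(seq_len(config$n_traces), function(s) {
        tr <- simulate_deformation_trace(kd, obj$behavior, noise_sd = 0.02,
                                         fps = 10, seed = config$seed + s)
        fit_elongation(tr)
      })
      mean(purrr::map_dbl(fits, "tau"))
    })
    names(taus) <- kinds
    cfits <- purrr::map(seq_len(config$n_traces), function(s) {
      tr <- simulate_deformation_trace("trumpet_to_droplet", obj$behavior,
                                       noise_sd = 0.01, fps = 2000,
                                       seed = config$seed + s)
      fit_contraction(tr)
    })
    pl <- purrr::map(seq_len(10), function(s) {
      d <- simulate_speed_length_transition(obj$behavior, noise_sd = 0.02,
                                            fps = 10, seed = config$seed + s)
      tidy(fit_power_laws(median_smooth(d$length, 10, 5),
                          median_smooth(d$speed, 10, 5)))
    })
    pl <- dplyr::bind_rows(pl)
    report$kinetics <- list(
      tau_droplet_to_cone = taus[["droplet_to_cone"]],
      tau_droplet_to_trumpet = taus[["droplet_to_trumpet"]],
      tau_cone_to_trumpet = taus[["cone_to_trumpet"]],
      contraction_tau1 = mean(purrr::map_dbl(cfits, "tau1")),
      contraction_tau2 = mean(purrr::map_dbl(cfits, "tau2")),
      power_exponent_lo = mean(pl$exponent[pl$range_lo == 1]),
      power_exponent_hi = mean(pl$exponent[pl$range_lo > 1])
    )
    lap_d <- purrr::map(seq_len(10), function(s) {
      bp <- obj$behavior
      bp$noise_position_sd <- 0.05
      rec_t <- simulate_behavior(bp, obj$geometry, duration = 300, fps = 10,
                                 seed = config$seed + 100L + s,
                                 fixed_state = "trumpet")
      rec_t$x <- median_smooth(rec_t$x, 10, 1)
      rec_t$y <- median_smooth(rec_t$y, 10, 1)
      lap_diameters(extract_laps(rec_t))
    })
    lap_d <- dplyr::bind_rows(lap_d)
    report$kinetics$lap_diameter <- mean(lap_d$diameter)
    report$kinetics$n_laps <- nrow(lap_d)
  }

  if (isTRUE(stages$spatial)) {
    report$density <- occupancy_density(track)
    adh <- detect_adhesions(track)
    if (config$structured) {
      cres <- crescent_mask(obj$geometry)
      other <- region_complement(cres, obj$geometry)
      adh <- detect_adhesions(track, region = cres)
      report$spatial <- list(
        crescent_area = cres$area,
        presence_crescent = presence_frequency(track, cres, adh),
        presence_other = presence_frequency(track, other, adh)
      )
    }
    report$adhesions <- adh
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_track_csv(rec_a, file.path(config$out_dir, "ground_truth.csv"))
    write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))
    slim <- report[setdiff(names(report), c("track", "clusters", "density"))]
    slim$config <- unclass(config)
    write_report_json(slim, file.path(config$out_dir, "report.json"))
  }
  class(report) <- "pipeline_report"
  report
}

#' Compare a pipeline report against simulator ground truth
#'
#' Builds a discrepancy table of recovered quantities versus their
#' generating values, with per-quantity relative tolerances.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param params The generating [behavior_params()] (defaults to the
#'   report's own configuration).
#' @param tolerances Named relative tolerances.
#' @return Tibble with `quantity`, `estimate`, `truth`, `rel_error`,
#'   `tol`, `pass`.
#' @export
validate_against_truth <- function(report, params = NULL,
                                   tolerances = c(tau = 0.1, diameter = 0.05,
                                                  exponent = 0.15,
                                                  occupancy = 0.1)) {
  if (is.null(params)) params <- config_objects(report$config)$behavior
  rows <- list()
  add <- function(q, est, tr, tol) {
    # quantities of magnitude below 1 are judged on absolute error,
    # otherwise tiny denominators make the relative criterion meaningless
    err <- if (abs(tr) < 1) abs(est - tr) else abs(est - tr) / abs(tr)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      quantity = q, estimate = est, truth = tr,
      rel_error = err, tol = tol, pass = err <= tol)
  }
  k <- report$kinetics
  if (!is.null(k)) {
    add("tau_droplet_to_cone", k$tau_droplet_to_cone,
        params$tau_droplet_to_cone, tolerances[["tau"]])
    add("tau_droplet_to_trumpet", k$tau_droplet_to_trumpet,
        params$tau_droplet_to_trumpet, tolerances[["tau"]])
    add("tau_cone_to_trumpet", k$tau_cone_to_trumpet,
        params$tau_cone_to_trumpet, tolerances[["tau"]])
    add("contraction_tau1", k$contraction_tau1, params$contraction_tau1,
        tolerances[["tau"]])
    add("contraction_tau2", k$contraction_tau2, params$contraction_tau2,
        tolerances[["tau"]])
    add("power_exponent_lo", k$power_exponent_lo, params$power_exponent_lo,
        tolerances[["exponent"]])
    add("power_exponent_hi", k$power_exponent_hi, params$power_exponent_hi,
        tolerances[["exponent"]])
    add("lap_diameter", k$lap_diameter, params$trumpet_orbit_diameter,
        tolerances[["diameter"]])
  }
  if (length(rows) == 0) return(tibble::tibble(
    quantity = character(), estimate = numeric(), truth = numeric(),
    rel_error = numeric(), tol = numeric(), pass = logical()))
  dplyr::bind_rows(rows)
}
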