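#' Speed-length coupling during the cone-to-trumpet transition
#'
#' While a swimming cell elongates into a trumpet its speed falls steeply
#' and then levels off. The simulator couples speed to normalized length
#' (cone = 1) by a continuous piecewise power law: s = l^a_lo on
#' normalized lengths (1, 1.25] and s proportional to l^a_hi above 1.25,
#' with default exponents -6.3 and 0.2. Below length 1 the coupling
#' returns 1 (full cone speed).
#'
#' @param l_norm Normalized length (cone = 1), vectorized.
#' @param params A [behavior_params()].
#' @return Normalized speed (cone speed = 1).
#' @export
speed_length_coupling <- function(l_norm, params = behavior_params()) {
  bp <- 1.25
  a1 <- params$power_exponent_lo
  a2 <- params$power_exponent_hi
  s <- rep(1, length(l_norm))
  mid <- l_norm > 1 & l_norm <= bp
  hi <- l_norm > bp
  s[mid] <- l_norm[mid]^a1
  s[hi] <- bp^a1 * (l_norm[hi] / bp)^a2
  s
}

#' Analytic stationary state occupancy of the behavior model
#'
#' Long-run fraction of time spent in each state under the semi-Markov
#' switching process of [simulate_behavior()] in a plain chamber, computed
#' from the embedded transition chain and the mean dwell times
#' (occupancy of state i is proportional to visit rate times mean dwell).
#' The embedded chain forbids the cone-to-droplet contraction, which was
#' essentially never observed; droplets elongate into cones with
#' probability `p_droplet_to_cone`, cones switch to rotating trumpets at
#' rate `1/dwell_mean_cone` in competition with adhesion at
#' `adhesion_base_hazard`, and every trumpet contracts back to a droplet.
#'
#' Only the plain chamber is handled analytically: with an inner disk the
#' adhesion hazard depends on position and the occupancy must be
#' simulated.
#'
#' @param params A [behavior_params()].
#' @return Named numeric (droplet, cone, trumpet) summing to 1, with the
#'   four-state breakdown (rotating vs adhered trumpet) in attribute
#'   `"detail"`.
#' @export
stationary_occupancy <- function(params = behavior_params()) {
  p <- params$p_droplet_to_cone
  h_switch <- 1 / params$dwell_mean_cone
  h_adh <- params$adhesion_base_hazard
  m_cone <- 1 / (h_switch + h_adh)
  q_adh <- h_adh / (h_switch + h_adh)
  # embedded-chain visit weights per cycle through the droplet state
  v <- c(droplet = 1,
         cone = p,
         trumpet_rot = (1 - p) + p * (1 - q_adh),
         trumpet_adh = p * q_adh)
  m <- c(params$dwell_mean_droplet, m_cone,
         params$dwell_mean_trumpet, params$dwell_mean_adhered)
  w <- v * m
  detail <- w / sum(w)
  out <- c(droplet = detail[[1]], cone = detail[[2]],
           trumpet = detail[[3]] + detail[[4]])
  attr(out, "detail") <- detail
  out
}

#' Simulate a ground-truthed behavioral recording
#'
#' Generates a single-cell recording of the three-state shape-behavior
#' process in a quasi-2D chamber: a semi-Markov state sequence with
#' gamma-distributed dwell times (see `dwell_shape`); cell length relaxing exponentially toward the
#' current state's target with the transition-specific time constant (a
#' fast two-mode decay for the trumpet-to-droplet contraction); straight
#' swimming with specular wall reflection in the cone state; local
#' circular orbiting of fixed diameter in the non-adhered trumpet state;
#' and stationary droplet and adhered-trumpet states. While the cell is
#' inside a crescent dead-end area of a structured chamber, the
#' cone-to-adhered-trumpet hazard is multiplied by
#' `crescent_adhesion_multiplier`.
#'
#' @param params A [behavior_params()].
#' @param geometry A [chamber_geometry()].
#' @param duration Simulated time (s).
#' @param fps Sampling rate (frames per second).
#' @param seed Integer seed; identical inputs give identical recordings.
#' @param fixed_state Optionally freeze the process in one state
#'   (`"droplet"`, `"cone"` or `"trumpet"`, the latter rotating and never
#'   adhered) — used e.g. to harvest rotation laps.
#' @param initial_state State at time zero when not frozen; default cone.
#' @return A `stentor_recording`: a tibble with columns `frame`, `t`,
#'   `x`, `y`, `length` (observed, i.e. truth plus any observation
#'   noise), `state`, `adhered`, `true_x`, `true_y`, `true_length`, and
#'   attributes `fps`, `params`, `geometry`, `seed`, `adhesion_truth`
#'   (tibble of events: start, duration, x, y, anterior_angle,
#'   in_crescent) and `contraction_resolved` (FALSE when 1/fps is too
#'   coarse to resolve the contraction decay).
#' @export
#' @examples
#' rec <- simulate_behavior(duration = 60, fps = 5, seed = 1)
#' table(rec$state)
simulate_behavior <- function(params = behavior_params(),
                              geometry = chamber_geometry(),
                              duration, fps, seed,
                              fixed_state = NULL,
                              initial_state = "cone") {
  stopifnot(duration > 0, fps > 0)
  if (free_area(geometry) <= 0) stop("geometry has no free area")
  r_orb <- params$trumpet_orbit_diameter / 2
  if (params$trumpet_orbit_diameter >= 2 * geometry$outer_radius)
    stop("orbit diameter does not fit inside the chamber")
  set.seed(as.integer(seed))

  n <- max(2L, as.integer(round(duration * fps)))
  dt <- 1 / fps
  tvec <- (seq_len(n) - 1L) * dt
  L0c <- params$target_length[["cone"]]
  Ltarg <- c(params$target_length[["droplet"]], L0c,
             params$target_length[["trumpet"]])
  tau_el <- c(dc = params$tau_droplet_to_cone,
              dt = params$tau_droplet_to_trumpet,
              ct = params$tau_cone_to_trumpet)

  has_crescent <- !is.null(geometry$inner_disk)
  if (has_crescent) {
    tips <- crescent_tips(geometry)
    cres_r2 <- 1  # 1 mm radius around each tip
  }
  in_crescent <- function(px, py) {
    if (!has_crescent) return(FALSE)
    ((px - tips[1, 1])^2 + (py - tips[1, 2])^2 <= cres_r2) ||
      ((px - tips[2, 1])^2 + (py - tips[2, 2])^2 <= cres_r2)
  }

  # state codes 1 droplet, 2 cone, 3 trumpet
  codes <- c(droplet = 1L, cone = 2L, trumpet = 3L)
  frozen <- !is.null(fixed_state)
  state <- codes[[if (frozen) fixed_state else initial_state]]
  adhered <- FALSE
  moving_trumpet <- frozen && state == 3L

  # current length-relaxation segment (closed form between switches)
  seg_t0 <- 0
  seg_L0 <- Ltarg[state]
  seg_Lt <- Ltarg[state]
  seg_tau <- 1          # irrelevant while L0 == Lt
  seg_contraction <- FALSE

  length_at <- function(t) {
    if (seg_contraction) {
      dms <- (t - seg_t0) * 1000
      seg_Lt + (seg_L0 - seg_Lt) *
        (params$contraction_B1 * exp(-dms / params$contraction_tau1) +
           params$contraction_B2 * exp(-dms / params$contraction_tau2))
    } else {
      seg_Lt + (seg_L0 - seg_Lt) * exp(-(t - seg_t0) / seg_tau)
    }
  }

  ksh <- params$dwell_shape
  draw_dwell <- function(st) {
    m <- switch(st, params$dwell_mean_droplet, params$dwell_mean_cone,
                params$dwell_mean_trumpet)
    stats::rgamma(1, shape = ksh, scale = m / ksh)
  }
  draw_adhered <- function() {
    stats::rgamma(1, shape = ksh, scale = params$dwell_mean_adhered / ksh)
  }

  # motion state
  pos <- c(0, 0)
  if (has_crescent) pos <- feasible_orbit_center(c(0, 0), 0.1, geometry)
  heading <- stats::runif(1, 0, 2 * pi)
  orbit <- NULL   # list(center, phi, dir, r_cur)
  hstep <- params$heading_noise * sqrt(dt)

  start_orbit <- function(pos, heading) {
    side <- sample(c(-1, 1), 1)
    perp <- c(-sin(heading), cos(heading)) * side
    ctr <- feasible_orbit_center(pos + r_orb * perp, r_orb, geometry)
    dvec <- pos - ctr
    list(center = ctr, phi = atan2(dvec[2], dvec[1]), dir = side,
         r_cur = max(sqrt(sum(dvec^2)), 1e-6))
  }

  dwell_end <- if (frozen) Inf else draw_dwell(state)
  if (state == 3L && !frozen) moving_trumpet <- TRUE
  entered_from <- 2L  # pretend the initial trumpet/cone came from cone

  # adhesion bookkeeping
  ev_start <- ev_dur <- ev_x <- ev_y <- ev_ang <- numeric(0)
  ev_cres <- logical(0)

  anterior_away_from_dead_end <- function(pos, cres) {
    # point away from the nearest dead end: toward the chamber center from
    # the nearest crescent tip, or inward from the outer wall otherwise
    if (cres) {
      d1 <- sum((pos - tips[1, ])^2); d2 <- sum((pos - tips[2, ])^2)
      tip <- if (d1 < d2) tips[1, ] else tips[2, ]
      base <- atan2(-tip[2], -tip[1])
    } else {
      base <- atan2(-pos[2], -pos[1])
    }
    sdv <- 1 / sqrt(params$anterior_concentration)
    (base + stats::rnorm(1, 0, sdv)) %% (2 * pi)
  }

  X <- Y <- L <- numeric(n)
  S <- integer(n)
  A <- logical(n)

  for (i in seq_len(n)) {
    t <- tvec[i]

    # state switching (skip when frozen)
    if (!frozen && t >= dwell_end) {
      if (state == 1L) {                       # droplet elongates
        if (stats::runif(1) < params$p_droplet_to_cone) {
          seg_L0 <- length_at(dwell_end); seg_t0 <- dwell_end
          seg_Lt <- Ltarg[2L]; seg_tau <- tau_el[["dc"]]
          seg_contraction <- FALSE
          state <- 2L
          heading <- stats::runif(1, 0, 2 * pi)
          dwell_end <- dwell_end + draw_dwell(2L)
        } else {
          seg_L0 <- length_at(dwell_end); seg_t0 <- dwell_end
          seg_Lt <- Ltarg[3L]; seg_tau <- tau_el[["dt"]]
          seg_contraction <- FALSE
          state <- 3L; adhered <- FALSE
          entered_from <- 1L; moving_trumpet <- FALSE; orbit <- NULL
          dwell_end <- dwell_end + draw_dwell(3L)
        }
      } else if (state == 2L) {                # cone -> rotating trumpet
        seg_L0 <- length_at(dwell_end); seg_t0 <- dwell_end
        seg_Lt <- Ltarg[3L]; seg_tau <- tau_el[["ct"]]
        seg_contraction <- FALSE
        state <- 3L; adhered <- FALSE
        entered_from <- 2L; moving_trumpet <- TRUE
        orbit <- start_orbit(pos, heading)
        dwell_end <- dwell_end + draw_dwell(3L)
      } else {                                 # trumpet contracts
        if (adhered) ev_dur[length(ev_dur)] <- dwell_end - ev_start[length(ev_start)]
        seg_L0 <- length_at(dwell_end); seg_t0 <- dwell_end
        seg_Lt <- Ltarg[1L]; seg_contraction <- TRUE
        state <- 1L; adhered <- FALSE
        moving_trumpet <- FALSE; orbit <- NULL
        dwell_end <- dwell_end + draw_dwell(1L)
      }
    }

    # motion update
    if (state == 2L) {
      if (!frozen && params$adhesion_base_hazard > 0) {
        lam <- params$adhesion_base_hazard
        cres_now <- in_crescent(pos[1], pos[2])
        if (cres_now) lam <- lam * params$crescent_adhesion_multiplier
        if (stats::runif(1) < 1 - exp(-lam * dt)) {
          # cone adheres as a trumpet right here
          seg_L0 <- length_at(t); seg_t0 <- t
          seg_Lt <- Ltarg[3L]; seg_tau <- tau_el[["ct"]]
          seg_contraction <- FALSE
          state <- 3L; adhered <- TRUE
          moving_trumpet <- FALSE; orbit <- NULL
          dwell_end <- t + draw_adhered()
          ev_start <- c(ev_start, t)
          ev_dur <- c(ev_dur, dwell_end - t)   # provisional, truncated below
          ev_x <- c(ev_x, pos[1]); ev_y <- c(ev_y, pos[2])
          ev_cres <- c(ev_cres, cres_now)
          ev_ang <- c(ev_ang,
                      anterior_away_from_dead_end(pos, cres_now) * 180 / pi)
        }
      }
      if (state == 2L) {
        heading <- heading + stats::rnorm(1, 0, hstep)
        upd <- reflect_into(pos, heading, params$cone_speed * dt, geometry)
        pos <- upd$pos; heading <- upd$heading
      }
    } else if (state == 3L && !adhered) {
      lnorm <- length_at(t) / L0c
      if (!moving_trumpet && lnorm >= 1.2) {
        moving_trumpet <- TRUE
        orbit <- start_orbit(pos, stats::runif(1, 0, 2 * pi))
      }
      if (moving_trumpet) {
        if (is.null(orbit)) orbit <- start_orbit(pos, heading)
        sp <- params$cone_speed * speed_length_coupling(lnorm, params)
        orbit$phi <- orbit$phi + orbit$dir * sp * dt / r_orb
        orbit$r_cur <- orbit$r_cur + (r_orb - orbit$r_cur) * (1 - exp(-dt / 2))
        pos <- orbit$center +
          orbit$r_cur * c(cos(orbit$phi), sin(orbit$phi))
        # the spiral onto the orbit may graze a wall while converging
        pos2 <- clamp_into(pos, geometry)
        if (!identical(pos2, pos)) {
          pos <- pos2
          dvec <- pos - orbit$center
          orbit$phi <- atan2(dvec[2], dvec[1])
          orbit$r_cur <- sqrt(sum(dvec^2))
        }
      }
    }
    # droplet / adhered trumpet: stationary

    X[i] <- pos[1]; Y[i] <- pos[2]; L[i] <- length_at(t)
    S[i] <- state; A[i] <- adhered
  }

  # truncate an adhesion running past the end of the recording
  if (length(ev_start) && ev_start[length(ev_start)] + ev_dur[length(ev_dur)] > duration) {
    k <- length(ev_dur)
    if (S[n] == 3L && A[n]) ev_dur[k] <- min(ev_dur[k], duration - ev_start[k])
  }

  # observation noise on a separate derived stream so the state/motion
  # sequence is unchanged by noise settings
  set.seed(as.integer(seed) %% 1000003L + 7L)
  xo <- X; yo <- Y; lo <- L
  if (params$noise_position_sd > 0) {
    xo <- X + stats::rnorm(n, 0, params$noise_position_sd)
    yo <- Y + stats::rnorm(n, 0, params$noise_position_sd)
  }
  if (params$noise_length_sd > 0)
    lo <- pmax(L + stats::rnorm(n, 0, params$noise_length_sd), 0)

  out <- tibble::tibble(
    frame = seq_len(n), t = tvec,
    x = xo, y = yo, length = lo,
    state = c("droplet", "cone", "trumpet")[S],
    adhered = A,
    true_x = X, true_y = Y, true_length = L
  )
  attr(out, "fps") <- fps
  attr(out, "params") <- params
  attr(out, "geometry") <- geometry
  attr(out, "seed") <- as.integer(seed)
  attr(out, "adhesion_truth") <- tibble::tibble(
    start = ev_start, duration = ev_dur, x = ev_x, y = ev_y,
    anterior_angle = ev_ang, in_crescent = ev_cres
  )
  attr(out, "contraction_resolved") <- (1 / fps) <= 5 * params$contraction_tau2 / 1000
  class(out) <- c("stentor_recording", class(out))
  out
}

#' Downsample a recording to a lower frame rate
#'
#' Keeps every `stride`-th frame and updates the `fps` attribute; used to
#' render and analyze long simulations at a coarser rate than the one
#' the dynamics were integrated at.
#'
#' @param recording A `stentor_recording`.
#' @param stride Integer subsampling stride.
#' @return A `stentor_recording` at `fps / stride`.
#' @export
thin_recording <- function(recording, stride) {
  stopifnot(stride >= 1, stride == round(stride))
  at <- attributes(recording)
  out <- recording[seq(1, nrow(recording), by = stride), ]
  out$frame <- seq_len(nrow(out))
  for (a in c("params", "geometry", "seed", "adhesion_truth",
              "contraction_resolved"))
    attr(out, a) <- at[[a]]
  attr(out, "fps") <- at$fps / stride
  class(out) <- unique(c("stentor_recording", class(out)))
  out
}
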