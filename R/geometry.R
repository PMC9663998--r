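#' Quasi-2D chamber geometry
#'
#' A disk chamber (default diameter 5 mm, depth 0.3 mm), optionally with
#' an inner disk structure (default diameter 2.5 mm) offset toward the
#' outer wall so that the free area forms a crescent with two dead-end
#' tips near the point of closest approach.
#'
#' The chamber is centered at the origin. With `inner_disk = TRUE` the
#' inner disk center is placed on the positive x axis at
#' `outer_radius - inner_radius - gap`, leaving a channel of width `gap`
#' at the closest approach. The two crescent tips are the points on the
#' channel mid-curve where the channel narrows to `passage_width`
#' (roughly one cell width), i.e. where the dead ends become impassable;
#' see [crescent_tips()].
#'
#' @param outer_radius Chamber radius (mm).
#' @param inner_disk `TRUE` for the structured chamber, `FALSE` for the
#'   plain one, or a list with elements `center` (length-2 numeric, mm)
#'   and `radius` (mm) for full control.
#' @param inner_radius,gap Inner disk radius and wall gap (mm) used when
#'   `inner_disk = TRUE`.
#' @param depth Chamber depth (mm); metadata only.
#' @return A `chamber_geometry` list with elements `outer_radius`,
#'   `inner_disk` (`NULL` or `list(center, radius)`) and `depth`.
#' @export
#' @examples
#' plain <- chamber_geometry()
#' structured <- chamber_geometry(inner_disk = TRUE)
chamber_geometry <- function(outer_radius = 2.5,
                             inner_disk = FALSE,
                             inner_radius = 1.25,
                             gap = 0.1,
                             depth = 0.3) {
  stopifnot(outer_radius > 0, depth > 0)
  inner <- NULL
  if (isTRUE(inner_disk)) {
    inner <- list(center = c(outer_radius - inner_radius - gap, 0),
                  radius = inner_radius)
  } else if (is.list(inner_disk)) {
    inner <- list(center = as.numeric(inner_disk$center),
                  radius = as.numeric(inner_disk$radius))
  }
  if (!is.null(inner)) {
    stopifnot(length(inner$center) == 2, inner$radius > 0)
    if (sqrt(sum(inner$center^2)) + inner$radius >= outer_radius)
      stop("inner disk must lie strictly inside the outer disk")
  }
  structure(list(outer_radius = outer_radius, inner_disk = inner,
                 depth = depth),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("<chamber_geometry> outer radius %.3g mm, depth %.3g mm\n",
              x$outer_radius, x$depth))
  if (!is.null(x$inner_disk))
    cat(sprintf("  inner disk: radius %.3g mm at (%.3g, %.3g)\n",
                x$inner_disk$radius, x$inner_disk$center[1],
                x$inner_disk$center[2]))
  invisible(x)
}

#' Test whether points lie in the free (swimmable) area
#'
#' @param x,y Point coordinates (mm), vectorized.
#' @param geometry A [chamber_geometry()].
#' @param margin Shrink the free area by this distance (mm) from both
#'   walls (useful to keep a finite-size cell inside).
#' @return Logical vector.
#' @export
in_free_area <- function(x, y, geometry, margin = 0) {
  r2 <- x^2 + y^2
  ok <- r2 <= (geometry$outer_radius - margin)^2
  if (!is.null(geometry$inner_disk)) {
    cc <- geometry$inner_disk$center
    d2 <- (x - cc[1])^2 + (y - cc[2])^2
    ok <- ok & d2 >= (geometry$inner_disk$radius + margin)^2
  }
  ok
}

#' Free area of a chamber
#'
#' Area (mm^2) of the swimmable region; exact for the disk/annulus
#' construction used here.
#'
#' @inheritParams in_free_area
#' @return Area in mm^2.
#' @export
free_area <- function(geometry) {
  a <- pi * geometry$outer_radius^2
  if (!is.null(geometry$inner_disk)) a <- a - pi * geometry$inner_disk$radius^2
  a
}

#' Crescent dead-end tips of a structured chamber
#'
#' The inner disk approaches the outer wall, leaving a channel that
#' narrows toward the point of closest approach. A swimming cell can
#' follow the channel only until its width falls below roughly one cell
#' width; the two points on the channel mid-curve where the width equals
#' `passage_width` are taken as the tips of the two crescent dead ends.
#' This closest-approach construction is one reading of the chamber's
#' "tip of the crescent".
#'
#' @param geometry A structured [chamber_geometry()] (must have an inner
#'   disk).
#' @param passage_width Channel width (mm) at which the dead end is
#'   considered closed; default 0.2 mm, about one cell width.
#' @return A 2 x 2 matrix, one tip per row (mm).
#' @export
crescent_tips <- function(geometry, passage_width = 0.2) {
  if (is.null(geometry$inner_disk))
    stop("crescent tips are only defined for a chamber with an inner disk")
  R <- geometry$outer_radius
  cc <- geometry$inner_disk$center
  r <- geometry$inner_disk$radius
  d <- sqrt(sum(cc^2))
  phi0 <- atan2(cc[2], cc[1])
  gap <- R - d - r
  if (passage_width <= gap)
    stop("passage_width must exceed the closest-approach gap")
  # distance from origin to inner-disk surface along direction phi (relative
  # to the inner-center azimuth); channel width is R minus that distance
  width_at <- function(a) {
    t <- d * cos(a) + sqrt(pmax(r^2 - d^2 * sin(a)^2, 0))
    R - t
  }
  f <- function(a) width_at(a) - passage_width
  upper <- asin(min(1, r / d))
  a_tip <- stats::uniroot(f, c(1e-9, upper * 0.999), tol = 1e-10)$root
  mid_r <- R - width_at(a_tip) / 2
  ang <- phi0 + c(a_tip, -a_tip)
  cbind(x = mid_r * cos(ang), y = mid_r * sin(ang))
}

#' Crescent areas of a structured chamber
#'
#' The crescent areas are the parts of the free area within `radius` of
#' either crescent tip. Returns a region object usable as a point
#' predicate and carrying its own area (computed by fine-grid
#' integration).
#'
#' @inheritParams crescent_tips
#' @param radius Distance from the tips defining the crescent areas (mm);
#'   default 1 mm.
#' @param grid_step Integration step (mm) for the area computation.
#' @return A `chamber_region`: list with `contains(x, y)`, `area` (mm^2)
#'   and `tips`.
#' @export
crescent_mask <- function(geometry, radius = 1, passage_width = 0.2,
                          grid_step = 0.005) {
  tips <- crescent_tips(geometry, passage_width)
  contains <- function(x, y) {
    near <- rep(FALSE, length(x))
    for (k in seq_len(nrow(tips)))
      near <- near | ((x - tips[k, 1])^2 + (y - tips[k, 2])^2 <= radius^2)
    near & in_free_area(x, y, geometry)
  }
  gx <- seq(-geometry$outer_radius, geometry$outer_radius, by = grid_step)
  gr <- expand.grid(x = gx, y = gx)
  area <- sum(contains(gr$x, gr$y)) * grid_step^2
  structure(list(contains = contains, area = area, tips = tips,
                 radius = radius),
            class = "chamber_region")
}

#' Complement of a region within the free area
#'
#' @param region A `chamber_region` (e.g. from [crescent_mask()]).
#' @param geometry The enclosing [chamber_geometry()].
#' @return A `chamber_region` covering the free area outside `region`.
#' @export
region_complement <- function(region, geometry) {
  contains <- function(x, y) in_free_area(x, y, geometry) & !region$contains(x, y)
  structure(list(contains = contains,
                 area = free_area(geometry) - region$area,
                 tips = region$tips),
            class = "chamber_region")
}

# Specular reflection helpers ------------------------------------------------

# Reflect a proposed step end point off the outer wall / inner disk until it
# lies in the free area. Used by the cone swimming update; a handful of
# iterations suffices for sub-chamber step sizes.
reflect_into <- function(pos, heading, step, geometry, margin = 0.02) {
  for (iter in 1:8) {
    prop <- pos + step * c(cos(heading), sin(heading))
    r <- sqrt(sum(prop^2))
    if (r > geometry$outer_radius - margin) {
      # reflect heading about the tangent at the wall-normal direction
      n <- prop / r
      v <- c(cos(heading), sin(heading))
      v <- v - 2 * sum(v * n) * n
      heading <- atan2(v[2], v[1])
      next
    }
    if (!is.null(geometry$inner_disk)) {
      cc <- geometry$inner_disk$center
      dvec <- prop - cc
      dd <- sqrt(sum(dvec^2))
      if (dd < geometry$inner_disk$radius + margin) {
        n <- dvec / dd
        v <- c(cos(heading), sin(heading))
        v <- v - 2 * sum(v * n) * n
        heading <- atan2(v[2], v[1])
        next
      }
    }
    return(list(pos = prop, heading = heading))
  }
  # pathological corner: stay put, randomize handled by caller via noise
  list(pos = pos, heading = heading + pi)
}

# Project a point back into the free area (radial clamp at the outer wall,
# push-out at the inner disk); used to keep the trumpet spiral confined.
clamp_into <- function(pos, geometry, margin = 0.02) {
  r <- sqrt(sum(pos^2))
  rmax <- geometry$outer_radius - margin
  if (r > rmax) pos <- pos * rmax / r
  if (!is.null(geometry$inner_disk)) {
    cc <- geometry$inner_disk$center
    dvec <- pos - cc
    dd <- sqrt(sum(dvec^2))
    rmin <- geometry$inner_disk$radius + margin
    if (dd < rmin) {
      if (dd < 1e-12) dvec <- c(0, 1) else dvec <- dvec / dd
      pos <- cc + dvec * rmin
      r <- sqrt(sum(pos^2))
      if (r > rmax) pos <- pos * rmax / r
    }
  }
  pos
}

# Nearest point to `target` from which a circle of radius r_orb fits inside
# the free area (used to place trumpet orbits).
feasible_orbit_center <- function(target, r_orb, geometry, margin = 0.02) {
  ctr <- target
  rmax <- geometry$outer_radius - r_orb - margin
  if (rmax <= 0) stop("orbit diameter does not fit inside the chamber")
  r <- sqrt(sum(ctr^2))
  if (r > rmax) ctr <- ctr * rmax / r
  if (!is.null(geometry$inner_disk)) {
    cc <- geometry$inner_disk$center
    rmin <- geometry$inner_disk$radius + r_orb + margin
    dvec <- ctr - cc
    dd <- sqrt(sum(dvec^2))
    if (dd < rmin) {
      if (dd < 1e-12) dvec <- c(0, 1) else dvec <- dvec / dd
      ctr <- cc + dvec * rmin
      # keep inside outer constraint too: project back and forth once more
      r <- sqrt(sum(ctr^2))
      if (r > rmax) ctr <- ctr * rmax / r
    }
  }
  ctr
}
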