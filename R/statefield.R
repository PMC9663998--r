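#' Classify behavioral states on the normalized state field
#'
#' Rule-based classification following the classical descriptive states:
#' a cell swimming at or above the speed cut is a cone; a slow cell is a
#' droplet when short, a trumpet when long, and "transition" in the
#' intermediate length band. Frames with missing normalized values are
#' labeled "invalid".
#'
#' @param track Tibble with `l_norm` and `s_norm` columns (see
#'   [normalize_track()]).
#' @param thresholds A [classification_thresholds()].
#' @return The track with a `label` column in
#'   `c("droplet", "cone", "trumpet", "transition", "invalid")`.
#' @export
classify_states <- function(track, thresholds = classification_thresholds()) {
  l <- track$l_norm; s <- track$s_norm
  lab <- dplyr::case_when(
    is.na(l) | is.na(s) ~ "invalid",
    s >= thresholds$speed_cut ~ "cone",
    l <= thresholds$length_cut_low ~ "droplet",
    l >= thresholds$length_cut_high ~ "trumpet",
    TRUE ~ "transition"
  )
  track$label <- lab
  track
}

#' State frequencies
#'
#' Fractions of frames per state over the counted frames (invalid and
#' transition frames are excluded); the fractions sum to 1.
#'
#' @param labels Character vector of labels, or a tibble with a `label`
#'   column.
#' @return Tibble with `state`, `n`, `fraction` for droplet, cone and
#'   trumpet.
#' @export
state_frequencies <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  keep <- labels %in% c("droplet", "cone", "trumpet")
  n <- c(droplet = sum(labels == "droplet"),
         cone = sum(labels == "cone"),
         trumpet = sum(labels == "trumpet"))
  tot <- sum(keep)
  tibble::tibble(state = names(n), n = as.integer(n),
                 fraction = if (tot > 0) as.numeric(n) / tot else NA_real_)
}

#' Transition vectors on the state field
#'
#' Central-difference displacement of the state point S_i = (l_norm,
#' s_norm), v_i = S_{i+1} - S_{i-1}, followed by an averaging window of
#' +/- `half_window` s. The vectors describe the direction and rate of
#' behavioral change at each point of the state field.
#'
#' @param track Tibble with `l_norm`, `s_norm` and attribute `fps` (or
#'   pass `fps`).
#' @param fps Frame rate.
#' @param half_window Averaging half window (s).
#' @return The track with `dl` and `ds` vector components added.
#' @export
transition_vectors <- function(track, fps = attr(track, "fps"),
                               half_window = 5) {
  stopifnot(!is.null(fps), nrow(track) >= 3)
  l <- track$l_norm; s <- track$s_norm
  n <- length(l)
  dl <- c(NA, l[3:n] - l[1:(n - 2)], NA)
  ds <- c(NA, s[3:n] - s[1:(n - 2)], NA)
  k <- floor(half_window * fps)
  if (k > 0) {
    roll_mean <- function(v) {
      vapply(seq_len(n), function(i) {
        w <- v[max(1, i - k):min(n, i + k)]
        if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
      }, numeric(1))
    }
    dl <- roll_mean(dl); ds <- roll_mean(ds)
  }
  track$dl <- dl
  track$ds <- ds
  track
}

#' Gridded median transition-vector field
#'
#' Divides the state field into square cells of side `cell` (normalized
#' units), assigns each state point to its cell, and summarizes the
#' member vectors by their componentwise median. Cells holding less than
#' `min_occupancy` of all points are emptied: their medians are too
#' poorly sampled to be meaningful.
#'
#' Note the intrinsic caveat of this summary: two transitions traversing
#' the same path in opposite directions cancel toward a zero median.
#'
#' @param track Tibble with `l_norm`, `s_norm`, `dl`, `ds`.
#' @param cell Grid interval in normalized units (default 0.1).
#' @param min_occupancy Minimum fraction of all points per kept cell
#'   (default 0.05% = 5e-4).
#' @return Tibble with cell centers `l_mid`, `s_mid`, counts `n`,
#'   `occupancy`, and median components `dl_med`, `ds_med`.
#' @export
grid_vector_field <- function(track, cell = 0.1, min_occupancy = 5e-4) {
  df <- tibble::tibble(l = track$l_norm, s = track$s_norm,
                       dl = track$dl, ds = track$ds)
  df <- df[stats::complete.cases(df), ]
  ntot <- nrow(df)
  if (ntot == 0)
    return(tibble::tibble(l_mid = numeric(), s_mid = numeric(),
                          n = integer(), occupancy = numeric(),
                          dl_med = numeric(), ds_med = numeric()))
  df |>
    dplyr::mutate(li = floor(.data$l / cell), si = floor(.data$s / cell)) |>
    dplyr::group_by(.data$li, .data$si) |>
    dplyr::summarise(n = dplyr::n(),
                     dl_med = stats::median(.data$dl),
                     ds_med = stats::median(.data$ds), .groups = "drop") |>
    dplyr::mutate(occupancy = .data$n / ntot,
                  l_mid = (.data$li + 0.5) * cell,
                  s_mid = (.data$si + 0.5) * cell) |>
    dplyr::filter(.data$occupancy >= min_occupancy) |>
    dplyr::select("l_mid", "s_mid", "n", "occupancy", "dl_med", "ds_med")
}

#' Mask out transition periods around state changes
#'
#' Frames within a state-specific margin of any label change are masked
#' so that only steady residence in a state remains: the margin of each
#' state applies on that state's own side of the boundary (+/- 15 s for
#' droplet, 60 s for cone, 30 s for trumpet by default). Margins are
#' truncated at the series ends, and frames labeled transition or
#' invalid are never steady.
#'
#' @param labels Character label vector (or tibble with `label`).
#' @param fps Frame rate.
#' @param margins Named margins in seconds for droplet, cone, trumpet.
#' @return Logical steady-frame mask.
#' @export
exclude_transition_periods <- function(labels, fps,
                                       margins = c(droplet = 15, cone = 60,
                                                   trumpet = 30)) {
  if (is.data.frame(labels)) labels <- labels$label
  n <- length(labels)
  steady <- labels %in% c("droplet", "cone", "trumpet")
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$values)) {
    st <- r$values[j]
    if (!st %in% names(margins)) next
    m <- floor(margins[[st]] * fps)
    if (m < 1) next
    if (starts[j] > 1)          # a change precedes this run
      steady[starts[j]:min(ends[j], starts[j] + m - 1)] <- FALSE
    if (ends[j] < n)            # a change follows this run
      steady[max(starts[j], ends[j] - m + 1):ends[j]] <- FALSE
  }
  steady
}

#' Agglomerative clustering of steady state points
#'
#' Hierarchical (complete-linkage, Euclidean) clustering of the steady
#' state-field points into `k` clusters, after 10-increment
#' downsampling. For `k = 3` the clusters are matched to states by their
#' centroid geometry: the cluster with the highest mean normalized speed
#' is the cone; of the remaining slow clusters the shorter is the
#' droplet and the longer the trumpet.
#'
#' @param track Tibble of steady points with `l_norm`, `s_norm` (filter
#'   with [exclude_transition_periods()] first).
#' @param k Number of clusters.
#' @param downsample Keep every `downsample`-th point.
#' @param phase Offset of the downsampling grid (1 to `downsample`).
#' @return Tibble of the downsampled points with `cluster` and (for
#'   `k = 3`) a `cluster_state` column.
#' @export
cluster_states <- function(track, k = 3, downsample = 10, phase = 1) {
  df <- tibble::tibble(l_norm = track$l_norm, s_norm = track$s_norm)
  df <- df[seq(phase, nrow(df), by = downsample), ]
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < k) stop("fewer points than clusters after downsampling")
  hc <- stats::hclust(stats::dist(cbind(df$l_norm, df$s_norm)),
                      method = "complete")
  df$cluster <- stats::cutree(hc, k = k)
  if (k == 3) {
    cen <- df |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(l = mean(.data$l_norm), s = mean(.data$s_norm),
                       .groups = "drop")
    cone_cl <- cen$cluster[which.max(cen$s)]
    rest <- cen[cen$cluster != cone_cl, ]
    droplet_cl <- rest$cluster[which.min(rest$l)]
    trumpet_cl <- rest$cluster[which.max(rest$l)]
    map <- stats::setNames(c("cone", "droplet", "trumpet"),
                           c(cone_cl, droplet_cl, trumpet_cl))
    df$cluster_state <- unname(map[as.character(df$cluster)])
  }
  df
}
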