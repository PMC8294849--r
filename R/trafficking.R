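#' Per-frame displacements of a track
#'
#' @param track data.frame for a single track with columns `t_s`, `x_um`,
#'   `y_um` and strictly increasing time stamps.
#' @return data.frame with one row per frame interval: `interval_s` (time
#'   step) and `step_um` (Euclidean distance between consecutive points).
#' @export
frame_displacements <- function(track) {
  validate_track(track)
  n <- nrow(track)
  data.frame(
    interval_s = diff(track$t_s),
    step_um = sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  )
}

validate_track <- function(track) {
  need <- c("t_s", "x_um", "y_um")
  if (!all(need %in% names(track))) {
    mito_stop("track must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(track) < 2) mito_stop("track needs at least 2 points")
  dt <- diff(track$t_s)
  if (any(dt <= 0)) mito_stop("track time stamps must be strictly increasing")
  if (diff(range(dt)) > 1e-6) {
    mito_stop("track frame interval must be uniform (tolerance 1e-6 s)")
  }
  invisible(track)
}

#' Total path length of a track
#'
#' Cumulative distance traveled: the sum of Euclidean frame-to-frame steps
#' over the whole track (not the net start-to-end displacement, which would
#' miss direction reversals).
#'
#' @inheritParams frame_displacements
#' @return path length in um.
#' @export
track_path_length <- function(track) {
  sum(frame_displacements(track)$step_um)
}

#' Classify a track as mobile or stationary
#'
#' A mitochondrion is considered mobile if the distance covered exceeds
#' `threshold` um within some contiguous time window of `window` seconds
#' (default 2 um in 5 min). The rule is evaluated over every possible
#' window start frame. Tracks shorter than the window use a pro-rated
#' threshold `threshold * duration / window` when `prorate = TRUE`;
#' otherwise short tracks are an error.
#'
#' @inheritParams frame_displacements
#' @param threshold path-length threshold, um.
#' @param window window length, s.
#' @param prorate scale the threshold for tracks shorter than `window`.
#' @return logical: is the track mobile?
#' @export
classify_mobility <- function(track, threshold = 2, window = 300,
                              prorate = TRUE) {
  disp <- frame_displacements(track)
  dt <- disp$interval_s[1]
  duration <- sum(disp$interval_s)
  w_steps <- as.integer(round(window / dt))
  if (nrow(disp) < w_steps) {
    if (!prorate) {
      mito_stop("track duration ", duration, " s is shorter than the ",
                window, " s mobility window and prorating is disabled")
    }
    threshold <- threshold * duration / window
    w_steps <- nrow(disp)
  }
  cs <- c(0, cumsum(disp$step_um))
  win <- cs[(w_steps + 1):length(cs)] - cs[1:(length(cs) - w_steps)]
  max(win) > threshold
}

#' Pause-excluding track velocity
#'
#' Velocity is path length divided by time, omitting intervals in which the
#' mitochondrion was immobile for longer than `pause_exclusion` seconds. A
#' pause is a maximal run of consecutive frames whose step is below
#' `immobility_step` and whose total duration exceeds `pause_exclusion`
#' (strictly; a stationary block of exactly 10 s is kept). Both the paused
#' path (jitter) and the paused time are excluded.
#'
#' @inheritParams frame_displacements
#' @param pause_exclusion minimum pause duration to exclude, s (default
#'   10 s).
#' @param immobility_step per-frame step below which a frame counts as
#'   immobile, um (default 0.1 um, below typical localization jitter).
#' @return velocity in um/s, with attribute `excluded_time_s`. `NA` (with
#'   the same attribute) if all time is excluded, which is distinct from a
#'   zero velocity.
#' @export
track_velocity <- function(track, pause_exclusion = 10,
                           immobility_step = 0.1) {
  disp <- frame_displacements(track)
  mask <- pause_mask(disp, pause_exclusion, immobility_step)
  excluded <- sum(disp$interval_s[mask])
  denom <- sum(disp$interval_s) - excluded
  v <- if (denom <= 0) NA_real_ else sum(disp$step_um[!mask]) / denom
  structure(v, excluded_time_s = excluded)
}

# logical mask over frame intervals: TRUE where the interval belongs to an
# excluded pause
pause_mask <- function(disp, pause_exclusion, immobility_step) {
  # strict "step < threshold" with a relative epsilon so steps equal to the
  # threshold are not misclassified by coordinate round-trip noise
  immobile <- disp$step_um < immobility_step * (1 - 1e-9)
  r <- rle(immobile)
  run_dur <- r$lengths * disp$interval_s[1]
  excl <- r$values & run_dur > pause_exclusion
  rep(excl, r$lengths)
}

#' Per-track trafficking statistics
#'
#' Convenience wrapper computing path length, pause-excluding velocity,
#' mobility and excluded time for each track of a long-format table.
#'
#' @param tracks long-format track table (`track_id`, `t_s`, `x_um`,
#'   `y_um`).
#' @inheritParams classify_mobility
#' @inheritParams track_velocity
#' @return data.frame with one row per track: `track_id`,
#'   `path_length_um`, `velocity_um_s`, `is_mobile`, `excluded_time_s`.
#' @export
track_stats <- function(tracks, threshold = 2, window = 300,
                        pause_exclusion = 10, immobility_step = 0.1,
                        prorate = TRUE) {
  res <- lapply(split_tracks(tracks), function(tr) {
    v <- track_velocity(tr, pause_exclusion, immobility_step)
    data.frame(
      track_id = tr$track_id[1],
      path_length_um = track_path_length(tr),
      velocity_um_s = as.numeric(v),
      is_mobile = classify_mobility(tr, threshold, window, prorate),
      excluded_time_s = attr(v, "excluded_time_s")
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Percentage of moving mitochondria in a movie
#'
#' @param stats per-track statistics from [track_stats()], or any
#'   data.frame with a logical `is_mobile` column (only tracked candidates
#'   appear here).
#' @param n_total_mito total number of mitochondria in the movie (tracked
#'   or not); must be at least the number of tracks.
#' @return mobile percentage, `100 * mobile / n_total_mito`.
#' @export
movie_mobile_fraction <- function(stats, n_total_mito = nrow(stats)) {
  if (n_total_mito <= 0) mito_stop("n_total_mito must be positive")
  if (n_total_mito < nrow(stats)) {
    mito_stop("n_total_mito is smaller than the number of tracked mitochondria")
  }
  100 * sum(stats$is_mobile) / n_total_mito
}
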