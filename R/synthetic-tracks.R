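#' Generate synthetic mitochondrial particle tracks with ground truth
#'
#' Emulates manually tracked time-lapse mitochondria in neuronal processes:
#' a movie imaged at one frame per `frame_dt` seconds for `duration`
#' seconds. A chosen fraction of tracks is mobile; mobile tracks move at a
#' constant ground-truth speed along a smoothly turning heading,
#' interrupted by optional stationary pauses. Immobile tracks only jitter,
#' with per-frame steps below 0.03 um so their path length stays strictly
#' under the 2 um / 300 s mobility threshold in every window.
#'
#' The number of mobile tracks is `round_half_away(n * mobile_fraction)`.
#' Generated tracks satisfy the mobility rule by construction: every mobile
#' track covers more than `mobility_threshold` um of path in at least one
#' contiguous `mobility_window`-second window, every immobile track stays
#' below it in all windows. If the requested speed and pauses make this
#' impossible the generator raises a parameter error instead of emitting an
#' unclassifiable track.
#'
#' @param n number of tracks (>= 1).
#' @param duration movie duration in seconds; must be a multiple of
#'   `frame_dt`.
#' @param frame_dt frame interval in seconds (default 5 s).
#' @param speed ground-truth speed of mobile tracks while moving, um/s.
#' @param mobile_fraction fraction of tracks that are mobile, in \[0, 1\].
#' @param pause_spec pause model for mobile tracks: a list with `n_range`
#'   (inclusive integer range for the number of pauses per track) and
#'   `len_range` (pause length range in seconds; realized pauses are whole
#'   frames). Use `list(n_range = c(0, 0))` for pause-free tracks.
#' @param mobility_threshold,mobility_window the mobility rule the tracks
#'   are constructed against (2 um in 300 s).
#' @param immobile_jitter maximum per-frame jitter step for immobile tracks
#'   and paused frames, um.
#' @param seed integer seed; generation is a pure function of the
#'   parameters and seed.
#' @return list with `tracks`, a data.frame of points
#'   (`track_id`, `frame`, `t_s`, `x_um`, `y_um`), and `truth`, one row per
#'   track (`track_id`, `is_mobile`, `true_speed_um_s`, `n_pauses`,
#'   `pause_time_s`) with pause intervals in the list column `pauses`
#'   (two-column matrices of start/end seconds).
#' @examples
#' g <- gen_tracks(10, mobile_fraction = 0.3, seed = 1)
#' table(g$truth$is_mobile)
#' @export
gen_tracks <- function(n,
                       duration = 500,
                       frame_dt = 5,
                       speed = 0.17,
                       mobile_fraction = 0.25,
                       pause_spec = list(n_range = c(0, 2), len_range = c(15, 60)),
                       mobility_threshold = 2,
                       mobility_window = 300,
                       immobile_jitter = 0.03,
                       seed = 1) {
  if (n < 1) mito_stop("n must be >= 1")
  if (frame_dt <= 0) mito_stop("frame_dt must be positive")
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    mito_stop("mobile_fraction must be in [0, 1]")
  }
  n_steps <- duration / frame_dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    mito_stop("duration must be a multiple of frame_dt")
  }
  n_steps <- as.integer(round(n_steps))
  n_mobile <- round_half_away(n * mobile_fraction)
  w_steps <- min(n_steps, as.integer(round(mobility_window / frame_dt)))
  eff_window <- w_steps * frame_dt

  n_pause_max <- max(pause_spec$n_range %||% 0L)
  max_pause_s <- if (n_pause_max > 0) {
    n_pause_max * frame_dt * ceiling(max(pause_spec$len_range) / frame_dt)
  } else 0
  # Feasibility: even if every pause fell inside the best window, a mobile
  # track must still exceed the threshold.
  if (n_mobile > 0 &&
      speed * max(eff_window - max_pause_s, 0) <= mobility_threshold) {
    mito_stop(
      "mobile tracks are infeasible: speed ", speed, " um/s over ",
      eff_window, " s (minus up to ", max_pause_s,
      " s of pauses) cannot exceed ", mobility_threshold, " um"
    )
  }
  if (immobile_jitter * w_steps >= mobility_threshold) {
    mito_stop("immobile_jitter too large: jittering tracks could cross the mobility threshold")
  }

  with_seed(seed, {
    tracks <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      mobile <- i <= n_mobile
      if (mobile) {
        n_pauses <- if (n_pause_max > 0) {
          sample(seq(pause_spec$n_range[1], pause_spec$n_range[2]), 1)
        } else 0L
        pause_frames <- integer(0)
        pauses <- matrix(numeric(0), ncol = 2)
        if (n_pauses > 0) {
          lens <- pmax(1L, round(runif(n_pauses,
                                       pause_spec$len_range[1],
                                       pause_spec$len_range[2]) / frame_dt))
          # place pauses without overlap by partitioning the step range
          starts <- sort(sample(n_steps - sum(lens), n_pauses))
          offs <- c(0, cumsum(lens))[seq_len(n_pauses)]
          starts <- starts + offs
          pause_frames <- unlist(mapply(function(s, l) seq(s, s + l - 1L),
                                        starts, lens, SIMPLIFY = FALSE))
          pauses <- cbind((starts - 1L) * frame_dt, (starts - 1L + lens) * frame_dt)
        }
        step_len <- rep(speed * frame_dt, n_steps)
        step_len[pause_frames] <- 0
        heading <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n_steps - 1, 0, 0.3)))
      } else {
        step_len <- runif(n_steps, 0, immobile_jitter)
        heading <- runif(n_steps, 0, 2 * pi)
        pauses <- matrix(numeric(0), ncol = 2)
      }
      x <- cumsum(c(runif(1, 0, 50), step_len * cos(heading)))
      y <- cumsum(c(runif(1, 0, 50), step_len * sin(heading)))
      # construction guarantee (windowed path length vs threshold)
      win_path <- max(stats::filter(step_len, rep(1, w_steps), sides = 1),
                      na.rm = TRUE)
      if (mobile && win_path <= mobility_threshold) {
        mito_stop("constructed mobile track fails the mobility rule; reduce pauses or raise speed")
      }
      tracks[[i]] <- data.frame(
        track_id = i, frame = seq_len(n_steps + 1L) - 1L,
        t_s = (seq_len(n_steps + 1L) - 1L) * frame_dt, x_um = x, y_um = y
      )
      truth[[i]] <- data.frame(
        track_id = i, is_mobile = mobile,
        true_speed_um_s = if (mobile) speed else 0,
        n_pauses = nrow(pauses), pause_time_s = sum(pauses[, 2] - pauses[, 1])
      )
      truth[[i]]$pauses <- list(pauses)
    }
    list(tracks = do.call(rbind, tracks), truth = do.call(rbind, truth))
  })
}

#' Split a long-format track table into single-track data.frames
#'
#' @param tracks data.frame with at least `track_id`, `t_s`, `x_um`, `y_um`.
#' @return named list of per-track data.frames, ordered by track id.
#' @export
split_tracks <- function(tracks) {
  split(tracks, tracks$track_id)
}

#' Write / read track tables as CSV
#'
#' The on-disk format is one row per point: `track_id, frame, t_s, x_um,
#' y_um`.
#'
#' @param tracks long-format track table as produced by [gen_tracks()].
#' @param path file path.
#' @return `read_tracks_csv` returns the track table.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(tracks[, c("track_id", "frame", "t_s", "x_um", "y_um")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  tr <- read.csv(path)
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tr))) {
    mito_stop("track CSV must have columns ", paste(need, collapse = ", "))
  }
  tr
}
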