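#' Zone maps for behavioral arenas
#'
#' A zone map is a named list of zones; each zone is one polygon (a
#' two-column matrix/data.frame of vertices) or a list of polygons (e.g.
#' the two closed arms of an elevated plus maze form one "closed" zone).
#' Zones must not overlap. Points on a polygon boundary count as inside,
#' so no frame is lost at arm junctions.
#'
#' `epm_zone_map()` builds the standard elevated-plus-maze template: four
#' `arm_length` x `arm_width` cm arms around a central
#' `arm_width` x `arm_width` junction square; closed arms run north-south,
#' open arms east-west.
#'
#' @param arm_length,arm_width arm dimensions, cm (defaults 30 x 5 cm).
#' @return named list of zones (`closed`, `open`, `center`).
#' @export
epm_zone_map <- function(arm_length = 30, arm_width = 5) {
  h <- arm_width / 2
  rect <- function(x1, y1, x2, y2) {
    cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))
  }
  list(
    closed = list(rect(-h, h, h, h + arm_length),
                  rect(-h, -h - arm_length, h, -h)),
    open = list(rect(h, -h, h + arm_length, h),
                rect(-h - arm_length, -h, -h, h)),
    center = list(rect(-h, -h, h, h))
  )
}

#' Open-field zone template
#'
#' Splits a square arena into a concentric `center` zone and the
#' remaining `periphery` (as a ring of four rectangles).
#'
#' @param side arena side, cm.
#' @param center_frac linear fraction of the side occupied by the center
#'   zone.
#' @return named list of zones.
#' @export
openfield_zone_map <- function(side = 45, center_frac = 0.5) {
  c0 <- side * (1 - center_frac) / 2
  c1 <- side - c0
  rect <- function(x1, y1, x2, y2) {
    cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))
  }
  list(
    center = list(rect(c0, c0, c1, c1)),
    periphery = list(rect(0, 0, side, c0), rect(0, c1, side, side),
                     rect(0, c0, c0, c1), rect(c1, c0, side, c1))
  )
}

# boundary-inclusive point-in-polygon (ray casting + on-edge test),
# vectorized over points
points_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  xs <- poly[, 1]
  ys <- poly[, 2]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-segment test
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    dot <- (px - xi) * (xj - xi) + (py - yi) * (yj - yi)
    len2 <- (xj - xi)^2 + (yj - yi)^2
    onedge <- onedge | (abs(cross) < 1e-9 * max(1, sqrt(len2)) &
                          dot >= -1e-12 & dot <= len2 + 1e-12)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

zone_polys <- function(zone) if (is.list(zone) && !is.data.frame(zone)) zone else list(zone)

points_in_zone <- function(px, py, zone) {
  res <- logical(length(px))
  for (poly in zone_polys(zone)) {
    res <- res | points_in_polygon(px, py, poly)
  }
  res
}

#' Percent time spent in each arena zone
#'
#' Assigns every trajectory frame to the zone containing it (boundary
#' points count as inside) and reports the percentage of frames per zone.
#' Frames outside all zones are allowed, so percentages sum to at most
#' 100.
#'
#' @param traj data.frame with `x`, `y` (one row per frame).
#' @param zones zone map, e.g. from [epm_zone_map()].
#' @return named numeric vector of percentages, one per zone.
#' @export
zone_occupancy <- function(traj, zones) {
  if (nrow(traj) == 0) mito_stop("trajectory has no frames")
  vapply(zones, function(z) {
    100 * sum(points_in_zone(traj$x, traj$y, z)) / nrow(traj)
  }, numeric(1))
}

#' Trajectory kinematics
#'
#' @param traj data.frame with `t_s`, `x`, `y`; coordinates in arena
#'   units.
#' @param calibration multiplicative units-to-cm factor.
#' @return list: `total_distance_cm` (sum of inter-frame Euclidean steps)
#'   and `mean_velocity_cm_s` (distance / elapsed time).
#' @export
traj_kinematics <- function(traj, calibration = 1) {
  if (nrow(traj) < 2) mito_stop("trajectory needs at least 2 frames")
  d <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)) * calibration
  list(total_distance_cm = d,
       mean_velocity_cm_s = d / (traj$t_s[nrow(traj)] - traj$t_s[1]))
}

#' Rotarod speed at fall
#'
#' Speed of the accelerating rod at the moment the animal fell:
#' `RPM = (end_speed - start_speed) / trial_length * seconds_run +
#' start_speed`.
#'
#' @param seconds_run time on the rod, s (within `[0, trial_length]`).
#' @param start_speed,end_speed rod speeds, RPM (defaults 4 to 40 RPM).
#' @param trial_length trial duration, s (default 300 s).
#' @return speed in RPM.
#' @export
rotarod_rpm <- function(seconds_run, start_speed = 4, end_speed = 40,
                        trial_length = 300) {
  if (any(seconds_run < 0 | seconds_run > trial_length)) {
    mito_stop("seconds_run must be within [0, trial_length]")
  }
  (end_speed - start_speed) / trial_length * seconds_run + start_speed
}

#' Spontaneous alternation score on the T-maze
#'
#' Percentage of consecutive valid arm choices that differ. Trials where
#' the animal made no choice (`NO-GO`) do not enter the score; an animal
#' with more than `max_no_go` NO-GOs is flagged excluded.
#'
#' @param choices character vector of arm choices in trial order, e.g.
#'   `c("L", "R", "NO-GO", "L")`.
#' @param no_go label marking NO-GO trials.
#' @param max_no_go NO-GO count above which the animal is excluded
#'   (default 3).
#' @return list: `percent_alternation` (`NA` with fewer than 2 valid
#'   choices), `n_no_go`, `excluded`.
#' @export
alternation_score <- function(choices, no_go = "NO-GO", max_no_go = 3) {
  n_no_go <- sum(choices == no_go)
  valid <- choices[choices != no_go]
  pct <- if (length(valid) < 2) NA_real_ else {
    100 * mean(head(valid, -1) != tail(valid, -1))
  }
  list(percent_alternation = pct, n_no_go = n_no_go,
       excluded = n_no_go > max_no_go)
}

#' Generate a synthetic animal trajectory with known zone occupancy
#'
#' Produces a frame-by-frame trajectory whose per-zone frame counts equal
#' `round_half_away(occupancy * n_frames)` with the rounding remainder
#' assigned to the lowest-index zones, by sampling points uniformly inside
#' each zone's polygons. Zones are checked for overlap (via their
#' vertices and centroids).
#'
#' @param zones zone map (see [epm_zone_map()]).
#' @param occupancy named/ordered vector of zone occupancy proportions,
#'   summing to 1.
#' @param n_frames number of frames.
#' @param frame_rate frames per second.
#' @param seed integer seed.
#' @return data.frame `frame`, `t_s`, `x`, `y` with the per-zone counts in
#'   attribute `truth`.
#' @export
gen_trajectory <- function(zones, occupancy, n_frames = 1000,
                           frame_rate = 25, seed = 1) {
  if (abs(sum(occupancy) - 1) > 1e-8) mito_stop("occupancy must sum to 1")
  if (length(occupancy) != length(zones)) {
    mito_stop("occupancy must have one entry per zone")
  }
  # overlap check on vertices and centroids
  for (i in seq_along(zones)) {
    for (poly in zone_polys(zones[[i]])) {
      probe_x <- c(mean(poly[, 1]), poly[, 1] * 0.999 + mean(poly[, 1]) * 0.001)
      probe_y <- c(mean(poly[, 2]), poly[, 2] * 0.999 + mean(poly[, 2]) * 0.001)
      for (j in seq_along(zones)) {
        if (j != i && any(points_in_zone(probe_x, probe_y, zones[[j]]))) {
          mito_stop("zones ", i, " and ", j, " overlap")
        }
      }
    }
  }
  counts <- allocate_counts(occupancy, n_frames)
  with_seed(seed, {
    pts <- lapply(seq_along(zones), function(i) {
      if (counts[i] == 0) return(matrix(numeric(0), ncol = 2))
      sample_in_zone(zones[[i]], counts[i])
    })
    xy <- do.call(rbind, pts)
    data.frame(frame = seq_len(n_frames) - 1L,
               t_s = (seq_len(n_frames) - 1L) / frame_rate,
               x = xy[, 1], y = xy[, 2]) |>
      structure(truth = list(counts = counts, occupancy = occupancy))
  })
}

# rejection-sample n points uniformly inside a zone (union of polygons,
# area-weighted)
sample_in_zone <- function(zone, n) {
  polys <- zone_polys(zone)
  areas <- vapply(polys, function(p) {
    p <- as.matrix(p)
    abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2])) / 2
  }, numeric(1))
  pick <- sample.int(length(polys), n, replace = TRUE, prob = areas)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    p <- as.matrix(polys[[pick[i]]])
    repeat {
      x <- runif(1, min(p[, 1]), max(p[, 1]))
      y <- runif(1, min(p[, 2]), max(p[, 2]))
      if (points_in_polygon(x, y, p)) break
    }
    out[i, ] <- c(x, y)
  }
  out
}
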