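test_that("frame displacements are per-interval Euclidean steps", {
  tr <- data.frame(track_id = 1, t_s = c(0, 5), x_um = c(0, 3), y_um = 0)
  d <- frame_displacements(tr)
  expect_equal(d$interval_s, 5)
  expect_equal(d$step_um, 3)
  still <- straight_track(10, 0)
  expect_true(all(frame_displacements(still)$step_um == 0))
  # re-summation: displacements add up to the path length
  g <- gen_tracks(5, seed = 3)
  for (t1 in split_tracks(g$tracks)) {
    expect_equal(sum(frame_displacements(t1)$step_um), track_path_length(t1))
  }
  bad <- data.frame(track_id = 1, t_s = c(0, 5, 4), x_um = 0:2, y_um = 0)
  expect_mitodyn_error(frame_displacements(bad))
})

test_that("mobility follows the 2 um per 300 s rule", {
  # 0.05 um/frame at 5 s/frame = 3 um per 300 s -> mobile
  expect_true(classify_mobility(straight_track(100, 0.05)))
  # 0.02 um/frame = 1.2 um per 300 s -> immobile
  expect_false(classify_mobility(straight_track(100, 0.02)))
})

test_that("mobility equals the exhaustive window-maximum oracle", {
  set.seed(99)
  for (rep in 1:20) {
    steps <- runif(100, 0, 0.05)
    tr <- track_from_steps(steps)
    w <- 60  # 300 s / 5 s frames
    oracle <- max(vapply(seq_len(length(steps) - w + 1), function(s) {
      sum(steps[s:(s + w - 1)])
    }, numeric(1))) > 2
    expect_identical(classify_mobility(tr), oracle)
  }
})

test_that("lowering the threshold never turns a mobile track immobile", {
  g <- gen_tracks(20, mobile_fraction = 0.5, seed = 11)
  for (tr in split_tracks(g$tracks)) {
    m2 <- classify_mobility(tr, threshold = 2)
    m1 <- classify_mobility(tr, threshold = 1)
    expect_true(!m2 || m1)
  }
})

test_that("velocity excludes pauses longer than 10 s", {
  # 10 moving frames of 0.1 um then a 50-s stationary block
  tr <- track_from_steps(c(rep(0.1, 10), rep(0, 10)))
  v <- track_velocity(tr)
  expect_equal(as.numeric(v), 1.0 / 50)
  expect_equal(attr(v, "excluded_time_s"), 50)
  # a 10-s block is not "longer than 10 s": kept in the denominator
  tr2 <- track_from_steps(c(rep(0.1, 10), rep(0, 2)))
  expect_equal(as.numeric(track_velocity(tr2)), 1.0 / 60)
  # fully stationary track: all time excluded, velocity undefined
  expect_true(is.na(track_velocity(track_from_steps(rep(0, 20)))))
})

test_that("velocity equals a brute-force pause-mask computation", {
  set.seed(7)
  for (rep in 1:20) {
    steps <- ifelse(runif(80) < 0.3, 0, runif(80, 0.1, 0.9))
    tr <- track_from_steps(steps)
    # oracle: explicit mask over frames, run-by-run
    immobile <- steps < 0.1
    excl <- logical(length(steps))
    i <- 1
    while (i <= length(steps)) {
      if (immobile[i]) {
        j <- i
        while (j < length(steps) && immobile[j + 1]) j <- j + 1
        if ((j - i + 1) * 5 > 10) excl[i:j] <- TRUE
        i <- j + 1
      } else i <- i + 1
    }
    denom <- (length(steps) - sum(excl)) * 5
    v_oracle <- if (denom == 0) NA_real_ else sum(steps[!excl]) / denom
    expect_equal(as.numeric(track_velocity(tr)), v_oracle)
  }
})

test_that("velocity is invariant to rigid motions and recovers constant speed", {
  g <- gen_tracks(10, mobile_fraction = 1, speed = 0.17, seed = 2)
  for (tr in split_tracks(g$tracks)) {
    v <- as.numeric(track_velocity(tr))
    expect_equal(v, 0.17, tolerance = 1e-12)
    th <- 0.7
    rot <- tr
    rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 12
    rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 5
    expect_equal(as.numeric(track_velocity(rot)), v, tolerance = 1e-9)
  }
})

test_that("pause exclusion never lowers velocity below the naive ratio", {
  g <- gen_tracks(15, mobile_fraction = 1, seed = 13)
  for (tr in split_tracks(g$tracks)) {
    naive <- track_path_length(tr) / (max(tr$t_s) - min(tr$t_s))
    expect_gte(as.numeric(track_velocity(tr)) + 1e-12, naive)
  }
})

test_that("path length sums steps and ignores direction", {
  expect_equal(track_path_length(straight_track(94, 0.5)), 47)
  expect_equal(track_path_length(straight_track(10, 0)), 0)
  loop <- data.frame(track_id = 1, t_s = seq(0, 20, 5),
                     x_um = c(0, 1, 1, 0, 0), y_um = c(0, 0, 1, 1, 0))
  expect_equal(track_path_length(loop), 4)
  expect_equal(loop$x_um[1], loop$x_um[5])  # closed: net displacement 0
})

test_that("movie mobile fraction is a percentage of all mitochondria", {
  st <- data.frame(is_mobile = c(rep(TRUE, 23), rep(FALSE, 77)))
  expect_equal(movie_mobile_fraction(st, 100), 23)
  expect_equal(movie_mobile_fraction(data.frame(is_mobile = logical(5)), 10), 0)
  expect_equal(movie_mobile_fraction(data.frame(is_mobile = !logical(7))), 100)
  expect_mitodyn_error(movie_mobile_fraction(st, 0))
  expect_mitodyn_error(movie_mobile_fraction(st, 50))
})
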