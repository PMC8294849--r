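test_that("zone occupancy reproduces constructed occupancy exactly", {
  zones <- epm_zone_map()
  traj <- gen_trajectory(zones, c(closed = 1, open = 0, center = 0),
                         n_frames = 200, seed = 1)
  occ <- zone_occupancy(traj, zones)
  expect_equal(unname(occ), c(100, 0, 0))
  traj2 <- gen_trajectory(zones, c(closed = 0.76, open = 0.18, center = 0.06),
                          n_frames = 1000, seed = 2)
  expect_equal(unname(zone_occupancy(traj2, zones)), c(76, 18, 6))
  expect_equal(attr(traj2, "truth")$counts, c(760L, 180L, 60L))
  # occupancies over disjoint zones are bounded by 100
  expect_lte(sum(zone_occupancy(traj2, zones)), 100 + 1e-9)
})

test_that("points on zone boundaries count as inside", {
  zones <- epm_zone_map()
  # the closed-arm mouth sits on the center's boundary y = 2.5
  border <- data.frame(x = 0, y = 2.5)
  expect_true(mitodyn:::points_in_zone(border$x, border$y, zones$closed))
  out <- data.frame(x = 40, y = 40)
  expect_false(mitodyn:::points_in_zone(out$x, out$y, zones$closed))
})

test_that("point-in-polygon agrees with mgcv for interior points", {
  skip_if_not_installed("mgcv")
  set.seed(5)
  poly <- cbind(x = c(0, 4, 5, 2, -1), y = c(0, -1, 3, 5, 2))
  px <- runif(300, -2, 6)
  py <- runif(300, -2, 6)
  mine <- mitodyn:::points_in_polygon(px, py, poly)
  ref <- as.logical(mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py)))
  # boundary handling may differ; random points are interior almost surely
  expect_equal(mine, ref)
})

test_that("zone occupancy is invariant under an arena similarity transform", {
  zones <- epm_zone_map()
  traj <- gen_trajectory(zones, c(closed = 0.5, open = 0.3, center = 0.2),
                         n_frames = 400, seed = 3)
  occ0 <- zone_occupancy(traj, zones)
  s <- 2.5; th <- 0.6; dx <- 11; dy <- -4
  rot <- function(x, y) {
    list(x = s * (cos(th) * x - sin(th) * y) + dx,
         y = s * (sin(th) * x + cos(th) * y) + dy)
  }
  traj_t <- traj
  xy <- rot(traj$x, traj$y)
  traj_t$x <- xy$x; traj_t$y <- xy$y
  zones_t <- lapply(zones, function(z) {
    lapply(mitodyn:::zone_polys(z), function(p) {
      q <- rot(p[, 1], p[, 2])
      cbind(x = q$x, y = q$y)
    })
  })
  expect_equal(zone_occupancy(traj_t, zones_t), occ0)
})

test_that("trajectory kinematics sum calibrated steps", {
  tr <- data.frame(t_s = seq(0, 50, 1),
                   x = seq(0, 100, 2), y = 0)
  k <- traj_kinematics(tr)
  expect_equal(k$total_distance_cm, 100)
  expect_equal(k$mean_velocity_cm_s, 2)
  still <- data.frame(t_s = 0:10, x = 5, y = 5)
  expect_equal(traj_kinematics(still)$total_distance_cm, 0)
  # re-summation oracle on a random walk
  set.seed(9)
  rw <- data.frame(t_s = 0:100, x = cumsum(rnorm(101)), y = cumsum(rnorm(101)))
  oracle <- sum(sqrt(diff(rw$x)^2 + diff(rw$y)^2))
  expect_equal(traj_kinematics(rw)$total_distance_cm, oracle)
})

test_that("rotarod RPM is affine with pinned endpoints", {
  expect_equal(rotarod_rpm(150, 4, 40, 300), 22)
  expect_equal(rotarod_rpm(0), 4)
  expect_equal(rotarod_rpm(300), 40)
  # affine: midpoint of two runs maps to midpoint of RPMs
  expect_equal(rotarod_rpm(mean(c(60, 240))),
               mean(rotarod_rpm(c(60, 240))))
  expect_mitodyn_error(rotarod_rpm(301))
  expect_mitodyn_error(rotarod_rpm(-1))
})

test_that("alternation scoring handles NO-GO exclusion", {
  expect_equal(alternation_score(rep(c("L", "R"), 4))$percent_alternation, 100)
  expect_equal(alternation_score(rep("L", 4))$percent_alternation, 0)
  four <- alternation_score(c("L", "NO-GO", "R", "NO-GO", "L", "NO-GO",
                              "R", "NO-GO"))
  expect_true(four$excluded)
  expect_equal(four$n_no_go, 4)
  three <- alternation_score(c("L", "NO-GO", "R", "NO-GO", "L", "NO-GO"))
  expect_false(three$excluded)
  expect_true(is.na(alternation_score(c("NO-GO", "L"))$percent_alternation))
})

test_that("overlapping zones are rejected by the trajectory generator", {
  overlapping <- list(
    a = cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)),
    b = cbind(x = c(5, 15, 15, 5), y = c(5, 5, 15, 15))
  )
  expect_mitodyn_error(
    gen_trajectory(overlapping, c(a = 0.5, b = 0.5), 100, seed = 1)
  )
  zones <- epm_zone_map()
  expect_mitodyn_error(
    gen_trajectory(zones, c(closed = 0.5, open = 0.4, center = 0.2), 100)
  )
})
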