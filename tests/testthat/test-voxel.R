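test_that("volume mask of a single sphere matches the analytic volume", {
  one <- swc_nodes(1, 1, 0, 0, 0, 2, -1)
  mask <- fill_volume_mask(one, voxel_size = 0.25)
  vol <- sum(mask$data) * 0.25^3
  expect_equal(vol, 4 / 3 * pi * 2^3, tolerance = 0.05)
})

test_that("volume mask grows monotonically with the tree", {
  m <- random_morph(2, ba = 2, bd = 1)
  df <- as.data.frame(m)
  # subtree: drop all dendritic nodes (they are leaves of the soma)
  sub <- as_swc_morphology(df[df$type != 3, ])
  full <- fill_volume_mask(m, voxel_size = 1)
  part <- fill_volume_mask(sub, voxel_size = 1, grid = full)
  expect_true(all(full$data[part$data]))
  # empty morphology (soma only, radius clamped): still a valid stack
  soma_only <- swc_nodes(1, 1, 0, 0, 0, 0, -1)
  m0 <- fill_volume_mask(soma_only, voxel_size = 1)
  expect_true(sum(m0$data) >= 1)
})

test_that("MitoSholl bins positive voxels into half-open 1 um shells", {
  # one positive voxel whose center sits at distance 5.5 um; the median
  # filter is off because a deliberate single-voxel signal is exactly what
  # it is designed to remove
  stk <- stack_with_positives(matrix(c(5.5, 0, 0), 1),
                              origin = c(-9.5, -10, -10))
  raw <- voxel_stack(ifelse(stk$data, 100, 0), stk$voxel_size, stk$origin)
  prof <- mito_sholl(raw, mask = NULL, center = c(0, 0, 0), step = 1,
                     rolling_ball_radius = 3, median_size = 0)
  expect_equal(prof$count[prof$radius_um == 5], 1)
  expect_equal(sum(prof$count), 1)
  # empty stack: all-zero profile
  empty <- voxel_stack(array(10, c(8, 8, 4)), 1)
  prof0 <- mito_sholl(empty, NULL, center = c(0, 0, 0),
                      rolling_ball_radius = 3)
  expect_equal(sum(prof0$count), 0)
})

test_that("shell counts equal exhaustive per-voxel binning and conserve totals", {
  set.seed(4)
  dims <- c(15, 12, 9)
  arr <- array(runif(prod(dims)) < 0.3, dims)
  stk <- voxel_stack(arr, c(0.5, 0.5, 1), origin = c(-2, -1, 0))
  center <- c(1, 1, 2)
  prof <- mitodyn:::shell_counts(arr, stk, center, step = 1)
  # oracle: explicit loop over voxels
  oracle <- integer(length(prof$radius_um))
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    if (!arr[i, j, k]) next
    p <- c(-2, -1, 0) + (c(i, j, k) - 1) * c(0.5, 0.5, 1)
    sh <- floor(sqrt(sum((p - center)^2)))
    oracle[sh + 1] <- oracle[sh + 1] + 1L
  }
  expect_equal(prof$count, oracle)
  expect_equal(sum(prof$count), sum(arr))  # conservation
})

test_that("minimum distances match geometry and brute force", {
  stk <- stack_with_positives(matrix(c(3, 4, 0), 1))
  bp <- data.frame(x = 0, y = 0, z = 0)
  expect_equal(min_branch_mito_distance(bp, stk)$min_dist_um, 5)
  # mito voxel exactly at the branch point
  stk0 <- stack_with_positives(matrix(c(0, 0, 0), 1))
  expect_equal(min_branch_mito_distance(bp, stk0)$min_dist_um, 0)
  # 1000 random voxels vs exhaustive all-pairs scan
  set.seed(11)
  dims <- c(20, 20, 10)
  arr <- array(FALSE, dims)
  arr[sample(prod(dims), 1000)] <- TRUE
  stka <- voxel_stack(arr, c(0.4, 0.4, 0.8), origin = c(0, 0, 0))
  pts <- data.frame(x = runif(5, 0, 8), y = runif(5, 0, 8), z = runif(5, 0, 7))
  res <- min_branch_mito_distance(pts, stka)
  idx <- which(arr, arr.ind = TRUE)
  for (q in seq_len(5)) {
    d_all <- apply(idx, 1, function(v) {
      p <- (v - 1) * c(0.4, 0.4, 0.8)
      sqrt(sum((p - as.numeric(pts[q, ]))^2))
    })
    expect_equal(res$min_dist_um[q], min(d_all))
  }
})

test_that("distances never increase when positive voxels are added", {
  set.seed(3)
  arr <- array(FALSE, c(12, 12, 6))
  arr[sample(prod(dim(arr)), 30)] <- TRUE
  more <- arr
  more[sample(which(!more), 40)] <- TRUE
  pts <- data.frame(x = runif(4, 0, 11), y = runif(4, 0, 11), z = runif(4, 0, 5))
  d1 <- min_branch_mito_distance(pts, voxel_stack(arr, 1))$min_dist_um
  d2 <- min_branch_mito_distance(pts, voxel_stack(more, 1))$min_dist_um
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("an empty mitochondrial stack yields an undefined-distance signal", {
  empty <- voxel_stack(array(FALSE, c(5, 5, 5)), 1)
  expect_error(
    min_branch_mito_distance(data.frame(x = 0, y = 0, z = 0), empty),
    class = "mitodyn_undefined"
  )
})

test_that("normalization pins the reference mean at 1 and is scale invariant", {
  set.seed(6)
  ref <- runif(50, 0.2, 3)
  other <- ref * 0.5
  norm <- normalize_distances(list(wt = ref, ko = other), reference = "wt")
  expect_equal(mean(norm$wt), 1)
  expect_equal(mean(norm$ko), 0.5)
  scaled <- normalize_distances(list(wt = 3 * ref, ko = 3 * other), "wt")
  expect_equal(scaled$ko, norm$ko)
  expect_mitodyn_error(normalize_distances(list(a = c(0, 0)), "a"))
})

test_that("probability within radius is the fraction of close branch points", {
  expect_equal(prob_within_radius(rep(0, 5), 1), 1)
  expect_equal(prob_within_radius(c(2, 3, 4), 1), 0)
  d <- c(runif(49, 0, 0.99), runif(51, 1.01, 5))
  expect_equal(prob_within_radius(d, 1), 0.49)
})

test_that("proximity analysis is invariant to a consistent rigid shift", {
  m <- random_morph(4, ba = 2, bd = 1)
  s <- gen_mito_stack(m, 40, voxel_size = 1, psf_sigma = 0.6, seed = 4)
  bin <- binarize(s$stack$data)
  bp <- branch_points(m)
  d0 <- min_branch_mito_distance(
    bp, voxel_stack(bin, s$stack$voxel_size, s$stack$origin))$min_dist_um
  shift <- c(7, -3, 2)
  bp2 <- bp
  bp2[, c("x", "y", "z")] <- sweep(as.matrix(bp[, c("x", "y", "z")]), 2,
                                   -shift)
  d1 <- min_branch_mito_distance(
    bp2, voxel_stack(bin, s$stack$voxel_size, s$stack$origin + shift)
  )$min_dist_um
  expect_equal(d1, d0, tolerance = 1e-9)
})
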