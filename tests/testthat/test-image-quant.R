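test_that("rolling-ball subtraction removes backgrounds, keeps small features", {
  expect_true(all(rolling_ball_subtract(matrix(7, 40, 40), 5) == 0))
  # impulse on a flat background survives
  img <- matrix(10, 50, 50)
  img[25, 25] <- 110
  out <- rolling_ball_subtract(img, 5)
  expect_equal(out[25, 25], 100, tolerance = 1)
  expect_true(all(out >= 0))
  # blobs on a linear gradient: peak heights recovered within 5%
  grad <- outer(seq(0, 50, length.out = 80), rep(1, 80))
  blobs <- matrix(0, 80, 80)
  for (ctr in list(c(20, 20), c(60, 50))) {
    d2 <- outer((1:80 - ctr[1])^2, (1:80 - ctr[2])^2, `+`)
    blobs <- blobs + 80 * exp(-d2 / (2 * 2^2))
  }
  rec <- rolling_ball_subtract(grad + blobs, 15)
  expect_equal(rec[20, 20], 80, tolerance = 80 * 0.05)
  expect_equal(rec[60, 50], 80, tolerance = 80 * 0.05)
})

test_that("region mean intensity equals an explicit loop", {
  img <- matrix(7, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(region_mean_intensity(img, mask), 7)
  img2 <- matrix(0, 10, 10)
  img2[, 6:10] <- 10
  mask2 <- col(img2) > 5
  expect_equal(region_mean_intensity(img2, mask2), 10)
  set.seed(1)
  img3 <- matrix(runif(100), 10, 10)
  mask3 <- matrix(runif(100) < 0.4, 10, 10)
  acc <- 0; n <- 0
  for (i in 1:10) for (j in 1:10) if (mask3[i, j]) {
    acc <- acc + img3[i, j]; n <- n + 1
  }
  expect_equal(region_mean_intensity(img3, mask3), acc / n)
  expect_mitodyn_error(region_mean_intensity(img3, matrix(FALSE, 10, 10)))
})

test_that("soma area fraction is bounded, exact and monotone", {
  soma <- matrix(FALSE, 100, 100)
  soma[1:100, 1:100] <- TRUE
  expect_equal(soma_mito_area_fraction(soma, soma), 100)
  none <- matrix(FALSE, 100, 100)
  expect_equal(soma_mito_area_fraction(none, soma), 0)
  mito <- none
  mito[1:39, 1:100] <- TRUE
  expect_equal(soma_mito_area_fraction(mito, soma), 39)
  mito2 <- mito
  mito2[40, 1:50] <- TRUE
  expect_gte(soma_mito_area_fraction(mito2, soma),
             soma_mito_area_fraction(mito, soma))
  expect_mitodyn_error(soma_mito_area_fraction(mito, none))
})

test_that("cluster detection keys on the largest component's dominance", {
  soma <- matrix(TRUE, 60, 60)
  single <- matrix(FALSE, 60, 60)
  single[20:30, 20:30] <- TRUE
  expect_true(detect_soma_cluster(single, soma))
  # 10 equal scattered blobs: none dominates at 0.5
  scattered <- matrix(FALSE, 60, 60)
  for (k in 0:9) scattered[5 + 5 * k, 5 + (k %% 3) * 20 + 1:2] <- TRUE
  expect_false(detect_soma_cluster(scattered, soma))
  expect_false(detect_soma_cluster(matrix(FALSE, 60, 60), soma))
})

test_that("punctum detection obeys area bounds and matches a labeling oracle", {
  expect_equal(nrow(detect_puncta(matrix(0, 30, 30), 0.2)), 0)
  # two discs and one merged oversized pair on a dark field
  img <- matrix(0, 80, 80)
  disc <- function(cx, cy, r) {
    d2 <- outer((1:80 - cx)^2, (1:80 - cy)^2, `+`)
    d2 <= r^2
  }
  img[disc(15, 15, 3)] <- 100
  img[disc(40, 40, 3)] <- 100
  img[disc(62, 62, 8) | disc(70, 62, 8)] <- 100  # merged, too large
  pn <- detect_puncta(img, pixel_size = 0.2, min_area = 0.2, max_area = 3)
  expect_equal(nrow(pn), 2)
  # oracle: EBImage labeling with the same threshold, then area filter
  lab <- EBImage::bwlabel(EBImage::Image(img > 50))
  areas <- table(as.integer(lab)[as.integer(lab) > 0]) * 0.2^2
  expect_equal(nrow(pn), sum(areas >= 0.2 & areas <= 3))
})

test_that("punctum detection tolerates a constant intensity offset", {
  g <- gen_axon_boutons(30, 0.5, axon_length = 150, seed = 8)
  n0 <- nrow(detect_puncta(g$biocytin, g$pixel_size))
  n1 <- nrow(detect_puncta(g$biocytin + 37, g$pixel_size))
  expect_equal(n0, n1)
})

test_that("bouton occupancy follows the 10 um scaling law", {
  pn <- data.frame(id = 1:5)
  expect_equal(bouton_occupancy(pn, 50), 1)
  expect_equal(bouton_occupancy(pn[0, , drop = FALSE], 50), 0)
  expect_equal(bouton_occupancy(pn, 100), 0.5)
  expect_mitodyn_error(bouton_occupancy(pn, 0))
})

test_that("bouton mitochondrial scoring reproduces ground-truth flags", {
  g <- gen_axon_boutons(80, 0.6, axon_length = 250, seed = 6)
  pn <- detect_puncta(g$biocytin, g$pixel_size)
  ct <- bouton_mito_content(pn, g$mito, g$shaft_mask)
  expect_equal(ct$fraction_containing, 100 * 48 / 80)
  # per-bouton decisions match truth (match detected puncta to truth by x)
  truth_sorted <- g$truth[order(g$truth$x_px), ]
  det_sorted <- order(pn$x_px)
  expect_equal(ct$contains[det_sorted], truth_sorted$has_mito)
  # all empty
  g0 <- gen_axon_boutons(20, 0, seed = 2)
  pn0 <- detect_puncta(g0$biocytin, g0$pixel_size)
  ct0 <- bouton_mito_content(pn0, g0$mito, g0$shaft_mask)
  expect_equal(ct0$fraction_containing, 0)
})

test_that("object colocalization accepts 33-100% overlap of the smaller object", {
  blank <- matrix(0, 100, 100)
  rect <- function(img, x, y, w, h, v = 100) {
    img[x:(x + w - 1), y:(y + h - 1)] <- v
    img
  }
  # identical images: every object pairs with itself
  same <- rect(rect(blank, 10, 10, 6, 6), 40, 40, 6, 6)
  res <- synapse_colocalization(same, same, rolling_ball_radius = 7)
  expect_equal(res$pre_count, 2)
  expect_equal(res$colocalized, 2)
  # disjoint sets: zero pairs
  pre <- rect(blank, 10, 10, 6, 6)
  post <- rect(blank, 60, 60, 6, 6)
  expect_equal(synapse_colocalization(pre, post)$colocalized, 0)
  # constructed overlaps: 20% -> rejected, 50% and 100% -> accepted
  pre1 <- rect(blank, 20, 20, 10, 10)
  overlaps <- c(`20` = 0, `50` = 1, `100` = 1)
  for (pct in names(overlaps)) {
    shift <- switch(pct, `20` = 8, `50` = 5, `100` = 0)
    post1 <- rect(blank, 20 + shift, 20, 10, 10)
    got <- synapse_colocalization(pre1, post1,
                                  max_filter_size = 0)$colocalized
    expect_equal(got, unname(overlaps[pct]),
                 label = paste0(pct, "% overlap pair count"))
  }
  # pair count bounded by the smaller object count
  many_pre <- rect(rect(rect(blank, 10, 10, 6, 6), 30, 10, 6, 6), 50, 10, 6, 6)
  one_post <- rect(blank, 10, 10, 6, 6)
  res2 <- synapse_colocalization(many_pre, one_post)
  expect_lte(res2$colocalized, min(res2$pre_count, res2$post_count))
})
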