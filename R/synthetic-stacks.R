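#' Generate a synthetic mitochondrial voxel stack on a morphology
#'
#' Places `n_mito` mitochondria on (or at given points near) a
#' reconstruction and renders each as an isotropic 3D Gaussian blob with
#' peak intensity 10x the background, on a constant background — bright
#' enough to survive default binarization deterministically. The stack
#' covers the morphology bounding box plus a margin.
#'
#' @param morph `swc_morphology` the mitochondria live on.
#' @param n_mito number of mitochondria (ignored for
#'   `placement = "at_given_points"`).
#' @param placement `"uniform_on_tree"` (uniform per unit cable length),
#'   `"biased_to_soma"` (edge weight decaying exponentially with distance
#'   from the soma, 30 um length constant), or `"at_given_points"`.
#' @param points n x 3 matrix of centers for `"at_given_points"`.
#' @param voxel_size voxel size, um (length 1 or 3).
#' @param psf_sigma Gaussian blob sigma, um. If `voxel_size` exceeds
#'   `2 * psf_sigma` a warning is issued (blobs may vanish after
#'   binarization).
#' @param background,peak background level and blob peak intensity (a.u.).
#' @param margin stack padding around the bounding box, um.
#' @param seed integer seed.
#' @return list with `stack` (a `voxel_stack`) and `truth`: `centers`
#'   (n x 3 matrix) and, when branch points exist, `branch_nearest_um`,
#'   the per-branch-point distance to the nearest true center.
#' @export
gen_mito_stack <- function(morph, n_mito = 100,
                           placement = c("uniform_on_tree", "biased_to_soma",
                                         "at_given_points"),
                           points = NULL, voxel_size = 0.5, psf_sigma = 0.4,
                           background = 10, peak = 100, margin = 3,
                           seed = 1) {
  placement <- match.arg(placement)
  morph <- as_swc_morphology(morph)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) mito_stop("voxel_size must be positive")
  if (n_mito < 0) mito_stop("n_mito must be >= 0")
  if (max(voxel_size) > 2 * psf_sigma) {
    warning("voxel_size exceeds 2*psf_sigma: blobs may vanish after binarization")
  }

  centers <- with_seed(seed, {
    if (placement == "at_given_points") {
      if (is.null(points)) mito_stop("placement 'at_given_points' needs points")
      m <- as.matrix(points)
      if (ncol(m) != 3) mito_stop("points must be n x 3")
      m
    } else if (n_mito == 0) {
      matrix(numeric(0), ncol = 3)
    } else {
      e <- swc_edges(morph)
      xyz <- as.matrix(morph[, c("x", "y", "z")])
      p1 <- xyz[e[, "parent"], , drop = FALSE]
      p2 <- xyz[e[, "child"], , drop = FALSE]
      len <- row_norms(p2 - p1)
      w <- len
      if (placement == "biased_to_soma") {
        soma <- xyz[morph$parent == -1, ]
        mid <- (p1 + p2) / 2
        w <- len * exp(-row_norms(sweep(mid, 2, soma)) / 30)
      }
      ei <- sample.int(nrow(e), n_mito, replace = TRUE, prob = w)
      t <- runif(n_mito)
      p1[ei, , drop = FALSE] + (p2[ei, , drop = FALSE] - p1[ei, , drop = FALSE]) * t
    }
  })

  xyz <- as.matrix(morph[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(1L, ceiling((hi - lo) / voxel_size) + 1L)
  stk <- voxel_stack(array(background, dims), voxel_size, origin = lo)
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 1) * voxel_size[d])
  ext <- 4 * psf_sigma
  for (i in seq_len(nrow(centers))) {
    cc <- centers[i, ]
    ii <- lapply(1:3, function(d) which(abs(ax[[d]] - cc[d]) <= ext))
    if (any(lengths(ii) == 0)) next
    dx2 <- lapply(1:3, function(d) (ax[[d]][ii[[d]]] - cc[d])^2)
    blob <- peak * exp(-(outer(outer(dx2[[1]], dx2[[2]], `+`), dx2[[3]], `+`)) /
                         (2 * psf_sigma^2))
    stk$data[ii[[1]], ii[[2]], ii[[3]]] <-
      stk$data[ii[[1]], ii[[2]], ii[[3]], drop = FALSE] + blob
  }

  truth <- list(centers = centers)
  bp <- branch_points(morph)
  if (nrow(bp) > 0 && nrow(centers) > 0) {
    truth$branch_nearest_um <- apply(as.matrix(bp[, c("x", "y", "z")]), 1,
      function(q) min(row_norms(sweep(centers, 2, q))))
  }
  list(stack = stk, truth = truth)
}

#' Generate a synthetic soma image with a known mitochondrial area fraction
#'
#' Builds a soma mask of exactly `soma_area` pixels (the pixels closest to
#' the image center, ties broken by index) and a mitochondrial mask
#' containing exactly `round_half_away(mito_area_fraction * soma_area)`
#' in-soma pixels. With `clustered = TRUE` the mitochondrial pixels are
#' the ones nearest to a perinuclear anchor point, forming one connected
#' component; otherwise they are scattered uniformly at random.
#'
#' @param size image side, pixels.
#' @param soma_area soma mask area, pixels.
#' @param mito_area_fraction target in-soma mitochondrial area fraction,
#'   in \[0, 1\].
#' @param clustered concentrate the mitochondria in one perinuclear blob?
#' @param seed integer seed (used only for scattered placement).
#' @return list with logical matrices `soma_mask` and `mito_mask`, and
#'   `truth`: `fraction` and `n_mito_px`.
#' @export
gen_soma_image <- function(size = 128, soma_area = 10000,
                           mito_area_fraction = 0.39, clustered = FALSE,
                           seed = 1) {
  if (mito_area_fraction < 0 || mito_area_fraction > 1) {
    mito_stop("mito_area_fraction must be in [0, 1]")
  }
  if (soma_area > size^2) mito_stop("soma_area exceeds the image")
  ctr <- (size + 1) / 2
  gx <- matrix(seq_len(size), size, size)
  gy <- matrix(seq_len(size), size, size, byrow = TRUE)
  d_ctr <- (gx - ctr)^2 + (gy - ctr)^2
  ord <- order(d_ctr, seq_along(d_ctr))
  soma <- matrix(FALSE, size, size)
  soma[ord[seq_len(soma_area)]] <- TRUE
  n_mito <- round_half_away(mito_area_fraction * soma_area)
  mito <- matrix(FALSE, size, size)
  if (n_mito > 0) {
    in_soma <- which(soma)
    if (clustered) {
      anchor <- c(ctr + sqrt(soma_area / pi) / 2, ctr)
      d_anchor <- (gx[in_soma] - anchor[1])^2 + (gy[in_soma] - anchor[2])^2
      sel <- in_soma[order(d_anchor, seq_along(d_anchor))[seq_len(n_mito)]]
    } else {
      sel <- with_seed(seed, sample(in_soma, n_mito))
    }
    mito[sel] <- TRUE
  }
  list(soma_mask = soma, mito_mask = mito,
       truth = list(fraction = mito_area_fraction, n_mito_px = n_mito))
}

#' Generate a synthetic axon with boutons and mitochondria
#'
#' Renders a horizontal axon shaft of known path length with `n_boutons`
#' bright boutons (discs) at jittered, non-overlapping positions, and a
#' mitochondrial channel in which exactly
#' `round_half_away(frac_with_mito * n_boutons)` boutons contain a
#' mitochondrial punctum. Boutons are much brighter than the shaft so Otsu
#' thresholding isolates them.
#'
#' @param n_boutons number of boutons (>= 1).
#' @param frac_with_mito fraction of boutons containing mitochondria.
#' @param axon_length axon path length, um.
#' @param pixel_size um per pixel.
#' @param bouton_radius_um bouton disc radius, um.
#' @param shaft_intensity,bouton_peak,mito_peak intensities (a.u.).
#' @param noise_sd Gaussian noise SD added to both channels (0 =
#'   noise-free render).
#' @param seed integer seed.
#' @return list with `biocytin` and `mito` intensity matrices,
#'   `shaft_mask` (logical; shaft excluding boutons, for background
#'   estimation), `pixel_size`, `axon_length`, and `truth`: data.frame
#'   `bouton` (`x_px`, `y_px`, `pos_um`, `has_mito`).
#' @export
gen_axon_boutons <- function(n_boutons = 100, frac_with_mito = 0.74,
                             axon_length = 300, pixel_size = 0.2,
                             bouton_radius_um = 0.6, shaft_intensity = 20,
                             bouton_peak = 250, mito_peak = 200,
                             noise_sd = 0, seed = 1) {
  if (n_boutons < 1) mito_stop("n_boutons must be >= 1")
  if (frac_with_mito < 0 || frac_with_mito > 1) {
    mito_stop("frac_with_mito must be in [0, 1]")
  }
  r_px <- bouton_radius_um / pixel_size
  min_sep <- 3 * r_px
  len_px <- axon_length / pixel_size
  if (n_boutons * min_sep > len_px) {
    mito_stop("boutons would overlap: ", n_boutons, " boutons need ",
              signif(n_boutons * min_sep * pixel_size, 3),
              " um of axon but only ", axon_length, " um is available")
  }
  width <- as.integer(ceiling(len_px + 8 * r_px))
  height <- as.integer(ceiling(16 * r_px))
  y0 <- (height + 1) / 2

  with_seed(seed, {
    # jittered regular spacing keeps the non-overlap guarantee
    slot <- len_px / n_boutons
    jit <- runif(n_boutons, -(slot - min_sep) / 2, (slot - min_sep) / 2)
    xs <- 4 * r_px + (seq_len(n_boutons) - 0.5) * slot + jit
    n_with <- round_half_away(frac_with_mito * n_boutons)
    has_mito <- logical(n_boutons)
    if (n_with > 0) has_mito[sample.int(n_boutons, n_with)] <- TRUE

    gx <- matrix(seq_len(width), width, height)
    gy <- matrix(rep(seq_len(height), each = width), width, height)
    bio <- matrix(0, width, height)
    shaft <- abs(gy - y0) <= max(1, r_px / 2) &
      gx >= 4 * r_px & gx <= 4 * r_px + len_px
    bio[shaft] <- shaft_intensity
    mito <- matrix(0, width, height)
    in_bouton <- matrix(FALSE, width, height)
    for (i in seq_len(n_boutons)) {
      d2 <- (gx - xs[i])^2 + (gy - y0)^2
      disc <- d2 <= r_px^2
      bio[disc] <- bouton_peak
      in_bouton <- in_bouton | disc
      if (has_mito[i]) mito[d2 <= (0.6 * r_px)^2] <- mito_peak
    }
    if (noise_sd > 0) {
      bio <- pmax(bio + matrix(rnorm(length(bio), 0, noise_sd), width), 0)
      mito <- pmax(mito + matrix(rnorm(length(mito), 0, noise_sd), width), 0)
    }
    list(
      biocytin = bio, mito = mito,
      shaft_mask = shaft & !in_bouton,
      pixel_size = pixel_size, axon_length = axon_length,
      truth = data.frame(x_px = xs, y_px = y0,
                         pos_um = (xs - 4 * r_px) * pixel_size,
                         has_mito = has_mito)
    )
  })
}
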