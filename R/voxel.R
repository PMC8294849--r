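#' Voxel stacks
#'
#' A `voxel_stack` is a 3D intensity (or logical) array together with its
#' physical calibration: `voxel_size` (um, length 3, possibly anisotropic)
#' and `origin`, the world coordinate of the center of voxel `[1, 1, 1]`.
#' Array axes map to x, y, z in that order; a voxel's position is its
#' center.
#'
#' @param data 3D array.
#' @param voxel_size voxel edge lengths in um (length 1 or 3).
#' @param origin world coordinate of the first voxel center (length 3).
#' @return object of class `voxel_stack`.
#' @export
voxel_stack <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3) mito_stop("voxel stack data must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) mito_stop("voxel_size must be positive")
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat("voxel stack", paste(dim(x$data), collapse = " x "),
      "voxels;", paste(signif(x$voxel_size, 3), collapse = " x "),
      "um/voxel\n")
  invisible(x)
}

# world coordinates (n x 3) of the voxels at the given array indices (n x 3)
voxel_centers <- function(stack, idx) {
  sweep(sweep(idx - 1, 2, stack$voxel_size, `*`), 2, stack$origin, `+`)
}

#' Fill the volume of a reconstruction into a binary voxel mask
#'
#' Generates the stack-mask of a morphology: a voxel is set when its
#' center lies inside the union of capsules swept along each parent-child
#' edge with linearly interpolated node radii (plus a sphere per node).
#' Degenerate radii are clamped to half the voxel diagonal so thin
#' neurites always capture at least the voxel centers they pass through.
#'
#' @inheritParams branch_points
#' @param voxel_size voxel size in um (length 1 or 3).
#' @param margin padding around the morphology bounding box, um.
#' @param grid optional `voxel_stack` whose dimensions, voxel size and
#'   origin define the output grid (e.g. a mitochondrial stack the mask
#'   will be ANDed with); overrides `voxel_size` and `margin`.
#' @return logical `voxel_stack`.
#' @export
fill_volume_mask <- function(morph, voxel_size = 1, margin = 2,
                             grid = NULL) {
  morph <- as_swc_morphology(morph)
  rad_src <- morph$radius
  xyz <- as.matrix(morph[, c("x", "y", "z")])
  if (!is.null(grid)) {
    if (!inherits(grid, "voxel_stack")) mito_stop("grid must be a voxel_stack")
    voxel_size <- grid$voxel_size
    dims <- dim(grid$data)
    lo <- grid$origin
  } else {
    voxel_size <- rep_len(as.numeric(voxel_size), 3)
    if (any(voxel_size <= 0)) mito_stop("voxel_size must be positive")
    rad <- pmax(rad_src, sqrt(sum(voxel_size^2)) / 2)
    lo <- apply(xyz - rad, 2, min) - margin
    hi <- apply(xyz + rad, 2, max) + margin
    dims <- pmax(1L, ceiling((hi - lo) / voxel_size) + 1L)
  }
  rad <- pmax(rad_src, sqrt(sum(voxel_size^2)) / 2)
  stk <- voxel_stack(array(FALSE, dims), voxel_size, origin = lo)
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 1) * voxel_size[d])

  paint_capsule <- function(p1, p2, r1, r2) {
    rmax <- max(r1, r2)
    bb_lo <- pmin(p1, p2) - rmax
    bb_hi <- pmax(p1, p2) + rmax
    ii <- lapply(1:3, function(d) which(ax[[d]] >= bb_lo[d] & ax[[d]] <= bb_hi[d]))
    if (any(lengths(ii) == 0)) return(invisible())
    g <- as.matrix(expand.grid(x = ax[[1]][ii[[1]]], y = ax[[2]][ii[[2]]],
                               z = ax[[3]][ii[[3]]]))
    u <- p2 - p1
    uu <- sum(u^2)
    w <- sweep(g, 2, p1)
    t <- if (uu > 0) pmin(1, pmax(0, (w %*% u) / uu)) else rep(0, nrow(g))
    d <- row_norms(w - outer(as.numeric(t), u))
    inside <- d <= r1 + as.numeric(t) * (r2 - r1)
    if (any(inside)) {
      gi <- as.matrix(expand.grid(ii[[1]], ii[[2]], ii[[3]]))[inside, , drop = FALSE]
      stk$data[gi] <<- TRUE
    }
  }

  for (i in seq_len(nrow(morph))) {
    paint_capsule(xyz[i, ], xyz[i, ], rad[i], rad[i])
  }
  e <- swc_edges(morph)
  for (k in seq_len(nrow(e))) {
    paint_capsule(xyz[e[k, "parent"], ], xyz[e[k, "child"], ],
                  rad[e[k, "parent"]], rad[e[k, "child"]])
  }
  stk
}

#' Binarize a voxel stack or image
#'
#' @param x numeric array/matrix.
#' @param method `"otsu"` (default; threshold maximizing between-class
#'   variance, 256 levels over the data range) or `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @return logical array, `x > threshold`. A constant input binarizes to
#'   all-`FALSE`.
#' @export
binarize <- function(x, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) mito_stop("fixed binarization needs a threshold value")
    return(x > value)
  }
  rng <- range(x)
  if (diff(rng) == 0) return(array(FALSE, dim(x)))
  thr <- EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)))
  (x - rng[1]) / diff(rng) > thr
}

#' MitoSholl: shell-binned mitochondrial voxel counts
#'
#' Quantifies the radial distribution of mitochondria around the soma.
#' The mitochondrial channel is preprocessed slice by slice (rolling-ball
#' background subtraction, then a median filter), binarized, combined with
#' the neuron's volume mask (logical AND so only in-cell mitochondria
#' count), and the positive voxel centers are binned into concentric
#' half-open shells `[k*step, (k+1)*step)` around `center`.
#'
#' @param stack mitochondrial intensity `voxel_stack`.
#' @param mask logical `voxel_stack` from [fill_volume_mask()] with
#'   identical dimensions and calibration, or `NULL` to skip masking.
#' @param center soma position in world coordinates (length 3).
#' @param step shell width, um (default 1 um).
#' @param rolling_ball_radius structuring-element radius for background
#'   subtraction, pixels (default 50 as used for these recordings; reduce
#'   for small synthetic stacks).
#' @param median_size half-width of the median filter window, pixels;
#'   0 disables it.
#' @param threshold,threshold_value binarization method and fixed value,
#'   see [binarize()].
#' @return `sholl_profile` data.frame: `radius_um` (shell lower bound) and
#'   `count` of positive voxels.
#' @export
mito_sholl <- function(stack, mask = NULL, center, step = 1,
                       rolling_ball_radius = 50, median_size = 1,
                       threshold = "otsu", threshold_value = NULL) {
  if (!inherits(stack, "voxel_stack")) mito_stop("stack must be a voxel_stack")
  if (!is.null(mask)) {
    if (!identical(dim(stack$data), dim(mask$data)) ||
        any(abs(stack$voxel_size - mask$voxel_size) > 1e-9)) {
      mito_stop("stack and mask dimensions/voxel sizes differ")
    }
  }
  pre <- stack$data
  for (z in seq_len(dim(pre)[3])) {
    sl <- rolling_ball_subtract(pre[, , z], rolling_ball_radius)
    if (median_size > 0 && diff(range(sl)) > 0) {
      mx <- max(sl)
      sl <- as.numeric(mx) *
        as.matrix(EBImage::medianFilter(EBImage::Image(sl / mx), median_size))
    }
    pre[, , z] <- sl
  }
  bin <- binarize(pre, threshold, threshold_value)
  if (!is.null(mask)) bin <- bin & mask$data
  shell_counts(bin, stack, center, step)
}

# bin positive voxel centers of a logical array into [k*step,(k+1)*step)
shell_counts <- function(bin, stack, center, step) {
  idx <- which(bin, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(structure(data.frame(radius_um = numeric(0), count = integer(0)),
                     class = c("sholl_profile", "data.frame"), step = step))
  }
  d <- row_norms(sweep(voxel_centers(stack, idx), 2, center))
  shell <- floor(d / step)
  radii <- seq(0, max(shell)) * step
  counts <- tabulate(shell + 1L, nbins = length(radii))
  structure(data.frame(radius_um = radii, count = counts),
            class = c("sholl_profile", "data.frame"), step = step)
}

#' Minimum branch-point-to-mitochondrion distances
#'
#' For every branch point, the Euclidean distance (um, honoring
#' anisotropic voxel size) to the nearest mitochondria-positive voxel
#' center is computed by exhaustive scan over the positive voxels. Ties
#' are irrelevant for the distance value; the reported nearest voxel is
#' the first in linear index order.
#'
#' @param branch_pts data.frame with `x`, `y`, `z` (um), e.g. from
#'   [branch_points()].
#' @param mito logical `voxel_stack` (binarized mitochondrial channel), or
#'   an intensity stack which is then binarized with Otsu.
#' @return a `proximity_result` data.frame: branch coordinates plus
#'   `min_dist_um`.
#' @export
min_branch_mito_distance <- function(branch_pts, mito) {
  if (!inherits(mito, "voxel_stack")) mito_stop("mito must be a voxel_stack")
  if (nrow(branch_pts) == 0) mito_stop("no branch points supplied")
  bin <- if (is.logical(mito$data)) mito$data else binarize(mito$data)
  idx <- which(bin, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    mito_stop("no positive voxels in the mitochondrial stack: distance undefined",
              class = "mitodyn_undefined")
  }
  pos <- voxel_centers(mito, idx)
  p <- as.matrix(branch_pts[, c("x", "y", "z")])
  d <- apply(p, 1, function(q) {
    min(sqrt((pos[, 1] - q[1])^2 + (pos[, 2] - q[2])^2 + (pos[, 3] - q[3])^2))
  })
  structure(data.frame(branch_pts[, c("x", "y", "z")], min_dist_um = d),
            class = c("proximity_result", "data.frame"))
}

#' Normalize proximity distances to a reference group
#'
#' Divides every group's distances by the mean of the reference group, so
#' the reference group has normalized mean exactly 1 (arbitrary units);
#' this is how between-genotype proximity is compared.
#'
#' @param groups named list of numeric distance vectors or
#'   `proximity_result` objects, one per experimental group.
#' @param reference name (or index) of the reference group.
#' @return named list of numeric vectors of normalized distances.
#' @export
normalize_distances <- function(groups, reference = 1) {
  vals <- lapply(groups, function(g) {
    if (inherits(g, "proximity_result")) g$min_dist_um else as.numeric(g)
  })
  ref_mean <- mean(vals[[reference]])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    mito_stop("reference group mean must be positive")
  }
  lapply(vals, function(v) v / ref_mean)
}

#' Probability of a mitochondrion within a radius of a branch point
#'
#' @param result `proximity_result` or numeric vector of minimum
#'   distances, um.
#' @param r radius, um (default 1 um).
#' @return fraction of branch points whose nearest mitochondrion lies
#'   within `r` um.
#' @export
prob_within_radius <- function(result, r = 1) {
  d <- if (inherits(result, "proximity_result")) result$min_dist_um else result
  mean(d <= r)
}
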