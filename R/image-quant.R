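#' Rolling-ball background subtraction
#'
#' Estimates a slowly varying background as the grayscale morphological
#' opening of the image with a disc structuring element of the given
#' radius (the flat-disc formulation of the rolling-ball algorithm) and
#' subtracts it. Features smaller than the disc survive with their height
#' intact; a flat image maps to zeros and the result is never negative.
#'
#' @param image numeric matrix.
#' @param radius structuring-element radius, pixels (>= 1).
#' @return background-subtracted matrix of the same shape.
#' @export
rolling_ball_subtract <- function(image, radius = 50) {
  if (radius < 1) mito_stop("radius must be >= 1")
  rng <- range(image)
  if (diff(rng) == 0) return(array(0, dim(image)))
  # EBImage grayscale morphology works on [0,1]
  norm <- (image - rng[1]) / diff(rng)
  side <- 2 * as.integer(radius) + 1
  if (side >= min(dim(image))) {
    # SE larger than the image: the opening degenerates to the global min
    bg <- 0
  } else {
    brush <- EBImage::makeBrush(side, shape = "disc")
    bg <- as.matrix(EBImage::opening(EBImage::Image(norm), brush))
  }
  pmax((norm - bg) * diff(rng), 0)
}

#' Mean intensity within a region mask
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same shape (the region of interest).
#' @return mean of the in-mask intensities (a.u.).
#' @export
region_mean_intensity <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) mito_stop("image and mask shapes differ")
  if (!any(mask)) mito_stop("mask is empty")
  mean(image[mask])
}

#' Percent mitochondrial area within the soma
#'
#' @param mito_mask,soma_mask logical matrices of identical shape.
#' @return percentage `100 * |mito & soma| / |soma|`.
#' @export
soma_mito_area_fraction <- function(mito_mask, soma_mask) {
  if (!identical(dim(mito_mask), dim(soma_mask))) {
    mito_stop("masks must have the same shape")
  }
  if (!any(soma_mask)) mito_stop("soma mask is empty")
  100 * sum(mito_mask & soma_mask) / sum(soma_mask)
}

#' Detect a dominant perinuclear mitochondrial cluster
#'
#' A soma is scored as containing a mitochondrial cluster when the largest
#' connected component of the in-soma mitochondrial mask holds at least
#' `dominance` of the total in-soma mitochondrial area. Somata without
#' mitochondria score `FALSE`.
#'
#' @inheritParams soma_mito_area_fraction
#' @param dominance required area share of the largest component (default
#'   0.5).
#' @return logical.
#' @export
detect_soma_cluster <- function(mito_mask, soma_mask, dominance = 0.5) {
  if (!identical(dim(mito_mask), dim(soma_mask))) {
    mito_stop("masks must have the same shape")
  }
  m <- mito_mask & soma_mask
  if (!any(m)) return(FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  areas <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  max(areas) >= dominance * sum(m)
}

#' Detect fluorescent puncta (boutons) in a 2D image
#'
#' Thresholds the image, labels connected components and keeps those whose
#' calibrated area falls within `[min_area, max_area]` um^2; merged blobs
#' above `max_area` are excluded. Per punctum the centroid, area and the
#' mean intensity in any number of additional co-registered channels are
#' reported.
#'
#' @param image numeric matrix (detection channel, e.g. biocytin).
#' @param pixel_size um per pixel.
#' @param min_area,max_area punctum area bounds, um^2 (defaults 0.2-3,
#'   typical presynaptic bouton sizes).
#' @param threshold,threshold_value see [binarize()].
#' @param channels named list of additional intensity matrices to sample
#'   within each punctum.
#' @return a `puncta_set` data.frame (`id`, `x_px`, `y_px`, `area_um2`,
#'   `mean_<channel>` columns) with the label matrix in attribute
#'   `labels` and `pixel_size` attached. May be empty.
#' @export
detect_puncta <- function(image, pixel_size, min_area = 0.2, max_area = 3,
                          threshold = "otsu", threshold_value = NULL,
                          channels = list()) {
  if (pixel_size <= 0) mito_stop("pixel_size must be positive")
  bin <- binarize(image, threshold, threshold_value)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bin * 1)))
  n <- max(lab)
  empty <- structure(
    data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
               area_um2 = numeric(0)),
    class = c("puncta_set", "data.frame"), labels = lab,
    pixel_size = pixel_size
  )
  if (n == 0) return(empty)
  px_area <- pixel_size^2
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  area <- tabulate(comp, n) * px_area
  keep <- which(area >= min_area & area <= max_area)
  if (!length(keep)) return(empty)
  out <- data.frame(
    id = seq_along(keep),
    x_px = tapply(rows, comp, mean)[keep],
    y_px = tapply(cols, comp, mean)[keep],
    area_um2 = area[keep]
  )
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch), dim(image))) mito_stop("channel ", nm, " shape differs")
    out[[paste0("mean_", nm)]] <- tapply(ch[idx], comp, mean)[keep]
  }
  relabel <- array(0L, dim(lab))
  for (j in seq_along(keep)) relabel[lab == keep[j]] <- j
  rownames(out) <- NULL
  structure(out, class = c("puncta_set", "data.frame"), labels = relabel,
            pixel_size = pixel_size)
}

#' Bouton density along the axon
#'
#' @param puncta a `puncta_set` (or anything with `nrow`).
#' @param axon_path_length axon path length, um (> 0).
#' @return boutons per 10 um of axon.
#' @export
bouton_occupancy <- function(puncta, axon_path_length) {
  if (axon_path_length <= 0) mito_stop("axon_path_length must be positive")
  10 * nrow(puncta) / axon_path_length
}

#' Mitochondrial content of detected boutons
#'
#' A bouton "contains" mitochondria when its mean intensity in the
#' mitochondrial channel exceeds a criterion. The default criterion is the
#' axon-shaft background mean plus two standard deviations in that
#' channel, a reproducible surrogate for visual punctum scoring; a fixed
#' numeric criterion may be supplied instead.
#'
#' @param puncta `puncta_set` from [detect_puncta()].
#' @param mito_image mitochondrial channel, co-registered with the
#'   detection image.
#' @param shaft_mask logical matrix marking shaft (non-bouton) axon pixels
#'   used to estimate background; required for the default criterion.
#' @param criterion `"shaft_mean_2sd"` or a numeric intensity threshold.
#' @return list: `fraction_containing` (percent), `contains` (logical per
#'   bouton), `mean_mito` (per-bouton mean intensity), `criterion` (the
#'   effective threshold).
#' @export
bouton_mito_content <- function(puncta, mito_image, shaft_mask = NULL,
                                criterion = "shaft_mean_2sd") {
  if (nrow(puncta) == 0) mito_stop("no puncta supplied")
  lab <- attr(puncta, "labels")
  if (is.null(lab) || !identical(dim(lab), dim(mito_image))) {
    mito_stop("puncta labels missing or not co-registered with mito_image")
  }
  idx <- which(lab > 0)
  mean_mito <- as.numeric(tapply(mito_image[idx], lab[idx], mean))
  if (identical(criterion, "shaft_mean_2sd")) {
    if (is.null(shaft_mask) || !any(shaft_mask)) {
      mito_stop("the shaft_mean_2sd criterion needs a non-empty shaft_mask")
    }
    bg <- mito_image[shaft_mask & lab == 0]
    criterion <- mean(bg) + 2 * sd(bg)
    if (is.na(criterion)) criterion <- mean(bg)
  }
  contains <- mean_mito > criterion
  list(fraction_containing = 100 * mean(contains), contains = contains,
       mean_mito = mean_mito, criterion = criterion)
}

#' Object-level pre/post synaptic colocalization
#'
#' Reimplements object-based synaptic marker colocalization: each channel
#' is background-subtracted (rolling ball), maximum-filtered, Otsu
#' thresholded and labeled; a pre/post object pair counts as colocalized
#' when their overlap area is 33-100% of the smaller object's area.
#' Many-to-many candidate matches are reduced to one-to-one pairs
#' greedily by descending overlap fraction, so the pair count never
#' exceeds the smaller object count.
#'
#' @param pre_image,post_image numeric matrices of identical shape
#'   (presynaptic and postsynaptic marker channels).
#' @param rolling_ball_radius background-subtraction radius, pixels
#'   (default 7).
#' @param max_filter_size maximum-filter radius, pixels (default 1, i.e. a
#'   3x3 window); 0 disables.
#' @param overlap_range accepted overlap fraction range (default
#'   `c(0.33, 1)`).
#' @return list: `pre_count`, `post_count`, `colocalized`, and `pairs`
#'   (data.frame of matched label pairs with overlap fractions).
#' @export
synapse_colocalization <- function(pre_image, post_image,
                                   rolling_ball_radius = 7,
                                   max_filter_size = 1,
                                   overlap_range = c(0.33, 1)) {
  if (!identical(dim(pre_image), dim(post_image))) {
    mito_stop("images must have the same shape")
  }
  seg <- function(img) {
    x <- rolling_ball_subtract(img, rolling_ball_radius)
    if (max_filter_size > 0 && diff(range(x)) > 0) {
      mx <- max(x)
      brush <- EBImage::makeBrush(2 * max_filter_size + 1, "box")
      x <- mx * as.matrix(EBImage::dilate(EBImage::Image(x / mx), brush))
    }
    as.matrix(EBImage::bwlabel(EBImage::Image(binarize(x) * 1)))
  }
  pre <- seg(pre_image)
  post <- seg(post_image)
  n_pre <- max(pre)
  n_post <- max(post)
  both <- pre > 0 & post > 0
  if (!any(both) || n_pre == 0 || n_post == 0) {
    return(list(pre_count = n_pre, post_count = n_post, colocalized = 0L,
                pairs = data.frame(pre = integer(0), post = integer(0),
                                   overlap = numeric(0))))
  }
  area_pre <- tabulate(pre[pre > 0], n_pre)
  area_post <- tabulate(post[post > 0], n_post)
  ov <- table(pre = pre[both], post = post[both])
  cand <- as.data.frame(ov, stringsAsFactors = FALSE)
  cand <- cand[cand$Freq > 0, ]
  cand$pre <- as.integer(cand$pre)
  cand$post <- as.integer(cand$post)
  cand$overlap <- cand$Freq / pmin(area_pre[cand$pre], area_post[cand$post])
  cand <- cand[cand$overlap >= overlap_range[1] &
                 cand$overlap <= overlap_range[2], ]
  cand <- cand[order(-cand$overlap), ]
  used_pre <- logical(n_pre)
  used_post <- logical(n_post)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_pre[cand$pre[i]] && !used_post[cand$post[i]]) {
      keep[i] <- TRUE
      used_pre[cand$pre[i]] <- TRUE
      used_post[cand$post[i]] <- TRUE
    }
  }
  pairs <- cand[keep, c("pre", "post", "overlap")]
  rownames(pairs) <- NULL
  list(pre_count = n_pre, post_count = n_post,
       colocalized = sum(keep), pairs = pairs)
}
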