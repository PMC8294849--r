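compartment_types <- function(compartment = c("all", "axon", "dendrite")) {
  switch(match.arg(compartment),
         all = 0:7, axon = 2L, dendrite = 3L)
}

#' Branch points of a reconstruction
#'
#' A branch point is a non-soma node with two or more children. Nodes with
#' more than two children count once (branch points are counted, not
#' bifurcations). The compartment filter applies to the type of the branch
#' node itself.
#'
#' @param morph an `swc_morphology`.
#' @param compartment `"all"`, `"axon"` (type 2) or `"dendrite"` (type 3).
#' @return data.frame of branch points: `id`, `type`, `x`, `y`, `z`.
#' @export
branch_points <- function(morph, compartment = "all") {
  morph <- as_swc_morphology(morph)
  counts <- swc_child_counts(morph)
  sel <- counts >= 2 & morph$type != 1 &
    morph$type %in% compartment_types(compartment)
  out <- as.data.frame(morph)[sel, c("id", "type", "x", "y", "z")]
  rownames(out) <- NULL
  out
}

#' Number of processes (unbranched segments)
#'
#' Processes are the edges of the condensed tree whose vertices are the
#' root, the branching nodes (>= 2 children) and the tips: every maximal
#' unbranched chain counts once.
#'
#' @inheritParams branch_points
#' @return integer count.
#' @export
count_processes <- function(morph) {
  morph <- as_swc_morphology(morph)
  counts <- swc_child_counts(morph)
  root <- morph$parent == -1
  condensed <- root | counts >= 2 | counts == 0
  sum(condensed) - 1L
}

#' Total neurite length per compartment
#'
#' Sum of parent-child Euclidean distances; each edge is assigned to the
#' compartment of its child node, so axonal and dendritic totals add up to
#' the whole-cell total when the soma is a single node.
#'
#' @inheritParams branch_points
#' @return length in um.
#' @export
total_length <- function(morph, compartment = "all") {
  morph <- as_swc_morphology(morph)
  e <- swc_edges(morph)
  if (nrow(e) == 0) return(0)
  keep <- morph$type[e[, "child"]] %in% compartment_types(compartment)
  p <- as.matrix(morph[e[keep, "parent"], c("x", "y", "z")])
  c2 <- as.matrix(morph[e[keep, "child"], c("x", "y", "z")])
  sum(row_norms(c2 - p))
}

#' 3D Sholl analysis of a reconstruction
#'
#' Counts intersections between the neurites and concentric spheres
#' centered on the soma root, at radii `step, 2*step, ...`. Crossings are
#' computed analytically per edge: the number of simple roots of
#' `|p(t)| = R` along the segment, so an edge dipping in and out of a
#' sphere contributes two crossings. Tangencies (double roots) contribute
#' zero.
#'
#' @inheritParams branch_points
#' @param step sphere spacing, um.
#' @param center Sholl center; defaults to the root (soma) node coordinate.
#' @param max_radius largest radius; defaults to the maximal node distance.
#' @return a `sholl_profile`: data.frame `radius_um`, `crossings`.
#' @export
sholl_intersections <- function(morph, compartment = "all", step = 1,
                                center = NULL, max_radius = NULL) {
  morph <- as_swc_morphology(morph)
  if (step <= 0) mito_stop("step must be positive")
  root <- which(morph$parent == -1)
  if (is.null(center)) center <- as.numeric(morph[root, c("x", "y", "z")])
  xyz <- sweep(as.matrix(morph[, c("x", "y", "z")]), 2, center)
  if (is.null(max_radius)) max_radius <- max(row_norms(xyz))
  radii <- seq(step, by = step, length.out = max(0, floor(max_radius / step)))
  e <- swc_edges(morph)
  keep <- morph$type[e[, "child"]] %in% compartment_types(compartment)
  e <- e[keep, , drop = FALSE]
  counts <- integer(length(radii))
  if (nrow(e)) {
    a <- xyz[e[, "parent"], , drop = FALSE]
    u <- xyz[e[, "child"], , drop = FALSE] - a
    c2 <- rowSums(u^2)
    c1 <- 2 * rowSums(a * u)
    a2 <- rowSums(a^2)
    for (k in seq_along(radii)) {
      counts[k] <- sum(segment_sphere_crossings(c2, c1, a2 - radii[k]^2))
    }
  }
  structure(data.frame(radius_um = radii, crossings = counts),
            class = c("sholl_profile", "data.frame"), step = step)
}

# number of simple roots of c2 t^2 + c1 t + c0 = 0 in (0, 1], vectorized
# over segments; degenerate (point) segments contribute 0
segment_sphere_crossings <- function(c2, c1, c0) {
  n <- integer(length(c2))
  ok <- c2 > 0
  disc <- c1^2 - 4 * c2 * c0
  pos <- ok & disc > 0
  if (any(pos)) {
    sq <- sqrt(disc[pos])
    t1 <- (-c1[pos] - sq) / (2 * c2[pos])
    t2 <- (-c1[pos] + sq) / (2 * c2[pos])
    n[pos] <- (t1 > 0 & t1 <= 1) + (t2 > 0 & t2 <= 1)
  }
  n
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat("Sholl profile:", nrow(x), "shells, step",
      attr(x, "step"), "um; total", sum(x[[2]]), "\n")
  invisible(x)
}
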