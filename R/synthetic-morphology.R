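#' Generate a synthetic neuronal reconstruction (SWC tree)
#'
#' Builds a valid SWC morphology with one soma node at the origin, one
#' axonal and one dendritic neurite, and exactly the requested number of
#' branch points per compartment. Each topological segment is a chain of
#' nodes with ~`node_spacing` um spacing and a smoothly drifting 3D
#' direction; branch points are created by picking a random open tip and
#' splitting it into two daughter segments.
#'
#' @param n_branch_axon,n_branch_dend number of branch points to create in
#'   the axon (SWC type 2) and dendrite (type 3); >= 0.
#' @param segment_len two-element range of topological segment lengths, um.
#' @param node_spacing approximate node-to-node spacing within a segment,
#'   um.
#' @param neurite_radius node radius for neurites, um.
#' @param seed integer seed.
#' @return `swc_morphology` with attribute `truth`: a list with
#'   `n_branch_axon` and `n_branch_dend`.
#' @examples
#' m <- gen_morphology(5, 3, seed = 1)
#' nrow(branch_points(m, "axon"))
#' @export
gen_morphology <- function(n_branch_axon = 5, n_branch_dend = 5,
                           segment_len = c(8, 15), node_spacing = 2,
                           neurite_radius = 0.4, seed = 1) {
  if (n_branch_axon < 0 || n_branch_dend < 0) {
    mito_stop("branch counts must be >= 0")
  }
  with_seed(seed, {
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = 5, parent = -1L)
    next_id <- 2L

    grow_segment <- function(parent_id, origin, dir, type) {
      len <- runif(1, segment_len[1], segment_len[2])
      k <- max(2L, ceiling(len / node_spacing))
      step <- len / k
      pos <- origin
      for (j in seq_len(k)) {
        dir <- dir + rnorm(3, 0, 0.15)
        dir <- dir / sqrt(sum(dir^2))
        pos <- pos + dir * step
        nodes[nrow(nodes) + 1L, ] <<- list(next_id, type, pos[1], pos[2],
                                           pos[3], neurite_radius, parent_id)
        parent_id <- next_id
        next_id <<- next_id + 1L
      }
      list(tip = parent_id, pos = pos, dir = dir)
    }

    grow_neurite <- function(type, n_branch, base_dir) {
      stem <- grow_segment(1L, c(0, 0, 0), base_dir, type)
      tips <- list(stem)
      for (b in seq_len(n_branch)) {
        i <- sample.int(length(tips), 1)
        t0 <- tips[[i]]
        tips[[i]] <- NULL
        for (s in c(-1, 1)) {
          ang <- s * runif(1, 0.3, 0.8)
          rot <- matrix(c(cos(ang), -sin(ang), 0,
                          sin(ang), cos(ang), 0,
                          0, 0, 1), 3, 3, byrow = TRUE)
          tips[[length(tips) + 1L]] <-
            grow_segment(t0$tip, t0$pos, as.numeric(rot %*% t0$dir), type)
        }
      }
    }

    grow_neurite(2L, n_branch_axon, c(1, 0, 0.1) / sqrt(1.01))
    grow_neurite(3L, n_branch_dend, c(-1, 0, -0.1) / sqrt(1.01))

    m <- as_swc_morphology(nodes)
    attr(m, "truth") <- list(n_branch_axon = n_branch_axon,
                             n_branch_dend = n_branch_dend)
    m
  })
}
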