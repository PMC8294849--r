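#' Read a neuronal reconstruction from an SWC file
#'
#' Parses the standard 7-column SWC format (node id, type, x, y, z, radius,
#' parent id; '#' comments). Invariants are enforced on read: exactly one
#' root (parent -1), every parent listed before its children, known type
#' codes (0-7), finite coordinates, no cycles or orphans.
#'
#' @param path SWC file path.
#' @return an object of class `swc_morphology`: a data.frame with columns
#'   `id`, `type`, `x`, `y`, `z`, `radius`, `parent`.
#' @export
read_swc <- function(path) {
  raw <- tryCatch(
    read.table(path, comment.char = "#",
               col.names = c("id", "type", "x", "y", "z", "radius", "parent")),
    error = function(e) mito_stop("cannot parse SWC file ", path, ": ",
                                  conditionMessage(e))
  )
  as_swc_morphology(raw)
}

#' Construct and validate an `swc_morphology`
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @return validated `swc_morphology`.
#' @export
as_swc_morphology <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    mito_stop("morphology needs columns ", paste(need, collapse = ", "))
  }
  nodes <- nodes[, need]
  if (anyDuplicated(nodes$id)) mito_stop("duplicate node ids in SWC")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) {
    mito_stop("SWC must have exactly one root (parent -1), found ",
              length(roots))
  }
  if (!all(nodes$type %in% 0:7)) {
    bad <- which(!(nodes$type %in% 0:7))[1]
    mito_stop("unknown SWC type code at line ", bad, ": ", nodes$type[bad])
  }
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z", "radius")])))) {
    mito_stop("non-finite coordinates or radii in SWC")
  }
  pidx <- match(nodes$parent, nodes$id)
  orphan <- which(nodes$parent != -1 & is.na(pidx))
  if (length(orphan)) {
    mito_stop("orphan node at line ", orphan[1], ": parent ",
              nodes$parent[orphan[1]], " not present")
  }
  before <- which(nodes$parent != -1 & pidx >= seq_len(nrow(nodes)))
  if (length(before)) {
    mito_stop("parent must precede child: violated at line ", before[1])
  }
  structure(nodes, class = c("swc_morphology", "data.frame"))
}

#' @rdname read_swc
#' @param morph an `swc_morphology`.
#' @export
write_swc <- function(morph, path) {
  morph <- as_swc_morphology(morph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by mitodyn (id type x y z radius parent)", con)
  write.table(as.data.frame(morph), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.swc_morphology <- function(x, ...) {
  cat("SWC morphology:", nrow(x), "nodes;",
      sum(x$type == 2), "axonal,", sum(x$type == 3), "dendritic\n")
  invisible(x)
}

# index of parent row for each node (NA for root)
swc_parent_index <- function(morph) match(morph$parent, morph$id)

# number of children per node (aligned with rows of morph)
swc_child_counts <- function(morph) {
  pidx <- swc_parent_index(morph)
  counts <- integer(nrow(morph))
  t <- table(pidx[!is.na(pidx)])
  counts[as.integer(names(t))] <- as.integer(t)
  counts
}

# edges as (parent row index, child row index); one row per non-root node
swc_edges <- function(morph) {
  pidx <- swc_parent_index(morph)
  child <- which(!is.na(pidx))
  cbind(parent = pidx[child], child = child)
}
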