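#' Polyline skeleton tree
#'
#' The bridge between the mesh and graph worlds: an indexed set of 3D points
#' (nm), undirected parent/child edges, a per-point radius (nm, filled in by
#' [mesh_correspondence()]) and the index of the root (soma) point when known.
#'
#' @param points numeric P x 3 matrix, nm.
#' @param edges integer E x 2 matrix of point indices.
#' @param radius numeric length-P vector of radii (nm); `NA` when unknown.
#' @param root integer index of the root point, or `NA`.
#' @return an object of class `neuro_skeleton`.
#' @export
neuro_skeleton <- function(points, edges, radius = rep(NA_real_, nrow(points)),
                           root = NA_integer_) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  if (nrow(edges) > 0) {
    len <- sqrt(rowSums((points[edges[, 1], , drop = FALSE] -
                           points[edges[, 2], , drop = FALSE])^2))
    if (any(len <= 0)) stop("neuro_skeleton: zero-length edge")
  }
  structure(list(points = points, edges = edges,
                 radius = as.numeric(radius), root = as.integer(root)),
            class = "neuro_skeleton")
}

#' @export
print.neuro_skeleton <- function(x, ...) {
  cat(sprintf("<neuro_skeleton> %d points, %d edges, length %.1f um%s\n",
              nrow(x$points), nrow(x$edges),
              skeleton_length(x) / 1000,
              if (isTRUE(attr(x, "degenerate"))) " (degenerate)" else ""))
  invisible(x)
}

#' Total skeletal length (nm)
#' @param skel a [neuro_skeleton()].
#' @return sum of edge lengths in nm.
#' @export
skeleton_length <- function(skel) {
  if (nrow(skel$edges) == 0) return(0)
  sum(sqrt(rowSums((skel$points[skel$edges[, 1], , drop = FALSE] -
                      skel$points[skel$edges[, 2], , drop = FALSE])^2)))
}

skeleton_graph <- function(skel) {
  g <- igraph::graph_from_edgelist(skel$edges, directed = FALSE)
  np <- nrow(skel$points)
  if (igraph::vcount(g) < np)
    g <- igraph::add_vertices(g, np - igraph::vcount(g))
  if (nrow(skel$edges) > 0)
    igraph::E(g)$weight <-
      sqrt(rowSums((skel$points[skel$edges[, 1], , drop = FALSE] -
                      skel$points[skel$edges[, 2], , drop = FALSE])^2))
  g
}

skeleton_degrees <- function(skel) {
  tabulate(c(skel$edges), nbins = nrow(skel$points))
}

# Per-point arc distance to the root along the tree.
skeleton_root_distance <- function(skel) {
  g <- skeleton_graph(skel)
  as.numeric(igraph::distances(g, v = skel$root)[1, ])
}
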