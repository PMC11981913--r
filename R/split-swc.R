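# Multi-soma splitting and SWC export/import.

#' Split a multi-soma skeleton into per-soma graphs
#'
#' For every soma pair the unique skeleton path between the two root points
#' is scored edge by edge with a suspicion score -- a weighted sum of the
#' (inverted, normalised) width minimum, the local double-back angle, and the
#' outgoing-synapse-fraction mismatch of the two sides -- and cut at the most
#' suspicious edge.  Each soma keeps its side; every cut is logged as an
#' edit record.
#'
#' @param skeleton a [neuro_skeleton()] whose attr `roots` names one root
#'   point per soma (as produced by [skeletonize()] with multiple somas).
#' @param somas list of soma detections, same order as the roots.
#' @param correspondence optional [mesh_correspondence()] result.
#' @param synapses optional synapse tibble (`x`,`y`,`z`,`direction`).
#' @param weights suspicion-score weights `c(width=, angle=, class=)`.
#' @return list with `graphs` (list of `neuro_decomp`, one per soma) and
#'   `cuts` (tibble of cut records).
#' @export
split_multi_soma <- function(skeleton, somas, correspondence = NULL,
                             synapses = NULL,
                             weights = c(width = 0.5, angle = 0.3,
                                         class = 0.2)) {
  roots <- attr(skeleton, "roots")
  if (is.null(roots)) roots <- skeleton$root
  k <- length(roots)
  if (k < 2) {
    warning("split_multi_soma: fewer than two somas; returning the single graph")
    g1 <- decompose(skeleton, correspondence, somas[[1]], synapses)
    return(list(graphs = list(g1), cuts = tibble::tibble()))
  }
  pts <- skeleton$points
  width <- if (!is.null(correspondence)) correspondence$width else
    2 * ifelse(is.na(skeleton$radius), 0, skeleton$radius)
  g <- skeleton_graph(skeleton)
  removed <- rep(FALSE, nrow(skeleton$edges))
  edge_key <- paste(pmin(skeleton$edges[, 1], skeleton$edges[, 2]),
                    pmax(skeleton$edges[, 1], skeleton$edges[, 2]))
  cuts <- list()

  syn_vertex <- NULL
  if (!is.null(synapses) && nrow(synapses) > 0) {
    spos <- as.matrix(synapses[, c("x", "y", "z")])
    # nearest skeleton vertex per synapse
    syn_vertex <- vapply(seq_len(nrow(spos)), function(i)
      which.min(dist_to_point(pts, spos[i, ])), integer(1))
  }

  for (j in 2:k) {
    ga <- igraph::subgraph_from_edges(
      g, igraph::E(g)[!removed], delete.vertices = FALSE)
    sp <- suppressWarnings(
      igraph::shortest_paths(ga, from = roots[1], to = roots[j],
                             output = "vpath"))$vpath[[1]]
    path <- as.integer(sp)
    if (length(path) < 2) next  # somas not connected (or already cut)
    m <- length(path) - 1
    # arc position of every path vertex
    arc <- c(0, cumsum(sqrt(rowSums(
      (pts[path[-1], , drop = FALSE] -
         pts[path[-length(path)], , drop = FALSE])^2))))
    # width term: low width => suspicious
    we <- pmin(width[path[-1]], width[path[-length(path)]])
    rngw <- range(we, finite = TRUE)
    w_term <- if (diff(rngw) > 0) 1 - (we - rngw[1]) / diff(rngw) else
      rep(0.5, m)
    # angle term: local double-back at the edge
    a_term <- vapply(seq_len(m), function(i) {
      i0 <- max(1, i - 3); i1 <- min(length(path), i + 4)
      din <- pts[path[i], ] - pts[path[i0], ]
      dout <- pts[path[i1], ] - pts[path[min(i + 1, length(path))], ]
      ang <- angle_deg(din, dout)
      if (is.na(ang)) 0 else ang / 180
    }, numeric(1))
    # class-mismatch term: outgoing-synapse fraction contrast between local
    # windows on either side of the candidate edge.  Only synapses lying
    # spatially on the path corridor count, so synapses of side arbors do
    # not masquerade as path character.
    c_term <- rep(0, m)
    if (!is.null(synapses) && nrow(synapses) > 0) {
      spos <- as.matrix(synapses[, c("x", "y", "z")])
      nnp <- nearest_segment(spos, pts[path[-length(path)], , drop = FALSE],
                             pts[path[-1], , drop = FALSE])
      near <- nnp$dist <= 5000
      if (sum(near) >= 6) {
        syn_arc <- arc[nnp$seg] +
          nnp$t * (arc[nnp$seg + 1] - arc[nnp$seg])
        out <- synapses$direction == "outgoing"
        window <- 20000
        c_term <- vapply(seq_len(m), function(i) {
          a_side <- near & syn_arc >= arc[i] - window & syn_arc <= arc[i]
          b_side <- near & syn_arc > arc[i + 1] &
            syn_arc <= arc[i + 1] + window
          if (sum(a_side) < 3 || sum(b_side) < 3) return(0)
          abs(mean(out[a_side]) - mean(out[b_side]))
        }, numeric(1))
      }
    }
    score <- weights["width"] * w_term + weights["angle"] * a_term +
      weights["class"] * c_term
    # a cut right next to either soma is degenerate (it keeps essentially
    # nothing of the other cell); push candidates out of a proximal buffer
    buffer <- 10000
    proximal <- arc[-length(arc)] < buffer | arc[-1] > arc[length(arc)] - buffer
    if (!all(proximal)) score[proximal] <- score[proximal] - 1
    best <- which.max(score)
    e_cut <- c(path[best], path[best + 1])
    row <- match(paste(min(e_cut), max(e_cut)), edge_key)
    removed[row] <- TRUE
    cuts[[length(cuts) + 1]] <- tibble::tibble(
      rule = "multi_soma_split",
      soma_a = 1L, soma_b = j,
      cut_x = mean(pts[e_cut, 1]), cut_y = mean(pts[e_cut, 2]),
      cut_z = mean(pts[e_cut, 3]),
      score = score[best], width_term = w_term[best],
      angle_term = a_term[best], class_term = c_term[best])
  }

  keep_rows <- which(!removed)
  sk_cut <- neuro_skeleton(pts, skeleton$edges[keep_rows, , drop = FALSE],
                           skeleton$radius, root = skeleton$root)
  gcut <- skeleton_graph(sk_cut)
  memb <- igraph::components(gcut)$membership
  graphs <- vector("list", k)
  for (i in seq_len(k)) {
    keep_v <- which(memb == memb[roots[i]])
    remap <- match(seq_len(nrow(pts)), keep_v)
    er <- keep_rows[memb[skeleton$edges[keep_rows, 1]] == memb[roots[i]]]
    sub_edges <- cbind(remap[skeleton$edges[er, 1]],
                       remap[skeleton$edges[er, 2]])
    sk_i <- neuro_skeleton(pts[keep_v, , drop = FALSE], sub_edges,
                           skeleton$radius[keep_v],
                           root = remap[roots[i]])
    attr(sk_i, "roots") <- remap[roots[i]]
    corr_i <- NULL
    if (!is.null(correspondence)) {
      fe <- match(correspondence$face_edge, er)
      corr_i <- list(face_edge = fe, face_dist = correspondence$face_dist,
                     width = correspondence$width[keep_v])
    }
    syn_i <- NULL
    if (!is.null(synapses) && nrow(synapses) > 0) {
      near_v <- syn_vertex
      syn_i <- synapses[memb[near_v] == memb[roots[i]], , drop = FALSE]
    }
    graphs[[i]] <- decompose(sk_i, corr_i, somas[[i]], syn_i)
  }
  list(graphs = graphs,
       cuts = if (length(cuts)) dplyr::bind_rows(cuts) else tibble::tibble())
}

SWC_TYPE_CODES <- c(soma = 1L, axon = 2L, AIS = 2L, basal = 3L,
                    apical = 4L, oblique = 4L)

#' Export a decomposition graph as SWC text
#'
#' Standard NeuroMorpho-style SWC: space-separated columns
#' `id type x y z radius parent`, coordinates and radii in micrometres,
#' `#` comments, ids contiguous from 1, root parent -1.  Type codes:
#' 1 soma, 2 axon (and AIS), 3 basal dendrite, 4 apical/oblique dendrite,
#' 0 undefined.
#'
#' @param graph a `neuro_decomp` (single root).
#' @param path optional file path; when `NULL` the SWC text is returned as a
#'   character vector.
#' @return invisibly the SWC lines (written to `path` when given).
#' @export
export_swc <- function(graph, path = NULL) {
  if (!inherits(graph, "neuro_decomp")) stop("export_swc needs a neuro_decomp")
  rows <- list()
  rows[[1]] <- data.frame(
    id = 1L, type = 1L,
    x = graph$root$center[1], y = graph$root$center[2],
    z = graph$root$center[3],
    radius = graph$root$radius, parent = -1L)
  next_id <- 2L
  # last emitted SWC id of each branch's terminal point
  branch_tail <- integer(length(graph$branches))
  ord <- graph$edges[order(graph$edges$parent, graph$edges$child), ]
  for (i in seq_len(nrow(ord))) {
    b <- graph$branches[[ord$child[i]]]
    ty <- SWC_TYPE_CODES[b$compartment]
    ty <- if (is.null(ty) || is.na(ty)) 0L else as.integer(ty)
    parent_swc <- if (b$parent == 0L) 1L else branch_tail[b$parent]
    from <- if (b$parent == 0L) 1L else 2L  # skip shared junction point
    idx <- seq(from, nrow(b$points))
    n <- length(idx)
    ids <- next_id:(next_id + n - 1L)
    rows[[length(rows) + 1]] <- data.frame(
      id = ids, type = ty,
      x = b$points[idx, 1], y = b$points[idx, 2], z = b$points[idx, 3],
      radius = b$width[idx] / 2, parent = c(parent_swc, ids[-n]))
    branch_tail[b$id] <- ids[n]
    next_id <- next_id + n
  }
  tab <- do.call(rbind, rows)
  lines <- c("# id type x y z radius parent (um)",
             sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                     tab$id, tab$type, tab$x / 1000, tab$y / 1000,
                     tab$z / 1000, tab$radius / 1000, tab$parent))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read an SWC file
#'
#' @param path file path or character vector of SWC lines.
#' @return tibble with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent` -- coordinates converted to nm -- plus attr `total_length_nm`.
#' @export
read_swc <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- matrix(scan(text = paste(lines, collapse = "\n"), quiet = TRUE),
              ncol = 7, byrow = TRUE)
  tab <- tibble::tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3] * 1000, y = m[, 4] * 1000, z = m[, 5] * 1000,
    radius = m[, 6] * 1000, parent = as.integer(m[, 7]))
  has_par <- tab$parent > 0
  pi <- match(tab$parent[has_par], tab$id)
  seg <- sqrt((tab$x[has_par] - tab$x[pi])^2 +
                (tab$y[has_par] - tab$y[pi])^2 +
                (tab$z[has_par] - tab$z[pi])^2)
  attr(tab, "total_length_nm") <- sum(seg)
  tab
}
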