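# Soma-rooted graph decomposition: the skeleton is cut at the soma surface
# and at every branch point; each maximal non-branching path becomes one
# node (Branch) carrying its sub-polyline, width profile, mesh faces and
# synapses, with directed edges pointing away from the soma.

#' Soma-rooted decomposition graph
#'
#' @description
#' `decompose()` turns a skeleton (plus optional mesh correspondence, soma
#' detection and synapse table) into a `neuro_decomp`: the soma is the
#' singular root node, every non-branching skeleton segment is one branch
#' node, and directed edges run downstream away from the soma.  Any skeleton
#' cycle is broken at the cycle edge farthest from the root (logged).
#' Synapses are assigned to the branch whose skeleton is nearest (the soma if
#' nearest the soma ball).
#'
#' @param skeleton a [neuro_skeleton()] with a single root.
#' @param correspondence optional result of [mesh_correspondence()] on the
#'   same skeleton (adds per-branch face ids and width profiles).
#' @param soma optional soma detection (see [detect_somas()]).
#' @param synapses optional synapse tibble with `x`, `y`, `z` (nm) columns.
#' @param soma_cut_factor points within `soma_cut_factor * soma radius` of
#'   the soma centroid accrue to the root.
#' @return an object of class `neuro_decomp`: `root`, `branches` (list),
#'   `edges` (tibble `parent`, `child`), `synapses` (tibble with `branch_id`,
#'   `spine_part`), `log` (character), attr `soma_internal_length`.
#' @export
decompose <- function(skeleton, correspondence = NULL, soma = NULL,
                      synapses = NULL, soma_cut_factor = 1.15) {
  if (nrow(skeleton$points) < 2 || nrow(skeleton$edges) == 0)
    stop("decompose: skeleton is degenerate; treat the component as a fragment")
  root <- skeleton$root
  if (is.na(root)) stop("decompose: skeleton has no root; no soma detected ",
                        "(treat as fragment)")
  log <- character(0)
  pts <- skeleton$points
  np <- nrow(pts)
  width <- if (!is.null(correspondence)) correspondence$width else
    2 * ifelse(is.na(skeleton$radius), 0, skeleton$radius)

  ## ---- keep only the root's connected component -------------------------
  g <- skeleton_graph(skeleton)
  memb <- igraph::components(g)$membership
  in_comp <- memb == memb[root]
  edge_in <- in_comp[skeleton$edges[, 1]] & in_comp[skeleton$edges[, 2]]

  ## ---- break cycles ------------------------------------------------------
  edges <- skeleton$edges
  elen <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                          pts[edges[, 2], , drop = FALSE])^2))
  active <- edge_in
  droot <- rep(Inf, np)
  repeat {
    ga <- igraph::graph_from_edgelist(edges[active, , drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(ga) < np) ga <- igraph::add_vertices(ga, np - igraph::vcount(ga))
    igraph::E(ga)$weight <- elen[active]
    nv_used <- sum(in_comp)
    ne_used <- sum(active)
    if (ne_used < nv_used) break             # already a tree (or forest)
    droot <- as.numeric(igraph::distances(ga, v = root)[1, ])
    # non-tree edge detection via BFS spanning tree
    bfs <- igraph::bfs(ga, root = root, unreachable = FALSE, father = TRUE)
    father <- as.integer(bfs$father)
    tree_e <- matrix(c(seq_len(np), father), ncol = 2)
    tree_keys <- paste(pmin(tree_e[, 1], tree_e[, 2]),
                       pmax(tree_e[, 1], tree_e[, 2]))
    act_idx <- which(active)
    keys <- paste(pmin(edges[act_idx, 1], edges[act_idx, 2]),
                  pmax(edges[act_idx, 1], edges[act_idx, 2]))
    extra <- act_idx[!(keys %in% tree_keys)]
    if (length(extra) == 0) break
    # remove the extra edge whose midpoint is graph-farthest from the root
    far <- extra[which.max(pmin(droot[edges[extra, 1]],
                                droot[edges[extra, 2]]) )]
    active[far] <- FALSE
    log <- c(log, sprintf(
      "cycle broken: removed edge %d-%d (%.0f nm from root)",
      edges[far, 1], edges[far, 2], min(droot[edges[far, ], drop = TRUE])))
  }

  ## ---- soma surface cut --------------------------------------------------
  soma_center <- if (!is.null(soma)) soma$centroid else pts[root, ]
  soma_radius <- if (!is.null(soma)) soma$radius else {
    r0 <- skeleton$radius[root]
    if (is.na(r0) || r0 <= 0) 0 else r0
  }
  interior <- rep(FALSE, np)
  if (soma_radius > 0)
    interior <- dist_to_point(pts, soma_center) <= soma_cut_factor * soma_radius
  interior[root] <- TRUE
  interior[!in_comp] <- FALSE

  act_idx <- which(active)
  e_act <- edges[act_idx, , drop = FALSE]
  i1 <- interior[e_act[, 1]]; i2 <- interior[e_act[, 2]]
  soma_internal <- sum(elen[act_idx][i1 & i2])
  crossing <- xor(i1, i2)
  soma_internal <- soma_internal + sum(elen[act_idx][crossing])
  # reduced edge list: exterior-exterior edges, plus root->boundary edges
  ext_rows <- act_idx[!i1 & !i2]
  boundary <- unique(ifelse(i1[crossing], e_act[crossing, 2],
                            e_act[crossing, 1]))

  ## ---- branch extraction -------------------------------------------------
  adj <- vector("list", np)
  for (r in ext_rows) {
    e <- edges[r, ]
    adj[[e[1]]] <- rbind(adj[[e[1]]], c(e[2], r))
    adj[[e[2]]] <- rbind(adj[[e[2]]], c(e[1], r))
  }
  deg_ext <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a),
                    integer(1))
  is_cut <- deg_ext >= 3
  # walk from every boundary point downstream
  branches <- list()
  edges_tbl <- list()
  edge_branch <- rep(NA_integer_, nrow(edges))
  visited_edge <- rep(FALSE, nrow(edges))
  queue <- lapply(sort(boundary), function(b) list(start = b, parent = 0L))
  while (length(queue) > 0) {
    job <- queue[[1]]; queue <- queue[-1]
    start <- job$start
    starts <- if (is.null(adj[[start]])) matrix(numeric(0), 0, 2) else
      adj[[start]]
    ord <- order(starts[, 1])
    for (k in ord) {
      erow <- starts[k, 2]
      if (visited_edge[erow]) next
      # walk a maximal non-branching path
      path_pts <- c(start)
      path_rows <- c()
      cur <- start; nxt <- starts[k, 1]; row <- erow
      repeat {
        visited_edge[row] <- TRUE
        path_rows <- c(path_rows, row)
        path_pts <- c(path_pts, nxt)
        if (is_cut[nxt] || deg_ext[nxt] == 1) break
        nb <- adj[[nxt]]
        nb <- nb[!visited_edge[nb[, 2]], , drop = FALSE]
        if (nrow(nb) == 0) break
        cur <- nxt
        nxt <- nb[which.min(nb[, 1]), 1]
        row <- nb[which.min(nb[, 1]), 2]
      }
      bid <- length(branches) + 1L
      edge_branch[path_rows] <- bid
      branches[[bid]] <- list(
        id = bid, parent = job$parent,
        point_ids = path_pts,
        points = pts[path_pts, , drop = FALSE],
        skeletal_length = sum(elen[path_rows]),
        width = width[path_pts],
        face_ids = integer(0), synapse_ids = integer(0),
        spine_ids = integer(0),
        compartment = NA_character_)
      edges_tbl[[bid]] <- tibble::tibble(parent = job$parent, child = bid)
      if (is_cut[nxt])
        queue <- c(queue, list(list(start = nxt, parent = bid)))
    }
  }
  if (length(branches) == 0)
    stop("decompose: no branches outside the soma")

  ## ---- faces -------------------------------------------------------------
  if (!is.null(correspondence)) {
    fb <- edge_branch[correspondence$face_edge]
    # faces whose nearest edge is soma-internal but which lie outside the
    # soma ball (e.g. spines on the proximal trunk) belong to the nearest
    # branch, not to the soma
    if (!is.null(attr(correspondence, "face_xyz"))) {
      fxyz <- attr(correspondence, "face_xyz")
    } else fxyz <- NULL
    orphan <- which(is.na(fb) & !is.na(correspondence$face_edge))
    if (length(orphan) > 0 && length(ext_rows) > 0 && !is.null(fxyz)) {
      far_out <- dist_to_point(fxyz[orphan, , drop = FALSE], soma_center) >
        soma_cut_factor * soma_radius
      orphan <- orphan[far_out]
      if (length(orphan) > 0) {
        nn_o <- nearest_segment(fxyz[orphan, , drop = FALSE],
                                pts[edges[ext_rows, 1], , drop = FALSE],
                                pts[edges[ext_rows, 2], , drop = FALSE])
        fb[orphan] <- edge_branch[ext_rows[nn_o$seg]]
      }
    }
    for (bid in seq_along(branches))
      branches[[bid]]$face_ids <- which(!is.na(fb) & fb == bid)
    soma_face_ids <- if (!is.null(soma)) soma$face_ids else
      which(is.na(fb))
  } else soma_face_ids <- integer(0)

  ## ---- synapses ----------------------------------------------------------
  syn <- synapses
  root_syn <- integer(0)
  if (!is.null(syn) && nrow(syn) > 0) {
    if (!"synapse_id" %in% names(syn)) syn$synapse_id <- seq_len(nrow(syn))
    spos <- as.matrix(syn[, c("x", "y", "z")])
    act2 <- which(!is.na(edge_branch))
    nn <- nearest_segment(spos, pts[edges[act2, 1], , drop = FALSE],
                          pts[edges[act2, 2], , drop = FALSE])
    bids <- edge_branch[act2][nn$seg]
    d_soma <- dist_to_point(spos, soma_center) - soma_radius
    to_soma <- d_soma < nn$dist & d_soma < 0.35 * soma_radius
    syn$branch_id <- ifelse(to_soma, 0L, bids)
    syn$dist_to_skeleton <- ifelse(to_soma, pmax(d_soma, 0), nn$dist)
    if (!"spine_part" %in% names(syn))
      syn$spine_part <- ifelse(syn$branch_id == 0L, "soma", "shaft")
    root_syn <- syn$synapse_id[syn$branch_id == 0L]
    for (bid in seq_along(branches))
      branches[[bid]]$synapse_ids <- syn$synapse_id[!is.na(syn$branch_id) &
                                                      syn$branch_id == bid]
  }

  graph <- structure(list(
    root = list(center = soma_center, radius = soma_radius, soma = soma,
                face_ids = soma_face_ids, synapse_ids = root_syn),
    branches = branches,
    edges = dplyr::bind_rows(edges_tbl),
    synapses = syn,
    removed = integer(0),
    log = log), class = "neuro_decomp")
  attr(graph, "soma_internal_length") <- soma_internal
  graph
}

#' @export
print.neuro_decomp <- function(x, ...) {
  cat(sprintf(
    "<neuro_decomp> %d branches (%.0f um), %d stems, %d synapses%s\n",
    length(x$branches), total_skeletal_length(x) / 1000,
    sum(x$edges$parent == 0L),
    if (is.null(x$synapses)) 0L else nrow(x$synapses),
    if (length(x$log)) sprintf(" [%d log entries]", length(x$log)) else ""))
  invisible(x)
}

#' Total skeletal length of a decomposition graph (nm)
#' @param graph a `neuro_decomp`.
#' @return sum of branch skeletal lengths in nm.
#' @export
total_skeletal_length <- function(graph) {
  ids <- active_branch_ids(graph)
  sum(vapply(graph$branches[ids], `[[`, 0, "skeletal_length"))
}

# children ids of a branch (0 = root), excluding removed branches
decomp_children <- function(graph, id) {
  ch <- sort(graph$edges$child[graph$edges$parent == id])
  setdiff(ch, graph$removed %||% integer(0))
}

# descendant closure (excluding `id` itself unless include_self)
decomp_descendants <- function(graph, id, include_self = FALSE) {
  out <- integer(0)
  stack <- decomp_children(graph, id)
  while (length(stack)) {
    x <- stack[1]; stack <- stack[-1]
    out <- c(out, x)
    stack <- c(stack, decomp_children(graph, x))
  }
  if (include_self) out <- c(id, out)
  sort(out)
}

# stems: root children with their descendant closures
decomp_stems <- function(graph) {
  lapply(decomp_children(graph, 0L), function(s)
    decomp_descendants(graph, s, include_self = TRUE))
}

#' Branch summary table of a decomposition graph
#' @param graph a `neuro_decomp`.
#' @return tibble, one row per branch.
#' @export
as_branch_table <- function(graph) {
  dplyr::bind_rows(lapply(graph$branches, function(b) tibble::tibble(
    branch_id = b$id, parent_id = b$parent,
    skeletal_length_nm = b$skeletal_length,
    width_mean_nm = mean(b$width, na.rm = TRUE),
    n_points = nrow(b$points),
    n_faces = length(b$face_ids),
    n_synapses = length(b$synapse_ids),
    n_spines = length(b$spine_ids),
    compartment = b$compartment)))
}
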