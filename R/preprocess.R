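# Mesh preprocessing: soma detection by interior chord analysis, a
# glia/fragment flag, centreline skeletonization by geodesic wavefront
# binning with soma collapse, and mesh-to-skeleton correspondence with
# per-point width estimates.

#' Detect somas on a cleaned mesh
#'
#' Candidate soma interiors are found by casting an inward chord from sampled
#' surface vertices (nearest opposite surface point inside a narrow cone
#' around the inward normal).  Vertices whose half-chord reaches `min_radius`
#' vote for a ball centre; votes are clustered, and each cluster's submesh is
#' accepted if its sphericity `(36*pi*V^2/A^3)^(1/3)` reaches
#' `compactness_threshold`.  Results are ordered by volume, descending.  An
#' empty list is a valid result (orphan neurites).
#'
#' @param mesh a cleaned [neuro_mesh()].
#' @param min_radius minimum soma radius in nm (default 2500).
#' @param compactness_threshold dimensionless sphericity cut (default 0.7).
#' @param max_samples number of surface vertices probed.
#' @return list of soma detections: `centroid`, `radius`, `face_ids`,
#'   `area_nm2`, `volume_nm3`, `sphericity`.
#' @export
detect_somas <- function(mesh, min_radius = 2500, max_radius = 15000,
                         compactness_threshold = 0.7, max_samples = 1500) {
  v <- mesh$vertices
  nv <- nrow(v)
  normals <- vertex_normals(mesh)
  idx <- unique(as.integer(seq(1, nv, length.out = min(nv, max_samples))))
  centers <- list(); radii <- c()
  for (i in idx) {
    inward <- -normals[i, ]
    rel <- sweep(v, 2, v[i, ])
    t <- rel %*% inward
    perp2 <- rowSums(rel^2) - t^2
    ok <- which(t > min_radius & perp2 < (0.25 * t)^2)
    if (length(ok) == 0) next
    chord <- min(t[ok])
    if (chord / 2 >= min_radius && chord / 2 <= max_radius) {
      centers[[length(centers) + 1]] <- v[i, ] + inward * chord / 2
      radii <- c(radii, chord / 2)
    }
  }
  if (length(centers) == 0) return(list())
  C <- do.call(rbind, centers)
  if (nrow(C) == 1) {
    memb <- 1L
  } else {
    hc <- stats::hclust(stats::dist(C), method = "single")
    memb <- stats::cutree(hc, h = min_radius)
  }
  cents <- face_centroids(mesh)
  areas <- face_areas(mesh)
  out <- list()
  for (k in sort(unique(memb))) {
    sel <- memb == k
    if (sum(sel) < 3) next  # too few votes to be a soma
    ctr <- colMeans(C[sel, , drop = FALSE])
    r0 <- stats::median(radii[sel])
    # a real soma surface surrounds its centre in every direction; chords
    # cast between distant parallel processes do not
    shell <- which(abs(dist_to_point(v, ctr) - r0) < 0.3 * r0)
    if (length(shell) < 30) next
    dirs <- sweep(v[shell, , drop = FALSE], 2, ctr)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    if (vec_norm(colMeans(dirs)) > 0.4) next
    fids <- which(dist_to_point(cents, ctr) <= 1.2 * r0)
    if (length(fids) < 10) next
    A <- sum(areas[fids])
    V <- mesh_volume(mesh, faces = fids, origin = ctr)
    spher <- (36 * pi * V^2 / A^3)^(1 / 3)
    r_est <- (3 * V / (4 * pi))^(1 / 3)
    if (spher >= compactness_threshold && r_est >= min_radius)
      out[[length(out) + 1]] <- list(
        centroid = ctr, radius = r_est, face_ids = fids,
        area_nm2 = A, volume_nm3 = V, sphericity = spher)
  }
  if (length(out) == 0) return(list())
  ord <- order(vapply(out, `[[`, 0, "volume_nm3"), decreasing = TRUE)
  out <- out[ord]
  # non-maximum suppression: a detection inside a bigger accepted ball is the
  # same soma seen from a second vote cluster
  keep <- rep(TRUE, length(out))
  for (k in seq_along(out)) {
    if (!keep[k]) next
    for (j in seq_along(out)) {
      if (j <= k || !keep[j]) next
      gap <- vec_norm(out[[k]]$centroid - out[[j]]$centroid)
      if (gap < 0.9 * (out[[k]]$radius + out[[j]]$radius)) keep[j] <- FALSE
    }
  }
  out <- out[keep]
  # enforce disjoint face sets: each face keeps its nearest accepted soma
  if (length(out) > 1) {
    ctrs <- do.call(rbind, lapply(out, `[[`, "centroid"))
    for (k in seq_along(out)) {
      f <- out[[k]]$face_ids
      d <- vapply(seq_along(out), function(j)
        dist_to_point(cents[f, , drop = FALSE], ctrs[j, ]) / out[[j]]$radius,
        numeric(length(f)))
      if (is.null(dim(d))) d <- matrix(d, nrow = 1)
      out[[k]]$face_ids <- f[apply(d, 1, which.min) == k]
    }
  }
  out
}

#' Classify a mesh component as neuron, glia-like or fragment
#'
#' A simplified non-neuronal flag: `fragment` if no soma is detected,
#' `glia_like` if a soma-sized body exists but carries essentially no
#' tube-like processes, `neuron` otherwise.
#'
#' @param mesh a [neuro_mesh()] (one connected component).
#' @param somas result of [detect_somas()]; computed when `NULL`.
#' @param min_process_fraction minimum fraction of surface area outside the
#'   soma submesh for the object to count as a process-bearing neuron.
#' @return one of `"neuron"`, `"glia_like"`, `"fragment"`.
#' @export
flag_non_neuronal <- function(mesh, somas = NULL, min_process_fraction = 0.15) {
  if (is.null(somas)) somas <- detect_somas(mesh)
  if (length(somas) == 0) return("fragment")
  areas <- face_areas(mesh)
  soma_faces <- unique(unlist(lapply(somas, `[[`, "face_ids")))
  frac_out <- sum(areas[-soma_faces]) / sum(areas)
  if (frac_out < min_process_fraction) "glia_like" else "neuron"
}

#' Skeletonize a mesh by geodesic path extraction
#'
#' Centreline extraction in the TEASAR family: one Dijkstra pass computes
#' surface-geodesic distances from the soma surface (or, for soma-less
#' fragments, from an extremal tip); the centreline tree is then grown by
#' repeatedly walking the shortest-path predecessor tree from the farthest
#' not-yet-covered vertex and invalidating a corridor of
#' `invalidation_radius` nm around each extracted path (which swallows spines
#' and surface detail).  Paths are resampled at ~`step` spacing and every
#' kept point is recentred to the centroid of the surface vertices around it,
#' so the polyline tracks the tube axis rather than the surface.  The soma is
#' collapsed to its centroid and becomes the single root point; short leaf
#' twigs below `prune` nm are removed and degree-2 points are lightly
#' smoothed.
#'
#' @param mesh a cleaned, single-component [neuro_mesh()].
#' @param somas a single soma detection, a list of them, or `NULL`.
#' @param step resampling spacing in nm (default 1000).
#' @param prune remove leaf twigs shorter than this (nm, default 4000).
#' @param invalidation_radius corridor radius (nm) marked as covered around
#'   each extracted path.
#' @param recenter_radius radius (nm) of the vertex neighbourhood used to
#'   recentre kept skeleton points onto the tube axis.
#' @param smooth_iter smoothing passes over degree-2 points.
#' @return a [neuro_skeleton()]; `root` is the first soma's centroid point
#'   (attr `roots` carries all soma root indices, one per detected soma).
#'   Degenerate inputs give a single-point skeleton with attr
#'   `degenerate = TRUE`.
#' @export
skeletonize <- function(mesh, somas = NULL, step = 1000, prune = 4000,
                        invalidation_radius = 4000, recenter_radius = 2000,
                        smooth_iter = 2) {
  v <- mesh$vertices
  nv <- nrow(v)
  if (!is.null(somas) && !is.null(somas$centroid)) somas <- list(somas)
  g <- mesh_vertex_graph(mesh)

  if (length(somas) > 0) {
    src_sets <- lapply(somas, function(s)
      which(dist_to_point(v, s$centroid) <= s$radius * 1.1))
  } else {
    d0 <- igraph::distances(g, v = 1)[1, ]
    d0[!is.finite(d0)] <- -1
    src_sets <- list(which.max(d0))
  }
  src_all <- unique(unlist(src_sets))
  n_roots <- length(src_sets)
  gv <- igraph::add_vertices(g, 1)
  virt <- nv + 1L
  gv <- igraph::add_edges(gv, as.vector(rbind(virt, src_all)),
                          weight = rep(0, length(src_all)))
  sp <- igraph::shortest_paths(gv, from = virt, to = igraph::V(gv),
                               predecessors = TRUE, output = "vpath")
  pred <- as.integer(sp$predecessors)
  d <- as.numeric(igraph::distances(gv, v = virt)[1, ])[seq_len(nv)]

  normals <- vertex_normals(mesh)
  recenter <- function(i) {
    # chord casting: the tube axis sits halfway along the chord from the
    # vertex to the opposite wall (nearest surface point inside a cone
    # around the inward normal); unlike a neighbourhood centroid this is
    # unaffected by spines and passing branches
    inward <- -normals[i, ]
    rel <- sweep(v, 2, v[i, ])
    t <- as.vector(rel %*% inward)
    perp2 <- rowSums(rel^2) - t^2
    ok <- which(t > 50 & perp2 < (0.35 * t)^2)
    chord <- if (length(ok) > 0) min(t[ok]) else Inf
    if (is.finite(chord) && chord <= 2 * recenter_radius)
      return(as.numeric(v[i, ] + inward * chord / 2))
    # fallback: trimmed centroid of a geodesic-depth band
    nb <- which(dist_to_point(v, v[i, ]) <= recenter_radius &
                  abs(d - d[i]) <= 0.5 * recenter_radius)
    if (length(nb) < 3) nb <- which(dist_to_point(v, v[i, ]) <= recenter_radius)
    c0 <- colMeans(v[nb, , drop = FALSE])
    for (pass in 1:2) {
      dd <- dist_to_point(v[nb, , drop = FALSE], c0)
      keep <- dd <= 1.25 * stats::median(dd)
      if (sum(keep) < 3) break
      c0 <- colMeans(v[nb[keep], , drop = FALSE])
    }
    c0
  }
  soma_of_source <- integer(nv)
  for (i in seq_len(n_roots)) soma_of_source[src_sets[[i]]] <- i
  # geodesic region of every vertex: which source its shortest path starts at
  region <- soma_of_source
  ordd <- order(d)
  for (vtx in ordd) {
    if (region[vtx] != 0L || !is.finite(d[vtx])) next
    pv <- pred[vtx]
    if (!is.na(pv) && pv <= nv) region[vtx] <- region[pv]
  }

  roots_xyz <- if (length(somas) > 0) lapply(somas, `[[`, "centroid")
               else lapply(src_sets, function(s) as.numeric(v[s[1], ]))
  roots_rad <- if (length(somas) > 0) vapply(somas, `[[`, 0, "radius")
               else rep(0, n_roots)

  covered <- !is.finite(d)
  covered[src_all] <- TRUE
  if (all(covered) || max(d[!covered]) < step) {
    sk <- neuro_skeleton(matrix(roots_xyz[[1]], 1, 3),
                         matrix(integer(), 0, 2),
                         radius = roots_rad[1], root = 1L)
    attr(sk, "degenerate") <- TRUE
    attr(sk, "roots") <- 1L
    return(sk)
  }

  pts <- do.call(rbind, roots_xyz)       # skeleton points, roots first
  rad <- roots_rad
  edges <- list()
  node_of_vertex <- rep(NA_integer_, nv) # mesh vertex -> skeleton node
  n_guard <- 0L

  while (any(!covered) && n_guard < 10000L) {
    n_guard <- n_guard + 1L
    u <- which.max(ifelse(covered, -Inf, d))
    # walk predecessors: u -> ... -> source
    path <- integer(0)
    cur <- u
    while (cur != virt && !is.na(cur)) {
      path <- c(path, cur)
      cur <- pred[cur]
    }
    path <- rev(path)                    # source -> tip
    # corridor invalidation
    probe <- path[unique(c(seq(1, length(path), by = 3), length(path)))]
    for (pv in probe)
      covered[dist_to_point(v, v[pv, ]) <= invalidation_radius] <- TRUE
    covered[path] <- TRUE

    root_id <- soma_of_source[path[1]]
    if (root_id == 0) root_id <- 1L
    # drop the part of the path inside the soma ball
    if (length(somas) > 0) {
      ctr <- somas[[root_id]]$centroid
      inside <- dist_to_point(v[path, , drop = FALSE], ctr) <=
        somas[[root_id]]$radius * 1.15
      if (all(inside)) next
      path <- path[seq(max(which(!inside)[1], 1), length(path))]
    }
    # attach to the existing tree at the last vertex already mapped
    mapped <- which(!is.na(node_of_vertex[path]))
    if (length(mapped) > 0) {
      i0 <- max(mapped)
      attach_node <- node_of_vertex[path[i0]]
      tail_path <- path[seq(i0 + 1, length.out = length(path) - i0)]
    } else {
      attach_node <- root_id
      tail_path <- path
    }
    if (length(tail_path) == 0) next
    # resample the tail at ~step spacing (always keep the tip)
    P <- v[tail_path, , drop = FALSE]
    dP <- matrix(diff(P), ncol = 3)
    seg <- c(0, cumsum(sqrt(rowSums(dP^2))))
    keep <- logical(length(tail_path))
    last_s <- -Inf
    for (i in seq_along(tail_path)) {
      if (seg[i] - last_s >= step) { keep[i] <- TRUE; last_s <- seg[i] }
    }
    keep[length(keep)] <- TRUE
    sel <- which(keep)
    prev_node <- attach_node
    for (i in seq_along(sel)) {
      tv <- tail_path[sel[i]]
      # the terminal point keeps its raw surface position (for capped tube
      # tips this is the on-axis apex), so endpoints reach the mesh tips
      pos <- if (i == length(sel) && tv == u) as.numeric(v[tv, ])
             else recenter(tv)
      if (vec_norm(pos - pts[prev_node, ]) < 1e-6) {
        node <- prev_node
      } else {
        pts <- rbind(pts, pos)
        rad <- c(rad, 0)
        node <- nrow(pts)
        edges[[length(edges) + 1]] <- c(prev_node, node)
      }
      upto <- if (i < length(sel)) sel[i + 1] - 1L else length(tail_path)
      from <- if (i == 1) 1L else sel[i]
      node_of_vertex[tail_path[from:upto]] <- node
      # map the whole invalidated corridor around this point to the node, so
      # later paths running along the far side of the same tube attach here
      # instead of extracting a duplicate centreline; only vertices of the
      # same geodesic region and compatible depth qualify, so branches that
      # merely pass close in space are not captured
      nbv <- which(dist_to_point(v, v[tv, ]) <= invalidation_radius)
      nbv <- nbv[is.na(node_of_vertex[nbv]) &
                   region[nbv] == region[tv] &
                   abs(d[nbv] - d[tv]) <= 1.5 * invalidation_radius]
      node_of_vertex[nbv] <- node
      prev_node <- node
    }
  }

  ed <- do.call(rbind, edges)
  if (is.null(ed)) {
    sk <- neuro_skeleton(matrix(roots_xyz[[1]], 1, 3),
                         matrix(integer(), 0, 2), roots_rad[1], root = 1L)
    attr(sk, "degenerate") <- TRUE
    attr(sk, "roots") <- 1L
    return(sk)
  }
  sk <- neuro_skeleton(pts, ed, rad, root = 1L)
  attr(sk, "roots") <- seq_len(n_roots)
  # When several somas seed the Dijkstra pass, their predecessor trees meet
  # at a geodesic watershed but never share a vertex.  Stitch the skeleton
  # components exactly where the wavefronts touch: mesh edges whose two
  # endpoints were claimed by nodes of different components.
  vmap <- node_of_vertex
  for (i in seq_len(n_roots)) vmap[src_sets[[i]]] <- i
  repeat {
    gsk <- skeleton_graph(sk)
    memb <- igraph::components(gsk)$membership
    if (max(memb) == 1) break
    me <- mesh_edges(mesh)
    na_ <- vmap[me[, 1]]; nb_ <- vmap[me[, 2]]
    ok <- !is.na(na_) & !is.na(nb_) & memb[na_] != memb[nb_]
    if (!any(ok)) break
    # pick the crossing closest to the watershed minimum
    sc <- d[me[ok, 1]] + d[me[ok, 2]]
    j <- which(ok)[which.min(sc)]
    sk$edges <- rbind(sk$edges, c(vmap[me[j, 1]], vmap[me[j, 2]]))
  }
  sk <- prune_skeleton(sk, prune)
  sk <- smooth_skeleton(sk, smooth_iter)
  sk
}

# Remove leaf twigs shorter than `prune` nm (never removing root points).
prune_skeleton <- function(sk, prune) {
  if (prune <= 0 || nrow(sk$edges) == 0) return(sk)
  roots <- attr(sk, "roots")
  repeat {
    deg <- skeleton_degrees(sk)
    g <- skeleton_graph(sk)
    leaves <- setdiff(which(deg == 1), roots)
    drop <- integer(0)
    for (lf in leaves) {
      path <- lf; cur <- lf; prev <- -1L; len <- 0
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nb) != 1) break
        len <- len + vec_norm(sk$points[cur, ] - sk$points[nb, ])
        if (deg[nb] >= 3 || nb %in% roots || len > prune) break
        prev <- cur; cur <- nb; path <- c(path, cur)
      }
      if (len <= prune &&
          (length(nb) == 1 && (deg[nb] >= 3 || nb %in% roots)))
        drop <- union(drop, path)
    }
    if (length(drop) == 0) break
    keep <- setdiff(seq_len(nrow(sk$points)), drop)
    remap <- match(seq_len(nrow(sk$points)), keep)
    ed <- sk$edges[!(sk$edges[, 1] %in% drop | sk$edges[, 2] %in% drop), ,
                   drop = FALSE]
    sk2 <- neuro_skeleton(sk$points[keep, , drop = FALSE],
                          cbind(remap[ed[, 1]], remap[ed[, 2]]),
                          sk$radius[keep], root = remap[sk$root])
    attr(sk2, "roots") <- remap[roots]
    sk <- sk2
  }
  sk
}

# Laplacian smoothing of degree-2 interior points (junctions, roots and
# leaves stay fixed so endpoints and topology are preserved).
smooth_skeleton <- function(sk, iterations = 2) {
  if (iterations <= 0 || nrow(sk$edges) == 0) return(sk)
  deg <- skeleton_degrees(sk)
  roots <- attr(sk, "roots")
  adj <- vector("list", nrow(sk$points))
  for (i in seq_len(nrow(sk$edges))) {
    e <- sk$edges[i, ]
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  movable <- which(deg == 2 & !(seq_along(deg) %in% roots))
  for (it in seq_len(iterations)) {
    newp <- sk$points
    for (i in movable) {
      nb <- adj[[i]]
      newp[i, ] <- 0.5 * sk$points[i, ] +
        0.25 * (sk$points[nb[1], ] + sk$points[nb[2], ])
    }
    sk$points <- newp
  }
  sk
}

#' Write a skeleton as an edge-list CSV
#'
#' Columns: `edge_id`, endpoint coordinates (nm), `length_nm`, and the
#' per-endpoint radii when present.
#'
#' @param skeleton a [neuro_skeleton()].
#' @param path output path.
#' @export
write_skeleton_csv <- function(skeleton, path) {
  e <- skeleton$edges
  p <- skeleton$points
  tab <- tibble::tibble(
    edge_id = seq_len(nrow(e)),
    x0 = p[e[, 1], 1], y0 = p[e[, 1], 2], z0 = p[e[, 1], 3],
    x1 = p[e[, 2], 1], y1 = p[e[, 2], 2], z1 = p[e[, 2], 3],
    length_nm = sqrt(rowSums((p[e[, 1], , drop = FALSE] -
                                p[e[, 2], , drop = FALSE])^2)),
    radius0_nm = skeleton$radius[e[, 1]],
    radius1_nm = skeleton$radius[e[, 2]])
  readr::write_csv(tab, path)
  invisible(path)
}

#' Mesh-to-skeleton correspondence and width estimation
#'
#' Assigns every face to its nearest skeleton edge (face-centroid to segment
#' distance, ties broken toward the lower edge index) and estimates a local
#' width at every skeleton point as twice the lower-quartile distance of the
#' faces assigned to its incident edges.  The lower quartile (rather than the
#' median) keeps the shaft width robust when spine faces dominate locally.
#'
#' @param mesh a [neuro_mesh()].
#' @param skeleton a [neuro_skeleton()] derived from the same mesh.
#' @return list with `face_edge` (edge index per face), `face_dist`
#'   (distance to the assigned edge, nm), `width` (per skeleton point, nm)
#'   and the input skeleton with its `radius` replaced by `width / 2`.
#' @export
mesh_correspondence <- function(mesh, skeleton) {
  if (nrow(skeleton$points) == 0 || nrow(skeleton$edges) == 0)
    stop("mesh_correspondence: empty skeleton")
  cents <- face_centroids(mesh)
  A <- skeleton$points[skeleton$edges[, 1], , drop = FALSE]
  B <- skeleton$points[skeleton$edges[, 2], , drop = FALSE]
  nn <- nearest_segment(cents, A, B)
  np <- nrow(skeleton$points)
  face_xyz <- cents
  width <- rep(NA_real_, np)
  # incident edge list per point
  inc <- vector("list", np)
  for (i in seq_len(nrow(skeleton$edges))) {
    e <- skeleton$edges[i, ]
    inc[[e[1]]] <- c(inc[[e[1]]], i)
    inc[[e[2]]] <- c(inc[[e[2]]], i)
  }
  by_edge <- split(nn$dist, nn$seg)
  for (p in seq_len(np)) {
    ds <- unlist(by_edge[as.character(inc[[p]])])
    if (length(ds) > 0)
      width[p] <- 2 * stats::quantile(ds, 0.25, names = FALSE)
  }
  width[is.na(width)] <- 0
  skeleton$radius <- width / 2
  out <- list(face_edge = nn$seg, face_dist = nn$dist, width = width,
              skeleton = skeleton)
  attr(out, "face_xyz") <- face_xyz
  out
}
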