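# Merged scenes: one mesh containing one or more ground-truth neurons plus
# deliberately injected merge errors (axon-on-axon, axon-on-dendrite,
# soma-soma bridges, double-back kinks, width jumps), with exact face-level
# and synapse-level ground truth.

MERGE_ERROR_TYPES <- c("axon_on_axon", "axon_on_dendrite", "soma_bridge",
                       "double_back", "width_jump")

translate_neuron <- function(neuron, dxyz) {
  neuron$skeleton$points <- sweep(neuron$skeleton$points, 2, dxyz, "+")
  neuron$soma_center <- neuron$soma_center + dxyz
  if (nrow(neuron$spine_spec) > 0) {
    neuron$spine_spec$base_x <- neuron$spine_spec$base_x + dxyz[1]
    neuron$spine_spec$base_y <- neuron$spine_spec$base_y + dxyz[2]
    neuron$spine_spec$base_z <- neuron$spine_spec$base_z + dxyz[3]
  }
  if (nrow(neuron$synapses) > 0) {
    neuron$synapses$x <- neuron$synapses$x + dxyz[1]
    neuron$synapses$y <- neuron$synapses$y + dxyz[2]
    neuron$synapses$z <- neuron$synapses$z + dxyz[3]
  }
  neuron
}

#' Assemble a merge scene from ground-truth neurons
#'
#' Meshes every neuron (applying the given translations), concatenates the
#' meshes into one labelled scene mesh, and pools the synapse tables.  Face
#' labels are prefixed `n<i>/`; synapses carry their `neuron_id`.
#'
#' @param neurons list of [generate_neuron()] objects.
#' @param offsets list of 3-vectors (nm), one per neuron.
#' @param resolution,head_subdiv meshing parameters, see [mesh_from_neuron()].
#' @return an object of class `merge_scene`: `mesh`, `labels`, `neurons`,
#'   `synapses` (tibble with `neuron_id`, `valid`, `error_id`),
#'   `error_truth` (tibble with list-column `face_ids`).
#' @export
make_scene <- function(neurons, offsets = NULL, resolution = 10,
                       head_subdiv = 1) {
  if (is.null(offsets)) offsets <- rep(list(c(0, 0, 0)), length(neurons))
  neurons <- purrr::map2(neurons, offsets, translate_neuron)
  meshed <- purrr::map(neurons, mesh_from_neuron, resolution = resolution,
                       head_subdiv = head_subdiv)
  nv <- 0L
  vs <- list(); fs <- list(); lab <- list()
  for (i in seq_along(meshed)) {
    m <- meshed[[i]]$mesh
    vs[[i]] <- m$vertices
    fs[[i]] <- m$faces + nv
    lab[[i]] <- paste0("n", i, "/", meshed[[i]]$labels)
    nv <- nv + nrow(m$vertices)
  }
  syn <- purrr::imap(neurons, function(nr, i)
    dplyr::mutate(nr$synapses, neuron_id = as.integer(i),
                  error_id = NA_integer_))
  syn <- dplyr::bind_rows(syn)
  if (nrow(syn) > 0) syn$synapse_id <- seq_len(nrow(syn))
  structure(list(
    mesh = neuro_mesh(do.call(rbind, vs), do.call(rbind, fs)),
    labels = unlist(lab),
    neurons = neurons,
    resolution = resolution,
    synapses = syn,
    error_truth = tibble::tibble(error_id = integer(), type = character(),
                                 weld_x = double(), weld_y = double(),
                                 weld_z = double(), face_ids = list())),
    class = "merge_scene")
}

#' @export
print.merge_scene <- function(x, ...) {
  cat(sprintf(
    "<merge_scene> %d neuron(s), %d faces, %d synapses (%d invalid), %d injected error(s)\n",
    length(x$neurons), nrow(x$mesh$faces), nrow(x$synapses),
    sum(!x$synapses$valid), nrow(x$error_truth)))
  invisible(x)
}

scene_host_vertices <- function(scene, label_regex) {
  rows <- grepl(label_regex, scene$labels)
  sort(unique(as.vector(scene$mesh$faces[rows, , drop = FALSE])))
}

# Append a labelled foreign part plus weld collar; returns updated scene and
# the new face ids.
scene_append_part <- function(scene, part, err_label, host_vertex_ids,
                              weld_ring) {
  nv <- nrow(scene$mesh$vertices)
  new_v <- rbind(scene$mesh$vertices, part$vertices)
  new_f <- part$faces + nv
  collar <- weld_collar_faces(new_v, weld_ring + nv, host_vertex_ids)
  f0 <- nrow(scene$mesh$faces)
  scene$mesh <- neuro_mesh(new_v, rbind(scene$mesh$faces, new_f, collar))
  scene$labels <- c(scene$labels, rep(err_label, nrow(new_f)),
                    rep(paste0(err_label, "/weld"), nrow(collar)))
  list(scene = scene, face_ids = f0 + seq_len(nrow(new_f) + nrow(collar)))
}

# Foreign-part synapses scattered over a tube path at `density` per um.
foreign_synapses <- function(path, radius, density, direction, host_id,
                             error_id, compartment = "error") {
  L_um <- polyline_length(path) / 1000
  n <- stats::rpois(1, density * L_um)
  if (n == 0) return(NULL)
  fr <- transport_frames(path)
  seg <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seg))
  s <- stats::runif(n) * cum[length(cum)]
  rows <- lapply(seq_len(n), function(j) {
    i <- min(max(1L, findInterval(s[j], cum)), length(seg))
    f <- (s[j] - cum[i]) / seg[i]
    pos <- path[i, ] + f * (path[i + 1, ] - path[i, ])
    az <- stats::runif(1, 0, 2 * pi)
    radial <- cos(az) * fr$e1[i, ] + sin(az) * fr$e2[i, ]
    pos <- pos + radial * radius
    tibble::tibble(
      pre_id = if (direction == "outgoing") -error_id else 0L,
      post_id = if (direction == "outgoing") 0L else -error_id,
      x = pos[1], y = pos[2], z = pos[3],
      size = stats::rlnorm(1, log(500), 0.4),
      direction = direction, compartment = compartment,
      spine_id = NA_integer_, valid = FALSE,
      neuron_id = as.integer(host_id), error_id = as.integer(error_id))
  })
  dplyr::bind_rows(rows)
}

#' Inject a merge error into a scene
#'
#' Welds foreign geometry onto a host neuron at a random valid attachment
#' point, appends the ground-truth record, and adds synapses on the foreign
#' part flagged `valid = FALSE`.  The five supported error types mirror the
#' merge-error families the proofreading filters target.
#'
#' @param scene a [make_scene()] object.
#' @param error_type one of `"axon_on_axon"`, `"axon_on_dendrite"`,
#'   `"soma_bridge"`, `"double_back"`, `"width_jump"`.
#' @param seed integer seed.
#' @param host index of the host neuron (default 1).
#' @return the updated `merge_scene`.
#' @export
inject_merge_error <- function(scene, error_type, seed = 1, host = 1L) {
  if (!error_type %in% MERGE_ERROR_TYPES)
    stop("unknown error_type '", error_type, "'; supported types: ",
         paste(MERGE_ERROR_TYPES, collapse = ", "))
  if (length(scene$neurons) < 1) stop("scene has no neurons")
  if (error_type == "soma_bridge" && length(scene$neurons) < 2)
    stop("soma_bridge needs at least two neurons in the scene")
  with_seed(seed, inject_impl(scene, error_type, host))
}

pick_branch <- function(neuron, compartments, leaf_only = FALSE) {
  cands <- Filter(function(b) b$compartment %in% compartments,
                  neuron$branches)
  if (leaf_only) {
    parents <- vapply(neuron$branches, `[[`, 0L, "parent")
    cands <- Filter(function(b) !(b$id %in% parents), cands)
  }
  if (length(cands) == 0) stop("host neuron has no suitable branch")
  cands[[sample.int(length(cands), 1)]]
}

inject_impl <- function(scene, error_type, host) {
  nr <- scene$neurons[[host]]
  res <- scene$resolution
  err_id <- nrow(scene$error_truth) + 1L
  err_label <- paste0("err", err_id)
  pts <- nr$skeleton$points

  straight_path <- function(from, dirv, length_nm, step = 2000) {
    n <- max(2L, ceiling(length_nm / step))
    sweep(outer(seq(0, length_nm, length.out = n + 1), dirv), 2, from, "+")
  }

  if (error_type %in% c("axon_on_axon", "axon_on_dendrite")) {
    comp <- if (error_type == "axon_on_axon") "axon"
            else c("basal", "apical", "oblique")
    b <- pick_branch(nr, comp)
    L <- polyline_length(pts[b$point_ids, , drop = FALSE])
    loc <- branch_point_at_arc(pts, b, stats::runif(1, 0.3, 0.7) * L)
    radial <- rotate_about(orthogonal_unit(loc$tangent), loc$tangent,
                           stats::runif(1, 0, 360))
    weld_at <- loc$point + radial * loc$radius
    r_f <- 250
    if (error_type == "axon_on_axon") {
      # straight foreign axon passing through: an X crossing
      half <- 20000
      dirv <- unitize(radial + 0.2 * loc$tangent)
      path <- straight_path(weld_at - dirv * half / 2, dirv, half)
    } else {
      dirv <- unitize(radial + 0.3 * jitter_direction(loc$tangent, 30))
      path <- straight_path(weld_at - radial * loc$radius * 0.5, dirv, 25000)
    }
    part <- tube_mesh(path, r_f, res, cap_start = TRUE, cap_end = TRUE)
    hostv <- scene_host_vertices(scene,
                                 paste0("^n", host, "/branch_", b$id, "$"))
    mid_ring <- if (error_type == "axon_on_axon")
      (floor(nrow(path) / 2) * res) + seq_len(res) else seq_len(res)
    ap <- scene_append_part(scene, part, err_label, hostv, mid_ring)
    scene <- ap$scene
    syn <- foreign_synapses(path, r_f, 1.0, "outgoing", host, err_id)
  } else if (error_type == "soma_bridge") {
    other <- if (host == 1L) 2L else 1L
    n2 <- scene$neurons[[other]]
    dirv <- unitize(n2$soma_center - nr$soma_center)
    from <- nr$soma_center + dirv * nr$soma_radius * 0.7
    to <- n2$soma_center - dirv * n2$soma_radius * 0.7
    path <- straight_path(from, unitize(to - from), vec_norm(to - from))
    weld_at <- nr$soma_center + dirv * nr$soma_radius
    part <- tube_mesh(path, 800, res, cap_start = FALSE, cap_end = FALSE)
    host1 <- scene_host_vertices(scene, paste0("^n", host, "/soma$"))
    host2 <- scene_host_vertices(scene, paste0("^n", other, "/soma$"))
    ap <- scene_append_part(scene, part, err_label, host1, seq_len(res))
    scene <- ap$scene
    # second collar to the far soma
    nv <- nrow(scene$mesh$vertices)
    last_ring <- nv - nrow(part$vertices) + (nrow(path) - 1) * res +
      seq_len(res)
    collar2 <- weld_collar_faces(scene$mesh$vertices, last_ring, host2)
    f0 <- nrow(scene$mesh$faces)
    scene$mesh <- neuro_mesh(scene$mesh$vertices,
                             rbind(scene$mesh$faces, collar2))
    scene$labels <- c(scene$labels, rep(paste0(err_label, "/weld"),
                                        nrow(collar2)))
    ap$face_ids <- c(ap$face_ids, f0 + seq_len(nrow(collar2)))
    syn <- foreign_synapses(path, 800, 0.2, "incoming", host, err_id)
  } else if (error_type == "double_back") {
    # a foreign axon piece welded at a branch point, heading sharply back
    # toward the soma: the decomposition sees a child whose branching angle
    # exceeds the double-back threshold
    b <- pick_branch(nr, "axon")
    L <- polyline_length(pts[b$point_ids, , drop = FALSE])
    loc <- branch_point_at_arc(pts, b, stats::runif(1, 0.4, 0.7) * L)
    back <- unitize(nr$soma_center - loc$point)
    # veer off the host axon so the doubled-back piece is a distinct arm
    dirv <- unitize(back + 0.45 * orthogonal_unit(back))
    if (angle_deg(dirv, loc$tangent) < 150)
      dirv <- unitize(-loc$tangent + 0.45 * orthogonal_unit(loc$tangent))
    weld_at <- loc$point
    path <- straight_path(loc$point, dirv, 15000)
    part <- tube_mesh(path, max(loc$radius, 250), res,
                      cap_start = FALSE, cap_end = TRUE)
    hostv <- scene_host_vertices(scene,
                                 paste0("^n", host, "/branch_", b$id, "$"))
    ap <- scene_append_part(scene, part, err_label, hostv, seq_len(res))
    scene <- ap$scene
    syn <- foreign_synapses(path, max(loc$radius, 250), 1.0, "outgoing",
                            host, err_id)
  } else { # width_jump
    # a much thicker foreign dendrite welded mid-branch
    b <- pick_branch(nr, c("basal", "apical", "oblique"))
    L <- polyline_length(pts[b$point_ids, , drop = FALSE])
    loc <- branch_point_at_arc(pts, b, stats::runif(1, 0.4, 0.7) * L)
    dirv <- unitize(jitter_direction(loc$tangent, 10) +
                      0.8 * orthogonal_unit(loc$tangent))
    weld_at <- loc$point
    r_fat <- max(3 * loc$radius, 1500)
    path <- straight_path(loc$point + dirv * loc$radius * 0.3, dirv, 15000)
    part <- tube_mesh(path, r_fat, res, cap_start = TRUE, cap_end = TRUE)
    hostv <- scene_host_vertices(scene,
                                 paste0("^n", host, "/branch_", b$id, "$"))
    ap <- scene_append_part(scene, part, err_label, hostv, seq_len(res))
    scene <- ap$scene
    syn <- foreign_synapses(path, r_fat, 0.2, "incoming", host, err_id)
  }

  scene$error_truth <- dplyr::bind_rows(scene$error_truth, tibble::tibble(
    error_id = err_id, type = error_type,
    weld_x = weld_at[1], weld_y = weld_at[2], weld_z = weld_at[3],
    face_ids = list(ap$face_ids)))
  if (!is.null(syn)) {
    scene$synapses <- dplyr::bind_rows(scene$synapses, syn)
    scene$synapses$synapse_id <- seq_len(nrow(scene$synapses))
  }
  scene
}

#' Weld one neuron's axon onto another neuron's dendrite
#'
#' Builds the canonical two-neuron merge: neuron 2 is translated so one of
#' its dendrites passes by neuron 1's axon tip, and a weld collar joins the
#' two meshes.  Used by the `merged-pair` preset and the multi-soma split
#' tests.
#'
#' @param n1,n2 [generate_neuron()] objects.
#' @param seed integer seed.
#' @param resolution tube-ring resolution.
#' @return a `merge_scene` of both neurons with one `error_truth` record of
#'   type `axon_on_dendrite` (the weld collar faces).
#' @export
make_merged_pair <- function(n1, n2, seed = 1, resolution = 10) {
  with_seed(seed, {
    axon_branches <- Filter(function(b) b$compartment == "axon", n1$branches)
    if (length(axon_branches) == 0) stop("neuron 1 has no axon")
    parents <- vapply(n1$branches, `[[`, 0L, "parent")
    leafs <- Filter(function(b) !(b$id %in% parents), axon_branches)
    ba <- leafs[[sample.int(length(leafs), 1)]]
    tip <- n1$skeleton$points[ba$point_ids[length(ba$point_ids)], ]

    bd <- pick_branch(n2, c("basal", "apical", "oblique"))
    L <- polyline_length(n2$skeleton$points[bd$point_ids, , drop = FALSE])
    loc <- branch_point_at_arc(n2$skeleton$points, bd, 0.5 * L)
    # translate n2 so the chosen dendrite point sits just beyond the axon tip
    target <- tip + ba$dir_end * (loc$radius + ba$r_end)
    offset <- target - loc$point
    scene <- make_scene(list(n1, n2), offsets = list(c(0, 0, 0), offset),
                        resolution = resolution)
    hostv <- scene_host_vertices(scene, paste0("^n2/branch_", bd$id, "$"))
    tipv <- scene_host_vertices(scene, paste0("^n1/branch_", ba$id, "$"))
    tip_pts <- scene$mesh$vertices[tipv, , drop = FALSE]
    near_tip <- tipv[order(dist_to_point(tip_pts, tip))[seq_len(min(
      scene$resolution, length(tipv)))]]
    collar <- weld_collar_faces(scene$mesh$vertices, near_tip, hostv)
    f0 <- nrow(scene$mesh$faces)
    scene$mesh <- neuro_mesh(scene$mesh$vertices,
                             rbind(scene$mesh$faces, collar))
    scene$labels <- c(scene$labels, rep("err1/weld", nrow(collar)))
    scene$error_truth <- tibble::tibble(
      error_id = 1L, type = "axon_on_dendrite",
      weld_x = tip[1], weld_y = tip[2], weld_z = tip[3],
      face_ids = list(f0 + seq_len(nrow(collar))))
    scene
  })
}

#' Scene presets
#'
#' `single`: one clean spiny neuron.  `merged-pair`: two neurons joined
#' axon-to-dendrite.  `orphan-axon`: one neuron with an orphan axon fragment
#' merged onto a dendrite.  `glia-blob`: a large lumpy sphere with no
#' processes (simplified non-neuronal object).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [neuron_params()].
#' @return a `merge_scene` (for `glia-blob`, a list with `mesh` only).
#' @export
synth_preset <- function(preset = c("single", "merged-pair", "orphan-axon",
                                    "glia-blob"), seed = 1, ...) {
  preset <- match.arg(preset)
  if (preset == "glia-blob") {
    return(with_seed(seed, {
      s <- icosphere_unit(3)
      bump <- 1 + stats::runif(nrow(s$v), -0.08, 0.08)
      list(mesh = neuro_mesh(s$v * bump * 8000, s$f), labels = NULL)
    }))
  }
  if (preset == "single")
    return(make_scene(list(generate_neuron(neuron_params(...), seed))))
  if (preset == "merged-pair") {
    n1 <- generate_neuron(neuron_params(...), seed)
    n2 <- generate_neuron(neuron_params(...), substream_seed(seed, 2))
    return(make_merged_pair(n1, n2, seed = substream_seed(seed, 3)))
  }
  # orphan-axon
  scene <- make_scene(list(generate_neuron(neuron_params(...), seed)))
  inject_merge_error(scene, "axon_on_dendrite",
                     seed = substream_seed(seed, 5))
}
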