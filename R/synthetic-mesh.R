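# Meshing of ground-truth neurons: frusta swept along the skeleton, an
# icosphere soma, sphere-on-cylinder mushroom spines and hemisphere stubby
# spines.  Boolean union is deliberately avoided: parts interpenetrate and a
# small collar of bridge faces (labelled "weld") joins each part to its host,
# so the per-face ground truth stays exact while the mesh remains a single
# connected component.

#' Mesh a synthetic neuron with per-face ground-truth labels
#'
#' @param neuron a [generate_neuron()] result.
#' @param resolution vertices per tube ring (>= 6).
#' @param soma_subdiv icosphere subdivision of the soma (3 keeps the enclosed
#'   volume within ~1% of the ideal sphere).
#' @param head_subdiv icosphere subdivision of mushroom spine heads.
#' @return a list with `mesh` ([neuro_mesh()]), `labels` (character per face:
#'   `soma`, `branch_<id>`, `spine_<id>_head`, `spine_<id>_neck`, `weld`) and
#'   `neuron` (the input).
#' @export
mesh_from_neuron <- function(neuron, resolution = 10, soma_subdiv = 3,
                             head_subdiv = 1) {
  if (resolution < 6) stop("resolution must be >= 6")
  parts <- list(); labels <- character(0)
  vert_offset <- 0L
  master_v <- list(); master_f <- list()
  part_vrange <- list()   # label -> vertex id range of the part

  push_part <- function(mesh, label) {
    n <- nrow(mesh$vertices)
    master_v[[length(master_v) + 1L]] <<- mesh$vertices
    master_f[[length(master_f) + 1L]] <<- mesh$faces + vert_offset
    labels <<- c(labels, rep(label, nrow(mesh$faces)))
    rng <- vert_offset + seq_len(n)
    part_vrange[[label]] <<- rng
    vert_offset <<- vert_offset + n
    rng
  }
  push_faces <- function(faces, label) {
    master_f[[length(master_f) + 1L]] <<- faces
    labels <<- c(labels, rep(label, nrow(faces)))
  }

  push_part(icosphere_mesh(neuron$soma_center, neuron$soma_radius,
                           soma_subdiv), "soma")

  skel_pts <- neuron$skeleton$points
  children_of <- table(vapply(neuron$branches, `[[`, 0L, "parent"))
  is_leaf <- function(bid) is.na(children_of[as.character(bid)])

  for (b in neuron$branches) {
    ids <- b$point_ids
    P <- skel_pts[ids, , drop = FALSE]
    nsteps <- length(ids) - 1
    radii <- b$r_start + (b$r_end - b$r_start) * (seq_along(ids) - 1) / nsteps
    if (b$parent == 0L) {
      inner <- neuron$soma_center +
        unitize(P[1, ] - neuron$soma_center) * neuron$soma_radius * 0.8
      P <- rbind(inner, P)
      radii <- c(radii[1], radii)
      host_label <- "soma"
    } else {
      host_label <- paste0("branch_", b$parent)
    }
    tm <- tube_mesh(P, radii, resolution, cap_start = FALSE,
                    cap_end = is_leaf(b$id))
    rng <- push_part(tm, paste0("branch_", b$id))
    ring1 <- rng[seq_len(resolution)]
    later_v <- do.call(rbind, master_v)
    collar <- weld_collar_faces(later_v, ring1, part_vrange[[host_label]])
    push_faces(collar, "weld")
  }

  if (nrow(neuron$spine_spec) > 0) {
    for (j in seq_len(nrow(neuron$spine_spec))) {
      sp <- neuron$spine_spec[j, ]
      base <- c(sp$base_x, sp$base_y, sp$base_z)
      dirv <- unitize(c(sp$dir_x, sp$dir_y, sp$dir_z))
      host_label <- paste0("branch_", sp$branch_id)
      all_v <- function() do.call(rbind, master_v)
      if (sp$type == "mushroom") {
        inset <- 150
        path <- rbind(base - dirv * inset, base + dirv * sp$neck_length)
        neck <- tube_mesh(path, sp$neck_radius, resolution,
                          cap_start = FALSE, cap_end = FALSE)
        nrng <- push_part(neck, paste0("spine_", sp$spine_id, "_neck"))
        collar <- weld_collar_faces(all_v(), nrng[seq_len(resolution)],
                                    part_vrange[[host_label]])
        push_faces(collar, "weld")
        head_center <- base + dirv * (sp$neck_length + sp$head_radius * 0.95)
        head <- icosphere_mesh(head_center, sp$head_radius,
                               max(head_subdiv, 1))
        hrng <- push_part(head, paste0("spine_", sp$spine_id, "_head"))
        top_ring <- nrng[resolution + seq_len(resolution)]
        collar2 <- weld_collar_faces(all_v(), top_ring, hrng)
        push_faces(collar2, "weld")
      } else {
        # sink the dome base slightly into the shaft so the surfaces overlap
        hemi <- dome_mesh(base - dirv * sp$head_radius * 0.15, sp$head_radius,
                          dirv, resolution)
        hrng <- push_part(hemi, paste0("spine_", sp$spine_id, "_head"))
        collar <- weld_collar_faces(all_v(), hrng[seq_len(resolution)],
                                    part_vrange[[host_label]])
        push_faces(collar, "weld")
      }
    }
  }

  mesh <- neuro_mesh(do.call(rbind, master_v), do.call(rbind, master_f))
  list(mesh = mesh, labels = labels, neuron = neuron)
}

#' Ground-truth face table of a meshed neuron or scene
#'
#' @param labels per-face label vector as returned by [mesh_from_neuron()].
#' @return tibble with `face_id`, `label`, `kind` and parsed `branch_id` /
#'   `spine_id` where applicable.
#' @export
face_truth_table <- function(labels) {
  lab <- sub("^n[0-9]+/", "", labels)
  kind <- dplyr::case_when(
    grepl("^soma$", lab) ~ "soma",
    grepl("^branch_", lab) ~ "branch",
    grepl("^spine_.*_head$", lab) ~ "spine_head",
    grepl("^spine_.*_neck$", lab) ~ "spine_neck",
    grepl("^err", lab) ~ "error",
    TRUE ~ "weld")
  branch_id <- rep(NA_integer_, length(lab))
  is_b <- kind == "branch"
  branch_id[is_b] <- as.integer(sub("branch_", "", lab[is_b]))
  spine_id <- rep(NA_integer_, length(lab))
  is_s <- kind %in% c("spine_head", "spine_neck")
  spine_id[is_s] <- as.integer(sub("spine_([0-9]+)_.*", "\\1", lab[is_s]))
  tibble::tibble(
    face_id = seq_along(labels),
    label = labels,
    kind = kind,
    branch_id = branch_id,
    spine_id = spine_id)
}
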