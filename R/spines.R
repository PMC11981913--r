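# Dendritic spine detection, head/neck segmentation and synapse spine-part
# labelling.  Spines are connected components of mesh faces protruding
# beyond the local shaft radius; heads are split from necks at a radial
# minimum of the width profile along the spine axis.

#' Detect spines on the dendritic branches of a decomposition graph
#'
#' Faces farther from the branch skeleton than
#' `shaft_factor * local width / 2` are marked protruding; connected
#' components of protruding faces with at least `min_faces` faces become
#' spine candidates.  The spine skeletal length is the height of the
#' farthest face centroid above the local shaft surface.
#'
#' @param graph a `neuro_decomp` whose branches carry `face_ids`.
#' @param mesh the [neuro_mesh()] the graph was decomposed from.
#' @param branch_ids branches to scan (default: all non-axonal branches, or
#'   every branch when compartments are unlabelled; detection on axons is
#'   permitted but flagged in the `on_axon` column).
#' @param shaft_factor protrusion threshold as a multiple of the local shaft
#'   radius (default 1.4).
#' @param min_faces minimum faces per spine component (default 20 at the
#'   generator's meshing resolution).
#' @return tibble of spines: `spine_id`, `branch_id`, base point, skeletal
#'   length (nm), face count and a `face_ids` list-column of mesh face ids.
#' @export
detect_spines <- function(graph, mesh, branch_ids = NULL, shaft_factor = 1.4,
                          min_faces = 20, max_length_nm = 4000,
                          core_margin = 400) {
  if (is.null(branch_ids)) {
    branch_ids <- active_branch_ids(graph)
    comp <- vapply(graph$branches[branch_ids], `[[`, "", "compartment")
    if (!all(is.na(comp)))
      branch_ids <- branch_ids[is.na(comp) | !(comp %in% c("axon", "AIS"))]
  }
  cents_all <- face_centroids(mesh)
  rows <- list()
  sid <- 0L
  for (id in branch_ids) {
    b <- graph$branches[[id]]
    if (length(b$face_ids) < min_faces || nrow(b$points) < 2) next
    cents <- cents_all[b$face_ids, , drop = FALSE]
    P <- b$points
    nn <- nearest_segment(cents, P[-nrow(P), , drop = FALSE],
                          P[-1, , drop = FALSE])
    # robust local shaft radius: per-point width capped slightly above the
    # branch median (within-branch taper is mild), so spine-inflated points
    # do not mask their own spines
    med_w <- stats::median(b$width, na.rm = TRUE)
    w_loc <- pmin(b$width, 1.2 * med_w)
    # terminal-point widths are deflated by cap / junction-gap faces
    k <- length(w_loc)
    if (k >= 2) {
      w_loc[1] <- max(w_loc[1], w_loc[2])
      w_loc[k] <- max(w_loc[k], w_loc[k - 1])
    }
    w_face <- w_loc[nn$seg]               # width at the proximal edge point
    # faces overhanging the branch ends (tip caps, the soma-cut gap) carry
    # an axial distance component; judge them by their perpendicular
    # distance to the end segment's line instead
    n_seg <- nrow(P) - 1
    d_eff <- nn$dist
    clamped <- which((nn$seg == 1 & nn$t <= 1e-9) |
                       (nn$seg == n_seg & nn$t >= 1 - 1e-9))
    for (ci in clamped) {
      a <- P[nn$seg[ci], ]; bb <- P[nn$seg[ci] + 1, ]
      u <- (bb - a) / vec_norm(bb - a)
      rel <- cents[ci, ] - a
      d_eff[ci] <- vec_norm(rel - sum(rel * u) * u)
    }
    protruding <- d_eff > shaft_factor * w_face / 2
    if (!any(protruding)) next
    # Marker-based components: cores are formed above a higher threshold so
    # neighbouring spines whose skirts touch do not merge, then each
    # remaining protruding face joins the nearest core.
    core <- nn$dist > shaft_factor * w_face / 2 + core_margin
    if (!any(core)) core <- protruding
    pf <- b$face_ids[protruding]
    is_core <- core[protruding]
    # vertex-sharing adjacency among the protruding faces (weld collars join
    # spine parts through single shared vertices)
    fvp <- mesh$faces[pf, , drop = FALSE]
    npf <- length(pf)
    vkey <- split(rep(seq_len(npf), 3), as.vector(fvp))
    vkey <- vkey[lengths(vkey) >= 2]
    el <- do.call(rbind, lapply(vkey, function(p) cbind(p[1], p[-1])))
    adjl <- vector("list", npf)
    if (!is.null(el)) for (r in seq_len(nrow(el))) {
      adjl[[el[r, 1]]] <- c(adjl[[el[r, 1]]], el[r, 2])
      adjl[[el[r, 2]]] <- c(adjl[[el[r, 2]]], el[r, 1])
    }
    # components of the cores, then watershed growth through the skirt
    gf <- igraph::make_empty_graph(n = npf, directed = FALSE)
    core_el <- if (!is.null(el))
      el[is_core[el[, 1]] & is_core[el[, 2]], , drop = FALSE] else NULL
    if (!is.null(core_el) && nrow(core_el) > 0)
      gf <- igraph::add_edges(gf, t(core_el))
    memb <- rep(NA_integer_, npf)
    memb[is_core] <- igraph::components(gf)$membership[is_core]
    frontier <- which(is_core)
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (f in frontier) for (nb2 in adjl[[f]]) {
        if (is.na(memb[nb2])) { memb[nb2] <- memb[f]; nxt <- c(nxt, nb2) }
      }
      frontier <- nxt
    }
    # protrusions not reachable from any core (short spines entirely below
    # the core threshold) form their own components
    left <- which(is.na(memb))
    if (length(left) > 0) {
      gl <- igraph::make_empty_graph(n = npf, directed = FALSE)
      left_el <- if (!is.null(el))
        el[is.na(memb[el[, 1]]) & is.na(memb[el[, 2]]), , drop = FALSE] else
          NULL
      if (!is.null(left_el) && nrow(left_el) > 0)
        gl <- igraph::add_edges(gl, t(left_el))
      base <- if (all(is.na(memb))) 0L else max(memb, na.rm = TRUE)
      memb[left] <- base + igraph::components(gl)$membership[left]
    }
    for (cmp in unique(memb[!is.na(memb)])) {
      fc <- pf[!is.na(memb) & memb == cmp]
      if (length(fc) < min_faces) next
      dists <- d_eff[match(fc, b$face_ids)]
      base_face <- fc[which.min(dists)]
      base_pt_idx <- nn$seg[match(base_face, b$face_ids)]
      base <- P[base_pt_idx, ]
      shaft_r <- w_loc[base_pt_idx] / 2
      # spine height above the shaft surface: maximal face distance to the
      # branch polyline minus the local shaft radius
      far <- max(dists)
      # protrusions taller than any realistic spine are junction or foreign
      # geometry picked up by the correspondence, not spines
      if (far - shaft_r > max_length_nm) next
      sid <- sid + 1L
      rows[[sid]] <- tibble::tibble(
        spine_id = sid, branch_id = id,
        base_x = base[1], base_y = base[2], base_z = base[3],
        skeletal_length_nm = max(far - shaft_r, 0),
        n_faces = length(fc),
        on_axon = isTRUE(graph$branches[[id]]$compartment %in%
                           c("axon", "AIS")),
        face_ids = list(fc))
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(spine_id = integer(), branch_id = integer(),
                          base_x = double(), base_y = double(),
                          base_z = double(), skeletal_length_nm = double(),
                          n_faces = integer(), on_axon = logical(),
                          face_ids = list()))
  dplyr::bind_rows(rows)
}

#' Filter spines by skeletal length
#'
#' Keeps spines whose skeletal length is strictly larger than
#' `min_skeletal_length` (default 700 nm, the scale above which detection is
#' benchmarked); order is preserved.
#'
#' @param spines tibble from [detect_spines()].
#' @param min_skeletal_length nm.
#' @return filtered tibble.
#' @export
filter_spines <- function(spines, min_skeletal_length = 700) {
  spines[spines$skeletal_length_nm > min_skeletal_length, , drop = FALSE]
}

#' Segment spine heads from necks
#'
#' For every spine, the radial width profile along the base-to-tip axis is
#' binned; if a local minimum below `neck_ratio` times the maximum distal
#' width exists, faces distal to it become the head and the proximal faces
#' the neck ("no neck" otherwise -- the whole spine is head).  Head volume is
#' computed by the divergence theorem over the head face set closed at the
#' cut ring.
#'
#' @param spines tibble from [detect_spines()].
#' @param mesh the scene mesh.
#' @param neck_ratio neck threshold relative to the maximum distal width
#'   (default 0.6).
#' @param nbins profile bins along the spine axis.
#' @return the spine tibble with added columns `has_neck`, `neck_length_nm`,
#'   `neck_width_nm`, `head_volume_nm3` and list-columns `head_face_ids`,
#'   `neck_face_ids`.
#' @export
segment_head_neck <- function(spines, mesh, neck_ratio = 0.6, nbins = 12) {
  if (nrow(spines) == 0) {
    spines$has_neck <- logical()
    spines$neck_length_nm <- double()
    spines$neck_width_nm <- double()
    spines$head_volume_nm3 <- double()
    spines$head_face_ids <- list()
    spines$neck_face_ids <- list()
    return(spines)
  }
  cents_all <- face_centroids(mesh)
  out <- lapply(seq_len(nrow(spines)), function(i) {
    fc <- spines$face_ids[[i]]
    base <- c(spines$base_x[i], spines$base_y[i], spines$base_z[i])
    cents <- cents_all[fc, , drop = FALSE]
    far_i <- which.max(dist_to_point(cents, base))
    axis <- cents[far_i, ] - base
    L <- vec_norm(axis)
    axis <- axis / L
    rel <- sweep(cents, 2, base)
    t <- as.vector(rel %*% axis)
    r <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
    bins <- pmin(pmax(ceiling(t / L * nbins), 1), nbins)
    prof <- vapply(seq_len(nbins), function(b)
      if (any(bins == b)) stats::median(r[bins == b]) else NA_real_,
      numeric(1))
    known <- which(!is.na(prof))
    cut_bin <- NA_integer_
    for (b in known) {
      distal <- known[known > b]
      if (length(distal) == 0) next
      if (prof[b] < neck_ratio * max(prof[distal]))
        cut_bin <- if (is.na(cut_bin) || prof[b] < prof[cut_bin]) b else cut_bin
    }
    if (!is.na(cut_bin)) {
      t_cut <- cut_bin / nbins * L
      head_sel <- t > t_cut
      head_f <- fc[head_sel]; neck_f <- fc[!head_sel]
      ring_origin <- base + axis * t_cut
      hv <- mesh_volume(mesh, faces = head_f, origin = ring_origin)
      tibble::tibble(has_neck = TRUE, neck_length_nm = t_cut,
                     neck_width_nm = 2 * stats::median(r[!head_sel]),
                     head_volume_nm3 = hv,
                     head_face_ids = list(head_f),
                     neck_face_ids = list(neck_f))
    } else {
      hv <- mesh_volume(mesh, faces = fc, origin = base)
      tibble::tibble(has_neck = FALSE, neck_length_nm = NA_real_,
                     neck_width_nm = NA_real_, head_volume_nm3 = hv,
                     head_face_ids = list(fc),
                     neck_face_ids = list(integer(0)))
    }
  })
  dplyr::bind_cols(spines, dplyr::bind_rows(out))
}

#' Propagate spine head/neck/shaft labels to synapses
#'
#' Each branch-assigned synapse is labelled `head` or `neck` when its nearest
#' face belongs to a spine's head or neck face set, `shaft` otherwise; soma
#' synapses keep `soma`.  Also fills each spine's synapse count and largest
#' synapse size.
#'
#' @param graph a `neuro_decomp` with an assigned synapse table.
#' @param spines tibble from [segment_head_neck()] (or [detect_spines()], in
#'   which case whole spines count as head).
#' @param mesh the scene mesh.
#' @return the graph, with `synapses$spine_part` and `synapses$spine_id`
#'   updated, and `spines` stored with `n_synapses` / `max_synapse_size`.
#' @export
label_synapse_spine_part <- function(graph, spines, mesh) {
  syn <- graph$synapses
  if (is.null(syn) || nrow(syn) == 0) {
    graph$spines <- spines
    return(graph)
  }
  cents_all <- face_centroids(mesh)
  part <- syn$spine_part
  spine_of <- rep(NA_integer_, nrow(syn))
  has_head_col <- "head_face_ids" %in% names(spines)
  for (i in seq_len(nrow(spines))) {
    bid <- spines$branch_id[i]
    b <- graph$branches[[bid]]
    sids <- b$synapse_ids
    if (length(sids) == 0) next
    rows <- match(sids, syn$synapse_id)
    spos <- as.matrix(syn[rows, c("x", "y", "z")])
    fc <- spines$face_ids[[i]]
    # nearest branch face per synapse: spine faces vs shaft faces
    all_f <- b$face_ids
    nf <- vapply(seq_len(nrow(spos)), function(j)
      all_f[which.min(dist_to_point(cents_all[all_f, , drop = FALSE],
                                    spos[j, ]))], integer(1))
    on_spine <- nf %in% fc
    if (!any(on_spine)) next
    head_f <- if (has_head_col) spines$head_face_ids[[i]] else fc
    neck_f <- if (has_head_col) spines$neck_face_ids[[i]] else integer(0)
    part[rows[on_spine & nf %in% head_f]] <- "head"
    part[rows[on_spine & nf %in% neck_f]] <- "neck"
    spine_of[rows[on_spine]] <- spines$spine_id[i]
  }
  syn$spine_part <- part
  syn$spine_part[syn$branch_id == 0L] <- "soma"
  syn$spine_id_assigned <- spine_of
  graph$synapses <- syn
  spines$n_synapses <- vapply(spines$spine_id, function(s)
    sum(!is.na(spine_of) & spine_of == s), integer(1))
  spines$max_synapse_size <- vapply(spines$spine_id, function(s) {
    sz <- syn$size[!is.na(spine_of) & spine_of == s]
    if (length(sz)) max(sz) else NA_real_
  }, numeric(1))
  # attach spine ids and counts to branches
  for (bid in unique(spines$branch_id))
    graph$branches[[bid]]$spine_ids <-
      spines$spine_id[spines$branch_id == bid]
  graph$spines <- spines
  graph
}

#' Spine detection precision/recall against generator ground truth
#'
#' Matches detections to ground-truth spines by face overlap: a detection
#' matches the truth spine holding the plurality of its faces when more than
#' `overlap` of the detection's faces belong to that spine.  Precision is
#' computed over detections longer than `min_len`, recall over truth spines
#' longer than `min_len`; matching itself uses all spines, so a
#' boundary-length spine is never double penalised.
#'
#' @param spines detected spine tibble (with `face_ids`, lengths).
#' @param truth_faces tibble from [face_truth_table()] for the same mesh.
#' @param truth_spines the generator's `spine_spec` (with `length_nm`).
#' @param min_len length threshold, nm (default 700).
#' @param overlap required fraction of truth faces covered (default 0.5).
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
evaluate_spine_pr <- function(spines, truth_faces, truth_spines,
                              min_len = 700, overlap = 0.5) {
  truth_sets <- split(truth_faces$face_id[!is.na(truth_faces$spine_id)],
                      truth_faces$spine_id[!is.na(truth_faces$spine_id)])
  spine_of_face <- rep(NA_integer_, max(truth_faces$face_id))
  for (ts in names(truth_sets))
    spine_of_face[truth_sets[[ts]]] <- as.integer(ts)
  match_of <- rep(NA_integer_, nrow(spines))
  for (i in seq_len(nrow(spines))) {
    fc <- spines$face_ids[[i]]
    hits <- spine_of_face[fc]
    hits <- hits[!is.na(hits)]
    if (length(hits) / length(fc) <= overlap) next
    match_of[i] <- as.integer(names(which.max(table(hits))))
  }
  det_long <- spines$skeletal_length_nm > min_len
  truth_long <- truth_spines$spine_id[truth_spines$length_nm > min_len]
  tp <- sum(det_long & !is.na(match_of))
  fp <- sum(det_long & is.na(match_of))
  fn <- sum(!(truth_long %in% match_of))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (length(truth_long) > 0)
      sum(truth_long %in% match_of) / length(truth_long) else NA_real_)
  }
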