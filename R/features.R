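# Node / subgraph / graph feature hierarchy.  Node features describe one
# non-branching segment; subgraph features describe parent-child relations
# at branch points; graph features aggregate over the whole neuron.

# Robust start/end widths: median over the proximal / distal third of the
# profile (junction-adjacent points are contaminated by the neighbour's
# faces, so single endpoint values are unreliable).
branch_end_widths <- function(branch) {
  w <- branch$width
  k <- length(w)
  m <- max(2L, min(6L, ceiling(k / 3)))
  c(stats::median(w[seq_len(min(m, k))], na.rm = TRUE),
    stats::median(w[seq(max(1, k - m + 1), k)], na.rm = TRUE))
}

# mean direction over a `window` nm of arc from one end of a branch
branch_window_direction <- function(branch, end = c("start", "end"),
                                    window = 5000) {
  end <- match.arg(end)
  P <- branch$points
  if (end == "end") P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  cum <- cumsum(seg)
  i <- which(cum >= window)[1]
  if (is.na(i)) i <- length(cum)
  d <- P[i + 1, ] - P[1, ]
  if (end == "end") d <- -d
  if (vec_norm(d) == 0) return(c(NA_real_, NA_real_, NA_real_))
  unitize(d)
}

active_branch_ids <- function(graph) {
  ids <- vapply(graph$branches, `[[`, 0L, "id")
  removed <- graph$removed %||% integer(0)
  setdiff(ids, removed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Node-level features of every branch
#'
#' One row per (active) branch: skeletal length, width summaries, synapse and
#' spine counts and densities (per um), shaft-synapse count, tortuosity
#' (arc length over endpoint chord) and the mean direction unit vector.
#'
#' @param graph a `neuro_decomp`.
#' @return a tibble, one row per branch.
#' @export
node_features <- function(graph) {
  syn <- graph$synapses
  rows <- lapply(active_branch_ids(graph), function(id) {
    b <- graph$branches[[id]]
    L <- b$skeletal_length
    if (L <= 0) stop("node_features: degenerate branch ", id)
    chord <- vec_norm(b$points[nrow(b$points), ] - b$points[1, ])
    n_syn <- length(b$synapse_ids)
    n_shaft <- if (!is.null(syn) && n_syn > 0)
      sum(syn$spine_part[match(b$synapse_ids, syn$synapse_id)] == "shaft",
          na.rm = TRUE) else 0L
    n_out <- if (!is.null(syn) && n_syn > 0)
      sum(syn$direction[match(b$synapse_ids, syn$synapse_id)] == "outgoing",
          na.rm = TRUE) else 0L
    dirv <- b$points[nrow(b$points), ] - b$points[1, ]
    dirv <- if (vec_norm(dirv) > 0) unitize(dirv) else c(NA, NA, NA)
    ends <- branch_end_widths(b)
    tibble::tibble(
      branch_id = b$id, parent_id = b$parent,
      compartment = b$compartment,
      skeletal_length_nm = L,
      width_mean_nm = mean(b$width, na.rm = TRUE),
      width_start_nm = ends[1],
      width_end_nm = ends[2],
      synapse_count = n_syn,
      synapse_density_um = n_syn / (L / 1000),
      outgoing_fraction = if (n_syn > 0) n_out / n_syn else NA_real_,
      spine_count = length(b$spine_ids),
      spine_density_um = length(b$spine_ids) / (L / 1000),
      shaft_synapse_count = n_shaft,
      tortuosity = L / max(chord, 1e-9),
      dir_x = dirv[1], dir_y = dirv[2], dir_z = dirv[3])
  })
  dplyr::bind_rows(rows)
}

#' Subgraph features of parent-child edges
#'
#' Branching angle (angle between the parent's distal mean direction and the
#' child's proximal mean direction over a `window` nm of arc; 0 = straight
#' continuation), sibling angle, width difference (child start minus parent
#' end) and the child degree at the branch point.  Edges from the root have
#' no parent direction and get `NA` angles.
#'
#' @param graph a `neuro_decomp`.
#' @param window direction-averaging window, nm.
#' @return a tibble, one row per directed edge.
#' @export
subgraph_features <- function(graph, window = 5000) {
  active <- active_branch_ids(graph)
  ed <- graph$edges[graph$edges$child %in% active, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ed)), function(i) {
    pid <- ed$parent[i]; cid <- ed$child[i]
    child <- graph$branches[[cid]]
    cdir <- branch_window_direction(child, "start", window)
    if (pid == 0L || !(pid %in% active)) {
      ang <- NA_real_; wdiff <- NA_real_
    } else {
      parent <- graph$branches[[pid]]
      pdir <- branch_window_direction(parent, "end", window)
      ang <- angle_deg(pdir, cdir)
      wdiff <- branch_end_widths(child)[1] - branch_end_widths(parent)[2]
    }
    sibs <- setdiff(intersect(decomp_children(graph, pid), active), cid)
    sib_ang <- if (length(sibs) > 0) {
      min(vapply(sibs, function(s) angle_deg(
        cdir, branch_window_direction(graph$branches[[s]], "start", window)),
        numeric(1)), na.rm = TRUE)
    } else NA_real_
    tibble::tibble(parent_id = pid, child_id = cid,
                   branching_angle_deg = ang,
                   sibling_angle_deg = sib_ang,
                   width_difference_nm = wdiff,
                   child_degree = length(intersect(
                     decomp_children(graph, pid), active)))
  })
  dplyr::bind_rows(rows)
}

#' Graph-level features of a neuron
#'
#' Totals and skeletal-length-weighted means of the node features, per-stem
#' summaries (initial width, leaf count, max depth) and soma measurements.
#'
#' @param graph a `neuro_decomp`.
#' @return list with `summary` (one-row tibble) and `stems` (tibble, one row
#'   per stem in root-child order).
#' @export
graph_features <- function(graph) {
  nf <- node_features(graph)
  w <- nf$skeletal_length_nm
  wmean <- function(x) sum(x * w, na.rm = TRUE) / sum(w[!is.na(x)])
  active <- active_branch_ids(graph)
  stems <- decomp_children(graph, 0L)
  stem_rows <- lapply(stems, function(s) {
    ids <- intersect(decomp_descendants(graph, s, include_self = TRUE), active)
    sub <- nf[nf$branch_id %in% ids, ]
    depth_of <- function(id, d = 1L) {
      ch <- intersect(decomp_children(graph, id), active)
      if (length(ch) == 0) return(d)
      max(vapply(ch, depth_of, integer(1), d = d + 1L))
    }
    tibble::tibble(
      stem_id = s,
      compartment = graph$branches[[s]]$compartment,
      initial_width_nm = nf$width_start_nm[nf$branch_id == s],
      skeletal_length_nm = sum(sub$skeletal_length_nm),
      n_branches = nrow(sub),
      n_leaves = sum(vapply(ids, function(i)
        length(intersect(decomp_children(graph, i), active)) == 0,
        logical(1))),
      max_depth = depth_of(s),
      synapse_count = sum(sub$synapse_count),
      spine_count = sum(sub$spine_count))
  })
  stems_tbl <- dplyr::bind_rows(stem_rows)
  soma <- graph$root
  summary <- tibble::tibble(
    n_branches = nrow(nf),
    n_stems = length(stems),
    n_leaves = sum(stems_tbl$n_leaves),
    total_skeletal_length_nm = sum(nf$skeletal_length_nm),
    weighted_width_nm = wmean(nf$width_mean_nm),
    weighted_synapse_density_um = wmean(nf$synapse_density_um),
    weighted_spine_density_um = wmean(nf$spine_density_um),
    weighted_tortuosity = wmean(nf$tortuosity),
    total_synapses = sum(nf$synapse_count) + length(soma$synapse_ids),
    total_spines = sum(nf$spine_count),
    soma_synapse_count = length(soma$synapse_ids),
    soma_radius_nm = soma$radius,
    soma_volume_nm3 = if (!is.null(soma$soma)) soma$soma$volume_nm3 else
      4 / 3 * pi * soma$radius^3,
    soma_area_nm2 = if (!is.null(soma$soma)) soma$soma$area_nm2 else
      4 * pi * soma$radius^2)
  list(summary = summary, stems = stems_tbl)
}

#' Write a feature table as CSV with a units header
#'
#' @param features a tibble from [node_features()], [subgraph_features()] or
#'   [graph_features()].
#' @param path output path.
#' @param units unit annotation written as a `# units:` comment line.
#' @export
write_feature_csv <- function(features, path,
                              units = "nm for lengths/widths, per-um for densities") {
  con <- file(path, "w")
  writeLines(paste0("# units: ", units), con)
  close(con)
  readr::write_csv(features, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
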