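# Automated proofreading: ordered heuristic graph filters locate merge
# errors, everything downstream of a flagged node is stripped back to the
# "sea of unconnected fragments", every edit is logged with its rule and
# parameters, and retained synapses are scored against ground truth.

#' Double-back rule
#'
#' Flags branches that turn sharply back toward the soma: branching angle
#' against the parent above `angle_threshold_deg` AND mean direction pointing
#' back at the soma (negative dot product with the soma-to-branch-point
#' direction).  Branches shorter than `min_length_nm` are ignored.
#'
#' @param graph a `neuro_decomp` (compartments labelled, or run
#'   class-agnostically with `compartment = NULL`).
#' @param compartment `"axon"`, `"dendrite"` or `NULL` for any.
#' @param angle_threshold_deg flag above this branching angle (default 120).
#' @param min_length_nm minimum branch length considered (default 4000).
#' @return integer vector of flagged branch ids.
#' @export
rule_double_back <- function(graph, compartment = "axon",
                             angle_threshold_deg = 120,
                             min_length_nm = 4000) {
  sg <- subgraph_features(graph)
  flags <- integer(0)
  for (i in seq_len(nrow(sg))) {
    cid <- sg$child_id[i]
    b <- graph$branches[[cid]]
    if (!is.null(compartment) && !is.na(b$compartment)) {
      comp_class <- if (b$compartment %in% c("axon", "AIS")) "axon" else
        "dendrite"
      if (!(comp_class %in% compartment)) next
    }
    if (b$skeletal_length < min_length_nm) next
    ang <- sg$branching_angle_deg[i]
    if (is.na(ang) || ang <= angle_threshold_deg) next
    mean_dir <- b$points[nrow(b$points), ] - b$points[1, ]
    soma_dir <- b$points[1, ] - graph$root$center
    if (sum(mean_dir * soma_dir) < 0) flags <- c(flags, cid)
  }
  sort(unique(flags))
}

#' Width-jump rule
#'
#' Flags children whose starting width exceeds the parent's ending width by
#' more than `jump_threshold_nm` -- the signature of a thin process merged
#' onto a thick foreign dendrite.  `direction = "either"` also flags sharp
#' decreases.
#'
#' @param graph a `neuro_decomp` with widths.
#' @param jump_threshold_nm threshold in nm (default 500).
#' @param direction `"increase"` (default) or `"either"`.
#' @return integer vector of flagged branch ids.
#' @export
rule_width_jump <- function(graph, jump_threshold_nm = 500,
                            direction = c("increase", "either")) {
  direction <- match.arg(direction)
  sg <- subgraph_features(graph)
  d <- sg$width_difference_nm
  # the jump must be sustained over the branch bodies, not only at the
  # junction, where width estimates are contaminated by the neighbour
  dmean <- vapply(seq_len(nrow(sg)), function(i) {
    if (sg$parent_id[i] == 0L) return(NA_real_)
    mean(graph$branches[[sg$child_id[i]]]$width, na.rm = TRUE) -
      mean(graph$branches[[sg$parent_id[i]]]$width, na.rm = TRUE)
  }, numeric(1))
  hit <- if (direction == "increase")
    !is.na(d) & d > jump_threshold_nm &
      !is.na(dmean) & dmean > 0.5 * jump_threshold_nm
  else !is.na(d) & abs(d) > jump_threshold_nm &
    !is.na(dmean) & abs(dmean) > 0.5 * jump_threshold_nm
  sort(unique(sg$child_id[hit]))
}

#' Axon degree rule
#'
#' Flags the children at axonal branch points with more than `max_children`
#' children (high-degree crossings typical of axon-axon welds), plus a
#' low-degree crossover variant: at any axonal branch point, a pair of
#' children forming a near-collinear throughway (pass-through deviation
#' below `crossover_angle_deg`) that is not the continuation of the parent
#' is flagged as a foreign axon passing through.
#'
#' @param graph a `neuro_decomp`.
#' @param max_children maximum allowed children (default 3).
#' @param crossover_angle_deg pass-through deviation threshold (default 35).
#' @param axon_only restrict to branches labelled axon/AIS when labels exist.
#' @return integer vector of flagged branch ids.
#' @export
rule_axon_degree <- function(graph, max_children = 3,
                             crossover_angle_deg = 35, axon_only = TRUE) {
  flags <- integer(0)
  active <- active_branch_ids(graph)
  comp <- vapply(graph$branches, `[[`, "", "compartment")
  labelled <- !all(is.na(comp))
  is_axonal <- function(id) {
    if (id == 0L) return(FALSE)
    !labelled || !axon_only || isTRUE(comp[id] %in% c("axon", "AIS"))
  }
  parents <- unique(graph$edges$parent)
  for (pid in setdiff(parents, 0L)) {
    if (!(pid %in% active) || !is_axonal(pid)) next
    ch <- decomp_children(graph, pid)
    if (length(ch) > max_children) flags <- c(flags, ch)
    if (length(ch) >= 2) {
      # effective children: a crossing often skeletonizes as two nearby
      # degree-3 points; look through short connector branches so both
      # foreign arms are seen at one junction
      eff <- list()
      for (cid in ch) {
        eff[[length(eff) + 1]] <- cid
        if (graph$branches[[cid]]$skeletal_length < 4000)
          for (g2 in decomp_children(graph, cid))
            eff[[length(eff) + 1]] <- g2
      }
      eff <- unlist(eff)
      pdir <- branch_window_direction(graph$branches[[pid]], "end")
      dirs <- lapply(eff, function(cid)
        branch_window_direction(graph$branches[[cid]], "start"))
      cont <- vapply(dirs, function(dd) {
        a <- angle_deg(pdir, dd); !is.na(a) && a < crossover_angle_deg
      }, logical(1))
      for (i in seq_along(eff)) for (j in seq_along(eff)) {
        if (j <= i) next
        if (graph$branches[[eff[j]]]$parent == eff[i]) next
        dev <- 180 - angle_deg(dirs[[i]], dirs[[j]])
        if (!is.na(dev) && dev < crossover_angle_deg &&
            !cont[i] && !cont[j])
          flags <- c(flags, eff[i], eff[j])
      }
    }
  }
  sort(unique(flags))
}

#' Axon-on-dendrite rule
#'
#' Flags subtrees hanging off dendritic branches whose aggregate profile is
#' axon-like: spine density at most `max_spine_density` per um, outgoing
#' synapse fraction at least `min_outgoing_fraction`, and mean width below
#' the host dendrite's.  Subtrees without synapses are never flagged
#' (insufficient evidence).
#'
#' @param graph a `neuro_decomp` with spines and synapse directions.
#' @param max_spine_density per um (default 0.2).
#' @param min_outgoing_fraction fraction in 0-1 (default 0.75).
#' @param min_synapses minimum synapses in the subtree to act (default 3).
#' @return integer vector of flagged branch ids (subtree roots).
#' @export
rule_axon_on_dendrite <- function(graph, max_spine_density = 0.2,
                                  min_outgoing_fraction = 0.75,
                                  min_synapses = 3) {
  flags <- integer(0)
  syn <- graph$synapses
  if (is.null(syn) || nrow(syn) == 0) return(flags)
  comp <- vapply(graph$branches, `[[`, "", "compartment")
  dend <- c("basal", "apical", "oblique")
  for (pid in active_branch_ids(graph)) {
    if (!is.na(comp[pid]) && !(comp[pid] %in% dend)) next
    host <- graph$branches[[pid]]
    host_w <- mean(host$width, na.rm = TRUE)
    for (cid in decomp_children(graph, pid)) {
      ids <- decomp_descendants(graph, cid, include_self = TRUE)
      bs <- graph$branches[ids]
      L_um <- sum(vapply(bs, `[[`, 0, "skeletal_length")) / 1000
      n_sp <- sum(vapply(bs, function(b) length(b$spine_ids), integer(1)))
      sids <- unlist(lapply(bs, `[[`, "synapse_ids"))
      if (length(sids) < min_synapses) next
      dirs <- syn$direction[match(sids, syn$synapse_id)]
      out_frac <- mean(dirs == "outgoing", na.rm = TRUE)
      mean_w <- stats::weighted.mean(
        vapply(bs, function(b) mean(b$width, na.rm = TRUE), numeric(1)),
        vapply(bs, `[[`, 0, "skeletal_length"))
      if (n_sp / L_um <= max_spine_density &&
          out_frac >= min_outgoing_fraction && mean_w < host_w)
        flags <- c(flags, cid)
    }
  }
  sort(unique(flags))
}

PROOFREAD_RULES <- list(
  axon_on_dendrite = rule_axon_on_dendrite,
  axon_degree = rule_axon_degree,
  double_back = rule_double_back,
  width_jump = rule_width_jump)

#' Default proofreading rule stack
#'
#' Coarse-to-fine: whole foreign subtrees first (axon-on-dendrite), then
#' axon-degree crossings, then local geometry (double-back, width-jump).
#'
#' @return named list of rule configurations for [apply_filters()].
#' @export
default_rules <- function() {
  list(
    list(rule = "axon_on_dendrite"),
    list(rule = "axon_degree"),
    list(rule = "double_back"),
    list(rule = "width_jump"))
}

#' Apply an ordered stack of proofreading filters
#'
#' Rules run in the given order; after each rule, every flagged node and its
#' descendant closure are removed before the next rule runs.  Removed
#' synapses are marked invalid (`valid_pred = FALSE`), and every edit is
#' recorded with its rule, parameter snapshot, cut location, removed nodes,
#' synapses and skeletal length.
#'
#' @param graph a decomposed, featured `neuro_decomp`.
#' @param rules list of `list(rule = "<name>", ...params)` entries; see
#'   [default_rules()].
#' @return list with `graph` (edited) and `edits` (tibble of edit records
#'   with list-columns `removed_branches`, `removed_synapses`).
#' @export
apply_filters <- function(graph, rules = default_rules()) {
  for (rc in rules)
    if (!rc$rule %in% names(PROOFREAD_RULES))
      stop("unknown proofreading rule '", rc$rule, "'; available: ",
           paste(names(PROOFREAD_RULES), collapse = ", "))
  if (!is.null(graph$synapses) && !("valid_pred" %in% names(graph$synapses)))
    graph$synapses$valid_pred <- TRUE
  edits <- list()
  for (rc in rules) {
    fn <- PROOFREAD_RULES[[rc$rule]]
    params <- rc[setdiff(names(rc), "rule")]
    flagged <- do.call(fn, c(list(graph), params))
    flagged <- setdiff(flagged, graph$removed)
    for (fid in flagged) {
      if (fid %in% graph$removed) next    # removed by an earlier flag
      closure <- decomp_descendants(graph, fid, include_self = TRUE)
      closure <- setdiff(closure, graph$removed)
      syn_rm <- unlist(lapply(graph$branches[closure], `[[`, "synapse_ids"))
      len_rm <- sum(vapply(graph$branches[closure], `[[`, 0,
                           "skeletal_length"))
      cut <- graph$branches[[fid]]$points[1, ]
      graph$removed <- sort(union(graph$removed, closure))
      if (!is.null(graph$synapses) && length(syn_rm) > 0)
        graph$synapses$valid_pred[
          graph$synapses$synapse_id %in% syn_rm] <- FALSE
      edits[[length(edits) + 1]] <- tibble::tibble(
        rule = rc$rule,
        params = list(params),
        flagged_branch = fid,
        cut_x = cut[1], cut_y = cut[2], cut_z = cut[3],
        n_removed_branches = length(closure),
        removed_branches = list(closure),
        removed_synapses = list(as.integer(syn_rm)),
        removed_skeletal_length_nm = len_rm)
    }
  }
  graph$log <- c(graph$log,
                 sprintf("proofreading: %d edit(s) across %d rule(s)",
                         length(edits), length(rules)))
  list(graph = graph,
       edits = if (length(edits)) dplyr::bind_rows(edits) else
         tibble::tibble(rule = character(), flagged_branch = integer(),
                        n_removed_branches = integer(),
                        removed_skeletal_length_nm = double(),
                        removed_branches = list(),
                        removed_synapses = list()))
}

#' Synapse-level precision and recall
#'
#' Compares the set of synapses retained as valid against the ground-truth
#' valid set: precision is the number of actually true synapses labelled
#' true over all synapses labelled true; recall is the number of correctly
#' retained synapses over all true synapses.
#'
#' @param predicted vector of synapse ids predicted valid.
#' @param truth vector of synapse ids actually valid.
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`
#'   (`precision` is `NA` when nothing is predicted valid).
#' @export
evaluate_synapse_pr <- function(predicted, truth) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Stratified synapse precision/recall
#'
#' @param synapses a synapse tibble with logical `valid_pred` and `valid`
#'   columns (prediction and ground truth).
#' @param by character vector of grouping columns (e.g. `"compartment"`).
#' @return tibble with one row per stratum plus the PR columns.
#' @export
evaluate_synapse_pr_by <- function(synapses, by = "compartment") {
  synapses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key)
      evaluate_synapse_pr(d$synapse_id[d$valid_pred], d$synapse_id[d$valid])) |>
    dplyr::ungroup()
}

#' Write an edit log as JSON lines
#'
#' @param edits tibble from [apply_filters()].
#' @param path output path; one JSON object per line.
#' @export
write_edit_log <- function(edits, path) {
  lines <- vapply(seq_len(nrow(edits)), function(i)
    jsonlite::toJSON(as.list(edits[i, , drop = FALSE]), auto_unbox = TRUE,
                     digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}
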