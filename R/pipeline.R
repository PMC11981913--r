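# End-to-end orchestration: preprocess -> decompose -> features -> spines
# -> classify -> proofread -> proximity -> motifs, with checkpointed
# artifacts, a structured run log, and an evaluation harness against
# synthetic ground truth.

#' Default pipeline configuration
#'
#' Every threshold of the pipeline with its default, plus stage toggles,
#' seed and I/O paths.  All lengths are nm (SWC output alone uses um).
#' Unknown keys are rejected.
#'
#' @param ... overrides.
#' @return named configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    units = "nm",
    # inputs: either a preset or explicit files
    preset = "single",           # synth preset name, or NA to read files
    mesh_file = NA_character_,
    synapse_file = NA_character_,
    cell_class = "excitatory",
    depth_axis = c(0, 0, 1),
    # stage toggles
    do_spines = TRUE, do_classify = TRUE, do_proofread = TRUE,
    do_proximity = FALSE, do_motifs = FALSE,
    # thresholds
    soma_min_radius = 2500, soma_compactness = 0.7,
    skeleton_step = 1000, skeleton_prune = 4000,
    spine_shaft_factor = 1.4, spine_min_faces = 20,
    spine_min_length = 700, spine_neck_ratio = 0.6,
    rule_angle_threshold = 120, rule_width_jump = 500,
    rule_max_children = 3, rule_crossover_angle = 35,
    rule_max_spine_density = 0.2, rule_min_outgoing_fraction = 0.75,
    proximity_radius = 5000, proximity_min_gap = 10000,
    ais_window = 50000,
    out_dir = NA_character_)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @param cfg configuration list.
#' @return `read_config()` returns a validated configuration list.
#' @export
read_config <- function(path) do.call(pipeline_config, yaml::read_yaml(path))

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the stages in fixed order on a synthetic preset scene (or a
#' mesh + synapse CSV pair), checkpointing each stage's outputs into
#' `out_dir`: decomposition JSON, SWC, feature CSVs, spine CSV, edit-log
#' JSONL, synapse PR CSV and a run log.  Reruns with the same config and
#' inputs are seed-stable.
#'
#' @param cfg configuration from [pipeline_config()].
#' @return (invisibly) a list with the scene, graphs, spines, edits and the
#'   output directory.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  out <- cfg$out_dir
  if (is.na(out)) out <- tempfile("neurodecomp_run_")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  stage <- function(name, expr) {
    logline("stage=%s status=start", name)
    val <- tryCatch(force(expr), error = function(e) {
      logline("stage=%s status=error message=%s", name, conditionMessage(e))
      stop("pipeline halted in stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
    logline("stage=%s status=ok", name)
    val
  }

  scene <- stage("input", {
    if (!is.na(cfg$preset)) {
      synth_preset(cfg$preset, seed = cfg$seed)
    } else {
      mesh <- if (grepl("\\.ply$", cfg$mesh_file)) read_ply(cfg$mesh_file)
              else read_off(cfg$mesh_file)
      syn <- read_synapse_csv(cfg$synapse_file)
      list(mesh = mesh, labels = NULL, neurons = list(), synapses = syn,
           error_truth = NULL)
    }
  })

  somas <- stage("preprocess", {
    m <- clean_mesh(scene$mesh)
    scene$mesh <- m
    detect_somas(m, min_radius = cfg$soma_min_radius,
                 compactness_threshold = cfg$soma_compactness)
  })
  if (length(somas) == 0)
    stop("pipeline: no soma detected; component is a fragment")
  sk <- stage("skeletonize",
              skeletonize(scene$mesh, somas, step = cfg$skeleton_step,
                          prune = cfg$skeleton_prune))
  co <- stage("correspondence", mesh_correspondence(scene$mesh, sk))

  graphs <- stage("decompose", {
    if (length(somas) >= 2) {
      split_multi_soma(sk, somas, co, scene$synapses)$graphs
    } else {
      list(decompose(sk, co, somas[[1]], scene$synapses))
    }
  })

  spines_all <- list(); edits_all <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    if (isTRUE(cfg$do_spines)) {
      g <- stage(paste0("spines_", gi), {
        sp <- detect_spines(g, scene$mesh,
                            shaft_factor = cfg$spine_shaft_factor,
                            min_faces = cfg$spine_min_faces)
        sp <- segment_head_neck(sp, scene$mesh,
                                neck_ratio = cfg$spine_neck_ratio)
        label_synapse_spine_part(g, sp, scene$mesh)
      })
      spines_all[[gi]] <- g$spines
    }
    if (isTRUE(cfg$do_classify))
      g <- stage(paste0("classify_", gi),
                 label_compartments(g, cfg$cell_class,
                                    depth_axis = cfg$depth_axis,
                                    ais_window = cfg$ais_window))
    if (isTRUE(cfg$do_proofread)) {
      pres <- stage(paste0("proofread_", gi), apply_filters(g, list(
        list(rule = "axon_on_dendrite",
             max_spine_density = cfg$rule_max_spine_density,
             min_outgoing_fraction = cfg$rule_min_outgoing_fraction),
        list(rule = "axon_degree", max_children = cfg$rule_max_children,
             crossover_angle_deg = cfg$rule_crossover_angle),
        list(rule = "double_back",
             angle_threshold_deg = cfg$rule_angle_threshold),
        list(rule = "width_jump",
             jump_threshold_nm = cfg$rule_width_jump))))
      g <- pres$graph
      edits_all[[gi]] <- pres$edits
    }
    graphs[[gi]] <- g
  }

  stage("export", {
    for (gi in seq_along(graphs)) {
      g <- graphs[[gi]]
      export_swc(g, file.path(out, sprintf("neuron_%d.swc", gi)))
      write_feature_csv(node_features(g),
                        file.path(out, sprintf("node_features_%d.csv", gi)))
      write_feature_csv(subgraph_features(g),
                        file.path(out, sprintf("subgraph_features_%d.csv", gi)))
      gf <- graph_features(g)
      write_feature_csv(gf$summary,
                        file.path(out, sprintf("graph_features_%d.csv", gi)))
      jsonlite::write_json(decomp_to_json(g),
                           file.path(out, sprintf("graph_%d.json", gi)),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(g$synapses))
        readr::write_csv(dplyr::select(g$synapses, -dplyr::any_of("face_ids")),
                         file.path(out, sprintf("synapses_%d.csv", gi)))
      if (!is.null(g$spines) && nrow(g$spines) > 0)
        readr::write_csv(spine_table(g$spines),
                         file.path(out, sprintf("spines_%d.csv", gi)))
    }
    if (length(edits_all) > 0) {
      ed <- dplyr::bind_rows(edits_all)
      if (nrow(ed) > 0) write_edit_log(ed, file.path(out, "edits.jsonl"))
    }
    TRUE
  })
  logline("stage=done graphs=%d", length(graphs))
  invisible(list(scene = scene, somas = somas, skeleton = sk,
                 graphs = graphs, spines = spines_all,
                 edits = if (length(edits_all)) dplyr::bind_rows(edits_all)
                         else NULL,
                 out_dir = out))
}

# flat spine CSV (list-columns dropped)
spine_table <- function(spines) {
  dplyr::select(spines, -dplyr::any_of(c("face_ids", "head_face_ids",
                                         "neck_face_ids")))
}

# JSON checkpoint of a decomposition graph
decomp_to_json <- function(g) {
  list(
    root = list(center = g$root$center, radius = g$root$radius,
                n_synapses = length(g$root$synapse_ids)),
    branches = lapply(active_branch_ids(g), function(id) {
      b <- g$branches[[id]]
      list(id = b$id, parent = b$parent,
           skeletal_length_nm = b$skeletal_length,
           compartment = b$compartment,
           n_points = nrow(b$points),
           points = unname(apply(b$points, 1, as.numeric, simplify = FALSE)),
           width = as.numeric(b$width),
           synapse_ids = as.integer(b$synapse_ids),
           spine_ids = as.integer(b$spine_ids))
    }),
    edges = list(parent = g$edges$parent, child = g$edges$child),
    removed = g$removed,
    log = g$log)
}

#' Read / write a synapse table CSV
#'
#' Columns: `synapse_id`, `pre_id`, `post_id`, `x`, `y`, `z` (nm), `size`
#' (cleft voxels) and optional annotation columns (`branch_id`,
#' `direction`, `compartment`, `spine_part`, `valid` as 0/1).
#'
#' @param path file path.
#' @param synapses synapse tibble.
#' @return `read_synapse_csv()` returns a tibble with `valid` as logical.
#' @export
read_synapse_csv <- function(path) {
  syn <- readr::read_csv(path, show_col_types = FALSE)
  if ("valid" %in% names(syn)) syn$valid <- as.logical(syn$valid)
  syn
}

#' @rdname read_synapse_csv
#' @export
write_synapse_csv <- function(synapses, path) {
  syn <- dplyr::mutate(synapses, valid = as.integer(valid))
  readr::write_csv(syn, path)
  invisible(path)
}

#' Evaluate a pipeline run against synthetic ground truth
#'
#' Computes the quantities the synthetic benchmark defines: synapse
#' precision/recall (overall and per compartment), spine precision/recall
#' above the length threshold, soma-detection counts, merge-error hit rate
#' and clean skeletal length removed.
#'
#' @param result the list returned by [run_pipeline()] (or an equivalent
#'   assembly of graphs/edits/scene).
#' @param min_spine_len spine benchmark threshold (nm, default 700).
#' @return a nested list (JSON-ready report).
#' @export
evaluate_run <- function(result, min_spine_len = 700) {
  scene <- result$scene
  if (is.null(scene$error_truth))
    stop("evaluate_run needs a synthetic scene with ground truth")
  graphs <- result$graphs
  syn_all <- dplyr::bind_rows(lapply(graphs, function(g) g$synapses))
  pr <- evaluate_synapse_pr(syn_all$synapse_id[syn_all$valid_pred %||% TRUE],
                            syn_all$synapse_id[syn_all$valid])
  report <- list(
    n_graphs = length(graphs),
    n_somas_detected = length(result$somas),
    n_somas_true = length(scene$neurons),
    synapse_pr = as.list(pr))
  # spine PR against truth (single-neuron scenes)
  if (length(scene$neurons) == 1 && !is.null(scene$labels) &&
      !is.null(graphs[[1]]$spines)) {
    ftt <- face_truth_table(scene$labels)
    spr <- evaluate_spine_pr(graphs[[1]]$spines, ftt,
                             scene$neurons[[1]]$spine_spec,
                             min_len = min_spine_len)
    report$spine_pr <- as.list(spr)
  }
  # merge-error hit rate: an error is hit when any edit removed >= 1 of its
  # invalid synapses or cut within its welded subtree
  if (!is.null(result$edits) && nrow(scene$error_truth) > 0) {
    hit <- vapply(seq_len(nrow(scene$error_truth)), function(i) {
      eid <- scene$error_truth$error_id[i]
      err_syn <- scene$synapses$synapse_id[
        !is.na(scene$synapses$error_id) & scene$synapses$error_id == eid]
      removed <- unlist(result$edits$removed_synapses)
      length(intersect(err_syn, removed)) > 0
    }, logical(1))
    report$error_hit_rate <- mean(hit)
    # clean length over-removal
    clean_removed <- 0
    for (gi in seq_along(graphs)) {
      g <- graphs[[gi]]
      for (rid in g$removed) {
        b <- g$branches[[rid]]
        sids <- b$synapse_ids
        truth_valid <- scene$synapses$valid[match(sids,
                                                  scene$synapses$synapse_id)]
        if (length(sids) == 0 || mean(truth_valid, na.rm = TRUE) > 0.5)
          clean_removed <- clean_removed + b$skeletal_length
      }
    }
    total_clean <- sum(vapply(scene$neurons, function(nr)
      sum(nr$branch_lengths), numeric(1)))
    report$clean_length_removed_fraction <-
      if (total_clean > 0) clean_removed / total_clean else 0
  }
  report
}
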