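# end-to-end preprocessing for a scene, shared by the rule tests
scene_graph <- function(scene, cell_class = "excitatory") {
  so <- detect_somas(scene$mesh)
  sk <- skeletonize(scene$mesh, so)
  co <- mesh_correspondence(scene$mesh, sk)
  g <- decompose(sk, co, so[[1]], scene$synapses)
  sp <- detect_spines(g, scene$mesh)
  g <- label_synapse_spine_part(g, sp, scene$mesh)
  label_compartments(g, cell_class)
}

test_that("each rule family catches its injected error and spares clean cells", {
  cases <- list(
    list(type = "axon_on_dendrite", rules = c("axon_on_dendrite")),
    list(type = "double_back", rules = c("double_back")),
    list(type = "width_jump", rules = c("width_jump")),
    list(type = "axon_on_axon", rules = c("axon_degree")))
  for (case in cases) {
    sc <- synth_preset("single", seed = 11, spine_density = 0.8)
    sc <- inject_merge_error(sc, case$type, seed = 9)
    g <- scene_graph(sc)
    res <- apply_filters(g)
    expect_gt(nrow(res$edits), 0, label = case$type)
    expect_true(any(res$edits$rule %in% case$rules), label = case$type)
    syn <- res$graph$synapses
    pr <- evaluate_synapse_pr(syn$synapse_id[syn$valid_pred],
                              syn$synapse_id[syn$valid])
    expect_gt(pr$precision, 0.95, label = case$type)
    expect_gt(pr$recall, 0.95, label = case$type)
  }
})

test_that("double-back needs both the angle and the soma-ward heading", {
  sc <- synth_preset("single", seed = 11, spine_density = 0.8)
  sc <- inject_merge_error(sc, "double_back", seed = 9)
  g <- scene_graph(sc)
  expect_gt(length(rule_double_back(g, angle_threshold_deg = 120)), 0)
  # a vacuous threshold flags nothing on any input
  expect_length(rule_double_back(g, angle_threshold_deg = 181), 0)
})

test_that("width-jump respects direction mode and an infinite threshold", {
  sc <- synth_preset("single", seed = 11, spine_density = 0.8)
  sc <- inject_merge_error(sc, "width_jump", seed = 9)
  g <- scene_graph(sc)
  expect_gt(length(rule_width_jump(g, 500)), 0)
  expect_length(rule_width_jump(g, Inf), 0)
  # ordinary taper (decrease) is not an increase-mode jump
  clean <- scene_graph(synth_preset("single", seed = 11,
                                    spine_density = 0.8))
  expect_length(rule_width_jump(clean, 500), 0)
})

test_that("axon-degree flags excess children at a branch point", {
  # synthetic star: one axon parent with five children
  p1 <- cbind(0, 0, seq(0, 10000, 1000))
  branches <- list(list(
    id = 1L, parent = 0L, point_ids = 1, points = p1,
    skeletal_length = 10000, width = rep(600, nrow(p1)),
    face_ids = integer(0), synapse_ids = integer(0),
    spine_ids = integer(0), compartment = "axon"))
  dirs <- rbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
                c(1, 1, 1))
  for (k in 1:5) {
    pk <- sweep(outer(seq(0, 8000, 1000), neurodecomp:::unitize(dirs[k, ])),
                2, c(0, 0, 10000), "+")
    branches[[k + 1]] <- list(
      id = k + 1L, parent = 1L, point_ids = 1, points = pk,
      skeletal_length = 8000, width = rep(600, nrow(pk)),
      face_ids = integer(0), synapse_ids = integer(0),
      spine_ids = integer(0), compartment = "axon")
  }
  g <- structure(list(
    root = list(center = c(0, 0, -2000), radius = 1000, soma = NULL,
                face_ids = integer(0), synapse_ids = integer(0)),
    branches = branches,
    edges = tibble::tibble(parent = c(0L, rep(1L, 5)), child = 1:6),
    synapses = NULL, removed = integer(0), log = character(0)),
    class = "neuro_decomp")
  expect_setequal(rule_axon_degree(g, max_children = 3), 2:6)
  # a binary arbor is fine
  g$edges <- g$edges[1:3, ]
  expect_length(rule_axon_degree(g, max_children = 3), 0)
})

test_that("axon-on-dendrite requires synaptic evidence", {
  sc <- synth_preset("orphan-axon", seed = 3)
  g <- scene_graph(sc)
  expect_gt(length(rule_axon_on_dendrite(g)), 0)
  # spiny side branches are never flagged
  clean <- scene_graph(synth_preset("single", seed = 7))
  expect_length(rule_axon_on_dendrite(clean), 0)
  # no synapses anywhere -> no evidence -> no flags
  g0 <- clean
  g0$synapses <- NULL
  expect_length(rule_axon_on_dendrite(g0), 0)
})

test_that("apply_filters strips exact closures and keeps the audit complete", {
  sc <- synth_preset("orphan-axon", seed = 5)
  g <- scene_graph(sc)
  expect_error(apply_filters(g, list(list(rule = "no_such_rule"))),
               "unknown proofreading rule")
  # empty stack: identity
  res0 <- apply_filters(g, list())
  expect_equal(nrow(res0$edits), 0)
  expect_length(res0$graph$removed, 0)

  res <- apply_filters(g)
  for (i in seq_len(nrow(res$edits))) {
    fid <- res$edits$flagged_branch[i]
    expect_setequal(
      res$edits$removed_branches[[i]],
      neurodecomp:::decomp_descendants(g, fid, include_self = TRUE))
  }
  # audit completeness: removed synapse ids == synapses flipped invalid
  flipped <- res$graph$synapses$synapse_id[!res$graph$synapses$valid_pred]
  expect_setequal(unlist(res$edits$removed_synapses), flipped)
  # removals disjoint across edits
  all_removed <- unlist(res$edits$removed_branches)
  expect_equal(anyDuplicated(all_removed), 0)
})

test_that("proofreading is monotone and idempotent across scenes", {
  for (sd in c(2, 4)) {
    sc <- synth_preset("single", seed = sd, spine_density = 0.8)
    sc <- inject_merge_error(sc, "axon_on_dendrite", seed = sd + 1)
    sc <- inject_merge_error(sc, "double_back", seed = sd + 2)
    g <- scene_graph(sc)
    truth <- g$synapses$synapse_id[g$synapses$valid]
    stack <- default_rules()
    prev_fp <- Inf; prev_recall <- Inf
    for (k in seq_along(stack)) {
      res_k <- apply_filters(g, stack[seq_len(k)])
      syn <- res_k$graph$synapses
      pr <- evaluate_synapse_pr(syn$synapse_id[syn$valid_pred], truth)
      # more rules: FP and recall never increase
      expect_lte(pr$fp, prev_fp)
      expect_lte(pr$recall, prev_recall)
      prev_fp <- pr$fp; prev_recall <- pr$recall
    }
    # idempotence: a second pass over the edited graph makes no new edits
    res1 <- apply_filters(g)
    res2 <- apply_filters(res1$graph)
    expect_equal(nrow(res2$edits), 0)
  }
})

test_that("synapse precision/recall arithmetic matches its definitions", {
  pr <- evaluate_synapse_pr(1:10, 1:10)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  pr2 <- evaluate_synapse_pr(integer(0), 1:5)
  expect_true(is.na(pr2$precision))
  expect_equal(pr2$fn, 5)
  pr3 <- evaluate_synapse_pr(c(1:6, 90:93), 1:8)
  expect_equal(pr3$precision, 0.6)
  expect_equal(pr3$recall, 0.75)
  # stratified version agrees with pooled counts
  syn <- tibble::tibble(synapse_id = 1:20,
                        compartment = rep(c("axon", "basal"), each = 10),
                        valid = rep(c(TRUE, FALSE), 10),
                        valid_pred = c(rep(TRUE, 15), rep(FALSE, 5)))
  st <- evaluate_synapse_pr_by(syn, "compartment")
  expect_equal(nrow(st), 2)
  expect_equal(sum(st$tp),
               evaluate_synapse_pr(syn$synapse_id[syn$valid_pred],
                                   syn$synapse_id[syn$valid])$tp)
})
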