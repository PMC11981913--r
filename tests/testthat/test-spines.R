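test_that("spine detection matches generator spines and ignores smooth tubes", {
  px <- std_neuron_pipeline()
  sp <- detect_spines(px$graph, px$meshed$mesh)
  expect_gt(nrow(sp), 0)
  ft <- face_truth_table(px$meshed$labels)
  pr <- evaluate_spine_pr(sp, ft, px$neuron$spine_spec, min_len = 0)
  # every long detection maps to a distinct truth spine
  expect_gt(pr$precision, 0.85)

  # smooth cylinder: no spines
  tm <- cyl_mesh(20000, 600, resolution = 12)
  sk <- skeletonize(tm, NULL, step = 1000, prune = 0)
  co <- mesh_correspondence(tm, sk)
  g <- decompose(sk, co)
  expect_equal(nrow(detect_spines(g, tm)), 0)
})

test_that("stubby spine height is recovered within 20%", {
  # one stubby hemisphere (r = 600) on a smooth dendrite
  n <- generate_neuron(neuron_params(spine_density = 0, syn_soma_mean = 0,
                                     n_stems = 1, depth = 0,
                                     has_axon = FALSE, apical = FALSE,
                                     segment_length = c(30000, 30000)),
                       seed = 3)
  n$spine_spec <- tibble::tibble(
    spine_id = 1L, branch_id = 1L, type = "stubby",
    base_x = NA, base_y = NA, base_z = NA, dir_x = NA, dir_y = NA,
    dir_z = NA, head_radius = 600, neck_radius = NA_real_,
    neck_length = 0, length_nm = 600, head_volume_nm3 = 2 / 3 * pi * 600^3)
  loc <- neurodecomp:::branch_point_at_arc(n$skeleton$points,
                                           n$branches[[1]], 15000)
  radial <- neurodecomp:::orthogonal_unit(loc$tangent)
  base <- loc$point + radial * loc$radius
  n$spine_spec[1, c("base_x", "base_y", "base_z")] <- as.list(base)
  n$spine_spec[1, c("dir_x", "dir_y", "dir_z")] <- as.list(radial)
  mm <- mesh_from_neuron(n, resolution = 12)
  so <- detect_somas(mm$mesh)
  sk <- skeletonize(mm$mesh, so)
  co <- mesh_correspondence(mm$mesh, sk)
  g <- decompose(sk, co, so[[1]])
  sp <- detect_spines(g, mm$mesh)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$skeletal_length_nm - 600) / 600, 0.2)
})

test_that("length filter is strict and order preserving", {
  sp <- tibble::tibble(spine_id = 1:3, skeletal_length_nm = c(600, 700, 800))
  kept <- filter_spines(sp, 700)
  expect_equal(kept$spine_id, 3L)
  expect_equal(filter_spines(sp, 0), sp)
  expect_equal(nrow(filter_spines(sp[0, ], 700)), 0)
})

test_that("head/neck segmentation: mushroom splits, stubby does not", {
  # dedicated mushroom at higher head resolution for the volume check
  n <- generate_neuron(neuron_params(spine_density = 0, syn_soma_mean = 0,
                                     n_stems = 1, depth = 0,
                                     has_axon = FALSE, apical = FALSE,
                                     segment_length = c(30000, 30000)),
                       seed = 5)
  loc <- neurodecomp:::branch_point_at_arc(n$skeleton$points,
                                           n$branches[[1]], 15000)
  radial <- neurodecomp:::orthogonal_unit(loc$tangent)
  base <- loc$point + radial * loc$radius
  n$spine_spec <- tibble::tibble(
    spine_id = 1L, branch_id = 1L, type = "mushroom",
    base_x = base[1], base_y = base[2], base_z = base[3],
    dir_x = radial[1], dir_y = radial[2], dir_z = radial[3],
    head_radius = 400, neck_radius = 100, neck_length = 1200,
    length_nm = 2000, head_volume_nm3 = 4 / 3 * pi * 400^3)
  mm <- mesh_from_neuron(n, resolution = 12, head_subdiv = 2)
  so <- detect_somas(mm$mesh)
  sk <- skeletonize(mm$mesh, so)
  co <- mesh_correspondence(mm$mesh, sk)
  g <- decompose(sk, co, so[[1]])
  sp <- detect_spines(g, mm$mesh)
  expect_equal(nrow(sp), 1)
  sh <- segment_head_neck(sp, mm$mesh)
  expect_true(sh$has_neck)
  v_true <- 4 / 3 * pi * 400^3
  expect_lt(abs(sh$head_volume_nm3 - v_true) / v_true, 0.15)
  # head and neck faces are disjoint subsets of the spine faces
  expect_length(intersect(sh$head_face_ids[[1]], sh$neck_face_ids[[1]]), 0)
  expect_true(all(c(sh$head_face_ids[[1]], sh$neck_face_ids[[1]]) %in%
                    sh$face_ids[[1]]))
  # head + neck volumes bounded by the whole spine's enclosed volume
  v_all <- mesh_volume(mm$mesh, faces = sh$face_ids[[1]],
                       origin = base)
  v_neck <- mesh_volume(mm$mesh, faces = sh$neck_face_ids[[1]],
                        origin = base + radial * sh$neck_length_nm / 2)
  expect_lt(sh$head_volume_nm3 + v_neck, v_all * 1.05)
})

test_that("neck splitting discriminates mushrooms from stubbies and head
           volume couples to synapse size", {
  # pool three seeded neurons; one pass computes both the head/neck type
  # discrimination and the head-volume / synapse-size coupling
  split_mushroom <- c(); split_stubby <- c()
  coupling <- list()
  for (sd in c(42, 2, 5)) {
    if (sd == 42) {
      px <- std_neuron_pipeline()
      n <- px$neuron; mm <- px$meshed; g <- px$graph
    } else {
      n <- generate_neuron(neuron_params(spine_density = 1), seed = sd)
      mm <- mesh_from_neuron(n, 10)
      so <- detect_somas(mm$mesh)
      sk <- skeletonize(mm$mesh, so)
      co <- mesh_correspondence(mm$mesh, sk)
      g <- decompose(sk, co, so[[1]], n$synapses)
    }
    sp <- segment_head_neck(detect_spines(g, mm$mesh), mm$mesh)
    g2 <- label_synapse_spine_part(g, sp, mm$mesh)
    ft <- face_truth_table(mm$labels)
    truth_type <- n$spine_spec$type
    for (i in seq_len(nrow(sp))) {
      ids <- ft$spine_id[sp$face_ids[[i]]]
      ids <- ids[!is.na(ids)]
      if (length(ids) == 0) next
      ty <- truth_type[as.integer(names(which.max(table(ids))))]
      if (ty == "mushroom") split_mushroom <- c(split_mushroom,
                                                sp$has_neck[i])
      else split_stubby <- c(split_stubby, sp$has_neck[i])
    }
    spn <- g2$spines[g2$spines$n_synapses > 0 & g2$spines$has_neck, ]
    coupling[[length(coupling) + 1]] <-
      spn[, c("head_volume_nm3", "max_synapse_size")]
  }
  # mushrooms split far more often than stubbies ("when possible")
  expect_gt(mean(split_mushroom) - mean(split_stubby), 0.2)
  expect_lt(mean(split_stubby), 0.3)
  # generator couples synapse size to head volume: the sign is recovered
  all <- dplyr::bind_rows(coupling)
  expect_gt(nrow(all), 50)
  ct <- stats::cor.test(all$head_volume_nm3, all$max_synapse_size,
                        alternative = "greater")
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-3)
})

test_that("synapse spine-part labels partition and land on heads", {
  px <- std_neuron_pipeline()
  sp <- segment_head_neck(detect_spines(px$graph, px$meshed$mesh),
                          px$meshed$mesh)
  g <- label_synapse_spine_part(px$graph, sp, px$meshed$mesh)
  syn <- g$synapses
  expect_true(all(syn$spine_part %in% c("head", "neck", "shaft", "soma")))
  expect_equal(sum(table(syn$spine_part)), nrow(syn))
  # head synapses of *detected* spines are predominantly labelled head
  # (undetected short stubbies legitimately fall back to shaft; detection
  # coverage itself is benchmarked separately)
  ftt <- face_truth_table(px$meshed$labels)
  truth_sets <- split(ftt$face_id[!is.na(ftt$spine_id)],
                      ftt$spine_id[!is.na(ftt$spine_id)])
  covered <- vapply(names(truth_sets), function(ts)
    any(vapply(sp$face_ids, function(fc)
      length(intersect(fc, truth_sets[[ts]])) > 10, logical(1))),
    logical(1))
  truth_head <- !is.na(syn$spine_id) &
    covered[as.character(syn$spine_id)] %in% TRUE
  expect_gt(mean(syn$spine_part[truth_head] == "head"), 0.8)
  truth_shaft <- is.na(syn$spine_id) & syn$compartment != "soma"
  expect_gt(mean(syn$spine_part[truth_shaft] == "shaft"), 0.75)
})

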