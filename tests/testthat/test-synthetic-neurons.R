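test_that("generator is deterministic and respects degenerate parameters", {
  n1 <- generate_neuron(neuron_params(), seed = 42)
  n2 <- generate_neuron(neuron_params(), seed = 42)
  expect_identical(n1, n2)
  n3 <- generate_neuron(neuron_params(), seed = 43)
  expect_false(identical(n1$skeleton$points, n3$skeleton$points))

  # minimal tree: one stem, no bifurcation
  nm <- generate_neuron(neuron_params(n_stems = 1, depth = 0,
                                      spine_density = 0), seed = 1)
  expect_length(nm$branches, 1)
  expect_identical(nm$spine_spec$spine_id, integer(0))

  # invalid parameters name the offender
  expect_error(neuron_params(spine_density = -1), "spine_density")
  expect_error(neuron_params(soma_radius = NaN), "soma_radius")
  expect_error(neuron_params(nonsense = 1), "nonsense")
})

test_that("generator invariants: tree skeleton, radii taper, coordinates finite", {
  for (sd in 1:5) {
    n <- generate_neuron(neuron_params(), seed = sd)
    expect_true(all(is.finite(n$skeleton$points)))
    # tree: |E| = |V| - 1 and connected
    expect_equal(nrow(n$skeleton$edges), nrow(n$skeleton$points) - 1)
    g <- neurodecomp:::skeleton_graph(n$skeleton)
    expect_equal(igraph::components(g)$no, 1)
    # soma bigger than any neurite radius
    expect_gt(n$soma_radius, max(n$skeleton$radius[-1]))
    # radii non-increasing root-ward along each branch chain
    for (b in n$branches) {
      expect_true(b$r_end <= b$r_start + 1e-9)
      if (b$parent > 0)
        expect_lte(b$r_start, n$branches[[b$parent]]$r_end + 1e-9)
    }
    # spines only on dendritic branches
    if (nrow(n$spine_spec) > 0) {
      host <- vapply(n$branches[n$spine_spec$branch_id], `[[`, "",
                     "compartment")
      expect_false(any(host == "axon"))
    }
  }
})

test_that("synapse counts follow the Poisson law of density x length", {
  # single unbranched 100 um dendrite at 2 synapses/um
  p <- neuron_params(n_stems = 1, depth = 0, has_axon = FALSE,
                     apical = FALSE, segment_length = c(1e5, 1e5),
                     spine_density = 0, syn_shaft_density = 2,
                     syn_soma_mean = 0, jitter_deg = 0)
  counts <- vapply(1:300, function(sd) {
    n <- generate_neuron(p, seed = sd)
    nrow(n$synapses)
  }, numeric(1))
  # mean within 3 sd of a Poisson(200) draw
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200))
  expect_gt(stats::var(counts), 100)  # genuinely dispersed
})

test_that("meshed neurons match closed-form area and volume", {
  tm <- cyl_mesh(10000, 500, resolution = 12)
  a_true <- 2 * pi * 500 * 10000 + 2 * pi * 500^2
  expect_lt(abs(mesh_area(tm) - a_true) / a_true, 0.05)

  n0 <- generate_neuron(neuron_params(n_stems = 0, has_axon = FALSE,
                                      spine_density = 0, syn_soma_mean = 0),
                        seed = 1)
  m0 <- mesh_from_neuron(n0)
  v_true <- 4 / 3 * pi * n0$soma_radius^3
  expect_lt(abs(mesh_volume(m0$mesh) - v_true) / v_true, 0.02)
})

test_that("face labels conserve counts and are resolution independent", {
  n <- generate_neuron(neuron_params(spine_density = 0.5), seed = 3)
  m6 <- mesh_from_neuron(n, resolution = 6)
  m24 <- mesh_from_neuron(n, resolution = 24)
  expect_length(m6$labels, nrow(m6$mesh$faces))
  expect_length(m24$labels, nrow(m24$mesh$faces))
  expect_setequal(unique(m6$labels), unique(m24$labels))
  expect_gt(nrow(m24$mesh$faces), nrow(m6$mesh$faces))
  # single connected component by construction
  expect_equal(max(neurodecomp:::mesh_components(m6$mesh)), 1)
})

test_that("merge-error injection welds, labels and invalidates correctly", {
  sc0 <- synth_preset("single", seed = 11, spine_density = 0.5)
  expect_error(inject_merge_error(sc0, "bogus"), "axon_on_axon")

  sc <- inject_merge_error(sc0, "axon_on_dendrite", seed = 2)
  expect_equal(nrow(sc$error_truth), 1)
  expect_equal(max(neurodecomp:::mesh_components(sc$mesh)), 1)
  expect_gt(length(sc$error_truth$face_ids[[1]]), 0)

  # invalid synapses sit on error-truth geometry
  bad <- sc$synapses[!sc$synapses$valid, ]
  if (nrow(bad) > 0) {
    cents <- neurodecomp:::face_centroids(sc$mesh)
    ef <- cents[sc$error_truth$face_ids[[1]], , drop = FALSE]
    for (i in seq_len(nrow(bad))) {
      d <- min(neurodecomp:::dist_to_point(
        ef, c(bad$x[i], bad$y[i], bad$z[i])))
      expect_lt(d, 2000)
    }
  }

  # soma bridge merges two neurons into one component with two somas
  n1 <- generate_neuron(neuron_params(spine_density = 0), seed = 5)
  n2 <- generate_neuron(neuron_params(spine_density = 0), seed = 6)
  sc2 <- make_scene(list(n1, n2), offsets = list(c(0, 0, 0),
                                                 c(60000, 0, 0)))
  sc2 <- inject_merge_error(sc2, "soma_bridge", seed = 1)
  expect_equal(max(neurodecomp:::mesh_components(sc2$mesh)), 1)
  expect_length(detect_somas(sc2$mesh), 2)
  expect_error(inject_merge_error(make_scene(list(n1)), "soma_bridge"),
               "two neurons")
})

test_that("mesh and scene round-trip through OFF/PLY and the sidecar", {
  sc <- synth_preset("single", seed = 2, spine_density = 0.2)
  dir <- withr::local_tempdir()
  export_scene(sc, dir, format = "off")
  m2 <- read_off(file.path(dir, "scene.off"))
  expect_equal(nrow(m2$faces), nrow(sc$mesh$faces))
  expect_equal(m2$vertices, sc$mesh$vertices, tolerance = 1e-3)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth$face_labels, nrow(sc$mesh$faces))
  syn <- read_synapse_csv(file.path(dir, "synapses.csv"))
  expect_equal(nrow(syn), nrow(sc$synapses))
  expect_type(syn$valid, "logical")

  # ascii PLY round trip
  ply <- file.path(dir, "scene_ascii.ply")
  write_ply(sc$mesh, ply, binary = FALSE)
  m3 <- read_ply(ply)
  expect_equal(m3$faces, sc$mesh$faces)
})
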