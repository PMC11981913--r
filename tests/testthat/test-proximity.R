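test_that("parallel processes yield one event at the true clearance", {
  pre <- path_graph(cbind(0, seq(0, 20000, 1000), 0))
  post <- path_graph(cbind(0, seq(0, 20000, 1000), 3000),
                     compartment = "basal",
                     soma_center = c(0, 60000, 3000))
  px <- compute_proximities(pre, post, include_soma = FALSE)
  expect_equal(nrow(px), 1)
  expect_lt(abs(px$min_dist_nm - 3000), 100)
  expect_equal(px$post_compartment, "basal")

  # 6 um separation exceeds the 5 um radius
  post_far <- path_graph(cbind(0, seq(0, 20000, 1000), 6000),
                         compartment = "basal",
                         soma_center = c(0, 60000, 6000))
  expect_equal(nrow(compute_proximities(pre, post_far,
                                        include_soma = FALSE)), 0)

  # no labelled axon: empty with a warning
  pre_d <- path_graph(cbind(0, seq(0, 20000, 1000), 0),
                      compartment = "basal")
  expect_warning(px0 <- compute_proximities(pre_d, post), "no labelled axon")
  expect_equal(nrow(px0), 0)
})

test_that("a U-shaped axon crossing a dendrite twice gives two events", {
  u <- rbind(cbind(0, seq(0, 20000, 1000), 0),
             cbind(seq(1000, 39000, 1000), 20000, 0),
             cbind(40000, seq(20000, 0, -1000), 0))
  pre <- path_graph(u)
  post <- path_graph(cbind(seq(-5000, 45000, 1000), 1000, 2000),
                     compartment = "basal",
                     soma_center = c(-7000, 1000, 2000))
  px <- compute_proximities(pre, post, include_soma = FALSE)
  expect_equal(nrow(px), 2)
  # linking: a synapse near the first crossing converts only that event
  syn <- tibble::tibble(synapse_id = 1L, pre_id = 1L, post_id = 2L,
                        x = 0, y = 1000, z = 1000)
  px2 <- compute_proximities(pre, post, synapses = syn,
                             include_soma = FALSE)
  expect_equal(sum(px2$n_synapses), 1)
  expect_equal(conversion_rate(px2), 0.5)
})

test_that("conversion rate degenerate cases", {
  px <- tibble::tibble(n_synapses = c(1L, 2L), min_dist_nm = c(1, 2))
  expect_equal(conversion_rate(px), 1)
  px0 <- tibble::tibble(n_synapses = c(0L, 0L), min_dist_nm = c(1, 2))
  expect_equal(conversion_rate(px0), 0)
  expect_warning(r <- conversion_rate(px[0, ]), "no proximities")
  expect_true(is.na(r))
})

test_that("skeletal walk equals the brute-force path sum", {
  # two-branch path: 10 um + 20 um
  p1 <- cbind(0, 0, seq(0, 10000, 1000))
  p2 <- cbind(0, seq(1000, 20000, 1000), 10000)
  b1 <- list(id = 1L, parent = 0L, point_ids = 1, points = p1,
             skeletal_length = 10000, width = rep(600, nrow(p1)),
             face_ids = integer(0), synapse_ids = integer(0),
             spine_ids = integer(0), compartment = "axon")
  b2 <- list(id = 2L, parent = 1L, point_ids = 1,
             points = rbind(c(0, 0, 10000), p2),
             skeletal_length = 20000, width = rep(600, nrow(p2) + 1),
             face_ids = integer(0), synapse_ids = integer(0),
             spine_ids = integer(0), compartment = "axon")
  g <- structure(list(
    root = list(center = c(0, 0, 0), radius = 0, soma = NULL,
                face_ids = integer(0), synapse_ids = integer(0)),
    branches = list(b1, b2),
    edges = tibble::tibble(parent = c(0L, 1L), child = c(1L, 2L)),
    synapses = NULL, removed = integer(0), log = character(0)),
    class = "neuro_decomp")
  expect_equal(skeletal_walk(g, c(0, 20000, 10000)), 30000)
  expect_equal(skeletal_walk(g, c(0, 0, 0)), 0)      # on the soma? root r=0
  expect_error(skeletal_walk(g, c(50000, 50000, 50000)), "beyond")

  # brute-force oracle on random points of a generated neuron
  px <- std_neuron_pipeline()
  gg <- px$graph
  ws <- neurodecomp:::branch_walk_starts(gg)
  set.seed(5)
  for (k in 1:25) {
    id <- sample(neurodecomp:::active_branch_ids(gg), 1)
    b <- gg$branches[[id]]
    i <- sample(nrow(b$points) - 1, 1)
    pt <- (b$points[i, ] + b$points[i + 1, ]) / 2
    seg <- sqrt(rowSums((b$points[-1, , drop = FALSE] -
                           b$points[-nrow(b$points), , drop = FALSE])^2))
    oracle <- unname(ws[id] + sum(seg[seq_len(i - 1)]) + seg[i] / 2)
    expect_equal(as.numeric(skeletal_walk(gg, pt)), oracle,
                 tolerance = 1e-6)
  }
})

test_that("circuit conversion probabilities are recovered within binomial CI", {
  circ <- generate_circuit(n_pairs = 400,
                           p_synapse = c("E->E" = 0.05, "E->I" = 0.3),
                           seed = 10)
  px <- circuit_proximities(circ)
  # every pair produces exactly one proximity by construction
  expect_equal(nrow(px), 400)
  st <- stratify_conversion(px, by = "post_class")
  for (cls in c("E", "I")) {
    p <- if (cls == "E") 0.05 else 0.3
    row <- st[st$post_class == cls, ]
    realized <- mean(circ$truth$has_synapse[circ$truth$post_class == cls])
    # exact recovery of the realized rate, which is a plausible binomial
    # draw of the design probability
    expect_equal(row$rate, realized, tolerance = 1e-12)
    expect_lt(abs(realized - p),
              3.29 * sqrt(p * (1 - p) / row$n_proximities))
  }
  # every placed synapse lies inside some proximity at the design radius
  expect_equal(sum(px$n_synapses), nrow(circ$synapses))
})

test_that("stratification reproduces the plain rate and sweeps monotonely", {
  circ <- generate_circuit(n_pairs = 120, seed = 3)
  px <- circuit_proximities(circ)
  st0 <- stratify_conversion(px)
  expect_equal(st0$rate, conversion_rate(px))
  sw <- stratify_conversion(px, radius_sweep = c(2000, 3500, 5000))
  expect_true(all(diff(sw$n_proximities) >= 0))
  expect_error(stratify_conversion(px, by = "nonexistent"),
               "unknown stratum")
})

test_that("proximities are directional: A->B independent of B->A", {
  pre <- path_graph(cbind(0, seq(0, 20000, 1000), 0))
  post <- path_graph(cbind(0, seq(0, 20000, 1000), 3000),
                     compartment = "basal",
                     soma_center = c(0, 60000, 3000))
  ab <- compute_proximities(pre, post, include_soma = FALSE)
  expect_equal(nrow(ab), 1)
  # reversed: post has no axon -> no events
  expect_warning(ba <- compute_proximities(post, pre), "no labelled axon")
  expect_equal(nrow(ba), 0)
})
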