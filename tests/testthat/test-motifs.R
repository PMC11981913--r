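# Independent brute-force triad counting: enumerate all triples and
# classify each by its dyad states (mutual / asymmetric / null), written
# directly from the adjacency matrix with no graph library involved.
brute_man_counts <- function(adj) {
  n <- nrow(adj)
  out <- new.env()
  add <- function(key) assign(key, (mget(key, out,
                                         ifnotfound = 0)[[1]]) + 1, out)
  combs <- utils::combn(n, 3)
  for (k in seq_len(ncol(combs))) {
    tri <- combs[, k]
    m <- a <- nl <- 0L
    for (pair in list(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)])) {
      e1 <- adj[pair[1], pair[2]]; e2 <- adj[pair[2], pair[1]]
      if (e1 && e2) m <- m + 1L
      else if (e1 || e2) a <- a + 1L
      else nl <- nl + 1L
    }
    add(sprintf("%d%d%d", m, a, nl))
  }
  unlist(as.list(out))
}

test_that("graph construction thresholds edges by synapse count", {
  syn <- tibble::tibble(
    synapse_id = 1:3, pre_id = c(1L, 1L, 2L), post_id = c(2L, 2L, 3L),
    valid = TRUE)
  cg <- build_graph(syn)
  expect_equal(nrow(cg$edges), 2)
  expect_setequal(cg$edges$n_synapses, c(2L, 1L))
  # invalid synapses contribute nothing
  syn$valid <- FALSE
  expect_equal(nrow(build_graph(syn)$edges), 0)
  # multi-synaptic threshold
  syn$valid <- TRUE
  cg4 <- build_graph(syn, min_synapses = 2)
  expect_equal(nrow(cg4$edges), 1)
  expect_equal(cg4$edges$pre_id, 1L)
  # autapses dropped by default
  syn2 <- tibble::tibble(synapse_id = 1L, pre_id = 5L, post_id = 5L,
                         valid = TRUE)
  expect_equal(nrow(build_graph(syn2)$edges), 0)
})

test_that("triad census matches canonical small graphs", {
  # directed 3-cycle
  syn <- tibble::tibble(synapse_id = 1:3, pre_id = c(1L, 2L, 3L),
                        post_id = c(2L, 3L, 1L), valid = TRUE)
  tc <- triad_census(build_graph(syn))
  expect_equal(tc$count[tc$class == "030C"], 1)
  expect_equal(sum(tc$count), 1)
  expect_equal(reciprocal_pairs(build_graph(syn)), 0)

  # fully reciprocal triangle: the six-edge class
  syn2 <- tibble::tibble(synapse_id = 1:6,
                         pre_id = c(1L, 2L, 2L, 3L, 3L, 1L),
                         post_id = c(2L, 1L, 3L, 2L, 1L, 3L), valid = TRUE)
  tc2 <- triad_census(build_graph(syn2))
  expect_equal(tc2$count[tc2$n_edges == 6], 1)
  expect_equal(reciprocal_pairs(build_graph(syn2)), 3)

  # n < 3: all-zero census
  syn3 <- tibble::tibble(synapse_id = 1L, pre_id = 1L, post_id = 2L,
                         valid = TRUE)
  expect_equal(sum(triad_census(build_graph(syn3))$count), 0)
})

test_that("triad census equals brute-force enumeration on random graphs", {
  for (sd in 1:50) {
    cn <- generate_connectome(n = 30, p = stats::runif(1, 0.02, 0.12),
                              seed = sd)
    cg <- build_graph(cn$synapses, cn$labels)
    tc <- triad_census(cg)
    # adjacency straight from the edge table
    ids <- cn$labels$neuron_id
    adj <- matrix(FALSE, length(ids), length(ids))
    adj[cbind(match(cg$edges$pre_id, ids),
              match(cg$edges$post_id, ids))] <- TRUE
    brute <- brute_man_counts(adj)
    # compare per dyad-state (MAN) group: the first three characters of
    # the triad class name encode (mutual, asymmetric, null)
    impl <- tapply(tc$count, substr(tc$class, 1, 3), sum)
    for (key in names(brute))
      expect_equal(unname(impl[key]), unname(brute[key]),
                   label = paste("seed", sd, "MAN", key))
    expect_equal(sum(tc$count), choose(nrow(cg$nodes), 3))
  }
})

test_that("orientation subtypes are distinguished on canonical triads", {
  mk <- function(pre, post) build_graph(tibble::tibble(
    synapse_id = seq_along(pre), pre_id = pre, post_id = post,
    valid = TRUE))
  # transitive triangle vs 3-cycle
  tcT <- triad_census(mk(c(1L, 1L, 2L), c(2L, 3L, 3L)))
  expect_equal(tcT$count[tcT$class == "030T"], 1)
  tcC <- triad_census(mk(c(1L, 2L, 3L), c(2L, 3L, 1L)))
  expect_equal(tcC$count[tcC$class == "030C"], 1)
  # divergent, convergent and chain two-edge triads
  tcD <- triad_census(mk(c(1L, 1L), c(2L, 3L)))
  expect_equal(tcD$count[tcD$class == "021D"], 1)
  tcU <- triad_census(mk(c(2L, 3L), c(1L, 1L)))
  expect_equal(tcU$count[tcU$class == "021U"], 1)
  tcC2 <- triad_census(mk(c(1L, 2L), c(2L, 3L)))
  expect_equal(tcC2$count[tcC2$class == "021C"], 1)
})

test_that("census is invariant under node relabelling", {
  cn <- generate_connectome(n = 25, p = 0.08, seed = 5)
  tc0 <- triad_census(build_graph(cn$synapses, cn$labels))
  for (k in 1:20) {
    perm <- sample(1000:2000, 25)
    syn <- cn$synapses
    syn$pre_id <- perm[syn$pre_id]
    syn$post_id <- perm[syn$post_id]
    labs <- cn$labels
    labs$neuron_id <- perm[labs$neuron_id]
    tc <- triad_census(build_graph(syn, labs))
    expect_equal(tc$count, tc0$count)
  }
})

test_that("null models keep their defining invariants", {
  cn <- generate_connectome(n = 40, p = 0.06, seed = 8)
  cg <- build_graph(cn$synapses, cn$labels)
  g0 <- igraph::simplify(cg$graph)
  din <- igraph::degree(g0, mode = "in")
  dout <- igraph::degree(g0, mode = "out")

  # degree-preserving swaps keep both degree sequences
  neurodecomp:::with_seed(1, {
    gs <- igraph::rewire(g0, igraph::keeping_degseq(loops = FALSE,
                                                    niter = 10 * igraph::ecount(g0)))
    expect_equal(igraph::degree(gs, mode = "in"), din)
    expect_equal(igraph::degree(gs, mode = "out"), dout)
  })

  # proximity-constrained samples draw only proximity edges
  ns <- null_sample(cg, "proximity_constrained", n_samples = 5, seed = 2,
                    proximity_edges = cn$proximity_edges)
  expect_equal(ncol(ns$census), 5)
  pe <- paste(cn$proximity_edges$pre_id, cn$proximity_edges$post_id)
  # verify a fresh draw directly
  neurodecomp:::with_seed(2, {
    pick <- as.matrix(cn$proximity_edges)[
      sample.int(nrow(cn$proximity_edges), nrow(cg$edges)), ]
    expect_true(all(paste(pick[, 1], pick[, 2]) %in% pe))
  })
  expect_error(null_sample(cg, "proximity_constrained", n_samples = 2,
                           seed = 1,
                           proximity_edges = cn$proximity_edges[1:3, ]),
               "smaller")

  # edge count conserved in every null
  for (kind in c("degree_preserving", "random_shuffle")) {
    ns2 <- null_sample(cg, kind, n_samples = 3, seed = 3)
    expect_equal(ncol(ns2$census), 3)
    expect_true(all(colSums(ns2$census) == choose(nrow(cg$nodes), 3)))
  }
})

test_that("uniform rewiring matches the analytic reciprocal-dyad mean", {
  # |E| iid uniform draws over the N = n(n-1) ordered pairs; a mutual
  # (unordered) dyad is present when both of its ordered pairs were drawn
  # at least once, so E[mut] = (N/2) (1 - 2(1-1/N)^E + (1-2/N)^E)
  n <- 50
  cn <- generate_connectome(n = n, p = 0.08, seed = 12)
  cg <- build_graph(cn$synapses, cn$labels)
  ne <- nrow(cg$edges)
  N <- n * (n - 1)
  expected <- N / 2 * (1 - 2 * (1 - 1 / N)^ne + (1 - 2 / N)^ne)
  recips <- neurodecomp:::with_seed(7, vapply(1:250, function(k) {
    from <- sample.int(n, ne, replace = TRUE)
    to <- vapply(from, function(f) {
      repeat { t <- sample.int(n, 1); if (t != f) return(t) }
    }, integer(1))
    g <- igraph::graph_from_edgelist(cbind(from, to))
    igraph::dyad_census(igraph::simplify(g))$mut
  }, numeric(1)))
  se <- stats::sd(recips) / sqrt(length(recips))
  expect_lt(abs(mean(recips) - expected), 3 * se + 0.05)
})

test_that("planted dense triangles are detected as enriched", {
  detected <- 0
  for (rep in 1:20) {
    cn <- generate_connectome(n = 40, p = 0.05, n_triangles = 6,
                              seed = 100 + rep)
    cg <- build_graph(cn$synapses, cn$labels)
    tc <- triad_census(cg)
    ns <- null_sample(cg, "degree_preserving", n_samples = 40,
                      seed = rep)
    en <- enrichment(tc, ns)
    dense <- en[en$n_edges >= 5, ]
    # zero null variance with a positive observed count is the extreme
    # enrichment case the census reports separately
    hit <- any(is.finite(dense$z) & dense$z > 2) ||
      any(dense$null_sd == 0 & dense$observed > dense$null_mean)
    if (hit) detected <- detected + 1
  }
  expect_gte(detected / 20, 0.95)
})

test_that("enrichment of a null sample against itself is centred", {
  cn <- generate_connectome(n = 30, p = 0.08, seed = 3)
  cg <- build_graph(cn$synapses, cn$labels)
  ns <- null_sample(cg, "random_shuffle", n_samples = 60, seed = 5)
  obs <- tibble::tibble(class = neurodecomp:::TRIAD_CLASSES,
                        n_edges = unname(neurodecomp:::TRIAD_EDGE_COUNT),
                        count = ns$mean)
  en <- enrichment(obs, ns)
  expect_true(all(abs(en$z) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(en$ratio - 1) < 1e-9, na.rm = TRUE))
})
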