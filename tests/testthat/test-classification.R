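# feature generator for E/I population tests (skeleton-level, no meshes)
ei_population <- function(n_per_class, seed,
                          exc = c(spine = 1.5, shaft = 0.1),
                          inh = c(spine = 0.05, shaft = 0.8)) {
  neurodecomp:::with_seed(seed, {
    tibble::tibble(
      cell_class = rep(c("excitatory", "inhibitory"), each = n_per_class),
      spine_density_um = c(pmax(stats::rnorm(n_per_class, exc["spine"], 0.3), 0),
                           pmax(stats::rnorm(n_per_class, inh["spine"], 0.05), 0)),
      shaft_density_um = c(pmax(stats::rnorm(n_per_class, exc["shaft"], 0.05), 0),
                           pmax(stats::rnorm(n_per_class, inh["shaft"], 0.2), 0)))
  })
}

test_that("E/I logistic model separates well-separated populations", {
  train <- ei_population(200, seed = 1)
  test <- ei_population(200, seed = 2)
  m <- suppressWarnings(fit_ei(train))
  pred <- predict(m, test)
  acc <- mean(pred$cell_class_pred == test$cell_class)
  expect_gte(acc, 0.95)
  # weight signs: spines pull excitatory, shaft synapses pull inhibitory
  co <- stats::coef(m$fit)
  expect_lt(co["spine_density_um"], 0)
  expect_gt(co["shaft_density_um"], 0)
  # broom-style accessors
  expect_equal(nrow(tidy(m)), 3)
  expect_equal(glance(m)$nobs, 400)
  expect_error(fit_ei(train[train$cell_class == "excitatory", ]),
               "both classes")
})

test_that("identical feature distributions give chance accuracy", {
  train <- ei_population(200, seed = 3, exc = c(spine = 1, shaft = 0.5),
                         inh = c(spine = 1, shaft = 0.5))
  test <- ei_population(200, seed = 4, exc = c(spine = 1, shaft = 0.5),
                        inh = c(spine = 1, shaft = 0.5))
  m <- fit_ei(train)
  acc <- mean(predict(m, test)$cell_class_pred == test$cell_class)
  expect_lt(abs(acc - 0.5), 0.07)
})

test_that("logistic parameter recovery within 15% at n = 2000", {
  # generate labels from a known logistic model, refit, compare
  beta <- c(intercept = -1, spine = -2.5, shaft = 4)
  dat <- neurodecomp:::with_seed(99, {
    spine <- stats::runif(2000, 0, 2)
    shaft <- stats::runif(2000, 0, 1)
    eta <- beta[1] + beta[2] * spine + beta[3] * shaft
    tibble::tibble(
      spine_density_um = spine, shaft_density_um = shaft,
      cell_class = ifelse(stats::runif(2000) < stats::plogis(eta),
                          "inhibitory", "excitatory"))
  })
  m <- fit_ei(dat)
  est <- stats::coef(m$fit)
  expect_lt(abs(est[2] - beta[2]) / abs(beta[2]), 0.15)
  expect_lt(abs(est[3] - beta[3]) / abs(beta[3]), 0.15)
})

test_that("axon identification recovers the generator's axon stem", {
  px <- std_neuron_pipeline()
  g <- px$graph
  sp <- detect_spines(g, px$meshed$mesh)
  g <- label_synapse_spine_part(g, sp, px$meshed$mesh)
  ax <- identify_axon(g)
  expect_false(is.na(ax))
  ft <- face_truth_table(px$meshed$labels)
  ids <- c(ax, neurodecomp:::decomp_descendants(g, ax))
  axf <- unlist(lapply(g$branches[ids], `[[`, "face_ids"))
  tb <- ft$branch_id[axf]
  tb <- tb[!is.na(tb)]
  truth_comp <- vapply(px$neuron$branches[sort(unique(tb))], `[[`, "",
                       "compartment")
  expect_true(all(truth_comp == "axon"))

  # dendrite-only fragment: no axon
  g0 <- g
  g0$synapses$direction <- "incoming"
  expect_true(is.na(identify_axon(g0)))

  # deterministic tie-break toward the lowest stem id
  p1 <- cbind(0, 0, seq(0, 10000, 1000))
  p2 <- cbind(0, seq(0, 10000, 1000), 0)
  syn <- tibble::tibble(synapse_id = 1:8, pre_id = 1L, post_id = 0L,
                        x = 0, y = c(rep(0, 4), seq(2000, 8000, 2000)),
                        z = c(seq(2000, 8000, 2000), rep(0, 4)),
                        size = 500, direction = "outgoing",
                        compartment = NA, spine_part = "shaft",
                        valid = TRUE, branch_id = rep(1:2, each = 4))
  gt <- structure(list(
    root = list(center = c(0, 0, 0), radius = 500, soma = NULL,
                face_ids = integer(0), synapse_ids = integer(0)),
    branches = list(
      list(id = 1L, parent = 0L, point_ids = 1, points = p1,
           skeletal_length = 10000, width = rep(600, 11),
           face_ids = integer(0), synapse_ids = 1:4,
           spine_ids = integer(0), compartment = NA_character_),
      list(id = 2L, parent = 0L, point_ids = 1, points = p2,
           skeletal_length = 10000, width = rep(600, 11),
           face_ids = integer(0), synapse_ids = 5:8,
           spine_ids = integer(0), compartment = NA_character_)),
    edges = tibble::tibble(parent = c(0L, 0L), child = c(1L, 2L)),
    synapses = syn, removed = integer(0), log = character(0)),
    class = "neuro_decomp")
  expect_equal(identify_axon(gt), 1L)
})

test_that("compartment labels recover apical/AIS and partition branches", {
  px <- std_neuron_pipeline()
  g <- px$graph
  sp <- detect_spines(g, px$meshed$mesh)
  g <- label_synapse_spine_part(g, sp, px$meshed$mesh)
  g <- label_compartments(g, "excitatory")
  comp <- vapply(g$branches[neurodecomp:::active_branch_ids(g)], `[[`, "",
                 "compartment")
  expect_false(any(is.na(comp)))
  expect_true(all(comp %in% c("axon", "AIS", "basal", "apical", "oblique")))
  # apical stem matches the generator's apical
  ap <- which(comp == "apical")
  expect_gt(length(ap), 0)
  ft <- face_truth_table(px$meshed$labels)
  ids <- neurodecomp:::active_branch_ids(g)[ap]
  apf <- unlist(lapply(g$branches[ids], `[[`, "face_ids"))
  tb <- ft$branch_id[apf]; tb <- tb[!is.na(tb)]
  truth_comp <- vapply(px$neuron$branches[sort(unique(tb))], `[[`, "",
                       "compartment")
  expect_true(all(truth_comp == "apical"))
  # inhibitory cells: no apical
  gi <- label_compartments(px$graph, "inhibitory")
  comp_i <- vapply(gi$branches[neurodecomp:::active_branch_ids(gi)], `[[`,
                   "", "compartment")
  expect_false(any(comp_i %in% c("apical", "oblique")))
  # a short axon is AIS throughout under a large window
  gw <- label_compartments(g, "excitatory", ais_window = 1e9)
  comp_w <- vapply(gw$branches[neurodecomp:::active_branch_ids(gw)], `[[`,
                   "", "compartment")
  expect_false(any(comp_w == "axon"))
  expect_true(any(comp_w == "AIS"))
})

test_that("compartment labels are translation invariant", {
  px <- std_neuron_pipeline()
  g <- px$graph
  sp <- detect_spines(g, px$meshed$mesh)
  g <- label_synapse_spine_part(g, sp, px$meshed$mesh)
  g1 <- label_compartments(g, "excitatory")
  g2 <- g
  shift <- c(1e6, -5e5, 3e5)
  for (i in seq_along(g2$branches))
    g2$branches[[i]]$points <- sweep(g2$branches[[i]]$points, 2, shift, "+")
  g2$root$center <- g2$root$center + shift
  g2$synapses$x <- g2$synapses$x + shift[1]
  g2$synapses$y <- g2$synapses$y + shift[2]
  g2$synapses$z <- g2$synapses$z + shift[3]
  g2 <- label_compartments(g2, "excitatory")
  expect_identical(
    vapply(g1$branches, `[[`, "", "compartment"),
    vapply(g2$branches, `[[`, "", "compartment"))
})
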