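# Skeleton-level circuit generator: pairs of axon/dendrite decomposition
# graphs with controlled clearances and Bernoulli synapse placement per
# proximity, for exercising the proximity and conversion-rate machinery
# with known ground truth.

# Build a minimal single-branch decomposition graph from a polyline.
decomp_from_path <- function(points, width = 600, soma_center = NULL,
                             soma_radius = 1000, compartment = "axon") {
  points <- as.matrix(points)
  if (is.null(soma_center)) soma_center <- points[1, ]
  branch <- list(
    id = 1L, parent = 0L,
    point_ids = seq_len(nrow(points)),
    points = points,
    skeletal_length = polyline_length(points),
    width = rep(width, nrow(points)),
    face_ids = integer(0), synapse_ids = integer(0),
    spine_ids = integer(0), compartment = compartment)
  structure(list(
    root = list(center = soma_center, radius = soma_radius, soma = NULL,
                face_ids = integer(0), synapse_ids = integer(0)),
    branches = list(branch),
    edges = tibble::tibble(parent = 0L, child = 1L),
    synapses = NULL, removed = integer(0), log = character(0)),
    class = "neuro_decomp")
}

#' Generate a synthetic axon-dendrite proximity circuit
#'
#' Builds `n_pairs` presynaptic/postsynaptic neuron pairs whose axon passes
#' the partner's dendrite exactly once within the proximity radius, with
#' pre/post cell classes and class-dependent synapse probabilities: each
#' proximity receives a synapse with probability
#' `p_synapse[<pre class>-><post class>]`.
#'
#' @param n_pairs number of pairs.
#' @param p_synapse named vector of conversion probabilities by connection
#'   type (names like `"E->E"`, `"E->I"`); a single unnamed value applies to
#'   all pairs.
#' @param p_inh_post probability the postsynaptic cell is inhibitory.
#' @param radius proximity radius the clearances are drawn under (nm).
#' @param seed integer seed.
#' @return list with `pairs` (list of `list(pre, post, pre_class,
#'   post_class)`), `synapses` (tibble with `pre_id`, `post_id`, positions)
#'   and `truth` (tibble of pair-level ground truth).
#' @export
generate_circuit <- function(n_pairs = 100, p_synapse = c("E->E" = 0.05,
                                                          "E->I" = 0.3),
                             p_inh_post = 0.5, radius = 5000, seed = 1) {
  with_seed(seed, {
    pairs <- vector("list", n_pairs)
    syn_rows <- list()
    truth <- list()
    for (i in seq_len(n_pairs)) {
      off <- c((i - 1) * 200000, 0, 0)   # pairs spatially separated
      clear <- stats::runif(1, 1500, radius - 500)
      # axon along +y; dendrite parallel, offset in z by the clearance
      axon <- cbind(off[1], off[2] + seq(0, 40000, 1000), off[3])
      dend <- cbind(off[1], off[2] + seq(10000, 30000, 1000),
                    off[3] + clear)
      pre <- decomp_from_path(axon, width = 600,
                              soma_center = axon[1, ] - c(0, 2000, 0),
                              compartment = "axon")
      post <- decomp_from_path(dend, width = 1400,
                               soma_center = dend[nrow(dend), ] +
                                 c(0, 2000, 0),
                               compartment = "basal")
      post_class <- if (stats::runif(1) < p_inh_post) "I" else "E"
      key <- paste0("E->", post_class)
      p <- if (!is.null(names(p_synapse)) && key %in% names(p_synapse))
        p_synapse[[key]] else p_synapse[[1]]
      has_syn <- stats::runif(1) < p
      if (has_syn) {
        mid <- (axon[21, ] + dend[11, ]) / 2
        syn_rows[[length(syn_rows) + 1]] <- tibble::tibble(
          synapse_id = length(syn_rows) + 1L,
          pre_id = i, post_id = n_pairs + i,
          x = mid[1], y = mid[2], z = mid[3],
          size = stats::rlnorm(1, log(500), 0.4), valid = TRUE)
      }
      pairs[[i]] <- list(pre = pre, post = post, pre_class = "E",
                         post_class = post_class)
      truth[[i]] <- tibble::tibble(pair = i, pre_class = "E",
                                   post_class = post_class,
                                   clearance_nm = clear,
                                   p_synapse = p, has_synapse = has_syn)
    }
    list(pairs = pairs,
         synapses = if (length(syn_rows)) dplyr::bind_rows(syn_rows) else
           tibble::tibble(synapse_id = integer(), pre_id = integer(),
                          post_id = integer(), x = double(), y = double(),
                          z = double(), size = double(), valid = logical()),
         truth = dplyr::bind_rows(truth))
  })
}

#' Pool proximities over the pairs of a circuit
#'
#' Runs [compute_proximities()] for every pair of a [generate_circuit()]
#' result and pools the events, carrying the pre/post cell classes.
#'
#' @param circuit result of [generate_circuit()].
#' @param radius,min_gap,step,link_radius see [compute_proximities()].
#' @return tibble of proximity events with `pre_class` / `post_class`.
#' @export
circuit_proximities <- function(circuit, radius = 5000, min_gap = 10000,
                                step = 500, link_radius = 5000) {
  n_pairs <- length(circuit$pairs)
  out <- lapply(seq_along(circuit$pairs), function(i) {
    pr <- circuit$pairs[[i]]
    syn_i <- circuit$synapses[circuit$synapses$pre_id == i, , drop = FALSE]
    px <- compute_proximities(pr$pre, pr$post, radius = radius,
                              min_gap = min_gap, step = step,
                              synapses = syn_i, link_radius = link_radius,
                              pre_id = i, post_id = n_pairs + i)
    if (nrow(px) > 0) {
      px$pre_class <- pr$pre_class
      px$post_class <- pr$post_class
    }
    px
  })
  dplyr::bind_rows(out)
}
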