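# Neuron-level connectivity graph, triad census and null models.  The
# census counts all C(n,3) node triples across the 16 directed three-node
# isomorphism classes; enrichment compares the observed census against
# degree-preserving, proximity-constrained and uniform-rewiring null
# ensembles.

TRIAD_CLASSES <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")
TRIAD_EDGE_COUNT <- c(`003` = 0L, `012` = 1L, `102` = 2L, `021D` = 2L,
                      `021U` = 2L, `021C` = 2L, `111D` = 3L, `111U` = 3L,
                      `030T` = 3L, `030C` = 3L, `201` = 4L, `120D` = 4L,
                      `120U` = 4L, `120C` = 4L, `210` = 5L, `300` = 6L)

#' Build the neuron-level connectivity graph
#'
#' Aggregates a synapse table into a weighted directed graph: an edge
#' `pre -> post` exists when at least `min_synapses` valid synapses connect
#' the pair.  Autapses are excluded by default.
#'
#' @param synapses tibble with `pre_id`, `post_id` and (optionally) a
#'   logical `valid` column; invalid synapses are dropped.
#' @param labels optional tibble `neuron_id`, `cell_class`.
#' @param min_synapses minimum synapses per edge (default 1).
#' @param allow_autapses keep self-edges (default `FALSE`).
#' @return an object of class `conn_graph`: `graph` (igraph), `edges`
#'   (tibble with `n_synapses` weights), `nodes` (tibble).
#' @export
build_graph <- function(synapses, labels = NULL, min_synapses = 1,
                        allow_autapses = FALSE) {
  syn <- synapses
  if ("valid" %in% names(syn)) syn <- syn[syn$valid, , drop = FALSE]
  syn <- syn[syn$pre_id > 0 & syn$post_id > 0, , drop = FALSE]
  if (!allow_autapses) syn <- syn[syn$pre_id != syn$post_id, , drop = FALSE]
  edges <- syn |>
    dplyr::count(pre_id, post_id, name = "n_synapses") |>
    dplyr::filter(n_synapses >= min_synapses)
  node_ids <- sort(unique(c(edges$pre_id, edges$post_id,
                            if (!is.null(labels)) labels$neuron_id)))
  nodes <- tibble::tibble(neuron_id = node_ids)
  if (!is.null(labels))
    nodes <- dplyr::left_join(nodes, labels, by = "neuron_id")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$pre_id),
               to = as.character(edges$post_id)),
    directed = TRUE,
    vertices = data.frame(name = as.character(node_ids)))
  igraph::E(g)$weight <- edges$n_synapses
  structure(list(graph = g, edges = edges, nodes = nodes),
            class = "conn_graph")
}

#' @export
print.conn_graph <- function(x, ...) {
  cat(sprintf("<conn_graph> %d neurons, %d edges, mean in/out degree %.2f\n",
              nrow(x$nodes), nrow(x$edges),
              nrow(x$edges) / max(1, nrow(x$nodes))))
  invisible(x)
}

#' Triad census of a connectivity graph
#'
#' Exact counts of all node triples over the 16 directed three-node
#' isomorphism classes (multi-edges collapsed), plus the edge-count
#' coarsening (number of directed edges among the three nodes, 0-6).
#'
#' @param cg a `conn_graph` (or igraph).
#' @return tibble with `class`, `n_edges`, `count`.
#' @export
triad_census <- function(cg) {
  g <- if (inherits(cg, "conn_graph")) cg$graph else cg
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  counts <- if (igraph::vcount(g) < 3) rep(0, 16) else
    suppressWarnings(igraph::triad_census(g))
  tibble::tibble(class = TRIAD_CLASSES,
                 n_edges = unname(TRIAD_EDGE_COUNT[TRIAD_CLASSES]),
                 count = as.numeric(counts))
}

conn_edge_matrix <- function(cg) {
  as.matrix(cg$edges[, c("pre_id", "post_id")])
}

graph_from_edge_matrix <- function(em, node_ids) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(em[, 1]), to = as.character(em[, 2])),
    directed = TRUE, vertices = data.frame(name = as.character(node_ids)))
  g
}

#' Sample a null ensemble of triad censuses
#'
#' Three null models: `degree_preserving` applies directed double-edge
#' swaps (burn-in `swaps_per_edge * |E|` swaps between samples) so in/out
#' degree sequences are conserved; `proximity_constrained` draws `|E|`
#' edges uniformly from the companion proximity edge set;
#' `random_shuffle` redraws both endpoints of every edge uniformly (no
#' self-loops).
#'
#' @param cg a `conn_graph`.
#' @param kind one of `"degree_preserving"`, `"proximity_constrained"`,
#'   `"random_shuffle"`.
#' @param n_samples ensemble size (default 250).
#' @param seed integer seed.
#' @param proximity_edges two-column matrix/tibble of allowed (pre, post)
#'   pairs; required for `proximity_constrained` and must contain at least
#'   `|E|` pairs.
#' @param swaps_per_edge double-edge-swap burn-in multiplier (default 10).
#' @return list with `census` (matrix 16 x n_samples), `mean` and `sd`
#'   (named by triad class), `kind`.
#' @export
null_sample <- function(cg, kind = c("degree_preserving",
                                     "proximity_constrained",
                                     "random_shuffle"),
                        n_samples = 250, seed = 1,
                        proximity_edges = NULL, swaps_per_edge = 10) {
  kind <- match.arg(kind)
  node_ids <- cg$nodes$neuron_id
  n <- length(node_ids)
  ne <- nrow(cg$edges)
  if (kind == "proximity_constrained") {
    if (is.null(proximity_edges))
      stop("proximity_constrained null needs proximity_edges")
    pe <- unique(as.matrix(as.data.frame(proximity_edges)[, 1:2]))
    if (nrow(pe) < ne)
      stop("proximity edge set (", nrow(pe),
           ") smaller than the observed edge count (", ne, ")")
  }
  census <- matrix(0, 16, n_samples,
                   dimnames = list(TRIAD_CLASSES, NULL))
  with_seed(seed, {
    g_cur <- igraph::simplify(cg$graph)
    for (s in seq_len(n_samples)) {
      if (kind == "degree_preserving") {
        g_cur <- igraph::rewire(
          g_cur, igraph::keeping_degseq(loops = FALSE,
                                        niter = swaps_per_edge * ne))
        gs <- g_cur
      } else if (kind == "proximity_constrained") {
        pick <- pe[sample.int(nrow(pe), ne), , drop = FALSE]
        gs <- graph_from_edge_matrix(pick, node_ids)
      } else {
        from <- node_ids[sample.int(n, ne, replace = TRUE)]
        to <- vapply(from, function(f) {
          repeat {
            t <- node_ids[sample.int(n, 1)]
            if (t != f) return(t)
          }
        }, node_ids[1])
        gs <- graph_from_edge_matrix(cbind(from, to), node_ids)
      }
      census[, s] <- triad_census(gs)$count
    }
  })
  list(census = census,
       mean = rowMeans(census),
       sd = apply(census, 1, stats::sd),
       kind = kind)
}

#' Motif enrichment against a null ensemble
#'
#' Per-class z-score `(obs - null mean) / null sd` and fold ratio
#' `obs / null mean`; classes with zero null variance are reported with
#' `NA` z-scores rather than dropped.
#'
#' @param observed census tibble from [triad_census()].
#' @param null result of [null_sample()].
#' @return tibble `class`, `n_edges`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `ratio`.
#' @export
enrichment <- function(observed, null) {
  mu <- unname(null$mean[observed$class])
  sdv <- unname(null$sd[observed$class])
  obs <- observed$count
  tibble::tibble(
    class = observed$class,
    n_edges = observed$n_edges,
    observed = obs,
    null_mean = mu,
    null_sd = sdv,
    z = ifelse(sdv > 0, (obs - mu) / sdv, NA_real_),
    ratio = ifelse(mu > 0, obs / mu, NA_real_))
}

#' Reciprocal-pair (mutual dyad) count of a connectivity graph
#' @param cg a `conn_graph`.
#' @return number of unordered neuron pairs connected in both directions.
#' @export
reciprocal_pairs <- function(cg) {
  g <- igraph::simplify(cg$graph)
  igraph::dyad_census(g)$mut
}

#' Generate a synthetic connectome with planted structure
#'
#' A background directed Erdos-Renyi graph with optional planted
#' fully-connected (reciprocal) triangles and a companion proximity edge
#' set that always contains the synapse edges.  Used to exercise the motif
#' census and null models with known ground truth.
#'
#' @param n neurons.
#' @param p background edge probability.
#' @param n_triangles planted dense triangles (default 0).
#' @param p_inh fraction of inhibitory neurons.
#' @param seed integer seed.
#' @param synapses_per_edge mean synapse multiplicity per edge.
#' @return list with `synapses` (tibble), `labels`, `proximity_edges`
#'   (every synapse edge plus extra candidate pairs).
#' @export
generate_connectome <- function(n = 50, p = 0.05, n_triangles = 0,
                                p_inh = 0.15, seed = 1,
                                synapses_per_edge = 1.3) {
  with_seed(seed, {
    em <- which(matrix(stats::runif(n * n) < p, n, n) &
                  !diag(TRUE, n), arr.ind = TRUE)
    edges <- unique(rbind(em))
    if (n_triangles > 0) {
      for (k in seq_len(n_triangles)) {
        tri <- sample.int(n, 3)
        edges <- rbind(edges,
                       cbind(tri, tri[c(2, 3, 1)]),
                       cbind(tri[c(2, 3, 1)], tri))
      }
      edges <- unique(edges)
    }
    n_syn <- 1 + stats::rpois(nrow(edges), synapses_per_edge - 1)
    synapses <- tibble::tibble(
      synapse_id = seq_len(sum(n_syn)),
      pre_id = rep(edges[, 1], n_syn),
      post_id = rep(edges[, 2], n_syn),
      size = stats::rlnorm(sum(n_syn), log(500), 0.4),
      valid = TRUE)
    labels <- tibble::tibble(
      neuron_id = seq_len(n),
      cell_class = ifelse(stats::runif(n) < p_inh, "inhibitory",
                          "excitatory"))
    # proximity superset: all synapse edges plus random candidate pairs
    extra <- cbind(sample.int(n, 4 * nrow(edges), replace = TRUE),
                   sample.int(n, 4 * nrow(edges), replace = TRUE))
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    prox <- unique(rbind(edges, extra))
    list(synapses = synapses, labels = labels,
         proximity_edges = tibble::tibble(pre_id = prox[, 1],
                                          post_id = prox[, 2]))
  })
}
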