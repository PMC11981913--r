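# Axon-dendrite proximities, conversion rates and skeletal-walk distances.
# A proximity is a contiguous stretch of one neuron's axon passing within a
# threshold radius (default 5 um) of another neuron's dendrite (or soma);
# the conversion rate is the fraction of proximities that contain at least
# one synapse.

# Per-branch walk distance (nm) from the soma root to each branch start.
branch_walk_starts <- function(graph) {
  out <- numeric(length(graph$branches))
  walk <- function(id, acc) {
    out[id] <<- acc
    b <- graph$branches[[id]]
    for (ch in decomp_children(graph, id))
      walk(ch, acc + b$skeletal_length)
  }
  for (s in decomp_children(graph, 0L))
    walk(s, vec_norm(graph$branches[[s]]$points[1, ] - graph$root$center))
  out
}

#' Skeletal-walk distance from a point to the soma
#'
#' Projects the point onto the nearest skeleton edge of the graph and sums
#' edge lengths along the unique tree path back to the soma root.
#'
#' @param graph a `neuro_decomp`.
#' @param point numeric 3-vector (nm).
#' @param max_width_factor reject points farther than this multiple of the
#'   local width from the skeleton (default 2).
#' @return walk distance in nm (0 for points on the soma).
#' @export
skeletal_walk <- function(graph, point, max_width_factor = 2) {
  pt <- matrix(point, 1, 3)
  if (dist_to_point(pt, graph$root$center) <= graph$root$radius * 1.05)
    return(0)
  ws <- branch_walk_starts(graph)
  best <- Inf; best_walk <- NA_real_; best_width <- NA_real_
  for (id in active_branch_ids(graph)) {
    b <- graph$branches[[id]]
    P <- b$points
    nn <- nearest_segment(pt, P[-nrow(P), , drop = FALSE],
                          P[-1, , drop = FALSE])
    if (nn$dist < best) {
      best <- nn$dist
      seg_len <- sqrt(rowSums((P[-1, , drop = FALSE] -
                                 P[-nrow(P), , drop = FALSE])^2))
      arc <- c(0, cumsum(seg_len))
      best_walk <- ws[id] + arc[nn$seg] + nn$t * seg_len[nn$seg]
      best_width <- b$width[nn$seg]
    }
  }
  if (is.finite(best_width) && best_width > 0 &&
      best > max_width_factor * best_width)
    stop("skeletal_walk: point is ", round(best), " nm from the skeleton, ",
         "beyond ", max_width_factor, "x the local width")
  best_walk
}

#' Compute axon-dendrite proximities between two neurons
#'
#' The presynaptic neuron's axon skeleton is resampled at `step` nm; for
#' every sample the nearest postsynaptic dendritic (and optionally somatic)
#' skeleton point is found, contiguous runs of samples within `radius` are
#' merged into proximity events, and two events merge when separated along
#' the axon by less than `min_gap`.  When a synapse table is supplied, each
#' synapse of the pair is linked to the nearest event within `link_radius`.
#'
#' @param pre_graph presynaptic `neuro_decomp` (axon labelled).
#' @param post_graph postsynaptic `neuro_decomp`.
#' @param radius proximity threshold, nm (default 5000).
#' @param min_gap along-axon separation below which two events merge
#'   (default 10000 nm).
#' @param step axon resampling step, nm (default 500).
#' @param synapses optional synapse tibble (`x`,`y`,`z`) of synapses from
#'   `pre` onto `post`.
#' @param link_radius synapse-to-event linking radius, nm (default 5000).
#' @param include_soma count the postsynaptic soma surface as a target.
#' @param pre_id,post_id ids recorded in the output.
#' @return tibble of proximity events (`ProximityRecord` columns): closest
#'   approach coordinates, `min_dist_nm`, `presyn_walk_nm`,
#'   `postsyn_walk_nm`, `post_compartment`, `n_synapses`, `synapse_ids`.
#' @export
compute_proximities <- function(pre_graph, post_graph, radius = 5000,
                                min_gap = 10000, step = 500,
                                synapses = NULL, link_radius = 5000,
                                include_soma = TRUE,
                                pre_id = 1L, post_id = 2L) {
  empty <- tibble::tibble(
    pre_id = integer(), post_id = integer(), event = integer(),
    x = double(), y = double(), z = double(),
    post_x = double(), post_y = double(), post_z = double(),
    min_dist_nm = double(), presyn_walk_nm = double(),
    postsyn_walk_nm = double(), post_compartment = character(),
    n_synapses = integer(), synapse_ids = list())
  comp_pre <- vapply(pre_graph$branches, `[[`, "", "compartment")
  axon_ids <- intersect(active_branch_ids(pre_graph),
                        which(comp_pre %in% c("axon", "AIS")))
  if (length(axon_ids) == 0) {
    warning("compute_proximities: presynaptic graph has no labelled axon")
    return(empty)
  }
  ws_pre <- branch_walk_starts(pre_graph)
  # axon samples in DFS order with walk coordinates
  samples <- list()
  dfs <- function(id) {
    b <- pre_graph$branches[[id]]
    P <- b$points
    seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    s_at <- seq(0, arc[length(arc)], by = step)
    idx <- findInterval(s_at, arc, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), length(seg))
    f <- (s_at - arc[idx]) / seg[idx]
    pts <- P[idx, , drop = FALSE] + (P[idx + 1, , drop = FALSE] -
                                       P[idx, , drop = FALSE]) * f
    samples[[length(samples) + 1]] <<- cbind(pts, ws_pre[id] + s_at)
    for (ch in intersect(decomp_children(pre_graph, id), axon_ids)) dfs(ch)
  }
  for (s in intersect(decomp_children(pre_graph, 0L), axon_ids)) dfs(s)
  S <- do.call(rbind, samples)
  if (is.null(S) || nrow(S) == 0) return(empty)

  # postsynaptic target segments (dendrites + soma ball)
  comp_post <- vapply(post_graph$branches, `[[`, "", "compartment")
  dend_ids <- intersect(active_branch_ids(post_graph),
                        which(is.na(comp_post) |
                                !(comp_post %in% c("axon", "AIS"))))
  seg_a <- list(); seg_b <- list(); seg_branch <- list(); seg_arc0 <- list()
  ws_post <- branch_walk_starts(post_graph)
  for (id in dend_ids) {
    P <- post_graph$branches[[id]]$points
    seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    seg_a[[length(seg_a) + 1]] <- P[-nrow(P), , drop = FALSE]
    seg_b[[length(seg_b) + 1]] <- P[-1, , drop = FALSE]
    seg_branch[[length(seg_branch) + 1]] <- rep(id, nrow(P) - 1)
    seg_arc0[[length(seg_arc0) + 1]] <- ws_post[id] + c(0, cumsum(seg))[-nrow(P)]
  }
  A <- do.call(rbind, seg_a); B <- do.call(rbind, seg_b)
  sb <- unlist(seg_branch); sa0 <- unlist(seg_arc0)
  if (is.null(A)) return(empty)
  nn <- nearest_segment(S[, 1:3, drop = FALSE], A, B)
  d <- nn$dist
  post_comp_at <- comp_post[sb[nn$seg]]
  if (include_soma) {
    d_soma <- dist_to_point(S[, 1:3, drop = FALSE],
                            post_graph$root$center) - post_graph$root$radius
    use_soma <- d_soma < d
    d[use_soma] <- pmax(d_soma[use_soma], 0)
    post_comp_at[use_soma] <- "soma"
  } else use_soma <- rep(FALSE, nrow(S))

  inside <- d <= radius
  if (!any(inside)) return(empty)
  # contiguous runs over the DFS sample order
  run_id <- cumsum(c(TRUE, diff(which(inside)) > 1))
  runs <- split(which(inside), run_id)
  # merge runs separated along the axon by <= min_gap
  ev <- list()
  for (r in runs) {
    w0 <- min(S[r, 4]); w1 <- max(S[r, 4])
    merged <- FALSE
    if (length(ev) > 0) {
      last <- ev[[length(ev)]]
      if (w0 - last$w1 <= min_gap && w0 >= last$w1 - min_gap) {
        last$samples <- c(last$samples, r)
        last$w1 <- max(last$w1, w1)
        ev[[length(ev)]] <- last
        merged <- TRUE
      }
    }
    if (!merged) ev[[length(ev) + 1]] <- list(samples = r, w0 = w0, w1 = w1)
  }
  rows <- lapply(seq_along(ev), function(k) {
    r <- ev[[k]]$samples
    j <- r[which.min(d[r])]
    post_pt <- if (use_soma[j]) {
      dirv <- unitize(S[j, 1:3] - post_graph$root$center)
      post_graph$root$center + dirv * post_graph$root$radius
    } else {
      a <- A[nn$seg[j], ]; b <- B[nn$seg[j], ]
      a + nn$t[j] * (b - a)
    }
    pw <- if (use_soma[j]) 0 else
      sa0[nn$seg[j]] + nn$t[j] * vec_norm(B[nn$seg[j], ] - A[nn$seg[j], ])
    tibble::tibble(
      pre_id = pre_id, post_id = post_id, event = k,
      x = S[j, 1], y = S[j, 2], z = S[j, 3],
      post_x = post_pt[1], post_y = post_pt[2], post_z = post_pt[3],
      min_dist_nm = d[j],
      presyn_walk_nm = S[j, 4],
      postsyn_walk_nm = pw,
      post_compartment = post_comp_at[j],
      n_synapses = 0L, synapse_ids = list(integer(0)))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(synapses) && nrow(synapses) > 0) {
    spos <- as.matrix(synapses[, c("x", "y", "z")])
    for (i in seq_len(nrow(spos))) {
      # a synapse links to the event whose axon run passes nearest to it
      dd <- vapply(ev, function(e)
        min(dist_to_point(S[e$samples, 1:3, drop = FALSE], spos[i, ])),
        numeric(1))
      j <- which.min(dd)
      if (dd[j] <= link_radius) {
        out$n_synapses[j] <- out$n_synapses[j] + 1L
        out$synapse_ids[[j]] <- c(out$synapse_ids[[j]],
                                  synapses$synapse_id[i])
      }
    }
  }
  out
}

#' Conversion rate of a set of proximities
#'
#' The fraction of proximity events containing at least one synapse.
#'
#' @param proximities tibble from [compute_proximities()] (with
#'   `n_synapses`).
#' @return a fraction in 0-1, or `NA` (with a warning) when there are no
#'   proximities.
#' @export
conversion_rate <- function(proximities) {
  if (nrow(proximities) == 0) {
    warning("conversion_rate undefined: no proximities")
    return(NA_real_)
  }
  mean(proximities$n_synapses > 0)
}

#' Stratified conversion rates
#'
#' Groups proximity events by any of their columns (pre/post class, post
#' compartment, walk-distance bins) and/or sweeps the proximity radius by
#' re-thresholding the stored minimum distances without recomputation.
#'
#' @param proximities tibble from [compute_proximities()] (rows pooled over
#'   pairs).
#' @param by character vector of grouping column names (may be empty).
#' @param radius_sweep optional numeric vector of radii (nm); each radius
#'   keeps events with `min_dist_nm <= r`.
#' @return tibble of (stratum columns, `radius_nm` if swept,
#'   `n_proximities`, `n_converted`, `rate`).
#' @export
stratify_conversion <- function(proximities, by = character(0),
                                radius_sweep = NULL) {
  bad <- setdiff(by, names(proximities))
  if (length(bad) > 0)
    stop("unknown stratum key(s): ", paste(bad, collapse = ", "))
  one <- function(d, r = NA_real_) {
    if (!is.na(r)) d <- d[d$min_dist_nm <= r, , drop = FALSE]
    g <- if (length(by)) dplyr::group_by(d, dplyr::across(dplyr::all_of(by)))
         else d
    s <- dplyr::summarise(
      g, n_proximities = dplyr::n(),
      n_converted = sum(n_synapses > 0),
      rate = mean(n_synapses > 0), .groups = "drop")
    if (!is.na(r)) s$radius_nm <- r
    s
  }
  if (is.null(radius_sweep)) return(one(proximities))
  dplyr::bind_rows(lapply(radius_sweep, function(r) one(proximities, r)))
}
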