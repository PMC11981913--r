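# Ground-truth neuron generator.  Emulates the statistical and geometric
# structure the downstream pipeline assumes -- tubular neurites with tapering
# radii, a spherical soma, mushroom/stubby spine protrusions, Poisson synapse
# placement with compartment-dependent densities -- and produces per-face and
# per-synapse ground truth, so every stage of the pipeline can be tested
# without external volumes.

#' Default morphology parameters for the synthetic-neuron generator
#'
#' All geometry is in nanometres; densities are quoted per micrometre and
#' converted exactly once, at intake.  The defaults describe a compact spiny
#' pyramidal-like cell: one axon stem, one apical and two basal dendritic
#' stems, one bifurcation per stem, dendritic spine density 1 per um spanning
#' mushroom (800-2,400 nm tall) and stubby (300-600 nm) shapes, shaft synapse
#' density 0.15 per um, axonal bouton density 1 per um.
#'
#' @param ... overrides for any default parameter.
#' @return a named list of generator parameters.
#' @export
neuron_params <- function(...) {
  p <- list(
    n_stems = 4L,            # total stems incl. axon
    depth = 1L,              # bifurcations per stem
    segment_length = c(15000, 30000),  # nm, uniform range per segment
    step = 2000,             # nm between consecutive skeleton points
    jitter_deg = 4,          # per-step direction jitter
    branch_angle = c(30, 50),# degrees, child vs parent
    taper_rate = 0.8,        # child start radius / parent end radius
    within_taper = 0.9,      # end radius / start radius within a segment
    axon_radius = 300,       # nm
    dendrite_radius = 750,   # nm
    soma_radius = 5000,      # nm
    spine_density = 1.0,     # per um of dendritic skeleton
    spine_mushroom_frac = 0.6,
    mushroom_head_radius = c(250, 450),   # nm
    mushroom_neck_radius = c(80, 150),    # nm
    mushroom_neck_length = c(300, 1500),  # nm
    stubby_radius = c(300, 600),          # nm
    syn_shaft_density = 0.15, # per um, incoming, dendritic shaft
    syn_axon_density = 1.0,   # per um, outgoing boutons
    syn_soma_mean = 15,       # Poisson mean of somatic synapses
    p_head_synapse = 0.9,     # probability a spine head carries a synapse
    syn_size_meanlog = log(500), syn_size_sdlog = 0.4,  # cleft voxels
    syn_size_coupling = TRUE, # couple head-synapse size to head volume
    cell_class = "excitatory",
    has_axon = TRUE,
    apical = TRUE,
    depth_axis = c(0, 0, 1),  # unit vector pointing away from the pia
    neuron_id = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  for (nm in c("segment_length", "step", "taper_rate", "axon_radius",
               "dendrite_radius", "soma_radius", "spine_density",
               "syn_shaft_density", "syn_axon_density", "syn_soma_mean",
               "p_head_synapse")) {
    val <- p[[nm]]
    if (!is.numeric(val) || any(!is.finite(val)) || any(val < 0))
      stop("generator parameter must be finite and non-negative: ", nm)
  }
  p
}

rotate_about <- function(v, axis, deg) {
  axis <- unitize(axis)
  th <- deg * pi / 180
  v * cos(th) + cross3(axis, v) * sin(th) + axis * sum(axis * v) * (1 - cos(th))
}

jitter_direction <- function(dir, sd_deg) {
  if (sd_deg <= 0) return(dir)
  ax <- orthogonal_unit(dir)
  ax <- rotate_about(ax, dir, stats::runif(1, 0, 360))
  unitize(rotate_about(dir, ax, stats::rnorm(1, 0, sd_deg)))
}

#' Generate a ground-truth neuron
#'
#' Builds a soma-rooted skeleton tree of tapering neurites with designated
#' axon/apical/basal/oblique compartments, a spine specification on the
#' dendrites, and a Poisson-placed synapse table (outgoing on the axon,
#' incoming on dendritic shafts, spine heads and the soma).  Deterministic for
#' a fixed seed; the caller's RNG state is left untouched.
#'
#' @param params a parameter list from [neuron_params()].
#' @param seed integer seed.
#' @return an object of class `synthetic_neuron` with fields `skeleton`
#'   ([neuro_skeleton()], root = point 1 at the soma centre), `branches`
#'   (list of per-branch records), `soma_center`, `soma_radius`, `spine_spec`
#'   (tibble), `synapses` (tibble), `cell_class`.
#' @export
generate_neuron <- function(params = neuron_params(), seed = 1) {
  p <- do.call(neuron_params, params[setdiff(names(params), "")])
  with_seed(seed, generate_neuron_impl(p))
}

generate_neuron_impl <- function(p) {
  pts <- matrix(c(0, 0, 0), 1, 3)   # point 1 = soma centre (root)
  rad <- p$soma_radius
  branches <- list()
  depth_axis <- unitize(p$depth_axis)

  add_point <- function(xyz, r) {
    pts <<- rbind(pts, xyz)
    rad <<- c(rad, r)
    nrow(pts)
  }

  grow_segment <- function(start_id, dir, r0, compartment, parent_branch) {
    target <- stats::runif(1, p$segment_length[1], p$segment_length[2])
    nstep <- max(2L, as.integer(round(target / p$step)))
    r1 <- r0 * p$within_taper
    ids <- start_id
    cur <- pts[start_id, ]
    for (i in seq_len(nstep)) {
      dir <- jitter_direction(dir, p$jitter_deg)
      cur <- cur + dir * p$step
      ids <- c(ids, add_point(cur, r0 + (r1 - r0) * i / nstep))
    }
    bid <- length(branches) + 1L
    branches[[bid]] <<- list(
      id = bid, parent = parent_branch, point_ids = ids,
      compartment = compartment, r_start = r0, r_end = r1,
      dir_end = dir)
    bid
  }

  grow_tree <- function(bid, depth_left) {
    if (depth_left <= 0) return(invisible())
    b <- branches[[bid]]
    comp_child <- if (b$compartment == "apical") "oblique" else b$compartment
    tip <- b$point_ids[length(b$point_ids)]
    # daughters leave the branch point on roughly opposite azimuths, as real
    # bifurcations do; this also keeps the two subtrees spatially separable
    az0 <- stats::runif(1, 0, 360)
    for (k in 1:2) {
      ang <- stats::runif(1, p$branch_angle[1], p$branch_angle[2])
      az <- az0 + (k - 1) * 180 + stats::runif(1, -40, 40)
      ax <- rotate_about(orthogonal_unit(b$dir_end), b$dir_end, az)
      cdir <- unitize(rotate_about(b$dir_end, ax, ang))
      cid <- grow_segment(tip, cdir, b$r_end * p$taper_rate, comp_child, bid)
      grow_tree(cid, depth_left - 1L)
    }
  }

  # stems: soma surface attachment points
  n_stems <- max(0L, as.integer(p$n_stems))
  stem_specs <- list()
  k <- 1L
  if (isTRUE(p$has_axon) && n_stems >= 1) {
    stem_specs[[k]] <- list(comp = "axon", dir = depth_axis, r = p$axon_radius)
    k <- k + 1L
  }
  if (identical(p$cell_class, "excitatory") && isTRUE(p$apical) && k <= n_stems) {
    stem_specs[[k]] <- list(comp = "apical", dir = -depth_axis,
                            r = p$dendrite_radius * 1.2)
    k <- k + 1L
  }
  while (k <= n_stems) {
    az <- stats::runif(1, 0, 360)
    lat <- unitize(rotate_about(orthogonal_unit(depth_axis), depth_axis, az))
    tilt <- stats::runif(1, -25, 25)
    dirv <- unitize(rotate_about(lat, cross3(depth_axis, lat), tilt))
    stem_specs[[k]] <- list(comp = "basal", dir = dirv, r = p$dendrite_radius)
    k <- k + 1L
  }

  for (s in stem_specs) {
    dirv <- jitter_direction(s$dir, p$jitter_deg)
    surf <- add_point(dirv * p$soma_radius, s$r)
    bid <- grow_segment(surf, dirv, s$r, s$comp, 0L)
    grow_tree(bid, as.integer(p$depth))
  }

  # skeleton edges: root -> stem surface points, then along branches
  edges <- list()
  for (b in branches) {
    ids <- b$point_ids
    if (b$parent == 0L) edges[[length(edges) + 1L]] <- cbind(1L, ids[1])
    edges[[length(edges) + 1L]] <- cbind(ids[-length(ids)], ids[-1])
  }
  edge_mat <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), 0, 2)
  skel <- neuro_skeleton(pts, edge_mat, rad, root = 1L)

  branch_lengths <- vapply(branches, function(b)
    polyline_length(pts[b$point_ids, , drop = FALSE]), numeric(1))

  # ---- spines (dendrites only) -------------------------------------------
  spine_rows <- list()
  sid <- 0L
  for (b in branches) {
    if (b$compartment == "axon" || p$spine_density <= 0) next
    L_um <- branch_lengths[b$id] / 1000
    n_sp <- stats::rpois(1, p$spine_density * L_um)
    if (n_sp == 0) next
    t_arc <- sort(stats::runif(n_sp, 0.05, 0.95)) * branch_lengths[b$id]
    for (j in seq_len(n_sp)) {
      sid <- sid + 1L
      loc <- branch_point_at_arc(pts, b, t_arc[j])
      radial <- rotate_about(orthogonal_unit(loc$tangent), loc$tangent,
                             stats::runif(1, 0, 360))
      base <- loc$point + radial * loc$radius
      if (stats::runif(1) < p$spine_mushroom_frac) {
        hr <- stats::runif(1, p$mushroom_head_radius[1], p$mushroom_head_radius[2])
        nr <- stats::runif(1, p$mushroom_neck_radius[1], p$mushroom_neck_radius[2])
        nl <- stats::runif(1, p$mushroom_neck_length[1], p$mushroom_neck_length[2])
        spine_rows[[sid]] <- tibble::tibble(
          spine_id = sid, branch_id = b$id, type = "mushroom",
          base_x = base[1], base_y = base[2], base_z = base[3],
          dir_x = radial[1], dir_y = radial[2], dir_z = radial[3],
          head_radius = hr, neck_radius = nr, neck_length = nl,
          length_nm = nl + 2 * hr,
          head_volume_nm3 = 4 / 3 * pi * hr^3)
      } else {
        sr <- stats::runif(1, p$stubby_radius[1], p$stubby_radius[2])
        spine_rows[[sid]] <- tibble::tibble(
          spine_id = sid, branch_id = b$id, type = "stubby",
          base_x = base[1], base_y = base[2], base_z = base[3],
          dir_x = radial[1], dir_y = radial[2], dir_z = radial[3],
          head_radius = sr, neck_radius = NA_real_, neck_length = 0,
          length_nm = sr,
          head_volume_nm3 = 2 / 3 * pi * sr^3)
      }
    }
  }
  spine_spec <- if (length(spine_rows)) dplyr::bind_rows(spine_rows) else
    tibble::tibble(spine_id = integer(), branch_id = integer(),
                   type = character(), base_x = double(), base_y = double(),
                   base_z = double(), dir_x = double(), dir_y = double(),
                   dir_z = double(), head_radius = double(),
                   neck_radius = double(), neck_length = double(),
                   length_nm = double(), head_volume_nm3 = double())

  # ---- synapses -----------------------------------------------------------
  syn_rows <- list()
  nid <- as.integer(p$neuron_id)
  add_syn <- function(pos, size, direction, compartment, spine_id = NA_integer_) {
    syn_rows[[length(syn_rows) + 1L]] <<- tibble::tibble(
      pre_id = if (direction == "outgoing") nid else 0L,
      post_id = if (direction == "outgoing") 0L else nid,
      x = pos[1], y = pos[2], z = pos[3], size = size,
      direction = direction, compartment = compartment,
      spine_id = spine_id, valid = TRUE)
  }
  syn_size <- function(n) stats::rlnorm(n, p$syn_size_meanlog, p$syn_size_sdlog)

  for (b in branches) {
    L_um <- branch_lengths[b$id] / 1000
    dens <- if (b$compartment == "axon") p$syn_axon_density else p$syn_shaft_density
    dirn <- if (b$compartment == "axon") "outgoing" else "incoming"
    n_syn <- stats::rpois(1, dens * L_um)
    if (n_syn == 0) next
    t_arc <- stats::runif(n_syn) * branch_lengths[b$id]
    sz <- syn_size(n_syn)
    for (j in seq_len(n_syn)) {
      loc <- branch_point_at_arc(pts, b, t_arc[j])
      radial <- rotate_about(orthogonal_unit(loc$tangent), loc$tangent,
                             stats::runif(1, 0, 360))
      add_syn(loc$point + radial * loc$radius, sz[j], dirn, b$compartment)
    }
  }
  if (nrow(spine_spec) > 0) {
    for (j in seq_len(nrow(spine_spec))) {
      if (stats::runif(1) >= p$p_head_synapse) next
      sp <- spine_spec[j, ]
      dirv <- c(sp$dir_x, sp$dir_y, sp$dir_z)
      base <- c(sp$base_x, sp$base_y, sp$base_z)
      tip <- if (sp$type == "mushroom")
        base + dirv * (sp$neck_length + 2 * sp$head_radius) else
        base + dirv * sp$head_radius
      sz <- if (isTRUE(p$syn_size_coupling))
        sp$head_volume_nm3 / 5e5 * stats::rlnorm(1, 0, 0.25) else syn_size(1)
      host <- branches[[sp$branch_id]]$compartment
      add_syn(tip, sz, "incoming", host, spine_id = sp$spine_id)
    }
  }
  n_soma <- stats::rpois(1, p$syn_soma_mean)
  if (n_soma > 0) {
    for (j in seq_len(n_soma)) {
      u <- unitize(stats::rnorm(3))
      add_syn(u * p$soma_radius, syn_size(1), "incoming", "soma")
    }
  }
  synapses <- if (length(syn_rows)) dplyr::bind_rows(syn_rows) else
    tibble::tibble(pre_id = integer(), post_id = integer(), x = double(),
                   y = double(), z = double(), size = double(),
                   direction = character(), compartment = character(),
                   spine_id = integer(), valid = logical())
  if (nrow(synapses) > 0)
    synapses <- dplyr::mutate(synapses,
                              synapse_id = dplyr::row_number(),
                              .before = 1)
  else synapses$synapse_id <- integer()

  structure(list(
    skeleton = skel, branches = branches,
    branch_lengths = branch_lengths,
    soma_center = c(0, 0, 0), soma_radius = p$soma_radius,
    spine_spec = spine_spec, synapses = synapses,
    cell_class = p$cell_class, depth_axis = depth_axis,
    neuron_id = nid, params = p), class = "synthetic_neuron")
}

# Interpolated point, tangent and radius at arc position `s` along a branch.
branch_point_at_arc <- function(pts, branch, s) {
  ids <- branch$point_ids
  P <- pts[ids, , drop = FALSE]
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  point <- P[i, ] + f * (P[i + 1, ] - P[i, ])
  nsteps <- length(ids) - 1
  r <- branch$r_start + (branch$r_end - branch$r_start) * (i - 1 + f) / nsteps
  list(point = point, tangent = unitize(P[i + 1, ] - P[i, ]), radius = r)
}

#' @export
print.synthetic_neuron <- function(x, ...) {
  cat(sprintf(
    "<synthetic_neuron> %s, %d branches (%.0f um), %d spines, %d synapses\n",
    x$cell_class, length(x$branches), sum(x$branch_lengths) / 1000,
    nrow(x$spine_spec), nrow(x$synapses)))
  invisible(x)
}
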