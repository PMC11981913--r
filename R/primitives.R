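# Mesh construction primitives for the synthetic-neuron generator: swept
# frustum tubes with parallel-transport frames, icospheres, hemispheres and
# weld collars.  All constructors emit counter-clockwise (outward) winding.

icosahedron_base <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)) + 1L
  list(v = v, f = f)
}

# Unit icosphere; `subdiv` rounds of 4-way triangle subdivision.
icosphere_unit <- function(subdiv = 2) {
  base <- icosahedron_base()
  v <- base$v; f <- base$f
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    extra <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mget(key, envir = mid_cache, ifnotfound = NA)[[1]]
      if (!is.na(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      extra[[length(extra) + 1]] <<- p
      id <- nv + length(extra)
      assign(key, id, envir = mid_cache)
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(k - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- nf
  }
  list(v = v, f = f)
}

icosphere_mesh <- function(center, radius, subdiv = 2) {
  s <- icosphere_unit(subdiv)
  neuro_mesh(sweep(s$v * radius, 2, center, "+"), s$f)
}

# Hemispherical dome of given radius over `center`, bulging along `axis`.
# Built from latitude rings so the open base ring is vertices 1..resolution
# in cyclic order (needed for weld collars).
dome_mesh <- function(center, radius, axis, resolution = 10, nrings = 4) {
  axis <- unitize(axis)
  e1 <- orthogonal_unit(axis); e2 <- cross3(axis, e1)
  theta <- seq(0, 2 * pi, length.out = resolution + 1)[-(resolution + 1)]
  phi <- seq(0, pi / 2, length.out = nrings + 1)[seq_len(nrings)]
  verts <- matrix(0, nrings * resolution + 1, 3)
  for (k in seq_len(nrings)) {
    ring <- outer(cos(theta) * cos(phi[k]), e1) +
      outer(sin(theta) * cos(phi[k]), e2) +
      matrix(rep(axis * sin(phi[k]), each = resolution), resolution, 3)
    verts[(k - 1) * resolution + seq_len(resolution), ] <-
      sweep(ring * radius, 2, center, "+")
  }
  apex_id <- nrings * resolution + 1L
  verts[apex_id, ] <- center + axis * radius
  faces <- list()
  j1 <- c(seq_len(resolution)[-1], 1)
  for (k in seq_len(nrings - 1)) {
    a <- (k - 1) * resolution + seq_len(resolution)
    b <- k * resolution + seq_len(resolution)
    faces[[k]] <- rbind(cbind(a, a[j1], b), cbind(a[j1], b[j1], b))
  }
  top <- (nrings - 1) * resolution + seq_len(resolution)
  faces[[nrings]] <- cbind(top, top[j1], apex_id)
  neuro_mesh(verts, do.call(rbind, faces))
}

# Parallel-transport orthonormal frames along a polyline (k x 3).
transport_frames <- function(pts) {
  k <- nrow(pts)
  tans <- matrix(0, k, 3)
  seg <- diff(pts)
  seg <- seg / sqrt(rowSums(seg^2))
  tans[1, ] <- seg[1, ]
  if (k > 2) for (i in 2:(k - 1)) tans[i, ] <- unitize(seg[i - 1, ] + seg[i, ])
  tans[k, ] <- seg[k - 1, ]
  e1 <- matrix(0, k, 3); e2 <- matrix(0, k, 3)
  e1[1, ] <- orthogonal_unit(tans[1, ])
  e2[1, ] <- cross3(tans[1, ], e1[1, ])
  if (k > 1) for (i in 2:k) {
    prev <- e1[i - 1, ]
    proj <- prev - sum(prev * tans[i, ]) * tans[i, ]
    e1[i, ] <- if (vec_norm(proj) < 1e-8) orthogonal_unit(tans[i, ]) else unitize(proj)
    e2[i, ] <- cross3(tans[i, ], e1[i, ])
  }
  list(tangent = tans, e1 = e1, e2 = e2)
}

# Swept frustum tube along `pts` with per-point `radii`; `resolution` vertices
# per ring.  Optional cone caps.  Returns a neuro_mesh.
tube_mesh <- function(pts, radii, resolution = 10,
                      cap_start = FALSE, cap_end = TRUE) {
  pts <- as.matrix(pts)
  k <- nrow(pts)
  if (k < 2) stop("tube_mesh needs >= 2 path points")
  if (length(radii) == 1) radii <- rep(radii, k)
  fr <- transport_frames(pts)
  theta <- seq(0, 2 * pi, length.out = resolution + 1)[-(resolution + 1)]
  verts <- matrix(0, k * resolution, 3)
  for (i in seq_len(k)) {
    ring <- outer(cos(theta), fr$e1[i, ]) + outer(sin(theta), fr$e2[i, ])
    verts[(i - 1) * resolution + seq_len(resolution), ] <-
      sweep(ring * radii[i], 2, pts[i, ], "+")
  }
  faces <- list()
  for (i in seq_len(k - 1)) {
    a <- (i - 1) * resolution + seq_len(resolution)
    b <- i * resolution + seq_len(resolution)
    j1 <- c(seq_len(resolution)[-1], 1)
    faces[[i]] <- rbind(cbind(a, a[j1], b),
                        cbind(a[j1], b[j1], b))
  }
  f <- do.call(rbind, faces)
  if (cap_end) {
    apex <- pts[k, ] + fr$tangent[k, ] * radii[k] * 0.3
    verts <- rbind(verts, apex)
    ai <- nrow(verts)
    b <- (k - 1) * resolution + seq_len(resolution)
    j1 <- c(seq_len(resolution)[-1], 1)
    f <- rbind(f, cbind(b, b[j1], ai))
  }
  if (cap_start) {
    apex <- pts[1, ] - fr$tangent[1, ] * radii[1] * 0.3
    verts <- rbind(verts, apex)
    ai <- nrow(verts)
    a <- seq_len(resolution)
    j1 <- c(seq_len(resolution)[-1], 1)
    f <- rbind(f, cbind(a[j1], a, ai))
  }
  neuro_mesh(verts, f)
}

# Concatenate labelled part meshes into one mesh + per-face label vector.
mesh_cat <- function(parts, labels) {
  stopifnot(length(parts) == length(labels))
  nv <- 0L
  vs <- list(); fs <- list(); lab <- list()
  for (i in seq_along(parts)) {
    m <- parts[[i]]
    vs[[i]] <- m$vertices
    fs[[i]] <- m$faces + nv
    lab[[i]] <- rep(labels[[i]], nrow(m$faces))
    nv <- nv + nrow(m$vertices)
  }
  list(mesh = neuro_mesh(do.call(rbind, vs), do.call(rbind, fs)),
       labels = unlist(lab))
}

# Bridge a part's base ring onto its host surface: one triangle per ring
# vertex, connecting consecutive ring vertices to the nearest host vertex.
# Keeps the combined mesh a single connected component while leaving the
# face-level ground truth exact (collar faces carry their own label).
weld_collar_faces <- function(vertices, ring_ids, host_ids) {
  hv <- vertices[host_ids, , drop = FALSE]
  nearest <- vapply(ring_ids, function(rid) {
    host_ids[which.min(dist_to_point(hv, vertices[rid, ]))]
  }, integer(1))
  n <- length(ring_ids)
  j1 <- c(seq_len(n)[-1], 1)
  f <- cbind(ring_ids, ring_ids[j1], nearest)
  f[f[, 1] != f[, 3] & f[, 2] != f[, 3], , drop = FALSE]
}
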