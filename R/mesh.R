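#' Indexed triangle mesh in nanometre coordinates
#'
#' A minimal container for the surface meshes the pipeline consumes: a numeric
#' `vertices` matrix (N x 3, nm) and an integer `faces` matrix (M x 3, 1-based
#' vertex indices).  Meshes produced by [mesh_from_neuron()] additionally carry
#' a per-face character label vector linking every face back to its generating
#' branch, spine, soma or weld collar.
#'
#' @param vertices numeric matrix, N x 3, coordinates in nm.
#' @param faces integer matrix, M x 3, 1-based indices into `vertices`.
#' @return An object of class `neuro_mesh`.
#' @export
neuro_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3) stop("vertices must be an N x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  structure(list(vertices = vertices, faces = faces), class = "neuro_mesh")
}

#' @export
print.neuro_mesh <- function(x, ...) {
  cat(sprintf("<neuro_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
      v[f[, 3], , drop = FALSE]) / 3
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx * cx + cy * cy + cz * cz)
}

#' Surface area of a mesh (nm^2)
#' @param mesh a [neuro_mesh()].
#' @return total triangle area in nm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a (near-)closed face set (nm^3)
#'
#' Divergence-theorem signed volume relative to `origin`.  Exact for closed,
#' consistently wound meshes; for an open cap-less submesh the origin should be
#' placed on the cut ring so the missing cap contributes ~0.
#'
#' @param mesh a [neuro_mesh()].
#' @param faces optional integer vector of face ids restricting the sum.
#' @param origin 3-vector reference point, defaults to the vertex centroid.
#' @return volume in nm^3 (absolute value of the signed sum).
#' @export
mesh_volume <- function(mesh, faces = NULL, origin = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  v <- mesh$vertices
  if (is.null(origin)) origin <- colMeans(v[unique(as.vector(f)), , drop = FALSE])
  a <- sweep(v[f[, 1], , drop = FALSE], 2, origin)
  b <- sweep(v[f[, 2], , drop = FALSE], 2, origin)
  cc <- sweep(v[f[, 3], , drop = FALSE], 2, origin)
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det6) / 6)
}

# Outward vertex normals, area-weighted over incident faces.  Assumes the
# counter-clockwise winding every constructor in this package uses.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], f[, k], nrow(v))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], f[, k], nrow(v))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], f[, k], nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Undirected unique vertex-edge list of the mesh (k x 2, i < j).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# igraph over mesh vertices with Euclidean edge weights.
mesh_vertex_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  igraph::E(g)$weight <- w
  g
}

# Connected components over vertices; returns integer membership per vertex.
mesh_components <- function(mesh) {
  g <- mesh_vertex_graph(mesh)
  igraph::components(g)$membership
}

#' Clean a triangle mesh
#'
#' Merges duplicate vertices (within `tol` nm), drops degenerate (zero-area)
#' faces and, optionally, keeps only the largest connected component.
#' Idempotent on already-clean meshes.
#'
#' @param mesh a [neuro_mesh()].
#' @param tol vertex merge tolerance in nm (default 1).
#' @param largest_component if `TRUE`, keep only the largest connected
#'   component (off by default: orphan fragments are real objects here).
#' @return a cleaned `neuro_mesh`; a `face_map` attribute gives, for every
#'   retained face, its row index in the input mesh.
#' @export
clean_mesh <- function(mesh, tol = 1, largest_component = FALSE) {
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0)
    stop("clean_mesh: empty mesh")
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  new_id <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f2 <- matrix(new_id[mesh$faces], ncol = 3)
  keep <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  m2 <- neuro_mesh(v2, f2[keep, , drop = FALSE])
  areas <- face_areas(m2)
  nz <- areas > 1e-9
  face_map <- which(keep)[nz]
  m2 <- neuro_mesh(m2$vertices, m2$faces[nz, , drop = FALSE])
  if (largest_component) {
    memb <- mesh_components(m2)
    big <- as.integer(names(which.max(table(memb))))
    fv <- memb[m2$faces[, 1]] == big
    face_map <- face_map[fv]
    keep_v <- which(memb == big)
    remap <- match(seq_len(nrow(m2$vertices)), keep_v)
    m2 <- neuro_mesh(m2$vertices[keep_v, , drop = FALSE],
                     matrix(remap[m2$faces[fv, ]], ncol = 3))
  }
  attr(m2, "face_map") <- face_map
  m2
}

# ---- I/O ------------------------------------------------------------------

#' Read / write meshes in OFF format
#'
#' Plain-text Object File Format: header `OFF`, counts line, vertex block,
#' face block.  Coordinates are taken as nanometres.
#'
#' @param path file path.
#' @return `read_off()` returns a [neuro_mesh()].
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1])) stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vert <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                      quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- lines[(3 + nv):(2 + nv + nf)]
  fx <- matrix(scan(text = paste(fl, collapse = "\n"), quiet = TRUE),
               ncol = 4, byrow = TRUE)
  if (any(fx[, 1] != 3)) stop("only triangle faces supported")
  neuro_mesh(vert, fx[, 2:4] + 1L)
}

#' @rdname read_off
#' @param mesh a [neuro_mesh()].
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.3f %.3f %.3f", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh in PLY format
#'
#' @param mesh a [neuro_mesh()].
#' @param path file path.
#' @param binary write binary little-endian PLY (default) or ASCII.
#' @export
write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.3f %.3f %.3f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path file path.
#' @return a [neuro_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(lines == "end_header")[1]
  if (is.na(end)) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines[1:end])))
    stop("read_ply only supports ASCII PLY")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines[1:end], value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines[1:end], value = TRUE)))
  vert <- matrix(scan(text = paste(lines[(end + 1):(end + nv)], collapse = "\n"),
                      quiet = TRUE), ncol = 3, byrow = TRUE)
  fx <- matrix(scan(text = paste(lines[(end + nv + 1):(end + nv + nf)],
                                 collapse = "\n"), quiet = TRUE),
               ncol = 4, byrow = TRUE)
  neuro_mesh(vert, fx[, 2:4] + 1L)
}
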