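# Small vector-geometry kernel shared by the mesh, skeleton and proximity code.
# All coordinates are nanometres; all direction vectors are unit length.

vec_norm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors in degrees, in [0, 180]
angle_deg <- function(a, b) {
  na <- vec_norm(a); nb <- vec_norm(b)
  if (na == 0 || nb == 0) return(NA_real_)
  ct <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, ct))) * 180 / pi
}

# any unit vector orthogonal to v
orthogonal_unit <- function(v) {
  v <- unitize(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(cross3(v, ref))
}

# Euclidean distances from points (n x 3) to a single point
dist_to_point <- function(pts, p) {
  sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2)
}

# Distance from each point in `pts` (n x 3) to segment a-b; vectorised over pts.
dist_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(dist_to_point(pts, a))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
          (pts[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- pts[, 1] - (a[1] + t * ab[1])
  dy <- pts[, 2] - (a[2] + t * ab[2])
  dz <- pts[, 3] - (a[3] + t * ab[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# For every point, the minimum distance over a set of segments (segments given
# as two n_seg x 3 matrices).  Returns list(dist, seg, t): nearest segment index
# and the parameter along it.  Brute force but fully vectorised per segment;
# meshes and skeletons at the scales handled here keep this well inside budget.
nearest_segment <- function(pts, seg_a, seg_b) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  best_seg <- rep(NA_integer_, n)
  best_t <- rep(NA_real_, n)
  for (j in seq_len(nrow(seg_a))) {
    a <- seg_a[j, ]; b <- seg_b[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- dist_to_point(pts, a)
      t <- rep(0, n)
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
              (pts[, 3] - a[3]) * ab[3]) / len2
      t <- pmin(1, pmax(0, t))
      dx <- pts[, 1] - (a[1] + t * ab[1])
      dy <- pts[, 2] - (a[2] + t * ab[2])
      dz <- pts[, 3] - (a[3] + t * ab[3])
      d <- sqrt(dx * dx + dy * dy + dz * dz)
    }
    hit <- d < best
    if (any(hit)) {
      best[hit] <- d[hit]
      best_seg[hit] <- j
      best_t[hit] <- t[hit]
    }
  }
  list(dist = best, seg = best_seg, t = best_t)
}

# Length of a polyline given as an ordered n x 3 matrix.
polyline_length <- function(pts) {
  if (is.null(dim(pts)) || nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic sub-stream seed from a master seed; keeps results
# reproducible while letting independent stages draw independently.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 9176) %% 2147483629)
}

um_to_nm <- function(x) x * 1000
nm_to_um <- function(x) x / 1000
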