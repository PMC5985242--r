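# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

# UV-sphere triangle mesh of given radius, centered at the origin,
# outward-oriented
make_sphere <- function(radius = 10, n_lat = 24L, n_lon = 48L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2L)[-c(1L, n_lat + 2L)]
  verts <- list(c(0, 0, -radius))
  for (la in lat) {
    lo <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
    verts <- c(verts, lapply(lo, function(l)
      radius * c(cos(la) * cos(l), cos(la) * sin(l), sin(la))))
  }
  verts <- c(verts, list(c(0, 0, radius)))
  v <- do.call(rbind, verts)
  ring <- function(i) 1L + (i - 1L) * n_lon + seq_len(n_lon)
  nxt <- c(seq_len(n_lon)[-1L], 1L)
  faces <- list(cbind(1L, ring(1L)[nxt], ring(1L)))
  for (i in seq_len(n_lat - 1L)) {
    lo <- ring(i); hi <- ring(i + 1L)
    faces[[length(faces) + 1L]] <- rbind(cbind(lo, lo[nxt], hi[nxt]),
                                         cbind(lo, hi[nxt], hi))
  }
  top <- nrow(v)
  faces[[length(faces) + 1L]] <- cbind(top, ring(n_lat), ring(n_lat)[nxt])
  triangle_mesh(v, do.call(rbind, faces))
}

# square planar patch in the z = z0 plane with +z normals
make_plane_patch <- function(n = 10L, size = 10, z0 = 0) {
  g <- seq(-size / 2, size / 2, length.out = n)
  v <- as.matrix(expand.grid(x = g, y = g))
  v <- cbind(v, z0)
  idx <- function(i, j) (j - 1L) * n + i
  faces <- list()
  for (j in seq_len(n - 1L)) for (i in seq_len(n - 1L)) {
    faces[[length(faces) + 1L]] <- rbind(
      c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
      c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  triangle_mesh(v, do.call(rbind, faces))
}

# uniformly random proper rotation (quaternion method) + random translation
random_rigid <- function(max_trans = 20) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  rigid_transform(R, stats::runif(3, -max_trans, max_trans))
}

# independent closest-point-on-triangle oracle: projection onto the
# triangle plane followed by clamping to each edge segment; exhaustive
# minimum over candidate points (orthogonal projection when it falls
# inside, plus closest points of all three edges)
oracle_closest_on_triangle <- function(p, a, b, c) {
  seg <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    u + min(max(t, 0), 1) * d
  }
  cands <- list(seg(p, a, b), seg(p, b, c), seg(p, c, a))
  n <- pracma::cross(b - a, c - a)
  if (sum(n^2) > 0) {
    q <- p - sum((p - a) * n) / sum(n * n) * n   # projection onto the plane
    # inside test via barycentric signs
    s1 <- sum(pracma::cross(b - a, q - a) * n)
    s2 <- sum(pracma::cross(c - b, q - b) * n)
    s3 <- sum(pracma::cross(a - c, q - c) * n)
    if (s1 >= -1e-12 && s2 >= -1e-12 && s3 >= -1e-12)
      cands <- c(cands, list(q))
  }
  d2 <- vapply(cands, function(q) sum((p - q)^2), numeric(1))
  cands[[which.min(d2)]]
}

# exhaustive nearest-point query over all triangles of a mesh
oracle_nearest_on_mesh <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  t(apply(points, 1L, function(p) {
    best <- NULL
    bd <- Inf
    for (k in seq_len(nrow(f))) {
      q <- oracle_closest_on_triangle(p, v[f[k, 1L], ], v[f[k, 2L], ],
                                      v[f[k, 3L], ])
      d <- sum((p - q)^2)
      if (d < bd) { bd <- d; best <- q }
    }
    c(best, sqrt(bd))
  }))
}

# default small tooth used across tests (cached per test run)
default_tooth <- local({
  cache <- NULL
  function(res = 3L) {
    if (is.null(cache)) cache <<- make_tooth(tooth_spec(mesh_resolution = res))
    cache
  }
})

max_vertex_error <- function(mesh, t_est, t_true) {
  d <- transform_points(mesh$vertices, t_est) -
    transform_points(mesh$vertices, t_true)
  max(sqrt(rowSums(d^2)))
}
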