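#' Triangle surface mesh
#'
#' The basic container of the package: an indexed triangle mesh with
#' coordinates in millimetres, the unit in which CBCT segmentations and
#' laser scans are exported and in which all displacements are reported.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param colors optional integer matrix of per-vertex RGB values in 0..255.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces` and (optionally) `colors`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1L, 2L, 3L)))
#' n_vertices(m)
#' @export
triangle_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) == 0L) stop("mesh has zero faces")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face index out of range (must be in 1..n_vertices)")
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  if (any(degen))
    stop("degenerate faces (repeated vertex index) at rows: ",
         paste(utils::head(which(degen), 5L), collapse = ", "))
  m <- list(vertices = vertices, faces = faces)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "integer"
    if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
      stop("colors must be an n_vertices x 3 RGB matrix")
    if (min(colors) < 0L || max(colors) > 255L)
      stop("colors must be in 0..255")
    m$colors <- colors
  }
  structure(m, class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$colors)) ", per-vertex colors" else ""))
  bb <- mesh_bbox(x)
  cat(sprintf("  extent (mm): [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `triangle_mesh`
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Axis-aligned bounding box
#' @param mesh a `triangle_mesh`
#' @return 2 x 3 matrix, rows min/max, columns x/y/z (mm).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2L, min),
        max = apply(mesh$vertices, 2L, max))
}

# cross products of the two edge vectors of every face, rows = faces
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Per-face areas and total surface area
#' @param mesh a `triangle_mesh`
#' @return `face_areas`: numeric vector of triangle areas (mm^2);
#'   `mesh_area`: their sum.
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Signed enclosed volume
#'
#' Divergence-theorem volume of a closed mesh; positive when faces are
#' consistently oriented with outward normals.
#' @param mesh a `triangle_mesh`
#' @return volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  d <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) +
      a[, 2L] * (b[, 3L] * d[, 1L] - b[, 1L] * d[, 3L]) +
      a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])) / 6
}

#' Per-vertex normals
#'
#' Area-weighted average of incident face normals, normalized. Used as the
#' perturbation direction of the scan-noise model.
#' @param mesh a `triangle_mesh`
#' @return n_vertices x 3 matrix of unit normals (zero rows for isolated
#'   vertices).
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)   # length = 2 * area, direction = face normal
  n <- matrix(0, nrow(mesh$vertices), 3L)
  idx <- as.vector(mesh$faces)          # each face contributes to 3 vertices
  for (j in 1:3) {
    acc <- rowsum(rep(cr[, j], 3L), idx)
    n[as.integer(rownames(acc)), j] <- acc[, 1L]
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Concatenate meshes
#'
#' Stacks vertices and faces of several meshes into one (used for the
#' per-arch "combined crowns" fit of the control superimposition).
#' @param meshes list of `triangle_mesh`
#' @return a single `triangle_mesh`; colors are dropped.
#' @export
merge_meshes <- function(meshes) {
  meshes <- meshes[!vapply(meshes, is.null, logical(1L))]
  if (length(meshes) == 0L) stop("no meshes to merge")
  vs <- lapply(meshes, `[[`, "vertices")
  offs <- cumsum(c(0L, vapply(vs, nrow, integer(1L))))
  fs <- mapply(function(m, o) m$faces + o, meshes, offs[-length(offs)],
               SIMPLIFY = FALSE)
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Drop vertices not referenced by any face
#' @param mesh a `triangle_mesh`
#' @return compacted `triangle_mesh` (colors carried over).
#' @export
compact_mesh <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[mesh$faces], ncol = 3L),
                colors = if (!is.null(mesh$colors))
                  mesh$colors[used, , drop = FALSE] else NULL)
}

#' Boundary edge loops
#'
#' Edges used by exactly one triangle, grouped into connected loops. A
#' watertight mesh has none; a crown cropped at the cemento-enamel junction
#' has exactly one (the cut rim).
#' @param mesh a `triangle_mesh`
#' @return list of integer vectors (vertex indices per loop), possibly empty.
#' @export
boundary_loops <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(list())
  be <- e[key %in% bkey, , drop = FALSE]
  # walk loops
  adj <- split(c(be[, 2L], be[, 1L]), c(be[, 1L], be[, 2L]))
  visited <- character(0)
  loops <- list()
  for (start in unique(be[, 1L])) {
    if (as.character(start) %in% visited) next
    loop <- integer(0)
    prev <- NA_integer_
    cur <- start
    repeat {
      loop <- c(loop, cur)
      visited <- c(visited, as.character(cur))
      nxts <- adj[[as.character(cur)]]
      nxts <- nxts[!(nxts %in% c(prev, loop[1L])) | (length(loop) > 2L & nxts == loop[1L])]
      nxt <- setdiff(nxts, loop)
      if (length(nxt) == 0L) break
      prev <- cur
      cur <- nxt[1L]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}
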