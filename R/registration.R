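#' Three-point landmark registration (Kabsch)
#'
#' Least-squares rigid alignment of paired landmark sets — the digital
#' analogue of picking three matching points on the CBCT crown and on the
#' laser-scanned crown. Solves the orthogonal Procrustes problem without
#' scaling (Kabsch/Umeyama with unit scale): for exact correspondences of
#' three or more non-collinear points the residual is zero and the rigid
#' map is unique.
#'
#' @param source,target k x 3 matrices (k >= 3) of corresponding points
#'   (mm), same row order.
#' @return a [rigid_transform()] `t` minimizing
#'   `sum(|transform_points(source, t) - target|^2)`.
#' @export
landmark_register <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) != nrow(target))
    stop("source and target must have the same number of points")
  if (nrow(source) < 3L) stop("at least 3 landmark points are required")
  check_not_collinear(source, "source")
  check_not_collinear(target, "target")
  cs <- colMeans(source)
  ct <- colMeans(target)
  H <- crossprod(sweep(source, 2L, cs), sweep(target, 2L, ct))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R <- orthonormalize(R)
  rigid_transform(R, as.numeric(ct - R %*% cs))
}

check_not_collinear <- function(pts, what = "landmark") {
  if (nrow(pts) < 3L) stop(what, " points: need at least 3")
  centered <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(centered, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-9)
    stop(what, " points are collinear (degenerate landmark set)")
  invisible(TRUE)
}

#' Nearest points on a mesh surface
#'
#' For each query point, the exact nearest point on the target surface
#' (point-to-triangle, not point-to-vertex), via an axis-aligned bounding
#' box tree over the triangles.
#'
#' @param points n x 3 query coordinates (mm).
#' @param mesh a [triangle_mesh()].
#' @return list with `point` (n x 3 nearest surface points), `distance`
#'   (unsigned, mm) and `triangle` (1-based index of the nearest triangle).
#' @export
nearest_on_mesh <- function(points, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  res <- cpp_nearest_on_mesh(points, mesh$vertices, mesh$faces)
  res[c("point", "distance", "triangle")]
}

#' Iterative closest point registration
#'
#' Point-to-point ICP from (sampled) source vertices to their exact nearest
#' points on the target surface. Each iteration matches, optionally rejects
#' correspondences farther than `reject_dist` (which discards regions with
#' no true counterpart — bracket and band artifacts, or root points facing
#' a crown-only scan), re-estimates the rigid transform by Kabsch on the
#' accepted pairs, and stops when the RMS improvement falls below `tol`.
#'
#' @param source,target [triangle_mesh()] objects; `source` moves onto
#'   `target`.
#' @param init initial [rigid_transform()] (e.g. from
#'   [landmark_register()]).
#' @param max_iterations maximum ICP iterations (default 500).
#' @param tol convergence tolerance on the change in RMS between
#'   iterations, mm (default 1e-7; point-to-point ICP creeps tangentially,
#'   so a loose tolerance stops it well before the pose has settled).
#' @param reject_dist correspondence rejection distance in mm (default
#'   1.0); `Inf` disables rejection.
#' @param sample_count number of source vertices used (default
#'   `min(5000, n_vertices)`), drawn deterministically from `seed`.
#' @param seed integer seed for the vertex subsample (default 0).
#' @return object of class `icp_result`: list with `transform` (composed
#'   with `init`), `rms` (mm, over accepted correspondences after the final
#'   iteration), `iterations_run`, `converged`, `n_accepted`.
#' @export
icp_register <- function(source, target, init = transform_identity(),
                         max_iterations = 500L, tol = 1e-7,
                         reject_dist = 1.0, sample_count = 5000L, seed = 0L) {
  stopifnot(inherits(source, "triangle_mesh"), inherits(target, "triangle_mesh"))
  stopifnot(inherits(init, "rigid_transform"))
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  pts <- source$vertices
  n <- nrow(pts)
  if (!is.null(sample_count) && sample_count < n) {
    idx <- with_seed(seed, sample.int(n, sample_count))
    pts <- pts[idx, , drop = FALSE]
  }
  t_cur <- init
  rms_prev <- Inf
  rms <- NA_real_
  rms_history <- numeric(0)
  n_acc <- 0L
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    iters <- it
    moved <- transform_points(pts, t_cur)
    nn <- nearest_on_mesh(moved, target)
    keep <- nn$distance <= reject_dist
    n_acc <- sum(keep)
    if (n_acc < 3L)
      stop("ICP correspondence starvation: ", n_acc,
           " pairs within reject_dist = ", reject_dist, " mm")
    rms <- sqrt(mean(nn$distance[keep]^2))
    rms_history <- c(rms_history, rms)
    if (abs(rms_prev - rms) < tol) { converged <- TRUE; break }
    rms_prev <- rms
    # Kabsch on the accepted pairs gives the incremental refinement
    step <- landmark_register(moved[keep, , drop = FALSE],
                              nn$point[keep, , drop = FALSE])
    t_cur <- compose_transform(step, t_cur)
  }
  structure(list(transform = t_cur, rms = rms, iterations_run = iters,
                 converged = converged, n_accepted = n_acc,
                 rms_history = rms_history),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("icp_result: rms %.6f mm after %d iterations (%s, %d pairs)\n",
              x$rms, x$iterations_run,
              if (x$converged) "converged" else "max iterations", x$n_accepted))
  invisible(x)
}

#' Read / write per-tooth landmark files
#'
#' JSON layout: `{"tooth": "11", "points": [[x,y,z], ...]}` with
#' coordinates in mm.
#' @param path JSON file path.
#' @param points k x 3 matrix of landmark coordinates.
#' @param tooth_id optional FDI code stored alongside the points.
#' @return `read_landmarks`: list with `points` (matrix) and `tooth_id`;
#'   `write_landmarks`: `path` invisibly.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$points)) stop("landmark JSON lacks a \"points\" key")
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  list(points = pts, tooth_id = if (!is.null(obj$tooth)) as.character(obj$tooth) else NULL)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(points, path, tooth_id = NULL) {
  obj <- list(points = apply(as.matrix(points), 1L, as.numeric, simplify = FALSE))
  if (!is.null(tooth_id)) obj <- c(list(tooth = tooth_id), obj)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
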