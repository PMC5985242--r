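#' Cemento-enamel junction (CEJ) plane
#'
#' A plane separating the crown from the root of one tooth. The clinical
#' cut is made "roughly" at the CEJ; this package uses an explicit plane so
#' the separation is deterministic and testable.
#'
#' @param point a 3D point on the plane (mm).
#' @param normal plane normal, oriented toward the crown; normalized
#'   internally.
#' @param tooth_id optional FDI code.
#' @return object of class `cej_plane`.
#' @export
cej_plane <- function(point, normal, tooth_id = NULL) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("point and normal must be 3-vectors")
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("zero-length plane normal")
  structure(list(point = point, normal = normal / len, tooth_id = tooth_id),
            class = "cej_plane")
}

#' Fit a CEJ plane to marked points
#'
#' Least-squares plane through three or more (non-collinear) points marked
#' around the cemento-enamel junction, with the normal oriented toward a
#' crown-side hint point.
#'
#' @param points k x 3 matrix (k >= 3) of CEJ points (mm).
#' @param crownward_hint a 3D point on the crown side (e.g. a cusp tip).
#' @param tooth_id optional FDI code carried into the result.
#' @return a [cej_plane()].
#' @export
fit_cej_plane <- function(points, crownward_hint, tooth_id = NULL) {
  points <- as.matrix(points)
  check_not_collinear(points, "CEJ")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2L, ctr))
  normal <- sv$v[, 3L]
  if (sum(normal * (as.numeric(crownward_hint) - ctr)) < 0) normal <- -normal
  cej_plane(ctr, normal, tooth_id)
}

#' Transform a CEJ plane rigidly
#' @param plane a [cej_plane()].
#' @param t a [rigid_transform()].
#' @return the transformed `cej_plane`.
#' @export
transform_plane <- function(plane, t) {
  stopifnot(inherits(plane, "cej_plane"), inherits(t, "rigid_transform"))
  cej_plane(as.numeric(t$rotation %*% plane$point) + t$translation,
            as.numeric(t$rotation %*% plane$normal), plane$tooth_id)
}

#' Cut a tooth mesh at its CEJ plane
#'
#' Splits the surface into a crown part (the side the plane normal points
#' to) and a root part. Triangles crossing the plane are split along it, so
#' both parts terminate exactly at the plane; the cut rim is left open (no
#' capping) and the total surface area is conserved. Intersection points
#' are computed once per mesh edge, so the crown and root rims share
#' identical coordinates.
#'
#' @param tooth a [triangle_mesh()].
#' @param plane a [cej_plane()].
#' @param eps classification tolerance in mm (default 1e-9): vertices
#'   within `eps` of the plane count as lying on it.
#' @return list with `crown` and `root` ([triangle_mesh()] or `NULL` when
#'   empty), and flags `crown_empty` / `root_empty`.
#' @export
cut_at_cej <- function(tooth, plane, eps = 1e-9) {
  stopifnot(inherits(tooth, "triangle_mesh"), inherits(plane, "cej_plane"))
  v <- tooth$vertices
  f <- tooth$faces
  s <- as.numeric(sweep(v, 2L, plane$point) %*% plane$normal)
  cls <- ifelse(s > eps, 1L, ifelse(s < -eps, -1L, 0L))
  fc <- matrix(cls[f], ncol = 3L)
  npos <- rowSums(fc > 0L)
  nneg <- rowSums(fc < 0L)
  crown_keep <- nneg == 0L            # includes faces lying in the plane
  root_keep <- npos == 0L & !crown_keep
  crossing <- which(npos > 0L & nneg > 0L)

  new_v <- list()
  edge_cache <- new.env(parent = emptyenv())
  n0 <- nrow(v)
  # canonical intersection point of the plane with edge (i, j)
  edge_point <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, "_", b)
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    tt <- s[a] / (s[a] - s[b])
    p <- v[a, ] + tt * (v[b, ] - v[a, ])
    idx <- n0 + length(new_v) + 1L
    new_v[[length(new_v) + 1L]] <<- p
    edge_cache[[key]] <- idx
    idx
  }

  crown_extra <- list()
  root_extra <- list()
  for (fi in crossing) {
    tri <- f[fi, ]
    sg <- cls[tri]
    if (any(sg == 0L)) {
      # one vertex on the plane, the others on opposite sides
      r <- which(sg == 0L)
      ord <- ((r - 1L + 0:2) %% 3L) + 1L   # rotate: zero vertex first
      z <- tri[ord[1L]]; a <- tri[ord[2L]]; b <- tri[ord[3L]]
      m <- edge_point(a, b)
      if (cls[a] > 0L) {
        crown_extra[[length(crown_extra) + 1L]] <- c(z, a, m)
        root_extra[[length(root_extra) + 1L]] <- c(z, m, b)
      } else {
        root_extra[[length(root_extra) + 1L]] <- c(z, a, m)
        crown_extra[[length(crown_extra) + 1L]] <- c(z, m, b)
      }
    } else {
      # lone vertex on one side, two on the other
      lone_sign <- if (npos[fi] == 1L) 1L else -1L
      r <- which(sg == lone_sign)
      ord <- ((r - 1L + 0:2) %% 3L) + 1L
      a <- tri[ord[1L]]; b <- tri[ord[2L]]; cc <- tri[ord[3L]]
      m1 <- edge_point(a, b)
      m2 <- edge_point(cc, a)
      lone <- list(c(a, m1, m2))
      pair <- list(c(m1, b, cc), c(m1, cc, m2))
      if (lone_sign > 0L) {
        crown_extra <- c(crown_extra, lone)
        root_extra <- c(root_extra, pair)
      } else {
        root_extra <- c(root_extra, lone)
        crown_extra <- c(crown_extra, pair)
      }
    }
  }
  all_v <- if (length(new_v)) rbind(v, do.call(rbind, new_v)) else v
  build_side <- function(keep, extra) {
    faces <- rbind(f[keep, , drop = FALSE],
                   if (length(extra)) do.call(rbind, extra))
    if (is.null(faces) || nrow(faces) == 0L) return(NULL)
    compact_mesh(triangle_mesh(all_v, faces))
  }
  crown <- build_side(crown_keep, crown_extra)
  root <- build_side(root_keep, root_extra)
  list(crown = crown, root = root,
       crown_empty = is.null(crown), root_empty = is.null(root))
}

#' Read / write per-tooth CEJ plane files
#'
#' JSON layout: `{"tooth": "11", "point": [x,y,z], "normal": [x,y,z]}`.
#' @param plane a [cej_plane()].
#' @param path JSON file path.
#' @return `read_cej_plane`: a `cej_plane`; `write_cej_plane`: `path`
#'   invisibly.
#' @export
write_cej_plane <- function(plane, path) {
  stopifnot(inherits(plane, "cej_plane"))
  obj <- list(point = plane$point, normal = plane$normal)
  if (!is.null(plane$tooth_id)) obj <- c(list(tooth = plane$tooth_id), obj)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cej_plane
#' @export
read_cej_plane <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cej_plane(obj$point, obj$normal,
            tooth_id = if (!is.null(obj$tooth)) as.character(obj$tooth) else NULL)
}

#' Generate the expected root position (ERP) setup
#'
#' The core of the method: each pre-treatment CBCT tooth (crown + root) is
#' rigidly registered, by its crown alone, onto the corresponding
#' crown-only scan from a later appointment, and the recovered transform is
#' applied to the full tooth. The moved roots are the expected root
#' positions — obtained without any new radiograph.
#'
#' Per tooth the alignment runs in three stages, mirroring standard
#' superimposition practice: (1) three-point landmark registration
#' initializes the pose; (2) an optional user-supplied pre-transform stands
#' in for manual translation/rotation corrections; (3) iterative closest
#' point refines the fit of the crown region against the target crown.
#'
#' @param pretx [dentition()] of full pre-treatment teeth (crown + root).
#' @param target_crowns [dentition()] of crown-only scans at the progress
#'   stage.
#' @param landmarks named list (by FDI code): each element a list with
#'   `source` and `target` k x 3 landmark matrices (k >= 3), source points
#'   on the pre-treatment crown, target points on the scanned crown.
#' @param manual_pre optional named list of [rigid_transform()] applied
#'   after landmark registration.
#' @param cej_planes optional named list of [cej_plane()] in pre-treatment
#'   coordinates; when present, only the crown side of each tooth drives
#'   the ICP (the root never influences the fit; without planes all
#'   vertices are used, which on a crown-only target is handled by
#'   correspondence rejection).
#' @param icp_params list of arguments forwarded to [icp_register()].
#' @return object of class `erp_setup`: `per_tooth_transforms` (named list
#'   of `rigid_transform`), `erp_teeth` ([dentition()] of full teeth moved
#'   into the target frame), `diagnostics` (named list of `icp_result`),
#'   `errors` (named character vector for teeth that failed and were
#'   excluded).
#' @export
generate_erp_setup <- function(pretx, target_crowns, landmarks,
                               manual_pre = NULL, cej_planes = NULL,
                               icp_params = list()) {
  stopifnot(inherits(pretx, "dentition"), inherits(target_crowns, "dentition"))
  shared <- intersect(tooth_ids(pretx), tooth_ids(target_crowns))
  missing <- setdiff(union(tooth_ids(pretx), tooth_ids(target_crowns)), shared)
  if (length(missing))
    warning("teeth present in only one dentition were skipped: ",
            paste(missing, collapse = ", "))
  transforms <- list()
  erp_teeth <- list()
  diagnostics <- list()
  errors <- character(0)
  for (id in shared) {
    res <- tryCatch({
      lm <- landmarks[[id]]
      if (is.null(lm) || is.null(lm$source) || is.null(lm$target))
        stop("missing landmarks for tooth ", id)
      t0 <- landmark_register(lm$source, lm$target)
      if (!is.null(manual_pre[[id]]))
        t0 <- compose_transform(manual_pre[[id]], t0)
      full <- pretx$teeth[[id]]
      moving <- full
      if (!is.null(cej_planes[[id]])) {
        cut <- cut_at_cej(full, cej_planes[[id]])
        if (!cut$crown_empty) moving <- cut$crown
      }
      icp <- do.call(icp_register,
                     c(list(source = moving, target = target_crowns$teeth[[id]],
                            init = t0), icp_params))
      list(transform = icp$transform,
           tooth = apply_transform(full, icp$transform),
           diag = icp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[id] <- conditionMessage(res)
      warning("tooth ", id, " excluded from the ERP setup: ",
              conditionMessage(res))
    } else {
      transforms[[id]] <- res$transform
      erp_teeth[[id]] <- res$tooth
      diagnostics[[id]] <- res$diag
    }
  }
  if (length(erp_teeth) == 0L) stop("no tooth could be registered")
  structure(list(per_tooth_transforms = transforms,
                 erp_teeth = dentition(erp_teeth,
                                       arch = pretx$arch[names(erp_teeth)]),
                 diagnostics = diagnostics, errors = errors),
            class = "erp_setup")
}

#' @export
print.erp_setup <- function(x, ...) {
  rms <- vapply(x$diagnostics, `[[`, numeric(1L), "rms")
  cat(sprintf("erp_setup: %d teeth registered (rms %.4f-%.4f mm)%s\n",
              length(x$erp_teeth$teeth), min(rms), max(rms),
              if (length(x$errors)) paste0(", ", length(x$errors), " failed")
              else ""))
  invisible(x)
}

#' Superimpose a control dentition onto the scan frame, one rigid body per
#' arch
#'
#' Used by the validation workflow: the progress-stage CBCT teeth (the
#' control, with true root positions) are brought into the laser-scan
#' frame by fitting the combined crowns of each arch as a single rigid
#' body — unlike ERP generation, which fits every tooth separately. The
#' maxilla and mandible are always treated as independent rigid bodies.
#'
#' @param control [dentition()] of full control teeth.
#' @param target_crowns [dentition()] of the laser-scanned crowns.
#' @param arch_landmarks named list (`maxillary`, `mandibular`), each with
#'   `source` / `target` landmark matrices on the combined crowns.
#' @param cej_planes optional named list of [cej_plane()] (control frame)
#'   used to restrict the control to its crowns before fitting.
#' @param icp_params list of arguments forwarded to [icp_register()].
#' @return list with `transforms` (per-arch [rigid_transform()]),
#'   `dentition` (control moved into the scan frame), `diagnostics`
#'   (per-arch `icp_result`).
#' @export
superimpose_control <- function(control, target_crowns, arch_landmarks,
                                cej_planes = NULL, icp_params = list()) {
  stopifnot(inherits(control, "dentition"), inherits(target_crowns, "dentition"))
  arches <- unique(control$arch)
  transforms <- list()
  diagnostics <- list()
  out_teeth <- control$teeth
  for (arch in arches) {
    ids <- tooth_ids(control, arch)
    tids <- tooth_ids(target_crowns, arch)
    if (length(ids) == 0L || length(tids) == 0L)
      stop("empty ", arch, " arch in control or target")
    crowns <- lapply(ids, function(id) {
      m <- control$teeth[[id]]
      if (!is.null(cej_planes[[id]])) {
        cut <- cut_at_cej(m, cej_planes[[id]])
        if (!cut$crown_empty) m <- cut$crown
      }
      m
    })
    combined <- merge_meshes(crowns)
    target <- merge_meshes(target_crowns$teeth[tids])
    lm <- arch_landmarks[[arch]]
    if (is.null(lm)) stop("missing arch landmarks for ", arch, " arch")
    t0 <- landmark_register(lm$source, lm$target)
    icp <- do.call(icp_register,
                   c(list(source = combined, target = target, init = t0),
                     icp_params))
    transforms[[arch]] <- icp$transform
    diagnostics[[arch]] <- icp
    for (id in ids)
      out_teeth[[id]] <- apply_transform(control$teeth[[id]], icp$transform)
  }
  list(transforms = transforms,
       dentition = dentition(out_teeth, arch = control$arch),
       diagnostics = diagnostics)
}

#' Pair ERP and control teeth after indirect superimposition
#'
#' Both dentitions have been registered to the same laser-scan frame (the
#' common intermediary); the scan itself is now dropped and the teeth are
#' compared directly, tooth by tooth. Teeth present in only one dentition
#' are excluded with a warning.
#'
#' @param erp an `erp_setup` (from [generate_erp_setup()]) or a
#'   [dentition()] already in the scan frame.
#' @param control_aligned [dentition()] of control teeth in the scan frame
#'   (from [superimpose_control()]).
#' @return object of class `tooth_pairs`: named list (FDI code) of lists
#'   with elements `erp` and `control` ([triangle_mesh()]), plus an `arch`
#'   attribute.
#' @export
indirect_superimpose <- function(erp, control_aligned) {
  erp_dent <- if (inherits(erp, "erp_setup")) erp$erp_teeth else erp
  stopifnot(inherits(erp_dent, "dentition"), inherits(control_aligned, "dentition"))
  shared <- intersect(tooth_ids(erp_dent), tooth_ids(control_aligned))
  missing <- setdiff(union(tooth_ids(erp_dent), tooth_ids(control_aligned)), shared)
  if (length(missing))
    warning("teeth without a counterpart were excluded: ",
            paste(missing, collapse = ", "))
  if (length(shared) == 0L) stop("no shared teeth to superimpose")
  pairs <- lapply(shared, function(id)
    list(erp = erp_dent$teeth[[id]], control = control_aligned$teeth[[id]]))
  names(pairs) <- shared
  structure(pairs, arch = erp_dent$arch[shared], class = "tooth_pairs")
}
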