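#' Parametric tooth specification
#'
#' Describes an idealized single-rooted tooth: a superellipsoid-like crown
#' joined to a tapered root along a known CEJ plane. The geometry is
#' deliberately parametric rather than anatomical — validation needs exact
#' ground-truth CEJ planes and movements, not realism.
#'
#' In the tooth-local frame the CEJ plane passes through `position` with
#' normal `long_axis` (crown-ward); the crown spans `(0, crown_height]`
#' along the axis and the root `[-root_length, 0)`.
#'
#' @param tooth_id FDI two-digit code.
#' @param crown_height crown height along the long axis, mm.
#' @param crown_widths length-2: (mesiodistal, buccolingual) crown width,
#'   mm.
#' @param root_length root length along the long axis, mm.
#' @param root_taper dimensionless mid-root thickness factor in (0, 1].
#' @param position CEJ center in world coordinates, mm.
#' @param long_axis unit vector from root toward crown.
#' @param axial_rotation_deg rotation of the mesiodistal axis about the
#'   long axis, degrees (used to align teeth with the arch tangent).
#' @param mesh_resolution integer subdivision level (>= 2); the mesh has
#'   `8 * mesh_resolution` segments around the axis.
#' @return object of class `tooth_spec`.
#' @export
tooth_spec <- function(tooth_id = "11", crown_height = 10.5,
                       crown_widths = c(8.5, 7.0), root_length = 13,
                       root_taper = 0.55, position = c(0, 0, 0),
                       long_axis = c(0, 0, 1), axial_rotation_deg = 0,
                       mesh_resolution = 4L) {
  if (crown_height <= 0 || root_length <= 0 || any(crown_widths <= 0))
    stop("all tooth dimensions must be positive")
  if (root_taper <= 0 || root_taper > 1) stop("root_taper must be in (0, 1]")
  if (mesh_resolution < 2L) stop("mesh_resolution must be >= 2")
  long_axis <- as.numeric(long_axis)
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  structure(list(tooth_id = as.character(tooth_id),
                 crown_height = crown_height,
                 crown_widths = as.numeric(crown_widths),
                 root_length = root_length, root_taper = root_taper,
                 position = as.numeric(position), long_axis = long_axis,
                 axial_rotation_deg = axial_rotation_deg,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "tooth_spec")
}

# superellipse boundary point at angle theta for semi-axes a, b, exponent n
superellipse_xy <- function(theta, a, b, n) {
  r <- (abs(cos(theta) / a)^n + abs(sin(theta) / b)^n)^(-1 / n)
  cbind(r * cos(theta), r * sin(theta))
}

#' Generate a watertight tooth mesh from its specification
#'
#' The surface is a single closed lattice: an apex point, stacked
#' cross-section rings (elliptical in the root, blending to a boxier
#' superellipse in the crown, with a cervical constriction at the CEJ) and
#' a crown-top point. Deterministic: the same spec always yields the
#' identical mesh.
#'
#' @param spec a [tooth_spec()].
#' @return list with `mesh` (watertight [triangle_mesh()], outward
#'   normals, positive enclosed volume), `cej` (the ground-truth
#'   [cej_plane()]) and `spec`.
#' @export
make_tooth <- function(spec) {
  stopifnot(inherits(spec, "tooth_spec"))
  res <- spec$mesh_resolution
  nseg <- 8L * res
  nroot <- 3L * res
  ncrown <- 3L * res
  H <- spec$crown_height
  L <- spec$root_length
  a_cej <- spec$crown_widths[1L] / 2 * 0.94   # cervical constriction
  b_cej <- spec$crown_widths[2L] / 2 * 0.94
  theta <- 2 * pi * (seq_len(nseg) - 1L) / nseg

  rings <- list()
  # root: apex (z = -L) upward to the CEJ (z = 0); elliptical sections
  for (i in seq_len(nroot)) {
    u <- i / nroot
    scale <- (spec$root_taper + (1 - spec$root_taper) * u) * u^0.25
    rings[[length(rings) + 1L]] <-
      list(z = -L * (1 - u), a = a_cej * scale, b = b_cej * scale, n = 2)
  }
  # crown: CEJ upward; bulges to full width near the middle third and the
  # cross-section becomes boxier (higher superellipse exponent)
  for (i in seq_len(ncrown - 1L)) {
    zf <- i / ncrown
    bulge <- 1 + (1 / 0.94 - 1) * sin(pi * zf)
    rings[[length(rings) + 1L]] <-
      list(z = H * zf, a = a_cej * bulge, b = b_cej * bulge, n = 2 + 1.5 * zf)
  }
  nr <- length(rings)
  verts <- matrix(0, 2L + nr * nseg, 3L)
  verts[1L, ] <- c(0, 0, -L)                     # apex
  for (i in seq_len(nr)) {
    xy <- superellipse_xy(theta, rings[[i]]$a, rings[[i]]$b, rings[[i]]$n)
    verts[1L + (i - 1L) * nseg + seq_len(nseg), ] <-
      cbind(xy, rings[[i]]$z)
  }
  top <- nrow(verts)
  verts[top, ] <- c(0, 0, H)                     # crown tip

  ring_idx <- function(i) 1L + (i - 1L) * nseg + seq_len(nseg)
  faces <- vector("list", nr + 1L)
  r1 <- ring_idx(1L)
  nxt <- c(seq_len(nseg)[-1L], 1L)
  faces[[1L]] <- cbind(1L, r1[nxt], r1)          # apex fan, outward-down
  for (i in seq_len(nr - 1L)) {
    lo <- ring_idx(i); hi <- ring_idx(i + 1L)
    faces[[i + 1L]] <- rbind(cbind(lo, lo[nxt], hi[nxt]),
                             cbind(lo, hi[nxt], hi))
  }
  rl <- ring_idx(nr)
  faces[[nr + 1L]] <- cbind(top, rl, rl[nxt])    # top fan, outward-up
  mesh <- triangle_mesh(verts, do.call(rbind, faces))

  # orient and place: local +z -> long_axis (with axial spin), CEJ center
  # at `position`
  Rspin <- rotation_about_axis(c(0, 0, 1), spec$axial_rotation_deg)$rotation
  Rtilt <- rotation_between(c(0, 0, 1), spec$long_axis)
  t <- rigid_transform(orthonormalize(Rtilt %*% Rspin), spec$position)
  list(mesh = apply_transform(mesh, t),
       cej = cej_plane(spec$position, spec$long_axis, spec$tooth_id),
       spec = spec)
}

# minimal rotation mapping unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {     # opposite: rotate pi about any orthogonal axis
    ax <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * u) * u
    return(rotation_about_axis(ax, 180)$rotation)
  }
  w <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  K <- matrix(c(0, w[3L], -w[2L], -w[3L], 0, w[1L], w[2L], -w[1L], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# mean crown dimensions (mm) by tooth position 1..7 within a quadrant
tooth_dimensions <- function(arch) {
  if (arch == "maxillary")
    data.frame(md = c(8.5, 6.6, 7.6, 7.1, 6.8, 10.1, 9.6),
               bl = c(7.0, 6.1, 8.1, 9.2, 9.2, 11.0, 11.3),
               crown_h = c(10.5, 9.0, 10.0, 8.5, 8.0, 7.7, 7.2),
               root_l = c(13.0, 13.0, 17.0, 14.0, 14.0, 13.0, 13.0))
  else
    data.frame(md = c(5.4, 5.9, 6.9, 7.0, 7.1, 11.0, 10.5),
               bl = c(5.9, 6.1, 7.5, 7.8, 8.1, 10.3, 10.3),
               crown_h = c(9.0, 9.5, 11.0, 8.5, 8.0, 7.7, 7.0),
               root_l = c(12.5, 14.0, 16.0, 14.0, 14.5, 14.0, 13.0))
}

#' Generate a synthetic dental arch
#'
#' Places parametric teeth along a parabolic arch form with
#' population-mean crown dimensions, mesiodistal axes tangent to the arch
#' and a fixed inter-tooth gap. FDI codes are assigned by position
#' (quadrants 1/2 for maxillary, 4/3 for mandibular, central incisors
#' outward). Generation fails if any two teeth come closer than 0.1 mm.
#'
#' @param n_teeth number of teeth, 1..16 (up to 8 per quadrant; positions
#'   beyond 7 reuse second-molar dimensions).
#' @param arch `"maxillary"` or `"mandibular"`.
#' @param arch_halfwidth,arch_depth parabola shape parameters, mm.
#' @param gap inter-tooth gap along the arch, mm (default 0.8).
#' @param mesh_resolution forwarded to [tooth_spec()].
#' @return list with `dentition` ([dentition()]), `cej_planes` (named list
#'   of ground-truth [cej_plane()]) and `specs` (named list of
#'   [tooth_spec()]).
#' @export
make_arch <- function(n_teeth = 14L, arch = c("maxillary", "mandibular"),
                      arch_halfwidth = 30, arch_depth = 42, gap = 0.8,
                      mesh_resolution = 4L) {
  arch <- match.arg(arch)
  if (n_teeth < 1L || n_teeth > 16L) stop("n_teeth must be in 1..16")
  dims <- tooth_dimensions(arch)
  quads <- if (arch == "maxillary") c(1L, 2L) else c(4L, 3L)
  n_side <- c(ceiling(n_teeth / 2), floor(n_teeth / 2))

  # arc-length parametrization of the arch curve x -> (x, -d * (x/w)^2)
  xs <- seq(0, arch_halfwidth * 1.4, length.out = 2000L)
  ys <- -arch_depth * (xs / arch_halfwidth)^2
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  arclen <- c(0, cumsum(seg))
  x_at <- function(s) stats::approx(arclen, xs, xout = s, rule = 2L)$y

  specs <- list()
  for (side in 1:2) {
    sgn <- if (side == 1L) 1 else -1
    s <- gap / 2
    for (k in seq_len(n_side[side])) {
      row <- dims[min(k, 7L), ]
      s_mid <- s + row$md / 2
      s <- s + row$md + gap
      x <- x_at(s_mid)
      y <- -arch_depth * (x / arch_halfwidth)^2
      tangent <- atan2(-2 * arch_depth * x / arch_halfwidth^2, 1)
      id <- sprintf("%d%d", quads[side], k)
      specs[[id]] <- tooth_spec(
        tooth_id = id, crown_height = row$crown_h,
        crown_widths = c(row$md, row$bl), root_length = row$root_l,
        position = c(sgn * x, y, 0), long_axis = c(0, 0, 1),
        axial_rotation_deg = sgn * tangent * 180 / pi,
        mesh_resolution = mesh_resolution)
    }
  }
  built <- lapply(specs, make_tooth)
  teeth <- lapply(built, `[[`, "mesh")
  cejs <- lapply(built, `[[`, "cej")
  check_no_overlap(teeth, min_gap = 0.1)
  list(dentition = dentition(teeth), cej_planes = cejs, specs = specs)
}

# error if any two meshes have surface distance below min_gap; bounding-box
# prefilter, exact nearest-point check on candidate pairs
check_no_overlap <- function(teeth, min_gap = 0.1) {
  ids <- names(teeth)
  if (length(ids) < 2L) return(invisible(TRUE))
  bbs <- lapply(teeth, mesh_bbox)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      if (any(bbs[[i]][1L, ] > bbs[[j]][2L, ] + min_gap) ||
          any(bbs[[j]][1L, ] > bbs[[i]][2L, ] + min_gap)) next
      d <- min(nearest_on_mesh(teeth[[i]]$vertices, teeth[[j]])$distance)
      if (d <= min_gap)
        stop("generated teeth ", ids[i], " and ", ids[j],
             " are closer than ", min_gap, " mm (", signif(d, 3), " mm)")
    }
  }
  invisible(TRUE)
}

#' Tooth movement specification
#'
#' Clinically parameterized rigid movement about the crown centroid: tip
#' (mesiodistal angulation, rotation about the buccolingual axis), torque
#' (buccolingual inclination, rotation about the mesiodistal axis),
#' rotation (about the long axis) and a translation.
#'
#' @param tip_deg,torque_deg,rotation_deg angles in degrees.
#' @param translation_mm length-3 translation, mm.
#' @return object of class `tooth_movement`.
#' @export
tooth_movement <- function(tip_deg = 0, torque_deg = 0, rotation_deg = 0,
                           translation_mm = c(0, 0, 0)) {
  structure(list(tip_deg = tip_deg, torque_deg = torque_deg,
                 rotation_deg = rotation_deg,
                 translation_mm = as.numeric(translation_mm)),
            class = "tooth_movement")
}

#' Simulate orthodontic tooth movement
#'
#' Applies a known rigid movement to every tooth (identity where no
#' movement is given) and co-transforms its CEJ plane. The exact transforms
#' are returned so downstream registration can be scored against ground
#' truth. Movements that bring teeth into collision are allowed (clinical
#' crowding exists) but flagged with a warning.
#'
#' @param arch result of [make_arch()] (or a list with `dentition`,
#'   `cej_planes`, `specs`).
#' @param movements named list (FDI code) of [tooth_movement()] or
#'   [rigid_transform()] entries; teeth not listed stay put. Unknown IDs
#'   are an error.
#' @return list with `dentition` (moved), `cej_planes` (moved),
#'   `transforms` (named list of ground-truth [rigid_transform()], one per
#'   tooth) and `collided` (logical flag).
#' @export
simulate_treatment <- function(arch, movements = list()) {
  dent <- arch$dentition
  unknown <- setdiff(names(movements), tooth_ids(dent))
  if (length(unknown))
    stop("movements for unknown teeth: ", paste(unknown, collapse = ", "))
  teeth <- list()
  cejs <- list()
  transforms <- list()
  for (id in tooth_ids(dent)) {
    mv <- movements[[id]]
    t <- if (is.null(mv)) {
      transform_identity()
    } else if (inherits(mv, "rigid_transform")) {
      mv
    } else if (inherits(mv, "tooth_movement")) {
      movement_to_transform(mv, dent$teeth[[id]], arch$cej_planes[[id]],
                            arch$specs[[id]])
    } else stop("movement for tooth ", id,
                " must be a tooth_movement or rigid_transform")
    transforms[[id]] <- t
    teeth[[id]] <- apply_transform(dent$teeth[[id]], t)
    cejs[[id]] <- transform_plane(arch$cej_planes[[id]], t)
  }
  moved <- dentition(teeth, arch = dent$arch)
  collided <- tryCatch({
    check_no_overlap(teeth, min_gap = 0)
    FALSE
  }, error = function(e) TRUE)
  if (collided) warning("simulated movements brought teeth into contact")
  list(dentition = moved, cej_planes = cejs, transforms = transforms,
       collided = collided)
}

# build the rigid transform of a clinically parameterized movement:
# rotations about tooth-local axes through the crown centroid, then the
# translation
movement_to_transform <- function(mv, tooth, cej, spec = NULL) {
  long <- cej$normal
  if (!is.null(spec)) {
    R0 <- rotation_between(c(0, 0, 1), spec$long_axis) %*%
      rotation_about_axis(c(0, 0, 1), spec$axial_rotation_deg)$rotation
    md <- as.numeric(R0 %*% c(1, 0, 0))
  } else {
    md <- c(1, 0, 0) - sum(c(1, 0, 0) * long) * long
    if (sqrt(sum(md^2)) < 1e-6) md <- c(0, 1, 0) - sum(c(0, 1, 0) * long) * long
    md <- md / sqrt(sum(md^2))
  }
  bl <- c(long[2L] * md[3L] - long[3L] * md[2L],
          long[3L] * md[1L] - long[1L] * md[3L],
          long[1L] * md[2L] - long[2L] * md[1L])
  s <- as.numeric(sweep(tooth$vertices, 2L, cej$point) %*% long)
  centroid <- colMeans(tooth$vertices[s > 0, , drop = FALSE])
  t <- compose_transform(
    rotation_about_axis(long, mv$rotation_deg, centroid),
    compose_transform(rotation_about_axis(md, mv$torque_deg, centroid),
                      rotation_about_axis(bl, mv$tip_deg, centroid)))
  compose_transform(rigid_transform(diag(3), mv$translation_mm), t)
}

#' Simulate a surface scan of a dentition
#'
#' Emulates the two acquisition paths of the clinical workflow: crown-only
#' laser scans of a cast (`crop = "crown_only"`) and CBCT threshold
#' segmentations (`crop = "full_tooth"`). Measurement error is modeled as
#' Gaussian noise along the vertex normals (scanner error is predominantly
#' radial to the surface) and incomplete coverage as random removal of a
#' fraction of faces. Deterministic for a given seed.
#'
#' @param dent a [dentition()].
#' @param cej_planes named list of [cej_plane()] (required for
#'   `crop = "crown_only"`).
#' @param crop `"crown_only"` or `"full_tooth"`.
#' @param vertex_noise_sd Gaussian noise standard deviation, mm (>= 0).
#' @param decimation_fraction fraction of faces removed, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a [dentition()] of degraded meshes.
#' @export
simulate_scan <- function(dent, cej_planes = NULL,
                          crop = c("crown_only", "full_tooth"),
                          vertex_noise_sd = 0, decimation_fraction = 0,
                          seed = 0L) {
  crop <- match.arg(crop)
  if (vertex_noise_sd < 0) stop("vertex_noise_sd must be >= 0")
  if (decimation_fraction < 0 || decimation_fraction >= 1)
    stop("decimation_fraction must be in [0, 1)")
  if (crop == "crown_only" && is.null(cej_planes))
    stop("crown_only cropping requires CEJ planes")
  ids <- tooth_ids(dent)
  out <- with_seed(seed, {
    teeth <- list()
    for (id in ids) {
      m <- dent$teeth[[id]]
      if (crop == "crown_only") {
        pl <- cej_planes[[id]]
        if (is.null(pl)) stop("missing CEJ plane for tooth ", id)
        cut <- cut_at_cej(m, pl)
        if (cut$crown_empty) stop("CEJ plane misses tooth ", id)
        m <- cut$crown
      }
      if (vertex_noise_sd > 0) {
        nrm <- vertex_normals(m)
        m$vertices <- m$vertices +
          nrm * stats::rnorm(nrow(m$vertices), 0, vertex_noise_sd)
      }
      if (decimation_fraction > 0) {
        keep_n <- round((1 - decimation_fraction) * n_faces(m))
        if (keep_n < 10L)
          stop("decimation would leave fewer than 10 faces on tooth ", id)
        keep <- sort(sample.int(n_faces(m), keep_n))
        m <- compact_mesh(triangle_mesh(m$vertices,
                                        m$faces[keep, , drop = FALSE]))
      }
      teeth[[id]] <- m
    }
    teeth
  })
  dentition(out, arch = dent$arch[ids])
}

#' Pick well-separated surface landmarks
#'
#' Deterministic farthest-point sampling of `k` mesh vertices, emulating
#' the manual selection of matching points on two crowns. For `k >= 3` on
#' any non-degenerate crown the picks are non-collinear and thus valid
#' input for [landmark_register()].
#'
#' @param mesh a [triangle_mesh()].
#' @param k number of points (default 3).
#' @param seed integer; selects the starting vertex.
#' @return k x 3 matrix of vertex coordinates.
#' @export
pick_landmarks <- function(mesh, k = 3L, seed = 0L) {
  n <- nrow(mesh$vertices)
  if (k > n) stop("cannot pick ", k, " landmarks from ", n, " vertices")
  v <- mesh$vertices
  picks <- integer(k)
  picks[1L] <- (as.integer(seed) %% n) + 1L
  d2 <- rowSums(sweep(v, 2L, v[picks[1L], ])^2)
  for (i in seq_len(k - 1L)) {
    picks[i + 1L] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(v, 2L, v[picks[i + 1L], ])^2))
  }
  v[picks, , drop = FALSE]
}

#' Corresponding landmark pair for a known transform
#'
#' Picks landmarks on `mesh` and maps them through the ground-truth
#' transform, optionally perturbing the target picks to emulate imprecise
#' manual clicking.
#'
#' @param mesh a [triangle_mesh()] (source frame).
#' @param transform ground-truth [rigid_transform()] from source to target
#'   frame.
#' @param k number of landmarks (default 3).
#' @param seed integer RNG / start-vertex seed.
#' @param perturb_sd isotropic Gaussian perturbation of the target picks,
#'   mm (default 0).
#' @return list with `source` and `target` k x 3 matrices.
#' @export
landmark_pair <- function(mesh, transform, k = 3L, seed = 0L,
                          perturb_sd = 0) {
  src <- pick_landmarks(mesh, k, seed)
  tgt <- transform_points(src, transform)
  if (perturb_sd > 0)
    tgt <- tgt + with_seed(seed + 1L,
                           matrix(stats::rnorm(length(tgt), 0, perturb_sd),
                                  ncol = 3L))
  list(source = src, target = tgt)
}
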