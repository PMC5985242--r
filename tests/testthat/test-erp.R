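test_that("CEJ plane fitting recovers exact and noisy planes", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  pl <- fit_cej_plane(pts, crownward_hint = c(0, 0, 5))
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)

  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pl <- fit_cej_plane(sq, crownward_hint = c(0, 0, -3))
  expect_equal(pl$normal, c(0, 0, -1), tolerance = 1e-12)

  set.seed(9)
  noisy <- cbind(matrix(stats::runif(40, -5, 5), 20L, 2L),
                 stats::rnorm(20, 0, 0.1))
  pl <- fit_cej_plane(noisy, crownward_hint = c(0, 0, 10))
  ang <- acos(min(1, sum(pl$normal * c(0, 0, 1))))
  expect_lt(ang * 180 / pi, 5)

  expect_error(fit_cej_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                             c(0, 0, 1)), "collinear")
})

test_that("cutting separates crown and root on the correct sides", {
  tooth <- default_tooth()
  cut <- cut_at_cej(tooth$mesh, tooth$cej)
  expect_false(cut$crown_empty)
  expect_false(cut$root_empty)
  s_crown <- sweep(cut$crown$vertices, 2L, tooth$cej$point) %*% tooth$cej$normal
  s_root <- sweep(cut$root$vertices, 2L, tooth$cej$point) %*% tooth$cej$normal
  expect_gte(min(s_crown), -1e-9)
  expect_lte(max(s_root), 1e-9)
})

test_that("a plane above the crown tip yields an empty crown with a flag", {
  tooth <- default_tooth()
  high <- cej_plane(tooth$cej$point + 100 * tooth$cej$normal, tooth$cej$normal)
  cut <- cut_at_cej(tooth$mesh, high)
  expect_true(cut$crown_empty)
  expect_null(cut$crown)
  expect_equal(mesh_area(cut$root), mesh_area(tooth$mesh), tolerance = 1e-12)
})

test_that("plane cutting conserves total surface area", {
  set.seed(21)
  for (i in 1:20) {
    sp <- tooth_spec(crown_height = stats::runif(1, 7, 11),
                     crown_widths = stats::runif(2, 5, 10),
                     root_length = stats::runif(1, 10, 17),
                     root_taper = stats::runif(1, 0.3, 0.8),
                     mesh_resolution = 2L)
    tooth <- make_tooth(sp)
    # oblique plane through the tooth, not aligned with any mesh ring
    pl <- cej_plane(point = c(stats::runif(2, -1, 1), stats::runif(1, -3, 3)),
                    normal = stats::rnorm(3) + c(0, 0, 2))
    cut <- cut_at_cej(tooth$mesh, pl)
    total <- (if (!cut$crown_empty) mesh_area(cut$crown) else 0) +
      (if (!cut$root_empty) mesh_area(cut$root) else 0)
    expect_equal(total, mesh_area(tooth$mesh), tolerance = 1e-6)
  }
})

test_that("the cut rim is a single shared boundary loop", {
  tooth <- default_tooth()
  pl <- cej_plane(c(0.2, -0.1, 1.3), c(0.1, 0.05, 1))
  cut <- cut_at_cej(tooth$mesh, pl)
  expect_length(boundary_loops(cut$crown), 1L)
  expect_length(boundary_loops(cut$root), 1L)
})

test_that("ERP generation is a fixed point when nothing moved", {
  arch <- make_arch(n_teeth = 4L, mesh_resolution = 3L)
  crowns <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only")
  landmarks <- lapply(stats::setNames(nm = tooth_ids(arch$dentition)),
                      function(id)
                        landmark_pair(arch$dentition$teeth[[id]],
                                      transform_identity()))
  erp <- generate_erp_setup(arch$dentition, crowns, landmarks,
                            cej_planes = arch$cej_planes)
  for (id in tooth_ids(erp$erp_teeth)) {
    t <- erp$per_tooth_transforms[[id]]
    expect_lt(rotation_angle(t$rotation), 1e-6)
    expect_lt(max(abs(t$translation)), 1e-6)
    expect_lt(max(abs(erp$erp_teeth$teeth[[id]]$vertices -
                      arch$dentition$teeth[[id]]$vertices)), 1e-5)
  }
})

test_that("ERP generation recovers known per-tooth movements", {
  arch <- make_arch(n_teeth = 4L, mesh_resolution = 3L)
  ids <- tooth_ids(arch$dentition)
  movements <- stats::setNames(lapply(seq_along(ids), function(i)
    tooth_movement(tip_deg = 2, translation_mm = c(0.5, 0, 0.2) * (-1)^i)),
    ids)
  moved <- simulate_treatment(arch, movements)
  crowns <- simulate_scan(moved$dentition, moved$cej_planes,
                          crop = "crown_only")
  landmarks <- lapply(stats::setNames(nm = ids), function(id)
    landmark_pair(arch$dentition$teeth[[id]], moved$transforms[[id]]))
  erp <- generate_erp_setup(arch$dentition, crowns, landmarks,
                            cej_planes = arch$cej_planes)
  for (id in ids) {
    expect_lt(max_vertex_error(arch$dentition$teeth[[id]],
                               erp$per_tooth_transforms[[id]],
                               moved$transforms[[id]]), 0.05)
  }
})

test_that("registration never uses root geometry when CEJ planes are given", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 3L)
  ids <- tooth_ids(arch$dentition)
  movements <- stats::setNames(
    lapply(ids, function(id) tooth_movement(tip_deg = 1.5,
                                            translation_mm = c(0.3, -0.2, 0.1))),
    ids)
  moved <- simulate_treatment(arch, movements)
  crowns <- simulate_scan(moved$dentition, moved$cej_planes, crop = "crown_only")
  landmarks <- lapply(stats::setNames(nm = ids), function(id)
    landmark_pair(arch$dentition$teeth[[id]], moved$transforms[[id]]))

  erp_full <- generate_erp_setup(arch$dentition, crowns, landmarks,
                                 cej_planes = arch$cej_planes)
  # replace roots with grossly wrong geometry: shrink the root by half
  mangled <- lapply(stats::setNames(nm = ids), function(id) {
    cut <- cut_at_cej(arch$dentition$teeth[[id]], arch$cej_planes[[id]])
    root <- cut$root
    ctr <- arch$cej_planes[[id]]$point
    root$vertices <- sweep(sweep(root$vertices, 2L, ctr) * 0.5, 2L, -ctr)
    merge_meshes(list(cut$crown, root))
  })
  erp_mangled <- generate_erp_setup(dentition(mangled), crowns, landmarks,
                                    cej_planes = arch$cej_planes)
  for (id in ids) {
    a <- erp_full$per_tooth_transforms[[id]]
    b <- erp_mangled$per_tooth_transforms[[id]]
    expect_lt(rotation_angle(crossprod(a$rotation, b$rotation)), 1e-4)
    expect_lt(max(abs(a$translation - b$translation)), 1e-3)
  }
})

test_that("teeth missing landmarks are excluded with a warning", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 2L)
  ids <- tooth_ids(arch$dentition)
  crowns <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only")
  landmarks <- list(landmark_pair(arch$dentition$teeth[[ids[1L]]],
                                  transform_identity()))
  names(landmarks) <- ids[1L]
  expect_warning(
    erp <- generate_erp_setup(arch$dentition, crowns, landmarks,
                              cej_planes = arch$cej_planes),
    "excluded")
  expect_identical(tooth_ids(erp$erp_teeth), ids[1L])
  expect_named(erp$errors, ids[2L])
})

test_that("control superimposition recovers per-arch rigid frames", {
  arch <- make_arch(n_teeth = 4L, mesh_resolution = 3L)
  ids <- tooth_ids(arch$dentition)
  crowns <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only")

  # control already in the scan frame: transform is the identity
  alm <- landmark_pair(merge_meshes(arch$dentition$teeth), transform_identity(),
                       k = 4L)
  ctl <- superimpose_control(arch$dentition, crowns,
                             list(maxillary = alm),
                             cej_planes = arch$cej_planes)
  expect_lt(rotation_angle(ctl$transforms$maxillary$rotation), 1e-5)
  expect_lt(max(abs(ctl$transforms$maxillary$translation)), 1e-4)

  # control displaced by a known rigid frame: recovered transform inverts it
  t_frame <- compose_transform(rotation_about_axis(c(0.2, 1, 0.5), 6),
                               rigid_transform(diag(3), c(4, -2, 3)))
  displaced <- dentition(lapply(arch$dentition$teeth, apply_transform,
                                t = t_frame), arch = arch$dentition$arch)
  cej_disp <- lapply(arch$cej_planes, transform_plane, t = t_frame)
  alm2 <- landmark_pair(
    merge_meshes(lapply(ids, function(id)
      cut_at_cej(displaced$teeth[[id]], cej_disp[[id]])$crown)),
    invert_transform(t_frame), k = 4L)
  ctl2 <- superimpose_control(displaced, crowns, list(maxillary = alm2),
                              cej_planes = cej_disp)
  for (id in ids) {
    d <- ctl2$dentition$teeth[[id]]$vertices -
      arch$dentition$teeth[[id]]$vertices
    expect_lt(max(sqrt(rowSums(d^2))), 0.05)
  }
})

test_that("arches recover independent frames", {
  upper <- make_arch(n_teeth = 2L, arch = "maxillary", mesh_resolution = 2L)
  lower <- make_arch(n_teeth = 2L, arch = "mandibular", mesh_resolution = 2L)
  lower_shift <- rigid_transform(diag(3), c(0, 0, -30))
  teeth <- c(upper$dentition$teeth,
             lapply(lower$dentition$teeth, apply_transform, t = lower_shift))
  cejs <- c(upper$cej_planes,
            lapply(lower$cej_planes, transform_plane, t = lower_shift))
  dent <- dentition(teeth)
  crowns <- simulate_scan(dent, cejs, crop = "crown_only")

  t_max <- rigid_transform(diag(3), c(2, 0, 1))
  t_man <- rotation_about_axis(c(0, 0, 1), 8, center = c(0, -20, -30))
  displaced <- dentition(c(
    lapply(upper$dentition$teeth, apply_transform, t = t_max),
    lapply(teeth[tooth_ids(dent, "mandibular")], apply_transform, t = t_man)))
  alm <- list(
    maxillary = landmark_pair(
      merge_meshes(displaced$teeth[tooth_ids(dent, "maxillary")]),
      invert_transform(t_max), k = 4L),
    mandibular = landmark_pair(
      merge_meshes(displaced$teeth[tooth_ids(dent, "mandibular")]),
      invert_transform(t_man), k = 4L))
  cej_disp <- c(lapply(upper$cej_planes, transform_plane, t = t_max),
                lapply(cejs[tooth_ids(dent, "mandibular")], transform_plane,
                       t = t_man))
  ctl <- superimpose_control(displaced, crowns, alm, cej_planes = cej_disp)
  for (id in tooth_ids(dent)) {
    d <- ctl$dentition$teeth[[id]]$vertices - dent$teeth[[id]]$vertices
    expect_lt(max(sqrt(rowSums(d^2))), 0.05)
  }
})

test_that("indirect superimposition pairs shared teeth and warns on gaps", {
  arch <- make_arch(n_teeth = 3L, mesh_resolution = 2L)
  dent <- arch$dentition
  pairs <- indirect_superimpose(dent, dent)
  expect_s3_class(pairs, "tooth_pairs")
  expect_setequal(names(pairs), tooth_ids(dent))
  for (id in names(pairs))
    expect_identical(pairs[[id]]$erp$vertices, pairs[[id]]$control$vertices)

  partial <- dentition(dent$teeth[-1L], arch = dent$arch[-1L])
  expect_warning(p2 <- indirect_superimpose(dent, partial),
                 tooth_ids(dent)[1L])
  expect_setequal(names(p2), tooth_ids(partial))
})

test_that("indirect comparison is invariant to a shared change of frame", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 3L)
  dent <- arch$dentition
  ids <- tooth_ids(dent)
  # make ERP and control slightly different so stats are non-trivial
  jitter <- rotation_about_axis(c(0, 1, 0), 0.5, center = c(0, 0, 0))
  erp_teeth <- lapply(dent$teeth, apply_transform, t = jitter)
  direct <- compare_pair_report(
    indirect_superimpose(dentition(erp_teeth), dent),
    cej_planes = arch$cej_planes)
  set.seed(33)
  t_frame <- random_rigid()
  moved_pairs <- indirect_superimpose(
    dentition(lapply(erp_teeth, apply_transform, t = t_frame)),
    dentition(lapply(dent$teeth, apply_transform, t = t_frame)))
  routed <- compare_pair_report(
    moved_pairs,
    cej_planes = lapply(arch$cej_planes, transform_plane, t = t_frame))
  expect_equal(direct$stats$mean_mm, routed$stats$mean_mm, tolerance = 1e-6)
  expect_equal(direct$stats$sd_mm, routed$stats$sd_mm, tolerance = 1e-6)
  expect_equal(direct$stats$max_mm, routed$stats$max_mm, tolerance = 1e-6)
})
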