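test_that("generated teeth are watertight with outward orientation", {
  tooth <- make_tooth(tooth_spec(mesh_resolution = 3L))
  expect_length(boundary_loops(tooth$mesh), 0L)
  expect_gt(mesh_volume(tooth$mesh), 0)
})

test_that("tooth extent along the long axis matches the specification", {
  sp <- tooth_spec(crown_height = 8, root_length = 12, mesh_resolution = 3L)
  tooth <- make_tooth(sp)
  bb <- mesh_bbox(tooth$mesh)
  expect_equal(unname(bb[2L, 3L] - bb[1L, 3L]), 20, tolerance = 20 * 0.02)
})

test_that("tooth generation is deterministic byte-for-byte", {
  sp <- tooth_spec(mesh_resolution = 2L)
  f1 <- withr::local_tempfile(fileext = ".ply")
  f2 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(make_tooth(sp)$mesh, f1)
  write_mesh(make_tooth(sp)$mesh, f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
})

test_that("invalid tooth specifications are rejected", {
  expect_error(tooth_spec(crown_height = -1), "positive")
  expect_error(tooth_spec(root_taper = 0), "root_taper")
  expect_error(tooth_spec(mesh_resolution = 1L), "resolution")
})

test_that("arches assign FDI codes by quadrant and keep teeth apart", {
  arch <- make_arch(n_teeth = 14L, mesh_resolution = 2L)
  ids <- tooth_ids(arch$dentition)
  expect_length(ids, 14L)
  expect_true(all(substr(ids, 1L, 1L) %in% c("1", "2")))
  expect_true(all(arch$dentition$arch == "maxillary"))

  lower <- make_arch(n_teeth = 5L, arch = "mandibular", mesh_resolution = 2L)
  expect_true(all(substr(tooth_ids(lower$dentition), 1L, 1L) %in% c("3", "4")))

  two <- make_arch(n_teeth = 2L, mesh_resolution = 2L)
  m <- two$dentition$teeth
  d <- min(nearest_on_mesh(m[[1L]]$vertices, m[[2L]])$distance)
  expect_gt(d, 0.1)
})

test_that("pairwise tooth gaps exceed 0.1 mm by exhaustive check", {
  skip_if_not_installed("pracma")
  arch <- make_arch(n_teeth = 4L, mesh_resolution = 2L)
  teeth <- arch$dentition$teeth
  for (i in 1:3) for (j in (i + 1):4) {
    # brute-force oracle on a subsample of vertices
    vs <- teeth[[i]]$vertices
    vs <- vs[seq(1L, nrow(vs), by = 7L), , drop = FALSE]
    d <- min(oracle_nearest_on_mesh(vs, teeth[[j]])[, 4L])
    expect_gt(d, 0.1)
  }
})

test_that("overlapping generation parameters raise an error naming the pair", {
  expect_error(make_arch(n_teeth = 4L, gap = -3, mesh_resolution = 2L),
               "closer than")
})

test_that("all-identity movements leave the dentition unchanged", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 2L)
  moved <- simulate_treatment(arch)
  for (id in tooth_ids(arch$dentition))
    expect_identical(moved$dentition$teeth[[id]]$vertices,
                     arch$dentition$teeth[[id]]$vertices)
})

test_that("a 2-degree tip rotates the long axis by 2 degrees", {
  arch <- make_arch(n_teeth = 1L, mesh_resolution = 2L)
  id <- tooth_ids(arch$dentition)[1L]
  mv <- stats::setNames(list(tooth_movement(tip_deg = 2)), id)
  moved <- simulate_treatment(arch, mv)
  t <- moved$transforms[[id]]
  expect_equal(rotation_angle(t$rotation) * 180 / pi, 2, tolerance = 1e-9)
  old_axis <- arch$cej_planes[[id]]$normal
  new_axis <- moved$cej_planes[[id]]$normal
  ang <- acos(min(1, sum(old_axis * new_axis))) * 180 / pi
  expect_equal(ang, 2, tolerance = 1e-6)
})

test_that("ground-truth transforms round-trip the movement", {
  arch <- make_arch(n_teeth = 3L, mesh_resolution = 2L)
  ids <- tooth_ids(arch$dentition)
  mv <- stats::setNames(lapply(seq_along(ids), function(i)
    tooth_movement(tip_deg = i, torque_deg = -i, rotation_deg = 2 * i,
                   translation_mm = c(0.2 * i, -0.1, 0.3))), ids)
  moved <- simulate_treatment(arch, mv)
  for (id in ids) {
    back <- apply_transform(moved$dentition$teeth[[id]],
                            invert_transform(moved$transforms[[id]]))
    expect_lt(max(abs(back$vertices - arch$dentition$teeth[[id]]$vertices)),
              1e-9)
  }
})

test_that("movements for unknown teeth are rejected", {
  arch <- make_arch(n_teeth = 1L, mesh_resolution = 2L)
  expect_error(simulate_treatment(arch, list("48" = tooth_movement(1))),
               "unknown")
})

test_that("clean crown-only scans equal the CEJ-cut crowns", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 2L)
  scan <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only")
  for (id in tooth_ids(arch$dentition)) {
    want <- cut_at_cej(arch$dentition$teeth[[id]], arch$cej_planes[[id]])$crown
    expect_identical(scan$teeth[[id]]$vertices, want$vertices)
    expect_identical(scan$teeth[[id]]$faces, want$faces)
  }
})

test_that("crown scans have exactly one open boundary loop", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 3L)
  scan <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only")
  for (id in tooth_ids(scan))
    expect_length(boundary_loops(scan$teeth[[id]]), 1L)
})

test_that("scans are deterministic for a fixed seed", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 2L)
  s1 <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only",
                      vertex_noise_sd = 0.05, decimation_fraction = 0.5,
                      seed = 7L)
  s2 <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only",
                      vertex_noise_sd = 0.05, decimation_fraction = 0.5,
                      seed = 7L)
  s3 <- simulate_scan(arch$dentition, arch$cej_planes, crop = "crown_only",
                      vertex_noise_sd = 0.05, decimation_fraction = 0.5,
                      seed = 8L)
  for (id in tooth_ids(s1)) {
    expect_identical(s1$teeth[[id]]$vertices, s2$teeth[[id]]$vertices)
    expect_identical(s1$teeth[[id]]$faces, s2$teeth[[id]]$faces)
    expect_false(identical(s1$teeth[[id]]$vertices, s3$teeth[[id]]$vertices))
  }
})

test_that("normal-directed noise matches the half-normal mean displacement", {
  arch <- make_arch(n_teeth = 2L, mesh_resolution = 5L)
  sd <- 0.05
  scan <- simulate_scan(arch$dentition, NULL, crop = "full_tooth",
                        vertex_noise_sd = sd, seed = 3L)
  disp <- unlist(lapply(tooth_ids(scan), function(id)
    sqrt(rowSums((scan$teeth[[id]]$vertices -
                  arch$dentition$teeth[[id]]$vertices)^2))))
  expect_gte(length(disp), 1000L)
  expect_equal(mean(disp), sd * sqrt(2 / pi), tolerance = 0.1)
})

test_that("excessive decimation raises a generation error", {
  arch <- make_arch(n_teeth = 1L, mesh_resolution = 2L)
  expect_error(simulate_scan(arch$dentition, arch$cej_planes,
                             crop = "crown_only",
                             decimation_fraction = 0.999),
               "fewer than 10")
})

test_that("picked landmarks are well separated and non-collinear", {
  tooth <- default_tooth()$mesh
  pts <- pick_landmarks(tooth, k = 3L, seed = 0L)
  expect_identical(dim(pts), c(3L, 3L))
  expect_silent(landmark_register(pts, pts))   # passes the collinearity check
  expect_error(pick_landmarks(tooth, k = n_vertices(tooth) + 1L), "cannot pick")
})

test_that("exact landmark pairs recover the ground-truth transform", {
  tooth <- default_tooth()$mesh
  set.seed(2)
  t_true <- random_rigid()
  lm <- landmark_pair(tooth, t_true)
  t_est <- landmark_register(lm$source, lm$target)
  expect_lt(max(abs(t_est$rotation - t_true$rotation)), 1e-9)
  expect_lt(max(abs(t_est$translation - t_true$translation)), 1e-9)
})

test_that("perturbed landmarks still let downstream ICP recover the pose", {
  tooth <- default_tooth()$mesh
  t_true <- compose_transform(rotation_about_axis(c(1, 0.5, 0.2), 4),
                              rigid_transform(diag(3), c(0.8, -0.5, 0.6)))
  lm <- landmark_pair(tooth, t_true, seed = 10L, perturb_sd = 0.3)
  init <- landmark_register(lm$source, lm$target)
  expect_gt(max_vertex_error(tooth, init, t_true), 0)   # residual exists
  r <- icp_register(tooth, apply_transform(tooth, t_true), init = init)
  expect_lt(max_vertex_error(tooth, r$transform, t_true), 0.05)
})
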