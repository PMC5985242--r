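#' Write a complete synthetic validation case to disk
#'
#' Generates the full set of inputs the ERP pipeline consumes, with known
#' ground truth: pre-treatment full-tooth meshes, simulated tooth
#' movements, crown-only "laser scan" meshes of the moved teeth, an
#' independently degraded full-tooth "CBCT control" dentition expressed in
#' its own scanner frame, per-tooth and per-arch landmark files, CEJ plane
#' files and the ground-truth transforms.
#'
#' Cases: `"static"` — no movement, no noise (the pipeline fixed point);
#' `"moved"` — known per-tooth movements, clean scans; `"noisy"` — the
#' same movements plus scan noise (vertex noise sd 0.05 mm, 50% face
#' decimation on the crowns), landmark picking error (sd 0.3 mm) and
#' independent noise on the control segmentation.
#'
#' @param out_dir output directory (created).
#' @param case one of `"static"`, `"moved"`, `"noisy"`.
#' @param n_teeth teeth per arch (default 14).
#' @param arches character subset of `c("maxillary", "mandibular")`.
#' @param seed integer master seed; every random element derives from it.
#' @param mesh_resolution forwarded to [tooth_spec()].
#' @return invisibly, a list with the ground truth (`tooth_transforms`,
#'   `arch_transforms`, `moved`, `arch`) for in-memory use.
#' @export
synth_case <- function(out_dir, case = c("static", "moved", "noisy"),
                       n_teeth = 14L, arches = c("maxillary", "mandibular"),
                       seed = 0L, mesh_resolution = 4L) {
  case <- match.arg(case)
  seed <- as.integer(seed)
  noise_sd <- if (case == "noisy") 0.05 else 0
  decim <- if (case == "noisy") 0.5 else 0
  lm_sd <- if (case == "noisy") 0.3 else 0
  for (d in c("pretx", "crowns", "control", "landmarks/source",
              "landmarks/target", "arch_landmarks/source",
              "arch_landmarks/target", "cej", "cej_control", "ground_truth"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)

  all_truth <- list(tooth_transforms = list(), arch_transforms = list())
  for (arch_name in arches) {
    arch <- make_arch(n_teeth = n_teeth, arch = arch_name,
                      mesh_resolution = mesh_resolution)
    ids <- tooth_ids(arch$dentition)
    movements <- list()
    if (case != "static") {
      movements <- with_seed(seed + match(arch_name, arches), {
        mv <- lapply(ids, function(id)
          tooth_movement(tip_deg = stats::runif(1, -2, 2),
                         torque_deg = stats::runif(1, -2, 2),
                         rotation_deg = stats::runif(1, -2, 2),
                         translation_mm = stats::runif(3, -0.5, 0.5)))
        names(mv) <- ids
        mv
      })
    }
    moved <- simulate_treatment(arch, movements)

    # crown-only laser scan of the moved dentition (the registration target)
    crowns <- simulate_scan(moved$dentition, moved$cej_planes,
                            crop = "crown_only", vertex_noise_sd = noise_sd,
                            decimation_fraction = decim, seed = seed + 11L)
    # CBCT control: full moved teeth with independent degradation, shifted
    # into its own scanner frame by a known per-arch transform
    control_local <- simulate_scan(moved$dentition, moved$cej_planes,
                                   crop = "full_tooth",
                                   vertex_noise_sd = noise_sd,
                                   decimation_fraction = 0,
                                   seed = seed + 23L)
    t_arch <- if (case == "static") transform_identity() else
      compose_transform(
        rotation_about_axis(c(0.3, 0.5, 1), 4 + match(arch_name, arches)),
        rigid_transform(diag(3), c(2.5, -1.5, 3) * match(arch_name, arches)))
    control <- dentition(lapply(control_local$teeth, apply_transform, t = t_arch),
                         arch = control_local$arch)

    write_dentition(arch$dentition, file.path(out_dir, "pretx"))
    write_dentition(crowns, file.path(out_dir, "crowns"))
    write_dentition(control, file.path(out_dir, "control"))

    for (id in ids) {
      lm <- landmark_pair(arch$dentition$teeth[[id]], moved$transforms[[id]],
                          seed = seed + match(id, ids), perturb_sd = lm_sd)
      write_landmarks(lm$source,
                      file.path(out_dir, "landmarks/source", paste0(id, ".json")),
                      tooth_id = id)
      write_landmarks(lm$target,
                      file.path(out_dir, "landmarks/target", paste0(id, ".json")),
                      tooth_id = id)
      write_cej_plane(arch$cej_planes[[id]],
                      file.path(out_dir, "cej", paste0(id, ".json")))
      write_cej_plane(transform_plane(moved$cej_planes[[id]], t_arch),
                      file.path(out_dir, "cej_control", paste0(id, ".json")))
      write_transform(moved$transforms[[id]],
                      file.path(out_dir, "ground_truth", paste0(id, ".json")))
      all_truth$tooth_transforms[[id]] <- moved$transforms[[id]]
    }
    # arch landmarks: picks on the combined control crowns, mapped into the
    # scan frame through the known inverse of the scanner-frame transform
    control_crowns <- lapply(ids, function(id) {
      cut <- cut_at_cej(control$teeth[[id]],
                        transform_plane(moved$cej_planes[[id]], t_arch))
      cut$crown
    })
    alm <- landmark_pair(merge_meshes(control_crowns), invert_transform(t_arch),
                         k = 4L, seed = seed + 37L, perturb_sd = lm_sd)
    write_landmarks(alm$source,
                    file.path(out_dir, "arch_landmarks/source",
                              paste0(arch_name, ".json")))
    write_landmarks(alm$target,
                    file.path(out_dir, "arch_landmarks/target",
                              paste0(arch_name, ".json")))
    write_transform(t_arch,
                    file.path(out_dir, "ground_truth",
                              paste0("arch_", arch_name, ".json")))
    all_truth$arch_transforms[[arch_name]] <- t_arch
    all_truth[[arch_name]] <- list(arch = arch, moved = moved)
  }
  invisible(all_truth)
}

read_landmark_dir <- function(dir_path) {
  files <- list.files(dir_path, pattern = "\\.json$")
  out <- lapply(file.path(dir_path, files), read_landmarks)
  names(out) <- sub("\\.json$", "", files)
  out
}

read_cej_dir <- function(dir_path) {
  files <- list.files(dir_path, pattern = "\\.json$")
  out <- lapply(file.path(dir_path, files), read_cej_plane)
  names(out) <- sub("\\.json$", "", files)
  out
}

#' Run the full ERP workflow from a configuration
#'
#' Orchestrates the complete pipeline: per-tooth ERP setup generation,
#' per-arch control superimposition into the scan frame, indirect
#' superimposition, crown/root separation and the displacement report.
#' Every produced file is listed in a JSON manifest with MD5 checksums, so
#' a rerun with the same inputs and seed can be proven identical.
#'
#' @param config a named list (or path to a JSON file) with entries:
#'   `pretx_dir`, `crowns_dir`, `landmarks_dir` (containing `source/` and
#'   `target/` per-tooth files) — required; `control_dir`,
#'   `arch_landmarks_dir`, `cej_dir` (pre-treatment frame),
#'   `cej_control_dir` (control frame), `manual_pre_dir` — optional;
#'   `out_dir` — required; `icp` (list of [icp_register()] arguments),
#'   `threshold` (default 0.75), `bin_width` (0.25), `hist_range`
#'   (c(-2, 2)).
#' @return invisibly, a list with the `erp_setup`, the displacement
#'   `report` (when a control is supplied) and the manifest path.
#' @export
run_end_to_end <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("pretx_dir", "crowns_dir", "landmarks_dir", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config lacks required entries: ",
                         paste(miss, collapse = ", "))
  for (d in c("pretx_dir", "crowns_dir"))
    if (!dir.exists(config[[d]])) stop("no such directory (", d, "): ",
                                       config[[d]])
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  icp_params <- config$icp %||% list()
  threshold <- config$threshold %||% 0.75
  bin_width <- config$bin_width %||% 0.25
  hist_range <- config$hist_range %||% c(-2, 2)

  pretx <- read_dentition(config$pretx_dir)
  crowns <- read_dentition(config$crowns_dir)
  src <- read_landmark_dir(file.path(config$landmarks_dir, "source"))
  tgt <- read_landmark_dir(file.path(config$landmarks_dir, "target"))
  landmarks <- lapply(stats::setNames(nm = intersect(names(src), names(tgt))),
                      function(id) list(source = src[[id]]$points,
                                        target = tgt[[id]]$points))
  cej <- if (!is.null(config$cej_dir)) read_cej_dir(config$cej_dir) else NULL
  manual_pre <- if (!is.null(config$manual_pre_dir)) {
    files <- list.files(config$manual_pre_dir, pattern = "\\.json$")
    tr <- lapply(file.path(config$manual_pre_dir, files), read_transform)
    names(tr) <- sub("\\.json$", "", files)
    tr
  } else NULL

  erp <- generate_erp_setup(pretx, crowns, landmarks, manual_pre = manual_pre,
                            cej_planes = cej, icp_params = icp_params)
  erp_dir <- file.path(out_dir, "erp")
  write_dentition(erp$erp_teeth, erp_dir)
  tdir <- file.path(out_dir, "transforms")
  dir.create(tdir, showWarnings = FALSE)
  for (id in names(erp$per_tooth_transforms))
    write_transform(erp$per_tooth_transforms[[id]],
                    file.path(tdir, paste0(id, ".json")))
  diag <- data.frame(
    tooth_id = names(erp$diagnostics),
    rms = vapply(erp$diagnostics, `[[`, numeric(1L), "rms"),
    iterations = vapply(erp$diagnostics, `[[`, integer(1L), "iterations_run"),
    converged = vapply(erp$diagnostics, `[[`, logical(1L), "converged"))
  utils::write.csv(diag, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)

  report <- NULL
  if (!is.null(config$control_dir)) {
    if (is.null(config$arch_landmarks_dir))
      stop("control validation requires arch_landmarks_dir")
    control <- read_dentition(config$control_dir)
    asrc <- read_landmark_dir(file.path(config$arch_landmarks_dir, "source"))
    atgt <- read_landmark_dir(file.path(config$arch_landmarks_dir, "target"))
    arch_landmarks <- lapply(stats::setNames(nm = names(asrc)), function(a)
      list(source = asrc[[a]]$points, target = atgt[[a]]$points))
    cej_control <- if (!is.null(config$cej_control_dir))
      read_cej_dir(config$cej_control_dir) else NULL
    ctl <- superimpose_control(control, crowns, arch_landmarks,
                               cej_planes = cej_control,
                               icp_params = icp_params)
    pairs <- indirect_superimpose(erp, ctl$dentition)
    # CEJ planes for the crown/root separation, expressed in the common
    # scan frame: control-frame planes mapped by the per-arch transforms
    cej_common <- NULL
    if (!is.null(cej_control)) {
      cej_common <- lapply(stats::setNames(nm = names(pairs)), function(id) {
        a <- attr(pairs, "arch")[[id]]
        transform_plane(cej_control[[id]], ctl$transforms[[a]])
      })
    }
    report <- compare_pair_report(
      pairs, cej_planes = cej_common,
      scenarios = if (is.null(cej_common)) "crowns" else c("crowns", "roots"),
      threshold = threshold, bin_width = bin_width, hist_range = hist_range,
      out_dir = file.path(out_dir, "report"))
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA)
  invisible(list(erp = erp, report = report, manifest = manifest_path))
}
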