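# The synthetic study conditions used by the end-to-end validation: a
# 14-tooth arch per jaw, per-tooth movements drawn once (uniform within
# +/- 2 degrees of tip/torque/rotation and +/- 0.5 mm of translation),
# landmark-picking error sd 0.3 mm, and for the degraded variant vertex
# noise sd 0.05 mm with 50% face decimation on the crown scans (seed 0).
# Returns pooled per-arch root displacement stats of the ERP setup against
# the ground-truth moved roots.
erp_root_recovery_stats <- function(arch_name, noisy = FALSE, seed = 0L,
                                    n_teeth = 14L, mesh_resolution = 4L) {
  arch <- make_arch(n_teeth = n_teeth, arch = arch_name,
                    mesh_resolution = mesh_resolution)
  ids <- tooth_ids(arch$dentition)
  set.seed(seed)
  movements <- stats::setNames(lapply(ids, function(id)
    tooth_movement(tip_deg = stats::runif(1, -2, 2),
                   torque_deg = stats::runif(1, -2, 2),
                   rotation_deg = stats::runif(1, -2, 2),
                   translation_mm = stats::runif(3, -0.5, 0.5))), ids)
  moved <- simulate_treatment(arch, movements)
  crowns <- simulate_scan(moved$dentition, moved$cej_planes,
                          crop = "crown_only",
                          vertex_noise_sd = if (noisy) 0.05 else 0,
                          decimation_fraction = if (noisy) 0.5 else 0,
                          seed = seed)
  landmarks <- lapply(stats::setNames(nm = ids), function(id)
    landmark_pair(arch$dentition$teeth[[id]], moved$transforms[[id]],
                  seed = seed + match(id, ids), perturb_sd = 0.3))
  erp <- generate_erp_setup(arch$dentition, crowns, landmarks,
                            cej_planes = arch$cej_planes)
  pooled <- numeric(0)
  per_tooth_max <- numeric(0)
  for (id in ids) {
    pl <- moved$cej_planes[[id]]
    erp_root <- cut_at_cej(erp$erp_teeth$teeth[[id]], pl)$root
    truth_root <- cut_at_cej(moved$dentition$teeth[[id]], pl)$root
    fld <- signed_displacement(erp_root, truth_root)
    pooled <- c(pooled, fld$distances)
    per_tooth_max[id] <- max(abs(fld$distances))
  }
  list(stats = displacement_stats(pooled), per_tooth_max = per_tooth_max,
       erp = erp, moved = moved, arch = arch, crowns = crowns,
       landmarks = landmarks)
}
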