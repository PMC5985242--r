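#' Signed surface-to-surface displacement field
#'
#' For every vertex of the test mesh, the distance to the exact nearest
#' point on the reference surface (point-to-triangle), signed by the side
#' of the reference surface: positive when the test vertex lies outside
#' the reference (along the outward pseudo-normal at the nearest point),
#' negative when inside. The sign is computed with angle-weighted
#' pseudo-normals, which are exact for consistently oriented meshes even
#' when the nearest feature is an edge or a vertex.
#'
#' @param test [triangle_mesh()] whose vertices are measured.
#' @param reference [triangle_mesh()] with consistently oriented outward
#'   normals (for a closed mesh, signed volume > 0).
#' @param test_id,reference_id optional labels carried into the result.
#' @return object of class `displacement_field`: list with `distances`
#'   (signed mm, one per test vertex), `test_id`, `reference_id`.
#' @export
signed_displacement <- function(test, reference, test_id = NULL,
                                reference_id = NULL) {
  stopifnot(inherits(test, "triangle_mesh"), inherits(reference, "triangle_mesh"))
  ar <- face_areas(reference)
  if (all(ar <= 0))
    stop("reference mesh has only zero-area triangles")
  res <- cpp_signed_distance(test$vertices, reference$vertices, reference$faces)
  structure(list(distances = as.numeric(res$distance),
                 test_id = test_id, reference_id = reference_id),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  st <- displacement_stats(x)
  cat(sprintf("displacement_field: %d vertices, mean %.4f mm, sd %.4f mm, max |d| %.4f mm\n",
              st$n_vertices, st$mean, st$sd, st$max_abs))
  invisible(x)
}

#' Three-color classification of a displacement field
#'
#' The deviation-map convention: displacements within the threshold band
#' (default 0.75 mm, inclusive) are green; inward displacement beyond the
#' threshold is blue; outward displacement beyond it is red.
#'
#' @param field a [signed_displacement()] field, or a numeric vector of
#'   signed displacements (mm).
#' @param threshold band half-width in mm (> 0, default 0.75).
#' @return list with `labels` (factor with levels green/blue/red) and
#'   `colors` (n x 3 integer RGB matrix: green (0,255,0), blue (0,0,255),
#'   red (255,0,0)).
#' @export
classify_colors <- function(field, threshold = 0.75) {
  if (threshold <= 0) stop("threshold must be > 0")
  d <- if (inherits(field, "displacement_field")) field$distances else as.numeric(field)
  lab <- ifelse(abs(d) <= threshold, "green", ifelse(d > 0, "red", "blue"))
  lab <- factor(lab, levels = c("green", "blue", "red"))
  pal <- rbind(green = c(0L, 255L, 0L), blue = c(0L, 0L, 255L),
               red = c(255L, 0L, 0L))
  list(labels = lab, colors = pal[as.character(lab), , drop = FALSE])
}

#' Attach displacement-map colors to a mesh
#' @param mesh the test [triangle_mesh()] the field was computed on.
#' @param field its [signed_displacement()] field.
#' @param threshold band half-width in mm (default 0.75).
#' @return the mesh with per-vertex colors set (exportable as colored PLY).
#' @export
color_mesh <- function(mesh, field, threshold = 0.75) {
  d <- if (inherits(field, "displacement_field")) field$distances else as.numeric(field)
  if (length(d) != nrow(mesh$vertices))
    stop("field length does not match the mesh vertex count")
  cls <- classify_colors(d, threshold)
  triangle_mesh(mesh$vertices, mesh$faces, colors = unname(cls$colors))
}

#' Summary statistics of a displacement field
#'
#' The reporting convention of deviation-map analyses: signed mean,
#' population standard deviation (the vertices are the complete population
#' of the mesh, not a sample) and maximum absolute displacement.
#'
#' @param field a [signed_displacement()] field or numeric vector (mm).
#' @return object of class `displacement_stats`: list with `mean`, `sd`,
#'   `max_abs` (mm) and `n_vertices`.
#' @export
displacement_stats <- function(field) {
  d <- if (inherits(field, "displacement_field")) field$distances else as.numeric(field)
  if (length(d) == 0L) stop("empty displacement field")
  m <- mean(d)
  structure(list(mean = m,
                 sd = sqrt(mean((d - m)^2)),
                 max_abs = max(abs(d)),
                 n_vertices = length(d)),
            class = "displacement_stats")
}

#' @export
print.displacement_stats <- function(x, ...) {
  cat(sprintf("displacement: %.3f +/- %.3f mm, max %.3f mm (n = %d)\n",
              x$mean, x$sd, x$max_abs, x$n_vertices))
  invisible(x)
}

#' Histogram of a displacement field
#'
#' Fixed-width bins over a stated range; values outside the range are
#' clipped into the end bins so the counts always sum to the number of
#' vertices. Defaults mirror the usual deviation-map plots: 0.25 mm bins
#' over -2..+2 mm.
#'
#' @param field a [signed_displacement()] field or numeric vector (mm).
#' @param bin_width bin width in mm (> 0).
#' @param range length-2 numeric, `(min, max)` of the binned range.
#' @return data.frame with columns `bin_left`, `bin_right`, `count`.
#' @export
displacement_histogram <- function(field, bin_width = 0.25, range = c(-2, 2)) {
  d <- if (inherits(field, "displacement_field")) field$distances else as.numeric(field)
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (range[2L] <= range[1L]) stop("inverted histogram range")
  edges <- seq(range[1L], range[2L], by = bin_width)
  if (edges[length(edges)] < range[2L]) edges <- c(edges, range[2L])
  nb <- length(edges) - 1L
  dc <- pmin(pmax(d, range[1L]), range[2L])          # clip into end bins
  idx <- findInterval(dc, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1L],
             count = counts)
}

#' Per-arch crown and root displacement report
#'
#' The validation table of the ERP workflow. For each arch and each
#' scenario — crowns and (when CEJ planes are given) roots, separated by
#' [cut_at_cej()] — the per-vertex signed displacements of the ERP teeth
#' (test) relative to the control teeth (reference) are pooled across the
#' arch and summarized as mean / SD / max rows, with per-tooth rows,
#' histograms and optional colored PLY deviation maps as supplements.
#'
#' @param pairs a `tooth_pairs` object from [indirect_superimpose()].
#' @param cej_planes named list of [cej_plane()] expressed in the common
#'   (scan) frame; required for the roots scenario.
#' @param scenarios character subset of `c("crowns", "roots")`.
#' @param threshold color-band half-width in mm (default 0.75).
#' @param bin_width,hist_range histogram parameters (see
#'   [displacement_histogram()]).
#' @param out_dir optional directory; when given, writes `stats.csv`,
#'   `per_tooth.csv`, one `hist_<scenario>_<arch>.csv` per block and one
#'   colored `map_<scenario>_<arch>.ply` per block.
#' @return object of class `displacement_report`: list with `stats`
#'   (data.frame: analysis, arch, mean_mm, sd_mm, max_mm, n_vertices),
#'   `per_tooth` (same schema plus tooth), `histograms` and `fields`
#'   (named lists keyed `<scenario>_<arch>`).
#' @export
compare_pair_report <- function(pairs, cej_planes = NULL,
                                scenarios = c("crowns", "roots"),
                                threshold = 0.75, bin_width = 0.25,
                                hist_range = c(-2, 2), out_dir = NULL) {
  stopifnot(inherits(pairs, "tooth_pairs"))
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if ("roots" %in% scenarios && is.null(cej_planes))
    stop("the roots scenario requires CEJ planes")
  if (length(pairs) == 0L) stop("no tooth pairs to compare")
  arch <- attr(pairs, "arch")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  part_of <- function(mesh, id, part) {
    if (part == "full") return(mesh)
    pl <- cej_planes[[id]]
    if (is.null(pl)) stop("missing CEJ plane for tooth ", id)
    cut <- cut_at_cej(mesh, pl)
    if (part == "crown") cut$crown else cut$root
  }
  stats_rows <- list()
  tooth_rows <- list()
  histograms <- list()
  fields <- list()
  for (scen in scenarios) {
    part <- if (scen == "crowns") "crown" else "root"
    use_part <- if (is.null(cej_planes)) "full" else part
    for (a in unique(arch)) {
      ids <- names(pairs)[arch == a]
      pooled <- numeric(0)
      colored <- list()
      for (id in ids) {
        test <- part_of(pairs[[id]]$erp, id, use_part)
        ref <- part_of(pairs[[id]]$control, id, use_part)
        if (is.null(test) || is.null(ref)) next
        fld <- signed_displacement(test, ref, test_id = paste0("erp_", id),
                                   reference_id = paste0("control_", id))
        st <- displacement_stats(fld)
        tooth_rows[[length(tooth_rows) + 1L]] <-
          data.frame(analysis = scen, arch = a, tooth = id,
                     mean_mm = st$mean, sd_mm = st$sd, max_mm = st$max_abs,
                     n_vertices = st$n_vertices)
        pooled <- c(pooled, fld$distances)
        if (!is.null(out_dir))
          colored[[id]] <- color_mesh(test, fld, threshold)
      }
      if (length(pooled) == 0L) next
      st <- displacement_stats(pooled)
      key <- paste0(scen, "_", a)
      stats_rows[[key]] <-
        data.frame(analysis = scen, arch = a, mean_mm = st$mean,
                   sd_mm = st$sd, max_mm = st$max_abs,
                   n_vertices = st$n_vertices)
      histograms[[key]] <- displacement_histogram(pooled, bin_width, hist_range)
      fields[[key]] <- pooled
      if (!is.null(out_dir)) {
        utils::write.csv(histograms[[key]],
                         file.path(out_dir, paste0("hist_", key, ".csv")),
                         row.names = FALSE)
        cm <- merge_colored(colored)
        if (!is.null(cm))
          write_mesh(cm, file.path(out_dir, paste0("map_", key, ".ply")),
                     with_colors = TRUE)
      }
    }
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL
  per_tooth <- do.call(rbind, tooth_rows)
  if (!is.null(out_dir)) {
    utils::write.csv(stats, file.path(out_dir, "stats.csv"), row.names = FALSE)
    utils::write.csv(per_tooth, file.path(out_dir, "per_tooth.csv"),
                     row.names = FALSE)
  }
  structure(list(stats = stats, per_tooth = per_tooth,
                 histograms = histograms, fields = fields),
            class = "displacement_report")
}

# merge colored meshes keeping vertex colors
merge_colored <- function(meshes) {
  meshes <- meshes[!vapply(meshes, is.null, logical(1L))]
  if (length(meshes) == 0L) return(NULL)
  m <- merge_meshes(meshes)
  m$colors <- do.call(rbind, lapply(meshes, `[[`, "colors"))
  m
}

#' @export
print.displacement_report <- function(x, ...) {
  cat("displacement_report:\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}
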