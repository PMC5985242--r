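#' Labeled dentition
#'
#' A set of tooth meshes keyed by FDI two-digit tooth codes, each assigned
#' to one arch. FDI quadrants 1 and 2 are maxillary, 3 and 4 mandibular;
#' the quadrant digit therefore determines the arch unless overridden.
#'
#' @param teeth named list of [triangle_mesh()] objects; names are FDI codes
#'   (`"11"`..`"48"`).
#' @param arch optional named character vector (`"maxillary"` /
#'   `"mandibular"`) overriding the FDI-inferred arch per tooth.
#' @return an object of class `dentition` with elements `teeth` and `arch`.
#' @export
dentition <- function(teeth, arch = NULL) {
  ids <- names(teeth)
  if (is.null(ids) || any(!nzchar(ids))) stop("teeth must be a named list")
  if (anyDuplicated(ids)) stop("duplicate tooth IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ok <- vapply(teeth, inherits, logical(1L), "triangle_mesh")
  if (!all(ok)) stop("all teeth must be triangle_mesh objects")
  inferred <- vapply(ids, fdi_arch, character(1L))
  if (!is.null(arch)) {
    bad <- setdiff(names(arch), ids)
    if (length(bad)) stop("arch override for unknown tooth: ",
                          paste(bad, collapse = ", "))
    if (!all(arch %in% c("maxillary", "mandibular")))
      stop("arch must be 'maxillary' or 'mandibular'")
    inferred[names(arch)] <- arch
  }
  structure(list(teeth = teeth, arch = inferred), class = "dentition")
}

#' @export
print.dentition <- function(x, ...) {
  cat(sprintf("dentition: %d teeth (%d maxillary, %d mandibular)\n",
              length(x$teeth), sum(x$arch == "maxillary"),
              sum(x$arch == "mandibular")))
  cat("  ", paste(names(x$teeth), collapse = " "), "\n")
  invisible(x)
}

#' Arch of an FDI tooth code
#'
#' Valid codes are 11-18, 21-28 (maxillary) and 31-38, 41-48 (mandibular);
#' anything else is rejected.
#' @param id character or numeric FDI code.
#' @return `"maxillary"` or `"mandibular"`.
#' @export
fdi_arch <- function(id) {
  id <- as.character(id)
  if (!grepl("^[1-4][1-8]$", id))
    stop("not a valid FDI tooth code: '", id, "'")
  if (substr(id, 1L, 1L) %in% c("1", "2")) "maxillary" else "mandibular"
}

#' Tooth IDs of a dentition, optionally restricted to one arch
#' @param dent a `dentition`.
#' @param arch optional `"maxillary"` or `"mandibular"`.
#' @return character vector of FDI codes.
#' @export
tooth_ids <- function(dent, arch = NULL) {
  ids <- names(dent$teeth)
  if (!is.null(arch)) ids <- ids[dent$arch[ids] == arch]
  ids
}

#' Read a dentition from a directory of mesh files
#'
#' By default every `<FDI>.ply` / `<FDI>.stl` file in the directory is
#' loaded and its arch inferred from the FDI quadrant. A JSON manifest
#' (`{"teeth": [{"id": "11", "file": "...", "arch": "maxillary"}]}`) may
#' instead list the files explicitly, allowing alias file names and arch
#' overrides.
#'
#' @param dir_path directory containing the mesh files.
#' @param manifest optional path to a manifest JSON inside or outside
#'   `dir_path`.
#' @return a [dentition()].
#' @export
read_dentition <- function(dir_path, manifest = NULL) {
  if (!dir.exists(dir_path)) stop("no such directory: ", dir_path)
  if (!is.null(manifest)) {
    man <- jsonlite::read_json(manifest)
    if (is.null(man$teeth)) stop("manifest lacks a \"teeth\" array")
    ids <- vapply(man$teeth, function(e) as.character(e$id), character(1L))
    if (anyDuplicated(ids))
      stop("duplicate tooth IDs in manifest: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    teeth <- list()
    arch <- character(0)
    for (e in man$teeth) {
      id <- as.character(e$id)
      f <- file.path(dir_path, e$file)
      teeth[[id]] <- read_mesh(f)
      if (!is.null(e$arch)) arch[id] <- e$arch
    }
    return(dentition(teeth, arch = if (length(arch)) arch else NULL))
  }
  files <- list.files(dir_path, pattern = "\\.(ply|stl)$", ignore.case = TRUE)
  if (length(files) == 0L) stop("no .ply/.stl files in ", dir_path)
  ids <- sub("\\.[^.]+$", "", files)
  if (anyDuplicated(ids))
    stop("duplicate tooth IDs in ", dir_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- ids[!grepl("^[1-4][1-8]$", ids)]
  if (length(bad))
    stop("file names are not FDI codes (supply a manifest): ",
         paste(bad, collapse = ", "))
  teeth <- lapply(file.path(dir_path, files), read_mesh)
  names(teeth) <- ids
  dentition(teeth)
}

#' Write a dentition as one PLY file per tooth
#' @param dent a `dentition`.
#' @param dir_path output directory (created if missing).
#' @param with_colors write vertex colors where present.
#' @return `dir_path`, invisibly.
#' @export
write_dentition <- function(dent, dir_path, with_colors = FALSE) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (id in names(dent$teeth)) {
    m <- dent$teeth[[id]]
    write_mesh(m, file.path(dir_path, paste0(id, ".ply")),
               with_colors = with_colors && !is.null(m$colors))
  }
  invisible(dir_path)
}
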