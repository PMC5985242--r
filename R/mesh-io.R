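#' Read a triangle mesh from PLY or STL
#'
#' Supports ASCII and binary little-endian PLY (vertex positions as float or
#' double, optional uchar red/green/blue), and ASCII or binary STL (the soup
#' is re-indexed by exact coordinate match). Coordinates are interpreted as
#' millimetres; no unit metadata is read.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension and magic bytes), `"ply"`,
#'   `"stl"`.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ply", "stl")) ext else {
      magic <- readBin(path, "raw", 3L)
      if (identical(rawToChar(magic), "ply")) "ply" else "stl"
    }
  }
  if (format == "ply") read_ply(path) else read_stl(path)
}

#' Write a triangle mesh to PLY or STL
#'
#' PLY is written binary little-endian with double-precision coordinates
#' (round-trips to better than 1e-6 mm) and optional uchar vertex colors.
#' STL is written ASCII with full-precision coordinates; STL carries no
#' color information.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path (parent directory must exist).
#' @param format `"ply"` or `"stl"`.
#' @param with_colors write per-vertex RGB (PLY only; the mesh must carry
#'   colors).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "stl"), with_colors = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!dir.exists(dirname(path)))
    stop("cannot write mesh: directory does not exist: ", dirname(path))
  if (with_colors && is.null(mesh$colors))
    stop("with_colors = TRUE but the mesh has no vertex colors")
  if (with_colors && format == "stl")
    stop("STL carries no vertex colors; use PLY")
  if (format == "ply") write_ply(mesh, path, with_colors) else write_stl(mesh, path)
  invisible(path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_column <- function(rawmat, offset, type, n) {
  sz <- ply_type_size[[type]]
  bytes <- as.raw(rawmat[offset + seq_len(sz), , drop = FALSE])
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  readBin(bytes, what, n = n, size = sz, signed = if (sz < 4L) signed else TRUE,
          endian = "little")
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  header <- character(0)
  repeat {
    line <- readLines(con, 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header in ", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000L) stop("PLY header too long; not a PLY file?")
  }
  if (header[1L] != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop("PLY header lacks a format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  # parse elements and their properties in declared order
  elems <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], list = TRUE, count_type = tok[3L], type = tok[4L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], list = FALSE, type = tok[2L])
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex)) stop("PLY file has no vertex element")
  if (is.null(elems$face) || elems$face$count == 0L)
    stop("mesh has zero faces: ", path)

  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    out <- list()
    for (el in elems) {
      rows <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      toks <- strsplit(trimws(rows), "\\s+")
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        vals <- matrix(as.numeric(unlist(toks)), nrow = el$count, byrow = TRUE)
        out$vertex <- vals
        out$vertex_names <- nm
      } else if (el$name == "face") {
        cnt <- as.integer(vapply(toks, `[[`, "", 1L))
        if (any(cnt != 3L)) stop("only triangular faces are supported")
        out$face <- matrix(as.integer(unlist(lapply(toks, `[`, 2:4))),
                           ncol = 3L, byrow = TRUE) + 1L
      }
    }
  } else {
    out <- list()
    for (el in elems) {
      if (el$name == "vertex") {
        sizes <- vapply(el$props, function(p) {
          if (p$list) stop("list properties on vertices are not supported")
          ply_type_size[[p$type]]
        }, integer(1L))
        stride <- sum(sizes)
        raw <- readBin(con, "raw", stride * el$count)
        if (length(raw) < stride * el$count) stop("truncated PLY vertex data")
        rawmat <- matrix(raw, nrow = stride)
        offs <- cumsum(c(0L, sizes))
        vals <- matrix(0, el$count, length(el$props))
        for (j in seq_along(el$props))
          vals[, j] <- ply_read_column(rawmat, offs[j], el$props[[j]]$type, el$count)
        out$vertex <- vals
        out$vertex_names <- vapply(el$props, `[[`, "", "name")
      } else if (el$name == "face") {
        p <- el$props[[1L]]
        if (!p$list) stop("face element must carry a vertex index list")
        csz <- ply_type_size[[p$count_type]]
        isz <- ply_type_size[[p$type]]
        stride <- csz + 3L * isz
        raw <- readBin(con, "raw", stride * el$count)
        if (length(raw) != stride * el$count)
          stop("non-triangular faces or truncated PLY face data")
        rawmat <- matrix(raw, nrow = stride)
        cnt <- ply_read_column(rawmat, 0L, p$count_type, el$count)
        if (any(cnt != 3L)) stop("only triangular faces are supported")
        idx <- sapply(0:2, function(k)
          ply_read_column(rawmat, csz + k * isz, p$type, el$count))
        out$face <- matrix(as.integer(idx), ncol = 3L) + 1L
      } else {
        stop("unsupported PLY element in binary file: ", el$name)
      }
    }
  }
  nm <- out$vertex_names
  need <- c("x", "y", "z")
  if (!all(need %in% nm)) stop("PLY vertex element lacks x/y/z properties")
  verts <- out$vertex[, match(need, nm), drop = FALSE]
  colors <- NULL
  if (all(c("red", "green", "blue") %in% nm))
    colors <- out$vertex[, match(c("red", "green", "blue"), nm), drop = FALSE]
  if (max(out$face) > nrow(verts) || min(out$face) < 1L)
    stop("PLY face index out of range")
  triangle_mesh(verts, out$face, colors = colors)
}

write_ply <- function(mesh, path, with_colors = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment erproot mesh, coordinates in mm",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (with_colors)
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  vraw <- matrix(writeBin(as.numeric(t(mesh$vertices)), raw(), size = 8L,
                          endian = "little"), nrow = 24L)
  if (with_colors) {
    craw <- matrix(as.raw(t(mesh$colors)), nrow = 3L)
    vraw <- rbind(vraw, craw)   # interleave: 3 doubles + 3 uchars per vertex
  }
  writeBin(as.raw(vraw), con)
  # face records: uchar count 3 then 3 int32 indices, per face
  iraw <- matrix(writeBin(as.integer(t(mesh$faces - 1L)), raw(), size = 4L,
                          endian = "little"), nrow = 12L)
  writeBin(as.raw(rbind(matrix(as.raw(3L), 1L, nf), iraw)), con)
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  binary <- length(ntri) == 1L && !is.na(ntri) && sz == 84 + 50 * ntri
  if (binary) {
    raw <- readBin(con, "raw", 50L * ntri)
    close(con)
    rawmat <- matrix(raw, nrow = 50L)
    tri <- matrix(0, ntri, 9L)
    for (k in 0:8) {   # skip the 12-byte normal, read 3 float32 vertices
      bytes <- as.raw(rawmat[12L + k * 4L + 1:4, , drop = FALSE])
      tri[, k + 1L] <- readBin(bytes, "double", n = ntri, size = 4L,
                               endian = "little")
    }
  } else {
    close(con)
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop("malformed ASCII STL: ", path)
    coords <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vlines), "\\s+"),
                                              `[`, 2:4))),
                     ncol = 3L, byrow = TRUE)
    ntri <- nrow(coords) / 3L
    tri <- matrix(t(coords), ntri, 9L, byrow = TRUE)
  }
  if (ntri == 0L) stop("mesh has zero faces: ", path)
  # re-index the triangle soup by exact coordinate identity
  pts <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(pts[, 1L], pts[, 2L], pts[, 3L])
  uidx <- !duplicated(key)
  verts <- pts[uidx, , drop = FALSE]
  idx <- match(key, key[uidx])
  faces <- matrix(idx, ncol = 3L)
  triangle_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2)); len[len == 0] <- 1
  nrm <- cr / len
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                "  vertex %.17g %.17g %.17g\n  vertex %.17g %.17g %.17g\n",
                "  vertex %.17g %.17g %.17g\n endloop\nendfacet")
  body <- sprintf(fmt, nrm[, 1L], nrm[, 2L], nrm[, 3L],
                  v[f[, 1L], 1L], v[f[, 1L], 2L], v[f[, 1L], 3L],
                  v[f[, 2L], 1L], v[f[, 2L], 2L], v[f[, 2L], 3L],
                  v[f[, 3L], 1L], v[f[, 3L], 2L], v[f[, 3L], 3L])
  writeLines(c("solid erproot", body, "endsolid erproot"), con)
  invisible(path)
}

#' Serialize a rigid transform to JSON
#'
#' The file holds the 4x4 row-major homogeneous matrix under key `"matrix"`;
#' round-trips are exact to 1e-12. Reading validates orthonormality and
#' determinant +1 of the rotation block.
#'
#' @param t a [rigid_transform()].
#' @param path JSON file path.
#' @return `write_transform`: `path` invisibly; `read_transform`: a
#'   `rigid_transform`.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- transform_to_matrix(t)
  jsonlite::write_json(list(matrix = apply(m, 1L, as.numeric, simplify = FALSE)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("no such transform file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$matrix)) stop("transform JSON lacks a \"matrix\" key")
  m <- obj$matrix
  if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))   # list of rows
  if (is.null(dim(m))) m <- matrix(as.numeric(m), 4L, 4L, byrow = TRUE)
  transform_from_matrix(m)
}
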