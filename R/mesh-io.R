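#' Read a triangle mesh from file
#'
#' Supports PLY (ASCII and binary little-endian), STL (ASCII and binary),
#' Wavefront OBJ, and VTK polydata (legacy ASCII and XML `.vtp` with ASCII
#' data arrays). Duplicate vertices are merged on load at a tolerance of
#' `1e-9` times the bounding-box diagonal (STL stores no shared-vertex
#' topology, so merging is what recovers it); faces made topologically
#' degenerate by the merge are dropped.
#'
#' @param path file path; the format is taken from the extension
#'   (`.ply`, `.stl`, `.obj`, `.vtk`, `.vtp`).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (file.size(path) == 0L) stop("mesh file is empty: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path),
    vtk = read_vtk_legacy(path),
    vtp = read_vtp(path),
    stop("unsupported mesh format: .", ext)
  )
  if (nrow(raw$faces) == 0L) stop("mesh file has no faces: ", path)
  merged <- merge_duplicate_vertices(raw$vertices, raw$faces)
  triangle_mesh(merged$vertices, merged$faces)
}

#' Write a triangle mesh to file
#'
#' Writes ASCII variants of PLY, STL, OBJ, VTK legacy polydata or XML `.vtp`
#' (chosen by extension). Coordinates are written with 17 significant digits,
#' so a read/write round trip reproduces geometry to well below 1e-6.
#'
#' @param mesh a [triangle_mesh()] with at least one face.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0L) stop("refusing to write a mesh with 0 faces")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path),
    stl = write_stl(mesh, path),
    vtk = write_vtk_legacy(mesh, path),
    vtp = write_vtp(mesh, path),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# Merge vertices closer than tol (default 1e-9 * bbox diagonal) by snapping
# to a rounding grid; exact duplicates always merge. Faces that collapse are
# dropped.
merge_duplicate_vertices <- function(V, F, tol = NULL) {
  if (is.null(tol)) tol <- 1e-9 * bbox_of(V)$diag
  key <- if (tol > 0) {
    apply(round(V / tol), 1, paste, collapse = " ")
  } else {
    apply(V, 1, paste, collapse = " ")
  }
  first <- match(key, key)           # index of first vertex with same key
  keep <- which(first == seq_along(first))
  map <- integer(nrow(V))
  map[keep] <- seq_along(keep)
  remap <- map[first]
  F2 <- matrix(remap[F], ncol = 3L)
  degen <- F2[, 1] == F2[, 2] | F2[, 2] == F2[, 3] | F2[, 1] == F2[, 3]
  list(vertices = V[keep, , drop = FALSE],
       faces = F2[!degen, , drop = FALSE])
}

# ---- OBJ -------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("OBJ file has no vertices: ", path)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- list()
  for (ln in flines) {
    tok <- strsplit(trimws(sub("^f", "", ln)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, character(1), 1L))
    if (length(idx) < 3L) next
    # fan-triangulate polygons
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  Fm <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  list(vertices = V, faces = Fm)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3])), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

# ---- PLY -------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  } else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", n = 1L, size = sz, signed = signed || sz == 4L,
            endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("PLY header not terminated: ", path)
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  if (!grepl("^ply", hdr[1])) stop("not a PLY file: ", path)
  fmt_line <- grep("^format", hdr, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]

  # parse elements/properties
  elements <- list()
  cur <- NULL
  for (ln in hdr) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY file has no vertex element: ", path)

  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 1L
    out <- list()
    for (el in elements) {
      n <- el$count
      block <- txt[seq.int(pos, length.out = n)]
      pos <- pos + n
      rows <- strsplit(trimws(block), "\\s+")
      out[[el$name]] <- list(el = el, rows = rows)
    }
    vx <- out$vertex
    pnames <- vapply(vx$el$props, `[[`, character(1), "name")
    Vall <- do.call(rbind, lapply(vx$rows, function(r) as.numeric(r)))
    V <- Vall[, match(c("x", "y", "z"), pnames), drop = FALSE]
    faces <- list()
    if (!is.null(out$face)) {
      for (r in out$face$rows) {
        v <- as.integer(r)
        cnt <- v[1]
        idx <- v[2:(1 + cnt)] + 1L
        for (k in seq_len(cnt - 2L))
          faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
      }
    }
  } else if (fmt == "binary_little_endian") {
    V <- NULL
    faces <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, character(1), "name")
        Vall <- matrix(0, el$count, length(el$props))
        for (i in seq_len(el$count))
          for (j in seq_along(el$props))
            Vall[i, j] <- ply_read_scalar(con, el$props[[j]]$type)
        V <- Vall[, match(c("x", "y", "z"), pnames), drop = FALSE]
      } else if (el$name == "face") {
        for (i in seq_len(el$count)) {
          for (p in el$props) {
            if (p$list) {
              cnt <- ply_read_scalar(con, p$count_type)
              idx <- integer(cnt)
              for (k in seq_len(cnt)) idx[k] <- ply_read_scalar(con, p$item_type)
              idx <- idx + 1L
              for (k in seq_len(cnt - 2L))
                faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
            } else {
              ply_read_scalar(con, p$type)
            }
          }
        }
      } else {
        # skip unknown fixed-size elements
        for (i in seq_len(el$count))
          for (p in el$props) ply_read_scalar(con, p$type)
      }
    }
    if (is.null(V)) stop("PLY file has no vertex data: ", path)
  } else {
    stop("unsupported PLY format: ", fmt)
  }
  Fm <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  list(vertices = V, faces = Fm)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3])), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

# ---- STL -------------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = min(80L, sz))
  is_binary <- FALSE
  if (sz > 84) {
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.double(ntri)) is_binary <- TRUE
  }
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    V <- matrix(0, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)
      V[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed ASCII STL: ", path)
    V <- do.call(rbind, lapply(strsplit(trimws(sub("vertex", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    ntri <- nrow(V) / 3L
  }
  Fm <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = V, faces = Fm)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      paste("  facet normal", fmt_num(nrm[i, 1]), fmt_num(nrm[i, 2]),
            fmt_num(nrm[i, 3])),
      "    outer loop",
      paste("      vertex", fmt_num(v[f[i, 1], 1]), fmt_num(v[f[i, 1], 2]),
            fmt_num(v[f[i, 1], 3])),
      paste("      vertex", fmt_num(v[f[i, 2], 1]), fmt_num(v[f[i, 2], 2]),
            fmt_num(v[f[i, 2], 3])),
      paste("      vertex", fmt_num(v[f[i, 3], 1]), fmt_num(v[f[i, 3], 2]),
            fmt_num(v[f[i, 3], 3])),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

# ---- VTK legacy polydata ---------------------------------------------------

read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", lines[1])) stop("not a legacy VTK file: ", path)
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("only ASCII legacy VTK is supported: ", path)
  toks <- scan(text = paste(lines[-(1:2)], collapse = "\n"), what = "character",
               quiet = TRUE)
  ip <- match("POINTS", toupper(toks))
  if (is.na(ip)) stop("VTK file has no POINTS: ", path)
  npts <- as.integer(toks[ip + 1L])
  V <- matrix(as.numeric(toks[(ip + 3L):(ip + 2L + 3L * npts)]), ncol = 3L,
              byrow = TRUE)
  ifc <- match("POLYGONS", toupper(toks))
  faces <- list()
  if (!is.na(ifc)) {
    npoly <- as.integer(toks[ifc + 1L])
    total <- as.integer(toks[ifc + 2L])
    pos <- ifc + 3L
    if (toupper(toks[pos]) == "OFFSETS") {
      # VTK 5.1+ legacy layout: OFFSETS <type> ... CONNECTIVITY <type> ...
      off <- as.integer(toks[(pos + 2L):(pos + 1L + npoly)])
      pos2 <- pos + 2L + npoly
      stopifnot(toupper(toks[pos2]) == "CONNECTIVITY")
      ncon <- off[npoly]
      conn <- as.integer(toks[(pos2 + 2L):(pos2 + 1L + ncon)]) + 1L
      for (i in seq_len(npoly - 1L)) {
        idx <- conn[(off[i] + 1L):off[i + 1L]]
        for (k in seq_len(length(idx) - 2L))
          faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
      }
    } else {
      vals <- as.integer(toks[pos:(pos - 1L + total)])
      i <- 1L
      while (i <= total) {
        cnt <- vals[i]
        idx <- vals[(i + 1L):(i + cnt)] + 1L
        for (k in seq_len(cnt - 2L))
          faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
        i <- i + cnt + 1L
      }
    }
  }
  Fm <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  list(vertices = V, faces = Fm)
}

write_vtk_legacy <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "shapeshared mesh", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nv, "double")), con)
  writeLines(paste(fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3])), con)
  writeLines(paste("POLYGONS", nf, 4L * nf), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

# ---- VTK XML polydata (.vtp, ASCII data arrays) ----------------------------

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("no <Piece> in VTP file: ", path)
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  if (!identical(xml2::xml_attr(pts, "format"), "ascii"))
    stop("only ascii VTP data arrays are supported: ", path)
  V <- matrix(scan(text = xml2::xml_text(pts), quiet = TRUE), ncol = 3L,
              byrow = TRUE)
  conn_node <- xml2::xml_find_first(piece,
    ".//Polys/DataArray[@Name='connectivity']")
  off_node <- xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='offsets']")
  faces <- list()
  if (!inherits(conn_node, "xml_missing")) {
    conn <- as.integer(scan(text = xml2::xml_text(conn_node), quiet = TRUE)) + 1L
    off <- as.integer(scan(text = xml2::xml_text(off_node), quiet = TRUE))
    start <- c(1L, head(off, -1L) + 1L)
    for (i in seq_along(off)) {
      idx <- conn[start[i]:off[i]]
      for (k in seq_len(length(idx) - 2L))
        faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
    }
  }
  Fm <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  list(vertices = V, faces = Fm)
}

write_vtp <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  pts <- paste(apply(mesh$vertices, 1, function(r)
    paste(fmt_num(r), collapse = " ")), collapse = "\n")
  conn <- paste(as.vector(t(mesh$faces - 1L)), collapse = " ")
  offs <- paste(seq_len(nf) * 3L, collapse = " ")
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    "  <PolyData>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfPolys="%d">', nv, nf),
    "      <Points>",
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    pts,
    "        </DataArray>",
    "      </Points>",
    "      <Polys>",
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    conn,
    "        </DataArray>",
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    offs,
    "        </DataArray>",
    "      </Polys>",
    "    </Piece>",
    "  </PolyData>",
    "</VTKFile>")
  writeLines(xml, path)
}

# ---- contours --------------------------------------------------------------

#' Read a contour from a plain-text file
#'
#' The format is one `x y z` triple per line; closure is implied.
#'
#' @param path file path.
#' @return a closed [contour3d()].
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("cannot read contour file: ", path)
  vals <- scan(path, quiet = TRUE)
  if (length(vals) < 9L || length(vals) %% 3L != 0L)
    stop("malformed contour file: ", path)
  contour3d(matrix(vals, ncol = 3L, byrow = TRUE), closed = TRUE)
}

#' Write a contour to a plain-text file (or VTK polyline)
#'
#' @param contour a [contour3d()].
#' @param path output path; extension `.vtk` writes a legacy VTK polyline for
#'   visualization, anything else the plain `x y z`-per-line format.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  stopifnot(is_contour3d(contour))
  v <- contour$vertices
  if (tolower(tools::file_ext(path)) == "vtk") {
    n <- nrow(v)
    idx <- c(seq_len(n) - 1L, if (contour$closed) 0L)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "shapeshared contour", "ASCII",
                 "DATASET POLYDATA", paste("POINTS", n, "double")), con)
    writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
    writeLines(paste("LINES 1", length(idx) + 1L), con)
    writeLines(paste(c(length(idx), idx), collapse = " "), con)
  } else {
    writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), path)
  }
  invisible(path)
}
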