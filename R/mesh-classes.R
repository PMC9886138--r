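#' Triangle surface mesh
#'
#' Constructs the basic surface representation used throughout the package:
#' a vertex matrix in millimetres and a face matrix of 1-based vertex index
#' triplets. Faces that repeat a vertex (topologically degenerate triangles)
#' are rejected.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates (mm).
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      stop("degenerate face: a face repeats a vertex")
  }
  if (anyNA(vertices)) stop("vertices contain NA")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Closed 3D contour (polyline)
#'
#' An ordered closed polyline in 3D, used for the exterior boundary of a
#' shared surface. Consecutive duplicate vertices are rejected; a closed
#' contour needs at least three vertices (the segment from the last vertex
#' back to the first is implied).
#'
#' @param vertices numeric matrix (n x 3), ordered along the curve (mm).
#' @param closed logical; shared-boundary contours are always closed.
#' @return an object of class `contour3d`.
#' @export
contour3d <- function(vertices, closed = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("contour vertices must have 3 columns")
  n <- nrow(vertices)
  if (closed && n < 3L) stop("a closed contour needs at least 3 vertices")
  if (n >= 2L) {
    seg <- vertices[-1L, , drop = FALSE] - vertices[-n, , drop = FALSE]
    if (any(rowSums(seg^2) == 0))
      stop("contour has zero-length segment (consecutive duplicate vertices)")
  }
  if (closed && n >= 2L && sum((vertices[n, ] - vertices[1L, ])^2) == 0)
    stop("closed contour must not repeat the first vertex at the end")
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, closed = isTRUE(closed)),
            class = "contour3d")
}

#' @export
print.contour3d <- function(x, ...) {
  cat(sprintf("contour3d: %d vertices (%s)\n", nrow(x$vertices),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

is_contour3d <- function(x) inherits(x, "contour3d")

# segment endpoints of a contour as two matrices (wraps around when closed)
contour_segments <- function(contour) {
  v <- contour$vertices
  n <- nrow(v)
  if (contour$closed) {
    list(a = v, b = v[c(seq_len(n)[-1L], 1L), , drop = FALSE])
  } else {
    list(a = v[-n, , drop = FALSE], b = v[-1L, , drop = FALSE])
  }
}

#' Total length of a contour polyline
#' @param contour a [contour3d()].
#' @return total arc length (mm).
#' @export
contour_length <- function(contour) {
  s <- contour_segments(contour)
  sum(sqrt(rowSums((s$b - s$a)^2)))
}

#' One subject's multi-organ sample
#'
#' Bundles the named domains of a single subject: organ meshes, optionally a
#' shared surface mesh, and optionally the shared-boundary contour. All
#' subjects in a cohort must carry the same domain names in the same order
#' for correspondence to be meaningful.
#'
#' @param subject_id character scalar.
#' @param domains named list of [triangle_mesh()] / [contour3d()] objects.
#' @param label optional group tag (e.g. `"control"` or `"pathology"`).
#' @return an object of class `multi_organ_sample`.
#' @export
multi_organ_sample <- function(subject_id, domains, label = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    stop("subject_id must be a single string")
  if (!is.list(domains) || is.null(names(domains)) ||
        any(names(domains) == "") || anyDuplicated(names(domains)))
    stop("domains must be a uniquely named list")
  ok <- vapply(domains, function(d) is_triangle_mesh(d) || is_contour3d(d),
               logical(1))
  if (!all(ok)) stop("each domain must be a triangle_mesh or contour3d")
  structure(list(subject_id = subject_id, domains = domains, label = label),
            class = "multi_organ_sample")
}

#' @export
print.multi_organ_sample <- function(x, ...) {
  kinds <- vapply(x$domains, function(d)
    if (is_contour3d(d)) "contour" else "mesh", character(1))
  cat(sprintf("multi_organ_sample '%s'%s: %s\n", x$subject_id,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              paste(names(x$domains), kinds, sep = ":", collapse = ", ")))
  invisible(x)
}

# --- small mesh helpers used across modules ---------------------------------

# undirected unique edges (columns: a < b)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Edge lengths of a mesh
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of unique-edge lengths (mm).
#' @export
edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                  mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Per-face triangle areas
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

#' Total surface area
#' @param mesh a [triangle_mesh()].
#' @return total area (mm^2).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

# bounding box of a coordinate matrix: list(lo, hi, center, diag)
bbox_of <- function(V) {
  lo <- apply(V, 2, min)
  hi <- apply(V, 2, max)
  list(lo = lo, hi = hi, center = (lo + hi) / 2,
       diag = sqrt(sum((hi - lo)^2)))
}

# all coordinates of a sample's domains stacked
sample_coords <- function(sample) {
  do.call(rbind, lapply(sample$domains, function(d) d$vertices))
}

# drop vertices not referenced by any face, remapping indices
compact_mesh <- function(V, F) {
  used <- sort(unique(as.vector(F)))
  map <- integer(nrow(V))
  map[used] <- seq_along(used)
  triangle_mesh(V[used, , drop = FALSE],
                matrix(map[F], ncol = 3L))
}

# occurrences of each undirected face edge; returns data frame-ish list with
# edge key per directed half-edge and the face it belongs to
half_edges <- function(F) {
  m <- nrow(F)
  a <- c(F[, 1], F[, 2], F[, 3])
  b <- c(F[, 2], F[, 3], F[, 1])
  list(a = a, b = b, face = rep.int(seq_len(m), 3L),
       key = paste(pmin(a, b), pmax(a, b)))
}
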