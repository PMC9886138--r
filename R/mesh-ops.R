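#' Distance from points to a triangle mesh
#'
#' Exact Euclidean distance from each query point to the closest point on
#' any triangle of the mesh (face interior, edge or vertex).
#'
#' @param points a length-3 vector or an n x 3 matrix of query points.
#' @param mesh a [triangle_mesh()] with at least one face.
#' @return numeric vector of distances (mm).
#' @export
point_mesh_distance <- function(points, mesh) {
  P <- as_point_matrix(points)
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  cpp_closest_on_mesh(P, mesh$vertices, mesh$faces)$dist
}

#' Closest point on a mesh surface
#'
#' @inheritParams point_mesh_distance
#' @return an object shaped like `points` containing the closest surface
#'   points, with attributes `dist` (distances) and `face` (face indices).
#' @export
closest_point_on_mesh <- function(points, mesh) {
  P <- as_point_matrix(points)
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  res <- cpp_closest_on_mesh(P, mesh$vertices, mesh$faces)
  out <- res$points
  if (is.null(dim(points))) out <- drop(out)
  attr(out, "dist") <- res$dist
  attr(out, "face") <- res$face
  out
}

#' Closest point on a contour polyline
#'
#' @param points a length-3 vector or an n x 3 matrix of query points.
#' @param contour a [contour3d()].
#' @return closest points on the contour segments, with attributes `dist`,
#'   `segment` and `t` (position along the segment in `[0, 1]`).
#' @export
closest_point_on_contour <- function(points, contour) {
  P <- as_point_matrix(points)
  s <- contour_segments(contour)
  res <- cpp_closest_on_segments(P, s$a, s$b)
  out <- res$points
  if (is.null(dim(points))) out <- drop(out)
  attr(out, "dist") <- res$dist
  attr(out, "segment") <- res$segment
  attr(out, "t") <- res$t
  out
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("a point must have 3 coordinates")
    matrix(points, 1L, 3L)
  } else {
    P <- as.matrix(points)
    if (ncol(P) != 3L) stop("points must have 3 columns")
    storage.mode(P) <- "double"
    P
  }
}

# vertex indices that lie on any boundary edge
boundary_vertices <- function(mesh) {
  he <- half_edges(mesh$faces)
  cnt <- table(he$key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(integer(0))
  idx <- he$key %in% bkey
  sort(unique(c(he$a[idx], he$b[idx])))
}

# boundary edges as a 2-column matrix (directed as they appear in faces)
boundary_edge_matrix <- function(mesh) {
  he <- half_edges(mesh$faces)
  cnt <- table(he$key)
  bkey <- names(cnt)[cnt == 1L]
  idx <- which(he$key %in% bkey)
  cbind(he$a[idx], he$b[idx])
}

#' All boundary loops of an open mesh
#'
#' A boundary edge is an edge incident to exactly one face. Boundary edges
#' are chained into closed loops; traversal follows the direction the edges
#' appear in their faces, so consecutive loop vertices always share a
#' boundary edge.
#'
#' @param mesh a [triangle_mesh()] with at least one boundary edge.
#' @return a list of closed [contour3d()] objects, longest (most vertices)
#'   first; each carries the vertex indices as attribute `indices`.
#' @export
boundary_loops <- function(mesh) {
  be <- boundary_edge_matrix(mesh)
  if (nrow(be) == 0L)
    stop("mesh is watertight: no boundary edge")
  nxt <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(be)))
    assign(as.character(be[i, 1]), be[i, 2], envir = nxt)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  loops <- list()
  for (i in seq_len(nrow(be))) {
    start <- be[i, 1]
    if (!is.null(visited[[as.character(start)]])) next
    loop <- integer(0)
    v <- start
    repeat {
      loop <- c(loop, v)
      assign(as.character(v), TRUE, envir = visited)
      nx <- nxt[[as.character(v)]]
      if (is.null(nx)) break   # non-manifold boundary; emit what we have
      v <- nx
      if (v == start) break
      if (!is.null(visited[[as.character(v)]])) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  if (length(loops) == 0L) stop("no closed boundary loop found")
  loops <- loops[order(-lengths(loops))]
  lapply(loops, function(idx) {
    ct <- contour3d(mesh$vertices[idx, , drop = FALSE], closed = TRUE)
    attr(ct, "indices") <- idx
    ct
  })
}

#' Longest boundary loop of an open mesh
#'
#' @inheritParams boundary_loops
#' @return the loop with the most vertices, as a closed [contour3d()].
#' @export
boundary_loop <- function(mesh) {
  boundary_loops(mesh)[[1L]]
}

#' Laplacian mesh smoothing
#'
#' Classical uniform (combinatorial) Laplacian smoothing: each interior
#' vertex moves toward the average of its 1-ring neighbours by the fraction
#' `relaxation` per iteration. Boundary-loop vertices are held fixed by
#' default so that a snapped shared-surface opening is not destroyed.
#' Topology is unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of smoothing passes (default 30).
#' @param relaxation step fraction in `(0, 1]` (default 1).
#' @param fix_boundary keep boundary vertices fixed (default `TRUE`).
#' @return the smoothed [triangle_mesh()].
#' @export
laplacian_smooth <- function(mesh, iterations = 30L, relaxation = 1.0,
                             fix_boundary = TRUE) {
  stopifnot(is_triangle_mesh(mesh))
  if (iterations < 0L) stop("iterations must be >= 0")
  if (relaxation <= 0 || relaxation > 1) stop("relaxation must be in (0, 1]")
  if (iterations == 0L) return(mesh)
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  free <- rep(TRUE, n)
  if (fix_boundary) free[boundary_vertices(mesh)] <- FALSE
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    avg <- as.matrix(A %*% V) / deg
    V[free, ] <- V[free, , drop = FALSE] +
      relaxation * (avg[free, , drop = FALSE] - V[free, , drop = FALSE])
  }
  triangle_mesh(V, mesh$faces)
}

#' Isotropic explicit remeshing
#'
#' Re-triangulates a surface toward a uniform target edge length using the
#' standard split-long / collapse-short / flip-for-valence / tangential-relax
#' cycle, re-projecting relaxed vertices onto the input surface each
#' iteration so the output conforms to the input geometry. Boundary vertices
#' stay on the boundary polyline (boundary edges may be split at their
#' midpoints but are never collapsed or relaxed).
#'
#' @param mesh a [triangle_mesh()].
#' @param target_edge_length desired edge length (mm); `NULL` keeps the
#'   current mean edge length (pure uniformization).
#' @param iterations outer iterations of the remeshing cycle (default 10).
#' @param max_vertices resource cap; an error is raised when the target
#'   implies more vertices than this (default `2e5`).
#' @return the remeshed [triangle_mesh()].
#' @export
isotropic_remesh <- function(mesh, target_edge_length = NULL,
                             iterations = 10L, max_vertices = 2e5) {
  stopifnot(is_triangle_mesh(mesh), nrow(mesh$faces) > 0L)
  L <- if (is.null(target_edge_length)) mean(edge_lengths(mesh))
       else target_edge_length
  if (L <= 0) stop("target_edge_length must be > 0")
  est <- mesh_area(mesh) / (sqrt(3) / 4 * L^2)
  if (est > max_vertices)
    stop(sprintf(paste("target edge length %.3g implies ~%.0f vertices,",
                       "above the cap of %.0f"), L, est, max_vertices))
  ref <- mesh   # projection target: the input surface
  V <- mesh$vertices
  F <- mesh$faces
  hi <- 4 / 3 * L
  lo <- 4 / 5 * L
  for (it in seq_len(iterations)) {
    sp <- remesh_split(V, F, hi, max_vertices)
    V <- sp$V; F <- sp$F
    co <- remesh_collapse(V, F, lo, hi)
    V <- co$V; F <- co$F
    fl <- remesh_flip(V, F)
    F <- fl$F
    rx <- remesh_relax(V, F, ref)
    V <- rx
  }
  compact_mesh(V, F)
}

# split every edge longer than `hi`; edges are processed in face-disjoint
# batches so the bulk face replacement is well defined
remesh_split <- function(V, F, hi, max_vertices) {
  for (round in 1:20) {
    he <- half_edges(F)
    ord <- !duplicated(he$key)
    ea <- he$a[ord]; eb <- he$b[ord]; ekey <- he$key[ord]
    len <- sqrt(rowSums((V[ea, , drop = FALSE] - V[eb, , drop = FALSE])^2))
    long <- which(len > hi)
    if (length(long) == 0L) break
    long <- long[order(-len[long])]
    efaces <- split(he$face, he$key)
    used_face <- logical(nrow(F))
    sel <- integer(0)
    for (e in long) {
      fs <- efaces[[ekey[e]]]
      if (any(used_face[fs])) next
      used_face[fs] <- TRUE
      sel <- c(sel, e)
    }
    if (length(sel) == 0L) break
    if (nrow(V) + length(sel) > max_vertices)
      stop("vertex budget exceeded during remeshing")
    mid <- (V[ea[sel], , drop = FALSE] + V[eb[sel], , drop = FALSE]) / 2
    newidx <- nrow(V) + seq_along(sel)
    V <- rbind(V, mid)
    drop_faces <- logical(nrow(F))
    newF <- list()
    for (k in seq_along(sel)) {
      e <- sel[k]
      m <- newidx[k]
      for (f in efaces[[ekey[e]]]) {
        tri <- F[f, ]
        # locate the directed occurrence of the edge within this face
        for (c1 in 1:3) {
          c2 <- if (c1 == 3L) 1L else c1 + 1L
          p <- tri[c1]; q <- tri[c2]
          if ((p == ea[e] && q == eb[e]) || (p == eb[e] && q == ea[e])) {
            r <- tri[setdiff(1:3, c(c1, c2))]
            newF[[length(newF) + 1L]] <- c(p, m, r)
            newF[[length(newF) + 1L]] <- c(m, q, r)
            drop_faces[f] <- TRUE
            break
          }
        }
      }
    }
    F <- rbind(F[!drop_faces, , drop = FALSE], do.call(rbind, newF))
    storage.mode(F) <- "integer"
  }
  list(V = V, F = F)
}

# collapse interior edges shorter than `lo` to their midpoints, skipping
# collapses that violate the link condition, touch the boundary, or would
# create an edge longer than `hi`
remesh_collapse <- function(V, F, lo, hi) {
  he <- half_edges(F)
  cnt <- table(he$key)
  bkey <- names(cnt)[cnt == 1L]
  bvert <- unique(c(he$a[he$key %in% bkey], he$b[he$key %in% bkey]))
  ord <- !duplicated(he$key)
  ea <- he$a[ord]; eb <- he$b[ord]
  len <- sqrt(rowSums((V[ea, , drop = FALSE] - V[eb, , drop = FALSE])^2))
  cand <- which(len < lo & !(ea %in% bvert) & !(eb %in% bvert))
  if (length(cand) == 0L) return(list(V = V, F = F))
  cand <- cand[order(len[cand])]
  # adjacency for link condition and length guard
  nbr <- adjacency_list(F, nrow(V))
  touched <- logical(nrow(V))
  vmap <- seq_len(nrow(V))
  for (e in cand) {
    a <- ea[e]; b <- eb[e]
    if (touched[a] || touched[b]) next
    na <- nbr[[a]]; nb <- nbr[[b]]
    if (length(intersect(na, nb)) != 2L) next   # link condition
    mid <- (V[a, ] + V[b, ]) / 2
    ring <- setdiff(union(na, nb), c(a, b))
    d <- sqrt(rowSums((V[ring, , drop = FALSE] -
                         matrix(mid, length(ring), 3L, byrow = TRUE))^2))
    if (any(d > hi)) next
    V[a, ] <- mid
    vmap[b] <- a
    touched[c(a, b, ring)] <- TRUE
  }
  F2 <- matrix(vmap[F], ncol = 3L)
  degen <- F2[, 1] == F2[, 2] | F2[, 2] == F2[, 3] | F2[, 1] == F2[, 3]
  storage.mode(F2) <- "integer"
  list(V = V, F = F2[!degen, , drop = FALSE])
}

adjacency_list <- function(F, n) {
  e <- rbind(F[, c(1, 2), drop = FALSE], F[, c(2, 3), drop = FALSE],
             F[, c(3, 1), drop = FALSE])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  lst <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  out <- vector("list", n)
  out[as.integer(names(lst))] <- lapply(lst, unique)
  out
}

# flip interior edges when doing so reduces squared valence deviation
# (target valence 6 interior, 4 on the boundary); candidates are found
# vectorized, then applied greedily on face-disjoint edges
remesh_flip <- function(V, F) {
  nv <- nrow(V)
  nf <- nrow(F)
  a0 <- c(F[, 1], F[, 2], F[, 3])
  b0 <- c(F[, 2], F[, 3], F[, 1])
  face <- rep.int(seq_len(nf), 3L)
  lo <- pmin(a0, b0)
  hi <- pmax(a0, b0)
  key <- (lo - 1) * nv + hi          # numeric undirected-edge key
  o <- order(key)
  ks <- key[o]
  fo <- face[o]
  start <- which(!duplicated(ks))
  mult <- diff(c(start, length(ks) + 1L))
  bidx <- start[mult == 1L]
  bvert <- unique(c(lo[o][bidx], hi[o][bidx]))
  val <- tabulate(F, nbins = nv)
  target <- rep(6L, nv)
  target[bvert] <- 4L
  ii <- start[mult == 2L]            # interior edges
  if (length(ii) == 0L) return(list(F = F))
  a <- lo[o][ii]
  b <- hi[o][ii]
  f1 <- fo[ii]
  f2 <- fo[ii + 1L]
  fsum <- F[, 1] + F[, 2] + F[, 3]
  c1 <- fsum[f1] - a - b             # opposite vertices
  c2 <- fsum[f2] - a - b
  ok <- c1 != c2 & c1 >= 1L & c2 >= 1L
  # would-be edge must not already exist
  newkey <- (pmin(c1, c2) - 1) * nv + pmax(c1, c2)
  exists_edge <- !is.na(match(newkey, ks))
  dev <- function(v, vl) (vl - target[v])^2
  before <- dev(a, val[a]) + dev(b, val[b]) + dev(c1, val[c1]) +
    dev(c2, val[c2])
  after <- dev(a, val[a] - 1L) + dev(b, val[b] - 1L) +
    dev(c1, val[c1] + 1L) + dev(c2, val[c2] + 1L)
  cand <- which(ok & !exists_edge & after < before)
  if (length(cand) == 0L) return(list(F = F))
  cand <- cand[order(after[cand] - before[cand])]
  used_face <- logical(nf)
  created <- new.env(hash = TRUE, parent = emptyenv())
  for (e in cand) {
    fa <- f1[e]; fb <- f2[e]
    if (used_face[fa] || used_face[fb]) next
    # valences drift as flips are applied; re-check the benefit
    vb <- dev(a[e], val[a[e]]) + dev(b[e], val[b[e]]) +
      dev(c1[e], val[c1[e]]) + dev(c2[e], val[c2[e]])
    va <- dev(a[e], val[a[e]] - 1L) + dev(b[e], val[b[e]] - 1L) +
      dev(c1[e], val[c1[e]] + 1L) + dev(c2[e], val[c2[e]] + 1L)
    if (va >= vb) next
    if (!is.null(created[[as.character(newkey[e])]])) next
    tri <- F[fa, ]
    p <- NA_integer_
    for (k in 1:3) {
      k2 <- if (k == 3L) 1L else k + 1L
      if ((tri[k] == a[e] && tri[k2] == b[e]) ||
            (tri[k] == b[e] && tri[k2] == a[e])) {
        p <- tri[k]; q <- tri[k2]
        break
      }
    }
    if (is.na(p)) next
    r1 <- c1[e]
    r2 <- c2[e]
    F[fa, ] <- c(p, r2, r1)
    F[fb, ] <- c(r2, q, r1)
    val[c(a[e], b[e])] <- val[c(a[e], b[e])] - 1L
    val[c(r1, r2)] <- val[c(r1, r2)] + 1L
    used_face[c(fa, fb)] <- TRUE
    assign(as.character(newkey[e]), TRUE, envir = created)
  }
  storage.mode(F) <- "integer"
  list(F = F)
}

# move interior vertices to the centroid of their 1-ring, then project back
# onto the reference (input) surface
remesh_relax <- function(V, F, ref) {
  n <- nrow(V)
  e <- rbind(F[, c(1, 2), drop = FALSE], F[, c(2, 3), drop = FALSE],
             F[, c(3, 1), drop = FALSE])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  he <- half_edges(F)
  cnt <- table(he$key)
  bkey <- names(cnt)[cnt == 1L]
  bvert <- unique(c(he$a[he$key %in% bkey], he$b[he$key %in% bkey]))
  free <- setdiff(which(deg > 0), bvert)
  if (length(free) == 0L) return(V)
  avg <- as.matrix(A %*% V) / deg
  moved <- avg[free, , drop = FALSE]
  proj <- cpp_closest_on_mesh(moved, ref$vertices, ref$faces)
  V[free, ] <- proj$points
  V
}
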