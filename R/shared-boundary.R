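#' Configuration for shared-boundary extraction
#'
#' @param threshold vertex-to-mesh distance cutoff (mm) deciding which
#'   triangles belong to the shared patch; `NULL` (default) uses half the
#'   remeshing target edge length, which scales with resolution and is
#'   always sub-edge for coincident surfaces.
#' @param remesh_target_edge target edge length for the isotropic remeshing
#'   step, or `"auto"` (mean edge length of the two input meshes).
#' @param remesh_iterations remeshing cycles (default 10).
#' @param smooth_iterations Laplacian smoothing passes applied to the three
#'   output meshes (default 30).
#' @param smooth_relaxation smoothing step fraction in `(0, 1]` (default 1).
#' @param min_component_area_frac connected components of the candidate
#'   shared patch smaller than this fraction of its total area are dropped
#'   as extraction specks (default 0.01).
#' @return a list of class `extraction_config`.
#' @export
extraction_config <- function(threshold = NULL, remesh_target_edge = "auto",
                              remesh_iterations = 10L,
                              smooth_iterations = 30L,
                              smooth_relaxation = 1.0,
                              min_component_area_frac = 0.01) {
  if (!is.null(threshold) && threshold <= 0) stop("threshold must be > 0")
  if (smooth_relaxation <= 0 || smooth_relaxation > 1)
    stop("smooth_relaxation must be in (0, 1]")
  structure(list(threshold = threshold,
                 remesh_target_edge = remesh_target_edge,
                 remesh_iterations = as.integer(remesh_iterations),
                 smooth_iterations = as.integer(smooth_iterations),
                 smooth_relaxation = smooth_relaxation,
                 min_component_area_frac = min_component_area_frac),
            class = "extraction_config")
}

#' Faces of one mesh close to another mesh
#'
#' A triangle is "close" to the other mesh iff all three of its vertices lie
#' within `threshold` of that mesh (vertices exactly at the threshold are
#' excluded). Triangles with only one or two close vertices straddle the
#' cutoff and are excluded.
#'
#' @param source,other [triangle_mesh()] objects.
#' @param threshold distance cutoff (mm).
#' @return integer vector of face indices of `source` (possibly empty).
#' @export
find_close_triangles <- function(source, other, threshold) {
  stopifnot(is_triangle_mesh(source), is_triangle_mesh(other), threshold > 0)
  vd <- point_mesh_distance(source$vertices, other)
  close_v <- vd < threshold
  f <- source$faces
  which(close_v[f[, 1]] & close_v[f[, 2]] & close_v[f[, 3]])
}

# keep only face components carrying at least `frac` of the candidate area
filter_small_components <- function(mesh, face_idx, frac) {
  if (length(face_idx) == 0L) return(face_idx)
  sub <- mesh$faces[face_idx, , drop = FALSE]
  he <- half_edges(sub)
  shared <- split(he$face, he$key)
  shared <- shared[lengths(shared) >= 2L]
  if (length(shared) > 0L) {
    edges <- do.call(rbind, lapply(shared, function(fs)
      cbind(fs[1], fs[-1])))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(face_idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(face_idx)
  }
  areas <- face_areas(mesh)[face_idx]
  comp_area <- tapply(areas, comp, sum)
  keep_comp <- as.integer(names(comp_area)[comp_area >= frac * sum(areas)])
  face_idx[comp %in% keep_comp]
}

#' Extract the shared boundary surface from a pair of adjoining meshes
#'
#' Implements the core detection step: the faces of `A_o` close to `B_o`
#' form `A_s`, the faces of `B_o` close to `A_o` form `B_s`; as surfaces
#' these coincide, and `B_s` is (arbitrarily) designated the shared surface
#' `M`. The remainders `A_r` and `B_r` are the inputs minus their close
#' faces. Each boundary vertex of `M` is then snapped to the closest point
#' on the boundary polyline of `A_r` (segment projection, so the two
#' openings coincide geometrically without requiring equal vertex counts).
#'
#' @param A_o,B_o re-meshed adjoining organ meshes.
#' @param config an [extraction_config()]; `config$threshold` must be set
#'   (the [extract_shared_boundary()] pipeline resolves the `"auto"` value).
#' @return list with [triangle_mesh()] elements `A_r`, `M`, `B_r`, plus a
#'   `report` list (face counts, areas, threshold).
#' @export
extract_shared_surface <- function(A_o, B_o, config = extraction_config()) {
  thr <- config$threshold
  if (is.null(thr)) stop("config$threshold must be resolved to a number")
  As_idx <- find_close_triangles(A_o, B_o, thr)
  Bs_idx <- find_close_triangles(B_o, A_o, thr)
  if (length(As_idx) == 0L || length(Bs_idx) == 0L)
    stop("no shared boundary at this threshold")
  As_idx <- filter_small_components(A_o, As_idx, config$min_component_area_frac)
  Bs_idx <- filter_small_components(B_o, Bs_idx, config$min_component_area_frac)
  if (length(As_idx) == 0L || length(Bs_idx) == 0L)
    stop("no shared boundary at this threshold")

  Ar_faces <- setdiff(seq_len(nrow(A_o$faces)), As_idx)
  Br_faces <- setdiff(seq_len(nrow(B_o$faces)), Bs_idx)
  if (length(Ar_faces) == 0L || length(Br_faces) == 0L)
    stop("threshold so large that an entire organ was classified as shared")
  A_r <- compact_mesh(A_o$vertices, A_o$faces[Ar_faces, , drop = FALSE])
  B_r <- compact_mesh(B_o$vertices, B_o$faces[Br_faces, , drop = FALSE])
  M <- compact_mesh(B_o$vertices, B_o$faces[Bs_idx, , drop = FALSE])

  # snap the opening of M onto the boundary polyline of A_r
  mb <- tryCatch(boundary_vertices(M), error = function(e) integer(0))
  if (length(mb) == 0L)
    stop("shared surface has no boundary loop (topology error)")
  ab_edges <- boundary_edge_matrix(A_r)
  if (nrow(ab_edges) > 0L) {
    seg_a <- A_r$vertices[ab_edges[, 1], , drop = FALSE]
    seg_b <- A_r$vertices[ab_edges[, 2], , drop = FALSE]
    snapped <- cpp_closest_on_segments(M$vertices[mb, , drop = FALSE],
                                       seg_a, seg_b)
    Vm <- M$vertices
    Vm[mb, ] <- snapped$points
    M <- triangle_mesh(Vm, M$faces)
  } else {
    warning("A_r has no boundary; skipping boundary snap of M")
  }
  report <- list(threshold = thr,
                 n_faces = c(A_r = nrow(A_r$faces), M = nrow(M$faces),
                             B_r = nrow(B_r$faces)),
                 area = c(A_s = sum(face_areas(A_o)[As_idx]),
                          M = mesh_area(M), A_r = mesh_area(A_r),
                          B_r = mesh_area(B_r)))
  list(A_r = A_r, M = M, B_r = B_r, report = report)
}

#' Full shared-boundary extraction pipeline
#'
#' Runs the four extraction steps on a pair of adjoining meshes: isotropic
#' remeshing of both inputs, shared-surface extraction at the distance
#' threshold, Laplacian smoothing of the three outputs with boundary
#' vertices held fixed, and boundary-loop extraction of the shared surface
#' to obtain the contour. The result is the four-part input the
#' shared-boundary particle optimizer expects, in fixed domain order
#' `A_r, M, B_r, C`.
#'
#' @param A_o,B_o the two adjoining organ meshes.
#' @param config an [extraction_config()].
#' @param subject_id id stored in the returned sample.
#' @param label optional group tag.
#' @return a [multi_organ_sample()] with domains `A_r`, `M`, `B_r` (meshes)
#'   and `C` (closed contour); the extraction report is attached as
#'   attribute `report`.
#' @export
extract_shared_boundary <- function(A_o, B_o, config = extraction_config(),
                                    subject_id = "sample", label = NULL) {
  target <- config$remesh_target_edge
  if (identical(target, "auto"))
    target <- mean(c(edge_lengths(A_o), edge_lengths(B_o)))
  A_m <- isotropic_remesh(A_o, target, config$remesh_iterations)
  B_m <- isotropic_remesh(B_o, target, config$remesh_iterations)
  cfg <- config
  if (is.null(cfg$threshold)) cfg$threshold <- 0.5 * target
  ext <- extract_shared_surface(A_m, B_m, cfg)
  sm <- function(m) laplacian_smooth(m, cfg$smooth_iterations,
                                     cfg$smooth_relaxation,
                                     fix_boundary = TRUE)
  A_r <- sm(ext$A_r)
  M <- sm(ext$M)
  B_r <- sm(ext$B_r)
  C <- boundary_loop(M)
  out <- multi_organ_sample(subject_id,
                            list(A_r = A_r, M = M, B_r = B_r, C = C),
                            label = label)
  attr(out, "report") <- c(ext$report, list(remesh_target_edge = target))
  out
}

#' Run shared-boundary extraction over a whole cohort
#'
#' @param cohort output of [generate_peanut_cohort()] or a list of two-mesh
#'   [multi_organ_sample()] objects (first domain = A, second = B).
#' @param config an [extraction_config()].
#' @param verbose print one line per subject.
#' @return list of extracted four-domain samples.
#' @export
extract_cohort <- function(cohort, config = extraction_config(),
                           verbose = FALSE) {
  samples <- if (!is.null(cohort$samples)) cohort$samples else cohort
  lapply(samples, function(s) {
    if (verbose) message("extracting ", s$subject_id)
    extract_shared_boundary(s$domains[[1]], s$domains[[2]], config,
                            subject_id = s$subject_id, label = s$label)
  })
}
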