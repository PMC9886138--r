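#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix with determinant +1.
#' @param translation length-3 translation vector (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
        max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be a proper orthonormal matrix (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform
#'
#' Maps `x` to `R x + t`. Works on coordinate matrices, meshes, contours and
#' whole multi-organ samples (every domain receives the same map, so all
#' intra-subject pairwise distances are preserved).
#'
#' @param x a point matrix, [triangle_mesh()], [contour3d()] or
#'   [multi_organ_sample()].
#' @param transform a [rigid_transform()].
#' @return the transformed object.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  tf_coords <- function(V)
    sweep(V %*% t(transform$rotation), 2, transform$translation, "+")
  if (is_triangle_mesh(x)) {
    triangle_mesh(tf_coords(x$vertices), x$faces)
  } else if (is_contour3d(x)) {
    contour3d(tf_coords(x$vertices), x$closed)
  } else if (inherits(x, "multi_organ_sample")) {
    x$domains <- lapply(x$domains, apply_transform, transform = transform)
    x
  } else {
    tf_coords(as_point_matrix(x))
  }
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

# closed-form least-squares rigid fit mapping P onto Q (Kabsch / SVD of the
# cross-covariance), deterministic
kabsch_fit <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, qc - as.numeric(R %*% pc))
}

#' Area-weighted random points on a mesh surface
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of samples (default 1000).
#' @param seed RNG seed (fixed default so clouds of different meshes built
#'   from a common template stay directionally comparable).
#' @return an n x 3 matrix of surface points.
#' @export
sample_surface_points <- function(mesh, n = 1000L, seed = 1L) {
  with_preserved_seed({
    set.seed(seed)
    ar <- face_areas(mesh)
    f <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = ar)
    u <- stats::runif(n)
    v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    a <- mesh$vertices[mesh$faces[f, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[f, 2], , drop = FALSE]
    c3 <- mesh$vertices[mesh$faces[f, 3], , drop = FALSE]
    a + u * (b - a) + v * (c3 - a)
  })
}

# symmetric Chamfer distance between two point clouds
chamfer_distance <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

#' Medoid reference selection
#'
#' Computes a vertex-count-free mean shape as the pointwise average of
#' per-sample surface point clouds (fixed-seed area-weighted resampling to a
#' common count) and returns the index of the sample whose cloud is closest
#' to that mean under the symmetric Chamfer distance. Ties break to the
#' lowest index.
#'
#' @param meshes list of [triangle_mesh()] objects.
#' @param n_points resampling count (default 1000).
#' @return integer index of the medoid sample.
#' @export
select_reference <- function(meshes, n_points = 1000L) {
  if (length(meshes) == 0L) stop("empty mesh list")
  clouds <- lapply(meshes, sample_surface_points, n = n_points)
  mean_cloud <- Reduce(`+`, clouds) / length(clouds)
  d <- vapply(clouds, chamfer_distance, numeric(1), Y = mean_cloud)
  which.min(d)
}

#' Rigid iterative-closest-point registration
#'
#' Alternates closest-point matching (vertices of `moving` onto the surface
#' of `fixed`) with the closed-form least-squares rigid fit until the mean
#' residual changes by less than `tol` or the iteration cap is reached.
#'
#' @param moving,fixed [triangle_mesh()] objects.
#' @param max_iterations iteration cap (default 50).
#' @param tol convergence tolerance on the mean residual change (mm).
#' @return a [rigid_transform()] mapping `moving` onto `fixed`; attribute
#'   `converged` is `FALSE` (with a warning) if the cap was hit first,
#'   attribute `residual` is the final mean residual.
#' @export
icp_rigid <- function(moving, fixed, max_iterations = 100L, tol = 1e-6) {
  P0 <- moving$vertices
  tf <- rigid_transform()
  prev <- Inf
  converged <- FALSE
  res <- NA_real_
  for (it in seq_len(max_iterations)) {
    X <- apply_transform(P0, tf)
    Q <- cpp_closest_on_mesh(X, fixed$vertices, fixed$faces)
    res <- mean(Q$dist)
    # absolute tolerance plus a relative floor: on coarse meshes the
    # vertex-to-surface residual plateaus at mesh-resolution scale
    if (abs(prev - res) < tol + 1e-6 * res) {
      converged <- TRUE
      break
    }
    prev <- res
    tf <- kabsch_fit(P0, Q$points)
  }
  if (!converged)
    warning("ICP hit the iteration cap without meeting tol; returning best fit")
  attr(tf, "converged") <- converged
  attr(tf, "residual") <- res
  tf
}

#' Rigidly align a cohort to a medoid reference
#'
#' Centres every sample (combined bounding-box centre to the origin),
#' selects the medoid of the reference domain, registers each subject's
#' reference-domain mesh to the medoid's with rigid ICP, and applies each
#' subject's single transform to all of that subject's domains (meshes and
#' contours alike), so intra-subject geometry is untouched.
#'
#' @param samples list of [multi_organ_sample()] objects.
#' @param reference_domain name of the surface-mesh domain driving the
#'   registration (transforms are computed on it only).
#' @param ... passed to [icp_rigid()].
#' @return list with `samples` (aligned), `transforms` (per subject, the
#'   total [rigid_transform()] incl. centering) and `reference` (medoid
#'   index).
#' @export
align_cohort <- function(samples, reference_domain, ...) {
  if (length(samples) == 0L) stop("empty cohort")
  ok <- vapply(samples, function(s)
    reference_domain %in% names(s$domains) &&
      is_triangle_mesh(s$domains[[reference_domain]]), logical(1))
  if (!all(ok))
    stop("every sample must contain surface-mesh domain '",
         reference_domain, "'")
  centred <- lapply(samples, function(s) {
    ctr <- bbox_of(sample_coords(s))$center
    tf <- rigid_transform(diag(3), -ctr)
    list(sample = apply_transform(s, tf), tf = tf)
  })
  ref_meshes <- lapply(centred, function(x)
    x$sample$domains[[reference_domain]])
  medoid <- select_reference(ref_meshes)
  out <- vector("list", length(samples))
  tfs <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    icp <- if (i == medoid) rigid_transform()
           else icp_rigid(ref_meshes[[i]], ref_meshes[[medoid]], ...)
    attributes(icp)[c("converged", "residual")] <- NULL
    out[[i]] <- apply_transform(centred[[i]]$sample, icp)
    tfs[[i]] <- compose_transforms(icp, centred[[i]]$tf)
  }
  names(tfs) <- vapply(samples, `[[`, character(1), "subject_id")
  list(samples = out, transforms = tfs, reference = medoid)
}
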