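#' Parameters of the synthetic peanut cohort
#'
#' The peanut test bed emulates a two-organ anatomy with a shared boundary:
#' each sample is built from two intersecting spheres centred at
#' `+/- center_offset/2` on the x-axis, with one sphere subtracted from the
#' other, so the two surface meshes share a coincident spherical-cap patch.
#' The two radii vary inversely under the constraint `r1 + r2 = radius_sum`,
#' which keeps the intersection condition satisfied over the whole `r1_range`.
#' Pathology samples replace the second sphere by an ellipsoid whose y and z
#' semi-axes are shrunk by factors drawn from `ellipsoid_yz_scale_range`.
#'
#' @param n_controls,n_pathology group sizes (defaults 15 and 15).
#' @param center_offset distance between the two centres (default 1).
#' @param radius_sum inverse-variation constraint `r1 + r2` (default 2).
#' @param r1_range interval over which `r1` is evenly spaced per group.
#' @param ellipsoid_yz_scale_range interval for the pathology y/z shrink
#'   factors (drawn uniformly, independently for y and z).
#' @param mesh_resolution icosphere subdivision level (default 4, 5120 faces).
#' @param seed RNG seed for the ellipsoid scale draws.
#' @return a list of class `peanut_params`.
#' @export
peanut_params <- function(n_controls = 15L, n_pathology = 15L,
                          center_offset = 1.0, radius_sum = 2.0,
                          r1_range = c(0.8, 1.2),
                          ellipsoid_yz_scale_range = c(0.6, 0.9),
                          mesh_resolution = 4L, seed = 1L) {
  if (n_controls < 1L || n_pathology < 1L)
    stop("n_controls and n_pathology must be >= 1")
  r1 <- range(r1_range)
  r2 <- radius_sum - r1
  if (any(abs(r1 - r2) >= center_offset) || any(center_offset >= r1 + r2))
    stop("radius range violates the sphere intersection condition")
  structure(list(n_controls = as.integer(n_controls),
                 n_pathology = as.integer(n_pathology),
                 center_offset = center_offset, radius_sum = radius_sum,
                 r1_range = sort(r1_range),
                 ellipsoid_yz_scale_range = sort(ellipsoid_yz_scale_range),
                 mesh_resolution = as.integer(mesh_resolution),
                 seed = as.integer(seed)),
            class = "peanut_params")
}

#' Subdivided icosahedron sphere mesh
#'
#' @param subdivisions number of 1-to-4 subdivision rounds.
#' @param radius sphere radius.
#' @param center length-3 centre.
#' @return a closed [triangle_mesh()] with `20 * 4^subdivisions` faces.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1.0, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    # one shared midpoint vertex per unique undirected edge
    ea <- c(F[, 1], F[, 2], F[, 3])
    eb <- c(F[, 2], F[, 3], F[, 1])
    key <- paste(pmin(ea, eb), pmax(ea, eb))
    ukey <- unique(key)
    eid <- match(key, ukey)
    first <- match(ukey, key)
    mids <- (V[ea[first], , drop = FALSE] + V[eb[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    midx <- nrow(V) + seq_along(ukey)
    nf <- nrow(F)
    ab <- midx[eid[seq_len(nf)]]
    bc <- midx[eid[nf + seq_len(nf)]]
    ca <- midx[eid[2L * nf + seq_len(nf)]]
    V <- rbind(V, mids)
    F <- rbind(cbind(F[, 1], ab, ca), cbind(F[, 2], bc, ab),
               cbind(F[, 3], ca, bc), cbind(ab, bc, ca))
  }
  V <- V * radius
  V <- sweep(V, 2, center, "+")
  triangle_mesh(V, F)
}

# quadric implicit f(p) = p'Ap + b'p + c (A diagonal), negative inside
quadric_sphere <- function(center, radius) {
  list(A = c(1, 1, 1), b = -2 * center, c = sum(center^2) - radius^2)
}

quadric_ellipsoid <- function(center, semi_axes) {
  iA <- 1 / semi_axes^2
  list(A = iA, b = -2 * center * iA, c = sum(center^2 * iA) - 1)
}

quadric_eval <- function(q, P) {
  P[, 1]^2 * q$A[1] + P[, 2]^2 * q$A[2] + P[, 3]^2 * q$A[3] +
    P %*% q$b + q$c
}

# exact root of the quadric along segment v0 -> v1 (signs of f differ)
quadric_edge_root <- function(q, v0, v1) {
  d <- v1 - v0
  a <- sum(d^2 * q$A)
  b <- 2 * sum(v0 * d * q$A) + sum(q$b * d)
  c0 <- sum(v0^2 * q$A) + sum(q$b * v0) + q$c
  if (abs(a) < 1e-14) {
    t <- -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    disc <- max(disc, 0)
    r1 <- (-b - sqrt(disc)) / (2 * a)
    r2 <- (-b + sqrt(disc)) / (2 * a)
    inr <- c(r1, r2)[c(r1, r2) >= -1e-12 & c(r1, r2) <= 1 + 1e-12]
    t <- if (length(inr) >= 1L) inr[1] else -c0 / b
  }
  min(max(t, 0), 1)
}

# clip a mesh against a quadric, keeping the side where sign(f) == keep_sign;
# straddling triangles are split exactly at the implicit surface
clip_mesh_by_quadric <- function(mesh, q, keep_sign = -1) {
  V <- mesh$vertices
  F <- mesh$faces
  f <- as.numeric(quadric_eval(q, V)) * keep_sign   # kept side now positive
  inside <- f > 0
  nin <- inside[F[, 1]] + inside[F[, 2]] + inside[F[, 3]]
  keepF <- F[nin == 3L, , drop = FALSE]
  crossF <- F[nin == 1L | nin == 2L, , drop = FALSE]
  newV <- list()
  newF <- list()
  cutcache <- new.env(hash = TRUE, parent = emptyenv())
  nV <- nrow(V)
  cut_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- cutcache[[key]]
    if (!is.null(hit)) return(hit)
    t <- quadric_edge_root(q, V[i, ], V[j, ])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    newV[[length(newV) + 1L]] <<- p
    idx <- nV + length(newV)
    assign(key, idx, envir = cutcache)
    idx
  }
  if (nrow(crossF) > 0L) {
    for (r in seq_len(nrow(crossF))) {
      tri <- crossF[r, ]
      ins <- inside[tri]
      # rotate so the pattern starts at position 1
      if (sum(ins) == 1L) {
        k <- which(ins)
        ord <- ((k - 1L) + 0:2) %% 3L + 1L
        a <- tri[ord[1]]; b <- tri[ord[2]]; c3 <- tri[ord[3]]
        pab <- cut_point(a, b)
        pca <- cut_point(c3, a)
        newF[[length(newF) + 1L]] <- c(a, pab, pca)
      } else {
        k <- which(!ins)
        ord <- ((k - 1L) + 0:2) %% 3L + 1L
        c3 <- tri[ord[1]]; a <- tri[ord[2]]; b <- tri[ord[3]]
        # a, b kept; c3 dropped
        pbc <- cut_point(b, c3)
        pca <- cut_point(c3, a)
        newF[[length(newF) + 1L]] <- c(a, b, pbc)
        newF[[length(newF) + 1L]] <- c(a, pbc, pca)
      }
    }
  }
  Vout <- rbind(V, do.call(rbind, newV))
  Fout <- rbind(keepF, do.call(rbind, lapply(newF, rbind)))
  if (is.null(Fout) || nrow(Fout) == 0L)
    stop("clipping removed the entire mesh")
  storage.mode(Fout) <- "integer"
  compact_mesh(Vout, Fout)
}

#' Build one peanut sample (pair of adjoining meshes)
#'
#' Mesh `B` is the closed surface of the second shape (sphere or ellipsoid,
#' centred at `+center_offset/2`). Mesh `A` is the boundary of the first ball
#' minus the second solid: the part of sphere 1 outside solid 2, together
#' with the part of shape 2's surface inside ball 1. `A` and `B` therefore
#' carry a coincident surface patch (the cap of shape 2 inside ball 1),
#' which is what shared-boundary extraction later recovers. Geometry is
#' built by analytic clipping of subdivided icospheres at the intersection
#' surface, not by boolean mesh operations, so the shared patches coincide
#' exactly. The composite is translated so its joint bounding-box centre is
#' the origin.
#'
#' @param r1 radius of the first sphere.
#' @param shape2_semi_axes length-3 semi-axes of the second shape (a sphere
#'   when all equal).
#' @param center_offset distance between the two centres along x.
#' @param resolution icosphere subdivision level.
#' @return list with [triangle_mesh()] elements `A` and `B`.
#' @export
make_peanut <- function(r1, shape2_semi_axes, center_offset = 1.0,
                        resolution = 4L) {
  c1 <- c(-center_offset / 2, 0, 0)
  c2 <- c(center_offset / 2, 0, 0)
  s1 <- icosphere(resolution, radius = r1, center = c1)
  s2 <- icosphere(resolution, radius = 1, center = c(0, 0, 0))
  v2 <- sweep(s2$vertices, 2, shape2_semi_axes, "*")
  v2 <- sweep(v2, 2, c2, "+")
  s2 <- triangle_mesh(v2, s2$faces)
  q1 <- quadric_sphere(c1, r1)
  q2 <- quadric_ellipsoid(c2, shape2_semi_axes)

  f2_on_1 <- quadric_eval(q2, s1$vertices)
  f1_on_2 <- quadric_eval(q1, s2$vertices)
  if (all(f2_on_1 > 0) || all(f2_on_1 < 0) ||
        all(f1_on_2 > 0) || all(f1_on_2 < 0))
    stop("shapes do not intersect: no shared surface exists")

  part1 <- clip_mesh_by_quadric(s1, q2, keep_sign = +1)  # sphere 1 outside 2
  cap <- clip_mesh_by_quadric(s2, q1, keep_sign = -1)    # shape 2 inside 1
  A <- triangle_mesh(rbind(part1$vertices, cap$vertices),
                     rbind(part1$faces, cap$faces + nrow(part1$vertices)))
  B <- s2

  ctr <- bbox_of(rbind(A$vertices, B$vertices))$center
  A <- triangle_mesh(sweep(A$vertices, 2, ctr, "-"), A$faces)
  B <- triangle_mesh(sweep(B$vertices, 2, ctr, "-"), B$faces)
  list(A = A, B = B)
}

#' Generate the synthetic peanut cohort
#'
#' Produces `n_controls + n_pathology` two-mesh samples (pre-extraction, with
#' domains `A` and `B`), group labels, and the generative metadata (r1, r2,
#' ellipsoid scales) needed for parameter-recovery tests. `r1` is evenly
#' spaced over `r1_range` within each group; a fixed seed gives bit-identical
#' output.
#'
#' @param params a [peanut_params()].
#' @return a list with `samples` (list of [multi_organ_sample()]) and
#'   `metadata` (data frame with one row per sample).
#' @export
generate_peanut_cohort <- function(params = peanut_params()) {
  stopifnot(inherits(params, "peanut_params"))
  with_preserved_seed({
    set.seed(params$seed)
    r1c <- even_spaced(params$r1_range, params$n_controls)
    r1p <- even_spaced(params$r1_range, params$n_pathology)
    sy <- stats::runif(params$n_pathology, params$ellipsoid_yz_scale_range[1],
                       params$ellipsoid_yz_scale_range[2])
    sz <- stats::runif(params$n_pathology, params$ellipsoid_yz_scale_range[1],
                       params$ellipsoid_yz_scale_range[2])
    samples <- vector("list", params$n_controls + params$n_pathology)
    meta <- list()
    for (i in seq_len(params$n_controls)) {
      r1 <- r1c[i]
      r2 <- params$radius_sum - r1
      pair <- make_peanut(r1, rep(r2, 3), params$center_offset,
                          params$mesh_resolution)
      id <- sprintf("control_%02d", i)
      samples[[i]] <- multi_organ_sample(id, list(A = pair$A, B = pair$B),
                                         label = "control")
      meta[[i]] <- data.frame(subject_id = id, group = "control", r1 = r1,
                              r2 = r2, scale_y = 1, scale_z = 1)
    }
    for (i in seq_len(params$n_pathology)) {
      r1 <- r1p[i]
      r2 <- params$radius_sum - r1
      pair <- make_peanut(r1, c(r2, r2 * sy[i], r2 * sz[i]),
                          params$center_offset, params$mesh_resolution)
      id <- sprintf("pathology_%02d", i)
      j <- params$n_controls + i
      samples[[j]] <- multi_organ_sample(id, list(A = pair$A, B = pair$B),
                                         label = "pathology")
      meta[[j]] <- data.frame(subject_id = id, group = "pathology", r1 = r1,
                              r2 = r2, scale_y = sy[i], scale_z = sz[i])
    }
    list(samples = samples, metadata = do.call(rbind, meta))
  })
}

even_spaced <- function(range, n) {
  if (n == 1L) mean(range) else seq(range[1], range[2], length.out = n)
}

# evaluate expr without disturbing the caller's RNG stream
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Analytic area of the shared spherical cap of a control sample
#'
#' For two spheres of radii `r1`, `r2` with centres `d` apart, the cap of
#' sphere 2 inside ball 1 has height `h = r2 - d/2 + (r1^2 - r2^2) / (2 d)`
#' and area `2 * pi * r2 * h`.
#'
#' @param r1,r2 sphere radii.
#' @param d centre separation.
#' @return cap area.
#' @export
sphere_cap_area <- function(r1, r2, d) {
  h <- r2 - d / 2 + (r1^2 - r2^2) / (2 * d)
  2 * pi * r2 * h
}
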