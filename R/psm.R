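#' Optimizer configuration for particle-based shape modeling
#'
#' @param mode `"shared_boundary"` (organ particles additionally repelled by
#'   the subject's contour particles), `"multi_domain"` (per-domain sampling,
#'   joint shape-space covariance) or `"single"` (one domain).
#' @param particles named integer vector of per-domain particle counts
#'   (powers of two). `NULL` applies the defaults: 512 for organ surface
#'   domains, 64 for the shared surface (domain named `"M"`) and 64 for
#'   contour domains.
#' @param iterations main optimization iterations combining correspondence
#'   and sampling terms (default 50).
#' @param iterations_per_split sampling-only iterations after each particle
#'   split round during initialization (default 10).
#' @param w relative weight of the correspondence (shape-space) term
#'   (default 1).
#' @param knn neighbour rank used for the adaptive Parzen kernel bandwidths
#'   (default 6).
#' @param alpha_init_scale,alpha_final_scale covariance regularization
#'   relative to the mean eigenvalue, decayed geometrically from the first
#'   to the last iteration (defaults 1e-2 and 1e-5).
#' @param step0 initial global step factor (default 1).
#' @param patience stop early after this many iterations without energy
#'   improvement (default 10).
#' @param seed seed for the split directions (default 1).
#' @return a list of class `optimizer_config`.
#' @export
optimizer_config <- function(mode = c("shared_boundary", "multi_domain",
                                      "single"),
                             particles = NULL, iterations = 50L,
                             iterations_per_split = 10L, w = 1.0,
                             knn = 6L, alpha_init_scale = 1e-2,
                             alpha_final_scale = 1e-5, step0 = 1.0,
                             patience = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (w < 0) stop("w must be >= 0")
  if (!is.null(particles)) {
    if (any(particles < 1L) || any(bitwAnd(particles, particles - 1L) != 0L))
      stop("particle counts must be powers of two")
  }
  structure(list(mode = mode, particles = particles,
                 iterations = as.integer(iterations),
                 iterations_per_split = as.integer(iterations_per_split),
                 w = w, knn = as.integer(knn),
                 alpha_init_scale = alpha_init_scale,
                 alpha_final_scale = alpha_final_scale,
                 step0 = step0, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

default_particle_counts <- function(domains, kinds) {
  out <- integer(length(domains))
  names(out) <- domains
  for (i in seq_along(domains)) {
    out[i] <- if (kinds[i] == "contour") 64L
              else if (domains[i] %in% c("M", "shared", "shared_surface")) 64L
              else 512L
  }
  out
}

#' Parzen-window log density at a point
#'
#' `log( 1/J * sum_j G(||x - x_j||; sigma_j) )` with isotropic 3D Gaussian
#' kernels centred on the neighbours. The evaluation point must not be in
#' the neighbour set. Underflowing densities are clamped to a numerical
#' floor and flagged via attribute `floored`.
#'
#' @param x length-3 point.
#' @param neighbors J x 3 matrix of kernel centres.
#' @param sigmas scalar or length-J kernel bandwidths.
#' @return log density, with attribute `floored`.
#' @export
parzen_log_density <- function(x, neighbors, sigmas) {
  neighbors <- as_point_matrix(neighbors)
  J <- nrow(neighbors)
  if (J < 1L) stop("need at least one neighbour")
  sigmas <- rep_len(sigmas, J)
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  d2 <- rowSums(sweep(neighbors, 2, x, "-")^2)
  dens <- mean(exp(-d2 / (2 * sigmas^2)) / ((2 * pi)^1.5 * sigmas^3))
  floored <- dens <= 0
  out <- if (floored) log(.Machine$double.xmin) / 2 else log(dens)
  attr(out, "floored") <- floored
  out
}

#' Sampling (configuration-space) entropy of a particle set
#'
#' `H(X) = -(1/M) sum_m log p(x_m)` with the Parzen density of each particle
#' estimated from all other particles of the set plus any frozen extra
#' neighbours (the contour particles in the conditional, shared-boundary
#' form). Larger spread means lower density and higher entropy.
#'
#' @param particles M x 3 particle matrix (M >= 2).
#' @param sigmas scalar or length-M bandwidths for the particles.
#' @param extra optional Me x 3 matrix of frozen extra neighbours.
#' @param extra_sigmas bandwidths for `extra`.
#' @return entropy value (scalar).
#' @export
sampling_entropy <- function(particles, sigmas, extra = NULL,
                             extra_sigmas = NULL) {
  particles <- as_point_matrix(particles)
  M <- nrow(particles)
  if (M < 2L) stop("sampling entropy needs at least 2 particles")
  sigmas <- rep_len(sigmas, M)
  if (is.null(extra)) {
    extra <- matrix(numeric(0), 0L, 3L)
    extra_sigmas <- numeric(0)
  } else {
    extra <- as_point_matrix(extra)
    extra_sigmas <- rep_len(extra_sigmas, nrow(extra))
  }
  cpp_parzen_entropy_grad(particles, extra, sigmas, extra_sigmas,
                          want_grad = FALSE)$entropy
}

#' Gradient of the sampling entropy
#'
#' The exact analytic gradient of [sampling_entropy()] with respect to each
#' particle (including the terms where the particle acts as a kernel centre
#' in other particles' densities). Frozen extra neighbours contribute
#' repulsion but receive no gradient.
#'
#' @inheritParams sampling_entropy
#' @return M x 3 gradient matrix.
#' @export
sampling_gradient <- function(particles, sigmas, extra = NULL,
                              extra_sigmas = NULL) {
  particles <- as_point_matrix(particles)
  M <- nrow(particles)
  if (M < 2L) stop("sampling gradient needs at least 2 particles")
  sigmas <- rep_len(sigmas, M)
  if (is.null(extra)) {
    extra <- matrix(numeric(0), 0L, 3L)
    extra_sigmas <- numeric(0)
  } else {
    extra <- as_point_matrix(extra)
    extra_sigmas <- rep_len(extra_sigmas, nrow(extra))
  }
  cpp_parzen_entropy_grad(particles, extra, sigmas, extra_sigmas,
                          want_grad = TRUE)$grad
}

#' Shape-space statistics of a cohort of shape vectors
#'
#' Mean, centred data and the eigen-spectrum of the sample covariance,
#' computed through the N x N Gram matrix (the cohort size N is far smaller
#' than the shape dimension dM). All `min(N-1, D)` possibly-nonzero
#' eigenvalues are retained; the remaining `D - q` eigenvalues of the
#' covariance are exactly zero and enter the entropy only through the
#' regularization `alpha`.
#'
#' @param Z N x D matrix of per-subject concatenated particle coordinates.
#' @param alpha covariance regularization (variance units, > 0).
#' @return a list of class `correspondence_stats` with elements `mean`,
#'   `lambda` (length q, descending), `basis` (D x r eigenvectors for the
#'   numerically nonzero spectrum), `alpha`, `n`, `dim`.
#' @export
correspondence_stats <- function(Z, alpha = 1e-6) {
  Z <- as.matrix(Z)
  N <- nrow(Z)
  D <- ncol(Z)
  if (N < 2L) stop("need at least 2 subjects")
  if (alpha <= 0) stop("alpha must be > 0")
  mu <- colMeans(Z)
  Y <- sweep(Z, 2, mu)
  G <- tcrossprod(Y) / (N - 1)
  eg <- eigen(G, symmetric = TRUE)
  q <- min(N - 1L, D)
  lambda <- pmax(eg$values, 0)[seq_len(q)]
  keep <- which(lambda > max(lambda[1], .Machine$double.eps) * 1e-12)
  basis <- if (length(keep) > 0L) {
    B <- crossprod(Y, eg$vectors[, keep, drop = FALSE])
    sweep(B, 2, sqrt((N - 1) * lambda[keep]), "/")
  } else {
    matrix(0, D, 0L)
  }
  structure(list(mean = mu, lambda = lambda, basis = basis,
                 basis_lambda = lambda[keep], alpha = alpha,
                 n = N, dim = D),
            class = "correspondence_stats")
}

#' Correspondence (shape-space) entropy
#'
#' The Gaussian shape-space entropy `H(Z) = 1/2 log |Sigma_reg|` with
#' `Sigma_reg = Sigma + alpha I`: one half the sum of `log(lambda_i +
#' alpha)` over the full D-dimensional spectrum (eigenvalues beyond the data
#' rank are exactly zero). Equals the dense regularized log-determinant.
#'
#' @param stats a [correspondence_stats()].
#' @return entropy value (scalar).
#' @export
correspondence_entropy <- function(stats) {
  stopifnot(inherits(stats, "correspondence_stats"))
  0.5 * (sum(log(stats$lambda + stats$alpha)) +
           (stats$dim - length(stats$lambda)) * log(stats$alpha))
}

#' Gradient of the correspondence entropy for one subject
#'
#' `dH(Z)/dz_n = 1/(N-1) * (Sigma + alpha I)^{-1} (z_n - mu)`, evaluated in
#' the retained eigenbasis (components outside the data span are scaled by
#' `1/alpha`; they are numerically zero for training subjects). Statistics
#' are lagged: the caller recomputes them once per outer iteration.
#'
#' @param stats a [correspondence_stats()].
#' @param z length-D shape vector of the subject.
#' @return length-D gradient vector.
#' @export
correspondence_gradient <- function(stats, z) {
  stopifnot(inherits(stats, "correspondence_stats"))
  y <- as.numeric(z) - stats$mean
  if (ncol(stats$basis) == 0L) return(y / stats$alpha / (stats$n - 1))
  coef <- crossprod(stats$basis, y)                    # r x 1
  inspan <- stats$basis %*% (coef / (stats$basis_lambda + stats$alpha))
  resid <- (y - stats$basis %*% coef) / stats$alpha
  as.numeric(inspan + resid) / (stats$n - 1)
}

#' Adaptive Parzen kernel bandwidths
#'
#' Per-particle bandwidth = distance to the k-th nearest neighbour within
#' the particle's Parzen neighbour set (the same set the entropy uses, so
#' contour particles count as neighbours for coupled organ domains), capped
#' at three times the nearest-neighbour distance and floored at
#' `floor_frac` of the domain bounding-box diagonal. The nearest-neighbour
#' cap keeps kernels local when particles are transiently clustered (as
#' right after a split round): without it the k-th neighbour of a tight
#' pair lies across the whole configuration and the pair never separates.
#'
#' @param particles M x 3 particle matrix.
#' @param k neighbour rank (default 6; capped at the neighbour-set size).
#' @param extra optional frozen extra neighbours included in the set.
#' @param bbox_diag bounding-box diagonal of the domain geometry; defaults
#'   to the particle cloud's own diagonal.
#' @param floor_frac bandwidth floor as a fraction of `bbox_diag`.
#' @return length-M vector of positive bandwidths.
#' @export
update_bandwidths <- function(particles, k = 6L, extra = NULL,
                              bbox_diag = NULL, floor_frac = 1e-3) {
  particles <- as_point_matrix(particles)
  M <- nrow(particles)
  all_pts <- if (is.null(extra)) particles else
    rbind(particles, as_point_matrix(extra))
  J <- nrow(all_pts) - 1L
  if (J < 1L) stop("need at least 2 points for bandwidth estimation")
  kk <- min(k, J)
  d2 <- outer(rowSums(particles^2), rep(1, nrow(all_pts))) +
    outer(rep(1, M), rowSums(all_pts^2)) - 2 * tcrossprod(particles, all_pts)
  d2[cbind(seq_len(M), seq_len(M))] <- Inf   # self-exclusion
  d2[d2 < 0] <- 0
  dk <- sqrt(apply(d2, 1, function(r) sort(r, partial = kk)[kk]))
  d1 <- sqrt(apply(d2, 1, min))
  if (is.null(bbox_diag)) bbox_diag <- bbox_of(particles)$diag
  floor_val <- floor_frac * bbox_diag
  sig <- pmin(dk, 3 * pmax(d1, floor_val))
  pmax(sig, floor_val)
}

# ---- particle system -------------------------------------------------------

new_particle_system <- function(subjects, domains, kinds, positions,
                                labels = NULL) {
  positions <- lapply(positions, function(doms)
    stats::setNames(doms, domains))
  structure(list(subjects = subjects, domains = domains,
                 domain_kind = stats::setNames(kinds, domains),
                 counts = stats::setNames(
                   vapply(positions[[1]], nrow, integer(1)), domains),
                 positions = positions, labels = labels),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d subjects, domains %s\n",
              length(x$subjects),
              paste(sprintf("%s(%d)", x$domains, x$counts), collapse = ", ")))
  invisible(x)
}

# project particle positions onto a domain (surface or contour)
project_to_domain <- function(P, domain) {
  if (is_contour3d(domain)) {
    s <- contour_segments(domain)
    cpp_closest_on_segments(P, s$a, s$b)$points
  } else {
    cpp_closest_on_mesh(P, domain$vertices, domain$faces)$points
  }
}

# local unit tangent of a contour at each particle (direction of the nearest
# segment)
contour_tangent_at <- function(P, domain) {
  s <- contour_segments(domain)
  res <- cpp_closest_on_segments(P, s$a, s$b)
  d <- s$b[res$segment, , drop = FALSE] - s$a[res$segment, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

# outward normal of the closest face under each particle
surface_normal_at <- function(P, mesh) {
  res <- cpp_closest_on_mesh(P, mesh$vertices, mesh$faces)
  f <- mesh$faces[res$face, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c3 <- mesh$vertices[f[, 3], , drop = FALSE]
  n <- cross3(b - a, c3 - a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# mean bounding-box diagonal of a domain across subjects
domain_bbox_diag <- function(samples, k) {
  mean(vapply(samples, function(s) bbox_of(s$domains[[k]]$vertices)$diag,
              numeric(1)))
}

#' Initialize a particle system by binary splitting
#'
#' Starts with one particle per domain (the surface point nearest the
#' domain centroid; the first contour vertex for contours) and repeatedly
#' doubles the count: each particle splits into two children offset by
#' `+/- epsilon` along a random tangent direction (along the polyline for
#' contours), followed by re-projection and a sampling-only relaxation
#' phase. Split directions are drawn once per level and shared across
#' subjects so the splitting preserves correspondence.
#'
#' @param samples list of [multi_organ_sample()] with identical domain
#'   layouts.
#' @param config an [optimizer_config()].
#' @return a `particle_system` at the target counts.
#' @export
initialize_by_splitting <- function(samples, config = optimizer_config()) {
  layout <- check_cohort_layout(samples)
  domains <- layout$domains
  kinds <- layout$kinds
  counts <- config$particles
  if (is.null(counts)) counts <- default_particle_counts(domains, kinds)
  counts <- counts[domains]
  if (anyNA(counts)) stop("particle counts missing for some domains")
  if (any(counts < 1L) || any(bitwAnd(as.integer(counts), counts - 1L) != 0L))
    stop("particle counts must be powers of two")
  diag_k <- vapply(domains, function(k) domain_bbox_diag(samples, k),
                   numeric(1))
  eps <- 0.005 * diag_k
  with_preserved_seed({
    set.seed(config$seed)
    positions <- lapply(samples, function(s) {
      lapply(seq_along(domains), function(ki) {
        d <- s$domains[[domains[ki]]]
        if (kinds[ki] == "contour") {
          # deterministic geometric anchor (extreme vertex along a fixed
          # axis): contour vertex numbering is a meshing accident that
          # differs across subjects, so starting at vertex 1 would seed the
          # ring correspondence at arbitrary relative rotations
          anchor <- which.max(d$vertices[, 2] + 1e-6 * d$vertices[, 3])
          d$vertices[anchor, , drop = FALSE]
        } else {
          ctr <- colMeans(d$vertices)
          matrix(closest_point_on_mesh(ctr, d), 1L, 3L)
        }
      })
    })
    sys <- new_particle_system(
      vapply(samples, `[[`, character(1), "subject_id"), domains, kinds,
      positions, labels = sample_labels(samples))
    repeat {
      below <- which(sys$counts < counts)
      if (length(below) == 0L) break
      for (ki in below) {
        m <- sys$counts[ki]
        dirs <- matrix(stats::rnorm(3L * m), m, 3L)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        # fixed axes for the first two split rounds: they pin the layout's
        # gauge (e.g. the azimuth on a near-axisymmetric organ) identically
        # across subjects, which random directions only do up to the local
        # tangent projection
        if (m == 1L) dirs <- matrix(c(0, 1, 0), 1L, 3L)
        if (m == 2L) dirs <- matrix(c(0, 0, 1), m, 3L, byrow = TRUE)
        for (n in seq_along(samples)) {
          dom <- samples[[n]]$domains[[sys$domains[ki]]]
          P <- sys$positions[[n]][[ki]]
          if (sys$domain_kind[ki] == "contour") {
            tang <- contour_tangent_at(P, dom)
            off <- tang * eps[ki]
          } else {
            nrm <- surface_normal_at(P, dom)
            tang <- dirs - rowSums(dirs * nrm) * nrm
            tl <- sqrt(rowSums(tang^2))
            bad <- tl < 1e-8
            if (any(bad)) {   # split direction parallel to the normal
              alt <- cross3(nrm[bad, , drop = FALSE],
                            matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3L,
                                   byrow = TRUE))
              alt_l <- sqrt(rowSums(alt^2))
              alt[alt_l < 1e-8, ] <- rep(c(0, 1, 0), each = sum(alt_l < 1e-8))
              tang[bad, ] <- alt
              tl <- sqrt(rowSums(tang^2))
            }
            off <- tang / tl * eps[ki]
          }
          children <- rbind(P + off, P - off)
          sys$positions[[n]][[ki]] <- project_to_domain(children, dom)
        }
        sys$counts[ki] <- 2L * m
      }
      sys <- relax_sampling_only(sys, samples, config,
                                 iterations = config$iterations_per_split)
    }
    sys
  })
}

check_cohort_layout <- function(samples) {
  if (length(samples) == 0L) stop("empty cohort")
  domains <- names(samples[[1]]$domains)
  kinds <- vapply(samples[[1]]$domains, function(d)
    if (is_contour3d(d)) "contour" else "surface", character(1))
  for (s in samples) {
    if (!identical(names(s$domains), domains))
      stop("all samples must share the same domain names in the same order")
  }
  list(domains = domains, kinds = unname(kinds))
}

sample_labels <- function(samples) {
  labs <- lapply(samples, `[[`, "label")
  if (all(vapply(labs, is.null, logical(1)))) return(NULL)
  vapply(labs, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

# Parzen neighbour wiring for a domain under the configured mode: returns
# indices of domains whose particles act as frozen extra neighbours
extra_neighbour_domains <- function(sys, ki, mode) {
  if (mode != "shared_boundary") return(integer(0))
  if (sys$domain_kind[ki] == "contour") return(integer(0))
  which(sys$domain_kind == "contour")
}

# per-subject, per-domain bandwidths under the configured neighbour wiring;
# for coupled organ domains the frozen contour neighbours also get
# bandwidths, computed within the same joint (organ + contour) set so their
# kernels act at the organ's local scale
system_bandwidths <- function(sys, samples, config) {
  lapply(seq_along(sys$subjects), function(n) {
    own <- vector("list", length(sys$domains))
    extras <- vector("list", length(sys$domains))
    for (ki in seq_along(sys$domains)) {
      ex <- extra_neighbour_domains(sys, ki, config$mode)
      extra <- if (length(ex) > 0L)
        do.call(rbind, sys$positions[[n]][ex]) else NULL
      dd <- bbox_of(samples[[n]]$domains[[sys$domains[ki]]]$vertices)$diag
      own[[ki]] <- update_bandwidths(sys$positions[[n]][[ki]],
                                     k = config$knn, extra = extra,
                                     bbox_diag = dd)
      if (!is.null(extra) && nrow(extra) >= 1L)
        extras[[ki]] <- update_bandwidths(extra, k = config$knn,
                                          extra = sys$positions[[n]][[ki]],
                                          bbox_diag = dd)
    }
    list(own = own, extras = extras)
  })
}

# total sampling entropy of the system (sum over subjects and domains)
system_sampling_entropy <- function(sys, bw, config) {
  tot <- 0
  for (n in seq_along(sys$subjects)) {
    for (ki in seq_along(sys$domains)) {
      if (sys$counts[ki] < 2L) next
      ex <- extra_neighbour_domains(sys, ki, config$mode)
      extra <- if (length(ex) > 0L)
        do.call(rbind, sys$positions[[n]][ex]) else NULL
      es <- bw[[n]]$extras[[ki]]
      tot <- tot + sampling_entropy(sys$positions[[n]][[ki]],
                                    bw[[n]]$own[[ki]], extra, es)
    }
  }
  tot
}

# one sampling-only gradient step on every domain, with projection
sampling_step <- function(sys, samples, bw, config, step) {
  for (n in seq_along(sys$subjects)) {
    for (ki in seq_along(sys$domains)) {
      if (sys$counts[ki] < 2L) next
      dom <- samples[[n]]$domains[[sys$domains[ki]]]
      ex <- extra_neighbour_domains(sys, ki, config$mode)
      extra <- if (length(ex) > 0L)
        do.call(rbind, sys$positions[[n]][ex]) else NULL
      es <- bw[[n]]$extras[[ki]]
      sig <- bw[[n]]$own[[ki]]
      g <- sampling_gradient(sys$positions[[n]][[ki]], sig, extra, es)
      # the entropy is mean-normalized over particles, so its per-particle
      # gradient carries a 1/M factor; scale by M for count-independent moves
      delta <- step * sys$counts[ki] * sig^2 * g   # ascend sampling entropy
      delta <- cap_norm(delta, 0.3 * sig)
      P <- sys$positions[[n]][[ki]] + delta
      if (sys$domain_kind[ki] == "contour") {
        tang <- contour_tangent_at(sys$positions[[n]][[ki]], dom)
        P <- sys$positions[[n]][[ki]] + rowSums(delta * tang) * tang
      }
      sys$positions[[n]][[ki]] <- project_to_domain(P, dom)
    }
  }
  sys
}

cap_norm <- function(delta, cap) {
  nrm <- sqrt(rowSums(delta^2))
  f <- ifelse(nrm > cap, cap / nrm, 1)
  delta * f
}

relax_sampling_only <- function(sys, samples, config, iterations) {
  for (it in seq_len(iterations)) {
    bw <- system_bandwidths(sys, samples, config)
    sys <- sampling_step(sys, samples, bw, config, step = 1.0)
  }
  sys
}

#' Build the N x dM shape matrix from a particle system
#'
#' Deterministic concatenation: domain order, then particle index, then
#' (x, y, z).
#'
#' @param system a `particle_system`.
#' @param labels optional per-subject group labels (defaults to the labels
#'   stored in the system).
#' @return an object of class `shape_matrix`: list with `data` (N x dM),
#'   `domains`, `domain_slices` (column index vectors), `counts`, `labels`.
#' @export
build_shape_matrix <- function(system, labels = NULL) {
  stopifnot(inherits(system, "particle_system"))
  if (is.null(labels)) labels <- system$labels
  if (!is.null(labels) && length(labels) != length(system$subjects))
    stop("label count does not match subject count")
  rows <- t(vapply(system$positions, function(doms)
    as.numeric(unlist(lapply(doms, function(P) as.vector(t(P))))),
    numeric(3L * sum(system$counts))))
  rownames(rows) <- system$subjects
  slices <- list()
  off <- 0L
  for (ki in seq_along(system$domains)) {
    len <- 3L * system$counts[ki]
    slices[[system$domains[ki]]] <- off + seq_len(len)
    off <- off + len
  }
  structure(list(data = rows, domains = system$domains,
                 domain_slices = slices, counts = system$counts,
                 domain_kind = system$domain_kind, labels = labels),
            class = "shape_matrix")
}

#' Rebuild a particle system from a shape matrix
#'
#' Inverse of [build_shape_matrix()] (round trip preserves positions
#' exactly).
#'
#' @param sm a `shape_matrix`.
#' @return a `particle_system`.
#' @export
particle_system_from_matrix <- function(sm) {
  stopifnot(inherits(sm, "shape_matrix"))
  positions <- lapply(seq_len(nrow(sm$data)), function(n)
    lapply(seq_along(sm$domains), function(ki) {
      v <- sm$data[n, sm$domain_slices[[ki]]]
      matrix(v, ncol = 3L, byrow = TRUE)
    }))
  new_particle_system(rownames(sm$data), sm$domains,
                      unname(sm$domain_kind[sm$domains]), positions,
                      labels = sm$labels)
}

# reshape one subject's length-D vector into per-domain M x 3 matrices
vector_to_domains <- function(z, sm_like) {
  lapply(seq_along(sm_like$domains), function(ki)
    matrix(z[sm_like$domain_slices[[ki]]], ncol = 3L, byrow = TRUE))
}

#' Optimize a correspondence particle system over a cohort
#'
#' Initializes by binary splitting, then alternates (a) recomputing the
#' shape-space statistics once per iteration (lagging statistics), (b) a
#' per-particle update combining the correspondence gradient, weighted by
#' `w`, with the sampling gradient, and (c) re-projection of every particle
#' onto its surface or contour. Contour particles have one degree of
#' freedom: their update is projected onto the local segment direction. The
#' covariance spans all domains jointly in every mode; the sampling
#' neighbour sets depend on the mode (per-domain for `multi_domain`, with
#' frozen contour neighbours for organ domains in `shared_boundary`).
#'
#' A global adaptive step factor halves (with revert) when the energy
#' `Q = w H(Z) - sum H(X)` increases and grows by 10% when it decreases;
#' moves are additionally capped at the local kernel bandwidth.
#'
#' @param samples list of [multi_organ_sample()] sharing a domain layout.
#' @param config an [optimizer_config()].
#' @return the optimized `particle_system`, with attributes `energy_log`
#'   (data frame: iteration, correspondence entropy, sampling entropy,
#'   energy, step) and `config`.
#' @export
optimize_particles <- function(samples, config = optimizer_config()) {
  sys <- initialize_by_splitting(samples, config)
  refine_particles(sys, samples, config)
}

# main optimization loop (shared with split-only initialized systems)
refine_particles <- function(sys, samples, config) {
  N <- length(sys$subjects)
  log_rows <- list()
  if (config$iterations < 1L || N < 2L) {
    attr(sys, "energy_log") <- empty_energy_log()
    attr(sys, "config") <- config
    return(sys)
  }
  alpha_sched <- function(it, mean_lambda) {
    fr <- if (config$iterations == 1L) 1 else (it - 1) / (config$iterations - 1)
    scale <- config$alpha_init_scale *
      (config$alpha_final_scale / config$alpha_init_scale)^fr
    max(scale * mean_lambda, 1e-12)
  }
  step <- config$step0
  best_Q <- Inf
  stall <- 0L
  prev_sys <- sys
  prev_Q <- Inf
  prev_bw <- NULL
  prev_stats <- NULL
  for (it in seq_len(config$iterations)) {
    bw <- system_bandwidths(sys, samples, config)
    sm <- build_shape_matrix(sys)
    # one eigendecomposition per outer iteration (lagging statistics); the
    # regularization schedule only changes alpha, not the spectrum
    stats <- correspondence_stats(sm$data, 1e-12)
    stats$alpha <- alpha_sched(it, mean(stats$lambda))
    HZ <- correspondence_entropy(stats)
    HS <- system_sampling_entropy(sys, bw, config)
    Q <- config$w * HZ - HS
    if (!is.finite(Q)) stop("energy is not finite; optimization aborted")
    if (Q > prev_Q && !is.null(prev_bw)) {
      # revert to the previous state (reusing its cached statistics) and
      # retry with a smaller step
      sys <- prev_sys
      bw <- prev_bw
      stats <- prev_stats
      step <- max(step / 2, 1e-6)
    } else {
      prev_sys <- sys
      prev_Q <- Q
      prev_bw <- bw
      prev_stats <- stats
      step <- min(step * 1.1, 10)
    }
    log_rows[[it]] <- data.frame(iteration = it, H_Z = HZ, H_sampling = HS,
                                 energy = Q, step = step)
    if (Q < best_Q - 1e-12) {
      best_Q <- Q
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        warning("energy plateaued; stopping after ", it, " iterations")
        break
      }
    }
    sys <- particle_update_step(sys, samples, bw, stats, config, step)
  }
  attr(sys, "energy_log") <- do.call(rbind, log_rows)
  attr(sys, "config") <- config
  sys
}

empty_energy_log <- function() {
  data.frame(iteration = integer(0), H_Z = numeric(0),
             H_sampling = numeric(0), energy = numeric(0), step = numeric(0))
}

particle_update_step <- function(sys, samples, bw, stats, config, step,
                                 frozen_subjects = NULL) {
  sm_like <- build_shape_matrix(sys)
  for (n in seq_along(sys$subjects)) {
    if (!is.null(frozen_subjects) && n %in% frozen_subjects) next
    cg <- correspondence_gradient(stats, sm_like$data[n, ])
    cg_dom <- vector_to_domains(cg, sm_like)
    for (ki in seq_along(sys$domains)) {
      if (sys$counts[ki] < 2L) next
      dom <- samples[[n]]$domains[[sys$domains[ki]]]
      ex <- extra_neighbour_domains(sys, ki, config$mode)
      extra <- if (length(ex) > 0L)
        do.call(rbind, sys$positions[[n]][ex]) else NULL
      es <- bw[[n]]$extras[[ki]]
      sig <- bw[[n]]$own[[ki]]
      sg <- sampling_gradient(sys$positions[[n]][[ki]], sig, extra, es)
      # descend Q = w H(Z) - H(X): move against w*corr minus sampling grads
      # (count scaling as in sampling_step keeps moves M-independent)
      delta <- -step * sys$counts[ki] * sig^2 * (config$w * cg_dom[[ki]] - sg)
      delta <- cap_norm(delta, 0.3 * sig)
      P0 <- sys$positions[[n]][[ki]]
      if (sys$domain_kind[ki] == "contour") {
        tang <- contour_tangent_at(P0, dom)
        delta <- rowSums(delta * tang) * tang
      }
      sys$positions[[n]][[ki]] <- project_to_domain(P0 + delta, dom)
    }
  }
  sys
}
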