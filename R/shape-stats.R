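#' PCA modes of variation of a shape matrix
#'
#' Eigen-decomposition of the sample covariance of the shape vectors,
#' computed through the N x N Gram matrix (the shape dimension dM is far
#' larger than the cohort size). Modes are ranked by the proportion of
#' total variance they explain; at most `min(N - 1, dM)` modes carry
#' variance.
#'
#' @param sm a `shape_matrix` from [build_shape_matrix()], or a plain
#'   numeric matrix (subjects in rows).
#' @param n_modes number of modes to retain (default: all nonzero).
#' @return an object of class `pca_model`: `mean`, `modes` (dM x q,
#'   orthonormal columns), `eigenvalues` (variance per mode, descending),
#'   `ratios` (explained-variance fractions over the full spectrum).
#' @export
pca_modes <- function(sm, n_modes = NULL) {
  Z <- if (inherits(sm, "shape_matrix")) sm$data else as.matrix(sm)
  N <- nrow(Z)
  if (N < 2L) stop("PCA needs at least 2 subjects")
  mu <- colMeans(Z)
  Y <- sweep(Z, 2, mu)
  G <- tcrossprod(Y) / (N - 1)
  eg <- eigen(G, symmetric = TRUE)
  q <- min(N - 1L, ncol(Z))
  lambda <- pmax(eg$values, 0)[seq_len(q)]
  total <- sum(lambda)
  keep <- which(lambda > max(total, .Machine$double.eps) * 1e-12)
  if (!is.null(n_modes)) keep <- keep[seq_len(min(n_modes, length(keep)))]
  modes <- crossprod(Y, eg$vectors[, keep, drop = FALSE])
  modes <- sweep(modes, 2, sqrt((N - 1) * lambda[keep]), "/")
  structure(list(mean = mu, modes = modes, eigenvalues = lambda[keep],
                 ratios = if (total > 0) lambda[keep] / total
                          else rep(0, length(keep)),
                 total_variance = total, n = N),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d modes, leading ratios %s\n",
              length(x$eigenvalues),
              paste(sprintf("%.3f", utils::head(x$ratios, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Walk along a PCA mode
#'
#' Returns the shape vectors `mean + c * sqrt(lambda_mode) * mode` for each
#' multiple `c` in `multiples` — the standard way to visualize a mode of
#' variation at, say, -2, 0 and +2 standard deviations.
#'
#' @param pca a [pca_modes()] model.
#' @param mode mode index (1 = dominant).
#' @param multiples numeric vector of standard-deviation multiples.
#' @return matrix with one shape vector per row of `multiples`.
#' @export
mode_walk <- function(pca, mode = 1L, multiples = c(-2, 0, 2)) {
  stopifnot(inherits(pca, "pca_model"))
  if (mode > ncol(pca$modes)) stop("mode index exceeds retained modes")
  sd_m <- sqrt(pca$eigenvalues[mode])
  out <- t(vapply(multiples, function(cc)
    pca$mean + cc * sd_m * pca$modes[, mode], numeric(length(pca$mean))))
  rownames(out) <- paste0(multiples, "sd")
  out
}

#' Project subjects onto a PCA mode
#'
#' @param pca a [pca_modes()] model.
#' @param Z shape matrix (or `shape_matrix`) to project.
#' @param mode mode index.
#' @return numeric vector of per-subject mode scores.
#' @export
pca_scores <- function(pca, Z, mode = 1L) {
  zz <- if (inherits(Z, "shape_matrix")) Z$data else as.matrix(Z)
  as.numeric(sweep(zz, 2, pca$mean) %*% pca$modes[, mode])
}

#' Multi-level component analysis: pose vs. shape
#'
#' Decomposes a multi-domain shape matrix into a between-organ component
#' (the per-domain particle centroids, i.e. the relative alignment of the
#' organs, centred on their cohort means and broadcast back to the domain
#' columns) and a within-organ component (the centroid-removed particle
#' residual minus its cohort mean). Grand mean + between + within
#' reconstructs every entry exactly. Separate PCA models are fitted to the
#' two components, disentangling relative-pose modes from shape modes.
#'
#' @param sm a `shape_matrix` with at least two domains.
#' @return an object of class `mlca_model`: `grand_mean`, `between`,
#'   `within` (both N x dM), `pca_between`, `pca_within`.
#' @export
mlca <- function(sm) {
  stopifnot(inherits(sm, "shape_matrix"))
  if (length(sm$domains) < 2L)
    stop("MLCA needs at least 2 domains")
  Z <- sm$data
  N <- nrow(Z)
  if (N < 2L) stop("MLCA needs at least 2 subjects")
  between <- matrix(0, N, ncol(Z))
  for (ki in seq_along(sm$domains)) {
    cols <- sm$domain_slices[[ki]]
    Mk <- sm$counts[ki]
    block <- Z[, cols, drop = FALSE]
    cent <- vapply(1:3, function(ax)
      rowMeans(block[, seq(ax, 3L * Mk, by = 3L), drop = FALSE]),
      numeric(N))
    cent <- matrix(cent, nrow = N)
    idx <- rep(1:3, times = Mk)
    between[, cols] <- cent[, idx, drop = FALSE]
  }
  between_centred <- sweep(between, 2, colMeans(between))
  within_raw <- Z - between
  within <- sweep(within_raw, 2, colMeans(within_raw))
  grand_mean <- colMeans(Z)
  structure(list(grand_mean = grand_mean, between = between_centred,
                 within = within,
                 pca_between = pca_modes(between_centred),
                 pca_within = pca_modes(within),
                 domains = sm$domains, domain_slices = sm$domain_slices),
            class = "mlca_model")
}

#' Group-difference shape scores
#'
#' Linear discrimination of variation between two groups: the difference
#' vector between the particle-wise mean shapes, the projection (dot
#' product) of each subject's shape vector onto it, and an affine
#' normalization placing the two group-mean configurations at exactly -1
#' (the pathology-like group) and +1 (the control-like group). A univariate
#' Gaussian (maximum-likelihood variance) is fitted to each group's
#' normalized scores.
#'
#' @param sm a labelled `shape_matrix` with exactly two groups.
#' @param positive_group label mapped to +1; defaults to a label matching
#'   "control" (case-insensitive) if present, otherwise the alphabetically
#'   second label.
#' @return an object of class `group_score_model`: `difference`, `raw`,
#'   `scores`, `gaussians` (per-group mean/sd), `positive_group`,
#'   `negative_group`, plus the raw projections of the two group means.
#' @export
group_difference <- function(sm, positive_group = NULL) {
  stopifnot(inherits(sm, "shape_matrix"))
  labels <- sm$labels
  if (is.null(labels)) stop("shape matrix carries no group labels")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (is.null(positive_group)) {
    hit <- grep("control", lev, ignore.case = TRUE, value = TRUE)
    positive_group <- if (length(hit) == 1L) hit else lev[2]
  }
  if (!positive_group %in% lev) stop("positive_group not among the labels")
  negative_group <- setdiff(lev, positive_group)
  Z <- sm$data
  mu_pos <- colMeans(Z[labels == positive_group, , drop = FALSE])
  mu_neg <- colMeans(Z[labels == negative_group, , drop = FALSE])
  d <- mu_pos - mu_neg
  raw <- as.numeric(Z %*% d)
  a <- sum(mu_neg * d)   # maps to -1
  b <- sum(mu_pos * d)   # maps to +1
  if (abs(b - a) < .Machine$double.eps)
    stop("group means are identical; difference vector is degenerate")
  scores <- (2 * raw - (a + b)) / (b - a)
  fits <- lapply(stats::setNames(lev, lev), function(g) {
    x <- scores[labels == g]
    list(mean = mean(x), sd = sqrt(mean((x - mean(x))^2)))
  })
  structure(list(difference = d, raw = raw, scores = scores,
                 labels = labels, raw_neg = a, raw_pos = b,
                 gaussians = fits, positive_group = positive_group,
                 negative_group = negative_group),
            class = "group_score_model")
}

#' Score arbitrary shape vectors under a group-difference model
#'
#' Applies the model's projection and affine normalization, so the stored
#' group-mean configurations score exactly -1 and +1 and scores are affine
#' in the shape vector.
#'
#' @param model a [group_difference()] model.
#' @param Z matrix of shape vectors (rows) or a single vector.
#' @return numeric vector of normalized shape-based scores.
#' @export
score_shapes <- function(model, Z) {
  stopifnot(inherits(model, "group_score_model"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  raw <- as.numeric(as.matrix(Z) %*% model$difference)
  (2 * raw - (model$raw_neg + model$raw_pos)) / (model$raw_pos - model$raw_neg)
}

#' Predict particles on held-out samples from a trained model
#'
#' Initializes each held-out subject's particles at the trained mean
#' configuration projected onto that subject's surfaces and contours, then
#' refines them with sampling updates plus the correspondence gradient
#' evaluated against the frozen trained statistics (the trained mean and
#' covariance are not updated, and trained subjects' particles never move).
#'
#' @param trained_system the optimized `particle_system`.
#' @param trained_stats the [correspondence_stats()] of the trained shape
#'   matrix.
#' @param new_samples list of [multi_organ_sample()] with the trained
#'   domain layout.
#' @param config optimizer configuration (mode and weights reused).
#' @param iterations refinement iterations (default 50).
#' @param step fixed step factor (default 0.5).
#' @return a `particle_system` for the held-out subjects.
#' @export
predict_heldout_particles <- function(trained_system, trained_stats,
                                      new_samples,
                                      config = optimizer_config(),
                                      iterations = 50L, step = 0.5) {
  layout <- check_cohort_layout(new_samples)
  if (!identical(layout$domains, trained_system$domains))
    stop("held-out samples do not share the trained domain layout")
  sm_like <- build_shape_matrix(trained_system)
  mean_doms <- vector_to_domains(trained_stats$mean, sm_like)
  positions <- lapply(new_samples, function(s)
    lapply(seq_along(layout$domains), function(ki)
      project_to_domain(mean_doms[[ki]], s$domains[[layout$domains[ki]]])))
  sys <- new_particle_system(
    vapply(new_samples, `[[`, character(1), "subject_id"),
    layout$domains, layout$kinds, positions,
    labels = sample_labels(new_samples))
  for (it in seq_len(iterations)) {
    bw <- system_bandwidths(sys, new_samples, config)
    sys <- heldout_update_step(sys, new_samples, bw, trained_stats, sm_like,
                               config, step)
  }
  sys
}

heldout_update_step <- function(sys, samples, bw, stats, sm_like, config,
                                step) {
  cur <- build_shape_matrix(sys)
  for (n in seq_along(sys$subjects)) {
    cg <- correspondence_gradient(stats, cur$data[n, ])
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
      # count scaling as in the optimizer keeps moves M-independent
      delta <- -step * sys$counts[ki] * sig^2 *
        (config$w * cg_dom[[ki]] - sg)
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

#' Class-imbalance robustness experiment
#'
#' Repeatedly builds a shape model from a balanced random training subset
#' (`train_per_group` subjects from each group), predicts particles on the
#' held-out subjects without re-optimizing the model, scores all subjects
#' with the trial's group-difference vector, and finally tests — per
#' subject, across the trials — whether the trial scores differ from the
#' score under the model built on the complete cohort (two-sided one-sample
#' t-test).
#'
#' @param samples labelled four-domain cohort (post extraction).
#' @param config optimizer configuration used for the trial models.
#' @param full_system optional pre-optimized full-cohort system (computed
#'   if missing).
#' @param n_trials number of repetitions (default 10).
#' @param train_per_group training subjects drawn from each group
#'   (default 6).
#' @param alpha significance level reported alongside the p-values
#'   (default 0.01).
#' @param seed seed for the trial subsampling.
#' @param predict_iterations refinement iterations for held-out prediction.
#' @return an object of class `imbalance_result`: `trial_scores`
#'   (subjects x trials), `full_scores`, `t`, `p`, `flagged_degenerate`,
#'   `sensitive` (p < alpha), `alpha`.
#' @export
imbalance_experiment <- function(samples, config = optimizer_config(),
                                 full_system = NULL, n_trials = 10L,
                                 train_per_group = 6L, alpha = 0.01,
                                 seed = 1L, predict_iterations = 25L) {
  labels <- sample_labels(samples)
  if (is.null(labels) || anyNA(labels)) stop("all samples must be labelled")
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two groups are required")
  for (g in lev)
    if (sum(labels == g) < train_per_group)
      stop("group '", g, "' has fewer than train_per_group members")
  ids <- vapply(samples, `[[`, character(1), "subject_id")
  N <- length(samples)

  if (is.null(full_system)) full_system <- optimize_particles(samples, config)
  full_sm <- build_shape_matrix(full_system)
  full_model <- group_difference(full_sm)
  full_scores <- stats::setNames(score_shapes(full_model, full_sm$data), ids)

  trial_scores <- matrix(NA_real_, N, n_trials,
                         dimnames = list(ids, paste0("trial_", seq_len(n_trials))))
  with_preserved_seed({
    set.seed(seed)
    for (tr in seq_len(n_trials)) {
      train_idx <- sort(unlist(lapply(lev, function(g)
        sample(which(labels == g), train_per_group))))
      hold_idx <- setdiff(seq_len(N), train_idx)
      tr_sys <- optimize_particles(samples[train_idx], config)
      tr_sm <- build_shape_matrix(tr_sys)
      tr_model <- group_difference(tr_sm)
      tr_stats <- correspondence_stats(
        tr_sm$data, alpha = config$alpha_final_scale *
          max(mean(correspondence_stats(tr_sm$data, 1e-12)$lambda), 1e-12))
      sc <- numeric(N)
      sc[train_idx] <- score_shapes(tr_model, tr_sm$data)
      if (length(hold_idx) > 0L) {
        pred <- predict_heldout_particles(tr_sys, tr_stats,
                                          samples[hold_idx], config,
                                          iterations = predict_iterations)
        pred_sm <- build_shape_matrix(pred)
        sc[hold_idx] <- score_shapes(tr_model, pred_sm$data)
      }
      trial_scores[, tr] <- sc
    }
  })

  tt <- lapply(seq_len(N), function(i)
    one_sample_t(trial_scores[i, ], full_scores[i]))
  pvals <- vapply(tt, `[[`, numeric(1), "p")
  tstat <- vapply(tt, `[[`, numeric(1), "t")
  flagged <- vapply(tt, `[[`, logical(1), "degenerate")
  structure(list(trial_scores = trial_scores, full_scores = full_scores,
                 t = stats::setNames(tstat, ids),
                 p = stats::setNames(pvals, ids),
                 flagged_degenerate = stats::setNames(flagged, ids),
                 sensitive = stats::setNames(pvals < alpha, ids),
                 alpha = alpha),
            class = "imbalance_result")
}

# two-sided one-sample t-test with an explicit degenerate branch: when the
# trial scores have zero variance the statistic is undefined, so p is 1 when
# the mean equals the reference and 0 otherwise (flagged)
one_sample_t <- function(x, mu) {
  if (stats::sd(x) < .Machine$double.eps * max(1, abs(mean(x)))) {
    same <- abs(mean(x) - mu) < 1e-12
    return(list(t = if (same) 0 else Inf, p = if (same) 1 else 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, mu = mu)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Warp a mesh by thin-plate-spline particle displacement
#'
#' Interpolates the displacement field defined by matched source and target
#' particle sets with a 3D thin-plate spline (kernel `U(r) = r`) and
#' applies it to every vertex of the reference mesh. Used to reconstruct
#' meshes along modes of variation; with `target == source` the mesh is
#' returned unchanged, and a pure translation of the particles translates
#' every vertex exactly.
#'
#' @param reference_mesh the [triangle_mesh()] to deform.
#' @param source_particles M x 3 control points (M >= 4, non-coplanar).
#' @param target_particles M x 3 matched targets.
#' @return the warped [triangle_mesh()].
#' @export
warp_mesh <- function(reference_mesh, source_particles, target_particles) {
  stopifnot(is_triangle_mesh(reference_mesh))
  S <- as_point_matrix(source_particles)
  Tg <- as_point_matrix(target_particles)
  if (nrow(S) != nrow(Tg)) stop("particle sets must have equal length")
  M <- nrow(S)
  if (M < 4L) stop("need at least 4 control points")
  P1 <- cbind(1, S)
  if (qr(P1)$rank < 4L)
    stop("control points are coplanar/degenerate; TPS is singular")
  K <- as.matrix(stats::dist(S))       # U(r) = r in 3D
  Lmat <- rbind(cbind(K, P1), cbind(t(P1), matrix(0, 4L, 4L)))
  rhs <- rbind(Tg - S, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(Lmat, rhs), error = function(e)
    stop("TPS system is singular: ", conditionMessage(e)))
  Wc <- sol[seq_len(M), , drop = FALSE]
  Ac <- sol[M + 1:4, , drop = FALSE]
  V <- reference_mesh$vertices
  d2 <- outer(rowSums(V^2), rep(1, M)) + outer(rep(1, nrow(V)), rowSums(S^2)) -
    2 * tcrossprod(V, S)
  d2[d2 < 0] <- 0
  U <- sqrt(d2)
  disp <- U %*% Wc + cbind(1, V) %*% Ac
  triangle_mesh(V + disp, reference_mesh$faces)
}
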