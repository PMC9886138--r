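# a small deterministic particle system for matrix-level tests
toy_system <- function(N = 4L, counts = c(A = 3L, B = 2L), seed = 1L,
                       labels = NULL) {
  set.seed(seed)
  domains <- names(counts)
  positions <- lapply(seq_len(N), function(n)
    lapply(counts, function(m) matrix(rnorm(3 * m), m, 3L)))
  shapeshared:::new_particle_system(sprintf("s%02d", seq_len(N)), domains,
                                    rep("surface", length(counts)),
                                    positions, labels = labels)
}

test_that("the shape matrix concatenates deterministically and round-trips", {
  sys <- toy_system(N = 2L, counts = c(A = 2L))
  sm <- build_shape_matrix(sys)
  expect_equal(dim(sm$data), c(2L, 6L))
  # layout: particle index then (x, y, z)
  expect_equal(sm$data[1, 1:3], sys$positions[[1]][[1]][1, ])
  expect_equal(sm$data[1, 4:6], sys$positions[[1]][[1]][2, ])
  back <- particle_system_from_matrix(sm)
  expect_equal(back$positions, sys$positions)
  # permuting subjects permutes rows identically
  sys2 <- sys
  sys2$positions <- sys$positions[c(2, 1)]
  sys2$subjects <- sys$subjects[c(2, 1)]
  sm2 <- build_shape_matrix(sys2)
  expect_equal(unname(sm2$data), unname(sm$data[c(2, 1), ]))
  expect_error(build_shape_matrix(sys, labels = c("a", "b", "c")),
               "label count")
})

test_that("PCA via the Gram trick equals the dense eigendecomposition", {
  set.seed(2)
  Z <- matrix(rnorm(60), 5, 12)
  pca <- pca_modes(Z)
  dense <- eigen(stats::cov(Z), symmetric = TRUE)
  expect_equal(pca$eigenvalues, dense$values[seq_along(pca$eigenvalues)],
               tolerance = 1e-9)
  for (j in seq_len(ncol(pca$modes))) {
    dot <- abs(sum(pca$modes[, j] * dense$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-9)
  }
  # eigenvalue sum equals the total variance of the centred data
  Y <- sweep(Z, 2, colMeans(Z))
  expect_equal(sum(pca$eigenvalues), sum(Y^2) / (nrow(Z) - 1),
               tolerance = 1e-9)
  expect_equal(sum(pca$ratios), 1, tolerance = 1e-9)
  # orthonormal modes
  expect_equal(crossprod(pca$modes), diag(ncol(pca$modes)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rank-one data yields a single mode explaining everything", {
  set.seed(3)
  dir <- rnorm(9)
  Z <- outer(seq(-2, 2, length.out = 6), dir)
  pca <- pca_modes(Z)
  expect_equal(length(pca$eigenvalues), 1L)
  expect_equal(pca$ratios, 1, tolerance = 1e-9)
  # duplicating every subject leaves the eigenvectors unchanged (up to sign)
  pca2 <- pca_modes(rbind(Z, Z))
  expect_equal(abs(sum(pca$modes[, 1] * pca2$modes[, 1])), 1,
               tolerance = 1e-9)
})

test_that("mode walks are symmetric about the mean and reconstruct subjects", {
  set.seed(4)
  Z <- matrix(rnorm(40), 4, 10)
  pca <- pca_modes(Z)
  w <- mode_walk(pca, 1L, c(-2, 0, 2))
  expect_equal(w[2, ], pca$mean, tolerance = 1e-12)
  expect_equal(w[1, ] + w[3, ], 2 * pca$mean, tolerance = 1e-12)
  # full-rank reconstruction of a training subject
  y <- Z[3, ] - pca$mean
  coef <- crossprod(pca$modes, y)
  rec <- pca$mean + as.numeric(pca$modes %*% coef)
  expect_equal(rec, Z[3, ], tolerance = 1e-6)
  expect_error(mode_walk(pca, 10L), "exceeds")
})

test_that("MLCA reconstructs exactly and separates pose from shape", {
  sys <- toy_system(N = 5L, counts = c(A = 4L, B = 3L), seed = 5L)
  sm <- build_shape_matrix(sys)
  ml <- mlca(sm)
  rec <- sweep(ml$between + ml$within, 2, ml$grand_mean, "+")
  expect_lt(max(abs(rec - sm$data)), 1e-9)

  # identical centroids across subjects: between variance is zero
  sysc <- toy_system(N = 4L, counts = c(A = 3L, B = 3L), seed = 6L)
  sysc$positions <- lapply(sysc$positions, function(doms)
    lapply(doms, function(P) sweep(P, 2, colMeans(P))))
  smc <- build_shape_matrix(sysc)
  mlc <- mlca(smc)
  expect_lt(max(abs(mlc$between)), 1e-12)

  # pure per-subject translations of one domain on a constant-shape cohort:
  # within stays zero, between mode 1 explains all between variance
  base <- toy_system(N = 1L, counts = c(A = 3L, B = 3L), seed = 7L)
  shifts <- seq(-0.5, 0.5, length.out = 4L)
  syst <- toy_system(N = 4L, counts = c(A = 3L, B = 3L), seed = 7L)
  syst$positions <- lapply(seq_len(4L), function(n) {
    doms <- base$positions[[1]]
    doms[[1]] <- sweep(doms[[1]], 2, c(shifts[n], 0, 0), "+")
    doms
  })
  smt <- build_shape_matrix(syst)
  mlt <- mlca(smt)
  expect_lt(max(abs(mlt$within)), 1e-12)
  expect_equal(mlt$pca_between$ratios[1], 1, tolerance = 1e-9)

  # between share grows monotonically with injected translation magnitude
  shares <- vapply(c(0.1, 0.5, 1.5), function(s) {
    sys2 <- toy_system(N = 4L, counts = c(A = 3L, B = 3L), seed = 8L)
    sys2$positions <- lapply(seq_len(4L), function(n) {
      doms <- sys2$positions[[n]]
      doms[[1]] <- sweep(doms[[1]], 2, c(s * n, 0, 0), "+")
      doms
    })
    m <- mlca(build_shape_matrix(sys2))
    sum(m$between^2) / (sum(m$between^2) + sum(m$within^2))
  }, numeric(1))
  expect_true(all(diff(shares) > 0))

  one <- toy_system(N = 3L, counts = c(A = 4L))
  expect_error(mlca(build_shape_matrix(one)), "2 domains")
})

test_that("group scores pin the group means at -1 and +1 and are affine", {
  sys <- toy_system(N = 6L, counts = c(A = 4L),
                    labels = rep(c("pathology", "control"), each = 3L))
  sm <- build_shape_matrix(sys)
  gd <- group_difference(sm)
  expect_identical(gd$positive_group, "control")
  expect_identical(gd$negative_group, "pathology")
  mu_pos <- colMeans(sm$data[sm$labels == "control", ])
  mu_neg <- colMeans(sm$data[sm$labels == "pathology", ])
  expect_equal(score_shapes(gd, mu_pos), 1, tolerance = 1e-12)
  expect_equal(score_shapes(gd, mu_neg), -1, tolerance = 1e-12)
  expect_equal(score_shapes(gd, (mu_pos + mu_neg) / 2), 0, tolerance = 1e-12)
  # affine in z
  z1 <- sm$data[1, ]; z2 <- sm$data[4, ]
  expect_equal(score_shapes(gd, (z1 + z2) / 2),
               (score_shapes(gd, z1) + score_shapes(gd, z2)) / 2,
               tolerance = 1e-12)
  # the stored per-subject scores agree with re-scoring
  expect_equal(gd$scores, score_shapes(gd, sm$data), tolerance = 1e-12)
  # Gaussian fits use maximum-likelihood variance
  ctl <- gd$scores[sm$labels == "control"]
  expect_equal(gd$gaussians$control$sd, sqrt(mean((ctl - mean(ctl))^2)),
               tolerance = 1e-12)
  bad <- toy_system(N = 3L, counts = c(A = 2L), labels = c("a", "b", "c"))
  expect_error(group_difference(build_shape_matrix(bad)), "two groups")
})

test_that("the one-sample t-test helper matches the textbook formula", {
  x <- c(1, 2, 3, 4, 5)
  res <- shapeshared:::one_sample_t(x, 3)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_false(res$degenerate)
  # hand-computed t for a nonzero shift
  res2 <- shapeshared:::one_sample_t(x, 2)
  tref <- (mean(x) - 2) / (sd(x) / sqrt(5))
  expect_equal(res2$t, tref, tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(tref), df = 4), tolerance = 1e-12)
  # degenerate: zero variance
  same <- shapeshared:::one_sample_t(rep(2, 10), 2)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  diff <- shapeshared:::one_sample_t(rep(2, 10), 3)
  expect_equal(diff$p, 0)
})

test_that("thin-plate-spline warps reproduce exact and affine displacements", {
  m <- icosphere(2L)
  set.seed(9)
  src <- sample_surface_points(m, 20L, seed = 2L)
  # identity
  expect_equal(warp_mesh(m, src, src)$vertices, m$vertices,
               tolerance = 1e-9)
  # pure translation
  t0 <- c(0.3, -0.1, 0.25)
  w <- warp_mesh(m, src, sweep(src, 2, t0, "+"))
  expect_equal(w$vertices, sweep(m$vertices, 2, t0, "+"), tolerance = 1e-9)
  # interpolation: control points land on their targets
  tgt <- src + matrix(rnorm(60, sd = 0.05), 20, 3)
  w2 <- warp_mesh(m, src, tgt)
  probe <- triangle_mesh(src[1:4, ] * 0 + src[1:4, ],
                         matrix(c(1, 2, 3, 1, 3, 4), 2, byrow = TRUE))
  w3 <- warp_mesh(probe, src, tgt)
  expect_lt(max(abs(w3$vertices - tgt[1:4, ])), 1e-6)
  # coplanar control points are rejected
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(warp_mesh(m, flat, flat), "coplanar|singular")
})

test_that("held-out prediction stays on the new surfaces and is deterministic", {
  cohort <- tiny_two_domain_cohort(4L, radii = c(0.9, 1.0, 1.1, 1.05))
  cfg <- optimizer_config(mode = "multi_domain",
                          particles = c(left = 16L, right = 16L),
                          iterations = 30L, iterations_per_split = 8L,
                          seed = 12L)
  sys <- optimize_particles(cohort[1:3], cfg)
  sm <- build_shape_matrix(sys)
  st0 <- correspondence_stats(sm$data, 1e-12)
  st <- correspondence_stats(sm$data,
                             max(1e-5 * mean(st0$lambda), 1e-12))
  pred <- predict_heldout_particles(sys, st, cohort[4], cfg,
                                    iterations = 10L)
  expect_equal(length(pred$subjects), 1L)
  for (ki in 1:2) {
    P <- pred$positions[[1]][[ki]]
    expect_equal(nrow(P), 16L)
    expect_lt(max(point_mesh_distance(P, cohort[[4]]$domains[[ki]])), 1e-6)
  }
  pred2 <- predict_heldout_particles(sys, st, cohort[4], cfg,
                                     iterations = 10L)
  expect_identical(pred$positions, pred2$positions)
  # a held-out subject identical to a training subject lands near that
  # subject's trained particles
  pred3 <- predict_heldout_particles(sys, st, cohort[3], cfg,
                                     iterations = 25L)
  for (ki in 1:2) {
    Pt <- sys$positions[[3]][[ki]]
    Pp <- pred3$positions[[1]][[ki]]
    spacing <- mean(apply(as.matrix(dist(Pt)) +
                            diag(Inf, nrow(Pt)), 1, min))
    err <- max(sqrt(rowSums((Pp - Pt)^2)))
    expect_lt(err, 2 * spacing)
  }
})
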