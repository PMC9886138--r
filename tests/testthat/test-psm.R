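# small helper: numeric gradient of the sampling entropy by central
# differences (bandwidths held fixed, as the optimizer does within an
# iteration)
fd_sampling_gradient <- function(X, sig, extra = NULL, es = NULL,
                                 h = 1e-5) {
  g <- matrix(0, nrow(X), 3L)
  for (i in seq_len(nrow(X))) {
    for (j in 1:3) {
      Xp <- X; Xm <- X
      Xp[i, j] <- Xp[i, j] + h
      Xm[i, j] <- Xm[i, j] - h
      g[i, j] <- (sampling_entropy(Xp, sig, extra, es) -
                    sampling_entropy(Xm, sig, extra, es)) / (2 * h)
    }
  }
  g
}

test_that("the Parzen log density matches hand evaluation of the formula", {
  # one neighbour at distance 0, sigma = 1
  expect_equal(as.numeric(parzen_log_density(c(0, 0, 0),
                                             matrix(0, 1, 3), 1)),
               log((2 * pi)^(-1.5)))
  # two neighbours at distances 1 and 2, direct summation
  nb <- rbind(c(1, 0, 0), c(0, 2, 0))
  want <- log(mean(exp(-c(1, 4) / 2) / (2 * pi)^1.5))
  expect_equal(as.numeric(parzen_log_density(c(0, 0, 0), nb, 1)), want)
  # isotropy: a rigid motion of the point and all neighbours changes nothing
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(0.5, -1, 2)
  x <- c(1, 2, 3)
  v1 <- as.numeric(parzen_log_density(x, nb, 1))
  v2 <- as.numeric(parzen_log_density(as.numeric(R %*% x) + tr,
                                      sweep(nb %*% t(R), 2, tr, "+"), 1))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("sampling entropy equals brute force and behaves with scale", {
  # unit tetrahedron vertices, sigma = 1
  X <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(2)
  H <- sampling_entropy(X, 1)
  brute <- -mean(vapply(1:4, function(m)
    log(mean(exp(-rowSums(sweep(X[-m, , drop = FALSE], 2, X[m, ])^2) / 2) /
               (2 * pi)^1.5)), numeric(1)))
  expect_equal(H, brute, tolerance = 1e-12)
  # doubling all pairwise distances (sigma fixed) increases entropy
  expect_gt(sampling_entropy(2 * X, 1), H)
  # permutation invariance
  expect_equal(sampling_entropy(X[c(3, 1, 4, 2), ], 1), H)
  expect_error(sampling_entropy(X[1, , drop = FALSE], 1), "at least 2")
})

test_that("analytic sampling gradients match central finite differences", {
  set.seed(42)
  for (rep in 1:3) {
    X <- matrix(rnorm(30), 10, 3)
    sig <- runif(10, 0.5, 1.5)
    g <- sampling_gradient(X, sig)
    fd <- fd_sampling_gradient(X, sig)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
  # with frozen extra neighbours (conditional form): gradient only on X
  X <- matrix(rnorm(24), 8, 3)
  E <- matrix(rnorm(9), 3, 3)
  sig <- rep(0.8, 8)
  es <- rep(0.6, 3)
  g <- sampling_gradient(X, sig, E, es)
  fd <- fd_sampling_gradient(X, sig, E, es)
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
})

test_that("two particles repel equally and oppositely; contour symmetry cancels", {
  X <- rbind(c(-0.5, 0, 0), c(0.5, 0, 0))
  g <- sampling_gradient(X, 1)
  expect_equal(g[1, ], -g[2, ], tolerance = 1e-12)
  expect_equal(g[1, 2:3], c(0, 0), tolerance = 1e-12)
  expect_lt(g[1, 1], 0)   # entropy grows as they separate
  # an organ particle exactly between two symmetric contour particles feels
  # no net contour repulsion
  org <- rbind(c(0, 0, 0), c(0, 0, 10))   # second particle far away
  ctr <- rbind(c(-1, 0, 0), c(1, 0, 0))
  g2 <- sampling_gradient(org, c(1, 1), ctr, c(1, 1))
  expect_lt(abs(g2[1, 1]), 1e-9)
})

test_that("correspondence entropy equals the dense regularized log-determinant", {
  set.seed(5)
  for (rep in 1:3) {
    Z <- matrix(rnorm(60), 5, 12)
    alpha <- 10^runif(1, -6, -2)
    st <- correspondence_stats(Z, alpha)
    H <- correspondence_entropy(st)
    Sigma <- stats::cov(Z)          # dense 12 x 12 sample covariance
    dense <- 0.5 * determinant(Sigma + alpha * diag(12),
                               logarithm = TRUE)$modulus
    expect_equal(H, as.numeric(dense), tolerance = 1e-9)
  }
  # translation invariance
  Z <- matrix(rnorm(60), 5, 12)
  st1 <- correspondence_stats(Z, 1e-4)
  st2 <- correspondence_stats(sweep(Z, 2, rnorm(12), "+") * 0 + Z +
                                rep(1, 5) %o% rnorm(12), 1e-4)
  expect_equal(correspondence_entropy(st1), correspondence_entropy(st2),
               tolerance = 1e-9)
  # all subjects identical: every eigenvalue is 0, entropy = D/2 log alpha
  Zc <- matrix(1, 4, 1) %*% matrix(rnorm(6), 1, 6)
  stc <- correspondence_stats(Zc, 1e-3)
  expect_equal(correspondence_entropy(stc), 0.5 * 6 * log(1e-3),
               tolerance = 1e-9)
})

test_that("correspondence gradients vanish at the mean and match differences", {
  set.seed(6)
  Z <- matrix(rnorm(48), 4, 12)
  alpha <- 1e-3
  st <- correspondence_stats(Z, alpha)
  mu <- colMeans(Z)
  expect_equal(correspondence_gradient(st, mu), rep(0, 12),
               tolerance = 1e-12)
  # two subjects symmetric about the mean get equal and opposite gradients
  Z2 <- rbind(mu + c(1, rep(0, 11)), mu - c(1, rep(0, 11)))
  g1 <- correspondence_gradient(st, Z2[1, ])
  g2 <- correspondence_gradient(st, Z2[2, ])
  expect_equal(g1, -g2, tolerance = 1e-12)
  # finite differences of H(Z) w.r.t. single coordinates of one subject;
  # the perturbed spectrum is recomputed densely each time
  h <- 1e-5
  dense_H <- function(Zm) {
    l <- pmax(eigen(stats::cov(Zm), symmetric = TRUE,
                    only.values = TRUE)$values, 0)
    0.5 * sum(log(l + alpha))
  }
  for (j in c(1L, 5L, 12L)) {
    Zp <- Z; Zm <- Z
    Zp[2, j] <- Zp[2, j] + h
    Zm[2, j] <- Zm[2, j] - h
    fd <- (dense_H(Zp) - dense_H(Zm)) / (2 * h)
    an <- correspondence_gradient(st, Z[2, ])[j]
    expect_lt(abs(fd - an) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("bandwidths equal k-NN distances with scale equivariance and floor", {
  # regular grid, k = 1: sigma equals the spacing for interior particles
  g <- expand.grid(x = 0:4, y = 0:4)
  X <- cbind(g$x, g$y, 0) * 0.7
  sig <- update_bandwidths(X, k = 1L, bbox_diag = 100)
  expect_equal(unname(sig), rep(0.7, 25), tolerance = 1e-12)
  # doubling all coordinates doubles sigma
  set.seed(7)
  Y <- matrix(rnorm(60), 20, 3)
  s1 <- update_bandwidths(Y, k = 6L)
  s2 <- update_bandwidths(2 * Y, k = 6L)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # brute-force oracle of the documented rule: k-NN distance capped at
  # 3x the nearest-neighbour distance
  k <- 4L
  sk <- update_bandwidths(Y, k = k, bbox_diag = 1e-9)
  brute <- vapply(seq_len(nrow(Y)), function(i) {
    d <- sort(sqrt(rowSums(sweep(Y[-i, , drop = FALSE], 2, Y[i, ])^2)))
    min(d[k], 3 * d[1])
  }, numeric(1))
  expect_equal(unname(sk), brute, tolerance = 1e-12)
})

test_that("binary splitting reaches power-of-two targets on every subject", {
  cohort <- tiny_two_domain_cohort(3L)
  cfg <- optimizer_config(mode = "multi_domain",
                          particles = c(left = 8L, right = 8L),
                          iterations_per_split = 3L, seed = 2L)
  sys <- initialize_by_splitting(cohort, cfg)
  expect_equal(unname(sys$counts), c(8L, 8L))
  for (n in seq_along(cohort)) {
    for (ki in 1:2) {
      P <- sys$positions[[n]][[ki]]
      expect_equal(nrow(P), 8L)
      dom <- cohort[[n]]$domains[[ki]]
      expect_lt(max(point_mesh_distance(P, dom)), 1e-6)
    }
  }
  # determinism: same seed, same particles
  sys2 <- initialize_by_splitting(cohort, cfg)
  expect_identical(sys$positions, sys2$positions)
  expect_error(optimizer_config(particles = c(left = 6L)), "powers of two")
})

test_that("two particles on a sphere drift to near-antipodal positions", {
  sphere <- multi_organ_sample("s", list(S = icosphere(3L)))
  cfg <- optimizer_config(mode = "single", particles = c(S = 2L),
                          iterations_per_split = 80L, seed = 3L)
  sys <- initialize_by_splitting(list(sphere), cfg)
  P <- sys$positions[[1]][[1]]
  chord <- sqrt(sum((P[1, ] - P[2, ])^2))
  expect_gt(chord, 1.9)
})

test_that("sampling-only relaxation spreads particles uniformly on a sphere", {
  sphere <- multi_organ_sample("s", list(S = icosphere(3L)))
  cfg <- optimizer_config(mode = "single", particles = c(S = 128L),
                          iterations_per_split = 12L, seed = 4L)
  sys <- initialize_by_splitting(list(sphere), cfg)
  sys <- shapeshared:::relax_sampling_only(sys, list(sphere), cfg, 40L)
  P <- sys$positions[[1]][[1]]
  d2 <- as.matrix(dist(P))
  diag(d2) <- Inf
  nn <- apply(d2, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.25)
  expect_lt(max(point_mesh_distance(P, sphere$domains$S)), 1e-6)
})

test_that("identical subjects stay in perfect correspondence", {
  one <- icosphere(2L)
  cohort <- lapply(c("a", "b", "c"), function(id)
    multi_organ_sample(id, list(S = one)))
  cfg <- optimizer_config(mode = "single", particles = c(S = 16L),
                          iterations = 10L, iterations_per_split = 4L,
                          seed = 5L)
  sys <- optimize_particles(cohort, cfg)
  for (n in 2:3)
    expect_lt(max(abs(sys$positions[[n]][[1]] - sys$positions[[1]][[1]])),
              1e-3)
  # energy log has exactly one row of lagged statistics per iteration
  el <- attr(sys, "energy_log")
  expect_equal(nrow(el), 10L)
  expect_true(all(is.finite(el$energy)))
})

test_that("optimization is bit-stable under a fixed seed", {
  cohort <- tiny_two_domain_cohort(3L)
  cfg <- optimizer_config(mode = "multi_domain",
                          particles = c(left = 8L, right = 8L),
                          iterations = 5L, iterations_per_split = 2L,
                          seed = 11L)
  s1 <- optimize_particles(cohort, cfg)
  s2 <- optimize_particles(cohort, cfg)
  expect_identical(s1$positions, s2$positions)
})

test_that("contour particles keep a single degree of freedom", {
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  ct <- contour3d(cbind(cos(theta), sin(theta), 0))
  samples <- lapply(c("a", "b"), function(id)
    multi_organ_sample(id, list(C = ct)))
  cfg <- optimizer_config(mode = "single", particles = c(C = 16L),
                          iterations = 5L, iterations_per_split = 5L,
                          seed = 6L)
  sys <- optimize_particles(samples, cfg)
  P <- sys$positions[[1]][[1]]
  # particles stay on the polyline
  d <- attr(closest_point_on_contour(P, ct), "dist")
  expect_lt(max(d), 1e-6)
  # and spread beyond their initial cluster
  ang <- sort(atan2(P[, 2], P[, 1]))
  expect_gt(max(diff(c(ang, ang[1] + 2 * pi))), 0)
  expect_gt(length(unique(round(ang, 6))), 8L)
})
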