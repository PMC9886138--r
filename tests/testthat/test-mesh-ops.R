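test_that("point-mesh distances and projections match the brute-force oracle", {
  set.seed(11)
  m <- icosphere(1L)                       # 80 faces
  P <- matrix(rnorm(300), ncol = 3L) * 1.5
  d <- point_mesh_distance(P, m)
  q <- closest_point_on_mesh(P, m)
  for (i in seq_len(nrow(P))) {
    expect_lt(abs(d[i] - bf_point_mesh_dist(P[i, ], m)), 1e-9)
    expect_lt(abs(sqrt(sum((q[i, ] - P[i, ])^2)) - d[i]), 1e-9)
  }
  # the returned point lies on some triangle
  expect_lt(max(point_mesh_distance(q, m)), 1e-9)
})

test_that("distance is exact on axis-aligned configurations", {
  tri <- single_triangle()
  expect_equal(point_mesh_distance(c(0, 0, 2), tri), 2.0)
  expect_equal(point_mesh_distance(c(0.25, 0.25, 0), tri), 0.0)
  on_surface <- c(0.2, 0.3, 0)
  expect_equal(drop(closest_point_on_mesh(on_surface, tri)), on_surface,
               ignore_attr = TRUE)
})

test_that("contour projection matches the per-segment oracle", {
  set.seed(12)
  theta <- sort(runif(50, 0, 2 * pi))
  ct <- contour3d(cbind(cos(theta), sin(theta), sin(3 * theta) * 0.2))
  P <- matrix(rnorm(150), ncol = 3L)
  q <- closest_point_on_contour(P, ct)
  d <- attr(q, "dist")
  for (i in seq_len(nrow(P)))
    expect_lt(abs(d[i] - bf_point_contour_dist(P[i, ], ct)), 1e-9)
  # a point on a segment projects to itself
  mid <- (ct$vertices[1, ] + ct$vertices[2, ]) / 2
  expect_equal(drop(closest_point_on_contour(mid, ct)), mid,
               tolerance = 1e-12, ignore_attr = TRUE)
  # a point off the plane of a planar square keeps its planar projection
  sq <- contour3d(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  pr <- closest_point_on_contour(c(0, 0, 1), sq)
  expect_equal(drop(pr)[3], 0)
  expect_gte(attr(pr, "dist"), 1)
})

test_that("boundary loops are ordered, closed and sized as the topology dictates", {
  expect_error(boundary_loop(icosphere(1L)), "watertight")
  n <- 6L
  g <- flat_grid(n)
  loop <- boundary_loop(g)
  expect_equal(nrow(loop$vertices), 4L * (n - 1L))
  # count edges with exactly one incident face (independent oracle)
  he <- shapeshared:::half_edges(g$faces)
  expect_equal(sum(table(he$key) == 1L), 4L * (n - 1L))
  # consecutive loop vertices share a boundary edge
  idx <- attr(loop, "indices")
  bkeys <- names(which(table(he$key) == 1L))
  pair_keys <- paste(pmin(idx, c(idx[-1], idx[1])),
                     pmax(idx, c(idx[-1], idx[1])))
  expect_true(all(pair_keys %in% bkeys))
  tri_loop <- boundary_loop(single_triangle())
  expect_equal(nrow(tri_loop$vertices), 3L)
})

test_that("laplacian smoothing honours its fixed points and contracts noise", {
  g <- flat_grid(7L)
  expect_equal(laplacian_smooth(g, iterations = 0L), g)
  # a regular grid is a fixed point of the uniform Laplacian
  sm <- laplacian_smooth(g, iterations = 10L)
  expect_lt(max(abs(sm$vertices - g$vertices)), 1e-9)
  # noisy sphere: radial spread strictly decreases (boundary-free mesh)
  set.seed(3)
  s <- icosphere(2L)
  noisy <- triangle_mesh(s$vertices * (1 + rnorm(nrow(s$vertices), 0, 0.05)),
                         s$faces)
  out <- laplacian_smooth(noisy, iterations = 30L, relaxation = 1)
  expect_lt(sd(sqrt(rowSums(out$vertices^2))),
            sd(sqrt(rowSums(noisy$vertices^2))))
  # per-iteration displacement is bounded by relaxation x max neighbour dist
  r <- 0.37
  one <- laplacian_smooth(noisy, iterations = 1L, relaxation = r)
  disp <- sqrt(rowSums((one$vertices - noisy$vertices)^2))
  maxnb <- max(edge_lengths(noisy))
  expect_true(all(disp <= r * maxnb + 1e-12))
})

test_that("isotropic remeshing approaches the target while conforming to the input", {
  # already-uniform grid at its own mean edge length: CV essentially unchanged
  g <- flat_grid(8L)
  out <- isotropic_remesh(g, mean(edge_lengths(g)), iterations = 3L)
  expect_lt(abs(edge_cv(out) - edge_cv(g)), 0.05)

  # halving the edge length roughly quadruples the face count
  s <- icosphere(2L)
  half <- mean(edge_lengths(s)) / 2
  fine <- isotropic_remesh(s, half, iterations = 5L)
  ratio <- nrow(fine$faces) / nrow(s$faces)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
  expect_lt(mean(abs(mean(edge_lengths(fine)) - half)) / half, 0.25)
  # conformance: every output vertex sits on the input surface
  expect_lt(max(point_mesh_distance(fine$vertices, s)), 1e-6)

  # strongly anisotropic grid: edge-length CV drops by at least half
  aniso <- flat_grid(5L, sx = 1, sy = 10)
  re <- isotropic_remesh(aniso, 1, iterations = 10L)
  expect_lt(edge_cv(re), 0.5 * edge_cv(aniso))
  expect_gt(min(face_areas(re)), 0)

  expect_error(isotropic_remesh(s, 1e-4, max_vertices = 1e4), "cap")
})

test_that("remeshed meshes keep finite edge ratios and positive areas", {
  s <- icosphere(2L, radius = 2)
  out <- isotropic_remesh(s, 0.35, iterations = 5L)
  el <- edge_lengths(out)
  expect_true(is.finite(max(el) / min(el)))
  expect_gt(min(face_areas(out)), 1e-12)
})
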