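test_that("close-triangle detection is exact against per-face evaluation", {
  g1 <- flat_grid(6L)
  # second grid with a linearly increasing gap crossing the threshold
  g2 <- g1
  gap <- 0.002 + 0.004 * g2$vertices[, 1] / max(g2$vertices[, 1])
  g2 <- triangle_mesh(cbind(g2$vertices[, 1:2], gap), g2$faces)
  thr <- 0.004
  got <- find_close_triangles(g1, g2, thr)
  vd <- vapply(seq_len(nrow(g1$vertices)), function(i)
    bf_point_mesh_dist(g1$vertices[i, ], g2), numeric(1))
  close_v <- vd < thr
  want <- which(close_v[g1$faces[, 1]] & close_v[g1$faces[, 2]] &
                  close_v[g1$faces[, 3]])
  expect_identical(got, want)
  expect_gt(length(got), 0L)
  expect_lt(length(got), nrow(g1$faces))
})

test_that("coincident grids are all close; separated grids are not", {
  g1 <- flat_grid(5L)
  expect_identical(find_close_triangles(g1, g1, 1e-3),
                   seq_len(nrow(g1$faces)))
  g2 <- triangle_mesh(cbind(g1$vertices[, 1:2], 0.02), g1$faces)
  expect_length(find_close_triangles(g1, g2, 0.01), 0L)
})

test_that("enlarging the threshold never shrinks the close set", {
  pair <- make_peanut(1, c(1, 1, 1), 1, resolution = 2L)
  prev <- integer(0)
  for (thr in c(0.01, 0.05, 0.1, 0.3)) {
    cur <- find_close_triangles(pair$A, pair$B, thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("extraction partitions faces and snaps the opening of M onto A_r", {
  pair <- make_peanut(1, c(1, 1, 1), 1, resolution = 3L)
  target <- mean(c(edge_lengths(pair$A), edge_lengths(pair$B)))
  A_m <- isotropic_remesh(pair$A, target, 5L)
  B_m <- isotropic_remesh(pair$B, target, 5L)
  cfg <- extraction_config(threshold = 0.5 * target)
  ext <- extract_shared_surface(A_m, B_m, cfg)
  # partition: M and B_r faces together account for all of B_m's faces
  expect_equal(nrow(ext$M$faces) + nrow(ext$B_r$faces), nrow(B_m$faces))
  # boundary vertices of M lie on A_r's boundary polyline after snapping
  mb <- shapeshared:::boundary_vertices(ext$M)
  be <- shapeshared:::boundary_edge_matrix(ext$A_r)
  seg_d <- shapeshared:::cpp_closest_on_segments(
    ext$M$vertices[mb, , drop = FALSE],
    ext$A_r$vertices[be[, 1], , drop = FALSE],
    ext$A_r$vertices[be[, 2], , drop = FALSE])$dist
  expect_lt(max(seg_d), 1e-9)
  # approximate symmetric coverage of the two close sets
  expect_lt(abs(ext$report$area[["A_s"]] - ext$report$area[["M"]]),
            2 * target * contour_length(boundary_loop(ext$M)))
})

test_that("disjoint inputs raise an extraction error", {
  s1 <- icosphere(2L, 1, c(-3, 0, 0))
  s2 <- icosphere(2L, 1, c(3, 0, 0))
  expect_error(extract_shared_surface(s1, s2, extraction_config(threshold = 0.1)),
               "no shared boundary")
})

test_that("the pipeline yields four parts with a closed contour on M's boundary", {
  pair <- make_peanut(1, c(1, 1, 1), 1, resolution = 3L)
  s <- extract_shared_boundary(pair$A, pair$B, subject_id = "demo",
                               label = "control")
  expect_s3_class(s, "multi_organ_sample")
  expect_identical(names(s$domains), c("A_r", "M", "B_r", "C"))
  kinds <- vapply(s$domains, inherits, logical(1), "contour3d")
  expect_identical(unname(kinds), c(FALSE, FALSE, FALSE, TRUE))
  expect_true(s$domains$C$closed)
  # contour lies exactly on M's boundary (it is M's longest boundary loop)
  idx <- attr(s$domains$C, "indices")
  expect_equal(s$domains$C$vertices, s$domains$M$vertices[idx, ])
  # extraction-stage shared-surface area matches the analytic cap within 5%
  expect_lt(abs(attr(s, "report")$area[["M"]] - pi) / pi, 0.05)
  # contour length close to the analytic intersection circle
  rho <- sqrt(1 - 0.25)
  expect_lt(abs(contour_length(s$domains$C) - 2 * pi * rho) / (2 * pi * rho),
            0.05)
})

test_that("zero smoothing iterations leave the extraction output untouched", {
  pair <- make_peanut(0.9, c(1.1, 1.1, 1.1), 1, resolution = 2L)
  cfg0 <- extraction_config(smooth_iterations = 0L, remesh_iterations = 3L)
  s0 <- extract_shared_boundary(pair$A, pair$B, cfg0)
  target <- mean(c(edge_lengths(pair$A), edge_lengths(pair$B)))
  A_m <- isotropic_remesh(pair$A, target, 3L)
  B_m <- isotropic_remesh(pair$B, target, 3L)
  ext <- extract_shared_surface(A_m, B_m,
                                extraction_config(threshold = 0.5 * target))
  expect_equal(s0$domains$A_r$vertices, ext$A_r$vertices)
  expect_equal(s0$domains$M$vertices, ext$M$vertices)
  expect_equal(s0$domains$B_r$vertices, ext$B_r$vertices)
})

test_that("every generated sample survives extraction with defaults", {
  extracted <- extracted_peanut_cohort()
  expect_length(extracted, 30L)
  for (s in extracted) {
    expect_identical(names(s$domains), c("A_r", "M", "B_r", "C"))
    expect_gt(nrow(s$domains$M$faces), 0L)
    expect_true(s$domains$C$closed)
    expect_gte(nrow(s$domains$C$vertices), 3L)
  }
})
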