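test_that("a minimal OBJ mesh loads with its vertices and face intact", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_equal(m$vertices[2, ], c(1, 0, 0))
})

test_that("STL loses shared-vertex topology and merging recovers it", {
  cube <- cube_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path)
  # raw STL stores 3 vertices per facet: 36 of them for 12 facets
  raw <- shapeshared:::read_stl(path)
  expect_equal(nrow(raw$vertices), 36L)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
  # brute-force dedup oracle at tolerance 1e-9: pairwise exact matches
  d <- as.matrix(dist(raw$vertices))
  n_unique <- sum(!duplicated(apply(d < 1e-9, 1, which.max)))
  expect_equal(nrow(m$vertices), n_unique)
})

test_that("round trips preserve geometry to 1e-6 and connectivity exactly", {
  m <- icosphere(2L, radius = 1.37, center = c(0.3, -0.2, 0.9))
  for (ext in c(".ply", ".obj", ".stl", ".vtk", ".vtp")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$faces), nrow(m$faces), info = ext)
    if (ext == ".stl") {
      # STL stores per-facet vertices, so vertex order is not preserved;
      # compare the two surfaces instead
      expect_lt(max(point_mesh_distance(m2$vertices, m)), 1e-6)
      expect_lt(max(point_mesh_distance(m$vertices, m2)), 1e-6)
    } else {
      expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
      expect_identical(m2$faces, m$faces)
    }
  }
})

test_that("OBJ and PLY writes of the same mesh agree exactly", {
  m <- flat_grid(4L)
  p1 <- withr::local_tempfile(fileext = ".obj")
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, p1)
  write_mesh(m, p2)
  m1 <- read_mesh(p1)
  m2 <- read_mesh(p2)
  expect_identical(m1$faces, m2$faces)
  expect_equal(m1$vertices, m2$vertices)
})

test_that("binary PLY and binary STL are readable", {
  m <- icosphere(1L)
  ply <- withr::local_tempfile(fileext = ".ply")
  con <- file(ply, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               paste("element vertex", nrow(m$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in seq_len(nrow(m$vertices)))
    writeBin(m$vertices[i, ], con, size = 8L, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4L,
             endian = "little")
  }
  close(con)
  m2 <- read_mesh(ply)
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices)

  stl <- withr::local_tempfile(fileext = ".stl")
  con <- file(stl, "wb")
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(m$faces)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    tri <- m$vertices[m$faces[i, ], ]
    writeBin(c(0, 0, 0, as.numeric(t(tri))), con, size = 4L,
             endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  close(con)
  m3 <- read_mesh(stl)
  expect_equal(nrow(m3$faces), nrow(m$faces))
  expect_equal(sort(unique(as.vector(round(m3$vertices, 5)))),
               sort(unique(as.vector(round(m$vertices, 5)))))
})

test_that("degenerate inputs are rejected with clear errors", {
  empty <- withr::local_tempfile(fileext = ".obj")
  file.create(empty)
  expect_error(read_mesh(empty), "empty")
  expect_error(read_mesh(file.path(tempdir(), "nope.obj")), "cannot read")
  novtx <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0"), novtx)
  expect_error(read_mesh(novtx), "no faces")
  expect_error(write_mesh(triangle_mesh(diag(3), matrix(integer(0), 0, 3)),
                          withr::local_tempfile(fileext = ".ply")),
               "0 faces")
  expect_error(triangle_mesh(diag(3), matrix(c(1, 1, 2), 1)), "degenerate")
  expect_error(triangle_mesh(diag(3), matrix(c(1, 2, 4), 1)), "out of range")
})

test_that("contours round-trip through the plain-text format", {
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  ct <- contour3d(cbind(cos(theta), sin(theta), 0.5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_contour(ct, path)
  ct2 <- read_contour(path)
  expect_equal(ct2$vertices, ct$vertices)
  expect_true(ct2$closed)
  # vtk polyline variant writes without error
  write_contour(ct, withr::local_tempfile(fileext = ".vtk"))
  expect_error(contour3d(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "zero-length")
  expect_error(contour3d(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
})
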