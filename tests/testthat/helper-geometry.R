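# small geometric fixtures and independent brute-force oracles, all built in
# code at test time

# n x n flat triangulated grid in the z = 0 plane, spacing sx / sy
flat_grid <- function(n = 5L, sx = 1, sy = 1) {
  g <- expand.grid(x = seq_len(n) - 1L, y = seq_len(n) - 1L)
  V <- cbind(g$x * sx, g$y * sy, 0)
  idx <- function(i, j) (j - 1L) * n + i
  faces <- list()
  for (j in seq_len(n - 1L)) {
    for (i in seq_len(n - 1L)) {
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j),
                                       idx(i + 1L, j + 1L))
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L),
                                       idx(i, j + 1L))
    }
  }
  triangle_mesh(V, do.call(rbind, faces))
}

# unit cube as 8 shared vertices / 12 triangles
cube_mesh <- function(side = 1) {
  V <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  colnames(V) <- NULL
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  triangle_mesh(V, F)
}

single_triangle <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                matrix(1:3, 1L))
}

# independent exact point-triangle distance: unconstrained quadratic solve in
# the triangle plane, falling back to the three clamped edge minimizations
bf_point_triangle_dist <- function(p, a, b, c3) {
  e1 <- b - a
  e2 <- c3 - a
  d <- p - a
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(e1 * d), sum(e2 * d))
  uv <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
  best <- Inf
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
    q <- a + uv[1] * e1 + uv[2] * e2
    best <- sqrt(sum((p - q)^2))
  }
  seg <- function(s0, s1) {
    v <- s1 - s0
    t <- sum((p - s0) * v) / sum(v * v)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (s0 + t * v))^2))
  }
  min(best, seg(a, b), seg(b, c3), seg(c3, a))
}

bf_point_mesh_dist <- function(p, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f) {
    tri <- mesh$faces[f, ]
    bf_point_triangle_dist(p, mesh$vertices[tri[1], ],
                           mesh$vertices[tri[2], ], mesh$vertices[tri[3], ])
  }, numeric(1)))
}

bf_point_contour_dist <- function(p, contour) {
  v <- contour$vertices
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], if (contour$closed) 1L)
  min(vapply(seq_along(nxt), function(i) {
    s0 <- v[i, ]; s1 <- v[nxt[i], ]
    w <- s1 - s0
    t <- min(max(sum((p - s0) * w) / sum(w * w), 0), 1)
    sqrt(sum((p - (s0 + t * w))^2))
  }, numeric(1)))
}

edge_cv <- function(mesh) {
  el <- edge_lengths(mesh)
  stats::sd(el) / mean(el)
}
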