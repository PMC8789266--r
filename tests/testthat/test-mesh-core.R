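test_that("duplicate vertices are merged and STL round-trips preserve geometry", {
  cube <- cube_mesh()
  expect_equal(nrow(cube$vertices), 8)
  expect_equal(nrow(cube$faces), 12)

  # binary round trip: STL stores each vertex once per facet, so writing and
  # reloading exercises the duplicate merge
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, p)
  back <- read_stl(p)
  expect_equal(nrow(back$vertices), 8)
  expect_equal(nrow(back$faces), 12)
  expect_equal(surface_area(back), 6, tolerance = 1e-6)

  # coordinates preserved to 1e-6 mm through save -> load
  m <- dental_mesh(tetra_vertices * 3.7 + 0.123, tetra_faces)
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, p2)
  m2 <- read_stl(p2)
  expect_equal(nrow(m2$vertices), nrow(m$vertices))
  d <- sqrt(rowSums((m2$vertices[order(m2$vertices[, 1]), ] -
    m$vertices[order(m$vertices[, 1]), ])^2))
  expect_lt(max(d), 1e-6 + 1e-5) # float32 storage at mm scale
})

test_that("ASCII and binary encodings of the same solid load identically", {
  m <- dental_mesh(tetra_vertices, tetra_faces)
  pa <- withr::local_tempfile(fileext = ".stl")
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, pa, format = "ascii")
  write_stl(m, pb, format = "binary")
  ma <- read_stl(pa)
  mb <- read_stl(pb)
  expect_equal(ma$faces, mb$faces)
  expect_equal(ma$vertices, mb$vertices, tolerance = 1e-6)
})

test_that("corrupt and empty STL files are rejected", {
  p <- withr::local_tempfile(fileext = ".stl")
  # binary header declaring zero triangles
  con <- file(p, "wb")
  writeBin(charToRaw(sprintf("%-80s", "empty")), con)
  writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_stl(p), "zero triangles")

  p2 <- withr::local_tempfile(fileext = ".stl")
  writeLines("this is not an stl file", p2)
  expect_error(read_stl(p2), "cannot parse|corrupt")
  expect_error(read_stl(file.path(tempdir(), "nope.stl")), "exist")
})

test_that("adjacency is symmetric, complete, and matches a brute-force scan", {
  cube <- cube_mesh()
  adj <- build_adjacency(cube)
  # every cube face has exactly 3 neighbours
  expect_true(all(rowSums(!is.na(adj$face_adj)) == 3))
  # symmetry
  for (f in seq_len(nrow(cube$faces))) {
    for (nb in adj$face_adj[f, ]) {
      if (!is.na(nb)) expect_true(f %in% adj$face_adj[nb, ])
    }
  }

  # two disjoint triangles share nothing
  m2 <- dental_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5), c(6, 5, 5), c(5, 6, 5)),
    rbind(c(1, 2, 3), c(4, 5, 6))
  )
  a2 <- build_adjacency(m2)
  expect_true(all(is.na(a2$face_adj)))

  # sphere mesh adjacency equals the O(F^2) all-pairs shared-edge oracle
  sp <- sphere_mesh(1, 0.45)
  a <- build_adjacency(sp)
  f <- sp$faces
  for (i in seq_len(nrow(f))) {
    nbs <- integer(0)
    for (j in seq_len(nrow(f))) {
      if (i != j && length(intersect(f[i, ], f[j, ])) == 2) nbs <- c(nbs, j)
    }
    expect_setequal(a$face_adj[i, !is.na(a$face_adj[i, ])], nbs)
  }
})

test_that("surface area is exact on knowns, matches the oracle, and is additive", {
  cube <- cube_mesh()
  expect_equal(surface_area(cube), 6)
  tri <- dental_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), rbind(1:3))
  expect_equal(surface_area(tri), 6)

  sp <- sphere_mesh(1, 0.3)
  # direct half-cross-product summation oracle
  v <- sp$vertices
  f <- sp$faces
  oracle <- 0
  for (i in seq_len(nrow(f))) {
    e1 <- v[f[i, 2], ] - v[f[i, 1], ]
    e2 <- v[f[i, 3], ] - v[f[i, 1], ]
    cr <- c(
      e1[2] * e2[3] - e1[3] * e2[2],
      e1[3] * e2[1] - e1[1] * e2[3],
      e1[1] * e2[2] - e1[2] * e2[1]
    )
    oracle <- oracle + 0.5 * sqrt(sum(cr^2))
  }
  expect_equal(surface_area(sp), oracle, tolerance = 1e-9)

  # additivity over disjoint subsets
  s1 <- seq_len(nrow(f) %/% 2)
  s2 <- setdiff(seq_len(nrow(f)), s1)
  expect_equal(surface_area(sp, s1) + surface_area(sp, s2), surface_area(sp))
  expect_error(surface_area(sp, nrow(f) + 1), "bounds")
})

test_that("smoothing preserves vertex and face indexing", {
  sp <- sphere_mesh(1, 0.35)
  sm <- smooth_mesh(sp, 2)
  expect_equal(dim(sm$vertices), dim(sp$vertices))
  expect_identical(sm$faces, sp$faces)
  # shrinkage is modest (Taubin is volume-preserving to first order)
  expect_gt(surface_area(sm) / surface_area(sp), 0.9)
})
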