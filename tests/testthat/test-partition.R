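test_that("edge curvature signs convex folds positive and creases negative", {
  cube <- cube_mesh()
  cv <- edge_curvature(cube, build_adjacency(cube))
  # all 12 fold edges of a cube exterior are convex right angles; the face
  # diagonals are flat
  expect_true(all(cv >= -1e-9))
  expect_equal(sort(unique(round(as.numeric(cv), 6))), c(0, round(pi / 2, 6)))

  flat <- grid_mesh(8, 8, 1)
  cvf <- edge_curvature(flat, build_adjacency(flat))
  expect_lt(max(abs(as.numeric(cvf))), 1e-9)

  vg <- v_groove_mesh()
  adj <- build_adjacency(vg)
  cvg <- as.numeric(edge_curvature(vg, adj))
  # edges along the crease line (both endpoints at x = 0) are concave ~ pi/2
  crease_edges <- which(
    vg$vertices[adj$edges[, 1], 1] == 0 & vg$vertices[adj$edges[, 2], 1] == 0
  )
  expect_true(length(crease_edges) > 0)
  expect_true(all(cvg[crease_edges] < 0))
  expect_equal(unique(round(cvg[crease_edges], 6)), round(-pi / 2, 6))
})

test_that("region growing recovers a single tooth and flags spills", {
  # one isolated canine on the base
  spec <- arch_spec(
    jaw = "mandibular", dentition = "permanent",
    missing_teeth = paste0(
      rep(c("LL", "LR"), each = 8),
      c(8:1, 1:8)
    )[-c(6)], # keep LL3 only
    noise_sd = 0, resolution = 0.5, seed = 3
  )
  gen <- generate_arch(spec)
  expect_equal(nrow(gen$truth$teeth), 1)
  mesh <- smooth_mesh(gen$mesh, 2)
  adj <- build_adjacency(mesh)
  fr <- arch_frame(colMeans(mesh$vertices), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pk <- find_peaks(mesh, adj, fr)
  cv <- edge_curvature(mesh, adj)
  conc <- vertex_concavity(mesh, adj)
  blob <- grow_tooth_region(mesh, adj, cv, pk[1, ], fr, concavity = conc)
  expect_false(blob$spilled)
  mask <- gen$truth$masks[[1]]
  jac <- length(intersect(blob$faces, mask)) / length(union(blob$faces, mask))
  expect_gte(jac, 0.9)

  # a peak on a smooth slab meets no crease: the travel cap fires
  slab <- grid_mesh(61, 61, 1, function(x, y) 0.001 * ((x - 30)^2 + (y - 30)^2) * -1)
  sadj <- build_adjacency(slab)
  sfr <- arch_frame(colMeans(slab$vertices), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  apex <- which.max(slab$vertices[, 3])
  sblob <- grow_tooth_region(
    mesh = slab, adjacency = sadj,
    curvature = edge_curvature(slab, sadj),
    peak = list(
      vertex = apex, x = slab$vertices[apex, 1],
      y = slab$vertices[apex, 2], z = slab$vertices[apex, 3]
    ),
    frame = sfr, max_travel = 12
  )
  expect_true(sblob$spilled)

  expect_error(
    grow_tooth_region(mesh, adj, cv, list(vertex = 10^7), fr),
    "not part of the mesh"
  )
})

test_that("two teeth separated by a crease grow disjoint blobs", {
  spec <- arch_spec(
    jaw = "mandibular", dentition = "permanent",
    missing_teeth = setdiff(
      paste0(rep(c("LL", "LR"), each = 8), c(8:1, 1:8)),
      c("LL4", "LL3")
    ),
    noise_sd = 0, seed = 4
  )
  gen <- generate_arch(spec)
  mesh <- smooth_mesh(gen$mesh, 2)
  adj <- build_adjacency(mesh)
  fr <- arch_frame(colMeans(mesh$vertices), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pk <- find_peaks(mesh, adj, fr)
  cv <- edge_curvature(mesh, adj)
  conc <- vertex_concavity(mesh, adj)
  masks <- gen$truth$masks
  b1 <- NULL
  b2 <- NULL
  for (i in seq_len(nrow(pk))) {
    b <- grow_tooth_region(mesh, adj, cv, pk[i, ], fr, concavity = conc)
    mv1 <- unique(as.vector(mesh$faces[masks[[1]], ]))
    if (pk$vertex[i] %in% mv1 && is.null(b1)) b1 <- b
    mv2 <- unique(as.vector(mesh$faces[masks[[2]], ]))
    if (pk$vertex[i] %in% mv2 && is.null(b2)) b2 <- b
  }
  expect_false(is.null(b1))
  expect_false(is.null(b2))
  expect_length(intersect(b1$faces, b2$faces), 0)
})

test_that("jawline fitting recovers quadratics and rejects degenerate input", {
  t <- seq(-30, 30, length.out = 25)
  pk <- tibble::tibble(t = t, ap = 0.05 * t^2 + 2, spilled = FALSE)
  jl <- fit_jawline(pk)
  expect_equal(jl$a, 0.05, tolerance = 1e-6)
  expect_equal(jl$b, 0, tolerance = 1e-6)
  expect_equal(jl$c, 2, tolerance = 1e-6)

  set.seed(9)
  pk20 <- tibble::tibble(
    t = seq(-30, 30, length.out = 20),
    spilled = FALSE
  )
  pk20$ap <- 0.05 * pk20$t^2 + 2 + rnorm(20, 0, 0.3)
  jln <- fit_jawline(pk20)
  expect_gte(jln$residual_rms, 0.15)
  expect_lte(jln$residual_rms, 0.6)

  expect_error(fit_jawline(pk[1:2, ]), "at least 3")
  # spilled peaks are excluded
  pk$spilled[3:25] <- TRUE
  expect_error(fit_jawline(pk), "at least 3")
})

test_that("jawline geometry helpers are consistent", {
  jl <- structure(list(a = -0.03, b = 0, c = 8), class = "jawline")
  expect_equal(jawline_ap(jl, 0), 8)
  # arc length is monotone and exceeds the chord
  s <- jawline_arclength(jl, c(0, 10, 20, 30))
  expect_true(all(diff(s) > 10))
  # buccal offset positive on the convex (outer) side of the arch
  expect_gt(jawline_offset(jl, 0, 10), 0) # anterior of the front = outside
  expect_lt(jawline_offset(jl, 0, 0), 0) # inside the horseshoe
})

test_that("blob merging unions overlaps and same-position halves, drops spills", {
  jl <- structure(list(a = -0.03, b = 0, c = 8), class = "jawline")
  mkpeak <- function(v, t, h) {
    tibble::tibble(
      vertex = v, x = t, y = 0, z = h, t = t,
      ap = jawline_ap(jl, t), height = h, spilled = FALSE
    )
  }
  # two overlapping blobs (two cusps of one tooth)
  b1 <- tooth_blob(1:50, mkpeak(1, 10, 9))
  b2 <- tooth_blob(40:90, mkpeak(2, 10.5, 8.7))
  # buccal and lingual halves: no shared face, same jawline position
  b3 <- tooth_blob(200:260, mkpeak(3, -20, 8))
  b4 <- tooth_blob(300:360, mkpeak(4, -20.6, 7.8))
  # a spilled blob
  b5 <- tooth_blob(400:900, mkpeak(5, 0, 9), spilled = TRUE)
  # an isolated distant blob
  b6 <- tooth_blob(1000:1040, mkpeak(6, 28, 8.5))

  out <- merge_blobs(list(b1, b2, b3, b4, b5, b6), jl, merge_distance = 3)
  expect_length(out, 3)
  faces <- lapply(out, `[[`, "faces")
  # pairwise disjoint, each with at least one peak, sorted by jaw parameter
  for (i in seq_along(out)) {
    expect_gt(nrow(out[[i]]$peaks), 0)
    for (j in seq_len(i - 1)) expect_length(intersect(faces[[i]], faces[[j]]), 0)
  }
  expect_true(all(diff(vapply(out, `[[`, numeric(1), "jaw_parameter")) > 0))
  # the overlap union contains both parents; the spilled blob is gone
  sizes <- vapply(faces, length, integer(1))
  expect_true(any(sizes == length(union(1:50, 40:90))))
  expect_true(any(sizes == length(union(200:260, 300:360))))
  expect_false(any(vapply(out, function(b) any(b$faces %in% 400:900), logical(1))))
})

test_that("partition is deterministic and one blob per tooth on the default arch", {
  res <- fixture_recognition()
  gen <- fixture_arch()
  expect_length(res$blobs, 16)
  mesh <- res$mesh
  adj <- build_adjacency(mesh)
  pk <- find_peaks(mesh, adj, res$frame)
  p1 <- partition_teeth(mesh, adj, res$frame, pk)
  p2 <- partition_teeth(mesh, adj, res$frame, pk)
  expect_identical(
    lapply(p1$blobs, `[[`, "faces"),
    lapply(p2$blobs, `[[`, "faces")
  )
})
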