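test_that("the default MHB mapping scores displacements as configured", {
  expect_equal(mhb_score(3.0, "buccal"), 0)
  expect_equal(mhb_score(-2.5, "buccal"), -2)
  expect_equal(mhb_score(0, "buccal"), -1)
  expect_equal(mhb_score(7, "labial"), 1)
  expect_equal(mhb_score(3, "labial"), 0)
  expect_equal(mhb_score(0, "labial"), -1)
  expect_equal(mhb_score(-2, "labial"), -2)
  expect_equal(mhb_score(-5, "labial"), -3)

  # non-increasing across a fine sweep of displacements
  for (seg in c("buccal", "labial")) {
    sweep <- mhb_score(seq(10, -10, by = -0.05), seg)
    expect_true(all(diff(sweep) <= 0))
  }

  # malformed mappings are rejected
  expect_error(
    mhb_mapping(buccal = list(breaks = c(-1, 1), scores = c(0, -1, -2))),
    "decreasing"
  )
  expect_error(
    mhb_mapping(buccal = list(breaks = c(1, -1), scores = c(0, 1, -2))),
    "non-increasing"
  )
  expect_error(
    mhb_mapping(buccal = list(breaks = c(1, -1), scores = c(0, -1))),
    "one more score"
  )
})

test_that("scored teeth follow the MHB convention", {
  full_perm <- paste0(rep(c("UR", "UL"), each = 8), c(8:1, 1:8))
  expect_length(select_scored_teeth(full_perm, "permanent"), 12)
  full_decid <- paste0(rep(c("UR", "UL"), each = 5), c("e", "d", "c", "b", "a"))
  expect_length(select_scored_teeth(full_decid, "deciduous"), 10)
  expect_length(select_scored_teeth(setdiff(full_perm, "UR3"), "permanent"), 11)
  # half-molar pairs count once
  with_halves <- c("UR6.0", "UR6.1", "UR5", "UR4")
  expect_setequal(
    select_scored_teeth(with_halves, "permanent"),
    c("UR6", "UR5", "UR4")
  )
})

test_that("landmark extraction picks the buccal cusp for posterior teeth", {
  gen <- fixture_arch()
  res <- fixture_recognition()
  cusps <- gen$truth$cusps
  for (tp in c("LL4", "LR6")) {
    lm <- res$landmarks[res$landmarks$tooth_type == tp, ]
    expect_equal(nrow(lm), 1)
    cu <- cusps[cusps$tooth_type == tp & cusps$cusp == "buccal", ]
    d <- min(sqrt((cu$x - lm$x)^2 + (cu$y - lm$y)^2 + (cu$z - lm$z)^2))
    expect_lt(d, 0.75)
  }
  # incisors and canines take the highest peak (the single apex)
  for (tp in c("LL1", "LR3")) {
    lm <- res$landmarks[res$landmarks$tooth_type == tp, ]
    cu <- cusps[cusps$tooth_type == tp, ]
    d <- min(sqrt((cu$x - lm$x)^2 + (cu$y - lm$y)^2 + (cu$z - lm$z)^2))
    expect_lt(d, 0.5)
  }
  # ties break to the lowest vertex index
  jl <- structure(list(a = -0.03, b = 0, c = 8), class = "jawline")
  pks <- tibble::tibble(
    vertex = c(9, 4), x = c(1, 2), y = 0, z = 5,
    t = c(1, 2), ap = jawline_ap(jl, c(1, 2)), height = c(5, 5), spilled = FALSE
  )
  fr <- arch_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  lm <- extract_landmark(
    fixture_arch()$mesh, tooth_blob(1:10, pks), "LL1", fr, jl
  )
  expect_equal(lm$vertex, 4)
})

test_that("the mandibular curve interpolates and the plane fit is robust", {
  t <- seq(0, 1, length.out = 8)
  pts <- tibble::tibble(x = 40 * t - 20, y = 30 * (t - 0.5)^2, z = 2 * t)
  cur <- fit_mandibular_curve(pts)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt(colSums((t(curve_point(cur, cur$knots[i])) - as.numeric(pts[i, ]))^2))
    expect_lt(d, 1e-6)
    # the closest point on the curve to an input landmark is that landmark
    us <- seq(0, cur$length, by = 0.05)
    dd <- sqrt(rowSums((curve_point(cur, us) -
      matrix(as.numeric(pts[i, ]), length(us), 3, byrow = TRUE))^2))
    expect_lt(min(dd), 0.05)
  }
  expect_error(fit_mandibular_curve(pts[1:3, ]), "at least 4")

  fr <- arch_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  flat <- tibble::tibble(x = rnorm(10, 0, 10), y = rnorm(10, 0, 10), z = 5)
  pl <- fit_reference_plane(flat, fr)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_gt(sum(pl$normal * fr$occlusal), 0)

  set.seed(2)
  noisy <- flat
  noisy$z <- noisy$z + rnorm(10, 0, 0.2)
  pln <- fit_reference_plane(noisy, fr)
  ang <- acos(min(1, abs(pln$normal[3]))) * 180 / pi
  expect_lt(ang, 3)

  expect_error(fit_reference_plane(flat[1:2, ], fr), "at least 3")
  coll <- tibble::tibble(x = 1:5, y = 2 * (1:5), z = 0)
  expect_error(fit_reference_plane(coll, fr), "collinear")
})

test_that("transverse displacement is signed buccal-positive and exact", {
  # mandibular landmarks on a parabola in the z = 0 plane
  t <- seq(-25, 25, length.out = 12)
  mand <- tibble::tibble(x = t, y = -0.03 * t^2 + 8, z = 0)
  cur <- fit_mandibular_curve(mand)
  fr <- arch_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pl <- fit_reference_plane(dplyr::mutate(mand, z = z + c(0.01, -0.01)), fr)

  # a landmark exactly 2 mm buccal (outward, in-plane) of a curve knot:
  # the spline passes through the knot, so the distance is exact there
  k <- 6
  slope <- -0.06 * mand$x[k]
  nrm <- c(-slope, 1) / sqrt(1 + slope^2) # outward horizontal normal
  lm <- list(
    x = mand$x[k] + 2 * nrm[1],
    y = mand$y[k] + 2 * nrm[2], z = 0
  )
  d <- transverse_displacement(lm, cur, pl)
  expect_equal(as.numeric(d), 2, tolerance = 1e-3)

  # landmark on the curve: zero
  on_curve <- list(x = mand$x[k], y = mand$y[k], z = 0)
  expect_lt(abs(as.numeric(transverse_displacement(on_curve, cur, pl))), 1e-6)

  # mirroring the landmark lingually flips only the sign
  lm_in <- list(
    x = mand$x[k] - 2 * nrm[1],
    y = mand$y[k] - 2 * nrm[2], z = 0
  )
  d_in <- transverse_displacement(lm_in, cur, pl)
  expect_equal(as.numeric(d_in), -as.numeric(d), tolerance = 1e-3)
})

test_that("arch-pair scoring from landmark sets matches the mapping", {
  # construct matched landmark sets directly (no meshes): mandibular on a
  # parabola, maxillary displaced by known transverse offsets
  t_pos <- c(-24, -18, -12, -6.5, -3, 3, 6.5, 12, 18, 24)
  types_m <- c("LR6", "LR5", "LR4", "LR3", "LR1", "LL1", "LL3", "LL4", "LL5", "LL6")
  mand <- tibble::tibble(
    tooth_type = types_m,
    x = t_pos, y = -0.035 * t_pos^2 + 10, z = 0
  )
  offsets <- c(-3, 2, 2, 0, 0, 0, 7, -2.5, 2, 2)
  jl <- list(a = -0.035, b = 0, c = 10)
  slope <- 2 * jl$a * t_pos
  nx <- -slope / sqrt(1 + slope^2) * sign(1) # buccal normal components
  ny <- 1 / sqrt(1 + slope^2)
  maxi <- tibble::tibble(
    tooth_type = sub("^L", "U", types_m),
    x = t_pos + offsets * nx,
    y = mand$y + offsets * ny,
    z = 2
  )
  card <- score_arch_pair(
    list(landmarks = maxi, dentition = "permanent"),
    list(landmarks = mand, dentition = "permanent")
  )
  sc <- card$scores
  expect_equal(nrow(sc), 10)
  got <- sc[match(maxi$tooth_type, sc$tooth_type), ]
  expect_equal(got$displacement, offsets, tolerance = 0.6)
  intended <- unname(mapply(
    function(d, seg) mhb_score(d, seg),
    offsets, got$segment
  ))
  expect_equal(got$score, intended)

  # a maxillary tooth with no mandibular partner is reported unscored
  maxi2 <- dplyr::bind_rows(maxi, tibble::tibble(
    tooth_type = "UR2", x = -8, y = 6, z = 2
  ))
  mand2 <- mand[mand$tooth_type != "LR4", ]
  card2 <- score_arch_pair(
    list(landmarks = maxi2, dentition = "permanent"),
    list(landmarks = mand2, dentition = "permanent")
  )
  expect_true("UR2" %in% card2$unscored$tooth_type)
  expect_true("UR4" %in% card2$unscored$tooth_type)
  expect_equal(card2$total, sum(card2$scores$score))

  # zero displacement everywhere scores mapping(0) for every tooth
  maxi0 <- mand
  maxi0$tooth_type <- sub("^L", "U", maxi0$tooth_type)
  maxi0$z <- 2
  card0 <- score_arch_pair(
    list(landmarks = maxi0, dentition = "permanent"),
    list(landmarks = mand, dentition = "permanent")
  )
  expect_true(all(abs(card0$scores$displacement) < 1e-6))
  expect_equal(
    card0$scores$score,
    unname(mapply(function(seg) mhb_score(0, seg), card0$scores$segment))
  )
})

test_that("rigid transforms of both arches leave displacements unchanged", {
  t_pos <- seq(-24, 24, length.out = 10)
  types_m <- c("LR6", "LR5", "LR4", "LR3", "LR1", "LL1", "LL3", "LL4", "LL5", "LL6")
  mand <- tibble::tibble(
    tooth_type = types_m, x = t_pos, y = -0.035 * t_pos^2 + 10,
    z = rnorm(10, 0, 0.1)
  )
  maxi <- mand
  maxi$tooth_type <- sub("^L", "U", maxi$tooth_type)
  maxi$y <- maxi$y + 1.5
  maxi$z <- maxi$z + 2
  base <- score_arch_pair(
    list(landmarks = maxi, dentition = "permanent"),
    list(landmarks = mand, dentition = "permanent")
  )
  R <- random_rotation(8)
  tr <- c(5, -11, 30)
  rot <- function(df) {
    p <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- p[, 1] + tr[1]
    df$y <- p[, 2] + tr[2]
    df$z <- p[, 3] + tr[3]
    df
  }
  # supply the rotated occlusal direction via a frame
  fr <- arch_frame(
    tr, as.vector(R %*% c(1, 0, 0)), as.vector(R %*% c(0, 1, 0)),
    as.vector(R %*% c(0, 0, 1))
  )
  moved <- score_arch_pair(
    list(landmarks = rot(maxi), dentition = "permanent"),
    list(landmarks = rot(mand), frame = fr, dentition = "permanent")
  )
  expect_equal(moved$scores$displacement, base$scores$displacement,
    tolerance = 1e-3
  )
})

test_that("landmark CSV round trip preserves the exchange columns", {
  lm <- tibble::tibble(
    tooth_type = c("UR3", "UL3"), x = c(1.5, -2.5), y = c(0, 1), z = c(9, 9.2)
  )
  p <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, p)
  back <- read_landmarks(p)
  expect_equal(as.data.frame(back), as.data.frame(lm))
})
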