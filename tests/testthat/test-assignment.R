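test_that("arch templates have the expected symmetric class sequences", {
  tp <- arch_template("maxillary", "permanent")
  expect_equal(nrow(tp), 16)
  code <- c(
    incisor = "I", canine = "C", premolar = "P", molar = "M"
  )[tp$class]
  expect_equal(paste(code, collapse = ""), "MMMPPCIIIICPPMMM")
  expect_equal(code, rev(code))

  td <- arch_template("mandibular", "deciduous")
  expect_equal(nrow(td), 10)
  coded <- c(incisor = "i", canine = "c", molar = "m")[td$class]
  expect_equal(paste(coded, collapse = ""), "mmciiiicmm")
})

test_that("tooth code helpers parse Palmer codes with half extensions", {
  expect_equal(tooth_position(c("UR6", "LLa", "UL6.1")), c("6", "a", "6"))
  expect_equal(tooth_quadrant("UR6.0"), "UR")
  expect_equal(tooth_half(c("UR6.0", "UR6.1", "UR6")), c("0", "1", NA))
  expect_equal(tooth_class(c("UR1", "LL3", "UR4", "LLe")),
    c("incisor", "canine", "premolar", "molar"))
  expect_equal(tooth_side_class(c("UR6", "UL6", "LR6.1")), c("U6", "U6", "L6.1"))
  expect_equal(tooth_base_type("UR6.1"), "UR6")
})

test_that("blob features match generator dimensions and are rigid-invariant", {
  gen <- fixture_arch()
  res <- fixture_recognition()
  mesh <- res$mesh
  # the canine blob: find it via the truth mask
  lab <- res$assignment$assignment$tooth_type
  i3 <- which(lab == "LL3")
  expect_length(i3, 1)
  f <- res$features[i3, ]
  truth <- gen$truth$teeth[gen$truth$teeth$type == "LL3", ]
  expect_lt(abs(f$mesiodistal_width - truth$md) / truth$md, 0.15)
  expect_lt(abs(f$buccolingual_width - truth$bl) / truth$bl, 0.15)
  expect_lt(abs(f$crown_height - truth$ch) / truth$ch, 0.2)
  expect_equal(f$peak_count, nrow(res$blobs[[i3]]$peaks))

  # rigid invariance: transform mesh and frame together
  R <- random_rotation(5)
  tr <- c(-4, 9, 2)
  mesh2 <- transform_mesh(mesh, R, tr)
  fr <- res$frame
  fr2 <- arch_frame(
    as.vector(R %*% fr$origin) + tr,
    as.vector(R %*% fr$transverse),
    as.vector(R %*% fr$anteroposterior),
    as.vector(R %*% fr$occlusal)
  )
  f2 <- compute_features(mesh2, res$blobs[[i3]], fr2, res$jawline)
  expect_equal(as.numeric(f2[1, ]), as.numeric(f[1, ]), tolerance = 1e-6)

  expect_error(
    compute_features(mesh, tooth_blob(integer(0), res$peaks[1, ]), fr, res$jawline),
    "empty blob"
  )
})

test_that("mismatch cost is a squared z-score with exact anchor points", {
  tr <- default_training_set("permanent")
  st <- tr$stats[tr$stats$tooth_type == "L4", ]
  at_mean <- tibble::tibble(
    surface_area = st$mean[st$feature == "surface_area"],
    mesiodistal_width = st$mean[st$feature == "mesiodistal_width"],
    buccolingual_width = st$mean[st$feature == "buccolingual_width"],
    crown_height = st$mean[st$feature == "crown_height"],
    peak_count = st$mean[st$feature == "peak_count"]
  )
  expect_equal(mismatch_cost(at_mean, "LL4", tr), 0)
  one_off <- at_mean
  one_off$crown_height <- one_off$crown_height + st$sd[st$feature == "crown_height"]
  expect_equal(mismatch_cost(one_off, "LL4", tr), 1)

  # cost strictly increases as a feature moves away from its mean
  costs <- vapply(seq(0, 3, by = 0.5), function(k) {
    x <- at_mean
    x$surface_area <- x$surface_area + k * st$sd[st$feature == "surface_area"]
    mismatch_cost(x, "LL4", tr)
  }, numeric(1))
  expect_true(all(diff(costs) > 0))

  expect_error(mismatch_cost(at_mean, "LL9", tr), "not in training")
})


test_that("the assignment DP labels ideal arches exactly and handles gaps", {
  tr <- default_training_set("permanent")
  template <- arch_template("mandibular", "permanent")
  blobs <- lapply(1:16, function(i) tooth_blob(i, tibble::tibble(height = 1)))

  feats <- features_at_means(template$type, tr)
  a <- assign_teeth(blobs, feats, template, tr)
  expect_equal(a$assignment$tooth_type, template$type)
  expect_equal(a$total_cost, 0)

  # remove one premolar: its slot is skipped, everything else unchanged
  drop <- which(template$type == "LR4")
  a2 <- assign_teeth(blobs[-drop], feats[-drop, ], template, tr)
  expect_equal(a2$assignment$tooth_type, template$type[-drop])
  expect_equal(a2$skipped, "LR4")

  # empty blob list: empty assignment
  a0 <- assign_teeth(list(), feats[0, ], template, tr)
  expect_equal(nrow(a0$assignment), 0)

  # tidy/glance accessors
  expect_equal(nrow(tidy(a)), 16)
  expect_equal(glance(a)$n_assigned, 16)
})

test_that("DP optimum equals brute-force enumeration on random small instances", {
  trd <- default_training_set("deciduous")
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    m <- sample(3:6, 1)
    tpl <- arch_template("mandibular", "deciduous")[sort(sample(1:10, m)), ]
    tpl$slot <- seq_len(m)
    feats <- features_at_means(sample(tpl$type, n, replace = TRUE), trd)
    # jitter so costs are generic
    feats <- feats * matrix(runif(n * 5, 0.7, 1.3), n, 5)
    blobs <- lapply(seq_len(n), function(i) tooth_blob(i, tibble::tibble(height = 1)))
    a <- assign_teeth(blobs, feats, tpl, trd, gap_penalty = 6, discard_penalty = 9)

    C <- matrix(Inf, n, m)
    H0 <- matrix(Inf, n, m)
    H1 <- matrix(Inf, n, m)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        C[i, j] <- mismatch_cost(feats[i, ], tpl$type[j], trd)
        if (tpl$is_molar[j]) {
          H0[i, j] <- mismatch_cost(feats[i, ], paste0(tpl$type[j], ".0"), trd)
          H1[i, j] <- mismatch_cost(feats[i, ], paste0(tpl$type[j], ".1"), trd)
        }
      }
    }
    oracle <- brute_force_assignment(C, H0, H1, tpl$is_molar, 6, 9)
    expect_equal(a$total_cost, oracle, tolerance = 1e-9)
  }
})

test_that("mirrored blobs against the mirrored template cost the same", {
  # half-types are excluded: the mesial/distal half statistics are not
  # exactly mirror-symmetric, while whole-tooth features are
  trd0 <- default_training_set("deciduous")
  trd <- training_set(trd0$samples[is.na(tooth_half(trd0$samples$tooth_type)), ])
  tpl <- arch_template("mandibular", "deciduous")
  set.seed(5)
  n <- 8
  feats <- features_at_means(sample(tpl$type, n, replace = TRUE), trd)
  feats <- feats * matrix(runif(n * 5, 0.8, 1.2), n, 5)
  blobs <- lapply(seq_len(n), function(i) tooth_blob(i, tibble::tibble(height = 1)))
  a_fwd <- assign_teeth(blobs, feats, tpl, trd)
  tpl_rev <- tpl[m <- rev(seq_len(nrow(tpl))), ]
  tpl_rev$slot <- seq_len(nrow(tpl))
  a_rev <- assign_teeth(rev(blobs), feats[rev(seq_len(n)), ], tpl_rev, trd)
  expect_equal(a_rev$total_cost, a_fwd$total_cost, tolerance = 1e-9)
})
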