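#' Specification of a synthetic dental arch
#'
#' The generator emulates the scan population the recognition pipeline is
#' meant for: a quadratic dental arch of parametric teeth (1-5 cusps each) on
#' a gingival base, separated by concave creases, with configurable missing
#' teeth, per-tooth transverse (buccal/lingual) offsets for crossbite and
#' overjet construction, crown height offsets, surface noise, and a
#' deterministic seed.
#'
#' Tooth crowns are rounded boxes with spherical-cap cusps, joined to the
#' base with a deliberately small blending radius so the tooth-gingiva
#' junction is a detectable concave crease. Default mesiodistal widths (mm):
#' permanent central incisor 8.5, lateral incisor 6.5, canine 7.5, first
#' premolar 7.0, second premolar 6.8, molars 10.5/10.0/9.5; deciduous teeth
#' are scaled by 0.8. Second premolar and the distal molars are made slightly
#' smaller than their mesial neighbours so that tooth types remain
#' discriminable by size when teeth are missing.
#'
#' @param jaw `"maxillary"` or `"mandibular"`.
#' @param dentition `"permanent"` or `"deciduous"`.
#' @param missing_teeth character vector of tooth codes absent from the arch
#'   (e.g. `c("UR4")`).
#' @param tooth_offsets named numeric: transverse offset (mm) per tooth code,
#'   positive buccal, negative lingual (crossbite).
#' @param height_offsets named numeric: vertical crown offset (mm) per tooth.
#' @param size_scale global linear scale of tooth dimensions.
#' @param arch_curvature quadratic coefficient of the arch form
#'   (`ap = front_ap - arch_curvature * t^2`). Default 0.03.
#' @param front_ap anteroposterior position of the arch front, mm. Default 8.
#' @param noise_sd i.i.d. Gaussian vertex noise, mm; must be < 0.3.
#'   Default 0.03 (the order of intra-oral scanner noise).
#' @param resolution marching grid spacing, mm; must lie in [0.15, 0.6].
#'   Default 0.5.
#' @param seed integer random seed (drives the vertex noise).
#' @return an `arch_spec` object; its `teeth` element is a tibble of
#'   per-tooth parameters.
#' @export
arch_spec <- function(jaw = c("mandibular", "maxillary"),
                      dentition = c("permanent", "deciduous"),
                      missing_teeth = character(),
                      tooth_offsets = c(),
                      height_offsets = c(),
                      size_scale = 1,
                      arch_curvature = 0.03,
                      front_ap = 8,
                      noise_sd = 0.03,
                      resolution = 0.5,
                      seed = 1L) {
  jaw <- match.arg(jaw)
  dentition <- match.arg(dentition)
  if (resolution < 0.15 || resolution > 0.6) {
    stop("`resolution` must lie in [0.15, 0.6] mm")
  }
  if (noise_sd >= 0.3) stop("`noise_sd` must be < 0.3 mm")

  dims <- .tooth_dims(dentition)
  template <- arch_template(jaw, dentition)
  template$position <- tooth_position(template$type)
  teeth <- dplyr::left_join(template, dims, by = c("class", "position"))
  teeth <- teeth[order(teeth$slot), ]
  teeth$md <- teeth$md * size_scale
  teeth$bl <- teeth$bl * size_scale
  teeth$ch <- teeth$ch * size_scale
  teeth$present <- !(teeth$type %in% missing_teeth)
  teeth$offset <- ifelse(teeth$type %in% names(tooth_offsets),
    as.numeric(tooth_offsets[teeth$type]), 0
  )
  teeth$height_offset <- ifelse(teeth$type %in% names(height_offsets),
    as.numeric(height_offsets[teeth$type]), 0
  )

  # arc-length tooth centres, midline between the two central slots
  m <- nrow(teeth)
  gap <- 1.0
  # the midline gap is widened (a small diastema): a slot exactly aligned
  # with the sampling grid needs extra clearance to surface cleanly
  acc0 <- 0.8
  s <- numeric(m)
  acc <- acc0
  for (i in (m / 2 + 1):m) { # left quadrant outward
    s[i] <- acc + teeth$md[i] / 2
    acc <- acc + teeth$md[i] + gap
  }
  acc <- acc0
  for (i in (m / 2):1) { # right quadrant outward
    s[i] <- -(acc + teeth$md[i] / 2)
    acc <- acc + teeth$md[i] + gap
  }
  teeth$s <- s

  structure(
    list(
      jaw = jaw, dentition = dentition, teeth = teeth,
      size_scale = size_scale,
      missing_teeth = missing_teeth,
      tooth_offsets = tooth_offsets, height_offsets = height_offsets,
      arch_curvature = arch_curvature, front_ap = front_ap,
      noise_sd = noise_sd, resolution = resolution, seed = as.integer(seed)
    ),
    class = "arch_spec"
  )
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf(
    "<arch_spec: %s %s, %d/%d teeth present, res %.2f mm, noise %.3f mm, seed %d>\n",
    x$jaw, x$dentition, sum(x$teeth$present), nrow(x$teeth),
    x$resolution, x$noise_sd, x$seed
  ))
  invisible(x)
}

.tooth_dims <- function(dentition) {
  if (dentition == "permanent") {
    tibble::tribble(
      ~position, ~class, ~md, ~bl, ~ch, ~n_cusps,
      "1", "incisor", 8.5, 7.0, 9.0, 1L,
      "2", "incisor", 6.5, 6.5, 8.5, 1L,
      "3", "canine", 7.5, 8.0, 9.5, 1L,
      "4", "premolar", 7.0, 9.0, 7.5, 2L,
      "5", "premolar", 6.8, 9.4, 7.3, 2L,
      "6", "molar", 10.5, 11.0, 7.0, 4L,
      "7", "molar", 10.0, 10.5, 6.8, 4L,
      "8", "molar", 9.5, 10.0, 6.5, 4L
    )
  } else {
    tibble::tribble(
      ~position, ~class, ~md, ~bl, ~ch, ~n_cusps,
      "a", "incisor", 6.8, 5.6, 7.2, 1L,
      "b", "incisor", 5.2, 5.2, 6.8, 1L,
      "c", "canine", 6.0, 6.4, 7.6, 1L,
      "d", "molar", 8.4, 8.8, 5.6, 4L,
      "e", "molar", 8.0, 8.4, 5.5, 4L
    )
  }
}

# swap patient left/right quadrants (UR<->UL, LR<->LL)
.swap_side <- function(type) {
  q <- substr(type, 1, 2)
  rest <- substring(type, 3)
  swapped <- c(UR = "UL", UL = "UR", LR = "LL", LL = "LR")[q]
  paste0(swapped, rest)
}

# signed arc length of y = front - a*x^2 at transverse x
.arch_arclength <- function(a, x) {
  jawline_arclength(list(a = -a, b = 0), x)
}

# invert arc length -> transverse coordinate
.arch_x_of_s <- function(a, s) {
  vapply(s, function(si) {
    if (si == 0) return(0)
    f <- function(x) .arch_arclength(a, x) - si
    stats::uniroot(f, c(-200, 200), tol = 1e-10)$root
  }, numeric(1))
}

# polynomial smooth minimum (blend radius k)
.smin <- function(a, b, k) {
  h <- pmax(k - abs(a - b), 0) / k
  pmin(a, b) - h * h * k * 0.25
}

# rounded-box SDF in local coordinates
.sdf_box <- function(lu, lv, lz, hu, hv, hz, r) {
  qu <- abs(lu) - hu + r
  qv <- abs(lv) - hv + r
  qz <- abs(lz) - hz + r
  outside <- sqrt(pmax(qu, 0)^2 + pmax(qv, 0)^2 + pmax(qz, 0)^2)
  inside <- pmin(pmax(qu, pmax(qv, qz)), 0)
  outside + inside - r
}

# per-tooth geometry: local frame, crown box, cusp centres and radii
.tooth_geometry <- function(tooth, spec, base_top) {
  a <- spec$arch_curvature
  xc <- .arch_x_of_s(a, tooth$s)
  yc <- spec$front_ap - a * xc^2
  slope <- -2 * a * xc
  u <- c(1, slope) / sqrt(1 + slope^2) # mesiodistal tangent
  v <- c(-slope, 1) / sqrt(1 + slope^2) # buccal (away from arch interior)
  centre <- c(xc, yc) + tooth$offset * v

  # embed deeply enough that the crown wall is vertical where it meets the
  # base top, so the gingival junction is a closed ~90 degree crease ring
  embed <- 2.5
  zb <- base_top - embed + tooth$height_offset
  z_top <- zb + tooth$ch
  scale <- spec$size_scale
  cusp <- switch(tooth$class,
    incisor = list(r = 2.0 * scale, protr = 1.6, uv = cbind(0, 0), lab = "central"),
    canine = list(r = 1.6 * scale, protr = 2.2, uv = cbind(0, 0), lab = "central"),
    premolar = list(
      r = 2.0 * scale, protr = 1.5,
      uv = cbind(c(0, 0), c(tooth$bl / 4, -tooth$bl / 4)),
      lab = c("buccal", "lingual")
    ),
    molar = list(
      r = 2.2 * scale, protr = 1.4,
      uv = cbind(
        c(
          -(tooth$md / 4 - 0.8), tooth$md / 4 - 0.8,
          -(tooth$md / 4 - 0.8), tooth$md / 4 - 0.8
        ),
        c(tooth$bl / 4, tooth$bl / 4, -tooth$bl / 4, -tooth$bl / 4)
      ),
      lab = c("buccal", "buccal", "lingual", "lingual")
    )
  )
  lift <- ifelse(cusp$lab == "buccal", 0.3, 0)
  cusp_z <- z_top - cusp$r + cusp$protr + lift
  apex_z <- z_top + cusp$protr + lift
  list(
    centre = centre, u = u, v = v, zb = zb, z_top = z_top,
    neck_z = base_top + 1.2 + tooth$height_offset,
    hu = tooth$md / 2 - 0.5, hv = tooth$bl / 2, hz = tooth$ch / 2,
    cusp_uv = cusp$uv, cusp_r = cusp$r, cusp_z = cusp_z,
    cusp_label = cusp$lab, apex_z = apex_z
  )
}

# evaluate one tooth's SDF at world points (vectorised)
.tooth_sdf <- function(geom, px, py, pz) {
  dx <- px - geom$centre[1]
  dy <- py - geom$centre[2]
  lu <- dx * geom$u[1] + dy * geom$u[2]
  lv <- dx * geom$v[1] + dy * geom$v[2]
  lz <- pz - (geom$zb + geom$hz)
  # cervical neck: the crown narrows towards the gingiva (emergence profile),
  # which makes the tooth-base junction a reentrant crease that survives
  # surfacing at coarse marching resolutions
  neck <- pmin(pmax((geom$neck_z - pz) / 1.8, 0), 1.2)
  # ovoid cross-section (corner radius ~ the half-width): real crowns have
  # no sharp corners, and a corner-free wall gives the gingival crease ring
  # uniform strength all the way round
  r_oval <- 0.85 * pmin(geom$hu - neck, geom$hv - neck)
  d <- .sdf_box(lu, lv, lz, geom$hu - neck, geom$hv - neck, geom$hz, r_oval)
  for (ci in seq_len(nrow(geom$cusp_uv))) {
    ds <- sqrt((lu - geom$cusp_uv[ci, 1])^2 + (lv - geom$cusp_uv[ci, 2])^2 +
      (pz - geom$cusp_z[ci])^2) - geom$cusp_r
    d <- .smin(d, ds, 1.2)
  }
  d
}

#' Generate a synthetic dental arch with ground truth
#'
#' Builds the implicit field of the arch (smooth union of a gingival base
#' band and per-tooth crown primitives, with a sharpened blend at the
#' gingival junction so the partition stage has a crease to find), extracts
#' the surface with [marching_tetrahedra()], adds optional vertex noise, and
#' returns the mesh together with full ground truth: per-tooth labels and
#' face masks, cusp apices with buccal/lingual labels, intended transverse
#' displacements, and the generator's vertical/anterior directions. Fully
#' deterministic given the spec's seed.
#'
#' @param spec an [arch_spec()].
#' @param mirror reflect the arch through a horizontal plane (used to place a
#'   maxillary arch in occlusion, crowns pointing down).
#' @param mirror_z the plane height for `mirror`, mm.
#' @return list with `mesh` (a [dental_mesh()]) and `truth` (list: `teeth`
#'   tibble, `cusps` tibble, `masks` named list of face indices, `vertical`,
#'   `anterior`, `spec`).
#' @export
generate_arch <- function(spec, mirror = FALSE, mirror_z = NULL) {
  base_top <- 3.5
  all_teeth <- spec$teeth
  if (mirror) {
    # a mirror swaps the patient's left and right: relabel the slots and
    # re-resolve the per-tooth options against the post-mirror labels, so
    # that an offset given for "UR6" lands on the tooth that will be
    # recognised as UR6 in occlusion
    all_teeth$type <- .swap_side(all_teeth$type)
    all_teeth$present <- !(all_teeth$type %in% spec$missing_teeth)
    all_teeth$offset <- ifelse(all_teeth$type %in% names(spec$tooth_offsets),
      as.numeric(spec$tooth_offsets[all_teeth$type]), 0
    )
    all_teeth$height_offset <- ifelse(
      all_teeth$type %in% names(spec$height_offsets),
      as.numeric(spec$height_offsets[all_teeth$type]), 0
    )
  }
  teeth <- all_teeth[all_teeth$present, , drop = FALSE]
  if (nrow(teeth) == 0L) stop("arch_spec has no present teeth")
  geoms <- lapply(seq_len(nrow(teeth)), function(i) {
    .tooth_geometry(teeth[i, ], spec, base_top)
  })

  # reject overlapping teeth (offsets can collide neighbours)
  if (nrow(teeth) > 1L) {
    for (i in seq_len(nrow(teeth) - 1L)) {
      d <- sqrt(sum((geoms[[i + 1]]$centre - geoms[[i]]$centre)^2))
      lim <- (teeth$md[i] + teeth$md[i + 1]) / 2 - 1
      if (teeth$slot[i + 1] == teeth$slot[i] + 1L && d < lim) {
        stop(sprintf(
          "teeth %s and %s overlap beyond tolerance (centres %.1f mm apart)",
          teeth$type[i], teeth$type[i + 1], d
        ))
      }
    }
  }

  res <- spec$resolution
  # the gingival band must extend beyond every (possibly offset) tooth wall
  band_hw <- 7.5 + max(abs(teeth$offset), 0)
  mar <- band_hw + 4.5
  xr <- range(vapply(geoms, function(g) g$centre[1], numeric(1)))
  yr <- range(vapply(geoms, function(g) g$centre[2], numeric(1)))
  zmax <- max(vapply(geoms, function(g) max(g$apex_z), numeric(1)))
  x <- seq(xr[1] - mar, xr[2] + mar, by = res)
  y <- seq(yr[1] - mar, yr[2] + mar, by = res)
  z <- seq(-1.2, zmax + 2, by = res)
  nx <- length(x)
  ny <- length(y)
  nz <- length(z)

  # base band SDF: 2D horizontal part broadcast over z slices
  a <- spec$arch_curvature
  gx <- rep(x, ny)
  gy <- rep(y, each = nx)
  slope <- -2 * a * gx
  off <- (gy - (spec$front_ap - a * gx^2)) / sqrt(1 + slope^2)
  s_here <- .arch_arclength(a, gx) # arc position, caps the band ends
  s_end <- max(abs(teeth$s)) + teeth$md[1] / 2
  d2d <- pmax(abs(off) - band_hw, abs(s_here) - (s_end + 10))
  F <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    dz <- abs(z[k] - base_top / 2) - base_top / 2
    r <- 0.8
    qa <- d2d + r
    qb <- dz + r
    F[, , k] <- sqrt(pmax(qa, 0)^2 + pmax(qb, 0)^2) + pmin(pmax(qa, qb), 0) - r
  }



  # teeth: evaluate on local subgrids, sharp blend (0.2 mm) at the gingiva
  for (g in geoms) {
    rad <- max(g$hu, g$hv) + max(g$cusp_r) + 4
    xi <- which(x >= g$centre[1] - rad & x <= g$centre[1] + rad)
    yi <- which(y >= g$centre[2] - rad & y <= g$centre[2] + rad)
    px <- rep(x[xi], length(yi))
    py <- rep(y[yi], each = length(xi))
    for (k in seq_len(nz)) {
      dt <- .tooth_sdf(g, px, py, rep(z[k], length(px)))
      F[xi, yi, k] <- .smin(F[xi, yi, k], dt, 0.05)
    }
  }

  mesh0 <- marching_tetrahedra(F, x, y, z)
  verts <- mesh0$vertices
  faces <- mesh0$faces

  if (mirror) {
    if (is.null(mirror_z)) mirror_z <- zmax + 1
    verts[, 3] <- 2 * mirror_z - verts[, 3]
    faces <- faces[, c(1, 3, 2), drop = FALSE]
  }

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    verts <- verts + matrix(
      stats::rnorm(length(verts), 0, spec$noise_sd),
      nrow(verts), 3
    )
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }

  mesh <- dental_mesh(verts, faces)

  # ground truth: face ownership by nearest primitive (tooth vs base)
  cen <- face_centroids(mesh)
  cz <- if (mirror) 2 * mirror_z - cen[, 3] else cen[, 3]
  slopec <- -2 * a * cen[, 1]
  offc <- (cen[, 2] - (spec$front_ap - a * cen[, 1]^2)) / sqrt(1 + slopec^2)
  sc <- .arch_arclength(a, cen[, 1])
  d2dc <- pmax(abs(offc) - band_hw, abs(sc) - (s_end + 10))
  dzc <- abs(cz - base_top / 2) - base_top / 2
  r <- 0.8
  qa <- d2dc + r
  qb <- dzc + r
  base_d <- sqrt(pmax(qa, 0)^2 + pmax(qb, 0)^2) + pmin(pmax(qa, qb), 0) - r
  D <- vapply(
    geoms,
    function(g) .tooth_sdf(g, cen[, 1], cen[, 2], cz),
    numeric(nrow(cen))
  )
  all_d <- cbind(base_d, D)
  owner <- max.col(-all_d, ties.method = "first") - 1L # 0 = base
  masks <- lapply(seq_len(nrow(teeth)), function(i) which(owner == i))
  names(masks) <- teeth$type

  cusps <- dplyr::bind_rows(lapply(seq_len(nrow(teeth)), function(i) {
    g <- geoms[[i]]
    nc <- nrow(g$cusp_uv)
    wx <- g$centre[1] + g$cusp_uv[, 1] * g$u[1] + g$cusp_uv[, 2] * g$v[1]
    wy <- g$centre[2] + g$cusp_uv[, 1] * g$u[2] + g$cusp_uv[, 2] * g$v[2]
    wz <- if (mirror) 2 * mirror_z - g$apex_z else g$apex_z
    tibble::tibble(
      tooth_type = teeth$type[i], cusp = g$cusp_label,
      x = wx, y = wy, z = rep(wz, length.out = nc)
    )
  }))

  truth_teeth <- teeth
  truth_teeth$centre_x <- vapply(geoms, function(g) g$centre[1], numeric(1))
  truth_teeth$centre_y <- vapply(geoms, function(g) g$centre[2], numeric(1))
  truth_teeth$intended_displacement <- truth_teeth$offset

  list(
    mesh = mesh,
    truth = list(
      teeth = truth_teeth,
      cusps = cusps,
      masks = masks,
      vertical = if (mirror) c(0, 0, -1) else c(0, 0, 1),
      anterior = c(0, 1, 0),
      mirror = mirror,
      spec = spec
    )
  )
}

#' Generate a registered occluded arch pair
#'
#' The mandibular arch is generated as-is; the maxillary arch is generated on
#' the same arch form, mirrored through a horizontal plane so its crowns
#' point down, and placed so the cusp tips of the two arches are separated by
#' `occlusal_gap`. Intended transverse displacements are realised as
#' maxillary per-tooth buccal offsets relative to the shared jawline, so the
#' ground truth for the MHB stage is exact by construction.
#'
#' @param spec_max,spec_mand [arch_spec()]s with equal `arch_curvature`,
#'   `front_ap` and `dentition`.
#' @param occlusal_gap vertical clearance between cusp tips, mm. Default 2.
#' @return list with `maxillary`, `mandibular` (each as [generate_arch()])
#'   and `intended` (tibble `tooth_type`, `displacement` for the maxillary
#'   teeth).
#' @export
generate_occluded_pair <- function(spec_max, spec_mand, occlusal_gap = 2) {
  if (spec_max$arch_curvature != spec_mand$arch_curvature ||
    spec_max$front_ap != spec_mand$front_ap ||
    spec_max$dentition != spec_mand$dentition) {
    stop("occluded pair needs compatible arch coefficients and dentition")
  }
  if (spec_max$jaw != "maxillary" || spec_mand$jaw != "mandibular") {
    stop("spec_max must be maxillary and spec_mand mandibular")
  }
  mand <- generate_arch(spec_mand)
  zmax_mand <- max(mand$truth$cusps$z)
  # apex height of the maxillary arch before mirroring
  tmp_teeth <- spec_max$teeth[spec_max$teeth$present, ]
  zmax_max <- max(vapply(
    seq_len(nrow(tmp_teeth)),
    function(i) max(.tooth_geometry(tmp_teeth[i, ], spec_max, 3.5)$apex_z),
    numeric(1)
  ))
  mirror_z <- (zmax_mand + occlusal_gap + zmax_max) / 2
  maxi <- generate_arch(spec_max, mirror = TRUE, mirror_z = mirror_z)
  list(
    maxillary = maxi,
    mandibular = mand,
    intended = tibble::tibble(
      tooth_type = maxi$truth$teeth$type,
      displacement = maxi$truth$teeth$intended_displacement
    )
  )
}

#' Derive a training set from synthetic arches
#'
#' Generates the given arch specs, partitions each arch by its ground-truth
#' region masks, computes blob features in the generator's own frame, and
#' aggregates per-type statistics. Molars additionally contribute
#' mesial/distal half-type samples (the mask split at the tooth centre along
#' the arch). Because the generator uses one dimension table for both jaws,
#' every arch contributes samples to both the `U` and `L` side classes.
#'
#' @param specs list of [arch_spec()]s; default 6 specs with jittered
#'   `size_scale` (0.92 to 1.08) for each dentition requested.
#' @param dentition used only when `specs` is `NULL`.
#' @param seed base seed for the default specs.
#' @return a [training_set()].
#' @export
generate_training_set <- function(specs = NULL,
                                  dentition = c("permanent", "deciduous"),
                                  seed = 100L) {
  if (is.null(specs)) {
    dentition <- match.arg(dentition)
    scales <- c(0.92, 0.95, 0.98, 1.02, 1.05, 1.08)
    specs <- lapply(seq_along(scales), function(i) {
      arch_spec(
        jaw = "mandibular", dentition = dentition,
        size_scale = scales[i], seed = seed + i
      )
    })
  }
  if (length(specs) < 2L) stop("need at least 2 specs with varying size scales")

  rows <- list()
  for (spec in specs) {
    gen <- generate_arch(spec)
    samp <- .truth_feature_samples(gen)
    rows[[length(rows) + 1L]] <- samp
  }
  samples <- dplyr::bind_rows(rows)
  # mirror to both jaws: the dimension tables are shared by design
  both <- dplyr::bind_rows(
    dplyr::mutate(samples, tooth_type = paste0("U", .data$tooth_type)),
    dplyr::mutate(samples, tooth_type = paste0("L", .data$tooth_type))
  )
  training_set(both)
}

# feature samples (side-collapsed, no jaw prefix) from one generated arch.
# The arch is processed exactly like a recognition input (smoothing,
# orientation, peak detection, partition); the resulting blobs are then
# labelled against the ground-truth region masks -- the synthetic analogue
# of an expert hand-labelling segmented blobs. Mask-derived samples fill in
# for molar half-types (mesial/distal split at the tooth centre) and for
# any tooth whose grown blob did not match cleanly.
.truth_feature_samples <- function(gen, smooth_iterations = 2L) {
  mesh <- smooth_mesh(gen$mesh, smooth_iterations)
  truth <- gen$truth
  adj <- build_adjacency(mesh)
  frame <- orient_arch(mesh, adj)
  peaks <- find_peaks(mesh, adj, frame)
  part <- partition_teeth(mesh, adj, frame, peaks)
  jl <- part$jawline

  vert_of <- function(faces) unique(as.vector(mesh$faces[faces, , drop = FALSE]))
  fc_cen <- frame_coordinates(face_centroids(mesh), frame)
  out <- list()
  whole_done <- character()
  half_cand <- list()

  for (b in part$blobs) {
    jac <- vapply(truth$masks, function(m) {
      length(intersect(b$faces, m)) / length(union(b$faces, m))
    }, numeric(1))
    best <- names(jac)[which.max(jac)]
    frac_in <- length(intersect(b$faces, truth$masks[[best]])) / length(b$faces)
    cls <- tooth_class(best)
    if (max(jac) >= 0.5) {
      fe <- compute_features(mesh, b, frame, jl)
      fe$tooth_type <- tooth_position(best)
      out[[length(out) + 1L]] <- fe
      whole_done <- c(whole_done, best)
    } else if (frac_in >= 0.7 && cls == "molar") {
      half_cand[[best]] <- c(half_cand[[best]], list(b))
    }
  }

  # split blobs of one molar: first half along the arch is the .0 type
  for (tp in names(half_cand)) {
    bs <- half_cand[[tp]]
    if (length(bs) != 2L) next
    ord <- order(vapply(bs, `[[`, numeric(1), "jaw_parameter"))
    for (k in 1:2) {
      fe <- compute_features(mesh, bs[[ord[k]]], frame, jl)
      fe$tooth_type <- paste0(tooth_position(tp), ".", k - 1L)
      out[[length(out) + 1L]] <- fe
    }
  }

  # mask-based samples: wholes missed by the partition, and molar halves
  # (mask split at the tooth centre along the arch)
  for (i in seq_len(nrow(truth$teeth))) {
    tp <- truth$teeth$type[i]
    mask <- truth$masks[[tp]]
    if (length(mask) < 10L) next
    mv <- vert_of(mask)
    pk <- peaks[peaks$vertex %in% mv, , drop = FALSE]
    if (nrow(pk) == 0L) pk <- .pseudo_peaks(truth, tp, frame)
    if (!(tp %in% whole_done)) {
      fe <- compute_features(mesh, tooth_blob(mask, pk), frame, jl)
      fe$tooth_type <- tooth_position(tp)
      out[[length(out) + 1L]] <- fe
    }
    if (truth$teeth$class[i] == "molar") {
      s_face <- jawline_arclength(jl, fc_cen[mask, "t"])
      s_mid <- jawline_arclength(jl, mean(fc_cen[mask, "t"]))
      first <- s_face < s_mid
      for (half in c(0, 1)) {
        hm <- mask[if (half == 0) first else !first]
        if (length(hm) < 3L) next
        hv <- vert_of(hm)
        hpk <- pk[pk$vertex %in% hv, , drop = FALSE]
        if (nrow(hpk) == 0L) hpk <- pk[1, ]
        hfe <- compute_features(mesh, tooth_blob(hm, hpk), frame, jl)
        hfe$tooth_type <- paste0(tooth_position(tp), ".", half)
        out[[length(out) + 1L]] <- hfe
      }
    }
  }
  dplyr::bind_rows(out)
}

# frame implied by the generator's ground truth
.truth_frame <- function(gen) {
  occ <- gen$truth$vertical
  ap <- gen$truth$anterior
  arch_frame(colMeans(gen$mesh$vertices), .cross3(ap, occ), ap, occ)
}

.pseudo_peaks <- function(truth, type, frame) {
  cu <- truth$cusps[truth$cusps$tooth_type == type, ]
  fc <- frame_coordinates(as.matrix(cu[, c("x", "y", "z")]), frame)
  tibble::tibble(
    vertex = NA_integer_, x = cu$x, y = cu$y, z = cu$z,
    t = fc[, "t"], ap = fc[, "ap"], height = fc[, "h"], spilled = FALSE
  )
}
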