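#' Signed edge curvature field
#'
#' Curvature here measures how far the surface bends at each mesh edge: the
#' dihedral deviation (radians) between the two incident face normals, signed
#' positive for convex folds (bumps, caps, cusp tips) and negative for concave
#' ones (grooves, creases). The tooth-gingiva junction is a concave crease, so
#' strongly negative edges mark tooth boundaries. Boundary and non-manifold
#' edges are assigned 0.
#'
#' @param mesh a [dental_mesh()].
#' @param adjacency a [build_adjacency()] index.
#' @return numeric vector of per-edge signed curvature (class
#'   `curvature_field`), aligned with `adjacency$edges`.
#' @export
edge_curvature <- function(mesh, adjacency) {
  ef <- adjacency$edge_faces
  curv <- numeric(nrow(ef))
  ok <- !is.na(ef[, 1]) & !is.na(ef[, 2])
  f1 <- ef[ok, 1]
  f2 <- ef[ok, 2]
  n1 <- mesh$normals[f1, , drop = FALSE]
  n2 <- mesh$normals[f2, , drop = FALSE]
  d <- rowSums(n1 * n2)
  ang <- acos(pmin(1, pmax(-1, d)))
  cen <- face_centroids(mesh)
  # convex fold: the opposite face's centroid lies below the first face's plane
  s <- rowSums((cen[f2, , drop = FALSE] - cen[f1, , drop = FALSE]) * n1)
  curv[ok] <- ifelse(s <= 0, ang, -ang)
  class(curv) <- "curvature_field"
  curv
}

#' Minimum principal curvature field
#'
#' The per-edge dihedral is a local measure: on finely tessellated meshes a
#' crease's total turn is split across several edge rows, each below any
#' useful per-edge threshold, and at the saddle cols between neighbouring
#' teeth the mean curvature is near zero even though the surface is strongly
#' concave across the col. The robust crease detector is the minimum
#' principal curvature: a quadric patch is fitted to each vertex's two-ring
#' neighbourhood in its tangent frame and the smaller eigenvalue of the
#' second fundamental form is returned (1/mm; convex positive, so crease
#' bands and interdental cols are strongly negative while crowns stay near
#' or above zero).
#'
#' @param mesh a [dental_mesh()].
#' @param adjacency a [build_adjacency()] index.
#' @param curvature unused (accepted for call compatibility).
#' @return numeric vector, one value per vertex (1/mm, negative = concave).
#' @export
vertex_concavity <- function(mesh, adjacency, curvature = NULL) {
  v <- mesh$vertices
  nv <- nrow(v)
  f <- mesh$faces

  # area-weighted vertex normals
  cr <- .face_cross(v, f) / 2 # normal * area
  idxf <- factor(as.vector(f), levels = seq_len(nv))
  vn <- cbind(
    as.vector(rowsum(rep(cr[, 1], 3), idxf)),
    as.vector(rowsum(rep(cr[, 2], 3), idxf)),
    as.vector(rowsum(rep(cr[, 3], 3), idxf))
  )
  nn <- sqrt(rowSums(vn^2))
  nn[nn == 0] <- 1
  vn <- vn / nn

  # tangent basis per vertex
  ref <- cbind(
    ifelse(abs(vn[, 1]) < 0.9, 1, 0),
    ifelse(abs(vn[, 1]) < 0.9, 0, 1),
    0
  )
  t1 <- cbind(
    vn[, 2] * ref[, 3] - vn[, 3] * ref[, 2],
    vn[, 3] * ref[, 1] - vn[, 1] * ref[, 3],
    vn[, 1] * ref[, 2] - vn[, 2] * ref[, 1]
  )
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(
    vn[, 2] * t1[, 3] - vn[, 3] * t1[, 2],
    vn[, 3] * t1[, 1] - vn[, 1] * t1[, 3],
    vn[, 1] * t1[, 2] - vn[, 2] * t1[, 1]
  )

  # directed 1-ring + 2-ring neighbour pairs
  e <- adjacency$edges
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  ord <- order(from)
  from_s <- from[ord]
  to_s <- to[ord]
  deg <- tabulate(from_s, nv)
  off <- cumsum(deg) - deg # start offset per vertex
  # second hop: for each directed edge (a,b), pair a with neighbours of b
  rep_idx <- sequence(deg[to_s]) + rep(off[to_s], deg[to_s])
  from2 <- rep(from_s, deg[to_s])
  to2 <- to_s[rep_idx]
  key <- unique(c(from_s * (nv + 1) + to_s, from2 * (nv + 1) + to2))
  a <- key %/% (nv + 1)
  b <- key %% (nv + 1)
  keep <- a != b & b >= 1
  a <- as.integer(a[keep])
  b <- as.integer(b[keep])

  d <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
  xi <- rowSums(d * t1[a, , drop = FALSE])
  eta <- rowSums(d * t2[a, , drop = FALSE])
  zeta <- rowSums(d * vn[a, , drop = FALSE])

  # least squares of zeta = p*xi^2 + q*xi*eta + r*eta^2 per vertex
  m1 <- xi^2
  m2 <- xi * eta
  m3 <- eta^2
  idx <- factor(a, levels = seq_len(nv))
  S11 <- as.vector(rowsum(m1 * m1, idx))
  S12 <- as.vector(rowsum(m1 * m2, idx))
  S13 <- as.vector(rowsum(m1 * m3, idx))
  S22 <- as.vector(rowsum(m2 * m2, idx))
  S23 <- as.vector(rowsum(m2 * m3, idx))
  S33 <- as.vector(rowsum(m3 * m3, idx))
  b1 <- as.vector(rowsum(m1 * zeta, idx))
  b2 <- as.vector(rowsum(m2 * zeta, idx))
  b3 <- as.vector(rowsum(m3 * zeta, idx))
  # ridge for stability
  tr <- S11 + S22 + S33
  lam <- 1e-8 * pmax(tr, 1e-12)
  S11 <- S11 + lam
  S22 <- S22 + lam
  S33 <- S33 + lam
  # analytic symmetric 3x3 solve
  det <- S11 * (S22 * S33 - S23^2) - S12 * (S12 * S33 - S23 * S13) +
    S13 * (S12 * S23 - S22 * S13)
  det[det == 0] <- 1e-30
  p <- (b1 * (S22 * S33 - S23^2) + b2 * (S13 * S23 - S12 * S33) +
    b3 * (S12 * S23 - S13 * S22)) / det
  q <- (b1 * (S23 * S13 - S12 * S33) + b2 * (S11 * S33 - S13^2) +
    b3 * (S12 * S13 - S11 * S23)) / det
  r <- (b1 * (S12 * S23 - S22 * S13) + b2 * (S12 * S13 - S11 * S23) +
    b3 * (S11 * S22 - S12^2)) / det

  # second fundamental form [[2p, q], [q, 2r]]; outward normal makes convex
  # patches curve away (negative), so flip the sign convention
  aa <- 2 * p
  bb <- q
  cc <- 2 * r
  disc <- sqrt((aa - cc)^2 + 4 * bb^2)
  kmin <- -((aa + cc) + disc) / 2
  kmin[!is.finite(kmin)] <- 0
  kmin
}

#' A candidate tooth region ("blob")
#'
#' @param faces integer face indices (connected in the mesh).
#' @param peaks tibble of member peak points (the growth seeds).
#' @param spilled `TRUE` when the growth hit the maximum-travel cap instead of
#'   a gingival crease; such regions are non-tooth and later discarded.
#' @param jaw_parameter arc-length position along the fitted jawline (mm),
#'   `NA` until a jawline is available.
#' @return a `tooth_blob` object.
#' @export
tooth_blob <- function(faces, peaks, spilled = FALSE, jaw_parameter = NA_real_) {
  structure(
    list(
      faces = as.integer(faces), peaks = peaks,
      spilled = isTRUE(spilled), jaw_parameter = jaw_parameter
    ),
    class = "tooth_blob"
  )
}

#' @export
print.tooth_blob <- function(x, ...) {
  cat(sprintf(
    "<tooth_blob: %d faces, %d peak(s), %s%s>\n",
    length(x$faces), nrow(x$peaks),
    if (x$spilled) "spilled" else "bounded",
    if (is.na(x$jaw_parameter)) "" else sprintf(", s = %.1f mm", x$jaw_parameter)
  ))
  invisible(x)
}

#' Grow a tooth region from a peak point
#'
#' Breadth-first traversal over faces starting from the faces incident to the
#' peak vertex. The front never crosses an edge whose signed curvature is at
#' or below `stop_curvature` (a pronounced concave crease — normally the
#' tooth-gingiva junction). As a safety net for peaks that do not sit on a
#' tooth and hence meet no crease, a face whose centroid lies farther than
#' `max_travel` (horizontal distance in the frame) from the peak is never
#' entered; if that cap is ever invoked the blob is flagged `spilled`.
#'
#' @param mesh a [dental_mesh()].
#' @param adjacency a [build_adjacency()] index.
#' @param curvature an [edge_curvature()] field.
#' @param peak one-row tibble from [find_peaks()] (or a list with `vertex`,
#'   `t`, `ap`).
#' @param frame the [arch_frame()] used for the horizontal distance.
#' @param stop_curvature crease threshold in radians, must be negative.
#'   Default -0.6.
#' @param max_travel horizontal travel cap in mm ("a tooth's width").
#'   Default 12 (permanent dentition; use ~9 for deciduous).
#' @param concavity optional [vertex_concavity()] field; edges whose
#'   endpoints reach `stop_concavity` are treated as crease edges too, which
#'   makes the stop rule robust on finely tessellated or noisy meshes where
#'   a crease's turn is split across several edge rows.
#' @param stop_concavity threshold for `concavity`, 1/mm. Default -0.7
#'   (calibrated so that gingival crease bands block growth while smooth
#'   crown surfaces stay passable).
#' @param centroid_th optional precomputed matrix of face-centroid `t`/`ap`
#'   frame coordinates (an optimisation for repeated calls).
#' @return a [tooth_blob()].
#' @export
grow_tooth_region <- function(mesh, adjacency, curvature, peak, frame,
                              stop_curvature = -0.6, max_travel = 12,
                              concavity = NULL, stop_concavity = -0.7,
                              centroid_th = NULL) {
  if (stop_curvature >= 0) stop("`stop_curvature` must be negative")
  if (max_travel <= 0) stop("`max_travel` must be positive")
  pk <- as.list(peak)
  v0 <- as.integer(pk$vertex)
  if (is.na(v0) || v0 < 1L || v0 > nrow(mesh$vertices)) {
    stop("peak vertex is not part of the mesh")
  }
  if (is.null(centroid_th)) {
    centroid_th <- frame_coordinates(face_centroids(mesh), frame)[, c("t", "ap"), drop = FALSE]
  }
  if (is.null(pk$t) || is.null(pk$ap)) {
    p <- frame_coordinates(matrix(c(pk$x, pk$y, pk$z), 1), frame)
    pk$t <- p[1, "t"]
    pk$ap <- p[1, "ap"]
  }
  d2 <- (centroid_th[, 1] - pk$t)^2 + (centroid_th[, 2] - pk$ap)^2
  within <- d2 <= max_travel^2

  passable <- curvature > stop_curvature
  if (!is.null(concavity)) {
    e <- adjacency$edges
    passable <- passable &
      pmin(concavity[e[, 1]], concavity[e[, 2]]) > stop_concavity
  }
  fa <- adjacency$face_adj
  fe <- adjacency$face_edges

  start <- adjacency$vertex_faces[[v0]]
  spilled <- any(!within[start])
  start <- start[within[start]]
  nf <- nrow(mesh$faces)
  visited <- logical(nf)
  visited[start] <- TRUE
  frontier <- sort(start)

  while (length(frontier)) {
    nb <- as.vector(fa[frontier, , drop = FALSE])
    ed <- as.vector(fe[frontier, , drop = FALSE])
    keep <- !is.na(nb) & passable[ed]
    nb <- nb[keep]
    nb <- unique(nb[!visited[nb]])
    if (length(nb) == 0L) break
    blocked <- !within[nb]
    if (any(blocked)) spilled <- TRUE
    nb <- nb[!blocked]
    visited[nb] <- TRUE
    frontier <- sort(nb)
  }

  peaks_tbl <- if (inherits(peak, "data.frame")) {
    peak
  } else {
    tibble::tibble(
      vertex = v0,
      x = if (is.null(pk$x)) NA_real_ else pk$x,
      y = if (is.null(pk$y)) NA_real_ else pk$y,
      z = if (is.null(pk$z)) NA_real_ else pk$z,
      t = pk$t, ap = pk$ap,
      height = if (is.null(pk$height)) NA_real_ else pk$height
    )
  }
  peaks_tbl$spilled <- spilled
  tooth_blob(which(visited), peaks_tbl, spilled = spilled)
}

#' Quadratic jawline through the peak points
#'
#' The dental arch form is approximated by a quadratic `ap = a*t^2 + b*t + c`
#' in the frame's horizontal coordinates, least-squares fitted to the
#' non-spilled peak points. It requires no landmarks, only peaks.
#'
#' @param peaks tibble from [find_peaks()] (column `spilled` respected).
#' @param frame an [arch_frame()] (recorded for provenance).
#' @return a `jawline` object with coefficients `a`, `b`, `c` and the RMS
#'   residual of the fit.
#' @export
fit_jawline <- function(peaks, frame = NULL) {
  use <- peaks[!peaks$spilled, , drop = FALSE]
  if (nrow(use) < 3L || length(unique(round(use$t, 9))) < 3L) {
    stop("need at least 3 non-spilled peaks with distinct transverse coordinates")
  }
  fit <- stats::lm(ap ~ t + I(t^2), data = use)
  co <- stats::coef(fit)
  structure(
    list(
      a = unname(co[3]), b = unname(co[2]), c = unname(co[1]),
      residual_rms = sqrt(mean(stats::residuals(fit)^2)),
      n_peaks = nrow(use)
    ),
    class = "jawline"
  )
}

#' @export
print.jawline <- function(x, ...) {
  cat(sprintf(
    "<jawline: ap = %.4f t^2 + %.4f t + %.2f, RMS residual %.3f mm (%d peaks)>\n",
    x$a, x$b, x$c, x$residual_rms, x$n_peaks
  ))
  invisible(x)
}

#' Evaluate the jawline and its local geometry
#'
#' `jawline_ap()` gives the anteroposterior coordinate at transverse `t`;
#' `jawline_arclength()` the signed arc length along the curve from `t = 0`
#' (the jaw parameter used to order blobs); `jawline_offset()` the signed
#' horizontal distance of points from the curve, positive on the buccal
#' (outer, convex) side.
#'
#' @param jawline a [fit_jawline()] result.
#' @param t transverse coordinate(s), mm.
#' @name jawline_geometry
#' @export
jawline_ap <- function(jawline, t) {
  jawline$a * t^2 + jawline$b * t + jawline$c
}

#' @rdname jawline_geometry
#' @export
jawline_arclength <- function(jawline, t) {
  a <- jawline$a
  b <- jawline$b
  if (abs(a) < 1e-12) {
    return(t * sqrt(1 + b^2))
  }
  F <- function(u) {
    g <- 2 * a * u + b
    (g * sqrt(1 + g^2) + asinh(g)) / (4 * a)
  }
  F(t) - F(0)
}

#' @rdname jawline_geometry
#' @param ap anteroposterior coordinate(s) matching `t`.
#' @export
jawline_offset <- function(jawline, t, ap) {
  slope <- 2 * jawline$a * t + jawline$b
  dap <- ap - jawline_ap(jawline, t)
  side <- if (jawline$a > 0) -1 else 1 # buccal = away from the concave side
  side * dap / sqrt(1 + slope^2)
}

#' Merge candidate tooth blobs
#'
#' Three rules, applied in order: spilled blobs are discarded (they are
#' non-tooth); blobs sharing at least one face are unioned (several cusps of
#' one tooth each seed a region, and those regions overlap); disjoint blobs
#' whose jawline arc-length positions differ by less than `merge_distance`
#' are unioned (the buccal and lingual halves of a molar do not overlap but
#' sit at the same point round the jawline). The result is sorted left to
#' right round the jaw by jaw parameter.
#'
#' @param blobs list of [tooth_blob()]s.
#' @param jawline a [fit_jawline()] result.
#' @param merge_distance arc-length tolerance in mm for the same-position
#'   rule. Default 3 (a quarter of the permanent travel cap): half-blobs of
#'   one tooth sit within ~2 mm of each other along the arch while adjacent
#'   teeth are at least a tooth's half-width apart.
#' @return list of disjoint `tooth_blob`s, each with `jaw_parameter` set,
#'   sorted by increasing jaw parameter.
#' @export
merge_blobs <- function(blobs, jawline, merge_distance = 3) {
  blobs <- Filter(function(b) !b$spilled, blobs)
  n <- length(blobs)
  if (n == 0L) return(list())

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  # rule ii: shared faces
  face_owner <- data.frame(
    face = unlist(lapply(blobs, `[[`, "faces")),
    blob = rep(seq_len(n), vapply(blobs, function(b) length(b$faces), integer(1)))
  )
  dup <- face_owner[duplicated(face_owner$face) | duplicated(face_owner$face, fromLast = TRUE), ]
  if (nrow(dup)) {
    for (grp in split(dup$blob, dup$face)) {
      for (k in seq_along(grp)[-1]) union(grp[1], grp[k])
    }
  }

  # jaw parameter: arc length at the highest member peak of each root group
  jp <- vapply(blobs, function(b) {
    pk <- b$peaks[which.max(b$peaks$height), ]
    jawline_arclength(jawline, pk$t)
  }, numeric(1))

  # rule iii: same position round the jawline (after overlap unions)
  roots <- vapply(seq_len(n), find, integer(1))
  grp_jp <- tapply(jp, roots, function(x) x[1]) # representative; refined below
  # use the group's highest peak for its jaw parameter
  for (r in unique(roots)) {
    members <- which(roots == r)
    pks <- do.call(rbind, lapply(blobs[members], function(b) b$peaks))
    grp_jp[as.character(r)] <- jawline_arclength(jawline, pks$t[which.max(pks$height)])
  }
  ur <- unique(roots)
  if (length(ur) > 1L) {
    for (i in seq_along(ur)) {
      for (j in seq_len(i - 1L)) {
        if (abs(grp_jp[as.character(ur[i])] - grp_jp[as.character(ur[j])]) < merge_distance) {
          union(ur[i], ur[j])
        }
      }
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    members <- which(roots == r)
    faces <- sort(unique(unlist(lapply(blobs[members], `[[`, "faces"))))
    pks <- dplyr::distinct(
      dplyr::bind_rows(lapply(blobs[members], `[[`, "peaks")),
      .data$vertex,
      .keep_all = TRUE
    )
    top <- pks[which.max(pks$height), ]
    tooth_blob(faces, pks,
      spilled = FALSE,
      jaw_parameter = jawline_arclength(jawline, top$t)
    )
  })
  out[order(vapply(out, `[[`, numeric(1), "jaw_parameter"))]
}

#' Partition an arch into candidate tooth blobs
#'
#' Driver for the partition stage: grows a region from every peak, fits the
#' jawline to the non-spilled peaks, and merges. Peaks whose growth spilled
#' are flagged in the returned peak table.
#'
#' @inheritParams grow_tooth_region
#' @param peaks tibble from [find_peaks()].
#' @param merge_distance see [merge_blobs()]; default `max_travel / 3`.
#' @return list with `blobs` (merged, sorted), `jawline`, and `peaks` (the
#'   input tibble with the `spilled` flags filled in).
#' @export
partition_teeth <- function(mesh, adjacency, frame, peaks,
                            curvature = NULL,
                            stop_curvature = -0.6, max_travel = 12,
                            merge_distance = max_travel / 3,
                            concavity = NULL, stop_concavity = -0.7) {
  if (is.null(curvature)) curvature <- edge_curvature(mesh, adjacency)
  if (is.null(concavity)) {
    concavity <- vertex_concavity(mesh, adjacency, curvature)
  }
  centroid_th <- frame_coordinates(face_centroids(mesh), frame)[, c("t", "ap"), drop = FALSE]
  raw <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    raw[[i]] <- grow_tooth_region(
      mesh, adjacency, curvature, peaks[i, ], frame,
      stop_curvature = stop_curvature, max_travel = max_travel,
      concavity = concavity, stop_concavity = stop_concavity,
      centroid_th = centroid_th
    )
  }
  peaks$spilled <- vapply(raw, `[[`, logical(1), "spilled")
  jl <- fit_jawline(peaks, frame)
  blobs <- merge_blobs(raw, jl, merge_distance = merge_distance)
  list(blobs = blobs, jawline = jl, peaks = peaks)
}
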