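#' Anatomical frame of a dental arch
#'
#' An `arch_frame` holds the arch's centroid and a right-handed orthonormal
#' triple of unit axes: `transverse` (left-right, the arch's widest
#' dimension), `anteroposterior` (pointing anterior, towards the incisors) and
#' `occlusal` (pointing towards the biting surfaces, i.e. towards the crowns).
#'
#' @param origin length-3 numeric, frame origin (mm).
#' @param transverse,anteroposterior,occlusal unit 3-vectors.
#' @return an `arch_frame` object.
#' @export
arch_frame <- function(origin, transverse, anteroposterior, occlusal) {
  B <- rbind(transverse, anteroposterior, occlusal)
  if (max(abs(B %*% t(B) - diag(3))) > 1e-6) {
    stop("arch_frame axes must be orthonormal")
  }
  structure(
    list(
      origin = as.numeric(origin),
      transverse = as.numeric(transverse) / sqrt(sum(transverse^2)),
      anteroposterior = as.numeric(anteroposterior) / sqrt(sum(anteroposterior^2)),
      occlusal = as.numeric(occlusal) / sqrt(sum(occlusal^2))
    ),
    class = "arch_frame"
  )
}

#' @export
print.arch_frame <- function(x, ...) {
  cat("<arch_frame>\n")
  cat(sprintf("  origin:          %8.3f %8.3f %8.3f\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  transverse:      %8.4f %8.4f %8.4f\n", x$transverse[1], x$transverse[2], x$transverse[3]))
  cat(sprintf("  anteroposterior: %8.4f %8.4f %8.4f\n", x$anteroposterior[1], x$anteroposterior[2], x$anteroposterior[3]))
  cat(sprintf("  occlusal:        %8.4f %8.4f %8.4f\n", x$occlusal[1], x$occlusal[2], x$occlusal[3]))
  invisible(x)
}

.cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Express mesh vertices in frame coordinates
#'
#' @param mesh a [dental_mesh()] (or a plain coordinate matrix).
#' @param frame an [arch_frame()].
#' @return matrix with columns `t` (transverse), `ap` (anteroposterior) and
#'   `h` (occlusal height), in mm relative to the frame origin.
#' @export
frame_coordinates <- function(mesh, frame) {
  v <- if (inherits(mesh, "dental_mesh")) mesh$vertices else as.matrix(mesh)
  centred <- sweep(v, 2, frame$origin)
  out <- centred %*% cbind(frame$transverse, frame$anteroposterior, frame$occlusal)
  colnames(out) <- c("t", "ap", "h")
  out
}

#' Provisional anatomical axes by principal component analysis
#'
#' A dental arch is wider (transverse) than it is long (anteroposterior) and
#' longer than it is tall, so the covariance eigenvectors of the vertex cloud,
#' ordered by decreasing variance, give transverse, anteroposterior and
#' occlusal directions. Signs are provisional; see [disambiguate_signs()].
#'
#' @param mesh a [dental_mesh()].
#' @return an [arch_frame()] centred on the vertex centroid.
#' @export
pca_axes <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) < 3L) stop("need at least 3 vertices for PCA")
  origin <- colMeans(v)
  cv <- stats::cov(v)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] <= 1e-9 * max(eg$values[1], 1e-12)) {
    stop("degenerate vertex covariance (rank < 3): cannot orient")
  }
  tr <- eg$vectors[, 1]
  ap <- eg$vectors[, 2]
  oc <- .cross3(tr, ap) # right-handed by construction
  arch_frame(origin, tr, ap, oc)
}

# area of the 2D convex hull of points (n x 2)
.hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy)
  p <- xy[h, , drop = FALSE]
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Resolve the up/down and anterior/posterior sign ambiguity
#'
#' PCA gives axes up to sign. The occlusal sign is fixed by a taper test:
#' crowns narrow towards the cusp tips while the base of a cast or scan is
#' broad, so the convex-hull footprint of the top decile slab of vertices
#' (along the occlusal axis) should be smaller than that of the bottom decile
#' slab. The anterior sign is fixed so that the quadratic arch form fitted to
#' the horizontal vertex coordinates opens towards posterior (the arch
#' concavity faces back). The transverse axis is then recomputed to keep the
#' frame right-handed.
#'
#' @param mesh a [dental_mesh()].
#' @param frame provisional [arch_frame()] from [pca_axes()].
#' @param taper_ratio footprint ratio below which the up/down call is deemed
#'   ambiguous and the provisional sign kept (with a warning). Default 1.05.
#' @return a sign-resolved [arch_frame()].
#' @export
disambiguate_signs <- function(mesh, frame, taper_ratio = 1.05) {
  fc <- frame_coordinates(mesh, frame)
  h <- fc[, "h"]
  rng <- range(h)
  slab <- 0.1 * diff(rng)
  top <- fc[h >= rng[2] - slab, c("t", "ap"), drop = FALSE]
  bot <- fc[h <= rng[1] + slab, c("t", "ap"), drop = FALSE]
  a_top <- .hull_area(top)
  a_bot <- .hull_area(bot)

  occ <- frame$occlusal
  if (a_top > 0 && a_bot > 0 &&
    max(a_top, a_bot) / min(a_top, a_bot) < taper_ratio) {
    warning("up/down taper test ambiguous (footprints within 5%); keeping provisional occlusal sign")
  } else if (a_top > a_bot) {
    occ <- -occ
  }

  # anterior: quadratic fit ap ~ t over the horizontal coordinates must open
  # towards posterior (negative leading coefficient)
  fc2 <- frame_coordinates(mesh, arch_frame(
    frame$origin, frame$transverse,
    frame$anteroposterior, occ
  ))
  tt <- fc2[, "t"]
  ap <- fc2[, "ap"]
  co <- stats::coef(stats::lm(ap ~ tt + I(tt^2)))
  apax <- frame$anteroposterior
  if (is.finite(co[3]) && co[3] > 0) apax <- -apax

  trans <- .cross3(apax, occ)
  arch_frame(frame$origin, trans, apax, occ)
}

#' Refine the occlusal axis from tooth-tip positions
#'
#' The vertical direction matters more than the horizontal ones, so after a
#' coarse peak pass the occlusal axis is re-estimated as the normal of the
#' least-squares plane through the peak points (total least squares via SVD).
#' The remaining axes are re-orthogonalised against it.
#'
#' @param frame an [arch_frame()].
#' @param peak_positions numeric matrix (>= 3 rows) of peak coordinates (mm).
#' @return an [arch_frame()] with attribute `refined` (`TRUE` if the
#'   refinement was applied, `FALSE` if skipped for lack of usable peaks).
#' @export
refine_occlusal <- function(frame, peak_positions) {
  p <- as.matrix(peak_positions)
  skip <- function() {
    attr(frame, "refined") <- FALSE
    frame
  }
  if (nrow(p) < 3L) return(skip())
  cen <- sweep(p, 2, colMeans(p))
  sv <- svd(cen)
  # collinear peaks: second singular value vanishes relative to the first
  if (sv$d[2] <= 1e-8 * max(sv$d[1], 1e-12)) return(skip())
  n <- sv$v[, 3]
  if (sum(n * frame$occlusal) < 0) n <- -n
  ap <- frame$anteroposterior - sum(frame$anteroposterior * n) * n
  ap <- ap / sqrt(sum(ap^2))
  trans <- .cross3(ap, n)
  out <- arch_frame(frame$origin, trans, ap, n)
  attr(out, "refined") <- TRUE
  out
}

#' Full orientation pass for one arch
#'
#' Runs [pca_axes()], [disambiguate_signs()], a coarse peak detection, one
#' [refine_occlusal()] iteration, and returns the refined frame. Exactly one
#' refinement iteration is used: the coarse peaks fix the tooth-tip plane well
#' enough that further iterations change the axis by less than the peak
#' detection's own resolution.
#'
#' @param mesh a [dental_mesh()].
#' @param adjacency optional [build_adjacency()] result (computed if missing).
#' @param depth_threshold depth band below the highest point searched for
#'   peaks during the refinement pass (mm). Default 6.
#' @return an [arch_frame()].
#' @export
orient_arch <- function(mesh, adjacency = NULL, depth_threshold = 6) {
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  frame <- disambiguate_signs(mesh, pca_axes(mesh))
  peaks <- find_peaks(mesh, adjacency, frame, depth_threshold = depth_threshold)
  refine_occlusal(frame, as.matrix(peaks[, c("x", "y", "z")]))
}
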