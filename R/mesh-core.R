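#' Triangle mesh of a dental arch
#'
#' A `dental_mesh` is a minimal triangle-mesh container: a numeric matrix of
#' vertex coordinates in millimetres and an integer matrix of 1-based face
#' indices. Per-face unit normals are derived from the face winding at
#' construction time. Duplicate vertices (within `merge_tol` mm, the per-facet
#' duplication inherent to STL) are merged and zero-area faces dropped so that
#' adjacency walks behave.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param merge_tol vertices closer than this (mm) are collapsed. Default 1e-6.
#' @return an object of class `dental_mesh` with elements `vertices`, `faces`
#'   and `normals` (per-face unit normals).
#' @examples
#' m <- dental_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
#' surface_area(m)
#' @export
dental_mesh <- function(vertices, faces, merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (any(is.na(vertices))) stop("`vertices` contains NA")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face index out of bounds")
  }

  # merge duplicate vertices: quantise coordinates on a merge_tol grid
  key <- paste(
    round(vertices[, 1] / merge_tol),
    round(vertices[, 2] / merge_tol),
    round(vertices[, 3] / merge_tol)
  )
  first <- !duplicated(key)
  remap <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces[] <- remap[faces]

  # drop degenerate faces (collapsed or numerically zero area)
  collapsed <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!collapsed, , drop = FALSE]
  if (nrow(faces) == 0L) stop("mesh has no non-degenerate faces")
  a <- .face_area_vec(vertices, faces)
  faces <- faces[a > 1e-12, , drop = FALSE]
  if (nrow(faces) == 0L) stop("mesh has no non-degenerate faces")

  structure(
    list(
      vertices = vertices,
      faces = faces,
      normals = .face_normal_mat(vertices, faces)
    ),
    class = "dental_mesh"
  )
}

#' @export
print.dental_mesh <- function(x, ...) {
  rng <- apply(x$vertices, 2, range)
  cat(sprintf(
    "<dental_mesh: %d vertices, %d faces, extent %.1f x %.1f x %.1f mm>\n",
    nrow(x$vertices), nrow(x$faces),
    diff(rng[, 1]), diff(rng[, 2]), diff(rng[, 3])
  ))
  invisible(x)
}

#' @export
format.dental_mesh <- function(x, ...) {
  sprintf("<dental_mesh: %d vertices, %d faces>", nrow(x$vertices), nrow(x$faces))
}

# unnormalised face cross products (rows)
.face_cross <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - p1
  e2 <- vertices[faces[, 3], , drop = FALSE] - p1
  cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
}

.face_area_vec <- function(vertices, faces) {
  cr <- .face_cross(vertices, faces)
  0.5 * sqrt(rowSums(cr^2))
}

.face_normal_mat <- function(vertices, faces) {
  cr <- .face_cross(vertices, faces)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

#' Face centroids
#' @param mesh a [dental_mesh()].
#' @return numeric matrix, one row per face.
#' @keywords internal
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
    mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
    mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Surface area of a mesh or a subset of its faces
#'
#' Sum of triangle areas (half cross-product magnitude), in square millimetres.
#'
#' @param mesh a [dental_mesh()].
#' @param face_subset optional integer vector of face indices; default all.
#' @return total area in mm^2.
#' @export
surface_area <- function(mesh, face_subset = NULL) {
  faces <- mesh$faces
  if (!is.null(face_subset)) {
    face_subset <- as.integer(face_subset)
    if (any(face_subset < 1L) || any(face_subset > nrow(faces))) {
      stop("face index out of bounds")
    }
    faces <- faces[face_subset, , drop = FALSE]
  }
  sum(.face_area_vec(mesh$vertices, faces))
}

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh a [dental_mesh()].
#' @param rotation 3x3 matrix applied to coordinates.
#' @param translation length-3 numeric offset, applied after rotation.
#' @return a transformed `dental_mesh`. If `rotation` has negative determinant
#'   (a reflection) the face winding is flipped so normals stay outward.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  f <- mesh$faces
  if (det(rotation) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  dental_mesh(v, f)
}

#' Read an STL file (binary or ASCII)
#'
#' Coordinates are taken to be millimetres, the convention of intra-oral
#' scanner exports. Duplicate vertices are merged (STL repeats each vertex per
#' facet) and facet normals are recomputed from the winding.
#'
#' @param path path to an `.stl` file.
#' @return a [dental_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file does not exist: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("STL file is empty or corrupt: ", path)

  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (size >= 84) {
    n_declared <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(n_declared) && n_declared >= 0 &&
      size == 84 + 50 * as.numeric(n_declared)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    if (n_declared == 0L) stop("STL file declares zero triangles: ", path)
    body <- readBin(con, "raw", 50L * n_declared)
    # strip the 2-byte per-facet attribute words, keep the 12 float32s
    keep <- rep(rep(c(TRUE, FALSE), c(48L, 2L)), n_declared)
    vals <- readBin(body[keep], "numeric",
      n = 12L * n_declared,
      size = 4L, endian = "little"
    )
    rec <- matrix(vals, ncol = 12L, byrow = TRUE)
    verts <- matrix(t(rec[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  } else {
    verts <- .parse_ascii_stl(path)
  }
  n_tri <- nrow(verts) / 3L
  if (n_tri < 1) stop("STL file contains no triangles: ", path)
  faces <- matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE)
  dental_mesh(verts, faces)
}

.parse_ascii_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    stop("cannot parse STL file (not binary, not valid ASCII): ", path)
  }
  nums <- suppressWarnings(vapply(
    strsplit(trimws(vlines), "\\s+"),
    function(x) as.numeric(x[2:4]), numeric(3)
  ))
  if (any(is.na(nums))) stop("corrupt vertex line in ASCII STL: ", path)
  t(nums)
}

#' Write a mesh to STL
#'
#' @param mesh a [dental_mesh()].
#' @param path output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  nf <- nrow(f)
  normals <- mesh$normals
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "dentomark binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    rec <- cbind(
      normals,
      v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
      v[f[, 3], , drop = FALSE]
    )
    floats <- writeBin(as.numeric(t(rec)), raw(), size = 4L, endian = "little")
    fm <- matrix(floats, nrow = 48L)
    body <- rbind(fm, matrix(as.raw(0), nrow = 2L, ncol = nf))
    writeBin(as.vector(body), con)
  } else {
    fmt_pt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c(
      "solid dentomark",
      as.vector(rbind(
        paste("  facet normal", fmt_pt(normals)),
        "    outer loop",
        paste("      vertex", fmt_pt(v[f[, 1], , drop = FALSE])),
        paste("      vertex", fmt_pt(v[f[, 2], , drop = FALSE])),
        paste("      vertex", fmt_pt(v[f[, 3], , drop = FALSE])),
        "    endloop",
        "  endfacet"
      )),
      "endsolid dentomark"
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Build the adjacency index of a mesh
#'
#' Face-to-face adjacency across shared edges, vertex incidence, and the edge
#' list with signed curvature support. Non-manifold edges (more than two
#' incident faces) are tolerated: they are recorded and treated as boundaries
#' by traversals, since imperfect scans routinely contain them.
#'
#' @param mesh a [dental_mesh()].
#' @return an object of class `mesh_adjacency`: `edges` (E x 2 vertex pairs,
#'   min first), `edge_faces` (E x 2 incident faces, NA where boundary),
#'   `face_edges` (F x 3 edge ids), `face_adj` (F x 3 neighbour faces across
#'   each edge, NA at boundaries/non-manifold), `vertex_faces` and
#'   `vertex_neighbours` (lists), `nonmanifold` (edge ids with >2 faces).
#' @export
build_adjacency <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  nv <- nrow(mesh$vertices)

  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(ea[, 1], ea[, 2])
  hi <- pmax(ea[, 1], ea[, 2])
  key <- (lo - 1) * as.numeric(nv) + hi
  ukey <- sort(unique(key))
  eid <- match(key, ukey) # edge id for each of the 3F half-edges
  ne <- length(ukey)

  edges <- cbind(
    as.integer((ukey - 1) %/% nv + 1),
    as.integer((ukey - 1) %% nv + 1)
  )

  half_face <- rep(seq_len(nf), 3L)
  ord <- order(eid, half_face)
  cnt <- tabulate(eid, ne)
  nonmanifold <- which(cnt > 2L)

  edge_faces <- matrix(NA_integer_, ne, 2L)
  pos <- ord[cumsum(cnt) - cnt + 1L] # first half-edge of each edge
  edge_faces[, 1] <- half_face[pos]
  two <- which(cnt >= 2L)
  pos2 <- ord[(cumsum(cnt) - cnt + 2L)[two]]
  edge_faces[two, 2] <- half_face[pos2]
  # >2-incident edges act as boundaries: drop their face pairing
  if (length(nonmanifold)) edge_faces[nonmanifold, ] <- NA_integer_

  face_edges <- matrix(eid, nf, 3L)
  face_adj <- matrix(NA_integer_, nf, 3L)
  for (k in 1:3) {
    e <- face_edges[, k]
    f1 <- edge_faces[e, 1]
    f2 <- edge_faces[e, 2]
    self <- seq_len(nf)
    nb <- ifelse(!is.na(f1) & f1 != self, f1, f2)
    nb[!is.na(nb) & nb == self] <- NA_integer_
    face_adj[, k] <- nb
  }

  vertex_faces <- split(
    rep(seq_len(nf), 3L),
    factor(as.vector(f), levels = seq_len(nv))
  )
  vertex_neighbours <- split(
    c(edges[, 2], edges[, 1]),
    factor(c(edges[, 1], edges[, 2]), levels = seq_len(nv))
  )

  structure(
    list(
      edges = edges, edge_faces = edge_faces, face_edges = face_edges,
      face_adj = face_adj, vertex_faces = vertex_faces,
      vertex_neighbours = vertex_neighbours, nonmanifold = nonmanifold
    ),
    class = "mesh_adjacency"
  )
}

#' @export
print.mesh_adjacency <- function(x, ...) {
  cat(sprintf(
    "<mesh_adjacency: %d edges, %d faces, %d non-manifold edges>\n",
    nrow(x$edges), nrow(x$face_edges), length(x$nonmanifold)
  ))
  invisible(x)
}

#' Light feature-preserving mesh smoothing (Taubin lambda/mu)
#'
#' Alternating positive/negative umbrella-operator passes remove the
#' high-frequency terracing that isosurfacing and scanner tessellation leave
#' on gentle slopes, without the shrinkage of plain Laplacian smoothing.
#' Creases and cusps (low-frequency features) are preserved.
#'
#' @param mesh a [dental_mesh()].
#' @param iterations number of lambda+mu pairs. Default 2.
#' @param lambda,mu Taubin coefficients. Defaults 0.5 / -0.53.
#' @return a smoothed [dental_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 2L, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices
  nv <- nrow(v)
  e <- build_adjacency(mesh)$edges
  idx <- c(e[, 1], e[, 2])
  deg <- tabulate(idx, nv)
  deg[deg == 0] <- 1
  step <- function(v, w) {
    nb <- rowsum(v[c(e[, 2], e[, 1]), , drop = FALSE], idx, reorder = TRUE)
    v + w * (nb / deg - v)
  }
  for (i in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  dimnames(v) <- NULL
  # rebuild in place: vertex count, order and face indexing are preserved so
  # that face-level annotations (region masks) remain valid
  structure(
    list(vertices = v, faces = mesh$faces, normals = .face_normal_mat(v, mesh$faces)),
    class = "dental_mesh"
  )
}
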