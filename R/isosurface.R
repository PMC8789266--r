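#' Extract the zero isosurface of a scalar field (marching tetrahedra)
#'
#' Converts a signed scalar field sampled on a regular grid into a triangle
#' mesh of its zero level set (negative = inside). Each grid cell is split
#' into the six Kuhn tetrahedra; because the Kuhn split draws every cube-face
#' diagonal from the low corner to the high corner it is consistent across
#' neighbouring cells, so the extracted surface is watertight wherever the
#' field is. Vertices are placed on tetrahedron edges by linear interpolation
#' and shared between adjacent triangles. Triangle winding is fixed so that
#' normals point from inside (negative field) to outside.
#'
#' @param f 3D numeric array of field values, dimensions
#'   `length(x) * length(y) * length(z)`.
#' @param x,y,z grid coordinate vectors (mm), strictly increasing.
#' @return a [dental_mesh()].
#' @export
marching_tetrahedra <- function(f, x, y, z) {
  nx <- length(x)
  ny <- length(y)
  nz <- length(z)
  stopifnot(all(dim(f) == c(nx, ny, nz)))
  f[f == 0] <- 1e-12 # avoid vertices exactly on the surface
  inside <- f < 0

  ii <- seq_len(nx - 1L)
  jj <- seq_len(ny - 1L)
  kk <- seq_len(nz - 1L)
  sh <- function(di, dj, dk) inside[ii + di, jj + dj, kk + dk]
  cnt <- sh(0, 0, 0) + sh(1, 0, 0) + sh(0, 1, 0) + sh(1, 1, 0) +
    sh(0, 0, 1) + sh(1, 0, 1) + sh(0, 1, 1) + sh(1, 1, 1)
  act <- which(cnt > 0L & cnt < 8L)
  if (length(act) == 0L) stop("field has no zero crossing: empty isosurface")
  ai <- arrayInd(act, c(nx - 1L, ny - 1L, nz - 1L))

  nxy <- as.numeric(nx) * ny
  gid0 <- ai[, 1] + (ai[, 2] - 1) * as.numeric(nx) + (ai[, 3] - 1) * nxy
  # corner b (bit0 -> +x, bit1 -> +y, bit2 -> +z)
  offs <- c(0, 1, nx, nx + 1, nxy, nxy + 1, nxy + nx, nxy + nx + 1)

  pos_of <- function(g) {
    g1 <- g - 1
    cbind(
      x[g1 %% nx + 1],
      y[(g1 %/% nx) %% ny + 1],
      z[g1 %/% nxy + 1]
    )
  }

  # Kuhn tetrahedra: vertex paths 0 -> 7 adding one axis at a time
  tets <- list(
    c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
    c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L)
  )

  # per sign-case: triangles as 3 rows of (inside local id, outside local id)
  cases <- vector("list", 14L)
  for (cs in 1:14) {
    ins <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0L)
    outs <- setdiff(1:4, ins)
    if (length(ins) == 1L) {
      cases[[cs]] <- list(cbind(rep(ins, 3L), outs))
    } else if (length(ins) == 3L) {
      cases[[cs]] <- list(cbind(ins, rep(outs, 3L)))
    } else {
      i1 <- ins[1]; i2 <- ins[2]; o1 <- outs[1]; o2 <- outs[2]
      cases[[cs]] <- list(
        rbind(c(i1, o1), c(i1, o2), c(i2, o2)),
        rbind(c(i1, o1), c(i2, o2), c(i2, o1))
      )
    }
  }

  tri_keys <- list() # per triangle batch: n x 3 edge keys
  tri_ref <- list() # per batch: n x 3 inside->outside reference vectors
  nbig <- nxy * nz

  for (tet in tets) {
    G <- cbind(
      gid0 + offs[tet[1] + 1L], gid0 + offs[tet[2] + 1L],
      gid0 + offs[tet[3] + 1L], gid0 + offs[tet[4] + 1L]
    )
    FV <- matrix(f[G], nrow(G), 4L)
    caseid <- (FV[, 1] < 0) + 2L * (FV[, 2] < 0) +
      4L * (FV[, 3] < 0) + 8L * (FV[, 4] < 0)
    for (cs in 1:14) {
      rows <- which(caseid == cs)
      if (length(rows) == 0L) next
      Gc <- G[rows, , drop = FALSE]
      ins <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      corner_mean <- function(cols) {
        P <- pos_of(as.vector(Gc[, cols, drop = FALSE]))
        if (length(cols) == 1L) return(P)
        k <- length(cols)
        cbind(
          rowMeans(matrix(P[, 1], ncol = k)),
          rowMeans(matrix(P[, 2], ncol = k)),
          rowMeans(matrix(P[, 3], ncol = k))
        )
      }
      ref <- corner_mean(outs) - corner_mean(ins)
      for (tri in cases[[cs]]) {
        k3 <- matrix(0, length(rows), 3L)
        for (e in 1:3) {
          ga <- Gc[, tri[e, 1]]
          gb <- Gc[, tri[e, 2]]
          k3[, e] <- pmin(ga, gb) * nbig + pmax(ga, gb)
        }
        tri_keys[[length(tri_keys) + 1L]] <- k3
        tri_ref[[length(tri_ref) + 1L]] <- ref
      }
    }
  }

  K <- do.call(rbind, tri_keys)
  REF <- do.call(rbind, tri_ref)
  uk <- unique(as.vector(K))
  ga <- floor((uk - 1e-9) / nbig)
  gb <- uk - ga * nbig
  fa <- f[ga]
  fb <- f[gb]
  tt <- fa / (fa - fb)
  pa <- pos_of(ga)
  pb <- pos_of(gb)
  verts <- pa + tt * (pb - pa)

  faces <- matrix(match(as.vector(K), uk), ncol = 3L)

  # orient: normal must point along the inside->outside reference
  v1 <- verts[faces[, 1], , drop = FALSE]
  e1 <- verts[faces[, 2], , drop = FALSE] - v1
  e2 <- verts[faces[, 3], , drop = FALSE] - v1
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  flip <- rowSums(nrm * REF) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]

  dental_mesh(verts, faces)
}
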