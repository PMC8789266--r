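#' Occlusal peak points of an arch
#'
#' Cusp tips and incisal edges are the highest parts of the teeth, so
#' candidate landmarks are local maxima of the vertex height along the
#' occlusal axis. Only a depth band below the arch's highest point is
#' searched (default 6 mm) — deep enough to catch worn or partially erupted
#' teeth while excluding most non-tooth structure. Non-tooth and duplicate
#' peaks are allowed here; later stages filter them.
#'
#' A vertex is a peak when its height is greater than or equal to every
#' vertex in its `ring`-neighbourhood and strictly greater than at least one
#' of them; exact ties are broken towards the lowest vertex index, so a flat
#' plateau yields a single representative.
#'
#' @param mesh a [dental_mesh()].
#' @param adjacency a [build_adjacency()] index for `mesh`.
#' @param frame an [arch_frame()].
#' @param depth_threshold depth band below the global maximum (mm). Default 6.
#' @param ring neighbourhood radius in edge hops. Default 2 (a 1-ring is too
#'   sensitive to scan noise on fine meshes).
#' @return a tibble sorted by descending height with columns `vertex`, `x`,
#'   `y`, `z`, `t`, `ap`, `height` and `spilled` (all `FALSE`; set by the
#'   partition stage).
#' @export
find_peaks <- function(mesh, adjacency, frame, depth_threshold = 6, ring = 2L) {
  if (depth_threshold <= 0) stop("`depth_threshold` must be positive")
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  fc <- frame_coordinates(mesh, frame)
  h <- fc[, "h"]
  hmax <- max(h)
  cand <- which(h >= hmax - depth_threshold)

  nb <- adjacency$vertex_neighbours
  is_peak <- logical(length(cand))
  for (i in seq_along(cand)) {
    v <- cand[i]
    ringset <- .ring_neighbourhood(nb, v, ring)
    if (length(ringset) == 0L) next
    hv <- h[v]
    hr <- h[ringset]
    dominated <- any(hr > hv) ||
      any(hr == hv & ringset < v)
    is_peak[i] <- !dominated && any(hr < hv)
  }

  idx <- cand[is_peak]
  ord <- order(-h[idx], idx)
  idx <- idx[ord]
  tibble::tibble(
    vertex = idx,
    x = mesh$vertices[idx, 1],
    y = mesh$vertices[idx, 2],
    z = mesh$vertices[idx, 3],
    t = fc[idx, "t"],
    ap = fc[idx, "ap"],
    height = h[idx],
    spilled = FALSE
  )
}

# vertices within `ring` edge hops of v, excluding v itself
.ring_neighbourhood <- function(vertex_neighbours, v, ring) {
  seen <- v
  frontier <- v
  for (r in seq_len(ring)) {
    nxt <- unique(unlist(vertex_neighbours[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    if (length(frontier) == 0L) break
    seen <- c(seen, frontier)
  }
  setdiff(seen, v)
}
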