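# shared fixtures, built in code and cached across test files

cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
  )
  dental_mesh(v, f)
}

tetra_vertices <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0.4, 1)
)
tetra_faces <- rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4))

# regular x-y grid triangulated into a plane (flat) or a height field
grid_mesh <- function(nx = 15, ny = 15, dx = 1, heightfun = NULL) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  z <- if (is.null(heightfun)) 0 else heightfun((g$x - 1) * dx, (g$y - 1) * dx)
  v <- cbind((g$x - 1) * dx, (g$y - 1) * dx, z)
  id <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    f <- rbind(
      f,
      cbind(id(i, j), id(i + 1, j), id(i, j + 1)),
      cbind(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
    )
  }
  dental_mesh(v, f)
}

# strip folded into a 90-degree concave V-groove along y
v_groove_mesh <- function(n = 10) {
  xs <- seq(-3, 3, length.out = 7)
  prof_z <- abs(xs) # V profile, crease at x = 0
  v <- NULL
  for (y in seq(0, n)) v <- rbind(v, cbind(xs, y, prof_z))
  nxp <- length(xs)
  id <- function(i, j) j * nxp + i
  f <- NULL
  for (j in seq_len(n) - 1) {
    i <- seq_len(nxp - 1)
    f <- rbind(
      f,
      cbind(id(i, j), id(i + 1, j), id(i, j + 1)),
      cbind(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
    )
  }
  dental_mesh(v, f)
}

sphere_mesh <- function(radius = 1, res = 0.25) {
  x <- seq(-radius - 2 * res, radius + 2 * res, by = res)
  f <- array(0, c(length(x), length(x), length(x)))
  for (k in seq_along(x)) {
    f[, , k] <- sqrt(outer(x^2, x^2, "+") + x[k]^2) - radius
  }
  marching_tetrahedra(f, x, x, x)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# cached default arch + recognition (expensive; built once per run)
.fixture_env <- new.env(parent = emptyenv())

fixture_arch <- function() {
  if (is.null(.fixture_env$arch)) {
    spec <- arch_spec(jaw = "mandibular", dentition = "permanent", seed = 1L)
    .fixture_env$arch <- generate_arch(spec)
  }
  .fixture_env$arch
}

fixture_recognition <- function() {
  if (is.null(.fixture_env$recog)) {
    gen <- fixture_arch()
    .fixture_env$recog <- run_recognition(
      gen$mesh,
      jaw = "mandibular", dentition = "permanent"
    )
  }
  .fixture_env$recog
}

# small fast arch: deciduous, coarse resolution
fixture_mini_arch <- function() {
  if (is.null(.fixture_env$mini)) {
    spec <- arch_spec(
      jaw = "mandibular", dentition = "deciduous",
      resolution = 0.55, seed = 7L
    )
    .fixture_env$mini <- generate_arch(spec)
  }
  .fixture_env$mini
}

# brute-force assignment oracle: enumerate every monotone alignment
brute_force_assignment <- function(C, H0, H1, is_molar, gap, discard) {
  n <- nrow(C)
  m <- ncol(C)
  best <- Inf
  rec <- function(i, j, cost) {
    if (cost >= best) return()
    if (i > n && j > m) {
      best <<- min(best, cost)
      return()
    }
    if (j <= m) rec(i, j + 1, cost + gap)
    if (i <= n) rec(i + 1, j, cost + discard)
    if (i <= n && j <= m) {
      rec(i + 1, j + 1, cost + C[i, j])
      if (is_molar[j] && i + 1 <= n && is.finite(H0[i, j])) {
        rec(i + 2, j + 1, cost + H0[i, j] + H1[i + 1, j])
      }
    }
  }
  rec(1, 1, 0)
  best
}

# exhaustive peak oracle: full ring-neighbourhood scan of every vertex
peak_oracle <- function(mesh, adjacency, frame, depth_threshold = 6, ring = 2) {
  fc <- frame_coordinates(mesh, frame)
  h <- fc[, "h"]
  hmax <- max(h)
  nb <- adjacency$vertex_neighbours
  out <- integer(0)
  for (v in seq_len(nrow(mesh$vertices))) {
    if (h[v] < hmax - depth_threshold) next
    seen <- v
    frontier <- v
    for (r in seq_len(ring)) {
      nxt <- setdiff(unique(unlist(nb[frontier], use.names = FALSE)), seen)
      if (length(nxt) == 0) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    ringset <- setdiff(seen, v)
    if (length(ringset) == 0) next
    hr <- h[ringset]
    if (!any(hr > h[v]) && !any(hr == h[v] & ringset < v) && any(hr < h[v])) {
      out <- c(out, v)
    }
  }
  sort(out)
}

# features exactly at a type's training means (zero mismatch by construction)
features_at_means <- function(types, training) {
  dplyr::bind_rows(lapply(types, function(tp) {
    st <- training$stats[training$stats$tooth_type == tooth_side_class(tp), ]
    tibble::tibble(
      surface_area = st$mean[st$feature == "surface_area"],
      mesiodistal_width = st$mean[st$feature == "mesiodistal_width"],
      buccolingual_width = st$mean[st$feature == "buccolingual_width"],
      crown_height = st$mean[st$feature == "crown_height"],
      peak_count = st$mean[st$feature == "peak_count"]
    )
  }))
}
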