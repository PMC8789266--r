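#' MHB score mapping
#'
#' The modified Huddart-Bodenham index scores each maxillary tooth by its
#' transverse relationship to the mandibular arch on an ordinal scale:
#' positive displacement is buccal (normal overjet side), negative is lingual
#' (towards crossbite). The mapping from signed displacement (mm) to ordinal
#' score is a configurable non-increasing step function per segment, so the
#' scoring stays auditable and adjustable without code change.
#'
#' Defaults: buccal segment (premolars, molars) — `d >= 1` scores 0,
#' `-1 <= d < 1` scores -1, `d < -1` scores -2 (crossbite). Labial segment
#' (incisors; canines by default, configurable) — `d >= 6` scores +1
#' (increased overjet), `1 <= d < 6` scores 0, `-1 <= d < 1` scores -1
#' (edge-to-edge), `-3 <= d < -1` scores -2, `d < -3` scores -3.
#'
#' @param buccal,labial lists with `breaks` (strictly decreasing displacement
#'   breakpoints, mm) and `scores` (one more than breaks, non-increasing).
#' @param canine_segment `"labial"` (default) or `"buccal"`.
#' @return an `mhb_mapping` object.
#' @export
mhb_mapping <- function(buccal = list(breaks = c(1, -1), scores = c(0, -1, -2)),
                        labial = list(
                          breaks = c(6, 1, -1, -3),
                          scores = c(1, 0, -1, -2, -3)
                        ),
                        canine_segment = c("labial", "buccal")) {
  canine_segment <- match.arg(canine_segment)
  check <- function(seg, nm) {
    if (length(seg$scores) != length(seg$breaks) + 1L) {
      stop("mhb mapping `", nm, "`: need one more score than breakpoints")
    }
    if (length(seg$breaks) > 1L && any(diff(seg$breaks) >= 0)) {
      stop("mhb mapping `", nm, "`: breakpoints must be strictly decreasing")
    }
    if (any(diff(seg$scores) > 0)) {
      stop("mhb mapping `", nm, "`: scores must be non-increasing as displacement decreases")
    }
  }
  check(buccal, "buccal")
  check(labial, "labial")
  structure(
    list(buccal = buccal, labial = labial, canine_segment = canine_segment),
    class = "mhb_mapping"
  )
}

#' Ordinal MHB score of one displacement
#'
#' @param displacement signed transverse displacement in mm (positive =
#'   buccal).
#' @param segment `"buccal"` or `"labial"`.
#' @param mapping an [mhb_mapping()].
#' @return integer ordinal score.
#' @export
mhb_score <- function(displacement, segment = c("buccal", "labial"),
                      mapping = mhb_mapping()) {
  segment <- match.arg(segment)
  seg <- mapping[[segment]]
  vapply(displacement, function(d) {
    seg$scores[1L + sum(d < seg$breaks)]
  }, numeric(1))
}

#' Teeth entering the MHB score
#'
#' The MHB ignores second and third permanent molars: in a permanent
#' dentition only positions 1-6 per quadrant are scored (at most 12 teeth per
#' arch), while a deciduous arch scores all positions (at most 10). A molar
#' represented by a half-type pair counts once.
#'
#' @param assignment a [assign_teeth()] result (or a character vector of
#'   assigned tooth types).
#' @param dentition `"permanent"` or `"deciduous"`.
#' @return character vector of scored tooth types present in the assignment.
#' @export
select_scored_teeth <- function(assignment, dentition = c("permanent", "deciduous")) {
  dentition <- match.arg(dentition)
  types <- if (inherits(assignment, "tooth_assignment")) {
    assignment$assignment$tooth_type
  } else {
    assignment
  }
  types <- unique(tooth_base_type(types[!is.na(types)]))
  if (dentition == "permanent") {
    types <- types[tooth_position(types) %in% as.character(1:6)]
  }
  types
}

#' Cusp landmark of a labelled blob
#'
#' Incisors and canines take their highest peak (incisal edge / cusp tip).
#' Premolars and molars take the buccal cusp: among the blob's peaks on the
#' buccal side of the jawline, the one with maximal buccal offset, falling
#' back to the highest peak when no peak lies buccally. Exact ties go to the
#' lowest vertex index.
#'
#' @param mesh a [dental_mesh()].
#' @param blob a [tooth_blob()] with at least one peak.
#' @param type the tooth code assigned to the blob.
#' @param frame an [arch_frame()].
#' @param jawline a [fit_jawline()] result.
#' @return one-row tibble: `tooth_type`, `vertex`, `x`, `y`, `z`,
#'   `jaw_parameter`.
#' @export
extract_landmark <- function(mesh, blob, type, frame, jawline) {
  pks <- blob$peaks
  if (is.null(pks) || nrow(pks) == 0L) stop("blob has no peaks")
  cls <- tooth_class(type)
  pick <- if (cls %in% c("premolar", "molar")) {
    off <- jawline_offset(jawline, pks$t, pks$ap)
    buccal <- which(off > 0)
    if (length(buccal)) {
      buccal[order(-off[buccal], pks$vertex[buccal])][1]
    } else {
      order(-pks$height, pks$vertex)[1]
    }
  } else {
    order(-pks$height, pks$vertex)[1]
  }
  pk <- pks[pick, ]
  tibble::tibble(
    tooth_type = type,
    vertex = pk$vertex,
    x = pk$x, y = pk$y, z = pk$z,
    jaw_parameter = jawline_arclength(jawline, pk$t)
  )
}

#' Mandibular curve through ordered landmarks
#'
#' An interpolating natural cubic spline per coordinate over the cumulative
#' chord-length parameter, through the mandibular cusp landmarks ordered
#' round the arch.
#'
#' @param landmarks tibble with `x`, `y`, `z`, ordered round the arch (e.g.
#'   by `jaw_parameter`); at least 4 rows.
#' @return a `mandibular_curve` object.
#' @export
fit_mandibular_curve <- function(landmarks) {
  p <- as.matrix(landmarks[, c("x", "y", "z")])
  if (nrow(p) < 4L) stop("need at least 4 landmarks for the mandibular curve")
  seg <- sqrt(rowSums(diff(p)^2))
  if (any(seg == 0)) stop("coincident consecutive landmarks")
  u <- c(0, cumsum(seg))
  structure(
    list(
      fx = stats::splinefun(u, p[, 1], method = "natural"),
      fy = stats::splinefun(u, p[, 2], method = "natural"),
      fz = stats::splinefun(u, p[, 3], method = "natural"),
      knots = u, length = u[length(u)], points = p
    ),
    class = "mandibular_curve"
  )
}

#' Evaluate a mandibular curve
#'
#' @param curve a [fit_mandibular_curve()] result.
#' @param u chord-length parameter(s) in `[0, length]`.
#' @param deriv 0 for position, 1 for tangent.
#' @return matrix with one row per parameter value.
#' @export
curve_point <- function(curve, u, deriv = 0) {
  cbind(
    curve$fx(u, deriv = deriv),
    curve$fy(u, deriv = deriv),
    curve$fz(u, deriv = deriv)
  )
}

#' Least-squares horizontal reference plane
#'
#' Total-least-squares plane through the mandibular landmarks (SVD of the
#' centred coordinates); the normal is signed to agree with the occlusal
#' axis.
#'
#' @param landmarks tibble with `x`, `y`, `z` (>= 3, non-collinear).
#' @param frame an [arch_frame()] supplying the occlusal direction.
#' @return a `reference_plane`: `normal` (unit), `offset` (`normal . x =
#'   offset`), `centroid`.
#' @export
fit_reference_plane <- function(landmarks, frame) {
  p <- as.matrix(landmarks[, c("x", "y", "z")])
  if (nrow(p) < 3L) stop("need at least 3 landmarks for the reference plane")
  cen <- colMeans(p)
  sv <- svd(sweep(p, 2, cen))
  if (sv$d[2] <= 1e-8 * max(sv$d[1], 1e-12)) {
    stop("landmarks are collinear: reference plane undefined")
  }
  n <- sv$v[, 3]
  if (sum(n * frame$occlusal) < 0) n <- -n
  structure(
    list(normal = n, offset = sum(n * cen), centroid = cen),
    class = "reference_plane"
  )
}

#' Signed transverse displacement of a maxillary landmark
#'
#' The shortest 3D distance from the landmark to the mandibular curve is
#' found (dense sampling at 0.05 mm plus golden-section refinement — robust
#' against the multiple local minima a curved arch produces), the
#' landmark-to-curve vector is projected onto the reference plane, and its
#' signed magnitude along the local buccal direction is returned: positive
#' buccal (away from the arch's concave side), negative lingual.
#'
#' @param landmark one-row tibble (or named list) with `x`, `y`, `z`.
#' @param curve a [fit_mandibular_curve()] result.
#' @param plane a [fit_reference_plane()] result.
#' @param step dense sampling step along the curve, mm. Default 0.05.
#' @return signed displacement in mm, with attribute `u` (curve parameter of
#'   the closest point).
#' @export
transverse_displacement <- function(landmark, curve, plane, step = 0.05) {
  p <- c(landmark$x, landmark$y, landmark$z)
  us <- seq(0, curve$length, by = step)
  pts <- curve_point(curve, us)
  d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
  k <- which.min(d2)
  lo <- max(0, us[k] - 2 * step)
  hi <- min(curve$length, us[k] + 2 * step)
  opt <- stats::optimize(
    function(u) sum((curve_point(curve, u) - p)^2),
    interval = c(lo, hi), tol = 1e-8
  )
  ustar <- opt$minimum
  q <- drop(curve_point(curve, ustar))
  n <- plane$normal

  v <- p - q
  v_h <- v - sum(v * n) * n

  tau <- drop(curve_point(curve, ustar, deriv = 1))
  tau <- tau - sum(tau * n) * n
  nt <- sqrt(sum(tau^2))
  if (nt < 1e-9) stop("degenerate curve tangent at the closest point")
  tau <- tau / nt

  b <- .cross3(n, tau)
  # buccal points away from the arch interior: use the landmark centroid
  # (inside the horseshoe) as the interior reference
  interior <- colMeans(curve$points)
  outward <- q - interior
  outward <- outward - sum(outward * n) * n
  if (sum(b * outward) < 0) b <- -b

  out <- sum(v_h * b)
  attr(out, "u") <- ustar
  out
}

#' Score a registered maxillary/mandibular pair with the MHB index
#'
#' Both arches must be in occlusion in a shared coordinate frame (as
#' intra-oral scanners export them). The mandibular cusp landmarks define the
#' mandibular curve and reference plane; each scored maxillary tooth present
#' in both arches gets a signed transverse displacement and an ordinal score;
#' the arch total is their sum. Teeth missing from either arch are reported
#' unscored.
#'
#' @param maxillary,mandibular `arch_recognition` results (see
#'   [run_recognition()]), or lists with elements `landmarks` (tibble
#'   `tooth_type`, `x`, `y`, `z`, optionally `jaw_parameter`), `frame`, and
#'   `dentition`.
#' @param mapping an [mhb_mapping()].
#' @return an `mhb_scorecard`: tibble `scores` (`tooth_type`, `segment`,
#'   `displacement`, `score`), `total`, tibble `unscored` (`tooth_type`,
#'   `reason`).
#' @export
score_arch_pair <- function(maxillary, mandibular, mapping = mhb_mapping()) {
  dentition <- maxillary$dentition %||% "permanent"
  max_lm <- maxillary$landmarks
  mand_lm <- mandibular$landmarks

  scored_max <- select_scored_teeth(max_lm$tooth_type, dentition)
  scored_mand <- select_scored_teeth(mand_lm$tooth_type, dentition)
  max_lm <- max_lm[tooth_base_type(max_lm$tooth_type) %in% scored_max, ]
  # the curve and plane use every mandibular landmark (second and third
  # molars included): the spline then supports the first molars from both
  # sides instead of ending at them
  if (nrow(mand_lm) < 4L) {
    stop("fewer than 4 mandibular landmarks: cannot fit the mandibular curve")
  }
  frame0 <- mandibular$frame
  ordc <- if ("jaw_parameter" %in% names(mand_lm)) {
    order(mand_lm$jaw_parameter)
  } else {
    .order_round_arch(mand_lm, frame0)
  }
  mand_lm <- mand_lm[ordc, ]
  curve <- fit_mandibular_curve(mand_lm)
  frame <- mandibular$frame %||% arch_frame(
    colMeans(as.matrix(mand_lm[, c("x", "y", "z")])),
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)
  )
  plane <- fit_reference_plane(mand_lm, frame)

  # position+side key: UR6 occludes against the mandibular tooth on the same
  # side of the arch
  key <- function(x) paste0(substr(tooth_quadrant(x), 2, 2), tooth_position(x))
  mand_keys <- key(scored_mand)

  rows <- list()
  unscored <- list()
  for (tp in sort(max_lm$tooth_type)) {
    if (!(key(tp) %in% mand_keys)) {
      unscored[[length(unscored) + 1L]] <- tibble::tibble(
        tooth_type = tp, reason = "no matching mandibular landmark"
      )
      next
    }
    lm <- max_lm[max_lm$tooth_type == tp, ][1, ]
    cls <- tooth_class(tp)
    segment <- if (cls == "incisor") {
      "labial"
    } else if (cls == "canine") {
      mapping$canine_segment
    } else {
      "buccal"
    }
    d <- transverse_displacement(lm, curve, plane)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tooth_type = tp, segment = segment,
      displacement = as.numeric(d),
      score = mhb_score(as.numeric(d), segment, mapping)
    )
  }
  scores <- dplyr::bind_rows(rows)
  if (nrow(scores) == 0L) {
    scores <- tibble::tibble(
      tooth_type = character(), segment = character(),
      displacement = numeric(), score = numeric()
    )
  }
  structure(
    list(
      scores = scores,
      total = sum(scores$score),
      unscored = dplyr::bind_rows(unscored),
      mapping = mapping
    ),
    class = "mhb_scorecard"
  )
}

# order landmarks round the arch by angle about a viewpoint placed behind
# the arch opening (so the angular sweep over the horseshoe is monotone)
.order_round_arch <- function(lm, frame = NULL) {
  p <- as.matrix(lm[, c("x", "y", "z")])
  if (!is.null(frame)) {
    fc <- frame_coordinates(p, frame)
    t <- fc[, "t"]
    ap <- fc[, "ap"]
  } else {
    t <- p[, 1]
    ap <- p[, 2]
  }
  ref_t <- mean(t)
  ref_ap <- min(ap) - diff(range(ap)) - 1
  order(-atan2(ap - ref_ap, t - ref_t))
}

#' @export
print.mhb_scorecard <- function(x, ...) {
  cat(sprintf(
    "<mhb_scorecard: %d scored teeth, total %d; %d unscored>\n",
    nrow(x$scores), as.integer(x$total), nrow(x$unscored)
  ))
  if (nrow(x$scores)) {
    print(as.data.frame(x$scores), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname score_arch_pair
#' @param x an `mhb_scorecard`.
#' @param ... unused.
#' @export
tidy.mhb_scorecard <- function(x, ...) {
  x$scores
}

#' @rdname score_arch_pair
#' @export
glance.mhb_scorecard <- function(x, ...) {
  tibble::tibble(
    n_scored = nrow(x$scores),
    n_unscored = nrow(x$unscored),
    total = x$total,
    mean_displacement = mean(x$scores$displacement)
  )
}

#' Read / write a landmark CSV
#'
#' Exchange format for landmark sets: header row, columns `tooth_type`, `x`,
#' `y`, `z` (mm). Extra columns are preserved on read.
#'
#' @param path CSV path.
#' @return tibble (read) or `path` invisibly (write).
#' @export
read_landmarks <- function(path) {
  lm <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("tooth_type", "x", "y", "z") %in% names(lm)))
  lm
}

#' @rdname read_landmarks
#' @param landmarks tibble with at least `tooth_type`, `x`, `y`, `z`.
#' @export
write_landmarks <- function(landmarks, path) {
  readr::write_csv(landmarks[, intersect(
    c("tooth_type", "x", "y", "z", "jaw_parameter"),
    names(landmarks)
  )], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
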