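#' Tooth type codes (Palmer shorthand with half-molar extension)
#'
#' Teeth are referenced by Palmer-style codes: quadrant (`UR`, `UL`, `LR`,
#' `LL`) plus position (`1`-`8` for permanent, `a`-`e` for deciduous), with an
#' optional half suffix on molars: `UR6.0` and `UR6.1` are the mesial and
#' distal halves of an UR6, used when a molar is segmented as two blobs.
#'
#' `tooth_position()`, `tooth_quadrant()`, `tooth_half()` parse a code;
#' `tooth_class()` maps it to the broad class (incisor, canine, premolar,
#' molar); `tooth_side_class()` collapses the left/right distinction (features
#' are mirror-invariant, so left and right share training statistics);
#' `tooth_base_type()` strips a half suffix.
#'
#' @param type character vector of tooth codes.
#' @name tooth_types
#' @export
tooth_position <- function(type) {
  sub("\\.[01]$", "", sub("^(UR|UL|LR|LL|U|L)", "", type))
}

#' @rdname tooth_types
#' @export
tooth_quadrant <- function(type) {
  q <- sub("^((UR|UL|LR|LL)).*$", "\\1", type)
  ifelse(q == type, NA_character_, q)
}

#' @rdname tooth_types
#' @export
tooth_half <- function(type) {
  h <- sub("^.*\\.([01])$", "\\1", type)
  ifelse(h == type, NA_character_, h)
}

#' @rdname tooth_types
#' @export
tooth_class <- function(type) {
  pos <- tooth_position(type)
  cls <- rep(NA_character_, length(pos))
  cls[pos %in% c("1", "2", "a", "b")] <- "incisor"
  cls[pos %in% c("3", "c")] <- "canine"
  cls[pos %in% c("4", "5")] <- "premolar"
  cls[pos %in% c("6", "7", "8", "d", "e")] <- "molar"
  cls
}

#' @rdname tooth_types
#' @export
tooth_side_class <- function(type) {
  jaw <- substr(type, 1, 1) # U or L
  pos <- tooth_position(type)
  half <- tooth_half(type)
  paste0(jaw, pos, ifelse(is.na(half), "", paste0(".", half)))
}

#' @rdname tooth_types
#' @export
tooth_base_type <- function(type) {
  sub("\\.[01]$", "", type)
}

#' Arch template for a jaw and dentition
#'
#' The ordered tooth-type sequence expected round one arch, right quadrant to
#' left quadrant: `MMMPPCIIIICPPMMM` for a permanent dentition (16 slots) and
#' `mmciiiicmm` for a deciduous one (10 slots). Molar slots may be filled by a
#' single blob or expanded into a (mesial-half, distal-half) pair of blobs
#' during assignment. Blobs are ordered by increasing jaw parameter, and by
#' package convention the first (lowest jaw parameter) end of the template is
#' the `R` quadrant; since the mirror image of an arch is geometrically
#' indistinguishable, the side naming is a convention, not an inference.
#'
#' Under that convention the quadrant at the low end is the patient's right
#' for a maxillary arch and the patient's left for a mandibular one (the two
#' jaws have opposite chirality when each is viewed along its own occlusal
#' axis).
#'
#' @param jaw `"maxillary"` or `"mandibular"`.
#' @param dentition `"permanent"` or `"deciduous"`.
#' @return tibble with columns `slot`, `type` (full Palmer code), `class`,
#'   `is_molar`.
#' @export
arch_template <- function(jaw = c("maxillary", "mandibular"),
                          dentition = c("permanent", "deciduous")) {
  jaw <- match.arg(jaw)
  dentition <- match.arg(dentition)
  q1 <- if (jaw == "maxillary") "UR" else "LL"
  q2 <- if (jaw == "maxillary") "UL" else "LR"
  pos <- if (dentition == "permanent") {
    c(paste0(q1, 8:1), paste0(q2, 1:8))
  } else {
    c(paste0(q1, c("e", "d", "c", "b", "a")), paste0(q2, c("a", "b", "c", "d", "e")))
  }
  tibble::tibble(
    slot = seq_along(pos),
    type = pos,
    class = tooth_class(pos),
    is_molar = tooth_class(pos) == "molar"
  )
}

.feature_names <- c(
  "surface_area", "mesiodistal_width", "buccolingual_width",
  "crown_height", "peak_count"
)

#' Dimensional features of a blob
#'
#' The characteristics used to tell tooth types apart: total surface area
#' (mm^2), mesiodistal width (extent along the local jawline tangent, mm),
#' buccolingual width (horizontal extent perpendicular to the jawline, mm),
#' crown height (occlusal extent, mm) and the number of member peaks. All are
#' computed in the oriented frame so they are invariant to the scan's
#' original pose, and mirror-invariant so left and right teeth of the same
#' type agree.
#'
#' @param mesh a [dental_mesh()].
#' @param blob a [tooth_blob()].
#' @param frame an [arch_frame()].
#' @param jawline a [fit_jawline()] result.
#' @return one-row tibble with columns `surface_area`, `mesiodistal_width`,
#'   `buccolingual_width`, `crown_height`, `peak_count`.
#' @export
compute_features <- function(mesh, blob, frame, jawline) {
  if (length(blob$faces) == 0L) stop("empty blob")
  verts <- unique(as.vector(mesh$faces[blob$faces, , drop = FALSE]))
  fc <- frame_coordinates(mesh$vertices[verts, , drop = FALSE], frame)

  top <- blob$peaks[which.max(blob$peaks$height), ]
  slope <- 2 * jawline$a * top$t + jawline$b
  u <- c(1, slope) / sqrt(1 + slope^2) # jawline tangent, horizontal
  proj_u <- fc[, "t"] * u[1] + fc[, "ap"] * u[2]
  proj_n <- -fc[, "t"] * u[2] + fc[, "ap"] * u[1]

  tibble::tibble(
    surface_area = surface_area(mesh, blob$faces),
    mesiodistal_width = diff(range(proj_u)),
    buccolingual_width = diff(range(proj_n)),
    crown_height = diff(range(fc[, "h"])),
    peak_count = nrow(blob$peaks)
  )
}

#' Training set of labelled tooth features
#'
#' Per-type feature statistics learned from labelled blobs. Types are
#' side-collapsed (`U6` covers UR6 and UL6). Standard deviations get
#' robustness floors so that a single unusual feature cannot produce an
#' unbounded mismatch: dimensional features are floored at 8% of the type
#' mean (and 1e-3 absolutely), the integer peak count at 0.75.
#'
#' @param samples tibble with columns `tooth_type` (side-collapsed code) and
#'   the five feature columns of [compute_features()].
#' @return a `tooth_training_set` with elements `samples` and `stats`
#'   (tibble: `tooth_type`, `feature`, `mean`, `sd`).
#' @export
training_set <- function(samples) {
  stopifnot(all(c("tooth_type", .feature_names) %in% names(samples)))
  counts <- table(samples$tooth_type)
  if (any(counts < 2)) {
    stop(
      "every tooth type needs >= 2 training samples; short: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    )
  }
  stats <- samples |>
    tidyr::pivot_longer(dplyr::all_of(.feature_names),
      names_to = "feature", values_to = "value"
    ) |>
    dplyr::group_by(.data$tooth_type, .data$feature) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sd = dplyr::if_else(
        .data$feature == "peak_count",
        pmax(.data$sd, 0.75),
        pmax(.data$sd, 0.08 * abs(.data$mean), 1e-3)
      )
    )
  structure(
    list(samples = tibble::as_tibble(samples), stats = stats),
    class = "tooth_training_set"
  )
}

#' @export
print.tooth_training_set <- function(x, ...) {
  cat(sprintf(
    "<tooth_training_set: %d samples, %d tooth types>\n",
    nrow(x$samples), length(unique(x$samples$tooth_type))
  ))
  invisible(x)
}

#' Read / write a training set CSV
#'
#' Plain-text exchange format: header row, columns `tooth_type`,
#' `surface_area`, `mesiodistal_width`, `buccolingual_width`, `crown_height`,
#' `peak_count`.
#'
#' @param path CSV file path.
#' @return [training_set()] object (read) or `path` invisibly (write).
#' @export
read_training_set <- function(path) {
  training_set(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_training_set
#' @param training a `tooth_training_set`.
#' @export
write_training_set <- function(training, path) {
  readr::write_csv(training$samples, path)
  invisible(path)
}

#' Mismatch between a blob's features and a tooth type
#'
#' Sum over features of the squared z-score against the type's training
#' statistics: zero for a blob exactly at the type means, 1 when a single
#' feature sits one standard deviation out. Features are treated as
#' independent (diagonal covariance); more characteristics can be added
#' without changing the metric.
#'
#' @param features one-row tibble from [compute_features()].
#' @param type a tooth code (full or side-collapsed; halves allowed).
#' @param training a [training_set()].
#' @return non-negative mismatch cost.
#' @export
mismatch_cost <- function(features, type, training) {
  cls <- tooth_side_class(type)
  st <- training$stats[training$stats$tooth_type == cls, ]
  if (nrow(st) == 0L) stop("tooth type not in training set: ", type, " (", cls, ")")
  x <- unlist(features[1, .feature_names])
  st <- st[match(.feature_names, st$feature), ]
  sum(((x - st$mean) / st$sd)^2)
}

#' Assign tooth types to ordered blobs
#'
#' Labels each blob (ordered left to right round the jaw) with a tooth type
#' from the arch template, minimising the total feature mismatch against the
#' training set. A dynamic programme over (blob, template slot) states allows
#' four moves: assign the blob to the slot, skip the slot (missing tooth,
#' `gap_penalty`), discard the blob (non-tooth residue, `discard_penalty`),
#' or fill a molar slot with two consecutive blobs via its mesial/distal
#' half types. The alignment is monotone (no crossing); ties are broken
#' towards fewer discards, then towards the earliest-assigning alignment.
#'
#' @param blobs list of [tooth_blob()]s sorted by jaw parameter.
#' @param features tibble, one row per blob, as from [compute_features()].
#' @param template an [arch_template()].
#' @param training a [training_set()]. Half-molar types absent from the
#'   training set simply disable the pair move.
#' @param gap_penalty cost of declaring a template slot missing (squared-z
#'   units). Default 6.
#' @param discard_penalty cost of declaring a blob non-tooth. Default 9.
#' @return a `tooth_assignment` object. Its element `assignment` is a tibble
#'   (`blob`, `tooth_type` — `NA` for discarded blobs, `cost`), `skipped` the
#'   unfilled template slots, `total_cost` the DP minimum.
#' @export
assign_teeth <- function(blobs, features, template, training,
                         gap_penalty = 6, discard_penalty = 9) {
  n <- length(blobs)
  m <- nrow(template)
  stopifnot(nrow(features) == n)

  has_type <- function(tp) any(training$stats$tooth_type == tooth_side_class(tp))
  C <- matrix(Inf, max(n, 1), m)
  H0 <- matrix(Inf, max(n, 1), m)
  H1 <- matrix(Inf, max(n, 1), m)
  for (j in seq_len(m)) {
    tp <- template$type[j]
    t0 <- paste0(tp, ".0")
    t1 <- paste0(tp, ".1")
    pair_ok <- template$is_molar[j] && has_type(t0) && has_type(t1)
    for (i in seq_len(n)) {
      C[i, j] <- mismatch_cost(features[i, ], tp, training)
      if (pair_ok) {
        H0[i, j] <- mismatch_cost(features[i, ], t0, training)
        H1[i, j] <- mismatch_cost(features[i, ], t1, training)
      }
    }
  }

  # suffix DP: S[i, j] = best cost using blobs i..n against slots j..m
  S <- matrix(Inf, n + 2L, m + 1L)
  D <- matrix(0L, n + 2L, m + 1L) # discards of the chosen suffix
  S[n + 1L, m + 1L] <- 0
  eps <- 1e-9
  better <- function(c1, d1, c2, d2) {
    c1 < c2 - eps || (abs(c1 - c2) <= eps && d1 < d2)
  }
  for (i in (n + 1L):1L) {
    for (j in (m + 1L):1L) {
      if (i == n + 1L && j == m + 1L) next
      bc <- Inf
      bd <- 0L
      if (i <= n && j <= m) { # assign
        cc <- C[i, j] + S[i + 1L, j + 1L]
        if (better(cc, D[i + 1L, j + 1L], bc, bd)) {
          bc <- cc
          bd <- D[i + 1L, j + 1L]
        }
        if (i + 1L <= n && is.finite(H0[i, j])) { # molar half pair
          cc <- H0[i, j] + H1[i + 1L, j] + S[i + 2L, j + 1L]
          if (better(cc, D[i + 2L, j + 1L], bc, bd)) {
            bc <- cc
            bd <- D[i + 2L, j + 1L]
          }
        }
      }
      if (j <= m) { # skip slot
        cc <- gap_penalty + S[i, j + 1L]
        if (better(cc, D[i, j + 1L], bc, bd)) {
          bc <- cc
          bd <- D[i, j + 1L]
        }
      }
      if (i <= n) { # discard blob
        cc <- discard_penalty + S[i + 1L, j]
        if (better(cc, D[i + 1L, j] + 1L, bc, bd)) {
          bc <- cc
          bd <- D[i + 1L, j] + 1L
        }
      }
      S[i, j] <- bc
      D[i, j] <- bd
    }
  }

  # forward walk, preferring assign > pair > skip > discard at ties
  lab <- rep(NA_character_, n)
  cost_i <- rep(NA_real_, n)
  skipped <- integer(0)
  i <- 1L
  j <- 1L
  reaches <- function(cc, dd) {
    abs(cc - S[i, j]) <= eps * (1 + abs(S[i, j])) && dd == D[i, j]
  }
  while (i <= n + 1L && j <= m + 1L && !(i == n + 1L && j == m + 1L)) {
    if (i <= n && j <= m &&
      reaches(C[i, j] + S[i + 1L, j + 1L], D[i + 1L, j + 1L])) {
      lab[i] <- template$type[j]
      cost_i[i] <- C[i, j]
      i <- i + 1L
      j <- j + 1L
    } else if (i + 1L <= n && j <= m && is.finite(H0[i, j]) &&
      reaches(H0[i, j] + H1[i + 1L, j] + S[i + 2L, j + 1L], D[i + 2L, j + 1L])) {
      lab[i] <- paste0(template$type[j], ".0")
      lab[i + 1L] <- paste0(template$type[j], ".1")
      cost_i[i] <- H0[i, j]
      cost_i[i + 1L] <- H1[i + 1L, j]
      i <- i + 2L
      j <- j + 1L
    } else if (j <= m &&
      reaches(gap_penalty + S[i, j + 1L], D[i, j + 1L])) {
      skipped <- c(skipped, j)
      j <- j + 1L
    } else if (i <= n &&
      reaches(discard_penalty + S[i + 1L, j], D[i + 1L, j] + 1L)) {
      cost_i[i] <- discard_penalty
      i <- i + 1L
    } else {
      stop("internal error: assignment backtrack failed") # nocov
    }
  }

  structure(
    list(
      assignment = tibble::tibble(
        blob = seq_len(n),
        tooth_type = lab,
        cost = cost_i
      ),
      skipped = template$type[skipped],
      total_cost = if (n == 0L && m == 0L) 0 else S[1L, 1L],
      template = template
    ),
    class = "tooth_assignment"
  )
}

#' @export
print.tooth_assignment <- function(x, ...) {
  ass <- x$assignment
  cat(sprintf(
    "<tooth_assignment: %d blobs -> %d labelled, %d discarded, %d slots skipped; total cost %.2f>\n",
    nrow(ass), sum(!is.na(ass$tooth_type)), sum(is.na(ass$tooth_type)),
    length(x$skipped), x$total_cost
  ))
  if (nrow(ass)) {
    lab <- ifelse(is.na(ass$tooth_type), "(discarded)", ass$tooth_type)
    cat(" ", paste(lab, collapse = " "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname assign_teeth
#' @param x a `tooth_assignment`.
#' @param ... unused.
#' @export
tidy.tooth_assignment <- function(x, ...) {
  x$assignment
}

#' @rdname assign_teeth
#' @export
glance.tooth_assignment <- function(x, ...) {
  ass <- x$assignment
  tibble::tibble(
    n_blobs = nrow(ass),
    n_assigned = sum(!is.na(ass$tooth_type)),
    n_discarded = sum(is.na(ass$tooth_type)),
    n_skipped = length(x$skipped),
    total_cost = x$total_cost
  )
}
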