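#' Pipeline configuration
#'
#' All tunable parameters of the recognition pipeline in one validated
#' object. Unknown arguments are rejected.
#'
#' @param depth_threshold peak search depth below the highest point, mm.
#' @param ring peak neighbourhood radius in edge hops.
#' @param stop_curvature crease threshold for region growing, radians
#'   (negative).
#' @param max_travel named numeric: horizontal travel cap per dentition, mm.
#' @param merge_distance jawline merge tolerance, mm; `NA` means
#'   `max_travel / 3` for the model's dentition.
#' @param stop_concavity integrated-concavity stop threshold, 1/mm (see
#'   [vertex_concavity()]).
#' @param smooth_iterations Taubin smoothing passes applied to the input
#'   mesh before analysis (0 disables). Scanner and isosurface meshes carry
#'   high-frequency tessellation noise that the curvature fields respond to;
#'   two passes remove it without rounding the gingival creases away.
#' @param gap_penalty,discard_penalty assignment penalties (squared-z units).
#' @param mapping an [mhb_mapping()].
#' @param training a [training_set()], a path to a training CSV, or `NULL`
#'   to use the packaged synthetic-derived defaults.
#' @param resolution default marching resolution for synthetic generation,
#'   mm.
#' @param seed default seed for synthetic generation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(depth_threshold = 6,
                            ring = 2L,
                            stop_curvature = -0.6,
                            stop_concavity = -0.7,
                            max_travel = c(permanent = 12, deciduous = 9),
                            merge_distance = NA_real_,
                            smooth_iterations = 2L,
                            gap_penalty = 6,
                            discard_penalty = 9,
                            mapping = mhb_mapping(),
                            training = NULL,
                            resolution = 0.5,
                            seed = 1L) {
  stopifnot(
    depth_threshold > 0, depth_threshold < 30,
    ring >= 1L, ring <= 5L,
    stop_curvature < 0, stop_curvature > -pi,
    stop_concavity < 0, stop_concavity > -10,
    smooth_iterations >= 0L, smooth_iterations <= 10L,
    all(max_travel > 0), all(max_travel < 40),
    is.na(merge_distance) || (merge_distance > 0 && merge_distance < 20),
    gap_penalty >= 0, discard_penalty >= 0
  )
  if (!all(c("permanent", "deciduous") %in% names(max_travel))) {
    stop("`max_travel` needs entries for permanent and deciduous")
  }
  structure(
    list(
      depth_threshold = depth_threshold, ring = as.integer(ring),
      stop_curvature = stop_curvature, stop_concavity = stop_concavity,
      max_travel = max_travel, merge_distance = merge_distance,
      smooth_iterations = as.integer(smooth_iterations),
      gap_penalty = gap_penalty, discard_penalty = discard_penalty,
      mapping = mapping, training = training,
      resolution = resolution, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Packaged default training set
#'
#' Synthetic-derived feature statistics shipped with the package (generated
#' by [generate_training_set()] over size-jittered arches and stored as
#' plain CSV). Substitute your own labelled data via the `training` slot of
#' [pipeline_config()] for real scans.
#'
#' @param dentition `"permanent"` or `"deciduous"`.
#' @return a [training_set()].
#' @export
default_training_set <- function(dentition = c("permanent", "deciduous")) {
  dentition <- match.arg(dentition)
  path <- system.file("extdata",
    paste0("training_", dentition, ".csv"),
    package = "dentomark"
  )
  if (!nzchar(path)) stop("packaged training set not found")
  read_training_set(path)
}

.resolve_training <- function(config, dentition) {
  tr <- config$training
  if (is.null(tr)) return(default_training_set(dentition))
  if (inherits(tr, "tooth_training_set")) return(tr)
  if (is.character(tr)) return(read_training_set(tr))
  stop("`training` must be NULL, a training set, or a CSV path")
}

#' Parse jaw and dentition from an STL filename
#'
#' Convention: `*_{U|L}_{perm|decid}.stl`, e.g. `case12_U_perm.stl`.
#'
#' @param path file path.
#' @return list with `jaw` and `dentition`, `NULL` entries if unparseable.
#' @export
parse_stl_name <- function(path) {
  b <- sub("\\.stl$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(b, regexec("_(U|L)_(perm|decid)$", b))[[1]]
  if (length(m) != 3L) {
    return(list(jaw = NULL, dentition = NULL))
  }
  list(
    jaw = if (m[2] == "U") "maxillary" else "mandibular",
    dentition = if (m[3] == "perm") "permanent" else "deciduous"
  )
}

#' Run the full landmark-recognition pipeline on one arch
#'
#' Executes orientation (PCA, sign disambiguation, coarse peaks, occlusal
#' refinement), peak detection, curvature partition, jawline fit, blob
#' merging, feature computation, template-constrained assignment, and cusp
#' landmark extraction. Any stage failure is reported with the stage name;
#' an orientation failure aborts the model.
#'
#' @param input an STL path or a [dental_mesh()].
#' @param jaw,dentition `"maxillary"`/`"mandibular"`,
#'   `"permanent"`/`"deciduous"`; if `NULL` and `input` is a path, parsed
#'   from the filename convention `*_{U|L}_{perm|decid}.stl`.
#' @param config a [pipeline_config()].
#' @return an `arch_recognition` object: mesh, frame, peaks, jawline, blobs,
#'   features, assignment, landmarks (tibble), jaw, dentition, warnings.
#' @export
run_recognition <- function(input, jaw = NULL, dentition = NULL,
                            config = pipeline_config()) {
  if (is.character(input)) {
    meta <- parse_stl_name(input)
    jaw <- jaw %||% meta$jaw
    dentition <- dentition %||% meta$dentition
    if (is.null(jaw) || is.null(dentition)) {
      stop(
        "jaw/dentition not given and not parseable from filename ",
        "(expected *_{U|L}_{perm|decid}.stl): ", input
      )
    }
    mesh <- read_stl(input)
  } else {
    mesh <- input
    if (is.null(jaw) || is.null(dentition)) {
      stop("jaw and dentition must be supplied when input is a mesh")
    }
  }
  jaw <- match.arg(jaw, c("maxillary", "mandibular"))
  dentition <- match.arg(dentition, c("permanent", "deciduous"))
  warnings <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  if (config$smooth_iterations > 0L) {
    mesh <- stage("smoothing", smooth_mesh(mesh, config$smooth_iterations))
  }
  adj <- stage("adjacency", build_adjacency(mesh))
  frame <- withCallingHandlers(
    stage("orientation", orient_arch(mesh, adj, config$depth_threshold)),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  peaks <- stage("peaks", find_peaks(
    mesh, adj, frame,
    depth_threshold = config$depth_threshold, ring = config$ring
  ))
  max_travel <- config$max_travel[[dentition]]
  merge_distance <- if (is.na(config$merge_distance)) max_travel / 3 else config$merge_distance
  part <- stage("partition", partition_teeth(
    mesh, adj, frame, peaks,
    stop_curvature = config$stop_curvature,
    stop_concavity = config$stop_concavity,
    max_travel = max_travel, merge_distance = merge_distance
  ))
  training <- .resolve_training(config, dentition)
  template <- arch_template(jaw, dentition)
  features <- stage("features", dplyr::bind_rows(lapply(
    part$blobs,
    function(b) compute_features(mesh, b, frame, part$jawline)
  )))
  assignment <- stage("assignment", assign_teeth(
    part$blobs, features, template, training,
    gap_penalty = config$gap_penalty,
    discard_penalty = config$discard_penalty
  ))

  landmarks <- stage("landmarks", .extract_all_landmarks(
    mesh, part$blobs, assignment, frame, part$jawline
  ))

  structure(
    list(
      mesh = mesh, frame = frame, peaks = part$peaks,
      jawline = part$jawline, blobs = part$blobs, features = features,
      assignment = assignment, landmarks = landmarks,
      jaw = jaw, dentition = dentition, warnings = warnings
    ),
    class = "arch_recognition"
  )
}

# one landmark per base tooth type; half-molar blob pairs are pooled first
.extract_all_landmarks <- function(mesh, blobs, assignment, frame, jawline) {
  lab <- assignment$assignment$tooth_type
  keep <- which(!is.na(lab))
  if (length(keep) == 0L) {
    return(tibble::tibble(
      tooth_type = character(), vertex = integer(),
      x = numeric(), y = numeric(), z = numeric(), jaw_parameter = numeric()
    ))
  }
  base <- tooth_base_type(lab[keep])
  rows <- list()
  for (tp in unique(base)) {
    idx <- keep[base == tp]
    blob <- if (length(idx) == 1L) {
      blobs[[idx]]
    } else {
      pooled_peaks <- dplyr::bind_rows(lapply(blobs[idx], `[[`, "peaks"))
      tooth_blob(
        sort(unique(unlist(lapply(blobs[idx], `[[`, "faces")))),
        pooled_peaks,
        jaw_parameter = blobs[[idx[1]]]$jaw_parameter
      )
    }
    rows[[length(rows) + 1L]] <- extract_landmark(mesh, blob, tp, frame, jawline)
  }
  dplyr::bind_rows(rows)
}

#' @export
print.arch_recognition <- function(x, ...) {
  cat(sprintf(
    "<arch_recognition: %s %s arch; %d peaks, %d blobs, %d labelled teeth>\n",
    x$jaw, x$dentition, nrow(x$peaks), length(x$blobs),
    sum(!is.na(x$assignment$assignment$tooth_type))
  ))
  print(x$assignment)
  invisible(x)
}

#' @rdname run_recognition
#' @param x an `arch_recognition`.
#' @param ... unused.
#' @export
tidy.arch_recognition <- function(x, ...) {
  # landmarks are per base type; report the assignment with landmark positions
  ass <- tidy(x$assignment)
  ass$base_type <- tooth_base_type(ass$tooth_type)
  dplyr::left_join(ass,
    x$landmarks |> dplyr::rename(base_type = "tooth_type"),
    by = "base_type"
  )
}

#' @rdname run_recognition
#' @export
glance.arch_recognition <- function(x, ...) {
  g <- glance(x$assignment)
  g$n_peaks <- nrow(x$peaks)
  g$n_landmarks <- nrow(x$landmarks)
  g$jaw <- x$jaw
  g$dentition <- x$dentition
  g
}

#' Score a maxillary/mandibular pair end to end
#'
#' Runs [run_recognition()] on both inputs (unless already-recognised
#' results or landmark tibbles/CSVs are supplied) and computes the MHB
#' scorecard via [score_arch_pair()].
#'
#' @param maxillary,mandibular STL paths, [dental_mesh()]es (with `jaw` and
#'   `dentition` in the filename or via `...`), `arch_recognition` objects,
#'   landmark CSV paths, or landmark tibbles.
#' @param dentition dentition of both arches (needed for meshes/landmarks).
#' @param config a [pipeline_config()].
#' @return an `mhb_result`: list with `maxillary`, `mandibular` (recognition
#'   results or landmark sets) and `scorecard` (an `mhb_scorecard`).
#' @export
run_mhb <- function(maxillary, mandibular, dentition = "permanent",
                    config = pipeline_config()) {
  prep <- function(input, jaw) {
    if (inherits(input, "arch_recognition")) {
      return(input)
    }
    if (is.character(input) && grepl("\\.csv$", input, ignore.case = TRUE)) {
      return(list(
        landmarks = read_landmarks(input), frame = NULL,
        dentition = dentition
      ))
    }
    if (is.data.frame(input)) {
      return(list(landmarks = input, frame = NULL, dentition = dentition))
    }
    if (is.character(input) && !file.exists(input)) {
      stop("input does not exist: ", input)
    }
    run_recognition(input, jaw = jaw, dentition = dentition, config = config)
  }
  maxr <- prep(maxillary, "maxillary")
  mandr <- prep(mandibular, "mandibular")
  card <- score_arch_pair(maxr, mandr, mapping = config$mapping)
  structure(
    list(maxillary = maxr, mandibular = mandr, scorecard = card),
    class = "mhb_result"
  )
}

#' @export
print.mhb_result <- function(x, ...) {
  print(x$scorecard)
  invisible(x)
}

#' Serialise / load a result report
#'
#' A compact JSON report of one model's pipeline outcome: frame, peak and
#' blob counts, the assignment with costs, landmarks, the optional MHB
#' scorecard and warnings. `read_report()` restores the same structure.
#'
#' @param result an `arch_recognition` or `mhb_result`.
#' @param path output JSON path.
#' @return `path` invisibly; `read_report()` returns a list.
#' @export
write_report <- function(result, path) {
  rep <- if (inherits(result, "mhb_result")) {
    list(
      kind = "mhb",
      maxillary = .report_of(result$maxillary),
      mandibular = .report_of(result$mandibular),
      scorecard = list(
        scores = result$scorecard$scores,
        total = result$scorecard$total,
        unscored = result$scorecard$unscored
      )
    )
  } else {
    c(list(kind = "recognition"), .report_of(result))
  }
  jsonlite::write_json(rep, path,
    auto_unbox = TRUE, digits = NA,
    dataframe = "columns", null = "null"
  )
  invisible(path)
}

.report_of <- function(r) {
  if (!inherits(r, "arch_recognition")) {
    return(list(landmarks = r$landmarks))
  }
  list(
    jaw = r$jaw, dentition = r$dentition,
    frame = list(
      origin = r$frame$origin, transverse = r$frame$transverse,
      anteroposterior = r$frame$anteroposterior, occlusal = r$frame$occlusal
    ),
    n_peaks = nrow(r$peaks), n_blobs = length(r$blobs),
    assignment = r$assignment$assignment,
    skipped = r$assignment$skipped,
    total_cost = r$assignment$total_cost,
    landmarks = r$landmarks,
    warnings = r$warnings
  )
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
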