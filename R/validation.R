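#' Classify one tooth-recognition outcome
#'
#' Per-tooth qualitative categories: `OK` — the tooth was found and correctly
#' labelled; `PartitionError` — the tooth was not found (no blob matched it);
#' `WrongAssignment` — found but mislabelled, with the `wrong_kind` flag set
#' when even the broad class (incisor, canine, premolar, molar) is wrong.
#' Teeth absent from the model are excluded from tallies by the caller.
#' Half-molar labels count as their base molar type.
#'
#' @param true_label the tooth's true code (must be present on the model).
#' @param predicted the predicted code, or `NA` if no blob matched.
#' @return one-row tibble: `category`, `wrong_kind`.
#' @export
classify_outcome <- function(true_label, predicted) {
  if (is.na(true_label)) stop("true tooth absent: excluded from tallies, not classified")
  if (is.na(predicted)) {
    return(tibble::tibble(category = "PartitionError", wrong_kind = FALSE))
  }
  tb <- tooth_base_type(true_label)
  pb <- tooth_base_type(predicted)
  if (tb == pb) {
    tibble::tibble(category = "OK", wrong_kind = FALSE)
  } else {
    tibble::tibble(
      category = "WrongAssignment",
      wrong_kind = !identical(tooth_class(tb), tooth_class(pb))
    )
  }
}

#' Tally recognition outcomes
#'
#' Counts and percentages per group and overall, in the layout of a
#' qualitative evaluation table: rows OK / PartitionError / WrongAssignment,
#' with WrongKind as a sub-row of WrongAssignment (not part of the column
#' sum). Percentages are count/total x 100, rounded to 1 decimal.
#'
#' @param outcomes tibble with columns `category`, `wrong_kind` and
#'   optionally `group`.
#' @return tibble with columns `group`, `row`, `n`, `pct` (includes an
#'   `Overall` group and a `Total` row).
#' @export
tally_outcomes <- function(outcomes) {
  if (!"group" %in% names(outcomes)) outcomes$group <- "All"
  tally_one <- function(df, label) {
    total <- nrow(df)
    rows <- c("OK", "PartitionError", "WrongAssignment")
    cnt <- vapply(rows, function(r) sum(df$category == r), integer(1))
    wk <- sum(df$wrong_kind & df$category == "WrongAssignment")
    pcts <- unname(c(round(100 * c(cnt, wk) / total, 1), NA))
    tibble::tibble(
      group = label,
      row = c(rows, "WrongKind", "Total"),
      n = unname(c(cnt, wk, total)),
      pct = pcts
    )
  }
  out <- dplyr::bind_rows(lapply(
    split(outcomes, outcomes$group),
    function(df) tally_one(df, df$group[1])
  ))
  dplyr::bind_rows(out, tally_one(outcomes, "Overall"))
}

#' Landmark deviation statistics
#'
#' Euclidean deviations between matched predicted and consensus landmarks:
#' arithmetic means per tooth class and overall, and the geometric mean with
#' a 95% confidence interval obtained by fitting a normal distribution to the
#' log deviations (`exp(mean_log +/- 1.96 * se_log)`) — the standard model
#' for positive error magnitudes. Zero distances are floored at 1e-6 mm
#' before taking logs.
#'
#' @param predicted,consensus tibbles with `tooth_type`, `x`, `y`, `z`;
#'   matched on `tooth_type`.
#' @return a `deviation_report`: `by_class` tibble (`class`, `n`, `mean_mm`),
#'   `overall_mean`, `geometric_mean`, `ci_lower`, `ci_upper`, `n`,
#'   `distances` tibble.
#' @export
deviation_stats <- function(predicted, consensus) {
  m <- dplyr::inner_join(
    predicted, consensus,
    by = "tooth_type", suffix = c("_p", "_c")
  )
  if (nrow(m) == 0L) stop("no matched landmark pairs")
  if (nrow(m) < 2L) stop("need at least 2 matched landmark pairs")
  d <- sqrt((m$x_p - m$x_c)^2 + (m$y_p - m$y_c)^2 + (m$z_p - m$z_c)^2)
  cls <- tooth_class(m$tooth_type)
  dist_tbl <- tibble::tibble(tooth_type = m$tooth_type, class = cls, deviation_mm = d)

  by_class <- dist_tbl |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(), mean_mm = mean(.data$deviation_mm),
      .groups = "drop"
    )

  ld <- log(pmax(d, 1e-6))
  mu <- mean(ld)
  se <- stats::sd(ld) / sqrt(length(ld))
  structure(
    list(
      by_class = by_class,
      overall_mean = mean(d),
      geometric_mean = exp(mu),
      ci_lower = exp(mu - 1.96 * se),
      ci_upper = exp(mu + 1.96 * se),
      n = length(d),
      distances = dist_tbl
    ),
    class = "deviation_report"
  )
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(
    "<deviation_report: n = %d, mean %.3f mm, geometric mean %.3f mm [%.3f, %.3f]>\n",
    x$n, x$overall_mean, x$geometric_mean, x$ci_lower, x$ci_upper
  ))
  print(as.data.frame(x$by_class), row.names = FALSE)
  invisible(x)
}

#' @rdname deviation_stats
#' @param x a `deviation_report`.
#' @param ... unused.
#' @export
tidy.deviation_report <- function(x, ...) {
  x$by_class
}

#' @rdname deviation_stats
#' @export
glance.deviation_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, overall_mean = x$overall_mean,
    geometric_mean = x$geometric_mean,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper
  )
}

#' Match predicted blobs to ground-truth teeth and classify outcomes
#'
#' A predicted blob "finds" a truth tooth when it contains the mesh vertex
#' nearest the tooth's highest cusp apex, or failing that when its face set
#' overlaps the truth mask with Jaccard index at least `jaccard_threshold`.
#' Discarded blobs do not count as found. One outcome row per present truth
#' tooth.
#'
#' @param result an `arch_recognition` from [run_recognition()].
#' @param truth the `truth` element of [generate_arch()].
#' @param jaccard_threshold overlap threshold for the mask fallback.
#'   Default 0.3.
#' @return tibble: `tooth_type`, `predicted`, `category`, `wrong_kind`.
#' @export
evaluate_recognition <- function(result, truth, jaccard_threshold = 0.3) {
  mesh <- result$mesh
  blobs <- result$blobs
  labels <- result$assignment$assignment$tooth_type
  rows <- list()
  for (i in seq_len(nrow(truth$teeth))) {
    tp <- truth$teeth$type[i]
    mask <- truth$masks[[tp]]
    if (is.null(mask) || length(mask) == 0L) next
    cu <- truth$cusps[truth$cusps$tooth_type == tp, ]
    top <- cu[which.max(cu$z * sign(truth$vertical[3])), ]
    apex <- c(top$x, top$y, top$z)
    d2 <- colSums((t(mesh$vertices) - apex)^2)
    apex_vertex <- which.min(d2)

    hit <- NA_integer_
    for (b in seq_along(blobs)) {
      if (apex_vertex %in% as.vector(mesh$faces[blobs[[b]]$faces, ])) {
        hit <- b
        break
      }
    }
    if (is.na(hit)) {
      jac <- vapply(blobs, function(b) {
        length(intersect(b$faces, mask)) / length(union(b$faces, mask))
      }, numeric(1))
      if (length(jac) && max(jac) >= jaccard_threshold) hit <- which.max(jac)
    }

    predicted <- if (is.na(hit)) NA_character_ else labels[hit]
    out <- classify_outcome(tp, predicted)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tooth_type = tp, predicted = predicted,
      category = out$category, wrong_kind = out$wrong_kind
    )
  }
  dplyr::bind_rows(rows)
}
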