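# File dialects. All outputs are UTF-8, comma-separated, '.' decimal, and
# start with a '#'-prefixed metadata line naming the package version;
# readers therefore use comment.char = "#".

meta_line <- function(extra = NULL) {
  paste0("# labiometry ",
         as.character(utils::packageVersion("labiometry")),
         if (!is.null(extra)) paste0(" | ", extra))
}

write_csv_with_meta <- function(df, path, extra = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_line(extra), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landmark CSV into subject landmarks
#'
#' The landmark dialect has one row per digitized point and columns
#' `subject_id`, `role` (`left_contour`, `right_contour` or `axis`),
#' `point_index` (0-based, giving the order along the contour), `x`, `y`.
#' The `axis` role has exactly two points: index 0 is the anterior end of
#' the vestibule, index 1 the posterior end.
#'
#' @param path Path to the CSV file.
#' @param on_error `"stop"` (default) raises on the first malformed
#'   subject; `"keep"` returns the error condition in that subject's slot
#'   so callers can skip selectively (as [run_measure()] does).
#' @return A named list of [subject_landmarks()] objects (possibly
#'   interspersed with error conditions when `on_error = "keep"`).
#' @export
read_landmarks_csv <- function(path, on_error = c("stop", "keep")) {
  on_error <- match.arg(on_error)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("schema error: cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("subject_id", "role", "point_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) || nrow(df) == 0L) {
    stop("schema error: landmark file needs non-empty columns ",
         paste(need, collapse = ", "),
         if (length(miss)) paste0(" (missing: ",
                                  paste(miss, collapse = ", "), ")"),
         call. = FALSE)
  }
  build_one <- function(d) {
    d <- d[order(d$point_index), ]
    ax <- d[d$role == "axis", ]
    if (nrow(ax) != 2L) {
      stop("subject '", d$subject_id[1],
           "' needs exactly 2 axis points", call. = FALSE)
    }
    subject_landmarks(
      as.character(d$subject_id[1]),
      left = as.matrix(d[d$role == "left_contour", c("x", "y")]),
      right = as.matrix(d[d$role == "right_contour", c("x", "y")]),
      anterior = c(ax$x[1], ax$y[1]),
      posterior = c(ax$x[2], ax$y[2])
    )
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    if (on_error == "stop") build_one(d)
    else tryCatch(build_one(d), error = function(e) e)
  })
  out[unique(as.character(df$subject_id))]
}

#' Write subject landmarks to the landmark CSV dialect
#'
#' @param landmarks A list of [subject_landmarks()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  rows <- lapply(landmarks, function(lm) {
    stopifnot(inherits(lm, "subject_landmarks"))
    rbind(
      data.frame(subject_id = lm$subject_id, role = "left_contour",
                 point_index = seq_len(nrow(lm$left)) - 1L,
                 x = lm$left[, 1], y = lm$left[, 2]),
      data.frame(subject_id = lm$subject_id, role = "right_contour",
                 point_index = seq_len(nrow(lm$right)) - 1L,
                 x = lm$right[, 1], y = lm$right[, 2]),
      data.frame(subject_id = lm$subject_id, role = "axis",
                 point_index = 0:1,
                 x = c(lm$anterior[1], lm$posterior[1]),
                 y = c(lm$anterior[2], lm$posterior[2]))
    )
  })
  write_csv_with_meta(do.call(rbind, rows), path, "landmark dialect")
}

#' Write a profile table to CSV
#'
#' @param profiles Data frame from [profiles_as_df()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profiles_csv <- function(profiles, path) {
  write_csv_with_meta(profiles, path, "width profiles, axis-tenth units")
}

#' Read a profile table written by [write_profiles_csv()]
#'
#' @param path Path to the CSV file.
#' @return A data frame with `subject_id`, `L1..L9`, `R1..R9`, `qc_flags`.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  miss <- setdiff(c("subject_id", seg_names()), names(df))
  if (length(miss)) {
    stop("schema error: profile file missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a cohort summary as JSON
#'
#' @param summary A [cohort_summary()] object.
#' @param path Output path.
#' @param digits Rounding for reported values (full precision if `NA`).
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(summary, path, digits = NA) {
  stopifnot(inherits(summary, "cohort_summary"))
  payload <- list(
    meta = list(package = "labiometry",
                version = as.character(utils::packageVersion("labiometry"))),
    n = summary$n,
    mean_L = summary$mean_L, mean_R = summary$mean_R,
    ratio_of_means_L = summary$ratio_of_means_L,
    ratio_of_means_R = summary$ratio_of_means_R,
    mean_of_ratios_L = summary$mean_of_ratios_L,
    mean_of_ratios_R = summary$mean_of_ratios_R,
    prominence_counts = as.list(summary$prominence_counts),
    prominence_percent = as.list(summary$prominence_percent),
    prominence_undefined = summary$prominence_undefined,
    golden_ratio = summary$golden_ratio
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = digits,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a group comparison table to CSV
#'
#' One row per (grouping, pair, segment) with the Levene gate and t-test
#' results.
#'
#' @param comparisons A named list of `"group_comparison"` data frames
#'   (e.g. from [compare_strata()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_comparisons_csv <- function(comparisons, path) {
  rows <- lapply(names(comparisons), function(k) {
    cmp <- comparisons[[k]]
    data.frame(grouping = attr(cmp, "grouping_name"), pair = k,
               as.data.frame(cmp))
  })
  df <- do.call(rbind, rows)
  write_csv_with_meta(
    df, path,
    "uncorrected per-segment p-values; interpret multiplicity with caution")
}

#' Render a mean shape as an SVG drawing
#'
#' Writes a minimal standalone SVG: the average-shape polygon (axis
#' vertical, anterior at the top) and the dashed vestibule axis, at a
#' configurable pixel scale.
#'
#' @param shape A [reconstruct_average_shape()] object.
#' @param path Output path.
#' @param px_per_unit Pixels per axis-tenth unit.
#' @return Invisibly, `path`.
#' @export
write_shape_svg <- function(shape, path, px_per_unit = 40) {
  stopifnot(inherits(shape, "mean_shape"), px_per_unit > 0)
  p <- shape$polygon
  xmax <- max(abs(p[, 1])) + 0.5
  w <- 2 * xmax * px_per_unit
  h <- 11 * px_per_unit
  px <- function(x) (x + xmax) * px_per_unit
  py <- function(y) (y + 0.5) * px_per_unit  # anterior (y = 0) at the top
  pts <- paste(sprintf("%.3f,%.3f", px(p[, 1]), py(p[, 2])), collapse = " ")
  svg <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
            w, h, w, h),
    sprintf('<!-- labiometry %s | average shape, %g px per axis-tenth unit -->',
            as.character(utils::packageVersion("labiometry")), px_per_unit),
    sprintf('<polygon points="%s" fill="#d9c2c8" stroke="#5c3a45" stroke-width="1.5"/>',
            pts),
    sprintf('<line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="#5c3a45" stroke-dasharray="6 4"/>',
            px(0), py(0), px(0), py(10)),
    '</svg>'
  )
  writeLines(svg, path, useBytes = TRUE)
  invisible(path)
}
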