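# Pipeline stage functions. These are the programmatic equivalents of the
# command-line subcommands in inst/cli/labiometry: each takes file paths,
# runs the corresponding package operations and writes the machine outputs.
# Diagnostics go to stderr via message()/warning(); data never does.

#' Measure every subject in a landmark file
#'
#' Pipeline stage: read a landmark CSV, measure each subject's width
#' profile and write the profile table. Subjects whose landmarks fail
#' validation (malformed contour, degenerate axis, side-assignment
#' conflict) are logged to stderr and skipped; an error is raised only if
#' every subject fails.
#'
#' @param landmark_csv Input landmark CSV path (see
#'   [read_landmarks_csv()]).
#' @param out_csv Output profile CSV path; `NULL` to skip writing.
#' @return Invisibly, the profile data frame.
#' @export
run_measure <- function(landmark_csv, out_csv = NULL) {
  landmarks <- read_landmarks_csv(landmark_csv, on_error = "keep")
  profiles <- list()
  for (lm in landmarks) {
    p <- tryCatch({
      if (inherits(lm, "condition")) stop(lm)
      measure_subject(lm)
    }, error = function(e) {
      message("skipping subject: ", conditionMessage(e))
      NULL
    })
    if (!is.null(p)) profiles[[p$subject_id]] <- p
  }
  if (length(profiles) == 0L) {
    stop("empty result: no subject could be measured", call. = FALSE)
  }
  flagged <- vapply(profiles, function(p) length(p$qc_flags) > 0, logical(1))
  if (any(flagged)) {
    warning("QC flags (zero-width segments) for: ",
            paste(names(profiles)[flagged], collapse = ", "), call. = FALSE)
  }
  df <- profiles_as_df(profiles)
  if (!is.null(out_csv)) write_profiles_csv(df, out_csv)
  invisible(df)
}

#' Compute per-subject features from a profile file
#'
#' Pipeline stage: read a profile CSV and write the per-subject feature
#' table (adjacent ratios, prominence zone, asymmetry).
#'
#' @param profile_csv Input profile CSV path.
#' @param out_csv Output feature CSV path; `NULL` to skip writing.
#' @return Invisibly, the feature data frame.
#' @export
run_features <- function(profile_csv, out_csv = NULL) {
  df <- read_profiles_csv(profile_csv)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    fs <- subject_features(row_profile(df[i, ]))
    data.frame(subject_id = fs$subject_id,
               t(fs$L_ratios), t(fs$R_ratios),
               prominence_zone = fs$prominence_zone,
               argmax_segment = fs$argmax_segment,
               t(fs$asymmetry),
               asym_summary = fs$asymmetry_summary,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("/", "_", names(out))   # L1/L2 -> L1_L2 for the header
  if (!is.null(out_csv)) {
    write_csv_with_meta(out, out_csv, "per-subject shape features")
  }
  invisible(out)
}

#' Run the cohort analysis and write the report artifacts
#'
#' Pipeline stage: join profiles with metadata, then write the cohort
#' summary JSON, the average-shape SVG and one comparison CSV per
#' grouping scheme. Schemes whose strata cannot be compared (a single
#' populated group, or all pairs undersized) are skipped with a stderr
#' note.
#'
#' @param profile_csv Profile CSV path.
#' @param metadata_csv Metadata CSV path (`subject_id`, `age`, `births`,
#'   `labiaplasty`).
#' @param out_dir Output directory, created if needed.
#' @param schemes Grouping schemes to run, a subset of
#'   `c("age4", "parity3", "labiaplasty2")`.
#' @param alpha Significance level for the comparison protocol.
#' @param center Levene centering (see [levene_test()]).
#' @param svg_px Pixels per unit for the SVG rendering.
#' @param golden Optional labial-distance list for the golden-ratio
#'   indices (see [cohort_summary()]).
#' @return Invisibly, a list with the `cohort_summary`, the comparison
#'   lists and the written paths.
#' @export
run_cohort <- function(profile_csv, metadata_csv, out_dir,
                       schemes = c("age4", "parity3", "labiaplasty2"),
                       alpha = 0.05, center = "mean", svg_px = 40,
                       golden = NULL) {
  profiles <- read_profiles_csv(profile_csv)
  metadata <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE,
                              comment.char = "#")
  cohort <- assemble_cohort(profiles, metadata)
  summary <- cohort_summary(cohort, golden = golden)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(summary = file.path(out_dir, "cohort_summary.json"),
                svg = file.path(out_dir, "mean_shape.svg"))
  write_summary_json(summary, paths$summary)
  write_shape_svg(summary$mean_shape, paths$svg, px_per_unit = svg_px)
  comparisons <- list()
  for (scheme in schemes) {
    cmp <- compare_strata(cohort, scheme, alpha = alpha, center = center)
    if (length(cmp) == 0L) next
    comparisons[[scheme]] <- cmp
    p <- file.path(out_dir, paste0("comparisons_", scheme, ".csv"))
    write_comparisons_csv(cmp, p)
    paths[[scheme]] <- p
  }
  invisible(list(summary = summary, comparisons = comparisons,
                 paths = paths))
}
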