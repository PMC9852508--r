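seg_names <- function() c(paste0("L", 1:9), paste0("R", 1:9))

#' Assemble a cohort table from profiles and metadata
#'
#' Joins a profile table (one row per subject, columns `subject_id`,
#' `L1..L9`, `R1..R9`, optionally `qc_flags`) with a metadata table
#' (`subject_id`, `age`, `births`, `labiaplasty`) on `subject_id`.
#' Unmatched ids on either side are dropped with a warning.
#'
#' @param profiles Data frame of width profiles (see [profiles_as_df()]).
#' @param metadata Data frame with columns `subject_id`, `age` (years),
#'   `births` (count), `labiaplasty` (logical: labiaplasty planned).
#' @return A data frame of class `"labia_cohort"`.
#' @export
assemble_cohort <- function(profiles, metadata) {
  need_p <- c("subject_id", seg_names())
  need_m <- c("subject_id", "age", "births", "labiaplasty")
  miss_p <- setdiff(need_p, names(profiles))
  miss_m <- setdiff(need_m, names(metadata))
  if (length(miss_p) || length(miss_m)) {
    stop("missing columns: ",
         paste(c(miss_p, miss_m), collapse = ", "), call. = FALSE)
  }
  unjoined <- c(setdiff(profiles$subject_id, metadata$subject_id),
                setdiff(metadata$subject_id, profiles$subject_id))
  if (length(unjoined)) {
    warning("dropping unjoined subject ids: ",
            paste(unique(unjoined), collapse = ", "), call. = FALSE)
  }
  out <- merge(metadata[need_m], profiles, by = "subject_id", sort = TRUE)
  if (nrow(out) == 0L) {
    stop("empty cohort: no subject ids in common", call. = FALSE)
  }
  out$labiaplasty <- as.logical(out$labiaplasty)
  class(out) <- c("labia_cohort", "data.frame")
  out
}

#' Flatten width-profile objects to a data frame
#'
#' @param profiles A list of [width_profile()] objects.
#' @return A data frame with `subject_id`, `L1..L9`, `R1..R9` and
#'   `qc_flags` (semicolon-joined flagged segment names, `""` if clean).
#' @export
profiles_as_df <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "width_profile"))
    v <- c(p$L, p$R)
    names(v) <- seg_names()
    data.frame(subject_id = p$subject_id, as.list(v),
               qc_flags = paste(p$qc_flags, collapse = ";"),
               check.names = FALSE)
  })
  do.call(rbind, rows)
}

cohort_matrix <- function(cohort) {
  as.matrix(cohort[, seg_names(), drop = FALSE])
}

row_profile <- function(row) {
  width_profile(as.character(row[["subject_id"]]),
                as.numeric(row[paste0("L", 1:9)]),
                as.numeric(row[paste0("R", 1:9)]))
}

#' Per-segment cohort means
#'
#' Arithmetic mean of each of the 18 widths over all subjects. Subjects
#' with QC-flagged zero segments are included: a zero is a real
#' measurement (the labial edge does not reach that level of the
#' vestibule).
#'
#' @param cohort A `"labia_cohort"` data frame (or any data frame with
#'   `L1..L9`, `R1..R9` columns).
#' @return A list with numeric vectors `mean_L` and `mean_R` (length 9).
#' @export
mean_profile <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  m <- colMeans(cohort_matrix(cohort))
  list(mean_L = m[paste0("L", 1:9)], mean_R = m[paste0("R", 1:9)])
}

#' Cohort adjacent-ratio tables
#'
#' Two distinct summaries of the adjacent-segment ratios, kept separate
#' because they differ in general: the ratio of means (ratios computed on
#' the cohort mean vectors) and the mean of ratios (per-subject ratios
#' averaged, skipping subjects whose denominator is zero and reporting how
#' many were skipped).
#'
#' @param cohort A `"labia_cohort"` data frame.
#' @return A list with `ratio_of_means_L/R`, `mean_of_ratios_L/R` (length-8
#'   named vectors) and `n_undefined_L/R` (per-ratio skip counts).
#' @export
cohort_ratio_tables <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  mp <- mean_profile(cohort)
  rom <- function(v, side) {
    if (any(v[2:9] == 0)) {
      warning("zero mean denominator on side ", side, call. = FALSE)
    }
    r <- ifelse(v[2:9] == 0, NA_real_, v[1:8] / v[2:9])
    names(r) <- paste0(side, 1:8, "/", side, 2:9)
    r
  }
  per_subject <- lapply(seq_len(nrow(cohort)),
                        function(i) adjacent_ratios(row_profile(cohort[i, ])))
  mor <- function(which, side) {
    m <- do.call(rbind, lapply(per_subject, `[[`, which))
    r <- colMeans(m, na.rm = TRUE)
    r[colSums(!is.na(m)) == 0L] <- NA_real_
    list(mean = r, n_undefined = colSums(is.na(m)))
  }
  ml <- mor("L_ratios", "L"); mr <- mor("R_ratios", "R")
  list(ratio_of_means_L = rom(mp$mean_L, "L"),
       ratio_of_means_R = rom(mp$mean_R, "R"),
       mean_of_ratios_L = ml$mean, mean_of_ratios_R = mr$mean,
       n_undefined_L = ml$n_undefined, n_undefined_R = mr$n_undefined)
}

#' Prominence-zone distribution of a cohort
#'
#' Tallies [prominence_class()] over all subjects: how many have their
#' widest point in the anterior (segments 1-3), middle (4-6) or posterior
#' (7-9) third of the vestibule. Percentages use the number of classifiable
#' subjects as denominator and are rounded to 2 decimals; subjects with an
#' all-zero profile are counted separately as `n_undefined`.
#'
#' @param cohort A `"labia_cohort"` data frame.
#' @return A list with integer `counts` and numeric `percent` (both named
#'   anterior/middle/posterior), `n` (classifiable subjects) and
#'   `n_undefined`.
#' @export
prominence_distribution <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  zones <- vapply(seq_len(nrow(cohort)), function(i) {
    prominence_class(row_profile(cohort[i, ]))$zone
  }, character(1))
  ok <- !is.na(zones)
  lev <- c("anterior", "middle", "posterior")
  counts <- table(factor(zones[ok], levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  n <- sum(ok)
  list(counts = counts,
       percent = round(100 * counts / n, 2),
       n = n, n_undefined = sum(!ok))
}

#' Reconstruct the cohort average shape
#'
#' Builds the average-shape outline from the per-segment mean widths: a
#' closed piecewise-linear polygon in axis units running from the anterior
#' axis end down the left edge (at x = -mean_L_k, y = k), through the
#' posterior axis end, and back up the right edge (x = +mean_R_k). The
#' graphic-to-digital conversion is thereby inverted: re-measuring this
#' polygon with [plumb_widths()] returns exactly the input means.
#'
#' @param mean_L,mean_R Numeric vectors of 9 non-negative mean widths
#'   (axis-tenth units).
#' @return An object of class `"mean_shape"`: a list with `polygon` (a
#'   closed 21 x 2 matrix, first row repeated last), `left` and `right`
#'   (the 11-point per-side polylines including both axis endpoints), and
#'   the input means.
#' @export
reconstruct_average_shape <- function(mean_L, mean_R) {
  mean_L <- as.numeric(mean_L); mean_R <- as.numeric(mean_R)
  if (length(mean_L) != 9L || length(mean_R) != 9L ||
      !all(is.finite(c(mean_L, mean_R))) || any(c(mean_L, mean_R) < 0)) {
    stop("need 9 finite non-negative mean widths per side", call. = FALSE)
  }
  left <- cbind(x = c(0, -mean_L, 0), y = 0:10)
  right <- cbind(x = c(0, mean_R, 0), y = 0:10)
  polygon <- rbind(left, right[10:2, , drop = FALSE], left[1, , drop = FALSE])
  rownames(polygon) <- NULL
  structure(list(polygon = polygon, left = left, right = right,
                 mean_L = mean_L, mean_R = mean_R),
            class = "mean_shape")
}

#' Shoelace area of a mean shape
#'
#' @param shape A [reconstruct_average_shape()] object.
#' @return Polygon area in squared axis units.
#' @export
shape_area <- function(shape) {
  stopifnot(inherits(shape, "mean_shape"))
  p <- shape$polygon
  n <- nrow(p)
  abs(sum(p[-n, 1] * p[-1, 2] - p[-1, 1] * p[-n, 2])) / 2
}

#' @export
plot.mean_shape <- function(x, ...) {
  p <- x$polygon
  graphics::plot(p, type = "n", asp = 1, xlab = "width (axis-tenth units)",
                 ylab = "axial position (anterior → posterior)", ...)
  graphics::polygon(p, col = "grey85", border = "grey30")
  graphics::segments(0, 0, 0, 10, lty = 2)
  invisible(x)
}

#' Stratify a cohort into the protocol's comparison groups
#'
#' Grouping schemes: `"age4"` bins age into 18-30 / 31-40 / 41-50 / >= 51
#' years (groups `A`-`D`); `"parity3"` bins number of births into 0 / 1 /
#' >= 2 (groups `1`-`3`); `"labiaplasty2"` splits by whether labiaplasty is
#' planned (`I` = yes, `II` = no). Subjects younger than 18 are outside the
#' protocol: they get `NA` with a warning and are excluded from group
#' sizes.
#'
#' @param cohort A `"labia_cohort"` data frame.
#' @param scheme One of `"age4"`, `"parity3"`, `"labiaplasty2"`.
#' @return A factor of length `nrow(cohort)` (NA = excluded).
#' @export
stratify <- function(cohort, scheme = c("age4", "parity3", "labiaplasty2")) {
  scheme <- match.arg(scheme)
  under <- cohort$age < 18
  if (any(under)) {
    warning(sum(under), " subject(s) younger than 18 excluded (out of protocol)",
            call. = FALSE)
  }
  g <- switch(scheme,
    age4 = cut(cohort$age, breaks = c(18, 30, 40, 50, Inf),
               labels = c("A", "B", "C", "D"),
               include.lowest = TRUE, right = TRUE),
    parity3 = cut(cohort$births, breaks = c(-Inf, 0, 1, Inf),
                  labels = c("1", "2", "3")),
    labiaplasty2 = factor(ifelse(cohort$labiaplasty, "I", "II"),
                          levels = c("I", "II"))
  )
  g[under] <- NA
  g
}

#' Levene's test for equality of variances, two groups
#'
#' Gate test of the comparison protocol: tests whether two samples have
#' equal variances before choosing the t-test variant. Classic Levene uses
#' absolute deviations from the group mean; `center = "median"` gives the
#' Brown-Forsythe variant. The statistic W is referred to
#' F(1, n1 + n2 - 2).
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @param center `"mean"` (default, classic Levene) or `"median"`.
#' @return A list with `W`, `p` and `df` (the two F degrees of freedom).
#' @export
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  res <- car::leveneTest(c(x, y), g,
                         center = if (center == "mean") mean else stats::median)
  W <- res[1, "F value"]
  p <- res[1, "Pr(>F)"]
  if (!is.finite(W)) { W <- 0; p <- 1 }   # zero spread in both groups
  list(W = W, p = p, df = c(1L, length(x) + length(y) - 2L))
}

#' Compare two cohort strata segment by segment
#'
#' The two-sample comparison protocol: for each of the 18 width segments,
#' Levene's test gates the variance assumption at `alpha`; if variances
#' are judged equal a pooled-variance Student t-test is used, otherwise
#' Welch's t-test. Tests are two-sided; significance is `p < alpha`. No
#' multiple-testing correction is applied across the 18 segments -- treat
#' isolated significant segments with caution.
#'
#' @param group_x,group_y `"labia_cohort"` data frames (>= 2 subjects each).
#' @param labels Character pair naming the two groups.
#' @param grouping_name Name of the stratification (e.g. `"age4"`).
#' @param alpha Significance level for both the gate and the t-test.
#' @param center Levene centering, see [levene_test()].
#' @return A data frame of class `"group_comparison"`, one row per segment:
#'   `segment`, `levene_W`, `levene_p`, `variance_equal`, `t_statistic`,
#'   `t_p`, `test_variant` (`"pooled"` or `"welch"`), `significant`.
#' @export
compare_groups <- function(group_x, group_y,
                           labels = c("X", "Y"), grouping_name = "",
                           alpha = 0.05, center = c("mean", "median")) {
  center <- match.arg(center)
  if (nrow(group_x) < 2L || nrow(group_y) < 2L) {
    small <- labels[c(nrow(group_x), nrow(group_y)) < 2L]
    stop("undersized stratum (need >= 2 subjects): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  mx <- cohort_matrix(group_x); my <- cohort_matrix(group_y)
  rows <- lapply(seg_names(), function(s) {
    lv <- levene_test(mx[, s], my[, s], center = center)
    eq <- lv$p >= alpha
    tt <- stats::t.test(mx[, s], my[, s], var.equal = eq,
                        alternative = "two.sided")
    data.frame(segment = s, levene_W = lv$W, levene_p = lv$p,
               variance_equal = eq,
               t_statistic = unname(tt$statistic), t_p = tt$p.value,
               test_variant = if (eq) "pooled" else "welch",
               significant = tt$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "grouping_name") <- grouping_name
  attr(out, "group_labels") <- labels
  attr(out, "alpha") <- alpha
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' All pairwise stratum comparisons for one grouping scheme
#'
#' Runs [compare_groups()] for every pair of groups produced by
#' [stratify()]. Pairs in which either group has fewer than 2 subjects are
#' skipped with a message.
#'
#' @inheritParams stratify
#' @inheritParams compare_groups
#' @return A named list of `"group_comparison"` data frames
#'   (`"A_vs_B"`, ...); empty if no pair is comparable.
#' @export
compare_strata <- function(cohort, scheme, alpha = 0.05,
                           center = c("mean", "median")) {
  center <- match.arg(center)
  g <- stratify(cohort, scheme)
  present <- levels(g)[levels(g) %in% g[!is.na(g)]]
  out <- list()
  if (length(present) < 2L) {
    message("scheme '", scheme, "': fewer than two populated groups, ",
            "comparisons skipped")
    return(out)
  }
  for (i in seq_len(length(present) - 1L)) {
    for (j in seq(i + 1L, length(present))) {
      a <- present[i]; b <- present[j]
      ga <- cohort[!is.na(g) & g == a, , drop = FALSE]
      gb <- cohort[!is.na(g) & g == b, , drop = FALSE]
      key <- paste0(a, "_vs_", b)
      if (nrow(ga) < 2L || nrow(gb) < 2L) {
        message("scheme '", scheme, "': pair ", key,
                " skipped (a stratum has < 2 subjects)")
        next
      }
      out[[key]] <- compare_groups(ga, gb, labels = c(a, b),
                                   grouping_name = scheme,
                                   alpha = alpha, center = center)
    }
  }
  out
}

#' Full cohort summary
#'
#' One-stop aggregation: n, per-segment means, both ratio tables, the
#' prominence distribution and the reconstructed average shape.
#'
#' @param cohort A `"labia_cohort"` data frame.
#' @param golden Optional list as returned by
#'   [reference_labial_distances()]; when supplied, golden-ratio indices
#'   are included.
#' @return A list of class `"cohort_summary"`.
#' @export
cohort_summary <- function(cohort, golden = NULL) {
  mp <- mean_profile(cohort)
  rt <- cohort_ratio_tables(cohort)
  pd <- prominence_distribution(cohort)
  gr <- if (!is.null(golden)) {
    list(left = golden_ratio_index(golden$left[[1]], golden$left[[2]]),
         right = golden_ratio_index(golden$right[[1]], golden$right[[2]]))
  }
  structure(
    list(n = nrow(cohort), mean_L = mp$mean_L, mean_R = mp$mean_R,
         ratio_of_means_L = rt$ratio_of_means_L,
         ratio_of_means_R = rt$ratio_of_means_R,
         mean_of_ratios_L = rt$mean_of_ratios_L,
         mean_of_ratios_R = rt$mean_of_ratios_R,
         prominence_counts = pd$counts, prominence_percent = pd$percent,
         prominence_undefined = pd$n_undefined,
         golden_ratio = gr,
         mean_shape = reconstruct_average_shape(mp$mean_L, mp$mean_R)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort summary (n = %d subjects)\n", x$n))
  m <- rbind(mean_L = x$mean_L, mean_R = x$mean_R)
  colnames(m) <- as.character(1:9)
  print(round(m, digits))
  cat("Ratio of means (L):",
      paste(round(x$ratio_of_means_L, digits), collapse = " "), "\n")
  cat("Ratio of means (R):",
      paste(round(x$ratio_of_means_R, digits), collapse = " "), "\n")
  cat("Prominence:",
      paste(sprintf("%s %d (%.2f%%)", names(x$prominence_counts),
                    x$prominence_counts, x$prominence_percent),
            collapse = ", "), "\n")
  if (!is.null(x$golden_ratio)) {
    cat(sprintf("Golden-ratio index: left %.3f, right %.3f\n",
                x$golden_ratio$left, x$golden_ratio$right))
  }
  invisible(x)
}
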