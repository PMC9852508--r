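#' Construct the vestibule axis from its two endpoints
#'
#' The longitudinal axis of the vaginal vestibule runs from its anterior to
#' its posterior end and is divided into ten equal segments; the length of
#' one segment is the measurement unit, so all widths derived from the axis
#' are scale-free (expressed in axis-tenth units).
#'
#' @param anterior Numeric length-2 vector `c(x, y)`: anterior axis endpoint.
#' @param posterior Numeric length-2 vector `c(x, y)`: posterior axis endpoint.
#'
#' @return An object of class `"labia_axis"`: a list with elements
#'   `anterior`, `posterior`, `length` (Euclidean endpoint distance) and
#'   `unit` (`length / 10`).
#'
#' @examples
#' ax <- build_axis(c(0, 0), c(0, 10))
#' ax$unit   # 1
#' @export
build_axis <- function(anterior, posterior) {
  anterior <- as_point(anterior, "anterior")
  posterior <- as_point(posterior, "posterior")
  len <- sqrt(sum((posterior - anterior)^2))
  if (len <= 0) {
    stop("degenerate axis: anterior and posterior endpoints coincide",
         call. = FALSE)
  }
  structure(
    list(anterior = anterior, posterior = posterior,
         length = len, unit = len / 10),
    class = "labia_axis"
  )
}

as_point <- function(p, what) {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p))) {
    stop(sprintf("%s must be a finite length-2 coordinate", what),
         call. = FALSE)
  }
  p
}

#' Bundle raw landmarks for one subject
#'
#' Raw digitized input for a single subject: the ordered outlines of the
#' left and right labial free edges plus the two vestibule-axis endpoints,
#' in arbitrary image coordinates (pixels, millimetres -- the method is
#' unit-free).
#'
#' @param subject_id Character scalar identifier.
#' @param left,right Two-column numeric matrices (or data frames with
#'   columns `x`, `y`) of ordered contour points, at least 2 rows each.
#' @param anterior,posterior Axis endpoints, each a numeric `c(x, y)`.
#'
#' @return An object of class `"subject_landmarks"`.
#' @export
subject_landmarks <- function(subject_id, left, right, anterior, posterior) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  left <- as_contour(left, "left")
  right <- as_contour(right, "right")
  structure(
    list(subject_id = subject_id,
         left = left, right = right,
         anterior = as_point(anterior, "anterior"),
         posterior = as_point(posterior, "posterior")),
    class = "subject_landmarks"
  )
}

as_contour <- function(m, side) {
  if (is.data.frame(m)) m <- as.matrix(m[, c("x", "y")])
  m <- unname(as.matrix(m))
  storage.mode(m) <- "double"
  if (ncol(m) != 2L || nrow(m) < 2L || !all(is.finite(m))) {
    stop(sprintf("malformed %s contour: need >= 2 finite (x, y) points", side),
         call. = FALSE)
  }
  m
}

#' Transform landmarks into the axis frame
#'
#' Applies the rigid transform (translation + rotation) that maps the
#' anterior axis endpoint to the origin and the posterior endpoint to
#' `(0, length)`, so the axis lies along +y. The anatomical left contour
#' must end up at negative x and the right contour at positive x; if the
#' digitized coordinates are mirrored (left at +x, right at -x, as happens
#' when a photograph is flipped) the frame is reflected about the axis so
#' the labels win. If both contours fall on the same side of the axis the
#' side assignment is irrecoverable and an error is raised.
#'
#' @param landmarks A [subject_landmarks()] object.
#' @return A `"subject_landmarks"` object in the axis frame (axis endpoints
#'   at `(0, 0)` and `(0, length)`).
#' @export
to_axis_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "subject_landmarks"))
  d <- landmarks$posterior - landmarks$anterior
  len <- sqrt(sum(d^2))
  if (len <= 0) {
    stop("degenerate axis: anterior and posterior endpoints coincide",
         call. = FALSE)
  }
  d <- d / len
  # rotation sending the unit axis direction d to (0, 1)
  rot <- rbind(c(d[2], -d[1]),
               c(d[1],  d[2]))
  tf <- function(m) t(rot %*% (t(m) - landmarks$anterior))
  left <- tf(landmarks$left)
  right <- tf(landmarks$right)
  sl <- mean(left[, 1])
  sr <- mean(right[, 1])
  if (sl * sr > 0 || (sl == 0 && sr == 0)) {
    stop(sprintf("side-assignment error for subject '%s': both contours lie on the same side of the axis",
                 landmarks$subject_id), call. = FALSE)
  }
  if (sl > 0 || sr < 0) {   # mirrored digitization: reflect across the axis
    left[, 1] <- -left[, 1]
    right[, 1] <- -right[, 1]
  }
  structure(
    list(subject_id = landmarks$subject_id,
         left = left, right = right,
         anterior = c(0, 0), posterior = c(0, len)),
    class = "subject_landmarks"
  )
}

#' Plumb-line widths of one contour
#'
#' Measures the perpendicular distance from the vestibule axis to a contour
#' at the nine interior division points. The contour must already be in the
#' axis frame (axis along +y from the origin). At each axial position
#' `k * unit` (k = 1..9) the horizontal plumb line is intersected with the
#' contour polyline (linear interpolation between vertices); the width is
#' the outermost intersection's `|x|`, divided by the unit so the result is
#' in axis-tenth units. A plumb line that misses the contour's axial span
#' gives width 0 and a QC flag for that segment.
#'
#' @param contour Two-column numeric matrix of ordered points in the axis
#'   frame.
#' @param axis A [build_axis()] object (only `unit` is used).
#' @return Numeric vector of 9 non-negative widths with attribute
#'   `"qc_flags"`: integer indices (1..9) of segments the contour did not
#'   span.
#' @export
plumb_widths <- function(contour, axis) {
  stopifnot(inherits(axis, "labia_axis"))
  contour <- as_contour(contour, "input")
  unit <- axis$unit
  w <- numeric(9)
  missed <- integer(0)
  x <- contour[, 1]
  y <- contour[, 2]
  n <- length(x)
  for (k in 1:9) {
    yk <- k * unit
    hits <- numeric(0)
    for (i in seq_len(n - 1L)) {
      y1 <- y[i]; y2 <- y[i + 1L]
      if ((y1 - yk) * (y2 - yk) > 0) next
      if (y1 == y2) {              # edge lying on the plumb line
        hits <- c(hits, x[i], x[i + 1L])
      } else {
        t <- (yk - y1) / (y2 - y1)
        hits <- c(hits, x[i] + t * (x[i + 1L] - x[i]))
      }
    }
    if (length(hits) == 0L) {
      missed <- c(missed, k)
      w[k] <- 0
    } else {
      w[k] <- max(abs(hits)) / unit
    }
  }
  attr(w, "qc_flags") <- missed
  w
}

#' Measure a subject's normalized width profile
#'
#' Composes [build_axis()], [to_axis_frame()] and [plumb_widths()] to turn
#' raw landmarks into the 18-value width profile: `L1..L9` from the left
#' contour and `R1..R9` from the right, each the axis-to-edge distance at a
#' division point in axis-tenth units. The profile is invariant under
#' rotation, translation and uniform scaling of the input coordinates.
#'
#' @param landmarks A [subject_landmarks()] object.
#' @return A [width_profile()] object.
#' @export
measure_subject <- function(landmarks) {
  stopifnot(inherits(landmarks, "subject_landmarks"))
  res <- tryCatch({
    axis <- build_axis(landmarks$anterior, landmarks$posterior)
    fr <- to_axis_frame(landmarks)
    list(L = plumb_widths(fr$left, axis),
         R = plumb_widths(fr$right, axis))
  }, error = function(e) {
    stop(sprintf("subject '%s': %s", landmarks$subject_id, conditionMessage(e)),
         call. = FALSE)
  })
  qc <- c(
    if (length(attr(res$L, "qc_flags"))) paste0("L", attr(res$L, "qc_flags")),
    if (length(attr(res$R, "qc_flags"))) paste0("R", attr(res$R, "qc_flags"))
  )
  width_profile(landmarks$subject_id,
                as.numeric(res$L), as.numeric(res$R),
                qc_flags = if (is.null(qc)) character(0) else qc)
}

#' Normalized width profile of one subject
#'
#' The core statistic of the method: nine left (`L1..L9`) and nine right
#' (`R1..R9`) axis-to-edge widths in axis-tenth units, anterior first.
#' Values are dimensionless multiples of the subject's own vestibule unit,
#' so profiles are comparable across subjects photographed at any scale.
#'
#' @param subject_id Character scalar.
#' @param L,R Numeric vectors of 9 non-negative finite widths.
#' @param qc_flags Character vector of segment names (e.g. `"L7"`) whose
#'   plumb line missed the contour (width recorded as 0).
#' @return An object of class `"width_profile"`.
#' @export
width_profile <- function(subject_id, L, R, qc_flags = character(0)) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  L <- as.numeric(L); R <- as.numeric(R)
  if (length(L) != 9L || length(R) != 9L ||
      !all(is.finite(c(L, R))) || any(c(L, R) < 0)) {
    stop("width profile needs 9 finite non-negative values per side",
         call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, L = L, R = R,
         qc_flags = as.character(qc_flags)),
    class = "width_profile"
  )
}

#' @export
print.width_profile <- function(x, digits = 3, ...) {
  cat(sprintf("Width profile for subject '%s' (axis-tenth units)\n",
              x$subject_id))
  m <- rbind(L = x$L, R = x$R)
  colnames(m) <- as.character(1:9)
  print(round(m, digits))
  if (length(x$qc_flags)) {
    cat("QC-flagged segments:", paste(x$qc_flags, collapse = ", "), "\n")
  }
  invisible(x)
}
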