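#' Simulation parameters for a synthetic cohort
#'
#' Defines the generative model for synthetic width-profile cohorts. Per
#' subject and side, the 9 segment widths are drawn from a multivariate
#' normal centred on the side's mean vector with covariance
#' `sd^2 * rho^|i-j|` (AR(1) along the contour: adjacent widths on a
#' smooth edge are correlated), plus independent per-side noise of
#' standard deviation `asym_sd` that creates left-right asymmetry beyond
#' the shared draw, plus optional covariate effects, truncated at 0.
#' Defaults produce a null cohort (no covariate effects) centred on the
#' reference cohort means with demographics matching the reference study
#' population: births 0/1/2/3 with probabilities 0.6075/0.2475/
#' 0.0725/0.0725 and labiaplasty planned with probability 0.5575.
#'
#' @param n Number of subjects (> 0).
#' @param mean_L,mean_R Length-9 non-negative mean width vectors
#'   (axis-tenth units); defaults from [reference_means()].
#' @param sd Per-segment noise standard deviation (> 0), axis-tenth units.
#' @param rho AR(1) correlation between adjacent segments, in [0, 1).
#' @param asym_sd Extra independent per-side noise SD (>= 0).
#' @param age_range Integer pair: ages are drawn uniformly over this range.
#' @param age_slope Width change (axis-tenth units) per decade of age,
#'   centred on the midpoint of `age_range`; 0 = no age effect.
#' @param parity_offsets Length-3 additive width offsets for the parity
#'   strata 0 / 1 / >= 2 births.
#' @param labiaplasty_effect Additive width offset for subjects planning
#'   labiaplasty.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the seed.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n = 400L,
                       mean_L = reference_means()$L,
                       mean_R = reference_means()$R,
                       sd = 0.5, rho = 0.5, asym_sd = 0,
                       age_range = c(18L, 70L),
                       age_slope = 0,
                       parity_offsets = c(0, 0, 0),
                       labiaplasty_effect = 0,
                       seed = 1L) {
  bad <- character(0)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    bad <- c(bad, "n")
  if (length(mean_L) != 9L || any(!is.finite(mean_L)) || any(mean_L < 0))
    bad <- c(bad, "mean_L")
  if (length(mean_R) != 9L || any(!is.finite(mean_R)) || any(mean_R < 0))
    bad <- c(bad, "mean_R")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    bad <- c(bad, "sd")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    bad <- c(bad, "rho")
  if (!is.numeric(asym_sd) || length(asym_sd) != 1L || asym_sd < 0)
    bad <- c(bad, "asym_sd")
  if (length(age_range) != 2L || age_range[1] < 18 ||
      age_range[2] < age_range[1])
    bad <- c(bad, "age_range")
  if (length(parity_offsets) != 3L || any(!is.finite(parity_offsets)))
    bad <- c(bad, "parity_offsets")
  if (!is.numeric(age_slope) || length(age_slope) != 1L ||
      !is.finite(age_slope))
    bad <- c(bad, "age_slope")
  if (!is.numeric(labiaplasty_effect) || length(labiaplasty_effect) != 1L ||
      !is.finite(labiaplasty_effect))
    bad <- c(bad, "labiaplasty_effect")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    bad <- c(bad, "seed")
  if (length(bad)) {
    stop("invalid simulation parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n = as.integer(n),
         mean_L = as.numeric(mean_L), mean_R = as.numeric(mean_R),
         sd = sd, rho = rho, asym_sd = asym_sd,
         age_range = as.integer(age_range), age_slope = age_slope,
         parity_offsets = as.numeric(parity_offsets),
         labiaplasty_effect = labiaplasty_effect,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

ar1_sigma <- function(sd, rho) {
  sd^2 * rho^abs(outer(1:9, 1:9, "-"))
}

#' Generate a synthetic cohort of width profiles
#'
#' Draws `params$n` subjects from the generative model described in
#' [sim_params()]: uniform ages, categorical births, Bernoulli labiaplasty
#' flag, and per side a 9-vector from the AR(1) multivariate normal plus
#' covariate offsets, truncated at 0 (widths are distances). The RNG state
#' is set from `params$seed` and restored afterwards, so the same
#' parameters always yield the same cohort.
#'
#' @param params A [sim_params()] object.
#' @return A `"labia_cohort"` data frame with columns `subject_id`, `age`,
#'   `births`, `labiaplasty`, `L1..L9`, `R1..R9`.
#' @export
generate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  n <- params$n
  ages <- seq(params$age_range[1], params$age_range[2])
  age <- ages[sample.int(length(ages), n, replace = TRUE)]
  births <- sample(0:3, n, replace = TRUE,
                   prob = c(0.6075, 0.2475, 0.0725, 0.0725))
  labiaplasty <- stats::runif(n) < 0.5575
  sigma <- ar1_sigma(params$sd, params$rho)
  eL <- MASS::mvrnorm(n, mu = rep(0, 9), Sigma = sigma)
  eR <- MASS::mvrnorm(n, mu = rep(0, 9), Sigma = sigma)
  if (params$asym_sd > 0) {
    eL <- eL + matrix(stats::rnorm(9 * n, sd = params$asym_sd), n, 9)
    eR <- eR + matrix(stats::rnorm(9 * n, sd = params$asym_sd), n, 9)
  }
  offset <- params$age_slope * (age - mean(params$age_range)) / 10 +
    params$parity_offsets[pmin(births, 2) + 1L] +
    params$labiaplasty_effect * labiaplasty
  L <- pmax(sweep(eL, 2, params$mean_L, "+") + offset, 0)
  R <- pmax(sweep(eR, 2, params$mean_R, "+") + offset, 0)
  colnames(L) <- paste0("L", 1:9)
  colnames(R) <- paste0("R", 1:9)
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, births = births, labiaplasty = labiaplasty,
    L, R, check.names = FALSE
  )
  class(out) <- c("labia_cohort", "data.frame")
  attr(out, "params") <- params
  out
}

#' Render a width profile as subject landmarks
#'
#' Inverse of the measurement operator, used for round-trip testing and
#' for turning simulated profiles into landmark files: each side becomes a
#' polyline with vertices at axial positions 0, 1, ..., 10 units and
#' lateral offsets 0, w1*unit, ..., w9*unit, 0 (negated for the left
#' side), with the axis endpoints at (0, 0) and (0, axis_length). With
#' `jitter = 0` the rendering is exact: [measure_subject()] of the result
#' reproduces the profile. `jitter > 0` perturbs the interior vertices
#' tangentially (along the axis direction) by N(0, jitter * unit), a crude
#' stand-in for digitization noise; the perturbation is deterministic
#' given `seed`.
#'
#' @param profile A [width_profile()] object.
#' @param axis_length Axis length in output coordinate units (> 0).
#' @param jitter Tangential vertex noise as a fraction of one unit (>= 0).
#' @param seed Integer seed for the jitter draw.
#' @return A [subject_landmarks()] object.
#' @export
profiles_to_contours <- function(profile, axis_length = 10, jitter = 0,
                                 seed = 1L) {
  stopifnot(inherits(profile, "width_profile"))
  if (axis_length <= 0) stop("axis_length must be > 0", call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  unit <- axis_length / 10
  yy <- (0:10) * unit
  left <- cbind(x = c(0, -profile$L, 0) * unit, y = yy)
  right <- cbind(x = c(0, profile$R, 0) * unit, y = yy)
  if (jitter > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    # tangential = along +y; endpoints stay pinned to the axis ends
    left[2:10, "y"] <- left[2:10, "y"] +
      stats::rnorm(9, sd = jitter * unit)
    right[2:10, "y"] <- right[2:10, "y"] +
      stats::rnorm(9, sd = jitter * unit)
  }
  subject_landmarks(profile$subject_id, left, right,
                    anterior = c(0, 0), posterior = c(0, axis_length))
}

#' Write a synthetic cohort to plain-text files
#'
#' Materializes a simulated cohort on disk in the package's file dialects:
#' a landmark CSV (every profile rendered via [profiles_to_contours()]), a
#' metadata CSV, and a ground-truth JSON recording the generator
#' parameters, for use by external harnesses.
#'
#' @param params A [sim_params()] object.
#' @param dir Output directory (created if needed).
#' @param axis_length Axis length used for the rendered contours.
#' @return Invisibly, a named list of the three file paths.
#' @export
simulate_to_files <- function(params = sim_params(), dir,
                              axis_length = 10) {
  cohort <- generate_cohort(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lm_list <- lapply(seq_len(nrow(cohort)), function(i) {
    profiles_to_contours(row_profile(cohort[i, ]),
                         axis_length = axis_length)
  })
  paths <- list(landmarks = file.path(dir, "landmarks.csv"),
                metadata = file.path(dir, "metadata.csv"),
                truth = file.path(dir, "ground_truth.json"))
  write_landmarks_csv(lm_list, paths$landmarks)
  utils::write.csv(cohort[, c("subject_id", "age", "births", "labiaplasty")],
                   paths$metadata, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(generator = unclass(params),
         package_version = as.character(utils::packageVersion("labiometry"))),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
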