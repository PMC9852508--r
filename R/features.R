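#' Adjacent-segment width ratios
#'
#' For each side, the ratio of consecutive widths `value_n / value_{n+1}`
#' for n = 1..8. Ratios trace the width trend along the free edge: a value
#' of 1 means two adjacent widths are equal, values far from 1 mark a steep
#' change. A zero denominator yields `NA` for that ratio (an undefined
#' marker, never an error), which downstream averaging skips.
#'
#' @param profile A [width_profile()] object.
#' @return A list with numeric vectors `L_ratios` and `R_ratios` (length 8
#'   each), named `"L1/L2"` ... `"R8/R9"`.
#' @export
adjacent_ratios <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  ratio8 <- function(v, side) {
    r <- v[1:8] / v[2:9]
    r[v[2:9] == 0] <- NA_real_
    names(r) <- paste0(side, 1:8, "/", side, 2:9)
    r
  }
  list(L_ratios = ratio8(profile$L, "L"),
       R_ratios = ratio8(profile$R, "R"))
}

#' Prominence-zone classification
#'
#' Locates the maximum of the 18 widths and assigns the subject to a
#' prominence zone: anterior (segments 1-3), middle (4-6) or posterior
#' (7-9), regardless of side. Ties are broken deterministically by the
#' lowest segment index, and left before right at an equal index.
#'
#' @param profile A [width_profile()] object.
#' @return A list with `zone` (one of `"anterior"`, `"middle"`,
#'   `"posterior"`, or `NA` for an all-zero profile) and `argmax_segment`
#'   (a label such as `"L2"`, or `NA`).
#' @export
prominence_class <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  # interleave so which.max's first-hit rule realizes the tie-break:
  # L1, R1, L2, R2, ..., L9, R9
  vals <- as.numeric(rbind(profile$L, profile$R))
  labs <- as.character(rbind(paste0("L", 1:9), paste0("R", 1:9)))
  if (all(vals == 0)) {
    return(list(zone = NA_character_, argmax_segment = NA_character_))
  }
  i <- which.max(vals)
  seg <- (i + 1L) %/% 2L
  zone <- c("anterior", "middle", "posterior")[(seg - 1L) %/% 3L + 1L]
  list(zone = zone, argmax_segment = labs[i])
}

#' Posterior/anterior golden-ratio index
#'
#' The ratio of the posterior labial distance to the anterior labial
#' distance, for comparison against the golden ratio 1.618. The two
#' distances are taken as explicit caller-supplied measurements (they are
#' separate linear measurements on the subject, not derivable from the
#' width profile).
#'
#' @param anterior_distance,posterior_distance Positive reals in any common
#'   unit.
#' @return `posterior_distance / anterior_distance`.
#' @examples
#' golden_ratio_index(4.794, 7.183)  # 1.498...
#' @export
golden_ratio_index <- function(anterior_distance, posterior_distance) {
  if (!is.numeric(anterior_distance) || !is.numeric(posterior_distance) ||
      length(anterior_distance) != 1L || length(posterior_distance) != 1L ||
      !is.finite(anterior_distance) || !is.finite(posterior_distance) ||
      anterior_distance <= 0 || posterior_distance <= 0) {
    stop("both labial distances must be finite and > 0", call. = FALSE)
  }
  unname(posterior_distance / anterior_distance)
}

#' Left-right asymmetry features
#'
#' Per-segment signed asymmetry `L_k - R_k` (positive when the left side is
#' wider at that level) and its summary, the mean absolute difference over
#' the nine segments. Zero everywhere for a perfectly symmetric subject.
#'
#' @param profile A [width_profile()] object.
#' @return A list with `asymmetry` (numeric length 9, names `asym_1..9`)
#'   and `asymmetry_summary` (mean of `|L_k - R_k|`).
#' @export
asymmetry_features <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  a <- profile$L - profile$R
  names(a) <- paste0("asym_", 1:9)
  list(asymmetry = a, asymmetry_summary = mean(abs(a)))
}

#' All derived features for one subject
#'
#' Convenience wrapper computing the full per-subject feature set from a
#' width profile: both adjacent-ratio vectors, the prominence zone and
#' argmax segment, the asymmetry vector and its summary, and (when the two
#' labial distances are supplied) the golden-ratio index per side.
#'
#' @param profile A [width_profile()] object.
#' @param golden_left,golden_right Optional numeric `c(anterior, posterior)`
#'   distance pairs for the golden-ratio index.
#' @return A list of class `"feature_set"`.
#' @export
subject_features <- function(profile, golden_left = NULL, golden_right = NULL) {
  ratios <- adjacent_ratios(profile)
  prom <- prominence_class(profile)
  asym <- asymmetry_features(profile)
  gr <- function(g) if (is.null(g)) NA_real_ else golden_ratio_index(g[1], g[2])
  structure(
    list(subject_id = profile$subject_id,
         L_ratios = ratios$L_ratios, R_ratios = ratios$R_ratios,
         prominence_zone = prom$zone, argmax_segment = prom$argmax_segment,
         asymmetry = asym$asymmetry,
         asymmetry_summary = asym$asymmetry_summary,
         golden_ratio_left = gr(golden_left),
         golden_ratio_right = gr(golden_right)),
    class = "feature_set"
  )
}
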