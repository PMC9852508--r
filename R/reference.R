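#' Reference cohort mean width profile
#'
#' Per-segment mean widths (axis-tenth units) of a 400-subject adult
#' reference cohort, the package's canonical average shape. These are the
#' default generator means of [sim_params()] and the input for the worked
#' examples.
#'
#' @return A list with numeric vectors `L` and `R` (length 9, names
#'   `L1..L9` / `R1..R9`) and `n` (400).
#' @examples
#' reference_means()$L[["L4"]]  # 3.333
#' @export
reference_means <- function() {
  L <- c(1.137, 2.314, 3.039, 3.333, 3.196, 2.784, 2.059, 1.784, 1.314)
  R <- c(0.941, 2.235, 3.059, 3.078, 2.843, 2.314, 1.765, 1.412, 0.941)
  names(L) <- paste0("L", 1:9)
  names(R) <- paste0("R", 1:9)
  list(L = L, R = R, n = 400L)
}

#' Reference labial distances for the golden-ratio index
#'
#' Anterior and posterior labial distances of the reference cohort's
#' average shape, per side, as used by [golden_ratio_index()]. The left
#' side's posterior/anterior ratio (1.498) is close to the golden ratio
#' 1.618.
#'
#' @return A list with `left` and `right`, each `c(anterior, posterior)`.
#' @export
reference_labial_distances <- function() {
  list(left = c(anterior = 4.794, posterior = 7.183),
       right = c(anterior = 5.200, posterior = 6.942))
}
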