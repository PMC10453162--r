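#' Mean background-subtracted stain intensity
#'
#' Mean intensity over the stain (membrane) mask minus the background,
#' estimated as the median intensity outside the mask. This is the
#' continuous "gray levels" readout reported for cell lines; tissue cores
#' additionally bin it into the 0-3 semiquantitative score.
#'
#' @param channel 2-D intensity matrix.
#' @param mask logical matrix of stained pixels (same shape, nonempty).
#' @return Mean background-subtracted gray level (floored at 0).
#' @export
mean_intensity <- function(channel, mask) {
  if (!identical(dim(channel), dim(mask)))
    stop("channel and mask shapes differ", call. = FALSE)
  if (!any(mask)) stop("stain mask is empty", call. = FALSE)
  bg <- if (all(mask)) 0 else stats::median(channel[!mask])
  max(0, mean(channel[mask]) - bg)
}

#' Default E-cadherin score cutpoints
#'
#' Midpoints between the synthetic generator's membrane amplitudes per level
#' (8, 70, 140, 210 gray levels), giving well-separated bins that recover
#' the generating level exactly. For real images the cutpoints are a
#' calibration input the user must supply - absolute gray levels are
#' instrument-specific.
#'
#' @return Three ascending gray-level cutpoints.
#' @export
default_ecad_edges <- function() {
  a <- ECAD_LEVEL_AMPLITUDE
  (a[-length(a)] + a[-1L]) / 2
}

#' Semiquantitative E-cadherin score
#'
#' Bins a mean membranous gray level into the 0-3 score: 0 no staining,
#' 1 low-to-moderate, 2 moderate-to-high, 3 high. The score is the number of
#' cutpoints strictly below the value, so a value exactly at an edge falls
#' in the lower bin.
#'
#' @param mean_gray background-subtracted mean gray level.
#' @param bin_edges three strictly increasing cutpoints.
#' @return Integer score 0-3 (vectorized over `mean_gray`).
#' @export
score_intensity <- function(mean_gray, bin_edges = default_ecad_edges()) {
  if (length(bin_edges) != 3L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be three strictly increasing cutpoints", call. = FALSE)
  vapply(mean_gray, function(v) sum(bin_edges < v), numeric(1))
}

#' Distribution of E-cadherin scores across a cohort
#'
#' @param scores integer vector of 0-3 scores.
#' @return A data frame with one row per score 0-3: `score`, `n`, `percent`
#'   (percentages sum to 100 up to rounding).
#' @export
score_distribution <- function(scores) {
  if (!length(scores)) stop("no scores supplied", call. = FALSE)
  if (any(!scores %in% 0:3)) stop("scores must be in 0..3", call. = FALSE)
  n <- vapply(0:3, function(s) sum(scores == s), numeric(1))
  data.frame(score = 0:3, n = as.integer(n), percent = 100 * n / sum(n))
}

#' Measure and score one synthetic tissue core
#'
#' @param core result of [generate_tissue_core()].
#' @param bin_edges score cutpoints, default [default_ecad_edges()].
#' @return A list with `mean_gray` and `score`.
#' @export
measure_core_ecad <- function(core, bin_edges = default_ecad_edges()) {
  mg <- mean_intensity(core$image, core$membrane_mask)
  list(mean_gray = mg, score = score_intensity(mg, bin_edges))
}
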