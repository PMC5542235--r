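#' Gray-level histogram of the tumor region
#'
#' Counts masked pixels into 256 unit-width bins (one per gray value 0--255)
#' and normalizes to a probability function. The image must already be
#' normalized so that bins are meaningful discrete gray levels.
#'
#' @param img a normalized [roi_image()].
#' @return An object of class `intensity_histogram`: list with `p` (length
#'   256, sums to 1; `p[v + 1]` is the probability of gray value `v`) and
#'   `n_pixels`.
#' @export
compute_histogram <- function(img) {
  stopifnot(inherits(img, "roi_image"))
  if (!img$normalized)
    stop("precondition error: image must be normalized to 0-255 first",
         call. = FALSE)
  v <- img$pixels[img$mask]
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(p = counts / length(v), n_pixels = length(v)),
            class = "intensity_histogram")
}

#' First four moments of an intensity histogram
#'
#' Mean, variance, skewness and kurtosis of the gray-value probability
#' function: mean = sum(v p(v)), variance the second central moment,
#' skewness the third standardized moment, kurtosis the fourth. Kurtosis is
#' reported as excess by default (normal limit -> 0); set
#' `kurtosis_excess = FALSE` for the Pearson convention (normal -> 3). A
#' zero-variance (constant) region returns 0 for both skewness and
#' kurtosis rather than failing, so degenerate ROIs stay usable.
#'
#' @param h an `intensity_histogram` from [compute_histogram()].
#' @param kurtosis_excess logical; subtract 3 from the fourth standardized
#'   moment (default `TRUE`).
#' @return Named vector `c(mean, variance, skewness, kurtosis)`.
#' @export
histogram_moments <- function(h, kurtosis_excess = TRUE) {
  stopifnot(inherits(h, "intensity_histogram"))
  v <- seq_along(h$p) - 1
  p <- h$p
  mu <- sum(v * p)
  m2 <- sum((v - mu)^2 * p)
  if (m2 == 0) {
    sk <- 0
    ku <- 0
  } else {
    sk <- sum((v - mu)^3 * p) / m2^1.5
    ku <- sum((v - mu)^4 * p) / m2^2 - if (kurtosis_excess) 3 else 0
  }
  c(mean = mu, variance = m2, skewness = sk, kurtosis = ku)
}

#' All intensity features of a ROI
#'
#' @param img a normalized [roi_image()].
#' @param kurtosis_excess passed to [histogram_moments()].
#' @return Named vector: `mean`, `variance`, `skewness`, `kurtosis`.
#' @export
intensity_features <- function(img, kurtosis_excess = TRUE) {
  histogram_moments(compute_histogram(img), kurtosis_excess = kurtosis_excess)
}
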